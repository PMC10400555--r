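#' Reference-hit filtering configuration
#'
#' Thresholds applied to a BLAST-style hit table before taxonomic
#' assignment: minimum query coverage and identity (both 98 percent,
#' inclusive), a maximum e-value, removal of hits to entries without
#' species-rank names, removal of species whose hit count is under a
#' fraction of that species' database entries (a guard against
#' misannotated reference entries), and removal of species represented
#' by a single database entry.
#'
#' @param min_coverage Minimum query coverage percent (98).
#' @param min_identity Minimum identity percent (98).
#' @param max_evalue Maximum e-value (1e-10).
#' @param min_entry_fraction Minimum hits-for-species over database
#'   entries for that species (0.01).
#' @param drop_single_entry_species Drop species with a single database
#'   entry (TRUE).
#' @param drop_supraspecific Drop hits whose name is not a clean Latin
#'   binomial, e.g. "Carcharhinus sp." or "unidentified shark" (TRUE).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 98, min_identity = 98,
                          max_evalue = 1e-10, min_entry_fraction = 0.01,
                          drop_single_entry_species = TRUE,
                          drop_supraspecific = TRUE) {
  stopifnot(min_coverage >= 0, min_coverage <= 100,
            min_identity >= 0, min_identity <= 100,
            max_evalue > 0, min_entry_fraction >= 0, min_entry_fraction <= 1)
  structure(list(min_coverage = min_coverage, min_identity = min_identity,
                 max_evalue = max_evalue,
                 min_entry_fraction = min_entry_fraction,
                 drop_single_entry_species = drop_single_entry_species,
                 drop_supraspecific = drop_supraspecific),
            class = "filter_config")
}

# a clean Latin binomial: "Genus epithet", no rank placeholders
.is_species_rank <- function(x) {
  grepl("^[A-Z][a-z]+ [a-z]+$", x) &
    !(sub("^\\S+ ", "", x) %in% c("sp", "spp", "cf", "aff"))
}

#' Filter a reference hit table
#'
#' Applies every clause of a [filter_config()] to a hit table with
#' columns `query`, `species`, `db`, `identity`, `coverage`, `evalue`,
#' `species_db_entries`. The per-(query, species) hit count
#' `hits_for_species` is derived from the input table if absent and is
#' preserved in the output, which makes the operation idempotent and
#' order-independent.
#'
#' @param hits Data frame of hit records.
#' @param cfg A [filter_config()].
#' @return The surviving rows, with a `hits_for_species` column.
#' @export
filter_hits <- function(hits, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  need <- c("query", "species", "identity", "coverage", "evalue",
            "species_db_entries")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(hits) == 0) return(cbind(hits, hits_for_species = integer(0)))
  bad <- which(is.na(hits$species_db_entries))
  if (length(bad))
    stop("missing species_db_entries in hit table row(s): ",
         paste(head(bad, 5), collapse = ", "))
  if (is.null(hits$hits_for_species)) {
    key <- paste(hits$query, hits$species, sep = "\r")
    hits$hits_for_species <- as.integer(table(key)[key])
  }
  keep <- hits$coverage >= cfg$min_coverage &
    hits$identity >= cfg$min_identity &
    hits$evalue <= cfg$max_evalue &
    hits$hits_for_species / hits$species_db_entries >= cfg$min_entry_fraction
  if (cfg$drop_single_entry_species)
    keep <- keep & hits$species_db_entries > 1
  if (cfg$drop_supraspecific)
    keep <- keep & .is_species_rank(hits$species)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a species from filtered hits for one query
#'
#' Chooses the species maximising, lexicographically, best identity,
#' then best coverage, then per-species hit support; remaining ties are
#' broken alphabetically and flagged as ambiguous. A best-supported
#' species on the exclusion list (a co-ingredient of a mixed product,
#' e.g. pig in a pork-and-prawn dumpling) yields
#' `contamination_excluded`.
#'
#' @param hits Filtered hit rows for a single query (see
#'   [filter_hits()]).
#' @param exclusion Character vector of species to treat as expected
#'   co-ingredient contamination for this product.
#' @param sample_id Identifier carried into the call.
#' @return One-row data frame: `sample_id`, `status`, `species`,
#'   `supporting_hits`, `ambiguous`.
#' @export
assign_species <- function(hits, exclusion = character(),
                           sample_id = NA_character_) {
  call <- function(status, species = NA_character_, support = 0L,
                   ambiguous = FALSE)
    data.frame(sample_id = sample_id, status = status, species = species,
               supporting_hits = as.integer(support), ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0) return(call("no_hits"))
  if (is.null(hits$hits_for_species))
    hits$hits_for_species <- as.integer(table(hits$species)[hits$species])
  agg <- do.call(rbind, lapply(split(hits, hits$species), function(h)
    data.frame(species = h$species[1],
               identity = max(h$identity),
               coverage = max(h$coverage),
               support = max(h$hits_for_species),
               stringsAsFactors = FALSE)))
  agg <- agg[order(-agg$identity, -agg$coverage, -agg$support, agg$species), ]
  top <- agg[1, ]
  tied <- sum(agg$identity == top$identity & agg$coverage == top$coverage &
                agg$support == top$support)
  if (top$species %in% exclusion) return(call("contamination_excluded"))
  call("assigned", top$species, top$support, ambiguous = tied >= 2)
}
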