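#' Label-to-species reference tables
#'
#' A `label_reference` bundles (i) a taxonomy table (species, genus, family,
#' higher-group tags, synonyms) and (ii) a long-format label-definition
#' table mapping each market-label term, under each named definition
#' regime, to the set of species it may legitimately denote. Synonyms are
#' resolved to accepted names at load time so all downstream comparison is
#' on accepted scientific names.
#'
#' Regimes are alternative label-to-species definitions: `comprehensive`
#' (umbrella terms cover every species sold under them in practice),
#' `afns` (the stricter standard-names definition), and two single-term
#' variants, `strict_flake` (the term "flake" means only *Mustelus
#' antarcticus* and *M. lenticulatus*) and `lenient_flake` ("flake"
#' additionally admits holocephalans). A term whose species column is
#' `"*"` is a universal generic ("fish", "fillet"): it resolves to the
#' whole taxonomy and can never be mislabelled.
#'
#' @param entries Data frame with columns `term`, `regime`, `species`.
#' @param taxonomy Data frame with columns `species`, `genus`, `family`,
#'   `tags` (semicolon-separated), `synonyms` (semicolon-separated, may be
#'   empty).
#' @return An object of class `label_reference`.
#' @export
label_reference <- function(entries, taxonomy) {
  stopifnot(all(c("term", "regime", "species") %in% names(entries)),
            all(c("species", "genus", "family") %in% names(taxonomy)))
  if (is.null(taxonomy$tags)) taxonomy$tags <- ""
  if (is.null(taxonomy$synonyms)) taxonomy$synonyms <- ""
  taxonomy$species <- trimws(taxonomy$species)
  if (anyDuplicated(taxonomy$species))
    stop("duplicate species in taxonomy: ",
         paste(unique(taxonomy$species[duplicated(taxonomy$species)]),
               collapse = ", "))

  syn_map <- setNames(taxonomy$species, .squash(taxonomy$species))
  has_syn <- nzchar(taxonomy$synonyms)
  if (any(has_syn)) {
    syns <- strsplit(taxonomy$synonyms[has_syn], ";", fixed = TRUE)
    extra <- setNames(rep(taxonomy$species[has_syn], lengths(syns)),
                      .squash(trimws(unlist(syns))))
    syn_map <- c(syn_map, extra)
  }

  entries$term <- vapply(entries$term, normalise_label, "", syn_map = NULL)
  entries$species <- trimws(entries$species)
  star <- entries$species == "*"
  entries$species[!star] <-
    .resolve_syn(entries$species[!star], syn_map, where = "label table")
  unknown <- !star & !(entries$species %in% taxonomy$species)
  if (any(unknown))
    stop("label table species absent from taxonomy: ",
         paste(unique(entries$species[unknown]), collapse = ", "))
  entries <- unique(entries[c("term", "regime", "species")])

  structure(
    list(entries = entries, taxonomy = taxonomy, syn_map = syn_map,
         regimes = sort(unique(entries$regime))),
    class = "label_reference"
  )
}

.resolve_syn <- function(x, syn_map, where = "input") {
  key <- .squash(x)
  hit <- syn_map[key]
  miss <- is.na(hit)
  hit[miss] <- x[miss]
  unname(hit)
}

#' @export
print.label_reference <- function(x, ...) {
  cat("<label_reference>", nrow(x$taxonomy), "species,",
      length(unique(x$entries$term)), "terms,",
      "regimes:", paste(x$regimes, collapse = ", "), "\n")
  invisible(x)
}

#' Load a label reference from CSV files
#'
#' @param entries_csv Path to a CSV with columns term, regime, species.
#' @param taxonomy_csv Path to a CSV with columns species, genus, family,
#'   tags, synonyms.
#' @return A [label_reference()] object.
#' @export
load_label_reference <- function(entries_csv, taxonomy_csv) {
  label_reference(
    read.csv(entries_csv, stringsAsFactors = FALSE),
    read.csv(taxonomy_csv, stringsAsFactors = FALSE)
  )
}

#' Demonstration label reference
#'
#' Loads the small synthetic label-to-species table and taxonomy shipped
#' with the package. It covers the six market seafood groups (hoki,
#' prawns, sharks and rays, snapper, squid and cuttlefish, tuna) with
#' umbrella, family, genus and species-level terms, all four definition
#' regimes, and the holocephalan/selachimorph distinction that the flake
#' regimes hinge on. It is a demonstration table, far smaller than a
#' real curated reference.
#'
#' @return A [label_reference()] object.
#' @export
demo_label_reference <- function() {
  load_label_reference(
    system.file("extdata", "demo_label_definitions.csv",
                package = "labelaudit", mustWork = TRUE),
    system.file("extdata", "demo_taxonomy.csv",
                package = "labelaudit", mustWork = TRUE)
  )
}

#' Normalise a raw label string to a canonical term
#'
#' Lowercases, collapses whitespace and punctuation, and strips plural
#' "s" from words (leaving short words and words in "-ss" alone). A
#' string that is exactly a two-token Latin binomial is resolved through
#' the synonym map to its accepted scientific name instead, preserving
#' capitalisation of the genus.
#'
#' @param x Raw label string.
#' @param syn_map Named character vector mapping squashed synonyms to
#'   accepted names, or NULL to skip scientific-name resolution. A
#'   [label_reference()] may be passed instead.
#' @return Canonical term (lowercase) or accepted scientific name.
#' @export
#' @examples
#' normalise_label("Gummy  Sharks")
normalise_label <- function(x, syn_map = NULL) {
  stopifnot(is.character(x), length(x) == 1, nzchar(trimws(x)))
  if (inherits(syn_map, "label_reference")) syn_map <- syn_map$syn_map
  raw <- gsub("\\s+", " ", trimws(x))
  if (grepl("^[A-Z][a-z]+ [a-z]+$", raw)) {
    if (!is.null(syn_map)) {
      hit <- syn_map[.squash(raw)]
      if (!is.na(hit)) return(unname(hit))
    }
    return(raw)
  }
  low <- tolower(raw)
  low <- gsub("[^a-z0-9 ]+", " ", low)
  low <- gsub("\\s+", " ", trimws(low))
  toks <- strsplit(low, " ", fixed = TRUE)[[1]]
  deplural <- function(t)
    if (nchar(t) >= 4 && grepl("s$", t) && !grepl("ss$", t))
      sub("s$", "", t) else t
  paste(vapply(toks, deplural, ""), collapse = " ")
}

#' Resolve a label term to its permitted species set
#'
#' @param label Raw or normalised label string.
#' @param regime One of the reference's definition regimes.
#' @param ref A [label_reference()].
#' @return Character vector of accepted species names. Attributes:
#'   `unknown` (TRUE when the term is not in the table and not a known
#'   scientific name — the empty set is returned, never treated as
#'   silently mislabelled), `universal` (TRUE for generic terms such as
#'   "fish" that denote the whole taxonomy).
#' @export
resolve_label <- function(label, regime, ref) {
  stopifnot(inherits(ref, "label_reference"))
  if (!regime %in% ref$regimes)
    stop("unknown definition regime: ", regime,
         " (configured: ", paste(ref$regimes, collapse = ", "), ")")
  term <- normalise_label(label, ref$syn_map)
  if (term %in% ref$taxonomy$species)   # scientific name on the label
    return(structure(term, unknown = FALSE, universal = FALSE))
  rows <- ref$entries[ref$entries$term == term &
                      ref$entries$regime == regime, "species"]
  if (length(rows) == 0)
    return(structure(character(0), unknown = TRUE, universal = FALSE))
  if (any(rows == "*"))
    return(structure(sort(ref$taxonomy$species),
                     unknown = FALSE, universal = TRUE))
  structure(sort(unique(rows)), unknown = FALSE, universal = FALSE)
}

#' Specificity level names, coarsest first
#'
#' Ordinal coding used throughout: higher taxonomic level = 1, family =
#' 2, genus = 3, species = 4. Larger codes mean more specific labels.
#' @export
specificity_levels <- c(higher = 1L, family = 2L, genus = 3L, species = 4L)

#' Classify the taxonomic specificity of a permitted species set
#'
#' The finest rank shared by every species in the set defines the label's
#' specificity: a singleton is species level (4); one genus, genus level
#' (3); one family, family level (2); otherwise higher taxonomic level
#' (1). Universal generic sets are higher level by construction.
#'
#' @param species_set Character vector of accepted species names (the
#'   result of [resolve_label()]).
#' @param ref A [label_reference()].
#' @return Integer specificity code in 1..4, or `NA` with attribute
#'   `unclassifiable = TRUE` for an empty set.
#' @export
classify_specificity <- function(species_set, ref) {
  stopifnot(inherits(ref, "label_reference"))
  if (length(species_set) == 0)
    return(structure(NA_integer_, unclassifiable = TRUE))
  if (isTRUE(attr(species_set, "universal")))
    return(specificity_levels[["higher"]])
  tax <- ref$taxonomy
  idx <- match(species_set, tax$species)
  if (anyNA(idx)) stop("species not in taxonomy: ",
                       paste(species_set[is.na(idx)], collapse = ", "))
  if (length(species_set) == 1) return(specificity_levels[["species"]])
  if (length(unique(tax$genus[idx])) == 1) return(specificity_levels[["genus"]])
  if (length(unique(tax$family[idx])) == 1) return(specificity_levels[["family"]])
  specificity_levels[["higher"]]
}

#' Lint the label reference tables
#'
#' Reports taxonomy species unreachable from any label term (orphans),
#' duplicated (term, regime) entries, terms missing from some regimes,
#' and species tagged with contradictory higher groups (a species cannot
#' be both a selachimorph and a holocephalan).
#'
#' @param ref A [label_reference()].
#' @return List with elements `orphan_species`, `missing_regimes` (data
#'   frame of term x regime gaps), `tag_conflicts`; all empty when the
#'   tables are clean.
#' @export
lint_label_tables <- function(ref) {
  stopifnot(inherits(ref, "label_reference"))
  reachable <- unique(ref$entries$species[ref$entries$species != "*"])
  if (any(ref$entries$species == "*")) reachable <- ref$taxonomy$species
  orphans <- setdiff(ref$taxonomy$species, reachable)

  terms <- unique(ref$entries$term)
  grid <- expand.grid(term = terms, regime = ref$regimes,
                      stringsAsFactors = FALSE)
  present <- paste(ref$entries$term, ref$entries$regime)
  missing <- grid[!(paste(grid$term, grid$regime) %in% present), ]

  tags <- strsplit(ref$taxonomy$tags, ";", fixed = TRUE)
  conflict <- vapply(tags, function(t)
    all(c("selachimorph", "holocephalan") %in% trimws(t)), logical(1))

  list(orphan_species = orphans,
       missing_regimes = missing[order(missing$term, missing$regime), ],
       tag_conflicts = ref$taxonomy$species[conflict])
}

# internal: species carrying a tag
.tagged_species <- function(ref, tag) {
  hit <- vapply(strsplit(ref$taxonomy$tags, ";", fixed = TRUE),
                function(t) tag %in% trimws(t), logical(1))
  ref$taxonomy$species[hit]
}
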