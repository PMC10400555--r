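#' Study design for the synthetic market survey
#'
#' Encodes the sampling frame the generator emulates: a national survey
#' of 672 products, 96 per state across seven states, six seafood
#' groups in fixed proportions, three outlet types, an exact 50:50
#' domestic:imported split within each state, per-group label
#' specificity mixes, per-(group x specificity) true substitution
#' probabilities, and log-uniform prices over the observed market range
#' with a small completely-at-random missing fraction.
#'
#' All stratum allocations are integer and exact for any seed
#' (largest-remainder rounding, ties broken by lexicographic stratum
#' name); only the cross-classification of strata and the per-product
#' draws are random.
#'
#' @param n_states Number of states (7).
#' @param samples_per_state Products per state (96).
#' @param states State names; length must equal `n_states`.
#' @param group_mix Named probability vector over the six seafood
#'   groups; defaults reproduce the surveyed group sizes 106, 116, 97,
#'   112, 128, 113 of 672.
#' @param outlet_mix Named probability vector over fishmonger,
#'   restaurant, supermarket; defaults reproduce 196, 238, 238 of 672.
#' @param origin_split Probability a product is domestic (0.5, exact
#'   within each state).
#' @param specificity_mix Matrix (group x 4 levels, coarsest first) of
#'   label-specificity probabilities per group.
#' @param true_mislabel_prob Matrix (group x 4 levels) of substitution
#'   probabilities: the chance the product's true species lies outside
#'   the species set its label permits under the comprehensive regime.
#' @param group_terms List: for each group, a list of 4 character
#'   vectors of label terms usable at each specificity level (repeat a
#'   term to weight it).
#' @param confusion List: for each group, preferred out-of-group
#'   substitute species (e.g. holocephalans for flake, tilapia and
#'   barramundi for snapper). When every preferred substitute is inside
#'   the label's permitted set, a uniform draw from all out-of-set
#'   species is used instead.
#' @param price_range Price per kg interval in dollars (3.43 to 299.90).
#' @param missing_price_frac Fraction of prices missing at random (0.055).
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return List of class `study_design`.
#' @export
study_design <- function(
    n_states = 7L,
    samples_per_state = 96L,
    states = c("NSW", "NT", "QLD", "SA", "TAS", "VIC", "WA"),
    group_mix = c(hoki = 106, prawns = 116, sharks_rays = 97,
                  snapper = 112, squid_cuttlefish = 128, tuna = 113) / 672,
    outlet_mix = c(fishmonger = 196, restaurant = 238, supermarket = 238) / 672,
    origin_split = 0.5,
    specificity_mix = NULL,
    true_mislabel_prob = NULL,
    group_terms = NULL,
    confusion = NULL,
    price_range = c(3.43, 299.90),
    missing_price_frac = 0.055,
    seed = 1L) {
  groups <- names(group_mix)
  lv <- names(specificity_levels)
  if (is.null(specificity_mix)) {
    specificity_mix <- rbind(
      hoki            = c(0.000, 0.075, 0.370, 0.555),
      prawns          = c(0.000, 0.600, 0.200, 0.200),
      sharks_rays     = c(0.794, 0.050, 0.100, 0.056),
      snapper         = c(0.571, 0.100, 0.150, 0.179),
      squid_cuttlefish = c(0.805, 0.080, 0.060, 0.055),
      tuna            = c(0.000, 0.300, 0.134, 0.566))
    colnames(specificity_mix) <- lv
  }
  if (is.null(true_mislabel_prob)) {
    true_mislabel_prob <- rbind(
      hoki            = c(0.02, 0.01, 0.01, 0.01),
      prawns          = c(0.05, 0.02, 0.02, 0.01),
      sharks_rays     = c(0.40, 0.20, 0.15, 0.05),
      snapper         = c(0.30, 0.10, 0.15, 0.05),
      squid_cuttlefish = c(0.14, 0.05, 0.05, 0.02),
      tuna            = c(0.08, 0.05, 0.03, 0.02))
    colnames(true_mislabel_prob) <- lv
  }
  if (is.null(group_terms))
    group_terms <- list(
      hoki = list(character(0), "grenadier", "hoki", "blue grenadier"),
      prawns = list(character(0), "prawn", "king prawn",
                    c("tiger prawn", "banana prawn", "endeavour prawn")),
      sharks_rays = list(c("flake", "flake", "shark", "stingray"),
                         "whaler shark", "gummy shark",
                         c("school shark", "sandbar shark",
                           "smooth hammerhead", "elephant fish")),
      snapper = list("snapper", "sea bream", "red snapper",
                     c("pink snapper", "saddletail snapper")),
      squid_cuttlefish = list(c("squid", "calamari"), "arrow squid",
                              "cuttlefish",
                              c("southern calamari", "giant cuttlefish")),
      tuna = list(character(0), "tuna", "bluefin tuna",
                  c("skipjack tuna", "yellowfin tuna",
                    "southern bluefin tuna", "atlantic bluefin tuna")))
  if (is.null(confusion))
    confusion <- list(
      hoki = "Merluccius australis",
      prawns = "Penaeus vannamei",
      sharks_rays = c("Callorhinchus milii", "Callorhinchus capensis",
                      "Callorhinchus callorynchus"),
      snapper = c("Oreochromis niloticus", "Oreochromis mossambicus",
                  "Lates calcarifer", "Protonibea diacanthus",
                  "Parupeneus cyclostomus"),
      squid_cuttlefish = "Octopus tetricus",
      tuna = "Gadus chalcogrammus")

  design <- structure(
    list(n_states = as.integer(n_states),
         samples_per_state = as.integer(samples_per_state),
         states = states, groups = groups, group_mix = group_mix,
         outlet_mix = outlet_mix, origin_split = origin_split,
         specificity_mix = specificity_mix,
         true_mislabel_prob = true_mislabel_prob,
         group_terms = group_terms, confusion = confusion,
         price_range = price_range,
         missing_price_frac = missing_price_frac,
         seed = as.integer(seed)),
    class = "study_design")
  validate_design(design)
  design
}

#' Validate a study design
#'
#' Checks the invariants: probability vectors sum to one (to 1e-12),
#' matrices cover every group and all four specificity levels,
#' probabilities lie in \[0, 1\], and the price range is positive and
#' increasing.
#'
#' @param design A [study_design()].
#' @return The design, invisibly; errors name the offending component.
#' @export
validate_design <- function(design) {
  ok1 <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-12)
      stop(what, " must sum to 1 (got ", sum(p), ")")
    if (any(p < 0)) stop(what, " has negative entries")
  }
  ok1(design$group_mix, "group_mix")
  ok1(design$outlet_mix, "outlet_mix")
  stopifnot(length(design$states) == design$n_states,
            design$origin_split >= 0, design$origin_split <= 1,
            design$price_range[1] > 0,
            design$price_range[2] > design$price_range[1],
            design$missing_price_frac >= 0, design$missing_price_frac <= 1)
  for (g in design$groups) {
    ok1(design$specificity_mix[g, ], paste0("specificity_mix[", g, "]"))
    p <- design$true_mislabel_prob[g, ]
    if (any(p < 0 | p > 1))
      stop("true_mislabel_prob[", g, "] outside [0, 1]")
  }
  invisible(design)
}

#' Generate a synthetic product table and its ground truth
#'
#' Draws one survey according to the design. Stratum counts (state,
#' origin within state, groups and outlets within state) are exact by
#' integer allocation; label specificity, label term, substitution
#' status, true species, prices, and the market covariates are random.
#' A substituted product's true species is guaranteed to lie outside
#' the species set its label permits under the comprehensive regime (the
#' group's confusion pool is preferred, any out-of-set species is the
#' fallback), and a non-substituted product's species is drawn from
#' inside that set, so `truth$substituted` matches the comprehensive
#' adjudication by construction.
#'
#' @param design A [study_design()].
#' @param ref A [label_reference()]; defaults to the demo reference.
#' @return List with `products` (one row per purchased product) and
#'   `truth` (sample_id, true_species, substituted,
#'   substitution_source).
#' @export
generate_products <- function(design, ref = demo_label_reference()) {
  validate_design(design)
  set.seed(design$seed)
  lv_names <- names(specificity_levels)

  # per-state exact allocations, cross-classified by seeded shuffles
  one_state <- function(st) {
    n <- design$samples_per_state
    gcount <- largest_remainder(design$group_mix, n)
    ocount <- largest_remainder(design$outlet_mix, n)
    ocount_v <- rep(names(ocount), ocount)
    dom <- largest_remainder(
      c(domestic = design$origin_split, imported = 1 - design$origin_split), n)
    data.frame(state = st,
               seafood_group = rep(names(gcount), gcount),
               outlet_type = sample(ocount_v),
               origin = sample(rep(names(dom), dom)),
               stringsAsFactors = FALSE)
  }
  prod <- do.call(rbind, lapply(design$states, one_state))
  n <- nrow(prod)
  prod$sample_id <- sprintf("P%04d", seq_len(n))

  # specificity level and label term, drawn per group
  prod$level <- NA_integer_
  prod$term <- NA_character_
  for (g in design$groups) {
    idx <- which(prod$seafood_group == g)
    mix <- design$specificity_mix[g, ]
    feasible <- vapply(design$group_terms[[g]], length, 0L) > 0
    bad <- which(mix > 0 & !feasible)
    if (length(bad))
      stop("infeasible design: group '", g, "' requests specificity level '",
           lv_names[bad[1]], "' but has no label term at that level")
    prod$level[idx] <- sample(1:4, length(idx), replace = TRUE, prob = mix)
    for (l in 1:4) {
      li <- idx[prod$level[idx] == l]
      if (length(li))
        prod$term[li] <- sample(design$group_terms[[g]][[l]], length(li),
                                replace = TRUE)
    }
  }

  # substitution and true species, per distinct term
  all_species <- ref$taxonomy$species
  edible <- setdiff(all_species, .tagged_species(ref, "mammal"))
  prod$substituted <- rbinom(n, 1,
    design$true_mislabel_prob[cbind(prod$seafood_group,
                                    lv_names[prod$level])]) == 1
  prod$true_species <- NA_character_
  prod$sub_source <- "none"
  group_pool <- lapply(design$groups, function(g) {
    terms <- unlist(design$group_terms[[g]])
    unique(unlist(lapply(unique(terms), resolve_label,
                         regime = "comprehensive", ref = ref)))
  })
  names(group_pool) <- design$groups
  for (tm in unique(prod$term)) {
    permitted <- resolve_label(tm, "comprehensive", ref)
    if (isTRUE(attr(permitted, "unknown")))
      stop("generator label term not in reference table: ", tm)
    idx <- which(prod$term == tm)
    ok_i <- idx[!prod$substituted[idx]]
    if (length(ok_i))
      prod$true_species[ok_i] <- sample(rep(permitted, 2), length(ok_i),
                                        replace = TRUE)
    sub_i <- idx[prod$substituted[idx]]
    if (length(sub_i)) {
      if (isTRUE(attr(permitted, "universal")))
        stop("infeasible design: term '", tm,
             "' is universal but has positive substitution probability")
      g <- prod$seafood_group[sub_i[1]]
      pool <- setdiff(design$confusion[[g]], permitted)
      if (length(pool) == 0) pool <- setdiff(edible, permitted)
      if (length(pool) == 0)
        stop("no substitute species available outside the set of term '",
             tm, "'")
      prod$true_species[sub_i] <- sample(rep(pool, 2), length(sub_i),
                                         replace = TRUE)
      within <- prod$true_species[sub_i] %in% group_pool[[g]]
      prod$sub_source[sub_i] <- ifelse(within, "within_group", "out_of_group")
    }
  }

  # label strings: capitalised term; species-level labels sometimes carry
  # the scientific name as the maximum level of detail
  cap <- function(x) gsub("(^|\\s)([a-z])", "\\1\\U\\2", x, perl = TRUE)
  prod$label_main <- cap(prod$term)
  plural <- runif(n) < 0.10 & !grepl("s$", prod$term)
  prod$label_main[plural] <- paste0(prod$label_main[plural], "s")
  prod$label_max_detail <- cap(prod$term)
  sci <- which(prod$level == 4 & runif(n) < 0.25)
  for (i in sci) {
    s <- resolve_label(prod$term[i], "comprehensive", ref)
    if (length(s) == 1) prod$label_max_detail[i] <- s
  }

  # market covariates
  prod$price_per_kg <- round(exp(runif(n, log(design$price_range[1]),
                                       log(design$price_range[2]))), 2)
  prod$price_per_kg[runif(n) < design$missing_price_frac] <- NA_real_
  prod$wild_or_farmed <- ifelse(runif(n) < 0.7, "wild", "farmed")
  prod$fresh_or_frozen <- ifelse(runif(n) < 0.5, "fresh", "frozen")
  prod$packaged <- runif(n) < ifelse(prod$outlet_type == "supermarket", 0.9, 0.2)
  prod$certified <- runif(n) < ifelse(prod$outlet_type == "supermarket", 0.3, 0.1)

  # vendor verbal claims, mostly at fishmongers and restaurants; a claim
  # names a species and is right only some of the time
  claim_p <- ifelse(prod$outlet_type == "supermarket", 0.02, 0.30)
  has_claim <- runif(n) < claim_p
  claim_right <- runif(n) < 0.55
  prod$vendor_claim <- NA_character_
  wrong_pool <- function(g) setdiff(group_pool[[g]], NA)
  for (i in which(has_claim)) {
    prod$vendor_claim[i] <- if (claim_right[i]) prod$true_species[i] else
      sample(setdiff(wrong_pool(prod$seafood_group[i]), prod$true_species[i]), 1)
  }

  truth <- data.frame(sample_id = prod$sample_id,
                      true_species = prod$true_species,
                      substituted = prod$substituted,
                      substitution_source = prod$sub_source,
                      stringsAsFactors = FALSE)
  keep <- c("sample_id", "state", "outlet_type", "seafood_group", "origin",
            "label_main", "label_max_detail", "vendor_claim", "price_per_kg",
            "wild_or_farmed", "fresh_or_frozen", "packaged", "certified")
  list(products = prod[keep], truth = truth)
}

# mutate a nucleotide vector at a given substitution rate
.mutate <- function(bases, rate) {
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- sample.int(3, length(hit), replace = TRUE)
    bases[hit] <- unlist(Map(function(b, k) alt[[b]][k], bases[hit], pick))
  }
  bases
}

#' Toy COI reference database
#'
#' Builds a deterministic synthetic reference-sequence set over the
#' taxonomy: one ancestral sequence per family, mutated per genus and
#' again per species, so congeners are a few percent divergent and
#' confamilials more so — enough structure for identity-based filtering
#' to be meaningful. Also assigns each species a database entry count,
#' with a configurable set of single-entry species to exercise the
#' low-confidence filter.
#'
#' @param ref A [label_reference()] supplying the taxonomy.
#' @param seq_len Reference sequence length in bases (650).
#' @param seed Integer seed (101).
#' @param genus_div,species_div Substitution rates applied per genus and
#'   per species (0.10, 0.04).
#' @param entries_range Range of database entry counts per species.
#' @param single_entry_species Species forced to a single database
#'   entry.
#' @return List with `seqs` (named character vector, one reference
#'   sequence per species) and `entries` (named integer vector of
#'   database entry counts).
#' @export
demo_refdb <- function(ref, seq_len = 650, seed = 101,
                       genus_div = 0.10, species_div = 0.04,
                       entries_range = c(3L, 60L),
                       single_entry_species = "Centroberyx gerrardi") {
  set.seed(seed)
  tax <- ref$taxonomy[order(ref$taxonomy$species), ]
  fam_seq <- list()
  gen_seq <- list()
  seqs <- character(nrow(tax))
  names(seqs) <- tax$species
  for (i in seq_len(nrow(tax))) {
    f <- tax$family[i]; g <- tax$genus[i]
    if (is.null(fam_seq[[f]]))
      fam_seq[[f]] <- sample(c("A", "C", "G", "T"), seq_len, replace = TRUE)
    if (is.null(gen_seq[[g]]))
      gen_seq[[g]] <- .mutate(fam_seq[[f]], genus_div)
    seqs[tax$species[i]] <- paste(.mutate(gen_seq[[g]], species_div),
                                  collapse = "")
  }
  entries <- sample(entries_range[1]:entries_range[2], nrow(tax),
                    replace = TRUE)
  names(entries) <- tax$species
  entries[intersect(single_entry_species, names(entries))] <- 1L
  list(seqs = seqs, entries = entries)
}

#' Simulate paired Sanger reads for each sample
#'
#' The forward read is a 5' subsequence of the true species' reference
#' with substitution errors at `error_rate`; the reverse read is the
#' reverse complement of an overlapping subsequence shifted by
#' `rev_offset`. Per-base Phred qualities are high over the read body
#' and decline over the final `tail_len` bases, giving the 3' window
#' trimmer something to do. Output is bit-reproducible given the seed.
#'
#' @param truth Truth table from [generate_products()].
#' @param refdb A [demo_refdb()] (or any list with `seqs`).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param read_len Read length before trimming (320).
#' @param rev_offset 5' offset of the reverse read's template (10).
#' @param tail_len Length of the declining-quality tail (40).
#' @return Read-pair data frame (see [write_read_pairs()]).
#' @export
generate_reads <- function(truth, refdb, error_rate = 0.002, seed = 1L,
                           read_len = 320L, rev_offset = 10L,
                           tail_len = 40L) {
  missing <- setdiff(unique(truth$true_species), names(refdb$seqs))
  if (length(missing))
    stop("species absent from reference database: ",
         paste(missing, collapse = ", "))
  short <- nchar(refdb$seqs[unique(truth$true_species)]) < 300
  if (any(short))
    stop("reference sequences shorter than 300 bases: ",
         paste(names(which(short)), collapse = ", "))
  set.seed(as.integer(seed))
  n <- nrow(truth)
  quals <- function(len) {
    q <- pmin(40L, pmax(2L, as.integer(round(rnorm(len, 37, 2)))))
    tl <- min(tail_len, len)
    if (tl > 0) {
      drop <- as.integer(round(seq(0, 25, length.out = tl)))
      idx <- (len - tl + 1):len
      q[idx] <- pmax(2L, q[idx] - drop)
    }
    q
  }
  fwd_seq <- character(n); rev_seq <- character(n)
  fwd_q <- vector("list", n); rev_q <- vector("list", n)
  for (i in seq_len(n)) {
    tmpl <- refdb$seqs[[truth$true_species[i]]]
    L <- nchar(tmpl)
    fl <- min(read_len, L)
    f <- strsplit(substr(tmpl, 1, fl), "", fixed = TRUE)[[1]]
    r_end <- min(rev_offset + read_len, L)
    r <- strsplit(substr(tmpl, rev_offset + 1, r_end), "", fixed = TRUE)[[1]]
    f <- .mutate(f, error_rate)
    r <- .mutate(r, error_rate)
    fwd_seq[i] <- paste(f, collapse = "")
    rev_seq[i] <- reverse_complement(paste(r, collapse = ""))
    fwd_q[[i]] <- quals(length(f))
    rev_q[[i]] <- quals(length(r))
  }
  data.frame(sample_id = truth$sample_id,
             forward_seq = fwd_seq, forward_qual = I(fwd_q),
             reverse_seq = rev_seq, reverse_qual = I(rev_q),
             stringsAsFactors = FALSE)
}

#' Emulate a reference-database search for consensus sequences
#'
#' Stands in for a BLAST run: each consensus is overlap-aligned against
#' every reference sequence; pairs whose alignment score reaches
#' `floor_frac` of the query length become hits. Each hit species
#' contributes a number of rows drawn from its database entry count (a
#' real search returns one row per matching entry), with identity and
#' coverage computed from the alignment and a monotone e-value proxy.
#' Optional `species_aliases` emit an outdated synonym as the database
#' label for one of the databases, mimicking reference-database synonym
#' drift.
#'
#' @param consensus Data frame from [consensus_pairs()] (rows with
#'   status `"ok"` and a non-empty sequence are searched), or a named
#'   character vector of sequences.
#' @param refdb A [demo_refdb()].
#' @param floor_frac Score floor as a fraction of query length (0.5).
#' @param hit_prob Probability each database entry of a matched species
#'   yields a row (0.9; at least one row is always emitted).
#' @param seed Integer seed for the per-entry row draws.
#' @param species_aliases Named character vector accepted -> database
#'   label, applied to BOLD rows.
#' @return Hit-record data frame (internal column names; see
#'   [filter_hits()]).
#' @export
generate_hit_table <- function(consensus, refdb, floor_frac = 0.5,
                               hit_prob = 0.9, seed = 1L,
                               species_aliases =
                                 c("Penaeus plebejus" = "Melicertus plebejus")) {
  if (is.data.frame(consensus)) {
    keep <- consensus$status == "ok" & nzchar(consensus$consensus)
    queries <- setNames(consensus$consensus[keep], consensus$sample_id[keep])
  } else queries <- consensus
  stopifnot(all(nzchar(queries)))
  set.seed(as.integer(seed))
  out <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    qlen <- nchar(q)
    rows <- list()
    for (sp in names(refdb$seqs)) {
      aln <- align_pair(q, refdb$seqs[[sp]], type = "overlap")
      if (aln$score < floor_frac * qlen) next
      st <- .alignment_stats(aln)
      n_entries <- unname(refdb$entries[[sp]])
      n_rows <- max(1L, rbinom(1, n_entries, hit_prob))
      db <- rep(c("NCBI", "BOLD"), length.out = n_rows)
      label <- ifelse(db == "BOLD" & sp %in% names(species_aliases),
                      unname(species_aliases[sp]), sp)
      rows[[sp]] <- data.frame(
        query = names(queries)[qi], species = label, db = db,
        identity = round(st$identity, 2), coverage = round(st$coverage, 2),
        evalue = max(10^(-aln$score / 2), 1e-180),
        species_db_entries = n_entries, stringsAsFactors = FALSE)
    }
    out[[qi]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(query = character(0), species = character(0),
                      db = character(0), identity = numeric(0),
                      coverage = numeric(0), evalue = numeric(0),
                      species_db_entries = integer(0))
  rownames(res) <- NULL
  res
}

# identity and query coverage from an overlap alignment: statistics are
# taken over the aligned core (first to last column where both
# sequences have a base)
.alignment_stats <- function(aln) {
  a <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  both <- which(a != "-" & b != "-")
  if (length(both) == 0) return(list(identity = 0, coverage = 0))
  core <- both[1]:both[length(both)]
  matches <- sum(a[core] == b[core] & a[core] != "-")
  list(identity = 100 * matches / length(core),
       coverage = 100 * sum(a[core] != "-") / sum(a != "-"))
}

#' Run the full synthetic study end to end
#'
#' Convenience wrapper: generates products and truth, simulates read
#' pairs, trims and calls consensus, emulates the reference search, and
#' assigns a species per sample.
#'
#' @param design A [study_design()].
#' @param ref A [label_reference()].
#' @param error_rate Sequencing substitution error rate.
#' @param trim_cfg,filter_cfg Trimming and hit-filter configurations.
#' @return List: `products`, `truth`, `pairs`, `consensus`, `hits`,
#'   `calls`.
#' @export
simulate_study <- function(design = study_design(),
                           ref = demo_label_reference(),
                           error_rate = 0.002,
                           trim_cfg = trim_config(),
                           filter_cfg = filter_config()) {
  gen <- generate_products(design, ref)
  refdb <- demo_refdb(ref)
  pairs <- generate_reads(gen$truth, refdb, error_rate = error_rate,
                          seed = design$seed)
  cons <- consensus_pairs(pairs, trim_cfg)
  hits <- generate_hit_table(cons, refdb, seed = design$seed)
  calls <- identify_samples(cons, hits, filter_cfg)
  c(gen, list(pairs = pairs, consensus = cons, hits = hits, calls = calls))
}
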