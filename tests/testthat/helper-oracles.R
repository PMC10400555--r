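# Independent oracles used by the property tests. These are written as
# plain-R re-derivations, structurally different from the package
# implementations they check.

# score-only dynamic programme for global / overlap alignment, filled
# row-by-row with vectorised pmax rather than the C++ cell loop
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2,
                            overlap = FALSE) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- if (overlap) rep(0, m + 1) else gap * (0:m)
  best_edge <- if (overlap) max(prev) else -Inf
  for (i in 1:n) {
    cur <- numeric(m + 1)
    cur[1] <- if (overlap) 0 else i * gap
    sub <- ifelse(x[i] == y, match, mismatch)
    for (j in 1:m) {
      cur[j + 1] <- max(prev[j] + sub[j], prev[j + 1] + gap, cur[j] + gap)
    }
    if (overlap) best_edge <- max(best_edge, cur[m + 1])
    prev <- cur
  }
  if (overlap) max(best_edge, max(prev)) else prev[m + 1]
}

# per-column consensus oracle: walks the two gapped strings with
# explicit quality cursors
consensus_oracle <- function(aligned_a, aligned_b, qa, qb) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  out <- character(0)
  i <- 0; j <- 0
  for (k in seq_along(a)) {
    if (a[k] != "-") i <- i + 1
    if (b[k] != "-") j <- j + 1
    if (a[k] == "-" && b[k] == "-") next
    if (a[k] == "-") { out <- c(out, b[k]); next }
    if (b[k] == "-") { out <- c(out, a[k]); next }
    if (a[k] == b[k]) { out <- c(out, a[k]); next }
    out <- c(out, if (qa[i] > qb[j]) a[k] else if (qb[j] > qa[i]) b[k] else "N")
  }
  paste(out, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# truth-derived species calls: stands in for the sequencing stages when a
# test targets the statistical layer only
truth_calls <- function(truth) {
  data.frame(sample_id = truth$sample_id, status = "assigned",
             species = truth$true_species, supporting_hits = 10L,
             ambiguous = FALSE, stringsAsFactors = FALSE)
}

# flat / cumulative substitution-probability matrices over the default
# six groups
prob_matrix <- function(p_by_level) {
  groups <- c("hoki", "prawns", "sharks_rays", "snapper",
              "squid_cuttlefish", "tuna")
  matrix(rep(p_by_level, each = length(groups)), nrow = length(groups),
         dimnames = list(groups, c("higher", "family", "genus", "species")))
}
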