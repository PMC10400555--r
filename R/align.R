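#' Reverse-complement a nucleotide sequence
#'
#' @param seq Nucleotide string over A, C, G, T, N (case kept upper).
#' @param qual Optional numeric vector of per-base Phred scores; reversed
#'   in step with the sequence.
#' @return If `qual` is NULL, the reverse-complemented string; otherwise a
#'   list with `seq` and `qual`.
#' @export
#' @examples
#' reverse_complement("AAAC")
reverse_complement <- function(seq, qual = NULL) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("invalid nucleotide character in sequence")
  rc <- chartr("ACGTN", "TGCAN", seq)
  rc <- paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
  if (is.null(qual)) return(rc)
  stopifnot(length(qual) == nchar(seq))
  list(seq = rc, qual = rev(qual))
}

#' Optimal global pairwise alignment of a read pair
#'
#' Needleman-Wunsch alignment with linear gap cost (match +1, mismatch
#' -1, gap -2 by default) and a fixed tie-break (diagonal over up over
#' left), so results are deterministic. `type = "overlap"` makes end gaps
#' free on both sequences, appropriate when one sequence is contained in
#' a longer one.
#'
#' @param a,b Nucleotide strings.
#' @param match,mismatch,gap Scoring parameters.
#' @param type `"global"` (default) or `"overlap"`.
#' @return List with `aligned_a`, `aligned_b` (equal-length gapped
#'   strings covering both inputs end to end) and `score`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap = -2,
                       type = c("global", "overlap")) {
  type <- match.arg(type)
  stopifnot(nzchar(a), nzchar(b))
  nw_align_cpp(toupper(a), toupper(b), match, mismatch, gap,
               type == "overlap")
}

#' Quality trimming configuration
#'
#' Parameters of the sliding-window Phred trimmer applied to each Sanger
#' read before consensus calling: a fixed front trim, a 3' sliding-window
#' cut at a mean-quality floor, a hard length cap, and minimum length and
#' mean-quality requirements for the read to be retained.
#'
#' @param qual_floor Phred floor for window mean and overall mean (20).
#' @param front_trim Bases removed from the 5' end (30).
#' @param max_len Maximum retained length after trimming (250).
#' @param window 3' sliding-window size in bases (10).
#' @param min_len Minimum retained length (100).
#' @return List of class `trim_config`.
#' @export
trim_config <- function(qual_floor = 20, front_trim = 30, max_len = 250,
                        window = 10, min_len = 100) {
  stopifnot(qual_floor > 0, front_trim > 0, max_len > 0, window > 0,
            min_len > 0, min_len <= max_len)
  structure(list(qual_floor = qual_floor, front_trim = front_trim,
                 max_len = max_len, window = window, min_len = min_len),
            class = "trim_config")
}

#' Quality-trim a Sanger read
#'
#' Removes `front_trim` bases from the 5' end; then repeatedly removes
#' the 3'-terminal window of `window` bases while its mean quality is
#' below `qual_floor`; then truncates to `max_len`. The read is rejected
#' when the final length is below `min_len` (`"too_short"`) or its mean
#' quality is below the floor (`"low_quality"`).
#'
#' @param seq Nucleotide string.
#' @param qual Numeric Phred scores, one per base.
#' @param cfg A [trim_config()].
#' @return List with `seq`, `qual`, `rejected` (logical) and `reason`
#'   (`NA`, `"too_short"` or `"low_quality"`).
#' @export
trim_read <- function(seq, qual, cfg = trim_config()) {
  stopifnot(inherits(cfg, "trim_config"), nchar(seq) == length(qual))
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  q <- as.numeric(qual)

  reject <- function(reason)
    list(seq = "", qual = numeric(0), rejected = TRUE, reason = reason)
  if (length(s) <= cfg$front_trim) return(reject("too_short"))
  s <- s[-seq_len(cfg$front_trim)]
  q <- q[-seq_len(cfg$front_trim)]

  while (length(q) >= cfg$window &&
         mean(q[(length(q) - cfg$window + 1):length(q)]) < cfg$qual_floor) {
    keep <- seq_len(length(q) - cfg$window)
    s <- s[keep]; q <- q[keep]
  }
  if (length(q) > cfg$max_len) {
    s <- s[seq_len(cfg$max_len)]; q <- q[seq_len(cfg$max_len)]
  }
  if (length(q) < cfg$min_len) return(reject("too_short"))
  if (mean(q) < cfg$qual_floor) return(reject("low_quality"))
  list(seq = paste(s, collapse = ""), qual = q, rejected = FALSE,
       reason = NA_character_)
}

#' Call the consensus of an aligned read pair
#'
#' Columns where both reads agree emit the shared base; disagreeing
#' base-vs-base columns emit the base with the higher Phred score (an
#' exact quality tie emits N); columns where one read has a gap emit the
#' other read's base regardless of quality. The number of disagreeing
#' base-vs-base columns is reported.
#'
#' @param alignment Result of [align_pair()] on the trimmed forward read
#'   and the reverse-complemented trimmed reverse read.
#' @param fwd_qual,rev_qual Phred scores of the two aligned (ungapped)
#'   sequences, in the orientation that was aligned.
#' @param sample_id Optional identifier carried through.
#' @return List of class `consensus_sequence` with `sample_id`, `seq`,
#'   `per_base_source` (`"forward"`, `"reverse"` or `"agreed"`) and
#'   `pair_disagreements`.
#' @export
call_consensus <- function(alignment, fwd_qual, rev_qual,
                           sample_id = NA_character_) {
  a <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  stopifnot(length(a) == length(b),
            sum(a != "-") == length(fwd_qual),
            sum(b != "-") == length(rev_qual))
  ia <- cumsum(a != "-")
  ib <- cumsum(b != "-")
  out <- character(length(a))
  src <- character(length(a))
  disagreements <- 0L
  for (k in seq_along(a)) {
    if (a[k] == "-" && b[k] == "-") next
    if (a[k] == "-") { out[k] <- b[k]; src[k] <- "reverse"; next }
    if (b[k] == "-") { out[k] <- a[k]; src[k] <- "forward"; next }
    if (a[k] == b[k]) { out[k] <- a[k]; src[k] <- "agreed"; next }
    disagreements <- disagreements + 1L
    qa <- fwd_qual[ia[k]]; qb <- rev_qual[ib[k]]
    if (qa > qb) { out[k] <- a[k]; src[k] <- "forward" }
    else if (qb > qa) { out[k] <- b[k]; src[k] <- "reverse" }
    else { out[k] <- "N"; src[k] <- "agreed" }
  }
  keep <- nzchar(out)
  structure(list(sample_id = sample_id,
                 seq = paste(out[keep], collapse = ""),
                 per_base_source = src[keep],
                 pair_disagreements = disagreements),
            class = "consensus_sequence")
}
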