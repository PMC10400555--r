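#' Trim and call consensus for every read pair
#'
#' Runs the per-sample QC chain: both reads absent means failed
#' amplification; a trimming rejection of either read means low quality;
#' otherwise the reverse read is reverse-complemented, the pair is
#' globally aligned and the quality-weighted consensus is called.
#'
#' @param pairs Data frame of read pairs (see [write_read_pairs()] for
#'   the layout).
#' @param trim_cfg A [trim_config()].
#' @return Data frame: `sample_id`, `status` (`ok`, `no_amplification`,
#'   `low_quality`), `consensus`, `pair_disagreements`.
#' @export
consensus_pairs <- function(pairs, trim_cfg = trim_config()) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    out <- data.frame(sample_id = pairs$sample_id[i], status = "ok",
                      consensus = "", pair_disagreements = NA_integer_,
                      stringsAsFactors = FALSE)
    if (!nzchar(pairs$forward_seq[i]) && !nzchar(pairs$reverse_seq[i])) {
      out$status <- "no_amplification"; return(out)
    }
    if (!nzchar(pairs$forward_seq[i]) || !nzchar(pairs$reverse_seq[i])) {
      out$status <- "low_quality"; return(out)
    }
    f <- trim_read(pairs$forward_seq[i], pairs$forward_qual[[i]], trim_cfg)
    r <- trim_read(pairs$reverse_seq[i], pairs$reverse_qual[[i]], trim_cfg)
    if (f$rejected || r$rejected) { out$status <- "low_quality"; return(out) }
    rc <- reverse_complement(r$seq, r$qual)
    aln <- align_pair(f$seq, rc$seq)
    cons <- call_consensus(aln, f$qual, rc$qual, pairs$sample_id[i])
    out$consensus <- cons$seq
    out$pair_disagreements <- cons$pair_disagreements
    out
  })
  do.call(rbind, rows)
}

#' Identify the species of every sample
#'
#' Combines per-sample QC status from [consensus_pairs()] with a
#' reference hit table: hits are filtered per [filter_hits()], then a
#' species is assigned per [assign_species()]. Samples failing QC keep
#' their QC status; samples whose filtered hit set is empty are
#' `no_hits`.
#'
#' @param consensus Data frame from [consensus_pairs()]; or NULL when
#'   only a hit table is available, in which case every query in `hits`
#'   is treated as having passed QC.
#' @param hits Hit table (internal column names, see [read_hit_table()]).
#' @param filter_cfg A [filter_config()].
#' @param exclusions Named list mapping sample id to a character vector
#'   of co-ingredient species expected in that product.
#' @return Species-call data frame: `sample_id`, `status`, `species`,
#'   `supporting_hits`, `ambiguous`. A query with raw hits that all fail
#'   the confidence filters is `low_confidence`; one with no raw hits at
#'   all is `no_hits`.
#' @export
identify_samples <- function(consensus, hits, filter_cfg = filter_config(),
                             exclusions = list()) {
  if (is.null(consensus))
    consensus <- data.frame(sample_id = unique(hits$query), status = "ok",
                            stringsAsFactors = FALSE)
  filtered <- filter_hits(hits, filter_cfg)
  by_query <- split(filtered, filtered$query)
  raw_n <- table(hits$query)
  rows <- lapply(seq_len(nrow(consensus)), function(i) {
    id <- consensus$sample_id[i]
    if (consensus$status[i] != "ok")
      return(data.frame(sample_id = id, status = consensus$status[i],
                        species = NA_character_, supporting_hits = 0L,
                        ambiguous = FALSE, stringsAsFactors = FALSE))
    out <- assign_species(by_query[[id]],
                          exclusion = if (id %in% names(exclusions))
                            exclusions[[id]] else character(),
                          sample_id = id)
    if (out$status == "no_hits" && !is.na(raw_n[id]) && raw_n[id] > 0)
      out$status <- "low_confidence"
    out
  })
  do.call(rbind, rows)
}
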