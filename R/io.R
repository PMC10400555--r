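#' Write paired Sanger reads as FASTQ
#'
#' Standard 4-line FASTQ, Phred+33, forward and reverse reads in two
#' files keyed by sample id.
#'
#' @param pairs Data frame with columns `sample_id`, `forward_seq`,
#'   `forward_qual` (list of integer vectors), `reverse_seq`,
#'   `reverse_qual`.
#' @param fwd_path,rev_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_read_pairs <- function(pairs, fwd_path, rev_path) {
  one <- function(seqs, quals, path) {
    keep <- nzchar(seqs)
    x <- Biostrings::DNAStringSet(seqs[keep])
    names(x) <- pairs$sample_id[keep]
    q <- Biostrings::PhredQuality(vapply(quals[keep], function(v)
      rawToChar(as.raw(as.integer(v) + 33L)), ""))
    Biostrings::writeQualityScaledXStringSet(
      Biostrings::QualityScaledDNAStringSet(x, q), path)
  }
  one(pairs$forward_seq, pairs$forward_qual, fwd_path)
  one(pairs$reverse_seq, pairs$reverse_qual, rev_path)
  invisible(c(fwd_path, rev_path))
}

#' Read paired Sanger reads from FASTQ
#'
#' @param fwd_path,rev_path FASTQ files written by [write_read_pairs()]
#'   or any Phred+33 FASTQ keyed by sample id. Samples present in only
#'   one file get an empty mate (recorded as failed amplification
#'   downstream).
#' @return Data frame with list-columns as in [write_read_pairs()].
#' @export
read_read_pairs <- function(fwd_path, rev_path) {
  one <- function(path) {
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    list(ids = names(x),
         seq = as.character(x),
         qual = lapply(as(x@quality, "IntegerList"), as.integer))
  }
  f <- one(fwd_path); r <- one(rev_path)
  ids <- union(f$ids, r$ids)
  fi <- match(ids, f$ids); ri <- match(ids, r$ids)
  data.frame(
    sample_id = ids,
    forward_seq = ifelse(is.na(fi), "", f$seq[fi]),
    forward_qual = I(lapply(fi, function(i)
      if (is.na(i)) integer(0) else f$qual[[i]])),
    reverse_seq = ifelse(is.na(ri), "", r$seq[ri]),
    reverse_qual = I(lapply(ri, function(i)
      if (is.na(i)) integer(0) else r$qual[[i]])),
    stringsAsFactors = FALSE
  )
}

#' Read a hit table TSV
#'
#' Accepts the package's augmented BLAST outfmt-6-like layout with
#' columns `qseqid`, `sseqid_species`, `db`, `pident`, `qcovs`,
#' `evalue`, `species_db_entries`, renaming them to the internal
#' `query`/`species`/`identity`/`coverage` names. Tables already using
#' internal names pass through.
#'
#' @param path TSV file with a header row.
#' @return Data frame of hit records.
#' @export
read_hit_table <- function(path) {
  h <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  ren <- c(qseqid = "query", sseqid_species = "species", pident = "identity",
           qcovs = "coverage")
  for (old in names(ren))
    if (old %in% names(h)) names(h)[names(h) == old] <- ren[[old]]
  h
}

#' Write a hit table TSV
#'
#' @param hits Data frame of hit records (internal column names).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits
  ren <- c(query = "qseqid", species = "sseqid_species",
           identity = "pident", coverage = "qcovs")
  for (old in names(ren))
    if (old %in% names(out)) names(out)[names(out) == old] <- ren[[old]]
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
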