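#' Load a standard-names list
#'
#' Reads a one-column CSV of approved standard fish names and
#' pre-normalises them with [normalise_label()] so matching uses the
#' same canonical form as label resolution.
#'
#' @param path CSV with a single column of names (header row).
#' @return Character vector of normalised approved names, class
#'   `standard_names`.
#' @export
load_standard_names <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)[[1]]
  standard_names(x)
}

#' @rdname load_standard_names
#' @param names Character vector of approved names.
#' @export
standard_names <- function(names) {
  structure(unique(vapply(names, normalise_label, "", syn_map = NULL)),
            class = "standard_names")
}

#' Demonstration standard-names list
#'
#' The approved-name list shipped with the demo reference tables. It is
#' synthetic: a plausible subset of standard names for the demo
#' taxonomy, deliberately omitting bare umbrella terms ("shark",
#' "calamari") and fancy variants ("red snapper", "pink snapper") so
#' that misnaming is observable.
#' @export
demo_standard_names <- function() {
  load_standard_names(system.file("extdata", "demo_standard_names.csv",
                                  package = "labelaudit", mustWork = TRUE))
}

#' Optimal string alignment distance
#'
#' Levenshtein distance extended with adjacent transpositions (no
#' substring edited twice). Vectorised over both arguments.
#'
#' @param a,b Character vectors.
#' @return Integer matrix of distances, `length(a)` x `length(b)`.
#' @export
#' @examples
#' osa_distance("flake", "falke")  # one transposition
osa_distance <- function(a, b) {
  osa_matrix_cpp(as.character(a), as.character(b))
}

#' Is a product misnamed?
#'
#' A product is named correctly when either its main label or its
#' maximum-detail string, after normalisation, is within `max_distance`
#' (optimal string alignment distance) of an approved standard name, or
#' when either string carries a valid scientific binomial. Otherwise it
#' is misnamed. Misnaming is about nomenclature only; it is computed
#' without reference to the DNA identification and never feeds the
#' mislabelling adjudication.
#'
#' @param label_main,label_max_detail Label strings (vectors of equal
#'   length; `label_max_detail` may be NA).
#' @param names A `standard_names` list.
#' @param max_distance Edit-distance bound (default 2).
#' @return Data frame: `misnamed` (logical), `matched_name` (the
#'   approved name matched, or NA).
#' @export
is_misnamed <- function(label_main, label_max_detail = NA, names,
                        max_distance = 2) {
  stopifnot(inherits(names, "standard_names"))
  n <- length(label_main)
  label_max_detail <- rep_len(label_max_detail, n)
  misnamed <- logical(n)
  matched <- rep(NA_character_, n)
  is_binomial <- function(x)
    !is.na(x) & grepl("^[A-Z][a-z]+ [a-z]+$", trimws(x))
  for (i in seq_len(n)) {
    cand <- c(label_main[i], label_max_detail[i])
    cand <- cand[!is.na(cand) & nzchar(trimws(cand))]
    if (any(is_binomial(cand))) { misnamed[i] <- FALSE; next }
    norm <- vapply(cand, normalise_label, "", syn_map = NULL)
    d <- osa_distance(norm, unclass(names))
    best <- which(d <= max_distance, arr.ind = TRUE)
    if (nrow(best) == 0) { misnamed[i] <- TRUE; next }
    j <- best[order(d[best]), , drop = FALSE][1, 2]
    matched[i] <- unclass(names)[j]
  }
  data.frame(misnamed = misnamed, matched_name = matched,
             stringsAsFactors = FALSE)
}

#' Misnaming rate with Wald intervals
#'
#' @param products Product table (needs `seafood_group` when
#'   stratified).
#' @param flags Logical vector, one misnaming flag per product.
#' @param by `"overall"` or `"group"`.
#' @param conf Confidence level.
#' @return Data frame of [wald_ci()] rows, one per stratum; empty
#'   strata are absent.
#' @export
misnaming_rate <- function(products, flags, by = c("overall", "group"),
                           conf = 0.95) {
  by <- match.arg(by)
  stopifnot(nrow(products) == length(flags))
  strata <- if (by == "overall") rep("overall", nrow(products)) else
    products$seafood_group
  out <- lapply(split(flags, strata), function(f)
    wald_ci(sum(f), length(f), conf))
  res <- do.call(rbind, out)
  res <- cbind(stratum = names(out), res)
  rownames(res) <- NULL
  res
}
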