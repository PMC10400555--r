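#' Adjudicate mislabelling for every product under each regime
#'
#' A product is mislabelled under a regime when its DNA-assigned species
#' lies outside the species set its maximum-detail label permits under
#' that regime; correct when inside (so a coarse label is judged
#' against its own coarse set); unassessable when no species was
#' assigned or the label term is unknown to the reference table
#' (unknown terms are surfaced, never silently counted as mislabelled).
#' Universal generic labels ("fish") are always correct and stay in
#' denominators. Label specificity is classified from the comprehensive
#' regime's permitted set.
#'
#' @param products Product table (needs `sample_id`,
#'   `label_max_detail`).
#' @param calls Species-call table from [identify_samples()].
#' @param ref A [label_reference()].
#' @param regimes Regimes to adjudicate (default: all configured).
#' @return Data frame with `sample_id`, `specificity` (1-4, NA when the
#'   term is unknown), `assigned_species`, `unknown_term`, and one
#'   `status_<regime>` column per regime with values `correct`,
#'   `mislabelled`, `unassessable`.
#' @export
adjudicate_products <- function(products, calls, ref,
                                regimes = ref$regimes) {
  stopifnot(inherits(ref, "label_reference"))
  idx <- match(products$sample_id, calls$sample_id)
  if (anyNA(idx)) stop("species calls missing for: ",
                       paste(head(products$sample_id[is.na(idx)], 5),
                             collapse = ", "))
  assigned <- ifelse(calls$status[idx] == "assigned",
                     .resolve_syn(calls$species[idx], ref$syn_map),
                     NA_character_)

  terms <- vapply(products$label_max_detail, normalise_label, "",
                  syn_map = ref$syn_map)
  uniq <- unique(terms)
  sets <- lapply(uniq, function(tm) {
    per_regime <- lapply(regimes, function(rg) resolve_label(tm, rg, ref))
    names(per_regime) <- regimes
    comp <- resolve_label(tm, "comprehensive", ref)
    list(per_regime = per_regime,
         specificity = classify_specificity(comp, ref),
         unknown = isTRUE(attr(comp, "unknown")))
  })
  names(sets) <- uniq

  out <- data.frame(
    sample_id = products$sample_id,
    specificity = vapply(terms, function(t) sets[[t]]$specificity, 0L),
    assigned_species = assigned,
    unknown_term = vapply(terms, function(t) sets[[t]]$unknown, TRUE),
    stringsAsFactors = FALSE)
  for (rg in regimes) {
    status <- character(nrow(out))
    for (t in uniq) {
      rows <- which(terms == t)
      s <- sets[[t]]$per_regime[[rg]]
      if (isTRUE(attr(s, "unknown"))) { status[rows] <- "unassessable"; next }
      if (isTRUE(attr(s, "universal"))) {
        status[rows] <- ifelse(is.na(assigned[rows]), "unassessable", "correct")
        next
      }
      status[rows] <- ifelse(is.na(assigned[rows]), "unassessable",
                             ifelse(assigned[rows] %in% s,
                                    "correct", "mislabelled"))
    }
    out[[paste0("status_", rg)]] <- status
  }
  rownames(out) <- NULL
  attr(out, "regimes") <- regimes
  out
}

.status_col <- function(adj, regime) {
  col <- paste0("status_", regime)
  if (!col %in% names(adj)) stop("regime not adjudicated: ", regime)
  adj[[col]]
}

#' Mislabelling rates with Wald intervals
#'
#' Proportions of mislabelled products among assessed products (the
#' unassessable are excluded from denominators and tallied separately),
#' overall or stratified.
#'
#' @param adj Result of [adjudicate_products()].
#' @param products Product table aligned to `adj` by `sample_id`.
#' @param regime Definition regime to report.
#' @param by One of `overall`, `group`, `origin`, `outlet`,
#'   `specificity`.
#' @param conf Confidence level.
#' @return Data frame: stratum, numerator, denominator, proportion
#'   (percent), ci_low, ci_high, method. Zero-denominator strata are
#'   absent.
#' @export
mislabelling_rates <- function(adj, products, regime = "comprehensive",
                               by = c("overall", "group", "origin",
                                      "outlet", "specificity"),
                               conf = 0.95) {
  by <- match.arg(by)
  status <- .status_col(adj, regime)
  idx <- match(adj$sample_id, products$sample_id)
  strata <- switch(by,
    overall = rep("overall", nrow(adj)),
    group = products$seafood_group[idx],
    origin = products$origin[idx],
    outlet = products$outlet_type[idx],
    specificity = names(specificity_levels)[adj$specificity])
  keep <- status != "unassessable" & !is.na(strata)
  res <- lapply(split(status[keep], strata[keep]), function(s)
    wald_ci(sum(s == "mislabelled"), length(s), conf))
  out <- cbind(stratum = names(res), do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Sensitivity of mislabelling rates to the label-to-species definition
#'
#' Re-computes overall and per-group mislabelling under each regime on
#' the identical assessed sample set, mirroring a definition-leniency
#' table. Errors if the assessable sample set differs between regimes
#' (rates would not be comparable).
#'
#' @param adj Result of [adjudicate_products()] covering the regimes.
#' @param products Product table.
#' @param regimes Regimes to tabulate.
#' @return Data frame: regime, stratum ("overall" or group name),
#'   numerator, denominator, proportion (percent).
#' @export
sensitivity_analysis <- function(adj, products,
                                 regimes = attr(adj, "regimes")) {
  assessed <- lapply(regimes, function(rg)
    adj$sample_id[.status_col(adj, rg) != "unassessable"])
  for (i in seq_along(regimes)[-1])
    if (!setequal(assessed[[1]], assessed[[i]]))
      stop("regimes differ in sample coverage: ", regimes[1], " vs ",
           regimes[i])
  idx <- match(adj$sample_id, products$sample_id)
  grp <- products$seafood_group[idx]
  one <- function(rg) {
    st <- .status_col(adj, rg)
    keep <- st != "unassessable"
    cell <- function(stratum, sel) data.frame(
      regime = rg, stratum = stratum,
      numerator = sum(st[sel] == "mislabelled"),
      denominator = sum(sel),
      proportion = 100 * mean(st[sel] == "mislabelled"),
      stringsAsFactors = FALSE)
    rbind(cell("overall", keep),
          do.call(rbind, lapply(sort(unique(grp)), function(g)
            cell(g, keep & grp == g))))
  }
  out <- do.call(rbind, lapply(regimes, one))
  rownames(out) <- NULL
  out
}

#' Goodman simultaneous confidence intervals for multinomial proportions
#'
#' For k categories with counts n_i summing to N, the per-category
#' bounds follow the chi-square quadratic with Bonferroni-adjusted
#' quantile A = qchisq(1 - alpha/k, df = 1):
#' (A + 2 n_i -/+ sqrt(A (A + 4 n_i (N - n_i) / N))) / (2 (N + A)).
#'
#' @param counts Non-negative integer vector (named or not), total > 0.
#' @param alpha Simultaneous error rate (0.05).
#' @return Data frame: category, count, proportion (percent), ci_low,
#'   ci_high (percent), method.
#' @export
goodman_intervals <- function(counts, alpha = 0.05) {
  stopifnot(all(counts >= 0))
  N <- sum(counts)
  if (N <= 0) stop("total count must be positive")
  k <- length(counts)
  A <- qchisq(1 - alpha / k, df = 1)
  lo <- (A + 2 * counts - sqrt(A * (A + 4 * counts * (N - counts) / N))) /
    (2 * (N + A))
  hi <- (A + 2 * counts + sqrt(A * (A + 4 * counts * (N - counts) / N))) /
    (2 * (N + A))
  data.frame(
    category = if (is.null(names(counts))) as.character(seq_len(k)) else
      names(counts),
    count = as.vector(counts),
    proportion = 100 * counts / N,
    ci_low = 100 * pmax(0, lo), ci_high = 100 * pmin(1, hi),
    method = "goodman", stringsAsFactors = FALSE)
}

#' Compare vendor verbal claims with the molecular identification
#'
#' Vendor claims never alter the written-label adjudication; this
#' summarises how often they agree with the DNA result, and how often a
#' claim would have rescued a product (written label mislabelled but
#' the claim names or contains the assigned species).
#'
#' @param adj Result of [adjudicate_products()].
#' @param products Product table with a `vendor_claim` column.
#' @param ref A [label_reference()].
#' @param regime Regime for the rescue check.
#' @return List: `n_claims` (assessed products with a claim), `agree`,
#'   `disagree`, `disagree_pct`, `rescued`, `absent`.
#' @export
vendor_comparison <- function(adj, products, ref, regime = "comprehensive") {
  idx <- match(adj$sample_id, products$sample_id)
  claim <- products$vendor_claim[idx]
  status <- .status_col(adj, regime)
  assessed <- status != "unassessable"
  has <- !is.na(claim) & nzchar(claim) & assessed
  agree <- logical(length(claim))
  for (i in which(has)) {
    set <- resolve_label(claim[i], regime, ref)
    if (length(set) == 0)
      set <- .resolve_syn(claim[i], ref$syn_map)
    agree[i] <- adj$assigned_species[i] %in% set
  }
  rescued <- sum(has & agree & status == "mislabelled")
  n <- sum(has)
  list(n_claims = n, agree = sum(agree[has]),
       disagree = n - sum(agree[has]),
       disagree_pct = if (n > 0) 100 * (n - sum(agree[has])) / n else NA_real_,
       rescued = rescued, absent = sum(assessed) - n)
}

#' Annotate adjudication results with conservation status
#'
#' Key-exact left join of a user-supplied species-to-status table onto
#' the assigned species (synonyms resolved first); species without an
#' entry are annotated `"unknown"`.
#'
#' @param adj Result of [adjudicate_products()].
#' @param status_table Data frame with columns `species` and `category`.
#' @param ref A [label_reference()] for synonym resolution.
#' @return `adj` with a `conservation` column appended.
#' @export
annotate_conservation <- function(adj, status_table, ref) {
  if (nrow(status_table) > 0)
    status_table$species <- .resolve_syn(status_table$species, ref$syn_map)
  m <- match(adj$assigned_species, status_table$species)
  adj$conservation <- ifelse(is.na(adj$assigned_species), NA_character_,
                             ifelse(is.na(m), "unknown",
                                    status_table$category[m]))
  adj
}
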