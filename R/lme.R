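#' Derive LME thresholds from enriched deciles
#'
#' For each metric, takes the maximal contiguous run of deciles enriched in
#' confirmed disorder genes starting at the stated extreme of the
#' distribution (the lowest deciles for a `low_extreme` metric such as LOEUF,
#' the highest for a `high_extreme` metric such as misZ or the exon
#' conservation score). The threshold is the outer boundary of that run — the
#' k*10 percent quantile for a k-decile low run, the (100 - k*10) percent
#' quantile for a high run. If no extreme decile is enriched the criterion is
#' disabled (threshold NA) with a warning when enrichment exists elsewhere.
#'
#' @param decile_results Named list of [decile_enrichment()] results, one per
#'   metric.
#' @param direction Named character vector over the same metrics:
#'   `"low_extreme"` or `"high_extreme"`.
#' @return List of class `lme_thresholds`: per metric `threshold` (NA when
#'   disabled), `direction`, and `provenance` (the enriched decile run).
#' @export
derive_thresholds <- function(decile_results, direction) {
  stopifnot(all(names(decile_results) %in% names(direction)))
  out <- lapply(names(decile_results), function(m) {
    dr <- decile_results[[m]]
    enr <- dr$enriched
    dir <- direction[[m]]
    run <- integer(0)
    if (dir == "low_extreme") {
      k <- 0
      while (k < 10 && enr[k + 1]) k <- k + 1
      if (k > 0) run <- seq_len(k)
      thr <- if (k > 0) dr$upper[k] else NA_real_
    } else if (dir == "high_extreme") {
      k <- 0
      while (k < 10 && enr[10 - k]) k <- k + 1
      if (k > 0) run <- seq(11 - k, 10)
      thr <- if (k > 0) dr$lower[11 - k] else NA_real_
    } else stop("input error: unknown direction '", dir, "'")
    if (is.na(thr) && any(enr))
      warning("metric '", m, "': enriched deciles exist but none at the ",
              dir, " extreme; criterion disabled")
    list(threshold = thr, direction = dir, provenance = run)
  })
  names(out) <- names(decile_results)
  structure(out, class = "lme_thresholds")
}

#' Classify genes by the LME criteria
#'
#' Applies the three threshold rules inclusively: L iff LOEUF <= loeuf_max,
#' M iff misZ >= misz_min, E iff exon conservation >= exon_min. A missing
#' feature makes that criterion false for the gene (flagged `incomplete`).
#' A disabled criterion (NA threshold) is false for every gene.
#'
#' @param features Feature data.frame (or `feature_table`) with columns
#'   `symbol`, `loeuf`, `mis_z`, `exon_score`.
#' @param thresholds An `lme_thresholds` object with metrics `loeuf`,
#'   `mis_z`, `exon_score`, or a named list with `$threshold` entries.
#' @param classes Optional named disorder-class vector for the summary.
#' @param min_criteria Minimum number of criteria for the summary flag
#'   `meets_min` (default 1: "at least one criterion"; 2 gives the stricter
#'   "at least two" cut).
#' @return List of class `lme_status`: `status` data.frame (symbol, L, M, E,
#'   n_criteria, meets_min, incomplete) and `euler` (counts of genes meeting
#'   each subset of criteria, overall and per class when `classes` is given).
#' @export
classify_lme <- function(features, thresholds, classes = NULL,
                         min_criteria = 1) {
  if (inherits(features, "feature_table")) features <- features$features
  thr <- function(m) thresholds[[m]]$threshold
  cmp <- function(v, t, op) {
    if (is.na(t)) rep(FALSE, length(v))
    else !is.na(v) & op(v, t)
  }
  L <- cmp(features$loeuf, thr("loeuf"), `<=`)
  M <- cmp(features$mis_z, thr("mis_z"), `>=`)
  E <- cmp(features$exon_score, thr("exon_score"), `>=`)
  status <- data.frame(
    symbol = features$symbol, L = L, M = M, E = E,
    n_criteria = L + M + E,
    meets_min = (L + M + E) >= min_criteria,
    incomplete = is.na(features$loeuf) | is.na(features$mis_z) |
      is.na(features$exon_score),
    stringsAsFactors = FALSE)
  subset_label <- paste0(ifelse(L, "L", ""), ifelse(M, "M", ""),
                         ifelse(E, "E", ""))
  subset_label[subset_label == ""] <- "none"
  lv <- c("none", "L", "M", "E", "LM", "LE", "ME", "LME")
  euler <- list(overall = table(factor(subset_label, levels = lv)))
  if (!is.null(classes)) {
    cl <- classes[status$symbol]
    euler$by_class <- table(cl, factor(subset_label, levels = lv))
  }
  structure(list(status = status, euler = euler, thresholds = thresholds,
                 min_criteria = min_criteria),
            class = "lme_status")
}
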