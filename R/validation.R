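#' Filter variants to damaging ones
#'
#' Keeps LoF (truncating) variants unconditionally and missense variants with
#' a deleteriousness score of at least `score_min` (scaled PHRED-like; the
#' conventional damaging-missense cutoff is 25, inclusive). Everything else
#' is dropped. Missense variants without a score are excluded and tallied in
#' a `no_score` bucket. Idempotent.
#'
#' @param variants data.frame with columns `gene`, `type`
#'   (`LoF`/`missense`/`splicing`/`other`) and `score` (NA allowed).
#' @param score_min Missense score cutoff (default 25).
#' @return The damaging subset, with attributes `counts` (kept per gene) and
#'   `no_score` (missense rows excluded for lack of a score).
#' @export
damaging_filter <- function(variants, score_min = 25) {
  lof <- variants$type == "LoF"
  mis_scored <- variants$type == "missense" & !is.na(variants$score)
  keep <- lof | (mis_scored & variants$score >= score_min)
  out <- variants[keep, , drop = FALSE]
  attr(out, "counts") <- table(out$gene)
  attr(out, "no_score") <- sum(variants$type == "missense" &
                                 is.na(variants$score))
  out
}

#' Variant-burden report for predicted vs non-predicted genes
#'
#' Delegates the Mann-Whitney comparisons and Pearson correlation to
#' [burden_comparison()] and adds a Fisher test of "has at least one reported
#' variant" against predicted status.
#'
#' @param counts Named per-gene variant counts (genes absent = 0 handled by
#'   the caller passing complete vectors).
#' @param predicted Named logical vector of predicted status over the same
#'   genes.
#' @param cds_lengths Named per-gene CDS lengths (bases).
#' @return List: `burden` ([burden_comparison()] output) and `any_variant`
#'   (`fisher_result`).
#' @export
burden_report <- function(counts, predicted, cds_lengths) {
  genes <- names(counts)
  predicted <- predicted[genes]
  if (!any(predicted) || all(predicted))
    stop("input error: both predicted and non-predicted genes required")
  bc <- burden_comparison(counts[predicted], counts[!predicted], cds_lengths)
  tab <- rbind(c(sum(counts > 0 & predicted), sum(counts == 0 & predicted)),
               c(sum(counts > 0 & !predicted), sum(counts == 0 & !predicted)))
  list(burden = bc, any_variant = fisher_enrichment(tab))
}

#' Database-overlap report for predicted vs non-predicted genes
#'
#' Fisher test of membership in at least one curated database against
#' predicted status, a Mann-Whitney test on the number of databases per gene,
#' and per-database membership counts. The presence-based odds ratio and the
#' count-based test are both emitted because either reading of "present in
#' more databases" is defensible.
#'
#' @param predicted Named logical vector over genes.
#' @param membership data.frame with columns `gene`, `database` (long
#'   format); genes absent are members of none.
#' @return List with `fisher`, `mann_whitney`, `per_database`; or a notice
#'   when the membership map is empty.
#' @export
overlap_report <- function(predicted, membership) {
  if (is.null(membership) || nrow(membership) == 0)
    return(list(notice = "empty database map; tests skipped"))
  n_db <- table(factor(membership$gene, levels = names(predicted)))
  n_db <- as.numeric(n_db)
  any_db <- n_db > 0
  tab <- rbind(c(sum(any_db & predicted), sum(!any_db & predicted)),
               c(sum(any_db & !predicted), sum(!any_db & !predicted)))
  mw <- stats::wilcox.test(n_db[predicted], n_db[!predicted], exact = FALSE)
  list(fisher = fisher_enrichment(tab),
       mann_whitney = list(p_value = mw$p.value,
                           statistic = unname(mw$statistic)),
       per_database = table(membership$database))
}

#' Protein-domain clustering report for curated missense variants
#'
#' Pools missense variants across the gene set and delegates to
#' [binomial_domain_test()] with k = in-domain missense count, n = total
#' missense count, and amino-acid totals summed over the genes.
#'
#' @param variants data.frame with `gene`, `type`, `in_domain`.
#' @param domains data.frame with `gene`, `domain_aa`, `total_aa`.
#' @param genes Optional gene subset to pool over.
#' @return List: `k`, `n`, `domain_aa`, `total_aa`, `p_value`; or a notice
#'   when there are no missense variants.
#' @export
domain_report <- function(variants, domains, genes = NULL) {
  if (!is.null(genes)) {
    variants <- variants[variants$gene %in% genes, , drop = FALSE]
    domains <- domains[domains$gene %in% genes, , drop = FALSE]
  }
  mis <- variants[variants$type == "missense" & !is.na(variants$in_domain), ,
                  drop = FALSE]
  if (nrow(mis) == 0)
    return(list(notice = "no missense variants; test skipped"))
  k <- sum(mis$in_domain); n <- nrow(mis)
  da <- sum(domains$domain_aa); ta <- sum(domains$total_aa)
  list(k = k, n = n, domain_aa = da, total_aa = ta,
       p_value = binomial_domain_test(k, n, da, ta))
}
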