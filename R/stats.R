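#' Vectorised two-sided Fisher exact p-value for 2x2 tables
#'
#' The two-sided p is the sum of hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (with the customary 1 + 1e-7 relative tolerance for
#' floating-point ties, as in [stats::fisher.test()]).
#'
#' @param a,b,c,d Cell counts (vectors are recycled to a common length);
#'   table layout is `rbind(c(a, b), c(c, d))`.
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(c(a, b, c, d) < 0)) stop("input error: negative counts")
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]          # row 1 total
    nn <- c[i] + d[i]         # row 2 total
    k <- a[i] + c[i]          # column 1 total
    lo <- max(0, k - nn); hi <- min(k, m)
    support <- lo:hi
    probs <- stats::dhyper(support, m, nn, k)
    obs <- probs[support == a[i]]
    sum(probs[probs <= obs * (1 + 1e-7)])
  }, numeric(1))
}

#' Fisher enrichment test with the pipeline's odds-ratio conventions
#'
#' Two-sided exact p from the hypergeometric distribution; the reported odds
#' ratio is the unconditional sample OR (ad)/(bc). For the log2 odds ratio, a
#' 1e-4 addend is applied to zero cells so the value is always finite.
#' Bonferroni adjustment multiplies by `n_tests` and caps at 1. The
#' conditional MLE odds ratio from [stats::fisher.test()] is exposed as
#' `odds_ratio_cmle`.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param n_tests Number of tests in the Bonferroni family (default 1).
#' @return List of class `fisher_result`: `table`, `odds_ratio`,
#'   `odds_ratio_cmle`, `log2_odds_ratio`, `p_value`, `p_adjusted`, `n_tests`.
#' @export
fisher_enrichment <- function(table, n_tests = 1) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0)) stop("input error: negative counts")
  if (sum(table) == 0) stop("input error: empty table")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  p <- fisher_exact_p(a, b, c, d)
  or <- (a * d) / (b * c)
  if (any(table == 0)) {
    aa <- ifelse(a == 0, a + 1e-4, a); bb <- ifelse(b == 0, b + 1e-4, b)
    cc <- ifelse(c == 0, c + 1e-4, c); dd <- ifelse(d == 0, d + 1e-4, d)
    l2 <- log2((aa * dd) / (bb * cc))
  } else l2 <- log2(or)
  structure(list(table = table, odds_ratio = or,
                 odds_ratio_cmle = unname(
                   stats::fisher.test(table)$estimate),
                 log2_odds_ratio = l2, p_value = min(1, p),
                 p_adjusted = min(1, p * n_tests), n_tests = n_tests),
            class = "fisher_result")
}

#' Decile enrichment of a labelled class along a continuous variable
#'
#' Decile boundaries are the 10..90 percent quantiles of the pooled
#' non-missing distribution (linear interpolation between order statistics);
#' genes are assigned by right-closed intervals, so ties spanning a boundary
#' fall in the lower decile. Each decile gets a two-sided Fisher test of
#' class-in-decile vs class-out-of-decile, Bonferroni-adjusted by `n_tests`.
#' A decile is `enriched` iff adjusted p < alpha and OR > 1, `depleted` iff
#' adjusted p < alpha and OR < 1.
#'
#' @param values Named numeric vector (gene -> value; NAs dropped).
#' @param labels Named logical or character vector; `TRUE`/`"confirmed"`
#'   marks the focal class.
#' @param n_tests Bonferroni family size (default 10, the deciles).
#' @param alpha Significance level after adjustment (default 0.05).
#' @return data.frame with one row per decile: boundaries, 2x2 counts,
#'   odds ratio, log2 OR, raw/adjusted p, `enriched`, `depleted`.
#' @export
decile_enrichment <- function(values, labels, n_tests = 10, alpha = .05) {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- labels[keep]
  if (length(values) < 10)
    stop("input error: fewer than 10 non-missing values")
  if (is.character(labels)) labels <- labels == "confirmed"
  q <- stats::quantile(values, seq(.1, .9, by = .1), type = 7, names = FALSE)
  breaks <- c(-Inf, q, Inf)
  decile <- cut(values, breaks, labels = FALSE, right = TRUE)
  res <- lapply(1:10, function(k) {
    a <- sum(labels & decile == k)
    b <- sum(labels & decile != k)
    c <- sum(!labels & decile == k)
    d <- sum(!labels & decile != k)
    fr <- fisher_enrichment(rbind(c(a, b), c(c, d)), n_tests)
    data.frame(decile = k, lower = breaks[k], upper = breaks[k + 1],
               n_in = a + c, class_in = a, class_out = b,
               other_in = c, other_out = d,
               odds_ratio = fr$odds_ratio,
               log2_odds_ratio = fr$log2_odds_ratio,
               p_value = fr$p_value, p_adjusted = fr$p_adjusted,
               enriched = fr$p_adjusted < alpha & fr$odds_ratio > 1,
               depleted = fr$p_adjusted < alpha & fr$odds_ratio < 1)
  })
  do.call(rbind, res)
}

#' Variant-burden comparison between two gene groups
#'
#' Two-sided Mann-Whitney U tests on raw per-gene variant counts and on
#' counts per kb of coding sequence, Bonferroni-adjusted over the two tests,
#' plus the Pearson correlation between CDS length and count over all genes.
#'
#' @param counts_a,counts_b Named per-gene variant counts for the two groups.
#' @param cds_lengths Named per-gene CDS length in bases covering both
#'   groups.
#' @return List: `raw` and `normalized` (each with `p_value`, `p_adjusted`,
#'   `statistic`), `pearson` (`r`, `p_value`).
#' @export
burden_comparison <- function(counts_a, counts_b, cds_lengths) {
  if (length(counts_a) == 0 || length(counts_b) == 0)
    stop("input error: empty group")
  kb_a <- cds_lengths[names(counts_a)] / 1000
  kb_b <- cds_lengths[names(counts_b)] / 1000
  raw <- stats::wilcox.test(counts_a, counts_b, exact = NULL)
  nrm <- stats::wilcox.test(counts_a / kb_a, counts_b / kb_b, exact = NULL)
  all_counts <- c(counts_a, counts_b)
  all_cds <- cds_lengths[names(all_counts)]
  pe <- suppressWarnings(stats::cor.test(all_cds, all_counts,
                                         method = "pearson"))
  list(
    raw = list(p_value = raw$p.value,
               p_adjusted = min(1, raw$p.value * 2),
               statistic = unname(raw$statistic)),
    normalized = list(p_value = nrm$p.value,
                      p_adjusted = min(1, nrm$p.value * 2),
                      statistic = unname(nrm$statistic)),
    pearson = list(r = unname(pe$estimate), p_value = pe$p.value))
}

#' One-tailed binomial test for variant clustering in protein domains
#'
#' Upper-tail exact probability P(X >= k) for X ~ Binomial(n,
#' domain_aa/total_aa): the chance of observing at least `k` of `n` variants
#' inside domains if variants land uniformly along the protein.
#'
#' @param k_in_domain Observed in-domain variant count (0 <= k <= n).
#' @param n_variants Total variant count.
#' @param domain_aa Amino acids within domains (> 0).
#' @param total_aa Total amino acids (>= domain_aa).
#' @return One-tailed p-value.
#' @export
binomial_domain_test <- function(k_in_domain, n_variants, domain_aa,
                                 total_aa) {
  if (k_in_domain < 0 || k_in_domain > n_variants)
    stop("input error: need 0 <= k <= n")
  if (domain_aa <= 0 || domain_aa > total_aa)
    stop("input error: need 0 < domain_aa <= total_aa")
  stats::pbinom(k_in_domain - 1, n_variants, domain_aa / total_aa,
                lower.tail = FALSE)
}
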