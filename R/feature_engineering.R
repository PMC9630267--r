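#' Convert RPKM to TPM
#'
#' TPM_g = RPKM_g / sum_g(RPKM_g) * 1e6, per sample. Column sums of the
#' result are 1e6 (within 1e-6 relative).
#'
#' @param values Numeric matrix (genes x samples) of RPKM, all >= 0.
#' @return Matrix of TPM with the same dimnames.
#' @export
rpkm_to_tpm <- function(values) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("input error: negative RPKM")
  cs <- colSums(values)
  bad <- which(cs == 0)
  if (length(bad))
    stop("conversion error: all-zero sample: ",
         paste(colnames(values)[bad] %||% bad, collapse = ", "))
  sweep(values, 2, cs, "/") * 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate brain tissues into cerebellar and other-brain metavalues
#'
#' @param values Named numeric vector of per-tissue TPM.
#' @param cerebellar_tissues,brain_tissues Non-empty, disjoint tissue sets.
#' @return `c(cerebellar = median, brain = median)`.
#' @export
aggregate_brain <- function(values, cerebellar_tissues, brain_tissues) {
  stopifnot(length(cerebellar_tissues) > 0, length(brain_tissues) > 0)
  if (length(intersect(cerebellar_tissues, brain_tissues)))
    stop("input error: cerebellar and brain tissue sets overlap")
  missing <- setdiff(c(cerebellar_tissues, brain_tissues), names(values))
  if (length(missing))
    stop("input error: tissue absent from values: ",
         paste(missing, collapse = ", "))
  c(cerebellar = stats::median(values[cerebellar_tissues]),
    brain = stats::median(values[brain_tissues]))
}

#' Tissue-specificity index tau
#'
#' tau = sum_i(1 - x_i) / (N - 1) where x_i is the expression profile
#' component normalised by the maximal component, computed by default on
#' log2(TPM + 1). 0 means uniform expression across tissues; 1 means
#' expression restricted to a single tissue. Undefined (NA) when the maximal
#' component is 0 (gene unexpressed).
#'
#' @param aggregated Numeric vector of per-tissue TPM (N >= 2), after any
#'   brain aggregation.
#' @param log_transform Apply log2(TPM + 1) first (default TRUE).
#' @return tau in \[0, 1\], or NA.
#' @export
compute_tau <- function(aggregated, log_transform = TRUE) {
  if (length(aggregated) < 2)
    stop("input error: tau needs at least 2 tissues")
  v <- if (log_transform) log2(aggregated + 1) else aggregated
  m <- max(v)
  if (m == 0) return(NA_real_)
  sum(1 - v / m) / (length(v) - 1)
}

#' Promoter CpG density (observed/expected ratio)
#'
#' CpG count / (C count x G count) x N, where N is the sequence length and
#' CpG occurrences are counted by a sliding one-base scan. Undefined (NA)
#' when the sequence contains no C or no G.
#'
#' @param sequence Nucleotide string over `{A,C,G,T,N}`, length >= 2.
#' @return Observed/expected CpG ratio, or NA.
#' @export
compute_cpg_density <- function(sequence) {
  if (is.na(sequence) || nchar(sequence) < 2)
    stop("input error: sequence must have length >= 2")
  s <- Biostrings::DNAString(sequence)
  n_c <- Biostrings::countPattern("C", s)
  n_g <- Biostrings::countPattern("G", s)
  if (n_c == 0 || n_g == 0) return(NA_real_)
  n_cg <- Biostrings::countPattern("CG", s)
  n_cg / (n_c * n_g) * length(s)
}

#' Mean conservation score over a set of intervals
#'
#' Unweighted per-base mean of track scores over the union of the given
#' half-open intervals. Bases without a track value are excluded from both
#' numerator and denominator (absence of track data is not evidence of
#' non-conservation).
#'
#' @param track data.frame with columns `start`, `end` (0-based half-open)
#'   and `score` in \[0, 1\]; segment-constant values.
#' @param intervals data.frame with columns `start`, `end` (0-based
#'   half-open).
#' @return Mean score in \[0, 1\].
#' @export
conservation_score <- function(track, intervals) {
  if (any(intervals$end <= intervals$start))
    stop("input error: invalid interval")
  q <- IRanges::reduce(IRanges::IRanges(intervals$start + 1, intervals$end))
  s <- IRanges::IRanges(track$start + 1, track$end)
  ov <- IRanges::findOverlaps(q, s)
  if (length(ov) == 0) stop("scoring error: zero covered bases")
  inter <- IRanges::pintersect(q[S4Vectors::queryHits(ov)],
                               s[S4Vectors::subjectHits(ov)])
  w <- IRanges::width(inter)
  sc <- track$score[S4Vectors::subjectHits(ov)]
  sum(w * sc) / sum(w)
}

#' Distances from the TSS to the centromere and the arm telomere
#'
#' The arm is determined by which side of the centromere the TSS lies on;
#' the telomere distance is measured to that arm's chromosome end.
#'
#' @param tss TSS position (0-based), outside the centromere interval.
#' @param centromere `c(start, end)` half-open centromere interval.
#' @param chromosome_ends `c(start, end)` of the chromosome.
#' @return `c(dist_centromere, dist_telomere)`, both >= 0.
#' @export
positional_features <- function(tss, centromere, chromosome_ends) {
  if (tss >= centromere[1] && tss < centromere[2])
    stop("annotation error: TSS inside the centromere interval")
  if (tss < centromere[1]) {
    c(dist_centromere = centromere[1] - tss,
      dist_telomere = tss - chromosome_ends[1])
  } else {
    c(dist_centromere = tss - centromere[2],
      dist_telomere = chromosome_ends[2] - tss)
  }
}

.parse_cds <- function(tx_row) {
  data.frame(
    start = as.numeric(strsplit(tx_row$cds_starts, ",")[[1]]),
    end = as.numeric(strsplit(tx_row$cds_ends, ",")[[1]]))
}

.cell_stats <- function(mat, cols) {
  sub <- mat[, cols, drop = FALSE]
  list(mean = rowMeans(sub),
       var = apply(sub, 1, stats::var))
}

#' Assemble the 83-column feature table
#'
#' Computes every per-gene feature from the universe inputs: constraint
#' metrics are taken from the transcript with the lowest LOEUF; conservation
#' scores average the track over the canonical CDS and the 4 kb promoter
#' window; expression aggregates are sex-stratified means/variances with
#' cerebellar/other-brain metavalues and tau indices; structure, position and
#' paralogue summaries complete the table. Missing values (undefined tau,
#' degenerate CpG denominator, uncovered conservation) are left as NA and
#' recorded in the mask, never imputed here.
#'
#' @param universe Universe list ([generate_universe()] / [read_universe()]).
#' @param annotated Annotated gene table ([annotate_genes()]); computed if
#'   omitted.
#' @param paralogue_percentile Percentile defining close paralogues.
#' @return Object of class `feature_table`: list with `features` (data.frame:
#'   `symbol` + 83 numeric columns in schema order) and `mask` (logical
#'   matrix of missingness).
#' @export
assemble_feature_table <- function(universe, annotated = NULL,
                                   paralogue_percentile = 95) {
  g <- universe$genes
  if (anyDuplicated(g$symbol))
    stop("assembly error: duplicate gene symbols")
  if (is.null(annotated)) annotated <- annotate_genes(universe)
  n <- nrow(g)
  out <- data.frame(symbol = g$symbol, stringsAsFactors = FALSE)
  schema <- feature_schema()

  # constraint block: transcript with lowest LOEUF per gene
  cons <- universe$constraints
  best <- unlist(lapply(split(seq_len(nrow(cons)), cons$symbol), function(i)
    i[which.min(cons$loeuf[i])]))
  best <- best[g$symbol]
  for (f in schema$feature[schema$group == "constraint"])
    out[[f]] <- cons[[f]][best]

  # conservation block
  canon_id <- annotated$canonical_transcript[match(g$symbol,
                                                   annotated$symbol)]
  tx <- universe$transcripts
  track_by_chr <- split(universe$conservation,
                        universe$conservation$chrom)
  exon_score <- promoter_score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    trk <- track_by_chr[[g$chromosome[i]]]
    if (is.null(trk)) next
    cds <- .parse_cds(tx[tx$transcript_id == canon_id[i], , drop = FALSE])
    exon_score[i] <- tryCatch(conservation_score(trk, cds),
                              error = function(e) NA_real_)
    prom <- data.frame(start = g$tss[i] - 2000, end = g$tss[i] + 2001)
    promoter_score[i] <- tryCatch(conservation_score(trk, prom),
                                  error = function(e) NA_real_)
  }
  out$exon_score <- exon_score
  out$promoter_score <- promoter_score

  # expression blocks
  expr <- universe$expression
  smp <- universe$samples
  adult <- smp$dataset == "adult"
  groups <- list(Cereb = "cerebellar", Brain = "brain", Nerve = "nerve",
                 All = c("cerebellar", "brain", "nerve", "other"))
  for (sex in c("F", "M")) {
    for (gn in names(groups)) {
      cols <- smp$sample_id[adult & smp$sex == sex &
                              smp$tissue_group %in% groups[[gn]]]
      st <- .cell_stats(expr, cols)
      out[[paste("mean", gn, sex, sep = "_")]] <- st$mean
      out[[paste("var", gn, sex, sep = "_")]] <- st$var
    }
  }
  tau_from <- function(cols_by_tissue) {
    med <- vapply(cols_by_tissue, function(cols)
      apply(expr[, cols, drop = FALSE], 1, stats::median), numeric(n))
    med <- matrix(med, nrow = n,
                  dimnames = list(NULL, names(cols_by_tissue)))
    tis <- colnames(med)
    agg_cereb <- c("Cerebellum_1", "Cerebellum_2")
    agg_brain <- setdiff(grep("^Brain_", tis, value = TRUE), agg_cereb)
    rest <- setdiff(tis, c(agg_cereb, agg_brain))
    vapply(seq_len(n), function(i) {
      ab <- aggregate_brain(med[i, ], agg_cereb, agg_brain)
      compute_tau(c(ab, med[i, rest]))
    }, numeric(1))
  }
  adult_tissues <- unique(smp$tissue[adult])
  for (sex in c("F", "M")) {
    cbt <- lapply(stats::setNames(adult_tissues, adult_tissues), function(t)
      smp$sample_id[adult & smp$sex == sex & smp$tissue == t])
    out[[if (sex == "F") "tau_1" else "tau_2"]] <- tau_from(cbt)
  }
  cbt_all <- lapply(stats::setNames(adult_tissues, adult_tissues), function(t)
    smp$sample_id[adult & smp$tissue == t])
  out$tau_all <- tau_from(cbt_all)

  dev <- smp$dataset == "devel"
  ages <- list(Pre = "Pre", Post1 = "Post1", Post2 = "Post2",
               Post = c("Post1", "Post2"))
  for (an in names(ages)) {
    for (sex in c("F", "M")) {
      cols <- smp$sample_id[dev & smp$sex == sex &
                              smp$age_group %in% ages[[an]]]
      st <- .cell_stats(expr, cols)
      out[[paste("mean", an, sex, sep = "_")]] <- st$mean
      out[[paste("var", an, sex, sep = "_")]] <- st$var
    }
  }

  # structure block
  canon_rows <- tx[match(canon_id, tx$transcript_id), , drop = FALSE]
  cds_list <- lapply(seq_len(n), function(i) .parse_cds(canon_rows[i, ]))
  out$cds_length <- vapply(cds_list, function(d) sum(d$end - d$start),
                           numeric(1))
  out$exon_count <- vapply(cds_list, nrow, integer(1))
  out$transcript_length <- canon_rows$length
  out$promoter_cpg <- vapply(universe$promoters[g$symbol],
                             compute_cpg_density, numeric(1),
                             USE.NAMES = FALSE)

  # position block
  ci <- universe$chrom_info
  pos <- t(vapply(seq_len(n), function(i) {
    r <- ci[ci$chrom == g$chromosome[i], ]
    positional_features(g$tss[i], c(r$cen_start, r$cen_end), c(0, r$length))
  }, c(dist_centromere = 0, dist_telomere = 0)))
  out$dist_centromere <- pos[, 1]
  out$dist_telomere <- pos[, 2]

  # paralogue block (genes without hits get 0, a documented convention)
  hits <- universe$paralogues
  out$n_paralogues <- out$n_close_paralogues <- out$max_target_pct <-
    out$max_query_pct <- out$mean_target_pct <- 0
  if (nrow(hits) > 0) {
    byg <- split(hits, hits$query)
    thr_t <- stats::quantile(hits$target_pct, paralogue_percentile / 100,
                             type = 7, names = FALSE)
    thr_q <- stats::quantile(hits$query_pct, paralogue_percentile / 100,
                             type = 7, names = FALSE)
    idx <- match(names(byg), out$symbol)
    keep <- !is.na(idx)
    byg <- byg[keep]; idx <- idx[keep]
    out$n_paralogues[idx] <- vapply(byg, nrow, integer(1))
    out$n_close_paralogues[idx] <- vapply(byg, function(h)
      sum(h$target_pct > thr_t & h$query_pct > thr_q), numeric(1))
    out$max_target_pct[idx] <- vapply(byg, function(h) max(h$target_pct),
                                      numeric(1))
    out$max_query_pct[idx] <- vapply(byg, function(h) max(h$query_pct),
                                     numeric(1))
    out$mean_target_pct[idx] <- vapply(byg, function(h) mean(h$target_pct),
                                       numeric(1))
  }

  out <- out[, c("symbol", schema$feature)]
  stopifnot(ncol(out) == 84)
  mask <- is.na(as.matrix(out[, -1]))
  rownames(mask) <- out$symbol
  structure(list(features = out, mask = mask), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$features), "genes x",
      ncol(x$features) - 1, "features;",
      sum(x$mask), "masked cells\n")
  invisible(x)
}
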