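#' Pipeline configuration
#'
#' Exactly one of `synth` (a [synth_config()]) or `input_dir` (a directory in
#' the layout of [write_universe()]) must be given. Every numeric convention
#' of the pipeline is a field with the published convention as default.
#'
#' @param out_dir Output directory.
#' @param synth Synthetic-universe configuration, or NULL.
#' @param input_dir Directory of pre-exported input tables, or NULL.
#' @param d Target FDR for the prediction threshold (default 0.05).
#' @param top_k Ensemble size (default 5).
#' @param outer_folds,inner_folds Nested-CV fold counts.
#' @param rule Final prediction rule, `"conjunction"` (default) or
#'   `"disjunction"`.
#' @param families Classifier families for [classifier_registry()].
#' @param n_tests_deciles Bonferroni family size for decile enrichment
#'   (default 30: three metrics x ten deciles).
#' @param paralogue_percentile Close-paralogue percentile (default 95).
#' @param seed Master seed; stage seeds are derived from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, synth = NULL, input_dir = NULL,
                            d = .05, top_k = 5, outer_folds = 10,
                            inner_folds = 5,
                            rule = c("conjunction", "disjunction"),
                            families = c("adaboost", "bagged_trees",
                                         "svm_linear", "mlp",
                                         "random_forest", "dummy"),
                            n_tests_deciles = 30,
                            paralogue_percentile = 95, seed = 1L) {
  if (is.null(synth) == is.null(input_dir))
    stop("validation error: exactly one of synth or input_dir must be given")
  structure(list(out_dir = out_dir, synth = synth, input_dir = input_dir,
                 d = d, top_k = top_k, outer_folds = outer_folds,
                 inner_folds = inner_folds, rule = match.arg(rule),
                 families = families, n_tests_deciles = n_tests_deciles,
                 paralogue_percentile = paralogue_percentile,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_entry <- function(name, params, seed, files) {
  list(stage = name, params = params, seed = seed,
       checksums = as.list(tools::md5sum(files[file.exists(files)])),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Run the full pipeline
#'
#' Executes the stages simulate, annotate, features, enrich, lme, train,
#' predict, validate in order, writing each stage's outputs under `out_dir`
#' and recording a manifest entry (parameters, derived seed, output
#' checksums). Reruns with an identical configuration reproduce byte-identical
#' outputs; manifests differ only in timestamps.
#'
#' @param config A [pipeline_config()].
#' @return List: `manifest`, plus the in-memory stage products (`universe`,
#'   `annotated`, `features`, `deciles`, `lme`, `cv`, `predictions`,
#'   `validation`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list()
  seed <- config$seed

  # -- simulate (or load) --------------------------------------------------
  if (!is.null(config$synth)) {
    universe <- generate_universe(config$synth)
    udir <- out("universe")
    files <- write_universe(universe, udir)
    manifest$simulate <- .stage_entry("simulate",
                                      list(n_genes = config$synth$n_genes),
                                      config$synth$seed, files)
  } else {
    universe <- read_universe(config$input_dir)
    manifest$simulate <- .stage_entry(
      "simulate", list(input_dir = config$input_dir), NA,
      list.files(config$input_dir, full.names = TRUE))
  }
  if (nrow(universe$genes) == 0) stop("dependency error: empty universe")

  # -- annotate ------------------------------------------------------------
  annotated <- annotate_genes(universe,
                              paralogue_percentile =
                                config$paralogue_percentile)
  .write_tsv(annotated, out("annotated_genes.tsv"),
             "# subgroup labels: {C,PMT,ND} x {b,nb} x {i,t}")
  manifest$annotate <- .stage_entry(
    "annotate", list(percentile = config$paralogue_percentile), seed,
    out("annotated_genes.tsv"))

  # -- features ------------------------------------------------------------
  ft <- assemble_feature_table(universe, annotated,
                               config$paralogue_percentile)
  .write_tsv(ft$features, out("features.tsv"),
             "# 83-column feature table; NA = masked")
  manifest$features <- .stage_entry("features", list(n_features = 83), seed,
                                    out("features.tsv"))

  # -- enrich: decile enrichment of confirmed genes ------------------------
  labels <- stats::setNames(annotated$disorder_class == "confirmed",
                            annotated$symbol)
  metrics <- c("loeuf", "mis_z", "exon_score")
  deciles <- lapply(metrics, function(m) {
    v <- stats::setNames(ft$features[[m]], ft$features$symbol)
    decile_enrichment(v, labels[names(v)], n_tests = config$n_tests_deciles)
  })
  names(deciles) <- metrics
  dec_df <- do.call(rbind, Map(cbind, metric = metrics, deciles))
  .write_tsv(dec_df, out("decile_enrichment.tsv"),
             "# right-closed deciles of the pooled distribution")
  manifest$enrich <- .stage_entry(
    "enrich", list(n_tests = config$n_tests_deciles), seed,
    out("decile_enrichment.tsv"))

  # -- lme -----------------------------------------------------------------
  thresholds <- derive_thresholds(
    deciles, direction = c(loeuf = "low_extreme", mis_z = "high_extreme",
                           exon_score = "high_extreme"))
  lme <- classify_lme(ft, thresholds,
                      classes = stats::setNames(annotated$disorder_class,
                                                annotated$symbol))
  .write_tsv(lme$status, out("lme_status.tsv"),
             "# inclusive thresholds: L: loeuf<=, M: mis_z>=, E: exon_score>=")
  jsonlite::write_json(
    list(thresholds = lapply(thresholds, function(t)
      list(threshold = t$threshold, direction = t$direction,
           provenance = t$provenance)),
      euler = as.list(lme$euler$overall)),
    out("lme_summary.json"), auto_unbox = TRUE, digits = NA)
  manifest$lme <- .stage_entry(
    "lme", list(metrics = metrics), seed,
    c(out("lme_status.tsv"), out("lme_summary.json")))

  # -- train: nested CV on Cbi vs NDt --------------------------------------
  train_pos <- annotated$symbol[annotated$subgroup == "Cbi"]
  train_neg <- annotated$symbol[annotated$subgroup == "NDt"]
  train_sym <- c(train_pos, train_neg)
  norm <- normalize_features(ft, reference = train_sym)
  xs <- norm$data
  xtrain <- xs[match(train_sym, xs$symbol), , drop = FALSE]
  ytrain <- as.integer(xtrain$symbol %in% train_pos)
  registry <- classifier_registry(config$families)
  cv <- nested_cv(xtrain, ytrain, registry,
                  outer_folds = config$outer_folds,
                  inner_folds = config$inner_folds, seed = seed + 11L)
  jsonlite::write_json(
    lapply(cv, function(r) list(family = r$family, fold_mcc = r$fold_mcc,
                                mcc_mean = r$mcc_mean, mcc_sd = r$mcc_sd,
                                best_params = r$best_params)),
    out("cv_results.json"), auto_unbox = TRUE, digits = NA)
  manifest$train <- .stage_entry(
    "train", list(families = config$families,
                  outer_folds = config$outer_folds,
                  inner_folds = config$inner_folds,
                  n_pos = length(train_pos), n_neg = length(train_neg)),
    seed + 11L, out("cv_results.json"))

  # -- predict: ensemble, FDR threshold, final gene set --------------------
  ens <- build_ensemble(cv, xtrain, ytrain, registry,
                        top_k = min(config$top_k, length(registry)),
                        seed = seed + 23L)
  set.seed(seed + 31L)
  preds <- predict_ensemble(ens, xs)
  # the threshold is calibrated on out-of-fold training scores; refit-on-all
  # scores of training genes are optimistically separated
  oof <- oof_scores(cv, xtrain, ytrain, registry,
                    top_k = min(config$top_k, length(registry)),
                    folds = min(5, min(table(ytrain))), seed = seed + 41L)
  fdr <- estimate_fdr_threshold(oof[ytrain == 1], oof[ytrain == 0],
                                d = config$d)
  if (!fdr$ok) warning("no valid FDR threshold at d = ", config$d)
  t_use <- if (fdr$ok) fdr$t else Inf
  preds <- final_prediction(preds, t_use, rule = config$rule)
  preds$fdr_threshold <- t_use
  preds$rule <- config$rule
  .write_tsv(preds, out("predictions.tsv"),
             "# calibrated per-classifier probabilities; mean; FDR threshold")
  manifest$predict <- .stage_entry(
    "predict", list(d = config$d, rule = config$rule, t = t_use,
                    top_k = ens$top_k, families = names(ens$models)),
    seed + 23L, out("predictions.tsv"))

  # -- validate ------------------------------------------------------------
  nd <- annotated$symbol[annotated$disorder_class == "no_disorder"]
  vt <- table(factor(universe$variants$gene, levels = nd))
  counts <- stats::setNames(as.numeric(vt), nd)
  pred_flag <- stats::setNames(preds$predicted[match(nd, preds$symbol)], nd)
  cds <- stats::setNames(ft$features$cds_length, ft$features$symbol)
  validation <- list()
  if (any(pred_flag) && any(!pred_flag)) {
    validation$burden <- burden_report(counts, pred_flag, cds)
    memb <- universe$db_membership
    validation$overlap <- overlap_report(
      pred_flag, memb[memb$gene %in% nd, , drop = FALSE])
  } else {
    validation$notice <- "predicted or non-predicted group empty"
  }
  dmg <- damaging_filter(universe$variants)
  validation$domains <- domain_report(dmg, universe$domains,
                                      genes = nd[pred_flag[nd]])
  val_json <- out("validation_report.json")
  jsonlite::write_json(
    list(burden = if (!is.null(validation$burden)) list(
      raw_p = validation$burden$burden$raw$p_value,
      normalized_p = validation$burden$burden$normalized$p_value,
      pearson_r = validation$burden$burden$pearson$r,
      any_variant_or = validation$burden$any_variant$odds_ratio),
      overlap = if (!is.null(validation$overlap$fisher)) list(
        p = validation$overlap$fisher$p_value,
        or = validation$overlap$fisher$odds_ratio),
      domains = validation$domains[setdiff(names(validation$domains),
                                           "notice")],
      notice = validation$notice),
    val_json, auto_unbox = TRUE, digits = NA, null = "null")
  manifest$validate <- .stage_entry("validate", list(), seed, val_json)

  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  list(manifest = manifest, universe = universe, annotated = annotated,
       features = ft, deciles = deciles, lme = lme, cv = cv, ensemble = ens,
       predictions = preds, fdr = fdr, validation = validation)
}
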