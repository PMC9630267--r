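#' Matthews correlation coefficient
#'
#' Balanced binary classification score in \[-1, 1\]; 0 is chance level.
#' Returns 0 by convention when the denominator vanishes (e.g. constant
#' predictions).
#'
#' @param truth,pred Binary vectors (0/1 or logical).
#' @return MCC.
#' @export
mcc <- function(truth, pred) {
  truth <- as.integer(as.logical(truth)); pred <- as.integer(as.logical(pred))
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Min-max normalise features to \[0, 1\] against a reference set
#'
#' Scaling minima/maxima and imputation medians are computed on the reference
#' rows only (the training genes); all rows are then scaled, values outside
#' the reference range clip to \[0, 1\], and missing values are imputed with
#' the scaled reference median (imputation recorded per cell). A feature
#' constant on the reference is set to 0.5 everywhere with a warning.
#'
#' @param features data.frame with `symbol` plus numeric feature columns, or
#'   a `feature_table`.
#' @param reference Character vector of reference (training) symbols, or a
#'   logical/integer row index.
#' @return List: `data` (scaled data.frame), `imputed` (logical matrix),
#'   `stats` (per-feature min/max/median used).
#' @export
normalize_features <- function(features, reference) {
  if (inherits(features, "feature_table")) features <- features$features
  cols <- setdiff(names(features), "symbol")
  if (is.character(reference)) reference <- features$symbol %in% reference
  ref <- features[reference, cols, drop = FALSE]
  if (nrow(ref) == 0) stop("input error: empty reference set")
  out <- features
  imputed <- matrix(FALSE, nrow(features), length(cols),
                    dimnames = list(features$symbol, cols))
  st <- list()
  constant <- character(0)
  for (f in cols) {
    lo <- min(ref[[f]], na.rm = TRUE); hi <- max(ref[[f]], na.rm = TRUE)
    med <- stats::median(ref[[f]], na.rm = TRUE)
    v <- features[[f]]
    if (!is.finite(lo) || !is.finite(hi) || lo == hi) {
      constant <- c(constant, f)
      sc <- rep(.5, length(v))
      smed <- .5
    } else {
      sc <- pmin(1, pmax(0, (v - lo) / (hi - lo)))
      smed <- min(1, max(0, (med - lo) / (hi - lo)))
    }
    miss <- is.na(sc)
    sc[miss] <- smed
    imputed[, f] <- miss
    out[[f]] <- sc
    st[[f]] <- c(min = lo, max = hi, median = med)
  }
  if (length(constant))
    warning("constant feature(s) on reference set to 0.5: ",
            paste(constant, collapse = ", "))
  list(data = out, imputed = imputed, stats = st)
}

.as_x <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[setdiff(names(x), "symbol")])
  storage.mode(x) <- "double"
  x
}

#' Classifier family registry
#'
#' Each entry defines a model family: a hyperparameter grid, fit and predict
#' closures, whether the family emits probabilities or uncalibrated scores,
#' and whether cross-validated Platt calibration applies. The default
#' registry carries the five winning families of the published tournament —
#' adaptive boosting (shallow boosted trees), bootstrap-aggregated trees,
#' a linear max-margin classifier, a multilayer perceptron and a random
#' forest — plus a label-independent dummy baseline; the full 25-family
#' tournament is a superset this registry is designed to be extended to.
#'
#' @param families Character subset of
#'   `c("dummy", "adaboost", "bagged_trees", "svm_linear", "mlp",
#'   "random_forest")`.
#' @return Named list of classifier specs.
#' @export
classifier_registry <- function(families = c("dummy", "adaboost",
                                             "bagged_trees", "svm_linear",
                                             "mlp", "random_forest")) {
  rf_fit <- function(x, y, p, bag) {
    x <- .as_x(x)
    mtry <- if (bag) ncol(x) else max(1, floor(p$mtry_frac * ncol(x)))
    randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                               ntree = p$ntree, mtry = mtry,
                               nodesize = p$nodesize)
  }
  rf_pred <- function(m, x) unname(
    stats::predict(m, .as_x(x), type = "prob")[, "1"])
  all <- list(
    dummy = list(
      grid = list(strategy = c("stratified", "prior")),
      fit = function(x, y, p) list(p1 = mean(y), strategy = p$strategy),
      predict = function(m, x) {
        n <- nrow(.as_x(x))
        if (m$strategy == "stratified")
          as.numeric(stats::rbinom(n, 1, m$p1))
        else rep(m$p1, n)
      },
      emits = "probability", calibrate = FALSE),
    adaboost = list(
      grid = list(nrounds = c(50, 100), max_depth = c(1, 2),
                  eta = c(.3, .6)),
      fit = function(x, y, p)
        xgboost::xgboost(.as_x(x), factor(y, levels = c(0, 1)),
                         nrounds = p$nrounds, max_depth = p$max_depth,
                         learning_rate = p$eta, nthreads = 1, verbosity = 0),
      predict = function(m, x)
        as.numeric(stats::predict(m, .as_x(x), type = "response")),
      emits = "probability", calibrate = FALSE),
    bagged_trees = list(
      grid = list(ntree = 100, nodesize = c(1, 5)),
      fit = function(x, y, p) rf_fit(x, y, p, bag = TRUE),
      predict = rf_pred,
      emits = "probability", calibrate = FALSE),
    svm_linear = list(
      grid = list(cost = c(.1, 1, 10)),
      fit = function(x, y, p)
        e1071::svm(x = .as_x(x), y = factor(y, levels = c(0, 1)),
                   kernel = "linear", cost = p$cost, scale = FALSE),
      predict = function(m, x) {
        pr <- stats::predict(m, .as_x(x), decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
      },
      emits = "score", calibrate = TRUE),
    mlp = list(
      grid = list(size = c(4, 8), decay = c(.01, .1)),
      fit = function(x, y, p)
        nnet::nnet(x = .as_x(x), y = y, size = p$size, decay = p$decay,
                   maxit = 150, entropy = TRUE, trace = FALSE),
      predict = function(m, x) as.numeric(stats::predict(m, .as_x(x))),
      emits = "probability", calibrate = FALSE),
    random_forest = list(
      grid = list(ntree = 100, mtry_frac = c(.11, .3), nodesize = 1),
      fit = function(x, y, p) rf_fit(x, y, p, bag = FALSE),
      predict = rf_pred,
      emits = "probability", calibrate = FALSE)
  )
  missing <- setdiff(families, names(all))
  if (length(missing)) stop("unknown classifier families: ",
                            paste(missing, collapse = ", "))
  all[families]
}

#' Resolve a hyperparameter search plan
#'
#' Full grid when the exact combination count is at most `max_combos`,
#' otherwise a random draw of `max_combos` combinations.
#'
#' @param grid Named list of candidate value vectors.
#' @param max_combos Grid-search ceiling (default 100).
#' @return data.frame of candidate hyperparameter settings.
#' @export
resolve_search <- function(grid, max_combos = 100) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  if (nrow(combos) <= max_combos) return(combos)
  combos[sample(nrow(combos), max_combos), , drop = FALSE]
}

.make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.inner_select <- function(x, y, spec, inner_folds, max_combos = 100) {
  candidates <- resolve_search(spec$grid, max_combos)
  fold <- .make_folds(y, inner_folds)
  scores <- vapply(seq_len(nrow(candidates)), function(ci) {
    p <- as.list(candidates[ci, , drop = FALSE])
    mean(vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      m <- spec$fit(x[tr, , drop = FALSE], y[tr], p)
      prob <- spec$predict(m, x[!tr, , drop = FALSE])
      mcc(y[!tr], prob > .5)
    }, numeric(1)))
  }, numeric(1))
  as.list(candidates[which.max(scores), , drop = FALSE])
}

#' Nested cross-validation tournament
#'
#' Stratified outer k-fold / inner k-fold nested cross-validation for every
#' family in the registry: the inner loop selects hyperparameters by mean
#' inner MCC (grid search, or random search when the grid exceeds 100
#' combinations), the outer loop scores the refit model on held-out folds.
#' The same outer folds are used for every family. Reproducible from `seed`.
#'
#' @param x Normalised feature matrix or data.frame (training genes only).
#' @param y Binary labels (1 = positive class Cbi, 0 = negative class NDt).
#' @param registry [classifier_registry()] subset.
#' @param outer_folds,inner_folds Fold counts (defaults 10 and 5).
#' @param seed Integer seed.
#' @return Named list (one per family) of `cv_result`: `family`, `fold_mcc`,
#'   `mcc_mean`, `mcc_sd`, `best_params`.
#' @export
nested_cv <- function(x, y, registry = classifier_registry(),
                      outer_folds = 10, inner_folds = 5, seed = 1) {
  x <- .as_x(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("training error: single-class data")
  if (outer_folds > min(table(y)))
    stop("training error: outer_folds exceeds the minority class size")
  set.seed(seed)
  outer <- .make_folds(y, outer_folds)
  lapply(registry_named(registry), function(spec) {
    fold_mcc <- vapply(seq_len(outer_folds), function(f) {
      tr <- outer != f
      best <- .inner_select(x[tr, , drop = FALSE], y[tr], spec, inner_folds)
      m <- spec$fit(x[tr, , drop = FALSE], y[tr], best)
      mcc(y[!tr], spec$predict(m, x[!tr, , drop = FALSE]) > .5)
    }, numeric(1))
    best_params <- .inner_select(x, y, spec, inner_folds)
    structure(list(family = spec$name, fold_mcc = fold_mcc,
                   mcc_mean = mean(fold_mcc), mcc_sd = stats::sd(fold_mcc),
                   best_params = best_params),
              class = "cv_result")
  })
}

registry_named <- function(registry) {
  for (nm in names(registry)) registry[[nm]]$name <- nm
  registry
}

.platt_calibrate <- function(spec, x, y, params, folds = 5) {
  fold <- .make_folds(y, folds)
  oof <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    m <- spec$fit(x[tr, , drop = FALSE], y[tr], params)
    oof[!tr] <- spec$predict(m, x[!tr, , drop = FALSE])
  }
  # separable training scores give a saturated fit; that is fine for ranking
  suppressWarnings(stats::glm(y ~ s, family = stats::binomial(),
                              data = data.frame(y = y, s = oof)))
}

#' Build the top-k calibrated classifier ensemble
#'
#' Ranks families by mean nested-CV MCC (ties broken by lower MCC standard
#' deviation, then family name), refits the top `top_k` on all training data
#' with their selected hyperparameters, and applies cross-validated Platt
#' calibration to families that emit uncalibrated scores. A family unable to
#' emit a probability or calibratable score is excluded with a warning and
#' the next-ranked family promoted.
#'
#' @param cv_results Output of [nested_cv()].
#' @param x,y Training features and labels.
#' @param registry The registry used for `cv_results`.
#' @param top_k Ensemble size (default 5).
#' @param seed Integer seed (refits and calibration are stochastic).
#' @return Object of class `gene_ensemble` with fitted models, calibrators
#'   and the family ranking.
#' @export
build_ensemble <- function(cv_results, x, y, registry = classifier_registry(),
                           top_k = 5, seed = 1) {
  x <- .as_x(x); y <- as.integer(y)
  registry <- registry_named(registry)
  ord <- order(-vapply(cv_results, `[[`, numeric(1), "mcc_mean"),
               vapply(cv_results, `[[`, numeric(1), "mcc_sd"),
               names(cv_results))
  ranked <- names(cv_results)[ord]
  set.seed(seed)
  models <- list()
  for (fam in ranked) {
    if (length(models) == top_k) break
    spec <- registry[[fam]]
    if (!spec$emits %in% c("probability", "score")) {
      warning("family '", fam, "' cannot emit a probability; excluded")
      next
    }
    best <- cv_results[[fam]]$best_params
    cal <- if (isTRUE(spec$calibrate))
      .platt_calibrate(spec, x, y, best) else NULL
    models[[fam]] <- list(spec = spec, model = spec$fit(x, y, best),
                          calibrator = cal, params = best)
  }
  if (length(models) < top_k)
    stop("training error: fewer than top_k usable families (",
         length(models), " < ", top_k, ")")
  structure(list(models = models, ranking = ranked, top_k = top_k),
            class = "gene_ensemble")
}

#' Per-gene calibrated ensemble probabilities
#'
#' @param ensemble A `gene_ensemble` from [build_ensemble()].
#' @param features Normalised feature data.frame (with `symbol`) or matrix.
#' @param symbols Optional symbols when `features` is a bare matrix.
#' @return data.frame: `symbol`, one probability column per family,
#'   `mean_prob`, `all_above_half`.
#' @export
predict_ensemble <- function(ensemble, features, symbols = NULL) {
  if (is.data.frame(features) && "symbol" %in% names(features))
    symbols <- features$symbol
  x <- .as_x(features)
  if (is.null(symbols)) symbols <- rownames(x) %||% seq_len(nrow(x))
  probs <- vapply(ensemble$models, function(m) {
    s <- m$spec$predict(m$model, x)
    if (!is.null(m$calibrator))
      s <- unname(stats::predict(m$calibrator, data.frame(s = s),
                                 type = "response"))
    pmin(1, pmax(0, s))
  }, numeric(nrow(x)))
  probs <- matrix(probs, nrow = nrow(x),
                  dimnames = list(NULL, names(ensemble$models)))
  out <- data.frame(symbol = symbols, probs, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$mean_prob <- rowMeans(probs)
  out$all_above_half <- apply(probs > .5, 1, all)
  out
}

#' Out-of-fold ensemble scores for the training genes
#'
#' Cross-validated ensemble mean probabilities: the top-k ensemble is refit
#' on each training fold and scores are taken on the held-out fold, so every
#' training gene receives a probability from models that never saw it. These
#' are the scores the FDR threshold is estimated on — refit-on-all scores of
#' the training genes are optimistically separated and would understate the
#' threshold.
#'
#' @param cv_results Output of [nested_cv()] (ranking and hyperparameters).
#' @param x,y Training features and labels.
#' @param registry Classifier registry.
#' @param top_k Ensemble size.
#' @param folds Number of scoring folds (default 5).
#' @param seed Integer seed.
#' @return Numeric vector of out-of-fold mean probabilities aligned with the
#'   rows of `x`.
#' @export
oof_scores <- function(cv_results, x, y, registry = classifier_registry(),
                       top_k = 5, folds = 5, seed = 1) {
  x <- .as_x(x); y <- as.integer(y)
  set.seed(seed)
  fold <- .make_folds(y, folds)
  out <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    ens <- build_ensemble(cv_results, x[tr, , drop = FALSE], y[tr],
                          registry, top_k = top_k, seed = seed + f)
    out[!tr] <- predict_ensemble(ens, x[!tr, , drop = FALSE])$mean_prob
  }
  out
}

#' Estimate the FDR-controlled probability threshold
#'
#' Scans the distinct observed ensemble scores in decreasing order, defining
#' predictions as score >= t. Returns the smallest candidate t such that for
#' it and every larger candidate the running false discovery proportion among
#' known-class genes, |D >= t| / (|B >= t| + |D >= t|), stays strictly below
#' `d` — the largest prediction set whose running FDR never reaches the
#' target. Fails explicitly when even the top score violates the bound.
#'
#' @param scores_b Ensemble mean probabilities of known positives (class B).
#' @param scores_d Ensemble mean probabilities of known negatives (class D).
#' @param d Target FDR in (0, 1).
#' @return List: `ok`, `t` (NA on failure), `realized_fdr`, `d`.
#' @export
estimate_fdr_threshold <- function(scores_b, scores_d, d = .05) {
  if (d <= 0 || d >= 1) stop("input error: d must be in (0, 1)")
  if (!length(scores_b) || !length(scores_d))
    stop("input error: both known classes must be scored")
  cand <- sort(unique(c(scores_b, scores_d)), decreasing = TRUE)
  t_ok <- NA_real_; fdr_ok <- NA_real_
  for (t in cand) {
    Bt <- sum(scores_b >= t); Dt <- sum(scores_d >= t)
    fdr <- Dt / (Bt + Dt)
    if (fdr < d) { t_ok <- t; fdr_ok <- fdr } else break
  }
  list(ok = !is.na(t_ok), t = t_ok, realized_fdr = fdr_ok, d = d)
}

#' Final predicted gene set
#'
#' Conjunction rule (default): predicted iff all ensemble probabilities
#' exceed 0.5 AND the mean probability exceeds t. Disjunction: either
#' condition suffices.
#'
#' @param predictions Output of [predict_ensemble()].
#' @param t FDR threshold from [estimate_fdr_threshold()].
#' @param rule `"conjunction"` or `"disjunction"`.
#' @return `predictions` with a logical `predicted` column; the rule and t
#'   are recorded as attributes.
#' @export
final_prediction <- function(predictions, t,
                             rule = c("conjunction", "disjunction")) {
  rule <- match.arg(rule)
  if (is.na(t)) stop("input error: no valid FDR threshold available")
  predictions$predicted <- if (rule == "conjunction")
    predictions$all_above_half & predictions$mean_prob > t
  else predictions$all_above_half | predictions$mean_prob > t
  attr(predictions, "rule") <- rule
  attr(predictions, "fdr_threshold") <- t
  predictions
}

#' Permutation feature importance of the ensemble
#'
#' Importance of a feature is the mean decrease in ensemble MCC over
#' `n_repeats` random permutations of that feature's column, evaluated on
#' the supplied (ideally held-out) data.
#'
#' @param ensemble A `gene_ensemble`.
#' @param features Normalised features (data.frame with `symbol`, or matrix).
#' @param y Binary labels for the evaluation rows.
#' @param n_repeats Permutations per feature (default 5).
#' @param seed Integer seed.
#' @return data.frame: `feature`, `importance` (mean MCC drop), sorted
#'   decreasing.
#' @export
permutation_importance <- function(ensemble, features, y, n_repeats = 5,
                                   seed = 1) {
  stopifnot(n_repeats >= 1)
  x <- .as_x(features)
  y <- as.integer(y)
  set.seed(seed)
  base_prob <- predict_ensemble(ensemble, x)$mean_prob
  baseline <- mcc(y, base_prob > .5)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- xp[sample(nrow(x)), j]
      baseline - mcc(y, predict_ensemble(ensemble, xp)$mean_prob > .5)
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(feature = colnames(x), importance = imp,
                    stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}
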