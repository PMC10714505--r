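# Evaluate expr with a private, seeded RNG stream; the caller's RNG state is
# untouched so library code never perturbs user scripts.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified fold assignment
#'
#' Assigns every sample to exactly one test fold such that each fold holds
#' roughly `1/n_folds` of the samples and the patient fraction of every fold
#' is within one sample of the global fraction (shuffle within cohort, then
#' deal round-robin). Deterministic given `seed`.
#'
#' @param manifest An `fqm_manifest`.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list of class `fold_assignment`: `n_folds`, `seed`, and
#'   `assignment`, a named integer vector (sample_id -> fold in `1:n_folds`).
#' @export
make_folds <- function(manifest, n_folds = 10L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  counts <- table(manifest$cohort)
  if (any(counts < n_folds))
    stop("every cohort needs at least n_folds = ", n_folds, " samples (have ",
         paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  assignment <- integer(0)
  with_private_seed(seed, {
    for (coh in levels(manifest$cohort)) {
      ids <- manifest$sample_id[manifest$cohort == coh]
      ids <- sample(ids)
      folds <- rep(seq_len(n_folds), length.out = length(ids))
      a <- stats::setNames(folds, ids)
      assignment <- c(assignment, a)
    }
  })
  assignment <- assignment[manifest$sample_id]
  structure(list(n_folds = n_folds, seed = as.integer(seed),
                 assignment = assignment),
            class = "fold_assignment")
}

#' Training / test sample ids of one fold
#' @param folds A `fold_assignment`.
#' @param fold Fold index in `1:n_folds`.
#' @return List with `train` and `test` character vectors.
#' @export
fold_split <- function(folds, fold) {
  stopifnot(inherits(folds, "fold_assignment"), fold %in% seq_len(folds$n_folds))
  list(train = names(folds$assignment)[folds$assignment != fold],
       test = names(folds$assignment)[folds$assignment == fold])
}

#' Binary presence/absence feature matrix over a frequentmer catalog
#'
#' Feature columns are the catalog's control frequentmers followed by its
#' patient frequentmers, each block in ascending encoded order, so
#' coefficients are comparable across runs. `X[i, j] = 1` iff feature k-mer j
#' is in sample i's k-mer set. By the frequentmer absence condition, training
#' control samples are all-zero on patient-frequentmer columns and vice
#' versa; test samples may violate this, which is exactly the signal.
#'
#' @param catalog A `frequentmer_catalog`.
#' @param ksets Named list of `kmer_set` (names = sample ids).
#' @param sample_ids Samples to include as rows, in order.
#' @param manifest An `fqm_manifest` supplying labels.
#' @return A list of class `feature_matrix`: `fold_id`, `feature_kmers`,
#'   `feature_side` (`"control"`/`"patient"` per column), `X` (binary matrix,
#'   rownames = sample ids), `y` (named 0/1 vector, 1 = patient).
#' @export
build_features <- function(catalog, ksets, sample_ids, manifest) {
  stopifnot(inherits(catalog, "frequentmer_catalog"))
  n_feat <- length(catalog$control_fms) + length(catalog$patient_fms)
  if (n_feat == 0)
    stop("empty frequentmer catalog (fold ", catalog$fold_id, ", r = ",
         catalog$r, "); try a lower recurrency threshold r")
  missing_ks <- setdiff(sample_ids, names(ksets))
  if (length(missing_ks))
    stop("no kmer_set for sample(s): ", paste(missing_ks, collapse = ", "))
  features <- c(catalog$control_fms, catalog$patient_fms)
  side <- rep(c("control", "patient"),
              c(length(catalog$control_fms), length(catalog$patient_fms)))
  X <- matrix(0L, nrow = length(sample_ids), ncol = n_feat,
              dimnames = list(sample_ids, format_code(features)))
  for (i in seq_along(sample_ids))
    X[i, ] <- as.integer(features %in% ksets[[sample_ids[i]]]$kmers)
  cohort <- manifest$cohort[match(sample_ids, manifest$sample_id)]
  if (anyNA(cohort))
    stop("sample(s) not in manifest: ",
         paste(sample_ids[is.na(cohort)], collapse = ", "))
  y <- stats::setNames(as.integer(cohort == "patient"), sample_ids)
  structure(list(fold_id = catalog$fold_id, feature_kmers = features,
                 feature_side = side, X = X, y = y),
            class = "feature_matrix")
}

#' Principal component analysis of a feature matrix
#'
#' Column-mean-centered PCA (no unit-variance scaling) of the binary
#' presence matrix, reporting explained-variance ratios for up to
#' `n_components` components and the first three component coordinates for
#' separation plots.
#'
#' @param X Numeric matrix (samples x features), or a `feature_matrix`.
#' @param n_components Maximum number of components (default 90).
#' @return A list of class `pca_report`: `explained_variance_ratio`
#'   (non-increasing, sums to <= 1), `cumulative_variance`, `scores3` (first
#'   three PC coordinates), and the full `prcomp` fit.
#' @export
run_pca <- function(X, n_components = 90L) {
  if (inherits(X, "feature_matrix")) X <- X$X
  if (nrow(X) < 2) stop("PCA needs at least 2 samples")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  total_var <- sum(fit$sdev^2)
  ncomp <- min(n_components, length(fit$sdev))
  ratio <- (fit$sdev^2 / total_var)[seq_len(ncomp)]
  scores3 <- fit$x[, seq_len(min(3, ncol(fit$x))), drop = FALSE]
  structure(list(explained_variance_ratio = ratio,
                 cumulative_variance = cumsum(ratio),
                 scores3 = scores3, fit = fit),
            class = "pca_report")
}

# Shared ridge-logistic fit: sklearn's C (inverse regularization strength)
# maps onto glmnet's scale as lambda = 1 / (n * C) for alpha = 0. A short
# descending lambda path ending at the target keeps coordinate descent
# well-behaved; predictions are taken at the target lambda.
ridge_logistic <- function(X, y, C = 0.01, max_iter = 2000L) {
  if (length(unique(y)) < 2)
    stop("training labels contain a single class; cannot fit a classifier")
  lambda_target <- 1 / (nrow(X) * C)
  path <- lambda_target * c(100, 10, 1)
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = path, standardize = FALSE,
                   maxit = max_iter),
    # expected at small fold sizes; the ridge penalty handles it
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(fit = fit, lambda = lambda_target)
}

#' Fit the ridge-penalized logistic classifier of one fold
#'
#' L2-regularized logistic regression with inverse regularization strength
#' `C = 0.01` and iteration cap 2000, fit on the fold's training rows; test
#' scores are predicted patient probabilities. Deterministic given inputs.
#'
#' @param fm_train Training `feature_matrix`.
#' @param fm_test Test `feature_matrix` over the same features.
#' @param C Inverse regularization strength (default 0.01).
#' @param max_iter Iteration cap (default 2000).
#' @return A list of class `model_result`: `fold_id`, `model_kind`,
#'   `scores` (named, in `[0,1]`), `test_labels`, `coefficients` (one signed
#'   value per feature), `intercept`, `auc`, `confusion` (counts at the 0.5
#'   threshold).
#' @export
fit_logistic <- function(fm_train, fm_test, C = 0.01, max_iter = 2000L) {
  rl <- ridge_logistic(fm_train$X, fm_train$y, C = C, max_iter = max_iter)
  scores <- as.numeric(predict(rl$fit, newx = fm_test$X, s = rl$lambda,
                               type = "response"))
  names(scores) <- rownames(fm_test$X)
  beta <- as.numeric(predict(rl$fit, s = rl$lambda, type = "coefficients"))
  model_result(fm_train$fold_id, "logistic", scores, fm_test$y,
               coefficients = stats::setNames(beta[-1], colnames(fm_train$X)),
               intercept = beta[1])
}

#' Fit the gradient-boosted tree classifier of one fold
#'
#' XGBoost with `max_depth = 11`, `gamma = 0.3`, `eta = 0.2`, `alpha = 6`
#' (L1), logistic objective, single-threaded and seeded so results are
#' reproducible.
#'
#' @inheritParams fit_logistic
#' @param seed Integer seed for the booster.
#' @param nrounds Number of boosting rounds (default 100).
#' @return A `model_result` (no coefficients; tree ensembles have none).
#' @export
fit_boosted <- function(fm_train, fm_test, seed = 1L, nrounds = 100L) {
  if (length(unique(fm_train$y)) < 2)
    stop("training labels contain a single class; cannot fit a classifier")
  dtrain <- xgboost::xgb.DMatrix(fm_train$X, label = fm_train$y)
  params <- list(objective = "binary:logistic", max_depth = 11, gamma = 0.3,
                 eta = 0.2, alpha = 6, nthread = 1, seed = as.integer(seed))
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = as.integer(nrounds), verbose = 0)
  scores <- predict(booster, xgboost::xgb.DMatrix(fm_test$X))
  names(scores) <- rownames(fm_test$X)
  model_result(fm_train$fold_id, "boosted", scores, fm_test$y,
               coefficients = NULL, intercept = NA_real_)
}

model_result <- function(fold_id, kind, scores, test_labels, coefficients,
                         intercept) {
  structure(list(fold_id = fold_id, model_kind = kind, scores = scores,
                 test_labels = test_labels, coefficients = coefficients,
                 intercept = intercept,
                 auc = safe_auc(test_labels, scores),
                 confusion = confusion_counts(test_labels, scores)),
            class = "model_result")
}

# AUC via pROC (trapezoidal); NA with a warning for single-class test folds.
safe_auc <- function(labels, scores) {
  if (length(unique(labels)) < 2) {
    warning("single-class test fold; AUC undefined")
    return(NA_real_)
  }
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

confusion_counts <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  matrix(c(sum(labels == 0 & pred == 0), sum(labels == 0 & pred == 1),
           sum(labels == 1 & pred == 0), sum(labels == 1 & pred == 1)),
         nrow = 2, byrow = TRUE,
         dimnames = list(truth = c("control", "patient"),
                         predicted = c("control", "patient")))
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("model_result (%s, fold %s): test AUC %.3f over %d samples\n",
              x$model_kind, x$fold_id, x$auc, length(x$scores)))
  invisible(x)
}

#' Rank features by absolute logistic coefficient
#'
#' Orders features by `|coefficient|` descending, ties broken by encoded
#' k-mer ascending, and tallies how many of the top ranks are patient vs
#' control frequentmers (informativeness composition).
#'
#' @param result A logistic `model_result`.
#' @param fm The `feature_matrix` the model was fit on (supplies sides).
#' @return A list of class `ranked_features`: `table` (data frame kmer, side,
#'   coefficient, abs_coefficient, rank), and `cum_patient` /` cum_control`,
#'   cumulative counts by rank.
#' @export
coefficient_report <- function(result, fm) {
  if (is.null(result$coefficients))
    stop("coefficient_report requires a logistic model_result")
  tab <- data.frame(kmer = fm$feature_kmers, side = fm$feature_side,
                    coefficient = unname(result$coefficients),
                    stringsAsFactors = FALSE)
  tab$abs_coefficient <- abs(tab$coefficient)
  ord <- order(-tab$abs_coefficient, tab$kmer)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 cum_patient = cumsum(tab$side == "patient"),
                 cum_control = cumsum(tab$side == "control")),
            class = "ranked_features")
}

#' Retrain on the top-N features and trace the AUC curve
#'
#' For each N in `grid`, restricts the same train/test split to the top-N
#' features by absolute coefficient (ranked on the training fit only; the
#' selected columns keep their original order, so N = all features reproduces
#' the full model exactly), refits the logistic model, and records the test
#' AUC. Across folds the mean AUC and a normal-approximation 95% CI are
#' reported.
#'
#' @param fm_pairs List, one element per fold, each a list with `train` and
#'   `test` `feature_matrix` objects.
#' @param rankings List of `ranked_features`, parallel to `fm_pairs`. With
#'   `average_ranks = TRUE` a single consensus ranking (mean signed
#'   coefficient over the folds where each k-mer was a feature, ranked by
#'   absolute value) is used for every fold instead.
#' @param grid Feature counts to examine (default 25 to 1000).
#' @param average_ranks Use the cross-fold averaged ranking (default FALSE:
#'   per-fold ranking).
#' @inheritParams fit_logistic
#' @return A list of class `topn_curve`: `per_fold` (data frame fold_id, N,
#'   auc), `curve` (data frame N, mean_auc, ci_lo, ci_hi, n_folds).
#' @export
topn_retrain <- function(fm_pairs, rankings, grid = c(25, 50, 100, 200, 300,
                                                      400, 500, 750, 1000),
                         average_ranks = FALSE, C = 0.01, max_iter = 2000L) {
  stopifnot(length(fm_pairs) == length(rankings))
  consensus <- if (average_ranks) average_coefficient_ranking(rankings)
  per_fold <- list()
  for (f in seq_along(fm_pairs)) {
    fm_tr <- fm_pairs[[f]]$train
    fm_te <- fm_pairs[[f]]$test
    n_feat <- ncol(fm_tr$X)
    ranked_kmers <- if (average_ranks) {
      consensus$kmer[consensus$kmer %in% fm_tr$feature_kmers]
    } else rankings[[f]]$table$kmer
    for (N in grid) {
      if (N > n_feat) {
        warning("fold ", fm_tr$fold_id, ": N = ", N, " exceeds feature count ",
                n_feat, "; skipped")
        next
      }
      sel <- sort(match(ranked_kmers[seq_len(N)], fm_tr$feature_kmers))
      sub_tr <- fm_tr; sub_te <- fm_te
      sub_tr$X <- fm_tr$X[, sel, drop = FALSE]
      sub_te$X <- fm_te$X[, sel, drop = FALSE]
      sub_tr$feature_kmers <- fm_tr$feature_kmers[sel]
      sub_te$feature_kmers <- fm_te$feature_kmers[sel]
      res <- fit_logistic(sub_tr, sub_te, C = C, max_iter = max_iter)
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(fold_id = fm_tr$fold_id, N = N, auc = res$auc)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  if (is.null(per_fold))
    return(structure(list(per_fold = data.frame(fold_id = integer(0),
                                                N = integer(0),
                                                auc = numeric(0)),
                          curve = data.frame(N = integer(0),
                                             mean_auc = numeric(0),
                                             ci_lo = numeric(0),
                                             ci_hi = numeric(0),
                                             n_folds = integer(0))),
                     class = "topn_curve"))
  curve <- do.call(rbind, lapply(split(per_fold, per_fold$N), function(d) {
    m <- mean(d$auc, na.rm = TRUE)
    s <- stats::sd(d$auc, na.rm = TRUE)
    nf <- sum(!is.na(d$auc))
    half <- if (nf > 1) 1.96 * s / sqrt(nf) else 0
    data.frame(N = d$N[1], mean_auc = m, ci_lo = m - half, ci_hi = m + half,
               n_folds = nf)
  }))
  rownames(curve) <- NULL
  structure(list(per_fold = per_fold, curve = curve[order(curve$N), ]),
            class = "topn_curve")
}

# Consensus ranking: mean signed coefficient per k-mer over the folds where
# it was a feature, ranked by absolute mean, ties by code ascending.
average_coefficient_ranking <- function(rankings) {
  all_tab <- do.call(rbind, lapply(rankings, `[[`, "table"))
  sp <- split(all_tab, format_code(all_tab$kmer))
  agg <- do.call(rbind, lapply(sp, function(d)
    data.frame(kmer = d$kmer[1], side = d$side[1],
               coefficient = mean(d$coefficient), n_folds = nrow(d))))
  agg <- agg[order(-abs(agg$coefficient), agg$kmer), ]
  rownames(agg) <- NULL
  agg
}

#' Summarize per-fold classifier results
#'
#' Reports per-fold and pooled (all test scores concatenated) AUC, the mean
#' AUC with a 95% normal-approximation CI across folds, the pooled confusion
#' percentages at the 0.5 threshold, and a mean ROC curve (per-fold curves
#' interpolated onto a common specificity grid). Degenerate single-class test
#' folds are excluded from AUC aggregation with a warning.
#'
#' @param results List of `model_result`, one per fold.
#' @return A list of class `model_summary`: `per_fold_auc`, `mean_auc`,
#'   `sd_auc`, `ci`, `pooled_auc`, `confusion_counts`, `confusion_percent`
#'   (rows sum to 100 within each true class), `mean_roc` (data frame fpr,
#'   mean_tpr).
#' @export
evaluate_models <- function(results) {
  stopifnot(length(results) >= 1)
  aucs <- vapply(results, `[[`, numeric(1), "auc")
  fold_ids <- vapply(results, `[[`, numeric(1), "fold_id")
  if (anyNA(aucs))
    warning("excluding ", sum(is.na(aucs)),
            " degenerate single-class fold(s) from AUC aggregation")
  ok <- !is.na(aucs)
  mean_auc <- mean(aucs[ok])
  sd_auc <- if (sum(ok) > 1) stats::sd(aucs[ok]) else 0
  half <- if (sum(ok) > 1) 1.96 * sd_auc / sqrt(sum(ok)) else 0

  all_scores <- unlist(lapply(results, `[[`, "scores"))
  all_labels <- unlist(lapply(results, `[[`, "test_labels"))
  pooled_auc <- safe_auc(all_labels, all_scores)
  cc <- confusion_counts(all_labels, all_scores)
  cp <- 100 * sweep(cc, 1, pmax(rowSums(cc), 1), "/")

  fpr_grid <- seq(0, 1, by = 0.01)
  tprs <- vapply(results[ok], function(r) {
    ro <- pROC::roc(response = r$test_labels, predictor = r$scores,
                    levels = c(0, 1), direction = "<", quiet = TRUE)
    fpr <- rev(1 - ro$specificities)
    tpr <- rev(ro$sensitivities)
    stats::approx(fpr, tpr, xout = fpr_grid, ties = max, rule = 2)$y
  }, numeric(length(fpr_grid)))
  mean_roc <- data.frame(fpr = fpr_grid, mean_tpr = rowMeans(tprs))

  structure(list(per_fold_auc = stats::setNames(aucs, fold_ids),
                 mean_auc = mean_auc, sd_auc = sd_auc,
                 ci = c(lower = mean_auc - half, upper = mean_auc + half),
                 pooled_auc = pooled_auc,
                 confusion_counts = cc, confusion_percent = cp,
                 mean_roc = mean_roc),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("model_summary: mean AUC %.3f (95%% CI %.3f-%.3f), pooled AUC %.3f over %d folds\n",
              x$mean_auc, x$ci["lower"], x$ci["upper"], x$pooled_auc,
              length(x$per_fold_auc)))
  cat("confusion (% within true class):\n")
  print(round(x$confusion_percent, 1))
  invisible(x)
}

#' Cross-validated frequentmer classification
#'
#' The full leakage-free loop: for every fold, build the cohort index from
#' the fold's training samples only, derive the frequentmer catalog at
#' recurrency `r`, build train/test feature matrices, and fit the classifier.
#'
#' @param ksets Named list of `kmer_set` for all samples.
#' @param manifest An `fqm_manifest`.
#' @param folds A `fold_assignment` (or NULL to create one from `seed`).
#' @param r Recurrency threshold.
#' @param model `"logistic"` or `"boosted"`.
#' @param seed Seed (fold assignment when `folds` is NULL, and the booster).
#' @param n_folds Used only when `folds` is NULL.
#' @return A list of class `crossval_result`: `folds`, `catalogs`,
#'   `fm_pairs` (train/test feature matrices per fold), `results`
#'   (`model_result` per fold), `summary` (from [evaluate_models()]).
#' @export
crossval_classify <- function(ksets, manifest, folds = NULL, r = 15L,
                              model = c("logistic", "boosted"), seed = 1L,
                              n_folds = 10L) {
  model <- match.arg(model)
  if (is.null(folds)) folds <- make_folds(manifest, n_folds = n_folds, seed = seed)
  catalogs <- list(); fm_pairs <- list(); results <- list()
  for (f in seq_len(folds$n_folds)) {
    sp <- fold_split(folds, f)
    idx <- build_index(ksets[sp$train], manifest, fold_id = f)
    cat_f <- derive_frequentmers(idx, r)
    fm_tr <- build_features(cat_f, ksets, sp$train, manifest)
    fm_te <- build_features(cat_f, ksets, sp$test, manifest)
    res <- if (model == "logistic") fit_logistic(fm_tr, fm_te)
           else fit_boosted(fm_tr, fm_te, seed = seed)
    catalogs[[f]] <- cat_f
    fm_pairs[[f]] <- list(train = fm_tr, test = fm_te)
    results[[f]] <- res
  }
  structure(list(folds = folds, catalogs = catalogs, fm_pairs = fm_pairs,
                 results = results, summary = evaluate_models(results)),
            class = "crossval_result")
}
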