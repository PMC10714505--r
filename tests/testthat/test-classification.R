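test_that("fold assignment is stratified, exhaustive and deterministic", {
  man <- make_manifest(paste0("S", 1:40), rep(c("patient", "control"), 20))
  f <- make_folds(man, n_folds = 10, seed = 3)
  per_fold <- table(f$assignment, man$cohort[match(names(f$assignment),
                                                   man$sample_id)])
  expect_true(all(per_fold == 2)) # 20+20 over 10 folds: 2 of each per fold
  expect_setequal(names(f$assignment), man$sample_id)

  # uneven cohorts: per-fold counts stay within one of each other
  man2 <- make_manifest(paste0("S", 1:237),
                        rep(c("patient", "control"), c(123, 114)))
  f2 <- make_folds(man2, n_folds = 10, seed = 3)
  tab <- table(f2$assignment, man2$cohort[match(names(f2$assignment),
                                                man2$sample_id)])
  expect_true(all(tab[, "patient"] %in% c(12, 13)))
  expect_true(all(tab[, "control"] %in% c(11, 12)))

  expect_identical(make_folds(man2, 10, seed = 9)$assignment,
                   make_folds(man2, 10, seed = 9)$assignment)
  expect_false(identical(make_folds(man2, 10, seed = 9)$assignment,
                         make_folds(man2, 10, seed = 10)$assignment))

  tiny <- make_manifest(paste0("S", 1:12), rep(c("patient", "control"), c(8, 4)))
  expect_error(make_folds(tiny, n_folds = 5), "at least n_folds")
})

test_that("feature matrices are binary presence over the catalog column order", {
  toy <- toy_cohort()
  idx <- build_index(toy$ksets, toy$manifest)
  cat1 <- suppressWarnings(derive_frequentmers(idx, 1)) # CCC | CCA
  fm <- build_features(cat1, toy$ksets, names(toy$ksets), toy$manifest)
  expect_equal(fm$feature_side, c("control", "patient"))
  expect_equal(unname(fm$X["H1", ]), c(1L, 0L)) # H1 has CCC
  expect_equal(unname(fm$X["P2", ]), c(0L, 1L)) # P2 has CCA
  expect_equal(unname(fm$X["P1", ]), c(0L, 0L)) # P1 has neither
  expect_equal(unname(fm$y), c(0L, 0L, 0L, 1L, 1L))
  # training controls are structurally zero on all patient-fm columns
  expect_true(all(fm$X[fm$y == 0, fm$feature_side == "patient"] == 0))
  expect_true(all(fm$X[fm$y == 1, fm$feature_side == "control"] == 0))

  empty_cat <- derive_frequentmers(idx, 5)
  expect_error(build_features(empty_cat, toy$ksets, names(toy$ksets),
                              toy$manifest), "lower recurrency")
})

test_that("PCA reports centered variance ratios and full-rank reconstruction", {
  # two distinct rows duplicated: rank-1 after centering, PC1 explains 100%
  X <- rbind(matrix(rep(c(1, 0, 1, 0), 5), 5, 4, byrow = TRUE),
             matrix(rep(c(0, 1, 0, 1), 5), 5, 4, byrow = TRUE))
  p <- run_pca(X)
  expect_equal(p$explained_variance_ratio[1], 1.0, tolerance = 1e-12)

  set.seed(51)
  Xr <- matrix(rbinom(200, 1, 0.5), 20, 10)
  pr <- run_pca(Xr)
  expect_true(all(diff(pr$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pr$explained_variance_ratio), 1 + 1e-8)
  # reconstruction with all components is exact
  rec <- pr$fit$x %*% t(pr$fit$rotation)
  rec <- sweep(rec, 2, pr$fit$center, "+")
  expect_equal(rec, Xr, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(ncol(pr$scores3), 3)

  expect_error(run_pca(Xr[1, , drop = FALSE]), "at least 2")
})

test_that("the ridge logistic model separates, signs and nulls as expected", {
  set.seed(52)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(1 * y, 1 * (1 - y)) # patients carry feature 1, controls feature 2
  colnames(X) <- c("pat", "ctl")
  fm <- make_fm(X, y, sides = c("patient", "control"))
  res <- fit_logistic(fm, fm)
  expect_equal(res$auc, 1.0)
  expect_gt(res$coefficients[["pat"]], 0)
  expect_lt(res$coefficients[["ctl"]], 0)
  expect_true(all(res$scores >= 0 & res$scores <= 1))

  # permuted labels, held-out scoring: AUC hovers around 0.5
  aucs <- replicate(12, {
    Xn <- matrix(rbinom(2 * n * 6, 1, 0.5), 2 * n, 6)
    yp <- sample(rep(0:1, n))
    tr <- seq_len(n); te <- n + seq_len(n)
    fit_logistic(make_fm(Xn[tr, ], yp[tr]), make_fm(Xn[te, ], yp[te]))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.12)

  expect_error(fit_logistic(make_fm(X, rep(1, n)), fm), "single class")
})

test_that("the boosted model is seeded, deterministic and signal-dependent", {
  set.seed(53)
  n <- 40
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(1 * y, rbinom(n, 1, 0.5))
  fm <- make_fm(X, y)
  r1 <- fit_boosted(fm, fm, seed = 4)
  r2 <- fit_boosted(fm, fm, seed = 4)
  expect_equal(r1$auc, 1.0)
  expect_identical(r1$scores, r2$scores)

  const <- make_fm(matrix(1, n, 3), y)
  expect_equal(fit_boosted(const, const, seed = 4)$auc, 0.5)
})

test_that("coefficient ranking orders by |coefficient| with code tie-breaks", {
  fm <- make_fm(matrix(0, 4, 3), c(0, 0, 1, 1),
                sides = c("control", "patient", "patient"),
                feature_kmers = c(30, 10, 20))
  res <- structure(list(coefficients = c(`30` = -1, `10` = 2, `20` = 0.5),
                        model_kind = "logistic"), class = "model_result")
  rk <- coefficient_report(res, fm)
  expect_equal(rk$table$coefficient, c(2, -1, 0.5))
  expect_equal(rk$table$kmer, c(10, 30, 20))

  # all-zero coefficients: pure code order
  res0 <- structure(list(coefficients = c(`30` = 0, `10` = 0, `20` = 0)),
                    class = "model_result")
  rk0 <- coefficient_report(res0, fm)
  expect_equal(rk0$table$kmer, c(10, 20, 30))

  # composition: patient count among the top ranks
  expect_equal(rk$cum_patient[2], 1)
  expect_equal(rk$cum_patient[3], 2)
})

test_that("top-N retraining reproduces the full model at N = all features", {
  set.seed(54)
  n <- 50; p <- 12
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(1 * y, 1 * (1 - y), matrix(rbinom(n * (p - 2), 1, 0.3), n, p - 2))
  colnames(X) <- NULL
  fm <- make_fm(X, y, sides = rep(c("patient", "control"), c(6, 6)),
                feature_kmers = as.numeric(1:p))
  full <- fit_logistic(fm, fm)
  rk <- coefficient_report(full, fm)
  tc <- topn_retrain(list(list(train = fm, test = fm)), list(rk),
                     grid = c(2, p))
  expect_identical(tc$per_fold$auc[tc$per_fold$N == p], full$auc)
  # only two features carry signal: the curve is flat from N = 2 onward
  expect_equal(tc$per_fold$auc[tc$per_fold$N == 2], full$auc)
  expect_warning(topn_retrain(list(list(train = fm, test = fm)), list(rk),
                              grid = p + 5), "skipped")
})

test_that("model evaluation matches hand-computable summaries", {
  mk_res <- function(scores, labels, fold)
    structure(list(fold_id = fold, model_kind = "logistic", scores = scores,
                   test_labels = labels,
                   auc = frequentmer:::safe_auc(labels, scores),
                   confusion = frequentmer:::confusion_counts(labels, scores)),
              class = "model_result")

  # scores equal to labels: perfect
  r_perf <- mk_res(c(1, 0, 1, 0), c(1, 0, 1, 0), 1)
  s <- evaluate_models(list(r_perf))
  expect_equal(s$mean_auc, 1)
  expect_equal(unname(diag(s$confusion_percent)), c(100, 100))

  # all scores 0.5: no discrimination
  expect_equal(mk_res(rep(0.5, 6), rep(c(0, 1), 3), 1)$auc, 0.5)

  # the 4-sample hand case: AUC 0.75 by threshold enumeration
  labels <- c(1, 0, 1, 0); scores <- c(.9, .8, .3, .1)
  expect_equal(brute_force_auc(labels, scores), 0.75)
  expect_equal(mk_res(scores, labels, 1)$auc, 0.75)

  # degenerate single-class fold excluded with a warning
  r_deg <- suppressWarnings(mk_res(c(.6, .7), c(1, 1), 2))
  expect_warning(s2 <- evaluate_models(list(r_perf, r_deg)), "degenerate")
  expect_equal(s2$mean_auc, 1)
})

test_that("AUC implementation agrees with brute-force threshold enumeration", {
  set.seed(55)
  for (trial in 1:10) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2) # ties likely
    expect_equal(frequentmer:::safe_auc(labels, scores),
                 brute_force_auc(labels, scores))
  }
})
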