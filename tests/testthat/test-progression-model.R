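test_that("leave-two-out folds enumerate every case-control pair", {
  f <- leave_two_out_folds(c("case", "case", "control", "control"))
  expect_length(f, 4L)
  f19 <- leave_two_out_folds(rep(c("case", "control"), each = 19))
  expect_length(f19, 361L)
  tested <- sort(unique(unlist(lapply(f19, `[[`, "test_pair"))))
  expect_equal(tested, 1:38)
  for (fd in f19) {
    expect_length(fd$train_ids, 36L)
    expect_length(intersect(fd$train_ids, fd$test_pair), 0L)
    held <- rep(c("case", "control"), each = 19)[fd$test_pair]
    expect_setequal(held, c("case", "control"))
  }
  expect_error(leave_two_out_folds(c("case", "control", "control")),
               "insufficient-data")
})

test_that("the fast linear decision path agrees with predict.svm", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(12:30, 1); p <- sample(1:4, 1)
    x <- matrix(rnorm(n * p), n)
    y <- factor(sample(c("control", "case"), n, TRUE),
                levels = c("control", "case"))
    if (nlevels(droplevels(y)) < 2) next
    fit <- e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
    m <- opgpredict:::.svm_linear_fit(x, y, 1)
    xt <- matrix(rnorm(8 * p), 8)
    expect_equal(opgpredict:::.svm_linear_class(m, xt),
                 as.character(predict(fit, xt)))
  }
})

test_that("sequential selection finds the separator and stops on noise", {
  set.seed(5)
  x <- cbind(sep = rep(c(2, 0), each = 10) + rnorm(20, 0, 0.05),
             matrix(rnorm(20 * 9), 20,
                    dimnames = list(NULL, sprintf("noise_%d", 1:9))))
  y <- rep(c("case", "control"), each = 10)
  sel <- sequential_forward_selection(x, y)
  expect_equal(sel[1], "sep")
  path <- attr(sel, "accuracy_path")
  expect_true(all(diff(c(0, path)) > 0))  # strictly improving additions
  # all-constant features: no candidate can beat the majority baseline
  xc <- matrix(1, 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_length(sequential_forward_selection(xc, y), 0L)
  # duplicated perfect feature: the lower column index wins
  xdup <- cbind(first = x[, "sep"], second = x[, "sep"])
  expect_equal(sequential_forward_selection(xdup, y)[1], "first")
  expect_error(sequential_forward_selection(x, rep("case", 20)),
               "insufficient-data")
})

test_that("svm predictions separate a separable toy set without leakage", {
  set.seed(8)
  x <- rbind(matrix(rnorm(20, 3, 0.3), 10, 2),
             matrix(rnorm(20, -3, 0.3), 10, 2))
  y <- rep(c("case", "control"), each = 10)
  res <- fit_predict_svm(x, y, x)
  expect_equal(res$pred, y)  # 100% training accuracy when separable
  expect_true(all(res$score[1:10] > res$score[11:20]))
  # a test row equal to a training case row is predicted case
  res1 <- fit_predict_svm(x, y, x[1, , drop = FALSE])
  expect_equal(res1$pred, "case")
  # permuting training rows does not change predictions
  perm <- sample(20)
  res2 <- fit_predict_svm(x[perm, ], y[perm], x)
  expect_equal(res2$pred, res$pred)
  expect_error(fit_predict_svm(x, rep("case", 20), x),
               "insufficient-data")
})

test_that("training is independent of held-out rows", {
  set.seed(12)
  x <- matrix(rnorm(30 * 5), 30,
              dimnames = list(NULL, sprintf("f%d", 1:5)))
  x[, 1] <- x[, 1] + rep(c(1.5, 0), each = 15)
  y <- rep(c("case", "control"), each = 15)
  tr <- 1:24; te <- 25:30
  sel1 <- sequential_forward_selection(x[tr, ], y[tr])
  probe <- matrix(rnorm(4 * 5), 4, dimnames = list(NULL, colnames(x)))
  p1 <- fit_predict_svm(x[tr, ], y[tr], probe)
  # corrupt the held-out rows: selection and the trained decision function
  # must not move
  x2 <- x; x2[te, ] <- 1e3
  sel2 <- sequential_forward_selection(x2[tr, ], y[tr])
  p2 <- fit_predict_svm(x2[tr, ], y[tr], probe)
  expect_identical(sel1, sel2)
  expect_equal(p1, p2)
})

test_that("metrics follow their defining formulas with guarded zeros", {
  m <- compute_metrics(c(TP = 17, TN = 0, FP = 0, FN = 2))
  expect_equal(m$sensitivity, 17 / 19)
  m2 <- compute_metrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(m2$accuracy, 1)
  expect_equal(m2$specificity, 1)
  m3 <- compute_metrics(c(TP = 0, TN = 5, FP = 3, FN = 0))
  expect_true(is.na(m3$sensitivity))
  expect_equal(m3$undefined, "sensitivity")
  expect_equal(m3$specificity, 5 / 8)
})

test_that("AUC equals the brute-force concordant-pair count", {
  set.seed(33)
  for (i in 1:20) {
    n1 <- sample(2:10, 1); n0 <- sample(2:10, 1)
    s <- c(rnorm(n1), rnorm(n0))
    if (i %% 3 == 0) s <- round(s)  # force ties
    y <- rep(c("case", "control"), c(n1, n0))
    r <- roc_analysis(s, y, n_boot = 0)
    conc <- 0
    for (a in s[seq_len(n1)]) for (b in s[n1 + seq_len(n0)])
      conc <- conc + (a > b) + 0.5 * (a == b)
    expect_identical(r$auc, conc / (n1 * n0))
  }
})

test_that("ROC endpoints and the optimal cutoff behave", {
  y <- rep(c("case", "control"), each = 5)
  r <- roc_analysis(c(6:10, 1:5), y, n_boot = 100, seed = 2)
  expect_equal(r$auc, 1)
  expect_equal(r$optimal_sensitivity, 1)
  expect_equal(r$optimal_specificity, 1)
  expect_true(all(r$auc_ci >= 0 & r$auc_ci <= 1))
  # label-independent scores drift to 0.5
  set.seed(6)
  y2 <- rep(c("case", "control"), each = 500)
  r2 <- roc_analysis(rnorm(1000), y2, n_boot = 0)
  expect_lt(abs(r2$auc - 0.5), 0.06)
  expect_error(roc_analysis(1:5, rep("case", 5)), "insufficient-data")
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  s <- rnorm(40); y <- rep(c("case", "control"), each = 20)
  r <- roc_analysis(s, y, n_boot = 0)
  ref <- pROC::roc(response = y, predictor = s, levels = c("control", "case"),
                   direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
})

test_that("feature ranking orients AUC and flags constants", {
  y <- rep(c("case", "control"), each = 10)
  x <- cbind(perfect = rep(c(1, 0), each = 10),
             anti = rep(c(0, 1), each = 10),
             flat = rep(1, 20))
  rk <- rank_features_by_auc(x, y)
  expect_equal(rk$auc[rk$feature == "perfect"], 1)
  expect_equal(rk$auc[rk$feature == "anti"], 1)  # orientation-corrected
  expect_equal(rk$direction[rk$feature == "anti"], -1)
  expect_equal(rk$auc[rk$feature == "flat"], 0.5)
  expect_equal(rk$p_value[rk$feature == "flat"], 1)
  # pure noise at the study's group sizes stays near chance
  set.seed(77)
  noise <- matrix(rnorm(38 * 20), 38,
                  dimnames = list(NULL, sprintf("n%d", 1:20)))
  rk2 <- rank_features_by_auc(noise, rep(c("case", "control"), each = 19))
  expect_lt(stats::median(rk2$auc), 0.70)
})

test_that("subject-level evaluation conserves the confusion counts", {
  tab <- simulate_progression_features(4, 4, n_noise = 3,
                                       fa_mean_case = 12, fa_sd_case = 1,
                                       fa_mean_control = 2, fa_sd_control = 1,
                                       seed = 3)
  rep <- evaluate_progression_model(tab, max_features = 3, n_boot = 50,
                                    seed = 1)
  expect_equal(rep$n_folds, 16L)
  expect_equal(unname(sum(rep$confusion)), 8L)  # one decision per subject
  expect_equal(rep$confusion[["TP"]] + rep$confusion[["FN"]], 4L)
  expect_equal(rep$confusion[["TN"]] + rep$confusion[["FP"]], 4L)
  # reported accuracy recomputed from the per-subject predictions exactly
  acc <- mean(rep$subject_predictions$pred == rep$subject_predictions$truth)
  expect_identical(rep$accuracy, acc)
  # a 10-sigma separation should be learned perfectly
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$roc$auc, 1)
})
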