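# Progression classification: linear SVM with sequential forward feature
# selection inside paired leave-two-out cross-validation; confusion
# metrics, ROC/AUC with optimal cutoff, and univariate feature ranking.

.as_label <- function(labels) {
  y <- factor(labels, levels = c("control", "case"))
  if (any(is.na(y)))
    stop("labels must be 'case' or 'control'", call. = FALSE)
  y
}

#' Enumerate paired leave-two-out folds
#'
#' One fold per (case, control) pair: the model is trained on all subjects
#' except one case and one control, and evaluated on the held-out pair,
#' repeated over every pair — `n_cases * n_controls` folds, so every
#' subject is tested at least once.
#'
#' @param labels character vector of "case"/"control" per subject; names
#'   (or indices) identify subjects
#' @return list of folds, each `list(train_ids, test_pair)` of indices
#'   into `labels`
#' @export
leave_two_out_folds <- function(labels) {
  y <- .as_label(labels)
  cases <- which(y == "case"); controls <- which(y == "control")
  if (length(cases) < 2L || length(controls) < 2L)
    stop("insufficient-data error: need >= 2 cases and >= 2 controls",
         call. = FALSE)
  folds <- vector("list", length(cases) * length(controls))
  i <- 0L
  for (ca in cases) for (co in controls) {
    i <- i + 1L
    folds[[i]] <- list(train_ids = setdiff(seq_along(y), c(ca, co)),
                       test_pair = c(ca, co))
  }
  folds
}

# z-score columns on the training rows only; zero-variance columns map to 0
.standardize <- function(train_x, test_x = NULL) {
  n <- nrow(train_x)
  mu <- colMeans(train_x)
  sd <- sqrt(pmax(0, (colSums(train_x^2) - n * mu^2) / (n - 1)))
  sd[sd < 1e-12 | is.na(sd)] <- 1
  tr <- sweep(sweep(train_x, 2, mu), 2, sd, "/")
  te <- if (!is.null(test_x)) sweep(sweep(test_x, 2, mu), 2, sd, "/")
  list(train = tr, test = te)
}

#' Fit a linear SVM and predict held-out rows
#'
#' Features are z-scored using the training rows only (no test leakage);
#' a linear-kernel SVM with fixed cost is fitted and applied to the test
#' rows. Decision scores are oriented so that larger means more
#' case-like.
#'
#' @param train_x,test_x numeric matrices (rows x features)
#' @param train_y labels ("case"/"control") for the training rows
#' @param cost SVM regularization constant (default 1)
#' @return `list(pred, score)`: predicted labels and oriented decision
#'   scores for the test rows
#' @export
fit_predict_svm <- function(train_x, train_y, test_x, cost = 1) {
  y <- .as_label(train_y)
  if (nlevels(droplevels(y)) < 2L)
    stop("insufficient-data error: training set has a single class",
         call. = FALSE)
  z <- .standardize(train_x, test_x)
  fit <- e1071::svm(z$train, y, kernel = "linear", cost = cost,
                    scale = FALSE, fitted = FALSE,
                    na.action = stats::na.pass)
  tr_dv <- as.numeric(attr(stats::predict(fit, z$train,
                                          decision.values = TRUE),
                           "decision.values"))
  flip <- mean(tr_dv[y == "case"]) < mean(tr_dv[y == "control"])
  pr <- stats::predict(fit, z$test, decision.values = TRUE)
  score <- as.numeric(attr(pr, "decision.values"))
  if (flip) score <- -score
  list(pred = as.character(pr), score = score)
}

# deterministic stratified inner folds: subjects of each class assigned
# round-robin in row order
.inner_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# fast linear-SVM path used inside the selection loop: the decision value
# of a linear svm is x.w - rho with w = t(SV) %*% coefs (verified against
# predict.svm in the test suite)
.svm_linear_fit <- function(x, y, cost) {
  # inputs are NA-free by construction; skipping na.omit and the fitted
  # values cuts most of the per-call overhead in the selection loop
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                    fitted = FALSE, na.action = stats::na.pass)
  list(w = crossprod(fit$SV, fit$coefs), rho = fit$rho,
       lab_pos = fit$levels[fit$labels[1L]],
       lab_neg = fit$levels[fit$labels[2L]])
}

.svm_linear_class <- function(m, x) {
  ifelse(as.numeric(x %*% m$w) - m$rho > 0, m$lab_pos, m$lab_neg)
}

# inner-CV accuracy of the SVM restricted to feature set `cols`, using
# per-fold pre-standardized matrices
.inner_cv_accuracy <- function(pre, n, cols, cost) {
  correct <- 0L
  for (pf in pre) {
    if (is.null(pf)) next
    m <- .svm_linear_fit(pf$ztr[, cols, drop = FALSE], pf$ytr, cost)
    correct <- correct +
      sum(.svm_linear_class(m, pf$zte[, cols, drop = FALSE]) == pf$yte)
  }
  correct / n
}

#' Sequential forward feature selection
#'
#' Greedy loop: at each step, the candidate feature maximizing the
#' stratified inner-CV accuracy of the linear SVM is added; the loop stops
#' at the first step with no accuracy improvement (or at `max_features`).
#' Ties are broken toward the lower column index, so the procedure is
#' deterministic. The starting accuracy is the majority-class rate, so a
#' table of uninformative features yields an empty selection.
#'
#' @param train_x numeric matrix (rows x features) with column names
#' @param train_y labels ("case"/"control")
#' @param max_features cap on the number of selected features
#' @param inner_k inner cross-validation folds (default 5, reduced when a
#'   class is smaller)
#' @param cost SVM cost
#' @return character vector of selected feature names in addition order;
#'   attribute `accuracy_path` records the inner-CV accuracy after each
#'   addition
#' @export
sequential_forward_selection <- function(train_x, train_y, max_features = 10L,
                                         inner_k = 5L, cost = 1) {
  y <- .as_label(train_y)
  if (nlevels(droplevels(y)) < 2L)
    stop("insufficient-data error: both classes required", call. = FALSE)
  k <- min(inner_k, min(table(y)))
  # with fewer than 2 subjects in a class no inner CV is possible: no
  # candidate can demonstrate an improvement, so nothing is selected
  if (k < 2L)
    return(structure(character(0), accuracy_path = numeric(0)))
  fold <- .inner_folds(y, k)
  # standardize once per inner fold (columnwise, training rows only);
  # candidate subsets then just pick columns
  pre <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2L) return(NULL)
    z <- .standardize(train_x[tr, , drop = FALSE],
                      train_x[!tr, , drop = FALSE])
    list(ztr = z$train, ytr = y[tr], zte = z$test,
         yte = as.character(y[!tr]))
  })
  p <- ncol(train_x)
  selected <- integer(0)
  best_acc <- max(table(y)) / length(y)  # majority-class baseline
  path <- numeric(0)
  while (length(selected) < min(max_features, p)) {
    cand <- setdiff(seq_len(p), selected)
    accs <- vapply(cand, function(j)
      .inner_cv_accuracy(pre, length(y), c(selected, j), cost),
      numeric(1))
    j_best <- cand[which.max(accs)]  # which.max -> lowest index on ties
    if (max(accs) <= best_acc) break
    selected <- c(selected, j_best)
    best_acc <- max(accs)
    path <- c(path, best_acc)
  }
  structure(colnames(train_x)[selected], accuracy_path = path)
}

#' Confusion counts from predictions
#'
#' @param pred,truth character vectors of "case"/"control"
#' @return named integer vector TP, TN, FP, FN ("case" is positive)
#' @export
confusion_counts <- function(pred, truth) {
  c(TP = sum(pred == "case" & truth == "case"),
    TN = sum(pred == "control" & truth == "control"),
    FP = sum(pred == "case" & truth == "control"),
    FN = sum(pred == "control" & truth == "case"))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' accuracy = (TP+TN)/N; sensitivity = TP/(TP+FN);
#' specificity = TN/(TN+FP). A zero denominator yields `NA` with the
#' `undefined` flag set, never an error.
#'
#' @param counts named vector with TP, TN, FP, FN
#' @return list with `accuracy`, `sensitivity`, `specificity` and a
#'   character vector `undefined` naming any metric with a zero
#'   denominator
#' @export
compute_metrics <- function(counts) {
  n <- sum(counts)
  if (n == 0) stop("insufficient-data error: no predictions", call. = FALSE)
  undef <- character(0)
  sens <- if ((counts["TP"] + counts["FN"]) > 0)
    unname(counts["TP"] / (counts["TP"] + counts["FN"]))
  else { undef <- c(undef, "sensitivity"); NA_real_ }
  spec <- if ((counts["TN"] + counts["FP"]) > 0)
    unname(counts["TN"] / (counts["TN"] + counts["FP"]))
  else { undef <- c(undef, "specificity"); NA_real_ }
  list(accuracy = unname((counts["TP"] + counts["TN"]) / n),
       sensitivity = sens, specificity = spec, undefined = undef)
}

# rank-based AUC: Mann-Whitney U / (n1 * n0), ties counted one half
.auc_rank <- function(scores, is_case) {
  n1 <- as.numeric(sum(is_case)); n0 <- as.numeric(sum(!is_case))
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis with optimal cutoff and bootstrap CI
#'
#' The AUC is the Mann-Whitney U statistic divided by `n1 * n0` (ties
#' counted one half). The ROC curve is swept over all unique score
#' thresholds (predict case when score >= threshold); the optimal cutoff
#' is the threshold whose ROC point is nearest (0, 1) in Euclidean
#' distance on the (1 - specificity, sensitivity) plane. The 95% CI is a
#' stratified bootstrap percentile interval.
#'
#' @param scores numeric decision scores (larger = more case-like)
#' @param labels "case"/"control" per score
#' @param n_boot bootstrap resamples for the CI (default 2000)
#' @param seed seed for the bootstrap
#' @return object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `auc_ci`, `optimal_cutoff`, plus the point
#'   (`optimal_sensitivity`, `optimal_specificity`)
#' @export
roc_analysis <- function(scores, labels, n_boot = 2000L, seed = 1L) {
  y <- .as_label(labels)
  is_case <- y == "case"
  if (!any(is_case) || all(is_case))
    stop("insufficient-data error: both classes required", call. = FALSE)
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[is_case] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!is_case] < t), numeric(1))
  auc <- .auc_rank(scores, is_case)
  d2 <- (1 - spec)^2 + (1 - sens)^2
  opt <- which.min(d2)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    i1 <- which(is_case); i0 <- which(!is_case)
    bt <- vapply(seq_len(n_boot), function(b) {
      s1 <- scores[sample(i1, length(i1), replace = TRUE)]
      s0 <- scores[sample(i0, length(i0), replace = TRUE)]
      .auc_rank(c(s1, s0), c(rep(TRUE, length(s1)), rep(FALSE, length(s0))))
    }, numeric(1))
    ci <- unname(stats::quantile(bt, c(0.025, 0.975)))
  }
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, auc_ci = ci, optimal_cutoff = thr[opt],
                 optimal_sensitivity = sens[opt],
                 optimal_specificity = spec[opt]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), optimal cutoff %.3f (sens %.2f, spec %.2f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$optimal_cutoff,
              x$optimal_sensitivity, x$optimal_specificity))
  invisible(x)
}

#' Univariate AUC ranking of features
#'
#' For every feature column: the rank-based AUC for case vs control,
#' orientation-corrected to >= 0.5, with a two-sided Mann-Whitney p-value
#' (normal approximation with tie correction). Constant features are
#' recorded as AUC 0.5, p 1. Rows are sorted by decreasing AUC.
#'
#' @param table a [feature_table] (or numeric matrix with column names)
#' @param labels "case"/"control" per row (defaults to the table's
#'   `group` column)
#' @return data frame with columns `feature`, `auc`, `direction`
#'   (+1 if cases score higher), `p_value`
#' @export
rank_features_by_auc <- function(table, labels = NULL) {
  x <- if (inherits(table, "feature_table")) feature_matrix(table) else as.matrix(table)
  if (is.null(labels)) labels <- table$group
  y <- .as_label(labels)
  is_case <- y == "case"
  res <- lapply(colnames(x), function(f) {
    v <- x[, f]
    if (length(unique(v)) == 1L)
      return(data.frame(feature = f, auc = 0.5, direction = 0, p_value = 1))
    a <- .auc_rank(v, is_case)
    p <- tryCatch(
      stats::wilcox.test(v[is_case], v[!is_case], exact = FALSE,
                         correct = FALSE)$p.value,
      error = function(e) NA_real_)
    data.frame(feature = f, auc = max(a, 1 - a),
               direction = sign(a - 0.5), p_value = p)
  })
  out <- do.call(rbind, res)
  out[order(-out$auc, out$feature), , drop = FALSE]
}

#' Evaluate a progression model under paired leave-two-out CV
#'
#' Full evaluation loop: for every (case, control) fold, feature
#' standardization, sequential forward selection and SVM fitting are done
#' on that fold's training rows only, and the held-out pair is scored.
#' Subject-level predictions aggregate multiple rows (static scheme) and
#' multiple fold appearances by majority vote, with mean decision scores
#' breaking ties and feeding the ROC.
#'
#' @param table a [feature_table] with `subject_id` and `group` columns
#' @param max_features SFS cap per fold
#' @param cost SVM cost
#' @param inner_k SFS inner CV folds
#' @param n_boot,seed bootstrap settings for the AUC CI
#' @param select_features logical; FALSE skips SFS and uses all features
#' @return object of class `model_report`: selected features per fold (and
#'   their frequency), per-fold and per-subject predictions, confusion
#'   counts, metrics, [roc_analysis] result and the univariate feature
#'   ranking
#' @export
evaluate_progression_model <- function(table, max_features = 10L, cost = 1,
                                       inner_k = 5L, n_boot = 2000L,
                                       seed = 1L, select_features = TRUE) {
  df <- as.data.frame(table)
  x <- feature_matrix(table)
  subj <- unique(df$subject_id)
  subj_label <- vapply(subj, function(s)
    df$group[df$subject_id == s][1L], character(1))
  folds <- leave_two_out_folds(subj_label)
  fold_rows <- lapply(subj, function(s) which(df$subject_id == s))
  names(fold_rows) <- subj
  per_fold <- vector("list", length(folds))
  sel_all <- list()
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    tr_rows <- unlist(fold_rows[subj[f$train_ids]], use.names = FALSE)
    sel <- colnames(x)
    if (select_features) {
      sel <- sequential_forward_selection(x[tr_rows, , drop = FALSE],
                                          df$group[tr_rows],
                                          max_features, inner_k, cost)
      if (!length(sel)) sel <- NULL
    }
    test_subjects <- subj[f$test_pair]
    preds <- lapply(test_subjects, function(s) {
      rows <- fold_rows[[s]]
      if (is.null(sel)) {
        # empty selection: fall back to the majority training class
        n_case_tr <- sum(df$group[tr_rows] == "case")
        maj <- if (n_case_tr * 2L > length(tr_rows)) "case" else "control"
        list(pred = maj, score = 0)
      } else {
        res <- fit_predict_svm(x[tr_rows, sel, drop = FALSE],
                               df$group[tr_rows],
                               x[rows, sel, drop = FALSE], cost)
        v_case <- sum(res$pred == "case")
        ms <- mean(res$score)
        list(pred = if (v_case * 2L > length(res$pred)) "case"
             else if (v_case * 2L < length(res$pred)) "control"
             else if (ms >= 0) "case" else "control",
             score = ms)
      }
    })
    sel_all[[fi]] <- sel %||% character(0)
    per_fold[[fi]] <- data.frame(
      fold = fi,
      subject_id = test_subjects,
      truth = subj_label[match(test_subjects, subj)],
      pred = vapply(preds, `[[`, "", "pred"),
      score = vapply(preds, `[[`, 0, "score"),
      stringsAsFactors = FALSE)
  }
  fold_df <- do.call(rbind, per_fold)
  # subject-level aggregation across fold appearances: majority vote,
  # mean score breaking ties
  agg <- lapply(subj, function(s) {
    rows <- fold_df[fold_df$subject_id == s, ]
    n_case <- sum(rows$pred == "case")
    ms <- mean(rows$score)
    pred <- if (n_case * 2L > nrow(rows)) "case"
    else if (n_case * 2L < nrow(rows)) "control"
    else if (ms >= 0) "case" else "control"
    data.frame(subject_id = s, truth = rows$truth[1L], pred = pred,
               score = ms, stringsAsFactors = FALSE)
  })
  subj_df <- do.call(rbind, agg)
  counts <- confusion_counts(subj_df$pred, subj_df$truth)
  metrics <- compute_metrics(counts)
  roc <- roc_analysis(subj_df$score, subj_df$truth, n_boot = n_boot,
                      seed = seed)
  sel_freq <- sort(base::table(unlist(sel_all)), decreasing = TRUE)
  structure(list(
    scheme = attr(table, "scheme") %||% "static",
    n_folds = length(folds),
    selected_features = sel_freq,
    fold_predictions = fold_df,
    subject_predictions = subj_df,
    confusion = counts,
    accuracy = metrics$accuracy,
    sensitivity = metrics$sensitivity,
    specificity = metrics$specificity,
    undefined_metrics = metrics$undefined,
    roc = roc,
    feature_ranking = rank_features_by_auc(table),
    notes = paste("specificity uses the standard TN/(TN+FP) form;",
                  "subject-level aggregation is majority vote over fold",
                  "appearances with mean-score tie-break")),
    class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("Progression model report (%s scheme)\n", x$scheme))
  cat(sprintf("  %d leave-two-out folds; confusion TP=%d TN=%d FP=%d FN=%d\n",
              x$n_folds, x$confusion["TP"], x$confusion["TN"],
              x$confusion["FP"], x$confusion["FN"]))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  print(x$roc)
  top <- utils::head(x$feature_ranking, 3L)
  cat("  top features by univariate AUC:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %s (AUC %.2f, p %.2g)\n",
                top$feature[i], top$auc[i], top$p_value[i]))
  invisible(x)
}
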