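#' Edge-weight feature vector
#'
#' Vectorizes the strict upper triangle of a symmetric network in
#' row-major order: (1,2), (1,3), ..., (1,P), (2,3), ...  For P ROIs
#' this yields P*(P-1)/2 edge features (6670 at P = 116, 19900 at
#' P = 200).
#'
#' @param W symmetric P x P connectivity matrix.
#' @return named numeric vector of length `P*(P-1)/2`; names are
#'   `"<roi_i>~<roi_j>"`.
#' @export
vectorize_upper_triangle <- function(W) {
  W <- check_network(W)
  v <- t(W)[lower.tri(W)]
  labs <- colnames(W)
  idx <- which(lower.tri(W), arr.ind = TRUE)   # (col, row) of the value
  names(v) <- paste0(labs[idx[, 2L]], "~", labs[idx[, 1L]])
  v
}

#' Two-sample t-test feature selection
#'
#' Per-feature pooled-variance two-sample t-test between the two label
#' groups, two-sided.  Features with p below `p_thresh` are selected;
#' if none passes, the single feature with the smallest p-value is
#' selected so the downstream classifier is never empty.  A feature
#' with zero between-group difference and zero within-group variance
#' (e.g. identical across all subjects) gets p = 1 and is excluded.
#'
#' @param features n x f numeric matrix, one row per subject.
#' @param labels vector of +1/-1 (or two-level factor), length n; each
#'   class needs at least 2 members.
#' @param p_thresh selection threshold on the two-sided p-value.
#' @param welch use the Welch (unequal-variance) statistic instead of
#'   the pooled-variance one.
#' @return logical mask of length f with attribute `"p_values"`.
#' @export
ttest_select <- function(features, labels, p_thresh = 0.05,
                         welch = FALSE) {
  features <- as.matrix(features)
  labels <- as_pm1(labels)
  if (length(labels) != nrow(features))
    stopf("labels length must match the number of feature rows")
  g1 <- features[labels > 0, , drop = FALSE]
  g2 <- features[labels < 0, , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 < 2L || n2 < 2L)
    stopf("both classes need at least 2 members (got %d and %d)", n1, n2)
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- colSums(sweep(g1, 2L, m1)^2) / (n1 - 1L)
  v2 <- colSums(sweep(g2, 2L, m2)^2) / (n2 - 1L)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
  } else {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2L
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  p[!is.finite(tstat) & (m1 - m2) == 0] <- 1      # flat feature: exclude
  p[is.infinite(tstat)] <- 0                      # perfect separation
  mask <- p < p_thresh
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) mask[which.min(p)] <- TRUE      # never-empty fallback
  attr(mask, "p_values") <- p
  mask
}

as_pm1 <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 1)))
      stopf("numeric labels must be +1/-1")
    return(as.numeric(labels))
  }
  f <- factor(labels)
  if (nlevels(f) != 2L) stopf("labels must have exactly 2 levels")
  ifelse(f == levels(f)[2L], 1, -1)
}

#' Train a soft-margin linear SVM
#'
#' Minimises `(1/2)||w||^2 + C * sum_i hinge(y_i, w.x_i + b)` by dual
#' coordinate descent (deterministic cyclic order).  The bias is
#' carried as an augmented constant feature, so it is weakly
#' regularised like the weights — the standard large-scale linear-SVM
#' formulation.
#'
#' @param features n x f numeric matrix.
#' @param labels +1/-1 vector (or two-level factor) of length n.
#' @param C positive soft-margin cost; default 1.
#' @param tol stopping tolerance on the maximal projected-gradient
#'   violation.
#' @param max_sweeps cap on coordinate-descent sweeps.
#' @return object of class `linear_svm` with weights `w`, bias `b` and
#'   dual variables `alpha`.
#' @export
train_linear_svm <- function(features, labels, C = 1, tol = 1e-8,
                             max_sweeps = 100000L) {
  features <- as.matrix(features)
  y <- as_pm1(labels)
  if (length(unique(y)) < 2L) stopf("training labels contain a single class")
  if (C <= 0) stopf("C must be positive")
  Xa <- cbind(features, BIAS = 1)
  out <- .svm_dual_cd(Xa, y, C, tol, as.integer(max_sweeps))
  d <- ncol(Xa)
  w <- out[seq_len(d - 1L)]
  names(w) <- colnames(features)
  structure(list(w = w, b = out[d], alpha = out[-seq_len(d)], C = C),
            class = "linear_svm")
}

#' @describeIn train_linear_svm decision values (`type = "decision"`)
#'   or +1/-1 class labels (`type = "class"`, the default) for new
#'   feature rows.
#' @param object fitted `linear_svm`.
#' @param newdata n x f matrix with the training feature columns.
#' @param type `"class"` or `"decision"`.
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- matrix(as.numeric(newdata), ncol = length(object$w))
  dec <- drop(newdata %*% object$w) + object$b
  if (type == "decision") dec else ifelse(dec >= 0, 1, -1)
}

#' Confusion counts to performance metrics
#'
#' `ACC = (TP+TN)/(TP+FP+TN+FN)`, `SEN = TP/(TP+FN)`,
#' `SPE = TN/(TN+FP)`; patients are the positive class.
#'
#' @param TP,TN,FP,FN non-negative integer confusion counts; both
#'   `TP+FN` and `TN+FP` must be positive.
#' @return object of class `eval_result` with the counts and ACC, SEN,
#'   SPE.
#' @export
compute_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("confusion counts must be non-negative integers")
  if (TP + FN == 0) stopf("no positive-class test subjects: SEN undefined")
  if (TN + FP == 0) stopf("no negative-class test subjects: SPE undefined")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 ACC = (TP + TN) / (TP + TN + FP + FN),
                 SEN = TP / (TP + FN),
                 SPE = TN / (TN + FP)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> TP %d  TN %d  FP %d  FN %d | ACC %.4f  SEN %.4f  SPE %.4f\n",
              x$TP, x$TN, x$FP, x$FN, x$ACC, x$SEN, x$SPE))
  invisible(x)
}

## Train selection + SVM on one training set for one grid value.
## Returns the fitted pieces needed to predict a held-out row.
fit_fold <- function(feats, labels, ttest_p, svm_C) {
  mask <- ttest_select(feats, labels, p_thresh = ttest_p)
  model <- train_linear_svm(feats[, mask, drop = FALSE], labels, C = svm_C)
  list(mask = mask, model = model)
}

predict_fold <- function(fit, feat_row) {
  predict(fit$model, feat_row[fit$mask])
}

#' Inner-loop hyperparameter selection
#'
#' For every candidate value in `grid`, runs a leave-one-out loop over
#' the training subjects, re-doing t-test feature selection and SVM
#' training inside each inner fold, and returns the index of the grid
#' value with the highest mean inner accuracy.  Ties go to the earliest
#' grid entry.  Inner folds whose training portion would lose a class
#' (fewer than 2 members per class remain) are skipped.
#'
#' @param features_by_param list (one element per grid value) of
#'   n x f feature matrices for the same n training subjects.
#' @param labels +1/-1 vector of length n.
#' @param ttest_p t-test selection threshold.
#' @param svm_C SVM cost.
#' @return integer index into the grid, with attribute
#'   `"inner_accuracy"` giving the per-value mean accuracies.
#' @export
inner_select_param <- function(features_by_param, labels, ttest_p = 0.05,
                               svm_C = 1) {
  if (length(features_by_param) == 0L) stopf("empty hyperparameter grid")
  y <- as_pm1(labels)
  n <- length(y)
  if (n < 3L) stopf("need at least 3 training subjects for inner LOOCV")
  acc <- vapply(features_by_param, function(feats) {
    feats <- as.matrix(feats)
    hits <- logical(0)
    for (j in seq_len(n)) {
      ytr <- y[-j]
      if (sum(ytr > 0) < 2L || sum(ytr < 0) < 2L) next
      fit <- fit_fold(feats[-j, , drop = FALSE], ytr, ttest_p, svm_C)
      hits <- c(hits, predict_fold(fit, feats[j, ]) == y[j])
    }
    if (length(hits) == 0L)
      stopf("every inner fold lost a class; training set too small")
    mean(hits)
  }, 0)
  best <- which.max(acc)           # which.max takes the first maximum
  attr(best, "inner_accuracy") <- acc
  best
}

#' Nested leave-one-out cross-validation
#'
#' The full evaluation protocol: an outer leave-one-out loop over
#' subjects estimates performance; inside each outer fold an inner
#' leave-one-out loop over the remaining subjects picks the network
#' hyperparameter from `grid`; feature selection (two-sample t-test)
#' and the linear SVM are refit from scratch inside every fold, so the
#' held-out subject never influences selection or training.
#'
#' @param cohort list of subjects, each a list with `id`, `base` (the
#'   per-subject input consumed by `recipe`: a time-series matrix, a
#'   network, or an initial high-order network) and `label`.
#' @param grid list (or vector) of hyperparameter values, in search
#'   order; ties in inner accuracy go to the earliest entry.
#' @param recipe `function(base, param)` returning the subject's
#'   symmetric connectivity matrix for one hyperparameter value;
#'   evaluated once per subject per grid value.
#' @param ttest_p t-test selection threshold (default 0.05).
#' @param svm_C SVM cost (default 1).
#' @return `eval_result` with extra components: `folds` (data frame of
#'   per-fold id, label, prediction, chosen parameter index) and
#'   `fold_fits` (per-fold selection mask and SVM, for audit).
#' @export
nested_loocv <- function(cohort, grid, recipe, ttest_p = 0.05, svm_C = 1) {
  if (length(cohort) < 4L) stopf("need at least 4 subjects")
  if (length(grid) == 0L) stopf("empty hyperparameter grid")
  grid <- as.list(grid)
  y <- as_pm1(vapply(cohort, function(s) as.character(s$label), ""))
  ids <- vapply(cohort, function(s) as.character(s$id), "")
  n <- length(cohort)

  ## Per-subject networks depend only on (base, param): compute once.
  feats_by_param <- lapply(grid, function(param) {
    do.call(rbind, lapply(cohort, function(s)
      vectorize_upper_triangle(recipe(s$base, param))))
  })

  pred <- numeric(n)
  chosen <- integer(n)
  fold_fits <- vector("list", n)
  for (t in seq_len(n)) {
    train_feats <- lapply(feats_by_param,
                          function(F) F[-t, , drop = FALSE])
    g <- tryCatch(
      inner_select_param(train_feats, y[-t], ttest_p = ttest_p,
                         svm_C = svm_C),
      error = function(e) stopf("outer fold %d (subject '%s'): %s",
                                t, ids[t], conditionMessage(e)))
    fit <- fit_fold(train_feats[[g]], y[-t], ttest_p, svm_C)
    pred[t] <- predict_fold(fit, feats_by_param[[g]][t, ])
    chosen[t] <- g
    fold_fits[[t]] <- list(param_index = g, mask = fit$mask,
                           model = fit$model)
  }

  res <- compute_metrics(TP = sum(pred > 0 & y > 0),
                         TN = sum(pred < 0 & y < 0),
                         FP = sum(pred > 0 & y < 0),
                         FN = sum(pred < 0 & y > 0))
  res$folds <- data.frame(id = ids, label = y, prediction = pred,
                          param_index = chosen,
                          stringsAsFactors = FALSE)
  res$fold_fits <- fold_fits
  res
}
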