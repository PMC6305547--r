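ESTIMATORS <- c("pc", "sr", "hofcn_mle", "s_hofcn", "m_hofcn")

#' Default hyperparameter grid of an estimator
#'
#' `pc` and `hofcn_mle` carry no model parameter, so their grid is the
#' 11 sparsity levels (keep fractions 1%, 10%, ..., 90%, 100%) used to
#' threshold the estimated network.  `sr` and `s_hofcn` use the
#' regularizer grid 2^-5, 2^-4, ..., 2^5; `m_hofcn` the full cross
#' product of that range for (mu1, mu2).
#'
#' @param method one of `"pc"`, `"sr"`, `"hofcn_mle"`, `"s_hofcn"`,
#'   `"m_hofcn"`.
#' @return list of parameter values in search order.
#' @export
default_grid <- function(method) {
  method <- match.arg(method, ESTIMATORS)
  switch(method,
    pc = ,
    hofcn_mle = as.list(c(0.01, seq(0.1, 1, by = 0.1))),
    sr = ,
    s_hofcn = as.list(2^(-5:5)),
    m_hofcn = {
      vals <- 2^(-5:5)
      out <- list()
      for (m1 in vals) for (m2 in vals)
        out[[length(out) + 1L]] <- c(mu1 = m1, mu2 = m2)
      out
    })
}

#' Per-subject base object for classification
#'
#' The part of the estimation pipeline that does not depend on the
#' tuned hyperparameter, computed once per subject: the full Pearson
#' network for `pc`, the raw time series for `sr`, and the initial
#' high-order network (windowed Pearson networks + matrix-normal MLE)
#' for the three high-order methods.
#'
#' @param X subject time-series matrix.
#' @param method estimator name.
#' @param window a [window_spec()]; required for high-order methods.
#' @return the base object consumed by [estimator_recipe()].
#' @export
subject_base <- function(X, method, window = NULL) {
  method <- match.arg(method, ESTIMATORS)
  X <- check_timeseries(X)
  switch(method,
    pc = pearson_fcn(X),
    sr = X,
    {
      if (is.null(window))
        stopf("method '%s' needs a window_spec", method)
      estimate_hofcn_mle(windowed_fcns(X, window))$omega
    })
}

#' Hyperparameter-dependent half of an estimator
#'
#' Returns the `function(base, param)` that [nested_loocv()] evaluates:
#' thresholding at a keep fraction for `pc`/`hofcn_mle`, the sparse-
#' representation solve at `lambda` for `sr`, and the proximal
#' refinement at `mu` / `(mu1, mu2)` for `s_hofcn` / `m_hofcn`.
#'
#' @param method estimator name.
#' @param prox a [prox_config()] carrying step size and solver
#'   controls for the refinement methods (penalties come from `param`).
#' @return a two-argument function.
#' @export
estimator_recipe <- function(method, prox = prox_config()) {
  method <- match.arg(method, ESTIMATORS)
  switch(method,
    pc = ,
    hofcn_mle = function(base, param) threshold_sparsify(base, param),
    sr = function(base, param) sparse_representation_fcn(base, param),
    s_hofcn = function(base, param)
      refine_s_hofcn(base, mu = param, cfg = prox),
    m_hofcn = function(base, param) {
      cfg <- prox_config(mu1 = param[[1L]], mu2 = param[[2L]],
                         alpha = prox$alpha, tol = prox$tol,
                         max_iter = prox$max_iter,
                         ista_scaling = prox$ista_scaling)
      refine_m_hofcn(base, cfg)
    })
}

#' One-shot network estimation for fixed parameters
#'
#' Runs the full estimator at a single parameter setting (no tuning):
#' the composition of [subject_base()] and [estimator_recipe()].
#'
#' @param X subject time-series matrix.
#' @param method estimator name.
#' @param param parameter value (`NULL` picks the identity threshold 1
#'   for `pc`/`hofcn_mle`; required for the others).
#' @param window a [window_spec()] for the high-order methods.
#' @param prox a [prox_config()] for the refinement methods.
#' @return symmetric P x P connectivity matrix.
#' @export
estimate_network <- function(X, method, param = NULL, window = NULL,
                             prox = prox_config()) {
  method <- match.arg(method, ESTIMATORS)
  if (is.null(param)) {
    if (method %in% c("pc", "hofcn_mle")) param <- 1
    else stopf("method '%s' requires a parameter value", method)
  }
  base <- subject_base(X, method, window = window)
  estimator_recipe(method, prox = prox)(base, param)
}

#' Classify a cohort with nested LOOCV
#'
#' End-to-end evaluation of one estimator on a cohort of time-series
#' matrices: per-subject bases are computed once, then [nested_loocv()]
#' tunes the estimator's hyperparameter in the inner loop and
#' aggregates outer-fold predictions.  Window parameters are *not*
#' tuned — they are fixed per call and swept externally.
#'
#' @param subjects list of subjects, each with `id`, `X` (time-series
#'   matrix) and `label` (positive class = `"patient"` unless
#'   `positive_label` says otherwise).
#' @param method estimator name.
#' @param window a [window_spec()] for high-order methods.
#' @param grid hyperparameter grid; `NULL` uses [default_grid()].
#' @param positive_label label string treated as the positive
#'   (patient) class.
#' @param ttest_p,svm_C selection threshold and SVM cost.
#' @param prox refinement solver controls.
#' @return `eval_result`, as from [nested_loocv()].
#' @export
classify_cohort <- function(subjects, method, window = NULL, grid = NULL,
                            positive_label = "patient", ttest_p = 0.05,
                            svm_C = 1, prox = prox_config()) {
  method <- match.arg(method, ESTIMATORS)
  if (is.null(grid)) grid <- default_grid(method)
  labels <- vapply(subjects, function(s) as.character(s$label), "")
  if (!any(labels == positive_label) || all(labels == positive_label))
    stopf("cohort must contain the positive label '%s' and at least one other",
          positive_label)
  cohort <- lapply(subjects, function(s)
    list(id = s$id,
         base = subject_base(s$X, method, window = window),
         label = if (s$label == positive_label) 1 else -1))
  nested_loocv(cohort, grid, estimator_recipe(method, prox = prox),
               ttest_p = ttest_p, svm_C = svm_C)
}
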