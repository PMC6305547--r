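#' Entrywise soft-thresholding
#'
#' The proximal operator of the l1 norm:
#' `sgn(x) * max(|x| - mu1, 0)` applied to every entry.
#'
#' @param omega numeric matrix.
#' @param mu1 non-negative threshold.
#' @return matrix of the same shape.
#' @export
soft_threshold <- function(omega, mu1) {
  if (length(mu1) != 1L || !is.finite(mu1) || mu1 < 0)
    stopf("mu1 must be a single non-negative number")
  sign(omega) * pmax(abs(omega) - mu1, 0)
}

#' Singular-value thresholding
#'
#' The proximal operator of the trace (nuclear) norm: shrinks every
#' singular value by `mu2` (to a floor of zero) and reconstructs
#' `U diag(max(sigma - mu2, 0)) t(V)`.  A symmetric input yields a
#' symmetric output.
#'
#' @param omega numeric matrix.
#' @param mu2 non-negative shrinkage.
#' @return matrix of the same shape, typically of reduced rank.
#' @export
singular_value_threshold <- function(omega, mu2) {
  if (length(mu2) != 1L || !is.finite(mu2) || mu2 < 0)
    stopf("mu2 must be a single non-negative number")
  if (mu2 == 0) return(omega)
  sv <- svd(omega)
  d <- pmax(sv$d - mu2, 0)
  out <- sv$u %*% (d * t(sv$v))
  dimnames(out) <- dimnames(omega)
  out
}

#' Proximal-refinement configuration
#'
#' Bundles the penalties and solver controls of the refinement step.
#' `mu1` weighs the l1 (sparsity) penalty, `mu2` the trace-norm
#' (modularity/low-rank) penalty, and `alpha` is the constant gradient
#' step size.  At the default `alpha = 1/2` (the reciprocal of the
#' Lipschitz constant of the gradient of `||omega - omega0||_F^2`) the
#' iteration collapses in one pass to the sequential proximal maps.
#' With `ista_scaling = TRUE` the thresholds are multiplied by `alpha`
#' (the textbook ISTA step); the default applies them unscaled, as the
#' refinement algorithm is usually stated.
#'
#' @param mu1 non-negative l1 penalty.
#' @param mu2 non-negative trace-norm penalty.
#' @param alpha step size in (0, 1).
#' @param tol relative Frobenius-change stopping tolerance.
#' @param max_iter iteration cap.
#' @param ista_scaling logical; scale thresholds by `alpha`?
#' @return object of class `prox_config`.
#' @export
prox_config <- function(mu1 = 0, mu2 = 0, alpha = 0.5, tol = 1e-6,
                        max_iter = 1000L, ista_scaling = FALSE) {
  if (mu1 < 0 || mu2 < 0) stopf("penalties must be non-negative")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  structure(list(mu1 = mu1, mu2 = mu2, alpha = alpha, tol = tol,
                 max_iter = as.integer(max_iter),
                 ista_scaling = isTRUE(ista_scaling)),
            class = "prox_config")
}

## Shared proximal-gradient loop: gradient step toward omega0, then
## soft-threshold, then (if mu2 > 0) singular-value threshold.
## Convergence is measured on the post-SVT iterate.
prox_iterate <- function(omega0, mu1, mu2, alpha, tol, max_iter,
                         ista_scaling) {
  t1 <- if (ista_scaling) alpha * mu1 else mu1
  t2 <- if (ista_scaling) alpha * mu2 else mu2
  omega <- omega0
  for (it in seq_len(max_iter)) {
    cand <- omega - alpha * 2 * (omega - omega0)
    cand <- soft_threshold(cand, t1)
    if (t2 > 0) cand <- singular_value_threshold(cand, t2)
    cand <- symmetrize(cand)        # absorb SVT float drift
    rel <- frob(cand - omega) / max(frob(omega), .Machine$double.eps)
    omega <- cand
    if (rel < tol) break
  }
  dimnames(omega) <- dimnames(omega0)
  omega
}

#' Sparsity-refined high-order network (S-HoFCN)
#'
#' Finds a sparse neighbourhood network of the initial high-order
#' estimate `omega0` by proximal-gradient minimisation of
#' `||omega - omega0||_F^2 + mu * ||omega||_1`.
#' At the default step size `alpha = 1/2` the result is exactly
#' `soft_threshold(omega0, mu)` (thresholds unscaled; with
#' `ista_scaling` the threshold becomes `alpha * mu`, the exact proximal
#' map of the stated objective).
#'
#' @param omega0 symmetric P x P initial high-order network.
#' @param mu non-negative sparsity penalty.
#' @param cfg a [prox_config()]; its `mu1`/`mu2` are overridden by
#'   `mu` and 0.
#' @return symmetric P x P refined network.
#' @export
refine_s_hofcn <- function(omega0, mu, cfg = prox_config()) {
  omega0 <- check_network(omega0, what = "omega0")
  if (mu < 0) stopf("mu must be non-negative")
  prox_iterate(omega0, mu1 = mu, mu2 = 0, alpha = cfg$alpha,
               tol = cfg$tol, max_iter = cfg$max_iter,
               ista_scaling = cfg$ista_scaling)
}

#' Modularity-refined high-order network (M-HoFCN)
#'
#' Finds a sparse, low-rank (modular) neighbourhood network of `omega0`
#' by proximal-gradient minimisation of
#' `||omega - omega0||_F^2 + mu1 * ||omega||_1 + mu2 * ||omega||_*`,
#' iterating gradient step, soft-threshold and singular-value threshold
#' in sequence.  With `mu2 = 0` this reduces exactly to
#' [refine_s_hofcn()]; at `alpha = 1/2` the result is
#' `singular_value_threshold(soft_threshold(omega0, mu1), mu2)`.
#'
#' @param omega0 symmetric P x P initial high-order network.
#' @param cfg a [prox_config()] carrying `mu1`, `mu2` and solver
#'   controls.
#' @return symmetric P x P refined network.
#' @export
refine_m_hofcn <- function(omega0, cfg) {
  omega0 <- check_network(omega0, what = "omega0")
  stopifnot(inherits(cfg, "prox_config"))
  prox_iterate(omega0, mu1 = cfg$mu1, mu2 = cfg$mu2, alpha = cfg$alpha,
               tol = cfg$tol, max_iter = cfg$max_iter,
               ista_scaling = cfg$ista_scaling)
}
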