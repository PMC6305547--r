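#' Mean of a network sequence
#'
#' Entrywise mean `M = (1/K) * sum_k W_k` of the windowed low-order
#' networks, the centring matrix of the matrix-normal model.
#'
#' @param Ws non-empty list of equally-sized square matrices.
#' @return matrix of the common shape.
#' @export
mean_network <- function(Ws) {
  if (!is.list(Ws) || length(Ws) == 0L)
    stopf("Ws must be a non-empty list of matrices")
  dims <- vapply(Ws, function(w) dim(w), integer(2))
  if (any(dims != dims[, 1L]))
    stopf("all networks must share the same shape")
  Reduce(`+`, Ws) / length(Ws)
}

## Invert omega with trace-scaled jitter, escalating x10 from eps0 to
## eps_max before giving up.  Rank-deficient scatter is expected when the
## number of windows K is small relative to P.
solve_jittered <- function(omega, eps0 = 1e-10, eps_max = 1e-6) {
  p <- ncol(omega)
  scale <- sum(diag(omega)) / p
  if (!is.finite(scale) || scale <= 0) scale <- 1
  eps <- eps0
  repeat {
    inv <- tryCatch(solve(omega + eps * scale * diag(p)),
                    error = function(e) NULL)
    if (!is.null(inv) && all(is.finite(inv))) return(inv)
    eps <- eps * 10
    if (eps > eps_max)
      stopf("omega is numerically singular even after jitter up to %g",
            eps_max)
  }
}

#' One fixed-point update of the high-order network
#'
#' The matrix-normal maximum-likelihood update
#' `(1/(K*P)) * sum_k (W_k - M) omega^{-1} t(W_k - M)`,
#' symmetrized as `(A + t(A))/2`.
#'
#' @param Ws list of K square matrices (windowed low-order networks).
#' @param M their mean, from [mean_network()].
#' @param omega current P x P estimate; must be invertible after jitter.
#' @return the updated symmetric P x P matrix.
#' @export
mle_step <- function(Ws, M, omega) {
  K <- length(Ws)
  p <- ncol(omega)
  inv <- solve_jittered(omega)
  acc <- matrix(0, p, p)
  for (k in seq_len(K)) {
    D <- Ws[[k]] - M
    acc <- acc + D %*% inv %*% t(D)
  }
  symmetrize(acc / (K * p))
}

#' Estimate the high-order network by matrix-normal MLE
#'
#' Runs the damped fixed-point iteration
#' `omega <- (1 - damping) * omega + damping * mle_step(omega)` from the
#' identity matrix until the relative Frobenius change falls below `tol`
#' or `max_iter` is reached.  The undamped iteration can oscillate with
#' period 2; damping preserves its fixed points while restoring
#' convergence.
#'
#' @param Ws list of K >= 2 square matrices (windowed low-order
#'   networks from [windowed_fcns()], or raw matrix-variate normal
#'   samples; symmetry is not required — the update symmetrizes).
#' @param damping relaxation factor in (0, 1\]; default 0.5.
#' @param tol relative Frobenius-change stopping tolerance.
#' @param max_iter iteration cap; hitting it records a warning in the
#'   result rather than failing.
#' @return object of class `hofcn_estimate`: list with `omega` (the
#'   symmetric PSD high-order network), `mean_network`, `n_windows`,
#'   `iterations_run`, `final_residual` (relative Frobenius residual of
#'   the fixed-point equation) and `converged`.
#' @export
estimate_hofcn_mle <- function(Ws, damping = 0.5, tol = 1e-6,
                               max_iter = 500L) {
  if (!is.list(Ws) || length(Ws) < 2L)
    stopf("need at least 2 windowed networks")
  if (damping <= 0 || damping > 1) stopf("damping must lie in (0, 1]")
  for (W in Ws) {
    if (!is.matrix(W) || nrow(W) != ncol(W) || !all(is.finite(W)))
      stopf("every element of Ws must be a finite square matrix")
  }
  M <- mean_network(Ws)
  scatter_norm <- sqrt(sum(vapply(Ws, function(w) sum((w - M)^2), 0)))
  if (scatter_norm < 1e-12 * max(1, sqrt(sum(M^2))))
    stopf("degenerate input: all windowed networks are identical")

  p <- ncol(M)
  omega <- diag(p)
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    omega_new <- (1 - damping) * omega + damping * mle_step(Ws, M, omega)
    rel <- frob(omega_new - omega) / max(frob(omega), .Machine$double.eps)
    omega <- omega_new
    iters <- it
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MLE fixed point did not converge in %d iterations",
                    max_iter), call. = FALSE)
  residual <- frob(omega - mle_step(Ws, M, omega)) /
    max(frob(omega), .Machine$double.eps)
  dimnames(omega) <- dimnames(M)
  structure(list(omega = omega, mean_network = M,
                 n_windows = length(Ws), iterations_run = iters,
                 final_residual = residual, converged = converged),
            class = "hofcn_estimate")
}

frob <- function(A) sqrt(sum(A^2))

#' @export
print.hofcn_estimate <- function(x, ...) {
  cat(sprintf(
    "<hofcn_estimate> P = %d, K = %d windows, %d iterations, residual %.3g%s\n",
    ncol(x$omega), x$n_windows, x$iterations_run, x$final_residual,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
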