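#' Centre and scale ROI time series
#'
#' Subtracts the column mean and rescales each column to unit Euclidean
#' norm, so that the cross-product `t(X) %*% X` of the result is exactly
#' the Pearson correlation matrix of the input.
#'
#' @param X numeric V x P matrix (rows = volumes, columns = ROIs).
#' @return matrix of the same shape; every column has mean 0 and
#'   Euclidean norm 1.
#' @seealso [pearson_fcn()]
#' @export
standardize_columns <- function(X) {
  X <- check_timeseries(X)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  nrm <- sqrt(colSums(Xc^2))
  if (any(nrm == 0)) {
    roi <- colnames(X)[which(nrm == 0)[1L]]
    stopf("degenerate signal: ROI '%s' is constant", roi)
  }
  sweep(Xc, 2L, nrm, "/")
}

#' Pearson-correlation functional connectivity network
#'
#' The full-correlation network: entry (i, j) is the Pearson correlation
#' between the i-th and j-th ROI time series.  Computed as `t(Xs) %*% Xs`
#' on the standardized matrix, which is the unconstrained minimiser of
#' `||W - t(X) X||_F^2`.
#'
#' @param X numeric V x P time-series matrix; no column may be constant.
#' @return symmetric P x P matrix with unit diagonal, entries in \[-1, 1\].
#' @examples
#' X <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
#' pearson_fcn(X)["a", "b"]  # 0.8
#' @export
pearson_fcn <- function(X) {
  Xs <- standardize_columns(X)
  W <- crossprod(Xs)
  W <- symmetrize(W)          # absorb float drift
  W[W > 1] <- 1
  W[W < -1] <- -1
  diag(W) <- 1
  W
}

## Cyclic coordinate-descent lasso for one target column.
## Minimises ||y - Z w||^2 + lambda * sum |w|  (note: no 1/2 factor),
## with unit-norm columns of Z assumed (so each coordinate step is exact).
lasso_cd <- function(Z, y, lambda, tol = 1e-8, max_sweeps = 1e4) {
  p <- ncol(Z)
  w <- numeric(p)
  r <- y                       # residual y - Z w
  zz <- colSums(Z^2)
  for (sweep in seq_len(max_sweeps)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      wj_old <- w[j]
      rho <- sum(Z[, j] * r) + zz[j] * wj_old
      wj <- sign(rho) * max(abs(rho) - lambda / 2, 0) / zz[j]
      if (wj != wj_old) {
        r <- r - (wj - wj_old) * Z[, j]
        delta_max <- max(delta_max, abs(wj - wj_old))
        w[j] <- wj
      }
    }
    if (delta_max < tol) break
  }
  w
}

#' Sparse-representation functional connectivity network
#'
#' Regularised partial-correlation network.  For each ROI i the other
#' ROIs' standardized series regress onto series i under an l1 penalty:
#' `min_w ||x_i - sum_{j != i} w_j x_j||^2 + lambda * sum |w_j|`,
#' with the self-weight fixed at zero.  The coefficient matrix is then
#' symmetrized.
#'
#' @param X numeric V x P time-series matrix (standardized internally).
#' @param lambda non-negative l1 penalty.
#' @param symmetrization `"average"` (default) replaces W by
#'   `(W + t(W))/2`; `"max"` keeps, for each pair, the entry of larger
#'   magnitude.
#' @param tol coordinate-descent convergence tolerance on the maximum
#'   coefficient change per sweep.
#' @param max_sweeps cap on coordinate-descent sweeps.
#' @return symmetric P x P matrix with zero diagonal.
#' @export
sparse_representation_fcn <- function(X, lambda,
                                      symmetrization = c("average", "max"),
                                      tol = 1e-8, max_sweeps = 1e4) {
  symmetrization <- match.arg(symmetrization)
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stopf("lambda must be a single non-negative number")
  Xs <- standardize_columns(X)
  p <- ncol(Xs)
  W <- matrix(0, p, p, dimnames = list(colnames(Xs), colnames(Xs)))
  for (i in seq_len(p)) {
    Z <- Xs[, -i, drop = FALSE]
    W[-i, i] <- lasso_cd(Z, Xs[, i], lambda, tol = tol,
                         max_sweeps = max_sweeps)
  }
  if (symmetrization == "average") {
    W <- symmetrize(W)
  } else {
    keep <- abs(W) >= abs(t(W))
    W <- ifelse(keep, W, t(W))
    W <- (W + t(W)) / 2          # pairs are now equal; fixes |a| == |b| ties
  }
  diag(W) <- 0
  W
}

#' Sliding-window scheme
#'
#' Describes contiguous windows of `N` volumes advanced by `s` volumes.
#' Trailing volumes that do not fill a complete window are discarded.
#'
#' @param N window width in volumes (>= 2).
#' @param s step size in volumes (>= 1).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(N, s = 1L) {
  N <- as.integer(N); s <- as.integer(s)
  if (is.na(N) || N < 2L) stopf("window width N must be an integer >= 2")
  if (is.na(s) || s < 1L) stopf("window step s must be an integer >= 1")
  structure(list(N = N, s = s), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> width N = %d, step s = %d\n", x$N, x$s))
  invisible(x)
}

#' Enumerate sliding windows
#'
#' Returns the `K = floor((V - N)/s) + 1` row-index ranges of the
#' sliding-window scheme over `V` volumes; window k covers rows
#' `(k-1)*s + 1 ... (k-1)*s + N` (1-based, inclusive).
#'
#' @param V total number of volumes.
#' @param spec a [window_spec()].
#' @return list of `K` integer vectors of length `N`.
#' @examples
#' length(sliding_windows(137, window_spec(70, 1)))  # 68
#' @export
sliding_windows <- function(V, spec) {
  stopifnot(inherits(spec, "window_spec"))
  V <- as.integer(V)
  if (spec$N > V)
    stopf("window width N = %d exceeds the number of volumes V = %d",
          spec$N, V)
  K <- (V - spec$N) %/% spec$s + 1L
  lapply(seq_len(K), function(k) {
    start <- (k - 1L) * spec$s
    seq.int(start + 1L, start + spec$N)
  })
}

#' Windowed low-order network sequence
#'
#' Computes one Pearson-correlation network per sliding window, each on
#' the window's rows alone (per-window standardization).
#'
#' @param X numeric V x P time-series matrix.
#' @param spec a [window_spec()].
#' @return list of `K` symmetric P x P correlation matrices.
#' @export
windowed_fcns <- function(X, spec) {
  X <- check_timeseries(X)
  idx <- sliding_windows(nrow(X), spec)
  lapply(seq_along(idx), function(k) {
    Xw <- X[idx[[k]], , drop = FALSE]
    tryCatch(pearson_fcn(Xw), error = function(e) {
      stopf("window %d: %s", k, conditionMessage(e))
    })
  })
}

#' Magnitude thresholding of a network
#'
#' Keeps the `ceiling(keep_fraction * P*(P-1)/2)` off-diagonal entries of
#' largest absolute value (upper triangle, ties broken by row then column
#' index), zeroes the rest, and mirrors the result below the diagonal.
#' The diagonal is untouched; `keep_fraction = 1` preserves the input.
#'
#' @param W symmetric P x P matrix.
#' @param keep_fraction fraction of edges to retain, in (0, 1\].
#' @return thresholded symmetric matrix.
#' @export
threshold_sparsify <- function(W, keep_fraction) {
  W <- check_network(W)
  if (length(keep_fraction) != 1L || !is.finite(keep_fraction) ||
      keep_fraction <= 0 || keep_fraction > 1)
    stopf("keep_fraction must lie in (0, 1]")
  p <- ncol(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  n_edges <- nrow(ut)
  n_keep <- ceiling(keep_fraction * n_edges)
  if (n_keep >= n_edges) return(W)
  vals <- W[upper.tri(W)]
  ord <- order(-abs(vals), ut[, "row"], ut[, "col"])
  drop <- ord[-seq_len(n_keep)]
  out <- W
  out[ut[drop, , drop = FALSE]] <- 0
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}
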