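#' @useDynLib hofcn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm pt sd var
#' @importFrom utils read.table write.table
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Default ROI labels
#'
#' Zero-padded labels `ROI_001`, `ROI_002`, ... used whenever a file or
#' matrix arrives without region names.
#'
#' @param p number of regions.
#' @return character vector of length `p`.
#' @keywords internal
default_roi_labels <- function(p) {
  sprintf("ROI_%03d", seq_len(p))
}

## Validate a V x P time-series matrix; attach labels if missing.
check_timeseries <- function(X, what = "time series") {
  if (!is.matrix(X) || !is.numeric(X))
    stopf("%s must be a numeric matrix", what)
  if (nrow(X) < 2L || ncol(X) < 2L)
    stopf("%s must have at least 2 rows (volumes) and 2 columns (ROIs)", what)
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stopf("%s contains a non-finite value at row %d, column %d",
          what, bad[1L], bad[2L])
  }
  if (is.null(colnames(X))) colnames(X) <- default_roi_labels(ncol(X))
  X
}

## Validate a square symmetric connectivity matrix.
check_network <- function(W, tol = 1e-10, what = "network") {
  if (!is.matrix(W) || !is.numeric(W))
    stopf("%s must be a numeric matrix", what)
  if (nrow(W) != ncol(W))
    stopf("%s must be square, got %d x %d", what, nrow(W), ncol(W))
  if (!all(is.finite(W)))
    stopf("%s contains non-finite entries", what)
  asym <- max(abs(W - t(W)))
  if (asym > tol) {
    idx <- which(abs(W - t(W)) == asym, arr.ind = TRUE)[1L, ]
    stopf("%s is asymmetric: max |W - t(W)| = %.3g at (%d, %d), tolerance %g",
          what, asym, idx[1L], idx[2L], tol)
  }
  if (is.null(rownames(W))) {
    labs <- colnames(W)
    if (is.null(labs)) labs <- default_roi_labels(ncol(W))
    dimnames(W) <- list(labs, labs)
  }
  W
}

symmetrize <- function(A) (A + t(A)) / 2

#' Drop initial volumes from a time-series matrix
#'
#' Removes the first `n_drop` rows (volumes), the usual signal-stabilisation
#' step for fMRI acquisitions where the first few volumes are discarded
#' before analysis.
#'
#' @param X numeric V x P time-series matrix.
#' @param n_drop number of leading volumes to remove.
#' @return the matrix with `V - n_drop` rows.
#' @examples
#' X <- matrix(rnorm(140 * 4), 140, 4)
#' nrow(drop_initial_volumes(X, 3))  # 137
#' @export
drop_initial_volumes <- function(X, n_drop) {
  X <- check_timeseries(X)
  n_drop <- as.integer(n_drop)
  if (n_drop < 0L) stopf("n_drop must be non-negative")
  if (nrow(X) - n_drop < 2L)
    stopf("dropping %d of %d volumes leaves fewer than 2", n_drop, nrow(X))
  if (n_drop == 0L) return(X)
  X[-seq_len(n_drop), , drop = FALSE]
}
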