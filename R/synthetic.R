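## All generators draw through with_local_seed(): they are pure
## functions of (spec, seed) and never disturb the caller's RNG state.

with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

#' Modular covariance specification
#'
#' Describes a block-structured ("modular") correlation matrix: ROIs
#' split into `n_modules` contiguous, equal-size groups with
#' correlation `within_corr` inside a group and `between_corr` across
#' groups, scaled by `noise_sd^2`.  This emulates the dense-within /
#' sparse-between structure that the modularity prior targets.
#'
#' @param P number of ROIs.
#' @param n_modules number of modules (P need not divide evenly; group
#'   sizes then differ by one).
#' @param within_corr within-module correlation, in (0, 1).
#' @param between_corr between-module correlation, in
#'   `[0, within_corr)`.
#' @param noise_sd marginal signal standard deviation.
#' @return object of class `modular_cov_spec`.
#' @export
modular_cov_spec <- function(P, n_modules = 2L, within_corr = 0.6,
                             between_corr = 0.1, noise_sd = 1) {
  P <- as.integer(P); n_modules <- as.integer(n_modules)
  if (P < 2L) stopf("P must be >= 2")
  if (n_modules < 1L || n_modules > P) stopf("n_modules must be in [1, P]")
  if (within_corr <= 0 || within_corr >= 1)
    stopf("within_corr must lie in (0, 1)")
  if (between_corr < 0 || between_corr > within_corr)
    stopf("between_corr must lie in [0, within_corr]")
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  spec <- structure(list(P = P, n_modules = n_modules,
                         within_corr = within_corr,
                         between_corr = between_corr,
                         noise_sd = noise_sd),
                    class = "modular_cov_spec")
  ev <- eigen(make_modular_cov(spec), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    stopf("spec implies an indefinite covariance (min eigenvalue %.3g); use smaller correlation contrasts",
          min(ev))
  spec
}

#' Build the modular covariance matrix
#'
#' @param spec a [modular_cov_spec()].
#' @return P x P positive-definite covariance matrix.
#' @export
make_modular_cov <- function(spec) {
  stopifnot(inherits(spec, "modular_cov_spec"))
  blocks <- module_assignment(spec$P, spec$n_modules)
  R <- matrix(spec$between_corr, spec$P, spec$P)
  same <- outer(blocks, blocks, `==`)
  R[same] <- spec$within_corr
  diag(R) <- 1
  cov <- spec$noise_sd^2 * R
  dimnames(cov) <- list(default_roi_labels(spec$P),
                        default_roi_labels(spec$P))
  cov
}

module_assignment <- function(P, n_modules) {
  rep(seq_len(n_modules), each = ceiling(P / n_modules))[seq_len(P)]
}

#' Sample a synthetic BOLD time-series matrix
#'
#' Draws `V` rows from a multivariate normal with the given covariance;
#' with `ar1 > 0`, each latent component additionally follows an AR(1)
#' process (variance-normalised), giving temporally smooth series for
#' sliding-window demonstrations.  Deterministic per seed.
#'
#' @param cov P x P positive-definite covariance.
#' @param V number of volumes (>= 2).
#' @param seed integer RNG seed.
#' @param ar1 AR(1) coefficient in `[0, 1)`; 0 (default) gives i.i.d.
#'   volumes.
#' @return V x P time-series matrix.
#' @export
sample_bold <- function(cov, V, seed, ar1 = 0) {
  V <- as.integer(V)
  if (V < 2L) stopf("V must be >= 2")
  if (ar1 < 0 || ar1 >= 1) stopf("ar1 must lie in [0, 1)")
  L <- tryCatch(chol(cov), error = function(e)
    stopf("covariance is not positive definite"))
  p <- ncol(cov)
  with_local_seed(seed, {
    Z <- matrix(rnorm(V * p), V, p)
    if (ar1 > 0) {
      Z <- apply(Z, 2L, function(z) {
        as.numeric(stats::filter(z * sqrt(1 - ar1^2), ar1,
                                 method = "recursive",
                                 init = z[1L]))
      })
    }
    X <- Z %*% L
    colnames(X) <- colnames(cov)
    X
  })
}

#' Sample matrix-variate normal connectivity matrices
#'
#' Draws `K` matrices `W_k = M + A %*% Z_k %*% t(A)` with
#' `A %*% t(A) = Sigma` and `Z_k` i.i.d. standard normal, i.e. the
#' matrix-variate normal with mean `M` and `Sigma` as both row and
#' column covariance — the sampling model under which the high-order
#' MLE fixed point recovers `Sigma`.  Draws are square but not
#' symmetric.
#'
#' @param M P x P mean matrix.
#' @param Sigma P x P positive-definite shared row/column covariance.
#' @param K number of draws (0 gives an empty list).
#' @param seed integer RNG seed.
#' @return list of K matrices.
#' @export
sample_matrix_normal <- function(M, Sigma, K, seed) {
  K <- as.integer(K)
  if (K < 0L) stopf("K must be non-negative")
  if (K == 0L) return(list())
  A <- tryCatch(t(chol(Sigma)), error = function(e)
    stopf("Sigma is not positive definite"))
  p <- ncol(Sigma)
  with_local_seed(seed, {
    lapply(seq_len(K), function(k) {
      Z <- matrix(rnorm(p * p), p, p)
      M + A %*% Z %*% t(A)
    })
  })
}

#' Two-class cohort specification
#'
#' Describes a synthetic case/control cohort: controls draw BOLD series
#' from the base modular covariance; patients draw from the same
#' covariance with `effect_size` added to the latent correlation of
#' each affected edge (the perturbed matrix is projected back to
#' positive definite by eigenvalue clipping at 1e-6).
#'
#' @param n_pos,n_neg patient / control group sizes.
#' @param V volumes per subject.
#' @param base a [modular_cov_spec()].
#' @param affected_edges 2-column matrix (or list of pairs) of edge
#'   indices `i < j` receiving the group effect.
#' @param effect_size correlation shift added for the patient group.
#' @param seed integer master seed; subject k draws with `seed + k`.
#' @param ar1 AR(1) coefficient passed to [sample_bold()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pos, n_neg, V, base, affected_edges,
                        effect_size, seed, ar1 = 0) {
  stopifnot(inherits(base, "modular_cov_spec"))
  edges <- as_edge_matrix(affected_edges, base$P)
  spec <- structure(list(n_pos = as.integer(n_pos),
                         n_neg = as.integer(n_neg),
                         V = as.integer(V), base = base,
                         affected_edges = edges,
                         effect_size = effect_size,
                         seed = as.integer(seed), ar1 = ar1),
                    class = "cohort_spec")
  if (spec$n_pos < 1L || spec$n_neg < 1L)
    stopf("both groups need at least one subject")
  cohort_covariances(spec)     # errors early if the perturbation breaks PD
  spec
}

as_edge_matrix <- function(edges, P) {
  if (is.list(edges)) edges <- do.call(rbind, lapply(edges, as.integer))
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (any(edges[, 1L] >= edges[, 2L]) || any(edges < 1L) ||
      any(edges > P))
    stopf("affected edges must satisfy 1 <= i < j <= P")
  edges
}

## Base and perturbed covariance for the two groups.
cohort_covariances <- function(spec) {
  cov_neg <- make_modular_cov(spec$base)
  R <- cov_neg / spec$base$noise_sd^2
  for (e in seq_len(nrow(spec$affected_edges))) {
    i <- spec$affected_edges[e, 1L]; j <- spec$affected_edges[e, 2L]
    R[i, j] <- R[i, j] + spec$effect_size
    R[j, i] <- R[i, j]
  }
  if (any(abs(R[upper.tri(R)]) > 0.999))
    stopf("effect_size pushes a correlation outside (-1, 1)")
  ## nearest-PD projection by eigenvalue clipping
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < 1e-6) {
    R <- eg$vectors %*% (pmax(eg$values, 1e-6) * t(eg$vectors))
    R <- symmetrize(R)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)       # restore unit diagonal
    dimnames(R) <- dimnames(cov_neg)
  }
  list(negative = cov_neg, positive = spec$base$noise_sd^2 * R)
}

#' Generate a two-class synthetic cohort
#'
#' Draws `n_pos + n_neg` subjects (patients first) with deterministic
#' per-subject sub-seeds `seed + k`, k = 1, ..., n_pos + n_neg.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `cohort`: `subjects` (each with `id`, `X`,
#'   `label`), `spec`, and the two group covariances.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  covs <- cohort_covariances(spec)
  n <- spec$n_pos + spec$n_neg
  subjects <- lapply(seq_len(n), function(k) {
    positive <- k <= spec$n_pos
    list(id = sprintf("sub_%03d", k),
         X = sample_bold(if (positive) covs$positive else covs$negative,
                         spec$V, seed = spec$seed + k, ar1 = spec$ar1),
         label = if (positive) "patient" else "control")
  })
  structure(list(subjects = subjects, spec = spec,
                 covariances = covs), class = "cohort")
}

#' @describeIn make_cohort write every subject's time series plus a
#'   manifest (`manifest.tsv`) under `dir`.
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    fname <- paste0(s$id, ".tsv")
    write_timeseries(s$X, file.path(dir, fname))
    data.frame(subject_id = s$id, path = fname, label = s$label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}
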