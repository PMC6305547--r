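# Fixtures are generated in code; seeds are fixed so runs are
# reproducible everywhere.

# Random symmetric matrix with a local seed.
rsym <- function(p, seed, scale = 1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(p * p, sd = scale), p, p)
    (A + t(A)) / 2
  })
}

# Random time-series matrix.
rts <- function(v, p, seed) {
  withr::with_seed(seed, matrix(rnorm(v * p), v, p))
}

# The frozen two-class cohort used by the end-to-end criteria: 10
# patients + 10 controls, 16 ROIs in two modules, 5 between-module
# edges shifted by +0.5 correlation in the patient group.  Calibrated
# once against the generator, then frozen (see the methods vignette).
acceptance_cohort <- function() {
  base <- modular_cov_spec(16, n_modules = 2, within_corr = 0.6,
                           between_corr = 0.1)
  edges <- rbind(c(1, 9), c(2, 10), c(3, 11), c(4, 12), c(5, 13))
  spec <- cohort_spec(n_pos = 10, n_neg = 10, V = 120, base = base,
                      affected_edges = edges, effect_size = 0.5,
                      seed = 11)
  make_cohort(spec)
}

acceptance_window <- function() window_spec(40, 5)

# Line search over the printed regularizer range with mu1 = mu2.
mhofcn_line_grid <- function() lapply(2^(-5:5), function(v)
  c(mu1 = v, mu2 = v))

# Objective of the sparse-representation column problem, for oracle
# checks: ||y - Z w||^2 + lambda * sum(|w|).
sr_objective <- function(Z, y, w, lambda) {
  sum((y - Z %*% w)^2) + lambda * sum(abs(w))
}
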