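test_that("standardize_columns centres and unit-norms every column", {
  X <- matrix(c(1, 2, 3), ncol = 1)
  X <- cbind(X, c(2, 2, 5))  # second column just to satisfy P >= 2
  Xs <- standardize_columns(X)
  expect_equal(Xs[, 1], c(-1, 0, 1) / sqrt(2))

  # idempotence
  expect_equal(standardize_columns(Xs), Xs, tolerance = 1e-12)

  # random matrix: exact mean-0 / norm-1 columns
  Xs2 <- standardize_columns(rts(50, 10, seed = 5))
  expect_lt(max(abs(colMeans(Xs2))), 1e-12)
  expect_lt(max(abs(sqrt(colSums(Xs2^2)) - 1)), 1e-12)

  Xc <- cbind(a = rnorm(10), flat = rep(2, 10))
  expect_error(standardize_columns(Xc), "flat")
})

test_that("pearson_fcn matches hand-computed correlations", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  W <- pearson_fcn(X)
  expect_equal(W["a", "b"], 0.8)
  expect_equal(diag(W), c(a = 1, b = 1))

  X2 <- cbind(x = c(1, 2, 5), same = c(1, 2, 5), anti = -c(1, 2, 5))
  W2 <- pearson_fcn(X2)
  expect_equal(W2["x", "same"], 1)
  expect_equal(W2["x", "anti"], -1)
})

test_that("pearson_fcn is invariant to positive affine maps per column", {
  for (seed in 1:5) {
    X <- rts(40, 6, seed)
    a <- withr::with_seed(seed + 100, runif(6, 0.1, 5))
    b <- withr::with_seed(seed + 200, rnorm(6, sd = 10))
    Y <- sweep(sweep(X, 2, a, "*"), 2, b, "+")
    expect_lt(max(abs(pearson_fcn(Y) - pearson_fcn(X))), 1e-10)
  }
})

test_that("sparse representation: lasso dead zone and 2-ROI closed form", {
  X <- rts(30, 4, seed = 9)
  Xs <- standardize_columns(X)
  lam_max <- 2 * max(abs(crossprod(Xs) - diag(4)))
  W <- sparse_representation_fcn(X, lam_max + 1e-6)
  expect_true(all(W == 0))

  X2 <- rts(25, 2, seed = 10)
  Xs2 <- standardize_columns(X2)
  W2 <- sparse_representation_fcn(X2, 0)
  expect_equal(W2[1, 2], sum(Xs2[, 1] * Xs2[, 2]), tolerance = 1e-8)
  expect_error(sparse_representation_fcn(X2, -1), "non-negative")
})

test_that("sparse representation solution is KKT-certified and matches glmnet", {
  skip_if_not_installed("glmnet")
  X <- rts(30, 5, seed = 13)
  Xs <- standardize_columns(X)
  for (lambda in c(0.05, 0.3, 1)) {
    W <- sparse_representation_fcn(X, lambda)
    for (i in 1:5) {
      Z <- Xs[, -i]; y <- Xs[, i]
      # recover the directed (pre-symmetrization) column via a fresh solve
      w <- hofcn:::lasso_cd(Z, y, lambda)
      # KKT: |2 Z'(y - Zw)| <= lambda (+ tol), with equality at nonzeros
      g <- 2 * crossprod(Z, y - Z %*% w)
      expect_true(all(abs(g) <= lambda + 1e-6))
      nz <- which(w != 0)
      if (length(nz))
        expect_equal(as.numeric(g[nz]), lambda * sign(w[nz]),
                     tolerance = 1e-6)
      # independent oracle: glmnet on the same column problem
      fit <- glmnet::glmnet(Z, y, alpha = 1, intercept = FALSE,
                            standardize = FALSE,
                            lambda = lambda / (2 * length(y)),
                            thresh = 1e-14)
      w_g <- as.numeric(fit$beta)
      expect_lte(sr_objective(Z, y, w, lambda),
                 sr_objective(Z, y, w_g, lambda) + 1e-6)
      expect_lt(max(abs(w - w_g)), 1e-4)
    }
  }
})

test_that("sparse representation support is monotone in lambda", {
  X <- rts(40, 6, seed = 21)
  nnz <- vapply(2^(-5:5), function(lam)
    sum(sparse_representation_fcn(X, lam) != 0), 0)
  expect_true(all(diff(nnz) <= 0))
})

test_that("sliding_windows enumerates half-open windows with remainder dropped", {
  expect_length(sliding_windows(137, window_spec(70, 1)), 68L)
  w1 <- sliding_windows(50, window_spec(50, 7))
  expect_length(w1, 1L)
  expect_equal(w1[[1]], 1:50)
  w2 <- sliding_windows(10, window_spec(4, 3))
  expect_equal(w2, list(1:4, 4:7, 7:10))
  expect_error(sliding_windows(10, window_spec(11, 1)), "exceeds")
})

test_that("windowed_fcns agrees with pearson_fcn per window", {
  X <- rts(60, 5, seed = 30)
  # one full-width window reproduces the global network
  expect_equal(windowed_fcns(X, window_spec(60, 1))[[1]], pearson_fcn(X))

  spec <- window_spec(20, 8)
  Ws <- windowed_fcns(X, spec)
  expect_length(Ws, length(sliding_windows(60, spec)))
  expect_equal(Ws[[2]], pearson_fcn(X[9:28, ]))

  # stationary data: window-mean close to the global estimate
  Xb <- sample_bold(make_modular_cov(modular_cov_spec(6, 2)), 4000, seed = 4)
  M <- mean_network(windowed_fcns(Xb, window_spec(400, 100)))
  expect_lt(max(abs(M - pearson_fcn(Xb))), 0.1)
})

test_that("threshold_sparsify keeps the largest-|.| edges deterministically", {
  W <- rsym(4, seed = 40)
  diag(W) <- 1
  expect_equal(unname(threshold_sparsify(W, 1)), W)

  W5 <- threshold_sparsify(W, 0.5)
  ut <- W5[upper.tri(W5)]
  expect_equal(sum(ut != 0), 3L)
  kept <- sort(abs(ut[ut != 0]))
  expect_equal(kept, sort(abs(W[upper.tri(W)]))[4:6])
  expect_equal(unname(diag(W5)), diag(W))
  expect_equal(W5, t(W5))

  # brute-force count oracle across fractions and sizes
  for (seed in 1:3) {
    W <- rsym(7, seed = 100 + seed)
    vals <- abs(W[upper.tri(W)])
    for (kf in c(0.01, 0.25, 0.5, 0.9)) {
      n_keep <- ceiling(kf * length(vals))
      out <- threshold_sparsify(W, kf)
      expect_equal(sum(out[upper.tri(out)] != 0), n_keep)
      expect_equal(sort(abs(out[upper.tri(out)]), decreasing = TRUE)[1:n_keep],
                   sort(vals, decreasing = TRUE)[1:n_keep])
    }
  }
  expect_error(threshold_sparsify(W, 0), "\\(0, 1\\]")
  expect_error(threshold_sparsify(W, 1.2), "\\(0, 1\\]")
})

test_that("threshold_sparsify nonzero count is non-decreasing in keep_fraction", {
  W <- rsym(10, seed = 55)
  counts <- vapply(c(0.01, seq(0.1, 1, 0.1)), function(kf)
    sum(threshold_sparsify(W, kf) != 0), 0)
  expect_true(all(diff(counts) >= 0))
})
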