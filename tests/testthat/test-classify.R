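test_that("vectorize_upper_triangle is row-major with P(P-1)/2 entries", {
  W <- matrix(c(1, 2, 3,
                2, 1, 4,
                3, 4, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  v <- vectorize_upper_triangle(W)
  expect_equal(unname(v), c(2, 3, 4))          # (1,2), (1,3), (2,3)
  expect_equal(names(v), c("a~b", "a~c", "b~c"))

  W2 <- rsym(2, 1); dimnames(W2) <- NULL
  expect_length(vectorize_upper_triangle(W2), 1L)
  expect_error(vectorize_upper_triangle(matrix(1:4, 2)), "asymmetric")
})

test_that("ttest_select applies the pooled two-sample test with fallback", {
  labels <- rep(c(1, -1), each = 10)
  set.seed(77)
  feats <- cbind(flat = rep(3, 20),
                 strong = c(rnorm(10, 10, 0.1), rnorm(10, -10, 0.1)),
                 noise = rnorm(20))
  mask <- ttest_select(feats, labels, 0.05)
  expect_false(mask[["flat"]])
  expect_true(mask[["strong"]])
  p <- attr(mask, "p_values")
  expect_lt(p[["strong"]], 1e-10)
  expect_identical(p[["flat"]], 1)

  # p-values agree with stats::t.test (var.equal) per feature
  for (j in 2:3)
    expect_equal(p[[j]],
                 t.test(feats[labels > 0, j], feats[labels < 0, j],
                        var.equal = TRUE)$p.value)

  # no feature passes a tiny threshold -> single best-p fallback
  mask2 <- ttest_select(feats[, c("flat", "noise")], labels, 1e-12)
  expect_equal(sum(mask2), 1L)

  expect_error(ttest_select(feats, rep("a", 20)), "2 levels")
  expect_error(ttest_select(feats, rep(1, 20)), "at least 2 members")
  expect_error(ttest_select(feats[1:3, ], labels[c(1, 2, 11)]),
               "at least 2 members")
})

test_that("t-test p-value tracks an exact permutation oracle on a 6-subject toy", {
  y <- c(1, 1, 1, -1, -1, -1)
  x <- c(2.1, 1.4, 2.6, 0.9, 0.3, 1.1)
  p_t <- attr(ttest_select(cbind(x, x2 = rev(x)), y, 0.5), "p_values")[[1]]

  tstat <- function(x, y) {
    a <- x[y > 0]; b <- x[y < 0]
    sp2 <- (var(a) * 2 + var(b) * 2) / 4
    (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  }
  t_obs <- abs(tstat(x, y))
  combos <- combn(6, 3)
  t_perm <- apply(combos, 2, function(idx) {
    yy <- rep(-1, 6); yy[idx] <- 1
    abs(tstat(x, yy))
  })
  p_perm <- mean(t_perm >= t_obs - 1e-12)
  # exact-null granularity at n = 6 is 1/20
  expect_lt(abs(p_t - p_perm), 0.15)
})

test_that("linear SVM separates, is label-symmetric, and duplication-invariant", {
  f <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(-1, -1, 1, 1)
  m <- train_linear_svm(f, y)
  expect_equal(predict(m, f), y)

  m_flip <- train_linear_svm(f, -y)
  expect_equal(predict(m_flip, f, type = "decision"),
               -predict(m, f, type = "decision"), tolerance = 1e-6)

  set.seed(5)
  f2 <- matrix(rnorm(40), 10, 4)
  y2 <- rep(c(1, -1), 5)
  m1 <- train_linear_svm(f2, y2, C = 1)
  m2 <- train_linear_svm(rbind(f2, f2), c(y2, y2), C = 0.5)
  expect_equal(c(m1$w, m1$b), c(m2$w, m2$b), tolerance = 1e-5)

  expect_error(train_linear_svm(f, rep(1, 4)), "single class")
})

test_that("SVM solution satisfies the KKT conditions of the hinge dual", {
  set.seed(8)
  f <- matrix(rnorm(24), 8, 3)
  y <- rep(c(1, -1), 4)
  C <- 1
  m <- train_linear_svm(f, y, C = C, tol = 1e-10)
  Xa <- cbind(f, 1)
  wa <- c(m$w, m$b)
  # stationarity: w = sum alpha_i y_i x_i
  expect_equal(colSums(m$alpha * y * Xa), wa, tolerance = 1e-8,
               ignore_attr = TRUE)
  margin <- y * (Xa %*% wa)
  expect_true(all(m$alpha >= -1e-12 & m$alpha <= C + 1e-12))
  # complementary slackness
  expect_true(all(margin[m$alpha < 1e-8] >= 1 - 1e-6))
  expect_true(all(margin[m$alpha > C - 1e-8] <= 1 + 1e-6))
  interior <- m$alpha > 1e-8 & m$alpha < C - 1e-8
  expect_true(all(abs(margin[interior] - 1) < 1e-6))
})

test_that("compute_metrics implements the confusion identities", {
  r <- compute_metrics(3, 2, 1, 0)
  expect_equal(r$ACC, 5 / 6)
  expect_equal(r$SEN, 1)
  expect_equal(r$SPE, 2 / 3)
  r2 <- compute_metrics(4, 7, 0, 0)
  expect_equal(c(r2$ACC, r2$SEN, r2$SPE), c(1, 1, 1))
  expect_equal(compute_metrics(0, 0, 5, 3)$ACC, 0)
  expect_error(compute_metrics(0, 3, 2, 0), "SEN undefined")
  expect_error(compute_metrics(1, 0, 0, 1), "SPE undefined")
})

test_that("inner_select_param picks the best grid value, first on ties", {
  set.seed(21)
  n <- 12
  y <- rep(c(1, -1), each = 6)
  good <- cbind(c(rnorm(6, 3, 0.3), rnorm(6, -3, 0.3)), rnorm(n))
  junk <- matrix(rnorm(2 * n), n, 2)

  expect_equal(as.integer(inner_select_param(list(good), y)), 1L)

  # identical feature sets tie -> earliest index
  sel <- inner_select_param(list(junk, junk), y)
  expect_equal(as.integer(sel), 1L)

  sel2 <- inner_select_param(list(junk, good, good), y)
  expect_equal(as.integer(sel2), 2L)
  acc <- attr(sel2, "inner_accuracy")
  expect_equal(acc[2], acc[3])
  expect_gt(acc[2], acc[1])

  expect_error(inner_select_param(list(), y), "empty")
})

test_that("inner_select_param matches a brute-force tabulation oracle", {
  set.seed(31)
  n <- 10
  y <- rep(c(1, -1), each = 5)
  feats_list <- lapply(1:3, function(g)
    matrix(rnorm(n * 4), n, 4) +
      outer(y, rep(g == 2, 4)) * 2)   # only grid value 2 separates

  got <- inner_select_param(feats_list, y)

  # independent double loop over grid x folds using the public pieces
  oracle_acc <- vapply(feats_list, function(feats) {
    hits <- logical(0)
    for (j in seq_len(n)) {
      mask <- ttest_select(feats[-j, ], y[-j], 0.05)
      mdl <- train_linear_svm(feats[-j, mask, drop = FALSE], y[-j], C = 1)
      hits <- c(hits, predict(mdl, feats[j, mask]) == y[j])
    }
    mean(hits)
  }, 0)
  expect_equal(as.integer(got), which.max(oracle_acc))
  expect_equal(attr(got, "inner_accuracy"), oracle_acc)
})

test_that("nested_loocv is deterministic and leak-free", {
  set.seed(41)
  p <- 6
  cohort <- lapply(1:10, function(k) {
    shift <- if (k <= 5) 0.8 else -0.8
    W <- rsym(p, 500 + k, scale = 0.3)
    W[1, 2] <- W[1, 2] + shift; W[2, 1] <- W[1, 2]
    diag(W) <- 1
    list(id = sprintf("s%02d", k), base = W,
         label = if (k <= 5) 1 else -1)
  })
  grid <- list(0.5, 1)
  recipe <- function(base, param) threshold_sparsify(base, param)

  r1 <- nested_loocv(cohort, grid, recipe)
  r2 <- nested_loocv(cohort, grid, recipe)
  expect_identical(r1$folds, r2$folds)
  expect_equal(r1$TP + r1$TN + r1$FP + r1$FN, 10)

  # leakage probe: poisoning the held-out subject's matrix must not
  # change the training-side choices for the fold that holds it out
  t_probe <- 3L
  poisoned <- cohort
  poison <- matrix(1e6, p, p); diag(poison) <- 0
  poisoned[[t_probe]]$base <- cohort[[t_probe]]$base + poison
  r3 <- nested_loocv(poisoned, grid, recipe)
  expect_identical(r3$fold_fits[[t_probe]]$param_index,
                   r1$fold_fits[[t_probe]]$param_index)
  expect_identical(r3$fold_fits[[t_probe]]$mask,
                   r1$fold_fits[[t_probe]]$mask)
  expect_identical(r3$fold_fits[[t_probe]]$model$w,
                   r1$fold_fits[[t_probe]]$model$w)
})
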