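test_that("FDR matches hand-evaluated values and tie/degenerate rules", {
  # class A {1,2,3}, class B {4,5,6}: (2-5)^2 / (1+1) = 4.5
  rk <- fdr_rank(matrix(c(1, 2, 3, 4, 5, 6), ncol = 1),
                 c(-1, -1, -1, 1, 1, 1))
  expect_equal(rk$fdr_values, 4.5)

  # identical class distributions rank last with FDR 0
  X <- cbind(c(1, 2, 3, 1, 2, 3), c(0, 0, 1, 5, 5, 6))
  rk <- fdr_rank(X, c(-1, -1, -1, 1, 1, 1))
  expect_equal(rk$order, c(2L, 1L))
  expect_equal(rk$fdr_values[2], 0)

  # equal FDR: lower original index precedes
  X <- cbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 3))
  rk <- fdr_rank(X, c(-1, -1, 1, 1))
  expect_equal(rk$order, c(1L, 2L))

  # zero denominator, nonzero numerator -> +Inf, ranks first
  X <- cbind(c(0, 0, 1, 1), c(0, 9, 1, 10))
  rk <- fdr_rank(X, c(-1, -1, 1, 1))
  expect_equal(rk$order[1], 1L)
  expect_equal(rk$fdr_values[1], Inf)

  expect_error(fdr_rank(matrix(1:4, ncol = 1), c(1, 1, 1, 1)), "class")
})

test_that("FDR agrees with brute-force evaluation and is shift/scale invariant", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(30 * 10), 30, 10)
    y <- rep(c(-1, 1), c(14, 16))
    rk <- fdr_rank(X, y)
    # independent brute force, feature by feature
    brute <- sapply(seq_len(ncol(X)), function(j) {
      a <- X[y == -1, j]
      b <- X[y == 1, j]
      va <- sum((a - mean(a))^2) / (length(a) - 1)
      vb <- sum((b - mean(b))^2) / (length(b) - 1)
      (mean(a) - mean(b))^2 / (va + vb)
    })
    expect_equal(rk$fdr_values, brute[rk$order], tolerance = 1e-12)
    expect_equal(rk$order, order(-brute))

    # invariance: adding a constant, and common positive rescaling
    rk_shift <- fdr_rank(X + 10, y)
    rk_scale <- fdr_rank(X * 3, y)
    expect_equal(rk_shift$fdr_values, rk$fdr_values, tolerance = 1e-9)
    expect_equal(rk_scale$order, rk$order)
    expect_equal(rk_scale$fdr_values, rk$fdr_values, tolerance = 1e-9)
  }
})

test_that("PCA recovers exact low-rank structure and centers correctly", {
  # points exactly on y = 2x: rank-1 covariance
  t <- c(-2, -1, 0, 1, 3)
  X <- cbind(t, 2 * t)
  m <- pca_fit(X)
  expect_equal(m$explained_variance[1] / sum(m$explained_variance), 1,
               tolerance = 1e-10)
  expect_lte(m$explained_variance[2], 1e-10)
  expect_equal(abs(m$loadings[, 1]), c(1, 2) / sqrt(5), tolerance = 1e-10)

  # the training mean maps to the zero coefficient vector
  expect_equal(as.numeric(pca_transform(matrix(m$mean, 1), m)),
               rep(0, m$n_components))
})

test_that("PCA satisfies orthonormality, variance bookkeeping and reconstruction", {
  set.seed(3)
  X <- matrix(rnorm(15 * 8), 15, 8)
  m <- pca_fit(X)
  G <- crossprod(m$loadings)
  expect_equal(G, diag(ncol(m$loadings)), tolerance = 1e-8)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  expect_equal(sum(m$explained_variance), sum(apply(X, 2, var)),
               tolerance = 1e-8)

  # reconstruction at full rank
  C <- pca_transform(X, m)
  rec <- sweep(C %*% t(m$loadings), 2, m$mean, "+")
  expect_equal(rec, X, tolerance = 1e-6, ignore_attr = TRUE)

  # training scores are uncorrelated and their variances are the EVs
  cors <- cor(C)
  expect_true(all(abs(cors[upper.tri(cors)]) <= 1e-6))
  expect_equal(apply(C, 2, var), m$explained_variance, tolerance = 1e-8)

  # held-out copy of a training sample gets identical coefficients
  expect_equal(pca_transform(X[3, , drop = FALSE], m), C[3, , drop = FALSE])

  # deterministic sign: largest-|entry| positive
  for (j in seq_len(ncol(m$loadings))) {
    expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
  }
  expect_error(pca_fit(X[1, , drop = FALSE]), "2 training samples")
})

test_that("PLS first direction maximizes label covariance and deflation decorrelates", {
  y <- rep(c(-1, 1), each = 5)
  # single feature exactly equal to y: direction is +/-1 on that feature
  m <- pls_fit(matrix(y, ncol = 1), y, 1)
  expect_equal(abs(m$weights[1, 1]), 1)

  # X orthogonal to y: first-direction covariance with y vanishes
  set.seed(5)
  X <- matrix(rnorm(10 * 4), 10, 4)
  Xc <- sweep(X, 2, colMeans(X))
  X_orth <- Xc - outer(y - mean(y), drop(crossprod(Xc, y - mean(y))) /
                         sum((y - mean(y))^2))
  m <- pls_fit(X_orth, y, 1)
  s <- pls_transform(X_orth, m)
  expect_lte(abs(cov(s[, 1], y)), 1e-10)

  # closed form for the first direction: proportional to t(Xc) %*% yc
  m <- pls_fit(X, y, 2)
  w_ref <- drop(crossprod(sweep(X, 2, colMeans(X)), y - mean(y)))
  expect_equal(m$weights[, 1], w_ref / sqrt(sum(w_ref^2)), tolerance = 1e-10)

  # two components on rank-2 data: projected scores uncorrelated
  S <- pls_transform(X, m)
  expect_lte(abs(cor(S[, 1], S[, 2])), 1e-6)
  expect_equal(apply(m$weights, 2, function(w) sum(w^2)), c(1, 1),
               tolerance = 1e-10)

  expect_error(pls_fit(X, y, 20), "out of range")
})

test_that("z-score normalization matches its definition and guards constants", {
  x <- matrix(c(1, 2, 3), ncol = 1)
  st <- zscore_fit(x)
  expect_equal(as.numeric(zscore_apply(x, st)), c(-1, 0, 1))

  X <- cbind(a = c(1, 2, 3, 4), b = rep(7, 4))
  st <- zscore_fit(X)
  expect_warning(Z <- zscore_apply(X, st), "constant")
  expect_equal(Z[, 2], rep(0, 4), ignore_attr = TRUE)
  expect_equal(mean(Z[, 1]), 0, tolerance = 1e-10)
  expect_equal(sd(Z[, 1]), 1, tolerance = 1e-10)

  expect_error(zscore_apply(X[, 1, drop = FALSE], st), "columns")
})

test_that("feature assembly respects rankings, boundaries and provenance", {
  set.seed(9)
  C <- matrix(rnorm(8 * 5), 8, 5)
  S <- matrix(rnorm(8 * 4), 8, 4,
              dimnames = list(NULL, paste0("score0", 1:4)))
  y <- rep(c(-1, 1), 4)
  rk_c <- fdr_rank(C, y)
  rk_s <- fdr_rank(S, y)

  # MRI-only and scores-only configurations
  F1 <- assemble_features(C, NULL, rk_c, NULL, k_mri = 3, k_np = 0)
  expect_equal(ncol(F1), 3)
  expect_true(all(grepl("^mri:", colnames(F1))))
  F2 <- assemble_features(NULL, S, NULL, rk_s, k_mri = 0, k_np = 4)
  expect_equal(ncol(F2), 4)

  # provenance roundtrip: each column equals the source column it names
  F3 <- assemble_features(C, S, rk_c, rk_s, k_mri = 2, k_np = 2)
  prov <- attr(F3, "provenance")
  for (j in seq_len(ncol(F3))) {
    src <- if (prov$stream[j] == "mri") C[, prov$source_index[j]]
           else S[, prov$source_index[j]]
    expect_equal(F3[, j], src, ignore_attr = TRUE)
  }
  expect_equal(prov$source_index[1:2], rk_c$order[1:2])

  expect_error(assemble_features(C, S, rk_c, rk_s, 0, 0), ">= 1")
})

test_that("extraction and normalization are functions of training data only", {
  set.seed(11)
  X <- matrix(rnorm(20 * 6), 20, 6)
  train <- 1:12
  m1 <- pca_fit(X[train, ])
  z1 <- zscore_fit(X[train, ])
  X_perturbed <- X
  X_perturbed[13:20, ] <- X_perturbed[13:20, ] + 100
  m2 <- pca_fit(X_perturbed[train, ])
  z2 <- zscore_fit(X_perturbed[train, ])
  expect_identical(m1, m2)
  expect_identical(z1, z2)
})
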