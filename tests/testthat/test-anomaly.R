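test_that("RBF kernel has its closed-form values", {
  u <- c(1, 2, 3); v <- c(1, 2, 3)
  expect_equal(rbf_kernel(u, v, 0.7), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), 1), exp(-1), tolerance = 1e-12)
  expect_equal(rbf_kernel(c(0, 5), c(2, 1), 0), 1)  # gamma -> 0 limit
  expect_error(rbf_kernel(1:3, 1:4, 1), "dimension")

  expect_equal(default_gamma(125), 1 / 125)
  expect_equal(default_gamma(124), 1 / 124)
  expect_equal(default_gamma(1), 1)
})

test_that("one-class dual solution matches brute-force enumeration on a tiny instance", {
  X <- matrix(c(0, 0,
                1, 0.2,
                0.1, 1,
                4, 4), 4, 2, byrow = TRUE)
  nu <- 0.5; gamma <- 0.3
  fit <- train_ocsvm(X, nu, gamma, tol = 1e-10)
  oracle <- brute_force_ocsvm(X, nu, gamma)
  expect_false(is.null(oracle))
  expect_equal(fit$alpha, oracle$alpha, tolerance = 1e-4)
  expect_equal(fit$rho, oracle$rho, tolerance = 1e-4)
})

test_that("nu bounds the outlier fraction and support-vector fraction over random cohorts", {
  for (r in 1:6) {
    n <- c(30, 42, 57)[(r %% 3) + 1]
    nu <- c(0.2, 0.5, 0.7)[(r %% 3) + 1]
    X <- random_features(n, 10, seed = 500 + r)
    m <- train_ocsvm(X, nu, default_gamma(10))
    # strict outliers only: margin support vectors sit within solver
    # tolerance of zero and must not be counted either way
    expect_lte(mean(m$decision < -1e-5), nu + 1e-12)
    expect_gte(m$n_support / n, nu - 1 / n)
    expect_equal(sum(m$alpha), 1, tolerance = 1e-9)
    expect_lte(max(m$alpha), 1 / (nu * n) + 1e-12)
  }
})

test_that("decision scores agree with an independent one-class SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(21)
  X <- rbind(matrix(rnorm(80), 40, 2), matrix(rnorm(20, mean = 3), 10, 2))
  nu <- 0.5; gamma <- 0.5
  mine <- train_ocsvm(X, nu, gamma, tol = 1e-8)
  ref <- e1071::svm(X, type = "one-classification", nu = nu, gamma = gamma,
                    scale = FALSE)
  dv <- attr(predict(ref, X, decision.values = TRUE), "decision.values")[, 1]
  # libsvm's one-class dual scales alpha by nu*n relative to the
  # sum-to-one convention; decision scores differ by that factor only
  expect_lt(max(abs(mine$decision - dv / (nu * nrow(X)))), 1e-3)
  expect_gt(cor(mine$decision, dv), 0.99999)
})

test_that("the abnormality index ranks outliers above central points", {
  set.seed(31)
  cloud <- matrix(rnorm(100), 50, 2)
  X <- rbind(cloud, c(8, 8))
  m <- train_ocsvm(X, 0.5, 0.5)
  idx <- abnormality_index(m, X)
  expect_gt(idx[51], max(idx[1:50]))     # far outlier most abnormal
  expect_gt(idx[51], 0)                   # flagged outside the region

  # density-oracle rank check on a 2-D Gaussian cloud
  kde <- sapply(seq_len(50), function(i) {
    d2 <- rowSums(sweep(cloud, 2, cloud[i, ])^2)
    mean(exp(-d2 / 0.5))
  })
  m2 <- train_ocsvm(cloud, 0.5, 0.5)
  expect_lt(cor(abnormality_index(m2, cloud), kde, method = "spearman"), -0.8)

  # all-identical training points give identical scores
  same <- matrix(1, 6, 3)
  ms <- train_ocsvm(same, 0.5, 1)
  expect_equal(max(ms$decision) - min(ms$decision), 0, tolerance = 1e-9)

  expect_error(abnormality_index(m, matrix(0, 1, 5)), "dimension")
})

test_that("indices are invariant to training-set duplication and row permutation", {
  X <- random_features(24, 6, seed = 77)
  base <- abnormality_index(train_ocsvm(X, 0.5, 1 / 6, tol = 1e-9), X)

  dup <- abnormality_index(train_ocsvm(rbind(X, X), 0.5, 1 / 6, tol = 1e-9), X)
  expect_equal(dup, base, tolerance = 1e-5)

  perm <- sample(24)
  shuffled <- abnormality_index(
    train_ocsvm(X[perm, ], 0.5, 1 / 6, tol = 1e-9), X)
  expect_equal(shuffled, base, tolerance = 1e-6)
})

test_that("the mixed-group protocol pools symmetrically", {
  A <- random_features(21, 8, seed = 91)
  fit <- mixed_group_protocol(A, A, nu = 0.5, groups = c("g1", "g2"))
  expect_equal(nrow(fit$model$X), 42)
  i1 <- sort(fit$results$abnormality_index[fit$results$group == "g1"])
  i2 <- sort(fit$results$abnormality_index[fit$results$group == "g2"])
  expect_equal(i1, i2, tolerance = 1e-8)   # identical groups, identical indices

  # a tight cluster scores less abnormal than a scattered one
  tight <- random_features(21, 8, seed = 92, spread = 0.2)
  loose <- random_features(21, 8, seed = 93, spread = 2)
  fit2 <- mixed_group_protocol(loose, tight, groups = c("loose", "tight"))
  expect_gt(median_separation(fit2$results, c("loose", "tight")), 0)

  expect_error(mixed_group_protocol(A, A[, 1:3]), "dimension")
})
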