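test_that("sample autocovariances behave like moment estimators", {
  set.seed(11)
  x <- rnorm(50000); y <- rnorm(50000)
  G <- sample_autocovariances(x, y, 2)
  expect_lt(max(abs(G[[1]] - diag(2))), 0.05)   # Gamma(0) ~ I for white noise
  expect_lt(max(abs(G[[2]])), 0.05)             # Gamma(1) ~ 0

  # perfect dependence: y = x makes all four entries of Gamma(0) equal
  Gxx <- sample_autocovariances(x, x, 1)
  expect_equal(max(Gxx[[1]]) - min(Gxx[[1]]), 0, tolerance = 1e-12)

  # bilinearity: scaling both series by c scales Gamma by c^2
  Gs <- sample_autocovariances(3 * x, 3 * y, 2)
  expect_equal(Gs[[2]], 9 * G[[2]], tolerance = 1e-12)

  expect_error(sample_autocovariances(x[1:5], y[1:5], 10), "max_lag")
})

test_that("Yule-Walker recovers generating coefficients and matches stats::ar", {
  B1 <- matrix(c(0.5, 0.1, 0.2, 0.4), 2, 2, byrow = TRUE)
  Z <- simulate_var(B1, diag(2), 100000, seed = 3)
  fit <- fit_var_yule_walker(Z[, 1], Z[, 2], 1)
  expect_lt(max(abs(fit$B[[1]] - B1)), 0.02)
  expect_true(fit$stable)

  # error shrinks with T (consistency)
  errs <- sapply(c(500, 5000, 50000), function(T_len) {
    Zt <- simulate_var(B1, diag(2), T_len, seed = 17)
    max(abs(suppressWarnings(
      fit_var_yule_walker(Zt[, 1], Zt[, 2], 1)$B[[1]]) - B1))
  })
  expect_true(errs[3] < errs[1])

  # independent route: base R's multivariate Yule-Walker fit, including a
  # higher order where the block-Toeplitz structure matters
  ref <- stats::ar(Z, aic = FALSE, order.max = 1, method = "yule-walker",
                   demean = TRUE)
  expect_lt(max(abs(fit$B[[1]] - ref$ar[1, , ])), 0.01)
  fit5 <- fit_var_yule_walker(Z[, 1], Z[, 2], 5)
  ref5 <- stats::ar(Z, aic = FALSE, order.max = 5, method = "yule-walker")
  for (k in 1:5) {
    expect_lt(max(abs(fit5$B[[k]] - ref5$ar[k, , ])), 1e-6)
  }
  # ar rescales its prediction variance by a degrees-of-freedom factor;
  # compare up to that O(1/T) correction
  expect_lt(max(abs(fit5$Sigma - ref5$var.pred)), 1e-3)

  # white noise at p = 1: coefficients near zero
  set.seed(5)
  w1 <- rnorm(20000); w2 <- rnorm(20000)
  fw <- fit_var_yule_walker(w1, w2, 1)
  expect_lt(max(abs(fw$B[[1]])), 0.05)
})

test_that("AIC order selection finds strong generating orders", {
  expect_identical(select_order_aic(rnorm(100), rnorm(100), candidates = 3L), 3L)

  B <- list(matrix(c(0.4, 0.1, 0.1, 0.3), 2, 2),
            matrix(c(-0.5, 0.1, 0.1, -0.5), 2, 2))
  picks <- sapply(1:10, function(r) {
    Z <- simulate_var(B, diag(2), 5000, seed = 100 + r)
    select_order_aic(Z[, 1], Z[, 2])
  })
  expect_equal(as.integer(names(which.max(table(picks)))), 2L)

  # white noise: no systematic preference for rich models
  prefs <- sapply(1:10, function(r) {
    set.seed(200 + r)
    x <- rnorm(2000); y <- rnorm(2000)
    aic <- function(p) {
      f <- suppressWarnings(fit_var_yule_walker(x, y, p))
      2000 * as.numeric(determinant(f$Sigma)$modulus) + 2 * p * 4
    }
    aic(1) <= aic(10)
  })
  expect_gt(mean(prefs), 0.5)
})

test_that("spectral matrix has closed-form values for simple models", {
  white <- structure(list(order = 1, B = list(matrix(0, 2, 2)),
                          Sigma = diag(2), dt = 2, stable = TRUE),
                     class = "var_model")
  for (f in c(0, 0.1, 0.25)) {
    expect_equal(spectral_matrix(white, f), diag(2) + 0i, tolerance = 1e-12)
  }

  coloured <- white; coloured$Sigma <- diag(c(3, 7))
  expect_equal(Re(diag(spectral_matrix(coloured, 0.2))), c(3, 7),
               tolerance = 1e-12)

  # decoupled AR(1) with coefficient 0.5: S(0) = 1 / (1 - 0.5)^2 = 4
  ar1 <- white; ar1$B <- list(diag(c(0.5, 0.5)))
  expect_equal(Re(diag(spectral_matrix(ar1, 0))), c(4, 4), tolerance = 1e-12)

  expect_error(spectral_matrix(white, 0.3), "f_hz")
})

test_that("the default frequency grid spans (0, Nyquist]", {
  g <- default_grid(2, 125)
  expect_length(g, 125)
  expect_equal(diff(g)[1], 0.002, tolerance = 1e-12)
  expect_equal(max(g), 0.25, tolerance = 1e-12)
  expect_gt(min(g), 0)
  expect_equal(default_grid(2, 2), c(0.125, 0.25), tolerance = 1e-12)
  expect_equal(max(default_grid(0.8)), 1 / (2 * 0.8), tolerance = 1e-12)
})

test_that("coherence is bounded, symmetric in channels, and zero for decoupled models", {
  decoupled <- structure(list(order = 1, B = list(diag(c(0.5, -0.3))),
                              Sigma = diag(c(1, 2)), dt = 2, stable = TRUE),
                         class = "var_model")
  spec <- coherence(decoupled)
  expect_length(spec$values, 125)
  expect_lt(max(spec$values), 1e-12)

  # randomized stable VARs: coherence in [0,1], invariant to channel swap
  # and to separate rescaling of each channel
  for (r in 1:5) {
    set.seed(300 + r)
    repeat {
      B1 <- matrix(runif(4, -0.6, 0.6), 2, 2)
      m <- structure(list(order = 1, B = list(B1), Sigma = diag(2), dt = 2),
                     class = "var_model")
      if (var_spectral_radius(m) < 0.95) break
    }
    Z <- simulate_var(B1, diag(2), 3000, seed = 400 + r)
    x <- znormalize(Z[, 1]); y <- znormalize(Z[, 2])
    c_xy <- coherence(suppressWarnings(fit_var_yule_walker(x, y, 3)))$values
    c_yx <- coherence(suppressWarnings(fit_var_yule_walker(y, x, 3)))$values
    expect_true(all(c_xy >= 0 & c_xy <= 1))
    expect_equal(c_xy, c_yx, tolerance = 1e-8)
    c_scaled <- coherence(suppressWarnings(
      fit_var_yule_walker(3 * x, 0.2 * y, 3)))$values
    expect_equal(c_scaled, c_xy, tolerance = 1e-8)
  }

  # magnitude convention is the square root of the squared convention
  m <- structure(list(order = 1,
                      B = list(matrix(c(0.5, 0.3, 0.3, 0.5), 2, 2)),
                      Sigma = diag(2), dt = 2, stable = TRUE),
                 class = "var_model")
  expect_equal(coherence(m, convention = "magnitude")$values,
               sqrt(coherence(m, convention = "squared")$values),
               tolerance = 1e-12)
})
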