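#' Sample autocovariance matrices of a bivariate series
#'
#' Computes the lag-k cross-covariance matrices Gamma(k) = E[z_t z_{t-k}'],
#' k = 0..max_lag, of the demeaned bivariate series z_t = (x_t, y_t)'. The
#' divisor is 1/T (biased form) at every lag, which guarantees that the
#' block-Toeplitz matrix assembled from them is positive semi-definite.
#'
#' @param x,y Numeric vectors of equal length T.
#' @param max_lag Largest lag; requires T > max_lag.
#' @return List of max_lag + 1 matrices (2x2), element k + 1 holding lag k.
#' @export
sample_autocovariances <- function(x, y, max_lag) {
  stopifnot(length(x) == length(y), max_lag >= 0)
  T_len <- length(x)
  if (T_len <= max_lag) stop("series length must exceed max_lag")
  z <- cbind(x - mean(x), y - mean(y))
  lapply(0:max_lag, function(k) {
    crossprod(z[(1 + k):T_len, , drop = FALSE],
              z[1:(T_len - k), , drop = FALSE]) / T_len
  })
}

#' Fit a bivariate VAR(p) by Yule-Walker
#'
#' Solves the multivariate Yule-Walker system for coefficient matrices
#' B_1..B_p from the sample autocovariances: stacking G = [Gamma(1) ...
#' Gamma(p)], the block-Toeplitz matrix R with blocks R_ij = Gamma(i - j)
#' (Gamma(-k) = Gamma(k)'), the solution is [B_1 ... B_p] = G R^{-1}. The
#' innovation covariance is Sigma = Gamma(0) - sum_k B_k Gamma(k)',
#' symmetrised.
#'
#' @param x,y Numeric series of equal length (normalised signals expected).
#' @param p Lag order, 1..10.
#' @return An object of class `var_model`: list with `order`, `B` (list of
#'   p 2x2 matrices), `Sigma`, `dt`, `stable` (companion spectral radius < 1).
#' @param dt Sampling interval in seconds, carried into spectral evaluation.
#' @export
fit_var_yule_walker <- function(x, y, p, dt = 2) {
  stopifnot(p >= 1, p <= 10)
  T_len <- length(x)
  if (T_len <= 10 * p) {
    warning(sprintf("T = %d is short for a VAR(%d); estimates may be noisy",
                    T_len, p))
  }
  G <- sample_autocovariances(x, y, p)
  # Block-Toeplitz R: 2p x 2p, block (k, j) = Gamma(j - k), so that
  # [B_1 ... B_p] R = [Gamma(1) ... Gamma(p)] stacks the YW equations
  # Gamma(j) = sum_k B_k Gamma(j - k); Gamma(-m) = Gamma(m)'.
  R <- matrix(0, 2 * p, 2 * p)
  for (k in seq_len(p)) {
    for (j in seq_len(p)) {
      blk <- if (j >= k) G[[j - k + 1]] else t(G[[k - j + 1]])
      R[(2 * k - 1):(2 * k), (2 * j - 1):(2 * j)] <- blk
    }
  }
  Gstack <- do.call(cbind, G[-1])  # 2 x 2p: [Gamma(1) ... Gamma(p)]
  Bstack <- tryCatch(t(solve(t(R), t(Gstack))), error = function(e) {
    stop(sprintf(paste0("singular Yule-Walker system at order %d; ",
                        "try a lower order"), p))
  })
  B <- lapply(seq_len(p), function(k) Bstack[, (2 * k - 1):(2 * k)])
  Sigma <- G[[1]]
  for (k in seq_len(p)) Sigma <- Sigma - B[[k]] %*% t(G[[k + 1]])
  Sigma <- (Sigma + t(Sigma)) / 2
  model <- structure(list(order = p, B = B, Sigma = Sigma, dt = dt,
                          stable = NA),
                     class = "var_model")
  model$stable <- var_spectral_radius(model) < 1
  if (!model$stable) {
    warning(sprintf("fitted VAR(%d) is unstable (companion spectral radius >= 1)", p))
  }
  model
}

#' Companion-matrix spectral radius of a VAR model
#'
#' @param model A `var_model`.
#' @return Largest eigenvalue modulus of the companion matrix; < 1 for a
#'   stable (stationary) model.
#' @export
var_spectral_radius <- function(model) {
  p <- model$order
  d <- nrow(model$B[[1]])
  comp <- matrix(0, d * p, d * p)
  comp[1:d, ] <- do.call(cbind, model$B)
  if (p > 1) {
    comp[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> bivariate VAR(%d), dt = %g s, %s\n", x$order, x$dt,
              if (isTRUE(x$stable)) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Select the VAR lag order by AIC
#'
#' Fits each candidate order by Yule-Walker and evaluates the
#' ranking-equivalent criterion AIC(p) = T log det(Sigma_p) + 2 p d^2 with
#' d = 2; returns the minimiser, smallest order on ties. Selection is done
#' independently per subject in the pipeline.
#'
#' @param x,y Numeric series.
#' @param candidates Integer vector of candidate orders (default 1:10).
#' @param dt Sampling interval in seconds.
#' @return The selected order (integer).
#' @export
select_order_aic <- function(x, y, candidates = 1:10, dt = 2) {
  stopifnot(length(candidates) >= 1, all(candidates >= 1))
  T_len <- length(x)
  aic <- vapply(candidates, function(p) {
    fit <- suppressWarnings(fit_var_yule_walker(x, y, p, dt))
    ldet <- determinant(fit$Sigma, logarithm = TRUE)
    if (ldet$sign <= 0) return(Inf)  # degenerate innovation covariance
    T_len * as.numeric(ldet$modulus) + 2 * p * 4
  }, numeric(1))
  candidates[which.min(aic)]
}

#' Evaluate the VAR spectral density matrix at one frequency
#'
#' S(f) = A(f)^{-1} Sigma A(f)^{-H} with A(f) = I - sum_k B_k
#' exp(-i 2 pi f dt k). The 1/(2 pi) density convention factor is omitted:
#' it cancels in coherence, the only exported quantity.
#'
#' @param model A `var_model`.
#' @param f_hz Frequency in Hz, within [0, Nyquist].
#' @return 2x2 complex Hermitian matrix with positive real diagonal.
#' @export
spectral_matrix <- function(model, f_hz) {
  nyq <- 1 / (2 * model$dt)
  stopifnot(f_hz >= 0, f_hz <= nyq + 1e-12)
  d <- nrow(model$Sigma)
  A <- diag(d) + 0i
  for (k in seq_len(model$order)) {
    A <- A - model$B[[k]] * exp(-2i * pi * f_hz * model$dt * k)
  }
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop(sprintf("transfer matrix numerically singular at %g Hz (model near unit root)",
                 f_hz))
  })
  S <- Ainv %*% model$Sigma %*% Conj(t(Ainv))
  (S + Conj(t(S))) / 2  # enforce exact Hermitian symmetry
}

#' Default frequency grid for coherence sampling
#'
#' n equally spaced frequencies f_j = j * f_Nyquist / n, j = 1..n: the grid
#' excludes 0 Hz (uninformative after z-normalisation and high-pass
#' preprocessing) and includes the Nyquist frequency 1/(2 dt). With the
#' study's TR of 2 s and n = 125 this spans 0.002 to 0.25 Hz in 0.002 Hz
#' steps.
#'
#' @param dt Sampling interval in seconds.
#' @param n Number of frequencies (default 125).
#' @return Numeric vector of n frequencies in Hz.
#' @export
default_grid <- function(dt, n = 125) {
  stopifnot(dt > 0, n >= 2)
  nyq <- 1 / (2 * dt)
  (seq_len(n) / n) * nyq
}

#' Parametric magnitude-squared coherence of a fitted VAR
#'
#' C(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f)), in [0, 1] at every frequency.
#' The unsquared magnitude variant |S_xy| / sqrt(S_xx S_yy) is available via
#' `convention = "magnitude"`.
#'
#' @param model A `var_model`.
#' @param grid Frequencies in Hz (default [default_grid()] at the model dt).
#' @param convention `"squared"` (default) or `"magnitude"`.
#' @param subject_id Label attached to the spectrum.
#' @return A `coherence_spectrum`: list with `subject_id`, `frequencies`,
#'   `values`.
#' @export
coherence <- function(model, grid = default_grid(model$dt),
                      convention = c("squared", "magnitude"),
                      subject_id = "subject") {
  convention <- match.arg(convention)
  vals <- vapply(grid, function(f) {
    S <- spectral_matrix(model, f)
    sxx <- Re(S[1, 1]); syy <- Re(S[2, 2])
    if (sxx <= 0 || syy <= 0) {
      stop(sprintf("non-positive diagonal spectrum at %g Hz", f))
    }
    c2 <- Mod(S[1, 2])^2 / (sxx * syy)
    c2 <- min(max(c2, 0), 1)  # clamp roundoff at the boundary
    if (convention == "squared") c2 else sqrt(c2)
  }, numeric(1))
  structure(list(subject_id = subject_id, frequencies = grid, values = vals),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> subject %s: %d frequencies, %g-%g Hz\n",
              x$subject_id, length(x$frequencies),
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Coherence feature vector for one subject
#'
#' The full per-subject estimation path: z-normalise both region signals,
#' select the VAR lag order by AIC over `orders`, fit by Yule-Walker, and
#' evaluate parametric coherence on the frequency grid.
#'
#' @param x,y Region signals: `roi_series` objects or numeric vectors.
#' @param dt Sampling interval in seconds (taken from `x` if a series).
#' @param n_freq Grid size (default 125).
#' @param orders Candidate lag orders (default 1:10).
#' @param convention Coherence convention, see [coherence()].
#' @param subject_id Label.
#' @return List with `spectrum` (a `coherence_spectrum`), `model` (the
#'   fitted `var_model`) and `order`.
#' @export
coherence_features <- function(x, y, dt = NULL, n_freq = 125, orders = 1:10,
                               convention = "squared",
                               subject_id = "subject") {
  if (inherits(x, "roi_series")) {
    if (is.null(dt)) dt <- x$dt
    x <- x$values
  }
  if (inherits(y, "roi_series")) y <- y$values
  if (is.null(dt)) dt <- 2
  x <- znormalize(x)
  y <- znormalize(y)
  p <- select_order_aic(x, y, orders, dt)
  model <- suppressWarnings(fit_var_yule_walker(x, y, p, dt))
  spec <- coherence(model, default_grid(dt, n_freq), convention, subject_id)
  list(spectrum = spec, model = model, order = p)
}

#' Coherence feature matrix for a cohort
#'
#' Applies [coherence_features()] to every subject listed in a manifest and
#' assembles the n x d feature matrix used by the anomaly model.
#'
#' @param manifest Data frame with columns `subject_id`, `group`, and
#'   `series_path` (two-column TSV per subject); optional `age`, `sex`.
#' @param dt Sampling interval in seconds.
#' @param n_freq,orders,convention Passed to [coherence_features()].
#' @return List with `features` (matrix, rownames = subject ids, colnames =
#'   grid frequencies in Hz), `frequencies`, `orders` (named integer vector
#'   of selected lags) and `manifest`.
#' @export
cohort_coherence <- function(manifest, dt = 2, n_freq = 125, orders = 1:10,
                             convention = "squared") {
  stopifnot(all(c("subject_id", "group", "series_path") %in% names(manifest)))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$subject_id[i]
    series <- tryCatch(
      read_series_tsv(manifest$series_path[i], dt, sid),
      error = function(e) stop(sprintf("subject %s: %s", sid, conditionMessage(e)))
    )
    cf <- coherence_features(series[[1]], series[[2]], dt, n_freq, orders,
                             convention, sid)
    list(values = cf$spectrum$values, order = cf$order,
         frequencies = cf$spectrum$frequencies)
  })
  features <- do.call(rbind, lapply(rows, `[[`, "values"))
  rownames(features) <- manifest$subject_id
  colnames(features) <- signif(rows[[1]]$frequencies, 6)
  sel <- vapply(rows, `[[`, integer(1), "order")
  names(sel) <- manifest$subject_id
  list(features = features, frequencies = rows[[1]]$frequencies,
       orders = sel, manifest = manifest)
}
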