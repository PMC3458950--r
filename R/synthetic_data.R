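# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate a stable VAR process
#'
#' Standard VAR recursion z_t = sum_k B_k z_{t-k} + e_t with Gaussian
#' innovations e_t ~ N(0, Sigma); a burn-in prefix is discarded so the
#' returned segment is (approximately) stationary.
#'
#' @param B List of d x d coefficient matrices (order p = length of list).
#' @param Sigma Innovation covariance (d x d, positive-definite).
#' @param T_len Number of samples returned.
#' @param burn_in Samples discarded from the start (default 200).
#' @param seed RNG seed; same seed, same output.
#' @return T_len x d numeric matrix.
#' @export
simulate_var <- function(B, Sigma, T_len, burn_in = 200, seed = 1) {
  if (is.matrix(B)) B <- list(B)
  d <- nrow(Sigma)
  p <- length(B)
  sr <- var_spectral_radius(structure(list(order = p, B = B), class = "var_model"))
  if (sr >= 1) {
    stop(sprintf("unstable VAR coefficients (companion spectral radius %.3f >= 1)", sr))
  }
  ch <- tryCatch(chol(Sigma), error = function(e) {
    stop("Sigma must be symmetric positive-definite")
  })
  n <- T_len + burn_in
  with_seed(seed, {
    E <- matrix(stats::rnorm(n * d), n, d) %*% ch
    Z <- matrix(0, n, d)
    for (t in seq_len(n)) {
      zt <- E[t, ]
      for (k in seq_len(p)) {
        if (t > k) zt <- zt + as.numeric(B[[k]] %*% Z[t - k, ])
      }
      Z[t, ] <- zt
    }
    Z[(burn_in + 1):n, , drop = FALSE]
  })
}

# Unit-variance Gaussian latent whose spectrum is confined to the union of
# the given frequency bands: white noise filtered in the Fourier domain.
# `bands` is a 2-column matrix of (f_lo, f_hi) in Hz.
band_limited_latent <- function(bands, T_len, dt) {
  freqs <- (0:(T_len - 1)) / (T_len * dt)
  fold <- pmin(freqs, 1 / dt - freqs)  # two-sided spectrum folding
  keep <- rep(FALSE, T_len)
  for (b in seq_len(nrow(bands))) {
    keep <- keep | (fold >= bands[b, 1] & fold <= bands[b, 2])
  }
  if (!any(keep)) {
    stop(sprintf("band set contains no Fourier bin at T = %d, dt = %g",
                 T_len, dt))
  }
  w <- stats::rnorm(T_len)
  W <- stats::fft(w)
  W[!keep] <- 0
  z <- Re(stats::fft(W, inverse = TRUE)) / T_len
  z / sqrt(mean((z - mean(z))^2))
}

#' Simulate a band-coupled bivariate pair
#'
#' Both channels share a band-limited latent component with mixing weight
#' lambda plus independent white noise:
#' x = sqrt(lambda) z + sqrt(1 - lambda) * noise * w_x (likewise y with its
#' own w_y), where z is unit-variance Gaussian noise confined to the given
#' frequency band(s) by Fourier-domain filtering. True coherence inside the
#' band increases monotonically with lambda and is ~0 well outside it.
#'
#' @param band Numeric 2-vector (f_lo, f_hi) in Hz, or a 2-column matrix of
#'   bands (the latent then spans their union).
#' @param lambda Shared-component weight in [0, 1].
#' @param T_len Series length (default 197).
#' @param dt Sampling interval in seconds (default 2).
#' @param noise White-noise scale of the channel-specific component
#'   (default 1).
#' @param seed RNG seed.
#' @return T_len x 2 matrix with columns x, y.
#' @export
simulate_band_coupled_pair <- function(band, lambda, T_len = 197, dt = 2,
                                       noise = 1, seed = 1) {
  bands <- if (is.matrix(band)) band else matrix(band, 1, 2)
  nyq <- 1 / (2 * dt)
  if (any(bands[, 1] < 0) || any(bands[, 2] > nyq + 1e-12) ||
      any(bands[, 1] >= bands[, 2])) {
    stop(sprintf("bands must satisfy 0 <= f_lo < f_hi <= Nyquist (%g Hz)", nyq))
  }
  stopifnot(length(lambda) == 1L, lambda >= 0, lambda <= 1)
  with_seed(seed, {
    z <- band_limited_latent(bands, T_len, dt)
    w_own <- sqrt(1 - lambda) * noise
    x <- sqrt(lambda) * z + w_own * stats::rnorm(T_len)
    y <- sqrt(lambda) * z + w_own * stats::rnorm(T_len)
    cbind(x = x, y = y)
  })
}

#' Cohort specification for the synthetic study
#'
#' Encodes the study conditions the generator emulates: two groups of 21
#' subjects, bivariate resting-state series of 197 volumes at TR = 2 s, and
#' low-frequency cross-coupling (0.012-0.048 Hz) whose structure differs
#' between groups. Under the default profiles the control group is coupled
#' across the whole low-frequency band while each case subject is coupled
#' only over a narrow subject-specific sub-band — the case group is "reduced
#' and heterogeneous": every patient departs from the normative coupling
#' profile in their own way, which is what drives their abnormality indices
#' up under the pooled one-class model.
#'
#' A group profile is a list with fields:
#' \describe{
#'   \item{band}{numeric 2-vector (f_lo, f_hi) Hz — the full coupling band.}
#'   \item{lambda, lambda_sd}{mean and between-subject SD of the coupling
#'     weight (truncated to `lambda_range`).}
#'   \item{lambda_range}{length-2 clip range for per-subject lambda.}
#'   \item{subband_halfwidth}{NULL for full-band coupling, or a length-2
#'     range: each subject is coupled only on `centre +/- halfwidth` with the
#'     halfwidth and centre drawn uniformly (centre kept inside the band).}
#'   \item{age_mean, age_sd, p_male}{demographic model for confound checks.}
#' }
#'
#' @param n_per_group Subjects per group (default 21).
#' @param T_len Series length (default 197).
#' @param dt Sampling interval, seconds (default 2).
#' @param groups Named list of group profiles; the FIRST group is the case
#'   group for downstream one-tailed comparisons.
#' @param noise White-noise scale (default 1).
#' @param seed Master seed (default 20120926).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 21, T_len = 197, dt = 2,
                        groups = default_group_profiles(),
                        noise = 1, seed = 20120926) {
  stopifnot(n_per_group >= 1, T_len >= 30, dt > 0, length(groups) >= 2)
  structure(list(n_per_group = n_per_group, T_len = T_len, dt = dt,
                 groups = groups, noise = noise, seed = seed),
            class = "cohort_spec")
}

#' Default group coupling and demographic profiles
#'
#' Both groups share the coupling weight distribution (lambda ~ N(0.7,
#' 0.03), clipped to [0.5, 0.9]) over the low-frequency band 0.012-0.048 Hz.
#' Controls are coupled over the full band; case subjects over a random
#' sub-band of half-width 0.005-0.008 Hz — reduced total coupling with
#' maximal between-subject heterogeneity in where the residual coupling
#' sits. Ages and sexes follow the adult study demographics (case: mean age
#' 36.5, SD 7.1, 16/21 male; control: mean 35.5, SD 9.9, 10/21 male).
#'
#' @return Named list of two group profiles (case first).
#' @export
default_group_profiles <- function() {
  band <- c(0.012, 0.048)
  list(
    case = list(band = band, lambda = 0.7, lambda_sd = 0.03,
                lambda_range = c(0.5, 0.9),
                subband_halfwidth = c(0.005, 0.008),
                age_mean = 36.5, age_sd = 7.1, p_male = 16 / 21),
    control = list(band = band, lambda = 0.7, lambda_sd = 0.03,
                   lambda_range = c(0.5, 0.9),
                   subband_halfwidth = NULL,
                   age_mean = 35.5, age_sd = 9.9, p_male = 10 / 21)
  )
}

# Deterministic per-subject seed derivation from the master seed: a fixed
# prime stride modulo the largest 32-bit prime keeps seeds distinct and
# below .Machine$integer.max.
subject_seed <- function(master, index) {
  as.integer((as.numeric(master) + 104729 * as.numeric(index)) %% 2147483647)
}

# Draw one subject's coupling parameters from a group profile.
draw_subject_profile <- function(prof) {
  lam <- stats::rnorm(1, prof$lambda, prof$lambda_sd)
  lam <- min(max(lam, prof$lambda_range[1]), prof$lambda_range[2])
  band <- matrix(prof$band, 1, 2)
  if (!is.null(prof$subband_halfwidth)) {
    hw <- stats::runif(1, prof$subband_halfwidth[1], prof$subband_halfwidth[2])
    ctr <- stats::runif(1, prof$band[1] + hw, prof$band[2] - hw)
    band <- matrix(c(ctr - hw, ctr + hw), 1, 2)
  }
  list(lambda = lam, band = band)
}

#' Generate a synthetic cohort on disk
#'
#' Writes one two-column TSV per subject (columns `pcc`, `dacc`; one row per
#' volume) plus a manifest CSV (`subject_id`, `group`, `age`, `sex`,
#' `series_path`). Per-subject seeds are derived from the master seed by a
#' fixed stride, so cohorts are fully reproducible and subjects mutually
#' independent.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data frame (also written to
#'   `file.path(out_dir, "manifest.csv")`), with per-subject coupling
#'   parameters attached as attribute `"coupling"`.
#' @export
generate_cohort <- function(spec = cohort_spec(), out_dir = tempfile("cohort")) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- spec$n_per_group
  rows <- list()
  coupling <- list()
  counter <- 0L
  for (gname in names(spec$groups)) {
    prof <- spec$groups[[gname]]
    for (i in seq_len(n)) {
      counter <- counter + 1L
      sseed <- subject_seed(spec$seed, counter)
      sid <- sprintf("%s_%02d", gname, i)
      subj <- with_seed(sseed, {
        c(draw_subject_profile(prof),
          list(age = round(stats::rnorm(1, prof$age_mean, prof$age_sd), 1),
               sex = if (stats::runif(1) < prof$p_male) "M" else "F"))
      })
      zpair <- simulate_band_coupled_pair(subj$band, subj$lambda, spec$T_len,
                                          spec$dt, spec$noise,
                                          seed = subject_seed(sseed, 1))
      path <- file.path(out_dir, paste0(sid, ".tsv"))
      series <- list(
        pcc = roi_series(sid, "pcc", zpair[, 1], spec$dt),
        dacc = roi_series(sid, "dacc", zpair[, 2], spec$dt)
      )
      tryCatch(write_series_tsv(series, path), error = function(e) {
        stop(sprintf("failed writing %s: %s", path, conditionMessage(e)))
      })
      rows[[counter]] <- data.frame(subject_id = sid, group = gname,
                                    age = subj$age, sex = subj$sex,
                                    series_path = path,
                                    stringsAsFactors = FALSE)
      coupling[[counter]] <- data.frame(subject_id = sid,
                                        lambda = subj$lambda,
                                        f_lo = subj$band[1, 1],
                                        f_hi = subj$band[1, 2])
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "coupling") <- do.call(rbind, coupling)
  manifest
}

#' Welch coherence oracle
#'
#' Nonparametric magnitude-squared coherence by the windowed
#' averaged-periodogram (Welch) method: Hann-tapered, demeaned, overlapping
#' segments; auto- and cross-spectra averaged across segments. This is the
#' independent estimator used to validate the parametric VAR coherence — it
#' shares no code with it.
#'
#' @param x,y Numeric series of equal length (>= 2 segments' worth).
#' @param dt Sampling interval in seconds.
#' @param segment_length Samples per segment (default 256).
#' @param overlap Fractional overlap in [0, 0.9] (default 0.5).
#' @return A `coherence_spectrum` on the segment FFT grid
#'   (k / (segment_length dt), k = 1..floor(segment_length/2)).
#' @export
welch_coherence_oracle <- function(x, y, dt, segment_length = 256,
                                   overlap = 0.5) {
  T_len <- length(x)
  stopifnot(length(y) == T_len, overlap >= 0, overlap < 0.95)
  if (T_len < 2 * segment_length) {
    stop("series too short: need at least two Welch segments")
  }
  L <- as.integer(segment_length)
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, T_len - L + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))  # Hann taper
  nf <- L %/% 2
  pxx <- pyy <- numeric(nf)
  pxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + L - 1L)]; ys <- y[s:(s + L - 1L)]
    X <- stats::fft((xs - mean(xs)) * win)[2:(nf + 1L)]
    Y <- stats::fft((ys - mean(ys)) * win)[2:(nf + 1L)]
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  m <- length(starts)
  coh <- Mod(pxy / m)^2 / ((pxx / m) * (pyy / m))
  coh[!is.finite(coh)] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  structure(list(subject_id = "oracle",
                 frequencies = (seq_len(nf)) / (L * dt),
                 values = coh),
            class = "coherence_spectrum")
}
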