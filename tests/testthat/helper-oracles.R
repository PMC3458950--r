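# Independent oracles used to validate the package's own implementations.
# None of these share code with the functions they check.

# Exact one-class-SVM dual solve by active-set enumeration: every coefficient
# is either 0, at the box bound C = 1/(nu n), or free; free coefficients
# satisfy (K alpha)_i = rho with sum(alpha) = 1. Enumerates all 3^n
# assignments (tiny n only) and returns the feasible KKT-consistent solution.
brute_force_ocsvm <- function(X, nu, gamma) {
  n <- nrow(X)
  stopifnot(n <= 8)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) exp(-gamma * sum((X[i, ] - X[j, ])^2))))
  C <- 1 / (nu * n)
  best <- NULL
  states <- expand.grid(rep(list(c("zero", "bound", "free")), n),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(states))) {
    st <- unlist(states[r, ])
    Fs <- which(st == "free"); Bs <- which(st == "bound")
    alpha <- numeric(n)
    alpha[Bs] <- C
    if (length(Fs) > 0) {
      # solve [K_FF, -1; 1', 0] [alpha_F; rho] = [-K_FB alpha_B; 1 - C|B|]
      m <- length(Fs)
      A <- rbind(cbind(K[Fs, Fs, drop = FALSE], -1),
                 c(rep(1, m), 0))
      b <- c(-K[Fs, Bs, drop = FALSE] %*% alpha[Bs], 1 - C * length(Bs))
      sol <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      alpha[Fs] <- sol[seq_len(m)]
      rho <- sol[m + 1]
      if (any(alpha[Fs] <= 1e-10) || any(alpha[Fs] >= C - 1e-10)) next
    } else {
      if (abs(C * length(Bs) - 1) > 1e-9) next
      rho <- NA  # any rho between group extremes; fix below
    }
    g <- as.numeric(K %*% alpha)
    if (is.na(rho)) rho <- (max(g[Bs]) + min(g[-Bs])) / 2
    zeros <- which(st == "zero")
    ok <- all(g[zeros] >= rho - 1e-8) && all(g[Bs] <= rho + 1e-8)
    if (!ok) next
    obj <- 0.5 * sum(alpha * g)
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(alpha = alpha, rho = rho, objective = obj)
    }
  }
  best
}

# Exact one-sided Mann-Whitney p-value by exhaustive enumeration of all
# C(n_a + n_b, n_a) group assignments (no ties assumed).
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  observed <- u_stat(a, b)
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(us >= observed - 1e-12)
}

# Random well-conditioned feature cohort for anomaly-model property tests.
random_features <- function(n, d, seed, spread = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * d, sd = spread), n, d)
}
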