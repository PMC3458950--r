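#' Radial basis function kernel
#'
#' k(u, v) = exp(-gamma ||u - v||^2), in (0, 1].
#'
#' @param u,v Numeric vectors of equal dimension.
#' @param gamma Positive kernel width.
#' @return Scalar kernel value.
#' @export
rbf_kernel <- function(u, v, gamma) {
  if (length(u) != length(v)) stop("rbf_kernel: dimension mismatch")
  stopifnot(gamma >= 0)
  exp(-gamma * sum((u - v)^2))
}

# Full RBF Gram matrix between the rows of X (and optionally Y).
rbf_gram <- function(X, Y = X, gamma) {
  sx <- rowSums(X^2)
  sy <- rowSums(Y^2)
  d2 <- outer(sx, sy, "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Default RBF kernel width
#'
#' The standard 1/d heuristic: with the default 125-frequency coherence
#' feature vector this gives gamma = 1/125. Recomputed from the current
#' feature dimension, so dropping a frequency during the relevance analysis
#' yields 1/124 (freeze it via the pipeline config if the fixed value is
#' wanted).
#'
#' @param d Feature dimension (>= 1).
#' @return 1/d.
#' @export
default_gamma <- function(d) {
  stopifnot(d >= 1)
  1 / d
}

#' Train a nu-parameterised one-class SVM
#'
#' Solves the standard one-class dual: minimise (1/2) a' K a subject to
#' 0 <= a_i <= 1/(nu n) and sum a_i = 1, with the RBF Gram matrix K. nu
#' upper-bounds the fraction of training points with a negative decision
#' score and lower-bounds the support-vector fraction. The solver is a
#' deterministic pairwise coordinate-descent (SMO-type) method with a fixed
#' duality tolerance; no randomness is involved, so no seed is needed.
#'
#' The offset rho is the median of the fitted scores sum_j a_j K_ij over the
#' margin support vectors (0 < a_i < 1/(nu n)), a numerically robust version
#' of the usual single-support-vector rule. The decision score of a point v
#' is f(v) = sum_i a_i k(x_i, v) - rho; f < 0 flags v as an outlier.
#'
#' @param features n x d numeric matrix, one training point per row.
#' @param nu Quantile parameter in (0, 1); study default 0.5.
#' @param gamma RBF width; default the 1/d heuristic.
#' @param tol Duality (KKT violation) tolerance.
#' @param max_iter Iteration cap.
#' @return An `ocsvm_model`: list with `alpha`, `rho`, `gamma`, `nu`, `X`
#'   (training matrix), `decision` (in-sample decision scores) and
#'   `n_support`.
#' @export
train_ocsvm <- function(features, nu = 0.5, gamma = default_gamma(ncol(features)),
                        tol = 1e-6, max_iter = 100000L) {
  X <- as.matrix(features)
  n <- nrow(X)
  stopifnot(n >= 2, nu > 0, nu < 1, all(is.finite(X)))
  K <- rbf_gram(X, gamma = gamma)
  C <- 1 / (nu * n)

  # Deterministic feasible start: fill the first floor(nu*n) coefficients to
  # the box bound, put the remainder on the next one (libsvm's convention).
  alpha <- numeric(n)
  nfull <- floor(nu * n)
  if (nfull > 0) alpha[seq_len(nfull)] <- C
  rest <- 1 - nfull * C
  if (rest > 1e-15) alpha[nfull + 1] <- rest
  g <- as.numeric(K %*% alpha)  # gradient of the dual objective

  eps_a <- 1e-12
  iter <- 0L
  repeat {
    iter <- iter + 1L
    up <- which(alpha < C - eps_a)     # can grow
    dn <- which(alpha > eps_a)         # can shrink
    i <- up[which.min(g[up])]
    j <- dn[which.max(g[dn])]
    gap <- g[j] - g[i]
    if (gap < tol) break
    if (iter > max_iter) {
      stop(sprintf("one-class SVM did not converge: KKT gap %.3g after %d iterations",
                   gap, max_iter))
    }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    delta <- if (eta > 1e-15) gap / eta else Inf
    delta <- min(delta, C - alpha[i], alpha[j])
    alpha[i] <- alpha[i] + delta
    alpha[j] <- alpha[j] - delta
    g <- g + delta * (K[, i] - K[, j])
  }

  margin <- which(alpha > eps_a & alpha < C - eps_a)
  rho <- if (length(margin) > 0) {
    stats::median(g[margin])
  } else {
    # no free SV: rho lies between the bound groups
    (max(g[alpha > eps_a]) + min(g[alpha < C - eps_a])) / 2
  }
  structure(list(alpha = alpha, rho = rho, gamma = gamma, nu = nu, X = X,
                 decision = g - rho,
                 n_support = sum(alpha > eps_a)),
            class = "ocsvm_model")
}

#' @export
print.ocsvm_model <- function(x, ...) {
  cat(sprintf("<ocsvm_model> n = %d, nu = %g, gamma = %g, support vectors = %d\n",
              nrow(x$X), x$nu, x$gamma, x$n_support))
  invisible(x)
}

#' Decision scores of a one-class SVM on new points
#'
#' @param model An `ocsvm_model`.
#' @param features Matrix (or vector) of points in the training dimension.
#' @return Numeric vector of decision scores f(v); negative flags an outlier.
#' @export
ocsvm_decision <- function(model, features) {
  V <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(V) != ncol(model$X)) {
    stop(sprintf("feature dimension %d does not match the model's %d",
                 ncol(V), ncol(model$X)))
  }
  as.numeric(rbf_gram(V, model$X, model$gamma) %*% model$alpha) - model$rho
}

#' Abnormality index of one or more subjects
#'
#' The negated one-class decision score, rho - sum_i a_i k(x_i, v): higher
#' values mean the subject's coherence profile is less typical of the pooled
#' training sample. Positive values correspond to points flagged outside the
#' learned normative region.
#'
#' @param model An `ocsvm_model`.
#' @param features Matrix (or single vector) of feature rows.
#' @return Numeric vector of abnormality indices.
#' @export
abnormality_index <- function(model, features) {
  -ocsvm_decision(model, features)
}

#' Mixed-group training protocol
#'
#' The two groups under comparison are pooled and treated as one population:
#' a single one-class SVM is trained on the concatenated feature matrix and
#' the in-sample abnormality index of every subject is returned with its
#' original group label. Pooling is the protocol's bias control — neither
#' group is privileged as the normative reference.
#'
#' @param features_g1,features_g2 Feature matrices (same number of columns);
#'   rownames are used as subject ids when present.
#' @param nu Quantile parameter (default 0.5).
#' @param gamma RBF width; default the 1/d heuristic on the pooled matrix.
#' @param groups Length-2 character vector of group labels, group 1 first
#'   (the case group by the pipeline's convention).
#' @return List with `results` (data frame: subject_id, group,
#'   abnormality_index) and `model` (the fitted `ocsvm_model`).
#' @export
mixed_group_protocol <- function(features_g1, features_g2, nu = 0.5,
                                 gamma = NULL, groups = c("g1", "g2")) {
  features_g1 <- as.matrix(features_g1)
  features_g2 <- as.matrix(features_g2)
  if (ncol(features_g1) != ncol(features_g2)) {
    stop("the two groups have different feature dimensions")
  }
  stopifnot(nrow(features_g1) >= 1, nrow(features_g2) >= 1)
  pooled <- rbind(features_g1, features_g2)
  if (is.null(gamma)) gamma <- default_gamma(ncol(pooled))
  model <- train_ocsvm(pooled, nu = nu, gamma = gamma)
  ids <- rownames(pooled)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(pooled)))
  results <- data.frame(
    subject_id = ids,
    group = rep(groups, c(nrow(features_g1), nrow(features_g2))),
    abnormality_index = abnormality_index(model, pooled),
    stringsAsFactors = FALSE
  )
  list(results = results, model = model)
}
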