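## Effective-information metrics for continuous (Gaussian-channel) neural
## dynamics, the exact discrete oracle, and mutual-information estimators.
##
## For a map mu: R^n -> R^m read as a conditional Gaussian
## Y ~ N(mu(X), diag(sigma^2)) with the intervention X ~ U([-L, L]^n), the
## effective information decomposes exactly as
##   EI = n ln(2L) + E ln|det J_mu(X)| - sum_i ln(sigma_i sqrt(2 pi e)),
## i.e. output entropy under the small-noise pushforward approximation
## minus the Gaussian conditional entropy. Only the Jacobian term is Monte
## Carlo; its standard error is reported.

#' Effective information of a continuous map
#'
#' Monte-Carlo estimate of the effective information of the Gaussian
#' channel \eqn{Y = \mu(X) + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \mathrm{diag}(\sigma^2))}, under the uniform
#' intervention \eqn{X \sim U([-L, L]^n)}.
#'
#' @param mu function mapping an n-vector to an m-vector.
#' @param sigmas m-vector of positive output SDs.
#' @param n input dimension.
#' @param L half-width of the intervention hypercube (default 1).
#' @param n_mc Monte-Carlo sample count (>= 100).
#' @param seed optional integer seed for the probe sample.
#' @param jacobian optional function returning the m x n Jacobian of
#'   \code{mu} at a point; when NULL a central-difference Jacobian is used.
#' @param det_tol absolute-determinant threshold below which a probe point
#'   counts as singular; if every probe point is singular the channel is
#'   degenerate and EI is reported as 0.
#' @return object of class \code{ei_estimate} with fields \code{value},
#'   \code{volume_term}, \code{jacobian_term}, \code{noise_term} (the
#'   decomposition is exact: value = volume + jacobian - noise),
#'   \code{se}, and \code{degenerate}.
#' @export
ei_continuous <- function(mu, sigmas, n, L = 1, n_mc = 1000L, seed = NULL,
                          jacobian = NULL, det_tol = 1e-12) {
  stopifnot(is.function(mu), n >= 1L, L > 0, n_mc >= 100L)
  sigmas <- as.numeric(sigmas)
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(jacobian)) jacobian <- function(x) numeric_jacobian(mu, x)
  m <- length(sigmas)
  X <- matrix(stats::runif(n_mc * n, -L, L), nrow = n_mc, ncol = n)
  ld <- numeric(n_mc)
  singular <- logical(n_mc)
  for (i in seq_len(n_mc)) {
    J <- jacobian(X[i, ])
    if (nrow(J) != m || ncol(J) != n)
      stop("jacobian must return an m x n matrix")
    ad <- if (nrow(J) == ncol(J)) {
      abs(det(J))
    } else {
      ## non-square channel: generalised determinant sqrt(det(J J^T))
      sqrt(max(det(J %*% t(J)), 0))
    }
    singular[i] <- ad < det_tol
    ld[i] <- log(max(ad, det_tol))
  }
  degenerate <- all(singular)
  volume_term <- n * log(2 * L)
  noise_term <- sum(log(sigmas * sqrt(2 * pi * exp(1))))
  jacobian_term <- mean(ld)
  se <- stats::sd(ld) / sqrt(n_mc)
  value <- if (degenerate) 0 else volume_term + jacobian_term - noise_term
  structure(list(value = value,
                 volume_term = volume_term,
                 jacobian_term = jacobian_term,
                 noise_term = noise_term,
                 se = se, n_mc = n_mc, L = L, n = n, m = m,
                 degenerate = degenerate),
            class = "ei_estimate")
}

#' @export
print.ei_estimate <- function(x, ...) {
  cat(sprintf(
    "EI = %.4f nats (SE %.4f)%s\n  = volume %.4f + Jacobian %.4f - noise %.4f\n",
    x$value, x$se, if (x$degenerate) " [degenerate]" else "",
    x$volume_term, x$jacobian_term, x$noise_term))
  invisible(x)
}

#' Dimension-averaged effective information
#'
#' Divides an EI estimate by the state dimension so that dynamics living in
#' spaces of different dimension become comparable.
#'
#' @param ei an \code{\link{ei_continuous}} estimate or a bare number of
#'   nats.
#' @param n state dimension (>= 1).
#' @return numeric nats per dimension, with attribute \code{"se"} when the
#'   input carries one.
#' @export
dEI <- function(ei, n) {
  if (n <= 0) stop("n must be >= 1")
  if (inherits(ei, "ei_estimate")) {
    out <- ei$value / n
    attr(out, "se") <- ei$se / n
    out
  } else {
    as.numeric(ei) / n
  }
}

#' Dimension-averaged causal emergence between two dynamics
#'
#' \eqn{dCE = dEI(f_M) - dEI(f_m)} for a macro-dynamics \eqn{f_M} in
#' \eqn{n_M} dimensions and a micro-dynamics \eqn{f_m} in \eqn{n_m}
#' dimensions, evaluated at the same hypercube half-width L. The
#' \eqn{\ln(2L)} terms cancel in the difference, so dCE is L-invariant up
#' to Monte-Carlo error.
#'
#' @param mu_M,mu_m the macro and micro maps.
#' @param sigmas_M,sigmas_m their output SD vectors.
#' @param n_M,n_m their state dimensions.
#' @param L hypercube half-width.
#' @param n_mc Monte-Carlo samples per map.
#' @param seed optional seed (split deterministically between the two
#'   estimates).
#' @param jacobian_M,jacobian_m optional analytic Jacobian functions.
#' @return object of class \code{dce_result} with \code{value}
#'   (= dEI_macro - dEI_micro exactly), both dEIs, dimensions, and a
#'   combined standard error.
#' @export
dce <- function(mu_M, sigmas_M, n_M, mu_m, sigmas_m, n_m,
                L = 1, n_mc = 1000L, seed = NULL,
                jacobian_M = NULL, jacobian_m = NULL) {
  ## common random numbers: both estimates share one probe seed, which pairs
  ## the Monte-Carlo noise (and makes dCE(f, f) exactly zero for matched
  ## dimensions)
  seed_M <- if (is.null(seed)) NULL else derive_seed(seed, "dce_probe")
  seed_m <- seed_M
  ei_M <- ei_continuous(mu_M, sigmas_M, n_M, L = L, n_mc = n_mc,
                        seed = seed_M, jacobian = jacobian_M)
  ei_m <- ei_continuous(mu_m, sigmas_m, n_m, L = L, n_mc = n_mc,
                        seed = seed_m, jacobian = jacobian_m)
  dei_M <- dEI(ei_M, n_M)
  dei_m <- dEI(ei_m, n_m)
  structure(list(value = as.numeric(dei_M) - as.numeric(dei_m),
                 dEI_macro = as.numeric(dei_M),
                 dEI_micro = as.numeric(dei_m),
                 n_macro = n_M, n_micro = n_m,
                 se = sqrt(attr(dei_M, "se")^2 + attr(dei_m, "se")^2),
                 ei_macro = ei_M, ei_micro = ei_m),
            class = "dce_result")
}

#' @export
print.dce_result <- function(x, ...) {
  cat(sprintf("dCE = %.4f nats/dim (SE %.4f): dEI macro %.4f (n=%d) - dEI micro %.4f (n=%d)\n",
              x$value, x$se, x$dEI_macro, x$n_macro, x$dEI_micro, x$n_micro))
  invisible(x)
}

#' Exact effective information of a discrete Markov kernel
#'
#' \eqn{EI = I(X; Y)} with \eqn{X} uniform over the N states and
#' \eqn{Y \sim P(\cdot | X)}; the exact discrete counterpart of
#' \code{\link{ei_continuous}}, used as an oracle for learned dynamics on
#' finite-state systems. Bounded by \eqn{0 \le EI \le \ln N}.
#'
#' @param P N x N row-stochastic matrix.
#' @return effective information in nats.
#' @export
ei_discrete <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("P must be square")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("P must be row-stochastic")
  N <- nrow(P)
  py <- colMeans(P)
  terms <- P * (log(pmax(P, .Machine$double.xmin)) -
                  rep(log(pmax(py, .Machine$double.xmin)), each = N))
  terms[P == 0] <- 0
  sum(terms) / N
}

#' Nonparametric mutual-information estimate
#'
#' Estimates I(X; Y) in nats. Method "knn" is the k-nearest-neighbour
#' (Kraskov) estimator with max-norm balls; a deterministic jitter of
#' relative scale 1e-10 breaks exact ties, which otherwise invalidate the
#' neighbour counts on discrete-valued or deterministic continuous data.
#' Method "discrete_plugin" bins exactly on distinct rows and computes the
#' plug-in MI of the empirical joint distribution.
#'
#' @param x,y numeric vectors or matrices with equal row counts.
#' @param method "knn" or "discrete_plugin".
#' @param k neighbour count for knn (default 5).
#' @return mutual information estimate in nats.
#' @export
mi_estimate <- function(x, y, method = c("knn", "discrete_plugin"), k = 5L) {
  method <- match.arg(method)
  x <- as_row_matrix(if (is.null(dim(x))) cbind(x) else x)
  y <- as_row_matrix(if (is.null(dim(y))) cbind(y) else y)
  if (nrow(x) != nrow(y)) stop("x and y need equal sample counts")
  n <- nrow(x)
  if (method == "discrete_plugin") {
    kx <- apply(x, 1L, paste, collapse = ",")
    ky <- apply(y, 1L, paste, collapse = ",")
    joint <- table(kx, ky) / n
    px <- rowSums(joint); py <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  } else {
    if (n < 50L) stop("knn estimator needs at least 50 samples")
    if (k >= n) stop("k must be smaller than the sample count")
    jitter_mat <- function(M, tag) {
      sc <- pmax(apply(M, 2L, stats::sd), 1)
      with_seed(derive_seed(20260911, tag), {
        M + matrix(stats::rnorm(length(M)), nrow(M)) *
          rep(sc * 1e-10, each = nrow(M))
      })
    }
    ksg_mi_cpp(jitter_mat(x, "mi_x"), jitter_mat(y, "mi_y"), as.integer(k))
  }
}

#' Split-based standard error of a mutual-information estimate
#'
#' Crude but serviceable uncertainty for \code{\link{mi_estimate}}:
#' deterministically partitions the sample into \code{n_blocks} interleaved
#' blocks, re-estimates MI on each, and returns the standard error of the
#' block mean. Captures sampling variability (not the estimator's
#' small-sample bias).
#'
#' @inheritParams mi_estimate
#' @param n_blocks number of disjoint blocks (default 8).
#' @return list with \code{value} (full-sample estimate), \code{se},
#'   and the per-block estimates.
#' @export
mi_with_se <- function(x, y, method = c("knn", "discrete_plugin"), k = 5L,
                       n_blocks = 8L) {
  method <- match.arg(method)
  x <- as_row_matrix(if (is.null(dim(x))) cbind(x) else x)
  y <- as_row_matrix(if (is.null(dim(y))) cbind(y) else y)
  n <- nrow(x)
  idx <- (seq_len(n) - 1L) %% n_blocks
  blocks <- vapply(seq_len(n_blocks) - 1L, function(b) {
    sel <- idx == b
    mi_estimate(x[sel, , drop = FALSE], y[sel, , drop = FALSE],
                method = method, k = k)
  }, numeric(1L))
  list(value = mi_estimate(x, y, method = method, k = k),
       se = stats::sd(blocks) / sqrt(n_blocks),
       blocks = blocks)
}
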