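## The full squeezer: bijector + projection encoder, residual macro
## dynamics, and the inverse bijector with Gaussian noise fill as decoder.

#' Construct a neural information squeezer model
#'
#' Composes an invertible bijector \eqn{\psi}, the projection onto the
#' first q coordinates, a residual macro-dynamics network
#' \eqn{y \mapsto y + f_\beta(y)}, and the decoder
#' \eqn{\psi^{-1}(y \oplus z)} with \eqn{z \sim N(0, I_{p-q})}. With q = p
#' the model degenerates to a pure bijector with full-dimensional dynamics
#' and no noise fill; that variant serves as the micro-dynamics reference
#' when measuring causal emergence.
#'
#' @param p micro dimension (>= 2).
#' @param q macro dimension, 1 <= q <= p (q < p for a genuine
#'   coarse-graining).
#' @param hidden hidden width of the coupling networks (default 64).
#' @param n_blocks number of coupling blocks (default 3).
#' @param dyn_hidden hidden widths of the dynamics network (default
#'   c(64, 64)).
#' @param noise_family macro-noise family, "gaussian" or "laplacian".
#' @param seed optional integer seed for initialisation.
#' @return object of class \code{nis_model}.
#' @export
nis_model <- function(p, q, hidden = 64L, n_blocks = 3L,
                      dyn_hidden = c(64L, 64L),
                      noise_family = c("gaussian", "laplacian"),
                      seed = NULL) {
  stopifnot(p >= 2L, q >= 1L, q <= p)
  noise_family <- match.arg(noise_family)
  if (!is.null(seed)) set.seed(seed)
  structure(list(
    p = p, q = q,
    bijector = bijector(p, n_blocks = n_blocks, hidden = hidden),
    dyn_net = mlp_init(c(q, dyn_hidden, q), zero_final = TRUE),
    sigma = rep(1, q),
    micro_sigma = rep(1, p),
    code_center = rep(0, q),
    code_scale = rep(1, q),
    noise_family = noise_family,
    trained = FALSE), class = "nis_model")
}

#' @export
print.nis_model <- function(x, ...) {
  cat("NIS model: p =", x$p, "-> q =", x$q,
      if (x$trained) "(trained)" else "(untrained)", "\n")
  cat("  macro-noise SDs:", signif(x$sigma, 3), "\n")
  invisible(x)
}

#' Project a bijected state onto the macro coordinates
#'
#' The information-discarding half of the encoder: keeps the first q
#' coordinates of \eqn{x' = \psi(x)}; the dropped \eqn{p - q} coordinates
#' are returned alongside for diagnostics.
#'
#' @param x_prime vector or matrix with p columns.
#' @param q number of leading coordinates to keep (1 <= q < p, or q = p for
#'   the degenerate full-dimensional case).
#' @return list with \code{y} (kept coordinates) and \code{discarded}.
#' @export
project_state <- function(x_prime, q) {
  x_prime <- as_row_matrix(x_prime)
  p <- ncol(x_prime)
  if (q < 1L || q > p) stop("q must satisfy 1 <= q <= p")
  list(y = x_prime[, seq_len(q), drop = FALSE],
       discarded = x_prime[, setdiff(seq_len(p), seq_len(q)), drop = FALSE])
}

#' Encode micro-states to macro-states
#'
#' \eqn{y = \chi_q(\psi(x))}: bijection followed by projection.
#' Deterministic.
#'
#' @param model a \code{nis_model}.
#' @param x vector of length p or matrix with p columns.
#' @return matrix of macro-states with q columns.
#' @export
nis_encode <- function(model, x) {
  h <- bijector_forward(model$bijector, x)$out
  project_state(h, model$q)$y
}

#' Decode macro-states back to micro-states
#'
#' \eqn{\hat x = \psi^{-1}(y \oplus z)} where the discarded dimensions are
#' filled with \eqn{z \sim N(0, I_{p-q})}, with \code{z} supplied
#' explicitly, or with zeros (the noise mean) in deterministic mode.
#'
#' @param model a \code{nis_model}.
#' @param y vector of length q or matrix with q columns.
#' @param z optional noise-fill matrix (rows matching y); when NULL it is
#'   sampled from the standard normal unless \code{deterministic}.
#' @param deterministic use z = 0, the canonical point estimate.
#' @return matrix of micro-states with p columns.
#' @export
nis_decode <- function(model, y, z = NULL, deterministic = FALSE) {
  y <- as_row_matrix(y, model$q)
  d <- model$p - model$q
  if (d > 0L) {
    if (is.null(z)) {
      z <- if (deterministic) matrix(0, nrow(y), d)
           else matrix(stats::rnorm(nrow(y) * d), nrow(y), d)
    } else {
      z <- as_row_matrix(z, d)
      if (nrow(z) != nrow(y)) stop("z must have one row per macro-state")
    }
    y <- cbind(y, z)
  }
  bijector_inverse(model$bijector, y)$out
}

#' One step of the learned macro-dynamics
#'
#' Returns the mean \eqn{\mu(y) = y + f_\beta(y)} of the one-step
#' transition kernel; with \code{stochastic = TRUE} adds noise from the
#' model's family with per-dimension scales matched to \code{model$sigma}.
#'
#' @param model a \code{nis_model}.
#' @param y vector of length q or matrix with q columns.
#' @param stochastic add transition noise.
#' @return matrix of next macro-states.
#' @export
nis_macro_step <- function(model, y, stochastic = FALSE) {
  y <- as_row_matrix(y, model$q)
  mu <- y + mlp_forward(model$dyn_net, y)
  if (stochastic) {
    n <- length(mu)
    noise <- if (model$noise_family == "gaussian") {
      stats::rnorm(n)
    } else {
      ## standard Laplace scaled to unit SD
      (stats::rexp(n) - stats::rexp(n)) / sqrt(2)
    }
    mu <- mu + matrix(noise, nrow(mu)) %*% diag(model$sigma, model$q)
  }
  mu
}

## Analytic Jacobian of the macro-step mean at a single point:
## I + J_{f_beta}(y); the ReLU dynamics net is piecewise linear.
macro_step_jacobian <- function(model, y) {
  diag(model$q) + mlp_jacobian(model$dyn_net, y)
}

#' Predict the next micro-state
#'
#' The full squeezer pass \eqn{\hat x_{t+1} =
#' \psi^{-1}(\chi_q^\dagger(\mu(\chi_q(\psi(x_t)))))}: encode, advance the
#' macro-dynamics mean, decode with noise fill.
#'
#' @param model a \code{nis_model}.
#' @param x vector of length p or matrix with p columns.
#' @param z optional explicit noise fill (see \code{\link{nis_decode}}).
#' @param deterministic use z = 0 and the dynamics mean (reproducible
#'   evaluation mode).
#' @param stochastic_macro also sample the macro transition noise.
#' @return matrix of predicted next micro-states (p columns).
#' @export
nis_predict <- function(model, x, z = NULL, deterministic = FALSE,
                        stochastic_macro = FALSE) {
  y <- nis_encode(model, x)
  y_next <- nis_macro_step(model, y, stochastic = stochastic_macro)
  nis_decode(model, y_next, z = z, deterministic = deterministic)
}

#' Fraction of epsilon-effective predictions
#'
#' Checks the effectiveness criterion on observed transitions: the fraction
#' of pairs whose decoded one-step prediction (deterministic mode, z = 0)
#' lies within \code{epsilon} of the observed next micro-state under the
#' chosen norm.
#'
#' @param model a \code{nis_model}.
#' @param data a \code{\link{transition_dataset}}.
#' @param epsilon positive tolerance.
#' @param norm "l2" (Euclidean) or "l1".
#' @return fraction in [0, 1].
#' @export
check_effectiveness <- function(model, data, epsilon, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  stopifnot(inherits(data, "transition_dataset"))
  if (epsilon <= 0) stop("epsilon must be positive")
  if (data$n < 1L) stop("empty dataset")
  x_hat <- nis_predict(model, data$x_t, deterministic = TRUE)
  r <- x_hat - data$x_next
  d <- if (norm == "l2") sqrt(rowSums(r^2)) else rowSums(abs(r))
  mean(d < epsilon)
}

nis_params <- function(model) {
  list(bij = bijector_params(model$bijector),
       dyn = mlp_params(model$dyn_net))
}

nis_set_params <- function(model, params) {
  model$bijector <- bijector_set_params(model$bijector, params$bij)
  model$dyn_net <- mlp_set_params(model$dyn_net, params$dyn)
  model
}
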