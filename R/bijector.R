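## Invertible bijector psi: R^p -> R^p built from affine coupling blocks.
##
## Each block splits the coordinates into a pass-through half `a` and a
## transformed half `b`; scale and translation of `b` are computed by small
## MLPs fed with `a`, so the map has a triangular Jacobian with closed-form
## log-determinant and an exact algebraic inverse. Masks alternate between
## consecutive blocks so every coordinate is transformed somewhere in the
## composition. The scale output is smoothly clamped to |s| <= s_cap for
## numerical stability; the clamp is the identity near 0, where training
## starts (zero-initialised final layers make the whole bijector start as
## the identity map).

#' Construct an affine-coupling bijector
#'
#' Builds an invertible map \eqn{\psi: R^p \to R^p} as a composition of
#' affine coupling blocks, each with one scale and one translation network
#' (feed-forward, ReLU, two hidden layers). The map starts as the exact
#' identity: final linear layers are zero-initialised.
#'
#' @param p dimension of the space (>= 2).
#' @param n_blocks number of coupling blocks (default 3).
#' @param hidden hidden-layer width of the scale/translation networks
#'   (default 64).
#' @param s_cap smooth clamp on the log-scale output; the effective
#'   log-scale is \code{s_cap * tanh(raw / s_cap)}.
#' @param seed optional integer seed for parameter initialisation.
#' @return an object of class \code{nisr_bijector}.
#' @export
bijector <- function(p, n_blocks = 3L, hidden = 64L, s_cap = 5, seed = NULL) {
  stopifnot(p >= 2L, n_blocks >= 1L, hidden >= 1L, s_cap > 0)
  if (!is.null(seed)) set.seed(seed)
  half <- ceiling(p / 2)
  blocks <- vector("list", n_blocks)
  for (k in seq_len(n_blocks)) {
    idx_a <- if (k %% 2L == 1L) seq_len(half) else seq.int(half + 1L, p)
    idx_b <- setdiff(seq_len(p), idx_a)
    la <- length(idx_a); lb <- length(idx_b)
    blocks[[k]] <- list(
      idx_a = idx_a, idx_b = idx_b,
      s_net = mlp_init(c(la, hidden, hidden, lb), zero_final = TRUE),
      t_net = mlp_init(c(la, hidden, hidden, lb), zero_final = TRUE))
  }
  structure(list(p = p, n_blocks = n_blocks, hidden = hidden,
                 s_cap = s_cap, blocks = blocks),
            class = "nisr_bijector")
}

#' Forward pass of the bijector
#'
#' Applies \eqn{\psi} to a batch of row vectors and returns the transformed
#' batch together with the analytic log-determinant of the Jacobian per
#' sample (sum of the effective log-scales over all blocks).
#'
#' @param bij a \code{nisr_bijector}.
#' @param X numeric vector of length p or matrix with p columns.
#' @param cache keep intermediates for the backward pass (internal).
#' @return list with \code{out} (matrix), \code{logdet} (vector), and, when
#'   requested, \code{cache}.
#' @export
bijector_forward <- function(bij, X, cache = FALSE) {
  X <- as_row_matrix(X, bij$p)
  logdet <- rep(0, nrow(X))
  caches <- if (cache) vector("list", bij$n_blocks) else NULL
  for (k in seq_len(bij$n_blocks)) {
    blk <- bij$blocks[[k]]
    A <- X[, blk$idx_a, drop = FALSE]
    B <- X[, blk$idx_b, drop = FALSE]
    sf <- mlp_forward(blk$s_net, A, cache = cache)
    tf <- mlp_forward(blk$t_net, A, cache = cache)
    s_raw <- if (cache) sf$out else sf
    t_out <- if (cache) tf$out else tf
    s <- bij$s_cap * tanh(s_raw / bij$s_cap)
    es <- exp(s)
    X[, blk$idx_b] <- B * es + t_out
    logdet <- logdet + rowSums(s)
    if (cache)
      caches[[k]] <- list(B = B, s = s, es = es,
                          scache = sf$cache, tcache = tf$cache)
  }
  out <- list(out = X, logdet = logdet)
  if (cache) out$cache <- caches
  out
}

#' Exact inverse of the bijector
#'
#' Algebraic inverse of \code{\link{bijector_forward}} (no iterative solve):
#' blocks are undone in reverse order, each by
#' \eqn{b = (b' - t(a)) e^{-s(a)}}.
#'
#' @inheritParams bijector_forward
#' @param Y numeric vector of length p or matrix with p columns.
#' @return list with \code{out} and, when requested, \code{cache}.
#' @export
bijector_inverse <- function(bij, Y, cache = FALSE) {
  Y <- as_row_matrix(Y, bij$p)
  caches <- if (cache) vector("list", bij$n_blocks) else NULL
  for (k in rev(seq_len(bij$n_blocks))) {
    blk <- bij$blocks[[k]]
    A <- Y[, blk$idx_a, drop = FALSE]
    B2 <- Y[, blk$idx_b, drop = FALSE]
    sf <- mlp_forward(blk$s_net, A, cache = cache)
    tf <- mlp_forward(blk$t_net, A, cache = cache)
    s_raw <- if (cache) sf$out else sf
    t_out <- if (cache) tf$out else tf
    s <- bij$s_cap * tanh(s_raw / bij$s_cap)
    ens <- exp(-s)
    B <- (B2 - t_out) * ens
    Y[, blk$idx_b] <- B
    if (cache)
      caches[[k]] <- list(B = B, s = s, ens = ens,
                          scache = sf$cache, tcache = tf$cache)
  }
  out <- list(out = Y)
  if (cache) out$cache <- caches
  out
}

## Backward pass through the forward direction. G is the upstream gradient
## w.r.t. the output batch; Gld (optional) the gradient w.r.t. the per-sample
## logdet. Returns gradient w.r.t. the input and per-block parameter grads.
bijector_forward_vjp <- function(bij, caches, G, Gld = NULL) {
  grads <- vector("list", bij$n_blocks)
  for (k in rev(seq_len(bij$n_blocks))) {
    blk <- bij$blocks[[k]]
    cc <- caches[[k]]
    gB2 <- G[, blk$idx_b, drop = FALSE]
    gB <- gB2 * cc$es
    gs <- gB2 * cc$B * cc$es
    if (!is.null(Gld)) gs <- gs + Gld
    gs_raw <- gs * (1 - (cc$s / bij$s_cap)^2)
    sv <- mlp_vjp(blk$s_net, cc$scache, gs_raw)
    tv <- mlp_vjp(blk$t_net, cc$tcache, gB2)
    G[, blk$idx_a] <- G[, blk$idx_a, drop = FALSE] + sv$gX + tv$gX
    G[, blk$idx_b] <- gB
    grads[[k]] <- list(s = sv$grads, t = tv$grads)
  }
  list(gX = G, grads = grads)
}

## Backward pass through the inverse direction (inverse applies blocks
## n..1, so its reverse sweep runs 1..n).
bijector_inverse_vjp <- function(bij, caches, G) {
  grads <- vector("list", bij$n_blocks)
  for (k in seq_len(bij$n_blocks)) {
    blk <- bij$blocks[[k]]
    cc <- caches[[k]]
    gB <- G[, blk$idx_b, drop = FALSE]
    gB2 <- gB * cc$ens
    gt <- -gB2
    gs <- -gB * cc$B
    gs_raw <- gs * (1 - (cc$s / bij$s_cap)^2)
    sv <- mlp_vjp(blk$s_net, cc$scache, gs_raw)
    tv <- mlp_vjp(blk$t_net, cc$tcache, gt)
    G[, blk$idx_a] <- G[, blk$idx_a, drop = FALSE] + sv$gX + tv$gX
    G[, blk$idx_b] <- gB2
    grads[[k]] <- list(s = sv$grads, t = tv$grads)
  }
  list(gX = G, grads = grads)
}

#' Brute-force log-determinant oracle
#'
#' Computes \eqn{\log|\det J_\psi(x)|} from the full \eqn{p \times p}
#' Jacobian obtained by central finite differences, independently of the
#' analytic per-block accumulation in \code{\link{bijector_forward}}. Test
#' oracle only; refuses p > 16.
#'
#' @param bij a \code{nisr_bijector}.
#' @param x a single p-vector.
#' @param h finite-difference step.
#' @return scalar log-absolute-determinant.
#' @export
logdet_bruteforce <- function(bij, x, h = 1e-5) {
  if (bij$p > 16L) stop("brute-force Jacobian oracle limited to p <= 16")
  f <- function(v) bijector_forward(bij, v)$out[1L, ]
  J <- numeric_jacobian(f, x, h = h)
  as.numeric(determinant(J, logarithm = TRUE)$modulus)
}

bijector_params <- function(bij) {
  lapply(bij$blocks, function(blk)
    list(s = mlp_params(blk$s_net), t = mlp_params(blk$t_net)))
}

bijector_set_params <- function(bij, params) {
  for (k in seq_len(bij$n_blocks)) {
    bij$blocks[[k]]$s_net <- mlp_set_params(bij$blocks[[k]]$s_net,
                                            params[[k]]$s)
    bij$blocks[[k]]$t_net <- mlp_set_params(bij$blocks[[k]]$t_net,
                                            params[[k]]$t)
  }
  bij
}

#' @export
print.nisr_bijector <- function(x, ...) {
  cat("Affine-coupling bijector: p =", x$p, ", blocks =", x$n_blocks,
      ", hidden =", x$hidden, "\n")
  invisible(x)
}
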