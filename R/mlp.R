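## Minimal dense feed-forward networks with explicit reverse-mode gradients.
## Everything downstream (coupling blocks, dynamics learner) is built from
## these three functions, so gradient correctness is tested by finite
## differences in the suite.

## He-initialised MLP; sizes = c(d_in, hidden..., d_out). The final linear
## layer can be zero-initialised so a fresh network computes the zero map
## (used to start the bijector at the identity and the dynamics at rest).
mlp_init <- function(sizes, zero_final = FALSE) {
  L <- length(sizes) - 1L
  stopifnot(L >= 1L)
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    sd <- sqrt(2 / fan_in)
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sd),
                     nrow = fan_in, ncol = sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  if (zero_final) W[[L]] <- W[[L]] * 0
  structure(list(W = W, b = b, sizes = sizes), class = "nisr_mlp")
}

## Forward pass on a batch (rows = samples). ReLU on hidden layers, linear
## output. With cache = TRUE also returns per-layer inputs and ReLU masks
## for the backward pass.
mlp_forward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  A <- X
  acts <- if (cache) vector("list", L) else NULL
  masks <- if (cache) vector("list", L - 1L) else NULL
  for (l in seq_len(L)) {
    if (cache) acts[[l]] <- A
    Z <- A %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], `+`)
    if (l < L) {
      M <- Z > 0
      Z <- Z * M
      if (cache) masks[[l]] <- M
    }
    A <- Z
  }
  if (cache) list(out = A, cache = list(acts = acts, masks = masks)) else A
}

## Vector-Jacobian product: given upstream gradient G (batch x d_out),
## returns the gradient w.r.t. the input batch and parameter gradients.
mlp_vjp <- function(net, cache, G) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$acts[[l]], G)
    gb[[l]] <- colSums(G)
    G <- tcrossprod(G, net$W[[l]])
    if (l > 1L) G <- G * cache$masks[[l - 1L]]
  }
  list(gX = G, grads = list(W = gW, b = gb))
}

## Analytic Jacobian d out / d in at a single point x (d_out x d_in),
## exploiting that a ReLU network is piecewise linear.
mlp_jacobian <- function(net, x) {
  L <- length(net$W)
  a <- matrix(as.numeric(x), nrow = 1L)
  J <- t(net$W[[1L]])
  z <- a %*% net$W[[1L]]
  z <- sweep(z, 2L, net$b[[1L]], `+`)
  for (l in seq_len(L - 1L)) {
    m <- as.numeric(z > 0)
    a <- z * (z > 0)
    J <- t(net$W[[l + 1L]]) %*% (m * J)
    z <- a %*% net$W[[l + 1L]]
    z <- sweep(z, 2L, net$b[[l + 1L]], `+`)
  }
  J
}

mlp_params <- function(net) list(W = net$W, b = net$b)

mlp_set_params <- function(net, params) {
  net$W <- params$W
  net$b <- params$b
  net
}
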