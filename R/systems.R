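## Benchmark simulators. Each emits a TransitionDataset: a batch of
## independent one-step micro-state transitions (x_t, x_next), which is all
## the training loss consumes.

#' Transition dataset
#'
#' Container for paired micro-state transitions \eqn{(x_t, x_{t+1})}.
#'
#' @param x_t,x_next numeric matrices, N rows by p columns, identical shape.
#' @param system_name label of the generating system.
#' @param seed integer seed used by the generator (NA for imported data).
#' @param meta list of generator parameters.
#' @return object of class \code{transition_dataset}.
#' @export
transition_dataset <- function(x_t, x_next, system_name = "unknown",
                               seed = NA_integer_, meta = list()) {
  x_t <- as.matrix(x_t)
  x_next <- as.matrix(x_next)
  if (!identical(dim(x_t), dim(x_next)))
    stop("x_t and x_next must have identical shape")
  if (ncol(x_t) < 2L) stop("micro dimension p must be >= 2")
  if (nrow(x_t) < 1L) stop("need at least one transition pair")
  if (!all(is.finite(x_t)) || !all(is.finite(x_next)))
    stop("non-finite values in dataset")
  structure(list(x_t = unname(x_t), x_next = unname(x_next),
                 p = ncol(x_t), n = nrow(x_t),
                 system_name = system_name, seed = seed, meta = meta),
            class = "transition_dataset")
}

#' @export
print.transition_dataset <- function(x, ...) {
  cat("Transition dataset '", x$system_name, "': ", x$n, " pairs, p = ",
      x$p, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate the noisy two-sensor spring oscillator
#'
#' Latent state \eqn{x = (z, v)} follows \eqn{dz/dt = v}, \eqn{dv/dt = -z},
#' advanced by one explicit Euler step of size \code{dt}. The micro-state is
#' the concatenation of two sensors reading the same latent state with a
#' shared Gaussian error of opposite sign,
#' \eqn{\tilde x_1 = x + \zeta}, \eqn{\tilde x_2 = x - \zeta},
#' \eqn{\zeta \sim N(0, \mathrm{diag}(noise\_sd^2))}, drawn fresh at every
#' observation time. The noise therefore cancels exactly in
#' \eqn{\tilde x_1 + \tilde x_2 = 2x}: the 4-dimensional micro description
#' hides a clean 2-dimensional macro state.
#'
#' @param n_pairs number of one-step transition pairs.
#' @param dt Euler step (default 0.1).
#' @param noise_sd length-2 vector of measurement SDs for (z, v).
#' @param seed integer seed.
#' @param init_range half-width of the uniform box the initial latent
#'   states are drawn from (default 2).
#' @return \code{transition_dataset} with p = 4, columns
#'   \eqn{(\tilde z_1, \tilde v_1, \tilde z_2, \tilde v_2)}.
#' @export
simulate_spring <- function(n_pairs, dt = 0.1, noise_sd = c(0.1, 0.1),
                            seed = 0L, init_range = 2) {
  stopifnot(n_pairs >= 1L)
  if (dt <= 0) stop("dt must be positive")
  noise_sd <- rep_len(as.numeric(noise_sd), 2L)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  set.seed(seed)
  z <- stats::runif(n_pairs, -init_range, init_range)
  v <- stats::runif(n_pairs, -init_range, init_range)
  z1 <- z + v * dt
  v1 <- v - z * dt
  observe <- function(z, v) {
    zeta_z <- stats::rnorm(length(z), sd = noise_sd[1L])
    zeta_v <- stats::rnorm(length(v), sd = noise_sd[2L])
    cbind(z + zeta_z, v + zeta_v, z - zeta_z, v - zeta_v)
  }
  transition_dataset(observe(z, v), observe(z1, v1),
                     system_name = "spring", seed = as.integer(seed),
                     meta = list(dt = dt, noise_sd = noise_sd,
                                 init_range = init_range,
                                 latent_t = unname(cbind(z, v)),
                                 latent_next = unname(cbind(z1, v1))))
}

#' Transition matrix of the 8-state benchmark Markov chain
#'
#' Seven states communicate uniformly (each row 1/7 over states 1..7, zero
#' into state 8); the eighth state is absorbing and standalone.
#'
#' @return an 8 x 8 row-stochastic matrix.
#' @export
markov_transition_matrix <- function() {
  P <- matrix(0, 8L, 8L)
  P[1:7, 1:7] <- 1 / 7
  P[8L, 8L] <- 1
  P
}

#' Simulate one-hot transitions from the 8-state Markov chain
#'
#' Initial states are uniform over the 8 states; one transition per pair is
#' sampled from \code{\link{markov_transition_matrix}}. States are one-hot
#' encoded (state 2 becomes (0,1,0,0,0,0,0,0)).
#'
#' @param n_pairs number of transition pairs.
#' @param seed integer seed.
#' @return \code{transition_dataset} with p = 8 and binary entries.
#' @export
simulate_markov <- function(n_pairs, seed = 0L) {
  stopifnot(n_pairs >= 1L)
  set.seed(seed)
  P <- markov_transition_matrix()
  s0 <- sample.int(8L, n_pairs, replace = TRUE)
  s1 <- vapply(s0, function(s) sample.int(8L, 1L, prob = P[s, ]), integer(1L))
  onehot <- function(s) {
    M <- matrix(0, length(s), 8L)
    M[cbind(seq_along(s), s)] <- 1
    M
  }
  transition_dataset(onehot(s0), onehot(s1),
                     system_name = "markov", seed = as.integer(seed),
                     meta = list(states_t = s0, states_next = s1))
}

#' Probabilistic Boolean network mechanism
#'
#' Four nodes (A, B, C, D); every node has exactly two parents and updates
#' independently given the current global state. \code{table} gives, per
#' node and per parent configuration (00, 01, 10, 11), the probability that
#' the node takes value 0 at the next step.
#'
#' The default wiring is the classic cross-coupled topology (A and B read C
#' and D; C and D read A and B). Only one table entry of the reference
#' mechanism is fixed by the benchmark (a node is 0 with probability 0.7
#' when its parents are 00); the default completes it symmetrically: 0.7
#' unless both parents are 1, in which case the complementary 0.3. Under
#' this mechanism a node's future depends on its parents only through the
#' indicator "both parents on", so the 16 micro-states collapse to 4
#' effective macro-states.
#'
#' @param adjacency list of 4 integer pairs: each node's parent indices.
#' @param table 4 x 4 numeric matrix, rows = nodes, columns = parent states
#'   c("00","01","10","11"), entries = P(node = 0 | parents).
#' @return object of class \code{boolean_mechanism}.
#' @export
boolean_mechanism <- function(adjacency = list(c(3L, 4L), c(3L, 4L),
                                               c(1L, 2L), c(1L, 2L)),
                              table = NULL) {
  if (is.null(table))
    table <- matrix(c(0.7, 0.7, 0.7, 0.3), nrow = 4L, ncol = 4L,
                    byrow = TRUE)
  table <- as.matrix(table)
  if (!identical(dim(table), c(4L, 4L)))
    stop("table must be 4 x 4 (nodes x parent states 00,01,10,11)")
  if (any(table < 0 | table > 1)) stop("probabilities must lie in [0, 1]")
  if (length(adjacency) != 4L ||
      !all(vapply(adjacency, length, integer(1L)) == 2L))
    stop("each of the 4 nodes needs exactly 2 parents")
  structure(list(adjacency = adjacency, table = table),
            class = "boolean_mechanism")
}

## Integer 0..15 -> 4-bit row (node 1 is the most significant bit).
bits4 <- function(s) {
  t(vapply(s, function(x) as.integer(intToBits(x)[4:1]), integer(4L)))
}

#' Exact 16-state transition matrix of a Boolean network mechanism
#'
#' Nodes update independently given the current global state, so entry
#' (s, s') is the product over nodes of the node-level conditional
#' probability of its bit in s' given its parents' bits in s.
#'
#' @param mech a \code{\link{boolean_mechanism}}.
#' @return a 16 x 16 row-stochastic matrix; rows index the current state
#'   (decimal coding of the 4 bits, 0..15, +1), columns the next state.
#' @export
build_boolean_transition_matrix <- function(mech) {
  stopifnot(inherits(mech, "boolean_mechanism"))
  states <- bits4(0:15)
  P <- matrix(0, 16L, 16L)
  for (i in 1:16) {
    cur <- states[i, ]
    p0 <- numeric(4L)
    for (node in 1:4) {
      pa <- mech$adjacency[[node]]
      cfg <- cur[pa[1L]] * 2L + cur[pa[2L]] + 1L  # 00,01,10,11 -> 1..4
      p0[node] <- mech$table[node, cfg]
    }
    for (j in 1:16) {
      nxt <- states[j, ]
      P[i, j] <- prod(ifelse(nxt == 0L, p0, 1 - p0))
    }
  }
  P
}

#' Simulate 4-bit transitions of the probabilistic Boolean network
#'
#' Initial 4-bit states are uniform over the 16 configurations; one-step
#' transitions are sampled from the exact matrix of
#' \code{\link{build_boolean_transition_matrix}}. Micro-states are emitted
#' as 4-dimensional 0/1 vectors.
#'
#' @param n_pairs number of transition pairs.
#' @param mech a \code{\link{boolean_mechanism}} (default mechanism if
#'   omitted).
#' @param seed integer seed.
#' @return \code{transition_dataset} with p = 4 and binary entries.
#' @export
simulate_boolean <- function(n_pairs, mech = boolean_mechanism(), seed = 0L) {
  stopifnot(n_pairs >= 1L)
  P <- build_boolean_transition_matrix(mech)
  set.seed(seed)
  s0 <- sample.int(16L, n_pairs, replace = TRUE)
  s1 <- vapply(s0, function(s) sample.int(16L, 1L, prob = P[s, ]),
               integer(1L))
  transition_dataset(bits4(s0 - 1L), bits4(s1 - 1L),
                     system_name = "boolean", seed = as.integer(seed),
                     meta = list(states_t = s0, states_next = s1))
}
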