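## Shared fixtures: small randomised bijectors/models built in code.

## Move a freshly initialised (identity) bijector or model away from the
## identity by perturbing every parameter.
perturb_params <- function(params, sd = 0.1, seed = 1L) {
  set.seed(seed)
  nisr:::tree_map(function(a)
    a + matrix(stats::rnorm(length(a), sd = sd), nrow = NROW(a)), params)
}

random_bijector <- function(p, hidden = 16L, n_blocks = 3L, sd = 0.1,
                            seed = 1L) {
  bij <- bijector(p, n_blocks = n_blocks, hidden = hidden,
                  seed = derive_seed_t(seed, "bij"))
  nisr:::bijector_set_params(bij,
                             perturb_params(nisr:::bijector_params(bij),
                                            sd = sd, seed = seed))
}

random_model <- function(p, q, hidden = 16L, sd = 0.1, seed = 1L) {
  m <- nis_model(p, q, hidden = hidden, dyn_hidden = c(16L, 16L),
                 seed = derive_seed_t(seed, "model"))
  nisr:::nis_set_params(m, perturb_params(nisr:::nis_params(m), sd = sd,
                                          seed = seed + 1L))
}

derive_seed_t <- function(seed, tag) nisr:::derive_seed(seed, tag)

## A tiny static dataset (x_next = x_t) for fixed-point training checks.
static_dataset <- function(n = 200L, p = 4L, seed = 2L) {
  set.seed(seed)
  X <- matrix(stats::runif(n * p, -1, 1), n, p)
  transition_dataset(X, X, system_name = "static", seed = seed)
}
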