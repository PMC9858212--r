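## Stage 1: likelihood training of a fixed-q squeezer (the l-norm
## prediction loss is the Gaussian/Laplacian negative log-likelihood up to
## constants). Stage 2: scan q, score every scale by dimension-averaged
## causal emergence against a full-dimensional reference model.

#' Training configuration
#'
#' @param q macro dimension.
#' @param l_norm 1 (Laplacian likelihood) or 2 (Gaussian likelihood).
#' @param epochs number of minibatch gradient steps.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param lr_decay total multiplicative learning-rate decay over the run
#'   (exponential schedule; 1 = constant, 0.1 = final rate is a tenth of
#'   the initial one).
#' @param seed integer master seed; initialisation, the train/validation
#'   split, minibatch order and decoder noise all draw named substreams
#'   from it.
#' @param val_fraction fraction of pairs held out for validation (in
#'   (0, 1)).
#' @param L hypercube half-width used when measuring effective information.
#' @param n_mc Monte-Carlo samples for the EI Jacobian term.
#' @param hidden coupling-network hidden width.
#' @param n_blocks coupling blocks in the bijector.
#' @param dyn_hidden dynamics-network hidden widths.
#' @param noise_family "gaussian" or "laplacian" macro noise.
#' @param sigma_floor lower bound for estimated noise SDs (guards the
#'   log-sigma term of EI against degenerate zero-residual fits).
#' @param eval_every validation-loss cadence, in steps.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(q, l_norm = 2L, epochs = 1000L, batch_size = 64L,
                         learning_rate = 1e-4, lr_decay = 1, seed = 0L,
                         val_fraction = 0.2, L = 1, n_mc = 1000L,
                         hidden = 64L, n_blocks = 3L,
                         dyn_hidden = c(64L, 64L),
                         noise_family = "gaussian",
                         sigma_floor = 1e-6, eval_every = 50L) {
  if (!l_norm %in% c(1L, 2L)) stop("l_norm must be 1 or 2")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must lie in (0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must lie in (0, 1]")
  structure(list(q = as.integer(q), l_norm = as.integer(l_norm),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 seed = as.integer(seed),
                 val_fraction = val_fraction, L = L,
                 n_mc = as.integer(n_mc), hidden = as.integer(hidden),
                 n_blocks = as.integer(n_blocks),
                 dyn_hidden = as.integer(dyn_hidden),
                 noise_family = noise_family,
                 sigma_floor = sigma_floor,
                 eval_every = as.integer(eval_every)),
            class = "train_config")
}

#' Prediction loss
#'
#' Mean over the batch of the l-norm of the micro-prediction residual;
#' l = 2 is the Gaussian negative log-likelihood up to constants, l = 1
#' the Laplacian one.
#'
#' @param x_hat,x matrices of identical shape (predictions, targets).
#' @param l 1 or 2.
#' @return scalar loss.
#' @export
nis_loss <- function(x_hat, x, l = 2L) {
  if (!identical(dim(as.matrix(x_hat)), dim(as.matrix(x))))
    stop("shape mismatch between predictions and targets")
  r <- as.matrix(x_hat) - as.matrix(x)
  if (l == 2L) mean(sqrt(rowSums(r^2)))
  else if (l == 1L) mean(rowSums(abs(r)))
  else stop("l must be 1 or 2")
}

## One full forward/backward pass through the squeezer graph on a
## minibatch. z is the decoder noise fill for this pass (may be zeros).
## Returns the loss and parameter gradients congruent with nis_params().
nis_grad_step <- function(model, xb, xnb, l_norm = 2L, z = NULL) {
  q <- model$q; p <- model$p
  nb <- nrow(xb)
  fwd <- bijector_forward(model$bijector, xb, cache = TRUE)
  y <- fwd$out[, seq_len(q), drop = FALSE]
  dyn <- mlp_forward(model$dyn_net, y, cache = TRUE)
  y_next <- y + dyn$out
  h2 <- if (q < p) {
    if (is.null(z)) z <- matrix(stats::rnorm(nb * (p - q)), nb, p - q)
    cbind(y_next, z)
  } else y_next
  inv <- bijector_inverse(model$bijector, h2, cache = TRUE)
  r <- inv$out - xnb
  if (l_norm == 2L) {
    rn <- sqrt(rowSums(r^2) + 1e-12)
    loss <- mean(rn)
    g_xhat <- r / (nb * rn)
  } else {
    loss <- mean(rowSums(abs(r)))
    g_xhat <- sign(r) / nb
  }
  vinv <- bijector_inverse_vjp(model$bijector, inv$cache, g_xhat)
  g_y_next <- vinv$gX[, seq_len(q), drop = FALSE]
  vdyn <- mlp_vjp(model$dyn_net, dyn$cache, g_y_next)
  g_y <- g_y_next + vdyn$gX
  gH <- matrix(0, nb, p)
  gH[, seq_len(q)] <- g_y
  vfwd <- bijector_forward_vjp(model$bijector, fwd$cache, gH)
  list(loss = loss,
       grads = list(bij = tree_add(vinv$grads, vfwd$grads),
                    dyn = vdyn$grads))
}

#' Train a fixed-q squeezer by likelihood maximisation
#'
#' Minimises the l-norm micro-prediction loss with Adam on minibatches.
#' The decoder noise fill is sampled fresh at every step (training mode);
#' validation losses are computed in deterministic mode (z = 0). After
#' training, the macro-noise SDs \code{sigma} are set to the per-dimension
#' RMSE of the one-step macro residual on the validation split, and
#' \code{micro_sigma} to the per-dimension RMSE of the deterministic micro
#' prediction; both are floored at \code{config$sigma_floor}.
#'
#' @param data a \code{\link{transition_dataset}}.
#' @param config a \code{\link{train_config}} with \code{config$q <= data$p}.
#' @return list with \code{model} (trained \code{nis_model}) and
#'   \code{history} (data.frame of per-step training loss and periodic
#'   validation loss).
#' @export
train_stage1 <- function(data, config) {
  stopifnot(inherits(data, "transition_dataset"),
            inherits(config, "train_config"))
  p <- data$p
  if (config$q > p) stop("config$q must be <= data$p")
  set.seed(derive_seed(config$seed, "init"))
  model <- nis_model(p, config$q, hidden = config$hidden,
                     n_blocks = config$n_blocks,
                     dyn_hidden = config$dyn_hidden,
                     noise_family = config$noise_family)
  set.seed(derive_seed(config$seed, "split"))
  perm <- sample.int(data$n)
  n_val <- max(1L, floor(config$val_fraction * data$n))
  val_idx <- perm[seq_len(n_val)]
  train_idx <- perm[-seq_len(n_val)]
  if (length(train_idx) < 1L) stop("no training data after validation split")
  xt_tr <- data$x_t[train_idx, , drop = FALSE]
  xn_tr <- data$x_next[train_idx, , drop = FALSE]
  xt_val <- data$x_t[val_idx, , drop = FALSE]
  xn_val <- data$x_next[val_idx, , drop = FALSE]

  params <- nis_params(model)
  opt <- adam_init(params, lr = config$learning_rate)
  set.seed(derive_seed(config$seed, "steps"))
  n_tr <- length(train_idx)
  bs <- min(config$batch_size, n_tr)
  hist_step <- integer(config$epochs)
  hist_train <- numeric(config$epochs)
  hist_val <- rep(NA_real_, config$epochs)
  val_loss <- function(m) nis_loss(nis_predict(m, xt_val,
                                               deterministic = TRUE),
                                   xn_val, l = config$l_norm)
  for (step in seq_len(config$epochs)) {
    idx <- sample.int(n_tr, bs)
    gs <- nis_grad_step(model, xt_tr[idx, , drop = FALSE],
                        xn_tr[idx, , drop = FALSE],
                        l_norm = config$l_norm)
    if (!is.finite(gs$loss))
      stop("training loss became non-finite at step ", step,
           "; try a smaller learning_rate")
    if (config$lr_decay < 1 && config$epochs > 1L)
      opt$lr <- config$learning_rate *
        config$lr_decay^((step - 1) / (config$epochs - 1))
    upd <- adam_step(opt, params, gs$grads)
    opt <- upd$state
    params <- upd$params
    model <- nis_set_params(model, params)
    hist_step[step] <- step
    hist_train[step] <- gs$loss
    if (step %% config$eval_every == 0L || step == config$epochs)
      hist_val[step] <- val_loss(model)
  }

  ## noise scales from validation residuals
  y_val <- nis_encode(model, xt_val)
  mu_val <- nis_macro_step(model, y_val)
  y_obs <- nis_encode(model, xn_val)
  model$sigma <- pmax(sqrt(colMeans((y_obs - mu_val)^2)),
                      config$sigma_floor)
  ## empirical code moments: the gauge in which effective information is
  ## measured (the macro coordinates are only defined up to an affine
  ## transformation the architecture never pins down)
  model$code_center <- colMeans(y_val)
  model$code_scale <- pmax(apply(y_val, 2L, stats::sd), config$sigma_floor)
  x_hat_val <- nis_decode(model, mu_val, deterministic = TRUE)
  model$micro_sigma <- pmax(sqrt(colMeans((x_hat_val - xn_val)^2)),
                            config$sigma_floor)
  model$trained <- TRUE
  list(model = model,
       history = data.frame(epoch = hist_step, train_loss = hist_train,
                            val_loss = hist_val))
}

## dEI of a model's learned macro-dynamics mean, using the analytic
## piecewise-linear Jacobian I + J_f. Measured in the standardised code
## gauge: the dynamics is conjugated by the affine map fixed by the
## empirical code mean/SD, so the probe hypercube covers the region the
## learned codes actually occupy and the noise scales are relative to the
## code spread. The conjugation leaves det(J) pointwise unchanged; it only
## picks the coordinates (a gauge the architecture does not fix).
model_dEI <- function(model, L = 1, n_mc = 1000L, seed = NULL) {
  ctr <- if (is.null(model$code_center)) rep(0, model$q)
         else model$code_center
  scl <- if (is.null(model$code_scale)) rep(1, model$q)
         else model$code_scale
  to_y <- function(yt) sweep(sweep(as_row_matrix(yt, model$q), 2L, scl,
                                   `*`), 2L, ctr, `+`)
  ei <- ei_continuous(
    mu = function(yt) {
      y <- to_y(yt)
      as.numeric(sweep(sweep(nis_macro_step(model, y), 2L, ctr, `-`),
                       2L, scl, `/`))
    },
    sigmas = model$sigma / scl, n = model$q, L = L, n_mc = n_mc,
    seed = seed,
    jacobian = function(yt) {
      J <- macro_step_jacobian(model, as.numeric(to_y(yt)))
      diag(1 / scl, model$q) %*% J %*% diag(scl, model$q)
    })
  out <- dEI(ei, model$q)
  attr(out, "ei") <- ei
  out
}

#' Scan the macro dimension for causal emergence
#'
#' Trains a squeezer from scratch for every \eqn{q \in \{1, ..., p-1\}}
#' (plus a full-dimensional q = p reference model acting as the
#' micro-dynamics), measures the dimension-averaged effective information
#' of each learned macro-dynamics, and reports
#' \eqn{dCE(q) = dEI(q) - dEI(micro)}. The selected scale \code{q_star}
#' maximises dCE; ties break toward the smaller (coarser) q.
#'
#' @param data a \code{\link{transition_dataset}}.
#' @param base_config a \code{\link{train_config}}; its \code{q} is
#'   ignored, everything else (seed policy included) is applied to every
#'   scale identically.
#' @param qs macro dimensions to scan (default 1..p-1).
#' @param epsilon tolerance for the reported effectiveness fraction.
#' @param keep_models also return the trained models (memory permitting).
#' @param ref_epochs optional distinct epoch budget for the reference
#'   model.
#' @return object of class \code{scan_report}: \code{per_q} data.frame
#'   (q, train_loss, val_loss, dEI, dCE, effectiveness, error), the
#'   selected \code{q_star}, the reference model's \code{dEI_micro}, and
#'   optionally \code{models}.
#' @export
scan_q <- function(data, base_config, qs = NULL, epsilon = 0.1,
                   keep_models = FALSE, ref_epochs = NULL) {
  stopifnot(inherits(data, "transition_dataset"))
  p <- data$p
  if (is.null(qs)) qs <- seq_len(p - 1L)
  stopifnot(all(qs >= 1L), all(qs < p))

  cfg_for <- function(q, epochs = base_config$epochs) {
    cfg <- base_config
    cfg$q <- as.integer(q)
    cfg$epochs <- as.integer(epochs)
    cfg
  }
  ref_fit <- train_stage1(data, cfg_for(p, epochs = if (is.null(ref_epochs))
    base_config$epochs else ref_epochs))
  dei_micro <- model_dEI(ref_fit$model, L = base_config$L,
                         n_mc = base_config$n_mc,
                         seed = derive_seed(base_config$seed, "ei_micro"))

  rows <- vector("list", length(qs))
  models <- if (keep_models) vector("list", length(qs)) else NULL
  for (i in seq_along(qs)) {
    q <- qs[i]
    res <- tryCatch({
      fit <- train_stage1(data, cfg_for(q))
      dei <- model_dEI(fit$model, L = base_config$L,
                       n_mc = base_config$n_mc,
                       seed = derive_seed(base_config$seed,
                                          paste0("ei_q", q)))
      eff <- check_effectiveness(fit$model, data, epsilon = epsilon)
      if (keep_models) models[[i]] <- fit$model
      h <- fit$history
      data.frame(q = q,
                 train_loss = mean(utils::tail(h$train_loss, 50L)),
                 val_loss = utils::tail(stats::na.omit(h$val_loss), 1L),
                 dEI = as.numeric(dei),
                 dCE = as.numeric(dei) - as.numeric(dei_micro),
                 effectiveness = eff,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(q = q, train_loss = NA_real_, val_loss = NA_real_,
                 dEI = NA_real_, dCE = NA_real_,
                 effectiveness = NA_real_, error = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  per_q <- do.call(rbind, rows)
  ok <- !is.na(per_q$dCE)
  if (!any(ok)) stop("every per-q training failed")
  best <- max(per_q$dCE[ok])
  q_star <- min(per_q$q[ok][per_q$dCE[ok] == best])
  if (keep_models) names(models) <- paste0("q", qs)
  structure(list(per_q = per_q, q_star = as.integer(q_star),
                 dEI_micro = as.numeric(dei_micro),
                 micro_model = if (keep_models) ref_fit$model else NULL,
                 models = models, epsilon = epsilon,
                 config = base_config),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat("Causal-emergence scan (reference dEI_micro =",
      signif(x$dEI_micro, 4), "nats/dim)\n")
  print(x$per_q, row.names = FALSE)
  cat("selected q* =", x$q_star, "\n")
  invisible(x)
}

#' Count macro-state clusters of a q = 1 encoder
#'
#' Operationalises the cluster readout used for finite-state systems:
#' encodes every distinct micro-state, sorts the scalar codes, and splits
#' wherever an adjacent gap exceeds \code{gap_factor} times the median
#' adjacent gap. Returns the number of clusters and a per-state assignment
#' (in the order of \code{states}).
#'
#' @param model a trained \code{nis_model} with q = 1.
#' @param states matrix of distinct micro-states (rows).
#' @param gap_factor multiplier on the median adjacent gap (default 5).
#' @return list with \code{n_clusters}, \code{assignment} (integer labels,
#'   1 = lowest code), and the encoded \code{codes}.
#' @export
count_macro_clusters <- function(model, states, gap_factor = 5) {
  if (model$q != 1L) stop("cluster readout is defined for q = 1 models")
  states <- as_row_matrix(states, model$p)
  codes <- as.numeric(nis_encode(model, states))
  ord <- order(codes)
  sorted <- codes[ord]
  n <- length(sorted)
  labels_sorted <- integer(n)
  labels_sorted[1L] <- 1L
  if (n > 1L) {
    gaps <- diff(sorted)
    thr <- max(gap_factor * stats::median(gaps), 1e-12)
    labels_sorted <- cumsum(c(1L, as.integer(gaps > thr)))
  }
  assignment <- integer(n)
  assignment[ord] <- labels_sorted
  list(n_clusters = max(labels_sorted), assignment = assignment,
       codes = codes)
}
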