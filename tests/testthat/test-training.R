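test_that("the loss is the mean l-norm of the residual", {
  x <- matrix(0, 2, 2)
  xh <- rbind(c(3, 4), c(3, 4))
  expect_equal(nis_loss(xh, x, l = 2), 5)
  expect_equal(nis_loss(xh, x, l = 1), 7)
  expect_equal(nis_loss(x, x, l = 2), 0)
  expect_error(nis_loss(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
})

test_that("l = 2 loss gradients align with the Gaussian log-likelihood", {
  ## on a Gaussian toy the squared-error direction and the l2-norm direction
  ## coincide (the norm only rescales the gradient per sample)
  ## single sample: the l2-norm gradient is the squared-error gradient
  ## rescaled by 1/||r||, so directions agree exactly
  m <- random_model(4, 2, sd = 0.1, seed = 11)
  set.seed(11)
  xb <- matrix(rnorm(4), 1, 4); xnb <- matrix(rnorm(4), 1, 4)
  z <- matrix(0, 1, 2)
  g <- nisr:::nis_grad_step(m, xb, xnb, l_norm = 2L, z = z)$grads
  ## numeric direction from the Gaussian NLL (= 0.5 sum of squares)
  eps <- 1e-6
  params <- nisr:::nis_params(m)
  sq_loss <- function(pp) {
    mm <- nisr:::nis_set_params(m, pp)
    sum((nis_predict(mm, xb, z = z) - xnb)^2) / 2
  }
  ## check a handful of leaves: gradients are positively aligned
  leaf_dirs <- numeric(0)
  for (k in 1:2) {  # output bias has length q = 2
    pp_plus <- params
    pp_plus$dyn$b[[3]][k] <- pp_plus$dyn$b[[3]][k] + eps
    num <- (sq_loss(pp_plus) - sq_loss(params)) / eps
    ana <- g$dyn$b[[3]][k]
    if (abs(num) > 1e-8) leaf_dirs <- c(leaf_dirs, sign(num) * sign(ana))
  }
  expect_true(all(leaf_dirs == 1))
})

test_that("analytic gradients match finite differences through the full graph", {
  m <- random_model(4, 2, hidden = 8, sd = 0.2, seed = 13)
  set.seed(13)
  xb <- matrix(rnorm(5 * 4), 5, 4)
  xnb <- matrix(rnorm(5 * 4), 5, 4)
  z <- matrix(rnorm(5 * 2), 5, 2)
  for (l_norm in c(1L, 2L)) {
    gs <- nisr:::nis_grad_step(m, xb, xnb, l_norm = l_norm, z = z)
    params <- nisr:::nis_params(m)
    loss_at <- function(pp) nisr:::nis_grad_step(
      nisr:::nis_set_params(m, pp), xb, xnb, l_norm = l_norm, z = z)$loss
    ## probe representative leaves in every component
    probes <- list(
      list(get = function(g) g$bij[[1]]$s$W[[2]][3, 4],
           set = function(pp, v) { pp$bij[[1]]$s$W[[2]][3, 4] <- v; pp }),
      list(get = function(g) g$bij[[2]]$t$b[[1]][2],
           set = function(pp, v) { pp$bij[[2]]$t$b[[1]][2] <- v; pp }),
      list(get = function(g) g$bij[[3]]$s$b[[3]][1],
           set = function(pp, v) { pp$bij[[3]]$s$b[[3]][1] <- v; pp }),
      list(get = function(g) g$dyn$W[[1]][1, 2],
           set = function(pp, v) { pp$dyn$W[[1]][1, 2] <- v; pp }))
    h <- 1e-6
    for (pr in probes) {
      v0 <- pr$get(params)
      num <- (loss_at(pr$set(params, v0 + h)) -
                loss_at(pr$set(params, v0 - h))) / (2 * h)
      expect_equal(pr$get(gs$grads), num, tolerance = 1e-4)
    }
  }
})

test_that("training a static dataset approaches the identity fixed point", {
  d <- static_dataset(400, 4)
  ## q = p: the identity model reproduces static data exactly, and training
  ## must stay at that fixed point
  fit4 <- train_stage1(d, train_config(q = 4, epochs = 100, batch_size = 32,
                                       learning_rate = 1e-3, seed = 1))
  expect_lt(tail(na.omit(fit4$history$val_loss), 1), 0.05)
  y4 <- nis_encode(fit4$model, d$x_t[1:50, ])
  expect_lt(max(abs(nis_macro_step(fit4$model, y4) - y4)), 0.1)
  ## q < p: full reconstruction is impossible (the data has no redundant
  ## dimensions), but the macro dynamics still converges to the identity
  fit2 <- train_stage1(d, train_config(q = 2, epochs = 300, batch_size = 32,
                                       learning_rate = 3e-3, seed = 1))
  y <- nis_encode(fit2$model, d$x_t[1:50, ])
  expect_lt(max(abs(nis_macro_step(fit2$model, y) - y)), 0.2)
  expect_true(fit2$model$trained)
  expect_true(all(fit2$model$sigma >= 1e-6))
})

test_that("training is deterministic given the seed", {
  d <- simulate_spring(300, seed = 3)
  cfg <- train_config(q = 2, epochs = 60, batch_size = 32,
                      learning_rate = 1e-3, seed = 42)
  f1 <- train_stage1(d, cfg)
  f2 <- train_stage1(d, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$sigma, f2$model$sigma)
  x <- d$x_t[1:5, ]
  expect_identical(nis_encode(f1$model, x), nis_encode(f2$model, x))
})

test_that("spring training reduces validation loss substantially", {
  d <- simulate_spring(2000, seed = 5)
  cfg <- train_config(q = 2, epochs = 600, batch_size = 64,
                      learning_rate = 3e-3, seed = 0)
  fit <- train_stage1(d, cfg)
  h <- fit$history
  ## compare against the loss of the untrained model (first step)
  expect_lt(tail(na.omit(h$val_loss), 1), 0.2 * h$train_loss[1])
})

test_that("scan_q reports one record per scale and breaks ties downward", {
  d <- static_dataset(300, 4)
  cfg <- train_config(q = 1, epochs = 80, batch_size = 32,
                      learning_rate = 3e-3, seed = 2, n_mc = 100)
  rep <- scan_q(d, cfg, epsilon = 0.5)
  expect_s3_class(rep, "scan_report")
  expect_equal(rep$per_q$q, 1:3)
  expect_equal(nrow(rep$per_q), 3L)
  ok <- !is.na(rep$per_q$dCE)
  best <- max(rep$per_q$dCE[ok])
  expect_equal(rep$q_star, min(rep$per_q$q[ok][rep$per_q$dCE[ok] == best]))
  ## dCE is dEI minus the micro reference, exactly
  expect_equal(rep$per_q$dCE, rep$per_q$dEI - rep$dEI_micro)
})

test_that("cluster readout splits on dominant gaps only", {
  ## p = 2 identity model: the code of a state is its first coordinate
  m <- nis_model(2, 1, hidden = 8)
  states <- cbind(c(0, 0.01, 0.02, 5), 0)
  cl <- count_macro_clusters(m, states)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(cl$assignment, c(1L, 1L, 1L, 2L))
  ## all-equal codes: a single cluster
  cl1 <- count_macro_clusters(m, cbind(rep(1, 4), 0))
  expect_equal(cl1$n_clusters, 1L)
  m2 <- nis_model(4, 2, hidden = 8)
  expect_error(count_macro_clusters(m2, matrix(0, 2, 4)), "q = 1")
})

test_that("invalid configurations are rejected", {
  expect_error(train_config(q = 2, l_norm = 3), "l_norm")
  expect_error(train_config(q = 2, epochs = 0), "epochs")
  expect_error(train_config(q = 2, val_fraction = 1), "val_fraction")
  d <- static_dataset(50, 4)
  expect_error(train_stage1(d, train_config(q = 5, epochs = 10)), "<= data\\$p")
})
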