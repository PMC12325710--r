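tiny_config <- function(...) {
  classifier_config(n_classes = 4L, input_size = 8L, in_channels = 2L,
                    n_blocks = 2L, widths = c(3L, 4L), pool_to = 8L, ...)
}

rand_stack <- function(S, C, seed = 1) {
  with_seed(seed, array(stats::runif(S * S * C), c(S, S, C)))
}

test_that("model outputs are valid probability vectors", {
  for (K in c(2L, 4L)) {
    cfg <- classifier_config(n_classes = K, input_size = 16L, in_channels = 3L,
                             n_blocks = 1L, widths = 4L, pool_to = 8L, seed = 2)
    model <- build_model(cfg)
    pr <- predict_with_ci(model, rand_stack(16, 3))
    expect_length(pr$probs, K)
    expect_equal(sum(pr$probs), 1, tolerance = 1e-9)
    expect_true(all(pr$probs >= 0))
    expect_equal(pr$ci, max(pr$probs))
    expect_equal(pr$score, which.max(pr$probs) - 1L)
    # constant-zero input stays finite
    pz <- predict_with_ci(model, array(0, c(16, 16, 3)))
    expect_false(any(!is.finite(pz$probs)))
  }
  expect_error(classifier_config(n_classes = 3L), "config error")
  expect_error(predict_with_ci(build_model(tiny_config()),
                               rand_stack(16, 2)), "shape error")
})

test_that("a zeroed head yields the uniform tie broken to the lowest score", {
  cfg <- tiny_config(seed = 3)
  model <- build_model(cfg)
  model$params$head$V[] <- 0
  model$params$head$b[] <- 0
  pr <- predict_with_ci(model, rand_stack(8, 2))
  expect_equal(pr$probs, rep(0.25, 4))
  expect_equal(pr$ci, 0.25)
  expect_equal(pr$score, 0L)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_config(seed = 3)
  model <- build_model(cfg)
  B <- 2L
  X <- with_seed(5, array(stats::rnorm(8 * 8 * 2 * B), c(8, 8, 2, B)))
  y <- c(1L, 3L)
  loss_of <- function(m) {
    fwd <- her2scan:::forward_batch(m, X)
    -mean(log(fwd$probs[cbind(1:B, y + 1L)]))
  }
  fwd <- her2scan:::forward_batch(model, X, keep = TRUE)
  dlog <- fwd$probs
  dlog[cbind(1:B, y + 1L)] <- dlog[cbind(1:B, y + 1L)] - 1
  dlog <- dlog / B
  gr <- her2scan:::backward_batch(model, X, fwd, dlog)
  eps <- 1e-6
  set.seed(11)
  for (nm in her2scan:::param_names(model$params)) {
    th0 <- her2scan:::get_param(model$params, nm)
    g <- her2scan:::get_param(gr, nm)
    for (idx in sample(length(th0), min(3L, length(th0)))) {
      m2 <- model
      th <- th0; th[idx] <- th[idx] + eps
      m2$params <- her2scan:::set_param(m2$params, nm, th)
      lp <- loss_of(m2)
      th[idx] <- th[idx] - 2 * eps
      m2$params <- her2scan:::set_param(m2$params, nm, th)
      lm <- loss_of(m2)
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(g[idx] - fd) / max(abs(fd), 1e-6), 1e-4)
    }
  }
})

test_that("cosine annealing restarts return the rate to its initial value", {
  lrs <- vapply(1:30, cosine_restart_lr, numeric(1),
                lr0 = 1e-3, T0 = 10L, mult = 2)
  expect_equal(lrs[1], 1e-3)
  expect_equal(lrs[11], 1e-3)   # restart after the first 10-epoch cycle
  expect_true(all(diff(lrs[1:10]) < 0))
  expect_true(all(diff(lrs[11:30]) < 0))  # second cycle spans 20 epochs
  expect_lt(lrs[10], 1e-4)
})

test_that("training is deterministic under fixed seeds and learns a toy task", {
  cfg <- classifier_config(n_classes = 2L, input_size = 16L, in_channels = 3L,
                           n_blocks = 1L, widths = 6L, pool_to = 8L, seed = 4)
  # class 1 is globally darker: separable from the GAP features
  stacks <- lapply(1:40, function(i)
    rand_stack(16, 3, seed = 100 + i) * (if (i %% 2) 1 else 0.6))
  labels <- rep(c(0L, 1L), 20)
  tc <- train_config(epochs = 10L, batch_size = 4L, val_frac = 0.2, seed = 5)
  r1 <- train(build_model(cfg), stacks, labels, tc)
  r2 <- train(build_model(cfg), stacks, labels, tc)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$history, r2$history)
  expect_equal(r1$history$lr,
               vapply(seq_len(tc$epochs), cosine_restart_lr, numeric(1),
                      lr0 = tc$lr, T0 = tc$restart_period,
                      mult = tc$restart_mult))
  expect_lt(tail(r1$history$train_loss, 1), r1$history$train_loss[1])
  # the learned positive-class probability ranks the held-out classes
  # perfectly even before the decision bias fully calibrates
  val_probs <- vapply(r1$val_idx, function(i)
    predict_with_ci(r1$model, stacks[[i]])$probs[2], numeric(1))
  expect_gte(roc_auc(val_probs, labels[r1$val_idx])$auc, 0.9)
  expect_error(train(build_model(cfg), stacks, rep(0L, 40), tc),
               "degenerate-data")
})

test_that("spectral blocks are shift-equivariant when linear", {
  cfg <- classifier_config(n_classes = 4L, input_size = 16L, in_channels = 2L,
                           n_blocks = 1L, widths = 3L, pool_to = 16L,
                           activation = "identity", seed = 6)
  model <- build_model(cfg)
  x <- rand_stack(16, 2, seed = 8)
  sh <- function(a, dy, dx) {
    idx <- function(n, d) ((seq_len(n) - 1L + d) %% n) + 1L
    a[idx(dim(a)[1], dy), idx(dim(a)[2], dx), , drop = FALSE]
  }
  f1 <- forward_features(model, sh(x, 3, 5))
  f2 <- sh(forward_features(model, x), 3, 5)
  expect_equal(f1, f2, tolerance = 1e-10)
})
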