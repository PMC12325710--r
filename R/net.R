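# Fourier-domain classification network with a GAP head.
#
# Each spectral block takes a 2-D discrete Fourier transform of the feature
# map, applies a learnable per-frequency complex linear map (a stationary
# linear filter per channel), transforms back, applies a pointwise
# nonlinearity, and mixes channels with a 1x1 convolution. A final 1x1
# convolution to n_classes followed by global average pooling yields the
# logits; softmax gives class probabilities and the confidence index (CI)
# is the maximum probability. Implemented from scratch in base R (batched
# FFTs via mvfft); trained with AdamW under cosine annealing with warm
# restarts and cross-entropy loss.

# ---- batched 2-D FFT over the first two dims of an array ----
# two mvfft passes with an aperm in between; dim<- reshapes are copy-free
fft2_batch <- function(x, inverse = FALSE) {
  d <- dim(x)
  rest <- prod(d) / (d[1] * d[2])
  dim(x) <- c(d[1], prod(d) / d[1])
  x <- stats::mvfft(x, inverse = inverse)
  dim(x) <- c(d[1], d[2], rest)
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- c(d[2], prod(d) / d[2])
  x <- stats::mvfft(x, inverse = inverse)
  dim(x) <- c(d[2], d[1], rest)
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- d
  if (inverse) x / (d[1] * d[2]) else x
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' Classifier configuration
#'
#' @param n_classes 2 (negative 0/1+ vs positive 2+/3+) or 4 (0, 1+, 2+, 3+).
#' @param input_size side length `S` of each stack slot.
#' @param in_channels stack channel count (15 for the 5-slot RGB stack).
#' @param n_blocks number of spectral blocks.
#' @param widths channel width after each block (length `n_blocks`).
#' @param pool_to side length of the internal feature grid; the input is
#'   area-pooled from `input_size` to this before the first block (compute
#'   scaling; set equal to `input_size` to disable).
#' @param activation `"gelu"` or `"identity"` (the latter makes each block a
#'   stationary linear filter, used by equivariance checks).
#' @param seed weight-initialization seed.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(n_classes = 4L, input_size = 512L,
                              in_channels = 15L, n_blocks = 3L,
                              widths = c(32L, 64L, 64L), pool_to = 16L,
                              activation = c("gelu", "identity"), seed = 1L) {
  if (!n_classes %in% c(2L, 4L))
    stop("config error: n_classes must be 2 or 4", call. = FALSE)
  if (length(widths) != n_blocks)
    stop("config error: widths must have n_blocks entries", call. = FALSE)
  if (pool_to > input_size)
    stop("config error: pool_to cannot exceed input_size", call. = FALSE)
  structure(list(n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 n_blocks = as.integer(n_blocks), widths = as.integer(widths),
                 pool_to = as.integer(pool_to),
                 activation = match.arg(activation), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Training configuration
#'
#' Defaults follow the training scheme: AdamW with decoupled weight decay
#' 1e-4, initial learning rate 1e-3 under cosine annealing with warm
#' restarts (initial period 10 epochs, period multiplier 2), cross-entropy
#' loss.
#'
#' @param weight_decay AdamW decoupled weight decay.
#' @param lr initial learning rate.
#' @param restart_period,restart_mult warm-restart schedule parameters.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param val_frac held-out fraction (stratified by class).
#' @param seed seed for the split, shuffling, and any augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(weight_decay = 1e-4, lr = 1e-3, restart_period = 10L,
                         restart_mult = 2, batch_size = 16L, epochs = 10L,
                         val_frac = 0.1, seed = 1L) {
  if (weight_decay <= 0 || lr <= 0)
    stop("config error: weight_decay and lr must be positive", call. = FALSE)
  structure(list(weight_decay = weight_decay, lr = lr,
                 restart_period = as.integer(restart_period),
                 restart_mult = restart_mult, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealing-with-warm-restarts learning rate
#'
#' The rate decays along a half cosine from `lr0` to `eta_min` over the
#' current cycle and jumps back to `lr0` at each restart; cycle lengths grow
#' by `mult` after every restart.
#'
#' @param epoch 1-based epoch index.
#' @param lr0 initial (restart) learning rate.
#' @param T0 first cycle length in epochs.
#' @param mult cycle-length multiplier.
#' @param eta_min floor learning rate.
#' @return learning rate for `epoch`.
#' @export
cosine_restart_lr <- function(epoch, lr0 = 1e-3, T0 = 10L, mult = 2,
                              eta_min = 0) {
  t <- epoch - 1
  Ti <- T0
  while (t >= Ti) { t <- t - Ti; Ti <- Ti * mult }
  eta_min + 0.5 * (lr0 - eta_min) * (1 + cos(pi * t / Ti))
}

#' Build an untrained spectral classifier
#'
#' Spectral filters initialize near identity (1 + small complex noise);
#' 1x1 convolutions use He-scaled Gaussian weights.
#'
#' @param config `classifier_config`.
#' @return object of class `spectral_net` with `config` and `params`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "classifier_config"))
  P <- config$pool_to
  chans <- c(config$in_channels, config$widths)
  params <- with_seed(config$seed, {
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      cin <- chans[b]; cout <- chans[b + 1L]
      list(Wr = array(1 + stats::rnorm(P * P * cin, 0, 0.02), c(P, P, cin)),
           Wi = array(stats::rnorm(P * P * cin, 0, 0.02), c(P, P, cin)),
           V = matrix(stats::rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin),
           b = rep(0, cout))
    })
    head <- list(V = matrix(stats::rnorm(config$n_classes * chans[length(chans)],
                                         0, sqrt(2 / chans[length(chans)])),
                            config$n_classes, chans[length(chans)]),
                 b = rep(0, config$n_classes))
    list(blocks = blocks, head = head)
  })
  structure(list(config = config, params = params), class = "spectral_net")
}

# pool a single stack (S x S x C) to the feature grid (P x P x C) and
# convert intensity to absorbance (1 - I): background maps to 0, staining to
# positive values, which centers the optimization
pool_stack <- function(stack, config) {
  d <- dim(stack)
  if (length(d) != 3L || d[1] != config$input_size || d[2] != config$input_size ||
      d[3] != config$in_channels)
    stop("shape error: stack dimensions do not match the classifier config",
         call. = FALSE)
  P <- config$pool_to
  if (P == d[1]) return(1 - array(as.double(stack), d))
  out <- array(0, c(P, P, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- downsample_mean(stack[, , k], P)
  1 - out
}

# forward pass on a pooled batch X (P x P x C x B); returns logits (K x B),
# probabilities and, if keep = TRUE, the per-block cache for backprop
forward_batch <- function(model, X, keep = FALSE) {
  cfg <- model$config
  P <- cfg$pool_to
  B <- dim(X)[4]
  act <- if (cfg$activation == "gelu") gelu else identity
  cache <- if (keep) vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    pr <- model$params$blocks[[b]]
    W <- complex(real = pr$Wr, imaginary = pr$Wi)
    Xf <- fft2_batch(X)
    Yf <- Xf * as.vector(W)                       # recycles over batch
    Y <- Re(fft2_batch(Yf, inverse = TRUE))
    A <- act(Y)
    C_in <- dim(X)[3]; C_out <- nrow(pr$V)
    Am <- matrix(aperm(A, c(1, 2, 4, 3)), ncol = C_in)
    Zm <- Am %*% t(pr$V)
    Zm <- sweep(Zm, 2L, pr$b, "+")
    Z <- aperm(array(Zm, c(P, P, B, C_out)), c(1, 2, 4, 3))
    if (keep) cache[[b]] <- list(Xf = Xf, Y = Y, Am = Am, C_in = C_in)
    X <- Z
  }
  hd <- model$params$head
  C_in <- dim(X)[3]
  Am <- matrix(aperm(X, c(1, 2, 4, 3)), ncol = C_in)
  gap <- rowsum(Am, rep(seq_len(B), each = P * P)) / (P * P)  # B x C_in
  logits <- gap %*% t(hd$V)
  logits <- sweep(logits, 2L, hd$b, "+")          # B x K
  lmax <- apply(logits, 1L, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  out <- list(logits = logits, probs = probs)
  if (keep) { out$cache <- cache; out$final <- X; out$gap <- gap }
  out
}

# backward pass; returns gradients matching the params structure
backward_batch <- function(model, X0, fwd, dlogits) {
  cfg <- model$config
  P <- cfg$pool_to
  B <- nrow(dlogits)
  hd <- model$params$head
  gV_head <- t(dlogits) %*% fwd$gap
  gb_head <- colSums(dlogits)
  dgap <- dlogits %*% hd$V                        # B x C_last
  C_last <- ncol(dgap)
  dXm <- dgap[rep(seq_len(B), each = P * P), , drop = FALSE] / (P * P)
  dX <- aperm(array(dXm, c(P, P, B, C_last)), c(1, 2, 4, 3))
  actg <- if (cfg$activation == "gelu") gelu_grad else function(x) 1
  gblocks <- vector("list", cfg$n_blocks)
  for (b in rev(seq_len(cfg$n_blocks))) {
    pr <- model$params$blocks[[b]]
    ca <- fwd$cache[[b]]
    C_in <- ca$C_in; C_out <- nrow(pr$V)
    dZm <- matrix(aperm(dX, c(1, 2, 4, 3)), ncol = C_out)
    gV <- t(dZm) %*% ca$Am
    gb <- colSums(dZm)
    dAm <- dZm %*% pr$V
    dA <- aperm(array(dAm, c(P, P, B, C_in)), c(1, 2, 4, 3))
    dY <- dA * actg(ca$Y)
    FdY <- fft2_batch(dY)
    gz <- FdY / (P * P)
    gW_full <- gz * Conj(ca$Xf)
    gW <- array(rowSums(matrix(gW_full, ncol = B)), c(P, P, C_in))
    W <- complex(real = pr$Wr, imaginary = pr$Wi)
    dX <- Re(fft2_batch(FdY * as.vector(Conj(W)), inverse = TRUE))
    gblocks[[b]] <- list(Wr = Re(gW), Wi = Im(gW), V = gV, b = gb)
  }
  list(blocks = gblocks, head = list(V = gV_head, b = gb_head))
}

# flat iteration over the params tree for the optimizer
param_names <- function(params) {
  c(unlist(lapply(seq_along(params$blocks), function(b)
    paste0("blocks.", b, ".", names(params$blocks[[b]])))),
    paste0("head.", names(params$head)))
}
get_param <- function(params, name) {
  p <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (p[1] == "head") params$head[[p[2]]] else params$blocks[[as.integer(p[2])]][[p[3]]]
}
set_param <- function(params, name, value) {
  p <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (p[1] == "head") params$head[[p[2]]] <- value
  else params$blocks[[as.integer(p[2])]][[p[3]]] <- value
  params
}

#' Train a spectral classifier
#'
#' Minimizes cross-entropy with AdamW (decoupled weight decay) under cosine
#' annealing with warm restarts; fully seeded (split, shuffling,
#' initialization), so retraining with the same inputs reproduces the same
#' weights and history.
#'
#' @param model `spectral_net` from [build_model()].
#' @param stacks list of `patch_stack` arrays (all `S x S x C`).
#' @param labels integer class labels `0 .. n_classes-1`.
#' @param tc `train_config`.
#' @param verbose print per-epoch progress.
#' @return list with `model` (trained), `history` (data.frame: epoch, lr,
#'   train_loss, val_acc), and `val_idx` (indices of the held-out stacks).
#' @export
train <- function(model, stacks, labels, tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "spectral_net"), inherits(tc, "train_config"))
  cfg <- model$config
  labels <- as.integer(labels)
  if (length(stacks) != length(labels))
    stop("shape error: stacks and labels differ in length", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("degenerate-data: training data must contain at least 2 classes",
         call. = FALSE)
  if (any(labels < 0L | labels >= cfg$n_classes))
    stop("labels must lie in 0 .. n_classes-1", call. = FALSE)
  N <- length(stacks)
  P <- cfg$pool_to
  Xall <- array(0, c(P, P, cfg$in_channels, N))
  for (i in seq_len(N)) Xall[, , , i] <- pool_stack(stacks[[i]], cfg)
  # stratified validation split
  val_idx <- with_seed(derive_seed(tc$seed, "split"), {
    unlist(lapply(unique(labels), function(cl) {
      ids <- which(labels == cl)
      nv <- max(1L, round(length(ids) * tc$val_frac))
      sample(ids, min(nv, length(ids)))
    }))
  })
  tr_idx <- setdiff(seq_len(N), val_idx)
  # Adam state
  nms <- param_names(model$params)
  mstate <- lapply(nms, function(nm) get_param(model$params, nm) * 0)
  vstate <- mstate
  names(mstate) <- names(vstate) <- nms
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  hist <- data.frame(epoch = integer(), lr = double(),
                     train_loss = double(), val_acc = double())
  for (ep in seq_len(tc$epochs)) {
    lr <- cosine_restart_lr(ep, tc$lr, tc$restart_period, tc$restart_mult)
    ord <- with_seed(derive_seed(tc$seed, "epoch", ep), sample(tr_idx))
    losses <- c()
    for (start in seq(1L, length(ord), by = tc$batch_size)) {
      bi <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
      Xb <- Xall[, , , bi, drop = FALSE]
      yb <- labels[bi]
      fwd <- forward_batch(model, Xb, keep = TRUE)
      pb <- fwd$probs
      ll <- -mean(log(pmax(pb[cbind(seq_along(bi), yb + 1L)], 1e-12)))
      losses <- c(losses, ll)
      dlogits <- pb
      dlogits[cbind(seq_along(bi), yb + 1L)] <-
        dlogits[cbind(seq_along(bi), yb + 1L)] - 1
      dlogits <- dlogits / length(bi)
      grads <- backward_batch(model, Xb, fwd, dlogits)
      step <- step + 1L
      for (nm in nms) {
        g <- get_param(grads, nm)
        m <- beta1 * mstate[[nm]] + (1 - beta1) * g
        v <- beta2 * vstate[[nm]] + (1 - beta2) * g * g
        mstate[[nm]] <- m; vstate[[nm]] <- v
        mh <- m / (1 - beta1^step); vh <- v / (1 - beta2^step)
        th <- get_param(model$params, nm)
        th <- th - lr * (mh / (sqrt(vh) + eps) + tc$weight_decay * th)
        model$params <- set_param(model$params, nm, th)
      }
    }
    va <- if (length(val_idx)) {
      pv <- forward_batch(model, Xall[, , , val_idx, drop = FALSE])$probs
      mean(max.col(pv, ties.method = "first") - 1L == labels[val_idx])
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr,
                                   train_loss = mean(losses), val_acc = va))
    if (verbose)
      message(sprintf("epoch %d lr %.2e loss %.4f val %.3f", ep, lr,
                      mean(losses), va))
  }
  list(model = model, history = hist, val_idx = val_idx)
}

#' Predict class probabilities, score and confidence for one stack
#'
#' The confidence index (CI) is the maximum class probability; the score is
#' the argmax (ties resolved to the lowest index). For the 2-class model the
#' score encodes 0 = HER2 0/1+ (negative), 1 = 2+/3+ (positive).
#'
#' @param model `spectral_net`.
#' @param stack `patch_stack` or `S x S x C` array.
#' @return list with `probs`, `score` (0-based), `ci`.
#' @export
predict_with_ci <- function(model, stack) {
  X <- pool_stack(stack, model$config)
  fwd <- forward_batch(model, array(X, c(dim(X), 1L)))
  p <- as.vector(fwd$probs)
  list(probs = p, score = which.max(p) - 1L, ci = max(p))
}

#' Predict a list of stacks into a predictions table
#'
#' @param model `spectral_net`.
#' @param stacks list of stacks.
#' @param core_ids,repeat_indices optional identifiers; taken from stack
#'   attributes when absent.
#' @param batch_size internal batch size.
#' @return data.frame: `core_id`, `repeat_index`, `score`, `ci`,
#'   `p0 .. p(K-1)`.
#' @export
predict_stacks <- function(model, stacks, core_ids = NULL,
                           repeat_indices = NULL, batch_size = 64L) {
  cfg <- model$config
  N <- length(stacks)
  if (is.null(core_ids))
    core_ids <- vapply(stacks, function(s) {
      cid <- attr(s, "core_id"); if (is.null(cid)) NA_character_ else cid
    }, character(1))
  if (is.null(repeat_indices))
    repeat_indices <- vapply(stacks, function(s) {
      ri <- attr(s, "repeat_index"); if (is.null(ri)) 1L else as.integer(ri)
    }, integer(1))
  P <- cfg$pool_to
  probs <- matrix(0, N, cfg$n_classes)
  for (start in seq(1L, N, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, N)
    Xb <- array(0, c(P, P, cfg$in_channels, length(bi)))
    for (j in seq_along(bi)) Xb[, , , j] <- pool_stack(stacks[[bi[j]]], cfg)
    probs[bi, ] <- forward_batch(model, Xb)$probs
  }
  df <- data.frame(core_id = core_ids, repeat_index = repeat_indices,
                   score = max.col(probs, ties.method = "first") - 1L,
                   ci = apply(probs, 1L, max), stringsAsFactors = FALSE)
  colnames(probs) <- paste0("p", seq_len(cfg$n_classes) - 1L)
  cbind(df, probs)
}

#' Final feature map of the spectral network
#'
#' Runs the spectral blocks only (no head, no GAP); used to verify the
#' shift-equivariance of the blocks as stationary filters.
#'
#' @param model `spectral_net`.
#' @param stack input stack.
#' @return array `P x P x C_last`.
#' @export
forward_features <- function(model, stack) {
  X <- pool_stack(stack, model$config)
  fwd <- forward_batch(model, array(X, c(dim(X), 1L)), keep = TRUE)
  fwd$final[, , , 1L]
}
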