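# Training: class-weighted Kullback-Leibler loss, Adam, learning-rate
# plateau reduction, early stopping and best-validation checkpointing.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 5e-4, batch size 60, up to 160 epochs, KL-divergence loss with class
#' weights, learning rate divided by 10 after 30 epochs without validation
#' loss improvement (floor 1e-6), early stopping after 50 stagnant epochs,
#' and the best-validation-accuracy weights restored at the end.
#'
#' @param lr Initial learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum epochs.
#' @param reduce_lr_factor,reduce_lr_patience ReduceLROnPlateau settings
#'   (monitoring validation loss).
#' @param min_lr Learning-rate floor.
#' @param early_stop_patience Epochs of stagnant validation loss tolerated
#'   before stopping (0 disables).
#' @param seed Integer seed controlling shuffling, dropout and init.
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 5e-4, batch_size = 60, epochs = 160,
                         reduce_lr_factor = 0.1, reduce_lr_patience = 30,
                         min_lr = 1e-6, early_stop_patience = 50,
                         seed = 1L, verbose = FALSE) {
  check_number(lr, "lr", lower = 1e-12)
  check_number(batch_size, "batch_size", lower = 1)
  check_number(epochs, "epochs", lower = 1)
  if (reduce_lr_factor <= 0 || reduce_lr_factor >= 1)
    abort("reduce_lr_factor must be in (0, 1)", "invalid_parameter")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 reduce_lr_factor = reduce_lr_factor,
                 reduce_lr_patience = as.integer(reduce_lr_patience),
                 min_lr = min_lr,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Class-weighted Kullback-Leibler divergence loss
#'
#' Mean over rows of `w_c(row) * sum_j t_j (log t_j - log p_j)` with
#' predictions clipped to `[1e-7, 1]` and the convention `0 log 0 = 0`.
#' For one-hot targets the target entropy is zero, so the loss equals the
#' class-weighted categorical cross-entropy.
#'
#' @param true_dist,pred_dist Matrices of probability rows (each row sums
#'   to 1 within 1e-5).
#' @param class_weights Per-class weights applied by the row's true class
#'   (`argmax` of the target row); default all 1.
#' @return Scalar loss.
#' @export
#' @examples
#' t <- diag(4)
#' p <- matrix(0.25, 4, 4)
#' kl_loss(t, p)  # log(4)
kl_loss <- function(true_dist, pred_dist,
                    class_weights = rep(1, ncol(true_dist))) {
  if (!all(dim(true_dist) == dim(pred_dist)))
    abort("distribution matrices must have identical shapes", "invalid_input")
  if (any(abs(rowSums(true_dist) - 1) > 1e-5) ||
      any(abs(rowSums(pred_dist) - 1) > 1e-5))
    abort("rows must lie on the probability simplex", "invalid_input")
  pc <- clip(pred_dist, 1e-7, 1)
  tl <- true_dist * (ifelse(true_dist > 0, log(true_dist), 0) - log(pc))
  w <- class_weights[max.col(true_dist, ties.method = "first")]
  mean(w * rowSums(tl))
}

# Gradient of kl_loss with respect to the pre-softmax logits.
kl_grad_logits <- function(probs, targets, class_weights) {
  n <- nrow(probs)
  pc <- clip(probs, 1e-7, 1)
  w <- class_weights[max.col(targets, ties.method = "first")]
  dldp <- -(w / n) * targets / pc
  dldp[probs < 1e-7] <- 0           # clipped entries are flat
  probs * (dldp - rowSums(dldp * probs))
}

# ---- Adam over nested parameter lists ---------------------------------------

adam_init <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else x * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  opt$t <- opt$t + 1L
  t <- opt$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- walk(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(m = r$m, v = r$v, t = t))
}

# ---- callbacks ---------------------------------------------------------------

# Plateau learning-rate scheduler state machine: reduce lr by `factor` after
# `patience` consecutive epochs without improvement of the monitored loss.
reduce_lr_update <- function(st, loss) {
  if (loss < st$best - 1e-12) {
    st$best <- loss; st$wait <- 0L
  } else {
    st$wait <- st$wait + 1L
    if (st$wait >= st$patience) {
      st$lr <- max(st$min_lr, st$lr * st$factor)
      st$wait <- 0L
    }
  }
  st
}

reduce_lr_state <- function(lr, factor, patience, min_lr) {
  list(lr = lr, factor = factor, patience = patience, min_lr = min_lr,
       best = Inf, wait = 0L)
}

# ---- inference over a window set in batches ---------------------------------

fdma_predict_probs <- function(params, state, x, ssm, cfg, batch = 64L) {
  n <- nrow(x)
  out <- matrix(0, n, cfg$n_classes)
  for (s in seq.int(1L, n, by = batch)) {
    idx <- s:min(n, s + batch - 1L)
    ss <- if (is.null(ssm)) NULL else ssm[idx, , , drop = FALSE]
    out[idx, ] <- fdma_forward(params, state, x[idx, , drop = FALSE], ss,
                               cfg, train = FALSE)$probs
  }
  out
}

one_hot <- function(y, k) {
  m <- matrix(0, length(y), k)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

# Core training loop. x/ssm/y are the training tensors; validation data is
# optional but required for the callbacks that monitor validation loss.
fdma_fit <- function(params, state, x, ssm, y, cfg, tcfg, class_weights,
                     x_val = NULL, ssm_val = NULL, y_val = NULL) {
  n <- nrow(x)
  k <- cfg$n_classes
  targets <- one_hot(y, k)
  opt <- adam_init(params)
  lr_st <- reduce_lr_state(tcfg$lr, tcfg$reduce_lr_factor,
                           tcfg$reduce_lr_patience, tcfg$min_lr)
  has_val <- !is.null(x_val)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), train_acc = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  best_acc <- -Inf; best_params <- params; best_state <- state
  best_epoch <- 0L
  es_best <- Inf; es_wait <- 0L
  set.seed(tcfg$seed)
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    tl <- 0; tc <- 0
    for (s in seq.int(1L, n, by = tcfg$batch_size)) {
      idx <- ord[s:min(n, s + tcfg$batch_size - 1L)]
      xb <- x[idx, , drop = FALSE]
      sb <- if (is.null(ssm)) NULL else ssm[idx, , , drop = FALSE]
      tb <- targets[idx, , drop = FALSE]
      fw <- fdma_forward(params, state, xb, sb, cfg, train = TRUE)
      state <- fw$state
      loss <- kl_loss(tb, fw$probs, class_weights)
      if (!is.finite(loss))
        abort(sprintf("non-finite loss at epoch %d (lr %.2g)", ep, lr_st$lr),
              "numeric_error")
      dlog <- kl_grad_logits(fw$probs, tb, class_weights)
      grads <- fdma_backward(dlog, fw$cache, params, cfg)
      up <- adam_step(params, grads, opt, lr_st$lr)
      params <- up$params; opt <- up$opt
      tl <- tl + loss * length(idx)
      tc <- tc + sum(max.col(fw$probs) == y[idx] + 1L)
    }
    train_loss <- tl / n; train_acc <- tc / n
    if (has_val) {
      vp <- fdma_predict_probs(params, state, x_val, ssm_val, cfg)
      val_loss <- kl_loss(one_hot(y_val, k), vp, class_weights)
      val_acc <- mean(max.col(vp) == y_val + 1L)
    } else {
      val_loss <- train_loss; val_acc <- train_acc
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr_st$lr,
                                   train_loss = train_loss,
                                   train_acc = train_acc,
                                   val_loss = val_loss, val_acc = val_acc))
    if (tcfg$verbose)
      message(sprintf("epoch %3d lr %.2g loss %.4f acc %.3f val_loss %.4f val_acc %.3f",
                      ep, lr_st$lr, train_loss, train_acc, val_loss, val_acc))
    if (val_acc > best_acc) {
      best_acc <- val_acc; best_params <- params; best_state <- state
      best_epoch <- ep
    }
    lr_st <- reduce_lr_update(lr_st, val_loss)
    if (tcfg$early_stop_patience > 0) {
      if (val_loss < es_best - 1e-12) { es_best <- val_loss; es_wait <- 0L }
      else {
        es_wait <- es_wait + 1L
        if (es_wait >= tcfg$early_stop_patience) break
      }
    }
  }
  list(params = best_params, state = best_state, history = hist,
       best_epoch = best_epoch, best_val_acc = best_acc)
}
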