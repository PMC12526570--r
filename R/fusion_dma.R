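# User-facing fitting function and S3 methods.

#' Fit the dual-domain attention classifier
#'
#' Trains the dual-branch time/frequency attention network on fixed-length
#' PPG windows. Self-similarity inputs for the frequency branch are derived
#' internally with [window_ssm_tensor()] unless supplied. Training follows
#' the reference protocol in [train_config()]; the best
#' validation-accuracy weights are kept.
#'
#' @param x Window matrix `[n, window_samples]` (rows in `[0, 1]` after
#'   [preprocess_record()]).
#' @param y Labels: class names, factor, or 0-3 integer codes.
#' @param ssm Optional precomputed `[n, B, B]` self-similarity tensor.
#' @param config A [model_config()].
#' @param train A [train_config()].
#' @param x_val,y_val,ssm_val Optional validation data (enables the
#'   plateau/early-stop/checkpoint callbacks to monitor validation metrics).
#' @param source_ids,val_source_ids Optional window provenance; when both
#'   are given, any overlap raises a hard leakage error.
#' @param class_weights Optional per-class loss weights (mean 1); default
#'   inverse-frequency weights from the training labels.
#' @return An object of class `fusion_dma` with elements `params`, `state`,
#'   `config`, `train_config`, `history`, `levels`, `class_weights`.
#' @seealso [predict.fusion_dma()], [evaluate_model()]
#' @export
fusion_dma <- function(x, y, ssm = NULL, config = model_config(),
                       train = train_config(), x_val = NULL, y_val = NULL,
                       ssm_val = NULL, source_ids = NULL,
                       val_source_ids = NULL, class_weights = NULL) {
  if (!is.null(source_ids) && !is.null(val_source_ids) &&
      length(intersect(unique(source_ids), unique(val_source_ids))))
    abort("training and validation windows share source records (data leakage)",
          "leakage_error")
  y <- encode_labels(y)
  if (ncol(x) != config$window_samples)
    abort(sprintf("windows have %d samples; the configuration expects %d",
                  ncol(x), config$window_samples), "config_error")
  if (is.null(ssm) && config$branches != "time")
    ssm <- window_ssm_tensor(x, config$fs, config$welch, config$n_bands)
  if (!is.null(x_val)) {
    y_val <- encode_labels(y_val)
    if (is.null(ssm_val) && config$branches != "time")
      ssm_val <- window_ssm_tensor(x_val, config$fs, config$welch,
                                   config$n_bands)
  }
  if (is.null(class_weights)) {
    counts <- table(factor(y, levels = 0:(config$n_classes - 1)))
    counts[counts == 0] <- 1        # absent classes get neutral weight
    class_weights <- compute_class_weights(as.numeric(counts))
  }
  ini <- init_fusion_dma(config, seed = train$seed)
  fit <- fdma_fit(ini$params, ini$state, x, ssm, y, config, train,
                  class_weights, x_val, ssm_val, y_val)
  structure(list(params = fit$params, state = fit$state, config = config,
                 train_config = train, history = fit$history,
                 best_epoch = fit$best_epoch,
                 levels = rhythm_classes()[seq_len(config$n_classes)],
                 class_weights = class_weights),
            class = "fusion_dma")
}

encode_labels <- function(y) {
  if (is.numeric(y)) return(as.integer(y))
  vapply(as.character(y), rhythm_code, 0L, USE.NAMES = FALSE)
}

#' Predict rhythm classes or probabilities
#'
#' @param object A fitted [fusion_dma()] model.
#' @param x Window matrix.
#' @param ssm Optional precomputed self-similarity tensor.
#' @param type `"prob"` (default) or `"class"`.
#' @param ... Unused.
#' @return Probability matrix (columns named by class) or a factor of
#'   predicted classes.
#' @export
predict.fusion_dma <- function(object, x, ssm = NULL,
                               type = c("prob", "class"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(ssm) && cfg$branches != "time")
    ssm <- window_ssm_tensor(x, cfg$fs, cfg$welch, cfg$n_bands)
  p <- fdma_predict_probs(object$params, object$state, x, ssm, cfg)
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  factor(object$levels[max.col(p)], levels = object$levels)
}

#' @export
print.fusion_dma <- function(x, ...) {
  cfg <- x$config
  cat("Fusion dual-domain attention classifier\n")
  cat(sprintf("  input: %g s windows at %g Hz (%d samples), %d bands\n",
              cfg$window_s, cfg$fs, cfg$window_samples, cfg$n_bands))
  cat(sprintf("  branches: %s; trainable parameters: %s\n",
              cfg$branches, format(count_parameters(cfg), big.mark = ",")))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; best val accuracy %.3f (epoch %d)\n",
                last$epoch, max(x$history$val_acc), x$best_epoch))
  }
  invisible(x)
}

#' @export
summary.fusion_dma <- function(object, ...) {
  print(object)
  fl <- flatten_params(object$params)
  sizes <- vapply(fl, length, 0L)
  cat("\nParameter tensors (top level):\n")
  top <- vapply(strsplit(names(sizes), ".", fixed = TRUE), `[[`, "", 1)
  print(tapply(sizes, top, sum))
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.fusion_dma <- function(object, ...) flatten_params(object$params)

#' Plot training curves
#'
#' Accuracy and loss per epoch for the training and validation sets.
#'
#' @param x A fitted `fusion_dma` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fusion_dma <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: the archive holds the named parameter
#' arrays, batch-norm state, the full model configuration and class levels.
#'
#' @param object A fitted `fusion_dma` model.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `fusion_dma` object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(unclass(object), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "fusion_dma")
}
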