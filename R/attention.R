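# Attention primitives. The exported functions operate on plain matrices
# (rows = positions, columns = channels) and are the single source of the
# math; the batched network wrappers in nn-attention.R reuse the same
# formulas with caches for backpropagation.

#' Attention configuration
#'
#' @param d_model Model (channel) width; must be divisible by `heads`.
#' @param heads Number of attention heads (4 by default).
#' @param dropout Dropout rate applied to attention weights during training.
#' @return An object of class `attention_config`.
#' @export
attention_config <- function(d_model, heads = 4, dropout = 0.2) {
  check_number(d_model, "d_model", lower = 1, class = "config_error")
  check_number(heads, "heads", lower = 1, class = "config_error")
  if (d_model %% heads != 0)
    abort("d_model must be divisible by the head count", "config_error")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)", "config_error")
  structure(list(d_model = as.integer(d_model), heads = as.integer(heads),
                 d_k = as.integer(d_model / heads), dropout = dropout),
            class = "attention_config")
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K^T / sqrt(d_k)) V`, with the softmax
#' stabilized by row-max subtraction. Every row of the returned weight
#' matrix sums to one.
#'
#' @param Q,K,V Matrices; `Q` and `K` share the key dimension, `K` and `V`
#'   share the row count.
#' @return List with `output` (`nrow(Q) x ncol(V)`) and `weights`
#'   (`nrow(Q) x nrow(K)`).
#' @export
#' @examples
#' q <- matrix(rnorm(8), 2); k <- matrix(rnorm(8), 2); v <- matrix(rnorm(6), 2)
#' rowSums(scaled_dot_attention(q, k, v)$weights)
scaled_dot_attention <- function(Q, K, V) {
  if (ncol(Q) != ncol(K)) abort("Q and K must share the key dimension", "shape_error")
  if (nrow(K) != nrow(V)) abort("K and V must have the same number of rows", "shape_error")
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(K)))
  list(output = A %*% V, weights = A)
}

#' He-normal initialized multi-head projection weights
#'
#' @param d_model Model width.
#' @param d_in_q,d_in_kv Input widths of the query and key/value sequences
#'   (default `d_model`).
#' @param seed Integer seed.
#' @return List with `Wq`, `Wk`, `Wv`, `Wo` and zero biases.
#' @export
mha_weights <- function(d_model, d_in_q = d_model, d_in_kv = d_model, seed = 1L) {
  with_seed(seed, list(
    Wq = he_matrix(d_in_q, d_model), bq = numeric(d_model),
    Wk = he_matrix(d_in_kv, d_model), bk = numeric(d_model),
    Wv = he_matrix(d_in_kv, d_model), bv = numeric(d_model),
    Wo = he_matrix(d_model, d_model), bo = numeric(d_model)))
}

he_matrix <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

#' Multi-head attention
#'
#' Projects queries, keys and values with per-head learnable weights, runs
#' scaled dot-product attention in each head in parallel subspaces,
#' concatenates the head outputs and applies the output projection `W^O`.
#'
#' @param Q,K,V Input matrices (rows = positions).
#' @param weights A [mha_weights()] list.
#' @param cfg An [attention_config()].
#' @return Matrix with `nrow(Q)` rows and `d_model` columns.
#' @export
multi_head_attention <- function(Q, K, V, weights, cfg) {
  if (ncol(Q) != nrow(weights$Wq) || ncol(K) != nrow(weights$Wk) ||
      ncol(V) != nrow(weights$Wv))
    abort("projection shapes do not match the inputs", "shape_error")
  Qp <- sweep_add(Q %*% weights$Wq, weights$bq)
  Kp <- sweep_add(K %*% weights$Wk, weights$bk)
  Vp <- sweep_add(V %*% weights$Wv, weights$bv)
  H <- cfg$heads; dk <- cfg$d_k
  out <- matrix(0, nrow(Q), cfg$d_model)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    out[, cols] <- scaled_dot_attention(Qp[, cols, drop = FALSE],
                                        Kp[, cols, drop = FALSE],
                                        Vp[, cols, drop = FALSE])$output
  }
  sweep_add(out %*% weights$Wo, weights$bo)
}

#' Residual connection with layer normalization
#'
#' `Y = LayerNorm(sublayer_output + X)`, normalizing each row over the
#' channel axis (epsilon 1e-5) and then applying the affine `gamma`/`beta`.
#'
#' @param X Input to the residual connection.
#' @param sublayer_output Output of the wrapped sub-layer, same shape as `X`.
#' @param gamma,beta Affine parameters (default identity).
#' @return Normalized matrix, same shape as `X`.
#' @export
residual_layernorm <- function(X, sublayer_output,
                               gamma = rep(1, ncol(X)),
                               beta = numeric(ncol(X))) {
  if (!all(dim(X) == dim(sublayer_output)))
    abort("residual inputs must have identical shapes", "shape_error")
  s <- X + sublayer_output
  ln <- layernorm_fwd(array(s, c(1L, nrow(s), ncol(s))), gamma, beta)
  matrix(ln$y, nrow(s), ncol(s))
}

#' Squeeze-and-excite channel attention
#'
#' Global average over time (squeeze), bottleneck of width `channels / r`
#' with ReLU, expansion back with a sigmoid, and per-channel multiplicative
#' gating of the input features.
#'
#' @param features `time x channels` matrix.
#' @param weights List with `W1`, `b1`, `W2`, `b2`
#'   (see [channel_attention_weights()]).
#' @param r Reduction factor (must not exceed the channel count).
#' @return List with `output` (gated features) and `gates` in (0, 1).
#' @export
channel_attention <- function(features, weights, r = 4) {
  C <- ncol(features)
  if (r > C) abort("reduction factor exceeds channel count", "config_error")
  s <- colMeans(features)
  h <- pmax(drop(s %*% weights$W1) + weights$b1, 0)
  g <- sigmoid(drop(h %*% weights$W2) + weights$b2)
  list(output = features * rep(g, each = nrow(features)), gates = g)
}

#' @rdname channel_attention
#' @param channels Channel count.
#' @param seed Integer seed for the He-normal init.
#' @export
channel_attention_weights <- function(channels, r = 4, seed = 1L) {
  hid <- max(1L, channels %/% r)
  with_seed(seed, list(W1 = he_matrix(channels, hid), b1 = numeric(hid),
                       W2 = he_matrix(hid, channels), b2 = numeric(channels)))
}

#' Gated fusion of two feature streams
#'
#' A learnable sigmoid gate `z = sigmoid([a || b] W + bias)` forms the
#' elementwise convex combination `z * a + (1 - z) * b`, so every output
#' element lies between the corresponding elements of `a` and `b`.
#'
#' @param a,b Matrices of identical shape.
#' @param gate_params List with `W` (`2*channels x channels`) and `b`.
#' @return List with `output` and `gate` (the matrix `z`).
#' @export
gated_fusion <- function(a, b, gate_params) {
  if (!all(dim(a) == dim(b)))
    abort("fusion inputs must have identical shapes", "shape_error")
  u <- cbind(a, b)
  z <- sigmoid(sweep_add(u %*% gate_params$W, gate_params$b))
  list(output = z * a + (1 - z) * b, gate = z)
}
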