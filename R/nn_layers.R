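# Shared neural-network helpers. The per-branch forward/backward passes
# (banded-gemm convolutions, fused batch-norm + ELU, dropout, pooling) live
# in compiled code (src/branch.cpp); here are initialisation and the losses.

# Glorot (Xavier) uniform initialisation.
glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# weighted mean cross-entropy over the batch; y is an integer class vector
# in 1..K, w an optional per-class weight vector (length K). Inverse-
# frequency weights counteract the majority-class bias that class-
# imbalanced training folds otherwise induce.
cross_entropy_loss <- function(probs, y, w = NULL) {
  n <- nrow(probs)
  p <- probs[cbind(seq_len(n), y)]
  if (is.null(w)) return(-mean(log(pmax(p, 1e-12))))
  wi <- w[y]
  -sum(wi * log(pmax(p, 1e-12))) / sum(wi)
}

cross_entropy_grad <- function(probs, y, w = NULL) {
  n <- nrow(probs)
  g <- probs
  g[cbind(seq_len(n), y)] <- g[cbind(seq_len(n), y)] - 1
  if (is.null(w)) return(g / n)
  wi <- w[y]
  g * (wi / sum(wi))
}

mse_loss <- function(yhat, y) mean((yhat - y)^2)

mse_grad <- function(yhat, y) 2 * (yhat - y) / length(y)
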