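# The multi-cue network: three parallel EEGNet-style branches (temporal
# convolution -> batch-norm/ELU -> depthwise spatial convolution ->
# separable temporal convolution, with average pooling and dropout), whose
# flattened features are concatenated and fed to a softmax classification
# head and/or a linear severity-regression head.

BRANCH_NAMES <- c("happy", "fear", "sad")

#' Configuration of a single EEGNet-style branch
#'
#' Describes the layer hyper-parameters shared by the three cue branches.
#' The layer sequence per branch is
#' `Conv(1 x temporal_kernel, f1, same padding) -> BatchNorm -> ELU ->
#' DepthwiseConv(C x 1, multiplier D) -> BatchNorm -> ELU -> Dropout ->
#' AvgPool(1 x pool1) -> SeparableConv(1 x sep_kernel, same padding) ->
#' BatchNorm -> ELU -> Dropout -> AvgPool(1 x pool2) -> flatten`.
#' Convolutions carry no bias; batch normalisation is affine.
#'
#' @param n_channels Number of EEG channels `C` spanned by the depthwise
#'   spatial kernel.
#' @param n_samples Number of time samples `T` per epoch.
#' @param f1 Number of temporal filters (default 8).
#' @param temporal_kernel Length of the temporal convolution kernel in
#'   samples (default 100, i.e. 400 ms at 250 Hz).
#' @param depth_multiplier Depth multiplier `D` of the depthwise spatial
#'   convolution; the branch produces `f2 = f1 * D` feature maps.
#' @param sep_kernel Length of the separable (depthwise temporal) kernel.
#' @param pool1,pool2 Average-pooling widths after the depthwise and
#'   separable blocks.
#' @param dropout_p Dropout probability in `[0, 1)`.
#' @return An object of class `branch_config`.
#' @export
branch_config <- function(n_channels, n_samples, f1 = 8L, temporal_kernel = 100L,
                          depth_multiplier = 2L, sep_kernel = 16L,
                          pool1 = 4L, pool2 = 8L, dropout_p = 0.5) {
  n_channels <- as.integer(n_channels)
  n_samples <- as.integer(n_samples)
  if (n_channels < 1L) stop_contract("n_channels must be >= 1")
  if (dropout_p < 0 || dropout_p >= 1) stop_contract("dropout_p must lie in [0, 1)")
  if (f1 < 1L || depth_multiplier < 1L) stop_contract("f1 and depth_multiplier must be >= 1")
  t_min <- as.integer(pool1) * as.integer(pool2)
  if ((n_samples %/% pool1) %/% pool2 < 1L) {
    stop_contract("n_samples = %d too small for pooling (%d, %d); need at least T = %d",
                  n_samples, pool1, pool2, t_min)
  }
  structure(list(
    n_channels = n_channels, n_samples = n_samples,
    f1 = as.integer(f1), temporal_kernel = as.integer(temporal_kernel),
    depth_multiplier = as.integer(depth_multiplier),
    f2 = as.integer(f1) * as.integer(depth_multiplier),
    sep_kernel = as.integer(sep_kernel),
    pool1 = as.integer(pool1), pool2 = as.integer(pool2),
    dropout_p = dropout_p
  ), class = "branch_config")
}

#' Configuration of the full multi-cue network
#'
#' @param branch A [branch_config()] shared (in shape, not in weights) by
#'   the three cue branches.
#' @param n_classes Number of output classes of the softmax head.
#' @param mode `"classify"`, `"regress"`, or `"joint"` (both heads, losses
#'   summed unweighted during training).
#' @return An object of class `mceegnet_config`.
#' @export
mceegnet_config <- function(branch, n_classes = 2L, mode = c("classify", "regress", "joint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(branch, "branch_config"))
  n_classes <- as.integer(n_classes)
  if (mode != "regress" && n_classes < 2L) {
    stop_contract("n_classes must be >= 2 for classification")
  }
  structure(list(branch = branch, n_classes = n_classes, mode = mode),
            class = "mceegnet_config")
}

#' Length of the fused feature vector
#'
#' Closed form `3 * f2 * floor(floor(T / pool1) / pool2)`: the three
#' branches each emit `f2` maps of the twice-pooled time axis, flattened
#' and concatenated.
#'
#' @param cfg An [mceegnet_config()].
#' @return Integer feature length.
#' @export
feature_dim <- function(cfg) {
  b <- cfg$branch
  3L * b$f2 * ((b$n_samples %/% b$pool1) %/% b$pool2)
}

#' Number of trainable parameters
#'
#' Closed-form count under the branch convention (convolutions bias-free,
#' batch normalisation affine): per branch
#' `f1*k + 2*f1 + D*f1*C + 2*f2 + f2*sep_kernel + f2^2 + 2*f2`,
#' plus the head(s) on the fused feature vector.
#'
#' @param cfg An [mceegnet_config()].
#' @param per_branch If `TRUE`, return only the single-branch count.
#' @return Integer parameter count.
#' @export
count_parameters <- function(cfg, per_branch = FALSE) {
  b <- cfg$branch
  branch_n <- b$f1 * b$temporal_kernel + 2L * b$f1 +
    b$depth_multiplier * b$f1 * b$n_channels + 2L * b$f2 +
    b$f2 * b$sep_kernel + b$f2^2 + 2L * b$f2
  if (per_branch) return(as.integer(branch_n))
  fd <- feature_dim(cfg)
  head_n <- switch(cfg$mode,
    classify = cfg$n_classes * fd + cfg$n_classes,
    regress = fd + 1L,
    joint = cfg$n_classes * fd + cfg$n_classes + fd + 1L
  )
  as.integer(3L * branch_n + head_n)
}

init_branch_params <- function(b) {
  k <- b$temporal_kernel
  list(
    W_temp = glorot_uniform(k, k * b$f1, c(b$f1, k)),
    bn1_gamma = rep(1, b$f1), bn1_beta = rep(0, b$f1),
    W_dw = glorot_uniform(b$n_channels, b$depth_multiplier * b$n_channels,
                          c(b$depth_multiplier, b$n_channels, b$f1)),
    bn2_gamma = rep(1, b$f2), bn2_beta = rep(0, b$f2),
    W_sepd = glorot_uniform(b$sep_kernel, b$sep_kernel, c(b$f2, b$sep_kernel)),
    W_sepp = glorot_uniform(b$f2, b$f2, c(b$f2, b$f2)),
    bn3_gamma = rep(1, b$f2), bn3_beta = rep(0, b$f2)
  )
}

#' Build a multi-cue network with deterministic initialisation
#'
#' Weights are drawn Glorot-uniform under the given seed (restored
#' afterwards), so the same seed yields bit-identical parameters. The three
#' branches have independent weights.
#'
#' @param cfg An [mceegnet_config()].
#' @param seed Integer seed controlling parameter initialisation.
#' @return An object of class `mceegnet_model`: configuration, a flat named
#'   parameter list, and per-branch batch-norm running statistics.
#' @export
build_model <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "mceegnet_config"))
  b <- cfg$branch
  params <- list()
  with_seed(seed, {
    for (br in BRANCH_NAMES) {
      bp <- init_branch_params(b)
      names(bp) <- paste(br, names(bp), sep = ".")
      params <- c(params, bp)
    }
    fd <- feature_dim(cfg)
    if (cfg$mode %in% c("classify", "joint")) {
      params$W_cls <- glorot_uniform(fd, cfg$n_classes, c(cfg$n_classes, fd))
      params$b_cls <- rep(0, cfg$n_classes)
    }
    if (cfg$mode %in% c("regress", "joint")) {
      params$W_reg <- glorot_uniform(fd, 1, c(fd))
      params$b_reg <- 0
    }
  })
  bn <- lapply(stats::setNames(BRANCH_NAMES, BRANCH_NAMES), function(br) {
    list(mean1 = rep(0, b$f1), var1 = rep(1, b$f1),
         mean2 = rep(0, b$f2), var2 = rep(1, b$f2),
         mean3 = rep(0, b$f2), var3 = rep(1, b$f2))
  })
  # workspace holding per-branch activation caches, reused across steps
  ws <- new.env(parent = emptyenv())
  structure(list(cfg = cfg, params = params, bn = bn, ws = ws),
            class = "mceegnet_model")
}

#' @export
print.mceegnet_model <- function(x, ...) {
  b <- x$cfg$branch
  cat(sprintf("Multi-cue EEG network (%s)\n", x$cfg$mode))
  cat(sprintf("  branches: 3 x EEGNet(C=%d, T=%d, f1=%d, D=%d, f2=%d)\n",
              b$n_channels, b$n_samples, b$f1, b$depth_multiplier, b$f2))
  cat(sprintf("  fused feature length: %d\n", feature_dim(x$cfg)))
  cat(sprintf("  trainable parameters: %d (%d per branch)\n",
              count_parameters(x$cfg), count_parameters(x$cfg, per_branch = TRUE)))
  invisible(x)
}

# ---- single-branch forward/backward --------------------------------------

branch_param_names <- c("W_temp", "bn1_gamma", "bn1_beta", "W_dw",
                        "bn2_gamma", "bn2_beta", "W_sepd", "W_sepp",
                        "bn3_gamma", "bn3_beta")

branch_params <- function(model, br) {
  bp <- model$params[paste(br, branch_param_names, sep = ".")]
  names(bp) <- branch_param_names
  bp
}

# Thin wrappers over the compiled branch pass (src/branch.cpp).
branch_forward <- function(p, st, X, b, train, reuse = NULL) {
  p$pool1 <- b$pool1
  p$pool2 <- b$pool2
  branch_fwd_cpp(X, p, st, train, b$dropout_p, reuse)
}

branch_backward <- function(p, b, cache, dF, train, need_input_grad = FALSE) {
  p$pool1 <- b$pool1
  p$pool2 <- b$pool2
  branch_bwd_cpp(cache, p, dF, need_input_grad)
}


# ---- full-model forward/backward ------------------------------------------

check_batch_dims <- function(cfg, batch) {
  b <- cfg$branch
  for (cue in c("x_happy", "x_fear", "x_sad")) {
    d <- dim(batch[[cue]])
    if (length(d) != 3L) stop_contract("%s must be a [trials x channels x samples] array", cue)
    if (d[2L] != b$n_channels) {
      stop_contract("%s has %d channels but the model expects %d", cue, d[2L], b$n_channels)
    }
    if (d[3L] != b$n_samples) {
      stop_contract("%s has %d samples but the model expects %d", cue, d[3L], b$n_samples)
    }
  }
  n <- vapply(c("x_happy", "x_fear", "x_sad"), function(cue) dim(batch[[cue]])[1L], 0)
  if (length(unique(n)) != 1L) stop_contract("cue arrays disagree on trial count")
  invisible(n[[1L]])
}

mceegnet_forward_full <- function(model, batch, train) {
  check_batch_dims(model$cfg, batch)
  b <- model$cfg$branch
  xs <- list(happy = batch$x_happy, fear = batch$x_fear, sad = batch$x_sad)
  outs <- list(); caches <- list(); states <- list()
  for (br in BRANCH_NAMES) {
    bp <- branch_params(model, br)
    fwd <- branch_forward(bp, model$bn[[br]], xs[[br]], b, train,
                          reuse = model$ws[[br]])
    model$ws[[br]] <- fwd$cache
    outs[[br]] <- fwd$out
    caches[[br]] <- fwd$cache
    states[[br]] <- fwd$state
  }
  Fcat <- cbind(outs$happy, outs$fear, outs$sad)
  res <- list(features = Fcat, caches = caches, states = states)
  if (model$cfg$mode %in% c("classify", "joint")) {
    logits <- Fcat %*% t(model$params$W_cls)
    logits <- sweep(logits, 2L, model$params$b_cls, `+`)
    res$logits <- logits
    res$class_probs <- softmax_rows(logits)
  }
  if (model$cfg$mode %in% c("regress", "joint")) {
    res$scores <- as.vector(Fcat %*% model$params$W_reg + model$params$b_reg)
  }
  res
}

#' Run the network on a batch of cue triplets
#'
#' @param model An `mceegnet_model` from [build_model()].
#' @param batch A [cue_triplet_batch()].
#' @param train_mode If `TRUE`, batch statistics and dropout are active
#'   (stochastic); with `FALSE` (default) the pass is a deterministic
#'   function of parameters and input, using running batch-norm statistics.
#' @return A list with `class_probs` (rows summing to one) and/or `scores`
#'   (predictions on the normalised label scale), according to the model
#'   mode.
#' @export
forward <- function(model, batch, train_mode = FALSE) {
  stopifnot(inherits(model, "mceegnet_model"))
  res <- mceegnet_forward_full(model, batch, train = train_mode)
  out <- list()
  if (!is.null(res$class_probs)) out$class_probs <- res$class_probs
  if (!is.null(res$scores)) out$scores <- res$scores
  out
}

#' @export
predict.mceegnet_model <- function(object, batch, ...) {
  forward(object, batch, train_mode = FALSE)
}

# Backward pass through heads and branches; returns a flat gradient list
# aligned with model$params.
mceegnet_backward <- function(model, full, dF_head, train) {
  cfg <- model$cfg
  b <- cfg$branch
  fd1 <- feature_dim(cfg) %/% 3L
  grads <- list()
  if (!is.null(dF_head$dlogits)) {
    grads$W_cls <- t(dF_head$dlogits) %*% full$features
    grads$b_cls <- colSums(dF_head$dlogits)
  }
  if (!is.null(dF_head$dscores)) {
    grads$W_reg <- as.vector(crossprod(full$features, dF_head$dscores))
    grads$b_reg <- sum(dF_head$dscores)
  }
  dFcat <- matrix(0, nrow(full$features), ncol(full$features))
  if (!is.null(dF_head$dlogits)) {
    dFcat <- dFcat + dF_head$dlogits %*% model$params$W_cls
  }
  if (!is.null(dF_head$dscores)) {
    dFcat <- dFcat + outer(dF_head$dscores, model$params$W_reg)
  }
  for (i in seq_along(BRANCH_NAMES)) {
    br <- BRANCH_NAMES[i]
    bp <- branch_params(model, br)
    dF <- dFcat[, (i - 1L) * fd1 + seq_len(fd1), drop = FALSE]
    bb <- branch_backward(bp, b, full$caches[[br]], dF, train)
    names(bb$grads) <- paste(br, names(bb$grads), sep = ".")
    grads <- c(grads, bb$grads)
  }
  grads
}
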