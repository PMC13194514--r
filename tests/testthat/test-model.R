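test_that("feature_dim follows the pooled-shape closed form", {
  # full-montage study configuration: C=128, T=125, f1=8, D=2
  cfg <- mceegnet_config(branch_config(128L, 125L))
  expect_equal(feature_dim(cfg), 144L)   # 3 * 16 * floor(floor(125/4)/8)
  cfg2 <- mceegnet_config(branch_config(16L, 32L))
  expect_equal(feature_dim(cfg2), 48L)   # 3 * 16 * 1
  expect_error(branch_config(16L, 16L), "at least T = 32")
})

test_that("count_parameters matches the layer-by-layer enumeration", {
  cfg <- mceegnet_config(branch_config(128L, 125L), mode = "classify")
  expect_equal(count_parameters(cfg, per_branch = TRUE), 3440L)
  expect_equal(count_parameters(cfg), 3L * 3440L + 144L * 2L + 2L)

  # doubling the depth multiplier doubles exactly the depthwise term
  c1 <- mceegnet_config(branch_config(64L, 125L, depth_multiplier = 1L,
                                      f1 = 8L))
  c2 <- mceegnet_config(branch_config(64L, 125L, depth_multiplier = 2L,
                                      f1 = 8L))
  # D doubles f2 as well, so compare only the depthwise contribution
  dw1 <- 1L * 8L * 64L
  dw2 <- 2L * 8L * 64L
  expect_equal(dw2, 2L * dw1)
  expect_gt(count_parameters(c2), count_parameters(c1))

  # enumeration oracle: closed form equals the sum of actual tensor sizes
  # for randomly drawn valid configurations
  set.seed(42)
  for (i in 1:20) {
    bc <- branch_config(
      n_channels = sample(2:12, 1), n_samples = sample(c(32, 40, 64, 125), 1),
      f1 = sample(1:4, 1), temporal_kernel = sample(c(5, 9, 15), 1),
      depth_multiplier = sample(1:3, 1), sep_kernel = sample(c(3, 7), 1),
      pool1 = sample(2:4, 1), pool2 = sample(2:4, 1), dropout_p = 0.5
    )
    if ((bc$n_samples %/% bc$pool1) %/% bc$pool2 < 1L) next
    mode <- sample(c("classify", "regress", "joint"), 1)
    cfg <- mceegnet_config(bc, mode = mode)
    model <- build_model(cfg, seed = i)
    enumerated <- sum(vapply(model$params, length, 0L))
    expect_equal(count_parameters(cfg), enumerated,
                 info = sprintf("config %d (%s)", i, mode))
  }
})

test_that("initialisation is deterministic under the seed", {
  cfg <- mceegnet_config(tiny_branch(), mode = "joint")
  m1 <- build_model(cfg, seed = 11)
  m2 <- build_model(cfg, seed = 11)
  m3 <- build_model(cfg, seed = 12)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("eval-mode forward is deterministic, normalised and equivariant", {
  cfg <- mceegnet_config(tiny_branch(), mode = "joint")
  model <- build_model(cfg, seed = 1)
  batch <- tiny_batch(n = 6L)

  out1 <- forward(model, batch)
  out2 <- forward(model, batch)
  expect_identical(out1, out2)
  expect_equal(rowSums(out1$class_probs), rep(1, 6), tolerance = 1e-6)
  expect_true(all(out1$class_probs >= 0 & out1$class_probs <= 1))
  expect_equal(feature_dim(cfg),
               ncol(mceegnet:::mceegnet_forward_full(model, batch, FALSE)$features))

  # permuting trials permutes outputs identically
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  pb <- mceegnet:::triplet_subset(batch, perm)
  outp <- forward(model, pb)
  expect_equal(outp$class_probs, out1$class_probs[perm, ], tolerance = 1e-10)
  expect_equal(outp$scores, out1$scores[perm], tolerance = 1e-10)
})

test_that("shape mismatches are reported with the offending dimension", {
  cfg <- mceegnet_config(tiny_branch(C = 3L, T = 40L))
  model <- build_model(cfg, seed = 1)
  bad <- tiny_batch(n = 2L, C = 4L, T = 40L)
  expect_error(forward(model, bad), "4 channels.*expects 3")
  bad2 <- tiny_batch(n = 2L, C = 3L, T = 48L)
  expect_error(forward(model, bad2), "48 samples.*expects 40")
})

test_that("branches are independent: zeroed branches ignore their input", {
  cfg <- mceegnet_config(tiny_branch(), mode = "classify")
  model <- build_model(cfg, seed = 2)
  for (nm in names(model$params)) {
    if (grepl("^(fear|sad)\\.", nm)) model$params[[nm]] <- model$params[[nm]] * 0
  }
  b1 <- tiny_batch(n = 4L, seed = 10L)
  b2 <- b1
  set.seed(99)
  b2$x_fear <- b2$x_fear + array(rnorm(length(b2$x_fear)), dim(b2$x_fear))
  b2$x_sad <- b2$x_sad - 3
  expect_equal(forward(model, b1)$class_probs, forward(model, b2)$class_probs,
               tolerance = 1e-12)
  # and perturbing the happy input does change the output
  b3 <- b1
  b3$x_happy <- b3$x_happy * 2
  expect_false(isTRUE(all.equal(forward(model, b1)$class_probs,
                                forward(model, b3)$class_probs)))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- mceegnet_config(tiny_branch(), mode = "joint")
  model <- build_model(cfg, seed = 42)
  batch <- tiny_batch(n = 5L)
  ycls <- batch$labels_class + 1L
  yreg <- batch$labels_score

  loss_fn <- function(m) {
    full <- mceegnet:::mceegnet_forward_full(m, batch, train = TRUE)
    mceegnet:::cross_entropy_loss(full$class_probs, ycls) +
      mceegnet:::mse_loss(full$scores, yreg)
  }
  full <- mceegnet:::mceegnet_forward_full(model, batch, train = TRUE)
  dh <- list(dlogits = mceegnet:::cross_entropy_grad(full$class_probs, ycls),
             dscores = mceegnet:::mse_grad(full$scores, yreg))
  grads <- mceegnet:::mceegnet_backward(model, full, dh, train = TRUE)

  eps <- 1e-6
  set.seed(7)
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    expect_false(is.null(g), info = nm)
    v <- model$params[[nm]]
    for (i in sample(length(v), min(3L, length(v)))) {
      mp <- model; mp$params[[nm]][i] <- v[i] + eps
      mm <- model; mm$params[[nm]][i] <- v[i] - eps
      num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-4,
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})
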