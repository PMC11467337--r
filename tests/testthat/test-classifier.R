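test_that("parameter count: closed form equals a brute-force layer walk", {
  # the smallest convolution oracle: 3x3x3, 4 -> 8 channels with bias
  expect_identical(27L * 4L * 8L + 8L, 872L)
  set.seed(20)
  for (i in 1:3) {
    arch <- arch_config(
      input_shape = c(16, 16, 8) * sample(1:2, 1),
      n_stages = sample(1:2, 1),
      base_channels = sample(c(4, 6, 8), 1),
      bottleneck_reduction = sample(2:4, 1),
      latent_dim = sample(c(8, 16, 32), 1))
    model <- build_network(arch, seed = i)
    walk <- sum(vapply(model$params, length, 0L))
    expect_identical(count_parameters(arch), as.integer(walk))
  }
})

test_that("indivisible input shapes are rejected before allocation", {
  expect_error(arch_config(input_shape = c(30, 32, 16), n_stages = 2),
               "divisible")
})

test_that("forward pass honours the shape contract and is deterministic", {
  arch <- arch_tiny(input_shape = c(16, 16, 8), base_channels = 4,
                    latent_dim = 7)
  model <- build_network(arch, seed = 2)
  set.seed(3)
  x <- array(rnorm(16 * 16 * 8 * 1 * 3), c(16, 16, 8, 1, 3))
  fw1 <- holoblast:::nn_forward(model, x, keep_cache = FALSE)
  fw2 <- holoblast:::nn_forward(model, x, keep_cache = FALSE)
  expect_identical(dim(fw1$logits), c(3L, 2L))
  expect_identical(dim(fw1$latent), c(3L, 7L))
  expect_identical(fw1$logits, fw2$logits)
})

test_that("backpropagation matches finite differences", {
  arch <- arch_config(input_shape = c(8, 8, 4), n_stages = 1,
                      base_channels = 3, bottleneck_reduction = 2,
                      latent_dim = 5)
  model <- build_network(arch, seed = 3)
  set.seed(1)
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 1, 2))
  y <- c(1L, 2L)
  w <- c(2, 1)
  fw <- holoblast:::nn_forward(model, x)
  ls <- holoblast:::weighted_softmax_ce(fw$logits, y, w)
  grads <- holoblast:::nn_backward(model, fw, ls$dlogits)
  loss_at <- function(params) {
    m2 <- model
    m2$params <- params
    f <- holoblast:::nn_forward(m2, x, keep_cache = FALSE)
    holoblast:::weighted_softmax_ce(f$logits, y, w)$loss
  }
  set.seed(7)
  errs <- vapply(1:20, function(t) {
    nm <- sample(names(grads), 1)
    i <- sample(length(model$params[[nm]]), 1)
    eps <- 1e-5
    pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    an <- grads[[nm]][i]
    abs(fd - an) / max(abs(fd), abs(an), 1e-8)
  }, 0)
  # two noise sources bound the attainable agreement: max-pool argmax
  # switches under perturbation, and single-precision convolution kernels
  # whose rounding is amplified by the finite-difference step
  expect_lt(median(errs), 1e-4)
  expect_lt(max(errs), 0.05)
})

test_that("weighted cross-entropy matches hand-computed values", {
  logits <- rbind(c(0.2, -0.1), c(-1.5, 2.0))
  y <- c(1L, 2L)
  w <- c(2, 1)
  p1 <- exp(0.2) / (exp(0.2) + exp(-0.1))
  p2 <- exp(2.0) / (exp(-1.5) + exp(2.0))
  by_hand <- (2 * (-log(p1)) + 1 * (-log(p2))) / 3
  ls <- holoblast:::weighted_softmax_ce(logits, y, w)
  expect_equal(ls$loss, by_hand, tolerance = 1e-6)
  # balanced weights degenerate to the unweighted mean cross-entropy
  ls_eq <- holoblast:::weighted_softmax_ce(logits, y, c(1, 1))
  expect_equal(ls_eq$loss, (-log(p1) - log(p2)) / 2, tolerance = 1e-12)
})

test_that("augmentation identities hold", {
  set.seed(4)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  cfg <- train_config(aug_noise_sd = 0)
  # no-op parameters give the identity
  same <- augment_volume(x, cfg, translate = c(0, 0, 0), rotate_deg = 0,
                         flip = c(x = FALSE, y = FALSE))
  expect_identical(same, x)
  # flips are involutions
  f1 <- augment_volume(x, cfg, translate = c(0, 0, 0), rotate_deg = 0,
                       flip = c(x = TRUE, y = FALSE))
  f2 <- augment_volume(f1, cfg, translate = c(0, 0, 0), rotate_deg = 0,
                       flip = c(x = TRUE, y = FALSE))
  expect_identical(f2, x)
  # overlong translations are clipped with a warning
  expect_warning(augment_volume(x, cfg, translate = c(9, 0, 0),
                                rotate_deg = 0,
                                flip = c(x = FALSE, y = FALSE)),
                 "clipped")
})

test_that("a 90-degree rotation transposes an axis-aligned bar", {
  x <- array(0, c(21, 21, 4))
  x[6:16, 10:12, ] <- 1   # bar along x
  r <- holoblast:::rotate_z(x, 90)
  expect_lt(abs(sum(r) / sum(x) - 1), 0.01)
  # the long axis moves from x to y
  ext <- function(m) apply(which(m > 0.5, arr.ind = TRUE), 2, function(v)
    diff(range(v)))
  expect_gt(ext(x)[1], ext(x)[2])
  expect_gt(ext(r)[2], ext(r)[1])
})

test_that("prediction is deterministic with the conservative tie rule", {
  expect_identical(holoblast:::logits_to_label(rbind(c(0.3, 0.7))), "MUT")
  expect_identical(holoblast:::logits_to_label(rbind(c(0.7, 0.3))), "WT")
  expect_identical(holoblast:::logits_to_label(rbind(c(0.5, 0.5))), "WT")
  arch <- arch_tiny(input_shape = c(16, 16, 8), base_channels = 4)
  model <- build_network(arch, seed = 5)
  model$config <- train_config()
  set.seed(6)
  v <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  p1 <- predict_classifier(model, list(a = v))
  p2 <- predict_classifier(model, list(a = v))
  expect_identical(p1, p2)
  # volumes are conformed to the input shape before inference
  big <- array(rnorm(20 * 18 * 10), c(20, 18, 10))
  expect_silent(predict_classifier(model, list(b = big)))
})

test_that("single-class training data are rejected", {
  vols <- list(a = array(0, c(8, 8, 4)), b = array(0, c(8, 8, 4)))
  expect_error(
    train_classifier(vols, c(a = "WT", b = "WT"),
                     c(a = "optimization", b = "optimization"),
                     arch_tiny(input_shape = c(8, 8, 4))),
    "both classes")
})

test_that("downsampling averages blocks and preserves totals", {
  x <- array(seq_len(4 * 4 * 2), c(4, 4, 2))
  d <- downsample_volume(x, 2)
  expect_identical(dim(d), c(2L, 2L, 1L))
  expect_equal(sum(d) * 8, sum(x))
})
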