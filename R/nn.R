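#' Architecture configuration for the tail-body-head 3D CNN
#'
#' The network follows a multi-resolution feature-preserving design: a tail
#' that downsamples (2x2x2 max pooling), a body that upsamples (2x2x2
#' nearest neighbour) and concatenates each upsampled map with the first
#' equal-resolution tail features, and a head that downsamples again.
#' Residual bottleneck blocks (1x1x1 shortcut summed with a
#' 1x1x1 -> 3x3x3 -> 1x1x1 reduced-channel path) precede every pooling or
#' upsampling step, and every convolution is preceded by instance
#' normalization and leaky-ReLU pre-activation. Global average pooling feeds
#' a latent feature layer ahead of the two-class output. Channel widths and
#' stage counts are configurable; the published network's exact widths are
#' not public, so presets target the described topology at chosen scale.
#'
#' @param input_shape Spatial input dimensions, default `c(160, 160, 72)`;
#'   test preset `c(32, 32, 16)`.
#' @param n_stages Stages per component (tail = body = head), default 3.
#' @param base_channels Channels after the initial convolution, default 16.
#' @param bottleneck_reduction Channel reduction factor inside residual
#'   bottlenecks, default 4 (the classic bottleneck convention).
#' @param latent_dim Dimension of the feature layer before the output
#'   (default 264).
#' @param leaky_slope Negative slope of the leaky ReLU, default 0.1.
#' @return An `arch_config` object.
#' @export
arch_config <- function(input_shape = c(160, 160, 72), n_stages = 3,
                        base_channels = 16, bottleneck_reduction = 4,
                        latent_dim = 264, leaky_slope = 0.1) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3, n_stages >= 1, base_channels >= 1,
            bottleneck_reduction >= 1, latent_dim >= 2)
  if (any(input_shape %% (2^n_stages) != 0))
    stop("input_shape must be divisible by 2^n_stages (pooling factor)")
  structure(list(input_shape = input_shape, n_stages = as.integer(n_stages),
                 base_channels = as.integer(base_channels),
                 bottleneck_reduction = as.integer(bottleneck_reduction),
                 latent_dim = as.integer(latent_dim),
                 leaky_slope = leaky_slope),
            class = "arch_config")
}

#' Tiny architecture preset for CPU-scale experiments
#' @param input_shape Spatial input dimensions, default `c(32, 32, 16)`.
#' @param n_stages,base_channels,latent_dim Reduced-scale defaults.
#' @param ... Further overrides passed to [arch_config()].
#' @export
arch_tiny <- function(input_shape = c(32, 32, 16), n_stages = 1,
                      base_channels = 8, latent_dim = 16, ...) {
  arch_config(input_shape = input_shape, n_stages = n_stages,
              base_channels = base_channels,
              bottleneck_reduction = 4, latent_dim = latent_dim, ...)
}

# ---- plan construction -----------------------------------------------------
# A model plan is an ordered op list; each op names its input/output buffers
# so the executor can run forward and reverse passes generically.
plan_op <- function(type, name, inputs, output, cin = NULL, cout = NULL) {
  list(type = type, name = name, inputs = inputs, output = output,
       cin = cin, cout = cout)
}

# pre-activated conv: instance norm + leaky relu + conv(k)
plan_preact_conv <- function(plan, name, input, output, cin, cout, k) {
  plan[[length(plan) + 1]] <- plan_op("inorm", paste0(name, "_in"),
                                      input, paste0(name, "_n"), cin, cin)
  plan[[length(plan) + 1]] <- plan_op("lrelu", paste0(name, "_act"),
                                      paste0(name, "_n"), paste0(name, "_a"))
  plan[[length(plan) + 1]] <- plan_op(
    if (k == 3) "conv3" else "conv1", name, paste0(name, "_a"), output,
    cin, cout)
  plan
}

# residual bottleneck: shortcut conv1 + (conv1 -> conv3 -> conv1), summed
plan_block <- function(plan, name, input, output, cin, cout, red) {
  cmid <- max(1L, cout %/% red)
  plan <- plan_preact_conv(plan, paste0(name, "_sc"), input,
                           paste0(name, "_s"), cin, cout, 1)
  plan <- plan_preact_conv(plan, paste0(name, "_r1"), input,
                           paste0(name, "_m1"), cin, cmid, 1)
  plan <- plan_preact_conv(plan, paste0(name, "_r2"), paste0(name, "_m1"),
                           paste0(name, "_m2"), cmid, cmid, 3)
  plan <- plan_preact_conv(plan, paste0(name, "_r3"), paste0(name, "_m2"),
                           paste0(name, "_m3"), cmid, cout, 1)
  plan[[length(plan) + 1]] <- plan_op(
    "add", paste0(name, "_sum"), c(paste0(name, "_s"), paste0(name, "_m3")),
    output)
  plan
}

build_plan <- function(arch) {
  B <- arch$base_channels
  S <- arch$n_stages
  red <- arch$bottleneck_reduction
  plan <- list()
  plan[[1]] <- plan_op("conv3", "init", "input", "x_t0", 1L, B)
  ch <- B
  tail_ch <- integer(S)
  for (s in seq_len(S)) {
    cout <- B * 2^s
    plan <- plan_block(plan, sprintf("tail%d", s), sprintf("x_t%d", s - 1),
                       sprintf("t%d", s), ch, cout, red)
    tail_ch[s] <- cout
    plan[[length(plan) + 1]] <- plan_op("maxpool", sprintf("pool%d", s),
                                        sprintf("t%d", s),
                                        sprintf("x_t%d", s))
    ch <- cout
  }
  plan <- plan_block(plan, "bridge", sprintf("x_t%d", S), "x_b", ch, ch, red)
  cur <- "x_b"
  for (s in rev(seq_len(S))) {
    cout <- max(B, B * 2^(s - 1))
    plan <- plan_block(plan, sprintf("body%d", s), cur,
                       sprintf("b%d", s), ch, cout, red)
    plan[[length(plan) + 1]] <- plan_op("upsample", sprintf("up%d", s),
                                        sprintf("b%d", s),
                                        sprintf("bu%d", s))
    first_ch <- if (s == 1) B else B * 2^(s - 1)
    plan[[length(plan) + 1]] <- plan_op(
      "concat", sprintf("cat%d", s),
      c(sprintf("bu%d", s), sprintf("x_t%d", s - 1)), sprintf("x_c%d", s),
      cout, cout + first_ch)
    ch <- cout + first_ch
    cur <- sprintf("x_c%d", s)
  }
  for (s in seq_len(S)) {
    cout <- B * 2^s
    plan <- plan_block(plan, sprintf("head%d", s), cur,
                       sprintf("h%d", s), ch, cout, red)
    plan[[length(plan) + 1]] <- plan_op("maxpool", sprintf("hpool%d", s),
                                        sprintf("h%d", s),
                                        sprintf("x_h%d", s))
    ch <- cout
    cur <- sprintf("x_h%d", s)
  }
  # no normalization between the last block and the pooling: instance norm
  # would standardize away per-sample magnitude information (compartment
  # volume, total contrast) that global pooling is meant to read out
  plan[[length(plan) + 1]] <- plan_op("gap", "gap", cur, "pooled")
  plan[[length(plan) + 1]] <- plan_op("dense", "latent", "pooled", "latent",
                                      ch, arch$latent_dim)
  plan[[length(plan) + 1]] <- plan_op("lrelu", "latent_act", "latent",
                                      "latent_a")
  plan[[length(plan) + 1]] <- plan_op("dense", "output", "latent_a",
                                      "logits", arch$latent_dim, 2L)
  plan
}

# ---- parameters ------------------------------------------------------------
init_params <- function(plan, seed = NULL) {
  with_seed(seed, {
    params <- list()
    for (op in plan) {
      nm <- op$name
      if (op$type == "conv3") {
        fan_in <- 27 * op$cin
        params[[paste0(nm, ".W")]] <-
          matrix(rnorm(fan_in * op$cout, 0, sqrt(2 / fan_in)),
                 fan_in, op$cout)
        params[[paste0(nm, ".b")]] <- numeric(op$cout)
      } else if (op$type == "conv1") {
        params[[paste0(nm, ".W")]] <-
          matrix(rnorm(op$cin * op$cout, 0, sqrt(2 / op$cin)),
                 op$cin, op$cout)
        params[[paste0(nm, ".b")]] <- numeric(op$cout)
      } else if (op$type == "inorm") {
        params[[paste0(nm, ".gamma")]] <- rep(1, op$cin)
        params[[paste0(nm, ".beta")]] <- numeric(op$cin)
      } else if (op$type == "dense") {
        params[[paste0(nm, ".W")]] <-
          matrix(rnorm(op$cin * op$cout, 0, sqrt(2 / op$cin)),
                 op$cin, op$cout)
        params[[paste0(nm, ".b")]] <- numeric(op$cout)
      }
    }
    params
  })
}

#' Build the 3D CNN classifier
#'
#' Instantiates the network for an architecture configuration and reports
#' its parameter count (closed-form, from the configuration arithmetic; the
#' allocated tensors are checked against it).
#'
#' @param arch An [arch_config()].
#' @param seed Seed for weight initialization.
#' @return An object of class `ht_classifier`: list with `arch`, `plan`,
#'   `params`, `n_parameters`.
#' @export
build_network <- function(arch, seed = 1) {
  stopifnot(inherits(arch, "arch_config"))
  plan <- build_plan(arch)
  params <- init_params(plan, seed = seed)
  n_closed <- count_parameters(arch)
  n_alloc <- sum(vapply(params, length, 0L))
  if (n_closed != n_alloc)
    stop(sprintf("internal: closed-form parameter count %d != allocated %d",
                 n_closed, n_alloc))
  structure(list(arch = arch, plan = plan, params = params,
                 n_parameters = n_closed),
            class = "ht_classifier")
}

#' @export
print.ht_classifier <- function(x, ...) {
  a <- x$arch
  cat(sprintf(
    "<ht_classifier> input %s, %d stage(s)/component, base %d ch, latent %d\n",
    paste(a$input_shape, collapse = "x"), a$n_stages, a$base_channels,
    a$latent_dim))
  cat(sprintf("  %s parameters, %d ops\n",
              format(x$n_parameters, big.mark = ","), length(x$plan)))
  invisible(x)
}

#' Closed-form parameter count of an architecture
#'
#' Sums the analytic per-layer formulas (k^3 * cin * cout + cout per
#' convolution, 2c per instance norm, cin * cout + cout per dense layer)
#' over the configured topology without allocating any tensor.
#'
#' @param arch An [arch_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(arch) {
  conv_p <- function(k, cin, cout) k^3 * cin * cout + cout
  preact_p <- function(k, cin, cout) 2 * cin + conv_p(k, cin, cout)
  block_p <- function(cin, cout, red) {
    cmid <- max(1, cout %/% red)
    preact_p(1, cin, cout) + preact_p(1, cin, cmid) +
      preact_p(3, cmid, cmid) + preact_p(1, cmid, cout)
  }
  B <- arch$base_channels
  S <- arch$n_stages
  red <- arch$bottleneck_reduction
  total <- conv_p(3, 1, B)
  ch <- B
  tail_ch <- integer(S)
  for (s in seq_len(S)) {
    cout <- B * 2^s
    total <- total + block_p(ch, cout, red)
    tail_ch[s] <- cout
    ch <- cout
  }
  total <- total + block_p(ch, ch, red)
  for (s in rev(seq_len(S))) {
    cout <- max(B, B * 2^(s - 1))
    total <- total + block_p(ch, cout, red)
    ch <- cout + (if (s == 1) B else B * 2^(s - 1))
  }
  for (s in seq_len(S)) {
    cout <- B * 2^s
    total <- total + block_p(ch, cout, red)
    ch <- cout
  }
  total <- total + ch * arch$latent_dim + arch$latent_dim
  total <- total + arch$latent_dim * 2 + 2
  as.integer(total)
}

# ---- forward / backward ----------------------------------------------------
INORM_EPS <- 1e-5

nn_forward <- function(model, x, keep_cache = TRUE) {
  slope <- model$arch$leaky_slope
  params <- model$params
  buf <- list(input = x)
  cache <- list()
  for (op in model$plan) {
    nm <- op$name
    xin <- buf[[op$inputs[1]]]
    out <- switch(op$type,
      conv3 = {
        d5 <- dim(xin)
        if (keep_cache) cache[[nm]] <- list(x = xin)
        .conv3_fw(xin, d5, params[[paste0(nm, ".W")]],
                  params[[paste0(nm, ".b")]])
      },
      conv1 = {
        d5 <- dim(xin)
        if (keep_cache) cache[[nm]] <- list(x = xin)
        .conv1_fw(xin, d5, params[[paste0(nm, ".W")]],
                  params[[paste0(nm, ".b")]])
      },
      inorm = {
        d5 <- dim(xin)
        r <- .inorm_fw(xin, d5, params[[paste0(nm, ".gamma")]],
                       params[[paste0(nm, ".beta")]], INORM_EPS)
        if (keep_cache) cache[[nm]] <- list(x = xin, mu = r$mu,
                                            istd = r$istd, d5 = d5)
        r$y
      },
      lrelu = {
        if (keep_cache) cache[[nm]] <- list(x = xin)
        .lrelu_fw(xin, slope)
      },
      maxpool = {
        r <- .maxpool3_fw(xin, dim(xin))
        if (keep_cache) cache[[nm]] <- list(idx = r$idx,
                                            n_in = length(xin),
                                            d5 = dim(xin))
        r$y
      },
      upsample = {
        if (keep_cache) cache[[nm]] <- list(d5 = dim(xin))
        .upsample3_fw(xin, dim(xin))
      },
      concat = {
        x2 <- buf[[op$inputs[2]]]
        d1 <- dim(xin)
        d2 <- dim(x2)
        y <- array(0, c(d1[1:3], d1[4] + d2[4], d1[5]))
        y[, , , seq_len(d1[4]), ] <- xin
        y[, , , d1[4] + seq_len(d2[4]), ] <- x2
        if (keep_cache) cache[[nm]] <- list(c1 = d1[4], c2 = d2[4])
        y
      },
      add = buf[[op$inputs[1]]] + buf[[op$inputs[2]]],
      gap = {
        d5 <- dim(xin)
        nvox <- prod(d5[1:3])
        if (keep_cache) cache[[nm]] <- list(d5 = d5)
        t(matrix(colMeans(matrix(xin, nvox, d5[4] * d5[5])), d5[4], d5[5]))
      },
      dense = {
        if (keep_cache) cache[[nm]] <- list(x = xin)
        sweep(xin %*% params[[paste0(nm, ".W")]], 2,
              params[[paste0(nm, ".b")]], `+`)
      },
      stop("unknown op type: ", op$type))
    buf[[op$output]] <- out
  }
  list(logits = buf$logits, latent = buf$latent_a, buf = buf, cache = cache)
}

nn_backward <- function(model, fw, dlogits) {
  slope <- model$arch$leaky_slope
  params <- model$params
  grads <- list()
  dbuf <- list(logits = dlogits)
  take <- function(name) {
    g <- dbuf[[name]]
    if (is.null(g)) stop("missing gradient for buffer ", name)
    g
  }
  accum <- function(name, g) {
    cur <- dbuf[[name]]
    dbuf[[name]] <<- if (is.null(cur)) g else cur + g
  }
  for (op in rev(model$plan)) {
    nm <- op$name
    dy <- dbuf[[op$output]]
    if (is.null(dy)) next
    switch(op$type,
      conv3 = {
        x <- fw$cache[[nm]]$x
        r <- .conv3_bw(x, dim(x), params[[paste0(nm, ".W")]], dy)
        grads[[paste0(nm, ".W")]] <- r$dW
        grads[[paste0(nm, ".b")]] <- as.numeric(r$db)
        accum(op$inputs[1], r$dx)
      },
      conv1 = {
        x <- fw$cache[[nm]]$x
        r <- .conv1_bw(x, dim(x), params[[paste0(nm, ".W")]], dy)
        grads[[paste0(nm, ".W")]] <- r$dW
        grads[[paste0(nm, ".b")]] <- as.numeric(r$db)
        accum(op$inputs[1], r$dx)
      },
      inorm = {
        cc <- fw$cache[[nm]]
        r <- .inorm_bw(cc$x, cc$d5, params[[paste0(nm, ".gamma")]],
                       cc$mu, cc$istd, dy)
        grads[[paste0(nm, ".gamma")]] <- as.numeric(r$dgamma)
        grads[[paste0(nm, ".beta")]] <- as.numeric(r$dbeta)
        accum(op$inputs[1], r$dx)
      },
      lrelu = {
        accum(op$inputs[1], .lrelu_bw(fw$cache[[nm]]$x, dy, slope))
      },
      maxpool = {
        cc <- fw$cache[[nm]]
        dx <- .maxpool3_bw(dy, cc$idx, cc$n_in)
        dim(dx) <- cc$d5
        accum(op$inputs[1], dx)
      },
      upsample = {
        accum(op$inputs[1], .upsample3_bw(dy, fw$cache[[nm]]$d5))
      },
      concat = {
        cc <- fw$cache[[nm]]
        accum(op$inputs[1], dy[, , , seq_len(cc$c1), , drop = FALSE])
        accum(op$inputs[2],
              dy[, , , cc$c1 + seq_len(cc$c2), , drop = FALSE])
      },
      add = {
        accum(op$inputs[1], dy)
        accum(op$inputs[2], dy)
      },
      gap = {
        d5 <- fw$cache[[nm]]$d5
        nvox <- prod(d5[1:3])
        dxm <- matrix(0, nvox, d5[4] * d5[5])
        dxm[] <- rep(as.numeric(t(dy)), each = nvox) / nvox
        accum(op$inputs[1], array(dxm, d5))
      },
      dense = {
        x <- fw$cache[[nm]]$x
        grads[[paste0(nm, ".W")]] <- t(x) %*% dy
        grads[[paste0(nm, ".b")]] <- colSums(dy)
        accum(op$inputs[1], dy %*% t(params[[paste0(nm, ".W")]]))
      })
    dbuf[[op$output]] <- NULL
  }
  grads
}

# softmax cross-entropy with per-sample weights; returns loss and dlogits
weighted_softmax_ce <- function(logits, y, w) {
  # logits (N x 2), y in {1, 2}, w per-sample weights
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  n <- nrow(logits)
  ce <- -log(pmax(p[cbind(seq_len(n), y)], 1e-12))
  wsum <- sum(w)
  loss <- sum(w * ce) / wsum
  onehot <- matrix(0, n, 2)
  onehot[cbind(seq_len(n), y)] <- 1
  dlogits <- (p - onehot) * (w / wsum)
  list(loss = loss, dlogits = dlogits, prob = p)
}
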