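#' Training configuration for the genotype classifier
#'
#' Defaults follow the published optimization recipe: Adam with initial
#' learning rate 5e-4, decoupled weight decay 1e-4 (the natural reading of a
#' "learning rate decay" hyperparameter alongside Adam; a multiplicative
#' schedule is available via `lr_decay_mode`), first-moment decay 0.5,
#' second-moment decay 0.999, cosine annealing with a 32-epoch period, batch
#' size 16, and inverse-class-size loss weights. During every epoch each
#' training image is presented twice: once as acquired and once randomly
#' augmented (Gaussian noise, random translation, in-plane flips, rotation
#' about the optical axis).
#'
#' @param lr0 Initial learning rate.
#' @param weight_decay Decoupled weight decay coefficient (or multiplicative
#'   per-epoch decay when `lr_decay_mode = "multiplicative"`).
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param cosine_period Cosine annealing period in epochs.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training data (<= 200).
#' @param lr_decay_mode `"decoupled"` (default) or `"multiplicative"`.
#' @param aug_noise_sd Sd of additive Gaussian noise in normalized input
#'   units.
#' @param aug_max_translate Maximum |translation| per axis, voxels.
#' @param aug_flip_axes In-plane axes that may be mirrored (`"x"`, `"y"`;
#'   the optical axis is never flipped).
#' @param aug_rotate_deg Maximum |rotation| about z, degrees.
#' @param input_scale RI contrast divisor for input normalization
#'   (x = (RI - medium) / input_scale).
#' @param stop_when_perfect Stop early once optimization and generalization
#'   accuracy both reach 1 (the selection rule cannot improve further).
#' @param seed RNG seed for shuffling and augmentation.
#' @return A `train_config` object.
#' @export
train_config <- function(lr0 = 5e-4, weight_decay = 1e-4,
                         adam_beta1 = 0.5, adam_beta2 = 0.999,
                         cosine_period = 32, batch_size = 16,
                         epochs = 30, lr_decay_mode = c("decoupled",
                                                        "multiplicative"),
                         aug_noise_sd = 0.02, aug_max_translate = 2,
                         aug_flip_axes = c("x", "y"), aug_rotate_deg = 15,
                         input_scale = 0.04, stop_when_perfect = FALSE,
                         seed = 1) {
  lr_decay_mode <- match.arg(lr_decay_mode)
  stopifnot(lr0 > 0, epochs >= 1, epochs <= 200, batch_size >= 1)
  structure(list(lr0 = lr0, weight_decay = weight_decay,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 cosine_period = cosine_period, batch_size = batch_size,
                 epochs = as.integer(epochs),
                 lr_decay_mode = lr_decay_mode,
                 aug_noise_sd = aug_noise_sd,
                 aug_max_translate = aug_max_translate,
                 aug_flip_axes = aug_flip_axes,
                 aug_rotate_deg = aug_rotate_deg,
                 input_scale = input_scale,
                 stop_when_perfect = stop_when_perfect, seed = seed),
            class = "train_config")
}

# normalize a tomogram (or raw array) to network input units
normalize_input <- function(x, medium_ri = 1.337, scale = 0.04) {
  ri <- if (inherits(x, "tomogram")) x$ri else x
  (ri - medium_ri) / scale
}

#' Random label-preserving augmentation of one input volume
#'
#' Applies, in order: in-plane flips, rotation about the optical axis
#' (nearest-neighbour resampling), integer translation, and additive
#' Gaussian noise. Padding uses the medium value (0 in normalized units).
#' Translations beyond the configured maximum are clipped with a warning.
#'
#' @param x 3D numeric array in normalized input units.
#' @param config A [train_config()] (augmentation fields are used).
#' @param translate Optional fixed integer translation (length 3); random
#'   when `NULL`.
#' @param rotate_deg Optional fixed rotation; random when `NULL`.
#' @param flip Optional named logical (x, y); random when `NULL`.
#' @param pad Pad value (default 0 = medium).
#' @return Augmented array, same dimensions.
#' @export
augment_volume <- function(x, config = train_config(), translate = NULL,
                           rotate_deg = NULL, flip = NULL, pad = 0) {
  d <- dim(x)
  if (is.null(flip)) {
    flip <- c(x = "x" %in% config$aug_flip_axes && runif(1) < 0.5,
              y = "y" %in% config$aug_flip_axes && runif(1) < 0.5)
  }
  if (isTRUE(flip[["x"]])) x <- x[rev(seq_len(d[1])), , , drop = FALSE]
  if (isTRUE(flip[["y"]])) x <- x[, rev(seq_len(d[2])), , drop = FALSE]
  if (is.null(rotate_deg))
    rotate_deg <- runif(1, -config$aug_rotate_deg, config$aug_rotate_deg)
  if (abs(rotate_deg) > 1e-9) x <- rotate_z(x, rotate_deg, pad = pad)
  if (is.null(translate)) {
    translate <- sample(seq(-config$aug_max_translate,
                            config$aug_max_translate), 3, replace = TRUE)
  } else {
    mx <- config$aug_max_translate
    if (any(abs(translate) > mx)) {
      warning("translation clipped to the configured maximum of ", mx)
      translate <- pmin(pmax(translate, -mx), mx)
    }
  }
  x <- translate_volume(x, as.integer(round(translate)), pad = pad)
  if (config$aug_noise_sd > 0)
    x <- x + array(rnorm(length(x), 0, config$aug_noise_sd), d)
  x
}

# nearest-neighbour rotation about z around the volume centre
rotate_z <- function(x, degrees, pad = 0) {
  d <- dim(x)
  th <- degrees * pi / 180
  cx <- (d[1] + 1) / 2
  cy <- (d[2] + 1) / 2
  ij <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  # inverse map: source = R(-theta) (target - centre) + centre
  si <- round(cos(th) * (ij$i - cx) + sin(th) * (ij$j - cy) + cx)
  sj <- round(-sin(th) * (ij$i - cx) + cos(th) * (ij$j - cy) + cy)
  ok <- si >= 1 & si <= d[1] & sj >= 1 & sj <= d[2]
  idx <- si + (sj - 1) * d[1]
  out <- array(pad, d)
  m_in <- matrix(x, d[1] * d[2], d[3])
  m_out <- matrix(pad, d[1] * d[2], d[3])
  m_out[ok, ] <- m_in[idx[ok], ]
  array(m_out, d)
}

translate_volume <- function(x, t3, pad = 0) {
  if (all(t3 == 0)) return(x)
  d <- dim(x)
  out <- array(pad, d)
  src <- lapply(1:3, function(a) {
    s <- seq_len(d[a]) - t3[a]
    s[s >= 1 & s <= d[a]]
  })
  dst <- lapply(1:3, function(a) src[[a]] + t3[a])
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# stack a list of 3D arrays into (nx, ny, nz, 1, N)
stack_batch <- function(vols) {
  d <- dim(vols[[1]])
  array(unlist(vols, use.names = FALSE), c(d, 1, length(vols)))
}

# batched forward pass returning logits (N x 2) and latent (N x L)
forward_logits <- function(model, vols, batch_size = 16) {
  n <- length(vols)
  logits <- matrix(NA_real_, n, 2)
  latent <- NULL
  i <- 1
  while (i <= n) {
    sel <- i:min(n, i + batch_size - 1)
    fw <- nn_forward(model, stack_batch(vols[sel]), keep_cache = FALSE)
    logits[sel, ] <- fw$logits
    if (is.null(latent))
      latent <- matrix(NA_real_, n, ncol(fw$latent))
    latent[sel, ] <- fw$latent
    i <- i + batch_size
  }
  list(logits = logits, latent = latent)
}

# class label from logits with the conservative tie rule: exact ties are
# called wild-type so screening errs toward confirmatory testing
logits_to_label <- function(logits) {
  ifelse(logits[, 2] > logits[, 1], "MUT", "WT")
}

#' Train the genotype classifier
#'
#' Optimizes the weighted cross-entropy with Adam under cosine-annealed
#' learning rates. Loss weights are inversely proportional to class sizes in
#' the optimization split. Per epoch, every optimization image is fed twice
#' (original + randomly augmented); accuracy is then evaluated on the
#' optimization and generalization splits, and the parameters with the
#' highest sum of the two accuracies are kept.
#'
#' @param volumes Named list of 3D arrays in normalized input units (see
#'   [normalize_input()]), or raw RI arrays with `normalize = TRUE`.
#' @param labels Named character vector (`"WT"`/`"MUT"`) over the same
#'   names.
#' @param roles Named character vector: `"optimization"` (gradient +
#'   training accuracy) or `"generalization"` (checkpoint selection only).
#' @param arch An [arch_config()].
#' @param config A [train_config()].
#' @param normalize Set TRUE when `volumes` hold raw RI values.
#' @param medium_ri Medium RI for normalization.
#' @param verbose Print per-epoch progress.
#' @return An `ht_classifier` with the selected parameters plus `history`
#'   (tibble) and `config`.
#' @export
train_classifier <- function(volumes, labels, roles, arch = arch_tiny(),
                             config = train_config(), normalize = FALSE,
                             medium_ri = 1.337, verbose = FALSE) {
  stopifnot(length(volumes) >= 2, !is.null(names(volumes)))
  labels <- labels[names(volumes)]
  roles <- roles[names(volumes)]
  if (any(is.na(labels)) || any(is.na(roles)))
    stop("labels/roles must cover every volume")
  if (length(unique(labels[roles == "optimization"])) < 2)
    stop("training (optimization) set must contain both classes")
  if (normalize)
    volumes <- lapply(volumes, normalize_input, medium_ri = medium_ri,
                      scale = config$input_scale)
  opt_ids <- names(volumes)[roles == "optimization"]
  gen_ids <- names(volumes)[roles == "generalization"]
  y_of <- function(ids) ifelse(labels[ids] == "MUT", 2L, 1L)
  # inverse class-size weights, normalized to mean 1 over classes
  n_wt <- sum(labels[opt_ids] == "WT")
  n_mut <- sum(labels[opt_ids] == "MUT")
  w_class <- c(WT = 1 / n_wt, MUT = 1 / n_mut)
  w_class <- w_class / mean(w_class)

  model <- build_network(arch, seed = config$seed)
  adam_m <- lapply(model$params, function(p) p * 0)
  adam_v <- lapply(model$params, function(p) p * 0)
  adam_t <- 0
  best <- list(score = -Inf, params = model$params, epoch = 0L)
  history <- vector("list", config$epochs)

  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr0 * 0.5 *
        (1 + cos(pi * ((epoch - 1) %% config$cosine_period) /
                   config$cosine_period))
      if (config$lr_decay_mode == "multiplicative")
        lr <- lr * (1 - config$weight_decay)^(epoch - 1)
      # each image appears twice per epoch: original and augmented
      sched <- data.frame(id = rep(opt_ids, 2),
                          aug = rep(c(FALSE, TRUE), each = length(opt_ids)))
      sched <- sched[sample.int(nrow(sched)), ]
      ep_loss <- 0
      n_batches <- 0
      ep_correct <- 0
      ep_n <- 0
      i <- 1
      while (i <= nrow(sched)) {
        rows <- sched[i:min(nrow(sched), i + config$batch_size - 1), ]
        vols <- lapply(seq_len(nrow(rows)), function(k) {
          v <- volumes[[rows$id[k]]]
          if (rows$aug[k]) augment_volume(v, config) else v
        })
        y <- y_of(rows$id)
        w <- unname(w_class[labels[rows$id]])
        fw <- nn_forward(model, stack_batch(vols))
        ls <- weighted_softmax_ce(fw$logits, y, w)
        ep_correct <- ep_correct +
          sum(logits_to_label(fw$logits) == labels[rows$id])
        ep_n <- ep_n + nrow(rows)
        grads <- nn_backward(model, fw, ls$dlogits)
        adam_t <- adam_t + 1
        b1 <- config$adam_beta1
        b2 <- config$adam_beta2
        for (nm in names(grads)) {
          g <- grads[[nm]]
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
          mhat <- adam_m[[nm]] / (1 - b1^adam_t)
          vhat <- adam_v[[nm]] / (1 - b2^adam_t)
          upd <- lr * mhat / (sqrt(vhat) + 1e-8)
          if (config$lr_decay_mode == "decoupled")
            upd <- upd + lr * config$weight_decay * model$params[[nm]]
          model$params[[nm]] <- model$params[[nm]] - upd
        }
        ep_loss <- ep_loss + ls$loss
        n_batches <- n_batches + 1
        i <- i + config$batch_size
      }
      acc_of <- function(ids) {
        if (length(ids) == 0) return(NA_real_)
        out <- forward_logits(model, volumes[ids], config$batch_size)
        mean(logits_to_label(out$logits) == labels[ids])
      }
      # training accuracy from the epoch's own forward passes (original and
      # augmented presentations); the generalization split gets a clean pass
      acc_opt <- ep_correct / ep_n
      acc_gen <- acc_of(gen_ids)
      score <- acc_opt + ifelse(is.na(acc_gen), 0, acc_gen)
      if (score > best$score) {
        best <- list(score = score, params = model$params, epoch = epoch)
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, loss = ep_loss / n_batches,
        acc_optimization = acc_opt, acc_generalization = acc_gen)
      if (verbose)
        message(sprintf(
          "epoch %3d  lr %.2e  loss %.4f  acc_opt %.3f  acc_gen %.3f",
          epoch, lr, ep_loss / n_batches, acc_opt, acc_gen))
      if (config$stop_when_perfect && isTRUE(acc_opt == 1) &&
          isTRUE(acc_gen == 1)) break
    }
  })
  model$params <- best$params
  model$history <- dplyr::bind_rows(history)
  model$selected_epoch <- best$epoch
  model$config <- config
  model$medium_ri <- medium_ri
  model
}

#' Predict genotype for tomograms
#'
#' Deterministic inference: raw two-class outputs, argmax label (exact ties
#' resolve to wild-type), and the latent feature vector per image.
#'
#' @param model A trained `ht_classifier`.
#' @param volumes Named list of 3D arrays (raw RI or normalized; see
#'   `normalize`), or a single array / [tomogram()].
#' @param normalize Set TRUE for raw RI inputs.
#' @param medium_ri Medium RI used for normalization.
#' @return Tibble: `image_id`, `out_wt`, `out_mut`, `label`, plus the
#'   latent matrix as attribute `"latent"`.
#' @export
predict_classifier <- function(model, volumes, normalize = FALSE,
                               medium_ri = model$medium_ri %||% 1.337) {
  if (inherits(volumes, "tomogram")) volumes <- list(image = volumes$ri)
  if (is.array(volumes)) volumes <- list(image = volumes)
  volumes <- lapply(volumes, function(v)
    if (inherits(v, "tomogram")) v$ri else v)
  if (is.null(names(volumes)))
    names(volumes) <- sprintf("image_%04d", seq_along(volumes))
  scale <- model$config$input_scale %||% 0.04
  if (normalize)
    volumes <- lapply(volumes, normalize_input, medium_ri = medium_ri,
                      scale = scale)
  shp <- model$arch$input_shape
  volumes <- lapply(volumes, conform_volume, shape = shp)
  out <- forward_logits(model, volumes,
                        model$config$batch_size %||% 16)
  res <- tibble::tibble(
    image_id = names(volumes),
    out_wt = out$logits[, 1],
    out_mut = out$logits[, 2],
    label = logits_to_label(out$logits))
  attr(res, "latent") <- out$latent
  res
}

# center-crop / zero-pad a volume to the network input shape
conform_volume <- function(v, shape, pad = 0) {
  d <- dim(v)
  if (all(d == shape)) return(v)
  out <- array(pad, shape)
  take <- pmin(d, shape)
  src0 <- (d - take) %/% 2
  dst0 <- (shape - take) %/% 2
  out[dst0[1] + seq_len(take[1]), dst0[2] + seq_len(take[2]),
      dst0[3] + seq_len(take[3])] <-
    v[src0[1] + seq_len(take[1]), src0[2] + seq_len(take[2]),
      src0[3] + seq_len(take[3])]
  out
}

#' Downsample a volume by block averaging
#'
#' Reduces resolution by an integer factor per axis (2x2x2 mean by
#' default), the operation used to feed fine-grid phantoms to a
#' coarse-input network and to study resolution dependence.
#'
#' @param x 3D numeric array; dimensions must be divisible by `factor`.
#' @param factor Integer block size per axis.
#' @return Downsampled array.
#' @export
downsample_volume <- function(x, factor = 2L) {
  d <- dim(x)
  stopifnot(length(d) == 3, all(d %% factor == 0))
  f <- as.integer(factor)
  a <- array(x, c(f, d[1] %/% f, f, d[2] %/% f, f, d[3] %/% f))
  out <- array(0, d %/% f)
  for (i in seq_len(f))
    for (j in seq_len(f))
      for (k in seq_len(f))
        out <- out + array(a[i, , j, , k, , drop = FALSE], d %/% f)
  out / f^3
}
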