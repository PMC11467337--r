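#' Parameters of the rule-based segmenter
#'
#' @param noise_sd Assumed sensor noise sd (RI units); sets the background
#'   threshold at `medium_ri + max(2 * noise_sd, 0.004)`.
#' @param smooth_um Optional Gaussian presmoothing scale (um) for the RI
#'   volume before interior thresholding. Default 0 (no smoothing): interior
#'   boundaries are convoluted, and smoothing erodes them faster than it
#'   suppresses sensor noise, which connected-component and hole-filling
#'   steps already absorb.
#' @param nucleolus_k Nucleoli are voxels above the nucleoplasm mean plus
#'   `nucleolus_k` nucleoplasm sds.
#' @param lipid_ri_cutoff RI cutoff for lipid droplets outside the nucleus.
#' @param min_component_voxels Components smaller than this are discarded.
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(noise_sd = 0.001, smooth_um = 0,
                           nucleolus_k = 2.5, lipid_ri_cutoff = 1.39,
                           min_component_voxels = 30L) {
  structure(list(noise_sd = noise_sd, smooth_um = smooth_um,
                 nucleolus_k = nucleolus_k,
                 lipid_ri_cutoff = lipid_ri_cutoff,
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "segment_params")
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x, nbins = 256) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + as.integer((x - rng[1]) / diff(rng) *
                                              nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}

largest_component <- function(mask) {
  labv <- .label_components(mask, dim(mask))
  n <- attr(labv, "n_components") %||% 0L
  if (n <= 1L) return(mask)
  la <- array(labv, dim(mask))
  la == which.max(tabulate(la[la > 0], nbins = n))
}

#' Rule-based subcellular segmentation of a tomogram
#'
#' Deterministic replacement for interactive pixel classification, built on
#' morphological priors: the background is everything below a small RI
#' contrast over the medium; the cell is the largest connected foreground
#' component after closing and hole filling; the nucleus is the largest
#' interior component above an Otsu split of the (smoothed) intracellular RI,
#' closed and hole-filled; nucleoli are high-RI components inside the nucleus
#' (above the nucleoplasm mean + k sd); lipid droplets are high-RI components
#' in the cytoplasm above a fixed cutoff.
#'
#' @param tomo A [tomogram()].
#' @param params A [segment_params()].
#' @return A [seg_mask()] with provenance `"rule_based"`.
#' @export
segment_rule_based <- function(tomo, params = segment_params()) {
  stopifnot(inherits(tomo, "tomogram"))
  d <- dim(tomo$ri)
  sp <- tomo$voxel_spacing
  thr_bg <- tomo$medium_ri + max(2 * params$noise_sd, 0.004)
  fg <- tomo$ri > thr_bg
  if (!any(fg)) stop("empty field: no voxels above the background threshold")
  fg <- array(.binary_morph(fg, d, 1L, "close"), d)
  fg <- array(.binary_morph(fg, d, 1L, "open"), d)
  if (!any(fg)) stop("empty field: no foreground survives morphology")
  labv <- .label_components(fg, d)
  ncomp <- attr(labv, "n_components") %||% 1L
  if (ncomp > 1L) {
    sizes <- tabulate(labv[labv > 0], nbins = ncomp)
    top <- sort(sizes, decreasing = TRUE)
    if (length(top) > 1 && top[2] > 0.5 * top[1])
      stop("ambiguous field: multiple similarly sized cells detected")
    la <- array(labv, d)
    fg <- la == which.max(sizes)
  }
  cell <- array(.fill_holes(fg, d), d)

  ri_s <- if (params$smooth_um > 0)
    array(.gauss_smooth(tomo$ri, d, params$smooth_um / sp), d)
  else tomo$ri

  # lipid first: its extreme RI would otherwise capture the Otsu split
  lipid0 <- cell & ri_s > params$lipid_ri_cutoff

  # nucleus threshold learned from interior, non-lipid voxels only, so
  # neither the partial-volume shell at the cell boundary nor the lipid
  # spike can capture the Otsu split
  din <- sqrt(array(.edt_sq(!cell, d, sp), d))
  interior <- din > 0.45 & !lipid0
  if (sum(interior) < 100) interior <- cell & !lipid0
  thr_nuc <- otsu_threshold(ri_s[interior])
  nuc <- cell & ri_s > thr_nuc & !lipid0
  nuc <- largest_component(nuc)
  nuc <- array(.fill_holes(nuc, d), d) & cell & !lipid0
  if (sum(nuc) < params$min_component_voxels) nuc[] <- FALSE

  # nucleoli: high-RI voxels inside the nucleus, iterated once so the
  # nucleoplasm statistics exclude the nucleolar tail. The threshold offset
  # uses the noise-corrected texture sd: sensor noise is voxel-independent
  # and is absorbed by the minimum-component-size rule instead.
  nucleolus <- array(FALSE, d)
  if (any(nuc)) {
    for (iter in 1:2) {
      np_vals <- ri_s[nuc & !nucleolus]
      sd_tex <- sqrt(max(stats::var(np_vals) - params$noise_sd^2,
                         0.25 * stats::var(np_vals)))
      thr_no <- mean(np_vals) + params$nucleolus_k * sd_tex
      cand <- nuc & ri_s > thr_no
      labn <- .label_components(cand, d)
      ncn <- attr(labn, "n_components") %||% 0L
      if (ncn > 0) {
        sizes <- tabulate(labn[labn > 0], nbins = ncn)
        keep <- which(sizes >= params$min_component_voxels)
        la <- array(labn, d)
        nucleolus <- array(la %in% keep, d)
      } else nucleolus[] <- FALSE
    }
  }

  # lipid droplets: bright particles in the cytoplasm
  lip_cand <- cell & !nuc & tomo$ri > params$lipid_ri_cutoff
  lipid <- array(FALSE, d)
  if (any(lip_cand)) {
    labl <- .label_components(lip_cand, d)
    ncl <- attr(labl, "n_components") %||% 0L
    sizes <- tabulate(labl[labl > 0], nbins = ncl)
    keep <- which(sizes >= params$min_component_voxels)
    la <- array(labl, d)
    lipid <- array(la %in% keep, d)
  }

  labels <- array(0L, d)
  labels[cell] <- LABELS[["cytoplasm"]]
  labels[nuc] <- LABELS[["nucleoplasm"]]
  labels[nucleolus] <- LABELS[["nucleolus"]]
  labels[lipid] <- LABELS[["lipid"]]
  seg_mask(labels, "rule_based")
}

#' Dice overlap between two masks for one region
#'
#' @param a,b [seg_mask()] objects on the same grid.
#' @param region Region name.
#' @return Dice coefficient in `[0, 1]` (NA when the region is empty in both).
#' @export
dice_coefficient <- function(a, b, region) {
  ma <- region_mask(a, region)
  mb <- region_mask(b, region)
  denom <- sum(ma) + sum(mb)
  if (denom == 0) return(NA_real_)
  2 * sum(ma & mb) / denom
}
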