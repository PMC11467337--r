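#' Phantom specification for a single myeloblast
#'
#' Collects the geometric and optical parameters that define one synthetic
#' cell: compartment volumes, sphericities and mean refractive indices.
#' Volumes are in fL, RI values dimensionless, sphericities in (0, 1].
#'
#' @param cell_volume Whole-cell volume (fL).
#' @param cell_sphericity Whole-cell sphericity.
#' @param nc_volume_ratio Nucleus-to-cell volume ratio in (0, 1); the nucleus
#'   volume is derived as `nc_volume_ratio * cell_volume`.
#' @param nucleus_sphericity Nucleus sphericity.
#' @param nucleolus_count Number of nucleoli (integer >= 0).
#' @param nucleolus_total_volume Total nucleolar volume (fL).
#' @param mean_ri_cytoplasm,mean_ri_nucleoplasm,mean_ri_nucleolus Region mean
#'   RI values; the nucleolus must exceed the nucleoplasm.
#' @param lipid_droplet_count Number of cytoplasmic lipid droplets.
#' @param lipid_ri RI of lipid droplets.
#' @param ri_texture_sd Intra-region RI heterogeneity (sd of the smoothed
#'   texture field), emulating e.g. chromatin distribution heterogeneity.
#' @return A `phantom_spec` object (named list).
#' @export
phantom_spec <- function(cell_volume = 462.18, cell_sphericity = 0.797,
                         nc_volume_ratio = 0.417, nucleus_sphericity = 0.538,
                         nucleolus_count = 2, nucleolus_total_volume = 14.99,
                         mean_ri_cytoplasm = 1.3632,
                         mean_ri_nucleoplasm = 1.3692,
                         mean_ri_nucleolus = 1.3759,
                         lipid_droplet_count = 0, lipid_ri = 1.40,
                         ri_texture_sd = 0.0015) {
  spec <- list(
    cell_volume = cell_volume, cell_sphericity = cell_sphericity,
    nc_volume_ratio = nc_volume_ratio,
    nucleus_sphericity = nucleus_sphericity,
    nucleolus_count = as.integer(nucleolus_count),
    nucleolus_total_volume = nucleolus_total_volume,
    mean_ri_cytoplasm = mean_ri_cytoplasm,
    mean_ri_nucleoplasm = mean_ri_nucleoplasm,
    mean_ri_nucleolus = mean_ri_nucleolus,
    lipid_droplet_count = as.integer(lipid_droplet_count),
    lipid_ri = lipid_ri, ri_texture_sd = ri_texture_sd)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec, medium_ri = 1.337) {
  with(spec, {
    if (cell_volume <= 0) stop("cell_volume must be positive")
    if (cell_sphericity <= 0 || cell_sphericity > 1)
      stop("cell_sphericity must lie in (0, 1]")
    if (nucleus_sphericity <= 0 || nucleus_sphericity > 1)
      stop("nucleus_sphericity must lie in (0, 1]")
    if (nc_volume_ratio <= 0 || nc_volume_ratio >= 1)
      stop("nc_volume_ratio must lie in (0, 1): nucleus smaller than cell")
    if (nucleolus_count > 0 &&
        nucleolus_total_volume >= nc_volume_ratio * cell_volume)
      stop("nucleolus_total_volume must be below the nucleus volume")
    if (mean_ri_nucleolus <= mean_ri_nucleoplasm)
      stop("mean_ri_nucleolus must exceed mean_ri_nucleoplasm")
    if (min(mean_ri_cytoplasm, mean_ri_nucleoplasm) <= medium_ri)
      stop("all region RI means must exceed the medium RI")
    if (nucleolus_count < 0 || lipid_droplet_count < 0)
      stop("counts must be non-negative")
    if (ri_texture_sd < 0) stop("ri_texture_sd must be >= 0")
  })
  invisible(spec)
}

#' Generate one phantom tomogram with its ground-truth mask
#'
#' Renders the cell described by `spec` onto a voxel grid: the cell and
#' nucleus outlines are calibrated shapes (see [synthesize_shape()]), the
#' nucleus shares the cell's angular field plus an independent component (its
#' lobes follow the cell while folding independently), nucleoli are spheres
#' packed inside the nucleus, and per-region RI values receive a smoothed,
#' mean-corrected texture field plus optional clamped Gaussian sensor noise.
#'
#' @param spec A [phantom_spec()].
#' @param grid_dim Grid size, default `c(160, 160, 72)`.
#' @param voxel_spacing Voxel pitch (um), default `c(0.156, 0.156, 0.312)`.
#' @param medium_ri Medium RI, default 1.337.
#' @param noise_sd Sd of additive sensor noise (clamped at 3 sd), default 0.
#' @param seed Optional integer seed.
#' @return List with elements `tomogram` ([tomogram()]), `mask` (ground-truth
#'   [seg_mask()]), and `achieved` (measured geometry of the rendered
#'   compartments).
#' @export
generate_phantom <- function(spec, grid_dim = c(160, 160, 72),
                             voxel_spacing = c(0.156, 0.156, 0.312),
                             medium_ri = 1.337, noise_sd = 0,
                             seed = NULL) {
  validate_phantom_spec(spec, medium_ri)
  grid_dim <- as.integer(grid_dim)
  with_seed(seed, {
    vxvol <- prod(voxel_spacing)
    extent <- grid_dim * voxel_spacing
    center <- (grid_dim - 1) * voxel_spacing / 2
    r_fov <- min(extent) / 2 - 2 * max(voxel_spacing)
    r_cell <- (3 * spec$cell_volume / (4 * pi))^(1 / 3)
    if (1.05 * r_cell > r_fov)
      stop("cell does not fit inside the grid with a 2-voxel margin")
    r_cap_cell <- min(r_fov, 1.6 * r_cell)

    cache <- star_cache(center, grid_dim, voxel_spacing,
                        r_eval = r_cap_cell + max(voxel_spacing))
    # --- cell outline
    field_c <- random_angular_field()
    cell <- solve_star_shape(spec$cell_volume, spec$cell_sphericity, cache,
                             field_c, voxel_spacing, r_cap = r_cap_cell,
                             s_max = 2, on_floor = "best")
    cell_mask <- cell$mask

    # --- nucleus: shares the cell field mixed with its own; retried with a
    # fresh own-field when the target sphericity is below this realization's
    # floor (deep irregularity is realization-dependent)
    din <- sqrt(array(.edt_sq(!cell_mask, dim(cell_mask),
                              voxel_spacing), dim(cell_mask)))
    interior <- din > 1.02 * min(voxel_spacing)
    nucleus_volume <- spec$nc_volume_ratio * spec$cell_volume
    best <- NULL
    for (attempt in 1:3) {
      field_n <- mix_fields(field_c, random_angular_field(), beta = 1.2)
      sol <- solve_star_shape(
        nucleus_volume, spec$nucleus_sphericity, cache, field_n,
        voxel_spacing, interior = interior, psi_tol = 0.008,
        on_floor = "best")
      # score attempts by sphericity error, but never accept a shape whose
      # volume missed the target while a closer-volume attempt exists
      vol_ok <- function(x) abs(x$volume / nucleus_volume - 1) < 0.05
      better <- is.null(best) ||
        (vol_ok(sol) && !vol_ok(best)) ||
        (vol_ok(sol) == vol_ok(best) &&
           abs(sol$sphericity - spec$nucleus_sphericity) <
             abs(best$sphericity - spec$nucleus_sphericity))
      if (better) best <- sol
      if (abs(best$sphericity - spec$nucleus_sphericity) <= 0.02 &&
          abs(best$volume / nucleus_volume - 1) < 0.05) break
    }
    nucleus_mask <- best$mask

    # --- nucleoli: spheres packed inside the nucleus
    nucleolus_mask <- array(FALSE, grid_dim)
    if (spec$nucleolus_count > 0) {
      shares <- rgamma(spec$nucleolus_count, shape = 2)
      shares <- shares / sum(shares)
      vols <- spec$nucleolus_total_volume * shares
      nucleolus_mask <- place_balls(nucleus_mask, vols, voxel_spacing,
                                    clearance = min(voxel_spacing))
    }

    # --- lipid droplets: small spheres in the cytoplasm
    lipid_mask <- array(FALSE, grid_dim)
    if (spec$lipid_droplet_count > 0) {
      cyto_room <- cell_mask & !nucleus_mask
      vols <- runif(spec$lipid_droplet_count, 0.5, 2.5)
      lipid_mask <- place_balls(cyto_room, vols, voxel_spacing,
                                clearance = min(voxel_spacing))
    }

    labels <- array(0L, grid_dim)
    labels[cell_mask] <- LABELS[["cytoplasm"]]
    labels[nucleus_mask] <- LABELS[["nucleoplasm"]]
    labels[nucleolus_mask] <- LABELS[["nucleolus"]]
    labels[lipid_mask] <- LABELS[["lipid"]]

    # --- RI assembly: region means + mean-corrected smoothed texture
    ri <- array(medium_ri, grid_dim)
    ri[labels == LABELS[["cytoplasm"]]] <- spec$mean_ri_cytoplasm
    ri[labels == LABELS[["nucleoplasm"]]] <- spec$mean_ri_nucleoplasm
    ri[labels == LABELS[["nucleolus"]]] <- spec$mean_ri_nucleolus
    ri[labels == LABELS[["lipid"]]] <- spec$lipid_ri
    if (spec$ri_texture_sd > 0) {
      tex <- texture_field(grid_dim, voxel_spacing, smooth_um = 0.5)
      for (lab in c(1L, 2L, 3L)) {
        sel <- labels == lab
        if (!any(sel)) next
        tv <- tex[sel]
        tv <- tv - mean(tv)
        s <- sd(tv)
        if (is.finite(s) && s > 0)
          ri[sel] <- ri[sel] + tv / s * spec$ri_texture_sd
      }
    }
    if (noise_sd > 0) {
      noise <- rnorm(length(ri), 0, noise_sd)
      noise <- pmin(pmax(noise, -3 * noise_sd), 3 * noise_sd)
      ri <- ri + array(noise, grid_dim)
    }

    list(
      tomogram = tomogram(ri, voxel_spacing, medium_ri),
      mask = seg_mask(labels, "ground_truth"),
      achieved = list(
        cell_volume = cell$volume, cell_sphericity = cell$sphericity,
        nucleus_volume = best$volume, nucleus_sphericity = best$sphericity)
    )
  })
}

# mix a parent angular field with an independent one (shared lobes plus own
# folding); corrugation, ellipsoid and bites come from the own field
mix_fields <- function(parent, own, beta = 1.2) {
  nrm <- sqrt(1 + beta^2)
  list(id = sprintf("f%015.0f", runif(1) * 1e15),
       eval = function(u) (parent$eval(u) + beta * own$eval(u)) / nrm,
       evalw = own$evalw, ellip = own$ellip, rot = own$rot, l0 = own$l0,
       qdirs = parent$qdirs,
       bite_dirs = own$bite_dirs, bite_rel = own$bite_rel)
}

# pack non-overlapping balls of given volumes inside `room` (logical array);
# rejection sampling with shrinking placement radius, clearance in um
place_balls <- function(room, volumes, spacing, clearance = 0.156) {
  out <- array(FALSE, dim(room))
  din <- sqrt(array(.edt_sq(!room, dim(room), spacing), dim(room)))
  vox_idx <- which(room, arr.ind = TRUE)
  if (nrow(vox_idx) == 0) return(out)
  for (v in sort(volumes, decreasing = TRUE)) {
    r <- (3 * v / (4 * pi))^(1 / 3)
    # candidate centres: voxels deeper than r + clearance
    ok <- din > (r + clearance)
    cand <- which(ok & !out)
    placed <- FALSE
    for (try in 1:25) {
      if (length(cand) == 0) break
      ci <- cand[sample.int(length(cand), 1)]
      ctr <- (arrayInd(ci, dim(room)) - 1) * spacing
      bm <- ball_voxels(dim(room), spacing, ctr, r)
      if (!any(bm & out)) { out <- out | bm; placed <- TRUE; break }
    }
    if (!placed) {
      # last resort: the deepest remaining point, radius shrunk to fit
      ci <- which.max(din * !out)
      if (din[ci] > clearance) {
        ctr <- (arrayInd(ci, dim(room)) - 1) * spacing
        r_eff <- min(r, max(din[ci] - clearance, 1.2 * min(spacing)))
        out <- out | ball_voxels(dim(room), spacing, ctr, r_eff)
      }
    }
  }
  out & room
}

# logical ball on a grid (physical units), evaluated on a tight bbox
ball_voxels <- function(grid_dim, spacing, center, radius) {
  lo <- pmax(1L, floor((center - radius) / spacing) + 1L - 1L)
  hi <- pmin(grid_dim, ceiling((center + radius) / spacing) + 1L + 1L)
  out <- array(FALSE, grid_dim)
  xs <- (seq(lo[1], hi[1]) - 1) * spacing[1] - center[1]
  ys <- (seq(lo[2], hi[2]) - 1) * spacing[2] - center[2]
  zs <- (seq(lo[3], hi[3]) - 1) * spacing[3] - center[3]
  sub <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`) <= radius^2
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  out
}

# smooth random texture field (white noise smoothed to `smooth_um`)
texture_field <- function(grid_dim, spacing, smooth_um = 0.5) {
  w <- array(rnorm(prod(grid_dim)), grid_dim)
  array(.gauss_smooth(w, grid_dim, smooth_um / spacing), grid_dim)
}
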