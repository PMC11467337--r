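#' Geometry of one segmented region
#'
#' Volume is voxel count times physical voxel volume; surface area comes from
#' iso-surface meshing of the binary region ([surface_area()]); sphericity is
#' \eqn{\psi = \pi^{1/3} (6V)^{2/3} / A}.
#'
#' @param mask A [seg_mask()].
#' @param region One of `"cell"`, `"nucleus"`, `"nucleoplasm"`,
#'   `"nucleolus"`, `"cytoplasm"`, `"lipid"`.
#' @param voxel_spacing Voxel pitch in micrometres.
#' @return A one-row tibble: region, present, n_voxels, volume (fL),
#'   area (um^2), sphericity. A region absent from the mask yields
#'   `present = FALSE` and NA measures rather than zeros.
#' @export
region_geometry <- function(mask, region, voxel_spacing) {
  stopifnot(inherits(mask, "seg_mask"))
  sel <- region_mask(mask, region)
  if (!any(sel)) {
    return(tibble::tibble(region = region, present = FALSE,
                          n_voxels = 0L, volume = NA_real_,
                          area = NA_real_, sphericity = NA_real_))
  }
  g <- mask_geometry(crop_mask(sel), voxel_spacing)
  tibble::tibble(region = region, present = TRUE, n_voxels = sum(sel),
                 volume = g$volume, area = g$area, sphericity = g$sphericity)
}

#' Dry mass and concentration of a region
#'
#' Uses the linear relation between biomolecular mass concentration and RI
#' contrast over the medium: per voxel `c = (n - n_m) / alpha` (g/mL, equal
#' to fg/fL), and `m = sum(c * voxel_volume)` in pg over the region.
#'
#' @param tomo A [tomogram()].
#' @param mask A [seg_mask()] on the same grid.
#' @param region Region name (see [region_geometry()]).
#' @param alpha Specific refractive increment in mL/g (default 0.185; with
#'   this value an RI contrast of 0.001 corresponds to 5.4 fg/fL).
#' @return One-row tibble: region, present, dry_mass (pg), concentration
#'   (g/mL, region mean), mean_ri, negative_total flag (TRUE when the summed
#'   mass is negative, possible in noisy voxels).
#' @export
dry_mass <- function(tomo, mask, region, alpha = 0.185) {
  stopifnot(alpha > 0, inherits(tomo, "tomogram"), inherits(mask, "seg_mask"))
  sel <- region_mask(mask, region)
  if (!any(sel)) {
    return(tibble::tibble(region = region, present = FALSE,
                          dry_mass = NA_real_, concentration = NA_real_,
                          mean_ri = NA_real_, negative_total = FALSE))
  }
  vals <- tomo$ri[sel]
  conc <- (vals - tomo$medium_ri) / alpha
  vxvol <- prod(tomo$voxel_spacing)
  m <- sum(conc) * vxvol
  tibble::tibble(region = region, present = TRUE, dry_mass = m,
                 concentration = mean(conc), mean_ri = mean(vals),
                 negative_total = m < 0)
}

#' Nucleus-to-cell ratios (3D volume and 2D projected area)
#'
#' The 3D ratio uses voxel volumes; the 2D ratio divides the axially (z)
#' projected nucleus area by the projected cell area, mirroring the en-face
#' view of conventional microscopy.
#'
#' @param mask A [seg_mask()].
#' @return One-row tibble: nc_volume_ratio, nc_area_ratio_2d.
#' @export
nc_ratios <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  cell <- region_mask(mask, "cell")
  nuc <- region_mask(mask, "nucleus")
  if (!any(nuc) || !any(cell)) {
    return(tibble::tibble(nc_volume_ratio = NA_real_,
                          nc_area_ratio_2d = NA_real_))
  }
  d <- dim(cell)
  proj_cell <- rowSums(matrix(cell, d[1] * d[2], d[3])) > 0
  proj_nuc <- rowSums(matrix(nuc, d[1] * d[2], d[3])) > 0
  tibble::tibble(
    nc_volume_ratio = sum(nuc) / sum(cell),
    nc_area_ratio_2d = sum(proj_nuc) / sum(proj_cell))
}

#' Full morphometric profile of one cell
#'
#' Computes, for each region (cell, nucleus, nucleoplasm, nucleolus,
#' cytoplasm, and lipid when present), the volume, surface area, sphericity,
#' mean RI, dry mass and mean concentration, plus the two N/C ratios.
#' Lipid droplets are excluded from the cytoplasm mean RI but included in
#' whole-cell dry mass (they are part of the cell).
#'
#' @inheritParams dry_mass
#' @return A one-row wide tibble with columns `<measure>_<region>` plus
#'   `nc_volume_ratio` and `nc_area_ratio_2d`.
#' @export
measure_cell <- function(tomo, mask, alpha = 0.185) {
  regions <- REGIONS
  if (any(mask$labels == LABELS[["lipid"]])) regions <- c(regions, "lipid")
  geo <- dplyr::bind_rows(lapply(regions, function(r)
    region_geometry(mask, r, tomo$voxel_spacing)))
  dm <- dplyr::bind_rows(lapply(regions, function(r)
    dry_mass(tomo, mask, r, alpha)))
  tab <- dplyr::left_join(geo, dplyr::select(dm, -"present"), by = "region")
  wide <- tidyr::pivot_wider(
    dplyr::select(tab, -"present", -"negative_total", -"n_voxels"),
    names_from = "region",
    values_from = c("volume", "area", "sphericity", "mean_ri", "dry_mass",
                    "concentration"),
    names_sep = "_")
  dplyr::bind_cols(wide, nc_ratios(mask))
}

#' Measure a batch of phantoms drawn from group parameters
#'
#' Convenience driver for parameter-recovery studies: samples `n` phantom
#' specifications, renders each phantom, and measures it with its ground-truth
#' mask (or with the rule-based segmenter).
#'
#' @param params A [group_params()].
#' @param n Number of phantoms.
#' @param seed Integer seed.
#' @param grid_dim,voxel_spacing,medium_ri,noise_sd Passed to
#'   [generate_phantom()].
#' @param segmentation `"ground_truth"` or `"rule_based"`.
#' @param alpha Specific refractive increment (mL/g).
#' @return Tibble with one row per phantom: the sampled spec columns
#'   (prefixed `spec_`) followed by all measured columns.
#' @export
measure_phantom_batch <- function(params, n, seed = 1,
                                  grid_dim = c(96, 96, 48),
                                  voxel_spacing = c(0.156, 0.156, 0.312),
                                  medium_ri = 1.337, noise_sd = 0.001,
                                  segmentation = c("ground_truth",
                                                   "rule_based"),
                                  alpha = 0.185) {
  segmentation <- match.arg(segmentation)
  specs <- sample_phantom_specs(params, n, seed = derive_seed(seed, "specs"))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(spec_from_row(specs[i, ]), grid_dim,
                           voxel_spacing, medium_ri, noise_sd,
                           seed = derive_seed(seed, paste0("phantom_", i)))
    msk <- if (segmentation == "ground_truth") ph$mask
           else segment_rule_based(ph$tomogram,
                                   segment_params(noise_sd = noise_sd))
    rows[[i]] <- measure_cell(ph$tomogram, msk, alpha)
  }
  meas <- dplyr::bind_rows(rows)
  spec_cols <- dplyr::rename_with(specs, ~ paste0("spec_", .x))
  dplyr::bind_cols(spec_cols, meas)
}
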