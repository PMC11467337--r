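#' Write a tomogram (and optional mask) to HDF5
#'
#' The canonical container: dataset `ri` with attributes `voxel_spacing`
#' (um, length 3) and `medium_ri`; an optional `mask` dataset holds the
#' voxel labels with a `provenance` attribute. Round trips are lossless.
#'
#' @param tomo A [tomogram()].
#' @param path Output file path (`.h5`).
#' @param mask Optional [seg_mask()] stored alongside.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(tomo, path, mask = NULL) {
  stopifnot(inherits(tomo, "tomogram"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(tomo$ri, path, "ri")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  did <- rhdf5::H5Dopen(fid, "ri")
  rhdf5::h5writeAttribute(tomo$voxel_spacing, did, "voxel_spacing")
  rhdf5::h5writeAttribute(tomo$medium_ri, did, "medium_ri")
  rhdf5::H5Dclose(did)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "seg_mask"))
    rhdf5::h5write(mask$labels, fid, "mask")
    mid <- rhdf5::H5Dopen(fid, "mask")
    rhdf5::h5writeAttribute(mask$provenance, mid, "provenance")
    rhdf5::H5Dclose(mid)
  }
  invisible(path)
}

#' Read a tomogram from HDF5 or TIFF
#'
#' HDF5 files must contain an `ri` dataset with `voxel_spacing` and
#' `medium_ri` attributes; missing metadata raises an error naming the
#' attribute (no silent defaults). Multi-page TIFF files require a JSON
#' sidecar `<path>.json` carrying `voxel_spacing`, `medium_ri` and the
#' affine stored-value mapping (see [write_tomogram_tiff()]).
#'
#' @param path File path (`.h5`/`.hdf5` or `.tif`/`.tiff`).
#' @param with_mask Also read the `mask` dataset when present (HDF5 only).
#' @return A [tomogram()]; with `with_mask = TRUE`, a list
#'   `(tomogram, mask)`.
#' @export
read_tomogram <- function(path, with_mask = FALSE) {
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
    return(read_tomogram_tiff(path))
  ri <- rhdf5::h5read(path, "ri")
  att <- rhdf5::h5readAttributes(path, "ri")
  for (need in c("voxel_spacing", "medium_ri"))
    if (is.null(att[[need]]))
      stop("tomogram file lacks required attribute: ", need)
  tomo <- tomogram(ri, as.numeric(att$voxel_spacing),
                   as.numeric(att$medium_ri))
  if (!with_mask) return(tomo)
  cont <- rhdf5::h5ls(path)
  msk <- NULL
  if ("mask" %in% cont$name) {
    lab <- rhdf5::h5read(path, "mask")
    matt <- rhdf5::h5readAttributes(path, "mask")
    msk <- seg_mask(array(as.integer(lab), dim(lab)),
                    matt$provenance %||% "ground_truth")
  }
  list(tomogram = tomo, mask = msk)
}

#' Export a tomogram as multi-page TIFF with a JSON sidecar
#'
#' TIFF float samples are clamped to `[0, 1]` by the writer, so RI values
#' are stored as `(ri - offset) / scale`; the sidecar `<path>.json` records
#' `offset`, `scale`, `voxel_spacing` and `medium_ri`. The round trip is
#' lossless at 32-bit float precision.
#'
#' @param tomo A [tomogram()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_tomogram_tiff <- function(tomo, path) {
  stopifnot(inherits(tomo, "tomogram"))
  offset <- floor(min(tomo$ri) * 100) / 100
  scale <- max(ceiling((max(tomo$ri) - offset) * 100) / 100, 0.01)
  pages <- lapply(seq_len(dim(tomo$ri)[3]), function(k)
    (tomo$ri[, , k] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(offset = offset, scale = scale,
         voxel_spacing = tomo$voxel_spacing, medium_ri = tomo$medium_ri),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_tomogram_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("TIFF tomogram requires a JSON sidecar with metadata: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (need in c("offset", "scale", "voxel_spacing", "medium_ri"))
    if (is.null(meta[[need]]))
      stop("tomogram sidecar lacks required field: ", need)
  pages <- tiff::readTIFF(path, all = TRUE)
  ri <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  tomogram(ri * meta$scale + meta$offset, meta$voxel_spacing, meta$medium_ri)
}

#' Write / read a cohort manifest
#'
#' CSV columns: patient_id, genotype, vaf, image_id, split, and image_path
#' when present; a JSON mirror is written alongside.
#'
#' @param manifest Manifest tibble (see [generate_cohort()]).
#' @param path CSV path.
#' @return `path` invisibly (write); manifest tibble (read).
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  jsonlite::write_json(manifest, sub("\\.csv$", ".json", path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    genotype = readr::col_character(),
                    vaf = readr::col_double(),
                    image_id = readr::col_character(),
                    split = readr::col_character(),
                    .default = readr::col_guess()))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline in one serializable
#' object; `pipeline_config()` round-trips losslessly through YAML.
#'
#' @param seed Master seed; all stage streams derive from it.
#' @param out_dir Artifact directory.
#' @param grid_dim,voxel_spacing,medium_ri,noise_sd Rendering parameters.
#' @param alpha Specific refractive increment (mL/g).
#' @param n_images_per_group Images per genotype (named list WT/MUT);
#'   `NULL` uses the group defaults (900 / 1,173).
#' @param n_patients Patients per genotype (named list); `NULL` for
#'   defaults (26 / 22).
#' @param wt_overrides,mut_overrides Named lists of [group_params()]
#'   overrides.
#' @param arch_preset `"tiny"` or `"paper"`.
#' @param train Named list of [train_config()] overrides.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 1, out_dir = "holoblast_run",
                            grid_dim = c(96, 96, 48),
                            voxel_spacing = c(0.156, 0.156, 0.312),
                            medium_ri = 1.337, noise_sd = 0.001,
                            alpha = 0.185,
                            n_images_per_group = NULL, n_patients = NULL,
                            wt_overrides = list(), mut_overrides = list(),
                            arch_preset = c("tiny", "paper"),
                            train = list()) {
  arch_preset <- match.arg(arch_preset)
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              grid_dim = as.integer(grid_dim),
              voxel_spacing = as.numeric(voxel_spacing),
              medium_ri = medium_ri, noise_sd = noise_sd, alpha = alpha,
              n_images_per_group = n_images_per_group,
              n_patients = n_patients,
              wt_overrides = wt_overrides, mut_overrides = mut_overrides,
              arch_preset = arch_preset, train = train)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(length(cfg$grid_dim) == 3, all(cfg$grid_dim > 0),
            length(cfg$voxel_spacing) == 3, all(cfg$voxel_spacing > 0),
            cfg$alpha > 0, cfg$noise_sd >= 0)
  for (ov in list(cfg$wt_overrides, cfg$mut_overrides)) {
    for (nm in c("cell_sphericity", "nucleus_sphericity")) {
      if (!is.null(ov[[nm]]) && (ov[[nm]][1] <= 0 || ov[[nm]][1] > 1))
        stop("invalid ", nm, " in config: mean must lie in (0, 1]")
    }
  }
  invisible(cfg)
}

#' Save / load a pipeline configuration as YAML
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly (save); a `pipeline_config` (load).
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$wt_overrides <- lapply(raw$wt_overrides, unlist)
  raw$mut_overrides <- lapply(raw$mut_overrides, unlist)
  do.call(pipeline_config, raw)
}
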