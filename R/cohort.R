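#' Group-level sampling parameters for one genotype
#'
#' Each continuous phantom parameter is sampled from a truncated normal whose
#' mean and sd default to the group statistics reported for myeloblast
#' holotomography (per-cell means across 900 wild-type and 1,173 mutant
#' images). The nucleolus RI is parameterized as nucleoplasm RI plus a
#' positive offset so that both marginal distributions keep their printed
#' mean and sd while the nucleolus always exceeds the nucleoplasm.
#'
#' @param genotype `"WT"` or `"MUT"`; selects the default parameter set.
#' @param ... Named overrides; each continuous parameter is a `c(mean, sd)`
#'   pair, counts are scalars.
#' @return A `group_params` object.
#' @details Defaults (mean, sd) per genotype:
#' * `cell_volume`: WT 446.24, 181.18; MUT 462.18, 187.43 (fL)
#' * `cell_sphericity`: WT 0.804, 0.052; MUT 0.797, 0.057
#' * `nc_volume_ratio`: WT 0.400, 0.059; MUT 0.417, 0.054
#' * `nucleus_sphericity`: WT 0.501, 0.065; MUT 0.538, 0.057
#' * `nucleolus_total_volume`: WT 14.48, 12.54; MUT 14.99, 13.09 (fL)
#' * `mean_ri_cytoplasm`: WT 1.3635, 0.0032; MUT 1.3632, 0.0029
#' * `mean_ri_nucleoplasm`: WT 1.3692, 0.0039; MUT 1.3692, 0.0031
#' * `mean_ri_nucleolus`: WT 1.3764, 0.0044; MUT 1.3759, 0.0034
#' * `image_count`: WT 900, MUT 1173; `patient_count`: WT 26, MUT 22
#' @export
group_params <- function(genotype = c("WT", "MUT"), ...) {
  genotype <- match.arg(genotype)
  p <- if (genotype == "WT") list(
    cell_volume = c(446.24, 181.18),
    cell_sphericity = c(0.804, 0.052),
    nc_volume_ratio = c(0.400, 0.059),
    nucleus_sphericity = c(0.501, 0.065),
    nucleolus_total_volume = c(14.48, 12.54),
    mean_ri_cytoplasm = c(1.3635, 0.0032),
    mean_ri_nucleoplasm = c(1.3692, 0.0039),
    mean_ri_nucleolus = c(1.3764, 0.0044),
    image_count = 900L, patient_count = 26L
  ) else list(
    cell_volume = c(462.18, 187.43),
    cell_sphericity = c(0.797, 0.057),
    nc_volume_ratio = c(0.417, 0.054),
    nucleus_sphericity = c(0.538, 0.057),
    nucleolus_total_volume = c(14.99, 13.09),
    mean_ri_cytoplasm = c(1.3632, 0.0029),
    mean_ri_nucleoplasm = c(1.3692, 0.0031),
    mean_ri_nucleolus = c(1.3759, 0.0034),
    image_count = 1173L, patient_count = 22L
  )
  common <- list(
    genotype = genotype,
    nucleolus_count_range = c(1L, 3L),
    lipid_droplet_prob = 0.15, lipid_droplet_max = 2L,
    lipid_ri = 1.40, ri_texture_sd = 0.0015,
    vaf_range = if (genotype == "MUT") c(0.2, 0.5) else c(0, 0),
    # fraction of each parameter's variance attributed to the patient level
    # (cells of one dominant clone resemble each other)
    patient_var_frac = 0.25
  )
  out <- utils::modifyList(c(p, common), list(...))
  for (nm in c("cell_volume", "cell_sphericity", "nc_volume_ratio",
               "nucleus_sphericity", "nucleolus_total_volume",
               "mean_ri_cytoplasm", "mean_ri_nucleoplasm",
               "mean_ri_nucleolus")) {
    v <- out[[nm]]
    if (length(v) != 2 || v[2] < 0)
      stop("parameter ", nm, " must be c(mean, sd) with sd >= 0")
  }
  structure(out, class = "group_params")
}

# expected value of a truncated normal
etrunc <- function(mu, sd, lo, hi) {
  if (sd <= 0) return(mu)
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  # with the location far outside the window the mass piles at the nearer
  # bound; returning that bound keeps the expectation monotone in mu
  if (z < 1e-12) return(if (mu < (lo + hi) / 2) lo else hi)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

# keep a (patient-shifted) target mean strictly inside truncation bounds
clamp_into <- function(x, lo, hi) {
  margin <- 0.02 * (hi - lo)
  min(max(x, lo + margin), hi - margin)
}

# truncated normal draws; when the bounds are asymmetric about the mean the
# location is adjusted so the expectation is preserved (symmetric bounds use
# the plain sampler, whose draws the adjustment would reproduce anyway)
rtrunc_norm_auto <- function(n, target_mean, sd, lo, hi) {
  if (abs((lo + hi) / 2 - target_mean) < 1e-9)
    rtrunc_norm(n, target_mean, sd, lo, hi)
  else
    rtrunc_norm_meanadj(n, clamp_into(target_mean, lo, hi), sd, lo, hi)
}

# truncated normal draws whose expectation equals `target_mean` even under
# asymmetric bounds (location solved numerically)
rtrunc_norm_meanadj <- function(n, target_mean, sd, lo, hi) {
  if (sd <= 0) return(rep(target_mean, n))
  if (target_mean <= lo || target_mean >= hi)
    stop("target mean must lie inside the truncation bounds")
  f <- function(mu) etrunc(mu, sd, lo, hi) - target_mean
  mu <- stats::uniroot(f, lower = lo - 8 * sd, upper = hi + 8 * sd,
                       extendInt = "upX", tol = 1e-10)$root
  rtrunc_norm(n, mu, sd, lo, hi)
}

#' Sample phantom specifications for one genotype group
#'
#' Draws n independent per-cell parameter sets from the group distributions.
#' Bounds keep every draw inside the geometrically renderable range; where a
#' bound is asymmetric (nucleus sphericity, nucleolus volume) the sampling
#' location is adjusted so the expectation still equals the group mean.
#'
#' @param params A [group_params()].
#' @param n Number of cells.
#' @param seed Optional seed.
#' @param patient_effects Optional named numeric vector of patient-level mean
#'   shifts in sd units (see [generate_cohort()]); default none.
#' @return A tibble with one row per cell and one column per spec field.
#' @export
sample_phantom_specs <- function(params, n, seed = NULL,
                                 patient_effects = NULL) {
  stopifnot(inherits(params, "group_params"))
  with_seed(seed, {
    shift <- function(nm) {
      if (is.null(patient_effects) || is.null(patient_effects[[nm]])) 0
      else patient_effects[[nm]] * params[[nm]][2]
    }
    cw <- function(nm) {
      # cell-level sd when part of the variance sits at the patient level
      frac <- if (is.null(patient_effects)) 0 else params$patient_var_frac
      params[[nm]][2] * sqrt(1 - frac)
    }
    mean_of <- function(nm) params[[nm]][1] + shift(nm)

    cell_volume <- rtrunc_norm_auto(
      n, mean_of("cell_volume"), cw("cell_volume"),
      max(120, params$cell_volume[1] - 2.5 * params$cell_volume[2]),
      params$cell_volume[1] + 2.5 * params$cell_volume[2])
    cell_sphericity <- rtrunc_norm_auto(
      n, mean_of("cell_sphericity"), cw("cell_sphericity"),
      max(0.40, params$cell_sphericity[1] - 2.5 * params$cell_sphericity[2]),
      min(0.96, params$cell_sphericity[1] + 2.5 * params$cell_sphericity[2]))
    nc_volume_ratio <- rtrunc_norm_auto(
      n, mean_of("nc_volume_ratio"), cw("nc_volume_ratio"),
      max(0.28, params$nc_volume_ratio[1] - 2 * params$nc_volume_ratio[2]),
      min(0.56, params$nc_volume_ratio[1] + 2 * params$nc_volume_ratio[2]))
    # lower bound set by the shape model's irregularity floor (relaxed for
    # configurations whose mean sits near or below it)
    psi_n_mean <- mean_of("nucleus_sphericity")
    psi_n_lo <- min(0.465, psi_n_mean - 0.5 * params$nucleus_sphericity[2])
    psi_n_hi <- min(0.97, psi_n_mean + 2 * params$nucleus_sphericity[2])
    nucleus_sphericity <- rtrunc_norm_meanadj(
      n, clamp_into(psi_n_mean, psi_n_lo, psi_n_hi),
      cw("nucleus_sphericity"), psi_n_lo, psi_n_hi)
    nv_hi <- params$nucleolus_total_volume[1] +
      2.5 * params$nucleolus_total_volume[2]
    nucleolus_total_volume <- rtrunc_norm_meanadj(
      n, clamp_into(mean_of("nucleolus_total_volume"), 1.5, nv_hi),
      cw("nucleolus_total_volume"), 1.5, nv_hi)
    mean_ri_cytoplasm <- rtrunc_norm(
      n, mean_of("mean_ri_cytoplasm"), cw("mean_ri_cytoplasm"),
      mean_of("mean_ri_cytoplasm") - 2.5 * params$mean_ri_cytoplasm[2],
      mean_of("mean_ri_cytoplasm") + 2.5 * params$mean_ri_cytoplasm[2])
    # nucleoplasm RI = cytoplasm RI + positive offset (whole-cell protein
    # content shifts both compartments together); offset moments chosen so
    # the nucleoplasm marginal keeps its printed mean and sd
    dnp_mean <- params$mean_ri_nucleoplasm[1] - params$mean_ri_cytoplasm[1] +
      shift("mean_ri_nucleoplasm") - shift("mean_ri_cytoplasm")
    dnp_sd <- sqrt(max(params$mean_ri_nucleoplasm[2]^2 -
                         params$mean_ri_cytoplasm[2]^2, 1e-8))
    dnp <- rtrunc_norm_meanadj(n, dnp_mean, dnp_sd, 0.0022,
                               dnp_mean + 3 * dnp_sd)
    mean_ri_nucleoplasm <- mean_ri_cytoplasm + dnp
    # nucleolus RI = nucleoplasm RI + positive offset; offset moments chosen
    # so the nucleolus marginal keeps its printed mean and sd
    d_mean <- params$mean_ri_nucleolus[1] - params$mean_ri_nucleoplasm[1] +
      shift("mean_ri_nucleolus") - shift("mean_ri_nucleoplasm")
    d_sd <- sqrt(max(params$mean_ri_nucleolus[2]^2 -
                       params$mean_ri_nucleoplasm[2]^2, 1e-8))
    delta <- rtrunc_norm(n, d_mean, d_sd, max(5e-4, d_mean - 3 * d_sd),
                         d_mean + 3 * d_sd)
    mean_ri_nucleolus <- mean_ri_nucleoplasm + delta

    nucleolus_count <- sample(
      seq(params$nucleolus_count_range[1], params$nucleolus_count_range[2]),
      n, replace = TRUE)
    lipid_droplet_count <- rbinom(n, 1, params$lipid_droplet_prob) *
      sample.int(params$lipid_droplet_max, n, replace = TRUE)

    tibble::tibble(
      cell_volume, cell_sphericity, nc_volume_ratio, nucleus_sphericity,
      nucleolus_count, nucleolus_total_volume,
      mean_ri_cytoplasm, mean_ri_nucleoplasm, mean_ri_nucleolus,
      lipid_droplet_count, lipid_ri = params$lipid_ri,
      ri_texture_sd = params$ri_texture_sd)
  })
}

# one tibble row -> phantom_spec
spec_from_row <- function(row) {
  do.call(phantom_spec, as.list(row[intersect(names(row), names(formals(phantom_spec)))]))
}

#' Generate a synthetic patient cohort manifest
#'
#' Builds the two-genotype cohort: patients, per-patient image counts, per-cell
#' phantom parameters (hierarchically sampled: a patient-level mean shift
#' followed by cell-level draws), variant allele fractions for mutant
#' patients, and the train / optimization / generalization / validation split.
#' Validation patients (4 per genotype by default) are disjoint from training
#' patients and hold 333 of the 2,073 default images, mirroring the study
#' design. Tomograms are not rendered here; see [render_cohort()].
#'
#' @param wt,mut [group_params()] for the two genotypes.
#' @param seed Integer seed.
#' @param n_validation_patients Validation patients per genotype.
#' @param n_validation_images Total validation images (split across genotypes
#'   proportionally to group size).
#' @param opt_gen_ratio Named list with the optimization:generalization image
#'   proportions per genotype (defaults follow the study: 637:144 for WT,
#'   574:410 for MUT).
#' @return List with `manifest` (tibble: patient_id, genotype, vaf, image_id,
#'   split) and `specs` (tibble of per-image phantom parameters, same order).
#' @export
generate_cohort <- function(wt = group_params("WT"),
                            mut = group_params("MUT"),
                            seed = 1,
                            n_validation_patients = 4L,
                            n_validation_images = 333L,
                            opt_gen_ratio = list(WT = c(637, 144),
                                                 MUT = c(574, 410))) {
  with_seed(derive_seed(seed, "cohort"), {
    groups <- list(WT = wt, MUT = mut)
    n_tot <- sum(vapply(groups, function(g) as.numeric(g$image_count), 0))
    out_manifest <- list()
    out_specs <- list()
    for (gname in names(groups)) {
      g <- groups[[gname]]
      n_img <- g$image_count
      n_pat <- g$patient_count
      if (n_pat < 1) stop("patient_count must be >= 1")
      if (n_img < n_pat) stop("image_count below patient_count for ", gname)
      n_val_img <- round(n_validation_images * n_img / n_tot)
      if (gname == names(groups)[length(groups)])
        n_val_img <- n_validation_images -
          sum(vapply(out_manifest, function(m) sum(m$split == "validation"), 0L))
      pat_ids <- sprintf("%s%02d", tolower(gname), seq_len(n_pat))
      val_pats <- sample(pat_ids, n_validation_patients)
      trn_pats <- setdiff(pat_ids, val_pats)
      # per-patient image counts: multinomial within the validation and
      # training blocks so the block totals are exact
      cnt <- integer(n_pat)
      names(cnt) <- pat_ids
      cnt[val_pats] <- as.integer(
        stats::rmultinom(1, n_val_img - length(val_pats),
                         rep(1, length(val_pats)))) + 1L
      cnt[trn_pats] <- as.integer(
        stats::rmultinom(1, (n_img - n_val_img) - length(trn_pats),
                         rep(1, length(trn_pats)))) + 1L
      ratio <- opt_gen_ratio[[gname]]
      p_opt <- ratio[1] / sum(ratio)
      rows <- list()
      specs <- list()
      for (p in pat_ids) {
        eff <- stats::rnorm(8, 0, sqrt(g$patient_var_frac))
        names(eff) <- c("cell_volume", "cell_sphericity", "nc_volume_ratio",
                        "nucleus_sphericity", "nucleolus_total_volume",
                        "mean_ri_cytoplasm", "mean_ri_nucleoplasm",
                        "mean_ri_nucleolus")
        if (g$patient_var_frac == 0) eff[] <- 0
        # RI offsets between compartments keep their distributions: all
        # three compartment RIs share one patient-level shift
        eff[["mean_ri_nucleoplasm"]] <- eff[["mean_ri_cytoplasm"]]
        eff[["mean_ri_nucleolus"]] <- eff[["mean_ri_cytoplasm"]]
        sp <- sample_phantom_specs(g, cnt[[p]], patient_effects = as.list(eff))
        vaf <- if (gname == "MUT")
          stats::runif(1, g$vaf_range[1], g$vaf_range[2]) else 0
        is_val <- p %in% val_pats
        split <- if (is_val) rep("validation", cnt[[p]]) else
          ifelse(stats::runif(cnt[[p]]) < p_opt, "optimization",
                 "generalization")
        rows[[p]] <- tibble::tibble(
          patient_id = p, genotype = gname, vaf = vaf,
          image_id = sprintf("%s_c%04d", p, seq_len(cnt[[p]])),
          split = split)
        specs[[p]] <- sp
      }
      out_manifest[[gname]] <- dplyr::bind_rows(rows)
      out_specs[[gname]] <- dplyr::bind_rows(specs)
    }
    manifest <- dplyr::bind_rows(out_manifest)
    specs <- dplyr::bind_rows(out_specs)
    specs$image_id <- manifest$image_id
    list(manifest = manifest, specs = specs)
  })
}

#' Render cohort phantoms to tomogram files
#'
#' Renders each image of a cohort (or a subset) with [generate_phantom()] and
#' writes HDF5 tomograms plus ground-truth masks into `output_dir`, updating
#' the manifest with file paths. Rendering is seeded per image, so any subset
#' can be rendered reproducibly in any order.
#'
#' @param cohort Result of [generate_cohort()].
#' @param output_dir Directory for tomogram files.
#' @param seed Integer master seed (per-image seeds are derived from it).
#' @param image_ids Optional subset of image ids to render.
#' @param grid_dim,voxel_spacing,medium_ri,noise_sd Rendering parameters,
#'   passed to [generate_phantom()].
#' @return The manifest tibble with an `image_path` column.
#' @export
render_cohort <- function(cohort, output_dir, seed = 1, image_ids = NULL,
                          grid_dim = c(96, 96, 48),
                          voxel_spacing = c(0.156, 0.156, 0.312),
                          medium_ri = 1.337, noise_sd = 0.001) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort$manifest
  specs <- cohort$specs
  sel <- if (is.null(image_ids)) manifest$image_id else image_ids
  paths <- character(length(sel))
  for (i in seq_along(sel)) {
    id <- sel[i]
    row <- specs[match(id, specs$image_id), ]
    ph <- generate_phantom(spec_from_row(row), grid_dim, voxel_spacing,
                           medium_ri, noise_sd,
                           seed = derive_seed(seed, paste0("render_", id)))
    paths[i] <- file.path(output_dir, paste0(id, ".h5"))
    write_tomogram(ph$tomogram, paths[i], mask = ph$mask)
  }
  manifest$image_path <- NA_character_
  manifest$image_path[match(sel, manifest$image_id)] <- paths
  manifest
}
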