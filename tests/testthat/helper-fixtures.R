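# Shared fixtures. All voxel data are generated in code; batch results that
# several test files reuse are memoized in this environment.
fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# digital ellipsoid mask (semi-axes in physical units)
mk_ellipsoid <- function(radii, spacing, grid_dim) {
  cx <- ((seq_len(grid_dim[1]) - (grid_dim[1] + 1) / 2) * spacing[1])
  cy <- ((seq_len(grid_dim[2]) - (grid_dim[2] + 1) / 2) * spacing[2])
  cz <- ((seq_len(grid_dim[3]) - (grid_dim[3] + 1) / 2) * spacing[3])
  q <- outer(outer((cx / radii[1])^2, (cy / radii[2])^2, `+`),
             (cz / radii[3])^2, `+`)
  array(q <= 1, grid_dim)
}

mk_cube <- function(side_vox, margin = 4L) {
  n <- side_vox + 2L * margin
  m <- array(FALSE, c(n, n, n))
  sel <- margin + seq_len(side_vox)
  m[sel, sel, sel] <- TRUE
  m
}

# closed-form surface area of an axis-aligned prolate spheroid (a >= b = c)
spheroid_area <- function(a, b) {
  e <- sqrt(1 - b^2 / a^2)
  2 * pi * b^2 * (1 + a / (b * e) * asin(e))
}

sphericity_of <- function(V, A) pi^(1 / 3) * (6 * V)^(2 / 3) / A

# default-parameter phantom on the reduced analysis grid
default_phantom <- function(noise_sd = 0, seed = 42) {
  memo(sprintf("phantom_%g_%d", noise_sd, seed),
       generate_phantom(phantom_spec(), grid_dim = c(96, 96, 48),
                        noise_sd = noise_sd, seed = seed))
}

# small uniform-RI tomogram for arithmetic oracles
uniform_tomogram <- function(delta_n, n_voxels_region, medium_ri = 1.337,
                             spacing = c(0.1, 0.1, 0.1)) {
  d <- c(8L, 8L, 8L)
  ri <- array(medium_ri, d)
  lab <- array(0L, d)
  idx <- seq_len(n_voxels_region)
  ri[idx] <- medium_ri + delta_n
  lab[idx] <- 1L
  list(tomo = tomogram(ri, spacing, medium_ri),
       mask = seg_mask(lab, "ground_truth"))
}

# toy two-class cohort for the classifier smoke test: strongly separated
# sphericities rendered at 64x64x32 and block-averaged to the 32x32x16
# network input
toy_cohort <- function(n_per_class = 100, seed = 5) {
  memo(sprintf("toy_%d_%d", n_per_class, seed), {
    sp <- c(0.235, 0.235, 0.47)
    gd <- c(64L, 64L, 32L)
    vols <- list(); labels <- c(); roles <- c()
    for (g in c("WT", "MUT")) {
      psi <- if (g == "WT") 0.66 else 0.44
      nc <- if (g == "WT") 0.52 else 0.30
      gp <- group_params(g, cell_volume = c(330, 60),
                         cell_sphericity = c(psi, 0.02),
                         nucleus_sphericity = c(psi, 0.02),
                         nc_volume_ratio = c(nc, 0.02),
                         mean_ri_cytoplasm = c(1.3633, 0.001),
                         mean_ri_nucleoplasm = c(1.3692, 0.0012),
                         mean_ri_nucleolus = c(1.3760, 0.0013))
      specs <- sample_phantom_specs(gp, n_per_class,
                                    seed = derive_seed(seed, g))
      for (i in seq_len(n_per_class)) {
        id <- sprintf("%s_%03d", g, i)
        ph <- generate_phantom(spec_from_row(specs[i, ]), gd, sp,
                               noise_sd = 0.001,
                               seed = derive_seed(seed, id))
        vols[[id]] <- downsample_volume(
          (ph$tomogram$ri - 1.337) / 0.04, 2L)
        labels[id] <- g
        roles[id] <- if (i <= 0.7 * n_per_class) "optimization"
          else if (i <= 0.8 * n_per_class) "generalization" else "holdout"
      }
    }
    list(vols = vols, labels = labels, roles = roles)
  })
}

# measured phantom batches at the study's reduced grid (shared between the
# round-trip recovery tests and the acceptance suite)
recovery_batch <- function(genotype, n = 200, seed = 20260921) {
  memo(sprintf("recovery_%s_%d_%d", genotype, n, seed),
       measure_phantom_batch(group_params(genotype), n,
                             seed = derive_seed(seed, genotype)))
}

# spec_from_row is internal to the package; reuse it in fixtures
spec_from_row <- holoblast:::spec_from_row
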