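test_that("dry mass follows the linear RI-concentration relation", {
  # 0.001 RI contrast at alpha = 0.185 mL/g -> 5.4 fg/fL
  u <- uniform_tomogram(0.001, 100)
  dm <- dry_mass(u$tomo, u$mask, "cytoplasm", alpha = 0.185)
  expect_lt(abs(dm$concentration * 1000 - 5.4), 0.1)  # fg/fL per 1e-3 RI
  # uniform contrast 0.037 over 15 fL -> 3.0 pg
  d <- c(10L, 10L, 15L)
  ri <- array(1.337 + 0.037, d)
  lab <- array(1L, d)
  # 15 fL as 1500 voxels of 0.01 fL each
  tomo <- tomogram(ri, rep(0.01^(1 / 3), 3), 1.337)
  dm <- dry_mass(tomo, seg_mask(lab, "ground_truth"), "cytoplasm", 0.185)
  expect_equal(dm$dry_mass, 0.037 / 0.185 * 15, tolerance = 1e-6)
  expect_equal(dm$dry_mass, 3.0, tolerance = 0.01)
})

test_that("dry mass vanishes at medium RI and scales linearly in contrast", {
  d <- c(6L, 6L, 6L)
  lab <- seg_mask(array(1L, d), "ground_truth")
  t0 <- tomogram(array(1.337, d), c(0.2, 0.2, 0.2), 1.337)
  expect_equal(dry_mass(t0, lab, "cytoplasm")$dry_mass, 0)
  set.seed(4)
  base <- array(1.337 + runif(prod(d), 0, 0.03), d)
  t1 <- tomogram(base, c(0.2, 0.2, 0.2), 1.337)
  t3 <- tomogram(1.337 + 3 * (base - 1.337), c(0.2, 0.2, 0.2), 1.337)
  expect_equal(dry_mass(t3, lab, "cytoplasm")$dry_mass,
               3 * dry_mass(t1, lab, "cytoplasm")$dry_mass,
               tolerance = 1e-12)
})

test_that("dry mass is additive over the compartment partition", {
  ph <- default_phantom(noise_sd = 0.001, seed = 42)
  parts <- c("cytoplasm", "nucleoplasm", "nucleolus")
  m_parts <- vapply(parts, function(r)
    dry_mass(ph$tomogram, ph$mask, r)$dry_mass, 0)
  lip <- dry_mass(ph$tomogram, ph$mask, "lipid")
  m_lip <- if (isTRUE(lip$present)) lip$dry_mass else 0
  m_cell <- dry_mass(ph$tomogram, ph$mask, "cell")$dry_mass
  expect_equal(m_cell, sum(m_parts) + m_lip, tolerance = 1e-10)
})

test_that("N/C ratios follow closed-form projections", {
  sp <- c(1, 1, 1)
  gd <- c(61L, 61L, 61L)
  cell <- mk_ellipsoid(c(24, 24, 24), sp, gd)
  # nucleus at half the cell radius: volume ratio 1/8, projected ratio 1/4
  nuc <- mk_ellipsoid(c(12, 12, 12), sp, gd)
  lab <- array(0L, gd)
  lab[cell] <- 1L
  lab[nuc] <- 2L
  r <- nc_ratios(seg_mask(lab, "ground_truth"))
  expect_lt(abs(r$nc_volume_ratio - 0.125), 0.003)
  expect_lt(abs(r$nc_area_ratio_2d - 0.25), 0.01)
  # concentric spheres at volume ratio 0.417: projected ratio 0.417^(2/3)
  nuc2 <- mk_ellipsoid(rep(24 * 0.417^(1 / 3), 3), sp, gd)
  lab2 <- array(0L, gd)
  lab2[cell] <- 1L
  lab2[nuc2] <- 2L
  r2 <- nc_ratios(seg_mask(lab2, "ground_truth"))
  expect_lt(abs(r2$nc_area_ratio_2d - 0.417^(2 / 3)), 0.01)
  # nucleus = cell: both ratios are exactly 1
  lab3 <- array(0L, gd)
  lab3[cell] <- 2L
  r3 <- nc_ratios(seg_mask(lab3, "ground_truth"))
  expect_identical(r3$nc_volume_ratio, 1)
  expect_identical(r3$nc_area_ratio_2d, 1)
})

test_that("absent regions yield explicit missing results, not zeros", {
  d <- c(8L, 8L, 8L)
  lab <- array(0L, d)
  lab[2:6, 2:6, 2:6] <- 1L
  msk <- seg_mask(lab, "ground_truth")
  g <- region_geometry(msk, "nucleolus", c(0.2, 0.2, 0.2))
  expect_false(g$present)
  expect_true(is.na(g$volume))
  tomo <- tomogram(array(1.35, d), c(0.2, 0.2, 0.2))
  expect_false(dry_mass(tomo, msk, "nucleus")$present)
  expect_true(is.na(nc_ratios(msk)$nc_volume_ratio))
})

test_that("measure_cell populates every field and respects the partition", {
  ph <- default_phantom(noise_sd = 0)
  m <- measure_cell(ph$tomogram, ph$mask)
  needed <- c("volume_cell", "area_cell", "sphericity_cell",
              "mean_ri_cell", "dry_mass_cell", "concentration_cell",
              "volume_nucleus", "volume_nucleoplasm", "volume_nucleolus",
              "volume_cytoplasm", "nc_volume_ratio", "nc_area_ratio_2d")
  expect_true(all(needed %in% names(m)))
  expect_true(all(!is.na(unlist(m[needed]))))
  expect_equal(m$volume_nucleus,
               m$volume_nucleoplasm + m$volume_nucleolus,
               tolerance = 1e-10)
  expect_gt(m$nc_volume_ratio, 0)
  expect_lt(m$nc_volume_ratio, 1)
})
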