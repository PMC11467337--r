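test_that("ground-truth region mean RI equals the spec before noise", {
  ph <- default_phantom(noise_sd = 0)
  spec <- phantom_spec()
  ri <- ph$tomogram$ri
  lab <- ph$mask$labels
  expect_lt(abs(mean(ri[lab == 3L]) - spec$mean_ri_nucleolus), 1e-4)
  expect_lt(abs(mean(ri[lab == 2L]) - spec$mean_ri_nucleoplasm), 1e-4)
  expect_lt(abs(mean(ri[lab == 1L]) - spec$mean_ri_cytoplasm), 1e-4)
})

test_that("ground-truth mask partitions the cell exactly", {
  ph <- default_phantom(noise_sd = 0)
  lab <- ph$mask$labels
  cell <- sum(lab != 0L)
  expect_identical(cell, sum(lab == 1L) + sum(lab == 2L) +
                     sum(lab == 3L) + sum(lab == 4L))
  # nucleus strictly inside cell, nucleoli strictly inside nucleus
  nuc <- lab == 2L | lab == 3L
  din <- sqrt(array(holoblast:::.edt_sq(!(lab != 0L), dim(lab),
                                        ph$tomogram$voxel_spacing),
                    dim(lab)))
  expect_true(all(din[nuc] > 0))
})

test_that("zero nucleolus count yields no nucleolus label", {
  spec <- phantom_spec(cell_volume = 250, nucleolus_count = 0)
  ph <- generate_phantom(spec, grid_dim = c(64, 64, 32), noise_sd = 0,
                         seed = 9)
  expect_identical(sum(ph$mask$labels == 3L), 0L)
})

test_that("the default cell fits the grid with margin and rendering is seeded", {
  ph1 <- generate_phantom(phantom_spec(), grid_dim = c(96, 96, 48),
                          noise_sd = 0.001, seed = 5)
  ph2 <- generate_phantom(phantom_spec(), grid_dim = c(96, 96, 48),
                          noise_sd = 0.001, seed = 5)
  expect_identical(ph1$tomogram$ri, ph2$tomogram$ri)
  expect_identical(ph1$mask$labels, ph2$mask$labels)
  # two-voxel margin: no cell voxel on the grid boundary shells
  lab <- ph1$mask$labels
  expect_true(all(lab[1:2, , ] == 0L) && all(lab[, , 1:2] == 0L))
  d <- dim(lab)
  expect_true(all(lab[(d[1] - 1):d[1], , ] == 0L))
  expect_true(all(lab[, , (d[3] - 1):d[3]] == 0L))
})

test_that("impossible compartment geometry is rejected before rendering", {
  expect_error(phantom_spec(nucleolus_total_volume = 400,
                            cell_volume = 450, nc_volume_ratio = 0.4),
               "below the nucleus volume")
  expect_error(phantom_spec(mean_ri_nucleolus = 1.360,
                            mean_ri_nucleoplasm = 1.369),
               "must exceed")
  expect_error(phantom_spec(nc_volume_ratio = 1.2), "nucleus smaller")
  expect_error(generate_phantom(phantom_spec(cell_volume = 4000),
                                grid_dim = c(64, 64, 32)),
               "does not fit")
})

test_that("tomogram noise floor respects the clamped-noise invariant", {
  ph <- default_phantom(noise_sd = 0.001, seed = 42)
  expect_gte(min(ph$tomogram$ri), ph$tomogram$medium_ri - 3 * 0.001)
  expect_true(all(is.finite(ph$tomogram$ri)))
})
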