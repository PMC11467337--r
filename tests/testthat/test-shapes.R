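test_that("iso-surface area matches closed forms for canonical solids", {
  sp <- c(1, 1, 1)
  ball <- mk_ellipsoid(c(20, 20, 20), sp, c(51, 51, 51))
  A <- surface_area(ball, sp)
  V <- sum(ball)
  expect_lt(abs(A / (4 * pi * 20^2) - 1), 0.03)
  expect_lt(abs(sphericity_of(V, A) - 1), 0.02)

  cube <- mk_cube(128L)
  A <- surface_area(cube, sp)
  V <- sum(cube)
  expect_lt(abs(A / (6 * 128^2) - 1), 0.03)
  expect_lt(abs(sphericity_of(V, A) - 0.806), 0.01)

  sph <- mk_ellipsoid(c(40, 20, 20), sp, c(91, 51, 51))
  A <- surface_area(sph, sp)
  V <- sum(sph)
  A_true <- spheroid_area(40, 20)
  psi_true <- sphericity_of(4 / 3 * pi * 40 * 20^2, A_true)
  expect_lt(abs(A / A_true - 1), 0.03)
  expect_lt(abs(sphericity_of(V, A) - psi_true), 0.02)
  expect_lt(abs(psi_true - 0.929), 0.002)  # closed-form oracle itself
})

test_that("sphericity is invariant to isotropic rescaling of the grid", {
  ball <- mk_ellipsoid(c(15, 15, 15), c(1, 1, 1), c(41, 41, 41))
  g1 <- holoblast:::mask_geometry(ball, c(1, 1, 1))
  g2 <- holoblast:::mask_geometry(ball, c(0.2, 0.2, 0.2))
  # invariant up to voxel-midpoint rounding ties in the guide lookup
  expect_equal(g1$sphericity, g2$sphericity, tolerance = 3e-3)
  expect_equal(g2$volume, g1$volume * 0.2^3, tolerance = 1e-10)
})

test_that("synthesize_shape hits target volume and sphericity", {
  s <- synthesize_shape(450, 0.80, seed = 7)
  expect_lt(abs(attr(s, "volume") / 450 - 1), 0.03)
  expect_gte(attr(s, "sphericity"), 0.78)
  expect_lte(attr(s, "sphericity"), 0.82)
  # single connected component
  lab <- holoblast:::.label_components(s, dim(s))
  expect_lte(attr(lab, "n_components"), 1L)
})

test_that("a sphericity-1 target yields a near-perfect ball", {
  s <- synthesize_shape(450, 1.0, seed = 8)
  expect_gte(attr(s, "sphericity"), 0.98)
})

test_that("shape synthesis is deterministic under a fixed seed", {
  a <- synthesize_shape(300, 0.75, seed = 3)
  b <- synthesize_shape(300, 0.75, seed = 3)
  expect_identical(a, b)
})

test_that("unreachable sphericity fails with the achievable range", {
  expect_error(synthesize_shape(300, 0.05, seed = 4),
               "achievable floor")
})

test_that("too-small targets are rejected at the given spacing", {
  expect_error(synthesize_shape(1, 0.9, voxel_spacing = c(0.5, 0.5, 1)),
               "fewer than 10 voxels")
})
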