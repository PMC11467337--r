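test_that("rule-based segmentation recovers the default phantom", {
  ph <- default_phantom(noise_sd = 0)
  sm <- segment_rule_based(ph$tomogram, segment_params(noise_sd = 0))
  expect_identical(sm$provenance, "rule_based")
  for (r in c("cell", "nucleus", "nucleolus", "cytoplasm"))
    expect_gte(dice_coefficient(ph$mask, sm, r), 0.95)
})

test_that("cell segmentation is robust at the default sensor noise", {
  ph <- default_phantom(noise_sd = 0.001, seed = 42)
  sm <- segment_rule_based(ph$tomogram, segment_params(noise_sd = 0.001))
  expect_gte(dice_coefficient(ph$mask, sm, "cell"), 0.90)
})

test_that("an all-medium field raises an empty-field error", {
  tomo <- tomogram(array(1.337, c(32, 32, 16)))
  expect_error(segment_rule_based(tomo), "empty field")
})

test_that("two similarly sized cells raise an ambiguity error", {
  d <- c(64L, 64L, 32L)
  ri <- array(1.337, d)
  sp <- c(0.3, 0.3, 0.6)
  b1 <- mk_ellipsoid(c(3, 3, 3), sp, c(24L, 24L, 16L))
  ri[1:24, 1:24, 9:24][b1] <- 1.365
  ri[40:63, 40:63, 9:24][b1] <- 1.365
  expect_error(segment_rule_based(tomogram(ri, sp)), "ambiguous")
})

test_that("segmentation output is a valid partition", {
  ph <- default_phantom(noise_sd = 0.001, seed = 42)
  sm <- segment_rule_based(ph$tomogram, segment_params(noise_sd = 0.001))
  lab <- sm$labels
  expect_true(all(lab %in% 0:4))
  # nucleoli inside nucleus region by construction
  expect_identical(sum(lab == 3L & !(lab %in% c(2L, 3L))), 0L)
  # the cell is a single connected component
  cc <- holoblast:::.label_components(lab != 0L, dim(lab))
  expect_identical(attr(cc, "n_components"), 1L)
})
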