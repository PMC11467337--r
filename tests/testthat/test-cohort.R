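test_that("default cohort reproduces the study's image and split counts", {
  cohort <- memo("cohort_default", generate_cohort(seed = 1))
  m <- cohort$manifest
  expect_identical(nrow(m), 2073L)
  expect_identical(sum(m$genotype == "MUT"), 1173L)
  expect_identical(sum(m$genotype == "WT"), 900L)
  expect_identical(sum(m$split == "validation"), 333L)
  expect_identical(sum(m$split != "validation"), 1740L)
  val_pat <- unique(m$patient_id[m$split == "validation"])
  trn_pat <- unique(m$patient_id[m$split != "validation"])
  expect_identical(length(val_pat), 8L)
  expect_identical(sum(grepl("^mut", val_pat)), 4L)
  expect_identical(sum(grepl("^wt", val_pat)), 4L)
  expect_length(intersect(val_pat, trn_pat), 0)
  # patient totals
  expect_identical(length(unique(m$patient_id)), 48L)
  expect_identical(length(unique(m$patient_id[m$genotype == "MUT"])), 22L)
  expect_identical(length(unique(m$patient_id[m$genotype == "WT"])), 26L)
  # every image belongs to exactly one patient and has one spec row
  expect_identical(anyDuplicated(m$image_id), 0L)
  expect_identical(cohort$specs$image_id, m$image_id)
})

test_that("mutant patients carry VAF in the configured range, wild-type zero", {
  cohort <- memo("cohort_default", generate_cohort(seed = 1))
  m <- cohort$manifest
  expect_true(all(m$vaf[m$genotype == "WT"] == 0))
  expect_true(all(m$vaf[m$genotype == "MUT"] >= 0.2 &
                    m$vaf[m$genotype == "MUT"] <= 0.5))
})

test_that("cohort generation is deterministic in the seed", {
  a <- generate_cohort(seed = 7)
  b <- generate_cohort(seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(seed = 8)
  expect_false(identical(a$manifest$patient_id, c$manifest$patient_id) &&
                 identical(a$specs, c$specs))
})

test_that("hierarchical sampling collapses to iid when patient variance is 0", {
  gp <- group_params("MUT", patient_var_frac = 0)
  eff <- as.list(stats::setNames(rep(0.9, 8),
    c("cell_volume", "cell_sphericity", "nc_volume_ratio",
      "nucleus_sphericity", "nucleolus_total_volume", "mean_ri_cytoplasm",
      "mean_ri_nucleoplasm", "mean_ri_nucleolus")))
  # with zero patient variance the same cell-level stream gives identical
  # draws whether or not patient effects are supplied
  a <- sample_phantom_specs(gp, 50, seed = 3,
                            patient_effects = lapply(eff, function(x) 0))
  b <- sample_phantom_specs(gp, 50, seed = 3)
  # b uses the full sd (no patient split); compare distributional location
  expect_lt(abs(mean(a$cell_volume) - mean(b$cell_volume)), 25)
  expect_identical(sample_phantom_specs(gp, 20, seed = 9),
                   sample_phantom_specs(gp, 20, seed = 9))
})

test_that("sampled specs satisfy the generator invariants", {
  specs <- sample_phantom_specs(group_params("WT"), 300, seed = 11)
  expect_true(all(specs$mean_ri_nucleolus > specs$mean_ri_nucleoplasm))
  expect_true(all(specs$mean_ri_nucleoplasm > specs$mean_ri_cytoplasm))
  expect_true(all(specs$nc_volume_ratio > 0 & specs$nc_volume_ratio < 1))
  expect_true(all(specs$nucleolus_total_volume <
                    specs$nc_volume_ratio * specs$cell_volume))
  expect_true(all(specs$nucleus_sphericity > 0 &
                    specs$nucleus_sphericity <= 1))
  # mean-preserving truncation: sample means stay near the group means
  expect_lt(abs(mean(specs$nucleus_sphericity) - 0.501),
            3 * sd(specs$nucleus_sphericity) / sqrt(300))
  expect_lt(abs(mean(specs$nc_volume_ratio) - 0.400),
            3 * sd(specs$nc_volume_ratio) / sqrt(300))
})
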