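test_that("stage_preset validates inputs and encodes the stage mixtures", {
  expect_error(stage_preset("severe", 10, seed = 1), "unknown stage")
  expect_error(stage_preset("normal", 0, seed = 1), "n_nuclei")

  spec <- stage_preset("normal", 500, seed = 1)
  expect_s3_class(spec, "scene_spec")
  expect_true(all(spec$nuclei$morphotype == "normal"))
  expect_lt(max(abs(spec$nuclei$dna_content - 1)), 4 * 0.08)

  light <- stage_preset("light", 500, seed = 1)
  expect_setequal(unique(light$nuclei$morphotype), c("normal", "A"))
  d <- light$nuclei$dna_content
  expect_gt(sum(abs(d - 6.2) < 1), 50)   # mode near 6.2
  expect_gt(sum(abs(d - 10.7) < 1.5), 20) # mode near 10.7
  expect_true(all(light$nuclei$morphotype[d > 3] == "A"))

  heavy <- stage_preset("heavy", 300, seed = 2)
  expect_true(all(heavy$nuclei$morphotype[heavy$nuclei$dna_content > 3]
                  == "B"))
  expect_true(all(heavy$nuclei$multinucleate[
    heavy$nuclei$dna_content > 20]))
  # nuclei fully inside the frame
  for (sp in list(spec, light, heavy)) {
    ext <- sp$nuclei$base_radius * sqrt(sp$nuclei$aspect_ratio) * 1.5
    expect_true(all(sp$nuclei$x - ext >= 0 & sp$nuclei$x + ext <= sp$width))
    expect_true(all(sp$nuclei$y - ext >= 0 &
                      sp$nuclei$y + ext <= sp$height))
  }
})

test_that("stage-preset mixture modes recover the component centres", {
  spec <- stage_preset("moderate", 800, seed = 3)
  pk <- ploidy_profile(spec$nuclei$dna_content)$peaks
  expect_equal(nrow(pk), 2L)
  expect_lt(abs(pk$location[1] - 1) / 1, 0.05)
  expect_lt(abs(pk$location[2] - 7) / 7, 0.05)
})

test_that("render_scene is deterministic and conservative", {
  spec <- stage_preset("normal", 8, seed = 5, noise_sd = 1.5)
  a <- render_scene(spec)
  b <- render_scene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$label_mask, b$truth$label_mask)

  # noise-free single nucleus: summed OD over the ground-truth mask equals
  # od_per_C * dna_content up to floating error
  spec1 <- stage_preset("normal", 1, seed = 6, noise_sd = 0)
  sc <- render_scene(spec1)
  od <- -log10(sc$image[, , 2] / sc$blank[, , 2])
  got <- sum(od[sc$truth$label_mask == 1L])
  expect_equal(got, spec1$od_per_C * spec1$nuclei$dna_content,
               tolerance = 1e-9)
  # whole-scene conservation within 1%
  spec2 <- stage_preset("light", 30, seed = 7, noise_sd = 0)
  sc2 <- render_scene(spec2)
  od2 <- -log10(sc2$image[, , 2] / sc2$blank[, , 2])
  expect_equal(sum(od2), spec2$od_per_C * sum(spec2$nuclei$dna_content),
               tolerance = 0.01)
  expect_error({
    bad <- spec1; bad$nuclei$base_radius <- 1.5
    render_scene(bad)
  }, "radius")
})

test_that("touching pairs stay separate in truth but fuse in the union", {
  spec <- stage_preset("normal", 10, seed = 3, touching_pair_fraction = 1,
                       noise_sd = 0)
  sc <- render_scene(spec)
  gt <- sc$truth$label_mask
  expect_equal(length(unique(gt[gt > 0])), 10L)
  union <- matrix(as.integer(gt > 0), nrow(gt))
  expect_lt(oracle_component_count(union), 10L)
})

test_that("sample_feature_table reproduces the published group means", {
  expect_error(sample_feature_table("weird", 10, seed = 1), "unknown group")
  expect_error(sample_feature_table("normal", 0, seed = 1), "n must")

  tab <- sample_feature_table("normal", 10000, seed = 7)
  expect_lt(abs(mean(tab$Area) - 117.1), 3 * 94.1 / sqrt(10000))
  tabn <- sample_feature_table("neoplastic", 10000, seed = 7)
  expect_lt(abs(mean(tabn$Perimeter) - 79.03), 3 * 21.3 / sqrt(10000))
  # determinism
  expect_identical(tab, sample_feature_table("normal", 10000, seed = 7))

  # a single record respects all support/ordering invariants
  one <- sample_feature_table("normal", 1, seed = 7)
  expect_equal(nrow(one), 1L)
  expect_true(all(one[, c("Area", "Perimeter", "IOD", "Feret")] > 0))
  expect_lte(one$MinR, one$MaxR)
  expect_lte(one$Breadth, one$Feret)
  expect_lte(one$Feret, 2 * one$MBCRadius + 1e-9)
  expect_lte(one$MBCRadius, one$MaxR + 1e-9)
  expect_gte(one$AspRatio, 1)
  expect_true(all(one[, c("Circularity", "Solidity", "Sphericity")] <= 1))

  big <- sample_feature_table("B", 2000, seed = 9)
  expect_true(all(big$Area > 0))
  expect_true(all(big$Solidity > 0 & big$Solidity <= 1))
  expect_true(all(big$MinR <= big$MaxR))
})

test_that("scene spec JSON round-trip preserves the scene", {
  spec <- stage_preset("moderate", 12, seed = 4)
  f <- tempfile(fileext = ".json")
  write_scene_spec(spec, f)
  back <- read_scene_spec(f)
  expect_equal(back$nuclei, spec$nuclei, tolerance = 1e-12)
  expect_equal(back$width, spec$width)
  expect_equal(back$stage_preset, spec$stage_preset)
  # a re-render from the restored spec is identical
  expect_identical(render_scene(spec)$image, render_scene(back)$image)
  unlink(f)
})
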