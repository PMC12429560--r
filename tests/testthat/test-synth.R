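test_that("striosome area fraction is enforced by quantile thresholding", {
  cfg <- synthesis_config(image_height_px = 512L, image_width_px = 512L,
                          striosome_area_fraction = 0.10, seed = 1L)
  lab <- generate_striosome_mask(cfg)
  frac <- sum(lab == 2L) / sum(lab == 1L | lab == 2L)
  expect_gt(frac, 0.09)
  expect_lt(frac, 0.11)
})

test_that("mask generation is deterministic and validates its inputs", {
  cfg <- small_config(seed = 7L)
  expect_identical(unclass(generate_striosome_mask(cfg)),
                   unclass(generate_striosome_mask(cfg)))
  expect_error(synthesis_config(image_height_px = 0L), "positive")
  expect_error(synthesis_config(striosome_area_fraction = 0.6), "0.5")
  expect_error(synthesis_config(striosome_area_fraction = 0), "0.5")
})

test_that("excluded structures appear only when requested", {
  cfg <- small_config(n_fiber_bundles = 0L, n_vessels = 0L)
  lab <- generate_striosome_mask(cfg)
  expect_false(any(lab == 3L | lab == 4L))
  cfg2 <- small_config(n_fiber_bundles = 3L, n_vessels = 2L)
  lab2 <- generate_striosome_mask(cfg2)
  expect_true(any(lab2 == 3L))
  expect_true(any(lab2 == 4L))
})

test_that("every pixel carries exactly one label and counts sum to size", {
  lab <- generate_striosome_mask(small_config(seed = 2L))
  counts <- tabulate(as.vector(lab) + 1L, nbins = 5L)
  expect_identical(sum(counts), length(lab))
  expect_true(all(lab %in% 0:4))
})

test_that("striosomes form several connected labyrinthine blobs", {
  cfg <- synthesis_config(image_height_px = 512L, image_width_px = 512L,
                          seed = 3L)
  lab <- generate_striosome_mask(cfg)
  expect_gte(max(EBImage::bwlabel(lab == 2L)), 3)
})

test_that("default effect table obeys the disease direction pattern", {
  eff <- default_effect_table()
  expect_true(all(eff$mean_intensity > 10))
  ri <- expected_indices(eff)$RI
  strio <- ri[ri$compartment == "striosome", ]
  expect_true(all(strio$RI[strio$molecule == "MOR1"] >= 1))
  expect_true(all(strio$RI[strio$molecule != "MOR1"] <= 1))
  # wildtype PDE10A striosome mean exceeds its matrix mean
  wt <- eff[eff$genotype == "WT" & eff$molecule == "PDE10A" &
              eff$segment == "DM" & eff$age == 3, ]
  expect_gt(wt$mean_intensity[wt$compartment == "striosome"],
            wt$mean_intensity[wt$compartment == "matrix"])
})

test_that("noiseless rendering reproduces effect-table means exactly", {
  cfg <- small_config(noise_sd = 0)
  lab <- generate_striosome_mask(cfg)
  eff <- default_effect_table()
  sec <- render_section(lab, eff, "PDE10A", "WT", 3L, cfg)
  for (seg in segment_names()) {
    parts <- partition_segments(lab == 1L | lab == 2L)
    sel <- lab == 2L & parts == match(seg, segment_names())
    if (!any(sel)) next
    expect_equal(unique(as.vector(sec$target[sel])),
                 eff$mean_intensity[eff$molecule == "PDE10A" &
                                      eff$genotype == "WT" & eff$age == 3 &
                                      eff$segment == seg &
                                      eff$compartment == "striosome"])
  }
  expect_true(all(sec$target[lab == 0L] == cfg$background_level))
})

test_that("noisy rendering hits configured means within standard error", {
  cfg <- synthesis_config(image_height_px = 512L, image_width_px = 512L,
                          noise_sd = 5, seed = 11L)
  lab <- generate_striosome_mask(cfg)
  eff <- default_effect_table()
  sec <- render_section(lab, eff, "MOR1", "WT", 3L, cfg)
  n <- sum(lab == 2L)
  expect_gt(n, 10000)
  # MOR1 wildtype striosome mean is 150 everywhere
  expect_lt(abs(mean(sec$reference[lab == 2L]) - 150), 0.5)
})

test_that("MOR1 striosome signal is upregulated in the Q175KI render", {
  cfg <- small_config(noise_sd = 5)
  lab <- generate_striosome_mask(cfg)
  eff <- default_effect_table()
  wt <- render_section(lab, eff, "MOR1", "WT", 12L, cfg)
  ki <- render_section(lab, eff, "MOR1", "Q175KI", 12L, cfg)
  expect_gte(mean(ki$reference[lab == 2L]), mean(wt$reference[lab == 2L]))
})

test_that("a missing effect-table condition raises an explicit error", {
  cfg <- small_config()
  lab <- generate_striosome_mask(cfg)
  eff <- default_effect_table()
  expect_error(render_section(lab, eff, "MOR1", "WT", 9L, cfg),
               "missing effect-table condition")
})

test_that("cohort size, seeds and reproducibility follow the design", {
  cfg <- small_config(noise_sd = 5)
  co <- generate_cohort(default_effect_table(), 1L, cfg,
                        molecules = c("MOR1", "PDE10A"))
  meta <- attr(co, "meta")
  # 2 genotypes x 3 ages x 1 mouse x 2 hemispheres per molecule
  expect_identical(nrow(meta), 24L)
  expect_identical(sum(meta$molecule == "MOR1"), 12L)
  expect_identical(anyDuplicated(meta$seed), 0L)
  co2 <- generate_cohort(default_effect_table(), 1L, cfg,
                         molecules = c("MOR1", "PDE10A"))
  expect_identical(co[[5]]$section$target, co2[[5]]$section$target)
  # extending the cohort preserves existing per-section seeds
  co3 <- generate_cohort(default_effect_table(), 2L, cfg,
                         molecules = c("MOR1", "PDE10A"))
  m3 <- attr(co3, "meta")
  expect_true(all(meta$seed %in% m3$seed))
})
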