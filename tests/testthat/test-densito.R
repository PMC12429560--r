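test_that("a centered square striatum splits into four equal quadrants", {
  mask <- matrix(FALSE, 40, 40)
  mask[11:30, 11:30] <- TRUE
  parts <- partition_segments(mask, "left")
  counts <- tabulate(parts[parts > 0], 4)
  expect_true(max(counts) - min(counts) <= 40)  # +/- one row/col of parity
  expect_identical(sum(counts), sum(mask))
})

test_that("segments partition the striatal mask exactly", {
  lab <- generate_striosome_mask(small_config(seed = 4L))
  mask <- lab == 1L | lab == 2L
  parts <- partition_segments(mask)
  expect_true(all((parts > 0) == mask))
  expect_true(all(parts[mask] %in% 1:4))
  expect_error(partition_segments(matrix(FALSE, 4, 4)), "empty")
})

test_that("the hemisphere flag swaps medial and lateral segments", {
  mask <- matrix(FALSE, 30, 30)
  mask[6:25, 6:25] <- TRUE
  left <- partition_segments(mask, "left")
  right <- partition_segments(mask, "right")
  # DM (1) <-> DL (2), VM (3) <-> VL (4)
  swap <- c(2L, 1L, 4L, 3L)
  expect_identical(swap[left[mask]], right[mask])
})

make_uniform_fixture <- function() {
  lab <- matrix(0L, 20, 20)
  lab[5:16, 5:16] <- 1L
  lab[6:8, 6:8] <- 2L
  lab[12:13, 12:13] <- 3L  # fiber bundle inside matrix
  img <- matrix(10, 20, 20)
  img[lab == 1L] <- 100
  img[lab == 2L] <- 150
  img[lab == 3L] <- 999
  sec <- section_image(img, img, bit_depth = 16L)
  list(lab = lab, sec = sec,
       parts = partition_segments(lab == 1L | lab == 2L))
}

test_that("densitometry subtracts background and excludes fibers", {
  fx <- make_uniform_fixture()
  rec <- measure_densitometry(fx$sec, fx$lab, fx$parts)
  wh <- rec[rec$segment == "WH", ]
  expect_equal(wh$mean_intensity[wh$compartment == "striosome"], 140)
  expect_equal(wh$mean_intensity[wh$compartment == "matrix"], 90)
  # fiber pixels at 999 do not contaminate the matrix mean
  no_fiber <- fx
  no_fiber$lab[no_fiber$lab == 3L] <- 1L
  img2 <- fx$sec$target
  img2[fx$lab == 3L] <- 100
  rec2 <- measure_densitometry(section_image(img2, img2, bit_depth = 16L),
                               no_fiber$lab, fx$parts)
  expect_equal(rec$mean_intensity[rec$compartment == "matrix" &
                                    rec$segment == "WH"],
               rec2$mean_intensity[rec2$compartment == "matrix" &
                                     rec2$segment == "WH"])
})

test_that("WH equals the pixel-weighted mean of the four segments", {
  cfg <- small_config(noise_sd = 8)
  lab <- generate_striosome_mask(cfg)
  sec <- render_section(lab, default_effect_table(), "Drd2", "Q175KI", 6L,
                        cfg)
  parts <- partition_segments(lab == 1L | lab == 2L)
  rec <- measure_densitometry(sec, lab, parts)
  for (cp in c("striosome", "matrix")) {
    segs <- rec[rec$segment != "WH" & rec$compartment == cp, ]
    wh <- rec[rec$segment == "WH" & rec$compartment == cp, ]
    expect_equal(wh$mean_intensity,
                 sum(segs$mean_intensity * segs$n_pixels) /
                   sum(segs$n_pixels))
    expect_identical(wh$n_pixels, sum(segs$n_pixels))
  }
})

test_that("records are invariant to a constant background shift", {
  fx <- make_uniform_fixture()
  rec <- measure_densitometry(fx$sec, fx$lab, fx$parts)
  shifted <- section_image(fx$sec$reference + 25, fx$sec$target + 25,
                           bit_depth = 16L)
  rec2 <- measure_densitometry(shifted, fx$lab, fx$parts)
  expect_equal(rec$mean_intensity, rec2$mean_intensity)
})

test_that("empty compartments are flagged qc_excluded, not dropped", {
  lab <- matrix(0L, 10, 10)
  lab[3:8, 3:8] <- 1L   # matrix only, no striosome anywhere
  img <- matrix(10, 10, 10); img[lab == 1L] <- 80
  sec <- section_image(img, img)
  rec <- measure_densitometry(sec, lab, partition_segments(lab == 1L))
  strio <- rec[rec$compartment == "striosome", ]
  expect_true(all(strio$qc_excluded))
  expect_true(all(is.na(strio$mean_intensity)))
  expect_identical(nrow(rec), 10L)
  expect_error(measure_densitometry(sec, lab,
                                    partition_segments(lab == 1L),
                                    background_region = matrix(FALSE, 10, 10)),
               "background")
})

test_that("RI and ISMP arithmetic follow their defining ratios", {
  rec <- expand.grid(animal = c("a1", "a2"), hemisphere = "left",
                     molecule = "PDE10A", genotype = c("WT", "Q175KI"),
                     age = 3L, segment = "WH",
                     compartment = c("striosome", "matrix"),
                     stringsAsFactors = FALSE)
  rec$qc_excluded <- FALSE
  rec$mean_intensity <- ifelse(rec$genotype == "WT",
                               ifelse(rec$compartment == "striosome", 140, 90),
                               ifelse(rec$compartment == "striosome", 112, 90))
  ri <- compute_RI(rec)
  expect_equal(ri$RI[ri$compartment == "striosome"], 0.8)
  expect_equal(ri$RI[ri$compartment == "matrix"], 1.0)
  ismp <- compute_ISMP(rec)
  expect_equal(ismp$ISMP[ismp$genotype == "WT"], rep(140 / 90, 2))
  summ <- summarize_ISMP(ismp)
  expect_equal(summ$sem[summ$genotype == "WT"], 0)
  # equal compartments give ISMP exactly 1
  rec2 <- rec
  rec2$mean_intensity <- 90
  expect_true(all(compute_ISMP(rec2)$ISMP == 1))
})

test_that("qc-excluded records are dropped from the group ratios", {
  rec <- expand.grid(animal = c("a1", "a2"), hemisphere = "left",
                     molecule = "MOR1", genotype = c("WT", "Q175KI"),
                     age = 3L, segment = "WH",
                     compartment = c("striosome", "matrix"),
                     stringsAsFactors = FALSE)
  rec$mean_intensity <- 100
  rec$qc_excluded <- FALSE
  rec$mean_intensity[rec$animal == "a2" & rec$genotype == "Q175KI"] <- 500
  rec$qc_excluded[rec$animal == "a2" & rec$genotype == "Q175KI"] <- TRUE
  ri <- compute_RI(rec)
  expect_true(all(ri$RI == 1))
  expect_true(all(ri$n_KI == 1))
})
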