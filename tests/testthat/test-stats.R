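test_that("Kruskal-Wallis H matches the hand-ranked formula", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  # oracle: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2, no ties
  rbar <- c(2, 5, 8)
  H_oracle <- 12 / (9 * 10) * sum(3 * (rbar - 5)^2)
  kw <- kruskal_wallis(groups)
  expect_equal(kw$H, H_oracle)
  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2)))$H, 0)
  expect_equal(kruskal_wallis(list(c(3, 3), c(3, 3)))$p, 1)
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(8)
  g <- list(rnorm(6), rnorm(5) + 1, rnorm(7) - 1)
  f <- function(v) exp(3 * v + 2)
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(lapply(g, f))$H)
  mw1 <- mann_whitney_pairwise(g[1:2])
  mw2 <- mann_whitney_pairwise(lapply(g[1:2], f))
  expect_equal(mw1$U, mw2$U)
  expect_equal(mw1$p_raw, mw2$p_raw)
})

test_that("the worked three-vs-three example gives p = 0.1 and r ~ 0.802", {
  mw <- mann_whitney_pairwise(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_raw, 0.1)
  # Z = (0 - 4.5)/sqrt(3*3*7/12); r = |Z|/sqrt(6)
  expect_equal(mw$Z, -4.5 / sqrt(5.25))
  expect_equal(mw$r, 4.5 / sqrt(5.25) / sqrt(6), tolerance = 1e-6)
  expect_equal(round(mw$r, 3), 0.802)
  expect_equal(cohens_r(0, 3, 3), mw$r)
})

test_that("exact Mann-Whitney p equals full permutation enumeration", {
  set.seed(21)
  for (i in 1:200) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    v <- sample(1:50, n1 + n2)      # tie-free
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    mw <- mann_whitney_pairwise(list(x = x, y = y))
    expect_equal(mw$p_raw, enumerate_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("large or tied samples switch to the corrected normal p", {
  set.seed(3)
  x <- rnorm(15); y <- rnorm(15) + 0.5
  mw <- mann_whitney_pairwise(list(x = x, y = y))
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw$p_raw, ref$p.value, tolerance = 1e-10)
  # ties force the approximation even for small n
  xt <- c(1, 2, 2, 3); yt <- c(2, 3, 4, 4)
  mwt <- mann_whitney_pairwise(list(x = xt, y = yt))
  reft <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE,
                                       correct = TRUE))
  expect_equal(mwt$p_raw, reft$p.value, tolerance = 1e-10)
})

test_that("Cohen's r is 0 at the null mean and bins at 0.1/0.3/0.5", {
  expect_equal(cohens_r(12.5, 5, 5), 0)
  expect_identical(as.character(effect_bin(c(0.05, 0.1, 0.29, 0.3, 0.49,
                                             0.5, 0.9))),
                   c("negligible", "small", "small", "medium", "medium",
                     "large", "large"))
})

test_that("tie-corrected variance reduces Z magnitude", {
  r_no_ties <- cohens_r(2, 4, 4)
  r_ties <- cohens_r(2, 4, 4, tie_structure = c(3, 2))
  expect_gt(r_ties, r_no_ties)  # smaller variance -> larger |Z| for same U
})

test_that("Bonferroni thresholds reproduce the figure conventions", {
  g <- list(a = 1:5, b = 6:10)
  expect_equal(unique(mann_whitney_pairwise(g, family_size = 10)$alpha_adjusted),
               0.005)
  expect_equal(unique(mann_whitney_pairwise(g, family_size = 3)$alpha_adjusted),
               0.05 / 3, tolerance = 1e-12)
  expect_error(mann_whitney_pairwise(list(a = 1:3, b = 4:6, c = 7:9),
                                     family_size = 2), "family_size")
})

test_that("shifting one group away from the other never decreases |Z|", {
  set.seed(14)
  for (i in 1:25) {
    x <- rnorm(6); y <- rnorm(7)
    z0 <- abs(mann_whitney_pairwise(list(x = x, y = y + 0.5))$Z)
    z1 <- abs(mann_whitney_pairwise(list(x = x, y = y + 1.5))$Z)
    expect_gte(z1 + 1e-12, z0)
  }
})

test_that("degenerate one-vs-one comparisons are flagged with p = 1", {
  mw <- mann_whitney_pairwise(list(a = 1, b = 2))
  expect_equal(mw$p_raw, 1)
  expect_true(mw$degenerate)
  expect_false(mw$significant)
})

test_that("significance flags mirror p < alpha_adjusted exactly", {
  set.seed(33)
  g <- list(a = rnorm(8), b = rnorm(8) + 3, c = rnorm(8))
  mw <- mann_whitney_pairwise(g, family_size = 10)
  expect_identical(mw$significant, mw$p_raw < mw$alpha_adjusted)
})

test_that("heatmap tables are complete with explicit NA and markers", {
  ri <- expand.grid(molecule = striatal_molecules(),
                    age = c(3L, 6L, 12L),
                    segment = c("WH", segment_names()),
                    stringsAsFactors = FALSE)
  ri$compartment <- "striosome"
  ri$RI <- ifelse(ri$molecule == "MOR1", 1.2, 0.8)
  st <- ri
  st$r <- 0.6
  st$significant <- st$molecule == "MOR1"
  st$p_raw <- ifelse(st$significant, 0.001, 0.5)
  ismp <- data.frame(molecule = "MOR1", genotype = "WT", age = 3L,
                     segment = "WH", mean = 1.3, sem = 0.05, n = 16)
  # drop one cell (a PDE10A one): it must surface as NA, never silently
  tabs <- heatmap_tables(ri[ri$molecule != "PDE10A" | ri$age != 3 |
                              ri$segment != "WH", ], ismp, st)
  expect_identical(dim(tabs$RI), c(6L, 15L))
  expect_identical(sum(is.na(tabs$RI)), 1L)
  expect_true(all(grepl("\\*", tabs$marked["MOR1", ])))
  expect_false(any(grepl("\\*", tabs$marked["PDE10A", ])))
  out <- file.path(tempdir(), "report-test")
  tabs2 <- heatmap_tables(ri, ismp, st, out_dir = out)
  expect_true(file.exists(file.path(out, "heatmap_RI.csv")))
  expect_true(file.exists(file.path(out, "ismp_summary.csv")))
  unlink(out, recursive = TRUE)
})

test_that("type-I error at the 0.005 threshold stays at the nominal rate", {
  # null model: 16 exchangeable caudoputamen samples per group drawn from
  # the generator's log-normal intensity distribution, no genotype effect
  set.seed(99)
  n_sim <- 2000
  hits <- 0
  for (i in 1:n_sim) {
    wt <- 100 * rlnorm(16, 0, 0.06)
    ki <- 100 * rlnorm(16, 0, 0.06)
    p <- mann_whitney_pairwise(list(wt = wt, ki = ki),
                               family_size = 10)$p_raw
    if (p < 0.005) hits <- hits + 1
  }
  expect_lte(hits / n_sim, 0.01)
})
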