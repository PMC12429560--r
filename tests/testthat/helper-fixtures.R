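# Shared small fixtures, built in code. Expensive objects are memoised for
# the session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# small synthesis config for fast tests
small_config <- function(seed = 1L, ...) {
  args <- list(image_height_px = 128L, image_width_px = 128L,
               striosome_scale_px = 10, n_fiber_bundles = 2L, n_vessels = 1L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthesis_config, args)
}

# a separable low-noise cohort of 96 x 96 sections (divisible by 4, so a
# depth-3 net applies) and a small trained model reused across test files
separable_cohort <- function() memo("separable_cohort", {
  cfg <- synthesis_config(image_height_px = 96L, image_width_px = 96L,
                          striosome_scale_px = 10, noise_sd = 4,
                          n_fiber_bundles = 1L, n_vessels = 1L, seed = 5L)
  generate_cohort(default_effect_table(), n_mice_per_group = 2L, cfg,
                  molecules = "MOR1")
})

small_model <- function() memo("small_model", {
  train_striosome_unet(
    separable_cohort(),
    unet_spec(depth = 3L, base_channels = 8L),
    train_config(batch_size = 8L, total_epochs = 15L, tile_size = 48L,
                 learning_rate = 2e-3, train_fraction = 0.85, seed = 5L))
})

# independent Mann-Whitney oracle: full enumeration of all C(n1+n2, n1)
# group assignments; two-sided p = fraction of assignments whose U is at
# least as extreme (as far from the null mean) as observed
enumerate_mw_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- abs(u_of(seq_len(n1)) - n1 * (n - n1) / 2)
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - n1 * (n - n1) / 2) >= obs - 1e-9)
}
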