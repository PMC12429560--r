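#' Synthesis configuration for synthetic striatal sections
#'
#' Defines the geometry and noise model of the synthetic two-channel
#' sections. Striosomes occupy a configurable minority fraction of the
#' striatal area and are drawn as labyrinthine blobs from thresholded
#' band-pass-filtered noise; fiber bundles (elliptical patches) and vessels
#' (thin tubes) are carved out of the matrix. Identical configurations
#' (including the seed) yield bit-identical outputs.
#'
#' @param image_height_px,image_width_px Image size in pixels.
#' @param striosome_area_fraction Fraction of striatal pixels occupied by
#'   striosomes, strictly inside (0, 0.5); striosomes are the minority
#'   compartment embedded in the larger matrix.
#' @param striosome_scale_px Characteristic striosome blob scale in pixels.
#' @param n_fiber_bundles,n_vessels Number of excluded structures.
#' @param noise_sd Additive Gaussian noise standard deviation (gray levels).
#' @param background_level Gray level of the slide glass outside the tissue.
#' @param fiber_level,vessel_level Gray levels of excluded structures
#'   (distinct low values).
#' @param bit_depth Bit depth of rendered channels (8 or 16).
#' @param animal_cv Between-animal coefficient of variation of the
#'   multiplicative intensity offset (log-normal, mean 1) used by
#'   [generate_cohort()].
#' @param seed Integer seed controlling all randomness.
#' @return A validated `synthesis_config` object.
#' @export
synthesis_config <- function(image_height_px = 768L, image_width_px = 1024L,
                             striosome_area_fraction = 0.10,
                             striosome_scale_px = 24,
                             n_fiber_bundles = 6L, n_vessels = 4L,
                             noise_sd = 15, background_level = 10,
                             fiber_level = 45, vessel_level = 35,
                             bit_depth = 8L, animal_cv = 0.06, seed = 1L) {
  if (image_height_px <= 0 || image_width_px <= 0)
    stop("image dimensions must be positive")
  if (striosome_area_fraction <= 0 || striosome_area_fraction >= 0.5)
    stop("striosome_area_fraction must lie strictly inside (0, 0.5)")
  if (striosome_scale_px <= 0) stop("striosome_scale_px must be > 0")
  if (n_fiber_bundles < 0 || n_vessels < 0)
    stop("structure counts must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    striosome_area_fraction = striosome_area_fraction,
    striosome_scale_px = striosome_scale_px,
    n_fiber_bundles = as.integer(n_fiber_bundles),
    n_vessels = as.integer(n_vessels),
    noise_sd = noise_sd, background_level = background_level,
    fiber_level = fiber_level, vessel_level = vessel_level,
    bit_depth = as.integer(bit_depth), animal_cv = animal_cv,
    seed = as.integer(seed)), class = "synthesis_config")
}

#' Molecules quantified per compartment
#' @return Character vector of the six molecules, MOR1 first.
#' @export
striatal_molecules <- function() {
  c("MOR1", "PDE10A", "Gaolf", "Drd2", "A2A", "Drd1")
}

#' Default effect table for synthetic cohorts
#'
#' Mean gray levels per (molecule, genotype, age, segment, compartment).
#' The wildtype baseline gives every molecule a striosome/matrix contrast
#' (MOR1 strongly striosome-enriched, PDE10A mildly so). The Q175KI rows
#' scale the wildtype means by per-age ratios whose directions follow the
#' disease pattern: MOR1 is upregulated in Q175KI striosomes (ratio >= 1,
#' growing with age) while PDE10A, Gaolf, Drd2, A2A and Drd1 are
#' downregulated (ratios <= 1, shrinking with age); matrix changes are
#' milder than striosomal ones, so the striosome-to-matrix balance of the
#' downregulated molecules declines. Magnitudes are configuration, not
#' ground truth from tissue; only the directions are constrained.
#'
#' @return Data frame with columns molecule, genotype, age, segment,
#'   compartment, mean_intensity.
#' @export
default_effect_table <- function() {
  base <- data.frame(
    molecule = striatal_molecules(),
    striosome = c(150, 140, 138, 128, 125, 132),
    matrix = c(110, 127, 115, 112, 108, 116))
  ki_strio <- rbind(
    MOR1 = c(1.08, 1.16, 1.22), PDE10A = c(0.85, 0.75, 0.65),
    Gaolf = c(0.80, 0.72, 0.66), Drd2 = c(0.86, 0.78, 0.70),
    A2A = c(0.84, 0.76, 0.70), Drd1 = c(0.92, 0.87, 0.80))
  ki_matrix <- rbind(
    MOR1 = c(1.00, 1.02, 1.05), PDE10A = c(0.97, 0.94, 0.90),
    Gaolf = c(0.96, 0.93, 0.90), Drd2 = c(0.97, 0.94, 0.91),
    A2A = c(0.96, 0.93, 0.90), Drd1 = c(0.99, 0.97, 0.93))
  ages <- c(3L, 6L, 12L)
  grid <- expand.grid(molecule = striatal_molecules(),
                      genotype = c("WT", "Q175KI"), age = ages,
                      segment = c("DM", "DL", "VM", "VL"),
                      compartment = c("striosome", "matrix"),
                      stringsAsFactors = FALSE)
  mean_intensity <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- grid$molecule[i]
    wt <- base[base$molecule == m, grid$compartment[i]]
    ratio <- 1
    if (grid$genotype[i] == "Q175KI") {
      tab <- if (grid$compartment[i] == "striosome") ki_strio else ki_matrix
      ratio <- tab[m, match(grid$age[i], ages)]
    }
    mean_intensity[i] <- wt * ratio
  }
  grid$mean_intensity <- mean_intensity
  validate_effect_table(grid)
  grid
}

# internal: structural checks on an effect table
validate_effect_table <- function(effects, background_level = 0) {
  need <- c("molecule", "genotype", "age", "segment", "compartment",
            "mean_intensity")
  if (!all(need %in% names(effects)))
    stop("effect table must have columns: ", paste(need, collapse = ", "))
  if (any(effects$mean_intensity <= background_level))
    stop("all effect-table mean intensities must exceed the background level")
  invisible(effects)
}

# internal: look up one mean intensity; explicit error when absent
effect_mean <- function(effects, molecule, genotype, age, segment,
                        compartment) {
  i <- which(effects$molecule == molecule & effects$genotype == genotype &
             effects$age == age & effects$segment == segment &
             effects$compartment == compartment)
  if (length(i) != 1)
    stop(sprintf("missing effect-table condition: %s/%s/%smo/%s/%s",
                 molecule, genotype, age, segment, compartment))
  effects$mean_intensity[i]
}

#' Generate a striosome/matrix ground-truth label map
#'
#' Draws a convex-ish striatal territory inside the frame, then carves
#' labyrinthine striosomes by thresholding band-pass-filtered seeded noise
#' at the quantile matching `striosome_area_fraction`, and finally carves
#' fiber bundles (ellipses) and vessels (thin tubes) out of the matrix.
#'
#' @param config A [synthesis_config()].
#' @return A [label_map()] with the coding of [label_levels()].
#' @export
generate_striosome_mask <- function(config) {
  stopifnot(inherits(config, "synthesis_config"))
  H <- config$image_height_px; W <- config$image_width_px
  with_seed(config$seed, {
    lab <- matrix(0L, H, W)

    # striatal territory: ellipse with low-frequency radial perturbation
    cy <- H / 2; cx <- W / 2
    ry <- 0.42 * H; rx <- 0.44 * W
    ph <- runif(2, 0, 2 * pi)
    row <- matrix(seq_len(H), H, W)
    col <- matrix(seq_len(W), H, W, byrow = TRUE)
    theta <- atan2((row - cy) / ry, (col - cx) / rx)
    rad <- sqrt(((row - cy) / ry)^2 + ((col - cx) / rx)^2)
    bound <- 1 + 0.08 * sin(2 * theta + ph[1]) + 0.05 * sin(3 * theta + ph[2])
    striatum <- rad <= bound
    lab[striatum] <- 1L

    # striosomes: difference-of-Gaussians band-pass of white noise
    s <- config$striosome_scale_px
    z <- matrix(rnorm(H * W), H, W)
    band <- EBImage::gblur(z, sigma = s / 3) - EBImage::gblur(z, sigma = s)
    thr <- quantile(band[striatum], 1 - config$striosome_area_fraction)
    lab[striatum & band > thr] <- 2L

    # fiber bundles: elliptical patches carved out of the matrix
    if (config$n_fiber_bundles > 0) {
      idx <- which(lab == 1L)
      for (k in seq_len(config$n_fiber_bundles)) {
        ctr <- idx[ceiling(runif(1) * length(idx))]
        r0 <- (ctr - 1) %% H + 1; c0 <- (ctr - 1) %/% H + 1
        a <- s * runif(1, 0.5, 0.9); b <- s * runif(1, 0.2, 0.4)
        ang <- runif(1, 0, pi)
        dr <- row - r0; dc <- col - c0
        u <- dc * cos(ang) + dr * sin(ang)
        v <- -dc * sin(ang) + dr * cos(ang)
        ell <- (u / a)^2 + (v / b)^2 <= 1
        lab[ell & lab == 1L] <- 3L
      }
    }

    # vessels: thin tubes (anti-diagonal distance bands) carved out of matrix
    if (config$n_vessels > 0) {
      idx <- which(lab == 1L)
      for (k in seq_len(config$n_vessels)) {
        ctr <- idx[ceiling(runif(1) * length(idx))]
        r0 <- (ctr - 1) %% H + 1; c0 <- (ctr - 1) %/% H + 1
        ang <- runif(1, 0, pi)
        len <- runif(1, 0.15, 0.35) * min(H, W)
        wdt <- runif(1, 1, 2)
        dr <- row - r0; dc <- col - c0
        along <- dc * cos(ang) + dr * sin(ang)
        across <- abs(-dc * sin(ang) + dr * cos(ang))
        tube <- abs(along) <= len / 2 & across <= wdt
        lab[tube & lab == 1L] <- 4L
      }
    }
    label_map(lab)
  })
}

#' Render a two-channel section from a label map and effect table
#'
#' Every pixel's expected gray level is the effect-table mean for its
#' (segment, compartment); background pixels take `background_level`, fiber
#' and vessel pixels a distinct low level. Independent Gaussian noise with
#' `noise_sd` is added and values are clipped to the bit-depth range. The
#' reference channel is always rendered from the MOR1 rows of the table so
#' it demarcates the compartments; the target channel uses `molecule`.
#'
#' @param labels A [label_map()].
#' @param effects Effect table, see [default_effect_table()].
#' @param molecule,genotype,age Condition of the rendered section.
#' @param config A [synthesis_config()].
#' @param hemisphere `"left"` or `"right"` (controls which image side is
#'   medial when assigning segments).
#' @param animal_scale Multiplicative between-animal intensity offset
#'   applied to tissue means (not to the background).
#' @param seed Seed for the rendering noise. The default derives a stream
#'   distinct from the mask-generation stream of `config$seed`, so the
#'   noise field is independent of the striosome geometry.
#' @return A [section_image()].
#' @export
render_section <- function(labels, effects, molecule, genotype, age, config,
                           hemisphere = "left", animal_scale = 1,
                           seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthesis_config"))
  validate_effect_table(effects, config$background_level)
  parts <- partition_segments(striatal_mask(labels), hemisphere = hemisphere)
  gmax <- 2^config$bit_depth - 1

  render_channel <- function(mol) {
    img <- matrix(config$background_level, nrow(labels), ncol(labels))
    img[labels == 3L] <- config$fiber_level
    img[labels == 4L] <- config$vessel_level
    for (seg in segment_names()) {
      for (cp in c("matrix", "striosome")) {
        code <- if (cp == "matrix") 1L else 2L
        sel <- labels == code & parts == match(seg, segment_names())
        if (any(sel))
          img[sel] <- effect_mean(effects, mol, genotype, age, seg, cp) *
            animal_scale
      }
    }
    img
  }
  ref <- render_channel("MOR1")
  tgt <- if (molecule == "MOR1") ref else render_channel(molecule)

  with_seed(seed, {
    if (config$noise_sd > 0) {
      n <- length(ref)
      ref <- ref + rnorm(n, sd = config$noise_sd)
      tgt <- tgt + rnorm(n, sd = config$noise_sd)
    }
    ref <- pmin(pmax(ref, 0), gmax)
    tgt <- pmin(pmax(tgt, 0), gmax)
    section_image(ref, tgt, channel_names = c("MOR1", molecule),
                  bit_depth = config$bit_depth)
  })
}

# internal: stable per-section seed derivation. The counter encodes the
# condition coordinates, so extending a cohort (more mice, more molecules)
# never reshuffles existing sections.
section_seed <- function(base_seed, molecule, genotype, age, mouse,
                         hemisphere) {
  mol <- match(molecule, striatal_molecules())
  gen <- match(genotype, c("WT", "Q175KI"))
  agi <- match(age, c(3L, 6L, 12L))
  hem <- match(hemisphere, c("none", "left", "right"))
  k <- ((((mol * 4 + gen) * 8 + agi) * 256 + mouse) * 4 + hem)
  as.integer((base_seed + 7919 * k) %% 2147483647)
}

#' Generate a synthetic cohort of sections
#'
#' Emulates the study design: for each molecule, 2 genotypes x 3 ages x
#' `n_mice_per_group` mice x 2 hemispheres, yielding
#' `12 * n_mice_per_group` sections per molecule. Each animal carries a
#' multiplicative intensity offset drawn from a log-normal distribution
#' with coefficient of variation `config$animal_cv` (mean 1), so group
#' comparisons are statistically nontrivial. Every section has its own
#' derived seed; the full cohort is reproducible from `config$seed`.
#'
#' @param effects Effect table, see [default_effect_table()].
#' @param n_mice_per_group Mice per (genotype, age) group, >= 1.
#' @param config A [synthesis_config()].
#' @param molecules Molecules to render (default all six).
#' @return A list of records, each `list(section, labels, meta)`; the
#'   combined metadata is attached as attribute `"meta"` (one row per
#'   section: animal, hemisphere, molecule, genotype, age, seed).
#' @export
generate_cohort <- function(effects, n_mice_per_group, config,
                            molecules = striatal_molecules()) {
  stopifnot(inherits(config, "synthesis_config"))
  if (n_mice_per_group < 1) stop("n_mice_per_group must be >= 1")
  sdlog <- sqrt(log(1 + config$animal_cv^2))
  records <- list()
  meta <- list()
  for (mol in molecules) {
    for (gen in c("WT", "Q175KI")) {
      for (age in c(3L, 6L, 12L)) {
        for (mouse in seq_len(n_mice_per_group)) {
          animal <- sprintf("%s_%02dmo_m%02d", gen, age, mouse)
          ascale <- if (config$animal_cv > 0) {
            aseed <- section_seed(config$seed, mol, gen, age, mouse, "none")
            with_seed(aseed, rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog))
          } else 1
          for (hemi in c("left", "right")) {
            sseed <- section_seed(config$seed, mol, gen, age, mouse, hemi)
            scfg <- config
            scfg$seed <- sseed
            labels <- generate_striosome_mask(scfg)
            section <- render_section(labels, effects, mol, gen, age, scfg,
                                      hemisphere = hemi,
                                      animal_scale = ascale, seed = sseed + 1L)
            row <- data.frame(animal = animal, hemisphere = hemi,
                              molecule = mol, genotype = gen, age = age,
                              seed = sseed, stringsAsFactors = FALSE)
            records[[length(records) + 1]] <-
              list(section = section, labels = labels, meta = row)
            meta[[length(meta) + 1]] <- row
          }
        }
      }
    }
  }
  structure(records, meta = do.call(rbind, meta), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("synthetic cohort: %d sections, %d molecule(s), %d animals\n",
              length(x), length(unique(m$molecule)),
              length(unique(paste(m$animal, m$molecule)))))
  invisible(x)
}

#' Expected RI and ISMP implied by an effect table
#'
#' Computes the background-referenced indices that a noiseless cohort must
#' recover exactly: intensities are referenced to `background_level` (the
#' densitometry subtracts the slide-glass background), then
#' `RI = (Q175KI - bg)/(WT - bg)` per (molecule, age, segment, compartment)
#' and `ISMP = (striosome - bg)/(matrix - bg)` per (molecule, genotype,
#' age, segment).
#'
#' @param effects Effect table.
#' @param background_level Background gray level subtracted by densitometry.
#' @return List with data frames `RI` and `ISMP`.
#' @export
expected_indices <- function(effects, background_level = 0) {
  e <- effects
  e$net <- e$mean_intensity - background_level
  key <- c("molecule", "age", "segment")
  wt <- e[e$genotype == "WT", ]
  ki <- e[e$genotype == "Q175KI", ]
  m <- merge(ki, wt, by = c(key, "compartment"), suffixes = c("_ki", "_wt"))
  ri <- data.frame(m[c(key, "compartment")], RI = m$net_ki / m$net_wt)
  st <- e[e$compartment == "striosome", ]
  mx <- e[e$compartment == "matrix", ]
  m2 <- merge(st, mx, by = c(key, "genotype"), suffixes = c("_s", "_m"))
  ismp <- data.frame(m2[c(key, "genotype")], ISMP = m2$net_s / m2$net_m)
  list(RI = ri[order(ri$molecule, ri$age, ri$segment, ri$compartment), ],
       ISMP = ismp[order(ismp$molecule, ismp$age, ismp$segment,
                         ismp$genotype), ])
}
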