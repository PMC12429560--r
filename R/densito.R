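#' Caudoputamen segment names
#' @return `c("DM", "DL", "VM", "VL")` (dorsomedial, dorsolateral,
#'   ventromedial, ventrolateral); `"WH"` denotes their union.
#' @export
segment_names <- function() c("DM", "DL", "VM", "VL")

#' Partition the striatal region into DM/DL/VM/VL quadrants
#'
#' Deterministic surrogate for the manual segment outlines: the striatal
#' mask is split at its centroid, dorsal/ventral by row (dorsal = top of
#' the image) and medial/lateral by column. For a left hemisphere the
#' medial side is the right of the image; for a right hemisphere the left.
#' Every striatal pixel is assigned to exactly one segment; WH is their
#' union.
#'
#' @param mask Logical matrix marking striatal pixels (striosome + matrix).
#' @param hemisphere `"left"` or `"right"`.
#' @return A `segment_partition`: integer matrix, 0 outside the striatum,
#'   otherwise the index of the segment in [segment_names()].
#' @export
partition_segments <- function(mask, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (!any(mask)) stop("empty striatal mask")
  idx <- which(mask)
  H <- nrow(mask)
  r <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  cy <- mean(r); cx <- mean(cc)
  dorsal <- r <= cy
  medial <- if (hemisphere == "left") cc > cx else cc <= cx
  seg <- ifelse(dorsal, ifelse(medial, 1L, 2L), ifelse(medial, 3L, 4L))
  out <- matrix(0L, H, ncol(mask))
  out[idx] <- seg
  structure(out, class = c("segment_partition", "matrix"))
}

#' Compartmental densitometry of one section
#'
#' Measures the mean optical intensity of the target channel in each
#' (segment, compartment) cell, excluding fiber-bundle and vessel pixels,
#' and referenced to the background measured on the slide glass outside
#' the tissue (the background mean is subtracted). Records are produced
#' for WH and the four quadrant segments; an empty compartment-within-
#' segment (or one below `min_pixels`) is flagged `qc_excluded`, mirroring
#' the exclusion of poorly stained segments.
#'
#' @param section A [section_image()].
#' @param compartments A [label_map()] defining striosome/matrix pixels
#'   (ground truth, or a predicted map from [predict_striosomes()]).
#' @param parts A [partition_segments()] result aligned with the section.
#' @param exclusions Optional logical matrix of pixels to exclude (defaults
#'   to fiber/vessel labels found in `compartments`).
#' @param background_region Optional logical matrix of background pixels
#'   (defaults to `compartments == background`); must be non-empty.
#' @param meta Optional one-row data frame of identifying columns
#'   (animal, hemisphere, molecule, genotype, age) bound to each record.
#' @param min_pixels Minimum pixel count for a valid record.
#' @return Data frame of densitometry records: segment, compartment,
#'   mean_intensity (background-referenced), n_pixels, qc_excluded.
#' @export
measure_densitometry <- function(section, compartments, parts,
                                 exclusions = NULL, background_region = NULL,
                                 meta = NULL, min_pixels = 1L) {
  img <- section$target
  if (!all(dim(img) == dim(compartments)) || !all(dim(img) == dim(parts)))
    stop("section, compartment map and segment partition must be aligned")
  if (is.null(exclusions))
    exclusions <- compartments == 3L | compartments == 4L
  if (is.null(background_region)) background_region <- compartments == 0L
  if (!any(background_region)) stop("background region is empty")
  bg <- mean(img[background_region])

  rows <- list()
  for (seg in c("WH", segment_names())) {
    seg_px <- if (seg == "WH") parts > 0L else parts == match(seg, segment_names())
    for (cp in c("striosome", "matrix")) {
      code <- if (cp == "striosome") 2L else 1L
      sel <- seg_px & compartments == code & !exclusions
      n <- sum(sel)
      rows[[length(rows) + 1]] <- data.frame(
        segment = seg, compartment = cp,
        mean_intensity = if (n >= min_pixels) mean(img[sel]) - bg else NA_real_,
        n_pixels = n, qc_excluded = n < min_pixels,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(meta)) out <- cbind(meta[rep(1L, nrow(out)), , drop = FALSE],
                                   out, row.names = NULL)
  out
}

#' Densitometry over a whole cohort
#'
#' Applies [measure_densitometry()] to every section of a synthetic
#' cohort, using either the ground-truth label map or predicted striosome
#' masks for the compartments. Fiber/vessel exclusion and the background
#' region always come from the ground-truth labels (in tissue work these
#' are annotated structures, not model outputs).
#'
#' @param cohort A [generate_cohort()] result.
#' @param model Optional trained model from [train_striosome_unet()]; when
#'   supplied, compartments are its predictions restricted to the striatal
#'   region, otherwise ground truth is used.
#' @return Data frame of densitometry records for the cohort.
#' @export
measure_cohort <- function(cohort, model = NULL) {
  out <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    labels <- rec$labels
    comp <- labels
    if (!is.null(model)) {
      pred <- predict_striosomes(model, rec$section,
                                 tissue = striatal_mask(labels))
      comp <- labels
      comp[striatal_mask(labels)] <- pred$labels[striatal_mask(labels)]
    }
    parts <- partition_segments(striatal_mask(labels),
                                hemisphere = rec$meta$hemisphere)
    out[[i]] <- measure_densitometry(rec$section, comp, parts,
                                     exclusions = labels == 3L | labels == 4L,
                                     background_region = labels == 0L,
                                     meta = rec$meta)
  }
  do.call(rbind, out)
}

#' Relative intensity (RI) of Q175KI to wildtype
#'
#' `RI = (mean optical intensity of Q175KI mice) / (mean optical intensity
#' of WT mice)` per (molecule, age, segment, compartment): the ratio of
#' group means over animals and hemispheres, with qc-excluded records
#' dropped.
#'
#' @param records Densitometry records from [measure_cohort()] (both
#'   genotypes present).
#' @return Data frame with columns molecule, age, segment, compartment, RI,
#'   n_KI, n_WT.
#' @export
compute_RI <- function(records) {
  r <- records[!records$qc_excluded, ]
  agg <- stats::aggregate(mean_intensity ~ molecule + age + segment +
                            compartment + genotype, data = r, FUN = mean)
  cnt <- stats::aggregate(mean_intensity ~ molecule + age + segment +
                            compartment + genotype, data = r, FUN = length)
  key <- c("molecule", "age", "segment", "compartment")
  wt <- merge(agg[agg$genotype == "WT", c(key, "mean_intensity")],
              cnt[cnt$genotype == "WT", c(key, "mean_intensity")], by = key,
              suffixes = c("", "_n"))
  ki <- merge(agg[agg$genotype == "Q175KI", c(key, "mean_intensity")],
              cnt[cnt$genotype == "Q175KI", c(key, "mean_intensity")],
              by = key, suffixes = c("", "_n"))
  m <- merge(ki, wt, by = key, suffixes = c("_ki", "_wt"))
  if (any(m$mean_intensity_wt <= 0))
    stop("WT group mean <= 0; RI undefined")
  data.frame(m[key], RI = m$mean_intensity_ki / m$mean_intensity_wt,
             n_KI = m$mean_intensity_n_ki, n_WT = m$mean_intensity_n_wt)
}

#' Index of striosome-to-matrix predominance (ISMP)
#'
#' `ISMP = (optical intensity in striosomes) / (optical intensity in
#' matrix)`, computed per sample (animal x hemisphere x segment); ISMP is
#' 1 when the compartments have equal mean intensity. Records whose matrix
#' intensity is non-positive are dropped with a warning.
#'
#' @param records Densitometry records.
#' @return Data frame of per-sample ISMP values.
#' @export
compute_ISMP <- function(records) {
  r <- records[!records$qc_excluded, ]
  key <- c("animal", "hemisphere", "molecule", "genotype", "age", "segment")
  key <- intersect(key, names(r))
  st <- r[r$compartment == "striosome", c(key, "mean_intensity")]
  mx <- r[r$compartment == "matrix", c(key, "mean_intensity")]
  m <- merge(st, mx, by = key, suffixes = c("_s", "_m"))
  bad <- m$mean_intensity_m <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) dropped: matrix intensity <= 0")
    m <- m[!bad, ]
  }
  data.frame(m[key], ISMP = m$mean_intensity_s / m$mean_intensity_m)
}

#' Group summaries of per-sample ISMP values
#'
#' @param ismp Output of [compute_ISMP()].
#' @return Data frame of mean, SEM and n per (molecule, genotype, age,
#'   segment) group.
#' @export
summarize_ISMP <- function(ismp) {
  key <- intersect(c("molecule", "genotype", "age", "segment"), names(ismp))
  f <- stats::as.formula(paste("ISMP ~", paste(key, collapse = " + ")))
  mean_df <- stats::aggregate(f, data = ismp, FUN = mean)
  sem_df <- stats::aggregate(f, data = ismp,
                             FUN = function(v) sd(v) / sqrt(length(v)))
  n_df <- stats::aggregate(f, data = ismp, FUN = length)
  out <- merge(merge(mean_df, sem_df, by = key, suffixes = c("_mean", "_sem")),
               n_df, by = key)
  names(out)[names(out) == "ISMP"] <- "n"
  names(out)[names(out) == "ISMP_mean"] <- "mean"
  names(out)[names(out) == "ISMP_sem"] <- "sem"
  out
}
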