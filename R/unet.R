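#' Residual U-Net architecture specification
#'
#' A fully convolutional encoder-decoder with residual blocks at every
#' resolution level, nearest-neighbour upsampling and skip concatenation.
#' The default (depth 4, base 16) is the smallest configuration exercising
#' the full tiled training protocol at desk scale.
#'
#' @param depth Number of resolution levels (>= 2).
#' @param base_channels Channels at the first level (>= 4); doubled at
#'   each deeper level.
#' @param residual_blocks Use residual (identity/projection) skips inside
#'   each two-convolution block.
#' @param n_classes Output classes (2: striosome vs. rest).
#' @return A `unet_spec` object.
#' @export
unet_spec <- function(depth = 4L, base_channels = 16L,
                      residual_blocks = TRUE, n_classes = 2L) {
  if (depth < 2) stop("depth must be >= 2")
  if (base_channels < 4) stop("base_channels must be >= 4")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 residual_blocks = isTRUE(residual_blocks),
                 n_classes = as.integer(n_classes)),
            class = "unet_spec")
}

#' Training configuration for the striosome U-Net
#'
#' @param batch_size Tiles per optimizer step.
#' @param total_epochs Epochs to run; the returned model is the checkpoint
#'   with minimum held-out cross-entropy, not the final epoch.
#' @param augmentation_arm `"vflip_only"` (vertical flip with probability
#'   1/2) or `"vflip_plus_photometric"` (additionally brightness jitter on
#'   the image tile only; hue/saturation apply to RGB tiles and are
#'   identity on single-channel sections).
#' @param train_fraction Fraction of sections assigned to the training
#'   split; the remainder is held out for the test curve and evaluation.
#' @param learning_rate Adam learning rate.
#' @param tile_size Training tile side; must be divisible by
#'   `2^(depth-1)`.
#' @param tiles_per_epoch Number of training tiles sampled (without
#'   replacement) per epoch; `NULL` uses every tile each epoch.
#' @param eval_tiles Number of held-out tiles used for the per-epoch test
#'   curve; `NULL` uses all held-out tiles.
#' @param brightness_jitter Relative brightness half-range for the
#'   photometric arm.
#' @param seed Seed for the split, shuffling and augmentation draws.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 32L, total_epochs = 160L,
                         augmentation_arm = c("vflip_only",
                                              "vflip_plus_photometric"),
                         train_fraction = 0.85, learning_rate = 1e-3,
                         tile_size = 512L, tiles_per_epoch = NULL,
                         eval_tiles = NULL, brightness_jitter = 0.2,
                         seed = 1L) {
  augmentation_arm <- match.arg(augmentation_arm)
  if (batch_size < 1 || total_epochs < 1) stop("batch/epoch counts must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly inside (0, 1)")
  structure(list(batch_size = as.integer(batch_size),
                 total_epochs = as.integer(total_epochs),
                 augmentation_arm = augmentation_arm,
                 train_fraction = train_fraction,
                 learning_rate = learning_rate,
                 tile_size = as.integer(tile_size),
                 tiles_per_epoch = if (is.null(tiles_per_epoch)) NULL
                                   else as.integer(tiles_per_epoch),
                 eval_tiles = if (is.null(eval_tiles)) NULL
                              else as.integer(eval_tiles),
                 brightness_jitter = brightness_jitter,
                 seed = as.integer(seed)), class = "train_config")
}

# internal: He-initialized weights in canonical layer order
unet_init <- function(spec, seed = 1L) {
  shapes <- unet_shapes_cpp(unclass(spec))
  with_seed(seed, {
    W <- vector("list", length(shapes))
    b <- vector("list", length(shapes))
    for (i in seq_along(shapes)) {
      s <- shapes[[i]]
      rows <- s[["k"]]^2 * s[["cin"]]
      W[[i]] <- matrix(rnorm(rows * s[["cout"]], sd = sqrt(2 / rows)),
                       rows, s[["cout"]])
      b[[i]] <- rep(0, s[["cout"]])
    }
    list(W = W, b = b)
  })
}

#' Select the checkpoint epoch from a training curve
#'
#' The selected epoch is the argmin of the recorded held-out
#' cross-entropy loss (the first epoch attaining the minimum on ties);
#' model state is restored from that epoch, not the final one.
#'
#' @param curve Data frame with a `test_loss` column (one row per epoch).
#' @return Integer epoch index (1-based).
#' @export
select_checkpoint <- function(curve) {
  if (!"test_loss" %in% names(curve) || nrow(curve) < 1)
    stop("curve must contain per-epoch test_loss")
  which.min(curve$test_loss)
}

#' Train the striosome U-Net on a synthetic cohort
#'
#' Implements the tiled training protocol: sections are split into train
#' and held-out sets at `train_fraction` (the split is by section, so no
#' tile of a held-out section is seen in training), cut into
#' `tile_size` tiles (tiles without striatal tissue are dropped from the
#' training set only), and optimized with Adam on pixel-wise cross-entropy
#' under the chosen augmentation arm. The per-epoch training curve records
#' train loss, held-out loss and held-out pixel accuracy; the returned
#' model carries the weights of the minimum-test-loss epoch.
#'
#' @param cohort A [generate_cohort()] result (the reference MOR1 channel
#'   and ground-truth striosome masks are used).
#' @param spec A [unet_spec()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `unet_model`: list with `weights`, `final_weights`, `spec`,
#'   `config`, `curve` (data frame), `selected_epoch`, `test_sections`
#'   (indices of held-out sections).
#' @export
train_striosome_unet <- function(cohort, spec = unet_spec(),
                                 config = train_config(), verbose = FALSE) {
  stopifnot(inherits(spec, "unet_spec"), inherits(config, "train_config"))
  div <- 2^(spec$depth - 1)
  if (config$tile_size %% div != 0)
    stop("tile_size must be divisible by 2^(depth-1)")
  n_sec <- length(cohort)
  n_train <- floor(config$train_fraction * n_sec)
  if (n_train < 1 || n_train >= n_sec)
    stop("train_fraction leaves no training or no held-out section")
  split <- with_seed(config$seed, sample.int(n_sec))
  train_sec <- split[seq_len(n_train)]
  test_sec <- split[(n_train + 1):n_sec]

  tiles_x <- list(); tiles_y <- list(); origin <- integer()
  for (i in seq_len(n_sec)) {
    rec <- cohort[[i]]
    tl <- tile_image(rec$section$reference, rec$labels, config$tile_size,
                     drop_empty = i %in% train_sec)
    for (t in tl) {
      tiles_x[[length(tiles_x) + 1]] <- t$image
      y <- matrix(0L, nrow(t$labels), ncol(t$labels))
      y[t$labels == 2L] <- 1L
      tiles_y[[length(tiles_y) + 1]] <- y
      origin <- c(origin, i)
    }
  }
  train_idx <- which(origin %in% train_sec) - 1L
  test_idx_full <- which(origin %in% test_sec) - 1L
  eval_idx <- test_idx_full
  if (!is.null(config$eval_tiles) &&
      config$eval_tiles < length(test_idx_full)) {
    eval_idx <- with_seed(config$seed + 1L,
                          sort(sample(test_idx_full, config$eval_tiles)))
  }
  if (length(train_idx) < 1 || length(eval_idx) < 1)
    stop("need >= 1 training and >= 1 held-out tile")

  gmax <- 2^cohort[[1]]$section$bit_depth - 1
  w0 <- unet_init(spec, seed = config$seed)
  arm <- match(config$augmentation_arm,
               c("vflip_only", "vflip_plus_photometric"))
  fit <- unet_train_cpp(tiles_x, tiles_y, unclass(spec), w0,
                        train_idx, eval_idx, config$batch_size,
                        config$total_epochs, config$learning_rate, arm,
                        config$brightness_jitter,
                        if (is.null(config$tiles_per_epoch)) 0L
                        else config$tiles_per_epoch,
                        config$seed, gmax, verbose)
  curve <- data.frame(epoch = seq_len(config$total_epochs),
                      train_loss = fit$train_loss,
                      test_loss = fit$test_loss,
                      test_accuracy = fit$test_accuracy)
  stopifnot(fit$selected_epoch == select_checkpoint(curve))
  structure(list(weights = fit$best_weights,
                 final_weights = fit$final_weights,
                 spec = spec, config = config, curve = curve,
                 selected_epoch = fit$selected_epoch,
                 test_sections = sort(test_sec), gray_max = gmax),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(paste0("unet_model: depth %d, base %d, %s; checkpoint epoch ",
                     "%d/%d (test loss %.5f, accuracy %.5f)\n"),
              x$spec$depth, x$spec$base_channels, x$config$augmentation_arm,
              x$selected_epoch, x$config$total_epochs,
              x$curve$test_loss[x$selected_epoch],
              x$curve$test_accuracy[x$selected_epoch]))
  invisible(x)
}

#' Predict striosomes on a section by tiled inference
#'
#' Runs the model over the reference (MOR1) channel in non-overlapping
#' tiles (reflection-padded at the edges and, if needed, up to a multiple
#' of `2^(depth-1)`), stitches the probability map, and binarizes at 0.5.
#' Probabilities of exactly 0.5 are assigned to striosome (documented
#' tie-break). Remaining pixels are labelled matrix within the supplied
#' tissue mask, background outside it.
#'
#' @param model A `unet_model` from [train_striosome_unet()].
#' @param section A [section_image()] (or a plain numeric matrix treated
#'   as the reference channel).
#' @param tissue Optional logical matrix restricting the matrix label to
#'   the striatal region.
#' @param tile_size Inference tile side (defaults to the training tile
#'   size, capped at 256 for memory locality).
#' @return `list(prob, labels)`: stitched probability map in \[0, 1\] and a
#'   [label_map()].
#' @export
predict_striosomes <- function(model, section, tissue = NULL,
                               tile_size = NULL) {
  img <- if (inherits(section, "section_image")) section$reference else section
  div <- 2^(model$spec$depth - 1)
  if (is.null(tile_size)) tile_size <- min(model$config$tile_size, 256L)
  tile_size <- as.integer(div * ceiling(tile_size / div))
  tiles <- tile_image(img, NULL, tile_size)
  for (i in seq_along(tiles)) {
    tiles[[i]]$prob <- unet_predict_cpp(tiles[[i]]$image,
                                        unclass(model$spec), model$weights,
                                        model$gray_max)
  }
  prob <- stitch_tiles(tiles, nrow(img), ncol(img), what = "prob")
  list(prob = prob, labels = binarize_probability(prob, tissue))
}

#' Binarize a striosome probability map
#'
#' Pixels with probability >= 0.5 (ties go to striosome) become
#' striosome; the remaining pixels become matrix within the tissue mask
#' and background outside it.
#'
#' @param prob Numeric matrix of striosome probabilities in \[0, 1\].
#' @param tissue Optional logical matrix of striatal pixels.
#' @param threshold Binarization threshold (default 0.5).
#' @return A [label_map()].
#' @export
binarize_probability <- function(prob, tissue = NULL, threshold = 0.5) {
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(prob), ncol(prob))
  lab <- matrix(0L, nrow(prob), ncol(prob))
  lab[tissue] <- 1L
  lab[tissue & prob >= threshold] <- 2L
  label_map(lab)
}

#' Evaluate a trained model on its held-out sections
#'
#' Computes macro-averaged (per-section, then averaged) segmentation
#' scores against the ground-truth striosome masks, plus pooled variants,
#' and whole-tile pixel accuracy, for the held-out sections recorded at
#' training time.
#'
#' @param model A `unet_model`.
#' @param cohort The cohort the model was trained on.
#' @param region Evaluation region for overlap metrics: `"tissue"`
#'   (striatal pixels of the ground truth; default) or `"all"`.
#' @return List with `per_section` (data frame of per-section scores),
#'   `macro` and `pooled` [segmentation_score()] rows, and `accuracy`
#'   (whole-tile pixel accuracy over all held-out pixels).
#' @export
evaluate_model <- function(model, cohort, region = c("tissue", "all")) {
  region <- match.arg(region)
  idx <- model$test_sections
  per <- list(); pooled <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  acc_num <- 0; acc_den <- 0
  for (i in idx) {
    rec <- cohort[[i]]
    pred <- predict_striosomes(model, rec$section,
                               tissue = striatal_mask(rec$labels))
    ev <- if (region == "tissue") striatal_mask(rec$labels) else NULL
    cc <- confusion_counts(pred$labels, rec$labels, region = ev)
    sc <- segmentation_score(cc)
    per[[length(per) + 1]] <- data.frame(section = i, t(unlist(cc)),
                                         iou = sc$iou, dice = sc$dice,
                                         precision = sc$precision,
                                         recall = sc$recall,
                                         accuracy = sc$accuracy)
    pooled <- pooled + unlist(cc)
    # whole-tile accuracy: striosome-vs-rest over every pixel of the section
    cc_all <- confusion_counts(pred$labels, rec$labels, region = NULL)
    acc_num <- acc_num + cc_all$tp + cc_all$tn
    acc_den <- acc_den + cc_all$tp + cc_all$tn + cc_all$fp + cc_all$fn
  }
  per <- do.call(rbind, per)
  macro <- as.list(colMeans(per[c("iou", "dice", "precision", "recall",
                                  "accuracy")]))
  macro$averaging_mode <- "macro"
  pooled_sc <- segmentation_score(as.list(pooled))
  pooled_sc$averaging_mode <- "pooled"
  list(per_section = per, macro = macro, pooled = pooled_sc,
       accuracy = acc_num / acc_den)
}
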