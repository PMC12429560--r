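#' Desk-scale striosome segmentation benchmark
#'
#' Runs the full segmentation protocol end to end at desk scale: a seeded
#' synthetic cohort of 48 two-channel 512 x 512 sections (striosome
#' fraction 0.10, additive noise at which plain Otsu thresholding of the
#' MOR1 channel performs poorly), an 85/15 section split (40 train, 8
#' held-out), training of the depth-4 base-16 residual U-Net under the
#' vertical-flip-only arm with checkpoint selection by minimum held-out
#' cross-entropy, and evaluation on the held-out sections: macro-averaged
#' Dice, IoU, Recall and Precision over the striatal region, and
#' whole-tile pixel accuracy at the selected checkpoint. The Otsu draft
#' score over the same held-out sections is reported as the baseline.
#'
#' @param seed Integer seed controlling the cohort, split, initialization
#'   and augmentation stream.
#' @param total_epochs Training epochs (checkpoint may be earlier).
#' @param tiles_per_epoch Training tiles sampled per epoch.
#' @param augmentation_arm Augmentation arm for training.
#' @param verbose Print training progress.
#' @return List with `metrics` (dice, iou, recall, precision, accuracy;
#'   macro-averaged where applicable), `otsu_baseline` (macro scores of
#'   the Otsu draft on the same sections), `model`, `evaluation`, and
#'   `n_test` (held-out section count).
#' @export
segmentation_benchmark <- function(seed = 1L, total_epochs = 14L,
                                   tiles_per_epoch = 192L,
                                   augmentation_arm = "vflip_only",
                                   verbose = FALSE) {
  cfg <- synthesis_config(image_height_px = 512L, image_width_px = 512L,
                          striosome_area_fraction = 0.10, noise_sd = 15,
                          seed = seed)
  cohort <- generate_cohort(default_effect_table(), n_mice_per_group = 4L,
                            cfg, molecules = "MOR1")
  tcfg <- train_config(batch_size = 32L, total_epochs = total_epochs,
                       augmentation_arm = augmentation_arm,
                       train_fraction = 0.85, tile_size = 128L,
                       tiles_per_epoch = tiles_per_epoch, eval_tiles = 24L,
                       seed = seed)
  model <- train_striosome_unet(cohort, unet_spec(depth = 4L,
                                                  base_channels = 16L),
                                tcfg, verbose = verbose)
  ev <- evaluate_model(model, cohort, region = "tissue")

  # Otsu-draft baseline on the same held-out sections
  otsu_pred <- list(); truths <- list(); regions <- list()
  for (i in model$test_sections) {
    rec <- cohort[[i]]
    sm <- striatal_mask(rec$labels)
    otsu_pred[[length(otsu_pred) + 1]] <-
      otsu_preannotate(rec$section$reference, tissue = sm)
    truths[[length(truths) + 1]] <- rec$labels
    regions[[length(regions) + 1]] <- sm
  }
  otsu_scores <- score_images(otsu_pred, truths, regions)

  list(metrics = list(dice = ev$macro$dice, iou = ev$macro$iou,
                      recall = ev$macro$recall,
                      precision = ev$macro$precision,
                      accuracy = ev$accuracy),
       otsu_baseline = as.list(otsu_scores[otsu_scores$averaging_mode ==
                                             "macro", ]),
       model = model, evaluation = ev, n_test = length(model$test_sections))
}
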