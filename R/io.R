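#' Write a section image to disk
#'
#' Channels are written as single-channel images: 16-bit TIFF
#' (`format = "tiff"`) or 8-bit PNG (`format = "png"`), gray levels scaled
#' by the declared bit depth. Files are `<prefix>_ref.<ext>` and
#' `<prefix>_target.<ext>`.
#'
#' @param section A [section_image()].
#' @param prefix Path prefix (directories are created).
#' @param format `"png"` or `"tiff"`.
#' @return Invisibly, the two file paths.
#' @export
write_section <- function(section, prefix, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  gmax <- gray_max(section)
  paths <- character(2)
  for (i in 1:2) {
    ch <- if (i == 1) section$reference else section$target
    nm <- if (i == 1) "ref" else "target"
    scaled <- pmin(pmax(ch / gmax, 0), 1)
    if (format == "png") {
      paths[i] <- paste0(prefix, "_", nm, ".png")
      png::writePNG(scaled, paths[i])
    } else {
      paths[i] <- paste0(prefix, "_", nm, ".tif")
      tiff::writeTIFF(scaled, paths[i], bits.per.sample = 16L)
    }
  }
  invisible(paths)
}

#' Read a section image written by [write_section()]
#'
#' @param prefix Path prefix used at write time.
#' @param format `"png"` or `"tiff"`.
#' @param bit_depth Bit depth to restore gray levels to.
#' @param channel_names Channel names for the restored section.
#' @return A [section_image()].
#' @export
read_section <- function(prefix, format = c("png", "tiff"), bit_depth = 8L,
                         channel_names = c("MOR1", "target")) {
  format <- match.arg(format)
  ext <- if (format == "png") ".png" else ".tif"
  rd <- function(p) {
    m <- if (format == "png") png::readPNG(p) else tiff::readTIFF(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * (2^bit_depth - 1)
  }
  section_image(rd(paste0(prefix, "_ref", ext)),
                rd(paste0(prefix, "_target", ext)),
                channel_names = channel_names, bit_depth = bit_depth)
}

# label codes are stored as gray level code * 50 / 255 in indexed PNGs
label_palette_step <- 50

#' Write a label map as an indexed PNG
#'
#' The palette maps label code k to gray level `50 k` (0 background,
#' 50 matrix, 100 striosome, 150 fiber bundle, 200 vessel).
#'
#' @param labels A [label_map()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_label_map <- function(labels, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(unclass(labels) * label_palette_step / 255, path)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path PNG path.
#' @return A [label_map()].
#' @export
read_label_map <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  label_map(matrix(as.integer(round(m * 255 / label_palette_step)),
                   nrow(m), ncol(m)))
}

#' Write a training curve as CSV
#' @param curve Training-curve data frame (`epoch`, `train_loss`,
#'   `test_loss`, `test_accuracy`).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_training_curve <- function(curve, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
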