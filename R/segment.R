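#' Otsu threshold by exhaustive between-class variance maximization
#'
#' Searches all cut points between the observed gray values (exactly, when
#' there are at most `max_exact` distinct values; otherwise on a histogram
#' with `n_bins` bins) and returns the threshold maximizing the
#' between-class variance. The threshold is the midpoint between the two
#' classes' boundary values; pixels strictly above it form the high class.
#'
#' @param x Numeric vector or matrix of gray values; must not be constant.
#' @param n_bins Histogram bins used for large value sets.
#' @param max_exact Maximum number of distinct values for the exact search.
#' @return Numeric threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256L, max_exact = 256L) {
  v <- as.vector(x)
  v <- v[is.finite(v)]
  u <- sort(unique(v))
  if (length(u) < 2) stop("constant image: no threshold exists")
  if (length(u) > max_exact) {
    br <- seq(min(v), max(v), length.out = n_bins + 1L)
    mid <- (br[-1] + br[-length(br)]) / 2
    cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
    u <- mid[cnt > 0]; w <- cnt[cnt > 0]
  } else {
    w <- tabulate(match(v, u), length(u))
  }
  n <- sum(w)
  cw <- cumsum(w)
  cs <- cumsum(w * u)
  tot <- cs[length(cs)]
  k <- seq_len(length(u) - 1L)              # cut after value u[k]
  w0 <- cw[k] / n
  mu0 <- cs[k] / cw[k]
  mu1 <- (tot - cs[k]) / (n - cw[k])
  bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
  best <- which.max(bcv)                    # first maximum on ties
  (u[best] + u[best + 1L]) / 2
}

#' Otsu-assisted striosome pre-annotation
#'
#' Draft binary striosome mask obtained by Otsu thresholding of the
#' reference (MOR1) channel within the tissue region; the high-intensity
#' class is marked striosome, the rest of the tissue matrix. Intended as
#' an annotation aid, not as final ground truth.
#'
#' @param image Numeric matrix (typically the MOR1 reference channel).
#' @param tissue Optional logical matrix restricting the threshold and the
#'   draft to the striatal tissue; default uses the whole frame.
#' @return A [label_map()] draft with striosome/matrix (and background
#'   outside `tissue`).
#' @export
otsu_preannotate <- function(image, tissue = NULL) {
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(image), ncol(image))
  thr <- otsu_threshold(image[tissue])
  lab <- matrix(0L, nrow(image), ncol(image))
  lab[tissue] <- 1L
  lab[tissue & image > thr] <- 2L
  label_map(lab)
}

# internal: reflect-pad a matrix to target size (bottom/right)
reflect_pad <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h < H) {
    need <- H - h
    if (need > h - 1) stop("tile larger than image allows for reflection padding")
    m <- rbind(m, m[seq(h - 1, by = -1, length.out = need), , drop = FALSE])
  }
  if (w < W) {
    need <- W - w
    if (need > w - 1) stop("tile larger than image allows for reflection padding")
    m <- cbind(m, m[, seq(w - 1, by = -1, length.out = need), drop = FALSE])
  }
  m
}

#' Tile an image (and optional labels) into a grid of fixed-size tiles
#'
#' Covers the image with a grid of `tile_size` tiles. Edge tiles are
#' anchored so the full tile still fits inside the image (overlapping the
#' previous tile); when the image itself is smaller than the tile the
#' margin is completed by reflection padding. Each tile records its
#' half-open crop window (0-based `row0`, `col0`, valid `height`, `width`)
#' and the offset of that window inside the tile (`off_r`, `off_c`), so
#' that [stitch_tiles()] reconstructs the image exactly.
#'
#' @param image Numeric matrix (one channel).
#' @param labels Optional aligned label/integer matrix, tiled identically.
#' @param tile_size Tile side in pixels.
#' @param drop_empty Drop tiles with no striatal tissue (`labels` 1 or 2);
#'   allowed for training sets, never for inference.
#' @return List of tiles: `list(image, labels, placement)` where
#'   `placement = c(row0, col0, height, width, off_r, off_c)`.
#' @export
tile_image <- function(image, labels = NULL, tile_size = 512L,
                       drop_empty = FALSE) {
  H <- nrow(image); W <- ncol(image)
  if (tile_size < 2) stop("tile_size must be >= 2")
  nr <- ceiling(H / tile_size); nc <- ceiling(W / tile_size)
  out <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- (i - 1L) * tile_size
      c0 <- (j - 1L) * tile_size
      h <- min(tile_size, H - r0)
      w <- min(tile_size, W - c0)
      rs <- max(0L, min(r0, H - tile_size))
      cs <- max(0L, min(c0, W - tile_size))
      rows <- rs + seq_len(min(tile_size, H - rs))
      cols <- cs + seq_len(min(tile_size, W - cs))
      img <- image[rows, cols, drop = FALSE]
      lab <- if (!is.null(labels)) labels[rows, cols, drop = FALSE] else NULL
      if (drop_empty && !is.null(lab) && !any(lab == 1L | lab == 2L)) next
      img <- reflect_pad(img, tile_size, tile_size)
      if (!is.null(lab)) lab <- reflect_pad(lab, tile_size, tile_size)
      out[[length(out) + 1]] <- list(
        image = img, labels = lab,
        placement = c(row0 = r0, col0 = c0, height = h, width = w,
                      off_r = r0 - rs, off_c = c0 - cs))
    }
  }
  out
}

#' Stitch tiles back into a full image
#'
#' Inverse of [tile_image()]: each tile's valid region (its recorded
#' half-open crop window) is written back; padded margins are discarded.
#'
#' @param tiles List of tiles from [tile_image()] (or tiles whose `image`
#'   was replaced by a same-size result, e.g. probabilities).
#' @param height,width Output dimensions.
#' @param what Element of each tile to stitch (default `"image"`).
#' @return Numeric matrix of size `height` x `width`.
#' @export
stitch_tiles <- function(tiles, height, width, what = "image") {
  out <- matrix(NA_real_, height, width)
  for (t in tiles) {
    p <- t$placement
    out[p["row0"] + seq_len(p["height"]), p["col0"] + seq_len(p["width"])] <-
      t[[what]][p["off_r"] + seq_len(p["height"]),
                p["off_c"] + seq_len(p["width"])]
  }
  if (anyNA(out)) stop("tiles do not cover the image")
  out
}

#' Augment a training tile
#'
#' `vflip_only`: with probability 1/2 the tile and its labels are flipped
#' vertically (top-bottom), nothing else. `vflip_plus_photometric`
#' additionally jitters brightness (and, for 3-channel arrays, hue and
#' saturation) of the image only; labels are never photometrically
#' altered. Geometric changes are always applied identically to image and
#' labels. Uses the current R RNG stream, so a fixed seed yields an
#' identical augmented stream.
#'
#' @param image Numeric matrix (gray) or H x W x 3 array (RGB).
#' @param labels Aligned label matrix.
#' @param arm `"vflip_only"` or `"vflip_plus_photometric"`.
#' @param brightness,saturation Relative jitter half-ranges.
#' @param hue Hue jitter half-range in cycles.
#' @param force_flip Force the vertical flip (for testing the involution).
#' @return `list(image, labels)`.
#' @export
augment_tile <- function(image, labels,
                         arm = c("vflip_only", "vflip_plus_photometric"),
                         brightness = 0.2, saturation = 0.2, hue = 0.05,
                         force_flip = FALSE) {
  arm <- match.arg(arm)
  flip <- force_flip || runif(1) < 0.5
  vflip <- function(m) {
    if (length(dim(m)) == 3) m[rev(seq_len(nrow(m))), , , drop = FALSE]
    else m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  if (flip) {
    image <- vflip(image)
    if (!is.null(labels)) labels <- vflip(labels)
  }
  if (arm == "vflip_plus_photometric") {
    b <- 1 + runif(1, -brightness, brightness)
    if (length(dim(image)) == 3) {
      # hue/saturation jitter in HSV space; gray-level range assumed [0, 255]
      dh <- runif(1, -hue, hue)
      ds <- 1 + runif(1, -saturation, saturation)
      d <- dim(image)
      hsv <- grDevices::rgb2hsv(rbind(as.vector(image[, , 1]),
                                      as.vector(image[, , 2]),
                                      as.vector(image[, , 3])),
                                maxColorValue = 255)
      hsv[1, ] <- (hsv[1, ] + dh) %% 1
      hsv[2, ] <- pmin(pmax(hsv[2, ] * ds, 0), 1)
      hsv[3, ] <- pmin(hsv[3, ] * b, 1)
      rgb <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ]))
      image <- array(as.numeric(t(rgb)), dim = d)
    } else {
      # single-channel: hue/saturation are identity, brightness scales
      image <- pmin(pmax(image * b, 0), 255)
    }
  }
  list(image = image, labels = labels)
}
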