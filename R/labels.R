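#' Label codes for compartment maps
#'
#' Per-pixel categorical maps use a fixed integer coding:
#' 0 = background (slide glass outside the tissue), 1 = matrix,
#' 2 = striosome, 3 = fiber bundle, 4 = vessel. Striosome and matrix
#' together make up the striatal tissue; fiber bundles and vessels are
#' excluded structures carved out of the matrix.
#'
#' @return Named integer vector mapping label names to codes.
#' @export
label_levels <- function() {
  c(background = 0L, matrix = 1L, striosome = 2L,
    fiber_bundle = 3L, vessel = 4L)
}

#' Construct a label map
#'
#' @param labels Integer matrix with values in `label_levels()`.
#' @return A `label_map` object (integer matrix with class attribute).
#' @export
label_map <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(label_levels()))
  if (length(bad) > 0)
    stop("invalid label codes: ", paste(bad, collapse = ", "))
  structure(labels, class = c("label_map", "matrix"))
}

#' @export
print.label_map <- function(x, ...) {
  lv <- label_levels()
  tab <- tabulate(as.vector(x) + 1L, nbins = 5L)
  cat(sprintf("label_map %d x %d\n", nrow(x), ncol(x)))
  for (i in seq_along(lv))
    cat(sprintf("  %-12s %d px\n", names(lv)[i], tab[lv[i] + 1L]))
  invisible(x)
}

# internal: logical masks
striatal_mask <- function(labels) labels == 1L | labels == 2L
tissue_mask <- function(labels) labels != 0L

#' Construct a two-channel section image
#'
#' A section image holds the compartment-defining reference channel (MOR1)
#' and the channel of the molecule under study, as gray-level matrices of
#' identical size.
#'
#' @param reference Numeric matrix, MOR1 reference channel.
#' @param target Numeric matrix, target-molecule channel.
#' @param channel_names Character vector of length 2.
#' @param bit_depth Declared bit depth (8 or 16).
#' @return A `section_image` object.
#' @export
section_image <- function(reference, target,
                          channel_names = c("MOR1", "target"),
                          bit_depth = 8L) {
  if (!all(dim(reference) == dim(target)))
    stop("reference and target channels must share identical dimensions")
  gmax <- 2^bit_depth - 1
  rng <- range(reference, target)
  if (rng[1] < 0 || rng[2] > gmax)
    stop("gray levels outside declared bit depth range")
  structure(list(reference = reference, target = target,
                 channel_names = channel_names, bit_depth = as.integer(bit_depth)),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("section_image %d x %d (%d-bit), channels: %s\n",
              nrow(x$reference), ncol(x$reference), x$bit_depth,
              paste(x$channel_names, collapse = " / ")))
  invisible(x)
}

#' Maximum gray level of a section image
#' @param section A `section_image`.
#' @return Numeric scalar, `2^bit_depth - 1`.
#' @export
gray_max <- function(section) 2^section$bit_depth - 1
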