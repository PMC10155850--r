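#' Collagen-fiber area fraction from a binary segmentation mask
#'
#' Computes the histology quantification
#' \code{100 * (collagen-positive area) / (total tissue area)} from a
#' pre-segmented mask: any nonzero (or \code{TRUE}) pixel counts as
#' collagen-positive. An optional tissue-region mask restricts both the
#' numerator and the denominator; otherwise the whole image is tissue.
#' Stain separation and thresholding are upstream concerns (typically done
#' in ImageJ) -- this function only implements the counting identity.
#'
#' @param mask matrix (or logical/0-1 array), or a path to a single-channel
#'   PNG/TIFF read via \code{\link{read_mask}}.
#' @param tissue optional mask of the same shape delimiting the tissue
#'   region.
#' @return percentage in [0, 100].
#' @export
#' @examples
#' m <- matrix(0, 10, 10); m[1:4, ] <- 1
#' collagen_fraction(m)  # 40
collagen_fraction <- function(mask, tissue = NULL) {
  if (is.character(mask)) mask <- read_mask(mask)
  if (is.character(tissue)) tissue <- read_mask(tissue)
  m <- mask != 0
  if (!length(m)) stop("empty mask")
  if (is.null(tissue)) {
    tis <- rep(TRUE, length(m))
  } else {
    if (!identical(dim(tissue), dim(mask)))
      stop("tissue mask dimensions do not match the collagen mask")
    tis <- tissue != 0
  }
  n_tis <- sum(tis)
  if (n_tis == 0) stop("tissue region is empty")
  100 * sum(m & tis) / n_tis
}

#' Read a single-channel raster mask
#'
#' Reads a PNG (or TIFF, if the \pkg{tiff} package is available) as a
#' numeric matrix; multi-channel images are collapsed to their first
#' channel. Nonzero means positive.
#'
#' @param path file path ending in \code{.png}, \code{.tif} or \code{.tiff}.
#' @return numeric matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF masks requires the 'tiff' package")
    tiff::readTIFF(path)
  } else stop("unsupported mask format '", ext, "' (use PNG or TIFF)")
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Generate a synthetic binary mask with an exact positive fraction
#'
#' Places \code{round(fraction * n)} positive pixels uniformly at random --
#' a fixture generator for testing the collagen-fraction metric against a
#' known ground truth.
#'
#' @param fraction target positive fraction in [0, 1].
#' @param nrow,ncol mask dimensions.
#' @param seed RNG seed (the only randomness in the package lives in
#'   fixture generation).
#' @return binary matrix.
#' @export
make_mask <- function(fraction, nrow = 100, ncol = 100, seed = 1) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n <- nrow * ncol
  k <- round(fraction * n)
  set.seed(seed)
  m <- matrix(0L, nrow, ncol)
  m[sample.int(n, k)] <- 1L
  m
}
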