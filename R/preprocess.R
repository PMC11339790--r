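# Canonicalization of raw fundus photographs: blank-area cropping to a
# square, resizing to the model resolution, eye-area mask extraction, and
# Gaussian-noise corruption for robustness experiments.
#
# Images are numeric arrays (H, W, 3) with intensities in [0, 1]; masks are
# binary (H, W) matrices. EBImage stores images as (x, y, c), so arrays are
# transposed at that boundary.

as_ebimage <- function(img) {
  EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
}

from_ebimage <- function(ebi) {
  a <- as.array(ebi)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
}

check_image <- function(img, min_side = 32L) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("image must be an (H, W, 3) array")
  }
  if (dim(img)[1] < min_side || dim(img)[2] < min_side) {
    stop("image sides must be at least ", min_side, " pixels")
  }
  if (!all(is.finite(img)) || min(img) < 0 || max(img) > 1) {
    stop("image intensities must be finite values in [0, 1]")
  }
  invisible(img)
}

#' Read / write an image file
#'
#' Thin wrappers over EBImage I/O that fix the in-memory layout to an
#' `(H, W, 3)` array in `[0, 1]`. Grayscale files are expanded to three
#' channels; an alpha channel is dropped on read. `write_mask()` writes a
#' binary mask either as a single-channel PNG or as the alpha channel of an
#' RGBA PNG.
#'
#' @param path file path (PNG or JPEG)
#' @param img `(H, W, 3)` array in `[0, 1]`
#' @param mask binary `(H, W)` matrix
#' @param alpha if `TRUE`, attach the mask as alpha channel over `img`
#' @return `read_image()` returns the image array; writers return the path
#' @export
read_image <- function(path) {
  ebi <- EBImage::readImage(path)
  a <- as.array(ebi)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  img <- aperm(a, c(2, 1, 3))
  pmin(pmax(img, 0), 1)
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  EBImage::writeImage(as_ebimage(pmin(pmax(img, 0), 1)), path)
  invisible(path)
}

#' @rdname read_image
#' @export
write_mask <- function(mask, path, img = NULL, alpha = FALSE) {
  if (alpha) {
    if (is.null(img)) stop("alpha-channel output requires the image")
    rgba <- array(0, dim = c(ncol(mask), nrow(mask), 4L))
    rgba[, , 1:3] <- aperm(img, c(2, 1, 3))
    rgba[, , 4] <- t(mask)
    EBImage::writeImage(EBImage::Image(rgba, colormode = "Color"), path)
  } else {
    EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  }
  invisible(path)
}

pixel_brightness <- function(img) {
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

#' Crop blank borders to a square
#'
#' Finds the bounding box of all pixels whose mean-channel brightness exceeds
#' `brightness_threshold`, then returns the tightest square crop containing
#' that box, centered on it. When the square extends past the frame the
#' image is padded with zeros symmetrically rather than cutting content.
#'
#' @param img `(H, W, 3)` array in `[0, 1]`
#' @param brightness_threshold pixels at or below this mean brightness count
#'   as blank (default 0.02)
#' @return a square `(S, S, 3)` array
#' @export
crop_blank_to_square <- function(img, brightness_threshold = 0.02) {
  check_image(img)
  b <- pixel_brightness(img)
  rows <- which(apply(b, 1, max) > brightness_threshold)
  cols <- which(apply(b, 2, max) > brightness_threshold)
  if (length(rows) == 0L || length(cols) == 0L) {
    stop("empty content: no pixel brighter than the blank threshold")
  }
  r0 <- min(rows); r1 <- max(rows)
  c0 <- min(cols); c1 <- max(cols)
  hh <- r1 - r0 + 1L
  ww <- c1 - c0 + 1L
  side <- max(hh, ww)
  # center the square hull on the content box
  r0 <- r0 - (side - hh) %/% 2L
  c0 <- c0 - (side - ww) %/% 2L
  out <- array(0, dim = c(side, side, 3L))
  # source range clipped to the frame; destination offset accordingly
  sr <- max(r0, 1L):min(r0 + side - 1L, nrow(b))
  sc <- max(c0, 1L):min(c0 + side - 1L, ncol(b))
  out[sr - r0 + 1L, sc - c0 + 1L, ] <- img[sr, sc, , drop = FALSE]
  out
}

#' Resize a square image to the canonical resolution
#'
#' Bilinear resize to `side x side` (default 512). The side must be divisible
#' by 32 so the downstream /32 feature grid is integral.
#'
#' @param img square `(S, S, 3)` array
#' @param side target side length, divisible by 32
#' @return `(side, side, 3)` array with values in `[0, 1]`
#' @export
resize_canonical <- function(img, side = 512L) {
  check_image(img)
  if (dim(img)[1] != dim(img)[2]) stop("image must be square; crop first")
  if (side %% 32L != 0L) stop("side must be divisible by 32, got ", side)
  if (dim(img)[1] == side) return(img)
  out <- from_ebimage(EBImage::resize(as_ebimage(img), w = side, h = side,
                                      filter = "bilinear", antialias = TRUE))
  pmin(pmax(out, 0), 1)
}

#' Compute the eye-area mask
#'
#' Binary map of the eye area from brightness and edge information: an
#' automatic (Otsu) brightness threshold is combined with a dilated
#' gradient-magnitude edge map, the largest connected component is kept and
#' its holes filled.
#'
#' @param img canonical `(S, S, 3)` array
#' @return binary `(S, S)` matrix, 1 inside the eye area
#' @export
compute_eye_mask <- function(img) {
  check_image(img)
  b <- pixel_brightness(img)
  eb <- EBImage::Image(t(b))
  thr <- EBImage::otsu(eb, range = c(0, 1))
  bright <- b > thr
  if (!any(bright)) stop("no eye area: image is uniformly dark")
  # gradient magnitude (Sobel) marks the rim of the eye area
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- as.array(EBImage::filter2(eb, sx))
  gy <- as.array(EBImage::filter2(eb, t(sx)))
  gmag <- t(sqrt(gx^2 + gy^2))
  edge <- gmag > max(stats::quantile(gmag, 0.98), 1e-6)
  edge_dil <- t(as.array(EBImage::dilate(EBImage::Image(t(edge * 1)),
                                         EBImage::makeBrush(5, "disc")))) > 0
  fg <- bright | edge_dil
  lab <- EBImage::bwlabel(EBImage::Image(t(fg * 1)))
  la <- t(as.array(lab))
  if (max(la) < 1) stop("no eye area: empty foreground")
  sizes <- tabulate(la[la > 0])
  keep <- which.max(sizes)
  comp <- la == keep
  filled <- t(as.array(EBImage::fillHull(EBImage::Image(t(comp * 1))))) > 0
  # the dilated edge band closed the boundary; erode with the same brush so
  # the final outline tracks the brightness boundary, not the dilation
  eroded <- t(as.array(EBImage::erode(EBImage::Image(t(filled * 1)),
                                      EBImage::makeBrush(5, "disc")))) > 0
  if (!any(eroded)) eroded <- filled
  mode(eroded) <- "integer"
  unname(eroded * 1L)
}

#' Add Gaussian noise to an image
#'
#' Adds i.i.d. Gaussian noise (default mean 0, variance 0.05 on the `[0, 1]`
#' intensity scale) per pixel and channel, then clips to `[0, 1]`.
#' Reproducible under a fixed seed.
#'
#' @param img `(H, W, 3)` array in `[0, 1]`
#' @param mean,var noise mean and variance (variance must be nonnegative)
#' @param seed optional integer seed
#' @return corrupted image, same shape
#' @export
corrupt_gaussian <- function(img, mean = 0, var = 0.05, seed = NULL) {
  check_image(img)
  if (var < 0) stop("noise variance must be nonnegative")
  if (var == 0 && mean == 0) return(img)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  noise <- array(stats::rnorm(length(img), mean = mean, sd = sqrt(var)),
                 dim = dim(img))
  pmin(pmax(img + noise, 0), 1)
}

#' Canonicalize a raw image
#'
#' Convenience composition: blank-crop to a square, then resize to the
#' canonical side.
#'
#' @inheritParams crop_blank_to_square
#' @inheritParams resize_canonical
#' @return `(side, side, 3)` canonical image
#' @export
canonicalize <- function(img, side = 512L, brightness_threshold = 0.02) {
  resize_canonical(crop_blank_to_square(img, brightness_threshold), side)
}
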