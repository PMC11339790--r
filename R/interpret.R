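# Saliency heat maps: where does the model look?
#
# Attention variants expose a learned spatial weighting that is visualized
# directly (for the self-attention variant, the average attention each
# position receives). Baseline variants have no attention module, so a
# gradient-weighted class-activation map on the stage-4 feature is used:
# channel weights are the spatially pooled logit gradients, and the map is
# the ReLU of the weighted channel sum.

# center-aligned bilinear upsampling with edge replication (so a constant
# grid stays exactly constant, unlike zero-padded resampling)
upsample_bilinear <- function(grid, sh, sw) {
  gh <- nrow(grid); gw <- ncol(grid)
  src <- function(n_out, n_in) {
    u <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pmin(pmax(u, 1), n_in)
  }
  uy <- src(sh, gh); ux <- src(sw, gw)
  y0 <- pmin(floor(uy), gh - 1L); x0 <- pmin(floor(ux), gw - 1L)
  if (gh == 1L) y0 <- rep(1L, sh)
  if (gw == 1L) x0 <- rep(1L, sw)
  wy <- uy - y0; wx <- ux - x0
  y1 <- pmin(y0 + 1L, gh); x1 <- pmin(x0 + 1L, gw)
  (1 - wy) %o% (1 - wx) * grid[cbind(rep(y0, sw), rep(x0, each = sh))] +
    (1 - wy) %o% wx * grid[cbind(rep(y0, sw), rep(x1, each = sh))] +
    wy %o% (1 - wx) * grid[cbind(rep(y1, sw), rep(x0, each = sh))] +
    wy %o% wx * grid[cbind(rep(y1, sw), rep(x1, each = sh))]
}

# raw low-resolution saliency map (feature grid resolution), one image
.saliency_grid <- function(model, x, masks = NULL) {
  out <- model_forward(model, x, masks = masks, training = FALSE)
  if (inherits(model$att, "nn_spatial_attention")) {
    return(out$attention[, , 1, 1])
  }
  if (inherits(model$att, "nn_self_attention")) {
    d <- dim(out$feature)
    P <- d[1] * d[2]
    X <- matrix(out$feature[, , , 1], nrow = P)
    A <- .softmax_rows(tcrossprod(X %*% model$att$Wq, X %*% model$att$Wk) /
                         sqrt(model$att$dk))
    return(matrix(colMeans(A), d[1], d[2]))     # attention received per position
  }
  # baseline variants: gradient-weighted activation map on the (gated)
  # stage-4 feature; only the head needs a cached pass
  feat <- out$feature
  if (model$uses_mask) {
    d <- dim(feat)
    mn <- if (is.list(masks)) masks[[1]] else masks[, , 1]
    md <- downsample_mask(mn, d[1], d[2])
    feat <- feat * as.vector(md)
  }
  nn_forward(model$head, feat, training = TRUE)
  dfeat <- nn_backward(model$head, 1)
  d <- dim(feat)
  w <- colMeans(matrix(dfeat[, , , 1], nrow = d[1] * d[2]))  # GAP of gradients
  cam <- matrix(matrix(feat[, , , 1], nrow = d[1] * d[2]) %*% w, d[1], d[2])
  pmax(cam, 0)
}

#' Saliency heat map for one canonical image
#'
#' Produces an `S x S` saliency map in `[0, 1]` (bilinear upsampling of the
#' model's attention map, or a gradient-weighted activation map for the
#' baseline variants), min-max normalized per image (an all-constant map
#' normalizes to 0.5 everywhere), masked to the eye area, plus a colorized
#' overlay on the input image.
#'
#' @param model an `iqa_model`
#' @param image canonical `(S, S, 3)` array
#' @param mask optional binary eye mask; computed with [compute_eye_mask()]
#'   when absent
#' @param alpha overlay blend weight of the colorized map (default 0.4)
#' @return list with `map` (`S x S` in `[0, 1]`) and `overlay`
#'   (`(S, S, 3)` blend)
#' @export
attention_heatmap <- function(model, image, mask = NULL, alpha = 0.4) {
  stopifnot(inherits(model, "iqa_model"))
  check_image(image)
  if (is.null(mask)) mask <- compute_eye_mask(image)
  x <- array(image, dim = c(dim(image), 1L))
  masks <- array(mask, dim = c(dim(mask), 1L))
  g <- .saliency_grid(model, x, masks)
  heatmap_from_grid(g, image, mask, alpha)
}

#' Render a feature-grid saliency map onto an image
#'
#' Upsamples a low-resolution saliency grid to the image size (bilinear),
#' min-max normalizes it per image (an all-constant grid maps to 0.5
#' everywhere), masks it to the eye area, and blends a colorized version
#' over the image. Used by [attention_heatmap()]; exposed so arbitrary
#' spatial weightings can be visualized.
#'
#' @param grid numeric matrix at feature-grid resolution
#' @param image canonical `(S, S, 3)` array
#' @param mask binary eye mask
#' @param alpha overlay blend weight
#' @return list with `map` and `overlay` as in [attention_heatmap()]
#' @export
heatmap_from_grid <- function(grid, image, mask, alpha = 0.4) {
  s <- dim(image)[1]
  up <- upsample_bilinear(grid, s, s)
  rng <- range(up)
  # an (effectively) constant map carries no ranking information: 0.5 by
  # convention rather than amplifying resampling noise to full range
  map <- if (diff(rng) <= 1e-8 * max(1, abs(rng[2])) + 1e-12) {
    matrix(0.5, s, s)
  } else {
    (up - rng[1]) / diff(rng)
  }
  map <- map * mask
  ramp <- grDevices::colorRamp(c("#00007F", "#007FFF", "#7FFF7F",
                                 "#FF7F00", "#7F0000"))
  colmat <- ramp(as.vector(map)) / 255
  colored <- array(colmat, dim = c(s, s, 3L))
  overlay <- (1 - alpha) * image + alpha * colored
  list(map = map, overlay = pmin(pmax(overlay, 0), 1))
}
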