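# 50-layer-style residual backbone exposing the four stage outputs.
#
# Stem: 7x7 stride-2 convolution + 3x3 stride-2 max pool (stride /4), then four
# stages of bottleneck blocks (strides /4, /8, /16, /32 relative to the input).
# At the reference width (64) the stage outputs carry 256, 512, 1024 and 2048
# channels; a reduced width shrinks every layer proportionally for desk-scale
# experiments while preserving the stride geometry the downstream rearrangement
# relies on.

bottleneck_new <- function(cin, mid, cout, stride = 1L, group = "backbone") {
  e <- new_layer("nn_bottleneck",
    conv1 = conv2d_new(cin, mid, 1L, bias = FALSE, group = group),
    bn1 = batchnorm2d_new(mid, group = group),
    relu1 = relu_new(),
    conv2 = conv2d_new(mid, mid, 3L, stride = stride, pad = 1L, bias = FALSE, group = group),
    bn2 = batchnorm2d_new(mid, group = group),
    relu2 = relu_new(),
    conv3 = conv2d_new(mid, cout, 1L, bias = FALSE, group = group),
    bn3 = batchnorm2d_new(cout, group = group),
    proj = NULL, proj_bn = NULL, cache = NULL)
  if (stride != 1L || cin != cout) {
    e$proj <- conv2d_new(cin, cout, 1L, stride = stride, bias = FALSE, group = group)
    e$proj_bn <- batchnorm2d_new(cout, group = group)
  }
  e
}

#' @export
nn_params.nn_bottleneck <- function(layer) {
  parts <- list(layer$conv1, layer$bn1, layer$conv2, layer$bn2, layer$conv3, layer$bn3)
  if (!is.null(layer$proj)) parts <- c(parts, list(layer$proj, layer$proj_bn))
  do.call(c, lapply(parts, nn_params))
}

#' @export
nn_forward.nn_bottleneck <- function(layer, x, training = FALSE) {
  h <- nn_forward(layer$conv1, x, training)
  h <- nn_forward(layer$bn1, h, training)
  h <- nn_forward(layer$relu1, h, training)
  h <- nn_forward(layer$conv2, h, training)
  h <- nn_forward(layer$bn2, h, training)
  h <- nn_forward(layer$relu2, h, training)
  h <- nn_forward(layer$conv3, h, training)
  h <- nn_forward(layer$bn3, h, training)
  s <- x
  if (!is.null(layer$proj)) {
    s <- nn_forward(layer$proj, s, training)
    s <- nn_forward(layer$proj_bn, s, training)
  }
  out <- h + s
  mask <- out > 0
  out <- out * mask
  layer$cache <- if (training) mask else NULL
  out
}

#' @export
nn_backward.nn_bottleneck <- function(layer, dout) {
  if (is.null(layer$cache)) stop("bottleneck: no cached forward pass")
  dsum <- dout * layer$cache
  dh <- nn_backward(layer$bn3, dsum)
  dh <- nn_backward(layer$conv3, dh)
  dh <- nn_backward(layer$relu2, dh)
  dh <- nn_backward(layer$bn2, dh)
  dh <- nn_backward(layer$conv2, dh)
  dh <- nn_backward(layer$relu1, dh)
  dh <- nn_backward(layer$bn1, dh)
  dx <- nn_backward(layer$conv1, dh)
  if (!is.null(layer$proj)) {
    ds <- nn_backward(layer$proj_bn, dsum)
    dx <- dx + nn_backward(layer$proj, ds)
  } else {
    dx <- dx + dsum
  }
  dx
}

backbone_new <- function(width = 64L, blocks = c(3L, 4L, 6L, 3L), in_ch = 3L) {
  stopifnot(length(blocks) == 4L, width >= 1L)
  stem <- sequential_new(list(
    conv2d_new(in_ch, width, 7L, stride = 2L, pad = 3L, bias = FALSE, group = "backbone"),
    batchnorm2d_new(width, group = "backbone"),
    relu_new(),
    maxpool_new(3L, 2L, 1L)
  ))
  stages <- vector("list", 4L)
  cin <- width
  for (i in 1:4) {
    mid <- width * 2L^(i - 1L)
    cout <- 4L * mid
    stride1 <- if (i == 1L) 1L else 2L
    blist <- vector("list", blocks[i])
    for (j in seq_len(blocks[i])) {
      blist[[j]] <- bottleneck_new(cin, mid, cout,
                                   stride = if (j == 1L) stride1 else 1L)
      cin <- cout
    }
    stages[[i]] <- blist
  }
  new_layer("nn_backbone", stem = stem, stages = stages,
            width = as.integer(width),
            stage_channels = 4L * width * 2L^(0:3))
}

#' @export
nn_params.nn_backbone <- function(layer) {
  c(nn_params(layer$stem),
    do.call(c, lapply(unlist(layer$stages, recursive = FALSE), nn_params)))
}

# Returns the four stage activations s1..s4 with strides /4, /8, /16, /32.
backbone_forward <- function(bb, x, training = FALSE) {
  d <- tdim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("input side must be divisible by 32 (got ", d[1], "x", d[2], ")")
  }
  h <- nn_forward(bb$stem, x, training)
  out <- vector("list", 4L)
  for (i in 1:4) {
    for (blk in bb$stages[[i]]) h <- nn_forward(blk, h, training)
    out[[i]] <- h
  }
  names(out) <- paste0("s", 1:4)
  out
}

#' @export
nn_forward.nn_backbone <- function(layer, x, training = FALSE) {
  backbone_forward(layer, x, training)
}

# grads: list with (possibly NULL) entries s1..s4; taps are summed where a
# stage output feeds both the next stage and the multi-scale extractor.
backbone_backward <- function(bb, grads) {
  g <- NULL
  for (i in 4:1) {
    gi <- grads[[paste0("s", i)]]
    if (!is.null(gi)) g <- if (is.null(g)) gi else g + gi
    if (is.null(g)) next
    for (blk in rev(bb$stages[[i]])) g <- nn_backward(blk, g)
  }
  if (is.null(g)) return(NULL)
  nn_backward(bb$stem, g)
}
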