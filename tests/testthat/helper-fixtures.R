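# Shared fixtures: tiny images and reduced models built in code.

ns <- asNamespace("fundusiqa")

# a bright disk on black background
disk_image <- function(side = 512L, cx = side / 2, cy = side / 2,
                       radius = 0.4 * side, value = c(0.8, 0.5, 0.2)) {
  xg <- matrix(rep(seq_len(side), each = side), side, side)
  yg <- matrix(rep(seq_len(side), times = side), side, side)
  inside <- (yg - cy)^2 + (xg - cx)^2 <= radius^2
  img <- array(0, dim = c(side, side, 3L))
  for (ch in 1:3) img[, , ch] <- value[ch] * inside
  img
}

disk_membership <- function(side, cx, cy, radius) {
  xg <- matrix(rep(seq_len(side), each = side), side, side)
  yg <- matrix(rep(seq_len(side), times = side), side, side)
  ((yg - cy)^2 + (xg - cx)^2 <= radius^2) * 1L
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)

tiny_config <- function() {
  reduced_model_config(width = 4L, blocks = c(1L, 1L, 1L, 1L),
                       o_channels = c(2L, 4L, 8L), sir_channels = 8L,
                       att_widths = c(8L), head_hidden = 8L)
}

random_batch <- function(side = 64L, n = 2L, seed = 99L) {
  set.seed(seed)
  array(runif(side * side * 3 * n), dim = c(side, side, 3L, n))
}

# central-difference numerical gradient of scalar-valued f at x
numerical_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
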