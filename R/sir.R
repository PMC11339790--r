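# Spatial-information-retained (SIR) multi-scale feature extraction.
#
# Each backbone scale is rescaled channel-wise (1x1 conv + BN + ReLU), split
# into non-overlapping spatial chunks the size of the coarsest (stage-4) grid,
# and the chunks are stacked along the channel axis — a space-to-depth
# rearrangement that unifies grid size without pooling away spatial detail.
# The rearranged scales and the stage-4 activations are each mapped to a
# common channel width by a further 1x1 unit and concatenated.

#' Split a feature map into stage-4-sized spatial chunks
#'
#' Partitions an `(h, w, C, N)` activation array into `(h/target_h) *
#' (w/target_w)` non-overlapping tiles of spatial size `target_h x target_w`,
#' in row-major order (row index outer, column index inner). The tiles cover
#' the map exactly once.
#'
#' @param x numeric array with dim `(h, w, C, N)`
#' @param target_h,target_w chunk spatial size; must divide `h` and `w`
#' @return an object of class `chunk_grid`: a list with `chunks` (list of
#'   `(target_h, target_w, C, N)` arrays), `grid_rows`, `grid_cols`
#' @export
spatial_split <- function(x, target_h, target_w) {
  d <- tdim(x)
  if (d[1] %% target_h != 0L || d[2] %% target_w != 0L) {
    stop(sprintf("spatial size %dx%d not divisible by chunk size %dx%d",
                 d[1], d[2], target_h, target_w))
  }
  gr <- d[1] %/% target_h
  gc <- d[2] %/% target_w
  chunks <- vector("list", gr * gc)
  for (m in seq_len(gr)) {
    rows <- ((m - 1L) * target_h + 1L):(m * target_h)
    for (n in seq_len(gc)) {
      cols <- ((n - 1L) * target_w + 1L):(n * target_w)
      chunks[[(m - 1L) * gc + n]] <- x[rows, cols, , , drop = FALSE]
    }
  }
  structure(list(chunks = chunks, grid_rows = gr, grid_cols = gc,
                 target_h = as.integer(target_h), target_w = as.integer(target_w)),
            class = "chunk_grid")
}

#' Concatenate a chunk grid channel-wise
#'
#' Stacks the chunks of a [spatial_split()] result along the channel axis in
#' their row-major order, so channel block `j` (of the original channel width)
#' equals chunk `j`.
#'
#' @param grid a `chunk_grid`
#' @return numeric array `(target_h, target_w, C * k, N)` with `k` the chunk count
#' @export
chunk_concat <- function(grid) {
  stopifnot(inherits(grid, "chunk_grid"))
  d1 <- dim(grid$chunks[[1]])
  for (ch in grid$chunks) {
    if (!identical(dim(ch), d1)) stop("inconsistent chunk shapes")
  }
  k <- length(grid$chunks)
  out <- array(0, dim = c(d1[1], d1[2], d1[3] * k, d1[4]))
  for (j in seq_len(k)) {
    out[, , ((j - 1L) * d1[3] + 1L):(j * d1[3]), ] <- grid$chunks[[j]]
  }
  out
}

#' Inverse of the split-and-concatenate rearrangement
#'
#' Scatters the channel blocks of a rearranged array back to their original
#' spatial positions, reconstructing the pre-split map exactly.
#'
#' @param y numeric array `(target_h, target_w, C * k, N)`
#' @param grid_rows,grid_cols chunk grid shape
#' @return numeric array `(target_h * grid_rows, target_w * grid_cols, C, N)`
#' @export
chunk_unsplit <- function(y, grid_rows, grid_cols) {
  d <- tdim(y)
  k <- grid_rows * grid_cols
  stopifnot(d[3] %% k == 0L)
  C <- d[3] %/% k
  out <- array(0, dim = c(d[1] * grid_rows, d[2] * grid_cols, C, d[4]))
  for (m in seq_len(grid_rows)) {
    rows <- ((m - 1L) * d[1] + 1L):(m * d[1])
    for (n in seq_len(grid_cols)) {
      j <- (m - 1L) * grid_cols + n
      cols <- ((n - 1L) * d[2] + 1L):(n * d[2])
      out[rows, cols, , ] <- y[, , ((j - 1L) * C + 1L):(j * C), , drop = FALSE]
    }
  }
  out
}

# space-to-depth as one call (used in the module forward/backward)
sir_rearrange <- function(x, target_h, target_w) {
  chunk_concat(spatial_split(x, target_h, target_w))
}

# ---- SIR module -------------------------------------------------------------

# o_channels: per-scale rescale widths for scales 1..3 (reference 16/32/64);
# sir_channels: common width after the final per-scale 1x1 unit (reference 128).
sir_new <- function(stage_channels, o_channels = c(16L, 32L, 64L),
                    sir_channels = 128L) {
  stopifnot(length(stage_channels) == 4L, length(o_channels) == 3L)
  rescale <- lapply(1:3, function(i) {
    conv_unit_new(stage_channels[i], o_channels[i], 1L, 0L)
  })
  # after rearrangement, scale i carries o_channels[i] * k_i channels with
  # k = 64, 16, 4 for the /4, /8, /16 strides
  k <- c(64L, 16L, 4L)
  to_common <- lapply(1:3, function(i) {
    conv_unit_new(o_channels[i] * k[i], sir_channels, 1L, 0L)
  })
  to_common[[4]] <- conv_unit_new(stage_channels[4], sir_channels, 1L, 0L)
  new_layer("nn_sir", rescale = rescale, to_common = to_common,
            o_channels = as.integer(o_channels),
            sir_channels = as.integer(sir_channels), cache = NULL)
}

#' @export
nn_params.nn_sir <- function(layer) {
  do.call(c, lapply(c(layer$rescale, layer$to_common), nn_params))
}

# stages: list s1..s4 from backbone_forward
sir_forward <- function(sir, stages, training = FALSE) {
  d4 <- tdim(stages$s4)
  th <- d4[1]; tw <- d4[2]
  feats <- vector("list", 4L)
  grids <- vector("list", 3L)
  for (i in 1:3) {
    r <- nn_forward(sir$rescale[[i]], stages[[i]], training)
    dr <- tdim(r)
    grids[[i]] <- c(dr[1] %/% th, dr[2] %/% tw)
    y <- sir_rearrange(r, th, tw)
    feats[[i]] <- nn_forward(sir$to_common[[i]], y, training)
  }
  feats[[4]] <- nn_forward(sir$to_common[[4]], stages$s4, training)
  out <- array(0, dim = c(th, tw, 4L * sir$sir_channels, d4[4]))
  for (i in 1:4) {
    out[, , ((i - 1L) * sir$sir_channels + 1L):(i * sir$sir_channels), ] <- feats[[i]]
  }
  sir$cache <- if (training) list(grids = grids, th = th, tw = tw) else NULL
  out
}

#' @export
nn_forward.nn_sir <- function(layer, x, training = FALSE) {
  sir_forward(layer, x, training)
}

# returns list of gradients w.r.t. the four stage activations
sir_backward <- function(sir, dout) {
  cc <- sir$cache
  if (is.null(cc)) stop("sir: no cached forward pass")
  sc <- sir$sir_channels
  grads <- list()
  for (i in 1:4) {
    dfi <- dout[, , ((i - 1L) * sc + 1L):(i * sc), , drop = FALSE]
    dyi <- nn_backward(sir$to_common[[i]], dfi)
    if (i == 4L) {
      grads$s4 <- dyi
    } else {
      dri <- chunk_unsplit(dyi, cc$grids[[i]][1], cc$grids[[i]][2])
      grads[[paste0("s", i)]] <- nn_backward(sir$rescale[[i]], dri)
    }
  }
  grads
}

# ---- user-facing extraction -------------------------------------------------

#' Extract the four backbone stage activations
#'
#' Runs the residual backbone in inference mode and returns the stage
#' activations `s1..s4` with spatial strides /4, /8, /16, /32 of the input
#' side. At the reference width the channel counts are 256, 512, 1024, 2048.
#'
#' @param model an `iqa_model`
#' @param x image batch `(S, S, 3, N)`, side divisible by 32
#' @return named list of activation arrays `s1`, `s2`, `s3`, `s4`
#' @export
extract_multiscale <- function(model, x) {
  stopifnot(inherits(model, "iqa_model"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  backbone_forward(model$backbone, x, training = FALSE)
}

#' Extract the spatial-information-retained multi-scale feature
#'
#' Composition of channel rescale, spatial split, channel-wise chunk
#' concatenation and the per-scale mapping to a common width, concatenated
#' over scales 1-4: an `(S/32, S/32)` grid carrying `4 * sir_channels`
#' channels (512 at the reference width).
#'
#' @inheritParams extract_multiscale
#' @return numeric array `(S/32, S/32, 4 * sir_channels, N)`
#' @export
sir_extract <- function(model, x) {
  stopifnot(inherits(model, "iqa_model"))
  if (is.null(model$sir)) {
    stop("variant ", model$variant, " has no multi-scale extractor (+MS variants only)")
  }
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  sir_forward(model$sir, backbone_forward(model$backbone, x, training = FALSE),
              training = FALSE)
}

# ---- reference implementation ----------------------------------------------

# Naive per-position loop implementation of the full extractor, sharing the
# trained parameters but avoiding every vectorized rearrangement and GEMM.
# Used as an independent validation path for the vectorized module
# (eval mode: batch norm uses running statistics).
sir_extract_reference <- function(backbone, sir, x) {
  stages <- backbone_forward(backbone, x, training = FALSE)
  d4 <- dim(stages$s4)
  th <- d4[1]; tw <- d4[2]; N <- d4[4]
  sc <- sir$sir_channels
  out <- array(0, dim = c(th, tw, 4L * sc, N))

  conv_unit_ref <- function(unit, x) {
    conv <- unit$layers[[1]]; bn <- unit$layers[[2]]
    d <- dim(x)
    co <- conv$cout
    y <- array(0, dim = c(d[1], d[2], co, d[4]))
    for (n in seq_len(d[4])) for (w in seq_len(d[2])) for (h in seq_len(d[1])) {
      v <- x[h, w, , n]
      for (o in seq_len(co)) {
        acc <- 0
        for (ci in seq_len(d[3])) acc <- acc + v[ci] * conv$W[1, 1, ci, o]
        y[h, w, o, n] <- acc
      }
    }
    for (o in seq_len(co)) {
      z <- (y[, , o, , drop = FALSE] - bn$running_mean[o]) /
        sqrt(bn$running_var[o] + bn$eps)
      z <- bn$gamma[o] * z + bn$beta[o]
      y[, , o, ] <- ifelse(z > 0, z, 0)
    }
    y
  }

  for (i in 1:3) {
    r <- conv_unit_ref(sir$rescale[[i]], stages[[i]])
    dr <- dim(r)
    gr <- dr[1] %/% th; gc <- dr[2] %/% tw
    C <- dr[3]
    y <- array(0, dim = c(th, tw, C * gr * gc, N))
    for (m in seq_len(gr)) for (n2 in seq_len(gc)) for (cc in seq_len(C)) {
      j <- (m - 1L) * gc + n2
      for (hh in seq_len(th)) for (ww in seq_len(tw)) {
        y[hh, ww, (j - 1L) * C + cc, ] <- r[(m - 1L) * th + hh, (n2 - 1L) * tw + ww, cc, ]
      }
    }
    f <- conv_unit_ref(sir$to_common[[i]], y)
    out[, , ((i - 1L) * sc + 1L):(i * sc), ] <- f
  }
  out[, , (3L * sc + 1L):(4L * sc), ] <- conv_unit_ref(sir$to_common[[4]], stages$s4)
  out
}
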