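# Attention modules and the aggregation head.

# ---- spatial attention ------------------------------------------------------

# Stacked conv(3x3)-BN-ReLU blocks narrowing the channel width, then a 1x1
# convolution to a single channel squashed through a sigmoid: a spatial
# weighting map in [0,1] broadcast across channels.
spatial_attention_new <- function(cin, widths = c(128L, 64L, 32L)) {
  layers <- list()
  c_prev <- cin
  for (w in widths) {
    layers <- c(layers, list(conv_unit_new(c_prev, w, 3L, 1L)))
    c_prev <- w
  }
  layers <- c(layers, list(conv2d_new(c_prev, 1L, 1L), sigmoid_new()))
  new_layer("nn_spatial_attention", net = sequential_new(layers), cin = as.integer(cin))
}

#' @export
nn_params.nn_spatial_attention <- function(layer) nn_params(layer$net)

#' @export
nn_forward.nn_spatial_attention <- function(layer, x, training = FALSE) {
  nn_forward(layer$net, x, training)            # (H, W, 1, N)
}

#' @export
nn_backward.nn_spatial_attention <- function(layer, dout) {
  nn_backward(layer$net, dout)
}

# ---- self-attention ---------------------------------------------------------

# Non-local block: scaled dot-product attention over the spatial positions
# (1x1 query/key/value projections, softmax over key positions, output
# projection, residual add). Permutation-equivariant: no positional encoding.
self_attention_new <- function(cin, dk = NULL, dv = NULL) {
  dk <- dk %||% max(1L, cin %/% 8L)
  dv <- dv %||% max(1L, cin %/% 2L)
  sd <- sqrt(1 / cin)
  new_layer("nn_self_attention",
            Wq = matrix(stats::rnorm(cin * dk, sd = sd), cin, dk),
            Wk = matrix(stats::rnorm(cin * dk, sd = sd), cin, dk),
            Wv = matrix(stats::rnorm(cin * dv, sd = sd), cin, dv),
            Wz = matrix(stats::rnorm(dv * cin, sd = sqrt(1 / dv)), dv, cin),
            cin = as.integer(cin), dk = as.integer(dk), dv = as.integer(dv),
            uniform_attention = FALSE, use_residual = TRUE,
            identity_value = FALSE, cache = NULL)
}

#' @export
nn_params.nn_self_attention <- function(layer) {
  lapply(c("Wq", "Wk", "Wv", "Wz"),
         function(nm) list(env = layer, name = nm, group = "new"))
}

.softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1, max))
  m / rowSums(m)
}

#' @export
nn_forward.nn_self_attention <- function(layer, x, training = FALSE) {
  d <- tdim(x)
  stopifnot(d[3] == layer$cin)
  P <- d[1] * d[2]
  out <- array(0, dim = d)
  caches <- if (training) vector("list", d[4]) else NULL
  for (n in seq_len(d[4])) {
    X <- matrix(x[, , , n], nrow = P)            # P x C (h fastest, then w)
    if (layer$uniform_attention) {
      A <- matrix(1 / P, P, P)
    } else {
      Q <- X %*% layer$Wq
      K <- X %*% layer$Wk
      A <- .softmax_rows(tcrossprod(Q, K) / sqrt(layer$dk))
    }
    V <- if (layer$identity_value) X else X %*% layer$Wv
    Z <- A %*% V
    Y <- if (layer$identity_value) Z else Z %*% layer$Wz
    if (layer$use_residual) Y <- Y + X
    out[, , , n] <- array(Y, dim = c(d[1], d[2], d[3]))
    if (training) caches[[n]] <- list(X = X, A = A, V = V, Z = Z,
                                      Q = if (layer$uniform_attention) NULL else Q,
                                      K = if (layer$uniform_attention) NULL else K)
  }
  layer$cache <- if (training) list(d = d, caches = caches) else NULL
  out
}

#' @export
nn_backward.nn_self_attention <- function(layer, dout) {
  cc <- layer$cache
  if (is.null(cc)) stop("self_attention: no cached forward pass")
  d <- cc$d
  P <- d[1] * d[2]
  dx <- array(0, dim = d)
  for (n in seq_len(d[4])) {
    s <- cc$caches[[n]]
    dY <- matrix(dout[, , , n], nrow = P)
    dX <- if (layer$use_residual) dY else matrix(0, P, d[3])
    if (layer$identity_value) {
      dZ <- dY
    } else {
      add_grad(layer, "Wz", crossprod(s$Z, dY))
      dZ <- dY %*% t(layer$Wz)
    }
    dA <- tcrossprod(dZ, s$V)
    dV <- crossprod(s$A, dZ)
    if (layer$identity_value) {
      dX <- dX + dV
    } else {
      add_grad(layer, "Wv", crossprod(s$X, dV))
      dX <- dX + dV %*% t(layer$Wv)
    }
    if (!layer$uniform_attention) {
      dS <- s$A * (dA - rowSums(dA * s$A))       # softmax jacobian, row-wise
      scale <- 1 / sqrt(layer$dk)
      dQ <- (dS %*% s$K) * scale
      dK <- (crossprod(dS, s$Q)) * scale
      add_grad(layer, "Wq", crossprod(s$X, dQ))
      add_grad(layer, "Wk", crossprod(s$X, dK))
      dX <- dX + dQ %*% t(layer$Wq) + dK %*% t(layer$Wk)
    }
    dx[, , , n] <- array(dX, dim = c(d[1], d[2], d[3]))
  }
  dx
}

# ---- mask gating ------------------------------------------------------------

#' Gate a feature map with a (downsampled) eye-area mask
#'
#' Downsamples a binary eye mask to the feature grid by block averaging,
#' binarizes at 0.5, and multiplies the feature elementwise, so activations
#' outside the eye area do not contribute to the pooled prediction.
#'
#' @param feature numeric array `(h, w, C, N)`
#' @param mask binary matrix whose side is a multiple of the feature side
#' @return the gated feature, same shape
#' @export
apply_mask <- function(feature, mask) {
  d <- tdim(feature)
  md <- downsample_mask(mask, d[1], d[2])
  feature * as.vector(md)                        # recycles over C, N
}

# area-average then binarize at 0.5
downsample_mask <- function(mask, th, tw) {
  stopifnot(is.matrix(mask))
  if (nrow(mask) %% th != 0L || ncol(mask) %% tw != 0L) {
    stop(sprintf("mask %dx%d not reducible to %dx%d",
                 nrow(mask), ncol(mask), th, tw))
  }
  fh <- nrow(mask) %/% th
  fw <- ncol(mask) %/% tw
  pooled <- matrix(0, th, tw)
  for (i in seq_len(th)) {
    for (j in seq_len(tw)) {
      pooled[i, j] <- mean(mask[((i - 1) * fh + 1):(i * fh),
                                ((j - 1) * fw + 1):(j * fw)])
    }
  }
  (pooled >= 0.5) * 1
}

# ---- aggregation head -------------------------------------------------------

# GAP -> fully connected stack (hidden width 128 by default) -> scalar logit.
head_new <- function(cin, hidden = 128L) {
  new_layer("nn_head",
            gap = gap_new(),
            fc1 = linear_new(cin, hidden),
            relu = relu_vec_new(),
            fc2 = linear_new(hidden, 1L),
            cin = as.integer(cin))
}

#' @export
nn_params.nn_head <- function(layer) {
  c(nn_params(layer$fc1), nn_params(layer$fc2))
}

#' @export
nn_forward.nn_head <- function(layer, x, training = FALSE) {
  h <- nn_forward(layer$gap, x, training)
  h <- nn_forward(layer$fc1, h, training)
  h <- nn_forward(layer$relu, h, training)
  drop(nn_forward(layer$fc2, h, training))       # length-N logits
}

#' @export
nn_backward.nn_head <- function(layer, dout) {
  g <- nn_backward(layer$fc2, matrix(dout, ncol = 1L))
  g <- nn_backward(layer$relu, g)
  g <- nn_backward(layer$fc1, g)
  nn_backward(layer$gap, g)
}

# ---- loss -------------------------------------------------------------------

#' Binary cross-entropy on logits
#'
#' Mean binary cross-entropy of `sigmoid(logit)` against 0/1 labels, computed
#' in the numerically stable logit form
#' `max(z, 0) - z * q + log(1 + exp(-|z|))`.
#'
#' @param logits numeric vector of raw scores
#' @param labels 0/1 vector, 1 = good quality
#' @return scalar loss (nonnegative)
#' @export
bce_loss <- function(logits, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  stopifnot(length(logits) == length(labels))
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

# gradient of mean BCE w.r.t. logits
bce_grad <- function(logits, labels) {
  (1 / (1 + exp(-logits)) - labels) / length(logits)
}
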