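# Minimal define-and-run neural-network kernel used by the quality models.
#
# Tensors are numeric arrays with dim (H, W, C, N). Layers are environments
# carrying parameters, gradients (g_<name>) and forward caches; composite
# modules implement the same three generics, so a whole model is just a layer.
# Convolutions are lowered to GEMM through im2col (src/conv_ops.cpp).

nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")
nn_backward <- function(layer, dout) UseMethod("nn_backward")

#' @export
print.nn_layer <- function(x, ...) {
  np <- sum(vapply(nn_params(x), function(p) length(p$env[[p$name]]), numeric(1)))
  cat(sprintf("<%s> %s parameters\n", class(x)[1], format(np, big.mark = ",")))
  invisible(x)
}

# Parameter descriptors: list(env = <layer env>, name = "W", group = "new").
nn_params <- function(layer) UseMethod("nn_params")

#' Count trainable parameters of a layer or model
#' @param layer a layer or model built by this package
#' @return integer number of scalar trainable parameters
#' @export
n_parameters <- function(layer) {
  sum(vapply(nn_params(layer), function(p) length(p$env[[p$name]]), numeric(1)))
}

new_layer <- function(.class, ...) {
  e <- new.env(parent = emptyenv())
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  class(e) <- c(.class, "nn_layer")
  e
}

zero_grads <- function(layer) {
  for (p in nn_params(layer)) {
    g <- paste0("g_", p$name)
    p$env[[g]] <- array(0, dim = dim(p$env[[p$name]]) %||% length(p$env[[p$name]]))
  }
  invisible(layer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

add_grad <- function(env, name, g) {
  gn <- paste0("g_", name)
  cur <- env[[gn]]
  env[[gn]] <- if (is.null(cur)) g else cur + g
}

tdim <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

# ---- convolution ------------------------------------------------------------

conv2d_new <- function(cin, cout, k, stride = 1L, pad = 0L, bias = TRUE,
                       group = "new") {
  fan_in <- k * k * cin
  W <- array(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
             dim = c(k, k, cin, cout))
  new_layer("nn_conv2d",
            W = W, b = if (bias) numeric(cout) else NULL,
            k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), cin = as.integer(cin),
            cout = as.integer(cout), group = group, cache = NULL)
}

#' @export
nn_params.nn_conv2d <- function(layer) {
  ps <- list(list(env = layer, name = "W", group = layer$group))
  if (!is.null(layer$b)) ps <- c(ps, list(list(env = layer, name = "b", group = layer$group)))
  ps
}

#' @export
nn_forward.nn_conv2d <- function(layer, x, training = FALSE) {
  d <- tdim(x)
  stopifnot(d[3] == layer$cin)
  cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], layer$k, layer$k,
                     layer$stride, layer$pad)
  oh <- (d[1] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  ow <- (d[2] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  Wm <- matrix(layer$W, nrow = layer$k * layer$k * layer$cin, ncol = layer$cout)
  out <- crossprod(Wm, cols)                    # cout x (oh*ow*N)
  if (!is.null(layer$b)) out <- out + layer$b
  out <- aperm(array(out, dim = c(layer$cout, oh, ow, d[4])), c(2, 3, 1, 4))
  layer$cache <- if (training) list(cols = cols, din = d, oh = oh, ow = ow) else NULL
  out
}

#' @export
nn_backward.nn_conv2d <- function(layer, dout) {
  cc <- layer$cache
  if (is.null(cc)) stop("conv2d: no cached forward pass (run with training = TRUE)")
  d <- cc$din
  dm <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = layer$cout)  # cout x J
  add_grad(layer, "W",
           array(cc$cols %*% t(dm), dim = dim(layer$W)))
  if (!is.null(layer$b)) add_grad(layer, "b", rowSums(dm))
  Wm <- matrix(layer$W, nrow = layer$k * layer$k * layer$cin, ncol = layer$cout)
  dcols <- Wm %*% dm
  col2im_cpp(dcols, d[1], d[2], d[3], d[4], layer$k, layer$k,
             layer$stride, layer$pad)
}

# ---- batch normalization ----------------------------------------------------

batchnorm2d_new <- function(nc, eps = 1e-5, momentum = 0.1, group = "new") {
  new_layer("nn_batchnorm2d",
            gamma = rep(1, nc), beta = numeric(nc),
            running_mean = numeric(nc), running_var = rep(1, nc),
            nc = as.integer(nc), eps = eps, momentum = momentum,
            group = group, cache = NULL)
}

#' @export
nn_params.nn_batchnorm2d <- function(layer) {
  list(list(env = layer, name = "gamma", group = layer$group),
       list(env = layer, name = "beta", group = layer$group))
}

# view (H,W,C,N) as (H*W*N) x C matrix and back
.bn_tomat <- function(x, d) {
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}
.bn_toarr <- function(m, d) {
  aperm(array(m, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

#' @export
nn_forward.nn_batchnorm2d <- function(layer, x, training = FALSE) {
  d <- tdim(x)
  stopifnot(d[3] == layer$nc)
  m <- .bn_tomat(x, d)
  if (training) {
    mu <- colMeans(m)
    ctr <- sweep(m, 2, mu)
    va <- colMeans(ctr^2)                      # biased, used for normalization
    n <- nrow(m)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * va * n / max(n - 1, 1)  # unbiased for running stats
    invstd <- 1 / sqrt(va + layer$eps)
    xhat <- sweep(ctr, 2, invstd, `*`)
    layer$cache <- list(xhat = xhat, invstd = invstd, d = d)
  } else {
    invstd <- 1 / sqrt(layer$running_var + layer$eps)
    xhat <- sweep(sweep(m, 2, layer$running_mean), 2, invstd, `*`)
    layer$cache <- NULL
  }
  out <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
  .bn_toarr(out, d)
}

#' @export
nn_backward.nn_batchnorm2d <- function(layer, dout) {
  cc <- layer$cache
  if (is.null(cc)) stop("batchnorm2d: no cached forward pass")
  d <- cc$d
  dm <- .bn_tomat(dout, d)
  n <- nrow(dm)
  add_grad(layer, "gamma", colSums(dm * cc$xhat))
  add_grad(layer, "beta", colSums(dm))
  dxhat <- sweep(dm, 2, layer$gamma, `*`)
  # dX = invstd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cc$xhat)
  dx <- sweep(n * dxhat, 2, s1) - sweep(cc$xhat, 2, s2, `*`)
  dx <- sweep(dx, 2, cc$invstd / n, `*`)
  .bn_toarr(dx, d)
}

# ---- pointwise layers -------------------------------------------------------

relu_new <- function() new_layer("nn_relu", cache = NULL)

#' @export
nn_params.nn_relu <- function(layer) list()

#' @export
nn_forward.nn_relu <- function(layer, x, training = FALSE) {
  out <- pmax(x, 0)
  dim(out) <- dim(x)
  layer$cache <- if (training) (x > 0) else NULL
  out
}

#' @export
nn_backward.nn_relu <- function(layer, dout) {
  if (is.null(layer$cache)) stop("relu: no cached forward pass")
  dout * layer$cache
}

sigmoid_new <- function() new_layer("nn_sigmoid", cache = NULL)

#' @export
nn_params.nn_sigmoid <- function(layer) list()

#' @export
nn_forward.nn_sigmoid <- function(layer, x, training = FALSE) {
  out <- 1 / (1 + exp(-x))
  layer$cache <- if (training) out else NULL
  out
}

#' @export
nn_backward.nn_sigmoid <- function(layer, dout) {
  s <- layer$cache
  if (is.null(s)) stop("sigmoid: no cached forward pass")
  dout * s * (1 - s)
}

maxpool_new <- function(k = 3L, stride = 2L, pad = 1L) {
  new_layer("nn_maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), cache = NULL)
}

#' @export
nn_params.nn_maxpool <- function(layer) list()

#' @export
nn_forward.nn_maxpool <- function(layer, x, training = FALSE) {
  d <- tdim(x)
  r <- maxpool_fwd_cpp(x, d[1], d[2], d[3], d[4], layer$k, layer$stride, layer$pad)
  layer$cache <- if (training) list(argmax = r$argmax, din = d) else NULL
  r$out
}

#' @export
nn_backward.nn_maxpool <- function(layer, dout) {
  cc <- layer$cache
  if (is.null(cc)) stop("maxpool: no cached forward pass")
  d <- cc$din
  maxpool_bwd_cpp(dout, cc$argmax, d[1], d[2], d[3], d[4])
}

# ---- dense layers on (N x F) matrices --------------------------------------

linear_new <- function(fin, fout, group = "new") {
  W <- matrix(stats::rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout)
  new_layer("nn_linear", W = W, b = numeric(fout),
            fin = as.integer(fin), fout = as.integer(fout),
            group = group, cache = NULL)
}

#' @export
nn_params.nn_linear <- function(layer) {
  list(list(env = layer, name = "W", group = layer$group),
       list(env = layer, name = "b", group = layer$group))
}

#' @export
nn_forward.nn_linear <- function(layer, x, training = FALSE) {
  stopifnot(is.matrix(x), ncol(x) == layer$fin)
  layer$cache <- if (training) x else NULL
  sweep(x %*% layer$W, 2, layer$b, `+`)
}

#' @export
nn_backward.nn_linear <- function(layer, dout) {
  x <- layer$cache
  if (is.null(x)) stop("linear: no cached forward pass")
  add_grad(layer, "W", crossprod(x, dout))
  add_grad(layer, "b", colSums(dout))
  dout %*% t(layer$W)
}

relu_vec_new <- function() new_layer("nn_relu_vec", cache = NULL)

#' @export
nn_params.nn_relu_vec <- function(layer) list()

#' @export
nn_forward.nn_relu_vec <- function(layer, x, training = FALSE) {
  layer$cache <- if (training) (x > 0) else NULL
  pmax(x, 0)
}

#' @export
nn_backward.nn_relu_vec <- function(layer, dout) {
  if (is.null(layer$cache)) stop("relu: no cached forward pass")
  dout * layer$cache
}

# Global average pooling: (H,W,C,N) -> (N x C)
gap_new <- function() new_layer("nn_gap", cache = NULL)

#' @export
nn_params.nn_gap <- function(layer) list()

#' @export
nn_forward.nn_gap <- function(layer, x, training = FALSE) {
  d <- tdim(x)
  layer$cache <- d
  m <- matrix(x, nrow = d[1] * d[2])            # (H*W) x (C*N)
  t(matrix(colMeans(m), d[3], d[4]))            # N x C
}

#' @export
nn_backward.nn_gap <- function(layer, dout) {
  d <- layer$cache
  if (is.null(d)) stop("gap: no cached forward pass")
  per <- t(dout) / (d[1] * d[2])                # C x N
  array(rep(as.vector(per), each = d[1] * d[2]), dim = d)
}

# ---- composition ------------------------------------------------------------

sequential_new <- function(layers) new_layer("nn_sequential", layers = layers)

#' @export
nn_params.nn_sequential <- function(layer) {
  do.call(c, lapply(layer$layers, nn_params))
}

#' @export
nn_forward.nn_sequential <- function(layer, x, training = FALSE) {
  for (l in layer$layers) x <- nn_forward(l, x, training)
  x
}

#' @export
nn_backward.nn_sequential <- function(layer, dout) {
  for (l in rev(layer$layers)) dout <- nn_backward(l, dout)
  dout
}

# conv(k) -> BN -> ReLU, the standard rescaling unit
conv_unit_new <- function(cin, cout, k, pad, stride = 1L, group = "new") {
  sequential_new(list(
    conv2d_new(cin, cout, k, stride = stride, pad = pad, bias = FALSE, group = group),
    batchnorm2d_new(cout, group = group),
    relu_new()
  ))
}

# ---- optimizer --------------------------------------------------------------

# Adam with L2 weight decay added to the gradient and per-group learning rates
# (the backbone group trains at one tenth of the rate of newly added layers).
adam_new <- function(model, lr = c(backbone = 1e-4, new = 1e-3),
                     weight_decay = 5e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  params <- nn_params(model)
  state <- lapply(params, function(p) {
    n <- length(p$env[[p$name]])
    list(m = numeric(n), v = numeric(n))
  })
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$state <- state
  e$lr <- lr
  e$weight_decay <- weight_decay
  e$beta1 <- beta1
  e$beta2 <- beta2
  e$eps <- eps
  e$t <- 0L
  class(e) <- "nn_adam"
  e
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    theta <- p$env[[p$name]]
    g <- p$env[[paste0("g_", p$name)]]
    if (is.null(g)) next
    g <- as.vector(g) + opt$weight_decay * as.vector(theta)
    st <- opt$state[[i]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    opt$state[[i]] <- st
    lr <- opt$lr[[p$group %||% "new"]] %||% opt$lr[["new"]]
    upd <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
    new_theta <- theta - upd
    dim(new_theta) <- dim(theta)
    p$env[[p$name]] <- new_theta
  }
  invisible(opt)
}

# ---- (de)serialization of parameters ---------------------------------------

# Includes batch-norm running statistics so a restored model is inference-ready.
model_state <- function(model) {
  ps <- nn_params(model)
  st <- vector("list", 0)
  seen <- new.env(parent = emptyenv())
  k <- 0L
  for (p in ps) {
    k <- k + 1L
    st[[sprintf("p%03d_%s", k, p$name)]] <- p$env[[p$name]]
    id <- format.default(p$env)
    if (!is.null(p$env$running_mean) && is.null(seen[[id]])) {
      assign(id, TRUE, envir = seen)
      st[[sprintf("p%03d_running_mean", k)]] <- p$env$running_mean
      st[[sprintf("p%03d_running_var", k)]] <- p$env$running_var
    }
  }
  st
}

restore_model_state <- function(model, state) {
  ps <- nn_params(model)
  k <- 0L
  seen <- new.env(parent = emptyenv())
  for (p in ps) {
    k <- k + 1L
    nm <- sprintf("p%03d_%s", k, p$name)
    if (is.null(state[[nm]])) stop("checkpoint state does not match model layout")
    p$env[[p$name]] <- state[[nm]]
    id <- format.default(p$env)
    rm_nm <- sprintf("p%03d_running_mean", k)
    if (!is.null(state[[rm_nm]]) && is.null(seen[[id]])) {
      assign(id, TRUE, envir = seen)
      p$env$running_mean <- state[[rm_nm]]
      p$env$running_var <- state[[sprintf("p%03d_running_var", k)]]
    }
  }
  invisible(model)
}
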