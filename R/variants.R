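# Model variants: baseline and attention/multi-scale configurations.

#' Model variant names
#'
#' The five supported architectures, from the plain baseline to the
#' attention-weighted multi-scale models:
#' \describe{
#'   \item{BL}{stage-4 backbone feature -> GAP -> fully connected head}
#'   \item{BL+MASK}{stage-4 feature gated by the eye-area mask -> GAP -> head}
#'   \item{BL+SpatialAtt}{stage-4 feature weighted by a learned spatial
#'     attention map -> GAP -> head}
#'   \item{BL+SpatialAtt+MS}{multi-scale (SIR) feature weighted by spatial
#'     attention -> GAP -> head}
#'   \item{BL+SelfAtt+MS}{multi-scale (SIR) feature weighted by a non-local
#'     self-attention block -> GAP -> head}
#' }
#' @export
MODEL_VARIANTS <- c("BL", "BL+MASK", "BL+SpatialAtt",
                    "BL+SpatialAtt+MS", "BL+SelfAtt+MS")

#' Model architecture configuration
#'
#' Collects the width hyperparameters of the network. The reference
#' configuration matches a 50-layer residual backbone (stage channels
#' 256/512/1024/2048), per-scale rescale widths 16/32/64, a common
#' multi-scale width of 128 (so the concatenated feature carries 128*4 = 512
#' channels), spatial-attention widths 128/64/32 and a 128-wide hidden layer
#' in the head. `reduced_model_config()` shrinks every width for desk-scale
#' CPU experiments while preserving all stride geometry and contracts.
#'
#' @param width backbone stem width (stage outputs are 4*width*2^(0:3))
#' @param blocks bottleneck blocks per stage
#' @param o_channels per-scale channel rescale widths (scales 1-3)
#' @param sir_channels common width of each scale after the final 1x1 unit
#' @param att_widths spatial-attention block widths
#' @param head_hidden hidden width of the fully connected head
#' @param threshold decision threshold on the predicted probability
#' @return a `model_config` list
#' @export
model_config <- function(width = 64L, blocks = c(3L, 4L, 6L, 3L),
                         o_channels = c(16L, 32L, 64L), sir_channels = 128L,
                         att_widths = c(128L, 64L, 32L), head_hidden = 128L,
                         threshold = 0.5) {
  structure(list(width = as.integer(width), blocks = as.integer(blocks),
                 o_channels = as.integer(o_channels),
                 sir_channels = as.integer(sir_channels),
                 att_widths = as.integer(att_widths),
                 head_hidden = as.integer(head_hidden),
                 threshold = threshold),
            class = "model_config")
}

#' @rdname model_config
#' @export
reduced_model_config <- function(width = 8L, blocks = c(1L, 1L, 1L, 1L),
                                 o_channels = c(4L, 8L, 16L), sir_channels = 16L,
                                 att_widths = c(16L, 8L), head_hidden = 32L,
                                 threshold = 0.5) {
  model_config(width, blocks, o_channels, sir_channels, att_widths,
               head_hidden, threshold)
}

#' Build a quality-classification model
#'
#' Wires one of the five [MODEL_VARIANTS]. The multi-scale (`+MS`) variants
#' aggregate the spatial-information-retained feature weighted elementwise by
#' the attention module output; `BL+MASK` gates the stage-4 feature with the
#' eye-area mask; `BL` pools the stage-4 feature directly.
#'
#' @param variant one of [MODEL_VARIANTS]
#' @param config a [model_config()]; defaults to the reference widths
#' @param seed optional integer seed for weight initialization
#' @return an `iqa_model` object
#' @export
build_variant <- function(variant, config = model_config(), seed = NULL) {
  if (!is.character(variant) || length(variant) != 1L ||
      !(variant %in% MODEL_VARIANTS)) {
    stop("unknown variant '", paste(variant, collapse = ","),
         "'; valid variants: ", paste(MODEL_VARIANTS, collapse = ", "))
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  bb <- backbone_new(config$width, config$blocks)
  use_ms <- grepl("\\+MS$", variant)
  sir <- if (use_ms) sir_new(bb$stage_channels, config$o_channels,
                             config$sir_channels) else NULL
  feat_ch <- if (use_ms) 4L * config$sir_channels else bb$stage_channels[4]
  att <- switch(variant,
    "BL+SpatialAtt" = ,
    "BL+SpatialAtt+MS" = spatial_attention_new(feat_ch, config$att_widths),
    "BL+SelfAtt+MS" = self_attention_new(feat_ch),
    NULL)
  head <- head_new(feat_ch, config$head_hidden)
  new_layer("iqa_model",
            variant = variant, config = config, backbone = bb, sir = sir,
            att = att, head = head, uses_mask = identical(variant, "BL+MASK"),
            feat_ch = as.integer(feat_ch), cache = NULL)
}

#' @export
nn_params.iqa_model <- function(layer) {
  ps <- nn_params(layer$backbone)
  if (!is.null(layer$sir)) ps <- c(ps, nn_params(layer$sir))
  if (!is.null(layer$att)) ps <- c(ps, nn_params(layer$att))
  c(ps, nn_params(layer$head))
}

# x: (S, S, 3, N); masks: NULL or (S, S, N) array / list of matrices
model_forward <- function(model, x, masks = NULL, training = FALSE) {
  stages <- backbone_forward(model$backbone, x, training)
  use_ms <- !is.null(model$sir)
  feat <- if (use_ms) sir_forward(model$sir, stages, training) else stages$s4
  att_map <- NULL
  if (!is.null(model$att)) {
    att_map <- nn_forward(model$att, feat, training)
    if (inherits(model$att, "nn_spatial_attention")) {
      d <- dim(feat)
      gated <- feat * att_map[, , rep(1L, d[3]), , drop = FALSE]
    } else {
      gated <- feat * att_map
    }
  } else if (model$uses_mask) {
    if (is.null(masks)) stop("variant BL+MASK requires eye-area masks")
    d <- dim(feat)
    mexp <- array(0, dim = d)
    for (n in seq_len(d[4])) {
      mn <- if (is.list(masks)) masks[[n]] else masks[, , n]
      md <- downsample_mask(mn, d[1], d[2])
      mexp[, , , n] <- rep(as.vector(md), d[3])
    }
    gated <- feat * mexp
    att_map <- mexp
  } else {
    gated <- feat
  }
  logit <- nn_forward(model$head, gated, training)
  model$cache <- if (training) list(feat = feat, att_map = att_map) else NULL
  list(logit = logit, prob = 1 / (1 + exp(-logit)),
       feature = feat, attention = att_map, stages = if (training) NULL else stages)
}

model_backward <- function(model, dlogit) {
  cc <- model$cache
  if (is.null(cc)) stop("model: no cached forward pass")
  dgated <- nn_backward(model$head, dlogit)
  feat <- cc$feat
  d <- dim(feat)
  if (!is.null(model$att)) {
    if (inherits(model$att, "nn_spatial_attention")) {
      amap <- cc$att_map[, , rep(1L, d[3]), , drop = FALSE]
      dfeat1 <- dgated * amap
      datt <- apply(dgated * feat, c(1, 2, 4), sum)
      datt <- array(datt, dim = c(d[1], d[2], 1L, d[4]))
      dfeat2 <- nn_backward(model$att, datt)
    } else {
      dfeat1 <- dgated * cc$att_map
      datt <- dgated * feat
      dfeat2 <- nn_backward(model$att, datt)
    }
    dfeat <- dfeat1 + dfeat2
  } else if (model$uses_mask) {
    dfeat <- dgated * cc$att_map
  } else {
    dfeat <- dgated
  }
  if (!is.null(model$sir)) {
    grads <- sir_backward(model$sir, dfeat)
  } else {
    grads <- list(s4 = dfeat)
  }
  backbone_backward(model$backbone, grads)
  invisible(NULL)
}

#' Predict quality scores for a batch of canonical images
#'
#' Runs the model in inference mode and returns, per image, the raw logit,
#' the probability `sigmoid(logit)` and the 0/1 label obtained by strict
#' thresholding (`probability > threshold`; 1 = good quality).
#'
#' @param model an `iqa_model`
#' @param x numeric array `(S, S, 3, N)` of canonical images
#' @param masks eye masks (`(S, S, N)` array or list of matrices), required
#'   for the `BL+MASK` variant
#' @param threshold decision threshold; defaults to the model configuration
#' @return data.frame with columns `logit`, `probability`, `label`
#' @export
predict_quality <- function(model, x, masks = NULL, threshold = NULL) {
  stopifnot(inherits(model, "iqa_model"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  threshold <- threshold %||% model$config$threshold
  out <- model_forward(model, x, masks, training = FALSE)
  data.frame(logit = out$logit, probability = out$prob,
             label = binarize(out$prob, threshold))
}
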