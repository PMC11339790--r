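# Dataset splitting, the training loop, and checkpointing.

#' Training hyperparameters
#'
#' Defaults follow the study settings: minibatch size 8, Adam with learning
#' rate 1e-3 for newly added layers and one tenth of that (1e-4) for the
#' backbone, weight decay 5e-4, 20 epochs, decision threshold 0.5. The
#' backbone rate is derived from `lr_new / 10` and the 1:10 ratio is
#' enforced.
#'
#' @param batch_size minibatch size
#' @param lr_new learning rate of newly added layers
#' @param lr_backbone learning rate of backbone layers (must equal `lr_new/10`)
#' @param weight_decay L2 weight decay
#' @param epochs training epochs
#' @param threshold decision threshold
#' @param seed integer seed controlling shuffling
#' @return a `hyperparams` list
#' @export
hyperparams <- function(batch_size = 8L, lr_new = 1e-3,
                        lr_backbone = lr_new / 10, weight_decay = 5e-4,
                        epochs = 20L, threshold = 0.5, seed = 1L) {
  if (any(c(batch_size, lr_new, lr_backbone, weight_decay, epochs) <= 0)) {
    stop("all hyperparameters must be positive")
  }
  if (abs(lr_backbone - lr_new / 10) > 1e-12 * lr_new) {
    stop("lr_backbone must be lr_new / 10 (1:10 backbone:new ratio)")
  }
  structure(list(batch_size = as.integer(batch_size), lr_new = lr_new,
                 lr_backbone = lr_backbone, weight_decay = weight_decay,
                 epochs = as.integer(epochs), optimizer = "adam",
                 threshold = threshold, seed = as.integer(seed)),
            class = "hyperparams")
}

#' Stratified train/test split
#'
#' Randomly assigns a fixed fraction of each class to the training set, so
#' the per-class training fraction is within one sample of the target.
#'
#' @param labels 0/1 label vector (the stratification column)
#' @param fraction training fraction in (0, 1)
#' @param seed integer seed
#' @return list with disjoint, exhaustive `train` and `test` index vectors
#' @export
stratified_split <- function(labels, fraction = 0.8, seed = 1L) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be strictly between 0 and 1")
  }
  if (min(table(labels)) < 2L) stop("each class needs at least 2 members")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  train <- integer(0)
  for (cl in c(0, 1)) {
    idx <- which(labels == cl)
    n_tr <- round(length(idx) * fraction)
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # keep both sides nonempty
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train),
       fraction = fraction)
}

#' Stratified k-fold partition
#'
#' Assigns every sample to exactly one of `k` test folds with per-fold class
#' proportions within one sample of the global proportions.
#'
#' @param labels 0/1 label vector
#' @param k number of folds (default 5)
#' @param seed integer seed
#' @return list of `k` splits, each with `train` and `test` indices
#' @export
kfold_stratified <- function(labels, k = 5L, seed = 1L) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (min(table(labels)) < k) stop("each class needs at least k = ", k, " members")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in c(0, 1)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
}

# dataset: list(images = (S,S,3,N) array, labels = 0/1 length N,
#               masks = optional (S,S,N) array)
dataset_subset <- function(data, idx) {
  list(images = data$images[, , , idx, drop = FALSE],
       labels = data$labels[idx],
       masks = if (!is.null(data$masks)) data$masks[, , idx, drop = FALSE])
}

eval_model_on <- function(model, data, threshold, batch_size = 8L) {
  n <- length(data$labels)
  probs <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out <- model_forward(model,
                         data$images[, , , idx, drop = FALSE],
                         masks = if (!is.null(data$masks))
                           data$masks[, , idx, drop = FALSE],
                         training = FALSE)
    probs[idx] <- out$prob
  }
  probs
}

#' Train a quality model
#'
#' Minibatch Adam training with two parameter groups (backbone at one tenth
#' of the new-layer learning rate), binary cross-entropy on logits, and
#' per-epoch test evaluation. The returned checkpoint holds the parameters
#' of the epoch with the highest test accuracy; the reported accuracy is the
#' maximum over epochs.
#'
#' @param model an `iqa_model` from [build_variant()]
#' @param train_data,test_data lists with `images` (`(S,S,3,N)` array),
#'   `labels` (0/1), and optionally `masks`
#' @param hp a [hyperparams()] object
#' @param verbose print per-epoch progress
#' @return list with `checkpoint` (best-epoch model state), `history`
#'   (data.frame epoch/train_loss/test_accuracy), `best_epoch`, `accuracy`
#' @export
train_model <- function(model, train_data, test_data, hp = hyperparams(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "iqa_model"))
  n <- length(train_data$labels)
  if (n == 0L || length(test_data$labels) == 0L) stop("empty dataset")
  if (!all(train_data$labels %in% c(0, 1))) stop("labels must be binary 0/1")
  opt <- adam_new(model, lr = c(backbone = hp$lr_backbone, new = hp$lr_new),
                  weight_decay = hp$weight_decay)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(hp$seed)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        test_accuracy = numeric(0))
  best_acc <- -Inf
  best_state <- NULL
  best_epoch <- NA_integer_
  for (epoch in seq_len(hp$epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = hp$batch_size)) {
      idx <- ord[start:min(start + hp$batch_size - 1L, n)]
      xb <- train_data$images[, , , idx, drop = FALSE]
      yb <- train_data$labels[idx]
      mb <- if (!is.null(train_data$masks))
        train_data$masks[, , idx, drop = FALSE]
      out <- model_forward(model, xb, masks = mb, training = TRUE)
      loss <- bce_loss(out$logit, yb)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite loss at epoch %d (loss = %s); aborting",
                     epoch, format(loss)))
      }
      losses <- c(losses, loss)
      zero_grads(model)
      model_backward(model, bce_grad(out$logit, yb))
      adam_step(opt)
    }
    probs <- eval_model_on(model, test_data, hp$threshold, hp$batch_size)
    acc <- mean(binarize(probs, hp$threshold) == test_data$labels)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         test_accuracy = acc))
    if (acc > best_acc) {
      best_acc <- acc
      best_state <- model_state(model)
      best_epoch <- epoch
    }
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f  test acc %.3f",
                      epoch, mean(losses), acc))
    }
  }
  restore_model_state(model, best_state)
  list(checkpoint = new_checkpoint(model, hp, history),
       history = history, best_epoch = best_epoch, accuracy = best_acc,
       model = model)
}

# ---- checkpoints ------------------------------------------------------------

CHECKPOINT_SCHEMA <- "fundusiqa-checkpoint-1"

new_checkpoint <- function(model, hp, history) {
  list(schema = CHECKPOINT_SCHEMA,
       variant = model$variant,
       config = model$config,
       hyperparams = hp,
       state = model_state(model),
       history = history)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive with a schema tag, the variant
#' name, the architecture configuration, all parameter tensors (including
#' batch-norm running statistics) and the training history.
#'
#' @param ckpt checkpoint list (from [train_model()])
#' @param path file path
#' @return `load_checkpoint()` returns a list with the rebuilt `model` and
#'   the checkpoint metadata
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(identical(ckpt$schema, CHECKPOINT_SCHEMA))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!identical(ckpt$schema, CHECKPOINT_SCHEMA)) {
    stop("not a recognized checkpoint file (schema tag mismatch)")
  }
  model <- build_variant(ckpt$variant, ckpt$config)
  restore_model_state(model, ckpt$state)
  list(model = model, checkpoint = ckpt)
}

#' Stratified cross-validation of a variant
#'
#' Runs [train_model()] over the folds of [kfold_stratified()] and collects
#' per-fold accuracy and AUC.
#'
#' @param data dataset list (`images`, `labels`, optional `masks`)
#' @param variant one of [MODEL_VARIANTS]
#' @param config a [model_config()]
#' @param k number of folds
#' @param hp a [hyperparams()] object
#' @param verbose print progress
#' @return data.frame with one row per fold: `fold`, `accuracy`, `auc`
#' @export
crossval_variant <- function(data, variant, config = reduced_model_config(),
                             k = 5L, hp = hyperparams(), verbose = FALSE) {
  folds <- kfold_stratified(data$labels, k = k, seed = hp$seed)
  res <- lapply(seq_along(folds), function(i) {
    model <- build_variant(variant, config, seed = hp$seed + i)
    fit <- train_model(model, dataset_subset(data, folds[[i]]$train),
                       dataset_subset(data, folds[[i]]$test), hp,
                       verbose = verbose)
    te <- dataset_subset(data, folds[[i]]$test)
    probs <- eval_model_on(fit$model, te, hp$threshold, hp$batch_size)
    auc <- if (length(unique(te$labels)) > 1L)
      auc_score(probs, te$labels) else NA_real_
    data.frame(fold = i, accuracy = fit$accuracy, auc = auc)
  })
  do.call(rbind, res)
}
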