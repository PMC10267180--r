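# The four window-classifier architectures. Exact layer hyperparameters are
# not part of the published description; defaults follow the conventions of
# the reference time-series-classification implementations and are fully
# exposed here, so tests and scaled-down runs can shrink them.

#' Describe a window-classifier architecture
#'
#' @param kind one of `"mlp"`, `"fcn"`, `"resnet"`, `"encoder"`.
#' @param input_length window length in samples.
#' @param n_classes number of output classes (2: normal vs stressed).
#' @param encoder list: `block_filters` (last entry must be even — the
#'   attention splits it in half), `kernel_sizes`, `dropout`, `pool`.
#' @param mlp list: `hidden` widths and per-position `dropout` rates
#'   (length = hidden + 1).
#' @param fcn,resnet lists: `filters` and `kernels` per block.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(kind = c("mlp", "fcn", "resnet", "encoder"),
                              input_length,
                              n_classes = 2,
                              encoder = list(block_filters = c(128, 256, 512),
                                             kernel_sizes = c(5, 11, 21),
                                             dropout = 0.2, pool = 2),
                              mlp = list(hidden = c(500, 500, 500),
                                         dropout = c(0.1, 0.2, 0.2, 0.3)),
                              fcn = list(filters = c(128, 256, 128),
                                         kernels = c(8, 5, 3)),
                              resnet = list(filters = c(64, 128, 128),
                                            kernels = c(8, 5, 3))) {
  kind <- match.arg(kind)
  stopifnot_scalar_num(input_length, "input_length", positive = TRUE)
  if (n_classes < 2) config_error("`n_classes` must be >= 2")
  max_kernel <- switch(kind,
                       encoder = max(encoder$kernel_sizes),
                       fcn = max(fcn$kernels),
                       resnet = max(resnet$kernels),
                       mlp = 1)
  if (input_length <= max_kernel)
    config_error("`input_length` must exceed the largest kernel size")
  if (kind == "encoder") {
    nf <- encoder$block_filters
    if (nf[length(nf)] %% 2 != 0)
      config_error(
        "encoder's last block filter count must be even (attention split)")
  }
  structure(list(kind = kind, input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes), encoder = encoder,
                 mlp = mlp, fcn = fcn, resnet = resnet),
            class = "architecture_spec")
}

# Instantiate the layer list for a spec (parameters drawn from the current
# RNG state; callers seed it).
init_layers <- function(spec) {
  Tin <- spec$input_length
  K <- spec$n_classes
  switch(spec$kind,
    mlp = {
      h <- spec$mlp$hidden
      dr <- spec$mlp$dropout
      layers <- list(layer_flatten(), layer_dropout(dr[1]))
      din <- Tin
      for (i in seq_along(h)) {
        layers <- c(layers, list(layer_dense(din, h[i]), layer_relu(),
                                 layer_dropout(dr[i + 1])))
        din <- h[i]
      }
      c(layers, list(layer_dense(din, K)))
    },
    fcn = {
      f <- spec$fcn$filters; k <- spec$fcn$kernels
      layers <- list()
      cin <- 1
      for (i in seq_along(f)) {
        layers <- c(layers, list(layer_conv(cin, f[i], k[i]),
                                 layer_bnorm(f[i]), layer_relu()))
        cin <- f[i]
      }
      c(layers, list(layer_gap(), layer_dense(cin, K)))
    },
    resnet = {
      f <- spec$resnet$filters; k <- spec$resnet$kernels
      layers <- list()
      cin <- 1
      for (i in seq_along(f)) {
        layers <- c(layers, list(layer_resblock(cin, f[i], k)))
        cin <- f[i]
      }
      c(layers, list(layer_gap(), layer_dense(cin, K)))
    },
    encoder = {
      f <- spec$encoder$block_filters; k <- spec$encoder$kernel_sizes
      dr <- spec$encoder$dropout; pool <- spec$encoder$pool
      layers <- list()
      cin <- 1
      Tt <- Tin
      for (i in seq_along(f)) {
        layers <- c(layers, list(layer_conv(cin, f[i], k[i]),
                                 layer_inorm(f[i]), layer_prelu(f[i]),
                                 layer_dropout(dr)))
        cin <- f[i]
        if (i < length(f)) {
          layers <- c(layers, list(layer_maxpool(pool)))
          Tt <- Tt %/% pool
        }
      }
      h <- cin %/% 2
      c(layers, list(layer_attention(cin), layer_inorm(h), layer_flatten(),
                     layer_dense(h * Tt, K)))
    })
}

#' Build an (untrained) window classifier
#'
#' The encoder forward pass is: three blocks of
#' conv1d (same padding) -> instance norm -> PReLU -> dropout, with max-pool
#' between blocks; then the last block's channels are split in half, a
#' softmax over the time axis of one half provides attention weights for the
#' other; the weighted half passes through instance normalization, a dense
#' layer and a class softmax. Inference is deterministic (dropout off).
#'
#' @param spec an [architecture_spec()].
#' @param seed seed for parameter initialisation.
#' @return An object of class `stress_classifier` (untrained).
#' @export
build_model <- function(spec, seed = 0) {
  if (!inherits(spec, "architecture_spec"))
    config_error("`spec` must be an architecture_spec")
  layers <- with_seed(seed, init_layers(spec))
  structure(list(spec = spec, layers = layers, trained = FALSE,
                 manifest = list(init_seed = seed)),
            class = "stress_classifier")
}

#' Number of trainable parameters of a classifier
#' @param model a `stress_classifier`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(l) count_params(layer_get_params(l)),
             numeric(1)))
}

#' @export
print.stress_classifier <- function(x, ...) {
  cat(sprintf("<stress_classifier> %s, input %d samples, %d classes, %s params%s\n",
              x$spec$kind, x$spec$input_length, x$spec$n_classes,
              format(n_params(x), big.mark = ","),
              if (x$trained) sprintf(" (trained, %d epochs)",
                                     x$manifest$epochs) else " (untrained)"))
  invisible(x)
}

# windows matrix (n x T) -> input tensor (1, T, n)
windows_to_tensor <- function(w) {
  x <- t(w)
  dim(x) <- c(1L, nrow(x), ncol(x))
  x
}

#' Train a window classifier
#'
#' Seeded and deterministic under a single-threaded BLAS: the seed governs
#' parameter initialisation, shuffling and dropout. Class imbalance is
#' handled with inverse-frequency class weights in the cross-entropy loss.
#' Optimiser: Adam, learning rate `lr`, minibatch `batch_size`.
#'
#' @param model an untrained `stress_classifier` from [build_model()].
#' @param train_windows a [window_set()]; only labels 0/1 are admitted.
#' @param budget number of epochs (integer), or a list with `epochs` and
#'   optionally `lr`, `batch_size`. 0 epochs returns the initialized model.
#' @param seed training seed.
#' @return A trained `stress_classifier` carrying a training manifest
#'   (seed, epochs run, per-epoch losses, configuration).
#' @export
train <- function(model, train_windows, budget = 5, seed = 0) {
  if (!inherits(model, "stress_classifier"))
    config_error("`model` must come from build_model()")
  ws <- train_windows
  if (!all(ws$labels %in% c(0L, 1L)))
    train_error("training labels must be 0/1 (drop unlabelled windows first)")
  if (length(unique(ws$labels)) < 2)
    train_error("training set must contain both classes")
  if (ncol(ws$windows) != model$spec$input_length)
    shape_error(sprintf("window length %d does not match spec input_length %d",
                        ncol(ws$windows), model$spec$input_length))
  if (is.numeric(budget)) budget <- list(epochs = budget)
  epochs <- budget$epochs %||% 5
  lr <- budget$lr %||% 1e-3
  batch_size <- budget$batch_size %||% 64

  n <- nrow(ws$windows)
  y <- ws$labels + 1L                       # 1-based class index
  counts <- tabulate(y, model$spec$n_classes)
  w_class <- ifelse(counts > 0, n / (sum(counts > 0) * counts), 0)
  x_all <- windows_to_tensor(ws$windows)

  losses <- numeric(0)
  layers <- with_seed(seed, {
    layers <- init_layers(model$spec)
    adam_state <- vector("list", length(layers))
    t_step <- 0
    if (epochs > 0) for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, n)]
        xb <- x_all[, , idx, drop = FALSE]
        fw <- net_forward(layers, xb, train = TRUE)
        layers <- fw$layers
        l <- ce_loss(fw$logits, y[idx], w_class)
        grads <- net_backward(layers, fw$caches, l$dlogits)
        t_step <- t_step + 1
        for (i in seq_along(layers)) {
          if (!length(grads[[i]])) next
          upd <- adam_update_params(layer_get_params(layers[[i]]), grads[[i]],
                                    adam_state[[i]] %||% list(), lr, t_step)
          layers[[i]] <- layer_set_params(layers[[i]], upd$params)
          adam_state[[i]] <- upd$state
        }
        ep_loss <- ep_loss + l$loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      losses <- c(losses, ep_loss / ep_n)
    }
    layers
  })
  model$layers <- layers
  model$trained <- TRUE
  model$manifest <- list(seed = seed, epochs = epochs, lr = lr,
                         batch_size = batch_size, epoch_losses = losses,
                         best_losses = if (length(losses)) cummin(losses)
                                       else numeric(0),
                         class_weights = w_class, n_train = n)
  model
}

#' Predict per-window stressed-state confidences
#'
#' Applies the classifier in inference mode (dropout off, batch norm using
#' running statistics), in batches. Batching never changes the values: each
#' window's forward pass is independent.
#'
#' @param classifier a `stress_classifier`.
#' @param windows a [window_set()] with rows of the spec's input length.
#' @param batch_size windows per forward pass (64 by default; 1 gives the
#'   single-window deployment setting).
#' @return A [prediction_trace()] with one stressed-class confidence per
#'   window, in input order.
#' @export
predict_confidences <- function(classifier, windows, batch_size = 64) {
  if (!inherits(classifier, "stress_classifier"))
    config_error("`classifier` must be a stress_classifier")
  ws <- windows
  if (ncol(ws$windows) != classifier$spec$input_length)
    shape_error(sprintf("window length %d does not match spec input_length %d",
                        ncol(ws$windows), classifier$spec$input_length))
  n <- nrow(ws$windows)
  conf <- numeric(n)
  x_all <- windows_to_tensor(ws$windows)
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    fw <- net_forward(classifier$layers, x_all[, , idx, drop = FALSE],
                      train = FALSE)
    P <- softmax_cols(fw$logits)
    conf[idx] <- P[2, ]
  }
  prediction_trace(plant_id = ws$plant_ids, start_times = ws$start_times,
                   confidences = conf,
                   window_length_s = ws$window_length_s)
}

#' Class probabilities for a set of windows
#'
#' Full softmax output (rows = classes, columns = windows), inference mode.
#'
#' @inheritParams predict_confidences
#' @return A `n_classes x n_windows` matrix with columns summing to 1.
#' @export
predict_proba <- function(classifier, windows, batch_size = 64) {
  ws <- windows
  x_all <- windows_to_tensor(ws$windows)
  n <- nrow(ws$windows)
  out <- matrix(NA_real_, classifier$spec$n_classes, n)
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    fw <- net_forward(classifier$layers, x_all[, , idx, drop = FALSE],
                      train = FALSE)
    out[, idx] <- softmax_cols(fw$logits)
  }
  out
}

#' Intermediate activations of a classifier on a window batch
#'
#' Inference-mode forward pass exposing per-layer outputs; used to assert
#' internal invariants such as the attention weights summing to one over the
#' time axis.
#'
#' @inheritParams predict_confidences
#' @return List with `outputs` (per-layer activations), `types` (layer
#'   types) and `attention` (the time-softmax weight array of the first
#'   attention layer, if any).
#' @export
forward_activations <- function(classifier, windows) {
  x <- windows_to_tensor(windows$windows)
  outputs <- list(); types <- character(0); attention <- NULL
  layers <- classifier$layers
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train = FALSE)
    x <- r$y
    outputs[[i]] <- x
    types[i] <- layers[[i]]$type
    if (layers[[i]]$type == "attention" && is.null(attention))
      attention <- r$cache$S
  }
  list(outputs = outputs, types = types, attention = attention)
}
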