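# Window classifiers: spec validation, forward-pass contracts, the attention
# mechanism, gradient correctness, training behaviour, prediction invariants.

test_that("specs validate their invariants", {
  expect_s3_class(architecture_spec("encoder", 800), "architecture_spec")
  expect_error(architecture_spec("encoder", 800,
                                 encoder = list(block_filters = c(8, 8, 7),
                                                kernel_sizes = c(3, 5, 7),
                                                dropout = 0, pool = 2)),
               class = "phytostress_config_error")
  expect_error(architecture_spec("fcn", 4),
               class = "phytostress_config_error")   # input <= kernel
})

test_that("forward pass returns normalized class confidences", {
  spec <- architecture_spec("encoder", 800, encoder = small_encoder())
  m <- build_model(spec, seed = 1)
  ws <- window_set(matrix(stats::rnorm(5 * 800), 5), rep("B0", 5), 1:5,
                   rep(-1L, 5), 50, 16)
  p <- predict_proba(m, ws)
  expect_equal(dim(p), c(2, 5))
  expect_equal(colSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("window length must match the spec", {
  spec <- architecture_spec("mlp", 2000,
                            mlp = list(hidden = c(8), dropout = c(0, 0)))
  m <- build_model(spec, seed = 1)
  ok <- window_set(matrix(stats::rnorm(2 * 2000), 2), rep("B0", 2), 1:2,
                   rep(-1L, 2), 500, 4)
  expect_length(predict_confidences(m, ok)$confidences, 2)
  bad <- window_set(matrix(stats::rnorm(2 * 1999), 2), rep("B0", 2), 1:2,
                    rep(-1L, 2), 500, 4)
  expect_error(predict_confidences(m, bad),
               class = "phytostress_shape_error")
})

test_that("attention: constant-over-time half gives uniform weights A/T", {
  # closed form: softmax of a constant sequence of length T is 1/T
  ns <- asNamespace("phytostress")
  set.seed(2)
  h <- 3; Tt <- 7; B <- 2
  A <- array(stats::rnorm(h * Tt * B), c(h, Tt, B))
  Bc <- array(rep(stats::rnorm(h * B), each = 1), c(h, 1, B))[, rep(1, Tt), ,
                                                              drop = FALSE]
  x <- array(0, c(2 * h, Tt, B))
  x[1:h, , ] <- A
  x[(h + 1):(2 * h), , ] <- Bc
  out <- ns$fw_attention(ns$layer_attention(2 * h), x, train = FALSE)
  expect_equal(out$y, A / Tt, tolerance = 1e-12)
  # attention weights sum to 1 over time for every (channel, batch)
  sums <- apply(out$cache$S, c(1, 3), sum)
  expect_equal(as.numeric(sums), rep(1, h * B), tolerance = 1e-12)
})

test_that("attention weights of a real encoder sum to one over time", {
  spec <- architecture_spec("encoder", 64, encoder = small_encoder())
  m <- build_model(spec, seed = 3)
  ws <- window_set(matrix(stats::rnorm(3 * 64), 3), rep("B0", 3), 1:3,
                   rep(-1L, 3), 4, 16)
  act <- forward_activations(m, ws)
  expect_false(is.null(act$attention))
  sums <- apply(act$attention, c(1, 3), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
})

test_that("backpropagation matches numerical gradients", {
  ns <- asNamespace("phytostress")
  for (setup in list(
    list(kind = "fcn", args = list(fcn = list(filters = c(4, 6, 4),
                                              kernels = c(5, 3, 3)))),
    list(kind = "resnet", args = list(resnet = list(filters = c(4, 6, 6),
                                                    kernels = c(5, 3, 3)))),
    list(kind = "encoder", args = list(encoder = list(
      block_filters = c(4, 6, 6), kernel_sizes = c(3, 5, 5),
      dropout = 0, pool = 2))))) {
    spec <- do.call(architecture_spec,
                    c(list(kind = setup$kind, input_length = 17), setup$args))
    set.seed(42)
    layers <- ns$init_layers(spec)
    x <- array(stats::rnorm(17 * 4), c(1, 17, 4))
    y <- c(1L, 2L, 1L, 2L)
    lossfn <- function(ls) {
      fw <- ns$net_forward(ls, x, train = TRUE)
      ns$ce_loss(fw$logits, y, c(1, 1))$loss
    }
    fw <- ns$net_forward(layers, x, train = TRUE)
    grads <- ns$net_backward(fw$layers, fw$caches,
                             ns$ce_loss(fw$logits, y, c(1, 1))$dlogits)
    worst <- 0
    for (i in seq_along(layers)) {
      g <- grads[[i]]
      if (!length(g)) next
      check_one <- function(path) {
        p0 <- ns$layer_get_params(layers[[i]])
        garr <- if (length(path) == 1) g[[path]] else g[[path[1]]][[path[2]]]
        for (k in sample(length(garr), min(2, length(garr)))) {
          eps <- 1e-5
          f <- function(d) {
            p <- p0
            if (length(path) == 1) p[[path]][k] <- p[[path]][k] + d
            else p[[path[1]]][[path[2]]][k] <- p[[path[1]]][[path[2]]][k] + d
            l2 <- layers
            l2[[i]] <- ns$layer_set_params(l2[[i]], p)
            lossfn(l2)
          }
          num <- (f(eps) - f(-eps)) / (2 * eps)
          rel <- abs(num - garr[k]) / max(1e-6, abs(num) + abs(garr[k]))
          worst <<- max(worst, rel)
        }
      }
      for (nm in names(g)) {
        if (is.list(g[[nm]])) for (nm2 in names(g[[nm]])) check_one(c(nm, nm2))
        else check_one(nm)
      }
    }
    expect_lt(worst, 1e-3)
  }
})

test_that("training learns separable toys, is seeded and budget-aware", {
  ws <- toy_windows()
  spec <- architecture_spec("encoder", 32, encoder = small_encoder())
  m <- build_model(spec, seed = 1)
  # oracle: a threshold on the window mean separates the classes perfectly
  means <- rowMeans(ws$windows)
  expect_equal(mean((means > 0) == (ws$labels == 1)), 1)
  mt <- train(m, ws, budget = list(epochs = 8), seed = 1)
  expect_gte(accuracy(predict_confidences(mt, ws), ws$labels), 0.95)
  # best-so-far loss is non-increasing and improves on the first epoch
  expect_true(all(diff(mt$manifest$best_losses) <= 0))
  expect_lt(min(mt$manifest$epoch_losses), mt$manifest$epoch_losses[1])
  # determinism
  mt2 <- train(m, ws, budget = list(epochs = 8), seed = 1)
  expect_identical(mt$manifest$epoch_losses, mt2$manifest$epoch_losses)
  # 0 epochs: initialized model; on labels independent of window content
  # accuracy is chance-level (an untrained net is an arbitrary fixed
  # function, so labels must not correlate with the inputs here)
  m0 <- train(m, ws, budget = 0, seed = 1)
  expect_equal(m0$manifest$epochs, 0)
  set.seed(99)
  rand_labels <- sample(ws$labels)
  acc0 <- accuracy(predict_confidences(m0, ws), rand_labels)
  expect_gte(acc0, 0.4); expect_lte(acc0, 0.6)
  # single-class training set is rejected
  ws1 <- subset_windows(ws, ws$labels == 1L)
  expect_error(train(m, ws1, 1, 1), class = "phytostress_train_error")
})

test_that("untrained symmetric model gives 0.5 on zero inputs", {
  for (kind in c("mlp", "fcn", "encoder")) {
    spec <- do.call(architecture_spec, c(
      list(kind = kind, input_length = 32),
      switch(kind,
             mlp = list(mlp = list(hidden = c(8), dropout = c(0, 0))),
             fcn = list(fcn = list(filters = c(4, 4, 4), kernels = c(5, 3, 3))),
             encoder = list(encoder = small_encoder()))))
    m <- build_model(spec, seed = 4)
    wz <- window_set(matrix(0, 3, 32), rep("B0", 3), 1:3, rep(-1L, 3), 2, 16)
    expect_equal(as.numeric(predict_proba(m, wz)), rep(0.5, 6),
                 tolerance = 1e-9)
  }
})

test_that("prediction is order-preserving, batch-invariant and permutation-equivariant", {
  ws <- toy_windows(n = 60)
  spec <- architecture_spec("encoder", 32, encoder = small_encoder())
  mt <- train(build_model(spec, 1), ws, budget = 2, seed = 1)
  tr64 <- predict_confidences(mt, ws, batch_size = 64)
  tr1 <- predict_confidences(mt, ws, batch_size = 1)
  expect_length(tr64$confidences, 60)
  expect_lt(max(abs(tr64$confidences - tr1$confidences)), 1e-6)
  expect_true(all(tr64$confidences >= 0 & tr64$confidences <= 1))
  # permuting windows permutes the trace identically
  set.seed(6)
  perm <- sample(60)
  wsp <- window_set(ws$windows[perm, ], rep("B0", 60), seq_len(60),
                    ws$labels[perm], 5, 16)
  trp <- predict_confidences(mt, wsp, batch_size = 64)
  expect_equal(trp$confidences, tr64$confidences[perm], tolerance = 1e-9)
})

test_that("the encoder has more trainable parameters than the MLP", {
  # at the published full-scale input of 2000 samples (4 s at 500 Hz)
  enc <- build_model(architecture_spec("encoder", 2000), seed = 1)
  mlp <- build_model(architecture_spec("mlp", 2000), seed = 1)
  expect_gt(n_params(enc), n_params(mlp))
  expect_gt(n_params(enc), 3e6)   # encoder is a multi-million-parameter net
})
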