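# Gradient-boosted decision trees for binary classification: second-order
# (Newton) boosting on the logistic loss with exact greedy splits, L2 (lambda)
# and L1 (alpha) leaf regularisation, row subsampling and gain-based feature
# importance — the standard tree-booster formulation, implemented here
# because no tree-ensemble package is part of the supported environment.

soft_threshold <- function(G, alpha) sign(G) * max(abs(G) - alpha, 0)

leaf_weight <- function(G, H, lambda, alpha)
  -soft_threshold(G, alpha) / (H + lambda)

split_score <- function(G, H, lambda, alpha)
  soft_threshold(G, alpha)^2 / (H + lambda)

# Recursive exact-greedy tree construction on instance subset `rows`.
# `imp` is an environment accumulating per-feature gain.
gbt_build_tree <- function(X, g, h, rows, depth, lambda, alpha,
                           min_child_weight, imp) {
  G <- sum(g[rows]); H <- sum(h[rows])
  make_leaf <- function() list(leaf = TRUE,
                               weight = leaf_weight(G, H, lambda, alpha))
  if (depth <= 0 || length(rows) < 2) return(make_leaf())
  base <- split_score(G, H, lambda, alpha)
  best <- list(gain = 0)
  for (j in seq_len(ncol(X))) {
    xv <- X[rows, j]
    ord <- order(xv)
    xs <- xv[ord]
    gl <- cumsum(g[rows][ord]); hl <- cumsum(h[rows][ord])
    n <- length(rows)
    cand <- which(xs[-n] < xs[-1])        # splits between distinct values
    if (!length(cand)) next
    HL <- hl[cand]; HR <- H - HL
    ok <- cand[HL >= min_child_weight & HR >= min_child_weight]
    if (!length(ok)) next
    GL <- gl[ok]; HL <- hl[ok]
    GR <- G - GL; HR <- H - HL
    stL <- sign(GL) * pmax(abs(GL) - alpha, 0)
    stR <- sign(GR) * pmax(abs(GR) - alpha, 0)
    gains <- 0.5 * (stL^2 / (HL + lambda) + stR^2 / (HR + lambda) - base)
    bi <- which.max(gains)
    if (gains[bi] > best$gain) {
      best <- list(gain = gains[bi], feature = j,
                   value = (xs[ok[bi]] + xs[ok[bi] + 1]) / 2)
    }
  }
  if (best$gain <= 0) return(make_leaf())
  imp$gain[best$feature] <- imp$gain[best$feature] + best$gain
  left <- rows[X[rows, best$feature] <= best$value]
  right <- setdiff(rows, left)
  list(leaf = FALSE, feature = best$feature, value = best$value,
       gain = best$gain,
       left = gbt_build_tree(X, g, h, left, depth - 1, lambda, alpha,
                             min_child_weight, imp),
       right = gbt_build_tree(X, g, h, right, depth - 1, lambda, alpha,
                              min_child_weight, imp))
}

gbt_predict_tree <- function(tree, X, rows = seq_len(nrow(X))) {
  out <- numeric(nrow(X))
  rec <- function(node, rows) {
    if (!length(rows)) return()
    if (node$leaf) {
      out[rows] <<- node$weight
    } else {
      go_left <- X[rows, node$feature] <= node$value
      rec(node$left, rows[go_left])
      rec(node$right, rows[!go_left])
    }
  }
  rec(tree, rows)
  out
}

#' Train a gradient-boosted tree classifier
#'
#' @param X numeric feature matrix (named columns).
#' @param y binary labels (0/1).
#' @param n_trees boosting rounds.
#' @param max_depth maximum tree depth.
#' @param eta learning rate (shrinkage).
#' @param lambda L2 regularisation on leaf weights.
#' @param alpha L1 regularisation on leaf weights.
#' @param subsample row-subsampling fraction per round.
#' @param min_child_weight minimum hessian sum per child.
#' @param seed RNG seed (subsampling).
#' @return An object of class `gbt_model` with trees, base margin and
#'   per-feature gain importance.
#' @export
gbt_train <- function(X, y, n_trees = 40, max_depth = 3, eta = 0.1,
                      lambda = 1, alpha = 0, subsample = 1,
                      min_child_weight = 1, seed = 0) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) train_error("gbt labels must be 0/1")
  n <- nrow(X)
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  base_margin <- log(p0 / (1 - p0))
  margin <- rep(base_margin, n)
  imp <- new.env()
  imp$gain <- numeric(ncol(X))
  trees <- with_seed(seed, {
    trees <- vector("list", n_trees)
    for (t in seq_len(n_trees)) {
      prob <- 1 / (1 + exp(-margin))
      g <- prob - y
      h <- pmax(prob * (1 - prob), 1e-12)
      rows <- if (subsample < 1)
        sort(sample.int(n, max(2, round(subsample * n)))) else seq_len(n)
      tree <- gbt_build_tree(X, g, h, rows, max_depth, lambda, alpha,
                             min_child_weight, imp)
      margin <- margin + eta * gbt_predict_tree(tree, X)
      trees[[t]] <- tree
    }
    trees
  })
  structure(list(trees = trees, eta = eta, base_margin = base_margin,
                 feature_names = colnames(X),
                 importance = stats::setNames(imp$gain,
                                              colnames(X) %||%
                                                paste0("f", seq_len(ncol(X)))),
                 params = list(n_trees = n_trees, max_depth = max_depth,
                               eta = eta, lambda = lambda, alpha = alpha,
                               subsample = subsample)),
            class = "gbt_model")
}

#' Predict stressed-class probabilities with a boosted-tree model
#' @param model a [gbt_train()] result.
#' @param X feature matrix with the training columns.
#' @return Numeric vector of probabilities.
#' @export
gbt_predict <- function(model, X) {
  X <- as.matrix(X)
  margin <- rep(model$base_margin, nrow(X))
  for (tree in model$trees)
    margin <- margin + model$eta * gbt_predict_tree(tree, X)
  1 / (1 + exp(-margin))
}
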