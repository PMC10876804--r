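#' Classifier specification
#'
#' The four learners evaluated by the pipeline. None of the usual R
#' machine-learning packages are required: KNN, the linear SVM (one-vs-rest
#' primal subgradient descent), the CART-style gini decision tree and the
#' bootstrap-bagged tree ensemble are implemented here, deterministically,
#' so that a seed fully fixes every evaluation.
#'
#' @param kind One of `"knn"`, `"linear_svm"`, `"decision_tree"`,
#'   `"ensemble_bagged_tree"`.
#' @param knn_k Neighbors for KNN.
#' @param svm_c Soft-margin cost C for the linear SVM.
#' @param tree_min_split Minimum node size eligible for splitting.
#' @param tree_max_depth Maximum tree depth.
#' @param ebt_n_trees Trees in the bagged ensemble.
#' @param random_seed Seed controlling bootstrap resampling.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "linear_svm", "decision_tree",
                                     "ensemble_bagged_tree"),
                            knn_k = 5, svm_c = 1, tree_min_split = 5,
                            tree_max_depth = 10, ebt_n_trees = 30,
                            random_seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(knn_k >= 1, svm_c > 0, ebt_n_trees >= 2, tree_min_split >= 2)
  structure(
    list(kind = kind, knn_k = as.integer(knn_k), svm_c = svm_c,
         tree_min_split = as.integer(tree_min_split),
         tree_max_depth = as.integer(tree_max_depth),
         ebt_n_trees = as.integer(ebt_n_trees),
         random_seed = as.integer(random_seed)),
    class = "classifier_spec"
  )
}

# ---- KNN ------------------------------------------------------------------

# Euclidean KNN with deterministic tie-breaking: among vote-tied classes
# the one with the smaller summed neighbor distance wins, then class order.
knn_predict <- function(train_x, train_y, test_x, k) {
  k <- min(k, nrow(train_x))
  lv <- levels(train_y)
  apply(test_x, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nb <- order(d)[seq_len(k)]
    votes <- table(factor(train_y[nb], lv))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      dist_by_class <- vapply(top, function(cl)
        sum(d[nb][train_y[nb] == cl]), 0)
      top <- top[order(dist_by_class)][1]
    }
    top[1]
  })
}

# ---- Linear SVM -----------------------------------------------------------

# Primal subgradient descent on the soft-margin objective
#   lambda/2 ||w||^2 + mean(hinge), lambda = 1 / (C n),
# full-batch with the classic 1/(lambda t) step schedule. Deterministic.
svm_train_binary <- function(x, y01, c_cost, epochs = 200) {
  n <- nrow(x); p <- ncol(x)
  y <- ifelse(y01, 1, -1)
  lambda <- 1 / (c_cost * n)
  w <- rep(0, p); b <- 0
  for (t in seq_len(epochs)) {
    eta <- 1 / (lambda * t)
    marg <- y * (x %*% w + b)
    viol <- marg < 1
    gw <- lambda * w - colMeans(x[viol, , drop = FALSE] * y[viol]) *
      (sum(viol) / n)
    gb <- -mean(y[viol]) * (sum(viol) / n)
    if (!any(viol)) { gw <- lambda * w; gb <- 0 }
    w <- w - eta * gw
    b <- b - eta * gb
  }
  list(w = w, b = b)
}

svm_predict <- function(train_x, train_y, test_x, c_cost) {
  lv <- levels(train_y)
  scores <- vapply(lv, function(cl) {
    fit <- svm_train_binary(train_x, train_y == cl, c_cost)
    as.numeric(test_x %*% fit$w + fit$b)
  }, numeric(nrow(test_x)))
  scores <- matrix(scores, nrow = nrow(test_x))
  lv[max.col(scores, ties.method = "first")]
}

# ---- CART decision tree ---------------------------------------------------

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# best gini split of one node; fully vectorized scan over the sorted
# feature values (weighted child impurity computed for every cut at once)
best_split <- function(x, y, min_leaf = 1L) {
  n <- length(y)
  nlv <- length(levels(y))
  best <- list(gain = -Inf)
  parent <- gini_impurity(tabulate(y, nlv))
  yi <- as.integer(y)
  for (f in seq_len(ncol(x))) {
    ord <- order(x[, f])
    xs <- x[ord, f]
    cut_ok <- which(diff(xs) > 0)
    cut_ok <- cut_ok[cut_ok >= min_leaf & cut_ok <= n - min_leaf]
    if (!length(cut_ok)) next
    # cumulative class counts after each sorted position
    cum <- vapply(seq_len(nlv), function(cl) cumsum(yi[ord] == cl),
                  numeric(n))
    i <- seq_len(n - 1)
    left_n <- i
    right_n <- n - i
    cl <- cum[i, , drop = FALSE]
    cr <- rep(cum[n, ], each = n - 1) - cl
    imp <- (left_n * (1 - rowSums((cl / left_n)^2)) +
              right_n * (1 - rowSums((cr / right_n)^2))) / n
    gain <- parent - imp
    j <- cut_ok[which.max(gain[cut_ok])]
    if (gain[j] > best$gain + 1e-12) {
      best <- list(gain = gain[j], feature = f,
                   threshold = (xs[j] + xs[j + 1]) / 2)
    }
  }
  if (is.finite(best$gain) && best$gain > 1e-12) best else NULL
}

tree_fit <- function(x, y, min_split = 5L, max_depth = 10L, depth = 0L) {
  lv <- levels(y)
  counts <- tabulate(y, length(lv))
  leaf <- list(leaf = TRUE, class = lv[which.max(counts)])
  if (length(y) < min_split || depth >= max_depth ||
      length(unique(y)) == 1) return(leaf)
  sp <- best_split(x, y)
  if (is.null(sp)) return(leaf)
  go_l <- x[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = tree_fit(x[go_l, , drop = FALSE], y[go_l],
                       min_split, max_depth, depth + 1L),
       right = tree_fit(x[!go_l, , drop = FALSE], y[!go_l],
                        min_split, max_depth, depth + 1L))
}

tree_predict_one <- function(tree, q) {
  while (!tree$leaf)
    tree <- if (q[tree$feature] <= tree$threshold) tree$left else tree$right
  tree$class
}

tree_predict <- function(tree, x) {
  apply(x, 1, tree_predict_one, tree = tree)
}

# ---- Bagged trees ---------------------------------------------------------

ebt_predict <- function(train_x, train_y, test_x, spec) {
  lv <- levels(train_y)
  n <- nrow(train_x)
  votes <- matrix(0L, nrow(test_x), length(lv),
                  dimnames = list(NULL, lv))
  for (b in seq_len(spec$ebt_n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    tr <- tree_fit(train_x[idx, , drop = FALSE],
                   droplevels_keep(train_y[idx], lv),
                   spec$tree_min_split, spec$tree_max_depth)
    pred <- tree_predict(tr, test_x)
    for (cl in lv) votes[, cl] <- votes[, cl] + (pred == cl)
  }
  lv[max.col(votes, ties.method = "first")]
}

# keep the full level set so vote columns stay aligned
droplevels_keep <- function(y, lv) factor(as.character(y), levels = lv)

# dispatch on classifier kind; train_y is a factor with the full level set
fit_and_predict <- function(spec, train_x, train_y, test_x) {
  pred <- switch(spec$kind,
    knn = knn_predict(train_x, train_y, test_x, spec$knn_k),
    linear_svm = svm_predict(train_x, train_y, test_x, spec$svm_c),
    decision_tree = tree_predict(
      tree_fit(train_x, train_y, spec$tree_min_split, spec$tree_max_depth),
      test_x),
    ensemble_bagged_tree = ebt_predict(train_x, train_y, test_x, spec)
  )
  factor(pred, levels = levels(train_y))
}
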