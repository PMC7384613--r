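# CART split mathematics and a small multi-output random forest.
#
# Univariate forests used by the movement framework are delegated to ranger;
# the split-rule primitives below exist because (a) they define the exact
# contract the framework relies on (threshold enumeration at midpoints,
# deterministic tie-breaking) and (b) multi-output trees — one split tree
# predicting states or velocities for every animal in a colony at once — are
# not provided by the installed forest implementations.

#' Gini impurity of a classification node
#'
#' `sum_k p_k (1 - p_k)` over class proportions.
#'
#' @param counts Non-negative per-class counts with positive total.
#' @return Impurity value in `[0, 1)`.
#' @export
gini_impurity <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("node must contain at least one sample", call. = FALSE)
  }
  p <- counts / sum(counts)
  sum(p * (1 - p))
}

#' Mean-squared-error impurity of a regression node
#'
#' Univariate responses give the mean squared deviation from the node mean;
#' multivariate responses (a matrix with one row per sample) give the mean
#' squared Euclidean deviation, i.e. the covariance-weighted impurity with an
#' identity weight matrix.
#'
#' @param responses Numeric vector or matrix (rows = samples).
#' @return Impurity value.
#' @export
mse_impurity <- function(responses) {
  y <- as.matrix(responses)
  if (nrow(y) == 0) stop("node must contain at least one sample", call. = FALSE)
  ybar <- colMeans(y)
  mean(rowSums((y - matrix(ybar, nrow(y), ncol(y), byrow = TRUE))^2))
}

#' Average Gini impurity across several categorical outputs
#'
#' The multi-output classification impurity: the mean over output columns of
#' each column's Gini impurity. All outputs share one class alphabet.
#'
#' @param labels Matrix (rows = samples, columns = outputs) of class labels.
#' @return Impurity value.
#' @export
multioutput_gini <- function(labels) {
  y <- as.matrix(labels)
  if (nrow(y) == 0) stop("node must contain at least one sample", call. = FALSE)
  mean(apply(y, 2, function(col) gini_impurity(table(col))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Best axis-aligned split of a node
#'
#' Enumerates candidate thresholds at midpoints between consecutive sorted
#' distinct values of each candidate predictor and returns the split
#' minimizing the weighted child impurity
#' `G = (n_left/N) H(Q_left) + (n_right/N) H(Q_right)` with the left child
#' taking rows with `x <= threshold`. Ties in `G` (within a small numerical
#' tolerance) are broken by lowest predictor index, then lowest threshold.
#'
#' @param x Predictor matrix (rows = samples).
#' @param y Response: factor/integer vector (`task = "class"`), numeric
#'   vector (`"reg"`), label matrix (`"mvclass"`) or numeric matrix
#'   (`"mvreg"`).
#' @param task Impurity type; see above.
#' @param candidates Indices of predictors eligible for splitting (default
#'   all).
#' @return A list `(predictor, threshold, impurity_parent, impurity_children,
#'   n_left, n_right)`, or `NULL` when no valid split exists (constant
#'   predictors): the node becomes a leaf.
#' @export
best_split <- function(x, y, task = c("class", "reg", "mvclass", "mvreg"),
                       candidates = NULL) {
  task <- match.arg(task)
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(candidates)) candidates <- seq_len(ncol(x))
  classification <- task %in% c("class", "mvclass")
  ym <- as.matrix(y)
  n_o <- ncol(ym)
  tol <- 1e-10

  if (classification) {
    lev <- sort(unique(as.vector(ym)))
    K <- length(lev)
    ci <- matrix(match(ym, lev), n, n_o) # class indices 1..K
    total <- matrix(0, K, n_o)
    for (o in seq_len(n_o)) total[, o] <- tabulate(ci[, o], K)
    gini_from <- function(counts, nn) {
      mean(1 - colSums((counts / nn)^2))
    }
    parent_H <- gini_from(total, n)
  } else {
    total_sum <- colSums(ym)
    total_sq <- sum(ym^2)
    mse_from <- function(sm, sq, nn) {
      sq / nn - sum((sm / nn)^2)
    }
    parent_H <- mse_from(total_sum, total_sq, n)
  }

  best <- NULL
  for (j in sort(candidates)) {
    xj <- x[, j]
    o <- order(xj)
    xs <- xj[o]
    if (xs[1] == xs[n]) next
    if (classification) {
      cl <- matrix(0, K, n_o)
      cr <- total
    } else {
      sl <- numeric(n_o); sql <- 0
    }
    for (i in seq_len(n - 1)) {
      r <- o[i]
      if (classification) {
        idx <- cbind(ci[r, ], seq_len(n_o))
        cl[idx] <- cl[idx] + 1
        cr[idx] <- cr[idx] - 1
      } else {
        sl <- sl + ym[r, ]
        sql <- sql + sum(ym[r, ]^2)
      }
      if (xs[i] == xs[i + 1]) next
      tm <- (xs[i] + xs[i + 1]) / 2
      nl <- i; nr <- n - i
      G <- if (classification) {
        (nl * gini_from(cl, nl) + nr * gini_from(cr, nr)) / n
      } else {
        (nl * mse_from(sl, sql, nl) +
           nr * mse_from(total_sum - sl, total_sq - sql, nr)) / n
      }
      if (is.null(best) || G < best$G - tol) {
        best <- list(predictor = j, threshold = tm, G = G,
                     n_left = nl, n_right = nr)
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$impurity_parent <- parent_H
  best$impurity_children <- best$G
  best
}

# -- multi-output tree ------------------------------------------------------

grow_tree <- function(x, y, task, max_depth = 12, min_split = 10,
                      min_leaf = 5, mtry = NULL, depth = 0) {
  n <- nrow(x)
  leaf_value <- function() {
    switch(task,
      mvclass = {
        ym <- as.matrix(y)
        lev <- attr(y, "levels_all")
        probs <- apply(ym, 2, function(col) {
          tab <- table(factor(col, levels = lev))
          as.numeric(tab) / sum(tab)
        })
        list(type = "mvclass", probs = t(probs), levels = lev) # outputs x K
      },
      mvreg = list(type = "mvreg", mean = colMeans(as.matrix(y)))
    )
  }
  make_leaf <- function() list(leaf = TRUE, value = leaf_value(), n = n)
  if (n < min_split || depth >= max_depth) return(make_leaf())
  p <- ncol(x)
  cand <- if (is.null(mtry) || mtry >= p) seq_len(p) else sample.int(p, mtry)
  sp <- best_split(x, y, task, candidates = cand)
  if (is.null(sp) || sp$n_left < min_leaf || sp$n_right < min_leaf) {
    return(make_leaf())
  }
  left <- x[, sp$predictor] <= sp$threshold
  subset_y <- function(rows) {
    out <- if (is.matrix(y)) y[rows, , drop = FALSE] else y[rows]
    attributes(out)$levels_all <- attr(y, "levels_all")
    out
  }
  list(
    leaf = FALSE, predictor = sp$predictor, threshold = sp$threshold, n = n,
    left = grow_tree(x[left, , drop = FALSE], subset_y(left), task,
                     max_depth, min_split, min_leaf, mtry, depth + 1),
    right = grow_tree(x[!left, , drop = FALSE], subset_y(!left), task,
                      max_depth, min_split, min_leaf, mtry, depth + 1)
  )
}

predict_tree_row <- function(tree, xrow) {
  node <- tree
  while (!node$leaf) {
    node <- if (xrow[node$predictor] <= node$threshold) node$left else node$right
  }
  node$value
}

#' Fit a multi-output random forest
#'
#' An ensemble of multi-output CART trees: each tree predicts every output
#' jointly (shared splits), with bootstrap resampling and random predictor
#' subsets at each node. For classification all outputs share one class
#' alphabet and leaves store per-output class proportions; for regression
#' leaves store the per-output mean.
#'
#' @param x Predictor matrix.
#' @param y Label matrix (`task = "mvclass"`) or numeric response matrix
#'   (`task = "mvreg"`).
#' @param task `"mvclass"` or `"mvreg"`.
#' @param num_trees,max_depth,min_split,min_leaf,mtry Forest hyperparameters;
#'   `mtry` defaults to `sqrt(p)` for classification and `p/3` for
#'   regression.
#' @param bootstrap Resample rows for each tree?
#' @param seed Integer seed; fitting is reproducible given (data, config,
#'   seed).
#' @return An object of class `mv_forest`.
#' @export
fit_mv_forest <- function(x, y, task = c("mvclass", "mvreg"), num_trees = 50,
                          max_depth = 12, min_split = 10, min_leaf = 5,
                          mtry = NULL, bootstrap = TRUE, seed = 1) {
  task <- match.arg(task)
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (task == "mvclass") {
    attr(y, "levels_all") <- sort(unique(as.vector(y)))
  }
  p <- ncol(x)
  if (is.null(mtry)) {
    mtry <- if (task == "mvclass") max(1L, floor(sqrt(p))) else
      max(1L, floor(p / 3))
  }
  set.seed(seed)
  trees <- lapply(seq_len(num_trees), function(b) {
    rows <- if (bootstrap) sample.int(nrow(x), replace = TRUE) else
      seq_len(nrow(x))
    yy <- y[rows, , drop = FALSE]
    attr(yy, "levels_all") <- attr(y, "levels_all")
    grow_tree(x[rows, , drop = FALSE], yy, task, max_depth, min_split,
              min_leaf, mtry)
  })
  structure(
    list(trees = trees, task = task, p = p,
         n_outputs = ncol(y), levels = attr(y, "levels_all"),
         config = list(num_trees = num_trees, max_depth = max_depth,
                       min_split = min_split, min_leaf = min_leaf,
                       mtry = mtry, bootstrap = bootstrap, seed = seed)),
    class = "mv_forest"
  )
}

# Average of per-tree leaf values: list of arrays [outputs x K] (mvclass) or
# a matrix n x outputs (mvreg).
#' @export
predict.mv_forest <- function(object, x, trees = NULL, ...) {
  x <- as.matrix(x)
  use <- if (is.null(trees)) object$trees else object$trees[trees]
  n <- nrow(x)
  if (object$task == "mvreg") {
    out <- matrix(0, n, object$n_outputs)
    for (tr in use) {
      for (i in seq_len(n)) {
        out[i, ] <- out[i, ] + predict_tree_row(tr, x[i, ])$mean
      }
    }
    out / length(use)
  } else {
    K <- length(object$levels)
    out <- array(0, c(n, object$n_outputs, K),
                 dimnames = list(NULL, NULL, object$levels))
    for (tr in use) {
      for (i in seq_len(n)) {
        out[i, , ] <- out[i, , ] + predict_tree_row(tr, x[i, ])$probs
      }
    }
    out / length(use)
  }
}
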