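# Pluggable stochastic learners behind the state and velocity models.
#
# Three learner families share one internal contract: `ml_fit()` fits to a
# predictor matrix and a response of a given task ("class", "reg", "mvclass",
# "mvreg"), `ml_predict()` returns the mean prediction (class probabilities
# for classification), and `ml_sample()` returns one stochastic draw — a
# uniformly sampled ensemble member for forests, a Monte Carlo dropout pass
# for networks. Univariate forests are delegated to ranger; multi-output
# forests use the package's own CART machinery (tree.R).

#' Random-forest learner specification
#'
#' @param num_trees Number of trees.
#' @param mtry Predictors sampled per node (default: ranger's default).
#' @param min_node_size Minimum samples per leaf.
#' @param max_depth Maximum tree depth (0 = unlimited).
#' @return A learner specification usable in [fit_framework()].
#' @export
learner_rf <- function(num_trees = 100, mtry = NULL, min_node_size = NULL,
                       max_depth = 0) {
  structure(list(num_trees = num_trees, mtry = mtry,
                 min_node_size = min_node_size, max_depth = max_depth),
            class = c("learner_rf", "learner_spec"))
}

#' Multi-output random-forest learner specification
#'
#' Joint trees over all outputs (states or velocities of every animal in a
#' colony), using the average-impurity multi-output split rule.
#'
#' @param num_trees,max_depth,min_split,min_leaf,mtry Forest settings; see
#'   [fit_mv_forest()].
#' @export
learner_mvrf <- function(num_trees = 25, max_depth = 10, min_split = 20,
                         min_leaf = 10, mtry = NULL) {
  structure(list(num_trees = num_trees, max_depth = max_depth,
                 min_split = min_split, min_leaf = min_leaf, mtry = mtry),
            class = c("learner_mvrf", "learner_spec"))
}

#' Neural-network learner specification
#'
#' A dense network with Monte Carlo dropout (see [fit_mlp()]); stochastic
#' draws keep dropout active at prediction time. `recurrent = TRUE` makes the
#' first hidden layer a simple recurrent layer.
#'
#' @param hidden Hidden-layer widths.
#' @param activation `"relu"`, `"tanh"` or `"elu"`.
#' @param dropout Dropout probability `p*`.
#' @param epochs,batch_size,lr Training settings.
#' @param recurrent Use a simple recurrent first layer?
#' @export
learner_mlp <- function(hidden = c(32, 16), activation = "relu",
                        dropout = 0.1, epochs = 30, batch_size = 64,
                        lr = 1e-3, recurrent = FALSE) {
  structure(list(hidden = hidden, activation = activation, dropout = dropout,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 recurrent = recurrent),
            class = c("learner_mlp", "learner_spec"))
}

ml_fit <- function(spec, x, y, task, seed = 1, seq_id = NULL) {
  UseMethod("ml_fit")
}

#' @export
ml_fit.learner_rf <- function(spec, x, y, task, seed = 1, seq_id = NULL) {
  x <- as.matrix(x)
  df <- as.data.frame(x)
  common <- list(num.trees = spec$num_trees, seed = seed, num.threads = 1,
                 verbose = FALSE, respect.unordered.factors = TRUE)
  if (!is.null(spec$mtry)) common$mtry <- spec$mtry
  if (!is.null(spec$min_node_size)) common$min.node.size <- spec$min_node_size
  if (spec$max_depth > 0) common$max.depth <- spec$max_depth
  fit <- switch(task,
    class = {
      yf <- factor(y)
      do.call(ranger::ranger, c(list(x = df, y = yf, probability = TRUE),
                                common))
    },
    reg = do.call(ranger::ranger, c(list(x = df, y = as.numeric(y)), common)),
    mvreg = {
      ym <- as.matrix(y)
      lapply(seq_len(ncol(ym)), function(j) {
        cj <- common
        cj$seed <- seed + j
        do.call(ranger::ranger, c(list(x = df, y = ym[, j]), cj))
      })
    },
    mvclass = stop("use learner_mvrf() or learner_mlp() for joint ",
                   "multi-output classification", call. = FALSE)
  )
  new_ms_learner(spec, fit, task,
                 levels = if (task == "class") levels(factor(y)) else NULL,
                 n_outputs = if (task == "mvreg") ncol(as.matrix(y)) else 1,
                 n_members = spec$num_trees,
                 feature_names = colnames(x))
}

#' @export
ml_fit.learner_mvrf <- function(spec, x, y, task, seed = 1, seq_id = NULL) {
  task_mv <- switch(task, class = "mvclass", reg = "mvreg", task)
  ym <- as.matrix(y)
  fit <- fit_mv_forest(x, ym, task = task_mv, num_trees = spec$num_trees,
                       max_depth = spec$max_depth, min_split = spec$min_split,
                       min_leaf = spec$min_leaf, mtry = spec$mtry, seed = seed)
  new_ms_learner(spec, fit, task, levels = fit$levels,
                 n_outputs = ncol(ym), n_members = spec$num_trees,
                 feature_names = colnames(as.matrix(x)))
}

#' @export
ml_fit.learner_mlp <- function(spec, x, y, task, seed = 1, seq_id = NULL) {
  head <- switch(task, class = "softmax", mvclass = "multi_softmax",
                 reg = "linear", mvreg = "linear")
  yy <- if (task == "reg") as.matrix(as.numeric(y)) else y
  fit <- fit_mlp(x, yy, head = head, hidden = spec$hidden,
                 activation = spec$activation, dropout = spec$dropout,
                 epochs = spec$epochs, batch_size = spec$batch_size,
                 lr = spec$lr, recurrent = spec$recurrent, seq_id = seq_id,
                 seed = seed)
  new_ms_learner(spec, fit, task, levels = fit$levels,
                 n_outputs = if (task %in% c("mvreg", "mvclass"))
                   ncol(as.matrix(y)) else 1,
                 n_members = NA_integer_,
                 feature_names = colnames(as.matrix(x)))
}

new_ms_learner <- function(spec, fit, task, levels, n_outputs, n_members,
                           feature_names) {
  structure(list(spec = spec, fit = fit, task = task, levels = levels,
                 n_outputs = n_outputs, n_members = n_members,
                 feature_names = feature_names),
            class = "ms_learner")
}

#' @export
print.ms_learner <- function(x, ...) {
  cat(sprintf("<ms_learner> %s, task %s, %d output(s)\n",
              class(x$spec)[1], x$task, x$n_outputs))
  invisible(x)
}

as_feature_matrix <- function(x, feature_names = NULL) {
  m <- as.matrix(x)
  if (!is.null(feature_names)) m <- m[, feature_names, drop = FALSE]
  m
}

# Mean / ensemble prediction. Classification returns probability matrices
# (class levels as columns); mvclass returns an n x outputs x K array.
ml_predict <- function(object, x) {
  x <- as_feature_matrix(x, object$feature_names)
  sp <- class(object$spec)[1]
  if (sp == "learner_rf") {
    if (object$task == "class") {
      if (length(object$levels) == 1) {
        matrix(1, nrow(x), 1, dimnames = list(NULL, object$levels))
      } else {
        predict(object$fit, data = as.data.frame(x),
                num.threads = 1)$predictions
      }
    } else if (object$task == "reg") {
      matrix(predict(object$fit, data = as.data.frame(x),
                     num.threads = 1)$predictions, ncol = 1)
    } else {
      sapply(object$fit, function(f) {
        predict(f, data = as.data.frame(x), num.threads = 1)$predictions
      }) |> matrix(nrow = nrow(x))
    }
  } else if (sp == "learner_mvrf") {
    out <- predict(object$fit, x)
    if (object$task == "class") {
      matrix(out[, 1, ], nrow = dim(out)[1],
             dimnames = list(NULL, dimnames(out)[[3]]))
    } else {
      out
    }
  } else {
    out <- predict(object$fit, x)
    if (object$task == "class") colnames(out) <- object$levels
    if (object$task == "mvclass") {
      out <- array(out, c(nrow(out), object$fit$n_classes, object$n_outputs))
      out <- aperm(out, c(1, 3, 2)) # n x outputs x K
      dimnames(out) <- list(NULL, NULL, as.character(object$levels))
    }
    out
  }
}

# One stochastic draw per row: a uniformly sampled ensemble member for
# forests (the same member across the output dimensions of a row), one
# dropout forward pass for networks. Uses the current RNG state.
ml_sample <- function(object, x) {
  x <- as_feature_matrix(x, object$feature_names)
  sp <- class(object$spec)[1]
  n <- nrow(x)
  if (sp == "learner_rf") {
    member <- sample.int(object$n_members, n, replace = TRUE)
    if (object$task == "class") {
      if (length(object$levels) == 1) {
        return(matrix(1, n, 1, dimnames = list(NULL, object$levels)))
      }
      all <- predict(object$fit, data = as.data.frame(x), predict.all = TRUE,
                     num.threads = 1)$predictions # n x K x trees
      if (length(dim(all)) == 2) all <- array(all, c(1, dim(all)))
      out <- matrix(0, n, dim(all)[2], dimnames = list(NULL, object$levels))
      for (i in seq_len(n)) out[i, ] <- all[i, , member[i]]
      out
    } else if (object$task == "reg") {
      all <- predict(object$fit, data = as.data.frame(x), predict.all = TRUE,
                     num.threads = 1)$predictions # n x trees
      all <- matrix(all, nrow = n)
      matrix(all[cbind(seq_len(n), member)], ncol = 1)
    } else {
      out <- matrix(0, n, object$n_outputs)
      for (j in seq_along(object$fit)) {
        all <- predict(object$fit[[j]], data = as.data.frame(x),
                       predict.all = TRUE, num.threads = 1)$predictions
        all <- matrix(all, nrow = n)
        out[, j] <- all[cbind(seq_len(n), member)]
      }
      out
    }
  } else if (sp == "learner_mvrf") {
    member <- sample.int(object$n_members, n, replace = TRUE)
    if (object$task %in% c("class", "mvclass")) {
      K <- length(object$fit$levels)
      out <- array(0, c(n, object$n_outputs, K),
                   dimnames = list(NULL, NULL, object$fit$levels))
      for (i in seq_len(n)) {
        out[i, , ] <- predict(object$fit, x[i, , drop = FALSE],
                              trees = member[i])[1, , ]
      }
      if (object$task == "class") {
        matrix(out[, 1, ], nrow = n,
               dimnames = list(NULL, dimnames(out)[[3]]))
      } else {
        out
      }
    } else {
      out <- matrix(0, n, object$n_outputs)
      for (i in seq_len(n)) {
        out[i, ] <- predict(object$fit, x[i, , drop = FALSE],
                            trees = member[i])[1, ]
      }
      out
    }
  } else {
    out <- mc_dropout_sample(object$fit, x)
    if (object$task == "class") colnames(out) <- object$levels
    if (object$task == "mvclass") {
      out <- array(out, c(nrow(out), object$fit$n_classes, object$n_outputs))
      out <- aperm(out, c(1, 3, 2))
      dimnames(out) <- list(NULL, NULL, as.character(object$levels))
    }
    out
  }
}

#' Prediction of a single uniformly sampled ensemble member
#'
#' Draws one member of a fitted ensemble uniformly at random (per input row)
#' and returns that member's prediction — the sampling rule used to make
#' forest-based simulations stochastic. Repeated calls under one seed
#' reproduce the same draws; the empirical mean over many draws converges to
#' the ensemble prediction.
#'
#' @param object A fitted learner (from the internal `ml_fit()`, as stored in
#'   framework models).
#' @param x Feature matrix or data frame.
#' @return The sampled member's prediction (probabilities for classification,
#'   responses for regression).
#' @export
sample_member_prediction <- function(object, x) {
  stopifnot(inherits(object, "ms_learner"))
  if (class(object$spec)[1] == "learner_mlp") {
    stop("sample_member_prediction() applies to ensemble learners; ",
         "use mc_dropout_sample() for networks", call. = FALSE)
  }
  ml_sample(object, x)
}

#' Principal-component reduction for wide colony inputs
#'
#' Centred PCA of a training feature matrix, keeping the top `k` components;
#' the returned transform is reusable on new rows (concatenated colony
#' feature vectors are reduced before entering network learners).
#'
#' @param x Training feature matrix.
#' @param k Number of components (must not exceed the feature count).
#' @return A `pca_transform` with elements `rotation`, `center`, `scores`,
#'   `cum_var` (non-decreasing cumulative variance fractions).
#' @export
pca_reduce <- function(x, k) {
  x <- as.matrix(x)
  if (k > ncol(x)) stop("k exceeds the number of features", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k_eff <- min(k, ncol(pc$rotation))
  v <- pc$sdev^2
  structure(
    list(rotation = pc$rotation[, seq_len(k_eff), drop = FALSE],
         center = pc$center, k = k_eff,
         scores = pc$x[, seq_len(k_eff), drop = FALSE],
         cum_var = cumsum(v) / sum(v)),
    class = "pca_transform"
  )
}

#' @export
predict.pca_transform <- function(object, x, ...) {
  x <- as.matrix(x)
  sweep(x, 2, object$center) %*% object$rotation
}

#' Permutation variable importance
#'
#' Loss increase when each predictor column is permuted on a validation set,
#' averaged over `repeats` seeded permutations. Classification loss is the
#' error rate of the most probable class; regression loss is mean squared
#' error summed over outputs.
#'
#' @param object A fitted learner stored in a framework model (internal class
#'   `ms_learner`).
#' @param x Validation feature matrix (> 1 row).
#' @param y Validation responses (labels or numeric matrix).
#' @param repeats Number of permutations per predictor.
#' @param seed Integer seed.
#' @return A tibble (`variable`, `importance`) sorted by decreasing
#'   importance.
#' @export
variable_importance <- function(object, x, y, repeats = 5, seed = 1) {
  x <- as_feature_matrix(x, object$feature_names)
  if (nrow(x) < 2) stop("validation set must have more than one row",
                        call. = FALSE)
  loss <- function(xx) {
    pred <- ml_predict(object, xx)
    if (object$task == "class") {
      cls <- colnames(pred)[max.col(pred, ties.method = "first")]
      mean(cls != as.character(y))
    } else {
      mean(rowSums((as.matrix(y) - pred)^2))
    }
  }
  base <- loss(x)
  set.seed(seed)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    mean(vapply(seq_len(repeats), function(r) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(x)), j]
      loss(xp) - base
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(
    variable = colnames(x) %||% paste0("V", seq_len(ncol(x))),
    importance = imp
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}
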