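# A compact dense neural network with Monte Carlo dropout.
#
# Heads: "linear" (multivariate regression), "softmax" (single categorical
# response), "multi_softmax" (one softmax group per animal, sharing the
# hidden layers; the loss is the sum of per-group cross-entropies). Dropout
# uses the inverted convention and can be kept active at prediction time,
# which turns repeated forward passes into approximate posterior predictive
# draws. Optimiser: Adam. An optional simple recurrent (Elman) first layer is
# trained by truncated backpropagation through time, treating the training
# set as one long time series with hidden-state resets at animal boundaries.

act_fun <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
    tanh = list(f = base::tanh, df = function(z, a) 1 - a^2),
    elu = list(
      f = function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
      df = function(z, a) ifelse(z > 0, 1, a + 1)
    ),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

init_mat <- function(n_out, n_in, activation) {
  sd <- if (activation == "tanh") sqrt(1 / n_in) else sqrt(2 / n_in)
  matrix(stats::rnorm(n_out * n_in, 0, sd), n_out, n_in)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Apply the output head to the final affine activations (n x d_out).
apply_head <- function(z, head, n_groups, n_classes) {
  if (head == "linear") return(z)
  if (head == "softmax") return(softmax_rows(z))
  out <- z
  for (g in seq_len(n_groups)) {
    cols <- ((g - 1) * n_classes + 1):(g * n_classes)
    out[, cols] <- softmax_rows(z[, cols, drop = FALSE])
  }
  out
}

mlp_forward <- function(net, x, dropout_active = FALSE) {
  L <- length(net$W)
  a <- x
  zs <- vector("list", L)
  as <- vector("list", L + 1)
  as[[1]] <- a
  for (l in seq_len(L)) {
    z <- a %*% t(net$W[[l]])
    if (l == 1 && net$recurrent) {
      # recurrent layer handled separately in training; at prediction time
      # run the recurrence over the rows of x in order
      h_prev <- rep(0, nrow(net$W[[1]]))
      h <- matrix(0, nrow(x), nrow(net$W[[1]]))
      for (t in seq_len(nrow(x))) {
        zt <- z[t, ] + as.vector(net$Wh %*% h_prev) + net$b[[1]]
        h[t, ] <- net$act$f(zt)
        h_prev <- h[t, ]
      }
      a <- h
      zs[[l]] <- NULL
    } else {
      z <- sweep(z, 2, net$b[[l]], "+")
      zs[[l]] <- z
      a <- if (l < L) net$act$f(z) else z
    }
    if (l < L && net$dropout > 0 && dropout_active) {
      mask <- matrix(stats::rbinom(length(a), 1, 1 - net$dropout),
                     nrow(a), ncol(a)) / (1 - net$dropout)
      a <- a * mask
    }
    as[[l + 1]] <- a
  }
  out <- apply_head(as[[L + 1]], net$head, net$n_groups, net$n_classes)
  list(output = out, zs = zs, as = as)
}

encode_targets <- function(y, head) {
  if (head == "linear") {
    Y <- as.matrix(y)
    list(Y = Y, n_groups = 1, n_classes = ncol(Y), levels = NULL)
  } else if (head == "softmax") {
    lev <- if (is.factor(y)) levels(y) else sort(unique(y))
    list(Y = one_hot(as.character(y), as.character(lev)) * 1,
         n_groups = 1, n_classes = length(lev), levels = lev)
  } else {
    ym <- as.matrix(y)
    lev <- sort(unique(as.vector(ym)))
    K <- length(lev)
    Y <- matrix(0, nrow(ym), ncol(ym) * K)
    for (g in seq_len(ncol(ym))) {
      Y[, ((g - 1) * K + 1):(g * K)] <-
        one_hot(as.character(ym[, g]), as.character(lev))
    }
    list(Y = Y, n_groups = ncol(ym), n_classes = K, levels = lev)
  }
}

#' Fit a dense neural network with dropout
#'
#' @param x Predictor matrix (rows in time order when `recurrent = TRUE`).
#' @param y Response: numeric matrix/vector (`head = "linear"`), factor or
#'   vector (`head = "softmax"`), or label matrix with a shared alphabet
#'   (`head = "multi_softmax"`).
#' @param head Output head.
#' @param hidden Integer vector of hidden-layer widths.
#' @param activation Hidden activation: `"relu"`, `"tanh"` or `"elu"`.
#' @param dropout Dropout probability `p*` in `[0, 1)`, applied to hidden
#'   activations during training and (for Monte Carlo sampling) at prediction.
#' @param epochs,batch_size,lr Training-loop settings (Adam optimiser).
#' @param recurrent Make the first hidden layer a simple recurrent (Elman)
#'   layer trained by truncated backpropagation through time; `batch_size`
#'   then acts as the truncation window and rows of `x` must be in time
#'   order.
#' @param seq_id Optional vector marking independent sequences (e.g. animal
#'   ids); the recurrent hidden state is reset at sequence boundaries.
#' @param seed Integer seed; fitting is reproducible.
#' @param verbose Print the running loss once per epoch?
#' @return An object of class `mlp_net`.
#' @export
fit_mlp <- function(x, y, head = c("linear", "softmax", "multi_softmax"),
                    hidden = c(32, 16), activation = "relu", dropout = 0.1,
                    epochs = 30, batch_size = 64, lr = 1e-3,
                    recurrent = FALSE, seq_id = NULL, seed = 1,
                    verbose = FALSE) {
  head <- match.arg(head)
  stopifnot(dropout >= 0, dropout < 1)
  x <- as.matrix(x)
  enc <- encode_targets(y, head)
  Y <- enc$Y
  p <- ncol(x)
  d_out <- ncol(Y)
  widths <- c(p, hidden, d_out)
  L <- length(widths) - 1

  set.seed(seed)
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- init_mat(widths[l + 1], widths[l], activation)
    b[[l]] <- rep(0, widths[l + 1])
  }
  Wh <- if (recurrent) init_mat(hidden[1], hidden[1], activation) * 0.5 else NULL

  net <- structure(
    list(W = W, b = b, Wh = Wh, act = act_fun(activation),
         activation = activation, head = head, dropout = dropout,
         recurrent = recurrent, n_groups = enc$n_groups,
         n_classes = enc$n_classes, levels = enc$levels,
         config = list(hidden = hidden, epochs = epochs,
                       batch_size = batch_size, lr = lr, seed = seed),
         fitted = FALSE),
    class = "mlp_net"
  )
  net <- if (recurrent) {
    train_mlp_recurrent(net, x, Y, epochs, batch_size, lr, seq_id, verbose)
  } else {
    train_mlp_dense(net, x, Y, epochs, batch_size, lr, verbose)
  }
  net$fitted <- TRUE
  net
}

adam_state <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, s), v = array(0, s)))
}

adam_update <- function(par, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# Gradient of the loss w.r.t. the final affine activations.
output_delta <- function(P, Y, head, n) {
  (P - Y) / n # holds for softmax/CE per group and for linear/mean-SSE (x2)
}

train_mlp_dense <- function(net, x, Y, epochs, batch_size, lr, verbose) {
  n <- nrow(x)
  L <- length(net$W)
  opt_W <- adam_state(lapply(net$W, dim))
  opt_b <- adam_state(lapply(net$b, length))
  step <- 0
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    loss_ep <- 0
    for (start in seq(1, n, by = batch_size)) {
      rows <- idx[start:min(start + batch_size - 1, n)]
      xb <- x[rows, , drop = FALSE]
      yb <- Y[rows, , drop = FALSE]
      nb <- nrow(xb)
      fw <- mlp_forward_dense(net, xb, dropout_active = TRUE)
      P <- apply_head(fw$as[[L + 1]], net$head, net$n_groups, net$n_classes)
      loss_ep <- loss_ep + batch_loss(P, yb, net$head)
      dZ <- output_delta(P, yb, net$head, nb)
      if (net$head == "linear") dZ <- 2 * dZ
      grads <- backprop_dense(net, fw, dZ)
      step <- step + 1
      for (l in seq_len(L)) {
        up <- adam_update(net$W[[l]], grads$dW[[l]], opt_W[[l]], lr, step)
        net$W[[l]] <- up$par; opt_W[[l]] <- up$state
        up <- adam_update(net$b[[l]], grads$db[[l]], opt_b[[l]], lr, step)
        net$b[[l]] <- up$par; opt_b[[l]] <- up$state
      }
    }
    if (verbose) message(sprintf("epoch %d loss %.5f", ep, loss_ep))
  }
  net
}

batch_loss <- function(P, Y, head) {
  if (head == "linear") {
    mean(rowSums((P - Y)^2))
  } else {
    -mean(rowSums(Y * log(pmax(P, 1e-12))))
  }
}

# Forward through dense layers only, recording pre-activations, activations
# and dropout masks.
mlp_forward_dense <- function(net, x, dropout_active = FALSE) {
  L <- length(net$W)
  as <- vector("list", L + 1)
  zs <- vector("list", L)
  masks <- vector("list", L)
  as[[1]] <- x
  a <- x
  for (l in seq_len(L)) {
    z <- sweep(a %*% t(net$W[[l]]), 2, net$b[[l]], "+")
    zs[[l]] <- z
    a <- if (l < L) net$act$f(z) else z
    if (l < L && net$dropout > 0 && dropout_active) {
      mask <- matrix(stats::rbinom(length(a), 1, 1 - net$dropout),
                     nrow(a), ncol(a)) / (1 - net$dropout)
      a <- a * mask
      masks[[l]] <- mask
    }
    as[[l + 1]] <- a
  }
  list(as = as, zs = zs, masks = masks)
}

backprop_dense <- function(net, fw, dZ_out) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  dZ <- dZ_out
  for (l in L:1) {
    dW[[l]] <- t(dZ) %*% fw$as[[l]]
    db[[l]] <- colSums(dZ)
    if (l > 1) {
      dA <- dZ %*% net$W[[l]]
      if (!is.null(fw$masks[[l - 1]])) dA <- dA * fw$masks[[l - 1]]
      a_prev <- net$act$f(fw$zs[[l - 1]])
      dZ <- dA * net$act$df(fw$zs[[l - 1]], a_prev)
    }
  }
  list(dW = dW, db = db)
}

train_mlp_recurrent <- function(net, x, Y, epochs, window, lr, seq_id,
                                verbose) {
  n <- nrow(x)
  L <- length(net$W)
  h1 <- nrow(net$W[[1]])
  if (is.null(seq_id)) seq_id <- rep(1L, n)
  opt_W <- adam_state(lapply(net$W, dim))
  opt_b <- adam_state(lapply(net$b, length))
  opt_Wh <- adam_state(list(dim(net$Wh)))[[1]]
  step <- 0
  starts <- seq(1, n, by = window)
  for (ep in seq_len(epochs)) {
    h_prev <- rep(0, h1)
    loss_ep <- 0
    for (s0 in starts) {
      rows <- s0:min(s0 + window - 1, n)
      if (s0 > 1 && seq_id[s0] != seq_id[s0 - 1]) h_prev <- rep(0, h1)
      xb <- x[rows, , drop = FALSE]
      yb <- Y[rows, , drop = FALSE]
      w <- length(rows)
      # forward: recurrent first layer
      Z1 <- xb %*% t(net$W[[1]])
      H <- matrix(0, w, h1)
      Z1full <- matrix(0, w, h1)
      hp <- h_prev
      for (t in seq_len(w)) {
        zt <- Z1[t, ] + as.vector(net$Wh %*% hp) + net$b[[1]]
        Z1full[t, ] <- zt
        H[t, ] <- net$act$f(zt)
        hp <- H[t, ]
      }
      mask1 <- NULL
      Hd <- H
      if (net$dropout > 0) {
        mask1 <- matrix(stats::rbinom(w * h1, 1, 1 - net$dropout), w, h1) /
          (1 - net$dropout)
        Hd <- H * mask1
      }
      # forward: remaining dense layers on the window as a batch
      sub <- net
      sub$W <- net$W[-1]; sub$b <- net$b[-1]
      fw <- mlp_forward_dense(sub, Hd, dropout_active = TRUE)
      P <- apply_head(fw$as[[length(sub$W) + 1]], net$head, net$n_groups,
                      net$n_classes)
      loss_ep <- loss_ep + batch_loss(P, yb, net$head)
      dZ <- output_delta(P, yb, net$head, w)
      if (net$head == "linear") dZ <- 2 * dZ
      gr <- backprop_dense(sub, fw, dZ)
      dH <- backprop_dense_input(sub, fw, dZ)
      if (!is.null(mask1)) dH <- dH * mask1
      # backward through time
      dW1 <- matrix(0, h1, ncol(xb))
      dWh <- matrix(0, h1, h1)
      db1 <- rep(0, h1)
      dh_acc <- rep(0, h1)
      for (t in w:1) {
        dz <- (dH[t, ] + dh_acc) * net$act$df(Z1full[t, ], H[t, ])
        dW1 <- dW1 + outer(dz, xb[t, ])
        hprev_t <- if (t == 1) h_prev else H[t - 1, ]
        dWh <- dWh + outer(dz, hprev_t)
        db1 <- db1 + dz
        dh_acc <- as.vector(t(net$Wh) %*% dz)
      }
      step <- step + 1
      up <- adam_update(net$W[[1]], dW1, opt_W[[1]], lr, step)
      net$W[[1]] <- up$par; opt_W[[1]] <- up$state
      up <- adam_update(net$b[[1]], db1, opt_b[[1]], lr, step)
      net$b[[1]] <- up$par; opt_b[[1]] <- up$state
      up <- adam_update(net$Wh, dWh, opt_Wh, lr, step)
      net$Wh <- up$par; opt_Wh <- up$state
      for (l in seq_along(sub$W)) {
        up <- adam_update(net$W[[l + 1]], gr$dW[[l]], opt_W[[l + 1]], lr, step)
        net$W[[l + 1]] <- up$par; opt_W[[l + 1]] <- up$state
        up <- adam_update(net$b[[l + 1]], gr$db[[l]], opt_b[[l + 1]], lr, step)
        net$b[[l + 1]] <- up$par; opt_b[[l + 1]] <- up$state
      }
      h_prev <- H[w, ]
    }
    if (verbose) message(sprintf("epoch %d loss %.5f", ep, loss_ep))
  }
  net
}

# Gradient of the dense stack's loss w.r.t. its input matrix.
backprop_dense_input <- function(net, fw, dZ_out) {
  L <- length(net$W)
  dZ <- dZ_out
  for (l in L:1) {
    dA <- dZ %*% net$W[[l]]
    if (l > 1) {
      if (!is.null(fw$masks[[l - 1]])) dA <- dA * fw$masks[[l - 1]]
      a_prev <- net$act$f(fw$zs[[l - 1]])
      dZ <- dA * net$act$df(fw$zs[[l - 1]], a_prev)
    }
  }
  dA
}

#' Deterministic prediction from a fitted network
#'
#' Dropout is switched off (the inverted-dropout convention needs no test-time
#' rescaling).
#'
#' @param object A fitted `mlp_net`.
#' @param x Predictor matrix (time order matters for recurrent networks).
#' @param ... Unused.
#' @return Output matrix (probabilities for classification heads).
#' @export
predict.mlp_net <- function(object, x, ...) {
  if (!isTRUE(object$fitted)) stop("network is not fitted", call. = FALSE)
  fw <- mlp_forward(object, as.matrix(x), dropout_active = FALSE)
  fw$output
}

#' Monte Carlo dropout draw from a fitted network
#'
#' One stochastic forward pass with dropout active, approximating a draw from
#' the posterior predictive distribution. With `dropout = 0` the draw is the
#' deterministic prediction.
#'
#' @param net A fitted `mlp_net`.
#' @param x Predictor matrix.
#' @return Output matrix for one draw.
#' @export
mc_dropout_sample <- function(net, x) {
  if (!isTRUE(net$fitted)) stop("network is not fitted", call. = FALSE)
  fw <- mlp_forward(net, as.matrix(x), dropout_active = TRUE)
  fw$output
}
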