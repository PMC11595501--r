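# Layer primitives: 3D convolution wrapper, LSTM cell and batched BPTT,
# dense/softmax, dropout, Adam. The convolution inner loops live in
# src/nn.cpp; everything here is plain matrix algebra.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Specification of one 3D convolutional layer
#'
#' @param n_filters number of output feature maps.
#' @param kernel integer vector of 3 kernel extents (default \code{c(3,3,3)}).
#' @param activation "relu" (default), "tanh" or "linear". The reference
#'   formulation of 3D convolution writes tanh; the architectures use ReLU
#'   throughout, so the nonlinearity is a per-layer parameter.
#' @param w kernel weights, array \code{kd x kh x kw x Cin x n_filters}.
#' @param b per-filter bias vector of length \code{n_filters}.
#' @param padding only \code{"same"} (zero fill) is supported.
#' @return Object of class \code{conv3d_layer_spec}.
#' @export
conv3d_layer_spec <- function(n_filters, kernel = c(3, 3, 3),
                              activation = "relu", w, b, padding = "same") {
  stopifnot(length(kernel) == 3, all(kernel >= 1),
            activation %in% c("relu", "tanh", "linear"),
            identical(padding, "same"))
  if (length(dim(w)) != 5 || any(dim(w)[1:3] != kernel) ||
      dim(w)[5] != n_filters) {
    stop("w must have dim (kd, kh, kw, Cin, n_filters)", call. = FALSE)
  }
  if (length(b) != n_filters) stop("b length must equal n_filters", call. = FALSE)
  structure(list(n_filters = as.integer(n_filters), kernel = as.integer(kernel),
                 activation = activation, w = w, b = as.numeric(b),
                 padding = padding),
            class = "conv3d_layer_spec")
}

#' Forward pass of one 3D convolutional layer
#'
#' Computes, at every position of the input volume, the triple sum of the
#' kernel window over all input feature maps plus the bias, under "same"
#' zero padding, followed by the layer's activation. Output spatial/temporal
#' extents equal the input extents.
#'
#' @param input numeric 4D array \code{D x H x W x Cin}.
#' @param layer a \code{\link{conv3d_layer_spec}} whose kernel's input
#'   channel extent matches \code{Cin}.
#' @return Numeric 4D array \code{D x H x W x n_filters}.
#' @export
conv3d_forward <- function(input, layer) {
  stopifnot(inherits(layer, "conv3d_layer_spec"))
  d <- dim(input)
  if (length(d) != 4) stop("input must be a 4D array", call. = FALSE)
  if (d[4] != dim(layer$w)[4]) {
    stop("input channel count does not match kernel", call. = FALSE)
  }
  k <- dim(layer$w)
  wm <- matrix(layer$w, nrow = prod(k[1:4]), ncol = k[5])
  out <- conv3d_fwd_cpp(input, as.integer(d), wm, as.integer(k[1:3]), layer$b)
  switch(layer$activation,
         relu = pmax(out, 0),
         tanh = tanh(out),
         linear = out)
}

#' Specification of one LSTM cell
#'
#' Gates are computed from the concatenation \code{[h_prev, x]}, so each
#' weight matrix has \code{units + input_dim} rows and \code{units} columns.
#'
#' @param units hidden state size.
#' @param W_i,W_f,W_c,W_o gate weight matrices
#'   (\code{(units + input_dim) x units}).
#' @param b_i,b_f,b_c,b_o gate bias vectors (length \code{units}).
#' @return Object of class \code{lstm_cell_spec}.
#' @export
lstm_cell_spec <- function(units, W_i, W_f, W_c, W_o, b_i, b_f, b_c, b_o) {
  units <- as.integer(units)
  for (W in list(W_i, W_f, W_c, W_o)) {
    if (ncol(W) != units) stop("gate weight matrices must have `units` columns", call. = FALSE)
    if (nrow(W) != nrow(W_i)) stop("gate weight matrices must agree in shape", call. = FALSE)
  }
  for (b in list(b_i, b_f, b_c, b_o)) {
    if (length(b) != units) stop("gate biases must have length `units`", call. = FALSE)
  }
  structure(list(units = units, W_i = W_i, W_f = W_f, W_c = W_c, W_o = W_o,
                 b_i = b_i, b_f = b_f, b_c = b_c, b_o = b_o),
            class = "lstm_cell_spec")
}

#' One LSTM time step
#'
#' Computes the gate activations and state update
#' \deqn{i = \sigma(W_i [h_{t-1}, x_t] + b_i), \quad
#'       f = \sigma(W_f [h_{t-1}, x_t] + b_f),}
#' \deqn{c_t = f \odot c_{t-1} + i \odot \tanh(W_c [h_{t-1}, x_t] + b_c),}
#' \deqn{o = \sigma(W_o [h_{t-1}, x_t] + b_o), \quad
#'       h_t = o \odot \tanh(c_t).}
#'
#' @param x input vector at time t (length \code{input_dim}).
#' @param h_prev,c_prev previous output and memory state (length
#'   \code{units}).
#' @param cell a \code{\link{lstm_cell_spec}}.
#' @return List with \code{h}, \code{c} and the gate activations \code{i},
#'   \code{f}, \code{o}.
#' @export
lstm_step <- function(x, h_prev, c_prev, cell) {
  stopifnot(inherits(cell, "lstm_cell_spec"))
  u <- cell$units
  if (length(h_prev) != u || length(c_prev) != u) {
    stop("h_prev and c_prev must have length `units`", call. = FALSE)
  }
  if (length(x) + u != nrow(cell$W_i)) {
    stop("input dimension does not match cell weights", call. = FALSE)
  }
  z <- c(h_prev, x)
  i <- .sigmoid(drop(z %*% cell$W_i) + cell$b_i)
  f <- .sigmoid(drop(z %*% cell$W_f) + cell$b_f)
  g <- tanh(drop(z %*% cell$W_c) + cell$b_c)
  o <- .sigmoid(drop(z %*% cell$W_o) + cell$b_o)
  cc <- f * c_prev + i * g
  h <- o * tanh(cc)
  list(h = h, c = cc, i = i, f = f, o = o)
}

# ---- internal batched layers (training path) ------------------------------

# Batched LSTM over a sequence. X: list of T matrices (B x d). W: combined
# ((d + u) x 4u) with column blocks [i, f, g, o]; b: length 4u.
.lstm_layer_fwd <- function(X, W, b, return_sequences = FALSE, reverse = FALSE) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  u <- length(b) / 4L
  h <- matrix(0, B, u)
  cc <- matrix(0, B, u)
  order_t <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  cache <- vector("list", Tn)
  H <- if (return_sequences) vector("list", Tn) else NULL
  for (t in order_t) {
    zin <- cbind(h, X[[t]])
    z <- zin %*% W
    z <- sweep(z, 2, b, "+")
    i <- .sigmoid(z[, 1:u, drop = FALSE])
    f <- .sigmoid(z[, (u + 1):(2 * u), drop = FALSE])
    g <- tanh(z[, (2 * u + 1):(3 * u), drop = FALSE])
    o <- .sigmoid(z[, (3 * u + 1):(4 * u), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    cache[[t]] <- list(zin = zin, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, c = cc, tc = tc)
    if (return_sequences) H[[t]] <- h
  }
  list(h = h, H = H, cache = cache, reverse = reverse, u = u)
}

# dh_last: gradient on the final state (B x u); dH: list of per-step
# gradients (for return_sequences consumers), or NULL.
.lstm_layer_bwd <- function(fwd, X, W, dh_last = NULL, dH = NULL) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  u <- fwd$u
  d <- ncol(X[[1]])
  dW <- matrix(0, d + u, 4 * u)
  db <- numeric(4 * u)
  dX <- vector("list", Tn)
  dh <- matrix(0, B, u)
  dc <- matrix(0, B, u)
  order_t <- if (fwd$reverse) rev(seq_len(Tn)) else seq_len(Tn)
  first <- TRUE
  for (t in rev(order_t)) {
    ch <- fwd$cache[[t]]
    if (first && !is.null(dh_last)) dh <- dh + dh_last
    first <- FALSE
    if (!is.null(dH)) dh <- dh + dH[[t]]
    do_ <- dh * ch$tc
    dc <- dc + dh * ch$o * (1 - ch$tc^2)
    di <- dc * ch$g
    dg <- dc * ch$i
    df <- dc * ch$c_prev
    dc <- dc * ch$f
    dz <- cbind(di * ch$i * (1 - ch$i),
                df * ch$f * (1 - ch$f),
                dg * (1 - ch$g^2),
                do_ * ch$o * (1 - ch$o))
    dW <- dW + crossprod(ch$zin, dz)
    db <- db + colSums(dz)
    dzin <- dz %*% t(W)
    dh <- dzin[, 1:u, drop = FALSE]
    dX[[t]] <- dzin[, (u + 1):(u + d), drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean categorical cross-entropy; Y is a one-hot matrix
.cross_entropy <- function(probs, Y) {
  -mean(rowSums(Y * log(pmax(probs, 1e-12))))
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

.adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
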