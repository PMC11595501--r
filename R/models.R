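# The three hybrid architectures: a shared 3D conv/pool stack
# (Conv16 -> Pool -> Conv32 -> Pool -> Conv64 -> Pool -> Flatten ->
# Reshape(16 timesteps)) followed by one of three recurrent heads, a 40%
# dropout layer and a dense softmax output.
#
# Flatten convention: the (D', H', W', 64) feature volume is flattened in
# row-major order (channel fastest) and reshaped to (16, flat/16); for the
# reference input (16, 64, 64, 3) this is (2, 8, 8, 64) -> 8192 -> (16, 512).

.flatten_rowmajor <- function(arr) as.vector(aperm(arr, c(4, 3, 2, 1)))

.unflatten_rowmajor <- function(vec, dims) {
  aperm(array(vec, dim = rev(dims)), c(4, 3, 2, 1))
}

.glorot <- function(nin, nout, n = nin * nout) {
  lim <- sqrt(6 / (nin + nout))
  runif(n, -lim, lim)
}

.he <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

#' Build one of the three hybrid 3DCNN + recurrent models
#'
#' All variants share the convolutional stack: three 3x3x3 "same"-padded
#' ReLU convolutions with 16, 32 and 64 filters, each followed by
#' non-overlapping 2x2x2 max pooling, then a row-major flatten and a reshape
#' into 16 timesteps. The heads differ:
#' \describe{
#'   \item{\code{lstm}}{one 64-unit LSTM, final state only (64 features).}
#'   \item{\code{stack_lstm}}{64-unit LSTM returning the full sequence,
#'     feeding a second 64-unit LSTM whose final state is kept.}
#'   \item{\code{bilstm}}{forward and backward 64-unit LSTMs; their final
#'     states are concatenated (128 features).}
#' }
#' The head output passes through 40\% dropout and a dense softmax layer
#' over \code{n_classes}. Weights are initialized with a seeded fan-in
#' scheme (He-normal for ReLU convolutions, Glorot-uniform for recurrent
#' and dense weights, forget-gate bias 1).
#'
#' @param variant one of \code{"lstm"}, \code{"stack_lstm"},
#'   \code{"bilstm"}.
#' @param n_classes number of output classes (>= 2).
#' @param input_shape integer vector \code{(frames, height, width,
#'   channels)}; every one of the first three extents must be divisible by
#'   8 (three 2x pools), default \code{c(16, 64, 64, 3)}.
#' @param dropout_rate dropout probability after the recurrent head
#'   (default 0.4).
#' @param units recurrent hidden size (default 64).
#' @param seed integer seed for weight initialization.
#' @return Object of class \code{topodecode_model}.
#' @examples
#' m <- build_model("bilstm", n_classes = 2, input_shape = c(8, 8, 8, 1))
#' count_params(m)
#' @export
build_model <- function(variant = c("lstm", "stack_lstm", "bilstm"),
                        n_classes, input_shape = c(16, 64, 64, 3),
                        dropout_rate = 0.4, units = 64, seed = 0) {
  variant <- match.arg(variant)
  stopifnot(n_classes >= 2, length(input_shape) == 4)
  if (any(input_shape[1:3] %% 8 != 0)) {
    stop("input shape extents must be divisible by 8 for three 2x2x2 poolings",
         call. = FALSE)
  }
  n_timesteps <- 16L
  filt <- c(16L, 32L, 64L)
  cin <- c(input_shape[4], filt[1], filt[2])
  out_dims <- c(input_shape[1:3] / 8, filt[3])
  flat <- prod(out_dims)
  if (flat %% n_timesteps != 0) {
    stop("flattened feature count not divisible into 16 timesteps", call. = FALSE)
  }
  feat <- flat / n_timesteps
  params <- .with_seed(seed, function() {
    p <- list()
    for (l in 1:3) {
      fan_in <- 27 * cin[l]
      p[[paste0("conv", l, "_w")]] <-
        array(.he(fan_in, fan_in * filt[l]), dim = c(3, 3, 3, cin[l], filt[l]))
      p[[paste0("conv", l, "_b")]] <- numeric(filt[l])
    }
    lstm_init <- function(d) {
      W <- matrix(.glorot(d + units, units, (d + units) * 4 * units),
                  d + units, 4 * units)
      b <- numeric(4 * units)
      b[(units + 1):(2 * units)] <- 1  # forget gate bias
      list(W = W, b = b)
    }
    head_dim <- units
    if (variant == "lstm") {
      ini <- lstm_init(feat)
      p$lstm1_W <- ini$W; p$lstm1_b <- ini$b
    } else if (variant == "stack_lstm") {
      ini <- lstm_init(feat)
      p$lstm1_W <- ini$W; p$lstm1_b <- ini$b
      ini2 <- lstm_init(units)
      p$lstm2_W <- ini2$W; p$lstm2_b <- ini2$b
    } else {
      inif <- lstm_init(feat)
      inib <- lstm_init(feat)
      p$lstmf_W <- inif$W; p$lstmf_b <- inif$b
      p$lstmb_W <- inib$W; p$lstmb_b <- inib$b
      head_dim <- 2L * units
    }
    p$dense_W <- matrix(.glorot(head_dim, n_classes, head_dim * n_classes),
                        head_dim, n_classes)
    p$dense_b <- numeric(n_classes)
    p
  })
  structure(list(variant = variant, n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape),
                 n_timesteps = n_timesteps,
                 dropout_rate = dropout_rate, units = as.integer(units),
                 conv_out_dims = as.integer(out_dims),
                 flat_dim = as.integer(flat), feat_dim = as.integer(feat),
                 head_dim = if (variant == "bilstm") 2L * units else units,
                 params = params, seed = as.integer(seed)),
            class = "topodecode_model")
}

#' Total number of trainable parameters
#' @param model a \code{\link{build_model}} result.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "topodecode_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.topodecode_model <- function(x, ...) {
  cat(sprintf("topodecode hybrid model '%s'\n", x$variant))
  cat(sprintf("  input %s -> conv/pool stack -> (%s) -> reshape (%d x %d)\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$conv_out_dims, collapse = "x"),
              x$n_timesteps, x$feat_dim))
  cat(sprintf("  head dim %d, dropout %.2f, softmax over %d classes\n",
              x$head_dim, x$dropout_rate, x$n_classes))
  cat(sprintf("  trainable parameters: %d\n", count_params(x)))
  invisible(x)
}

# conv/pool stack forward for one sample. x: (D,H,W,C) array.
.conv_stack_fwd <- function(x, params, keep_cache = TRUE) {
  cache <- list(x = if (keep_cache) x else NULL)
  a <- x
  for (l in 1:3) {
    w <- params[[paste0("conv", l, "_w")]]
    b <- params[[paste0("conv", l, "_b")]]
    k <- dim(w)
    wm <- matrix(w, nrow = prod(k[1:4]), ncol = k[5])
    pre <- conv3d_fwd_cpp(a, as.integer(dim(a)), wm, as.integer(k[1:3]), b)
    act <- pmax(pre, 0)
    pl <- maxpool3d_fwd_cpp(act, as.integer(dim(act)))
    if (keep_cache) {
      cache[[paste0("in", l)]] <- a
      cache[[paste0("mask", l)]] <- pre > 0
      cache[[paste0("actdim", l)]] <- dim(act)
      cache[[paste0("argmax", l)]] <- pl$argmax
    }
    a <- pl$y
  }
  list(out = a, cache = cache)
}

# backward through the conv/pool stack for one sample; returns per-layer
# weight grads and (optionally) nothing for the input.
.conv_stack_bwd <- function(dout, params, cache) {
  grads <- list()
  d <- dout
  for (l in 3:1) {
    d <- maxpool3d_bwd_cpp(d, cache[[paste0("argmax", l)]],
                           as.integer(cache[[paste0("actdim", l)]]))
    d <- d * cache[[paste0("mask", l)]]
    w <- params[[paste0("conv", l, "_w")]]
    k <- dim(w)
    wm <- matrix(w, nrow = prod(k[1:4]), ncol = k[5])
    a_in <- cache[[paste0("in", l)]]
    n_pos <- prod(dim(a_in)[1:3])
    bwd <- conv3d_bwd_cpp(a_in, as.integer(dim(a_in)), wm, as.integer(k[1:3]),
                          matrix(d, n_pos, k[5]))
    grads[[paste0("conv", l, "_w")]] <- array(bwd$dw, dim = k)
    grads[[paste0("conv", l, "_b")]] <- bwd$db
    d <- bwd$dx
  }
  grads
}

# Full forward pass over a batch. X: array (B, D, H, W, C). Returns probs
# and, if training, the caches needed for the backward pass.
.model_fwd <- function(model, X, training = FALSE, drop_mask = NULL) {
  B <- dim(X)[1]
  p <- model$params
  flat <- matrix(0, B, model$flat_dim)
  conv_caches <- if (training) vector("list", B) else NULL
  for (b in seq_len(B)) {
    x <- array(X[b, , , , ], dim = model$input_shape)
    cs <- .conv_stack_fwd(x, p, keep_cache = training)
    flat[b, ] <- .flatten_rowmajor(cs$out)
    if (training) conv_caches[[b]] <- cs$cache
  }
  Tn <- model$n_timesteps
  feat <- model$feat_dim
  S <- lapply(seq_len(Tn), function(t) {
    flat[, ((t - 1) * feat + 1):(t * feat), drop = FALSE]
  })
  head_caches <- list()
  if (model$variant == "lstm") {
    f1 <- .lstm_layer_fwd(S, p$lstm1_W, p$lstm1_b)
    hout <- f1$h
    head_caches$f1 <- f1
  } else if (model$variant == "stack_lstm") {
    f1 <- .lstm_layer_fwd(S, p$lstm1_W, p$lstm1_b, return_sequences = TRUE)
    f2 <- .lstm_layer_fwd(f1$H, p$lstm2_W, p$lstm2_b)
    hout <- f2$h
    head_caches$f1 <- f1
    head_caches$f2 <- f2
  } else {
    ff <- .lstm_layer_fwd(S, p$lstmf_W, p$lstmf_b)
    fb <- .lstm_layer_fwd(S, p$lstmb_W, p$lstmb_b, reverse = TRUE)
    hout <- cbind(ff$h, fb$h)
    head_caches$ff <- ff
    head_caches$fb <- fb
  }
  if (training && model$dropout_rate > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- matrix(
        (runif(length(hout)) >= model$dropout_rate) / (1 - model$dropout_rate),
        nrow(hout), ncol(hout))
    }
    hdrop <- hout * drop_mask
  } else {
    hdrop <- hout
  }
  logits <- sweep(hdrop %*% p$dense_W, 2, p$dense_b, "+")
  probs <- .softmax(logits)
  list(probs = probs, hout = hout, hdrop = hdrop, drop_mask = drop_mask,
       S = S, conv_caches = conv_caches, head_caches = head_caches)
}

# Full backward pass; Y is the one-hot target matrix. Returns grads named
# like the params.
.model_bwd <- function(model, fwd, Y) {
  B <- nrow(Y)
  p <- model$params
  grads <- list()
  dlogits <- (fwd$probs - Y) / B
  grads$dense_W <- crossprod(fwd$hdrop, dlogits)
  grads$dense_b <- colSums(dlogits)
  dhdrop <- dlogits %*% t(p$dense_W)
  dhout <- if (!is.null(fwd$drop_mask)) dhdrop * fwd$drop_mask else dhdrop
  hc <- fwd$head_caches
  if (model$variant == "lstm") {
    b1 <- .lstm_layer_bwd(hc$f1, fwd$S, p$lstm1_W, dh_last = dhout)
    grads$lstm1_W <- b1$dW; grads$lstm1_b <- b1$db
    dS <- b1$dX
  } else if (model$variant == "stack_lstm") {
    b2 <- .lstm_layer_bwd(hc$f2, hc$f1$H, p$lstm2_W, dh_last = dhout)
    grads$lstm2_W <- b2$dW; grads$lstm2_b <- b2$db
    b1 <- .lstm_layer_bwd(hc$f1, fwd$S, p$lstm1_W, dH = b2$dX)
    grads$lstm1_W <- b1$dW; grads$lstm1_b <- b1$db
    dS <- b1$dX
  } else {
    u <- model$units
    bf <- .lstm_layer_bwd(hc$ff, fwd$S, p$lstmf_W,
                          dh_last = dhout[, 1:u, drop = FALSE])
    bb <- .lstm_layer_bwd(hc$fb, fwd$S, p$lstmb_W,
                          dh_last = dhout[, (u + 1):(2 * u), drop = FALSE])
    grads$lstmf_W <- bf$dW; grads$lstmf_b <- bf$db
    grads$lstmb_W <- bb$dW; grads$lstmb_b <- bb$db
    dS <- lapply(seq_along(bf$dX), function(t) bf$dX[[t]] + bb$dX[[t]])
  }
  feat <- model$feat_dim
  dflat <- matrix(0, B, model$flat_dim)
  for (t in seq_len(model$n_timesteps)) {
    dflat[, ((t - 1) * feat + 1):(t * feat)] <- dS[[t]]
  }
  conv_grads <- NULL
  for (b in seq_len(B)) {
    dout <- .unflatten_rowmajor(dflat[b, ], model$conv_out_dims)
    g <- .conv_stack_bwd(dout, p, fwd$conv_caches[[b]])
    if (is.null(conv_grads)) {
      conv_grads <- g
    } else {
      for (nm in names(g)) conv_grads[[nm]] <- conv_grads[[nm]] + g[[nm]]
    }
  }
  c(grads, conv_grads)
}

#' Class probabilities for a batch of topomap sequences
#'
#' Runs the model forward in evaluation mode (dropout disabled).
#'
#' @param model a \code{\link{build_model}} result.
#' @param X either a numeric array \code{(n, frames, height, width,
#'   channels)} or a \code{trial_set} of \code{topomap_sequence}s.
#' @return Numeric matrix \code{n x n_classes} of softmax probabilities
#'   (rows sum to 1); column names are the class labels when \code{X} is a
#'   trial set.
#' @export
model_predict <- function(model, X) {
  stopifnot(inherits(model, "topodecode_model"))
  cls <- NULL
  if (inherits(X, "trial_set")) {
    cls <- X$classes
    X <- .stack_sequences(X)$X
  }
  probs <- .model_fwd(model, X, training = FALSE)$probs
  if (!is.null(cls) && length(cls) == ncol(probs)) colnames(probs) <- cls
  probs
}

# trial_set of topomap_sequences -> list(X array (n,T,H,W,C), y int labels)
.stack_sequences <- function(set) {
  stopifnot(inherits(set, "trial_set"))
  n <- length(set)
  d <- dim(set$trials[[1]]$frames)
  X <- array(0, dim = c(n, d))
  for (i in seq_len(n)) X[i, , , , ] <- set$trials[[i]]$frames
  y <- match(set_labels(set), set$classes)
  list(X = X, y = y)
}
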