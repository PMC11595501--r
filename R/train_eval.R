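# Subject-dependent training and evaluation: Adam + categorical
# cross-entropy, per-subject accuracy and the cross-subject average.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4 and
#' batch size 32. The epoch budget and stopping rule are implementation
#' choices (50 epochs, early stopping on training loss with patience 10);
#' there is no validation split in the protocol, so early stopping monitors
#' the training loss.
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param batch_size minibatch size (default 32).
#' @param epochs maximum epochs (default 50).
#' @param early_stop_patience epochs without training-loss improvement
#'   before stopping (default 10); \code{Inf} disables early stopping.
#' @param seed integer seed for shuffling and dropout.
#' @return Object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32, epochs = 50,
                         early_stop_patience = 10, seed = 0) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stop_patience = early_stop_patience,
                 loss = "categorical_crossentropy",
                 optimizer = "adam",
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a hybrid model on the training half of a split
#'
#' Minimizes categorical cross-entropy with Adam on shuffled minibatches.
#' Training is fully deterministic given the config seed (shuffling and
#' dropout draw from a private RNG stream).
#'
#' @param model a \code{\link{build_model}} result.
#' @param split a \code{\link{make_split}} result whose trial sets contain
#'   \code{topomap_sequence}s matching the model input shape (use
#'   \code{\link{transform_set}} first if needed).
#' @param config a \code{\link{train_config}}.
#' @return List with \code{model} (trained), \code{history} (numeric vector
#'   of per-epoch mean training losses) and \code{epochs_run}.
#' @export
train <- function(model, split, config = train_config()) {
  stopifnot(inherits(model, "topodecode_model"),
            inherits(split, "dataset_split"),
            inherits(config, "train_config"))
  if (length(split$train) < 1) stop("empty training set", call. = FALSE)
  st <- .stack_sequences(split$train)
  d <- dim(st$X)[-1]
  if (!all(d == model$input_shape)) {
    stop(sprintf("sequence shape (%s) does not match model input shape (%s)",
                 paste(d, collapse = ","),
                 paste(model$input_shape, collapse = ",")), call. = FALSE)
  }
  n <- dim(st$X)[1]
  Y <- matrix(0, n, model$n_classes)
  Y[cbind(seq_len(n), st$y)] <- 1
  params <- model$params
  adam <- .adam_init(params)
  history <- numeric(0)
  best <- Inf
  stale <- 0
  # private RNG stream for shuffling and dropout
  if (exists(".Random.seed", envir = globalenv())) {
    old_rng <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_rng, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(config$seed)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      model$params <- params
      fwd <- .model_fwd(model, st$X[idx, , , , , drop = FALSE],
                        training = TRUE)
      loss <- .cross_entropy(fwd$probs, Y[idx, , drop = FALSE])
      grads <- .model_bwd(model, fwd, Y[idx, , drop = FALSE])
      upd <- .adam_update(params, grads, adam, config$learning_rate)
      params <- upd$params
      adam <- upd$state
      losses <- c(losses, loss)
    }
    epoch_loss <- mean(losses)
    history[epoch] <- epoch_loss
    if (epoch_loss < best - 1e-6) {
      best <- epoch_loss
      stale <- 0
    } else {
      stale <- stale + 1
      if (stale >= config$early_stop_patience) break
    }
  }
  model$params <- params
  list(model = model, history = history, epochs_run = length(history))
}

#' Classification accuracy in percent
#'
#' \code{100 * (number of correct predictions) / (total predictions)}.
#'
#' @param predictions,truth equal-length label vectors.
#' @return Accuracy in percent.
#' @examples
#' accuracy(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) == 0 || length(predictions) != length(truth)) {
    stop("predictions and truth must be equal-length, non-empty", call. = FALSE)
  }
  100 * mean(predictions == truth)
}

#' Cross-subject average accuracy in percent
#'
#' The arithmetic mean of the per-subject accuracies,
#' \eqn{\sum_{s=1}^{N} \mathrm{Accuracy}_s / N}. Full precision is
#' retained; result tables round to one decimal for display.
#'
#' @param per_subject numeric vector of per-subject accuracies (percent).
#' @return Average accuracy in percent.
#' @export
average_accuracy <- function(per_subject) {
  if (length(per_subject) == 0) stop("empty accuracy list", call. = FALSE)
  mean(per_subject)
}

# half-up rounding to `digits`, the convention used in printed tables
.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Run a subject-dependent experiment
#'
#' For each subject: balance classes, make the stratified 80/20 split,
#' transform trials to topomap sequences (raw trial sets only), build and
#' train the model, and measure test accuracy; then aggregate the
#' per-subject accuracies into the cross-subject average. Subjects missing
#' one of the requested classes are skipped with a warning and excluded
#' from the average's \code{N}.
#'
#' @param data named list mapping subject ID to a \code{trial_set} (raw
#'   trials or precomputed \code{topomap_sequence}s).
#' @param variant model variant(s); one column of the results table per
#'   variant.
#' @param classes classes to keep (default: classes of the first subject).
#' @param schedule \code{\link{frame_schedule}} for the topomap transform.
#' @param spec \code{\link{split_spec}} for the train/test partition.
#' @param config \code{\link{train_config}}.
#' @param grid_size topomap raster size (default 64).
#' @param model_seed seed for weight initialization.
#' @param verbose print per-subject progress.
#' @return Object of class \code{eval_result}: list with \code{per_subject}
#'   (matrix, subjects x variants, percent), \code{n_correct} and
#'   \code{n_total} (same shape), \code{average} (named vector),
#'   \code{N}, and \code{table} (data.frame shaped like the reference
#'   result tables: one row per subject plus an Average row, one column per
#'   variant, accuracies rounded half-up to 2 decimals, averages to 1).
#' @export
run_experiment <- function(data, variant = "lstm", classes = NULL,
                           schedule = frame_schedule(), spec = split_spec(),
                           config = train_config(), grid_size = 64,
                           model_seed = 0, verbose = FALSE) {
  stopifnot(is.list(data), length(data) >= 1)
  if (is.null(names(data))) names(data) <- sprintf("S%02d", seq_along(data))
  if (is.null(classes)) classes <- data[[1]]$classes
  variants <- variant
  acc <- matrix(NA_real_, length(data), length(variants),
                dimnames = list(names(data), variants))
  ncor <- acc
  ntot <- acc
  keep <- rep(TRUE, length(data))
  montage2d <- project_to_disk(standard_1020_positions(frontal_subset()))
  for (s in seq_along(data)) {
    set <- data[[s]]
    labels <- set_labels(set)
    sel <- which(labels %in% classes)
    if (!all(classes %in% labels[sel])) {
      warning("subject ", names(data)[s], " is missing a class; skipped")
      keep[s] <- FALSE
      next
    }
    set <- trial_set(set$trials[sel], classes = classes)
    set <- balance_classes(set, seed = spec$seed)
    if (inherits(set$trials[[1]], "trial_recording")) {
      m2d <- montage2d
      if (!all(tolower(montage2d$labels) %in%
               tolower(set$trials[[1]]$channel_names))) {
        m2d <- project_to_disk(
          standard_1020_positions(set$trials[[1]]$channel_names))
      }
      set <- transform_set(set, montage2d = m2d, schedule = schedule,
                           grid_size = grid_size)
    }
    split <- make_split(set, spec)
    test_st <- .stack_sequences(split$test)
    for (v in seq_along(variants)) {
      d1 <- dim(split$train$trials[[1]]$frames)
      model <- build_model(variants[v], n_classes = length(classes),
                           input_shape = d1, seed = model_seed)
      fit <- train(model, split, config)
      probs <- model_predict(fit$model, split$test)
      pred <- classes[max.col(probs, ties.method = "first")]
      truth <- set_labels(split$test)
      ncor[s, v] <- sum(pred == truth)
      ntot[s, v] <- length(truth)
      acc[s, v] <- accuracy(pred, truth)
      if (verbose) {
        message(sprintf("%s / %s: %.2f%% (%d epochs)", names(data)[s],
                        variants[v], acc[s, v], fit$epochs_run))
      }
    }
  }
  acc <- acc[keep, , drop = FALSE]
  ncor <- ncor[keep, , drop = FALSE]
  ntot <- ntot[keep, , drop = FALSE]
  if (nrow(acc) == 0) stop("no usable subjects", call. = FALSE)
  avg <- apply(acc, 2, average_accuracy)
  tab <- as.data.frame(.round_half_up(acc, 2))
  tab <- rbind(tab, as.list(.round_half_up(avg, 1)))
  rownames(tab) <- c(rownames(acc), "Average")
  structure(list(per_subject = acc, n_correct = ncor, n_total = ntot,
                 average = avg, N = nrow(acc), table = tab),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Subject-dependent evaluation over %d subject(s)\n", x$N))
  print(x$table)
  invisible(x)
}

#' Published per-subject reference accuracies
#'
#' Loads one of the per-subject accuracy tables measured on the public
#' BCI2020 imagined-speech benchmark (15 subjects; columns are the three
#' hybrid models), shipped with the package as plain CSV. These are
#' reference numbers for metric-aggregation checks, not outputs of this
#' package.
#'
#' @param task one of \code{"wordpair_short"} (three short-word pairs),
#'   \code{"phrase_long"} (Help me vs Thank you), \code{"five_class"},
#'   \code{"three_class"}.
#' @return data.frame with a \code{subject} column and one accuracy column
#'   (percent) per model/word-pair combination.
#' @export
reference_accuracies <- function(task = c("wordpair_short", "phrase_long",
                                          "five_class", "three_class")) {
  task <- match.arg(task)
  path <- system.file("extdata", paste0("ref_accuracy_", task, ".csv"),
                      package = "topodecode")
  utils::read.csv(path, check.names = FALSE)
}
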