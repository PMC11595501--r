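# Trial collections, class balancing, and the stratified 80/20
# subject-dependent split.

#' Construct a trial set
#'
#' @param trials list of \code{\link{trial_recording}} or
#'   \code{topomap_sequence} objects.
#' @param classes ordered character vector of word labels; defaults to the
#'   sorted unique labels present.
#' @return Object of class \code{trial_set}.
#' @export
trial_set <- function(trials, classes = NULL) {
  stopifnot(is.list(trials))
  labels <- vapply(trials, function(t) t$label, character(1))
  if (is.null(classes)) classes <- sort(unique(labels))
  if (!all(labels %in% classes)) {
    stop("trial label not in classes: ",
         setdiff(labels, classes)[1], call. = FALSE)
  }
  structure(list(trials = trials, classes = classes), class = "trial_set")
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' Labels of the trials in a set
#' @param set a \code{trial_set}.
#' @return Character vector of per-trial labels.
#' @export
set_labels <- function(set) {
  vapply(set$trials, function(t) t$label, character(1))
}

.container_fields_raw <- c("data", "labels", "subjects", "channel_names", "rate")

#' Write a trial set to a container file
#'
#' The container is a serialized R list (RDS) with fields \code{format},
#' \code{data} (n_trials x channels x samples array) or \code{frames}
#' (n_trials x n_frames x grid x grid x 3 array for image sequences),
#' \code{labels}, \code{subjects}, \code{channel_names} and \code{rate}.
#' RDS is used because no HDF5 interface is assumed at runtime; the layout
#' mirrors an HDF5-style dataset naming so converters stay trivial.
#'
#' @param set a \code{trial_set}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_trials <- function(set, path) {
  stopifnot(inherits(set, "trial_set"), length(set) >= 1)
  t1 <- set$trials[[1]]
  if (inherits(t1, "trial_recording")) {
    n <- length(set)
    dat <- array(0, dim = c(n, nrow(t1$data), ncol(t1$data)))
    for (i in seq_len(n)) dat[i, , ] <- set$trials[[i]]$data
    obj <- list(format = "topodecode-trials", version = 1L,
                data = dat,
                labels = set_labels(set),
                subjects = vapply(set$trials, function(t) t$subject, character(1)),
                channel_names = t1$channel_names,
                rate = t1$rate,
                classes = set$classes)
  } else if (inherits(t1, "topomap_sequence")) {
    n <- length(set)
    d <- dim(t1$frames)
    fr <- array(0, dim = c(n, d))
    for (i in seq_len(n)) fr[i, , , , ] <- set$trials[[i]]$frames
    obj <- list(format = "topodecode-sequences", version = 1L,
                frames = fr,
                labels = set_labels(set),
                subjects = vapply(set$trials, function(t) t$subject, character(1)),
                classes = set$classes)
  } else {
    stop("unsupported trial type", call. = FALSE)
  }
  saveRDS(obj, path)
  invisible(path)
}

#' Load a trial set from a container file
#'
#' Supports both raw-EEG containers (\code{data} field) and image-sequence
#' containers (\code{frames} field); see \code{\link{write_trials}} for the
#' layout. Shapes and required fields are validated, and raw trials with the
#' reference geometry (256 Hz, 512 samples) are flagged via
#' the \code{conformant} attribute.
#'
#' @param path container file path.
#' @return A \code{\link{trial_set}}.
#' @export
load_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format)) {
    stop("malformed container: missing field: format", call. = FALSE)
  }
  if (obj$format == "topodecode-trials") {
    for (f in .container_fields_raw) {
      if (is.null(obj[[f]])) stop("missing field: ", f, call. = FALSE)
    }
    d <- dim(obj$data)
    if (length(d) != 3) stop("malformed container: data must be 3-dimensional", call. = FALSE)
    if (length(obj$labels) != d[1]) stop("malformed container: labels length mismatch", call. = FALSE)
    if (length(obj$subjects) != d[1]) stop("malformed container: subjects length mismatch", call. = FALSE)
    if (length(obj$channel_names) != d[2]) {
      stop("malformed container: channel_names length mismatch", call. = FALSE)
    }
    trials <- lapply(seq_len(d[1]), function(i) {
      trial_recording(obj$data[i, , , drop = TRUE], obj$rate, obj$labels[i],
                      obj$subjects[i], obj$channel_names)
    })
    trial_set(trials, classes = obj$classes)
  } else if (obj$format == "topodecode-sequences") {
    for (f in c("frames", "labels", "subjects")) {
      if (is.null(obj[[f]])) stop("missing field: ", f, call. = FALSE)
    }
    d <- dim(obj$frames)
    if (length(d) != 5) stop("malformed container: frames must be 5-dimensional", call. = FALSE)
    if (length(obj$labels) != d[1]) stop("malformed container: labels length mismatch", call. = FALSE)
    trials <- lapply(seq_len(d[1]), function(i) {
      structure(list(frames = array(obj$frames[i, , , , ], dim = d[-1]),
                     label = obj$labels[i], subject = obj$subjects[i]),
                class = "topomap_sequence")
    })
    trial_set(trials, classes = obj$classes)
  } else {
    stop("malformed container: unknown format: ", obj$format, call. = FALSE)
  }
}

# run fn with a private, seeded RNG stream; global RNG state untouched
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  fn()
}

#' Balance classes by seeded downsampling
#'
#' Downsamples every class uniformly at random to the minimum per-class
#' count, so all classes are equally represented before splitting.
#'
#' @param set a \code{trial_set} with at least one trial per class.
#' @param seed integer RNG seed (selection is reproducible).
#' @return A balanced \code{trial_set} (original trial order preserved).
#' @export
balance_classes <- function(set, seed = 0) {
  stopifnot(inherits(set, "trial_set"))
  labels <- set_labels(set)
  counts <- table(factor(labels, levels = set$classes))
  if (any(counts == 0)) {
    stop("empty class: ", names(counts)[counts == 0][1], call. = FALSE)
  }
  m <- min(counts)
  keep <- .with_seed(seed, function() {
    sort(unlist(lapply(set$classes, function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > m) sample(idx, m) else idx
    })))
  })
  trial_set(set$trials[keep], classes = set$classes)
}

#' Specification of a train/test split
#'
#' @param train_fraction proportion of each class assigned to training
#'   (default 0.8).
#' @param seed integer RNG seed.
#' @param stratified partition each class separately (default TRUE); the
#'   exact per-task train/test counts require per-class proportionality.
#' @return Object of class \code{split_spec}.
#' @export
split_spec <- function(train_fraction = 0.8, seed = 0, stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

#' Stratified seeded train/test partition
#'
#' Partitions a balanced trial set into disjoint train and test sets; per
#' class, the train count is \code{round(train_fraction * n_class)}. With
#' the defaults this yields the reference 80/20 geometry: 112/28 for two
#' classes of 70 trials, 168/42 for three, 280/70 for five.
#'
#' @param set a balanced \code{trial_set}.
#' @param spec a \code{\link{split_spec}}.
#' @return Object of class \code{dataset_split}: list with \code{train} and
#'   \code{test} trial sets; attributes \code{train_idx}/\code{test_idx}
#'   record the partition (for audit) and \code{seed} the RNG seed used.
#' @export
make_split <- function(set, spec = split_spec()) {
  stopifnot(inherits(set, "trial_set"), inherits(spec, "split_spec"))
  labels <- set_labels(set)
  counts <- table(factor(labels, levels = set$classes))
  if (any(counts < 2)) {
    stop("class with fewer than 2 trials: ",
         names(counts)[counts < 2][1], call. = FALSE)
  }
  groups <- if (spec$stratified) set$classes else list(set$classes)
  train_idx <- .with_seed(spec$seed, function() {
    unlist(lapply(groups, function(cl) {
      idx <- which(labels %in% cl)
      n_train <- round(spec$train_fraction * length(idx))
      sample(idx, n_train)
    }))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(labels), train_idx)
  out <- structure(
    list(train = trial_set(set$trials[train_idx], classes = set$classes),
         test = trial_set(set$trials[test_idx], classes = set$classes)),
    class = "dataset_split")
  attr(out, "train_idx") <- train_idx
  attr(out, "test_idx") <- test_idx
  attr(out, "seed") <- spec$seed
  out
}

#' Transform every trial of a set into a topomap sequence
#'
#' Convenience bulk application of \code{\link{trial_to_sequence}}; sets
#' containing sequences already are returned unchanged.
#'
#' @param set a \code{trial_set} of \code{trial_recording}s.
#' @param montage2d,schedule,grid_size passed to
#'   \code{\link{trial_to_sequence}}.
#' @return A \code{trial_set} of \code{topomap_sequence}s.
#' @export
transform_set <- function(set,
                          montage2d = project_to_disk(
                            standard_1020_positions(frontal_subset())),
                          schedule = frame_schedule(),
                          grid_size = 64) {
  stopifnot(inherits(set, "trial_set"))
  if (length(set) >= 1 && inherits(set$trials[[1]], "topomap_sequence")) {
    return(set)
  }
  seqs <- lapply(set$trials, trial_to_sequence, montage2d = montage2d,
                 schedule = schedule, grid_size = grid_size)
  trial_set(seqs, classes = set$classes)
}
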