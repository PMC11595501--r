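# Trial -> sequence of topographic map images.
#
# Each 2 s trial is cut into 16 windows of 125 ms (starting 4 ms after trial
# onset), the per-channel window means are interpolated onto a 64 x 64 head
# raster by inverse-distance weighting, and each field is rendered to RGB
# with a fixed piecewise-linear diverging colormap scaled symmetrically by
# the trial's maximum absolute value.

#' Frame schedule for topographic map extraction
#'
#' @param window_ms window length in milliseconds (default 125, chosen to
#'   cover the 60--120 ms quasi-stable period of scalp microstates).
#' @param offset_ms start offset of the first window after trial onset, in
#'   milliseconds (default 4).
#' @param n_frames number of frames (default 16, covering a 2 s trial).
#' @return Object of class \code{frame_schedule}.
#' @examples
#' frame_schedule()
#' @export
frame_schedule <- function(window_ms = 125, offset_ms = 4, n_frames = 16) {
  stopifnot(window_ms > 0, offset_ms >= 0, n_frames >= 1)
  structure(list(window_ms = window_ms, offset_ms = offset_ms,
                 n_frames = as.integer(n_frames)),
            class = "frame_schedule")
}

#' Construct a single EEG trial recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz.
#' @param label word-class identifier (character or factor level).
#' @param subject subject identifier.
#' @param channel_names character vector aligned to the rows of \code{data}.
#' @return Object of class \code{trial_recording}. The attribute
#'   \code{conformant} flags trials with the reference geometry
#'   (256 Hz, 512 samples).
#' @examples
#' tr <- trial_recording(matrix(rnorm(15 * 512), 15), 256, "hello", "S01",
#'                       frontal_subset())
#' attr(tr, "conformant")
#' @export
trial_recording <- function(data, rate, label, subject, channel_names) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (nrow(data) < 1 || ncol(data) < 1) stop("data must be non-empty", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a positive scalar (Hz)", call. = FALSE)
  }
  if (length(channel_names) != nrow(data)) {
    stop("channel_names length must equal the channel count", call. = FALSE)
  }
  obj <- structure(list(data = data, rate = rate, label = as.character(label),
                        subject = as.character(subject),
                        channel_names = as.character(channel_names)),
                   class = "trial_recording")
  attr(obj, "conformant") <- (rate == 256 && ncol(data) == 512)
  obj
}

# 0-based start sample of frame k (1-based) under the rounding rule
# start = round(offset_ms * rate / 1000) + (k - 1) * W, W = round(window_ms * rate / 1000)
.frame_bounds <- function(trial, k, schedule) {
  w <- round(schedule$window_ms * trial$rate / 1000)
  s0 <- round(schedule$offset_ms * trial$rate / 1000) + (k - 1) * w
  s1 <- min(s0 + w, ncol(trial$data))
  list(start = s0, end = s1, w = w)
}

#' Per-channel mean voltage of one topomap window
#'
#' Frame \code{k} (1-based) covers samples
#' \code{[round(offset_ms * rate / 1000) + (k - 1) * W, ... + k * W)} in
#' 0-based sample indexing, with \code{W = round(window_ms * rate / 1000)};
#' a window overhanging the trial end is clipped to it (frame 16 of a 2 s,
#' 256 Hz trial keeps 31 of its 32 samples).
#'
#' @param trial a \code{\link{trial_recording}}.
#' @param k frame index, 1-based, in \code{1:schedule$n_frames}.
#' @param schedule a \code{\link{frame_schedule}}.
#' @return Numeric vector of per-channel window means (microvolts), named by
#'   channel.
#' @export
extract_frame_values <- function(trial, k, schedule = frame_schedule()) {
  stopifnot(inherits(trial, "trial_recording"), inherits(schedule, "frame_schedule"))
  if (length(k) != 1 || k < 1 || k > schedule$n_frames) {
    stop("frame index k must be in 1..n_frames", call. = FALSE)
  }
  b <- .frame_bounds(trial, k, schedule)
  if (b$start >= ncol(trial$data)) stop("frame out of range", call. = FALSE)
  v <- rowMeans(trial$data[, (b$start + 1):b$end, drop = FALSE])
  names(v) <- trial$channel_names
  v
}

#' Interpolate electrode values onto a head-disk raster
#'
#' Inverse-distance weighting with exponent 2 over all electrodes, evaluated
#' at the pixel centers of a \code{grid_size} x \code{grid_size} raster
#' spanning \eqn{[-1, 1]^2}. A pixel whose center lies within 1e-9 of an
#' electrode takes that electrode's value exactly (IDW node exactness);
#' pixels outside the closed unit disk are masked. The interpolant is a
#' convex combination of the electrode values, so the field never over- or
#' undershoots them.
#'
#' @param values numeric vector of per-electrode values, aligned to
#'   \code{montage2d$labels}.
#' @param montage2d a \code{\link{project_to_disk}} result.
#' @param grid_size raster edge length in pixels (>= 8; default 64).
#' @return Object of class \code{scalar_field}: list with \code{grid}
#'   (matrix, rows = raster rows top to bottom, i.e. \code{y} decreasing from
#'   nose to back; columns = \code{x} increasing left to right; \code{NA}
#'   outside the head) and \code{mask} (logical matrix).
#' @export
interpolate_scalp <- function(values, montage2d, grid_size = 64) {
  stopifnot(inherits(montage2d, "montage2d"), grid_size >= 8)
  pos <- montage2d$positions2d
  if (length(values) != nrow(pos)) {
    stop("values length must equal the montage electrode count", call. = FALSE)
  }
  d2e <- as.matrix(stats::dist(pos))
  if (any(d2e[upper.tri(d2e)] < 1e-12)) {
    stop("duplicate electrode coordinates in montage", call. = FALSE)
  }
  g <- as.integer(grid_size)
  centers <- -1 + (2 * seq_len(g) - 1) / g
  xs <- rep(centers, each = g)        # column-major over (row, col)
  ys <- rep(rev(centers), times = g)  # row 1 = top = +y (nose)
  d2 <- outer(xs, pos[, 1], "-")^2 + outer(ys, pos[, 2], "-")^2
  w <- 1 / d2
  field <- as.vector((w %*% values) / rowSums(w))
  # node exactness: pixel center within 1e-9 of an electrode
  hit <- which(d2 < 1e-18, arr.ind = TRUE)
  if (nrow(hit) > 0) field[hit[, 1]] <- values[hit[, 2]]
  mask <- xs^2 + ys^2 <= 1 + 1e-9
  field[!mask] <- NA_real_
  structure(list(grid = matrix(field, g, g), mask = matrix(mask, g, g)),
            class = "scalar_field")
}

#' Render an interpolated scalp field to an RGB frame
#'
#' Values are normalized to \code{u = clamp((v + vmax) / (2 * vmax), 0, 1)}
#' (symmetric about zero) and mapped through a fixed piecewise-linear
#' jet-like colormap, \code{R = clamp(1.5 - |4u - 3|, 0, 1)},
#' \code{G = clamp(1.5 - |4u - 2|, 0, 1)}, \code{B = clamp(1.5 - |4u - 1|, 0, 1)};
#' pixels outside the head disk render white.
#'
#' @param field a \code{\link{interpolate_scalp}} result.
#' @param vmax positive half-range of the color scale (microvolts).
#' @return Numeric array \code{grid_size x grid_size x 3} with values in
#'   \eqn{[0, 1]}.
#' @export
render_rgb <- function(field, vmax) {
  stopifnot(inherits(field, "scalar_field"))
  if (!is.numeric(vmax) || length(vmax) != 1 || vmax <= 0) {
    stop("vmax must be a positive scalar", call. = FALSE)
  }
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  u <- clamp01((field$grid + vmax) / (2 * vmax))
  g <- nrow(field$grid)
  out <- array(1, dim = c(g, g, 3))
  m <- field$mask
  r <- clamp01(1.5 - abs(4 * u - 3))
  gg <- clamp01(1.5 - abs(4 * u - 2))
  b <- clamp01(1.5 - abs(4 * u - 1))
  ch <- out[, , 1]; ch[m] <- r[m]; out[, , 1] <- ch
  ch <- out[, , 2]; ch[m] <- gg[m]; out[, , 2] <- ch
  ch <- out[, , 3]; ch[m] <- b[m]; out[, , 3] <- ch
  out
}

#' Convert one EEG trial into a sequence of topographic map frames
#'
#' Applies \code{\link{extract_frame_values}},
#' \code{\link{interpolate_scalp}} and \code{\link{render_rgb}} per frame.
#' The color half-range \code{vmax} is the maximum absolute windowed value
#' across all frames of the trial, so the frames of one trial share a common
#' symmetric scale and their temporal dynamics stay comparable; an all-zero
#' trial falls back to \code{vmax = 1} (every frame renders mid-scale).
#' Trial channels are matched to montage labels by name (case-insensitive),
#' so row order in the trial does not matter.
#'
#' @param trial a \code{\link{trial_recording}} whose channels match the
#'   montage labels.
#' @param montage2d a \code{\link{project_to_disk}} result; defaults to the
#'   projected \code{\link{frontal_subset}} montage.
#' @param schedule a \code{\link{frame_schedule}}.
#' @param grid_size raster edge length in pixels (default 64).
#' @return Object of class \code{topomap_sequence}: list with \code{frames}
#'   (array \code{n_frames x grid x grid x 3}, values in \eqn{[0, 1]}),
#'   \code{label} and \code{subject}.
#' @examples
#' tr <- trial_recording(matrix(rnorm(15 * 512), 15), 256, "hello", "S01",
#'                       frontal_subset())
#' dim(trial_to_sequence(tr)$frames)
#' @export
trial_to_sequence <- function(trial,
                              montage2d = project_to_disk(
                                standard_1020_positions(frontal_subset())),
                              schedule = frame_schedule(),
                              grid_size = 64) {
  stopifnot(inherits(trial, "trial_recording"), inherits(montage2d, "montage2d"))
  idx <- match(tolower(montage2d$labels), tolower(trial$channel_names))
  if (anyNA(idx)) {
    stop("trial is missing montage channel: ",
         montage2d$labels[is.na(idx)][1], call. = FALSE)
  }
  vals <- vapply(seq_len(schedule$n_frames), function(k) {
    extract_frame_values(trial, k, schedule)[idx]
  }, numeric(length(idx)))
  vmax <- max(abs(vals))
  if (vmax == 0) vmax <- 1.0
  frames <- array(0, dim = c(schedule$n_frames, grid_size, grid_size, 3))
  for (k in seq_len(schedule$n_frames)) {
    fld <- interpolate_scalp(vals[, k], montage2d, grid_size)
    frames[k, , , ] <- render_rgb(fld, vmax)
  }
  structure(list(frames = frames, label = trial$label, subject = trial$subject),
            class = "topomap_sequence")
}

#' Quantize a topomap sequence through 8-bit storage and back
#'
#' Emulates writing the frames to 8-bit image files and reloading them with
#' pixel values divided by 255: each value becomes
#' \code{round(v * 255) / 255}.
#'
#' @param sequence a \code{\link{trial_to_sequence}} result.
#' @return A \code{topomap_sequence} whose values lie on the 8-bit lattice
#'   \code{{0/255, ..., 255/255}}.
#' @export
quantize_roundtrip <- function(sequence) {
  stopifnot(inherits(sequence, "topomap_sequence"))
  sequence$frames <- round(sequence$frames * 255) / 255
  sequence
}

#' Export the frames of a sequence as plain-text PPM images
#'
#' Writes one ASCII PPM (P3) file per frame for visual inspection with any
#' image viewer. PPM is used instead of PNG so the export has no binary
#' dependencies.
#'
#' @param sequence a \code{topomap_sequence}.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix; frames become \code{<prefix>_01.ppm}, ...
#' @return Invisibly, the written file paths.
#' @export
export_frames_ppm <- function(sequence, dir, prefix = "frame") {
  stopifnot(inherits(sequence, "topomap_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(sequence$frames)[1]
  g <- dim(sequence$frames)[2]
  paths <- character(n)
  for (k in seq_len(n)) {
    bytes <- round(sequence$frames[k, , , ] * 255)
    # interleave R,G,B per pixel, row by row
    px <- aperm(bytes, c(3, 2, 1))
    path <- file.path(dir, sprintf("%s_%02d.ppm", prefix, k))
    con <- file(path, "w")
    writeLines(c("P3", paste(g, g), "255"), con)
    writeLines(paste(as.integer(px), collapse = " "), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}
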