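# Electrode geometry: idealized spherical 10-20/10-10 montage and the
# azimuthal-equidistant head projection used for rasterizing scalp maps.

.montage_env <- new.env(parent = emptyenv())

# Static spherical table: label, inclination from vertex (deg), azimuth (deg,
# counterclockwise from the right pre-auricular axis; nose = 90).
.montage_table <- function() {
  if (is.null(.montage_env$table)) {
    path <- system.file("extdata", "electrodes_1010.txt", package = "topodecode")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    .montage_env$table <- tab
  }
  .montage_env$table
}

#' Standard 10-20/10-10 electrode positions on the unit sphere
#'
#' Looks up head-centered unit-sphere coordinates for the requested channels
#' in the package's idealized spherical 10-10 table (vertex Cz at the pole,
#' ear-level circumference ring at 90 degrees inclination, intermediate rows
#' by great-circle interpolation). Matching is case-insensitive; output labels
#' use canonical capitalization ("Fp1", not "FP1").
#'
#' @param labels character vector of 10-20/10-10 channel names.
#' @return An object of class \code{electrode_montage}: a list with
#'   \code{labels} (canonical names, input order) and \code{positions3d}
#'   (numeric matrix, one row per label, columns \code{x}, \code{y},
#'   \code{z}; \code{+x} right ear, \code{+y} nose, \code{+z} vertex).
#' @examples
#' m <- standard_1020_positions(c("Fp1", "Fz", "Cz"))
#' m$positions3d
#' @export
standard_1020_positions <- function(labels) {
  stopifnot(is.character(labels), length(labels) >= 1)
  tab <- .montage_table()
  idx <- match(tolower(labels), tolower(tab$label))
  if (anyNA(idx)) {
    bad <- labels[is.na(idx)][1]
    stop("unknown electrode label: ", bad, call. = FALSE)
  }
  canon <- tab$label[idx]
  if (anyDuplicated(canon)) {
    stop("duplicate electrode label: ", canon[duplicated(canon)][1],
         call. = FALSE)
  }
  theta <- tab$inclination_deg[idx] * pi / 180
  phi <- tab$azimuth_deg[idx] * pi / 180
  pos <- cbind(x = sin(theta) * cos(phi),
               y = sin(theta) * sin(phi),
               z = cos(theta))
  rownames(pos) <- canon
  structure(list(labels = canon, positions3d = pos),
            class = "electrode_montage")
}

#' Project an electrode montage onto the unit disk
#'
#' Azimuthal-equidistant ("polar") projection, the de-facto standard for EEG
#' topographic plots: a point at polar angle \eqn{\theta} from the vertex maps
#' to radius \eqn{\theta / (\pi/2)}, so the vertex lands at the origin and the
#' ear-level circle at radius 1; azimuth is preserved exactly.
#'
#' @param montage an \code{electrode_montage} from
#'   \code{\link{standard_1020_positions}}.
#' @return An object of class \code{montage2d}: list with \code{labels} and
#'   \code{positions2d} (matrix, columns \code{x}, \code{y}; \code{+y} toward
#'   the nose).
#' @examples
#' project_to_disk(standard_1020_positions(c("Cz", "T8")))$positions2d
#' @export
project_to_disk <- function(montage) {
  stopifnot(inherits(montage, "electrode_montage"))
  p <- montage$positions3d
  theta <- acos(pmin(pmax(p[, "z"], -1), 1))
  r <- theta / (pi / 2)
  # azimuth from 3D x,y; degenerate only at the exact vertex where r = 0
  phi <- atan2(p[, "y"], p[, "x"])
  phi[theta < 1e-12] <- 0
  pos <- cbind(x = r * cos(phi), y = r * sin(phi))
  rownames(pos) <- montage$labels
  structure(list(labels = montage$labels, positions2d = pos),
            class = "montage2d")
}

#' The 15-channel frontal electrode subset
#'
#' Channels over the left and right frontal lobes used for imagined-speech
#' decoding: frontal regions carry most of the discriminative activity for
#' covert speech, and restricting the montage to them keeps the scalp maps
#' focused on it. The order is fixed and documented; all downstream code
#' matches channels by name, not position.
#'
#' @return Character vector of 15 channel names.
#' @examples
#' frontal_subset()
#' @export
frontal_subset <- function() {
  c("Fp1", "AF3", "Fp2", "AF4", "AF7", "AF8", "F1", "Fz", "F2",
    "F7", "F5", "F3", "F4", "F6", "F8")
}
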