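#' Canal curve and labyrinth configuration containers
#'
#' A `canal_curve` is an ordered 3D polyline digitized along the centerline
#' of one semicircular canal (anterior, posterior or lateral), with
#' anatomical tags for its start and end (e.g. "anterior ampulla",
#' "junction with crus communis"). Arc length is the chord sum of the
#' polyline; curves are piecewise linear throughout the package.
#'
#' @param canal one of `"anterior"`, `"posterior"`, `"lateral"`.
#' @param points numeric matrix, one row per vertex, 3 columns (x, y, z, mm).
#' @param start_anatomy,end_anatomy free-text anatomical tags.
#' @return an object of class `canal_curve`.
#' @export
canal_curve <- function(canal = c("anterior", "posterior", "lateral"),
                        points,
                        start_anatomy = "", end_anatomy = "") {
  canal <- match.arg(canal)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("canal_curve: 'points' must have 3 columns (x, y, z)")
  if (nrow(points) < 2L)
    stop("canal_curve: need at least 2 points")
  storage.mode(points) <- "double"
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0))
    stop("canal_curve: consecutive points must be distinct")
  structure(list(canal = canal, points = unname(points),
                 start_anatomy = start_anatomy, end_anatomy = end_anatomy),
            class = "canal_curve")
}

#' @export
print.canal_curve <- function(x, ...) {
  cat(sprintf("<canal_curve> %s canal: %d vertices, arc length %.4g\n",
              x$canal, nrow(x$points), curve_arc_length(x)))
  invisible(x)
}

#' Total arc length of a canal curve (chord sum)
#' @param curve a `canal_curve`.
#' @return positive scalar.
#' @export
curve_arc_length <- function(curve) {
  p <- curve$points
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Resample a canal curve at equal arc-length spacing
#'
#' Projects `n` evenly spaced landmarks onto the piecewise-linear curve:
#' the first and last coincide with the curve endpoints, interior points
#' sit at arc-length positions `k * L / (n - 1)`.
#'
#' @param curve a `canal_curve`.
#' @param n number of landmarks (>= 2); 20 per canal in the standard scheme.
#' @return an `n` x 3 matrix of positions on the curve.
#' @export
resample_curve <- function(curve, n = 20L) {
  stopifnot(inherits(curve, "canal_curve"))
  n <- as.integer(n)
  if (n < 2L) stop("resample_curve: n must be >= 2")
  p <- curve$points
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  L <- sum(seg)
  if (L <= 0) stop("resample_curve: degenerate curve (zero arc length)")
  cum <- c(0, cumsum(seg))
  target <- seq(0, L, length.out = n)
  out <- matrix(0, n, 3L)
  out[1L, ] <- p[1L, ]
  out[n, ] <- p[nrow(p), ]
  if (n > 2L) {
    idx <- findInterval(target[2:(n - 1L)], cum, rightmost.closed = TRUE)
    idx <- pmin(idx, nrow(p) - 1L)
    frac <- (target[2:(n - 1L)] - cum[idx]) / seg[idx]
    out[2:(n - 1L), ] <- p[idx, , drop = FALSE] +
      frac * (p[idx + 1L, , drop = FALSE] - p[idx, , drop = FALSE])
  }
  out
}

CANALS <- c("anterior", "posterior", "lateral")

#' Assemble a labyrinth configuration from three canal curves
#'
#' Builds the standard 60-landmark scheme: 20 equally spaced landmarks per
#' canal (anterior, posterior, lateral, in that order). Curve endpoints
#' (landmarks 1 and 20 of each canal) are fixed anatomical landmarks; the
#' 54 interior landmarks are semilandmarks allowed to slide along their
#' source polyline.
#'
#' @param curves named list with elements `anterior`, `posterior`,
#'   `lateral`, each a `canal_curve`.
#' @param specimen_id,taxon identifiers.
#' @param side `"left"` or `"right"`.
#' @param ecology ecology label or `NA` for fossils of unknown ecology.
#' @param n_per_curve landmarks per canal (default 20).
#' @return an object of class `labyrinth_config` with fields `landmarks`
#'   (60 x 3), `curve_id` (factor of length 60), `fixed` (indices of the 6
#'   fixed endpoints), `curves` (the source polylines, kept for sliding).
#' @export
labyrinth_config <- function(curves, specimen_id, taxon = specimen_id,
                             side = c("left", "right"), ecology = NA_character_,
                             n_per_curve = 20L) {
  side <- match.arg(side)
  if (!all(CANALS %in% names(curves)))
    stop("labyrinth_config: curves must be named anterior/posterior/lateral")
  n_per_curve <- as.integer(n_per_curve)
  lm <- do.call(rbind, lapply(CANALS, function(cn)
    resample_curve(curves[[cn]], n_per_curve)))
  new_labyrinth_config(lm, specimen_id, taxon, side, ecology,
                       n_per_curve, curves[CANALS])
}

# internal constructor from an already-resampled landmark block
new_labyrinth_config <- function(landmarks, specimen_id, taxon, side,
                                 ecology = NA_character_, n_per_curve = 20L,
                                 curves = NULL) {
  k <- 3L * n_per_curve
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) != k || ncol(landmarks) != 3L)
    stop(sprintf("labyrinth_config: expected %d x 3 landmarks, got %d x %d",
                 k, nrow(landmarks), ncol(landmarks)))
  curve_id <- factor(rep(CANALS, each = n_per_curve), levels = CANALS)
  fixed <- as.integer(outer(c(1L, n_per_curve),
                            (seq_len(3L) - 1L) * n_per_curve, "+"))
  structure(list(specimen_id = specimen_id, taxon = taxon, side = side,
                 ecology = ecology, landmarks = unname(landmarks),
                 curve_id = curve_id, fixed = sort(fixed),
                 n_per_curve = n_per_curve, curves = curves),
            class = "labyrinth_config")
}

#' @export
print.labyrinth_config <- function(x, ...) {
  cat(sprintf("<labyrinth_config> %s (%s, %s side): %d landmarks, %d fixed%s\n",
              x$specimen_id, x$taxon, x$side, nrow(x$landmarks),
              length(x$fixed),
              if (is.na(x$ecology)) "" else paste0(", ecology ", x$ecology)))
  invisible(x)
}

#' Mirror a labyrinth configuration across the sagittal plane
#'
#' Right labyrinths are mirrored so they can be analysed alongside left
#' ones: one coordinate axis is negated, landmark ordering is preserved,
#' and the side flag flips. Mirroring is an involution and an isometry
#' (centroid size is unchanged).
#'
#' @param config a `labyrinth_config`.
#' @param axis which coordinate to negate (default 1, the mediolateral x).
#' @return the mirrored `labyrinth_config`.
#' @export
mirror_configuration <- function(config, axis = 1L) {
  stopifnot(inherits(config, "labyrinth_config"))
  config$landmarks[, axis] <- -config$landmarks[, axis]
  if (!is.null(config$curves))
    config$curves <- lapply(config$curves, function(cv) {
      cv$points[, axis] <- -cv$points[, axis]
      cv
    })
  config$side <- if (identical(config$side, "left")) "right" else "left"
  config
}
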