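#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid — the standard size measure in geometric morphometrics.
#'
#' @param config a k x 3 landmark matrix or a `labyrinth_config`.
#' @return a positive scalar (0 if all landmarks coincide).
#' @export
centroid_size <- function(config) {
  x <- if (inherits(config, "labyrinth_config")) config$landmarks else as.matrix(config)
  xc <- sweep(x, 2L, colMeans(x))
  sqrt(sum(xc^2))
}

# optimal rotation (det +1, no reflection) taking a onto b, both centered
kabsch_rotation <- function(a, b) {
  m <- crossprod(a, b)
  s <- svd(m)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Generalized Procrustes alignment of landmark configurations
#'
#' Removes translation (centering), size (scaling to unit centroid size)
#' and orientation (optimal rotations, determinant +1 so reflections are
#' never introduced) from a sample of configurations, iterating rotations
#' against the updated consensus until it stabilizes.
#'
#' @param configs list of k x 3 matrices or `labyrinth_config` objects
#'   sharing one landmark scheme.
#' @param tol convergence tolerance on the consensus root-mean-square
#'   change between iterations.
#' @param max_iter maximum consensus-update iterations.
#' @return an object of class `aligned_sample`: `coordinates` (list of
#'   aligned k x 3 matrices), `consensus` (k x 3 mean shape, unit centroid
#'   size), `centroid_sizes` (pre-scaling sizes), `transforms` (per
#'   specimen: `center`, `size`, `rotation`, mapping original to aligned
#'   frame), `ids`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  n <- length(configs)
  if (n < 2L) stop("gpa: need at least 2 configurations")
  ids <- vapply(seq_len(n), function(i) {
    ci <- configs[[i]]
    if (inherits(ci, "labyrinth_config")) ci$specimen_id else paste0("spec_", i)
  }, character(1))
  mats <- lapply(configs, function(ci)
    if (inherits(ci, "labyrinth_config")) ci$landmarks else as.matrix(ci))
  k <- nrow(mats[[1L]])
  if (any(vapply(mats, nrow, 1L) != k))
    stop("gpa: configurations differ in landmark count")

  centers <- lapply(mats, colMeans)
  centered <- Map(function(x, c) sweep(x, 2L, c), mats, centers)
  cs <- vapply(centered, function(x) sqrt(sum(x^2)), numeric(1))
  bad <- which(cs <= k * 1e-14)
  if (length(bad))
    stop("gpa: degenerate configuration (zero centroid size): ",
         paste(ids[bad], collapse = ", "))
  z <- Map(function(x, s) x / s, centered, cs)

  consensus <- z[[1L]]
  rots <- vector("list", n)
  aligned <- z
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      rots[[i]] <- kabsch_rotation(z[[i]], consensus)
      aligned[[i]] <- z[[i]] %*% rots[[i]]
    }
    m <- Reduce(`+`, aligned) / n
    m <- m / sqrt(sum(m^2))
    delta <- sqrt(mean((m - consensus)^2))
    consensus <- m
    if (delta < tol) break
  }
  structure(list(coordinates = aligned, consensus = consensus,
                 centroid_sizes = stats::setNames(cs, ids),
                 transforms = Map(function(c, s, r)
                   list(center = c, size = s, rotation = r),
                   centers, cs, rots),
                 ids = ids, k = k),
            class = "aligned_sample")
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat(sprintf("<aligned_sample> %d configurations, %d landmarks\n",
              length(x$coordinates), x$k))
  invisible(x)
}

# vectorize a k x 3 configuration row-major (x1,y1,z1,x2,...)
flatten_config <- function(x) as.vector(t(x))
unflatten_config <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Tangent-space principal component analysis of aligned shapes
#'
#' Projects aligned configurations orthogonally into the tangent space at
#' the consensus and decomposes the centered data by SVD (numerically
#' stable for n much smaller than the coordinate dimension). Each
#' component's loading vector is sign-fixed so its largest-magnitude
#' element is positive, making outputs deterministic.
#'
#' @param aligned an `aligned_sample` from [gpa()].
#' @return an object of class `shape_space`: `scores` (n x m), `eigenvalues`
#'   (descending), `variance_fractions` (summing to 1 over retained axes),
#'   `loadings` (m x 3k), `center` (the consensus vector), `ids`.
#' @export
pca_shapes <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_sample"))
  n <- length(aligned$coordinates)
  if (n < 3L) stop("pca_shapes: need at least 3 specimens")
  X <- do.call(rbind, lapply(aligned$coordinates, flatten_config))
  m <- flatten_config(aligned$consensus)
  Xc <- sweep(X, 2L, m)
  v <- m / sqrt(sum(m^2))
  Xt <- Xc - (Xc %*% v) %*% t(v)      # orthogonal tangent projection
  s <- svd(Xt)
  keep <- which(s$d > max(s$d) * 1e-8 & s$d > 1e-9)
  if (!length(keep))
    stop("pca_shapes: all shapes identical (zero shape variance)")
  d <- s$d[keep]
  scores <- s$u[, keep, drop = FALSE] %*% diag(d, length(keep))
  loadings <- t(s$v[, keep, drop = FALSE])
  for (j in seq_along(keep)) {           # deterministic axis signs
    i_max <- which.max(abs(loadings[j, ]))
    if (loadings[j, i_max] < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  eig <- d^2 / (n - 1)
  rownames(scores) <- aligned$ids
  colnames(scores) <- paste0("PC", seq_along(keep))
  structure(list(scores = scores, eigenvalues = eig,
                 variance_fractions = eig / sum(eig),
                 loadings = loadings, center = m, ids = aligned$ids),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("<shape_space> %d specimens, %d axes; PC1 %.2f%% of variance\n",
              nrow(x$scores), ncol(x$scores), 100 * x$variance_fractions[1L]))
  invisible(x)
}

#' Minimum number of PCs reaching a cumulative variance threshold
#'
#' @param space a `shape_space` (or any object with `variance_fractions`),
#'   or a numeric vector of variance fractions.
#' @param threshold cumulative fraction in (0, 1].
#' @return smallest k with cumulative variance >= threshold.
#' @export
min_pcs_for_variance <- function(space, threshold = 0.95) {
  if (!(threshold > 0 && threshold <= 1))
    stop("min_pcs_for_variance: threshold must be in (0, 1]")
  fr <- if (is.numeric(space)) space else space$variance_fractions
  cum <- cumsum(fr)
  k <- which(cum >= threshold - 1e-12)
  if (!length(k)) length(fr) else k[1L]
}
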