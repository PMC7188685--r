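#' Thin-plate-spline bending energy model
#'
#' Builds the bending-energy matrix of a reference configuration: the
#' upper-left k x k block of the inverse of the TPS system matrix
#' L = [[K, Q], [Q', 0]], with the 3D kernel U(r) = -r and Q = [1 | X].
#' The matrix is symmetric positive semi-definite and annihilates every
#' affine function of the reference, so affine transforms of the reference
#' have zero bending energy.
#'
#' @param reference k x 3 landmark matrix (non-degenerate, no coincident
#'   landmarks).
#' @return object of class `bending_energy_model` with `reference` and the
#'   k x k `bending_matrix`.
#' @export
bending_energy_model <- function(reference) {
  X <- as.matrix(reference)
  k <- nrow(X)
  D <- as.matrix(stats::dist(X))
  coincident <- which(D + diag(Inf, k) == 0, arr.ind = TRUE)
  if (nrow(coincident))
    stop("bending_energy_model: coincident reference landmarks at indices ",
         paste(unique(sort(coincident)), collapse = ", "))
  K <- -D
  Q <- cbind(1, X)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4L, 4L)))
  Linv <- solve(L)
  Be <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  Be <- (Be + t(Be)) / 2
  structure(list(reference = X, bending_matrix = Be),
            class = "bending_energy_model")
}

#' Bending energy of a target configuration
#'
#' `trace(T' Be T)` summed over the x, y, z coordinate columns of the
#' target; zero iff the target is an affine transform of the reference.
#'
#' @param model a `bending_energy_model`.
#' @param target k x 3 matrix (same landmark count as the reference).
#' @return nonnegative scalar.
#' @export
bending_energy <- function(model, target) {
  stopifnot(inherits(model, "bending_energy_model"))
  T <- as.matrix(target)
  if (nrow(T) != nrow(model$reference))
    stop("bending_energy: landmark count mismatch")
  sum(T * (model$bending_matrix %*% T))
}

# project points (m x 3) onto a piecewise-linear curve; returns projected
# positions. Vectorized over segments for each point.
project_onto_polyline <- function(pts, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  out <- matrix(0, nrow(pts), 3L)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    ap <- sweep(a, 2L, p, `-`)
    t <- pmin(1, pmax(0, -rowSums(ap * ab) / len2))
    cand <- a + t * ab
    d2 <- rowSums(sweep(cand, 2L, p, `-`)^2)
    out[i, ] <- cand[which.min(d2), ]
  }
  out
}

# unit tangents at semilandmarks from their along-curve neighbors
semilandmark_tangents <- function(landmarks, curve_id, fixed) {
  k <- nrow(landmarks)
  tang <- matrix(0, k, 3L)
  for (i in setdiff(seq_len(k), fixed)) {
    same <- which(curve_id == curve_id[i])
    lo <- max(same[same < i])
    hi <- min(same[same > i])
    d <- landmarks[hi, ] - landmarks[lo, ]
    nrm <- sqrt(sum(d^2))
    if (nrm > 0) tang[i, ] <- d / nrm
  }
  tang
}

#' Slide semilandmarks to minimize thin-plate-spline bending energy
#'
#' Iterative tangent-direction sliding against an updated Procrustes
#' consensus: in the aligned frame, each semilandmark takes a
#' bending-energy gradient step projected onto its local curve tangent
#' (with backtracking so energy never increases), is re-projected onto its
#' specimen's original centerline polyline, and the consensus is
#' recomputed. Fixed anatomical endpoints (the six curve endpoints) never
#' move. Returns configurations in their original coordinate frames, with
#' every slid landmark on its source polyline.
#'
#' @param configs list of `labyrinth_config` objects carrying their source
#'   curves.
#' @param max_iter maximum outer (consensus-update) iterations.
#' @param tol relative total-bending-energy change below which sliding is
#'   declared converged.
#' @return list with `configs` (slid configurations), `energy` (per-outer-
#'   iteration total bending energy versus the current consensus),
#'   `converged` (logical), `iterations`.
#' @export
slide_semilandmarks <- function(configs, max_iter = 10L, tol = 1e-6) {
  n <- length(configs)
  stopifnot(n >= 2L, all(vapply(configs, inherits, TRUE, "labyrinth_config")))
  if (any(vapply(configs, function(cf) is.null(cf$curves), TRUE)))
    stop("slide_semilandmarks: configurations must carry their source curves")
  cur <- configs
  energy_path <- numeric(0)
  prev_energy <- Inf
  converged <- FALSE
  it_done <- 0L

  for (it in seq_len(max_iter)) {
    al <- gpa(cur)
    be <- bending_energy_model(al$consensus)
    Bmat <- be$bending_matrix
    new <- cur
    total_e <- 0
    for (i in seq_len(n)) {
      tr_i <- al$transforms[[i]]
      Y <- al$coordinates[[i]]
      cf <- cur[[i]]
      # specimen's source polylines mapped into the aligned frame
      polys <- lapply(cf$curves, function(cv)
        sweep(cv$points, 2L, tr_i$center) %*% tr_i$rotation / tr_i$size)
      free <- setdiff(seq_len(nrow(Y)), cf$fixed)
      Ybest <- Y
      ebest <- sum(Y * (Bmat %*% Y))
      # descend against the current consensus before updating it: solve the
      # closed-form tangent-direction slide (energy is quadratic in the
      # per-landmark slide amounts), then re-project onto the polyline,
      # damping the step if the projection breaks the descent
      for (inner in 1:10) {
        tang <- semilandmark_tangents(Ybest, cf$curve_id, cf$fixed)
        A <- Bmat * tcrossprod(tang)
        b <- -rowSums(tang * (Bmat %*% Ybest))
        s_amt <- numeric(nrow(Y))
        s_amt[free] <- solve(A[free, free] + diag(1e-12, length(free)),
                             b[free])
        damp <- 1
        improved <- FALSE
        for (bt in 1:8) {
          Ytry <- Ybest
          Ytry[free, ] <- Ybest[free, ] +
            damp * s_amt[free] * tang[free, , drop = FALSE]
          for (cn in CANALS) {
            rows <- intersect(free, which(cf$curve_id == cn))
            Ytry[rows, ] <- project_onto_polyline(Ytry[rows, , drop = FALSE],
                                                  polys[[cn]])
          }
          etry <- sum(Ytry * (Bmat %*% Ytry))
          if (etry < ebest) {
            improved <- ebest - etry > tol * max(ebest, 1e-300) / 10
            Ybest <- Ytry
            ebest <- etry
            break
          }
          damp <- damp / 2
        }
        if (!improved) break
      }
      total_e <- total_e + ebest
      # back to the specimen's original frame (lands exactly on the
      # original polyline: the frame map is a similarity)
      Xnew <- Ybest %*% t(tr_i$rotation) * tr_i$size
      Xnew <- sweep(Xnew, 2L, tr_i$center, `+`)
      Xnew[cf$fixed, ] <- cf$landmarks[cf$fixed, ]
      new[[i]]$landmarks <- Xnew
    }
    it_done <- it
    if (total_e > prev_energy) {
      # consensus re-estimation can leave a small plateau oscillation;
      # treat it as convergence and keep the better (previous) iterate
      if (total_e - prev_energy < 1e-2 * prev_energy) converged <- TRUE
      break
    }
    cur <- new
    energy_path <- c(energy_path, total_e)
    if (is.finite(prev_energy) &&
        abs(prev_energy - total_e) < tol * max(prev_energy, 1e-300)) {
      converged <- TRUE
      break
    }
    prev_energy <- total_e
  }
  if (!converged && it_done == max_iter)
    warning("slide_semilandmarks: not converged after ", max_iter,
            " iterations; returning last iterate")
  list(configs = cur, energy = energy_path, converged = converged,
       iterations = it_done)
}
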