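#' Ecology labels recognised by the classifier
#' @export
ECOLOGY_LEVELS <- c("aerial", "aquatic", "arboreal", "fossorial", "terrestrial")

#' Drop ecology groups represented by a single specimen
#'
#' Canonical variates analysis needs a within-group covariance, so groups
#' of n = 1 cannot be used for training; their specimens are removed (and
#' reported) before fitting.
#'
#' @param labels vector of ecology labels, one per specimen.
#' @return list with `keep` (logical vector), `dropped` (indices removed),
#'   `reason` (character, one entry per dropped specimen).
#' @export
filter_singleton_groups <- function(labels) {
  lab <- as.character(labels)
  cnt <- table(lab)
  singles <- names(cnt)[cnt == 1L]
  keep <- !(lab %in% singles)
  if (sum(table(lab[keep]) > 0) < 2L)
    stop("filter_singleton_groups: fewer than 2 groups remain")
  list(keep = keep, dropped = which(!keep),
       reason = sprintf("only member of group '%s'", lab[!keep]))
}

#' Canonical variates analysis of PC scores by ecology group
#'
#' Canonical axes are the eigenvectors of W^-1 B (pooled within-group vs
#' between-group covariance), scaled so the pooled within-group variance
#' along each axis is 1, ordered by descending between/within eigenvalue.
#' At most min(g - 1, k) axes are returned.
#'
#' @param scores n x k matrix of retained PC scores.
#' @param labels ecology labels, one per row; every group needs n >= 2
#'   (see [filter_singleton_groups()]).
#' @return object of class `cva_model`: `canonical_basis` (k x (g-1)),
#'   `group_means` (g x (g-1) canonical positions), `grand_mean`,
#'   `pooled_within_covariance` (k x k), `group_sizes`, `groups`,
#'   `training_scores` (canonical scores of the training specimens),
#'   `training_labels`, `eigenvalues`.
#' @export
fit_cva <- function(scores, labels) {
  X <- as.matrix(scores)
  n <- nrow(X)
  k <- ncol(X)
  g_f <- factor(labels)
  groups <- levels(g_f)
  g <- length(groups)
  if (g < 2L) stop("fit_cva: need at least 2 groups")
  sizes <- table(g_f)
  if (any(sizes < 2L))
    stop("fit_cva: group(s) of size 1: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (n - g <= k)
    stop("fit_cva: pooled within-group covariance singular (n - g <= k); ",
         "retain fewer PCs")
  grand <- colMeans(X)
  means_k <- t(vapply(groups, function(gr)
    colMeans(X[g_f == gr, , drop = FALSE]), numeric(k)))
  W <- matrix(0, k, k)
  B <- matrix(0, k, k)
  for (i in seq_len(g)) {
    Xi <- X[g_f == groups[i], , drop = FALSE]
    Xc <- sweep(Xi, 2L, means_k[i, ])
    W <- W + crossprod(Xc)
    d <- means_k[i, ] - grand
    B <- B + sizes[i] * tcrossprod(d)
  }
  W <- W / (n - g)
  B <- B / (g - 1)
  # eigenproblem W^-1 B via symmetric whitening for numerical stability
  Wi_half <- inv_sqrt_spd(W)
  M <- Wi_half %*% B %*% Wi_half
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(g - 1L, k)
  A <- Wi_half %*% e$vectors[, seq_len(n_axes), drop = FALSE]
  # unit pooled within-group variance along each axis: a' W a = 1 already
  # (Wi_half is symmetric W^-1/2 and eigenvectors are orthonormal); fix signs
  for (j in seq_len(n_axes)) {
    i_max <- which.max(abs(A[, j]))
    if (A[i_max, j] < 0) A[, j] <- -A[, j]
  }
  colnames(A) <- paste0("CV", seq_len(n_axes))
  train <- sweep(X, 2L, grand) %*% A
  gm <- sweep(means_k, 2L, grand) %*% A
  rownames(gm) <- groups
  structure(list(retained_pc_count = k, canonical_basis = A,
                 group_means = gm, group_means_pc = means_k,
                 grand_mean = grand, pooled_within_covariance = W,
                 group_sizes = as.integer(sizes), groups = groups,
                 training_scores = train, training_pc = X,
                 training_labels = g_f,
                 eigenvalues = e$values[seq_len(n_axes)]),
            class = "cva_model")
}

#' @export
print.cva_model <- function(x, ...) {
  cat(sprintf("<cva_model> %d groups (%s), %d PCs, %d canonical axes\n",
              length(x$groups), paste(x$groups, collapse = ", "),
              x$retained_pc_count, ncol(x$canonical_basis)))
  invisible(x)
}

#' Project a specimen's PC scores into canonical space
#'
#' @param model a `cva_model`.
#' @param specimen_scores length-k vector (or n x k matrix) of PC scores.
#' @return canonical coordinates ((g-1)-vector, or matrix).
#' @export
project_cva <- function(model, specimen_scores) {
  x <- if (is.matrix(specimen_scores)) specimen_scores
       else matrix(specimen_scores, nrow = 1L)
  if (ncol(x) != model$retained_pc_count)
    stop("project_cva: expected ", model$retained_pc_count, " PC scores")
  out <- sweep(x, 2L, model$grand_mean) %*% model$canonical_basis
  if (nrow(out) == 1L) drop(out) else out
}

# squared Mahalanobis distances of a PC-space point to every group mean,
# under the pooled within-group covariance
mahalanobis_to_groups <- function(model, specimen_scores) {
  Wi <- solve(model$pooled_within_covariance)
  vapply(seq_along(model$groups), function(i) {
    d <- specimen_scores - model$group_means_pc[i, ]
    drop(t(d) %*% Wi %*% d)
  }, numeric(1))
}

#' Typicality probabilities and ecological assignment for a specimen
#'
#' Computes the Mahalanobis distance from the specimen to each group mean
#' (pooled within-group covariance), then a typicality probability per
#' group: the resampled (bootstrap, `n_perm` draws) fraction of
#' within-group member distances at least as large as the specimen's,
#' with the add-one convention. A specimen farther from a group mean than
#' 95% of that group's own members is atypical of the group. Group
#' assignment is by normalized multivariate-normal likelihood under the
#' pooled covariance with equal priors.
#'
#' @param model a `cva_model`.
#' @param specimen_scores length-k vector of PC scores (a specimen not
#'   used in fitting, for fossils).
#' @param n_perm number of bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param alpha_corrected significance level for the atypicality call
#'   (Bonferroni-corrected upstream).
#' @return object of class `typicality_result`: `mahalanobis` (per group),
#'   `typicality_p` (per group), `likelihood` (per group, sums to 1),
#'   `assigned_group`, `significantly_different` (logical per group).
#' @export
typicality <- function(model, specimen_scores, n_perm = 10000L, seed = 1L,
                       alpha_corrected = 0.05) {
  stopifnot(inherits(model, "cva_model"), n_perm >= 100L)
  d2 <- mahalanobis_to_groups(model, specimen_scores)
  names(d2) <- model$groups
  Wi <- solve(model$pooled_within_covariance)
  set.seed(as.integer(seed))
  # within-group member distances to their own mean, PC space
  member_d2 <- lapply(seq_along(model$groups), function(i) {
    idx <- which(model$training_labels == model$groups[i])
    vapply(idx, function(j) {
      dv <- model$training_pc[j, ] - model$group_means_pc[i, ]
      drop(t(dv) %*% Wi %*% dv)
    }, numeric(1))
  })
  tp <- vapply(seq_along(model$groups), function(i) {
    boot <- sample(member_d2[[i]], n_perm, replace = TRUE)
    (sum(boot >= d2[i]) + 1) / (n_perm + 1)
  }, numeric(1))
  names(tp) <- model$groups
  loglik <- -0.5 * d2
  lik <- exp(loglik - max(loglik))
  lik <- lik / sum(lik)
  names(lik) <- model$groups
  structure(list(mahalanobis = sqrt(d2), typicality_p = tp,
                 likelihood = lik,
                 assigned_group = model$groups[which.max(lik)],
                 significantly_different = tp < alpha_corrected,
                 n_permutations = n_perm),
            class = "typicality_result")
}

#' @export
print.typicality_result <- function(x, ...) {
  cat(sprintf("assigned group: %s\n", x$assigned_group))
  print(data.frame(mahalanobis = round(x$mahalanobis, 3),
                   typicality_p = signif(x$typicality_p, 3),
                   likelihood = signif(x$likelihood, 3)))
  invisible(x)
}

#' Confidence ellipse of a group in a canonical-variate plane
#'
#' Ellipse from the group's 2D canonical-score covariance scaled by the
#' chi-square quantile at `level` with 2 degrees of freedom.
#'
#' @param model a `cva_model`.
#' @param group group name.
#' @param level coverage level (default 0.95).
#' @param axes pair of canonical-axis indices (default c(1, 2)).
#' @return list with `center` (2-vector), `semi_axes` (2-vector,
#'   descending), `orientation` (2 x 2 rotation, columns = ellipse axes).
#' @export
confidence_ellipse <- function(model, group, level = 0.95, axes = c(1L, 2L)) {
  stopifnot(inherits(model, "cva_model"), group %in% model$groups,
            level >= 0, level < 1)
  idx <- which(model$training_labels == group)
  if (length(idx) < 3L) stop("confidence_ellipse: group needs n >= 3")
  S2 <- model$training_scores[idx, axes, drop = FALSE]
  ctr <- colMeans(S2)
  V <- stats::cov(S2)
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("confidence_ellipse: degenerate 2D covariance")
  r2 <- stats::qchisq(level, df = 2)
  list(center = ctr, semi_axes = sqrt(e$values * r2), orientation = e$vectors)
}

#' Classification accuracy of a CVA
#'
#' Fraction of specimens whose maximum-likelihood group assignment
#' (Mahalanobis distance under the pooled within-group covariance, equal
#' priors) matches their label; either resubstitution on the fitted model
#' or leave-one-out (the model is refit without each specimen).
#'
#' @param scores n x k PC scores.
#' @param labels ecology labels.
#' @param method `"resubstitution"` or `"loo"`.
#' @return fraction in [0, 1].
#' @export
classification_accuracy <- function(scores, labels,
                                    method = c("resubstitution", "loo")) {
  method <- match.arg(method)
  X <- as.matrix(scores)
  lab <- factor(labels)
  n <- nrow(X)
  pred <- character(n)
  if (method == "resubstitution") {
    model <- fit_cva(X, lab)
    for (i in seq_len(n)) {
      d2 <- mahalanobis_to_groups(model, X[i, ])
      pred[i] <- model$groups[which.min(d2)]
    }
  } else {
    for (i in seq_len(n)) {
      model <- fit_cva(X[-i, , drop = FALSE], droplevels(lab[-i]))
      d2 <- mahalanobis_to_groups(model, X[i, ])
      pred[i] <- model$groups[which.min(d2)]
    }
  }
  mean(pred == as.character(lab))
}
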