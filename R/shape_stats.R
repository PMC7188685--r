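#' @keywords internal
hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# Shared RRPP engine: sequential (Type I) sums of squares over a nested
# design sequence, with significance from residual randomization under
# each term's reduced model. `designs` is a list of design matrices from
# intercept-only to the full model; the same permutation schedule is used
# for every term (drawn once from `seed`).
rrpp_sequential <- function(Y, designs, term_names, n_perm, seed) {
  n <- nrow(Y)
  hats <- lapply(designs, hat_matrix)
  ranks <- vapply(designs, function(X) qr(X)$rank, 1L)
  nt <- length(designs) - 1L
  H0 <- hats[[1L]]
  Hf <- hats[[length(hats)]]
  ss_total <- sum(Y * ((diag(n) - H0) %*% Y))
  if (ss_total <= n * 1e-14)
    stop("constant response matrix: no variation to partition")
  ss_res <- sum(Y * ((diag(n) - Hf) %*% Y))
  df_res <- n - ranks[length(ranks)]

  ss <- df <- numeric(nt)
  for (i in seq_len(nt)) {
    ss[i] <- sum(Y * ((hats[[i + 1L]] - hats[[i]]) %*% Y))
    df[i] <- ranks[i + 1L] - ranks[i]
  }
  Fobs <- (ss / df) / (ss_res / df_res)

  set.seed(as.integer(seed))
  perms <- lapply(seq_len(n_perm), function(b) sample.int(n))
  p <- z <- numeric(nt)
  for (i in seq_len(nt)) {
    Hr <- hats[[i]]
    Dh <- hats[[i + 1L]] - Hr
    fit_r <- Hr %*% Y
    res_r <- Y - fit_r
    Fperm <- vapply(perms, function(pr) {
      Ystar <- fit_r + res_r[pr, , drop = FALSE]
      ssi <- sum(Ystar * (Dh %*% Ystar))
      sse <- sum(Ystar * ((diag(n) - Hf) %*% Ystar))
      (ssi / df[i]) / (sse / df_res)
    }, numeric(1))
    b <- sum(Fperm >= Fobs[i])
    p[i] <- (b + 1) / (n_perm + 1)
    z[i] <- stats::qnorm(1 - p[i])
  }
  tab <- data.frame(
    Df = c(df, df_res, n - ranks[1L]),
    SS = c(ss, ss_res, ss_total),
    R2 = c(ss / ss_total, ss_res / ss_total, 1),
    F = c(Fobs, NA, NA),
    Z = c(z, NA, NA),
    p = c(p, NA, NA),
    row.names = c(term_names, "Residuals", "Total"))
  tab
}

#' Permutation Procrustes ANCOVA of shape on ecology and size
#'
#' Fits the sequential (Type I) linear model shape ~ ecology + size +
#' ecology:size on tangent-space shape coordinates, with term significance
#' by residual randomization in a permutation procedure (RRPP): each
#' term's reduced-model residuals are permuted, the model refit, and the
#' permutation F distribution compared with the observed F (add-one p).
#'
#' @param shape n x p matrix of tangent coordinates (or PC scores).
#' @param ecology factor or character vector of ecology labels.
#' @param size positive covariate (centroid size).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param log_size if TRUE, the covariate enters as log(size).
#' @param alpha,n_tests nominal alpha and the number of tests in the
#'   family, used to report the Bonferroni-corrected level.
#' @return an object of class `anova_table`.
#' @export
procrustes_ancova <- function(shape, ecology, size, n_perm = 1000L, seed = 1L,
                              log_size = FALSE, alpha = 0.05, n_tests = 1L) {
  Y <- as.matrix(shape)
  n <- nrow(Y)
  eco <- factor(ecology)
  if (length(eco) != n || length(size) != n)
    stop("procrustes_ancova: ecology/size length mismatch")
  cnt <- table(eco)
  if (any(cnt < 2L))
    stop("procrustes_ancova: ecology group(s) of size 1: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  s <- if (log_size) log(size) else as.numeric(size)
  designs <- list(
    matrix(1, n, 1L),
    stats::model.matrix(~eco),
    stats::model.matrix(~eco + s),
    stats::model.matrix(~eco * s))
  if (n < ncol(designs[[4L]]) + 2L)
    stop("procrustes_ancova: too few specimens for the model")
  tab <- rrpp_sequential(Y, designs, c("ecology", "size", "ecology:size"),
                         n_perm, seed)
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 alpha_corrected = bonferroni_alpha(alpha, n_tests),
                 type = "ANCOVA"),
            class = "anova_table")
}

#' Phylogenetic generalized least squares on shape (permutation test)
#'
#' Whitens the shape data and the design by the inverse square root of the
#' Brownian-motion covariance of the tree, then applies the same RRPP
#' machinery as [procrustes_ancova()] in the transformed space. On a star
#' tree with unit branch lengths the covariance is the identity and the
#' table equals the non-phylogenetic ANCOVA.
#'
#' @inheritParams procrustes_ancova
#' @param tree a `time_tree` whose tips match the shape rows (by row name
#'   if present, otherwise by order).
#' @return an object of class `anova_table`.
#' @export
procrustes_pgls <- function(shape, ecology, size, tree, n_perm = 1000L,
                            seed = 1L, log_size = FALSE, alpha = 0.05,
                            n_tests = 1L) {
  Y <- as.matrix(shape)
  n <- nrow(Y)
  C <- bm_covariance(tree)
  if (nrow(C) != n) stop("procrustes_pgls: tree tip count mismatch")
  if (!is.null(rownames(Y))) {
    ord <- match(colnames(C), rownames(Y))
    if (anyNA(ord)) stop("procrustes_pgls: shape rows do not match tips")
    Y <- Y[ord, , drop = FALSE]
    ecology <- ecology[ord]
    size <- size[ord]
  }
  eco <- factor(ecology)
  cnt <- table(eco)
  if (any(cnt < 2L))
    stop("procrustes_pgls: ecology group(s) of size 1: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  s <- if (log_size) log(size) else as.numeric(size)
  P <- inv_sqrt_spd(C)
  designs <- list(
    matrix(1, n, 1L),
    stats::model.matrix(~eco),
    stats::model.matrix(~eco + s),
    stats::model.matrix(~eco * s))
  designs <- lapply(designs, function(X) P %*% X)
  tab <- rrpp_sequential(P %*% Y, designs,
                         c("ecology", "size", "ecology:size"), n_perm, seed)
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 alpha_corrected = bonferroni_alpha(alpha, n_tests),
                 type = "PGLS"),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Procrustes %s (RRPP, %d permutations, seed %d)\n",
              x$type, x$n_perm, x$seed))
  print(round(x$table, 5))
  cat(sprintf("Bonferroni-corrected alpha: %.4g\n", x$alpha_corrected))
  invisible(x)
}

#' Bonferroni-corrected alpha level
#'
#' alpha / m, truncated (not rounded) to three significant figures for
#' reporting: 0.05 over 3 tests gives 0.0166, over 8 gives 0.00625.
#'
#' @param alpha nominal significance level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return the corrected level.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 1L) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  x <- alpha / m
  f <- 10^(floor(log10(x)) - 2)
  trunc(round(x / f, 9)) * f
}
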