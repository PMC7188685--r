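test_that("centroid size matches hand values and the naive double loop", {
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(centroid_size(sq), sqrt(8))
  expect_equal(centroid_size(3.7 * sq), 3.7 * sqrt(8))
  set.seed(31)
  X <- matrix(rnorm(180L), 60L, 3L)
  ctr <- colMeans(X)
  naive <- 0
  for (i in seq_len(60L)) naive <- naive + sum((X[i, ] - ctr)^2)
  expect_equal(centroid_size(X), sqrt(naive))
})

test_that("gpa exactly aligns similarity-transformed copies of one shape", {
  set.seed(32)
  X <- matrix(rnorm(180L), 60L, 3L)
  Y <- 2.5 * X %*% random_rotation() + rep(1, 60L) %o% c(4, -2, 9)
  al <- gpa(list(X, Y))
  expect_lt(sqrt(sum((al$coordinates[[1L]] - al$coordinates[[2L]])^2)), 1e-8)
  for (i in 1:2) {
    expect_lt(max(abs(colMeans(al$coordinates[[i]]))), 1e-9)
    expect_equal(centroid_size(al$coordinates[[i]]), 1, tolerance = 1e-9)
  }
})

test_that("pairwise gpa agrees with an independent Kabsch SVD oracle", {
  set.seed(33)
  A <- matrix(rnorm(36L), 12L, 3L)
  B <- A + matrix(rnorm(36L, sd = 0.3), 12L, 3L)
  # oracle: closed-form orthogonal Procrustes superposition of the
  # unit-size centered shapes, written independently of the package
  ctr <- function(x) sweep(x, 2L, colMeans(x))
  nrm <- function(x) x / sqrt(sum(x^2))
  a <- nrm(ctr(A)); b <- nrm(ctr(B))
  s <- svd(t(b) %*% a)                      # rotate b onto a
  R <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
  d_oracle <- sqrt(sum((b %*% R - a)^2))
  al <- gpa(list(A, B))
  d_pkg <- sqrt(sum((al$coordinates[[1L]] - al$coordinates[[2L]])^2))
  expect_equal(d_pkg, d_oracle, tolerance = 1e-8)
})

test_that("gpa never uses reflections: a mirrored chiral shape keeps residual", {
  cfg <- chiral_config()
  m <- mirror_configuration(cfg)
  al <- gpa(list(cfg$landmarks, m$landmarks))
  d_norefl <- sqrt(sum((al$coordinates[[1L]] - al$coordinates[[2L]])^2))
  # oracle allowing reflection: plain SVD solution without the det fix
  ctr <- function(x) sweep(x, 2L, colMeans(x))
  nrm <- function(x) x / sqrt(sum(x^2))
  a <- nrm(ctr(cfg$landmarks)); b <- nrm(ctr(m$landmarks))
  s <- svd(t(b) %*% a)
  d_refl <- sqrt(sum((b %*% (s$u %*% t(s$v)) - a)^2))
  expect_lt(d_refl, 1e-8)     # reflection recovers the shape exactly
  expect_gt(d_norefl, 1e-3)   # rotation-only alignment cannot
})

test_that("gpa output is invariant to pre-transforming any input", {
  tt <- simulate_tree(8L, seed = 35L)
  sim <- simulate_shapes(simulation_spec(n_taxa = 8L, seed = 36L), tt$tree)
  mats <- lapply(sim$configs, `[[`, "landmarks")
  al1 <- gpa(mats)
  set.seed(37)
  mats2 <- mats
  mats2[[3L]] <- 0.2 * mats2[[3L]] %*% random_rotation() +
    rep(1, 60L) %o% c(10, 0, -5)
  al2 <- gpa(mats2)
  expect_equal(al1$coordinates[[3L]], al2$coordinates[[3L]], tolerance = 1e-7)
  expect_equal(al1$consensus, al2$consensus, tolerance = 1e-7)
})

test_that("pca recovers planted variance structure and reconstruction identity", {
  tt <- simulate_tree(10L, seed = 38L)
  sim <- simulate_shapes(simulation_spec(n_taxa = 10L, seed = 39L), tt$tree)
  al <- gpa(sim$configs)
  sp <- pca_shapes(al)
  expect_true(all(diff(sp$eigenvalues) <= 1e-12))
  expect_equal(sum(sp$variance_fractions), 1)
  # scores reproduce the centered tangent coordinates
  X <- do.call(rbind, lapply(al$coordinates, canalmorph:::flatten_config))
  m <- canalmorph:::flatten_config(al$consensus)
  v <- m / sqrt(sum(m^2))
  Xc <- sweep(X, 2L, m)
  Xt <- Xc - (Xc %*% v) %*% t(v)
  expect_equal(unname(sp$scores %*% sp$loadings), unname(Xt),
               tolerance = 1e-8)
  # scores are mutually orthogonal columns
  G <- crossprod(sp$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("a rank-1 sample yields a single axis carrying all variance", {
  base <- labyrinth_config(base_labyrinth_template(), "a")$landmarks
  dir <- matrix(0, 60L, 3L)
  dir[5L, 1L] <- 1
  mats <- lapply(seq(-0.02, 0.02, length.out = 6L),
                 function(a) base + a * dir)
  al <- gpa(mats)
  sp <- pca_shapes(al)
  expect_gt(sp$variance_fractions[1L], 0.999)
})

test_that("identical shapes are rejected by pca", {
  base <- labyrinth_config(base_labyrinth_template(), "a")$landmarks
  al <- gpa(list(base, base, base))
  expect_error(pca_shapes(al), "identical")
})

test_that("planted two-factor variance 3:1 is recovered at n = 200", {
  set.seed(40)
  n <- 200L
  X0 <- labyrinth_config(base_labyrinth_template(), "a")$landmarks
  X0 <- sweep(X0, 2L, colMeans(X0))
  X0 <- X0 / sqrt(sum(X0^2))
  base <- as.vector(t(X0))
  # similarity-group tangent directions at the template: translations,
  # scaling, infinitesimal rotations -- planted deviations must avoid these
  # or alignment redistributes their variance
  sim_dirs <- cbind(
    rep(c(1, 0, 0), 60L), rep(c(0, 1, 0), 60L), rep(c(0, 0, 1), 60L),
    base,
    as.vector(t(X0 %*% matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3L))),
    as.vector(t(X0 %*% matrix(c(0, 0, -1, 0, 0, 0, 1, 0, 0), 3L))),
    as.vector(t(X0 %*% matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3L))))
  Qs <- qr.Q(qr(sim_dirs))
  ortho <- function(v) {
    v <- v - Qs %*% (t(Qs) %*% v)
    v / sqrt(sum(v^2))
  }
  d1 <- ortho(rnorm(180L))
  d2 <- ortho(rnorm(180L))
  d2 <- d2 - sum(d2 * d1) * d1; d2 <- d2 / sqrt(sum(d2^2))
  mats <- lapply(seq_len(n), function(i)
    matrix(base + rnorm(1L, sd = sqrt(3) * 0.01) * d1 +
             rnorm(1L, sd = 0.01) * d2, 60L, 3L, byrow = TRUE))
  sp <- pca_shapes(gpa(mats))
  expect_lt(abs(sp$variance_fractions[1L] - 0.75), 0.05)
  expect_lt(abs(sp$variance_fractions[2L] - 0.25), 0.05)
})

test_that("minimum-PC selection matches a cumulative scan", {
  expect_equal(min_pcs_for_variance(c(0.6, 0.3, 0.1), 0.95), 3L)
  expect_equal(min_pcs_for_variance(c(0.96, 0.03, 0.01), 0.95), 1L)
  set.seed(41)
  fr <- sort(runif(12L), decreasing = TRUE); fr <- fr / sum(fr)
  for (th in c(0.5, 0.9, 0.99)) {
    oracle <- which(cumsum(fr) >= th)[1L]
    expect_equal(min_pcs_for_variance(fr, th), oracle)
  }
})
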