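# planted two-group scores: groups separated along a chosen coordinate
planted_scores <- function(n_per, k, sep, axis = 1L) {
  X <- matrix(stats::rnorm(2L * n_per * k), 2L * n_per, k)
  X[seq_len(n_per), axis] <- X[seq_len(n_per), axis] + sep
  list(scores = X, labels = rep(c("aquatic", "terrestrial"), each = n_per))
}

test_that("singleton ecology groups are dropped with a reason", {
  lab <- c(rep("aquatic", 3L), rep("aerial", 2L), "fossorial")
  f <- filter_singleton_groups(lab)
  expect_equal(f$dropped, 6L)
  expect_match(f$reason, "fossorial")
  expect_true(all(table(lab[f$keep]) >= 2L))
  f2 <- filter_singleton_groups(rep(c("a", "b"), each = 4L))
  expect_length(f2$dropped, 0L)
  # two singleton groups, counts verified against a frequency table
  lab3 <- c(rep("aquatic", 2L), "aerial", "arboreal", rep("terrestrial", 2L))
  f3 <- filter_singleton_groups(lab3)
  expect_equal(sort(lab3[f3$dropped]), c("aerial", "arboreal"))
  expect_error(filter_singleton_groups(c("a", "b", "c")), "fewer than 2")
})

test_that("CVA recovers a planted separating direction and normalizes within-variance", {
  set.seed(71)
  d <- planted_scores(300L, 5L, sep = 10)
  m <- fit_cva(d$scores, d$labels)
  expect_equal(ncol(m$canonical_basis), 1L)          # g = 2 -> one axis
  cv1 <- m$canonical_basis[, 1L]
  expect_gt(abs(cv1[1L]) / sqrt(sum(cv1^2)), 0.99)   # aligned with axis 1
  # independent cross-check: MASS::lda discriminant direction
  sc <- MASS::lda(d$scores, grouping = factor(d$labels))$scaling[, 1L]
  expect_gt(abs(sum(cv1 * sc)) / sqrt(sum(cv1^2) * sum(sc^2)), 1 - 1e-8)
  # pooled within-group variance of training scores along each CV is 1
  w <- tapply(m$training_scores[, 1L], m$training_labels, function(x)
    sum((x - mean(x))^2))
  expect_equal(sum(w) / (600L - 2L), 1, tolerance = 1e-6)
})

test_that("projection is affine, maps group means to canonical means, and is self-consistent", {
  set.seed(72)
  X <- matrix(rnorm(80L * 4L), 80L)
  lab <- rep(c("aerial", "aquatic", "arboreal", "terrestrial"), each = 20L)
  m <- fit_cva(X, lab)
  for (i in seq_along(m$groups))
    expect_equal(unname(project_cva(m, m$group_means_pc[i, ])),
                 unname(m$group_means[i, ]), tolerance = 1e-9)
  a <- rnorm(4L); b <- rnorm(4L)
  expect_equal(project_cva(m, a) - project_cva(m, b),
               drop(t(m$canonical_basis) %*% (a - b)), tolerance = 1e-10)
  expect_equal(unname(project_cva(m, X)), unname(m$training_scores),
               tolerance = 1e-9)
})

test_that("typicality hits its limiting values and likelihoods sum to one", {
  set.seed(73)
  d <- planted_scores(25L, 3L, sep = 6)
  m <- fit_cva(d$scores, d$labels)
  at_mean <- typicality(m, m$group_means_pc[1L, ], n_perm = 200L, seed = 1L)
  expect_equal(unname(at_mean$typicality_p[1L]), 1)
  expect_equal(unname(at_mean$mahalanobis[1L]), 0)
  far <- typicality(m, rep(1e3, 3L), n_perm = 200L, seed = 1L)
  expect_true(all(far$typicality_p == 1 / 201))
  expect_equal(sum(far$likelihood), 1, tolerance = 1e-9)
  expect_equal(at_mean$assigned_group, "aquatic")
})

test_that("Mahalanobis machinery is invariant to invertible linear maps", {
  set.seed(74)
  d <- planted_scores(20L, 4L, sep = 5)
  m1 <- fit_cva(d$scores, d$labels)
  A <- matrix(rnorm(16L), 4L) + 4 * diag(4L)
  m2 <- fit_cva(d$scores %*% A, d$labels)
  q <- rnorm(4L)
  d1 <- canalmorph:::mahalanobis_to_groups(m1, q)
  d2 <- canalmorph:::mahalanobis_to_groups(m2, drop(q %*% A))
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("typicality is deterministic under a fixed seed", {
  set.seed(75)
  d <- planted_scores(15L, 3L, sep = 4)
  m <- fit_cva(d$scores, d$labels)
  q <- rnorm(3L)
  r1 <- typicality(m, q, n_perm = 500L, seed = 42L)
  r2 <- typicality(m, q, n_perm = 500L, seed = 42L)
  expect_identical(r1$typicality_p, r2$typicality_p)
  expect_identical(r1$likelihood, r2$likelihood)
})

test_that("confidence ellipses follow the chi-square scaling of the score covariance", {
  set.seed(76)
  n_per <- 2000L
  X <- matrix(rnorm(3L * n_per * 4L), 3L * n_per, 4L)
  lab <- rep(c("aerial", "aquatic", "terrestrial"), each = n_per)
  X[lab == "aquatic", 1L] <- X[lab == "aquatic", 1L] + 8
  X[lab == "terrestrial", 2L] <- X[lab == "terrestrial", 2L] + 8
  m <- fit_cva(X, lab)
  e <- confidence_ellipse(m, "aquatic", level = 0.95)
  # canonical axes carry unit within-group variance, so at large n the
  # 95% ellipse of a group approaches a circle of radius sqrt(chi2_{.95,2})
  r <- sqrt(stats::qchisq(0.95, 2L))
  expect_equal(r, 2.4477, tolerance = 1e-4)
  expect_equal(unname(e$semi_axes), c(r, r), tolerance = 0.08)
  e0 <- confidence_ellipse(m, "aquatic", level = 0)
  expect_equal(unname(e0$semi_axes), c(0, 0))
})

test_that("classification accuracy reaches 1 on separated groups and chance on shuffled labels", {
  set.seed(77)
  d <- planted_scores(25L, 4L, sep = 12)
  expect_equal(classification_accuracy(d$scores, d$labels), 1)
  n <- 400L
  X <- matrix(rnorm(n * 3L), n)
  lab <- sample(rep(c("a", "b", "c", "d"), each = 100L))
  acc <- classification_accuracy(X, lab, "loo")
  expect_lt(abs(acc - 0.25), 0.05)
})

test_that("leave-one-out accuracy does not exceed resubstitution on average", {
  set.seed(78)
  diffs <- replicate(30L, {
    X <- matrix(rnorm(36L * 3L), 36L)
    lab <- rep(c("a", "b", "c"), each = 12L)
    X[lab == "b", 1L] <- X[lab == "b", 1L] + 1.2   # overlapping groups
    X[lab == "c", 2L] <- X[lab == "c", 2L] + 1.2
    classification_accuracy(X, lab, "resubstitution") -
      classification_accuracy(X, lab, "loo")
  })
  expect_gte(mean(diffs), 0)
})

test_that("CVA of canonical scores is the identity up to sign", {
  set.seed(79)
  X <- matrix(rnorm(60L * 4L), 60L)
  lab <- rep(c("a", "b", "c"), each = 20L)
  m1 <- fit_cva(X, lab)
  m2 <- fit_cva(m1$training_scores, lab)
  S <- m2$training_scores
  for (j in seq_len(ncol(S))) {
    cors <- abs(stats::cor(S[, j], m1$training_scores))
    expect_gt(max(cors), 0.9999)
  }
})
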