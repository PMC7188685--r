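test_that("extinction rate is recovered from exponential durations", {
  set.seed(51)
  d <- rexp(500L, rate = 0.5) + 1.01   # all above the 1 Myr resolution
  r1 <- estimate_rates(d, interval_length = 1)
  # with no censored taxa the ML estimate is the plain exponential MLE
  expect_lt(abs(r1$extinction_rate - 1 / mean(d)), 1e-10)
  r2 <- estimate_rates(rexp(500L, rate = 0.5), interval_length = 0.01)
  expect_equal(r2$extinction_rate, 0.5, tolerance = 0.15)
})

test_that("doubling durations halves the extinction rate; rates tied", {
  set.seed(52)
  d <- rexp(200L, 0.4) + 1.5
  r1 <- estimate_rates(d, interval_length = 1)
  r2 <- estimate_rates(2 * d, interval_length = 2)
  expect_equal(r2$extinction_rate, r1$extinction_rate / 2, tolerance = 1e-8)
  expect_identical(r1$speciation_rate, r1$extinction_rate)
})

test_that("degenerate duration data is rejected", {
  expect_error(estimate_rates(c(0, 0, 0)), "uninformative")
  expect_error(estimate_rates(c(1, 2)), "at least 3")
})

test_that("calibrated trees honour stratigraphic constraints", {
  ph <- ape::read.tree(text = "(A,B);")
  occ <- data.frame(taxon = c("A", "B"),
                    first_appearance = c(80, 70),
                    last_appearance = c(72, 0))
  rates <- structure(list(sampling_rate = 0.5, extinction_rate = 0.2,
                          speciation_rate = 0.2), class = "rate_estimates")
  trees <- time_calibrate(ph, occ, rates, n_trees = 50L, seed = 7L)
  roots <- vapply(trees, `[[`, numeric(1), "root_age")
  expect_true(all(roots >= 80))
  expect_true(all(vapply(trees, function(t) all(t$phylo$edge.length > 0),
                         logical(1))))
  # tips terminate at their last appearances
  expect_equal(trees[[1L]]$tip_ages, c(A = 72, B = 0))
})

test_that("extensions shrink as the sampling rate grows", {
  ph <- ape::read.tree(text = "((A,B),(C,D));")
  occ <- data.frame(taxon = c("A", "B", "C", "D"),
                    first_appearance = c(60, 50, 40, 0),
                    last_appearance = c(55, 45, 30, 0))
  mk_rates <- function(r) structure(list(sampling_rate = r,
                                         extinction_rate = 0.2,
                                         speciation_rate = 0.2),
                                    class = "rate_estimates")
  root_mean <- function(r) mean(vapply(
    time_calibrate(ph, occ, mk_rates(r), n_trees = 100L, seed = 3L),
    `[[`, numeric(1), "root_age"))
  lo <- root_mean(0.01)
  hi <- root_mean(100)
  expect_gt(lo, hi)
  expect_lt(hi - 60, 0.2)    # near the minimum-age bound
})

test_that("calibration is deterministic under a fixed seed", {
  ph <- ape::read.tree(text = "((A,B),C);")
  occ <- data.frame(taxon = c("A", "B", "C"),
                    first_appearance = c(10, 8, 12),
                    last_appearance = c(2, 0, 6))
  rates <- structure(list(sampling_rate = 1, extinction_rate = 0.3,
                          speciation_rate = 0.3), class = "rate_estimates")
  t1 <- time_calibrate(ph, occ, rates, n_trees = 10L, seed = 9L)
  t2 <- time_calibrate(ph, occ, rates, n_trees = 10L, seed = 9L)
  expect_identical(lapply(t1, `[[`, "node_ages"), lapply(t2, `[[`, "node_ages"))
  expect_error(time_calibrate(ape::read.tree(text = "(A,Z);"), occ, rates,
                              2L, 1L), "without occurrence")
})

test_that("the consensus tree averages node ages", {
  ph <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  t80 <- time_tree(local({p <- ph; p$edge.length <- c(40, 40, 40, 80); p}), 80)
  t100 <- time_tree(local({p <- ph; p$edge.length <- c(50, 50, 50, 100); p}), 100)
  cons <- consensus_tree(list(t80, t100))
  expect_equal(cons$root_age, 90)
  expect_equal(consensus_tree(rep(list(t80), 250L))$node_ages, t80$node_ages)
  # brute-force per-node average
  expect_equal(cons$node_ages, (t80$node_ages + t100$node_ages) / 2)
})

test_that("bm covariance matches trivial cases and path enumeration", {
  st <- star_tree(5L, len = 3)
  expect_equal(unname(bm_covariance(st)), 3 * diag(5L))
  t2 <- time_tree(ape::read.tree(text = "(A:7,B:7);"), 7)
  expect_equal(unname(bm_covariance(t2)), 7 * diag(2L))
  # 4-tip balanced tree: oracle by enumerating shared root-to-MRCA paths
  bt <- balanced4_tree()
  C <- bm_covariance(bt)
  oracle <- matrix(0, 4L, 4L, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(oracle) <- 2
  oracle["A", "B"] <- oracle["B", "A"] <- 1   # share the root->AB-node path
  oracle["C", "D"] <- oracle["D", "C"] <- 1
  expect_equal(C[rownames(oracle), colnames(oracle)], oracle)
})

test_that("univariate multivariate-K reduces to the direct K formula", {
  bt <- balanced4_tree()
  x <- matrix(c(1.2, 0.9, -0.4, -1.1), 4L, 1L,
              dimnames = list(LETTERS[1:4], NULL))
  # independent direct-formula oracle (Blomberg et al. univariate K)
  C <- bm_covariance(bt)
  Ci <- solve(C)
  n <- 4L
  a <- sum(Ci %*% x) / sum(Ci)
  xc <- x - a
  num <- sum(xc^2) / (t(xc) %*% Ci %*% xc)
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  k_oracle <- drop(num) / expected
  res <- blomberg_k_mult(x, bt, n_perm = 23L, seed = 1L)
  expect_equal(res$K, k_oracle, tolerance = 1e-8)
  expect_gte(res$p_value, 1 / 24)
})

test_that("univariate K agrees with phytools::phylosig", {
  set.seed(55)
  tt <- simulate_tree(16L, seed = 56L)$tree
  x <- drop(rbm_tips(tt, 1L))
  res <- blomberg_k_mult(matrix(x, ncol = 1L,
                                dimnames = list(names(x), NULL)),
                         tt, n_perm = 5L, seed = 1L)
  k_ref <- unname(phytools::phylosig(tt$phylo, x, method = "K"))
  expect_equal(res$K, as.numeric(k_ref), tolerance = 1e-6)
})

test_that("K is invariant to global scaling and rotation of the data", {
  set.seed(57)
  tt <- simulate_tree(12L, seed = 58L)$tree
  Y <- rbm_tips(tt, 4L)
  k0 <- blomberg_k_mult(Y, tt, n_perm = 3L, seed = 1L)$K
  k_scaled <- blomberg_k_mult(10 * Y, tt, n_perm = 3L, seed = 1L)$K
  Q <- qr.Q(qr(matrix(rnorm(16L), 4L)))
  k_rot <- blomberg_k_mult(Y %*% Q, tt, n_perm = 3L, seed = 1L)$K
  expect_equal(k_scaled, k0, tolerance = 1e-10)
  expect_equal(k_rot, k0, tolerance = 1e-10)
})

test_that("ancestral states match closed forms and a GLS oracle", {
  st <- star_tree(6L, len = 2)
  Y <- matrix(rnorm(12L), 6L, 2L, dimnames = list(paste0("t", 1:6), NULL))
  anc <- ancestral_states_bm(Y, st)
  expect_equal(unname(anc[1L, ]), unname(colMeans(Y)))

  t2 <- time_tree(ape::read.tree(text = "(A:3,B:5);"), 5)
  Y2 <- matrix(c(1, 9), 2L, 1L, dimnames = list(c("A", "B"), NULL))
  anc2 <- ancestral_states_bm(Y2, t2)
  expect_equal(unname(drop(anc2)), (1 / 3 + 9 / 5) / (1 / 3 + 1 / 5))

  # 5-tip fixture versus ape::ace ML estimates
  ph <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(D:1.5,E:1.5):1.5);")
  tt <- time_tree(ph, 3)
  set.seed(59)
  y <- rnorm(5L)
  names(y) <- ph$tip.label
  anc5 <- ancestral_states_bm(matrix(y, ncol = 1L,
                                     dimnames = list(names(y), NULL)), tt)
  ref <- ape::ace(y, ph, method = "ML")$ace
  expect_equal(unname(drop(anc5)), unname(ref[rownames(anc5)]),
               tolerance = 1e-4)
})
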