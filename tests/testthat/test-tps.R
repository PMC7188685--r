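test_that("bending energy vanishes for the reference and its affine images", {
  set.seed(11)
  ref <- matrix(rnorm(15L), 5L, 3L)
  bm <- bending_energy_model(ref)
  expect_lt(abs(bending_energy(bm, ref)), 1e-10)
  A <- matrix(rnorm(9L), 3L, 3L)
  aff <- ref %*% A + rep(1, 5L) %o% c(2, -1, 3)
  expect_lt(abs(bending_energy(bm, aff)), 1e-8)
})

test_that("bending energy is invariant to rigid motion of the target", {
  set.seed(12)
  ref <- matrix(rnorm(24L), 8L, 3L)
  bm <- bending_energy_model(ref)
  tgt <- ref + matrix(rnorm(24L, sd = 0.1), 8L, 3L)
  e0 <- bending_energy(bm, tgt)
  moved <- tgt %*% random_rotation() + rep(1, 8L) %o% c(5, 5, 5)
  expect_equal(bending_energy(bm, moved), e0, tolerance = 1e-10)
  expect_gt(e0, 0)
})

test_that("bending energy matches an independent TPS L-matrix evaluation", {
  # oracle: solve the interpolation system L [W; A] = [T; 0] and evaluate
  # the classical energy identity trace(W' K W) with the 3D kernel -r
  set.seed(13)
  ref <- matrix(rnorm(15L), 5L, 3L)
  tgt <- ref
  tgt[2L, ] <- tgt[2L, ] + c(0.4, -0.2, 0.1)
  K <- -as.matrix(dist(ref))
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4L, 4L)))
  sol <- solve(L, rbind(tgt, matrix(0, 4L, 3L)))
  W <- sol[1:5, , drop = FALSE]
  oracle <- sum(diag(t(W) %*% K %*% W))
  bm <- bending_energy_model(ref)
  expect_equal(bending_energy(bm, tgt), oracle, tolerance = 1e-8)
})

test_that("coincident reference landmarks are reported by index", {
  ref <- matrix(rnorm(15L), 5L, 3L)
  ref[4L, ] <- ref[2L, ]
  expect_error(bending_energy_model(ref), "2.*4|coincident")
})

test_that("sliding keeps endpoints fixed, stays on the polyline, and lowers energy", {
  tpl <- base_labyrinth_template()
  base <- labyrinth_config(tpl, "a")
  # second specimen: same curves, interior landmarks perturbed along-curve
  pert <- base
  for (cn in CANALS) {
    rows <- which(pert$curve_id == cn)
    interior <- rows[-c(1L, length(rows))]
    poly <- pert$curves[[cn]]$points
    # move each interior landmark toward its next neighbour (along curve)
    pert$landmarks[interior, ] <- 0.65 * pert$landmarks[interior, ] +
      0.35 * pert$landmarks[interior + 1L, ]
  }
  configs <- list(base, pert)
  configs[[2L]]$specimen_id <- "b"

  al0 <- gpa(configs)
  bm0 <- bending_energy_model(al0$consensus)
  e_pre <- sum(vapply(al0$coordinates, function(y) bending_energy(bm0, y),
                      numeric(1)))
  sl <- suppressWarnings(slide_semilandmarks(configs, max_iter = 8L))
  al1 <- gpa(sl$configs)
  bm1 <- bending_energy_model(al1$consensus)
  e_post <- sum(vapply(al1$coordinates, function(y) bending_energy(bm1, y),
                       numeric(1)))
  expect_lt(e_post, e_pre)
  expect_true(all(diff(sl$energy) <= 1e-12))

  for (i in 1:2) {
    # type 1 endpoints never move
    expect_equal(sl$configs[[i]]$landmarks[configs[[i]]$fixed, ],
                 configs[[i]]$landmarks[configs[[i]]$fixed, ])
    # every slid landmark still lies on its specimen's original polyline
    for (cn in CANALS) {
      rows <- which(configs[[i]]$curve_id == cn)
      pts <- sl$configs[[i]]$landmarks[rows, ]
      proj <- canalmorph:::project_onto_polyline(pts,
                configs[[i]]$curves[[cn]]$points)
      expect_lt(max(abs(pts - proj)), 1e-8)
    }
  }
})

test_that("configurations equal to the consensus are a fixed point of sliding", {
  cfg <- labyrinth_config(base_labyrinth_template(), "a")
  cfg2 <- cfg
  cfg2$specimen_id <- "b"
  sl <- slide_semilandmarks(list(cfg, cfg2), max_iter = 5L)
  expect_equal(sl$configs[[1L]]$landmarks, cfg$landmarks, tolerance = 1e-8)
  expect_equal(sl$configs[[2L]]$landmarks, cfg$landmarks, tolerance = 1e-8)
})

test_that("re-sliding a converged sample changes energy below tolerance", {
  tt <- simulate_tree(8L, seed = 21L)
  sim <- simulate_shapes(simulation_spec(n_taxa = 8L, seed = 22L,
                                         landmark_noise_sd = 0.02),
                         tt$tree)
  sl1 <- suppressWarnings(slide_semilandmarks(sim$configs, max_iter = 25L,
                                              tol = 1e-7))
  sl2 <- suppressWarnings(slide_semilandmarks(sl1$configs, max_iter = 25L,
                                              tol = 1e-7))
  e1 <- utils::tail(sl1$energy, 1L)
  e2 <- utils::tail(sl2$energy, 1L)
  # the energy reference (the consensus) is itself re-estimated, so
  # idempotence holds to the plateau level, not machine precision
  expect_lt(abs(e1 - e2) / e1, 1e-2)
  expect_true(sl1$converged)
})
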