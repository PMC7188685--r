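# shared fixtures, all built in code

# random proper rotation matrix
random_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3L, 3L)))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# a small asymmetric (chiral) labyrinth-like configuration built from the
# template plus a deterministic skew so it has no mirror symmetry
chiral_config <- function(id = "chiral") {
  tpl <- base_labyrinth_template()
  cfg <- labyrinth_config(tpl, id)
  skew <- matrix(c(1, 0.2, 0, 0, 1, 0.35, 0.1, 0, 1), 3L, 3L)
  cfg$landmarks <- cfg$landmarks %*% skew
  cfg$curves <- lapply(cfg$curves, function(cv) {
    cv$points <- cv$points %*% skew
    cv
  })
  cfg
}

# 4-tip balanced time tree: ((A:1,B:1):1,(C:1,D:1):1);  root age 2
balanced4_tree <- function() {
  ph <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  time_tree(ph, root_age = 2)
}

# star tree with n tips, branch length len
star_tree <- function(n, len = 1, labels = paste0("t", seq_len(n))) {
  ph <- ape::read.tree(text = paste0("(", paste0(labels, ":", len,
                                                 collapse = ","), ");"))
  time_tree(ph, root_age = len)
}

# simulate tip data under Brownian motion on a tree (independent of the
# package's own simulator): chol of the BM covariance times iid normals
rbm_tips <- function(tree, d, rate = 1) {
  C <- bm_covariance(tree)
  L <- chol(C)
  Y <- sqrt(rate) * t(L) %*% matrix(stats::rnorm(nrow(C) * d), nrow(C))
  rownames(Y) <- colnames(C)
  Y
}

# write a small synthetic input bundle for the pipeline; returns the paths
write_pipeline_bundle <- function(dir, n_taxa = 14L, seed = 4L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim_tree <- simulate_tree(n_taxa, seed = seed)
  spec <- simulation_spec(n_taxa = n_taxa,
                          groups = c(aerial = 0.25, aquatic = 0.3,
                                     arboreal = 0, fossorial = 0,
                                     terrestrial = 0.45),
                          ecology_effect_size = 0.25, seed = seed + 1L)
  shapes <- simulate_shapes(spec, sim_tree$tree)
  # hold one specimen out as the fossil of unknown ecology
  meta <- data.frame(specimen_id = names(shapes$configs),
                     taxon = names(shapes$configs),
                     side = "left",
                     ecology = as.character(shapes$labels),
                     group_role = "training")
  meta$group_role[1L] <- "projection"
  meta$ecology[1L] <- ""
  paths <- list(
    curves = file.path(dir, "landmarks.csv"),
    meta = file.path(dir, "specimens.csv"),
    tree = file.path(dir, "topology.nwk"),
    occ = file.path(dir, "occurrences.csv"),
    hearing = file.path(dir, "hearing.csv"))
  write_landmarks(shapes$configs, paths$curves)
  utils::write.csv(meta, paths$meta, row.names = FALSE)
  write_newick(sim_tree$tree$phylo, paths$tree)
  utils::write.csv(sim_tree$occurrences, paths$occ, row.names = FALSE)
  utils::write.csv(simulate_hearing_table(25, seed = seed + 2L),
                   paths$hearing, row.names = FALSE)
  paths
}
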