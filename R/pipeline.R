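#' Run the full labyrinth inference pipeline
#'
#' Executes every stage on files on disk: read landmarks and metadata,
#' slide semilandmarks, generalized Procrustes alignment, tangent-space
#' PCA, occurrence-based tree time-calibration (consensus of calibrated
#' trees), multivariate phylogenetic signal on centroid size and shape,
#' permutation ANCOVA and PGLS of shape on ecology and size, CVA on the
#' retained PCs with projection, typicality and likelihood assignment of
#' the projection (fossil) specimens, and the hearing regression. All
#' stochastic stages are seeded from `config$random_seed`; re-running
#' with the same inputs and seed reproduces every output byte-for-byte.
#'
#' @param config a `run_config`.
#' @param curve_file curve-csv landmark file.
#' @param specimen_file specimen metadata CSV.
#' @param newick_file rooted topology (Newick), tips = taxa.
#' @param occurrence_file occurrence CSV.
#' @param hearing_file hearing reference CSV.
#' @param out_dir output directory (created if absent).
#' @param pars_inferior,basicranium optional measurements (mm) of the
#'   focal fossil, used for the hearing prediction.
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, curve_file, specimen_file, newick_file,
                         occurrence_file, hearing_file, out_dir,
                         pars_inferior = NULL, basicranium = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seed <- config$random_seed

  configs <- stage("read", read_landmarks(curve_file, "curve-csv"))
  meta <- stage("read", read_specimen_table(specimen_file))
  miss <- setdiff(meta$specimen_id, names(configs))
  if (length(miss))
    stop("pipeline stage 'read' failed: specimens in metadata without ",
         "landmarks: ", paste(miss, collapse = ", "))
  configs <- configs[meta$specimen_id]
  for (i in seq_along(configs)) {
    configs[[i]]$taxon <- meta$taxon[i]
    configs[[i]]$ecology <- meta$ecology[i]
    if (meta$side[i] == "right")
      configs[[i]] <- mirror_configuration(configs[[i]])
  }

  slid <- stage("slide", slide_semilandmarks(configs))
  aligned <- stage("gpa", gpa(slid$configs))
  space <- stage("pca", pca_shapes(aligned))
  csize <- aligned$centroid_sizes

  topology <- stage("timecal", read_newick(newick_file))
  occ <- stage("timecal", read_occurrences(occurrence_file))
  rates <- stage("timecal", estimate_rates(
    occ$first_appearance - occ$last_appearance))
  trees <- stage("timecal", time_calibrate(
    topology, occ, rates, n_trees = config$n_calibrated_trees,
    seed = seed + 1L))
  cons <- stage("timecal", consensus_tree(trees))

  # one specimen per tip for the phylogenetic analyses
  tip_rows <- match(cons$phylo$tip.label, meta$taxon)
  if (anyNA(tip_rows))
    stop("pipeline stage 'timecal' failed: tree tips without specimens: ",
         paste(cons$phylo$tip.label[is.na(tip_rows)], collapse = ", "))
  tip_ids <- meta$specimen_id[tip_rows]
  shape_mat <- do.call(rbind, lapply(aligned$coordinates, flatten_config))
  rownames(shape_mat) <- aligned$ids
  tip_shape <- shape_mat[tip_ids, , drop = FALSE]
  rownames(tip_shape) <- cons$phylo$tip.label
  tip_size <- matrix(csize[tip_ids], ncol = 1L,
                     dimnames = list(cons$phylo$tip.label, "csize"))

  sig_size <- stage("physignal", blomberg_k_mult(
    tip_size, cons, n_perm = config$n_perm_signal, seed = seed + 2L))
  sig_shape <- stage("physignal", blomberg_k_mult(
    tip_shape, cons, n_perm = config$n_perm_signal, seed = seed + 3L))

  train <- meta$group_role == "training"
  anova_tab <- stage("anova", procrustes_ancova(
    shape_mat[meta$specimen_id[train], , drop = FALSE],
    meta$ecology[train], csize[meta$specimen_id[train]],
    n_perm = config$n_perm_anova, seed = seed + 4L,
    alpha = config$alpha, n_tests = 3L))
  # PGLS on the labelled tips only (unknown-ecology fossils pruned)
  tip_train <- !is.na(meta$ecology[tip_rows])
  pgls_tab <- if (sum(tip_train) >= 8L) {
    cons_tr <- prune_time_tree(cons, cons$phylo$tip.label[tip_train])
    stage("pgls", procrustes_pgls(
      tip_shape[tip_train, , drop = FALSE], meta$ecology[tip_rows][tip_train],
      drop(tip_size)[tip_train], cons_tr,
      n_perm = config$n_perm_anova, seed = seed + 4L,
      alpha = config$alpha, n_tests = 3L))
  } else NULL

  # classifier on retained PCs; fossils (projection role) held out
  k95 <- min_pcs_for_variance(space, config$variance_threshold)
  flt <- stage("cva", filter_singleton_groups(
    ifelse(train, meta$ecology, NA_character_)))
  use <- flt$keep & train
  n_train <- sum(use)
  g <- length(unique(meta$ecology[use]))
  k <- max(1L, min(k95, n_train - g - 1L))
  scores_k <- space$scores[meta$specimen_id, seq_len(k), drop = FALSE]
  model <- stage("cva", fit_cva(scores_k[use, , drop = FALSE],
                                meta$ecology[use]))
  proj_ids <- meta$specimen_id[meta$group_role == "projection"]
  m_comp <- max(1L, length(proj_ids) * length(model$groups))
  alpha_c <- bonferroni_alpha(config$alpha, m_comp)
  class_report <- lapply(seq_along(proj_ids), function(i) {
    tr <- stage("classify", typicality(
      model, scores_k[proj_ids[i], ], n_perm = config$n_perm_typicality,
      seed = seed + 10L + i, alpha_corrected = alpha_c))
    c(list(specimen_id = proj_ids[i],
           canonical = as.list(project_cva(model, scores_k[proj_ids[i], ]))),
      unclass(tr))
  })
  acc_resub <- stage("classify", classification_accuracy(
    scores_k[use, , drop = FALSE], meta$ecology[use], "resubstitution"))

  hear <- stage("hearing", read_hearing_table(hearing_file))
  hm_freq <- stage("hearing", fit_hearing_model(
    hear$x, hear$best_freq, "mean_best_frequency"))
  hm_range <- stage("hearing", fit_hearing_model(
    hear$x, hear$best_range, "best_range"))
  hearing_pred <- NULL
  if (!is.null(pars_inferior) && !is.null(basicranium)) {
    xq <- scale_and_transform(pars_inferior, basicranium)
    hearing_pred <- summarize_hearing(predict(hm_freq, xq),
                                      predict(hm_range, xq))
    hearing_pred <- c(list(x = xq), unclass(hearing_pred))
  }

  # ---- outputs -------------------------------------------------------
  num <- function(x) format(x, digits = 17, trim = TRUE)
  ali_df <- do.call(rbind, lapply(seq_along(aligned$coordinates), function(i)
    data.frame(specimen_id = aligned$ids[i],
               landmark = seq_len(aligned$k),
               x = num(aligned$coordinates[[i]][, 1L]),
               y = num(aligned$coordinates[[i]][, 2L]),
               z = num(aligned$coordinates[[i]][, 3L]))))
  utils::write.csv(ali_df, file.path(out_dir, "aligned_coordinates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(specimen_id = rownames(space$scores),
                              apply(space$scores, 2L, num)),
                   file.path(out_dir, "pc_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(axis = seq_along(space$eigenvalues),
                              eigenvalue = num(space$eigenvalues),
                              variance_fraction = num(space$variance_fractions)),
                   file.path(out_dir, "pc_eigenvalues.csv"),
                   row.names = FALSE, quote = FALSE)
  write_newick(cons, file.path(out_dir, "consensus_tree.nwk"))
  stat_tab <- function(at) cbind(term = rownames(at$table), at$table)
  utils::write.csv(stat_tab(anova_tab), file.path(out_dir, "ancova.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(pgls_tab))
    utils::write.csv(stat_tab(pgls_tab), file.path(out_dir, "pgls.csv"),
                     row.names = FALSE, quote = FALSE)
  report <- list(
    seed = seed,
    rates = unclass(rates),
    phylo_signal = list(centroid_size = unclass(sig_size),
                        shape = unclass(sig_shape)),
    retained_pcs = k,
    dropped_specimens = meta$specimen_id[train][flt$dropped],
    classification = class_report,
    classification_accuracy_resubstitution = acc_resub,
    alpha_corrected = alpha_c,
    hearing_models = list(mean_best_frequency = unclass(hm_freq),
                          best_range = unclass(hm_range)),
    hearing_prediction = hearing_pred)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(aligned = aligned, space = space, consensus = cons,
                 rates = rates, signal_size = sig_size,
                 signal_shape = sig_shape, ancova = anova_tab,
                 pgls = pgls_tab, cva = model, report = report))
}
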