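#!/usr/bin/env Rscript
# Stage 5: ecological classification of the fossil.
#
# CVA on the PCs carrying 95% of shape variation (training taxa only,
# singleton groups dropped), projection of the unknown-ecology fossil,
# Mahalanobis typicality probabilities with 10 000 resampling draws at
# the Bonferroni-corrected alpha, 95% confidence ellipses, and the CVA's
# classification accuracy.

suppressPackageStartupMessages(library(canalmorph))
library(jsonlite)
seed <- 20L

meta <- read_specimen_table("results/input/specimens.csv")
scores <- as.matrix(read.csv("results/pc_scores.csv", row.names = 1L))
eig <- read.csv("results/pc_eigenvalues.csv")
k95 <- min_pcs_for_variance(eig$variance_fraction, 0.95)

train_ids <- meta$specimen_id[meta$group_role == "training"]
eco <- setNames(meta$ecology, meta$specimen_id)
flt <- filter_singleton_groups(eco[train_ids])
if (length(flt$dropped))
  cat("dropped before CVA:", paste(flt$reason, collapse = "; "), "\n")
train_ids <- train_ids[flt$keep]
g <- length(unique(eco[train_ids]))
k <- max(1L, min(k95, length(train_ids) - g - 1L))
cat(sprintf("CVA on the first %d PC scores (95%% rule gave %d), %d groups\n",
            k, k95, g))

model <- fit_cva(scores[train_ids, seq_len(k), drop = FALSE], eco[train_ids])
acc_res <- classification_accuracy(scores[train_ids, seq_len(k)],
                                   eco[train_ids], "resubstitution")
acc_loo <- classification_accuracy(scores[train_ids, seq_len(k)],
                                   eco[train_ids], "loo")
cat(sprintf("classification accuracy: %.1f%% resubstitution, %.1f%% leave-one-out\n",
            100 * acc_res, 100 * acc_loo))

proj_ids <- meta$specimen_id[meta$group_role == "projection"]
alpha_c <- bonferroni_alpha(0.05, length(proj_ids) * length(model$groups))
cat(sprintf("Bonferroni-corrected alpha: %.4g\n", alpha_c))

report <- lapply(seq_along(proj_ids), function(i) {
  id <- proj_ids[i]
  tr <- typicality(model, scores[id, seq_len(k)], n_perm = 10000L,
                   seed = seed + 10L + i, alpha_corrected = alpha_c)
  cat(sprintf("\n%s: assigned to '%s' (likelihood %.3f)\n", id,
              tr$assigned_group, max(tr$likelihood)))
  print(tr)
  c(list(specimen_id = id), unclass(tr))
})

ellipses <- do.call(rbind, lapply(model$groups, function(gr) {
  e <- confidence_ellipse(model, gr, level = 0.95)
  data.frame(group = gr, cv1 = e$center[1L], cv2 = e$center[2L],
             semi_major = e$semi_axes[1L], semi_minor = e$semi_axes[2L],
             angle_deg = atan2(e$orientation[2L, 1L],
                               e$orientation[1L, 1L]) * 180 / pi)
}))
write.csv(ellipses, "results/cva_ellipses.csv", row.names = FALSE)
write_json(list(retained_pcs = k, alpha_corrected = alpha_c,
                accuracy_resubstitution = acc_res,
                accuracy_leave_one_out = acc_loo,
                fossils = report),
           "results/classification.json", auto_unbox = TRUE, digits = NA,
           pretty = TRUE)
cat("\nwrote cva_ellipses.csv, classification.json\n")
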