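#!/usr/bin/env Rscript
# Stage 2: semilandmark sliding, Procrustes alignment, tangent-space PCA.
#
# Interior canal landmarks slide along their centerlines to minimize
# thin-plate-spline bending energy against the sample consensus; the
# sample is then aligned by generalized Procrustes analysis and projected
# into tangent space for PCA.

suppressPackageStartupMessages(library(canalmorph))
input <- "results/input"
dir.create("results", showWarnings = FALSE)

configs <- read_landmarks(file.path(input, "landmarks.csv"))
meta <- read_specimen_table(file.path(input, "specimens.csv"))
configs <- configs[meta$specimen_id]

slid <- suppressWarnings(slide_semilandmarks(configs, max_iter = 15L))
cat(sprintf("sliding: %d iterations, bending energy %.4f -> %.4f%s\n",
            slid$iterations, slid$energy[1L], tail(slid$energy, 1L),
            if (slid$converged) " (converged)" else ""))

aligned <- gpa(slid$configs)
space <- pca_shapes(aligned)

k95 <- min_pcs_for_variance(space, 0.95)
cat(sprintf("PCA: %d axes; PC1-3 carry %.2f%%, %.2f%%, %.2f%% of variance\n",
            ncol(space$scores), 100 * space$variance_fractions[1L],
            100 * space$variance_fractions[2L],
            100 * space$variance_fractions[3L]))
cat(sprintf("%d PCs describe 95%% of the total variation\n", k95))

# aligned coordinates, scores, eigenvalues, centroid sizes
ali <- do.call(rbind, lapply(seq_along(aligned$coordinates), function(i)
  data.frame(specimen_id = aligned$ids[i], landmark = seq_len(aligned$k),
             aligned$coordinates[[i]])))
names(ali)[3:5] <- c("x", "y", "z")
write.csv(ali, "results/aligned_landmarks.csv", row.names = FALSE)
write.csv(data.frame(specimen_id = rownames(space$scores), space$scores),
          "results/pc_scores.csv", row.names = FALSE)
write.csv(data.frame(axis = seq_along(space$eigenvalues),
                     eigenvalue = space$eigenvalues,
                     variance_fraction = space$variance_fractions),
          "results/pc_eigenvalues.csv", row.names = FALSE)
write.csv(data.frame(specimen_id = names(aligned$centroid_sizes),
                     centroid_size = aligned$centroid_sizes),
          "results/centroid_sizes.csv", row.names = FALSE)
cat("wrote aligned_landmarks, pc_scores, pc_eigenvalues, centroid_sizes\n")
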