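#!/usr/bin/env Rscript
# Stage 4: does canal shape track ecology once size and phylogeny are
# accounted for? Permutation ANCOVA (lineages treated as independent) and
# PGLS (Brownian-motion covariance from the consensus tree), both with
# residual randomization, 1000 permutations, and a Bonferroni-corrected
# alpha for the three model terms.

suppressPackageStartupMessages(library(canalmorph))
seed <- 20L
input <- "results/input"

meta <- read_specimen_table(file.path(input, "specimens.csv"))
ali <- read.csv("results/aligned_landmarks.csv")
ids <- unique(ali$specimen_id)
shape <- t(vapply(ids, function(id) {
  m <- as.matrix(ali[ali$specimen_id == id, c("x", "y", "z")])
  as.vector(t(m))
}, numeric(180L)))
rownames(shape) <- ids
cs <- read.csv("results/centroid_sizes.csv")
csize <- setNames(cs$centroid_size, cs$specimen_id)

train <- meta$specimen_id[meta$group_role == "training"]
eco <- setNames(meta$ecology, meta$specimen_id)[train]
flt <- filter_singleton_groups(eco)
train <- train[flt$keep]
if (length(flt$dropped))
  cat("dropped before modelling:", paste(flt$reason, collapse = "; "), "\n")

anova_tab <- procrustes_ancova(shape[train, ], eco[train], csize[train],
                               n_perm = 1000L, seed = seed + 6L,
                               n_tests = 3L)
cat("\nProcrustes ANCOVA:\n"); print(anova_tab)

# PGLS on the training tips, pruned to the labelled taxa
cons_full <- read_newick("results/consensus_tree.nwk")
occ <- read_occurrences(file.path(input, "occurrences.csv"))
d1 <- ape::node.depth.edgelength(cons_full)[1L]
root_age <- d1 + occ$last_appearance[match(cons_full$tip.label[1L], occ$taxon)]
cons <- prune_time_tree(time_tree(cons_full, root_age), train)
pgls_tab <- procrustes_pgls(shape[train, ], eco[train], csize[train], cons,
                            n_perm = 1000L, seed = seed + 6L, n_tests = 3L)
cat("\nProcrustes PGLS:\n"); print(pgls_tab)

save_tab <- function(at, f)
  write.csv(cbind(term = rownames(at$table), at$table), f, row.names = FALSE)
save_tab(anova_tab, "results/ancova.csv")
save_tab(pgls_tab, "results/pgls.csv")
cat("wrote ancova.csv, pgls.csv\n")
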