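#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates the study conditions end to end: 61 labyrinths (60 landmarks
# each) on a birth-death time tree with fossil and extant tips, shape
# variation from Brownian motion along the tree plus additive ecology
# effects across five classes, a fossil occurrence table, and a
# Walsh-style extant hearing reference table. One specimen is declared a
# fossil of unknown ecology (the projection target). All files land in
# results/input/.

suppressPackageStartupMessages(library(canalmorph))
seed <- 20L
out <- "results/input"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim_tree <- simulate_tree(61L, seed = seed)
spec <- simulation_spec(n_taxa = 61L, seed = seed + 1L)
shapes <- simulate_shapes(spec, sim_tree$tree)

meta <- data.frame(specimen_id = names(shapes$configs),
                   taxon = names(shapes$configs),
                   side = "left",
                   ecology = as.character(shapes$labels),
                   group_role = "training")
# the oldest fossil tip plays the role of the unknown-ecology fossil
fossil <- names(which.max(sim_tree$tree$tip_ages))
meta$group_role[meta$specimen_id == fossil] <- "projection"
meta$ecology[meta$specimen_id == fossil] <- ""

write_landmarks(shapes$configs, file.path(out, "landmarks.csv"))
write.csv(meta, file.path(out, "specimens.csv"), row.names = FALSE)
write_newick(sim_tree$tree$phylo, file.path(out, "topology.nwk"))
write.csv(sim_tree$occurrences, file.path(out, "occurrences.csv"),
          row.names = FALSE)
write.csv(simulate_hearing_table(30L, seed = seed + 2L),
          file.path(out, "hearing.csv"), row.names = FALSE)

cat(sprintf("wrote synthetic bundle to %s\n", out))
cat(sprintf("  %d specimens (%d fossil tips, %d extant)\n",
            length(shapes$configs), sum(sim_tree$tree$tip_ages > 0),
            sum(sim_tree$tree$tip_ages == 0)))
cat(sprintf("  projection specimen: %s (%.1f Ma)\n", fossil,
            sim_tree$tree$tip_ages[fossil]))
print(table(shapes$labels))
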