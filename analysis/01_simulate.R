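#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study region.
#
# Produces everything the real study would read from floras, range atlases
# and remote sensing: spatially autocorrelated climate surfaces on a 50-km
# grid, a species pool whose AET niche optima covary with leaf size,
# Bernoulli-sampled presence/absence ranges, and a dated birth-death
# phylogeny over the species pool. All outputs are plain text under
# results/.

suppressMessages(library(leafprod))

dir.create("results", showWarnings = FALSE)
seed <- 2020L
scenario <- leaf_scenario(nx = 25, ny = 25, n_species = 300, seed = seed)

climate <- make_climate_fields(scenario, seed)
pool <- make_species_pool(scenario, seed + 1L)
presence <- make_ranges(pool, climate, scenario, seed + 2L)
phylo <- make_phylogeny(scenario, seed + 3L)
phylo$tree$tip.label <- pool$traits$species

# occurrences as one record per occupied (species, cell centre)
occ <- which(presence, arr.ind = TRUE)
occurrences <- data.frame(
  species = colnames(presence)[occ[, 2]],
  x = climate$x[occ[, 1]], y = climate$y[occ[, 1]])

write.csv(climate, "results/cells_climate.csv", row.names = FALSE)
write.csv(pool$traits, "results/species_traits.csv", row.names = FALSE)
write.csv(pool$niche, "results/species_niche.csv", row.names = FALSE)
write.csv(occurrences, "results/occurrences.csv", row.names = FALSE)
ape::write.tree(phylo$tree, "results/phylogeny.nwk")

cat(sprintf("simulated %d cells, %d species, %d occurrence records\n",
            nrow(climate), nrow(pool$traits), nrow(occurrences)))
cat(sprintf("AET range %.0f-%.0f mm; species median leaf length %.1f-%.1f cm\n",
            min(climate$AET), max(climate$AET),
            min(pool$niche$length_med), max(pool$niche$length_med)))
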