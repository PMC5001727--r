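#!/usr/bin/env Rscript
# Stage 1: build the synthetic study worlds used by the downstream drivers.
#
# Three worlds are generated and written under results/data/:
#   main/   16-leaf coarse ontology, 200 genes with a spread of tree-signal
#           scales (half null), 2 donors x 3 samples per region
#   ages/   the same ontology, four age groups whose tree-signal multiplier
#           follows an hourglass (high embryo, dip at birth, rise, late dip)
#   pairs/  300 genes including 100 anti-correlated gene pairs (target
#           increment correlation -0.6)

suppressPackageStartupMessages(library(brotree))
seed <- 20160826L
root <- "results/data"
dir.create(root, recursive = TRUE, showWarnings = FALSE)

ont <- simulate_ontology(depth = 1, branching = 16)
write_ontology(ont, file.path(root, "ontology.tsv"))

## main world: graded signal, half exact nulls
sigma_tree <- c(seq(0.25, 2.5, length.out = 100), rep(0, 100))
spec <- synthetic_spec(n_genes = 200, n_donors = 2,
                       samples_per_region_per_donor = 3,
                       sigma_tree = sigma_tree, sigma_noise = 1,
                       sigma_donor = 0.5, seed = seed)
sim <- simulate_expression(spec, ont)
dir.create(file.path(root, "main"), showWarnings = FALSE)
write_expression(sim$dataset, file.path(root, "main", "matrix.tsv"),
                 file.path(root, "main", "metadata.tsv"))
write.table(data.frame(gene_id = names(sim$truth$sigma_tree),
                       sigma_tree = unname(sim$truth$sigma_tree)),
            file.path(root, "main", "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("main: %d genes x %d samples (%d regions, %d donors)\n",
            n_genes(sim$dataset), n_samples(sim$dataset),
            length(unique(sim$dataset$samples$region_id)),
            length(unique(sim$dataset$samples$donor_id))))

## age series: hourglass multipliers on the tree signal
mult <- c(embryo = 1.8, birth = 0.5, adult = 1.2, late = 0.8)
spec_age <- synthetic_spec(n_genes = 100, n_donors = 2,
                           samples_per_region_per_donor = 3,
                           sigma_tree = 1, sigma_noise = 1,
                           sigma_donor = 0.5, age_profile = mult,
                           seed = seed + 1L)
series <- simulate_age_series(spec_age, ont)
dir.create(file.path(root, "ages"), showWarnings = FALSE)
for (g in names(series)) {
  write_expression(series[[g]]$dataset,
                   file.path(root, "ages", paste0(g, "_matrix.tsv")),
                   file.path(root, "ages", paste0(g, "_metadata.tsv")))
}
cat("ages:", length(series), "groups with multipliers",
    paste(sprintf("%s=%.1f", names(mult), mult), collapse = ", "), "\n")

## paired world: 100 anti-correlated pairs among 300 genes
pair_spec <- data.frame(gene_a = sprintf("G%04d", 1:100),
                        gene_b = sprintf("G%04d", 101:200), rho = -0.6)
spec_pairs <- synthetic_spec(n_genes = 300, n_donors = 4,
                             samples_per_region_per_donor = 2,
                             sigma_tree = 2, sigma_noise = 0.5,
                             sigma_donor = 0.5, pair_spec = pair_spec,
                             seed = seed + 2L)
simp <- simulate_pairs(spec_pairs, ont)
dir.create(file.path(root, "pairs"), showWarnings = FALSE)
write_expression(simp$dataset, file.path(root, "pairs", "matrix.tsv"),
                 file.path(root, "pairs", "metadata.tsv"))
write.table(data.frame(pair_spec[c("gene_a", "gene_b")],
                       source_label = "anticorr"),
            file.path(root, "pairs", "pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("pairs:", nrow(pair_spec), "anti-correlated pairs (target rho -0.6)\n")
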