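#!/usr/bin/env Rscript
# Stage 5: spatial correlations of gene pairs.
#
# Anti-correlated pairs (generated with increment correlation -0.6) are
# compared against a random-pair baseline, the pair-level BRO association
# is measured, and developmental trends of pair correlations are fitted
# across the simulated age groups.

suppressPackageStartupMessages(library(brotree))
seed <- 20160826L
ont <- parse_ontology("results/data/ontology.tsv")
ds <- load_expression("results/data/pairs/matrix.tsv",
                      "results/data/pairs/metadata.tsv", ont)
pairs <- read.delim("results/data/pairs/pairs.tsv")

psd <- pair_set_distribution(ds, pairs, n_random_baseline = 100,
                             seed = seed)
write.table(psd$records, "results/pair_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(psd$tests, "results/pair_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("anti-correlated set: median signed log10 p = %.2f vs baseline %.2f (one-tailed rank-sum p = %.2g)\n",
            psd$tests$median_signed_logp,
            psd$tests$baseline_median_signed_logp, psd$tests$wilcoxon_p))

## pair-level BRO association (pair score = min of the two genes' scores)
bro <- bro_score_all(ds, ont)
rec <- psd$records[psd$records$source_label == "anticorr", ]
gene_sd <- apply(ds$values, 1, sd)
bv <- bro_vs_pairs(rec, bro, gene_sd = gene_sd)
write.table(bv, "results/bro_vs_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("pairs with higher BRO are more strongly anti-correlated: Spearman = %.2f\n",
            bv$rho[bv$measure == "signed_logp_vs_pair_bro"]))
cat(sprintf("control against spatial variability (per-gene SD): Spearman = %.2f\n",
            bv$rho[bv$measure == "signed_logp_vs_pair_sd"]))

## developmental trends across the age-series world
groups <- c("embryo", "birth", "adult", "late")
series <- lapply(groups, function(g)
  load_expression(sprintf("results/data/ages/%s_matrix.tsv", g),
                  sprintf("results/data/ages/%s_metadata.tsv", g), ont))
names(series) <- groups
age_pairs <- data.frame(gene_a = sprintf("G%04d", 1:20),
                        gene_b = sprintf("G%04d", 21:40))
pt <- pair_trends(series, age_pairs, ages = c(-0.5, 0, 20, 60))
write.table(pt, "results/pair_trends.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d/%d pairs show an FDR-significant linear trend in spatial correlation\n",
            sum(pt$significant), nrow(pt)))
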