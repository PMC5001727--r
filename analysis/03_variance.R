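#!/usr/bin/env Rscript
# Stage 3: companion variance analyses on the main world -- per-gene ANOVA
# across regions, PCA of samples, region/donor explained-variance
# partitioning, and hierarchical clustering of region profiles.

suppressPackageStartupMessages(library(brotree))
ont <- parse_ontology("results/data/ontology.tsv")
ds <- load_expression("results/data/main/matrix.tsv",
                      "results/data/main/metadata.tsv", ont)

av <- anova_by_region(ds)
write.table(av, "results/anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("ANOVA: %.0f%% of genes differentially expressed across regions (q < 0.01)\n",
            100 * mean(av$significant)))

bro <- read.delim("results/bro_scores.tsv")
both <- merge(av, bro, by = "gene_id")
cat(sprintf("ANOVA-significant and BRO-significant overlap: %.0f%% of genes\n",
            100 * mean(both$significant & both$significant_fdr)))

pc <- pca_samples(ds, k = 4)
coords <- data.frame(sample_id = rownames(pc$coords), pc$coords,
                     region_id = ds$samples$region_id,
                     donor_id = ds$samples$donor_id, check.names = FALSE)
write.table(coords, "results/pca_coords.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PCA: first two components explain %.0f%% of sample variance\n",
            100 * sum(pc$explained[1:2])))

ev <- explained_variance(ds)
write.table(ev, "results/explained_variance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("explained variance (median): region %.2f, donor %.2f, joint %.2f\n",
            median(ev$r2_region), median(ev$r2_donor), median(ev$r2_joint)))
cat(sprintf("region vs donor R2 are anti-correlated: Spearman = %.2f\n",
            cor(ev$r2_region, ev$r2_donor, method = "spearman")))

cl <- cluster_regions(ds)
writeLines(cl$newick, "results/region_dendrogram.nwk")
cat("wrote region dendrogram (Newick);",
    nrow(cl$merges), "agglomeration steps\n")
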