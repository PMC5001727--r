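#!/usr/bin/env Rscript
# Stage 4: gene-set comparisons of BRO scores.
#
# In the synthetic world the "marker-like" set is the top tercile of
# generating signal scales (the analogue of cell-type markers, which in
# real data score far above the average gene), and the "weak" set is drawn
# from the null genes (the analogue of gene families with little regional
# patterning). Also: marker-based explained variance of individual genes,
# and a combined two-replicate ranking.

suppressPackageStartupMessages(library(brotree))
seed <- 20160826L
ont <- parse_ontology("results/data/ontology.tsv")
ds <- load_expression("results/data/main/matrix.tsv",
                      "results/data/main/metadata.tsv", ont)
truth <- read.delim("results/data/main/truth.tsv")
bro <- read.delim("results/bro_scores.tsv")

ord <- truth$gene_id[order(-truth$sigma_tree)]
sets <- list(strong_signal = ord[1:50], weak_signal = rev(ord)[1:50])
cmp <- compare_gene_sets(bro, sets, background = "all_genes", tail = "one")
write.table(cmp, "results/set_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (i in seq_len(nrow(cmp))) {
  cat(sprintf("%s: median %.3f vs background %.3f, one-tailed Wilcoxon p = %.2g; %.0f%% set genes significant\n",
              cmp$set_name[i], cmp$median_in_set[i],
              cmp$median_background[i], cmp$wilcoxon_p[i],
              100 * cmp$fraction_significant_in_set[i]))
}

## marker-based explained variance: strongest genes as the marker panel
markers <- ord[1:11]
targets <- c(ord[12:16], rev(ord)[1:5])
mev <- vapply(targets, function(g)
  marker_explained_variance(ds, g, setdiff(markers, g))$r2, numeric(1))
mev_tab <- data.frame(gene_id = targets, r2 = mev,
                      class = rep(c("signal", "null"), each = 5))
write.table(mev_tab, "results/marker_explained_variance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("marker panel explains median R2 = %.2f for signal genes, %.2f for null genes\n",
            median(mev[1:5]), median(mev[6:10])))

## combined score across two replicate datasets from the same truth
spec2 <- synthetic_spec(n_genes = 200, n_donors = 2,
                        samples_per_region_per_donor = 3,
                        sigma_tree = truth$sigma_tree, sigma_noise = 1,
                        sigma_donor = 0.5, seed = seed + 10L)
rep2 <- simulate_expression(spec2, ont)$dataset
bro2 <- bro_score_all(rep2, ont)
cs <- combined_score(bro, bro2)
write_ranked_list(cs, "results/ranked_genes.txt")
cat(sprintf("combined two-replicate ranking tracks the truth: Spearman = %.2f\n",
            cor(cs$combined,
                truth$sigma_tree[match(cs$gene_id, truth$gene_id)],
                method = "spearman")))
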