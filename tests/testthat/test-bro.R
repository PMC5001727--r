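test_that("pairwise_distances enumerates every unordered pair once", {
  w <- path_tree_world(5)
  dp <- pairwise_distances(w$ds, w$ont, "g1")
  expect_equal(dp$n_pairs, 10L)
  # path tree with expression = position: the two distances coincide
  expect_equal(dp$expr_d, dp$tree_d)

  two <- subset_samples(w$ds, regions = c("p1", "p2"), ont = w$ont,
                        subtree = FALSE)
  expect_equal(pairwise_distances(two, w$ont, "g1")$n_pairs, 1L)
  one <- subset_samples(w$ds, regions = "p1", ont = w$ont, subtree = FALSE)
  expect_error(pairwise_distances(one, w$ont, "g1"), ">= 2 samples")
})

test_that("bro_score hits the monotone extremes and handles zero variance", {
  w <- path_tree_world(6)
  dp <- pairwise_distances(w$ds, w$ont, "g1")
  expect_equal(bro_score(dp), 1)
  dp_neg <- dp
  dp_neg$expr_d <- max(dp$expr_d) - dp$expr_d  # anti-monotone transform
  expect_equal(bro_score(dp_neg), -1)
  dp_flat <- dp
  dp_flat$expr_d <- rep(1, dp$n_pairs)
  expect_true(is.na(bro_score(dp_flat)))
})

test_that("bro_score equals the brute-force rank oracle on tied toy pairs", {
  dp <- list(tree_d = c(0, 0, 2, 2, 4, 4), expr_d = c(1, 2, 2, 3, 3, 3),
             n_pairs = 6L)
  expect_equal(bro_score(dp), oracle_spearman(dp$expr_d, dp$tree_d),
               tolerance = 1e-12)
})

test_that("bro_score is invariant to affine expression maps and increasing
           tree-distance transforms", {
  # the statistic ranks |x_a - x_b|, so expression invariance holds for
  # affine increasing maps (nonlinear monotone maps reorder differences);
  # tree distance enters directly, so any increasing transform of it works
  ont <- simulate_ontology(2, 3)
  sp <- synthetic_spec(n_genes = 5, n_donors = 2,
                       samples_per_region_per_donor = 2, seed = 9)
  ds <- simulate_expression(sp, ont)$dataset
  base <- bro_score_all(ds, ont)$bro
  warp <- ds
  warp$values <- 2.5 * ds$values + 7
  expect_equal(bro_score_all(warp, ont)$bro, base, tolerance = 1e-12)
  dp <- pairwise_distances(ds, ont, "G0001")
  dp2 <- dp
  dp2$tree_d <- dp$tree_d^2 + 3 * dp$tree_d
  expect_equal(bro_score(dp2), bro_score(dp), tolerance = 1e-12)
})

test_that("bro_score_all is deterministic and order-equivariant", {
  ont <- simulate_ontology(1, 4)
  sp <- synthetic_spec(n_genes = 6, n_donors = 2,
                       samples_per_region_per_donor = 2, seed = 13)
  ds <- simulate_expression(sp, ont)$dataset
  tab <- bro_score_all(ds, ont)
  # duplicate gene rows give identical scores
  expect_equal(bro_score_all(ds, ont, c("G0001", "G0001"))$bro,
               rep(tab$bro[1], 2))
  # permuting the gene list permutes rows only
  rev_tab <- bro_score_all(ds, ont, rev(tab$gene_id))
  expect_equal(rev_tab$bro, rev(tab$bro))
})

test_that("triplet score is exact on monotone worlds and matches
           exhaustive enumeration on a 15-sample instance", {
  w <- path_tree_world(6)
  expect_equal(triplet_score(w$ds, w$ont, "g1", n_triplets = 2e4, seed = 1),
               1)
  # anti-monotone construction: samples at path positions 1, 2, 5 with
  # expression (0, 10, 1) reverse every tree-distance comparison
  # (checked by hand over all 6 ordered triplets)
  antiw <- path_tree_world(5)
  anti <- antiw$ds
  anti$samples <- anti$samples[c(1, 2, 5), ]
  anti$values <- anti$values[, c(1, 2, 5), drop = FALSE]
  anti$values[1, ] <- c(0, 10, 1)
  expect_equal(triplet_score(anti, antiw$ont, "g1", n_triplets = 2e4,
                             seed = 1), 0)

  ont <- simulate_ontology(2, 3)
  sp <- synthetic_spec(n_genes = 1, n_donors = 1,
                       samples_per_region_per_donor = 2, sigma_tree = 1.2,
                       regions = "all", seed = 5)
  ds <- simulate_expression(sp, ont)$dataset
  ds$values <- ds$values[, 1:15, drop = FALSE]
  ds$samples <- ds$samples[1:15, ]
  expect_equal(n_samples(ds), 15L)
  exact <- oracle_triplet_exhaustive(ds, ont, "G0001")
  sampled <- triplet_score(ds, ont, "G0001", n_triplets = 1e5, seed = 2)
  expect_lt(abs(sampled - exact), 0.02)
})

test_that("permutation p-values follow the add-one rule and rank logic", {
  ont <- simulate_ontology(1, 4)
  sp <- synthetic_spec(n_genes = 1, n_donors = 1,
                       samples_per_region_per_donor = 3, sigma_tree = 0,
                       sigma_donor = 0, seed = 4)
  ds <- simulate_expression(sp, ont)$dataset
  pn <- permutation_null(ds, ont, n_permutations = 1, seed = 8)
  expect_true(pn$result$p_empirical %in% c(1 / 2, 1))

  # a gene whose observed score sits below the null median has p > 0.5
  sp2 <- synthetic_spec(n_genes = 40, n_donors = 1,
                        samples_per_region_per_donor = 3, sigma_tree = 0,
                        sigma_donor = 0, seed = 14)
  ds2 <- simulate_expression(sp2, ont)$dataset
  pn2 <- permutation_null(ds2, ont, n_permutations = 25, seed = 15)
  med <- stats::median(pn2$null$scores)
  below <- pn2$result$bro < med
  expect_true(all(pn2$result$p_empirical[below] > 0.5))

  # per-gene mode produces one threshold per gene
  pn3 <- permutation_null(ds2, ont, genes = c("G0001", "G0002"),
                          n_permutations = 30, seed = 16, pooled = FALSE)
  expect_length(pn3$null$threshold_top1, 2L)
  expect_true(pn3$null$per_gene)

  # region-unit shuffle runs and returns calibrated-looking p-values
  pn4 <- permutation_null(ds2, ont, n_permutations = 20, seed = 17,
                          unit = "region")
  expect_true(all(pn4$result$p_empirical > 0 & pn4$result$p_empirical <= 1))
})

test_that("zero-variance genes are flagged and excluded from the null", {
  ont <- simulate_ontology(1, 4)
  sp <- synthetic_spec(n_genes = 3, n_donors = 1,
                       samples_per_region_per_donor = 2, seed = 19)
  ds <- simulate_expression(sp, ont)$dataset
  ds$values["G0002", ] <- 7  # constant gene
  pn <- permutation_null(ds, ont, n_permutations = 10, seed = 20)
  row <- pn$result[pn$result$gene_id == "G0002", ]
  expect_identical(row$status, "zero_variance")
  expect_true(is.na(row$bro) && is.na(row$p_empirical))
  expect_equal(length(pn$null$scores), 10 * 2)  # only the two live genes
})

test_that("combine_subjects modes agree on degenerate donor structures", {
  ont <- simulate_ontology(1, 6)
  sp <- synthetic_spec(n_genes = 10, n_donors = 1,
                       samples_per_region_per_donor = 3, sigma_tree = 1.5,
                       seed = 23)
  ds <- simulate_expression(sp, ont)$dataset
  pooled <- combine_subjects(ds, ont, mode = "pooled")
  per <- combine_subjects(ds, ont, mode = "per_subject_mean")
  expect_equal(per$bro, pooled$bro)  # single donor: identical

  # two donors with byte-identical data: mean equals either donor's score
  ds2 <- ds
  ds2$values <- cbind(ds$values, ds$values)
  colnames(ds2$values) <- paste0("s", seq_len(2 * n_samples(ds)))
  ds2$samples <- rbind(ds$samples, ds$samples)
  ds2$samples$sample_id <- colnames(ds2$values)
  ds2$samples$donor_id <- rep(c("D1", "D2"), each = n_samples(ds))
  per2 <- combine_subjects(ds2, ont, mode = "per_subject_mean")
  expect_equal(per2$bro, attr(per2, "per_donor")[, "D1"],
               ignore_attr = TRUE)
})

test_that("donor scores are mutually consistent under shared signal", {
  ont <- simulate_ontology(1, 8)
  sp <- synthetic_spec(n_genes = 40, n_donors = 4,
                       samples_per_region_per_donor = 3, sigma_tree = 2,
                       sigma_noise = 1, sigma_donor = 0.5, seed = 27)
  ds <- simulate_expression(sp, ont)$dataset
  per <- attr(combine_subjects(ds, ont, mode = "per_subject_mean"),
              "per_donor")
  cc <- stats::cor(per, method = "spearman")
  expect_gt(mean(cc[upper.tri(cc)]), 0.5)
})

test_that("bro_by_age_group intersects regions and tracks the trajectory", {
  ont <- simulate_ontology(1, 6)
  sp <- synthetic_spec(n_genes = 20, n_donors = 2,
                       samples_per_region_per_donor = 2, sigma_tree = 1,
                       age_profile = c(a = 1, b = 1), seed = 30)
  series <- lapply(simulate_age_series(sp, ont), `[[`, "dataset")
  # identical generative settings: single group reduces to bro_score_all
  bag1 <- bro_by_age_group(series[1], ont)
  expect_equal(bag1$per_gene[, 1],
               bro_score_all(series[[1]], ont)$bro, ignore_attr = TRUE)
  # identical datasets per group give a flat trajectory
  bag2 <- bro_by_age_group(list(x = series[[1]], y = series[[1]]), ont)
  expect_equal(bag2$trajectory$mean_bro[1], bag2$trajectory$mean_bro[2])
})
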