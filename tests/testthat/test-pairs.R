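test_that("spatial correlation hits the exact extremes and is symmetric", {
  ont <- toy_ontology()
  set.seed(91)
  x <- rnorm(12)
  vals <- rbind(g1 = x, g1copy = x, g1neg = max(x) + min(x) - x)
  colnames(vals) <- paste0("s", 1:12)
  ds <- toy_dataset(vals, regions = rep(c("L1", "L2"), 6),
                    donors = rep(c("d1", "d2"), each = 6), ont = ont)
  same <- spatial_correlation(ds, "g1", "g1copy")
  expect_equal(unname(same$per_subject_rho), c(1, 1))
  neg <- spatial_correlation(ds, "g1", "g1neg")
  expect_equal(neg$median_rho, -1)
  expect_lt(neg$signed_logp, 0)
  # symmetry
  ab <- spatial_correlation(ds, "g1", "g1neg")
  ba <- spatial_correlation(ds, "g1neg", "g1")
  expect_equal(ab$median_rho, ba$median_rho)
  expect_equal(ab$signed_logp, ba$signed_logp)
})

test_that("per-donor rho matches the brute-force rank oracle", {
  ont <- toy_ontology()
  vals <- rbind(g1 = c(3.1, 0.2, 5.5, 2.2, 4.4, 1.0),
                g2 = c(2.0, 1.1, 4.9, 5.0, 3.3, 0.4))
  colnames(vals) <- paste0("s", 1:6)
  ds <- toy_dataset(vals, regions = "L1", donors = "d1", ont = ont)
  r <- spatial_correlation(ds, "g1", "g2")
  expect_equal(unname(r$per_subject_rho["d1"]),
               oracle_spearman(vals["g1", ], vals["g2", ]),
               tolerance = 1e-12)
})

test_that("short or flat donors are omitted from pair records", {
  ont <- toy_ontology()
  vals <- rbind(g1 = c(1, 2, 3, 4, 5, 9, 9, 9, 9, 7),
                g2 = c(2, 1, 4, 3, 5, 1, 2, 3, 4, 5))
  colnames(vals) <- paste0("s", 1:10)
  ds <- toy_dataset(vals, regions = "L1",
                    donors = rep(c("d1", "d2"), each = 5), ont = ont)
  # d2 has zero variance in g1 within its last 4... make d2 flat in g1
  ds$values["g1", 6:10] <- 9
  r <- spatial_correlation(ds, "g1", "g2")
  expect_equal(r$n_donors, 1L)
  expect_true(is.na(r$per_subject_rho["d2"]))
})

test_that("baseline draws are seed-reproducible and exclude listed pairs", {
  genes <- sprintf("g%03d", 1:50)
  listed <- data.frame(gene_a = "g001", gene_b = "g002")
  b1 <- random_pair_baseline(genes, 200, seed = 5, exclude = listed)
  b2 <- random_pair_baseline(genes, 200, seed = 5, exclude = listed)
  expect_identical(b1, b2)
  expect_false(any(b1$gene_a == b1$gene_b))
  expect_false(any(b1$gene_a == "g001" & b1$gene_b == "g002"))
  expect_error(random_pair_baseline(genes, 0, seed = 1), ">= 1")
})

test_that("anti-correlated pair sets separate from the random baseline", {
  ont <- simulate_ontology(1, 16)
  ps <- data.frame(gene_a = sprintf("G%04d", 1:60),
                   gene_b = sprintf("G%04d", 61:120), rho = -0.6)
  sp <- synthetic_spec(n_genes = 200, n_donors = 3,
                       samples_per_region_per_donor = 2, sigma_tree = 2,
                       sigma_noise = 0.5, pair_spec = ps, seed = 95)
  ds <- simulate_pairs(sp, ont)$dataset
  pairs <- data.frame(ps[c("gene_a", "gene_b")], source_label = "anti")
  psd <- pair_set_distribution(ds, pairs, n_random_baseline = 60, seed = 96)
  expect_lt(psd$tests$wilcoxon_p, 0.01)
  expect_lt(psd$tests$median_signed_logp,
            psd$tests$baseline_median_signed_logp)
})

test_that("trend_fit matches the closed-form F oracle and its edge cases", {
  # 4-point hand-computable instance
  ages <- c(1, 2, 3, 4)
  rho <- c(0.10, 0.30, 0.20, 0.60)
  tf <- trend_fit(rho, ages)
  fit1 <- stats::lm(rho ~ ages)
  rss1 <- sum(stats::resid(fit1)^2)
  rss0 <- sum((rho - mean(rho))^2)
  f_oracle <- (rss0 - rss1) / (rss1 / 2)
  expect_equal(tf$f_stat, f_oracle, tolerance = 1e-10)
  expect_equal(tf$slope, unname(stats::coef(fit1)[2]), tolerance = 1e-10)
  expect_equal(tf$p, stats::pf(f_oracle, 1, 2, lower.tail = FALSE),
               tolerance = 1e-10)

  # perfectly linear series: slope exact, p ~ 0
  lin <- trend_fit(0.05 * (1:5) - 0.1, 1:5)
  expect_equal(lin$slope, 0.05, tolerance = 1e-10)
  expect_lt(lin$p, 1e-6)

  # constant series: F = 0, p = 1
  flat <- trend_fit(rep(0.2, 5), 1:5)
  expect_equal(flat$f_stat, 0)
  expect_equal(flat$p, 1)
  expect_error(trend_fit(c(0.1, 0.2), 1:2), ">= 3")
})

test_that("trend_fit_many agrees with trend_fit and controls the null", {
  set.seed(99)
  rho_mat <- matrix(rnorm(400 * 12), 400, 12)
  ages <- seq(0.5, 40, length.out = 12)
  many <- trend_fit_many(rho_mat, ages)
  one <- trend_fit(rho_mat[7, ], ages)
  expect_equal(many$f_stat[7], one$f_stat, tolerance = 1e-12)
  expect_equal(many$p[7], one$p, tolerance = 1e-12)
  ks <- suppressWarnings(stats::ks.test(many$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(many$significant), 0.02)
})

test_that("trend power increases with slope magnitude", {
  set.seed(101)
  ages <- 1:10
  power_at <- function(beta) {
    hits <- replicate(200, {
      rho <- beta * ages + rnorm(10, 0, 0.5)
      trend_fit(rho, ages)$p < 0.05
    })
    mean(hits)
  }
  pw <- vapply(c(0.02, 0.06, 0.12), power_at, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("bro_vs_pairs recovers a simulated coupling and degrades safely", {
  ont <- simulate_ontology(1, 16)
  # anti-correlation strength grows with sigma_tree across pairs
  n_pair <- 100
  st_pair <- seq(0.2, 2.5, length.out = n_pair)
  st <- c(st_pair, st_pair, rep(1, 50))
  ps <- data.frame(gene_a = sprintf("G%04d", 1:n_pair),
                   gene_b = sprintf("G%04d", n_pair + 1:n_pair),
                   rho = -0.8)
  sp <- synthetic_spec(n_genes = 250, n_donors = 3,
                       samples_per_region_per_donor = 2, sigma_tree = st,
                       sigma_noise = 0.6, pair_spec = ps, seed = 103)
  ds <- simulate_pairs(sp, ont)$dataset
  rec <- pair_correlations(ds, ps[c("gene_a", "gene_b")])
  bro <- bro_score_all(ds, ont)
  bv <- bro_vs_pairs(rec, bro)
  rho_main <- bv$rho[bv$measure == "signed_logp_vs_pair_bro"]
  expect_lt(rho_main, 0)

  # shuffling the pair BRO association breaks it
  set.seed(104)
  bro_shuf <- bro
  bro_shuf$bro <- sample(bro_shuf$bro)
  bv_shuf <- bro_vs_pairs(rec, bro_shuf)
  expect_lt(abs(bv_shuf$rho[bv_shuf$measure == "signed_logp_vs_pair_bro"]),
            2 / sqrt(n_pair) + 0.1)

  # constant pair BRO: undefined, flagged
  bro_const <- bro
  bro_const$bro <- 0.5
  bv_const <- bro_vs_pairs(rec, bro_const)
  expect_true(all(bv_const$status == "undefined"))
  expect_error(bro_vs_pairs(rec[1:5, ], bro), ">= 10 pairs")
})

test_that("pair_trends assembles per-age correlations with FDR", {
  ont <- simulate_ontology(1, 8)
  mult <- stats::setNames(rep(1, 4), paste0("a", 1:4))
  ps <- data.frame(gene_a = "G0001", gene_b = "G0002", rho = -0.9)
  sp <- synthetic_spec(n_genes = 30, n_donors = 2,
                       samples_per_region_per_donor = 3, sigma_tree = 1.5,
                       sigma_noise = 0.3, age_profile = mult,
                       pair_spec = ps, seed = 107)
  series <- lapply(simulate_age_series(sp, ont), `[[`, "dataset")
  pairs <- data.frame(gene_a = c("G0001", "G0003"),
                      gene_b = c("G0002", "G0004"))
  pt <- pair_trends(series, pairs, ages = 1:4)
  expect_equal(nrow(pt), 2L)
  expect_true(all(pt$p >= 0 & pt$p <= 1))
  expect_equal(dim(attr(pt, "per_age_rho")), c(2L, 4L))
})
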