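test_that("simulate_ontology builds complete trees with the right counts", {
  star <- simulate_ontology(depth = 1, branching = 16)
  expect_equal(nrow(star$regions), 17L)
  expect_equal(sum(star$regions$parent_id %in% "R"), 16L)

  t24 <- simulate_ontology(depth = 2, branching = 4)
  expect_equal(nrow(t24$regions), 21L)  # 1 + 4 + 16

  # combinatorial oracle: independent count of nodes per level
  for (cfg in list(c(3, 2), c(2, 5), c(4, 2))) {
    ont <- simulate_ontology(cfg[1], cfg[2])
    expect_equal(nrow(ont$regions), sum(cfg[2]^(0:cfg[1])))
    expect_equal(as.vector(table(ont$depth)), cfg[2]^(0:cfg[1]))
  }
  expect_error(simulate_ontology(0, 2), "depth")
  expect_error(simulate_ontology(2, 1), "branching")
})

test_that("identical spec and seed reproduce the dataset bit-identically", {
  ont <- simulate_ontology(2, 3)
  sp <- synthetic_spec(n_genes = 12, n_donors = 3,
                       samples_per_region_per_donor = 2, seed = 11)
  a <- simulate_expression(sp, ont)
  b <- simulate_expression(sp, ont)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth$region_effects, b$truth$region_effects)
  expect_error(synthetic_spec(n_genes = 5), "seed")
})

test_that("null construction gives i.i.d. samples centred on the baseline", {
  ont <- simulate_ontology(1, 8)
  sp <- synthetic_spec(n_genes = 60, n_donors = 2,
                       samples_per_region_per_donor = 4, sigma_tree = 0,
                       sigma_donor = 0, sigma_noise = 1, baseline_mean = 8,
                       seed = 13)
  sim <- simulate_expression(sp, ont)
  expect_true(all(sim$truth$region_effects == 0))
  expect_equal(mean(sim$dataset$values), 8, tolerance = 0.05)
  expect_equal(stats::sd(sim$dataset$values), 1, tolerance = 0.05)
  sc <- bro_score_all(sim$dataset, ont)
  expect_lt(abs(mean(sc$bro)), 3 * stats::sd(sc$bro) / sqrt(60))
})

test_that("squared expression distances follow the Brownian closed form", {
  ont <- simulate_ontology(2, 3)
  s_tree <- 1.5; s_noise <- 0.8; s_donor <- 0.6
  sp <- synthetic_spec(n_genes = 500, n_donors = 2,
                       samples_per_region_per_donor = 1,
                       sigma_tree = s_tree, sigma_noise = s_noise,
                       sigma_donor = s_donor, regions = "all", seed = 21)
  ds <- simulate_expression(sp, ont)$dataset
  pr <- pairwise_distances(ds, ont, "G0001")
  same_donor <- ds$samples$donor_id[pr$i] == ds$samples$donor_id[pr$j]
  sq <- t(apply(ds$values, 1, function(x) (x[pr$i] - x[pr$j])^2))
  for (t in c(1, 2, 4)) {
    for (sd_ in c(TRUE, FALSE)) {
      sel <- pr$tree_d == t & same_donor == sd_
      if (!any(sel)) next
      draws <- as.numeric(sq[, sel])
      expe <- s_tree^2 * t + 2 * s_noise^2 + if (sd_) 0 else 2 * s_donor^2
      sem <- stats::sd(draws) / sqrt(500)  # genes are the independent unit
      expect_lt(abs(mean(draws) - expe), 3 * sem)
    }
  }
})

test_that("per-gene sample variance obeys the law of total variance", {
  ont <- simulate_ontology(1, 16)
  sp <- synthetic_spec(n_genes = 400, n_donors = 4,
                       samples_per_region_per_donor = 2, sigma_tree = 1.2,
                       sigma_noise = 0.9, sigma_donor = 0.5, seed = 23)
  sim <- simulate_expression(sp, ont)
  v_obs <- mean(apply(sim$dataset$values, 1, stats::var))
  # leaves sit one edge from the root: region-effect variance = sigma_tree^2
  v_exp <- 1.2^2 + 0.5^2 + 0.9^2
  expect_equal(v_obs, v_exp, tolerance = 0.1)
})

test_that("strong tree signal drives BRO to the model's noiseless ceiling", {
  # Under Brownian regional effects the score is capped even without noise
  # (expression distance is a sqrt(t)-scaled half-normal, not a function of
  # t), so "near its maximum" means near the same world's noiseless score.
  ids <- sprintf("p%02d", 1:16)
  ont <- region_ontology(data.frame(region_id = ids,
                                    parent_id = c("", ids[-16]),
                                    name = ids, acronym = ids,
                                    stringsAsFactors = FALSE))
  mk <- function(noise) {
    sp <- synthetic_spec(n_genes = 50, n_donors = 2,
                         samples_per_region_per_donor = 2, sigma_tree = 10,
                         sigma_noise = noise, regions = "all", seed = 25)
    mean(bro_score_all(simulate_expression(sp, ont)$dataset, ont)$bro)
  }
  strong <- mk(1)       # sigma_tree / sigma_noise = 10
  ceiling <- mk(1e-4)   # effectively noiseless
  expect_gt(strong, 0.4)
  expect_gt(strong, 0.9 * ceiling)
})

test_that("age series scale the signal per group with disjoint donors", {
  ont <- simulate_ontology(1, 8)
  sp <- synthetic_spec(n_genes = 20, n_donors = 2,
                       samples_per_region_per_donor = 2, sigma_tree = 1,
                       age_profile = c(young = 1, old = 1), seed = 27)
  series <- simulate_age_series(sp, ont)
  expect_named(series, c("young", "old"))
  d1 <- series$young$dataset$samples$donor_id
  d2 <- series$old$dataset$samples$donor_id
  expect_length(intersect(unique(d1), unique(d2)), 0)
  expect_identical(unique(series$old$dataset$samples$age_group), "old")
  # single group reduces to simulate_expression modulo donor prefix
  sp1 <- synthetic_spec(n_genes = 20, n_donors = 2,
                        samples_per_region_per_donor = 2, sigma_tree = 1,
                        age_profile = c(only = 1), seed = 29)
  one <- simulate_age_series(sp1, ont)$only
  sp_plain <- synthetic_spec(n_genes = 20, n_donors = 2,
                             samples_per_region_per_donor = 2,
                             sigma_tree = 1, seed = 29)
  plain <- simulate_expression(sp_plain, ont, donor_prefix = "A1D")
  expect_identical(one$dataset$values, plain$dataset$values)
})

test_that("paired increments reach the target correlation limits", {
  ont <- simulate_ontology(2, 4)  # 20 edges
  mk <- function(rho, seed) {
    ps <- data.frame(gene_a = "G0001", gene_b = "G0002", rho = rho)
    sp <- synthetic_spec(n_genes = 2, n_donors = 1,
                         samples_per_region_per_donor = 1, sigma_tree = 1,
                         sigma_noise = 0.01, regions = "all",
                         pair_spec = ps, seed = seed)
    simulate_pairs(sp, ont)
  }
  plus <- mk(1, 31)
  expect_equal(plus$truth$region_effects["G0001", ],
               plus$truth$region_effects["G0002", ], tolerance = 1e-12)
  r_plus <- spatial_correlation(plus$dataset, "G0001", "G0002",
                                min_samples = 4)
  expect_gt(r_plus$median_rho, 0.99)
  minus <- mk(-1, 33)
  expect_equal(minus$truth$region_effects["G0001", ],
               -minus$truth$region_effects["G0002", ], tolerance = 1e-12)
  r_minus <- spatial_correlation(minus$dataset, "G0001", "G0002",
                                 min_samples = 4)
  expect_lt(r_minus$median_rho, -0.99)

  # intermediate target: realised increment correlation near 0.5
  set.seed(35)
  cors <- replicate(100, {
    sim <- mk(0.5, sample.int(1e6, 1))
    # recover per-edge increments from region effects via parent differences
    reg <- sim$truth$region_effects
    ids <- colnames(reg)
    par <- stats::setNames(ont$regions$parent_id, ont$regions$region_id)
    nonroot <- ids[!is.na(par[ids])]
    za <- reg["G0001", nonroot] - reg["G0001", par[nonroot]]
    zb <- reg["G0002", nonroot] - reg["G0002", par[nonroot]]
    stats::cor(za, zb)
  })
  expect_lt(abs(mean(cors) - 0.5), 0.1)
})
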