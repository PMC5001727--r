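#' Simulate a complete region ontology
#'
#' Builds a complete rooted tree of given depth and branching factor with
#' deterministic, position-derived region ids (`R`, `R.1`, `R.1.2`, ...),
#' emulating the shapes of real region hierarchies (a 16-leaf star for the
#' coarse granularity; deeper trees for fine granularities).
#'
#' @param depth tree depth (>= 1; root is depth 0).
#' @param branching children per internal node (>= 2).
#' @param seed unused (construction is deterministic); accepted for
#'   interface uniformity.
#' @return a `region_ontology` with `sum(branching^d), d = 0..depth` nodes.
#' @export
simulate_ontology <- function(depth, branching, seed = NULL) {
  if (depth < 1L) stop("depth must be >= 1")
  if (branching < 2L) stop("branching must be >= 2")
  ids <- "R"
  parents <- NA_character_
  frontier <- "R"
  for (d in seq_len(depth)) {
    kids <- as.vector(t(outer(frontier, seq_len(branching), paste,
                              sep = ".")))
    ids <- c(ids, kids)
    parents <- c(parents, rep(frontier, each = branching))
    frontier <- kids
  }
  region_ontology(data.frame(
    region_id = ids, parent_id = parents,
    name = paste("region", ids), acronym = ids, stringsAsFactors = FALSE))
}

#' Specification of a synthetic expression world
#'
#' Collects the generative parameters for [simulate_expression()]. The
#' signal model is Brownian diffusion on the ontology tree: each gene's
#' latent regional effect starts at 0 at the root and each child adds an
#' independent Normal(0, sigma_tree(g)^2) increment per edge, so the
#' expected squared expression difference between regions grows linearly
#' with tree distance -- exactly the structure the BRO statistic targets.
#' Samples add a per-(gene, donor) intercept shift
#' (Normal(0, sigma_donor^2)) and per-sample measurement noise
#' (Normal(0, sigma_noise^2)). Genes with sigma_tree = 0 are exact nulls.
#'
#' Defaults emulate the source-data structure at desk scale: 6 donors, a
#' baseline log-intensity of 8, donor effects half the size of measurement
#' noise.
#'
#' @param n_genes number of genes.
#' @param n_donors number of donors (default 6).
#' @param samples_per_region_per_donor samples in each (region, donor) cell.
#' @param sigma_tree per-edge diffusion SD; scalar or per-gene vector
#'   (>= 0).
#' @param sigma_donor donor intercept SD (>= 0, default 0.5).
#' @param sigma_noise measurement noise SD (> 0, default 1).
#' @param baseline_mean per-gene baseline; scalar or per-gene (default 8).
#' @param regions `"leaves"` (sample leaf regions only) or `"all"`.
#' @param age_profile optional named numeric vector: age_group ->
#'   multiplier on sigma_tree (for [simulate_age_series()]).
#' @param pair_spec optional data.frame(gene_a, gene_b, rho): target
#'   correlation of the two genes' per-edge increments (for
#'   [simulate_pairs()]).
#' @param seed RNG seed (mandatory).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200, n_donors = 6,
                           samples_per_region_per_donor = 2,
                           sigma_tree = 1, sigma_donor = 0.5,
                           sigma_noise = 1, baseline_mean = 8,
                           regions = c("leaves", "all"),
                           age_profile = NULL, pair_spec = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  regions <- match.arg(regions)
  sigma_tree <- rep_len(sigma_tree, n_genes)
  baseline_mean <- rep_len(baseline_mean, n_genes)
  if (any(sigma_tree < 0) || sigma_donor < 0) stop("scales must be >= 0")
  if (sigma_noise <= 0) stop("sigma_noise must be > 0")
  if (!is.null(pair_spec)) {
    stopifnot(all(c("gene_a", "gene_b", "rho") %in% names(pair_spec)))
    if (any(abs(pair_spec$rho) > 1)) stop("pair target rho must be in [-1, 1]")
  }
  structure(list(n_genes = n_genes, n_donors = n_donors,
                 samples_per_region_per_donor = samples_per_region_per_donor,
                 sigma_tree = sigma_tree, sigma_donor = sigma_donor,
                 sigma_noise = sigma_noise, baseline_mean = baseline_mean,
                 regions = regions, age_profile = age_profile,
                 pair_spec = pair_spec, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# regions receiving samples under a spec
.sampled_regions <- function(spec, ont) {
  if (spec$regions == "leaves") {
    reg <- ont$regions
    setdiff(reg$region_id, stats::na.omit(reg$parent_id))
  } else {
    region_ids(ont)
  }
}

# path indicator: P[region, edge] = 1 if the edge (to each non-root node)
# lies on the root path of `region`; regional effects are then Z %*% t(P).
.path_matrix <- function(ont) {
  ids <- region_ids(ont)
  nonroot <- setdiff(ids, ont$root)
  P <- ont$anc[, nonroot, drop = FALSE] * 1
  rownames(P) <- ids
  P
}

#' Simulate a tree-structured expression dataset with known truth
#'
#' See [synthetic_spec()] for the generative model. Under it,
#' E\[(x_a - x_b)^2\] for samples in regions at tree distance t equals
#' sigma_tree^2 * t + 2 * sigma_noise^2, plus 2 * sigma_donor^2 when the
#' samples come from different donors.
#'
#' @param spec a `synthetic_spec`.
#' @param ont a `region_ontology`.
#' @param donor_prefix prefix for donor ids (default "D").
#' @return list(dataset = `expr_dataset`, truth = list(sigma_tree,
#'   region_effects (genes x regions), donor_effects (genes x donors),
#'   baseline_mean, spec)).
#' @export
simulate_expression <- function(spec, ont, donor_prefix = "D") {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(ont, "region_ontology"))
  set.seed(spec$seed)
  .simulate_expression_impl(spec, ont, donor_prefix)
}

# core generator; assumes the RNG state is already set
.simulate_expression_impl <- function(spec, ont, donor_prefix = "D") {
  G <- spec$n_genes
  genes <- sprintf("G%04d", seq_len(G))
  P <- .path_matrix(ont)
  n_edge <- ncol(P)

  # per-edge Brownian increments; paired genes draw jointly with target rho
  Z <- matrix(stats::rnorm(G * n_edge), G, n_edge,
              dimnames = list(genes, colnames(P)))
  if (!is.null(spec$pair_spec)) {
    ps <- spec$pair_spec
    ia <- match(as.character(ps$gene_a), genes)
    ib <- match(as.character(ps$gene_b), genes)
    if (anyNA(ia) || anyNA(ib)) stop("pair_spec gene(s) outside G0001..G",
                                     sprintf("%04d", G))
    for (k in seq_len(nrow(ps))) {
      r <- ps$rho[k]
      za <- stats::rnorm(n_edge)
      zb <- r * za + sqrt(1 - r^2) * stats::rnorm(n_edge)
      Z[ia[k], ] <- za
      Z[ib[k], ] <- zb
    }
  }
  effects <- (Z * spec$sigma_tree) %*% t(P)   # genes x regions

  regions <- .sampled_regions(spec, ont)
  donors <- paste0(donor_prefix, seq_len(spec$n_donors))
  reps <- spec$samples_per_region_per_donor
  grid <- expand.grid(rep = seq_len(reps), donor_id = donors,
                      region_id = regions, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$region_id, grid$donor_id, grid$rep), ]
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(nrow(grid))),
    region_id = grid$region_id, donor_id = grid$donor_id,
    age_group = NA_character_, stringsAsFactors = FALSE)

  donor_eff <- matrix(stats::rnorm(G * length(donors), 0, spec$sigma_donor),
                      G, length(donors), dimnames = list(genes, donors))
  noise <- matrix(stats::rnorm(G * nrow(samples), 0, spec$sigma_noise),
                  G, nrow(samples))
  vals <- spec$baseline_mean +
    effects[, samples$region_id, drop = FALSE] +
    donor_eff[, samples$donor_id, drop = FALSE] + noise
  dimnames(vals) <- list(genes, samples$sample_id)

  list(dataset = expression_dataset(vals, samples, ont = ont),
       truth = list(sigma_tree = stats::setNames(spec$sigma_tree, genes),
                    region_effects = effects, donor_effects = donor_eff,
                    baseline_mean = stats::setNames(spec$baseline_mean, genes),
                    spec = spec))
}

#' Simulate one dataset per age group
#'
#' One independent dataset per entry of `spec$age_profile`, with each
#' group's sigma_tree scaled by its multiplier and disjoint donors across
#' groups (a cross-sectional design). Group order follows the profile.
#'
#' @param spec a `synthetic_spec` with non-empty `age_profile`.
#' @param ont a `region_ontology`.
#' @return named list of list(dataset, truth), one per age group.
#' @export
simulate_age_series <- function(spec, ont) {
  stopifnot(inherits(spec, "synthetic_spec"))
  prof <- spec$age_profile
  if (is.null(prof) || !length(prof)) stop("age_profile is empty")
  if (is.null(names(prof))) names(prof) <- paste0("age", seq_along(prof))
  set.seed(spec$seed)
  out <- vector("list", length(prof))
  names(out) <- names(prof)
  for (k in seq_along(prof)) {
    sp <- spec
    sp$sigma_tree <- spec$sigma_tree * prof[[k]]
    sim <- .simulate_expression_impl(sp, ont,
                                     donor_prefix = paste0("A", k, "D"))
    sim$dataset$samples$age_group <- names(prof)[k]
    out[[k]] <- sim
  }
  out
}

#' Simulate a dataset containing correlated gene pairs
#'
#' Convenience wrapper: [simulate_expression()] on a spec carrying a
#' `pair_spec`, whose listed pairs get jointly drawn (bivariate normal)
#' per-edge increments with the target correlation; marginals are
#' unchanged.
#'
#' @param spec a `synthetic_spec` with non-NULL `pair_spec`.
#' @param ont a `region_ontology`.
#' @return as [simulate_expression()].
#' @export
simulate_pairs <- function(spec, ont) {
  if (is.null(spec$pair_spec)) stop("spec has no pair_spec")
  simulate_expression(spec, ont)
}
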