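#' Tree and expression distances over all sample pairs
#'
#' For every unordered pair of distinct samples (a, b) this returns the
#' ontology distance d_tree(a, b) (edge count between the samples' regions;
#' 0 for within-region pairs) and, for one gene, the expression distance
#' |x_a - x_b|. The tree distances depend only on the sample annotations and
#' are shared across genes.
#'
#' @param ds an `expr_dataset` with >= 2 samples.
#' @param ont a `region_ontology` covering all sample regions.
#' @param gene gene id (row of the dataset).
#' @return list(tree_d, expr_d, n_pairs, i, j): two numeric vectors of
#'   length n(n-1)/2 in a fixed pair order, plus the pair index vectors.
#' @export
pairwise_distances <- function(ds, ont, gene) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(ont, "region_ontology"))
  n <- n_samples(ds)
  if (n < 2L) stop("need >= 2 samples")
  if (!gene %in% rownames(ds$values)) stop("unknown gene: ", gene)
  pr <- .pair_index(n)
  td <- .tree_pair_distances(ds, ont, pr)
  x <- unname(ds$values[gene, ])
  list(tree_d = td, expr_d = abs(x[pr$i] - x[pr$j]),
       n_pairs = length(td), i = pr$i, j = pr$j)
}

# unordered pair index (i < j), fixed enumeration order
.pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  list(i = i, j = j)
}

.tree_pair_distances <- function(ds, ont, pr) {
  D <- region_distance_matrix(ont)
  bad <- setdiff(unique(ds$samples$region_id), rownames(D))
  if (length(bad)) stop("sample region(s) not in ontology: ",
                        paste(bad, collapse = ", "))
  ridx <- match(ds$samples$region_id, rownames(D))
  as.numeric(D[cbind(ridx[pr$i], ridx[pr$j])])
}

# Spearman with mid-rank ties; rank of x against a pre-ranked y
.spearman <- function(x, y_rank) {
  stats::cor(rank(x), y_rank)
}

#' BRO-agreement score of one gene
#'
#' The BRO (brain-region ontology) agreement score of a gene is the Spearman
#' rank correlation, over all unordered sample pairs, between the ontology
#' tree distance of the two samples' regions and the absolute difference of
#' the gene's expression in the two samples. It measures how strongly the
#' gene's spatial expression pattern agrees with the region hierarchy.
#'
#' @param dp pair distances from [pairwise_distances()].
#' @return numeric score in \[-1, 1\]; `NA` when the expression distances
#'   have zero variance (undefined score).
#' @export
bro_score <- function(dp) {
  if (stats::var(dp$expr_d) == 0 || stats::var(dp$tree_d) == 0) {
    return(NA_real_)
  }
  .spearman(dp$expr_d, rank(dp$tree_d))
}

#' BRO-agreement scores for all genes of a dataset
#'
#' Tree distances (and their ranks) are computed once and reused across
#' genes; the result is deterministic given the inputs.
#'
#' @param ds an `expr_dataset`.
#' @param ont a `region_ontology`.
#' @param genes gene ids to score (default: all rows).
#' @return data.frame(gene_id, bro, n_pairs, status) with status `"ok"` or
#'   `"zero_variance"` (score `NA`, excluded downstream).
#' @export
bro_score_all <- function(ds, ont, genes = NULL) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(ont, "region_ontology"))
  if (is.null(genes)) genes <- rownames(ds$values)
  miss <- setdiff(genes, rownames(ds$values))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  n <- n_samples(ds)
  if (n < 2L) stop("need >= 2 samples")
  pr <- .pair_index(n)
  td <- .tree_pair_distances(ds, ont, pr)
  if (stats::var(td) == 0) {
    warning("all sample pairs have equal tree distance; scores undefined")
    return(data.frame(gene_id = genes, bro = NA_real_,
                      n_pairs = length(td), status = "zero_variance",
                      stringsAsFactors = FALSE))
  }
  tr <- rank(td)
  score <- vapply(genes, function(g) {
    e <- abs(ds$values[g, pr$i] - ds$values[g, pr$j])
    if (stats::var(e) == 0) NA_real_ else .spearman(e, tr)
  }, numeric(1))
  data.frame(gene_id = genes, bro = unname(score), n_pairs = length(td),
             status = ifelse(is.na(score), "zero_variance", "ok"),
             stringsAsFactors = FALSE)
}

#' Triplet-ranking agreement score
#'
#' Random sample triplets (a, b, c) are drawn; among triplets whose tree
#' distances are strictly ordered (d_tree(a,b) < d_tree(a,c); ties excluded
#' from the denominator), the score is the fraction for which the expression
#' distances are ordered the same way. An ordering-based alternative to the
#' pairwise BRO score.
#'
#' @param ds an `expr_dataset` with >= 3 samples.
#' @param ont a `region_ontology`.
#' @param gene gene id.
#' @param n_triplets number of sampled triplets (the source analyses used
#'   1e6; scale down for small data).
#' @param seed RNG seed (required; sampling is reproducible).
#' @return numeric score in \[0, 1\]; `NA` if no triplet qualifies.
#' @export
triplet_score <- function(ds, ont, gene, n_triplets = 1e5, seed) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(ont, "region_ontology"))
  n <- n_samples(ds)
  if (n < 3L) stop("need >= 3 samples")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  D <- region_distance_matrix(ont)
  ridx <- match(ds$samples$region_id, rownames(D))
  x <- ds$values[gene, ]
  a <- sample.int(n, n_triplets, replace = TRUE)
  b <- sample.int(n, n_triplets, replace = TRUE)
  cc <- sample.int(n, n_triplets, replace = TRUE)
  ok <- a != b & a != cc & b != cc
  a <- a[ok]; b <- b[ok]; cc <- cc[ok]
  dt_ab <- D[cbind(ridx[a], ridx[b])]
  dt_ac <- D[cbind(ridx[a], ridx[cc])]
  keep <- dt_ab != dt_ac
  if (!any(keep)) return(NA_real_)
  # orient each triplet so the tree distances satisfy d(a,b) < d(a,c)
  swap <- dt_ab > dt_ac
  b2 <- ifelse(swap, cc, b)
  c2 <- ifelse(swap, b, cc)
  a <- a[keep]; b2 <- b2[keep]; c2 <- c2[keep]
  de_ab <- abs(x[a] - x[b2])
  de_ac <- abs(x[a] - x[c2])
  mean(de_ab < de_ac)
}

#' Permutation null and empirical significance for BRO scores
#'
#' Each permutation shuffles a gene's expression values across samples
#' (breaking the sample-to-region link) and recomputes the BRO score. By
#' default the permuted scores of all genes are pooled into one null
#' distribution. Per gene: add-one empirical p-value
#' p = (1 + #\{null >= observed\}) / (1 + N_null); `significant_top1pct`
#' flags observed scores above the null's 99th percentile (the "top 1%"
#' rule); Benjamini-Hochberg on the empirical p-values gives `q` and
#' `significant_fdr` (q < fdr_q).
#'
#' @param ds an `expr_dataset`.
#' @param ont a `region_ontology`.
#' @param genes gene ids (default all).
#' @param n_permutations permutations per gene (default 100).
#' @param seed RNG seed (required).
#' @param pooled pool permuted scores across genes into a single null
#'   (default TRUE); otherwise each gene is ranked against its own null.
#' @param unit `"sample"` (default; shuffle values across samples) or
#'   `"region"` (shuffle region identities of region-mean profiles, a
#'   coarser null).
#' @param fdr_q FDR threshold for `significant_fdr` (default 0.01).
#' @return list(result, null): `result` is a data.frame(gene_id, bro,
#'   p_empirical, q, significant_top1pct, significant_fdr, n_pairs, status);
#'   `null` is list(scores, per_gene, threshold_top1).
#' @export
permutation_null <- function(ds, ont, genes = NULL, n_permutations = 100,
                             seed, pooled = TRUE,
                             unit = c("sample", "region"), fdr_q = 0.01) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(ont, "region_ontology"))
  if (missing(seed)) stop("seed is required")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  unit <- match.arg(unit)
  obs <- bro_score_all(ds, ont, genes)
  genes <- obs$gene_id
  live <- obs$status == "ok"

  n <- n_samples(ds)
  pr <- .pair_index(n)
  td <- .tree_pair_distances(ds, ont, pr)
  tr <- rank(td)
  set.seed(seed)

  if (unit == "sample") {
    perm_scores <- function(g) {
      x <- ds$values[g, ]
      vapply(seq_len(n_permutations), function(k) {
        xp <- x[sample.int(n)]
        .spearman(abs(xp[pr$i] - xp[pr$j]), tr)
      }, numeric(1))
    }
  } else {
    # region-level shuffle: permute which region carries which mean profile
    reg <- sort(unique(ds$samples$region_id))
    prof <- average_by_region(ds)
    rpos <- match(ds$samples$region_id, reg)
    perm_scores <- function(g) {
      mu <- prof[g, reg]
      x <- ds$values[g, ]
      dev <- x - mu[rpos]
      vapply(seq_len(n_permutations), function(k) {
        xp <- mu[sample.int(length(reg))][rpos] + dev
        .spearman(abs(xp[pr$i] - xp[pr$j]), tr)
      }, numeric(1))
    }
  }

  null_mat <- matrix(NA_real_, n_permutations, length(genes))
  for (k in which(live)) null_mat[, k] <- perm_scores(genes[k])

  p <- rep(NA_real_, length(genes))
  top1 <- rep(NA, length(genes))
  if (pooled) {
    null_scores <- as.numeric(null_mat[, live, drop = FALSE])
    thr <- stats::quantile(null_scores, 0.99, names = FALSE)
    for (k in which(live)) {
      p[k] <- (1 + sum(null_scores >= obs$bro[k])) / (1 + length(null_scores))
      top1[k] <- obs$bro[k] > thr
    }
  } else {
    thr <- rep(NA_real_, length(genes))
    for (k in which(live)) {
      ns <- null_mat[, k]
      thr[k] <- stats::quantile(ns, 0.99, names = FALSE)
      p[k] <- (1 + sum(ns >= obs$bro[k])) / (1 + length(ns))
      top1[k] <- obs$bro[k] > thr[k]
    }
    null_scores <- null_mat
  }
  q <- rep(NA_real_, length(genes))
  q[live] <- stats::p.adjust(p[live], method = "BH")

  result <- data.frame(
    gene_id = genes, bro = obs$bro, p_empirical = p, q = q,
    significant_top1pct = top1, significant_fdr = !is.na(q) & q < fdr_q,
    n_pairs = obs$n_pairs, status = obs$status, stringsAsFactors = FALSE)
  list(result = result,
       null = list(scores = null_scores, per_gene = !pooled,
                   threshold_top1 = thr))
}

#' Combine BRO scores across subjects
#'
#' Two combination modes: `pooled` computes one score over all samples of
#' all donors; `per_subject_mean` scores each donor separately and averages
#' (unweighted). The per-donor score table is also returned, supporting
#' robustness-across-subjects checks.
#'
#' @param ds an `expr_dataset`.
#' @param ont a `region_ontology`.
#' @param genes gene ids (default all).
#' @param mode `"pooled"` or `"per_subject_mean"`.
#' @return data.frame(gene_id, bro, n_donors_used); per-donor scores in
#'   attribute `per_donor` (genes x donors matrix).
#' @export
combine_subjects <- function(ds, ont, genes = NULL,
                             mode = c("pooled", "per_subject_mean")) {
  mode <- match.arg(mode)
  if (is.null(genes)) genes <- rownames(ds$values)
  donors <- unique(ds$samples$donor_id)
  per <- matrix(NA_real_, length(genes), length(donors),
                dimnames = list(genes, donors))
  for (d in donors) {
    sub <- subset_samples(ds, donors = d, subtree = FALSE)
    if (n_samples(sub) < 2L || length(unique(sub$samples$region_id)) < 2L) {
      warning("donor ", d, " lacks >= 2 samples in >= 2 regions; dropped")
      next
    }
    per[, d] <- bro_score_all(sub, ont, genes)$bro
  }
  if (mode == "pooled") {
    out <- bro_score_all(ds, ont, genes)[c("gene_id", "bro")]
    out$n_donors_used <- length(donors)
  } else {
    used <- colSums(!is.na(per)) > 0
    if (!any(used)) stop("no donor usable for per_subject_mean")
    out <- data.frame(gene_id = genes,
                      bro = rowMeans(per[, used, drop = FALSE], na.rm = TRUE),
                      n_donors_used = sum(used), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "per_donor") <- per
  out
}

#' BRO-agreement trajectory across age groups
#'
#' Scores each age group's dataset on the regions shared by all groups and
#' reports the cross-gene mean score per group, in the given group order --
#' the quantity whose life-course shape (high in embryo, dipping around
#' birth, rising after) is the "hourglass" pattern.
#'
#' @param datasets named list of `expr_dataset`, one per age group, in age
#'   order.
#' @param ont a `region_ontology`.
#' @param genes gene ids (default: genes common to all groups).
#' @return list(trajectory = data.frame(age_group, mean_bro, n_genes,
#'   n_subjects, n_regions), per_gene = genes x groups score matrix).
#' @export
bro_by_age_group <- function(datasets, ont, genes = NULL) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("group", seq_along(datasets))
  }
  shared <- Reduce(intersect, lapply(datasets, function(d)
    unique(d$samples$region_id)))
  if (length(shared) < 2L) stop("age groups share < 2 regions")
  if (is.null(genes)) {
    genes <- Reduce(intersect, lapply(datasets, function(d)
      rownames(d$values)))
  }
  groups <- names(datasets)
  per <- matrix(NA_real_, length(genes), length(groups),
                dimnames = list(genes, groups))
  meta <- data.frame(age_group = groups, mean_bro = NA_real_,
                     n_genes = NA_integer_, n_subjects = NA_integer_,
                     n_regions = length(shared), stringsAsFactors = FALSE)
  keep <- rep(TRUE, length(groups))
  for (k in seq_along(groups)) {
    sub <- tryCatch(
      subset_samples(datasets[[k]], regions = shared, subtree = FALSE),
      error = function(e) NULL)
    if (is.null(sub) || length(unique(sub$samples$region_id)) < 2L) {
      warning("age group ", groups[k], " has < 2 shared regions; dropped")
      keep[k] <- FALSE
      next
    }
    sc <- bro_score_all(sub, ont, genes)
    per[, k] <- sc$bro
    meta$mean_bro[k] <- mean(sc$bro, na.rm = TRUE)
    meta$n_genes[k] <- sum(!is.na(sc$bro))
    meta$n_subjects[k] <- length(unique(sub$samples$donor_id))
  }
  list(trajectory = meta[keep, , drop = FALSE],
       per_gene = per[, keep, drop = FALSE])
}
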