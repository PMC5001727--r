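#' Per-gene one-way ANOVA of expression across regions
#'
#' For each gene, a one-way ANOVA of expression on region label tests whether
#' regional means differ. By default the ANOVA is computed separately within
#' each donor and the per-gene summary is the average F statistic across
#' donors, with the summary p-value the average of per-donor p-values
#' (a Fisher combination is available); BH-FDR is applied to the summary p.
#' Unlike the BRO score, ANOVA is blind to the ontology structure: it flags
#' any regional mean difference regardless of tree position.
#'
#' @param ds an `expr_dataset`.
#' @param regions optional region ids defining the granularity (samples
#'   outside are dropped); default: all sampled regions.
#' @param per_donor compute within donor and average (default TRUE);
#'   FALSE pools all samples into a single ANOVA.
#' @param combine_p `"mean"` (default; average of per-donor p) or
#'   `"fisher"`.
#' @param fdr_q FDR threshold for the `significant` flag.
#' @return data.frame(gene_id, f_stat, p, q, significant) with the per-donor
#'   p-value matrix in attribute `per_donor_p`.
#' @export
anova_by_region <- function(ds, regions = NULL, per_donor = TRUE,
                            combine_p = c("mean", "fisher"), fdr_q = 0.01) {
  stopifnot(inherits(ds, "expr_dataset"))
  combine_p <- match.arg(combine_p)
  if (!is.null(regions)) {
    ds <- subset_samples(ds, regions = regions, subtree = FALSE)
  }
  genes <- rownames(ds$values)
  if (per_donor) {
    donors <- unique(ds$samples$donor_id)
    fmat <- matrix(NA_real_, length(genes), length(donors),
                   dimnames = list(genes, donors))
    pmat <- fmat
    for (d in donors) {
      sub <- subset_samples(ds, donors = d, subtree = FALSE)
      g <- factor(sub$samples$region_id)
      k <- nlevels(g)
      if (k < 2L || n_samples(sub) - k < 1L) {
        warning("donor ", d, " lacks region replication; dropped")
        next
      }
      fp <- .anova_f(sub$values, g)
      fmat[, d] <- fp$f
      pmat[, d] <- fp$p
    }
    if (all(is.na(fmat))) stop("no donor with region replication")
    f <- rowMeans(fmat, na.rm = TRUE)
    p <- if (combine_p == "mean") {
      rowMeans(pmat, na.rm = TRUE)
    } else {
      k <- rowSums(!is.na(pmat))
      stats::pchisq(-2 * rowSums(log(pmat), na.rm = TRUE), df = 2 * k,
                    lower.tail = FALSE)
    }
  } else {
    g <- factor(ds$samples$region_id)
    if (nlevels(g) < 2L) stop("need >= 2 regions")
    fp <- .anova_f(ds$values, g)
    f <- fp$f
    p <- fp$p
    pmat <- matrix(p, ncol = 1, dimnames = list(genes, "pooled"))
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = genes, f_stat = unname(f), p = unname(p),
                    q = unname(q), significant = unname(q < fdr_q),
                    stringsAsFactors = FALSE)
  attr(out, "per_donor_p") <- pmat
  out
}

# vectorised one-way ANOVA over the rows of Y (genes x samples)
.anova_f <- function(Y, g) {
  g <- droplevels(g)
  n <- ncol(Y)
  k <- nlevels(g)
  cnt <- as.vector(table(g))
  sums <- rowsum(t(Y), g)                    # k x genes
  gm <- colSums(sums) / n
  ssb <- colSums(sums^2 / cnt) - n * gm^2
  sst <- colSums(t(Y)^2) - n * gm^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  list(f = f, p = p)
}

#' Principal component analysis of samples
#'
#' PCA of the sample-by-sample covariance of gene-centered expression (each
#' gene centered across samples; no variance scaling). Component signs are
#' fixed by making the largest-magnitude gene loading positive, so results
#' are deterministic.
#'
#' @param ds an `expr_dataset` with >= 2 samples.
#' @param k number of components to return (default
#'   `min(n_genes, n_samples - 1)`).
#' @return list(coords = samples x k coordinate matrix, explained = fraction
#'   of total sample variance per component, loadings = genes x k).
#' @export
pca_samples <- function(ds, k = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  n <- n_samples(ds)
  if (n < 2L) stop("need >= 2 samples")
  maxk <- min(n_genes(ds), n - 1L)
  if (is.null(k)) k <- maxk
  if (k > min(n_genes(ds), n)) stop("k exceeds min(genes, samples)")
  k <- min(k, maxk)
  X <- t(ds$values)                      # samples x genes
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  flip <- vapply(seq_len(k), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2L, flip, "*")
  rownames(coords) <- colnames(ds$values)
  list(coords = coords,
       explained = pc$sdev[seq_len(k)]^2 / total_var,
       loadings = loadings)
}

#' Explained sample-variance from region and donor identity
#'
#' For each gene, expression across samples is regressed on one-hot region
#' indicators, one-hot donor indicators, and both together; the explained
#' variance is R^2 = 1 - RSS/TSS against the constant model. Quantifies how
#' much of sample-to-sample variability each identity source accounts for.
#'
#' @param ds an `expr_dataset`.
#' @return data.frame(gene_id, r2_region, r2_donor, r2_joint, status);
#'   a factor with a single level yields R^2 = 0 and status
#'   `"single_level"`.
#' @export
explained_variance <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  Y <- t(ds$values)                       # samples x genes
  Yc <- sweep(Y, 2L, colMeans(Y))
  tss <- colSums(Yc^2)
  reg <- factor(ds$samples$region_id)
  don <- factor(ds$samples$donor_id)
  r2_of <- function(f) {
    X <- stats::model.matrix(~f)
    rss <- colSums(qr.resid(qr(X), Y)^2)
    pmin(pmax(1 - rss / tss, 0), 1)
  }
  status <- rep("ok", n_genes(ds))
  if (nlevels(reg) < 2L) {
    r2r <- rep(0, n_genes(ds)); status <- rep("single_level", n_genes(ds))
  } else r2r <- r2_of(reg)
  if (nlevels(don) < 2L) {
    r2d <- rep(0, n_genes(ds)); status <- rep("single_level", n_genes(ds))
  } else r2d <- r2_of(don)
  if (nlevels(reg) >= 2L && nlevels(don) >= 2L) {
    X <- stats::model.matrix(~reg + don)
    rss <- colSums(qr.resid(qr(X), Y)^2)
    r2j <- pmin(pmax(1 - rss / tss, 0), 1)
  } else {
    r2j <- pmax(r2r, r2d)
  }
  zero <- tss == 0
  r2r[zero] <- r2d[zero] <- r2j[zero] <- NA_real_
  status[zero] <- "zero_variance"
  data.frame(gene_id = rownames(ds$values), r2_region = unname(r2r),
             r2_donor = unname(r2d), r2_joint = unname(r2j),
             status = status, stringsAsFactors = FALSE)
}

#' Hierarchical clustering of regions
#'
#' Samples are first averaged into one profile per region; regions are then
#' agglomerated with average linkage on Euclidean distances. Region columns
#' are sorted lexicographically before clustering so equal-distance merges
#' resolve deterministically. At high signal-to-noise on tree-structured
#' expression, the dendrogram recovers the generating ontology topology.
#'
#' @param ds an `expr_dataset` with samples in >= 3 regions.
#' @return list(hclust, newick, merges = data.frame(step, height, size))
#' @export
cluster_regions <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  prof <- average_by_region(ds)           # genes x regions, sorted cols
  if (ncol(prof) < 3L) stop("need >= 3 regions with samples")
  hc <- stats::hclust(stats::dist(t(prof), method = "euclidean"),
                      method = "average")
  ph <- ape::as.phylo(hc)
  sizes <- integer(nrow(hc$merge))
  csize <- function(x) if (x < 0) 1L else sizes[x]
  for (i in seq_len(nrow(hc$merge))) {
    sizes[i] <- csize(hc$merge[i, 1]) + csize(hc$merge[i, 2])
  }
  list(hclust = hc,
       newick = ape::write.tree(ph),
       merges = data.frame(step = seq_len(nrow(hc$merge)),
                           height = hc$height, size = sizes))
}
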