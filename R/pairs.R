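#' Spatial correlation of a gene pair
#'
#' Rank correlation (Spearman by default) of the two genes' expression
#' across samples, computed within each donor. The pair summary is the
#' median per-donor correlation; `signed_logp` is
#' sign(median_rho) * (-log10 p) where p is the correlation p-value of the
#' donor whose rho is closest to the median (ties: first such donor).
#' Negative values therefore mark spatially anti-correlated pairs --
#' region-specific switching between functionally similar variants.
#'
#' @param ds an `expr_dataset`.
#' @param gene_a,gene_b gene ids.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_samples minimum samples per donor (default 4; smaller donors
#'   are omitted).
#' @return list(gene_a, gene_b, per_subject_rho (named by donor),
#'   median_rho, signed_logp, n_donors).
#' @export
spatial_correlation <- function(ds, gene_a, gene_b,
                                method = c("spearman", "pearson"),
                                min_samples = 4L) {
  stopifnot(inherits(ds, "expr_dataset"))
  method <- match.arg(method)
  miss <- setdiff(c(gene_a, gene_b), rownames(ds$values))
  if (length(miss)) stop("gene(s) not in dataset: ",
                         paste(miss, collapse = ", "))
  donors <- unique(ds$samples$donor_id)
  rho <- p <- stats::setNames(rep(NA_real_, length(donors)), donors)
  for (d in donors) {
    sel <- ds$samples$donor_id == d
    if (sum(sel) < min_samples) next
    x <- ds$values[gene_a, sel]
    y <- ds$values[gene_b, sel]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                           exact = FALSE))
    rho[d] <- unname(ct$estimate)
    p[d] <- ct$p.value
  }
  ok <- !is.na(rho)
  if (!any(ok)) {
    return(list(gene_a = gene_a, gene_b = gene_b, per_subject_rho = rho,
                median_rho = NA_real_, signed_logp = NA_real_, n_donors = 0L))
  }
  med <- stats::median(rho[ok])
  d_med <- names(which.min(abs(rho[ok] - med)))
  logp <- -log10(max(p[d_med], 1e-300))
  list(gene_a = gene_a, gene_b = gene_b, per_subject_rho = rho,
       median_rho = med, signed_logp = sign(med) * logp,
       n_donors = sum(ok))
}

#' Spatial correlations for a table of gene pairs
#'
#' @param ds an `expr_dataset`.
#' @param pairs data.frame with columns `gene_a`, `gene_b` and optionally
#'   `source_label`.
#' @param ... passed to [spatial_correlation()].
#' @return data.frame(gene_a, gene_b, source_label, median_rho, signed_logp,
#'   n_donors); pairs are stored in canonical (sorted) gene order.
#' @export
pair_correlations <- function(ds, pairs, ...) {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  a <- as.character(pairs$gene_a)
  b <- as.character(pairs$gene_b)
  if (any(a == b)) stop("self-pair(s) found (gene_a == gene_b)")
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  lab <- if ("source_label" %in% names(pairs)) {
    as.character(pairs$source_label)
  } else "custom"
  rows <- lapply(seq_along(a), function(k) {
    r <- spatial_correlation(ds, a[k], b[k], ...)
    data.frame(gene_a = a[k], gene_b = b[k],
               source_label = lab[min(k, length(lab))],
               median_rho = r$median_rho, signed_logp = r$signed_logp,
               n_donors = r$n_donors, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Draw a random baseline of gene pairs
#'
#' Uniform pairs of distinct genes, excluding any listed pairs; seeded and
#' reproducible.
#'
#' @param genes gene-id universe.
#' @param n number of baseline pairs (> 0).
#' @param seed RNG seed (required).
#' @param exclude optional data.frame(gene_a, gene_b) of pairs to avoid.
#' @return data.frame(gene_a, gene_b, source_label = "random_baseline").
#' @export
random_pair_baseline <- function(genes, n, seed, exclude = NULL) {
  if (n < 1L) stop("n_random_baseline must be >= 1")
  if (missing(seed)) stop("seed is required")
  if (length(genes) < 2L) stop("need >= 2 genes")
  forbid <- character(0)
  if (!is.null(exclude)) {
    a <- as.character(exclude$gene_a); b <- as.character(exclude$gene_b)
    forbid <- paste(pmin(a, b), pmax(a, b))
  }
  set.seed(seed)
  out_a <- character(0); out_b <- character(0)
  guard <- 0L
  while (length(out_a) < n && guard < 100L) {
    m <- 2L * (n - length(out_a))
    a <- sample(genes, m, replace = TRUE)
    b <- sample(genes, m, replace = TRUE)
    lo <- pmin(a, b); hi <- pmax(a, b)
    ok <- a != b & !(paste(lo, hi) %in% forbid)
    out_a <- c(out_a, lo[ok]); out_b <- c(out_b, hi[ok])
    guard <- guard + 1L
  }
  if (length(out_a) < n) stop("could not draw enough baseline pairs")
  data.frame(gene_a = out_a[seq_len(n)], gene_b = out_b[seq_len(n)],
             source_label = "random_baseline", stringsAsFactors = FALSE)
}

#' Compare pair-set spatial correlations to a random baseline
#'
#' Computes spatial-correlation records for each listed pair set and for a
#' seeded random baseline, then rank-sum-compares each set's `signed_logp`
#' distribution against the baseline (one-tailed "less": a left shift means
#' the set is more strongly anti-correlated than random pairs).
#'
#' @param ds an `expr_dataset`.
#' @param pairs data.frame(gene_a, gene_b, source_label); one set per
#'   distinct `source_label`.
#' @param n_random_baseline baseline size (> 0).
#' @param seed RNG seed for the baseline draw.
#' @param tail `"less"` (default), `"greater"` or `"two.sided"`.
#' @param ... passed to [spatial_correlation()].
#' @return list(records = per-pair table incl. baseline rows,
#'   tests = data.frame(set_name, n_pairs, median_signed_logp,
#'   median_rho, baseline_median_signed_logp, wilcoxon_p)).
#' @export
pair_set_distribution <- function(ds, pairs, n_random_baseline, seed,
                                  tail = c("less", "greater", "two.sided"),
                                  ...) {
  tail <- match.arg(tail)
  if (!nrow(pairs)) stop("pairs is empty")
  base <- random_pair_baseline(rownames(ds$values), n_random_baseline, seed,
                               exclude = pairs)
  rec_sets <- pair_correlations(ds, pairs, ...)
  rec_base <- pair_correlations(ds, base, ...)
  base_lp <- rec_base$signed_logp[!is.na(rec_base$signed_logp)]
  sets <- unique(rec_sets$source_label)
  tests <- do.call(rbind, lapply(sets, function(nm) {
    lp <- rec_sets$signed_logp[rec_sets$source_label == nm]
    lp <- lp[!is.na(lp)]
    data.frame(
      set_name = nm, n_pairs = length(lp),
      median_signed_logp = stats::median(lp),
      median_rho = stats::median(
        rec_sets$median_rho[rec_sets$source_label == nm], na.rm = TRUE),
      baseline_median_signed_logp = stats::median(base_lp),
      wilcoxon_p = stats::wilcox.test(lp, base_lp,
                                      alternative = tail)$p.value,
      stringsAsFactors = FALSE)
  }))
  list(records = rbind(rec_sets, rec_base), tests = tests)
}

#' Linear trend of spatial correlation across age
#'
#' Least-squares regression of a pair's spatial correlation on age; trend
#' significance is the F statistic of the linear model against the constant
#' model. A constant correlation series yields F = 0, p = 1.
#'
#' @param rho correlations, one per age point (NAs dropped with their ages).
#' @param ages numeric ages (same length as `rho`; >= 3 defined points).
#' @return list(slope, intercept, f_stat, p, n).
#' @export
trend_fit <- function(rho, ages) {
  ok <- !is.na(rho) & !is.na(ages)
  rho <- rho[ok]; ages <- ages[ok]
  if (length(rho) < 3L) stop("need >= 3 age points with defined correlations")
  n <- length(rho)
  sxx <- sum((ages - mean(ages))^2)
  if (sxx == 0) stop("ages are constant")
  slope <- sum((ages - mean(ages)) * (rho - mean(rho))) / sxx
  rss0 <- sum((rho - mean(rho))^2)
  rss1 <- rss0 - slope^2 * sxx
  if (rss0 == 0 || rss1 <= .Machine$double.eps * rss0) {
    f <- if (rss0 == 0) 0 else Inf
    p <- if (rss0 == 0) 1 else 0
  } else {
    f <- (rss0 - rss1) / (rss1 / (n - 2))
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  list(slope = slope, intercept = mean(rho) - slope * mean(ages),
       f_stat = f, p = p, n = n)
}

#' Trend fits for many pairs with FDR control
#'
#' Vectorised [trend_fit()] over the rows of a pairs-by-ages correlation
#' matrix, with Benjamini-Hochberg correction across pairs.
#'
#' @param rho_mat numeric matrix, one row per pair, one column per age
#'   point.
#' @param ages numeric ages (one per column).
#' @param fdr_q FDR threshold for the `significant` flag (default 0.01).
#' @return data.frame(slope, f_stat, p, q, significant), one row per pair.
#' @export
trend_fit_many <- function(rho_mat, ages, fdr_q = 0.01) {
  stopifnot(is.matrix(rho_mat), ncol(rho_mat) == length(ages))
  if (ncol(rho_mat) < 3L) stop("need >= 3 age points")
  n <- ncol(rho_mat)
  xc <- ages - mean(ages)
  sxx <- sum(xc^2)
  ym <- rowMeans(rho_mat)
  yc <- rho_mat - ym
  slope <- as.vector(yc %*% xc) / sxx
  rss0 <- rowSums(yc^2)
  rss1 <- pmax(rss0 - slope^2 * sxx, 0)
  f <- ifelse(rss0 == 0, 0, (rss0 - rss1) / (rss1 / (n - 2)))
  p <- ifelse(rss0 == 0, 1, stats::pf(f, 1, n - 2, lower.tail = FALSE))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(slope = slope, f_stat = f, p = p, q = q,
             significant = q < fdr_q)
}

#' Spatial correlations of pairs per age group, with trend tests
#'
#' For each pair, the median spatial correlation is computed within every
#' age-group dataset; a linear trend across ages is then fitted per pair
#' and FDR-corrected across pairs.
#'
#' @param datasets named list of `expr_dataset`, one per age group, in age
#'   order.
#' @param pairs data.frame(gene_a, gene_b, ...).
#' @param ages numeric age assigned to each group (same length/order as
#'   `datasets`).
#' @param fdr_q FDR threshold.
#' @param ... passed to [spatial_correlation()].
#' @return data.frame(gene_a, gene_b, slope, f_stat, p, q, significant)
#'   with the pairs-by-ages correlation matrix in attribute `per_age_rho`.
#' @export
pair_trends <- function(datasets, pairs, ages, fdr_q = 0.01, ...) {
  stopifnot(is.list(datasets), length(datasets) == length(ages),
            length(datasets) >= 3L)
  mats <- lapply(datasets, function(d) pair_correlations(d, pairs, ...))
  rho_mat <- do.call(cbind, lapply(mats, `[[`, "median_rho"))
  colnames(rho_mat) <- names(datasets)
  tf <- trend_fit_many(rho_mat, ages, fdr_q = fdr_q)
  out <- cbind(mats[[1]][c("gene_a", "gene_b")], tf)
  attr(out, "per_age_rho") <- rho_mat
  out
}

#' Association of pair-level BRO scores with spatial-correlation strength
#'
#' The pair-level BRO score is the minimum of the two genes' BRO scores.
#' Reports its rank correlation with (i) the pairs' signed log-p of spatial
#' correlation, (ii) the anti-correlation magnitude |signed log-p| among
#' anti-correlated pairs, and (iii) the trend -log10 p when trend results
#' are supplied; plus a confound control: the same correlations computed
#' against a spatial-variability measure (the pair minimum of the genes'
#' expression SD across samples) when `gene_sd` is given.
#'
#' @param records pair table from [pair_correlations()] (columns `gene_a`,
#'   `gene_b`, `median_rho`, `signed_logp`).
#' @param bro BRO result table (`gene_id`, `bro`).
#' @param trends optional table from [pair_trends()] aligned with `records`
#'   (columns `p`).
#' @param gene_sd optional named numeric vector of per-gene expression SD.
#' @return data.frame(measure, rho, n, status) of Spearman associations.
#' @export
bro_vs_pairs <- function(records, bro, trends = NULL, gene_sd = NULL) {
  stopifnot(is.data.frame(records), is.data.frame(bro))
  if (nrow(records) < 10L) stop("need >= 10 pairs for a stable association")
  sc <- stats::setNames(bro$bro, bro$gene_id)
  miss <- setdiff(unique(c(records$gene_a, records$gene_b)), names(sc))
  if (length(miss)) stop("pair gene(s) missing from BRO table: ",
                         paste(miss, collapse = ", "))
  pair_bro <- pmin(sc[records$gene_a], sc[records$gene_b])
  assoc <- function(measure, x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 10L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(measure = measure, rho = NA_real_, n = sum(ok),
                        status = "undefined", stringsAsFactors = FALSE))
    }
    data.frame(measure = measure,
               rho = stats::cor(x[ok], y[ok], method = "spearman"),
               n = sum(ok), status = "ok", stringsAsFactors = FALSE)
  }
  out <- rbind(
    assoc("signed_logp_vs_pair_bro", pair_bro, records$signed_logp),
    {
      anti <- !is.na(records$median_rho) & records$median_rho < 0
      assoc("anticorrelation_magnitude_vs_pair_bro", pair_bro[anti],
            abs(records$signed_logp[anti]))
    })
  if (!is.null(trends)) {
    out <- rbind(out, assoc("trend_logp_vs_pair_bro", pair_bro,
                            -log10(pmax(trends$p, 1e-300))))
  }
  if (!is.null(gene_sd)) {
    pair_sd <- pmin(gene_sd[records$gene_a], gene_sd[records$gene_b])
    out <- rbind(out, assoc("signed_logp_vs_pair_sd", pair_sd,
                            records$signed_logp))
  }
  out
}
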