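#' Construct an expression dataset
#'
#' Container for a gene-by-sample matrix of (log-scale) expression values
#' plus per-sample annotations: region of origin, donor, and optionally an
#' ordered age-group label. Expression is assumed already log-scaled and
#' positive; no transform is applied.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `region_id`,
#'   `donor_id` and optionally `age_group`. Column order of `values` is
#'   aligned to `samples$sample_id`.
#' @param ont optional `region_ontology`; when given, every `region_id` must
#'   exist in it.
#' @param impute_missing mean-impute missing values per gene (default FALSE:
#'   missingness is rejected).
#' @return object of class `expr_dataset`: list(values, samples).
#' @export
expression_dataset <- function(values, samples, ont = NULL,
                               impute_missing = FALSE) {
  stopifnot(is.matrix(values), is.data.frame(samples))
  req <- c("sample_id", "region_id", "donor_id")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)
  samples$sample_id <- as.character(samples$sample_id)
  samples$region_id <- as.character(samples$region_id)
  samples$donor_id <- as.character(samples$donor_id)
  if (is.null(samples$age_group)) samples$age_group <- NA_character_
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup)) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  orphans <- setdiff(colnames(values), samples$sample_id)
  if (length(orphans)) stop("matrix column(s) absent from metadata: ",
                            paste(orphans, collapse = ", "))
  absent <- setdiff(samples$sample_id, colnames(values))
  if (length(absent)) stop("metadata sample(s) absent from matrix: ",
                           paste(absent, collapse = ", "))
  values <- values[, samples$sample_id, drop = FALSE]
  if (anyNA(values)) {
    if (!impute_missing) stop("expression matrix contains ",
                              sum(is.na(values)), " missing values")
    n_imp <- sum(is.na(values))
    mu <- rowMeans(values, na.rm = TRUE)
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- mu[idx[, 1]]
    message("mean-imputed ", n_imp, " missing values")
  }
  if (!is.null(ont)) {
    bad <- setdiff(unique(samples$region_id), region_ids(ont))
    if (length(bad)) stop("unknown region id(s) in metadata: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(values = values, samples = samples), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("expr_dataset:", nrow(x$values), "genes x", ncol(x$values), "samples |",
      length(unique(x$samples$region_id)), "regions,",
      length(unique(x$samples$donor_id)), "donors\n")
  invisible(x)
}

#' Number of genes / samples in a dataset
#' @param ds an `expr_dataset`.
#' @return integer count.
#' @export
n_genes <- function(ds) nrow(ds$values)

#' @rdname n_genes
#' @export
n_samples <- function(ds) ncol(ds$values)

#' Load an expression dataset from delimited files
#'
#' The matrix file has gene ids in the first column and one column per
#' sample; the metadata file has columns `sample_id  region_id  donor_id`
#' and optionally `age_group`. Matrix columns and metadata sample ids must
#' agree as sets; samples are ordered as in the metadata.
#'
#' @param matrix_path path to the expression table.
#' @param metadata_path path to the sample metadata table.
#' @param ont optional `region_ontology` used to validate region ids.
#' @param sep field separator.
#' @param impute_missing see [expression_dataset()].
#' @return an `expr_dataset`.
#' @export
load_expression <- function(matrix_path, metadata_path, ont = NULL,
                            sep = "\t", impute_missing = FALSE) {
  tab <- utils::read.delim(matrix_path, sep = sep, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  meta <- utils::read.delim(metadata_path, sep = sep, comment.char = "#",
                            colClasses = "character", check.names = FALSE,
                            stringsAsFactors = FALSE)
  ds <- expression_dataset(vals, meta, ont = ont,
                           impute_missing = impute_missing)
  message("loaded ", n_genes(ds), " genes, ", n_samples(ds), " samples, ",
          length(unique(ds$samples$region_id)), " regions, ",
          length(unique(ds$samples$donor_id)), " donors")
  ds
}

#' Write an expression dataset to delimited files
#'
#' Writers emit a stable column order and a fixed float format (default 6
#' significant digits), so identical datasets produce byte-identical files.
#'
#' @param ds an `expr_dataset`.
#' @param matrix_path,metadata_path output paths.
#' @param sep field separator.
#' @param digits significant digits for expression values.
#' @export
write_expression <- function(ds, matrix_path, metadata_path, sep = "\t",
                             digits = 6) {
  stopifnot(inherits(ds, "expr_dataset"))
  fmt <- formatC(ds$values, digits = digits, format = "g")
  tab <- data.frame(gene_id = rownames(ds$values), fmt, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c("gene_id", colnames(ds$values))
  utils::write.table(tab, matrix_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  meta <- ds$samples[c("sample_id", "region_id", "donor_id", "age_group")]
  meta$age_group[is.na(meta$age_group)] <- ""
  utils::write.table(meta, metadata_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' Collapse probes to genes by cross-donor consistency
#'
#' For a gene measured by several probes, each probe's expression is averaged
#' per (region, donor); for every donor pair the two donors' region profiles
#' are rank-correlated over shared regions; the probe with the highest mean
#' pairwise correlation is kept (ties broken by the lexicographically
#' smallest probe id). Single-probe genes pass through unchanged.
#'
#' @param probe_values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`; every
#'   probe maps to exactly one gene.
#' @param samples sample metadata as for [expression_dataset()]; needs >= 2
#'   donors.
#' @param ont optional ontology for validation of the returned dataset.
#' @return an `expr_dataset` with one row per distinct gene, plus a
#'   `probe_selection` attribute recording the winning probe and its score.
#' @export
collapse_probes <- function(probe_values, probe_map, samples, ont = NULL) {
  stopifnot(is.matrix(probe_values), is.data.frame(probe_map))
  probe_map <- data.frame(probe_id = as.character(probe_map$probe_id),
                          gene_id = as.character(probe_map$gene_id),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(probe_map$probe_id))
    stop("a probe maps to more than one gene")
  miss <- setdiff(probe_map$probe_id, rownames(probe_values))
  if (length(miss)) stop("probe(s) missing from matrix: ",
                         paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)
  donors <- unique(as.character(samples$donor_id))
  if (length(donors) < 2L) stop("probe collapse requires >= 2 donors")
  probe_values <- probe_values[probe_map$probe_id, samples$sample_id,
                               drop = FALSE]

  # per-probe mean profile over (region, donor) cells
  grp <- interaction(samples$region_id, samples$donor_id, drop = TRUE,
                     sep = "\r")
  sums <- rowsum(t(probe_values), grp)
  cnt <- as.vector(table(grp)[rownames(sums)])
  cell_means <- t(sums / cnt)
  cell_region <- sub("\r.*$", "", colnames(cell_means))
  cell_donor <- sub("^.*\r", "", colnames(cell_means))

  probe_consistency <- function(p) {
    prof <- cell_means[p, ]
    cc <- utils::combn(donors, 2L)
    vals <- apply(cc, 2L, function(dd) {
      r1 <- cell_region[cell_donor == dd[1]]
      r2 <- cell_region[cell_donor == dd[2]]
      shared <- intersect(r1, r2)
      if (length(shared) < 3L) return(NA_real_)
      x <- prof[cell_donor == dd[1]][match(shared, r1)]
      y <- prof[cell_donor == dd[2]][match(shared, r2)]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y, method = "spearman")
    })
    mean(vals, na.rm = TRUE)
  }

  gene_ids <- unique(probe_map$gene_id)
  sel <- character(length(gene_ids))
  score <- rep(NA_real_, length(gene_ids))
  for (k in seq_along(gene_ids)) {
    probes <- sort(probe_map$probe_id[probe_map$gene_id == gene_ids[k]])
    if (length(probes) == 1L) {
      sel[k] <- probes
      next
    }
    sc <- vapply(probes, probe_consistency, numeric(1))
    if (all(is.nan(sc) | is.na(sc))) {
      warning("gene ", gene_ids[k],
              ": no probe has cross-donor variance; keeping first probe")
      sel[k] <- probes[1]
    } else {
      sc[is.nan(sc)] <- -Inf
      sel[k] <- probes[which.max(sc)]  # ties: first in sorted id order
      score[k] <- max(sc, na.rm = TRUE)
    }
  }
  vals <- probe_values[sel, , drop = FALSE]
  rownames(vals) <- gene_ids
  ds <- expression_dataset(vals, samples, ont = ont)
  attr(ds, "probe_selection") <- data.frame(
    gene_id = gene_ids, probe_id = sel, mean_pair_cor = score,
    stringsAsFactors = FALSE)
  ds
}

#' Default highly-stable (housekeeping) gene set
#'
#' Eleven genes with highly stable expression across tissues, usable as the
#' reference set for `normalize_samples(mode = "stable_genes")`.
#' @format character vector of 11 gene symbols.
#' @export
stable_genes_default <- c("C1orf43", "CHMP2A", "EMC7", "GPI", "PSMB2",
                          "PSMB4", "RAB7A", "REEP5", "SNRPD3", "VCP", "VPS29")

#' Scale samples by their mean expression
#'
#' Controls for tissue-wide effects (sampling fluctuations, cell-density
#' bias): each sample is divided by its mean expression over all genes, or
#' over a set of highly-stable genes. The report carries each sample's scale
#' factor and their coefficient of variation (CV = sd/mean).
#'
#' @param ds an `expr_dataset` (positive-scale expression).
#' @param mode `"sample_mean"` (mean over all genes) or `"stable_genes"`.
#' @param stable_set gene ids for `stable_genes` mode (default
#'   [stable_genes_default]); must be a subset of the dataset genes.
#' @return list(dataset = scaled `expr_dataset`,
#'   scale_report = data.frame(sample_id, scale_factor), cv = numeric).
#' @export
normalize_samples <- function(ds, mode = c("sample_mean", "stable_genes"),
                              stable_set = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  mode <- match.arg(mode)
  if (mode == "stable_genes") {
    if (is.null(stable_set)) stable_set <- stable_genes_default
    miss <- setdiff(stable_set, rownames(ds$values))
    if (length(miss)) stop("stable gene(s) not in dataset: ",
                           paste(miss, collapse = ", "))
    sf <- colMeans(ds$values[stable_set, , drop = FALSE])
  } else {
    sf <- colMeans(ds$values)
  }
  if (any(sf <= 0)) stop("sample(s) with non-positive mean expression: ",
                         paste(names(sf)[sf <= 0], collapse = ", "))
  out <- ds
  out$values <- sweep(ds$values, 2L, sf, "/")
  list(dataset = out,
       scale_report = data.frame(sample_id = colnames(ds$values),
                                 scale_factor = unname(sf),
                                 stringsAsFactors = FALSE),
       cv = stats::sd(sf) / mean(sf))
}

#' Subset samples by region, donor and/or age group
#'
#' Region selection includes the whole subtree below each named region when
#' `subtree = TRUE` (requires `ont`), so e.g. excluding the cerebellum node
#' removes every cerebellar sample.
#'
#' @param ds an `expr_dataset`.
#' @param regions,donors,age_groups label sets (NULL = no constraint).
#' @param exclude drop matching samples instead of keeping them.
#' @param ont `region_ontology`, needed when `subtree = TRUE` and `regions`
#'   given.
#' @param subtree expand `regions` to their ontology subtrees (default TRUE).
#' @return an `expr_dataset` with filtered samples (genes unchanged).
#' @export
subset_samples <- function(ds, regions = NULL, donors = NULL,
                           age_groups = NULL, exclude = FALSE, ont = NULL,
                           subtree = TRUE) {
  stopifnot(inherits(ds, "expr_dataset"))
  sm <- ds$samples
  if (!is.null(regions)) {
    regions <- as.character(regions)
    if (subtree) {
      if (is.null(ont)) stop("subtree = TRUE requires an ontology")
      regions <- unique(unlist(lapply(regions, descendants, ont = ont)))
    }
  }
  hit <- rep(TRUE, nrow(sm))
  if (!is.null(regions)) hit <- hit & sm$region_id %in% regions
  if (!is.null(donors)) hit <- hit & sm$donor_id %in% donors
  if (!is.null(age_groups)) hit <- hit & sm$age_group %in% age_groups
  keep <- if (exclude) !hit else hit
  if (!any(keep)) stop("no samples remain after subsetting")
  out <- ds
  out$samples <- sm[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  out$values <- ds$values[, keep, drop = FALSE]
  out
}

#' Average samples into one profile per region
#'
#' @param ds an `expr_dataset`.
#' @return numeric matrix, genes x regions (only regions with >= 1 sample),
#'   columns in lexicographic region-id order.
#' @export
average_by_region <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  reg <- factor(ds$samples$region_id)
  sums <- rowsum(t(ds$values), reg)
  cnt <- as.vector(table(reg)[rownames(sums)])
  prof <- t(sums / cnt)
  prof[, sort(colnames(prof)), drop = FALSE]
}
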