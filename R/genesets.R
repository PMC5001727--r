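#' Read gene sets from a plain-text file
#'
#' Format: one gene id per line; a line starting with `#name:` opens a new
#' named set (several sets may share a file). Genes are deduplicated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  sets <- list()
  current <- "set1"
  for (ln in lines) {
    if (startsWith(ln, "#name:")) {
      current <- trimws(sub("^#name:", "", ln))
    } else if (!startsWith(ln, "#")) {
      sets[[current]] <- c(sets[[current]], ln)
    }
  }
  lapply(sets, unique)
}

#' Compare BRO-score distributions of gene sets against a background
#'
#' For each set, a rank-sum (Wilcoxon / Mann-Whitney) test compares the BRO
#' scores of set genes against the background (all scored genes, or the
#' complement of the set). Used to ask whether e.g. neuron-specific markers,
#' axon-guidance genes or evolutionary-age classes agree with the region
#' ontology more than the average gene. Also reports the fraction of set
#' genes carrying the table's significance flag, when present.
#'
#' @param bro a BRO result table with columns `gene_id`, `bro` (and
#'   optionally a logical significance column named by `flag`).
#' @param sets named list of gene-id vectors (see [read_gene_sets()]).
#' @param background `"all_genes"` or `"complement"`.
#' @param tail `"one"` (set greater than background) or `"two"`.
#' @param flag name of the logical column used for
#'   `fraction_significant_in_set` (default `"significant_fdr"` if present).
#' @return data.frame(set_name, n_in_data, median_in_set, median_background,
#'   wilcoxon_p, fraction_significant_in_set, status).
#' @export
compare_gene_sets <- function(bro, sets,
                              background = c("all_genes", "complement"),
                              tail = c("one", "two"), flag = NULL) {
  background <- match.arg(background)
  tail <- match.arg(tail)
  stopifnot(is.data.frame(bro), all(c("gene_id", "bro") %in% names(bro)))
  if (is.null(flag) && "significant_fdr" %in% names(bro)) {
    flag <- "significant_fdr"
  }
  bro <- bro[!is.na(bro$bro), ]
  scores <- stats::setNames(bro$bro, bro$gene_id)
  alt <- if (tail == "one") "greater" else "two.sided"
  rows <- lapply(names(sets), function(nm) {
    g <- intersect(sets[[nm]], names(scores))
    if (!length(g)) {
      return(data.frame(set_name = nm, n_in_data = 0L,
                        median_in_set = NA_real_,
                        median_background = NA_real_, wilcoxon_p = NA_real_,
                        fraction_significant_in_set = NA_real_,
                        status = "no overlap", stringsAsFactors = FALSE))
    }
    bg <- if (background == "complement") {
      setdiff(names(scores), g)
    } else {
      names(scores)
    }
    p <- if (length(bg)) {
      stats::wilcox.test(scores[g], scores[bg],
                         alternative = alt, exact = NULL)$p.value
    } else NA_real_
    frac <- if (!is.null(flag)) {
      fl <- stats::setNames(bro[[flag]], bro$gene_id)
      mean(fl[g], na.rm = TRUE)
    } else NA_real_
    data.frame(set_name = nm, n_in_data = length(g),
               median_in_set = stats::median(scores[g]),
               median_background = stats::median(scores[bg]),
               wilcoxon_p = p, fraction_significant_in_set = frac,
               status = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Explained variance of a gene from cell-type marker expression
#'
#' Least-squares fit of the target gene's expression across samples on each
#' marker's expression and its square (no cross-terms); R^2 is reported
#' against the constant model. Probes how much of a gene's spatial
#' variability is accounted for by cell-type composition as proxied by
#' marker genes.
#'
#' @param ds an `expr_dataset`.
#' @param target_gene gene id to explain.
#' @param markers character vector of marker gene ids (all present in the
#'   dataset).
#' @return list(r2, n_predictors, rank_deficient): `rank_deficient` flags a
#'   collinear design, solved by minimum-norm least squares (SVD
#'   pseudoinverse).
#' @export
marker_explained_variance <- function(ds, target_gene, markers) {
  stopifnot(inherits(ds, "expr_dataset"))
  miss <- setdiff(c(target_gene, markers), rownames(ds$values))
  if (length(miss)) stop("gene(s) not in dataset: ",
                         paste(miss, collapse = ", "))
  y <- ds$values[target_gene, ]
  M <- t(ds$values[markers, , drop = FALSE])
  X <- cbind(1, M, M^2)
  n <- length(y)
  if (n < ncol(X) + 1L) {
    stop("need >= ", ncol(X) + 1L, " samples for ", ncol(X), " predictors")
  }
  qx <- qr(X)
  deficient <- qx$rank < ncol(X)
  if (deficient) {
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    res <- y - as.vector(X %*% coef)
  } else {
    res <- qr.resid(qx, y)
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(list(r2 = NA_real_, n_predictors = ncol(X) - 1L,
                            rank_deficient = deficient))
  list(r2 = max(0, 1 - sum(res^2) / tss), n_predictors = ncol(X) - 1L,
       rank_deficient = deficient)
}

#' Combine BRO scores from two datasets into one ranked list
#'
#' Per-gene product of the two scores over the intersected gene universe,
#' ranked descending -- a robust combined ranking suitable for external
#' enrichment tools.
#'
#' @param bro_a,bro_b BRO result tables (`gene_id`, `bro`).
#' @return data.frame(gene_id, bro_a, bro_b, combined) sorted by descending
#'   `combined`; the number of dropped genes is reported via a message.
#' @export
combined_score <- function(bro_a, bro_b) {
  a <- bro_a[!is.na(bro_a$bro), c("gene_id", "bro")]
  b <- bro_b[!is.na(bro_b$bro), c("gene_id", "bro")]
  shared <- intersect(a$gene_id, b$gene_id)
  if (!length(shared)) stop("empty gene-universe intersection")
  dropped <- length(union(a$gene_id, b$gene_id)) - length(shared)
  if (dropped > 0) message(dropped, " gene(s) missing in one dataset dropped")
  out <- data.frame(
    gene_id = shared,
    bro_a = a$bro[match(shared, a$gene_id)],
    bro_b = b$bro[match(shared, b$gene_id)],
    stringsAsFactors = FALSE)
  out$combined <- out$bro_a * out$bro_b
  out <- out[order(-out$combined, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Write a ranked gene list
#'
#' Single-column file of gene ids in ranking order (consumable by external
#' enrichment services).
#'
#' @param ranked data.frame from [combined_score()] (or any table with
#'   `gene_id` already in rank order).
#' @param path output path.
#' @export
write_ranked_list <- function(ranked, path) {
  writeLines(ranked$gene_id, path)
  invisible(path)
}
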