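#' Construct a region ontology from a region table
#'
#' A region ontology is a rooted tree of brain regions. The upper levels of
#' the real Allen-style hierarchy follow the embryonic vesicle divisions
#' (telencephalon, diencephalon, mesencephalon, metencephalon,
#' myelencephalon); lower levels follow cytoarchitecture. All tree distances
#' used by the BRO-agreement score are edge counts on this tree.
#'
#' @param regions data.frame with columns `region_id`, `parent_id`, `name`,
#'   `acronym`. Exactly one row must have an empty/NA `parent_id` (the root).
#' @return An object of class `region_ontology`: the validated region table
#'   plus cached node depths and the full region-by-region edge-count
#'   distance matrix.
#' @export
region_ontology <- function(regions) {
  stopifnot(is.data.frame(regions))
  req <- c("region_id", "parent_id", "name", "acronym")
  miss <- setdiff(req, names(regions))
  if (length(miss)) {
    stop("ontology table is missing column(s): ", paste(miss, collapse = ", "))
  }
  regions <- as.data.frame(regions)[req]
  regions$region_id <- as.character(regions$region_id)
  regions$parent_id <- as.character(regions$parent_id)
  regions$name <- as.character(regions$name)
  regions$acronym <- as.character(regions$acronym)
  regions$parent_id[!is.na(regions$parent_id) & !nzchar(regions$parent_id)] <-
    NA_character_

  id <- regions$region_id
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate region_id(s): ", paste(dup, collapse = ", "))
  }
  root_rows <- which(is.na(regions$parent_id))
  if (length(root_rows) == 0L) stop("no root region (empty parent_id) found")
  if (length(root_rows) > 1L) {
    stop("multiple roots (rows ", paste(root_rows, collapse = ", "),
         "): ", paste(id[root_rows], collapse = ", "))
  }
  unknown <- setdiff(stats::na.omit(regions$parent_id), id)
  if (length(unknown)) {
    bad <- which(regions$parent_id %in% unknown)
    stop("missing parent: row(s) ", paste(bad, collapse = ", "),
         " reference unknown parent_id(s) ", paste(unknown, collapse = ", "))
  }

  n <- length(id)
  idx <- stats::setNames(seq_len(n), id)
  pidx <- ifelse(is.na(regions$parent_id), NA_integer_,
                 idx[regions$parent_id])

  # depths by repeated relaxation; nodes left unresolved sit on a cycle
  depth <- rep(NA_integer_, n)
  depth[root_rows] <- 0L
  for (iter in seq_len(n)) {
    todo <- which(is.na(depth) & !is.na(depth[pidx]))
    if (!length(todo)) break
    depth[todo] <- depth[pidx[todo]] + 1L
  }
  if (anyNA(depth)) {
    bad <- which(is.na(depth))
    stop("cycle or disconnected subgraph involving region(s): ",
         paste(id[bad], collapse = ", "))
  }

  # anc[i, j] is TRUE when j is an ancestor of i or i itself; because
  # root-paths are nested chains, the common count of two rows is
  # depth(LCA) + 1, giving d(a,b) = depth(a) + depth(b) + 2 - 2 * common.
  anc <- diag(n) > 0
  for (i in order(depth)) {
    if (!is.na(pidx[i])) anc[i, ] <- anc[i, ] | anc[pidx[i], ]
  }
  common <- tcrossprod(anc * 1)
  d <- outer(depth, depth, "+") + 2L - 2L * common
  storage.mode(d) <- "integer"
  dimnames(d) <- list(id, id)
  dimnames(anc) <- list(id, id)

  structure(
    list(regions = regions, root = id[root_rows], depth = stats::setNames(depth, id),
         dist = d, anc = anc),
    class = "region_ontology"
  )
}

#' Read a region ontology from a delimited table
#'
#' Expected header: `region_id  parent_id  name  acronym` (tab-separated by
#' default); an empty `parent_id` marks the root. Row order is irrelevant.
#'
#' @param path file path.
#' @param sep field separator.
#' @return A [region_ontology()].
#' @export
parse_ontology <- function(path, sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, colClasses = "character",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  region_ontology(tab)
}

#' Write a region ontology to a delimited table
#'
#' Inverse of [parse_ontology()]; round-trips exactly.
#'
#' @param ont a `region_ontology`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_ontology <- function(ont, path, sep = "\t") {
  stopifnot(inherits(ont, "region_ontology"))
  tab <- ont$regions
  tab$parent_id[is.na(tab$parent_id)] <- ""
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.region_ontology <- function(x, ...) {
  cat("region_ontology:", nrow(x$regions), "regions, root =", x$root,
      ", max depth =", max(x$depth), "\n")
  invisible(x)
}

#' Region identifiers of an ontology
#' @param ont a `region_ontology`.
#' @return character vector of region ids.
#' @export
region_ids <- function(ont) {
  stopifnot(inherits(ont, "region_ontology"))
  ont$regions$region_id
}

#' Tree distance between regions (edge count)
#'
#' Length of the unique path between two regions in the ontology tree; this
#' is the "ontology distance" entering the BRO-agreement score. Vectorised
#' over `a` and `b`.
#'
#' @param ont a `region_ontology`.
#' @param a,b region ids (recycled to common length).
#' @return integer vector of edge counts; 0 iff `a == b`.
#' @export
tree_distance <- function(ont, a, b) {
  stopifnot(inherits(ont, "region_ontology"))
  a <- as.character(a)
  b <- as.character(b)
  bad <- setdiff(unique(c(a, b)), region_ids(ont))
  if (length(bad)) stop("unknown region id(s): ", paste(bad, collapse = ", "))
  n <- max(length(a), length(b))
  ont$dist[cbind(rep_len(a, n), rep_len(b, n))]
}

#' Full region-by-region distance matrix
#' @param ont a `region_ontology`.
#' @return integer matrix of pairwise edge counts (region ids as dimnames).
#' @export
region_distance_matrix <- function(ont) {
  stopifnot(inherits(ont, "region_ontology"))
  ont$dist
}

#' Descendants of a region
#'
#' @param ont a `region_ontology`.
#' @param id region id.
#' @param include_self include `id` itself (default TRUE).
#' @return character vector of region ids in the subtree rooted at `id`.
#' @export
descendants <- function(ont, id, include_self = TRUE) {
  stopifnot(inherits(ont, "region_ontology"))
  id <- as.character(id)
  if (!id %in% region_ids(ont)) stop("unknown region id: ", id)
  out <- region_ids(ont)[ont$anc[, id]]
  if (!include_self) out <- setdiff(out, id)
  out
}

#' Prune an ontology to a subset of regions
#'
#' Each kept region is re-parented to its nearest kept proper ancestor, so
#' the analysis can run at a coarser granularity (e.g. the 16 gross regions
#' of a fine hierarchy). Distances are recomputed on the pruned tree.
#'
#' @param ont a `region_ontology`.
#' @param keep character vector of region ids to retain.
#' @return A `region_ontology` over `keep`.
#' @export
prune_to_regions <- function(ont, keep) {
  stopifnot(inherits(ont, "region_ontology"))
  keep <- unique(as.character(keep))
  bad <- setdiff(keep, region_ids(ont))
  if (length(bad)) stop("unknown region id(s): ", paste(bad, collapse = ", "))
  reg <- ont$regions
  rownames(reg) <- reg$region_id
  parent_of <- stats::setNames(reg$parent_id, reg$region_id)
  new_parent <- vapply(keep, function(r) {
    p <- parent_of[[r]]
    while (!is.na(p) && !(p %in% keep)) p <- parent_of[[p]]
    if (is.na(p)) NA_character_ else p
  }, character(1))
  if (sum(is.na(new_parent)) != 1L) {
    stop("pruned region set induces ", sum(is.na(new_parent)),
         " roots; exactly one region may lack a kept ancestor")
  }
  out <- reg[keep, ]
  out$parent_id <- unname(new_parent)
  rownames(out) <- NULL
  region_ontology(out)
}

#' Convert an ontology to an ape \code{phylo} tree
#'
#' Leaves are regions without children; internal regions become labelled
#' internal nodes. Unit edge lengths, so cophenetic path lengths equal tree
#' distances.
#'
#' @param ont a `region_ontology`.
#' @return An object of class `phylo`.
#' @export
ontology_phylo <- function(ont) {
  stopifnot(inherits(ont, "region_ontology"))
  reg <- ont$regions
  id <- reg$region_id
  has_child <- id %in% stats::na.omit(reg$parent_id)
  tips <- id[!has_child]
  internal <- id[has_child]
  # ape numbering: tips 1..Ntip, then internal nodes with the root first
  internal <- c(ont$root, setdiff(internal, ont$root))
  num <- stats::setNames(c(seq_along(tips), length(tips) + seq_along(internal)),
                         c(tips, internal))
  child <- id[!is.na(reg$parent_id)]
  edge <- cbind(num[reg$parent_id[!is.na(reg$parent_id)]], num[child])
  dimnames(edge) <- NULL
  tr <- structure(
    list(edge = edge, tip.label = tips, node.label = internal,
         Nnode = length(internal), edge.length = rep(1, nrow(edge))),
    class = "phylo"
  )
  ape::reorder.phylo(tr, "cladewise")
}

#' Export an ontology as a Newick string
#' @param ont a `region_ontology`.
#' @return single Newick string (semicolon-terminated).
#' @export
ontology_newick <- function(ont) {
  ape::write.tree(ontology_phylo(ont))
}
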