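# Independent oracles and small fixture builders shared across test files.

# mid-rank vector built by explicit position averaging (no rank())
oracle_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Pearson correlation from the sum formulas (no stats::cor)
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# brute-force Spearman: explicit mid-ranks + Pearson-on-ranks
oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midranks(x), oracle_midranks(y))
}

# exhaustive triplet agreement score over all ordered triplets
oracle_triplet_exhaustive <- function(ds, ont, gene) {
  n <- n_samples(ds)
  D <- region_distance_matrix(ont)
  ridx <- match(ds$samples$region_id, rownames(D))
  x <- ds$values[gene, ]
  num <- 0L
  den <- 0L
  for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
    if (a == b || a == cc || b == cc) next
    dt_ab <- D[ridx[a], ridx[b]]
    dt_ac <- D[ridx[a], ridx[cc]]
    if (dt_ab >= dt_ac) next
    den <- den + 1L
    if (abs(x[a] - x[b]) < abs(x[a] - x[cc])) num <- num + 1L
  }
  num / den
}

# BFS tree distances on the undirected ontology graph (igraph oracle)
oracle_tree_distances <- function(ont) {
  reg <- ont$regions
  edges <- reg[!is.na(reg$parent_id), c("parent_id", "region_id")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = reg$region_id)
  d <- igraph::distances(g)
  d[reg$region_id, reg$region_id]
}

# random rooted tree as a region table (root "n1")
random_region_table <- function(n_nodes, seed) {
  set.seed(seed)
  ids <- paste0("n", seq_len(n_nodes))
  parent <- c(NA_character_,
              vapply(2:n_nodes, function(i) ids[sample.int(i - 1L, 1L)],
                     character(1)))
  data.frame(region_id = ids, parent_id = parent,
             name = paste("node", ids), acronym = ids,
             stringsAsFactors = FALSE)
}

# small hand-built ontology: root with two arms of two levels
toy_ontology <- function() {
  region_ontology(data.frame(
    region_id = c("root", "L", "R", "L1", "L2", "R1", "R2"),
    parent_id = c("", "root", "root", "L", "L", "R", "R"),
    name = paste("n", 1:7), acronym = paste0("a", 1:7),
    stringsAsFactors = FALSE))
}

# dataset with explicit values on a chosen ontology
toy_dataset <- function(values, regions, donors = "d1", ont = NULL,
                        age = NA_character_) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(nrow(values)))
  expression_dataset(values, data.frame(
    sample_id = colnames(values),
    region_id = rep_len(regions, n),
    donor_id = rep_len(donors, n),
    age_group = rep_len(age, n),
    stringsAsFactors = FALSE), ont = ont)
}

# path-tree dataset where expression equals position, so expression and
# tree distances agree exactly
path_tree_world <- function(n = 5) {
  ids <- paste0("p", seq_len(n))
  ont <- region_ontology(data.frame(
    region_id = ids, parent_id = c("", ids[-n]),
    name = ids, acronym = ids, stringsAsFactors = FALSE))
  vals <- matrix(as.numeric(seq_len(n)), 1, n,
                 dimnames = list("g1", paste0("s", seq_len(n))))
  list(ont = ont, ds = toy_dataset(vals, regions = ids, ont = ont))
}
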