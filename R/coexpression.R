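# Ortholog mapping and co-expression networks ------------------------------

#' Map orthologs from a tabular alignment file
#'
#' Reads a 12-column tabular alignment (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score) or any table with query/subject/score
#' columns, filters hits at the score threshold and keeps one best subject
#' per query (highest score, ties broken lexicographically by subject id).
#'
#' @param alignment_table path to a TSV, or a data frame.
#' @param score_threshold minimum score for a hit to count (default 70).
#' @param score_col column holding the score; by default the 12th (bit
#'   score) of the tabular dialect, or a column named `score`/`bitscore`.
#' @return data frame (class `ortholog_map`) with `query_id`, `subject_id`,
#'   `score`; attribute `n_skipped` counts malformed rows.
#' @export
map_orthologs <- function(alignment_table, score_threshold = 70,
                          score_col = NULL) {
  if (is.character(alignment_table) && length(alignment_table) == 1L) {
    raw <- tryCatch(
      read.table(alignment_table, header = FALSE, sep = "\t",
                 stringsAsFactors = FALSE, fill = TRUE,
                 colClasses = "character"),
      error = function(e) data.frame())
  } else raw <- as.data.frame(alignment_table)
  empty <- structure(data.frame(query_id = character(0),
                                subject_id = character(0),
                                score = numeric(0)),
                     class = c("ortholog_map", "data.frame"),
                     n_skipped = 0L)
  if (!nrow(raw)) return(empty)
  if (is.null(score_col)) {
    nm <- intersect(c("score", "bitscore"), names(raw))
    score_col <- if (length(nm)) nm[1L] else min(12L, ncol(raw))
  }
  score <- suppressWarnings(as.numeric(raw[[score_col]]))
  qs <- as.character(raw[[1L]])
  ss <- as.character(raw[[2L]])
  bad <- is.na(score) | is.na(qs) | is.na(ss) | qs == "" | ss == ""
  n_skipped <- sum(bad)
  tab <- data.frame(query_id = qs[!bad], subject_id = ss[!bad],
                    score = score[!bad], stringsAsFactors = FALSE)
  tab <- tab[tab$score >= score_threshold, , drop = FALSE]
  if (nrow(tab)) {
    tab <- tab[order(tab$query_id, -tab$score, tab$subject_id), ]
    tab <- tab[!duplicated(tab$query_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, class = c("ortholog_map", "data.frame"),
            n_skipped = n_skipped)
}

#' Build a Pearson co-expression network
#'
#' Computes all pairwise Pearson correlations within the supplied gene set
#' (depth-0 search: no expansion to outside neighbours), draws an edge
#' wherever the absolute correlation reaches the threshold, and partitions
#' the nodes into connected components.  Genes with constant expression
#' have undefined correlation and are excluded with a warning.
#'
#' @param expr numeric matrix, rows = genes, columns = observations
#'   (>= 3 observations).
#' @param threshold minimum `|r|` for an edge (default 0.65).
#' @return object of class `coexpression_network`: list with `nodes`,
#'   `edges` (data frame `from`, `to`, `r`), `membership` (component id per
#'   node), `component_sizes` (descending) and the correlation matrix `r`.
#' @export
pearson_network <- function(expr, threshold = 0.65) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3L, !is.null(rownames(expr)))
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant-expression gene(s) excluded: ",
            paste(head(rownames(expr)[sds == 0], 5L), collapse = ", "))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  genes <- rownames(expr)
  r <- cor(t(expr))
  adj <- abs(r) >= threshold
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = genes[idx[, 1L]], to = genes[idx[, 2L]],
                      r = r[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genes)
  comp <- igraph::components(g)
  sizes <- sort(comp$csize, decreasing = TRUE)
  structure(list(nodes = genes, edges = edges,
                 membership = comp$membership,
                 component_sizes = sizes, r = r,
                 threshold = threshold),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("Co-expression network (|r| >=", x$threshold, "):",
      length(x$nodes), "nodes,", nrow(x$edges), "edges,",
      length(x$component_sizes), "components\n")
  cat("Component sizes:",
      paste(head(x$component_sizes, 10L), collapse = ", "), "\n")
  invisible(x)
}

#' Write network edge list and components
#'
#' @param net a `coexpression_network`.
#' @param edges_path edge-list TSV path.
#' @param components_path optional components TSV path.
#' @export
write_network <- function(net, edges_path, components_path = NULL) {
  write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(components_path)) {
    write.table(data.frame(gene_id = names(net$membership),
                           component = as.integer(net$membership)),
                components_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(edges_path)
}

#' Average-linkage correlation tree in Newick format
#'
#' Clusters genes by average linkage on the correlation distance
#' `d = 1 - r` (optionally `1 - |r|`) and returns a Newick string with
#' branch lengths.  A single node yields a trivial one-leaf tree.
#'
#' @param x a `coexpression_network` or a correlation matrix.
#' @param absolute use `1 - |r|` instead of `1 - r` (default `FALSE`, so
#'   anti-correlated genes stay far apart).
#' @return Newick string (terminated by `;`).
#' @export
cluster_tree <- function(x, absolute = FALSE) {
  r <- if (inherits(x, "coexpression_network")) x$r else x
  stopifnot(is.matrix(r))
  if (nrow(r) == 1L) return(paste0(rownames(r)[1L], ";"))
  d <- if (absolute) 1 - abs(r) else 1 - r
  hc <- hclust(as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}
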