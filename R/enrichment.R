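# GO enrichment with randomization FDR -------------------------------------
#
# One-sided hypergeometric enrichment per term, followed by an FDR estimate
# obtained by redrawing random gene sets of the query's size from the
# universe: FDR(term) = E[# terms reaching p <= p_obs by chance] divided by
# the observed count of terms at that level, capped at 1.

#' Build a GO annotation object
#'
#' @param mapping data frame with columns `term_id`, `gene_id` (one row per
#'   annotation), or a path to such a two-column TSV.
#' @param term_names optional named character vector (term id -> name).
#' @param universe gene universe; defaults to all annotated genes.  Terms
#'   with no universe gene are excluded.
#' @return object of class `go_annotation`: list with `terms` (named list of
#'   gene-id vectors), `names`, `universe`.
#' @export
go_annotation <- function(mapping, term_names = NULL, universe = NULL) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- read.table(mapping, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("term_id", "gene_id") %in% names(mapping)))
  if (is.null(universe)) universe <- unique(mapping$gene_id)
  mapping <- mapping[mapping$gene_id %in% universe, , drop = FALSE]
  terms <- lapply(split(mapping$gene_id, mapping$term_id), unique)
  terms <- terms[vapply(terms, length, integer(1L)) >= 1L]
  structure(list(terms = terms,
                 names = term_names,
                 universe = unique(universe)),
            class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat("GO annotation:", length(x$terms), "terms over",
      length(x$universe), "genes\n")
  invisible(x)
}

term_pvalues <- function(anno, query) {
  N <- length(anno$universe)
  n <- length(query)
  K <- vapply(anno$terms, length, integer(1L))
  k <- vapply(anno$terms, function(g) sum(query %in% g), integer(1L))
  # upper tail P(X >= k)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(term_id = names(anno$terms), k = k, K = K, n = n, N = N,
             p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric term enrichment
#'
#' One-sided upper-tail hypergeometric test of query/term overlap against
#' the annotation universe.  Query genes outside the universe are dropped
#' with a warning reporting how many.
#'
#' @param query character vector of gene ids.
#' @param anno a [go_annotation()].
#' @return data frame (class `enrichment_table`) with per-term `k`, `K`,
#'   `n`, `N` and `p`.
#' @export
hypergeom_enrich <- function(query, anno) {
  stopifnot(inherits(anno, "go_annotation"))
  query <- unique(query)
  if (!length(query)) stop("empty query gene set")
  outside <- sum(!query %in% anno$universe)
  if (outside > 0) {
    warning(outside, " query gene(s) outside the universe dropped")
    query <- intersect(query, anno$universe)
    if (!length(query)) stop("no query genes inside the universe")
  }
  out <- term_pvalues(anno, query)
  if (!is.null(anno$names)) out$name <- unname(anno$names[out$term_id])
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Randomization-based FDR for term enrichment
#'
#' Draws `R` random gene sets of the query's size from the universe,
#' recomputes every term's p-value per draw, and estimates
#' `FDR(term) = mean_r #\{terms with p_r <= p_obs(term)\} /
#' #\{terms with p_obs <= p_obs(term)\}`, capped at 1.  Deterministic under
#' a fixed seed.
#'
#' @param anno a [go_annotation()].
#' @param query_size size of the observed query (inside the universe).
#' @param observed an `enrichment_table` from [hypergeom_enrich()].
#' @param R number of randomizations (default 100).
#' @param seed integer seed.
#' @return the table with an `fdr` column added.
#' @export
randomization_fdr <- function(anno, query_size, observed, R = 100,
                              seed = 1L) {
  stopifnot(R >= 1L)
  if (query_size > length(anno$universe)) {
    stop("query_size exceeds the universe size")
  }
  p_obs <- observed$p
  set.seed(seed)
  null_counts <- matrix(0, nrow = R, ncol = length(p_obs))
  for (r in seq_len(R)) {
    draw <- sample(anno$universe, query_size)
    p_r <- term_pvalues(anno, draw)$p
    sp <- sort(p_r)
    null_counts[r, ] <- findInterval(p_obs, sp)
  }
  obs_counts <- vapply(p_obs, function(q) sum(p_obs <= q), numeric(1L))
  fdr <- pmin(colMeans(null_counts) / obs_counts, 1)
  # monotonize so the estimate never decreases with observed p
  ord <- order(p_obs, decreasing = TRUE)
  fdr[ord] <- cummin(fdr[ord])
  observed$fdr <- fdr
  observed
}

#' Run enrichment with randomization FDR in one call
#'
#' @inheritParams hypergeom_enrich
#' @inheritParams randomization_fdr
#' @export
enrich_go <- function(query, anno, R = 100, seed = 1L) {
  tab <- hypergeom_enrich(query, anno)
  randomization_fdr(anno, tab$n[1L], tab, R = R, seed = seed)
}

#' Select terms significant in at least one class
#'
#' @param tables named list of enrichment tables with `fdr` columns, one per
#'   transcript class (e.g. DIT/DRT/DIMT/DRMT).
#' @param cutoff FDR cutoff (strict; default 0.05).
#' @return character vector: union of term ids with `fdr < cutoff` in at
#'   least one table.
#' @export
select_terms <- function(tables, cutoff = 0.05) {
  stopifnot(length(tables) >= 1L)
  hits <- lapply(tables, function(t) t$term_id[t$fdr < cutoff])
  sort(unique(unlist(hits)))
}

#' Scale FDR values to signed heatmap scores
#'
#' Significant FDR values (below `cutoff`) map linearly onto `[0.5, 5]`,
#' with more enriched terms closer to 5; non-significant values map to 0.
#' Scores for repressed classes are negated.
#'
#' @param fdr numeric vector in `[0, 1]`.
#' @param direction `"induced"` (positive scores) or `"repressed"`
#'   (negative).
#' @param cutoff significance cutoff (default 0.05; the boundary itself is
#'   non-significant).
#' @return numeric vector of scores in `{0} U [0.5, 5]` (sign by direction).
#' @export
scale_scores <- function(fdr, direction = c("induced", "repressed"),
                         cutoff = 0.05) {
  direction <- match.arg(direction)
  stopifnot(all(fdr >= 0 & fdr <= 1))
  score <- ifelse(fdr >= cutoff, 0, 0.5 + 4.5 * (cutoff - fdr) / cutoff)
  if (direction == "repressed") score <- -score
  score
}

#' Combined signed score matrix across classes
#'
#' Builds the term x class signed score matrix for the selected terms, with
#' rows ordered by average-linkage hierarchical clustering of the score
#' profiles (presentation only).
#'
#' @param tables named list of enrichment tables with `fdr`.
#' @param directions named character vector giving `"induced"`/`"repressed"`
#'   per class; defaults to `induced` for classes containing "I" before "T"
#'   must be given explicitly otherwise.
#' @param cutoff FDR cutoff for term selection and scaling.
#' @return numeric matrix (selected terms x classes), clustered row order.
#' @export
score_matrix <- function(tables, directions, cutoff = 0.05) {
  stopifnot(all(names(tables) %in% names(directions)))
  sel <- select_terms(tables, cutoff)
  if (!length(sel)) return(matrix(numeric(0), 0, length(tables),
                                  dimnames = list(NULL, names(tables))))
  m <- vapply(names(tables), function(cl) {
    t <- tables[[cl]]
    fdr <- t$fdr[match(sel, t$term_id)]
    fdr[is.na(fdr)] <- 1
    scale_scores(fdr, directions[[cl]], cutoff)
  }, numeric(length(sel)))
  m <- matrix(m, nrow = length(sel),
              dimnames = list(sel, names(tables)))
  if (nrow(m) > 2L) {
    hc <- hclust(dist(m), method = "average")
    m <- m[hc$order, , drop = FALSE]
  }
  m
}
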