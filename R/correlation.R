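#' All-pairs Pearson correlation table for one condition
#'
#' Computes Pearson's r between every pair of genes across the samples of one
#' condition. Genes with zero variance (after the optional log transform) are
#' excluded from the table and recorded in `dropped`, since their correlation
#' is undefined and NA entries would poison downstream quantile cutoffs.
#'
#' @param matrix an [expression_matrix()] with at least 3 samples.
#' @param log_transform if `TRUE`, correlate `log2(x + pseudocount)` instead of
#'   raw values (used for tumor-data robustness checks).
#' @param pseudocount added before the log transform; default 1.
#' @return An object of class `correlation_table`: list with `r` (symmetric
#'   gene-by-gene correlation matrix), `condition`, `n_samples`, `dropped`
#'   (zero-variance gene ids), `log_transform`.
#' @export
correlation_table <- function(matrix, log_transform = FALSE, pseudocount = 1) {
  m <- as_expression_matrix(matrix)
  n <- ncol(m$values)
  if (n < 3L) stop("correlation requires at least 3 samples", call. = FALSE)
  v <- m$values
  if (isTRUE(log_transform)) v <- log2(v + pseudocount)
  sds <- apply(v, 1L, stats::sd)
  dropped <- rownames(v)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning(sprintf("excluding %d zero-variance gene(s)", length(dropped)), call. = FALSE)
    v <- v[!(rownames(v) %in% dropped), , drop = FALSE]
  }
  if (nrow(v) < 2L) stop("fewer than 2 genes with variance", call. = FALSE)
  r <- stats::cor(t(v))
  structure(list(r = r, condition = m$condition, n_samples = n,
                 dropped = dropped, log_transform = isTRUE(log_transform)),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat(sprintf("<correlation_table> %d genes, condition '%s' (%d samples%s)\n",
              nrow(x$r), x$condition, x$n_samples,
              if (x$log_transform) ", log scale" else ""))
  invisible(x)
}

#' Look up pairwise correlations
#'
#' Vectorized lookup of r for gene pairs; pairs with a gene absent from the
#' table yield `NA`.
#'
#' @param table a [correlation_table()].
#' @param a,b character vectors of gene ids (recycled to common length).
#' @return Numeric vector of correlations.
#' @export
pair_r <- function(table, a, b) {
  stopifnot(inherits(table, "correlation_table"))
  genes <- rownames(table$r)
  i <- match(a, genes)
  j <- match(b, genes)
  out <- rep(NA_real_, length(i))
  ok <- !is.na(i) & !is.na(j)
  out[ok] <- table$r[cbind(i[ok], j[ok])]
  out
}

# All unordered pairs of the table as a data.frame (gene_a < gene_b, r).
# Used for edge ranking and as the background co-expression distribution.
all_pairs <- function(table) {
  genes <- rownames(table$r)
  g <- length(genes)
  idx <- which(upper.tri(table$r))
  i <- ((idx - 1L) %% g) + 1L   # row index
  j <- ((idx - 1L) %/% g) + 1L  # col index
  ab <- canonical_pairs(genes[i], genes[j])  # gene input order must not matter
  data.frame(gene_a = ab[, 1L], gene_b = ab[, 2L], r = table$r[idx],
             stringsAsFactors = FALSE)
}

#' Build a co-expression network with a quantile edge cutoff
#'
#' Ranks all evaluated gene pairs by signed Pearson r (descending) and keeps
#' the top `ceiling(q * P)` pairs, where P is the number of evaluated pairs;
#' the smallest retained r is recorded as the cutoff. With `absolute = TRUE`
#' pairs are ranked by |r| instead. Boundary ties are broken deterministically
#' by (r descending, then the lexicographic gene-id pair).
#'
#' @param table a [correlation_table()].
#' @param q quantile of pairs to keep, in `(0, 1]`; default 0.01 (top 1%).
#' @param absolute rank by absolute correlation instead of signed.
#' @return An object of class `coexpression_network`: list with `edges`
#'   (data.frame `gene_a`, `gene_b`, `r`, sorted as ranked), `nodes` (genes
#'   incident to at least one edge), `genes_evaluated`, `cutoff`, `q`,
#'   `condition`.
#' @export
build_network <- function(table, q = 0.01, absolute = FALSE) {
  stopifnot(inherits(table, "correlation_table"))
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q > 1) {
    stop("'q' must be in (0, 1]", call. = FALSE)
  }
  pairs <- all_pairs(table)
  p_total <- nrow(pairs)
  if (p_total == 0L) stop("empty correlation table", call. = FALSE)
  key <- if (absolute) abs(pairs$r) else pairs$r
  n_keep <- as.integer(ceiling(q * p_total))
  ord <- order(-key, pairs$gene_a, pairs$gene_b)
  edges <- pairs[ord[seq_len(n_keep)], , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 genes_evaluated = rownames(table$r),
                 cutoff = if (absolute) min(abs(edges$r)) else min(edges$r),
                 q = q, absolute = absolute, condition = table$condition),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d edges over %d genes (q = %g, cutoff r = %.4f), condition '%s'\n",
              nrow(x$edges), length(x$nodes), x$q, x$cutoff, x$condition))
  invisible(x)
}

#' Convert a co-expression network to an igraph object
#'
#' @param network a [build_network()] result.
#' @param weighted attach r as the `weight` edge attribute.
#' @return An undirected `igraph` graph whose vertices are the network nodes.
#' @export
as_igraph <- function(network, weighted = FALSE) {
  stopifnot(inherits(network, "coexpression_network"))
  g <- igraph::graph_from_data_frame(network$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = network$nodes)
  if (weighted) igraph::E(g)$weight <- network$edges$r
  g
}
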