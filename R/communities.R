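#' Detect co-expression clusters by random-walk community detection
#'
#' Partitions the co-expression network into disjoint gene clusters with the
#' walktrap algorithm (agglomeration over short random walks, cut at maximum
#' modularity). The graph is treated as unweighted by default, reflecting the
#' thresholded nature of the network; set `use_weights = TRUE` to weight the
#' walks by edge r. Isolated vertices (possible when a network is subset)
#' become singleton clusters.
#'
#' @param network a [build_network()] result.
#' @param steps random-walk length; default 4.
#' @param use_weights weight the random walk by edge correlation.
#' @return An object of class `community_partition`: list with `membership`
#'   (named integer vector gene -> cluster id), `clusters` (data.frame
#'   `cluster`, `size`, `coefficient`, `key` -- coefficients filled by
#'   [clustering_coefficient()], key flags by [select_key_clusters()]),
#'   and `condition`.
#' @export
detect_communities <- function(network, steps = 4, use_weights = FALSE) {
  stopifnot(inherits(network, "coexpression_network"))
  if (nrow(network$edges) == 0L) stop("empty network", call. = FALSE)
  g <- as_igraph(network, weighted = use_weights)
  w <- if (use_weights) igraph::E(g)$weight else NA
  comm <- igraph::cluster_walktrap(g, steps = steps, weights = w)
  mem <- igraph::membership(comm)
  membership <- as.integer(mem)
  names(membership) <- names(mem)
  sizes <- table(membership)
  clusters <- data.frame(cluster = as.integer(names(sizes)),
                         size = as.integer(sizes),
                         coefficient = NA_real_, key = NA,
                         stringsAsFactors = FALSE)
  structure(list(membership = membership, clusters = clusters,
                 condition = network$condition),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d genes in %d clusters%s, condition '%s'\n",
              length(x$membership), nrow(x$clusters),
              if (any(x$clusters$key %in% TRUE)) sprintf(" (%d key)", sum(x$clusters$key)) else "",
              x$condition))
  invisible(x)
}

#' Per-cluster clustering coefficients
#'
#' Computes, for each cluster, the mean local clustering coefficient (triangle
#' density around each member). By default the coefficient is computed on the
#' subgraph induced by the cluster's members, so it measures how densely
#' co-expressed the cluster is internally; `induced = FALSE` instead uses each
#' member's local coefficient in the full network. Nodes with degree < 2
#' contribute 0.
#'
#' @param network a [build_network()] result.
#' @param partition a [detect_communities()] partition covering the network.
#' @param induced compute on the intra-cluster induced subgraph (default).
#' @param method `"average"` for node-averaged local coefficients, or
#'   `"transitivity"` for the global triangle/triple ratio of the subgraph.
#' @return The partition with `clusters$coefficient` filled in.
#' @export
clustering_coefficient <- function(network, partition, induced = TRUE,
                                   method = c("average", "transitivity")) {
  stopifnot(inherits(partition, "community_partition"))
  method <- match.arg(method)
  g <- as_igraph(network)
  if (!all(names(partition$membership) %in% igraph::V(g)$name)) {
    stop("partition does not cover the network", call. = FALSE)
  }
  coefs <- vapply(partition$clusters$cluster, function(cl) {
    members <- names(partition$membership)[partition$membership == cl]
    sub <- if (induced) igraph::induced_subgraph(g, members) else g
    if (method == "transitivity") {
      tr <- igraph::transitivity(sub, type = "global")
      if (is.nan(tr)) 0 else tr
    } else {
      loc <- igraph::transitivity(sub, type = "local", vids = members, isolates = "zero")
      mean(loc)
    }
  }, numeric(1))
  partition$clusters$coefficient <- coefs
  partition
}

#' Flag key co-expression clusters
#'
#' Flags the top half of clusters -- `ceiling(K/2)` of K clusters -- by
#' clustering coefficient as key clusters. Ties are broken by (coefficient
#' descending, size descending, cluster id ascending).
#'
#' @param partition a partition with coefficients filled in
#'   (see [clustering_coefficient()]).
#' @return The partition with `clusters$key` set.
#' @export
select_key_clusters <- function(partition) {
  stopifnot(inherits(partition, "community_partition"))
  cl <- partition$clusters
  if (nrow(cl) == 0L) stop("no clusters", call. = FALSE)
  if (anyNA(cl$coefficient)) {
    stop("coefficients missing; run clustering_coefficient() first", call. = FALSE)
  }
  n_key <- ceiling(nrow(cl) / 2)
  ord <- order(-cl$coefficient, -cl$size, cl$cluster)
  cl$key <- FALSE
  cl$key[ord[seq_len(n_key)]] <- TRUE
  partition$clusters <- cl
  partition
}

#' Genes belonging to key clusters
#'
#' @param partition a partition with key flags set.
#' @return Character vector of gene ids.
#' @export
key_cluster_genes <- function(partition) {
  stopifnot(inherits(partition, "community_partition"))
  key <- partition$clusters$cluster[partition$clusters$key %in% TRUE]
  sort(names(partition$membership)[partition$membership %in% key])
}

#' Cluster-level graph from observed vs expected inter-cluster edges
#'
#' Links two clusters A, B when the observed number of edges between them,
#' O_AB, is at least `factor` times the configuration-model expectation
#' `E_AB = sum_{a in A, b in B} k_a * k_b / (2N)`, with k the gene degrees in
#' the full network and N the total edge count. Cluster pairs with no
#' observed edge are never linked.
#'
#' @param network a [build_network()] result.
#' @param partition a [detect_communities()] partition covering the network.
#' @param factor enrichment factor required for an edge; default 2.
#' @return An object of class `cluster_graph`: data.frame with `cluster_a`,
#'   `cluster_b`, `observed`, `expected`, `edge`, plus attributes `n_edges`
#'   (N) and `within` (named vector of within-cluster edge counts).
#' @export
build_cluster_graph <- function(network, partition, factor = 2.0) {
  stopifnot(inherits(network, "coexpression_network"),
            inherits(partition, "community_partition"))
  edges <- network$edges
  n_edges <- nrow(edges)
  if (n_edges == 0L) stop("network has no edges", call. = FALSE)
  mem <- partition$membership
  if (!all(c(edges$gene_a, edges$gene_b) %in% names(mem))) {
    stop("partition does not cover the network", call. = FALSE)
  }
  deg <- table(c(edges$gene_a, edges$gene_b))
  # per-cluster total degree: sum of member degrees
  cl_ids <- sort(unique(mem))
  deg_by_cluster <- vapply(cl_ids, function(cl) {
    sum(deg[names(mem)[mem == cl]])
  }, numeric(1))
  names(deg_by_cluster) <- cl_ids
  ca <- mem[edges$gene_a]
  cb <- mem[edges$gene_b]
  within <- tapply(rep(1L, n_edges)[ca == cb], ca[ca == cb], sum)
  within_full <- setNames(integer(length(cl_ids)), cl_ids)
  within_full[names(within)] <- as.integer(within)
  if (length(cl_ids) < 2L) {
    out <- data.frame(cluster_a = integer(), cluster_b = integer(),
                      observed = integer(), expected = numeric(), edge = logical())
    return(structure(out, class = c("cluster_graph", "data.frame"),
                     n_edges = n_edges, within = within_full))
  }
  cross <- ca != cb
  lo <- pmin(ca, cb)[cross]
  hi <- pmax(ca, cb)[cross]
  obs <- table(paste(lo, hi, sep = "|"))
  pairs <- t(combn(cl_ids, 2L))
  keys <- paste(pairs[, 1L], pairs[, 2L], sep = "|")
  o <- integer(length(keys))
  hit <- match(keys, names(obs))
  o[!is.na(hit)] <- as.integer(obs[hit[!is.na(hit)]])
  e <- deg_by_cluster[as.character(pairs[, 1L])] *
    deg_by_cluster[as.character(pairs[, 2L])] / (2 * n_edges)
  out <- data.frame(cluster_a = pairs[, 1L], cluster_b = pairs[, 2L],
                    observed = o, expected = as.numeric(e),
                    edge = o > 0L & o >= factor * e,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("cluster_graph", "data.frame"),
            n_edges = n_edges, within = within_full)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test `P[X >= k]` for the overlap k between a
#' query gene set and each term set, over a stated universe. Term sets are
#' intersected with the universe before testing.
#'
#' @param query character vector of query gene ids (must lie in `universe`).
#' @param term_sets named list of character vectors (e.g. read from GMT).
#' @param universe character vector of background gene ids.
#' @param alpha significance threshold for the `significant` flag.
#' @return data.frame `term`, `universe_size`, `term_size`, `query_size`,
#'   `overlap`, `p`, `significant`, sorted by p ascending (ties by term id).
#' @export
hypergeometric_enrichment <- function(query, term_sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query genes must be in the universe", call. = FALSE)
  if (is.null(names(term_sets)) || any(names(term_sets) == "")) {
    stop("term_sets must be a named list", call. = FALSE)
  }
  n_u <- length(universe)
  n_q <- length(query)
  res <- lapply(names(term_sets), function(tm) {
    term <- intersect(unique(term_sets[[tm]]), universe)
    k <- length(intersect(term, query))
    # P[X >= k] with X ~ Hypergeometric(n_u, |term|, n_q)
    p <- stats::phyper(k - 1, length(term), n_u - length(term), n_q, lower.tail = FALSE)
    data.frame(term = tm, universe_size = n_u, term_size = length(term),
               query_size = n_q, overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, out$term), , drop = FALSE]
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
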