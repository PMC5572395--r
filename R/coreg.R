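#' Physical interaction network (regulatory or protein-protein)
#'
#' @param edges two-column data.frame or matrix of edges. For
#'   `kind = "regulatory"` columns are TF, target (directed); for
#'   `kind = "ppi"` the edge is undirected and duplicate/self edges are
#'   rejected.
#' @param kind `"regulatory"` or `"ppi"`.
#' @return Object of class `physical_network`: list with `edges` (data.frame
#'   `from`, `to`), `kind`, `nodes`, and for regulatory networks `tfs`.
#' @export
physical_network <- function(edges, kind = c("regulatory", "ppi")) {
  kind <- match.arg(kind)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges must have two columns", call. = FALSE)
  edges <- data.frame(from = as.character(edges[[1L]]), to = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  if (kind == "ppi") {
    if (any(edges$from == edges$to)) stop("self-loop in PPI edges", call. = FALSE)
    ab <- canonical_pairs(edges$from, edges$to)
    edges <- data.frame(from = ab[, 1L], to = ab[, 2L], stringsAsFactors = FALSE)
  }
  if (anyDuplicated(edges)) stop("duplicate edges", call. = FALSE)
  out <- list(edges = edges, kind = kind,
              nodes = sort(unique(c(edges$from, edges$to))))
  if (kind == "regulatory") out$tfs <- sort(unique(edges$from))
  structure(out, class = "physical_network")
}

#' @export
print.physical_network <- function(x, ...) {
  cat(sprintf("<physical_network> %s, %d edges, %d nodes\n",
              x$kind, nrow(x$edges), length(x$nodes)))
  invisible(x)
}

#' Mean co-expression of a set of gene pairs
#'
#' @param edges data.frame/matrix with two gene-id columns (e.g.
#'   `physical_network$edges`).
#' @param table a [correlation_table()].
#' @return list with `mean_r`, `n_pairs` (mappable pairs), and
#'   `frac_unmappable` (pairs with a gene absent from the table).
#' @export
mean_edge_coexpression <- function(edges, table) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  r <- pair_r(table, as.character(edges[[1L]]), as.character(edges[[2L]]))
  ok <- !is.na(r)
  if (!any(ok)) stop("no edge maps to genes in the correlation table", call. = FALSE)
  list(mean_r = mean(r[ok]), n_pairs = sum(ok),
       frac_unmappable = mean(!ok))
}

#' Permutation null for mean edge co-expression
#'
#' Compares the observed mean correlation of a set of edges against a null in
#' which, for each of `n_perm` permutations, the same number of edges is
#' redrawn with both endpoints uniform over the actual network's node set
#' (self-loops and duplicate pairs rejected). The empirical p-value uses the
#' add-one rule `(1 + #\{null >= observed\}) / (1 + n_perm)` and so is never 0.
#'
#' @param edges two-column data.frame/matrix of observed edges.
#' @param table a [correlation_table()].
#' @param n_perm number of permutations; default 1000.
#' @param seed integer seed for the permutation stream.
#' @param nodes optional node universe; defaults to the genes incident to
#'   `edges`.
#' @return list with `observed` (mean r), `null` (numeric length `n_perm`),
#'   `p`, `n_edges`, `seed`, `collision_rate` (fraction of permuted edges that
#'   coincide with an observed edge; resampling allows such collisions).
#' @export
permutation_null <- function(edges, table, n_perm = 1000, seed = 1L, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  m <- nrow(edges)
  if (is.null(nodes)) nodes <- sort(unique(c(as.character(edges[[1L]]),
                                             as.character(edges[[2L]]))))
  if (length(nodes) < 3L) stop("node set too small to permute", call. = FALSE)
  if (m > choose(length(nodes), 2)) stop("too many edges for the node set", call. = FALSE)
  obs <- mean_edge_coexpression(edges, table)$mean_r
  observed_keys <- pair_key(as.character(edges[[1L]]), as.character(edges[[2L]]))
  null <- numeric(n_perm)
  collisions <- 0
  set.seed(as.integer(seed))
  for (b in seq_len(n_perm)) {
    keys <- character(0)
    a_all <- character(0); b_all <- character(0)
    # rejection sampling until m unique non-self pairs are placed
    while (length(keys) < m) {
      need <- m - length(keys)
      a <- sample(nodes, need, replace = TRUE)
      bb <- sample(nodes, need, replace = TRUE)
      ok <- a != bb
      k <- pair_key(a[ok], bb[ok])
      fresh <- !(k %in% keys) & !duplicated(k)
      keys <- c(keys, k[fresh])
      a_all <- c(a_all, a[ok][fresh]); b_all <- c(b_all, bb[ok][fresh])
    }
    collisions <- collisions + sum(keys %in% observed_keys)
    r <- pair_r(table, a_all, b_all)
    null[b] <- mean(r, na.rm = TRUE)
  }
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  list(observed = obs, null = null, p = p, n_edges = m, seed = as.integer(seed),
       collision_rate = collisions / (n_perm * m))
}

#' Co-regulator counts for gene pairs
#'
#' For a regulatory network, counts for every unordered pair of target genes
#' the number of TFs binding both; for a PPI network, counts for every pair
#' of proteins the number of shared interaction partners (the pair members
#' themselves are never counted as partners). Pairs are stratified into the
#' top 0.1% by count (ties broken by count descending, then pair id) and the
#' zero-co-regulation stratum.
#'
#' @param phys a [physical_network()].
#' @param top_q quantile for the top stratum; default 0.001.
#' @return Object of class `coregulation_profile`: list with `pairs`
#'   (data.frame `gene_a`, `gene_b`, `count`, `stratum` in
#'   `c("top", "zero", "mid")`), `kind`, `universe`.
#' @export
coregulation_counts <- function(phys, top_q = 0.001) {
  stopifnot(inherits(phys, "physical_network"))
  if (phys$kind == "regulatory") {
    universe <- sort(unique(phys$edges$to))
    inc <- table(phys$edges$from, phys$edges$to) > 0  # TF x target incidence
    counts_mat <- crossprod(inc * 1)                  # shared-TF counts
  } else {
    universe <- phys$nodes
    g <- length(universe)
    adj <- matrix(0L, g, g, dimnames = list(universe, universe))
    adj[cbind(match(phys$edges$from, universe), match(phys$edges$to, universe))] <- 1L
    adj <- adj + t(adj)
    counts_mat <- adj %*% adj                         # shared-neighbor counts
  }
  counts_mat <- counts_mat[universe, universe, drop = FALSE]
  n <- length(universe)
  if (n < 2L) stop("need at least 2 genes in the universe", call. = FALSE)
  idx <- which(upper.tri(counts_mat))
  i <- ((idx - 1L) %% n) + 1L
  j <- ((idx - 1L) %/% n) + 1L
  pairs <- data.frame(gene_a = universe[i], gene_b = universe[j],
                      count = as.integer(counts_mat[idx]), stringsAsFactors = FALSE)
  n_top <- as.integer(ceiling(top_q * nrow(pairs)))
  ord <- order(-pairs$count, pairs$gene_a, pairs$gene_b)
  pairs$stratum <- "mid"
  pairs$stratum[ord[seq_len(n_top)]] <- "top"
  pairs$stratum[pairs$count == 0L & pairs$stratum != "top"] <- "zero"
  structure(list(pairs = pairs, kind = phys$kind, universe = universe),
            class = "coregulation_profile")
}

#' Mean co-expression as a function of co-regulator count
#'
#' For each threshold t, computes the mean Pearson r over pairs whose
#' co-regulator count is at least t. Thresholds with no qualifying mappable
#' pair are omitted.
#'
#' @param profile a [coregulation_counts()] result.
#' @param table a [correlation_table()].
#' @param thresholds ascending integer co-regulator cutoffs.
#' @return data.frame `threshold`, `mean_r`, `n_pairs`.
#' @export
coexpression_by_coregulator_count <- function(profile, table,
                                              thresholds = 0:5) {
  stopifnot(inherits(profile, "coregulation_profile"))
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("'thresholds' must be strictly ascending", call. = FALSE)
  }
  r <- pair_r(table, profile$pairs$gene_a, profile$pairs$gene_b)
  rows <- lapply(thresholds, function(t) {
    sel <- profile$pairs$count >= t & !is.na(r)
    if (!any(sel)) return(NULL)
    data.frame(threshold = t, mean_r = mean(r[sel]), n_pairs = sum(sel))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(threshold = integer(), mean_r = numeric(),
                                      n_pairs = integer())
  rownames(out) <- NULL
  out
}

#' Select regulators co-expressed with their bound genes
#'
#' For each regulator (TF in a regulatory network, protein in a PPI network),
#' compares the correlations between the regulator and each of its linked
#' genes against the background of all pair correlations in the table with a
#' two-sided two-sample Kolmogorov-Smirnov test. A regulator is selected when
#' KS p < `alpha` and the absolute mean correlation of its linked pairs
#' exceeds `min_abs_mean`. Regulators with fewer than `min_pairs` usable
#' linked pairs are skipped (reported with `tested = FALSE`).
#'
#' @param phys a [physical_network()].
#' @param table a [correlation_table()].
#' @param alpha KS significance threshold; default 0.05.
#' @param min_abs_mean minimum |mean r|; default 0.1.
#' @param min_pairs minimum usable linked pairs per regulator; default 3.
#' @return data.frame `regulator`, `n_pairs`, `mean_r`, `ks_p`, `tested`,
#'   `selected`, sorted by regulator id.
#' @export
select_coexpressed_regulators <- function(phys, table, alpha = 0.05,
                                          min_abs_mean = 0.1, min_pairs = 3L) {
  stopifnot(inherits(phys, "physical_network"))
  background <- all_pairs(table)$r
  regulators <- if (phys$kind == "regulatory") phys$tfs else phys$nodes
  rows <- lapply(regulators, function(reg) {
    linked <- unique(c(phys$edges$to[phys$edges$from == reg],
                       if (phys$kind == "ppi") phys$edges$from[phys$edges$to == reg]))
    linked <- setdiff(linked, reg)
    r <- pair_r(table, rep(reg, length(linked)), linked)
    r <- r[!is.na(r)]
    if (length(r) < min_pairs) {
      return(data.frame(regulator = reg, n_pairs = length(r), mean_r = NA_real_,
                        ks_p = NA_real_, tested = FALSE, selected = FALSE))
    }
    ks <- suppressWarnings(stats::ks.test(r, background))
    data.frame(regulator = reg, n_pairs = length(r), mean_r = mean(r),
               ks_p = ks$p.value, tested = TRUE,
               selected = ks$p.value < alpha && abs(mean(r)) > min_abs_mean)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}
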