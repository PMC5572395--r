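#' Reaction-enzyme map
#'
#' Maps metabolic reactions to their enzyme genes and subsystem annotations
#' (HMR2-style long format: one row per reaction-enzyme assignment).
#'
#' @param assignments data.frame with columns `reaction`, `gene`, `subsystem`.
#' @return Object of class `reaction_map`: list with `enzymes` (named list
#'   reaction -> gene ids), `subsystem` (named character reaction ->
#'   subsystem), `reactions`.
#' @export
reaction_map <- function(assignments) {
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  need <- c("reaction", "gene", "subsystem")
  if (!all(need %in% names(assignments))) {
    stop("assignments need columns reaction, gene, subsystem", call. = FALSE)
  }
  if (any(!nzchar(assignments$subsystem))) stop("empty subsystem label", call. = FALSE)
  enzymes <- lapply(split(assignments$gene, assignments$reaction), unique)
  if (any(lengths(enzymes) == 0L)) stop("reaction with no enzyme", call. = FALSE)
  subsystem <- vapply(split(assignments$subsystem, assignments$reaction),
                      function(s) s[[1L]], character(1))
  structure(list(enzymes = enzymes, subsystem = subsystem,
                 reactions = names(enzymes)),
            class = "reaction_map")
}

#' @export
print.reaction_map <- function(x, ...) {
  cat(sprintf("<reaction_map> %d reactions, %d subsystems, %d enzyme genes\n",
              length(x$reactions), length(unique(x$subsystem)),
              length(unique(unlist(x$enzymes)))))
  invisible(x)
}

#' Reaction-level co-expression: maximum over enzyme pairs
#'
#' Assigns each reaction pair the maximum Pearson correlation over all pairs
#' of their enzyme genes (enzymes shared between two distinct reactions
#' contribute r = 1). Reactions with no enzyme present in the correlation
#' table are excluded and listed.
#'
#' @param map a [reaction_map()].
#' @param table a [correlation_table()].
#' @return Object of class `reaction_coexpression`: list with `r_max`
#'   (symmetric reactions-by-reactions matrix, unit diagonal), `excluded`
#'   (reaction ids with no expressed enzyme), `condition`.
#' @export
reaction_coexpression_matrix <- function(map, table) {
  stopifnot(inherits(map, "reaction_map"), inherits(table, "correlation_table"))
  genes <- rownames(table$r)
  idx <- lapply(map$enzymes, function(e) match(intersect(e, genes), genes))
  usable <- names(idx)[lengths(idx) > 0L]
  excluded <- setdiff(map$reactions, usable)
  if (length(usable) < 2L) stop("fewer than 2 reactions with expressed enzymes", call. = FALSE)
  idx <- idx[usable]
  n <- length(usable)
  rmax <- matrix(1, n, n, dimnames = list(usable, usable))
  for (i in seq_len(n - 1L)) {
    ei <- idx[[i]]
    for (j in seq.int(i + 1L, n)) {
      rmax[i, j] <- rmax[j, i] <- max(table$r[ei, idx[[j]], drop = FALSE])
    }
  }
  structure(list(r_max = rmax, excluded = excluded, condition = table$condition),
            class = "reaction_coexpression")
}

#' Hierarchical clustering of reactions by co-expression
#'
#' Clusters reactions with agglomerative hierarchical clustering on the
#' distance `1 - r_max` and cuts the tree into exactly `k` clusters. Cluster
#' ids are relabelled canonically (ascending by each cluster's
#' lexicographically smallest member), so the result is invariant to the
#' input order of reactions.
#'
#' @param matrix a [reaction_coexpression_matrix()] result.
#' @param k number of clusters; default 100.
#' @param linkage `hclust` agglomeration method; default `"average"`.
#' @return Object of class `reaction_clustering`: list with `membership`
#'   (named integer reaction -> cluster), `k`, `linkage`, `condition`.
#' @export
cluster_reactions <- function(matrix, k = 100, linkage = "average") {
  stopifnot(inherits(matrix, "reaction_coexpression"))
  rxns <- rownames(matrix$r_max)
  if (length(k) != 1L || !is.finite(k) || k < 1 || k > length(rxns)) {
    stop("'k' must be between 1 and the number of usable reactions", call. = FALSE)
  }
  ord <- order(rxns)  # canonical input order for order-invariant merges
  d <- stats::as.dist(1 - matrix$r_max[ord, ord])
  hc <- stats::hclust(d, method = linkage)
  mem <- stats::cutree(hc, k = k)
  # relabel: cluster 1 holds the lexicographically first reaction, etc.
  first_member <- vapply(split(names(mem), mem), min, character(1))
  relabel <- rank(first_member)
  membership <- as.integer(relabel[as.character(mem)])
  names(membership) <- names(mem)
  membership <- membership[rxns[ord]]
  structure(list(membership = membership, k = as.integer(k), linkage = linkage,
                 condition = matrix$condition),
            class = "reaction_clustering")
}

#' Fisher Z-transform of correlation values
#'
#' `z = atanh(r)`, with r clamped to +/-(1 - 1e-7) so that correlations of
#' exactly +/-1 map to a large finite value. Strictly increasing and odd.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return Numeric vector of z values.
#' @export
fisher_z <- function(r) {
  if (any(!is.na(r) & abs(r) > 1)) stop("|r| > 1", call. = FALSE)
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Differential Fisher-Z scores of reaction clusters between conditions
#'
#' For a reference-condition clustering, computes each cluster's mean Fisher-Z
#' co-expression over its within-cluster reaction pairs in the reference
#' condition and in each comparison condition, and ranks clusters by
#' `delta = z_ref - z_other`. The top `ceiling(q * k)` clusters of each
#' comparison are flagged; a cluster flagged in a comparison named in
#' `disease` and in at least one other (tissue) comparison additionally gets
#' the combined `disease_and_tissue` flag. Clusters with fewer than 2
#' reactions mappable in a condition have an undefined mean there and are
#' excluded from that comparison's ranking.
#'
#' @param clustering a [cluster_reactions()] result (reference condition).
#' @param map the [reaction_map()] used for the clustering.
#' @param table_ref reference-condition [correlation_table()].
#' @param tables_other named list of comparison [correlation_table()]s.
#' @param q fraction of clusters to flag per comparison; default 0.01.
#' @param disease names in `tables_other` treated as disease comparisons.
#' @return Object of class `differential_clusters`: list with `scores`
#'   (data.frame `cluster`, `comparison`, `z_ref`, `z_other`, `delta`,
#'   `rank`, `flagged`), `combined` (clusters with the disease + tissue
#'   combined flag), `z_ref` (named per-cluster reference means).
#' @export
differential_cluster_scores <- function(clustering, map, table_ref, tables_other,
                                        q = 0.01, disease = character(0)) {
  stopifnot(inherits(clustering, "reaction_clustering"))
  if (inherits(tables_other, "correlation_table")) tables_other <- list(other = tables_other)
  if (is.null(names(tables_other))) stop("'tables_other' must be named", call. = FALSE)
  mem <- clustering$membership
  clusters <- sort(unique(mem))
  mean_z <- function(table) {
    rc <- reaction_coexpression_matrix(map, table)
    vapply(clusters, function(cl) {
      members <- intersect(names(mem)[mem == cl], rownames(rc$r_max))
      if (length(members) < 2L) return(NA_real_)
      sub <- rc$r_max[members, members]
      mean(fisher_z(sub[upper.tri(sub)]))
    }, numeric(1))
  }
  z_ref <- mean_z(table_ref)
  names(z_ref) <- clusters
  n_flag <- as.integer(ceiling(q * clustering$k))
  rows <- lapply(names(tables_other), function(cmp) {
    z_other <- mean_z(tables_other[[cmp]])
    delta <- z_ref - z_other
    ok <- which(!is.na(delta))
    rk <- rep(NA_integer_, length(delta))
    rk[ok] <- rank(-delta[ok], ties.method = "first")
    data.frame(cluster = clusters, comparison = cmp, z_ref = z_ref,
               z_other = z_other, delta = delta, rank = rk,
               flagged = !is.na(rk) & rk <= n_flag,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  dis <- unique(scores$cluster[scores$flagged & scores$comparison %in% disease])
  tis <- unique(scores$cluster[scores$flagged & !(scores$comparison %in% disease)])
  structure(list(scores = scores, combined = sort(intersect(dis, tis)),
                 z_ref = z_ref, q = q, disease = disease),
            class = "differential_clusters")
}

#' TF enrichment within reaction clusters
#'
#' Tests, for each (cluster, TF), whether the TF's regulatory targets are
#' over-represented among the cluster's enzyme genes, by an upper-tail
#' hypergeometric test over the universe of all enzyme genes of clustered
#' reactions.
#'
#' @param clustering a [cluster_reactions()] result.
#' @param map the matching [reaction_map()].
#' @param phys a regulatory [physical_network()].
#' @param alpha significance threshold; default 0.05.
#' @return data.frame `cluster`, `tf`, `universe_size`, `term_size`,
#'   `query_size`, `overlap`, `p`, `significant`.
#' @export
cluster_tf_enrichment <- function(clustering, map, phys, alpha = 0.05) {
  stopifnot(inherits(clustering, "reaction_clustering"),
            inherits(map, "reaction_map"), inherits(phys, "physical_network"))
  if (phys$kind != "regulatory") stop("'phys' must be regulatory", call. = FALSE)
  mem <- clustering$membership
  universe <- sort(unique(unlist(map$enzymes[names(mem)])))
  if (length(universe) == 0L) stop("empty enzyme universe", call. = FALSE)
  targets_by_tf <- lapply(split(phys$edges$to, phys$edges$from),
                          function(tg) intersect(unique(tg), universe))
  targets_by_tf <- targets_by_tf[lengths(targets_by_tf) > 0L]
  if (length(targets_by_tf) == 0L) {
    return(data.frame(cluster = integer(), tf = character(),
                      universe_size = integer(), term_size = integer(),
                      query_size = integer(), overlap = integer(),
                      p = numeric(), significant = logical()))
  }
  rows <- lapply(sort(unique(mem)), function(cl) {
    query <- sort(unique(unlist(map$enzymes[names(mem)[mem == cl]])))
    query <- intersect(query, universe)
    res <- hypergeometric_enrichment(query, targets_by_tf, universe, alpha = alpha)
    data.frame(cluster = cl, tf = res$term, universe_size = res$universe_size,
               term_size = res$term_size, query_size = res$query_size,
               overlap = res$overlap, p = res$p, significant = res$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Highly regulated reaction clusters
#'
#' Selects clusters whose enriched TFs (from [cluster_tf_enrichment()]) have
#' importance scores stochastically greater than the overall TF importance
#' distribution, by a one-sided two-sample Kolmogorov-Smirnov test at
#' `alpha`. Enriched TFs missing from the importance table are skipped; a
#' cluster needs at least 2 scored enriched TFs to be testable.
#'
#' @param enrichment a [cluster_tf_enrichment()] result.
#' @param importance a [fit_importance()] table.
#' @param alpha KS threshold; default 0.25.
#' @param enrich_alpha which enrichment p-values count as enriched; default 0.05.
#' @return data.frame `cluster`, `n_enriched`, `n_scored`, `ks_p`, `selected`.
#' @export
select_highly_regulated_clusters <- function(enrichment, importance,
                                             alpha = 0.25, enrich_alpha = 0.05) {
  stopifnot(inherits(importance, "tf_importance"))
  all_scores <- importance$importance
  rows <- lapply(sort(unique(enrichment$cluster)), function(cl) {
    tfs <- enrichment$tf[enrichment$cluster == cl & enrichment$p < enrich_alpha]
    scores <- importance$importance[match(tfs, importance$tf)]
    scores <- scores[!is.na(scores)]
    if (length(scores) < 2L) {
      return(data.frame(cluster = cl, n_enriched = length(tfs),
                        n_scored = length(scores), ks_p = NA_real_,
                        selected = FALSE))
    }
    # alternative "less": CDF of enriched scores below the overall CDF,
    # i.e. enriched TFs score stochastically greater
    ks <- suppressWarnings(stats::ks.test(scores, all_scores, alternative = "less"))
    data.frame(cluster = cl, n_enriched = length(tfs), n_scored = length(scores),
               ks_p = ks$p.value, selected = ks$p.value < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subsystem enrichment of reaction clusters
#'
#' Upper-tail hypergeometric test of each metabolic subsystem within each
#' reaction cluster, over the universe of clustered reactions.
#'
#' @param clustering a [cluster_reactions()] result.
#' @param map the matching [reaction_map()].
#' @param alpha significance threshold; default 0.01.
#' @return data.frame `cluster`, `subsystem`, `universe_size`, `term_size`,
#'   `query_size`, `overlap`, `p`, `significant`.
#' @export
subsystem_enrichment <- function(clustering, map, alpha = 0.01) {
  stopifnot(inherits(clustering, "reaction_clustering"),
            inherits(map, "reaction_map"))
  mem <- clustering$membership
  universe <- names(mem)
  subsys <- map$subsystem[universe]
  term_sets <- split(universe, subsys)
  rows <- lapply(sort(unique(mem)), function(cl) {
    query <- names(mem)[mem == cl]
    res <- hypergeometric_enrichment(query, term_sets, universe, alpha = alpha)
    data.frame(cluster = cl, subsystem = res$term, universe_size = res$universe_size,
               term_size = res$term_size, query_size = res$query_size,
               overlap = res$overlap, p = res$p, significant = res$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
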