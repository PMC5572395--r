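#' Co-binding feature matrix for top co-expressed pairs
#'
#' One row per co-expression network edge (the top-quantile co-expressed gene
#' pairs) and one binary column per TF: 1 when the TF binds both genes of the
#' pair in the regulatory network, 0 otherwise. TFs that co-bind no pair are
#' dropped (recorded in `dropped_tfs`); rows with no co-binding TF are kept
#' (they anchor the baseline co-expression level). The response vector is the
#' pair's correlation.
#'
#' @param network a [build_network()] result.
#' @param phys a regulatory [physical_network()].
#' @return Object of class `cobinding_matrix`: list with `x` (binary matrix,
#'   rows = pair keys, cols = TFs), `y` (pair r), `pairs` (data.frame),
#'   `dropped_tfs`.
#' @export
build_feature_matrix <- function(network, phys) {
  stopifnot(inherits(network, "coexpression_network"),
            inherits(phys, "physical_network"))
  if (phys$kind != "regulatory") stop("'phys' must be a regulatory network", call. = FALSE)
  edges <- network$edges
  targets_by_tf <- split(phys$edges$to, phys$edges$from)
  tfs <- names(targets_by_tf)
  x <- vapply(tfs, function(tf) {
    tg <- targets_by_tf[[tf]]
    as.integer(edges$gene_a %in% tg & edges$gene_b %in% tg)
  }, integer(nrow(edges)))
  x <- matrix(x, nrow = nrow(edges), dimnames = list(
    pair_key(edges$gene_a, edges$gene_b), tfs))
  keep <- colSums(x) > 0L
  if (!any(keep)) stop("no TF co-binds any co-expressed pair", call. = FALSE)
  structure(list(x = x[, keep, drop = FALSE], y = edges$r, pairs = edges,
                 dropped_tfs = tfs[!keep]),
            class = "cobinding_matrix")
}

#' TF importance for co-expression via a regression forest
#'
#' Fits a random forest regressing pair co-expression on the binary
#' co-binding features and reports per-TF variable importance. The default
#' importance is the total decrease in node impurity (residual sum of
#' squares); `type = "permutation"` uses out-of-bag permutation importance
#' instead, which is less biased for correlated binary features. Results are
#' deterministic given `seed`.
#'
#' @param matrix a [build_feature_matrix()] result.
#' @param n_trees number of trees; default 500.
#' @param seed integer seed.
#' @param type `"impurity"` or `"permutation"`.
#' @return Object of class `tf_importance`: data.frame `tf`, `importance`,
#'   `rank`, with attributes `seed`, `type`.
#' @export
fit_importance <- function(matrix, n_trees = 500, seed = 1L,
                           type = c("impurity", "permutation")) {
  stopifnot(inherits(matrix, "cobinding_matrix"))
  type <- match.arg(type)
  if (nrow(matrix$x) < 10L) stop("need at least 10 pairs", call. = FALSE)
  if (ncol(matrix$x) < 2L) stop("need at least 2 TF features", call. = FALSE)
  if (stats::var(matrix$y) == 0) stop("constant response", call. = FALSE)
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = matrix$x, y = matrix$y, ntree = n_trees,
                                    importance = (type == "permutation"))
  imp <- randomForest::importance(fit, type = if (type == "permutation") 1L else 2L)
  score <- as.numeric(imp[, 1L])
  out <- data.frame(tf = rownames(imp), importance = score, stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$tf), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("tf_importance", "data.frame"),
            seed = as.integer(seed), type = type)
}

#' Select the most influential TFs
#'
#' Returns the top `ceiling(q * T)` TFs by importance score (ties by score
#' descending, then TF id) -- by default the top 1%.
#'
#' @param table a [fit_importance()] result.
#' @param q fraction of TFs to keep; default 0.01.
#' @return Character vector of TF ids.
#' @export
select_top_influential <- function(table, q = 0.01) {
  stopifnot(inherits(table, "tf_importance"))
  if (nrow(table) == 0L) stop("empty importance table", call. = FALSE)
  n <- as.integer(ceiling(q * nrow(table)))
  ord <- order(-table$importance, table$tf)
  table$tf[ord[seq_len(n)]]
}
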