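# Independent brute-force oracles and small shared fixtures.

# two-pass Pearson correlation, straight from the definition
pearson_brute <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# local clustering coefficient by explicit triangle counting on an edge list
local_cc_brute <- function(edges, node) {
  nbrs <- unique(c(edges[edges[, 1] == node, 2], edges[edges[, 2] == node, 1]))
  k <- length(nbrs)
  if (k < 2) return(0)
  links <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      a <- nbrs[i]; b <- nbrs[j]
      if (any((edges[, 1] == a & edges[, 2] == b) |
              (edges[, 1] == b & edges[, 2] == a))) links <- links + 1
    }
  }
  links / choose(k, 2)
}

# exact upper-tail hypergeometric by enumerating all draws of size n
hyper_enum <- function(n_universe, term_size, n_query, k_min) {
  universe <- seq_len(n_universe)
  term <- seq_len(term_size)
  draws <- combn(universe, n_query)
  mean(apply(draws, 2, function(d) sum(d %in% term) >= k_min))
}

# rank-based AUC of `scores` for separating positives from negatives
rank_auc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# a tiny deterministic expression matrix on a simple scale
toy_expression <- function(values, genes = NULL, condition = "toy") {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  rownames(values) <- genes
  expression_matrix(values, condition = condition)
}

# small, fast generator configuration for unit tests
small_config <- function(seed = 1L, ...) {
  synth_config(n_genes = 120, n_conditions = 3, samples_per_condition = 60,
               n_modules = 3, module_correlation = 0.8, n_tfs = 10,
               targets_per_tf = 8, ppin_density = 0.05, n_reactions = 40,
               hub_partner_count = 4, seed = seed, ...)
}
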