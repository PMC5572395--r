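#' Hub-gene co-expression neighborhood in one condition
#'
#' Ranks the genes most correlated with a hub gene (e.g. FASN) in one
#' condition, restricted to genes whose mean expression exceeds `min_tpm`
#' (1 TPM by default), and keeps the top `top_n`. Ties are broken by r
#' descending, then gene id.
#'
#' @param table a [correlation_table()] for the condition (raw or
#'   log-transformed).
#' @param matrix the condition's [expression_matrix()] (TPM), used for the
#'   expression floor.
#' @param hub hub gene id.
#' @param min_tpm mean-expression floor for candidate genes; default 1.
#' @param top_n neighborhood size; default 100.
#' @return data.frame `gene`, `r`, `rank` (at most `top_n` rows), with
#'   attributes `hub`, `condition`.
#' @export
hub_neighborhood <- function(table, matrix, hub, min_tpm = 1.0, top_n = 100) {
  stopifnot(inherits(table, "correlation_table"))
  m <- as_expression_matrix(matrix)
  means <- rowMeans(m$values)
  if (!(hub %in% rownames(m$values)) || !(hub %in% rownames(table$r))) {
    stop(sprintf("hub gene '%s' absent from the data", hub), call. = FALSE)
  }
  if (means[hub] <= min_tpm) {
    stop(sprintf("hub gene '%s' not expressed above %g", hub, min_tpm), call. = FALSE)
  }
  candidates <- setdiff(rownames(table$r)[rownames(table$r) %in%
                                            names(means)[means > min_tpm]], hub)
  r <- pair_r(table, rep(hub, length(candidates)), candidates)
  ord <- order(-r, candidates)
  keep <- ord[seq_len(min(top_n, length(candidates)))]
  out <- data.frame(gene = candidates[keep], r = r[keep],
                    rank = seq_along(keep), stringsAsFactors = FALSE)
  attr(out, "hub") <- hub
  attr(out, "condition") <- table$condition
  out
}

#' Robust hub neighborhood: intersection of raw and log-scale lists
#'
#' Genes that stay in the hub's top list whether correlations are computed on
#' raw or log-transformed expression.
#'
#' @param list_raw,list_log [hub_neighborhood()] results for the same
#'   condition on raw and log-transformed correlations.
#' @return Sorted character vector of gene ids.
#' @export
robust_hub_set <- function(list_raw, list_log) {
  sort(intersect(list_raw$gene, list_log$gene))
}

#' Tissue-specificity filter for hub partners
#'
#' Keeps genes of the focal condition's robust set that (a) appear in the hub
#' top lists of fewer than `max_conditions` conditions (the focal condition
#' counts) and (b) belong to the supplied tissue-enriched annotation set.
#' Without an annotation set only criterion (a) applies, with a warning.
#'
#' @param neighborhoods named list of [hub_neighborhood()] data.frames, one
#'   per condition (at least 2).
#' @param focal name of the focal condition in `neighborhoods`.
#' @param robust_set genes to consider (e.g. [robust_hub_set()] of the focal
#'   condition); defaults to the focal neighborhood's genes.
#' @param enriched_genes character vector of tissue-enriched gene ids, or
#'   `NULL`.
#' @param max_conditions genes present in this many or more conditions are
#'   dropped; default 3 ("fewer than three tissues").
#' @return data.frame `gene`, `n_conditions`, `enriched`, `kept`.
#' @export
tissue_specificity_filter <- function(neighborhoods, focal, robust_set = NULL,
                                      enriched_genes = NULL, max_conditions = 3L) {
  if (length(neighborhoods) < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (!(focal %in% names(neighborhoods))) stop("unknown focal condition", call. = FALSE)
  if (is.null(robust_set)) robust_set <- neighborhoods[[focal]]$gene
  counts <- vapply(robust_set, function(g) {
    sum(vapply(neighborhoods, function(nb) g %in% nb$gene, logical(1)))
  }, integer(1))
  enriched <- if (is.null(enriched_genes)) {
    warning("no tissue-enriched annotation supplied; filtering on condition counts only",
            call. = FALSE)
    rep(TRUE, length(robust_set))
  } else {
    robust_set %in% enriched_genes
  }
  out <- data.frame(gene = robust_set, n_conditions = counts, enriched = enriched,
                    kept = counts < max_conditions & enriched,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quartile stratification by hub expression
#'
#' Splits samples into a high group (top quartile of hub expression) and a
#' low group (bottom quartile). Each group has `round(n/4)` samples with 0.5
#' rounding up, reproducing 371 samples -> 93 per group. Ties in expression
#' are broken by sample id for determinism.
#'
#' @param hub_expression named numeric vector of the hub gene's expression
#'   per sample (names = sample ids).
#' @return list with `high`, `low` (disjoint character vectors of sample
#'   ids) and `n_group`.
#' @export
quartile_groups <- function(hub_expression) {
  n <- length(hub_expression)
  if (n < 8L) stop("need at least 8 samples for quartile groups", call. = FALSE)
  if (is.null(names(hub_expression))) {
    names(hub_expression) <- sprintf("s%04d", seq_len(n))
  }
  n_group <- as.integer(round_half_up(n / 4))
  ord <- order(hub_expression, names(hub_expression))
  ids <- names(hub_expression)[ord]
  list(high = rev(ids)[seq_len(n_group)], low = ids[seq_len(n_group)],
       n_group = n_group)
}

#' Negative-binomial two-group differential expression
#'
#' A self-contained negative-binomial Wald test for count data: library sizes
#' are normalized with median-of-ratios size factors, a per-gene NB
#' dispersion is estimated by the method of moments pooled across both
#' groups (floored at `min_dispersion`), and the log2 fold change high/low is
#' tested with a Wald statistic on the log scale. P-values are adjusted by
#' Benjamini-Hochberg. Genes with all-zero counts get p = 1 and are flagged.
#'
#' @param counts integer matrix, genes x samples (colnames = sample ids).
#' @param groups list with `high` and `low` character vectors of sample ids
#'   (e.g. from [quartile_groups()]), each of size >= 2.
#' @param alpha significance threshold on adjusted p; default 0.05.
#' @param min_dispersion dispersion floor; default 1e-8.
#' @return data.frame `gene`, `base_mean`, `log2_fc`, `dispersion`, `stat`,
#'   `p`, `padj`, `significant`, `all_zero`.
#' @export
nb_differential_expression <- function(counts, groups, alpha = 0.05,
                                       min_dispersion = 1e-8) {
  if (!is.matrix(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be a matrix of non-negative integers", call. = FALSE)
  }
  high <- groups$high
  low <- groups$low
  if (length(high) < 2L || length(low) < 2L) stop("both groups need >= 2 samples", call. = FALSE)
  if (length(intersect(high, low))) stop("groups overlap", call. = FALSE)
  if (!all(c(high, low) %in% colnames(counts))) stop("group sample ids not in counts", call. = FALSE)
  k <- counts[, c(high, low), drop = FALSE]
  grp <- rep(c("high", "low"), c(length(high), length(low)))

  # median-of-ratios size factors over genes with all-positive counts
  log_geo <- rowMeans(log(k))
  ref_ok <- is.finite(log_geo)
  if (!any(ref_ok)) stop("no gene with all-positive counts for size factors", call. = FALSE)
  sf <- apply(k, 2L, function(col) exp(stats::median(log(col[ref_ok]) - log_geo[ref_ok])))
  norm <- sweep(k, 2L, sf, "/")

  inv_sf <- 1 / sf
  res <- t(apply(norm, 1L, function(x) {
    xh <- x[grp == "high"]; xl <- x[grp == "low"]
    mu_h <- mean(xh); mu_l <- mean(xl)
    if (mu_h == 0 && mu_l == 0) return(c(0, 0, NA, NA, 1))
    # pooled method-of-moments dispersion: Var(K_j / s_j) = mu / s_j + a mu^2
    zh <- mean(inv_sf[grp == "high"]); zl <- mean(inv_sf[grp == "low"])
    a_h <- if (mu_h > 0) (stats::var(xh) - mu_h * zh) / mu_h^2 else NA
    a_l <- if (mu_l > 0) (stats::var(xl) - mu_l * zl) / mu_l^2 else NA
    disp <- max(mean(c(a_h, a_l), na.rm = TRUE), min_dispersion)
    pc <- 0.5  # pseudo-mean keeps the log and its variance finite at zero
    var_mean_h <- (mu_h * sum(inv_sf[grp == "high"]) + length(xh) * disp * mu_h^2) / length(xh)^2
    var_mean_l <- (mu_l * sum(inv_sf[grp == "low"]) + length(xl) * disp * mu_l^2) / length(xl)^2
    se <- sqrt(var_mean_h / (mu_h + pc)^2 + var_mean_l / (mu_l + pc)^2)
    lfc <- log2((mu_h + pc) / (mu_l + pc))
    stat <- (log(mu_h + pc) - log(mu_l + pc)) / se
    p <- 2 * stats::pnorm(-abs(stat))
    c((mu_h + mu_l) / 2, lfc, disp, stat, p)
  }))
  out <- data.frame(gene = rownames(k), base_mean = res[, 1L], log2_fc = res[, 2L],
                    dispersion = res[, 3L], stat = res[, 4L], p = res[, 5L],
                    stringsAsFactors = FALSE)
  out$all_zero <- rowSums(k) == 0
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$padj < alpha
  rownames(out) <- NULL
  out
}
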