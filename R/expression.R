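#' Expression matrix with condition and unit metadata
#'
#' A light container for a genes-by-samples expression matrix. Values must be
#' finite and non-negative; gene ids must be unique. The unit tag records
#' whether values are RPKM (reads per kilobase per million) or TPM
#' (transcripts per million); all correlation-based analyses expect TPM.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @param condition single string labelling the condition (tissue, tumor, ...).
#' @param unit `"TPM"` or `"RPKM"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `condition`, `unit`.
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, dimnames = list(c("g1", "g2"), NULL)),
#'                        condition = "liver")
#' dim(m)
#' @export
expression_matrix <- function(values, condition = "condition", unit = c("TPM", "RPKM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    stop("'values' must have gene ids as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and >= 0", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  structure(list(values = values, condition = condition, unit = unit),
            class = "expression_matrix")
}

as_expression_matrix <- function(x, condition = "condition", unit = "TPM") {
  if (inherits(x, "expression_matrix")) return(x)
  expression_matrix(x, condition = condition, unit = unit)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, condition '%s' [%s]\n",
              nrow(x$values), ncol(x$values), x$condition, x$unit))
  invisible(x)
}

#' Convert RPKM values to TPM
#'
#' Rescales each sample so that transcript proportions sum to one million:
#' `TPM[g, s] = RPKM[g, s] / sum_g RPKM[g, s] * 1e6`. Column sums of the
#' result are exactly 1e6.
#'
#' @param matrix an [expression_matrix()] with unit `"RPKM"`.
#' @return An `expression_matrix` with unit `"TPM"`.
#' @examples
#' m <- expression_matrix(matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s1")),
#'                        unit = "RPKM")
#' rpkm_to_tpm(m)$values  # 250000, 750000
#' @export
rpkm_to_tpm <- function(matrix) {
  m <- as_expression_matrix(matrix, unit = "RPKM")
  if (m$unit != "RPKM") stop("input unit is not RPKM", call. = FALSE)
  cs <- colSums(m$values)
  bad <- which(cs <= 0)
  if (length(bad)) {
    stop(sprintf("all-zero sample(s): %s", paste(colnames(m$values)[bad], collapse = ", ")),
         call. = FALSE)
  }
  expression_matrix(sweep(m$values, 2, cs, "/") * 1e6,
                    condition = m$condition, unit = "TPM")
}

#' Drop the lowest-expressed fraction of genes
#'
#' Removes the `floor(fraction * G)` genes with the lowest mean expression
#' before correlation analysis (default: the lowest-expressed third). Ties in
#' mean expression are broken by gene id, dropping the lexicographically
#' earlier gene first. The order of retained genes is preserved.
#'
#' @param matrix an [expression_matrix()] (or plain matrix with rownames).
#' @param fraction fraction of genes to drop, in `[0, 1)`.
#' @return The filtered `expression_matrix`.
#' @export
filter_low_expression <- function(matrix, fraction = 1 / 3) {
  m <- as_expression_matrix(matrix)
  if (length(fraction) != 1L || !is.finite(fraction) || fraction < 0 || fraction >= 1) {
    stop("'fraction' must be in [0, 1)", call. = FALSE)
  }
  g <- nrow(m$values)
  n_drop <- floor(fraction * g)
  if (n_drop == 0L) return(m)
  means <- rowMeans(m$values)
  # lowest mean first; ties broken by gene id ascending so earlier ids drop first
  ord <- order(means, rownames(m$values))
  drop <- ord[seq_len(n_drop)]
  if (n_drop >= g) stop("filter would drop every gene", call. = FALSE)
  expression_matrix(m$values[-sort(drop), , drop = FALSE],
                    condition = m$condition, unit = m$unit)
}
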