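# Readers and writers for the plain-text formats the pipeline consumes:
# expression TSV / GCT 1.2, edge-list TSV, reaction-map TSV, GMT gene sets,
# counts TSV and ground-truth JSON.

#' Read / write an expression matrix as TSV
#'
#' Tab-separated, first column `gene`, remaining columns one per sample.
#'
#' @param path file path.
#' @param condition,unit metadata attached on read.
#' @return [expression_matrix()] (read) or `path`, invisibly (write).
#' @export
read_expression_tsv <- function(path, condition = "condition", unit = "TPM") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  expression_matrix(m, condition = condition, unit = unit)
}

#' @param matrix an [expression_matrix()].
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(matrix, path) {
  m <- as_expression_matrix(matrix)
  df <- data.frame(gene = rownames(m$values), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GCT 1.2 expression files
#'
#' The two-line GCT 1.2 header (`#1.2`, then `genes<TAB>samples`) followed by
#' `Name`, `Description` and one column per sample.
#'
#' @param path file path.
#' @param condition,unit metadata attached on read.
#' @return [expression_matrix()] (read) or `path`, invisibly (write).
#' @export
read_gct <- function(path, condition = "condition", unit = "TPM") {
  header <- readLines(path, n = 2L)
  if (!startsWith(header[1L], "#1.2")) stop("not a GCT 1.2 file", call. = FALSE)
  df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df[[1L]]
  expression_matrix(m, condition = condition, unit = unit)
}

#' @param matrix an [expression_matrix()].
#' @rdname read_gct
#' @export
write_gct <- function(matrix, path) {
  m <- as_expression_matrix(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m$values), ncol(m$values), sep = "\t")), con)
  df <- data.frame(Name = rownames(m$values), Description = rownames(m$values),
                   m$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write physical-network edge lists as TSV
#'
#' Two tab-separated columns: `tf`/`target` for regulatory networks,
#' `protein_a`/`protein_b` for PPI networks.
#'
#' @param path file path.
#' @param kind `"regulatory"` or `"ppi"`.
#' @return [physical_network()] (read) or `path`, invisibly (write).
#' @export
read_edge_tsv <- function(path, kind = c("regulatory", "ppi")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  physical_network(df[, 1:2], kind = kind)
}

#' @param phys a [physical_network()].
#' @rdname read_edge_tsv
#' @export
write_edge_tsv <- function(phys, path) {
  stopifnot(inherits(phys, "physical_network"))
  df <- phys$edges
  names(df) <- if (phys$kind == "regulatory") c("tf", "target") else
    c("protein_a", "protein_b")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a reaction-enzyme map as TSV
#'
#' Long format with columns `reaction_id`, `gene_id`, `subsystem` (one row
#' per reaction-enzyme assignment, HMR2-style flat export).
#'
#' @param path file path.
#' @return [reaction_map()] (read) or `path`, invisibly (write).
#' @export
read_reaction_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  reaction_map(data.frame(reaction = df$reaction_id, gene = df$gene_id,
                          subsystem = df$subsystem, stringsAsFactors = FALSE))
}

#' @param map a [reaction_map()].
#' @rdname read_reaction_map_tsv
#' @export
write_reaction_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "reaction_map"))
  df <- data.frame(reaction_id = rep(names(map$enzymes), lengths(map$enzymes)),
                   gene_id = unlist(map$enzymes, use.names = FALSE),
                   stringsAsFactors = FALSE)
  df$subsystem <- map$subsystem[df$reaction_id]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return Named list of character vectors (read) or `path`, invisibly
#'   (write).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  sets
}

#' @param sets named list of character vectors.
#' @param descriptions optional per-set description strings.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) stop("'sets' must be named", call. = FALSE)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Write co-expression network edges as TSV
#'
#' Three tab-separated columns: `gene_a`, `gene_b`, `r`.
#'
#' @param network a [build_network()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the ground truth of a synthetic study as JSON
#'
#' @param sim a `synth_study`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(sim, path) {
  stopifnot(inherits(sim, "synth_study"))
  truth <- sim$truth
  out <- list(
    modules = split(names(truth$modules), truth$modules),
    decorrelated_module = truth$decorrelated_module,
    disease_condition = truth$disease_condition,
    hub = truth$hub,
    causal_tfs = truth$causal_tfs,
    hub_specific = truth$hub_specific,
    hub_ubiquitous = truth$hub_ubiquitous,
    planted_reactions = truth$planted_reactions,
    planted_subsystem = truth$planted_subsystem)
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
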