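#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor ks.test median p.adjust phyper pnorm rnbinom rnorm
#'   as.dist cutree hclust runif var setNames complete.cases quantile
#' @importFrom utils head combn
NULL

# Canonical unordered pair key "a|b" with a < b (lexicographic).
pair_key <- function(a, b) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "|")
}

# Order pairs so gene_a < gene_b lexicographically; returns a 2-col matrix.
canonical_pairs <- function(a, b) {
  swap <- a > b
  cbind(ifelse(swap, b, a), ifelse(swap, a, b))
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
}

# round-half-up, used for quartile group sizes (371 samples -> groups of 93)
round_half_up <- function(x) floor(x + 0.5)
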