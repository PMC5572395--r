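# Reaction-level co-expression, hierarchical clustering, Fisher-Z
# differential scores and the enrichment/selection layers.

corr_from_matrix <- function(r, condition = "toy") {
  structure(list(r = r, condition = condition, n_samples = 50L,
                 dropped = character(0), log_transform = FALSE),
            class = "correlation_table")
}

toy_corr <- function(genes, fill = 0) {
  r <- matrix(fill, length(genes), length(genes), dimnames = list(genes, genes))
  diag(r) <- 1
  r
}

test_that("reaction co-expression takes the maximum over enzyme pairs", {
  genes <- c("a", "b", "c", "s")
  r <- toy_corr(genes)
  r["a", "c"] <- r["c", "a"] <- 0.2
  r["b", "c"] <- r["c", "b"] <- 0.7
  tab <- corr_from_matrix(r)
  map <- reaction_map(data.frame(
    reaction = c("R1", "R1", "R2", "R3", "R4"),
    gene = c("a", "b", "c", "s", "s"),
    subsystem = "x", stringsAsFactors = FALSE))
  rc <- reaction_coexpression_matrix(map, tab)
  expect_equal(rc$r_max["R1", "R2"], 0.7)  # max(r(a,c), r(b,c))
  # R3 and R4 share the single enzyme s: r(s, s) = 1
  expect_equal(rc$r_max["R3", "R4"], 1.0)
  expect_equal(unname(diag(rc$r_max)), rep(1, 4))
  expect_true(isSymmetric(rc$r_max))

  # a reaction with no expressed enzyme lands in the excluded list
  map2 <- reaction_map(data.frame(reaction = c("R1", "R2", "R5"),
                                  gene = c("a", "b", "zz"),
                                  subsystem = "x", stringsAsFactors = FALSE))
  rc2 <- reaction_coexpression_matrix(map2, tab)
  expect_identical(rc2$excluded, "R5")
  expect_false("R5" %in% rownames(rc2$r_max))
})

test_that("r_max dominates every enzyme-pair correlation (brute force)", {
  set.seed(70)
  genes <- sprintf("g%02d", 1:15)
  v <- matrix(exp(rnorm(15 * 20)), 15, 20, dimnames = list(genes, NULL))
  tab <- correlation_table(expression_matrix(v))
  assign <- data.frame(
    reaction = rep(sprintf("R%d", 1:6), times = c(2, 3, 1, 2, 3, 2)),
    gene = sample(genes, 13, replace = FALSE),
    subsystem = "s", stringsAsFactors = FALSE)
  map <- reaction_map(assign)
  rc <- reaction_coexpression_matrix(map, tab)
  for (i in 1:5) for (j in (i + 1):6) {
    ri <- sprintf("R%d", i); rj <- sprintf("R%d", j)
    for (e1 in map$enzymes[[ri]]) for (e2 in map$enzymes[[rj]]) {
      expect_gte(rc$r_max[ri, rj], pair_r(tab, e1, e2))
    }
  }
})

test_that("fisher_z is the clamped atanh with odd symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.1), "> 1")
  z <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(tanh(fisher_z(z)), z, tolerance = 1e-12)
  expect_true(all(diff(fisher_z(z)) > 0))
})

test_that("hierarchical clustering recovers blocks and known dendrograms", {
  # hand-built 5-reaction distance structure: {A,B} at 0.1, {C,D} at 0.2,
  # E far from everything; average linkage merges (A,B), (C,D), then E last
  rxns <- c("A", "B", "C", "D", "E")
  rmax <- toy_corr(rxns, fill = 0)
  rmax["A", "B"] <- rmax["B", "A"] <- 0.9
  rmax["C", "D"] <- rmax["D", "C"] <- 0.8
  rc <- structure(list(r_max = rmax, excluded = character(0), condition = "toy"),
                  class = "reaction_coexpression")
  cl3 <- cluster_reactions(rc, k = 3)
  expect_equal(cl3$membership[["A"]], cl3$membership[["B"]])
  expect_equal(cl3$membership[["C"]], cl3$membership[["D"]])
  expect_length(unique(cl3$membership), 3)

  hc <- hclust(as.dist(1 - rmax), method = "average")
  expect_equal(hc$height[1:2], c(0.1, 0.2))

  # k = n gives singletons; canonical labels follow reaction order
  cln <- cluster_reactions(rc, k = 5)
  expect_equal(unname(cln$membership[rxns]), 1:5)
  expect_error(cluster_reactions(rc, k = 6), "'k'")
})

test_that("two separated correlation blocks are recovered at k = 2", {
  set.seed(71)
  genes <- sprintf("g%02d", 1:20)
  f1 <- rnorm(100); f2 <- rnorm(100)
  v <- rbind(
    t(sapply(1:10, function(i) exp(sqrt(0.9) * f1 + sqrt(0.1) * rnorm(100)))),
    t(sapply(1:10, function(i) exp(sqrt(0.9) * f2 + sqrt(0.1) * rnorm(100)))))
  rownames(v) <- genes
  tab <- correlation_table(expression_matrix(v))
  map <- reaction_map(data.frame(reaction = sprintf("R%02d", 1:20),
                                 gene = genes, subsystem = "s"))
  rc <- reaction_coexpression_matrix(map, tab)
  cl <- cluster_reactions(rc, k = 2)
  expect_length(unique(cl$membership[sprintf("R%02d", 1:10)]), 1)
  expect_length(unique(cl$membership[sprintf("R%02d", 11:20)]), 1)
})

test_that("clustering is invariant to reaction input order", {
  set.seed(72)
  genes <- sprintf("g%02d", 1:12)
  v <- matrix(exp(rnorm(12 * 30)), 12, 30, dimnames = list(genes, NULL))
  tab <- correlation_table(expression_matrix(v))
  df <- data.frame(reaction = sprintf("R%02d", 1:12), gene = genes, subsystem = "s")
  cl1 <- cluster_reactions(reaction_coexpression_matrix(reaction_map(df), tab), k = 4)
  df2 <- df[sample(nrow(df)), ]
  cl2 <- cluster_reactions(reaction_coexpression_matrix(reaction_map(df2), tab), k = 4)
  expect_identical(cl1$membership[sort(names(cl1$membership))],
                   cl2$membership[sort(names(cl2$membership))])
})

test_that("differential Fisher-Z scores flag the planted deregulated cluster", {
  cfg <- small_config(seed = 73)
  sim <- gen_reaction_map(gen_expression(cfg))
  tab_ref <- correlation_table(sim$expression$tissue_1)
  tab_dis <- correlation_table(sim$expression$disease)
  rc <- reaction_coexpression_matrix(sim$reaction_map, tab_ref)
  cl <- cluster_reactions(rc, k = 30)
  # identical conditions: all deltas are zero
  same <- differential_cluster_scores(cl, sim$reaction_map, tab_ref,
                                      list(self = tab_ref), q = 0.01)
  expect_true(all(abs(same$scores$delta[!is.na(same$scores$delta)]) < 1e-12))
  # k = 30, q = 0.01 -> exactly one flagged cluster per comparison
  diff <- differential_cluster_scores(cl, sim$reaction_map, tab_ref,
                                      list(disease = tab_dis, other = tab_ref),
                                      q = 0.01, disease = "disease")
  expect_equal(sum(diff$scores$flagged[diff$scores$comparison == "disease"]), 1)
  flagged <- diff$scores$cluster[diff$scores$flagged &
                                   diff$scores$comparison == "disease"]
  members <- names(cl$membership)[cl$membership == flagged]
  expect_true(all(members %in% sim$truth$planted_reactions))
  expect_gte(length(members), 2)
})

test_that("combined disease-and-tissue flag needs both comparisons", {
  cfg <- small_config(seed = 74)
  sim <- gen_reaction_map(gen_expression(cfg))
  tab_ref <- correlation_table(sim$expression$tissue_1)
  tab_t2 <- correlation_table(sim$expression$tissue_2)
  tab_dis <- correlation_table(sim$expression$disease)
  rc <- reaction_coexpression_matrix(sim$reaction_map, tab_ref)
  cl <- cluster_reactions(rc, k = 30)
  # vs another healthy tissue the planted cluster is NOT condition-specific
  # (same correlation there), so the combined flag stays empty or differs
  # from the disease flag only when a tissue comparison also ranks it first
  d <- differential_cluster_scores(cl, sim$reaction_map, tab_ref,
                                   list(disease = tab_dis, tissue_2 = tab_t2),
                                   q = 0.01, disease = "disease")
  dis_flag <- d$scores$cluster[d$scores$flagged & d$scores$comparison == "disease"]
  tis_flag <- d$scores$cluster[d$scores$flagged & d$scores$comparison == "tissue_2"]
  expect_identical(d$combined, sort(intersect(dis_flag, tis_flag)))
})

test_that("TF enrichment of clusters matches the enumeration oracle", {
  # two clusters of reactions; TF1 binds exactly cluster 1's enzymes
  genes <- sprintf("e%02d", 1:8)
  map <- reaction_map(data.frame(reaction = sprintf("R%d", 1:8), gene = genes,
                                 subsystem = "s"))
  cl <- structure(list(membership = setNames(rep(1:2, each = 4), sprintf("R%d", 1:8)),
                       k = 2L, linkage = "average", condition = "toy"),
                  class = "reaction_clustering")
  rn <- physical_network(data.frame(from = "TF1", to = genes[1:4]),
                         kind = "regulatory")
  enr <- cluster_tf_enrichment(cl, map, rn)
  p1 <- enr$p[enr$cluster == 1]
  expect_equal(p1, 1 / choose(8, 4), tolerance = 1e-12)
  expect_equal(p1, hyper_enum(8, 4, 4, 4), tolerance = 1e-12)
  expect_equal(enr$p[enr$cluster == 2], 1.0)

  # a TF binding every enzyme gene is never enriched
  rn_all <- physical_network(data.frame(from = "TFall", to = genes),
                             kind = "regulatory")
  enr_all <- cluster_tf_enrichment(cl, map, rn_all)
  expect_true(all(enr_all$p == 1))

  # no TFs overlapping the universe: empty result
  rn_none <- physical_network(data.frame(from = "TFx", to = "zz"),
                              kind = "regulatory")
  expect_equal(nrow(cluster_tf_enrichment(cl, map, rn_none)), 0)
})

test_that("highly regulated clusters require top-importance enriched TFs", {
  imp <- structure(data.frame(tf = sprintf("T%03d", 1:100),
                              importance = rev(seq_len(100)) / 100,
                              rank = 1:100),
                   class = c("tf_importance", "data.frame"))
  enr <- data.frame(cluster = c(1L, 1L, 2L, 2L, 3L),
                    tf = c("T001", "T002", "T050", "T085", "T001"),
                    p = c(0.001, 0.01, 0.02, 0.04, 0.2))
  out <- select_highly_regulated_clusters(enr, imp, alpha = 0.25)
  # cluster 1: the two top-scoring TFs -> one-sided KS p below 0.25
  expect_true(out$selected[out$cluster == 1])
  ks_direct <- suppressWarnings(
    ks.test(imp$importance[1:2], imp$importance, alternative = "less"))
  expect_equal(out$ks_p[out$cluster == 1], ks_direct$p.value)
  # cluster 3 has a single sub-threshold enrichment: not testable
  expect_false(out$selected[out$cluster == 3])
  expect_true(is.na(out$ks_p[out$cluster == 3]))
})

test_that("uniformly sampled enriched TFs are selected at about the KS alpha", {
  imp <- structure(data.frame(tf = sprintf("T%03d", 1:100),
                              importance = seq_len(100) / 100, rank = 100:1),
                   class = c("tf_importance", "data.frame"))
  set.seed(75)
  hits <- replicate(200, {
    tfs <- sample(imp$tf, 8)
    enr <- data.frame(cluster = 1L, tf = tfs, p = 0.001)
    select_highly_regulated_clusters(enr, imp, alpha = 0.25)$selected
  })
  # discrete two-sample KS p-values make the rate only approximately alpha
  expect_gt(mean(hits), 0.10)
  expect_lt(mean(hits), 0.40)
})

test_that("subsystem enrichment isolates a planted subsystem", {
  # one subsystem everywhere: p = 1 for every (cluster, subsystem)
  map1 <- reaction_map(data.frame(reaction = sprintf("R%d", 1:6),
                                  gene = sprintf("g%d", 1:6), subsystem = "only"))
  cl <- structure(list(membership = setNames(rep(1:2, each = 3), sprintf("R%d", 1:6)),
                       k = 2L, linkage = "average", condition = "toy"),
                  class = "reaction_clustering")
  expect_true(all(subsystem_enrichment(cl, map1)$p == 1))

  # a subsystem concentrated in one cluster is that cluster's minimal p
  map2 <- reaction_map(data.frame(
    reaction = sprintf("R%d", 1:6), gene = sprintf("g%d", 1:6),
    subsystem = c("planted", "planted", "planted", "bg", "bg", "bg")))
  enr <- subsystem_enrichment(cl, map2)
  hit <- enr[enr$cluster == 1 & enr$subsystem == "planted", ]
  expect_equal(hit$p, 1 / choose(6, 3), tolerance = 1e-12)
  expect_equal(hit$p, min(enr$p))
})
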