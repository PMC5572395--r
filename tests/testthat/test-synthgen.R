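# Ground-truth generators: determinism, planted correlation levels,
# physical-network fixtures, reaction maps, hub partners and NB counts.

test_that("identical seeds give bit-identical studies", {
  a <- gen_study(small_config(seed = 7))
  b <- gen_study(small_config(seed = 7))
  expect_identical(a$expression, b$expression)
  expect_identical(a$rn$edges, b$rn$edges)
  expect_identical(a$ppin$edges, b$ppin$edges)
  expect_identical(a$reaction_map$enzymes, b$reaction_map$enzymes)
  expect_identical(gen_counts(a), gen_counts(b))
  c <- gen_study(small_config(seed = 8))
  expect_false(identical(a$expression, c$expression))
})

test_that("adding downstream generators never perturbs expression modules", {
  base <- gen_expression(small_config(seed = 9))
  full <- gen_reaction_map(gen_ppin(gen_regulatory_network(
    gen_expression(small_config(seed = 9)))))
  mod_genes <- names(base$truth$modules)
  expect_identical(base$latent$tissue_1[mod_genes, ],
                   full$latent$tissue_1[mod_genes, ])
})

test_that("within-module latent correlation converges to the planted rho", {
  cfg <- synth_config(n_genes = 120, n_conditions = 1, samples_per_condition = 2000,
                      n_modules = 2, module_correlation = c(0.8, 0),
                      n_tfs = 4, targets_per_tf = 4, n_reactions = 10,
                      hub_partner_count = 2, seed = 10)
  sim <- gen_expression(cfg)
  L <- sim$latent$tissue_1
  m1 <- names(sim$truth$modules)[sim$truth$modules == 1]
  r1 <- cor(t(L[m1, ]))
  expect_lt(abs(mean(r1[upper.tri(r1)]) - 0.8), 3 / sqrt(2000))

  # rho = 0 module: members are independent
  m2 <- names(sim$truth$modules)[sim$truth$modules == 2]
  r2 <- cor(t(L[m2, ]))
  expect_lt(abs(mean(r2[upper.tri(r2)])), 0.05)

  # two members of a rho = 0.8 module: sample r within +/- 0.05 at n = 2000
  expect_lt(abs(cor(L[m1[1], ], L[m1[2], ]) - 0.8), 0.05)
})

test_that("the disease condition loses module 1 correlation only", {
  sim <- gen_expression(small_config(seed = 11))
  m1 <- names(sim$truth$modules)[sim$truth$modules == sim$truth$decorrelated_module]
  m2 <- names(sim$truth$modules)[sim$truth$modules == 2]
  rd <- cor(t(sim$latent$disease[m1, ]))
  rt <- cor(t(sim$latent$tissue_1[m1, ]))
  expect_lt(mean(rd[upper.tri(rd)]), 0.15)
  expect_gt(mean(rt[upper.tri(rt)]), 0.6)
  rd2 <- cor(t(sim$latent$disease[m2, ]))
  expect_gt(mean(rd2[upper.tri(rd2)]), 0.6)
})

test_that("config validation rejects degenerate settings", {
  expect_error(synth_config(samples_per_condition = 2), "samples_per_condition")
  expect_error(synth_config(module_correlation = 1), "module_correlation")
  expect_error(synth_config(de_fold_change = 0), "de_fold_change")
  expect_error(synth_config(ppin_density = 0), "ppin_density")
  expect_error(synth_config(enzymes_per_reaction = c(3, 1)), "enzymes_per_reaction")
  expect_error(synth_config(n_genes = 40), "layout")
  expect_error(synth_config(targets_per_tf = 1000), "targets_per_tf")
  expect_error(synth_config(tf_effect = NaN), "non-finite")
})

test_that("shared causal TFs raise pair correlation as the factor model predicts", {
  cfg <- synth_config(n_genes = 260, n_conditions = 1, samples_per_condition = 2000,
                      n_modules = 2, module_correlation = 0.8, n_tfs = 30,
                      targets_per_tf = 20, tf_effect = 1, n_reactions = 10,
                      hub_partner_count = 2, seed = 12)
  sim <- gen_regulatory_network(gen_expression(cfg))
  tg <- sim$truth$tf_targets
  expect_equal(length(tg), 3L)  # 10% of 30 TFs are causal
  pool <- sim$truth$layout$pool
  L <- sim$latent$tissue_1
  n_shared <- function(a, b) sum(vapply(tg, function(t) all(c(a, b) %in% t), logical(1)))
  pairs <- t(combn(pool, 2))
  shared <- apply(pairs, 1, function(p) n_shared(p[1], p[2]))
  r <- vapply(seq_len(nrow(pairs)),
              function(i) cor(L[pairs[i, 1], ], L[pairs[i, 2], ]), numeric(1))
  # every pool gene is bound by exactly 2 causal TFs of weight b:
  # corr = j b^2 / (1 + 2 b^2); here b = 1 -> 1/3 and 2/3
  expect_equal(mean(r[shared == 1]), 1 / 3, tolerance = 0.05)
  expect_equal(mean(r[shared == 2]), 2 / 3, tolerance = 0.05)
  expect_gt(mean(r[shared == 2]), mean(r[shared == 1]))
})

test_that("regulatory network construction covers causal TFs with >= 2 targets", {
  sim <- gen_regulatory_network(gen_expression(small_config(seed = 13)))
  edges <- sim$rn$edges
  expect_true(all(sim$truth$causal_tfs %in% edges$from))
  n_targets <- table(edges$from[edges$from %in% sim$truth$causal_tfs])
  expect_true(all(n_targets >= 2))
  # with zero effect, targets of the same TF stay at background correlation
  cfg0 <- synth_config(n_genes = 260, n_conditions = 1, samples_per_condition = 500,
                       n_modules = 2, module_correlation = 0.8, n_tfs = 30,
                       targets_per_tf = 20, tf_effect = 0, n_reactions = 10,
                       hub_partner_count = 2, seed = 13)
  sim0 <- gen_regulatory_network(gen_expression(cfg0))
  pool <- sim0$truth$layout$pool
  L <- sim0$latent$tissue_1
  rp <- cor(t(L[pool, ]))
  expect_lt(abs(mean(rp[upper.tri(rp)])), 0.05)
})

test_that("ppin respects density, loops and the within-module fraction", {
  # density 1 on a tiny universe gives the complete graph
  cfg <- synth_config(n_genes = 70, n_conditions = 1, samples_per_condition = 30,
                      n_modules = 2, module_correlation = 0.8, n_tfs = 2,
                      targets_per_tf = 2, ppin_density = 1, n_reactions = 5,
                      hub_partner_count = 2, seed = 14)
  sim <- gen_ppin(gen_expression(cfg))
  expect_equal(nrow(sim$ppin$edges), choose(70, 2))
  expect_true(all(sim$ppin$edges$from != sim$ppin$edges$to))

  # zero within-module fraction: mean edge r stays at background level
  sim2 <- gen_ppin(gen_expression(small_config(seed = 15)),
                   within_module_fraction = 0)
  tab <- correlation_table(sim2$expression$tissue_1)
  expect_lt(mean_edge_coexpression(sim2$ppin$edges, tab)$mean_r, 0.1)
  # half within modules: clearly above background
  sim3 <- gen_ppin(gen_expression(small_config(seed = 15)),
                   within_module_fraction = 0.5)
  expect_gt(mean_edge_coexpression(sim3$ppin$edges, tab)$mean_r, 0.2)
})

test_that("reaction map honours enzyme ranges and plants module-1 enzymes", {
  cfg <- small_config(seed = 16, enzymes_per_reaction = c(1, 1))
  sim <- gen_reaction_map(gen_expression(cfg))
  expect_true(all(lengths(sim$reaction_map$enzymes) == 1))

  sim2 <- gen_reaction_map(gen_expression(small_config(seed = 17)))
  planted <- sim2$truth$planted_reactions
  m1 <- names(sim2$truth$modules)[sim2$truth$modules == 1]
  expect_true(all(unlist(sim2$reaction_map$enzymes[planted]) %in% m1))
  expect_true(all(sim2$reaction_map$subsystem[planted] == "planted_subsystem"))
  # non-planted reactions never draw module-1 enzymes
  others <- setdiff(names(sim2$reaction_map$enzymes), planted)
  expect_false(any(unlist(sim2$reaction_map$enzymes[others]) %in% m1))
})

test_that("hub partners are condition-specific or ubiquitous as planted", {
  cfg <- small_config(seed = 18)
  sim <- gen_hub_dataset(gen_expression(cfg))
  hub <- sim$truth$hub
  top_n <- cfg$hub_partner_count + cfg$n_ubiq
  lists <- lapply(sim$expression, function(e) {
    hub_neighborhood(correlation_table(e), e, hub, top_n = top_n)$gene
  })
  spec1 <- sim$truth$hub_specific$tissue_1
  in_lists <- vapply(lists, function(g) mean(spec1 %in% g), numeric(1))
  expect_equal(unname(in_lists["tissue_1"]), 1.0)
  # planted specific partners appear in fewer than 3 conditions' lists
  per_gene <- vapply(spec1, function(g) sum(vapply(lists, function(l) g %in% l,
                                                  logical(1))), numeric(1))
  expect_true(all(per_gene < 3))
  # ubiquitous partners appear in every condition's list
  ubiq <- sim$truth$hub_ubiquitous
  expect_true(all(vapply(lists, function(l) all(ubiq %in% l), logical(1))))
})

test_that("counts are integer NB draws with the planted mean-variance law", {
  cfg <- synth_config(n_genes = 120, n_conditions = 1, samples_per_condition = 30,
                      n_modules = 2, module_correlation = 0, n_tfs = 4,
                      targets_per_tf = 4, n_reactions = 10, hub_partner_count = 2,
                      de_fold_change = 1, nb_dispersion = 0.15, seed = 19)
  sim <- gen_expression(cfg)
  cts <- gen_counts(sim, groupsizes = c(2500, 2500))
  k <- cts$counts
  expect_true(all(k >= 0) && all(k == round(k)))
  expect_equal(nrow(cts$de_genes), 0)  # fold change 1 -> nothing planted
  # empirical var ~ mu + a' mu^2 over 5000 draws per gene, where the
  # quadratic coefficient a' folds in the lognormal(0, 0.2) library noise:
  # a' = (a E[s^2] + Var(s)) / E[s]^2 with E[s] = e^{0.02}, E[s^2] = e^{0.08}
  mu <- rowMeans(k)
  v <- apply(k, 1, var)
  big <- mu > 50
  ratio <- (v[big] - mu[big]) / mu[big]^2
  a_eff <- (0.15 * exp(0.08) + (exp(0.08) - exp(0.04))) / exp(0.04)
  expect_equal(median(ratio), a_eff, tolerance = 0.035)
})

test_that("planted DE genes are the ones shifted between groups", {
  sim <- gen_expression(small_config(seed = 20))
  cts <- gen_counts(sim, groupsizes = c(50, 50))
  expect_equal(nrow(cts$de_genes),
               round(0.1 * (sim$config$n_genes + sim$config$n_tfs)))
  expect_true(all(abs(cts$de_genes$log2_fc) == 2))  # 4-fold
  expect_setequal(unique(sign(cts$de_genes$log2_fc)), c(-1, 1))
  k <- sweep(cts$counts, 2, cts$size_factors, "/")
  up <- cts$de_genes$gene[cts$de_genes$log2_fc > 0]
  lr <- log2(rowMeans(k[up, cts$groups$high, drop = FALSE]) + 1) -
    log2(rowMeans(k[up, cts$groups$low, drop = FALSE]) + 1)
  expect_gt(median(lr), 1.5)
})

test_that("ground truth is consistent with every emitted component", {
  sim <- gen_study(small_config(seed = 21))
  universe <- rownames(sim$expression$tissue_1$values)
  expect_true(all(names(sim$truth$modules) %in% universe))
  expect_true(all(unlist(sim$truth$hub_specific) %in% universe))
  expect_true(all(sim$truth$hub_ubiquitous %in% universe))
  expect_true(sim$truth$hub %in% universe)
  expect_true(all(sim$truth$causal_tfs %in% sim$rn$edges$from))
  expect_true(all(unlist(sim$reaction_map$enzymes) %in% universe))
  expect_true(all(sim$truth$planted_reactions %in% sim$reaction_map$reactions))
  expect_true(all(c(sim$ppin$edges$from, sim$ppin$edges$to) %in% universe))
  cts <- gen_counts(sim)
  expect_true(all(cts$de_genes$gene %in% universe))
})
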