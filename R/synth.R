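# Synthetic multi-condition study generator.
#
# The generator plants known structure so every pipeline stage can be
# validated against ground truth: correlation modules via a one-factor model,
# TF-driven co-regulation via additive shared factors, a PPIN with a tunable
# within-module edge fraction, a reaction map whose planted subsystem draws
# enzymes from a module that is decorrelated in the disease condition, a hub
# gene with condition-specific partners, and negative-binomial counts with
# planted fold changes.

# latent -> TPM-like scale; correlations downstream are computed on these
# positive values, so planted latent correlations are recovered with
# attenuation, not exactly. The moderate log-sd keeps expression-scale
# sample correlations close to the latent ones; a larger spread would give
# Pearson r on the exponential scale a heavy noise tail that drowns the
# planted ordering of pair correlations.
.LOG_MU <- 2
.LOG_SIGMA <- 0.5

#' Configuration for the synthetic study generator
#'
#' Fixes every size, effect and rate of the synthetic study, plus the master
#' seed. One RNG stream per generator is derived from the seed at
#' construction time, so adding or re-running one generator never perturbs
#' the draws of another, and identical seeds give bit-identical studies.
#'
#' Gene layout (derived): `floor(n_genes / (2 * n_modules))` genes per
#' correlation module; a TF target pool of `2 * targets_per_tf` genes; one
#' hub gene; `hub_partner_count` condition-specific hub partners per
#' condition plus `ceiling(hub_partner_count / 2)` ubiquitous partners; the
#' remainder background. TF genes are appended to the universe. The last
#' condition is the disease condition; correlation module 1 is decorrelated
#' there.
#'
#' @param n_genes number of non-TF genes; default 300.
#' @param n_conditions number of conditions (last one = disease); default 3.
#' @param samples_per_condition samples per condition (>= 3); default 200.
#' @param n_modules number of planted correlation modules; default 5.
#' @param module_correlation within-module latent correlation(s) in `[0, 1)`,
#'   recycled over modules; default 0.8.
#' @param n_tfs number of TFs (10% causal, rounded, at least 1); default 33.
#' @param targets_per_tf targets per TF (>= 2); default 30.
#' @param tf_effect additive latent weight of each causal TF on its targets;
#'   default 2 (pairs sharing two causal TFs then exceed the within-module
#'   correlation, so TF-driven pairs reach the top co-expression quantile).
#' @param ppin_density fraction of all gene pairs carrying a PPI edge, in
#'   `(0, 1]`; default 0.02.
#' @param n_reactions number of metabolic reactions; default 250 (with the
#'   default 100-cluster cut this leaves a realistic agglomeration depth --
#'   at near-equal reaction counts almost no merges happen and clusters are
#'   singletons).
#' @param enzymes_per_reaction integer range `c(min, max)` of enzymes per
#'   reaction; default `c(1, 2)`.
#' @param hub_partner_count condition-specific hub partners per condition;
#'   default 12.
#' @param de_fraction fraction of genes with planted differential expression;
#'   default 0.1.
#' @param de_fold_change planted fold change (> 0; 1 means none); default 4.
#' @param nb_dispersion negative-binomial dispersion of counts (> 0);
#'   default 0.1.
#' @param seed master integer seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 300, n_conditions = 3,
                         samples_per_condition = 200, n_modules = 5,
                         module_correlation = 0.8, n_tfs = 33,
                         targets_per_tf = 30, tf_effect = 2,
                         ppin_density = 0.02, n_reactions = 250,
                         enzymes_per_reaction = c(1, 2),
                         hub_partner_count = 12, de_fraction = 0.1,
                         de_fold_change = 4, nb_dispersion = 0.1, seed = 1L) {
  num <- c(n_genes = n_genes, n_conditions = n_conditions,
           samples_per_condition = samples_per_condition, n_modules = n_modules,
           n_tfs = n_tfs, targets_per_tf = targets_per_tf, tf_effect = tf_effect,
           ppin_density = ppin_density, n_reactions = n_reactions,
           hub_partner_count = hub_partner_count, de_fraction = de_fraction,
           de_fold_change = de_fold_change, nb_dispersion = nb_dispersion,
           seed = seed, module_correlation = module_correlation,
           enzymes_per_reaction = enzymes_per_reaction)
  if (any(!is.finite(num))) stop("non-finite config value", call. = FALSE)
  for (nm in c("n_genes", "n_conditions", "n_modules", "n_tfs", "n_reactions",
               "hub_partner_count")) {
    stop_if_not_count(get(nm), nm)
  }
  stop_if_not_count(samples_per_condition, "samples_per_condition", min = 3L)
  stop_if_not_count(targets_per_tf, "targets_per_tf", min = 2L)
  if (targets_per_tf > n_genes) stop("targets_per_tf > n_genes", call. = FALSE)
  if (any(module_correlation < 0) || any(module_correlation >= 1)) {
    stop("module_correlation must be in [0, 1)", call. = FALSE)
  }
  if (de_fold_change <= 0) stop("de_fold_change must be > 0", call. = FALSE)
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (ppin_density <= 0 || ppin_density > 1) stop("ppin_density must be in (0, 1]", call. = FALSE)
  if (length(enzymes_per_reaction) != 2L || any(enzymes_per_reaction < 1) ||
      enzymes_per_reaction[1] > enzymes_per_reaction[2] ||
      any(enzymes_per_reaction != round(enzymes_per_reaction))) {
    stop("enzymes_per_reaction must be an integer range c(min, max), min >= 1", call. = FALSE)
  }
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0, 1]", call. = FALSE)

  module_size <- max(2L, n_genes %/% (2L * n_modules))
  n_causal <- max(1L, as.integer(round(0.1 * n_tfs)))
  # each pool gene is bound by exactly two causal TFs (one when only one
  # causal TF exists), so every causal TF binds ~targets_per_tf pool genes
  pool_size <- if (n_causal > 1L) {
    as.integer(ceiling(n_causal * targets_per_tf / 2))
  } else as.integer(targets_per_tf)
  n_ubiq <- as.integer(ceiling(hub_partner_count / 2))
  need <- n_modules * module_size + pool_size + 1L +
    n_conditions * hub_partner_count + n_ubiq
  if (need > n_genes) {
    stop(sprintf("gene layout needs %d genes but n_genes = %d", need, n_genes),
         call. = FALSE)
  }
  cfg <- list(n_genes = as.integer(n_genes), n_conditions = as.integer(n_conditions),
              samples_per_condition = as.integer(samples_per_condition),
              n_modules = as.integer(n_modules),
              module_correlation = rep_len(module_correlation, n_modules),
              n_tfs = as.integer(n_tfs), targets_per_tf = as.integer(targets_per_tf),
              tf_effect = tf_effect, ppin_density = ppin_density,
              n_reactions = as.integer(n_reactions),
              enzymes_per_reaction = as.integer(enzymes_per_reaction),
              hub_partner_count = as.integer(hub_partner_count),
              de_fraction = de_fraction, de_fold_change = de_fold_change,
              nb_dispersion = nb_dispersion, seed = as.integer(seed),
              module_size = module_size, pool_size = pool_size,
              n_causal = n_causal, n_ubiq = n_ubiq)
  # one independent stream per generator, all derived from the master seed
  set.seed(cfg$seed)
  cfg$stream_seeds <- setNames(
    sample.int(.Machine$integer.max - 1L, 6L),
    c("expression", "rn", "ppin", "reactions", "hub", "counts"))
  structure(cfg, class = "synth_config")
}

# deterministic gene layout shared by all generators
synth_layout <- function(config) {
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  tf_genes <- sprintf("tf%03d", seq_len(config$n_tfs))
  i <- 0L
  take <- function(n) {
    out <- genes[seq.int(i + 1L, i + n)]
    i <<- i + n
    out
  }
  modules <- lapply(seq_len(config$n_modules), function(m) take(config$module_size))
  names(modules) <- paste0("module_", seq_len(config$n_modules))
  pool <- take(config$pool_size)
  hub <- take(1L)
  cond_names <- if (config$n_conditions == 1L) "tissue_1" else {
    c(paste0("tissue_", seq_len(config$n_conditions - 1L)), "disease")
  }
  specific <- lapply(cond_names, function(cn) take(config$hub_partner_count))
  names(specific) <- cond_names
  ubiquitous <- take(config$n_ubiq)
  background <- genes[seq.int(i + 1L, config$n_genes)]
  list(genes = genes, tf_genes = tf_genes, all = c(genes, tf_genes),
       modules = modules, pool = pool, hub = hub, conditions = cond_names,
       hub_specific = specific, hub_ubiquitous = ubiquitous,
       background = background)
}

# Each gene's latent is standardized by its theoretical sd before the
# exponential map: additive TF factors inflate latent variance, and
# unstandardized high-variance genes would have their expression-scale
# Pearson r attenuated far more than others (lognormal tail effect).
rebuild_expression <- function(sim) {
  scale <- sim$latent_scale
  sim$expression <- lapply(names(sim$latent), function(cn) {
    z <- sim$latent[[cn]] / scale[rownames(sim$latent[[cn]])]
    expression_matrix(exp(.LOG_MU + .LOG_SIGMA * z), condition = cn, unit = "TPM")
  })
  names(sim$expression) <- names(sim$latent)
  sim
}

#' Generate per-condition expression with planted correlation modules
#'
#' Draws, for each condition, a latent genes-by-samples matrix in which the
#' members of module m follow the one-factor model
#' `x = sqrt(rho_m) * f_m + sqrt(1 - rho_m) * eps` (within-module latent
#' correlation exactly `rho_m` in the population) and all other genes are
#' independent standard normals. Module 1 is generated without its factor in
#' the disease condition (the planted decorrelation that downstream stages
#' must detect). Values are mapped to a TPM-like positive scale by
#' `exp(2 + x)`.
#'
#' @param config a [synth_config()].
#' @return Object of class `synth_study`: list with `config`, `truth`
#'   (gene -> module map, disease condition, decorrelated module, layout),
#'   `latent` (per-condition latent matrices) and `expression`
#'   (per-condition [expression_matrix()]s).
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lay <- synth_layout(config)
  set.seed(config$stream_seeds[["expression"]])
  n_s <- config$samples_per_condition
  n_all <- length(lay$all)
  decor_module <- 1L
  disease <- if (config$n_conditions > 1L) "disease" else NA_character_
  latent <- lapply(lay$conditions, function(cn) {
    L <- matrix(rnorm(n_all * n_s), n_all, n_s,
                dimnames = list(lay$all, sprintf("%s_s%03d", cn, seq_len(n_s))))
    for (m in seq_len(config$n_modules)) {
      if (identical(cn, disease) && m == decor_module) next
      rho <- config$module_correlation[m]
      f <- rnorm(n_s)
      members <- lay$modules[[m]]
      L[members, ] <- sqrt(rho) * matrix(f, length(members), n_s, byrow = TRUE) +
        sqrt(1 - rho) * L[members, ]
    }
    L
  })
  names(latent) <- lay$conditions
  module_map <- setNames(rep(seq_len(config$n_modules), each = config$module_size),
                         unlist(lay$modules))
  truth <- list(modules = module_map, decorrelated_module = decor_module,
                disease_condition = disease, hub = lay$hub, layout = lay)
  sim <- structure(list(config = config, truth = truth, latent = latent,
                        latent_scale = setNames(rep(1, n_all), lay$all)),
                   class = "synth_study")
  rebuild_expression(sim)
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("<synth_study> %d genes (+%d TFs) x %d samples x %d conditions, seed %d\n",
              x$config$n_genes, x$config$n_tfs, x$config$samples_per_condition,
              x$config$n_conditions, x$config$seed))
  cat(sprintf("  components: %s\n",
              paste(intersect(c("expression", "rn", "ppin", "reaction_map"),
                              names(x)), collapse = ", ")))
  invisible(x)
}

#' Generate a TF-target regulatory network and inject causal TF effects
#'
#' Designates 10% of TFs (at least one) as causal. The target pool is
#' partitioned over pairs of causal TFs so that every pool gene is bound by
#' exactly two of them (by the single one when only one exists): with a
#' homogeneous number of bound TFs per gene, the expected pair correlation
#' under the additive factor model, `j * b^2 / (1 + 2 b^2)` for `j` shared
#' TFs of weight `b = tf_effect`, increases cleanly with `j`. Per condition,
#' each causal TF contributes an additive latent factor to all its targets
#' and to its own gene. Decoy TFs are bound to `ceiling(targets_per_tf / 2)`
#' random genes outside both the modules and the pool, so decoy binding
#' carries no co-expression signal at all. The edge list covers causal and
#' decoy TFs alike.
#'
#' @param sim a `synth_study` from [gen_expression()].
#' @return The study with `rn` (a regulatory [physical_network()]) added,
#'   expression updated, and `truth$causal_tfs` / `truth$tf_targets` set.
#' @export
gen_regulatory_network <- function(sim) {
  stopifnot(inherits(sim, "synth_study"))
  config <- sim$config
  lay <- sim$truth$layout
  set.seed(config$stream_seeds[["rn"]])
  n_causal <- config$n_causal
  causal <- lay$tf_genes[seq_len(n_causal)]
  decoys <- setdiff(lay$tf_genes, causal)
  if (n_causal > 1L) {
    tf_pairs <- combn(causal, 2L)
    assign_pair <- rep_len(seq_len(ncol(tf_pairs)), length(lay$pool))
    causal_targets <- lapply(setNames(causal, causal), function(tf) {
      lay$pool[apply(tf_pairs[, assign_pair, drop = FALSE] == tf, 2L, any)]
    })
  } else {
    causal_targets <- setNames(list(lay$pool), causal)
  }
  n_decoy_targets <- max(2L, as.integer(ceiling(config$targets_per_tf / 2)))
  targets <- c(
    causal_targets,
    lapply(setNames(decoys, decoys),
           function(tf) sample(setdiff(lay$genes, c(unlist(lay$modules), lay$pool)),
                               n_decoy_targets)))
  edges <- data.frame(
    from = rep(names(targets), lengths(targets)),
    to = unlist(targets, use.names = FALSE), stringsAsFactors = FALSE)
  if (config$tf_effect != 0) {
    for (cn in names(sim$latent)) {
      for (tf in causal) {
        h <- rnorm(config$samples_per_condition)
        tg <- targets[[tf]]
        sim$latent[[cn]][tg, ] <- sim$latent[[cn]][tg, ] +
          config$tf_effect * matrix(h, length(tg), length(h), byrow = TRUE)
        sim$latent[[cn]][tf, ] <- sim$latent[[cn]][tf, ] + config$tf_effect * h
      }
    }
  } else {
    # keep the stream advanced identically so later draws do not shift
    for (cn in names(sim$latent)) {
      for (tf in causal) rnorm(config$samples_per_condition)
    }
  }
  # latent variance is now 1 + (number of bound causal TFs) * tf_effect^2
  n_bound <- table(unlist(targets[causal]))
  sim$latent_scale[names(n_bound)] <-
    sqrt(1 + as.integer(n_bound) * config$tf_effect^2)
  sim$latent_scale[causal] <- sqrt(1 + config$tf_effect^2)
  sim$rn <- physical_network(edges, kind = "regulatory")
  sim$truth$causal_tfs <- causal
  sim$truth$tf_targets <- targets[causal]
  rebuild_expression(sim)
}

#' Generate a protein-protein interaction network
#'
#' Places `round(ppin_density * choose(G, 2))` undirected edges over the
#' (non-TF) gene universe: a fraction `within_module_fraction` of them inside
#' planted correlation modules (physically coupled and co-expressed), the
#' remainder uniformly among all gene pairs. No self-loops or duplicates.
#'
#' @param sim a `synth_study` from [gen_expression()].
#' @param within_module_fraction fraction of edges placed within modules;
#'   default 0.5.
#' @return The study with `ppin` (a ppi [physical_network()]) added.
#' @export
gen_ppin <- function(sim, within_module_fraction = 0.5) {
  stopifnot(inherits(sim, "synth_study"))
  config <- sim$config
  lay <- sim$truth$layout
  if (within_module_fraction < 0 || within_module_fraction > 1) {
    stop("within_module_fraction must be in [0, 1]", call. = FALSE)
  }
  set.seed(config$stream_seeds[["ppin"]])
  n_nodes <- length(lay$genes)
  m <- max(1L, as.integer(round(config$ppin_density * choose(n_nodes, 2))))
  max_within <- sum(vapply(lay$modules, function(g) choose(length(g), 2), numeric(1)))
  n_within <- min(as.integer(round(within_module_fraction * m)),
                  as.integer(max_within))
  keys <- character(0)
  a_all <- character(0); b_all <- character(0)
  draw <- function(n, within) {
    if (within) {
      mod <- sample(seq_along(lay$modules), n, replace = TRUE)
      a <- vapply(mod, function(mm) sample(lay$modules[[mm]], 1L), character(1))
      b <- vapply(mod, function(mm) sample(lay$modules[[mm]], 1L), character(1))
    } else {
      a <- sample(lay$genes, n, replace = TRUE)
      b <- sample(lay$genes, n, replace = TRUE)
    }
    list(a = a, b = b)
  }
  for (phase in c(TRUE, FALSE)) {
    goal <- if (phase) n_within else m
    while (length(keys) < goal) {
      d <- draw(goal - length(keys), phase)
      ok <- d$a != d$b
      k <- pair_key(d$a[ok], d$b[ok])
      fresh <- !(k %in% keys) & !duplicated(k)
      keys <- c(keys, k[fresh])
      a_all <- c(a_all, d$a[ok][fresh]); b_all <- c(b_all, d$b[ok][fresh])
    }
  }
  sim$ppin <- physical_network(data.frame(from = a_all, to = b_all), kind = "ppi")
  sim$truth$ppin_within_fraction <- within_module_fraction
  sim
}

#' Generate a reaction-enzyme map aligned to planted modules
#'
#' Builds `n_reactions` reactions with 1..k enzymes each. The planted
#' subsystem's reactions draw their enzymes from correlation module 1 -- the
#' module that loses its factor in the disease condition -- so its reaction
#' cluster is strongly co-expressed in the reference tissues and decorrelated
#' in disease. Up to three further subsystems are aligned to stable modules
#' (co-expressed everywhere, a realistic pathway-structure control); the
#' remaining reactions draw enzymes from genes outside module 1. Within each
#' block, genes are assigned without reuse until the block's pool is
#' exhausted, so reaction pairs do not share enzymes unless a pool is
#' oversubscribed.
#'
#' @param sim a `synth_study` from [gen_expression()].
#' @return The study with `reaction_map` (a [reaction_map()]) added and
#'   `truth$planted_reactions` / `truth$planted_subsystem` set.
#' @export
gen_reaction_map <- function(sim) {
  stopifnot(inherits(sim, "synth_study"))
  config <- sim$config
  lay <- sim$truth$layout
  set.seed(config$stream_seeds[["reactions"]])
  n_rxn <- config$n_reactions
  rng <- config$enzymes_per_reaction
  n_planted <- min(max(4L, as.integer(round(n_rxn / 15))), n_rxn)
  aligned_modules <- if (config$n_modules >= 2L) {
    seq.int(2L, min(config$n_modules, 4L))
  } else integer(0)
  n_aligned <- length(aligned_modules) * n_planted
  if (n_planted + n_aligned > n_rxn) {
    aligned_modules <- integer(0)
    n_aligned <- 0L
  }
  rxn_ids <- sprintf("rxn%04d", seq_len(n_rxn))
  n_enz <- sample(seq.int(rng[1], rng[2]), n_rxn, replace = TRUE)
  subsystem <- character(n_rxn)
  enzymes <- vector("list", n_rxn)
  # enzymes are drawn from a shuffled cycle per gene pool, so genes are not
  # reused across reactions until a pool is exhausted: promiscuous shared
  # enzymes would pin reaction pairs at r_max = 1 in every condition and
  # mask the planted co-expression structure
  pool_taker <- function(genes) {
    bag <- sample(genes)
    function(n) {
      if (n > length(bag)) bag <<- c(bag, sample(genes))
      out <- bag[seq_len(n)]
      bag <<- bag[-seq_len(n)]
      out
    }
  }
  take_bg <- pool_taker(setdiff(lay$genes,
                                unlist(lay$modules[c(1L, aligned_modules)])))
  take_planted <- pool_taker(lay$modules[[1L]])
  take_aligned <- lapply(lay$modules[aligned_modules], pool_taker)
  idx <- 1L
  for (r in seq_len(n_planted)) {
    enzymes[[idx]] <- take_planted(min(n_enz[idx], config$module_size))
    subsystem[idx] <- "planted_subsystem"
    idx <- idx + 1L
  }
  for (m in seq_along(aligned_modules)) {
    for (r in seq_len(n_planted)) {
      enzymes[[idx]] <- take_aligned[[m]](min(n_enz[idx], config$module_size))
      subsystem[idx] <- sprintf("module_%d_subsystem", aligned_modules[m])
      idx <- idx + 1L
    }
  }
  bg_labels <- paste0("background_", 1:5)
  while (idx <= n_rxn) {
    enzymes[[idx]] <- take_bg(n_enz[idx])
    subsystem[idx] <- bg_labels[1L + (idx %% 5L)]
    idx <- idx + 1L
  }
  assignments <- data.frame(
    reaction = rep(rxn_ids, lengths(enzymes)),
    gene = unlist(enzymes), subsystem = rep(subsystem, lengths(enzymes)),
    stringsAsFactors = FALSE)
  sim$reaction_map <- reaction_map(assignments)
  sim$truth$planted_reactions <- rxn_ids[seq_len(n_planted)]
  sim$truth$planted_subsystem <- "planted_subsystem"
  sim
}

#' Plant condition-specific and ubiquitous hub partners
#'
#' Couples each condition's designated specific partners to the hub gene at
#' the module correlation level -- in that condition only -- and the
#' ubiquitous partners to the hub in every condition. The hub's own latent
#' trajectory serves as the shared factor.
#'
#' @param sim a `synth_study` from [gen_expression()].
#' @return The study with hub structure injected into expression and
#'   `truth$hub_specific` / `truth$hub_ubiquitous` / `truth$hub_enriched`
#'   (per-condition tissue-enriched annotation stand-in) set.
#' @export
gen_hub_dataset <- function(sim) {
  stopifnot(inherits(sim, "synth_study"))
  config <- sim$config
  lay <- sim$truth$layout
  set.seed(config$stream_seeds[["hub"]])
  rho <- config$module_correlation[1L]
  hub <- lay$hub
  n_s <- config$samples_per_condition
  for (cn in names(sim$latent)) {
    h <- sim$latent[[cn]][hub, ]
    couple <- function(genes) {
      eps <- matrix(rnorm(length(genes) * n_s), length(genes), n_s)
      sim$latent[[cn]][genes, ] <<-
        sqrt(rho) * matrix(h, length(genes), n_s, byrow = TRUE) + sqrt(1 - rho) * eps
    }
    couple(lay$hub_specific[[cn]])
    couple(lay$hub_ubiquitous)
  }
  sim$truth$hub_specific <- lay$hub_specific
  sim$truth$hub_ubiquitous <- lay$hub_ubiquitous
  sim$truth$hub_enriched <- lay$hub_specific
  rebuild_expression(sim)
}

#' Generate negative-binomial counts with planted fold changes
#'
#' Draws a genes-by-samples integer count matrix for a two-group comparison.
#' Per-gene baseline means are tied to the disease-condition expression of
#' the study (scaled to sequencing-depth counts), per-sample library sizes
#' vary log-normally, and counts follow a negative binomial with dispersion
#' `nb_dispersion` (`var = mu + dispersion * mu^2`). A `de_fraction` of genes
#' is shifted by `de_fold_change` in the "high" group, alternately up- and
#' down-regulated; with `de_fold_change = 1` no differential expression is
#' planted.
#'
#' @param sim a `synth_study` from [gen_expression()].
#' @param groupsizes integer vector `c(high, low)`; default `c(93, 93)`, the
#'   upper/lower-quartile group size of a 371-sample cohort.
#' @return list with `counts` (integer matrix), `groups` (list `high`, `low`
#'   of sample ids), `de_genes` (data.frame `gene`, `log2_fc`), `size_factors`
#'   (true per-sample library scalings).
#' @export
gen_counts <- function(sim, groupsizes = c(93, 93)) {
  stopifnot(inherits(sim, "synth_study"))
  config <- sim$config
  set.seed(config$stream_seeds[["counts"]])
  if (length(groupsizes) != 2L || any(groupsizes < 2)) {
    stop("groupsizes must be two counts >= 2", call. = FALSE)
  }
  cond <- if (!is.na(sim$truth$disease_condition)) sim$truth$disease_condition else
    names(sim$expression)[1L]
  base_tpm <- rowMeans(sim$expression[[cond]]$values)
  lambda <- base_tpm * 10  # depth scaling: mean TPM -> expected counts
  genes <- names(lambda)
  n_h <- as.integer(groupsizes[1L]); n_l <- as.integer(groupsizes[2L])
  samples <- c(sprintf("high_s%03d", seq_len(n_h)), sprintf("low_s%03d", seq_len(n_l)))
  grp <- rep(c("high", "low"), c(n_h, n_l))
  lib <- exp(rnorm(n_h + n_l, 0, 0.2))  # true library-size variation
  lfc <- setNames(numeric(length(genes)), genes)
  if (config$de_fraction > 0 && config$de_fold_change != 1) {
    n_de <- as.integer(round(config$de_fraction * length(genes)))
    de <- sample(genes, n_de)
    signs <- rep(c(1, -1), length.out = n_de)
    lfc[de] <- signs * log2(config$de_fold_change)
  }
  mu <- outer(lambda, lib)
  mu[, grp == "high"] <- mu[, grp == "high"] * 2^lfc
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                   nrow(mu), ncol(mu), dimnames = list(genes, samples))
  de_genes <- data.frame(gene = genes[lfc != 0], log2_fc = lfc[lfc != 0],
                         stringsAsFactors = FALSE, row.names = NULL)
  list(counts = counts, groups = list(high = samples[grp == "high"],
                                      low = samples[grp == "low"]),
       de_genes = de_genes, size_factors = setNames(lib, samples))
}

#' Generate a complete synthetic study
#'
#' Runs every generator in order: expression modules, regulatory network,
#' PPIN, reaction map and hub partners.
#'
#' @param config a [synth_config()].
#' @param within_module_fraction passed to [gen_ppin()].
#' @return A fully populated `synth_study`.
#' @export
gen_study <- function(config, within_module_fraction = 0.5) {
  sim <- gen_expression(config)
  sim <- gen_regulatory_network(sim)
  sim <- gen_ppin(sim, within_module_fraction = within_module_fraction)
  sim <- gen_reaction_map(sim)
  gen_hub_dataset(sim)
}
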