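mc <- mini_cancer_model()

test_that("gene-family values aggregate onto nodes as specified", {
  mapping <- gene_node_mapping(mini_cancer_mapping(), mc$model)
  # single datum passes through
  one <- map_genes_to_nodes(tibble::tibble(gene = "AKT1", value = 0.9),
                            mapping, "continuous")
  expect_equal(one$value[one$node == "AKT"], 0.9)
  # family members average
  two <- map_genes_to_nodes(
    tibble::tibble(gene = c("AKT1", "AKT2"), value = c(0.8, 0.4)),
    mapping, "continuous")
  expect_equal(two$value[two$node == "AKT"], 0.6)
  # opposite discrete effects in one family drop the node with a warning
  expect_warning(
    conf <- map_genes_to_nodes(
      tibble::tibble(gene = c("AKT1", "AKT2"), value = c(0L, 1L)),
      mapping, "discrete"),
    "conflicting")
  expect_false("AKT" %in% conf$node)
  expect_error(gene_node_mapping(tibble::tibble(node = "NOPE", gene = "X"),
                                 mc$model), "absent")
})

test_that("strict node variants freeze value, initial state and opposing rate", {
  s <- apply_strict_nv(mc$settings, "p53", 0)
  i <- match("p53", s$nodes$node)
  expect_equal(s$nodes$istate[i], 0)
  expect_equal(s$nodes$k_up[i], 0)
  s1 <- apply_strict_nv(mc$settings, "AKT", 1)
  j <- match("AKT", s1$nodes$node)
  expect_equal(s1$nodes$istate[j], 1)
  expect_equal(s1$nodes$k_down[j], 0)
  # a frozen node's simulated probability equals its value at every bin
  res <- simulate_ensemble(mc$model, s1, record_states = FALSE)
  expect_true(all(res$node_prob[, "AKT"] == 1))
  res0 <- simulate_ensemble(mc$model, s, record_states = FALSE)
  expect_true(all(res0$node_prob[, "p53"] == 0))
})

test_that("soft node variants implement the amplification-factor rate map", {
  s <- apply_soft_nv(mc$settings, "AKT", 1, amplification = 100)
  i <- match("AKT", s$nodes$node)
  expect_identical(s$nodes$k_up[i], 100)
  expect_identical(s$nodes$k_down[i], 0.01)
  expect_equal(s$nodes$istate[i], 1)
  s <- apply_soft_nv(mc$settings, "AKT", 0.5)
  expect_equal(s$nodes$k_up[match("AKT", s$nodes$node)], 1)
  expect_equal(s$nodes$k_down[match("AKT", s$nodes$node)], 1)
  s <- apply_soft_nv(mc$settings, "AKT", 0.8, amplification = 100)
  expect_equal(s$nodes$k_up[i], 100^0.6, tolerance = 1e-12)
  expect_equal(s$nodes$k_down[i], 100^-0.6, tolerance = 1e-12)
  expect_error(apply_soft_nv(mc$settings, "AKT", 1.2), "outside")
  expect_error(apply_soft_nv(mc$settings, "AKT", 0.5, amplification = 1),
               "exceed 1")
})

test_that("soft rates are reciprocal and monotone in the normalized value", {
  set.seed(8)
  norms <- c(0, runif(20), 1)
  ks <- vapply(norms, function(v) {
    s <- apply_soft_nv(mc$settings, "RAS", v, amplification = 100)
    i <- match("RAS", s$nodes$node)
    expect_equal(s$nodes$k_up[i] * s$nodes$k_down[i], 1, tolerance = 1e-12)
    s$nodes$k_up[i]
  }, numeric(1))
  expect_true(all(diff(ks[order(norms)]) > 0))
  expect_equal(ks[1], 1 / 100)
  expect_equal(ks[length(ks)], 100)
})

test_that("precedence resolution ranks data types and separates channels", {
  strat <- personalization_strategy("case5")
  strict <- tibble::tibble(node = "p53", value = 0, data_type = "mutation")
  soft <- tibble::tibble(node = c("p53", "AKT", "AKT"),
                         value = c(0.9, 0.7, 0.2),
                         data_type = c("rna", "protein", "rna"))
  prof <- resolve_precedence(strict, soft, strat)
  # a strict node receives no soft assignment
  expect_false("p53" %in% prof$soft$node)
  expect_equal(prof$strict$value[prof$strict$node == "p53"], 0)
  # protein beats rna in the soft channel
  expect_equal(prof$soft$value[prof$soft$node == "AKT"], 0.7)
  # nodes without data are untouched
  expect_false("RAS" %in% c(prof$strict$node, prof$soft$node))
  # mutation-derived strict beats CNA-derived strict
  strat2 <- personalization_strategy("case2")
  s2 <- resolve_precedence(
    tibble::tibble(node = c("p53", "p53"), value = c(0, 1),
                   data_type = c("cna", "mutation")),
    NULL, strat2)
  expect_equal(s2$strict$value, 1)
  expect_equal(s2$strict$data_type, "mutation")
})

test_that("named recipes wire the documented channels", {
  expect_equal(personalization_strategy("case1")$strict_data, "mutation")
  expect_equal(personalization_strategy("case2")$strict_data,
               c("mutation", "cna"))
  expect_equal(personalization_strategy("case3")$soft_data, "cna")
  expect_equal(personalization_strategy("case4")$strict_data, character(0))
  expect_equal(personalization_strategy("case6")$soft_data,
               c("protein", "rna"))
  expect_error(personalization_strategy("case9"), "unknown strategy")
})

test_that("cohort personalization is deterministic, rule-preserving and filters by data", {
  gen <- generate_genomic_profiles(n_samples = 12, seed = 3)
  prof <- build_discrete_profile(gen$mutations, gen$cna, gen$kb)
  expr <- generate_model_expression(n_samples = 12, seed = 3)
  ep <- process_expression(expr, n_null = 300)
  bnd_before <- write_bnd(mc$model)
  pc <- personalize_cohort(
    mc$model, mc$settings, mini_cancer_mapping(),
    personalization_strategy("case5"),
    mutation_effects = dplyr::filter(prof, data_type == "mutation"),
    rna_normalized = ep$normalized)
  # the rule file is untouched by personalization
  expect_identical(write_bnd(mc$model), bnd_before)
  # two identical patients get identical settings apart from their seeds
  p <- names(pc$settings)[1]
  again <- personalize_cohort(
    mc$model, mc$settings, mini_cancer_mapping(),
    personalization_strategy("case5"),
    mutation_effects = dplyr::filter(prof, data_type == "mutation"),
    rna_normalized = ep$normalized)
  expect_identical(pc$settings[[p]]$nodes, again$settings[[p]]$nodes)
  # personalized rates obey the soft map for a pure-RNA node
  s1 <- pc$settings[[p]]
  ras_genes <- c("KRAS", "NRAS", "HRAS")
  rna <- ep$normalized
  present <- intersect(ras_genes, rna$gene)
  if (length(present) > 0 &&
      !"RAS" %in% prof$gene) {
    want <- mean(vapply(present, function(g) rna[[p]][rna$gene == g],
                        numeric(1)))
    i <- match("RAS", s1$nodes$node)
    expect_equal(s1$nodes$k_up[i], 100^(2 * (want - 0.5)), tolerance = 1e-9)
  }
  # a strategy whose only soft channel is protein excludes patients without it
  expect_error(
    personalize_cohort(mc$model, mc$settings, mini_cancer_mapping(),
                       personalization_strategy("custom",
                                                strict_data = "mutation",
                                                soft_data = "protein"),
                       mutation_effects = dplyr::filter(prof, data_type == "mutation")),
    "not supplied")
})

test_that("per-patient seeds depend on the patient, not the cohort", {
  s1 <- logiprofile:::derive_seed(42L, "P0001")
  s2 <- logiprofile:::derive_seed(42L, "P0002")
  expect_true(s1 != s2)
  expect_identical(s1, logiprofile:::derive_seed(42L, "P0001"))
  expect_true(s1 >= 0 && s1 < 2^31)
})

test_that("strictly fixed nodes dominate every downstream simulation", {
  # across several personalizations, frozen nodes sit at their value in
  # every time bin
  gen <- generate_genomic_profiles(n_samples = 8, seed = 11)
  prof <- build_discrete_profile(gen$mutations, gen$cna, gen$kb)
  pc <- personalize_cohort(
    mc$model, mc$settings, mini_cancer_mapping(),
    personalization_strategy("case2"),
    mutation_effects = dplyr::filter(prof, data_type == "mutation"),
    cna_effects = dplyr::filter(prof, data_type == "cna"))
  for (p in names(pc$settings)[1:min(4, length(pc$settings))]) {
    s <- pc$settings[[p]]
    s$n_trajectories <- 200L
    frozen <- s$nodes$node[(s$nodes$k_up == 0 & s$nodes$istate == 0) |
                             (s$nodes$k_down == 0 & s$nodes$istate == 1)]
    res <- simulate_ensemble(mc$model, s, record_states = FALSE)
    for (nm in frozen) {
      val <- s$nodes$istate[match(nm, s$nodes$node)]
      expect_true(all(res$node_prob[, nm] == val), label = paste(p, nm))
    }
  }
})
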