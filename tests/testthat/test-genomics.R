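kb <- fixture_knowledge_base()

test_that("mutation cascade routes produce the expected effects", {
  mut <- tibble::tribble(
    ~sample, ~gene,    ~variant_classification, ~protein_change, ~sift,               ~polyphen,
    "P1",    "TP53",   "Nonsense_Mutation",     "p.Q192*",       NA,                  NA,
    "P1",    "PIK3CA", "Missense_Mutation",     "p.H1047R",      "deleterious(0.01)", NA,
    "P2",    "TP53",   "Missense_Mutation",     "p.R175H",       NA,                  "probably_damaging",
    "P2",    "KRAS",   "Missense_Mutation",     "p.G12V",        "deleterious(0.02)", NA,
    "P3",    "ATM",    "Missense_Mutation",     "p.S49C",        NA,                  "possibly_damaging",
    "P3",    "KRAS",   "Missense_Mutation",     "p.G12D",        NA,                  NA,
    "P4",    "TP53",   "Silent",                "p.L35L",        NA,                  NA,
    "P4",    "AKT1",   "Missense_Mutation",     "p.E17K",        "deleterious(0.01)", NA
  )
  eff <- infer_mutation_effects(mut, kb)
  get <- function(s, g) eff[eff$sample == s & eff$gene == g, ]
  expect_equal(get("P1", "TP53")$value, 0L)       # truncating -> LOF
  expect_equal(get("P1", "TP53")$source, "truncating")
  expect_equal(get("P1", "PIK3CA")$value, 1L)     # curated GOF variant
  expect_equal(get("P1", "PIK3CA")$source, "known_variant")
  expect_equal(get("P2", "TP53")$value, 0L)       # curated LOF variant
  expect_equal(get("P2", "KRAS")$value, 1L)       # oncogene missense
  expect_equal(get("P2", "KRAS")$source, "gene_role")
  expect_equal(get("P3", "ATM")$value, 0L)        # TSG missense, PolyPhen possibly damaging
  # oncogene missense without a deleteriousness label yields nothing
  expect_equal(nrow(get("P3", "KRAS")), 0L)
  # silent and unknown-gene missense yield nothing
  expect_equal(nrow(get("P4", "TP53")), 0L)
  expect_equal(nrow(get("P4", "AKT1")), 0L)
})

test_that("CNA inference keeps only the high-confidence extremes", {
  cna <- tibble::tibble(
    sample = "P1", gene = c("MYC", "PTEN", "A", "B", "C"),
    gistic_call = c(2L, -2L, 1L, -1L, 0L)
  )
  eff <- infer_cna_effects(cna)
  expect_equal(nrow(eff), 2L)
  expect_equal(eff$value[eff$gene == "MYC"], 1L)
  expect_equal(eff$value[eff$gene == "PTEN"], 0L)
  expect_error(infer_cna_effects(dplyr::mutate(cna, gistic_call = 5L)),
               "-2..2")
  # matrix input works too
  m <- matrix(c(2L, -2L), nrow = 2, dimnames = list(c("G1", "G2"), "P1"))
  em <- infer_cna_effects(m)
  expect_equal(em$value, c(1L, 0L))
})

test_that("profile assembly applies mutation-over-CNA and source precedence", {
  mut <- tibble::tibble(
    sample = c("P1", "P2", "P2"),
    gene = c("CCND1", "TP53", "TP53"),
    variant_classification = c("Missense_Mutation", "Nonsense_Mutation",
                               "Missense_Mutation"),
    protein_change = c("p.A1B", "p.Q192*", "p.R175H"),
    sift = c("deleterious(0.01)", NA, NA),
    polyphen = c(NA, NA, "probably_damaging")
  )
  cna <- tibble::tibble(sample = c("P1", "P3"), gene = c("CCND1", "ATM"),
                        gistic_call = c(2L, -2L))
  prof <- build_discrete_profile(mut, cna, kb)
  # CCND1 (P1): oncogene missense (1) and amplification (1); the mutation
  # route wins the provenance
  expect_equal(prof$data_type[prof$sample == "P1" & prof$gene == "CCND1"],
               "mutation")
  # within mutations, truncating outranks the curated missense variant
  expect_equal(prof$value[prof$sample == "P2" & prof$gene == "TP53"], 0L)
  expect_equal(prof$source[prof$sample == "P2" & prof$gene == "TP53"],
               "truncating")
  expect_equal(prof$value[prof$sample == "P3" & prof$gene == "ATM"], 0L)

  # LOF mutation beats amplification for the same gene
  mut2 <- tibble::tibble(sample = "P1", gene = "TP53",
                         variant_classification = "Nonsense_Mutation",
                         protein_change = "p.X1*", sift = NA, polyphen = NA)
  cna2 <- tibble::tibble(sample = "P1", gene = "TP53", gistic_call = 2L)
  p2 <- build_discrete_profile(mut2, cna2, kb)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$value, 0L)
  expect_equal(p2$data_type, "mutation")
})

test_that("profiles are deterministic under record permutation", {
  gen <- generate_genomic_profiles(n_samples = 25, mut_rate = 0.3,
                                   cna_rate = 0.3, seed = 5)
  p1 <- build_discrete_profile(gen$mutations, gen$cna, gen$kb)
  set.seed(99)
  p2 <- build_discrete_profile(gen$mutations[sample(nrow(gen$mutations)), ],
                               gen$cna[sample(nrow(gen$cna)), ], gen$kb)
  expect_identical(p1, p2)
})

test_that("same-precedence conflicts drop the gene with a warning", {
  mut <- tibble::tibble(
    sample = "P1", gene = "PIK3CA",
    variant_classification = "Missense_Mutation",
    protein_change = c("p.H1047R", "p.X9Y"),
    sift = "deleterious(0.01)", polyphen = NA
  )
  kb2 <- knowledge_base(
    known_variants = tibble::tibble(gene = c("PIK3CA", "PIK3CA"),
                                    protein_change = c("p.H1047R", "p.X9Y"),
                                    effect = c("GOF", "LOF")),
    gene_roles = tibble::tibble(gene = character(0), role = character(0))
  )
  expect_warning(p <- build_discrete_profile(mut, NULL, kb2), "conflicting")
  expect_equal(nrow(p), 0L)
})

test_that("knowledge-base validation catches duplicates and bad effects", {
  expect_error(knowledge_base(
    tibble::tibble(gene = c("A", "A"), protein_change = c("p.X", "p.X"),
                   effect = c("GOF", "LOF")),
    tibble::tibble(gene = "B", role = "oncogene")), "duplicate")
  expect_error(knowledge_base(
    tibble::tibble(gene = "A", protein_change = "p.X", effect = "UP"),
    tibble::tibble(gene = "B", role = "oncogene")), "GOF or LOF")
})
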