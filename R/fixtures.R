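# Seeded synthetic-data generators: every input the pipeline consumes can
# be produced in-code, so the full workflow (inference -> personalization
# -> simulation -> stratification) runs without downloads. The generators
# emulate the distribution classes, sparsity patterns and survival
# structure the method exercises, not any particular real cohort.

#' Three-node toy model
#'
#' Input node A keeps its initial state (self-rule), B copies A and C is
#' the complement of A; all rates 1. From (A=1, B=0, C=1) the unique
#' absorbing state is (1, 1, 0).
#'
#' @return list with `model` (read-outs B, C) and default `settings`.
#' @export
toy_model <- function() {
  model <- parse_bnd("
    node A { logic = A; }
    node B { logic = A; }
    node C { logic = !A; }
  ")
  model <- set_outputs(model, c("B", "C"))
  list(model = model, settings = default_settings(model))
}

#' Eleven-node miniature cancer signaling model
#'
#' A desk-scale network with the canonical wiring motifs: growth-factor
#' input (EGF) driving RAS/PI3K/AKT, a DNA-damage input engaging p53,
#' mutual inhibition between AKT and p53 (a stochastic race deciding cell
#' fate), p21 blocking CyclinD, and two phenotype read-outs -
#' Proliferation follows CyclinD, Apoptosis latches once CASP fires
#' (self-sustaining, hence absorbing). Small enough (11 nodes) for the
#' exact master-equation oracle.
#'
#' Wild-type conditions have both inputs present and p53 activation
#' (rate 2) faster than the three-step AKT cascade, so the p53 branch
#' wins the race in 26 of 27 trajectories: the exact asymptotic
#' probabilities are Proliferation = 1/27 and Apoptosis = 26/27 - a
#' low-proliferative, high-apoptotic baseline with most nodes resolved
#' near 0 or 1, as in larger published cancer models.
#'
#' @return list with `model` (read-outs Proliferation, Apoptosis) and
#'   default `settings` (inputs at istate 1, all other nodes initially
#'   off).
#' @export
mini_cancer_model <- function() {
  model <- parse_bnd("
    node EGF        { logic = EGF; }
    node DNA_Damage { logic = DNA_Damage; }
    node RAS        { logic = EGF; }
    node PI3K       { logic = RAS; }
    node AKT        { logic = PI3K & !p53; }
    node p53        { logic = (p53 | DNA_Damage) & !AKT; rate_up = 2; }
    node p21        { logic = p53; }
    node CyclinD    { logic = RAS & !p21; }
    node CASP       { logic = p53 & !AKT; }
    node Proliferation { logic = CyclinD; }
    node Apoptosis  { logic = CASP | Apoptosis; }
  ")
  model <- set_outputs(model, c("Proliferation", "Apoptosis"))
  settings <- default_settings(model)
  settings$nodes$istate <- ifelse(
    settings$nodes$node %in% c("EGF", "DNA_Damage"), 1, 0)
  list(model = model, settings = settings)
}

#' Gene-to-node mapping for the miniature cancer model
#'
#' Covers family nodes (RAS from KRAS/NRAS/HRAS, AKT from AKT1/AKT2,
#' CASP from CASP3/CASP9).
#'
#' @return mapping tibble (`node`, `gene`).
#' @export
mini_cancer_mapping <- function() {
  tibble::tribble(
    ~node,        ~gene,
    "EGF",        "EGF",
    "DNA_Damage", "ATM",
    "RAS",        "KRAS",
    "RAS",        "NRAS",
    "RAS",        "HRAS",
    "PI3K",       "PIK3CA",
    "AKT",        "AKT1",
    "AKT",        "AKT2",
    "p53",        "TP53",
    "p21",        "CDKN1A",
    "CyclinD",    "CCND1",
    "CASP",       "CASP3",
    "CASP",       "CASP9"
  )
}

#' Fictional knowledge base for the fixtures
#'
#' Small curated tables covering every inference route: two known variants
#' (one GOF, one LOF), oncogene and tumor-suppressor roles, and genes with
#' no annotation. Synthetic content for testing only - not derived from
#' any curation database.
#'
#' @return a [knowledge_base()].
#' @export
fixture_knowledge_base <- function() {
  knowledge_base(
    known_variants = tibble::tribble(
      ~gene,     ~protein_change, ~effect,
      "PIK3CA",  "p.H1047R",      "GOF",
      "TP53",    "p.R175H",       "LOF"
    ),
    gene_roles = tibble::tribble(
      ~gene,    ~role,
      "KRAS",   "oncogene",
      "CCND1",  "oncogene",
      "TP53",   "tumor_suppressor",
      "ATM",    "tumor_suppressor"
    )
  )
}

#' Expression-cohort generative specification
#'
#' Defaults describe a cohort on a log-like expression scale with three
#' clearly identifiable distribution classes: balanced bimodal genes with
#' standardized mode distance 4, unimodal Gaussians, and 70%-zero
#' zero-inflated genes with an exponential tail.
#'
#' @param n_samples cohort size (>= 10).
#' @param n_per_class genes simulated per class.
#' @param bimodal list `pi` (lower-component weight), `mu1`, `mu2`, `sigma`.
#' @param unimodal list `median`, `scale` (MAD-equivalent).
#' @param zero_inflated list `zero_frac`, `tail_scale`.
#' @param seed RNG seed.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 1000L, n_per_class = 20L,
                        bimodal = list(pi = 0.5, mu1 = 4, mu2 = 8, sigma = 1),
                        unimodal = list(median = 8, scale = 1),
                        zero_inflated = list(zero_frac = 0.7, tail_scale = 2),
                        seed = 42L) {
  stopifnot(n_samples >= 10L, n_per_class >= 1L,
            bimodal$pi >= 0, bimodal$pi <= 1, bimodal$sigma > 0,
            unimodal$scale > 0,
            zero_inflated$zero_frac >= 0, zero_inflated$zero_frac < 1,
            zero_inflated$tail_scale > 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_per_class = as.integer(n_per_class),
                 bimodal = bimodal, unimodal = unimodal,
                 zero_inflated = zero_inflated, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic expression cohort with known classes
#'
#' Values are clipped at zero (log-like nonnegative scale). Ground-truth
#' class labels are returned for recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @return list with `matrix` (genes x samples, rownames = genes,
#'   colnames = S001...) and `truth` (tibble `gene`, `class`).
#' @export
generate_expression_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  k <- spec$n_per_class
  local_seed(spec$seed)
  rows <- list()
  truth <- list()
  for (j in seq_len(k)) {
    b <- spec$bimodal
    comp <- stats::runif(n) < b$pi
    v <- ifelse(comp, stats::rnorm(n, b$mu1, b$sigma),
                stats::rnorm(n, b$mu2, b$sigma))
    g <- sprintf("BIM%03d", j)
    rows[[g]] <- pmax(v, 0)
    truth[[g]] <- "bimodal"
  }
  for (j in seq_len(k)) {
    u <- spec$unimodal
    v <- stats::rnorm(n, u$median, u$scale / 0.6745)  # MAD(normal) = 0.6745 sd
    g <- sprintf("UNI%03d", j)
    rows[[g]] <- pmax(v, 0)
    truth[[g]] <- "unimodal"
  }
  for (j in seq_len(k)) {
    z <- spec$zero_inflated
    zero <- stats::runif(n) < z$zero_frac
    v <- ifelse(zero, 0, stats::rexp(n, rate = 1 / z$tail_scale))
    g <- sprintf("ZIN%03d", j)
    rows[[g]] <- v
    truth[[g]] <- "zero_inflated"
  }
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("S%04d", seq_len(n))
  list(matrix = m,
       truth = tibble::tibble(gene = names(truth),
                              class = unlist(truth, use.names = FALSE)))
}

# run code under a temporary seed, restoring the caller's RNG state
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  set.seed(seed)
  invisible(NULL)
}

#' Generate unimodal expression for a panel of model genes
#'
#' Companion to [generate_genomic_profiles()]: produces a cohort expression
#' matrix for the given genes (unimodal Gaussians with jittered medians)
#' whose sample names (`P0001`, ...) line up with the genomic tables, so
#' the full personalization pipeline can run on fixtures alone.
#'
#' @param genes character vector of gene symbols (default: all genes of the
#'   miniature model mapping).
#' @param n_samples cohort size.
#' @param median_range medians are drawn uniformly from this range.
#' @param scale MAD-equivalent per-gene dispersion.
#' @param seed RNG seed.
#' @return genes x samples matrix.
#' @export
generate_model_expression <- function(genes = unique(mini_cancer_mapping()$gene),
                                      n_samples = 50L,
                                      median_range = c(6, 10), scale = 1,
                                      seed = 43L) {
  local_seed(seed)
  med <- stats::runif(length(genes), median_range[1], median_range[2])
  m <- t(vapply(seq_along(genes), function(i) {
    pmax(stats::rnorm(n_samples, med[i], scale / 0.6745), 0)
  }, numeric(n_samples)))
  rownames(m) <- genes
  colnames(m) <- sprintf("P%04d", seq_len(n_samples))
  m
}

# record templates covering every mutation-inference route; `expected` is
# the record-level effect (NA = no effect by construction)
mutation_route_templates <- function() {
  tibble::tribble(
    ~gene,    ~variant_classification, ~protein_change, ~sift,                ~polyphen,           ~expected, ~route,
    "TP53",   "Nonsense_Mutation",     "p.Q192*",       NA_character_,        NA_character_,       0L,        "truncating",
    "ATM",    "Frame_Shift_Del",       "p.K750fs",      NA_character_,        NA_character_,       0L,        "truncating",
    "TP53",   "Splice_Site",           NA_character_,   NA_character_,        NA_character_,       0L,        "truncating",
    "PIK3CA", "Missense_Mutation",     "p.H1047R",      "deleterious(0.01)",  NA_character_,       1L,        "known_variant",
    "TP53",   "Missense_Mutation",     "p.R175H",       NA_character_,        "probably_damaging", 0L,        "known_variant",
    "KRAS",   "Missense_Mutation",     "p.G12V",        "deleterious(0.03)",  NA_character_,       1L,        "gene_role",
    "ATM",    "Missense_Mutation",     "p.S49C",        NA_character_,        "possibly_damaging", 0L,        "gene_role",
    "KRAS",   "Missense_Mutation",     "p.A59T",        "tolerated(0.4)",     "benign",            NA_integer_, "missense_no_label",
    "TP53",   "Silent",                "p.L35L",        NA_character_,        NA_character_,       NA_integer_, "silent",
    "AKT1",   "Missense_Mutation",     "p.E17K",        "deleterious(0.02)",  NA_character_,       NA_integer_, "missense_unknown_gene"
  )
}

cna_route_templates <- function() {
  tibble::tribble(
    ~gene,    ~gistic_call, ~expected,   ~route,
    "CCND1",  2L,           1L,          "amplification",
    "ATM",    -2L,          0L,          "homozygous_deletion",
    "CASP3",  1L,           NA_integer_, "low_confidence_gain",
    "AKT2",   -1L,          NA_integer_, "low_confidence_loss",
    "EGF",    0L,           NA_integer_, "neutral"
  )
}

#' Generate synthetic mutation and CNA tables with known effects
#'
#' The first samples receive the route-covering record templates
#' round-robin, guaranteeing that every inference-cascade branch is
#' exercised at least once; further records are sprinkled at the given
#' frequencies. Record-level ground truth is returned.
#'
#' @param n_samples cohort size.
#' @param mut_rate per-sample probability of each extra mutation template.
#' @param cna_rate per-sample probability of each extra CNA template.
#' @param seed RNG seed.
#' @return list with `mutations` (MAF-like tibble), `cna` (long tibble),
#'   `truth_mutations`, `truth_cna` (record tibbles with `expected` and
#'   `route`), and `kb` (the fixture knowledge base).
#' @export
generate_genomic_profiles <- function(n_samples = 50L, mut_rate = 0.1,
                                      cna_rate = 0.1, seed = 42L) {
  stopifnot(mut_rate >= 0, mut_rate <= 1, cna_rate >= 0, cna_rate <= 1,
            n_samples >= 1L)
  local_seed(seed)
  samples <- sprintf("P%04d", seq_len(n_samples))
  mt <- mutation_route_templates()
  ct <- cna_route_templates()

  take <- function(templates, sample_id) {
    dplyr::mutate(templates, sample = sample_id, .before = 1)
  }
  mut_rows <- list()
  cna_rows <- list()
  # deterministic coverage: template i goes to sample ((i - 1) mod n) + 1
  for (i in seq_len(nrow(mt))) {
    mut_rows[[length(mut_rows) + 1L]] <-
      take(mt[i, ], samples[(i - 1L) %% n_samples + 1L])
  }
  for (i in seq_len(nrow(ct))) {
    cna_rows[[length(cna_rows) + 1L]] <-
      take(ct[i, ], samples[(i - 1L) %% n_samples + 1L])
  }
  # random extras
  for (s in samples) {
    hit <- stats::runif(nrow(mt)) < mut_rate
    if (any(hit)) mut_rows[[length(mut_rows) + 1L]] <- take(mt[hit, ], s)
    hit <- stats::runif(nrow(ct)) < cna_rate
    if (any(hit)) cna_rows[[length(cna_rows) + 1L]] <- take(ct[hit, ], s)
  }
  mut <- dplyr::bind_rows(mut_rows) %>% dplyr::distinct()
  cna <- dplyr::bind_rows(cna_rows) %>% dplyr::distinct()
  list(
    mutations = mut %>% dplyr::select("sample", "gene",
                                      "variant_classification",
                                      "protein_change", "sift", "polyphen"),
    cna = cna %>% dplyr::select("sample", "gene", "gistic_call"),
    truth_mutations = mut,
    truth_cna = cna,
    kb = fixture_knowledge_base()
  )
}

#' Survival-data generative specification
#'
#' @param baseline_hazard events per time unit for a hazard multiplier of 1.
#' @param hazard_multipliers named vector, group label -> multiplier.
#' @param censoring_rate target fraction of censored observations in [0, 1).
#' @param seed RNG seed.
#' @return a `survival_spec`.
#' @export
survival_spec <- function(baseline_hazard = 0.05,
                          hazard_multipliers = c(low = 1, high = 2),
                          censoring_rate = 0.2, seed = 42L) {
  stopifnot(baseline_hazard > 0, all(hazard_multipliers > 0),
            censoring_rate >= 0, censoring_rate < 1)
  structure(list(baseline_hazard = baseline_hazard,
                 hazard_multipliers = hazard_multipliers,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "survival_spec")
}

#' Generate exponential survival times with group-specific hazards
#'
#' Event times are exponential with hazard `baseline * multiplier[group]`;
#' censoring is an independent exponential calibrated to the requested
#' censoring rate (0 means every event is observed).
#'
#' @param groups data frame with columns `patient`, `group` (labels must
#'   appear in the spec's multipliers).
#' @param spec a [survival_spec()].
#' @return tibble `patient`, `time`, `event` (1 observed, 0 censored),
#'   `group`.
#' @export
generate_survival <- function(groups, spec = survival_spec()) {
  g <- tibble::as_tibble(groups)
  stopifnot(all(c("patient", "group") %in% names(g)))
  unknown <- setdiff(unique(g$group), names(spec$hazard_multipliers))
  if (length(unknown) > 0L)
    stop("group(s) without hazard multiplier: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  local_seed(spec$seed)
  rate <- spec$baseline_hazard * spec$hazard_multipliers[g$group]
  t_event <- stats::rexp(nrow(g), rate = rate)
  if (spec$censoring_rate > 0) {
    c_rate <- spec$baseline_hazard * spec$censoring_rate /
      (1 - spec$censoring_rate)
    t_cens <- stats::rexp(nrow(g), rate = c_rate)
  } else {
    t_cens <- rep(Inf, nrow(g))
  }
  tibble::tibble(
    patient = g$patient,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    group = g$group
  )
}

#' Write a complete fixture set to disk
#'
#' Emits every file format the pipeline consumes: BND + CFG for the
#' miniature model, expression TSV, MAF-like mutation TSV, CNA TSV,
#' knowledge-base TSVs and the gene-node mapping CSV.
#'
#' @param dir output directory.
#' @param seed RNG seed for the generators.
#' @return invisible character vector of written paths.
#' @export
write_fixtures <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mc <- mini_cancer_model()
  cohort <- generate_expression_cohort(cohort_spec(n_samples = 100L,
                                                   n_per_class = 5L,
                                                   seed = seed))
  gen <- generate_genomic_profiles(n_samples = 20L, seed = seed)
  paths <- c(
    bnd = file.path(dir, "mini_cancer.bnd"),
    cfg = file.path(dir, "mini_cancer.cfg"),
    expression = file.path(dir, "expression.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    cna = file.path(dir, "cna.tsv"),
    kb_variants = file.path(dir, "kb_variants.tsv"),
    kb_roles = file.path(dir, "kb_roles.tsv"),
    mapping = file.path(dir, "mapping.csv")
  )
  write_bnd(mc$model, paths["bnd"])
  write_cfg(mc$settings, mc$model, paths["cfg"])
  utils::write.table(
    data.frame(gene = rownames(cohort$matrix), cohort$matrix,
               check.names = FALSE),
    paths["expression"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gen$mutations, paths["mutations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gen$cna, paths["cna"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gen$kb$known_variants, paths["kb_variants"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gen$kb$gene_roles, paths["kb_roles"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(mini_cancer_mapping(), paths["mapping"], row.names = FALSE)
  invisible(paths)
}
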