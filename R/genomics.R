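# Functional inference for discrete genomic data: mutation records and
# GISTIC copy-number calls become per-gene 0/1 effects through a fixed
# decision cascade, with auditable sources and precedence.

TRUNCATING_CLASSES <- c("nonsense", "frameshift_ins", "frameshift_del",
                        "splice_site", "translation_start_site")

# normalize MAF-style variant classifications onto the controlled vocabulary
normalize_variant_class <- function(x) {
  key <- gsub("[ _]", "", tolower(x))
  dplyr::case_when(
    key %in% c("nonsense", "nonsensemutation") ~ "nonsense",
    key %in% c("frameshiftins", "frameshiftinsertion") ~ "frameshift_ins",
    key %in% c("frameshiftdel", "frameshiftdeletion") ~ "frameshift_del",
    key %in% c("splicesite", "splice") ~ "splice_site",
    key %in% c("translationstartsite", "startcodon") ~ "translation_start_site",
    key %in% c("missense", "missensemutation") ~ "missense",
    key %in% c("silent", "synonymous") ~ "silent",
    TRUE ~ "other"
  )
}

is_deleterious_label <- function(sift, polyphen) {
  sift_del <- !is.na(sift) & grepl("deleterious", tolower(sift))
  # "possibly_damaging" counts: inclusive reading of deleteriousness
  poly_dam <- !is.na(polyphen) & grepl("damaging", tolower(polyphen))
  sift_del | poly_dam
}

#' Build a knowledge base for mutation-effect inference
#'
#' @param known_variants data frame with columns `gene`, `protein_change`,
#'   `effect` ("GOF"/"LOF"): curated per-variant effects (OncoKB-like).
#' @param gene_roles data frame with columns `gene`, `role`
#'   ("oncogene"/"tumor_suppressor"): driver-gene role calls.
#' @return a `knowledge_base`.
#' @export
knowledge_base <- function(known_variants, gene_roles) {
  kv <- tibble::as_tibble(known_variants)
  gr <- tibble::as_tibble(gene_roles)
  stopifnot(all(c("gene", "protein_change", "effect") %in% names(kv)),
            all(c("gene", "role") %in% names(gr)))
  if (anyDuplicated(kv[, c("gene", "protein_change")]))
    stop("duplicate (gene, protein_change) keys in known-variant table",
         call. = FALSE)
  kv$effect <- toupper(kv$effect)
  if (!all(kv$effect %in% c("GOF", "LOF")))
    stop("known-variant effects must be GOF or LOF", call. = FALSE)
  gr$role <- tolower(gr$role)
  structure(list(known_variants = kv, gene_roles = gr),
            class = "knowledge_base")
}

#' Infer functional effects of mutation records
#'
#' Decision cascade per record: (1) truncating classes (nonsense,
#' frameshift insertions/deletions, splice-site, translation-start-site)
#' are loss of function, value 0; (2) missense variants found in the
#' known-variant table take the curated GOF (1) / LOF (0) effect;
#' (3) remaining missense variants in oncogenes give 1, in tumor
#' suppressors 0. Routes (2) and (3) additionally require a
#' deleteriousness label (SIFT "deleterious" or PolyPhen "damaging"), which
#' rules likely passengers out; truncating calls do not. Silent, other and
#' unmatched records yield no effect.
#'
#' @param mutations data frame with columns `sample`, `gene`,
#'   `variant_classification`, `protein_change`, `sift`, `polyphen`
#'   (MAF-style column names `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#'   `Variant_Classification`, `HGVSp_Short`, `SIFT`, `PolyPhen` are also
#'   accepted).
#' @param kb a [knowledge_base()].
#' @return tibble with one row per record that produced an effect:
#'   `sample`, `gene`, `value` (0/1), `source` (truncating / known_variant
#'   / gene_role), `data_type` ("mutation").
#' @export
infer_mutation_effects <- function(mutations, kb) {
  mut <- normalize_mutation_columns(mutations)
  if (any(!nzchar(mut$gene)) || any(is.na(mut$gene)))
    stop("empty gene symbol in mutation table", call. = FALSE)
  mut$vc <- normalize_variant_class(mut$variant_classification)
  mut$deleterious <- is_deleterious_label(mut$sift, mut$polyphen)

  mut <- mut %>%
    dplyr::left_join(
      kb$known_variants %>%
        dplyr::select("gene", "protein_change", kv_effect = "effect"),
      by = c("gene", "protein_change")
    ) %>%
    dplyr::left_join(kb$gene_roles, by = "gene")

  mut %>%
    dplyr::mutate(
      value = dplyr::case_when(
        .data$vc %in% TRUNCATING_CLASSES ~ 0L,
        .data$vc == "missense" & .data$deleterious & !is.na(.data$kv_effect) ~
          as.integer(.data$kv_effect == "GOF"),
        .data$vc == "missense" & .data$deleterious & .data$role %in% "oncogene" ~ 1L,
        .data$vc == "missense" & .data$deleterious & .data$role %in% "tumor_suppressor" ~ 0L,
        TRUE ~ NA_integer_
      ),
      source = dplyr::case_when(
        .data$vc %in% TRUNCATING_CLASSES ~ "truncating",
        .data$vc == "missense" & .data$deleterious & !is.na(.data$kv_effect) ~ "known_variant",
        .data$vc == "missense" & .data$deleterious &
          .data$role %in% c("oncogene", "tumor_suppressor") ~ "gene_role",
        TRUE ~ NA_character_
      )
    ) %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::transmute(.data$sample, .data$gene, .data$value, .data$source,
                     data_type = "mutation")
}

normalize_mutation_columns <- function(mutations) {
  d <- tibble::as_tibble(mutations)
  ali <- c(sample = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
           variant_classification = "Variant_Classification",
           protein_change = "HGVSp_Short", sift = "SIFT", polyphen = "PolyPhen")
  for (nm in names(ali)) {
    if (!nm %in% names(d) && ali[[nm]] %in% names(d)) d[[nm]] <- d[[ali[[nm]]]]
  }
  need <- c("sample", "gene", "variant_classification")
  if (!all(need %in% names(d)))
    stop("mutation table must provide sample, gene and variant_classification",
         call. = FALSE)
  if (!"protein_change" %in% names(d)) d$protein_change <- NA_character_
  if (!"sift" %in% names(d)) d$sift <- NA_character_
  if (!"polyphen" %in% names(d)) d$polyphen <- NA_character_
  d[, c("sample", "gene", "variant_classification", "protein_change",
        "sift", "polyphen")]
}

#' Infer functional effects of copy-number calls
#'
#' Only the high-confidence extremes are used: GISTIC +2 (amplification)
#' gives value 1 and -2 (homozygous deletion) gives 0; -1, 0 and +1 are
#' discarded.
#'
#' @param cna data frame with columns `sample`, `gene`, `gistic_call`
#'   (integers in -2..2), or a gene-by-sample integer matrix with gene
#'   rownames.
#' @return tibble `sample`, `gene`, `value`, `source` ("gistic"),
#'   `data_type` ("cna").
#' @export
infer_cna_effects <- function(cna) {
  if (is.matrix(cna)) {
    cna <- tibble::as_tibble(cna, rownames = "gene") %>%
      tidyr::pivot_longer(-"gene", names_to = "sample",
                          values_to = "gistic_call")
  }
  d <- tibble::as_tibble(cna)
  stopifnot(all(c("sample", "gene", "gistic_call") %in% names(d)))
  if (any(!d$gistic_call %in% -2:2))
    stop("GISTIC calls must be integers in -2..2", call. = FALSE)
  d %>%
    dplyr::filter(.data$gistic_call %in% c(-2L, 2L)) %>%
    dplyr::transmute(.data$sample, .data$gene,
                     value = as.integer(.data$gistic_call == 2L),
                     source = "gistic", data_type = "cna")
}

#' Build per-sample discrete gene profiles from mutation and CNA effects
#'
#' Combines both effect tables with the fixed precedence: mutation-derived
#' effects always override CNA-derived ones for the same gene; among
#' mutation effects, truncating beats known-variant beats gene-role.
#' Conflicting effects at equal precedence (e.g. one GOF and one LOF known
#' variant in the same gene and sample) drop that gene for that sample
#' with a warning - a wrong forced state is worse than no constraint.
#'
#' @param mutations mutation table (see [infer_mutation_effects()]), or
#'   `NULL`.
#' @param cna CNA table or matrix (see [infer_cna_effects()]), or `NULL`.
#' @param kb a [knowledge_base()] (required when `mutations` given).
#' @return tibble `sample`, `gene`, `value`, `source`, `data_type` with one
#'   row per (sample, gene).
#' @export
build_discrete_profile <- function(mutations = NULL, cna = NULL, kb = NULL) {
  eff <- list()
  if (!is.null(mutations)) {
    if (is.null(kb)) stop("mutation inference requires a knowledge base", call. = FALSE)
    eff$mut <- infer_mutation_effects(mutations, kb)
  }
  if (!is.null(cna)) eff$cna <- infer_cna_effects(cna)
  all_eff <- dplyr::bind_rows(eff)
  if (nrow(all_eff) == 0L) {
    return(tibble::tibble(sample = character(0), gene = character(0),
                          value = integer(0), source = character(0),
                          data_type = character(0)))
  }
  prec <- c(truncating = 1L, known_variant = 2L, gene_role = 3L, gistic = 4L)
  resolved <- all_eff %>%
    dplyr::mutate(.prec = prec[.data$source]) %>%
    # sort before resolution so the output never depends on record order
    dplyr::arrange(.data$sample, .data$gene, .data$.prec, .data$value) %>%
    dplyr::group_by(.data$sample, .data$gene) %>%
    dplyr::filter(.data$.prec == min(.data$.prec)) %>%
    dplyr::summarise(
      n_values = dplyr::n_distinct(.data$value),
      value = .data$value[1],
      source = .data$source[1],
      data_type = .data$data_type[1],
      .groups = "drop"
    )
  conflicts <- resolved %>% dplyr::filter(.data$n_values > 1L)
  if (nrow(conflicts) > 0L) {
    warning(sprintf(
      "dropping %d gene/sample pair(s) with conflicting same-precedence effects: %s",
      nrow(conflicts),
      paste(utils::head(paste(conflicts$sample, conflicts$gene, sep = ":"), 5),
            collapse = ", ")), call. = FALSE)
    resolved <- resolved %>% dplyr::anti_join(
      conflicts, by = c("sample", "gene"))
  }
  resolved %>%
    dplyr::select("sample", "gene", "value", "source", "data_type") %>%
    dplyr::arrange(.data$sample, .data$gene)
}
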