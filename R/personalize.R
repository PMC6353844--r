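# Merging per-patient omics values onto model nodes and emitting one
# personalized simulation-settings object per patient. Two mechanisms:
# Strict Node Variants freeze a node (initial state set, opposing rate
# zeroed, rule overridden for good); Soft Node Variants bias the initial
# state and tilt the transition rates while the rule stays active.

#' Gene-to-node mapping table
#'
#' Model nodes often stand for gene families (e.g. an AKT node for AKT1/2/3);
#' the mapping lists, per node, the data genes that inform it.
#'
#' @param mapping data frame with columns `node`, `gene` (one row per pair).
#' @param model the `logical_model` the mapping must refer to.
#' @return validated mapping tibble.
#' @export
gene_node_mapping <- function(mapping, model) {
  m <- tibble::as_tibble(mapping)
  stopifnot(all(c("node", "gene") %in% names(m)))
  missing <- setdiff(unique(m$node), model$nodes)
  if (length(missing) > 0L)
    stop("mapping refers to node(s) absent from the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(is.na(m$gene) | !nzchar(m$gene)))
    stop("empty gene symbol in mapping", call. = FALSE)
  m[, c("node", "gene")]
}

#' Aggregate per-gene values onto model nodes
#'
#' Discrete values (0/1 effects): any definitive effect propagates to the
#' node; genes of one family voting for opposite values drop the node with
#' a warning. Continuous values: arithmetic mean of the available family
#' members.
#'
#' @param profile tibble with columns `gene`, `value` (one patient's data;
#'   a `source` column, if present, is carried along).
#' @param mapping a [gene_node_mapping()].
#' @param type `"discrete"` or `"continuous"`.
#' @return tibble `node`, `value` (+ `source` for discrete data).
#' @export
map_genes_to_nodes <- function(profile, mapping, type = c("discrete", "continuous")) {
  type <- match.arg(type)
  joined <- mapping %>%
    dplyr::inner_join(tibble::as_tibble(profile), by = "gene")
  if (nrow(joined) == 0L) {
    return(tibble::tibble(node = character(0), value = numeric(0)))
  }
  if (type == "continuous") {
    return(joined %>%
      dplyr::group_by(.data$node) %>%
      dplyr::summarise(value = mean(.data$value), .groups = "drop"))
  }
  res <- joined %>%
    dplyr::group_by(.data$node) %>%
    dplyr::summarise(
      n_values = dplyr::n_distinct(.data$value),
      value = .data$value[1],
      source = if ("source" %in% names(joined)) .data$source[1] else NA_character_,
      .groups = "drop"
    )
  conf <- res %>% dplyr::filter(.data$n_values > 1L)
  if (nrow(conf) > 0L) {
    warning("dropping node(s) with conflicting family effects: ",
            paste(conf$node, collapse = ", "), call. = FALSE)
    res <- res %>% dplyr::anti_join(conf, by = "node")
  }
  res %>% dplyr::select(-"n_values")
}

#' Apply a Strict Node Variant
#'
#' Freezes a node at 0 or 1 for the whole simulation: the initial-state
#' probability becomes the value and the opposing rate is zeroed (value 0
#' zeroes `k_up`, value 1 zeroes `k_down`), so the logical rule can never
#' flip the node back.
#'
#' @param settings a `simulation_settings`.
#' @param node node name.
#' @param value 0 or 1.
#' @return modified settings.
#' @export
apply_strict_nv <- function(settings, node, value) {
  i <- match(node, settings$nodes$node)
  if (is.na(i)) stop(sprintf("unknown node '%s'", node), call. = FALSE)
  if (!value %in% c(0, 1)) stop("strict value must be 0 or 1", call. = FALSE)
  settings$nodes$istate[i] <- value
  if (value == 0) settings$nodes$k_up[i] <- 0 else settings$nodes$k_down[i] <- 0
  settings
}

#' Apply a Soft Node Variant
#'
#' Biases a node toward a normalized data value in `[0, 1]`: the
#' initial-state probability becomes the value and the transition rates
#' are tilted exponentially,
#' `k_up = AF^(2 (value - 0.5))`, `k_down = 1 / k_up`,
#' with amplification factor `AF` (default 100, so a fully expressed gene
#' gets `k_up = 100`, `k_down = 0.01`). The rule stays active; the node is
#' nudged, not frozen.
#'
#' @inheritParams apply_strict_nv
#' @param value normalized value in `[0, 1]`.
#' @param amplification amplification factor (> 1).
#' @return modified settings.
#' @export
apply_soft_nv <- function(settings, node, value, amplification = 100) {
  i <- match(node, settings$nodes$node)
  if (is.na(i)) stop(sprintf("unknown node '%s'", node), call. = FALSE)
  if (value < 0 || value > 1) stop("normalized value outside [0, 1]", call. = FALSE)
  if (!(amplification > 1)) stop("amplification factor must exceed 1", call. = FALSE)
  k_up <- amplification^(2 * (value - 0.5))
  settings$nodes$istate[i] <- value
  settings$nodes$k_up[i] <- k_up
  settings$nodes$k_down[i] <- 1 / k_up
  settings
}

#' Personalization strategies (data-type recipes)
#'
#' The six named recipes describe which data feed Strict Node Variants and
#' which feed Soft Node Variants:
#' case1 mutations strict; case2 mutations + CNA strict; case3 mutations
#' strict + CNA soft; case4 RNA soft; case5 mutations strict + RNA soft;
#' case6 mutations + CNA strict + RNA soft. Protein data, when present in
#' the soft channel, takes precedence over RNA node-wise.
#'
#' @param name one of `"case1"`..`"case6"`, or `"custom"`.
#' @param strict_data character subset of `c("mutation", "cna")` (custom).
#' @param soft_data character subset of `c("cna", "rna", "protein")` (custom).
#' @param amplification soft-NV amplification factor.
#' @return a `personalization_strategy`.
#' @export
personalization_strategy <- function(name = "case5", strict_data = NULL,
                                     soft_data = NULL, amplification = 100) {
  recipes <- list(
    case1 = list(strict = "mutation", soft = character(0)),
    case2 = list(strict = c("mutation", "cna"), soft = character(0)),
    case3 = list(strict = "mutation", soft = "cna"),
    case4 = list(strict = character(0), soft = c("protein", "rna")),
    case5 = list(strict = "mutation", soft = c("protein", "rna")),
    case6 = list(strict = c("mutation", "cna"), soft = c("protein", "rna"))
  )
  if (name %in% names(recipes)) {
    strict_data <- recipes[[name]]$strict
    soft_data <- recipes[[name]]$soft
  } else if (name != "custom" || is.null(strict_data) && is.null(soft_data)) {
    stop("unknown strategy; use case1..case6 or 'custom' with explicit data",
         call. = FALSE)
  }
  if (!(amplification > 1)) stop("amplification factor must exceed 1", call. = FALSE)
  structure(list(name = name,
                 strict_data = strict_data %||% character(0),
                 soft_data = soft_data %||% character(0),
                 amplification = amplification),
            class = "personalization_strategy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.personalization_strategy <- function(x, ...) {
  cat(sprintf("<personalization_strategy> %s | strict: %s | soft: %s | AF %g\n",
              x$name,
              if (length(x$strict_data)) paste(x$strict_data, collapse = "+") else "-",
              if (length(x$soft_data)) paste(x$soft_data, collapse = ">") else "-",
              x$amplification))
  invisible(x)
}

#' Resolve strict/soft candidates into a patient profile
#'
#' Precedence per node: mutation-derived strict assignments beat
#' CNA-derived strict ones beat anything expression-derived; within the
#' soft channel, protein beats RNA. A node with a strict assignment never
#' also receives a soft one.
#'
#' @param strict_candidates tibble `node`, `value`, `data_type` (subset of
#'   mutation/cna/expression).
#' @param soft_candidates tibble `node`, `value`, `data_type` (cna, rna,
#'   protein).
#' @param strategy a [personalization_strategy()].
#' @return a `patient_profile`: tibbles `strict` and `soft` after
#'   precedence resolution.
#' @export
resolve_precedence <- function(strict_candidates, soft_candidates, strategy) {
  strict_prec <- c(mutation = 1L, cna = 2L, expression = 3L)
  soft_prec <- c(protein = 1L, rna = 2L, cna = 3L)
  empty <- tibble::tibble(node = character(0), value = numeric(0),
                          data_type = character(0))
  strict <- tibble::as_tibble(strict_candidates %||% empty)
  soft <- tibble::as_tibble(soft_candidates %||% empty)
  if (nrow(strict) > 0L) {
    strict <- strict %>%
      dplyr::filter(.data$data_type %in% strategy$strict_data) %>%
      dplyr::mutate(.p = strict_prec[.data$data_type]) %>%
      dplyr::arrange(.data$node, .data$.p) %>%
      dplyr::distinct(.data$node, .keep_all = TRUE) %>%
      dplyr::select(-".p")
  } else {
    strict <- empty
  }
  if (nrow(soft) > 0L) {
    soft <- soft %>%
      dplyr::filter(.data$data_type %in% strategy$soft_data,
                    !.data$node %in% strict$node) %>%
      dplyr::mutate(.p = soft_prec[.data$data_type]) %>%
      dplyr::arrange(.data$node, .data$.p) %>%
      dplyr::distinct(.data$node, .keep_all = TRUE) %>%
      dplyr::select(-".p")
  } else {
    soft <- empty
  }
  structure(list(strict = strict, soft = soft), class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile> %d strict, %d soft node(s)\n",
              nrow(x$strict), nrow(x$soft)))
  invisible(x)
}

#' Apply a resolved patient profile to base settings
#'
#' @param settings base `simulation_settings`.
#' @param profile a `patient_profile` from [resolve_precedence()].
#' @param strategy a [personalization_strategy()].
#' @return personalized settings; nodes without data keep the base
#'   (generic) settings.
#' @export
apply_profile <- function(settings, profile, strategy) {
  for (i in seq_len(nrow(profile$strict))) {
    settings <- apply_strict_nv(settings, profile$strict$node[i],
                                profile$strict$value[i])
  }
  for (i in seq_len(nrow(profile$soft))) {
    settings <- apply_soft_nv(settings, profile$soft$node[i],
                              profile$soft$value[i],
                              amplification = strategy$amplification)
  }
  settings
}

# deterministic 31-bit seed from the master seed and a patient id, so a
# patient's simulation never depends on who else is in the cohort
derive_seed <- function(master_seed, patient_id) {
  h <- as.double(master_seed %% 2147483647)
  for (ch in utf8ToInt(as.character(patient_id))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h * 48271) %% 2147483647)
}

#' Personalize a cohort of patients
#'
#' Builds one personalized `simulation_settings` per patient from the
#' omics tables the strategy requires. Patients missing a required data
#' type are excluded (and counted in the manifest). The model's rules are
#' never modified; only the per-patient configuration changes.
#'
#' @param model a `logical_model`.
#' @param base_settings generic settings (e.g. [default_settings()]).
#' @param mapping a [gene_node_mapping()].
#' @param strategy a [personalization_strategy()].
#' @param mutation_effects long tibble `sample`, `gene`, `value` from
#'   [build_discrete_profile()] restricted to mutations (or with
#'   `data_type` column).
#' @param cna_effects same shape, for CNA effects.
#' @param rna_normalized,protein_normalized normalized expression tibbles
#'   (`gene` column plus one column per sample) from
#'   [process_expression()].
#' @return list with `settings` (named list, one `simulation_settings` per
#'   retained patient) and `manifest` (tibble: patient, counts of strict
#'   and soft nodes, derived seed, excluded patients flagged).
#' @export
personalize_cohort <- function(model, base_settings, mapping, strategy,
                               mutation_effects = NULL, cna_effects = NULL,
                               rna_normalized = NULL,
                               protein_normalized = NULL) {
  mapping <- gene_node_mapping(mapping, model)
  need <- unique(c(strategy$strict_data, strategy$soft_data))
  provided <- list(
    mutation = mutation_effects,
    cna = cna_effects,
    rna = rna_normalized,
    protein = protein_normalized
  )
  # protein is an optional upgrade of the soft channel when rna is also listed
  required <- need
  if (all(c("protein", "rna") %in% strategy$soft_data) &&
      is.null(protein_normalized)) {
    required <- setdiff(required, "protein")
    need <- setdiff(need, "protein")
  }
  missing_types <- setdiff(required,
                           names(provided)[!vapply(provided, is.null, logical(1))])
  if (length(missing_types) > 0L)
    stop("strategy requires data type(s) not supplied: ",
         paste(missing_types, collapse = ", "), call. = FALSE)

  samples_of <- function(x, wide) {
    if (is.null(x)) return(NULL)
    if (wide) setdiff(names(x), "gene") else unique(x$sample)
  }
  sample_sets <- list(
    mutation = samples_of(mutation_effects, wide = FALSE),
    cna = samples_of(cna_effects, wide = FALSE),
    rna = samples_of(rna_normalized, wide = TRUE),
    protein = samples_of(protein_normalized, wide = TRUE)
  )
  # patients must carry every required data type except protein, which is
  # an optional upgrade of the rna channel
  hard_need <- setdiff(need, "protein")
  if ("protein" %in% need && !"rna" %in% need &&
      is.null(sample_sets$rna)) hard_need <- union(hard_need, "protein")
  all_patients <- sort(unique(unlist(sample_sets[need])))
  retained <- all_patients
  for (ty in hard_need) {
    retained <- intersect(retained, sample_sets[[ty]] %||% character(0))
  }
  if (length(retained) == 0L) stop("no patient carries all required data types",
                                   call. = FALSE)
  excluded <- setdiff(all_patients, retained)

  wide_col <- function(tbl, patient) {
    if (is.null(tbl) || !patient %in% names(tbl)) return(NULL)
    tibble::tibble(gene = tbl$gene, value = tbl[[patient]]) %>%
      dplyr::filter(!is.na(.data$value))
  }
  long_rows <- function(tbl, patient) {
    if (is.null(tbl)) return(NULL)
    d <- tbl %>% dplyr::filter(.data$sample == patient)
    if (nrow(d) == 0L) return(NULL)
    d %>% dplyr::select("gene", "value")
  }

  settings_list <- list()
  manifest <- list()
  for (patient in retained) {
    strict_cand <- list()
    if ("mutation" %in% strategy$strict_data) {
      p <- long_rows(mutation_effects, patient)
      if (!is.null(p)) {
        nodes <- map_genes_to_nodes(p, mapping, "discrete")
        if (nrow(nodes)) strict_cand$mut <- nodes %>%
            dplyr::mutate(data_type = "mutation")
      }
    }
    if ("cna" %in% strategy$strict_data) {
      p <- long_rows(cna_effects, patient)
      if (!is.null(p)) {
        nodes <- map_genes_to_nodes(p, mapping, "discrete")
        if (nrow(nodes)) strict_cand$cna <- nodes %>%
            dplyr::mutate(data_type = "cna")
      }
    }
    soft_cand <- list()
    if ("cna" %in% strategy$soft_data) {
      # discrete CNA effects feed the soft channel with norm values 0/1
      p <- long_rows(cna_effects, patient)
      if (!is.null(p)) {
        nodes <- map_genes_to_nodes(p, mapping, "discrete")
        if (nrow(nodes)) soft_cand$cna <- nodes %>%
            dplyr::select("node", "value") %>%
            dplyr::mutate(data_type = "cna")
      }
    }
    if ("rna" %in% strategy$soft_data) {
      p <- wide_col(rna_normalized, patient)
      if (!is.null(p) && nrow(p)) {
        nodes <- map_genes_to_nodes(p, mapping, "continuous")
        if (nrow(nodes)) soft_cand$rna <- nodes %>%
            dplyr::mutate(data_type = "rna")
      }
    }
    if ("protein" %in% strategy$soft_data) {
      p <- wide_col(protein_normalized, patient)
      if (!is.null(p) && nrow(p)) {
        nodes <- map_genes_to_nodes(p, mapping, "continuous")
        if (nrow(nodes)) soft_cand$protein <- nodes %>%
            dplyr::mutate(data_type = "protein")
      }
    }
    profile <- resolve_precedence(dplyr::bind_rows(strict_cand),
                                  dplyr::bind_rows(soft_cand), strategy)
    s <- apply_profile(base_settings, profile, strategy)
    s$seed <- derive_seed(base_settings$seed, patient)
    settings_list[[patient]] <- s
    manifest[[patient]] <- tibble::tibble(
      patient = patient, retained = TRUE,
      n_strict = nrow(profile$strict), n_soft = nrow(profile$soft),
      seed = s$seed
    )
  }
  manifest <- dplyr::bind_rows(
    dplyr::bind_rows(manifest),
    tibble::tibble(patient = excluded, retained = FALSE,
                   n_strict = NA_integer_, n_soft = NA_integer_,
                   seed = NA_integer_)
  )
  if (length(excluded) > 0L)
    message(sprintf("%d patient(s) excluded for missing required data types",
                    length(excluded)))
  list(settings = settings_list, manifest = manifest)
}

#' Write personalized CFG files for a cohort
#'
#' One CFG per patient plus a manifest CSV; the BND is shared and
#' untouched.
#'
#' @param personalized result of [personalize_cohort()].
#' @param model the `logical_model`.
#' @param dir output directory (created if needed).
#' @return invisible tibble of written files.
#' @export
write_cohort_cfgs <- function(personalized, model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::imap_chr(personalized$settings, function(s, patient) {
    path <- file.path(dir, paste0(patient, ".cfg"))
    write_cfg(s, model, path)
    path
  })
  utils::write.csv(personalized$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(tibble::tibble(patient = names(files), path = unname(files)))
}
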