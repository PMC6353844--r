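# Cohort-level analysis: simulate every personalized model, summarize
# phenotype-probability distributions, correlate them with external scores
# and build prognostic groups by median split.

#' Simulate a personalized cohort
#'
#' Runs the ensemble simulation for each patient's settings and collects
#' the asymptotic probabilities of the phenotype read-out nodes, together
#' with a wild-type (unpersonalized) reference run. Per-patient seeds were
#' derived at personalization time, so results do not depend on cohort
#' composition or iteration order.
#'
#' @param model a `logical_model` with read-outs set (see [set_outputs()]).
#' @param settings_map named list of per-patient `simulation_settings`
#'   (the `settings` element of [personalize_cohort()]).
#' @param base_settings settings for the wild-type reference run.
#' @param phenotypes nodes to report (default: the model's read-outs).
#' @param strategy_label free-text label stored on the result.
#' @return a `phenotype_table`: tibble `patient` x phenotype columns, with
#'   the wild-type reference in `attr(, "wild_type")` and failed patients
#'   in `attr(, "failures")`.
#' @export
simulate_cohort <- function(model, settings_map, base_settings,
                            phenotypes = NULL, strategy_label = NA_character_) {
  if (is.null(phenotypes)) phenotypes <- model$outputs
  if (length(phenotypes) == 0L)
    stop("no phenotype read-outs: set model outputs or pass `phenotypes`",
         call. = FALSE)
  one_run <- function(s) {
    res <- simulate_ensemble(model, s, record_states = FALSE)
    ap <- asymptotic_probabilities(res)
    stats::setNames(ap$probability[match(phenotypes, ap$node)], phenotypes)
  }
  wt <- one_run(base_settings)
  rows <- list()
  failures <- character(0)
  for (patient in names(settings_map)) {
    p <- tryCatch(one_run(settings_map[[patient]]), error = function(e) {
      warning(sprintf("simulation failed for patient %s: %s", patient,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(p)) {
      failures <- c(failures, patient)
      next
    }
    rows[[patient]] <- tibble::as_tibble_row(c(list(patient = patient),
                                               as.list(p)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "wild_type") <- wt
  attr(out, "failures") <- failures
  attr(out, "strategy") <- strategy_label
  class(out) <- c("phenotype_table", class(out))
  out
}

#' Median-split stratification on a phenotype
#'
#' The threshold is the cohort median of the phenotype probability;
#' patients above it are "high", at or below it "low" (ties go to low).
#' With two phenotypes the combined label is the Cartesian product (e.g.
#' "high_Proliferation/low_Apoptosis").
#'
#' @param table a `phenotype_table` (or any tibble with a `patient` column
#'   and numeric phenotype columns).
#' @param phenotypes one or two phenotype column names.
#' @return a `stratification`: tibble `patient`, one `<phenotype>_group`
#'   column each, and `group` (combined); thresholds in
#'   `attr(, "thresholds")`.
#' @export
median_split <- function(table, phenotypes) {
  stopifnot(length(phenotypes) >= 1L, all(phenotypes %in% names(table)))
  if (nrow(table) < 2L) stop("need at least 2 patients", call. = FALSE)
  out <- tibble::tibble(patient = table$patient)
  thresholds <- stats::setNames(numeric(length(phenotypes)), phenotypes)
  for (ph in phenotypes) {
    v <- table[[ph]]
    med <- stats::median(v)
    thresholds[ph] <- med
    if (all(v == v[1])) {
      warning(sprintf("phenotype '%s' is constant: single group", ph),
              call. = FALSE)
    }
    out[[paste0(ph, "_group")]] <- ifelse(v > med, "high", "low")
  }
  lab <- purrr::map_chr(seq_len(nrow(out)), function(i) {
    paste(purrr::map_chr(phenotypes,
                         function(ph) paste0(out[[paste0(ph, "_group")]][i], "_", ph)),
          collapse = "/")
  })
  out$group <- lab
  attr(out, "thresholds") <- thresholds
  class(out) <- c("stratification", class(out))
  out
}

#' Spearman correlation with an external score, with bootstrap CI
#'
#' Rank correlation between a phenotype probability and any user-computed
#' per-patient score (signature score, clinical index, ...), with a
#' percentile bootstrap 95% confidence interval (1000 resamples, seeded).
#'
#' @param table a `phenotype_table`.
#' @param phenotype phenotype column name.
#' @param score numeric vector aligned to `table$patient` (or a named
#'   vector matched by patient).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return tibble `estimate`, `conf_low`, `conf_high`, `n`.
#' @export
correlate_with_score <- function(table, phenotype, score, n_boot = 1000L,
                                 conf = 0.95, seed = 1L) {
  stopifnot(phenotype %in% names(table))
  x <- table[[phenotype]]
  if (!is.null(names(score))) score <- score[table$patient]
  if (length(score) != length(x))
    stop("score vector does not align with the patient table", call. = FALSE)
  ok <- is.finite(x) & is.finite(score)
  x <- x[ok]; y <- score[ok]
  if (length(x) < 3L) stop("need at least 3 patients", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  boots <- with_seed2(seed, n = n_boot, x = x, y = y)
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  tibble::tibble(estimate = rho, conf_low = ci[1], conf_high = ci[2],
                 n = length(x))
}

# seeded bootstrap worker kept separate so the caller's RNG is untouched
with_seed2 <- function(seed, n, x, y) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    idx <- sample.int(length(x), replace = TRUE)
    suppressWarnings(stats::cor(x[idx], y[idx], method = "spearman"))
  }, numeric(1))
}

#' Merge stratification groups with survival data
#'
#' Produces an analysis-ready table (patient, time, event, group labels)
#' for any downstream Kaplan-Meier / log-rank / Cox routine; the test
#' itself is delegated to standard survival tooling.
#'
#' @param stratification a [median_split()] result.
#' @param survival data frame with columns `patient`, `time`, `event`
#'   (event: 1 = observed, 0 = censored).
#' @return tibble of matched patients; patients without survival rows are
#'   dropped with a message.
#' @export
export_survival_groups <- function(stratification, survival) {
  surv <- tibble::as_tibble(survival)
  stopifnot(all(c("patient", "time", "event") %in% names(surv)))
  merged <- dplyr::inner_join(tibble::as_tibble(stratification), surv,
                              by = "patient")
  dropped <- setdiff(stratification$patient, merged$patient)
  if (length(dropped) > 0L)
    message(sprintf("%d patient(s) without survival data dropped",
                    length(dropped)))
  merged
}

#' @export
glance.phenotype_table <- function(x, ...) {
  wt <- attr(x, "wild_type")
  phenos <- setdiff(names(x), "patient")
  tibble::tibble(
    phenotype = phenos,
    median = vapply(phenos, function(p) stats::median(x[[p]]), numeric(1)),
    mean = vapply(phenos, function(p) mean(x[[p]]), numeric(1)),
    wild_type = unname(wt[phenos]),
    n_patients = nrow(x)
  )
}
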