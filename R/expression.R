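# Classification of per-gene expression distributions across a cohort and
# the three normalization transforms (Gaussian-mixture posterior, sigmoid,
# clipped linear), plus binarization.

.dip_cache <- new.env(parent = emptyenv())

#' Hartigan dip test of unimodality
#'
#' The dip statistic is the largest distance between the empirical CDF and
#' the closest unimodal CDF. P-values come from a seeded Monte-Carlo null
#' (uniform samples of the same size, the asymptotically least favorable
#' unimodal distribution); the null table is cached per sample size.
#' `p < 0.05` flags multimodality.
#'
#' @param values numeric vector (at least 4 finite values).
#' @param n_null Monte-Carlo null size (default 1000).
#' @return list with `statistic` and `p_value`.
#' @examples
#' dip_test(c(rnorm(100), rnorm(100, 8)))$p_value
#' @export
dip_test <- function(values, n_null = 1000L) {
  values <- values[is.finite(values)]
  if (length(values) < 4L)
    stop("dip test requires at least 4 finite values", call. = FALSE)
  stat <- .dip_stat_cpp(values)
  key <- sprintf("n%d_b%d", length(values), n_null)
  if (is.null(.dip_cache[[key]]))
    .dip_cache[[key]] <- .dip_null_cpp(length(values), as.integer(n_null), 217L)
  null <- .dip_cache[[key]]
  p <- (1 + sum(null >= stat)) / (n_null + 1)
  list(statistic = stat, p_value = min(p, 1))
}

#' Bimodality index of an expression vector
#'
#' Fits a two-component equal-variance Gaussian mixture (via mclust, model
#' "E") and reports `BI = sqrt(pi (1 - pi)) * delta` with
#' `delta = |mu1 - mu2| / sigma`, where `pi` is the weight of the
#' lower-mean component. `BI > 1.5` is the bimodality cut-off used in
#' classification. Degenerate data on which the fit fails give `BI = 0`.
#'
#' @param values numeric vector (at least 10 finite values).
#' @return list with `bi`, `mu1`, `mu2` (`mu1 <= mu2`), `sigma`, `pi`,
#'   `delta`; fitted parameters are `NA` when the fit fails.
#' @importFrom mclust Mclust mclustBIC
#' @export
bimodality_index <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10L)
    stop("bimodality index requires at least 10 finite values", call. = FALSE)
  failed <- list(bi = 0, mu1 = NA_real_, mu2 = NA_real_, sigma = NA_real_,
                 pi = NA_real_, delta = NA_real_)
  if (stats::sd(values) == 0) return(failed)
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(values, G = 2, modelNames = "E",
                                    verbose = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed)
  mu <- fit$parameters$mean
  pro <- fit$parameters$pro
  sigma <- sqrt(fit$parameters$variance$sigmasq[1])
  ord <- order(mu)
  mu <- mu[ord]; pro <- pro[ord]
  if (sigma <= 0) return(failed)
  delta <- unname(abs(mu[2] - mu[1]) / sigma)
  p1 <- unname(pro[1])
  list(bi = sqrt(p1 * (1 - p1)) * delta,
       mu1 = unname(mu[1]), mu2 = unname(mu[2]), sigma = sigma,
       pi = unname(p1), delta = delta)
}

#' Fisher excess kurtosis
#'
#' Moment-based excess kurtosis (normal distribution gives 0). Platykurtic
#' (negative) values are a bimodality hint; the classification cut-off is
#' `K < 1`, a relaxed version of the usual 0.
#'
#' @param values numeric vector (at least 4 finite values, nonzero variance).
#' @return excess kurtosis `K`.
#' @export
excess_kurtosis <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L)
    stop("kurtosis requires at least 4 finite values", call. = FALSE)
  if (stats::var(values) == 0) stop("zero variance", call. = FALSE)
  unname(e1071::kurtosis(values, type = 1))
}

#' Admissibility filter for a cohort expression matrix
#'
#' A gene is admissible when its amplitude (max - min across the cohort) is
#' at least one tenth of the median amplitude over all genes and at least
#' 5% of its values are non-zero. Everything else is too flat or too
#' dropout-ridden to classify.
#'
#' @param exprs genes-by-samples numeric matrix with gene rownames, or a
#'   data frame whose first column is the gene identifier.
#' @return tibble with `gene`, `amplitude`, `fraction_nonzero`, `admissible`.
#' @export
admissibility_filter <- function(exprs) {
  m <- as_expression_matrix(exprs)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  amplitude <- apply(m, 1, function(v) max(v) - min(v))
  frac_nz <- rowMeans(m != 0)
  med_amp <- stats::median(amplitude)
  tibble::tibble(
    gene = rownames(m),
    amplitude = unname(amplitude),
    fraction_nonzero = unname(frac_nz),
    admissible = unname(amplitude >= 0.1 * med_amp & frac_nz >= 0.05)
  )
}

as_expression_matrix <- function(exprs) {
  if (is.data.frame(exprs)) {
    genes <- as.character(exprs[[1]])
    m <- as.matrix(exprs[, -1, drop = FALSE])
    rownames(m) <- genes
  } else {
    m <- as.matrix(exprs)
    if (is.null(rownames(m))) stop("expression matrix needs gene rownames", call. = FALSE)
  }
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty expression matrix", call. = FALSE)
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers", call. = FALSE)
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values", call. = FALSE)
  m
}

#' Classify a gene's expression distribution
#'
#' A gene is called bimodal when all three criteria agree: dip test
#' p < 0.05, bimodality index > 1.5 and excess kurtosis < 1. Non-bimodal
#' genes whose kernel-density mode sits in the lowest `peak_frac` fraction
#' of the observed range (default 10%, a scale-free reading of "density
#' peak close to zero") are zero-inflated; the rest are unimodal. Unimodal
#' genes with zero MAD fall back to IQR/1.349 as the scale; genes where
#' that is also zero are discarded.
#'
#' @param values the gene's expression across the (reference) cohort.
#' @param dip_p,bi_cut,kurt_cut classification thresholds.
#' @param peak_frac zero-inflation peak-location threshold.
#' @param n_null dip-test Monte-Carlo null size.
#' @return a `gene_fit`: `category` in `{bimodal, unimodal, zero_inflated,
#'   discarded}` plus the fitted parameters of its transform and the test
#'   statistics.
#' @export
classify_gene <- function(values, dip_p = 0.05, bi_cut = 1.5, kurt_cut = 1,
                          peak_frac = 0.10, n_null = 1000L) {
  values <- values[is.finite(values)]
  fit <- list(category = "discarded", dip_pvalue = NA_real_, bi = NA_real_,
              kurtosis = NA_real_, peak_location = NA_real_,
              mu1 = NA_real_, mu2 = NA_real_, sigma = NA_real_, pi = NA_real_,
              delta = NA_real_, median = NA_real_, mad = NA_real_,
              lambda = NA_real_, q1 = NA_real_, q99 = NA_real_,
              min = NA_real_, max = NA_real_)
  class(fit) <- "gene_fit"
  if (length(values) < 10L || stats::sd(values) == 0) return(fit)

  dp <- dip_test(values, n_null = n_null)
  bim <- bimodality_index(values)
  K <- excess_kurtosis(values)
  dens <- stats::density(values)
  peak <- dens$x[which.max(dens$y)]
  rng <- range(values)
  fit$dip_pvalue <- dp$p_value
  fit$bi <- bim$bi
  fit$kurtosis <- K
  fit$peak_location <- peak
  fit$min <- rng[1]
  fit$max <- rng[2]

  if (dp$p_value < dip_p && bim$bi > bi_cut && K < kurt_cut &&
      is.finite(bim$mu1)) {
    fit$category <- "bimodal"
    fit[c("mu1", "mu2", "sigma", "pi", "delta")] <-
      bim[c("mu1", "mu2", "sigma", "pi", "delta")]
    return(fit)
  }
  if ((peak - rng[1]) <= peak_frac * (rng[2] - rng[1])) {
    fit$category <- "zero_inflated"
    fit$q1 <- unname(stats::quantile(values, 0.01, type = 7))
    fit$q99 <- unname(stats::quantile(values, 0.99, type = 7))
    if (fit$q99 <= fit$q1) fit$category <- "discarded"
    return(fit)
  }
  fit$category <- "unimodal"
  fit$median <- stats::median(values)
  s <- stats::mad(values, constant = 1)
  if (s == 0) s <- stats::IQR(values) / 1.349
  if (s == 0) {
    fit$category <- "discarded"
    return(fit)
  }
  fit$mad <- s
  fit$lambda <- log(3) / s
  fit
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("<gene_fit> %s (dip p = %.3g, BI = %.3g, K = %.3g)\n",
              x$category, x$dip_pvalue, x$bi, x$kurtosis))
  invisible(x)
}

#' Normalize expression values for a bimodal gene
#'
#' The normalized value is the posterior probability of membership in the
#' upper-mean mixture component, using the same equal-variance fit as the
#' bimodality index, so the two posteriors sum to one and the transform is
#' monotone in the raw value.
#'
#' @param values raw expression values to transform.
#' @param fit a `gene_fit` with `category == "bimodal"`.
#' @return normalized values in `[0, 1]`.
#' @export
normalize_bimodal <- function(values, fit) {
  stopifnot(fit$category == "bimodal")
  d1 <- (1 - fit$pi) * stats::dnorm(values, fit$mu2, fit$sigma)
  d0 <- fit$pi * stats::dnorm(values, fit$mu1, fit$sigma)
  # far tails: both densities underflow; membership follows the nearest mean
  p <- ifelse(d0 + d1 > 0, d1 / (d0 + d1),
              as.numeric(values > (fit$mu1 + fit$mu2) / 2))
  pmin(pmax(p, 0), 1)
}

#' Normalize expression values for a unimodal gene
#'
#' Centered at the cohort median and squashed through a sigmoid whose slope
#' `lambda = ln(3) / MAD` maps median +/- one MAD to 0.75 / 0.25, keeping a
#' comparable spread in `[0, 1]` across genes of different dispersions.
#'
#' @inheritParams normalize_bimodal
#' @export
normalize_unimodal <- function(values, fit) {
  stopifnot(fit$category == "unimodal")
  1 / (1 + exp(-fit$lambda * (values - fit$median)))
}

#' Normalize expression values for a zero-inflated gene
#'
#' Linear rescaling computed on the 1st-99th percentile range, preserving
#' the asymmetric shape; values outside the range clip to 0 and 1.
#'
#' @inheritParams normalize_bimodal
#' @export
normalize_zero_inflated <- function(values, fit) {
  stopifnot(fit$category == "zero_inflated")
  if (fit$q99 <= fit$q1) stop("degenerate percentile range", call. = FALSE)
  pmin(pmax((values - fit$q1) / (fit$q99 - fit$q1), 0), 1)
}

#' Normalize values with whatever transform the gene's category requires
#'
#' @inheritParams normalize_bimodal
#' @export
normalize_gene <- function(values, fit) {
  switch(fit$category,
    bimodal = normalize_bimodal(values, fit),
    unimodal = normalize_unimodal(values, fit),
    zero_inflated = normalize_zero_inflated(values, fit),
    stop("cannot normalize a discarded gene", call. = FALSE)
  )
}

#' Binarize expression values
#'
#' Bimodal genes binarize by posterior majority (upper component wins at
#' posterior > 0.5). Unimodal and zero-inflated genes only call the tails:
#' normalized values at or above `1 - tau` give 1, at or below `tau` give
#' 0, anything in between is `NA` (missing), yielding sparse,
#' outlier-driven calls.
#'
#' @inheritParams normalize_bimodal
#' @param tau tail threshold for non-bimodal genes (default 0.25).
#' @return values in `{0, 1, NA}`.
#' @export
binarize_gene <- function(values, fit, tau = 0.25) {
  norm <- normalize_gene(values, fit)
  if (fit$category == "bimodal") return(as.integer(norm > 0.5))
  out <- rep(NA_integer_, length(values))
  out[norm >= 1 - tau] <- 1L
  out[norm <= tau] <- 0L
  out
}

#' Process a cohort expression matrix
#'
#' Runs the full pipeline: admissibility filter, per-gene distribution
#' classification, normalization and binarization. In `"cohort"` mode all
#' samples define the per-gene fits; in `"reference"` mode the fits are
#' estimated on the reference-flagged (e.g. healthy) samples only and then
#' applied to the remaining samples.
#'
#' @inheritParams admissibility_filter
#' @param mode `"cohort"` or `"reference"`.
#' @param reference_samples sample names defining the reference set
#'   (required in `"reference"` mode).
#' @param tau binarization tail threshold.
#' @param log2_transform apply `log2(x + 1)` before processing (off by
#'   default; input is assumed to be on the scale to classify).
#' @inheritParams classify_gene
#' @return list with `fits` (per-gene tibble including test statistics and
#'   transform parameters), `normalized` and `binarized` (tibbles, gene
#'   column plus one column per processed sample; discarded genes absent).
#' @examples
#' cohort <- generate_expression_cohort(cohort_spec(n_samples = 200))
#' res <- process_expression(cohort$matrix)
#' table(res$fits$category)
#' @export
process_expression <- function(exprs, mode = c("cohort", "reference"),
                               reference_samples = NULL, tau = 0.25,
                               log2_transform = FALSE,
                               dip_p = 0.05, bi_cut = 1.5, kurt_cut = 1,
                               peak_frac = 0.10, n_null = 1000L) {
  mode <- match.arg(mode)
  m <- as_expression_matrix(exprs)
  if (log2_transform) m <- log2(m + 1)
  if (mode == "reference") {
    if (is.null(reference_samples) || !any(colnames(m) %in% reference_samples))
      stop("reference mode requires at least one reference-flagged sample",
           call. = FALSE)
    ref <- m[, colnames(m) %in% reference_samples, drop = FALSE]
    target <- m[, !colnames(m) %in% reference_samples, drop = FALSE]
  } else {
    ref <- m
    target <- m
  }

  adm <- admissibility_filter(ref)
  fits <- purrr::map(rownames(ref), function(g) {
    if (!adm$admissible[adm$gene == g]) {
      f <- classify_gene(numeric(0))  # discarded shell
      f$category <- "discarded"
      return(f)
    }
    classify_gene(ref[g, ], dip_p = dip_p, bi_cut = bi_cut,
                  kurt_cut = kurt_cut, peak_frac = peak_frac, n_null = n_null)
  })
  names(fits) <- rownames(ref)

  fits_tbl <- purrr::map_dfr(rownames(ref), function(g) {
    f <- fits[[g]]
    tibble::tibble(
      gene = g, category = f$category,
      amplitude = adm$amplitude[adm$gene == g],
      fraction_nonzero = adm$fraction_nonzero[adm$gene == g],
      dip_p = f$dip_pvalue, bi = f$bi, kurtosis = f$kurtosis,
      mu1 = f$mu1, mu2 = f$mu2, sigma = f$sigma, pi = f$pi, delta = f$delta,
      median = f$median, mad = f$mad, lambda = f$lambda,
      q1 = f$q1, q99 = f$q99
    )
  })

  kept <- names(fits)[vapply(fits, function(f) f$category != "discarded",
                             logical(1))]
  norm_rows <- purrr::map(kept, function(g) normalize_gene(target[g, ], fits[[g]]))
  bin_rows <- purrr::map(kept, function(g) binarize_gene(target[g, ], fits[[g]],
                                                         tau = tau))
  to_tbl <- function(rows, genes) {
    if (length(rows) == 0L) {
      return(tibble::tibble(gene = character(0)))
    }
    m2 <- do.call(rbind, rows)
    colnames(m2) <- colnames(target)
    dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m2))
  }
  list(
    fits = fits_tbl,
    normalized = to_tbl(norm_rows, kept),
    binarized = to_tbl(bin_rows, kept),
    gene_fits = fits[kept]
  )
}
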