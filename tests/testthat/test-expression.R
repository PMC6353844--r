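test_that("admissibility filter applies the amplitude and non-zero rules", {
  m <- rbind(
    FLAT  = rep(5, 100),                 # zero amplitude
    SPARSE = c(rep(0, 97), 8, 9, 10),    # 3% non-zero
    OK1   = seq(0, 10, length.out = 100),
    OK2   = seq(2, 12, length.out = 100)
  )
  colnames(m) <- paste0("S", 1:100)
  adm <- admissibility_filter(m)
  expect_false(adm$admissible[adm$gene == "FLAT"])
  expect_false(adm$admissible[adm$gene == "SPARSE"])
  expect_true(all(adm$admissible[adm$gene %in% c("OK1", "OK2")]))
  # equal amplitudes everywhere: all pass the relative-amplitude rule
  m2 <- matrix(rep(seq(1, 5, length.out = 20), 4), nrow = 4, byrow = TRUE,
               dimnames = list(paste0("G", 1:4), paste0("S", 1:20)))
  expect_true(all(admissibility_filter(m2)$admissible))
  expect_error(admissibility_filter(m[, 1, drop = FALSE]), "2 samples")
  expect_error(admissibility_filter(-m), "negative")
})

test_that("bimodality index recovers mixture parameters and the closed-form value", {
  set.seed(9)
  # pi = 0.5, separation 4 sd: population BI = sqrt(0.25) * 4 = 2
  v <- c(rnorm(2500, 0), rnorm(2500, 4))
  fit <- bimodality_index(v)
  expect_equal(fit$bi, 2, tolerance = 0.1)
  expect_equal(fit$mu1, 0, tolerance = 0.15)
  expect_equal(fit$mu2, 4, tolerance = 0.15)
  expect_equal(fit$pi, 0.5, tolerance = 0.05)
  # separation 3 sd, balanced: population BI = 1.5
  v2 <- c(rnorm(2500, 0), rnorm(2500, 3))
  expect_equal(bimodality_index(v2)$bi, 1.5, tolerance = 0.12)
  # degenerate data: fit fails, BI = 0 by convention
  expect_equal(bimodality_index(rep(1, 50))$bi, 0)
})

test_that("excess kurtosis matches analytic values", {
  set.seed(2)
  expect_lt(abs(excess_kurtosis(rnorm(10000))), 0.2)
  expect_equal(excess_kurtosis(runif(20000)), -1.2, tolerance = 0.05)
  # symmetric two-point mass at +/-1: K = -2 exactly for balanced counts
  expect_equal(excess_kurtosis(c(rep(-1, 50), rep(1, 50))), -2)
  expect_error(excess_kurtosis(rep(2, 10)), "variance")
})

test_that("distribution classification assigns the three generating classes", {
  set.seed(17)
  bim <- c(rnorm(1000, 4), rnorm(1000, 8))
  uni <- rnorm(2000, 8)
  zin <- ifelse(runif(2000) < 0.7, 0, rexp(2000, 0.5))
  expect_equal(classify_gene(bim)$category, "bimodal")
  expect_equal(classify_gene(uni)$category, "unimodal")
  expect_equal(classify_gene(zin)$category, "zero_inflated")
  f <- classify_gene(bim)
  expect_true(f$dip_pvalue < 0.05 && f$bi > 1.5 && f$kurtosis < 1)
})

test_that("bimodality criteria are invariant under affine transforms", {
  set.seed(23)
  v <- c(rnorm(800, 2), rnorm(800, 6))
  a <- classify_gene(v)
  b <- classify_gene(3 * v + 10)
  expect_equal(a$dip_pvalue, b$dip_pvalue)
  expect_equal(a$bi, b$bi, tolerance = 1e-6)
  expect_equal(a$kurtosis, b$kurtosis, tolerance = 1e-12)
  expect_equal(a$category, b$category)
})

test_that("bimodal normalization is the upper-component posterior", {
  set.seed(31)
  v <- c(rnorm(1500, 3), rnorm(1500, 7))
  fit <- classify_gene(v)
  expect_equal(fit$category, "bimodal")
  norm <- normalize_bimodal(v, fit)
  expect_true(all(norm >= 0 & norm <= 1))
  # posteriors of the two components sum to one
  d0 <- fit$pi * dnorm(v, fit$mu1, fit$sigma)
  d1 <- (1 - fit$pi) * dnorm(v, fit$mu2, fit$sigma)
  expect_equal(norm + d0 / (d0 + d1), rep(1, length(v)), tolerance = 1e-12)
  # equal-posterior crossing point of a balanced fit maps to 0.5
  fit_bal <- fit
  fit_bal$pi <- 0.5
  expect_equal(normalize_bimodal((fit$mu1 + fit$mu2) / 2, fit_bal), 0.5,
               tolerance = 1e-12)
  # far above the upper mean the posterior saturates
  expect_equal(normalize_bimodal(fit$mu2 + 10, fit), 1, tolerance = 1e-6)
  # monotone in the raw value
  grid <- seq(min(v), max(v), length.out = 200)
  expect_true(all(diff(normalize_bimodal(grid, fit)) >= 0))
})

test_that("unimodal sigmoid maps the median and the MAD anchors exactly", {
  set.seed(37)
  v <- rnorm(1000, 8, 1.5)
  fit <- classify_gene(v)
  expect_equal(fit$category, "unimodal")
  expect_equal(fit$lambda, log(3) / fit$mad, tolerance = 1e-12)
  expect_equal(normalize_unimodal(fit$median, fit), 0.5)
  expect_equal(normalize_unimodal(fit$median + fit$mad, fit), 0.75,
               tolerance = 1e-12)
  expect_equal(normalize_unimodal(fit$median - fit$mad, fit), 0.25,
               tolerance = 1e-12)
  grid <- seq(0, 20, length.out = 100)
  expect_true(all(diff(normalize_unimodal(grid, fit)) > 0))
})

test_that("zero-inflated normalization rescales the robust range with clipping", {
  set.seed(41)
  v <- ifelse(runif(3000) < 0.6, 0, rexp(3000, 0.3))
  fit <- classify_gene(v)
  expect_equal(fit$category, "zero_inflated")
  expect_equal(normalize_zero_inflated(fit$q1, fit), 0)
  expect_equal(normalize_zero_inflated(fit$q99, fit), 1)
  expect_equal(normalize_zero_inflated((fit$q1 + fit$q99) / 2, fit), 0.5)
  expect_equal(normalize_zero_inflated(fit$q99 + 100, fit), 1)
  expect_equal(normalize_zero_inflated(0, fit), 0)
})

test_that("binarization is sparse for non-bimodal genes and consistent with normalization", {
  set.seed(43)
  v <- rnorm(1000, 8, 1.5)
  fit <- classify_gene(v)
  bin <- binarize_gene(v, fit, tau = 0.25)
  norm <- normalize_unimodal(v, fit)
  expect_true(is.na(bin[which.min(abs(v - fit$median))[1]]))
  expect_true(all(norm[!is.na(bin) & bin == 1] >= 0.5))
  expect_true(all(norm[!is.na(bin) & bin == 0] <= 0.5))
  # bimodal genes binarize by posterior majority, no missing values
  vb <- c(rnorm(1000, 3), rnorm(1000, 7))
  fb <- classify_gene(vb)
  binb <- binarize_gene(vb, fb)
  expect_false(anyNA(binb))
  expect_equal(binb[which.max(vb)], 1L)
  expect_equal(binb[which.min(vb)], 0L)
})

test_that("cohort processing recovers generating classes and keeps values in range", {
  cohort <- generate_expression_cohort(cohort_spec(n_samples = 600,
                                                   n_per_class = 6, seed = 7))
  res <- process_expression(cohort$matrix, n_null = 500)
  joined <- dplyr::inner_join(res$fits, cohort$truth, by = "gene")
  acc <- mean(joined$category == joined$class)
  expect_gte(acc, 0.9)
  vals <- as.matrix(res$normalized[, -1])
  expect_true(all(vals >= 0 & vals <= 1))
  bins <- as.matrix(res$binarized[, -1])
  expect_true(all(bins %in% c(0, 1, NA)))
})

test_that("reference mode fits on reference samples and transforms the rest", {
  set.seed(53)
  n_ref <- 200; n_tum <- 150
  ref_vals <- rnorm(n_ref, 8, 1)
  fit_ref <- classify_gene(ref_vals)
  # tumors shifted up by 2 MAD must concentrate above the 0.75 anchor
  tum_vals <- rnorm(n_tum, 8 + 2 * fit_ref$mad, 0.3)
  m <- rbind(G1 = c(ref_vals, tum_vals))
  colnames(m) <- c(sprintf("H%03d", 1:n_ref), sprintf("T%03d", 1:n_tum))
  res <- process_expression(m, mode = "reference",
                            reference_samples = sprintf("H%03d", 1:n_ref),
                            n_null = 500)
  expect_equal(ncol(res$normalized) - 1L, n_tum)
  expect_gt(mean(as.numeric(res$normalized[1, -1]) > 0.75), 0.8)
  # a single-sample tumor set is a well-defined transform application
  res1 <- process_expression(m[, c(1:n_ref, n_ref + 1), drop = FALSE],
                             mode = "reference",
                             reference_samples = sprintf("H%03d", 1:n_ref),
                             n_null = 500)
  expect_equal(ncol(res1$normalized) - 1L, 1L)
  expect_error(process_expression(m, mode = "reference",
                                  reference_samples = "NOPE"),
               "reference")
})
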