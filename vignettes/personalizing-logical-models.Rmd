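---
title: "Personalizing stochastic Boolean network models with multi-omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalizing stochastic Boolean network models with multi-omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logiprofile)
library(dplyr)
```

## The modeling problem

Logical (Boolean) models of signaling pathways encode causal regulatory
knowledge — each node carries a rule over its regulators built from AND,
OR and NOT — but are generic: the same model describes every tumor.
logiprofile turns one generic model plus per-patient omics tables into one
*configuration* per patient, leaving the rules untouched. The
stochastic semantics make this possible: under asynchronous updating the
model is a continuous-time Markov chain whose parameters (initial-state
probabilities and per-node transition rates) are exactly the knobs that
patient data can set.

The chain is defined on the 2^n complete Boolean states. In a state `S`, a
node whose rule evaluates opposite to its current value may flip; the flip
fires after an exponential waiting time with rate `k_up` (activation) or
`k_down` (inactivation). The Gillespie algorithm samples the total
waiting time from the sum of enabled rates and picks the flipped node
proportionally to its rate. An ensemble of trajectories (default 1,000)
estimates time-binned node and model-state probabilities; each trajectory
contributes its *time-weighted occupancy* inside a bin, which is unbiased
for jump processes (sampling at bin edges is not).

Assumptions worth stating plainly: rates are per-node constants, not
state-dependent; nodes are Boolean (no multi-valued levels); and the
"asymptotic" read-out presumes the horizon is long enough that the
ensemble has settled into its attractors.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `max_time` | 50 | simulation time | long enough for the shipped models to absorb; the read-out is attractor-like, not transient |
| `n_trajectories` | 1000 | trajectories | run-to-run spread of asymptotic estimates has median node-wise sd below 0.01 on the shipped cancer-model analogue (checked in the tests) |
| `time_bins` | 100 | bins over `[0, max_time]` | bin width 0.5 time units; fine enough that bin-averaging bias is negligible against Monte-Carlo error |
| `asymptotic_window` | 0.1 | fraction of horizon | the long-run estimator is a time-average over the trailing window; averaging several bins suppresses single-bin noise. The window is a definition choice, not a fitted value |
| `amplification` (AF) | 100 | dimensionless | soft-variant rate map `k_up = AF^(2(Norm−0.5))`, `k_down = 1/k_up`; 100 gives two orders of magnitude between a fully-on and fully-off gene while keeping `k_up·k_down = 1` so the pair only tilts, never accelerates, the clock |
| `tau` | 0.25 | normalized expression | binarization tail threshold for non-bimodal genes: only values mapping outside `(0.25, 0.75)` are called, yielding sparse, outlier-driven calls |
| `dip_p`, `bi_cut`, `kurt_cut` | 0.05, 1.5, 1 | — | the three bimodality gates; all three must agree before a gene is treated as two-state |
| `peak_frac` | 0.10 | fraction of range | a gene is zero-inflated when its kernel-density mode lies in the lowest 10% of the observed range — a scale-free formalization of "density peak close to zero" |

## Expression classification and the three transforms

Classification runs per gene on the cross-cohort distribution, after an
admissibility filter (amplitude at least one tenth of the median amplitude
across genes, at least 5% non-zero values) removes flat or dropout-ridden
genes.

* **Bimodal** genes get the posterior probability of the upper component
  of an equal-variance two-Gaussian fit. The same fit feeds the
  bimodality index `BI = sqrt(pi (1 - pi)) * |mu1 - mu2| / sigma` and the
  posterior, rather than refitting with free variances: equal variances
  guarantee a monotone posterior, so normalization can never invert the
  ranking of two samples.
* **Unimodal** genes are centered at the median and squashed through a
  sigmoid with slope `lambda = ln(3) / MAD`; the anchors (median ± MAD map
  to 0.75/0.25) follow from solving `1/(1 + e^(±lambda·MAD)) = 1/2 ∓ 1/4`.
  Median and MAD rather than mean and sd keep outliers from flattening
  the map.
* **Zero-inflated** genes are linearly rescaled on the 1st–99th
  percentile range with clipping, preserving the asymmetric shape.

The dip test is computed by a compiled implementation of the classic
greatest-convex-minorant / least-concave-majorant algorithm; the test
suite validates it against an independent linear-programming oracle
(minimizing the band half-width within which a convex-then-concave CDF
can track the empirical CDF) on small samples, plus exact structural
cases. P-values come from a seeded Monte-Carlo null of uniform samples —
the asymptotically least favorable unimodal distribution — cached per
sample size (1,000 draws by default, enough to decide the 0.05 gate).

Degenerate inputs: constant genes are discarded by the amplitude rule; a
unimodal gene with zero MAD falls back to IQR/1.349, and is discarded if
that is also zero; a zero-inflated gene with `q1 = q99` is discarded. The
mixture fit failing (degenerate data) yields `BI = 0`, i.e. never bimodal.

## Genomic inference

The cascade is deliberately conservative. Truncating variant classes are
loss of function outright. Missense variants must carry a deleteriousness
label (SIFT "deleterious" or PolyPhen "damaging"; "possibly_damaging"
counts, an inclusive reading) before either a curated per-variant effect
or a gene-role default (oncogene → gain, tumor suppressor → loss) is
applied — the label requirement filters likely passengers, and it is *not*
imposed on truncating calls, whose effect does not depend on fine protein
chemistry. Everything else infers nothing: an absent constraint is safer
than a wrong frozen node. The same principle resolves conflicts:
mutation-derived effects override CNA, truncating beats curated beats
role-based, and a same-precedence contradiction drops the gene for that
sample with a warning.

## Personalization

Strict Node Variants set the initial state to the data value and zero the
opposing rate, so the rule can never flip the node back — the
data-asserted state is absorbing for that node, and its simulated
probability equals the assigned value identically. Soft Node Variants
keep the rule active and only bias initial state and rates. Gene families
mapped to one node aggregate by arithmetic mean for continuous values
(no principled weighting is available without isoform-level knowledge)
and by consensus for discrete effects, dropping the node on disagreement.
Discrete CNA effects fed through the soft channel (recipe case3) use
their 0/1 value directly as the normalized input — CNA has no continuous
scale here, and the amplification map sends 0/1 to the extreme rate pair.
Patients missing a data type their recipe requires are excluded and
counted; nodes without any data keep the generic configuration. Protein
data, when present, supersedes RNA node-wise.

Per-patient seeds are derived from the master seed and the patient
identifier (a deterministic 31-bit hash), so adding or removing patients
never changes another patient's simulation.

## Synthetic data: what it does and does not emulate

The generators produce: a three-class expression cohort (balanced
two-Gaussian mixtures at standardized distance 4, unimodal Gaussians,
70%-zero exponential-tailed genes) on a nonnegative log-like scale;
mutation/CNA tables built from route-covering templates so every branch
of the inference cascade is exercised deterministically; exponential
survival with group-specific hazards and independent censoring; and two
models — a three-node toy (input, follower, complement) and an 11-node
cancer-pathway analogue whose p53/AKT mutual-inhibition race gives exact
wild-type read-outs of Proliferation = 1/27 and Apoptosis = 26/27, i.e. a
low-proliferative, high-apoptotic baseline with most nodes resolved near
0 or 1, as in published large cancer models.

They do **not** emulate: gene–gene correlation structure, batch effects,
library-size artifacts, subclonality or purity, annotation errors in
variant calls, or realistic linkage between expression and mutation
status. Passing tests therefore demonstrate correctness of the mechanics
and recoverability under clean conditions, not robustness to the full
messiness of a real cohort — the classification thresholds in particular
are known to be operating far from their decision boundaries on the
synthetic classes.

## Numerical choices

* **Ensemble engine** (C++): per-trajectory RNG streams seeded by
  splitmix64 of (master seed, trajectory index): reproducible,
  order-independent, and immune to R's global RNG state. Occupancy is
  accumulated exactly over jump intervals; an absorbed trajectory fills
  its remaining bins analytically.
* **Exact oracle**: uniformization on the sparse generator,
  `p(t) = Σ_k Pois(k; Λt) p₀ Pᵏ`, truncated at the 1e−12 Poisson tail;
  refused beyond 12 nodes or overly stiff rate-time products. Intended
  for unit-scale rates; amplified-rate configurations are validated
  through invariants (reciprocity, strict-node dominance) instead.
* **Comparisons against the oracle** in tests use bin-averaged exact
  solutions (Simpson on the bin) so discretization bias does not consume
  the Monte-Carlo error budget, and floor the empirical standard error at
  the known-probability binomial value near 0/1 where the sample SE
  degenerates.
* **Median split**: ties go to "low" (≤ median) — deterministic and
  documented; group sizes can differ by the number of ties.
* **Bootstrap CI**: percentile, 1,000 resamples, seeded, restoring the
  caller's RNG state.
* **Problem sizes**: the shipped test and acceptance runs use ensembles
  of 300–10,000 trajectories, cohorts of 10–60 genes × 200–1,000 samples,
  and 10–50 patients — sizes at which every check completes comfortably on
  a single core while keeping Monte-Carlo error well inside the stated
  tolerances.

## Known limitations

Only Boolean levels are supported (no multi-valued logic); SBML-qual /
GINsim import is out of scope (the BND/CFG dialect plus JSON export are
the interchange surface); the exact oracle is exponential in model size
by design; binarization rules for non-bimodal genes use the `tau`
tail-threshold convention; and survival modeling stops at group
construction — the tests call standard log-rank routines on the exported
tables rather than reimplementing them.
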