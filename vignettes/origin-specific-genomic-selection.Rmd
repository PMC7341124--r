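---
title: "Origin specific genomic selection: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Origin specific genomic selection: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osgs)
library(dplyr)
```

## The problem

When a breeder crosses an elite line with an exotic donor (a landrace or
wild relative), ordinary genomic selection on total predicted breeding
value tends to sweep the population back toward the elite genome: the
elite parent carries more favorable alleles on average, and favorable
donor alleles sit in repulsion with elite ones, so they are lost through
linkage drag. Origin specific genomic selection (OSGS) addresses this by
*partitioning* the genomic prediction by the parental origin of each
favorable allele and selecting on an index that can put weight back on
the donor component.

## Model

Marker effects come from the standard genomic-selection mixed model

$$y = Xb + Wu + e, \qquad u \sim N(0, I\sigma^2_u), \quad e \sim N(0, I\sigma^2_e),$$

with $W$ the line-by-marker matrix in **origin coding**: $-1$ for the
homozygous primary-parent (elite) genotype, $+1$ for the secondary
(donor), $0$ for heterozygotes. Under this coding the sign of an
estimated effect $\hat u_j$ identifies which parent carries the
trait-increasing allele, so for a trait where larger values are favorable
the marker classes are simply

* $P = \{j : \hat u_j < 0\}$ — favorable allele from the primary parent,
* $S = \{j : \hat u_j > 0\}$ — favorable allele from the secondary parent,

and the predicted breeding value splits additively:
$\hat a = W\hat u = W\hat u_1 + W\hat u_2 = \hat a_1 + \hat a_2$, where
$\hat u_1$ keeps the $P$ effects and $\hat u_2$ the $S$ effects. GS
selects on $\hat a$; OSGS selects on the weighted rank index

$$\mathrm{rank}(\hat a_1)\,\omega + \mathrm{rank}(\hat a_2)\,(1 - \omega),$$

with ranks ascending so the most favorable component value has the
highest rank. $\omega = 1$ selects on the elite component alone,
$\omega = 0$ on the donor component alone; intermediate weights trade
genetic gain against retention of favorable donor alleles.

```{r table1}
ex <- table1_example()
part <- partition_effects(ex$effects, "higher")
predict_breeding_values(ex$genotypes, part)
expected_component_correlations(part)
```

For unlinked markers of equal genotype variance, the expected correlation
between $\hat a$ and $\hat a_1$ is
$\sqrt{\sum_P \hat u_j^2 / \sum \hat u_j^2}$ (0.89 for the ten-marker
example above, and 0.45 for the donor component). The test suite verifies
this closed form against exact enumeration of all $2^{10}$ homozygous
genotype vectors.

## Estimation choices

**REML on the kernel spectrum.** `fit_ridge_blup()` profiles the
restricted likelihood on the spectral decomposition of the genomic kernel
$WW'$ projected on the orthocomplement of the fixed effects: one
symmetric eigendecomposition, then a one-dimensional optimization in
$\log\lambda$, $\lambda = \sigma^2_e/\sigma^2_u$, over
$\lambda \in [10^{-9}, 10^9]$. Variance components are floored at
$10^{-8}\,\mathrm{var}(y)$ so degenerate traits cannot produce an
infinite or zero ridge parameter; a trait that is constant after the
fixed effects returns a zero effect vector rather than an error. The
kernel-form BLUP $\hat u = W'(WW' + \lambda I)^{-1}(y - X\hat b)$ is
checked in the tests against the dense penalized-normal-equation ridge
solution (the Woodbury identity makes them equal), and REML itself is
checked by recovering a known heritability of 0.5 within $\pm 0.1$ on
self-simulated data (300 lines, 500 markers, 20 seeds).

**Sign partitioning.** Effects that are exactly zero form their own
class `Z` and enter neither component; they contribute nothing to any
prediction, and assigning them a side would be arbitrary. With
`favorable_direction = "lower"` the $P$/$S$ classes swap; the selection
indexes then rank with the sign flipped so that "larger criterion =
better" holds for every method.

**Distribution comparison.** `ks_compare_effects()` contrasts the
$|\hat u|$ distributions of the two classes with the two-sample
Kolmogorov–Smirnov test (asymptotic p-value at effective size
$n_P n_S/(n_P+n_S)$), reported as $-\log_{10}(p)$, with an optional
Bonferroni threshold of $0.05/n$ when many families are tested. The
statistic is verified against exhaustive evaluation of both empirical
CDFs.

**Estimator interface.** Ridge BLUP is the only estimator implemented;
`partition_effects()` accepts any `(marker, effect)` table, so sparser
estimators (LASSO-type) can be plugged in upstream without changing the
partitioning or selection machinery.

## Recoding and imputation of real marker data

`recode_biparental()` converts IUPAC calls to origin coding by matching
each call against the two homozygous parental calls; two-allele ambiguity
codes consistent with both parents are heterozygotes. Calls of `N`,
calls inconsistent with either parent (including heterozygous codes
involving a non-parental allele — the contingency is not covered by the
coding rules, so we treat it as missing rather than an error), and
markers monomorphic between the parents are set to missing. A marker at
which a *parent* is heterozygous cannot be origin-phased at all and is
dropped with a warning.

`impute_flanking()` fills each missing entry with the arithmetic mean of
the nearest non-missing marker value on each side, *nearest in map
order* (not in cM): the rule treats uneven maps the same as even ones,
and a run of missing markers takes the constant mean of its two flanking
values rather than a linear interpolation. Runs at chromosome ends copy
the single nearest value, and a line with an entire chromosome missing
is set to 0, the uninformative midpoint between the two origins (logged;
such a line carries no origin information on that chromosome in any
case). The operation is idempotent, never leaves the range of the line's
observed values on the chromosome, and fractional imputed values are
carried into prediction unchanged.

## The simulator

The simulator emulates the introgression study conditions:

* **Genome** — 10 chromosomes, 7,750 markers spread evenly over
  1,550 cM (0.2 cM spacing), all configurable via `sim_genome()`.
* **QTL architecture** — `sample_qtl_model()` draws QTL positions
  uniformly among markers at a density of 2 or 20 cM/QTL; effect
  magnitudes are half-normal with scale $1/\sqrt{p}$ so each QTL has
  $E[u^2] = 1/p$ and the aggregate QTL variance is 1. We read the
  stated "aggregated QTL marker variance equal to $p^{-1}$" as the
  per-QTL variance (aggregate 1): under this reading the all-elite
  parent has expected breeding value
  $(n_P - n_S)\sqrt{2/\pi}/\sqrt{p} = 4.44$ at 775 QTL and a 60:40
  ratio, matching the study's simulated 4.40, whereas the alternative
  reading (aggregate $1/p$) is off by a factor $\sqrt{p}$.
* **Meiosis** — Poisson crossover count per chromosome (mean = length in
  Morgan), uniform positions, no interference and no obligate chiasma,
  i.e. Haldane-consistent recombination fractions (checked in the tests:
  $r = \tfrac12(1-e^{-1}) \approx 0.316$ at 50 cM). The source study
  delegated meiosis to an external simulator without specifying its
  interference model; Haldane is the standard neutral choice.
* **Populations** — F2, BC1 and reverse-BC1 bases; four generations of
  single-seed descent (one selfed offspring per line, the simplest
  scheme consistent with "selfed for four generations"); double haploids
  by doubling one recombinant F1 gamete.
* **Recurrent selection** — phenotypes are true BV plus a standard
  normal residual; marker effects are fitted *once* on the cycle-0
  population and reused in every later cycle (retraining is available
  behind `retrain = TRUE` but off by default, matching the study
  design); each cycle crosses the top 5 lines in a half diallel and
  derives 20 DHs per cross, so the population stays at
  $\binom{5}{2} \times 20 = 200$ lines.

**Base population size.** The study does not state the size of the
cycle-0 population (that detail lived in supplementary material that is
not available). We default to 200 lines so the population size is
constant from cycle 0 onward — the same 200 that the crossing scheme
maintains — and expose it as `n_base`. Under this assumption the
simulator reproduces the published five-cycle endpoints within
Monte-Carlo error (GS cycle-5 mean BV ≈ 5.1–5.2 vs the published 5.29;
OSGS at $\omega = 0.5$ ≈ 4.3–4.4 vs 4.40, at 50–100 replicates) and the
published favorable-allele proportions closely (GS ≈ 0.46/0.13, OSGS ≈
0.37/0.20). Because the endpoint does vary with `n_base` (selection
intensity and training-set size both scale with it), the acceptance
test reports a sensitivity sweep over `n_base` ∈ \{100, 200, 400\}
whenever a run lands outside the comparison band. The per-replicate
standard deviation of the cycle-5 mean BV is large (~0.8), so
small-replicate comparisons against the published table are unreliable
below a few dozen replicates.

**Randomness.** Every replicate draws its own seed from the master seed
by a single `sample.int()` call, and each method re-seeds from a
per-replicate draw, so a method's trajectory is identical whether or not
other methods were run alongside it (tested). All stochastic entry
points take an explicit seed.

**What passing tests do and do not show.** The simulator reproduces
Mendelian segregation, Haldane recombination, inbreeding decay of
heterozygosity and the published population compositions; it does not
model crossover interference, mutation, dominance/epistasis,
genotype-by-environment interaction, or real linkage-disequilibrium
structure in the founders (founders are fully inbred and maximally
diverged). Agreement here therefore validates the selection machinery
under the stated idealization, not performance on any particular real
population.

## Problem sizes used in the checks

The package's own verification uses the full study geometry (7,750
markers, 775 QTL, 200 lines) for the composition and base-population
checks, 100 replicates in the acceptance script for the stochastic
quantities, and reduced replicate counts (24–50) plus a 100-marker
genome for the property-style test-suite checks, sizes chosen to keep
the default test run brisk while leaving the Monte-Carlo bands
comfortably tighter than the tolerances they guard.

## A small worked run

```{r run, eval = FALSE}
metrics <- run_recurrent_selection(
  pop_type = "F2", n_base = 200, density_cM_per_qtl = 2, ratio_P = 0.6,
  methods = c("GS", "OSGS"), omega = 0.5, n_cycles = 5, n_reps = 20, seed = 1
)
metrics |>
  dplyr::filter(cycle %in% c(0, 5)) |>
  dplyr::group_by(method, cycle) |>
  dplyr::summarise(dplyr::across(c(mu_BV, mu_P, mu_S), mean), .groups = "drop")
autoplot(metrics)
```

GS converts donor-favorable alleles into elite background (S falls from
0.20 toward ~0.13 by cycle 5) while OSGS at $\omega = 0.5$ holds S near
its starting value at a cost in total gain — the trade the selection
weight $\omega$ is there to control.

## Known limitations

* Only ridge BLUP is implemented natively; sparse-prior estimators must
  be fitted externally and passed in as effect tables.
* The expected-correlation formula assumes unlinked, equal-variance
  markers; on linked data it is an approximation (the within-sample
  Pearson correlations of `prediction_accuracy()` are the honest
  quantity there).
* Selection accuracy decays over cycles because effects are not
  re-estimated; this is faithful to the study design but pessimistic
  relative to a program that retrains.
* The five-cycle breeding-value endpoint depends on the undocumented
  base population size discussed above.
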