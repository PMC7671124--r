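---
title: "Parentage inference from pooled broods: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parentage inference from pooled broods: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolpat)
```

## The observation model

Many marine invertebrates deposit broods of thousands of embryos that are
far too numerous to genotype one by one. A practical alternative is pooled
genotyping: DNA is extracted from a few hundred embryos of one brood at
once, and the observable at each microsatellite locus is the *union of
alleles present in the pool* — not individual offspring genotypes, and not
allele dosages. poolpat is built around this observation model. The bundled
dataset comes from a population of the pair-living hermaphroditic limpet
*Siphonaria gigas*, where egg masses of >75,000 embryos were sampled as
pools of roughly 500 embryos and scored at four microsatellite loci, with
the maternal individual known by direct observation of egg deposition.

Alleles are treated strictly as categorical labels (PCR fragment lengths in
base pairs). No arithmetic is ever performed on fragment lengths: two
sequence variants of the same length would be indistinguishable anyway, and
all inference below only uses set membership.

## Minimum number of sires

Every embryo receives one maternal and one paternal allele, so any pooled
allele absent from the known mother must come from a sire. Let $k_\ell$ be
the number of non-maternal alleles at locus $\ell$. Since a sire carries at
most two alleles:

- **conservative estimate** (all sires assumed heterozygous):
  $\lceil k_\ell / 2 \rceil$;
- **liberal estimate** (all sires assumed homozygous): $k_\ell$.

The mass-level estimate is the **maximum** over informative loci, floored
at one. A maximum, not a sum, because the sires detected at different loci
are not distinguishable individuals — the same extra sire can explain a
novel allele at every locus. Loci without data (`ND`) are ignored; a mass
with no informative locus is an error, not a silent 1.

When the mother was never sampled (`NS`), the two most-explaining alleles
are assumed maternal and $k_\ell = \max(0, |\text{pool}_\ell| - 2)$. This
rule is the only one consistent with the per-mass estimates reported for
the two unsampled-mother masses in the bundled dataset, and such estimates
are flagged `maternal_known = FALSE`.

These choices reproduce the reported per-mass minimum-sires column exactly
(16/16 masses; `reproduce_reference_tables()`).

## Monogamy versus extra-pair paternity

For a brood of a paired mother whose social partner was genotyped, the
brood is *consistent with sexual monogamy* (MO) when every pooled allele at
every locus occurs in the mother or the partner, and shows *extra-pair
paternity* (EP) as soon as one allele at one locus falls outside that
union. A single novel allele suffices: with hundreds of embryos pooled, a
called allele is not a one-embryo artifact (and egg masses are scored only
for alleles seen in at least one adult,
`filter_alleles_to_adult_panel()`). Two diagnostic sets accompany each
call: loci where the partner cannot be the *sole* sire, and loci where the
pool contains *no* partner allele at all — the latter excludes the partner
as a sire outright, since a sire of any embryos would leave at least one
allele in the pool.

## Panel diagnostics

`panel_summary()` reports, per locus: allele counts, gene-count allele
frequencies, observed heterozygosity, Nei's unbiased expected
heterozygosity $\frac{2N}{2N-1}(1 - \sum_i p_i^2)$, a chi-square
goodness-of-fit test against Hardy–Weinberg expectations, the
homozygote-excess null-allele estimate $(H_e - H_o)/(H_e + H_o)$, and
parentage exclusion probabilities.

Numerical choices:

- **HWE test pooling.** Genotype classes with expected count below
  `min_expected` (default 1) are pooled, lowest first, into a single rare
  class; degrees of freedom are `classes − alleles`, floored at 1; the
  Yates continuity correction applies at one degree of freedom. This
  mirrors the common "minimum expected count" device of parentage software
  while remaining fully deterministic. p-values are reported raw and
  Bonferroni-multiplied across the panel.
- **Null alleles.** The closed-form homozygote-excess moment estimator is
  used rather than an iterative maximum-likelihood fit. Near zero — where
  a usable parentage panel lives — all common estimators agree; simulation
  tests show the estimator recovers a true null frequency of 0.1–0.2
  within ±0.05 at $N = 500$ and is unbiased to within 0.02 on clean
  Hardy–Weinberg data.
- **Small-sample $H_e$.** The unbiased estimator is used throughout, so
  third-decimal differences from software using the plug-in estimator are
  expected.

### Exclusion probabilities

The definitions are operational, not formula transcriptions. For a random
Hardy–Weinberg mother–father pair, their Mendelian offspring, and a random
unrelated Hardy–Weinberg candidate:

- $P_1$ (no parent known): the candidate shares no allele with the
  offspring;
- $P_2$ (one parent known): the candidate carries none of the alleles that
  could complete the offspring genotype paternally, given the true
  mother's genotype.

`exclusion_probabilities()` evaluates closed-form sums derived directly
from these definitions; `exclusion_probabilities_enum()` recomputes both by
brute-force enumeration of every
(mother, father, offspring, candidate) combination with generic
set-compatibility logic. The two routes must agree to $10^{-12}$, and do,
on randomized frequency vectors of up to eight alleles. Independent loci
combine as $1 - \prod_\ell (1 - P_\ell)$.

## PrDM: probability of detecting multiple paternity

`prdm()` estimates, by Monte Carlo, the probability that a brood truly
sired by several individuals is *called* multiply sired. A replicate draws
a Hardy–Weinberg mother and sires, assigns `n_offspring` embryos to sires
by a multinomial paternity-skew vector (shared across loci, as in a real
brood), and transmits alleles Mendelianly. Two detection models matter,
and the package implements both:

- **`detection = "pooled"`** (default): detection happens when some locus
  shows at least three non-maternal alleles in the pooled union — the same
  conservative rule the estimators above apply to real pooled data. Under
  this model a paternal allele identical to a maternal one is invisible.
- **`detection = "individual"`**: every offspring is genotyped separately,
  the classical assumption of published PrDM power tables. A paternal
  allele shared with the mother is then still observable (e.g. through
  homozygous offspring), and a brood is detected when *no single father
  genotype* can explain the offspring array at some locus (a two-allele
  hitting-set test over per-embryo paternal-allele possibility sets).

The distinction is large and real: with the bundled panel's frequencies,
two equal sires and 100 embryos give a detection probability near 0.96
under the individual model but only about 0.44 under the pooled model.
Published power tables for this kind of study are computed under the
individual model and therefore overstate the power of a pooled design;
both numbers are reported by `scripts/acceptance.R`.

`prdm_exact()` is the enumeration oracle for both models: it sums over all
multinomial embryo-to-sire assignments and all genotype/transmission
patterns, refusing state spaces beyond $10^7$ with a size estimate. It is
practical up to roughly two loci, three to four alleles, and four
offspring, and the Monte Carlo must agree with it within three binomial
standard errors (tested). One sire returns exactly zero without
simulation; a two-allele locus (or any three-allele locus under the pooled
rule with a known mother) can never trigger detection.

The mother is drawn afresh each replicate (marginal PrDM); replicate
counts default to 20,000 and a seed is mandatory. Only the known-mother
case is modeled exactly; the unknown-mother pooled rule is available in
the Monte Carlo for completeness.

## The synthetic mating system

`synth_config()` / `generate_population()` / `generate_masses()` /
`generate_eggmass_counts()` emulate the statistical structure of the field
system, with every random draw recorded as ground truth:

- per-locus allele frequencies from a symmetric Dirichlet
  (`dirichlet_alpha`, default 1) over 4–7 alleles per locus, matching the
  observed panel's allele-count range; adults are Hardy–Weinberg
  genotypes;
- 75% of adults paired (the observed pairing rate), with partner identity
  tracked; shell lengths normal by status, 50.6 ± 6.9 mm (paired) and
  47.2 ± 6.0 mm (solitary), the observed summaries;
- mating: a paired mother's partner sires with probability
  `p_within_pair_use` (default 0.8, reflecting predominantly within-pair
  mating observed in the field); extra-pair sires join with probability
  `p_extra_pair` (default 0.5) and are drawn uniformly — no spatial
  kernel, since per-individual coordinates are not available. The number
  of sires per mass follows `sires_per_mass_dist`, default
  {1: 0.8, 2: 0.2}; the observed data constrain this only to "one to two"
  under the conservative estimator, so the default is a labeled modeling
  choice, not an estimate. Sperm storage is represented only implicitly
  through this distribution;
- broods: 500 embryos pooled per mass (the study's pooling depth), embryos
  allocated to sires multinomially with equal expected shares unless
  `paternity_skew` is set; an allele enters the pooled set when at least
  `detection_min_count` embryos carry it (default 1; larger values emulate
  read-depth dropout);
- egg-mass output: per-cycle counts are negative binomial
  ($\log \mu = a_{\text{status}} + 0.0471 \cdot \text{length}$, size
  $\theta = 5$) truncated at two masses per cycle, summed over four
  cycles. The status intercepts are solved numerically (normal-integral
  expectation of the truncated mean, then `uniroot`) so the *truncated*
  status-marginal means equal the configured targets 1.57 (paired) and
  0.81 (solitary) — the observed means. The reported status-specific
  spreads imply different dispersions by status (about 8 paired, 2
  solitary); a single middling $\theta = 5$ is used since only the means
  are modeled as targets.

What the generator deliberately does **not** emulate: genotyping error and
stutter artifacts, linkage between loci, spatial structure of extra-pair
mating, temporal sperm-storage kinetics, inbreeding, and social-status
transitions. Tests passing on synthetic data therefore validate the
estimators' logic under clean Mendelian inheritance, not robustness to
scoring error — the adult-panel allele filter is the only artifact guard.

`recovery_experiment()` runs generate → estimate → classify and reports
estimated versus true multiple-paternity frequencies, extra-pair
frequencies, and the sire-count confusion table. Two properties are
enforced by tests: the conservative estimator never exceeds the true sire
count, and a strictly monogamous configuration yields zero extra-pair and
zero multiple-paternity calls. The liberal estimator carries no such
guarantee — assuming homozygous sires can overcount — and is reported as
such.

## Problem sizes and tolerances

Stochastic checks use: 2,000 masses for generator/classifier agreement
(binomial 3-SE tolerance, combined with Monte Carlo error where two
stochastic quantities are compared), 20,000 Monte Carlo replicates for
PrDM (3 SE against the exact oracle), 10,000 adults for egg-mass output
means (2 SE), 200 replicates of $N = 500$ for null-allele bias, and 100
randomized frequency vectors for the $10^{-12}$ closed-form/enumeration
agreement. Seeds are fixed in every stochastic test.

## Known limitations

- The bundled adult table contains the 16 adults recoverable from the
  printed study tables; three further genotyped adults exist only in the
  study's archived dataset and carry rare alleles seen in egg masses
  (e.g. 269 at MS-26). Frequency-based statistics computed from the
  bundled table (combined exclusion probabilities, PrDM with
  panel-estimated frequencies) are therefore slight underestimates of the
  full-data values.
- Shared alleles between mother and sire are never attributed; the
  conservative estimator is a lower bound by construction.
- No likelihood-based parentage assignment, no sibship reconstruction, and
  no sperm-precedence modeling are attempted.
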