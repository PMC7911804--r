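---
title: "Assessing genetic variability from pedigrees and STR panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing genetic variability from pedigrees and STR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedvar)
```

## Scope and model

`pedvar` assesses genetic variability in a small, closed animal
population — the motivating case is a rare studbook dog breed such as the
Polish Greyhound — from two complementary data sources:

1. **The pedigree**: a registry of animals with sire, dam, sex, birth
   year and breeding status, with unknown parentage allowed (the `NN`
   convention of studbooks).
2. **A microsatellite panel**: diploid STR genotypes, by default the 21
   ISAG-recommended canine parentage markers, with alleles recorded as
   fragment lengths in base pairs.

The pedigree side rests on identity-by-descent probabilities; the marker
side on allele-frequency summaries and an exact test of Hardy–Weinberg
proportions. Both sides share one assumption set: autosomal loci, no
selection or mutation within the time horizon, and fair Mendelian
segregation.

## Pedigree statistics

### Kinship and inbreeding

The coancestry $f(i,j)$ is the probability that random alleles drawn one
from each animal are identical by descent. `kinship_matrix()` uses the
tabular method over a topological ordering: with parents $s, d$ of $i$,

$$f(i,i) = \tfrac12\bigl(1 + f(s,d)\bigr), \qquad
  f(i,j) = \tfrac12\bigl(f(s,j) + f(d,j)\bigr),$$

an unknown parent contributing 0 (every unknown slot is treated as a
distinct phantom founder, unrelated and non-inbred — the standard device
that makes the recursion total on half-known parentage). The inbreeding
coefficient is $F_i = f(s_i, d_i)$ and average relatedness
$AR_i = \frac1N \sum_j 2 f(i,j)$, self included. All values are dyadic
rationals, so double-precision arithmetic is exact; the test suite
verifies the matrix against an independent Wright path-counting
enumerator to $10^{-12}$ on random pedigrees.

### Mean kinship, gene diversity, founder genome equivalents

For a cohort, mean kinship $MK$ averages $f$ over all ordered pairs
*including* self-pairs (the "mean kinship matrix" convention of captive
population-management software; an `include_diagonal = FALSE` option
exists because published reports rarely state the convention). Then gene
diversity is $GD = 1 - MK$ and founder genome equivalents
$f_{ge} = 1/(2\,MK)$: the number of equally contributing founders with
no random allele loss that would yield the observed diversity. These
identities, not any particular printed rounding of them, are the
package's contract — e.g. $MK = 0.138$ implies $GD = 0.862$ and
$f_{ge} \approx 3.62$.

### Rate of inbreeding and effective population size

`delta_F_and_Ne()` uses the individual-increase formulation. With
equivalent complete generations
$t_i = \sum_{\text{known ancestors}} (1/2)^{g}$, each animal with
$t_i > 1$ contributes

$$\Delta F_i = 1 - (1 - F_i)^{1/(t_i - 1)},$$

and the realized effective size is $N_e = 1/(2\,\overline{\Delta F})$.
The exponent discounts the animal's own generation: in an idealized
population inbreeding lags the mating system by one generation
($F$ first appears in generation 2), and with $t-1$ the estimator is
consistent for the true per-generation rate — the package's closed
random-mating simulator (`simulate_closed_population()`, 10 sires and
10 dams per generation, idealized $N_e \approx 20$) recovers
$N_e$ within 10%. A demographic alternative
$N_e = 4N_mN_f/(N_m+N_f)$ from breeder counts is reported alongside,
because the two estimators answer slightly different questions and
published reports rarely say which was used.

### Gene drop and founder genome surviving

`run_gene_drop()` labels each founder's two alleles uniquely and
transmits them down the pedigree with fair coin flips. Retention
$r_f$ is the expected fraction of founder $f$'s alleles present in the
scoring cohort, and founder genome surviving is $FGS = \sum_f r_f$, with
a Monte-Carlo standard error from the replicate-level totals. The
literature names this statistic more often than it defines it; the
definition here follows the founder-genome framework in which $FGS$
equals the founder count when nothing has been lost, and exceeds
$f_{ge}$ otherwise (retention ignores the evenness of surviving
contributions, which $f_{ge}$ penalizes). Phantom founders carry real
genome and are scored by default; `named_founders_only = TRUE` restricts
the accounting to records with both parents unknown. Closed forms anchor
the tests: a single offspring always carries exactly half of each
parent's labels; two offspring retain $\tfrac34$ in expectation.

### Descriptive registry statistics

`identify_founders()` reports both founder definitions at once —
"any unknown parent" (the default, matching studbook practice for breeds
with open preliminary books) and the stricter "both parents unknown"
subset. `classify_matings()` assigns each animal with two known parents
to parent–offspring, full-sib or half-sib classes, checked in that
order so the classes are disjoint, and reports percentages over the
total record count (the convention under which 2 such animals among 912
registrations are 0.22%). `litter_statistics()` distinguishes full-sib
groups (same sire and dam) from litters (same sire, dam and birth year)
and summarizes groups of size ≥ 2, the studbook reporting convention.

## Marker statistics

Per locus, with allele frequencies $p_a$ over the $n_L$ typed animals:

* $He = 1 - \sum_a p_a^2$ (plain; an unbiased variant multiplies by
  $2n_L/(2n_L - 1)$),
* $PIC = 1 - \sum_a p_a^2 - \sum_{a<b} 2 p_a^2 p_b^2$ (Botstein's
  informativeness measure, always ≤ He),
* $F_{IS} = 1 - Ho/He$, negative under heterozygote excess.

The **plain** He is the default because it reproduces published canine
panel tables to their printed precision; published frequency columns are
rounded to three decimals (some sum to 0.999–1.008), which propagates
about ±0.005 into He and PIC, so the package renormalizes off-unity
frequency vectors with a warning and the tests compare printed values at
that tolerance. Panel means are unweighted across loci, matching how
such tables print their bottom row.

One estimator subtlety matters for null calibration: the plain He
computed from sample frequencies is biased downward by a factor
$1 - 1/(2n)$, so under perfect random mating $E[F_{IS}] \approx
-1/(2n)$ — at $n = 174$ about $-0.003$, the same order as the
Monte-Carlo resolution of a 200-replicate calibration. The null-FIS
calibration in the test suite therefore uses the unbiased He, while
table reproduction keeps the plain default.

## The exact Hardy–Weinberg test

Conditional on the allele counts $m_a$, the probability of a genotype
array $\{n_{ab}\}$ under Hardy–Weinberg proportions is

$$P = \frac{n!\,\prod_a m_a!\,2^{h}}{(2n)!\,\prod_{a \le b} n_{ab}!},$$

with $h$ the number of heterozygotes. `hwe_exhaustive()` enumerates the
whole fiber when it is small (the oracle; probabilities are verified to
sum to 1) and reports the exact-test p-value: the total probability of
arrays no more probable than the observed one, ties included.

`hwe_mcmc()` handles real panels. The chain is run on the underlying
*pairing* of the $2n$ alleles rather than on genotype arrays: a move
picks two pair slots and swaps one member between them. In that lifted
representation the stationary law is uniform, so every proposal is
accepted, and the induced walk on arrays is exactly the classical
genotype-switch chain with its correct Hastings ratio — a formulation
chosen because a Metropolis rule using only the ratio of array
probabilities, without the proposal correction, does not leave the
conditional law invariant. Defaults follow common practice for this
test: 100 batches and 10,000 dememorization steps, with 5,000 sampled
switches per batch (the per-batch count is rarely printed in
applications; all three are arguments). The p-value's standard error
comes from between-batch variance; the chain is deterministic given an
integer seed via a self-contained 64-bit generator, so results are
reproducible across platforms. The test suite checks the chain against
the exhaustive oracle on 200 random small fibers and verifies its
type-I error at nominal 0.05 over 1,000 simulated loci at $n = 174$.

## Synthetic data

The study populations this package targets are documented in
non-deposited studbooks, so the generators are first-class components:

* `simulate_pedigree()` grows a registry over birth-year cohorts with
  overlapping generations: founders enter over the early cohorts (83
  with ≥ 1 unknown parent, 27 with both unknown, by default), litters of
  2–16 pups (mean ≈ 6, via $2 + \min(\text{Pois}(4), 14)$) are produced
  by pairs of breeding age 1.5–10 years, one litter per dam per year,
  and close-kin pairs are rejected under the default policy. Planted
  close matings (full-sib, half-sib, parent–offspring) are injected in
  scheduled years as single-pup litters, so the classifier's per-record
  counts equal the planted mating counts exactly — this is how the
  2/21/2-in-912 configuration (0.22% / 2.30% / 0.22%) is reproduced.
  Founder sexes alternate so tiny configurations always contain a
  breeding pair; internal birth times are fractional years (honoring the
  1.5-year minimum) and are emitted as integer years, the studbook
  granularity.
* `simulate_genotypes()` drops Mendelian STR genotypes down any
  pedigree, founders drawing from configurable frequency sets that
  default to the bundled 21-locus reference panel
  (`greyhound_frequencies()`), with an optional missingness rate.
* `fixture_bundle()` writes a matched pedigree CSV + GenePop file +
  summary JSON, byte-stable given its seed; seeds are propagated through
  named sub-streams so components can be regenerated independently.

What the generators do *not* emulate: genotyping error beyond
missingness, mutation, selection on phenotype, non-random sampling of
the genotyped subset, and the year-by-year census trajectory of any real
breed. Passing tests therefore demonstrate the correctness of the
estimators under their stated assumptions, not the field realism of any
particular breed's history.

## Numerical and design choices

* Kinship is computed on the full pedigree and then subset to a cohort;
  truncating the pedigree first would change $F$.
* Kinship/inbreeding values are dyadic rationals, exact in doubles; the
  oracle comparisons use $10^{-12}$ only as a formality.
* Exact-test ties are counted into the rejection tail with a relative
  $10^{-9}$ log-probability tolerance, in both the exhaustive and the
  MCMC path, so the two methods agree on tie handling.
* `hwe_test()` switches from enumeration to MCMC when a composition
  bound on the fiber size exceeds 20,000 states.
* Degenerate inputs: a monomorphic locus returns $p = 1$ with zero SE;
  FIS at $He = 0$ is NA with a warning; a pedigree with no $t_i > 1$
  refuses to estimate $\Delta F$.
* Problem sizes in the test suite (200 oracle pedigrees of ≤ 50 animals,
  200 small HWE fibers, 1,000 type-I loci, 200 FIS calibration
  replicates, 10,000 gene-drop replicates) were chosen as the smallest
  sizes at which the Monte-Carlo bounds quoted above are meaningful.

## Known limitations

* The pedigree-side headline numbers of any particular breed (mean F,
  AR, $f_{ge}$, $N_e$) depend on its actual registry, which for the
  motivating breed is not public; the package validates those estimators
  by property (oracles, closed forms, parameter recovery) rather than by
  reproducing unpublishable values.
* The dense kinship matrix is comfortable to a few thousand animals;
  very large registries would need a sparse or blockwise approach.
* The demographic $N_e$ uses pedigree-wide breeder counts; with strongly
  overlapping generations it is a coarse summary.
* GenePop support covers the single-population, 3-digit-allele dialect
  used for panel tables, not the format's every variant.
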