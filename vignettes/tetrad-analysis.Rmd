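---
title: "Tetrad analysis: models, estimators, and the forward meiosis simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetrad analysis: models, estimators, and the forward meiosis simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradkit)
```

## The measurement

When a *Saccharomyces cerevisiae* diploid heterozygous at several loci goes
through meiosis, the four haploid spores of each ascus can be dissected,
germinated and genotyped together. A tetrad is therefore a complete record
of one meiosis, and three classical quantities can be read off a collection
of them:

* **Genetic map distances.** For two linked heterozygous markers, each
  4-spore-viable tetrad is a parental ditype (PD; two spore genotypes, both
  parental), a tetratype (TT; all four genotypes) or a nonparental ditype
  (NPD; two genotypes, both recombinant). Zero crossovers in the interval
  give PD, a single crossover gives TT, and only double (or higher)
  crossovers can give NPD.
* **Crossover interference.** In most organisms a crossover suppresses
  further crossovers nearby, so double crossovers — and hence NPDs — are
  rarer than independence predicts.
* **Gene conversion.** A heterozygous marker normally segregates 2:2.
  Non-reciprocal repair during recombination produces 3:1 or 1:3 tetrads,
  the footprint of a conversion event at that marker.

The package also summarises spore viability (how many of the four spores
germinate) and infers meiosis-I nondisjunction of the MAT-bearing
chromosome: an MI nondisjunction followed by a normal MII produces a tetrad
whose two surviving spores are MATa/MATalpha disomes, and such spores mate
as neither **a** nor **alpha**. Counting 2-spore-viable tetrads whose both
survivors are nonmaters therefore estimates the MI nondisjunction rate of
chromosome III.

## Estimators

With counts $PD$, $TT$, $NPD$ and $N = PD + TT + NPD$ for one interval:

**Perkins map distance.**
$$\widehat{cM} = 100\,\frac{TT/2 + 3\,NPD}{N}.$$
The $TT/2$ term is the recombinant-spore frequency contributed by single
crossovers; the $3\,NPD$ term corrects for double crossovers. Its standard
error comes from the multinomial delta method with $t = TT/N$, $d = NPD/N$:
$$\widehat{se} = 100\sqrt{\frac{t(1-t)/4 + 9d(1-d) - 3td}{N}}.$$

**Papazian expected NPD.** If crossovers occurred without interference, the
observed tetratype frequency $f_T = TT/N$ implies an expected NPD count
$$E[NPD] = N\cdot\tfrac12\!\left[1 - f_T - (1 - 3f_T/2)^{2/3}\right].$$
The interference ratio is $NPD_{obs}/NPD_{exp}$, with values below 1
indicating positive interference. Its standard error is computed as
$ratio/\sqrt{NPD_{obs}}$, treating the observed NPD count as Poisson. When
$NPD = 0$ the ratio is undefined and is reported as `n.d.`.

Two numerical choices deserve mention:

* For $f_T > 2/3$ the bracket's base is negative; the power is evaluated
  with the real cube root, $(x)^{2/3} = (x^2)^{1/3}$, which keeps the
  expectation defined and continuous. Tetratype frequencies above 2/3 do
  occur in real tallies and yield finite, sensible ratios there.
* The delta-method SE and the Poisson ratio SE reproduce almost all of the
  reference values produced by the field's online calculators, but those
  tools do not publish their error formulas, and a few cells differ by one
  unit in the last printed digit (the worst ratio-SE discrepancy, 0.09
  versus 0.06, sits exactly at an $f_T > 2/3$ cell). The package reports
  its own delta-method/Poisson values rather than emulating an
  unspecified formula.

**Rounding conventions.** All arithmetic is done at full precision;
reports round half-up at presentation time: distances and SEs to 1 decimal,
ratios and their SEs to 2 decimals, percentages to integers.
Cumulative chromosome lengths are sums of the 1-decimal interval distances,
matching how such totals are conventionally tabulated next to 1-decimal
interval values; full-precision sums are available via
`chromosome_cumulative(..., digits = Inf)`. The per-tetrad
gene-conversion ratio against the reference strain is likewise the ratio of
the 2-decimal rates, which is what appears next to 2-decimal columns in
published tables.

## Classification and filtering rules

* Segregation patterns are scored over the four spores of 4-spore-viable
  tetrads only; any missing allele makes the marker `incomplete`.
* 4:0 and 0:4 patterns are counted as conversions but flagged separately
  (`n_flagged_40`), since with independently scored markers they can also
  arise from genotyping error.
* An interval's PD/TT/NPD tally excludes a tetrad exactly when either
  flanking marker is non-2:2 or incomplete. This is why interval totals
  within one strain differ from each other.
* Mapping uses tetrads with exactly 4 viable spores and at most 2 gene
  conversions (`filter_for_mapping()`, cap configurable). Counts removed by
  each rule are reported and attached to the result, so input = kept +
  excluded is auditable at every stage.
* Dead spores carry no genotype; nothing is inferred about them. A
  not-determined mating phenotype is missing data: a 2-spore-viable tetrad
  enters the nondisjunction denominator only when both surviving spores
  were actually typed.
* All p-values are reported unadjusted; the analyses these tables support
  are single planned comparisons per strain, and no multiple-testing
  correction is applied by default.

## Statistical tests

The two-proportion Z-test (pooled SE, two-sided; `two_proportion_z()`) is
used for conversion frequencies; its square equals the uncorrected
chi-square statistic, which the tests verify. Fisher's exact test
(`fisher_exact_2x2()`) uses the probability-mass two-sided convention via
`stats::fisher.test()`, and the test suite checks it against explicit
hypergeometric enumeration. `student_t()` exposes the 1/2-tailed and
paired/unpaired Student variants through `stats::t.test()`.

For tetrads carrying exactly two conversions, `gc_adjacency_test()` asks
whether the converted markers are adjacent more often than chance. The
null model draws the pair uniformly from all $\binom{M}{2}$ marker pairs;
a pair is adjacent only if consecutive on the same chromosome, so the
9-marker map gives $P(\text{adjacent}) = 7/36$. The alternative — long
conversion tracts spanning neighbouring markers — would inflate adjacency.
The comparison is an exact binomial test. This uniform-pair null matches
the simulator's assumption that conversions strike markers independently.

## The forward simulator

`simulate_experiment()` generates tetrad tables with the statistical
structure the estimators assume, so every stage of the analysis can be
validated by parameter recovery without external data.

* **Coordinates** are genetic (Morgans); markers are points on each
  chromosome's chiasma line. No physical coordinates exist in the model.
* **Chiasmata** come from the counting model: with interference parameter
  $m = 0$, the count on a bivalent of length $x$ Morgans is Poisson with
  mean $2x$ and positions are uniform (each chiasma involves 2 of the 4
  chromatids, so per-chromatid crossovers average $x$ — the Morgan
  definition). For $m > 0$, every $(m+1)$-th event of a rate-$2x(m+1)$
  Poisson stream is a chiasma, with uniformly random initial phase; the
  enforced gaps produce positive interference while preserving the mean.
* **Strand choice** is uniform with no chromatid interference: each chiasma
  exchanges the material distal to its position between one strand carrying
  P-derived and one carrying Q-derived material *at that position*. Choosing
  by local content rather than by original strand label matters: after an
  earlier crossover, a label-based choice can pair two strands that locally
  carry the same homolog's material, making the exchange genetically
  silent and deflating crossover counts in distal intervals. Under the
  content-based rule the conditional tetratype probability given $k$
  chiasmata is Mather's $\tfrac23\bigl(1 - (-\tfrac12)^k\bigr)$, which the
  tests verify directly.
* **Segregation.** Sisterhood is defined by centromere origin, tracked
  through the exchanges. MI orientation and MII spore assignment are
  randomised per chromosome. MI nondisjunction sends both homologs to one
  pole: two disomic viable spores, two nullisomic dead ones. An MII
  missegregation (following precocious sister separation) makes one spore
  disomic and its sister nullisomic, typically yielding 3-spore-viable
  tetrads. These two event classes reproduce the diagnostic viability
  signatures: MI events enrich the 2-viable class with double-nonmater
  survivors; MII events enrich the 3-viable class.
* **Gene conversion** strikes each marker independently with probability
  `gc_prob` and overwrites one uniformly chosen spore's allele, giving 3:1
  and 1:3 with equal probability. There is no tract-length model and no
  conversion-associated crossover, matching the adjacency test's null.
* **Mating phenotype** follows MAT content: a single P allele mates as
  **a**, Q as **alpha**, both as a nonmater. A heterocentromeric disome
  (the MI nondisjunction product) is assigned the nonmating phenotype
  structurally. This is an idealisation: with MAT 19.3 cM from CEN3, a
  CEN-MAT crossover can in reality leave a disome homoallelic at MAT, so a
  real dissection would slightly undercount nondisjunction events. The
  idealisation is what makes the inference exactly invertible in
  validation runs.
* **Determinism.** One RNG stream per experiment; the seed is mandatory,
  echoed in the output header, and the per-meiosis order of draws is fixed
  (chiasmata, strands, segregation mode, orientation, conversion, death).
  Identical configurations produce byte-identical tables.

### Defaults

The default configuration emulates a wild-type dissection: true interval
distances 28.4, 19.3, 35.0, 20.8 cM (chromosome III) and 41.6, 10.6,
32.4 cM (chromosome VIII); `gc_prob = 0.015` per marker, which over 9
markers gives ~0.135 conversions per tetrad, the wild-type rate;
`death = 0.04`, matching ~96% spore viability. Missegregation rates are not
quantified by dissection data, so the defaults (`mi_ndj = 0.002`,
`mii_pssc = 0.005`) are illustrative, small enough to keep the 4-viable
class near its observed frequency. The default `m = 0` is the
no-interference baseline under which the Perkins and Papazian formulas are
exact expectations; runs probing interference pass `m` explicitly (values
of 4-10 reproduce observed interference ratios of ~0.1-0.4).

### What the simulator does and does not establish

Passing parameter-recovery tests shows the estimators are correct *for
data generated under the model's assumptions*: independent meioses, no
chromatid interference, conversions independent of crossovers, death
independent of genotype. Real dissections can violate any of these
(conversion-associated crossovers, genotype-linked death, scoring errors),
so recovery results bound estimator correctness, not data quality.

A genuine limitation surfaced by validation: under the no-interference
model the exact expectation of the Perkins statistic for an interval of
$x$ Morgans is
$$100\left[\tfrac32\,(1 - e^{-2x}) - \tfrac23\,(1 - e^{-3x})\right]
  = 100\,(x - x^3 + O(x^4)),$$
so intervals beyond ~25 cM are systematically shortened (about 1.6 cM at
28.4 cM, 4.5 cM at 41.6 cM) — triple and higher crossovers that the
$3\,NPD$ term does not correct. Positive interference suppresses exactly
those multi-crossover meioses, which is why the estimator performs better
on strongly interfering chromosomes than the no-interference analysis
suggests. The test suite asserts simulated estimates agree with this
closed form, and recovery-of-truth holds cleanly for intervals up to
~20 cM.

### Validation problem sizes

The shipped tests use 5 000 meioses for full-map recovery runs, 3 000 for
interference and nondisjunction recovery, 10 000 draws per condition for
conditional tetratype probabilities, and $10^5$ multinomial resamples for
the delta-method SE oracle. These sizes put Monte-Carlo error well below
the tolerances being asserted while keeping the suite fast.

## File formats and reproduction

Tetrad tables are tab-separated with a versioned `#` header (provenance,
including the seed, for simulated tables), one row per spore, alleles
coded `P`/`Q`/`-`; concrete allele names (e.g. HIS4/his4) belong in the
marker-map configuration, keeping classification generic. Reports are
tab-separated mirrors of the three standard table layouts plus
full-precision companions, with `n.d.` emitted verbatim.

The bundled dissection counts (`tetrad_count_data()`) carry the published
values alongside the raw counts; `reproduction_checks()` (or the
`reproduce` CLI subcommand) recomputes every derived quantity and diffs it
against the printed value — map distances and percentages must match
exactly at printed precision, while standard errors and interference
ratios, whose original computation used an external tool with an
unpublished error formula, are allowed one unit in the last printed digit.
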