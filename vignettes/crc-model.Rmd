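---
title: "Cosegregation of recombinant chromatids: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cosegregation of recombinant chromatids: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcmeiosis)
```

## The biological problem

Auto-pseudogamous nematodes such as *Mesorhabditis belari* produce ~90%
asexual females and ~10% sexual males. The females' diploid oocytes arise
from a meiosis whose first division fails: after replication and one
crossover per bivalent, a single equational division retains one chromatid
from each homolog (two *nonsister* chromatids). Because recombination is
active, random assortment of those nonsister chromatids should homozygose
every locus distal to the crossover — yet these genomes stay heterozygous
genome-wide. The resolution is a segregation bias: the two *recombinant*
chromatids of a bivalent cosegregate into the oocyte (CRC), which transmits
the mother's complete diploid genotype.

`crcmeiosis` implements this meiosis with an evolvable cosegregation bias,
embeds it in an island-model life cycle, and provides the study system's
bespoke statistics: an exact parity test for chromatid-paint counts, a
multinomial likelihood-ratio screen for sister read counts, and the
population-genomic summaries (heterozygosity, F~IS~, r²).

## The meiosis model

Each chromosome receives exactly one obligate crossover per meiosis, at a
coordinate drawn uniformly on (0, 1). The position law is a modeling choice:
the empirical observation the model mirrors is that recombination (and
heterozygosity) is *not* confined to chromosome ends, and a uniform law is
the least-structured choice consistent with that. After replication and the
crossover, each homolog contributes one nonrecombinant (N) and one
recombinant (R) chromatid. The retained oocyte pair takes one chromatid per
homolog, so four assortments exist: {R,R}, {N,N}, {R,N}, {N,R}. The two
matched pairs conserve heterozygosity at every locus; the two mixed pairs
homozygose every maternal-heterozygous locus distal to the crossover
("distal" is the end beyond the crossover coordinate; one fixed orientation
per chromosome).

The cosegregation bias `b` in [-1, 1] tilts these odds. The per-chromosome
LOH probability is

    beta = (1 - b) / 2

so `b = 1` (always a conserving pair) gives beta = 0, `b = 0` recovers the
uniform assortment law (beta = 1/2), and `b = -1` (a recombinant always
retained with a nonrecombinant) gives beta = 1. `enumerateAssortments()` and
`lohProbDistal()` expose this enumeration; `automicticOocyte()` samples it.

Which conserving pair is retained is biologically undetermined: the parity
data cannot distinguish "always both recombinants" from "both recombinants
or both nonrecombinants with equal odds", since both keep heterozygosity
intact and differ only in distal phase shuffling (they affect linkage, not
heterozygosity or F~IS~). Both are kept as `nonLohMode` options and the
default is `recombinants_only`, the titular mechanism.

```{r meiosis}
g <- diploidGenome(uniformLocusMap(5, 4))   # het at all 20 loci
res <- automicticOocyte(g, meiosisConfig(bias = 1))
all(heterozygosity(res$oocyte))             # full CRC: no LOH, ever
```

## Life cycle and fitness regimes

Generations are discrete and nonoverlapping. Each deme of size `demeSize`
regenerates itself from fitness-weighted mothers: an offspring is automictic
(an asexual female carrying the mother's post-meiosis genome) with
probability sigma_i, else amphimictic with a fitness-weighted father —
a sexual female with probability phi_i, a male otherwise. Small demes plus
rare migration (`migration`) stand in for the strong consanguineous mating
structure of natural populations; no explicit pedigree is modeled. When
`sexRatioTarget` is set (default policy in the evolution experiments),
phi_i = 1 - target/(1 - sigma_i), which pins the expected male share (10%
in the natural system) while pseudogamy spreads. The automixis rate is
capped at `sigmaMax = 0.9`: males must keep being produced because sperm is
required to activate every oocyte.

Two regulation details keep the demography honest. First, a deme whose own
males all died is served by roaming males from the rest of the
metapopulation (extinction occurs only when males vanish everywhere);
second, a deme whose amphimictic offspring happened to be single-sex has one
of them resampled, so demes keep at least one individual of each sex
whenever that is possible. Without these, binomial sampling of ~10% males in
demes of a few dozen individuals causes a steady drumbeat of irreversible
deme extinctions that is an artifact of small-deme discretization, not of
the biology being modeled.

Fitness comes in three regimes:

* `neutral` — everyone has fitness 1.
* `explicit_deleterious` — recessive (or partially dominant) deleterious
  alleles at dedicated loci *interleaved on the same chromosomes* as the
  neutral markers (linkage is what lets LOH expose load). Fitness is
  (1 - hs)^n_het (1 - s)^n_hom. Mutation is irreversible 0 to 1 at rate
  `uDel` per haplotype per locus; populations are initialized at the
  recessive mutation–selection equilibrium frequency sqrt(uDel/s).
  Defaults (uDel = 1e-3, s = 0.2, h = 0) give a modest, realistic load.
* `phenomenological_delta` — automictic offspring pay
  `w = 1 - delta * exposure / 0.25`, where *exposure* is the structural LOH
  exposure of the meiosis that produced them: the mean over chromosomes of
  I(LOH assortment) x (1 - crossover position). Its expectation at
  beta = 1/2 is exactly 1/4, so a fully random segregation costs `delta` on
  average and full CRC costs nothing. The cost is deliberately a function
  of the meiosis events, not of the current neutral heterozygosity: the
  biological cost it abbreviates (exposure of recessive deleterious
  mutations, replenished every generation by mutation) does not fade away
  once neutral markers have become homozygous. Conditioning the cost on
  remaining marker heterozygosity would let pseudogamy sneak through any
  threshold after an initial LOH phase, which contradicts the explicit-
  mutation model it stands in for. Negative values are clamped to zero.

## Evolution experiments

`invasionExperiment()` starts from a fully sexual population (sigma_i = 0)
with 10% males and lets a sigma-raising modifier locus mutate;
`crcSelectionExperiment()` starts already pseudogamous (sigma = 0.9) and
lets the bias locus evolve from b = 0. Modifier loci are unlinked to the
markers and to each other, additive with clamping to the legal range, and
maternal-acting (an individual's sigma_i and b_i govern her own meiosis).
They are implemented as fully proximal loci: automixis transmits both
alleles intact, amphimixis transmits one random allele per parent. Modifier
mutation is a Gaussian step (SD 0.25, rate 0.01 per allele per generation)
in *both* directions — negative-bias mutants (more LOH) arise as readily as
positive ones. Small Gaussian steps rather than jump-to-extreme alleles are
a choice: nothing in the modeled biology singles out large-effect alleles,
and gradual alleles make "never selected for" a meaningful statement about
a whole mutational spectrum.

The classic logic: an automictic daughter carries two maternal allele
copies where a sexual one carries one, so pseudogamy doubles transmission
at cost `delta` — it should invade when 2(1 - delta) > 1, i.e.
delta < 1/2. The packaged experiments recover this threshold by simulation
(delta = 0.4 invades, delta = 0.6 does not), and with the bias locus
evolvable, CRC rescues pseudogamy even above the threshold by removing the
LOH cost.

Problem sizes used throughout (tests and the acceptance script) are a
deliberately compact experimental design: 5 demes x 40
individuals (total 200), 20 neutral loci on 5 chromosomes, 20 replicates,
at most 2000 generations. These sizes resolve the threshold crisply while
keeping a full experiment in the minutes range; the original design (total
population 1000, migration 5e-4) shifts nothing qualitatively, only
tightens the confidence bands.

## Summary statistics

* `obsExpHet()` — observed heterozygosity, and expected heterozygosity as
  Nei's unbiased gene diversity 2p(1-p) x 2n/(2n-1) on the allele count 2n.
* `fisProfile()` / `fisGlobal()` — F_IS = 1 - sum(H_obs)/sum(H_exp)
  aggregated as a ratio of sums over the polymorphic sites of each window
  (fixed number of loci per window, default 20 — the loci-grid analog of
  fixed-width genomic windows). Ratio-of-sums is the simplest estimator
  consistent with the sign convention (positive = homozygote excess); it is
  deliberately swappable, and monomorphic sites are excluded. Windows with
  no polymorphic site return NA.
* `r2Decay()` — r² on *true* phased haplotypes (the simulation knows the
  phase), averaged in distance bins, with a between-chromosome row as the
  small-sample null (~1/n_haplotypes). Estimating the population
  recombination rate from unphased data is an external-tool problem and out
  of scope; the decay shape is the comparable object.
* `sibClassTable()` — the sister-trio site classification
  (one/two/three-heterozygote). "Other" is implementer-defined as
  conflicting homozygotes among the sisters (or a multiallelic flag), the
  only configuration left once het counts take the first three classes.
* `lohTracts()` — maximal mother-het/offspring-hom runs; under this meiosis
  each LOH chromosome yields exactly one run from the crossover to the
  distal end.

## The sister read-count screen

`lrtScreen()` implements the nested multinomial test exactly: M0 (3 df)
gives the three sisters a common A/C/G/T read frequency, M1 (9 df) gives
each her own; the statistic 2(logL1 - logL0) is referred to chi-square with
9 - 3 = 6 df and sites with p < 1e-8 carry genuine between-sister
differences. Multinomial constants are dropped identically in both models.
Coverage filters (contig mean >= 15x, site >= 20x) are applied *per
sister* — the stricter of the two possible readings, chosen because a site
effectively unobserved in one sister cannot enter a three-sister test.

The chi-square reference is asymptotic: at 40x coverage the empirical size
at nominal 5% runs slightly high (about 0.058 with uniform base
frequencies), so the calibration tests document a +/- 0.015 tolerance
around 0.05. Note that a *realistic* biallelic site concentrates counts on
two bases, which makes the test conservative there (empirical size well
below nominal) — the screen's stringency at p < 1e-8 is unaffected either
way.

`callGenotypes()` is a deliberately simple maximum-likelihood caller
(symmetric error rate, 10 candidate diploid genotypes, ties broken toward
the heterozygote and flagged) standing behind the same interface a
production caller would occupy. `classifyTrio()` chains filter, screen and
caller: sites where M0 is *not* rejected are assigned the pooled-count
consensus genotype (their between-sister variation is calling noise by the
test's own verdict); sites where M0 is rejected keep their per-sister
calls. This is the reading under which a heterozygosity-conserving trio
yields ~100% three-heterozygote sites while a sexual trio scatters across
the one- and two-heterozygote classes.

## The parity test

Under CRC every bivalent contributes 0 or 2 recombinant chromatids to the
oocyte, so their total is always even; under random assortment the per-pair
count is {0: 1/4, 1: 1/2, 2: 1/4} and the total's parity is a fair coin —
`parityProbRandom()` confirms P(even) = 1/2 by exhaustive enumeration of
all 4^10 assortments. Observing n embryos that are all even then has
probability 0.5^n: `allEvenPvalue(11, 11)` returns 0.5^11 ≈ 4.88e-4.
`simulatePaints()` links the bias to the *observable*: one chromatid per
chromosome is label-painted, so a crossover is visible only when it falls
between a labeled and an unlabeled chromatid (probability 1/2 by design,
exposed as `visibility`); retained recombinants are scored bicolor only for
visible crossovers. Counting is at the one-cell stage, before replication
dilutes the label. Why scored embryos show 4–8 bicolor chromosomes rather
than the Binomial(10, 1/2) spread under full CRC is not resolved here;
`visibility` is a free parameter, not a fitted one.

```{r parity}
parityProbRandom(10)
allEvenPvalue(11, 11)
```

## Synthetic data

The generators are pure functions of (parameters, seed) and every one
returns its truth table, so callers can be scored exactly rather than
estimated. `genTrioReadCounts()` emulates the structure of the real trio
experiment: negative-binomial coverage (default mean 40x, size 10 —
matching the ~28–42x scale of the real libraries), uniform base-miscall
error (default 0.5%), and three inheritance modes (CRC, per-site random
automixis at the genome-average LOH rate 1/4, Mendelian sexual). What it
does *not* emulate: LOH tract structure in the random mode (per-site
independence instead), allele-specific expression, mapping bias, indels, or
any sequence context — so passing tests demonstrate the statistics behave
as designed on data with the assumed structure, not that the assumed
structure exhausts real RNA-seq data.

## Numerical and degenerate-input choices

* A mother with zero heterozygous loci has `realizedLohFraction` defined as
  0, with a warning.
* Demes with no females (or no males anywhere) produce nothing; whole-
  metapopulation extinction is reported as an outcome, never raised.
* `sigma = 1` is rejected at config validation (sperm dependence).
* Genotype-caller likelihood ties go to the heterozygote (flagged);
  "substantial support" for the multiallelic flag is count >= max(2, 5% of
  the sister's coverage).
* Exported coordinates are 1-based locus indices per chromosome; internal
  positions are real-valued in (0, 1].

## Known limitations

No sequence-level simulation (abstract biallelic loci), no aneuploidy or
kinetochore mechanics, no overlapping generations or age structure, no
evolvable sex ratio, and no re-analysis of real accessions: the real-data
figures (1.3% genome heterozygosity, F_IS = 0.019, rho = 0.038/bp, the
exact trio class percentages) depend on external data and tools and are
covered only by directional analogues on synthetic data.
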