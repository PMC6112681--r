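---
title: "Models and methods behind fwdsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fwdsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwdsim)
```

`fwdsim` simulates evolving populations forward in time at the level of
individuals and whole genomes, for the design and analysis of
Evolve-and-Resequencing (E&R) experiments.  This vignette documents the
model, the numerical choices, and what the bundled validations do and do
not establish.

## Genome representation

Founder haplotypes enter as nucleotides at biallelic SNPs and are
converted to a bit matrix: one row per haplotype, one column per locus,
0 for the allele declared ancestral in the input, 1 for the derived
allele.  Polarity is taken from the haplotype file's allele column, not
from the first haplotype encountered, so the encoding does not depend on
input row order.  Only biallelic sites are representable; loci observed
with three or more nucleotides are rejected at read time.  Monomorphic
columns are allowed — they are the targets de novo mutations need.
Coordinates are 1-based inclusive throughout, matching the sync format
and common variant formats.

A diploid individual owns two adjacent rows of the matrix.  On a
configured hemizygous chromosome (e.g. the X; identification is by
configured name only, never autodetected) a male carries a single
haplotype.  Internally his second row mirrors the first on those columns
so the matrix stays rectangular; every dose, frequency and count
accessor recognises this and counts the copy once.  Two properties fall
out of this representation for free: crossovers and assortment between
a male's two identical X rows are no-ops, so males never effectively
recombine on the X; and zygote assembly only has to copy the maternal
gamete into both X rows of a son.  Daughters receive the paternal X
unchanged.  The male X is transmitted to daughters only — a convention;
the alternative (sons inheriting a paternal X) would contradict
hemizygosity.

## Generation cycle

Each generation executes eight steps in fixed order: truncating
selection (qt-mode only), mate-pair formation, gamete formation,
mutation, zygote formation, migration, evaluation of genotype →
phenotype → fitness, output.  Consequences of this ordering worth
noting:

* parents are drawn only from truncation survivors (step i precedes
  ii), which the suite checks directly;
* stored snapshots reflect post-migration genotypes (step vi precedes
  viii);
* population size is restored to exactly `N` at zygote formation, and
  offspring sexes are assigned by deterministic rounding of the
  configured ratio followed by shuffling — exact counts rather than
  Bernoulli draws, so sex pools cannot drift empty at small `N`.

Mating success scales with fitness: each parent is drawn with
probability proportional to fitness within its eligible sex pool,
sampling `N` pairs with replacement.  In qt-mode survivors mate with
equal probability; selection acts only through truncation.  Fitness
acts on fertility (mating success) only — there is no additional
viability stage.  Hermaphrodites self with a configured probability;
clonal populations skip mating entirely and copy fitness-sampled
parents, mutation aside.

Migration replaces `round(mN)` randomly chosen residents with
individuals assembled from random migrant-pool haplotypes.  Replacement
(rather than augmentation) keeps `N` constant; replaced residents keep
their sex so the configured ratio is undisturbed.

## Recombination

The map is windowed: each window spans `rate` centiMorgans, optionally
with a separate male rate (zero for Drosophila males).  The expected
crossover count per meiosis in a window is the inverse of Haldane's
mapping function applied to the window fraction `c = rate/100`:
`m = -log(1 - 2c)/2`.  The realised count is Poisson(`m`), positions
uniform integers on the window, counts independent across windows — no
interference, consistent with Haldane.  Windows must keep `c < 0.5`;
a longer stretch is expressed as several windows.  Applying inverse
Haldane to `c = cM/100` rather than treating cM/100 directly as Morgans
is a deliberate choice; the two readings converge for the small windows
maps are built from (for a 1-cM window they differ in `m` by 0.02%).

Crossover/locus ties: a locus at position `p` stays on the left
template iff `p <= c` for a crossover at `c`.  Chromosome assortment is
an independent fair coin per chromosome per gamete.  Gamete formation
is vectorised across all gametes of a generation; only
gamete-chromosome pairs actually hit by a crossover take a per-pair
template walk.

## Selection models

**w-mode.**  Genotype fitness at a selected locus is 1, 1+*hs*, 1+*s*
for 0/1/2 copies of the selected allele (1 or 1+*s* for single-copy
loci: haploids and hemizygous males).  Total fitness is the product
over selected loci — multiplicative composition keeps fitness positive
for `s > -1` and is the standard choice.  A pairwise epistasis table
assigns one of 3×3 (diploid) or 2×2 (haploid) fitness values by the
dose pair; loci inside a pair contribute *only* through their table,
never also through the per-locus product, to avoid double counting.

**qt-mode.**  The genotype value is `g = sum(-a, d, +a)` over QTLs
(±*a* for single-copy loci), phenotype `z = g + e` with
`e ~ N(0, V_E)` drawn fresh each generation.  `V_E` is derived once
from the founder genetic variance, `V_E = V_G0 (1 - h2)/h2`, and held
fixed for the run: the environmental noise model should not silently
strengthen as selection erodes `V_G`.  Heritability is a run-level
parameter; per-QTL dominance effects `d` are supported with default 0.
Truncation retains exactly `round(fN)` individuals (round-half-up;
base R's `round()` is banker's rounding, so the count is computed as
`floor(fN + 0.5)`), ties broken by stable input order, and the fraction
may be a per-generation schedule.

**qff-mode.**  The same phenotype is mapped to fitness.  Closed forms
(chosen here; tunable parameters in brackets):

| kind | fitness |
|---|---|
| gaussian_stabilizing | `exp(-(z-opt)^2 / (2 sigma^2))` [optimum, sigma] |
| directional_linear | `max(0, 1 + slope (z - z_ref))` [slope, z_ref] |
| disruptive | `1 + min((z-opt)^2/(2 sigma^2), cap)` [optimum, sigma, cap] |
| diminishing_returns | `w_max (1 - exp(-lambda max(z - z0, 0))) + w_base` [w_max, lambda, z0, w_base] |
| moving_optimum | Gaussian with `opt(t)` linearly interpolated from a schedule |

The diminishing-returns and disruptive forms are this package's
canonical choices (a saturating exponential and a capped quadratic);
the literature states the concepts but no standard closed form, so both
are exposed with all parameters configurable.

## Determinism and replication

A run is fully determined by its configuration: per-replicate seeds are
drawn once from the base seed (`sample.int(2^31 - 2)`), so results are
byte-identical across runs and independent of how many replicates are
requested — replicate 2 of a 2-replicate run equals replicate 2 of a
10-replicate run.  Replicates are therefore embarrassingly parallel by
contract, though the package itself runs them sequentially.

## The synthetic founder generator

`generate_fixture_panel()` builds a self-consistent input set with no
external data: per-chromosome locus counts, evenly spaced positions,
random allele pairs, a windowed map, and optional designated selected
loci whose founder frequencies are hit *exactly* (`round(f n)` derived
bits placed on random haplotypes).  Undesignated loci draw their
derived count uniformly from `1..n-1`, i.e. a flat founder frequency
spectrum with every locus segregating.

What it emulates: the shape of a real founder panel (e.g. ~200 inbred
line haplotypes over a few chromosomes with a sex-specific map) and
exact experimental frequencies for designated loci.  What it does not:
a realistic site-frequency spectrum (real panels are skewed toward rare
alleles), linkage disequilibrium structure among neutral loci (bits are
placed independently per column), inbreeding structure, or sequencing
noise.  Tests that pass on these panels therefore establish the
engine's population-genetic behaviour, not the power of any analysis on
real DGRP-like data.

## Validations

Four closed-form expectations double as the acceptance surface, run by
`tests/testthat/test-acceptance.R`, the `validate` CLI subcommand and
`scripts/acceptance.R`.  Validation populations are monoecious
(hermaphroditic), so the reference model of `2N` exchangeable allele
copies applies exactly.  Problem sizes are the package's chosen desk
scale:

1. **Drift** — 10,000 unlinked loci (one per chromosome), `p0 = 0.5`,
   `N = 250`, 50 generations, against the Wright–Fisher Markov chain
   (transition `Binomial(2N, j/2N)`).  The χ² goodness-of-fit pools
   adjacent count classes left-to-right until each expects ≥ 5.
2. **Selection** — one codominant locus, `s = 0.1`, `p0 = 0.1`,
   `N = 2000`, 50 replicates, against the deterministic recursion
   `p_t = p_{t-1}(p_{t-1}W_AA + q_{t-1}W_Aa)/wbar`, compared at every
   10th generation (3 SE).  100 generations are simulated: the
   trajectory is essentially complete (`p ≈ 0.93`), while running to
   near-fixation would collapse the replicate SE to zero and make the
   band degenerate.
3. **Breeder's equation** — 10 additive QTLs, `p0 = 0.5`, `N = 1000`,
   `h² = 0.5`; one generation of truncation at retained fractions
   0.2–0.8, 100 replicates each; the mean per-replicate `R/S` is
   compared to `h²` (3 SE).  Note the per-replicate ratio is
   heavy-tailed at weak selection (fraction 0.8: `S` is small and
   noisy), so this is the statistically touchiest of the four checks.
4. **LD decay** — two loci in complete coupling (`D0 = 0.25`,
   frequencies 0.5), `c = 0.05`, `N = 1000`, 100 generations, 100
   replicates, against `D_t = D0 (1-c)^t` (3 SE at every 10th
   generation).  The founder pairs haplotypes into individuals at
   random: the closed form presumes random mating from generation 0,
   and a founder assembled from sorted haplotypes (all coupling
   homozygotes) provably lags the decay by one generation.

A fifth, property-style check mirrors a truncating-selection E&R
walkthrough on synthetic founders: 205 haplotypes on three chromosomes
(hemizygous X, no male recombination, 50 cM female map per chromosome),
4 additive QTLs (`a = 1`) at founder frequency 0.1, `h² = 0.5`, top 80%
surviving truncation, `N = 250`, 10 replicates, 40 generations.  All
four selected loci must exceed the 99th percentile of mean absolute
frequency change among neutral loci matched to ±0.05 founder frequency.
These parameters were fixed once as a realistic small E&R design; the
check demonstrates that true targets separate from drift under the
simulated design, not any claim about real starvation-resistance data.

All stochastic tests run at fixed seeds.  A 3-SE band on a few dozen
simultaneous statistics carries an irreducible few-percent a-priori
failure probability at any fixed seed; the suite accepts that rather
than widening bands.

## Numerical and degenerate-input choices

* Truncation count: round-half-up, minimum 1 survivor; fraction must
  lie in (0, 1].
* `h² = 1` gives `V_E = 0` exactly (phenotype = genotype value);
  `h² ≤ 0` is an error.  A monomorphic trait (founder `V_G = 0`) yields
  `V_E = 0` and a flat phenotype.
* Window fraction `c = 0` gives `m = 0` exactly; `c ≥ 0.5` is an error
  rather than clamped.
* Fitness must be positive somewhere in every eligible pool; an empty
  pool (e.g. all-zero fitness, or a sex missing after truncation) stops
  the run with an extinction error.
* `ld_D` returns 0 at monomorphic loci; mixing hemizygous and autosomal
  loci in one haplotype-copy matrix is refused because copy numbers
  differ.
* Mutation flips bits symmetrically (0↔1) at existing columns; there is
  no infinite-sites model.

## Known limitations

No crossover interference, gene conversion, structural variants,
tri-/tetra-allelic sites, Y or mitochondrial inheritance, spatial
structure, gene–environment interaction, or multi-trait pleiotropy.
Read-level simulation is out of scope by design: the sync writer can
optionally binomially downsample counts to a fixed coverage, but
realistic read simulation belongs to dedicated tools downstream.
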