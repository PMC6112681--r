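# fwdsim

Individual-based forward simulation of Evolve-and-Resequencing (E&R)
experiments.

E&R studies evolve replicated populations under selection and sequence
them at intervals (typically as pools, "Pool-Seq") to track allele
frequencies.  Designing such an experiment — how many replicates,
generations, founder haplotypes? — and interpreting its outcome both
require forward simulations that start from realistic haplotype panels,
respect the biology of the model organism (sex, hemizygous X, no
recombination in *Drosophila* males, selfing, clonality), and write
output that downstream Pool-Seq tools can read.  `fwdsim` is a compact,
fully scriptable simulator for that niche.

## The model

Populations evolve in discrete generations at constant census size `N`.
Founder haplotypes are biallelic SNPs supplied as nucleotides and stored
as a bit matrix (0 = ancestral, 1 = derived).  Each generation executes,
in order: (i) truncating selection (if configured), (ii) fitness-
proportional mate-pair formation, (iii) gamete formation by crossovers
and random assortment of chromosomes, (iv) de novo mutation, (v) zygote
formation restoring `N`, (vi) migration, (vii) evaluation of genotype,
phenotype and fitness, (viii) output.

Recombination uses a windowed map in centiMorgans, optionally
sex-specific.  A window spanning recombination fraction *c* = cM/100
receives Poisson(*m*) crossovers with *m* from the inverse of Haldane's
mapping function,

&nbsp;&nbsp;&nbsp;&nbsp;*c* = ½(1 − e^(−2m)) ⟹ *m* = −½ ln(1 − 2*c*),

each placed uniformly within the window (no interference).

Three selection modes:

* **w-mode** — fitness directly from per-SNP selection coefficients:
  genotype fitness 1, 1 + *hs*, 1 + *s* for 0/1/2 copies of the selected
  allele, multiplicative across loci, with optional pairwise 3×3
  epistasis fitness tables.
* **qt-mode** — a quantitative trait *z* = Σ(−*a*, *d*, +*a*) + ε with
  ε ~ N(0, V_E), V_E fixed from the founder genetic variance to give the
  configured heritability *h*² = V_G/(V_G + V_E); truncating selection
  retains a fraction of the most extreme phenotypes as parents.
* **qff-mode** — the same trait mapped to fitness through a fitness
  function (Gaussian stabilizing, directional, disruptive, diminishing
  returns, moving optimum).

Closed-form expectations used to validate the machinery are exported:
the Wright–Fisher Markov chain (`drift_markov_expectation`), the
selection recursion `p_t = p_{t−1}(p_{t−1}W_AA + q_{t−1}W_Aa)/w̄`
(`selection_recursion`), the breeder's equation `R = h²S`
(`breeders_response`) and LD decay `D_t = D_0(1 − c)^t`
(`ld_decay_expectation`).

## Worked example

Simulate a small truncating-selection experiment on a synthetic founder
panel (4 additive QTLs, top 80% survive) and inspect the selected loci:

```r
library(fwdsim)

panel <- generate_fixture_panel(
  n_haplotypes = 205,
  loci_spec = list(X = 100, `2` = 100, `3` = 100),
  selected = data.frame(chrom = c("2", "3"), index = c(50L, 50L),
                        freq = 0.1, a = 1, d = 0),
  cM_per_chrom = 50, male_cM = 0, seed = 42)

em <- effect_model("qt",
  chrom = panel$snp$chrom[panel$selected$idx],
  pos = panel$snp$pos[panel$selected$idx],
  allele = panel$snp$der[panel$selected$idx],
  a = 1, d = 0, snp = panel$snp)

cfg <- sim_config("qt", N = 250, generations = 20, replicates = 3,
                  hemi = "X", truncation = list(fraction = 0.8, tail = "high"),
                  h2 = 0.5, output_generations = c(0, 20), seed = 42)

res <- run_simulation(cfg, panel, map = panel$map, em = em)
f <- result_frequencies(res)
d <- with(f, tapply(freq, list(generation, locus), mean))
round(d[, panel$selected$idx], 3)   # mean frequency of the two QTLs
#>      150   250
#> 0  0.111 0.091
#> 20 0.999 1.000
write_sync("run.sync", result_snapshots(res), panel$snp)
```

With only two QTLs the trait variance is small, so truncation puts
strong selection on each: both selected alleles sweep from a founder
frequency near 0.1 to fixation within 20 generations, while neutral
loci merely drift; `run.sync`
holds per-locus `A:T:C:G:N:del` allele counts for every (replicate,
generation) column, ready for PoPoolation2-style analysis.

The same run from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/fwdsim", package = "fwdsim"))')
Rscript $CLI fixtures --out fx --haplotypes 205 --selected 4 --mode qt --seed 42
Rscript $CLI qt --haplotypes fx/haplotypes.txt --map fx/map.txt \
    --effects fx/effects.txt --N 250 --gens 20 --reps 3 --seed 42 \
    --truncation-fraction 0.8 --out run.sync
Rscript $CLI validate drift --N 250 --loci 10000 --gens 50 --seed 1
```

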