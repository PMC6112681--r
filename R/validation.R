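#' Validation runs against closed-form population-genetic expectations
#'
#' These functions re-run the simulator under textbook conditions and
#' compare the outcome to the corresponding theoretical expectation:
#' neutral drift against the Wright-Fisher Markov chain, a selected
#' locus against the deterministic selection recursion, truncating
#' selection on a quantitative trait against the breeder's equation,
#' and the decay of linkage disequilibrium against
#' `D_t = D_0 (1 - c)^t`.  Validation populations are monoecious
#' (hermaphrodite) so that the drift reference of `2N` exchangeable
#' allele copies applies exactly.
#'
#' @name validation
NULL

neutral_cfg <- function(N, generations, replicates, seed, output_generations) {
  sim_config("w", N = N, generations = generations, replicates = replicates,
             hermaphrodite = TRUE, output_generations = output_generations,
             seed = seed)
}

# exact-frequency founder panel: loci x counts derived bits per column
exact_panel <- function(n_hap, counts, chrom = NULL) {
  L <- length(counts)
  if (is.null(chrom)) chrom <- paste0("chr", seq_len(L))
  pos <- stats::ave(seq_len(L), chrom, FUN = seq_along)
  snp <- snp_table(chrom, pos, rep("A", L), rep("T", L))
  H <- matrix(0L, n_hap, L)
  for (j in seq_len(L)) {
    if (counts[j] > 0L) H[sample.int(n_hap, counts[j]), j] <- 1L
  }
  list(snp = snp, haplo = H, ploidy = 1L)
}

#' @describeIn validation Neutral drift of unlinked loci versus the
#'   Markov-chain expectation.  Simulates `loci` unlinked loci (one per
#'   chromosome, free assortment) at exact founder frequency `p0` for
#'   `generations` generations at census size `N` and tests the final
#'   distribution of derived-copy counts with a pooled chi-squared
#'   goodness-of-fit.  Returns the test, the mean final frequency and
#'   its expected standard error under the drift-variance closed form.
#' @param N census size.
#' @param loci number of unlinked neutral loci.
#' @param generations generations simulated.
#' @param p0 founder derived-allele frequency.
#' @param seed base seed.
#' @export
validate_drift <- function(N = 250, loci = 10000, generations = 50,
                           p0 = 0.5, seed = 1L) {
  set.seed(seed)
  founder <- exact_panel(2L * N, rep.int(as.integer(round(2 * N * p0)), loci))
  cfg <- neutral_cfg(N, generations, 1L, seed, c(0L, generations))
  res <- run_simulation(cfg, founder)
  snap <- res$replicates[[1]]$snapshots[[2]]
  expectation <- drift_markov_expectation(N, p0, generations)
  gof <- drift_gof(snap$derived, expectation)
  mean_freq <- mean(snap$derived / snap$total)
  se_mean <- sqrt(drift_variance(p0, N, generations) / loci)
  list(gof = gof, mean_freq = mean_freq, expected_mean = p0,
       se_mean = se_mean, z = (mean_freq - p0) / se_mean,
       counts = snap$derived, expectation = expectation)
}

#' @describeIn validation Selected-locus trajectories versus the
#'   deterministic recursion.  Simulates one codominant locus under
#'   w-mode selection in `replicates` populations and compares the
#'   across-replicate mean frequency to [selection_recursion()] at
#'   every `check_every`-th generation.
#' @param s,h selection coefficient and dominance of the selected
#'   allele.
#' @param replicates number of replicate populations.
#' @param check_every compare mean trajectory to the recursion at these
#'   generation intervals.
#' @export
validate_selection <- function(N = 2000, replicates = 50, s = 0.1, h = 0.5,
                               p0 = 0.1, generations = 100, check_every = 10,
                               seed = 1L) {
  set.seed(seed)
  founder <- exact_panel(2L * N, as.integer(round(2 * N * p0)))
  em <- effect_model("w", chrom = founder$snp$chrom[1], pos = founder$snp$pos[1],
                     allele = founder$snp$der[1], s = s, h = h,
                     snp = founder$snp)
  gens_out <- seq(0L, generations, by = check_every)
  cfg <- sim_config("w", N = N, generations = generations,
                    replicates = replicates, hermaphrodite = TRUE,
                    output_generations = gens_out, seed = seed)
  res <- run_simulation(cfg, founder, em = em)
  freqs <- result_frequencies(res)
  expected <- selection_recursion(p0, s, h, generations)
  checks <- do.call(rbind, lapply(gens_out, function(t) {
    f <- freqs$freq[freqs$generation == t]
    data.frame(generation = t, mean = mean(f),
               se = stats::sd(f) / sqrt(length(f)),
               expected = expected[t + 1L])
  }))
  checks$z <- ifelse(checks$se > 0,
                     (checks$mean - checks$expected) / checks$se, 0)
  checks
}

#' @describeIn validation Realised response to truncating selection
#'   versus the breeder's equation.  For each retained fraction,
#'   `replicates` one-generation qt-mode simulations are run with
#'   `n_qtl` unlinked additive QTLs at founder frequency `p0`; the
#'   selection differential `S` (survivor mean minus population mean
#'   phenotype) and the response `R` (offspring mean minus parental
#'   population mean) are recorded and the mean ratio `R/S` is compared
#'   to the heritability `h2`.
#' @param n_qtl number of additive QTLs.
#' @param a additive effect per QTL (trait units).
#' @param h2 narrow-sense heritability.
#' @param fractions retained fractions of truncating selection.
#' @export
validate_breeder <- function(N = 1000, n_qtl = 10, a = 1, p0 = 0.5, h2 = 0.5,
                             fractions = c(0.2, 0.4, 0.6, 0.8),
                             replicates = 100, seed = 1L) {
  set.seed(seed)
  founder <- exact_panel(2L * N, rep.int(as.integer(round(2 * N * p0)), n_qtl))
  em <- effect_model("qt", chrom = founder$snp$chrom, pos = founder$snp$pos,
                     allele = founder$snp$der, a = a, d = 0, snp = founder$snp)
  out <- lapply(fractions, function(frac) {
    cfg <- sim_config("qt", N = N, generations = 1L, hermaphrodite = TRUE,
                      truncation = list(fraction = frac, tail = "high"),
                      h2 = h2, seed = seed)
    ratios <- S_all <- R_all <- numeric(replicates)
    for (r in seq_len(replicates)) {
      pop <- make_founder_population(founder, cfg, replicate_id = r)
      V_G0 <- stats::var(genotype_value(pop, em))
      V_E <- environmental_variance(h2, V_G0)
      pop <- evaluate_population(pop, cfg, em, V_E)
      survivors <- truncate_select(pop$phenotype, frac, "high")
      S <- mean(pop$phenotype[survivors]) - mean(pop$phenotype)
      off <- advance_generation(pop, cfg, em, NULL, V_E)
      R <- mean(off$phenotype) - mean(pop$phenotype)
      S_all[r] <- S; R_all[r] <- R; ratios[r] <- R / S
    }
    data.frame(fraction = frac, mean_ratio = mean(ratios),
               se_ratio = stats::sd(ratios) / sqrt(replicates),
               mean_S = mean(S_all), mean_R = mean(R_all), expected = h2)
  })
  checks <- do.call(rbind, out)
  checks$z <- (checks$mean_ratio - checks$expected) / checks$se_ratio
  checks
}

#' @describeIn validation Decay of linkage disequilibrium versus
#'   `D_t = D_0 (1 - c)^t`.  Two loci start in complete coupling
#'   (`D = D0`, both frequencies 0.5) with a recombination window of
#'   `100 c` cM between them; the across-replicate mean `D` is compared
#'   to the closed form at every `check_every`-th generation.
#' @param D0 initial linkage disequilibrium (0.25 = complete coupling at
#'   frequency 0.5).
#' @param c recombination fraction between the loci.
#' @export
validate_ld <- function(N = 1000, D0 = 0.25, c = 0.05, generations = 100,
                        replicates = 100, check_every = 10, seed = 1L) {
  span <- 1000000L
  snp <- snp_table(c("2L", "2L"), c(1L, span), c("A", "A"), c("T", "T"))
  n_hap <- 2L * N
  H <- matrix(0L, n_hap, 2L)
  H[seq_len(n_hap / 2L), ] <- 1L  # complete coupling: half AB, half ab
  founder <- list(snp = snp, haplo = H, ploidy = 1L)
  map <- recomb_map("2L", 1L, span - 1L, rate_female = 100 * c)
  cfg <- neutral_cfg(N, generations, 1L, seed, c(0L, generations))
  gens_out <- seq(0L, generations, by = check_every)
  seeds <- replicate_seeds(seed, replicates)
  D <- matrix(NA_real_, replicates, length(gens_out),
              dimnames = list(NULL, gens_out))
  for (r in seq_len(replicates)) {
    set.seed(seeds[r])
    # pair haplotypes into individuals at random: the closed-form decay
    # assumes a random-mating founder, with double heterozygotes at
    # Hardy-Weinberg proportions from generation 0 on
    shuffled <- founder
    shuffled$haplo <- founder$haplo[sample.int(n_hap), , drop = FALSE]
    pop <- make_founder_population(shuffled, cfg, replicate_id = r)
    pop <- evaluate_population(pop, cfg, NULL, 0)
    D[r, "0"] <- ld_D(pop, 1L, 2L)
    for (t in seq_len(generations)) {
      pop <- advance_generation(pop, cfg, NULL, map, 0)
      lab <- as.character(t)
      if (lab %in% colnames(D)) D[r, lab] <- ld_D(pop, 1L, 2L)
    }
  }
  checks <- data.frame(generation = gens_out,
                       mean_D = colMeans(D),
                       se_D = apply(D, 2L, stats::sd) / sqrt(replicates),
                       expected = ld_decay_expectation(D0, c, gens_out))
  checks$z <- ifelse(checks$se_D > 0,
                     (checks$mean_D - checks$expected) / checks$se_D, 0)
  rownames(checks) <- NULL
  list(checks = checks, D = D, D0_observed = unname(D[1, "0"]))
}

#' @describeIn validation Synthetic truncating-selection walkthrough.
#'   Generates a founder panel of `n_haplotypes` haplotypes on three
#'   chromosomes (a hemizygous X without male recombination and two
#'   autosomes), designates `n_selected` additive QTLs at founder
#'   frequency `sel_freq`, and runs qt-mode truncating selection
#'   (retaining `survive_fraction` of the most extreme phenotypes) for
#'   `generations` generations in `replicates` replicates.  Returns the
#'   per-locus mean absolute frequency change and, per selected locus,
#'   the 99th percentile of the same statistic among frequency-matched
#'   neutral loci.
#' @param n_haplotypes founder panel size.
#' @param loci_per_chrom loci per chromosome.
#' @param n_selected number of selected QTLs (placed on the autosomes).
#' @param sel_freq founder frequency of the selected alleles.
#' @param sel_effect additive effect `a` of each QTL.
#' @param survive_fraction fraction surviving truncation.
#' @param match_band half-width of the founder-frequency band used to
#'   match neutral loci to a selected locus.
#' @export
validate_walkthrough <- function(n_haplotypes = 205, loci_per_chrom = 500,
                                 n_selected = 4, sel_freq = 0.1,
                                 sel_effect = 1, survive_fraction = 0.8,
                                 N = 250, generations = 40, replicates = 10,
                                 h2 = 0.5, match_band = 0.05, seed = 1L) {
  sel <- data.frame(
    chrom = rep(c("2", "3"), length.out = n_selected),
    index = as.integer(seq(0.2, 0.8, length.out = n_selected) * loci_per_chrom),
    freq = sel_freq, a = sel_effect, d = 0)
  panel <- generate_fixture_panel(
    n_haplotypes,
    loci_spec = list(X = loci_per_chrom, `2` = loci_per_chrom,
                     `3` = loci_per_chrom),
    chrom_length = 1000000L, selected = sel,
    cM_per_chrom = 50, male_cM = 0, n_windows = 10L, seed = seed)
  em <- effect_model("qt", chrom = panel$snp$chrom[panel$selected$idx],
                     pos = panel$snp$pos[panel$selected$idx],
                     allele = panel$snp$der[panel$selected$idx],
                     a = sel$a, d = sel$d, snp = panel$snp)
  cfg <- sim_config("qt", N = N, generations = generations,
                    replicates = replicates, female_frac = 0.5, hemi = "X",
                    truncation = list(fraction = survive_fraction,
                                      tail = "high"),
                    h2 = h2, output_generations = c(0L, generations),
                    seed = seed)
  res <- run_simulation(cfg, panel, map = panel$map, em = em)
  L <- nrow(panel$snp)
  delta <- matrix(NA_real_, replicates, L)
  for (r in seq_len(replicates)) {
    s0 <- res$replicates[[r]]$snapshots[[1]]
    s1 <- res$replicates[[r]]$snapshots[[2]]
    delta[r, ] <- abs(s1$derived / s1$total - s0$derived / s0$total)
  }
  mean_delta <- colMeans(delta)
  founder_freq <- colMeans(panel$haplo)
  sel_idx <- panel$selected$idx
  neutral <- setdiff(seq_len(L), sel_idx)
  per_locus <- lapply(sel_idx, function(i) {
    band <- neutral[abs(founder_freq[neutral] - founder_freq[i]) <= match_band]
    q99 <- stats::quantile(mean_delta[band], 0.99, names = FALSE)
    data.frame(locus = i, mean_abs_change = mean_delta[i],
               neutral_q99 = q99, n_matched = length(band))
  })
  list(selected = do.call(rbind, per_locus), mean_delta = mean_delta,
       founder_freq = founder_freq, panel = panel, result = res)
}
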