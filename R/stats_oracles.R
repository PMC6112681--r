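#' Wright-Fisher drift expectation via a Markov chain
#'
#' The drift reference is a monoecious Wright-Fisher population of `2N`
#' allele copies: the derived-copy count `j` transitions to `k` with
#' probability `Binomial(2N, j/2N)` evaluated at `k`.  Starting from a
#' point mass at the copy count nearest `2N p0`, the distribution after
#' `t` generations is obtained by `t` applications of the transition
#' matrix.
#'
#' @param N diploid population size.
#' @param p0 initial derived-allele frequency.
#' @param t generations (>= 0).
#' @return A list of class `drift_expectation`: `N`, `p0`, `t`, and
#'   `pmf` — the probability mass over copy counts `0..2N`.
#' @export
drift_markov_expectation <- function(N, p0, t) {
  if (t < 0) stop("t must be >= 0")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  two_n <- 2L * as.integer(N)
  k <- 0:two_n
  v <- numeric(two_n + 1L)
  v[round(two_n * p0) + 1L] <- 1
  if (t > 0) {
    P <- outer(k, k, function(j, kk) stats::dbinom(kk, two_n, j / two_n))
    for (i in seq_len(t)) v <- as.numeric(v %*% P)
  }
  structure(list(N = N, p0 = p0, t = t, pmf = v),
            class = "drift_expectation")
}

#' Across-replicate drift variance of the allele frequency
#'
#' Closed form for the variance of the frequency after `t` Wright-
#' Fisher generations: `p0 (1 - p0) (1 - (1 - 1/(2N))^t)`.
#'
#' @param p0 initial frequency.
#' @param N diploid population size.
#' @param t generations.
#' @export
drift_variance <- function(p0, N, t) {
  p0 * (1 - p0) * (1 - (1 - 1 / (2 * N))^t)
}

#' Deterministic single-locus selection recursion
#'
#' `p_t = p_{t-1} (p_{t-1} W_AA + q_{t-1} W_Aa) / wbar`, with genotype
#' fitnesses `W_AA = 1 + s`, `W_Aa = 1 + hs`, `W_aa = 1` and mean
#' fitness `wbar = p^2 W_AA + 2pq W_Aa + q^2 W_aa`.
#'
#' @param p0 initial frequency of the selected allele A.
#' @param s selection coefficient (> -1).
#' @param h dominance of the selected allele.
#' @param t generations.
#' @return Numeric vector `p_0 .. p_t` (length `t + 1`).
#' @export
selection_recursion <- function(p0, s, h, t) {
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  W_AA <- 1 + s
  W_Aa <- 1 + h * s
  W_aa <- 1
  p <- numeric(t + 1L)
  p[1] <- p0
  for (i in seq_len(t)) {
    pp <- p[i]; qq <- 1 - pp
    wbar <- pp^2 * W_AA + 2 * pp * qq * W_Aa + qq^2 * W_aa
    p[i + 1L] <- pp * (pp * W_AA + qq * W_Aa) / wbar
  }
  p
}

#' Linkage disequilibrium between two loci
#'
#' `D = f(AB) - pA pB`, computed over all phased haplotype copies of the
#' population (a hemizygous male contributes a single X copy).  A
#' monomorphic locus gives `D = 0`.
#'
#' @param pop a population.
#' @param locusA,locusB locus column indices.
#' @return The coefficient `D`.
#' @export
ld_D <- function(pop, locusA, locusB) {
  H <- haplotype_copies(pop, c(locusA, locusB))
  fAB <- mean(H[, 1] == 1L & H[, 2] == 1L)
  fAB - mean(H[, 1]) * mean(H[, 2])
}

#' Expected LD decay under recombination
#'
#' `D_t = D_0 (1 - c)^t` for recombination fraction `c` between the two
#' loci.
#'
#' @param D0 initial linkage disequilibrium.
#' @param c recombination fraction in `[0, 0.5]`.
#' @param t generations (vectorised).
#' @export
ld_decay_expectation <- function(D0, c, t) {
  if (c < 0 || c > 0.5) stop("c must lie in [0, 0.5]")
  D0 * (1 - c)^t
}

#' Breeder's equation
#'
#' `R = h2 * S`: the expected response to selection `R` given the
#' selection differential `S` and the narrow-sense heritability.
#'
#' @param S selection differential (survivor mean minus population mean
#'   phenotype).
#' @param h2 heritability.
#' @export
breeders_response <- function(S, h2) h2 * S

#' Goodness-of-fit of simulated drift against the Markov expectation
#'
#' Compares the empirical distribution of derived-copy counts across
#' loci (or replicates) with a [drift_markov_expectation()] using a
#' chi-squared test.  Adjacent count classes are pooled until every
#' class has expected count >= `min_expected`, then the statistic is
#' computed with `df = classes - 1`.
#'
#' @param counts integer vector of observed derived-copy counts, each in
#'   `0..2N`.
#' @param expectation a [drift_markov_expectation()].
#' @param min_expected minimum expected count per pooled class.
#' @return A list with `statistic`, `df`, `p.value`, `classes`.
#' @export
drift_gof <- function(counts, expectation, min_expected = 5) {
  pmf <- expectation$pmf
  n <- length(counts)
  obs <- tabulate(counts + 1L, nbins = length(pmf))
  exp_counts <- pmf * n
  # pool adjacent classes left to right until each reaches min_expected
  breaks <- integer(0)
  acc <- 0
  for (i in seq_along(exp_counts)) {
    acc <- acc + exp_counts[i]
    if (acc >= min_expected) {
      breaks <- c(breaks, i)
      acc <- 0
    }
  }
  if (length(breaks) == 0L) stop("too few observations for a pooled test")
  breaks[length(breaks)] <- length(exp_counts)  # absorb the remainder
  grp <- findInterval(seq_along(exp_counts), c(0, breaks[-length(breaks)]) + 1L)
  o <- tapply(obs, grp, sum)
  e <- tapply(exp_counts, grp, sum)
  stat <- sum((o - e)^2 / e)
  df <- length(o) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       classes = length(o))
}

#' Generate a synthetic founder panel
#'
#' Builds a self-consistent input set — SNP table, haplotype bit panel,
#' windowed recombination map and effect entries — without external
#' data.  Designated loci hit their requested founder frequencies
#' exactly by construction: `round(freq * n_haplotypes)` derived bits
#' are placed on randomly chosen haplotypes.  Undesignated loci draw
#' their derived-bit count uniformly from `1 .. n_haplotypes - 1`
#' (segregating by construction).
#'
#' @param n_haplotypes number of haplotype rows in the panel.
#' @param loci_spec named list: chromosome name -> locus count.
#' @param chrom_length base-pair span of each chromosome; positions are
#'   evenly spaced.
#' @param selected data frame with columns `chrom`, `index` (locus
#'   number within the chromosome), `freq` (requested founder frequency
#'   of the derived allele) and optionally per-mode effect columns
#'   (`s`, `h` or `a`, `d`); may be `NULL`.
#' @param cM_per_chrom female map length of each chromosome, split over
#'   `n_windows` equal windows; single value recycled.
#' @param male_cM male map length (0 = no recombination in males);
#'   recycled likewise.
#' @param n_windows recombination windows per chromosome.
#' @param seed integer seed; the panel is deterministic given the seed.
#' @return A list with `snp`, `haplo`, `ploidy = 1` (a haplotype panel),
#'   `map`, and `selected` (the input data frame with a locus `idx`
#'   column added).
#' @export
generate_fixture_panel <- function(n_haplotypes, loci_spec,
                                   chrom_length = 1e6L, selected = NULL,
                                   cM_per_chrom = 50, male_cM = cM_per_chrom,
                                   n_windows = 10L, seed = 1L) {
  set.seed(seed)
  chroms <- names(loci_spec)
  if (is.null(chroms)) stop("loci_spec must be a named list: chrom -> count")
  n_loci <- unlist(loci_spec)
  chrom_col <- rep(chroms, n_loci)
  pos <- unlist(lapply(n_loci, function(k) {
    as.integer(round(seq(1, chrom_length, length.out = k + 1L)[-1]))
  }))
  alleles <- t(vapply(seq_along(chrom_col), function(i) {
    sample(NUCLEOTIDES, 2L)
  }, character(2)))
  snp <- snp_table(chrom_col, pos, alleles[, 1], alleles[, 2])
  L <- nrow(snp)

  sel_idx <- integer(0)
  sel_freq <- numeric(0)
  if (!is.null(selected) && nrow(selected)) {
    offset <- c(0, cumsum(n_loci))[match(selected$chrom, chroms)]
    sel_idx <- as.integer(offset + selected$index)
    sel_freq <- selected$freq
    if (any(round(sel_freq * n_haplotypes) < 1) ||
        any(round(sel_freq * n_haplotypes) > n_haplotypes - 1L)) {
      stop("requested frequency unreachable with ", n_haplotypes, " haplotypes")
    }
    selected$idx <- sel_idx
  }

  H <- matrix(0L, n_haplotypes, L)
  counts <- sample(seq_len(n_haplotypes - 1L), L, replace = TRUE)
  counts[sel_idx] <- as.integer(round(sel_freq * n_haplotypes))
  for (j in seq_len(L)) {
    H[sample.int(n_haplotypes, counts[j]), j] <- 1L
  }

  cM <- rep_len(cM_per_chrom, length(chroms))
  cMm <- rep_len(male_cM, length(chroms))
  edges <- as.integer(round(seq(1, chrom_length, length.out = n_windows + 1L)))
  map <- recomb_map(
    chrom = rep(chroms, each = n_windows),
    start = rep(c(edges[-(n_windows + 1L)][1], edges[-c(1, n_windows + 1L)] + 1L),
                times = length(chroms)),
    end = rep(edges[-1], times = length(chroms)),
    rate_female = rep(cM / n_windows, each = n_windows),
    rate_male = rep(cMm / n_windows, each = n_windows))

  list(snp = snp, haplo = H, ploidy = 1L, map = map, selected = selected)
}

#' Write a generated fixture panel to disk
#'
#' Emits the haplotype table, recombination map and (if selected loci
#' are designated) effect file in the package's tab-separated dialects,
#' ready for [read_haplotypes()], [read_recombination_map()] and
#' [read_effects()].
#'
#' @param panel a [generate_fixture_panel()] result.
#' @param dir output directory (created if missing).
#' @param mode effect-file mode: `"w"` writes `s`/`h` columns, `qt`/
#'   `qff` write `a`/`d` columns.
#' @return Named character vector of the written paths.
#' @export
write_fixture_panel <- function(panel, dir, mode = c("w", "qt", "qff")) {
  mode <- match.arg(mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hap <- file.path(dir, "haplotypes.txt")
  write_haplotypes(hap, panel)
  mapf <- file.path(dir, "map.txt")
  writeLines(paste(panel$map$chrom, panel$map$start, panel$map$end,
                   panel$map$rate_female, panel$map$rate_male, sep = "\t"),
             mapf)
  paths <- c(haplotypes = hap, map = mapf)
  sel <- panel$selected
  if (!is.null(sel) && nrow(sel)) {
    eff <- file.path(dir, "effects.txt")
    snp <- panel$snp
    if (mode == "w") {
      rows <- paste(snp$chrom[sel$idx], snp$pos[sel$idx], snp$der[sel$idx],
                    sel$s, sel$h, sep = "\t")
    } else {
      d <- if ("d" %in% names(sel)) sel$d else 0
      rows <- paste(snp$chrom[sel$idx], snp$pos[sel$idx], snp$der[sel$idx],
                    sel$a, d, sep = "\t")
    }
    writeLines(rows, eff)
    paths <- c(paths, effects = eff)
  }
  paths
}
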