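#' Expected crossover count of a map window (Haldane)
#'
#' Haldane's mapping function, `c = (1 - exp(-2m)) / 2`, relates the
#' recombination fraction `c` spanned by a window to the expected number
#' of crossovers `m` under no interference.  A window of `rate` cM
#' implies `c = rate / 100`, and the inverse mapping gives
#' `m = -log(1 - 2c) / 2`.  `c` must stay below 0.5 (free
#' recombination), the supremum of the mapping function.
#'
#' @param rate_cM window width in centiMorgans (vectorised).
#' @return Expected crossover count per meiosis, `m >= 0`; `m = 0` iff
#'   the rate is 0.
#' @examples
#' mean_crossovers(25)  # c = 0.25 -> m = 0.3465736
#' @export
mean_crossovers <- function(rate_cM) {
  c <- rate_cM / 100
  if (any(c < 0)) stop("negative recombination rate")
  if (any(c >= 0.5)) stop("window recombination fraction must be < 0.5")
  -0.5 * log(1 - 2 * c)
}

chrom_levels <- function(snp) unique(snp$chrom)

#' Sample a crossover plan for one meiosis
#'
#' Per map window the crossover count is drawn from a Poisson
#' distribution with mean given by [mean_crossovers()]; each event is
#' placed uniformly at random on the window's base-pair interval.
#' Counts across windows are independent (no interference).  The plan
#' also records the random assortment choice — an independent fair coin
#' per chromosome selecting the starting genome copy.
#'
#' @param map a [recomb_map()].
#' @param sex `"F"`, `"M"` or `"H"` — selects the sex-specific rate
#'   column (hermaphrodites use the female column).
#' @param chroms chromosome names of the genome (assortment is drawn
#'   for every chromosome, mapped or not).
#' @return A list with `crossovers` (named list of sorted integer
#'   positions per chromosome) and `assortment` (named vector, 1 or 2).
#' @export
sample_crossover_plan <- function(map, sex, chroms) {
  msex <- map_for_sex(map, sex)
  xo <- stats::setNames(vector("list", length(chroms)), chroms)
  for (i in seq_len(nrow(msex))) {
    if (msex$rate[i] <= 0) next
    if (!msex$chrom[i] %in% chroms) next
    m <- mean_crossovers(msex$rate[i])
    n <- stats::rpois(1L, m)
    if (n > 0L) {
      pos <- as.integer(pmin(floor(stats::runif(n, msex$start[i], msex$end[i] + 1)),
                             msex$end[i]))
      ch <- msex$chrom[i]
      xo[[ch]] <- c(xo[[ch]], pos)
    }
  }
  xo <- lapply(xo, function(p) if (is.null(p)) integer(0) else sort(p))
  assort <- stats::setNames(sample.int(2L, length(chroms), replace = TRUE), chroms)
  list(crossovers = xo, assortment = assort)
}

#' Form one gamete from a diploid parent
#'
#' Per chromosome the gamete starts on the genome copy chosen by the
#' plan's assortment coin and switches template after every crossover:
#' a locus at position `p` with the nearest crossover at `c` stays on
#' the left template iff `p <= c`.
#'
#' @param pop a diploid population.
#' @param individual parent index.
#' @param plan a [sample_crossover_plan()] result.
#' @return Integer 0/1 vector of length `nrow(pop$snp)`.
#' @export
make_gamete <- function(pop, individual, plan) {
  if (pop$ploidy != 2L) stop("gamete formation requires a diploid parent")
  snp <- pop$snp
  r1 <- 2L * individual - 1L
  g1 <- pop$haplo[r1, ]
  g2 <- pop$haplo[r1 + 1L, ]
  gam <- integer(nrow(snp))
  for (ch in chrom_levels(snp)) {
    cols <- which(snp$chrom == ch)
    if (!ch %in% names(plan$assortment)) {
      stop("plan does not cover chromosome ", ch)
    }
    tmpl <- rep.int(plan$assortment[[ch]] - 1L, length(cols))  # 0 -> genome1
    xo <- plan$crossovers[[ch]]
    if (length(xo)) {
      tmpl <- (tmpl + findInterval(snp$pos[cols] - 1L, xo)) %% 2L
    }
    gam[cols] <- ifelse(tmpl == 0L, g1[cols], g2[cols])
  }
  gam
}

# Batch gamete formation for the engine: one parent sex per call.
# Fully vectorised when no crossover lands in a gamete; gametes hit by
# crossovers get a per-chromosome template walk.
make_gametes_batch <- function(pop, parents, parent_sex, map) {
  snp <- pop$snp
  L <- nrow(snp)
  chroms <- chrom_levels(snp)
  K <- length(chroms)
  ci <- match(snp$chrom, chroms)
  G <- length(parents)
  A <- matrix(sample.int(2L, G * K, replace = TRUE) - 1L, G, K)
  C <- A[, ci, drop = FALSE]

  msex <- map_for_sex(map, parent_sex)
  msex <- msex[msex$rate > 0 & msex$chrom %in% chroms, , drop = FALSE]
  W <- nrow(msex)
  if (W > 0L) {
    m <- mean_crossovers(msex$rate)
    X <- matrix(stats::rpois(G * W, rep(m, each = G)), G, W)
    hot <- which(X > 0L, arr.ind = TRUE)
    if (nrow(hot)) {
      win_chrom <- match(msex$chrom, chroms)
      cols_by_chrom <- split(seq_len(L), ci)
      grp <- split(seq_len(nrow(hot)),
                   paste(hot[, 1L], win_chrom[hot[, 2L]]))
      for (ids in grp) {
        g <- hot[ids[1L], 1L]
        k <- win_chrom[hot[ids[1L], 2L]]
        pos <- unlist(lapply(ids, function(i) {
          w <- hot[i, 2L]
          pmin(floor(stats::runif(X[g, w], msex$start[w], msex$end[w] + 1)),
               msex$end[w])
        }))
        pos <- sort(as.integer(pos))
        cols <- cols_by_chrom[[as.character(k)]]
        C[g, cols] <- (C[g, cols] + findInterval(snp$pos[cols] - 1L, pos)) %% 2L
      }
    }
  }
  G1 <- pop$haplo[2L * parents - 1L, , drop = FALSE]
  G2 <- pop$haplo[2L * parents, , drop = FALSE]
  G1 + C * (G2 - G1)
}

#' Hemizygous X transmission
#'
#' With a hemizygous X configured, a male carries a single X haplotype:
#' daughters receive one recombined maternal X plus the paternal X
#' unchanged (males do not recombine on the X because they have nothing
#' to recombine against), and sons receive only the recombined maternal
#' X.
#'
#' @param maternal_x,paternal_x integer 0/1 vectors over the X-linked
#'   loci: the recombined maternal gamete and the father's single X.
#' @param offspring_sex `"F"` or `"M"`.
#' @return A list with `genome1` and `genome2` rows for the X columns;
#'   for a son both rows mirror the single maternal copy.
#' @export
transmit_sex_chromosome <- function(maternal_x, paternal_x, offspring_sex) {
  if (!offspring_sex %in% c("F", "M")) {
    stop("hemizygous transmission requires F/M offspring")
  }
  if (offspring_sex == "F") {
    list(genome1 = maternal_x, genome2 = paternal_x)
  } else {
    list(genome1 = maternal_x, genome2 = maternal_x)
  }
}
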