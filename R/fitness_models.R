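#' Effect models: per-SNP selection coefficients or QTL effect sizes
#'
#' In `w` mode each selected locus carries a selection coefficient `s`
#' and dominance `h`, giving genotype fitnesses 1, 1+hs, 1+s for 0, 1, 2
#' copies of the selected allele (1 and 1+s for a single copy in
#' haploids and hemizygous males).  In `qt`/`qff` mode each QTL carries
#' an additive effect `a` and dominance effect `d`, contributing -a, d,
#' +a to the genotype value for 0, 1, 2 copies (-a/+a for a single
#' copy).  Pairwise epistasis fitness tables may be attached with
#' [set_epistasis()]; loci inside a pair contribute to fitness only
#' through their table.
#'
#' @param mode `"w"`, `"qt"` or `"qff"`.
#' @param chrom,pos,allele selected locus coordinates and the selected
#'   allele (must be one of the two alleles at the locus).
#' @param s,h selection coefficient and dominance (w-mode); `s > -1`.
#' @param a,d additive and dominance effect in trait units (qt/qff).
#' @param snp the [snp_table()] the loci refer to.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(mode = c("w", "qt", "qff"), chrom = character(0),
                         pos = integer(0), allele = character(0),
                         s = numeric(0), h = numeric(0),
                         a = numeric(0), d = 0, snp) {
  mode <- match.arg(mode)
  k <- length(chrom)
  idx <- if (k) locus_index(snp, chrom, pos) else integer(0)
  allele <- toupper(allele)
  sel_derived <- logical(k)
  for (i in seq_len(k)) {
    if (allele[i] == snp$der[idx[i]]) {
      sel_derived[i] <- TRUE
    } else if (allele[i] == snp$anc[idx[i]]) {
      sel_derived[i] <- FALSE
    } else {
      stop("selected allele ", allele[i], " not segregating at ",
           chrom[i], ":", pos[i])
    }
  }
  if (mode == "w") {
    s <- rep_len(as.numeric(s), k); h <- rep_len(as.numeric(h), k)
    if (any(s <= -1)) stop("selection coefficients must exceed -1")
    loci <- data.frame(idx = idx, sel_derived = sel_derived, s = s, h = h)
  } else {
    a <- rep_len(as.numeric(a), k); d <- rep_len(as.numeric(d), k)
    loci <- data.frame(idx = idx, sel_derived = sel_derived, a = a, d = d)
  }
  structure(list(mode = mode, loci = loci, epistasis = list()),
            class = "effect_model")
}

#' @rdname effect_model
#' @param em an `effect_model`.
#' @param pairs epistasis entries from [read_epistasis()] or built in
#'   code: `list(list(a = <locus idx>, b = <locus idx>, table = <3x3>))`.
#' @export
set_epistasis <- function(em, pairs) {
  for (p in pairs) {
    if (any(p$table < 0)) stop("epistasis fitness values must be >= 0")
  }
  em$epistasis <- pairs
  em
}

#' @export
print.effect_model <- function(x, ...) {
  cat("<effect_model> mode", x$mode, "|", nrow(x$loci), "selected loci |",
      length(x$epistasis), "epistatic pair(s)\n")
  invisible(x)
}

# dose of the *selected* allele plus the local copy number (1 or 2)
selected_dose <- function(pop, em) {
  idx <- em$loci$idx
  D <- dose_matrix(pop, idx)
  n <- pop_size(pop)
  copies <- matrix(pop$ploidy, n, length(idx))
  if (!is.null(pop$hemi)) {
    xc <- which(pop$snp$chrom[idx] == pop$hemi)
    males <- which(pop$sex == "M")
    if (length(xc) && length(males)) copies[males, xc] <- 1L
  }
  flip <- !em$loci$sel_derived
  if (any(flip)) D[, flip] <- copies[, flip, drop = FALSE] - D[, flip, drop = FALSE]
  list(dose = D, copies = copies)
}

#' Multiplicative fitness from per-SNP selection coefficients (w-mode)
#'
#' Fitness is the product over selected loci of the genotype fitness
#' 1, 1+hs, 1+s (dose 0, 1, 2 of the selected allele; 1 or 1+s for
#' single-copy loci), times the table lookup for every configured
#' epistatic pair.  Loci belonging to an epistatic pair are excluded
#' from the per-locus product so they are not counted twice.
#'
#' @param pop a population.
#' @param em a `w`-mode [effect_model()].
#' @return Numeric vector of fitnesses, one per individual; all > 0 for
#'   `s > -1` and positive epistasis tables.
#' @export
w_mode_fitness <- function(pop, em) {
  if (em$mode != "w") stop("effect model is not w-mode")
  n <- pop_size(pop)
  w <- rep(1, n)
  in_pair <- unique(unlist(lapply(em$epistasis, function(p) c(p$a, p$b))))
  sd <- if (nrow(em$loci)) selected_dose(pop, em)
  for (i in seq_len(nrow(em$loci))) {
    if (em$loci$idx[i] %in% in_pair) next
    dose <- sd$dose[, i]
    copies <- sd$copies[, i]
    s <- em$loci$s[i]; h <- em$loci$h[i]
    wi <- ifelse(copies == 1L, 1 + dose * s,
                 1 + (dose == 1L) * h * s + (dose == 2L) * s)
    w <- w * wi
  }
  for (p in em$epistasis) {
    da <- pair_dose(pop, p$a)
    db <- pair_dose(pop, p$b)
    w <- w * p$table[cbind(da + 1L, db + 1L)]
  }
  w
}

# derived-allele dose at one locus for every individual
pair_dose <- function(pop, locus) {
  as.integer(dose_matrix(pop, locus))
}

#' Additive genotype value of a quantitative trait
#'
#' `g = sum over QTLs of (-a, d, +a)` for dose 0, 1, 2 of the selected
#' allele (`-a`/`+a` for single-copy loci).
#'
#' @param pop a population.
#' @param em a `qt`/`qff`-mode [effect_model()].
#' @return Numeric vector of genotype values in trait units.
#' @export
genotype_value <- function(pop, em) {
  if (em$mode == "w") stop("effect model is not a quantitative-trait model")
  n <- pop_size(pop)
  g <- rep(0, n)
  if (!nrow(em$loci)) return(g)
  sd <- selected_dose(pop, em)
  for (i in seq_len(nrow(em$loci))) {
    dose <- sd$dose[, i]
    copies <- sd$copies[, i]
    a <- em$loci$a[i]; d <- em$loci$d[i]
    gi <- ifelse(copies == 1L, (2 * dose - 1) * a,
                 (dose - 1) * a * (dose != 1L) + (dose == 1L) * d)
    g <- g + gi
  }
  g
}

#' Environmental variance implied by a target heritability
#'
#' The narrow-sense heritability is fixed once against the founder
#' genetic variance: `h2 = V_G0 / (V_G0 + V_E)`, so
#' `V_E = V_G0 (1 - h2) / h2`.  `V_E` then stays constant for the whole
#' run even as selection erodes `V_G`.
#'
#' @param h2 heritability in `(0, 1]`.
#' @param V_G0 genetic variance of the founder population (variance of
#'   [genotype_value()]).
#' @return Environmental variance `V_E >= 0`.
#' @export
environmental_variance <- function(h2, V_G0) {
  if (!is.finite(h2) || h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (V_G0 < 0) stop("V_G0 must be >= 0")
  V_G0 * (1 - h2) / h2
}

#' Phenotypes: genotype value plus Gaussian environmental noise
#'
#' `z = g + e`, `e ~ Normal(0, V_E)`, drawn fresh each generation.
#'
#' @param g genotype values.
#' @param V_E environmental variance (>= 0).
#' @return Numeric vector of phenotypes.
#' @export
phenotype_values <- function(g, V_E) {
  if (V_E < 0) stop("V_E must be >= 0")
  g + stats::rnorm(length(g), 0, sqrt(V_E))
}

#' Trait-to-fitness mapping specifications (qff-mode)
#'
#' Supported kinds and closed forms (`z` = phenotype):
#' * `gaussian_stabilizing`: `w = exp(-(z - optimum)^2 / (2 sigma^2))`.
#' * `directional_linear`: `w = max(0, 1 + slope (z - z_ref))`.
#' * `disruptive`: `w = 1 + min((z - optimum)^2 / (2 sigma^2), cap)` —
#'   extremes gain fitness, bounded by `cap`.
#' * `diminishing_returns`:
#'   `w = w_max (1 - exp(-lambda * max(z - z0, 0))) + w_base` —
#'   saturating gains above the threshold `z0`.
#' * `moving_optimum`: Gaussian stabilizing with the optimum taken from
#'   a per-generation `schedule` (data frame with columns `generation`,
#'   `optimum`; linear interpolation between listed generations,
#'   constant extrapolation beyond).
#'
#' @param kind one of the five kinds above.
#' @param optimum trait optimum (gaussian/disruptive).
#' @param sigma width of the fitness function, trait units; > 0.
#' @param slope linear selection gradient (directional).
#' @param z_ref reference phenotype for the directional form.
#' @param cap upper bound of the disruptive fitness bonus.
#' @param w_max,lambda,z0,w_base saturating-exponential parameters for
#'   diminishing returns; `w_max > 0`, `lambda > 0`, `w_base >= 0`.
#' @param schedule moving-optimum schedule (see above).
#' @return An object of class `fitness_function_spec`.
#' @export
fitness_function_spec <- function(kind = c("gaussian_stabilizing",
                                           "directional_linear", "disruptive",
                                           "diminishing_returns",
                                           "moving_optimum"),
                                  optimum = 0, sigma = 1, slope = 0.1,
                                  z_ref = 0, cap = 10, w_max = 1, lambda = 1,
                                  z0 = 0, w_base = 0.01, schedule = NULL) {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("sigma must be > 0")
  if (w_max <= 0) stop("w_max must be > 0")
  if (lambda <= 0) stop("lambda must be > 0")
  if (kind == "moving_optimum") {
    if (is.null(schedule) || !all(c("generation", "optimum") %in% names(schedule))) {
      stop("moving_optimum needs a schedule with columns generation, optimum")
    }
  }
  structure(list(kind = kind, optimum = optimum, sigma = sigma, slope = slope,
                 z_ref = z_ref, cap = cap, w_max = w_max, lambda = lambda,
                 z0 = z0, w_base = w_base, schedule = schedule),
            class = "fitness_function_spec")
}

#' Map phenotypes to fitness
#'
#' @param z phenotype vector.
#' @param spec a [fitness_function_spec()].
#' @param generation current generation (used by `moving_optimum`).
#' @return Numeric vector of non-negative fitnesses.
#' @export
apply_fitness_function <- function(z, spec, generation = 0L) {
  switch(spec$kind,
    gaussian_stabilizing = exp(-(z - spec$optimum)^2 / (2 * spec$sigma^2)),
    directional_linear = pmax(0, 1 + spec$slope * (z - spec$z_ref)),
    disruptive = 1 + pmin((z - spec$optimum)^2 / (2 * spec$sigma^2), spec$cap),
    diminishing_returns =
      spec$w_max * (1 - exp(-spec$lambda * pmax(z - spec$z0, 0))) + spec$w_base,
    moving_optimum = {
      opt <- stats::approx(spec$schedule$generation, spec$schedule$optimum,
                           xout = generation, rule = 2)$y
      exp(-(z - opt)^2 / (2 * spec$sigma^2))
    },
    stop("unknown fitness function kind: ", spec$kind))
}

#' Truncating selection on phenotypes
#'
#' Retains exactly `round(survive_fraction * N)` individuals
#' (round-half-up) with the most extreme phenotypes in the surviving
#' tail; ties are broken by stable input order, so the result is
#' deterministic given the phenotype vector.
#'
#' @param phenotypes numeric vector.
#' @param survive_fraction fraction in `(0, 1]` retained as parents.
#' @param tail `"high"` (largest values survive) or `"low"`.
#' @return Sorted integer indices of the survivors.
#' @export
truncate_select <- function(phenotypes, survive_fraction, tail = c("high", "low")) {
  tail <- match.arg(tail)
  if (!is.finite(survive_fraction) || survive_fraction <= 0 || survive_fraction > 1) {
    stop("survive_fraction must lie in (0, 1]")
  }
  n <- length(phenotypes)
  k <- max(1L, as.integer(floor(survive_fraction * n + 0.5)))
  ord <- order(phenotypes, decreasing = (tail == "high"), method = "radix")
  sort(ord[seq_len(k)])
}
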