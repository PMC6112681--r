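#' Simulation run configuration
#'
#' Collects every knob of a forward run.  Replicate seeds are derived
#' deterministically from `seed`, so a config fully determines the
#' output.
#'
#' @param mode `"w"` (direct fitness from selection coefficients),
#'   `"qt"` (quantitative trait + truncating selection) or `"qff"`
#'   (quantitative trait mapped to fitness).
#' @param N census population size, constant across generations.
#' @param generations number of generations to simulate.
#' @param replicates number of independently seeded replicates.
#' @param female_frac fraction of females among offspring (dioecious
#'   populations); sexes are assigned by deterministic rounding and
#'   shuffling so the realised ratio is exact up to integer rounding.
#' @param hermaphrodite if `TRUE` all individuals are hermaphrodites and
#'   `selfing` applies.
#' @param selfing probability that a hermaphrodite offspring is produced
#'   by self-fertilisation.
#' @param clonal if `TRUE`, haploid clonal reproduction: offspring are
#'   exact copies of fitness-sampled parents (plus de novo mutation).
#' @param hemi name of the hemizygous chromosome (e.g. `"X"`), or
#'   `NULL`.
#' @param mutation_rate per-site per-gamete bit-flip probability.
#' @param migration `NULL` or `list(fraction =, haplo =)`: each
#'   generation `round(fraction * N)` random residents are replaced by
#'   individuals assembled from random rows of the migrant haplotype
#'   pool.
#' @param truncation qt-mode truncating selection:
#'   `list(fraction =, tail =)` where `fraction` is the surviving
#'   fraction — a scalar or one value per generation — and `tail` is
#'   `"high"` or `"low"`.
#' @param h2 heritability of the trait (qt/qff); the environmental
#'   variance is fixed once from the founder genetic variance via
#'   [environmental_variance()].
#' @param fitness_fun a [fitness_function_spec()] (qff mode).
#' @param output_generations generations at which allele counts are
#'   recorded; defaults to founder and final generation.
#' @param seed base random seed (integer).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(mode = c("w", "qt", "qff"), N, generations,
                       replicates = 1L, female_frac = 0.5,
                       hermaphrodite = FALSE, selfing = 0, clonal = FALSE,
                       hemi = NULL, mutation_rate = 0, migration = NULL,
                       truncation = list(fraction = 1, tail = "high"),
                       h2 = 0.5, fitness_fun = NULL,
                       output_generations = NULL, seed = 1L) {
  mode <- match.arg(mode)
  N <- as.integer(N)
  generations <- as.integer(generations)
  replicates <- as.integer(replicates)
  if (N < 2L && !clonal) stop("N must be >= 2 (>= 1 if clonal)")
  if (N < 1L) stop("N must be >= 1")
  if (generations < 0L) stop("generations must be >= 0")
  if (female_frac < 0 || female_frac > 1) stop("female_frac must lie in [0,1]")
  if (selfing < 0 || selfing > 1) stop("selfing must lie in [0,1]")
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate must lie in [0,1]")
  if (!is.null(migration)) {
    if (migration$fraction < 0 || migration$fraction > 1) {
      stop("migration fraction must lie in [0,1]")
    }
  }
  if (!is.null(hemi) && (hermaphrodite || clonal)) {
    stop("hemizygosity requires a dioecious diploid population")
  }
  frac <- truncation$fraction
  if (any(frac <= 0 | frac > 1)) stop("truncation fraction must lie in (0,1]")
  if (!length(frac) %in% c(1L, max(generations, 1L))) {
    stop("truncation fraction must be a scalar or one value per generation")
  }
  if (mode == "qff" && is.null(fitness_fun)) {
    stop("qff mode requires a fitness_fun spec")
  }
  if (is.null(output_generations)) output_generations <- unique(c(0L, generations))
  structure(list(mode = mode, N = N, generations = generations,
                 replicates = replicates, female_frac = female_frac,
                 hermaphrodite = hermaphrodite, selfing = selfing,
                 clonal = clonal, hemi = hemi, mutation_rate = mutation_rate,
                 migration = migration,
                 truncation = list(fraction = frac,
                                   tail = truncation$tail %||% "high"),
                 h2 = h2, fitness_fun = fitness_fun,
                 output_generations = as.integer(sort(unique(output_generations))),
                 seed = as.integer(seed)),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

replicate_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  set.seed(seed)
  s <- sample.int(2147483646L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

offspring_sexes <- function(cfg) {
  if (cfg$clonal || cfg$hermaphrodite) return(rep("H", cfg$N))
  n_f <- as.integer(floor(cfg$female_frac * cfg$N + 0.5))
  sample(c(rep("F", n_f), rep("M", cfg$N - n_f)))
}

#' Assemble a founder population from a haplotype panel
#'
#' If the panel holds exactly `ploidy * N` haplotypes they are used in
#' file order (individual i gets rows 2i-1, 2i); otherwise `ploidy * N`
#' rows are sampled from the panel with replacement, mimicking the
#' common E&R practice of seeding an experimental population from a
#' limited set of founder lines.
#'
#' @param founder list with `snp`, `haplo`, `ploidy` (see
#'   [read_haplotypes()]).
#' @param cfg a [sim_config()].
#' @param replicate_id replicate label stored on the population.
#' @return A [new_population()] object at generation 0.
#' @export
make_founder_population <- function(founder, cfg, replicate_id = 1L) {
  ploidy <- if (cfg$clonal) 1L else 2L
  need <- ploidy * cfg$N
  H <- founder$haplo
  if (nrow(H) != need) {
    H <- H[sample.int(nrow(H), need, replace = TRUE), , drop = FALSE]
  }
  new_population(founder$snp, H, sex = offspring_sexes(cfg), ploidy = ploidy,
                 hemi = cfg$hemi, generation = 0L, replicate_id = replicate_id)
}

# step vii: genotype -> phenotype -> fitness, mode-specific
evaluate_population <- function(pop, cfg, em, V_E) {
  n <- pop_size(pop)
  if (cfg$mode == "w") {
    pop$fitness <- if (is.null(em) || !nrow(em$loci) && !length(em$epistasis)) {
      rep(1, n)
    } else {
      w_mode_fitness(pop, em)
    }
    pop$phenotype <- NULL
  } else {
    g <- genotype_value(pop, em)
    pop$phenotype <- phenotype_values(g, V_E)
    pop$fitness <- if (cfg$mode == "qff") {
      apply_fitness_function(pop$phenotype, cfg$fitness_fun, pop$generation)
    } else {
      rep(1, n)  # qt: selection acts through truncation only
    }
  }
  pop
}

#' Form fitness-proportional mating pairs
#'
#' Samples `N` parent pairs with replacement; each parent is drawn with
#' probability proportional to fitness within its eligible sex pool
#' (females x males for dioecious populations).  Hermaphrodites may
#' self-fertilise with the configured probability, which pairs an
#' individual with itself; otherwise both parents are drawn
#' independently.
#'
#' @param pop a population with fitness computed.
#' @param cfg a [sim_config()].
#' @param eligible indices of individuals allowed to mate (qt-mode
#'   truncation survivors); default all.
#' @return A list with integer vectors `mothers` and `fathers` of length
#'   `cfg$N` (for hermaphrodites: parent 1 and parent 2).
#' @export
form_mating_pairs <- function(pop, cfg, eligible = NULL) {
  if (is.null(eligible)) eligible <- seq_len(pop_size(pop))
  fit <- pop$fitness[eligible]
  if (all(fit <= 0)) stop("no parent with positive fitness")
  N <- cfg$N
  if (cfg$hermaphrodite || all(pop$sex[eligible] == "H")) {
    p1 <- sample_weighted(eligible, N, fit)
    p2 <- sample_weighted(eligible, N, fit)
    self <- stats::runif(N) < cfg$selfing
    p2[self] <- p1[self]
    return(list(mothers = p1, fathers = p2))
  }
  females <- eligible[pop$sex[eligible] == "F"]
  males <- eligible[pop$sex[eligible] == "M"]
  if (!length(females) || !length(males)) {
    stop("extinction: an eligible sex pool is empty")
  }
  wf <- pop$fitness[females]
  wm <- pop$fitness[males]
  if (all(wf <= 0) || all(wm <= 0)) stop("no parent with positive fitness")
  list(mothers = sample_weighted(females, N, wf),
       fathers = sample_weighted(males, N, wm))
}

sample_weighted <- function(idx, n, w) {
  if (length(idx) == 1L) return(rep.int(idx, n))
  idx[sample.int(length(idx), n, replace = TRUE, prob = w)]
}

#' Introduce de novo mutations into gametes
#'
#' Each site flips its bit (ancestral <-> derived) independently with
#' probability `mutation_rate`.  Monomorphic columns reserved in the SNP
#' table are valid targets, which is how new variation enters.
#'
#' @param gametes integer 0/1 matrix (gametes x loci) or a single gamete
#'   vector.
#' @param mutation_rate per-site flip probability in `[0, 1]`.
#' @return The mutated gametes, same shape.
#' @export
apply_mutation <- function(gametes, mutation_rate) {
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must lie in [0, 1]")
  }
  if (mutation_rate == 0) return(gametes)
  flip <- stats::runif(length(gametes)) < mutation_rate
  gametes[flip] <- 1L - gametes[flip]
  gametes
}

#' Replace residents with migrants
#'
#' `round(fraction * N)` randomly chosen residents are replaced by
#' individuals assembled from random haplotypes of the migrant pool
#' (rows sampled with replacement).  Replaced individuals keep their sex
#' so the configured sex ratio is undisturbed; population size is
#' constant.
#'
#' @param pop a population.
#' @param migration `list(fraction =, haplo =)`; the pool must have one
#'   column per SNP-table locus.
#' @return The population after replacement.
#' @export
apply_migration <- function(pop, migration) {
  m <- migration$fraction
  if (m <= 0) return(pop)
  pool <- migration$haplo
  if (ncol(pool) != nrow(pop$snp)) {
    stop("migrant pool incompatible with SNP table")
  }
  n <- pop_size(pop)
  k <- as.integer(floor(m * n + 0.5))
  if (k == 0L) return(pop)
  who <- sample.int(n, k)
  rows <- pool[sample.int(nrow(pool), pop$ploidy * k, replace = TRUE), ,
               drop = FALSE]
  for (j in seq_len(k)) {
    i <- who[j]
    if (pop$ploidy == 1L) {
      pop$haplo[i, ] <- rows[j, ]
    } else {
      pop$haplo[2L * i - 1L, ] <- rows[2L * j - 1L, ]
      pop$haplo[2L * i, ] <- rows[2L * j, ]
    }
  }
  if (!is.null(pop$hemi)) {
    xc <- hemi_cols(pop)
    males <- intersect(who, which(pop$sex == "M"))
    if (length(males) && length(xc)) {
      pop$haplo[2L * males, xc] <- pop$haplo[2L * males - 1L, xc, drop = FALSE]
    }
  }
  pop
}

#' Clonal reproduction
#'
#' Clones do not mate: each of the `N` offspring is an exact genome copy
#' of a parent sampled with probability proportional to fitness, subject
#' only to de novo mutation.  No recombination, no assortment.
#'
#' @param pop a haploid clonal population with fitness computed.
#' @param cfg a [sim_config()] with `clonal = TRUE`.
#' @return The offspring population (unevaluated).
#' @export
reproduce_clonal <- function(pop, cfg) {
  parents <- sample_weighted(seq_len(pop_size(pop)), cfg$N, pop$fitness)
  H <- pop$haplo[parents, , drop = FALSE]
  H <- apply_mutation(H, cfg$mutation_rate)
  new_population(pop$snp, H, sex = pop$sex[parents], ploidy = 1L,
                 generation = pop$generation + 1L,
                 replicate_id = pop$replicate_id)
}

#' Advance a population by one generation
#'
#' Executes the per-generation event loop in fixed order:
#' i) truncating selection (qt-mode), ii) mate-pair formation,
#' iii) gamete formation via crossovers and random assortment of
#' chromosomes, iv) de novo mutation of gametes, v) zygote formation
#' restoring the census size `N`, vi) migration, vii) evaluation of
#' genotype, phenotype and fitness of the new generation, viii) output
#' (handled by the caller via [take_snapshot()]).
#'
#' @param pop the current population, already evaluated (phenotype and
#'   fitness present).
#' @param cfg a [sim_config()].
#' @param em an [effect_model()] or `NULL` for a neutral run.
#' @param map a [recomb_map()]; `NULL` means no recombination beyond
#'   free assortment of chromosomes.
#' @param V_E environmental variance (qt/qff), from
#'   [environmental_variance()].
#' @return The next generation, evaluated.
#' @export
advance_generation <- function(pop, cfg, em = NULL, map = NULL, V_E = 0) {
  if (is.null(map)) {
    map <- recomb_map(character(0), integer(0), integer(0), numeric(0))
  }
  if (cfg$clonal) {
    off <- reproduce_clonal(pop, cfg)
    if (!is.null(cfg$migration)) off <- apply_migration(off, cfg$migration)
    return(evaluate_population(off, cfg, em, V_E))
  }
  # i) truncating selection
  eligible <- NULL
  if (cfg$mode == "qt") {
    frac <- cfg$truncation$fraction
    f_now <- if (length(frac) == 1L) frac else frac[pop$generation + 1L]
    eligible <- truncate_select(pop$phenotype, f_now, cfg$truncation$tail)
  }
  # ii) mate pairs
  pairs <- form_mating_pairs(pop, cfg, eligible)
  # iii) gametes: crossovers + random assortment
  Gm <- make_gametes_batch(pop, pairs$mothers,
                           if (cfg$hermaphrodite) "H" else "F", map)
  Gp <- make_gametes_batch(pop, pairs$fathers,
                           if (cfg$hermaphrodite) "H" else "M", map)
  # iv) mutation
  Gm <- apply_mutation(Gm, cfg$mutation_rate)
  Gp <- apply_mutation(Gp, cfg$mutation_rate)
  # v) zygotes
  N <- cfg$N
  L <- nrow(pop$snp)
  H <- matrix(0L, 2L * N, L)
  H[seq(1L, 2L * N, by = 2L), ] <- Gm
  H[seq(2L, 2L * N, by = 2L), ] <- Gp
  off <- new_population(pop$snp, H, sex = offspring_sexes(cfg), ploidy = 2L,
                        hemi = cfg$hemi, generation = pop$generation + 1L,
                        replicate_id = pop$replicate_id)
  # vi) migration
  if (!is.null(cfg$migration)) off <- apply_migration(off, cfg$migration)
  # vii) evaluate
  evaluate_population(off, cfg, em, V_E)
}

#' Run a full multi-replicate simulation
#'
#' Each replicate runs with its own seed derived deterministically from
#' the base seed, so an identical config yields byte-identical output
#' and replicates are independent of execution order.  Allele counts are
#' recorded at the configured output generations.
#'
#' @param cfg a [sim_config()].
#' @param founder founder haplotype panel: list with `snp`, `haplo`,
#'   `ploidy` (from [read_haplotypes()] or [generate_fixture_panel()]).
#' @param map a [recomb_map()] or `NULL`.
#' @param em an [effect_model()] or `NULL` (neutral).
#' @param keep_populations if `TRUE`, the final population of each
#'   replicate is returned (memory permitting).
#' @return A list of class `sim_result`: `snp`, `config`, and
#'   `replicates` — per replicate a list with `replicate_id`, `seed`,
#'   `V_E`, `snapshots` and optionally `final_pop`.
#' @export
run_simulation <- function(cfg, founder, map = NULL, em = NULL,
                           keep_populations = FALSE) {
  if (cfg$mode %in% c("qt", "qff") &&
      (is.null(em) || em$mode == "w")) {
    stop("qt/qff runs need a qt/qff effect model")
  }
  seeds <- replicate_seeds(cfg$seed, cfg$replicates)
  reps <- vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    set.seed(seeds[r])
    pop <- make_founder_population(founder, cfg, replicate_id = r)
    V_E <- 0
    if (cfg$mode %in% c("qt", "qff")) {
      V_G0 <- stats::var(genotype_value(pop, em))
      V_E <- environmental_variance(cfg$h2, V_G0)
    }
    pop <- evaluate_population(pop, cfg, em, V_E)
    snaps <- list()
    if (0L %in% cfg$output_generations) snaps <- list(take_snapshot(pop))
    for (t in seq_len(cfg$generations)) {
      pop <- advance_generation(pop, cfg, em, map, V_E)
      if (t %in% cfg$output_generations) {
        snaps[[length(snaps) + 1L]] <- take_snapshot(pop)
      }
    }
    reps[[r]] <- list(replicate_id = r, seed = seeds[r], V_E = V_E,
                      snapshots = snaps,
                      final_pop = if (keep_populations) pop)
  }
  structure(list(snp = founder$snp, config = cfg, replicates = reps),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", length(x$replicates), "replicate(s) |",
      nrow(x$snp), "loci | mode", x$config$mode, "\n")
  invisible(x)
}

#' Allele-frequency trajectories from a simulation result
#'
#' @param res a [run_simulation()] result.
#' @return A data frame with columns `replicate`, `generation`, `locus`,
#'   `freq`.
#' @export
result_frequencies <- function(res) {
  out <- list()
  for (rep in res$replicates) {
    for (s in rep$snapshots) {
      out[[length(out) + 1L]] <- data.frame(
        replicate = rep$replicate_id, generation = s$generation,
        locus = seq_along(s$derived), freq = s$derived / s$total)
    }
  }
  do.call(rbind, out)
}

#' Collect all snapshots of a result for [write_sync()]
#'
#' @param res a [run_simulation()] result.
#' @export
result_snapshots <- function(res) {
  unlist(lapply(res$replicates, `[[`, "snapshots"), recursive = FALSE)
}
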