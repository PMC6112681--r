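test_that("census size and sex ratio are restored every generation", {
  set.seed(31)
  founder <- generate_fixture_panel(100, list(A = 20), seed = 31)
  cfg <- sim_config("w", N = 50, generations = 5, female_frac = 0.5, seed = 31)
  pop <- make_founder_population(founder, cfg)
  pop <- fwdsim:::evaluate_population(pop, cfg, NULL, 0)
  for (t in 1:5) {
    pop <- advance_generation(pop, cfg)
    expect_identical(pop_size(pop), 50L)
    expect_identical(sum(pop$sex == "F"), 25L)
    expect_identical(pop$generation, t)
  }
})

test_that("parents are drawn only from truncation survivors (step order)", {
  set.seed(32)
  pop <- random_population(100L)
  pop$phenotype <- rnorm(100)
  pop$fitness <- rep(1, 100)
  cfg <- sim_config("qt", N = 100, generations = 1,
                    truncation = list(fraction = 0.3, tail = "high"),
                    hermaphrodite = TRUE, seed = 1)
  survivors <- truncate_select(pop$phenotype, 0.3, "high")
  for (i in 1:20) {
    pairs <- form_mating_pairs(pop, cfg, survivors)
    expect_true(all(c(pairs$mothers, pairs$fathers) %in% survivors))
  }
})

test_that("truncating selection on a fully heritable trait raises the allele frequency", {
  set.seed(33)
  L <- 1L
  snp <- snp_table("1", 1L, "A", "T")
  founder <- list(snp = snp, haplo = matrix(rbinom(400, 1, 0.5), 400, L),
                  ploidy = 1L)
  em <- effect_model("qt", "1", 1L, "T", a = 1, d = 0, snp = snp)
  cfg <- sim_config("qt", N = 200, generations = 1, hermaphrodite = TRUE,
                    truncation = list(fraction = 0.2, tail = "high"),
                    h2 = 1, seed = 33)
  res <- run_simulation(cfg, founder, em = em)
  f <- result_frequencies(res)
  expect_gt(f$freq[f$generation == 1], f$freq[f$generation == 0] + 0.1)
})

test_that("fitness-proportional mating samples fathers in fitness ratio", {
  snp <- snp_table("1", 1L, "A", "T")
  pop <- new_population(snp, matrix(0L, 8, 1),
                        sex = c("F", "F", "M", "M"), ploidy = 2L)
  pop$fitness <- c(1, 1, 2, 1)  # father 3 twice as fit as father 4
  cfg <- sim_config("w", N = 4, generations = 1, seed = 1)
  set.seed(34)
  draws <- integer(0)
  for (i in 1:5000) {
    draws <- c(draws, form_mating_pairs(pop, cfg)$fathers)
  }
  p_hat <- mean(draws == 3L)
  expect_lt(abs(p_hat - 2 / 3), 3 * sqrt((2 / 3) * (1 / 3) / length(draws)))
  # zero-fitness individuals are never sampled
  pop$fitness <- c(1, 0, 1, 0)
  for (i in 1:50) {
    pairs <- form_mating_pairs(pop, cfg)
    expect_false(any(pairs$mothers == 2L) || any(pairs$fathers == 4L))
  }
})

test_that("an empty eligible sex pool is an extinction error", {
  snp <- snp_table("1", 1L, "A", "T")
  pop <- new_population(snp, matrix(0L, 4, 1), sex = c("F", "F"), ploidy = 2L)
  cfg <- sim_config("w", N = 2, generations = 1, seed = 1)
  expect_error(form_mating_pairs(pop, cfg), "extinction")
})

test_that("mutation flips bits at the configured rate", {
  G <- matrix(0L, 100, 50)
  expect_identical(apply_mutation(G, 0), G)
  expect_identical(apply_mutation(G, 1), G + 1L)  # full complement
  expect_error(apply_mutation(G, 1.5), "mutation_rate")
  set.seed(35)
  rate <- 0.02
  flips <- sum(apply_mutation(G, rate))
  n <- length(G)
  expect_lt(abs(flips - n * rate), 3 * sqrt(n * rate * (1 - rate)))
})

test_that("migration replaces the configured fraction and drives frequencies to the pool", {
  set.seed(36)
  snp <- snp_table("1", 1L, "A", "T")
  resident <- list(snp = snp, haplo = matrix(1L, 200, 1), ploidy = 1L)
  pool <- matrix(0L, 50, 1)  # migrants fixed ancestral
  cfg0 <- sim_config("w", N = 100, generations = 1, hermaphrodite = TRUE,
                     seed = 1)
  pop <- make_founder_population(resident, cfg0)
  pop <- fwdsim:::evaluate_population(pop, cfg0, NULL, 0)
  # m = 0 is the identity
  expect_identical(apply_migration(pop, list(fraction = 0, haplo = pool)),
                   pop)
  # m = 1 replaces everyone
  p1 <- apply_migration(pop, list(fraction = 1, haplo = pool))
  expect_equal(allele_frequency(p1), 0)
  # m = 0.1 per generation: E[p_t] = (1 - m)^t geometric decay to the pool
  m <- 0.1; gens <- 5L; reps <- 60L
  cfg <- sim_config("w", N = 100, generations = gens, hermaphrodite = TRUE,
                    migration = list(fraction = m, haplo = pool), seed = 1)
  finals <- vapply(seq_len(reps), function(r) {
    set.seed(1000 + r)
    p <- make_founder_population(resident, cfg, r)
    p <- fwdsim:::evaluate_population(p, cfg, NULL, 0)
    for (t in seq_len(gens)) p <- advance_generation(p, cfg)
    allele_frequency(p)
  }, 0)
  expected <- (1 - m)^gens
  expect_lt(abs(mean(finals) - expected),
            3 * sd(finals) / sqrt(reps) + 1e-12)
  expect_error(apply_migration(pop, list(fraction = 1, haplo = matrix(0L, 5, 3))),
               "incompatible")
})

test_that("clonal reproduction copies parents exactly and responds to selection", {
  set.seed(37)
  snp <- snp_table("1", 1L, "A", "T")
  H <- matrix(c(1L, rep(0L, 49)), 50, 1)  # one derived clone
  cfg <- sim_config("w", N = 50, generations = 1, clonal = TRUE, seed = 1)
  pop <- new_population(snp, H, ploidy = 1L)
  pop$fitness <- rep(1, 50)
  off <- reproduce_clonal(pop, cfg)
  expect_true(all(off$haplo %in% H))  # exact copies, no recombination
  # strong selection: the fit clone sweeps
  em <- effect_model("w", "1", 1L, "T", s = 5, h = 0.5, snp = snp)
  cfgs <- sim_config("w", N = 50, generations = 15, clonal = TRUE, seed = 5)
  res <- run_simulation(cfgs, list(snp = snp, haplo = H, ploidy = 1L), em = em)
  f <- result_frequencies(res)
  expect_equal(f$freq[f$generation == 15], 1)
})

test_that("identical config and seed give byte-identical sync output", {
  founder <- generate_fixture_panel(40, list(A = 10, B = 10), seed = 9)
  cfg <- sim_config("w", N = 20, generations = 5, replicates = 3,
                    hermaphrodite = TRUE,
                    output_generations = c(0, 5), seed = 99)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  r1 <- run_simulation(cfg, founder, map = founder$map)
  r2 <- run_simulation(cfg, founder, map = founder$map)
  write_sync(f1, result_snapshots(r1), founder$snp)
  write_sync(f2, result_snapshots(r2), founder$snp)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("replicates are independent of how many are run", {
  founder <- generate_fixture_panel(40, list(A = 10), seed = 9)
  cfg3 <- sim_config("w", N = 20, generations = 3, replicates = 3,
                     hermaphrodite = TRUE, seed = 5)
  cfg2 <- sim_config("w", N = 20, generations = 3, replicates = 2,
                     hermaphrodite = TRUE, seed = 5)
  r3 <- run_simulation(cfg3, founder)
  r2 <- run_simulation(cfg2, founder)
  expect_identical(r3$replicates[[1]]$snapshots, r2$replicates[[1]]$snapshots)
  expect_identical(r3$replicates[[2]]$snapshots, r2$replicates[[2]]$snapshots)
})

test_that("across-replicate drift variance follows the closed form", {
  set.seed(38)
  N <- 100L
  founder <- list(snp = snp_table("1", 1L, "A", "T"),
                  haplo = matrix(rep(c(0L, 1L), each = N), 2L * N, 1),
                  ploidy = 1L)
  gens <- 10L
  reps <- 200L
  cfg <- sim_config("w", N = N, generations = gens, replicates = reps,
                    hermaphrodite = TRUE, output_generations = gens, seed = 7)
  res <- run_simulation(cfg, founder)
  f <- result_frequencies(res)
  v_obs <- var(f$freq)
  v_exp <- drift_variance(0.5, N, gens)
  # sampling error of a variance over `reps` replicates, ~3 SE
  expect_lt(abs(v_obs - v_exp), 3 * v_exp * sqrt(2 / (reps - 1)))
})

test_that("temporally variable truncation schedules are honoured", {
  set.seed(39)
  founder <- generate_fixture_panel(80, list(A = 5), seed = 4)
  em <- effect_model("qt", founder$snp$chrom[1], founder$snp$pos[1],
                     founder$snp$der[1], a = 1, d = 0, snp = founder$snp)
  cfg <- sim_config("qt", N = 40, generations = 3, hermaphrodite = TRUE,
                    truncation = list(fraction = c(0.9, 0.5, 1), tail = "low"),
                    h2 = 0.8, seed = 11)
  res <- run_simulation(cfg, founder, em = em, keep_populations = TRUE)
  expect_identical(pop_size(res$replicates[[1]]$final_pop), 40L)
  expect_length(result_snapshots(res), 2L)
  # a schedule of the wrong length is rejected
  expect_error(sim_config("qt", N = 40, generations = 3,
                          truncation = list(fraction = c(0.9, 0.5))),
               "per generation")
})
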