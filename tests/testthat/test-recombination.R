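test_that("Haldane inverse gives the expected crossover count", {
  expect_equal(mean_crossovers(0), 0)
  expect_equal(mean_crossovers(25), 0.346574, tolerance = 1e-5)
  # closed form agrees with numerically inverting c = (1 - exp(-2m))/2
  inv <- uniroot(function(m) (1 - exp(-2 * m)) / 2 - 0.25, c(0, 10),
                 tol = 1e-12)$root
  expect_equal(mean_crossovers(25), inv, tolerance = 1e-9)
  expect_error(mean_crossovers(50), "0.5")
  expect_error(mean_crossovers(-1), "negative")
})

test_that("crossover plans are empty under a zero map and for non-recombining males", {
  snp <- toy_snp()
  zero <- recomb_map("2L", 1L, 1000L, rate_female = 0)
  sexmap <- recomb_map(c("2L", "X"), c(1L, 1L), c(1000L, 1000L),
                       rate_female = c(10, 10), rate_male = c(0, 0))
  set.seed(1)
  for (i in 1:100) {
    p0 <- sample_crossover_plan(zero, "F", chrom_levels(snp))
    expect_true(all(lengths(p0$crossovers) == 0L))
    pm <- sample_crossover_plan(sexmap, "M", chrom_levels(snp))
    expect_true(all(lengths(pm$crossovers) == 0L))
  }
})

test_that("crossover counts are Poisson with the Haldane mean", {
  map <- recomb_map("2L", 1L, 1000L, rate_female = 20)
  m <- mean_crossovers(20)
  set.seed(5)
  n <- 5000L
  counts <- vapply(seq_len(n), function(i) {
    length(sample_crossover_plan(map, "F", "2L")$crossovers[["2L"]])
  }, 0L)
  se <- sqrt(m / n)  # Poisson: var = mean
  expect_lt(abs(mean(counts) - m), 3 * se)
  # positions land inside the window
  plan <- sample_crossover_plan(recomb_map("2L", 50L, 60L, 40), "F", "2L")
  expect_true(all(plan$crossovers[["2L"]] >= 50L &
                  plan$crossovers[["2L"]] <= 60L))
})

test_that("gamete formation matches a brute-force template walk", {
  snp <- toy_snp()
  set.seed(11)
  for (i in 1:50) {
    g1 <- rbinom(5, 1, 0.5)
    g2 <- rbinom(5, 1, 0.5)
    pop <- new_population(snp, rbind(g1, g2), ploidy = 2L)
    plan <- list(
      crossovers = list("2L" = sort(sample(1:1000, rpois(1, 2))),
                        "X" = sort(sample(1:1000, rpois(1, 2)))),
      assortment = c("2L" = sample(1:2, 1), "X" = sample(1:2, 1)))
    expect_identical(make_gamete(pop, 1L, plan),
                     brute_force_gamete(snp, g1, g2, plan))
  }
})

test_that("no crossovers + assortment copies whole parental chromosomes", {
  snp <- toy_snp()
  g1 <- c(1L, 1L, 1L, 0L, 0L)
  g2 <- c(0L, 0L, 0L, 1L, 1L)
  pop <- new_population(snp, rbind(g1, g2), ploidy = 2L)
  plan <- list(crossovers = list("2L" = integer(0), "X" = integer(0)),
               assortment = c("2L" = 1L, "X" = 2L))
  expect_identical(make_gamete(pop, 1L, plan), c(g1[1:3], g2[4:5]))
  # homozygous parent: gamete identical regardless of plan
  hom <- new_population(snp, rbind(g1, g1), ploidy = 2L)
  set.seed(2)
  map <- recomb_map(c("2L", "X"), c(1L, 1L), c(1000L, 1000L), 30)
  for (i in 1:20) {
    plan <- sample_crossover_plan(map, "F", chrom_levels(snp))
    expect_identical(make_gamete(hom, 1L, plan), g1)
  }
})

test_that("a single crossover splits prefix and suffix between templates", {
  snp <- snp_table(rep("1", 4), c(10L, 20L, 30L, 40L), rep("A", 4), rep("T", 4))
  pop <- new_population(snp, rbind(rep(1L, 4), rep(0L, 4)), ploidy = 2L)
  plan <- list(crossovers = list("1" = 25L), assortment = c("1" = 1L))
  # loci at p <= 25 stay on template 1, the rest switch
  expect_identical(make_gamete(pop, 1L, plan), c(1L, 1L, 0L, 0L))
  # crossover exactly on a locus position: that locus stays left
  plan$crossovers[["1"]] <- 20L
  expect_identical(make_gamete(pop, 1L, plan), c(1L, 1L, 0L, 0L))
})

test_that("realised recombinant fraction between loci equals the map fraction", {
  snp <- snp_table(c("1", "1"), c(1L, 100000L), c("A", "A"), c("T", "T"))
  pop <- new_population(snp, rbind(c(1L, 1L), c(0L, 0L)), ploidy = 2L)
  map <- recomb_map("1", 1L, 99999L, rate_female = 20)  # c = 0.2
  set.seed(8)
  G <- fwdsim:::make_gametes_batch(pop, rep(1L, 100000L), "F", map)
  frac <- mean(G[, 1] != G[, 2])
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 100000))
})

test_that("hemizygous X transmission follows the single-copy rules", {
  mat <- c(1L, 0L)
  pat <- c(0L, 1L)
  son <- transmit_sex_chromosome(mat, pat, "M")
  expect_identical(son$genome1, mat)
  expect_identical(son$genome2, mat)  # only the maternal X
  dau <- transmit_sex_chromosome(mat, pat, "F")
  expect_identical(dau$genome2, pat)  # paternal X unchanged
  expect_error(transmit_sex_chromosome(mat, pat, "H"), "F/M")
})

test_that("sons carry one maternal X and daughters the unrecombined paternal X", {
  set.seed(21)
  snp <- toy_snp()
  xcols <- which(snp$chrom == "X")
  n <- 40L
  H <- matrix(rbinom(2L * n * nrow(snp), 1, 0.5), 2L * n, nrow(snp))
  sex <- rep(c("F", "M"), n / 2L)
  pop <- new_population(snp, H, sex = sex, ploidy = 2L, hemi = "X")
  cfg <- sim_config("w", N = n, generations = 1L, hemi = "X", seed = 3)
  off <- advance_generation(pop, cfg)
  sons <- which(off$sex == "M")
  expect_true(all(off$haplo[2L * sons, xcols] ==
                  off$haplo[2L * sons - 1L, xcols]))
  # every daughter's paternal X equals some father's X haplotype
  fathers_x <- unique(apply(pop$haplo[2L * which(pop$sex == "M") - 1L, xcols,
                                      drop = FALSE], 1L, paste, collapse = ""))
  daughters <- which(off$sex == "F")
  dau_pat <- apply(off$haplo[2L * daughters, xcols, drop = FALSE], 1L,
                   paste, collapse = "")
  expect_true(all(dau_pat %in% fathers_x))
})
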