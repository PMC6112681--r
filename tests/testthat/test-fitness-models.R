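test_that("w-mode genotype fitnesses follow 1, 1+hs, 1+s and multiply across loci", {
  snp <- toy_snp()
  # individual doses at loci 1,2: (1,0), (2,2), (0,1)
  pop <- toy_population(list(
    c(1L, 0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 0L),
    c(1L, 1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L, 0L),
    c(0L, 1L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 0L)))
  em1 <- effect_model("w", "2L", 100L, "T", s = 0.1, h = 0.5, snp = snp)
  expect_equal(w_mode_fitness(pop, em1), c(1.05, 1.1, 1))
  em2 <- effect_model("w", c("2L", "2L"), c(100L, 500L), c("T", "G"),
                      s = 0.1, h = 0.5, snp = snp)
  # two loci both dose 2: multiplicative 1.1 * 1.1 = 1.21
  expect_equal(w_mode_fitness(pop, em2), c(1.05 * 1, 1.21, 1 * 1.05))
  # selecting the ancestral allele flips the dose
  em3 <- effect_model("w", "2L", 100L, "A", s = 0.1, h = 0.5, snp = snp)
  expect_equal(w_mode_fitness(pop, em3), c(1.05, 1, 1.1))
})

test_that("hemizygous males get single-copy fitness 1 or 1+s on the X", {
  snp <- toy_snp()
  pop <- toy_population(list(
    c(0L, 0L, 0L, 1L, 0L), c(0L, 0L, 0L, 1L, 0L),   # F: X hom derived
    c(0L, 0L, 0L, 1L, 0L), c(0L, 0L, 0L, 0L, 0L)),  # M: single derived X
    sex = c("F", "M"), hemi = "X")
  em <- effect_model("w", "X", 200L, "C", s = 0.2, h = 0.5, snp = snp)
  expect_equal(w_mode_fitness(pop, em), c(1.2, 1.2))
})

test_that("epistatic pairs contribute only through their table", {
  snp <- toy_snp()
  tab <- matrix(1, 3, 3); tab[3, 3] <- 1.2
  pop <- toy_population(list(
    c(1L, 1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L, 0L),   # doses (2,2)
    c(1L, 1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L, 0L),   # doses (1,2)
    c(0L, 0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 0L)))  # doses (0,0)
  em <- effect_model("w", c("2L", "2L"), c(100L, 500L), c("T", "G"),
                     s = 0.5, h = 0.5, snp = snp)
  em <- set_epistasis(em, list(list(a = 1L, b = 2L, table = tab)))
  # the s=0.5 baseline is suppressed for loci inside the pair
  expect_equal(w_mode_fitness(pop, em), c(1.2, 1, 1))
  expect_error(set_epistasis(em, list(list(a = 1L, b = 2L,
                                           table = -tab))), ">= 0")
})

test_that("genotype values are additive with dominance on the -a, d, +a scale", {
  snp <- toy_snp()
  pop <- toy_population(list(
    c(0L, 0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 0L),
    c(1L, 0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 0L),
    c(1L, 0L, 0L, 0L, 0L), c(1L, 0L, 0L, 0L, 0L)))
  em0 <- effect_model("qt", snp = snp)
  expect_equal(genotype_value(pop, em0), c(0, 0, 0))
  em <- effect_model("qt", "2L", 100L, "T", a = 1, d = 0, snp = snp)
  expect_equal(genotype_value(pop, em), c(-1, 0, 1))
  emd <- effect_model("qt", "2L", 100L, "T", a = 1, d = 0.3, snp = snp)
  expect_equal(genotype_value(pop, emd), c(-1, 0.3, 1))
})

test_that("founder genetic variance matches 2 p q a^2 summed over QTLs", {
  # 10 unlinked QTLs, a = 1, p = 0.5: V_G = 10 * 2 * 0.25 = 5
  set.seed(13)
  L <- 10L
  n <- 4000L
  snp <- snp_table(paste0("c", 1:L), rep(1L, L), rep("A", L), rep("T", L))
  H <- matrix(rbinom(2L * n * L, 1, 0.5), 2L * n, L)
  pop <- new_population(snp, H, ploidy = 2L)
  em <- effect_model("qt", snp$chrom, snp$pos, snp$der, a = 1, d = 0, snp = snp)
  vg <- var(genotype_value(pop, em))
  expect_lt(abs(vg - 5), 5 * sqrt(2 / n) * 3)
})

test_that("environmental variance realises the target heritability", {
  expect_equal(environmental_variance(1, 3), 0)
  expect_equal(environmental_variance(0.5, 2), 2)  # h2 = VG/(VG+VE)
  expect_error(environmental_variance(0, 1), "h2")
  expect_error(environmental_variance(1.2, 1), "h2")
  set.seed(4)
  g <- rnorm(5000, 0, sqrt(2))
  z <- phenotype_values(g, environmental_variance(0.5, 2))
  fit <- lm(z ~ g)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  expect_equal(summary(fit)$r.squared, 0.5, tolerance = 0.05)
})

test_that("phenotype noise has the configured variance and zero mean", {
  g <- rep(2, 1e5)
  expect_identical(phenotype_values(g, 0), g)
  set.seed(6)
  z <- phenotype_values(g, 1.5)
  expect_lt(abs(var(z - g) - 1.5), 3 * 1.5 * sqrt(2 / 1e5))
  expect_lt(abs(mean(z) - 2), 3 * sqrt(1.5 / 1e5))
})

test_that("fitness functions have their defining shapes", {
  gauss <- fitness_function_spec("gaussian_stabilizing", optimum = 2, sigma = 1)
  expect_equal(apply_fitness_function(2, gauss), 1)
  expect_equal(apply_fitness_function(2 + 0.7, gauss),
               apply_fitness_function(2 - 0.7, gauss))
  expect_true(all(diff(apply_fitness_function(seq(2, 5, 0.1), gauss)) < 0))

  dirn <- fitness_function_spec("directional_linear", slope = 0.5, z_ref = 0)
  expect_equal(apply_fitness_function(c(-10, 0, 2), dirn), c(0, 1, 2))

  disr <- fitness_function_spec("disruptive", optimum = 0, sigma = 1, cap = 3)
  w <- apply_fitness_function(c(-5, 0, 5), disr)
  expect_equal(w, c(4, 1, 4))  # capped and symmetric

  dr <- fitness_function_spec("diminishing_returns", w_max = 1, lambda = 0.5,
                              z0 = 0, w_base = 0.01)
  grid <- apply_fitness_function(seq(0, 6, 0.5), dr)
  expect_true(all(diff(grid) > 0))          # increasing
  expect_true(all(diff(diff(grid)) < 0))    # concave: shrinking increments

  mov <- fitness_function_spec("moving_optimum", sigma = 1,
                               schedule = data.frame(generation = c(0, 10),
                                                     optimum = c(0, 2)))
  expect_equal(apply_fitness_function(1, mov, generation = 5), 1)  # opt = 1
  expect_equal(apply_fitness_function(2, mov, generation = 50), 1) # clamped
  expect_error(fitness_function_spec("moving_optimum"), "schedule")
})

test_that("truncation keeps the extreme tail with stable ties and half-up rounding", {
  expect_identical(truncate_select(1:10, 1), 1:10)
  expect_identical(truncate_select(1:10, 0.8, "high"), 3:10)
  expect_identical(truncate_select(1:10, 0.8, "low"), 1:8)
  expect_identical(truncate_select(1:10, 0.25), 8:10)  # round(2.5) -> 3 survivors
  expect_identical(truncate_select(rep(1, 6), 0.5), 1:3)  # stable ties
  expect_identical(truncate_select(c(5, 1, 5, 5, 2), 0.4, "high"), c(1L, 3L))
  expect_error(truncate_select(1:10, 0), "survive_fraction")
  expect_error(truncate_select(1:10, 1.2), "survive_fraction")
})
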