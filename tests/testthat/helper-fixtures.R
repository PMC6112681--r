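# Shared in-code fixtures and independent brute-force oracles.

# A tiny two-chromosome SNP table.
toy_snp <- function() {
  snp_table(chrom = c("2L", "2L", "2L", "X", "X"),
            pos = c(100L, 500L, 900L, 200L, 800L),
            anc = c("A", "C", "G", "T", "A"),
            der = c("T", "G", "A", "C", "G"))
}

# Diploid population with explicit haplotype rows.
toy_population <- function(rows, sex = NULL, hemi = NULL) {
  H <- do.call(rbind, rows)
  new_population(toy_snp(), H, sex = sex, ploidy = 2L, hemi = hemi)
}

random_population <- function(n_ind, L = 8L, p = 0.5, ploidy = 2L) {
  snp <- snp_table(rep("1", L), seq_len(L) * 10L, rep("A", L), rep("T", L))
  H <- matrix(rbinom(ploidy * n_ind * L, 1L, p), ploidy * n_ind, L)
  new_population(snp, H, ploidy = ploidy)
}

# Independent gamete oracle: walk each chromosome left to right,
# switching template after every crossover position.
brute_force_gamete <- function(snp, g1, g2, plan) {
  gam <- integer(nrow(snp))
  for (j in seq_len(nrow(snp))) {
    ch <- snp$chrom[j]
    tmpl <- plan$assortment[[ch]]
    for (x in plan$crossovers[[ch]]) {
      if (snp$pos[j] > x) tmpl <- 3L - tmpl  # p <= c stays on left template
    }
    gam[j] <- if (tmpl == 1L) g1[j] else g2[j]
  }
  gam
}

# Exhaustive Wright-Fisher path enumeration for tiny N: probability of
# each copy count after t generations, summing over all intermediate
# states explicitly (independent of the matrix-power implementation).
brute_force_drift <- function(N, p0, t) {
  two_n <- 2L * N
  states <- 0:two_n
  prob <- numeric(two_n + 1L)
  prob[round(two_n * p0) + 1L] <- 1
  for (gen in seq_len(t)) {
    nxt <- numeric(two_n + 1L)
    for (j in states) {
      if (prob[j + 1L] == 0) next
      for (k in states) {
        nxt[k + 1L] <- nxt[k + 1L] +
          prob[j + 1L] * dbinom(k, two_n, j / two_n)
      }
    }
    prob <- nxt
  }
  prob
}

write_toy_haplotype_file <- function(path, lines) {
  writeLines(lines, path)
  path
}
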