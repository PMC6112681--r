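#' SNP table: ordered biallelic loci
#'
#' A `snp_table` holds the loci simulated by the engine: chromosome,
#' 1-based position and the two segregating nucleotides at each site.
#' Bit 0 in the haplotype matrix encodes the ancestral (reference/major)
#' allele, bit 1 the derived allele.  Only biallelic SNPs are
#' representable; positions must be strictly increasing within a
#' chromosome.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param anc,der single nucleotides in `A`, `C`, `G`, `T`; the allele
#'   encoded as bit 0 resp. bit 1.  `anc == der` is allowed nowhere.
#' @return A data frame of class `snp_table` with columns `chrom`, `pos`,
#'   `anc`, `der`.
#' @examples
#' snp_table(c("2L", "2L"), c(100L, 200L), c("A", "C"), c("T", "G"))
#' @export
snp_table <- function(chrom, pos, anc, der) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  anc <- toupper(as.character(anc))
  der <- toupper(as.character(der))
  n <- length(chrom)
  if (length(pos) != n || length(anc) != n || length(der) != n) {
    stop("chrom, pos, anc, der must have equal length")
  }
  if (n > 0) {
    if (anyNA(pos) || any(pos < 1L)) stop("positions must be positive integers")
    bad <- !(anc %in% NUCLEOTIDES) | !(der %in% NUCLEOTIDES)
    if (any(bad)) stop("alleles must be one of A, C, G, T")
    if (any(anc == der)) stop("ancestral and derived allele identical at some locus")
    for (ch in unique(chrom)) {
      p <- pos[chrom == ch]
      if (any(diff(p) <= 0)) {
        stop("positions not strictly increasing on chromosome ", ch)
      }
    }
  }
  out <- data.frame(chrom = chrom, pos = pos, anc = anc, der = der,
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_table", "data.frame")
  out
}

NUCLEOTIDES <- c("A", "C", "G", "T")

#' @export
print.snp_table <- function(x, ...) {
  cat("<snp_table> ", nrow(x), " loci on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  NextMethod()
}

n_loci <- function(snp) nrow(snp)

#' Locate loci in a SNP table
#'
#' @param snp a [snp_table()].
#' @param chrom,pos vectors identifying loci by chromosome and position.
#' @return Integer column indices; an error if any locus is absent.
#' @export
locus_index <- function(snp, chrom, pos) {
  key <- paste(snp$chrom, snp$pos)
  idx <- match(paste(as.character(chrom), as.integer(pos)), key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("locus ", chrom[miss], ":", pos[miss], " not present in SNP table")
  }
  idx
}

#' Convert a nucleotide haplotype matrix to bits and back
#'
#' Haplotypes enter as nucleotides; the simulator works on a `{0,1}`
#' matrix (rows = haplotypes, columns = loci in `snp_table` order) where
#' the table's `anc` allele maps to 0 and `der` to 1, independent of the
#' order haplotypes appear in.
#'
#' @param snp a [snp_table()].
#' @param nuc character matrix of single nucleotides, one column per locus.
#' @return `nuc_to_bits()`: an integer 0/1 matrix; `bits_to_nuc()`: the
#'   nucleotide matrix.
#' @export
nuc_to_bits <- function(snp, nuc) {
  nuc <- as.matrix(nuc)
  if (ncol(nuc) != nrow(snp)) stop("one column per locus required")
  bits <- matrix(NA_integer_, nrow(nuc), ncol(nuc))
  for (j in seq_len(ncol(nuc))) {
    col <- toupper(nuc[, j])
    b <- ifelse(col == snp$der[j], 1L, ifelse(col == snp$anc[j], 0L, NA_integer_))
    if (anyNA(b)) {
      stop("allele not in {", snp$anc[j], ",", snp$der[j], "} at locus ",
           snp$chrom[j], ":", snp$pos[j])
    }
    bits[, j] <- b
  }
  bits
}

#' @rdname nuc_to_bits
#' @param bits integer 0/1 matrix, one column per locus.
#' @export
bits_to_nuc <- function(snp, bits) {
  bits <- as.matrix(bits)
  if (ncol(bits) != nrow(snp)) stop("one column per locus required")
  nuc <- matrix("", nrow(bits), ncol(bits))
  for (j in seq_len(ncol(bits))) {
    nuc[, j] <- ifelse(bits[, j] == 1L, snp$der[j], snp$anc[j])
  }
  nuc
}

validate_pool <- function(snp, bits) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (ncol(bits) != nrow(snp)) {
    stop("haplotype matrix has ", ncol(bits), " columns but SNP table has ",
         nrow(snp), " loci")
  }
  if (nrow(bits) > 0 && !all(bits %in% c(0L, 1L))) stop("haplotype bits must be 0 or 1")
  bits
}

#' Construct a population of individuals
#'
#' A population couples a [snp_table()] with a bit matrix of phased
#' haplotypes.  Diploid individual `i` owns rows `2i-1` (maternal) and
#' `2i` (paternal); haploid/clonal individual `i` owns row `i`.  On a
#' hemizygous chromosome (`hemi`, e.g. the X) a male carries a single
#' haplotype; internally his second row mirrors the first on those
#' columns so the matrix stays rectangular, and all dose/count accessors
#' count that copy once.
#'
#' @param snp a [snp_table()].
#' @param haplo integer 0/1 matrix; `ploidy * N` rows.
#' @param sex character vector, one of `"F"`, `"M"`, `"H"` per individual.
#'   Defaults to all-hermaphrodite.
#' @param ploidy 1 (haploid/clonal) or 2 (diploid).
#' @param hemi name of the hemizygous chromosome (males carry one copy),
#'   or `NULL` for none.  Requires diploids with sexes `F`/`M`.
#' @param generation,replicate_id bookkeeping labels.
#' @return An object of class `sim_population`.
#' @export
new_population <- function(snp, haplo, sex = NULL, ploidy = 2L, hemi = NULL,
                           generation = 0L, replicate_id = 1L) {
  haplo <- validate_pool(snp, haplo)
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  if (nrow(haplo) %% ploidy != 0L) stop("row count not a multiple of ploidy")
  n <- nrow(haplo) %/% ploidy
  if (is.null(sex)) sex <- rep("H", n)
  sex <- as.character(sex)
  if (length(sex) != n) stop("one sex label per individual required")
  if (!all(sex %in% c("F", "M", "H"))) stop("sex must be F, M or H")
  if (!is.null(hemi)) {
    if (ploidy != 2L) stop("hemizygosity requires diploids")
    if (any(sex == "H")) stop("hemizygosity requires F/M sexes")
    if (!hemi %in% snp$chrom && nrow(snp) > 0) {
      stop("hemizygous chromosome ", hemi, " not in SNP table")
    }
    xcols <- which(snp$chrom == hemi)
    males <- which(sex == "M")
    if (length(males) && length(xcols)) {
      haplo[2L * males, xcols] <- haplo[2L * males - 1L, xcols, drop = FALSE]
    }
  }
  structure(
    list(snp = snp, haplo = haplo, sex = sex, ploidy = ploidy, hemi = hemi,
         phenotype = NULL, fitness = rep(1, n),
         generation = as.integer(generation),
         replicate_id = as.integer(replicate_id)),
    class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population> N =", pop_size(x), "| ploidy", x$ploidy,
      "|", nrow(x$snp), "loci | generation", x$generation, "\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a [new_population()] object.
#' @export
pop_size <- function(pop) nrow(pop$haplo) %/% pop$ploidy

hemi_cols <- function(pop) {
  if (is.null(pop$hemi)) integer(0) else which(pop$snp$chrom == pop$hemi)
}

#' Derived-allele dose of one individual at one locus
#'
#' Returns the number of derived-allele copies carried: 0/1/2 for a
#' diploid autosomal locus, 0/1 for haploids and for males at loci on the
#' hemizygous chromosome.
#'
#' @param pop a population.
#' @param individual individual index (1-based).
#' @param locus locus column index (1-based).
#' @export
genotype_at <- function(pop, individual, locus) {
  if (locus < 1L || locus > nrow(pop$snp)) stop("invalid locus index")
  if (individual < 1L || individual > pop_size(pop)) stop("invalid individual index")
  if (pop$ploidy == 1L) return(pop$haplo[individual, locus])
  r1 <- 2L * individual - 1L
  hemi_male <- !is.null(pop$hemi) && pop$sex[individual] == "M" &&
    pop$snp$chrom[locus] == pop$hemi
  if (hemi_male) pop$haplo[r1, locus] else pop$haplo[r1, locus] + pop$haplo[r1 + 1L, locus]
}

#' Derived-allele dose matrix (individuals x loci)
#'
#' Hemizygous male loci appear with dose 0/1.
#'
#' @param pop a population.
#' @param loci optional column indices (default all).
#' @return Integer matrix, `pop_size(pop)` rows.
#' @export
dose_matrix <- function(pop, loci = NULL) {
  if (is.null(loci)) loci <- seq_len(nrow(pop$snp))
  H <- pop$haplo[, loci, drop = FALSE]
  if (pop$ploidy == 1L) return(H)
  n <- pop_size(pop)
  D <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  if (!is.null(pop$hemi)) {
    xc <- which(pop$snp$chrom[loci] == pop$hemi)
    males <- which(pop$sex == "M")
    if (length(xc) && length(males)) {
      # male rows are duplicated on hemizygous columns; halve to the true dose
      D[males, xc] <- D[males, xc, drop = FALSE] %/% 2L
    }
  }
  D
}

#' Allele counts and frequencies
#'
#' `allele_counts()` returns, per locus, the number of derived-allele
#' copies and the total number of allele copies in the population
#' (hemizygous male loci contribute a single copy).
#' `allele_frequency()` is the derived count divided by the total.
#'
#' @param pop a population.
#' @param locus for `allele_frequency()`, optional locus indices (default
#'   all loci).
#' @return `allele_counts()`: list with integer vectors `derived` and
#'   `total`; `allele_frequency()`: numeric vector of frequencies in
#'   `[0, 1]`.
#' @export
allele_counts <- function(pop) {
  if (pop_size(pop) == 0L) stop("empty population")
  D <- dose_matrix(pop)
  derived <- as.integer(colSums(D))
  total <- rep.int(pop$ploidy * pop_size(pop), nrow(pop$snp))
  if (!is.null(pop$hemi)) {
    xc <- hemi_cols(pop)
    total[xc] <- total[xc] - sum(pop$sex == "M")
  }
  list(derived = derived, total = as.integer(total))
}

#' @rdname allele_counts
#' @export
allele_frequency <- function(pop, locus = NULL) {
  ac <- allele_counts(pop)
  f <- ac$derived / ac$total
  if (is.null(locus)) f else f[locus]
}

#' Phased haplotype copies at selected loci
#'
#' Returns one row per transmitted allele copy: both rows per diploid
#' individual, except that a hemizygous male contributes a single row
#' when all requested loci lie on the hemizygous chromosome.  Mixing
#' hemizygous and autosomal loci in one call is refused since copy
#' numbers differ.
#'
#' @param pop a population.
#' @param loci locus column indices.
#' @return Integer 0/1 matrix with one column per requested locus.
#' @export
haplotype_copies <- function(pop, loci) {
  on_hemi <- !is.null(pop$hemi) & pop$snp$chrom[loci] == pop$hemi
  if (any(on_hemi) && !all(on_hemi)) {
    stop("cannot mix hemizygous and autosomal loci in one copy matrix")
  }
  H <- pop$haplo[, loci, drop = FALSE]
  if (pop$ploidy == 2L && all(on_hemi) && length(loci)) {
    drop_rows <- 2L * which(pop$sex == "M")
    if (length(drop_rows)) H <- H[-drop_rows, , drop = FALSE]
  }
  H
}
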