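#' Read founder haplotypes from a tabular nucleotide file
#'
#' The haplotype dialect is tab-separated with no header: chromosome,
#' 1-based position, allele column, then one genotype field per
#' individual.  A genotype field holds two nucleotide characters for a
#' diploid (maternal then paternal haplotype) or one for a haploid.  The
#' allele column is either a single nucleotide (the ancestral allele;
#' the derived allele is inferred from the genotypes) or `anc/der`
#' naming both explicitly — the latter is what [write_haplotypes()]
#' emits and is required to represent monomorphic loci kept as de novo
#' mutation targets.  Lines starting with `#` are ignored.
#'
#' Loci with more than two distinct observed nucleotides are rejected:
#' the bit encoding is defined for biallelic SNPs only.
#'
#' @param path file path.
#' @return A list with elements `snp` (a [snp_table()]), `haplo`
#'   (integer 0/1 matrix, rows = haplotypes) and `ploidy`.
#' @export
read_haplotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("no loci in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) stop("ragged rows in ", path)
  if (nf[1] < 4L) stop("expected at least one genotype column in ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos)) stop("non-integer position in ", path)
  allele_col <- toupper(vapply(fields, `[[`, "", 3L))
  geno <- t(vapply(fields, function(f) toupper(f[-(1:3)]), character(nf[1] - 3L)))
  if (nf[1] == 4L) geno <- matrix(toupper(vapply(fields, `[[`, "", 4L)), ncol = 1L)

  widths <- unique(as.vector(nchar(geno)))
  if (length(widths) != 1L || !widths %in% c(1L, 2L)) {
    stop("genotype fields must be uniformly 1 (haploid) or 2 (diploid) characters")
  }
  ploidy <- widths

  n_ind <- ncol(geno)
  L <- length(chrom)
  nuc <- matrix("", nrow = ploidy * n_ind, ncol = L)
  for (i in seq_len(n_ind)) {
    if (ploidy == 2L) {
      nuc[2L * i - 1L, ] <- substr(geno[, i], 1L, 1L)
      nuc[2L * i, ] <- substr(geno[, i], 2L, 2L)
    } else {
      nuc[i, ] <- geno[, i]
    }
  }
  if (!all(nuc %in% NUCLEOTIDES)) stop("characters outside {A,C,G,T} in ", path)

  anc <- character(L)
  der <- character(L)
  has_der <- grepl("/", allele_col, fixed = TRUE)
  for (j in seq_len(L)) {
    if (has_der[j]) {
      parts <- strsplit(allele_col[j], "/", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("malformed allele column at row ", j)
      anc[j] <- parts[1]; der[j] <- parts[2]
    } else {
      anc[j] <- allele_col[j]
      der[j] <- ""
    }
    obs <- unique(nuc[, j])
    extra <- setdiff(obs, c(anc[j], if (nzchar(der[j])) der[j]))
    if (nzchar(der[j])) {
      if (length(extra)) {
        stop("non-biallelic locus ", chrom[j], ":", pos[j],
             " (alleles beyond ", anc[j], "/", der[j], ")")
      }
    } else {
      if (length(extra) > 1L) {
        stop("non-biallelic locus ", chrom[j], ":", pos[j])
      }
      # monomorphic-ancestral locus: pick a deterministic placeholder
      der[j] <- if (length(extra)) extra else setdiff(NUCLEOTIDES, anc[j])[1]
    }
  }
  snp <- snp_table(chrom, pos, anc, der)
  bits <- nuc_to_bits(snp, nuc)
  list(snp = snp, haplo = bits, ploidy = ploidy)
}

#' Write haplotypes as nucleotides
#'
#' The tabular dialect is the inverse of [read_haplotypes()] (allele
#' column always written as `anc/der`).  The FASTA dialect emits one
#' record per haplotype row whose sequence is the nucleotide at each SNP
#' column in order.
#'
#' @param path output file path.
#' @param pop a [new_population()] object, or a list with `snp`, `haplo`
#'   and `ploidy` as returned by [read_haplotypes()].
#' @param format `"tabular"` or `"fasta"`.
#' @export
write_haplotypes <- function(path, pop, format = c("tabular", "fasta")) {
  format <- match.arg(format)
  snp <- pop$snp
  H <- pop$haplo
  ploidy <- pop$ploidy
  nuc <- bits_to_nuc(snp, H)
  if (format == "fasta") {
    seqs <- apply(nuc, 1L, paste0, collapse = "")
    out <- character(2L * length(seqs))
    out[c(TRUE, FALSE)] <- sprintf(">hap_%d", seq_along(seqs))
    out[c(FALSE, TRUE)] <- seqs
    writeLines(out, path)
    return(invisible(path))
  }
  n_ind <- nrow(H) %/% ploidy
  geno <- matrix("", nrow = ncol(H), ncol = n_ind)
  for (i in seq_len(n_ind)) {
    if (ploidy == 2L) {
      geno[, i] <- paste0(nuc[2L * i - 1L, ], nuc[2L * i, ])
    } else {
      geno[, i] <- nuc[i, ]
    }
  }
  rows <- paste(snp$chrom, snp$pos, paste0(snp$anc, "/", snp$der),
                apply(geno, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Read a windowed recombination map
#'
#' Tab-separated, no header: chromosome, window start, window end
#' (1-based, inclusive), rate in centiMorgans spanned by the window, and
#' optionally a second rate column for males (e.g. all zeros for
#' Drosophila, where males do not recombine).  With four columns the
#' single rate applies to both sexes.  Windows must not overlap within a
#' chromosome; each window's implied recombination fraction `cM/100`
#' must stay below 0.5, the supremum of Haldane's mapping function.
#' Loci outside every window recombine at rate 0.
#'
#' @param path file path.
#' @return A data frame of class `recomb_map` with columns `chrom`,
#'   `start`, `end`, `rate_female`, `rate_male` (cM).
#' @export
read_recombination_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(recomb_map(character(0), integer(0), integer(0), numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- unique(lengths(fields))
  if (length(nf) != 1L || !nf %in% c(4L, 5L)) {
    stop("recombination map needs 4 or 5 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  rate_f <- as.numeric(vapply(fields, `[[`, "", 4L))
  rate_m <- if (nf == 5L) as.numeric(vapply(fields, `[[`, "", 5L)) else rate_f
  recomb_map(chrom, start, end, rate_f, rate_m)
}

#' Construct a recombination map in code
#'
#' @param chrom,start,end window coordinates (1-based, inclusive).
#' @param rate_female,rate_male window width in centiMorgans per sex;
#'   `rate_male` defaults to the female rate.
#' @return A `recomb_map` data frame; see [read_recombination_map()].
#' @export
recomb_map <- function(chrom, start, end, rate_female, rate_male = rate_female) {
  m <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), rate_female = as.numeric(rate_female),
                  rate_male = as.numeric(rate_male), stringsAsFactors = FALSE)
  if (nrow(m)) {
    if (any(m$end < m$start)) stop("window end before start")
    if (any(m$rate_female < 0 | m$rate_male < 0)) stop("negative recombination rate")
    if (any(m$rate_female / 100 >= 0.5 | m$rate_male / 100 >= 0.5)) {
      stop("window recombination fraction must be < 0.5 (split the window)")
    }
    for (ch in unique(m$chrom)) {
      w <- m[m$chrom == ch, ]
      w <- w[order(w$start), ]
      if (nrow(w) > 1L && any(w$start[-1] <= w$end[-nrow(w)])) {
        stop("overlapping recombination windows on chromosome ", ch)
      }
    }
    m <- m[order(m$chrom, m$start), ]
    rownames(m) <- NULL
  }
  class(m) <- c("recomb_map", "data.frame")
  m
}

map_for_sex <- function(map, sex) {
  rate <- if (identical(sex, "M")) map$rate_male else map$rate_female
  data.frame(chrom = map$chrom, start = map$start, end = map$end,
             rate = rate, stringsAsFactors = FALSE)
}

#' Read per-SNP selection or effect-size files
#'
#' Tab-separated, no header.  In `w` mode the columns are chromosome,
#' position, selected allele, selection coefficient `s` and dominance
#' `h` (genotype fitnesses 1, 1+hs, 1+s for 0/1/2 copies of the selected
#' allele).  In `qt`/`qff` mode they are chromosome, position, selected
#' allele, additive effect `a` (half the difference between the two
#' homozygotes, trait units) and optionally a dominance effect `d`
#' (default 0, i.e. codominance).  Every locus must exist in `snp` and
#' the selected allele must be one of its two alleles.  An empty file is
#' a neutral run.
#'
#' @param path file path.
#' @param mode `"w"`, `"qt"` or `"qff"`.
#' @param snp the [snp_table()] the effects refer to.
#' @return An object of class `effect_model`; see [effect_model()].
#' @export
read_effects <- function(path, mode = c("w", "qt", "qff"), snp) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(effect_model(mode, snp = snp))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- unique(lengths(fields))
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  allele <- toupper(vapply(fields, `[[`, "", 3L))
  if (mode == "w") {
    if (length(nf) != 1L || nf != 5L) stop("w-mode effect rows need 5 columns")
    effect_model("w", chrom = chrom, pos = pos, allele = allele,
                 s = as.numeric(vapply(fields, `[[`, "", 4L)),
                 h = as.numeric(vapply(fields, `[[`, "", 5L)),
                 snp = snp)
  } else {
    if (length(nf) != 1L || !nf %in% c(4L, 5L)) {
      stop("qt/qff effect rows need 4 or 5 columns")
    }
    d <- if (nf == 5L) as.numeric(vapply(fields, `[[`, "", 5L)) else 0
    effect_model(mode, chrom = chrom, pos = pos, allele = allele,
                 a = as.numeric(vapply(fields, `[[`, "", 4L)), d = d,
                 snp = snp)
  }
}

#' Read pairwise epistasis fitness tables
#'
#' Each tab-separated record names two loci (`chromA posA chromB posB`)
#' followed by 9 fitness values for diploids — the 3x3 grid over
#' derived-allele doses, row-major in locus-A dose 0,1,2 by locus-B dose
#' 0,1,2 — or 4 values (2x2) for haploids.  Fitness values must be
#' non-negative.
#'
#' @param path file path.
#' @param snp the [snp_table()] the loci refer to.
#' @param ploidy 1 or 2.
#' @return A list of `list(a, b, table)` entries with locus column
#'   indices and a dose-indexed fitness matrix.
#' @export
read_epistasis <- function(path, snp, ploidy = 2L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  k <- if (ploidy == 2L) 3L else 2L
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L + k * k) {
      stop("epistasis record needs 4 locus fields + ", k * k, " fitness values")
    }
    a <- locus_index(snp, f[1], as.integer(f[2]))
    b <- locus_index(snp, f[3], as.integer(f[4]))
    w <- as.numeric(f[-(1:4)])
    if (anyNA(w) || any(w < 0)) stop("epistasis fitness values must be >= 0")
    list(a = a, b = b, table = matrix(w, k, k, byrow = TRUE,
                                      dimnames = list(0:(k - 1), 0:(k - 1))))
  })
}

#' Snapshot of population allele counts
#'
#' @param pop a population.
#' @param coverage optional Pool-Seq sampling depth: if given, the
#'   stored counts are a binomial draw of `coverage` reads per locus at
#'   the population allele frequency instead of exact population counts.
#' @return A `snapshot` list: `generation`, `replicate_id`, `derived`,
#'   `total`.
#' @export
take_snapshot <- function(pop, coverage = NULL) {
  ac <- allele_counts(pop)
  if (!is.null(coverage)) {
    p <- ac$derived / ac$total
    ac$derived <- stats::rbinom(length(p), coverage, p)
    ac$total <- rep.int(as.integer(coverage), length(p))
  }
  structure(list(generation = pop$generation, replicate_id = pop$replicate_id,
                 derived = ac$derived, total = ac$total),
            class = "snapshot")
}

#' Write snapshots in the sync allele-count format
#'
#' One row per locus: chromosome, position, reference (ancestral)
#' allele, then per snapshot a column `A:T:C:G:N:del` of allele copy
#' counts.  Columns are ordered lexicographically by (replicate,
#' generation), documented in a `#` header comment.  The simulator has
#' no missing data, so `N` and `del` are always 0.
#'
#' @param path output file path.
#' @param snapshots list of [take_snapshot()] objects over one SNP table.
#' @param snp the shared [snp_table()].
#' @export
write_sync <- function(path, snapshots, snp) {
  if (!length(snapshots)) stop("no snapshots to write")
  L <- nrow(snp)
  for (s in snapshots) {
    if (length(s$derived) != L) stop("inconsistent loci across snapshots")
  }
  ord <- order(vapply(snapshots, `[[`, 0L, "replicate_id"),
               vapply(snapshots, `[[`, 0L, "generation"))
  snapshots <- snapshots[ord]
  slot <- c(A = 1L, T = 2L, C = 3L, G = 4L)
  cols <- vapply(snapshots, function(s) {
    counts <- matrix(0L, 6L, L)
    counts[cbind(slot[snp$der], seq_len(L))] <- s$derived
    counts[cbind(slot[snp$anc], seq_len(L))] <- s$total - s$derived
    apply(counts, 2L, paste, collapse = ":")
  }, character(L))
  cols <- matrix(cols, nrow = L)
  header <- paste(c("#chrom", "pos", "ref",
                    vapply(snapshots, function(s)
                      sprintf("rep%d.gen%d", s$replicate_id, s$generation), "")),
                  collapse = "\t")
  body <- paste(snp$chrom, snp$pos, snp$anc,
                apply(cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Parse a sync file back into frequencies
#'
#' Convenience reader for round-trips and downstream checks; returns the
#' derived-allele counts of each column keyed by the header labels.
#'
#' @param path sync file written by [write_sync()].
#' @param snp the [snp_table()] used to write it.
#' @return List with `labels`, integer matrices `derived` and `total`
#'   (loci x columns).
#' @export
read_sync <- function(path, snp) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")][1]
  labels <- strsplit(sub("^#", "", header), "\t")[[1]][-(1:3)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  L <- length(fields)
  ncol_sync <- length(fields[[1]]) - 3L
  slot <- c(A = 1L, T = 2L, C = 3L, G = 4L)
  derived <- total <- matrix(0L, L, ncol_sync)
  for (i in seq_len(L)) {
    for (j in seq_len(ncol_sync)) {
      cnt <- as.integer(strsplit(fields[[i]][3L + j], ":", fixed = TRUE)[[1]])
      derived[i, j] <- cnt[slot[snp$der[i]]]
      total[i, j] <- sum(cnt)
    }
  }
  list(labels = labels, derived = derived, total = total)
}

#' Extract phased haplotypes from a VCF file
#'
#' Convenience converter for building founder panels from variant calls:
#' keeps biallelic SNP records with fully phased `GT` fields and returns
#' the same structure as [read_haplotypes()] (REF as ancestral, ALT as
#' derived).  Requires the vcfR package.
#'
#' @param path VCF file path (plain text or gzip).
#' @return A list with `snp`, `haplo`, `ploidy = 2`.
#' @export
haplotypes_from_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("haplotypes_from_vcf() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- fix[, "REF"] %in% NUCLEOTIDES & fix[, "ALT"] %in% NUCLEOTIDES
  phased <- apply(gt, 1L, function(g) all(grepl("^[01]\\|[01]$", g)))
  keep <- keep & phased
  if (!any(keep)) stop("no phased biallelic SNPs in ", path)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  snp <- snp_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                   fix[, "REF"], fix[, "ALT"])
  n_ind <- ncol(gt)
  bits <- matrix(0L, 2L * n_ind, nrow(snp))
  for (i in seq_len(n_ind)) {
    parts <- strsplit(gt[, i], "|", fixed = TRUE)
    bits[2L * i - 1L, ] <- as.integer(vapply(parts, `[[`, "", 1L))
    bits[2L * i, ] <- as.integer(vapply(parts, `[[`, "", 2L))
  }
  list(snp = snp, haplo = bits, ploidy = 2L)
}
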