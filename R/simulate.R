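#' Simulate diverged populations under the Balding-Nichols model
#'
#' Each marker draws an ancestral B-allele frequency p uniformly on
#' `ancestral_freq_range`; each population then draws its own frequency from
#' Beta(p(1-theta)/theta, (1-p)(1-theta)/theta), which has mean p and
#' variance theta * p(1-p). Genotypes are Binomial(2, population frequency),
#' so the expected Weir-Cockerham F_ST between any two populations equals
#' `theta` — a clean parameter-recovery target for the estimator. Markers
#' are statistically independent (no linkage) and placed on a synthetic
#' equally spaced map.
#'
#' @param n_populations number of populations.
#' @param n_per_population diploid samples per population.
#' @param n_markers number of markers.
#' @param theta divergence parameter in (0, 1); equals the expected F_ST.
#' @param ancestral_freq_range interval within (0, 1) for ancestral
#'   frequencies; the default (0.1, 0.9) avoids boundary monomorphism.
#' @param n_chromosomes number of chromosomes markers are spread over.
#' @param marker_spacing base pairs between adjacent markers.
#' @param seed integer seed; the output is bit-reproducible given the
#'   arguments and the seed.
#' @return A [genotype_dataset] with group labels `pop1 ... popK`.
#' @export
simulate_divergent_populations <- function(n_populations = 2,
                                           n_per_population = 100,
                                           n_markers = 1000,
                                           theta = 0.1,
                                           ancestral_freq_range = c(0.1, 0.9),
                                           n_chromosomes = 1,
                                           marker_spacing = 55000,
                                           seed = 1) {
  if (theta <= 0 || theta >= 1) stop("theta must lie strictly in (0, 1)")
  stopifnot(n_populations >= 1, n_per_population >= 1, n_markers >= 1,
            n_chromosomes >= 1)
  set.seed(as.integer(seed))
  p_anc <- stats::runif(n_markers, ancestral_freq_range[1],
                        ancestral_freq_range[2])
  shape_scale <- (1 - theta) / theta
  n_total <- n_populations * n_per_population
  dos <- matrix(NA_real_, n_total, n_markers)
  for (k in seq_len(n_populations)) {
    p_pop <- stats::rbeta(n_markers, p_anc * shape_scale,
                          (1 - p_anc) * shape_scale)
    rows <- (k - 1) * n_per_population + seq_len(n_per_population)
    dos[rows, ] <- matrix(
      stats::rbinom(n_per_population * n_markers, 2,
                    rep(p_pop, each = n_per_population)),
      n_per_population, n_markers)
  }
  markers <- synthetic_map(n_markers, n_chromosomes, marker_spacing)
  samples <- data.frame(
    id = sprintf("s%05d", seq_len(n_total)),
    group = rep(paste0("pop", seq_len(n_populations)),
                each = n_per_population),
    stringsAsFactors = FALSE)
  genotype_dataset(dos, markers, samples)
}

# Equally spaced synthetic map: n markers over n_chromosomes (as even as
# possible), positions spacing, 2*spacing, ... within each chromosome.
synthetic_map <- function(n_markers, n_chromosomes, spacing) {
  per <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  chrom <- rep(paste0("chr", seq_len(n_chromosomes)), per)
  pos <- unlist(lapply(per, function(m) spacing * seq_len(m)), use.names = FALSE)
  data.frame(id = sprintf("m%06d", seq_len(n_markers)),
             chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Simulates a closed random-mating diploid population of constant census
#' size N (equal to the effective size by construction: no selection, no
#' sex structure, non-overlapping generations). Founder haplotypes carry
#' independent alleles at frequency 0.5 per locus. Each generation every
#' offspring draws two parents uniformly with replacement and receives one
#' recombinant gamete from each; a crossover falls in each adjacent marker
#' interval with probability `marker_spacing * morgan_per_bp` (an adequate
#' small-distance approximation of Haldane's map at typical SNP-chip
#' spacings), and chromosomes segregate independently. Mutation is ignored:
#' over the few hundred generations relevant to LD-based Ne recovery, drift
#' and recombination dominate, and starting at p = 0.5 keeps most loci
#' polymorphic.
#'
#' The returned dosages are unphased; the phased haplotypes of the sampled
#' individuals are retained in `attr(, "haplotypes")` (a 2N x L 0/1 matrix,
#' rows 2i-1 and 2i belonging to individual i) so haplotype-level LD can be
#' computed as an oracle. Loci monomorphic at output are flagged in
#' `attr(, "monomorphic")`.
#'
#' @param diploid_size census (= effective) population size N.
#' @param n_chromosomes number of independently segregating chromosomes.
#' @param markers_per_chromosome loci per chromosome.
#' @param marker_spacing base pairs between adjacent loci.
#' @param n_generations generations of random mating after the founders.
#' @param morgan_per_bp map scale; the default 1e-8 corresponds to
#'   1 Morgan = 100 Mb.
#' @param n_sample diploid individuals sampled (without replacement) at the
#'   end; default all N.
#' @param seed integer seed.
#' @return A [genotype_dataset] (group label `"wf"`) with attributes
#'   `haplotypes` and `monomorphic`.
#' @export
simulate_wright_fisher <- function(diploid_size = 100,
                                   n_chromosomes = 2,
                                   markers_per_chromosome = 500,
                                   marker_spacing = 50000,
                                   n_generations = 200,
                                   morgan_per_bp = 1e-8,
                                   n_sample = NULL,
                                   seed = 1) {
  stopifnot(diploid_size >= 2, n_chromosomes >= 1,
            markers_per_chromosome >= 1, marker_spacing > 0,
            n_generations >= 0, morgan_per_bp >= 0)
  if (is.null(n_sample)) n_sample <- diploid_size
  if (n_sample > diploid_size)
    stop("cannot sample more individuals than the population holds")
  set.seed(as.integer(seed))
  N <- diploid_size
  L <- n_chromosomes * markers_per_chromosome
  r <- min(0.5, marker_spacing * morgan_per_bp)

  # two haplotype matrices: hapA[i, ] and hapB[i, ] are individual i's gametes
  hapA <- matrix(stats::rbinom(N * L, 1, 0.5), N, L)
  hapB <- matrix(stats::rbinom(N * L, 1, 0.5), N, L)

  for (g in seq_len(n_generations)) {
    pa <- sample.int(N, N, replace = TRUE)
    pb <- sample.int(N, N, replace = TRUE)
    newA <- recombine_gametes(hapA, hapB, pa, n_chromosomes,
                              markers_per_chromosome, r)
    newB <- recombine_gametes(hapA, hapB, pb, n_chromosomes,
                              markers_per_chromosome, r)
    hapA <- newA
    hapB <- newB
  }

  keep <- if (n_sample == N) seq_len(N) else sort(sample.int(N, n_sample))
  hapA <- hapA[keep, , drop = FALSE]
  hapB <- hapB[keep, , drop = FALSE]
  dos <- hapA + hapB
  hap_freq <- (colSums(hapA) + colSums(hapB)) / (2 * n_sample)
  mono <- hap_freq == 0 | hap_freq == 1
  if (all(mono))
    stop("all loci monomorphic at output; increase diploid_size or reduce ",
         "n_generations")
  markers <- synthetic_map(L, n_chromosomes, marker_spacing)
  samples <- data.frame(id = sprintf("wf%04d", seq_len(n_sample)),
                        group = "wf", stringsAsFactors = FALSE)
  out <- genotype_dataset(dos, markers, samples)
  haps <- matrix(0L, 2 * n_sample, L)
  haps[seq(1, 2 * n_sample, 2), ] <- hapA
  haps[seq(2, 2 * n_sample, 2), ] <- hapB
  attr(out, "haplotypes") <- haps
  attr(out, "monomorphic") <- as.vector(mono)
  out
}

# One recombinant gamete per row: parent[i] contributes a mosaic of its two
# haplotypes, switching between them with probability r per adjacent
# interval; each chromosome restarts with a fresh coin flip.
recombine_gametes <- function(hapA, hapB, parent, n_chrom, m_per_chrom, r) {
  n <- length(parent)
  L <- n_chrom * m_per_chrom
  mask <- matrix(0L, n, L)
  for (ch in seq_len(n_chrom)) {
    cols <- (ch - 1) * m_per_chrom + seq_len(m_per_chrom)
    start <- stats::rbinom(n, 1, 0.5)
    if (m_per_chrom > 1) {
      x <- matrix(stats::rbinom(n * (m_per_chrom - 1), 1, r),
                  n, m_per_chrom - 1)
      # cumulative crossovers mod 2 give the source haplotype per locus
      cum <- matrixRowCumsum(x)
      mask[, cols] <- (start + cbind(0L, cum)) %% 2L
    } else {
      mask[, cols] <- start
    }
  }
  A <- hapA[parent, , drop = FALSE]
  B <- hapB[parent, , drop = FALSE]
  A * (1L - mask) + B * mask
}

matrixRowCumsum <- function(x) {
  if (ncol(x) == 0) return(x)
  t(apply(x, 1, cumsum))
}

#' Simulate half-sib families on top of a base population
#'
#' The first `n_sires` base individuals act as sires; each progeny receives
#' one gamete from its sire and one from a dam drawn at random among the
#' remaining base individuals, gametes formed by independent Mendelian
#' sampling per marker (no linkage). Progeny of the same sire are therefore
#' (at least) half sibs with expected additive relationship 0.25 above the
#' base level. The output stacks the base samples (group `"base"`) and the
#' progeny (group `sire<k>`).
#'
#' @param base a [genotype_dataset] with complete dosages (the founders).
#' @param n_sires number of sire families.
#' @param progeny_per_sire progeny per sire.
#' @param seed integer seed.
#' @return A [genotype_dataset] with base and progeny samples.
#' @export
simulate_families <- function(base, n_sires = 5, progeny_per_sire = 10,
                              seed = 1) {
  stopifnot(inherits(base, "genotype_dataset"),
            n_sires >= 1, progeny_per_sire >= 1)
  if (anyNA(base$dosages)) stop("base population must have complete dosages")
  n_base <- nrow(base$dosages)
  if (n_base < n_sires + 1)
    stop("base population too small: need at least ", n_sires + 1,
         " individuals (", n_sires, " sires plus dams), have ", n_base)
  set.seed(as.integer(seed))
  L <- ncol(base$dosages)
  n_prog <- n_sires * progeny_per_sire
  dams_pool <- setdiff(seq_len(n_base), seq_len(n_sires))
  prog <- matrix(NA_real_, n_prog, L)
  fam <- character(n_prog)
  row <- 0
  for (k in seq_len(n_sires)) {
    for (j in seq_len(progeny_per_sire)) {
      row <- row + 1
      dam <- if (length(dams_pool) == 1) dams_pool else sample(dams_pool, 1)
      prog[row, ] <- mendelian_gamete(base$dosages[k, ]) +
        mendelian_gamete(base$dosages[dam, ])
      fam[row] <- paste0("sire", k)
    }
  }
  dos <- rbind(base$dosages, prog)
  samples <- data.frame(
    id = c(base$samples$id, sprintf("prog%05d", seq_len(n_prog))),
    group = c(rep("base", n_base), fam),
    stringsAsFactors = FALSE)
  genotype_dataset(dos, base$markers, samples)
}

# One allele per marker: homozygotes transmit deterministically,
# heterozygotes by a fair coin.
mendelian_gamete <- function(dosage) {
  allele <- as.numeric(dosage >= 1)
  het <- dosage == 1
  allele[het] <- stats::rbinom(sum(het), 1, 0.5)
  allele
}

#' Set genotype cells missing at random
#'
#' Cells are set missing independently; the two rates combine
#' independently, so the per-cell missingness probability is
#' `1 - (1 - marker_rate) * (1 - sample_rate)`. The same (data, rates,
#' seed) triple always yields the same mask.
#'
#' @param data a [genotype_dataset].
#' @param marker_rate per-cell missingness rate, in \[0, 1).
#' @param sample_rate additional independent per-cell rate, in \[0, 1).
#' @param seed integer seed.
#' @return A [genotype_dataset] with injected missing values.
#' @export
inject_missingness <- function(data, marker_rate = 0, sample_rate = 0,
                               seed = 1) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (marker_rate < 0 || marker_rate >= 1 || sample_rate < 0 || sample_rate >= 1)
    stop("rates must lie in [0, 1)")
  rate <- 1 - (1 - marker_rate) * (1 - sample_rate)
  if (rate == 0) return(data)
  set.seed(as.integer(seed))
  dos <- data$dosages
  mask <- stats::runif(length(dos)) < rate
  dos[mask] <- NA_real_
  genotype_dataset(dos, data$markers, data$samples)
}
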