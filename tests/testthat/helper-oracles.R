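# Independent oracles and fixture builders shared across the suite.
# The oracles are deliberately written as plain scalar transcriptions of
# the defining formulas, independent of the vectorised package code paths.

# Straight scalar transcription of the Weir-Cockerham a/b/c components for
# one marker: n, p, h are per-group vectors (sample size, B-allele
# frequency, observed heterozygote proportion).
wc_oracle_one_marker <- function(n, p, h) {
  r <- length(n)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Ratio-of-sums theta over a marker list of (n, p, h) rows.
wc_oracle_theta <- function(n_mat, p_mat, h_mat) {
  comps <- t(vapply(seq_len(nrow(n_mat)), function(i)
    wc_oracle_one_marker(n_mat[i, ], p_mat[i, ], h_mat[i, ]),
    c(a = 0, b = 0, c = 0)))
  keep <- rowSums(abs(comps)) > 0
  sum(comps[keep, "a"]) / sum(comps[keep, ])
}

# Haplotype-frequency definition of r-squared from two 0/1 haplotype
# vectors (one entry per gamete).
hap_r2_oracle <- function(hap_a, hap_b) {
  pA <- mean(hap_a); pB <- mean(hap_b); pAB <- mean(hap_a * hap_b)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Mean silhouette of a one-dimensional embedding with two or more groups.
silhouette_1d <- function(x, grp) {
  mean(vapply(seq_along(x), function(i) {
    own <- abs(x[i] - x[grp == grp[i]])
    a <- sum(own) / (length(own) - 1)
    b <- min(vapply(setdiff(unique(grp), grp[i]),
                    function(g) mean(abs(x[i] - x[grp == g])), 0))
    (b - a) / max(a, b)
  }, 0))
}

# Tiny 3-sample x 4-marker dataset with two chromosomes and two groups.
tiny_dataset <- function() {
  dos <- matrix(c(0, 1, 2,
                  1, 1, 0,
                  2, 0, 1,
                  0, 2, 2), nrow = 3)
  markers <- data.frame(id = c("mA", "mB", "mC", "mD"),
                        chrom = c("1", "1", "2", "2"),
                        pos = c(100, 250, 100, 900),
                        stringsAsFactors = FALSE)
  samples <- data.frame(id = c("s1", "s2", "s3"),
                        group = c("g1", "g1", "g2"),
                        stringsAsFactors = FALSE)
  genotype_dataset(dos, markers, samples)
}

# Hand-buildable decay curve for Ne arithmetic checks.
fake_decay_curve <- function(distance_bp, mean_r2, n_samples = 100) {
  curve <- data.frame(depth = seq_along(distance_bp),
                      distance_bp = distance_bp,
                      mean_r2 = mean_r2,
                      n_pairs = rep(100L, length(distance_bp)))
  attr(curve, "mean_adjacent_spacing") <- distance_bp[1]
  attr(curve, "n_full_depth_markers") <- 1L
  attr(curve, "n_samples") <- n_samples
  class(curve) <- c("ld_decay_curve", "data.frame")
  curve
}
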