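test_that("pairwise r2 reproduces exact and degenerate cases", {
  dup <- genotype_dataset(
    cbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 1, 0, 1)),
    data.frame(id = c("m1", "m2", "m3"), chrom = "1", pos = c(1, 2, 3) * 10),
    data.frame(id = paste0("s", 1:4), group = "g"))
  rec <- pairwise_ld(dup, max_depth = 2)
  # identical dosage vectors -> r2 = 1; perfect negative correlation too
  expect_equal(rec$r2[rec$a == 1 & rec$b == 2], 1)
  expect_equal(rec$r2[rec$a == 2 & rec$b == 3], 1)

  # monomorphic marker: pair skipped and counted
  mono <- genotype_dataset(
    cbind(c(1, 1, 1, 1), c(0, 1, 2, 1)),
    data.frame(id = c("m1", "m2"), chrom = "1", pos = c(1, 2)),
    data.frame(id = paste0("s", 1:4), group = "g"))
  mrec <- pairwise_ld(mono, max_depth = 1)
  expect_equal(nrow(mrec), 0)
  expect_equal(attr(mrec, "n_skipped"), 1)

  # independent loci at large n: r2 at the noise floor, not at zero exactly
  set.seed(5)
  n <- 2000
  ind <- genotype_dataset(
    matrix(rbinom(n * 2, 2, 0.4), n, 2),
    data.frame(id = c("m1", "m2"), chrom = "1", pos = c(1, 2)),
    data.frame(id = sprintf("s%04d", 1:n), group = "g"))
  expect_lt(pairwise_ld(ind, 1)$r2, 10 / n)

  # r2 is symmetric in the pair and invariant to allele relabeling
  flip <- dup; flip$dosages[, 2] <- 2 - flip$dosages[, 2]
  flip <- genotype_dataset(flip$dosages, flip$markers, flip$samples)
  expect_equal(pairwise_ld(flip, 2)$r2, rec$r2, tolerance = 1e-12)
})

test_that("dosage r2 converges to the haplotype-formula oracle", {
  # haplotype counts AB = 40, Ab = 10, aB = 10, ab = 40 (per 100):
  # r2 = (0.4 - 0.25)^2 / (0.25 * 0.25) = 0.36
  hap_a <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40) * 100)
  hap_b <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40) * 100)
  expect_equal(hap_r2_oracle(hap_a, hap_b), 0.36, tolerance = 1e-12)

  # genotypes formed by random pairing of those haplotypes
  set.seed(31)
  perm <- sample(length(hap_a))
  h1 <- cbind(hap_a, hap_b)
  odd <- perm[seq(1, length(perm), 2)]; even <- perm[seq(2, length(perm), 2)]
  dos <- h1[odd, ] + h1[even, ]
  d <- genotype_dataset(
    dos, data.frame(id = c("mA", "mB"), chrom = "1", pos = c(1, 2)),
    data.frame(id = sprintf("s%04d", seq_along(odd)), group = "g"))
  expect_lt(abs(pairwise_ld(d, 1)$r2 - 0.36), 0.02)

  # the forward simulator's retained phase gives the same correspondence
  wf <- simulate_wright_fisher(diploid_size = 150, n_chromosomes = 1,
                               markers_per_chromosome = 40,
                               marker_spacing = 50000, n_generations = 50,
                               seed = 77)
  haps <- attr(wf, "haplotypes")
  rec <- pairwise_ld(wf, max_depth = 1)
  poly <- which(!attr(wf, "monomorphic"))
  adj <- rec[rec$a %in% poly & rec$b %in% poly, ]
  oracle <- vapply(seq_len(nrow(adj)), function(i)
    hap_r2_oracle(haps[, adj$a[i]], haps[, adj$b[i]]), 0)
  # composite (dosage) r2 tracks haplotype r2 closely under random mating
  expect_lt(mean(abs(adj$r2 - oracle)), 0.05)
  expect_gt(stats::cor(adj$r2, oracle), 0.95)
})

test_that("full-depth syntenic bookkeeping matches brute force", {
  # boundary case: one chromosome of 401 markers at depth 400
  map <- data.frame(id = sprintf("m%03d", 1:401), chrom = "1",
                    pos = 55000 * (1:401))
  expect_equal(full_depth_marker_count(map, 400), 1)
  expect_equal(which(full_depth_markers(map, 400)), 1)

  # random maps vs an explicit per-marker successor count
  set.seed(8)
  for (rep in 1:5) {
    sizes <- sample(1:60, sample(2:6, 1), replace = TRUE)
    map <- data.frame(
      id = sprintf("m%04d", seq_len(sum(sizes))),
      chrom = rep(paste0("c", seq_along(sizes)), sizes),
      pos = unlist(lapply(sizes, function(k) sort(sample(1e6, k)))))
    depth <- sample(1:30, 1)
    brute <- vapply(seq_len(nrow(map)), function(i)
      sum(map$chrom[-seq_len(i)] == map$chrom[i]) >= depth, TRUE)
    expect_equal(full_depth_markers(map, depth), brute)
  }
})

test_that("syntenic decay restricts to the full-depth set and maps depth to distance", {
  # single chromosome, 401 equally spaced markers, depth 400:
  # exactly one contributing marker, 400 depth bins
  set.seed(10)
  n <- 30
  dos <- matrix(rbinom(n * 401, 2, 0.5), n, 401)
  d <- genotype_dataset(
    dos, data.frame(id = sprintf("m%03d", 1:401), chrom = "1",
                    pos = 55000 * (1:401)),
    data.frame(id = sprintf("s%02d", 1:n), group = "g"))
  rec <- pairwise_ld(d, max_depth = 400)
  curve <- syntenic_decay(rec, d$markers)
  expect_equal(nrow(curve), 400)
  expect_true(all(curve$n_pairs <= 1))
  expect_equal(attr(curve, "n_full_depth_markers"), 1)
  expect_equal(curve$distance_bp, 55000 * (1:400))
  expect_true(all(diff(curve$distance_bp) > 0))

  expect_error(syntenic_decay(pairwise_ld(d, 3), d$markers, max_depth = 600),
               "smaller max_depth")

  # Wright-Fisher panel: LD decays with depth toward the sampling floor
  wf <- simulate_wright_fisher(diploid_size = 100, n_chromosomes = 1,
                               markers_per_chromosome = 300,
                               marker_spacing = 50000, n_generations = 100,
                               seed = 3)
  wrec <- pairwise_ld(wf, max_depth = 100)
  wc <- syntenic_decay(wrec, wf$markers)
  expect_gt(mean(wc$mean_r2[1:5]), mean(wc$mean_r2[80:100]))
})

test_that("non-syntenic LD is undefined on one chromosome, ~1/N otherwise", {
  one <- simulate_divergent_populations(1, 30, 100, theta = 0.3,
                                        n_chromosomes = 1, seed = 2)
  ns1 <- nonsyntenic_ld(pairwise_ld(one, 50))
  expect_false(ns1$defined)
  expect_true(is.na(ns1$mean_r2))

  many <- simulate_divergent_populations(1, 64, 600, theta = 0.5,
                                         n_chromosomes = 12, seed = 6)
  ns64 <- nonsyntenic_ld(pairwise_ld(many, 100))
  expect_true(ns64$defined)
  expect_lt(abs(ns64$mean_r2 * 64 - 1), 0.25)

  few <- subset_genotypes(many, samples = 1:16)
  ns16 <- nonsyntenic_ld(pairwise_ld(few, 100))
  expect_lt(abs(ns16$mean_r2 * 16 - 1), 0.25)
  expect_gt(ns16$mean_r2, ns64$mean_r2)
})

test_that("the sample-size experiment is deterministic and consistent", {
  d <- simulate_divergent_populations(1, 64, 400, theta = 0.5,
                                      n_chromosomes = 8, seed = 13)
  tab <- sample_size_experiment(d, exponents = c(4, 5, 6), seed = 2,
                                max_depth = 60)
  tab2 <- sample_size_experiment(d, exponents = c(4, 5, 6), seed = 2,
                                 max_depth = 60)
  expect_identical(tab, tab2)
  expect_equal(tab$inv_N, 1 / tab$N)

  # the full-panel row equals the direct non-syntenic mean (no subsampling)
  full <- nonsyntenic_ld(pairwise_ld(d, 60))
  expect_equal(tab$mean_r2[tab$N == 64], full$mean_r2, tolerance = 1e-12)

  expect_error(sample_size_experiment(d, exponents = 0), "below 2")
  expect_error(sample_size_experiment(d, exponents = 10), "exceeds")
})

test_that("the 1/N correction subtracts the sampling expectation", {
  cor1 <- sample_size_ld_correction(0.30, 10)
  expect_equal(cor1$value, 0.20)
  expect_false(cor1$floored)

  cor2 <- sample_size_ld_correction(0.01, 10)
  expect_equal(cor2$value, 0)
  expect_true(cor2$floored)

  rep_ <- sample_size_ld_correction(0.30, 10, mode = "report")
  expect_equal(rep_$value, 0.30)
  expect_equal(rep_$expectation, 0.1)

  # on unlinked panels the corrected non-syntenic mean collapses to ~0
  d <- simulate_divergent_populations(1, 256, 300, theta = 0.5,
                                      n_chromosomes = 6, seed = 19)
  for (N in c(16, 64, 256)) {
    sub <- subset_genotypes(d, samples = seq_len(N))
    raw <- nonsyntenic_ld(pairwise_ld(sub, 60))$mean_r2
    corrected <- sample_size_ld_correction(raw, N)$value
    expect_lt(corrected, 0.3 / N)
  }
})

test_that("Ne arithmetic follows (1 - r2) / (4 c r2) with t = 1/(2c)", {
  curve <- fake_decay_curve(c(55e3, 2.5e6), c(0.5, 0.2))
  traj <- ne_from_ld(curve)
  # adjacent bin: c = 5.5e-4 M, t ~ 909 generations, Ne ~ 454.5
  expect_equal(traj$c_morgans[1], 5.5e-4)
  expect_equal(traj$t_generations[1], 1 / (2 * 5.5e-4))
  expect_equal(traj$ne[1], 0.5 / (4 * 5.5e-4 * 0.5), tolerance = 1e-12)
  expect_equal(traj$ne[1], 454.5455, tolerance = 1e-4)
  expect_false(traj$in_window[1])  # t ~ 909 lies beyond 500 generations
  # 2.5 MB bin: c = 0.025 M, t = 20, Ne = 40
  expect_equal(traj$t_generations[2], 20)
  expect_equal(traj$ne[2], 40)
  expect_true(traj$in_window[2])
  expect_equal(current_ne(traj), 40)
  expect_true(all(diff(traj$t_generations) < 0))

  # ties at |t - 20| resolve toward the smaller t
  tie <- ne_from_ld(fake_decay_curve(c(1 / (2 * 25) / 1e-8,
                                       1 / (2 * 15) / 1e-8),
                                     c(0.3, 0.3)))
  expect_equal(attr(tie, "current_t_bin"), 15)

  # degenerate r2 values are flagged
  deg <- ne_from_ld(fake_decay_curve(c(1e6, 2e6, 3e6), c(0, 1, 0.5)))
  expect_true(is.na(deg$ne[1]))
  expect_equal(deg$ne[2], 0)
  expect_true(all(deg$flagged[1:2]))
  expect_false(deg$flagged[3])
})
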