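test_that("construction sorts markers and enforces the invariants", {
  d <- tiny_dataset()
  expect_equal(d$markers$id, c("mA", "mB", "mC", "mD"))

  # unsorted map entries are re-sorted, dosages follow their markers
  shuffled <- genotype_dataset(d$dosages[, c(3, 1, 4, 2)],
                               d$markers[c(3, 1, 4, 2), ], d$samples)
  expect_equal(shuffled$markers, d$markers)
  expect_equal(shuffled$dosages, d$dosages)
  for (ch in unique(shuffled$markers$chrom))
    expect_true(all(diff(shuffled$markers$pos[shuffled$markers$chrom == ch]) > 0))

  expect_error(genotype_dataset(matrix(3, 1, 1),
                                data.frame(id = "m", chrom = "1", pos = 1),
                                data.frame(id = "s", group = "g")),
               "outside")
  expect_error(genotype_dataset(d$dosages,
                                transform(d$markers, id = rep("m", 4)),
                                d$samples), "duplicate")
  dup_pos <- d$markers; dup_pos$pos[2] <- 100
  expect_error(genotype_dataset(d$dosages, dup_pos, d$samples),
               "strictly increasing")
})

test_that("every dialect round-trips losslessly", {
  d <- tiny_dataset()
  d$dosages[2, 3] <- NA
  d <- genotype_dataset(d$dosages, d$markers, d$samples)
  tmp <- withr::local_tempdir()
  for (fmt in c("plink-ped", "additive-table", "dosage-matrix")) {
    base <- file.path(tmp, paste0("panel_", gsub("-", "_", fmt)))
    path <- switch(fmt, "plink-ped" = paste0(base, ".ped"),
                   "additive-table" = paste0(base, ".txt"),
                   "dosage-matrix" = paste0(base, ".dose"))
    write_genotypes(d, path, fmt)
    back <- read_genotypes(path, fmt)
    expect_equal(back$dosages, d$dosages, info = fmt)
    expect_equal(back$markers, d$markers, info = fmt)
    expect_equal(back$samples$id, d$samples$id, info = fmt)
  }
  # group labels survive the ped (family column) and dosage-matrix dialects
  expect_equal(read_genotypes(file.path(tmp, "panel_plink_ped.ped"),
                              "plink-ped")$samples$group,
               d$samples$group)
  expect_equal(read_genotypes(file.path(tmp, "panel_dosage_matrix.dose"),
                              "dosage-matrix")$samples$group,
               d$samples$group)
})

test_that("malformed inputs are rejected with informative errors", {
  d <- tiny_dataset()
  tmp <- withr::local_tempdir()
  write_genotypes(d, file.path(tmp, "p.ped"), "plink-ped")
  # drop a marker from the map: ped no longer aligns
  map <- readLines(file.path(tmp, "p.map"))
  writeLines(map[-1], file.path(tmp, "p.map"))
  expect_error(read_genotypes(file.path(tmp, "p.ped"), "plink-ped"),
               "mismatch")
  writeLines(map, file.path(tmp, "p.map"))
  # a non-AB allele marks the marker as unusable
  ped <- readLines(file.path(tmp, "p.ped"))
  ped[1] <- sub(" A ", " C ", ped[1])
  writeLines(ped, file.path(tmp, "p.ped"))
  expect_error(read_genotypes(file.path(tmp, "p.ped"), "plink-ped"),
               "mA|allele")
})

test_that("quality control filters in the documented order with per-rule counts", {
  set.seed(42)
  n <- 100; m <- 30
  dos <- matrix(rbinom(n * m, 2, 0.4), n, m)
  # markers 1-3: call rate 0.90 (10 missing cells each, spread over samples
  # 11-40 so no sample accumulates enough missingness to fail)
  for (j in 1:3) dos[10 + (j - 1) * 10 + 1:10, j] <- NA
  # samples 1-2: 3 missing cells among the 27 surviving markers (call rate
  # 24/27 = 0.889 < 0.95)
  dos[1, 4:6] <- NA; dos[2, 7:9] <- NA
  # markers 4-8: monomorphic for the reference allele among survivors -> MAF 0
  dos[, 4:8][!is.na(dos[, 4:8])] <- 0
  data <- genotype_dataset(
    dos,
    data.frame(id = sprintf("m%02d", 1:m), chrom = "1", pos = 1000 * (1:m)),
    data.frame(id = sprintf("s%03d", 1:n), group = "g"))
  res <- apply_qc(data, qc_thresholds())
  expect_equal(unname(res$report$markers_removed_by_rule["call_rate"]), 3)
  expect_equal(unname(res$report$markers_removed_by_rule["maf"]), 5)
  expect_equal(res$report$samples_removed, 2)
  expect_equal(res$report$markers_retained, 22)
  expect_equal(res$report$samples_retained, 98)

  # idempotence: a second pass removes nothing
  res2 <- apply_qc(res$data, qc_thresholds())
  expect_equal(sum(res2$report$markers_removed_by_rule), 0)
  expect_equal(res2$report$samples_removed, 0)

  # a marker at p = 0.005 falls under the MAF rule at default thresholds
  dos2 <- matrix(2, 100, 2); dos2[, 1] <- c(1, rep(0, 99))
  d2 <- genotype_dataset(
    dos2, data.frame(id = c("ma", "mb"), chrom = "1", pos = c(1, 2)),
    data.frame(id = sprintf("s%03d", 1:100), group = "g"))
  expect_error(apply_qc(d2), "every marker")  # both markers fail MAF
})

test_that("mean imputation fills with marker means and preserves frequencies", {
  d <- genotype_dataset(
    matrix(c(0, 2, NA), 3, 1),
    data.frame(id = "m1", chrom = "1", pos = 1),
    data.frame(id = c("a", "b", "c"), group = "g"))
  expect_equal(mean_impute(d)$dosages[3, 1], 1.0)

  full <- tiny_dataset()
  expect_identical(mean_impute(full), full)

  set.seed(7)
  big <- simulate_divergent_populations(1, 20, 50, theta = 0.2, seed = 3)
  miss <- big
  cells <- sample(length(miss$dosages), 7)
  # keep at least one call per marker
  miss$dosages[cells] <- NA
  miss <- genotype_dataset(miss$dosages, miss$markers, miss$samples)
  pre <- allele_frequencies(miss)$frequencies
  post <- allele_frequencies(mean_impute(miss))$frequencies
  expect_equal(post, pre, tolerance = 1e-12)

  all_missing <- d; all_missing$dosages[, 1] <- NA
  expect_error(mean_impute(genotype_dataset(all_missing$dosages,
                                            d$markers, d$samples)),
               "m1")
})

test_that("allele frequencies follow the dosage-sum definition", {
  d <- genotype_dataset(
    cbind(c(1, 1, 0, 0), c(0, 0, 0, 2)),
    data.frame(id = c("m1", "m2"), chrom = "1", pos = c(1, 2)),
    data.frame(id = letters[1:4], group = c("g1", "g1", "g2", "g2")))
  expect_equal(allele_frequencies(d, "g1")$frequencies[1], 0.5)
  expect_equal(allele_frequencies(d)$frequencies[2], 0.25)
  expect_error(allele_frequencies(d, "nope"), "no samples")

  # pooled frequency is the sample-size-weighted mean of group frequencies
  set.seed(11)
  pan <- simulate_divergent_populations(2, c(30), 40, theta = 0.3, seed = 5)
  p_all <- allele_frequencies(pan)$frequencies
  f1 <- allele_frequencies(pan, "pop1")
  f2 <- allele_frequencies(pan, "pop2")
  w <- f1$n_samples_used + f2$n_samples_used
  expect_equal(p_all, (f1$n_samples_used * f1$frequencies +
                         f2$n_samples_used * f2$frequencies) / w,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1$frequencies, f2$frequencies)))

  # invariance to sample and marker permutations
  perm <- subset_genotypes(pan, samples = sample(nrow(pan$dosages)))
  expect_equal(allele_frequencies(perm)$frequencies, p_all)
})
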