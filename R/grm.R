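#' VanRaden genomic relationship matrix
#'
#' Computes G = (M - 2P)(M - 2P)' / (2 sum_j p_j (1 - p_j)), where M is the
#' samples x markers dosage matrix and the j-th column of P repeats the
#' B-allele frequency p_j of the reference sample set. When
#' `reference_frequencies` is omitted the frequencies are computed from the
#' samples in `data` itself, in which case every row and column of G sums
#' to zero (the centered matrix has zero column sums). Recomputing G on a
#' sample subset with subset frequencies (e.g. a single breed) is not the
#' same as slicing the full-panel G: centering and scaling both change.
#'
#' @param data a [genotype_dataset] with no missing dosages (run
#'   [mean_impute] first if needed).
#' @param reference_frequencies optional [allele_frequencies] result
#'   providing the centering/scaling frequencies.
#' @return An object of class `grm`: `G` (dense symmetric matrix with
#'   sample-id dimnames), `frequencies`, `denominator` and `sample_ids`.
#' @export
compute_grm <- function(data, reference_frequencies = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (anyNA(data$dosages))
    stop("missing dosages present; impute before computing the GRM")
  if (is.null(reference_frequencies)) {
    freqs <- allele_frequencies(data)
  } else {
    freqs <- reference_frequencies
    stopifnot(inherits(freqs, "allele_frequency_set"))
    if (length(freqs$frequencies) != ncol(data$dosages))
      stop("reference frequencies cover ", length(freqs$frequencies),
           " markers but the panel has ", ncol(data$dosages))
  }
  p <- freqs$frequencies
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers monomorphic in the reference set (denominator 0)")
  Z <- sweep(data$dosages, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(data$samples$id, data$samples$id)
  structure(list(G = G, frequencies = freqs, denominator = denom,
                 sample_ids = data$samples$id,
                 groups = data$samples$group),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("VanRaden GRM:", nrow(x$G), "x", nrow(x$G),
      sprintf("| mean diagonal %.4f\n", mean(diag(x$G))))
  invisible(x)
}

#' Genomic inbreeding coefficients from a GRM
#'
#' Per-sample genomic inbreeding F_VR = G_ii - 1, summarised per group as
#' minimum, mean +/- SD and maximum, together with the grand mean diagonal
#' of G (a useful diagnostic: subsetting and re-centering a structured
#' panel lowers it).
#'
#' @param grm a [compute_grm] result.
#' @param grouping group label per sample; default the labels stored in the
#'   GRM.
#' @return An object of class `inbreeding_summary`: `per_sample` (named
#'   vector of F_VR), `by_group` (data frame with group, n, min, mean, sd,
#'   max) and `mean_diagonal`.
#' @export
genomic_inbreeding <- function(grm, grouping = NULL) {
  stopifnot(inherits(grm, "grm"))
  if (is.null(grouping)) grouping <- grm$groups
  stopifnot(length(grouping) == nrow(grm$G))
  f <- diag(grm$G) - 1
  names(f) <- grm$sample_ids
  groups <- unique(grouping)
  by_group <- do.call(rbind, lapply(groups, function(g) {
    fg <- f[grouping == g]
    data.frame(group = g, n = length(fg), min = min(fg), mean = mean(fg),
               sd = if (length(fg) > 1) stats::sd(fg) else NA_real_,
               max = max(fg), stringsAsFactors = FALSE)
  }))
  structure(list(per_sample = f, by_group = by_group,
                 mean_diagonal = mean(diag(grm$G))),
            class = "inbreeding_summary")
}

#' @export
print.inbreeding_summary <- function(x, ...) {
  cat(sprintf("genomic inbreeding (mean diagonal of G: %.4f)\n",
              x$mean_diagonal))
  print(x$by_group, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Group-block relatedness from a GRM
#'
#' Mean off-diagonal relatedness within and between groups: the
#' within-group block mean excludes the diagonal of G; the between-group
#' block mean averages the full rectangular block. For each group an
#' external mean is also reported — the mean relatedness of its samples to
#' all samples outside the group — which is the conventional replacement
#' for the diagonal when plotting the block matrix. Groups of size one have
#' no within-group pairs; their internal relatedness is `NA` and flagged.
#'
#' @param grm a [compute_grm] result.
#' @param grouping group label per sample; default stored labels.
#' @return An object of class `group_relatedness`: `block_means` (symmetric
#'   matrix, diagonal = internal relatedness), `internal` (named vector),
#'   `external_mean` (named vector), `singleton_groups`.
#' @export
group_relatedness <- function(grm, grouping = NULL) {
  stopifnot(inherits(grm, "grm"))
  if (is.null(grouping)) grouping <- grm$groups
  stopifnot(length(grouping) == nrow(grm$G))
  groups <- unique(grouping)
  k <- length(groups)
  bm <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  external <- stats::setNames(numeric(k), groups)
  G <- grm$G
  for (i in seq_len(k)) {
    gi <- grouping == groups[i]
    ni <- sum(gi)
    if (ni > 1) {
      block <- G[gi, gi, drop = FALSE]
      bm[i, i] <- (sum(block) - sum(diag(block))) / (ni * (ni - 1))
    }
    if (any(!gi)) external[i] <- mean(G[gi, !gi, drop = FALSE])
    else external[i] <- NA_real_
    if (i < k) for (j in (i + 1):k) {
      gj <- grouping == groups[j]
      bm[i, j] <- bm[j, i] <- mean(G[gi, gj, drop = FALSE])
    }
  }
  structure(list(groups = groups, block_means = bm,
                 internal = stats::setNames(diag(bm), groups),
                 external_mean = external,
                 singleton_groups = groups[tabulate(
                   factor(grouping, levels = groups), k) == 1]),
            class = "group_relatedness")
}

#' @export
print.group_relatedness <- function(x, digits = 3, ...) {
  cat("group-block mean relatedness (diagonal = internal, excl. G diagonal):\n")
  print(round(x$block_means, digits))
  if (length(x$singleton_groups))
    cat("singleton group(s), internal relatedness undefined:",
        paste(x$singleton_groups, collapse = ", "), "\n")
  invisible(x)
}

#' Principal component decomposition of a GRM
#'
#' Eigendecomposition of the (symmetric) relationship matrix. Component
#' scores are eigenvector times the square root of the eigenvalue; the
#' proportion of variance (POV) of component k is its eigenvalue over the
#' sum of all non-negative eigenvalues. G is positive semi-definite in
#' exact arithmetic, so small negative eigenvalues are numerical: they are
#' clamped to zero for POV and flagged. The sign of each component is fixed
#' deterministically (the loading of largest magnitude is positive), so
#' results are reproducible.
#'
#' @param grm a [compute_grm] result.
#' @param n_components number of leading components to keep (default 40,
#'   capped at the matrix dimension).
#' @return An object of class `grm_pca`: `scores` (samples x K),
#'   `loadings` (eigenvectors), `eigenvalues`, `pov`, `cumulative_pov`,
#'   `n_negative_eigenvalues`.
#' @export
grm_pca <- function(grm, n_components = 40) {
  stopifnot(inherits(grm, "grm"))
  G <- grm$G
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G))))
    stop("relationship matrix is not symmetric")
  n <- nrow(G)
  k <- min(n_components, n)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lambda <- e$values
  n_neg <- sum(lambda < 0)
  lambda_pos <- pmax(lambda, 0)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    m <- which.max(abs(vec[, j]))
    if (vec[m, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- vec %*% diag(sqrt(lambda_pos[seq_len(k)]), k)
  rownames(scores) <- grm$sample_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  pov <- lambda_pos[seq_len(k)] / sum(lambda_pos)
  structure(list(scores = scores, loadings = vec,
                 eigenvalues = lambda[seq_len(k)],
                 all_eigenvalue_sum = sum(lambda_pos),
                 pov = pov, cumulative_pov = cumsum(pov),
                 n_negative_eigenvalues = n_neg,
                 groups = grm$groups),
            class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  k <- length(x$pov)
  cat(sprintf("GRM PCA: %d components, cumulative POV %.3f\n",
              k, x$cumulative_pov[k]))
  invisible(x)
}

#' Write a GRM to disk
#'
#' Either a labeled dense matrix or a three-column sparse text file
#' (id1, id2, value; upper triangle including the diagonal).
#'
#' @param grm a [compute_grm] result.
#' @param path output file.
#' @param format `"dense"` or `"sparse"`.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  stopifnot(inherits(grm, "grm"))
  if (format == "dense") {
    df <- data.frame(id = grm$sample_ids, grm$G, check.names = FALSE)
    utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  } else {
    idx <- which(upper.tri(grm$G, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = grm$sample_ids[idx[, 1]],
                     id2 = grm$sample_ids[idx[, 2]],
                     value = grm$G[idx])
    utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  }
  invisible(path)
}
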