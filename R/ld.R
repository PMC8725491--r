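#' Depth-limited pairwise linkage disequilibrium
#'
#' For every marker, r-squared is computed against each of the `max_depth`
#' markers that succeed it in global genome order. The depth window crosses
#' chromosome boundaries; such pairs are flagged non-syntenic rather than
#' dropped, because they estimate the sampling noise floor. r-squared is
#' the squared Pearson correlation of the two dosage vectors (composite
#' LD): real panels are unphased, and for genotypes formed by random
#' pairing of haplotypes this converges to the haplotype-frequency
#' definition r^2 = (p_AB - p_A p_B)^2 / (p_A(1-p_A) p_B(1-p_B)).
#'
#' Pairs involving a monomorphic marker have no defined correlation; they
#' are skipped and counted in `attr(, "n_skipped")`.
#'
#' @param data a [genotype_dataset] with complete dosages, markers in
#'   genome order (guaranteed by construction).
#' @param max_depth successor window size (default 400).
#' @return A data frame of LD records (class `ld_records`): columns `a`,
#'   `b` (marker indices), `depth`, `same_chrom`, `r2`; attributes
#'   `n_samples`, `max_depth`, `n_skipped`.
#' @export
pairwise_ld <- function(data, max_depth = 400) {
  stopifnot(inherits(data, "genotype_dataset"), max_depth >= 1)
  dos <- data$dosages
  if (anyNA(dos)) stop("missing dosages present; impute before computing LD")
  n <- nrow(dos); m <- ncol(dos)
  if (m < 2) stop("need at least two markers")
  mu <- colMeans(dos)
  ss <- colSums(dos^2) - n * mu^2
  mono <- ss <= 0
  Z <- sweep(dos, 2, mu)
  sdv <- sqrt(ss)
  sdv[mono] <- 1
  Z <- sweep(Z, 2, sdv, "/")  # unit-norm centered columns
  Z[, mono] <- 0
  D <- min(max_depth, m - 1)
  chrom <- data$markers$chrom

  total <- sum(m - seq_len(D))
  av <- integer(total); dv <- integer(total); r2v <- numeric(total)
  pos <- 0L
  for (d in seq_len(D)) {
    a <- seq_len(m - d)
    r <- colSums(Z[, a, drop = FALSE] * Z[, a + d, drop = FALSE])
    r2 <- pmin(r^2, 1)
    r2[mono[a] | mono[a + d]] <- NA_real_
    idx <- pos + seq_along(a)
    av[idx] <- a; dv[idx] <- d; r2v[idx] <- r2
    pos <- pos + length(a)
  }
  bv <- av + dv
  keep <- !is.na(r2v)
  rec <- data.frame(a = av[keep], b = bv[keep], depth = dv[keep],
                    same_chrom = chrom[av[keep]] == chrom[bv[keep]],
                    r2 = r2v[keep])
  attr(rec, "n_samples") <- n
  attr(rec, "max_depth") <- max_depth
  attr(rec, "n_skipped") <- sum(!keep)
  class(rec) <- c("ld_records", "data.frame")
  rec
}

#' Markers with a full same-chromosome successor window
#'
#' A marker contributes a complete set of syntenic LD estimates only when
#' at least `max_depth` markers follow it on its own chromosome. With
#' markers sorted by position, these are the first (m_c - max_depth)
#' markers of every chromosome carrying more than `max_depth` markers.
#'
#' @param markers a marker table (`id`, `chrom`, `pos`) in genome order.
#' @param max_depth successor window size.
#' @return Logical vector, one element per marker.
#' @export
full_depth_markers <- function(markers, max_depth) {
  chrom <- markers$chrom
  counts <- table(factor(chrom, levels = unique(chrom)))
  unlist(lapply(as.integer(counts), function(mc) {
    c(rep(TRUE, max(0, mc - max_depth)),
      rep(FALSE, min(mc, max_depth)))
  }), use.names = FALSE)
}

#' Count markers with a full syntenic successor window
#'
#' @inheritParams full_depth_markers
#' @return Integer count.
#' @export
full_depth_marker_count <- function(markers, max_depth) {
  sum(full_depth_markers(markers, max_depth))
}

#' Syntenic LD-decay curve
#'
#' Restricts the LD records to markers that have the full `max_depth`
#' same-chromosome successor window, then averages r-squared per depth.
#' Each depth is assigned a nominal physical distance: depth times the
#' mean adjacent marker spacing of the map (the decay curve is a function
#' of marker rank, translated to base pairs by this single panel-wide
#' constant). Depth 1 is the adjacent-marker LD.
#'
#' @param records output of [pairwise_ld].
#' @param markers the marker table of the same dataset.
#' @param max_depth window size; default the records' own.
#' @return An object of class `ld_decay_curve`: data frame columns
#'   `depth`, `distance_bp`, `mean_r2`, `n_pairs`; attributes
#'   `mean_adjacent_spacing`, `n_full_depth_markers`, `n_samples`.
#' @export
syntenic_decay <- function(records, markers, max_depth = NULL) {
  stopifnot(inherits(records, "ld_records"))
  if (is.null(max_depth)) max_depth <- attr(records, "max_depth")
  full <- full_depth_markers(markers, max_depth)
  if (!any(full))
    stop("no marker has ", max_depth, " same-chromosome successors; ",
         "use a smaller max_depth")
  sel <- records$same_chrom & full[records$a] & records$depth <= max_depth
  rec <- records[sel, , drop = FALSE]
  mean_r2 <- tapply(rec$r2, factor(rec$depth, levels = seq_len(max_depth)),
                    mean)
  n_pairs <- tapply(rec$r2, factor(rec$depth, levels = seq_len(max_depth)),
                    length)
  n_pairs[is.na(n_pairs)] <- 0
  spacing <- mean_adjacent_spacing(markers)
  curve <- data.frame(depth = seq_len(max_depth),
                      distance_bp = seq_len(max_depth) * spacing,
                      mean_r2 = as.numeric(mean_r2),
                      n_pairs = as.integer(n_pairs))
  attr(curve, "mean_adjacent_spacing") <- spacing
  attr(curve, "n_full_depth_markers") <- sum(full)
  attr(curve, "n_samples") <- attr(records, "n_samples")
  class(curve) <- c("ld_decay_curve", "data.frame")
  curve
}

#' Mean adjacent marker spacing of a map
#'
#' Mean base-pair gap between consecutive markers on the same chromosome.
#'
#' @param markers a marker table in genome order.
#' @return A single number (base pairs).
#' @export
mean_adjacent_spacing <- function(markers) {
  gaps <- unlist(tapply(markers$pos,
                        factor(markers$chrom, levels = unique(markers$chrom)),
                        diff), use.names = FALSE)
  if (length(gaps) == 0) stop("map has no adjacent same-chromosome markers")
  mean(gaps)
}

#' Mean non-syntenic LD
#'
#' Averages r-squared over the cross-chromosome pairs of the depth window.
#' With unlinked markers this mean estimates the sampling noise floor,
#' approximately 1/N for N samples. A single-chromosome panel has no such
#' pairs: the result is explicitly undefined, never a silent zero.
#'
#' @param records output of [pairwise_ld].
#' @return An object of class `nonsyntenic_ld`: `mean_r2`, `n_pairs`,
#'   `sample_size`, `defined`.
#' @export
nonsyntenic_ld <- function(records) {
  stopifnot(inherits(records, "ld_records"))
  r2 <- records$r2[!records$same_chrom]
  structure(list(mean_r2 = if (length(r2)) mean(r2) else NA_real_,
                 n_pairs = length(r2),
                 sample_size = attr(records, "n_samples"),
                 defined = length(r2) > 0),
            class = "nonsyntenic_ld")
}

#' @export
print.nonsyntenic_ld <- function(x, ...) {
  if (x$defined)
    cat(sprintf("non-syntenic LD: mean r2 %.5f over %d pairs (N = %d)\n",
                x$mean_r2, x$n_pairs, x$sample_size))
  else cat("non-syntenic LD: undefined (no cross-chromosome pairs)\n")
  invisible(x)
}

#' Non-syntenic LD across sub-sampled panel sizes
#'
#' Draws random sub-panels of N = 2^n individuals and recomputes the mean
#' non-syntenic r-squared for each, tabulating it against 1/N. On unlinked
#' markers the regression of mean r-squared on 1/N has slope close to one
#' and intercept close to the true background LD — the classic
#' demonstration that r-squared carries a 1/N sampling inflation.
#'
#' @param data a [genotype_dataset] with complete dosages and at least two
#'   chromosomes.
#' @param exponents values of n; panel sizes are N = round(2^n).
#' @param seed integer seed for the sub-sampling.
#' @param max_depth LD window (default 400).
#' @return A data frame with columns `exponent`, `N`, `inv_N`, `mean_r2`,
#'   `n_pairs`.
#' @export
sample_size_experiment <- function(data, exponents, seed = 1,
                                   max_depth = 400) {
  stopifnot(inherits(data, "genotype_dataset"))
  sizes <- round(2^exponents)
  n_all <- nrow(data$dosages)
  if (any(sizes < 2)) stop("sample sizes below 2 are not usable")
  if (any(sizes > n_all))
    stop("requested sample size exceeds the panel (", n_all, " samples)")
  set.seed(as.integer(seed))
  rows <- lapply(seq_along(sizes), function(i) {
    N <- sizes[i]
    sub <- if (N == n_all) data
           else subset_genotypes(data, samples = sort(sample.int(n_all, N)))
    ns <- nonsyntenic_ld(pairwise_ld(sub, max_depth = max_depth))
    data.frame(exponent = exponents[i], N = N, inv_N = 1 / N,
               mean_r2 = ns$mean_r2, n_pairs = ns$n_pairs)
  })
  do.call(rbind, rows)
}

#' Sample-size correction of r-squared
#'
#' Subtracts the finite-sample expectation 1/N from an r-squared estimate
#' (the chance LD created by sampling N individuals). Estimates near the
#' noise floor go negative under this correction; they are floored at zero
#' and flagged. `mode = "report"` leaves the estimate untouched and simply
#' reports the 1/N expectation alongside.
#'
#' @param r_squared numeric vector of r-squared values.
#' @param n_samples number of individuals behind the estimates.
#' @param mode `"subtract"` (default) or `"report"`.
#' @return A list: `value` (corrected or original r-squared), `floored`
#'   (logical, only for `"subtract"`), `expectation` (1/N).
#' @export
sample_size_ld_correction <- function(r_squared, n_samples,
                                      mode = c("subtract", "report")) {
  mode <- match.arg(mode)
  if (n_samples < 2) stop("need at least two samples")
  expectation <- 1 / n_samples
  if (mode == "report")
    return(list(value = r_squared, floored = NULL, expectation = expectation))
  corrected <- r_squared - expectation
  floored <- corrected < 0
  corrected[floored] <- 0
  list(value = corrected, floored = floored, expectation = expectation)
}

#' Historical effective population size from an LD-decay curve
#'
#' Translates each depth bin of a syntenic decay curve into a
#' recombination fraction c (nominal distance times the Morgan-per-bp map
#' scale, default 1 Morgan = 100 Mb), a time point t = 1/(2c) generations
#' ago, and an effective size Ne_t = (1 - r^2) / (4 c r^2). The "current"
#' effective size is read from the bin whose t is nearest `current_t`
#' (default 20 generations; ties resolved toward the smaller t). Bins with
#' r^2 = 0 have undefined Ne; bins with r^2 = 1 give Ne = 0; both are
#' flagged. The `in_window` column marks the conventional reporting window
#' of t in \[2, 500\] generations.
#'
#' @param curve an [syntenic_decay] result.
#' @param morgan_per_bp map scale (default 1e-8).
#' @param current_t time point (generations ago) for the current-Ne readout.
#' @param t_window reporting window on t, default `c(2, 500)`.
#' @return An object of class `ne_trajectory`: data frame columns `depth`,
#'   `distance_bp`, `c_morgans`, `t_generations`, `mean_r2`, `n_pairs`,
#'   `ne`, `flagged`, `in_window`; attributes `current_ne`, `current_t_bin`.
#' @export
ne_from_ld <- function(curve, morgan_per_bp = 1e-8, current_t = 20,
                       t_window = c(2, 500)) {
  stopifnot(inherits(curve, "ld_decay_curve"))
  if (any(curve$distance_bp <= 0)) stop("distances must be positive")
  cM <- curve$distance_bp * morgan_per_bp
  t <- 1 / (2 * cM)
  r2 <- curve$mean_r2
  ne <- (1 - r2) / (4 * cM * r2)
  flagged <- !is.na(r2) & (r2 <= 0 | r2 >= 1)
  ne[!is.na(r2) & r2 <= 0] <- NA_real_
  ne[!is.na(r2) & r2 >= 1] <- 0
  traj <- data.frame(depth = curve$depth, distance_bp = curve$distance_bp,
                     c_morgans = cM, t_generations = t,
                     mean_r2 = r2, n_pairs = curve$n_pairs,
                     ne = ne, flagged = flagged,
                     in_window = t >= t_window[1] & t <= t_window[2])
  usable <- !is.na(ne) & !flagged
  if (!any(usable)) stop("no usable bins for Ne estimation")
  d <- abs(t - current_t)
  d[!usable] <- Inf
  cand <- which(d == min(d))
  pick <- cand[which.min(t[cand])]  # tie toward the smaller t
  attr(traj, "current_ne") <- ne[pick]
  attr(traj, "current_t_bin") <- t[pick]
  attr(traj, "current_t_requested") <- current_t
  class(traj) <- c("ne_trajectory", "data.frame")
  traj
}

#' Current effective population size of a trajectory
#'
#' @param traj an [ne_from_ld] result.
#' @return The Ne value at the bin nearest the requested time point.
#' @export
current_ne <- function(traj) {
  stopifnot(inherits(traj, "ne_trajectory"))
  attr(traj, "current_ne")
}
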