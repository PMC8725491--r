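#' Quality-control thresholds
#'
#' Defaults follow the common 50K-chip convention: minor allele frequency
#' above 0.01 and call rates above 0.95 for both markers and samples
#' (strict inequalities).
#'
#' @param min_maf minimum minor allele frequency (exclusive), in \[0, 1\].
#' @param min_marker_call_rate minimum marker call rate (exclusive).
#' @param min_sample_call_rate minimum sample call rate (exclusive).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.01,
                          min_marker_call_rate = 0.95,
                          min_sample_call_rate = 0.95) {
  vals <- c(min_maf, min_marker_call_rate, min_sample_call_rate)
  if (any(vals < 0 | vals > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(min_maf = min_maf,
                 min_marker_call_rate = min_marker_call_rate,
                 min_sample_call_rate = min_sample_call_rate),
            class = "qc_thresholds")
}

#' Apply marker and sample quality control
#'
#' Filtering proceeds in a fixed order: (1) markers failing the marker call
#' rate are removed, (2) samples failing the sample call rate are removed,
#' (3) allele frequencies are recomputed on the surviving samples and
#' markers failing the MAF rule (min(p, 1-p) on the combined panel) are
#' removed. Recomputing frequencies after sample removal matters because
#' MAF depends on the surviving sample set.
#'
#' @param data a [genotype_dataset].
#' @param thresholds a [qc_thresholds] object.
#' @return A list with elements `data` (the filtered dataset) and `report`
#'   (class `qc_report`: per-rule removal counts and retention totals).
#' @export
apply_qc <- function(data, thresholds = qc_thresholds()) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (!inherits(thresholds, "qc_thresholds"))
    thresholds <- do.call(qc_thresholds, as.list(thresholds))
  n_markers_in <- ncol(data$dosages)
  n_samples_in <- nrow(data$dosages)

  marker_cr <- colMeans(!is.na(data$dosages))
  keep_m1 <- marker_cr > thresholds$min_marker_call_rate
  removed_marker_cr <- sum(!keep_m1)
  data <- subset_genotypes(data, markers = keep_m1)

  sample_cr <- rowMeans(!is.na(data$dosages))
  keep_s <- sample_cr > thresholds$min_sample_call_rate
  removed_samples <- sum(!keep_s)
  if (all(!keep_s)) stop("quality control removed every sample")
  data <- subset_genotypes(data, samples = keep_s)

  p <- allele_frequencies(data)$frequencies
  maf <- pmin(p, 1 - p)
  keep_m2 <- !is.na(maf) & maf > thresholds$min_maf
  removed_maf <- sum(!keep_m2)
  if (all(!keep_m2))
    stop("quality control removed every marker (empty panel)")
  data <- subset_genotypes(data, markers = keep_m2)

  report <- structure(list(
    markers_removed_by_rule = c(call_rate = removed_marker_cr,
                                maf = removed_maf),
    samples_removed = removed_samples,
    markers_retained = ncol(data$dosages),
    samples_retained = nrow(data$dosages),
    markers_input = n_markers_in,
    samples_input = n_samples_in,
    thresholds = thresholds), class = "qc_report")
  list(data = data, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("quality control:",
      x$markers_input, "markers /", x$samples_input, "samples in;",
      x$markers_retained, "/", x$samples_retained, "retained\n")
  cat("  markers removed: call rate", x$markers_removed_by_rule[["call_rate"]],
      "| MAF", x$markers_removed_by_rule[["maf"]], "\n")
  cat("  samples removed:", x$samples_removed, "\n")
  invisible(x)
}

#' Replace missing dosages by the marker mean
#'
#' Each missing cell is replaced by the mean dosage of the non-missing
#' samples at that marker, producing a complete (possibly fractional)
#' dosage matrix. This deliberately simple scheme preserves per-marker
#' allele frequencies exactly; it is not a statistical (haplotype-based)
#' imputation.
#'
#' @param data a [genotype_dataset].
#' @return A [genotype_dataset] with no missing values.
#' @export
mean_impute <- function(data) {
  stopifnot(inherits(data, "genotype_dataset"))
  dos <- data$dosages
  if (!anyNA(dos)) return(data)
  mu <- colMeans(dos, na.rm = TRUE)
  if (anyNA(mu))
    stop("marker(s) entirely missing, cannot impute: ",
         paste(utils::head(data$markers$id[is.na(mu)], 5), collapse = ", "))
  idx <- which(is.na(dos), arr.ind = TRUE)
  dos[idx] <- mu[idx[, 2]]
  genotype_dataset(dos, data$markers, data$samples)
}

#' Construct an allele-frequency set directly
#'
#' Wraps a vector of per-marker B-allele frequencies so it can be supplied
#' as the reference set of [compute_grm] (e.g. known founder frequencies).
#'
#' @param frequencies numeric vector of B-allele frequencies in \[0, 1\].
#' @param n_samples_used per-marker sample counts behind the frequencies
#'   (`NA` if unknown).
#' @param scope label of the sample set the frequencies describe.
#' @return An object of class `allele_frequency_set`.
#' @export
allele_frequency_set <- function(frequencies, n_samples_used = NA_integer_,
                                 scope = "supplied") {
  if (any(!is.na(frequencies) & (frequencies < 0 | frequencies > 1)))
    stop("frequencies must lie in [0, 1]")
  structure(list(frequencies = as.numeric(frequencies),
                 n_samples_used = rep_len(n_samples_used,
                                          length(frequencies)),
                 marker_id = NULL, scope = scope),
            class = "allele_frequency_set")
}

#' Per-marker B-allele frequencies
#'
#' @param data a [genotype_dataset].
#' @param sample_subset `"all"` or a group label naming the samples to use.
#' @return An object of class `allele_frequency_set`: `frequencies`
#'   (per-marker B-allele frequency), `n_samples_used` (non-missing count
#'   per marker) and `scope`.
#' @export
allele_frequencies <- function(data, sample_subset = "all") {
  stopifnot(inherits(data, "genotype_dataset"))
  idx <- group_index(data, sample_subset)
  dos <- data$dosages[idx, , drop = FALSE]
  n_used <- colSums(!is.na(dos))
  p <- colSums(dos, na.rm = TRUE) / (2 * n_used)
  p[n_used == 0] <- NA_real_
  structure(list(frequencies = unname(p),
                 n_samples_used = unname(n_used),
                 marker_id = data$markers$id,
                 scope = sample_subset),
            class = "allele_frequency_set")
}
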