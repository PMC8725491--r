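#' Expected heterozygosity from allele frequencies
#'
#' Per-marker expected heterozygosity under Hardy-Weinberg equilibrium,
#' H_exp = 2 p (1 - p), summarised by its mean and standard deviation
#' across markers.
#'
#' @param freqs an [allele_frequencies] result.
#' @return A list (class `heterozygosity_summary`) with `per_marker`,
#'   `mean`, `sd`, `n_markers` and the `scope` of the frequencies.
#' @export
expected_heterozygosity <- function(freqs) {
  stopifnot(inherits(freqs, "allele_frequency_set"))
  p <- freqs$frequencies
  h <- 2 * p * (1 - p)
  structure(list(per_marker = h,
                 mean = mean(h, na.rm = TRUE),
                 sd = stats::sd(h[!is.na(h)]),
                 n_markers = sum(!is.na(h)),
                 statistic = "expected",
                 scope = freqs$scope),
            class = "heterozygosity_summary")
}

#' Observed heterozygosity per marker
#'
#' Per-marker proportion of heterozygous (dosage 1) genotypes among
#' non-missing calls in a group, summarised across markers. Markers with no
#' non-missing genotype in the group are excluded and counted. Fractional
#' (imputed) dosages do not count as heterozygous.
#'
#' @param data a [genotype_dataset].
#' @param group group label or `"all"`.
#' @return A `heterozygosity_summary` with `per_marker`, `mean`, `sd`,
#'   `n_markers`, `markers_excluded` and `n_samples`.
#' @export
observed_heterozygosity <- function(data, group = "all") {
  stopifnot(inherits(data, "genotype_dataset"))
  idx <- group_index(data, group)
  dos <- data$dosages[idx, , drop = FALSE]
  n_called <- colSums(!is.na(dos))
  h <- colSums(dos == 1, na.rm = TRUE) / n_called
  excluded <- sum(n_called == 0)
  h[n_called == 0] <- NA_real_
  ok <- !is.na(h)
  structure(list(per_marker = unname(h),
                 mean = mean(h[ok]),
                 sd = stats::sd(h[ok]),
                 n_markers = sum(ok),
                 markers_excluded = excluded,
                 statistic = "observed",
                 n_samples = length(idx),
                 scope = group),
            class = "heterozygosity_summary")
}

#' @export
print.heterozygosity_summary <- function(x, ...) {
  cat(sprintf("%s heterozygosity (%s): mean %.4f sd %.4f over %d markers\n",
              x$statistic, x$scope, x$mean, x$sd, x$n_markers))
  invisible(x)
}

#' Heterozygosity summary table per group
#'
#' Convenience wrapper producing one row per group with sample count and
#' mean +/- SD expected and observed heterozygosity, frequencies computed
#' within each group.
#'
#' @param data a [genotype_dataset].
#' @param groups group labels to include; default all groups present.
#' @return A data frame with columns `group`, `n`, `hexp_mean`, `hexp_sd`,
#'   `hobs_mean`, `hobs_sd`.
#' @export
heterozygosity_table <- function(data, groups = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (is.null(groups)) groups <- unique(data$samples$group)
  rows <- lapply(groups, function(g) {
    he <- expected_heterozygosity(allele_frequencies(data, g))
    ho <- observed_heterozygosity(data, g)
    data.frame(group = g, n = ho$n_samples,
               hexp_mean = he$mean, hexp_sd = he$sd,
               hobs_mean = ho$mean, hobs_sd = ho$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
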