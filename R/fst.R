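#' Weir-Cockerham variance components and the ratio-of-sums F_ST
#'
#' Computes, per marker, the among-population (a), among-individuals-
#' within-population (b) and within-individual (c) variance components of
#' the Weir-Cockerham F-statistic framework, and the ratio-of-sums
#' estimator theta_W = sum(a) / sum(a + b + c). Summation across markers
#' happens before division — the ratio-of-sums, not a mean of per-marker
#' ratios. Negative per-marker components are retained in the sums, as the
#' estimator is defined on raw components.
#'
#' With r groups and per-group sample size n_i, B-allele frequency p_i and
#' observed heterozygote proportion h_i at a marker:
#' \deqn{\bar n = \sum n_i / r,\quad
#'       n_c = (r \bar n - \sum n_i^2/(r \bar n)) / (r - 1)}
#' \deqn{\bar p = \sum n_i p_i / (r \bar n),\quad
#'       s^2 = \sum n_i (p_i - \bar p)^2 / ((r-1) \bar n),\quad
#'       \bar h = \sum n_i h_i / (r \bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'       \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 -
#'       \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'       \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right],\quad
#'       c = \bar h / 2}
#'
#' Markers monomorphic across all groups (a = b = c = 0) are skipped and
#' counted, as are markers where any group has fewer than two genotyped
#' individuals.
#'
#' @param n markers x groups matrix of genotyped sample counts.
#' @param p markers x groups matrix of B-allele frequencies.
#' @param h markers x groups matrix of observed heterozygote proportions.
#' @return An object of class `fst_components`: `per_marker_a/b/c`,
#'   `theta_w`, `markers_used`, `markers_skipped`.
#' @export
weir_cockerham_components <- function(n, p, h) {
  n <- as_marker_group_matrix(n)
  p <- as_marker_group_matrix(p)
  h <- as_marker_group_matrix(h)
  stopifnot(all(dim(n) == dim(p)), all(dim(n) == dim(h)))
  r <- ncol(n)
  if (r < 2) stop("need at least two groups")

  usable <- rowSums(n < 2) == 0
  nbar <- rowSums(n) / r
  nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n * p) / (r * nbar)
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2

  mono <- (pbar == 0 | pbar == 1) & hbar == 0
  keep <- usable & !mono & is.finite(a + b + cc)
  if (!any(keep)) stop("no usable polymorphic markers for F_ST")
  denom <- sum(a[keep] + b[keep] + cc[keep])
  theta <- sum(a[keep]) / denom

  structure(list(per_marker_a = a, per_marker_b = b, per_marker_c = cc,
                 markers_included = keep,
                 theta_w = theta,
                 markers_used = sum(keep),
                 markers_skipped = sum(!keep)),
            class = "fst_components")
}

as_marker_group_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

#' @export
print.fst_components <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta_W = %.6f (%d markers used, %d skipped)\n",
              x$theta_w, x$markers_used, x$markers_skipped))
  invisible(x)
}

# Per-group per-marker (n, p, h) summaries used by the F_ST estimator.
group_marker_summaries <- function(data, groups) {
  n <- p <- h <- matrix(NA_real_, ncol(data$dosages), length(groups))
  colnames(n) <- colnames(p) <- colnames(h) <- groups
  for (j in seq_along(groups)) {
    idx <- group_index(data, groups[j])
    dos <- data$dosages[idx, , drop = FALSE]
    called <- colSums(!is.na(dos))
    n[, j] <- called
    p[, j] <- ifelse(called > 0, colSums(dos, na.rm = TRUE) / (2 * called), 0)
    h[, j] <- ifelse(called > 0, colSums(dos == 1, na.rm = TRUE) / called, 0)
  }
  list(n = n, p = p, h = h)
}

#' Pairwise F_ST between all group pairs
#'
#' For every unordered pair of groups the Weir-Cockerham ratio-of-sums
#' estimator is computed using only the two groups of the pair (their own
#' sample sizes, frequencies and heterozygote proportions). Markers
#' monomorphic across a pair are dropped for that pair only. Pairs
#' involving a singleton group are reported as `NA`.
#'
#' @param data a [genotype_dataset].
#' @param groups group labels to compare; default all groups present.
#' @return An object of class `fst_matrix`: a symmetric matrix of theta_W
#'   with `NA` diagonal, plus per-pair marker counts.
#' @export
pairwise_fst <- function(data, groups = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (is.null(groups)) groups <- unique(data$samples$group)
  if (length(groups) < 2) stop("need at least two groups")
  sizes <- table(factor(data$samples$group, levels = groups))
  gs <- group_marker_summaries(data, groups)
  k <- length(groups)
  m <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  used <- matrix(NA_integer_, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (sizes[i] < 2 || sizes[j] < 2) next  # singleton pair undefined
      comp <- tryCatch(
        weir_cockerham_components(gs$n[, c(i, j), drop = FALSE],
                                  gs$p[, c(i, j), drop = FALSE],
                                  gs$h[, c(i, j), drop = FALSE]),
        error = function(e) NULL)  # no shared polymorphic markers
      if (is.null(comp)) next
      m[i, j] <- m[j, i] <- comp$theta_w
      used[i, j] <- used[j, i] <- comp$markers_used
    }
  }
  structure(list(groups = groups, theta = m, markers_used = used),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat("pairwise Weir-Cockerham F_ST:\n")
  print(round(x$theta, digits))
  invisible(x)
}

#' Write a pairwise F_ST matrix as a delimited table
#'
#' Upper triangle populated, diagonal and lower triangle blank, mirroring
#' the usual publication layout.
#'
#' @param x an `fst_matrix`.
#' @param path output file.
#' @param digits decimal places (default 4).
#' @return `path`, invisibly.
#' @export
write_fst_matrix <- function(x, path, digits = 4) {
  stopifnot(inherits(x, "fst_matrix"))
  k <- length(x$groups)
  out <- matrix("", k, k, dimnames = list(x$groups, x$groups))
  for (i in seq_len(k)) for (j in seq_len(k))
    if (j > i && !is.na(x$theta[i, j]))
      out[i, j] <- formatC(x$theta[i, j], format = "f", digits = digits)
  df <- data.frame(group = x$groups, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
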