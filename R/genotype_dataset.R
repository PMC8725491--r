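#' Construct a genotype dataset
#'
#' The central container of the package: a sample-by-marker matrix of
#' B-allele dosages (0, 1, 2 or `NA`) under the Illumina AB calling
#' convention, together with an ordered marker map and a sample table
#' carrying group (and optionally country) labels.
#'
#' Markers are sorted by (chromosome, position) on construction; positions
#' must be strictly increasing within each chromosome. Chromosome labels are
#' opaque strings: if every label parses as a number they are ordered
#' numerically, otherwise lexicographically. Dosages are allowed to be
#' fractional (mean imputation produces continuous values) but must lie in
#' \[0, 2\].
#'
#' @param dosages numeric matrix, samples in rows, markers in columns.
#' @param markers data frame with columns `id`, `chrom`, `pos` (1-based
#'   base pairs), one row per column of `dosages`.
#' @param samples data frame with columns `id`, `group` and optionally
#'   `country`, one row per row of `dosages`.
#' @return An object of class `genotype_dataset` (a list with elements
#'   `dosages`, `markers`, `samples`).
#' @export
genotype_dataset <- function(dosages, markers, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  if (!all(c("id", "chrom", "pos") %in% names(markers)))
    stop("markers must have columns id, chrom, pos")
  if (!all(c("id", "group") %in% names(samples)))
    stop("samples must have columns id, group")
  markers$id <- as.character(markers$id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.numeric(markers$pos)
  samples$id <- as.character(samples$id)
  samples$group <- as.character(samples$group)

  if (nrow(markers) != ncol(dosages))
    stop("marker table has ", nrow(markers), " rows but dosage matrix has ",
         ncol(dosages), " columns")
  if (nrow(samples) != nrow(dosages))
    stop("sample table has ", nrow(samples), " rows but dosage matrix has ",
         nrow(dosages), " rows")
  if (anyDuplicated(markers$id))
    stop("duplicate marker ids: ",
         paste(utils::head(markers$id[duplicated(markers$id)], 5), collapse = ", "))
  if (anyDuplicated(samples$id))
    stop("duplicate sample ids: ",
         paste(utils::head(samples$id[duplicated(samples$id)], 5), collapse = ", "))
  if (any(is.na(samples$group)) || any(samples$group == ""))
    stop("every sample needs a non-empty group label")

  if (any(!is.na(dosages) & (dosages < 0 | dosages > 2)))
    stop("dosages outside [0, 2] (range observed: ",
         paste(range(dosages, na.rm = TRUE), collapse = " to "), ")")

  ord <- order(match(markers$chrom, chrom_order(markers$chrom)), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  rownames(markers) <- NULL
  rownames(samples) <- NULL

  dup <- stats::ave(markers$pos, markers$chrom,
                    FUN = function(p) c(FALSE, diff(p) <= 0))
  if (any(dup > 0))
    stop("positions not strictly increasing within chromosome near marker ",
         markers$id[which(dup > 0)[1]])

  dimnames(dosages) <- list(samples$id, markers$id)
  structure(list(dosages = dosages, markers = markers, samples = samples),
            class = "genotype_dataset")
}

# Deterministic chromosome ordering: numeric when all labels are numeric,
# lexicographic otherwise.
chrom_order <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else sort(u)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "markers\n")
  cat("  chromosomes:", length(unique(x$markers$chrom)),
      " missing dosages:", sum(is.na(x$dosages)), "\n")
  grp <- table(x$samples$group)
  cat("  groups:", paste(names(grp), "(", as.integer(grp), ")",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

#' Subset a genotype dataset by samples and/or markers
#'
#' @param data a `genotype_dataset`.
#' @param samples sample ids, logical mask or indices; `NULL` keeps all.
#' @param markers marker ids, logical mask or indices; `NULL` keeps all.
#' @return A `genotype_dataset` restricted to the selection.
#' @export
subset_genotypes <- function(data, samples = NULL, markers = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  si <- resolve_index(samples, data$samples$id, "sample")
  mi <- resolve_index(markers, data$markers$id, "marker")
  genotype_dataset(data$dosages[si, mi, drop = FALSE],
                   data$markers[mi, , drop = FALSE],
                   data$samples[si, , drop = FALSE])
}

resolve_index <- function(sel, ids, what) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.logical(sel)) {
    stopifnot(length(sel) == length(ids))
    return(which(sel))
  }
  if (is.character(sel)) {
    idx <- match(sel, ids)
    if (anyNA(idx))
      stop("unknown ", what, " id(s): ",
           paste(utils::head(sel[is.na(idx)], 5), collapse = ", "))
    return(idx)
  }
  as.integer(sel)
}

# Indices of the samples belonging to a group ("all" = everyone).
group_index <- function(data, group) {
  if (identical(group, "all")) return(seq_len(nrow(data$samples)))
  idx <- which(data$samples$group == group)
  if (length(idx) == 0) stop("no samples in group '", group, "'")
  idx
}
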