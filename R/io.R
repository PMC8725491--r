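#' Read a genotype panel from disk
#'
#' Three text dialects are supported:
#' \describe{
#'   \item{`plink-ped`}{PLINK `.ped`/`.map` pair. `path` is the basename or
#'     either file; six leading ped columns (family, id, father, mother, sex,
#'     phenotype) then two space-separated alleles per marker coded `A`/`B`,
#'     missing as `0 0`. The family column is used as the group label.}
#'   \item{`additive-table`}{a delimited table with a header of marker ids,
#'     a leading `id` column of sample ids, and integer dosages with `NA`
#'     for missing; a `.map` file with the same basename supplies the map.}
#'   \item{`dosage-matrix`}{three files sharing a basename: `<base>.dose`
#'     (samples x markers dosage matrix with header and id column, `NA`
#'     missing), `<base>.map` (marker id, chromosome, position) and
#'     `<base>.groups` (sample id, group, optional country).}
#' }
#' Markers are re-sorted by (chromosome, position) on load.
#'
#' @param path file path or basename, see above.
#' @param format one of `"plink-ped"`, `"additive-table"`, `"dosage-matrix"`.
#' @param groups optional path to a groups file (sample id, group, optional
#'   country) overriding group labels found in the genotype files.
#' @return A [genotype_dataset].
#' @export
read_genotypes <- function(path,
                           format = c("plink-ped", "additive-table",
                                      "dosage-matrix"),
                           groups = NULL) {
  format <- match.arg(format)
  data <- switch(format,
    "plink-ped" = read_plink_ped(path),
    "additive-table" = read_additive_table(path),
    "dosage-matrix" = read_dosage_matrix(path))
  if (!is.null(groups)) {
    g <- read_groups_file(groups)
    idx <- match(data$samples$id, g$id)
    if (anyNA(idx))
      stop("groups file missing sample(s): ",
           paste(utils::head(data$samples$id[is.na(idx)], 5), collapse = ", "))
    data$samples$group <- g$group[idx]
    if (!is.null(g$country)) data$samples$country <- g$country[idx]
    data <- genotype_dataset(data$dosages, data$markers, data$samples)
  }
  data
}

#' Write a genotype panel to disk
#'
#' Inverse of [read_genotypes] for every supported dialect; a round trip is
#' lossless (up to the continuous dosages that only the `dosage-matrix`
#' dialect can carry).
#'
#' @param data a [genotype_dataset]; `plink-ped` and `additive-table` require
#'   integer dosages.
#' @param path basename for the output file set.
#' @param format one of `"plink-ped"`, `"additive-table"`, `"dosage-matrix"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(data, path,
                            format = c("plink-ped", "additive-table",
                                       "dosage-matrix")) {
  format <- match.arg(format)
  stopifnot(inherits(data, "genotype_dataset"))
  switch(format,
    "plink-ped" = write_plink_ped(data, path),
    "additive-table" = write_additive_table(data, path),
    "dosage-matrix" = write_dosage_matrix(data, path))
  invisible(path)
}

strip_ext <- function(path, exts) {
  for (e in exts) path <- sub(paste0("\\.", e, "$"), "", path)
  path
}

# PLINK maps have 4 columns (chrom id cm pos); the dosage-matrix dialect
# uses 3 (id chrom pos).
read_map_file <- function(path) {
  map <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) == 4) names(map) <- c("chrom", "id", "cm", "pos")
  else if (ncol(map) == 3) names(map) <- c("id", "chrom", "pos")
  else stop("map file must have 3 (id chrom pos) or 4 (chrom id cm pos) columns")
  data.frame(id = as.character(map$id), chrom = as.character(map$chrom),
             pos = as.numeric(map$pos), stringsAsFactors = FALSE)
}

read_plink_ped <- function(path) {
  base <- strip_ext(path, c("ped", "map"))
  ped_path <- paste0(base, ".ped"); map_path <- paste0(base, ".map")
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map <- read_map_file(map_path)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nfield <- lengths(fields)
  expected <- 6 + 2 * nrow(map)
  if (any(nfield != expected))
    stop("ped/map mismatch: map lists ", nrow(map), " markers (",
         expected, " ped fields) but ped line(s) have ",
         paste(unique(nfield[nfield != expected]), collapse = ", "), " fields")
  n <- length(fields)
  fam <- vapply(fields, `[`, "", 1)
  ids <- vapply(fields, `[`, "", 2)
  dos <- matrix(NA_real_, n, nrow(map))
  for (i in seq_len(n)) {
    al <- fields[[i]][-(1:6)]
    a1 <- al[seq(1, length(al), 2)]
    a2 <- al[seq(2, length(al), 2)]
    bad <- !(a1 %in% c("A", "B", "0")) | !(a2 %in% c("A", "B", "0"))
    if (any(bad))
      stop("non-biallelic or unrecognised allele at marker(s) ",
           paste(utils::head(map$id[bad], 5), collapse = ", "),
           " for sample ", ids[i], " (expected A/B coding, 0 0 missing)")
    miss <- a1 == "0" | a2 == "0"
    d <- (a1 == "B") + (a2 == "B")
    d[miss] <- NA_real_
    dos[i, ] <- d
  }
  genotype_dataset(dos, map,
                   data.frame(id = ids, group = fam, stringsAsFactors = FALSE))
}

write_plink_ped <- function(data, path) {
  base <- strip_ext(path, c("ped", "map"))
  if (any(!is.na(data$dosages) & data$dosages != round(data$dosages)))
    stop("plink-ped cannot represent fractional dosages")
  m <- data$markers
  utils::write.table(
    data.frame(m$chrom, m$id, 0, format(m$pos, scientific = FALSE, trim = TRUE)),
    paste0(base, ".map"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  dos <- data$dosages
  al1 <- ifelse(is.na(dos), "0", ifelse(dos >= 1, "B", "A"))
  al2 <- ifelse(is.na(dos), "0", ifelse(dos == 2, "B", "A"))
  lines <- vapply(seq_len(nrow(dos)), function(i) {
    paste(c(data$samples$group[i], data$samples$id[i], "0", "0", "0", "-9",
            as.vector(rbind(al1[i, ], al2[i, ]))), collapse = " ")
  }, "")
  writeLines(lines, paste0(base, ".ped"))
}

read_additive_table <- function(path) {
  base <- strip_ext(path, c("raw", "txt", "tsv"))
  map_path <- paste0(base, ".map")
  if (!file.exists(path)) stop("additive table not found: ", path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  map <- read_map_file(map_path)
  ids <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  if (ncol(dos) != nrow(map))
    stop("additive table has ", ncol(dos), " markers but map lists ", nrow(map))
  if (!setequal(colnames(dos), map$id))
    stop("marker ids in table header do not match the map")
  dos <- dos[, map$id, drop = FALSE]
  genotype_dataset(dos, map,
                   data.frame(id = ids, group = "all", stringsAsFactors = FALSE))
}

write_additive_table <- function(data, path) {
  base <- strip_ext(path, c("raw", "txt", "tsv"))
  if (any(!is.na(data$dosages) & data$dosages != round(data$dosages)))
    stop("additive-table cannot represent fractional dosages")
  m <- data$markers
  utils::write.table(
    data.frame(m$id, m$chrom, format(m$pos, scientific = FALSE, trim = TRUE)),
    paste0(base, ".map"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  tab <- data.frame(id = data$samples$id, data$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     na = "NA")
}

read_dosage_matrix <- function(path) {
  base <- strip_ext(path, c("dose", "map", "groups"))
  dose_path <- paste0(base, ".dose")
  map_path <- paste0(base, ".map")
  grp_path <- paste0(base, ".groups")
  for (p in c(dose_path, map_path, grp_path))
    if (!file.exists(p)) stop("file not found: ", p)
  tab <- utils::read.table(dose_path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  map <- read_map_file(map_path)
  grp <- read_groups_file(grp_path)
  ids <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  if (ncol(dos) != nrow(map))
    stop("dosage matrix has ", ncol(dos), " markers but map lists ", nrow(map))
  dos <- dos[, map$id, drop = FALSE]
  idx <- match(ids, grp$id)
  if (anyNA(idx))
    stop("groups file missing sample(s): ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  samples <- data.frame(id = ids, group = grp$group[idx],
                        stringsAsFactors = FALSE)
  if (!is.null(grp$country)) samples$country <- grp$country[idx]
  genotype_dataset(dos, map, samples)
}

write_dosage_matrix <- function(data, path) {
  base <- strip_ext(path, c("dose", "map", "groups"))
  m <- data$markers
  utils::write.table(
    data.frame(m$id, m$chrom, format(m$pos, scientific = FALSE, trim = TRUE)),
    paste0(base, ".map"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  tab <- data.frame(id = data$samples$id, data$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, paste0(base, ".dose"), quote = FALSE, sep = "\t",
                     row.names = FALSE, na = "NA")
  g <- data$samples[, intersect(c("id", "group", "country"),
                                names(data$samples)), drop = FALSE]
  utils::write.table(g, paste0(base, ".groups"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
}

#' Read a sample-to-group assignment file
#'
#' Two delimited columns (sample id, group label), optional third (country).
#'
#' @param path file path.
#' @return data frame with columns `id`, `group` and optionally `country`.
#' @export
read_groups_file <- function(path) {
  g <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(g) < 2) stop("groups file needs at least 2 columns (id, group)")
  out <- data.frame(id = as.character(g[[1]]), group = as.character(g[[2]]),
                    stringsAsFactors = FALSE)
  if (ncol(g) >= 3) out$country <- as.character(g[[3]])
  out
}
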