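#' Build a pipeline configuration
#'
#' A validated configuration for [run_pipeline]. Either `input` (paths to
#' genotype files) or `simulation` (a simulator spec) must be supplied.
#'
#' @param input `NULL`, or a list with `path`, `format` (see
#'   [read_genotypes]) and optionally `groups` (a groups-file path).
#' @param simulation `NULL`, or a list with `kind` (one of `"divergence"`,
#'   `"wright_fisher"`, `"families"`) and the corresponding simulator
#'   arguments; `families` takes a nested `base` divergence spec.
#' @param qc list of [qc_thresholds] arguments.
#' @param grm_subsets named list; each element is a character vector of
#'   group labels defining a subset GRM that is recomputed (re-centered and
#'   re-scaled) on those samples only.
#' @param pca_components leading components to keep (default 40).
#' @param ld list: `max_depth` (default 400), `min_group_size` (default 64,
#'   groups below it are excluded from the LD/Ne tables but kept
#'   elsewhere), `include_groups` (explicit per-group overrides of the
#'   size rule).
#' @param ne list: `current_t` (default 20 generations), `morgan_per_bp`
#'   (default 1e-8), `t_window` (default `c(2, 500)`).
#' @param seed master seed; every stage derives its own seed from it.
#' @param output_dir directory for the output tables.
#' @param write_grm also write the dense GRM (can be large).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            qc = list(), grm_subsets = list(),
                            pca_components = 40,
                            ld = list(), ne = list(),
                            seed = 1, output_dir = "snppop-out",
                            write_grm = FALSE) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of 'input' or 'simulation' must be given")
  ld <- utils::modifyList(list(max_depth = 400, min_group_size = 64,
                               include_groups = character()), ld)
  ne <- utils::modifyList(list(current_t = 20, morgan_per_bp = 1e-8,
                               t_window = c(2, 500)), ne)
  structure(list(input = input, simulation = simulation,
                 qc = qc, grm_subsets = grm_subsets,
                 pca_components = pca_components,
                 ld = ld, ne = ne, seed = as.integer(seed),
                 output_dir = output_dir, write_grm = isTRUE(write_grm)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

pipeline_stages <- c("data", "qc", "impute", "diversity", "fst", "grm",
                     "pca", "ld", "ne", "report")

# Deterministic per-stage seed derived from the master seed (kept well
# below 2^31).
stage_seed <- function(master, stage) {
  (as.integer(master) * 97L + match(stage, pipeline_stages) * 1009L) %% 2000000011L
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — load or simulate genotypes, quality
#' control, mean imputation, per-group heterozygosity and genomic
#' inbreeding, pairwise F_ST, GRM with block relatedness (full panel and
#' any configured subsets), PCA of the GRM, and per-group LD decay with Ne
#' trajectories — writing one delimited table per result into
#' `output_dir`, plus a JSON run manifest. A failure aborts with the stage
#' name and the list of completed stages. Given the same configuration and
#' seed, all tables are byte-identical across runs.
#'
#' Groups smaller than `ld$min_group_size` are dropped from the LD/Ne
#' tables (r-squared is strongly inflated at small N) but retained, with a
#' caution flag, everywhere else; `ld$include_groups` overrides the rule
#' per group.
#'
#' @param config a [pipeline_config], or the path of a YAML file.
#' @param through last stage to execute (default `"report"` = everything);
#'   earlier stages always run, later ones are skipped.
#' @return The run manifest (a list), invisibly.
#' @export
run_pipeline <- function(config, through = "report") {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  through <- match.arg(through, pipeline_stages)
  last <- match(through, pipeline_stages)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  completed <- character()
  counts <- list()
  run_stage <- function(name, fn, default = NULL) {
    if (match(name, pipeline_stages) > last) return(default)
    res <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (completed stages: ",
           paste(completed, collapse = ", "), ")", call. = FALSE))
    completed <<- c(completed, name)
    res
  }

  data <- run_stage("data", function() {
    if (!is.null(config$simulation)) {
      d <- simulate_from_spec(config$simulation, stage_seed(config$seed, "data"))
    } else {
      d <- read_genotypes(config$input$path, config$input$format,
                          groups = config$input$groups)
    }
    counts$samples_in <<- nrow(d$dosages)
    counts$markers_in <<- ncol(d$dosages)
    d
  })

  data <- run_stage("qc", default = data, function() {
    res <- apply_qc(data, do.call(qc_thresholds, config$qc))
    write_tsv(qc_report_table(res$report), file.path(out, "qc_report.tsv"))
    counts$markers_post_qc <<- res$report$markers_retained
    counts$samples_post_qc <<- res$report$samples_retained
    res$data
  })

  data <- run_stage("impute", default = data, function() mean_impute(data))

  groups <- unique(data$samples$group)
  group_sizes <- table(factor(data$samples$group, levels = groups))

  grm_full <- NULL
  het <- run_stage("diversity", function() heterozygosity_table(data))

  run_stage("fst", function() {
    if (length(groups) >= 2) {
      fst <- pairwise_fst(data)
      write_fst_matrix(fst, file.path(out, "fst_pairwise.tsv"))
      counts$fst_pairs <<- sum(!is.na(fst$theta[upper.tri(fst$theta)]))
    }
    NULL
  })

  run_stage("grm", function() {
    grm_full <<- compute_grm(data)
    inb <- genomic_inbreeding(grm_full)
    rel <- group_relatedness(grm_full)
    summary_tab <- merge(het, inbreeding_table(inb), by = "group", sort = FALSE)
    summary_tab$ld_eligible <- ld_eligible(groups, group_sizes, config$ld)[
      match(summary_tab$group, groups)]
    write_tsv(summary_tab, file.path(out, "group_summary.tsv"))
    write_tsv(relatedness_table(rel), file.path(out, "group_relatedness.tsv"))
    if (config$write_grm) write_grm(grm_full, file.path(out, "grm_dense.tsv"))
    for (nm in names(config$grm_subsets)) {
      sub <- subset_genotypes(
        data, samples = data$samples$group %in% config$grm_subsets[[nm]])
      g <- compute_grm(sub)  # recomputed frequencies: re-centered, re-scaled
      write_tsv(inbreeding_table(genomic_inbreeding(g)),
                file.path(out, paste0("inbreeding_subset_", nm, ".tsv")))
      write_tsv(relatedness_table(group_relatedness(g)),
                file.path(out, paste0("group_relatedness_subset_", nm, ".tsv")))
    }
    NULL
  })

  run_stage("pca", function() {
    pca <- grm_pca(grm_full, config$pca_components)
    scores <- data.frame(id = rownames(pca$scores), group = pca$groups,
                         pca$scores, check.names = FALSE)
    write_tsv(scores, file.path(out, "pca_scores.tsv"))
    write_tsv(data.frame(component = seq_along(pca$pov),
                         eigenvalue = pca$eigenvalues, pov = pca$pov,
                         cumulative_pov = pca$cumulative_pov),
              file.path(out, "pca_pov.tsv"))
    counts$pca_components <<- length(pca$pov)
    NULL
  })

  ld_results <- run_stage("ld", function() {
    eligible <- groups[ld_eligible(groups, group_sizes, config$ld)]
    res <- list()
    for (g in eligible) {
      sub <- subset_genotypes(data, samples = data$samples$group == g)
      rec <- pairwise_ld(sub, max_depth = config$ld$max_depth)
      curve <- syntenic_decay(rec, sub$markers)
      write_tsv(curve, file.path(out, paste0("ld_decay_", g, ".tsv")))
      res[[g]] <- list(curve = curve, nonsyn = nonsyntenic_ld(rec),
                       n = as.integer(group_sizes[[g]]))
    }
    counts$ld_groups <<- length(res)
    res
  })

  run_stage("ne", function() {
    rows <- lapply(names(ld_results), function(g) {
      r <- ld_results[[g]]
      traj <- ne_from_ld(r$curve, morgan_per_bp = config$ne$morgan_per_bp,
                         current_t = config$ne$current_t,
                         t_window = config$ne$t_window)
      write_tsv(traj[traj$in_window, , drop = FALSE],
                file.path(out, paste0("ne_trajectory_", g, ".tsv")))
      data.frame(group = g, n = r$n,
                 adjacent_r2 = r$curve$mean_r2[1],
                 nonsyntenic_r2 = r$nonsyn$mean_r2,
                 ne_current = current_ne(traj),
                 ne_t_bin = attr(traj, "current_t_bin"))
    })
    excluded <- setdiff(groups, names(ld_results))
    tab <- do.call(rbind, rows)
    write_tsv(tab, file.path(out, "ld_ne_summary.tsv"))
    if (length(excluded))
      writeLines(c("group\treason",
                   paste0(excluded, "\tbelow_min_group_size")),
                 file.path(out, "ld_excluded_groups.tsv"))
    NULL
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("snppop")),
    seed = config$seed,
    config = unclass(config),
    stages_completed = completed,
    counts = counts,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  run_stage("report", function() make_report(out))
  invisible(manifest)
}

simulate_from_spec <- function(spec, seed) {
  kind <- spec$kind
  args <- spec[setdiff(names(spec), "kind")]
  if (is.null(args$seed)) args$seed <- seed
  switch(kind,
    divergence = do.call(simulate_divergent_populations, args),
    wright_fisher = do.call(simulate_wright_fisher, args),
    families = {
      base_args <- args$base
      if (is.null(base_args$seed)) base_args$seed <- seed + 1L
      base <- do.call(simulate_divergent_populations, base_args)
      args$base <- base
      do.call(simulate_families, args)
    },
    stop("unknown simulation kind: ", kind))
}

ld_eligible <- function(groups, sizes, ld_cfg) {
  as.integer(sizes) >= ld_cfg$min_group_size | groups %in% ld_cfg$include_groups
}

qc_report_table <- function(report) {
  data.frame(
    rule = c("marker_call_rate", "marker_maf", "sample_call_rate"),
    removed = c(report$markers_removed_by_rule[["call_rate"]],
                report$markers_removed_by_rule[["maf"]],
                report$samples_removed),
    retained = c(NA, report$markers_retained, report$samples_retained))
}

inbreeding_table <- function(inb) {
  tab <- inb$by_group
  names(tab) <- c("group", "n", "fvr_min", "fvr_mean", "fvr_sd", "fvr_max")
  tab$mean_g_diagonal <- inb$mean_diagonal
  tab
}

relatedness_table <- function(rel) {
  tab <- as.data.frame(rel$block_means)
  data.frame(group = rel$groups, tab,
             external_mean = rel$external_mean[rel$groups],
             check.names = FALSE, row.names = NULL)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Summarise a pipeline run into a single report
#'
#' Scans the output directory of [run_pipeline] and writes `report.md`, a
#' navigable markdown summary embedding the group summary, F_ST matrix,
#' block relatedness, POV table and LD/Ne summary, and pointing at the
#' plot-ready series (decay curves, trajectories, PCA scores). Tables that
#' are missing are listed; the report is still produced.
#'
#' @param output_dir a [run_pipeline] output directory.
#' @return The report path, invisibly.
#' @export
make_report <- function(output_dir) {
  expect <- c("qc_report.tsv", "group_summary.tsv", "fst_pairwise.tsv",
              "group_relatedness.tsv", "pca_scores.tsv", "pca_pov.tsv",
              "ld_ne_summary.tsv")
  present <- file.exists(file.path(output_dir, expect))
  lines <- c("# Population-genomic analysis report", "")
  embed <- function(title, file, max_rows = 30) {
    path <- file.path(output_dir, file)
    if (!file.exists(path)) return(character())
    tab <- readLines(path)
    shown <- utils::head(tab, max_rows + 1)
    c(paste("##", title), "", "```",
      shown,
      if (length(tab) > max_rows + 1)
        paste0("... (", length(tab) - 1, " rows total)"),
      "```", "")
  }
  lines <- c(lines,
             embed("Quality control", "qc_report.tsv"),
             embed("Heterozygosity and genomic inbreeding by group",
                   "group_summary.tsv"),
             embed("Pairwise F_ST", "fst_pairwise.tsv"),
             embed("Group-block relatedness (external mean in last column)",
                   "group_relatedness.tsv"),
             embed("Proportion of variance of the leading GRM components",
                   "pca_pov.tsv", 15),
             embed("Adjacent and non-syntenic LD, current Ne",
                   "ld_ne_summary.tsv"))
  excl <- file.path(output_dir, "ld_excluded_groups.tsv")
  if (file.exists(excl)) {
    ex <- utils::read.table(excl, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    lines <- c(lines, "## Groups excluded from LD/Ne", "",
               paste0("- ", ex$group, " (", ex$reason, ")"), "")
  }
  series <- list.files(output_dir,
                       pattern = "^(ld_decay_|ne_trajectory_|pca_scores)")
  lines <- c(lines, "## Plot-ready series", "",
             paste0("- `", series, "`"), "")
  if (any(!present))
    lines <- c(lines, "## Missing tables", "",
               paste0("- `", expect[!present], "`"), "")
  writeLines(lines, file.path(output_dir, "report.md"))
  invisible(file.path(output_dir, "report.md"))
}
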