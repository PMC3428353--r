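#' Load the packaged per-gene annotation table
#'
#' Reads the packaged transcription of the published summary table for the
#' 90 wasp OBP genes (scaffold, coding status, EST support, subfamily).
#' The table is shipped verbatim, including its internal inconsistencies
#' (e.g. pseudogenes listed with full EST support), which are preserved
#' rather than corrected.
#'
#' @param path Fixture path; defaults to the packaged copy.
#' @return Data frame with columns `name`, `scaffold`, `status`,
#'   `est_support`, `subfamily`, `notes`.
#' @export
load_annotation_fixture <- function(path = system.file(
                                      "extdata", "gene_annotations.tsv",
                                      package = "obpscaffold")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("annotation fixture not found")
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   na.strings = character(0))
  needed <- c("name", "scaffold", "status", "est_support", "subfamily")
  if (!all(needed %in% names(df))) {
    stop("annotation fixture malformed: need columns ",
         paste(needed, collapse = ", "))
  }
  df
}

#' Summarise a per-gene annotation table
#'
#' Counts genes by coding status, EST support and subfamily. A gene counts
#' as double-domain when its subfamily label contains the double-domain
#' marker (`"Double"`).
#'
#' @param table Data frame as returned by [load_annotation_fixture()].
#' @return List with `n_genes`, `by_status`, `by_est_support`,
#'   `by_subfamily` (tables) and `n_double_domain`.
#' @export
summarize_annotations <- function(table) {
  if (anyDuplicated(table$name)) {
    stop("duplicate gene names: ",
         paste(unique(table$name[duplicated(table$name)]), collapse = ", "))
  }
  if (any(!nzchar(table$name))) stop("empty gene name")
  list(n_genes = nrow(table),
       by_status = table(table$status),
       by_est_support = table(table$est_support),
       by_subfamily = table(table$subfamily),
       n_double_domain = sum(grepl("Double", table$subfamily,
                                   fixed = TRUE)))
}

#' Run the cysteine-scaffold analysis pipeline
#'
#' Executes profile -> classify -> loss inference -> event tabulation ->
#' bond-bias test, in one of three modes:
#' \describe{
#'   \item{`fixtures`}{reproduces the packaged reference analysis: loads
#'     the packaged loss-event and annotation tables, tabulates events,
#'     counts two-cysteine and bond-pair events, computes the bond-bias
#'     p-value and the site-model LRT p-values, and summarises the gene
#'     annotations. No sequence analysis is recomputed.}
#'   \item{`simulate`}{simulates a family (see [simulate_family()]),
#'     writes it under `out_dir`, re-reads the written files through the
#'     package readers and runs the full inference chain on them.}
#'   \item{`files`}{reads a user alignment (`alignment`, with optional
#'     `format`) and Newick `tree` from `config` and runs the chain.}
#' }
#'
#' @param config Named list. `mode` selects the branch above; `simulate`
#'   mode accepts any [simulation_config()] argument; `files` mode needs
#'   `alignment` and `tree` paths.
#' @param out_dir Optional directory for TSV/JSON reports and the run log.
#' @return A report list; see details of each mode.
#' @export
run_pipeline <- function(config = list(mode = "fixtures"), out_dir = NULL) {
  mode <- config$mode %||% "fixtures"
  report <- switch(
    mode,
    fixtures = pipeline_fixtures(),
    simulate = pipeline_simulate(config, out_dir),
    files = pipeline_files(config),
    stop("unknown pipeline mode: ", mode))
  report$mode <- mode
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_fixtures <- function() {
  events <- load_event_fixture()
  tab <- tabulate_events(events)
  xy <- count_bond_events(tab)
  bias <- bond_bias_pvalue(xy[["x"]], xy[["y"]])
  lrt <- lrt_table(read_lrt_table())
  ann <- summarize_annotations(load_annotation_fixture())
  list(event_table = tab,
       total_events = sum(tab$event_count),
       x = bias$x, y = bias$y, q = bias$q, p_value = bias$p_value,
       lrt = lrt, annotation_summary = ann)
}

pipeline_simulate <- function(config, out_dir) {
  sim_args <- config[setdiff(names(config), "mode")]
  cfg <- do.call(simulation_config, sim_args)
  fam <- simulate_family(cfg)
  dir <- out_dir %||% tempfile("obpsim")
  paths <- write_family(fam, dir)
  aln <- read_alignment(paths[["alignment"]])
  tree <- ape::read.tree(paths[["tree"]])
  cols <- new_canonical_columns(fam$scaffold_columns, aln$length)
  prof <- profile_alignment(aln, cols, mature_start = cfg$mature_start)
  events <- infer_losses(tree, prof)
  tab <- tabulate_events(events)
  xy <- count_bond_events(tab)
  bias <- bond_bias_pvalue(xy[["x"]], xy[["y"]])
  list(family = fam, profiles = prof, events = events, event_table = tab,
       total_events = sum(tab$event_count),
       truth_total_events = length(fam$truth_events),
       x = bias$x, y = bias$y, q = bias$q, p_value = bias$p_value,
       files = paths)
}

pipeline_files <- function(config) {
  if (is.null(config$alignment) || is.null(config$tree)) {
    stop("files mode needs 'alignment' and 'tree' paths in the config")
  }
  for (p in c(config$alignment, config$tree)) {
    if (!file.exists(p)) stop("input not found: ", p)
  }
  aln <- read_alignment(config$alignment,
                        format = config$format %||% "fasta")
  tree <- ape::read.tree(config$tree)
  cols <- if (!is.null(config$reference_ids)) {
    # reference mode survives family-wide losses that sink a canonical
    # column's occupancy below any majority threshold
    locate_canonical_columns(aln, mode = "reference",
                             reference_ids = config$reference_ids)
  } else {
    locate_canonical_columns(aln, min_fraction = config$min_fraction %||% 0.5)
  }
  prof <- profile_alignment(aln, cols,
                            mature_start = config$mature_start %||% 25L)
  events <- infer_losses(tree, prof,
                         mode = config$parsimony %||% "dollo")
  tab <- tabulate_events(events)
  xy <- count_bond_events(tab)
  bias <- bond_bias_pvalue(xy[["x"]], xy[["y"]])
  list(canonical_columns = cols, profiles = prof, events = events,
       event_table = tab, total_events = sum(tab$event_count),
       x = bias$x, y = bias$y, q = bias$q, p_value = bias$p_value)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$event_table)) {
    write_event_table(report$event_table,
                      file.path(out_dir, "event_table.tsv"))
  }
  summary <- report[intersect(names(report),
                              c("mode", "total_events",
                                "truth_total_events", "x", "y", "q",
                                "p_value"))]
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- c(paste("obpscaffold version:",
                 as.character(utils::packageVersion("obpscaffold"))),
           paste("R version:", R.version.string),
           paste("mode:", report$mode %||% "unknown"))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
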