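# End-to-end pipeline: simulate / analyze / report with file artifacts.

#' Run the index-switching pipeline
#'
#' Ties the stages together behind a single configuration: optionally
#' simulate a batch to fixture files, then read the expression matrix and
#' layout, fit the switching model, and write every report table plus a
#' machine-readable summary.  Identical config and inputs produce identical
#' outputs.
#'
#' @param config A list (or path to a YAML file holding one) with fields:
#'   \describe{
#'     \item{simulate}{optional list of \code{\link{sim_params}} arguments;
#'       when present the batch is simulated and its fixtures written to
#'       \code{out_dir} before analysis.}
#'     \item{layout,expression}{paths to the layout YAML and expression TSV
#'       (ignored when simulating).}
#'     \item{batch_id}{which batch of the layout to analyze (default: the
#'       first).}
#'     \item{floor,clonal_threshold,fivefold,include_bcr,convention}{passed
#'       to \code{\link{fit_switching}}.}
#'     \item{out_dir}{output directory (created).}
#'   }
#' @return The \code{switch_fit}, invisibly; side effect: files
#'   \code{spread_report.tsv}, \code{curation.tsv}, \code{estimates.tsv},
#'   \code{propensities.tsv}, \code{summary.json} (and, when simulating,
#'   \code{expression.tsv}, \code{layout.yaml}, \code{truth.json}) under
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    params <- do.call(sim_params, config$simulate)
    sim <- generate_batch(params)
    table <- sim$table; space <- sim$space
    write_expression_matrix(table, file.path(out_dir, "expression.tsv"))
    yaml::write_yaml(list(batches = list(space_to_config(space))),
                     file.path(out_dir, "layout.yaml"))
    jsonlite::write_json(
      list(marker_of_well = as.list(sim$truth$marker_of_well),
           clonal_pairs = sim$truth$clonal_pairs,
           s_row = sim$truth$s_row, s_col = sim$truth$s_col,
           contamination_rate = sim$truth$contamination_rate),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    spaces <- read_layout(config$layout %||% stop("config needs layout"))
    space <- spaces[[config$batch_id %||% 1L]]
    table <- read_expression_matrix(config$expression %||%
                                      stop("config needs expression"), space)
  }

  fit <- fit_switching(table, space,
                       floor = config$floor %||% 0,
                       clonal_threshold = config$clonal_threshold %||% 0.1,
                       fivefold = config$fivefold %||% 5,
                       include_bcr = isTRUE(config$include_bcr),
                       convention = config$convention %||% "sum")
  write_reports(fit, out_dir)
  invisible(fit)
}

tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write the report files of a fit
#'
#' @param fit A \code{switch_fit}.
#' @param out_dir Output directory.
#' @return \code{out_dir}, invisibly.
#' @export
write_reports <- function(fit, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- fit$curation$profiles
  spread <- do.call(rbind, lapply(prof, function(p) data.frame(
    marker = p$marker, origin = p$origin,
    n_within_detected = length(p$detected_within),
    n_within_total = length(p$cross),
    n_outside_detected = length(p$detected_outside),
    n_outside_total = length(p$outside),
    sum_relexp = sum(p$relexp) - 1,
    n_clonal_flagged = length(p$clonal_flagged),
    stringsAsFactors = FALSE)))
  if (is.null(spread)) spread <- data.frame(marker = character(0))
  tsv(spread, file.path(out_dir, "spread_report.tsv"))

  curation <- rbind(
    if (nrow(fit$curation$accepted))
      data.frame(marker = fit$curation$accepted$marker, status = "accepted",
                 detail = fit$curation$accepted$sources),
    if (nrow(fit$curation$rejected))
      data.frame(marker = fit$curation$rejected$marker, status = "rejected",
                 detail = fit$curation$rejected$reason))
  if (is.null(curation))
    curation <- data.frame(marker = character(0), status = character(0),
                           detail = character(0))
  tsv(curation, file.path(out_dir, "curation.tsv"))
  tsv(fit$estimates, file.path(out_dir, "estimates.tsv"))
  tsv(fit$propensities, file.path(out_dir, "propensities.tsv"))

  s <- fit$summary
  cont <- fit$contamination_test
  jsonlite::write_json(list(
    batch_id = fit$space$batch_id,
    platform = fit$space$platform,
    n_markers_profiled = length(prof),
    n_low_evidence = nrow(fit$curation$low_evidence),
    n_accepted = nrow(fit$curation$accepted),
    n_source_wells = if (!is.null(s)) s$n_source_wells else 0L,
    misassignment = if (!is.null(s)) s$overall else NULL,
    misassignment_by_well = if (!is.null(s)) s$by_well else NULL,
    contamination_test = if (!is.null(cont))
      list(statistic = cont$statistic, df = cont$df, p_value = cont$p_value,
           degenerate = cont$degenerate) else NULL,
    conventions = fit$params,
    quantile_type = 7,
    package_version = as.character(utils::packageVersion("crossbleed"))),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(out_dir)
}
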