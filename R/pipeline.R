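# Orchestration: end-to-end commands mirroring the analysis workflow, each
# writing delimited-text and JSON reports plus the resolved configuration,
# so any run can be reproduced exactly from its output directory.

.write_config <- function(config, out_dir, extra = list()) {
  cfg <- c(unclass(config), extra)
  jsonlite::write_json(cfg, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Full MR analysis from summary-statistics files
#'
#' Reads exposure and outcome associations, selects instruments
#' (significance filter, cross-trait deduplication, exclusion list, LD
#' pruning per protocol), harmonizes alleles, runs all six estimators and
#' the heterogeneity/influence diagnostics, and writes the report files
#' (`mr_table.tsv`, `mr_results.json`, `heterogeneity.tsv`,
#' `leave_one_out.tsv`, `single_snp.tsv`, `instruments.tsv`,
#' `resolved_config.json`) to `out_dir`.
#'
#' @param exposure,outcome paths to summary-statistics files.
#' @param out_dir output directory (created if needed).
#' @param ld optional path to a pairwise LD table.
#' @param protocol instrument-screening protocol
#'   (`"r2_0.8"`, `"r2_0.001"`, `"lead_snp"`).
#' @param exclusions optional character vector (or path to a one-column
#'   file) of gene/variant identifiers to exclude.
#' @param p_threshold genome-wide significance cutoff.
#' @param palindrome_policy passed to [harmonize_set()].
#' @param column_map passed to [read_summary_stats()].
#' @param config an [mr_config()].
#' @return invisibly, a list with `instruments`, `results`,
#'   `heterogeneity`, `loo`, `single_snp`.
#' @export
cmd_mr <- function(exposure, outcome, out_dir, ld = NULL,
                   protocol = "r2_0.8", exclusions = NULL,
                   p_threshold = 5e-8, palindrome_policy = "drop",
                   column_map = default_column_map(),
                   config = mr_config()) {
  exp_df <- read_summary_stats(exposure, column_map)
  out_df <- read_summary_stats(outcome, column_map)
  ld_tab <- if (!is.null(ld)) read_ld_table(ld) else NULL
  if (!is.null(exclusions) && length(exclusions) == 1L &&
      file.exists(exclusions)) {
    exclusions <- readLines(exclusions, warn = FALSE)
  }
  sel <- select_instruments(exp_df, p_threshold, ld_tab, protocol, exclusions)
  instr <- harmonize_set(sel, out_df, palindrome_policy,
                         protocol_label = protocol)
  results <- mr_run_all(instr, config)
  het <- cochran_q(instr)
  loo <- leave_one_out(instr, config$ivw_model)
  sst <- single_snp_table(instr)

  .ensure_dir(out_dir)
  write_mr_report(results, file.path(out_dir, "mr_results"))
  file.rename(file.path(out_dir, "mr_results.tsv"),
              file.path(out_dir, "mr_table.tsv"))
  write.table(data.frame(q = het$q_statistic, df = het$df, pvalue = het$pvalue),
              file.path(out_dir, "heterogeneity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(loo, file.path(out_dir, "leave_one_out.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sst, file.path(out_dir, "single_snp.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_instruments(instr, file.path(out_dir, "instruments.tsv"))
  .write_config(config, out_dir,
                list(command = "mr", exposure = exposure, outcome = outcome,
                     ld = ld, protocol = protocol,
                     p_threshold = p_threshold,
                     palindrome_policy = palindrome_policy,
                     exclusions = exclusions))
  invisible(list(instruments = instr, results = results, heterogeneity = het,
                 loo = loo, single_snp = sst))
}

#' Mediation analysis command
#'
#' Reads a mediator table (columns `mediator, xm_beta, xm_se, my_beta,
#' my_se`), applies [mediate_all()] against the supplied total effect and
#' writes `mediation.tsv` / `mediation.json`.
#'
#' @param mediators path to the mediator table, or a `data.frame`.
#' @param total_beta,total_se the total exposure-outcome effect.
#' @param out_dir output directory.
#' @return invisibly, the mediation report `data.frame`.
#' @export
cmd_mediate <- function(mediators, total_beta, total_se, out_dir) {
  tab <- if (is.character(mediators)) {
    if (!file.exists(mediators)) {
      .stop_bcaamr(sprintf("input file not found: %s", mediators),
                   "bcaamr_io_error")
    }
    read.table(mediators, header = TRUE, sep = .sniff_sep(mediators),
               stringsAsFactors = FALSE)
  } else mediators
  mrs <- setNames(lapply(seq_len(nrow(tab)), function(i) {
    list(xm = c(tab$xm_beta[i], tab$xm_se[i]),
         my = c(tab$my_beta[i], tab$my_se[i]))
  }), tab$mediator)
  rep <- mediate_all(c(total_beta, total_se), mrs)
  .ensure_dir(out_dir)
  write.table(rep, file.path(out_dir, "mediation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(attr(rep, "results"),
                       file.path(out_dir, "mediation.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(rep)
}

#' Meta-analysis command
#'
#' Pools a study table overall and within a grouping column and writes
#' `meta.tsv` / `meta.json`.
#'
#' @param studies path to a study table (see [read_study_table()]) or a
#'   `data.frame`.
#' @param out_dir output directory.
#' @param group_field grouping column (default `"design"`).
#' @param model pooling model (see [pool_studies()]).
#' @return invisibly, the subgroup report `data.frame`.
#' @export
cmd_meta <- function(studies, out_dir, group_field = "design",
                     model = "random_dl") {
  tab <- if (is.character(studies)) {
    if (!file.exists(studies)) {
      .stop_bcaamr(sprintf("input file not found: %s", studies),
                   "bcaamr_io_error")
    }
    read_study_table(studies)
  } else study_effects(studies)
  rep <- subgroup_pool(tab, group_field, model)
  .ensure_dir(out_dir)
  write.table(rep, file.path(out_dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(attr(rep, "results"), file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(rep)
}

#' Write simulated summary statistics to disk
#'
#' Emits `exposure.tsv` and `outcome.tsv` in the exact format
#' [read_summary_stats()] consumes, plus `manifest.json` with the resolved
#' generator parameters (including the seed); identical parameters yield
#' bit-identical files.
#'
#' @param params a [sim_params()] object.
#' @param out_dir output directory.
#' @return invisibly, the simulation list from [simulate_two_sample()].
#' @export
cmd_simulate <- function(params, out_dir) {
  sim <- simulate_two_sample(params)
  .ensure_dir(out_dir)
  for (nm in c("exposure", "outcome")) {
    write.table(sim[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(unclass(sim$truth$params),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(sim)
}

#' Reproduce the headline BCAA-CAD causal analysis
#'
#' Runs all six estimators, the Cochran Q and leave-one-out diagnostics and
#' the variance-explained computation on the bundled 17-variant instrument
#' ([fixture_table2()]); no external inputs. With `out_dir` given, writes
#' the same report files as [cmd_mr()].
#'
#' @param out_dir optional output directory.
#' @param config an [mr_config()].
#' @return list with `instruments`, `results` (an `mr_result_set`),
#'   `heterogeneity`, `loo`, `single_snp`, `variance_explained`.
#' @export
reproduce_paper <- function(out_dir = NULL, config = mr_config()) {
  instr <- fixture_table2()
  results <- mr_run_all(instr, config)
  het <- cochran_q(instr)
  loo <- leave_one_out(instr, config$ivw_model)
  sst <- single_snp_table(instr)
  ve <- variance_explained(instr)
  if (!is.null(out_dir)) {
    .ensure_dir(out_dir)
    write_mr_report(results, file.path(out_dir, "mr_results"))
    file.rename(file.path(out_dir, "mr_results.tsv"),
                file.path(out_dir, "mr_table.tsv"))
    write.table(data.frame(q = het$q_statistic, df = het$df,
                           pvalue = het$pvalue),
                file.path(out_dir, "heterogeneity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(loo, file.path(out_dir, "leave_one_out.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sst, file.path(out_dir, "single_snp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .write_config(config, out_dir, list(command = "reproduce-paper",
                                        variance_explained = ve$total))
  }
  list(instruments = instr, results = results, heterogeneity = het,
       loo = loo, single_snp = sst, variance_explained = ve)
}
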