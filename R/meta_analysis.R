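# Random-effects meta-analysis of observational study effects.

#' Validate a table of study-level relative risks
#'
#' @param x `data.frame` with columns `study, rr, ci_low, ci_high` and
#'   optionally `design` (`"case_control"` / `"cohort"` / other labels).
#' @return the validated `data.frame` (class `study_effects`).
#' @export
study_effects <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- c("study", "rr", "ci_low", "ci_high")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    .stop_bcaamr(sprintf("study table lacks column(s): %s",
                         paste(missing, collapse = ", ")),
                 "bcaamr_config_error")
  }
  if (any(x$rr <= 0 | x$ci_low <= 0 | x$ci_high <= 0) ||
      any(x$ci_low > x$rr | x$rr > x$ci_high)) {
    .stop_bcaamr("study effects must satisfy 0 < ci_low <= rr <= ci_high",
                 "bcaamr_domain_error")
  }
  class(x) <- c("study_effects", "data.frame")
  x
}

#' Read a delimited study table
#'
#' @param path file with header columns `study, rr, ci_low, ci_high`
#'   (+ optional `design, n, cases`).
#' @return a [study_effects()] table.
#' @export
read_study_table <- function(path) {
  study_effects(read.table(path, header = TRUE, sep = .sniff_sep(path),
                           stringsAsFactors = FALSE))
}

#' Pool study effects by inverse-variance meta-analysis
#'
#' Pools on the log relative-risk scale, with per-study SEs back-computed
#' from the printed CIs. `"random_dl"` (default) uses the
#' DerSimonian-Laird between-study variance; `"fixed"` is the common-effect
#' model; `"random_reml"` is offered as an alternative. Model fitting is
#' delegated to [metafor::rma()]. Heterogeneity is summarized by Cochran Q
#' and `I2 = max(0, 100 (Q - df)/Q)`. A single study passes through with a
#' warning and no between-study variance.
#'
#' @param studies a [study_effects()] table (or coercible `data.frame`).
#' @param model `"random_dl"`, `"fixed"` or `"random_reml"`.
#' @param level CI coverage used both to read the per-study CIs and for the
#'   pooled CI.
#' @return list of class `meta_result`: `rr, ci_low, ci_high` (ratio
#'   scale), `log_rr, se`, `tau2`, `q, df, q_pvalue`, `i_squared`
#'   (percent), per-study `weights`, `k`, `model`.
#' @export
pool_studies <- function(studies, model = c("random_dl", "fixed", "random_reml"),
                         level = 0.95) {
  model <- match.arg(model)
  studies <- study_effects(studies)
  conv <- se_from_ci(studies$rr, studies$ci_low, studies$ci_high, level)
  yi <- conv$beta; sei <- conv$se
  k <- length(yi)
  z <- qnorm((1 + level) / 2)
  if (k == 1L) {
    warning("single study: pooled estimate is a pass-through", call. = FALSE)
    return(structure(list(rr = studies$rr, ci_low = studies$ci_low,
                          ci_high = studies$ci_high, log_rr = yi, se = sei,
                          tau2 = NA_real_, q = NA_real_, df = 0L,
                          q_pvalue = NA_real_, i_squared = NA_real_,
                          weights = setNames(1, studies$study), k = 1L,
                          model = model, single_study = TRUE),
                     class = "meta_result"))
  }
  method <- switch(model, random_dl = "DL", fixed = "FE", random_reml = "REML")
  fit <- metafor::rma(yi = yi, sei = sei, method = method, level = 100 * level)
  q <- as.numeric(fit$QE); df <- k - 1L
  structure(list(rr = exp(as.numeric(fit$beta)),
                 ci_low = exp(fit$ci.lb), ci_high = exp(fit$ci.ub),
                 log_rr = as.numeric(fit$beta), se = fit$se,
                 tau2 = if (method == "FE") 0 else fit$tau2,
                 q = q, df = df, q_pvalue = fit$QEp,
                 i_squared = max(0, 100 * (q - df) / q),
                 weights = setNames(metafor::weights.rma.uni(fit) /
                                      100, studies$study),
                 k = k, model = model, single_study = FALSE),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("pooled RR %.3f (%.3f-%.3f), k = %d, tau2 = %s, I2 = %s%%\n",
              x$rr, x$ci_low, x$ci_high, x$k,
              formatC(x$tau2, digits = 4, format = "g"),
              formatC(x$i_squared, digits = 3, format = "g")))
  invisible(x)
}

#' Subgroup meta-analysis
#'
#' Pools within each level of a grouping column (e.g. study design) and
#' appends the overall pooled row. Groups with one study pass through
#' flagged; empty groups are skipped with a warning.
#'
#' @param studies a [study_effects()] table.
#' @param group_field grouping column name (default `"design"`).
#' @inheritParams pool_studies
#' @return `data.frame` with one row per subgroup plus `"overall"`
#'   (group, k, rr, ci, tau2, i_squared, single_study flag); full
#'   `meta_result` objects in `attr(, "results")`.
#' @export
subgroup_pool <- function(studies, group_field = "design",
                          model = "random_dl", level = 0.95) {
  studies <- study_effects(studies)
  if (!group_field %in% names(studies)) {
    .stop_bcaamr(sprintf("grouping column '%s' not present", group_field),
                 "bcaamr_config_error")
  }
  groups <- split(seq_len(nrow(studies)), studies[[group_field]])
  results <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (!length(idx)) { warning("empty group skipped: ", g, call. = FALSE); next }
    results[[g]] <- suppressWarnings(
      pool_studies(studies[idx, , drop = FALSE], model, level))
  }
  results[["overall"]] <- pool_studies(studies, model, level)
  rows <- lapply(names(results), function(g) {
    r <- results[[g]]
    data.frame(group = g, k = r$k, rr = r$rr, ci_low = r$ci_low,
               ci_high = r$ci_high, tau2 = r$tau2, i_squared = r$i_squared,
               single_study = isTRUE(r$single_study), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
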