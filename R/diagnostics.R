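# Heterogeneity and influence diagnostics for a harmonized instrument set.

#' Cochran Q heterogeneity test for the IVW estimate
#'
#' Weighted dispersion of the per-variant Wald ratios around the pooled
#' IVW estimate: `Q = sum(w (ratio - beta_ivw)^2)`, referred to a
#' chi-square with `n - 1` degrees of freedom. First-order weights
#' `w = beta_exposure^2 / se_outcome^2` are the default; `second_order`
#' adds the exposure-side variance term to each ratio's SE (the modified
#' form).
#'
#' @param instr an [instrument_set()] with at least 2 variants.
#' @param second_order use second-order Wald-ratio weights.
#' @return list of class `heterogeneity_result`: `q_statistic`, `df`,
#'   `pvalue`.
#' @export
cochran_q <- function(instr, second_order = FALSE) {
  if (nrow(instr) < 2L) {
    .stop_bcaamr("heterogeneity testing requires at least 2 instruments",
                 "bcaamr_insufficient_instruments")
  }
  wr <- wald_ratio(instr, order = if (second_order) "second" else "first")
  b <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  q <- sum(wr$weight * (wr$ratio - b)^2)
  df <- nrow(wr) - 1L
  structure(list(q_statistic = q, df = df,
                 pvalue = pchisq(q, df, lower.tail = FALSE),
                 second_order = second_order),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran Q = %.3f on %d df, p = %.3g%s\n", x$q_statistic, x$df,
              x$pvalue, if (x$second_order) " (second-order weights)" else ""))
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Re-runs the IVW estimator on every n-1 subset. A subset is flagged when
#' its estimate changes sign relative to the full-set estimate or when its
#' CI excludes the full-set estimate — either indicates a single variant
#' driving the result.
#'
#' @param instr an [instrument_set()] with at least 2 variants.
#' @param model IVW flavor passed to [mr_ivw()].
#' @return `data.frame` of class `loo_result`: one row per left-out
#'   variant (`snp, beta, se, ci_low, ci_high, flagged`), with the full-set
#'   estimate in `attr(, "full")`.
#' @export
leave_one_out <- function(instr, model = "random_effects") {
  if (nrow(instr) < 2L) {
    .stop_bcaamr("leave-one-out requires at least 2 instruments",
                 "bcaamr_insufficient_instruments")
  }
  full <- mr_ivw(instr, model)
  rows <- lapply(seq_len(nrow(instr)), function(i) {
    e <- mr_ivw(instr[-i, , drop = FALSE], model)
    data.frame(snp = instr$snp[i], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high,
               flagged = (sign(e$beta) != sign(full$beta)) ||
                 full$beta < e$ci_low || full$beta > e$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  class(out) <- c("loo_result", "data.frame")
  out
}

#' Per-variant Wald ratio table with confidence intervals
#'
#' Deterministic single-variant causal estimates (forest-plot data),
#' ordered by variant identifier.
#'
#' @param instr an [instrument_set()].
#' @param order SE order passed to [wald_ratio()].
#' @return `data.frame`: `snp, ratio, se, ci_low, ci_high`.
#' @export
single_snp_table <- function(instr, order = "first") {
  wr <- wald_ratio(instr, order)
  out <- data.frame(snp = wr$snp, ratio = wr$ratio, se = wr$se,
                    ci_low = wr$ratio - .z95() * wr$se,
                    ci_high = wr$ratio + .z95() * wr$se,
                    stringsAsFactors = FALSE)
  out[order(out$snp), , drop = FALSE]
}

#' Forest plot of per-variant and pooled causal estimates
#'
#' Convenience display; not part of the numerical surface.
#'
#' @param instr an [instrument_set()].
#' @param pooled optional [mr_estimate()] drawn as a reference line.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted table.
#' @export
plot_forest <- function(instr, pooled = NULL, ...) {
  tab <- single_snp_table(instr)
  n <- nrow(tab)
  graphics::plot(tab$ratio, seq_len(n), xlim = range(tab$ci_low, tab$ci_high),
                 yaxt = "n", ylab = "", xlab = "causal estimate (log odds per SD)",
                 pch = 15, ...)
  graphics::segments(tab$ci_low, seq_len(n), tab$ci_high, seq_len(n))
  graphics::axis(2, at = seq_len(n), labels = tab$snp, las = 2, cex.axis = 0.6)
  if (!is.null(pooled)) graphics::abline(v = pooled$beta, lty = 2)
  graphics::abline(v = 0, col = "grey")
  invisible(tab)
}

#' Funnel plot of instrument precision against Wald ratio
#'
#' @param instr an [instrument_set()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted table.
#' @export
plot_funnel <- function(instr, ...) {
  wr <- wald_ratio(instr)
  graphics::plot(wr$ratio, 1 / wr$se, xlab = "Wald ratio",
                 ylab = "precision (1/se)", ...)
  invisible(wr)
}
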