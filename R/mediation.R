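# Two-step MR mediation: indirect effects and proportions mediated.

.effect_pair <- function(x, what) {
  if (is.list(x)) x <- c(x$beta, x$se)
  if (length(x) == 1L) x <- c(x, 0)
  if (length(x) != 2L || anyNA(x[1])) {
    .stop_bcaamr(sprintf("%s must be c(beta, se)", what), "bcaamr_domain_error")
  }
  x
}

#' Two-step MR mediation for one mediator
#'
#' Product-of-coefficients mediation from three MR estimates: the total
#' exposure-outcome effect, the exposure-mediator effect and the
#' mediator-outcome effect. The indirect effect is exactly
#' `beta_xm * beta_my`; the proportion mediated is exactly
#' `indirect / beta_total` (unclipped — it may fall outside \[0,1\] when
#' estimates are noisy or paths oppose). SEs come from the delta method
#' treating the three estimates as independent, as they derive from
#' non-overlapping GWAS sources.
#'
#' @param total total exposure-outcome effect, `c(beta, se)` (log-odds per
#'   SD exposure).
#' @param xm exposure-mediator effect, `c(beta, se)` (mediator SD per
#'   exposure SD).
#' @param my mediator-outcome effect, `c(beta, se)` (log-odds per mediator
#'   SD).
#' @param mediator mediator label.
#' @return list of class `mediation_result`: component effects,
#'   `indirect` (+ `indirect_se`, CI), `proportion` (+ SE, CI) and
#'   `proportion_pct`. With a zero total effect the proportion is `NA`
#'   while the indirect effect is still returned.
#' @export
two_step_mediation <- function(total, xm, my, mediator = NA_character_) {
  total <- .effect_pair(total, "total")
  xm <- .effect_pair(xm, "xm")
  my <- .effect_pair(my, "my")
  ind <- xm[1] * my[1]
  ind_se <- sqrt(xm[1]^2 * my[2]^2 + my[1]^2 * xm[2]^2)
  z <- .z95()
  if (total[1] == 0) {
    prop <- prop_se <- NA_real_
  } else {
    prop <- ind / total[1]
    # delta method on (xm, my, total), independent components
    prop_se <- if (ind == 0) {
      sqrt(xm[1]^2 * my[2]^2 + my[1]^2 * xm[2]^2) / abs(total[1])
    } else {
      abs(prop) * sqrt((ind_se / ind)^2 + (total[2] / total[1])^2)
    }
  }
  structure(list(mediator = mediator,
                 beta_xm = xm[1], se_xm = xm[2],
                 beta_my = my[1], se_my = my[2],
                 beta_total = total[1], se_total = total[2],
                 indirect = ind, indirect_se = ind_se,
                 indirect_ci = c(ind - z * ind_se, ind + z * ind_se),
                 proportion = prop, proportion_se = prop_se,
                 proportion_ci = c(prop - z * prop_se, prop + z * prop_se),
                 proportion_pct = 100 * prop),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("%s: indirect %.4f (se %.4f), proportion mediated %.1f%%\n",
              if (is.na(x$mediator)) "mediator" else x$mediator,
              x$indirect, x$indirect_se, x$proportion_pct))
  invisible(x)
}

#' Mediation analysis over several candidate mediators
#'
#' Applies [two_step_mediation()] per mediator against a common total
#' effect; failures are recorded per mediator without aborting the rest.
#'
#' @param total total exposure-outcome effect: `c(beta, se)` or an
#'   [mr_estimate()].
#' @param mediator_mrs named list; each element a list with components
#'   `xm` and `my`, each `c(beta, se)`.
#' @return `data.frame` in report layout (mediator, mediator-outcome
#'   beta/se, p, mediation %), with the full `mediation_result` objects in
#'   `attr(, "results")`.
#' @export
mediate_all <- function(total, mediator_mrs) {
  if (inherits(total, "mr_estimate")) total <- c(total$beta, total$se)
  res <- lapply(names(mediator_mrs), function(m) {
    tryCatch(
      two_step_mediation(total, mediator_mrs[[m]]$xm, mediator_mrs[[m]]$my,
                         mediator = m),
      error = function(e) structure(list(mediator = m,
                                         error = conditionMessage(e)),
                                    class = "mediation_failure"))
  })
  names(res) <- names(mediator_mrs)
  rows <- lapply(res, function(r) {
    if (inherits(r, "mediation_failure")) {
      data.frame(mediator = r$mediator, beta_my = NA_real_, se_my = NA_real_,
                 pvalue_my = NA_real_, mediation_pct = NA_real_,
                 note = r$error, stringsAsFactors = FALSE)
    } else {
      data.frame(mediator = r$mediator, beta_my = r$beta_my, se_my = r$se_my,
                 pvalue_my = if (r$se_my > 0)
                   2 * pnorm(-abs(r$beta_my / r$se_my)) else NA_real_,
                 mediation_pct = r$proportion_pct, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- res
  out
}
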