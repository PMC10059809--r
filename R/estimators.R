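# Causal-effect estimators operating on a harmonized instrument set.
#
# All estimators take the per-variant exposure/outcome effect pairs
# (beta_exposure, se_exposure, beta_outcome, se_outcome): SD-unit exposure
# effects, log-odds outcome effects. Every estimator is invariant to
# per-variant sign flips (beta_x, beta_y) -> (-beta_x, -beta_y), i.e. to the
# arbitrary choice of effect allele.

.method_order <- c("Inverse variance weighted", "Weighted median",
                   "Simple median", "MR-RAPS", "MR-PRESSO", "MR-Egger")

#' Construct an MR causal-effect estimate
#'
#' Container for a single method's estimate: log-odds causal effect per SD
#' exposure, its SE, two-sided CI and p-value, the exponentiated (odds
#' ratio) scale, and method-specific extras (Egger intercept, PRESSO test
#' results, solver traces, bootstrap settings).
#'
#' @param method method label.
#' @param beta,se causal log-odds estimate and standard error.
#' @param n_snp number of instruments used.
#' @param pvalue two-sided p-value (normal unless the method defines
#'   otherwise).
#' @param ci_low,ci_high CI on the beta scale.
#' @param extras named list of method-specific results.
#' @return object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, n_snp, pvalue,
                        ci_low = beta - .z95() * se,
                        ci_high = beta + .z95() * se,
                        extras = list()) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high,
                 or_point = exp(beta), or_low = exp(ci_low),
                 or_high = exp(ci_high),
                 pvalue = pvalue, n_snp = n_snp, extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta %.4f (se %.4f), OR %.3f (%.3f-%.3f), p %.3g\n",
              x$method, x$n_snp, x$beta, x$se,
              x$or_point, x$or_low, x$or_high, x$pvalue))
  invisible(x)
}

.instr_mats <- function(instr) {
  list(bx = instr$beta_exposure, sx = instr$se_exposure,
       by = instr$beta_outcome, sy = instr$se_outcome,
       snp = instr$snp, n = nrow(instr))
}

.require_n <- function(n, k, method) {
  if (n < k) {
    .stop_bcaamr(sprintf("%s requires at least %d instruments (got %d)",
                         method, k, n), "bcaamr_insufficient_instruments")
  }
}

#' Per-variant Wald ratio estimates
#'
#' The ratio `beta_outcome / beta_exposure` per variant, with the
#' first-order delta-method SE `se_outcome / |beta_exposure|` or the
#' second-order version adding the exposure-side term
#' `beta_outcome^2 se_exposure^2 / beta_exposure^4`. Variants with a zero
#' exposure effect cannot be used and are skipped with a warning.
#'
#' @param instr an [instrument_set()].
#' @param order `"first"` or `"second"` order SE.
#' @return `data.frame` (class `wald_ratios`): `snp, ratio, se, weight`
#'   with inverse-variance weights; skipped variant ids in
#'   `attr(, "skipped")`.
#' @export
wald_ratio <- function(instr, order = c("first", "second")) {
  order <- match.arg(order)
  d <- .instr_mats(instr)
  zero <- d$bx == 0
  if (any(zero)) {
    warning("skipping variant(s) with zero exposure effect: ",
            paste(d$snp[zero], collapse = ", "), call. = FALSE)
  }
  bx <- d$bx[!zero]; by <- d$by[!zero]
  sx <- d$sx[!zero]; sy <- d$sy[!zero]
  se2 <- sy^2 / bx^2
  if (order == "second") se2 <- se2 + by^2 * sx^2 / bx^4
  out <- data.frame(snp = d$snp[!zero], ratio = by / bx,
                    se = sqrt(se2), weight = 1 / se2,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- d$snp[zero]
  class(out) <- c("wald_ratios", "data.frame")
  out
}

# Weighted regression of by on bx through the origin with weights 1/sy^2.
# Returns the slope, the fixed-effect SE (residual variance forced to 1) and
# the residual SD of the weighted fit.
.ivw_fit <- function(bx, by, sy) {
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  n <- length(bx)
  sigma <- if (n > 1) sqrt(sum(w * (by - beta * bx)^2) / (n - 1)) else NA_real_
  list(beta = beta, se_fixed = se_fixed, sigma = sigma, n = n)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin, weights `1/se_outcome^2` (equivalently the
#' inverse-variance-weighted mean of the Wald ratios). Under
#' `"fixed_effects"` the slope SE is scaled so the residual variance is
#' exactly 1; under `"random_effects"` (the default, multiplicative random
#' effects) it is additionally multiplied by the residual SD floored at 1,
#' so overdispersion widens the interval but underdispersion never narrows
#' it.
#'
#' @param instr an [instrument_set()].
#' @param model `"random_effects"` or `"fixed_effects"`.
#' @return an [mr_estimate()]; `extras` carries the residual SD and model.
#' @export
mr_ivw <- function(instr, model = c("random_effects", "fixed_effects")) {
  model <- match.arg(model)
  d <- .instr_mats(instr)
  .require_n(d$n, 1L, "IVW")
  if (d$n == 1L) {
    wr <- wald_ratio(instr)
    est <- wr$ratio[1]; se <- wr$se[1]
    return(mr_estimate("Inverse variance weighted", est, se, 1L,
                       2 * pnorm(-abs(est / se)),
                       extras = list(model = model, sigma = NA_real_)))
  }
  fit <- .ivw_fit(d$bx, d$by, d$sy)
  se <- if (model == "random_effects") {
    fit$se_fixed * max(1, fit$sigma)
  } else fit$se_fixed
  mr_estimate("Inverse variance weighted", fit$beta, se, d$n,
              2 * pnorm(-abs(fit$beta / se)),
              extras = list(model = model, sigma = fit$sigma))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept, weights `1/se_outcome^2`, after orienting every
#' variant so its exposure effect is non-negative. The intercept estimates
#' average directional pleiotropy; its t-test (n-2 df) is the pleiotropy
#' test. Both coefficient SEs carry the multiplicative residual scaling of
#' the weighted fit (not floored; see the methods vignette), and CIs use t
#' quantiles.
#'
#' @param instr an [instrument_set()] with at least 3 variants.
#' @return an [mr_estimate()]; `extras` carries `intercept`,
#'   `intercept_se`, `intercept_ci_low/high`, `intercept_p`, `sigma`.
#' @export
mr_egger <- function(instr) {
  d <- .instr_mats(instr)
  .require_n(d$n, 3L, "MR-Egger")
  flip <- sign(d$bx); flip[flip == 0] <- 1
  bx <- d$bx * flip; by <- d$by * flip
  fit <- summary(lm(by ~ bx, weights = 1 / d$sy^2))
  slope <- fit$coefficients["bx", 1]; se_slope <- fit$coefficients["bx", 2]
  int <- fit$coefficients["(Intercept)", 1]
  se_int <- fit$coefficients["(Intercept)", 2]
  df <- d$n - 2L
  tq <- qt(0.975, df)
  mr_estimate("MR-Egger", slope, se_slope, d$n,
              2 * pt(-abs(slope / se_slope), df),
              ci_low = slope - tq * se_slope, ci_high = slope + tq * se_slope,
              extras = list(intercept = int, intercept_se = se_int,
                            intercept_ci_low = int - tq * se_int,
                            intercept_ci_high = int + tq * se_int,
                            intercept_p = 2 * pt(-abs(int / se_int), df),
                            sigma = fit$sigma, df = df))
}

# Interpolated weighted median of ratios r with weights w: the 50th
# percentile of the weighted empirical distribution with mass centred at
# p_j = (cumsum(w) - w/2) / sum(w). With equal weights this reduces exactly
# to the sample median (midpoint of central order statistics for even n).
.weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (length(r) == 1L) return(r)
  approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

.median_boot_se <- function(bx, sx, by, sy, weighted, n_boot, seed) {
  n <- length(bx)
  with_seed(seed, {
    est <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      bxb <- rnorm(n, bx, sx)
      byb <- rnorm(n, by, sy)
      ok <- bxb != 0
      rb <- byb[ok] / bxb[ok]
      wb <- if (weighted) bxb[ok]^2 / sy[ok]^2 else rep(1, sum(ok))
      est[b] <- .weighted_median(rb, wb)
    }
    sd(est)
  })
}

.median_estimator <- function(instr, weighted, n_boot, seed) {
  d <- .instr_mats(instr)
  label <- if (weighted) "Weighted median" else "Simple median"
  .require_n(d$n, 3L, label)
  w <- if (weighted) d$bx^2 / d$sy^2 else rep(1, d$n)
  est <- .weighted_median(d$by / d$bx, w)
  se <- .median_boot_se(d$bx, d$sx, d$by, d$sy, weighted, n_boot, seed)
  mr_estimate(label, est, se, d$n, 2 * pnorm(-abs(est / se)),
              extras = list(n_boot = n_boot, seed = seed))
}

#' Simple-median causal estimate
#'
#' Median of the per-variant Wald ratios (midpoint of the two central
#' ratios for an even count). The SE comes from a parametric bootstrap:
#' exposure and outcome effects are redrawn from normal distributions at
#' their reported SEs and the median recomputed, `n_boot` times under a
#' fixed seed; the CI and p-value are normal approximations.
#'
#' @param instr an [instrument_set()] with at least 3 variants.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed mandatory RNG seed for the bootstrap.
#' @return an [mr_estimate()].
#' @export
mr_simple_median <- function(instr, n_boot = 1000L, seed) {
  .median_estimator(instr, weighted = FALSE, n_boot = n_boot, seed = seed)
}

#' Weighted-median causal estimate
#'
#' The 50th percentile of the inverse-variance-weighted empirical
#' distribution of Wald ratios (linear interpolation of ratio against
#' cumulative standardized weight), consistent when valid instruments carry
#' at least half the weight. Bootstrap SE as in [mr_simple_median()].
#'
#' @inheritParams mr_simple_median
#' @return an [mr_estimate()].
#' @export
mr_weighted_median <- function(instr, n_boot = 1000L, seed) {
  .median_estimator(instr, weighted = TRUE, n_boot = n_boot, seed = seed)
}

.raps_score <- function(b, bx, by, sx, sy, tau2 = 0, loss = "l2", k = 1.345) {
  v <- sy^2 + b^2 * sx^2 + tau2
  r <- (by - b * bx) / sqrt(v)
  psi <- if (loss == "l2") r else pmax(pmin(r, k), -k)
  sum(psi * bx / sqrt(v))
}

#' Robust adjusted profile score (MR-RAPS) estimate
#'
#' Solves the profile-score estimating equation
#' `sum((by - b bx) bx / (sy^2 + b^2 sx^2)) = 0`, which accounts for the
#' exposure-side sampling error ignored by IVW and is therefore robust to
#' weak instruments. The default is the plain squared-error score without
#' overdispersion; a Huber loss and a method-of-moments overdispersion
#' variance are available. The solver is a deterministic bracketed root
#' find started from the IVW estimate. With all exposure SEs zero the
#' equation reduces exactly to fixed-effects IVW.
#'
#' @param instr an [instrument_set()] with at least 3 variants.
#' @param overdispersion if `TRUE`, iterate a method-of-moments estimate of
#'   an additive pleiotropy variance `tau2` with the causal effect.
#' @param loss `"l2"` (default) or `"huber"` (k = 1.345).
#' @return an [mr_estimate()]; `extras$convergence` carries the bracket,
#'   iteration count, `tau2` and the score at the root.
#' @export
mr_raps <- function(instr, overdispersion = FALSE, loss = c("l2", "huber")) {
  loss <- match.arg(loss)
  d <- .instr_mats(instr)
  .require_n(d$n, 3L, "MR-RAPS")
  start <- .ivw_fit(d$bx, d$by, d$sy)$beta
  tau2 <- 0
  solve_b <- function(tau2) {
    f <- function(b) .raps_score(b, d$bx, d$by, d$sx, d$sy, tau2, loss)
    half <- 0.5; lo <- start - half; hi <- start + half; tries <- 0L
    while (sign(f(lo)) == sign(f(hi))) {
      half <- half * 2; lo <- start - half; hi <- start + half
      tries <- tries + 1L
      if (tries > 60L) {
        .stop_bcaamr("MR-RAPS estimating equation has no sign change; solver failed",
                     "bcaamr_estimation_error")
      }
    }
    list(root = uniroot(f, c(lo, hi), tol = 1e-12)$root,
         bracket = c(lo, hi), widenings = tries)
  }
  sol <- solve_b(tau2)
  iter <- 0L
  if (overdispersion) {
    for (iter in seq_len(50L)) {
      res2 <- (d$by - sol$root * d$bx)^2 - d$sy^2 - sol$root^2 * d$sx^2
      tau2_new <- max(0, mean(res2))
      if (abs(tau2_new - tau2) < 1e-12) break
      tau2 <- tau2_new
      sol <- solve_b(tau2)
    }
  }
  b <- sol$root
  se <- 1 / sqrt(sum(d$bx^2 / (d$sy^2 + b^2 * d$sx^2 + tau2)))
  mr_estimate("MR-RAPS", b, se, d$n, 2 * pnorm(-abs(b / se)),
              extras = list(convergence = list(
                bracket = sol$bracket, widenings = sol$widenings,
                overdispersion_iter = iter, tau2 = tau2,
                score_at_root = .raps_score(b, d$bx, d$by, d$sx, d$sy, tau2, loss)),
                loss = loss))
}

# Leave-one-out IVW slopes (fixed-effects), closed form: removing variant i
# from the weighted cross-products. by_mat may be a matrix (rows =
# simulations) sharing bx/weights, in which case a matrix of slopes returns.
.loo_slopes <- function(bx, by, w) {
  sxx <- sum(w * bx^2)
  if (is.matrix(by)) {
    sxy <- as.vector(by %*% (w * bx))
    num <- sxy - sweep(by, 2, w * bx, `*`)
    den <- matrix(sxx - w * bx^2, nrow(by), length(bx), byrow = TRUE)
    num / den
  } else {
    sxy <- sum(w * bx * by)
    (sxy - w * bx * by) / (sxx - w * bx^2)
  }
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based outlier framework. The observed residual sum of squares
#' of leave-one-out IVW predictions is compared with its null distribution
#' obtained by redrawing, `n_sim` times, outcome effects around the
#' leave-one-out predictions and exposure effects around their estimates at
#' the reported SEs (global test). Each variant's squared residual is
#' compared with its simulated distribution, Bonferroni-adjusted, to flag
#' outliers (outlier test). The outlier-corrected estimate is the IVW fit on
#' the retained variants; when outliers are removed, a distortion test
#' compares the corrected and uncorrected estimates against a null built
#' from random same-size variant subsets. Empirical p-values use the
#' `(1 + k)/(1 + n_sim)` correction.
#'
#' @param instr an [instrument_set()] with at least 4 variants.
#' @param n_sim parametric simulations (default 1000).
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   per-variant outlier test (default 0.05).
#' @param seed mandatory RNG seed.
#' @return an [mr_estimate()] for the outlier-corrected effect; `extras`
#'   carries `global_rss`, `global_p`, `outlier_p` (per variant),
#'   `outliers` (flagged ids), `distortion_p`, `n_sim`, `seed`.
#' @export
mr_presso <- function(instr, n_sim = 1000L, outlier_alpha = 0.05, seed) {
  d <- .instr_mats(instr)
  .require_n(d$n, 4L, "MR-PRESSO")
  w <- 1 / d$sy^2
  b_loo <- .loo_slopes(d$bx, d$by, w)
  resid2 <- (d$by - b_loo * d$bx)^2
  rss_obs <- sum(resid2)

  sim <- with_seed(seed, {
    bx_s <- matrix(rnorm(n_sim * d$n, rep(d$bx, each = n_sim),
                         rep(d$sx, each = n_sim)), n_sim, d$n)
    by_s <- matrix(rnorm(n_sim * d$n, rep(b_loo * d$bx, each = n_sim),
                         rep(d$sy, each = n_sim)), n_sim, d$n)
    loo_s <- matrix(0, n_sim, d$n)
    for (i in seq_len(n_sim)) {
      loo_s[i, ] <- .loo_slopes(bx_s[i, ], by_s[i, ], w)
    }
    res2_s <- (by_s - loo_s * bx_s)^2
    list(rss = rowSums(res2_s), res2 = res2_s)
  })
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (1 + n_sim)
  outlier_p <- (1 + colSums(sim$res2 >= matrix(resid2, n_sim, d$n,
                                               byrow = TRUE))) / (1 + n_sim)
  is_out <- outlier_p * d$n < outlier_alpha
  keep <- !is_out
  if (sum(keep) < 2L) {
    .stop_bcaamr("MR-PRESSO flagged too many outliers to re-estimate",
                 "bcaamr_estimation_error")
  }
  fit_all <- summary(lm(d$by ~ 0 + d$bx, weights = w))
  fit_cor <- summary(lm(d$by[keep] ~ 0 + d$bx[keep], weights = w[keep]))
  beta <- fit_cor$coefficients[1, 1]
  se <- fit_cor$coefficients[1, 2]

  distortion_p <- NA_real_
  distortion <- NA_real_
  if (any(is_out)) {
    b_all <- fit_all$coefficients[1, 1]
    distortion <- 100 * (beta - b_all) / abs(b_all)
    d_null <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(s) {
        drop_idx <- sample.int(d$n, sum(is_out))
        b_s <- .ivw_fit(d$bx[-drop_idx], d$by[-drop_idx], d$sy[-drop_idx])$beta
        100 * (b_s - b_all) / abs(b_all)
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(distortion))) / (1 + n_sim)
  }
  mr_estimate("MR-PRESSO", beta, se, as.integer(sum(keep)),
              2 * pnorm(-abs(beta / se)),
              extras = list(global_rss = rss_obs, global_p = global_p,
                            outlier_p = setNames(outlier_p, d$snp),
                            outliers = d$snp[is_out],
                            distortion = distortion,
                            distortion_p = distortion_p,
                            n_sim = n_sim, outlier_alpha = outlier_alpha,
                            seed = seed))
}

#' Configuration for a full estimator run
#'
#' @param n_boot bootstrap replicates for the median estimators.
#' @param n_sim MR-PRESSO simulations.
#' @param seed RNG seed for every stochastic stage.
#' @param outlier_alpha MR-PRESSO outlier-test level.
#' @param ivw_model IVW flavor, `"random_effects"` or `"fixed_effects"`.
#' @return list of class `mr_config`.
#' @export
mr_config <- function(n_boot = 1000L, n_sim = 1000L, seed = 1L,
                      outlier_alpha = 0.05,
                      ivw_model = c("random_effects", "fixed_effects")) {
  structure(list(n_boot = as.integer(n_boot), n_sim = as.integer(n_sim),
                 seed = as.integer(seed), outlier_alpha = outlier_alpha,
                 ivw_model = match.arg(ivw_model)),
            class = "mr_config")
}

#' Run all six causal estimators on one instrument set
#'
#' Fixed order: inverse-variance weighted, weighted median, simple median,
#' MR-RAPS, MR-PRESSO, MR-Egger. A failure in one method (e.g. too few
#' instruments) is recorded on that row and does not abort the others.
#'
#' @param instr an [instrument_set()].
#' @param config an [mr_config()].
#' @return list of class `mr_result_set`; coerce with
#'   `as.data.frame()` for the tabular (method, beta, se, OR, CI, p) layout.
#' @export
mr_run_all <- function(instr, config = mr_config()) {
  runs <- list(
    `Inverse variance weighted` = function() mr_ivw(instr, config$ivw_model),
    `Weighted median` = function()
      mr_weighted_median(instr, config$n_boot, seed = config$seed),
    `Simple median` = function()
      mr_simple_median(instr, config$n_boot, seed = config$seed + 1L),
    `MR-RAPS` = function() mr_raps(instr),
    `MR-PRESSO` = function()
      mr_presso(instr, config$n_sim, config$outlier_alpha, seed = config$seed + 2L),
    `MR-Egger` = function() mr_egger(instr)
  )
  out <- lapply(names(runs), function(m) {
    tryCatch(runs[[m]](), error = function(e) {
      mr_estimate(m, NA_real_, NA_real_, nrow(instr), NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_,
                  extras = list(error = conditionMessage(e)))
    })
  })
  names(out) <- names(runs)
  structure(out, class = "mr_result_set", config = config,
            protocol = attr(instr, "protocol_label"))
}

#' @export
as.data.frame.mr_result_set <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(e) {
    data.frame(method = e$method, n_snp = e$n_snp,
               beta = e$beta, se = e$se,
               or = e$or_point, or_low = e$or_low, or_high = e$or_high,
               pvalue = e$pvalue,
               note = if (!is.null(e$extras$error)) e$extras$error else "",
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.mr_result_set <- function(x, ...) {
  df <- as.data.frame(x)
  df[c("beta", "se", "or", "or_low", "or_high")] <-
    lapply(df[c("beta", "se", "or", "or_low", "or_high")], round, 3)
  df$pvalue <- signif(df$pvalue, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Write an estimator-run report
#'
#' Emits the tabular layout as tab-separated text and the full results
#' (including method extras) as JSON.
#'
#' @param results an `mr_result_set` from [mr_run_all()].
#' @param path_prefix path prefix; `<prefix>.tsv` and `<prefix>.json` are
#'   written.
#' @return the two paths, invisibly.
#' @export
write_mr_report <- function(results, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  js <- paste0(path_prefix, ".json")
  write.table(as.data.frame(results), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(lapply(unclass(results), function(e) {
    e$extras <- e$extras[setdiff(names(e$extras), "convergence")]
    e
  }), js, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(c(tsv, js))
}
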