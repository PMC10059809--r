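# Seeded generators for two-sample MR summary statistics, mediation
# triples and study-level meta-analysis inputs, plus the bundled
# 17-variant instrument fixture.

#' Parameters for a two-sample summary-statistics simulation
#'
#' The generating model: per variant, an effect-allele frequency `f` is
#' drawn log-uniformly over `maf_range` (log-uniform, so rare variants with
#' large per-allele effects occur, as in real BCAA instruments), and a true
#' exposure effect is sized so the per-variant variance explained
#' `2 f (1-f) beta_x^2` is uniform over `r2_range`. True outcome effects
#' are `true_beta * beta_x` plus a direct (pleiotropic) effect for the
#' invalid fraction. Observed effects add normal noise at the SE implied by
#' the sample sizes, `se = 1/sqrt(2 f (1-f) n)`.
#'
#' @param n_snps number of variants (>= 1).
#' @param true_beta causal effect (log-odds outcome per SD exposure).
#' @param maf_range range of effect-allele frequencies (default
#'   `c(0.01, 0.5)`).
#' @param r2_range per-variant exposure variance explained range
#'   (default `c(0.001, 0.006)`).
#' @param n_x,n_y exposure and outcome GWAS sample sizes (default 25000
#'   and 180000).
#' @param pleiotropy_mean,pleiotropy_sd normal distribution of direct
#'   outcome effects for invalid variants; a nonzero mean gives directional
#'   pleiotropy, zero-mean gives balanced.
#' @param invalid_fraction fraction of variants with direct outcome
#'   effects, in \[0,1\].
#' @param outlier_spec list of `c(index, offset)` pairs: variant `index`'s
#'   observed outcome effect is shifted by `offset` outcome SEs.
#' @param palindromes if `FALSE` (default) allele pairs are drawn
#'   non-palindromic so harmonization behaviour is exercised separately.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_snps = 50L, true_beta = 0.1,
                       maf_range = c(0.01, 0.5), r2_range = c(0.001, 0.006),
                       n_x = 25000L, n_y = 180000L,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       invalid_fraction = 0, outlier_spec = NULL,
                       palindromes = FALSE, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    .stop_bcaamr("sim_params requires an explicit seed", "bcaamr_validation_error")
  }
  if (n_snps < 1L) {
    .stop_bcaamr("n_snps must be >= 1", "bcaamr_validation_error")
  }
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    .stop_bcaamr("invalid_fraction must lie in [0, 1]", "bcaamr_validation_error")
  }
  if (any(maf_range <= 0) || any(maf_range > 0.5) || diff(maf_range) < 0) {
    .stop_bcaamr("maf_range must be an increasing range within (0, 0.5]",
                 "bcaamr_validation_error")
  }
  if (!is.null(outlier_spec)) {
    for (o in outlier_spec) {
      if (length(o) != 2L || o[1] < 1 || o[1] > n_snps) {
        .stop_bcaamr("outlier_spec entries must be c(index, offset) within range",
                     "bcaamr_validation_error")
      }
    }
  }
  structure(list(n_snps = as.integer(n_snps), true_beta = true_beta,
                 maf_range = maf_range, r2_range = r2_range,
                 n_x = n_x, n_y = n_y,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 invalid_fraction = invalid_fraction,
                 outlier_spec = outlier_spec, palindromes = palindromes,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Canonical simulation scenarios
#'
#' Fixed parameterizations used throughout the validation suite:
#' \describe{
#'   \item{A}{no pleiotropy, 50 variants, true effect 0.1 — every
#'     estimator should recover the truth.}
#'   \item{A0}{as A with a zero causal effect — the joint null used for
#'     test calibration.}
#'   \item{B}{balanced pleiotropy: every variant carries a zero-mean direct
#'     effect (sd 0.005) — the Egger intercept should centre on zero.}
#'   \item{C}{as A plus one planted outlier, shifted +5 outcome SEs — the
#'     PRESSO outlier target.}
#'   \item{D}{17 variants (the size of the real instrument), 30% invalid
#'     with directional pleiotropy (mean 0.02, sd 0.005) — IVW is biased by
#'     construction, the weighted median should stay near the truth.}
#' }
#'
#' @param scenario `"A"`, `"A0"`, `"B"`, `"C"` or `"D"`.
#' @param seed mandatory RNG seed.
#' @param n_snps optional override of the scenario's variant count.
#' @return a [sim_params()] object.
#' @export
scenario_params <- function(scenario = c("A", "A0", "B", "C", "D"), seed,
                            n_snps = NULL) {
  scenario <- match.arg(scenario)
  p <- switch(scenario,
    A = list(n_snps = 50L, true_beta = 0.1),
    A0 = list(n_snps = 50L, true_beta = 0),
    B = list(n_snps = 50L, true_beta = 0.1, invalid_fraction = 1,
             pleiotropy_mean = 0, pleiotropy_sd = 0.005),
    C = list(n_snps = 50L, true_beta = 0.1,
             outlier_spec = list(c(25, 5))),
    D = list(n_snps = 17L, true_beta = 0.1, invalid_fraction = 0.3,
             pleiotropy_mean = 0.02, pleiotropy_sd = 0.005)
  )
  if (!is.null(n_snps)) {
    p$n_snps <- n_snps
    if (scenario == "C") p$outlier_spec <- list(c(max(1L, n_snps %/% 2L), 5))
  }
  do.call(sim_params, c(p, list(seed = seed)))
}

.bases <- c("A", "C", "G", "T")

.draw_allele_pairs <- function(n, palindromes) {
  ea <- sample(.bases, n, replace = TRUE)
  oa <- vapply(ea, function(a) {
    pool <- setdiff(.bases, if (palindromes) a else c(a, .complement(a)))
    sample(pool, 1L)
  }, character(1))
  list(ea = ea, oa = unname(oa))
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Draws one realization of the generating model described in
#' [sim_params()]. Output is deterministic given the seed; the same seed
#' always yields bit-identical tables.
#'
#' @param params a [sim_params()] object.
#' @return list with `exposure` and `outcome` (`variant_assoc`-shaped
#'   `data.frame`s sharing identifiers, alleles and frequencies), and
#'   `truth` (true per-variant exposure effects, pleiotropy effects,
#'   invalid indices and the parameters).
#' @export
simulate_two_sample <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_snps
    f <- exp(runif(n, log(p$maf_range[1]), log(p$maf_range[2])))
    r2 <- runif(n, p$r2_range[1], p$r2_range[2])
    v <- 2 * f * (1 - f)
    bx_true <- sqrt(r2 / v)
    se_x <- 1 / sqrt(v * p$n_x)
    se_y <- 1 / sqrt(v * p$n_y)
    alpha <- numeric(n)
    n_invalid <- round(p$invalid_fraction * n)
    invalid <- integer(0)
    if (n_invalid > 0) {
      invalid <- sample.int(n, n_invalid)
      alpha[invalid] <- rnorm(n_invalid, p$pleiotropy_mean, p$pleiotropy_sd)
    }
    by_true <- p$true_beta * bx_true + alpha
    bx_obs <- rnorm(n, bx_true, se_x)
    by_obs <- rnorm(n, by_true, se_y)
    if (!is.null(p$outlier_spec)) {
      for (o in p$outlier_spec) by_obs[o[1]] <- by_obs[o[1]] + o[2] * se_y[o[1]]
    }
    al <- .draw_allele_pairs(n, p$palindromes)
    snp <- sprintf("snp%04d", seq_len(n))
    chr <- as.character(sample.int(22L, n, replace = TRUE))
    base <- data.frame(snp = snp, gene = sprintf("locus%04d", seq_len(n)),
                       chr = chr, effect_allele = al$ea, other_allele = al$oa,
                       eaf = f, stringsAsFactors = FALSE)
    exposure <- base
    exposure$beta <- bx_obs; exposure$se <- se_x
    exposure$pvalue <- pmax(2 * pnorm(-abs(bx_obs / se_x)), 1e-320)
    exposure$n <- p$n_x; exposure$trait <- "exposure"
    outcome <- base
    outcome$beta <- by_obs; outcome$se <- se_y
    outcome$pvalue <- pmax(2 * pnorm(-abs(by_obs / se_y)), 1e-320)
    outcome$n <- p$n_y; outcome$trait <- "outcome"
    class(exposure) <- class(outcome) <- c("variant_assoc", "data.frame")
    list(exposure = exposure, outcome = outcome,
         truth = list(beta_x = bx_true, alpha = alpha, invalid = sort(invalid),
                      params = p))
  })
}

#' Instrument set straight from a simulation
#'
#' Convenience wrapper: simulated exposure and outcome tables share allele
#' orientation, so the harmonized instrument is assembled directly.
#'
#' @param params a [sim_params()] object.
#' @return an [instrument_set()] with the simulation `truth` attached as
#'   `attr(, "truth")`.
#' @export
simulate_instruments <- function(params) {
  sim <- simulate_two_sample(params)
  out <- instrument_set(data.frame(
    snp = sim$exposure$snp,
    beta_exposure = sim$exposure$beta, se_exposure = sim$exposure$se,
    beta_outcome = sim$outcome$beta, se_outcome = sim$outcome$se,
    eaf = sim$exposure$eaf, gene = sim$exposure$gene, chr = sim$exposure$chr,
    stringsAsFactors = FALSE), protocol_label = "simulated")
  attr(out, "truth") <- sim$truth
  out
}

#' Simulate a mediation effect triple
#'
#' Constructs true total, exposure-mediator and mediator-outcome effects
#' satisfying `xm * my = proportion * total` exactly, then adds normal
#' noise at the stated SEs. Defaults mirror the scale of the real analysis:
#' a total effect of 0.076 log-odds per SD and a mediator-outcome effect of
#' 0.566 with SE 0.091, with the exposure-mediator and total effects
#' estimated at ~10-15% relative SE.
#'
#' @param total_beta true total effect (nonzero).
#' @param proportion true proportion mediated.
#' @param my_true true mediator-outcome effect (sets the split of the
#'   indirect effect between the two legs).
#' @param se_xm,se_my,se_total component standard errors.
#' @param seed mandatory RNG seed.
#' @return list with noisy `total`, `xm`, `my` (each `c(beta, se)`) and
#'   `truth`.
#' @export
simulate_mediation <- function(total_beta = 0.076, proportion = 0.342,
                               my_true = 0.566, se_xm = 0.007, se_my = 0.091,
                               se_total = 0.008, seed) {
  if (total_beta == 0) {
    .stop_bcaamr("total_beta must be nonzero", "bcaamr_validation_error")
  }
  xm_true <- proportion * total_beta / my_true
  with_seed(seed, {
    list(total = c(rnorm(1, total_beta, se_total), se_total),
         xm = c(rnorm(1, xm_true, se_xm), se_xm),
         my = c(rnorm(1, my_true, se_my), se_my),
         truth = list(total = total_beta, xm = xm_true, my = my_true,
                      proportion = proportion))
  })
}

#' Simulate study-level effects for meta-analysis
#'
#' Study log relative risks are drawn around `true_log_rr` with
#' between-study SD `tau`, then observed with sampling noise at per-study
#' SEs drawn uniformly from `se_range`.
#'
#' @param k number of studies (>= 2).
#' @param true_log_rr true pooled effect on the log scale.
#' @param tau between-study SD.
#' @param se_range range of per-study sampling SEs.
#' @param designs study-design labels (recycled); default mirrors a
#'   7-study mix of three case-control, three cohort and one other design.
#' @param seed mandatory RNG seed.
#' @return a [study_effects()] table.
#' @export
simulate_meta_studies <- function(k = 7L, true_log_rr = log(1.18), tau = 0.05,
                                  se_range = c(0.04, 0.15),
                                  designs = c(rep("case_control", 3),
                                              rep("cohort", 3), "other"),
                                  seed) {
  if (k < 2L) .stop_bcaamr("k must be >= 2", "bcaamr_validation_error")
  with_seed(seed, {
    sei <- runif(k, se_range[1], se_range[2])
    theta <- rnorm(k, true_log_rr, tau)
    yi <- rnorm(k, theta, sei)
    z <- .z95()
    study_effects(data.frame(
      study = sprintf("study%02d", seq_len(k)),
      rr = exp(yi), ci_low = exp(yi - z * sei), ci_high = exp(yi + z * sei),
      design = rep_len(designs, k), stringsAsFactors = FALSE))
  })
}

#' The bundled 17-variant BCAA-CAD instrument
#'
#' Loads the packaged serum-BCAA instrument (17 variants with exposure
#' effects in SD units and CAD outcome odds ratios with 95% CIs), converts
#' the outcome ORs and CI bounds to log-odds and SEs via [se_from_ci()],
#' and returns the harmonized instrument set. Byte-stable across calls.
#'
#' @return an [instrument_set()] with 17 rows and `gene`/`chr`/`eaf`
#'   columns.
#' @export
fixture_table2 <- function() {
  path <- system.file("extdata", "table2_bcaa_cad.tsv", package = "bcaamr",
                      mustWork = TRUE)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  conv <- se_from_ci(tab$or_out, tab$ci_low, tab$ci_high, 0.95)
  instrument_set(data.frame(
    snp = tab$snp, beta_exposure = tab$beta_exp, se_exposure = tab$se_exp,
    beta_outcome = conv$beta, se_outcome = conv$se, eaf = tab$eaf,
    gene = tab$gene, chr = as.character(tab$chr),
    palindromic = .is_palindromic(tab$effect_allele, tab$other_allele),
    aligned = TRUE, stringsAsFactors = FALSE), protocol_label = "r2_0.8")
}
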