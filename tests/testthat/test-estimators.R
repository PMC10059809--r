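# The six causal estimators: exact small cases, conventions, invariances
# and recovery under the generating model.

test_that("wald_ratio computes first- and second-order ratios", {
  i1 <- make_instr(0.1, 0.02, sx = 0.01, sy = 0.01)
  wr <- wald_ratio(i1)
  expect_equal(wr$ratio, 0.2)
  expect_equal(wr$se, 0.1)
  # second order adds the exposure-side term
  wr2 <- wald_ratio(i1, "second")
  expect_equal(wr2$se, sqrt(0.01^2 / 0.1^2 + 0.02^2 * 0.01^2 / 0.1^4))
  # null numerator
  expect_equal(wald_ratio(make_instr(0.1, 0, sy = 0.02))$ratio, 0)
  # bundled instrument, first row, after OR -> log-odds conversion
  fx <- fixture_table2()
  wrf <- wald_ratio(fx[1, , drop = FALSE])
  expect_equal(wrf$ratio, 0.2183, tolerance = 1e-3)
  expect_equal(wrf$se, 0.1613, tolerance = 1e-3)
  # zero exposure effect is skipped with a warning
  expect_warning(wz <- wald_ratio(make_instr(c(0, 0.1), c(0.01, 0.02))),
                 "zero exposure")
  expect_equal(nrow(wz), 1L)
})

test_that("IVW equals the inverse-variance weighted mean of ratios", {
  # single variant: identical to its Wald ratio
  one <- make_instr(0.1, 0.02, sy = 0.01)
  e <- mr_ivw(one)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.1)
  # two equal-weight variants: plain weighted mean
  two <- make_instr(c(1, 1), c(0.1, 0.3), sy = c(1, 1))
  expect_equal(mr_ivw(two)$beta, 0.2)
  # random-effects SE never narrower than fixed
  set.seed(5)
  for (i in 1:10) {
    instr <- simulate_instruments(scenario_params("A", seed = i))
    expect_gte(mr_ivw(instr, "random_effects")$se,
               mr_ivw(instr, "fixed_effects")$se)
  }
})

test_that("Egger recovers an exact affine relation with zero residual", {
  instr <- make_instr(c(1, 2, 3), 0.1 + 0.4 * c(1, 2, 3), sy = c(1, 1, 1))
  e <- suppressWarnings(mr_egger(instr)) # lm warns on the zero-residual fit
  expect_equal(e$beta, 0.4, tolerance = 1e-10)
  expect_equal(e$extras$intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$extras$sigma, 0, tolerance = 1e-6)
  expect_error(mr_egger(make_instr(c(1, 2), c(0.1, 0.2))),
               class = "bcaamr_insufficient_instruments")
})

test_that("Egger intercept centres on zero under balanced pleiotropy", {
  ints <- ses <- numeric(50)
  for (i in 1:50) {
    e <- mr_egger(simulate_instruments(scenario_params("B", seed = 1000 + i)))
    ints[i] <- e$extras$intercept
    ses[i] <- e$extras$intercept_se
  }
  expect_lt(abs(mean(ints)), 2 * sd(ints) / sqrt(50))
})

test_that("median estimators match their order-statistic definitions", {
  odd <- make_instr(c(1, 1, 1), c(0.1, 0.2, 0.4), sy = c(1, 1, 1))
  expect_equal(mr_simple_median(odd, n_boot = 50, seed = 1)$beta, 0.2)
  four <- make_instr(c(1, 1, 1, 1), c(0.1, 0.3, 0.6, 0.9), sy = c(1, 1, 1, 1))
  expect_equal(mr_simple_median(four, n_boot = 50, seed = 1)$beta, 0.45)
  # hand-executed weighted interpolation: ratios (1,2,3), weights (1,1,2)
  wm <- make_instr(c(1, 1, 1), c(1, 2, 3), sy = c(1, 1, 1 / sqrt(2)))
  expect_equal(mr_weighted_median(wm, n_boot = 50, seed = 1)$beta,
               2 + 1 / 3, tolerance = 1e-10)
  # equal weights reduce the weighted median to the simple median
  instr <- simulate_instruments(scenario_params("A", seed = 3))
  eq <- instr
  eq$se_outcome <- eq$se_outcome * 0 + 0.005
  eq$beta_exposure <- rep(0.1, nrow(eq))
  expect_equal(mr_weighted_median(eq, n_boot = 50, seed = 2)$beta,
               mr_simple_median(eq, n_boot = 50, seed = 2)$beta)
})

test_that("RAPS solves the profile score and degenerates to fixed-effects IVW", {
  instr <- simulate_instruments(scenario_params("A", seed = 11))
  nox <- instr
  nox$se_exposure <- rep(1e-300, nrow(nox)) # exposure measured exactly
  expect_equal(mr_raps(nox)$beta, mr_ivw(nox, "fixed_effects")$beta,
               tolerance = 1e-9)
  # parameter recovery at 200 variants: estimate within 2 SEs of truth
  big <- simulate_instruments(scenario_params("A", seed = 12, n_snps = 200))
  e <- mr_raps(big)
  expect_lt(abs(e$beta - 0.1), 2 * e$se)
  expect_lt(abs(e$extras$convergence$score_at_root), 1e-6)
})

test_that("PRESSO flags a planted outlier and reports the three tests", {
  instr <- simulate_instruments(scenario_params("C", seed = 21))
  e <- mr_presso(instr, n_sim = 1000, seed = 31)
  expect_true("snp0025" %in% e$extras$outliers)
  expect_lt(e$extras$global_p, 0.05)
  expect_false(is.na(e$extras$distortion_p))
  # clean data: no outliers, corrected estimate = IVW on all variants
  clean <- simulate_instruments(scenario_params("A", seed = 22))
  ec <- mr_presso(clean, n_sim = 500, seed = 32)
  expect_length(ec$extras$outliers, 0)
  expect_equal(ec$beta, mr_ivw(clean, "fixed_effects")$beta)
  expect_error(mr_presso(make_instr(c(1, 1, 1), c(0.1, 0.2, 0.3)), seed = 1),
               class = "bcaamr_insufficient_instruments")
})

test_that("all estimators are invariant to per-variant allele sign flips", {
  instr <- simulate_instruments(scenario_params("A", seed = 41, n_snps = 20))
  flip <- rep(c(1, -1), 10)
  flipped <- instr
  flipped$beta_exposure <- flipped$beta_exposure * flip
  flipped$beta_outcome <- flipped$beta_outcome * flip
  expect_equal(mr_ivw(flipped)$beta, mr_ivw(instr)$beta)
  expect_equal(mr_egger(flipped)$beta, mr_egger(instr)$beta)
  expect_equal(mr_egger(flipped)$extras$intercept,
               mr_egger(instr)$extras$intercept)
  expect_equal(mr_raps(flipped)$beta, mr_raps(instr)$beta, tolerance = 1e-9)
  expect_equal(mr_simple_median(flipped, n_boot = 50, seed = 1)$beta,
               mr_simple_median(instr, n_boot = 50, seed = 1)$beta)
  expect_equal(mr_weighted_median(flipped, n_boot = 50, seed = 1)$beta,
               mr_weighted_median(instr, n_boot = 50, seed = 1)$beta)
  expect_equal(mr_presso(flipped, n_sim = 200, seed = 2)$beta,
               mr_presso(instr, n_sim = 200, seed = 2)$beta)
})

test_that("mr_run_all reports all six methods in fixed order with gating", {
  instr <- simulate_instruments(scenario_params("A", seed = 51, n_snps = 10))
  res <- mr_run_all(instr, mr_config(n_boot = 50, n_sim = 200, seed = 5))
  df <- as.data.frame(res)
  expect_equal(df$method,
               c("Inverse variance weighted", "Weighted median",
                 "Simple median", "MR-RAPS", "MR-PRESSO", "MR-Egger"))
  expect_true(all(df$note == ""))
  expect_equal(df$or, exp(df$beta))
  # single variant: IVW succeeds, the rest report their precondition
  single <- instr[1, , drop = FALSE]
  res1 <- as.data.frame(mr_run_all(single, mr_config(n_boot = 50, seed = 5)))
  expect_equal(res1$note[1], "")
  expect_true(all(grepl("at least", res1$note[-1])))
})
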