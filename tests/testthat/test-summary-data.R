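# Summary-statistics I/O, CI back-conversion, harmonization, instrument
# selection and variance explained.

test_that("read_summary_stats parses the bundled instrument file", {
  path <- system.file("extdata", "table2_bcaa_cad.tsv", package = "bcaamr")
  map <- c(beta = "beta_exp", se = "se_exp", pvalue = "pval_exp")
  assoc <- read_summary_stats(path, column_map = map)
  expect_s3_class(assoc, "variant_assoc")
  expect_equal(nrow(assoc), 17L)
  expect_equal(assoc$snp[1], "rs116564150")
  expect_equal(assoc$beta[1], 0.31)
  expect_equal(assoc$se[1], 0.05)
  expect_equal(assoc$gene[1], "PPM1K")
})

test_that("read_summary_stats handles empty files, bad rows and bad config", {
  hdr <- assoc_row("rs1", "A", "G", 0.2, 0.1)[0, ]
  empty <- write_temp_sumstats(hdr)
  expect_equal(nrow(read_summary_stats(empty)), 0L)

  bad <- rbind(assoc_row("rs1", "A", "G", 0.2, 0.1),
               assoc_row("rs2", "C", "T", 1.2, 0.1))
  expect_error(read_summary_stats(write_temp_sumstats(bad)),
               "line.*3", class = "bcaamr_row_error")

  noneaf <- assoc_row("rs1", "A", "G", 0.2, 0.1)
  names(noneaf)[names(noneaf) == "eaf"] <- "freq"
  expect_error(read_summary_stats(write_temp_sumstats(noneaf)),
               "eaf", class = "bcaamr_config_error")

  expect_error(read_summary_stats(tempfile()), class = "bcaamr_io_error")
})

test_that("se_from_ci matches direct evaluation of the closed form", {
  expect_equal(se_from_ci(1, 1, 1)$beta, 0)
  expect_equal(se_from_ci(1, 1, 1)$se, 0)
  r1 <- se_from_ci(1.07, 0.97, 1.18)
  expect_equal(r1$beta, 0.0677, tolerance = 1e-3)
  expect_equal(r1$se, 0.0500, tolerance = 1e-3)
  r2 <- se_from_ci(1.01, 0.99, 1.03)
  expect_equal(r2$beta, 0.00995, tolerance = 1e-3)
  expect_equal(r2$se, (log(1.03) - log(0.99)) / (2 * qnorm(0.975)),
               tolerance = 1e-10)
  expect_equal(r2$se, 0.010105, tolerance = 1e-4)
  expect_error(se_from_ci(-1, 0.5, 2), class = "bcaamr_domain_error")
  expect_error(se_from_ci(1.1, 1.2, 1.05), class = "bcaamr_order_error")
})

test_that("se_from_ci round-trips log-scale effects", {
  set.seed(42)
  z <- qnorm(0.975)
  for (i in 1:25) {
    b <- rnorm(1); s <- rexp(1)
    r <- se_from_ci(exp(b), exp(b - z * s), exp(b + z * s))
    expect_equal(r$beta, b, tolerance = 1e-9)
    expect_equal(r$se, s, tolerance = 1e-9)
  }
})

test_that("harmonize aligns, flips and strand-flips correctly", {
  e <- assoc_row("rs1", "A", "G", 0.013, 0.31)
  # identical orientation: untouched
  h <- harmonize(e, assoc_row("rs1", "A", "G", 0.013, 0.068))
  expect_true(h$aligned)
  expect_equal(h$beta_outcome, 0.068)
  expect_equal(h$eaf, 0.013)
  # swapped labels: sign and frequency flip
  h <- harmonize(e, assoc_row("rs1", "G", "A", 0.987, -0.068))
  expect_equal(h$beta_outcome, 0.068)
  expect_equal(h$eaf, 0.013)
  # complementary-strand representation
  h <- harmonize(e, assoc_row("rs1", "T", "C", 0.013, 0.068))
  expect_equal(h$beta_outcome, 0.068)
  # strand + swap
  h <- harmonize(e, assoc_row("rs1", "C", "T", 0.987, -0.068))
  expect_equal(h$beta_outcome, 0.068)
  # harmonizing an already-aligned pair changes nothing (idempotence)
  o <- assoc_row("rs1", "A", "G", 0.013, h$beta_outcome)
  h2 <- harmonize(e, o)
  expect_equal(h2$beta_outcome, h$beta_outcome)
  # irreconcilable alleles: exclusion record, not a pass-through
  x <- harmonize(e, assoc_row("rs1", "A", "C", 0.013, 0.068))
  expect_s3_class(x, "mr_exclusion")
  expect_equal(x$reason, "allele mismatch")
})

test_that("palindromic variants follow the stated policy", {
  e <- assoc_row("rs9", "A", "T", 0.48, 0.1)
  o <- assoc_row("rs9", "A", "T", 0.48, 0.05)
  expect_s3_class(harmonize(e, o, "drop"), "mr_exclusion")
  x <- harmonize(e, o, "align_by_frequency")
  expect_s3_class(x, "mr_exclusion")
  expect_equal(x$reason, "ambiguous palindromic frequency")
  expect_true(harmonize(e, o, "keep")$aligned)
  # outside the ambiguity band, discordant frequency sides mean the
  # outcome is reported on the opposite strand orientation
  e2 <- assoc_row("rs9", "A", "T", 0.2, 0.1)
  o2 <- assoc_row("rs9", "A", "T", 0.8, 0.05)
  h <- harmonize(e2, o2, "align_by_frequency")
  expect_equal(h$beta_outcome, -0.05)
  h2 <- harmonize(e2, assoc_row("rs9", "A", "T", 0.2, 0.05),
                  "align_by_frequency")
  expect_equal(h2$beta_outcome, 0.05)
})

test_that("select_instruments applies filter, dedup, exclusions and pruning", {
  # cross-trait dedup keeps the strongest (smallest p) association
  a <- rbind(assoc_row("rs1", "A", "G", 0.2, 0.10, pvalue = 1e-9,
                       trait = "valine"),
             assoc_row("rs1", "A", "G", 0.2, 0.12, pvalue = 1e-12,
                       trait = "leucine"))
  sel <- select_instruments(a, protocol = "r2_0.8")
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$trait, "leucine")

  # significance filter is strict
  b <- rbind(assoc_row("rs1", "A", "G", 0.2, 0.1, pvalue = 5e-8),
             assoc_row("rs2", "C", "T", 0.3, 0.1, pvalue = 1e-9))
  expect_equal(select_instruments(b, protocol = "r2_0.8")$snp, "rs2")

  # exclusion list removes by gene or id
  cset <- rbind(assoc_row("rs1", "A", "G", 0.2, 0.1, gene = "APOE"),
                assoc_row("rs2", "C", "T", 0.3, 0.1, gene = "PPM1K"))
  expect_equal(select_instruments(cset, exclusions = "APOE",
                                  protocol = "r2_0.8")$snp, "rs2")

  # greedy pruning: rs with r2 0.9 to a stronger hit is dropped
  d <- rbind(assoc_row("rs1", "A", "G", 0.2, 0.1, pvalue = 1e-12),
             assoc_row("rs2", "C", "T", 0.3, 0.1, pvalue = 1e-10),
             assoc_row("rs3", "A", "C", 0.4, 0.1, pvalue = 1e-9))
  ld <- data.frame(snp_a = c("rs1", "rs2"), snp_b = c("rs2", "rs1"),
                   r2 = c(0.9, 0.9))
  expect_warning(sel <- select_instruments(d, ld = ld, protocol = "r2_0.8"),
                 "missing")
  expect_setequal(sel$snp, c("rs1", "rs3"))

  # lead_snp keeps the lowest-p variant per locus
  e <- rbind(assoc_row("rs1", "A", "G", 0.2, 0.1, pvalue = 1e-12, gene = "G1"),
             assoc_row("rs2", "C", "T", 0.3, 0.1, pvalue = 1e-10, gene = "G1"),
             assoc_row("rs3", "A", "C", 0.4, 0.1, pvalue = 1e-9, gene = "G2"))
  expect_setequal(select_instruments(e, protocol = "lead_snp")$snp,
                  c("rs1", "rs3"))

  expect_error(select_instruments(b[0, ], protocol = "r2_0.8"),
               class = "bcaamr_empty_instrument")
})

test_that("selection is row-order independent and matches the greedy oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    snp <- sprintf("rs%02d", seq_len(n))
    a <- do.call(rbind, lapply(seq_len(n), function(i) {
      assoc_row(snp[i], "A", "G", 0.3, 0.1, pvalue = 10^-runif(1, 9, 15))
    }))
    r2mat <- matrix(0, n, n, dimnames = list(snp, snp))
    pairs <- which(upper.tri(r2mat), arr.ind = TRUE)
    r2v <- runif(nrow(pairs))
    ld <- data.frame(snp_a = snp[pairs[, 1]], snp_b = snp[pairs[, 2]], r2 = r2v)
    for (k in seq_len(nrow(pairs))) {
      r2mat[pairs[k, 1], pairs[k, 2]] <- r2v[k]
      r2mat[pairs[k, 2], pairs[k, 1]] <- r2v[k]
    }
    ld <- rbind(ld, setNames(ld[c(2, 1, 3)], names(ld)))
    kept <- select_instruments(a, ld = ld, protocol = "r2_0.8")$snp
    expect_setequal(kept, oracle_greedy_prune(a$snp, a$pvalue, r2mat, 0.8))
    shuffled <- a[sample(n), ]
    expect_setequal(select_instruments(shuffled, ld = ld,
                                       protocol = "r2_0.8")$snp, kept)
  }
})

test_that("variance explained sums per-variant 2f(1-f)b^2 contributions", {
  one <- make_instr(0.11, 0.01, eaf = 0.436)
  expect_equal(variance_explained(one)$total, 0.005950, tolerance = 1e-3)
  mono <- make_instr(c(0.11, 0.2), c(0.01, 0.01), eaf = c(0, 0.3))
  expect_equal(unname(variance_explained(mono)$per_snp[1]), 0)
  # invariant under relabeling the effect allele for any subset
  set.seed(1)
  instr <- make_instr(runif(6, 0.05, 0.3), runif(6, -0.02, 0.02),
                      eaf = runif(6, 0.05, 0.95))
  flip <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  flipped <- instr
  flipped$beta_exposure[flip] <- -flipped$beta_exposure[flip]
  flipped$eaf[flip] <- 1 - flipped$eaf[flip]
  expect_equal(variance_explained(flipped)$total,
               variance_explained(instr)$total)
  noeaf <- make_instr(0.1, 0.01)
  expect_error(variance_explained(noeaf), "rs001",
               class = "bcaamr_domain_error")
})
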