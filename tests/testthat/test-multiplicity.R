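# FDR/Bonferroni control and Ward clustering of Z-score matrices.

test_that("BH q-values match the step-up rule on worked cases", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$qvalue, rep(0.04, 4))
  expect_equal(bh_fdr(0.03)$qvalue, 0.03)
  expect_equal(bh_fdr(rep(0.2, 5))$qvalue, rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 0)), class = "bcaamr_domain_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "bcaamr_domain_error")
})

test_that("BH equals the brute-force definition for all small inputs", {
  set.seed(23)
  for (rep in 1:200) {
    n <- sample(1:10, 1)
    p <- runif(n)^sample(1:3, 1) # mix of uniform and skewed-to-small
    p[p == 0] <- 1e-12
    expect_equal(bh_fdr(p)$qvalue, oracle_bh(p))
  }
})

test_that("Bonferroni threshold is alpha over the test count", {
  expect_equal(bonferroni_threshold(0.05, 136), 0.05 / 136)
  expect_equal(bonferroni_threshold(0.05, 136), 3.676e-4, tolerance = 1e-3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_error(bonferroni_threshold(0.05, 0), class = "bcaamr_domain_error")
})

test_that("zscore_matrix builds, fills, proxies and round-trips", {
  loci <- sprintf("locus%02d", 1:17)
  traits <- sprintf("trait%d", 1:8)
  full <- expand.grid(locus = loci, trait = traits,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(3)
  full$z <- rnorm(nrow(full))
  m <- zscore_matrix(full, loci, traits)
  expect_equal(dim(m), c(17L, 8L))
  expect_false(any(attr(m, "filled")))

  # a missing cell is zero-filled and flagged
  part <- full[-1, ]
  expect_message(m2 <- zscore_matrix(part, loci, traits), "zero-filled")
  expect_equal(m2[full$locus[1], full$trait[1]], 0)
  expect_true(attr(m2, "filled")[full$locus[1], full$trait[1]])

  # a mapped proxy stands in for the missing sentinel
  proxy_rows <- data.frame(locus = "proxyA", trait = full$trait[1],
                           z = 9.9, stringsAsFactors = FALSE)
  m3 <- zscore_matrix(rbind(part, proxy_rows), loci, traits,
                      proxy_map = c(locus01 = "proxyA"))
  expect_equal(m3["locus01", full$trait[1]], 9.9)

  expect_error(zscore_matrix(rbind(full, full[1, ]), loci, traits),
               "duplicate", class = "bcaamr_config_error")

  path <- tempfile(fileext = ".tsv")
  write_zscore_matrix(m, path)
  expect_equal(read_zscore_matrix(path), m, ignore_attr = TRUE)
})

test_that("Ward clustering handles worked cases and degenerate input", {
  # identical rows merge first at height zero
  m <- rbind(a = c(1, 1), b = c(1, 1), c = c(5, 9))
  cl <- ward_cluster(m)
  expect_equal(sort(cl$merge[1, ]), c(-2, -1))
  expect_equal(cl$height[1], 0)
  # two tight pairs merge before anything crosses between them
  m4 <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  cl4 <- ward_cluster(m4)
  first_two <- list(sort(cl4$merge[1, ]), sort(cl4$merge[2, ]))
  has_pair <- function(pair) {
    any(vapply(first_two, function(m) all(m == pair), logical(1)))
  }
  expect_true(has_pair(c(-2, -1)))
  expect_true(has_pair(c(-4, -3)))
  # merge heights are non-decreasing
  set.seed(9)
  for (i in 1:10) {
    mm <- matrix(rnorm(8 * 3), 8, 3)
    expect_true(all(diff(ward_cluster(mm)$height) >= -1e-12))
  }
  expect_error(ward_cluster(matrix(1, 1, 2)), class = "bcaamr_domain_error")
  bad <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(ward_cluster(bad), "missing", class = "bcaamr_domain_error")
})

test_that("Ward clustering equals the naive Lance-Williams agglomeration", {
  set.seed(29)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    mm <- matrix(rnorm(n * sample(2:5, 1)), nrow = n)
    rownames(mm) <- sprintf("r%d", seq_len(n))
    cl <- ward_cluster(mm)
    expect_equal(unname(cl$cophenetic),
                 unname(oracle_ward_cophenetic(mm)), tolerance = 1e-8)
  }
})
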