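# Shared fixtures and independent brute-force oracles.

# Small instrument set straight from numeric vectors.
make_instr <- function(bx, by, sx = rep(0.01, length(bx)),
                       sy = rep(0.01, length(bx)), eaf = NULL, gene = NULL) {
  df <- data.frame(snp = sprintf("rs%03d", seq_along(bx)),
                   beta_exposure = bx, se_exposure = sx,
                   beta_outcome = by, se_outcome = sy,
                   stringsAsFactors = FALSE)
  if (!is.null(eaf)) df$eaf <- eaf
  if (!is.null(gene)) df$gene <- gene
  instrument_set(df)
}

# One-row variant association record.
assoc_row <- function(snp, ea, oa, eaf, beta, se = 0.05, pvalue = 1e-10,
                      gene = NA, chr = "1", trait = "bcaa") {
  data.frame(snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = pvalue, gene = gene, chr = chr,
             trait = trait, stringsAsFactors = FALSE)
}

# Brute-force greedy LD pruning: visit in ascending p (ties by id), keep a
# variant iff r2 with every kept variant is below the threshold.
oracle_greedy_prune <- function(snp, p, r2mat, thr) {
  ord <- order(p, snp)
  kept <- character(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) if (r2mat[snp[i], k] >= thr) { ok <- FALSE; break }
    if (ok) kept <- c(kept, snp[i])
  }
  kept
}

# Brute-force Benjamini-Hochberg q-values from the step-up definition:
# q_(i) = min over j >= i of m p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Textbook DerSimonian-Laird random-effects pooling.
oracle_dl <- function(yi, sei) {
  w <- 1 / sei^2
  ybar <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - ybar)^2)
  df <- length(yi) - 1
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / cc)
  wstar <- 1 / (sei^2 + tau2)
  mu <- sum(wstar * yi) / sum(wstar)
  se <- sqrt(1 / sum(wstar))
  list(mu = mu, se = se, tau2 = tau2, q = q,
       i2 = max(0, 100 * (q - df) / q))
}

# Naive O(n^3) Ward agglomeration: Lance-Williams update on squared
# Euclidean distances, merging the closest pair (ties: smallest index
# pair). Returns the cophenetic matrix of merge heights.
oracle_ward_cophenetic <- function(m) {
  n <- nrow(m)
  d <- as.matrix(dist(m))^2
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n)
  dd <- d
  diag(dd) <- Inf
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestv <- Inf
    idx <- which(active)
    for (a in idx) for (b in idx) {
      if (a < b && dd[a, b] < bestv - 1e-12) { bestv <- dd[a, b]; best <- c(a, b) }
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- bestv
    }
    # Lance-Williams Ward update of distances to the merged cluster
    for (k in idx) {
      if (k == i || k == j) next
      dd[i, k] <- dd[k, i] <-
        ((sizes[i] + sizes[k]) * dd[i, k] + (sizes[j] + sizes[k]) * dd[j, k] -
           sizes[k] * dd[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    dd[j, ] <- dd[, j] <- Inf
  }
  coph
}

write_temp_sumstats <- function(df, sep = "\t") {
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
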