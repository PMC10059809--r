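# Multiple-testing control and cross-trait Z-score clustering.

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up q-values (via [stats::p.adjust()]) with rejection flags at the
#' stated level.
#'
#' @param pvalues numeric vector of p-values in (0,1].
#' @param level FDR level (default 0.05).
#' @return `data.frame`: `pvalue, qvalue, reject`.
#' @export
bh_fdr <- function(pvalues, level = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    .stop_bcaamr("p-values must lie in (0, 1]", "bcaamr_domain_error")
  }
  q <- p.adjust(pvalues, method = "BH")
  data.frame(pvalue = pvalues, qvalue = q, reject = q <= level)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1L || is.na(m) || m < 1) {
    .stop_bcaamr("number of tests must be >= 1", "bcaamr_domain_error")
  }
  alpha / m
}

#' Assemble a locus-by-trait directional Z-score matrix
#'
#' Builds the dense matrix of directional Z-scores (effect divided by SE,
#' oriented to the exposure-raising allele) underlying cross-trait
#' clustering. Each (locus, trait) pair may contribute at most one record.
#' A missing sentinel can be backed by a proxy variant via `proxy_map`; any
#' remaining missing cell is handled per `missing_policy` (zero-filled with
#' a provenance flag, or left `NA`).
#'
#' @param assocs `data.frame` with columns `locus, trait, z`.
#' @param loci,traits row and column orders of the matrix.
#' @param proxy_map optional named character vector mapping a sentinel
#'   locus to its proxy locus label; the proxy's records fill the
#'   sentinel's row where needed.
#' @param missing_policy `"zero"` (default) or `"na"`.
#' @return numeric matrix `loci x traits`; `attr(, "filled")` is a logical
#'   matrix marking policy-filled cells.
#' @export
zscore_matrix <- function(assocs, loci, traits, proxy_map = NULL,
                          missing_policy = c("zero", "na")) {
  missing_policy <- match.arg(missing_policy)
  key <- paste(assocs$locus, assocs$trait, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    .stop_bcaamr(sprintf("duplicate association for (locus, trait): %s",
                         paste(gsub("\r", ", ", key[dup]), collapse = "; ")),
                 "bcaamr_config_error")
  }
  lookup <- setNames(assocs$z, key)
  m <- matrix(NA_real_, length(loci), length(traits),
              dimnames = list(loci, traits))
  filled <- matrix(FALSE, length(loci), length(traits),
                   dimnames = list(loci, traits))
  for (i in seq_along(loci)) {
    for (j in seq_along(traits)) {
      k <- paste(loci[i], traits[j], sep = "\r")
      if (!is.na(lookup[k])) { m[i, j] <- lookup[[k]]; next }
      if (!is.null(proxy_map) && loci[i] %in% names(proxy_map)) {
        pk <- paste(proxy_map[[loci[i]]], traits[j], sep = "\r")
        if (!is.na(lookup[pk])) { m[i, j] <- lookup[[pk]]; next }
      }
      if (missing_policy == "zero") {
        m[i, j] <- 0
        filled[i, j] <- TRUE
      }
    }
  }
  if (any(filled)) {
    message(sum(filled), " missing locus-trait cell(s) zero-filled")
  }
  attr(m, "filled") <- filled
  m
}

#' Write / read a Z-score matrix as delimited text
#'
#' Tab-separated with locus row labels and trait column headers; reading
#' back reproduces the matrix exactly.
#'
#' @param m matrix from [zscore_matrix()].
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_zscore_matrix <- function(m, path) {
  df <- data.frame(locus = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_zscore_matrix
#' @export
read_zscore_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Ward agglomerative clustering of a Z-score matrix
#'
#' Agglomerative hierarchical clustering with Ward's minimum-variance
#' criterion on squared Euclidean row distances (Lance-Williams update;
#' delegated to [stats::hclust()] with `method = "ward.D"`). Merge heights
#' are non-decreasing.
#'
#' @param m numeric matrix with at least 2 rows and no missing values.
#' @return list of class `cluster_result`: `merge` (pair indices),
#'   `height`, `order` (leaf order), `labels`, `cophenetic` (distance
#'   matrix of merge heights) and the underlying `hclust` object.
#' @export
ward_cluster <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2L) {
    .stop_bcaamr("clustering needs a matrix with >= 2 rows",
                 "bcaamr_domain_error")
  }
  if (anyNA(m)) {
    .stop_bcaamr(paste("matrix contains missing values; impute them first",
                       "(see zscore_matrix missing_policy)"),
                 "bcaamr_domain_error")
  }
  hc <- hclust(dist(m)^2, method = "ward.D")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = rownames(m),
                 cophenetic = as.matrix(cophenetic(hc)), hclust = hc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Ward clustering of %d rows; merge heights %.3g .. %.3g\n",
              length(x$height) + 1L, min(x$height), max(x$height)))
  invisible(x)
}
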