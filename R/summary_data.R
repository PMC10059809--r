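# GWAS summary-statistics data model: reading, validation, allele
# harmonization, instrument selection and variance explained.

.mandatory_cols <- c("snp", "effect_allele", "other_allele", "eaf",
                     "beta", "se", "pvalue")
.optional_cols <- c("gene", "chr", "n", "trait")

#' Default column mapping for summary-statistics files
#'
#' Named character vector mapping the canonical field names used throughout
#' the package to the column headers of an input file. Override entries to
#' match your file, e.g. `column_map = c(snp = "rsid", beta = "b")`.
#'
#' @return named character vector.
#' @export
default_column_map <- function() {
  setNames(c(.mandatory_cols, .optional_cols), c(.mandatory_cols, .optional_cols))
}

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read per-variant GWAS summary associations
#'
#' Reads a delimited text file (tab or comma separated, sniffed from the
#' header unless `sep` is given) into a validated table of per-variant
#' associations. Every mapped mandatory column must be present; rows whose
#' numeric fields cannot be parsed, or that violate the field invariants
#' (`eaf` in \[0,1\], `se > 0` unless `beta == 0`, `pvalue` in (0,1\],
#' distinct alleles), raise a single error listing the offending file line
#' numbers rather than being dropped silently.
#'
#' @param path path to the file.
#' @param column_map named character vector mapping canonical names
#'   (see [default_column_map()]) to file headers. Unmapped optional
#'   columns are filled with `NA`.
#' @param sep field separator; `NULL` to sniff.
#' @param trait optional trait label stored on every row (overrides a
#'   mapped trait column).
#' @return a `data.frame` of class `variant_assoc` with columns
#'   `snp, effect_allele, other_allele, eaf, beta, se, pvalue` plus the
#'   optional `gene, chr, n, trait`.
#' @export
read_summary_stats <- function(path, column_map = default_column_map(),
                               sep = NULL, trait = NULL) {
  if (!file.exists(path)) {
    .stop_bcaamr(sprintf("input file not found: %s", path), "bcaamr_io_error")
  }
  map <- default_column_map()
  map[names(column_map)] <- column_map
  if (is.null(sep)) sep <- .sniff_sep(path)
  raw <- read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  missing <- setdiff(map[.mandatory_cols], names(raw))
  if (length(missing)) {
    .stop_bcaamr(sprintf("missing mandatory column(s): %s",
                         paste(missing, collapse = ", ")),
                 "bcaamr_config_error")
  }
  out <- data.frame(snp = raw[[map[["snp"]]]],
                    effect_allele = toupper(raw[[map[["effect_allele"]]]]),
                    other_allele = toupper(raw[[map[["other_allele"]]]]),
                    stringsAsFactors = FALSE)
  for (col in c("eaf", "beta", "se", "pvalue")) {
    out[[col]] <- suppressWarnings(as.numeric(raw[[map[[col]]]]))
  }
  for (col in .optional_cols) {
    out[[col]] <- if (map[[col]] %in% names(raw)) raw[[map[[col]]]] else
      rep(NA, nrow(out))
  }
  if (!is.null(trait)) out$trait <- rep(trait, nrow(out))
  out$n <- suppressWarnings(as.numeric(out$n))
  if (nrow(out)) {
    bad <- !complete.cases(out[c("eaf", "beta", "se", "pvalue")]) |
      out$eaf < 0 | out$eaf > 1 |
      (out$se <= 0 & out$beta != 0) | out$se < 0 |
      out$pvalue <= 0 | out$pvalue > 1 |
      out$effect_allele == out$other_allele
    if (any(bad)) {
      .stop_bcaamr(sprintf(
        "invalid summary-statistics row(s) at file line(s): %s",
        paste(which(bad) + 1L, collapse = ", ")), "bcaamr_row_error")
    }
  }
  class(out) <- c("variant_assoc", "data.frame")
  out
}

#' Convert a ratio estimate with confidence interval to log scale
#'
#' Back-computes the log-scale point estimate and standard error from an
#' odds/risk ratio and its confidence bounds: `beta = log(point)`,
#' `se = (log(upper) - log(lower)) / (2 z)`, with `z` the standard-normal
#' quantile at `(1 + level)/2`.
#'
#' @param point,lower,upper positive ratio-scale estimate and CI bounds
#'   (vectorized).
#' @param level CI coverage, in (0,1). Default 0.95.
#' @return list with numeric vectors `beta` and `se`.
#' @export
se_from_ci <- function(point, lower, upper, level = 0.95) {
  if (any(point <= 0 | lower <= 0 | upper <= 0)) {
    .stop_bcaamr("ratio and CI bounds must be positive", "bcaamr_domain_error")
  }
  if (length(level) != 1L || level <= 0 || level >= 1) {
    .stop_bcaamr("level must be a single value in (0,1)", "bcaamr_domain_error")
  }
  if (any(lower > upper | point < lower | point > upper)) {
    .stop_bcaamr("CI bounds must satisfy lower <= point <= upper",
                 "bcaamr_order_error")
  }
  z <- qnorm((1 + level) / 2)
  list(beta = log(point), se = (log(upper) - log(lower)) / (2 * z))
}

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) {
  nchar(ea) == 1L & nchar(oa) == 1L & .complement(ea) == oa
}

.exclusion <- function(snp, reason) {
  structure(data.frame(snp = snp, reason = reason, stringsAsFactors = FALSE),
            class = c("mr_exclusion", "data.frame"))
}

#' Harmonize one exposure/outcome association pair to a shared effect allele
#'
#' Expresses the outcome association on the exposure's effect allele.
#' Swapped allele labels flip the outcome beta sign and complement its
#' frequency; complementary-strand representations are strand-flipped before
#' comparison. Palindromic variants (A/T, C/G) are handled by `policy`:
#' dropped, kept as reported, or aligned by comparing allele frequencies to
#' 0.5 on both sides (dropping when either frequency falls inside the
#' ambiguity band, where strand cannot be resolved). Irreconcilable allele
#' pairs yield an exclusion record, never a silent pass-through.
#'
#' @param exposure,outcome single-row `data.frame`s (or lists) with fields
#'   `snp, effect_allele, other_allele, eaf, beta, se`.
#' @param palindrome_policy one of `"drop"`, `"align_by_frequency"`, `"keep"`.
#' @param ambiguity_band half-width of the frequency band around 0.5 inside
#'   which a palindromic variant is considered unresolvable (default 0.08).
#' @return a one-row harmonized `data.frame` (columns `snp, beta_exposure,
#'   se_exposure, beta_outcome, se_outcome, eaf, palindromic, aligned`), or a
#'   one-row `mr_exclusion` `data.frame` with a `reason` code.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "align_by_frequency", "keep"),
                      ambiguity_band = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (exposure$snp != outcome$snp) {
    .stop_bcaamr("exposure and outcome records refer to different variants",
                 "bcaamr_domain_error")
  }
  e_ea <- toupper(exposure$effect_allele); e_oa <- toupper(exposure$other_allele)
  o_ea <- toupper(outcome$effect_allele); o_oa <- toupper(outcome$other_allele)
  pal <- .is_palindromic(e_ea, e_oa)
  snv <- nchar(e_ea) == 1L && nchar(e_oa) == 1L &&
    nchar(o_ea) == 1L && nchar(o_oa) == 1L

  b_out <- outcome$beta; f_out <- outcome$eaf
  matched <- FALSE
  if (o_ea == e_ea && o_oa == e_oa) {
    matched <- TRUE
  } else if (o_ea == e_oa && o_oa == e_ea) {
    b_out <- -b_out; f_out <- 1 - f_out; matched <- TRUE
  } else if (snv && !pal && .complement(o_ea) == e_ea && .complement(o_oa) == e_oa) {
    matched <- TRUE
  } else if (snv && !pal && .complement(o_ea) == e_oa && .complement(o_oa) == e_ea) {
    b_out <- -b_out; f_out <- 1 - f_out; matched <- TRUE
  }
  if (!matched) return(.exclusion(exposure$snp, "allele mismatch"))

  if (pal) {
    if (palindrome_policy == "drop") {
      return(.exclusion(exposure$snp, "palindromic"))
    }
    if (palindrome_policy == "align_by_frequency") {
      if (abs(exposure$eaf - 0.5) < ambiguity_band ||
          abs(f_out - 0.5) < ambiguity_band) {
        return(.exclusion(exposure$snp, "ambiguous palindromic frequency"))
      }
      # label-based matching cannot see strand for palindromes: if the two
      # frequencies disagree about which allele is minor, the outcome is on
      # the opposite strand orientation.
      if ((exposure$eaf - 0.5) * (f_out - 0.5) < 0) {
        b_out <- -b_out; f_out <- 1 - f_out
      }
    }
  }
  data.frame(snp = exposure$snp,
             beta_exposure = exposure$beta, se_exposure = exposure$se,
             beta_outcome = b_out, se_outcome = outcome$se,
             eaf = exposure$eaf, palindromic = pal, aligned = TRUE,
             stringsAsFactors = FALSE)
}

#' Construct an instrument set from harmonized per-variant rows
#'
#' @param x `data.frame` with columns `snp, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome` (plus optional `eaf, gene, chr, palindromic`).
#' @param protocol_label instrument-screening protocol label
#'   (`"r2_0.8"`, `"r2_0.001"`, `"lead_snp"` or `NA`).
#' @param exclusions optional `mr_exclusion` `data.frame` recording variants
#'   removed during harmonization (kept as provenance).
#' @return `data.frame` of class `instrument_set`.
#' @export
instrument_set <- function(x, protocol_label = NA_character_, exclusions = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(x) == 0L) {
    .stop_bcaamr("instrument set is empty", "bcaamr_empty_instrument")
  }
  needed <- c("snp", "beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    .stop_bcaamr(sprintf("instrument set lacks column(s): %s",
                         paste(missing, collapse = ", ")), "bcaamr_config_error")
  }
  if (anyDuplicated(x$snp)) {
    .stop_bcaamr("duplicated variant identifiers in instrument set",
                 "bcaamr_config_error")
  }
  if (any(x$se_exposure <= 0) || any(x$se_outcome <= 0)) {
    .stop_bcaamr("instrument standard errors must be positive",
                 "bcaamr_domain_error")
  }
  attr(x, "protocol_label") <- protocol_label
  attr(x, "exclusions") <- exclusions
  class(x) <- c("instrument_set", "data.frame")
  x
}

#' Harmonize matched exposure and outcome association tables
#'
#' Joins the two tables on variant identifier and applies [harmonize()] to
#' each shared variant. Exclusions (palindrome policy, allele mismatches)
#' are collected on the result as provenance, available via
#' `attr(x, "exclusions")`.
#'
#' @inheritParams harmonize
#' @param exposure,outcome `variant_assoc` tables (see
#'   [read_summary_stats()]).
#' @param protocol_label label recorded on the resulting [instrument_set()].
#' @return an [instrument_set()]; `gene`/`chr` columns from the exposure
#'   table are carried through when present.
#' @export
harmonize_set <- function(exposure, outcome,
                          palindrome_policy = c("drop", "align_by_frequency", "keep"),
                          ambiguity_band = 0.08,
                          protocol_label = NA_character_) {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure$snp, outcome$snp)
  if (!length(shared)) {
    .stop_bcaamr("no shared variants between exposure and outcome",
                 "bcaamr_empty_instrument")
  }
  rows <- vector("list", length(shared))
  excl <- list()
  for (i in seq_along(shared)) {
    e <- exposure[exposure$snp == shared[i], , drop = FALSE][1, ]
    o <- outcome[outcome$snp == shared[i], , drop = FALSE][1, ]
    h <- harmonize(e, o, palindrome_policy, ambiguity_band)
    if (inherits(h, "mr_exclusion")) excl[[length(excl) + 1L]] <- h
    else {
      for (col in c("gene", "chr")) if (col %in% names(e)) h[[col]] <- e[[col]]
      rows[[i]] <- h
    }
  }
  kept <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  exclusions <- if (length(excl)) do.call(rbind, excl) else NULL
  if (is.null(kept) || nrow(kept) == 0L) {
    .stop_bcaamr("all variants were excluded during harmonization",
                 "bcaamr_empty_instrument")
  }
  instrument_set(kept, protocol_label, exclusions)
}

#' Read a pairwise LD table
#'
#' Three-column delimited text (`snp_a`, `snp_b`, `r2`); symmetric
#' completion is applied.
#'
#' @param path file path.
#' @return `data.frame` with both orientations of every pair.
#' @export
read_ld_table <- function(path) {
  ld <- read.table(path, header = TRUE, sep = .sniff_sep(path),
                   stringsAsFactors = FALSE)
  names(ld)[1:3] <- c("snp_a", "snp_b", "r2")
  rbind(ld[c("snp_a", "snp_b", "r2")],
        setNames(ld[c("snp_b", "snp_a", "r2")], c("snp_a", "snp_b", "r2")))
}

.ld_lookup <- function(ld, a, b, chr_a, chr_b, warned) {
  # cross-chromosome pairs are independent by construction
  if (!is.na(chr_a) && !is.na(chr_b) && chr_a != chr_b) return(0)
  if (!is.null(ld)) {
    hit <- ld$r2[ld$snp_a == a & ld$snp_b == b]
    if (length(hit)) return(hit[1])
  }
  if (!warned$done) {
    warning("LD r2 missing for same-chromosome pair(s) (e.g. ", a, "/", b,
            "); treating missing pairs as r2 = 0", call. = FALSE)
    warned$done <- TRUE
  }
  0
}

#' Select genetic instruments from exposure associations
#'
#' Applies the instrument-screening protocol: (1) keep genome-wide
#' significant associations (`pvalue < p_threshold`); (2) for a variant
#' associated with several exposure traits (e.g. the three BCAAs), keep the
#' strongest association — smallest p-value, ties broken by largest
#' `|beta|`, then trait label; (3) drop variants whose `gene` or `snp` is on
#' the exclusion list (confounder loci); (4) prune for linkage
#' disequilibrium greedily in ascending p-value order (ties by variant id),
#' keeping a variant only if its r-squared with every already-kept variant
#' is below the protocol threshold (0.8 or 0.001). The `lead_snp` protocol
#' instead keeps exactly the lowest-p variant per gene/locus label.
#' Same-chromosome pairs absent from the LD table count as r2 = 0 with a
#' warning; cross-chromosome pairs are always independent.
#'
#' @param assocs `variant_assoc` table covering one or more exposure traits.
#' @param p_threshold genome-wide significance cutoff (default 5e-8).
#' @param ld pairwise LD table from [read_ld_table()] (or a `data.frame`
#'   with columns `snp_a, snp_b, r2`), `NULL` for none.
#' @param protocol `"r2_0.8"`, `"r2_0.001"` or `"lead_snp"`.
#' @param exclusions character vector of gene names and/or variant ids to
#'   exclude.
#' @return the selected rows of `assocs` (class `selected_instruments`),
#'   ordered by ascending p-value, with the protocol stored as an attribute.
#' @export
select_instruments <- function(assocs, p_threshold = 5e-8, ld = NULL,
                               protocol = c("r2_0.8", "r2_0.001", "lead_snp"),
                               exclusions = NULL) {
  protocol <- match.arg(protocol)
  keep <- assocs[assocs$pvalue < p_threshold, , drop = FALSE]
  # strongest association per variant across exposure traits
  if (nrow(keep)) {
    trait <- if ("trait" %in% names(keep)) as.character(keep$trait) else ""
    ord <- order(keep$pvalue, -abs(keep$beta), trait)
    keep <- keep[ord, , drop = FALSE]
    keep <- keep[!duplicated(keep$snp), , drop = FALSE]
  }
  if (!is.null(exclusions) && nrow(keep)) {
    gene <- if ("gene" %in% names(keep)) as.character(keep$gene) else NA
    keep <- keep[!(keep$snp %in% exclusions | gene %in% exclusions), ,
                 drop = FALSE]
  }
  if (nrow(keep)) {
    ord <- order(keep$pvalue, keep$snp)
    keep <- keep[ord, , drop = FALSE]
    if (protocol == "lead_snp") {
      locus <- if ("gene" %in% names(keep) && !all(is.na(keep$gene))) {
        as.character(keep$gene)
      } else as.character(keep$chr)
      keep <- keep[!duplicated(locus), , drop = FALSE]
    } else {
      thr <- if (protocol == "r2_0.8") 0.8 else 0.001
      chr <- if ("chr" %in% names(keep)) as.character(keep$chr) else
        rep(NA_character_, nrow(keep))
      warned <- new.env(); warned$done <- FALSE
      sel <- logical(nrow(keep))
      for (i in seq_len(nrow(keep))) {
        ok <- TRUE
        for (j in which(sel)) {
          r2 <- .ld_lookup(ld, keep$snp[i], keep$snp[j], chr[i], chr[j], warned)
          if (r2 >= thr) { ok <- FALSE; break }
        }
        sel[i] <- ok
      }
      keep <- keep[sel, , drop = FALSE]
    }
  }
  if (nrow(keep) == 0L) {
    .stop_bcaamr("no instruments survive selection", "bcaamr_empty_instrument")
  }
  rownames(keep) <- NULL
  attr(keep, "protocol_label") <- protocol
  class(keep) <- c("selected_instruments", "data.frame")
  keep
}

#' Proportion of exposure variance explained by an instrument set
#'
#' Per-variant contribution `2 f (1 - f) beta^2` for a standardized
#' (SD-unit) exposure, summed over the set. Invariant under relabeling the
#' effect allele (`f -> 1 - f`, `beta -> -beta`).
#'
#' @param instr an [instrument_set()] (uses `beta_exposure`) or a
#'   `variant_assoc` table (uses `beta`).
#' @return list with `total` (fraction) and `per_snp` (named vector).
#' @export
variance_explained <- function(instr) {
  beta <- if ("beta_exposure" %in% names(instr)) instr$beta_exposure else instr$beta
  f <- instr$eaf
  if (is.null(f) || anyNA(f)) {
    missing <- if (is.null(f)) instr$snp else instr$snp[is.na(f)]
    .stop_bcaamr(sprintf("effect-allele frequency missing for: %s",
                         paste(missing, collapse = ", ")),
                 "bcaamr_domain_error")
  }
  per <- setNames(2 * f * (1 - f) * beta^2, instr$snp)
  list(total = sum(per), per_snp = per)
}

#' Write an instrument set as delimited text
#'
#' Tab-separated with a provenance column carrying the screening protocol.
#'
#' @param instr an [instrument_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(instr, path) {
  out <- as.data.frame(instr)
  out$protocol <- attr(instr, "protocol_label")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
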