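#' Instrument-selection configuration
#'
#' Bundles the thresholds of the five-step instrument selection: cis-region
#' restriction, genome-wide significance with an adjusted-p screen, LD
#' clumping, and F-statistic weak-instrument filtering.
#'
#' @param pval_max Keep SNPs with p-value strictly below this (default
#'   `5e-8`, genome-wide significance).
#' @param pval_adj_max Keep SNPs with adjusted p-value strictly below this
#'   (default `0.05`); set `NULL` to skip the adjusted-p screen.
#' @param clump_r2_max Maximum pairwise r-squared retained after LD clumping
#'   (default `0.01`).
#' @param f_min Minimum instrument F-statistic `beta^2/se^2`; SNPs with F
#'   strictly less than this are removed (default `10`, so F = 10 is kept).
#' @param cis_chrom,cis_start,cis_end Chromosome label and 1-based inclusive
#'   boundaries of the target gene; `cis_chrom = NULL` disables the region
#'   filter.
#' @param cis_flank Flank added on both sides of the gene, in bp (default
#'   1 Mb, the usual cis-eQTL window).
#' @return A `selection_config` list.
#' @export
selection_config <- function(pval_max = 5e-8, pval_adj_max = 0.05,
                             clump_r2_max = 0.01, f_min = 10,
                             cis_chrom = NULL, cis_start = NULL,
                             cis_end = NULL, cis_flank = 1e6) {
  assert_scalar_number(pval_max, "pval_max", positive = TRUE)
  if (!is.null(pval_adj_max)) assert_scalar_number(pval_adj_max, "pval_adj_max", positive = TRUE)
  assert_scalar_number(clump_r2_max, "clump_r2_max", positive = TRUE)
  assert_scalar_number(f_min, "f_min", positive = TRUE)
  if (!is.null(cis_chrom)) {
    assert_scalar_number(cis_start, "cis_start")
    assert_scalar_number(cis_end, "cis_end")
    assert_scalar_number(cis_flank, "cis_flank")
    if (cis_start > cis_end) stop("cis_start must be <= cis_end", call. = FALSE)
  }
  structure(list(pval_max = pval_max, pval_adj_max = pval_adj_max,
                 clump_r2_max = clump_r2_max, f_min = f_min,
                 cis_chrom = cis_chrom, cis_start = cis_start,
                 cis_end = cis_end, cis_flank = cis_flank),
            class = "selection_config")
}

#' Restrict a table to the cis region of the target gene
#'
#' Keeps records on the configured chromosome with position inside
#' `[cis_start - cis_flank, cis_end + cis_flank]`, inclusive on both ends.
#'
#' @param table A `sumstats` table carrying `chrom` and `pos`.
#' @param config A [selection_config()].
#' @return Filtered `sumstats` table.
#' @export
restrict_to_cis_region <- function(table, config) {
  if (is.null(config$cis_chrom)) return(table)
  if (any(is.na(table$chrom)) || any(is.na(table$pos))) {
    stop("cis-region filter requested but records lack chrom/pos", call. = FALSE)
  }
  lo <- config$cis_start - config$cis_flank
  hi <- config$cis_end + config$cis_flank
  keep <- table$chrom == as.character(config$cis_chrom) &
    table$pos >= lo & table$pos <= hi
  table[keep, , drop = FALSE]
}

#' Filter by significance thresholds
#'
#' Keeps records with `pval < pval_max` and, when `pval_adj_max` is
#' configured, `pval_adj < pval_adj_max`. Both inequalities are strict, so a
#' p-value exactly at the genome-wide threshold is dropped.
#'
#' @inheritParams restrict_to_cis_region
#' @return Filtered `sumstats` table.
#' @export
filter_by_pvalue <- function(table, config) {
  keep <- table$pval < config$pval_max
  if (!is.null(config$pval_adj_max)) {
    if (all(is.na(table$pval_adj))) {
      stop("pval_adj_max configured but the table has no adjusted p-values",
           call. = FALSE)
    }
    keep <- keep & !is.na(table$pval_adj) & table$pval_adj < config$pval_adj_max
  }
  table[keep, , drop = FALSE]
}

#' Bonferroni-adjusted p-values for a candidate table
#'
#' Fallback for sources that do not ship an adjusted-p column: multiplies
#' each p-value by the number of rows in the (cis-restricted) table, capped
#' at 1.
#'
#' @param table A `sumstats` table.
#' @return The table with `pval_adj` filled in.
#' @export
add_bonferroni_adjustment <- function(table) {
  table$pval_adj <- pmin(1, table$pval * nrow(table))
  table
}

#' Remove SNPs on an exclusion list
#'
#' @param table A `sumstats` table.
#' @param excl Exclusion list: a data frame with a `snp_id` column (see
#'   [read_exclusion_list()]), a character vector of identifiers, or `NULL`
#'   for a no-op.
#' @return List with `table` (filtered) and `removed` (identifiers actually
#'   removed, for reporting).
#' @export
apply_exclusion_list <- function(table, excl = NULL) {
  ids <- if (is.null(excl)) character(0)
  else if (is.data.frame(excl)) excl$snp_id
  else as.character(excl)
  removed <- intersect(table$snp_id, ids)
  list(table = table[!table$snp_id %in% ids, , drop = FALSE], removed = removed)
}

#' Greedy LD clumping
#'
#' Sorts candidates by p-value (ties broken by `snp_id` lexicographic order,
#' making the result deterministic and invariant to input row order), then
#' repeatedly accepts the best remaining SNP and discards every remaining
#' SNP with r-squared above `r2_max` against any accepted SNP. The returned
#' set is mutually quasi-independent: all pairwise r-squared <= `r2_max`.
#'
#' @param table A `sumstats` table.
#' @param ld Named square LD correlation matrix (correlations r, not r^2)
#'   covering every SNP in `table`.
#' @param r2_max r-squared threshold (default 0.01).
#' @return Filtered `sumstats` table (original row order preserved).
#' @export
ld_clump <- function(table, ld, r2_max = 0.01) {
  validate_ld_matrix(ld)
  absent <- setdiff(table$snp_id, rownames(ld))
  if (length(absent)) {
    stop("SNP(s) missing from LD matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(table$pval, table$snp_id)
  cand <- table$snp_id[ord]
  kept <- character(0)
  while (length(cand)) {
    top <- cand[[1L]]
    kept <- c(kept, top)
    cand <- cand[-1L]
    if (length(cand)) {
      r2 <- ld[cand, top]^2
      cand <- cand[r2 <= r2_max]
    }
  }
  table[table$snp_id %in% kept, , drop = FALSE]
}

#' Instrument F-statistic
#'
#' The per-SNP instrument-strength statistic `beta^2 / se^2`; values below
#' 10 conventionally signal a weak instrument.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), all > 0.
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) stop("`se` must be finite and > 0", call. = FALSE)
  beta^2 / se^2
}

#' Remove weak instruments
#'
#' Keeps records whose F-statistic is at least `f_min`; an F of exactly
#' `f_min` is retained (only values *less than* the threshold are excluded).
#'
#' @param table A `sumstats` table.
#' @param f_min Minimum F (default 10).
#' @return Filtered `sumstats` table.
#' @export
filter_weak <- function(table, f_min = 10) {
  table[f_statistic(table$beta, table$se) >= f_min, , drop = FALSE]
}

#' Five-step instrument selection
#'
#' Applies, in order: cis-region restriction, significance filtering (raw
#' and adjusted p), exclusion-list removal, greedy LD clumping and
#' weak-instrument (F-statistic) filtering. Each step only removes records,
#' so the per-step survivor counts in the report are non-increasing.
#'
#' @param table Candidate `sumstats` table (e.g. cis-eQTLs of the target
#'   gene).
#' @param config A [selection_config()].
#' @param excl Optional exclusion list (see [apply_exclusion_list()]).
#' @param ld Optional LD correlation matrix; `NULL` skips clumping (treated
#'   as no LD between candidates).
#' @return List with `table` (the selected instruments) and `report` (a
#'   `selection_report`: per-step survivor counts, removed identifiers, and
#'   the F-statistics of the final set).
#' @export
select_instruments <- function(table, config, excl = NULL, ld = NULL) {
  fail <- function(step) {
    stop("no instruments survive selection (first emptying step: ", step, ")",
         call. = FALSE)
  }
  s1 <- restrict_to_cis_region(table, config)
  if (!nrow(s1)) fail("cis-region")
  s2 <- filter_by_pvalue(s1, config)
  if (!nrow(s2)) fail("p-value")
  ex <- apply_exclusion_list(s2, excl)
  s3 <- ex$table
  if (!nrow(s3)) fail("exclusion-list")
  s4 <- if (is.null(ld)) s3 else ld_clump(s3, ld, config$clump_r2_max)
  if (!nrow(s4)) fail("ld-clump")
  s5 <- filter_weak(s4, config$f_min)
  if (!nrow(s5)) fail("weak-instrument")

  f <- stats::setNames(f_statistic(s5$beta, s5$se), s5$snp_id)
  report <- structure(list(
    counts = c(input = nrow(table), cis = nrow(s1), pvalue = nrow(s2),
               exclusion = nrow(s3), ld_clump = nrow(s4), weak = nrow(s5)),
    removed_by_exclusion = ex$removed,
    f_statistics = f
  ), class = "selection_report")
  list(table = s5, report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Instrument selection report\n")
  cat("  survivors per step:\n")
  for (nm in names(x$counts)) cat(sprintf("    %-10s %d\n", nm, x$counts[[nm]]))
  if (length(x$removed_by_exclusion)) {
    cat("  removed by exclusion list:",
        paste(x$removed_by_exclusion, collapse = ", "), "\n")
  }
  cat(sprintf("  final F-statistics: %.2f to %.2f (n = %d)\n",
              min(x$f_statistics), max(x$f_statistics), length(x$f_statistics)))
  invisible(x)
}
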