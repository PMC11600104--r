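# Canonical on-disk column names for summary-statistics tables.
# Internal field name -> canonical header.
CANONICAL_COLUMNS <- c(
  snp_id = "SNP", chrom = "CHR", pos = "POS",
  effect_allele = "EA", other_allele = "OA", eaf = "EAF",
  beta = "BETA", se = "SE", pval = "P", pval_adj = "P_ADJ", n = "N"
)

MANDATORY_FIELDS <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")

#' Column maps for common summary-statistics header dialects
#'
#' A column map is a named character vector translating the package's
#' internal field names (`snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `pval_adj`, `n`) to the
#' headers used in a particular file. `column_map_canonical()` matches files
#' written by [write_sumstats()]; `column_map_finngen()` matches FinnGen
#' release exports (where the effect allele is the alternate allele).
#'
#' @return Named character vector usable as the `column_map` argument of
#'   [read_sumstats()].
#' @export
column_map_canonical <- function() CANONICAL_COLUMNS

#' @rdname column_map_canonical
#' @export
column_map_finngen <- function() {
  c(snp_id = "rsids", chrom = "#chrom", pos = "pos",
    effect_allele = "alt", other_allele = "ref", eaf = "af_alt",
    beta = "beta", se = "sebeta", pval = "pval")
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("file is empty: ", path, call. = FALSE)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab, comma or whitespace separated; the
#' delimiter is auto-detected from the header line) with one row per SNP and
#' validates every row. Rows violating the per-record invariants (alleles not
#' a single A/C/G/T character, identical alleles, non-positive standard
#' error, p-value outside (0, 1], allele frequency outside \[0, 1\]) are
#' dropped and counted; alleles are upper-cased.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping internal field names to
#'   file headers (see [column_map_canonical()]). `NULL` uses the canonical
#'   headers. Must identify at least `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`.
#' @param trait_id Label attached to the table and every record.
#' @return A `sumstats` data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `pval_adj`, `n`, `trait_id`, and attributes `trait_id`, `n_dropped`
#'   (invalid rows removed) and `metadata`.
#' @seealso [write_sumstats()], [harmonize()]
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = "trait") {
  if (!file.exists(path)) stop("cannot read summary statistics file: ", path, call. = FALSE)
  column_map <- column_map %||% CANONICAL_COLUMNS
  missing_fields <- setdiff(MANDATORY_FIELDS, names(column_map))
  if (length(missing_fields)) {
    stop("column_map must identify mandatory column(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  absent <- setdiff(names(column_map)[names(column_map) %in% MANDATORY_FIELDS],
                    names(column_map)[column_map %in% names(raw)])
  if (length(absent)) {
    stop("mandatory column(s) missing from file: ",
         paste(column_map[absent], collapse = ", "), call. = FALSE)
  }

  pull <- function(field, as = "character") {
    header <- if (field %in% names(column_map)) column_map[[field]]
    if (is.null(header) || !header %in% names(raw)) {
      return(switch(as, character = NA_character_, numeric = NA_real_,
                    integer = NA_integer_))
    }
    x <- raw[[header]]
    switch(as,
           character = as.character(x),
           numeric = suppressWarnings(as.numeric(x)),
           integer = suppressWarnings(as.integer(round(as.numeric(x)))))
  }

  tab <- data.frame(
    snp_id = pull("snp_id"),
    chrom = pull("chrom"),
    pos = pull("pos", "integer"),
    effect_allele = toupper(pull("effect_allele")),
    other_allele = toupper(pull("other_allele")),
    eaf = pull("eaf", "numeric"),
    beta = pull("beta", "numeric"),
    se = pull("se", "numeric"),
    pval = pull("pval", "numeric"),
    pval_adj = pull("pval_adj", "numeric"),
    n = pull("n", "numeric"),
    stringsAsFactors = FALSE
  )
  new_sumstats(tab, trait_id = trait_id, metadata = list(path = path))
}

#' Construct a validated summary-statistics table from a data frame
#'
#' The in-memory counterpart of [read_sumstats()]: validates record
#' invariants, drops and counts offending rows, and stamps the class and
#' attributes used throughout the pipeline.
#'
#' @param tab Data frame with (a subset of) the internal columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `pval_adj`, `n`.
#' @param trait_id Trait label.
#' @param metadata Free-form provenance list.
#' @return A `sumstats` data frame.
#' @export
new_sumstats <- function(tab, trait_id = "trait", metadata = list()) {
  for (col in names(CANONICAL_COLUMNS)) {
    if (!col %in% names(tab)) tab[[col]] <- NA
  }
  tab <- tab[names(CANONICAL_COLUMNS)]
  tab$effect_allele <- toupper(as.character(tab$effect_allele))
  tab$other_allele <- toupper(as.character(tab$other_allele))

  valid_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  ok <- !is.na(tab$snp_id) & nzchar(tab$snp_id) &
    valid_allele(tab$effect_allele) & valid_allele(tab$other_allele) &
    tab$effect_allele != tab$other_allele &
    is.finite(tab$beta) &
    is.finite(tab$se) & tab$se > 0 &
    is.finite(tab$pval) & tab$pval > 0 & tab$pval <= 1 &
    (is.na(tab$eaf) | (tab$eaf >= 0 & tab$eaf <= 1)) &
    (is.na(tab$pval_adj) | (tab$pval_adj > 0 & tab$pval_adj <= 1))
  n_dropped <- sum(!ok)
  tab <- tab[ok, , drop = FALSE]
  if (!nrow(tab)) stop("no valid summary-statistics rows", call. = FALSE)
  if (anyDuplicated(tab$snp_id)) {
    stop("duplicate snp_id in summary-statistics table: ",
         paste(unique(tab$snp_id[duplicated(tab$snp_id)]), collapse = ", "),
         call. = FALSE)
  }
  tab$trait_id <- trait_id
  rownames(tab) <- NULL
  structure(tab,
            trait_id = trait_id,
            n_dropped = n_dropped,
            metadata = metadata,
            class = c("sumstats", "data.frame"))
}

#' Write a summary-statistics table
#'
#' Writes the canonical tab-separated layout (`SNP CHR POS EA OA EAF BETA SE
#' P P_ADJ N`). Numeric fields are written with 17 significant digits so a
#' read/write round trip reproduces every finite value bit-exactly; missing
#' values are encoded as `NA`.
#'
#' @param table A `sumstats` table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(table, path) {
  out <- as.data.frame(table)[names(CANONICAL_COLUMNS)]
  names(out) <- unname(CANONICAL_COLUMNS)
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  for (col in c("POS", "EAF", "BETA", "SE", "P", "P_ADJ", "N")) {
    out[[col]] <- fmt_num(as.numeric(out[[col]]))
  }
  out$CHR <- ifelse(is.na(out$CHR), "NA", as.character(out$CHR))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write summary statistics to: ", path, call. = FALSE)
  invisible(path)
}

#' Is a variant palindromic?
#'
#' A biallelic variant is palindromic (strand-ambiguous) when its allele pair
#' is A/T or C/G: the alleles read the same on both strands, so effect-allele
#' alignment between two datasets cannot be resolved from allele labels.
#'
#' @param effect_allele Effect allele(s), or a data frame with
#'   `effect_allele` and `other_allele` columns.
#' @param other_allele Other allele(s); ignored when `effect_allele` is a
#'   data frame.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele = NULL) {
  if (is.data.frame(effect_allele)) {
    other_allele <- effect_allele$other_allele
    effect_allele <- effect_allele$effect_allele
  }
  a <- toupper(effect_allele)
  b <- toupper(other_allele)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize exposure and outcome summary statistics
#'
#' Pairs SNPs present in both tables (matching on `snp_id`) and aligns the
#' outcome association to the exposure's effect allele. Palindromic (A/T,
#' C/G) variants are discarded outright — no frequency-based strand
#' inference is attempted. When the outcome's alleles are swapped relative
#' to the exposure, the outcome beta's sign is flipped and its allele
#' frequency complemented; when they match only as strand complements the
#' outcome alleles are complemented first and alignment is retried.
#' Irreconcilable allele pairs are dropped.
#'
#' @param exposure,outcome `sumstats` tables (see [read_sumstats()]).
#' @return A `harmonized_pairs` data frame with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `beta_outcome`, `se_outcome`, `flipped`, and a
#'   `report` attribute counting SNPs in each harmonization category
#'   (retrievable with [harmonization_report()]).
#' @export
harmonize <- function(exposure, outcome) {
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared)) {
    stop("no overlapping SNPs between exposure and outcome tables", call. = FALSE)
  }
  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  pal <- is_palindromic(ex) | is_palindromic(ou)

  o_ea <- ou$effect_allele
  o_oa <- ou$other_allele
  aligned <- o_ea == ex$effect_allele & o_oa == ex$other_allele
  swapped <- o_ea == ex$other_allele & o_oa == ex$effect_allele
  c_ea <- unname(COMPLEMENT[o_ea])
  c_oa <- unname(COMPLEMENT[o_oa])
  comp_aligned <- !aligned & !swapped &
    c_ea == ex$effect_allele & c_oa == ex$other_allele
  comp_swapped <- !aligned & !swapped &
    c_ea == ex$other_allele & c_oa == ex$effect_allele

  usable <- !pal & (aligned | swapped | comp_aligned | comp_swapped)
  flip <- (swapped | comp_swapped)[usable]

  pairs <- data.frame(
    snp_id = ex$snp_id[usable],
    effect_allele = ex$effect_allele[usable],
    other_allele = ex$other_allele[usable],
    beta_exposure = ex$beta[usable],
    se_exposure = ex$se[usable],
    eaf_exposure = ex$eaf[usable],
    beta_outcome = ifelse(flip, -ou$beta[usable], ou$beta[usable]),
    se_outcome = ou$se[usable],
    eaf_outcome = ifelse(flip, 1 - ou$eaf[usable], ou$eaf[usable]),
    flipped = flip,
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  report <- list(
    n_exposure = nrow(exposure),
    n_outcome = nrow(outcome),
    n_overlap = length(shared),
    n_palindromic = sum(pal),
    n_aligned = sum(aligned & !pal),
    n_flipped = sum((swapped | comp_swapped) & !pal),
    n_strand_complemented = sum((comp_aligned | comp_swapped) & !pal),
    n_irreconcilable = sum(!pal & !(aligned | swapped | comp_aligned | comp_swapped)),
    n_pairs = nrow(pairs)
  )
  structure(pairs, report = report,
            class = c("harmonized_pairs", "data.frame"))
}

#' @rdname harmonize
#' @param pairs A `harmonized_pairs` object.
#' @export
harmonization_report <- function(pairs) attr(pairs, "report")

# Validate a harmonized-pairs-shaped data frame before estimation.
as_pairs <- function(pairs) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs))) {
    stop("`pairs` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"snp_id" %in% names(pairs)) pairs$snp_id <- sprintf("snp_%d", seq_len(nrow(pairs)))
  if (any(!is.finite(pairs$se_exposure) | pairs$se_exposure <= 0) ||
      any(!is.finite(pairs$se_outcome) | pairs$se_outcome <= 0)) {
    stop("standard errors must be finite and > 0", call. = FALSE)
  }
  pairs
}

#' Read an LD correlation matrix
#'
#' Expects delimited text whose first row and first column are SNP
#' identifiers and whose body holds pairwise correlations r (not r-squared).
#' The matrix must be square, symmetric, with unit diagonal and all |r| <= 1.
#'
#' @param path Path to the matrix file.
#' @return A named square numeric matrix.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("cannot read LD matrix file: ", path, call. = FALSE)
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  validate_ld_matrix(m)
  m
}

validate_ld_matrix <- function(m) {
  if (nrow(m) != ncol(m)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("LD matrix row and column names must be identical SNP identifiers",
         call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8) stop("LD matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(m) - 1)) > 1e-8) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (any(abs(m) > 1 + 1e-8)) stop("LD correlations must satisfy |r| <= 1", call. = FALSE)
  invisible(m)
}

#' Write an LD correlation matrix
#'
#' @param m Named square correlation matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ld_matrix <- function(m, path) {
  validate_ld_matrix(m)
  out <- data.frame(SNP = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP exclusion list
#'
#' One SNP identifier per line, with an optional tab-separated reason column.
#' Such a list typically records variants found to be associated with other
#' genes or phenotypes in a catalogue lookup, to be removed from the
#' instrument set.
#'
#' @param path Path to the list.
#' @return Data frame with columns `snp_id` and `reason` (NA when absent).
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop("cannot read exclusion list: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    snp_id = vapply(parts, `[[`, character(1), 1L),
    reason = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
                    character(1)),
    stringsAsFactors = FALSE
  )
}
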