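#' Confounder pathway triple for two-step cis-MR
#'
#' Packages the quantities needed to subtract one confounder pathway from
#' each instrument's outcome association: per-SNP variant-to-confounder
#' effects (`b_gc`, `se_gc`) and a single confounder-to-outcome estimate
#' (`b_co`, `se_co`) — "one MR estimate and two variant-phenotype
#' estimates" per pathway.
#'
#' @param confounder_id Confounder label.
#' @param snp_id Instrument identifiers.
#' @param b_gc,se_gc Per-SNP SNP-to-confounder betas and SEs (vectors
#'   matching `snp_id`; `se_gc` >= 0).
#' @param b_co,se_co Scalar confounder-to-outcome estimate and SE
#'   (`se_co` >= 0), typically itself an MR estimate.
#' @return A `confounder_triple` list.
#' @export
confounder_triple <- function(confounder_id, snp_id, b_gc, se_gc, b_co, se_co) {
  n <- length(snp_id)
  if (length(b_gc) != n || length(se_gc) != n) {
    stop("b_gc and se_gc must match snp_id in length", call. = FALSE)
  }
  if (any(se_gc < 0)) stop("se_gc must be >= 0", call. = FALSE)
  assert_scalar_number(b_co, "b_co")
  assert_scalar_number(se_co, "se_co")
  if (se_co < 0) stop("se_co must be >= 0", call. = FALSE)
  structure(list(confounder_id = confounder_id,
                 snp_id = as.character(snp_id),
                 b_gc = as.numeric(b_gc), se_gc = as.numeric(se_gc),
                 b_co = b_co, se_co = se_co),
            class = "confounder_triple")
}

#' Adjust instrument-outcome associations for a confounder pathway
#'
#' Two-step cis-MR correction: for each instrument the outcome beta is
#' reduced by the pathway through the confounder,
#' `beta_outcome' = beta_outcome - b_gc * b_co`, and the standard error is
#' inflated by first-order delta propagation,
#' `se' = sqrt(se_outcome^2 + b_gc^2 se_co^2 + b_co^2 se_gc^2)`. The
#' exposure side is untouched. A null pathway (`b_gc * b_co = 0` with zero
#' SEs on the null component) is the identity, and the adjusted SE is never
#' smaller than the unadjusted one.
#'
#' @param pairs Harmonized pairs (see [harmonize()]).
#' @param triple A [confounder_triple()] covering every SNP in `pairs`.
#' @return The pairs with adjusted `beta_outcome` and `se_outcome`.
#' @export
tscmr_adjust <- function(pairs, triple) {
  pairs <- as_pairs(pairs)
  idx <- match(pairs$snp_id, triple$snp_id)
  if (anyNA(idx)) {
    stop("SNP(s) missing from confounder triple '", triple$confounder_id,
         "': ", paste(pairs$snp_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  b_gc <- triple$b_gc[idx]
  se_gc <- triple$se_gc[idx]
  pairs$beta_outcome <- pairs$beta_outcome - b_gc * triple$b_co
  pairs$se_outcome <- sqrt(pairs$se_outcome^2 +
                             b_gc^2 * triple$se_co^2 +
                             triple$b_co^2 * se_gc^2)
  pairs
}

#' Re-estimate the causal effect under confounder adjustment
#'
#' Applies [tscmr_adjust()] for each confounder pathway in turn (one at a
#' time, as separate sensitivity analyses, not jointly) and re-runs the IVW
#' estimator, comparing every adjusted estimate against the unadjusted
#' baseline.
#'
#' @param pairs Harmonized pairs.
#' @param triples A list of [confounder_triple()] objects.
#' @param model IVW model passed to [mr_ivw()].
#' @return List of class `tscmr_result` with `table` (one row per
#'   confounder plus the unadjusted baseline) and `estimates`.
#' @export
tscmr_pipeline <- function(pairs, triples, model = c("random", "fixed")) {
  pairs <- as_pairs(pairs)
  model <- match.arg(model)
  if (inherits(triples, "confounder_triple")) triples <- list(triples)
  baseline <- mr_ivw(pairs, model)
  ests <- list(unadjusted = baseline)
  for (tr in triples) {
    ests[[tr$confounder_id]] <- mr_ivw(tscmr_adjust(pairs, tr), model)
  }
  rows <- Map(function(nm, e) {
    data.frame(confounder = nm, n_snps = e$n_snps, beta = e$beta, se = e$se,
               or = e$odds_ratio, or_ci_low = e$or_ci_low,
               or_ci_high = e$or_ci_high, pval = e$pval,
               stringsAsFactors = FALSE)
  }, names(ests), ests)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, estimates = ests), class = "tscmr_result")
}

#' @export
print.tscmr_result <- function(x, ...) {
  cat("Two-step cis-MR confounder adjustment\n")
  print(x$table, digits = 4)
  invisible(x)
}
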