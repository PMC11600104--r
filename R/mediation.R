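#' Back-derive a standard error from a 95% confidence interval
#'
#' `se = (ci_high - ci_low) / (2 * 1.959964)`, the inverse of the symmetric
#' normal interval. Useful when only point estimates and CIs are published.
#'
#' @param ci_low,ci_high Interval bounds.
#' @return Standard error.
#' @export
se_from_ci <- function(ci_low, ci_high) {
  if (any(ci_high <= ci_low)) stop("ci_high must exceed ci_low", call. = FALSE)
  (ci_high - ci_low) / (2 * Z95)
}

#' Indirect effect by the product of coefficients
#'
#' Combines the exposure-to-mediator effect (`beta1`) and the
#' mediator-to-outcome effect (`beta2`) into the indirect effect
#' `beta1 * beta2`. The variance uses the first-order delta method with the
#' two estimates treated as independent (the two-sample design draws them
#' from non-overlapping cohorts):
#' `Var = beta1^2 se2^2 + beta2^2 se1^2`. The 95% CI is
#' `indirect +/- 1.959964 * SE` and the p-value is two-sided normal.
#'
#' @param beta1,se1 Exposure-to-mediator estimate and SE.
#' @param beta2,se2 Mediator-to-outcome estimate and SE (log-odds for a
#'   binary outcome).
#' @return List with `indirect`, `se`, `ci_low`, `ci_high`, `pval`.
#' @export
product_of_coefficients <- function(beta1, se1, beta2, se2) {
  assert_scalar_number(beta1, "beta1"); assert_scalar_number(beta2, "beta2")
  assert_scalar_number(se1, "se1", positive = TRUE)
  assert_scalar_number(se2, "se2", positive = TRUE)
  indirect <- beta1 * beta2
  se <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  list(indirect = indirect, se = se,
       ci_low = indirect - Z95 * se, ci_high = indirect + Z95 * se,
       pval = two_sided_normal_p(indirect / se))
}

#' Mediated proportion with a delta-method interval
#'
#' `proportion = indirect / beta3`, the share of the total effect flowing
#' through the mediator. The total effect `beta3` is treated as fixed, so
#' `SE(proportion) = se_indirect / |beta3|`; the 95% CI is symmetric normal.
#' A `warn` flag is raised when the proportion falls outside \[0, 1\]
#' (indirect and total effects of opposite sign, or indirect exceeding the
#' total), where the proportion loses its interpretation as a share.
#'
#' @param indirect Indirect effect (from [product_of_coefficients()]).
#' @param se_indirect Its delta-method SE.
#' @param beta3 Total effect of exposure on outcome, non-zero.
#' @return List with `proportion`, `se`, `ci_low`, `ci_high` (all on the
#'   fraction scale) and logical `warn`.
#' @export
mediated_proportion <- function(indirect, se_indirect, beta3) {
  assert_scalar_number(indirect, "indirect")
  assert_scalar_number(se_indirect, "se_indirect", positive = TRUE)
  assert_scalar_number(beta3, "beta3")
  if (beta3 == 0) stop("total effect beta3 must be non-zero", call. = FALSE)
  proportion <- indirect / beta3
  se <- se_indirect / abs(beta3)
  warn <- proportion < 0 || proportion > 1
  if (warn) {
    warning("mediated proportion outside [0, 1]: indirect and total effects ",
            "disagree in sign or magnitude", call. = FALSE)
  }
  list(proportion = proportion, se = se,
       ci_low = proportion - Z95 * se, ci_high = proportion + Z95 * se,
       warn = warn)
}

extract_beta_se <- function(est, name) {
  if (inherits(est, "mr_estimate") || (is.list(est) && !is.null(est$beta) && !is.null(est$se))) {
    return(list(beta = est$beta, se = est$se))
  }
  stop("`", name, "` must be an mr_estimate or a list with beta and se", call. = FALSE)
}

new_mediation_result <- function(beta1, se1, beta2, se2, beta3, se3,
                                 indirect, se_indirect, ci, pval,
                                 proportion, method, mediator_id) {
  structure(list(
    mediator_id = mediator_id, method = method,
    beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
    beta3 = beta3, se3 = se3,
    indirect = indirect, se_indirect = se_indirect,
    indirect_ci_low = ci[[1L]], indirect_ci_high = ci[[2L]],
    indirect_pval = pval,
    proportion = proportion$proportion,
    prop_ci_low = proportion$ci_low, prop_ci_high = proportion$ci_high,
    prop_warn = proportion$warn,
    direct = beta3 - indirect
  ), class = "mediation_result")
}

#' Two-step MR mediation (product of coefficients)
#'
#' Composes the two-step design: step 1 estimates the causal effect of the
#' exposure on the mediator (`beta1`), step 2 the effect of the mediator on
#' the outcome (`beta2`, using the mediator's own instruments), and the
#' total effect `beta3` comes from the main MR analysis. The indirect
#' effect is `beta1 * beta2` with a delta-method CI
#' ([product_of_coefficients()]); the mediated proportion is
#' `indirect / beta3` with `beta3` fixed ([mediated_proportion()]); the
#' direct effect is `beta3 - indirect`.
#'
#' @param step1 Exposure-to-mediator estimate (`mr_estimate` or list with
#'   `beta`, `se`).
#' @param step2 Mediator-to-outcome estimate.
#' @param total Total exposure-to-outcome estimate.
#' @param mediator_id Mediator label.
#' @return A `mediation_result` with the coefficients, indirect effect,
#'   delta-method CI and p, mediated proportion and its CI, and the direct
#'   effect.
#' @export
two_step_mediation <- function(step1, step2, total, mediator_id = "mediator") {
  s1 <- extract_beta_se(step1, "step1")
  s2 <- extract_beta_se(step2, "step2")
  s3 <- extract_beta_se(total, "total")
  ind <- product_of_coefficients(s1$beta, s1$se, s2$beta, s2$se)
  prop <- mediated_proportion(ind$indirect, ind$se, s3$beta)
  new_mediation_result(s1$beta, s1$se, s2$beta, s2$se, s3$beta, s3$se,
                       ind$indirect, ind$se, c(ind$ci_low, ind$ci_high),
                       ind$pval, prop,
                       method = "product-of-coefficients",
                       mediator_id = mediator_id)
}

#' Difference-in-coefficients mediation (sensitivity method)
#'
#' Estimates the indirect effect as `total - direct`, where the direct
#' effect comes from a multivariable IVW regression adjusting the exposure
#' for the mediator ([mvmr_ivw()]). The variance is the independence
#' approximation `se_total^2 + se_direct^2` — a documented simplification,
#' since total and direct effects share the same outcome data. The mediated
#' proportion again treats the total effect as fixed.
#'
#' @param total Total-effect estimate (`mr_estimate` or list with `beta`,
#'   `se`).
#' @param direct Direct-effect estimate from multivariable IVW.
#' @param mediator_id Mediator label.
#' @return A `mediation_result` (with `beta1`, `beta2` unset).
#' @export
difference_in_coefficients <- function(total, direct, mediator_id = "mediator") {
  s3 <- extract_beta_se(total, "total")
  sd_ <- extract_beta_se(direct, "direct")
  indirect <- s3$beta - sd_$beta
  se <- sqrt(s3$se^2 + sd_$se^2)
  ci <- c(indirect - Z95 * se, indirect + Z95 * se)
  pval <- two_sided_normal_p(indirect / se)
  prop <- suppressWarnings(mediated_proportion(indirect, se, s3$beta))
  res <- new_mediation_result(NA_real_, NA_real_, NA_real_, NA_real_,
                              s3$beta, s3$se, indirect, se, ci, pval, prop,
                              method = "difference-in-coefficients",
                              mediator_id = mediator_id)
  res$direct <- sd_$beta
  res
}

#' Direct effect from multivariable IVW on combined instrument sets
#'
#' Assembles the multivariable MR design for the difference-in-coefficients
#' method from harmonized pair sets: at the exposure's instruments it takes
#' the exposure, mediator and outcome betas; at the mediator's instruments
#' (when supplied) it adds the mediator, outcome and exposure betas, the
#' latter from an exposure lookup at those variants. Using the union of
#' both instrument sets gives the regression conditional strength in both
#' columns; with exposure instruments alone the mediator column is
#' identified only through SNP-level mediator pathways. Fits [mvmr_ivw()]
#' with no intercept and returns the coefficient on the exposure column —
#' the direct effect with the mediator adjusted for.
#'
#' @param total_pairs Exposure instruments vs the outcome (from
#'   [harmonize()]).
#' @param step1_pairs The same exposure instruments vs the mediator.
#' @param step2_pairs Mediator instruments vs the outcome.
#' @param exposure_at_mediator_pairs Optional: mediator instruments vs the
#'   exposure (align by harmonizing the exposure lookup against the same
#'   mediator-instrument table as `step2_pairs`). When `NULL`, only the
#'   exposure instruments enter the regression.
#' @return An `mr_estimate` for the direct effect.
#' @export
mvmr_direct_effect <- function(total_pairs, step1_pairs, step2_pairs = NULL,
                               exposure_at_mediator_pairs = NULL) {
  tot <- as.data.frame(as_pairs(total_pairs))
  s1 <- as.data.frame(as_pairs(step1_pairs))
  shared <- merge(tot, s1[c("snp_id", "beta_outcome", "se_outcome")],
                  by = "snp_id", suffixes = c("", "_mediator"))
  x <- shared$beta_exposure; sx <- shared$se_exposure
  m <- shared$beta_outcome_mediator; sm <- shared$se_outcome_mediator
  y <- shared$beta_outcome; sy <- shared$se_outcome
  if (!is.null(exposure_at_mediator_pairs) && !is.null(step2_pairs)) {
    s2 <- as.data.frame(as_pairs(step2_pairs))
    em <- as.data.frame(as_pairs(exposure_at_mediator_pairs))
    med <- merge(s2, em[c("snp_id", "beta_outcome", "se_outcome")],
                 by = "snp_id", suffixes = c("", "_exposure"))
    x <- c(x, med$beta_outcome_exposure); sx <- c(sx, med$se_outcome_exposure)
    m <- c(m, med$beta_exposure); sm <- c(sm, med$se_exposure)
    y <- c(y, med$beta_outcome); sy <- c(sy, med$se_outcome)
  }
  fit <- mvmr_ivw(cbind(exposure = x, mediator = m),
                  cbind(exposure = sx, mediator = sm), y, sy)
  fit$exposure
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation through %s (%s)\n", x$mediator_id, x$method))
  if (is.finite(x$beta1)) {
    cat(sprintf("  beta1 %.4f (se %.4f), beta2 %.4f (se %.4f)\n",
                x$beta1, x$se1, x$beta2, x$se2))
  }
  cat(sprintf("  total %.4f, direct %.4f\n", x$beta3, x$direct))
  cat(sprintf("  indirect %.4f, 95%% CI %.4f to %.4f, p = %.3g\n",
              x$indirect, x$indirect_ci_low, x$indirect_ci_high, x$indirect_pval))
  cat(sprintf("  mediated proportion %.2f%% (95%% CI %.2f%% to %.2f%%)%s\n",
              100 * x$proportion, 100 * x$prop_ci_low, 100 * x$prop_ci_high,
              if (isTRUE(x$prop_warn)) " [outside 0-100%]" else ""))
  invisible(x)
}

#' Flat mediation table
#'
#' One row per mediation result, mirroring the usual reporting layout:
#' mediator, coefficients with CIs, indirect effect with CI and p, and the
#' mediated proportion in percent with its CI.
#'
#' @param results A list of `mediation_result` objects (a single result is
#'   accepted).
#' @return A data frame.
#' @export
mediation_table <- function(results) {
  if (inherits(results, "mediation_result")) results <- list(results)
  rows <- lapply(results, function(m) {
    data.frame(
      mediator = m$mediator_id, method = m$method,
      beta1 = m$beta1, se1 = m$se1, beta2 = m$beta2, se2 = m$se2,
      total = m$beta3, direct = m$direct,
      indirect = m$indirect, indirect_ci_low = m$indirect_ci_low,
      indirect_ci_high = m$indirect_ci_high, indirect_pval = m$indirect_pval,
      proportion_pct = 100 * m$proportion,
      prop_ci_low_pct = 100 * m$prop_ci_low,
      prop_ci_high_pct = 100 * m$prop_ci_high,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}
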