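# Causal-effect estimate container shared by every estimator.
new_mr_estimate <- function(beta, se, method, n_snps, model = NA_character_,
                            df = NULL, intercept = NULL, intercept_se = NULL) {
  if (!is.finite(beta) || !is.finite(se) || se <= 0) {
    stop("estimate requires finite beta and se > 0", call. = FALSE)
  }
  z <- beta / se
  pval <- if (is.null(df)) two_sided_normal_p(z) else 2 * stats::pt(-abs(z), df)
  est <- list(
    beta = beta, se = se, pval = pval,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    odds_ratio = exp(beta),
    or_ci_low = exp(beta - Z95 * se),
    or_ci_high = exp(beta + Z95 * se),
    method = method, n_snps = as.integer(n_snps), model = model
  )
  if (!is.null(intercept)) {
    zi <- intercept / intercept_se
    est$intercept <- intercept
    est$intercept_se <- intercept_se
    est$intercept_pval <- if (is.null(df)) two_sided_normal_p(zi) else 2 * stats::pt(-abs(zi), df)
  }
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNP%s%s)\n", x$method, x$n_snps,
              if (x$n_snps == 1L) "" else "s",
              if (!is.na(x$model)) paste0(", ", x$model) else ""))
  cat(sprintf("  beta %.4f (se %.4f), 95%% CI %.4f to %.4f, p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  OR %.3f, 95%% CI %.3f to %.3f\n",
              x$odds_ratio, x$or_ci_low, x$or_ci_high))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

# Per-SNP Wald ratios and their standard errors.
# First-order: se = se_out/|beta_exp| (exposure noise ignored).
# Second-order adds the exposure-side term.
wald_components <- function(pairs, second_order = FALSE) {
  if (any(pairs$beta_exposure == 0)) {
    stop("degenerate instrument: beta_exposure = 0", call. = FALSE)
  }
  ratio <- pairs$beta_outcome / pairs$beta_exposure
  se <- if (second_order) {
    sqrt(pairs$se_outcome^2 / pairs$beta_exposure^2 +
           pairs$beta_outcome^2 * pairs$se_exposure^2 / pairs$beta_exposure^4)
  } else {
    pairs$se_outcome / abs(pairs$beta_exposure)
  }
  list(ratio = ratio, se = se, weight = 1 / se^2)
}

#' Wald ratio estimate for a single SNP
#'
#' The per-SNP causal estimate: SNP-outcome beta divided by SNP-exposure
#' beta. Its standard error uses the first-order delta approximation
#' `se_outcome / |beta_exposure|` (exposure-side sampling noise ignored);
#' `second_order = TRUE` adds the exposure-side variance term.
#'
#' @param pair One harmonized pair (a one-row data frame with
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`).
#' @param second_order Use second-order delta weights (default `FALSE`).
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(pair, second_order = FALSE) {
  pair <- as_pairs(pair)
  if (nrow(pair) != 1L) stop("wald_ratio expects a single pair", call. = FALSE)
  wc <- wald_components(pair, second_order)
  new_mr_estimate(wc$ratio, wc$se, method = "Wald ratio", n_snps = 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Combines per-SNP Wald ratios with inverse-variance weights; equivalently
#' the slope of a zero-intercept weighted regression of outcome betas on
#' exposure betas with weights `1/se_outcome^2`. Under the multiplicative
#' random-effects model (the default for two or more SNPs) the standard
#' error is inflated by `max(1, sqrt(Q/(J-1)))`, where Q is Cochran's
#' statistic; the fixed-effect model leaves it at `(sum of weights)^-1/2`.
#' P-values use the normal reference.
#'
#' @param pairs Harmonized pairs (see [harmonize()]).
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`. A single SNP always uses the fixed model and reduces exactly
#'   to the Wald ratio.
#' @param second_order Use second-order delta Wald weights.
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(pairs, model = c("random", "fixed"), second_order = FALSE) {
  pairs <- as_pairs(pairs)
  model <- match.arg(model)
  J <- nrow(pairs)
  if (J < 1L) stop("IVW requires at least 1 SNP", call. = FALSE)
  if (model == "random" && J < 2L) model <- "fixed"
  wc <- wald_components(pairs, second_order)
  w <- wc$weight
  beta <- sum(w * wc$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  label <- "fixed"
  if (model == "random") {
    Q <- sum(w * (wc$ratio - beta)^2)
    se <- se * max(1, sqrt(Q / (J - 1)))
    label <- "multiplicative random"
  }
  new_mr_estimate(beta, se, method = "IVW", n_snps = J, model = label)
}

#' MR-Egger regression
#'
#' Weighted regression (weights `1/se_outcome^2`) of outcome betas on
#' exposure betas with a free intercept. The slope is the
#' pleiotropy-corrected causal estimate; the intercept estimates the average
#' directional pleiotropy, and an intercept deviating from zero signals
#' horizontal pleiotropy. Because the regression is not invariant to allele
#' orientation, each pair is first flipped so that `beta_exposure >= 0`.
#' Standard errors carry the multiplicative overdispersion factor
#' `max(1, sqrt(RSS_w/(J-2)))`; slope and intercept p-values use the t
#' reference with J-2 degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with `intercept`, `intercept_se` and
#'   `intercept_pval` fields.
#' @export
mr_egger <- function(pairs) {
  pairs <- as_pairs(pairs)
  J <- nrow(pairs)
  if (J < 3L) stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  sgn <- ifelse(pairs$beta_exposure < 0, -1, 1)
  x <- pairs$beta_exposure * sgn
  y <- pairs$beta_outcome * sgn
  w <- 1 / pairs$se_outcome^2
  if (stats::var(x) == 0) stop("zero variance in exposure betas", call. = FALSE)

  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  fitted <- intercept + slope * x
  rss_w <- sum(w * (y - fitted)^2)
  phi <- max(1, rss_w / (J - 2))
  se_slope <- sqrt(phi * sw / det)
  se_intercept <- sqrt(phi * swxx / det)

  new_mr_estimate(slope, se_slope, method = "MR-Egger", n_snps = J,
                  model = "multiplicative random", df = J - 2,
                  intercept = intercept, intercept_se = se_intercept)
}

#' Weighted median estimate
#'
#' Orders the per-SNP Wald ratios and returns the value at which the
#' cumulative inverse-variance weight crosses one half, using linear
#' interpolation on the cumulative-weight midpoint scale
#' (`s_j = cumsum(w_j) - w_j/2` after normalising the weights to sum to 1).
#' Consistent when variants contributing more than 50% of the weight are
#' valid instruments. The standard error comes from a parametric bootstrap:
#' each ratio is resampled from `Normal(ratio_j, se_j)` `n_boot` times and
#' the SE is the standard deviation of the bootstrap medians.
#'
#' @inheritParams mr_ivw
#' @param n_boot Number of bootstrap resamples (>= 100; default 1000).
#' @param seed Optional integer seed making the bootstrap reproducible
#'   without disturbing the session RNG.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = NULL,
                               second_order = FALSE) {
  pairs <- as_pairs(pairs)
  J <- nrow(pairs)
  if (J < 3L) stop("weighted median requires at least 3 SNPs", call. = FALSE)
  if (n_boot < 100L) stop("n_boot must be at least 100", call. = FALSE)
  wc <- wald_components(pairs, second_order)

  beta <- weighted_median_point(wc$ratio, wc$weight)
  boots <- with_seed(seed, {
    draws <- matrix(stats::rnorm(J * n_boot, mean = wc$ratio, sd = wc$se),
                    nrow = J)
    apply(draws, 2L, weighted_median_point, w = wc$weight)
  })
  se <- stats::sd(boots)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  new_mr_estimate(beta, se, method = "Weighted median", n_snps = J)
}

# Interpolated weighted median on the cumulative-weight midpoint scale.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1L] >= 0.5) return(b[1L])
  below <- max(which(s < 0.5))
  if (below == length(b)) return(b[length(b)])
  b[below] + (b[below + 1L] - b[below]) * (0.5 - s[below]) / (s[below + 1L] - s[below])
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (ratio_j - beta_ref)^2` with inverse-variance weights
#' `w_j = 1/se(ratio_j)^2`, referred to a chi-square upper tail with J-1
#' degrees of freedom for an IVW reference (J-2 for an MR-Egger reference,
#' which spends one extra degree of freedom on the intercept).
#'
#' @inheritParams mr_ivw
#' @param reference An `mr_estimate` providing the pooled beta (typically
#'   from [mr_ivw()] or [mr_egger()]).
#' @return List of class `heterogeneity_result` with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(pairs, reference, second_order = FALSE) {
  pairs <- as_pairs(pairs)
  J <- nrow(pairs)
  if (J < 2L) stop("Cochran's Q requires at least 2 SNPs", call. = FALSE)
  wc <- wald_components(pairs, second_order)
  Q <- sum(wc$weight * (wc$ratio - reference$beta)^2)
  df <- if (identical(reference$method, "MR-Egger")) J - 2L else J - 1L
  structure(list(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n", x$Q, x$df, x$pval))
  invisible(x)
}

#' Leave-one-out analysis
#'
#' Sequentially excludes each SNP and recomputes the IVW estimate on the
#' remainder, exposing variants that single-handedly drive the pooled
#' estimate.
#'
#' @inheritParams mr_ivw
#' @return List of class `leave_one_out_result` with `table` (one row per
#'   excluded SNP plus an `All` row: beta, se, CI, p) and `estimates` (the
#'   underlying `mr_estimate` objects).
#' @export
leave_one_out <- function(pairs, model = c("random", "fixed")) {
  pairs <- as_pairs(pairs)
  model <- match.arg(model)
  J <- nrow(pairs)
  if (J < 3L) stop("leave-one-out requires at least 3 SNPs", call. = FALSE)
  ests <- lapply(seq_len(J), function(j) mr_ivw(pairs[-j, , drop = FALSE], model))
  names(ests) <- pairs$snp_id
  full <- mr_ivw(pairs, model)
  row <- function(nm, e) {
    data.frame(excluded = nm, n_snps = e$n_snps, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(Map(row, pairs$snp_id, ests), list(row("All", full))))
  rownames(tab) <- NULL
  structure(list(table = tab, estimates = ests, full = full),
            class = "leave_one_out_result")
}

#' Multivariable IVW regression
#'
#' Weighted multiple regression (weights `1/se_outcome^2`) of outcome betas
#' on two or more columns of exposure betas, with no intercept. The
#' coefficient on each column is that exposure's direct effect conditional
#' on the others; adjusting the primary exposure for a mediator in this way
#' yields the direct effect used by the difference-in-coefficients mediation
#' method. Standard errors carry the multiplicative overdispersion factor
#' `max(1, sqrt(RSS_w/(J-K)))` and p-values use the normal reference.
#'
#' @param exposure_beta Numeric matrix (J SNPs x K exposures) of per-SNP
#'   exposure betas; column names label the exposures.
#' @param exposure_se Matrix of matching standard errors (carried for
#'   provenance; the regression weights come from the outcome side).
#' @param outcome_beta,outcome_se Per-SNP outcome betas and standard errors.
#' @return Named list of `mr_estimate` objects, one per exposure column.
#' @export
mvmr_ivw <- function(exposure_beta, exposure_se, outcome_beta, outcome_se) {
  B <- as.matrix(exposure_beta)
  J <- nrow(B); K <- ncol(B)
  if (is.null(colnames(B))) colnames(B) <- sprintf("exposure_%d", seq_len(K))
  if (length(outcome_beta) != J || length(outcome_se) != J) {
    stop("outcome vectors must match the exposure matrix rows", call. = FALSE)
  }
  if (any(outcome_se <= 0)) stop("outcome standard errors must be > 0", call. = FALSE)
  if (J < K + 1L) stop("multivariable IVW requires more SNPs than exposures", call. = FALSE)
  if (qr(B)$rank < K) stop("exposure-beta matrix is rank deficient (collinear exposures)", call. = FALSE)
  w <- 1 / outcome_se^2
  Bw <- B * sqrt(w)
  yw <- outcome_beta * sqrt(w)
  XtX <- crossprod(Bw)
  coefs <- drop(solve(XtX, crossprod(Bw, yw)))
  rss_w <- sum((yw - Bw %*% coefs)^2)
  phi <- max(1, rss_w / (J - K))
  ses <- sqrt(phi * diag(solve(XtX)))
  out <- Map(function(b, s, nm) {
    new_mr_estimate(b, s, method = paste0("Multivariable IVW (", nm, ")"),
                    n_snps = J, model = "multiplicative random")
  }, coefs, ses, colnames(B))
  stats::setNames(out, colnames(B))
}

#' Populate odds-ratio fields of an estimate
#'
#' Exponentiates a log-odds estimate and its 95% confidence bounds
#' (`exp(beta +/- 1.959964 * se)`).
#'
#' @param estimate An `mr_estimate` with `beta` on the log-odds scale.
#' @return The estimate with `odds_ratio`, `or_ci_low`, `or_ci_high` set.
#' @export
to_odds_ratio <- function(estimate) {
  estimate$odds_ratio <- exp(estimate$beta)
  estimate$or_ci_low <- exp(estimate$beta - Z95 * estimate$se)
  estimate$or_ci_high <- exp(estimate$beta + Z95 * estimate$se)
  estimate
}

#' Flat forest table from a set of estimates
#'
#' Serializes estimates into the flat layout of a forest plot: one row per
#' method with SNP count, beta, SE, OR, CI and p-value.
#'
#' @param estimates A list of `mr_estimate` objects (a single estimate is
#'   accepted).
#' @param outcome Optional outcome label prepended as a column.
#' @return A data frame.
#' @export
forest_table <- function(estimates, outcome = NULL) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  rows <- lapply(estimates, function(e) {
    data.frame(method = e$method, n_snps = e$n_snps, beta = e$beta, se = e$se,
               or = e$odds_ratio, or_ci_low = e$or_ci_low,
               or_ci_high = e$or_ci_high, pval = e$pval,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(outcome)) tab <- cbind(outcome = outcome, tab)
  tab
}
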