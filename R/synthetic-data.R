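#' Configuration for the synthetic summary-statistics generator
#'
#' Parameters of the generative model used by [simulate_two_sample()],
#' [simulate_mediation_chain()] and [simulate_ld()]. Defaults are sized to
#' the drug-target setting the package targets: 22 cis instruments whose
#' strength gives F-statistics near 50, a protective total effect of
#' `ln(0.493)` on the log-odds scale, and sampling-noise scales in the range
#' produced by biobank-sized GWAS.
#'
#' @param n_snps Number of instruments J (default 22).
#' @param gamma_mean,gamma_sd Distribution of true SNP-to-exposure effects
#'   (SD units of expression per allele). The defaults (0.14, 0.04) with
#'   `se_exposure_scale = 0.02` give F = `beta^2/se^2` near 50 on average,
#'   with the across-SNP effect-size spread that real cis-eQTL signals show
#'   (and that MR-Egger and multivariable MR need for identification).
#' @param se_exposure_scale,se_outcome_scale Sampling-noise scales of the
#'   exposure and outcome associations (per-SNP SEs are jittered within
#'   +/-10% of the scale).
#' @param theta_total True total causal effect on the outcome, log-odds per
#'   SD of exposure (default `log(0.493)`).
#' @param pleiotropy_mean,pleiotropy_sd Direct SNP-to-outcome effects
#'   (directional pleiotropy when the mean is non-zero, balanced when only
#'   the SD is).
#' @param n_outliers,outlier_magnitude Number of planted pleiotropic
#'   outliers and the shift added to their outcome betas.
#' @param beta1_true Exposure-to-mediator effect of the mediation chain.
#' @param beta2_true Mediator-to-outcome effect (log-odds).
#' @param theta_direct Direct exposure-to-outcome effect; the chain's total
#'   effect is `theta_direct + beta1_true * beta2_true` and the implied
#'   mediated proportion is `beta1_true * beta2_true / total`.
#' @param mediator_snp_sd SD of per-SNP mediator effects beyond the
#'   exposure pathway (heterogeneous SNP-level mediator pathways; also what
#'   identifies the mediator column in multivariable MR).
#' @param se_mediator_scale SE scale of the mediator associations measured
#'   at the exposure instruments (a large mediator GWAS, hence small).
#' @param n_mediator_snps,mediator_gamma_mean,mediator_gamma_sd,se_mediator_inst_scale
#'   Count, strength distribution and SE scale of the mediator's own
#'   instruments used in step 2.
#' @param b_gc_true,b_co_true True confounder-pathway effects (per-SNP
#'   variant-to-confounder effect scale and confounder-to-outcome effect)
#'   used when simulating confounded data.
#' @param ld_block_sizes,ld_r LD block sizes (must sum to `n_snps`) and the
#'   constant within-block correlation for [simulate_ld()].
#' @param palindrome_fraction Fraction of SNPs assigned palindromic (A/T or
#'   C/G) allele pairs; 0 by default so generated tables harmonize without
#'   loss, used only to exercise harmonization.
#' @param cis_chrom,cis_start,cis_end Region in which generated SNPs are
#'   placed (defaults to the GLP1R locus on chromosome 6, GRCh37).
#' @param seed Mandatory integer seed; all generation is reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 22,
                       gamma_mean = 0.14, gamma_sd = 0.04,
                       se_exposure_scale = 0.02, se_outcome_scale = 0.04,
                       theta_total = log(0.493),
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       n_outliers = 0, outlier_magnitude = 0,
                       beta1_true = -0.167, beta2_true = 0.122,
                       theta_direct = log(0.493) - (-0.167 * 0.122),
                       mediator_snp_sd = 0.02,
                       se_mediator_scale = 0.005,
                       n_mediator_snps = 22,
                       mediator_gamma_mean = 0.1, mediator_gamma_sd = 0.01,
                       se_mediator_inst_scale = 0.008,
                       b_gc_true = 0, b_co_true = 0,
                       ld_block_sizes = NULL, ld_r = 0,
                       palindrome_fraction = 0,
                       cis_chrom = "6", cis_start = 39016574, cis_end = 39059079,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducible simulation", call. = FALSE)
  assert_scalar_number(seed, "seed")
  if (n_snps < 1) stop("n_snps must be >= 1", call. = FALSE)
  assert_scalar_number(se_exposure_scale, "se_exposure_scale", positive = TRUE)
  assert_scalar_number(se_outcome_scale, "se_outcome_scale", positive = TRUE)
  if (n_outliers >= n_snps && n_outliers > 0) {
    stop("n_outliers must be smaller than n_snps", call. = FALSE)
  }
  if (abs(ld_r) >= 1 && ld_r != 0) stop("|ld_r| must be < 1", call. = FALSE)
  if (palindrome_fraction < 0 || palindrome_fraction > 1) {
    stop("palindrome_fraction must be in [0, 1]", call. = FALSE)
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# Deterministic SNP metadata (ids, positions, alleles, frequencies) for J
# variants; consumes RNG for eaf and palindromic placement.
snp_frame <- function(J, config, id_offset = 0L, chrom = NULL,
                      start = NULL, end = NULL) {
  chrom <- chrom %||% config$cis_chrom
  start <- start %||% config$cis_start
  end <- end %||% config$cis_end
  nonpal <- list(c("A", "G"), c("G", "T"), c("T", "C"), c("C", "A"))
  pal <- list(c("A", "T"), c("C", "G"))
  pick <- nonpal[(seq_len(J) - 1L) %% length(nonpal) + 1L]
  n_pal <- round(config$palindrome_fraction * J)
  if (n_pal > 0) {
    idx <- sample.int(J, n_pal)
    pick[idx] <- pal[(seq_len(n_pal) - 1L) %% 2L + 1L]
  }
  data.frame(
    snp_id = sprintf("rs%07d", id_offset + seq_len(J)),
    chrom = as.character(chrom),
    pos = as.integer(round(seq(start, end, length.out = J))),
    effect_allele = vapply(pick, `[[`, character(1), 1L),
    other_allele = vapply(pick, `[[`, character(1), 2L),
    eaf = stats::runif(J, 0.1, 0.9),
    stringsAsFactors = FALSE
  )
}

assemble_table <- function(snps, beta, se, trait_id, n = NA_real_,
                           adjusted = FALSE) {
  tab <- snps
  tab$beta <- beta
  tab$se <- se
  tab$pval <- two_sided_normal_p(beta / se)
  tab$pval <- pmin(1, pmax(tab$pval, .Machine$double.xmin))
  if (adjusted) tab$pval_adj <- pmin(1, tab$pval * nrow(tab))
  tab$n <- n
  new_sumstats(tab, trait_id = trait_id, metadata = list(synthetic = TRUE))
}

#' Simulate a two-sample MR dataset with known truth
#'
#' Generates exposure and outcome summary-statistics tables for J
#' instruments. Per SNP j a true effect `gamma_j` is drawn; the observed
#' exposure beta is `Normal(gamma_j, se_exp_j)` and the observed outcome
#' beta is `Normal(theta * gamma_j + alpha_j, se_out_j)`, with `alpha_j`
#' the pleiotropy draw (plus any planted outlier shift). P-values are
#' consistent with beta/se, alleles are non-palindromic by default, and the
#' exposure table carries an adjusted-p column (Bonferroni over the table).
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` (`sumstats` tables) and
#'   `truth` (latent `gamma`, `alpha`, `theta_total`, `outlier_ids`,
#'   per-SNP true F).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    J <- config$n_snps
    snps <- snp_frame(J, config)
    gamma <- stats::rnorm(J, config$gamma_mean, config$gamma_sd)
    se_x <- config$se_exposure_scale * stats::runif(J, 0.9, 1.1)
    se_y <- config$se_outcome_scale * stats::runif(J, 0.9, 1.1)
    alpha <- stats::rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd)
    confounder <- NULL
    if (config$b_gc_true != 0 && config$b_co_true != 0) {
      # SNP -> confounder -> outcome pathway contaminating the outcome betas;
      # the observed variant-confounder effects feed a confounder_triple
      b_gc <- stats::rnorm(J, config$b_gc_true, 0.2 * abs(config$b_gc_true))
      se_gc <- rep(0.05 * abs(config$b_gc_true), J)
      alpha <- alpha + b_gc * config$b_co_true
      confounder <- list(b_gc_true = b_gc,
                         b_gc_hat = stats::rnorm(J, b_gc, se_gc),
                         se_gc = se_gc,
                         b_co = config$b_co_true,
                         se_co = 0.05 * abs(config$b_co_true))
    }
    outlier_ids <- character(0)
    if (config$n_outliers > 0) {
      out_idx <- sample.int(J, config$n_outliers)
      alpha[out_idx] <- alpha[out_idx] + config$outlier_magnitude
      outlier_ids <- snps$snp_id[out_idx]
    }
    bx <- stats::rnorm(J, gamma, se_x)
    by <- stats::rnorm(J, config$theta_total * gamma + alpha, se_y)
    exposure <- assemble_table(snps, bx, se_x, "exposure", n = 31684,
                               adjusted = TRUE)
    outcome <- assemble_table(snps, by, se_y, "outcome", n = 223805)
    truth <- list(snp_id = snps$snp_id, gamma = gamma, alpha = alpha,
                  theta_total = config$theta_total,
                  outlier_ids = outlier_ids,
                  f_true = (gamma / se_x)^2,
                  confounder = confounder)
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate a two-step mediation chain
#'
#' Generates the three internally consistent summary-statistics designs of
#' a two-step mediation study, all with independent sampling noise
#' (two-sample assumption):
#'
#' * `step1` — exposure instruments against the exposure and against the
#'   mediator; the per-SNP mediator effect is
#'   `beta1_true * gamma_j + delta_j` with `delta_j ~
#'   Normal(0, mediator_snp_sd)` (SNP-level mediator pathways, which also
#'   make the mediator column identifiable in multivariable MR);
#' * `step2` — the mediator's own, independently drawn instruments against
#'   the mediator and against the outcome (`beta2_true` per mediator unit);
#' * `total` — the exposure instruments against the outcome, whose true
#'   slope is `theta_direct + beta2_true * beta1_true` in expectation.
#'
#' @param config A [sim_config()] with the mediation block set.
#' @return List with `step1`, `step2`, `total` (each a list of `exposure`
#'   and `outcome` tables ready for [harmonize()]) and `truth` (`beta1`,
#'   `beta2`, `theta_direct`, `theta_total`, analytic `proportion`, and the
#'   latent per-SNP values).
#' @export
simulate_mediation_chain <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    J <- config$n_snps
    snps <- snp_frame(J, config)
    gamma <- stats::rnorm(J, config$gamma_mean, config$gamma_sd)
    delta <- stats::rnorm(J, 0, config$mediator_snp_sd)
    m_true <- config$beta1_true * gamma + delta
    theta_total <- config$theta_direct + config$beta1_true * config$beta2_true
    y_true <- config$theta_direct * gamma + config$beta2_true * m_true

    se_x <- config$se_exposure_scale * stats::runif(J, 0.9, 1.1)
    se_m <- config$se_mediator_scale * stats::runif(J, 0.9, 1.1)
    se_y <- config$se_outcome_scale * stats::runif(J, 0.9, 1.1)
    bx <- stats::rnorm(J, gamma, se_x)
    bm <- stats::rnorm(J, m_true, se_m)
    by <- stats::rnorm(J, y_true, se_y)

    K <- config$n_mediator_snps
    med_snps <- snp_frame(K, config, id_offset = 1e6L, chrom = "10",
                          start = 112998590, end = 113036822)
    gm <- stats::rnorm(K, config$mediator_gamma_mean, config$mediator_gamma_sd)
    se_gm <- config$se_mediator_inst_scale * stats::runif(K, 0.9, 1.1)
    se_y2 <- config$se_outcome_scale * stats::runif(K, 0.9, 1.1)
    bgm <- stats::rnorm(K, gm, se_gm)
    by2 <- stats::rnorm(K, config$beta2_true * gm, se_y2)
    # exposure associations at the mediator's instruments: truly null
    # (the mediator's variants do not act on the drug-target gene), so the
    # union of both instrument sets identifies both columns in MVMR
    se_x2 <- config$se_exposure_scale * stats::runif(K, 0.9, 1.1)
    bx2 <- stats::rnorm(K, 0, se_x2)

    exposure_tab <- assemble_table(snps, bx, se_x, "exposure", n = 31684,
                                   adjusted = TRUE)
    mediator_at_exposure <- assemble_table(snps, bm, se_m, "mediator", n = 4e5)
    outcome_at_exposure <- assemble_table(snps, by, se_y, "outcome", n = 223805)
    mediator_inst <- assemble_table(med_snps, bgm, se_gm, "mediator", n = 4e5,
                                    adjusted = TRUE)
    outcome_at_mediator <- assemble_table(med_snps, by2, se_y2, "outcome",
                                          n = 223805)
    exposure_at_mediator <- assemble_table(med_snps, bx2, se_x2, "exposure",
                                           n = 31684)

    list(
      step1 = list(exposure = exposure_tab, outcome = mediator_at_exposure),
      step2 = list(exposure = mediator_inst, outcome = outcome_at_mediator),
      total = list(exposure = exposure_tab, outcome = outcome_at_exposure),
      exposure_at_mediator = exposure_at_mediator,
      truth = list(beta1 = config$beta1_true, beta2 = config$beta2_true,
                   theta_direct = config$theta_direct,
                   theta_total = theta_total,
                   proportion = config$beta1_true * config$beta2_true / theta_total,
                   gamma = gamma, delta = delta, m_true = m_true)
    )
  })
}

#' Plant pleiotropic outliers into an outcome table
#'
#' Shifts the outcome betas of randomly chosen SNPs by `magnitude`
#' (recomputing p-values), returning the planted identifiers so detection
#' machinery can be scored against truth.
#'
#' @param outcome A `sumstats` outcome table.
#' @param n_outliers Number of SNPs to shift (must be < number of rows).
#' @param magnitude Shift added to each chosen beta.
#' @param seed Integer seed.
#' @return List with `outcome` (modified table) and `outlier_ids`.
#' @export
plant_outliers <- function(outcome, n_outliers, magnitude, seed) {
  J <- nrow(outcome)
  if (n_outliers >= J) stop("n_outliers must be smaller than the table", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(J, n_outliers)
    outcome$beta[idx] <- outcome$beta[idx] + magnitude
    outcome$pval <- pmin(1, pmax(two_sided_normal_p(outcome$beta / outcome$se),
                                 .Machine$double.xmin))
    list(outcome = outcome, outlier_ids = outcome$snp_id[idx])
  })
}

#' Simulate a block-diagonal LD matrix
#'
#' Constant correlation `ld_r` within blocks of the configured sizes, unit
#' diagonal, zero between blocks: symmetric and positive semi-definite by
#' construction.
#'
#' @param config A [sim_config()] with `ld_block_sizes` summing to
#'   `n_snps` (`NULL` means one SNP per block, i.e. the identity) and
#'   `ld_r` the within-block correlation.
#' @param snp_ids Identifiers to label the matrix with; defaults to the ids
#'   [simulate_two_sample()] generates.
#' @return A named correlation matrix.
#' @export
simulate_ld <- function(config, snp_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_snps
  sizes <- config$ld_block_sizes %||% rep(1L, J)
  if (sum(sizes) != J) stop("ld_block_sizes must sum to n_snps", call. = FALSE)
  if (abs(config$ld_r) >= 1 && config$ld_r != 0) stop("|ld_r| must be < 1", call. = FALSE)
  snp_ids <- snp_ids %||% sprintf("rs%07d", seq_len(J))
  m <- matrix(0, J, J, dimnames = list(snp_ids, snp_ids))
  at <- 1L
  for (s in sizes) {
    idx <- at:(at + s - 1L)
    m[idx, idx] <- config$ld_r
    at <- at + s
  }
  diag(m) <- 1
  m
}
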