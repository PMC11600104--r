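# Shared fixture builders; everything is generated in code.

# Harmonized-pairs data frame straight from numeric vectors.
make_pairs <- function(bx, sx, by, sy, ids = sprintf("rs%03d", seq_along(bx))) {
  data.frame(snp_id = ids,
             effect_allele = "A", other_allele = "G",
             beta_exposure = bx, se_exposure = sx,
             beta_outcome = by, se_outcome = sy,
             flipped = FALSE, stringsAsFactors = FALSE)
}

# Random but reproducible pairs for oracle comparisons.
random_pairs <- function(J, seed) {
  set.seed(seed)
  make_pairs(bx = rnorm(J, 0.15, 0.05),
             sx = runif(J, 0.015, 0.03),
             by = rnorm(J, -0.1, 0.08),
             sy = runif(J, 0.03, 0.06))
}

# Minimal valid summary-statistics table.
make_table <- function(snp_id, beta, se, pval = NULL,
                       effect_allele = "A", other_allele = "G",
                       chrom = "1", pos = seq_along(snp_id) * 100L,
                       eaf = 0.3, pval_adj = NA, n = NA,
                       trait_id = "trait") {
  pval <- pval %||% pmin(1, pmax(2 * pnorm(-abs(beta / se)), 1e-300))
  new_sumstats(data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval, pval_adj = pval_adj,
    n = n, stringsAsFactors = FALSE
  ), trait_id = trait_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 12-SNP fixture engineered so the five selection steps remove 2, 2, 1, 3, 1:
# cis keeps rs001..rs010; p-filter drops rs009 (boundary) and rs010
# (adjusted p); exclusion drops rs008; clumping collapses blocks
# {rs001,rs002,rs003} and {rs004,rs005}; F-filter drops rs006 (F = 9).
selection_fixture <- function() {
  ids <- sprintf("rs%03d", 1:12)
  tab <- make_table(
    ids,
    beta = c(1, 1, 1, 1, 1, 0.3, 1, 1, 1, 1, 1, 1),
    se = rep(0.1, 12),
    pval = c(1e-12, 1e-10, 1e-10, 1e-11, 1e-10, 1e-10, 1e-10, 1e-10,
             5e-8, 1e-9, 1e-10, 1e-10),
    pval_adj = c(rep(0.01, 9), 0.06, 0.01, 0.01),
    chrom = c(rep("1", 10), "2", "1"),
    pos = c(100L * 1:10, 500L, 5000L)
  )
  ld <- diag(1, 10)
  dimnames(ld) <- list(ids[1:10], ids[1:10])
  ld[1:3, 1:3] <- 0.9
  ld[4:5, 4:5] <- 0.9
  diag(ld) <- 1
  cfg <- selection_config(cis_chrom = "1", cis_start = 100, cis_end = 1000,
                          cis_flank = 0)
  list(table = tab, ld = ld, excl = "rs008", config = cfg)
}

# Independent weighted-least-squares oracle built on stats::lm.
# Returns coefficients and SEs under the multiplicative-overdispersion
# convention (residual scale floored at 1).
lm_wls_oracle <- function(X, y, w, intercept = FALSE) {
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$y <- y
  form <- if (intercept) {
    stats::as.formula(paste("y ~", paste(names(df)[-ncol(df)], collapse = "+")))
  } else {
    stats::as.formula(paste("y ~", paste(names(df)[-ncol(df)], collapse = "+"), "- 1"))
  }
  fit <- stats::lm(form, data = df, weights = w)
  s <- summary(fit)
  scale <- max(1, s$sigma^2)
  list(coef = unname(stats::coef(fit)),
       se = unname(sqrt(scale * diag(s$cov.unscaled))))
}
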