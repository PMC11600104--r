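test_that("Wald ratio arithmetic and degenerate instruments", {
  expect_equal(wald_ratio(make_pairs(0.1, 0.01, 0.2, 0.05))$beta, 2)
  expect_equal(wald_ratio(make_pairs(0.3, 0.01, 0, 0.05))$beta, 0)
  w <- wald_ratio(make_pairs(-0.5, 0.02, 0.05, 0.01))
  expect_equal(w$beta, -0.1)
  expect_equal(w$se, 0.02)
  expect_error(wald_ratio(make_pairs(0, 0.01, 0.1, 0.05)), "degenerate")
})

test_that("IVW with one SNP reduces exactly to the Wald ratio", {
  p <- make_pairs(0.12, 0.02, -0.08, 0.03)
  ivw <- mr_ivw(p)
  wr <- wald_ratio(p)
  expect_identical(ivw$beta, wr$beta)
  expect_identical(ivw$se, wr$se)
})

test_that("constant Wald ratios give beta = theta, Q = 0, fixed = random", {
  theta <- -0.7
  bx <- c(0.1, 0.15, 0.2, 0.12)
  p <- make_pairs(bx, 0.02, theta * bx, c(0.03, 0.04, 0.05, 0.035))
  f <- mr_ivw(p, "fixed")
  r <- mr_ivw(p, "random")
  expect_equal(f$beta, theta, tolerance = 1e-14)
  expect_equal(r$beta, f$beta)
  expect_equal(r$se, f$se)  # Q = 0 so no inflation
  expect_equal(cochran_q(p, f)$Q, 0, tolerance = 1e-20)
  expect_equal(cochran_q(p, f)$pval, 1)
})

test_that("IVW matches an independent weighted-least-squares oracle", {
  for (seed in 1:5) {
    p <- random_pairs(8, seed)
    # IVW == zero-intercept WLS of outcome on exposure betas, weights 1/se_out^2
    oracle <- lm_wls_oracle(matrix(p$beta_exposure), p$beta_outcome,
                            1 / p$se_outcome^2)
    expect_equal(mr_ivw(p, "fixed")$beta, oracle$coef, tolerance = 1e-12)
    expect_equal(mr_ivw(p, "random")$beta, oracle$coef, tolerance = 1e-12)
  }
})

test_that("MR-Egger matches the weighted-regression oracle and nests IVW", {
  for (seed in 1:5) {
    p <- random_pairs(6, seed + 100)
    e <- mr_egger(p)
    sgn <- sign(p$beta_exposure)
    oracle <- lm_wls_oracle(matrix(p$beta_exposure * sgn),
                            p$beta_outcome * sgn, 1 / p$se_outcome^2,
                            intercept = TRUE)
    expect_equal(e$intercept, oracle$coef[1], tolerance = 1e-12)
    expect_equal(e$beta, oracle$coef[2], tolerance = 1e-12)
    expect_equal(e$intercept_se, oracle$se[1], tolerance = 1e-10)
    expect_equal(e$se, oracle$se[2], tolerance = 1e-10)
  }
  # noise-free data with no pleiotropy: Egger slope == IVW estimate
  bx <- c(0.08, 0.12, 0.18, 0.22, 0.1, 0.15)
  p0 <- make_pairs(bx, 0.02, -0.5 * bx, 0.03)
  expect_equal(mr_egger(p0)$beta, mr_ivw(p0)$beta, tolerance = 1e-10)
  expect_equal(mr_egger(p0)$intercept, 0, tolerance = 1e-12)
  expect_error(mr_egger(random_pairs(2, 1)), "at least 3")
  expect_error(mr_egger(make_pairs(rep(0.1, 4), 0.02, rnorm(4), 0.03)),
               "zero variance")
})

test_that("weighted median reduces to the plain median under equal weights", {
  # ratios {1, 2, 3} with equal weights
  p <- make_pairs(rep(0.1, 3), 0.01, c(0.1, 0.2, 0.3), rep(0.05, 3))
  wm <- mr_weighted_median(p, n_boot = 200, seed = 1)
  expect_equal(wm$beta, 2)
  # larger panels, odd and even
  for (J in c(5, 6)) {
    ratios <- seq_len(J) / 2
    pj <- make_pairs(rep(0.2, J), 0.01, 0.2 * ratios, rep(0.04, J))
    expect_equal(mr_weighted_median(pj, n_boot = 200, seed = 2)$beta,
                 median(ratios))
  }
})

test_that("weighted median interpolates on the cumulative-weight midpoint scale", {
  # unequal weights, hand-computed oracle
  bx <- c(0.1, 0.1, 0.1, 0.1, 0.1)
  by <- c(0.01, 0.03, 0.05, 0.07, 0.09)
  sy <- c(0.02, 0.05, 0.04, 0.03, 0.025)
  p <- make_pairs(bx, 0.001, by, sy)
  ratios <- by / bx
  w <- (bx / sy)^2
  o <- order(ratios); rs <- ratios[o]; ws <- w[o] / sum(w[o])
  s <- cumsum(ws) - ws / 2
  k <- max(which(s < 0.5))
  hand <- rs[k] + (rs[k + 1] - rs[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
  expect_equal(mr_weighted_median(p, n_boot = 200, seed = 3)$beta, hand)
  # identical ratios: point estimate theta, bootstrap se shrinks with se_out
  pe <- make_pairs(rep(0.1, 4), 0.001, rep(0.05, 4), rep(1e-6, 4))
  wm <- mr_weighted_median(pe, n_boot = 500, seed = 4)
  expect_equal(wm$beta, 0.5)
  expect_lt(wm$se, 1e-4)
  # reproducible under a fixed seed
  expect_identical(mr_weighted_median(p, n_boot = 200, seed = 9)$se,
                   mr_weighted_median(p, n_boot = 200, seed = 9)$se)
})

test_that("Cochran's Q follows the weighted-deviation formula", {
  # two ratios beta +/- d with equal weights: Q = 2 w d^2
  p <- make_pairs(c(0.1, 0.1), 0.001, c(0.04, 0.06), c(0.02, 0.02))
  ivw <- mr_ivw(p, "fixed")
  q <- cochran_q(p, ivw)
  w <- (0.1 / 0.02)^2
  d <- 0.1  # ratios 0.4 and 0.6, deviation 0.1 from pooled 0.5
  expect_equal(q$Q, 2 * w * d^2, tolerance = 1e-12)
  expect_equal(q$df, 1L)
  # unequal-weight fixture against the direct sum
  p2 <- random_pairs(7, 55)
  ref <- mr_ivw(p2, "fixed")
  ratios <- p2$beta_outcome / p2$beta_exposure
  ws <- (p2$beta_exposure / p2$se_outcome)^2
  expect_equal(cochran_q(p2, ref)$Q, sum(ws * (ratios - ref$beta)^2),
               tolerance = 1e-12)
  # Egger reference spends one more degree of freedom
  expect_equal(cochran_q(p2, mr_egger(p2))$df, 5L)
})

test_that("leave-one-out exposes the influential variant", {
  bx <- rep(0.1, 5)
  p <- make_pairs(bx, 0.001, 0.05 * bx, rep(0.02, 5))
  loo <- leave_one_out(p)
  expect_equal(nrow(loo$table), 6L)  # J sub-estimates plus the full row
  expect_true(all(abs(loo$table$beta - 0.05) < 1e-12))
  # plant one outlier: removing it moves the estimate most
  p$beta_outcome[3] <- p$beta_outcome[3] + 0.3
  loo2 <- leave_one_out(p)
  full <- loo2$table$beta[loo2$table$excluded == "All"]
  shifts <- abs(loo2$table$beta[1:5] - full)
  expect_equal(which.max(shifts), 3L)
  expect_equal(loo2$table$n_snps[1:5], rep(4L, 5))
})

test_that("multivariable IVW matches the multiple-regression oracle", {
  set.seed(77)
  J <- 10
  B <- cbind(exposure = rnorm(J, 0.15, 0.05), mediator = rnorm(J, -0.05, 0.08))
  y <- drop(B %*% c(-0.5, 0.3)) + rnorm(J, 0, 0.02)
  sy <- runif(J, 0.02, 0.05)
  fit <- mvmr_ivw(B, NULL, y, sy)
  oracle <- lm_wls_oracle(B, y, 1 / sy^2)
  expect_equal(fit$exposure$beta, oracle$coef[1], tolerance = 1e-12)
  expect_equal(fit$mediator$beta, oracle$coef[2], tolerance = 1e-12)
  expect_equal(fit$exposure$se, oracle$se[1], tolerance = 1e-10)
  # rank-deficient design is rejected
  B0 <- cbind(exposure = rnorm(J), mediator = 0)
  expect_error(mvmr_ivw(B0, NULL, y, sy), "rank deficient")
  expect_error(mvmr_ivw(B[1:2, ], NULL, y[1:2], sy[1:2]), "more SNPs")
})

test_that("odds-ratio transform and CI ordering", {
  p <- make_pairs(0.1, 0.01, 0, 0.05)
  expect_equal(wald_ratio(p)$odds_ratio, 1)
  est <- mr_ivw(make_pairs(0.1, 0.01, -0.070712, 0.004))
  expect_equal(round(to_odds_ratio(est)$odds_ratio, 3), 0.493)
  r <- random_pairs(5, 9)
  e <- mr_ivw(r)
  expect_lt(e$or_ci_low, e$odds_ratio)
  expect_lt(e$odds_ratio, e$or_ci_high)
  ft <- forest_table(list(mr_ivw(r), mr_egger(r)), outcome = "ed")
  expect_equal(nrow(ft), 2L)
  expect_named(ft, c("outcome", "method", "n_snps", "beta", "se", "or",
                     "or_ci_low", "or_ci_high", "pval"))
})
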