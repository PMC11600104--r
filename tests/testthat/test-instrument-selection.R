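test_that("cis-region boundaries are inclusive on both ends", {
  cfg <- selection_config(cis_chrom = "1", cis_start = 500, cis_end = 600,
                          cis_flank = 100)
  tab <- make_table(c("rs1", "rs2", "rs3", "rs4"), beta = 1, se = 0.1,
                    pos = c(400L, 399L, 700L, 701L))
  kept <- restrict_to_cis_region(tab, cfg)
  expect_equal(kept$snp_id, c("rs1", "rs3"))
  # mixed-chromosome fixture: 4 of 6 on the cis chromosome inside the window
  tab2 <- make_table(sprintf("rs%d", 1:6), beta = 1, se = 0.1,
                     chrom = c("1", "1", "1", "1", "2", "2"),
                     pos = c(450L, 500L, 600L, 650L, 500L, 550L))
  expect_equal(nrow(restrict_to_cis_region(tab2, cfg)), 4L)
  tab3 <- make_table("rs1", 1, 0.1, pos = NA_integer_)
  expect_error(restrict_to_cis_region(tab3, cfg), "chrom/pos")
})

test_that("p-value filtering is strict at both thresholds", {
  cfg <- selection_config()
  tab <- make_table(c("rs1", "rs2", "rs3"), beta = 1, se = 0.1,
                    pval = c(5e-8, 4.9e-8, 1e-9),
                    pval_adj = c(0.01, 0.04, 0.06))
  kept <- filter_by_pvalue(tab, cfg)
  expect_equal(kept$snp_id, "rs2")  # rs1 at the boundary, rs3 fails adjusted p
  no_adj <- make_table("rs1", 1, 0.1, pval = 1e-9)
  expect_error(filter_by_pvalue(no_adj, cfg), "adjusted")
  cfg2 <- selection_config(pval_adj_max = NULL)
  expect_equal(nrow(filter_by_pvalue(no_adj, cfg2)), 1L)
})

test_that("exclusion-list removal reports removed identifiers", {
  tab <- make_table(sprintf("rs%d", 1:5), beta = 1, se = 0.1)
  expect_equal(apply_exclusion_list(tab, NULL)$table, tab)
  res <- apply_exclusion_list(tab, c("rs2", "rs4"))
  expect_equal(nrow(res$table), 3L)
  expect_equal(res$removed, c("rs2", "rs4"))
  res2 <- apply_exclusion_list(tab, c("zzz1", "zzz2"))
  expect_equal(nrow(res2$table), 5L)
  expect_length(res2$removed, 0L)
})

test_that("greedy LD clumping keeps the best SNP per correlated set", {
  tab <- make_table(c("rsA", "rsB"), beta = 1, se = 0.1, pval = c(1e-10, 1e-9))
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("rsA", "rsB"), c("rsA", "rsB")))
  expect_equal(ld_clump(tab, ld)$snp_id, "rsA")
  # identity LD leaves the table unchanged
  tab5 <- make_table(sprintf("rs%d", 1:5), beta = 1, se = 0.1)
  id5 <- diag(1, 5); dimnames(id5) <- list(tab5$snp_id, tab5$snp_id)
  expect_equal(ld_clump(tab5, id5), tab5)
  expect_error(ld_clump(make_table("zzz", 1, 0.1), id5), "zzz")
})

test_that("clumping matches a brute-force greedy oracle on block LD", {
  set.seed(31)
  ids <- sprintf("rs%03d", 1:10)
  pv <- sort(runif(10, 1e-12, 1e-8))[sample.int(10)]
  tab <- make_table(ids, beta = 1, se = 0.1, pval = pv)
  r <- sqrt(0.8)
  ld <- diag(1, 10); dimnames(ld) <- list(ids, ids)
  ld[1:5, 1:5] <- r^2 * 0 + r; ld[6:10, 6:10] <- r  # constant r within blocks
  ld[1:5, 6:10] <- 0; ld[6:10, 1:5] <- 0
  diag(ld) <- 1
  kept <- ld_clump(tab, ld, r2_max = 0.01)$snp_id
  # brute-force greedy re-implementation
  oracle <- function(tab, ld, r2max) {
    remaining <- tab$snp_id[order(tab$pval, tab$snp_id)]
    acc <- character(0)
    while (length(remaining)) {
      acc <- c(acc, remaining[1])
      remaining <- remaining[ld[remaining, remaining[1]]^2 <= r2max]
      remaining <- setdiff(remaining, acc)
    }
    acc
  }
  expect_setequal(kept, oracle(tab, ld, 0.01))
  expect_length(kept, 2L)  # one survivor per block
  expect_true(all(c(tab$snp_id[1:5][which.min(tab$pval[1:5])],
                    tab$snp_id[6:10][which.min(tab$pval[6:10])]) %in% kept))
  # invariance to input row order
  perm <- tab[sample.int(10), ]
  expect_setequal(ld_clump(perm, ld, 0.01)$snp_id, kept)
})

test_that("F-statistic arithmetic and the weak-instrument boundary", {
  expect_equal(f_statistic(2, 1), 4)
  expect_equal(f_statistic(0, 0.5), 0)
  expect_equal(f_statistic(-0.3, 0.1), 9)
  expect_error(f_statistic(1, 0), "> 0")
  tab <- make_table(c("rs_strong", "rs_weak"), beta = c(1, 0.3), se = 0.1)
  expect_equal(filter_weak(tab, 10)$snp_id, "rs_strong")
  # F exactly at the threshold is kept ("less than" is excluded)
  f_weak <- f_statistic(0.3, 0.1)
  expect_equal(filter_weak(tab, f_min = f_weak)$snp_id, tab$snp_id)
  expect_equal(filter_weak(tab, f_min = f_weak * (1 + 1e-12))$snp_id, "rs_strong")
})

test_that("composite selection reproduces hand-enumerated survivor counts", {
  fx <- selection_fixture()
  res <- select_instruments(fx$table, fx$config, excl = fx$excl, ld = fx$ld)
  expect_equal(unname(res$report$counts),
               c(12L, 10L, 8L, 7L, 4L, 3L))
  expect_setequal(res$table$snp_id, c("rs001", "rs004", "rs007"))
  expect_equal(res$report$removed_by_exclusion, "rs008")
  expect_false(any(diff(res$report$counts) > 0))  # non-increasing
})

test_that("all-pass selection is the identity and empty steps are named", {
  tab <- make_table(sprintf("rs%d", 1:4), beta = 1, se = 0.1,
                    pval = 1e-10, pval_adj = 0.01)
  cfg <- selection_config()  # no cis filter, identity LD skipped
  res <- select_instruments(tab, cfg)
  expect_equal(res$table, tab)
  weakened <- make_table(sprintf("rs%d", 1:4), beta = 1, se = 0.1,
                         pval = 0.5, pval_adj = 0.01)
  expect_error(select_instruments(weakened, cfg), "p-value")
})
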