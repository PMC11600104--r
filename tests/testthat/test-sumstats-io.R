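write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("well-formed tables parse and invalid rows are dropped with a count", {
  path <- write_lines_tmp(c(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP",
    "rs1\t6\t100\ta\tg\t0.2\t0.1\t0.02\t1e-9",
    "rs2\t6\t200\tC\tT\t0.5\t-0.2\t0.03\t1e-10",
    "rs3\t6\t300\tG\tA\t0.7\t0.05\t0.01\t1e-8"
  ))
  tab <- read_sumstats(path, trait_id = "expr")
  expect_s3_class(tab, "sumstats")
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "n_dropped"), 0L)
  expect_equal(tab$effect_allele, c("A", "C", "G"))  # upper-cased
  expect_equal(tab$trait_id, rep("expr", 3))

  bad <- write_lines_tmp(c(
    "SNP\tEA\tOA\tBETA\tSE\tP",
    "rs1\tA\tG\t0.1\t0\t1e-9",     # se = 0
    "rs2\tA\tG\t0.1\t0.02\t1e-9",
    "rs3\tA\tA\t0.1\t0.02\t1e-9",  # identical alleles
    "rs4\tA\tG\t0.1\t0.02\t1.5"    # p > 1
  ))
  tab2 <- read_sumstats(bad)
  expect_equal(nrow(tab2), 1L)
  expect_equal(attr(tab2, "n_dropped"), 3L)
})

test_that("errors name missing columns, unreadable files, empty input", {
  path <- write_lines_tmp(c("SNP\tEA\tOA\tBETA\tSE", "rs1\tA\tG\t0.1\t0.02"))
  expect_error(read_sumstats(path), "P")
  expect_error(read_sumstats(tempfile()), "cannot read")
  empty <- write_lines_tmp(c("SNP\tEA\tOA\tBETA\tSE\tP", "rs1\tA\tG\t0.1\t0\t1e-9"))
  expect_error(read_sumstats(empty), "no valid")
})

test_that("FinnGen-style headers map onto the same table as canonical headers", {
  rows <- data.frame(
    snp = c("rs10", "rs11", "rs12", "rs13", "rs14"),
    chr = "6", pos = 1:5 * 1000L,
    ea = c("A", "C", "G", "T", "A"), oa = c("G", "T", "A", "C", "C"),
    eaf = c(0.1, 0.2, 0.3, 0.4, 0.5),
    beta = c(0.11, -0.2, 0.35, -0.01, 0.07),
    se = c(0.02, 0.03, 0.05, 0.004, 0.011),
    p = c(1e-8, 1e-9, 2e-12, 0.01, 1e-10)
  )
  canon <- write_lines_tmp(c(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP",
    apply(rows, 1, paste, collapse = "\t")
  ))
  finn <- write_lines_tmp(c(
    "#chrom\tpos\tref\talt\trsids\tpval\tbeta\tsebeta\taf_alt",
    apply(rows[, c("chr", "pos", "oa", "ea", "snp", "p", "beta", "se", "eaf")],
          1, paste, collapse = "\t")
  ))
  t1 <- read_sumstats(canon, trait_id = "t2d")
  t2 <- read_sumstats(finn, column_map = column_map_finngen(), trait_id = "t2d")
  for (col in c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval")) {
    expect_equal(t2[[col]], t1[[col]], info = col)
  }
})

test_that("write/read round trip is bit-exact, including missing eaf", {
  set.seed(7)
  tab <- make_table(sprintf("rs%d", 1:5),
                    beta = rnorm(5) / 7, se = runif(5, 0.01, 0.05),
                    eaf = c(0.123456789123456, NA, 0.5, NA, 1 / 3),
                    pval_adj = c(0.01, NA, 0.2, NA, 1e-5), n = 31684)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path, trait_id = attr(tab, "trait_id"))
  for (col in c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "pval_adj", "n")) {
    expect_identical(back[[col]], tab[[col]], info = col)
  }
})

test_that("palindromic detection follows the A/T, C/G definition", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("g", "c"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("T", "C"))
})

test_that("harmonization aligns, flips, rescues strand, drops palindromes", {
  exposure <- make_table(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                         beta = rep(0.1, 5), se = rep(0.02, 5),
                         effect_allele = c("A", "A", "A", "A", "A"),
                         other_allele = c("G", "G", "T", "G", "G"))
  outcome <- make_table(c("rs1", "rs2", "rs3", "rs4", "rs5", "rs9"),
                        beta = c(0.2, 0.2, 0.2, 0.2, 0.2, 1),
                        se = rep(0.03, 6),
                        effect_allele = c("A", "G", "A", "T", "A", "A"),
                        other_allele = c("G", "A", "T", "C", "C", "G"),
                        eaf = 0.25)
  # rs1 aligned; rs2 swapped; rs3 palindromic; rs4 = complement of A/G
  # (T/C) aligned; rs5 irreconcilable (A/C vs A/G); rs9 not shared
  pairs <- harmonize(exposure, outcome)
  rep_ <- harmonization_report(pairs)
  expect_equal(sort(pairs$snp_id), c("rs1", "rs2", "rs4"))
  expect_equal(pairs$beta_outcome[pairs$snp_id == "rs1"], 0.2)
  expect_false(pairs$flipped[pairs$snp_id == "rs1"])
  expect_equal(pairs$beta_outcome[pairs$snp_id == "rs2"], -0.2)
  expect_true(pairs$flipped[pairs$snp_id == "rs2"])
  expect_equal(pairs$eaf_outcome[pairs$snp_id == "rs2"], 0.75)
  expect_equal(pairs$beta_outcome[pairs$snp_id == "rs4"], 0.2)
  expect_equal(rep_$n_overlap, 5L)
  expect_equal(rep_$n_palindromic, 1L)
  expect_equal(rep_$n_strand_complemented, 1L)
  expect_equal(rep_$n_irreconcilable, 1L)
  expect_error(harmonize(exposure, make_table("zzz", 0.1, 0.02)), "overlap")
})

test_that("harmonization is idempotent and invariant to outcome allele flips", {
  sim <- simulate_two_sample(sim_config(seed = 11))
  pairs <- harmonize(sim$exposure, sim$outcome)
  # idempotence: rebuild the outcome table from the harmonized pairs (now
  # aligned to the exposure alleles) and harmonize again -- nothing changes
  out_aligned <- make_table(pairs$snp_id, beta = pairs$beta_outcome,
                            se = pairs$se_outcome,
                            effect_allele = pairs$effect_allele,
                            other_allele = pairs$other_allele,
                            eaf = pairs$eaf_outcome)
  pairs2 <- harmonize(sim$exposure, out_aligned)
  expect_equal(pairs2$snp_id, pairs$snp_id)
  expect_identical(pairs2$beta_outcome, pairs$beta_outcome)
  expect_false(any(pairs2$flipped))
  # flip every outcome allele pair and beta sign: same harmonized effects
  flipped <- sim$outcome
  ea <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- ea
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  pairs3 <- harmonize(sim$exposure, flipped)
  expect_equal(pairs3$snp_id, pairs$snp_id)
  expect_equal(pairs3$beta_outcome, pairs$beta_outcome, tolerance = 1e-15)
  expect_equal(pairs3$eaf_outcome, pairs$eaf_outcome, tolerance = 1e-15)
})

test_that("no palindromic pair ever survives harmonization (allele enumeration)", {
  alleles <- c("A", "C", "G", "T")
  combos <- expand.grid(ea1 = alleles, oa1 = alleles,
                        ea2 = alleles, oa2 = alleles,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ea1 != combos$oa1 & combos$ea2 != combos$oa2, ]
  for (i in seq_len(nrow(combos))) {
    co <- combos[i, ]
    exposure <- make_table("rs1", 0.1, 0.02,
                           effect_allele = co$ea1, other_allele = co$oa1)
    outcome <- make_table("rs1", 0.2, 0.03,
                          effect_allele = co$ea2, other_allele = co$oa2)
    pairs <- tryCatch(harmonize(exposure, outcome), error = function(e) NULL)
    if (!is.null(pairs) && nrow(pairs)) {
      expect_false(any(is_palindromic(pairs)))
    }
  }
})

test_that("LD matrix and exclusion list round-trip through their readers", {
  m <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  path <- withr::local_tempfile()
  write_ld_matrix(m, path)
  expect_equal(read_ld_matrix(path), m)
  bad <- m; bad[1, 2] <- 0.6
  expect_error(write_ld_matrix(bad, path), "symmetric")

  lpath <- withr::local_tempfile()
  writeLines(c("rs1\tknown pleiotropic locus", "rs2"), lpath)
  excl <- read_exclusion_list(lpath)
  expect_equal(excl$snp_id, c("rs1", "rs2"))
  expect_equal(excl$reason, c("known pleiotropic locus", NA))
})
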