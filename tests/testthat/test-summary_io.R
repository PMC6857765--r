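test_that("summary files parse, validate with line numbers, and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tEA\tOA\tfreq\tb\tstderr\tp\tN",
               "rs1\tA\tG\t0.2\t0.10\t0.01\t1e-20\t1000",
               "rs2\tT\tC\t0.5\t-0.05\t0.02\t0.012\t1000",
               "rs3\tG\tA\t0.9\t0.00\t0.03\t1.0\t1000"), path)
  dia <- summary_dialect(snp = "rsid", effect_allele = "EA", other_allele = "OA",
                         eaf = "freq", beta = "b", se = "stderr", pvalue = "p",
                         n = "N")
  ss <- read_summary_stats(path, dialect = dia, trait = "hdl")
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss), 3)
  expect_equal(ss$beta, c(0.10, -0.05, 0.00))
  expect_equal(ss$trait, rep("hdl", 3))

  # round trip in the default dialect
  out <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, out, header_lines = "seed: 1")
  back <- read_summary_stats(out, trait = "hdl")
  expect_equal(as.data.frame(back), as.data.frame(ss))

  # gzip round trip
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_summary_stats(ss, gz)
  expect_equal(read_summary_stats(gz, trait = "hdl")$beta, ss$beta)

  # violations are named with their file line
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tEA\tOA\tfreq\tb\tstderr\tp\tN",
               "rs1\tA\tG\t0.2\t0.1\t0.01\t0.5\t100",
               "rs2\tA\tG\t0.2\t0.1\t0\t0.5\t100"), bad)
  expect_error(read_summary_stats(bad, dialect = dia), "se.*line 3")
  writeLines(c("rsid\tEA\tOA\tfreq\tb\tstderr\tp\tN",
               "rs1\tA\tG\t0.2\tnot_a_number\t0.01\t0.5\t100"), bad)
  expect_error(read_summary_stats(bad, dialect = dia), "non-numeric beta.*line 2")
  writeLines(c("rsid\tEA\tOA", "rs1\tA\tG"), bad)
  expect_error(read_summary_stats(bad, dialect = dia), "missing mandatory column")
})

exposure_df <- function(snp, ea, oa, beta, eaf = 0.2, se = 0.01,
                        trait = "hdl") {
  df <- data.frame(snp = snp, effect_allele = ea, other_allele = oa,
                   eaf = eaf, beta = beta, se = se,
                   pvalue = 2 * pnorm(-abs(beta / se)), n = 1000,
                   trait = trait, stringsAsFactors = FALSE)
  class(df) <- c("summary_stats", "data.frame")
  df
}

outcome_df <- function(snp, ea, oa, beta_mat, eaf = 0.2) {
  df <- data.frame(snp = snp, effect_allele = ea, other_allele = oa,
                   eaf = eaf, beta_mat = beta_mat, se_mat = 0.02,
                   beta_fet = -beta_mat / 2, se_fet = 0.02, cov_mat_fet = 0,
                   stringsAsFactors = FALSE)
  class(df) <- c("partitioned_outcome", "data.frame")
  df
}

test_that("harmonization aligns alleles, flips swaps, drops palindromes", {
  expo <- exposure_df(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                      ea = c("A", "A", "A", "A", "A"),
                      oa = c("G", "G", "G", "T", "G"),
                      beta = c(0.1, 0.1, 0.1, 0.1, 0.1),
                      eaf = c(0.2, 0.2, 0.2, 0.50, 0.2))
  out <- outcome_df(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                    ea = c("A", "G", "C", "A", "A"),
                    oa = c("G", "A", "T", "T", "C"),
                    beta_mat = c(0.10, 0.10, 0.10, 0.10, 0.10))
  tab <- suppressWarnings(harmonize_instruments(expo, out))
  # rs1 same alleles: untouched; rs2 swapped: flipped; rs3 strand complement
  # of swapped (C/T vs A/G = complement G/A): flipped
  expect_equal(tab$snp, c("rs1", "rs2", "rs3"))
  expect_equal(tab$beta_mat, c(0.10, -0.10, -0.10))
  expect_equal(tab$beta_hdl, rep(0.1, 3))
  # rs4 palindromic near 0.5 dropped and logged; rs5 irreconcilable
  log <- exclusion_log(tab)
  expect_setequal(log$snp, c("rs4", "rs5"))
  expect_equal(log$reason[log$snp == "rs4"], "palindromic")
  expect_equal(log$reason[log$snp == "rs5"], "irreconcilable_alleles")
  expect_warning(harmonize_instruments(expo, out), "irreconcilable")
})

test_that("palindromic SNPs with informative frequency align by eaf", {
  expo <- exposure_df(c("rs1", "rs2"), ea = c("A", "C"), oa = c("T", "G"),
                      beta = c(0.1, 0.1), eaf = c(0.9, 0.1))
  out <- outcome_df(c("rs1", "rs2"), ea = c("A", "C"), oa = c("T", "G"),
                    beta_mat = c(0.2, 0.2), eaf = c(0.12, 0.15))
  tab <- harmonize_instruments(expo, out)
  # rs1: outcome eaf on the other side of 0.5, so the outcome's effect
  # allele is the complement-swap -> flip; rs2 same side -> keep
  expect_equal(tab$beta_mat[tab$snp == "rs1"], -0.2)
  expect_equal(tab$beta_mat[tab$snp == "rs2"], 0.2)
})

test_that("harmonization is idempotent", {
  expo <- exposure_df(c("rs1", "rs2"), ea = c("A", "T"), oa = c("G", "C"),
                      beta = c(0.1, -0.2))
  out <- outcome_df(c("rs1", "rs2"), ea = c("G", "T"), oa = c("A", "C"),
                    beta_mat = c(0.3, 0.1))
  tab1 <- harmonize_instruments(expo, out)
  # feed the harmonized rows back through as fresh exposure/outcome tables
  expo2 <- exposure_df(tab1$snp, tab1$effect_allele, tab1$other_allele,
                       tab1$beta_hdl, eaf = tab1$eaf)
  out2 <- out[match(tab1$snp, out$snp), ]
  out2$beta_mat <- ifelse(out2$effect_allele == tab1$effect_allele,
                          tab1$beta_mat, -tab1$beta_mat)
  tab2 <- harmonize_instruments(expo2, out2)
  expect_equal(tab2$beta_mat, tab1$beta_mat)
  expect_equal(tab2$beta_hdl, tab1$beta_hdl)
})

test_that("instrument selection applies the unrestricted/restricted rules", {
  df <- data.frame(snp = paste0("rs", 1:4), effect_allele = "A",
                   other_allele = "G", eaf = 0.3,
                   beta_hdl = 0.1, se_hdl = 0.01,
                   pval_hdl = c(1e-9, 1e-9, 1e-9, 1e-4),
                   beta_ldl = 0.05, se_ldl = 0.01,
                   pval_ldl = c(0.5, 0.01, 0.5, 0.5),
                   beta_tg = 0.05, se_tg = 0.01,
                   pval_tg = c(0.9, 0.9, 0.02, 0.9),
                   beta_mat = 0.01, se_mat = 0.02, beta_fet = 0,
                   se_fet = 0.02, stringsAsFactors = FALSE)
  tab <- as_instrument_table(df, c("hdl", "ldl", "tg"))
  unres <- select_instruments(tab, "hdl")
  expect_setequal(unres$snp, c("rs1", "rs2", "rs3"))
  # restricted: strong for HDL only -> rs2 (LDL p = .01) and rs3 (TG p = .02) fall
  res <- select_instruments(tab, "hdl", mode = "restricted")
  expect_equal(res$snp, "rs1")
  expect_equal(attr(res, "selection")$mode, "restricted")
  expect_error(select_instruments(tab, "hdl", genome_wide_threshold = 0.1),
               "genome_wide_threshold")

  # restricted output is always a subset of unrestricted output
  set.seed(1)
  for (i in 1:20) {
    t2 <- rand_table(30)
    for (lab in c("ldl", "tg")) {
      t2[[paste0("beta_", lab)]] <- rnorm(30)
      t2[[paste0("se_", lab)]] <- 0.01
      t2[[paste0("pval_", lab)]] <- runif(30)
    }
    t2 <- as_instrument_table(as.data.frame(t2), c("hdl", "ldl", "tg"))
    r <- select_instruments(t2, "hdl", mode = "restricted")
    u <- select_instruments(t2, "hdl")
    expect_true(all(r$snp %in% u$snp))
  }

  # missing other-lipid p-values cannot verify the rule
  df$pval_ldl[1] <- NA
  tab <- as_instrument_table(df, c("hdl", "ldl", "tg"))
  expect_error(select_instruments(tab, "hdl", mode = "restricted"),
               "cannot verify")
})

test_that("orientation flips all betas jointly and preserves Wald ratios", {
  tab <- make_table(bx = c(-0.1, 0.2), by = c(0.02, 0.03), sy = c(0.01, 0.01))
  ori <- orient_positive(tab, "hdl")
  expect_equal(ori$beta_hdl, c(0.1, 0.2))
  expect_equal(ori$beta_mat, c(-0.02, 0.03))
  expect_equal(ori$beta_fet, c(0, 0))
  expect_equal(ori$effect_allele, c("G", "A"))
  expect_equal(ori$eaf, c(0.7, 0.3))
  expect_identical(attr(ori, "oriented"), "hdl")

  # already positive: unchanged
  expect_equal(as.data.frame(orient_positive(ori, "hdl")), as.data.frame(ori))

  # ratio preservation and IVW invariance on random tables
  set.seed(42)
  for (i in 1:10) {
    t2 <- rand_table(12)
    o2 <- orient_positive(t2, "hdl")
    r_before <- wald_ratios(t2, "hdl")
    r_after <- wald_ratios(o2, "hdl")
    expect_equal(r_after$ratio[match(r_before$snp, r_after$snp)],
                 r_before$ratio, tolerance = 1e-14)
    expect_equal(mr_ivw(o2, "hdl")$estimate, mr_ivw(t2, "hdl")$estimate,
                 tolerance = 1e-14)
  }

  # zero exposure beta has no orientation
  t3 <- make_table(bx = c(0, 1), by = c(0.1, 0.1), sy = c(0.1, 0.1))
  expect_warning(o3 <- orient_positive(t3, "hdl"), "orientation undefined")
  expect_equal(nrow(o3), 1)
  expect_true("rs1" %in% exclusion_log(o3)$snp)
})
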