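test_that("well-formed tables round-trip with zero rejects", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- make_gwas(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                   se = c(0.01, 0.02, 0.01), pval = c(1e-9, 1e-12, 1e-8))
  write_summary_stats(tab, path)
  got <- read_summary_stats(path)
  expect_equal(nrow(got), 3L)
  expect_equal(nrow(attr(got, "rejects")), 0L)
  expect_equal(got$beta, tab$beta)
  expect_equal(got$snp_id, tab$snp_id)
})

test_that("invariant-violating rows are rejected with line numbers and reasons", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- make_gwas(c("rs1", "rs2", "rs3", "rs4"),
                   beta = 0.1, se = c(0.01, 0, 0.01, 0.01),
                   pval = c(1e-9, 1e-9, 1.5, 1e-9))
  write_summary_stats(tab, path)
  got <- read_summary_stats(path)
  rej <- attr(got, "rejects")
  expect_equal(got$snp_id, c("rs1", "rs4"))
  expect_setequal(rej$snp_id, c("rs2", "rs3"))
  expect_match(rej$reason[rej$snp_id == "rs2"], "se")
  expect_match(rej$reason[rej$snp_id == "rs3"], "pvalue")
  # line numbers count the header: first data row is line 2
  expect_equal(sort(rej$line), c(3L, 4L))
})

test_that("column_map adapts dialects and missing headers error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rsid,A1,A2,b,sderr,P",
               "rs1,A,G,0.1,0.01,1e-9",
               "rs2,C,T,-0.2,0.02,1e-10"), path)
  cm <- c(snp_id = "rsid", effect_allele = "A1", other_allele = "A2",
          beta = "b", se = "sderr", pvalue = "P")
  got <- read_summary_stats(path, cm)
  expect_equal(got$beta, c(0.1, -0.2))
  expect_true(all(is.na(got$eaf)))  # unmapped optional field is absent
  expect_error(read_summary_stats(path, replace(cm, 4, "nonexistent")),
               "missing mapped column")
  expect_error(read_summary_stats(path, cm[-1]), "required field")
})

test_that("a file with zero valid rows errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- make_gwas("rs1", beta = 0.1, se = -1, pval = 1e-9)
  write_summary_stats(tab, path)
  expect_error(read_summary_stats(path), "zero valid rows")
})

test_that("harmonization copies, swaps and complements correctly", {
  expo <- make_gwas(c("rs1", "rs2", "rs3"), beta = 0.10, se = 0.01,
                    pval = 1e-9, ea = "A", oa = "G", eaf = 0.3)
  outc <- make_gwas(c("rs1", "rs2", "rs3"), beta = 0.02, se = 0.01,
                    pval = 0.5, ea = c("A", "G", "T"),
                    oa = c("G", "A", "C"), eaf = c(0.3, 0.7, 0.3))
  h <- harmonize(expo, outc)
  expect_equal(h$beta_out, c(0.02, -0.02, 0.02))
  expect_equal(h$flipped, c(FALSE, TRUE, TRUE))
  expect_equal(h$eaf_out, c(0.3, 0.3, 0.3))
})

test_that("ambiguous palindromic variants are dropped and counted", {
  expo <- make_gwas(c("rs1", "rs2"), beta = 0.1, se = 0.01, pval = 1e-9,
                    ea = c("A", "A"), oa = c("T", "T"),
                    eaf = c(0.50, 0.10))
  outc <- make_gwas(c("rs1", "rs2"), beta = 0.02, se = 0.01, pval = 0.5,
                    ea = "A", oa = "T", eaf = c(0.50, 0.12))
  h <- harmonize(expo, outc, palindrome_policy = "drop_ambiguous",
                 eaf_window = 0.08)
  expect_equal(h$snp_id, "rs2")  # rs1 eaf 0.5 is inside the window
  drops <- attr(h, "drops")
  expect_equal(drops$snp_id, "rs1")
  expect_equal(drops$reason, "palindromic_ambiguous")
  # drop_all removes both; keep retains both
  expect_equal(nrow(harmonize(expo, outc, "drop_all")), 0L)
  expect_equal(nrow(harmonize(expo, outc, "keep")), 2L)
})

test_that("harmonize is idempotent and allele-order invariant", {
  set.seed(42)
  for (rep in 1:5) {
    j <- 8
    expo <- make_gwas(sprintf("rs%d", 1:j), beta = rnorm(j, 0.2, 0.05),
                      se = 0.01, pval = 1e-9,
                      ea = sample(c("A", "C"), j, TRUE), oa = "G",
                      eaf = runif(j, 0.1, 0.45))
    expo$oa[expo$ea == "G"] <- "T"
    swap <- sample(c(TRUE, FALSE), j, TRUE)
    outc <- expo
    outc$beta <- rnorm(j, 0.05, 0.02)
    outc$pval <- 0.5
    outc$ea[swap] <- expo$oa[swap]
    outc$oa[swap] <- expo$ea[swap]
    outc$eaf[swap] <- 1 - expo$eaf[swap]
    h1 <- harmonize(expo, outc)
    # idempotence: re-harmonizing the harmonized pair changes nothing
    expo2 <- data.frame(snp_id = h1$snp_id, chrom = h1$chrom, pos = h1$pos,
                        ea = h1$ea, oa = h1$oa, eaf = h1$eaf_exp,
                        beta = h1$beta_exp, se = h1$se_exp,
                        pval = h1$pval_exp, n = h1$n_exp)
    outc2 <- data.frame(snp_id = h1$snp_id, chrom = h1$chrom, pos = h1$pos,
                        ea = h1$ea, oa = h1$oa, eaf = h1$eaf_out,
                        beta = h1$beta_out, se = h1$se_out,
                        pval = h1$pval_out, n = h1$n_out)
    h2 <- harmonize(expo2, outc2)
    expect_equal(h2$beta_out, h1$beta_out)
    expect_equal(h2$eaf_out, h1$eaf_out)
    expect_false(any(h2$flipped))
    # allele-order invariance: relabel outcome alleles + negate beta
    outc3 <- outc
    outc3$ea <- outc$oa
    outc3$oa <- outc$ea
    outc3$beta <- -outc$beta
    outc3$eaf <- 1 - outc$eaf
    h3 <- harmonize(expo, outc3)
    expect_equal(h3$beta_out, h1$beta_out)
    expect_equal(h3$eaf_out, h1$eaf_out)
  }
})

test_that("harmonization conserves counts across kept and dropped", {
  expo <- make_gwas(sprintf("rs%d", 1:6), beta = 0.1, se = 0.01,
                    pval = 1e-9, ea = c("A", "A", "A", "A", "A", "C"),
                    oa = c("G", "G", "T", "T", "G", "G"),
                    eaf = c(0.3, 0.3, 0.5, 0.2, 0.3, 0.3))
  outc <- make_gwas(sprintf("rs%d", 1:6), beta = 0.02, se = 0.01,
                    pval = 0.5, ea = c("A", "C", "A", "A", "A", "C"),
                    oa = c("G", "G", "T", "T", "G", "G"),
                    eaf = c(0.3, 0.3, 0.5, 0.2, 0.3, 0.3))
  h <- harmonize(expo, outc)
  n_shared <- length(intersect(expo$snp_id, outc$snp_id))
  expect_equal(n_shared, nrow(h) + nrow(attr(h, "drops")))
  counts <- attr(h, "drop_counts")
  expect_equal(sum(counts), nrow(attr(h, "drops")))
})

test_that("duplicate snp_id raises an error", {
  expo <- make_gwas(c("rs1", "rs1"), beta = 0.1, se = 0.01, pval = 1e-9)
  outc <- make_gwas("rs1", beta = 0.02, se = 0.01, pval = 0.5)
  expect_error(harmonize(expo, outc), "duplicate snp_id")
})
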