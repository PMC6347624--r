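test_that("sumstats round-trips through the canonical dialect", {
  ss <- toy_sumstats()
  path <- withr_tempfile()
  write_sumstats(ss, path)
  back <- read_sumstats(path, trait_name = "toy")
  expect_equal(back$snps$snp_id, ss$snps$snp_id)
  expect_equal(back$snps$z, ss$snps$z, tolerance = 1e-9)
  expect_equal(back$snps$eaf, ss$snps$eaf, tolerance = 1e-9)
  # second round trip is byte-stable
  path2 <- withr_tempfile()
  write_sumstats(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("reading drops invalid rows and rejects empty tables", {
  df <- toy_snps()
  df$z[2] <- NA  # p without z must not be reconstructed
  df$p <- 2 * pnorm(-abs(df$z))
  df$p[2] <- 0.01
  path <- withr_tempfile()
  names(df) <- c("SNP", "CHR", "BP", "A1", "A2", "Z", "N", "EAF", "P")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(ss <- read_sumstats(path), "dropping 1")
  expect_equal(nrow(ss$snps), 5)
  expect_false("rs2" %in% ss$snps$snp_id)

  # inconsistent p vs z is also dropped
  df2 <- toy_snps()
  df2$p <- 2 * pnorm(-abs(df2$z))
  df2$p[1] <- 0.5
  expect_message(ss2 <- sumstats(df2), "dropping 1")
  expect_false("rs1" %in% ss2$snps$snp_id)

  # all-invalid input is fatal
  df3 <- toy_snps()
  df3$eaf <- 0
  expect_error(sumstats(df3), "no valid")
})

test_that("dialect mapping resolves arbitrary column names", {
  df <- toy_snps()
  names(df) <- c("rsid", "chromosome", "position", "ea", "oa",
                 "zscore", "samples", "freq")
  path <- withr_tempfile()
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dial <- c(snp_id = "rsid", chrom = "chromosome", pos = "position",
            a1 = "ea", a2 = "oa", z = "zscore", n = "samples",
            eaf = "freq")
  ss <- read_sumstats(path, dialect = dial)
  expect_equal(nrow(ss$snps), 6)
  expect_error(read_sumstats(path), "not found")
})

test_that("harmonization flips, drops ambiguity, and is an involution", {
  ss <- toy_sumstats()
  ref <- data.frame(snp_id = paste0("rs", 1:6),
                    a1 = c("G", "G", "A", "C", "C", "A"),
                    a2 = c("A", "A", "C", "A", "A", "C"))
  # rs1 flipped, rs2/rs3/rs4 match, rs5 mismatched alleles -> dropped
  expect_message(h <- harmonize_to_reference(ss, ref), "removed 1")
  expect_false("rs5" %in% h$snps$snp_id)
  r1 <- h$snps[h$snps$snp_id == "rs1", ]
  expect_equal(r1$z, -1.2)
  expect_equal(r1$eaf, 0.7)
  expect_equal(r1$a1, "G")
  r3 <- h$snps[h$snps$snp_id == "rs3", ]
  expect_equal(r3$z, 2.0)  # exact match unchanged

  # flipping twice restores the original orientation
  ref_back <- data.frame(snp_id = "rs1", a1 = "A", a2 = "G")
  h2 <- suppressMessages(harmonize_to_reference(h, ref_back))
  expect_equal(h2$snps$z[h2$snps$snp_id == "rs1"], 1.2)
  expect_equal(h2$snps$eaf[h2$snps$snp_id == "rs1"], 0.3)

  # strand-ambiguous records are always removed
  amb <- toy_snps()
  amb$a1[1] <- "A"; amb$a2[1] <- "T"
  ss_amb <- sumstats(amb)
  ref_amb <- data.frame(snp_id = paste0("rs", 1:6),
                        a1 = amb$a1, a2 = amb$a2)
  h3 <- suppressMessages(harmonize_to_reference(ss_amb, ref_amb))
  expect_false("rs1" %in% h3$snps$snp_id)
})

test_that("QC enforces MAF, keep-list and MHC rules idempotently", {
  df <- toy_snps()
  df$eaf[1] <- 0.005  # below the 1% MAF rule
  ss <- sumstats(df)
  q <- suppressMessages(apply_qc_filters(ss))
  expect_false("rs1" %in% q$snps$snp_id)   # MAF > 1% rule
  expect_false("rs6" %in% q$snps$snp_id)   # inside default MHC interval
  expect_true(all(c("rs2", "rs3", "rs4", "rs5") %in% q$snps$snp_id))

  # idempotent
  q2 <- apply_qc_filters(q)
  expect_identical(q$snps, q2$snps)

  # keep-list restriction
  q3 <- suppressMessages(apply_qc_filters(ss, keep_list = c("rs2", "rs3")))
  expect_identical(q3$snps$snp_id, c("rs2", "rs3"))

  # passing table unchanged with no exclusions
  ok <- sumstats(toy_snps()[1:5, ])
  expect_identical(apply_qc_filters(ok, exclude = region_set())$snps,
                   ok$snps)

  expect_error(suppressMessages(
    apply_qc_filters(ss, keep_list = "absent")), "removed every SNP")
})

test_that("region sets merge, test membership and round-trip as BED", {
  rs <- region_set(c(1, 1, 2), c(100, 150, 50), c(200, 300, 80))
  expect_equal(nrow(rs), 2)
  expect_equal(rs$end[rs$chrom == 1], 300)
  # 1-based SNP positions against 0-based half-open intervals
  expect_equal(in_regions(rs, c(1, 1, 1, 2), c(101, 300, 301, 60)),
               c(TRUE, TRUE, FALSE, TRUE))
  path <- withr_tempfile()
  write_regions(rs, path)
  expect_equal(as.data.frame(read_regions(path)), as.data.frame(rs))
  expect_error(region_set(1, 200, 100))
})

test_that("annotation matrices enforce base column and read/write TSV", {
  am <- annot_matrix(paste0("rs", 1:4),
                     cbind(coding = c(1, 0, 1, 0)))
  expect_true(all(am$values[, "base"] == 1))
  path <- withr_tempfile()
  write_annotations(am, path)
  back <- read_annotations(path)
  expect_equal(back$values, am$values)
  expect_error(annot_matrix("rs1", cbind(base = 0.5)), "base column")
  expect_error(annot_matrix("rs1", matrix(1, 1, 1)), "named")
})
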