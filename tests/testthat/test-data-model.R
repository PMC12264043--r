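test_that("count tables round-trip through write and read", {
  df <- data.frame(site_id = c("s1", "s2", "s3"),
                   sample_id = "a_F1i",
                   t_c57 = c(10L, 0L, 7L), t_pwk = c(5L, 2L, 7L),
                   p_c57 = c(20L, 1L, 0L), p_pwk = c(8L, 0L, 30L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeResultsTable(df, f)
  expect_identical(readCountTable(f), df)
})

test_that("malformed count tables are rejected with named column and row", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site_id\tsample_id\tt_c57\tt_pwk\tp_c57\tp_pwk",
               "s1\ta\t5.5\t3\t4\t4"), f)
  expect_error(readCountTable(f), "t_c57.*row.*1")
  writeLines(c("site_id\tsample_id\tt_c57\tt_pwk\tp_c57\tp_pwk",
               "s1\ta\t5\t-3\t4\t4"), f)
  expect_error(readCountTable(f), "t_pwk")
  writeLines("site_id\tsample_id\tt_c57\tp_c57\tp_pwk", f)
  expect_error(readCountTable(f), "t_pwk")
})

test_that("a header-only count file yields an empty collection", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("site_id\tsample_id\tt_c57\tt_pwk\tp_c57\tp_pwk", f)
  out <- readCountTable(f)
  expect_equal(nrow(out), 0)
})

test_that("SNP tables are read from TSV and minimal VCF identically", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tallele_c57\tallele_pwk",
               "chr1\t100\tA\tG", "chr2\t7\tC\tT"), tsv)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tG\t.\tPASS\t.",
               "chr2\t7\t.\tC\tT\t.\tPASS\t."), vcf)
  expect_equal(readSnpTable(tsv), readSnpTable(vcf), ignore_attr = TRUE)
})

test_that("multi-allelic and malformed SNP records are rejected", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tG,T\t.\tPASS\t."), vcf)
  expect_error(readSnpTable(vcf), "multi-allelic")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tallele_c57\tallele_pwk", "chr1\t100\tA\tA"), tsv)
  expect_error(readSnpTable(tsv), "distinct")
})

test_that("strain-specific adenine flagging matches exact coordinates only", {
  sites <- data.frame(site_id = c("s1", "s2"), chrom = "chr1",
                      pos = c(100L, 200L), strand = "+",
                      motif_c57 = "GGACT", motif_pwk = "GGACT")
  snps <- data.frame(chrom = "chr1", pos = c(100L, 201L),
                     allele_c57 = "A", allele_pwk = "G")
  out <- flagStrainSpecificAdenines(sites, snps)
  expect_equal(out$is_strain_specific_A, c(TRUE, FALSE))
  # idempotent and order-independent
  expect_equal(flagStrainSpecificAdenines(out, snps)$is_strain_specific_A,
               c(TRUE, FALSE))
  expect_equal(flagStrainSpecificAdenines(sites[2:1, ], snps)$is_strain_specific_A,
               c(FALSE, TRUE))
  none <- flagStrainSpecificAdenines(sites, snps[0, ])
  expect_false(any(none$is_strain_specific_A))
})

test_that("parent-axis orientation resolves through the cross and is an involution", {
  # F1i: PWK mother, so maternal-first order puts PWK counts first
  o <- orientCounts(1, 2, 3, 4, "F1i", axis = "parent")
  expect_equal(unlist(o), c(t_first = 2, t_second = 1, p_first = 4, p_second = 3))
  o <- orientCounts(1, 2, 3, 4, "F1r", axis = "parent")
  expect_equal(unlist(o), c(t_first = 1, t_second = 2, p_first = 3, p_second = 4))
  expect_equal(unlist(orientCounts(1, 2, 3, 4, "F1i", axis = "strain")),
               c(t_first = 1, t_second = 2, p_first = 3, p_second = 4))
  # applying the parent orientation twice restores strain order for both crosses
  for (cr in c("F1i", "F1r")) {
    once <- orientCounts(1, 2, 3, 4, cr, axis = "parent")
    twice <- orientCounts(once$t_first, once$t_second,
                          once$p_first, once$p_second, cr, axis = "parent")
    expect_equal(unlist(twice), c(t_first = 1, t_second = 2,
                                  p_first = 3, p_second = 4))
  }
  expect_error(orientCounts(1, 2, 3, 4, "F2", axis = "parent"), "cross")
})

test_that("Asm6aExperiment validity enforces pairing and motif invariants", {
  sim <- simulateCohort(simConfig(n_sites = 20, n_groups = 2, seed = 3))
  ax <- Asm6aExperiment(sim$counts, sim$sites, sim$samples)
  expect_s4_class(ax, "Asm6aExperiment")
  expect_true(validObject(ax))
  # breaking the F1i/F1r pairing is caught
  bad <- sim$samples
  bad$cross <- "F1i"
  expect_error(Asm6aExperiment(sim$counts, sim$sites, bad), "F1i and.*F1r")
  # motif without a central A on either allele is caught
  badSites <- sim$sites
  badSites$motif_c57 <- sub("^(..).(..)$", "\\1G\\2", badSites$motif_c57)
  badSites$motif_pwk <- badSites$motif_c57
  expect_error(Asm6aExperiment(sim$counts, badSites, sim$samples), "center")
})

test_that("maternal strain follows the cross and groupPairs reports the pairing", {
  sim <- simulateCohort(simConfig(n_sites = 10, n_groups = 2, seed = 5))
  ax <- Asm6aExperiment(sim$counts, sim$sites, sim$samples)
  ms <- maternalStrain(ax)
  expect_equal(unname(ms[crossOf(ax) == "F1i"]), rep("pwk", 2))
  expect_equal(unname(ms[crossOf(ax) == "F1r"]), rep("c57", 2))
  gp <- groupPairs(ax)
  expect_equal(nrow(gp), 2)
  expect_setequal(gp$f1i_sample_id, sim$groups$f1i_sample_id)
})

test_that("BED export converts coordinates and caps the score", {
  sim <- simulateCohort(simConfig(n_sites = 30, n_groups = 1,
                                  frac_seq_meth = 0.5, seq_meth_effect = 3,
                                  depth_input = 300, depth_ip = 300, seed = 8))
  ax <- quantifyAllelic(Asm6aExperiment(sim$counts, sim$sites, sim$samples))
  calls <- callASm6A(ax)
  expect_gt(sum(calls$klass != "none"), 0)
  f <- withr::local_tempfile(fileext = ".bed")
  exportCallsBed(calls, ax, f)
  bed <- read.table(f, sep = "\t")
  called <- calls[calls$klass != "none", ]
  pos1 <- sim$sites$pos[match(called$site_id, sim$sites$site_id)]
  expect_equal(bed$V2, pos1 - 1L)   # 0-based half-open start
  expect_equal(bed$V3, pos1)
  expect_true(all(bed$V5 <= 1000))
  expect_equal(bed$V5, pmin(round(abs(called$group_log2_cpfc) * 100), 1000),
               tolerance = 1e-6)
})
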