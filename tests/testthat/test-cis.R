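test_that("flank layout reports transcript-strand signed positions", {
  sites <- data.frame(site_id = c("p", "m"), chrom = "chr1",
                      pos = c(1000L, 5000L), strand = c("+", "-"))
  snps <- data.frame(chrom = "chr1", pos = c(1005L, 995L, 1000L,
                                             5005L, 4900L, 5200L))
  lay <- flankLayout(sites, snps)
  # '+' site: +5 and -5; SNP at the site itself excluded
  expect_equal(lay$positions$position[lay$positions$site_id == "p"], c(-5L, 5L))
  # '-' site: genomic +5 becomes -5; genomic -100 becomes +100; 5200 out of range
  expect_equal(sort(lay$positions$position[lay$positions$site_id == "m"]),
               c(-5L, 100L))
  # nearest with the upstream tie-break
  expect_equal(lay$nearest$nearest_position[lay$nearest$site_id == "p"], -5L)
  expect_equal(lay$nearest$nearest_position[lay$nearest$site_id == "m"], -5L)
  # no SNPs in range: NA nearest, empty layout is valid
  far <- flankLayout(sites, data.frame(chrom = "chr9", pos = 1L))
  expect_true(all(is.na(far$nearest$nearest_position)))
})

test_that("ties at equal distance resolve to the upstream side", {
  sites <- data.frame(site_id = "s", chrom = "chr1", pos = 1000L, strand = "+")
  snps <- data.frame(chrom = "chr1", pos = c(1003L, 997L))
  expect_equal(flankLayout(sites, snps)$nearest$nearest_position, -3L)
})

test_that("SNP distribution score follows the 1/D + 1/B formula", {
  expect_equal(snpDistributionScore(c(-5, 95)), (1 / 5 + 1 / 95) + (1 / 1 + 1 / 10))
  # bin boundary: |position| 10 is still bin 1 under the ceiling rule
  expect_equal(snpDistributionScore(10), 1 / 10 + 1 / 1)
  expect_equal(snpDistributionScore(11), 1 / 11 + 1 / 2)
  expect_equal(snpDistributionScore(integer(0)), 0)
})

test_that("the score strictly increases when any single SNP moves closer", {
  set.seed(31)
  for (i in 1:10000) {
    k <- sample(1:6, 1)
    pos <- sample(c(-100:-1, 1:100), k)
    j <- sample(k, 1)
    d <- abs(pos[j])
    if (d == 1) next
    closer <- pos
    closer[j] <- sign(pos[j]) * sample(seq_len(d - 1), 1)
    expect_gt(snpDistributionScore(closer), snpDistributionScore(pos))
  }
})

test_that("positional enrichment recovers the uniform closed form", {
  # 10 testable sites at every one of the 200 positions, 1 seq-call each
  posAll <- setdiff(-100:100, 0)
  testable <- sprintf("t%03d_%d", seq_along(rep(posAll, each = 10)),
                      rep(posAll, each = 10))
  nearest <- data.frame(site_id = testable,
                        nearest_position = rep(posAll, each = 10))
  seqIds <- nearest$site_id[!duplicated(nearest$nearest_position)]
  enr <- positionalEnrichment(seqIds, testable, nearest)
  expect_equal(attr(enr, "R"), 0.1)
  expect_equal(nrow(enr), 200)
  # closed form: P(Bin(10, 0.1) >= 1) = 1 - 0.9^10
  expect_equal(enr$p_value, rep(1 - 0.9^10, 200), tolerance = 1e-12)
  expect_false(any(enr$candidate))
})

test_that("concentrating the calls at +1 puts the minimum p-value there", {
  set.seed(33)
  posAll <- setdiff(-100:100, 0)
  n <- 4000
  sid <- sprintf("s%04d", 1:n)
  nearest <- data.frame(site_id = sid,
                        nearest_position = sample(posAll, n, TRUE))
  at1 <- nearest$site_id[nearest$nearest_position == 1L]
  other <- sample(setdiff(sid, at1), 60)
  seqIds <- c(at1, other)
  enr <- positionalEnrichment(seqIds, sid, nearest)
  expect_equal(enr$position[which.min(enr$p_value)], 1L)
  expect_true(enr$candidate[enr$position == 1L])
})

test_that("uncovered positions are excluded from baseline and testing", {
  nearest <- data.frame(site_id = c("a", "b", "c", "d"),
                        nearest_position = c(5L, 5L, -3L, -3L))
  enr <- positionalEnrichment(c("a", "c"), c("a", "b", "c", "d"), nearest)
  expect_equal(nrow(enr), 2)            # only positions 5 and -3 covered
  expect_equal(attr(enr, "R"), 0.5)     # mean(1/2, 1/2)
  expect_error(positionalEnrichment("a", character(0), nearest), "empty")
  expect_error(positionalEnrichment("zzz", c("a", "b"), nearest), "subset")
})

test_that("motif ranking and pair matrix aggregate log2(cpFC) by labels", {
  motifs <- c(rep("GGACT", 5), rep("GAACT", 3), rep("AGACT", 2), "TGACT")
  expect_equal(rankMotifs(motifs, 2), c("GGACT", "GAACT"))
  ranked <- rankMotifs(motifs, 2)
  m <- motifPairMatrix(motif_c57 = c("GGACT", "GGACT", "AGACT", "TGACT"),
                       motif_pwk = c("GAACT", "GAACT", "TGACT", "AGACT"),
                       cpfc = c(1.0, 0.6, 0.3, -0.2),
                       ranked_motifs = ranked)
  expect_equal(dim(m$mean), c(3, 3))
  expect_equal(m$mean["GGACT", "GAACT"], 0.8)
  expect_equal(m$n["GGACT", "GAACT"], 2)
  # two distinct non-top motifs land in (Other, Other)
  expect_equal(m$n["Other", "Other"], 2)
  expect_equal(m$mean["Other", "Other"], mean(c(0.3, -0.2)))
  # unused pairs stay NA
  expect_true(is.na(m$mean["GAACT", "GGACT"]))
  # identical allelic motifs are excluded
  m2 <- motifPairMatrix("GGACT", "GGACT", 1.0, ranked)
  expect_equal(sum(m2$n), 0)
})

test_that("the PWM uses per-column pseudocounted frequencies and log2 odds", {
  pwm <- buildPwm(rep("GGACT", 7))
  # column 3: 7 A's + pseudocount 1 over 7 + 4
  expect_equal(unname(pwm$prob["A", 3]), 8 / 11)
  expect_equal(unname(pwm$logodds["A", 3]), log2((8 / 11) / 0.25))
  expect_gt(pwm$logodds["A", 3], 0)
  expect_equal(unname(colSums(pwm$prob)), rep(1, 5))
  expect_true(all(pwm$prob > 0))
  expect_error(buildPwm(c("GGACT", "GGAC")), "5-mers")
  expect_error(buildPwm(character(0)), "at least one")
  # single motif: dominated by pseudocounts but valid
  one <- buildPwm("GGACT")
  expect_equal(unname(colSums(one$prob)), rep(1, 5))
})

test_that("uniform random motifs give near-zero log odds", {
  set.seed(37)
  motifs <- apply(matrix(sample(c("A", "C", "G", "T"), 5 * 50000, TRUE), ncol = 5),
                  1, paste0, collapse = "")
  pwm <- buildPwm(motifs)
  expect_lt(max(abs(pwm$logodds)), 0.05)
})

test_that("motif variation effect is antisymmetric with the stated sign convention", {
  pwm <- buildPwm(rep("GGACT", 50))
  expect_equal(motifVariationEffect(pwm, "GGACT", "GGACT"), 0)
  # PWK matches the consensus where C57 does not: positive
  expect_gt(motifVariationEffect(pwm, "GTACT", "GGACT"), 0)
  expect_equal(motifVariationEffect(pwm, "GTACT", "GGACT"),
               -motifVariationEffect(pwm, "GGACT", "GTACT"))
})
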