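test_that("exact binomial p-values match enumeration and stats::binom.test", {
  # frozen spot checks
  expect_equal(binomialAllelicTest(5, 5, 0.5), 1)
  expect_equal(binomialAllelicTest(10, 0, 0.5), 2 * 0.5^10)
  expect_equal(binomialAllelicTest(12, 8, 0.6), enumBinomPvalue(12, 20, 0.6),
               tolerance = 1e-12)
  # a modest grid against both oracles
  for (n in c(1, 7, 18, 25)) {
    for (p in c(0.3, 0.5, 0.75)) {
      k <- 0:n
      mine <- binomialAllelicTest(k, n - k, rep(p, n + 1))
      oracle <- vapply(k, enumBinomPvalue, numeric(1), n = n, prob = p)
      expect_equal(mine, oracle, tolerance = 1e-12)
      bt <- vapply(k, function(kk) binom.test(kk, n, p)$p.value, numeric(1))
      expect_equal(mine, bt, tolerance = 1e-12)
    }
  }
})

test_that("the PWK-oriented mirror test returns the identical p-value", {
  set.seed(5)
  k1 <- rbinom(50, 60, 0.5); k2 <- 60 - k1
  arr <- runif(50, 0.2, 0.8)
  expect_equal(binomialAllelicTest(k1, k2, arr),
               binomialAllelicTest(k2, k1, 1 - arr))
})

test_that("degenerate binomial inputs are refused", {
  expect_error(binomialAllelicTest(0, 0, 0.5), "positive")
  expect_error(binomialAllelicTest(5, 5, 0), "inside")
  expect_error(binomialAllelicTest(5, 5, 1), "inside")
})

test_that("BH q-values match the textbook step-up on random vectors", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_identical(bhFdr(numeric(0)), numeric(0))
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bhFdr(p), stepUpBH(p), tolerance = 1e-12)
  }
  # q >= p always
  p <- runif(100)
  expect_true(all(bhFdr(p) >= p))
})

test_that("cutoff calibration reproduces the closed-form symmetric case", {
  # medians +/-1.2 in both crosses: d = 2.4, D = 2.4*sqrt(2), C = 2.4, cutoff 1.2
  cal <- calibrateCutoff(c(1.2, -1.2), c(1.2, -1.2), c("C57", "C57"))
  expect_equal(cal$C57$d_i, 2.4)
  expect_equal(cal$C57$D, 2.4 * sqrt(2))
  expect_equal(cal$C57$C, 2.4)
  expect_equal(cal$cutoff, 1.2)
  # two classes average
  cal2 <- calibrateCutoff(c(1, -1, 2, -2), c(1, -1, 2, -2),
                          c("C57", "C57", "PWK", "PWK"))
  expect_equal(cal2$cutoff, mean(c(1, 2)))
  # a class with no negative values is skipped with a warning
  expect_warning(
    cal3 <- calibrateCutoff(c(1, -1, 2, 2), c(1, -1, 2, 2),
                            c("C57", "C57", "PWK", "PWK")),
    "PWK")
  expect_equal(cal3$cutoff, 1)
  expect_error(
    suppressWarnings(calibrateCutoff(c(1, 1), c(1, 1), c("C57", "C57"))),
    "no control class")
})

test_that("candidate criteria are strict at all three boundaries", {
  expect_true(callCandidates(0.04, 0.09, 0.61))
  expect_false(callCandidates(0.04, 0.09, 0.60))   # |cpfc| not > 0.6
  expect_false(callCandidates(0.05, 0.05, 2))      # p not < 0.05
  expect_false(callCandidates(0.04, 0.10, 2))      # q not < 0.1
  expect_true(callCandidates(0.04, 0.09, -0.61))   # magnitude, either sign
  expect_false(callCandidates(NA, 0.01, 2))
})

test_that("candidate calling is monotone in |cpfc| and anti-monotone in p and q", {
  set.seed(11)
  for (i in 1:100) {
    p <- runif(1, 0, 0.1); q <- runif(1, 0, 0.2); fc <- runif(1, 0, 1.5)
    a <- callCandidates(p, q, fc)
    expect_true(!a || callCandidates(p / 2, q, fc))
    expect_true(!a || callCandidates(p, q / 2, fc))
    expect_true(!a || callCandidates(p, q, fc * 2))
  }
})

test_that("four-class assignment covers the sign grid with strict thresholds", {
  expect_equal(classifyAsm6a(1.0, 0.8), "C57_seq")
  expect_equal(classifyAsm6a(-0.7, -2), "PWK_seq")
  expect_equal(classifyAsm6a(-0.7, 0.9), "Mat_parent")
  expect_equal(classifyAsm6a(0.9, -0.7), "Pat_parent")
  # boundary: exactly +/-0.6 is inside the dead zone
  grid <- expand.grid(i = c(-1, -0.6, 0, 0.6, 1), r = c(-1, -0.6, 0, 0.6, 1))
  kl <- classifyAsm6a(grid$i, grid$r)
  expected <- ifelse(grid$i > 0.6 & grid$r > 0.6, "C57_seq",
              ifelse(grid$i < -0.6 & grid$r < -0.6, "PWK_seq",
              ifelse(grid$i < -0.6 & grid$r > 0.6, "Mat_parent",
              ifelse(grid$i > 0.6 & grid$r < -0.6, "Pat_parent", "none"))))
  expect_equal(kl, expected)
})

test_that("negating all cpFC swaps C57<->PWK and Mat<->Pat", {
  set.seed(21)
  vi <- runif(200, -2, 2); vr <- runif(200, -2, 2)
  a <- classifyAsm6a(vi, vr)
  b <- classifyAsm6a(-vi, -vr)
  map <- c(C57_seq = "PWK_seq", PWK_seq = "C57_seq",
           Mat_parent = "Pat_parent", Pat_parent = "Mat_parent", none = "none")
  expect_equal(unname(map[a]), b)
})

test_that("the high-reproducibility filter needs 4 detectable samples and sign agreement", {
  expect_false(filterHighlyReproducible("C57_seq", 3, 1, 1, 1))
  expect_true(filterHighlyReproducible("C57_seq", 5, 1, 0.4, 0.2))
  expect_false(filterHighlyReproducible("C57_seq", 6, 1, 0.4, -0.2))
  expect_false(filterHighlyReproducible("C57_seq", 6, -1, 0.4, 0.2))
  expect_false(filterHighlyReproducible("C57_seq", 6, 1, NA, 0.2))
})

test_that("callASm6A assembles per-group calls consistent with its parts", {
  sim <- simulateCohort(simConfig(n_sites = 400, n_groups = 2,
                                  frac_seq_meth = 0.15, seq_meth_effect = 2,
                                  depth_input = 150, depth_ip = 150, seed = 23))
  ax <- quantifyAllelic(Asm6aExperiment(sim$counts, sim$sites, sim$samples))
  calls <- callASm6A(ax)
  # only group-testable sites appear
  cov <- assay(ax, "coverage")
  gp <- groupPairs(ax)
  for (k in seq_len(nrow(gp))) {
    rows <- calls[calls$group_id == gp$group_id[k], ]
    tst <- groupTestable(setNames(cov[, gp$f1i_sample_id[k]], rownames(ax)),
                         setNames(cov[, gp$f1r_sample_id[k]], rownames(ax)))
    expect_setequal(rows$site_id, tst)
  }
  # q is a BH image of p within each sample's tested set
  g1 <- calls[calls$group_id == "g01", ]
  expect_equal(g1$q_f1i, bhFdr(g1$p_f1i))
  expect_equal(g1$q_f1r, bhFdr(g1$p_f1r))
  # classes only where candidates in both samples
  called <- calls$klass != "none"
  expect_true(all(calls$candidate_f1i[called] & calls$candidate_f1r[called]))
  expect_equal(unname(calls$klass[called]),
               classifyAsm6a(calls$cpfc_f1i[called], calls$cpfc_f1r[called]))
  # group metrics are the sample means
  expect_equal(calls$group_log2_cpfc,
               groupLevelMetric(calls$cpfc_f1i, calls$cpfc_f1r))
})
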