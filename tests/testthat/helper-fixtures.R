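# Builders for tiny hand-specified cohorts used across test files.

# A minimal one-group experiment from explicit per-site count quadruples.
# counts_f1i / counts_f1r: data.frames with t_c57, t_pwk, p_c57, p_pwk.
tinyExperiment <- function(counts_f1i, counts_f1r,
                           is_strain_specific_A = NULL,
                           motif_c57 = NULL, motif_pwk = NULL,
                           tissue = "cerebrum") {
  n <- nrow(counts_f1i)
  stopifnot(nrow(counts_f1r) == n)
  sid <- sprintf("s%03d", seq_len(n))
  if (is.null(is_strain_specific_A)) is_strain_specific_A <- rep(FALSE, n)
  if (is.null(motif_c57)) motif_c57 <- rep("GGACT", n)
  if (is.null(motif_pwk)) motif_pwk <- motif_c57
  sites <- data.frame(site_id = sid, chrom = "chr1",
                      pos = 1000L * seq_len(n), strand = "+",
                      gene = "g", motif_c57 = motif_c57,
                      motif_pwk = motif_pwk,
                      is_strain_specific_A = is_strain_specific_A)
  samples <- data.frame(sample_id = c("a_F1i", "a_F1r"),
                        tissue = tissue, age = "P0", sex = "male",
                        cross = c("F1i", "F1r"), group_id = "a")
  counts <- rbind(
    data.frame(site_id = sid, sample_id = "a_F1i", counts_f1i),
    data.frame(site_id = sid, sample_id = "a_F1r", counts_f1r))
  Asm6aExperiment(counts, sites, samples)
}

# Equal counts for all sites: handy symmetric baseline.
flatCounts <- function(n, t = 50L, p = 50L) {
  data.frame(t_c57 = rep(t, n), t_pwk = rep(t, n),
             p_c57 = rep(p, n), p_pwk = rep(p, n))
}

# Independent enumeration oracle for the two-sided minlike exact binomial
# p-value, using choose()-based masses (not dbinom); floating-point ties are
# detected with a small relative tolerance.
enumBinomPvalue <- function(k, n, prob) {
  x <- 0:n
  mass <- choose(n, x) * prob^x * (1 - prob)^(n - x)
  sum(mass[mass <= mass[k + 1] * (1 + 1e-7)])
}

# Textbook Benjamini-Hochberg step-up adjusted values.
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
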