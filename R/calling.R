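#' Exact binomial test of allelic methylation imbalance
#'
#' Under the null of no allelic methylation imbalance, a read in the IP sample
#' comes from the C57 allele with the probability observed in the paired
#' untreated input sample: `k_c57 ~ Binomial(n = k_c57 + k_pwk,
#' p = ARR_c57,input)`. The two-sided p-value is the "minimum-likelihood"
#' mass: the sum of `P(X = x)` over all outcomes no more likely than the
#' observed one (the same convention as [stats::binom.test()], including its
#' relative tolerance of 1e-7 for floating-point ties). The PWK-oriented test
#' with the complementary input ratio is the mirror image and returns the
#' identical p-value.
#'
#' @param k_c57,k_pwk allele-resolved IP read counts (vectorized).
#' @param arr_c57_input input-sample C57 allelic read ratio, strictly inside
#'   (0, 1) — guaranteed for detectable sites, whose per-allele input counts
#'   are at least 5.
#' @return p-values in `[0, 1]`.
#' @examples
#' binomialAllelicTest(10, 0, 0.5)   # 2 * 0.5^10
#' binomialAllelicTest(5, 5, 0.5)    # 1
#' @export
binomialAllelicTest <- function(k_c57, k_pwk, arr_c57_input) {
  n <- k_c57 + k_pwk
  if (any(n <= 0)) stop("total IP count must be positive")
  if (any(arr_c57_input <= 0 | arr_c57_input >= 1))
    stop("input allelic read ratio must be strictly inside (0, 1)")
  relErr <- 1 + 1e-7
  mapply(function(k, n, p) {
    d <- stats::dbinom(0:n, n, p)
    min(1, sum(d[d <= d[k + 1L] * relErr]))
  }, k_c57, n, arr_c57_input)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR-adjusted q-values (via [stats::p.adjust()]), clipped to 1 and
#' returned in the input order. Adjustment is done within whatever family the
#' caller supplies; [callASm6A()] adjusts within each sample's tested
#' (group-testable) site set.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bhFdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Calibrate the |log2(cpFC)| cutoff from strain-specific positive controls
#'
#' Testable sites where the methylatable A exists in only one strain have a
#' known allelic direction and serve as positive controls. For one control
#' class, let `N_i+`/`N_i-` be the medians of the positive/negative
#' `log2(cpFC)` values among F1i samples (`N_r+`/`N_r-` in F1r). The spread
#' per cross is `d_i = N_i+ - N_i-` and `d_r = N_r+ - N_r-`; the group-level
#' Euclidean spread is `D = sqrt(d_i^2 + d_r^2)`, the per-sample spread
#' `C = sqrt(D^2 / 2)`, and the cutoff `C / 2` (the fluctuation is
#' bidirectional). The classes of C57-specific and PWK-specific adenine sites
#' are calibrated separately and the final cutoff is the mean of the two; a
#' class lacking positive or negative values in either cross is skipped with a
#' warning. The cohort analysed alongside this package's methods yields 0.6,
#' shipped as the default constant in [callASm6A()].
#'
#' @param cpfc_f1i,cpfc_f1r `log2(cpFC)` values of the control sites in the
#'   group's F1i and F1r samples.
#' @param control_class per-site class labels, `"C57"` or `"PWK"` (the strain
#'   carrying the adenine).
#' @return list with per-class results (`d_i`, `d_r`, `D`, `C`, `cutoff`) and
#'   the final `cutoff`.
#' @examples
#' calibrateCutoff(c(1.2, -1.2), c(1.2, -1.2), c("C57", "C57"))$cutoff  # 0.6
#' @export
calibrateCutoff <- function(cpfc_f1i, cpfc_f1r, control_class) {
  stopifnot(length(cpfc_f1i) == length(cpfc_f1r),
            length(control_class) == length(cpfc_f1i))
  perClass <- function(cls) {
    vi <- cpfc_f1i[control_class == cls]
    vr <- cpfc_f1r[control_class == cls]
    vi <- vi[is.finite(vi)]; vr <- vr[is.finite(vr)]
    if (!any(vi > 0) || !any(vi < 0) || !any(vr > 0) || !any(vr < 0)) {
      warning("control class '", cls,
              "' lacks positive or negative log2(cpFC) values; skipped")
      return(NULL)
    }
    d_i <- stats::median(vi[vi > 0]) - stats::median(vi[vi < 0])
    d_r <- stats::median(vr[vr > 0]) - stats::median(vr[vr < 0])
    D <- sqrt(d_i^2 + d_r^2)
    C <- sqrt(D^2 / 2)
    list(d_i = d_i, d_r = d_r, D = D, C = C, cutoff = C / 2)
  }
  classes <- intersect(c("C57", "PWK"), unique(control_class))
  res <- lapply(classes, perClass)
  names(res) <- classes
  res <- Filter(Negate(is.null), res)
  if (!length(res))
    stop("no control class with both positive and negative values")
  res$cutoff <- mean(vapply(res, `[[`, numeric(1), "cutoff"))
  res
}

#' Candidate ASm6A criteria in one sample
#'
#' A testable site is a candidate in a sample iff `p < 0.05`, BH `q < 0.1`
#' and `|log2(cpFC)| > cutoff`, all strict.
#'
#' @param p,q,cpfc per-site p-values, q-values and `log2(cpFC)` in the sample.
#' @param cutoff the |log2(cpFC)| threshold (default 0.6).
#' @param p_threshold,fdr_level the significance thresholds.
#' @return logical vector.
#' @export
callCandidates <- function(p, q, cpfc, cutoff = 0.6,
                           p_threshold = 0.05, fdr_level = 0.1) {
  !is.na(p) & !is.na(q) & !is.na(cpfc) &
    p < p_threshold & q < fdr_level & abs(cpfc) > cutoff
}

#' Four-class ASm6A assignment from the paired samples' directions
#'
#' For a site passing the candidate criteria in both samples of an F1i-F1r
#' group, the pair of `log2(cpFC)` signs identifies the effect axis: agreement
#' means the same strain is favoured in both crosses (sequence-dependent),
#' disagreement means the same *parent* is favoured (parent-of-origin, since
#' the maternal strain flips between crosses).
#' `(+,+) -> C57_seq`; `(-,-) -> PWK_seq`; `(-,+) -> Mat_parent`
#' (maternal = PWK in F1i and C57 in F1r); `(+,-) -> Pat_parent`. Values
#' inside `(-cutoff, cutoff)` yield `"none"`.
#'
#' @param cpfc_f1i,cpfc_f1r the group's two `log2(cpFC)` values (vectorized).
#' @param cutoff the |log2(cpFC)| threshold (default 0.6).
#' @return character vector in
#'   `{"C57_seq", "PWK_seq", "Mat_parent", "Pat_parent", "none"}`.
#' @export
classifyAsm6a <- function(cpfc_f1i, cpfc_f1r, cutoff = 0.6) {
  out <- rep("none", length(cpfc_f1i))
  hi_i <- !is.na(cpfc_f1i) & cpfc_f1i > cutoff
  lo_i <- !is.na(cpfc_f1i) & cpfc_f1i < -cutoff
  hi_r <- !is.na(cpfc_f1r) & cpfc_f1r > cutoff
  lo_r <- !is.na(cpfc_f1r) & cpfc_f1r < -cutoff
  out[hi_i & hi_r] <- "C57_seq"
  out[lo_i & lo_r] <- "PWK_seq"
  out[lo_i & hi_r] <- "Mat_parent"
  out[hi_i & lo_r] <- "Pat_parent"
  out
}

#' High-reproducibility filter for an ASm6A call
#'
#' A called site is highly reproducible when (a) it is allelically detectable
#' in at least four samples of the same tissue and (b) its group-level metric
#' agrees in sign with the corresponding tissue-level metric computed from
#' F1i samples and with the one from F1r samples — `log2(cpFC)` for the
#' sequence classes, `log2(mpFC)` for the parent classes.
#'
#' @param klass the call's class (one of the four non-`"none"` labels).
#' @param n_detectable number of samples in the tissue where the site is
#'   allelically detectable.
#' @param group_metric the group-level `log2(cpFC)` (seq classes) or
#'   `log2(mpFC)` (parent classes).
#' @param tissue_f1i,tissue_f1r the tissue-level metric on the same scale,
#'   aggregated over F1i and over F1r samples.
#' @return logical.
#' @export
filterHighlyReproducible <- function(klass, n_detectable, group_metric,
                                     tissue_f1i, tissue_f1r) {
  ok <- !is.na(group_metric) & !is.na(tissue_f1i) & !is.na(tissue_f1r)
  ok & n_detectable >= 4 &
    sign(ifelse(ok, group_metric, 0)) == sign(ifelse(ok, tissue_f1i, 1)) &
    sign(ifelse(ok, group_metric, 0)) == sign(ifelse(ok, tissue_f1r, 1))
}

#' Identify and classify ASm6A sites in every F1i-F1r group
#'
#' Runs the full calling procedure on a quantified experiment. Per group, the
#' sites testable in both samples are tested with [binomialAllelicTest()]
#' (IP counts against the same sample's input allelic read ratio), BH-adjusted
#' within each sample's tested set, filtered with the candidate criteria
#' (`p < p_threshold`, `q < fdr_level`, `|log2(cpFC)| > cutoff`), intersected
#' across the two samples, classified with [classifyAsm6a()], and flagged
#' with [filterHighlyReproducible()].
#'
#' @param x a quantified [Asm6aExperiment-class].
#' @param cutoff |log2(cpFC)| threshold; the default 0.6 is the
#'   positive-control-calibrated constant (see [calibrateCutoff()]).
#' @param p_threshold,fdr_level binomial-test and BH-FDR thresholds
#'   (defaults 0.05 and 0.1).
#' @return data.frame with one row per group-testable site per group:
#'   `site_id`, `group_id`, per-sample `p_f1i`, `p_f1r`, `q_f1i`, `q_f1r`,
#'   `cpfc_f1i`, `cpfc_f1r`, `candidate_f1i`, `candidate_f1r`,
#'   `group_log2_cpfc`, `group_log2_mpfc`, `klass`, `highly_reproducible`.
#' @examples
#' cfg <- simConfig(n_sites = 300, n_groups = 2, frac_seq_meth = 0.2,
#'                  seq_meth_effect = 2, seed = 7)
#' sim <- simulateCohort(cfg)
#' ax <- quantifyAllelic(Asm6aExperiment(sim$counts, sim$sites, sim$samples))
#' calls <- callASm6A(ax)
#' table(calls$klass)
#' @export
callASm6A <- function(x, cutoff = 0.6, p_threshold = 0.05, fdr_level = 0.1) {
  .assertQuantified(x)
  gp <- groupPairs(x)
  cov <- assay(x, "coverage")
  cpfc <- assay(x, "log2_cpfc")
  mpfc <- assay(x, "log2_mpfc")
  pC <- ipCounts(x, "c57"); pP <- ipCounts(x, "pwk")
  arrIn <- assay(x, "arr_c57_input")
  cd <- as.data.frame(colData(x))
  detect <- cov != "undetectable"

  # tissue-level metrics per cross, over samples where the site is detectable
  tissueMetric <- function(metric, tissue, cross) {
    cols <- which(cd$tissue == tissue & cd$cross == cross)
    m <- metric[, cols, drop = FALSE]
    d <- detect[, cols, drop = FALSE] & !is.na(m)
    v <- rowSums(ifelse(d, m, 0)) / rowSums(d)
    v[rowSums(d) == 0] <- NA_real_
    v
  }
  tisC <- list(); tisM <- list()
  for (tis in unique(cd$tissue)) {
    for (cr in c("F1i", "F1r")) {
      tisC[[paste(tis, cr)]] <- tissueMetric(cpfc, tis, cr)
      tisM[[paste(tis, cr)]] <- tissueMetric(mpfc, tis, cr)
    }
  }
  nDetectTissue <- vapply(unique(cd$tissue), function(tis)
    rowSums(detect[, cd$tissue == tis, drop = FALSE]), numeric(nrow(x)))
  if (is.null(dim(nDetectTissue)))
    nDetectTissue <- matrix(nDetectTissue, ncol = 1,
                            dimnames = list(NULL, unique(cd$tissue)))

  res <- vector("list", nrow(gp))
  for (k in seq_len(nrow(gp))) {
    i <- gp$f1i_sample_id[k]; r <- gp$f1r_sample_id[k]
    tis <- gp$tissue[k]
    sel <- which(cov[, i] == "testable" & cov[, r] == "testable")
    if (!length(sel)) next
    p_i <- binomialAllelicTest(pC[sel, i], pP[sel, i], arrIn[sel, i])
    p_r <- binomialAllelicTest(pC[sel, r], pP[sel, r], arrIn[sel, r])
    q_i <- bhFdr(p_i); q_r <- bhFdr(p_r)
    cand_i <- callCandidates(p_i, q_i, cpfc[sel, i], cutoff, p_threshold, fdr_level)
    cand_r <- callCandidates(p_r, q_r, cpfc[sel, r], cutoff, p_threshold, fdr_level)
    klass <- rep("none", length(sel))
    both <- cand_i & cand_r
    klass[both] <- classifyAsm6a(cpfc[sel, i][both], cpfc[sel, r][both], cutoff)
    gC <- groupLevelMetric(cpfc[sel, i], cpfc[sel, r])
    gM <- groupLevelMetric(mpfc[sel, i], mpfc[sel, r])
    isSeq <- klass %in% c("C57_seq", "PWK_seq")
    isPar <- klass %in% c("Mat_parent", "Pat_parent")
    hr <- rep(FALSE, length(sel))
    if (any(isSeq))
      hr[isSeq] <- filterHighlyReproducible(
        klass[isSeq], nDetectTissue[sel, tis][isSeq], gC[isSeq],
        tisC[[paste(tis, "F1i")]][sel][isSeq], tisC[[paste(tis, "F1r")]][sel][isSeq])
    if (any(isPar))
      hr[isPar] <- filterHighlyReproducible(
        klass[isPar], nDetectTissue[sel, tis][isPar], gM[isPar],
        tisM[[paste(tis, "F1i")]][sel][isPar], tisM[[paste(tis, "F1r")]][sel][isPar])
    res[[k]] <- data.frame(
      site_id = rownames(x)[sel], group_id = gp$group_id[k],
      p_f1i = p_i, p_f1r = p_r, q_f1i = q_i, q_f1r = q_r,
      cpfc_f1i = cpfc[sel, i], cpfc_f1r = cpfc[sel, r],
      candidate_f1i = cand_i, candidate_f1r = cand_r,
      group_log2_cpfc = gC, group_log2_mpfc = gM,
      klass = klass, highly_reproducible = hr,
      row.names = NULL)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(site_id = character(), group_id = character(),
                      p_f1i = numeric(), p_f1r = numeric(),
                      q_f1i = numeric(), q_f1r = numeric(),
                      cpfc_f1i = numeric(), cpfc_f1r = numeric(),
                      candidate_f1i = logical(), candidate_f1r = logical(),
                      group_log2_cpfc = numeric(), group_log2_mpfc = numeric(),
                      klass = character(), highly_reproducible = logical())
  out
}
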