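#' Strain-axis allelic imbalance for one record
#'
#' `log2Cpfc()` computes `log2(cpFC)` for one site in one sample directly from
#' counts and library sizes: the log2 ratio of the C57 and PWK linear
#' library-normalized enrichments `(p/t)/(P/T)`, with the shared +0.5 IP
#' pseudocount when either allele's IP count is zero. `log2Mpfc()` is the
#' parent-oriented version, equal to `-log2(cpFC)` in F1i samples (PWK mother)
#' and `+log2(cpFC)` in F1r samples (C57 mother). Both refuse sites that are
#' not allelically detectable. [quantifyAllelic()] computes the same
#' quantities for a whole experiment.
#'
#' @param t_c57,t_pwk,p_c57,p_pwk the site's counts in this sample.
#' @param libs library sizes from [computeLibrarySizes()].
#' @param cross `"F1i"` or `"F1r"` (for `log2Mpfc`).
#' @return signed numeric; positive `log2(cpFC)` means the C57 allele is more
#'   methylated, positive `log2(mpFC)` means the maternal allele is.
#' @export
log2Cpfc <- function(t_c57, t_pwk, p_c57, p_pwk, libs) {
  st <- classifyCoverage(t_c57, t_pwk, p_c57, p_pwk)
  if (any(st == "undetectable"))
    stop("log2(cpFC) is only defined for allelically detectable sites")
  en <- .enrichment(p_c57, p_pwk, t_c57, t_pwk, libs)
  log2(en$E_c57 / en$E_pwk)
}

#' @rdname log2Cpfc
#' @export
log2Mpfc <- function(t_c57, t_pwk, p_c57, p_pwk, libs, cross) {
  if (!all(cross %in% c("F1i", "F1r"))) stop("unknown cross label")
  ifelse(cross == "F1r", 1, -1) * log2Cpfc(t_c57, t_pwk, p_c57, p_pwk, libs)
}

#' Group- and tissue-level imbalance aggregates
#'
#' The group-level metric is the arithmetic mean of the F1i and F1r sample
#' values (undefined if either is); for a sequence effect the two agree in
#' sign and the mean preserves it, for a parent-of-origin effect the
#' strain-axis values cancel. The tissue-level metric for one cross is the
#' mean across that cross's samples in a tissue, over samples where the site
#' is allelically detectable.
#'
#' @param v_f1i,v_f1r per-sample metric values (vectorized).
#' @return `groupLevelMetric`: the mean, `NA` if either input is `NA`.
#' @export
groupLevelMetric <- function(v_f1i, v_f1r) {
  (v_f1i + v_f1r) / 2
}

#' @rdname groupLevelMetric
#' @param values numeric vector of one site's per-sample metric values.
#' @param detectable logical vector: is the site allelically detectable in
#'   each sample.
#' @return `tissueLevelMetric`: list with `value` (mean over detectable
#'   samples, `NA` if none) and `n` (contributing samples).
#' @export
tissueLevelMetric <- function(values, detectable) {
  use <- detectable & !is.na(values)
  list(value = if (any(use)) mean(values[use]) else NA_real_,
       n = sum(use))
}

#' Virtual-control imbalance metrics for one site in one group
#'
#' Two negative-control comparisons quantify background fluctuation without
#' strain effects: `I_s = |log2(E_{s,F1i} / E_{s,F1r})|` compares the *same*
#' strain's enrichment across the group's two samples (`Inter` = mean of
#' `I_c57` and `I_pwk`), while `Intra` = mean of `|log2(cpFC)|` in the two
#' samples compares different strains within each sample. Under a pure
#' sequence effect Intra exceeds Inter; under no effect they are comparable.
#'
#' @param rec_f1i,rec_f1r lists/rows with `t_c57`, `t_pwk`, `p_c57`, `p_pwk`
#'   for the site in the F1i and F1r samples.
#' @param libs_f1i,libs_f1r the two samples' [computeLibrarySizes()] results.
#' @return list with `inter` and `intra` (both non-negative; `NA` when an
#'   enrichment is undefined after pseudocounting).
#' @export
strainControlMetrics <- function(rec_f1i, rec_f1r, libs_f1i, libs_f1r) {
  ei <- .enrichment(rec_f1i$p_c57, rec_f1i$p_pwk,
                    rec_f1i$t_c57, rec_f1i$t_pwk, libs_f1i)
  er <- .enrichment(rec_f1r$p_c57, rec_f1r$p_pwk,
                    rec_f1r$t_c57, rec_f1r$t_pwk, libs_f1r)
  I_c57 <- abs(log2(ei$E_c57 / er$E_c57))
  I_pwk <- abs(log2(ei$E_pwk / er$E_pwk))
  intra <- (abs(log2(ei$E_c57 / ei$E_pwk)) + abs(log2(er$E_c57 / er$E_pwk))) / 2
  inter <- (I_c57 + I_pwk) / 2
  bad <- !is.finite(inter) | !is.finite(intra)
  list(inter = ifelse(bad, NA_real_, inter),
       intra = ifelse(bad, NA_real_, intra))
}

#' Inter/Intra control metrics for all sites of one group
#'
#' Convenience wrapper applying [strainControlMetrics()] to every site of an
#' F1i-F1r group that is allelically detectable in both samples.
#'
#' @param x a quantified [Asm6aExperiment-class].
#' @param group_id one group id from `groupPairs(x)`.
#' @return data.frame with `site_id`, `inter`, `intra`.
#' @export
strainControlTable <- function(x, group_id) {
  .assertQuantified(x)
  gp <- groupPairs(x)
  g <- gp[gp$group_id == group_id, ]
  if (nrow(g) != 1L) stop("unknown group_id: ", group_id)
  i <- g$f1i_sample_id; r <- g$f1r_sample_id
  cov <- assay(x, "coverage")
  keep <- cov[, i] != "undetectable" & cov[, r] != "undetectable"
  cd <- colData(x)
  libsOf <- function(s) list(T_c57 = cd[s, "T_c57"], T_pwk = cd[s, "T_pwk"],
                             P_c57 = cd[s, "P_c57"], P_pwk = cd[s, "P_pwk"])
  recOf <- function(s) list(t_c57 = inputCounts(x, "c57")[keep, s],
                            t_pwk = inputCounts(x, "pwk")[keep, s],
                            p_c57 = ipCounts(x, "c57")[keep, s],
                            p_pwk = ipCounts(x, "pwk")[keep, s])
  m <- strainControlMetrics(recOf(i), recOf(r), libsOf(i), libsOf(r))
  data.frame(site_id = rownames(x)[keep], inter = m$inter, intra = m$intra,
             row.names = NULL)
}
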