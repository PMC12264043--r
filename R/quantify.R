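#' Allele-specific library sizes for one sample
#'
#' The four allele-specific library sizes of a sample are the totals of
#' allele-resolved reads over sites: `T_c57 = sum(t_c57)`, etc. Sites flagged
#' as strain-specific adenines are excluded from the sums: their IP reads were
#' removed upstream when counting neighbouring sites, so including them would
#' make the totals inconsistent with the usable site universe.
#'
#' @param counts data.frame of one sample's rows (columns `t_c57`, `t_pwk`,
#'   `p_c57`, `p_pwk`, optionally `site_id`).
#' @param exclude logical vector marking rows to exclude (typically the
#'   strain-specific-adenine flags), or `NULL`.
#' @return named list `T_c57`, `T_pwk`, `P_c57`, `P_pwk` with attribute
#'   `usable` (FALSE when any total is zero).
#' @export
computeLibrarySizes <- function(counts, exclude = NULL) {
  if (!is.null(exclude)) counts <- counts[!exclude, , drop = FALSE]
  out <- list(T_c57 = sum(counts$t_c57), T_pwk = sum(counts$t_pwk),
              P_c57 = sum(counts$p_c57), P_pwk = sum(counts$p_pwk))
  attr(out, "usable") <- all(unlist(out) > 0)
  out
}

#' Allele-specific m6A level
#'
#' The level of one allele at one site is the natural log of its
#' library-normalized IP/input enrichment, `L = log((p/t) / (P/T))`.
#' A zero IP count yields `-Inf` (undefined enrichment); a zero input count
#' yields `NaN`/`Inf` and cannot occur for allelically detectable sites, whose
#' input counts are at least 5 per allele.
#'
#' @param p,t allele-resolved IP and input counts at the site.
#' @param P,T allele-specific IP and input library sizes.
#' @return numeric; `-Inf` when `p == 0`.
#' @examples
#' alleleLevel(50, 25, 1e6, 2e6)  # log 4
#' @export
alleleLevel <- function(p, t, P, T) {
  log((p / t) / (P / T))
}

#' Coverage classification of a site in one sample
#'
#' A site is *allelically detectable* in a sample when both alleles are
#' adequately covered: `t_c57 >= 5`, `t_pwk >= 5`, `t_c57 + t_pwk >= 20` and
#' `p_c57 + p_pwk >= 20`. It is *testable* (eligible for the binomial test)
#' when additionally `t_c57 + t_pwk >= 30`. The classification is monotone in
#' every count.
#'
#' @param t_c57,t_pwk,p_c57,p_pwk counts (vectorized).
#' @return character vector in `{"undetectable", "detectable", "testable"}`.
#' @export
classifyCoverage <- function(t_c57, t_pwk, p_c57, p_pwk) {
  det <- t_c57 >= 5 & t_pwk >= 5 & (t_c57 + t_pwk) >= 20 & (p_c57 + p_pwk) >= 20
  tst <- det & (t_c57 + t_pwk) >= 30
  ifelse(tst, "testable", ifelse(det, "detectable", "undetectable"))
}

#' Sites testable in both samples of an F1i-F1r group
#'
#' @param f1i_status,f1r_status named character vectors of coverage status
#'   (names = site ids) for the group's F1i and F1r samples.
#' @return character vector of site ids testable in both.
#' @export
groupTestable <- function(f1i_status, f1r_status) {
  intersect(names(f1i_status)[f1i_status == "testable"],
            names(f1r_status)[f1r_status == "testable"])
}

#' Allelic read ratio
#'
#' Fraction of allele-resolved reads from the first allele,
#' `r_first / (r_first + r_second)`; `NA` when both counts are zero.
#'
#' @param r_first,r_second counts (vectorized).
#' @return proportion in `[0, 1]` or `NA`.
#' @export
allelicReadRatio <- function(r_first, r_second) {
  tot <- r_first + r_second
  ifelse(tot > 0, r_first / tot, NA_real_)
}

# Linear IP/input enrichment per allele with the shared pseudocount rule:
# when either allele's IP count is 0, BOTH IP counts get +0.5 so the ratio
# metrics stay finite and antisymmetric; the affected entries are flagged.
.enrichment <- function(p_c57, p_pwk, t_c57, t_pwk, libs) {
  pseudo <- (p_c57 == 0 | p_pwk == 0)
  pc <- p_c57 + 0.5 * pseudo
  pp <- p_pwk + 0.5 * pseudo
  list(E_c57 = (pc / t_c57) / (libs$P_c57 / libs$T_c57),
       E_pwk = (pp / t_pwk) / (libs$P_pwk / libs$T_pwk),
       pseudocounted = pseudo)
}

#' Derive allelic levels, ratios, coverage and imbalance metrics
#'
#' Computes, for every site x sample, the allele-specific m6A levels
#' (`L_c57`, `L_pwk`; natural log), coverage status, input and IP allelic
#' read ratios on both axes (`arr_c57_input`, `arr_c57_ip`, `arr_mat_input`,
#' `arr_mat_ip`), and the allelic imbalance metrics `log2_cpfc` (strain axis:
#' C57 over PWK) and `log2_mpfc` (parent axis: maternal over paternal), and
#' stores them as assays. Per-sample library sizes (strain-specific adenine
#' sites excluded) land in `colData`.
#'
#' `log2(cpFC)` is the log2 ratio of the two alleles' linear library-normalized
#' enrichments; it equals `(L_c57 - L_pwk)/log(2)` where both levels are
#' finite, and uses a shared +0.5 IP pseudocount (flagged in assay
#' `pseudocounted`) when one allele's IP count is zero. `log2(mpFC)` is its
#' parent-oriented relabeling: `-log2(cpFC)` in F1i samples, `+log2(cpFC)` in
#' F1r samples. Metrics are `NA` where a site lacks input coverage on either
#' allele.
#'
#' @param x an [Asm6aExperiment-class].
#' @return `x` with derived assays added and `metadata(x)$quantified = TRUE`.
#' @examples
#' sim <- simulateCohort(simConfig(n_sites = 100, n_groups = 1, seed = 1))
#' ax <- quantifyAllelic(Asm6aExperiment(sim$counts, sim$sites, sim$samples))
#' assayNames(ax)
#' @export
quantifyAllelic <- function(x) {
  tC <- inputCounts(x, "c57"); tP <- inputCounts(x, "pwk")
  pC <- ipCounts(x, "c57");    pP <- ipCounts(x, "pwk")
  flag <- isStrainSpecificA(x)
  nS <- ncol(x)
  dims <- dimnames(tC)
  mk <- function() matrix(NA_real_, nrow(x), nS, dimnames = dims)
  L_c57 <- mk(); L_pwk <- mk(); cpfc <- mk(); pseudo <-
    matrix(FALSE, nrow(x), nS, dimnames = dims)
  libdf <- data.frame(T_c57 = integer(nS), T_pwk = integer(nS),
                      P_c57 = integer(nS), P_pwk = integer(nS))
  usable <- logical(nS)
  for (j in seq_len(nS)) {
    libs <- computeLibrarySizes(
      data.frame(t_c57 = tC[, j], t_pwk = tP[, j],
                 p_c57 = pC[, j], p_pwk = pP[, j]),
      exclude = flag)
    libdf[j, ] <- unlist(libs)
    usable[j] <- attr(libs, "usable")
    if (!usable[j]) next
    L_c57[, j] <- alleleLevel(pC[, j], tC[, j], libs$P_c57, libs$T_c57)
    L_pwk[, j] <- alleleLevel(pP[, j], tP[, j], libs$P_pwk, libs$T_pwk)
    en <- .enrichment(pC[, j], pP[, j], tC[, j], tP[, j], libs)
    v <- log2(en$E_c57 / en$E_pwk)
    v[tC[, j] == 0 | tP[, j] == 0] <- NA_real_
    cpfc[, j] <- v
    pseudo[, j] <- en$pseudocounted
  }
  if (any(!usable))
    warning("sample(s) with a zero allele-specific library size marked unusable: ",
            paste(colnames(x)[!usable], collapse = ", "))
  cover <- matrix(classifyCoverage(tC, tP, pC, pP), nrow(x), nS, dimnames = dims)
  arrCin <- allelicReadRatio(tC, tP)
  arrCip <- allelicReadRatio(pC, pP)
  matC57 <- maternalStrain(x) == "c57"
  arrMin <- arrCin; arrMip <- arrCip
  arrMin[, !matC57] <- 1 - arrCin[, !matC57]
  arrMip[, !matC57] <- 1 - arrCip[, !matC57]
  mpfc <- sweep(cpfc, 2, ifelse(matC57, 1, -1), `*`)
  assays(x, withDimnames = FALSE)[c("L_c57", "L_pwk", "coverage",
                                    "arr_c57_input", "arr_c57_ip",
                                    "arr_mat_input", "arr_mat_ip",
                                    "log2_cpfc", "log2_mpfc",
                                    "pseudocounted")] <-
    list(L_c57, L_pwk, cover, arrCin, arrCip, arrMin, arrMip, cpfc, mpfc, pseudo)
  cd <- colData(x)
  cd[, colnames(libdf)] <- libdf
  cd$usable <- usable
  colData(x) <- cd
  metadata(x)$quantified <- TRUE
  validObject(x)
  x
}

#' @importFrom SummarizedExperiment assays<-
NULL

.assertQuantified <- function(x) {
  if (!isTRUE(metadata(x)$quantified))
    stop("run quantifyAllelic() first")
  invisible(x)
}
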