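#' Allele-specific expression class from input allelic read ratios
#'
#' Classifies a site's expression bias within an F1i-F1r group from the two
#' *input*-sample allelic read ratios on the requested axis (C57 ratio for the
#' strain axis, maternal ratio for the parent axis): `first_biased` when both
#' ratios exceed 0.6, `second_biased` when both are below 0.4, `balanced`
#' when both lie in `[0.4, 0.6]`, otherwise (including any undefined ratio)
#' `unclassified`. "First" is C57 on the strain axis and maternal on the
#' parent axis.
#'
#' @param arr_f1i,arr_f1r input allelic read ratios in the group's F1i and
#'   F1r samples (vectorized).
#' @return character vector in
#'   `{"first_biased", "second_biased", "balanced", "unclassified"}`.
#' @export
classifyAse <- function(arr_f1i, arr_f1r) {
  out <- rep("unclassified", length(arr_f1i))
  ok <- !is.na(arr_f1i) & !is.na(arr_f1r)
  out[ok & arr_f1i > 0.6 & arr_f1r > 0.6] <- "first_biased"
  out[ok & arr_f1i < 0.4 & arr_f1r < 0.4] <- "second_biased"
  out[ok & arr_f1i >= 0.4 & arr_f1i <= 0.6 &
        arr_f1r >= 0.4 & arr_f1r <= 0.6] <- "balanced"
  out
}

#' Methylation-minus-expression allelic delta
#'
#' The difference between a site's IP and input allelic read ratios on the
#' same axis, `ARR_ip - ARR_input`; negative values mean the allele favoured
#' in expression is *less* favoured in methylation.
#'
#' @param arr_ip,arr_input allelic read ratios (vectorized).
#' @return numeric in `[-1, 1]`; `NA` when either ratio is.
#' @export
methExprDelta <- function(arr_ip, arr_input) {
  arr_ip - arr_input
}

#' Bin imprinted-gene sites by maternal expression ratio
#'
#' Allelically detectable sites within imprinted genes are binned on
#' `ARR_mat,input`: `(0.6, 1]` strong maternal, `(0.5, 0.6]` mild maternal,
#' `[0.4, 0.5)` mild paternal, `[0, 0.4)` strong paternal. The printed
#' intervals omit the point 0.5; it is assigned to `mild_paternal` so the
#' bins partition `[0, 1]`.
#'
#' @param arr_mat_input maternal input allelic read ratio(s) in `[0, 1]`.
#' @return character vector in `{"strong_maternal", "mild_maternal",
#'   "mild_paternal", "strong_paternal"}`.
#' @export
binImprinted <- function(arr_mat_input) {
  if (any(arr_mat_input < 0 | arr_mat_input > 1, na.rm = TRUE))
    stop("allelic read ratios must lie in [0, 1]")
  unname(ifelse(arr_mat_input > 0.6, "strong_maternal",
                ifelse(arr_mat_input > 0.5, "mild_maternal",
                       ifelse(arr_mat_input >= 0.4, "mild_paternal",
                              "strong_paternal"))))
}

#' Fraction of sites with opposing methylation and expression bias
#'
#' Over pairs of (input ARR, IP ARR) on a common axis, the fraction whose
#' allelic directions oppose: `sign(ARR_ip - 0.5) != sign(ARR_input - 0.5)`.
#' Pairs in which either ratio is exactly 0.5 (no direction) or undefined are
#' excluded from the denominator.
#'
#' @param arr_input,arr_ip paired allelic read ratios.
#' @return proportion in `[0, 1]`; `NA` if no pair has a direction.
#' @export
opposingFraction <- function(arr_input, arr_ip) {
  ok <- !is.na(arr_input) & !is.na(arr_ip) & arr_input != 0.5 & arr_ip != 0.5
  if (!any(ok)) return(NA_real_)
  mean(sign(arr_ip[ok] - 0.5) != sign(arr_input[ok] - 0.5))
}

#' Link allelic methylation to allelic expression per group
#'
#' Per F1i-F1r group and allelically detectable site, computes the ASE class
#' on both axes from the input ratios, the methylation-minus-expression deltas
#' per sample, and (when an imprinted-gene list is supplied) the imprint bin
#' from the maternal input ratio.
#'
#' @param x a quantified [Asm6aExperiment-class].
#' @param imprinted_genes optional character vector of imprinted gene symbols.
#' @return data.frame with one row per detectable site x group.
#' @export
aseLinkTable <- function(x, imprinted_genes = NULL) {
  .assertQuantified(x)
  gp <- groupPairs(x)
  cov <- assay(x, "coverage")
  aci <- assay(x, "arr_c57_input"); acp <- assay(x, "arr_c57_ip")
  ami <- assay(x, "arr_mat_input"); amp <- assay(x, "arr_mat_ip")
  gene <- mcols(rowRanges(x))$gene
  res <- vector("list", nrow(gp))
  for (k in seq_len(nrow(gp))) {
    i <- gp$f1i_sample_id[k]; r <- gp$f1r_sample_id[k]
    sel <- which(cov[, i] != "undetectable" & cov[, r] != "undetectable")
    if (!length(sel)) next
    df <- data.frame(
      site_id = rownames(x)[sel], group_id = gp$group_id[k],
      ase_strain = classifyAse(aci[sel, i], aci[sel, r]),
      ase_parent = classifyAse(ami[sel, i], ami[sel, r]),
      delta_c57_f1i = methExprDelta(acp[sel, i], aci[sel, i]),
      delta_c57_f1r = methExprDelta(acp[sel, r], aci[sel, r]),
      delta_mat_f1i = methExprDelta(amp[sel, i], ami[sel, i]),
      delta_mat_f1r = methExprDelta(amp[sel, r], ami[sel, r]),
      row.names = NULL)
    if (!is.null(imprinted_genes)) {
      imp <- gene[sel] %in% imprinted_genes
      df$imprint_bin <- NA_character_
      df$imprint_bin[imp] <-
        binImprinted(rowMeans(cbind(ami[sel, i][imp], ami[sel, r][imp])))
    }
    res[[k]] <- df
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame()
  out
}
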