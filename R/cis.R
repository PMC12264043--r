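#' Transcript-strand SNP layout in the 100-nt flanks of m6A sites
#'
#' For every site, finds the SNPs with `1 <= |offset| <= window` nt from the
#' methylatable A and reports their signed positions on the *transcript*
#' strand (negative = upstream of the A; on `-` strand sites the genomic
#' offset is negated). Offset 0 is excluded — a SNP at the A itself defines a
#' strain-specific adenine site, handled by [flagStrainSpecificAdenines()].
#' The nearest position is the minimum |position|, ties broken toward the
#' upstream (negative) side.
#'
#' @param sites data.frame with `site_id`, `chrom`, `pos`, `strand`.
#' @param snps data.frame with `chrom`, `pos` (same assembly, 1-based).
#' @param window flank width in nt (default 100).
#' @return list with `positions` (data.frame `site_id`, `position`, sorted by
#'   |position| within site) and `nearest` (data.frame `site_id`,
#'   `nearest_position`, `NA` when the flanks hold no SNP).
#' @export
flankLayout <- function(sites, snps, window = 100L) {
  sgr <- GRanges(sites$chrom,
                 IRanges(pmax(1L, sites$pos - window), sites$pos + window))
  ngr <- GRanges(snps$chrom, IRanges(snps$pos, width = 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ngr, sgr))
  si <- S4Vectors::subjectHits(hits); qi <- S4Vectors::queryHits(hits)
  off <- snps$pos[qi] - sites$pos[si]
  keep <- off != 0L
  si <- si[keep]; off <- off[keep]
  off <- ifelse(sites$strand[si] == "-", -off, off)
  ord <- order(si, abs(off), off)
  positions <- data.frame(site_id = sites$site_id[si][ord],
                          position = off[ord], row.names = NULL)
  first <- !duplicated(positions$site_id)
  nearest <- data.frame(site_id = sites$site_id,
                        nearest_position = positions$position[first][
                          match(sites$site_id, positions$site_id[first])],
                        row.names = NULL)
  list(positions = positions, nearest = nearest)
}

#' Weighted SNP distribution score
#'
#' For the SNPs in a site's 200-nt window the score is
#' `S = sum(1/D_n) + sum(1/B_n)`, with `D_n = |position|` the distance in nt
#' and `B_n = ceiling(|position|/10)` the 10-nt bin index (the two nearest
#' bins on either side are numbered 1, the two farthest 10). Higher scores
#' mean denser SNPs closer to the site; moving any single SNP strictly closer
#' strictly increases `S`.
#'
#' @param positions signed transcript-strand SNP positions of one site
#'   (from [flankLayout()]); the empty layout scores 0.
#' @return non-negative numeric.
#' @examples
#' snpDistributionScore(c(-5, 95))  # (1/5 + 1/95) + (1/1 + 1/10)
#' @export
snpDistributionScore <- function(positions) {
  if (!length(positions)) return(0)
  d <- abs(positions)
  stopifnot(all(d >= 1), all(d <= 100))
  sum(1 / d) + sum(1 / ceiling(d / 10))
}

#' Per-position enrichment of nearest SNPs at seq-ASm6A sites
#'
#' Tests, for every flanking position `i` in `[-100,-1] U [1,100]`, whether
#' highly reproducible seq-ASm6A sites have their *nearest* SNP at `i` more
#' often than testable sites at large do. With `S_i` (seq-ASm6A sites whose
#' nearest SNP sits at `i`) and `T_i` (testable sites likewise), the null is
#' `S_i ~ Binomial(T_i, R)` with the baseline `R` the average of `S_i/T_i`
#' over covered positions; the one-sided upper-tail exact p-value is
#' `P(X >= S_i)`. Positions with `T_i = 0` are excluded from both the
#' baseline and the testing. Positions with `p < 0.05` are flagged as
#' candidate cis-regulatory loci.
#'
#' @param seq_site_ids union of highly reproducible seq-ASm6A site ids across
#'   groups (must be a subset of `testable_site_ids`).
#' @param testable_site_ids union of group-testable site ids.
#' @param nearest data.frame `site_id`, `nearest_position` from
#'   [flankLayout()].
#' @return data.frame with `position`, `S`, `T`, `p_value`, `candidate`;
#'   baseline `R` as attribute `"R"`.
#' @export
positionalEnrichment <- function(seq_site_ids, testable_site_ids, nearest) {
  if (!length(testable_site_ids)) stop("empty testable-site union")
  if (length(setdiff(seq_site_ids, testable_site_ids)))
    stop("seq-ASm6A sites must be a subset of the testable sites")
  np <- nearest[!is.na(nearest$nearest_position), ]
  posAll <- setdiff(seq(-100L, 100L), 0L)
  Tn <- table(factor(np$nearest_position[np$site_id %in% testable_site_ids],
                     levels = posAll))
  Sn <- table(factor(np$nearest_position[np$site_id %in% seq_site_ids],
                     levels = posAll))
  Tn <- as.integer(Tn); Sn <- as.integer(Sn)
  covered <- Tn > 0
  if (!any(covered)) stop("no flanking position is covered by a testable site")
  R <- mean(Sn[covered] / Tn[covered])
  p <- rep(NA_real_, length(posAll))
  p[covered] <- stats::pbinom(Sn[covered] - 1L, Tn[covered], R,
                              lower.tail = FALSE)
  out <- data.frame(position = posAll, S = Sn, T = Tn, p_value = p,
                    candidate = !is.na(p) & p < 0.05)
  out <- out[covered, , drop = FALSE]
  attr(out, "R") <- R
  rownames(out) <- NULL
  out
}

#' Rank motif 5-mers by occurrence frequency
#'
#' @param motifs character vector of 5-mers over all high-confidence sites in
#'   a tissue (both alleles' motifs may be supplied).
#' @param k how many top motifs to label (default 16); ties broken
#'   alphabetically.
#' @return character vector of the top-`k` motifs, most frequent first.
#' @export
rankMotifs <- function(motifs, k = 16L) {
  tab <- table(motifs)
  ord <- order(-as.integer(tab), names(tab))
  utils::head(names(tab)[ord], k)
}

#' Motif-pair allelic methylation matrix
#'
#' Sites whose two allelic motifs differ are grouped by the ordered pair
#' (C57 motif label, PWK motif label), where a label is the motif itself when
#' it is among the top-`k` ranked motifs and `"Other"` otherwise. Each cell
#' holds the mean `log2(cpFC)` of its sites (positive = the C57-sequence
#' allele is more methylated) and the site count. Diagonal cells can only be
#' populated by two distinct sequences both mapping to `"Other"`.
#'
#' @param motif_c57,motif_pwk allelic 5-mers per site.
#' @param cpfc per-site `log2(cpFC)` values (e.g. group-level).
#' @param ranked_motifs top motif list from [rankMotifs()].
#' @return list of two 17x17 matrices, `mean` (NA where empty) and `n`.
#' @export
motifPairMatrix <- function(motif_c57, motif_pwk, cpfc, ranked_motifs) {
  keep <- motif_c57 != motif_pwk & !is.na(cpfc)
  labs <- c(ranked_motifs, "Other")
  lab <- function(m) ifelse(m %in% ranked_motifs, m, "Other")
  r <- factor(lab(motif_c57[keep]), levels = labs)
  c_ <- factor(lab(motif_pwk[keep]), levels = labs)
  n <- tapply(cpfc[keep], list(r, c_), length)
  m <- tapply(cpfc[keep], list(r, c_), mean)
  n[is.na(n)] <- 0
  list(mean = m, n = n)
}

#' Position weight matrix from m6A motif 5-mers
#'
#' Estimates the methylation-consensus model from the motif sequences of all
#' high-confidence sites: per-column base frequencies with a pseudocount of 1
#' per base, and log2 odds against the uniform 0.25 background.
#'
#' @param motifs character vector of 5-mers.
#' @return list of class `"asm6aPwm"` with `prob` and `logodds`
#'   (4 base rows x 5 position columns).
#' @export
buildPwm <- function(motifs) {
  if (!length(motifs)) stop("at least one motif is required")
  if (any(nchar(motifs) != 5L)) stop("all motifs must be 5-mers")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(motifs))
  counts <- matrix(0, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  common <- intersect(rownames(cm), rownames(counts))
  counts[common, ] <- cm[common, ]
  counts <- counts + 1
  prob <- sweep(counts, 2, colSums(counts), "/")
  structure(list(prob = prob, logodds = log2(prob / 0.25)),
            class = "asm6aPwm")
}

#' @export
print.asm6aPwm <- function(x, ...) {
  cat("5-mer position weight matrix (base probabilities):\n")
  print(round(x$prob, 3))
  invisible(x)
}

#' PWM log-odds score of a 5-mer
#'
#' @param pwm an `"asm6aPwm"` from [buildPwm()].
#' @param motif 5-mer(s).
#' @return numeric score(s); the sum over positions of the base log2 odds.
#' @export
pwmScore <- function(pwm, motif) {
  vapply(motif, function(m) {
    b <- strsplit(m, "")[[1]]
    if (length(b) != 5L) stop("motifs must be 5-mers")
    ri <- match(b, rownames(pwm$logodds))
    if (anyNA(ri)) stop("motifs must be over the A/C/G/T alphabet")
    sum(pwm$logodds[cbind(ri, seq_len(5))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Motif variation effect of an allelic motif substitution
#'
#' Scores the C57 -> PWK motif substitution against the consensus model:
#' the PWM log-odds score of the PWK motif minus that of the C57 motif.
#' Positive values indicate a stronger match of the PWK motif with the
#' consensus, negative values a stronger match of the C57 motif. Swapping the
#' two motifs negates the score. Note the direction relative to methylation:
#' the better-matching allele tends to be the *more* methylated one, so
#' positive effects go with PWK-biased methylation, i.e. negative
#' `log2(cpFC)`.
#'
#' @param pwm an `"asm6aPwm"` from [buildPwm()].
#' @param motif_c57,motif_pwk allelic 5-mers (vectorized).
#' @return signed numeric score(s).
#' @export
motifVariationEffect <- function(pwm, motif_c57, motif_pwk) {
  pwmScore(pwm, motif_pwk) - pwmScore(pwm, motif_c57)
}
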