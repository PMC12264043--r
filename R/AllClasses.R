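#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assayNames rowRanges colData colData<-
NULL

.COUNT_ASSAYS <- c("inputC57", "inputPWK", "ipC57", "ipPWK")

#' Asm6aExperiment: allele-resolved m6A-seq counts for a reciprocal-cross cohort
#'
#' An `Asm6aExperiment` is a [SummarizedExperiment::RangedSummarizedExperiment]
#' holding the four allele-resolved read-count matrices of an m6A-seq cohort
#' (rows = single-base m6A sites, columns = paired input/IP samples):
#' assays `inputC57`, `inputPWK` (untreated input counts per allele) and
#' `ipC57`, `ipPWK` (IP counts per allele). Row ranges carry the site
#' annotation (1-based position of the methylatable A on the transcript
#' strand, gene, the two allelic 5-mer motifs, and the strain-specific-adenine
#' flag); column data carry sample metadata (`tissue`, `age`, `sex`, `cross`
#' in `{F1i, F1r}`, and the F1i-F1r `group_id` pairing).
#'
#' The cross label fixes the strain-to-parent orientation: in F1i hybrids
#' (PWK mother x C57 father) the maternal allele is PWK; in F1r hybrids
#' (C57 mother x PWK father) it is C57.
#'
#' @seealso [Asm6aExperiment()] for construction, [quantifyAllelic()] for the
#'   derived allelic levels and ratios, [callASm6A()] for ASm6A calls.
#' @export
setClass("Asm6aExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("Asm6aExperiment", function(object) {
  msg <- character()
  if (!all(.COUNT_ASSAYS %in% assayNames(object)))
    msg <- c(msg, paste("assays must include",
                        paste(.COUNT_ASSAYS, collapse = ", ")))
  for (a in intersect(.COUNT_ASSAYS, assayNames(object))) {
    m <- assay(object, a)
    if (any(m < 0, na.rm = TRUE))
      msg <- c(msg, paste0("assay '", a, "' contains negative counts"))
    if (any(m != round(m), na.rm = TRUE))
      msg <- c(msg, paste0("assay '", a, "' contains non-integer counts"))
  }
  cd <- colData(object)
  need <- c("tissue", "age", "sex", "cross", "group_id")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, paste("colData must have columns",
                        paste(need, collapse = ", ")))
  } else {
    if (!all(cd$cross %in% c("F1i", "F1r")))
      msg <- c(msg, "cross labels must be 'F1i' or 'F1r'")
    for (g in unique(cd$group_id)) {
      i <- which(cd$group_id == g)
      if (length(i) != 2L) {
        msg <- c(msg, paste0("group '", g, "' must pair exactly two samples"))
      } else {
        if (!setequal(cd$cross[i], c("F1i", "F1r")))
          msg <- c(msg, paste0("group '", g,
                               "' must pair one F1i and one F1r sample"))
        same <- vapply(c("tissue", "age", "sex"),
                       function(f) length(unique(cd[[f]][i])) == 1L,
                       logical(1))
        if (!all(same))
          msg <- c(msg, paste0("group '", g,
                               "' samples must share tissue, age and sex"))
      }
    }
  }
  rd <- mcols(rowRanges(object))
  if (!all(c("motif_c57", "motif_pwk", "is_strain_specific_A") %in%
           colnames(rd))) {
    msg <- c(msg, "rowRanges mcols must have motif_c57, motif_pwk, is_strain_specific_A")
  } else {
    if (any(nchar(rd$motif_c57) != 5L) || any(nchar(rd$motif_pwk) != 5L))
      msg <- c(msg, "allelic motifs must be 5-mers")
    centerA <- substr(rd$motif_c57, 3, 3) == "A" |
      substr(rd$motif_pwk, 3, 3) == "A"
    if (!all(centerA))
      msg <- c(msg, "at least one allelic motif must have A at the center")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Asm6aExperiment from site, sample and count tables
#'
#' Assembles the central container from plain data frames, e.g. as returned by
#' [readCountTable()], [readSiteTable()] and [readSampleTable()], or by
#' [simulateCohort()]. Counts are given in long format (one row per
#' site x sample) and are pivoted into the four count matrices; sites or
#' samples without any count row get zeros.
#'
#' @param counts data.frame with columns `site_id`, `sample_id`, `t_c57`,
#'   `t_pwk` (input counts per allele) and `p_c57`, `p_pwk` (IP counts).
#' @param sites data.frame with columns `site_id`, `chrom`, `pos` (1-based
#'   position of the methylatable A), `strand` (`+`/`-`, transcript strand),
#'   `gene`, `motif_c57`, `motif_pwk` and optionally `is_strain_specific_A`.
#' @param samples data.frame with columns `sample_id`, `tissue`, `age`, `sex`,
#'   `cross` (`F1i`/`F1r`) and `group_id` naming the F1i-F1r pairing.
#' @return an [Asm6aExperiment-class] object.
#' @examples
#' sim <- simulateCohort(simConfig(n_sites = 50, n_groups = 1, seed = 1))
#' ax <- Asm6aExperiment(sim$counts, sim$sites, sim$samples)
#' ax
#' @export
Asm6aExperiment <- function(counts, sites, samples) {
  counts <- as.data.frame(counts)
  sites <- as.data.frame(sites)
  samples <- as.data.frame(samples)
  stopifnot(all(c("site_id", "sample_id", "t_c57", "t_pwk", "p_c57", "p_pwk")
                %in% colnames(counts)))
  if (is.null(sites$is_strain_specific_A))
    sites$is_strain_specific_A <- FALSE
  if (is.null(sites$gene)) sites$gene <- ""
  sid <- as.character(sites$site_id)
  smp <- as.character(samples$sample_id)
  if (anyDuplicated(sid)) stop("duplicated site_id in 'sites'")
  if (anyDuplicated(smp)) stop("duplicated sample_id in 'samples'")
  bad <- setdiff(unique(counts$site_id), sid)
  if (length(bad))
    stop("count rows reference unknown site_id: ", paste(head(bad), collapse = ", "))
  pivot <- function(col) {
    m <- matrix(0L, nrow = length(sid), ncol = length(smp),
                dimnames = list(sid, smp))
    m[cbind(match(counts$site_id, sid), match(counts$sample_id, smp))] <-
      as.integer(counts[[col]])
    m
  }
  rr <- GRanges(seqnames = sites$chrom,
                ranges = IRanges(start = sites$pos, width = 1L),
                strand = sites$strand)
  names(rr) <- sid
  mcols(rr) <- DataFrame(gene = sites$gene,
                         motif_c57 = toupper(sites$motif_c57),
                         motif_pwk = toupper(sites$motif_pwk),
                         is_strain_specific_A = as.logical(sites$is_strain_specific_A))
  cd <- DataFrame(samples[match(smp, samples$sample_id), , drop = FALSE],
                  row.names = smp)
  se <- SummarizedExperiment(
    assays = list(inputC57 = pivot("t_c57"), inputPWK = pivot("t_pwk"),
                  ipC57 = pivot("p_c57"), ipPWK = pivot("p_pwk")),
    rowRanges = rr, colData = cd)
  new("Asm6aExperiment", se)
}

#' @describeIn Asm6aExperiment-class compact summary of sites, samples and
#'   groups; reports which derived assays are present.
#' @param object an `Asm6aExperiment`.
#' @export
setMethod("show", "Asm6aExperiment", function(object) {
  cd <- colData(object)
  cat("Asm6aExperiment with", nrow(object), "m6A sites x",
      ncol(object), "samples\n")
  cat("  groups:", length(unique(cd$group_id)),
      "F1i-F1r pairs; tissues:", paste(unique(cd$tissue), collapse = ", "), "\n")
  cat("  strain-specific adenine sites:",
      sum(isStrainSpecificA(object)), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (isTRUE(metadata(object)$quantified))
    cat("  allelic quantification: done (see assayNames)\n")
  invisible(NULL)
})

#' Accessors for Asm6aExperiment components
#'
#' `inputCounts()` and `ipCounts()` return one allele's count matrix;
#' `crossOf()` the per-sample cross labels; `maternalStrain()` the strain of
#' the maternal allele per sample (PWK for F1i, C57 for F1r); `groupPairs()`
#' the F1i-F1r pairing table; `isStrainSpecificA()` the per-site
#' strain-specific-adenine flags; `siteMotifs()` the allelic 5-mer motifs.
#'
#' @param x an [Asm6aExperiment-class].
#' @param allele `"c57"` or `"pwk"`.
#' @return matrices, vectors or a data.frame as described per function.
#' @name asm6a-accessors
NULL

#' @rdname asm6a-accessors
#' @export
inputCounts <- function(x, allele = c("c57", "pwk")) {
  allele <- match.arg(allele)
  assay(x, if (allele == "c57") "inputC57" else "inputPWK")
}

#' @rdname asm6a-accessors
#' @export
ipCounts <- function(x, allele = c("c57", "pwk")) {
  allele <- match.arg(allele)
  assay(x, if (allele == "c57") "ipC57" else "ipPWK")
}

#' @rdname asm6a-accessors
#' @export
crossOf <- function(x) {
  setNames(as.character(colData(x)$cross), colnames(x))
}

#' @rdname asm6a-accessors
#' @export
maternalStrain <- function(x) {
  cr <- crossOf(x)
  setNames(ifelse(cr == "F1i", "pwk", "c57"), names(cr))
}

#' @rdname asm6a-accessors
#' @export
groupPairs <- function(x) {
  cd <- as.data.frame(colData(x))
  cd$sample_id <- colnames(x)
  f1i <- cd[cd$cross == "F1i", c("group_id", "sample_id", "tissue", "age", "sex")]
  f1r <- cd[cd$cross == "F1r", c("group_id", "sample_id")]
  names(f1i)[2] <- "f1i_sample_id"
  names(f1r)[2] <- "f1r_sample_id"
  out <- merge(f1i, f1r, by = "group_id", sort = TRUE)
  out[, c("group_id", "f1i_sample_id", "f1r_sample_id", "tissue", "age", "sex")]
}

#' @rdname asm6a-accessors
#' @export
isStrainSpecificA <- function(x) {
  setNames(mcols(rowRanges(x))$is_strain_specific_A, rownames(x))
}

#' @rdname asm6a-accessors
#' @export
siteMotifs <- function(x) {
  rd <- mcols(rowRanges(x))
  data.frame(site_id = rownames(x), motif_c57 = rd$motif_c57,
             motif_pwk = rd$motif_pwk, row.names = NULL)
}
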