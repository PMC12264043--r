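#' Read a long-format allele-resolved count table
#'
#' Count tables are tab-separated with one row per site x sample and columns
#' `site_id`, `sample_id`, `t_c57`, `t_pwk`, `p_c57`, `p_pwk`: allele-resolved
#' read counts in the untreated input (`t_*`) and IP (`p_*`) samples.
#'
#' @param path path to a TSV file.
#' @return data.frame with the six columns above; counts as integers.
#' @export
readCountTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("site_id", "sample_id", "t_c57", "t_pwk", "p_c57", "p_pwk")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in need[3:6]) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad))
      stop("column '", col, "' must hold non-negative integers; offending row(s): ",
           paste(head(bad), collapse = ", "))
    df[[col]] <- as.integer(num)
  }
  df[, need]
}

#' Read a site annotation table
#'
#' Sites are tab-separated with columns `site_id`, `chrom`, `pos` (1-based
#' coordinate of the methylatable A), `strand` (transcript strand), `gene`,
#' `motif_c57`, `motif_pwk` (allelic 5-mers on the transcript strand, positions
#' -2..+2 around the A) and optionally `is_strain_specific_A`.
#'
#' @param path path to a TSV file.
#' @return validated data.frame.
#' @export
readSiteTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("site_id", "chrom", "pos", "strand", "motif_c57", "motif_pwk")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("site table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(nchar(df$motif_c57) != 5L) || any(nchar(df$motif_pwk) != 5L))
    stop("allelic motifs must be 5-mers")
  if (is.null(df$gene)) df$gene <- ""
  if (is.null(df$is_strain_specific_A)) df$is_strain_specific_A <- FALSE
  df$pos <- as.integer(df$pos)
  df$is_strain_specific_A <- as.logical(df$is_strain_specific_A)
  df
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `tissue`, `age`, `sex`,
#'   `cross` (`F1i`/`F1r`) and `group_id` (the F1i-F1r pairing).
#' @return validated data.frame.
#' @export
readSampleTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "tissue", "age", "sex", "cross", "group_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$cross %in% c("F1i", "F1r")))
    stop("cross labels must be 'F1i' or 'F1r'")
  df
}

#' Read a SNP table (TSV or VCF)
#'
#' High-confidence SNPs distinguishing the C57 and PWK genomes. Two formats
#' are accepted: a TSV with columns `chrom`, `pos` (1-based), `allele_c57`,
#' `allele_pwk`; or a VCF, of which only CHROM/POS/REF/ALT are consumed (REF
#' is taken as the C57 reference allele). Multi-allelic VCF rows are rejected,
#' mirroring the high-confidence single-alternate filter applied upstream.
#'
#' @param path path to the file; VCF is detected by extension `.vcf` or a
#'   leading `##fileformat` line.
#' @return data.frame with columns `chrom`, `pos`, `allele_c57`, `allele_pwk`.
#' @export
readSnpTable <- function(path) {
  first <- readLines(path, n = 1L)
  isVcf <- grepl("\\.vcf$", path, ignore.case = TRUE) ||
    startsWith(first, "##fileformat")
  if (isVcf) {
    fix <- vcfR::getFIX(vcfR::read.vcfR(path, verbose = FALSE))
    if (is.null(dim(fix)))
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    alt <- fix[, "ALT"]
    if (any(grepl(",", alt, fixed = TRUE)))
      stop("multi-allelic VCF rows are not accepted")
    df <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     allele_c57 = fix[, "REF"],
                     allele_pwk = alt,
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("chrom", "pos", "allele_c57", "allele_pwk")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
      stop("SNP table is missing column(s): ", paste(miss, collapse = ", "))
    df$pos <- as.integer(df$pos)
    df <- df[, need]
  }
  ok <- df$allele_c57 %in% c("A", "C", "G", "T") &
    df$allele_pwk %in% c("A", "C", "G", "T") &
    df$allele_c57 != df$allele_pwk
  if (!all(ok))
    stop("SNP alleles must be distinct single bases; offending row(s): ",
         paste(head(which(!ok)), collapse = ", "))
  df
}

#' Flag strain-specific adenine sites
#'
#' A methylatable A that itself coincides with a C57/PWK SNP exists in only one
#' strain; such sites are internal positive controls with a known allelic
#' direction. Sets `is_strain_specific_A` true exactly where `(chrom, pos)`
#' matches a SNP record; all other fields are untouched. Idempotent and
#' independent of row order.
#'
#' @param sites site data.frame (see [readSiteTable()]).
#' @param snps SNP data.frame (see [readSnpTable()]).
#' @return `sites` with the flag recomputed.
#' @export
flagStrainSpecificAdenines <- function(sites, snps) {
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  sites$is_strain_specific_A <-
    key(sites$chrom, sites$pos) %in% key(snps$chrom, snps$pos)
  sites
}

#' Orient one site's counts along the strain or parent axis
#'
#' The strain axis always orders counts (C57, PWK). The parent axis orders
#' them (maternal, paternal), which depends on the cross: F1i hybrids have a
#' PWK mother, F1r hybrids a C57 mother. Applying the parent orientation twice
#' with flipped cross labels restores the strain order.
#'
#' @param t_c57,t_pwk,p_c57,p_pwk counts (vectors allowed).
#' @param cross `"F1i"` or `"F1r"` (recycled).
#' @param axis `"strain"` or `"parent"`.
#' @return list with elements `t_first`, `t_second`, `p_first`, `p_second`.
#' @export
orientCounts <- function(t_c57, t_pwk, p_c57, p_pwk, cross,
                         axis = c("strain", "parent")) {
  axis <- match.arg(axis)
  if (!all(cross %in% c("F1i", "F1r")))
    stop("unknown cross label: ", paste(setdiff(cross, c("F1i", "F1r")), collapse = ", "))
  if (axis == "strain")
    return(list(t_first = t_c57, t_second = t_pwk,
                p_first = p_c57, p_second = p_pwk))
  matIsC57 <- cross == "F1r"
  list(t_first  = ifelse(matIsC57, t_c57, t_pwk),
       t_second = ifelse(matIsC57, t_pwk, t_c57),
       p_first  = ifelse(matIsC57, p_c57, p_pwk),
       p_second = ifelse(matIsC57, p_pwk, p_c57))
}

#' Write / export results
#'
#' `writeResultsTable()` writes any results data.frame (e.g. from
#' [callASm6A()]) as TSV. `exportCallsBed()` exports ASm6A calls as BED6:
#' internal 1-based fully-closed coordinates are converted to BED's 0-based
#' half-open convention; the score column is the group-level |log2(cpFC)|
#' x 100, capped at 1000.
#'
#' @param results data.frame of results.
#' @param path output path.
#' @export
writeResultsTable <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @param calls data.frame from [callASm6A()]; rows with `klass == "none"`
#'   are dropped.
#' @param x the [Asm6aExperiment-class] the calls came from (for coordinates).
#' @export
exportCallsBed <- function(calls, x, path) {
  calls <- calls[calls$klass != "none", , drop = FALSE]
  rr <- rowRanges(x)[calls$site_id]
  gr <- GRanges(seqnames = GenomeInfoDb::seqnames(rr), ranges = IRanges::ranges(rr),
                strand = BiocGenerics::strand(rr))
  mcols(gr)$name <- paste(calls$site_id, calls$group_id, calls$klass, sep = "|")
  mcols(gr)$score <- round(pmin(abs(calls$group_log2_cpfc) * 100, 1000))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
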