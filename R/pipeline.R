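#' Run the full ASm6A pipeline from on-disk inputs
#'
#' Ties the stages together: read and validate inputs, flag strain-specific
#' adenines, quantify allelic levels and ratios, call and classify ASm6A per
#' F1i-F1r group, run the cis-regulatory analyses (when SNPs are supplied),
#' link methylation to expression, and write flat TSV outputs plus a JSON
#' manifest and a human-readable summary. Each stage failure aborts with the
#' stage name; partial outputs are retained next to a `FAILED` marker file.
#'
#' @param config a named list, or path to a YAML file, with elements:
#'   `counts`, `sites`, `samples` (input paths, required), `snps` (path,
#'   optional), `imprinted_genes` (path to a one-symbol-per-line file,
#'   optional), `outdir` (required), and optional `cutoff` (default 0.6),
#'   `p_threshold` (0.05), `fdr_level` (0.1), `flank_window` (100),
#'   `top_k_motifs` (16). Defaults equal the method's published constants.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(cutoff = 0.6, p_threshold = 0.05, fdr_level = 0.1,
                   flank_window = 100L, top_k_motifs = 16L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("counts", "sites", "samples", "outdir"))
    if (is.null(config[[nm]])) stop("config is missing '", nm, "'")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  failed <- file.path(outdir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste(name, conditionMessage(e)), failed)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  rows <- list()

  x <- stage("read", {
    counts <- readCountTable(config$counts)
    sites <- readSiteTable(config$sites)
    samples <- readSampleTable(config$samples)
    if (!is.null(config$snps)) {
      snps <- readSnpTable(config$snps)
      sites <- flagStrainSpecificAdenines(sites, snps)
    } else snps <- NULL
    rows$counts <- nrow(counts)
    ax <- Asm6aExperiment(counts, sites, samples)
    attr(ax, "snps") <- snps
    ax
  })
  snps <- attr(x, "snps")

  x <- stage("quantify", quantifyAllelic(x))
  lv <- stage("quantify", {
    long <- data.frame(
      site_id = rep(rownames(x), ncol(x)),
      sample_id = rep(colnames(x), each = nrow(x)),
      coverage = as.vector(assay(x, "coverage")),
      L_c57 = as.vector(assay(x, "L_c57")),
      L_pwk = as.vector(assay(x, "L_pwk")),
      arr_c57_input = as.vector(assay(x, "arr_c57_input")),
      arr_c57_ip = as.vector(assay(x, "arr_c57_ip")),
      arr_mat_input = as.vector(assay(x, "arr_mat_input")),
      arr_mat_ip = as.vector(assay(x, "arr_mat_ip")),
      log2_cpfc = as.vector(assay(x, "log2_cpfc")),
      log2_mpfc = as.vector(assay(x, "log2_mpfc")))
    writeResultsTable(long, file.path(outdir, "levels.tsv"))
    long
  })
  rows$levels <- nrow(lv)

  calls <- stage("call", {
    cl <- callASm6A(x, cutoff = config$cutoff,
                    p_threshold = config$p_threshold,
                    fdr_level = config$fdr_level)
    writeResultsTable(cl, file.path(outdir, "calls.tsv"))
    if (any(cl$klass != "none"))
      exportCallsBed(cl, x, file.path(outdir, "calls.bed"))
    cl
  })
  rows$calls <- nrow(calls)

  if (!is.null(snps)) {
    stage("cis", {
      sites <- as.data.frame(rowRanges(x))
      sites <- data.frame(site_id = rownames(x), chrom = sites$seqnames,
                          pos = sites$start, strand = sites$strand)
      lay <- flankLayout(sites, snps, window = config$flank_window)
      writeResultsTable(lay$nearest, file.path(outdir, "nearest_snp.tsv"))
      cov <- assay(x, "coverage")
      gp <- groupPairs(x)
      testable <- unique(unlist(lapply(seq_len(nrow(gp)), function(k)
        groupTestable(setNames(cov[, gp$f1i_sample_id[k]], rownames(x)),
                      setNames(cov[, gp$f1r_sample_id[k]], rownames(x))))))
      seqIds <- unique(calls$site_id[calls$highly_reproducible &
                                       calls$klass %in% c("C57_seq", "PWK_seq")])
      if (length(seqIds) && length(testable)) {
        enr <- positionalEnrichment(seqIds, testable, lay$nearest)
        enr$baseline_R <- attr(enr, "R")
        writeResultsTable(enr, file.path(outdir, "positional_enrichment.tsv"))
      }
      mot <- siteMotifs(x)
      pwm <- buildPwm(mot$motif_c57)
      writeResultsTable(as.data.frame(t(pwm$prob)), file.path(outdir, "pwm.tsv"))
      varIdx <- mot$motif_c57 != mot$motif_pwk
      if (any(varIdx)) {
        grpC <- tapply(calls$group_log2_cpfc, calls$site_id, mean, na.rm = TRUE)
        ranked <- rankMotifs(mot$motif_c57, config$top_k_motifs)
        mp <- motifPairMatrix(mot$motif_c57[varIdx], mot$motif_pwk[varIdx],
                              as.numeric(grpC[mot$site_id[varIdx]]), ranked)
        writeResultsTable(cbind(motif_c57 = rownames(mp$mean),
                                as.data.frame(mp$mean)),
                          file.path(outdir, "motif_pair_matrix.tsv"))
      }
      NULL
    })
  }

  ase <- stage("ase", {
    genes <- if (!is.null(config$imprinted_genes))
      readLines(config$imprinted_genes) else NULL
    tab <- aseLinkTable(x, imprinted_genes = genes)
    writeResultsTable(tab, file.path(outdir, "ase.tsv"))
    tab
  })
  rows$ase <- nrow(ase)

  manifest <- stage("report", {
    called <- calls[calls$klass != "none", ]
    opp <- opposingFraction(as.vector(assay(x, "arr_c57_input")),
                            as.vector(assay(x, "arr_c57_ip")))
    man <- list(
      package_version = as.character(utils::packageVersion("asm6a")),
      config = config[order(names(config))],
      config_md5 = .md5Of(config[sort(setdiff(names(config), "outdir"))]),
      n_sites = nrow(x), n_samples = ncol(x),
      rows_per_stage = rows,
      class_counts = as.list(table(called$klass)),
      highly_reproducible_fraction =
        if (nrow(called)) mean(called$highly_reproducible) else NA,
      opposing_direction_fraction = opp)
    jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summaryLines <- c(
      sprintf("ASm6A pipeline summary (%d sites x %d samples)",
              nrow(x), ncol(x)),
      sprintf("  calls by class: %s",
              paste(names(table(called$klass)), table(called$klass),
                    sep = "=", collapse = ", ")),
      sprintf("  highly reproducible fraction: %s",
              format(man$highly_reproducible_fraction, digits = 3)),
      sprintf("  opposing methylation/expression direction fraction: %s",
              format(opp, digits = 3)))
    writeLines(summaryLines, file.path(outdir, "summary.txt"))
    man
  })
  invisible(manifest)
}

# deterministic md5 of an R object via its deparsed representation
.md5Of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(obj), f)
  unname(tools::md5sum(f))
}
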