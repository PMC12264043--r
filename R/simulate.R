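#' Configuration for the reciprocal-cross cohort simulator
#'
#' Builds the parameter list consumed by [simulateCohort()]. Defaults emulate
#' the statistical structure the analysis assumes for an early-postnatal
#' mouse-brain m6A-seq cohort: per-site allele-resolved depths around 100
#' reads with negative-binomial site-to-site variation, baseline input
#' allelic ratios concentrated near 0.5 (Beta(40, 40), sd about 0.06), a
#' minority of sites carrying sequence- or parent-of-origin-dependent effects,
#' SNPs scattered over the 100-nt flanks at about two per site (PWK and C57
#' are highly divergent strains), and a small fraction of strain-specific
#' adenine sites.
#'
#' Methylation effects act on the IP-allele probability through a log-odds
#' shift of the *realized* input allelic ratio, the simplest generative model
#' that exactly matches the calling module's binomial null when the shift is
#' zero; effect magnitudes are in log2 units so a planted effect of `b` yields
#' an expected `log2(cpFC)` near `b`.
#'
#' @param n_sites,n_groups number of m6A sites and F1i-F1r groups.
#' @param tissues tissue labels cycled over groups (default one tissue).
#' @param depth_input,depth_ip mean per-site allele-resolved read depths.
#' @param depth_dispersion negative-binomial size for depth variation;
#'   `Inf` fixes every depth at its mean.
#' @param baseline_arr_shape Beta(shape, shape) for baseline input ratios.
#' @param frac_seq_meth,seq_meth_effect fraction of sites with a
#'   sequence-dependent methylation effect and its |log2| magnitude
#'   (sign uniform, applied to the C57 allele).
#' @param frac_parent_meth,parent_meth_effect likewise for parent-of-origin
#'   effects (applied to the maternal allele, so the affected strain flips
#'   between F1i and F1r).
#' @param frac_seq_expr,seq_expr_effect fraction of sites with a
#'   sequence-dependent *expression* effect and its |log2-odds| magnitude.
#' @param frac_coupled,opposing_prob fraction of sites carrying both an
#'   expression and a methylation effect; the methylation effect opposes the
#'   expression direction with probability `opposing_prob` (default 0.7, the
#'   opposing-direction structure of real cohorts).
#' @param frac_strain_A fraction of strain-specific adenine sites (SNP at the
#'   methylatable A; the non-A allele has zero true IP enrichment).
#' @param snp_rate Poisson mean of background SNPs per 200-nt flank.
#' @param motif_snp_prob probability that a site carries one additional SNP
#'   at a motif position (-2, -1, +1, +2).
#' @param pwm_coupled,pwm_effect_scale,pwm_link_k when `pwm_coupled = TRUE`,
#'   motif-SNP sites get a methylation effect
#'   `scale * (2 * plogis(k * (score_c57 - score_pwk)) - 1)` from the
#'   generator's own motif PWM: the allele matching the consensus better is
#'   the more methylated one.
#' @param seed integer seed; all randomness flows from one stream, making the
#'   run bit-reproducible.
#' @return a validated list of class `"simConfig"`.
#' @export
simConfig <- function(n_sites = 2000L, n_groups = 3L, tissues = "cerebrum",
                      depth_input = 100, depth_ip = 100,
                      depth_dispersion = 20,
                      baseline_arr_shape = 40,
                      frac_seq_meth = 0, seq_meth_effect = 1.5,
                      frac_parent_meth = 0, parent_meth_effect = 1.5,
                      frac_seq_expr = 0, seq_expr_effect = 1.0,
                      frac_coupled = 0, opposing_prob = 0.7,
                      frac_strain_A = 0.02,
                      snp_rate = 2, motif_snp_prob = 0,
                      pwm_coupled = FALSE, pwm_effect_scale = 2,
                      pwm_link_k = 0.5,
                      seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(frac_seq_meth, frac_parent_meth, frac_seq_expr, frac_coupled,
          frac_strain_A)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("effect-class fractions must lie in [0,1] and sum to at most 1")
  if (opposing_prob < 0 || opposing_prob > 1)
    stop("opposing_prob must lie in [0,1]")
  if (n_sites < 1 || n_groups < 1) stop("n_sites and n_groups must be >= 1")
  if (depth_input <= 0 || depth_ip <= 0) stop("depths must be positive")
  structure(cfg, class = "simConfig")
}

# DRACH-flavoured sampling distribution for the central 5-mer
.genPwmProb <- function() {
  m <- matrix(c(0.30, 0.05, 0.40, 0.25,   # -2: D = G/A/T
                0.35, 0.03, 0.60, 0.02,   # -1: R = A/G
                1.00, 0.00, 0.00, 0.00,   #  0: A
                0.05, 0.85, 0.05, 0.05,   # +1: C
                0.30, 0.25, 0.05, 0.40),  # +2: H = A/C/T
              nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  m
}

#' Simulate a reciprocal-cross allele-specific m6A cohort with ground truth
#'
#' Generates the full input set of the pipeline — site annotations, SNPs,
#' long-format counts, sample metadata, group pairing — plus the planted
#' truth per site. Per sample and site, input allele counts are binomial in
#' the (possibly expression-shifted) true allelic ratio; IP allele counts are
#' binomial in the realized input ratio shifted on the log-odds scale by the
#' site's total methylation effect, oriented by strain for sequence effects
#' and by parental origin (flipping strain between F1i and F1r) for
#' parent-of-origin effects. Strain-specific adenine sites place all IP reads
#' on the A-carrying allele.
#'
#' @param config a [simConfig()].
#' @return list with `sites`, `snps`, `counts`, `samples`, `groups`, `truth`
#'   data.frames and the `config`.
#' @examples
#' sim <- simulateCohort(simConfig(n_sites = 100, n_groups = 1, seed = 42))
#' head(sim$truth)
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  n <- config$n_sites
  bases <- c("A", "C", "G", "T")

  ## ---- sites, motifs, SNPs -------------------------------------------------
  site_id <- sprintf("site_%05d", seq_len(n))
  pos <- 1000L + (seq_len(n) - 1L) * 1000L
  strand <- rep(c("+", "-"), length.out = n)
  gen <- .genPwmProb()
  motif_c57 <- apply(
    vapply(1:5, function(j) sample(bases, n, TRUE, prob = gen[, j]),
           character(n)),
    1, paste0, collapse = "")

  cls <- sample(c("seq_meth", "parent_meth", "seq_expr", "coupled",
                  "strain_specific_A", "null"),
                n, TRUE,
                prob = c(config$frac_seq_meth, config$frac_parent_meth,
                         config$frac_seq_expr, config$frac_coupled,
                         config$frac_strain_A,
                         1 - config$frac_seq_meth - config$frac_parent_meth -
                           config$frac_seq_expr - config$frac_coupled -
                           config$frac_strain_A))

  ## SNP layout per site: background + optional motif SNP + centre SNP for
  ## strain-specific adenines. Flanks never overlap (1-kb site spacing).
  nBg <- stats::rpois(n, config$snp_rate)
  flank <- setdiff(-100:100, 0L)
  snpPos <- lapply(seq_len(n), function(i) {
    p <- if (nBg[i] > 0) sample(flank, min(nBg[i], length(flank))) else integer(0)
    if (stats::runif(1) < config$motif_snp_prob) {
      cand <- setdiff(c(-2L, -1L, 1L, 2L), p)
      if (length(cand)) p <- c(p, if (length(cand) == 1L) cand else sample(cand, 1))
    }
    sort(p)
  })
  isA <- cls == "strain_specific_A"
  aStrain <- ifelse(stats::runif(n) < 0.5, "c57", "pwk")

  motif_pwk <- motif_c57
  for (i in seq_len(n)) {
    mp <- intersect(snpPos[[i]], c(-2L, -1L, 1L, 2L))
    for (q in mp) {
      j <- q + 3L
      old <- substr(motif_c57[i], j, j)
      substr(motif_pwk[i], j, j) <- sample(setdiff(bases, old), 1)
    }
    if (isA[i]) {
      if (aStrain[i] == "c57") {
        substr(motif_pwk[i], 3, 3) <- sample(c("C", "G", "T"), 1)
      } else {
        substr(motif_c57[i], 3, 3) <- sample(c("C", "G", "T"), 1)
        substr(motif_pwk[i], 3, 3) <- "A"
      }
    }
  }

  sites <- data.frame(site_id = site_id, chrom = "chr1", pos = pos,
                      strand = strand, gene = paste0("gene_", ceiling(seq_len(n) / 5)),
                      motif_c57 = motif_c57, motif_pwk = motif_pwk,
                      is_strain_specific_A = isA)

  snps <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- snpPos[[i]]
    if (isA[i]) p <- c(p, 0L)
    if (!length(p)) return(NULL)
    gOff <- if (strand[i] == "+") p else -p
    inMotif <- p >= -2L & p <= 2L
    j <- p + 3L
    a1 <- ifelse(inMotif, substring(motif_c57[i], j, j), NA)
    a2 <- ifelse(inMotif, substring(motif_pwk[i], j, j), NA)
    for (u in which(!inMotif | a1 == a2)) {
      pair <- sample(bases, 2)
      a1[u] <- pair[1]; a2[u] <- pair[2]
    }
    data.frame(chrom = "chr1", pos = pos[i] + gOff,
               allele_c57 = a1, allele_pwk = a2)
  }))
  if (is.null(snps))
    snps <- data.frame(chrom = character(), pos = integer(),
                       allele_c57 = character(), allele_pwk = character())

  ## ---- planted effects -----------------------------------------------------
  sgn <- function(k) sample(c(-1, 1), k, TRUE)
  beta_seq <- numeric(n)
  beta_seq[cls == "seq_meth"] <- config$seq_meth_effect * sgn(sum(cls == "seq_meth"))
  beta_parent <- numeric(n)
  beta_parent[cls == "parent_meth"] <-
    config$parent_meth_effect * sgn(sum(cls == "parent_meth"))
  e_expr <- numeric(n)
  hasExpr <- cls %in% c("seq_expr", "coupled")
  e_expr[hasExpr] <- config$seq_expr_effect * sgn(sum(hasExpr))
  cpl <- which(cls == "coupled")
  if (length(cpl)) {
    opp <- stats::runif(length(cpl)) < config$opposing_prob
    beta_seq[cpl] <- config$seq_meth_effect *
      ifelse(opp, -sign(e_expr[cpl]), sign(e_expr[cpl]))
  }
  if (config$pwm_coupled) {
    pwm <- buildPwm(motif_c57)
    hasMotifSnp <- motif_c57 != motif_pwk & !isA
    delta <- pwmScore(pwm, motif_c57[hasMotifSnp]) -
      pwmScore(pwm, motif_pwk[hasMotifSnp])
    beta_seq[hasMotifSnp] <- config$pwm_effect_scale *
      (2 * stats::plogis(config$pwm_link_k * delta) - 1)
    cls[hasMotifSnp & cls == "null"] <- "seq_meth"
  }
  true_arr <- stats::rbeta(n, config$baseline_arr_shape, config$baseline_arr_shape)
  arr_expr <- stats::plogis(stats::qlogis(true_arr) + log(2) * e_expr)

  ## ---- samples and groups --------------------------------------------------
  g <- seq_len(config$n_groups)
  tissue <- rep(config$tissues, length.out = config$n_groups)
  age <- rep(c("P0", "P7"), length.out = config$n_groups)
  sex <- rep(c("male", "male", "female", "female"), length.out = config$n_groups)
  samples <- data.frame(
    sample_id = as.vector(rbind(sprintf("g%02d_F1i", g), sprintf("g%02d_F1r", g))),
    tissue = rep(tissue, each = 2), age = rep(age, each = 2),
    sex = rep(sex, each = 2), cross = rep(c("F1i", "F1r"), config$n_groups),
    group_id = rep(sprintf("g%02d", g), each = 2))
  groups <- data.frame(group_id = sprintf("g%02d", g),
                       f1i_sample_id = sprintf("g%02d_F1i", g),
                       f1r_sample_id = sprintf("g%02d_F1r", g),
                       tissue = tissue, age = age, sex = sex)

  ## ---- counts --------------------------------------------------------------
  rdepth <- function(mu) {
    if (is.infinite(config$depth_dispersion)) rep(round(mu), n)
    else stats::rnbinom(n, mu = mu, size = config$depth_dispersion)
  }
  counts <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    matIsC57 <- samples$cross[s] == "F1r"
    nt <- rdepth(config$depth_input)
    np <- rdepth(config$depth_ip)
    t_c57 <- stats::rbinom(n, nt, arr_expr)
    t_pwk <- nt - t_c57
    arrObs <- ifelse(nt > 0, t_c57 / nt, arr_expr)
    arrObs <- pmin(pmax(arrObs, 0.25 / pmax(nt, 1)), 1 - 0.25 / pmax(nt, 1))
    beta <- beta_seq + beta_parent * (if (matIsC57) 1 else -1)
    ipP <- stats::plogis(stats::qlogis(arrObs) + log(2) * beta)
    p_c57 <- stats::rbinom(n, np, ipP)
    p_c57[isA] <- ifelse(aStrain[isA] == "c57", np[isA], 0L)
    p_pwk <- np - p_c57
    counts[[s]] <- data.frame(site_id = site_id,
                              sample_id = samples$sample_id[s],
                              t_c57 = t_c57, t_pwk = t_pwk,
                              p_c57 = p_c57, p_pwk = p_pwk)
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL

  truth <- data.frame(
    site_id = site_id, effect_class = cls,
    beta_seq = beta_seq, beta_parent = beta_parent, e_expr = e_expr,
    true_arr = true_arr, a_strain = ifelse(isA, aStrain, NA_character_),
    motif_c57 = motif_c57, motif_pwk = motif_pwk,
    n_flank_snps = vapply(snpPos, length, integer(1)),
    snp_positions = vapply(snpPos, paste, character(1), collapse = ","))

  list(sites = sites, snps = snps, counts = counts, samples = samples,
       groups = groups, truth = truth, config = config)
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits exactly the on-disk input formats of the package readers
#' (`counts.tsv`, `sites.tsv`, `samples.tsv`, `snps.tsv`) plus `truth.tsv`.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("counts", "sites", "samples", "snps", "truth"))
    utils::write.table(sim[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Confront ASm6A calls with the planted simulation truth
#'
#' Summarizes recovery of the planted effects: per effect axis, the fraction
#' of planted sites recovered as highly reproducible calls of the matching
#' class (recall), the fraction of call rows sitting on sites with a true
#' effect of that axis (precision; strain-specific adenine and coupled sites
#' count as true sequence effects), the direction accuracy of the recovered
#' calls, and for parent effects the class-axis accuracy (fraction of ASm6A
#' calls at planted parent sites classified as Mat/Pat rather than seq).
#'
#' @param calls data.frame from [callASm6A()].
#' @param truth the `truth` component of [simulateCohort()].
#' @return one-row data.frame of summary statistics.
#' @export
truthConfusion <- function(calls, truth) {
  if (!length(intersect(calls$site_id, truth$site_id)))
    stop("calls and truth share no site ids")
  seqTrue <- truth$site_id[truth$effect_class %in% c("seq_meth", "coupled")]
  seqLike <- truth$site_id[truth$effect_class %in%
                             c("seq_meth", "coupled", "strain_specific_A")]
  parTrue <- truth$site_id[truth$effect_class == "parent_meth"]
  hr <- calls[calls$highly_reproducible &
                calls$klass %in% c("C57_seq", "PWK_seq"), ]
  hrPar <- calls[calls$highly_reproducible &
                   calls$klass %in% c("Mat_parent", "Pat_parent"), ]
  betaOf <- function(ids, col) truth[[col]][match(ids, truth$site_id)]
  dirSeq <- {
    rows <- hr[hr$site_id %in% seqTrue, ]
    if (nrow(rows))
      mean((rows$klass == "C57_seq") == (betaOf(rows$site_id, "beta_seq") > 0))
    else NA_real_
  }
  dirPar <- {
    rows <- hrPar[hrPar$site_id %in% parTrue, ]
    if (nrow(rows))
      mean((rows$klass == "Mat_parent") ==
             (betaOf(rows$site_id, "beta_parent") > 0))
    else NA_real_
  }
  called <- calls[calls$klass != "none", ]
  axisRows <- called[called$site_id %in% parTrue, ]
  data.frame(
    n_seq_true = length(seqTrue),
    seq_recall = if (length(seqTrue))
      mean(seqTrue %in% hr$site_id) else NA_real_,
    seq_precision = if (nrow(hr))
      mean(hr$site_id %in% seqLike) else NA_real_,
    seq_direction_accuracy = dirSeq,
    n_parent_true = length(parTrue),
    parent_recall = if (length(parTrue))
      mean(parTrue %in% hrPar$site_id) else NA_real_,
    parent_precision = if (nrow(hrPar))
      mean(hrPar$site_id %in% parTrue) else NA_real_,
    parent_direction_accuracy = dirPar,
    parent_axis_accuracy = if (nrow(axisRows))
      mean(axisRows$klass %in% c("Mat_parent", "Pat_parent")) else NA_real_,
    n_false_calls = sum(!(called$site_id %in%
                            c(seqLike, parTrue))))
}
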