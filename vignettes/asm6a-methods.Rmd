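---
title: "Methods: allele-specific m6A inference in reciprocal-cross hybrids"
author: "asm6a"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific m6A inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asm6a)
```

## The inference problem

An m6A-seq experiment pairs an untreated input library (expression) with an
immunoprecipitated library (methylation). In an F1 hybrid of two divergent
strains, reads overlapping transcribed SNPs are assignable to one allele, so
each site contributes four counts per sample pair: input and IP counts for
the C57 and PWK alleles. The package infers, per site and per F1i-F1r group,
whether methylation is allelically imbalanced, and whether the imbalance
follows the *sequence* (same strain favoured in both crosses) or the
*parental origin* (same parent favoured, hence opposite strains, because the
maternal strain flips between the initial cross F1i, PWK mother, and the
reciprocal cross F1r, C57 mother).

## Model and assumptions

**Allelic levels.** The level of allele $j$ at site $i$ is
$L_{ij} = \log\!\big((p_{ij}/t_{ij}) / (P_j/T_j)\big)$, the log of the
library-normalized IP/input enrichment. Natural log is used for the stored
levels; every decision rule operates on explicit log2 ratios, so the base of
$L$ affects no call. Library sizes $T_j, P_j$ are the totals of
allele-resolved reads over the sites in the supplied count table —
the visible universe of sites — as the full per-allele totals of the
original alignments are not recoverable from count tables. Strain-specific
adenine sites are excluded from these totals because their IP reads are
removed upstream when neighbouring sites are counted.

**Imbalance metrics.** Allelic imbalance is quantified on the linear
enrichment scale, $\log_2(\mathrm{cpFC}) = \log_2(E_{c57}/E_{pwk})$ with
$E_j = (p_j/t_j)/(P_j/T_j)$, equal to the difference of log2 enrichments.
A formulation that divides the (signed, log-scale) $L$ values themselves is
ill-defined whenever a level is zero or negative; the linear-scale reading
is antisymmetric, zero-centred, and is the quantity every downstream rule
(sign = direction, magnitude thresholded at 0.6) actually uses.
$\log_2(\mathrm{mpFC})$ is its parent-oriented relabeling:
$-\log_2(\mathrm{cpFC})$ in F1i samples, $+\log_2(\mathrm{cpFC})$ in F1r.

**Coverage filters.** Allelically detectable: $t_{c57} \ge 5$,
$t_{pwk} \ge 5$, $t_{c57}+t_{pwk} \ge 20$, $p_{c57}+p_{pwk} \ge 20$;
testable: detectable and $t_{c57}+t_{pwk} \ge 30$. The per-allele input
minimums guarantee a strictly interior input allelic ratio, which the test
below requires. Group-level analysis intersects the testable sets of the
two samples of an F1i-F1r pair.

**The test.** Under no allelic methylation imbalance, an IP read is drawn
from the C57 allele with the probability observed in the paired input:
$R_{c57,ip} \sim \mathrm{Binomial}(n = R_{c57,ip}+R_{pwk,ip},
p = \mathrm{ARR}_{c57,input})$. The p-value is exact and two-sided by the
minimum-likelihood convention (the total probability of outcomes no more
likely than the observed one), with the same $1+10^{-7}$ relative tolerance
for floating-point ties as `stats::binom.test`; the PWK-oriented test with
the complementary ratio is its exact mirror and is therefore not computed
twice. Benjamini-Hochberg adjustment controls the FDR at 10% within each
sample's tested set; the package adjusts per sample (the criteria are
evaluated per sample before the cross-sample intersection). Sidedness is
two-sided because bias in either direction is called.

**Calling and classification.** A site is a candidate in a sample iff
$p < 0.05$, $q < 0.1$ and $|\log_2(\mathrm{cpFC})| > 0.6$, all strict;
candidates replicated in both samples of a group are ASm6A and classified by
their sign pair: $(+,+)$ C57-seq, $(-,-)$ PWK-seq, $(-,+)$ Mat-parent,
$(+,-)$ Pat-parent. The 0.6 constant is the positive-control-calibrated
default; `calibrateCutoff()` recomputes it when strain-specific adenine
controls are supplied, via the median spread of positive and negative
$\log_2(\mathrm{cpFC})$ values per cross ($d_i, d_r$), the Euclidean group
spread $D$, the per-sample spread $C = \sqrt{D^2/2}$ and the bidirectional
cutoff $C/2$, averaged over the C57- and PWK-specific control classes.
The high-reproducibility filter additionally demands detectability in at
least four same-tissue samples and directional agreement of the group-level
metric with both per-cross tissue-level aggregates (cpFC for seq classes,
mpFC for parent classes).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 0.6 | minimal $|\log_2(\mathrm{cpFC})|$ (log2 units), calibrated from positive controls |
| `p_threshold` | 0.05 | raw binomial p-value bound (strict) |
| `fdr_level` | 0.1 | BH FDR level within the tested set (strict) |
| `flank_window` | 100 nt | cis-regulatory window on each side of the site |
| `top_k_motifs` | 16 | motif labels kept before pooling into "Other" |

## Numerical choices and degenerate inputs

* A per-allele IP count of zero makes one enrichment zero; both IP counts
  then receive +0.5 (flagged `pseudocounted`) so ratio metrics stay finite
  and antisymmetric without perturbing well-covered sites. Raw levels keep
  the $-\infty$ sentinel.
* Samples with any zero allele-specific library size are marked unusable and
  excluded rather than patched.
* Nearest-SNP ties at equal distance resolve to the upstream (negative)
  side; a SNP at offset 0 is the strain-specific-adenine case, handled by
  flagging, never by the layout.
* Flank bins use $B = \lceil |\mathrm{position}|/10 \rceil$, the only
  indexing under which the two nearest 10-nt bins are numbered 1 and the two
  farthest 10.
* The positional-enrichment baseline $R$ averages $S_i/T_i$ over *covered*
  positions ($T_i > 0$); uncovered positions are excluded from baseline and
  testing alike. When all 200 positions are covered this equals the plain
  1/200-weighted sum.
* An input allelic ratio of exactly 0.5 carries no direction and is excluded
  from opposing-direction denominators; the imprint-bin boundary 0.5 is
  assigned to the mild-paternal bin so the four bins partition $[0,1]$.
* Aggregates skip undefined inputs only at the tissue level (where
  detectability masks are part of the definition); the group level requires
  both members.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis assumes:
baseline input allelic ratios from Beta(40, 40) (sd about 0.06 around 0.5,
the concentration typical of balanced allelic expression), per-site depths
negative-binomial around 100 (size 20) to mimic site-to-site coverage
variation, a minority of sites carrying planted effects, SNPs scattered
Poisson(2) per 200-nt flank with optional extra mass at motif positions, and
about 2% strain-specific adenine sites. Input allele counts are binomial in
the (possibly expression-shifted) true ratio. IP allele counts are binomial
in the *realized* input ratio shifted on the log-odds scale by
$\log(2)\,\beta$, where $\beta$ is the planted log2 methylation effect —
the simplest generative model that coincides exactly with the calling
module's binomial null at $\beta = 0$, which keeps type-I-error checks
clean. Sequence effects shift the C57 allele in both crosses; parent effects
shift the maternal allele, so their strain-axis sign flips between F1i and
F1r — the identifiability property the classifier exploits. The PWM-coupled
option draws the methylation effect through a logistic link from the
difference of the two alleles' motif PWM scores, with the better-matching
allele more methylated.

What the generator does *not* emulate: biological replicate variance beyond
binomial sampling (no overdispersion of the allele split), read-level
artifacts (mapping bias, fragment-level exclusion around SNP-overlapping
sites), genuine motif-position effects on antibody pulldown, or correlated
effects among neighbouring sites. Passing tests therefore demonstrate the
correctness and calibration of the inference under its own model
assumptions, not robustness to every artifact of real libraries.

One structural consequence of any binomial allele-split model is worth
stating: the intra-sample different-strain control (`Intra`) carries about
four times the sampling variance of the inter-sample same-strain control
(`Inter`), because comparing two alleles within a sample compounds the
allelic odds noise of both input and IP, whereas comparing one allele across
samples only involves its own proportions. The two controls are therefore
not exchangeable even with zero strain effects; the discriminating signal —
and what the package's tests check — is that planted strain effects inflate
`Intra` strongly while leaving `Inter` at its background level.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script use cohorts of 800-20,000 sites
and 1-3 groups: 20,000 sites at fixed 100/100 depths for the type-I-error
check, 2,000 sites at 150/150 with 10% planted effects of magnitude 1.5 for
the recovery checks, 5,000 motif-SNP sites for the PWM-coupling correlation,
and 10,000 sites at 400/400 for the opposing-direction recovery. These sizes
put Monte-Carlo error well below the asserted margins while keeping the
whole suite inside a few minutes on one core.

## Known limitations

* The binomial test ignores overdispersion between replicate pairs; a
  beta-binomial extension would be the natural next step and the generator's
  dispersion switch already supports stress-testing one.
* Library sizes computed from the analysed site set approximate the true
  per-allele totals; with few sites the normalizers are noisy.
* The PWM consensus model is estimated from the supplied 5-mers and carries
  only the sign semantics of a variant-effect score; it does not reproduce
  any particular external motif tool's numerics.
* Calibration requires both positive and negative control values per class;
  cohorts without misdirected controls (e.g. noise-free synthetic ones) fall
  back to the shipped 0.6 constant.
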