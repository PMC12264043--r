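#' Re-exported generics
#'
#' Commonly needed generics from the Bioconductor core, re-exported so the
#' derived assays and metadata of an [Asm6aExperiment-class] can be reached
#' without attaching SummarizedExperiment explicitly.
#'
#' @name reexports
#' @importFrom SummarizedExperiment assay assayNames colData rowRanges
#' @export assay assayNames colData rowRanges
#' @importFrom S4Vectors metadata
#' @export metadata
NULL
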