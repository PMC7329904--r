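#' @include AllClasses.R
NULL

#' Extract the dosage matrix
#'
#' Returns the variant-by-sample alternate-allele dosage matrix of a
#' [ReferencePanel-class] or [BiobankCohort-class].
#'
#' @param x a panel or cohort object.
#' @return integer matrix, rows = variants (named by rsID), columns = samples.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "RangedSummarizedExperiment", function(x) {
  d <- SummarizedExperiment::assay(x, "dosage")
  rownames(d) <- variantInfo(x)$rsid
  colnames(d) <- sampleIDs(x)
  d
})

#' Variant metadata table
#'
#' @param x a panel or cohort object.
#' @return data.frame with columns rsid, chrom, pos, ref, alt, maf (one row
#'   per variant, in panel order).
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname variantInfo
#' @export
setMethod("variantInfo", "RangedSummarizedExperiment", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  mc <- as.data.frame(S4Vectors::mcols(rr))
  data.frame(rsid = mc$rsid,
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             mc[, setdiff(colnames(mc), "rsid"), drop = FALSE],
             stringsAsFactors = FALSE, row.names = NULL)
})

#' Sample identifiers
#'
#' @param x a panel or cohort object.
#' @return character vector of sample IDs in column order.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "ReferencePanel", function(x) colnames(x))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "BiobankCohort", function(x) {
  as.character(SummarizedExperiment::colData(x)$sample_id)
})

#' Cohort covariate table
#'
#' @param x a [BiobankCohort-class].
#' @return data.frame of per-sample covariates, ultrasound measures and
#'   principal components.
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname covariates
#' @export
setMethod("covariates", "BiobankCohort", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' Genome-wide relatedness markers
#'
#' @param x a [BiobankCohort-class].
#' @return samples x markers matrix of dosages (raw bytes 0/1/2), or NULL
#'   when the cohort carries none.
#' @export
setGeneric("kinshipMarkers", function(x) standardGeneric("kinshipMarkers"))

#' @rdname kinshipMarkers
#' @export
setMethod("kinshipMarkers", "BiobankCohort", function(x) {
  S4Vectors::metadata(x)$kinship_markers
})

setMethod("show", "ReferencePanel", function(object) {
  vi <- variantInfo(object)
  cat("ReferencePanel:", nrow(object), "variants x", ncol(object), "samples\n")
  cat("  chromosomes:", paste(unique(vi$chrom), collapse = " "), "\n")
  cat("  MAF range: [", signif(min(vi$maf), 3), ", ",
      signif(max(vi$maf), 3), "]\n", sep = "")
})

setMethod("show", "BiobankCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  km <- kinshipMarkers(object)
  cat("BiobankCohort:", ncol(object), "participants,",
      nrow(object), "candidate variants\n")
  cat("  sex: ", sum(cd$sex == "female"), " female / ",
      sum(cd$sex == "male"), " male\n", sep = "")
  if (!is.null(km))
    cat("  relatedness markers:", ncol(km), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed ", object@seed, ")\n", sep = "")
  cat("  panel: ", object@n_panel_samples, " samples, ",
      object@n_blocks, " blocks x ", object@snps_per_block, " SNPs\n", sep = "")
  cat("  signals: ", object@n_planted_pleiotropic, " planted + ",
      object@n_decoy_signals, " decoy + ",
      object@n_known_bmd_planted, " known-BMD-proxy\n", sep = "")
  cat("  cohort: ", object@n_biobank_samples, " participants, ",
      object@n_related_pairs, " related pairs\n", sep = "")
})
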