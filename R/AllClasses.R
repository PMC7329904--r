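#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importFrom S4Vectors metadata DataFrame mcols
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

#' Reference genotype panel
#'
#' A sample-by-variant allele-dosage panel used for all linkage
#' disequilibrium (LD) computations: r-squared between variant pairs,
#' perfect-proxy lookup and independence pruning. The class extends
#' \linkS4class{RangedSummarizedExperiment}: rows are variants (a
#' \code{GRanges} with \code{rsid}, \code{ref}, \code{alt} and \code{maf}
#' metadata columns), columns are samples, and the single \code{"dosage"}
#' assay holds alternate-allele counts in \{0, 1, 2\} (\code{NA} allowed).
#'
#' @slot .S4 inherits all slots from \code{RangedSummarizedExperiment}.
#' @seealso [simulateReferencePanel()], [readPanelVCF()], [computeR2()]
#' @export
setClass("ReferencePanel", contains = "RangedSummarizedExperiment")

setValidity("ReferencePanel", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      msg <- c(msg, "dosages must be in {0, 1, 2} or NA")
  }
  mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
  need <- c("rsid", "ref", "alt", "maf")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    msg <- c(msg, paste0("variant metadata lacks: ", paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(mc$rsid)) msg <- c(msg, "variant rsIDs must be unique")
    if (any(mc$maf < 0 | mc$maf > 0.5, na.rm = TRUE))
      msg <- c(msg, "maf must lie in [0, 0.5]")
  }
  if (length(msg)) msg else TRUE
})

#' Individual-level replication cohort
#'
#' Holds one replication cohort: per-sample covariates and heel-ultrasound
#' measures as \code{colData}, candidate-variant dosages as the
#' \code{"dosage"} assay (rows = variants, columns = samples), ancestry
#' principal components in \code{colData} columns \code{PC1..PC15}, and an
#' optional genome-wide relatedness marker matrix (samples x markers, raw
#' bytes 0/1/2) in \code{metadata()$kinship_markers} used by
#' [kinshipPairs()].
#'
#' Required \code{colData} columns: \code{sample_id}, \code{sex}
#' (\code{"male"}/\code{"female"}), \code{age} (years), \code{weight} (kg),
#' \code{sos} (m/s), \code{bua} (dB/MHz), \code{bmd_device} (g/cm^2),
#' \code{entry_mode}, \code{PC1}..\code{PC15}.
#'
#' @seealso [simulateBiobank()], [applyQC()], [zscorePhenotype()]
#' @export
setClass("BiobankCohort", contains = "RangedSummarizedExperiment")

setValidity("BiobankCohort", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "sex", "age", "weight", "sos", "bua",
            "bmd_device", "entry_mode", paste0("PC", 1:15))
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  else {
    if (!all(cd$sex %in% c("male", "female")))
      msg <- c(msg, "sex must be 'male' or 'female'")
    if (any(cd$age <= 0) || any(cd$weight <= 0))
      msg <- c(msg, "age and weight must be positive")
    if (anyDuplicated(cd$sample_id)) msg <- c(msg, "sample_id must be unique")
  }
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic study generator. Defaults are the package's
#' reference study conditions: a 1000-sample reference panel; 401 LD blocks
#' of 5 SNPs (2005 variants) with a perfect-LD pair anchoring every block;
#' 3 planted pleiotropic SNPs, 2 discovery-only decoys and a known-BMD-proxy
#' signal among 2000 nulls; GWAS summary statistics at n = 80000 per trait;
#' and a 20000-participant replication cohort with 60 related pairs and
#' 16000 genome-wide relatedness markers.
#'
#' @slot seed integer seed; all generator randomness derives from it.
#' @slot n_panel_samples,n_biobank_samples sample counts.
#' @slot n_blocks,snps_per_block LD block layout of the variant set.
#' @slot maf_range minor-allele-frequency range, within (0, 0.5].
#' @slot within_block_r2 target r^2 between a block's anchor pair and each
#'   other SNP of the block (non-anchor pairs fall off as its square).
#' @slot n_catalog_traits number of distinct non-bone trait labels.
#' @slot n_planted_pleiotropic planted shared (pleiotropic) effects.
#' @slot n_decoy_signals SNPs given effects in the summary statistics but
#'   not in the cohort (discovery-only false signals).
#' @slot n_known_bmd_planted signals whose perfect proxy is a known BMD SNP.
#' @slot effect_size_sd magnitude of planted standardized effects.
#' @slot gwas_n per-trait GWAS sample size for summary-statistic noise.
#' @slot n_related_pairs,relationship_mix related-pair count and the
#'   proportions over duplicate/parent-offspring/full-sibling/second/third
#'   degree relationships.
#' @slot covariate_effects named coefficients of age (per year, centred at
#'   55), age2, weight (per kg, centred at 78) and male sex on the latent
#'   standardized BMD scale.
#' @slot noise_sd residual SD of the latent phenotype.
#' @slot qc_fail_fraction fraction of cohort records pushed outside (or onto)
#'   the ultrasound QC bounds to exercise the outlier filters.
#' @slot n_kinship_snps genome-wide markers generated for relatedness
#'   estimation.
#' @export
setClass("SimulationConfig", representation(
  seed = "integer",
  n_panel_samples = "integer",
  n_biobank_samples = "integer",
  n_blocks = "integer",
  snps_per_block = "integer",
  maf_range = "numeric",
  within_block_r2 = "numeric",
  n_catalog_traits = "integer",
  n_planted_pleiotropic = "integer",
  n_decoy_signals = "integer",
  n_known_bmd_planted = "integer",
  effect_size_sd = "numeric",
  gwas_n = "integer",
  n_related_pairs = "integer",
  relationship_mix = "numeric",
  covariate_effects = "numeric",
  noise_sd = "numeric",
  qc_fail_fraction = "numeric",
  n_kinship_snps = "integer"
))

.relationship_classes <- c("duplicate", "parent_offspring", "full_sib",
                           "second_degree", "third_degree")

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(n_panel_samples = object@n_panel_samples,
           n_biobank_samples = object@n_biobank_samples,
           n_blocks = object@n_blocks,
           snps_per_block = object@snps_per_block,
           n_catalog_traits = object@n_catalog_traits,
           gwas_n = object@gwas_n)
  if (any(cnt <= 0))
    msg <- c(msg, paste0("counts must be positive: ",
                         paste(names(cnt)[cnt <= 0], collapse = ", ")))
  if (object@n_planted_pleiotropic < 0 || object@n_decoy_signals < 0 ||
      object@n_related_pairs < 0 || object@n_known_bmd_planted < 0)
    msg <- c(msg, "signal and pair counts must be non-negative")
  if (length(object@maf_range) != 2 || any(object@maf_range <= 0) ||
      any(object@maf_range > 0.5) || diff(object@maf_range) < 0)
    msg <- c(msg, "maf_range must be an increasing pair within (0, 0.5]")
  if (object@within_block_r2 < 0 || object@within_block_r2 > 1)
    msg <- c(msg, "within_block_r2 must lie in [0, 1]")
  nsig <- object@n_planted_pleiotropic + object@n_decoy_signals +
    object@n_known_bmd_planted
  if (nsig > object@n_blocks)
    msg <- c(msg, "at most one planted signal per block: too many signals for n_blocks")
  if (object@n_known_bmd_planted > 0 && object@snps_per_block < 2)
    msg <- c(msg, "known-BMD-proxy signals need blocks of at least 2 SNPs")
  if (length(object@relationship_mix) != 5 ||
      !setequal(names(object@relationship_mix), .relationship_classes) ||
      any(object@relationship_mix < 0) ||
      abs(sum(object@relationship_mix) - 1) > 1e-8)
    msg <- c(msg, "relationship_mix must be named proportions over the five relationship classes summing to 1")
  if (object@noise_sd <= 0) msg <- c(msg, "noise_sd must be positive")
  if (object@qc_fail_fraction < 0 || object@qc_fail_fraction >= 1)
    msg <- c(msg, "qc_fail_fraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})
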