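#' @include AllClasses.R AllGenerics.R
NULL

#' Write study tables as TSV
#'
#' Plain TSV writers for the pipeline inputs the simulator produces:
#' the catalog table, a summary-statistics set, the cohort covariate +
#' dosage table, and the truth tables.
#'
#' @param x the table (catalog/summary-stats data.frame, or for
#'   \code{writeBiobankTSV} a [BiobankCohort-class]).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTSV
#' @export
writeBiobankTSV <- function(x, path) {
  stopifnot(is(x, "BiobankCohort"))
  d <- t(dosages(x))
  colnames(d) <- paste0("dosage_", colnames(d))
  writeTSV(cbind(covariates(x), as.data.frame(d)), path)
}

#' Read a cohort table written by [writeBiobankTSV()]
#'
#' Relatedness markers are not part of the TSV; [kinshipPairs()] falls back
#' to the candidate dosages (with a warning) for cohorts loaded this way.
#'
#' @param path TSV path.
#' @param panel the [ReferencePanel-class] supplying variant metadata for
#'   the dosage columns.
#' @return a [BiobankCohort-class].
#' @export
readBiobankTSV <- function(path, panel) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  dcols <- grep("^dosage_", colnames(df), value = TRUE)
  rsids <- sub("^dosage_", "", dcols)
  d <- t(as.matrix(df[, dcols, drop = FALSE]))
  storage.mode(d) <- "integer"
  rownames(d) <- rsids
  gr <- SummarizedExperiment::rowRanges(panel)[rsids]
  cv <- df[, setdiff(colnames(df), dcols), drop = FALSE]
  cd <- S4Vectors::DataFrame(cv, row.names = cv$sample_id)
  new("BiobankCohort", SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = d), rowRanges = gr, colData = cd))
}

#' Write every input of a simulated study to a directory
#'
#' Persists the panel (VCF and PLINK-style text dosage), catalog, both
#' summary-statistic sets, the cohort table and the truth tables.
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return named vector of the files written, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(panel_vcf = file.path(dir, "panel.vcf"),
         panel_traw = file.path(dir, "panel.traw"),
         catalog = file.path(dir, "catalog.tsv"),
         stats_fn = file.path(dir, "stats_fn.tsv"),
         stats_ls = file.path(dir, "stats_ls.tsv"),
         biobank = file.path(dir, "biobank.tsv"),
         truth_variants = file.path(dir, "truth_variants.tsv"),
         truth_samples = file.path(dir, "truth_samples.tsv"))
  writePanelVCF(study$panel, f["panel_vcf"])
  writePanelTraw(study$panel, f["panel_traw"])
  writeTSV(study$catalog, f["catalog"])
  writeTSV(study$stats_fn, f["stats_fn"])
  writeTSV(study$stats_ls, f["stats_ls"])
  writeBiobankTSV(study$cohort, f["biobank"])
  writeTSV(study$truth$variants, f["truth_variants"])
  writeTSV(study$truth$samples, f["truth_samples"])
  invisible(f)
}
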