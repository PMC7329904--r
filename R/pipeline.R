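#' @include AllClasses.R AllGenerics.R
NULL

#' Pipeline parameters
#'
#' Houses every threshold of the two-stage scan: genome-wide significance
#' 5e-8 for catalog inclusion and replication, perfect-proxy r^2 = 1,
#' independence pruning r^2 < 0.2, FDR level 5\%, the printed ultrasound QC
#' bounds, the degree-3 kinship cutoff 1/2^(9/2), and the |Z| < 4
#' phenotype bound.
#'
#' @param curation a [curationConfig()].
#' @param proxy_r2 minimum r^2 for proxy expansion (default 1).
#' @param proxy_window_bp proxy search window each side (default 500 kb).
#' @param prune_r2 independence threshold (default 0.2).
#' @param fdr_q discovery FDR level (default 0.05).
#' @param qc a [qcThresholds()].
#' @param use_ebmd use recalculated eBMD instead of the device BMD for QC
#'   and as the phenotype (sensitivity analysis).
#' @param kinship_threshold relatedness cutoff (default \code{2^(-9/2)}).
#' @param gws replication genome-wide significance level (default 5e-8).
#' @param z_bound phenotype Z-score exclusion bound (default 4).
#' @param keep_override rsIDs exempt from the known-BMD-proxy drop.
#' @return a \code{PipelineParams} list.
#' @export
pipelineParams <- function(curation = curationConfig(),
                           proxy_r2 = 1, proxy_window_bp = 5e5,
                           prune_r2 = 0.2, fdr_q = 0.05,
                           qc = qcThresholds(), use_ebmd = FALSE,
                           kinship_threshold = kinshipDegreeCutoff,
                           gws = 5e-8, z_bound = 4,
                           keep_override = character()) {
  if (!(fdr_q > 0 && fdr_q < 1)) stop("fdr_q must lie in (0, 1)")
  if (!(proxy_r2 > 0 && proxy_r2 <= 1)) stop("proxy_r2 must lie in (0, 1]")
  if (!(prune_r2 > 0 && prune_r2 < 1)) stop("prune_r2 must lie in (0, 1)")
  if (!(gws > 0 && gws < 1)) stop("gws must lie in (0, 1)")
  if (kinship_threshold <= 0) stop("kinship_threshold must be positive")
  if (z_bound <= 0) stop("z_bound must be positive")
  structure(list(curation = curation, proxy_r2 = proxy_r2,
                 proxy_window_bp = proxy_window_bp, prune_r2 = prune_r2,
                 fdr_q = fdr_q, qc = qc, use_ebmd = use_ebmd,
                 kinship_threshold = kinship_threshold, gws = gws,
                 z_bound = z_bound, keep_override = keep_override),
            class = "PipelineParams")
}

#' Save / load pipeline parameters
#'
#' JSON round-trip of [pipelineParams()]; loading a written file
#' reproduces an equivalent parameter object.
#'
#' @param params a \code{PipelineParams} list.
#' @param path JSON file path.
#' @return \code{savePipelineParams}: the path, invisibly;
#'   \code{loadPipelineParams}: a \code{PipelineParams} list.
#' @export
savePipelineParams <- function(params, path) {
  x <- unclass(params)
  x$curation <- unclass(x$curation)
  x$qc <- unclass(x$qc)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname savePipelineParams
#' @export
loadPipelineParams <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  qc <- qcThresholds(male = lapply(raw$qc$male, as.numeric),
                     female = lapply(raw$qc$female, as.numeric))
  cur <- curationConfig(gws_threshold = raw$curation$gws_threshold,
                        bone_trait_keywords = raw$curation$bone_trait_keywords,
                        known_bmd_snps = as.character(raw$curation$known_bmd_snps %||% character()),
                        pleiotropy_rules = raw$curation$pleiotropy_rules)
  pipelineParams(curation = cur, proxy_r2 = raw$proxy_r2,
                 proxy_window_bp = raw$proxy_window_bp,
                 prune_r2 = raw$prune_r2, fdr_q = raw$fdr_q, qc = qc,
                 use_ebmd = raw$use_ebmd,
                 kinship_threshold = raw$kinship_threshold, gws = raw$gws,
                 z_bound = raw$z_bound,
                 keep_override = as.character(raw$keep_override %||% character()))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the two-stage pleiotropy scan
#'
#' Executes curation, proxy expansion, per-trait FDR discovery, union,
#' independence pruning, the known-BMD-proxy drop, and individual-level
#' replication (ultrasound QC, kinship-based unrelated-set selection,
#' per-sex Z-scores, PC-adjusted per-SNP association at genome-wide
#' significance, direction-of-effect concordance), and assembles a
#' pleiotropy report. Any stage failure aborts with the stage name.
#'
#' @param inputs list with elements \code{catalog} (data.frame from
#'   [readCatalog()] or a TSV path), \code{panel} ([ReferencePanel-class]
#'   or a VCF path), \code{stats_fn}, \code{stats_ls} (data.frames or TSV
#'   paths) and \code{cohort} (a [BiobankCohort-class]) — e.g. the output
#'   of [simulateStudy()].
#' @param params a [pipelineParams()].
#' @return a \code{PleiotropyReport}: per-stage tables, a per-replicated-SNP
#'   report table, the concordance table, and summary counts.
#' @export
runPipeline <- function(inputs, params = pipelineParams()) {
  stopifnot(inherits(params, "PipelineParams"))
  catalog <- .stage("catalog", {
    if (is.character(inputs$catalog)) readCatalog(inputs$catalog)
    else if (all(c("rsid", "trait", "p_value") %in% colnames(inputs$catalog)))
      inputs$catalog
    else {
      tf <- tempfile(fileext = ".tsv")
      utils::write.table(inputs$catalog, tf, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      on.exit(unlink(tf))
      readCatalog(tf)
    }
  })
  panel <- .stage("panel", {
    if (is.character(inputs$panel)) readPanelVCF(inputs$panel)
    else inputs$panel
  })
  stats_fn <- .stage("summary-stats",
    if (is.character(inputs$stats_fn)) readSummaryStats(inputs$stats_fn)
    else inputs$stats_fn)
  stats_ls <- .stage("summary-stats",
    if (is.character(inputs$stats_ls)) readSummaryStats(inputs$stats_ls)
    else inputs$stats_ls)
  cohort <- inputs$cohort
  stopifnot(is(cohort, "BiobankCohort"))

  cur <- .stage("curation", curateCatalog(catalog, params$curation))
  proxies <- .stage("proxies",
    findProxies(panel, cur$candidates, r2_min = params$proxy_r2,
                window_bp = params$proxy_window_bp))
  disc <- .stage("discovery",
    runDiscovery(cur$candidates, proxies, stats_fn, stats_ls,
                 q = params$fdr_q))
  sig <- disc$results[disc$results$significant, , drop = FALSE]
  pruned <- .stage("pruning", {
    cand <- data.frame(rsid = sig$rsid,
                       p_value = pmin(sig$p_FN, sig$p_LS, na.rm = TRUE))
    pruneIndependent(cand, panel, r2_max = params$prune_r2)
  })
  flagged <- .stage("known-bmd-drop", {
    res <- sig[match(pruned$rsid, sig$rsid), , drop = FALSE]
    dropKnownBMD(res, params$curation$known_bmd_snps, proxies,
                 keep_override = params$keep_override)
  })
  final <- flagged[!flagged$known_bmd_proxy, , drop = FALSE]

  # --- replication stage ---
  qc <- .stage("qc", applyQC(cohort, params$qc, use_ebmd = params$use_ebmd))
  retained <- qc$retained
  ids_qc <- sampleIDs(retained)
  pairs <- .stage("kinship", {
    km <- kinshipMarkers(cohort)
    if (is.null(km)) {
      warning("cohort carries no relatedness markers; using candidate dosages")
      km <- t(dosages(cohort))
    }
    km <- km[match(ids_qc, sampleIDs(cohort)), , drop = FALSE]
    rownames(km) <- ids_qc
    kinshipPairs(km, threshold = params$kinship_threshold)
  })
  unrelated <- .stage("unrelated-selection",
    selectUnrelated(ids_qc, pairs, threshold = params$kinship_threshold))
  zres <- .stage("z-score", {
    cv <- covariates(retained)
    i <- match(unrelated, cv$sample_id)
    bmd <- if (params$use_ebmd) deriveEBMD(cv$sos[i], cv$bua[i])
           else cv$bmd_device[i]
    zscorePhenotype(cv[i, , drop = FALSE], bmd, z_bound = params$z_bound)
  })
  assoc <- .stage("association", {
    z <- zres$z
    cv <- covariates(cohort)
    i <- match(names(z), cv$sample_id)
    pcs <- as.matrix(cv[i, paste0("PC", 1:15)])
    d <- dosages(cohort)
    vi <- variantInfo(panel)
    do.call(rbind, lapply(final$rsid, function(rs) {
      if (!rs %in% rownames(d)) {
        warning("SNP ", rs, " has no cohort genotypes; skipped")
        return(NULL)
      }
      snpAssociation(z, d[rs, i], pcs, rsid = rs,
                     effect_allele = vi$alt[match(rs, vi$rsid)],
                     gws = params$gws)
    }))
  })
  replicated <- if (is.null(assoc) || nrow(assoc) == 0)
    assoc else assoc[assoc$replicated, , drop = FALSE]

  conc <- .stage("concordance", {
    if (is.null(replicated) || nrow(replicated) == 0)
      list(table = data.frame(), fraction = NA_real_)
    else {
      disc_side <- stats_fn[match(replicated$rsid, stats_fn$rsid), , drop = FALSE]
      use_ls <- is.na(disc_side$rsid)
      if (any(use_ls))
        disc_side[use_ls, ] <- stats_ls[match(replicated$rsid[use_ls],
                                              stats_ls$rsid), , drop = FALSE]
      directionConcordance(disc_side, replicated)
    }
  })

  report_table <- .stage("report", {
    if (is.null(replicated) || nrow(replicated) == 0) {
      data.frame(rsid = character(), locus = character(), gene = character(),
                 phenotypes = character(), direction_phenotype = character(),
                 direction_bmd = character(), p_FN = numeric(),
                 p_LS = numeric(), beta = numeric(), se = numeric(),
                 p = numeric(), stringsAsFactors = FALSE)
    } else {
      vi <- variantInfo(panel)
      j <- match(replicated$rsid, vi$rsid)
      cat_attr <- catalog[!is.na(catalog$rsid) & catalog$rsid %in% replicated$rsid &
                            catalog$p_value <= params$curation$gws_threshold, ,
                          drop = FALSE]
      phen <- vapply(replicated$rsid, function(rs) {
        tr <- unique(cat_attr$trait[cat_attr$rsid == rs])
        if (length(tr)) paste(sort(tr), collapse = "; ") else "(proxy signal)"
      }, character(1))
      dirp <- vapply(replicated$rsid, function(rs) {
        es <- cat_attr$effect_size[cat_attr$rsid == rs]
        if (!length(es) || all(is.na(es))) "NR"
        else if (mean(es, na.rm = TRUE) >= 0) "up" else "down"
      }, character(1))
      gene <- if (!is.null(inputs$gene_table))
        inputs$gene_table$gene[match(replicated$rsid, inputs$gene_table$rsid)]
      else NA_character_
      out <- data.frame(
        rsid = replicated$rsid,
        locus = paste0(vi$chrom[j], ":", vi$pos[j]),
        gene = gene, phenotypes = phen, direction_phenotype = dirp,
        direction_bmd = ifelse(replicated$beta >= 0, "up", "down"),
        p_FN = final$p_FN[match(replicated$rsid, final$rsid)],
        p_LS = final$p_LS[match(replicated$rsid, final$rsid)],
        beta = replicated$beta, se = replicated$se, p = replicated$p,
        stringsAsFactors = FALSE)
      out[order(as.integer(out$locus |> sub(pattern = ":.*", replacement = "")),
                vi$pos[j]), , drop = FALSE]
    }
  })

  summary <- list(
    n_catalog_records = nrow(catalog),
    n_candidates = length(cur$candidates),
    n_unresolved_proxies = length(proxies$unresolved),
    m_FN = if (!is.null(disc$fdr_fn)) disc$fdr_fn$m else 0L,
    m_LS = if (!is.null(disc$fdr_ls)) disc$fdr_ls$m else 0L,
    k_FN = if (!is.null(disc$fdr_fn)) disc$fdr_fn$k else 0L,
    k_LS = if (!is.null(disc$fdr_ls)) disc$fdr_ls$k else 0L,
    p_threshold_FN = if (!is.null(disc$fdr_fn)) disc$fdr_fn$threshold_bound else 0,
    p_threshold_LS = if (!is.null(disc$fdr_ls)) disc$fdr_ls$threshold_bound else 0,
    n_significant_union = nrow(sig),
    n_independent = nrow(pruned),
    n_dropped_known_bmd = sum(flagged$known_bmd_proxy),
    n_final_discovery = nrow(final),
    n_cohort = ncol(cohort),
    n_qc_excluded = qc$report$n_excluded,
    n_related_pairs = nrow(pairs),
    n_related_removed = length(ids_qc) - length(unrelated),
    n_z_excluded = length(zres$excluded),
    n_association_samples = length(zres$z),
    n_replicated = if (is.null(replicated)) 0L else nrow(replicated),
    concordant_fraction = conc$fraction)

  structure(list(table = report_table, summary = summary,
                 curation = cur$report, discovery = disc,
                 pruned = pruned, final_discovery = final,
                 qc_report = qc$report, kinship_pairs = pairs,
                 association = assoc, concordance = conc,
                 params = params),
            class = "PleiotropyReport")
}

#' @export
print.PleiotropyReport <- function(x, ...) {
  s <- x$summary
  cat("Two-stage pleiotropy scan\n")
  cat("  catalog records:        ", s$n_catalog_records, "\n")
  cat("  candidates after curation:", s$n_candidates, "\n")
  cat("  FDR (q=", x$params$fdr_q, "): FN m=", s$m_FN, " k=", s$k_FN,
      " thr=", signif(s$p_threshold_FN, 2),
      "; LS m=", s$m_LS, " k=", s$k_LS,
      " thr=", signif(s$p_threshold_LS, 2), "\n", sep = "")
  cat("  significant (union):    ", s$n_significant_union, "\n")
  cat("  independent:            ", s$n_independent, "\n")
  cat("  dropped as known-BMD:   ", s$n_dropped_known_bmd, "\n")
  cat("  taken to replication:   ", s$n_final_discovery, "\n")
  cat("  replicated at 5e-8:     ", s$n_replicated, "\n")
  if (!is.na(s$concordant_fraction))
    cat("  direction concordance:  ",
        round(100 * s$concordant_fraction, 1), "%\n", sep = "")
  invisible(x)
}

#' Render a pleiotropy report to files
#'
#' Writes the per-SNP report table and summary counts in deterministic
#' order (chromosome, position). TSV and JSON renderings carry identical
#' values; the markdown rendering mirrors the per-SNP table layout
#' (SNP, locus, gene, phenotypes, directions, statistics).
#'
#' @param report a \code{PleiotropyReport} from [runPipeline()].
#' @param dir output directory (created if needed).
#' @param formats subset of \code{c("tsv", "json", "markdown")}.
#' @return named character vector of the files written, invisibly.
#' @export
renderReport <- function(report, dir, formats = c("tsv", "json", "markdown")) {
  stopifnot(inherits(report, "PleiotropyReport"))
  bad <- setdiff(formats, c("tsv", "json", "markdown"))
  if (length(bad)) stop("unknown format(s): ", paste(bad, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$table
  out <- character()
  if ("tsv" %in% formats) {
    f <- file.path(dir, "pleiotropy_report.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    out["tsv"] <- f
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "pleiotropy_report.json")
    jsonlite::write_json(list(table = tab, summary = report$summary), f,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    out["json"] <- f
  }
  if ("markdown" %in% formats) {
    f <- file.path(dir, "pleiotropy_report.md")
    hdr <- c("SNP", "Locus", "Gene", "Associated phenotype(s)",
             "Direction (phenotype)", "Direction (BMD)", "Replication p")
    lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"))
    if (nrow(tab))
      lines <- c(lines, vapply(seq_len(nrow(tab)), function(i) {
        paste0("| ", paste(c(tab$rsid[i], tab$locus[i],
                             tab$gene[i] %||% "NA", tab$phenotypes[i],
                             tab$direction_phenotype[i], tab$direction_bmd[i],
                             format(tab$p[i], digits = 3)),
                           collapse = " | "), " |")
      }, character(1)))
    writeLines(lines, f)
    out["markdown"] <- f
  }
  invisible(out)
}
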