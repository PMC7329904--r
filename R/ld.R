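#' @include AllClasses.R AllGenerics.R
NULL

#' Pairwise r-squared between two panel variants
#'
#' Squared Pearson correlation of the two dosage vectors over
#' pairwise-complete samples (composite, phase-free LD). Symmetric in its
#' arguments and invariant to allele relabeling (\code{g -> 2 - g}).
#'
#' @param panel a [ReferencePanel-class].
#' @param a,b variant rsIDs.
#' @return r^2 in [0, 1].
#' @examples
#' panel <- simulateReferencePanel(
#'   simulationConfig(seed = 3, n_blocks = 1, snps_per_block = 3,
#'                    n_panel_samples = 100))
#' rs <- variantInfo(panel)$rsid
#' computeR2(panel, rs[1], rs[2])  # anchor pair: exactly 1
#' @export
computeR2 <- function(panel, a, b) {
  d <- dosages(panel)
  for (v in c(a, b)) if (!v %in% rownames(d))
    stop("variant not in panel: ", v)
  if (a == b) return(1)
  r2 <- r2_pair(d[a, ], d[b, ])
  if (is.na(r2))
    stop("undefined LD: monomorphic variant or too few complete samples for ",
         a, " / ", b)
  r2
}

#' Find LD proxies of a set of SNPs
#'
#' For each query SNP in the panel, returns every same-chromosome variant
#' within \code{window_bp} whose r^2 with the query is at least
#' \code{r2_min} (a SNP is always its own proxy with r^2 = 1). Variants
#' with undefined LD (monomorphic) are skipped. Query SNPs absent from the
#' panel are reported as unresolved, not silently dropped.
#'
#' @param panel a [ReferencePanel-class].
#' @param snps character vector of query rsIDs.
#' @param r2_min minimum r^2, in (0, 1]; default 1 (perfect proxies).
#' @param window_bp search window to each side, default 500 kb.
#' @return list with \code{proxies} (named list of data.frames rsid, r2)
#'   and \code{unresolved} (query rsIDs absent from the panel).
#' @export
findProxies <- function(panel, snps, r2_min = 1, window_bp = 5e5) {
  stopifnot(r2_min > 0, r2_min <= 1, window_bp > 0)
  vi <- variantInfo(panel)
  d <- dosages(panel)
  unresolved <- setdiff(snps, vi$rsid)
  snps <- intersect(snps, vi$rsid)
  out <- lapply(snps, function(s) {
    i <- match(s, vi$rsid)
    cand <- which(vi$chrom == vi$chrom[i] &
                    abs(vi$pos - vi$pos[i]) <= window_bp)
    r2 <- vapply(cand, function(j) {
      if (j == i) return(1)
      v <- r2_pair(d[i, ], d[j, ])
      if (is.na(v)) -1 else v
    }, numeric(1))
    # guard against fp wobble at the r2 = 1 boundary
    keep <- r2 >= r2_min - 1e-12
    data.frame(rsid = vi$rsid[cand[keep]], r2 = pmin(r2[keep], 1),
               stringsAsFactors = FALSE)
  })
  names(out) <- snps
  list(proxies = out, unresolved = unresolved)
}

#' Prune candidates to an independent SNP set
#'
#' Greedy best-first clumping: candidates are visited in ascending p-value
#' order (ties by chromosome, position, then rsID) and kept iff their r^2
#' with every already-kept same-chromosome SNP is below \code{r2_max}.
#' Candidates absent from the panel are kept with a warning (their LD is
#' unassessable) and flagged; undefined LD against a kept SNP counts as
#' r^2 = 0.
#'
#' @param candidates data.frame with columns rsid and p_value.
#' @param panel a [ReferencePanel-class].
#' @param r2_max independence threshold, in (0, 1); default 0.2.
#' @return data.frame of retained SNPs in selection order: rsid, p_value,
#'   ld_assessed.
#' @export
pruneIndependent <- function(candidates, panel, r2_max = 0.2) {
  stopifnot(r2_max > 0, r2_max < 1,
            all(c("rsid", "p_value") %in% colnames(candidates)))
  if (nrow(candidates) == 0)
    return(data.frame(rsid = character(), p_value = numeric(),
                      ld_assessed = logical()))
  vi <- variantInfo(panel)
  d <- dosages(panel)
  idx <- match(candidates$rsid, vi$rsid)
  chrom <- vi$chrom[idx]; pos <- vi$pos[idx]
  ord <- order(candidates$p_value, chrom, pos, candidates$rsid)
  in_panel <- !is.na(idx)
  if (any(!in_panel))
    warning("candidate(s) not in panel kept without LD assessment: ",
            paste(candidates$rsid[!in_panel], collapse = ", "))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    if (in_panel[i]) {
      for (j in kept) {
        if (!in_panel[j] || chrom[j] != chrom[i]) next
        r2 <- r2_pair(d[candidates$rsid[i], ], d[candidates$rsid[j], ])
        if (!is.na(r2) && r2 >= r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, i)
  }
  data.frame(rsid = candidates$rsid[kept],
             p_value = candidates$p_value[kept],
             ld_assessed = in_panel[kept],
             stringsAsFactors = FALSE)
}

#' Read a reference panel from VCF
#'
#' Parses a VCF (via \pkg{vcfR}) into a [ReferencePanel-class]. Only
#' biallelic SNVs are used; multiallelic or non-SNV records are skipped
#' with a warning. Genotypes are converted to alternate-allele dosages;
#' phasing is ignored and missing genotypes become NA.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [ReferencePanel-class].
#' @export
readPanelVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snv))
    warning(sum(!snv), " non-biallelic-SNV record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")[snv, , drop = FALSE]
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  fix <- fix[snv, , drop = FALSE]
  afreq <- rowMeans(dose, na.rm = TRUE) / 2
  gr <- GenomicRanges::GRanges(
    seqnames = fix$CHROM,
    ranges = IRanges::IRanges(start = as.integer(fix$POS), width = 1L),
    rsid = fix$ID, ref = fix$REF, alt = fix$ALT,
    maf = pmin(afreq, 1 - afreq))
  names(gr) <- fix$ID
  new("ReferencePanel", SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dose), rowRanges = gr,
    colData = S4Vectors::DataFrame(row.names = colnames(dose))))
}

#' Write a reference panel as plain-text VCF
#'
#' Emits an uncompressed VCFv4.2 file with GT-only genotype columns
#' (dosage 0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.). Round-trips through
#' [readPanelVCF()].
#'
#' @param panel a [ReferencePanel-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePanelVCF <- function(panel, path) {
  vi <- variantInfo(panel)
  d <- dosages(panel)
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[d == 0] <- "0/0"; gt[d == 1] <- "0/1"; gt[d == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=pleioscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sampleIDs(panel)), collapse = "\t"))
  body <- paste(vi$chrom, vi$pos, vi$rsid, vi$ref, vi$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read a PLINK-style text dosage table
#'
#' A transposed-dosage text format (one row per variant: CHR, SNP, POS,
#' COUNTED (alt), ALT (ref), then one dosage column per sample), akin to
#' PLINK's \code{--recode A-transpose} output.
#'
#' @param panel a [ReferencePanel-class].
#' @param path file path.
#' @return \code{writePanelTraw}: the path, invisibly;
#'   \code{readPanelTraw}: a [ReferencePanel-class].
#' @export
writePanelTraw <- function(panel, path) {
  vi <- variantInfo(panel)
  d <- dosages(panel)
  df <- data.frame(CHR = vi$chrom, SNP = vi$rsid, POS = vi$pos,
                   COUNTED = vi$alt, ALT = vi$ref, d,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[-(1:5)] <- sampleIDs(panel)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePanelTraw
#' @export
readPanelTraw <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  d <- as.matrix(df[, -(1:5), drop = FALSE])
  storage.mode(d) <- "integer"
  rownames(d) <- df$SNP
  afreq <- rowMeans(d, na.rm = TRUE) / 2
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$CHR),
    ranges = IRanges::IRanges(start = df$POS, width = 1L),
    rsid = df$SNP, ref = df$ALT, alt = df$COUNTED,
    maf = pmin(afreq, 1 - afreq))
  names(gr) <- df$SNP
  new("ReferencePanel", SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = d), rowRanges = gr,
    colData = S4Vectors::DataFrame(row.names = colnames(d))))
}
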