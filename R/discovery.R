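#' @include AllClasses.R
NULL

#' Simes/Benjamini-Hochberg step-up FDR threshold
#'
#' Sorts the p-values ascending, finds the largest rank k with
#' \eqn{p_{(k)} \le (k/m) q}, and declares every p-value at or below
#' \eqn{p_{(k)}} significant (exact step-up semantics: p-values below a
#' passing rank are significant even if they fail their own bound). The
#' data-dependent threshold \eqn{p_{(k)}} and its rank bound \eqn{(k/m) q}
#' are both reported; with no passing rank, k = 0 and the threshold is 0.
#'
#' @param p_values numeric p-values in (0, 1].
#' @param q nominal FDR level in (0, 1); default 0.05.
#' @return an \code{FDRResult} list: m, q, k, p_threshold (= \eqn{p_{(k)}}),
#'   threshold_bound (= \eqn{(k/m) q}), significant (logical over the
#'   input order).
#' @examples
#' r <- bhThreshold(c(0.001, 0.01, 0.02, 0.5), q = 0.05)
#' r$k            # 3
#' r$p_threshold  # 0.02
#' @export
bhThreshold <- function(p_values, q = 0.05) {
  stopifnot(length(p_values) > 0, q > 0, q < 1)
  bad <- which(is.na(p_values) | p_values <= 0 | p_values > 1)
  if (length(bad))
    stop("p-value outside (0, 1] at position ", bad[1], ": ",
         p_values[bad[1]])
  m <- length(p_values)
  ps <- sort(p_values)
  pass <- which(ps <= seq_len(m) / m * q)
  k <- if (length(pass)) max(pass) else 0L
  p_thr <- if (k > 0) ps[k] else 0
  structure(list(m = m, q = q, k = k,
                 p_threshold = p_thr,
                 threshold_bound = k / m * q,
                 significant = p_values <= p_thr & k > 0),
            class = "FDRResult")
}

#' @export
print.FDRResult <- function(x, ...) {
  cat("FDR step-up: m =", x$m, ", q =", x$q, "-> k =", x$k,
      "discoveries, p-threshold", signif(x$p_threshold, 2),
      "(rank bound", paste0(signif(x$threshold_bound, 2), ")\n"))
  invisible(x)
}

#' Run the discovery stage
#'
#' Intersects the candidate SNPs (plus all their LD proxies) with each
#' BMD summary-statistic set, applies the FDR step-up independently per
#' trait, and carries forward the union: a SNP is discovery-significant if
#' significant for femoral-neck or lumbar-spine BMD. Per-trait test-set
#' sizes and thresholds are recorded.
#'
#' @param candidates character rsIDs from [curateCatalog()].
#' @param proxies proxy map from [findProxies()] (or NULL for none).
#' @param stats_fn,stats_ls summary-statistic data.frames (columns rsid,
#'   p at least; see [simulateSummaryStats()]).
#' @param q nominal FDR level, default 0.05.
#' @return list with \code{results} (data.frame rsid, source, p_FN, p_LS,
#'   significant_FN, significant_LS, significant), \code{fdr_fn} and
#'   \code{fdr_ls} (the per-trait \code{FDRResult}s).
#' @export
runDiscovery <- function(candidates, proxies, stats_fn, stats_ls, q = 0.05) {
  proxy_rsids <- if (is.null(proxies)) character() else
    unique(unlist(lapply(proxies$proxies, function(x) x$rsid)))
  test_set <- unique(c(candidates, proxy_rsids))
  source <- ifelse(test_set %in% candidates, "catalog-indexed", "proxy")
  in_fn <- test_set %in% stats_fn$rsid
  in_ls <- test_set %in% stats_ls$rsid
  tested <- in_fn | in_ls
  if (!any(tested)) {
    warning("empty test set: no candidate or proxy present in either summary-statistic set")
    return(list(results = data.frame(), fdr_fn = NULL, fdr_ls = NULL))
  }
  test_set <- test_set[tested]; source <- source[tested]
  in_fn <- in_fn[tested]; in_ls <- in_ls[tested]
  p_fn <- stats_fn$p[match(test_set, stats_fn$rsid)]
  p_ls <- stats_ls$p[match(test_set, stats_ls$rsid)]
  fdr_fn <- if (any(in_fn)) bhThreshold(p_fn[in_fn], q) else NULL
  fdr_ls <- if (any(in_ls)) bhThreshold(p_ls[in_ls], q) else NULL
  sig_fn <- rep(FALSE, length(test_set))
  sig_ls <- rep(FALSE, length(test_set))
  if (!is.null(fdr_fn)) sig_fn[in_fn] <- fdr_fn$significant
  if (!is.null(fdr_ls)) sig_ls[in_ls] <- fdr_ls$significant
  list(results = data.frame(rsid = test_set, source = source,
                            p_FN = p_fn, p_LS = p_ls,
                            significant_FN = sig_fn, significant_LS = sig_ls,
                            significant = sig_fn | sig_ls,
                            stringsAsFactors = FALSE),
       fdr_fn = fdr_fn, fdr_ls = fdr_ls)
}

#' Drop SNPs that proxy known BMD loci
#'
#' Flags every discovery result whose rsID, or any of its perfect
#' (r^2 = 1) proxies, is a known BMD-associated SNP; flagged SNPs leave
#' the final pleiotropic set. An override list forces retention of named
#' SNPs regardless (dataset-specific rescues).
#'
#' @param results discovery results data.frame (from
#'   [runDiscovery()]\code{$results} or after pruning).
#' @param known_bmd character rsIDs previously associated with BMD.
#' @param proxies proxy map from [findProxies()] at \code{r2_min = 1}.
#' @param keep_override rsIDs never flagged.
#' @return the results data.frame with a logical \code{known_bmd_proxy}
#'   column added.
#' @export
dropKnownBMD <- function(results, known_bmd, proxies = NULL,
                         keep_override = character()) {
  if (nrow(results) == 0) {
    results$known_bmd_proxy <- logical(0)
    return(results)
  }
  flag <- results$rsid %in% known_bmd
  if (!is.null(proxies)) {
    for (i in seq_len(nrow(results))) {
      px <- proxies$proxies[[results$rsid[i]]]
      if (!is.null(px) && any(px$rsid[px$r2 >= 1 - 1e-12] %in% known_bmd))
        flag[i] <- TRUE
    }
  }
  flag[results$rsid %in% keep_override] <- FALSE
  results$known_bmd_proxy <- flag
  results
}

#' Read a summary-statistics TSV
#'
#' @param path TSV with header columns rsid, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, p, n (extra columns kept). Warns when p
#'   is inconsistent with |beta/se| under the two-sided normal test by
#'   more than 10\% relative.
#' @return data.frame of summary statistics.
#' @export
readSummaryStats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "beta", "se", "p")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("summary-statistics file lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$se <= 0, na.rm = TRUE)) stop("se must be positive")
  p_imp <- 2 * stats::pnorm(-abs(df$beta / df$se))
  ok <- p_imp > 1e-300 & df$p > 1e-300
  rel <- abs(df$p[ok] - p_imp[ok]) / p_imp[ok]
  if (any(rel > 0.10, na.rm = TRUE))
    warning(sum(rel > 0.10, na.rm = TRUE),
            " record(s) with p inconsistent with beta/se beyond 10% relative")
  df
}
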