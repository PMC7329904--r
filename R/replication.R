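#' @include AllClasses.R AllGenerics.R
NULL

#' Degree-3 kinship cutoff
#'
#' The relatedness cutoff used throughout: pairs with estimated kinship
#' coefficient at or above \code{1/2^(9/2)} (about 0.0442) are third-degree
#' relatives or closer and one member is removed before association.
#' @export
kinshipDegreeCutoff <- 2^(-9/2)

#' Derive estimated BMD from heel ultrasound
#'
#' Applies the heel quantitative-ultrasound calibration
#' \deqn{eBMD = 0.002592 (BUA + SOS) - 3.687}
#' mapping speed of sound (SOS, m/s) and broadband ultrasound attenuation
#' (BUA, dB/MHz) to estimated bone mineral density in g/cm^2.
#'
#' @param sos speed of sound, m/s.
#' @param bua broadband ultrasound attenuation, dB/MHz.
#' @return estimated BMD, g/cm^2 (vectorized).
#' @examples
#' deriveEBMD(1550, 80)   # 0.53796
#' @export
deriveEBMD <- function(sos, bua) {
  if (!all(is.finite(sos)) || !all(is.finite(bua)))
    stop("non-finite SOS/BUA input")
  .ebmd_slope * (bua + sos) + .ebmd_intercept
}

#' Ultrasound outlier QC thresholds
#'
#' Per-sex exclusion bounds for speed of sound (m/s), broadband ultrasound
#' attenuation (dB/MHz) and device-calculated BMD (g/cm^2). A record is an
#' outlier when any measure is at or beyond a bound (boundary values are
#' excluded). Defaults: SOS male (1450, 1750), female (1455, 1700); BUA
#' male (27, 138), female (22, 138); BMD male (0.18, 1.06), female
#' (0.12, 1.025).
#'
#' @param male,female named lists with numeric \code{c(lower, upper)}
#'   elements \code{sos}, \code{bua}, \code{bmd}.
#' @return a \code{QCThresholds} list.
#' @export
qcThresholds <- function(male = list(sos = c(1450, 1750), bua = c(27, 138),
                                     bmd = c(0.18, 1.06)),
                         female = list(sos = c(1455, 1700), bua = c(22, 138),
                                       bmd = c(0.12, 1.025))) {
  thr <- list(male = male, female = female)
  for (s in names(thr)) for (m in c("sos", "bua", "bmd")) {
    b <- thr[[s]][[m]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("invalid bounds for ", s, " ", m, ": need lower < upper")
  }
  structure(thr, class = "QCThresholds")
}

#' Apply ultrasound outlier QC
#'
#' Excludes participants whose SOS, BUA or BMD sits at or beyond the
#' per-sex bounds of [qcThresholds()]. With \code{use_ebmd = TRUE} the BMD
#' bound is applied to [deriveEBMD()] of the recorded SOS/BUA rather than
#' the device-calculated BMD (sensitivity analysis).
#'
#' @param cohort a [BiobankCohort-class] or a data.frame with columns sex,
#'   sos, bua, bmd_device.
#' @param thresholds a \code{QCThresholds} list.
#' @param use_ebmd logical; apply the BMD bound to the recalculated eBMD.
#' @return list with \code{retained} (object of the input type, outliers
#'   dropped) and \code{report} (per-measure, per-sex exclusion counts and
#'   the excluded sample indices).
#' @export
applyQC <- function(cohort, thresholds = qcThresholds(), use_ebmd = FALSE) {
  df <- if (is(cohort, "BiobankCohort")) covariates(cohort) else cohort
  if (!all(df$sex %in% c("male", "female")))
    stop("unknown sex label: ",
         paste(unique(setdiff(df$sex, c("male", "female"))), collapse = ", "))
  flags <- .qc_flags(df, thresholds, use_ebmd)
  excluded <- rowSums(flags) > 0
  counts <- do.call(rbind, lapply(c("male", "female"), function(s) {
    i <- df$sex == s
    data.frame(sex = s,
               sos = sum(flags$sos[i]), bua = sum(flags$bua[i]),
               bmd = sum(flags$bmd[i]), excluded = sum(excluded[i]))
  }))
  retained <- if (is(cohort, "BiobankCohort")) cohort[, !excluded]
              else cohort[!excluded, , drop = FALSE]
  list(retained = retained,
       report = list(counts = counts,
                     n_input = nrow(df), n_excluded = sum(excluded),
                     excluded_ids = if (!is.null(df$sample_id))
                       df$sample_id[excluded] else which(excluded)))
}

#' KING-robust kinship coefficient for one sample pair
#'
#' Moment estimator from heterozygote and opposite-homozygote counts over
#' shared non-missing sites:
#' \deqn{\hat\phi = (N_{Aa,Aa} - 2 N_{AA,aa}) / (N^{(i)}_{Aa} + N^{(j)}_{Aa})}
#' Symmetric in its arguments and invariant to allele relabeling
#' (\code{g -> 2 - g}) at any subset of sites. Expectation: 0.5 for
#' duplicates/MZ twins, 0.25 for parent-offspring and full siblings,
#' 0.125/0.0625 for second/third degree, 0 for unrelated pairs.
#'
#' @param a,b dosage vectors in \{0, 1, 2\} (NA allowed).
#' @param min_shared minimum shared non-missing variants; below the floor
#'   the pair is unassessable and \code{NA} is returned with a warning.
#' @return estimated kinship coefficient (phi).
#' @export
estimateKinship <- function(a, b, min_shared = 100L) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_shared) {
    warning("fewer than ", min_shared,
            " shared non-missing variants; kinship unassessable")
    return(NA_real_)
  }
  a <- a[ok]; b <- b[ok]
  het_a <- a == 1; het_b <- b == 1
  n_hethet <- sum(het_a & het_b)
  n_oppo <- sum((a == 0 & b == 2) | (a == 2 & b == 0))
  denom <- sum(het_a) + sum(het_b)
  if (denom == 0) return(NA_real_)
  (n_hethet - 2 * n_oppo) / denom
}

#' All-pairs related-sample scan
#'
#' Estimates the KING-robust kinship coefficient (see [estimateKinship()])
#' for every sample pair and returns the pairs at or above the threshold.
#' Genotypes are bit-packed and scanned in compiled code, making a full
#' biobank-scale scan (tens of thousands of samples, ~2e8 pairs) feasible.
#'
#' @param x a [BiobankCohort-class] (its genome-wide relatedness markers
#'   are used; with a warning, the candidate dosages if none), or a
#'   samples-by-variants dosage matrix (integer or raw; NA/other values are
#'   treated as missing).
#' @param threshold kinship cutoff; defaults to the degree-3 cutoff
#'   \code{2^(-9/2)}.
#' @param min_shared pairs sharing fewer non-missing variants are treated
#'   as unrelated (with a warning when any occur).
#' @return data.frame with columns sample_a, sample_b, phi, degree.
#' @export
kinshipPairs <- function(x, threshold = kinshipDegreeCutoff,
                         min_shared = 100L) {
  if (is(x, "BiobankCohort")) {
    ids <- sampleIDs(x)
    g <- kinshipMarkers(x)
    if (is.null(g)) {
      warning("cohort carries no relatedness markers; using candidate dosages")
      g <- t(dosages(x))
    }
  } else {
    g <- x
    ids <- rownames(g) %||% sprintf("S%05d", seq_len(nrow(g)))
  }
  if (!is.raw(g)) {
    storage.mode(g) <- "integer"
    g[is.na(g) | g < 0L | g > 2L] <- 3L
  }
  res <- king_pairs(g, threshold, as.integer(min_shared))
  if (res$n_low_shared > 0)
    warning(res$n_low_shared,
            " pair(s) below the shared-variant floor treated as unrelated")
  data.frame(sample_a = ids[res$i], sample_b = ids[res$j], phi = res$phi,
             degree = kinshipDegree(res$phi),
             stringsAsFactors = FALSE)
}

#' Classify kinship coefficients into relationship degrees
#'
#' KING degree intervals on powers of two: duplicate/MZ above
#' \code{2^(-3/2)}, then first/second/third degree down to the degree-3
#' cutoff \code{2^(-9/2)}; below it, unrelated.
#'
#' @param phi numeric kinship coefficients.
#' @return character vector of degree labels.
#' @export
kinshipDegree <- function(phi) {
  cut(phi,
      breaks = c(-Inf, 2^(-9/2), 2^(-7/2), 2^(-5/2), 2^(-3/2), Inf),
      labels = c("unrelated", "third_degree", "second_degree",
                 "first_degree", "duplicate"),
      right = FALSE) |> as.character()
}

#' Select an unrelated sample set
#'
#' Greedy removal: while any pair at or above the threshold remains among
#' the retained samples, remove the member with the larger number of
#' related partners (ties broken towards the lexicographically larger
#' sample ID). The result contains no pair at or above the threshold; when
#' only one pair involves a sample, exactly one member is dropped.
#'
#' @param samples character vector of sample IDs under consideration.
#' @param pairs data.frame from [kinshipPairs()] (columns sample_a,
#'   sample_b, phi).
#' @param threshold kinship cutoff, default the degree-3 cutoff.
#' @return character vector of retained sample IDs (input order).
#' @export
selectUnrelated <- function(samples, pairs, threshold = kinshipDegreeCutoff) {
  keep <- rep(TRUE, length(samples))
  names(keep) <- samples
  act <- pairs[pairs$phi >= threshold &
                 pairs$sample_a %in% samples & pairs$sample_b %in% samples, ,
               drop = FALSE]
  while (nrow(act) > 0) {
    deg <- table(c(act$sample_a, act$sample_b))
    worst <- max(deg)
    drop <- max(names(deg)[deg == worst])  # lexicographically larger on ties
    keep[drop] <- FALSE
    act <- act[act$sample_a != drop & act$sample_b != drop, , drop = FALSE]
  }
  samples[keep]
}

#' Sex-specific standardized BMD Z-scores
#'
#' Within each sex, fits ordinary least squares of BMD on intercept, age,
#' age^2 and weight, and standardizes the residuals by their sample
#' standard deviation, so each sex stratum has mean 0 and SD 1 before
#' exclusions. Samples with |Z| > \code{z_bound} are then excluded.
#'
#' @param covars data.frame with columns sample_id, sex, age, weight.
#' @param bmd numeric BMD values aligned with \code{covars} rows.
#' @param z_bound exclusion bound on |Z| (default 4).
#' @return list with \code{z} (named numeric, retained samples),
#'   \code{excluded} (sample IDs with |Z| > bound) and \code{fits}
#'   (per-sex coefficient tables).
#' @export
zscorePhenotype <- function(covars, bmd, z_bound = 4) {
  stopifnot(nrow(covars) == length(bmd))
  z <- rep(NA_real_, nrow(covars))
  fits <- list()
  for (s in unique(covars$sex)) {
    i <- which(covars$sex == s)
    if (length(i) < 5)
      stop("fewer samples than regression parameters in sex stratum '", s, "'")
    X <- cbind(1, covars$age[i], covars$age[i]^2, covars$weight[i])
    colnames(X) <- c("(Intercept)", "age", "age2", "weight")
    fit <- stats::lm.fit(X, bmd[i])
    r <- fit$residuals
    z[i] <- r / stats::sd(r)
    fits[[s]] <- stats::setNames(fit$coefficients, colnames(X))
  }
  names(z) <- covars$sample_id
  out <- abs(z) > z_bound
  list(z = z[!out], excluded = covars$sample_id[out], fits = fits)
}

#' Per-SNP association with the BMD Z-score
#'
#' Ordinary least squares of the Z-score on intercept, allele dosage and
#' the first 15 ancestry principal components; reports the dosage term's
#' effect, standard error, two-sided t-test p-value (n - 17 df), 95\%
#' confidence interval, and whether the SNP replicates at genome-wide
#' significance.
#'
#' @param z named numeric Z-scores (output of [zscorePhenotype()]).
#' @param dosage numeric allele dosages aligned with \code{z}.
#' @param pcs numeric matrix of 15 principal-component columns aligned with
#'   \code{z}.
#' @param rsid,effect_allele annotations carried into the result.
#' @param gws genome-wide significance level (default 5e-8).
#' @param missing how to handle missing dosages: \code{"mean"} imputes the
#'   SNP's mean dosage, \code{"drop"} removes the samples.
#' @return one-row data.frame: rsid, effect_allele, beta, se, p, n_used,
#'   ci_low, ci_high, replicated.
#' @export
snpAssociation <- function(z, dosage, pcs, rsid = NA_character_,
                           effect_allele = NA_character_, gws = 5e-8,
                           missing = c("mean", "drop")) {
  missing <- match.arg(missing)
  stopifnot(length(dosage) == length(z), nrow(pcs) == length(z))
  if (anyNA(dosage)) {
    if (missing == "mean") {
      dosage[is.na(dosage)] <- mean(dosage, na.rm = TRUE)
    } else {
      ok <- !is.na(dosage)
      z <- z[ok]; dosage <- dosage[ok]; pcs <- pcs[ok, , drop = FALSE]
    }
  }
  n <- length(z)
  if (n < ncol(pcs) + 4)
    stop("too few complete-case samples for the association model")
  if (stats::sd(dosage) == 0)
    stop("monomorphic dosage after imputation for SNP ", rsid)
  X <- cbind(`(Intercept)` = 1, dosage = dosage, pcs)
  fit <- stats::lm.fit(X, z)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(qr.R(fit$qr))  # pivoted order
  ii <- which(fit$qr$pivot == 2L)    # position of the dosage column
  se <- sqrt(sigma2 * XtX_inv[ii, ii])
  beta <- fit$coefficients[["dosage"]]
  p <- 2 * stats::pt(-abs(beta / se), df)
  data.frame(rsid = rsid, effect_allele = effect_allele,
             beta = beta, se = se, p = p, n_used = n,
             ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
             replicated = p < gws,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Direction-of-effect concordance between stages
#'
#' Harmonizes each replication result to the discovery effect allele (the
#' replication beta's sign is flipped when effect and other alleles are
#' swapped; an allele-set mismatch is recorded as an error entry and
#' excluded), flags strand-ambiguous palindromic SNPs (A/T or C/G) with
#' MAF > 0.4 and excludes them from the denominator, and reports per-SNP
#' concordance plus the overall concordant fraction.
#'
#' @param discovery data.frame of discovery summary statistics (rsid,
#'   effect_allele, other_allele, eaf, beta).
#' @param replication data.frame of [snpAssociation()] results (rsid,
#'   effect_allele, beta); the replication other allele is taken from
#'   \code{replication$other_allele} when present, otherwise inferred from
#'   discovery.
#' @return list with \code{table} (per-SNP status and concordance) and
#'   \code{fraction} (concordant / assessable).
#' @export
directionConcordance <- function(discovery, replication) {
  m <- merge(replication, discovery, by = "rsid",
             suffixes = c(".rep", ".disc"))
  pick <- function(base, side) {
    suff <- paste0(base, ".", side)
    toupper(if (suff %in% colnames(m)) m[[suff]] else m[[base]])
  }
  ea_d <- pick("effect_allele", "disc")
  oa_d <- pick("other_allele", "disc")
  ea_r <- pick("effect_allele", "rep")
  oa_r <- if ("other_allele" %in% colnames(replication))
    pick("other_allele", "rep")
  else ifelse(ea_r == ea_d, oa_d, ea_d)  # infer from discovery alleles
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palindromic <- oa_d == comp[ea_d]
  maf_d <- pmin(m$eaf, 1 - m$eaf)
  status <- character(nrow(m))
  beta_rep <- m$beta.rep
  for (i in seq_len(nrow(m))) {
    if (ea_r[i] == ea_d[i] && oa_r[i] == oa_d[i]) {
      status[i] <- "same"
    } else if (ea_r[i] == oa_d[i] && oa_r[i] == ea_d[i]) {
      status[i] <- "swapped"; beta_rep[i] <- -beta_rep[i]
    } else {
      status[i] <- "allele_mismatch"
    }
  }
  status[palindromic & maf_d > 0.4] <- "ambiguous_palindromic"
  assessable <- status %in% c("same", "swapped")
  concordant <- assessable & sign(beta_rep) == sign(m$beta.disc)
  tab <- data.frame(rsid = m$rsid, status = status,
                    beta_discovery = m$beta.disc,
                    beta_replication_harmonized = ifelse(assessable, beta_rep, NA),
                    concordant = ifelse(assessable, concordant, NA),
                    stringsAsFactors = FALSE)
  list(table = tab,
       fraction = if (any(assessable)) sum(concordant) / sum(assessable)
                  else NA_real_)
}
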