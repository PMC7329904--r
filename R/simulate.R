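#' @include AllClasses.R AllGenerics.R
NULL

# Latent-phenotype scale: latent eBMD (g/cm^2) = .bmd_base + .bmd_scale * raw,
# where `raw` is the standardized latent (genetics + covariates + noise).
.bmd_base <- 0.55
.bmd_scale <- 0.10

# eBMD formula constants (heel ultrasound calibration).
.ebmd_slope <- 0.002592
.ebmd_intercept <- -3.687

.default_covariate_effects <- c(age = -0.02, age2 = -0.0005,
                                weight = 0.01, sex_male = 0.3)

.nonbone_traits <- c(
  "Height", "Waist circumference", "Parkinson's disease",
  "Atopic dermatitis", "Allergic disease", "Coffee consumption",
  "Educational attainment", "Blood protein levels", "Magnesium levels",
  "Urinary magnesium/calcium ratio", "Male-pattern baldness",
  "Noncardia gastric cancer", "High light scatter reticulocyte count",
  "Inflammatory bowel disease", "Type 2 diabetes", "Body mass index",
  "Systolic blood pressure", "LDL cholesterol", "Triglycerides",
  "Rheumatoid arthritis", "Asthma", "Hay fever", "Schizophrenia",
  "Chronotype", "Smoking initiation", "Platelet count",
  "Red blood cell count", "Serum urate levels", "Gout",
  "Age at menarche")

#' Build a simulation configuration
#'
#' Constructs a validated [SimulationConfig-class]. See the class
#' documentation for the meaning of each parameter; the defaults are the
#' package's reference study conditions.
#'
#' @param seed integer seed driving all generator randomness.
#' @param n_panel_samples,n_biobank_samples,n_blocks,snps_per_block,maf_range,within_block_r2,n_catalog_traits,n_planted_pleiotropic,n_decoy_signals,n_known_bmd_planted,effect_size_sd,gwas_n,n_related_pairs,relationship_mix,covariate_effects,noise_sd,qc_fail_fraction,n_kinship_snps see [SimulationConfig-class].
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1, n_blocks = 4, snps_per_block = 3,
#'                         n_biobank_samples = 200, n_kinship_snps = 100)
#' @export
simulationConfig <- function(seed = 1L,
                             n_panel_samples = 1000L,
                             n_biobank_samples = 20000L,
                             n_blocks = 401L,
                             snps_per_block = 5L,
                             maf_range = c(0.05, 0.5),
                             within_block_r2 = 0.6,
                             n_catalog_traits = 30L,
                             n_planted_pleiotropic = 3L,
                             n_decoy_signals = 2L,
                             n_known_bmd_planted = 1L,
                             effect_size_sd = 0.08,
                             gwas_n = 80000L,
                             n_related_pairs = 60L,
                             relationship_mix = c(duplicate = 0.2,
                                                  parent_offspring = 0.2,
                                                  full_sib = 0.2,
                                                  second_degree = 0.2,
                                                  third_degree = 0.2),
                             covariate_effects = .default_covariate_effects,
                             noise_sd = 1,
                             qc_fail_fraction = 0.005,
                             n_kinship_snps = 16000L) {
  new("SimulationConfig",
      seed = as.integer(seed),
      n_panel_samples = as.integer(n_panel_samples),
      n_biobank_samples = as.integer(n_biobank_samples),
      n_blocks = as.integer(n_blocks),
      snps_per_block = as.integer(snps_per_block),
      maf_range = as.numeric(maf_range),
      within_block_r2 = as.numeric(within_block_r2),
      n_catalog_traits = as.integer(n_catalog_traits),
      n_planted_pleiotropic = as.integer(n_planted_pleiotropic),
      n_decoy_signals = as.integer(n_decoy_signals),
      n_known_bmd_planted = as.integer(n_known_bmd_planted),
      effect_size_sd = as.numeric(effect_size_sd),
      gwas_n = as.integer(gwas_n),
      n_related_pairs = as.integer(n_related_pairs),
      relationship_mix = relationship_mix,
      covariate_effects = as.numeric(covariate_effects) |>
        stats::setNames(names(covariate_effects)),
      noise_sd = as.numeric(noise_sd),
      qc_fail_fraction = as.numeric(qc_fail_fraction),
      n_kinship_snps = as.integer(n_kinship_snps))
}

# Variant layout shared by panel and cohort generation. Blocks are spread
# over chromosomes 1..22 with >1 Mb between blocks so the default 500 kb
# proxy window never spans blocks.
.variant_layout <- function(config) {
  nb <- config@n_blocks; k <- config@snps_per_block
  block <- rep(seq_len(nb), each = k)
  within <- rep(seq_len(k), times = nb)
  chrom <- as.character(((block - 1L) %% 22L) + 1L)
  chrom_rank <- (block - 1L) %/% 22L
  pos <- 1e6 + chrom_rank * 2e6 + (within - 1L) * 1000
  data.frame(rsid = sprintf("rs%06d", seq_len(nb * k)),
             chrom = chrom, pos = as.integer(pos),
             block = block, within = within,
             ref = "A", alt = "G",
             stringsAsFactors = FALSE)
}

# Per-block generating allele frequencies and anchor-pair orientation.
.block_params <- function(config) {
  freq <- stats::runif(config@n_blocks, config@maf_range[1], config@maf_range[2])
  pair_complementary <- (seq_len(config@n_blocks) %% 2L) == 0L
  list(freq = freq, pair_complementary = pair_complementary)
}

# Haplotype-copy genotype generator: for each block an anchor haplotype z is
# drawn per chromosome; SNPs 1-2 equal z (SNP 2 complemented in alternating
# blocks), later SNPs copy z with probability sqrt(within_block_r2) so their
# r^2 with the anchor is ~within_block_r2. Returns an n x m integer dosage
# matrix of alternate-allele counts.
.gen_genotypes <- function(n, layout, freq, pair_complementary, rho) {
  m <- nrow(layout)
  g <- matrix(0L, nrow = n, ncol = m)
  for (b in unique(layout$block)) {
    idx <- which(layout$block == b)
    f <- freq[b]
    z <- stats::rbinom(2L * n, 1L, f)
    for (j in seq_along(idx)) {
      w <- layout$within[idx[j]]
      if (w == 1L) x <- z
      else if (w == 2L) x <- if (pair_complementary[b]) 1L - z else z
      else {
        copy <- stats::rbinom(2L * n, 1L, rho)
        x <- ifelse(copy == 1L, z, stats::rbinom(2L * n, 1L, f))
      }
      g[, idx[j]] <- x[seq_len(n)] + x[n + seq_len(n)]
    }
  }
  g
}

#' Simulate a genotype reference panel
#'
#' Generates an LD-structured reference panel under the haplotype-copy
#' scheme described in [SimulationConfig-class]: every block carries a
#' perfect-LD anchor pair (identical in odd blocks, complementary in even
#' blocks), non-anchor SNPs have r^2 of about \code{within_block_r2} with
#' the anchors, and blocks are mutually independent.
#'
#' @param config a [SimulationConfig-class].
#' @return a [ReferencePanel-class]. Block assignment is kept in the variant
#'   metadata; the generating allele frequencies are stored in
#'   \code{metadata()$generating}.
#' @examples
#' panel <- simulateReferencePanel(
#'   simulationConfig(seed = 7, n_blocks = 2, snps_per_block = 3,
#'                    n_panel_samples = 50))
#' panel
#' @export
simulateReferencePanel <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  with_seed(stage_seed(config@seed, "panel"), {
    layout <- .variant_layout(config)
    bp <- .block_params(config)
    rho <- sqrt(config@within_block_r2)
    g <- .gen_genotypes(config@n_panel_samples, layout, bp$freq,
                        bp$pair_complementary, rho)
    afreq <- colMeans(g) / 2
    gr <- GenomicRanges::GRanges(
      seqnames = layout$chrom,
      ranges = IRanges::IRanges(start = layout$pos, width = 1L),
      rsid = layout$rsid, ref = layout$ref, alt = layout$alt,
      maf = pmin(afreq, 1 - afreq), block = layout$block)
    names(gr) <- layout$rsid
    samples <- sprintf("P%05d", seq_len(config@n_panel_samples))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(dosage = t(g)),
      rowRanges = gr,
      colData = S4Vectors::DataFrame(row.names = samples))
    panel <- new("ReferencePanel", se)
    S4Vectors::metadata(panel)$generating <- data.frame(
      rsid = layout$rsid, block = layout$block,
      freq_alt = ifelse(layout$within == 2L & bp$pair_complementary[layout$block],
                        1 - bp$freq[layout$block], bp$freq[layout$block]),
      stringsAsFactors = FALSE)
    panel
  })
}

# Assign signal roles to blocks/variants. Planted and decoy effects sit on
# SNP 3 of their block (the first non-anchor SNP) so that anchor proxies and
# decaying-LD block-mates exercise proxy lookup and pruning; the
# known-BMD-proxy signal sits on a block anchor whose perfect twin is
# declared a known BMD SNP.
.assign_signals <- function(config, layout) {
  n_sig <- config@n_planted_pleiotropic + config@n_decoy_signals +
    config@n_known_bmd_planted
  blocks <- sample(config@n_blocks, n_sig)
  eff_idx <- if (config@snps_per_block >= 3L) 3L else 1L
  roles <- rep(c("planted", "decoy", "known_bmd_signal"),
               c(config@n_planted_pleiotropic, config@n_decoy_signals,
                 config@n_known_bmd_planted))
  out <- data.frame(block = blocks, role = roles,
                    stringsAsFactors = FALSE)
  out$within <- ifelse(out$role == "known_bmd_signal", 1L, eff_idx)
  out$rsid <- layout$rsid[match(
    paste(out$block, out$within), paste(layout$block, layout$within))]
  out$beta <- config@effect_size_sd * sample(c(-1, 1), n_sig, replace = TRUE)
  out$twin_rsid <- ifelse(
    out$role == "known_bmd_signal",
    layout$rsid[match(paste(out$block, 2L), paste(layout$block, layout$within))],
    NA_character_)
  out
}

#' Simulate a GWAS-catalog-style association table
#'
#' Produces the catalog input of the pipeline: one genome-wide-significant
#' non-bone association per panel variant (the candidate records), plus a
#' deliberate set of records that each curation rule must remove
#' (non-genome-wide-significant entries, interaction and haplotype flags,
#' missing rsIDs, bone-related traits, known BMD SNPs, pleiotropy-rule
#' traits, duplicates), with the injected counts recorded in the truth
#' table.
#'
#' @param config a [SimulationConfig-class].
#' @param panel the [ReferencePanel-class] from [simulateReferencePanel()].
#' @return list with elements \code{catalog} (data.frame in the default
#'   catalog dialect, see [readCatalog()]) and \code{truth} (a
#'   \code{TruthTable} list: \code{$variants}, \code{$catalog},
#'   \code{$known_bmd_snps}, \code{$counts}).
#' @export
simulateCatalog <- function(config, panel) {
  stopifnot(is(config, "SimulationConfig"), is(panel, "ReferencePanel"))
  with_seed(stage_seed(config@seed, "catalog"), {
    layout <- .variant_layout(config)
    gen <- S4Vectors::metadata(panel)$generating
    signals <- .assign_signals(config, layout)

    traits <- .nonbone_traits[seq_len(min(config@n_catalog_traits,
                                          length(.nonbone_traits)))]
    # variant truth
    vt <- data.frame(rsid = layout$rsid, block = layout$block,
                     within = layout$within,
                     role = "null", beta_stats = 0, beta_bmd = 0,
                     trait = sample(traits, nrow(layout), replace = TRUE),
                     freq_alt = gen$freq_alt,
                     stringsAsFactors = FALSE)
    i <- match(signals$rsid, vt$rsid)
    vt$role[i] <- signals$role
    vt$beta_stats[i] <- signals$beta
    vt$beta_bmd[i] <- ifelse(signals$role == "decoy", 0, signals$beta)
    twin <- signals$twin_rsid[!is.na(signals$twin_rsid)]
    vt$role[vt$rsid %in% twin] <- "known_bmd_twin"
    known_bmd <- twin

    gws_p <- function(n) 10^(-stats::runif(n, 8.5, 30))
    mk_row <- function(rsid, trait, p, hap = FALSE, int = FALSE) {
      j <- match(rsid, layout$rsid)
      data.frame(rsid = rsid,
                 chrom = ifelse(is.na(j), "1", layout$chrom[j]),
                 pos = ifelse(is.na(j), 1L, layout$pos[j]),
                 trait = trait, trait_category = trait,
                 p_value = p, effect_allele = "G",
                 effect_size = round(stats::runif(length(rsid), 0.02, 0.3), 3),
                 eaf = ifelse(is.na(j), 0.25, round(gen$freq_alt[j], 4)),
                 ancestry = sample(c("European", "East Asian", "Mixed"),
                                   length(rsid), replace = TRUE,
                                   prob = c(0.8, 0.1, 0.1)),
                 study_id = sprintf("GCST%06d", sample.int(999999, length(rsid))),
                 is_haplotype = hap, is_interaction = int,
                 stringsAsFactors = FALSE)
    }

    # candidate records: every panel variant except the known-BMD twin(s)
    cand_rsid <- setdiff(layout$rsid, known_bmd)
    rows <- mk_row(cand_rsid, vt$trait[match(cand_rsid, vt$rsid)],
                   gws_p(length(cand_rsid)))
    truth_rows <- data.frame(rsid = rows$rsid, expected_excluded = FALSE,
                             rule = NA_character_, stringsAsFactors = FALSE)
    add <- function(r, rule) {
      rows <<- rbind(rows, r)
      truth_rows <<- rbind(truth_rows,
                           data.frame(rsid = r$rsid, expected_excluded = TRUE,
                                      rule = rule, stringsAsFactors = FALSE))
    }

    counts <- list(non_gws = 5L, interaction = 3L, haplotype = 3L,
                   missing_rsid = 4L, bone_trait = 6L, known_bmd = 1L,
                   pleiotropy_rule = 2L, duplicate = 4L)
    some <- function(n) sample(cand_rsid, n)
    add(mk_row(some(counts$non_gws), "Asthma",
               stats::runif(counts$non_gws, 6e-8, 1e-4)), "non_gws")
    add(mk_row(some(counts$interaction), "Type 2 diabetes",
               gws_p(counts$interaction), int = TRUE), "interaction")
    add(mk_row(some(counts$haplotype), "Height",
               gws_p(counts$haplotype), hap = TRUE), "haplotype")
    add(mk_row(rep(NA_character_, counts$missing_rsid), "Platelet count",
               gws_p(counts$missing_rsid)), "missing_rsid")
    bone_traits <- c("Osteoporosis", "Bone mineral density", "Fracture risk",
                     "Calcium levels", "Heel bone mineral density",
                     "Bone mineral density (spine)")
    bone_ids <- c(known_bmd,
                  sprintf("rsBONE%02d", seq_len(counts$bone_trait - length(known_bmd))))
    add(mk_row(bone_ids, bone_traits[seq_along(bone_ids)], gws_p(length(bone_ids))),
        "bone_trait")
    # a null variant listed among known BMD SNPs, carrying a non-bone trait
    known_null <- sample(vt$rsid[vt$role == "null"], counts$known_bmd)
    known_bmd <- c(known_bmd, known_null)
    add(mk_row(known_null, "Chronotype", gws_p(counts$known_bmd)), "known_bmd")
    add(mk_row(sprintf("rsPLEI%02d", seq_len(counts$pleiotropy_rule)),
               c("Vitamin D levels", "Skeletal size")[seq_len(counts$pleiotropy_rule)],
               gws_p(counts$pleiotropy_rule)), "pleiotropy_rule")
    dup_rsid <- sample(setdiff(cand_rsid, known_bmd), counts$duplicate)
    add(mk_row(dup_rsid, sample(traits, counts$duplicate, replace = TRUE),
               gws_p(counts$duplicate)), "duplicate")

    # the known-BMD-listed null and twin must not count as candidates
    truth_rows$expected_excluded[truth_rows$rsid %in% known_bmd] <- TRUE
    truth_rows$rule[truth_rows$rsid %in% known_bmd &
                      is.na(truth_rows$rule)] <- "known_bmd"
    vt$role[vt$rsid %in% known_null] <- "known_bmd_null"

    catalog <- data.frame(
      SNPS = rows$rsid, CHR_ID = rows$chrom, CHR_POS = rows$pos,
      `DISEASE/TRAIT` = rows$trait, MAPPED_TRAIT = rows$trait_category,
      `P-VALUE` = rows$p_value, EFFECT_ALLELE = rows$effect_allele,
      OR_BETA = rows$effect_size, EAF = rows$eaf, ANCESTRY = rows$ancestry,
      STUDY_ACCESSION = rows$study_id, IS_HAPLOTYPE = rows$is_haplotype,
      IS_INTERACTION = rows$is_interaction,
      check.names = FALSE, stringsAsFactors = FALSE)

    truth <- structure(list(variants = vt, catalog = truth_rows,
                            known_bmd_snps = known_bmd, counts = counts,
                            signals = signals),
                       class = "TruthTable")
    list(catalog = catalog, truth = truth)
  })
}

#' Simulate GWAS summary statistics for one BMD trait
#'
#' Draws per-SNP effect estimates \code{beta = true beta + N(0, se)} with
#' \code{se = 1/sqrt(2 maf (1-maf) gwas_n)} (standardized phenotype,
#' per-allele effects) and two-sided normal p-values. Planted signal blocks
#' propagate attenuated effects to their block-mates in proportion to the
#' signed panel correlation r with the causal SNP, as marginal GWAS effects
#' do under LD.
#'
#' @param config a [SimulationConfig-class].
#' @param panel the reference panel (source of allele frequencies and LD).
#' @param truth truth table from [simulateCatalog()].
#' @param trait \code{"FN"} or \code{"LS"} (femoral neck / lumbar spine).
#' @param snps rsIDs to generate statistics for; defaults to every panel
#'   variant. Requesting a SNP absent from the panel is an error.
#' @return data.frame with columns rsid, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, p, n, trait.
#' @export
simulateSummaryStats <- function(config, panel, truth,
                                 trait = c("FN", "LS"),
                                 snps = NULL) {
  stopifnot(is(config, "SimulationConfig"), is(panel, "ReferencePanel"),
            inherits(truth, "TruthTable"))
  trait <- match.arg(trait)
  vi <- variantInfo(panel)
  if (is.null(snps)) snps <- vi$rsid
  missing <- setdiff(snps, vi$rsid)
  if (length(missing))
    stop("SNP(s) absent from panel: ", paste(utils::head(missing, 5), collapse = ", "))
  with_seed(stage_seed(config@seed, if (trait == "FN") "stats_fn" else "stats_ls"), {
    d <- dosages(panel)
    idx <- match(snps, vi$rsid)
    eaf <- colMeans(t(d[idx, , drop = FALSE])) / 2
    if (any(eaf <= 0 | eaf >= 1))
      stop("monomorphic variant(s) in panel: MAF of 0 or 1 rejected")
    maf <- pmin(eaf, 1 - eaf)

    # marginal standardized effects: within a signal block, beta_j = r_jc * beta_c
    beta_std <- numeric(length(snps))
    sig <- truth$signals
    vt <- truth$variants
    for (s in seq_len(nrow(sig))) {
      in_block <- which(vt$block[idx] == sig$block[s])
      if (!length(in_block)) next
      causal <- d[sig$rsid[s], ]
      for (j in in_block) {
        r <- r_pair(d[idx[j], ], causal)
        beta_std[j] <- beta_std[j] + (if (is.na(r)) 0 else r) * sig$beta[s]
      }
    }
    sd_g <- sqrt(2 * maf * (1 - maf))
    beta_true <- beta_std / sd_g
    se <- 1 / sqrt(2 * maf * (1 - maf) * config@gwas_n)
    beta_hat <- stats::rnorm(length(snps), beta_true, se)
    p <- pmax(2 * stats::pnorm(-abs(beta_hat / se)), .Machine$double.xmin)
    data.frame(rsid = snps, chrom = vi$chrom[idx], pos = vi$pos[idx],
               effect_allele = vi$alt[idx], other_allele = vi$ref[idx],
               eaf = eaf, beta = beta_hat, se = se, p = p,
               n = config@gwas_n,
               trait = paste0(trait, "-BMD"),
               stringsAsFactors = FALSE)
  })
}

# Derive one relative's dosage vector from a base sample under per-locus
# identity-by-descent sharing appropriate to the relationship class.
.derive_relative <- function(g, f, class) {
  m <- length(g)
  pop <- function() stats::rbinom(m, 1L, f)
  from_parent <- function() stats::rbinom(m, 1L, g / 2)
  switch(class,
    duplicate = g,
    parent_offspring = from_parent() + pop(),
    full_sib = {
      ibd <- sample(0:2, m, replace = TRUE, prob = c(0.25, 0.5, 0.25))
      ifelse(ibd == 2L, g,
             ifelse(ibd == 1L, from_parent() + pop(), pop() + pop()))
    },
    second_degree = {
      share <- stats::rbinom(m, 1L, 0.5)
      ifelse(share == 1L, from_parent(), pop()) + pop()
    },
    third_degree = {
      share <- stats::rbinom(m, 1L, 0.25)
      ifelse(share == 1L, from_parent(), pop()) + pop()
    },
    stop("unknown relationship class: ", class))
}

# Per-measure QC flags under the printed boundary-inclusive bounds; shared
# by the simulator's truth bookkeeping and applyQC().
.qc_flags <- function(df, thresholds, use_ebmd = FALSE) {
  bmd_val <- if (use_ebmd) deriveEBMD(df$sos, df$bua) else df$bmd_device
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (measure in c("sos", "bua", "bmd")) {
    val <- switch(measure, sos = df$sos, bua = df$bua, bmd = bmd_val)
    lo <- vapply(df$sex, function(s) thresholds[[s]][[measure]][1], numeric(1))
    hi <- vapply(df$sex, function(s) thresholds[[s]][[measure]][2], numeric(1))
    out[[measure]] <- val <= lo | val >= hi
  }
  out
}

#' Simulate an individual-level replication cohort
#'
#' Generates a biobank-style cohort: candidate-variant genotypes under the
#' same LD-block scheme as the panel, a genome-wide relatedness marker set,
#' related sample pairs sharing genotypes by descent, covariates (age
#' uniform on 40-69, weight normal truncated at 30 kg, sex balanced), and
#' heel-ultrasound measures constructed so that
#' \code{0.002592 (BUA + SOS) - 3.687} reproduces the latent eBMD exactly.
#' A \code{qc_fail_fraction} of records is pushed outside (or exactly onto)
#' the printed ultrasound QC bounds, with reasons recorded in the truth
#' table.
#'
#' @param config a [SimulationConfig-class].
#' @param panel the reference panel (defines the candidate variant set).
#' @param truth truth table from [simulateCatalog()]; returned augmented
#'   with per-sample records (\code{$samples}) and per-variant true
#'   per-allele slopes on the latent eBMD scale (\code{$variants$slope_ebmd}).
#' @return list with elements \code{cohort} (a [BiobankCohort-class]) and
#'   \code{truth}.
#' @export
simulateBiobank <- function(config, panel, truth) {
  stopifnot(is(config, "SimulationConfig"), is(panel, "ReferencePanel"),
            inherits(truth, "TruthTable"))
  n <- config@n_biobank_samples
  k <- config@n_related_pairs
  if (2L * k > n)
    stop("relationship_mix/n_related_pairs inconsistent with cohort size: ",
         "need at least 2*n_related_pairs samples")
  with_seed(stage_seed(config@seed, "biobank"), {
    layout <- .variant_layout(config)
    gen <- S4Vectors::metadata(panel)$generating
    bp_freq <- tapply(gen$freq_alt, gen$block,
                      function(x) x[1])[as.character(seq_len(config@n_blocks))]
    # reconstruct block-level anchor frequency / orientation from metadata
    pair_comp <- (seq_len(config@n_blocks) %% 2L) == 0L
    rho <- sqrt(config@within_block_r2)
    g <- .gen_genotypes(n, layout, as.numeric(bp_freq), pair_comp, rho)
    colnames(g) <- layout$rsid

    # genome-wide relatedness markers (independent loci)
    mk <- config@n_kinship_snps
    kin <- NULL
    kin_f <- NULL
    if (mk > 0L) {
      kin_f <- stats::runif(mk, 0.05, 0.5)
      kin <- matrix(raw(0), nrow = n, ncol = mk)
      chunk <- 2000L
      for (s in seq(1L, mk, by = chunk)) {
        e <- min(s + chunk - 1L, mk)
        blockm <- matrix(stats::rbinom(n * (e - s + 1L), 2L,
                                       rep(kin_f[s:e], each = n)),
                         nrow = n)
        kin[, s:e] <- as.raw(blockm)
      }
    }

    # related pairs: relative i' = n - k + j derived from base sample j
    relationship <- rep(NA_character_, n)
    relative_of <- rep(NA_integer_, n)
    if (k > 0L) {
      # largest-remainder allocation of the k pairs over the class mix
      exact <- config@relationship_mix[.relationship_classes] * k
      cnt <- floor(exact)
      rem <- k - sum(cnt)
      if (rem > 0) {
        ord <- order(exact - cnt, decreasing = TRUE)
        cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
      }
      classes <- sample(rep(.relationship_classes, times = cnt))
      for (j in seq_len(k)) {
        tgt <- n - k + j
        g[tgt, ] <- .derive_relative(g[j, ], gen$freq_alt, classes[j])
        if (!is.null(kin))
          kin[tgt, ] <- as.raw(.derive_relative(as.integer(kin[j, ]),
                                                kin_f, classes[j]))
        relationship[tgt] <- classes[j]
        relative_of[tgt] <- j
      }
    }

    # covariates
    sex <- sample(c("female", "male"), n, replace = TRUE)
    age <- stats::runif(n, 40, 69)
    weight <- pmax(30, stats::rnorm(n, 78, 15))
    pcs <- matrix(stats::rnorm(n * 15L), n, 15L,
                  dimnames = list(NULL, paste0("PC", 1:15)))

    # latent standardized phenotype
    sig <- truth$signals
    gscore <- numeric(n)
    slope_ebmd <- numeric(nrow(layout))
    for (s in seq_len(nrow(sig))) {
      if (sig$role[s] == "decoy") next
      f <- gen$freq_alt[match(sig$rsid[s], gen$rsid)]
      sdg <- sqrt(2 * f * (1 - f))
      gscore <- gscore + sig$beta[s] * (g[, sig$rsid[s]] - 2 * f) / sdg
      slope_ebmd[match(sig$rsid[s], layout$rsid)] <-
        .bmd_scale * sig$beta[s] / sdg
    }
    ce <- config@covariate_effects
    raw_lat <- gscore +
      ce[["age"]] * (age - 55) + ce[["age2"]] * (age - 55)^2 +
      ce[["weight"]] * (weight - 78) + ce[["sex_male"]] * (sex == "male") +
      stats::rnorm(n, 0, config@noise_sd)
    latent <- .bmd_base + .bmd_scale * raw_lat

    # split latent eBMD into SOS + BUA, exactly invertible
    total <- (latent - .ebmd_intercept) / .ebmd_slope
    sos <- total / 2 + 733 + stats::rnorm(n, 0, 8)
    bua <- total - sos
    bmd_device <- .ebmd_slope * (sos + bua) + .ebmd_intercept

    # inject QC failures: cycle over the six bounds, alternating exactly-on
    # and strictly-outside placements
    thr <- qcThresholds()
    nf <- round(config@qc_fail_fraction * n)
    injected <- integer(0)
    if (nf > 0L) {
      injected <- sample(n, nf)
      modes <- rep(c("sos_lo", "sos_hi", "bua_lo", "bua_hi",
                     "bmd_lo", "bmd_hi"), length.out = nf)
      on_bound <- rep(c(TRUE, FALSE), length.out = nf)
      for (t in seq_len(nf)) {
        i <- injected[t]
        b <- thr[[sex[i]]]
        ms <- strsplit(modes[t], "_")[[1]]
        bound <- if (ms[2] == "lo") b[[ms[1]]][1] else b[[ms[1]]][2]
        tgt <- bound + (if (on_bound[t]) 0 else
                          (if (ms[2] == "lo") -1 else 1) * (abs(bound) * 0.02 + 1e-3))
        if (ms[1] == "sos") {
          sos[i] <- tgt
        } else if (ms[1] == "bua") {
          bua[i] <- tgt
        } else {
          # move both measures so the device formula lands on the target BMD
          tot <- (tgt - .ebmd_intercept) / .ebmd_slope
          sos[i] <- tot / 2 + 733
          bua[i] <- tot - sos[i]
        }
        bmd_device[i] <- .ebmd_slope * (sos[i] + bua[i]) + .ebmd_intercept
      }
    }

    sample_id <- sprintf("B%06d", seq_len(n))
    cd <- S4Vectors::DataFrame(
      sample_id = sample_id, sex = sex, age = age, weight = weight,
      sos = sos, bua = bua, bmd_device = bmd_device,
      entry_mode = sample(c("direct", "manual"), n, TRUE, prob = c(0.95, 0.05)),
      pcs, row.names = sample_id)

    gr <- SummarizedExperiment::rowRanges(panel)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(dosage = t(g)), rowRanges = gr, colData = cd)
    cohort <- new("BiobankCohort", se)
    S4Vectors::metadata(cohort)$kinship_markers <- kin

    flags <- .qc_flags(as.data.frame(cd), thr)
    reason <- apply(flags, 1, function(z)
      if (any(z)) paste(c("sos", "bua", "bmd")[z], collapse = "+") else NA_character_)
    truth$samples <- data.frame(
      sample_id = sample_id,
      expected_excluded_qc = rowSums(flags) > 0,
      qc_reason = reason,
      injected_qc_fail = seq_len(n) %in% injected,
      relationship = relationship,
      relative_of = ifelse(is.na(relative_of), NA_character_,
                           sample_id[relative_of]),
      stringsAsFactors = FALSE)
    truth$variants$slope_ebmd <- slope_ebmd[match(truth$variants$rsid,
                                                  layout$rsid)]
    list(cohort = cohort, truth = truth)
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper running [simulateReferencePanel()],
#' [simulateCatalog()], [simulateSummaryStats()] for both BMD traits (the
#' lumbar-spine set omits one null variant, so the two traits' test sets
#' differ by one as intersected summary-statistic sets typically do) and
#' [simulateBiobank()].
#'
#' @param config a [SimulationConfig-class].
#' @return list with panel, catalog, truth, stats_fn, stats_ls, cohort.
#' @export
simulateStudy <- function(config) {
  panel <- simulateReferencePanel(config)
  cat_sim <- simulateCatalog(config, panel)
  truth <- cat_sim$truth
  stats_fn <- simulateSummaryStats(config, panel, truth, "FN")
  nulls <- truth$variants$rsid[truth$variants$role == "null"]
  ls_snps <- setdiff(variantInfo(panel)$rsid, utils::tail(nulls, 1))
  stats_ls <- simulateSummaryStats(config, panel, truth, "LS", snps = ls_snps)
  bb <- simulateBiobank(config, panel, truth)
  list(panel = panel, catalog = cat_sim$catalog, truth = bb$truth,
       stats_fn = stats_fn, stats_ls = stats_ls, cohort = bb$cohort)
}
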