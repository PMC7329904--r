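# Synthetic study generator: LD structure, seeded determinism, catalog
# injections, summary-statistic calibration, cohort construction.

test_that("within_block_r2 = 1 makes every intra-block pair a perfect proxy", {
  cfg <- simulationConfig(seed = 11, n_blocks = 2, snps_per_block = 3,
                          n_panel_samples = 200, within_block_r2 = 1,
                          n_planted_pleiotropic = 1, n_decoy_signals = 0,
                          n_known_bmd_planted = 0)
  panel <- simulateReferencePanel(cfg)
  vi <- variantInfo(panel)
  for (b in unique(vi$block)) {
    rs <- vi$rsid[vi$block == b]
    for (i in seq_along(rs)) for (j in seq_along(rs)) {
      expect_equal(computeR2(panel, rs[i], rs[j]), 1, tolerance = 1e-12)
    }
  }
})

test_that("every block carries a perfect anchor pair at any within_block_r2", {
  cfg <- simulationConfig(seed = 3, n_blocks = 6, snps_per_block = 4,
                          n_panel_samples = 300, within_block_r2 = 0.5)
  panel <- simulateReferencePanel(cfg)
  vi <- variantInfo(panel)
  for (b in unique(vi$block)) {
    rs <- vi$rsid[vi$block == b]
    expect_equal(computeR2(panel, rs[1], rs[2]), 1, tolerance = 1e-12)
  }
})

test_that("identical config and seed give identical output, other seeds differ", {
  cfg <- simulationConfig(seed = 5, n_blocks = 2, snps_per_block = 3,
                          n_panel_samples = 50, n_planted_pleiotropic = 1,
                          n_decoy_signals = 0, n_known_bmd_planted = 0)
  p1 <- simulateReferencePanel(cfg)
  p2 <- simulateReferencePanel(cfg)
  expect_identical(dosages(p1), dosages(p2))
  p3 <- simulateReferencePanel(simulationConfig(
    seed = 6, n_blocks = 2, snps_per_block = 3, n_panel_samples = 50,
    n_planted_pleiotropic = 1, n_decoy_signals = 0, n_known_bmd_planted = 0))
  expect_false(identical(dosages(p1), dosages(p3)))
  # calling another generator in between must not disturb the stream
  st1 <- simulateStudy(mini_config(seed = 9, n_biobank_samples = 300,
                                   n_related_pairs = 5,
                                   n_kinship_snps = 200))
  st2 <- simulateStudy(mini_config(seed = 9, n_biobank_samples = 300,
                                   n_related_pairs = 5,
                                   n_kinship_snps = 200))
  expect_identical(dosages(st1$cohort), dosages(st2$cohort))
  expect_identical(st1$stats_fn$beta, st2$stats_fn$beta)
})

test_that("sample MAF tracks the generating MAF at panel scale", {
  cfg <- simulationConfig(seed = 21, n_blocks = 40, snps_per_block = 5,
                          n_panel_samples = 1000, maf_range = c(0.05, 0.5))
  panel <- simulateReferencePanel(cfg)
  gen <- S4Vectors::metadata(panel)$generating
  vi <- variantInfo(panel)
  gen_maf <- pmin(gen$freq_alt, 1 - gen$freq_alt)
  within <- abs(vi$maf - gen_maf) <= 0.03
  expect_gte(mean(within), 0.95)
})

test_that("degenerate configurations are rejected with a clear message", {
  expect_error(simulationConfig(n_panel_samples = 0), "positive")
  expect_error(simulationConfig(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulationConfig(n_blocks = 2, n_planted_pleiotropic = 5),
               "per block")
  expect_error(simulationConfig(relationship_mix = c(duplicate = 0.5)),
               "relationship_mix")
})

test_that("catalog carries the planted signals and each injected exclusion", {
  cfg <- mini_config(seed = 31)
  panel <- simulateReferencePanel(cfg)
  cs <- simulateCatalog(cfg, panel)
  truth <- cs$truth
  expect_equal(sum(truth$variants$role == "planted"),
               cfg@n_planted_pleiotropic)
  # bone-trait record present and expected-excluded
  bone_rows <- cs$catalog[grepl("Osteoporosis", cs$catalog$`DISEASE/TRAIT`), ]
  expect_gt(nrow(bone_rows), 0)
  # injected duplicate count is recorded
  expect_equal(sum(truth$catalog$rule == "duplicate", na.rm = TRUE),
               truth$counts$duplicate)
  expect_equal(sum(truth$catalog$rule == "bone_trait", na.rm = TRUE),
               truth$counts$bone_trait)
  # planted SNPs appear in the catalog and in both summary-stat sets
  st <- simulateStudy(cfg)
  planted <- truth$variants$rsid[truth$variants$role == "planted"]
  expect_true(all(planted %in% cs$catalog$SNPS))
  expect_true(all(planted %in% st$stats_fn$rsid))
  expect_true(all(planted %in% st$stats_ls$rsid))
})

test_that("null summary-statistic p-values are uniform", {
  cfg <- simulationConfig(seed = 41, n_blocks = 250, snps_per_block = 4,
                          n_panel_samples = 300, within_block_r2 = 0,
                          n_planted_pleiotropic = 0, n_decoy_signals = 0,
                          n_known_bmd_planted = 0)
  panel <- simulateReferencePanel(cfg)
  cs <- simulateCatalog(cfg, panel)
  ss <- simulateSummaryStats(cfg, panel, cs$truth, "FN")
  # anchors duplicate each other's genotypes but their estimates carry
  # independent noise, so all 1000 p-values are marginally uniform
  ks <- suppressWarnings(stats::ks.test(ss$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted effect of 0.05 at n = 50000 is overwhelmingly significant", {
  # normal oracle: ncp = 0.05 * sqrt(50000) ~ 11.2, median p ~ 5e-29
  cfg0 <- simulationConfig(seed = 1, n_blocks = 5, snps_per_block = 3,
                           n_panel_samples = 500, maf_range = c(0.3, 0.3),
                           n_planted_pleiotropic = 1, n_decoy_signals = 0,
                           n_known_bmd_planted = 0, effect_size_sd = 0.05,
                           gwas_n = 50000)
  panel <- simulateReferencePanel(cfg0)
  cs <- simulateCatalog(cfg0, panel)
  planted <- cs$truth$variants$rsid[cs$truth$variants$role == "planted"]
  p_planted <- vapply(1:200, function(s) {
    cfg <- cfg0; cfg@seed <- 1000L + s
    ss <- simulateSummaryStats(cfg, panel, cs$truth, "FN")
    ss$p[ss$rsid == planted]
  }, numeric(1))
  expect_lt(median(p_planted), 5e-8)
})

test_that("summary statistics for a SNP absent from the panel are refused", {
  cfg <- simulationConfig(seed = 2, n_blocks = 2, snps_per_block = 3,
                          n_panel_samples = 100, n_planted_pleiotropic = 1,
                          n_decoy_signals = 0, n_known_bmd_planted = 0)
  panel <- simulateReferencePanel(cfg)
  cs <- simulateCatalog(cfg, panel)
  expect_error(simulateSummaryStats(cfg, panel, cs$truth, "FN",
                                    snps = c("rs000001", "rsNOPE")),
               "absent from panel")
})

test_that("cohort ultrasound split inverts exactly to the latent eBMD", {
  st <- simulateStudy(mini_config(seed = 51, n_biobank_samples = 500,
                                  n_related_pairs = 5, n_kinship_snps = 300))
  cv <- covariates(st$cohort)
  expect_lt(max(abs(deriveEBMD(cv$sos, cv$bua) - cv$bmd_device)), 1e-12)
})

test_that("duplicate pairs share genotypes; QC injections are truth-flagged", {
  st <- simulateStudy(mini_config(seed = 61, n_biobank_samples = 600,
                                  n_related_pairs = 20, n_kinship_snps = 300,
                                  qc_fail_fraction = 0.05))
  truth <- st$truth$samples
  d <- dosages(st$cohort)
  km <- kinshipMarkers(st$cohort)
  dups <- truth[!is.na(truth$relationship) & truth$relationship == "duplicate", ]
  expect_gt(nrow(dups), 0)
  for (i in seq_len(nrow(dups))) {
    expect_identical(d[, dups$sample_id[i]], d[, dups$relative_of[i]])
    expect_identical(km[match(dups$sample_id[i], truth$sample_id), ],
                     km[match(dups$relative_of[i], truth$sample_id), ])
  }
  expect_true(all(truth$expected_excluded_qc[truth$injected_qc_fail]))
  # e.g. an injected low-SOS male sits at/below the printed 1450 bound
  cv <- covariates(st$cohort)
  low_sos <- cv$sex == "male" & cv$sos <= 1450
  if (any(low_sos))
    expect_true(all(truth$expected_excluded_qc[low_sos]))
})

test_that("planted cohort effects are recoverable by regression", {
  cfg <- simulationConfig(seed = 71, n_blocks = 10, snps_per_block = 5,
                          n_panel_samples = 400, n_biobank_samples = 20000,
                          n_planted_pleiotropic = 3, n_decoy_signals = 0,
                          n_known_bmd_planted = 0, n_related_pairs = 0,
                          n_kinship_snps = 0)
  st <- simulateStudy(cfg)
  truth <- st$truth$variants
  d <- dosages(st$cohort)
  cv <- covariates(st$cohort)
  for (rs in truth$rsid[truth$role == "planted"]) {
    fit <- summary(lm(cv$bmd_device ~ d[rs, ] + cv$age + I(cv$age^2) +
                        cv$weight + cv$sex))$coefficients
    slope <- fit[2, 1]; se <- fit[2, 2]
    expect_lt(abs(slope - truth$slope_ebmd[truth$rsid == rs]), 3 * se)
  }
})

test_that("impossible related-pair requests are rejected", {
  cfg <- mini_config(seed = 81, n_biobank_samples = 30, n_related_pairs = 20,
                     n_kinship_snps = 100)
  panel <- simulateReferencePanel(cfg)
  cs <- simulateCatalog(cfg, panel)
  expect_error(simulateBiobank(cfg, panel, cs$truth), "inconsistent")
})
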