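# r-squared computation, proxy lookup, independence pruning, panel I/O.

test_that("r2 is 1 on identity and under allele relabeling", {
  a <- c(0, 1, 2, 0, 1, 2, 0, 1)
  panel <- make_panel(cbind(a, 2 - a, c(0, 1, 2, 0, 1, 1, 0, 1)))
  rs <- variantInfo(panel)$rsid
  expect_identical(computeR2(panel, rs[1], rs[1]), 1)
  expect_equal(computeR2(panel, rs[1], rs[2]), 1, tolerance = 1e-12)  # flip
  # 8-sample worked example against a from-scratch Pearson oracle
  b <- c(0, 1, 2, 0, 1, 1, 0, 1)
  expect_equal(computeR2(panel, rs[1], rs[3]), pearson_r2_oracle(a, b),
               tolerance = 1e-12)
  expect_equal(computeR2(panel, rs[1], rs[3]), computeR2(panel, rs[3], rs[1]))
})

test_that("r2 equals the brute-force oracle on all pairs of a 20-variant panel", {
  set.seed(19)
  repeat {  # ensure no monomorphic columns
    d <- matrix(rbinom(50 * 20, 2, runif(20, 0.2, 0.8)), 50, 20, byrow = TRUE)
    if (all(apply(d, 2, sd) > 0)) break
  }
  panel <- make_panel(d)
  rs <- variantInfo(panel)$rsid
  for (i in 1:19) for (j in (i + 1):20) {
    expect_equal(computeR2(panel, rs[i], rs[j]),
                 pearson_r2_oracle(d[, i], d[, j]), tolerance = 1e-12)
  }
})

test_that("monomorphic variants give an undefined-LD error", {
  panel <- make_panel(cbind(rep(1, 10), rbinom(10, 2, 0.5)))
  rs <- variantInfo(panel)$rsid
  expect_error(computeR2(panel, rs[1], rs[2]), "undefined LD")
})

test_that("perfect proxies are found exactly and symmetrically", {
  cfg <- simulationConfig(seed = 23, n_blocks = 4, snps_per_block = 5,
                          n_panel_samples = 500, within_block_r2 = 0.8,
                          n_planted_pleiotropic = 1, n_decoy_signals = 0,
                          n_known_bmd_planted = 0)
  panel <- simulateReferencePanel(cfg)
  vi <- variantInfo(panel)
  b1 <- vi$rsid[vi$block == 1]
  px <- findProxies(panel, b1, r2_min = 1)
  # anchors return each other; a non-anchor SNP in an r2 = 0.8 block
  # has no perfect proxy but itself
  expect_setequal(px$proxies[[b1[1]]]$rsid, b1[1:2])
  expect_setequal(px$proxies[[b1[2]]]$rsid, b1[1:2])
  expect_identical(px$proxies[[b1[3]]]$rsid, b1[3])
  # symmetry at r2_min = 1 across the whole panel
  all_px <- findProxies(panel, vi$rsid, r2_min = 1)$proxies
  for (s in vi$rsid) for (t in all_px[[s]]$rsid) {
    expect_true(s %in% all_px[[t]]$rsid)
  }
})

test_that("query SNPs absent from the panel are reported as unresolved", {
  panel <- make_panel(matrix(rbinom(40, 2, 0.4), 20, 2))
  px <- findProxies(panel, c(variantInfo(panel)$rsid[1], "rsMISSING"))
  expect_identical(px$unresolved, "rsMISSING")
  expect_length(findProxies(panel, character())$proxies, 0)
})

test_that("pruning keeps the best of a perfect-proxy pair and singletons", {
  a <- rbinom(30, 2, 0.5)
  panel <- make_panel(cbind(a, a))
  rs <- variantInfo(panel)$rsid
  one <- pruneIndependent(data.frame(rsid = rs[1], p_value = 1e-5), panel)
  expect_identical(one$rsid, rs[1])
  both <- pruneIndependent(
    data.frame(rsid = rs, p_value = c(1e-9, 1e-10)), panel)
  expect_identical(both$rsid, rs[2])  # the 1e-10 SNP wins
})

test_that("greedy pruning follows the p-value order and stays maximal", {
  # construct three SNPs with r2 pattern AB >= 0.2, AC < 0.2, BC < 0.2
  found <- FALSE
  for (s in 1:200) {
    set.seed(100 + s)
    A <- rbinom(40, 2, 0.5)
    B <- ifelse(rbinom(40, 1, 0.65) == 1, A, rbinom(40, 2, 0.5))
    C <- rbinom(40, 2, 0.5)
    r2 <- c(pearson_r2_oracle(A, B), pearson_r2_oracle(A, C),
            pearson_r2_oracle(B, C))
    if (r2[1] >= 0.3 && r2[2] < 0.15 && r2[3] < 0.15 &&
        sd(A) > 0 && sd(B) > 0 && sd(C) > 0) { found <- TRUE; break }
  }
  expect_true(found)
  panel <- make_panel(cbind(A, B, C))
  rs <- variantInfo(panel)$rsid
  kept <- pruneIndependent(
    data.frame(rsid = rs, p_value = c(1e-10, 1e-9, 1e-8)), panel)
  expect_identical(kept$rsid, rs[c(1, 3)])  # A kept, B clumped away, C kept
  # retained pairs all below threshold; removed SNPs all conflict with a kept one
  for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
    if (i < j)
      expect_lt(computeR2(panel, kept$rsid[i], kept$rsid[j]), 0.2)
  }
  removed <- setdiff(rs, kept$rsid)
  for (r in removed) {
    expect_true(any(vapply(kept$rsid, function(k)
      computeR2(panel, r, k) >= 0.2, logical(1))))
  }
})

test_that("candidates missing from the panel are kept but flagged", {
  panel <- make_panel(matrix(rbinom(60, 2, 0.4), 30, 2))
  rs <- variantInfo(panel)$rsid
  expect_warning(
    out <- pruneIndependent(
      data.frame(rsid = c(rs[1], "rsGHOST"), p_value = c(1e-8, 1e-9)), panel),
    "without LD assessment")
  expect_true("rsGHOST" %in% out$rsid)
  expect_false(out$ld_assessed[out$rsid == "rsGHOST"])
})

test_that("panels round-trip through VCF and text-dosage formats", {
  cfg <- simulationConfig(seed = 29, n_blocks = 3, snps_per_block = 4,
                          n_panel_samples = 25, n_planted_pleiotropic = 1,
                          n_decoy_signals = 0, n_known_bmd_planted = 0)
  panel <- simulateReferencePanel(cfg)
  vcf <- tempfile(fileext = ".vcf")
  writePanelVCF(panel, vcf)
  back <- readPanelVCF(vcf)   # vcfR-based reader as oracle for the writer
  expect_identical(unname(dosages(back)), unname(dosages(panel)))
  expect_identical(variantInfo(back)$rsid, variantInfo(panel)$rsid)
  expect_identical(variantInfo(back)$pos, variantInfo(panel)$pos)
  traw <- tempfile(fileext = ".traw")
  writePanelTraw(panel, traw)
  back2 <- readPanelTraw(traw)
  expect_identical(unname(dosages(back2)), unname(dosages(panel)))
  unlink(c(vcf, traw))
})
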