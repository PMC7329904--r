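# Replication stage: eBMD derivation, outlier QC, kinship, Z-scores,
# PC-adjusted association, direction concordance.

test_that("the eBMD calibration evaluates, crosses zero and has unit slope", {
  expect_equal(deriveEBMD(1550, 80), 0.002592 * 1630 - 3.687)
  expect_equal(deriveEBMD(1550, 80), 0.53796, tolerance = 1e-12)
  split <- 3.687 / 0.002592
  expect_equal(deriveEBMD(split / 2, split / 2), 0, tolerance = 1e-12)
  for (s in c(1450, 1600.5, 1725)) for (b in c(30, 77.7, 120)) {
    expect_equal(deriveEBMD(s + 1, b) - deriveEBMD(s, b), 0.002592,
                 tolerance = 1e-12)
  }
  expect_error(deriveEBMD(NA, 80), "non-finite")
  expect_error(deriveEBMD(1550, Inf), "non-finite")
})

test_that("records exactly on any printed bound are excluded, inside retained", {
  thr <- qcThresholds()
  mk <- function(sex, sos = 1500, bua = 70, bmd = 0.5)
    data.frame(sample_id = "s", sex = sex, sos = sos, bua = bua,
               bmd_device = bmd, stringsAsFactors = FALSE)
  inside <- rbind(mk("male"), mk("female"))
  expect_equal(applyQC(inside, thr)$report$n_excluded, 0)
  for (sex in c("male", "female")) for (measure in c("sos", "bua", "bmd")) {
    for (side in 1:2) {
      bound <- thr[[sex]][[measure]][side]
      rec <- mk(sex)
      rec[[if (measure == "bmd") "bmd_device" else measure]] <- bound
      out <- applyQC(rec, thr)
      expect_equal(out$report$n_excluded, 1,
                   label = paste(sex, measure, c("lower", "upper")[side]))
      # strictly inside the same bound by a hair: retained
      rec2 <- mk(sex)
      eps <- if (measure == "bmd") 1e-4 else 0.5
      rec2[[if (measure == "bmd") "bmd_device" else measure]] <-
        bound + (if (side == 1) eps else -eps)
      expect_equal(applyQC(rec2, thr)$report$n_excluded, 0)
    }
  }
  expect_error(applyQC(mk("other"), thr), "unknown sex")
})

test_that("eBMD-based QC applies the BMD bound to the recalculated value", {
  # SOS/BUA inside their bounds, device BMD inside too, but the
  # recalculated eBMD sits exactly on the female upper BMD bound
  sos <- 1690
  bua <- (1.025 + 3.687) / 0.002592 - sos   # ~127.9 dB/MHz
  rec <- data.frame(sample_id = "s", sex = "female", sos = sos, bua = bua,
                    bmd_device = 0.5, stringsAsFactors = FALSE)
  expect_equal(applyQC(rec)$report$n_excluded, 0)
  expect_equal(applyQC(rec, use_ebmd = TRUE)$report$n_excluded, 1)
})

test_that("simulated cohorts are QC-filtered exactly as the truth table says", {
  st <- simulateStudy(mini_config(seed = 47, n_biobank_samples = 800,
                                  n_related_pairs = 5, n_kinship_snps = 300,
                                  qc_fail_fraction = 0.02))
  out <- applyQC(st$cohort)
  expect_setequal(out$report$excluded_ids,
                  st$truth$samples$sample_id[st$truth$samples$expected_excluded_qc])
})

test_that("kinship classes are recovered from pedigree-simulated pairs", {
  set.seed(53)
  dup <- simulate_pair("duplicate")
  expect_gte(estimateKinship(dup$a, dup$b), 0.45)
  expect_lte(estimateKinship(dup$a, dup$b), 0.55)
  po <- simulate_pair("parent_offspring")
  phi_po <- estimateKinship(po$a, po$b)
  expect_gte(phi_po, 2^(-5/2)); expect_lte(phi_po, 2^(-3/2))
  un <- simulate_pair("unrelated")
  expect_lt(abs(estimateKinship(un$a, un$b)), 2^(-9/2))
})

test_that("kinship is symmetric, relabeling-invariant and floor-guarded", {
  set.seed(59)
  pr <- simulate_pair("full_sib", m = 2000)
  a <- pr$a; b <- pr$b
  expect_equal(estimateKinship(a, b), estimateKinship(b, a))
  flip <- sample(2000, 700)
  af <- a; bf <- b
  af[flip] <- 2 - af[flip]; bf[flip] <- 2 - bf[flip]
  expect_equal(estimateKinship(af, bf), estimateKinship(a, b))
  expect_warning(phi <- estimateKinship(a[1:50], b[1:50]), "unassessable")
  expect_true(is.na(phi))
})

test_that("the compiled all-pairs scan matches the per-pair estimator", {
  set.seed(61)
  n <- 25; m <- 600
  g <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)), n, m, byrow = TRUE)
  g[sample(length(g), 200)] <- NA
  rownames(g) <- sprintf("S%02d", 1:n)
  pairs <- kinshipPairs(g, threshold = -1, min_shared = 50)
  expect_equal(nrow(pairs), choose(n, 2))
  for (k in sample(nrow(pairs), 40)) {
    i <- match(pairs$sample_a[k], rownames(g))
    j <- match(pairs$sample_b[k], rownames(g))
    expect_equal(pairs$phi[k],
                 suppressWarnings(estimateKinship(g[i, ], g[j, ], min_shared = 50)),
                 tolerance = 1e-12)
  }
  # raw-matrix input path agrees (complete data)
  g2 <- g; g2[is.na(g2)] <- 1L
  praw <- kinshipPairs(matrix(as.raw(g2), n, m,
                              dimnames = list(rownames(g), NULL)),
                       threshold = -1)
  pint <- kinshipPairs(g2, threshold = -1)
  expect_equal(praw$phi, pint$phi, tolerance = 1e-15)
})

test_that("unrelated-set selection removes one member per pair and clears triangles", {
  pairs1 <- data.frame(sample_a = "s1", sample_b = "s2", phi = 0.5)
  expect_setequal(selectUnrelated(c("s1", "s2", "s3"), pairs1), c("s1", "s3"))
  none <- data.frame(sample_a = "s1", sample_b = "s2", phi = 0.01)
  expect_setequal(selectUnrelated(c("s1", "s2", "s3"), none),
                  c("s1", "s2", "s3"))
  tri <- data.frame(sample_a = c("s1", "s1", "s2"),
                    sample_b = c("s2", "s3", "s3"), phi = 0.3)
  kept <- selectUnrelated(c("s1", "s2", "s3"), tri)
  expect_length(kept, 1)
  expect_identical(kept, "s1")  # ties drop the lexicographically larger ID
  # property: no residual pair at/above threshold on random graphs
  set.seed(67)
  for (rep in 1:20) {
    ids <- sprintf("x%02d", 1:12)
    k <- sample(3:12, 1)
    pr <- data.frame(sample_a = sample(ids, k, TRUE),
                     sample_b = sample(ids, k, TRUE),
                     phi = runif(k, 0, 0.3))
    pr <- pr[pr$sample_a != pr$sample_b, , drop = FALSE]
    kept <- selectUnrelated(ids, pr, threshold = kinshipDegreeCutoff)
    bad <- pr$phi >= kinshipDegreeCutoff &
      pr$sample_a %in% kept & pr$sample_b %in% kept
    expect_false(any(bad))
  }
})

test_that("Z-scores standardize each sex stratum and match a closed-form fit", {
  set.seed(71)
  n <- 400
  cv <- data.frame(sample_id = sprintf("s%03d", 1:n),
                   sex = rep(c("male", "female"), each = n / 2),
                   age = runif(n, 40, 69), weight = rnorm(n, 78, 15))
  bmd <- 0.5 - 0.002 * cv$age + 0.001 * cv$weight + rnorm(n, 0, 0.1)
  zr <- zscorePhenotype(cv, bmd)
  for (s in c("male", "female")) {
    zi <- zr$z[cv$sex[match(names(zr$z), cv$sample_id)] == s]
    expect_lt(abs(mean(zi)), 1e-10)
    expect_equal(sd(zi), 1, tolerance = 1e-6)
  }
  # 6-sample stratum against the normal-equations oracle
  cv6 <- data.frame(sample_id = paste0("t", 1:6), sex = "male",
                    age = c(41, 45, 50, 55, 60, 68),
                    weight = c(60, 70, 80, 90, 75, 85))
  bmd6 <- c(0.41, 0.52, 0.48, 0.60, 0.55, 0.47)
  zr6 <- zscorePhenotype(cv6, bmd6)
  X <- cbind(1, cv6$age, cv6$age^2, cv6$weight)
  want <- ols_oracle(X, bmd6)
  expect_equal(unname(zr6$z), want$residuals / sd(want$residuals),
               tolerance = 1e-8)
  expect_error(zscorePhenotype(cv6[1:3, ], bmd6[1:3]), "fewer samples")
})

test_that("extreme Z-scores are excluded at the |Z| > 4 bound", {
  set.seed(73)
  n <- 300
  cv <- data.frame(sample_id = sprintf("s%03d", 1:n), sex = "female",
                   age = runif(n, 40, 69), weight = rnorm(n, 70, 12))
  bmd <- 0.55 + 0.001 * cv$weight + rnorm(n, 0, 0.05)
  bmd[7] <- bmd[7] + 0.05 * 8  # engineered ~8 SD outlier
  zr <- zscorePhenotype(cv, bmd)
  expect_true("s007" %in% zr$excluded)
  expect_false("s007" %in% names(zr$z))
  expect_true(all(abs(zr$z) <= 4))
})

test_that("association is exact on orthogonal and noiseless designs", {
  set.seed(79)
  n <- 40
  dosage <- rbinom(n, 2, 0.4)
  pcs <- matrix(rnorm(n * 15), n, 15)
  X <- cbind(1, dosage, pcs)
  z0 <- rnorm(n)
  z_orth <- drop(z0 - X %*% solve(crossprod(X), crossprod(X, z0)))
  r <- snpAssociation(z_orth, dosage, pcs, rsid = "rsO")
  expect_lt(abs(r$beta), 1e-12)
  # noiseless planted slope is recovered exactly
  n2 <- 30
  d2 <- rbinom(n2, 2, 0.5)
  pcs2 <- matrix(rnorm(n2 * 15), n2, 15)
  r2 <- snpAssociation(0.5 * d2, d2, pcs2, rsid = "rsN")
  expect_equal(r2$beta, 0.5, tolerance = 1e-10)
  expect_true(r2$replicated)
})

test_that("association matches the normal-equations oracle on random designs", {
  set.seed(83)
  for (rep in 1:20) {
    n <- 50
    dosage <- rbinom(n, 2, runif(1, 0.2, 0.8))
    if (sd(dosage) == 0) next
    pcs <- matrix(rnorm(n * 15), n, 15)
    z <- rnorm(n)
    got <- snpAssociation(z, dosage, pcs)
    want <- ols_oracle(cbind(1, dosage, pcs), z)
    expect_equal(got$beta, want$beta[2], tolerance = 1e-8)
    expect_equal(got$se, unname(want$se[2]), tolerance = 1e-8)
    expect_equal(got$p, 2 * pt(-abs(want$beta[2] / want$se[2]), want$df),
                 tolerance = 1e-8)
    expect_equal(got$ci_low, got$beta - 1.96 * got$se)
  }
})

test_that("missing dosages are mean-imputed or dropped as configured", {
  set.seed(89)
  n <- 60
  dosage <- rbinom(n, 2, 0.5)
  pcs <- matrix(rnorm(n * 15), n, 15)
  z <- 0.3 * dosage + rnorm(n)
  dna <- dosage; dna[1:5] <- NA
  imp <- snpAssociation(z, dna, pcs, missing = "mean")
  expect_equal(imp$n_used, n)
  drp <- snpAssociation(z, dna, pcs, missing = "drop")
  expect_equal(drp$n_used, n - 5)
  want <- ols_oracle(cbind(1, dosage[-(1:5)], pcs[-(1:5), ]), z[-(1:5)])
  expect_equal(drp$beta, want$beta[2], tolerance = 1e-8)
  expect_error(snpAssociation(z, rep(1, n), pcs, rsid = "rsM"), "monomorphic")
})

test_that("direction concordance harmonizes alleles and flags palindromes", {
  disc <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"),
                     effect_allele = c("A", "A", "A", "A"),
                     other_allele = c("G", "G", "T", "G"),
                     eaf = c(0.3, 0.3, 0.49, 0.3),
                     beta = c(0.02, 0.02, 0.05, 0.01))
  repl <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"),
                     effect_allele = c("A", "G", "A", "C"),
                     other_allele = c("G", "A", "T", "T"),
                     beta = c(0.01, -0.02, 0.05, 0.01))
  out <- directionConcordance(disc, repl)
  tab <- out$table[match(c("rs1", "rs2", "rs3", "rs4"), out$table$rsid), ]
  expect_identical(tab$status,
                   c("same", "swapped", "ambiguous_palindromic",
                     "allele_mismatch"))
  expect_true(tab$concordant[1])
  expect_true(tab$concordant[2])  # concordant after the flip
  expect_true(is.na(tab$concordant[3]))
  expect_equal(out$fraction, 1)  # 2 of 2 assessable
})
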