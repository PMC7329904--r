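# Shared fixtures and independent oracles. Oracles are implemented here,
# from scratch, so tests never validate package code against itself.

# Build a ReferencePanel from an explicit samples x variants dosage matrix
# by round-tripping the public text-dosage format.
make_panel <- function(d, chrom = NULL, pos = NULL, rsid = NULL) {
  m <- ncol(d)
  if (is.null(rsid)) rsid <- sprintf("snp%03d", seq_len(m))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  df <- data.frame(CHR = chrom, SNP = rsid, POS = pos,
                   COUNTED = "G", ALT = "A", t(d),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[-(1:5)] <- sprintf("S%03d", seq_len(nrow(d)))
  tf <- tempfile(fileext = ".traw")
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  on.exit(unlink(tf))
  readPanelTraw(tf)
}

# Brute-force squared Pearson correlation from first principles.
pearson_r2_oracle <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  (num / den)^2
}

# Exhaustive BH step-up: evaluate every rank bound directly.
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i / m * q) k <- i
  thr <- if (k > 0) ps[k] else 0
  list(k = k, p_threshold = thr,
       significant = if (k > 0) p <= thr else rep(FALSE, m))
}

# Normal-equations least squares with classical standard errors.
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  bhat <- solve(XtX, crossprod(X, y))
  res <- y - X %*% bhat
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(beta = unname(drop(bhat)), se = unname(se),
       residuals = unname(drop(res)), df = df)
}

# Pedigree simulation oracle for kinship classes: draws a pair of dosage
# vectors with per-locus identity-by-descent sharing appropriate to the
# relationship, independently of the package's generator.
simulate_pair <- function(class, m = 5000, maf = NULL) {
  f <- if (is.null(maf)) runif(m, 0.05, 0.5) else rep(maf, m)
  a <- rbinom(m, 2L, f)
  pop <- function() rbinom(m, 1L, f)
  from_a <- function() rbinom(m, 1L, a / 2)
  b <- switch(class,
    duplicate = a,
    parent_offspring = from_a() + pop(),
    full_sib = {
      ibd <- sample(0:2, m, replace = TRUE, prob = c(0.25, 0.5, 0.25))
      ifelse(ibd == 2L, a, ifelse(ibd == 1L, from_a() + pop(), pop() + pop()))
    },
    second_degree = ifelse(rbinom(m, 1L, 0.5) == 1L, from_a(), pop()) + pop(),
    third_degree = ifelse(rbinom(m, 1L, 0.25) == 1L, from_a(), pop()) + pop(),
    unrelated = rbinom(m, 2L, f))
  list(a = a, b = b)
}

king_degree_interval <- function(class) {
  switch(class,
    duplicate = c(2^(-3/2), Inf),
    parent_offspring = c(2^(-5/2), 2^(-3/2)),
    full_sib = c(2^(-5/2), 2^(-3/2)),
    second_degree = c(2^(-7/2), 2^(-5/2)),
    third_degree = c(2^(-9/2), 2^(-7/2)),
    unrelated = c(-Inf, 2^(-9/2)))
}

# Small, fast study configuration used by several end-to-end tests.
mini_config <- function(seed = 42, ...) {
  args <- list(seed = seed, n_blocks = 30, snps_per_block = 5,
               n_panel_samples = 400, n_biobank_samples = 4000,
               n_planted_pleiotropic = 2, n_decoy_signals = 1,
               n_known_bmd_planted = 1, effect_size_sd = 0.2,
               gwas_n = 20000, n_related_pairs = 10, n_kinship_snps = 6000)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulationConfig, args)
}

# Parse a dialect-shaped catalog data.frame through the public reader.
read_catalog_df <- function(df) {
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  on.exit(unlink(tf))
  readCatalog(tf)
}

# Internal-layout catalog record builder for curation tests.
catalog_record <- function(rsid = "rs1", trait = "Height", p = 1e-9,
                           hap = FALSE, int = FALSE, category = trait) {
  data.frame(rsid = rsid, chrom = "1", pos = 1000, trait = trait,
             trait_category = category, p_value = p, effect_allele = "G",
             effect_size = 0.1, eaf = 0.3, ancestry = "European",
             study_id = "GCST000001", is_haplotype = hap,
             is_interaction = int, stringsAsFactors = FALSE)
}
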