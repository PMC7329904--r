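# Internal helpers shared across modules.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. All simulator operations use this so that identical (config, seed)
# pairs give identical output regardless of call order.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Named per-stage substreams derived from one top-level seed; offsets keep
# the derived seed a valid 32-bit integer.
stage_seed <- function(seed, stage) {
  offs <- c(panel = 11L, catalog = 29L, stats_fn = 47L, stats_ls = 61L,
            biobank = 83L, qc = 101L, pipeline = 131L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1000 + offs[[stage]]) %% .Machine$integer.max)
}

# Squared Pearson correlation of two dosage vectors over pairwise-complete
# entries; NA when either is monomorphic or fewer than 2 complete pairs.
r2_pair <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  min(stats::cor(a, b)^2, 1)
}

# Signed Pearson correlation, same conventions (used for effect attenuation).
r_pair <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
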