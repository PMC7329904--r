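#' @include AllClasses.R
NULL

#' Default column mapping for catalog tables
#'
#' Maps the internal record fields onto the column headers of a
#' GWAS-Catalog-style export. Override entries to ingest other dialects.
#'
#' @param ... named overrides, e.g. \code{rsid = "SNP_ID"}.
#' @return named character vector field -> column.
#' @export
catalogDialect <- function(...) {
  d <- c(rsid = "SNPS", chrom = "CHR_ID", pos = "CHR_POS",
         trait = "DISEASE/TRAIT", trait_category = "MAPPED_TRAIT",
         p_value = "P-VALUE", effect_allele = "EFFECT_ALLELE",
         effect_size = "OR_BETA", eaf = "EAF", ancestry = "ANCESTRY",
         study_id = "STUDY_ACCESSION", is_haplotype = "IS_HAPLOTYPE",
         is_interaction = "IS_INTERACTION")
  over <- c(...)
  d[names(over)] <- over
  d
}

#' Read a catalog-style association table
#'
#' Parses a TSV of SNP-trait associations into the internal record layout.
#' Mandatory columns are rsid, trait and p-value; unparseable p-values or
#' positions yield per-row warnings and NA, not a failure. Missing optional
#' columns are filled with NA/FALSE.
#'
#' @param path TSV file.
#' @param dialect column mapping from [catalogDialect()].
#' @return data.frame with columns rsid, chrom, pos, trait, trait_category,
#'   p_value, effect_allele, effect_size, eaf, ancestry, study_id,
#'   is_haplotype, is_interaction.
#' @export
readCatalog <- function(path, dialect = catalogDialect()) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  for (f in c("rsid", "trait", "p_value")) {
    if (!dialect[[f]] %in% colnames(raw))
      stop("mandatory column missing for field '", f, "': expected column '",
           dialect[[f]], "'")
  }
  get_col <- function(field, default = NA_character_) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% colnames(raw)) raw[[col]]
    else rep(default, nrow(raw))
  }
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      warning("unparseable ", what, " in row(s) ",
              paste(utils::head(bad, 5), collapse = ", "),
              if (length(bad) > 5) " ..." else "", "; set to NA")
    v
  }
  flag <- function(x) !is.na(x) & toupper(x) %in% c("TRUE", "T", "1", "YES")
  data.frame(
    rsid = get_col("rsid"),
    chrom = get_col("chrom"),
    pos = num(get_col("pos"), "position"),
    trait = get_col("trait"),
    trait_category = get_col("trait_category"),
    p_value = num(get_col("p_value"), "p-value"),
    effect_allele = get_col("effect_allele"),
    effect_size = num(get_col("effect_size"), "effect size"),
    eaf = num(get_col("eaf"), "EAF"),
    ancestry = get_col("ancestry"),
    study_id = get_col("study_id"),
    is_haplotype = flag(get_col("is_haplotype")),
    is_interaction = flag(get_col("is_interaction")),
    stringsAsFactors = FALSE)
}

#' Curation configuration
#'
#' Thresholds, keyword lists and rules for [curateCatalog()]. The
#' bone-relatedness and pleiotropy-criteria decisions are judgment calls;
#' they are encoded here as auditable case-insensitive keyword rules with
#' extensible defaults rather than hard-coded logic.
#'
#' @param gws_threshold genome-wide significance cutoff (default 5e-8).
#' @param bone_trait_keywords case-insensitive substrings marking
#'   bone-related traits.
#' @param known_bmd_snps rsIDs already associated with BMD.
#' @param pleiotropy_rules case-insensitive substrings marking phenotypes
#'   excluded under the pleiotropy criteria (pathophysiological
#'   counterparts, subsets, derived or causally linked measures of BMD).
#' @return a \code{CurationConfig} list.
#' @export
curationConfig <- function(gws_threshold = 5e-8,
                           bone_trait_keywords = c("bone mineral density",
                                                   "bmd", "osteoporosis",
                                                   "fracture",
                                                   "calcium levels", "bone"),
                           known_bmd_snps = character(),
                           pleiotropy_rules = c("quantitative ultrasound",
                                                "skeletal size",
                                                "vitamin d",
                                                "parathyroid",
                                                "lean body mass")) {
  stopifnot(gws_threshold > 0, gws_threshold < 1,
            length(bone_trait_keywords) > 0)
  structure(list(gws_threshold = gws_threshold,
                 bone_trait_keywords = bone_trait_keywords,
                 known_bmd_snps = known_bmd_snps,
                 pleiotropy_rules = pleiotropy_rules),
            class = "CurationConfig")
}

.curation_rules <- c("non_gws", "interaction", "haplotype", "missing_rsid",
                     "bone_trait", "known_bmd", "pleiotropy_rule",
                     "duplicate")

#' Curate a catalog to the candidate non-bone SNP set
#'
#' Applies the exclusion rules in fixed order, attributing every removed
#' record to the first matching rule so that the report partitions the
#' input: (1) p-value above the genome-wide threshold (or missing);
#' (2) gene-gene interaction entries; (3) haplotype entries; (4) missing
#' rsID; (5) bone-related trait keyword (trait or mapped category);
#' (6) known BMD SNPs; (7) pleiotropy-criteria keyword rules;
#' (8) duplicate rsIDs (first occurrence in file order kept).
#'
#' @param records data.frame from [readCatalog()].
#' @param config a [curationConfig()].
#' @return list with \code{candidates} (character rsIDs, file order) and
#'   \code{report} (per-rule removal counts, retained count, and the
#'   per-record rule attribution).
#' @export
curateCatalog <- function(records, config = curationConfig()) {
  n <- nrow(records)
  rule <- rep(NA_character_, n)
  hit <- function(field, patterns) {
    x <- tolower(ifelse(is.na(field), "", field))
    Reduce(`|`, lapply(tolower(patterns), function(p) grepl(p, x, fixed = TRUE)))
  }
  assign_rule <- function(mask, r) {
    rule[is.na(rule) & mask] <<- r
  }
  assign_rule(is.na(records$p_value) | records$p_value > config$gws_threshold,
              "non_gws")
  assign_rule(records$is_interaction, "interaction")
  assign_rule(records$is_haplotype, "haplotype")
  assign_rule(is.na(records$rsid) | records$rsid == "", "missing_rsid")
  assign_rule(hit(records$trait, config$bone_trait_keywords) |
                hit(records$trait_category, config$bone_trait_keywords),
              "bone_trait")
  assign_rule(records$rsid %in% config$known_bmd_snps, "known_bmd")
  assign_rule(hit(records$trait, config$pleiotropy_rules) |
                hit(records$trait_category, config$pleiotropy_rules),
              "pleiotropy_rule")
  # deduplicate among survivors: first occurrence in file order is kept
  surv <- which(is.na(rule))
  rule[surv[duplicated(records$rsid[surv])]] <- "duplicate"
  retained <- is.na(rule)
  removed <- table(factor(rule, levels = .curation_rules))
  report <- list(removed = as.list(removed),
                 n_input = n, n_retained = sum(retained),
                 attribution = data.frame(rsid = records$rsid, rule = rule,
                                          retained = retained,
                                          stringsAsFactors = FALSE))
  stopifnot(sum(removed) + sum(retained) == n)
  list(candidates = records$rsid[retained], report = report)
}
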