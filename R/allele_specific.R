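#' Genotype the phasing SNP from fragment base calls
#'
#' Counts ref-, alt- and other-base fragments at the SNP locus and calls
#' zygosity: heterozygous when the alt-allele fraction (among ref + alt)
#' lies inside `het_band`, homozygous for the major allele otherwise, and
#' undetermined below `min_depth`. Refuses SNPs that are not bisulfite
#' safe, since C/T-confounded alleles cannot be read in bisulfite space.
#'
#' @param fragments Fragment tibble for one sample (must carry `snp_base`).
#' @param map A [promoter_map()].
#' @param min_depth Minimum ref+alt depth for a call (default 100).
#' @param het_band Alt-fraction interval called heterozygous (default
#'   `c(0.2, 0.8)`, a conventional amplicon-genotyping band).
#' @return One-row tibble of class `vef_genotype`: `sample_id`, `zygosity`
#'   (`hom_ref`/`het`/`hom_alt`/`undetermined`), `depth_ref`, `depth_alt`,
#'   `depth_other`, `minor_allele_fraction`.
#' @export
genotype_snp <- function(fragments, map, min_depth = 100L,
                         het_band = c(0.2, 0.8)) {
  if (!isTRUE(map$snp$bisulfite_safe)) {
    stop("SNP alleles are confounded by bisulfite conversion ",
         "(bisulfite_safe = FALSE); allele-specific assessment is refused",
         call. = FALSE)
  }
  sid <- unique(fragments$sample_id)
  if (length(sid) != 1L) stop("genotype one sample at a time", call. = FALSE)
  b <- fragments$snp_base
  depth_ref <- sum(b == map$snp$ref_base)
  depth_alt <- sum(b == map$snp$alt_base)
  depth_other <- sum(b %in% setdiff(c("A", "C", "G", "T"),
                                    c(map$snp$ref_base, map$snp$alt_base)))
  total <- depth_ref + depth_alt
  maf <- if (total > 0) min(depth_ref, depth_alt) / total else NA_real_
  zyg <- if (total < min_depth) {
    "undetermined"
  } else {
    af_alt <- depth_alt / total
    if (af_alt < het_band[1]) "hom_ref"
    else if (af_alt > het_band[2]) "hom_alt"
    else "het"
  }
  out <- tibble::tibble(sample_id = sid, zygosity = zyg,
                        depth_ref = depth_ref, depth_alt = depth_alt,
                        depth_other = depth_other,
                        minor_allele_fraction = maf)
  class(out) <- c("vef_genotype", class(out))
  out
}

#' Per-allele VEF for a heterozygous sample
#'
#' Splits the SNP-amplicon epialleles by their within-read SNP base and
#' computes the hypermethylated epiallele frequency separately for ref- and
#' alt-tagged molecules. Epialleles without an informative SNP base are
#' excluded. Only heterozygous samples have a defined allele-specific
#' measure; other zygosities are rejected.
#'
#' @param epialleles Epiallele tibble (from [extract_epialleles()]) over
#'   the SNP-covering amplicon, carrying `snp_base`.
#' @param genotype A [genotype_snp()] result (zygosity must be `het`).
#' @param map A [promoter_map()].
#' @param config A [calling_config()].
#' @return One-row tibble of class `vef_allele_specific`: `sample_id`,
#'   `vef_ref`, `vef_alt`, `n_informative`, `fe_magnitude`, `fe_direction`,
#'   `fe_infinite`.
#' @export
allele_vef <- function(epialleles, genotype, map, config = calling_config()) {
  if (!identical(genotype$zygosity, "het")) {
    stop("allele-specific methylation is defined only for heterozygous ",
         "samples (zygosity is '", genotype$zygosity, "')", call. = FALSE)
  }
  ep <- dplyr::filter(epialleles, .data$amplicon_id == map$snp$amplicon_id)
  hyper <- ep$beta >= config$beta_threshold
  is_ref <- ep$snp_base == map$snp$ref_base
  is_alt <- ep$snp_base == map$snp$alt_base
  n_ref <- sum(is_ref); n_alt <- sum(is_alt)
  vef_ref <- if (n_ref > 0) mean(hyper[is_ref]) else NA_real_
  vef_alt <- if (n_alt > 0) mean(hyper[is_alt]) else NA_real_
  fe <- fold_enrichment(vef_ref, vef_alt)
  out <- tibble::tibble(
    sample_id = genotype$sample_id,
    vef_ref = vef_ref, vef_alt = vef_alt,
    n_informative = n_ref + n_alt,
    fe_magnitude = fe$magnitude, fe_direction = fe$direction,
    fe_infinite = fe$infinite
  )
  class(out) <- c("vef_allele_specific", class(out))
  out
}

#' Allelic fold enrichment of hypermethylation
#'
#' The ratio of the larger to the smaller per-allele VEF, with the
#' direction naming the preferentially methylated allele. No pseudocounts:
#' exclusive methylation of a single allele (the other allele's VEF is
#' exactly 0) is reported as infinite, matching the "Inf" plotting
#' convention; both-zero input is balanced with undefined magnitude.
#'
#' @param vef_ref,vef_alt Non-negative per-allele VEFs (vectorised).
#' @return Tibble: `magnitude` (>= 1, possibly `Inf` or `NA`), `direction`
#'   (`"ref"`, `"alt"` or `"balanced"`), `infinite` (logical).
#' @export
fold_enrichment <- function(vef_ref, vef_alt) {
  if (any(stats::na.omit(c(vef_ref, vef_alt)) < 0)) {
    stop("per-allele VEFs must be non-negative", call. = FALSE)
  }
  hi <- pmax(vef_ref, vef_alt)
  lo <- pmin(vef_ref, vef_alt)
  magnitude <- dplyr::case_when(
    is.na(hi) | is.na(lo) ~ NA_real_,
    hi == 0 ~ NA_real_,          # both zero: undefined-balanced
    lo == 0 ~ Inf,               # exclusive single-allele methylation
    TRUE ~ hi / lo
  )
  direction <- dplyr::case_when(
    is.na(vef_ref) | is.na(vef_alt) ~ NA_character_,
    vef_ref == vef_alt ~ "balanced",
    vef_ref > vef_alt ~ "ref",
    TRUE ~ "alt"
  )
  tibble::tibble(
    magnitude = magnitude,
    direction = direction,
    infinite = !is.na(magnitude) & is.infinite(magnitude)
  )
}

#' Allelic concordance of a matched sample pair
#'
#' Two allele-specific results (e.g. blood and tumor from one patient, or
#' child and parent) are concordant when methylation is enriched on the
#' same allele in both, discordant when on opposite alleles, and
#' uninformative when either member is balanced, undetermined, or has
#' fewer than `min_informative` SNP-tagged epialleles (keeping zero-count
#' "Inf" calls meaningful at VEFs near 1e-3).
#'
#' @param result_a,result_b One-row [allele_vef()] results.
#' @param pair_id Identifier for the pair.
#' @param min_informative Minimum SNP-tagged epialleles per member
#'   (default 500).
#' @return One-row tibble: `pair_id`, `direction_a`, `direction_b`,
#'   `verdict` (`concordant`/`discordant`/`uninformative`).
#' @export
pair_concordance <- function(result_a, result_b, pair_id = NULL,
                             min_informative = 500L) {
  pair_id <- pair_id %||% paste(result_a$sample_id, result_b$sample_id,
                                sep = "|")
  da <- result_a$fe_direction
  db <- result_b$fe_direction
  verdict <- if (is.na(da) || is.na(db) || da == "balanced" ||
                 db == "balanced" ||
                 result_a$n_informative < min_informative ||
                 result_b$n_informative < min_informative) {
    "uninformative"
  } else if (da == db) {
    "concordant"
  } else {
    "discordant"
  }
  tibble::tibble(pair_id = pair_id, direction_a = da, direction_b = db,
                 verdict = verdict)
}

#' Null probability of all-concordant allele assignment
#'
#' Probability that `n_pairs` independent sample pairs all show
#' methylation on the same allele if alleles were assigned at random: with
#' four informative pairs and a fair coin this is 0.5^4 = 6.25%, i.e. below
#' 7% — the chance level against which observed all-concordant allelic
#' methylation is judged.
#'
#' @param n_pairs Number of informative pairs (>= 1).
#' @param p_match Per-pair match probability under the null (default 0.5).
#' @return A probability.
#' @export
concordance_null_prob <- function(n_pairs, p_match = 0.5) {
  if (n_pairs < 1) stop("n_pairs must be at least 1", call. = FALSE)
  if (p_match <= 0 || p_match >= 1) {
    stop("p_match must lie in (0, 1)", call. = FALSE)
  }
  p_match^n_pairs
}

#' Tumor-to-blood VEF fold
#'
#' Ratio of the tumor combined VEF to the matched blood (WBC) combined
#' VEF, quantifying clonal expansion of the methylated lineage; a
#' methylation-free blood sample yields an infinite fold, flagged.
#'
#' @param vef_tumor,vef_wbc Combined VEFs (vectorised).
#' @return Tibble: `fold`, `infinite`.
#' @export
tumor_blood_fold <- function(vef_tumor, vef_wbc) {
  if (any(stats::na.omit(c(vef_tumor, vef_wbc)) < 0)) {
    stop("VEFs must be non-negative", call. = FALSE)
  }
  fold <- ifelse(vef_wbc == 0, Inf, vef_tumor / vef_wbc)
  tibble::tibble(fold = fold, infinite = is.infinite(fold))
}

#' One-call allele-specific analysis of a sample
#'
#' Convenience wrapper: genotypes the SNP from the fragments, extracts the
#' SNP-amplicon epialleles and, for heterozygous samples, computes the
#' per-allele VEFs and fold enrichment.
#'
#' @inheritParams genotype_snp
#' @param config A [calling_config()].
#' @return A list with `genotype` and (for het samples) `result`; for
#'   non-het samples `result` is `NULL`.
#' @export
allele_specific <- function(fragments, map, config = calling_config(),
                            min_depth = 100L, het_band = c(0.2, 0.8)) {
  snp_fr <- dplyr::filter(tibble::as_tibble(fragments),
                          .data$amplicon_id == map$snp$amplicon_id)
  gt <- genotype_snp(snp_fr, map, min_depth, het_band)
  res <- if (identical(gt$zygosity, "het")) {
    ep <- extract_epialleles(snp_fr, map, config)
    allele_vef(ep, gt, map, config)
  } else {
    NULL
  }
  list(genotype = gt, result = res)
}
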