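#' Configuration for epiallele calling and methylation positivity
#'
#' @param beta_threshold A fragment is a hypermethylated epiallele when its
#'   beta value (fraction of methylated CpGs among observed CpGs) is at or
#'   above this threshold (default 0.5).
#' @param wbc_cutoff,tumor_cutoff Tissue-specific positivity cutoffs on the
#'   combined VEF. Defaults 6.96e-4 (white blood cells) and 4.71e-2
#'   (tumor); a sample is positive only when its VEF strictly exceeds the
#'   cutoff. The two orders of magnitude between them reflect mosaic
#'   low-level methylation in blood versus clonally expanded tumors.
#' @param min_cpg_completeness Fraction of an amplicon's scored CpGs a
#'   fragment must cover to count as an epiallele (default 1: full
#'   coverage, the norm in amplicon sequencing; partial fragments bias
#'   beta).
#' @param min_fragments Minimum retained epialleles per amplicon to report
#'   a VEF (default 1000), guarding estimates at the 1e-4 scale.
#' @return A validated list of class `calling_config`.
#' @export
calling_config <- function(beta_threshold = 0.5,
                           wbc_cutoff = 6.96e-4,
                           tumor_cutoff = 4.71e-2,
                           min_cpg_completeness = 1.0,
                           min_fragments = 1000L) {
  if (wbc_cutoff <= 0 || tumor_cutoff <= 0) {
    stop("cutoffs must be positive", call. = FALSE)
  }
  if (wbc_cutoff >= tumor_cutoff) {
    stop("the WBC cutoff must be below the tumor cutoff", call. = FALSE)
  }
  if (beta_threshold < 0 || beta_threshold > 1 ||
      min_cpg_completeness < 0 || min_cpg_completeness > 1) {
    stop("beta_threshold and min_cpg_completeness must lie in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(beta_threshold = beta_threshold, wbc_cutoff = wbc_cutoff,
         tumor_cutoff = tumor_cutoff,
         min_cpg_completeness = min_cpg_completeness,
         min_fragments = as.integer(min_fragments)),
    class = "calling_config"
  )
}

#' Turn fragments into epialleles
#'
#' Counts methylated and observed CpGs per fragment, discards fragments
#' covering fewer than `min_cpg_completeness` of their amplicon's scored
#' CpGs, and computes the per-epiallele beta value (methylated / observed).
#'
#' @param fragments Fragment tibble (columns `sample_id`, `amplicon_id`,
#'   `fragment_id`, `cpg_calls`, `snp_base`).
#' @param map A [promoter_map()].
#' @param config A [calling_config()].
#' @param amplicon_ids Optional subset of amplicons to keep.
#' @return Tibble of epialleles: `sample_id`, `amplicon_id`, `fragment_id`,
#'   `n_cpg` (scored by the amplicon), `n_obs` (non-missing), `n_meth`,
#'   `beta`, `snp_base`.
#' @export
extract_epialleles <- function(fragments, map, config = calling_config(),
                               amplicon_ids = NULL) {
  fr <- tibble::as_tibble(fragments)
  if (!is.null(amplicon_ids)) {
    fr <- dplyr::filter(fr, .data$amplicon_id %in% amplicon_ids)
  }
  if (nrow(fr) == 0L) {
    return(tibble::tibble(sample_id = character(), amplicon_id = character(),
                          fragment_id = character(), n_cpg = integer(),
                          n_obs = integer(), n_meth = integer(),
                          beta = double(), snp_base = character()))
  }
  k_of <- stats::setNames(
    map$amplicons$cpg_hi - map$amplicons$cpg_lo + 1L,
    map$amplicons$amplicon_id
  )
  if (!all(fr$amplicon_id %in% names(k_of))) {
    stop("fragments reference amplicons absent from the map", call. = FALSE)
  }
  fr |>
    dplyr::mutate(
      n_cpg = unname(k_of[.data$amplicon_id]),
      n_meth = stringr::str_count(.data$cpg_calls, stringr::fixed("M")),
      n_obs = .data$n_meth + stringr::str_count(.data$cpg_calls,
                                                stringr::fixed("U"))
    ) |>
    dplyr::filter(.data$n_obs >= config$min_cpg_completeness * .data$n_cpg,
                  .data$n_obs > 0L) |>
    dplyr::mutate(beta = .data$n_meth / .data$n_obs) |>
    dplyr::select("sample_id", "amplicon_id", "fragment_id",
                  "n_cpg", "n_obs", "n_meth", "beta", "snp_base")
}

#' Per-amplicon hypermethylated variant epiallele frequency
#'
#' The VEF of an amplicon is the fraction of its epialleles whose beta
#' value is at or above `beta_threshold`. Amplicons with fewer than
#' `min_fragments` epialleles are flagged `insufficient` and get `NA`.
#'
#' @param epialleles Epiallele tibble from [extract_epialleles()].
#' @param config A [calling_config()].
#' @return Tibble: `sample_id`, `amplicon_id`, `n_fragments`, `vef`,
#'   `insufficient`.
#' @export
amplicon_vef <- function(epialleles, config = calling_config()) {
  epialleles |>
    dplyr::group_by(.data$sample_id, .data$amplicon_id) |>
    dplyr::summarise(
      n_fragments = dplyr::n(),
      vef = mean(.data$beta >= config$beta_threshold),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      insufficient = .data$n_fragments < config$min_fragments,
      vef = ifelse(.data$insufficient, NA_real_, .data$vef)
    )
}

#' Combined VEF over the central region
#'
#' The sample-level methylation measure: the arithmetic mean of the VEFs of
#' the two central amplicons (CpG14-31 and CpG17-34 in the default panel,
#' jointly covering the biologically relevant CpG14-34 window). Missing or
#' insufficient-depth VEF in either amplicon yields `NA`.
#'
#' @param vefs Per-amplicon VEF tibble from [amplicon_vef()].
#' @param map A [promoter_map()] (names the central amplicons).
#' @return Tibble: `sample_id`, `combined_vef`, `n_fragments` (total over
#'   the two amplicons).
#' @export
combined_vef <- function(vefs, map) {
  amps <- central_amplicons(map)
  vefs |>
    dplyr::filter(.data$amplicon_id %in% amps) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      combined_vef = ifelse(dplyr::n() == length(amps) && !anyNA(.data$vef),
                            mean(.data$vef), NA_real_),
      n_fragments = sum(.data$n_fragments),
      .groups = "drop"
    )
}

#' Call methylation positivity against a tissue-specific cutoff
#'
#' Positive if and only if the combined VEF strictly exceeds the cutoff of
#' the sample's tissue; a VEF exactly at the cutoff is negative.
#'
#' @param vef Numeric combined VEF (vectorised).
#' @param tissue `"WBC"` or `"tumor"` (recycled).
#' @param config A [calling_config()].
#' @return Character vector `"positive"`/`"negative"` (`NA` in, `NA` out).
#' @export
call_status <- function(vef, tissue, config = calling_config()) {
  if (!all(tissue %in% c("WBC", "tumor"))) {
    stop("tissue must be \"WBC\" or \"tumor\"", call. = FALSE)
  }
  cutoff <- ifelse(tissue == "WBC", config$wbc_cutoff, config$tumor_cutoff)
  ifelse(is.na(vef), NA_character_,
         ifelse(vef > cutoff, "positive", "negative"))
}

#' Full per-sample methylation calling
#'
#' Chains [extract_epialleles()], [amplicon_vef()], [combined_vef()] and
#' [call_status()] into the per-sample methylation table.
#'
#' @param fragments Fragment tibble covering one or more samples.
#' @param map A [promoter_map()].
#' @param config A [calling_config()].
#' @param tissue Tissue per sample: a single value or a data frame with
#'   `sample_id` and `tissue` columns.
#' @return Tibble: `sample_id`, `tissue`, one `vef_*` column per central
#'   amplicon, `combined_vef`, `n_fragments`, `status`. The full
#'   per-amplicon VEF table is attached as attribute `"per_amplicon"`.
#' @export
#' @examples
#' map <- default_promoter_map()
#' sim <- simulate_sample(map, simulation_params("het",
#'   clone_fraction_ref = 0.05, coverage = 2000), seed = 1)
#' call_samples(sim$fragments, map, calling_config(min_fragments = 500))
call_samples <- function(fragments, map, config = calling_config(),
                         tissue = "WBC") {
  ep <- extract_epialleles(fragments, map, config)
  pv <- amplicon_vef(ep, config)
  cv <- combined_vef(pv, map)
  amps <- central_amplicons(map)
  wide <- pv |>
    dplyr::filter(.data$amplicon_id %in% amps) |>
    dplyr::mutate(amplicon_id = paste0("vef_", gsub("-", "_",
                                                    tolower(.data$amplicon_id)))) |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "amplicon_id",
                       values_from = "vef")
  out <- dplyr::left_join(wide, cv, by = "sample_id")
  tis <- if (is.data.frame(tissue)) {
    dplyr::left_join(out["sample_id"], tissue, by = "sample_id")$tissue
  } else {
    rep(tissue, nrow(out))
  }
  out$tissue <- tis
  out$status <- call_status(out$combined_vef, out$tissue, config)
  out <- dplyr::relocate(out, "sample_id", "tissue")
  attr(out, "per_amplicon") <- pv
  out
}

#' Data-driven positivity cutoff from background samples
#'
#' A documented stand-in for computational cutoff derivation: the cutoff is
#' the smallest background VEF strictly exceeding the empirical
#' `1 - alpha` quantile of the background null (the quantile itself when no
#' value exceeds it). It never replaces the calibrated defaults of
#' [calling_config()] unless the caller installs it explicitly.
#'
#' @param background_vefs Numeric VEFs from samples assumed
#'   methylation-negative; at least 20 values.
#' @param alpha Upper-tail mass (default 0.01).
#' @param floor Returned (with a warning) when the background is
#'   degenerate all-zero; default 1e-4.
#' @return A single cutoff value.
#' @export
estimate_cutoff <- function(background_vefs, alpha = 0.01, floor = 1e-4) {
  v <- background_vefs[!is.na(background_vefs)]
  if (length(v) < 20L) {
    stop("need at least 20 background VEF values", call. = FALSE)
  }
  if (any(v < 0)) stop("background VEFs must be non-negative", call. = FALSE)
  if (all(v == 0)) {
    warning("degenerate all-zero background; returning the configured floor",
            call. = FALSE)
    return(floor)
  }
  q <- stats::quantile(v, 1 - alpha, names = FALSE, type = 8)
  above <- v[v > q]
  if (length(above)) min(above) else q
}

#' Ranked epiallele beta curve
#'
#' Sorts epiallele betas ascending and centres the rank axis so that the
#' first epiallele with beta at or above 0.5 sits at rank 0 (when no
#' epiallele reaches 0.5, the curve ends just below rank 0). At most
#' `max_ranks` ranks are retained on either side. A sharp incline through
#' rank 0 visualises the hypo/hyper bimodality of mosaic epimutations.
#'
#' @param epialleles Epiallele tibble (or a numeric vector of betas).
#' @param beta_threshold Centring threshold (default 0.5).
#' @param max_ranks Ranks retained each side of 0 (default 2500).
#' @return Tibble of class `vef_rank_curve`: `rank`, `beta` (plus
#'   `sample_id` when present in the input).
#' @export
rank_epialleles <- function(epialleles, beta_threshold = 0.5,
                            max_ranks = 2500L) {
  one <- function(betas, sample_id = NA_character_) {
    betas <- sort(betas)
    n <- length(betas)
    if (n == 0L) stop("no epialleles to rank", call. = FALSE)
    i0 <- match(TRUE, betas >= beta_threshold)
    if (is.na(i0)) i0 <- n + 1L  # all hypo: curve sits left of rank 0
    tibble::tibble(sample_id = sample_id,
                   rank = seq_len(n) - i0, beta = betas) |>
      dplyr::filter(abs(.data$rank) <= max_ranks)
  }
  out <- if (is.numeric(epialleles)) {
    one(epialleles)
  } else {
    epialleles |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_map(~ one(.x$beta, .y$sample_id)) |>
      dplyr::bind_rows()
  }
  class(out) <- c("vef_rank_curve", class(out))
  out
}

#' Per-CpG methylation profiles of hyper- and hypomethylated epialleles
#'
#' Partitions fragments into hypermethylated (beta >= `beta_threshold`) and
#' hypomethylated epialleles, computes the per-CpG mean methylation within
#' each partition (over fragments observing that CpG, pooled across the
#' selected amplicons), and smooths each curve with a fixed-bandwidth
#' normal-kernel mean over genomic coordinate. Raw values are returned
#' alongside the smoothed ones. An empty partition is flagged via the
#' `"missing_partitions"` attribute.
#'
#' @param fragments Fragment tibble.
#' @param map A [promoter_map()].
#' @param config A [calling_config()].
#' @param amplicon_ids Amplicons to profile (default: the central two).
#' @param bandwidth Kernel bandwidth in bases (default 40).
#' @return Tibble of class `vef_cpg_profile`: `partition` (hyper/hypo),
#'   `cpg_index`, `cpg_label`, `pos`, `n_obs`, `mean_meth`, `smoothed`.
#' @export
cpg_profile <- function(fragments, map, config = calling_config(),
                        amplicon_ids = NULL, bandwidth = 40) {
  amplicon_ids <- amplicon_ids %||% central_amplicons(map)
  ep <- extract_epialleles(fragments, map, config, amplicon_ids)
  if (nrow(ep) == 0L) stop("no epialleles to profile", call. = FALSE)
  fr <- dplyr::semi_join(tibble::as_tibble(fragments), ep,
                         by = c("sample_id", "amplicon_id", "fragment_id"))
  fr <- dplyr::left_join(
    fr, ep[, c("sample_id", "amplicon_id", "fragment_id", "beta")],
    by = c("sample_id", "amplicon_id", "fragment_id")
  )
  fr$partition <- ifelse(fr$beta >= config$beta_threshold, "hyper", "hypo")

  per_cpg <- purrr::map_dfr(amplicon_ids, function(aid) {
    sub <- fr[fr$amplicon_id == aid, ]
    if (nrow(sub) == 0L) return(NULL)
    idx <- amplicon_cpg_indices(map, aid)
    m <- matrix(unlist(strsplit(sub$cpg_calls, "", fixed = TRUE)),
                nrow = nrow(sub), byrow = TRUE)
    purrr::map_dfr(c("hyper", "hypo"), function(p) {
      rows <- sub$partition == p
      if (!any(rows)) return(NULL)
      mm <- m[rows, , drop = FALSE]
      obs <- mm != "."
      tibble::tibble(
        partition = p, cpg_index = idx,
        n_obs = colSums(obs),
        n_meth = colSums(mm == "M")
      )
    })
  })
  prof <- per_cpg |>
    dplyr::group_by(.data$partition, .data$cpg_index) |>
    dplyr::summarise(n_obs = sum(.data$n_obs), n_meth = sum(.data$n_meth),
                     .groups = "drop") |>
    dplyr::filter(.data$n_obs > 0L) |>
    dplyr::mutate(mean_meth = .data$n_meth / .data$n_obs) |>
    dplyr::left_join(map$cpgs, by = "cpg_index") |>
    dplyr::arrange(.data$partition, .data$cpg_index)

  prof <- prof |>
    dplyr::group_by(.data$partition) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) >= 2L) {
        sm <- stats::ksmooth(d$pos, d$mean_meth, kernel = "normal",
                             bandwidth = bandwidth, x.points = d$pos)
        # ksmooth sorts x.points ascending; map back to CpG order
        d$smoothed <- sm$y[match(d$pos, sm$x)]
      } else {
        d$smoothed <- d$mean_meth
      }
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::select("partition", "cpg_index", "cpg_label", "pos",
                  "n_obs", "mean_meth", "smoothed")

  missing <- setdiff(c("hyper", "hypo"), unique(prof$partition))
  if (length(missing)) {
    message("empty partition(s): ", paste(missing, collapse = ", "))
  }
  attr(prof, "missing_partitions") <- missing
  class(prof) <- c("vef_cpg_profile", class(prof))
  prof
}
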