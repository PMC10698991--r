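#' Simulation parameters for the mosaic epimutation read simulator
#'
#' The simulator draws each fragment from one of two molecular populations:
#' a hypermethylated clone (every CpG methylated before noise) emulating
#' cells carrying the epimutation, or the unmethylated background. The
#' clone fraction is set per allele, so a monoallelic constitutional
#' epimutation is a nonzero clone fraction on exactly one allele of a
#' heterozygous sample.
#'
#' Noise model, applied per CpG independently: an unmethylated cytosine is
#' read as methylated (failed bisulfite conversion) with probability
#' `conversion_failure_rate`; a methylated cytosine is read as unmethylated
#' with probability `methylation_miscall_rate`; a sequencing substitution
#' occurs with probability `sequencing_error_rate`, flipping the call with
#' probability 1/3 (C<->T) and destroying it (missing, '.') with
#' probability 2/3 (substitution to a non-informative base). The default
#' noise rates are configurable package defaults chosen so that background
#' VEF stays far below the WBC positivity cutoff.
#'
#' @param genotype `"hom_ref"`, `"het"` or `"hom_alt"`.
#' @param clone_fraction_ref,clone_fraction_alt Fraction of fragments of
#'   that allele drawn from the hypermethylated clone, each in \[0,1\]. For
#'   homozygous genotypes the clone fraction of the absent allele must be 0.
#' @param coverage Fragments simulated per amplicon (default 30000,
#'   matching the ~30,000x ultradeep design).
#' @param conversion_failure_rate,methylation_miscall_rate,sequencing_error_rate
#'   Noise rates in \[0,1\]; defaults 0.005, 0.005, 0.001.
#' @param read_length Mate length in bases (default 226; mates are paired,
#'   so fragments up to 2x226 bp minus the overlap are covered).
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(genotype = c("het", "hom_ref", "hom_alt"),
                              clone_fraction_ref = 0,
                              clone_fraction_alt = 0,
                              coverage = 30000L,
                              conversion_failure_rate = 0.005,
                              methylation_miscall_rate = 0.005,
                              sequencing_error_rate = 0.001,
                              read_length = 226L) {
  genotype <- match.arg(genotype)
  rates <- c(clone_fraction_ref, clone_fraction_alt,
             conversion_failure_rate, methylation_miscall_rate,
             sequencing_error_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("all fractions and rates must lie in [0, 1]", call. = FALSE)
  }
  if (genotype == "hom_ref" && clone_fraction_alt > 0) {
    stop("hom_ref genotype has no alt allele; clone_fraction_alt must be 0",
         call. = FALSE)
  }
  if (genotype == "hom_alt" && clone_fraction_ref > 0) {
    stop("hom_alt genotype has no ref allele; clone_fraction_ref must be 0",
         call. = FALSE)
  }
  if (coverage < 1L) stop("coverage must be >= 1", call. = FALSE)
  structure(
    list(genotype = genotype,
         clone_fraction_ref = clone_fraction_ref,
         clone_fraction_alt = clone_fraction_alt,
         coverage = as.integer(coverage),
         conversion_failure_rate = conversion_failure_rate,
         methylation_miscall_rate = methylation_miscall_rate,
         sequencing_error_rate = sequencing_error_rate,
         read_length = as.integer(read_length)),
    class = "simulation_params"
  )
}

#' Deterministic per-sample seed
#'
#' Derives a 32-bit seed from a master seed and a sample identifier, so a
#' cohort is reproducible sample-by-sample regardless of simulation order.
#'
#' @param seed Master integer seed.
#' @param sample_id Character identifier.
#' @return An integer seed in \[0, 2^31-2\].
#' @export
sample_seed <- function(seed, sample_id) {
  h <- 0
  for (cp in utf8ToInt(as.character(sample_id))) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# allele-weighted probability that a fragment belongs to the clone
clone_prob <- function(params) {
  switch(params$genotype,
         het = 0.5 * params$clone_fraction_ref + 0.5 * params$clone_fraction_alt,
         hom_ref = params$clone_fraction_ref,
         hom_alt = params$clone_fraction_alt)
}

#' Exact per-fragment call probabilities under the noise model
#'
#' Collapses the per-CpG noise model into the fragment-level law: the
#' probability a fragment survives the full-completeness filter (no missing
#' CpG) and, given survival, the probability it is called hypermethylated
#' (beta >= `beta_threshold`). Useful for power calculations and as the
#' exact sampling law behind [simulate_cohort()]'s fast observation mode.
#'
#' @param clone_fraction Allele-weighted clone fraction (true VEF).
#' @param params A [simulation_params()] object (noise rates are used).
#' @param n_cpg Number of CpGs scored by the amplicon.
#' @param beta_threshold Hypermethylation threshold on the fragment beta.
#' @return List with `p_retain`, `p_hyper_given_retained`, and the
#'   per-CpG conditional methylation-call probabilities for clone and
#'   background fragments.
#' @export
hyper_call_prob <- function(clone_fraction, params, n_cpg,
                            beta_threshold = 0.5) {
  se <- params$sequencing_error_rate
  mm <- params$methylation_miscall_rate
  cf <- params$conversion_failure_rate
  p_miss <- 2 * se / 3
  p_retain <- (1 - p_miss)^n_cpg
  # P(call M | pre-noise state), then condition on the call not missing
  pM_clone <- ((1 - mm) * (1 - se) + mm * se / 3) / (1 - p_miss)
  pM_bg <- (cf * (1 - se) + (1 - cf) * se / 3) / (1 - p_miss)
  m_min <- ceiling(beta_threshold * n_cpg)  # beta >= t  <=>  m >= t*k
  p_hyper_clone <- stats::pbinom(m_min - 1L, n_cpg, pM_clone, lower.tail = FALSE)
  p_hyper_bg <- stats::pbinom(m_min - 1L, n_cpg, pM_bg, lower.tail = FALSE)
  v <- clone_fraction
  list(
    p_retain = p_retain,
    p_hyper_given_retained = v * p_hyper_clone + (1 - v) * p_hyper_bg,
    p_meth_call_clone = pM_clone,
    p_meth_call_background = pM_bg
  )
}

# simulate CpG call strings for one amplicon; returns list(calls, clone)
simulate_amplicon_calls <- function(n, k, clone, params) {
  mm <- params$methylation_miscall_rate
  cf <- params$conversion_failure_rate
  se <- params$sequencing_error_rate
  state <- matrix(clone, nrow = n, ncol = k)  # TRUE = methylated
  if (mm > 0 || cf > 0) {
    u <- matrix(stats::runif(n * k), n, k)
    state <- (state & u >= mm) | (!state & u < cf)
  }
  ch <- matrix("U", n, k)
  ch[state] <- "M"
  if (se > 0) {
    u <- matrix(stats::runif(n * k), n, k)
    flip <- u >= 2 * se / 3 & u < se
    ch[flip] <- ifelse(ch[flip] == "M", "U", "M")
    ch[u < 2 * se / 3] <- "."
  }
  do.call(paste0, lapply(seq_len(k), function(j) ch[, j]))
}

#' Simulate one sample's bisulfite amplicon fragments
#'
#' Per amplicon, `coverage` fragments are drawn. Each fragment is assigned
#' an allele (50/50 for heterozygous samples), drawn from the
#' hypermethylated clone with the clone fraction of its allele, and CpG
#' calls are produced under the noise model of [simulation_params()]. The
#' SNP base is emitted for fragments of the amplicon covering the SNP.
#' Identical `(map, params, sample_id, seed)` give bit-identical output.
#'
#' @param map A [promoter_map()].
#' @param params A [simulation_params()].
#' @param sample_id Sample identifier (also seeds the per-sample stream via
#'   [sample_seed()]).
#' @param seed Master integer seed.
#' @param amplicon_ids Optional subset of amplicons to simulate (default:
#'   all amplicons of the map).
#' @return List with `fragments` (tibble: `sample_id`, `amplicon_id`,
#'   `fragment_id`, `cpg_calls` over \{M,U,.\}, `snp_base`, truth columns
#'   `true_allele`, `true_clone`) and `truth` (tibble of true VEF per
#'   amplicon plus the combined region; the combined value is the mean of
#'   the two central amplicons' clone fractions).
#' @export
#' @examples
#' map <- default_promoter_map()
#' p <- simulation_params("het", clone_fraction_ref = 0.02, coverage = 500)
#' sim <- simulate_sample(map, p, sample_id = "S1", seed = 7)
#' head(sim$fragments)
simulate_sample <- function(map, params, sample_id = "S1", seed = 1L,
                            amplicon_ids = NULL) {
  stopifnot(inherits(map, "promoter_map"), inherits(params, "simulation_params"))
  amplicon_ids <- amplicon_ids %||% map$amplicons$amplicon_id
  if (!all(amplicon_ids %in% map$amplicons$amplicon_id)) {
    stop("unknown amplicon id(s)", call. = FALSE)
  }
  n <- params$coverage
  frags <- withr::with_seed(sample_seed(seed, sample_id), {
    purrr::map(amplicon_ids, function(aid) {
      k <- length(amplicon_cpg_indices(map, aid))
      allele <- switch(params$genotype,
        het = sample(c("ref", "alt"), n, replace = TRUE),
        hom_ref = rep("ref", n),
        hom_alt = rep("alt", n))
      cfrac <- ifelse(allele == "ref",
                      params$clone_fraction_ref, params$clone_fraction_alt)
      clone <- stats::runif(n) < cfrac
      calls <- simulate_amplicon_calls(n, k, clone, params)
      covers_snp <- aid == map$snp$amplicon_id
      if (covers_snp) {
        base <- ifelse(allele == "ref", map$snp$ref_base, map$snp$alt_base)
        se <- params$sequencing_error_rate
        if (se > 0) {
          err <- which(stats::runif(n) < se)
          if (length(err)) {
            base[err] <- vapply(base[err], function(b) {
              sample(setdiff(c("A", "C", "G", "T"), b), 1L)
            }, character(1))
          }
        }
      } else {
        base <- rep(".", n)
      }
      tibble::tibble(
        sample_id = sample_id,
        amplicon_id = aid,
        fragment_id = sprintf("%s:%s:%06d", sample_id, aid, seq_len(n)),
        cpg_calls = calls,
        snp_base = base,
        true_allele = allele,
        true_clone = clone
      )
    })
  })
  fragments <- dplyr::bind_rows(frags)

  v <- clone_prob(params)
  true_allele <- if (params$clone_fraction_ref > 0 && params$clone_fraction_alt > 0) {
    "both"
  } else if (params$clone_fraction_ref > 0) {
    "ref"
  } else if (params$clone_fraction_alt > 0) {
    "alt"
  } else {
    "none"
  }
  truth <- tibble::tibble(
    sample_id = sample_id,
    amplicon_id = c(amplicon_ids, "combined"),
    true_vef = v,
    true_allele = true_allele
  )
  list(fragments = fragments, truth = truth, params = params)
}

#' Simulate a cohort of samples with mosaic epimutation carriers
#'
#' Carrier status is drawn per sample from the group prevalence;
#' non-carriers have clone fraction 0 on both alleles, carriers draw a true
#' combined VEF from a log-uniform distribution over
#' \[`vef_min`, `vef_max`\] (default \[1e-3, 1e-1\], a blood-like mosaic
#' range) and place the clone on one randomly chosen allele of a
#' heterozygous genotype. With `observe = TRUE` the observed per-amplicon
#' VEFs and the positivity call are drawn from the exact fragment-level law
#' ([hyper_call_prob()]) without materialising fragments, which makes
#' large cohorts cheap; with `fragments = TRUE` full fragment tibbles are
#' generated via [simulate_sample()] (intended for small designs).
#'
#' @param design Data frame with one row per group: `group`, `n`,
#'   `prevalence`, optional `vef_min`, `vef_max`, `tissue` (default WBC).
#' @param map A [promoter_map()].
#' @param params Baseline [simulation_params()] (noise, coverage).
#' @param seed Master seed; each sample's stream derives from it.
#' @param config A [calling_config()] used for the observation-mode status
#'   call.
#' @param observe Draw observed VEFs and statuses (default TRUE).
#' @param fragments Also generate per-fragment data (default FALSE).
#' @return List with `truth` (tibble: `sample_id`, `group`, `tissue`,
#'   `carrier`, `true_vef`, `true_allele`, and when `observe = TRUE` the
#'   observed `vef_*`, `combined_vef`, `status`) and, when
#'   `fragments = TRUE`, `fragments` (bound tibble over all samples).
#' @export
simulate_cohort <- function(design, map, params = simulation_params(),
                            seed = 1L, config = calling_config(),
                            observe = TRUE, fragments = FALSE) {
  design <- tibble::as_tibble(design)
  if (nrow(design) == 0L) stop("empty cohort design", call. = FALSE)
  if (!all(c("group", "n", "prevalence") %in% names(design))) {
    stop("`design` needs columns group, n, prevalence", call. = FALSE)
  }
  if (any(design$prevalence < 0 | design$prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (!"vef_min" %in% names(design)) design$vef_min <- 1e-3
  if (!"vef_max" %in% names(design)) design$vef_max <- 1e-1
  if (!"tissue" %in% names(design)) design$tissue <- "WBC"
  if (any(design$vef_max > 0.5)) {
    stop("carrier VEF above 0.5 cannot be placed on a single allele ",
         "of a heterozygous sample", call. = FALSE)
  }

  truth <- withr::with_seed(as.integer(seed), {
    purrr::pmap_dfr(design, function(group, n, prevalence, vef_min, vef_max,
                                     tissue, ...) {
      carrier <- stats::runif(n) < prevalence
      vef <- rep(0, n)
      if (any(carrier)) {
        if (vef_min == vef_max) {
          vef[carrier] <- vef_min
        } else {
          vef[carrier] <- 10^stats::runif(sum(carrier),
                                          log10(vef_min), log10(vef_max))
        }
      }
      allele <- rep("none", n)
      allele[carrier] <- sample(c("ref", "alt"), sum(carrier), replace = TRUE)
      tibble::tibble(
        sample_id = sprintf("%s_%04d", group, seq_len(n)),
        group = group, tissue = tissue,
        carrier = carrier, true_vef = vef, true_allele = allele
      )
    })
  })

  if (observe) {
    amps <- central_amplicons(map)
    ks <- vapply(amps, function(a) length(amplicon_cpg_indices(map, a)), 1L)
    obs <- withr::with_seed(sample_seed(seed, "cohort_observation"), {
      purrr::map_dfr(seq_len(nrow(truth)), function(i) {
        v <- truth$true_vef[i]
        vefs <- vapply(seq_along(amps), function(j) {
          pr <- hyper_call_prob(v, params, ks[j], config$beta_threshold)
          n_ret <- stats::rbinom(1L, params$coverage, pr$p_retain)
          if (n_ret == 0L) return(NA_real_)
          stats::rbinom(1L, n_ret, pr$p_hyper_given_retained) / n_ret
        }, numeric(1))
        tibble::tibble(!!!stats::setNames(as.list(vefs),
                                          paste0("vef_", gsub("-", "_", tolower(amps)))))
      })
    })
    truth <- dplyr::bind_cols(truth, obs)
    truth$combined_vef <- rowMeans(as.matrix(obs))
    truth$status <- call_status(truth$combined_vef, truth$tissue, config)
  }

  out <- list(truth = truth, design = design)
  if (fragments) {
    out$fragments <- dplyr::bind_rows(purrr::map(seq_len(nrow(truth)), function(i) {
      p <- params
      if (truth$carrier[i]) {
        cf <- 2 * truth$true_vef[i]  # one allele of a het carries the clone
        p <- simulation_params(
          genotype = "het",
          clone_fraction_ref = if (truth$true_allele[i] == "ref") cf else 0,
          clone_fraction_alt = if (truth$true_allele[i] == "alt") cf else 0,
          coverage = params$coverage,
          conversion_failure_rate = params$conversion_failure_rate,
          methylation_miscall_rate = params$methylation_miscall_rate,
          sequencing_error_rate = params$sequencing_error_rate,
          read_length = params$read_length
        )
      } else {
        p <- simulation_params(
          genotype = "het", coverage = params$coverage,
          conversion_failure_rate = params$conversion_failure_rate,
          methylation_miscall_rate = params$methylation_miscall_rate,
          sequencing_error_rate = params$sequencing_error_rate,
          read_length = params$read_length
        )
      }
      simulate_sample(map, p, sample_id = truth$sample_id[i],
                      seed = seed)$fragments
    }))
  }
  out
}
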