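make_fragments <- function(calls, amplicon_id = "CpG14-31",
                           sample_id = "T1", snp_base = ".") {
  tibble::tibble(
    sample_id = sample_id, amplicon_id = amplicon_id,
    fragment_id = sprintf("%s:%s:%04d", sample_id, amplicon_id,
                          seq_along(calls)),
    cpg_calls = calls, snp_base = snp_base
  )
}

test_that("beta is the methylated fraction of observed CpGs", {
  map <- test_map()
  cc <- calling_config(min_cpg_completeness = 0)
  # M,M,M,U over an 18-CpG amplicon with the rest missing -> beta 0.75
  fr <- make_fragments(paste0("MMMU", strrep(".", 14L)))
  ep <- extract_epialleles(fr, map, cc)
  expect_equal(ep$beta, 0.75)
  expect_equal(ep$n_obs, 4L)
  # full completeness discards a fragment covering 3 of 18 CpGs
  cc1 <- calling_config(min_cpg_completeness = 1)
  fr2 <- make_fragments(paste0("MUM", strrep(".", 15L)))
  expect_equal(nrow(extract_epialleles(fr2, map, cc1)), 0L)
  # empty in, empty out
  expect_equal(nrow(extract_epialleles(fr2[0, ], map, cc1)), 0L)
})

test_that("zero-noise background fragments all have beta 0", {
  map <- test_map()
  sim <- simulate_sample(map, quiet_params("het", coverage = 1000L), seed = 6,
                         amplicon_ids = "CpG17-34")
  ep <- extract_epialleles(sim$fragments, map, calling_config())
  expect_equal(nrow(ep), 1000L)
  expect_true(all(ep$beta == 0))
})

test_that("amplicon VEF is the hypermethylated epiallele fraction", {
  map <- test_map()
  cc <- calling_config(min_fragments = 50L, min_cpg_completeness = 0)
  calls <- c(rep(strrep("M", 18L), 3L), rep(strrep("U", 18L), 97L))
  ep <- extract_epialleles(make_fragments(calls), map, cc)
  v <- amplicon_vef(ep, cc)
  expect_equal(v$vef, 0.03)
  expect_false(v$insufficient)
  # below min_fragments -> flagged, no value
  cc2 <- calling_config(min_fragments = 1000L)
  v2 <- amplicon_vef(ep, cc2)
  expect_true(v2$insufficient)
  expect_true(is.na(v2$vef))
})

test_that("simulated VEF recovers the clone fraction within binomial error", {
  map <- test_map()
  p <- simulation_params("hom_ref", clone_fraction_ref = 0.01,
                         coverage = 30000L)
  sim <- simulate_sample(map, p, "R1", seed = 13, amplicon_ids = "CpG14-31")
  cc <- calling_config()
  v <- amplicon_vef(extract_epialleles(sim$fragments, map, cc), cc)
  expect_lt(abs(v$vef - 0.01), 4 * sqrt(0.01 * 0.99 / 30000))
})

test_that("combined VEF averages the two central amplicons", {
  map <- test_map()
  pv <- tibble::tibble(
    sample_id = "T1",
    amplicon_id = c("CpG00-13", "CpG14-31", "CpG17-34", "CpG33-49"),
    n_fragments = 2000L, vef = c(0.9, 0.02, 0.04, 0.5),
    insufficient = FALSE
  )
  cv <- combined_vef(pv, map)
  expect_equal(cv$combined_vef, 0.03)  # flanking amplicons do not enter
  expect_equal(cv$n_fragments, 4000L)
  # either central VEF missing -> no combined value
  pv$vef[2] <- NA_real_
  expect_true(is.na(combined_vef(pv, map)$combined_vef))
  pv2 <- pv[pv$amplicon_id == "CpG17-34", ]
  expect_true(is.na(combined_vef(pv2, map)$combined_vef))
})

test_that("positivity is strict: at the cutoff is negative", {
  cc <- calling_config()
  expect_equal(call_status(1e-3, "WBC", cc), "positive")
  expect_equal(call_status(1e-3, "tumor", cc), "negative")
  expect_equal(call_status(6.96e-4, "WBC", cc), "negative")
  expect_equal(call_status(4.71e-2, "tumor", cc), "negative")
  expect_error(call_status(0.1, "saliva", cc), "tissue")
  expect_true(is.na(call_status(NA_real_, "WBC", cc)))
})

test_that("calling config rejects inconsistent cutoffs", {
  expect_error(calling_config(wbc_cutoff = 0), "positive")
  expect_error(calling_config(wbc_cutoff = 0.5, tumor_cutoff = 0.1),
               "below the tumor cutoff")
})

test_that("estimate_cutoff follows the background null", {
  expect_error(estimate_cutoff(rep(0, 10)), "at least 20")
  expect_warning(cut0 <- estimate_cutoff(rep(0, 50), floor = 1e-4),
                 "all-zero")
  expect_equal(cut0, 1e-4)
  # uniform background on [0, 1e-4] at alpha = 0.01: cutoff near 0.99e-4
  bg <- withr::with_seed(8, runif(20000, 0, 1e-4))
  expect_lt(abs(estimate_cutoff(bg, alpha = 0.01) - 0.99e-4), 0.03e-4)
  # a null cohort under default noise yields a cutoff below the smallest
  # carrier VEF considered detectable (1e-3)
  map <- test_map()
  p <- simulation_params("het", coverage = 3000L)
  cc <- calling_config(min_fragments = 500L)
  null_vefs <- vapply(1:25, function(s) {
    sim <- simulate_sample(map, p, paste0("N", s), seed = s,
                           amplicon_ids = c("CpG14-31", "CpG17-34"))
    combined_vef(amplicon_vef(extract_epialleles(sim$fragments, map, cc), cc),
                 map)$combined_vef
  }, numeric(1))
  # at default noise no background fragment reaches beta 0.5, so the null
  # is degenerate and the floor applies -- a conservative noise regime
  expect_warning(cut_null <- estimate_cutoff(null_vefs, floor = 1e-4),
                 "all-zero")
  expect_lt(cut_null, 1e-3)
})

test_that("ranked beta curves are centred at the first hyper epiallele", {
  betas <- c(rep(0.98, 60L), rep(0.01, 40L))
  rc <- rank_epialleles(betas)
  expect_equal(rc$rank, -40:59)
  expect_equal(rc$beta[rc$rank == 0], 0.98)
  expect_true(all(rc$beta[rc$rank < 0] < 0.5))
  # all-hypo sample: the whole curve sits left of rank 0
  rc0 <- rank_epialleles(rep(0, 30L))
  expect_true(all(rc0$rank < 0))
  expect_equal(max(rc0$rank), -1L)
  # rank window is clipped at +/- max_ranks
  rc3 <- rank_epialleles(c(rep(0, 4000L), rep(1, 4000L)), max_ranks = 2500L)
  expect_equal(range(rc3$rank), c(-2500L, 2500L))
  expect_error(rank_epialleles(numeric(0)), "no epialleles")
})

test_that("simulated carriers show few intermediate-methylation epialleles", {
  map <- test_map()
  p <- simulation_params("het", clone_fraction_ref = 0.4, coverage = 4000L)
  sim <- simulate_sample(map, p, "BM1", seed = 17,
                         amplicon_ids = c("CpG14-31", "CpG17-34"))
  ep <- extract_epialleles(sim$fragments, map, calling_config())
  expect_lt(mean(ep$beta > 0.2 & ep$beta < 0.8), 0.05)
})

test_that("CpG profiles separate hyper and hypo epialleles", {
  map <- test_map()
  p <- simulation_params("het", clone_fraction_ref = 0.3, coverage = 1500L)
  sim <- simulate_sample(map, p, "P1", seed = 19,
                         amplicon_ids = c("CpG14-31", "CpG17-34"))
  prof <- cpg_profile(sim$fragments, map, calling_config())
  expect_setequal(unique(prof$partition), c("hyper", "hypo"))
  # the profiled window is CpG14..34
  expect_equal(sort(unique(prof$cpg_index)), 14:34)
  hyper <- prof$mean_meth[prof$partition == "hyper"]
  hypo <- prof$mean_meth[prof$partition == "hypo"]
  expect_true(all(hyper > 0.9))
  # hypo raw profile sits at the conversion-failure rate, within binomial error
  n_hypo <- min(prof$n_obs[prof$partition == "hypo"])
  expect_true(all(abs(hypo - 0.005) < 4 * sqrt(0.005 * 0.995 / n_hypo) + 5e-4))
  expect_true(all(prof$smoothed >= 0 & prof$smoothed <= 1))

  # zero-noise degenerate partitions: raw profiles exactly 0 / 1
  sim0 <- simulate_sample(map, quiet_params("hom_ref",
    clone_fraction_ref = 0.5, coverage = 400L), seed = 23,
    amplicon_ids = "CpG14-31")
  prof0 <- cpg_profile(sim0$fragments, map, calling_config())
  expect_true(all(prof0$mean_meth[prof0$partition == "hyper"] == 1))
  expect_true(all(prof0$mean_meth[prof0$partition == "hypo"] == 0))
  # an all-background sample has no hyper partition and says so
  simbg <- simulate_sample(map, quiet_params(coverage = 200L), seed = 29,
                           amplicon_ids = "CpG14-31")
  expect_message(profbg <- cpg_profile(simbg$fragments, map),
                 "empty partition")
  expect_equal(attr(profbg, "missing_partitions"), "hyper")
})
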