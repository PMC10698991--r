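test_that("exact intervals reproduce the published cohort frequencies", {
  r1 <- function(x) round(x, 1)
  ci <- clopper_pearson_ci(14, 72)
  expect_equal(r1(ci$point_pct), 19.4)
  expect_equal(r1(c(ci$lower_pct, ci$upper_pct)), c(11.1, 30.5))
  ci <- clopper_pearson_ci(9, 200)
  expect_equal(r1(c(ci$lower_pct, ci$upper_pct)), c(2.1, 8.4))
  ci <- clopper_pearson_ci(17, 66)
  expect_equal(r1(c(ci$lower_pct, ci$upper_pct)), c(15.8, 38.0))
  ci <- clopper_pearson_ci(10, 66)
  expect_equal(r1(ci$upper_pct), 26.1)
  ci <- clopper_pearson_ci(16, 531)
  expect_equal(r1(c(ci$lower_pct, ci$upper_pct)), c(1.7, 4.8))
  ci <- clopper_pearson_ci(46, 575)
  expect_equal(r1(c(ci$lower_pct, ci$upper_pct)), c(5.9, 10.5))
  # boundary: zero successes pin the lower bound at 0
  expect_equal(clopper_pearson_ci(0, 50)$lower_pct, 0)
  expect_equal(clopper_pearson_ci(50, 50)$upper_pct, 100)
  expect_error(clopper_pearson_ci(5, 0), "trials")
  expect_error(clopper_pearson_ci(6, 5), "successes")
})

test_that("interval bounds agree with binomial-tail bisection (spot grid)", {
  grid <- expand.grid(n = c(1, 7, 72, 131, 200), frac = c(0, 0.1, 0.5, 0.9, 1))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]
    x <- round(grid$frac[i] * n)
    ci <- clopper_pearson_ci(x, n)
    oracle <- cp_bisect(x, n)
    expect_equal(ci$lower_pct / 100, oracle$lower, tolerance = 1e-9)
    expect_equal(ci$upper_pct / 100, oracle$upper, tolerance = 1e-9)
  }
})

test_that("Fisher p matches publication values and the enumeration oracle", {
  girls_boys <- matrix(c(113, 1147, 9, 191), 2, byrow = TRUE)
  expect_equal(round(fisher_exact_2x2(girls_boys)$p_two_sided, 3), 0.038)
  parents <- matrix(c(46, 529, 16, 515), 2, byrow = TRUE)
  expect_equal(round(fisher_exact_2x2(parents)$p_two_sided, 4), 3e-04)
  tnbc <- matrix(c(10, 7, 5, 44), 2, byrow = TRUE)
  expect_lt(fisher_exact_2x2(tnbc)$p_two_sided, 0.001)
  # enumeration oracle on the small table with 8 candidate configurations
  m <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact_2x2(m)$p_two_sided, fisher_enum_p(m))
  # symmetric table
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_two_sided, 1)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "positive")
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Fisher p is invariant under simultaneous row and column swap", {
  set.seed(53)
  for (i in 1:20) {
    m <- matrix(rpois(4, 8), 2)
    if (sum(m) == 0) next
    swapped <- m[2:1, 2:1]
    expect_equal(fisher_exact_2x2(m)$p_two_sided,
                 fisher_exact_2x2(swapped)$p_two_sided)
  }
})

test_that("Clopper-Pearson coverage is conservative at p = 0.09, n = 200", {
  x <- withr::with_seed(61, rbinom(2000, 200, 0.09))
  ci <- clopper_pearson_ci(x, rep(200L, 2000L))
  covered <- ci$lower_pct / 100 <= 0.09 & ci$upper_pct / 100 >= 0.09
  expect_gte(mean(covered), 0.95)
})

test_that("concordance tables reproduce the matched-cohort layout", {
  # 17/66 tumor-methylated of whom 10 WBC-positive; 5/49 among unmethylated
  pairs <- tibble::tibble(
    tumor = rep(c("positive", "negative"), c(17L, 49L)),
    wbc = c(rep(c("positive", "negative"), c(10L, 7L)),
            rep(c("positive", "negative"), c(5L, 44L)))
  )
  ct <- concordance_table(pairs, tumor, wbc)
  expect_equal(unname(ct$counts), matrix(c(10L, 5L, 7L, 44L), 2))
  expect_lt(ct$fisher$p_two_sided, 0.001)
  # all-negative pairs: degenerate table, p = 1
  allneg <- tibble::tibble(a = rep("negative", 12L), b = rep("negative", 12L))
  ct0 <- concordance_table(allneg, a, b)
  expect_equal(sum(ct0$counts), 12L)
  expect_equal(ct0$fisher$p_two_sided, 1)
  # pairs with missing status are excluded with a message
  pairs$wbc[1] <- NA
  expect_message(ct2 <- concordance_table(pairs, tumor, wbc), "excluded")
  expect_equal(sum(ct2$counts), 65L)
})

test_that("independent statuses show no systematic pair concordance", {
  ps <- vapply(1:40, function(s) {
    d <- withr::with_seed(1000 + s, tibble::tibble(
      a = sample(c("positive", "negative"), 60, TRUE, prob = c(0.3, 0.7)),
      b = sample(c("positive", "negative"), 60, TRUE, prob = c(0.3, 0.7))
    ))
    concordance_table(d, a, b)$fisher$p_two_sided
  }, numeric(1))
  # under the null, small p should be rare, not systematic
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps > 0.2), 0.5)
})

test_that("group comparisons dispatch the requested tests", {
  d <- tibble::tibble(
    vef = c(1, 2, 3, 4, 1, 2, 3, 4),
    sex = rep(c("f", "m"), each = 4L),
    pid = rep(1:4, 2L)
  )
  w <- group_vef_comparison(d, vef, "wilcoxon", sex)
  expect_equal(w$p_value, 1, tolerance = 0.01)
  # a large constructed paired shift is significant
  d2 <- d
  d2$vef[d2$sex == "m"] <- d2$vef[d2$sex == "m"] + c(9.6, 10.3, 9.9, 10.4)
  pt <- group_vef_comparison(d2, vef, "paired_t", sex, pair = pid)
  expect_lt(pt$p_value, 0.01)
  expect_error(group_vef_comparison(d[d$sex == "f", ], vef, "wilcoxon", sex),
               "non-empty")
  expect_error(
    group_vef_comparison(d[-1, ], vef, "paired_t", sex, pair = pid),
    "complete pairing"
  )
})

test_that("two-way ANOVA on a null design rarely rejects either factor", {
  rejections <- vapply(1:50, function(s) {
    d <- withr::with_seed(2000 + s, tibble::tibble(
      vef = 10^runif(48, -3, -1),
      sex = rep(c("f", "m"), each = 24L),
      age = rep(rep(c("newborn", "adult"), each = 12L), 2L)
    ))
    res <- group_vef_comparison(d, vef, "anova2", sex, age)
    any(res$p_value < 0.05)
  }, logical(1))
  expect_lte(mean(rejections), 0.1)
})

test_that("cohort reports assemble frequencies, CIs and comparisons", {
  map <- test_map()
  design <- tibble::tibble(group = c("girls", "boys"), n = c(300L, 100L),
                           prevalence = c(0.09, 0.045))
  sim <- simulate_cohort(design, map, simulation_params(coverage = 30000L),
                         seed = 71, observe = TRUE)
  rep_ <- cohort_report(sim$truth, sim$truth[, c("sample_id", "group")])
  expect_setequal(rep_$frequencies$group, c("girls", "boys"))
  expect_true(all(rep_$frequencies$lower_pct <= rep_$frequencies$point_pct))
  expect_true(all(rep_$frequencies$upper_pct >= rep_$frequencies$point_pct))
  expect_equal(nrow(rep_$comparisons), 1L)
  expect_identical(rep_$adjustment, "none")
  # single group: one CI, no tests
  one <- cohort_report(sim$truth[sim$truth$group == "girls", ],
                       tibble::tibble(
                         sample_id = sim$truth$sample_id[sim$truth$group == "girls"],
                         group = "girls"))
  expect_equal(nrow(one$frequencies), 1L)
  expect_equal(nrow(one$comparisons), 0L)
  expect_error(cohort_report(sim$truth, sim$truth[0, c("sample_id", "group")]),
               "empty sample sheet")
  expect_error(
    cohort_report(sim$truth, sim$truth[, c("sample_id", "group")],
                  comparisons = list(c("girls", "fathers"))),
    "absent"
  )
})
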