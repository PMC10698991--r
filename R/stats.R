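#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Tail-inversion exact interval for a binomial proportion, the interval
#' family behind every cohort methylation frequency this package reports
#' (e.g. 14 methylation-concordant patients out of 72 gives 19.4%, 95% CI
#' 11.1-30.5%). Bounds are computed via the beta-quantile form of the
#' binomial tail inversion and kept at full precision; percentages are
#' rounded only for display.
#'
#' @param successes,trials Non-negative integer counts (vectorised),
#'   `successes <= trials`, `trials >= 1`.
#' @param confidence Confidence level (default 0.95).
#' @return Tibble of class `vef_ci`: `successes`, `trials`, `point_pct`,
#'   `lower_pct`, `upper_pct`, `confidence`.
#' @export
#' @examples
#' clopper_pearson_ci(14, 72)
clopper_pearson_ci <- function(successes, trials, confidence = 0.95) {
  if (any(trials < 1)) stop("trials must be >= 1", call. = FALSE)
  if (any(successes < 0) || any(successes > trials)) {
    stop("need 0 <= successes <= trials", call. = FALSE)
  }
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must lie in (0, 1)", call. = FALSE)
  }
  a <- 1 - confidence
  x <- successes
  n <- trials
  lower <- ifelse(x == 0, 0, stats::qbeta(a / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - a / 2, x + 1, n - x))
  out <- tibble::tibble(
    successes = x, trials = n,
    point_pct = 100 * x / n,
    lower_pct = 100 * lower, upper_pct = 100 * upper,
    confidence = confidence
  )
  class(out) <- c("vef_ci", class(out))
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Standard two-sided Fisher test: the p-value sums hypergeometric
#' probabilities of all tables (with the observed margins) no more
#' probable than the observed one. The odds ratio is the conditional
#' maximum-likelihood estimate and may be infinite.
#'
#' @param table A 2x2 matrix (or coercible) of non-negative integer
#'   counts with a positive total.
#' @return Object of class `vef_fisher`: list with `table`, `p_two_sided`,
#'   `odds_ratio`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(113, 9, 1147, 191), 2))
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(m) == 0) stop("the table total must be positive", call. = FALSE)
  ft <- stats::fisher.test(m)
  structure(
    list(table = m, p_two_sided = ft$p.value,
         odds_ratio = unname(ft$estimate)),
    class = "vef_fisher"
  )
}

#' @export
print.vef_fisher <- function(x, ...) {
  cat("<vef_fisher> two-sided Fisher exact test\n")
  print(x$table)
  cat(sprintf("p = %.4g, odds ratio (cMLE) = %.4g\n",
              x$p_two_sided, x$odds_ratio))
  invisible(x)
}

#' Paired-status concordance table
#'
#' Cross-tabulates a binary methylation status in two paired measurements
#' (e.g. WBC vs tumor of the same patient, or newborn vs parent) and
#' attaches a two-sided Fisher exact test. Rows index the first status
#' (positive first), columns the second. Pairs with a missing status are
#' excluded with a message.
#'
#' @param pairs Data frame with one row per pair.
#' @param status_a,status_b Columns (tidy-eval) holding
#'   `"positive"`/`"negative"` statuses.
#' @return Object of class `vef_concordance`: list with `counts` (2x2
#'   matrix), `fisher` ([fisher_exact_2x2()] result) and `n_excluded`.
#' @export
concordance_table <- function(pairs, status_a, status_b) {
  a <- dplyr::pull(pairs, {{ status_a }})
  b <- dplyr::pull(pairs, {{ status_b }})
  ok <- !is.na(a) & !is.na(b)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(n_excluded, " pair(s) excluded for missing status")
  }
  lv <- c("positive", "negative")
  counts <- table(factor(a[ok], levels = lv), factor(b[ok], levels = lv))
  counts <- matrix(as.integer(counts), 2, 2, dimnames = dimnames(counts))
  structure(
    list(counts = counts, fisher = fisher_exact_2x2(counts),
         n_excluded = n_excluded),
    class = "vef_concordance"
  )
}

#' @export
print.vef_concordance <- function(x, ...) {
  cat("<vef_concordance>\n")
  print(x$counts)
  cat(sprintf("Fisher two-sided p = %.4g (%d pair(s) excluded)\n",
              x$fisher$p_two_sided, x$n_excluded))
  invisible(x)
}

#' Compare VEF distributions between groups
#'
#' Dispatches the comparison the study design calls for: a two-way
#' analysis of variance over two crossed factors (e.g. sex by age group),
#' a Wilcoxon rank-sum test between two groups, or a paired t test on
#' matched measurements. Groups must be non-empty; the paired t requires a
#' complete pairing.
#'
#' @param data Data frame of per-sample values.
#' @param vef Column (tidy-eval) holding the VEF (or any numeric measure).
#' @param kind `"anova2"`, `"wilcoxon"` or `"paired_t"`.
#' @param factor1,factor2 Grouping columns (tidy-eval). `anova2` uses
#'   both; `wilcoxon` uses `factor1` (two levels); `paired_t` uses
#'   `factor1` (two levels) with `pair` identifying matched rows.
#' @param pair Pairing column (tidy-eval), `paired_t` only.
#' @return Tibble of class `vef_comparison`: `kind`, `term`, `statistic`,
#'   `p_value`.
#' @export
group_vef_comparison <- function(data, vef, kind = c("anova2", "wilcoxon",
                                                     "paired_t"),
                                 factor1, factor2 = NULL, pair = NULL) {
  kind <- match.arg(kind)
  y <- dplyr::pull(data, {{ vef }})
  f1 <- factor(dplyr::pull(data, {{ factor1 }}))
  if (any(table(f1) == 0L) || nlevels(f1) < 2L) {
    stop("each comparison group must be non-empty (>= 2 groups)", call. = FALSE)
  }
  out <- switch(kind,
    anova2 = {
      f2 <- factor(dplyr::pull(data, {{ factor2 }}))
      if (nlevels(f2) < 2L) stop("anova2 needs two factors", call. = FALSE)
      fit <- stats::aov(y ~ f1 + f2)
      sm <- summary(fit)[[1L]]
      terms <- trimws(rownames(sm))
      keep <- terms != "Residuals"
      tibble::tibble(kind = "two-way ANOVA",
                     term = c("factor1", "factor2")[seq_len(sum(keep))],
                     statistic = sm$`F value`[keep],
                     p_value = sm$`Pr(>F)`[keep])
    },
    wilcoxon = {
      if (nlevels(f1) != 2L) {
        stop("wilcoxon compares exactly two groups", call. = FALSE)
      }
      wt <- stats::wilcox.test(y ~ f1, exact = FALSE)
      tibble::tibble(kind = "Wilcoxon rank-sum", term = "group",
                     statistic = unname(wt$statistic), p_value = wt$p.value)
    },
    paired_t = {
      if (nlevels(f1) != 2L) {
        stop("paired_t compares exactly two conditions", call. = FALSE)
      }
      pid <- dplyr::pull(data, {{ pair }})
      wide <- split(stats::setNames(y, pid), f1)
      ids <- intersect(names(wide[[1L]]), names(wide[[2L]]))
      if (length(ids) != length(wide[[1L]]) ||
          length(ids) != length(wide[[2L]])) {
        stop("paired_t requires a complete pairing of equal-length sets",
             call. = FALSE)
      }
      tt <- stats::t.test(wide[[1L]][ids], wide[[2L]][ids], paired = TRUE)
      tibble::tibble(kind = "paired t", term = "difference",
                     statistic = unname(tt$statistic), p_value = tt$p.value)
    }
  )
  class(out) <- c("vef_comparison", class(out))
  out
}

#' Cohort methylation report
#'
#' Assembles the cohort-level summary from per-sample methylation calls
#' and a sample sheet: per-group positivity frequencies with exact
#' binomial confidence intervals, and two-sided Fisher exact comparisons
#' between requested group pairs. No multiple-testing adjustment is
#' applied (comparisons are reported unadjusted, as noted in the output).
#'
#' @param methylation Per-sample methylation tibble (needs `sample_id`,
#'   `status`).
#' @param sample_sheet Data frame with `sample_id` and a `group` column.
#' @param comparisons List of 2-element character vectors naming group
#'   pairs to compare (default: all pairs of groups present). Groups named
#'   here must exist in the data.
#' @param confidence CI level (default 0.95).
#' @return Object of class `vef_report`: list with `frequencies` (tibble
#'   with CIs), `comparisons` (tibble with Fisher p per pair), and
#'   `adjustment` (`"none"`).
#' @export
cohort_report <- function(methylation, sample_sheet, comparisons = NULL,
                          confidence = 0.95) {
  sheet <- tibble::as_tibble(sample_sheet)
  if (nrow(sheet) == 0L) stop("empty sample sheet", call. = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    stop("sample sheet needs columns sample_id and group", call. = FALSE)
  }
  d <- dplyr::inner_join(tibble::as_tibble(methylation)[, c("sample_id",
                                                            "status")],
                         sheet, by = "sample_id")
  if (anyNA(d$status)) stop("statuses must be called for all samples",
                            call. = FALSE)
  groups <- sort(unique(d$group))
  freq <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(positives = sum(.data$status == "positive"),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$group)
  ci <- clopper_pearson_ci(freq$positives, freq$n, confidence)
  freq <- dplyr::bind_cols(freq, ci[, c("point_pct", "lower_pct", "upper_pct")])

  comparisons <- comparisons %||%
    (if (length(groups) >= 2L) utils::combn(groups, 2L, simplify = FALSE)
     else list())
  named <- unique(unlist(comparisons))
  if (length(named) && !all(named %in% groups)) {
    stop("group(s) named in comparisons but absent from the data: ",
         paste(setdiff(named, groups), collapse = ", "), call. = FALSE)
  }
  comp <- purrr::map_dfr(comparisons, function(pr) {
    fa <- freq[freq$group == pr[1L], ]
    fb <- freq[freq$group == pr[2L], ]
    m <- matrix(c(fa$positives, fa$n - fa$positives,
                  fb$positives, fb$n - fb$positives),
                nrow = 2L, byrow = TRUE)
    ft <- fisher_exact_2x2(m)
    tibble::tibble(group_a = pr[1L], group_b = pr[2L],
                   p_two_sided = ft$p_two_sided,
                   odds_ratio = ft$odds_ratio)
  })
  structure(list(frequencies = freq, comparisons = comp,
                 adjustment = "none"),
            class = "vef_report")
}

#' @export
print.vef_report <- function(x, ...) {
  cat("<vef_report> per-group methylation frequencies (exact CIs)\n")
  print(x$frequencies)
  if (nrow(x$comparisons)) {
    cat("pairwise Fisher exact comparisons (unadjusted):\n")
    print(x$comparisons)
  } else {
    cat("no between-group comparisons requested\n")
  }
  invisible(x)
}
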