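#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an exact binomial confidence interval
#'
#' @param x A `vef_ci` object.
#' @param ... Unused.
#' @return A tibble with one row per interval: `successes`, `trials`,
#'   `estimate`, `conf.low`, `conf.high` (proportions, not percent) and
#'   `conf.level`.
#' @method tidy vef_ci
#' @export
tidy.vef_ci <- function(x, ...) {
  tibble::tibble(
    successes = x$successes, trials = x$trials,
    estimate = x$point_pct / 100,
    conf.low = x$lower_pct / 100, conf.high = x$upper_pct / 100,
    conf.level = x$confidence
  )
}

#' Tidy a Fisher exact test result
#'
#' @param x A `vef_fisher` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate` (conditional-MLE odds ratio),
#'   `p.value`, `method`, `alternative`.
#' @method tidy vef_fisher
#' @export
tidy.vef_fisher <- function(x, ...) {
  tibble::tibble(estimate = x$odds_ratio, p.value = x$p_two_sided,
                 method = "Fisher's exact test", alternative = "two.sided")
}

#' @rdname tidy.vef_fisher
#' @method glance vef_fisher
#' @export
glance.vef_fisher <- function(x, ...) {
  tibble::tibble(p.value = x$p_two_sided, odds_ratio = x$odds_ratio,
                 n = sum(x$table))
}

#' Tidy a group comparison
#'
#' @param x A `vef_comparison` object.
#' @param ... Unused.
#' @return Tibble with `term`, `statistic`, `p.value`, `method`.
#' @method tidy vef_comparison
#' @export
tidy.vef_comparison <- function(x, ...) {
  tibble::tibble(term = x$term, statistic = x$statistic,
                 p.value = x$p_value, method = x$kind)
}

#' Tidy a concordance table
#'
#' @param x A `vef_concordance` object.
#' @param ... Unused.
#' @return Long tibble of the 2x2 counts with the Fisher p attached.
#' @method tidy vef_concordance
#' @export
tidy.vef_concordance <- function(x, ...) {
  cn <- x$counts
  tibble::tibble(
    status_a = rep(rownames(cn), times = 2L),
    status_b = rep(colnames(cn), each = 2L),
    n = as.integer(cn),
    p.value = x$fisher$p_two_sided
  )
}
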