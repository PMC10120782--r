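# Table-shaped rendering of results: regression blocks with "beta (95% CI)"
# strings and reference rows, and descriptive summaries with mean (SD),
# median (range) and Kruskal-Wallis p per category.

#' Format an estimate with its 95% CI
#'
#' @param beta,ci_low,ci_high numeric vectors
#' @param digits decimals (2, matching the published tables)
#' @return character vector like `"2.92 (1.04, 4.81)"`
#' @export
format_beta_ci <- function(beta, ci_low, ci_high, digits = 2) {
  sprintf("%.*f (%.*f, %.*f)", digits, beta, digits, ci_low, digits, ci_high)
}

#' Render a regression result as a publication-shaped exposure block
#'
#' One row per exposure level: the reference level is labeled
#' `"1.00 (reference)"`, other levels show `beta (95% CI)` to two decimals,
#' and the trend p (when available) is attached to the last row of the
#' block. Accepts a [fit_linear()] term table, an [rubin_pool()] result, or
#' an `sme_pooled_fit`.
#'
#' @param x result object
#' @param p_trend optional trend p-value to attach
#' @param ... unused
#' @return tibble (`exposure`, `level`, `estimate`, `p_value`, `p_trend`)
#' @export
make_report <- function(x, ...) UseMethod("make_report")

#' @rdname make_report
#' @export
make_report.data.frame <- function(x, p_trend = NA_real_, ...) {
  if (nrow(x) == 0L) {
    warning("empty exposure block: nothing to report")
    return(tibble::tibble(exposure = character(), level = character(),
                          estimate = character(), p_value = numeric(),
                          p_trend = numeric()))
  }
  ref <- if ("reference" %in% names(x)) x$reference[1] else "(reference)"
  body <- tibble::tibble(
    exposure = x$term,
    level = x$level,
    estimate = format_beta_ci(x$beta, x$ci_low, x$ci_high),
    p_value = x$p_value,
    p_trend = NA_real_
  )
  out <- dplyr::bind_rows(
    tibble::tibble(exposure = x$term[1], level = ref,
                   estimate = "1.00 (reference)",
                   p_value = NA_real_, p_trend = NA_real_),
    body
  )
  out$p_trend[nrow(out)] <- p_trend
  out
}

#' @rdname make_report
#' @export
make_report.sme_pooled_fit <- function(x, ...) {
  make_report(x$terms, p_trend = x$p_trend)
}

#' @rdname make_report
#' @export
make_report.sme_pooled <- function(x, ...) {
  make_report(tibble::as_tibble(x), ...)
}

#' Descriptive summary of an SME outcome by patient characteristics
#'
#' For each variable and category: mean (SD), median (range), and a
#' Kruskal-Wallis p for the across-category comparison -- the shape of the
#' study's descriptive comparison table. `n/a` / missing categories are
#' excluded.
#'
#' @param data cohort data frame
#' @param outcome outcome column name (string)
#' @param variables character vector of grouping variables
#' @return tibble (`variable`, `level`, `n`, `mean_sd`, `median_range`,
#'   `p_value` on each variable's first row)
#' @export
kw_summary <- function(data, outcome, variables) {
  purrr::map_dfr(variables, function(v) {
    grp <- drop_na_levels(data[[v]])
    keep <- !is.na(grp) & !is.na(data[[outcome]])
    vals <- data[[outcome]][keep]
    grp <- factor(grp[keep],
                  levels = intersect(
                    if (is.factor(data[[v]])) levels(data[[v]]) else unique(grp),
                    unique(grp)))
    kw <- kruskal_wallis(tibble::tibble(y = vals, g = grp), y, g)
    rows <- purrr::map_dfr(levels(grp), function(l) {
      x <- vals[grp == l]
      tibble::tibble(
        variable = v, level = l, n = length(x),
        mean_sd = sprintf("%.1f (%.1f)", mean(x), stats::sd(x)),
        median_range = sprintf("%.1f (%.1f-%.1f)", stats::median(x),
                               min(x), max(x)),
        p_value = NA_real_
      )
    })
    rows$p_value[1] <- kw$p_value
    rows
  })
}
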