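# Association engine: nonparametric group comparisons, partially and
# mutually adjusted linear models, ordinal trend tests and multiplicative
# interaction (heterogeneity) tests. Outcomes are the SME phenotypes
# (percent Ta-SCD, TSR); exposures are categorical risk factors or tumor
# characteristics. All p-values are two-sided; "n/a" categories and rows
# with missing model variables are excluded from complete-case fits (the
# multiple-imputation path is the primary missing-data route).

drop_na_levels <- function(x) {
  x <- as.character(x)
  x[x %in% c("n/a", "unknown", "missing")] <- NA
  x
}

#' Kruskal-Wallis comparison of an outcome across exposure categories
#'
#' Ties-corrected H statistic referred to a chi-square with k - 1 df.
#' When every value is tied across all groups there is no evidence of any
#' difference and H = 0 (the ties correction is degenerate there).
#'
#' @param data data frame
#' @param outcome outcome column (unquoted)
#' @param group grouping column (unquoted); `n/a` / missing rows dropped
#' @return tibble (`statistic`, `df`, `p_value`, `n`, `k`)
#' @export
kruskal_wallis <- function(data, outcome, group) {
  vals <- dplyr::pull(data, {{ outcome }})
  grp <- drop_na_levels(dplyr::pull(data, {{ group }}))
  keep <- !is.na(vals) & !is.na(grp)
  vals <- vals[keep]; grp <- factor(grp[keep])
  k <- nlevels(droplevels(grp))
  if (k < 2L) {
    stop("at least two non-empty groups are required", call. = FALSE)
  }
  if (length(unique(vals)) == 1L) {
    return(tibble::tibble(statistic = 0, df = k - 1L, p_value = 1,
                          n = length(vals), k = k))
  }
  kt <- stats::kruskal.test(vals, grp)
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, n = length(vals), k = k)
}

#' Model specification for the association engine
#'
#' Partially adjusted models contain the exposure plus age, study site and
#' tissue area. Mutually adjusted models add the other risk factors of the
#' mutual set. Age enters as its 4-level category by default (continuous
#' age is available via `age_form`).
#'
#' @param outcome `"tascd_percent"` or `"tsr_percent"`
#' @param exposure exposure variable name (categorical)
#' @param adjustment `"partial"` or `"mutual"`
#' @param mutual_set risk-factor variables mutually adjusted for
#' @param age_form `"category"` (4-level age group) or `"continuous"`
#' @param modifier optional effect-modifier variable for
#'   [heterogeneity_test()]
#' @param trend_scores optional named numeric scores for [trend_test()];
#'   default is consecutive integers 0, 1, 2, ... in category order
#' @return a `model_spec`
#' @export
model_spec <- function(outcome = c("tascd_percent", "tsr_percent"),
                       exposure,
                       adjustment = c("partial", "mutual"),
                       mutual_set = c("menarche_cat", "parity",
                                      "body_size", "fhbc"),
                       age_form = c("category", "continuous"),
                       modifier = NULL,
                       trend_scores = NULL) {
  outcome <- match.arg(outcome)
  adjustment <- match.arg(adjustment)
  age_form <- match.arg(age_form)
  age_var <- if (age_form == "category") "age_group" else "age_years"
  base <- setdiff(c(age_var, "site", "tissue_area_mm2"), exposure)
  covariates <- if (adjustment == "partial") base
                else unique(setdiff(c(mutual_set, base), exposure))
  if (exposure %in% covariates) {
    stop("exposure must not appear among the covariates", call. = FALSE)
  }
  structure(list(outcome = outcome, exposure = exposure,
                 adjustment = adjustment, covariates = covariates,
                 modifier = modifier, trend_scores = trend_scores),
            class = "model_spec")
}

# complete-case model frame with clean factors
model_frame <- function(data, spec, extra = character(0)) {
  vars <- unique(c(spec$outcome, spec$exposure, spec$covariates, extra))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("missing model variables: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  df <- data[vars]
  for (v in vars) {
    if (is.factor(df[[v]]) || is.character(df[[v]])) {
      lv <- if (is.factor(df[[v]])) levels(df[[v]]) else unique(df[[v]])
      cleaned <- drop_na_levels(df[[v]])
      df[[v]] <- droplevels(factor(cleaned, levels = setdiff(lv, c("n/a", "unknown", "missing"))))
    }
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (v in vars) if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
  df
}

check_aliased <- function(fit) {
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("collinear design: aliased terms ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  invisible(fit)
}

exposure_term_table <- function(fit, df, exposure) {
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  lv <- levels(df[[exposure]])
  rows <- paste0(exposure, lv[-1])
  rows <- rows[rows %in% rownames(sm)]
  tibble::tibble(
    term = exposure,
    level = sub(paste0("^", exposure), "", rows),
    reference = lv[1],
    beta = sm[rows, "Estimate"],
    se = sm[rows, "Std. Error"],
    ci_low = ci[rows, 1],
    ci_high = ci[rows, 2],
    p_value = sm[rows, "Pr(>|t|)"],
    df_residual = stats::df.residual(fit),
    n = stats::nobs(fit)
  )
}

#' Fit a partially or mutually adjusted linear model on one dataset
#'
#' Ordinary least squares with treatment (dummy) coding of the exposure
#' against its first level; returns the exposure coefficients with 95%
#' confidence intervals and two-sided p-values. An exposure observed at a
#' single level yields a zero-row table (the intercept-plus-covariates fit
#' still runs); a collinear design is an error naming the aliased terms.
#'
#' @param data cohort data frame
#' @param spec a [model_spec()]
#' @return tibble of exposure terms (`term`, `level`, `reference`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `p_value`, `df_residual`, `n`)
#' @export
fit_linear <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  df <- model_frame(data, spec)
  df[[spec$exposure]] <- factor(df[[spec$exposure]], ordered = FALSE)
  for (v in spec$covariates) {
    if (is.factor(df[[v]])) df[[v]] <- factor(df[[v]], ordered = FALSE)
  }
  covs <- spec$covariates[vapply(spec$covariates, function(v) {
    !is.factor(df[[v]]) || nlevels(df[[v]]) > 1L
  }, logical(1))]
  rhs <- if (nlevels(df[[spec$exposure]]) > 1L) {
    c(spec$exposure, covs)
  } else {
    covs
  }
  fml <- stats::reformulate(if (length(rhs)) rhs else "1",
                            response = spec$outcome)
  fit <- stats::lm(fml, data = df)
  check_aliased(fit)
  if (nlevels(df[[spec$exposure]]) < 2L) {
    return(exposure_term_table(fit, df, spec$exposure)[0, ])
  }
  exposure_term_table(fit, df, spec$exposure)
}

#' Ordinal trend test
#'
#' Refits the model replacing the exposure dummies with integer scores
#' (0, 1, 2, ... in category order, or the scores supplied in the spec);
#' `p_trend` is the two-sided p-value of the score coefficient.
#'
#' @param data cohort data frame
#' @param spec a [model_spec()] whose exposure is ordinal with >= 3 levels
#' @return tibble (`score_beta`, `se`, `ci_low`, `ci_high`, `p_trend`,
#'   `df_residual`, `n`)
#' @export
trend_test <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  df <- model_frame(data, spec)
  x <- df[[spec$exposure]]
  if (!is.null(spec$trend_scores)) {
    scores <- spec$trend_scores[as.character(x)]
  } else {
    if (!is.ordered(data[[spec$exposure]]) &&
        !is.ordered(x)) {
      stop("exposure '", spec$exposure,
           "' is not ordinal; supply trend_scores or an ordered factor",
           call. = FALSE)
    }
    scores <- as.numeric(x) - 1
  }
  if (length(unique(stats::na.omit(scores))) < 3L) {
    stop("trend test needs an ordinal exposure with at least 3 levels",
         call. = FALSE)
  }
  df$.score <- as.numeric(scores)
  covs <- spec$covariates[vapply(spec$covariates, function(v) {
    !is.factor(df[[v]]) || nlevels(droplevels(df[[v]])) > 1L
  }, logical(1))]
  for (v in covs) if (is.factor(df[[v]])) df[[v]] <- factor(df[[v]], ordered = FALSE)
  fml <- stats::reformulate(c(".score", covs), response = spec$outcome)
  fit <- stats::lm(fml, data = df)
  check_aliased(fit)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)[".score", ]
  tibble::tibble(score_beta = sm[".score", "Estimate"],
                 se = sm[".score", "Std. Error"],
                 ci_low = ci[1], ci_high = ci[2],
                 p_trend = sm[".score", "Pr(>|t|)"],
                 df_residual = stats::df.residual(fit),
                 n = stats::nobs(fit))
}

#' Effect-modification (heterogeneity) test
#'
#' Fits the full model with exposure-by-modifier product terms and tests
#' them jointly with a Wald chi-square; stratum-specific exposure effects
#' are reported as linear combinations of the main and product terms.
#'
#' @param data cohort data frame
#' @param spec a [model_spec()] with a `modifier`
#' @return list of class `sme_heterogeneity`: `strata` (per-modifier-level
#'   exposure betas with 95% CIs), `p_heterogeneity`, `wald`, `df`
#' @export
heterogeneity_test <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(spec$modifier)) stop("spec has no modifier", call. = FALSE)
  df <- model_frame(data, spec, extra = spec$modifier)
  expo <- spec$exposure; modf <- spec$modifier
  df[[expo]] <- factor(df[[expo]], ordered = FALSE)
  df[[modf]] <- factor(df[[modf]], ordered = FALSE)
  if (nlevels(df[[modf]]) < 2L) {
    stop("modifier '", modf, "' has a single level", call. = FALSE)
  }
  cells <- table(df[[expo]], df[[modf]])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty exposure x modifier cell(s): ",
         paste(sprintf("%s x %s", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = "; "),
         call. = FALSE)
  }
  covs <- setdiff(spec$covariates, modf)
  covs <- covs[vapply(covs, function(v) {
    !is.factor(df[[v]]) || nlevels(df[[v]]) > 1L
  }, logical(1))]
  for (v in covs) if (is.factor(df[[v]])) df[[v]] <- factor(df[[v]], ordered = FALSE)
  fml <- stats::reformulate(c(sprintf("%s * %s", expo, modf), covs),
                            response = spec$outcome)
  fit <- stats::lm(fml, data = df)
  check_aliased(fit)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  int_idx <- grep(":", names(cf))
  if (!length(int_idx)) stop("no interaction terms in the fit", call. = FALSE)
  b <- cf[int_idx]
  W <- as.numeric(t(b) %*% solve(V[int_idx, int_idx]) %*% b)
  q <- length(int_idx)
  p_het <- stats::pchisq(W, q, lower.tail = FALSE)

  elv <- levels(df[[expo]]); mlv <- levels(df[[modf]])
  strata <- purrr::map_dfr(mlv, function(ml) {
    purrr::map_dfr(elv[-1], function(el) {
      contrast <- stats::setNames(numeric(length(cf)), names(cf))
      contrast[paste0(expo, el)] <- 1
      int_name <- paste0(expo, el, ":", modf, ml)
      if (int_name %in% names(cf)) contrast[int_name] <- 1
      est <- sum(contrast * cf)
      se <- sqrt(as.numeric(t(contrast) %*% V %*% contrast))
      tcrit <- stats::qt(0.975, stats::df.residual(fit))
      tibble::tibble(modifier_level = ml, level = el, beta = est, se = se,
                     ci_low = est - tcrit * se, ci_high = est + tcrit * se)
    })
  })
  structure(list(strata = strata, p_heterogeneity = p_het, wald = W, df = q,
                 exposure = expo, modifier = modf),
            class = "sme_heterogeneity")
}

#' @export
print.sme_heterogeneity <- function(x, ...) {
  cat(sprintf("<heterogeneity of %s by %s> Wald chi2 = %.2f (df %d), p = %.4g\n",
              x$exposure, x$modifier, x$wald, x$df, x$p_heterogeneity))
  print(x$strata)
  invisible(x)
}
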