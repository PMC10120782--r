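# Multiple imputation by chained equations for the incomplete tumor
# variables, and Rubin's-rules pooling of per-imputation model fits.

default_impute_targets <- c("er", "pr", "her2", "grade", "size_cat")

default_impute_predictors <- c("tascd_percent", "tsr_percent", "age_group",
                               "site", "tissue_area_mm2", "parity",
                               "body_size", "fhbc", "menarche_cat")

# one conditional draw for variable v given predictors; fits on a bootstrap
# resample of the observed rows so that model-parameter uncertainty
# propagates into between-imputation variance (approximately proper MI)
draw_conditional <- function(df, v, preds, obs_idx, mis_idx) {
  lv <- levels(df[[v]])
  boot <- sample(obs_idx, length(obs_idx), replace = TRUE)
  train <- df[boot, c(v, preds)]
  present <- unique(as.character(train[[v]]))
  if (length(present) < 2L) {
    return(factor(rep(present, length(mis_idx)), levels = lv))
  }
  newdata <- df[mis_idx, preds, drop = FALSE]
  if (length(lv) == 2L) {
    fit <- suppressWarnings(
      stats::glm(stats::reformulate(preds, response = v),
                 data = train, family = stats::binomial()))
    p <- stats::predict(fit, newdata = newdata, type = "response")
    p[!is.finite(p)] <- 0.5
    factor(lv[1L + (stats::runif(length(p)) < p)], levels = lv)
  } else {
    fit <- nnet::multinom(stats::reformulate(preds, response = v),
                          data = train, trace = FALSE, maxit = 200)
    p <- stats::predict(fit, newdata = newdata, type = "probs")
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    cls <- colnames(p)
    picked <- apply(p, 1L, function(pr) {
      pr[!is.finite(pr) | pr < 0] <- 0
      if (sum(pr) <= 0) pr[] <- 1
      sample(cls, 1L, prob = pr)
    })
    factor(picked, levels = lv)
  }
}

#' Multiple imputation by chained equations (MICE)
#'
#' Iteratively imputes each incomplete tumor variable from a conditional
#' model given all other variables (logistic for binary, multinomial for
#' >= 3 categories), sweeping the variables `n_iter` times per imputation
#' and producing `m` independent completed datasets. Observed values are
#' never altered; the whole procedure is reproducible per seed. Valid under
#' missingness at random (MAR).
#'
#' @param data cohort data frame (missingness only in the tumor variables)
#' @param m number of imputations (the study used 5)
#' @param n_iter chained-equation sweeps per imputation
#' @param seed RNG seed
#' @param variables variables to impute; default: those of
#'   `er, pr, her2, grade, size_cat` present in `data` with any NA
#' @param predictors fully observed predictors of the imputation models
#' @return an `sme_imputations` object: list of `m` completed tibbles
#' @export
mice_impute <- function(data, m = 5L, n_iter = 10L, seed = 1L,
                        variables = NULL, predictors = NULL) {
  stopifnot(is.data.frame(data), m >= 1L, n_iter >= 1L)
  variables <- variables %||%
    intersect(default_impute_targets, names(data))
  variables <- variables[vapply(variables,
                                function(v) anyNA(data[[v]]), logical(1))]
  for (v in variables) {
    if (all(is.na(data[[v]]))) {
      stop("variable '", v, "' is 100% missing and cannot be imputed",
           call. = FALSE)
    }
  }
  if (!length(variables)) {
    out <- replicate(m, tibble::as_tibble(data), simplify = FALSE)
    return(structure(out, class = "sme_imputations",
                     variables = character(0), m = m, n_iter = n_iter))
  }
  predictors <- predictors %||%
    intersect(default_impute_predictors, names(data))
  set.seed(seed)
  # impute in order of ascending missingness
  variables <- variables[order(vapply(variables,
                                      function(v) sum(is.na(data[[v]])),
                                      numeric(1)))]
  mis <- lapply(variables, function(v) which(is.na(data[[v]])))
  obs <- lapply(variables, function(v) which(!is.na(data[[v]])))
  names(mis) <- names(obs) <- variables

  out <- vector("list", m)
  for (imp in seq_len(m)) {
    df <- tibble::as_tibble(data)
    for (v in variables) df[[v]] <- droplevels(factor(df[[v]]))
    # initialize by sampling observed values
    for (v in variables) {
      df[[v]][mis[[v]]] <- sample(df[[v]][obs[[v]]], length(mis[[v]]),
                                  replace = TRUE)
    }
    for (it in seq_len(n_iter)) {
      for (v in variables) {
        preds <- c(predictors, setdiff(variables, v))
        df[[v]][mis[[v]]] <- draw_conditional(df, v, preds,
                                              obs[[v]], mis[[v]])
      }
    }
    if ("subtype" %in% names(df)) {
      df$subtype <- derive_subtype(df$er, df$pr, df$her2)
    }
    out[[imp]] <- df
  }
  structure(out, class = "sme_imputations",
            variables = variables, m = m, n_iter = n_iter)
}

#' @export
print.sme_imputations <- function(x, ...) {
  cat(sprintf("<sme_imputations> m = %d completed datasets (%s)\n",
              attr(x, "m"),
              if (length(attr(x, "variables")))
                paste(attr(x, "variables"), collapse = ", ")
              else "no missing data"))
  invisible(x)
}

#' Pool per-imputation estimates with Rubin's rules
#'
#' For each term: pooled beta is the mean of the per-imputation betas;
#' within-imputation variance `W = mean(se^2)`; between-imputation variance
#' `B = var(beta)`; total variance `T = W + (1 + 1/m) B`. Degrees of
#' freedom follow the Barnard-Rubin small-sample formula (reducing to the
#' complete-data df when B = 0), and the CI and two-sided p come from the
#' t distribution on those df.
#'
#' @param fits list of per-imputation term tables as returned by
#'   [fit_linear()] (columns `term`/`level`/`beta`/`se`, optionally
#'   `df_residual`); term sets must align across imputations
#' @param df_complete complete-data residual df; default taken from the
#'   fits' `df_residual` (Inf if absent)
#' @return tibble of class `sme_pooled` with `beta`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `W`, `B`, `T`, `df`, `m` per term
#' @export
rubin_pool <- function(fits, df_complete = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  fits <- lapply(fits, function(f) {
    f <- tibble::as_tibble(f)
    if (!"term" %in% names(f)) f$term <- "term"
    if (!"level" %in% names(f)) f$level <- ""
    f$key <- paste(f$term, f$level, sep = "|")
    f
  })
  keys <- fits[[1]]$key
  for (f in fits[-1]) {
    if (!identical(sort(f$key), sort(keys))) {
      stop("imputation fits have mismatched term sets", call. = FALSE)
    }
  }
  m <- length(fits)
  purrr::map_dfr(keys, function(k) {
    rows <- purrr::map_dfr(fits, function(f) f[f$key == k, ])
    qbar <- mean(rows$beta)
    W <- mean(rows$se^2)
    B <- if (m > 1L) stats::var(rows$beta) else 0
    Tvar <- W + (1 + 1 / m) * B
    dfc <- df_complete %||%
      (if ("df_residual" %in% names(rows)) min(rows$df_residual) else Inf)
    if (B <= 0 || m == 1L) {
      df <- dfc
    } else {
      lambda <- (1 + 1 / m) * B / Tvar
      df_old <- (m - 1) / lambda^2
      df <- if (is.finite(dfc)) {
        df_obs <- ((dfc + 1) / (dfc + 3)) * dfc * (1 - lambda)
        1 / (1 / df_old + 1 / df_obs)
      } else {
        df_old
      }
    }
    se <- sqrt(Tvar)
    tcrit <- stats::qt(0.975, df)
    tibble::tibble(
      term = rows$term[1], level = rows$level[1],
      beta = qbar, se = se,
      ci_low = qbar - tcrit * se, ci_high = qbar + tcrit * se,
      p_value = 2 * stats::pt(abs(qbar) / se, df, lower.tail = FALSE),
      W = W, B = B, T = Tvar, df = df, m = m
    )
  }) -> pooled
  class(pooled) <- c("sme_pooled", class(pooled))
  pooled
}

#' Fit a model on every imputation and pool with Rubin's rules
#'
#' Runs [fit_linear()] (and, when the exposure is ordinal with at least 3
#' levels, [trend_test()]) on each completed dataset and pools the
#' estimates. This is the primary missing-data analysis path.
#'
#' @param imputations an `sme_imputations` object (or list of data frames)
#' @param spec a [model_spec()]
#' @return `sme_pooled_fit`: list with `terms` (pooled exposure betas),
#'   `p_trend` (pooled trend p, or NA when the exposure is not ordinal),
#'   `m`, `spec`
#' @export
fit_pooled <- function(imputations, spec) {
  stopifnot(inherits(spec, "model_spec"))
  fits <- lapply(imputations, fit_linear, spec = spec)
  terms <- rubin_pool(fits)
  p_trend <- NA_real_
  trend_ok <- tryCatch({
    tr <- lapply(imputations, trend_test, spec = spec)
    tr <- lapply(tr, function(t) tibble::tibble(term = "trend", level = "",
                                                beta = t$score_beta, se = t$se,
                                                df_residual = t$df_residual))
    pooled_tr <- rubin_pool(tr)
    p_trend <- pooled_tr$p_value
    TRUE
  }, error = function(e) FALSE)
  structure(list(terms = terms, p_trend = p_trend, m = length(imputations),
                 spec = spec, has_trend = trend_ok),
            class = "sme_pooled_fit")
}

#' @export
print.sme_pooled_fit <- function(x, ...) {
  cat(sprintf("<pooled fit> %s ~ %s (%s adjustment), m = %d\n",
              x$spec$outcome, x$spec$exposure, x$spec$adjustment, x$m))
  print(x$terms)
  if (!is.na(x$p_trend)) cat(sprintf("p-trend = %.4g\n", x$p_trend))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy sme_pooled_fit
#' @export
tidy.sme_pooled_fit <- function(x, ...) {
  out <- x$terms
  out$p_trend <- x$p_trend
  tibble::as_tibble(out)
}

#' @method glance sme_pooled_fit
#' @export
glance.sme_pooled_fit <- function(x, ...) {
  tibble::tibble(outcome = x$spec$outcome, exposure = x$spec$exposure,
                 adjustment = x$spec$adjustment, m = x$m,
                 p_trend = x$p_trend)
}

#' @method tidy sme_heterogeneity
#' @export
tidy.sme_heterogeneity <- function(x, ...) {
  out <- x$strata
  out$p_heterogeneity <- x$p_heterogeneity
  tibble::as_tibble(out)
}

#' @method tidy tissue_segmentation
#' @export
tidy.tissue_segmentation <- function(x, ...) {
  tibble::tibble(slide_id = x$slide_id,
                 tumor_area_mm2 = x$tumor_area_mm2,
                 stroma_area_mm2 = x$stroma_area_mm2,
                 tissue_area_mm2 = x$tissue_area_mm2)
}

#' @method tidy stromal_cell_detection
#' @export
tidy.stromal_cell_detection <- function(x, ...) {
  dplyr::mutate(x$cells, slide_id = x$slide_id, .before = 1)
}

#' @method glance stromal_cell_detection
#' @export
glance.stromal_cell_detection <- function(x, ...) {
  tibble::tibble(slide_id = x$slide_id, n_cells = x$n_cells,
                 stroma_area_mm2 = x$stroma_area_mm2,
                 density_per_mm2 = x$n_cells / x$stroma_area_mm2)
}
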