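# Synthetic patient cohorts with the GBHS covariate structure: category
# marginals taken from the published frequency table, injectable linear
# effects of risk factors on the SME outcomes, and MAR missingness in the
# tumor variables at the published unknown rates.

cohort_levels <- function() {
  list(
    site = c("A", "B", "C"),
    age_group = c("<35", "35-44", "45-54", ">=55"),
    menarche_cat = c("<15", "15", "16", ">=17"),
    parity = c("nulliparous", "parous"),
    n_children = c("0", "1", "2", "3", "4", "5+"),
    afb_cat = c("<19", "19-21", "22-25", ">=26", "n/a"),
    breastfeeding_cat = c("<13", "13-18", ">=19", "n/a"),
    body_size = c("slight", "moderate", "heavy"),
    fhbc = c("no", "yes"),
    er = c("neg", "pos"),
    pr = c("neg", "pos"),
    her2 = c("neg", "pos"),
    grade = c("1", "2", "3"),
    size_cat = c("<2", "2-5", ">5"),
    subtype = c("luminal A-like", "luminal B-like", "HER2-enriched", "TNBC")
  )
}

ordinal_variables <- function() {
  c("age_group", "menarche_cat", "n_children", "afb_cat",
    "breastfeeding_cat", "body_size", "grade", "size_cat")
}

marginal_from_table1 <- function(variable) {
  tab <- gbhs_table1()
  tab <- tab[tab$variable == variable & tab$level != "unknown", ]
  stats::setNames(tab$count / sum(tab$count), tab$level)
}

#' Default cohort category marginals
#'
#' Category probabilities for the covariate generator, derived from the
#' published GBHS frequencies (among known values). The three-site split is
#' not tabulated in the source and is set to 45/35/20.
#'
#' @return named list of named probability vectors
#' @export
cohort_marginals <- function() {
  list(
    site = c(A = 0.45, B = 0.35, C = 0.20),
    age_group = marginal_from_table1("age_group"),
    menarche_cat = marginal_from_table1("menarche_cat"),
    parity = marginal_from_table1("parity"),
    n_children_parous = marginal_from_table1("n_children"),
    afb_cat_parous = marginal_from_table1("afb_cat"),
    breastfeeding_cat_parous = marginal_from_table1("breastfeeding_cat"),
    body_size = marginal_from_table1("body_size"),
    fhbc = marginal_from_table1("fhbc"),
    er_pos = 0.517,
    pr_pos_given_er = c(neg = 0.20, pos = 0.82),
    her2_pos = 0.245,
    grade = marginal_from_table1("grade"),
    size_cat = marginal_from_table1("size_cat")
  )
}

#' Injectable effect specification for the cohort generator
#'
#' Additive effects (vs the reference level) of covariate categories on the
#' mean percent Ta-SCD and TSR, residual SDs, optional interaction effects,
#' and MAR missingness rates for the tumor variables. Default effect sizes
#' are at the scale of the study's mutually adjusted estimates (parous
#' +2.92, FHBC +2.36, body size -1.02/-2.42, grade +3.53/+5.22 on Ta-SCD;
#' grade -2.07/-9.19 on TSR); default missingness rates are the published
#' unknown fractions.
#'
#' @param tascd_intercept,tsr_intercept outcome means at reference levels
#' @param tascd_sd,tsr_sd residual standard deviations
#' @param tascd_effects,tsr_effects named list: element `var` is a named
#'   vector of per-level additive effects (levels absent = 0)
#' @param tascd_tissue_slope,tsr_tissue_slope effect per mm^2 of tissue
#'   area (centered at 3.5 mm^2)
#' @param tascd_interactions,tsr_interactions list of data frames with
#'   columns `var1`, `level1`, `var2`, `level2`, `delta` adding `delta` to
#'   the mean when both levels co-occur
#' @param missingness named vector of MAR missingness rates in \[0, 1) for
#'   any of `er`, `pr`, `her2`, `grade`, `size_cat`
#' @return an `effect_spec` list
#' @export
effect_spec <- function(
    tascd_intercept = 29, tascd_sd = 7,
    tascd_effects = list(
      parity = c(parous = 2.92),
      body_size = c(moderate = -1.02, heavy = -2.42),
      fhbc = c(yes = 2.36),
      grade = c("2" = 3.53, "3" = 5.22),
      age_group = c("35-44" = -0.9, "45-54" = -1.4, ">=55" = 0.4),
      site = c(B = 0.5, C = -0.5)
    ),
    tascd_tissue_slope = 0.15,
    tascd_interactions = list(),
    tsr_intercept = 76, tsr_sd = 13,
    tsr_effects = list(grade = c("2" = -2.07, "3" = -9.19)),
    tsr_tissue_slope = 0,
    tsr_interactions = list(),
    missingness = c(er = 0.250, pr = 0.254, her2 = 0.294,
                    grade = 0.141, size_cat = 0.048)) {
  spec <- structure(
    list(tascd_intercept = tascd_intercept, tascd_sd = tascd_sd,
         tascd_effects = tascd_effects,
         tascd_tissue_slope = tascd_tissue_slope,
         tascd_interactions = tascd_interactions,
         tsr_intercept = tsr_intercept, tsr_sd = tsr_sd,
         tsr_effects = tsr_effects, tsr_tissue_slope = tsr_tissue_slope,
         tsr_interactions = tsr_interactions,
         missingness = missingness),
    class = "effect_spec")
  validate_effect_spec(spec)
  spec
}

#' Null effect specification (no injected signal, no missingness)
#' @export
null_effect_spec <- function() {
  effect_spec(tascd_effects = list(), tascd_tissue_slope = 0,
              tsr_effects = list(), missingness = numeric(0))
}

validate_effect_spec <- function(spec) {
  stopifnot(spec$tascd_sd > 0, spec$tsr_sd > 0)
  lv <- cohort_levels()
  check_effects <- function(effects) {
    for (v in names(effects)) {
      if (!v %in% names(lv)) {
        stop("effect on unknown variable '", v, "'", call. = FALSE)
      }
      bad <- setdiff(names(effects[[v]]), lv[[v]])
      if (length(bad)) {
        stop("effect on unknown level(s) ", paste(bad, collapse = ", "),
             " of '", v, "'", call. = FALSE)
      }
    }
  }
  check_effects(spec$tascd_effects)
  check_effects(spec$tsr_effects)
  for (ints in list(spec$tascd_interactions, spec$tsr_interactions)) {
    for (d in ints) {
      stopifnot(all(c("var1", "level1", "var2", "level2", "delta") %in% names(d)))
      check_effects(stats::setNames(
        list(stats::setNames(rep(0, nrow(d)), d$level1),
             stats::setNames(rep(0, nrow(d)), d$level2)),
        c(d$var1[1], d$var2[1])))
    }
  }
  if (length(spec$missingness)) {
    stopifnot(all(names(spec$missingness) %in%
                    c("er", "pr", "her2", "grade", "size_cat")),
              all(spec$missingness >= 0), all(spec$missingness < 1))
  }
  invisible(spec)
}

sample_cat <- function(n, probs, levels = names(probs), ordered = FALSE) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = levels, ordered = ordered)
}

linear_predictor <- function(df, intercept, effects, tissue_slope,
                             interactions) {
  mu <- rep(intercept, nrow(df)) + tissue_slope * (df$tissue_area_mm2 - 3.5)
  for (v in names(effects)) {
    val <- unname(effects[[v]][as.character(df[[v]])])
    val[is.na(val)] <- 0  # reference level, level without an effect, or NA
    mu <- mu + val
  }
  for (d in interactions) {
    for (i in seq_len(nrow(d))) {
      hit <- !is.na(df[[d$var1[i]]]) & !is.na(df[[d$var2[i]]]) &
        df[[d$var1[i]]] == d$level1[i] & df[[d$var2[i]]] == d$level2[i]
      mu[hit] <- mu[hit] + d$delta[i]
    }
  }
  mu
}

#' Generate a synthetic patient cohort
#'
#' Draws covariates from the configured category marginals (parity is made
#' age-dependent so that age confounds parity-outcome associations, while
#' keeping the marginal parous fraction at its configured value), derives
#' intrinsic subtype from the joint ER/PR/HER2 draw, builds the SME
#' outcomes as linear-in-effects means plus Gaussian noise (percent Ta-SCD
#' clipped to (5, 95); TSR to (5, 99.5)), and finally masks tumor variables
#' missing-at-random with probabilities that depend on observed site and
#' age but average to the configured rates.
#'
#' @param n cohort size (>= 50)
#' @param effects an [effect_spec()]
#' @param seed RNG seed; generation is deterministic per seed
#' @param marginals category marginals, see [cohort_marginals()]
#' @return tibble with one row per patient
#' @export
generate_cohort <- function(n, effects = effect_spec(), seed = 1L,
                            marginals = cohort_marginals()) {
  if (n < 50) stop("cohort size must be at least 50", call. = FALSE)
  validate_effect_spec(effects)
  set.seed(seed)
  lv <- cohort_levels()

  site <- sample_cat(n, marginals$site)
  age_group <- sample_cat(n, marginals$age_group, lv$age_group, ordered = TRUE)
  age_lo <- c("<35" = 17, "35-44" = 35, "45-54" = 45, ">=55" = 55)
  age_hi <- c("<35" = 34, "35-44" = 44, "45-54" = 54, ">=55" = 84)
  age_years <- round(stats::runif(n, age_lo[as.character(age_group)],
                                  age_hi[as.character(age_group)] + 1 - 1e-9))

  # parity probability rises with age; weights calibrated so the marginal
  # stays at the configured parous fraction
  p_parous_by_age <- c("<35" = 0.78, "35-44" = 0.90,
                       "45-54" = 0.93, ">=55" = 0.95)
  w <- p_parous_by_age / sum(p_parous_by_age * marginals$age_group) *
    marginals$parity[["parous"]]
  p_parous <- clip(w[as.character(age_group)], 0, 0.99)
  parous <- stats::runif(n) < p_parous
  parity <- factor(ifelse(parous, "parous", "nulliparous"), levels = lv$parity)

  n_children <- factor(rep("0", n), levels = lv$n_children, ordered = TRUE)
  n_children[parous] <- sample_cat(sum(parous), marginals$n_children_parous,
                                   lv$n_children, ordered = TRUE)[seq_len(sum(parous))]
  afb_cat <- factor(rep("n/a", n), levels = lv$afb_cat, ordered = TRUE)
  afb_cat[parous] <- sample_cat(sum(parous), marginals$afb_cat_parous,
                                lv$afb_cat, ordered = TRUE)
  breastfeeding_cat <- factor(rep("n/a", n), levels = lv$breastfeeding_cat,
                              ordered = TRUE)
  breastfeeding_cat[parous] <- sample_cat(
    sum(parous), marginals$breastfeeding_cat_parous,
    lv$breastfeeding_cat, ordered = TRUE)

  menarche_cat <- sample_cat(n, marginals$menarche_cat, lv$menarche_cat,
                             ordered = TRUE)
  body_size <- sample_cat(n, marginals$body_size, lv$body_size, ordered = TRUE)
  fhbc <- sample_cat(n, marginals$fhbc, lv$fhbc)

  er <- factor(ifelse(stats::runif(n) < marginals$er_pos, "pos", "neg"),
               levels = lv$er)
  p_pr <- marginals$pr_pos_given_er[as.character(er)]
  pr <- factor(ifelse(stats::runif(n) < p_pr, "pos", "neg"), levels = lv$pr)
  her2 <- factor(ifelse(stats::runif(n) < marginals$her2_pos, "pos", "neg"),
                 levels = lv$her2)
  grade <- sample_cat(n, marginals$grade, lv$grade, ordered = TRUE)
  size_cat <- sample_cat(n, marginals$size_cat, lv$size_cat, ordered = TRUE)

  tissue_area_mm2 <- stats::rlnorm(n, log(3.2), 0.35)

  df <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    site, age_years, age_group, menarche_cat, parity, n_children,
    afb_cat, breastfeeding_cat, body_size, fhbc,
    er, pr, her2, grade, size_cat,
    tissue_area_mm2
  )

  mu_ta <- linear_predictor(df, effects$tascd_intercept, effects$tascd_effects,
                            effects$tascd_tissue_slope,
                            effects$tascd_interactions)
  mu_tsr <- linear_predictor(df, effects$tsr_intercept, effects$tsr_effects,
                             effects$tsr_tissue_slope,
                             effects$tsr_interactions)
  df$tascd_percent <- clip(stats::rnorm(n, mu_ta, effects$tascd_sd), 5, 95)
  df$tsr_percent <- clip(stats::rnorm(n, mu_tsr, effects$tsr_sd), 5, 99.5)

  # MAR missingness: probability depends on observed site and age only,
  # scaled so the expected missing fraction equals the configured rate
  for (v in names(effects$missingness)) {
    rate <- effects$missingness[[v]]
    if (rate <= 0) next
    w <- exp(0.4 * (site == "B") + 0.8 * (site == "C") +
               0.3 * (age_group >= ">=55"))
    p <- clip(rate * w / mean(w), 0, 0.95)
    df[[v]][stats::runif(n) < p] <- NA
  }
  df$subtype <- derive_subtype(df$er, df$pr, df$her2)
  df
}

#' Derive intrinsic-like subtype from ER/PR/HER2
#'
#' luminal A-like = ER+/PR+/HER2-; HER2-enriched = ER-/PR-/HER2+;
#' TNBC = ER-/PR-/HER2-; everything else with ER and/or PR positive
#' (HER2+ combinations and ER+/PR-/HER2-) is luminal B-like. Any missing
#' marker yields a missing subtype.
#'
#' @param er,pr,her2 factors/characters with levels `neg` / `pos` (NA allowed)
#' @return factor with the four subtype levels (NA where any marker is NA)
#' @export
derive_subtype <- function(er, pr, her2) {
  er <- as.character(er); pr <- as.character(pr); her2 <- as.character(her2)
  out <- rep(NA_character_, length(er))
  known <- !is.na(er) & !is.na(pr) & !is.na(her2)
  both_neg <- known & er == "neg" & pr == "neg"
  out[both_neg & her2 == "pos"] <- "HER2-enriched"
  out[both_neg & her2 == "neg"] <- "TNBC"
  lum <- known & !both_neg
  out[lum & er == "pos" & pr == "pos" & her2 == "neg"] <- "luminal A-like"
  out[lum & is.na(out)] <- "luminal B-like"
  factor(out, levels = cohort_levels()$subtype)
}
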