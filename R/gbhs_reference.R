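#' Published GBHS category frequencies
#'
#' Category counts of clinicopathologic and risk-factor characteristics of
#' the 792 Ghana Breast Health Study (GBHS) breast cancer patients, as
#' printed in the study's descriptive table. These counts drive the default
#' marginals of [generate_cohort()] and allow the printed percentages
#' (e.g. 91.0% parous; 27.7% TNBC among subtyped patients) to be recomputed.
#'
#' @return tibble (`variable`, `level`, `count`); "unknown" rows carry the
#'   missing-value counts
#' @export
gbhs_table1 <- function() {
  tibble::tribble(
    ~variable, ~level, ~count,
    "age_group", "<35", 84,
    "age_group", "35-44", 198,
    "age_group", "45-54", 231,
    "age_group", ">=55", 277,
    "age_group", "unknown", 2,
    "er", "neg", 287,
    "er", "pos", 307,
    "er", "unknown", 198,
    "pr", "neg", 282,
    "pr", "pos", 309,
    "pr", "unknown", 201,
    "her2", "neg", 422,
    "her2", "pos", 137,
    "her2", "unknown", 233,
    "grade", "1", 38,
    "grade", "2", 168,
    "grade", "3", 474,
    "grade", "unknown", 112,
    "size_cat", "<2", 23,
    "size_cat", "2-5", 248,
    "size_cat", ">5", 483,
    "size_cat", "unknown", 38,
    "subtype", "luminal A-like", 166,
    "subtype", "luminal B-like", 188,
    "subtype", "HER2-enriched", 47,
    "subtype", "TNBC", 154,
    "subtype", "unknown", 237,
    "menarche_cat", "<15", 185,
    "menarche_cat", "15", 183,
    "menarche_cat", "16", 151,
    "menarche_cat", ">=17", 167,
    "menarche_cat", "unknown", 106,
    "parity", "nulliparous", 71,
    "parity", "parous", 719,
    "parity", "unknown", 2,
    "n_children", "1", 88,
    "n_children", "2", 125,
    "n_children", "3", 136,
    "n_children", "4", 123,
    "n_children", "5+", 247,
    "afb_cat", "<19", 230,
    "afb_cat", "19-21", 200,
    "afb_cat", "22-25", 180,
    "afb_cat", ">=26", 137,
    "breastfeeding_cat", "<13", 240,
    "breastfeeding_cat", "13-18", 415,
    "breastfeeding_cat", ">=19", 97,
    "breastfeeding_cat", "unknown", 40,
    "body_size", "slight", 190,
    "body_size", "moderate", 296,
    "body_size", "heavy", 260,
    "body_size", "unknown", 46,
    "fhbc", "no", 726,
    "fhbc", "yes", 55,
    "fhbc", "unknown", 11
  )
}

#' Category percentage among known values
#'
#' Recomputes the percentage of a category among patients with a known
#' value for the variable, exactly as tabulated in the study (one decimal).
#'
#' @param variable variable name in [gbhs_table1()]
#' @param level category level
#' @param digits decimals to round to (`NULL` = unrounded)
#' @return percentage of `level` among non-unknown `variable` values
#' @export
gbhs_category_percent <- function(variable, level, digits = 1) {
  tab <- gbhs_table1()
  tab <- tab[tab$variable == variable & tab$level != "unknown", ]
  if (!nrow(tab)) stop("unknown variable: ", variable, call. = FALSE)
  if (!level %in% tab$level) stop("unknown level: ", level, call. = FALSE)
  pct <- 100 * tab$count[tab$level == level] / sum(tab$count)
  if (is.null(digits)) pct else round(pct, digits)
}
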