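# Bundled worked example: univariate cross-tabulations of neonatal
# characteristics and NICU-strategy indicators against the two childhood
# enterotypes (Bacteroides-type n = 128 vs Prevotella-type n = 31) in a
# cohort of 159 very preterm children. Counts are complete-case: rows with
# a missing value for a variable are dropped for that variable's test.

#' Example cohort: neonatal covariates by childhood enterotype
#'
#' Cross-tabulated counts (and summary statistics for the continuous
#' covariates) of neonatal characteristics against the Bacteroides-type
#' (n = 128) and Prevotella-type (n = 31) enterotypes of a 159-child very
#' preterm cohort, as used by the univariate association screen. Counts
#' are complete-case per variable. Useful as a worked example for
#' [contingency_test()] and [t_test_summary()].
#'
#' @return A list with `categorical` (named list of `levels x 2` count
#'   matrices, columns `B_type`, `P_type`) and `continuous` (data frame of
#'   per-group mean, sd, n).
#' @export
preterm_covariate_tables <- function() {
  m <- function(b, p, lev) {
    matrix(c(b, p), ncol = 2,
           dimnames = list(lev, c("B_type", "P_type")))
  }
  yn <- c("yes", "no")
  categorical <- list(
    maternal_age = m(c(6, 85, 32), c(3, 23, 5), c("<25", "25-35", ">=35")),
    mother_born_abroad = m(c(112, 16), c(26, 5), c("France", "other")),
    maternal_education = m(c(24, 19, 30, 55), c(11, 8, 7, 4),
                           c("<high_school", "high_school",
                             "diploma_plus_1_2", "diploma_plus_3")),
    male_sex = m(c(66, 62), c(20, 11), yn),
    c_section = m(c(82, 46), c(16, 15), yn),
    skin_to_skin_start = m(c(29, 39, 53), c(8, 13, 9),
                           c("day_0_3", "day_4_7", "not_practiced")),
    antibiotic_therapy = m(c(104, 13), c(28, 3), yn),
    human_milk = m(c(109, 16), c(25, 5), yn),
    direct_breastfeeding_strategy = m(c(11, 117), c(2, 29), yn),
    skin_to_skin_strategy = m(c(74, 54), c(21, 10), yn),
    longer_primary_antibiotics = m(c(38, 90), c(13, 18), yn),
    longer_secondary_antibiotics = m(c(60, 68), c(17, 14), yn),
    sedation = m(c(81, 47), c(20, 11), yn),
    no_intubation_day1 = m(c(46, 82), c(14, 17), yn),
    low_enteral_volume_day7 = m(c(35, 93), c(14, 17), yn))
  continuous <- data.frame(
    variable = c("gestational_age_weeks", "birth_weight_g",
                 "birth_weight_zscore"),
    mean_b = c(28.7, 1130, -0.913), sd_b = c(1.96, 335, 1.38),
    n_b = c(128, 128, 128),
    mean_p = c(29.3, 1280, -0.483), sd_p = c(1.89, 317, 1.36),
    n_p = c(31, 31, 31))
  list(categorical = categorical, continuous = continuous)
}

#' Univariate association screen of covariates against the example tables
#'
#' Applies the compatibility profile to every bundled cross-tabulation
#' (Yates-corrected chi-squared for 2x2, plain Pearson otherwise) and a
#' pooled t-test to each continuous summary row.
#'
#' @return A data frame with one row per covariate: `variable`, `method`,
#'   `statistic`, `p_value`.
#' @export
preterm_covariate_screen <- function() {
  tabs <- preterm_covariate_tables()
  cat_res <- lapply(names(tabs$categorical), function(v) {
    r <- contingency_test(t(tabs$categorical[[v]]), method = "chisq")
    data.frame(variable = v, method = r$method,
               statistic = r$statistic, p_value = r$p_value)
  })
  cont_res <- lapply(seq_len(nrow(tabs$continuous)), function(i) {
    row <- tabs$continuous[i, ]
    r <- t_test_summary(row$mean_b, row$sd_b, row$n_b,
                        row$mean_p, row$sd_p, row$n_p, pooled = TRUE)
    data.frame(variable = row$variable, method = r$method,
               statistic = r$statistic, p_value = r$p_value)
  })
  out <- do.call(rbind, c(cat_res, cont_res))
  rownames(out) <- NULL
  out
}
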