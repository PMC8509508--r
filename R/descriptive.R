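#' Demographic summary table with stratified comparisons
#'
#' Produces a Table-1-style cohort description: counts and percentages for
#' the categorical characteristics (sex, age group, region, reporter type,
#' seriousness, death) and mean (SD) plus median (IQR) for age and drugs per
#' report — overall and, when `strata` is `"sex"` or `"age65"`, per stratum
#' with a between-stratum test: Pearson chi-squared for categorical rows
#' (unknown categories excluded from the test), Welch two-sample t-test for
#' numeric rows. Reports with unknown stratum appear in the overall column
#' but are excluded from the two-column comparison. Percentages are computed
#' on raw counts; for reporter type the denominator is the known-reporter
#' total, for the other categorical rows the stratum size.
#'
#' @param x an `icsr_set`.
#' @param strata `"none"`, `"sex"` (female vs male) or `"age65"` (`<65` vs
#'   `>=65`).
#' @param yates apply Yates continuity correction to 2x2 chi-squared tests.
#' @return tibble with columns `characteristic`, `level`, `overall_n`,
#'   `overall_pct` (or mean/median strings for numeric rows), one `n`/`pct`
#'   pair per stratum, and `p_value` (repeated within a characteristic).
#' @export
demographics_table <- function(x, strata = c("none", "sex", "age65"),
                               yates = FALSE) {
  strata <- match.arg(strata)
  stopifnot(inherits(x, "icsr_set"))
  meta <- x$meta
  meta$n_drugs <- as.integer(table(x$drugs$report_id)[meta$report_id])
  meta$n_drugs[is.na(meta$n_drugs)] <- 0L

  group <- switch(strata,
    none = NULL,
    sex = ifelse(meta$sex %in% c("female", "male"), meta$sex, NA),
    age65 = ifelse(is.na(meta$age_years), NA,
                   ifelse(meta$age_years < 65, "under65", "over65"))
  )
  levels_g <- switch(strata, none = character(), sex = c("female", "male"),
                     age65 = c("under65", "over65"))

  rows <- list()
  add_cat <- function(characteristic, values, level_order,
                      denominator = c("all", "known")) {
    denominator <- match.arg(denominator)
    known <- !is.na(values) & values != "unknown"
    base_all <- if (denominator == "known") sum(known) else length(values)
    row <- tibble::tibble(characteristic = characteristic,
                          level = level_order,
                          overall_n = vapply(level_order,
                                             function(l) sum(values == l,
                                                             na.rm = TRUE), 1,
                                             USE.NAMES = FALSE),
                          overall_pct = .data$overall_n / base_all * 100)
    p <- NA_real_
    if (strata != "none") {
      for (gl in levels_g) {
        in_g <- !is.na(group) & group == gl
        base_g <- if (denominator == "known") sum(in_g & known) else sum(in_g)
        row[[paste0(gl, "_n")]] <-
          vapply(level_order, function(l) sum(values == l & in_g,
                                              na.rm = TRUE), 1,
                 USE.NAMES = FALSE)
        row[[paste0(gl, "_pct")]] <- row[[paste0(gl, "_n")]] / base_g * 100
      }
      tab <- table(values[known & !is.na(group)], group[known & !is.na(group)])
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) >= 2 && ncol(tab) == 2)
        p <- suppressWarnings(stats::chisq.test(
          tab, correct = yates && nrow(tab) == 2)$p.value)
    }
    row$p_value <- p
    rows[[length(rows) + 1]] <<- row
  }
  add_num <- function(characteristic, values) {
    row <- tibble::tibble(
      characteristic = characteristic,
      level = c("mean (SD)", "median (IQR)"),
      overall_n = c(mean(values, na.rm = TRUE),
                    stats::median(values, na.rm = TRUE)),
      overall_pct = c(sd(values, na.rm = TRUE),
                      unname(diff(quantile(values, c(0.25, 0.75),
                                           na.rm = TRUE))))
    )
    p <- NA_real_
    if (strata != "none") {
      for (gl in levels_g) {
        v <- values[!is.na(group) & group == gl]
        row[[paste0(gl, "_n")]] <- c(mean(v, na.rm = TRUE),
                                     stats::median(v, na.rm = TRUE))
        row[[paste0(gl, "_pct")]] <- c(sd(v, na.rm = TRUE),
                                       unname(diff(quantile(v, c(0.25, 0.75),
                                                            na.rm = TRUE))))
      }
      a <- values[!is.na(group) & group == levels_g[1]]
      b <- values[!is.na(group) & group == levels_g[2]]
      p <- welch_p(a, b)
    }
    row$p_value <- p
    rows[[length(rows) + 1]] <<- row
  }

  add_cat("sex", meta$sex, c("female", "male", "unknown"))
  add_num("age_years", meta$age_years)
  add_cat("age_group", meta$age_group, age_group_levels)
  add_cat("region", meta$region, region_levels)
  add_cat("reporter", meta$reporter, reporter_levels, denominator = "known")
  add_cat("serious", ifelse(is.na(meta$serious), "unknown",
                            ifelse(meta$serious, "yes", "no")),
          c("yes", "no", "unknown"), denominator = "known")
  add_cat("death", ifelse(is.na(meta$death), "unknown",
                          ifelse(meta$death, "yes", "no")),
          c("yes", "no", "unknown"), denominator = "known")
  add_num("n_drugs", meta$n_drugs)
  dplyr::bind_rows(rows)
}

# Welch t-test p-value, defined (p = 1) for identical degenerate inputs.
welch_p <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (sd(a) == 0 && sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b)$p.value
}
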