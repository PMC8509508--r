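#' Construct an ICSR report set
#'
#' The central container of the package: a cohort of individual case safety
#' reports after (or before) exclusion filtering. It pairs a long drug table
#' (one row per report x distinct drug) with per-report metadata and the
#' counters of the inclusion cascade.
#'
#' @param drugs tibble with columns `report_id`, `drug` (normalized ingredient
#'   name) and optionally `atc_code`, `atc1`, `role`. Rows must be distinct per
#'   (report_id, drug): a report carries a *set* of ingredients, so a pair of
#'   drugs can be counted at most once per report.
#' @param meta optional tibble with one row per report: `report_id` plus any of
#'   `age_years`, `age_group`, `sex`, `region`, `reporter`, `serious`, `death`,
#'   `duplicate_flag`. Missing demographic columns are filled with `NA`/
#'   `"unknown"`. Reports present in `drugs` but absent from `meta` get a
#'   metadata row of unknowns.
#' @param flow optional named integer vector of inclusion-cascade counters
#'   (e.g. `extracted`, `unique`, `with_mapped_drug`, `retained`). Must be
#'   non-increasing.
#' @return an object of class `icsr_set` with elements `drugs`, `meta`, `flow`.
#' @seealso [apply_exclusions()], [drug_marginals()], [build_graph()]
#' @export
report_set <- function(drugs, meta = NULL, flow = NULL) {
  stopifnot(is.data.frame(drugs), all(c("report_id", "drug") %in% names(drugs)))
  drugs <- tibble::as_tibble(drugs)
  drugs$report_id <- as.character(drugs$report_id)
  drugs$drug <- as.character(drugs$drug)
  if (anyDuplicated(drugs[, c("report_id", "drug")]))
    stop("duplicated (report_id, drug) rows: drug lists must be sets")
  if (any(!nzchar(trimws(drugs$drug))))
    stop("empty drug names are not allowed in a report set")
  ids <- unique(drugs$report_id)
  meta <- normalize_meta(meta, ids)
  if (!is.null(flow)) {
    flow <- as.integer(flow) |> setNames(names(flow))
    if (is.unsorted(rev(flow))) stop("flow counters must be non-increasing")
  }
  structure(list(drugs = drugs, meta = meta, flow = flow), class = "icsr_set")
}

meta_columns <- c("age_years", "age_group", "sex", "region", "reporter",
                  "serious", "death", "duplicate_flag")

sex_levels <- c("female", "male", "unknown")
region_levels <- c("Europe", "Asia", "Africa", "North America", "Oceania",
                   "South America", "unknown")
reporter_levels <- c("physician", "other health professional",
                     "nonhealth professional", "unknown")
age_group_levels <- c("<16", "16-44", "45-64", "65-84", "85+", "unknown")

normalize_meta <- function(meta, ids) {
  if (is.null(meta)) meta <- tibble::tibble(report_id = ids)
  meta <- tibble::as_tibble(meta)
  stopifnot("report_id" %in% names(meta))
  meta$report_id <- as.character(meta$report_id)
  if (anyDuplicated(meta$report_id)) stop("meta must have one row per report")
  missing_ids <- setdiff(ids, meta$report_id)
  if (length(missing_ids))
    meta <- dplyr::bind_rows(meta, tibble::tibble(report_id = missing_ids))
  for (col in meta_columns) if (!col %in% names(meta)) meta[[col]] <- NA
  meta$age_years <- as.numeric(meta$age_years)
  if (any(meta$age_years < 0, na.rm = TRUE)) stop("age_years must be >= 0")
  meta$sex <- coerce_level(meta$sex, sex_levels)
  meta$region <- coerce_level(meta$region, region_levels)
  meta$reporter <- coerce_level(meta$reporter, reporter_levels)
  grp <- age_group_of(meta$age_years)
  if (all(is.na(meta$age_group))) {
    meta$age_group <- grp
  } else {
    meta$age_group <- coerce_level(meta$age_group, age_group_levels)
    bad <- !is.na(meta$age_years) & meta$age_group != grp
    if (any(bad)) stop("age_group inconsistent with age_years for ",
                       sum(bad), " report(s)")
  }
  meta$serious <- as.logical(meta$serious)
  meta$death <- as.logical(meta$death)
  meta$duplicate_flag <- !is.na(meta$duplicate_flag) &
    as.logical(meta$duplicate_flag)
  meta[, c("report_id", meta_columns)]
}

coerce_level <- function(x, levels) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- "unknown"
  bad <- !x %in% levels
  if (any(bad)) stop("invalid level(s): ", paste(unique(x[bad]), collapse = ", "))
  x
}

#' Age group of an age in years
#'
#' Bands used in the demographic tables: `<16`, `16-44`, `45-64`, `65-84`,
#' `85+`; missing ages map to `"unknown"`.
#'
#' @param age_years numeric vector of ages (may contain `NA`).
#' @return character vector of age-group labels.
#' @export
age_group_of <- function(age_years) {
  out <- cut(age_years, breaks = c(-Inf, 16, 45, 65, 85, Inf),
             labels = c("<16", "16-44", "45-64", "65-84", "85+"),
             right = FALSE)
  out <- as.character(out)
  out[is.na(out)] <- "unknown"
  out
}

#' @export
print.icsr_set <- function(x, ...) {
  cat("<icsr_set> ", n_reports(x), " reports, ",
      dplyr::n_distinct(x$drugs$drug), " distinct drugs\n", sep = "")
  if (!is.null(x$flow)) {
    cat("inclusion cascade:\n")
    for (i in seq_along(x$flow))
      cat("  ", format(names(x$flow)[i], width = 18), x$flow[i], "\n")
  }
  invisible(x)
}

#' Number of reports in a report set
#' @param x an `icsr_set`.
#' @return integer count of reports.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  nrow(x$meta)
}

#' Inclusion-cascade counters as a table
#'
#' Mirrors a study flowchart: reports extracted, remaining after duplicate
#' removal, after dropping unmappable drugs, and after restriction to reports
#' with two or more distinct drugs.
#'
#' @param x an `icsr_set` produced by [apply_exclusions()].
#' @return tibble with columns `stage`, `n_reports`, `excluded`.
#' @export
flow_table <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  if (is.null(x$flow)) stop("this report set carries no flow counters")
  tibble::tibble(
    stage = names(x$flow),
    n_reports = as.integer(x$flow),
    excluded = c(0L, -diff(as.integer(x$flow)))
  )
}

# Subset a report set to given report ids (keeps flow = NULL: a subset is a
# new cohort, not a cascade stage).
subset_reports <- function(x, ids) {
  report_set(
    drugs = dplyr::filter(x$drugs, .data$report_id %in% ids),
    meta = dplyr::filter(x$meta, .data$report_id %in% ids)
  )
}
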