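#' Assign ATC codes to drug entries
#'
#' Attaches `atc_code` and `atc1` (the one-letter anatomical main group, the
#' first character of the code) to each entry. Entries whose name is absent
#' from the map stay unmapped (`NA`) and are dropped later by
#' [apply_exclusions()]. When a name carries several codes in the map, the
#' lexicographically smallest code is chosen deterministically and a warning
#' is emitted.
#'
#' @param entries tibble with at least `report_id`, `drug`.
#' @param atc_map tibble from [read_atc_map()] (`drug`, `atc_code`).
#' @return `entries` with `atc_code` and `atc1` columns added.
#' @export
assign_atc <- function(entries, atc_map) {
  stopifnot(all(c("drug", "atc_code") %in% names(atc_map)))
  multi <- unique(atc_map$drug[duplicated(atc_map$drug)])
  if (length(multi)) {
    warning("multiple ATC codes for: ", paste(multi, collapse = ", "),
            "; lexicographically smallest code used")
    atc_map <- atc_map |>
      dplyr::arrange(.data$drug, .data$atc_code) |>
      dplyr::distinct(.data$drug, .keep_all = TRUE)
  }
  entries$atc_code <- NULL
  entries$atc1 <- NULL
  entries <- dplyr::left_join(entries, atc_map, by = "drug")
  entries$atc1 <- substr(entries$atc_code, 1, 1)
  entries
}

#' Apply the inclusion cascade to raw ICSR entries
#'
#' Reproduces the report-inclusion flowchart of a spontaneous-report
#' drug-combination analysis, in this order:
#'
#' 1. drop reports flagged as possible duplicates;
#' 2. drop drug entries whose name is unknown (unmappable) or that carry no
#'    ATC code, and collapse repeated ingredients within a report to a set;
#' 3. keep only reports with at least two distinct mapped drugs.
#'
#' Flow counters record the number of reports at each stage: `extracted`,
#' `unique` (after duplicate removal), `with_mapped_drug` (reports retaining
#' at least one mapped drug), `retained` (>= 2 distinct drugs). The drug role
#' (suspected/interacting/concomitant) is carried along as metadata but never
#' used for filtering.
#'
#' @param entries tibble with `report_id`, `drug`, optional `role`,
#'   `atc_code`/`atc1` (added via [assign_atc()] if absent).
#' @param meta per-report metadata tibble (see [report_set()]); its
#'   `duplicate_flag` column drives stage 1.
#' @param atc_map tibble (`drug`, `atc_code`); used when `entries` has no
#'   `atc_code` column.
#' @return an `icsr_set` of the retained cohort with populated `flow`.
#' @export
apply_exclusions <- function(entries, meta = NULL, atc_map = NULL) {
  entries <- tibble::as_tibble(entries)
  if (!"atc_code" %in% names(entries)) {
    if (is.null(atc_map))
      stop("entries carry no atc_code and no atc_map was given")
    entries <- assign_atc(entries, atc_map)
  }
  all_ids <- unique(entries$report_id)
  meta <- normalize_meta(meta, all_ids)
  n_extracted <- length(all_ids)

  dup_ids <- meta$report_id[meta$duplicate_flag]
  entries <- entries[!entries$report_id %in% dup_ids, ]
  n_unique <- dplyr::n_distinct(entries$report_id)

  mapped <- entries[!is.na(entries$atc_code), ]
  mapped <- mapped[!duplicated(mapped[, c("report_id", "drug")]), ]
  n_with_drug <- dplyr::n_distinct(mapped$report_id)

  keep_ids <- mapped |>
    dplyr::count(.data$report_id) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::pull(.data$report_id)
  retained <- mapped[mapped$report_id %in% keep_ids, ]

  report_set(
    drugs = retained,
    meta = meta[meta$report_id %in% keep_ids, ],
    flow = c(extracted = n_extracted, unique = n_unique,
             with_mapped_drug = n_with_drug, retained = length(keep_ids))
  )
}
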