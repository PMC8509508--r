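#' Column dialect for ICSR tables
#'
#' ICSR extracts arrive as delimited text with one row per (report, drug).
#' Column names, the delimiter and the decimal mark vary by source; a dialect
#' object maps them onto the names the package uses internally. The default is
#' tab-separated UTF-8 with the package's own column names.
#'
#' @param delim field delimiter.
#' @param report_id,drug,role names of the required id/drug columns and the
#'   optional drug-role column (`role` may be absent from the file).
#' @param age_years,sex,region,reporter,serious,death,duplicate_flag names of
#'   the optional per-report demographic columns.
#' @return a named list of class `icsr_dialect`.
#' @export
icsr_dialect <- function(delim = "\t",
                         report_id = "report_id",
                         drug = "drug_name",
                         role = "role",
                         age_years = "age_years",
                         sex = "sex",
                         region = "region",
                         reporter = "reporter",
                         serious = "serious",
                         death = "death",
                         duplicate_flag = "duplicate_flag") {
  structure(list(delim = delim, report_id = report_id, drug = drug,
                 role = role, age_years = age_years, sex = sex,
                 region = region, reporter = reporter, serious = serious,
                 death = death, duplicate_flag = duplicate_flag),
            class = "icsr_dialect")
}

drug_roles <- c("suspected", "interacting", "concomitant", "unknown")

#' Read an ICSR table
#'
#' Parses a delimited one-row-per-(report, drug) file into normalized drug
#' entries and per-report metadata. Drug names are whitespace-trimmed and
#' lowercased; rows whose drug name is empty after normalization are rejected
#' (counted, not fatal). Row order is preserved so downstream behaviour is
#' deterministic.
#'
#' @param path path to the delimited text file.
#' @param dialect an [icsr_dialect()] describing delimiter and column names.
#' @return a list with `entries` (tibble: `report_id`, `drug`, `role`),
#'   `meta` (tibble: one row per report with demographics and
#'   `duplicate_flag`), and `n_rejected` (rows dropped for empty drug names).
#' @export
read_icsr_table <- function(path, dialect = icsr_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = dialect$delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), fileEncoding = "UTF-8")
  for (col in c("report_id", "drug")) {
    if (!dialect[[col]] %in% names(raw))
      stop("required column missing from ", path, ": '", dialect[[col]], "'")
  }
  entries <- tibble::tibble(
    report_id = as.character(raw[[dialect$report_id]]),
    drug = tolower(trimws(gsub("\\s+", " ", raw[[dialect$drug]]))),
    role = if (dialect$role %in% names(raw)) tolower(raw[[dialect$role]])
           else NA_character_
  )
  entries$role[is.na(entries$role) | !entries$role %in% drug_roles] <- "unknown"
  keep <- !is.na(entries$drug) & nzchar(entries$drug) &
    !is.na(entries$report_id)
  n_rejected <- sum(!keep)
  entries <- entries[keep, ]
  meta <- raw[keep, , drop = FALSE]
  meta <- meta[!duplicated(meta[[dialect$report_id]]), , drop = FALSE]
  pick <- function(col) if (dialect[[col]] %in% names(meta))
    meta[[dialect[[col]]]] else NA
  meta <- tibble::tibble(
    report_id = as.character(meta[[dialect$report_id]]),
    age_years = suppressWarnings(as.numeric(pick("age_years"))),
    sex = pick("sex"), region = pick("region"), reporter = pick("reporter"),
    serious = parse_flag(pick("serious")),
    death = parse_flag(pick("death")),
    duplicate_flag = parse_flag(pick("duplicate_flag"))
  )
  list(entries = entries, meta = meta, n_rejected = n_rejected)
}

parse_flag <- function(x) {
  if (all(is.na(x))) return(rep(NA, length(x)))
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Read a drug-name to ATC-code mapping
#'
#' Two-column delimited text: normalized drug name, ATC code. Codes must match
#' the ATC syntax (letter, two digits, letter, letter, two digits) or a
#' truncated level prefix thereof. A name listed with several codes is kept
#' with all of them; tie-breaking happens in [assign_atc()].
#'
#' @param path path to the mapping file.
#' @param delim field delimiter.
#' @param header does the file have a header line?
#' @return tibble with columns `drug`, `atc_code`.
#' @export
read_atc_map <- function(path, delim = "\t", header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = delim, header = header,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("ATC map must have two columns (name, code)")
  map <- tibble::tibble(
    drug = tolower(trimws(gsub("\\s+", " ", raw[[1]]))),
    atc_code = toupper(trimws(raw[[2]]))
  )
  map <- dplyr::distinct(map[!is.na(map$drug) & !is.na(map$atc_code), ])
  bad <- !grepl(atc_pattern, map$atc_code)
  if (any(bad))
    stop("invalid ATC code(s): ", paste(unique(map$atc_code[bad]), collapse = ", "))
  map
}

# full 7-character code or any truncated ATC level (1, 3, 4, 5 characters)
atc_pattern <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"

#' Write a report set (or raw entries) back to the table dialect
#'
#' Inverse of [read_icsr_table()]: one row per (report, drug) with the
#' demographics repeated on each row. Used to materialize synthetic cohorts.
#'
#' @param entries tibble with `report_id`, `drug` and optionally `role`.
#' @param meta per-report metadata tibble (as in [report_set()]).
#' @param path output path.
#' @param dialect an [icsr_dialect()].
#' @return `path`, invisibly.
#' @export
write_icsr_table <- function(entries, meta, path, dialect = icsr_dialect()) {
  rows <- dplyr::left_join(entries, meta, by = "report_id")
  out <- data.frame(
    rows$report_id, rows$drug,
    if ("role" %in% names(rows)) rows$role else "unknown",
    rows$age_years, rows$sex, rows$region, rows$reporter,
    rows$serious, rows$death, rows$duplicate_flag,
    check.names = FALSE
  )
  names(out) <- c(dialect$report_id, dialect$drug, dialect$role,
                  dialect$age_years, dialect$sex, dialect$region,
                  dialect$reporter, dialect$serious, dialect$death,
                  dialect$duplicate_flag)
  utils::write.table(out, path, sep = dialect$delim, quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
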