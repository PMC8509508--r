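#' Per-drug report counts and prevalences
#'
#' Counts, for each drug, the number of distinct reports containing it;
#' prevalence is that count divided by the cohort size N. Because every
#' retained report lists two or more drugs, prevalences sum to more than 1
#' (polypharmacy).
#'
#' @param x an `icsr_set`.
#' @return tibble with columns `drug`, `n`, `prevalence`, `atc1`, sorted by
#'   descending `n` (ties alphabetical).
#' @export
drug_marginals <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  if (n_reports(x) == 0) stop("empty report set")
  N <- n_reports(x)
  x$drugs |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$report_id),
      atc1 = if ("atc1" %in% names(x$drugs)) .data$atc1[1] else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::mutate(prevalence = .data$n / N) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$drug) |>
    dplyr::select("drug", "n", "prevalence", "atc1")
}

#' Count observed drug pairs or triads
#'
#' Each report contributes each k-subset of its drug set exactly once; sets
#' are unordered, so the pair (A, B) and (B, A) are the same combination.
#' Member names within a combination are stored in alphabetical order.
#'
#' @param x an `icsr_set`.
#' @param k subset size, 2 (pairs) or 3 (triads).
#' @return tibble with columns `drug1`, ..., `drugk`, `n_obs`.
#' @export
count_ksets <- function(x, k) {
  stopifnot(inherits(x, "icsr_set"))
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3")
  sets <- split(x$drugs$drug, x$drugs$report_id)
  sets <- sets[lengths(sets) >= k]
  cols <- paste0("drug", seq_len(k))
  if (!length(sets)) {
    out <- tibble::as_tibble(setNames(rep(list(character()), k), cols))
    out$n_obs <- integer()
    return(out)
  }
  combos <- lapply(sets, function(d) combn(sort(d), k))
  mat <- do.call(cbind, combos)
  keys <- if (k == 2L) paste(mat[1, ], mat[2, ], sep = "\r")
          else paste(mat[1, ], mat[2, ], mat[3, ], sep = "\r")
  counts <- table(keys)
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- tibble::as_tibble(setNames(
    lapply(seq_len(k), function(i) vapply(parts, `[`, "", i)), cols))
  out$n_obs <- as.integer(counts)
  dplyr::arrange(out, dplyr::desc(.data$n_obs),
                 !!!rlang::syms(cols))
}

#' O/E ratio of a drug combination from counts
#'
#' The observed-to-expected ratio compares the observed co-reporting
#' prevalence of a pair or triad with the prevalence expected if the member
#' drugs occurred independently, i.e. the product of their marginal
#' prevalences over the same cohort of N reports:
#' \deqn{O/E = \frac{n_{obs}/N}{\prod_i n_i/N}}
#' which reduces to `n_obs * N / (n1 * n2)` for pairs and
#' `n_obs * N^2 / (n1 * n2 * n3)` for triads. Values above one mean the
#' combination is reported together more often than expected.
#'
#' @param n_obs number of reports containing all member drugs.
#' @param marginals vector of the member drugs' marginal report counts
#'   (length 2 or 3), all positive.
#' @param n_total cohort size N.
#' @return a list with `obs_prev`, `exp_prev`, `oe` (all unrounded).
#' @export
oe_from_counts <- function(n_obs, marginals, n_total) {
  if (!length(marginals) %in% c(2L, 3L))
    stop("a combination has 2 or 3 member drugs")
  if (any(marginals <= 0))
    stop("O/E undefined: a member drug has zero marginal count")
  if (n_obs > min(marginals))
    stop("n_obs cannot exceed the smallest marginal count")
  obs_prev <- n_obs / n_total
  exp_prev <- prod(marginals / n_total)
  list(obs_prev = obs_prev, exp_prev = exp_prev, oe = obs_prev / exp_prev)
}

#' Pair/triad statistics with O/E ratios for a cohort
#'
#' Combines [count_ksets()] with marginal counts to produce a Table-2-style
#' combination table: observed count, observed prevalence, expected prevalence
#' under independence, and the O/E ratio, all computed on unrounded values.
#'
#' @param x an `icsr_set`.
#' @param k 2 for pairs, 3 for triads.
#' @return tibble with member-drug columns plus `n_obs`, `obs_prev`,
#'   `exp_prev`, `oe`.
#' @export
combo_stats <- function(x, k) {
  N <- n_reports(x)
  marg <- drug_marginals(x)
  counts <- count_ksets(x, k)
  lookup <- setNames(marg$n, marg$drug)
  cols <- paste0("drug", seq_len(k))
  prod_marg <- Reduce(`*`, lapply(cols, function(cl)
    unname(lookup[counts[[cl]]])))
  counts$obs_prev <- counts$n_obs / N
  counts$exp_prev <- prod_marg / N^k
  counts$oe <- counts$obs_prev / counts$exp_prev
  counts
}

#' Rank a statistics table and keep the top rows
#'
#' Descending sort on the ranking column with a deterministic alphabetical
#' tie-break on the drug-name columns; percentages are left unrounded (use
#' [format_prevalence()] for display).
#'
#' @param stats a tibble from [drug_marginals()] or [combo_stats()].
#' @param rank_by column to rank by: `"n"`/`"n_obs"` or `"oe"`.
#' @param top_n number of rows to keep; if larger than available, all rows.
#' @return the ranked head of `stats`.
#' @export
top_table <- function(stats, rank_by = c("n_obs", "n", "oe"), top_n = 20) {
  rank_by <- match.arg(rank_by)
  if (!rank_by %in% names(stats))
    stop("no such ranking column: ", rank_by)
  stopifnot(top_n >= 1)
  name_cols <- intersect(c("drug", paste0("drug", 1:3)), names(stats))
  out <- dplyr::arrange(stats, dplyr::desc(.data[[rank_by]]),
                        !!!rlang::syms(name_cols))
  head(out, top_n)
}

#' Format a proportion as a 2-decimal percentage string
#'
#' Display-only helper (half-up rounding); no downstream computation should
#' consume its output.
#'
#' @param p proportion in `[0, 1]`.
#' @param digits decimal places.
#' @return character vector like `"21.63%"`.
#' @export
format_prevalence <- function(p, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * p, digits))
}

#' Monte-Carlo permutation null for O/E ratios
#'
#' Optional check (off by default in [run_pipeline()]): shuffles drug sets
#' across reports while preserving each report's set size and each drug's
#' total count approximately, then recomputes pair O/E ratios to show the
#' null spread. The primary analysis reports raw O/E point estimates without
#' confidence intervals or multiplicity correction.
#'
#' @param x an `icsr_set`.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return tibble with `perm`, `mean_oe`, `max_oe` over observed pairs.
#' @export
oe_permutation_null <- function(x, n_perm = 20, seed = 1) {
  stopifnot(inherits(x, "icsr_set"))
  sizes <- lengths(split(x$drugs$drug, x$drugs$report_id))
  pool <- x$drugs$drug
  with_local_seed(seed, {
    out <- lapply(seq_len(n_perm), function(b) {
      perm <- sample(pool)
      # redistribute into the original set sizes, dropping within-report
      # repeats (kept as sets, as in the real data)
      ids <- rep(seq_along(sizes), sizes)
      d <- tibble::tibble(report_id = as.character(ids), drug = perm) |>
        dplyr::distinct()
      keep <- d |> dplyr::count(.data$report_id) |>
        dplyr::filter(.data$n >= 2) |> dplyr::pull(.data$report_id)
      xs <- report_set(d[d$report_id %in% keep, ])
      cs <- combo_stats(xs, 2)
      tibble::tibble(perm = b, mean_oe = mean(cs$oe), max_oe = max(cs$oe))
    })
    dplyr::bind_rows(out)
  })
}
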