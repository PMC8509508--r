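#' Summarize detected communities
#'
#' For each community: its size (number of drugs), the dominant ATC-1
#' anatomical main group with its share of the community, and the top drugs
#' by prevalence with their node degree (number of distinct co-reported
#' drugs), report count and prevalence.
#'
#' @param g graph from [build_graph()].
#' @param partition a `drug_partition` over `g`'s vertices.
#' @param top_n how many drugs to list per community.
#' @return list with `clusters` (tibble: `community`, `size`,
#'   `dominant_atc1`, `dominant_share`) and `top_drugs` (tibble: `community`,
#'   `drug`, `degree`, `n`, `prevalence`), communities ordered by size.
#' @export
cluster_summary <- function(g, partition, top_n = 20) {
  stopifnot(inherits(partition, "drug_partition"))
  memb <- partition$membership
  vnames <- igraph::V(g)$name
  if (!all(vnames %in% names(memb)))
    stop("partition does not cover every node of the graph")
  nodes <- tibble::tibble(
    drug = vnames,
    community = as.integer(memb[vnames]),
    degree = igraph::degree(g),
    n = igraph::V(g)$count,
    prevalence = igraph::V(g)$prevalence,
    atc1 = igraph::V(g)$atc1
  )
  clusters <- nodes |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(size = dplyr::n(),
                     dominant_atc1 = modal_group(.data$atc1),
                     dominant_share = mean(!is.na(.data$atc1) &
                                             .data$atc1 == modal_group(.data$atc1)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$community)
  top_drugs <- nodes |>
    dplyr::group_by(.data$community) |>
    dplyr::arrange(dplyr::desc(.data$prevalence), .data$drug,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup() |>
    dplyr::select("community", "drug", "degree", "n", "prevalence")
  list(clusters = clusters, top_drugs = top_drugs)
}

# modal value, alphabetical tie-break; NA/empty codes excluded unless alone
modal_group <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  if (!length(x)) return(NA_character_)
  tab <- table(x)
  names(tab)[which.max(tab)]  # which.max takes the first = alphabetical
}

#' Stratified network analysis
#'
#' Splits the cohort by sex (female vs male) or by age at 65 (`<65` vs
#' `>=65`; reports with unknown sex/age are excluded from their
#' stratification only), then reruns the full network pipeline per stratum:
#' graph construction, Louvain, leading-eigenvector, and cluster summary.
#' Strata with fewer than 2 reports are skipped with a warning.
#'
#' @param x an `icsr_set`.
#' @param strata `"sex"` or `"age65"`.
#' @param seed seed forwarded to [louvain_communities()].
#' @param top_n per-community drugs listed in the summaries.
#' @return named list (one element per stratum) of lists with `n_reports`,
#'   `graph`, `louvain`, `leading_eigen`, `summary`.
#' @export
stratified_analysis <- function(x, strata = c("sex", "age65"), seed = 1,
                                top_n = 20) {
  strata <- match.arg(strata)
  stopifnot(inherits(x, "icsr_set"))
  groups <- switch(strata,
    sex = list(female = x$meta$report_id[x$meta$sex == "female"],
               male = x$meta$report_id[x$meta$sex == "male"]),
    age65 = list(
      `under65` = x$meta$report_id[!is.na(x$meta$age_years) &
                                     x$meta$age_years < 65],
      `over65` = x$meta$report_id[!is.na(x$meta$age_years) &
                                    x$meta$age_years >= 65])
  )
  out <- list()
  for (nm in names(groups)) {
    ids <- groups[[nm]]
    if (length(ids) < 2) {
      warning("stratum '", nm, "' has fewer than 2 reports; skipped")
      next
    }
    xs <- subset_reports(x, ids)
    g <- build_graph(xs)
    lv <- louvain_communities(g, seed = seed)
    le <- leading_eigen_communities(g)
    out[[nm]] <- list(n_reports = n_reports(xs), graph = g, louvain = lv,
                      leading_eigen = le,
                      summary = cluster_summary(g, lv, top_n = top_n))
  }
  out
}
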