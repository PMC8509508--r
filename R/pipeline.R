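#' Pipeline run configuration
#'
#' Either point the pipeline at an ICSR table and an ATC map on disk, or give
#' it a [sim_config()] to generate the cohort in memory. Exactly one of the
#' two input modes must be present.
#'
#' @param icsr_table,atc_map paths to the input files (file mode).
#' @param simulate a `sim_config` (simulate mode).
#' @param out_dir output directory (created if needed).
#' @param dialect an [icsr_dialect()] for reading the ICSR table.
#' @param top_n rows kept in the ranked tables.
#' @param min_edge_weight edge-weight threshold for the exported
#'   reduced graph (the full graph is always exported too).
#' @param strata stratified reruns to perform: subset of `c("sex", "age65")`.
#' @param seed top-level seed; all randomness (simulation, Louvain visit
#'   order) derives from it.
#' @return a `run_config` list.
#' @export
run_config <- function(icsr_table = NULL, atc_map = NULL, simulate = NULL,
                       out_dir = "icsrnet-output", dialect = icsr_dialect(),
                       top_n = 20, min_edge_weight = 2,
                       strata = c("sex", "age65"), seed = 1) {
  if (is.null(simulate) && (is.null(icsr_table) || is.null(atc_map)))
    stop("run_config needs either input paths or a simulate block")
  if (!is.null(simulate) && !inherits(simulate, "sim_config"))
    stop("simulate must be a sim_config")
  structure(list(icsr_table = icsr_table, atc_map = atc_map,
                 simulate = simulate, out_dir = out_dir, dialect = dialect,
                 top_n = top_n, min_edge_weight = min_edge_weight,
                 strata = match.arg(strata, several.ok = TRUE),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full drug-combination analysis
#'
#' Executes the whole pipeline: read or simulate the ICSR table, apply the
#' exclusion cascade, compute marginal/pair/triad statistics with O/E ratios,
#' build and export the co-reporting network, detect communities with Louvain
#' and with the leading-eigenvector method, write cluster and demographic
#' summaries, rerun the network analysis per stratum, and write a JSON
#' manifest (seed, package version, flow counters, output list). Identical
#' config and seed give identical outputs. Any stage failure aborts the run
#' and removes the partially written output directory.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with the retained `icsr_set`, the graph, both
#'   partitions, the summary tables and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  created <- !dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out, recursive = TRUE))
  say <- function(...) if (!quiet) message("[icsrnet] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  say("stage: input")
  inputs <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- simulate_icsr(config$simulate, seed = config$seed)
      list(entries = sim$entries, meta = sim$meta,
           atc_map = atc_table(config$simulate))
    } else {
      parsed <- read_icsr_table(config$icsr_table, config$dialect)
      list(entries = parsed$entries, meta = parsed$meta,
           atc_map = read_atc_map(config$atc_map))
    }
  })

  say("stage: filter")
  x <- stage("filter", apply_exclusions(inputs$entries, inputs$meta,
                                        inputs$atc_map))
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  emit(flow_table(x), "flow.csv")

  say("stage: stats")
  stage("stats", {
    marg <- drug_marginals(x)
    emit(fmt_stats(top_table(marg, "n", config$top_n)), "drugs_top.csv")
    emit(fmt_stats(top_table(combo_stats(x, 2), "n_obs", config$top_n)),
         "pairs_top.csv")
    emit(fmt_stats(top_table(combo_stats(x, 3), "n_obs", config$top_n)),
         "triads_top.csv")
  })

  say("stage: network")
  g <- stage("network", build_graph(x))
  stage("network-export", {
    export_graph(g, file.path(out, "network.graphml"))
    export_graph(g, file.path(out, "network.gexf"))
    export_graph(g, file.path(out, "network_edges.csv"))
    files <<- c(files, "network.graphml", "network.gexf", "network_edges.csv")
    if (config$min_edge_weight > 1) {
      export_graph(filter_graph(g, config$min_edge_weight),
                   file.path(out, "network_reduced.graphml"))
      files <<- c(files, "network_reduced.graphml")
    }
  })

  say("stage: communities")
  parts <- stage("communities", {
    lv <- louvain_communities(g, seed = config$seed)
    le <- leading_eigen_communities(g)
    emit(partition_frame(lv), "communities_louvain.csv")
    emit(partition_frame(le), "communities_eigen.csv")
    cs <- cluster_summary(g, lv, top_n = config$top_n)
    emit(cs$clusters, "cluster_sizes.csv")
    emit(cs$top_drugs, "cluster_top_drugs.csv")
    list(louvain = lv, leading_eigen = le, summary = cs)
  })

  say("stage: descriptive")
  stage("descriptive", {
    emit(demographics_table(x, "none"), "demographics.csv")
    emit(demographics_table(x, "sex"), "demographics_by_sex.csv")
  })

  say("stage: stratified")
  stratified <- list()
  for (st in config$strata) {
    stratified[[st]] <- stage(paste0("stratified-", st), {
      res <- stratified_analysis(x, st, seed = config$seed,
                                 top_n = config$top_n)
      for (nm in names(res)) {
        emit(partition_frame(res[[nm]]$louvain),
             sprintf("communities_louvain_%s_%s.csv", st, nm))
        emit(res[[nm]]$summary$clusters,
             sprintf("cluster_sizes_%s_%s.csv", st, nm))
      }
      res
    })
  }

  manifest <- list(
    package = "icsrnet",
    version = as.character(utils::packageVersion("icsrnet")),
    seed = config$seed,
    mode = if (is.null(config$simulate)) "files" else "simulate",
    flow = as.list(x$flow),
    n_drugs = dplyr::n_distinct(x$drugs$drug),
    modularity = list(louvain = parts$louvain$modularity,
                      leading_eigen = parts$leading_eigen$modularity),
    outputs = files
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  missing <- files[!file.exists(file.path(out, files))]
  if (length(missing)) stop("declared outputs missing: ",
                            paste(missing, collapse = ", "))
  ok <- TRUE
  say("done: ", out)
  invisible(list(report_set = x, graph = g, louvain = parts$louvain,
                 leading_eigen = parts$leading_eigen,
                 summary = parts$summary, stratified = stratified,
                 manifest = manifest))
}

# round display columns of a stats table (raw values stay in memory only)
fmt_stats <- function(df) {
  for (col in intersect(c("prevalence", "obs_prev", "exp_prev"), names(df)))
    df[[col]] <- round_half_up(100 * df[[col]], 2)
  if ("oe" %in% names(df)) df$oe <- round_half_up(df$oe, 2)
  df
}

partition_frame <- function(p) {
  tibble::tibble(drug = names(p$membership),
                 community = as.integer(p$membership))
}
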