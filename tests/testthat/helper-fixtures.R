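# Fixtures and independent oracles used across the test files. Everything is
# built in code at test time; no binary data.

# --- deterministic cohort matching the printed top-table counts ------------
# A cohort of 2649 two-or-three-drug reports constructed so that the tracked
# marginal counts, the paracetamol-amoxicillin pair count (109), the
# ibuprofen-amoxicillin-paracetamol triad count (17), the
# bisoprolol-furosemide pair (44) and the acetylsalicylic acid-atorvastatin
# pair (46) all take known values. Filler partners are unique per report so
# they never disturb a tracked pair.
make_reference_cohort <- function() {
  target_total <- 2649
  rows <- list()
  rid <- 0L
  add_reports <- function(drug_sets, times = 1) {
    for (i in seq_len(times)) {
      rid <<- rid + 1L
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        report_id = sprintf("f%04d", rid), drug = drug_sets)
    }
  }
  add_reports(c("ibuprofen", "amoxicillin", "paracetamol"), 17)
  add_reports(c("paracetamol", "amoxicillin"), 92)   # pair total 109
  add_reports(c("acetylsalicylic acid", "atorvastatin"), 46)
  add_reports(c("bisoprolol", "furosemide"), 44)
  top_up <- c(amoxicillin = 573 - 109, paracetamol = 397 - 109,
              furosemide = 197 - 44, bisoprolol = 108 - 44,
              ibuprofen = 102 - 17, `acetylsalicylic acid` = 189 - 46)
  filler <- 0L
  for (drug in names(top_up)) {
    for (i in seq_len(top_up[[drug]])) {
      filler <- filler + 1L
      add_reports(c(drug, sprintf("filler%05d", filler)))
    }
  }
  while (rid < target_total) {
    filler <- filler + 2L
    add_reports(sprintf("filler%05d", filler - c(1L, 0L)))
  }
  drugs <- dplyr::bind_rows(rows)
  atc1_of <- c(amoxicillin = "J", paracetamol = "N", ibuprofen = "M",
               `acetylsalicylic acid` = "B", atorvastatin = "C",
               bisoprolol = "C", furosemide = "C")
  drugs$atc1 <- unname(atc1_of[drugs$drug])
  report_set(drugs)
}

# --- tiny hand-written ICSR table + ATC map --------------------------------
write_tiny_icsr <- function(path, lines) {
  writeLines(lines, path)
  path
}

# --- brute-force k-subset counter (independent double/triple loop) ---------
brute_force_ksets <- function(x, k) {
  sets <- split(x$drugs$drug, x$drugs$report_id)
  counts <- new.env()
  for (s in sets) {
    s <- sort(unique(s))
    if (length(s) < k) next
    idx <- combn(length(s), k)
    for (col in seq_len(ncol(idx))) {
      key <- paste(s[idx[, col]], collapse = "|")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  out <- tibble::tibble(key = ls(counts),
                        n_obs = vapply(ls(counts), function(k2)
                          as.integer(counts[[k2]]), 1L))
  out[order(-out$n_obs, out$key), ]
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# --- exhaustive modularity oracle over all set partitions ------------------
# Enumerates partitions via restricted growth strings; feasible to n = 8
# (Bell(8) = 4140).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_label) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (lab in seq_len(next_label))
      recurse(c(labels, lab), max(next_label, lab + 1L))
  }
  recurse(integer(), 1L)
  out
}

exhaustive_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8)
  parts <- all_partitions(n)
  qs <- vapply(parts, function(p) graph_modularity(g, p), 1)
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# --- random small weighted graphs (fixed-seed suite) -----------------------
random_weighted_graph <- function(n, p = 0.5, wmax = 5) {
  repeat {
    el <- t(combn(n, 2))
    keep <- runif(nrow(el)) < p
    if (sum(keep) >= 1) break
  }
  el <- el[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- sample.int(wmax, nrow(el), replace = TRUE)
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  g
}
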