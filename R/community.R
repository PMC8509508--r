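# Community detection on the weighted co-reporting network: Newman-Girvan
# modularity, Louvain multi-level optimisation, and recursive
# leading-eigenvector bisection. These are authored here (not delegated)
# because the clustering behaviour is the object under study; igraph's
# implementations are used as independent cross-checks in the test suite.

# Internal edge-list view of an igraph: 1-based endpoint indices, weights,
# per-node weighted degree (self-loops count twice), total weight m.
graph_data <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  n <- igraph::vcount(g)
  deg <- numeric(n)
  for (e in seq_len(nrow(el))) {
    deg[el[e, 1]] <- deg[el[e, 1]] + w[e]
    deg[el[e, 2]] <- deg[el[e, 2]] + w[e]
  }
  list(i = el[, 1], j = el[, 2], w = w, deg = deg, n = n, m = sum(w),
       names = igraph::V(g)$name %||% as.character(seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Modularity of a partition
#'
#' Newman-Girvan modularity of a node partition on a weighted undirected
#' graph:
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \gamma\frac{k_i k_j}{2m}\right]
#'   \delta(c_i, c_j)}
#' with weighted adjacency A (self-loops counted twice on the diagonal),
#' weighted degrees k, total edge weight m and resolution `gamma`. Q lies in
#' `[-1, 1]`; larger values mean denser within-community connections than the
#' degree-preserving null expects.
#'
#' @param g weighted undirected igraph (edge attribute `weight`; unweighted
#'   graphs count each edge as 1).
#' @param membership community labels, one per vertex (order of `V(g)`), or a
#'   `drug_partition`.
#' @param resolution resolution parameter `gamma` (1 = classic modularity).
#' @return the modularity Q as a single number.
#' @export
graph_modularity <- function(g, membership, resolution = 1) {
  gd <- graph_data(g)
  if (gd$m <= 0) stop("modularity undefined: graph has no edge weight")
  memb <- as_membership_vector(membership, gd)
  two_m <- 2 * gd$m
  within <- sum(2 * gd$w[memb[gd$i] == memb[gd$j]])
  tot <- tapply(gd$deg, memb, sum)
  within / two_m - resolution * sum((tot / two_m)^2)
}

as_membership_vector <- function(membership, gd) {
  if (inherits(membership, "drug_partition"))
    membership <- membership$membership
  if (!is.null(names(membership)) && all(gd$names %in% names(membership)))
    membership <- membership[gd$names]
  if (length(membership) != gd$n)
    stop("membership must cover every node exactly once")
  if (anyNA(membership)) stop("membership contains NA")
  as.integer(factor(membership))
}

new_partition <- function(labels, names, g, method, resolution = 1) {
  labels <- as.integer(factor(labels, levels = unique(labels))) - 1L
  memb <- setNames(labels, names)
  structure(
    list(membership = memb,
         modularity = graph_modularity(g, memb, resolution = 1),
         method = method, resolution = resolution),
    class = "drug_partition")
}

#' @export
print.drug_partition <- function(x, ...) {
  cat("<drug_partition> ", x$method, ": ",
      length(unique(x$membership)), " communities over ",
      length(x$membership), " nodes, Q = ",
      format(x$modularity, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Community sizes of a partition
#' @param partition a `drug_partition`.
#' @return tibble with `community`, `size`, largest first.
#' @export
partition_sizes <- function(partition) {
  tab <- sort(table(partition$membership), decreasing = TRUE)
  tibble::tibble(community = as.integer(names(tab)), size = as.integer(tab))
}

#' Louvain community detection
#'
#' Multi-level greedy modularity optimisation. Phase one moves single nodes
#' to the neighbouring community with the largest modularity gain
#' \deqn{\Delta Q \propto w_{i \to C} - \gamma\, k_i \Sigma_{tot}(C) / (2m)}
#' (ties broken toward the smallest community label) until a full pass makes
#' no move; phase two aggregates communities into a weighted super-graph with
#' self-loops and repeats. The outer loop stops when aggregation no longer
#' increases Q. The node visiting order is shuffled once per pass by a
#' generator seeded from `seed`, so results are reproducible.
#'
#' @param g weighted undirected igraph with positive total edge weight.
#' @param seed integer seed for the visit-order shuffle.
#' @param resolution resolution parameter (1 = classic modularity, as used
#'   for the primary analysis).
#' @return a `drug_partition` (0-based contiguous labels named by vertex,
#'   with the classic-modularity Q of the final partition).
#' @export
louvain_communities <- function(g, seed = 1, resolution = 1) {
  gd <- graph_data(g)
  if (gd$n == 0) stop("empty graph")
  if (gd$m <= 0) stop("graph has no edge weight")
  with_local_seed(seed, {
    memb_global <- seq_len(gd$n)
    level <- list(i = gd$i, j = gd$j, w = gd$w, deg = gd$deg, n = gd$n,
                  m = gd$m)
    q_prev <- -Inf
    repeat {
      comm <- louvain_one_level(level, resolution)
      memb_global <- comm[memb_global]
      q_now <- membership_quality(gd, memb_global, resolution)
      if (q_now <= q_prev + 1e-12) break
      q_prev <- q_now
      level <- aggregate_level(level, comm)
      if (level$n == max(comm) && all(comm == seq_along(comm))) break
    }
    new_partition(memb_global, gd$names, g, "louvain", resolution)
  })
}

# resolution-gamma quality on the original graph for a membership vector
membership_quality <- function(gd, memb, resolution) {
  two_m <- 2 * gd$m
  within <- sum(2 * gd$w[memb[gd$i] == memb[gd$j]])
  tot <- tapply(gd$deg, memb, sum)
  within / two_m - resolution * sum((tot / two_m)^2)
}

# One local-moving phase; returns a community id per node (1..n, relabelled
# contiguously).
louvain_one_level <- function(level, resolution) {
  n <- level$n
  # neighbour lists excluding self-loops (a node's own loop moves with it and
  # cancels out of every gain comparison)
  nb <- vector("list", n)
  keep <- level$i != level$j
  ii <- level$i[keep]; jj <- level$j[keep]; ww <- level$w[keep]
  ord <- order(ii)
  nb_j <- split(jj[ord], factor(ii[ord], levels = seq_len(n)))
  nb_w <- split(ww[ord], factor(ii[ord], levels = seq_len(n)))
  ord <- order(jj)
  nb_j2 <- split(ii[ord], factor(jj[ord], levels = seq_len(n)))
  nb_w2 <- split(ww[ord], factor(jj[ord], levels = seq_len(n)))
  for (v in seq_len(n))
    nb[[v]] <- list(j = c(nb_j[[v]], nb_j2[[v]]), w = c(nb_w[[v]], nb_w2[[v]]))

  comm <- seq_len(n)
  tot <- level$deg
  two_m <- 2 * level$m
  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {
      c_old <- comm[v]
      tot[c_old] <- tot[c_old] - level$deg[v]
      cand_comm <- comm[nb[[v]]$j]
      w_vc <- tapply(nb[[v]]$w, cand_comm, sum)
      cands <- as.integer(names(w_vc))
      if (!c_old %in% cands) { cands <- c(cands, c_old); w_vc <- c(w_vc, 0) }
      gain <- w_vc - resolution * level$deg[v] * tot[cands] / two_m
      best <- max(gain)
      pick <- min(cands[gain >= best - 1e-12])
      cur <- gain[match(c_old, cands)]
      if (pick != c_old && best > cur + 1e-12) {
        comm[v] <- pick
        moved <- TRUE
      }
      tot[comm[v]] <- tot[comm[v]] + level$deg[v]
    }
    if (!moved) break
  }
  as.integer(factor(comm))
}

# Aggregate communities into a super-graph: inter-community weights summed,
# intra-community weight (including former loops) becomes a self-loop.
aggregate_level <- function(level, comm) {
  ci <- comm[level$i]; cj <- comm[level$j]
  lo <- pmin(ci, cj); hi <- pmax(ci, cj)
  key <- paste(lo, hi)
  w <- tapply(level$w, key, sum)
  parts <- strsplit(names(w), " ", fixed = TRUE)
  i <- vapply(parts, function(p) as.integer(p[1]), 1L)
  j <- vapply(parts, function(p) as.integer(p[2]), 1L)
  n <- max(comm)
  deg <- numeric(n)
  for (e in seq_along(w)) {
    deg[i[e]] <- deg[i[e]] + w[e]
    deg[j[e]] <- deg[j[e]] + w[e]
  }
  list(i = i, j = j, w = as.numeric(w), deg = deg, n = n, m = sum(w))
}

#' Leading-eigenvector community detection
#'
#' Recursive spectral bisection on the modularity matrix
#' \eqn{B_{ij} = A_{ij} - k_i k_j / (2m)}: each group is split by the sign
#' pattern of the leading eigenvector of its generalized modularity matrix
#' \eqn{B^{(g)}_{ij} = B_{ij} - \delta_{ij} \sum_{k \in g} B_{ik}}. A split is
#' kept only when its leading eigenvalue exceeds the solver tolerance and the
#' split increases total Q; otherwise the group is left indivisible. The
#' eigenvector's sign is fixed by making its largest-magnitude component
#' positive, so the method is fully deterministic.
#'
#' @param g weighted undirected igraph with positive total edge weight.
#' @param max_communities stop splitting once this many communities exist.
#' @param tol eigenvalue tolerance: a leading eigenvalue `<= tol` means the
#'   group is indivisible.
#' @return a `drug_partition`.
#' @export
leading_eigen_communities <- function(g, max_communities = Inf, tol = 1e-9) {
  gd <- graph_data(g)
  if (gd$n == 0) stop("empty graph")
  if (gd$m <= 0) stop("graph has no edge weight")
  n <- gd$n
  A <- matrix(0, n, n)
  for (e in seq_along(gd$w)) {
    if (gd$i[e] == gd$j[e]) {
      A[gd$i[e], gd$i[e]] <- A[gd$i[e], gd$i[e]] + 2 * gd$w[e]
    } else {
      A[gd$i[e], gd$j[e]] <- A[gd$i[e], gd$j[e]] + gd$w[e]
      A[gd$j[e], gd$i[e]] <- A[gd$j[e], gd$i[e]] + gd$w[e]
    }
  }
  two_m <- 2 * gd$m
  B <- A - outer(gd$deg, gd$deg) / two_m
  memb <- rep(1L, n)
  queue <- list(seq_len(n))
  next_label <- 2L
  while (length(queue)) {
    idx <- queue[[1]]
    queue <- queue[-1]
    if (length(idx) < 2 || length(unique(memb)) >= max_communities) next
    Bg <- B[idx, idx, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    es <- eigen(Bg, symmetric = TRUE)
    lead <- es$values[1]
    if (lead <= tol) next
    v <- es$vectors[, 1]
    if (v[which.max(abs(v))] < 0) v <- -v
    s <- ifelse(v >= 0, 1, -1)
    s <- fine_tune_split(Bg, s)
    if (length(unique(s)) < 2) next
    dq <- as.numeric(t(s) %*% Bg %*% s) / (2 * two_m)
    if (dq <= 1e-12) next
    new_idx <- idx[s < 0]
    memb[new_idx] <- next_label
    next_label <- next_label + 1L
    queue <- c(queue, list(idx[s > 0]), list(new_idx))
  }
  new_partition(memb, gd$names, g, "leading_eigenvector")
}

# Kernighan-Lin style fine-tuning of a spectral bipartition (the refinement
# stage of the leading-eigenvector method): repeatedly sweep over all
# vertices, flipping each at most once per sweep in greedy order of the
# modularity change 4 s_i (B s)_i, and keep the best intermediate state.
# Deterministic: ties resolved by vertex index.
fine_tune_split <- function(Bg, s) {
  n <- length(s)
  repeat {
    s0 <- s
    moved <- rep(FALSE, n)
    states <- matrix(0, n, n)
    gains <- numeric(n)
    cur <- s
    cur_q <- as.numeric(t(cur) %*% Bg %*% cur)
    for (step in seq_len(n)) {
      bs <- as.numeric(Bg %*% cur)
      delta <- -4 * cur * bs + 4 * diag(Bg)  # flip vertex i: dq
      delta[moved] <- -Inf
      i <- which.max(delta)
      cur[i] <- -cur[i]
      moved[i] <- TRUE
      cur_q <- cur_q + delta[i]
      states[step, ] <- cur
      gains[step] <- cur_q
    }
    best <- which.max(gains)
    base_q <- as.numeric(t(s0) %*% Bg %*% s0)
    if (gains[best] > base_q + 1e-12) s <- states[best, ] else return(s0)
    if (all(s == s0)) return(s)
  }
}
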