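# Orthogonal minimal spanning trees: iteratively extract edge-disjoint
# MSTs (distance = 1/weight) and keep the union that maximises global
# efficiency minus wiring cost.

graph_from_w <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Minimum spanning tree of a weighted functional graph
#'
#' Spanning tree minimising total distance `d = 1/w` (equivalently
#' maximising total coupling weight) over the available (`w > 0`) edges.
#'
#' @param w symmetric weight matrix with zero diagonal, weights in `[0, 1]`.
#' @return Integer matrix of tree edges, one `(i, j)` row per edge.
#' @export
graph_mst <- function(w) {
  check_weight_matrix(w)
  g <- graph_from_w(w)
  comps <- igraph::components(g)
  if (comps$no > 1L) {
    parts <- split(seq_len(nrow(w)), comps$membership)
    stop("graph disconnected; components: ",
         paste(vapply(parts, function(x) paste0("{", paste(x, collapse = ","), "}"),
                      ""), collapse = " "))
  }
  t <- igraph::mst(g, weights = 1 / igraph::E(g)$weight)
  el <- igraph::as_edgelist(t, names = FALSE)
  matrix(as.integer(el), ncol = 2)
}

check_weight_matrix <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop("w must be a square matrix")
  if (any(abs(w - t(w)) > 1e-12)) stop("w must be symmetric")
  if (any(diag(w) != 0)) stop("w must have a zero diagonal")
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  invisible(w)
}

global_efficiency <- function(w_sel) {
  n <- nrow(w_sel)
  if (n < 2) return(0)
  g <- graph_from_w(w_sel)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d[upper.tri(d)]
  mean(inv)
}

#' Orthogonal-MST topological filter
#'
#' Iteratively extracts edge-disjoint minimum spanning trees (distance
#' `1/w`). After adding the m-th tree, the objective
#' `J_m = GE_m - Cost_m` is evaluated, where `GE` is the mean inverse
#' shortest-path distance over node pairs of the union and `Cost` is the
#' ratio of selected to total edge weight. The union maximising `J` is
#' returned. Extraction stops when the unused edges no longer contain a
#' spanning tree. Disconnected inputs are filtered per connected component.
#'
#' @param w symmetric weight matrix, zero diagonal, weights in `[0, 1]`;
#'   absent (statistically rejected) edges are 0 and ineligible.
#' @return List with `adjacency` (logical matrix of surviving edges),
#'   `trees` (edge matrices of every extracted tree), `J` (objective after
#'   each tree), `n_trees_kept`, `cost` of the selection.
#' @export
omst_filter <- function(w) {
  check_weight_matrix(w)
  n <- nrow(w)
  comps <- igraph::components(graph_from_w(w))
  keep <- matrix(FALSE, n, n)
  trees <- list()
  J_all <- numeric(0)
  total_w <- sum(w) / 2
  for (cid in seq_len(comps$no)) {
    nodes <- which(comps$membership == cid)
    if (length(nodes) < 2) next
    sub <- w[nodes, nodes, drop = FALSE]
    used <- matrix(FALSE, length(nodes), length(nodes))
    sub_trees <- list()
    unions <- list()
    repeat {
      avail <- sub * (!used)
      g <- graph_from_w(avail)
      if (igraph::components(g)$no > 1L) break
      el <- graph_mst(avail)
      for (r in seq_len(nrow(el)))
        used[el[r, 1], el[r, 2]] <- used[el[r, 2], el[r, 1]] <- TRUE
      sub_trees[[length(sub_trees) + 1L]] <- el
      unions[[length(unions) + 1L]] <- used
    }
    if (!length(sub_trees)) next
    J <- vapply(seq_along(unions), function(m) {
      u <- unions[[m]]
      global_efficiency(sub * u) - sum(sub[u]) / 2 / total_w
    }, 0)
    best <- which.max(J)
    J_all <- c(J_all, J)
    u <- unions[[best]]
    keep[nodes, nodes] <- keep[nodes, nodes] | u
    trees <- c(trees, lapply(sub_trees, function(el)
      matrix(nodes[el], ncol = 2)))
  }
  list(adjacency = keep, trees = trees, J = J_all,
       n_trees_kept = if (length(J_all)) which.max(J_all) else 0L,
       cost = sum(w[keep]) / 2 / max(total_w, .Machine$double.eps))
}

#' Apply OMST filtering to a dominant-coupling tensor
#'
#' Per window, builds the significant-strength graph (slot-1 records),
#' runs [omst_filter()] and clears the records of edges that do not
#' survive.
#'
#' @param dicm a `dicm_tensor`.
#' @return The filtered `dicm_tensor` (meta flag `omst = TRUE`).
#' @export
apply_omst <- function(dicm) {
  stopifnot(inherits(dicm, "dicm_tensor"))
  C <- length(dicm$channel_names)
  for (t in seq_len(dicm$n_windows)) {
    w <- matrix(0, C, C)
    has_edge <- FALSE
    for (pi in seq_len(nrow(dicm$pairs))) {
      if (dicm$code[1, t, pi] > 0) {
        a <- dicm$pairs$a[pi]; b <- dicm$pairs$b[pi]
        w[a, b] <- w[b, a] <- min(max(dicm$strength[1, t, pi], 0), 1)
        has_edge <- TRUE
      }
    }
    if (!has_edge) next
    keep <- omst_filter(w)$adjacency
    for (pi in seq_len(nrow(dicm$pairs))) {
      a <- dicm$pairs$a[pi]; b <- dicm$pairs$b[pi]
      if (dicm$code[1, t, pi] > 0 && !keep[a, b]) {
        dicm$est[, t, pi] <- 0
        dicm$code[, t, pi] <- 0
        dicm$strength[, t, pi] <- NA_real_
        dicm$p[, t, pi] <- NA_real_
      }
    }
  }
  dicm$meta$omst <- TRUE
  dicm
}
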