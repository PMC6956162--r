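rand_graph <- function(n, density = 1, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  iu <- which(upper.tri(w))
  keep <- runif(length(iu)) < density
  w[iu[keep]] <- runif(sum(keep), 0.05, 1)
  w <- w + t(w)
  w
}

test_that("MST matches brute-force enumeration on all small graphs", {
  for (i in 1:20) {
    n <- 3 + (i %% 4)
    w <- rand_graph(n, density = 1, seed = i)
    el <- graph_mst(w)
    expect_equal(nrow(el), n - 1)
    expect_equal(sum(1 / w[el]), brute_mst_distance(w), tolerance = 1e-9)
  }
})

test_that("MST handles the triangle, 2-node and star examples", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9; w[1, 3] <- w[3, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.4
  el <- graph_mst(w)
  key <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(key, c("1-2", "1-3"))
  w2 <- matrix(c(0, 0.3, 0.3, 0), 2)
  expect_equal(nrow(graph_mst(w2)), 1)
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- c(0.2, 0.4, 0.6, 0.8)
  el3 <- graph_mst(star)
  expect_equal(nrow(el3), 4)
  expect_true(all(el3 == 1 | el3 > 1))  # all spokes include the hub
  expect_true(all(apply(el3, 1, function(r) 1 %in% r)))
  wd <- matrix(0, 4, 4); wd[1, 2] <- wd[2, 1] <- 0.5
  expect_error(graph_mst(wd), "disconnected")
})

test_that("OMST trees are edge-disjoint spanning trees; first equals the MST", {
  for (i in 1:10) {
    n <- 4 + (i %% 3)
    w <- rand_graph(n, density = 1, seed = 100 + i)
    om <- omst_filter(w)
    mst_d <- brute_mst_distance(w)
    expect_equal(sum(1 / w[om$trees[[1]]]), mst_d, tolerance = 1e-9)
    seen <- character(0)
    for (tr in om$trees) {
      expect_equal(nrow(tr), n - 1)            # spanning tree size
      g <- igraph::graph_from_edgelist(tr, directed = FALSE)
      expect_true(igraph::is_connected(igraph::add_vertices(
        g, max(0, n - igraph::vcount(g)))))
      key <- apply(tr, 1, function(r) paste(sort(r), collapse = "-"))
      expect_length(intersect(key, seen), 0)   # edge-disjoint
      seen <- c(seen, key)
    }
    expect_lte(om$cost, 1)
    # selected union is connected
    g <- igraph::graph_from_adjacency_matrix(om$adjacency, mode = "undirected")
    expect_true(igraph::is_connected(g))
  }
})

test_that("a triangle admits exactly one orthogonal MST", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9; w[1, 3] <- w[3, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.4
  om <- omst_filter(w)
  expect_length(om$trees, 1)
})

test_that("the OMST objective beats single-MST and full-graph alternatives", {
  w <- rand_graph(10, density = 0.9, seed = 7)
  om <- omst_filter(w)
  J_of <- function(mask) {
    sel <- w * mask
    dicmflex:::global_efficiency(sel) - sum(sel) / sum(w)
  }
  mst1 <- matrix(FALSE, 10, 10)
  el <- graph_mst(w)
  for (r in seq_len(nrow(el)))
    mst1[el[r, 1], el[r, 2]] <- mst1[el[r, 2], el[r, 1]] <- TRUE
  expect_gte(max(om$J) + 1e-12, J_of(mst1))
  expect_gte(max(om$J) + 1e-12, J_of(w > 0))
  expect_equal(max(om$J), J_of(om$adjacency), tolerance = 1e-9)
})

test_that("per-window OMST filtering keeps tensors consistent", {
  set.seed(9)
  T <- 6; C <- 5; P <- choose(C, 2)
  cmb <- utils::combn(C, 2)
  est <- code <- strength <- p <- array(0, c(2, T, P))
  code[1, , ] <- 1; est[1, , ] <- 1
  strength[1, , ] <- matrix(runif(T * P, 0.2, 0.9), T, P)
  p[1, , ] <- 0
  dt <- dicm_tensor(est, code, strength, p,
                    data.frame(a = cmb[1, ], b = cmb[2, ]), paste0("ch", 1:C))
  filt <- apply_omst(dt)
  expect_true(all(filt$code[1, , ] %in% c(0, 1)))
  expect_lt(mean(filt$code[1, , ] > 0), 1)      # some edges removed
  expect_gte(min(filt$code[1, , ] %*% rep(1, P)), C - 1)  # stays spanning
})
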