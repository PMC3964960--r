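test_that("identical geometries form a single DS cluster", {
  loops <- geometry_loops(rep(10, 3), rep(50, 3), rep(140, 3), rep(-20, 3))
  r <- ds_cluster(loops)
  expect_length(r$clusters, 1)
  expect_setequal(r$clusters[[1]], loops$loop_id)
  expect_length(r$unclassified, 0)
})

test_that("loops beyond the cutoffs stay unclassified", {
  loops <- geometry_loops(c(1, 20, 40), c(10, 80, 150), c(10, 90, 170),
                          c(-170, -60, 100))
  r <- ds_cluster(loops)
  expect_length(r$clusters, 0)
  expect_setequal(r$unclassified, loops$loop_id)
})

test_that("two well-separated triplets give two DS clusters", {
  loops <- geometry_loops(
    distance = c(10, 10.2, 9.9, 30, 30.1, 29.8),
    hoist = c(50, 51, 49, 120, 121, 119),
    packing = c(140, 141, 139, 40, 41, 39),
    meridian = c(-20, -21, -19, 130, 131, 129)
  )
  r <- ds_cluster(loops)
  o <- ds_oracle(loops, geometry_cutoffs())
  expect_length(r$clusters, 2)
  expect_equal(lapply(r$clusters, sort), lapply(o$clusters, sort))
})

test_that("DS matches the exhaustive densest-neighborhood oracle", {
  cutoffs <- geometry_cutoffs()
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:12, 1)
    loops <- geometry_loops(
      distance = runif(n, 0, 12),
      hoist = runif(n, 0, 180),
      packing = runif(n, 0, 180),
      meridian = runif(n, -180, 180)
    )
    r <- ds_cluster(loops, cutoffs)
    o <- ds_oracle(loops, cutoffs)
    expect_equal(r$clusters, o$clusters, info = paste("seed", seed))
    expect_equal(r$unclassified, o$unclassified, info = paste("seed", seed))
  }
})

test_that("DS refuses mixed lengths or types", {
  loops <- geometry_loops(rep(10, 4), rep(50, 4), rep(140, 4), rep(-20, 4))
  loops$length[1] <- 5L
  expect_error(ds_cluster(loops), "single type and a single length")
})

test_that("length categories cover all lengths with shared boundaries", {
  expect_setequal(length_category(4), c("S", "M"))
  expect_equal(length_category(0), "S")
  expect_equal(length_category(25), "XL")
  expect_setequal(length_category(9), c("M", "L"))
  # every length gets at least one label
  for (l in 0:30) expect_gte(length(length_category(l)), 1)
})

test_that("similarity edges gate on geometry and flank-anchored strings", {
  loops <- geometry_loops(c(10, 10), c(50, 50), c(140, 140), c(-20, -20))
  g <- build_similarity_graph(loops)
  expect_equal(nrow(g), 1)
  expect_equal(g$weight, 1.0)

  # one parameter beyond its cutoff kills the edge
  loops2 <- loops
  loops2$distance[2] <- loops2$distance[1] + 2.5
  expect_equal(nrow(build_similarity_graph(loops2)), 0)

  # cross-length edge: lengths 4 and 5, same flank codes, near geometry
  loops3 <- geometry_loops(c(10, 10.5), c(50, 52), c(140, 141), c(-20, -22))
  loops3$length <- c(4L, 5L)
  loops3$conformation <- c("aabbbbaa", "aabbbbbaa")
  g3 <- build_similarity_graph(loops3)
  expect_equal(nrow(g3), 1)
  expect_true(g3$weight > 0 && g3$weight < 1)

  # flank mismatch kills the edge even with identical geometry
  loops4 <- loops
  loops4$conformation[2] <- sub("^aa", "ab", loops4$conformation[2])
  expect_equal(nrow(build_similarity_graph(loops4)), 0)
})

test_that("MCL separates disjoint triangles like the dense-matrix oracle", {
  tri <- function(p) t(combn(p, 2))
  e <- rbind(tri(c("a1", "a2", "a3")), tri(c("b1", "b2", "b3")))
  g <- tibble::tibble(from = e[, 1], to = e[, 2], weight = 1)
  attr(g, "nodes") <- sort(unique(c(g$from, g$to)))
  r <- mcl(g, min_size = 3)
  expect_length(r$clusters, 2)
  expect_setequal(r$clusters[[1]], c("a1", "a2", "a3"))
  expect_setequal(r$clusters[[2]], c("b1", "b2", "b3"))

  nodes <- attr(g, "nodes")
  adj <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(g))) {
    adj[g$from[k], g$to[k]] <- adj[g$to[k], g$from[k]] <- 1
  }
  oc <- mcl_oracle(adj)
  expect_length(oc, 2)
  expect_setequal(nodes[oc[[1]]], r$clusters[[1]])
  expect_setequal(nodes[oc[[2]]], r$clusters[[2]])
})

test_that("a weak bridge between cliques does not merge them", {
  clique <- function(p) t(combn(p, 2))
  e <- rbind(clique(paste0("a", 1:4)), clique(paste0("b", 1:4)))
  g <- tibble::tibble(from = e[, 1], to = e[, 2], weight = 1)
  g <- dplyr::bind_rows(g, tibble::tibble(from = "a1", to = "b1",
                                          weight = 0.1))
  attr(g, "nodes") <- sort(unique(c(g$from, g$to)))
  r <- mcl(g, min_size = 3)
  expect_length(r$clusters, 2)
  expect_setequal(r$clusters[[1]], paste0("a", 1:4))
  expect_setequal(r$clusters[[2]], paste0("b", 1:4))
})

test_that("single nodes and tiny clusters fall below the minimum size", {
  g <- tibble::tibble(from = character(), to = character(),
                      weight = double())
  attr(g, "nodes") <- "only"
  r <- mcl(g, min_size = 3)
  expect_length(r$clusters, 0)
  expect_equal(r$unclassified, "only")
  r1 <- mcl(g, min_size = 1)
  expect_length(r1$clusters, 1)
})

test_that("columns stay stochastic throughout the MCL iteration", {
  set.seed(21)
  n <- 12
  pairs <- t(combn(sprintf("n%02d", 1:n), 2))
  keep <- runif(nrow(pairs)) < 0.4
  g <- tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2],
                      weight = runif(sum(keep), 0.1, 1))
  attr(g, "nodes") <- sprintf("n%02d", 1:n)
  r <- mcl(g)
  expect_lt(attr(r, "max_colsum_dev"), 1e-12)
})

test_that("MCL clusters never span disconnected graph components", {
  set.seed(33)
  for (trial in 1:10) {
    mk <- function(prefix, n) {
      pairs <- t(combn(paste0(prefix, seq_len(n)), 2))
      keep <- runif(nrow(pairs)) < 0.7
      tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2],
                     weight = runif(sum(keep), 0.3, 1))
    }
    g <- dplyr::bind_rows(mk("x", 5), mk("y", 4))
    attr(g, "nodes") <- sort(unique(c(g$from, g$to)))
    r <- mcl(g, min_size = 2)
    for (cl in r$clusters) {
      pref <- unique(substr(cl, 1, 1))
      expect_length(pref, 1)
    }
  }
})

test_that("planted geometry blobs are recovered exactly by both methods", {
  set.seed(55)
  centers <- list(c(5, 40, 60, -120), c(25, 100, 120, 0),
                  c(45, 160, 30, 120))
  blobs <- lapply(seq_along(centers), function(k) {
    c0 <- centers[[k]]
    geometry_loops(
      distance = c0[1] + rnorm(10, sd = 0.3),
      hoist = c0[2] + rnorm(10, sd = 3),
      packing = c0[3] + rnorm(10, sd = 3),
      meridian = c0[4] + rnorm(10, sd = 5),
      ids = sprintf("B%d_%02d", k, 1:10)
    )
  })
  loops <- dplyr::bind_rows(blobs)
  r_ds <- ds_cluster(loops)
  expect_length(r_ds$clusters, 3)
  for (k in 1:3) {
    cl <- r_ds$clusters[vapply(r_ds$clusters,
                               function(c) any(grepl(paste0("^B", k), c)),
                               TRUE)]
    expect_setequal(cl[[1]], blobs[[k]]$loop_id)
  }
  mem <- cluster_loops(loops)
  mcl_clusters <- split(mem$MCL$loop_id, mem$MCL$cluster)
  expect_length(mcl_clusters, 3)
  for (k in 1:3) {
    cl <- mcl_clusters[vapply(mcl_clusters,
                              function(c) any(grepl(paste0("^B", k), c)),
                              TRUE)]
    expect_setequal(cl[[1]], blobs[[k]]$loop_id)
  }
})
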