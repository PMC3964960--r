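test_that("consensus strings follow the plurality rule", {
  expect_equal(cluster_consensus(rep("aabaa", 3)), "aabaa")
  expect_equal(cluster_consensus(c("aabaa", "aabaa", "aabaa", "aabba")),
               "aabaa")   # 75% > 50% at every disputed position
  expect_equal(cluster_consensus(c("aabaa", "aabaa", "aabba", "aabba")),
               "aabxa")   # 50% is not > 50%
  expect_error(cluster_consensus(character()), "empty")
})

test_that("variable-length members align flank-anchored with centered gaps", {
  # lengths 1 and 3: the short member's single loop code votes at the
  # first loop position, gaps do not vote
  s <- cluster_consensus(c("aabaa", "aabbbaa", "aabbbaa"))
  expect_equal(nchar(s), 7L)
  expect_equal(substr(s, 1, 2), "aa")
  expect_equal(substr(s, 6, 7), "aa")
  expect_equal(substr(s, 3, 3), "b")
})

test_that("consensus geometry uses medians and a circular meridian median", {
  loops <- geometry_loops(c(10, 12, 14), c(50, 55, 60), c(140, 141, 142),
                          c(-20, -25, -30))
  g <- consensus_geometry(loops)
  expect_equal(g$distance, 12)
  expect_equal(g$hoist, 55)
  expect_equal(g$meridian, -25)
  # wrap-aware: {179, -179, 177} has circular median 179
  loops2 <- geometry_loops(rep(10, 3), rep(50, 3), rep(140, 3),
                           c(179, -179, 177))
  expect_equal(consensus_geometry(loops2)$meridian, 179)
  # exhaustive circular-median oracle over the candidates
  vals <- c(179, -179, 177)
  costs <- sapply(vals, function(c) {
    sum(pmin(abs(c - vals), 360 - abs(c - vals)))
  })
  expect_equal(vals[which.min(costs)], 179)
})

test_that("Kabsch superposition recovers exact and transformed copies", {
  set.seed(13)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_kabsch(a, a)$rmsd, 0, tolerance = 1e-12)
  R <- random_rotation_test()
  b <- a %*% t(R) + matrix(rep(c(3, -2, 7), each = 10), 10, 3)
  fit <- superpose_kabsch(a, b)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rotation, R, tolerance = 1e-6)
  # symmetry of the rmsd
  b2 <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
  expect_equal(superpose_kabsch(a, b2)$rmsd, superpose_kabsch(b2, a)$rmsd,
               tolerance = 1e-9)
  # invariance to pre-rotating both sets identically
  Q <- random_rotation_test()
  expect_equal(superpose_kabsch(a %*% t(Q), b2 %*% t(Q))$rmsd,
               superpose_kabsch(a, b2)$rmsd, tolerance = 1e-9)
  expect_error(superpose_kabsch(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose_kabsch(line, line), "collinear")
})

test_that("Kabsch rmsd agrees with bio3d and a rotation-sampling oracle", {
  set.seed(17)
  a <- matrix(rnorm(24, sd = 3), 8, 3)
  b <- a + matrix(rnorm(24, sd = 0.7), 8, 3)
  ours <- superpose_kabsch(a, b)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d prints 3 decimals

  # 4 points, one displaced by 2 A: grid oracle approaches the optimum
  a4 <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  b4 <- a4
  b4[4, ] <- b4[4, ] + c(0, 0, 2)
  opt <- superpose_kabsch(a4, b4)$rmsd
  grid <- rmsd_grid_oracle(a4, b4, n_rot = 20000)
  expect_lte(opt, grid + 1e-9)
  expect_equal(opt, grid, tolerance = 0.02)
})

test_that("subclass RMSD statistics are zero for copies and bounded for noise", {
  s <- hlh_structure(c(-80, -90, -70), c(80, 0, 120))
  base <- loops_from_structures(list(s))
  copies <- dplyr::bind_rows(base, base, base)
  copies$loop_id <- paste0(copies$loop_id, c("_1", "_2", "_3"))
  st <- subclass_rmsd_stats(copies)
  expect_equal(st$rmsd_mean, 0, tolerance = 1e-12)
  expect_equal(st$rmsd_max, 0, tolerance = 1e-12)

  # rigidly moved copies stay at rmsd ~ 0
  set.seed(19)
  moved <- lapply(1:3, function(k) {
    transform_structure(s, random_rotation_test(), rnorm(3, sd = 15))
  })
  lm <- loops_from_structures(moved)
  lm$loop_id <- paste0(lm$loop_id, "_", 1:3)
  st2 <- subclass_rmsd_stats(lm)
  expect_lt(st2$rmsd_max, 1e-6)

  # jittered members have positive but bounded rmsd
  fam <- generate_loop_family(c(-80, -90, -70), c(80, 0, 120), 5, seed = 3)
  lf <- loops_from_structures(fam)
  st3 <- subclass_rmsd_stats(lf)
  expect_gt(st3$rmsd_mean, 0)
  expect_lt(st3$rmsd_mean, 1.5)
})

test_that("hierarchy codes follow the size-then-tie ordering rules", {
  # craft loops and memberships directly
  mk_loops <- function(n, prefix, conf, geom) {
    s <- hlh_structure(c(-80, -90, -70), c(80, 0, 120))
    base <- loops_from_structures(list(s))
    out <- dplyr::bind_rows(lapply(seq_len(n), function(k) base))
    out$loop_id <- sprintf("%s%02d", prefix, seq_len(n))
    out$conformation <- conf
    out$distance <- geom[1]; out$hoist <- geom[2]
    out$packing <- geom[3]; out$meridian <- geom[4]
    out
  }
  l1 <- mk_loops(8, "aa", "aababaa", c(10, 50, 140, -20))
  l2 <- mk_loops(5, "bb", "aababaa", c(20, 90, 60, 100))
  l3 <- mk_loops(3, "cc", "aabbbaa", c(30, 120, 30, 160))
  loops <- dplyr::bind_rows(l1, l2, l3)
  mem <- tibble::tibble(
    method = "DS", type = "HH", bucket = "3",
    cluster = rep(c(1L, 2L, 3L), c(8, 5, 3)),
    loop_id = loops$loop_id
  )
  h <- build_hierarchy(list(DS = mem), loops)
  s <- h$subclasses
  # clusters 1 and 2 share a consensus -> one class with subclasses by size
  expect_equal(s$code[s$n == 8], "DS.HH.3.1.1")
  expect_equal(s$code[s$n == 5], "DS.HH.3.1.2")
  expect_equal(s$code[s$n == 3], "DS.HH.3.2.1")
})

test_that("a single dominant cluster gets the top code", {
  fam <- generate_loop_family(c(-90, 100, -85), c(-5, 20, 110), 4, seed = 2)
  loops <- loops_from_structures(fam)
  # force loop length-1-style minimal case is unnecessary; check format
  mem <- cluster_loops(loops)
  h <- build_hierarchy(mem, loops)
  expect_true(all(grepl("^(DS|MCL)\\.[A-Z]{2}\\.\\d+[SMLX]*\\.\\d+\\.\\d+$",
                        h$subclasses$code)))
  ds <- h$subclasses[h$subclasses$method == "DS", ]
  expect_equal(ds$class, 1L)
  expect_equal(ds$subclass, 1L)
})

test_that("class ordinals resolve ties lexicographically by consensus", {
  s <- hlh_structure(c(-80, -90, -70), c(80, 0, 120))
  base <- loops_from_structures(list(s))
  mk <- function(n, prefix, conf, d) {
    out <- dplyr::bind_rows(lapply(seq_len(n), function(k) base))
    out$loop_id <- sprintf("%s%02d", prefix, seq_len(n))
    out$conformation <- conf
    out$distance <- d
    out
  }
  loops <- dplyr::bind_rows(
    mk(10, "aa", "aababaa", 5),
    mk(7, "bb", "aabbbaa", 30),
    mk(7, "cc", "aabapaa", 60)
  )
  mem <- tibble::tibble(
    method = "DS", type = "HH", bucket = "3",
    cluster = rep(1:3, c(10, 7, 7)),
    loop_id = loops$loop_id
  )
  h <- build_hierarchy(list(DS = mem), loops)
  s <- h$subclasses[order(h$subclasses$class), ]
  expect_equal(s$n, c(10L, 7L, 7L))
  expect_equal(s$class, 1:3)
  # the two 7s: "aabapaa" < "aabbbaa" lexicographically
  expect_equal(s$consensus_conformation[s$class == 2], "aabapaa")
})

test_that("report percentages reproduce published-table arithmetic", {
  counts <- tibble::tibble(
    type = c("BK", "EG"),
    total = c(28418L, 18349L),
    ds_classified = c(11777L, 6950L),
    mcl_classified = c(6054L, 8531L)
  )
  out <- summarize_type_counts(counts)
  expect_equal(out$ds_pct[out$type == "BK"], 41.4)
  expect_equal(out$mcl_pct[out$type == "EG"], 46.5)  # 8531/18349
  expect_equal(out$total[out$type == "All"], 28418L + 18349L)
  # zero classified of a positive total prints 0.0
  z <- summarize_type_counts(tibble::tibble(type = "GG", total = 10L,
                                            ds_classified = 0L,
                                            mcl_classified = 0L))
  expect_equal(z$ds_pct[1], 0)
})

test_that("hierarchy totals conserve the classifiable loops", {
  structs <- planted_families(seed = 4, n_members = 4)
  loops <- loops_from_structures(structs)
  mem <- cluster_loops(loops)
  h <- build_hierarchy(mem, loops)
  classifiable <- loops$loop_id[loops$classifiable]
  for (m in c("DS", "MCL")) {
    codes <- h$subclasses$code[h$subclasses$method == m]
    in_cl <- unique(h$members$loop_id[h$members$code %in% codes])
    un <- h$unclassified$loop_id[h$unclassified$method == m]
    expect_setequal(c(in_cl, un), classifiable)
  }
  # DS memberships are unique; MCL allows at most two
  ds_codes <- h$subclasses$code[h$subclasses$method == "DS"]
  ds_mem <- h$members[h$members$code %in% ds_codes, ]
  expect_false(any(duplicated(ds_mem$loop_id)))
  mcl_mem <- h$members[!h$members$code %in% ds_codes, ]
  expect_lte(max(table(mcl_mem$loop_id)), 2)
})

test_that("tidy and glance summarise a hierarchy", {
  structs <- planted_families(seed = 6, n_members = 3)
  loops <- loops_from_structures(structs)
  h <- build_hierarchy(cluster_loops(loops), loops)
  td <- tidy(h)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("code", "n", "rmsd_mean") %in% names(td)))
  gl <- glance(h)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_subclasses, nrow(td))
})
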