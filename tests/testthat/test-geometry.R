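test_that("axis fitting recovers exact lines and helix axes", {
  ca <- cbind(seq(0, 10, length.out = 5), 0, 0)
  ax <- fit_axis(ca)
  expect_equal(ax$direction, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(ax$origin_start, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ax$origin_end, c(10, 0, 0), tolerance = 1e-12)
  # reversing residue order flips the direction
  expect_equal(fit_axis(ca[5:1, ])$direction, c(-1, 0, 0), tolerance = 1e-12)
  expect_error(fit_axis(ca[1, , drop = FALSE]), "at least 2")

  # all CA of an ideal alpha helix are equidistant from the fitted axis
  s <- generate_synthetic_structure(synthetic_spec(synth_segment("helix", 12)))
  ca <- looparch:::res_coords(s$residues, 1:12)
  ax <- fit_axis(ca)
  d <- apply(ca, 1, function(p) {
    v <- p - ax$origin_start
    sqrt(sum((v - sum(v * ax$direction) * ax$direction)^2))
  })
  expect_lt(diff(range(d)), 0.1)
  expect_equal(mean(d), 2.3, tolerance = 0.1)  # canonical helix radius
})

test_that("the four geometry parameters match a constructed frame", {
  mk <- function(s, e, dir) list(origin_start = s, origin_end = e,
                                 direction = dir)
  # colinear, same sense
  g <- compute_geometry(mk(c(0, 0, 0), c(0, 0, 5), c(0, 0, 1)),
                        mk(c(0, 0, 9), c(0, 0, 14), c(0, 0, 1)))
  expect_equal(g$distance, 4)
  expect_equal(g$hoist, 0)
  expect_equal(g$packing, 0)
  expect_equal(g$meridian, 0)
  # antiparallel
  g2 <- compute_geometry(mk(c(0, 0, 0), c(0, 0, 5), c(0, 0, 1)),
                         mk(c(1, 0, 5), c(1, 0, 0), c(0, 0, -1)))
  expect_equal(g2$packing, 180)
  # independent frame oracle: axis1 = +z, D = +x (10 A), axis2 = +y
  g3 <- compute_geometry(mk(c(0, 0, -5), c(0, 0, 0), c(0, 0, 1)),
                         mk(c(10, 0, 0), c(10, 5, 0), c(0, 1, 0)))
  expect_equal(g3$distance, 10)
  expect_equal(g3$hoist, 90)
  expect_equal(g3$packing, 90)
  expect_equal(g3$meridian, 90)
  expect_error(compute_geometry(mk(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0)),
                                mk(c(1, 0, 0), c(2, 0, 0), c(1, 0, 0))),
               "zero-length")
})

test_that("geometry is invariant under rigid motion", {
  set.seed(101)
  mk <- function(s, e) {
    d <- (e - s) / sqrt(sum((e - s)^2))
    list(origin_start = s, origin_end = e, direction = d)
  }
  a1 <- mk(rnorm(3), rnorm(3) + 3)
  a2 <- mk(rnorm(3) + 8, rnorm(3) + 12)
  g0 <- compute_geometry(a1, a2)
  worst <- 0
  for (k in 1:100) {
    R <- random_rotation_test()
    t <- rnorm(3, sd = 20)
    move <- function(a) {
      list(origin_start = as.numeric(R %*% a$origin_start + t),
           origin_end = as.numeric(R %*% a$origin_end + t),
           direction = as.numeric(R %*% a$direction))
    }
    g <- compute_geometry(move(a1), move(a2))
    worst <- max(worst, abs(g$distance - g0$distance),
                 abs(g$hoist - g0$hoist), abs(g$packing - g0$packing),
                 looparch:::circ_diff(g$meridian, g0$meridian))
  }
  expect_lt(worst, 1e-9)
})

test_that("swapping the axes with D reversed preserves packing and distance", {
  set.seed(7)
  for (k in 1:20) {
    s1 <- rnorm(3); e1 <- s1 + rnorm(3)
    s2 <- rnorm(3) + 6; e2 <- s2 + rnorm(3)
    mk <- function(s, e) list(origin_start = s, origin_end = e,
                              direction = (e - s) / sqrt(sum((e - s)^2)))
    g <- compute_geometry(mk(s1, e1), mk(s2, e2))
    # reverse roles: axis2 seen from its start, D negated
    gr <- compute_geometry(
      list(origin_start = e2, origin_end = s2, direction = mk(s2, e2)$direction),
      list(origin_start = e1, origin_end = s1, direction = mk(s1, e1)$direction)
    )
    expect_equal(gr$distance, g$distance, tolerance = 1e-9)
    expect_equal(gr$packing, g$packing, tolerance = 1e-9)
  }
})

test_that("the Ramachandran partition is total with one code per point", {
  part <- default_ramachandran_partition()
  set.seed(3)
  phis <- c(runif(400, -180, 180), -57, -120, 60, -180 + 1e-9, 180)
  psis <- c(runif(400, -180, 180), -47, 130, 40, 180, -180 + 1e-9)
  for (i in seq_along(phis)) {
    code <- ramachandran_code(phis[i], psis[i], part)
    expect_true(nchar(code) == 1 && code %in% c(part$code, "x"))
  }
  expect_equal(ramachandran_code(-57, -47), "a")
  expect_equal(ramachandran_code(-49, -26), "a")
  expect_equal(ramachandran_code(-120, 130), "b")
  expect_equal(ramachandran_code(60, 40), "l")
  expect_equal(ramachandran_code(NA, 40), "-")
})

test_that("conformation strings cover the loop plus two flank residues", {
  s <- hlh_structure(c(-80, -90, -70), c(80, 0, 120))
  loops <- loops_from_structures(list(s))
  expect_equal(nchar(loops$conformation), loops$length + 4L)
  # flank positions of an ideal helix code as the helical basin
  expect_match(loops$conformation, "^aa.*aa$")

  # zero-length loop: flanks only
  s0 <- generate_synthetic_structure(synthetic_spec(synth_segment("loop", 12)))
  sses <- tibble::tibble(sse_id = 1:2, chain = "A", type = c("E", "H"),
                         start = c(1L, 6L), end = c(5L, 12L),
                         start_resno = c(1L, 6L), end_resno = c(5L, 12L),
                         n = c(5L, 7L))
  l0 <- annotate_loops(extract_loops(s0, sses), s0, sses)
  expect_equal(nchar(l0$conformation), 4L)
})

test_that("the conformation length law holds across generated fixtures", {
  loops <- loops_from_structures(planted_families(seed = 9, n_members = 2))
  expect_true(all(nchar(loops$conformation[loops$classifiable]) ==
                    loops$length[loops$classifiable] + 4L))
})

test_that("loops with undefined dihedrals are flagged non-classifiable", {
  s <- generate_synthetic_structure(synthetic_spec(synth_segment("loop", 10)))
  # SSE right at the chain start: flank residue 1 has no phi
  sses <- tibble::tibble(sse_id = 1:2, chain = "A", type = c("H", "H"),
                         start = c(1L, 7L), end = c(4L, 10L),
                         start_resno = c(1L, 7L), end_resno = c(4L, 10L),
                         n = c(4L, 4L))
  # use n_flank covering residue 1
  l <- annotate_loops(extract_loops(s, sses), s, sses, n_flank = 4)
  expect_false(l$classifiable)
})
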