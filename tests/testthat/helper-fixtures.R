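# Fixtures and independent oracles shared across the test files.
# Everything is generated in code; no binary data.

# Run assignment + smoothing + extraction + annotation over a list of
# structures and bind the loop inventories.
loops_from_structures <- function(structs, n_flank = 2) {
  out <- list()
  for (s in structs) {
    ss <- assign_secondary_structure(s)
    sses <- smooth_assignment(ss, s)
    lp <- suppressMessages(extract_loops(s, sses, attr(ss, "bridges")))
    if (nrow(lp)) out[[length(out) + 1]] <- annotate_loops(lp, s, sses,
                                                           n_flank)
  }
  dplyr::bind_rows(out)
}

# A helix-loop-helix structure with the given loop dihedrals.
hlh_structure <- function(loop_phi, loop_psi, helix_len = 12, id = "hlh") {
  spec <- synthetic_spec(
    synth_segment("helix", helix_len),
    synth_segment("loop", length(loop_phi), phi = loop_phi, psi = loop_psi),
    synth_segment("helix", helix_len),
    id = id
  )
  generate_synthetic_structure(spec)
}

# The three planted helix-loop-helix families used in the recovery tests:
# three geometric blobs (different loop dihedrals and lengths, none at a
# length-category boundary), ten members each, smooth 0.3 A coordinate
# jitter.
planted_families <- function(seed = 1, n_members = 10, amplitude = 0.3) {
  fams <- list(
    generate_loop_family(c(-80, -90, -70), c(80, 0, 120), n_members,
                         amplitude = amplitude, seed = seed,
                         id_prefix = "fa"),
    generate_loop_family(c(60, 75), c(40, 25), n_members,
                         amplitude = amplitude, seed = seed + 100,
                         id_prefix = "fb"),
    generate_loop_family(c(-130, -100, -80, -140, -70),
                         c(150, 130, -10, 20, 140), n_members,
                         amplitude = amplitude, seed = seed + 200,
                         id_prefix = "fc")
  )
  unlist(fams, recursive = FALSE)
}

# Fake annotated loops living directly in geometry space (for clustering
# unit tests that do not need coordinates).
geometry_loops <- function(distance, hoist, packing, meridian,
                           type = "HH", length = 3,
                           conformation = NULL, ids = NULL) {
  n <- base::length(distance)
  if (is.null(conformation)) {
    conformation <- rep(paste0("aa", strrep("b", length), "aa"), n)
  }
  if (is.null(ids)) ids <- sprintf("L%02d", seq_len(n))
  tibble::tibble(
    loop_id = ids, type = type, length = as.integer(length),
    distance = distance, hoist = hoist, packing = packing,
    meridian = meridian,
    conformation = rep_len(conformation, n), classifiable = TRUE
  )
}

# --- independent oracles -------------------------------------------------

# Exhaustive densest-neighborhood clustering oracle: literal, unoptimized
# re-statement of the greedy density-search contract, with its own
# neighborhood code.
ds_oracle <- function(loops, cutoffs, min_size = 3) {
  delta <- function(i, j) {
    c(abs(loops$distance[i] - loops$distance[j]),
      abs(loops$hoist[i] - loops$hoist[j]),
      abs(loops$packing[i] - loops$packing[j]),
      min(abs(loops$meridian[i] - loops$meridian[j]),
          360 - abs(loops$meridian[i] - loops$meridian[j])))
  }
  lims <- c(cutoffs$distance, cutoffs$hoist, cutoffs$packing,
            cutoffs$meridian)
  is_nb <- function(i, j) all(delta(i, j) <= lims)
  active <- seq_len(nrow(loops))
  clusters <- list()
  repeat {
    if (!length(active)) break
    stats <- lapply(active, function(i) {
      nbrs <- active[vapply(active, function(j) j != i && is_nb(i, j), TRUE)]
      mnd <- if (length(nbrs)) {
        mean(vapply(nbrs, function(j) sqrt(sum((delta(i, j) / lims)^2)), 0))
      } else 0
      list(i = i, nbrs = nbrs, count = length(nbrs), mnd = mnd)
    })
    counts <- vapply(stats, `[[`, 0L, "count")
    cand <- stats[counts == max(counts)]
    if (length(cand) > 1) {
      mnds <- vapply(cand, `[[`, 0, "mnd")
      cand <- cand[mnds == min(mnds)]
      if (length(cand) > 1) {
        ids <- vapply(cand, function(s) loops$loop_id[s$i], "")
        cand <- cand[order(ids)]
      }
    }
    seed_ <- cand[[1]]
    members <- c(seed_$i, seed_$nbrs)
    if (length(members) < min_size) break
    clusters[[length(clusters) + 1]] <- sort(loops$loop_id[members])
    active <- setdiff(active, members)
  }
  list(clusters = clusters, unclassified = sort(loops$loop_id[active]))
}

# Minimal independent MCL oracle on a weighted adjacency matrix; clusters
# read as components of the thresholded limit matrix (union of attractor
# rows), ignoring overlap subtleties (used only on clean separable graphs).
mcl_oracle <- function(adj, inflation = 2, iter = 60) {
  diag(adj) <- 1
  m <- adj %*% diag(1 / colSums(adj))
  for (k in seq_len(iter)) {
    m <- m %*% m
    m <- m ^ inflation
    m <- m %*% diag(1 / colSums(m))
    m[m < 1e-8] <- 0
    m <- m %*% diag(1 / colSums(m))
  }
  support <- (m + t(m)) > 0
  comp <- rep(NA_integer_, nrow(adj))
  cur <- 0
  for (v in seq_len(nrow(adj))) {
    if (!is.na(comp[v])) next
    cur <- cur + 1
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cur
      queue <- c(queue, which(support[u, ] & is.na(comp)))
    }
  }
  split(seq_len(nrow(adj)), comp)
}

# Brute-force minimum RMSD over rotations: coarse random sampling of
# axis-angle space followed by Nelder-Mead refinement from the best starts
# (translation handled by centroid alignment). Independent of the SVD route.
rmsd_grid_oracle <- function(a, b, n_rot = 2000, seed = 1) {
  set.seed(seed)
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  rot <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  f <- function(v) sqrt(mean(rowSums((a0 %*% t(rot(v)) - b0)^2)))
  starts <- lapply(seq_len(n_rot), function(k) runif(3, -pi, pi))
  vals <- vapply(starts, f, 0)
  best <- Inf
  for (s in starts[order(vals)][1:5]) {
    opt <- optim(s, f, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, opt$value)
  }
  best
}

random_rotation_test <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Tiny hand-written PDB fixtures -----------------------------------------

two_residue_pdb <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       1.988   1.429   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.250   2.390   0.230  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.310   1.540   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       3.950   2.850   0.100  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.440   2.700   0.400  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       5.950   1.580   0.420  1.00  0.00           O",
    "END")
}

altloc_pdb <- function() {
  c("ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.60  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   9.000   9.000  0.40  0.00           N",
    "ATOM      3  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      4  CA BALA A   1       9.000   9.500   9.000  0.40  0.00           C",
    "ATOM      5  C   ALA A   1       1.988   1.429   0.000  1.00  0.00           C",
    "ATOM      6  O   ALA A   1       1.250   2.390   0.230  1.00  0.00           O",
    "END")
}

dssp_fixture <- function() {
  c("==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A A  H  >        0   0    0",
    "    2    2 A A  T  <        0   0    0",
    "    3    3 A A  G           0   0    0",
    "    4        !              0   0    0",
    "    5    5 A A  E           0   0    0",
    "    6    6 A A  S           0   0    0")
}
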