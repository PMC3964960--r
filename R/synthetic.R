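# Synthetic backbone construction: ideal-geometry chains built from
# per-residue (phi, psi), so the whole pipeline can be exercised on
# structures with known ground truth.

# Ideal backbone internal coordinates (angstrom / degrees).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.5
OMEGA <- 180

CANONICAL_DIHEDRALS <- list(
  helix = c(phi = -57, psi = -47),
  three10 = c(phi = -49, psi = -26),
  strand = c(phi = -120, psi = 120),
  loop = c(phi = -80, psi = 80)
)

#' Describe one segment of a synthetic chain
#'
#' @param kind One of `"helix"` (alpha), `"three10"` (3-10 helix),
#'   `"strand"` (beta) or `"loop"`.
#' @param n Number of residues (>= 1).
#' @param phi,psi Dihedrals in degrees; either scalars recycled over the
#'   segment or length-`n` vectors. `NULL` uses the canonical values for the
#'   segment kind: helix (-57, -47), three10 (-49, -26), strand (-120, 120).
#' @param sequence One-letter amino-acid string of length `n`; default
#'   poly-alanine.
#' @return A segment description for [synthetic_spec()].
#' @export
synth_segment <- function(kind, n, phi = NULL, psi = NULL, sequence = NULL) {
  kind <- match.arg(kind, names(CANONICAL_DIHEDRALS))
  stopifnot(n >= 1)
  if (is.null(phi)) phi <- CANONICAL_DIHEDRALS[[kind]][["phi"]]
  if (is.null(psi)) psi <- CANONICAL_DIHEDRALS[[kind]][["psi"]]
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  if (is.null(sequence)) sequence <- strrep("A", n)
  stopifnot(nchar(sequence) == n)
  list(kind = kind, n = as.integer(n), phi = phi, psi = psi,
       sequence = sequence)
}

#' Specify a synthetic structure
#'
#' @param ... Segments from [synth_segment()], in N-to-C order.
#' @param seed Integer seed for dihedral jitter (ignored when `jitter = 0`).
#' @param jitter Standard deviation, in degrees, of Gaussian noise added to
#'   every phi/psi (>= 0).
#' @param chain Chain identifier.
#' @param id Structure identifier.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(..., seed = 1L, jitter = 0, chain = "A",
                           id = "synt") {
  segments <- list(...)
  if (length(segments) == 1 && is.list(segments[[1]]) &&
      is.null(segments[[1]]$kind)) {
    segments <- segments[[1]]
  }
  if (length(segments) == 0) stop("a synthetic spec needs at least one segment")
  stopifnot(jitter >= 0)
  structure(list(segments = segments, seed = as.integer(seed),
                 jitter = jitter, chain = chain, id = id),
            class = "synthetic_spec")
}

#' Build a structure from a synthetic specification
#'
#' Places backbone atoms sequentially from ideal bond lengths (N-CA 1.458,
#' CA-C 1.525, C-N 1.329 angstrom), ideal bond angles, trans peptide bonds
#' (omega = 180) and the spec's per-residue dihedrals. The same spec and seed
#' always give identical coordinates.
#'
#' @param spec A `synthetic_spec`.
#' @return A `pdb_structure` with computed dihedrals.
#' @export
generate_synthetic_structure <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  phi <- unlist(lapply(spec$segments, `[[`, "phi"))
  psi <- unlist(lapply(spec$segments, `[[`, "psi"))
  seqs <- paste(vapply(spec$segments, `[[`, "", "sequence"), collapse = "")
  n <- length(phi)
  if (spec$jitter > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    phi <- phi + stats::rnorm(n, sd = spec$jitter)
    psi <- psi + stats::rnorm(n, sd = spec$jitter)
  }
  build_backbone(phi, psi, seqs, chain = spec$chain, id = spec$id)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

AA1TO3 <- stats::setNames(names(AA3TO1)[1:20], unname(AA3TO1)[1:20])

# Build an n-residue backbone from phi/psi vectors. phi[1] is unused (no
# preceding residue); psi[n] orients the final carbonyl only.
build_backbone <- function(phi, psi, sequence, chain = "A", id = "synt",
                           resno_start = 1L) {
  n <- length(phi)
  stopifnot(length(psi) == n, nchar(sequence) == n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  th <- deg2rad(ANGLE_N_CA_C)
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                               BOND_C_N, ANGLE_CA_C_N, psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                                BOND_N_CA, ANGLE_C_N_CA, OMEGA)
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                               BOND_CA_C, ANGLE_N_CA_C, phi[i + 1])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANGLE_CA_C_O, psi[i] + 180)
  }
  aa1 <- strsplit(sequence, "")[[1]]
  res <- tibble(
    chain = chain, resno = seq.int(resno_start, length.out = n),
    ins = "", resid = unname(ifelse(is.na(AA1TO3[aa1]), "ALA", AA1TO3[aa1])),
    aa = aa1,
    n_x = N[, 1], n_y = N[, 2], n_z = N[, 3],
    ca_x = CA[, 1], ca_y = CA[, 2], ca_z = CA[, 3],
    c_x = C[, 1], c_y = C[, 2], c_z = C[, 3],
    o_x = O[, 1], o_y = O[, 2], o_z = O[, 3]
  )
  res <- flag_bonded(res)
  atoms <- residue_atom_table(res)
  compute_dihedrals(new_structure(id, res, empty_hetero(), atoms))
}

empty_hetero <- function() {
  tibble(het = character(), group_id = character(), atom = character(),
         x = double(), y = double(), z = double())
}

residue_atom_table <- function(res) {
  out <- list()
  for (at in c("n", "ca", "c", "o")) {
    out[[at]] <- tibble(
      record = "ATOM", chain = res$chain, resno = res$resno, ins = res$ins,
      resid = res$resid, atom = toupper(at),
      x = res[[paste0(at, "_x")]], y = res[[paste0(at, "_y")]],
      z = res[[paste0(at, "_z")]]
    )
  }
  out <- bind_rows(out)
  out[order(match(paste(out$chain, out$resno), paste(res$chain, res$resno))), ]
}

# Merge several single-chain structures into one multi-chain structure.
combine_structures <- function(structures, id = "comb") {
  res <- bind_rows(lapply(structures, function(s) s$residues))
  res <- flag_bonded(res)
  het <- bind_rows(lapply(structures, function(s) s$hetero))
  atoms <- bind_rows(lapply(structures, function(s) s$atoms))
  compute_dihedrals(new_structure(id, res, het, atoms))
}

#' Build an idealized two-chain antiparallel beta sheet
#'
#' Generates two extended strands and rigidly places the second one,
#' antiparallel to the first, by least-squares fitting canonical inter-strand
#' hydrogen-bond distances (O...N about 2.9 angstrom for the bonded pairs).
#' Useful as a fixture for strand-pairing detection.
#'
#' @param n Residues per strand (>= 3).
#' @param chains Chain identifiers for the two strands.
#' @return A two-chain `pdb_structure`.
#' @export
generate_antiparallel_sheet <- function(n = 5, chains = c("A", "B")) {
  stopifnot(n >= 3)
  s1 <- build_backbone(rep(-139, n), rep(135, n), strrep("A", n),
                       chain = chains[1], id = "shet")
  s2 <- build_backbone(rep(-139, n), rep(135, n), strrep("A", n),
                       chain = chains[2], id = "shet")
  # antiparallel pairing: residue i of strand 1 pairs with residue n+1-i of
  # strand 2; in the canonical register, H-bonds O1(i)...N2(j) and
  # N1(i)...O2(j) form on alternating pairs
  pairs <- which(seq_len(n) %% 2 == 1)
  targets <- list()
  for (i in pairs) {
    j <- n + 1 - i
    targets[[length(targets) + 1]] <- list(a = res_atom(s1$residues, i, "o"),
                                           bi = j, batom = "n", d = 2.9)
    targets[[length(targets) + 1]] <- list(a = res_atom(s1$residues, i, "n"),
                                           bi = j, batom = "o", d = 2.9)
  }
  # CA-CA separations of non-bonded pairs kept near 5.2 A to hold the register
  for (i in seq_len(n)) {
    j <- n + 1 - i
    targets[[length(targets) + 1]] <- list(a = res_atom(s1$residues, i, "ca"),
                                           bi = j, batom = "ca", d = 5.2)
  }
  obj <- function(p) {
    rot <- rotation_from_vector(p[1:3])
    dev <- vapply(targets, function(t) {
      b <- rot %*% res_atom(s2$residues, t$bi, t$batom) + p[4:6]
      vnorm(b - t$a) - t$d
    }, 0)
    sum(dev^2)
  }
  best <- NULL
  for (start in list(c(0, pi, 0, 0, 5, 0), c(0, pi, 0, 5, 5, 0),
                     c(0.3, pi, 0, 0, 5, 2))) {
    fit <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  rot <- rotation_from_vector(best$par[1:3])
  s2 <- transform_structure(s2, rot, best$par[4:6])
  combine_structures(list(s1, s2), id = "shet")
}

# Rotation matrix from an axis-angle vector (Rodrigues).
rotation_from_vector <- function(v) {
  th <- vnorm(v)
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply smooth coordinate jitter to a structure
#'
#' Perturbs every atom by a low-frequency random displacement field along the
#' chain, scaled so the per-atom root-mean-square displacement equals
#' `amplitude`. Unlike independent per-atom noise, a smooth field leaves
#' covalent geometry (and hence bonding and secondary structure assignment)
#' intact, which is how coordinate variation between related structures
#' actually behaves. Dihedrals are recomputed.
#'
#' @param x A `pdb_structure`.
#' @param amplitude Per-atom RMS displacement in angstrom.
#' @param seed Integer seed.
#' @param n_modes Number of random sinusoidal modes per axis (default 3).
#' @return The jittered structure.
#' @export
jitter_structure <- function(x, amplitude, seed = 1L, n_modes = 3) {
  if (amplitude <= 0) return(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  res <- x$residues
  n <- nrow(res)
  idx <- seq_len(n)
  field <- sapply(1:3, function(axis) {
    f <- rep(0, n)
    for (k in seq_len(n_modes)) {
      f <- f + stats::rnorm(1) * sin(2 * pi * k * idx / n + stats::runif(1, 0, 2 * pi))
    }
    f
  })
  field <- field * amplitude / sqrt(mean(field^2))
  for (at in c("n", "ca", "c", "o")) {
    for (axis in 1:3) {
      col <- paste0(at, c("_x", "_y", "_z")[axis])
      res[[col]] <- res[[col]] + field[, axis]
    }
  }
  x$residues <- flag_bonded(res)
  x$atoms <- residue_atom_table(x$residues)
  compute_dihedrals(x)
}

#' Generate a planted family of helix-loop-helix structures
#'
#' Builds `n_members` copies of an ideal helix-loop-helix backbone with the
#' given loop dihedrals, each perturbed by smooth coordinate jitter; all
#' members of a family therefore share loop length, conformation string and
#' (up to the jitter) flank geometry, forming one geometric blob.
#'
#' @param loop_phi,loop_psi Loop dihedrals in degrees (equal lengths; the
#'   loop length is `length(loop_phi)`).
#' @param n_members Structures in the family (default 10).
#' @param helix_len Residues per flanking helix (default 12).
#' @param amplitude Coordinate jitter RMS in angstrom (default 0.3).
#' @param seed Integer seed; member k uses `seed + k`.
#' @param id_prefix Structure id prefix (ids are `<prefix><k>`).
#' @return List of `pdb_structure` objects.
#' @export
generate_loop_family <- function(loop_phi, loop_psi, n_members = 10,
                                 helix_len = 12, amplitude = 0.3, seed = 1L,
                                 id_prefix = "fam") {
  stopifnot(length(loop_phi) == length(loop_psi), length(loop_phi) >= 1)
  base <- synthetic_spec(
    synth_segment("helix", helix_len),
    synth_segment("loop", length(loop_phi), phi = loop_phi, psi = loop_psi),
    synth_segment("helix", helix_len)
  )
  lapply(seq_len(n_members), function(k) {
    s <- generate_synthetic_structure(base)
    s$id <- sprintf("%s%02d", id_prefix, k)
    s$residues <- s$residues   # ids propagate via loop_id at extraction
    jitter_structure(s, amplitude, seed = seed + k)
  })
}
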