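# Loop geometry: SSE axis fitting, the four-parameter description of the
# relation between the two flanking SSEs (distance, hoist, packing,
# meridian), and the Ramachandran-alphabet conformation strings.

#' Fit the axis of a secondary structure element
#'
#' For SSEs with at least four residues the axis is the screw axis of the
#' least-squares rigid transform mapping CA(1..n-1) onto CA(2..n): for an
#' ideal helix this is exactly the helix axis (every CA equidistant from it),
#' and for strands it degenerates gracefully to the strand direction. When
#' the inter-residue rotation is negligible or the fit is degenerate, the
#' total-least-squares line through the CA cloud is used instead. For 2-3
#' residues the axis is the line through the first and last CA. The direction
#' is oriented N to C; the endpoints are the projections of the first and
#' last CA onto the axis.
#'
#' @param ca A numeric matrix (n x 3) of CA coordinates in N-to-C order.
#' @return A list with `origin_start`, `origin_end` (angstrom points) and the
#'   unit vector `direction`.
#' @export
fit_axis <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 2) stop("axis fitting needs at least 2 CA atoms")
  axis <- NULL
  if (n >= 4) axis <- screw_axis(ca)
  if (is.null(axis)) {
    ctr <- colMeans(ca)
    v <- if (n >= 4) svd(sweep(ca, 2, ctr))$v[, 1] else ca[n, ] - ca[1, ]
    axis <- list(point = ctr, v = vunit(v))
  }
  v <- axis$v
  if (sum(v * (ca[n, ] - ca[1, ])) < 0) v <- -v
  proj <- function(p) axis$point + sum((p - axis$point) * v) * v
  list(origin_start = proj(ca[1, ]), origin_end = proj(ca[n, ]),
       direction = v)
}

# Screw axis of the least-squares transform CA(1..n-1) -> CA(2..n); NULL when
# the rotation is too small or the superposition is degenerate.
screw_axis <- function(ca) {
  n <- nrow(ca)
  fit <- tryCatch(superpose_kabsch(ca[-n, , drop = FALSE],
                                   ca[-1, , drop = FALSE]),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  R <- fit$rotation
  cosang <- (sum(diag(R)) - 1) / 2
  if (cosang > cos(deg2rad(5))) return(NULL)   # near-pure translation
  e <- eigen(R)
  i <- which(abs(Re(e$values) - 1) < 1e-6 & abs(Im(e$values)) < 1e-6)
  if (!length(i)) return(NULL)
  u <- vunit(Re(e$vectors[, i[1]]))
  t_perp <- fit$translation - sum(u * fit$translation) * u
  p <- tryCatch(qr.solve(diag(3) - R + outer(u, u), t_perp),
                error = function(e) NULL)
  if (is.null(p)) return(NULL)
  list(point = p, v = u)
}

#' Four-parameter geometry of two SSE axes
#'
#' Let D be the vector from the C-terminal end of the first axis to the
#' N-terminal start of the second. Then: `distance` = |D|; `hoist` = angle
#' between the first axis direction and D; `packing` = angle between the two
#' axis directions; `meridian` = signed dihedral from the plane spanned by
#' (axis1 direction, D) to the plane spanned by (axis1 direction, axis2
#' direction), measured right-handed about the first axis direction.
#' Degenerate cases (D of zero length or parallel to axis1, or parallel
#' axes) give meridian 0 by convention. All four values are invariant under
#' rigid motion of the structure.
#'
#' @param axis1,axis2 Axes from [fit_axis()] for the N- and C-terminal flank.
#' @return A named list: `distance` (angstrom, >= 0), `hoist` and `packing`
#'   (degrees in \[0, 180\]), `meridian` (degrees in (-180, 180\]).
#' @export
compute_geometry <- function(axis1, axis2) {
  u1 <- axis1$direction
  u2 <- axis2$direction
  if (vnorm(u1) < 1e-12 || vnorm(u2) < 1e-12) stop("zero-length axis direction")
  D <- axis2$origin_start - axis1$origin_end
  distance <- vnorm(D)
  hoist <- if (distance < 1e-9) 0 else vangle(u1, D)
  packing <- vangle(u1, u2)
  a <- if (distance < 1e-9) c(0, 0, 0) else D - sum(D * u1) * u1
  b <- u2 - sum(u2 * u1) * u1
  meridian <- if (vnorm(a) < 1e-9 || vnorm(b) < 1e-9) 0 else {
    wrap180(rad2deg(atan2(sum(vcross(a, b) * u1), sum(a * b))))
  }
  list(distance = distance, hoist = hoist, packing = packing,
       meridian = meridian)
}

#' Default Ramachandran partition
#'
#' An ordered set of rectangles over the (phi, psi) torus, first match wins,
#' with eight letters: `a` right-handed helical basin (alpha and 3-10), `b`
#' extended/beta basin, `l` left-handed helical basin, `e` positive-phi
#' extended region, `p` the psi band below the beta basin, `g` the bridge
#' column near phi = 0, `t` remaining sparse territory, and `x` as fallback
#' for anything not covered. The exact boundaries are configuration, not
#' code: this set is a documented stand-in tiling, shipped in the default
#' config file.
#'
#' @return Tibble with columns `code`, `phi_min`, `phi_max`, `psi_min`,
#'   `psi_max`; intervals are (min, max].
#' @export
default_ramachandran_partition <- function() {
  tribble_part <- rbind(
    data.frame(code = "a", phi_min = -160, phi_max = -20, psi_min = -90,  psi_max = 50),
    data.frame(code = "b", phi_min = -180, phi_max = -20, psi_min = 50,   psi_max = 180),
    data.frame(code = "b", phi_min = -180, phi_max = -20, psi_min = -180, psi_max = -150),
    data.frame(code = "t", phi_min = -180, phi_max = -160, psi_min = -90, psi_max = 50),
    data.frame(code = "p", phi_min = -180, phi_max = -20, psi_min = -150, psi_max = -90),
    data.frame(code = "g", phi_min = -20,  phi_max = 20,  psi_min = -180, psi_max = 180),
    data.frame(code = "l", phi_min = 20,   phi_max = 160, psi_min = -50,  psi_max = 90),
    data.frame(code = "e", phi_min = 20,   phi_max = 180, psi_min = 90,   psi_max = 180),
    data.frame(code = "e", phi_min = 20,   phi_max = 180, psi_min = -180, psi_max = -90),
    data.frame(code = "t", phi_min = 20,   phi_max = 180, psi_min = -90,  psi_max = -50),
    data.frame(code = "t", phi_min = 160,  phi_max = 180, psi_min = -50,  psi_max = 90)
  )
  as_tibble(tribble_part)
}

#' Encode one (phi, psi) pair as a Ramachandran letter
#'
#' @param phi,psi Dihedrals in degrees in (-180, 180]; NA gives the sentinel
#'   code "-".
#' @param partition Rectangle table as in [default_ramachandran_partition()].
#' @return A single-character code; `x` when no rectangle matches.
#' @export
ramachandran_code <- function(phi, psi,
                              partition = default_ramachandran_partition()) {
  if (is.na(phi) || is.na(psi)) return("-")
  hit <- phi > partition$phi_min & phi <= partition$phi_max &
    psi > partition$psi_min & psi <= partition$psi_max
  if (any(hit)) partition$code[which(hit)[1]] else "x"
}

ramachandran_codes <- function(phi, psi, partition) {
  vapply(seq_along(phi), function(i) ramachandran_code(phi[i], psi[i],
                                                       partition), "")
}

#' Conformation string of a loop
#'
#' Concatenated Ramachandran codes of the last `n_flank` residues of the
#' first flank, the loop residues, and the first `n_flank` residues of the
#' second flank; total length = loop length + 2 * n_flank. Loops with an
#' undefined dihedral anywhere in that range are non-classifiable and get NA.
#'
#' @param structure A `pdb_structure` with dihedrals computed.
#' @param loop One row of the loop inventory (with `loop_rows`,
#'   `flank1_rows`, `flank2_rows` list-columns).
#' @param n_flank Flank residues coded on each side (default 2).
#' @param partition Ramachandran partition.
#' @return The conformation string, or NA if any covered residue lacks phi
#'   or psi.
#' @export
conformation_string <- function(structure, loop, n_flank = 2,
                                partition = default_ramachandran_partition()) {
  rows <- conformation_rows(loop, n_flank)
  res <- structure$residues
  codes <- ramachandran_codes(res$phi[rows], res$psi[rows], partition)
  if (any(codes == "-")) return(NA_character_)
  paste(codes, collapse = "")
}

conformation_rows <- function(loop, n_flank = 2) {
  f1 <- loop$flank1_rows[[1]]
  f2 <- loop$flank2_rows[[1]]
  c(utils::tail(f1, n_flank), loop$loop_rows[[1]], utils::head(f2, n_flank))
}

#' Annotate a loop inventory with geometry and conformation
#'
#' Adds the four geometry parameters (from the fitted flank axes), the
#' conformation string, and a `classifiable` flag to each loop. Loops whose
#' conformation string has undefined positions are flagged non-classifiable.
#'
#' @param loops Loop inventory from [extract_loops()].
#' @param structure The `pdb_structure` the loops came from.
#' @param sses The SSE tibble used for extraction.
#' @param n_flank Flank residues coded on each side (default 2).
#' @param partition Ramachandran partition.
#' @return The inventory with columns `distance`, `hoist`, `packing`,
#'   `meridian`, `conformation`, `classifiable` added.
#' @export
annotate_loops <- function(loops, structure, sses, n_flank = 2,
                           partition = default_ramachandran_partition()) {
  res <- structure$residues
  n <- nrow(loops)
  dist <- hoist <- pack <- merid <- rep(NA_real_, n)
  conf <- rep(NA_character_, n)
  bb <- vector("list", n)
  for (k in seq_len(n)) {
    ax1 <- fit_axis(res_coords(res, loops$flank1_rows[[k]]))
    ax2 <- fit_axis(res_coords(res, loops$flank2_rows[[k]]))
    g <- compute_geometry(ax1, ax2)
    dist[k] <- g$distance; hoist[k] <- g$hoist
    pack[k] <- g$packing; merid[k] <- g$meridian
    conf[k] <- conformation_string(structure, loops[k, ], n_flank, partition)
    rows <- conformation_rows(loops[k, ], n_flank)
    bb[[k]] <- do.call(rbind, lapply(rows, function(i) {
      rbind(res_atom(res, i, "n"), res_atom(res, i, "ca"),
            res_atom(res, i, "c"))
    }))
  }
  loops$bb <- bb
  loops$distance <- dist
  loops$hoist <- hoist
  loops$packing <- pack
  loops$meridian <- merid
  loops$conformation <- conf
  loops$classifiable <- !is.na(conf)
  loops
}
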