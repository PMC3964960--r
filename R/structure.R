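#' @importFrom dplyr %>% filter mutate arrange group_by ungroup summarise select
#'   bind_rows left_join n row_number desc across all_of first distinct slice
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

# Maximum C(i)-N(i+1) distance for two residues to be considered bonded.
BOND_CUTOFF <- 1.9

new_structure <- function(id, residues, hetero, atoms, resolution = NA_real_) {
  structure(
    list(id = id, residues = residues, hetero = hetero, atoms = atoms,
         resolution = resolution),
    class = "pdb_structure"
  )
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf(
    "<pdb_structure %s: %d residues in %d chain(s), %d hetero atoms%s>\n",
    x$id, nrow(x$residues), length(unique(x$residues$chain)),
    nrow(x$hetero),
    if (is.na(x$resolution)) "" else sprintf(", %.2f A", x$resolution)
  ))
  invisible(x)
}

empty_residues <- function() {
  tibble(
    chain = character(), resno = integer(), ins = character(),
    resid = character(), aa = character(),
    n_x = double(), n_y = double(), n_z = double(),
    ca_x = double(), ca_y = double(), ca_z = double(),
    c_x = double(), c_y = double(), c_z = double(),
    o_x = double(), o_y = double(), o_z = double(),
    bonded_next = logical(), phi = double(), psi = double()
  )
}

#' Read a protein structure from PDB text
#'
#' Parses ATOM/HETATM records into a backbone-centric structure object.
#' Alternate locations are resolved to the highest occupancy (ties go to the
#' first occurrence in the file), only the first MODEL of multi-model files is
#' used, and waters are excluded from the hetero-atom table. Residues without
#' a CA atom are dropped with a warning. Consecutive residues are flagged as
#' bonded when their C(i)-N(i+1) distance is at most 1.9 angstrom.
#'
#' @param file Path to a PDB file, or a character vector of PDB-format lines.
#' @param id Structure identifier; defaults to the HEADER id or the file name.
#' @param resolution Resolution in angstrom; parsed from REMARK 2 when absent.
#' @return A `pdb_structure` object with tibbles `residues` (one row per
#'   residue: chain, number, insertion code, amino acid, backbone N/CA/C/O
#'   coordinates, bonded flag, phi/psi placeholders), `hetero` (non-water
#'   HETATM atoms) and `atoms` (every parsed atom, for contact searches).
#' @export
read_structure <- function(file, id = NULL, resolution = NULL) {
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(file))
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    if (is.null(id)) id <- "XXXX"
  }
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr) && nchar(hdr[1]) >= 66) {
    code <- trimws(substr(hdr[1], 63, 66))
    if (nchar(code) == 4) id <- tolower(code)
  }
  if (is.null(resolution)) {
    rem <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
    resolution <- if (length(rem)) {
      suppressWarnings(as.numeric(sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1",
                                      rem[1])))
    } else NA_real_
    if (length(resolution) == 0) resolution <- NA_real_
  }
  # keep the first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1])]

  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records found")
  at <- parse_atom_lines(lines[rec], which(rec))

  # altloc: keep highest occupancy per (chain, resno, ins, record, resid, name)
  at <- at %>%
    group_by(.data$record, .data$chain, .data$resno, .data$ins, .data$resid,
             .data$elety) %>%
    arrange(desc(.data$occ), .data$line, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    arrange(.data$line)

  het <- at %>%
    filter(.data$record == "HETATM", !(.data$resid %in% WATER_NAMES)) %>%
    mutate(group_id = paste0(.data$resid, "_", .data$chain, .data$resno)) %>%
    select(het = "resid", "group_id", atom = "elety", "x", "y", "z")

  prot <- filter(at, .data$record == "ATOM")
  residues <- build_residue_table(prot)
  atoms <- select(at, "record", "chain", "resno", "ins", "resid",
                  atom = "elety", "x", "y", "z")
  compute_dihedrals(new_structure(id, residues, het, atoms, resolution))
}

parse_atom_lines <- function(lines, lineno) {
  f <- function(lo, hi) trimws(substr(lines, lo, hi))
  num <- function(lo, hi, what) {
    s <- substr(lines, lo, hi)
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & trimws(s) != "")
    if (length(bad)) {
      stop(sprintf("unparsable %s field at line %d: '%s'",
                   what, lineno[bad[1]], trimws(s[bad[1]])))
    }
    v
  }
  tibble(
    line = lineno,
    record = trimws(substr(lines, 1, 6)),
    elety = f(13, 16),
    alt = f(17, 17),
    resid = f(18, 20),
    chain = substr(lines, 22, 22),
    resno = as.integer(num(23, 26, "residue number")),
    ins = f(27, 27),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    occ = {
      o <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
      ifelse(is.na(o), 1, o)
    }
  )
}

build_residue_table <- function(prot) {
  if (nrow(prot) == 0) return(empty_residues())
  key <- paste(prot$chain, prot$resno, prot$ins, sep = "\r")
  prot$rkey <- factor(key, levels = unique(key))
  res <- prot %>%
    group_by(.data$rkey) %>%
    summarise(
      chain = first(.data$chain), resno = first(.data$resno),
      ins = first(.data$ins), resid = first(.data$resid),
      n_x = bb(.data, "N", "x"), n_y = bb(.data, "N", "y"),
      n_z = bb(.data, "N", "z"),
      ca_x = bb(.data, "CA", "x"), ca_y = bb(.data, "CA", "y"),
      ca_z = bb(.data, "CA", "z"),
      c_x = bb(.data, "C", "x"), c_y = bb(.data, "C", "y"),
      c_z = bb(.data, "C", "z"),
      o_x = bb(.data, "O", "x"), o_y = bb(.data, "O", "y"),
      o_z = bb(.data, "O", "z"),
      .groups = "drop"
    ) %>%
    select(-"rkey") %>%
    mutate(aa = unname(AA3TO1[.data$resid]),
           aa = ifelse(is.na(.data$aa), "X", .data$aa))
  no_ca <- is.na(res$ca_x)
  if (any(no_ca)) {
    warning(sprintf("dropping %d residue(s) without a CA atom", sum(no_ca)))
    res <- res[!no_ca, ]
  }
  flag_bonded(res)
}

bb <- function(d, name, coord) {
  i <- which(d$elety == name)
  if (length(i) == 0) return(NA_real_)
  d[[coord]][i[1]]
}

flag_bonded <- function(res) {
  n <- nrow(res)
  bonded <- rep(FALSE, max(n, 0))
  if (n > 1) {
    i <- seq_len(n - 1)
    d2 <- (res$c_x[i] - res$n_x[i + 1])^2 +
      (res$c_y[i] - res$n_y[i + 1])^2 +
      (res$c_z[i] - res$n_z[i + 1])^2
    bonded[i] <- !is.na(d2) & d2 <= BOND_CUTOFF^2 &
      res$chain[i] == res$chain[i + 1]
  }
  res$bonded_next <- bonded
  if (!"phi" %in% names(res)) res$phi <- NA_real_
  if (!"psi" %in% names(res)) res$psi <- NA_real_
  res
}

#' Compute backbone dihedral angles
#'
#' Fills the `phi`/`psi` columns of the residue table: phi(i) from
#' C(i-1)-N(i)-CA(i)-C(i) and psi(i) from N(i)-CA(i)-C(i)-N(i+1), in degrees
#' in (-180, 180]. Angles are undefined (NA) across chain breaks and at
#' termini.
#'
#' @param x A `pdb_structure`.
#' @return The structure with phi/psi columns populated.
#' @export
compute_dihedrals <- function(x) {
  res <- x$residues
  n <- nrow(res)
  phi <- psi <- rep(NA_real_, n)
  if (n >= 2) {
    for (i in seq_len(n)) {
      if (i > 1 && res$bonded_next[i - 1] &&
          !anyNA(c(res$c_x[i - 1], res$n_x[i], res$ca_x[i], res$c_x[i]))) {
        phi[i] <- dihedral_angle(
          res_atom(res, i - 1, "c"), res_atom(res, i, "n"),
          res_atom(res, i, "ca"), res_atom(res, i, "c")
        )
      }
      if (i < n && res$bonded_next[i] &&
          !anyNA(c(res$n_x[i], res$ca_x[i], res$c_x[i], res$n_x[i + 1]))) {
        psi[i] <- dihedral_angle(
          res_atom(res, i, "n"), res_atom(res, i, "ca"),
          res_atom(res, i, "c"), res_atom(res, i + 1, "n")
        )
      }
    }
  }
  x$residues$phi <- phi
  x$residues$psi <- psi
  x
}

res_atom <- function(res, i, atom) {
  c(res[[paste0(atom, "_x")]][i],
    res[[paste0(atom, "_y")]][i],
    res[[paste0(atom, "_z")]][i])
}

# n x 3 matrix of one backbone atom over a set of residue rows
res_coords <- function(res, rows, atom = "ca") {
  cbind(res[[paste0(atom, "_x")]][rows],
        res[[paste0(atom, "_y")]][rows],
        res[[paste0(atom, "_z")]][rows])
}

#' Write a structure to a PDB file
#'
#' Backbone atoms (N, CA, C, O) of every residue are written as ATOM records
#' via [bio3d::write.pdb()]; hetero atoms are not written.
#'
#' @param x A `pdb_structure`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(x, file) {
  res <- x$residues
  atoms <- c("n", "ca", "c", "o")
  names_out <- c("N", "CA", "C", "O")
  rows <- list()
  for (i in seq_len(nrow(res))) {
    for (k in seq_along(atoms)) {
      xyz <- res_atom(res, i, atoms[k])
      if (anyNA(xyz)) next
      rows[[length(rows) + 1]] <- tibble(
        elety = names_out[k], resid = res$resid[i], chain = res$chain[i],
        resno = res$resno[i], insert = res$ins[i],
        x = xyz[1], y = xyz[2], z = xyz[3]
      )
    }
  }
  a <- bind_rows(rows)
  ins <- ifelse(a$insert == "", "", a$insert)
  bio3d::write.pdb(
    file = file, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resid, chain = a$chain, insert = ins,
    elety = a$elety
  )
  invisible(file)
}

#' Apply a rigid motion to a structure
#'
#' Rotates every coordinate by `rot` and then translates by `trans`. Used in
#' tests of the rigid-motion invariance of loop geometry, and generally handy
#' for constructing fixtures.
#'
#' @param x A `pdb_structure`.
#' @param rot 3x3 proper rotation matrix.
#' @param trans Length-3 translation vector (angstrom).
#' @return The transformed structure (dihedrals recomputed).
#' @export
transform_structure <- function(x, rot = diag(3), trans = c(0, 0, 0)) {
  res <- x$residues
  for (atom in c("n", "ca", "c", "o")) {
    cols <- paste0(atom, c("_x", "_y", "_z"))
    m <- as.matrix(res[, cols])
    ok <- stats::complete.cases(m)
    m[ok, ] <- sweep(m[ok, , drop = FALSE] %*% t(rot), 2, -trans)
    res[, cols] <- as.data.frame(m)
  }
  x$residues <- res
  if (nrow(x$hetero)) {
    m <- as.matrix(x$hetero[, c("x", "y", "z")])
    x$hetero[, c("x", "y", "z")] <- as.data.frame(sweep(m %*% t(rot), 2, -trans))
  }
  if (nrow(x$atoms)) {
    m <- as.matrix(x$atoms[, c("x", "y", "z")])
    x$atoms[, c("x", "y", "z")] <- as.data.frame(sweep(m %*% t(rot), 2, -trans))
  }
  compute_dihedrals(x)
}
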