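# Secondary structure: reading DSSP output files, an internal hydrogen-bond
# based assigner for when no DSSP file is available, and smoothing of raw
# per-residue letters into secondary structure elements (SSEs).

SSE_MIN_LENGTH <- c(E = 2L, G = 3L, H = 4L)

# Kabsch-Sander electrostatic H-bond model constants
HB_Q1Q2F <- 27.888   # kcal*A/mol
HB_CUTOFF <- -0.5    # kcal/mol

#' Read per-residue secondary structure from DSSP output
#'
#' Parses the per-residue table of a DSSP output file (classic and mkdssp 2.x
#' layouts). Structure-summary letters are reduced to the four-state alphabet
#' used here: H and G kept, E kept, everything else (I, T, S, B, blank)
#' becomes C. Chain-break rows ('!') are preserved as break markers.
#'
#' @param file Path to a DSSP file or a character vector of its lines.
#' @return A tibble with one row per residue (or break marker): `chain`,
#'   `resno`, `ins`, `ss` and logical `brk`.
#' @export
read_dssp <- function(file) {
  lines <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else unlist(strsplit(file, "\n", fixed = TRUE))
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP file: per-residue table header missing")
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(trimws(body)) > 0]
  is_break <- substr(body, 14, 14) == "!"
  resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  ss <- substr(body, 17, 17)
  tibble(
    chain = substr(body, 12, 12),
    resno = resno,
    ins = trimws(substr(body, 11, 11)),
    ss = ifelse(is_break, NA_character_,
                ifelse(ss %in% c("H", "G", "E"), ss, "C")),
    brk = is_break
  )
}

# Map a DSSP table onto a structure's residues; rows are matched by
# (chain, resno, ins); unmatched residues become C. Returns a character
# vector aligned with the residue table.
align_dssp <- function(structure, dssp) {
  res <- structure$residues
  key <- paste(res$chain, res$resno, res$ins, sep = "\r")
  d <- dssp[!dssp$brk, ]
  dkey <- paste(d$chain, d$resno, d$ins, sep = "\r")
  ss <- d$ss[match(key, dkey)]
  ifelse(is.na(ss), "C", ss)
}

#' Assign secondary structure from backbone geometry
#'
#' A Kabsch-Sander style assigner used when no DSSP file is supplied. The
#' amide hydrogen is imputed from the previous residue's carbonyl
#' (H = N + unit(C_prev - O_prev)); a hydrogen bond from the CO of residue i
#' to the NH of residue j is declared when the electrostatic energy
#' `27.888 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` falls below -0.5 kcal/mol.
#' Two consecutive n -> n+4 turns make an alpha-helix (H), two consecutive
#' n -> n+3 turns a 3-10 helix (G), and Kabsch-Sander bridge pairs make
#' strand residues (E); priority H > E > G; everything else is coil.
#'
#' @param structure A `pdb_structure`.
#' @return An object of class `ss_assignment`: a character vector of letters
#'   {H, G, E, C} aligned with the residue table, with a `bridges` attribute
#'   (tibble of paired residue row indices) used for hairpin/link typing.
#' @export
assign_secondary_structure <- function(structure) {
  res <- structure$residues
  n <- nrow(res)
  ss <- rep("C", n)
  hb <- hbond_matrix(res)   # hb[i, j]: CO(i) accepts from NH(j)

  if (n >= 3) {
    # turns: turn_k[i] TRUE when CO(i) bonds NH(i+k) within one bonded stretch
    turn <- function(k) {
      t <- rep(FALSE, n)
      for (i in seq_len(n - k)) {
        if (all(res$bonded_next[i:(i + k - 1)]) && hb[i, i + k]) t[i] <- TRUE
      }
      t
    }
    t4 <- turn(4)
    t3 <- turn(3)
    is_h <- rep(FALSE, n)
    for (i in which(t4)) if (i > 1 && t4[i - 1]) is_h[i:(i + 3)] <- TRUE
    is_g <- rep(FALSE, n)
    for (i in which(t3)) if (i > 1 && t3[i - 1]) is_g[i:(i + 2)] <- TRUE

    br <- find_bridges(res, hb)
    is_e <- rep(FALSE, n)
    if (nrow(br)) is_e[unique(c(br$i, br$j))] <- TRUE

    ss[is_g] <- "G"
    ss[is_e & !is_h] <- "E"
    ss[is_h] <- "H"
    attr(ss, "bridges") <- br
  } else {
    attr(ss, "bridges") <- tibble(i = integer(), j = integer())
  }
  class(ss) <- "ss_assignment"
  ss
}

# n x n logical matrix of Kabsch-Sander hydrogen bonds: hb[i, j] means the
# carbonyl of residue i accepts a bond from the amide of residue j.
hbond_matrix <- function(res) {
  n <- nrow(res)
  hb <- matrix(FALSE, n, n)
  if (n < 2) return(hb)
  # imputed amide H for every residue with a bonded predecessor (except PRO)
  H <- matrix(NA_real_, n, 3)
  for (j in 2:n) {
    if (!res$bonded_next[j - 1] || res$resid[j] == "PRO") next
    cprev <- res_atom(res, j - 1, "c")
    oprev <- res_atom(res, j - 1, "o")
    nj <- res_atom(res, j, "n")
    if (anyNA(c(cprev, oprev, nj))) next
    H[j, ] <- nj + vunit(cprev - oprev)
  }
  for (i in seq_len(n)) {
    Ci <- res_atom(res, i, "c")
    Oi <- res_atom(res, i, "o")
    if (anyNA(c(Ci, Oi))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || anyNA(H[j, ])) next
      Nj <- res_atom(res, j, "n")
      e <- HB_Q1Q2F * (1 / vnorm(Oi - Nj) + 1 / vnorm(Ci - H[j, ]) -
                         1 / vnorm(Oi - H[j, ]) - 1 / vnorm(Ci - Nj))
      hb[i, j] <- e < HB_CUTOFF
    }
  }
  hb
}

# Kabsch-Sander bridge pairs (parallel or antiparallel) between nonadjacent
# residues. hb[i, j]: CO(i) to NH(j).
find_bridges <- function(res, hb) {
  n <- nrow(res)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i + 3) next
      para <- (i > 1 && j < n && hb[i - 1, j] && hb[j, i + 1]) ||
        (j > 1 && i < n && hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
        (i > 1 && j < n && j - 1 > i + 1 && hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (para || anti) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) return(tibble(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  tibble(i = m[, 1], j = m[, 2])
}

#' Smooth a raw assignment into secondary structure elements
#'
#' Maximal runs of identical letters over bonded residues become SSEs only
#' when the run reaches the minimum length for its type (E: 2, G: 3, H: 4
#' residues); shorter runs are relabelled coil. Runs never extend across a
#' chain break.
#'
#' @param assignment Character vector of per-residue letters {H,G,E,C}
#'   aligned with the residue table (an `ss_assignment` or plain vector).
#' @param structure The `pdb_structure` the assignment belongs to.
#' @param min_lengths Named minimum run lengths; default `c(E=2, G=3, H=4)`.
#' @return A tibble of SSEs: `sse_id`, `chain`, `type`, `start`/`end` (row
#'   indices into the residue table), `start_resno`/`end_resno`, `n`.
#' @export
smooth_assignment <- function(assignment, structure,
                              min_lengths = SSE_MIN_LENGTH) {
  res <- structure$residues
  n <- nrow(res)
  letters_ <- as.character(assignment)
  letters_[!letters_ %in% c("H", "G", "E")] <- "C"
  stopifnot(length(letters_) == n)
  # split positions into maximal bonded stretches
  stretch <- cumsum(c(TRUE, !res$bonded_next[-n]))
  out <- list()
  for (s in split(seq_len(n), stretch)) {
    r <- rle(letters_[s])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      type <- r$values[k]
      if (type == "C") next
      if (r$lengths[k] < min_lengths[[type]]) next
      i0 <- s[starts[k]]; i1 <- s[ends[k]]
      out[[length(out) + 1]] <- tibble(
        chain = res$chain[i0], type = type, start = i0, end = i1,
        start_resno = res$resno[i0], end_resno = res$resno[i1],
        n = i1 - i0 + 1L
      )
    }
  }
  sses <- if (length(out)) bind_rows(out) else {
    tibble(chain = character(), type = character(), start = integer(),
           end = integer(), start_resno = integer(), end_resno = integer(),
           n = integer())
  }
  sses <- arrange(sses, .data$start)
  sses$sse_id <- seq_len(nrow(sses))
  select(sses, "sse_id", "chain", "type", "start", "end",
         "start_resno", "end_resno", "n")
}
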