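# Loop extraction: enumerate loops between consecutive SSEs, assign one of
# the ten loop types, and find heteroatom contacts.

LOOP_TYPES <- c("HH", "HE", "EH", "BN", "BK", "EG", "GE", "GH", "HG", "GG")

#' Extract loops between consecutive secondary structure elements
#'
#' One loop per pair of consecutive SSEs on the same chain with no chain
#' break between them. Zero-length loops (directly adjacent SSEs) are
#' included. Loops spanning a chain break, or containing residues that lack
#' backbone atoms, are skipped with a logged reason (a message).
#'
#' @param structure A `pdb_structure`.
#' @param sses SSE tibble from [smooth_assignment()], in chain order.
#' @param bridges Strand-pairing evidence: tibble of residue row-index pairs
#'   (the `bridges` attribute of an `ss_assignment`); used to split beta-beta
#'   loops into hairpins (BN) and links (BK).
#' @return A loop inventory tibble: `loop_id`, `pdb`, `chain`, `type`,
#'   `start`, `end` (residue numbers bracketing the loop), `length`,
#'   `sequence`, plus list-columns `loop_rows`, `flank1_rows`, `flank2_rows`
#'   holding residue row indices, and `flank1`/`flank2` SSE ids.
#' @export
extract_loops <- function(structure, sses, bridges = NULL) {
  res <- structure$residues
  if (is.null(bridges)) bridges <- tibble(i = integer(), j = integer())
  out <- list()
  if (nrow(sses) >= 2) {
    for (k in seq_len(nrow(sses) - 1)) {
      f1 <- sses[k, ]
      f2 <- sses[k + 1, ]
      if (f1$chain != f2$chain) next
      span <- f1$end:(f2$start - 1L)
      if (!all(res$bonded_next[span])) {
        message(sprintf("skipping loop between SSE %d and %d: chain break",
                        f1$sse_id, f2$sse_id))
        next
      }
      loop_rows <- if (f2$start - f1$end > 1L) (f1$end + 1L):(f2$start - 1L)
        else integer()
      bb_cols <- c("n_x", "ca_x", "c_x", "o_x")
      if (length(loop_rows) &&
          anyNA(as.matrix(res[loop_rows, bb_cols]))) {
        message(sprintf("skipping loop between SSE %d and %d: missing backbone",
                        f1$sse_id, f2$sse_id))
        next
      }
      type <- classify_loop_type(f1$type, f2$type,
                                 pairing = flanks_paired(f1, f2, bridges))
      start <- if (length(loop_rows)) res$resno[loop_rows[1]] else
        res$resno[f1$end]
      end <- if (length(loop_rows)) res$resno[loop_rows[length(loop_rows)]]
        else res$resno[f2$start]
      out[[length(out) + 1]] <- tibble(
        loop_id = sprintf("%s_%s_%d-%d", structure$id, f1$chain, start, end),
        pdb = structure$id, chain = f1$chain, type = type,
        start = start, end = end, length = length(loop_rows),
        sequence = paste(res$aa[loop_rows], collapse = ""),
        flank1 = f1$sse_id, flank2 = f2$sse_id,
        loop_rows = list(loop_rows),
        flank1_rows = list(f1$start:f1$end),
        flank2_rows = list(f2$start:f2$end)
      )
    }
  }
  if (!length(out)) {
    return(tibble(
      loop_id = character(), pdb = character(), chain = character(),
      type = character(), start = integer(), end = integer(),
      length = integer(), sequence = character(), flank1 = integer(),
      flank2 = integer(), loop_rows = list(), flank1_rows = list(),
      flank2_rows = list()
    ))
  }
  bind_rows(out)
}

# TRUE when any bridge pair connects the residue ranges of the two SSEs
flanks_paired <- function(f1, f2, bridges) {
  if (nrow(bridges) == 0) return(FALSE)
  in1 <- function(v) v >= f1$start & v <= f1$end
  in2 <- function(v) v >= f2$start & v <= f2$end
  any((in1(bridges$i) & in2(bridges$j)) | (in1(bridges$j) & in2(bridges$i)))
}

#' Classify a loop by its flanking SSE types
#'
#' Non beta-beta pairs map positionally (first letter = N-terminal flank):
#' HH, HE, EH, EG, GE, GH, HG, GG. A beta-beta pair is a hairpin (BN) when
#' the two strands share at least one main-chain bridge hydrogen-bond pair,
#' and a link (BK) otherwise. Ten codes in total.
#'
#' @param type1,type2 Flank SSE types, each one of "H", "G", "E".
#' @param pairing Logical: do the two strands share a bridge? Only consulted
#'   for E-E pairs.
#' @return One of the ten loop type codes.
#' @export
classify_loop_type <- function(type1, type2, pairing = FALSE) {
  if (!type1 %in% c("H", "G", "E") || !type2 %in% c("H", "G", "E")) {
    stop("flank types must be H, G or E")
  }
  if (type1 == "E" && type2 == "E") {
    return(if (isTRUE(pairing)) "BN" else "BK")
  }
  paste0(type1, type2)
}

#' Find heteroatom contacts of loops
#'
#' Reports, per loop and hetero group, the minimum atom-atom distance between
#' any atom of the group and any atom of the loop residues, keeping contacts
#' strictly closer than `cutoff`. Waters are excluded already at parse time.
#'
#' @param structure A `pdb_structure`.
#' @param loops Loop inventory from [extract_loops()].
#' @param cutoff Contact distance cutoff in angstrom (default 6).
#' @return Tibble: `loop_id`, `het`, `group_id`, `atom` (closest hetero
#'   atom), `distance`.
#' @export
find_hetero_contacts <- function(structure, loops, cutoff = 6.0) {
  het <- structure$hetero
  empty <- tibble(loop_id = character(), het = character(),
                  group_id = character(), atom = character(),
                  distance = double())
  if (nrow(het) == 0 || nrow(loops) == 0) return(empty)
  res <- structure$residues
  at <- structure$atoms
  out <- list(empty)
  for (k in seq_len(nrow(loops))) {
    rows <- loops$loop_rows[[k]]
    if (!length(rows)) next
    keys <- paste(res$chain[rows], res$resno[rows], res$ins[rows])
    la <- at[at$record == "ATOM" &
               paste(at$chain, at$resno, at$ins) %in% keys, ]
    if (nrow(la) == 0) next
    lm <- as.matrix(la[, c("x", "y", "z")])
    for (g in unique(het$group_id)) {
      hm <- het[het$group_id == g, ]
      d2 <- outer(rowSums(lm^2), rowSums(as.matrix(hm[, c("x", "y", "z")])^2),
                  "+") - 2 * lm %*% t(as.matrix(hm[, c("x", "y", "z")]))
      mind <- sqrt(max(0, min(d2)))
      if (mind < cutoff) {
        idx <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
        out[[length(out) + 1]] <- tibble(
          loop_id = loops$loop_id[k], het = hm$het[1], group_id = g,
          atom = hm$atom[idx[2]], distance = mind
        )
      }
    }
  }
  bind_rows(out)
}
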