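# Non-redundant chain selection: resolution filter plus greedy sequence
# identity clustering (global alignment, match 1 / mismatch 0 / gap -1).

#' Select non-redundant chains
#'
#' Chains with resolution worse than `max_resolution` are removed. The
#' remaining chains are scanned longest sequence first (ties keep the input
#' order) and a chain is discarded when its global pairwise identity
#' (matches / alignment length, Needleman-Wunsch with match 1, mismatch 0,
#' gap -1) with any already-kept chain reaches `identity_threshold`. The
#' result is deterministic given the input order.
#'
#' @param metadata Data frame with columns `chain_id`, `resolution`
#'   (angstrom, numeric) and `sequence` (one-letter amino acids).
#' @param max_resolution Resolution cutoff in angstrom (default 2.5).
#' @param identity_threshold Identity fraction at or above which a chain is
#'   redundant (default 0.40).
#' @return Character vector of kept chain ids.
#' @export
select_chains <- function(metadata, max_resolution = 2.5,
                          identity_threshold = 0.40) {
  if (nrow(metadata) == 0) return(character())
  stopifnot(all(nchar(metadata$sequence) > 0))
  md <- metadata[metadata$resolution <= max_resolution, , drop = FALSE]
  if (nrow(md) == 0) return(character())
  md <- md[order(-nchar(md$sequence)), , drop = FALSE]
  kept <- character()
  kept_seq <- character()
  for (i in seq_len(nrow(md))) {
    s <- md$sequence[i]
    redundant <- FALSE
    for (k in kept_seq) {
      if (sequence_identity(s, k) >= identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) {
      kept <- c(kept, md$chain_id[i])
      kept_seq <- c(kept_seq, s)
    }
  }
  kept
}

#' Global sequence identity
#'
#' Needleman-Wunsch global alignment (via Biostrings) with match 1,
#' mismatch 0 and linear gap penalty -1; identity is the number of identical
#' aligned positions divided by the alignment length (gaps included).
#'
#' @param a,b Sequences (character scalars).
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  alpha <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  mat <- matrix(0, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
  diag(mat) <- 1
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1
  )
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  pv <- strsplit(ap, "")[[1]]
  sv <- strsplit(as_, "")[[1]]
  sum(pv == sv & pv != "-") / length(pv)
}
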