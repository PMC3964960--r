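# Pipeline configuration: one structured file holds every threshold, with
# the documented defaults built in code and mirrored in
# inst/extdata/default_config.yaml.

#' Default pipeline configuration
#'
#' @return Named list: `resolution_cutoff` (2.5 angstrom),
#'   `identity_threshold` (0.40), `sse_min` (E 2, G 3, H 4), `n_flank` (2),
#'   `hetero_cutoff` (6 angstrom), `ramachandran` (rectangle table),
#'   `cutoffs`, `kernel_widths`, `ds` and `mcl` parameter lists,
#'   `length_categories`, `consensus_threshold` (0.5) and `seed`.
#' @export
default_config <- function() {
  cutoffs <- geometry_cutoffs()
  list(
    resolution_cutoff = 2.5,
    identity_threshold = 0.40,
    sse_min = list(E = 2L, G = 3L, H = 4L),
    n_flank = 2L,
    hetero_cutoff = 6.0,
    ramachandran = default_ramachandran_partition(),
    cutoffs = cutoffs,
    kernel_widths = kernel_widths(cutoffs),
    ds = list(min_cluster_size = 3L),
    mcl = c(mcl_params(), list(min_cluster_size = 3L)),
    length_categories = default_length_categories(),
    consensus_threshold = 0.5,
    seed = 1L
  )
}

#' Read a configuration file
#'
#' Loads a YAML configuration and overlays it on the defaults. Unknown keys
#' (at the top level or inside a parameter block) are rejected.
#'
#' @param file Path to a YAML config file.
#' @return A config list as in [default_config()].
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  cfg <- default_config()
  merge_block <- function(base, new, path) {
    unknown <- setdiff(names(new), names(base))
    if (length(unknown)) {
      stop(sprintf("unknown config key(s): %s",
                   paste0(path, unknown, collapse = ", ")))
    }
    for (k in names(new)) {
      if (is.list(base[[k]]) && !is.data.frame(base[[k]]) &&
          is.list(new[[k]])) {
        base[[k]] <- merge_block(base[[k]], new[[k]], paste0(path, k, "."))
      } else if (is.data.frame(base[[k]])) {
        base[[k]] <- as_tibble(do.call(rbind.data.frame, new[[k]]))
      } else {
        base[[k]] <- new[[k]]
      }
    }
    base
  }
  out <- merge_block(cfg, raw, "")
  # YAML has no Inf literal; very large category bounds mean unbounded
  if (!is.null(out$length_categories$max)) {
    out$length_categories$max[out$length_categories$max >= 1e9] <- Inf
  }
  out$sse_min <- lapply(out$sse_min, as.integer)
  out
}
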