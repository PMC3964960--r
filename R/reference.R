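# Published per-type loop counts shipped with the package.

#' Published per-type loop counts
#'
#' The per-type totals and per-method classified counts of the full-PDB
#' loop classification release this package re-implements (ArchDB 2014).
#' Shipped as plain text in `inst/extdata/archdb2014_types.tsv` and used to
#' check the report arithmetic; the counts themselves depend on a 2013 PDB
#' snapshot and are inputs here, not outputs.
#'
#' @return Tibble: `type`, `description`, `total`, `ds_classified`,
#'   `mcl_classified`.
#' @export
reference_type_counts <- function() {
  f <- system.file("extdata", "archdb2014_types.tsv", package = "looparch",
                   mustWork = TRUE)
  as_tibble(utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE))
}
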