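# End-to-end pipeline: structures in, tab-formatted classification out.

#' Run the full classification pipeline
#'
#' Executes every stage in order: chain selection (when metadata is given),
#' secondary structure assignment (DSSP files when supplied, otherwise the
#' internal assigner) and smoothing, loop extraction and typing, geometry and
#' conformation annotation, DS and MCL clustering, hierarchy construction and
#' report generation. Writes `loops.tsv`, `clusters_ds.tsv`,
#' `clusters_mcl.tsv`, `classification.tsv`, `summary_by_type.tsv`,
#' `summary_by_length.tsv` and `run_summary.yaml` into `out_dir`. Stage
#' counts and every dropped entity are logged via `message()`.
#'
#' @param structures Character vector of PDB file paths, or a list of
#'   `pdb_structure` objects.
#' @param dssp Optional named character vector of DSSP file paths, named by
#'   structure id.
#' @param metadata Optional chain metadata (chain_id, resolution, sequence)
#'   for the redundancy filter; chains not selected are dropped.
#' @param config Configuration list from [default_config()] /
#'   [read_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the loop inventory, memberships, hierarchy
#'   and report.
#' @export
run_pipeline <- function(structures, dssp = NULL, metadata = NULL,
                         config = default_config(), out_dir) {
  if (length(structures) == 0) stop("no input structures",
                                    call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  if (is.character(structures)) {
    structures <- lapply(structures, read_structure)
  }
  message(sprintf("read %d structure(s)", length(structures)))

  if (!is.null(metadata)) {
    keep <- select_chains(metadata, config$resolution_cutoff,
                          config$identity_threshold)
    message(sprintf("chain selection kept %d of %d chain(s)",
                    length(keep), nrow(metadata)))
    structures <- lapply(structures, function(s) {
      key <- paste0(s$id, "_", s$residues$chain)
      s$residues <- s$residues[key %in% keep, , drop = FALSE]
      if (nrow(s$residues)) s$residues <- flag_bonded(s$residues)
      s
    })
    structures <- Filter(function(s) nrow(s$residues) > 0, structures)
  }

  all_loops <- list()
  min_lengths <- unlist(config$sse_min)
  for (s in structures) {
    ss <- if (!is.null(dssp) && s$id %in% names(dssp)) {
      align_dssp(s, read_dssp(dssp[[s$id]]))
    } else {
      assign_secondary_structure(s)
    }
    sses <- smooth_assignment(ss, s, min_lengths)
    loops <- extract_loops(s, sses, attr(ss, "bridges"))
    if (nrow(loops) == 0) next
    loops <- annotate_loops(loops, s, sses, config$n_flank,
                            config$ramachandran)
    all_loops[[length(all_loops) + 1]] <- loops
  }
  loops <- if (length(all_loops)) bind_rows(all_loops) else
    tibble(loop_id = character())
  n_classifiable <- if ("classifiable" %in% names(loops)) {
    sum(loops$classifiable)
  } else 0L
  message(sprintf("extracted %d loop(s), %d classifiable",
                  nrow(loops), n_classifiable))
  if (n_classifiable == 0) {
    write_classification_empty(file.path(out_dir, "classification.tsv"))
    stop_no_loops()
  }

  memberships <- cluster_loops(
    loops, config$cutoffs, config$kernel_widths,
    ds_min = config$ds$min_cluster_size,
    mcl_min = config$mcl$min_cluster_size,
    params = config$mcl[names(mcl_params())],
    categories = config$length_categories, n_flank = config$n_flank
  )
  message(sprintf("DS: %d memberships; MCL: %d memberships",
                  nrow(memberships$DS), nrow(memberships$MCL)))
  hierarchy <- build_hierarchy(memberships, loops,
                               threshold = config$consensus_threshold,
                               n_flank = config$n_flank,
                               categories = config$length_categories)
  report <- classification_report(hierarchy, loops)

  write_loop_inventory(loops, file.path(out_dir, "loops.tsv"))
  write_memberships(memberships$DS, file.path(out_dir, "clusters_ds.tsv"))
  write_memberships(memberships$MCL, file.path(out_dir, "clusters_mcl.tsv"))
  write_classification(hierarchy, loops,
                       file.path(out_dir, "classification.tsv"))
  write_tsv_plain(report$by_type, file.path(out_dir, "summary_by_type.tsv"))
  write_tsv_plain(report$by_length,
                  file.path(out_dir, "summary_by_length.tsv"))
  yaml::write_yaml(
    list(structures = length(structures), loops = nrow(loops),
         classifiable = sum(loops$classifiable),
         ds_subclasses = sum(hierarchy$subclasses$method == "DS"),
         mcl_subclasses = sum(hierarchy$subclasses$method == "MCL")),
    file.path(out_dir, "run_summary.yaml")
  )
  invisible(list(loops = loops, memberships = memberships,
                 hierarchy = hierarchy, report = report))
}

stop_no_loops <- function() {
  cond <- structure(
    class = c("looparch_no_loops", "error", "condition"),
    list(message = "no classifiable loops in input", call = NULL)
  )
  stop(cond)
}

write_classification_empty <- function(file) {
  utils::write.table(
    empty_subclasses()[, 0][FALSE, ], file, sep = "\t", quote = FALSE,
    row.names = FALSE
  )
}

#' Write the loop inventory as a tab-separated file
#'
#' @param loops Loop inventory (annotated or not).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_loop_inventory <- function(loops, file) {
  cols <- intersect(
    c("loop_id", "pdb", "chain", "type", "start", "end", "length",
      "sequence", "distance", "hoist", "packing", "meridian",
      "conformation", "classifiable"),
    names(loops)
  )
  out <- loops[, cols]
  for (cc in intersect(c("distance", "hoist", "packing", "meridian"), cols)) {
    out[[cc]] <- sprintf(if (cc == "distance") "%.2f" else "%.1f", out[[cc]])
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

write_memberships <- function(m, file) {
  utils::write.table(m, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

write_tsv_plain <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}
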