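# Assembling clusters into the type -> length -> class -> subclass hierarchy
# with size-ranked codes, consensus conformation/geometry and RMSD quality
# statistics.

GAP <- "-"

# Align a conformation string to a common loop length: flank codes stay
# anchored, the loop region is padded with centered gaps. Returns the padded
# code vector and the map from aligned position to residue ordinal (NA at
# gaps).
align_conformation <- function(s, target_loop_len, n_flank = 2) {
  v <- strsplit(s, "")[[1]]
  len <- length(v) - 2 * n_flank
  stopifnot(len >= 0, target_loop_len >= len)
  gaps <- target_loop_len - len
  left <- ceiling(len / 2)
  codes <- c(v[seq_len(n_flank)],
             v[n_flank + seq_len(left)],
             rep(GAP, gaps),
             if (len > left) v[(n_flank + left + 1):(n_flank + len)],
             v[(length(v) - n_flank + 1):length(v)])
  map <- c(seq_len(n_flank),
           n_flank + seq_len(left),
           rep(NA_integer_, gaps),
           if (len > left) (n_flank + left + 1):(n_flank + len),
           (length(v) - n_flank + 1):length(v))
  list(codes = codes, map = map)
}

#' Consensus conformation of a cluster
#'
#' Members are aligned positionally (anchored at both flanks, gaps centered
#' in the loop region for shorter members); at each aligned position the code
#' supported by more than `threshold` of the voting members (gaps do not
#' vote) becomes the consensus, otherwise the wildcard `x`.
#'
#' @param strings Conformation strings of the cluster members.
#' @param threshold Plurality threshold (fraction, default 0.5).
#' @param n_flank Flank residues coded each side (default 2).
#' @return The consensus string (length = longest member).
#' @export
cluster_consensus <- function(strings, threshold = 0.5, n_flank = 2) {
  if (length(strings) == 0) stop("empty cluster")
  lens <- nchar(strings) - 2 * n_flank
  lmax <- max(lens)
  aligned <- lapply(strings, align_conformation, target_loop_len = lmax,
                    n_flank = n_flank)
  mat <- do.call(rbind, lapply(aligned, `[[`, "codes"))
  apply_consensus <- function(col) {
    col <- col[col != GAP]
    if (length(col) == 0) return("x")
    tab <- table(col)
    top <- names(tab)[which.max(tab)]
    if (tab[[top]] / length(col) > threshold) top else "x"
  }
  paste(apply(mat, 2, apply_consensus), collapse = "")
}

#' Consensus geometry of a cluster
#'
#' Component-wise medians for distance, hoist and packing; a circular median
#' for the meridian (the member value minimizing the summed circular
#' distance, ties resolved toward the circular mean).
#'
#' @param loops Tibble of cluster members with the four geometry columns.
#' @return Named list (distance, hoist, packing, meridian).
#' @export
consensus_geometry <- function(loops) {
  stopifnot(nrow(loops) > 0)
  med <- circular_median(loops$meridian)
  list(distance = stats::median(loops$distance),
       hoist = stats::median(loops$hoist),
       packing = stats::median(loops$packing),
       meridian = med)
}

circular_median <- function(x) {
  if (length(x) == 1) return(x)
  cost <- vapply(x, function(c) sum(circ_diff(c, x)), 0)
  cand <- x[cost == min(cost)]
  if (length(cand) == 1) return(cand)
  cm <- rad2deg(atan2(mean(sin(deg2rad(x))), mean(cos(deg2rad(x)))))
  cand[which.min(circ_diff(cand, cm))]
}

#' Optimal rigid superposition of two point sets
#'
#' Kabsch least-squares superposition (proper rotation only; reflections are
#' excluded via the determinant correction). The returned transform maps
#' `a` onto `b`: x -> R x + t.
#'
#' @param a,b Matched coordinate matrices (n x 3, n >= 3, not collinear).
#' @return List with `rotation` (3x3), `translation` (length 3) and `rmsd`
#'   (angstrom) after the transform.
#' @export
superpose_kabsch <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3, ncol(b) == 3)
  if (nrow(a) != nrow(b)) stop("point sets must have equal size")
  if (nrow(a) < 3) stop("superposition needs at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(t(a0) %*% b0)
  if (s$d[2] < 1e-9 * max(s$d[1], 1)) stop("degenerate (collinear) point set")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- a0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  list(rotation = R, translation = as.numeric(cb - R %*% ca), rmsd = rmsd)
}

# Backbone (N, CA, C) coordinates for the aligned positions of one member;
# keep is a logical over aligned positions.
member_bb_coords <- function(bb, map, keep) {
  rows <- map[keep]
  idx <- as.vector(rbind(3 * rows - 2, 3 * rows - 1, 3 * rows))
  bb[idx, , drop = FALSE]
}

#' RMSD quality statistics of a subclass
#'
#' Members are put in correspondence over their aligned positions (flank
#' anchors plus centered loop alignment; positions where either member has a
#' gap are skipped), using the N, CA and C atoms of each aligned residue. The
#' medoid is the member minimizing the summed pairwise RMSD; the statistics
#' are taken over every other member's superposition onto the medoid.
#'
#' @param members Tibble with `loop_id`, `conformation` and a `bb`
#'   list-column of (3 * residues) x 3 backbone coordinate matrices covering
#'   the flank anchors and loop residues.
#' @param n_flank Flank residues each side (default 2).
#' @return List: `rmsd_mean`, `rmsd_max`, `medoid` (loop id) and `pairs`
#'   (tibble loop_id, rmsd_to_medoid).
#' @export
subclass_rmsd_stats <- function(members, n_flank = 2) {
  m <- nrow(members)
  stopifnot(m >= 1)
  lens <- nchar(members$conformation) - 2 * n_flank
  lmax <- max(lens)
  maps <- lapply(members$conformation, function(s) {
    align_conformation(s, lmax, n_flank)$map
  })
  pr <- function(i, j) {
    keep <- !is.na(maps[[i]]) & !is.na(maps[[j]])
    superpose_kabsch(member_bb_coords(members$bb[[i]], maps[[i]], keep),
                     member_bb_coords(members$bb[[j]], maps[[j]], keep))$rmsd
  }
  rm <- matrix(0, m, m)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) rm[i, j] <- rm[j, i] <- pr(i, j)
    }
  }
  tot <- rowSums(rm)
  med <- which(tot == min(tot))
  med <- med[order(members$loop_id[med])][1]
  others <- setdiff(seq_len(m), med)
  pairs <- tibble(loop_id = members$loop_id[others],
                  rmsd_to_medoid = rm[others, med])
  list(rmsd_mean = if (length(others)) mean(pairs$rmsd_to_medoid) else 0,
       rmsd_max = if (length(others)) max(pairs$rmsd_to_medoid) else 0,
       medoid = members$loop_id[med], pairs = pairs)
}

#' Build the type/length/class/subclass hierarchy
#'
#' Places every cluster under (method, type, length), the length level being
#' the shortest member length; for MCL clusters whose shortest length sits on
#' a category boundary the length label carries the category suffix (e.g.
#' "4S", "4M"). Clusters with identical consensus strings within one
#' (type, length) merge into a class. Classes are numbered from 1 by
#' descending total membership (ties: lexicographic consensus string) and
#' subclasses within a class by descending size (ties: smallest member id),
#' yielding codes `METHOD.TYPE.LENGTH.CLASS.SUBCLASS`.
#'
#' @param memberships Result of [cluster_loops()].
#' @param loops The annotated loop inventory (with `bb` list-column for RMSD
#'   statistics; see [annotate_loops()]).
#' @param threshold Consensus plurality threshold (default 0.5).
#' @param n_flank Flank residues each side (default 2).
#' @param categories Length category table (for boundary suffixes).
#' @return A `loop_hierarchy`: list with tibbles `subclasses`, `members` and
#'   `unclassified`.
#' @export
build_hierarchy <- function(memberships, loops, threshold = 0.5, n_flank = 2,
                            categories = default_length_categories()) {
  sub_rows <- list()
  mem_rows <- list()
  for (method in c("DS", "MCL")) {
    mt <- memberships[[method]]
    if (is.null(mt) || nrow(mt) == 0) next
    keys <- unique(mt[, c("type", "bucket", "cluster")])
    clusters <- list()
    for (r in seq_len(nrow(keys))) {
      ids <- mt$loop_id[mt$type == keys$type[r] & mt$bucket == keys$bucket[r] &
                          mt$cluster == keys$cluster[r]]
      mem <- loops[match(ids, loops$loop_id), ]
      lmin <- min(mem$length)
      label <- as.character(lmin)
      if (method == "MCL" &&
          length(length_category(lmin, categories)) > 1) {
        label <- paste0(lmin, keys$bucket[r])
      }
      clusters[[length(clusters) + 1]] <- list(
        type = keys$type[r], length_label = label, members = mem,
        consensus = cluster_consensus(mem$conformation, threshold, n_flank)
      )
    }
    if (!length(clusters)) next
    info <- tibble(
      idx = seq_along(clusters),
      type = vapply(clusters, `[[`, "", "type"),
      length_label = vapply(clusters, `[[`, "", "length_label"),
      consensus = vapply(clusters, `[[`, "", "consensus"),
      size = vapply(clusters, function(c) nrow(c$members), 0L)
    )
    for (grp in split(info, paste(info$type, info$length_label, sep = "\r"))) {
      cls <- grp %>%
        group_by(.data$consensus) %>%
        summarise(total = sum(.data$size), .groups = "drop") %>%
        arrange(desc(.data$total), .data$consensus) %>%
        mutate(class = row_number())
      grp <- left_join(grp, cls[, c("consensus", "class")], by = "consensus")
      for (cl in sort(unique(grp$class))) {
        sub <- grp[grp$class == cl, ]
        first_id <- vapply(sub$idx, function(i) {
          min(clusters[[i]]$members$loop_id)
        }, "")
        ord <- order(-sub$size, first_id)
        for (s in seq_along(ord)) {
          cinfo <- sub[ord[s], ]
          clu <- clusters[[cinfo$idx]]
          code <- sprintf("%s.%s.%s.%d.%d", method, clu$type,
                          clu$length_label, cl, s)
          geo <- consensus_geometry(clu$members)
          stats_ <- subclass_rmsd_stats(clu$members, n_flank)
          sub_rows[[length(sub_rows) + 1]] <- tibble(
            code = code, method = method, type = clu$type,
            length_label = clu$length_label, class = cl, subclass = s,
            n = nrow(clu$members), consensus_conformation = clu$consensus,
            distance = geo$distance, hoist = geo$hoist,
            packing = geo$packing, meridian = geo$meridian,
            rmsd_mean = stats_$rmsd_mean, rmsd_max = stats_$rmsd_max,
            medoid = stats_$medoid
          )
          mem_rows[[length(mem_rows) + 1]] <- tibble(
            code = code, loop_id = clu$members$loop_id,
            rmsd_to_medoid = c(0, stats_$pairs$rmsd_to_medoid)[
              match(clu$members$loop_id,
                    c(stats_$medoid, stats_$pairs$loop_id))]
          )
        }
      }
    }
  }
  unc <- bind_rows(
    memberships$DS_unclassified %||% tibble(),
    memberships$MCL_unclassified %||% tibble()
  )
  structure(
    list(
      subclasses = if (length(sub_rows)) bind_rows(sub_rows) else
        empty_subclasses(),
      members = if (length(mem_rows)) bind_rows(mem_rows) else
        tibble(code = character(), loop_id = character(),
               rmsd_to_medoid = double()),
      unclassified = unc
    ),
    class = "loop_hierarchy"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_subclasses <- function() {
  tibble(code = character(), method = character(), type = character(),
         length_label = character(), class = integer(), subclass = integer(),
         n = integer(), consensus_conformation = character(),
         distance = double(), hoist = double(), packing = double(),
         meridian = double(), rmsd_mean = double(), rmsd_max = double(),
         medoid = character())
}

#' @export
print.loop_hierarchy <- function(x, ...) {
  cat(sprintf("<loop_hierarchy: %d subclasses (%s), %d classified loops>\n",
              nrow(x$subclasses),
              paste(sprintf("%s: %d", c("DS", "MCL"),
                            c(sum(x$subclasses$method == "DS"),
                              sum(x$subclasses$method == "MCL"))),
                    collapse = ", "),
              length(unique(x$members$loop_id))))
  invisible(x)
}

#' Tidy a hierarchy into its subclass table
#'
#' @param x A `loop_hierarchy`.
#' @param ... Unused.
#' @return The subclass tibble (one row per subclass, with code, sizes,
#'   consensus conformation and geometry, RMSD statistics).
#' @export
tidy.loop_hierarchy <- function(x, ...) x$subclasses

#' One-row summary of a hierarchy
#'
#' @param x A `loop_hierarchy`.
#' @param ... Unused.
#' @return Tibble with subclass/class counts per method and overall RMSD
#'   means.
#' @export
glance.loop_hierarchy <- function(x, ...) {
  s <- x$subclasses
  tibble(
    n_subclasses = nrow(s),
    n_classes = nrow(distinct(s[, c("method", "type", "length_label",
                                    "class")])),
    n_subclasses_ds = sum(s$method == "DS"),
    n_subclasses_mcl = sum(s$method == "MCL"),
    n_classified_loops = length(unique(x$members$loop_id)),
    rmsd_mean = if (nrow(s)) stats::weighted.mean(s$rmsd_mean, s$n) else
      NA_real_
  )
}

# round half up to `digits` decimals (matches tabulated percentage style)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-type classification percentages
#'
#' Adds DS and MCL percentage columns (to one decimal, half-up rounding) to a
#' per-type count table and appends an `All` totals row.
#'
#' @param counts Tibble with `type`, `total`, `ds_classified`,
#'   `mcl_classified`.
#' @return The table with `ds_pct`, `mcl_pct` and a totals row.
#' @export
summarize_type_counts <- function(counts) {
  pct <- function(x, n) ifelse(n > 0, round_half_up(100 * x / n, 1), NA_real_)
  out <- counts %>%
    mutate(ds_pct = pct(.data$ds_classified, .data$total),
           mcl_pct = pct(.data$mcl_classified, .data$total))
  tot <- tibble(
    type = "All",
    total = sum(counts$total),
    ds_classified = sum(counts$ds_classified),
    mcl_classified = sum(counts$mcl_classified)
  )
  tot$ds_pct <- pct(tot$ds_classified, tot$total)
  tot$mcl_pct <- pct(tot$mcl_classified, tot$total)
  bind_rows(out, tot)
}

#' Summary tables of a classification
#'
#' Per-type totals with the number and percentage classified by each method,
#' and per-length classified counts.
#'
#' @param hierarchy A `loop_hierarchy`.
#' @param loops The loop inventory the clustering ran on.
#' @return List with tibbles `by_type` (type, total, per-method classified
#'   counts and percentages, plus an All row) and `by_length` (length,
#'   total, ds_classified, mcl_classified).
#' @export
classification_report <- function(hierarchy, loops) {
  mem <- left_join(hierarchy$members,
                   hierarchy$subclasses[, c("code", "method")], by = "code")
  classified <- function(method, ids) {
    length(unique(mem$loop_id[mem$method == method & mem$loop_id %in% ids]))
  }
  types <- sort(unique(loops$type))
  by_type <- bind_rows(lapply(types, function(ty) {
    ids <- loops$loop_id[loops$type == ty]
    tibble(type = ty, total = length(ids),
           ds_classified = classified("DS", ids),
           mcl_classified = classified("MCL", ids))
  }))
  by_type <- summarize_type_counts(by_type)
  lens <- sort(unique(loops$length))
  by_length <- bind_rows(lapply(lens, function(l) {
    ids <- loops$loop_id[loops$length == l]
    tibble(length = l, total = length(ids),
           ds_classified = classified("DS", ids),
           mcl_classified = classified("MCL", ids))
  }))
  list(by_type = by_type, by_length = by_length)
}

#' Write the tab-formatted classification file
#'
#' One row per (subclass, member loop): subclass code, loop id, pdb, chain,
#' residue span, loop length, sequence, conformation string, the four
#' geometry values and the RMSD to the subclass medoid. Rows are ordered by
#' code, then loop id; angles are printed to one decimal.
#'
#' @param hierarchy A `loop_hierarchy`.
#' @param loops The annotated loop inventory.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_classification <- function(hierarchy, loops, file) {
  rows <- hierarchy$members %>%
    left_join(loops, by = "loop_id") %>%
    arrange(.data$code, .data$loop_id) %>%
    mutate(
      span = sprintf("%d-%d", .data$start, .data$end),
      distance = sprintf("%.2f", .data$distance),
      hoist = sprintf("%.1f", .data$hoist),
      packing = sprintf("%.1f", .data$packing),
      meridian = sprintf("%.1f", .data$meridian),
      rmsd_to_medoid = sprintf("%.3f", .data$rmsd_to_medoid)
    ) %>%
    select("code", "loop_id", "pdb", "chain", "span", "length", "sequence",
           "conformation", "distance", "hoist", "packing", "meridian",
           "rmsd_to_medoid")
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}
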