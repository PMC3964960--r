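# Clustering of loops in geometry space: the greedy density-search (DS)
# algorithm over same-length loops, and Markov Clustering (MCL) over a
# loop-similarity graph built per length category.

#' Geometry difference cutoffs
#'
#' The neighborhood notion shared by both clustering routes: two loops are
#' geometric neighbors when all four parameter differences fall within these
#' cutoffs (the meridian difference is circular).
#'
#' @param distance Max distance difference, angstrom (default 2).
#' @param hoist,packing Max angle differences, degrees (default 30).
#' @param meridian Max circular meridian difference, degrees (default 45).
#' @return Named list of cutoffs.
#' @export
geometry_cutoffs <- function(distance = 2, hoist = 30, packing = 30,
                             meridian = 45) {
  stopifnot(distance > 0, hoist > 0, packing > 0, meridian > 0)
  list(distance = distance, hoist = hoist, packing = packing,
       meridian = meridian)
}

#' Similarity kernel widths
#'
#' Per-parameter Gaussian widths for edge weights; default is half the
#' corresponding cutoff.
#'
#' @param cutoffs A [geometry_cutoffs()] list.
#' @return Named list of widths.
#' @export
kernel_widths <- function(cutoffs = geometry_cutoffs()) {
  lapply(cutoffs, function(x) x / 2)
}

geom_deltas <- function(loops, i, j) {
  c(distance = abs(loops$distance[i] - loops$distance[j]),
    hoist = abs(loops$hoist[i] - loops$hoist[j]),
    packing = abs(loops$packing[i] - loops$packing[j]),
    meridian = circ_diff(loops$meridian[i], loops$meridian[j]))
}

within_cutoffs <- function(deltas, cutoffs) {
  deltas[["distance"]] <= cutoffs$distance &&
    deltas[["hoist"]] <= cutoffs$hoist &&
    deltas[["packing"]] <= cutoffs$packing &&
    deltas[["meridian"]] <= cutoffs$meridian
}

# n x n logical neighbor matrix under the cutoffs
neighbor_matrix <- function(loops, cutoffs) {
  n <- nrow(loops)
  nb <- matrix(FALSE, n, n)
  if (n < 2) return(nb)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- within_cutoffs(geom_deltas(loops, i, j), cutoffs)
      nb[i, j] <- nb[j, i] <- ok
    }
  }
  nb
}

# normalized 4-D geometric distance between loops i and j (each delta scaled
# by its cutoff)
norm_geom_dist <- function(loops, i, j, cutoffs) {
  d <- geom_deltas(loops, i, j)
  sqrt(sum((d / unlist(cutoffs)[names(d)])^2))
}

new_clustering <- function(method, clusters, unclassified,
                           categories = NULL) {
  structure(list(method = method, clusters = clusters,
                 unclassified = unclassified, categories = categories),
            class = "loop_clustering")
}

#' @export
print.loop_clustering <- function(x, ...) {
  cat(sprintf("<loop_clustering %s: %d cluster(s), %d unclassified>\n",
              x$method, length(x$clusters), length(x$unclassified)))
  invisible(x)
}

#' Tidy a clustering into a membership table
#'
#' @param x A `loop_clustering`.
#' @param ... Unused.
#' @return Tibble with `method`, `cluster` (ordinal), `loop_id`; unclassified
#'   loops appear with cluster NA.
#' @export
tidy.loop_clustering <- function(x, ...) {
  rows <- purrr::imap(x$clusters, function(members, k) {
    tibble(method = x$method, cluster = as.integer(k), loop_id = members)
  })
  bind_rows(
    bind_rows(rows),
    tibble(method = x$method, cluster = NA_integer_,
           loop_id = x$unclassified)
  )
}

#' Density-search clustering of same-length loops
#'
#' Greedy extraction of the densest geometric neighborhoods: at each round,
#' every unassigned loop's neighbor set (all four geometry differences within
#' the cutoffs) is computed; the loop with the most neighbors seeds the next
#' cluster (ties broken by the smallest mean normalized 4-D geometric
#' distance to its neighbors, then by lexicographic loop id). If the
#' neighborhood including the seed reaches `min_size`, it is emitted and its
#' members removed; otherwise clustering stops and everything left is
#' unclassified. Deterministic.
#'
#' @param loops Annotated loop inventory; all rows must share one type and
#'   one length, with geometry and conformation present.
#' @param cutoffs [geometry_cutoffs()].
#' @param min_size Minimum cluster size (default 3).
#' @return A `loop_clustering` with method "DS".
#' @export
ds_cluster <- function(loops, cutoffs = geometry_cutoffs(), min_size = 3) {
  stopifnot(min_size >= 2)
  if (nrow(loops) == 0) return(new_clustering("DS", list(), character()))
  if (length(unique(loops$type)) > 1 || length(unique(loops$length)) > 1) {
    stop("ds_cluster requires loops of a single type and a single length")
  }
  nb <- neighbor_matrix(loops, cutoffs)
  active <- rep(TRUE, nrow(loops))
  clusters <- list()
  repeat {
    idx <- which(active)
    if (length(idx) == 0) break
    counts <- vapply(idx, function(i) sum(nb[i, idx]), 0L)
    best <- max(counts)
    cand <- idx[counts == best]
    if (length(cand) > 1) {
      means <- vapply(cand, function(i) {
        nbrs <- idx[nb[i, idx]]
        if (length(nbrs) == 0) return(0)
        mean(vapply(nbrs, function(j) norm_geom_dist(loops, i, j, cutoffs), 0))
      }, 0)
      cand <- cand[means == min(means)]
      if (length(cand) > 1) cand <- cand[order(loops$loop_id[cand])][1]
    }
    seed <- cand[1]
    members <- c(seed, idx[nb[seed, idx]])
    if (length(members) < min_size) break
    clusters[[length(clusters) + 1]] <- sort(loops$loop_id[members])
    active[members] <- FALSE
  }
  new_clustering("DS", clusters, sort(loops$loop_id[active]))
}

#' Default loop length categories
#'
#' Short, medium, long and extra-long bins; every boundary length belongs to
#' both of its neighboring categories (e.g. length 4 is both S and M).
#'
#' @return Tibble with `label`, `min`, `max` (inclusive).
#' @export
default_length_categories <- function() {
  tibble(label = c("S", "M", "L", "XL"),
         min = c(0, 4, 9, 19), max = c(4, 9, 19, Inf))
}

#' Length categories of a loop length
#'
#' @param length Loop length (residue count >= 0).
#' @param categories Category table as [default_length_categories()].
#' @return Character vector of all category labels containing the length
#'   (two labels at the shared boundaries).
#' @export
length_category <- function(length, categories = default_length_categories()) {
  stopifnot(length >= 0)
  categories$label[length >= categories$min & length <= categories$max]
}

# flank codes of a conformation string (first and last n_flank characters)
flank_codes <- function(s, n_flank = 2) {
  c(substr(s, 1, n_flank), substr(s, nchar(s) - n_flank + 1, nchar(s)))
}

#' Build the loop-similarity graph
#'
#' Nodes are loop ids; an undirected edge joins two loops when (a) all four
#' geometry differences are within the cutoffs and (b) the shorter
#' conformation string can be aligned inside the longer with at most
#' (length difference) insertions, confined to the loop region, and no
#' mismatches at the flank positions. The weight is the product over the four
#' parameters of `exp(-(delta / sigma)^2)`, in (0, 1].
#'
#' @param loops Annotated loops of one type and one length category.
#' @param cutoffs [geometry_cutoffs()].
#' @param widths [kernel_widths()].
#' @param n_flank Number of coded flank residues each side (default 2).
#' @return Edge tibble `from`, `to`, `weight` with a `nodes` attribute
#'   listing all loop ids (isolated nodes included).
#' @export
build_similarity_graph <- function(loops, cutoffs = geometry_cutoffs(),
                                   widths = kernel_widths(cutoffs),
                                   n_flank = 2) {
  n <- nrow(loops)
  edges <- list(tibble(from = character(), to = character(),
                       weight = double()))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- geom_deltas(loops, i, j)
        if (!within_cutoffs(d, cutoffs)) next
        if (!strings_compatible(loops$conformation[i], loops$conformation[j],
                                n_flank)) next
        w <- exp(-sum((d / unlist(widths)[names(d)])^2))
        edges[[length(edges) + 1]] <- tibble(
          from = loops$loop_id[i], to = loops$loop_id[j], weight = w
        )
      }
    }
  }
  g <- bind_rows(edges)
  attr(g, "nodes") <- loops$loop_id
  g
}

# Conformation-string compatibility: the shorter string must embed in the
# longer as an ordered alignment with exactly (length difference) insertions;
# wherever an aligned pair touches a flank position (the first or last
# n_flank characters of either string) the codes must match, while
# loop-interior mismatches are tolerated. This lets the graph connect loops
# whose secondary structure boundaries were delineated one residue apart.
strings_compatible <- function(a, b, n_flank = 2) {
  if (is.na(a) || is.na(b)) return(FALSE)
  s <- strsplit(if (nchar(a) <= nchar(b)) a else b, "")[[1]]
  t <- strsplit(if (nchar(a) <= nchar(b)) b else a, "")[[1]]
  ns <- length(s)
  nt <- length(t)
  is_flank <- function(pos, len) pos <= n_flank | pos > len - n_flank
  # ok[i, j]: can s[1..i] align to t[1..j] (j - i gaps used so far)?
  ok <- matrix(FALSE, ns + 1, nt + 1)
  ok[1, 1] <- TRUE
  for (j in seq_len(nt)) ok[1, j + 1] <- j <= nt - ns
  for (i in seq_len(ns)) {
    for (j in i:(i + nt - ns)) {
      pair_ok <- s[i] == t[j] ||
        (!is_flank(i, ns) && !is_flank(j, nt))
      ok[i + 1, j + 1] <- (ok[i, j] && pair_ok) || (j > i && ok[i + 1, j])
    }
  }
  ok[ns + 1, nt + 1]
}

#' Markov Clustering parameters
#'
#' @param inflation Inflation exponent (> 1, default 2).
#' @param expansion Expansion power (fixed at 2).
#' @param prune Entries below this are zeroed each iteration (default 1e-5).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence tolerance on the max entry change (default 1e-8).
#' @param self_loop Self-loop weight added to every node (default 1).
#' @return Named parameter list.
#' @export
mcl_params <- function(inflation = 2, expansion = 2, prune = 1e-5,
                       max_iter = 100, tol = 1e-8, self_loop = 1) {
  stopifnot(inflation > 1, expansion == 2)
  list(inflation = inflation, expansion = expansion, prune = prune,
       max_iter = max_iter, tol = tol, self_loop = self_loop)
}

#' Markov Clustering of a similarity graph
#'
#' Adds self-loops, column-normalizes to a stochastic matrix and alternates
#' expansion (matrix squaring), inflation (entrywise powering plus column
#' renormalization) and pruning until the maximum entry change falls below
#' the tolerance. Clusters are read from the limit matrix as the connected
#' components induced by the rows of attractor nodes (positive diagonal);
#' a node attracted by several clusters joins the largest one (ties go to
#' the cluster holding the lexicographically smallest attractor id).
#' Clusters below `min_size` are unclassified.
#'
#' @param graph Edge tibble from [build_similarity_graph()] (with its `nodes`
#'   attribute), or any tibble with `from`, `to`, `weight`.
#' @param params [mcl_params()].
#' @param min_size Minimum cluster size (default 3).
#' @return A `loop_clustering` with method "MCL". The attribute
#'   `max_colsum_dev` records the largest deviation of any column sum from 1
#'   seen after the normalization steps.
#' @export
mcl <- function(graph, params = mcl_params(), min_size = 3) {
  nodes <- attr(graph, "nodes")
  if (is.null(nodes)) nodes <- unique(c(graph$from, graph$to))
  if (length(nodes) == 0) stop("empty graph")
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph)) {
    fi <- match(graph$from, nodes)
    ti <- match(graph$to, nodes)
    for (k in seq_along(fi)) {
      M[fi[k], ti[k]] <- graph$weight[k]
      M[ti[k], fi[k]] <- graph$weight[k]
    }
  }
  diag(M) <- params$self_loop
  normalize <- function(m) sweep(m, 2, colSums(m), "/")
  M <- normalize(M)
  max_dev <- max(abs(colSums(M) - 1))
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    prev <- M
    M <- M %*% M
    M <- normalize(M ^ params$inflation)
    max_dev <- max(max_dev, abs(colSums(M) - 1))
    M[M < params$prune] <- 0
    M <- normalize(M)
    max_dev <- max(max_dev, abs(colSums(M) - 1))
    if (max(abs(M - prev)) < params$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("MCL did not converge; interpreting current matrix")
  interpret_mcl(M, nodes, min_size, max_dev)
}

interpret_mcl <- function(M, nodes, min_size, max_dev) {
  n <- length(nodes)
  attractors <- which(diag(M) > 0)
  # group attractors that share any node into one cluster
  groups <- list()
  assigned <- rep(0L, n)
  for (a in attractors) {
    covered <- which(M[a, ] > 0)
    hit <- unique(assigned[covered])
    hit <- hit[hit > 0]
    if (length(hit) == 0) {
      groups[[length(groups) + 1]] <- covered
      assigned[covered] <- length(groups)
    } else {
      tgt <- min(hit)
      merged <- sort(unique(c(unlist(groups[hit]), covered)))
      for (h in hit) groups[[h]] <- integer()
      groups[[tgt]] <- merged
      assigned[merged] <- tgt
    }
  }
  groups <- groups[vapply(groups, length, 0L) > 0]
  # resolve multi-membership: a node covered by several groups joins the
  # largest; ties -> group with the lexicographically smallest attractor id
  membership <- rep(NA_integer_, n)
  for (gi in seq_along(groups)) {
    for (v in groups[[gi]]) {
      if (is.na(membership[v])) {
        membership[v] <- gi
      } else {
        cur <- membership[v]
        if (length(groups[[gi]]) > length(groups[[cur]])) {
          membership[v] <- gi
        } else if (length(groups[[gi]]) == length(groups[[cur]])) {
          amin <- function(g) min(nodes[intersect(groups[[g]],
                                                  which(diag(M) > 0))])
          if (amin(gi) < amin(cur)) membership[v] <- gi
        }
      }
    }
  }
  clusters <- list()
  unclassified <- nodes[is.na(membership)]
  for (gi in sort(unique(stats::na.omit(membership)))) {
    members <- sort(nodes[which(membership == gi)])
    if (length(members) >= min_size) {
      clusters[[length(clusters) + 1]] <- members
    } else {
      unclassified <- c(unclassified, members)
    }
  }
  out <- new_clustering("MCL", clusters, sort(unclassified))
  attr(out, "max_colsum_dev") <- max_dev
  out
}

#' Cluster a loop inventory with both algorithms
#'
#' DS runs per (type, length) bucket; MCL runs per (type, length category)
#' bucket, so a loop at a boundary length can receive up to two MCL
#' memberships. Only classifiable loops (complete conformation strings)
#' participate.
#'
#' @param loops Annotated loop inventory.
#' @param cutoffs,widths Geometry cutoffs and kernel widths.
#' @param ds_min,mcl_min Minimum cluster sizes.
#' @param params MCL parameters.
#' @param categories Length category table.
#' @param n_flank Coded flank residues per side.
#' @return Named list with `DS` and `MCL`, each a tibble: `method`, `type`,
#'   `bucket` (length or category label), `cluster` (ordinal within bucket),
#'   `loop_id`; plus `unclassified` tibbles.
#' @export
cluster_loops <- function(loops, cutoffs = geometry_cutoffs(),
                          widths = kernel_widths(cutoffs),
                          ds_min = 3, mcl_min = 3, params = mcl_params(),
                          categories = default_length_categories(),
                          n_flank = 2) {
  cl <- loops[loops$classifiable, , drop = FALSE]
  ds_rows <- list()
  ds_un <- list()
  for (ty in sort(unique(cl$type))) {
    for (len in sort(unique(cl$length[cl$type == ty]))) {
      sub <- cl[cl$type == ty & cl$length == len, ]
      r <- ds_cluster(sub, cutoffs, ds_min)
      ds_rows[[length(ds_rows) + 1]] <- membership_rows("DS", ty,
                                                        as.character(len), r)
      ds_un[[length(ds_un) + 1]] <- tibble(method = "DS", type = ty,
                                           loop_id = r$unclassified)
    }
  }
  mcl_rows <- list()
  mcl_un <- list()
  for (ty in sort(unique(cl$type))) {
    for (cat in categories$label) {
      lo <- categories$min[categories$label == cat]
      hi <- categories$max[categories$label == cat]
      sub <- cl[cl$type == ty & cl$length >= lo & cl$length <= hi, ]
      if (nrow(sub) == 0) next
      g <- build_similarity_graph(sub, cutoffs, widths, n_flank)
      r <- mcl(g, params, mcl_min)
      mcl_rows[[length(mcl_rows) + 1]] <- membership_rows("MCL", ty, cat, r)
      mcl_un[[length(mcl_un) + 1]] <- tibble(method = "MCL", type = ty,
                                             loop_id = r$unclassified)
    }
  }
  empty_m <- tibble(method = character(), type = character(),
                    bucket = character(), cluster = integer(),
                    loop_id = character())
  empty_u <- tibble(method = character(), type = character(),
                    loop_id = character())
  ds_m <- bind_rows(c(list(empty_m), ds_rows))
  mcl_m <- bind_rows(c(list(empty_m), mcl_rows))
  mcl_un <- distinct(bind_rows(c(list(empty_u), mcl_un)))
  # a loop clustered in one category is classified even if another category
  # left it out
  mcl_un <- mcl_un[!mcl_un$loop_id %in% mcl_m$loop_id, , drop = FALSE]
  list(
    DS = ds_m,
    MCL = mcl_m,
    DS_unclassified = distinct(bind_rows(c(list(empty_u), ds_un))),
    MCL_unclassified = mcl_un
  )
}

membership_rows <- function(method, type, bucket, clustering) {
  rows <- purrr::imap(clustering$clusters, function(members, k) {
    tibble(method = method, type = type, bucket = bucket,
           cluster = as.integer(k), loop_id = members)
  })
  bind_rows(rows)
}
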