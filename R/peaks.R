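#' Node tables
#'
#' A `node_set` is an ordered data.frame of network nodes with columns
#' `region`, `hemisphere`, `x`, `y`, `z` (MNI mm) and optionally `zstat` and
#' `source`. The package ships the 21 meta-analytically derived nodes of the
#' impulsivity network as `system.file("extdata", "impulsivity_nodes.tsv",
#' package = "alenet")`.
#'
#' @param df data.frame with at least `x`, `y`, `z`; `region` and
#'   `hemisphere` are filled with placeholders when absent.
#' @export
node_set <- function(df) {
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  if (!"region" %in% names(df)) {
    df$region <- paste0("node_", seq_len(nrow(df)))
  }
  if (!"hemisphere" %in% names(df)) df$hemisphere <- ""
  for (col in c("x", "y", "z")) {
    if (!is.numeric(df[[col]])) stop("column '", col, "' must be numeric")
  }
  front <- c("region", "hemisphere", "x", "y", "z")
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("node_set", "data.frame")
  df
}

#' @rdname node_set
#' @param nodes a `node_set`.
#' @return `node_coords`: n x 3 matrix of mm coordinates.
#' @export
node_coords <- function(nodes) {
  as.matrix(nodes[, c("x", "y", "z")])
}

#' Read / write a node table
#'
#' Tab-separated node tables with columns `region`, `hemisphere`, `x`, `y`,
#' `z` (and any extra columns, preserved). Row order is preserved.
#'
#' @param path TSV file path.
#' @return A [node_set()].
#' @export
read_node_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("empty node table: ", path)
  need <- c("region", "hemisphere", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("node table must have columns ", paste(need, collapse = ", "),
         " -- got: ", paste(names(tab), collapse = ", "))
  }
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric coordinate in column '%s' at row %d",
                   col, which(is.na(v))[1]))
    }
    tab[[col]] <- v
  }
  node_set(tab)
}

#' @rdname read_node_table
#' @param nodes a [node_set()].
#' @export
write_node_table <- function(nodes, path) {
  utils::write.table(as.data.frame(nodes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Logical array marking voxels that are >= all their 26 neighbours
# (out-of-bounds neighbours count as -Inf). Every voxel of a plateau
# qualifies; the greedy selection's deterministic ordering (descending value,
# then linear index) makes the first lexicographic voxel win.
local_maxima <- function(arr) {
  dm <- dim(arr)
  ok <- array(TRUE, dm)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    src_i <- max(1, 1 + di):min(dm[1], dm[1] + di)
    src_j <- max(1, 1 + dj):min(dm[2], dm[2] + dj)
    src_k <- max(1, 1 + dk):min(dm[3], dm[3] + dk)
    dst_i <- src_i - di
    dst_j <- src_j - dj
    dst_k <- src_k - dk
    ok[dst_i, dst_j, dst_k] <- ok[dst_i, dst_j, dst_k] &
      (arr[dst_i, dst_j, dst_k] >= arr[src_i, src_j, src_k])
  }
  ok
}

#' Extract peaks from a thresholded z map
#'
#' Local maxima (each voxel at least as large as all 26 neighbours) of a
#' thresholded map, restricted to grey matter, selected greedily in
#' descending z: a candidate is accepted iff it lies at least `min_distance`
#' mm from every already-accepted peak.
#'
#' @param zmap a `stat_map` with zeros outside the significant clusters.
#' @param min_distance minimum inter-peak distance in mm (default 15).
#' @param gm_mask optional logical array of grey-matter eligibility
#'   (defaults to the grid mask).
#' @param source label recorded with each peak (default "zmap").
#' @return data.frame with columns `x`, `y`, `z`, `zstat`, `source`;
#'   zero rows for an empty map.
#' @export
extract_peaks <- function(zmap, min_distance = 15, gm_mask = NULL,
                          source = "zmap") {
  g <- zmap$grid
  if (is.null(gm_mask)) gm_mask <- g$mask
  active <- zmap$data != 0 & gm_mask & g$mask
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      zstat = numeric(0), source = character(0))
  if (!any(active)) return(empty)
  cand <- which(active & local_maxima(zmap$data))
  if (!length(cand)) return(empty)
  cand <- cand[order(-zmap$data[cand], cand)]
  xyz <- vox_to_mm(g, arrayInd(cand, g$shape))
  acc <- integer(0)
  for (i in seq_along(cand)) {
    if (!length(acc)) {
      acc <- i
      next
    }
    d2 <- rowSums(sweep(xyz[acc, , drop = FALSE], 2, xyz[i, ])^2)
    if (all(d2 >= min_distance^2)) acc <- c(acc, i)
  }
  data.frame(x = xyz[acc, 1], y = xyz[acc, 2], z = xyz[acc, 3],
             zstat = zmap$data[cand[acc]], source = source)
}

#' Merge peak lists across maps
#'
#' Peaks from different maps closer than `min_distance` mm collapse to the
#' higher-z peak. Ties in z are broken deterministically: the peak from the
#' earlier-listed map wins, then lexicographic coordinate order.
#'
#' @param peak_lists list of data.frames as returned by [extract_peaks()].
#' @param min_distance minimum inter-peak distance in mm (default 15).
#' @return A [node_set()] with `zstat` and `source` columns, ordered by
#'   descending `zstat`.
#' @export
merge_across_maps <- function(peak_lists, min_distance = 15) {
  all_pk <- do.call(rbind, lapply(seq_along(peak_lists), function(m) {
    pk <- peak_lists[[m]]
    if (nrow(pk)) pk$map_rank <- m
    pk
  }))
  if (is.null(all_pk) || !nrow(all_pk)) {
    return(node_set(data.frame(x = numeric(0), y = numeric(0),
                               z = numeric(0), zstat = numeric(0),
                               source = character(0))))
  }
  ord <- order(-all_pk$zstat, all_pk$map_rank, all_pk$x, all_pk$y, all_pk$z)
  all_pk <- all_pk[ord, , drop = FALSE]
  xyz <- as.matrix(all_pk[, c("x", "y", "z")])
  acc <- integer(0)
  for (i in seq_len(nrow(all_pk))) {
    if (!length(acc)) {
      acc <- i
      next
    }
    d2 <- rowSums(sweep(xyz[acc, , drop = FALSE], 2, xyz[i, ])^2)
    if (all(d2 >= min_distance^2)) acc <- c(acc, i)
  }
  out <- all_pk[acc, c("x", "y", "z", "zstat", "source"), drop = FALSE]
  node_set(out)
}
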