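#' Read an atlas table
#'
#' Expects columns `index` (1-based, complete and unique over `1..R`),
#' `name`, `lobe`, `hemisphere` (`L`/`R`), and MNI centroid coordinates
#' `x`, `y`, `z` in mm.
#'
#' @param path CSV path.
#' @return validated data frame of class `atlas_info`.
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("index", "name", "lobe", "hemisphere", "x", "y", "z")
  missing <- setdiff(required, names(atlas))
  if (length(missing)) stop("atlas file lacks column(s): ", paste(missing, collapse = ", "))
  R <- nrow(atlas)
  if (!setequal(atlas$index, seq_len(R))) stop("atlas indices must be exactly 1..R")
  atlas <- atlas[order(atlas$index), ]
  if (any(!nzchar(atlas$lobe)) || any(is.na(atlas$lobe))) stop("empty lobe label(s)")
  if (!all(atlas$hemisphere %in% c("L", "R"))) {
    stop("hemisphere labels must be 'L' or 'R'")
  }
  class(atlas) <- c("atlas_info", "data.frame")
  atlas
}

#' The packaged 90-region AAL atlas table
#'
#' Standard AAL-90 region names and hemispheres with the package's lobe
#' partition (Frontal, Insula, Limbic, Medial-Temporal, Occipital,
#' Parietal, Subcortical, Temporal). The centroid coordinates shipped in
#' this fixture are synthetic approximations intended for file-format
#' export and plumbing tests, not measured AAL centroids; supply your own
#' table via [read_atlas()] for real anatomical work.
#'
#' @return `atlas_info` data frame with 90 rows.
#' @export
aal90_atlas <- function() {
  read_atlas(system.file("extdata", "aal90_atlas_synthetic.csv",
                         package = "tsfs", mustWork = TRUE))
}

#' Convert selected feature indices to a region-pair edge set
#'
#' Each connectivity feature maps to one unordered region pair through
#' the fixed upper-triangle lookup; edges get unit weight. Duplicate
#' feature indices are dropped with a warning.
#'
#' @param indices feature indices (1-based).
#' @param R region count.
#' @return data frame of class `edge_set` with columns `a`, `b`
#'   (`a < b`), `weight`, in the input order.
#' @export
features_to_edges <- function(indices, R) {
  if (anyDuplicated(indices)) {
    warning("duplicate feature indices dropped")
    indices <- indices[!duplicated(indices)]
  }
  pairs <- feature_to_pair(indices, R)
  edges <- data.frame(a = pairs[, "j"], b = pairs[, "k"],
                      weight = rep(1, nrow(pairs)))
  class(edges) <- c("edge_set", "data.frame")
  edges
}

.edge_lobes <- function(edges, atlas) {
  if (max(edges$a, edges$b, 0) > nrow(atlas)) stop("edge endpoint outside atlas")
  cbind(atlas$lobe[edges$a], atlas$lobe[edges$b])
}

#' Lobe-wise edge count tables
#'
#' Splits the edges into same-lobe (intra) and cross-lobe (inter)
#' buckets; the two totals always sum to the edge count.
#'
#' @param edges an `edge_set`.
#' @param atlas an `atlas_info`.
#' @return list with `intra` (data frame `lobe`, `count`) and `inter`
#'   (data frame `lobe_a`, `lobe_b`, `count`, unordered pairs with
#'   `lobe_a <= lobe_b` alphabetically).
#' @export
lobe_counts <- function(edges, atlas) {
  lob <- .edge_lobes(edges, atlas)
  intra_mask <- lob[, 1] == lob[, 2]
  intra <- as.data.frame(table(lobe = lob[intra_mask, 1]),
                         responseName = "count", stringsAsFactors = FALSE)
  if (nrow(intra) == 0) intra <- data.frame(lobe = character(0), count = integer(0))
  inter_pairs <- lob[!intra_mask, , drop = FALSE]
  if (nrow(inter_pairs) > 0) {
    key <- t(apply(inter_pairs, 1L, sort))
    inter <- as.data.frame(table(lobe_a = key[, 1], lobe_b = key[, 2]),
                           responseName = "count", stringsAsFactors = FALSE)
    inter <- inter[inter$count > 0, , drop = FALSE]
    rownames(inter) <- NULL
  } else {
    inter <- data.frame(lobe_a = character(0), lobe_b = character(0),
                        count = integer(0))
  }
  list(intra = intra, inter = inter)
}

#' Hemisphere-wise edge counts
#'
#' @param edges an `edge_set`.
#' @param atlas an `atlas_info`.
#' @return named integer vector `intra_L`, `intra_R`, `inter`; the three
#'   always sum to the edge count.
#' @export
hemisphere_counts <- function(edges, atlas) {
  if (nrow(edges) == 0) return(c(intra_L = 0L, intra_R = 0L, inter = 0L))
  if (max(edges$a, edges$b) > nrow(atlas)) stop("edge endpoint outside atlas")
  ha <- atlas$hemisphere[edges$a]
  hb <- atlas$hemisphere[edges$b]
  c(intra_L = sum(ha == "L" & hb == "L"),
    intra_R = sum(ha == "R" & hb == "R"),
    inter = sum(ha != hb))
}

#' Export node/edge files for BrainNet Viewer
#'
#' Writes the whitespace-separated `.node` file (`x y z color size
#' label`, one line per region touched by the exported edges) and the
#' matching symmetric 0/1 `.edge` adjacency whose row order follows the
#' node file. Only the first `top_k` edges (the edge set is assumed
#' ranked, best first) are exported to keep the rendering readable; node
#' color and size are fixed at 1.
#'
#' @param edges an `edge_set`, ordered best-first.
#' @param atlas an `atlas_info` with MNI coordinates.
#' @param node_path,edge_path output paths.
#' @param top_k number of leading edges to export (default 50, capped at
#'   the edge count).
#' @return invisible list with the exported `nodes` (region indices) and
#'   `edges`.
#' @export
export_brainnet <- function(edges, atlas, node_path, edge_path, top_k = 50L) {
  if (nrow(edges) == 0) stop("empty edge set")
  if (any(is.na(atlas$x) | is.na(atlas$y) | is.na(atlas$z))) {
    stop("atlas lacks coordinates for some regions")
  }
  top_k <- min(top_k, nrow(edges))
  sel <- edges[seq_len(top_k), , drop = FALSE]
  nodes <- sort(unique(c(sel$a, sel$b)))
  node_df <- data.frame(
    x = atlas$x[nodes], y = atlas$y[nodes], z = atlas$z[nodes],
    color = 1L, size = 1L, label = atlas$name[nodes]
  )
  utils::write.table(node_df, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  adj <- matrix(0L, length(nodes), length(nodes))
  ia <- match(sel$a, nodes)
  ib <- match(sel$b, nodes)
  adj[cbind(ia, ib)] <- 1L
  adj[cbind(ib, ia)] <- 1L
  utils::write.table(adj, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(nodes = nodes, edges = sel))
}

#' Re-read BrainNet node/edge files as an edge set
#'
#' Inverse of [export_brainnet()]: reconstructs the unordered region-pair
#' edges using the node labels to recover atlas indices.
#'
#' @param node_path,edge_path paths written by [export_brainnet()].
#' @param atlas the `atlas_info` used at export time.
#' @return an `edge_set` (columns `a`, `b`, `weight`), sorted by `(a, b)`.
#' @export
read_brainnet <- function(node_path, edge_path, atlas) {
  nodes <- utils::read.table(node_path, sep = "\t", stringsAsFactors = FALSE)
  names(nodes) <- c("x", "y", "z", "color", "size", "label")
  region_idx <- match(nodes$label, atlas$name)
  if (anyNA(region_idx)) stop("node label(s) not found in atlas")
  adj <- as.matrix(utils::read.table(edge_path, sep = "\t"))
  if (nrow(adj) != nrow(nodes) || ncol(adj) != nrow(nodes)) {
    stop("edge matrix dimensions do not match the node file")
  }
  up <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  edges <- data.frame(a = region_idx[up[, 1]], b = region_idx[up[, 2]], weight = 1)
  sw <- edges$a > edges$b
  edges[sw, c("a", "b")] <- edges[sw, c("b", "a")]
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("edge_set", "data.frame")
  edges
}

#' Site table of the reference multi-site cohort
#'
#' Per-site case/control participant counts of the 17-site reference
#' cohort shipped as a text fixture (columns `site`, `cases`,
#' `controls`).
#'
#' @return data frame with 17 rows.
#' @export
site_counts <- function() {
  utils::read.csv(system.file("extdata", "abide_site_counts.csv",
                              package = "tsfs", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
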