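#' Functional network labels
#'
#' The 14 functional-network labels used by the packaged 264-region
#' parcellation stand-in, and the subset of 9 networks over which hub
#' topography is analysed.  Three networks are task-irrelevant (auditory and
#' the two somatomotor networks) and two are functionally imprecise
#' (memory retrieval, uncertain); these five are excluded from hub tallies.
#'
#' @return character vector of network names.
#' @export
network_names <- function() {
  c("cerebellar", "cingulo_opercular", "frontoparietal", "default_mode",
    "dorsal_attention", "ventral_attention", "salience", "subcortical",
    "visual",
    "auditory", "somatomotor_hand", "somatomotor_mouth",
    "memory_retrieval", "uncertain")
}

#' @rdname network_names
#' @export
analyzed_network_names <- function() network_names()[1:9]

#' Generate a synthetic parcellation
#'
#' Draws `n_nodes` region centroids uniformly inside a brain-scale ellipsoid
#' (semi-axes 70 x 85 x 60 mm, rejection sampling) and assigns them to
#' `n_networks` functional networks of near-equal size.  Only relative
#' distances between centroids matter downstream (motion-artifact and
#' distance-profile analyses), so a uniform ellipsoid is an adequate
#' geometric stand-in for real stereotaxic coordinates.
#'
#' @param n_nodes number of regions (default 264).
#' @param n_networks number of functional networks (default 14; when 14, the
#'   canonical labels of [network_names()] are used and the first 9 are
#'   flagged as analyzed).
#' @param seed integer seed; output is deterministic given the seed.
#' @return A `parcellation`: a data frame with columns `node_id` (0-based),
#'   `x`, `y`, `z` (mm), `network`, `analyzed` (logical).
#' @examples
#' parc <- generate_parcellation(258, 14, seed = 1)
#' table(parc$network)
#' @export
generate_parcellation <- function(n_nodes = 264, n_networks = 14, seed = 1) {
  if (n_nodes < 1 || n_networks < 1)
    stop("n_nodes and n_networks must be positive")
  if (n_nodes < n_networks)
    stop("n_nodes must be at least n_networks")
  set.seed(as.integer(seed))
  semi <- c(70, 85, 60)
  pts <- matrix(numeric(0), ncol = 3)
  while (nrow(pts) < n_nodes) {
    cand <- matrix(runif(3 * 2 * n_nodes, -1, 1), ncol = 3)
    pts <- rbind(pts, cand[rowSums(cand^2) <= 1, , drop = FALSE])
  }
  pts <- pts[seq_len(n_nodes), , drop = FALSE] %*% diag(semi)

  if (n_networks == 14) {
    labs <- network_names()
  } else {
    labs <- sprintf("network_%02d", seq_len(n_networks))
  }
  base <- n_nodes %/% n_networks
  sizes <- base + (seq_len(n_networks) <= n_nodes %% n_networks)
  network <- sample(rep(labs, times = sizes))
  analyzed <- if (n_networks == 14) network %in% analyzed_network_names()
              else rep(TRUE, n_nodes)

  parc <- data.frame(node_id = seq_len(n_nodes) - 1L,
                     x = pts[, 1], y = pts[, 2], z = pts[, 3],
                     network = network, analyzed = analyzed,
                     stringsAsFactors = FALSE)
  class(parc) <- c("parcellation", "data.frame")
  parc
}

#' Drop excluded nodes from a parcellation
#'
#' Removes regions (e.g. nodes falling outside the brain in some
#' participants) by node id.  Original node ids are preserved; downstream
#' matrices follow the row order of the returned parcellation.
#'
#' @param parc a `parcellation`.
#' @param excluded_ids integer vector of `node_id` values to drop.
#' @return the filtered `parcellation`.
#' @export
apply_node_exclusions <- function(parc, excluded_ids) {
  stopifnot(is.data.frame(parc))
  missing_ids <- setdiff(excluded_ids, parc$node_id)
  if (length(missing_ids))
    stop("excluded ids not present in parcellation: ",
         paste(missing_ids, collapse = ", "))
  out <- parc[!(parc$node_id %in% excluded_ids), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Load the packaged 264-region parcellation stand-in
#'
#' The package ships a synthetic 264-region, 14-network parcellation
#' (`inst/extdata/parcellation264_synthetic.tsv`) together with a 6-node
#' exclusion list (`excluded_nodes_synthetic.tsv`), mirroring the standard
#' design in which 6 of 264 regions are discarded for incomplete coverage,
#' leaving 258 analysis nodes.
#'
#' @param exclude apply the packaged exclusion list (default `TRUE`,
#'   returning 258 nodes).
#' @return a `parcellation`.
#' @export
load_packaged_parcellation <- function(exclude = TRUE) {
  parc <- read_parcellation(system.file("extdata",
    "parcellation264_synthetic.tsv", package = "endoconn", mustWork = TRUE))
  if (exclude) {
    excl <- read.delim(system.file("extdata", "excluded_nodes_synthetic.tsv",
      package = "endoconn", mustWork = TRUE))
    parc <- apply_node_exclusions(parc, excl$node_id)
  }
  parc
}

#' Read / write a parcellation as TSV
#'
#' Tab-separated text with columns `node_id`, `x`, `y`, `z`, `network`,
#' `analyzed`; coordinates round-trip at 12 significant digits.
#'
#' @param parc a `parcellation`.
#' @param path file path.
#' @return `read_parcellation` returns a `parcellation`; `write_parcellation`
#'   returns `path` invisibly.
#' @export
write_parcellation <- function(parc, path) {
  out <- parc
  for (cl in c("x", "y", "z")) out[[cl]] <- signif(out[[cl]], 12)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  parc <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "x", "y", "z", "network", "analyzed")
  if (!all(need %in% names(parc)))
    stop("parcellation file must have columns: ", paste(need, collapse = ", "))
  parc$analyzed <- as.logical(parc$analyzed)
  class(parc) <- c("parcellation", "data.frame")
  parc
}

# Pairwise Euclidean centroid distances (mm), full matrix.
centroid_distances <- function(parc) {
  as.matrix(dist(as.matrix(parc[, c("x", "y", "z")])))
}

#' Edge distances in canonical edge order
#'
#' Euclidean distances (mm) between region centroids for every unordered
#' node pair, in the package's canonical column-major upper-triangle edge
#' order (the order used by FC edge stacks).
#'
#' @param parc a `parcellation`.
#' @return numeric vector of length `N(N-1)/2`.
#' @export
edge_distances <- function(parc) {
  upper_tri_values(centroid_distances(parc))
}
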