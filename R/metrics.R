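#' Node strengths
#'
#' Total retained connection weight incident to each node.
#'
#' @param net a `weighted_network` (or a plain symmetric weight matrix).
#' @return numeric vector of length N.
#' @export
node_strengths <- function(net) {
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  rowSums(w)
}

net_weights <- function(net) {
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  if (any(w < 0))
    stop("negative weights; threshold to a non-negative network first")
  w
}

#' Weighted clustering coefficient (Onnela)
#'
#' Mean over nodes of the Onnela geometric-mean clustering coefficient:
#' weights are scaled by the network maximum, each node's coefficient is the
#' sum of cube-rooted triangle intensities around it divided by
#' `k (k - 1)` for binarized degree `k`, and nodes with fewer than two
#' neighbours contribute zero.
#'
#' @param net a `weighted_network` with non-negative weights.
#' @return scalar mean clustering coefficient.
#' @export
clustering_coefficient <- function(net) {
  w <- net_weights(net)
  mx <- max(w)
  if (mx == 0) return(0)
  wh <- (w / mx)^(1 / 3)
  num <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

#' Weighted global efficiency
#'
#' Mean inverse shortest weighted path length over all ordered node pairs,
#' with edge lengths `1 / weight` and disconnected pairs contributing zero.
#'
#' @param net a `weighted_network` with non-negative weights.
#' @return scalar efficiency in `[0, 1]` for weights in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  w <- net_weights(net)
  n <- nrow(w)
  if (n < 2) stop("need at least two nodes")
  if (all(w == 0)) return(0)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Degree- and strength-preserving null ensemble
#'
#' Random reference networks matched to the input: each null shares the node
#' count, edge count, degree sequence and weight multiset exactly, and
#' approximates the strength sequence.  Topology is randomised by
#' degree-preserving double-edge swaps (`swap_factor * m` attempted swaps);
#' the original weight multiset is then reassigned to the rewired edges by
#' iterative rank matching against residual node strengths, in
#' `match_batches` re-ranked batches, so that high weights land on edges
#' between high-strength nodes.
#'
#' @param net a `weighted_network` with at least 2 edges.
#' @param n ensemble size (default 100).
#' @param seed integer seed.
#' @param swap_factor attempted swaps per edge (default 10).
#' @param match_batches number of re-ranking batches in the weight
#'   reassignment (default 20; more batches track strengths more closely).
#' @return list of `n` `weighted_network` objects.
#' @export
null_ensemble <- function(net, n = 100, seed = 1, swap_factor = 10,
                          match_batches = 20) {
  stopifnot(inherits(net, "weighted_network"))
  if (n < 1) stop("ensemble size must be at least 1")
  if (net$retained_count < 2) stop("need at least 2 edges to rewire")
  w <- net_weights(net)
  nn <- nrow(w)
  ei <- edge_index(nn)
  vals <- upper_tri_values(w)
  on_edge <- vals != 0
  edges <- cbind(ei$i[on_edge], ei$j[on_edge])
  weights <- vals[on_edge]
  m <- nrow(edges)
  s_orig <- rowSums(w)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, nn - igraph::vcount(g))

  set.seed(as.integer(seed))
  lapply(seq_len(n), function(dummy) {
    rg <- igraph::rewire(g, igraph::keeping_degseq(niter = swap_factor * m))
    el <- igraph::as_edgelist(rg, names = FALSE)
    assigned <- match_weights_to_strengths(el, weights, s_orig, match_batches)
    wm <- matrix(0, nn, nn)
    wm[el] <- assigned
    wm <- wm + t(wm)
    structure(list(weights = wm, density = net$density,
                   retained_count = m),
              class = "weighted_network")
  })
}

# Greedy batched rank matching: assign the sorted weight multiset to edges
# ranked by the product of residual endpoint strengths, re-ranking between
# batches.  Exactly preserves the weight multiset; approximately preserves
# the strength sequence.
match_weights_to_strengths <- function(el, weights, s_target, n_batches) {
  m <- nrow(el)
  ws <- sort(weights, decreasing = TRUE)
  resid <- s_target
  assigned <- numeric(m)
  unas <- seq_len(m)
  pos <- 1L
  batch <- max(1L, ceiling(m / n_batches))
  while (length(unas)) {
    score <- resid[el[unas, 1]] * resid[el[unas, 2]]
    ord <- unas[order(-score)]
    take <- ord[seq_len(min(batch, length(ord)))]
    wts <- ws[pos:(pos + length(take) - 1L)]
    assigned[take] <- wts
    # each edge weight counts toward both endpoint strengths
    for (idx in seq_along(take)) {
      e <- take[idx]
      resid[el[e, 1]] <- resid[el[e, 1]] - wts[idx]
      resid[el[e, 2]] <- resid[el[e, 2]] - wts[idx]
    }
    pos <- pos + length(take)
    unas <- setdiff(unas, take)
  }
  assigned
}

#' Normalise a graph metric against a null ensemble
#'
#' Divides the observed metric by its mean over a reference ensemble,
#' removing the part of the metric explained by size, density, degree and
#' strength alone.
#'
#' @param metric_fn function mapping a `weighted_network` to a scalar.
#' @param net the observed `weighted_network`.
#' @param ensemble list of null networks (see [null_ensemble()]).
#' @return a `metric_result` list: `raw`, `null_mean`, `normalized`
#'   (`raw / null_mean`), `ensemble_size`.
#' @export
normalize_metric <- function(metric_fn, net, ensemble) {
  if (!length(ensemble)) stop("ensemble must be non-empty")
  raw <- metric_fn(net)
  nulls <- vapply(ensemble, metric_fn, numeric(1))
  null_mean <- mean(nulls)
  if (null_mean == 0) stop("null mean is zero; normalised metric undefined")
  structure(list(raw = raw, null_mean = null_mean,
                 normalized = raw / null_mean,
                 ensemble_size = length(ensemble)),
            class = "metric_result")
}

#' Node disruption index
#'
#' Slope of the ordinary least-squares regression of
#' `(individual - template)` node strengths on the template strengths.
#' Zero means the individual's strength profile matches the reference
#' group average; negative values indicate that normally strong nodes are
#' disproportionately weakened.
#'
#' @param subject numeric vector of the subject's node strengths.
#' @param template numeric vector of reference (e.g. control-group mean)
#'   strengths, non-degenerate.
#' @param template_id optional label of the reference group.
#' @return an `ndi_result`: `slope` (the NDI), `intercept`, `r_squared`,
#'   `template_id`.
#' @export
node_disruption_index <- function(subject, template, template_id = "CON") {
  if (length(subject) != length(template))
    stop("subject and template strengths must have equal length")
  if (var(template) == 0)
    stop("template strengths are degenerate (zero variance)")
  d <- subject - template
  xc <- template - mean(template)
  slope <- sum(xc * d) / sum(xc^2)
  intercept <- mean(d) - slope * mean(template)
  sst <- sum((d - mean(d))^2)
  ssr <- sum((d - intercept - slope * template)^2)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = if (sst > 0) 1 - ssr / sst else 1,
                 template_id = template_id),
            class = "ndi_result")
}

#' Group-average strength template
#'
#' Per-node arithmetic mean of subject strength vectors.  In leave-one-out
#' mode, each subject's template excludes that subject, for evaluating
#' members of the reference group against the rest of their group.
#'
#' @param strengths `S x N` matrix of node strengths (one row per subject).
#' @param leave_one_out return per-subject templates (`S x N` matrix)
#'   instead of a single vector.
#' @return numeric vector of length N, or an `S x N` matrix when
#'   `leave_one_out = TRUE`.
#' @export
group_template <- function(strengths, leave_one_out = FALSE) {
  strengths <- as.matrix(strengths)
  s <- nrow(strengths)
  if (s < 2) stop("need at least 2 subjects to form a template")
  if (!leave_one_out) return(colMeans(strengths))
  tot <- colSums(strengths)
  t(vapply(seq_len(s), function(i) (tot - strengths[i, ]) / (s - 1),
           numeric(ncol(strengths))))
}

#' Identify hub nodes and tally them per network
#'
#' Hubs are the top `round(fraction * N)` nodes by strength (ties broken by
#' node id ascending).  Counts are tallied over the analyzed functional
#' networks only; hubs falling in excluded networks are in `hub_set` but in
#' no count.
#'
#' @param strengths numeric vector of node strengths, in parcellation row
#'   order.
#' @param parc the matching `parcellation`.
#' @param fraction hub fraction, in (0, 1] (default 0.2).
#' @return a `hub_profile`: `hub_set` (node ids), `counts` (named integer
#'   vector over analyzed networks), `fraction`.
#' @export
identify_hubs <- function(strengths, parc, fraction = 0.2) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- length(strengths)
  if (n != nrow(parc)) stop("strengths and parcellation sizes differ")
  n_hubs <- max(1L, as.integer(round_half_away(fraction * n)))
  ord <- order(-strengths, parc$node_id)
  hubs <- ord[seq_len(n_hubs)]
  analyzed <- sort(unique(parc$network[parc$analyzed]))
  counts <- table(factor(parc$network[hubs], levels = analyzed))
  structure(list(hub_set = parc$node_id[hubs],
                 counts = setNames(as.integer(counts), names(counts)),
                 fraction = fraction),
            class = "hub_profile")
}

#' Intra- and inter-network block weights
#'
#' For each analyzed network A: the mean weight over all node pairs inside
#' A (`intra`, `NA` when A has fewer than 2 nodes) and the mean weight over
#' all pairs with exactly one endpoint in A (`inter`, network-to-rest).
#' Discarded pairs count as zero, so the means are comparable across
#' subjects at fixed density.
#'
#' @param net a `weighted_network`.
#' @param parc the matching `parcellation`.
#' @return data frame with columns `network`, `n_nodes`, `intra`, `inter`.
#' @export
network_block_weights <- function(net, parc) {
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  if (nrow(w) != nrow(parc)) stop("network and parcellation sizes differ")
  analyzed <- sort(unique(parc$network[parc$analyzed]))
  rows <- lapply(analyzed, function(a) {
    idx <- which(parc$network == a)
    intra <- if (length(idx) >= 2)
      mean(upper_tri_values(w[idx, idx, drop = FALSE])) else NA_real_
    inter <- mean(w[idx, -idx, drop = FALSE])
    data.frame(network = a, n_nodes = length(idx),
               intra = intra, inter = inter)
  })
  do.call(rbind, rows)
}
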