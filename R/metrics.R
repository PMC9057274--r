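#' Degree (coordination) moments of a network
#'
#' @param net a [planar_network()].
#' @return list with `mean_k` and `mu2_k`, the mean and second central
#'   moment (population variance) of the node-coordination distribution.
#'   The pristine honeycomb gives (3, 0).
#' @export
degree_moments <- function(net) {
  k <- lengths(net$adjacency)
  if (!length(k)) stop("empty network")
  m <- mean(k)
  list(mean_k = m, mu2_k = mean((k - m)^2))
}

#' Ring (polygon) statistics
#'
#' Moments of the ring-size multiset; for finite networks the outer face is
#' already excluded by [find_rings()]. For periodic networks
#' `mean_n = 2E/F` exactly, so a trivalent periodic network has mean ring
#' size 6; the finite-size analogue is [finite_ring_mean()].
#'
#' @param net a [planar_network()]; rings computed on demand.
#' @return list with `mean_n`, `mu2_n` (second central moment) and
#'   `N_rings`.
#' @export
ring_stats <- function(net) {
  rings <- net$rings
  if (is.null(rings)) rings <- find_rings(net)
  if (!length(rings)) stop("network has no rings")
  n <- lengths(rings)
  m <- mean(n)
  list(mean_n = m, mu2_n = mean((n - m)^2), N_rings = length(rings))
}

#' Euler finite-size correction to the mean ring size
#'
#' For a finite aperiodic trivalent network with N counted polygons, the
#' Euler characteristic gives N = E - V + 1 and trivalency gives V = 2E/3,
#' so E = 3(N - 1); with each edge contributing two polygon sides the mean
#' side count is 2E/N = 6(N - 1)/N. At N = 100 this evaluates to 5.94,
#' against the exact 6 of the periodic (or infinite) trivalent network.
#' The full derivation is worked through in the methods vignette and
#' cross-checked on the explicit [trivalent_patch()] construction.
#'
#' @param N number of rings (> 1).
#' @return the corrected mean ring size 6(N - 1)/N.
#' @export
finite_ring_mean <- function(N) {
  if (any(N <= 1)) stop("N must exceed 1")
  6 * (N - 1) / N
}

#' Ring-adjacency (dual) edge list
#'
#' One dual edge per shared primal edge between two distinct rings: a pair
#' of rings sharing m primal edges contributes m dual edges. On a periodic
#' network every primal edge borders exactly two rings, so the dual edge
#' count equals E. Finite-network edges bordering the (excluded) outer face
#' contribute nothing.
#'
#' @param net a [planar_network()]; rings computed on demand.
#' @return two-column matrix of ring sizes `(n_i, n_j)`, one row per dual
#'   edge, with ring indices in attribute `"ring_pair"`.
#' @export
ring_adjacency <- function(net) {
  rings <- net$rings
  if (is.null(rings)) rings <- find_rings(net)
  sizes <- lengths(rings)
  keys <- character(0); owner <- integer(0)
  for (r in seq_along(rings)) {
    rg <- rings[[r]]
    nxt <- c(rg[-1], rg[1])
    keys <- c(keys, paste(pmin(rg, nxt), pmax(rg, nxt)))
    owner <- c(owner, rep.int(r, length(rg)))
  }
  split_owner <- split(owner, keys)
  pairs <- do.call(rbind, lapply(split_owner, function(o) {
    if (length(o) == 2 && o[1] != o[2]) sort(o) else NULL
  }))
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
  out <- cbind(n_i = sizes[pairs[, 1]], n_j = sizes[pairs[, 2]])
  attr(out, "ring_pair") <- pairs
  out
}

#' Assortativity of ring sizes over the dual network
#'
#' Newman's degree-correlation formula applied to ring sizes across
#' adjacent ring pairs: the Pearson correlation of the two size columns
#' over the dual edge list with each edge counted in both orientations,
#'
#' \deqn{r = \frac{\langle n_i n_j\rangle - \langle \tfrac12(n_i+n_j)
#'   \rangle^2}{\langle \tfrac12(n_i^2+n_j^2)\rangle -
#'   \langle \tfrac12(n_i+n_j)\rangle^2}.}
#'
#' Bounded in \[-1, 1\]; negative values mean polygons neighbour dissimilar
#' polygons (the disassortative, Stone--Wales-defect regime), positive
#' values similar polygons (demixing), and 0 no preference. When every ring
#' has the same size the denominator vanishes and the statistic is
#' undefined: `NA` is returned (never 0, which has the distinct meaning
#' "no preference").
#'
#' @param dual_edges matrix of `(n_i, n_j)` pairs from [ring_adjacency()],
#'   or a [planar_network()] (converted automatically).
#' @return assortativity in \[-1, 1\], or `NA` when undefined.
#' @export
ring_assortativity <- function(dual_edges) {
  if (inherits(dual_edges, "planar_network"))
    dual_edges <- ring_adjacency(dual_edges)
  if (!nrow(dual_edges)) stop("empty dual edge list")
  a <- c(dual_edges[, 1], dual_edges[, 2])  # both orientations
  b <- c(dual_edges[, 2], dual_edges[, 1])
  num <- mean(a * b) - mean((a + b) / 2)^2
  den <- mean((a^2 + b^2) / 2) - mean((a + b) / 2)^2
  if (den <= .Machine$double.eps * mean(a^2)) return(NA_real_)
  num / den
}

#' Remove boundary-terminated edges from a finite network
#'
#' Image-derived networks are clipped by the frame: every edge with an
#' endpoint at (or flagged as terminated by) the boundary is removed from
#' the calculations, reducing the coordination of edge nodes. Dangling
#' chains left behind (degree <= 1 nodes) are then removed iteratively,
#' since they fall outside the polygon formalism. Rings are recomputed.
#'
#' @param net a finite [planar_network()].
#' @param boundary rectangle `c(xmin, ymin, xmax, ymax)`; defaults to the
#'   cell.
#' @param terminal optional logical vector flagging extraction-terminal
#'   nodes.
#' @param tol distance from the rectangle within which a node counts as
#'   boundary-terminated.
#' @return The pruned [planar_network()] (rings populated when any remain);
#'   attribute `"kept"` maps new node indices to input indices.
#' @export
boundary_prune <- function(net, boundary = NULL, terminal = NULL, tol = 1e-6) {
  if (net$cell$periodic) stop("boundary_prune applies to finite networks")
  V <- nrow(net$positions)
  if (is.null(boundary))
    boundary <- c(0, 0, net$cell$width, net$cell$height)
  flagged <- net$positions[, 1] <= boundary[1] + tol |
    net$positions[, 2] <= boundary[2] + tol |
    net$positions[, 1] >= boundary[3] - tol |
    net$positions[, 2] >= boundary[4] - tol
  if (!is.null(terminal)) flagged <- flagged | terminal
  ed <- network_edges(net)
  keep_edge <- !(flagged[ed[, 1]] | flagged[ed[, 2]])
  ed <- ed[keep_edge, , drop = FALSE]
  # iteratively drop dangling nodes (degree <= 1)
  repeat {
    deg <- tabulate(ed, nbins = V)
    dangling <- deg == 1
    if (!any(dangling)) break
    ed <- ed[!(dangling[ed[, 1]] | dangling[ed[, 2]]), , drop = FALSE]
  }
  keep_node <- tabulate(ed, nbins = V) > 0
  if (!any(keep_node)) stop("boundary pruning removed the entire network")
  map <- cumsum(keep_node)
  out <- planar_network(net$positions[keep_node, , drop = FALSE],
                        cbind(map[ed[, 1]], map[ed[, 2]]), net$cell)
  out$rings <- tryCatch(find_rings(out), error = function(e) NULL)
  attr(out, "kept") <- which(keep_node)
  out
}

#' Structural metric report of a network
#'
#' Assembles the full metric set used to place a network in the
#' {mu2(k), r} landscape: mean and second central moment of the node
#' coordination, mean and second central moment of the polygon side count,
#' ring count, ring-size assortativity, and the raw node/edge counts,
#' together with the validity flags of [validate_network()].
#'
#' @param net a [planar_network()]; rings computed on demand.
#' @return An object of class `metrics_report` (also a one-row data frame
#'   via [as.data.frame()]).
#' @export
network_report <- function(net) {
  if (is.null(net$rings)) net$rings <- find_rings(net)
  dm <- degree_moments(net)
  rs <- ring_stats(net)
  r <- ring_assortativity(net)
  val <- validate_network(net)
  structure(list(mean_k = dm$mean_k, mu2_k = dm$mu2_k,
                 mean_n = rs$mean_n, mu2_n = rs$mu2_n,
                 N_rings = rs$N_rings, r_assort = r,
                 V = nrow(net$positions), E = network_edge_count(net),
                 valid = isTRUE(val$all_passed)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "  <k> = %.4g  mu2(k) = %.4g  <n> = %.4g  mu2(n) = %.4g\n  N = %d  r = %s  (V = %d, E = %d%s)\n",
    x$mean_k, x$mu2_k, x$mean_n, x$mu2_n, x$N_rings,
    if (is.na(x$r_assort)) "undefined" else sprintf("%.4g", x$r_assort),
    x$V, x$E, if (x$valid) "" else "; INVALID"))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(mean_k = x$mean_k, mu2_k = x$mu2_k, mean_n = x$mean_n,
             mu2_n = x$mu2_n, N_rings = x$N_rings, r_assort = x$r_assort,
             V = x$V, E = x$E, valid = x$valid)
}
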