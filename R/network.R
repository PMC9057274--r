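#' Embedded 2D planar network
#'
#' A `planar_network` stores the continuous 2D embedding of a network: node
#' coordinates, a symmetric adjacency structure, an optional explicit ring
#' (face) list, and the simulation cell. Periodic cells are rectangular with
#' coordinates wrapped into `[0, width) x [0, height)`; a vertical wrap may
#' carry a horizontal shear offset, which is what makes a honeycomb lattice
#' with an odd number of hexagon rows strain-free on the torus.
#'
#' @param positions numeric matrix with one row per node and columns x, y.
#' @param edges two-column integer matrix of node indices (1-based).
#' @param cell list with elements `width`, `height`, `periodic`, and
#'   optionally `shear` (x-offset applied on a vertical wrap, default 0).
#' @param rings optional list of integer vectors, each a cyclic node sequence
#'   bounding one face. Computed on demand by [find_rings()] when absent.
#'
#' @return An object of class `planar_network`.
#' @seealso [build_honeycomb()], [find_rings()], [validate_network()]
#' @export
planar_network <- function(positions, edges, cell, rings = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) stop("positions must have two columns (x, y)")
  storage.mode(positions) <- "double"
  V <- nrow(positions)
  if (V == 0) stop("empty network: no nodes")
  cell <- as_cell(cell)
  if (!is.null(edges) && length(edges)) {
    edges <- matrix(as.integer(edges), ncol = 2)
    if (any(edges < 1 | edges > V)) stop("edge refers to an unknown node id")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("parallel edges are not allowed")
  } else {
    edges <- matrix(integer(0), ncol = 2)
  }
  adjacency <- rep(list(integer(0)), V)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adjacency[[a]] <- c(adjacency[[a]], b)
    adjacency[[b]] <- c(adjacency[[b]], a)
  }
  adjacency <- lapply(adjacency, sort)
  if (cell$periodic) positions <- wrap_positions(positions, cell)
  structure(list(positions = positions, adjacency = adjacency,
                 rings = rings, cell = cell),
            class = "planar_network")
}

as_cell <- function(cell) {
  stopifnot(is.list(cell))
  if (is.null(cell$shear)) cell$shear <- 0
  if (!(cell$width > 0) || !(cell$height > 0)) stop("cell dimensions must be positive")
  cell[c("width", "height", "periodic", "shear")]
}

#' @export
print.planar_network <- function(x, ...) {
  E <- network_edge_count(x)
  cat(sprintf("planar_network: %d nodes, %d edges (%s cell %.3g x %.3g)\n",
              nrow(x$positions), E,
              if (x$cell$periodic) "periodic" else "finite",
              x$cell$width, x$cell$height))
  if (!is.null(x$rings))
    cat(sprintf("  %d rings, sizes %s\n", length(x$rings),
                paste(range(lengths(x$rings)), collapse = "-")))
  invisible(x)
}

#' Number of edges of a planar network
#' @param net a [planar_network()].
#' @return integer edge count.
#' @export
network_edge_count <- function(net) {
  as.integer(sum(lengths(net$adjacency)) / 2)
}

#' Edge list of a planar network
#' @param net a [planar_network()].
#' @return two-column integer matrix, each row one undirected edge (a < b).
#' @export
network_edges <- function(net) {
  V <- nrow(net$positions)
  a <- rep.int(seq_len(V), lengths(net$adjacency))
  b <- unlist(net$adjacency, use.names = FALSE)
  keep <- a < b
  cbind(a[keep], b[keep])
}

wrap_positions <- function(pos, cell) {
  x <- pos[, 1]; y <- pos[, 2]
  m <- floor(y / cell$height)
  y <- y - m * cell$height
  x <- x - m * cell$shear
  x <- x - floor(x / cell$width) * cell$width
  cbind(x, y, deparse.level = 0)
}

#' Minimum-image displacement between two nodes
#'
#' Returns the vector from node `a` to node `b`. In a periodic cell the
#' minimum-image convention is applied (with the cell's shear taken into
#' account on vertical wraps); in a finite cell the plain coordinate
#' difference is returned.
#'
#' @param net a [planar_network()].
#' @param a,b node indices.
#' @return length-2 numeric vector.
#' @export
displacement <- function(net, a, b) {
  V <- nrow(net$positions)
  if (any(c(a, b) < 1) || any(c(a, b) > V)) stop("unknown node id")
  d <- net$positions[b, ] - net$positions[a, ]
  if (net$cell$periodic) {
    m <- round(d[2] / net$cell$height)
    d[2] <- d[2] - m * net$cell$height
    d[1] <- d[1] - m * net$cell$shear
    d[1] <- d[1] - round(d[1] / net$cell$width) * net$cell$width
  }
  unname(d)
}

# displacement for many pairs at once; rows of ab are (from, to)
displacement_many <- function(net, ab) {
  d <- net$positions[ab[, 2], , drop = FALSE] - net$positions[ab[, 1], , drop = FALSE]
  if (net$cell$periodic) {
    m <- round(d[, 2] / net$cell$height)
    d[, 2] <- d[, 2] - m * net$cell$height
    d[, 1] <- d[, 1] - m * net$cell$shear
    d[, 1] <- d[, 1] - round(d[, 1] / net$cell$width) * net$cell$width
  }
  d
}

#' Build a periodic honeycomb lattice
#'
#' Constructs the strain-free trivalent honeycomb starting configuration:
#' `nx * ny` hexagonal rings on a periodic rectangular cell of width
#' `nx * sqrt(3) * bond_length` and height `ny * 1.5 * bond_length`. All
#' nodes have degree 3 and all nearest-neighbour distances equal
#' `bond_length`. When `ny` is odd the vertical wrap carries a shear of
#' `sqrt(3)/2 * bond_length`, which keeps the lattice periodic.
#'
#' @param nx,ny number of hexagon columns and rows; both must be >= 2.
#' @param bond_length nearest-neighbour distance (length units).
#' @return A periodic [planar_network()] with rings populated.
#' @export
build_honeycomb <- function(nx, ny, bond_length = 1) {
  if (nx < 2 || ny < 2) stop("honeycomb needs nx >= 2 and ny >= 2 (periodic wrapping)")
  b <- bond_length
  s3 <- sqrt(3)
  V <- 2L * nx * ny
  pos <- matrix(0, V, 2)
  # node ids: cell (r, c) holds n1 = 2*(r*nx + c) + 1 and n2 = n1 + 1
  id1 <- function(r, c) 2L * ((r %% ny) * nx + (c %% nx)) + 1L
  edges <- matrix(0L, 3L * nx * ny, 2)
  k <- 0L
  for (r in 0:(ny - 1)) {
    off <- 0.5 * (r %% 2)
    for (cc in 0:(nx - 1)) {
      n1 <- id1(r, cc); n2 <- n1 + 1L
      x1 <- s3 * b * (cc + off)
      pos[n1, ] <- c(x1, 1.5 * b * r)
      pos[n2, ] <- c(x1 + s3 / 2 * b, 1.5 * b * r + 0.5 * b)
      cprime <- if (r %% 2 == 0) cc else cc + 1L
      e <- rbind(c(n1, n2),
                 c(n2, id1(r, cc + 1L)),
                 c(n2, id1(r + 1L, cprime)))
      edges[k + 1:3, ] <- e
      k <- k + 3L
    }
  }
  cell <- list(width = nx * s3 * b, height = ny * 1.5 * b,
               periodic = TRUE, shear = if (ny %% 2 == 1) s3 / 2 * b else 0)
  net <- planar_network(pos, edges, cell)
  net$rings <- find_rings(net)
  net
}

#' Validate the topological invariants of a network
#'
#' Report-only check of the invariants every network produced by the package
#' must satisfy: adjacency symmetry, no self-loops, minimum degree 2, the
#' Euler relation (V - E + F = 0 on the periodic torus, 2 for a finite net
#' when the excluded outer face is counted back in), the ring-side sum
#' `sum(n_i) = 2E` (periodic), each edge bordering exactly two rings
#' (periodic), and consistency of each ring with the adjacency.
#'
#' @param net a [planar_network()].
#' @param rings optional precomputed ring list; defaults to `net$rings` or
#'   [find_rings()].
#' @return A list of logical check results with class `network_validation`.
#' @export
validate_network <- function(net, rings = NULL) {
  V <- nrow(net$positions)
  adj <- net$adjacency
  sym <- TRUE; selfloop <- FALSE
  for (i in seq_len(V)) {
    if (any(adj[[i]] == i)) selfloop <- TRUE
    for (j in adj[[i]]) if (!(i %in% adj[[j]])) sym <- FALSE
  }
  degrees_ok <- all(lengths(adj) >= 2)
  if (is.null(rings)) rings <- net$rings
  if (is.null(rings) && sym && !selfloop)
    rings <- tryCatch(find_rings(net), error = function(e) NULL)
  E <- network_edge_count(net)
  checks <- list(symmetric = sym, no_self_loops = !selfloop,
                 degrees_ok = degrees_ok)
  if (!is.null(rings)) {
    F_ <- length(rings)
    if (net$cell$periodic) {
      checks$euler <- (V - E + F_) == 0
      checks$ring_side_sum <- sum(lengths(rings)) == 2 * E
      # every edge borders exactly two rings
      keys <- unlist(lapply(rings, function(r) {
        nxt <- c(r[-1], r[1])
        paste(pmin(r, nxt), pmax(r, nxt))
      }))
      tab <- table(keys)
      checks$edges_two_rings <- length(tab) == E && all(tab == 2)
    } else {
      checks$euler <- (V - E + F_ + 1) == 2  # outer face counted back in
    }
    cons <- TRUE
    for (r in rings) {
      nxt <- c(r[-1], r[1])
      for (q in seq_along(r)) if (!(nxt[q] %in% adj[[r[q]]])) cons <- FALSE
      if (anyDuplicated(r)) cons <- FALSE
    }
    checks$rings_consistent <- cons
  } else {
    checks$euler <- NA
  }
  checks$all_passed <- all(unlist(checks[!is.na(checks)]))
  structure(checks, class = "network_validation")
}

#' @export
print.network_validation <- function(x, ...) {
  cat("network validation:\n")
  for (nm in setdiff(names(x), "all_passed"))
    cat(sprintf("  %-18s %s\n", nm,
                if (is.na(x[[nm]])) "skipped" else if (x[[nm]]) "pass" else "FAIL"))
  cat(if (isTRUE(x$all_passed)) "  all checks passed\n" else "  FAILURES present\n")
  invisible(x)
}

#' Cut a periodic network open into a finite one
#'
#' Removes every edge whose minimum-image vector differs from the plain
#' coordinate difference (i.e. edges crossing the periodic seam), yielding a
#' finite network in the same rectangular window. Boundary nodes lose degree
#' accordingly. Rings are not carried over; recompute with [find_rings()].
#'
#' @param net a periodic [planar_network()].
#' @param tol tolerance for detecting a seam crossing.
#' @return A finite [planar_network()].
#' @export
unwrap_network <- function(net, tol = 1e-9) {
  if (!net$cell$periodic) return(net)
  ed <- network_edges(net)
  keep <- logical(nrow(ed))
  for (i in seq_len(nrow(ed))) {
    d <- displacement(net, ed[i, 1], ed[i, 2])
    plain <- net$positions[ed[i, 2], ] - net$positions[ed[i, 1], ]
    keep[i] <- max(abs(d - plain)) < tol
  }
  cell <- net$cell; cell$periodic <- FALSE; cell$shear <- 0
  planar_network(net$positions, ed[keep, , drop = FALSE], cell)
}

#' @export
plot.planar_network <- function(x, node_cex = 0.3, ...) {
  ed <- network_edges(x)
  d <- displacement_many(x, ed)
  p0 <- x$positions[ed[, 1], , drop = FALSE]
  graphics::plot(NA, xlim = c(0, x$cell$width), ylim = c(0, x$cell$height),
                 asp = 1, xlab = "x", ylab = "y", ...)
  graphics::segments(p0[, 1], p0[, 2], p0[, 1] + d[, 1], p0[, 2] + d[, 2])
  graphics::points(x$positions, pch = 16, cex = node_cex)
  invisible(x)
}

# breadth-first ball of given hop radius around a set of centres
graph_ball <- function(adjacency, centers, radius) {
  dist <- rep(-1L, length(adjacency))
  queue <- unique(as.integer(centers))
  dist[queue] <- 0L
  out <- integer(0)
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    out <- c(out, u)
    if (dist[u] < radius) {
      for (w in adjacency[[u]]) if (dist[w] < 0) {
        dist[w] <- dist[u] + 1L
        queue <- c(queue, w)
      }
    }
  }
  sort(out)
}
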