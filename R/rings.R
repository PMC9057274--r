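#' Enumerate the faces of an embedded planar network
#'
#' Traverses all faces of the embedding with the standard half-edge
#' leftmost-turn rule: incident edges at each node are sorted by angle (ties
#' broken by node id) and the successor of a directed edge (u, v) is the edge
#' from v to the angular predecessor of u among v's neighbours. On a periodic
#' cell this enumerates all F = E - V faces of the torus embedding; on a
#' finite cell the outer face of each connected component (the face of
#' largest absolute enclosed area, cross-checked by its signed-area sign) is
#' identified and excluded.
#'
#' @param net a [planar_network()].
#' @return A list of integer vectors, each the cyclic node sequence of one
#'   ring. Finite networks exclude the outer face.
#' @export
find_rings <- function(net) {
  V <- nrow(net$positions)
  adj <- net$adjacency
  if (all(lengths(adj) == 0)) stop("empty network: no edges to traverse")
  # per-node neighbours in increasing angular order
  sorted_nb <- vector("list", V)
  pos_in <- vector("list", V)  # lookup: position of neighbour id in sorted order
  for (v in seq_len(V)) {
    nb <- adj[[v]]
    if (!length(nb)) next
    d <- displacement_many(net, cbind(rep.int(v, length(nb)), nb))
    ang <- atan2(d[, 2], d[, 1])
    o <- order(ang, nb)
    sorted_nb[[v]] <- nb[o]
    lk <- integer(0)
    lk[nb[o]] <- seq_along(nb)
    pos_in[[v]] <- lk
  }
  # directed edge indexing
  deg <- lengths(adj)
  first <- cumsum(c(0L, deg[-V]))  # directed edge block start per node
  de_id <- function(v, slot) first[v] + slot
  used <- logical(sum(deg))
  faces <- list()
  nf <- 0L
  for (v0 in seq_len(V)) {
    for (s0 in seq_len(deg[v0])) {
      if (used[de_id(v0, s0)]) next
      u <- v0; slot <- s0
      face <- integer(0)
      repeat {
        used[de_id(u, slot)] <- TRUE
        w <- sorted_nb[[u]][slot]
        face <- c(face, u)
        # next directed edge: at w, angular predecessor of u
        iu <- pos_in[[w]][u]
        slot <- if (iu == 1L) length(sorted_nb[[w]]) else iu - 1L
        u <- w
        if (u == v0 && slot == s0) break
        if (length(face) > 2L * sum(deg)) stop("face traversal failed to close")
      }
      nf <- nf + 1L
      faces[[nf]] <- face
    }
  }
  E <- network_edge_count(net)
  if (net$cell$periodic) {
    if (V - E + length(faces) != 0)
      stop("topology error: face count inconsistent with a torus embedding ",
           "(crossing edges?)")
    return(faces)
  }
  # finite: drop the outer face of each connected component
  comp <- component_labels(adj)
  ncomp <- max(comp)
  if (ncomp > 1) warning("network is disconnected; faces traversed per component")
  areas <- vapply(faces, function(f) polygon_area(net$positions[f, , drop = FALSE]),
                  numeric(1))
  face_comp <- vapply(faces, function(f) comp[f[1]], integer(1))
  drop <- integer(0)
  for (cmp in seq_len(ncomp)) {
    idx <- which(face_comp == cmp)
    if (!length(idx)) next
    out <- idx[which.max(abs(areas[idx]))]
    drop <- c(drop, out)
  }
  faces[-drop]
}

# signed (shoelace) area of a polygon given its vertex coordinates in order
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

component_labels <- function(adjacency) {
  V <- length(adjacency)
  comp <- integer(V)
  cur <- 0L
  for (v in seq_len(V)) {
    if (comp[v]) next
    cur <- cur + 1L
    queue <- v; comp[v] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adjacency[[u]]) if (!comp[w]) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# rings as a sorted size multiset, convenient for comparisons in tests
ring_size_multiset <- function(rings) sort(lengths(rings))

#' Explicitly constructed finite trivalent patch
#'
#' Builds a finite planar network in which every node has degree exactly 3
#' and which has `n_rings` faces once the outer face is excluded: an
#' (n_rings - 1)-gonal prism drawn as two concentric regular polygons joined
#' by rungs. Used to cross-check the Euler finite-size correction of
#' [finite_ring_mean()] on a concrete graph: the patch has V = 2(N - 1)
#' nodes and E = 3(N - 1) edges, so 2E/N equals `finite_ring_mean(N)`.
#'
#' @param n_rings number of counted rings N (>= 4).
#' @return A finite [planar_network()] with rings populated.
#' @export
trivalent_patch <- function(n_rings) {
  if (n_rings < 4) stop("patch needs at least 4 rings")
  m <- n_rings - 1L                       # prism over an m-gon
  th <- 2 * pi * (seq_len(m) - 1) / m
  r_in <- 1; r_out <- 2
  ctr <- 2.5
  pos <- rbind(cbind(ctr + r_in * cos(th), ctr + r_in * sin(th)),
               cbind(ctr + r_out * cos(th), ctr + r_out * sin(th)))
  nxt <- c(seq_len(m)[-1], 1L)
  edges <- rbind(cbind(seq_len(m), nxt),            # inner polygon
                 cbind(m + seq_len(m), m + nxt),    # outer polygon
                 cbind(seq_len(m), m + seq_len(m))) # rungs
  net <- planar_network(pos, edges,
                        list(width = 5, height = 5, periodic = FALSE))
  net$rings <- find_rings(net)
  net
}
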