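#' Render a network to a binary raster
#'
#' Draws every edge as a straight stroke of the given width into a binary
#' image, emulating an idealised micrograph of the network. Periodic
#' networks are first cut open with [unwrap_network()]. Rendering is
#' deterministic for fixed inputs. Raster convention: single channel,
#' foreground = TRUE, pixel-centre coordinates, row 1 at the top
#' (converted back to y-up coordinates on extraction).
#'
#' @param net a [planar_network()].
#' @param scale pixels per length unit (> 0).
#' @param line_width stroke width in pixels.
#' @param pad background margin in pixels added around the cell (keeps
#'   strokes at the cell boundary unclipped); 0 reproduces image dimensions
#'   equal to the cell dimensions times `scale`, rounded up.
#' @return An object of class `raster_image`: list with `pixels` (logical
#'   matrix), `scale`, `pad`.
#' @export
render_network <- function(net, scale = 20, line_width = 3, pad = 0) {
  if (net$cell$periodic) net <- unwrap_network(net)
  W <- as.integer(ceiling(net$cell$width * scale)) + 2L * pad
  H <- as.integer(ceiling(net$cell$height * scale)) + 2L * pad
  pos <- net$positions
  if (nrow(pos) > 1) {
    dmin <- min(stats::dist(pos))
    if (dmin * scale < 2)
      stop("resolution error: distinct nodes collide onto one pixel at this scale")
  }
  img <- matrix(FALSE, H, W)
  ed <- network_edges(net)
  if (nrow(ed)) {
    # disc offsets for the stroke width
    rad <- max(line_width / 2, 0.5)
    off <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                       dc = -ceiling(rad):ceiling(rad))
    off <- off[off$dr^2 + off$dc^2 <= rad^2, ]
    colc <- function(x) pad + x * scale + 0.5
    rowc <- function(y) H + 0.5 - pad - y * scale
    for (i in seq_len(nrow(ed))) {
      p1 <- pos[ed[i, 1], ]; p2 <- pos[ed[i, 2], ]
      c1 <- colc(p1[1]); r1 <- rowc(p1[2])
      c2 <- colc(p2[1]); r2 <- rowc(p2[2])
      npts <- max(2L, ceiling(3 * sqrt((c2 - c1)^2 + (r2 - r1)^2)))
      tt <- seq(0, 1, length.out = npts)
      rr <- round(r1 + tt * (r2 - r1)); cc <- round(c1 + tt * (c2 - c1))
      allr <- rep(rr, each = nrow(off)) + off$dr
      allc <- rep(cc, each = nrow(off)) + off$dc
      ok <- allr >= 1 & allr <= H & allc >= 1 & allc <= W
      img[cbind(allr[ok], allc[ok])] <- TRUE
    }
  }
  structure(list(pixels = img, scale = scale, pad = pad),
            class = "raster_image")
}

#' Write / read a binary raster
#'
#' Single-channel PNG or TIFF; foreground is any non-zero pixel.
#'
#' @param img a `raster_image` (for writing).
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param scale pixels per length unit to attach on read.
#' @return `read_raster()` returns a `raster_image`; `write_raster()`
#'   returns `path` invisibly.
#' @export
write_raster <- function(img, path) {
  m <- img$pixels * 1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(m, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(m, path)
  else stop("unsupported raster format: ", ext)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, scale = 1) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported raster format: ", ext)
  if (length(dim(m)) == 3) m <- m[, , 1]
  structure(list(pixels = m > 0, scale = scale, pad = 0L),
            class = "raster_image")
}

# value of the neighbour at offset (dr, dc) for every pixel (zero-padded):
# out(r, c) = m(r + dr, c + dc)
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- max(1, 1 - dr):min(H, H - dr)
  cs <- max(1, 1 - dc):min(W, W - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Skeletonise a binary image to unit width
#'
#' Standard Zhang--Suen morphological thinning: pixels are iteratively
#' deleted in two alternating sub-passes until the foreground is one pixel
#' wide, preserving connectivity. Sub-pixel accuracy is not attempted.
#'
#' @param m logical matrix (foreground = TRUE).
#' @return thinned logical matrix.
#' @export
skeletonize <- function(m) {
  m <- m > 0
  # neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW (row 1 = top)
  sh <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
             c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      P <- lapply(sh, function(s) shift_mat(m, s[1], s[2]))
      B <- Reduce(`+`, P)
      seqP <- c(P, P[1])
      A <- Reduce(`+`, lapply(1:8, function(i) (!seqP[[i]]) & seqP[[i + 1]]))
      if (phase == 1)
        cond <- (!P[[1]] | !P[[3]] | !P[[5]]) & (!P[[3]] | !P[[5]] | !P[[7]])
      else
        cond <- (!P[[1]] | !P[[3]] | !P[[7]]) & (!P[[1]] | !P[[5]] | !P[[7]])
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { m <- m & !del; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Settings for skeleton-to-graph extraction
#'
#' @param junction_merge_radius junction skeleton pixels closer than this
#'   (in pixels) collapse into a single node.
#' @param min_branch_length spur branches shorter than this many pixels are
#'   dropped.
#' @param boundary_margin nodes within this many pixels of the frame are
#'   flagged as boundary-terminated (consumed by [boundary_prune()]).
#' @param mode `"contract"` suppresses degree-2 chain pixels between
#'   junctions into single edges (their count is recorded); `"keep"`
#'   retains every chain pixel as a degree-2 node.
#' @return An object of class `extraction_settings`.
#' @export
extraction_settings <- function(junction_merge_radius = 3,
                                min_branch_length = 5,
                                boundary_margin = 4,
                                mode = c("contract", "keep")) {
  if (junction_merge_radius < 0 || min_branch_length < 0 || boundary_margin < 0)
    stop("extraction settings must be non-negative")
  structure(list(junction_merge_radius = junction_merge_radius,
                 min_branch_length = min_branch_length,
                 boundary_margin = boundary_margin,
                 mode = match.arg(mode)), class = "extraction_settings")
}

#' Extract a graph from a binary raster
#'
#' Simplified skeleton tracer standing in for ridge-detection micrograph
#' analysis: the image is thinned to unit width, skeleton pixels are
#' classified by their Rutovitz crossing number (1 = terminal, 2 = path,
#' 3 or more = junction; the crossing number is robust against the spurious
#' 3-neighbour pixels thinning leaves at staircase corners, where a plain
#' 8-neighbour count is not), junction clusters within
#' `junction_merge_radius` collapse
#' into single nodes, paths between nodes are traced into edges, spur
#' branches shorter than `min_branch_length` are dropped, and nodes within
#' `boundary_margin` of the frame are flagged as boundary-terminated.
#' Closed junction-free curves are retained as rings via synthetic degree-2
#' division points. Extraction is deterministic for a fixed image and
#' settings.
#'
#' @param img a `raster_image` (see [render_network()], [read_raster()]).
#' @param settings an [extraction_settings()].
#' @return A finite [planar_network()] with attributes `terminal` (logical
#'   per-node flags) and `suppressed_degree2` (count of contracted chain
#'   pixels).
#' @export
extract_graph <- function(img, settings = extraction_settings()) {
  m <- img$pixels
  if (!is.logical(m)) {
    vals <- unique(as.vector(m))
    if (!all(vals %in% c(0, 1))) stop("format error: input raster is not binary")
    m <- m > 0
  }
  if (!any(m)) stop("empty-extraction error: image has no foreground")
  scale <- img$scale; pad <- img$pad
  H <- nrow(m); W <- ncol(m)
  sk <- skeletonize(m)
  # Rutovitz crossing number: branch points have >= 3 dark-to-bright
  # transitions around the 8-neighbourhood (robust against the spurious
  # 3-neighbour pixels thinning leaves at staircase corners)
  sh <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
             c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  P <- lapply(sh, function(s) shift_mat(sk, s[1], s[2]))
  seqP <- c(P, P[1])
  crossing <- Reduce(`+`, lapply(1:8, function(i) (!seqP[[i]]) & seqP[[i + 1]]))
  junction <- sk & crossing >= 3

  # --- junction clustering -------------------------------------------------
  jidx <- which(junction, arr.ind = TRUE)
  ncl <- 0L
  clid <- integer(nrow(jidx))
  if (nrow(jidx) > 0) {
    radius <- max(settings$junction_merge_radius, 1.5)
    d <- as.matrix(stats::dist(jidx))
    g <- igraph::graph_from_adjacency_matrix(d <= radius, mode = "undirected",
                                             diag = FALSE)
    clid <- as.integer(igraph::components(g)$membership)
    ncl <- max(clid)
  }
  centroids <- if (ncl > 0)
    t(vapply(seq_len(ncl), function(cl)
      colMeans(jidx[clid == cl, , drop = FALSE]), numeric(2)))
  else matrix(numeric(0), ncol = 2)

  # cluster id per pixel over the one-pixel-dilated junction regions (0 =
  # path pixel); dilation is needed because branch ends stay 8-connected
  # around a removed junction pixel
  pixcl <- matrix(0L, H, W)
  if (nrow(jidx)) {
    for (i in seq_len(nrow(jidx))) {
      rs <- max(1, jidx[i, 1] - 1):min(H, jidx[i, 1] + 1)
      cs <- max(1, jidx[i, 2] - 1):min(W, jidx[i, 2] + 1)
      blk <- pixcl[rs, cs]
      blk[sk[rs, cs] & blk == 0L] <- clid[i]
      pixcl[rs, cs] <- blk
    }
    pixcl[jidx] <- clid
  }

  # --- path components -----------------------------------------------------
  path <- sk & pixcl == 0L
  lab <- label_components(path)
  ncomp <- attr(lab, "n")

  nodes <- centroids                     # pixel (row, col) coordinates
  node_terminal <- rep(FALSE, ncl)
  edges <- matrix(integer(0), ncol = 2)
  suppressed <- 0L

  add_node <- function(rc, terminal = FALSE) {
    nodes <<- rbind(nodes, rc)
    node_terminal <<- c(node_terminal, terminal)
    nrow(nodes)
  }
  add_edge <- function(a, b, via = NULL) {
    # insert synthetic division points when a direct edge would create a
    # self-loop or a parallel edge
    dup <- function(a, b) a == b ||
      (nrow(edges) > 0 && any(edges[, 1] == min(a, b) & edges[, 2] == max(a, b)))
    if (!dup(a, b)) {
      edges <<- rbind(edges, c(min(a, b), max(a, b)))
    } else if (!is.null(via) && nrow(via) >= 2) {
      q <- unique(round(stats::quantile(seq_len(nrow(via)), c(1 / 3, 2 / 3))))
      if (length(q) == 1) q <- c(q, q)
      m1 <- add_node(via[q[1], , drop = FALSE])
      m2 <- add_node(via[q[2], , drop = FALSE])
      edges <<- rbind(edges, c(min(a, m1), max(a, m1)),
                      c(min(m1, m2), max(m1, m2)),
                      c(min(m2, b), max(m2, b)))
    }  # else: unrepresentable degenerate contact; drop silently
  }
  nearest_cluster <- function(rc) {
    # cluster adjacent (Chebyshev <= 1) to a pixel, 0 if none
    rs <- max(1, rc[1] - 1):min(H, rc[1] + 1)
    cs <- max(1, rc[2] - 1):min(W, rc[2] + 1)
    cl <- pixcl[rs, cs, drop = FALSE]
    cl <- cl[cl > 0]
    if (length(cl)) cl[1] else 0L
  }

  for (cmp in seq_len(ncomp)) {
    px <- which(lab == cmp, arr.ind = TRUE)
    ordered <- walk_chain(px)
    n <- nrow(ordered)
    is_cycle <- attr(ordered, "cycle")
    c1 <- nearest_cluster(ordered[1, ])
    c2 <- nearest_cluster(ordered[n, ])
    if (c1 == 0 || c2 == 0) {
      # walk ordering can be thrown off by small side twigs; fall back to
      # scanning every component pixel for cluster contacts
      contacts <- unique(vapply(seq_len(n), function(i) nearest_cluster(ordered[i, ]),
                                integer(1)))
      contacts <- setdiff(contacts, c(c1, c2, 0L))
      if (c1 == 0 && length(contacts)) { c1 <- contacts[1]; contacts <- contacts[-1] }
      if (c2 == 0 && length(contacts)) c2 <- contacts[1]
    }
    if (c1 > 0 && c2 > 0) {
      if (settings$mode == "contract") {
        add_edge(c1, c2, via = ordered)
        suppressed <- suppressed + n
      } else {
        prev <- c1
        for (i in seq_len(n)) { cur <- add_node(ordered[i, , drop = FALSE]); add_edge(prev, cur); prev <- cur }
        add_edge(prev, c2)
      }
    } else if (c1 > 0 || c2 > 0) {
      # spur: one attached end, one free end
      if (n >= settings$min_branch_length) {
        att <- if (c1 > 0) c1 else c2
        free <- if (c1 > 0) ordered[n, , drop = FALSE] else ordered[1, , drop = FALSE]
        tnode <- add_node(free, terminal = TRUE)
        add_edge(att, tnode, via = ordered)
        suppressed <- suppressed + n - 1L
      }
    } else if (is_cycle) {
      # closed junction-free curve: retain as a ring via synthetic
      # degree-2 division points (three, the minimal simple cycle)
      if (n >= settings$min_branch_length) {
        at <- unique(pmax(1, round(n * c(1 / 6, 3 / 6, 5 / 6))))
        ids <- vapply(at, function(i) add_node(ordered[i, , drop = FALSE]),
                      integer(1))
        if (length(ids) == 3) {
          add_edge(ids[1], ids[2]); add_edge(ids[2], ids[3])
          add_edge(ids[3], ids[1])
          suppressed <- suppressed + n - 3L
        }
      }
    } else {
      # isolated open stroke
      if (n >= settings$min_branch_length) {
        a <- add_node(ordered[1, , drop = FALSE], terminal = TRUE)
        b <- add_node(ordered[n, , drop = FALSE], terminal = TRUE)
        add_edge(a, b, via = ordered)
        suppressed <- suppressed + n - 2L
      }
    }
  }

  if (nrow(nodes) == 0 || nrow(edges) == 0)
    stop("empty-extraction error: no edges traced")
  used <- sort(unique(as.vector(edges)))
  map <- integer(nrow(nodes)); map[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  node_terminal <- node_terminal[used]
  edges <- cbind(map[edges[, 1]], map[edges[, 2]])

  # pixel (row, col) -> y-up unit coordinates
  xs <- (nodes[, 2] - 0.5 - pad) / scale
  ys <- (H + 0.5 - pad - nodes[, 1]) / scale
  near_frame <- nodes[, 1] <= settings$boundary_margin |
    nodes[, 2] <= settings$boundary_margin |
    nodes[, 1] > H - settings$boundary_margin |
    nodes[, 2] > W - settings$boundary_margin
  cell <- list(width = W / scale, height = H / scale, periodic = FALSE)
  net <- planar_network(cbind(xs, ys), edges, cell)
  terminal <- node_terminal | near_frame
  if (settings$mode == "contract") {
    # corner artifacts of thinning surface as spurious degree-2 junction
    # nodes; contracting the traced graph removes them
    con <- contract_degree2(net)
    suppressed <- suppressed + attr(con, "suppressed_degree2")
    terminal <- terminal[attr(con, "kept")]
    net <- con
  }
  attr(net, "terminal") <- terminal
  attr(net, "suppressed_degree2") <- suppressed
  net
}

# label 8-connected components of a logical matrix
label_components <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  n <- 0L
  idx <- which(m)
  for (start in idx) {
    if (lab[start]) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% H + 1L; cc <- (p - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W) {
          q <- (c2 - 1L) * H + rr
          if (m[q] && !lab[q]) { lab[q] <- n; queue <- c(queue, q) }
        }
      }
    }
  }
  attr(lab, "n") <- n
  lab
}

# order the pixels of an 8-connected chain component; attr "cycle" marks
# closed curves
walk_chain <- function(px) {
  n <- nrow(px)
  if (n == 1) {
    out <- px; attr(out, "cycle") <- FALSE; return(out)
  }
  key <- paste(px[, 1], px[, 2])
  lk <- seq_len(n); names(lk) <- key
  nbrs <- lapply(seq_len(n), function(i) {
    cand <- expand.grid(r = px[i, 1] + (-1:1), c = px[i, 2] + (-1:1))
    ids <- lk[paste(cand$r, cand$c)]
    ids <- ids[!is.na(ids)]
    setdiff(unname(ids), i)
  })
  degs <- lengths(nbrs)
  start <- if (any(degs <= 1)) which(degs <= 1)[1] else 1L
  visited <- logical(n)
  order_out <- integer(0)
  cur <- start
  repeat {
    visited[cur] <- TRUE
    order_out <- c(order_out, cur)
    nxt <- nbrs[[cur]][!visited[nbrs[[cur]]]]
    if (!length(nxt)) break
    cur <- nxt[1]
  }
  # unvisited leftovers (thick corners): append by proximity
  if (any(!visited)) order_out <- c(order_out, which(!visited))
  out <- px[order_out, , drop = FALSE]
  # a closed curve has no free end; staircase corners may have 3 neighbours
  attr(out, "cycle") <- all(degs >= 2)
  out
}

#' Suppress degree-2 nodes of a network
#'
#' Contracts chains of 2-coordinate nodes into single edges, the quotient
#' under which a traced skeleton graph and its source network agree. Where
#' contraction would create a self-loop or parallel edge (small cycles),
#' the degree-2 node is kept. The number of suppressed nodes is recorded,
#' mirroring the ambiguity of whether a network strand is one biomolecule
#' or two.
#'
#' @param net a finite [planar_network()].
#' @return The contracted network with attribute `"suppressed_degree2"`.
#' @export
contract_degree2 <- function(net) {
  adj <- net$adjacency
  alive <- rep(TRUE, length(adj))
  suppressed <- 0L
  repeat {
    deg <- lengths(adj)
    cand <- which(alive & deg == 2)
    done <- TRUE
    for (v in cand) {
      ab <- adj[[v]]
      if (length(ab) != 2) next
      a <- ab[1]; b <- ab[2]
      if (a == b || b %in% adj[[a]]) next  # would create loop/parallel edge
      adj[[a]] <- sort(c(setdiff(adj[[a]], v), b))
      adj[[b]] <- sort(c(setdiff(adj[[b]], v), a))
      adj[[v]] <- integer(0)
      alive[v] <- FALSE
      suppressed <- suppressed + 1L
      done <- FALSE
    }
    if (done) break
  }
  keep <- which(alive)
  map <- integer(length(adj)); map[keep] <- seq_along(keep)
  new_adj <- lapply(adj[keep], function(x) sort(map[x]))
  ed <- do.call(rbind, lapply(seq_along(new_adj), function(i) {
    js <- new_adj[[i]][new_adj[[i]] > i]
    if (length(js)) cbind(i, js) else NULL
  }))
  out <- planar_network(net$positions[keep, , drop = FALSE], ed, net$cell)
  attr(out, "suppressed_degree2") <- suppressed
  attr(out, "kept") <- keep
  out
}

#' Render/extract round-trip comparison
#'
#' Quantifies how faithfully the skeleton tracer recovers a known network:
#' the source is rendered, extracted, boundary-pruned and compared, metric
#' by metric, against the boundary-pruned and degree-2-contracted source
#' (contraction is the shared quotient of the two representations). Used as
#' a regression surface for the caution that image-derived metrics carry
#' methodological uncertainty.
#'
#' @param net a finite [planar_network()] (unwrap periodic nets first).
#' @param scale pixels per length unit for the render.
#' @param line_width stroke width in pixels.
#' @param settings an [extraction_settings()].
#' @param pad render padding in pixels.
#' @return A list with `source_report`, `extracted_report`, `deltas`
#'   (named numeric differences), and `ring_multiset_match`.
#' @export
roundtrip_check <- function(net, scale = 25, line_width = 3,
                            settings = extraction_settings(), pad = 6) {
  if (net$cell$periodic) stop("roundtrip_check needs a finite network")
  img <- render_network(net, scale = scale, line_width = line_width, pad = pad)
  ext <- extract_graph(img, settings)
  ext_p <- boundary_prune(ext, terminal = attr(ext, "terminal"))
  # contract the source to the shared quotient and drop its dangling chains
  # the same way the extracted side is pruned
  src_c <- boundary_prune(contract_degree2(net),
                          boundary = c(-Inf, -Inf, Inf, Inf))
  src_rep <- network_report(src_c)
  ext_rep <- network_report(ext_p)
  fields <- c("mean_k", "mu2_k", "mean_n", "mu2_n", "N_rings", "r_assort")
  deltas <- vapply(fields, function(f)
    as.numeric(ext_rep[[f]]) - as.numeric(src_rep[[f]]), numeric(1))
  list(source_report = src_rep, extracted_report = ext_rep, deltas = deltas,
       ring_multiset_match = identical(
         ring_size_multiset(src_c$rings %||% find_rings(src_c)),
         ring_size_multiset(ext_p$rings %||% find_rings(ext_p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
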