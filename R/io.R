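#' Read and write planar networks
#'
#' Two interchange formats are supported. The JSON dialect is
#' `{"cell": {"width", "height", "periodic"}, "nodes": [{"id", "x", "y"}],
#' "edges": [[id, id]]}` with non-negative integer ids (an optional
#' `"shear"` cell field records a sheared vertical wrap, written only when
#' non-zero). GraphML files carry node attributes `x` and `y` and graph
#' attributes `cell_width`, `cell_height`, `periodic` (and optionally
#' `cell_shear`). The JSON dialect additionally stores the ring list (an
#' optional `"rings"` array of cyclic 0-based node-id sequences) whenever it
#' is known: strongly disordered generated states can carry crossed edges,
#' for which geometric face traversal is unreliable, so the combinatorial
#' ring bookkeeping travels with the network. Networks without stored rings
#' (and all GraphML files) get rings recomputed on demand by [find_rings()].
#'
#' @param net a [planar_network()].
#' @param path file path.
#' @param format `"json"` or `"graphml"`; guessed from the file extension
#'   when omitted.
#' @return `read_network()` returns a [planar_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(net, path, format = NULL) {
  format <- guess_format(path, format)
  if (format == "json") {
    V <- nrow(net$positions)
    cell <- list(width = net$cell$width, height = net$cell$height,
                 periodic = net$cell$periodic)
    if (net$cell$shear != 0) cell$shear <- net$cell$shear
    ed <- network_edges(net)
    obj <- list(
      cell = cell,
      nodes = lapply(seq_len(V), function(i)
        list(id = i - 1L, x = net$positions[i, 1], y = net$positions[i, 2])),
      edges = lapply(seq_len(nrow(ed)), function(i) ed[i, ] - 1L))
    # rings are stored when known: geometric face traversal is not reliable
    # on disordered states whose embedding carries crossed edges
    if (!is.null(net$rings))
      obj$rings <- lapply(net$rings, function(r) r - 1L)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    g <- igraph::graph_from_edgelist(network_edges(net), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nrow(net$positions) - igraph::vcount(g)))
    igraph::V(g)$x <- net$positions[, 1]
    igraph::V(g)$y <- net$positions[, 2]
    g <- igraph::set_graph_attr(g, "cell_width", net$cell$width)
    g <- igraph::set_graph_attr(g, "cell_height", net$cell$height)
    g <- igraph::set_graph_attr(g, "periodic", as.logical(net$cell$periodic))
    g <- igraph::set_graph_attr(g, "cell_shear", net$cell$shear)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = NULL) {
  format <- guess_format(path, format)
  if (format == "json") {
    obj <- tryCatch(jsonlite::read_json(path),
                    error = function(e) stop("parse error reading ", path, ": ",
                                             conditionMessage(e)))
    if (is.null(obj$nodes) || length(obj$nodes) == 0)
      stop("empty-network error: file has no nodes")
    if (is.null(obj$cell)) stop("format error: missing cell record")
    ids <- vapply(obj$nodes, function(n) {
      if (is.null(n$id)) stop("format error: node record without id") else as.integer(n$id)
    }, integer(1))
    xs <- vapply(obj$nodes, function(n) {
      if (is.null(n$x) || is.null(n$y))
        stop("format error: node ", n$id, " missing coordinates")
      as.numeric(n$x)
    }, numeric(1))
    ys <- vapply(obj$nodes, function(n) as.numeric(n$y), numeric(1))
    lk <- integer(0); lk[ids + 1L] <- seq_along(ids)
    edges <- t(vapply(obj$edges, function(e) {
      e <- unlist(e)
      if (length(e) != 2) stop("format error: malformed edge record [",
                               paste(e, collapse = ","), "]")
      idx <- lk[as.integer(e) + 1L]
      if (any(is.na(idx)) || any(idx == 0))
        stop("format error: edge [", paste(e, collapse = ","),
             "] refers to an unknown node")
      idx
    }, integer(2)))
    if (length(obj$edges) == 0) edges <- matrix(integer(0), ncol = 2)
    cell <- list(width = as.numeric(obj$cell$width),
                 height = as.numeric(obj$cell$height),
                 periodic = isTRUE(obj$cell$periodic),
                 shear = if (is.null(obj$cell$shear)) 0 else as.numeric(obj$cell$shear))
    net <- planar_network(cbind(xs, ys), edges, cell)
    if (!is.null(obj$rings)) {
      rings <- lapply(obj$rings, function(r) lk[unlist(r) + 1L])
      for (rg in rings) {
        nxt <- c(rg[-1], rg[1])
        if (any(is.na(rg)) ||
            !all(mapply(function(a, b) b %in% net$adjacency[[a]], rg, nxt)))
          stop("format error: stored ring inconsistent with the edge list")
      }
      net$rings <- rings
    }
    net
  } else {
    g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                  error = function(e) stop("parse error reading ", path, ": ",
                                           conditionMessage(e)))
    va <- igraph::vertex_attr_names(g)
    if (!("x" %in% va) || !("y" %in% va))
      stop("format error: GraphML file lacks x/y node attributes")
    if (igraph::vcount(g) == 0) stop("empty-network error: file has no nodes")
    ga <- igraph::graph_attr_names(g)
    if (!all(c("cell_width", "cell_height") %in% ga))
      stop("format error: GraphML file lacks cell dimensions")
    cell <- list(width = igraph::graph_attr(g, "cell_width"),
                 height = igraph::graph_attr(g, "cell_height"),
                 periodic = isTRUE(as.logical(igraph::graph_attr(g, "periodic"))),
                 shear = if ("cell_shear" %in% ga)
                   igraph::graph_attr(g, "cell_shear") else 0)
    planar_network(cbind(igraph::V(g)$x, igraph::V(g)$y),
                   igraph::as_edgelist(g, names = FALSE), cell)
  }
}

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "graphml")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json")) "json"
  else if (ext %in% c("graphml", "xml")) "graphml"
  else stop("cannot guess format from extension '", ext,
            "'; pass format = \"json\" or \"graphml\"")
}
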