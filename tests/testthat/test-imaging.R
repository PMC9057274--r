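make_hexagon <- function(r = 1.5, ctr = 2.5) {
  th <- 2 * pi * (0:5) / 6
  planar_network(cbind(ctr + r * cos(th), ctr + r * sin(th)),
                 cbind(1:6, c(2:6, 1)),
                 list(width = 5, height = 5, periodic = FALSE))
}

test_that("rendering is deterministic and scales with stroke geometry", {
  hexn <- make_hexagon()
  img1 <- render_network(hexn, scale = 20, line_width = 3, pad = 4)
  img2 <- render_network(hexn, scale = 20, line_width = 3, pad = 4)
  expect_identical(img1$pixels, img2$pixels)
  expect_true(any(img1$pixels))
  # foreground area close to total stroke area (edges 1.5 long, 6 of them)
  net <- unwrap_network(build_honeycomb(4, 4))
  img <- render_network(net, scale = 20, line_width = 3, pad = 4)
  ed <- network_edges(net)
  len <- sum(sqrt(rowSums((net$positions[ed[, 1], ] - net$positions[ed[, 2], ])^2)))
  expect_lt(abs(sum(img$pixels) / (len * 20 * 3) - 1), 0.25)
  # resolution guard
  expect_error(render_network(net, scale = 1), "resolution")
})

test_that("raster files round trip through PNG and TIFF", {
  img <- render_network(make_hexagon(), scale = 15, line_width = 3, pad = 4)
  for (ext in c(".png", ".tif")) {
    p <- tempfile(fileext = ext)
    write_raster(img, p)
    back <- read_raster(p, scale = 15)
    expect_identical(back$pixels, img$pixels)
    unlink(p)
  }
})

test_that("skeletonisation thins strokes to unit width preserving topology", {
  img <- render_network(make_hexagon(), scale = 20, line_width = 5, pad = 4)
  sk <- skeletonize(img$pixels)
  expect_true(any(sk))
  expect_lt(sum(sk), sum(img$pixels) / 3)
  # a thinned closed curve has no branch points: every pixel has exactly two
  # dark-to-bright transitions around its 8-neighbourhood
  sh <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
             c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  P <- lapply(sh, function(s) netswitch:::shift_mat(sk, s[1], s[2]))
  seqP <- c(P, P[1])
  crossing <- Reduce(`+`, lapply(1:8, function(i) (!seqP[[i]]) & seqP[[i + 1]]))
  expect_true(all(crossing[sk] == 2))
})

test_that("a junction-free closed curve extracts as a single ring", {
  img <- render_network(make_hexagon(), scale = 20, line_width = 3, pad = 4)
  net <- extract_graph(img)
  rings <- find_rings(net)
  expect_equal(length(rings), 1)
})

test_that("a short isolated stroke is pruned as a spur", {
  stub <- planar_network(rbind(c(2.4, 2.5), c(2.6, 2.5)), rbind(c(1, 2)),
                         list(width = 5, height = 5, periodic = FALSE))
  img <- render_network(stub, scale = 20, line_width = 3, pad = 4)
  expect_error(extract_graph(img, extraction_settings(min_branch_length = 30)),
               "empty-extraction")
})

test_that("extraction inputs are validated", {
  expect_error(extract_graph(structure(list(pixels = matrix(FALSE, 5, 5),
                                            scale = 1, pad = 0L),
                                       class = "raster_image")),
               "no foreground")
  expect_error(extract_graph(structure(list(pixels = matrix(0.5, 5, 5),
                                            scale = 1, pad = 0L),
                                       class = "raster_image")),
               "not binary")
})

test_that("clean renders round trip to the exact interior ring multiset", {
  net <- unwrap_network(build_honeycomb(4, 4))
  img <- render_network(net, scale = 25, line_width = 3, pad = 8)
  ext <- extract_graph(img)
  # compare against the degree-2-contracted source (the shared quotient)
  src <- contract_degree2(net)
  expect_identical(ring_size_multiset(find_rings(ext)),
                   ring_size_multiset(find_rings(src)))
  # extraction is deterministic
  ext2 <- extract_graph(img)
  expect_identical(ext$positions, ext2$positions)
  expect_identical(ext$adjacency, ext2$adjacency)
})

test_that("roundtrip_check reports near-zero deltas for clean renders", {
  net <- unwrap_network(build_honeycomb(4, 4))
  rt <- roundtrip_check(net, scale = 25, line_width = 3, pad = 8)
  expect_true(rt$ring_multiset_match)
  expect_lte(abs(rt$deltas[["mean_k"]]), 0.05)
  expect_equal(rt$extracted_report$N_rings, rt$source_report$N_rings)
})

test_that("over-thick strokes fuse edges and are flagged by the ring count", {
  net <- unwrap_network(build_honeycomb(4, 4))
  rt_bad <- tryCatch(roundtrip_check(net, scale = 5, line_width = 7, pad = 8),
                     error = function(e) NULL)
  expect_true(is.null(rt_bad) ||
                !(rt_bad$ring_multiset_match && rt_bad$deltas[["N_rings"]] == 0))
})

test_that("two extraction settings give two differing reports on one image", {
  net <- unwrap_network(build_honeycomb(4, 4))
  img <- render_network(net, scale = 25, line_width = 3, pad = 8)
  a <- extract_graph(img, extraction_settings(mode = "contract"))
  b <- extract_graph(img, extraction_settings(mode = "keep"))
  expect_false(identical(nrow(a$positions), nrow(b$positions)))
  expect_false(identical(degree_moments(a)$mean_k, degree_moments(b)$mean_k))
})

test_that("contract_degree2 suppresses chains but keeps small cycles drawable", {
  # a path of degree-2 nodes between two junction-ish anchors
  pos <- rbind(c(1, 1), c(2, 1), c(3, 1), c(4, 1),
               c(2.5, 2), c(2.5, 0.2))
  ed <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 5), c(4, 5), c(1, 6), c(4, 6))
  net <- planar_network(pos, ed, list(width = 5, height = 5, periodic = FALSE))
  con <- contract_degree2(net)
  # the chain 1-2-3-4 contracts to a direct 1-4 edge; the two parallel
  # detours keep their degree-2 guards (no parallel edges allowed)
  expect_equal(nrow(con$positions), 4)
  expect_gte(attr(con, "suppressed_degree2"), 2)
  # a bare triangle of degree-2 nodes survives contraction
  tri <- planar_network(rbind(c(1, 1), c(2, 1), c(1.5, 2)),
                        rbind(c(1, 2), c(2, 3), c(3, 1)),
                        list(width = 3, height = 3, periodic = FALSE))
  con2 <- contract_degree2(tri)
  expect_equal(nrow(con2$positions), 3)
})
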