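# Independent brute-force oracles, written without reference to the package
# internals they check.

# term-by-term energy summation in plain R: harmonic bonds over the edge list
# plus harmonic angular gaps around every node, minimum-image geometry
oracle_energy <- function(net, k_r = 1, K_theta = 1, r_eqm = 1) {
  mi <- function(a, b) {
    d <- net$positions[b, ] - net$positions[a, ]
    if (net$cell$periodic) {
      m <- round(d[2] / net$cell$height)
      d[2] <- d[2] - m * net$cell$height
      d[1] <- d[1] - m * net$cell$shear
      d[1] <- d[1] - round(d[1] / net$cell$width) * net$cell$width
    }
    d
  }
  E <- 0
  V <- nrow(net$positions)
  for (a in seq_len(V)) for (b in net$adjacency[[a]]) if (a < b) {
    r <- sqrt(sum(mi(a, b)^2))
    E <- E + k_r / 2 * (r - r_eqm)^2
  }
  if (K_theta > 0) {
    for (c in seq_len(V)) {
      nb <- net$adjacency[[c]]
      k <- length(nb)
      if (k < 2) stop("degree < 2")
      ang <- sort(vapply(nb, function(w) atan2(mi(c, w)[2], mi(c, w)[1]),
                         numeric(1)))
      gaps <- diff(c(ang, ang[1] + 2 * pi))
      E <- E + sum(K_theta / 2 * (gaps - 2 * pi / k)^2)
    }
  }
  E
}

# plain two-vector Pearson correlation over the orientation-doubled dual list
oracle_assortativity <- function(pairs) {
  a <- c(pairs[, 1], pairs[, 2])
  b <- c(pairs[, 2], pairs[, 1])
  suppressWarnings(stats::cor(a, b))
}

# two-pass mean / second central moment
oracle_moments <- function(x) {
  m <- sum(x) / length(x)
  c(mean = m, mu2 = sum((x - m)^2) / length(x))
}

# deterministic small strained fixture: honeycomb with one node displaced
strained_honeycomb <- function(nx = 3, ny = 3, node = 1, delta = c(0.1, 0)) {
  net <- build_honeycomb(nx, ny)
  net$positions[node, ] <- net$positions[node, ] + delta
  net
}
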