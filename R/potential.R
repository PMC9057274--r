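#' Parameters of the simplified Keating-type potential
#'
#' The network energy consists of harmonic bond and harmonic angle terms,
#'
#' \deqn{E = \sum_{bonds} \frac{k_r}{2}(r - r_{eqm})^2 +
#'       \sum_{nodes} \sum_{gaps} \frac{K_\theta}{2}(\theta -
#'       \theta_{eqm}(k))^2,}
#'
#' where the inner sum at a node of coordination k runs over the k
#' consecutive-neighbour angular gaps (which add up to 2*pi) and the
#' equilibrium angle is the coordination-dependent \eqn{\theta_{eqm}(k) =
#' 2\pi/k}. Bond lengths use the minimum-image convention in periodic cells.
#' Both force constants are free parameters in reduced units; `r_eqm` is 1
#' by convention. Setting `fixed_theta = TRUE` freezes the equilibrium angle
#' at `theta_fixed` instead of recomputing it with k (a mode known to leave
#' more artefacts in the final networks; off by default).
#'
#' @param k_r bond force constant (reduced units, >= 0).
#' @param K_theta angle force constant (reduced units, >= 0). When 0, angle
#'   terms are skipped entirely (so isolated test dimers are allowed).
#' @param r_eqm equilibrium bond length (> 0).
#' @param fixed_theta logical; freeze the equilibrium angle?
#' @param theta_fixed the frozen equilibrium angle in radians.
#' @return An object of class `potential_params`.
#' @export
potential_params <- function(k_r = 1, K_theta = 1, r_eqm = 1,
                             fixed_theta = FALSE, theta_fixed = 2 * pi / 3) {
  if (k_r < 0 || K_theta < 0) stop("force constants must be non-negative")
  if (r_eqm <= 0) stop("r_eqm must be positive")
  structure(list(k_r = k_r, K_theta = K_theta, r_eqm = r_eqm,
                 fixed_theta = isTRUE(fixed_theta), theta_fixed = theta_fixed),
            class = "potential_params")
}

#' Coordination-dependent equilibrium angle
#'
#' The angles around a node must add up to 360 degrees, so a node of
#' coordination k prefers equal gaps of `2*pi/k`: 120 degrees for the
#' trivalent honeycomb, 90 degrees at k = 4, and a straight angle (pi) for
#' 2-coordinate nodes, which consequently prefer to sit on a long boundary
#' between two large rings.
#'
#' @param k coordination number (>= 2).
#' @return equilibrium angle in radians.
#' @export
theta_eqm <- function(k) {
  if (any(k < 2)) stop("theta_eqm is defined for coordination k >= 2")
  2 * pi / k
}

#' Settings for local geometry relaxation
#'
#' @param radius graph-distance hop count defining the mobile region around
#'   the relaxation centres (>= 1).
#' @param force_tol gradient-norm stopping threshold (> 0).
#' @param max_iter iteration cap (>= 1).
#' @return An object of class `relax_settings`.
#' @export
relax_settings <- function(radius = 2, force_tol = 1e-6, max_iter = 200) {
  if (radius < 1 || force_tol <= 0 || max_iter < 1)
    stop("invalid relaxation settings")
  structure(list(radius = as.integer(radius), force_tol = force_tol,
                 max_iter = as.integer(max_iter)), class = "relax_settings")
}

#' Network energy under the Keating-type potential
#'
#' @param net a [planar_network()].
#' @param params a [potential_params()].
#' @param nodes optional subset of node indices; when given, the energy
#'   includes every bond and angle term touching a subset node exactly once.
#' @return energy in reduced units (always >= 0).
#' @export
network_energy <- function(net, params = potential_params(), nodes = NULL) {
  cpp_energy(net$positions, net$adjacency,
             net$cell$width, net$cell$height, net$cell$shear, net$cell$periodic,
             unclass(params),
             if (is.null(nodes)) integer(0) else as.integer(nodes))
}

#' Analytic gradient of the network energy
#'
#' Returns dE/d(x, y) per node; used mainly to verify the relaxation force
#' evaluation against finite differences.
#'
#' @inheritParams network_energy
#' @return V x 2 numeric matrix of gradients.
#' @export
network_gradient <- function(net, params = potential_params()) {
  cpp_gradient(net$positions, net$adjacency,
               net$cell$width, net$cell$height, net$cell$shear,
               net$cell$periodic, unclass(params))
}

#' Locally relax the geometry around given centres
#'
#' Damped gradient descent with backtracking line search over the nodes
#' within `settings$radius` hops of any centre; all other coordinates are
#' left bit-identical. The descent never increases the energy and stops when
#' the gradient norm over the mobile nodes falls below `force_tol` or after
#' `max_iter` iterations.
#'
#' @param net a [planar_network()].
#' @param params a [potential_params()].
#' @param centers node indices around which to relax.
#' @param settings a [relax_settings()].
#' @return A list with elements `network` (relaxed), `delta_E` (full-network
#'   energy change relative to the input configuration, <= 0), `iterations`,
#'   and `mobile` (the relaxed node set).
#' @export
relax_local <- function(net, params = potential_params(), centers,
                        settings = relax_settings()) {
  if (!length(centers)) stop("centers must be non-empty")
  centers <- sort(unique(as.integer(centers)))
  if (any(centers < 1 | centers > nrow(net$positions))) stop("unknown node id")
  mobile <- graph_ball(net$adjacency, centers, settings$radius)
  E0 <- network_energy(net, params)
  res <- cpp_relax(net$positions, net$adjacency,
                   net$cell$width, net$cell$height, net$cell$shear,
                   net$cell$periodic, unclass(params), mobile,
                   settings$force_tol, settings$max_iter)
  out <- net
  out$positions <- res$positions
  list(network = out, delta_E = res$energy - E0,
       iterations = res$iterations, mobile = mobile)
}
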