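#' Topological screening constraints for bond-switch moves
#'
#' Trial configurations are rejected outright when any node would leave the
#' coordination window or any ring would grow beyond `n_max` sides. The
#' defaults implement the rejection of configurations with k >= 8 or a
#' polygon with n >= 20 sides; `k_max` is the knob varied in
#' coordination-capped sweeps (sensible range 3--10). `k_min = 2` keeps
#' every node inside the polygon formalism (no dangling ends).
#'
#' @param k_min minimum coordination (>= 2).
#' @param k_max maximum coordination.
#' @param n_max maximum ring side count (>= 3).
#' @return An object of class `mc_constraints`.
#' @export
mc_constraints <- function(k_min = 2, k_max = 7, n_max = 19) {
  if (k_min < 2 || k_max < k_min) stop("need 2 <= k_min <= k_max")
  if (n_max < 3) stop("n_max must be >= 3")
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_max = as.integer(n_max)), class = "mc_constraints")
}

#' Metropolis acceptance rule
#'
#' Accepts a trial move with probability `min(1, exp(-delta_E / T))`
#' (temperatures in reduced units, k_B = 1). Exactly one uniform variate is
#' drawn when `delta_E > 0`, none otherwise, so seeded trajectories are
#' reproducible move-for-move.
#'
#' @param delta_E energy difference of the trial move.
#' @param T temperature (> 0, reduced units).
#' @return logical: accept the move?
#' @export
metropolis_accept <- function(delta_E, T) {
  if (T <= 0) stop("temperature must be positive")
  if (delta_E <= 0) return(TRUE)
  stats::runif(1) < exp(-delta_E / T)
}

reason_labels <- c("none", "constraint_k", "constraint_n", "topology", "metropolis")

switch_rejection <- function(reason) {
  structure(list(rejected = TRUE, reason = reason), class = "switch_rejection")
}

#' Propose one degree-transferring bond switch
#'
#' Selects an edge (A, B) uniformly with random orientation, then a new
#' partner C uniformly among the valid candidates: C is a neighbour of B,
#' distinct from and not already bonded to A, and lies on the ring formed by
#' notionally deleting A--B (the planarity guard). The move deletes A--B and
#' adds A--C, transferring one unit of coordination from B to C while
#' leaving the mean coordination untouched. Proposals whose degrees or ring
#' sizes would violate `constraints` return a screening rejection carrying
#' the reason (`constraint_k`, `constraint_n` or `topology`).
#'
#' @param net a periodic [planar_network()] with rings populated.
#' @param constraints an [mc_constraints()].
#' @return A `switch_proposal` (fields `A`, `B`, `C`, `merged_ring`,
#'   `split_rings`, `ring_ids`) or a `switch_rejection`.
#' @export
propose_switch <- function(net, constraints = mc_constraints()) {
  if (is.null(net$rings)) net$rings <- find_rings(net)
  E <- network_edge_count(net)
  if (E == 0) stop("network has no edges")
  deg <- lengths(net$adjacency)
  # uniform directed edge
  r <- sample.int(2L * E, 1L)
  cum <- cumsum(deg)
  A <- which(r <= cum)[1]
  B <- net$adjacency[[A]][r - c(0, cum)[A]]
  if (deg[B] - 1L < constraints$k_min) return(switch_rejection("constraint_k"))
  er <- edge_ring_ids(net$rings, A, B)
  if (length(er) != 2) return(switch_rejection("topology"))
  M <- merge_rings(net$rings[[er[1]]], net$rings[[er[2]]], A, B)
  if (is.null(M) || anyDuplicated(M)) return(switch_rejection("topology"))
  idxA <- match(A, M)
  nM <- length(M)
  cand <- setdiff(net$adjacency[[B]], c(A, net$adjacency[[A]]))
  cand <- cand[cand %in% M]
  if (!length(cand)) return(switch_rejection("topology"))
  k_ok <- deg[cand] + 1L <= constraints$k_max
  if (!any(k_ok)) return(switch_rejection("constraint_k"))
  cand <- cand[k_ok]
  # only the post-split rings are screened against n_max; the merged ring is
  # a transient construction, not a configuration
  sizes_ok <- vapply(cand, function(C) {
    d <- (match(C, M) - idxA) %% nM
    s1 <- d + 1L; s2 <- nM - d + 1L
    s1 >= 3 && s2 >= 3 && s1 <= constraints$n_max && s2 <= constraints$n_max
  }, logical(1))
  if (!any(sizes_ok)) return(switch_rejection("constraint_n"))
  cand <- cand[sizes_ok]
  C <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1L)]
  d <- (match(C, M) - idxA) %% nM
  idx <- c(seq_len(nM), seq_len(nM))
  S1 <- M[idx[idxA + 0:d]]
  S2 <- M[idx[((idxA + d - 1L) %% nM + 1L) + 0:(nM - d)]]
  structure(list(A = A, B = B, C = C, edge_ab = c(A, B), new_partner = C,
                 merged_ring = M, split_rings = list(S1, S2),
                 ring_ids = er, rejected = FALSE),
            class = "switch_proposal")
}

# ids of the (up to two) rings in which a and b are cyclically consecutive
edge_ring_ids <- function(rings, a, b) {
  hits <- integer(0)
  for (r in seq_along(rings)) {
    rg <- rings[[r]]
    i <- match(a, rg)
    if (is.na(i)) next
    n <- length(rg)
    if (rg[i %% n + 1L] == b || rg[(i - 2L) %% n + 1L] == b) hits <- c(hits, r)
  }
  hits
}

# cycle obtained by deleting edge a-b between rings R1, R2 (NULL if malformed)
merge_rings <- function(R1, R2, a, b) {
  r1 <- rotate_ring(R1, a, b)  # starts a, b, ...
  r2 <- rotate_ring(R2, b, a)  # starts b, a, ...
  if (is.null(r1) || is.null(r2)) return(NULL)
  c(r1[-1], a, r2[-(1:2)])     # b, x2..x_{n1-1}, a, y2..y_{n2-1}
}

rotate_ring <- function(ring, a, b) {
  n <- length(ring)
  i <- match(a, ring)
  if (is.na(i)) return(NULL)
  fwd <- ring[(i - 1L + seq_len(n) - 1L) %% n + 1L]
  if (fwd[2] == b) return(fwd)
  bwd <- ring[(i - 1L - (seq_len(n) - 1L)) %% n + 1L]
  if (bwd[2] == b) return(bwd)
  NULL
}

#' Apply a screened bond switch to a network
#'
#' Deletes edge A--B, adds edge A--C and updates the ring list locally: the
#' two rings bordering A--B are replaced by the two rings obtained by
#' splitting the merged ring along A--C. Node count, edge count, ring count
#' and the mean coordination are all conserved. The proposal must have been
#' screened on this exact network; a stale proposal raises a consistency
#' error.
#'
#' @param net the [planar_network()] the proposal was screened on.
#' @param move a `switch_proposal` from [propose_switch()].
#' @return The modified [planar_network()].
#' @export
apply_switch <- function(net, move) {
  if (inherits(move, "switch_rejection")) stop("cannot apply a rejected proposal")
  A <- move$A; B <- move$B; C <- move$C
  if (!(B %in% net$adjacency[[A]]) || (C %in% net$adjacency[[A]]) ||
      !(C %in% net$adjacency[[B]]))
    stop("stale proposal: network changed since screening")
  er <- move$ring_ids
  if (!setequal(net$rings[[er[1]]], intersect(net$rings[[er[1]]], move$merged_ring)) ||
      is.na(match(A, net$rings[[er[1]]])))
    stop("stale proposal: rings changed since screening")
  net$adjacency[[A]] <- sort(c(setdiff(net$adjacency[[A]], B), C))
  net$adjacency[[B]] <- setdiff(net$adjacency[[B]], A)
  net$adjacency[[C]] <- sort(c(net$adjacency[[C]], A))
  net$rings[[er[1]]] <- move$split_rings[[1]]
  net$rings[[er[2]]] <- move$split_rings[[2]]
  net
}

#' One Monte Carlo bond-switch step
#'
#' Executes the full propose -> apply -> local relaxation (centres A, B, C)
#' -> Metropolis pipeline. On any rejection (screening or Metropolis) the
#' returned network is bit-identical to the input, including positions; on
#' acceptance it is the relaxed trial network with updated rings.
#'
#' @param net a periodic [planar_network()] (the last accepted state).
#' @param params a [potential_params()].
#' @param constraints an [mc_constraints()].
#' @param relax a [relax_settings()].
#' @param T temperature (> 0, reduced units).
#' @return A list with `network` and `result` (a `step_result` with fields
#'   `accepted`, `delta_E`, `rejection_reason`).
#' @export
mc_step <- function(net, params = potential_params(),
                    constraints = mc_constraints(),
                    relax = relax_settings(), T) {
  eng <- mc_engine(net, params, constraints, relax)
  res <- eng_step(eng$ptr, T, FALSE)
  out <- if (res$accepted) engine_network(eng) else net
  list(network = out,
       result = structure(list(accepted = res$accepted,
                               delta_E = res$delta_E,
                               rejection_reason = reason_labels[res$reason + 1L]),
                          class = "step_result"))
}

#' Persistent Monte Carlo engine
#'
#' Wraps the compiled bond-switch engine holding the evolving network state,
#' so that schedule drivers can run long trajectories without copying the
#' network at every step. Randomness is drawn from R's global RNG stream, so
#' `set.seed()` makes entire trajectories reproducible.
#'
#' @param net a periodic [planar_network()]; rings are computed when absent.
#' @param params a [potential_params()].
#' @param constraints an [mc_constraints()].
#' @param relax a [relax_settings()].
#' @return An object of class `mc_engine`.
#' @export
mc_engine <- function(net, params = potential_params(),
                      constraints = mc_constraints(),
                      relax = relax_settings()) {
  if (!net$cell$periodic) stop("the Monte Carlo engine requires a periodic network")
  if (is.null(net$rings)) net$rings <- find_rings(net)
  ptr <- eng_create(net$positions, net$adjacency, net$rings,
                    net$cell$width, net$cell$height, net$cell$shear,
                    net$cell$periodic, unclass(params), unclass(constraints),
                    unclass(relax))
  structure(list(ptr = ptr, cell = net$cell), class = "mc_engine")
}

#' Extract the current network from an engine
#' @param engine an [mc_engine()].
#' @return A [planar_network()] with rings populated.
#' @export
engine_network <- function(engine) {
  pos <- eng_positions(engine$ptr)
  adj <- eng_adjacency(engine$ptr)
  rings <- eng_rings(engine$ptr)
  structure(list(positions = pos, adjacency = adj, rings = rings,
                 cell = engine$cell), class = "planar_network")
}

#' Acceptance and rejection counters of an engine
#' @param engine an [mc_engine()].
#' @return named list of attempt/acceptance/rejection counts.
#' @export
engine_counters <- function(engine) eng_counters(engine$ptr)

#' Run attempted steps on a persistent engine
#'
#' @param engine an [mc_engine()].
#' @param T temperatures, one per attempted step (recycled if scalar against
#'   `n_steps`).
#' @param n_steps number of attempted steps when `T` is scalar.
#' @param max_accepts stop early after this many acceptances (default: no cap).
#' @param check verify the topological invariants after every accepted move.
#' @return A per-step data frame log with columns `step`, `T`, `accepted`,
#'   `reason`, `delta_E`, `energy`, `mean_k`, `mu2_k`.
#' @export
engine_run <- function(engine, T, n_steps = length(T), max_accepts = -1,
                       check = FALSE) {
  Ts <- if (length(T) == 1) rep(T, n_steps) else T
  log <- eng_run(engine$ptr, Ts, as.integer(max_accepts), check)
  log$reason <- factor(reason_labels[log$reason + 1L], levels = reason_labels)
  log
}
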