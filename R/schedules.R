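#' Simulated-annealing schedule
#'
#' The generation protocol first melts the lattice completely by
#' thermalising at a very high temperature (10^4 reduced units by default,
#' at which effectively every screened move is accepted), then cools on a
#' logarithmic ladder: `moves_per_T` attempted moves at each temperature,
#' the temperature reduced by the constant multiplicative `factor` (10^-0.2
#' per rung by default) until the first temperature at or below `T_min` has
#' been run. The default ladder is therefore 10^4, 10^3.8, ..., 10^-2 (31
#' rungs). "Steps" and "moves" both count attempted switches, including
#' screening rejections.
#'
#' @param T_start melting/starting temperature (reduced units).
#' @param therm_steps attempted steps of thermalisation at `T_start`.
#' @param moves_per_T attempted steps per temperature rung.
#' @param factor multiplicative cooling ratio in (0, 1).
#' @param T_min final temperature (the first rung at or below it is run).
#' @param seed optional RNG seed applied by the drivers.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(T_start = 1e4, therm_steps = 10000,
                            moves_per_T = 1000, factor = 10^-0.2,
                            T_min = 1e-2, seed = NULL) {
  if (!(factor > 0 && factor < 1)) stop("factor must be in (0, 1)")
  if (T_min >= T_start) stop("T_min must be below T_start")
  if (therm_steps < 0 || moves_per_T < 1) stop("invalid step counts")
  structure(list(T_start = T_start, therm_steps = as.integer(therm_steps),
                 moves_per_T = as.integer(moves_per_T), factor = factor,
                 T_min = T_min, seed = seed), class = "anneal_schedule")
}

#' Fixed-temperature schedule
#'
#' Partial thermalisation at one temperature; used to map how the defect
#' population grows with temperature, from isolated Stone--Wales-like
#' defects in a near-pristine lattice at low T to the entropy-dominated
#' melt at high T.
#'
#' @param T_fixed temperature (> 0).
#' @param steps attempted steps (>= 1).
#' @param seed optional RNG seed applied by the drivers.
#' @return An object of class `fixed_t_schedule`.
#' @export
fixed_t_schedule <- function(T_fixed, steps, seed = NULL) {
  if (T_fixed <= 0 || steps < 1) stop("invalid fixed-temperature schedule")
  structure(list(T_fixed = T_fixed, steps = as.integer(steps), seed = seed),
            class = "fixed_t_schedule")
}

#' Temperature ladder of an annealing schedule
#'
#' Strictly decreasing geometric sequence `T_start * factor^j`, ending at
#' the first rung at or below `T_min` (inclusive).
#'
#' @param schedule an [anneal_schedule()].
#' @return numeric vector of rung temperatures.
#' @export
temperature_ladder <- function(schedule) {
  ladder <- schedule$T_start
  tol <- 1 + 1e-9
  while (ladder[length(ladder)] > schedule$T_min * tol)
    ladder <- c(ladder, ladder[length(ladder)] * schedule$factor)
  ladder
}

#' Thermalise a network at the melting temperature
#'
#' Runs `therm_steps` attempted switches at `T_start`, which at the default
#' 10^4 reduced units accepts essentially every screened move and melts the
#' starting lattice completely. The mean coordination is conserved exactly
#' throughout.
#'
#' @param net a periodic [planar_network()].
#' @param params a [potential_params()].
#' @param constraints an [mc_constraints()].
#' @param relax a [relax_settings()].
#' @param schedule an [anneal_schedule()].
#' @param engine optionally, a pre-built [mc_engine()] to drive in place.
#' @return A list with `network`, `log` (per-step data frame) and
#'   `acceptance_rate` (fraction of screened moves accepted).
#' @export
thermalize <- function(net, params = potential_params(),
                       constraints = mc_constraints(),
                       relax = relax_settings(),
                       schedule = anneal_schedule(), engine = NULL) {
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  eng <- if (is.null(engine)) mc_engine(net, params, constraints, relax) else engine
  if (schedule$therm_steps == 0)
    return(list(network = net, log = NULL, acceptance_rate = NA_real_))
  log <- engine_run(eng, schedule$T_start, schedule$therm_steps)
  screened <- log$reason %in% c("none", "metropolis")
  list(network = engine_network(eng), log = log,
       acceptance_rate = if (any(screened)) mean(log$accepted[screened]) else NA_real_)
}

#' Anneal a network down the temperature ladder
#'
#' Runs `moves_per_T` attempted switches at each rung of
#' [temperature_ladder()]. The caller is responsible for thermalising first
#' (see [thermalize()]); this is not enforced.
#'
#' @inheritParams thermalize
#' @return A list with `network`, `trajectory` (per-step log) and `rungs`
#'   (per-rung summary: `T`, `acceptance_rate`, `energy`, `mu2_k`).
#' @export
anneal <- function(net, params = potential_params(),
                   constraints = mc_constraints(),
                   relax = relax_settings(),
                   schedule = anneal_schedule(), engine = NULL) {
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  eng <- if (is.null(engine)) mc_engine(net, params, constraints, relax) else engine
  ladder <- temperature_ladder(schedule)
  Ts <- rep(ladder, each = schedule$moves_per_T)
  log <- engine_run(eng, Ts)
  list(network = engine_network(eng), trajectory = log,
       rungs = summarise_rungs(log))
}

summarise_rungs <- function(log) {
  grp <- cumsum(c(TRUE, log$T[-1] != log$T[-nrow(log)]))
  data.frame(
    T = tapply(log$T, grp, function(x) x[1]),
    acceptance_rate = tapply(log$accepted, grp, mean),
    energy = tapply(log$energy, grp, function(x) x[length(x)]),
    mu2_k = tapply(log$mu2_k, grp, function(x) x[length(x)]),
    row.names = NULL)
}

#' Partially thermalise at a fixed temperature
#'
#' @inheritParams thermalize
#' @param schedule a [fixed_t_schedule()].
#' @return A list with `network`, `trajectory` and `rungs` (one row).
#' @export
run_fixed_T <- function(net, params = potential_params(),
                        constraints = mc_constraints(),
                        relax = relax_settings(), schedule, engine = NULL) {
  stopifnot(inherits(schedule, "fixed_t_schedule"))
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  eng <- if (is.null(engine)) mc_engine(net, params, constraints, relax) else engine
  log <- engine_run(eng, schedule$T_fixed, schedule$steps)
  list(network = engine_network(eng), trajectory = log,
       rungs = summarise_rungs(log))
}

#' Generate a disordered network by bond-switching Monte Carlo
#'
#' Convenience driver for the full generation pipeline: build the periodic
#' honeycomb starting lattice, melt it by thermalisation, then either anneal
#' it down the temperature ladder or partially thermalise it at a fixed
#' temperature, and compute the structural metric report of the result.
#'
#' @param nx,ny honeycomb lattice size in rings.
#' @param params a [potential_params()].
#' @param constraints an [mc_constraints()].
#' @param relax a [relax_settings()].
#' @param schedule an [anneal_schedule()] (drives both thermalisation and,
#'   for `protocol = "anneal"`, the cooling ladder).
#' @param protocol `"anneal"` or `"fixed_T"`.
#' @param fixed a [fixed_t_schedule()], required for `protocol = "fixed_T"`.
#' @param seed optional seed for the whole trajectory.
#' @return An object of class `generated_network`: a list with `network`,
#'   `report` (a [network_report()]), `trajectory`, `rungs`, and the inputs.
#' @export
generate_network <- function(nx = 10, ny = 10, params = potential_params(),
                             constraints = mc_constraints(),
                             relax = relax_settings(),
                             schedule = anneal_schedule(),
                             protocol = c("anneal", "fixed_T"),
                             fixed = NULL, seed = NULL) {
  protocol <- match.arg(protocol)
  if (!is.null(seed)) set.seed(seed)
  net <- build_honeycomb(nx, ny)
  eng <- mc_engine(net, params, constraints, relax)
  th <- thermalize(net, params, constraints, relax,
                   schedule = within_seedless(schedule), engine = eng)
  res <- if (protocol == "anneal") {
    anneal(net, params, constraints, relax,
           schedule = within_seedless(schedule), engine = eng)
  } else {
    if (is.null(fixed)) stop("protocol = \"fixed_T\" needs a fixed_t_schedule")
    run_fixed_T(net, params, constraints, relax,
                schedule = within_seedless(fixed), engine = eng)
  }
  structure(list(network = res$network, report = network_report(res$network),
                 trajectory = res$trajectory, rungs = res$rungs,
                 thermalisation = th$log, params = params,
                 constraints = constraints, schedule = schedule,
                 protocol = protocol, seed = seed),
            class = "generated_network")
}

# drop the per-schedule seed so a single seed set by the caller governs all stages
within_seedless <- function(schedule) { schedule$seed <- NULL; schedule }

#' @export
print.generated_network <- function(x, ...) {
  cat(sprintf("generated_network (%s protocol)\n", x$protocol))
  print(x$network)
  print(x$report)
  invisible(x)
}

#' @export
summary.generated_network <- function(object, ...) {
  cat(sprintf("Bond-switch Monte Carlo network, %s protocol\n", object$protocol))
  cat(sprintf("  potential: k_r = %g, K_theta = %g\n",
              object$params$k_r, object$params$K_theta))
  st <- object$trajectory
  cat(sprintf("  %d attempted moves, %.1f%% accepted\n",
              nrow(st), 100 * mean(st$accepted)))
  print(object$report)
  invisible(object)
}

#' @export
plot.generated_network <- function(x, ...) plot(x$network, ...)
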