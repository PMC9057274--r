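#' Configuration of a network-landscape sweep
#'
#' A sweep generates one network per grid point (potential parameters x
#' protocol variant x seed) and records its metrics, mapping the generated
#' ensemble into the {mu2(k), r} network landscape. The default force
#' constant grid is log-spaced over the 0.01--100 reduced-unit range, from
#' bond-strain- to angle-strain-dominated networks. The default schedule is
#' a reduced desk-scale preset (thermalise 2000 steps, 200 moves per rung);
#' `schedule = anneal_schedule()` gives the full protocol (10000 and 1000).
#'
#' @param k_r,K_theta force-constant grids (reduced units).
#' @param protocol `"anneal"` or `"fixed_T"`.
#' @param T_fixed fixed temperatures (used when `protocol = "fixed_T"`).
#' @param fixed_steps attempted steps per fixed-T run.
#' @param T_min minimum temperatures (one sweep dimension for annealing).
#' @param k_max maximum node coordinations to sweep over.
#' @param seeds integer seeds, at least one.
#' @param nx,ny lattice size in rings.
#' @param schedule base [anneal_schedule()] (T_min is overridden per grid
#'   point).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(k_r = c(0.01, 0.1, 1, 10, 100),
                         K_theta = c(0.01, 0.1, 1, 10, 100),
                         protocol = c("anneal", "fixed_T"),
                         T_fixed = 1, fixed_steps = 5000,
                         T_min = 1e-2, k_max = 7, seeds = 1L,
                         nx = 10, ny = 10,
                         schedule = anneal_schedule(therm_steps = 2000,
                                                    moves_per_T = 200)) {
  protocol <- match.arg(protocol)
  if (!length(seeds)) stop("at least one seed is required")
  if (any(k_r <= 0) || any(K_theta <= 0)) stop("force constants must be positive")
  if (any(k_max < 3 | k_max > 10)) stop("k_max must lie in [3, 10]")
  structure(list(k_r = k_r, K_theta = K_theta, protocol = protocol,
                 T_fixed = T_fixed, fixed_steps = as.integer(fixed_steps),
                 T_min = T_min, k_max = as.integer(k_max),
                 seeds = as.integer(seeds), nx = as.integer(nx),
                 ny = as.integer(ny), schedule = schedule),
            class = "sweep_config")
}

#' Read a sweep configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [sweep_config()]; schedule
#' fields (`T_start`, `therm_steps`, `moves_per_T`, `factor`, `T_min`) may
#' be given under a `schedule:` block.
#'
#' @param path YAML file path.
#' @return A [sweep_config()].
#' @export
read_sweep_config <- function(path) {
  y <- yaml::read_yaml(path)
  y <- lapply(y, function(x) if (is.list(x) && length(names(x)) == 0) unlist(x) else x)
  sch <- do.call(anneal_schedule, c(y$schedule,
    if (is.null(y$schedule)) list(therm_steps = 2000, moves_per_T = 200)))
  args <- y[setdiff(names(y), "schedule")]
  do.call(sweep_config, c(args, list(schedule = sch)))
}

sweep_grid <- function(config) {
  base <- expand.grid(k_r = config$k_r, K_theta = config$K_theta,
                      k_max = config$k_max,
                      T_min = if (config$protocol == "anneal") config$T_min else NA,
                      T_fixed = if (config$protocol == "fixed_T") config$T_fixed else NA,
                      seed = config$seeds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base[order(base$k_r, base$K_theta, base$k_max, base$T_min, base$T_fixed,
             base$seed), , drop = FALSE]
}

#' Run a network-landscape parameter sweep
#'
#' For every grid point and seed: build the honeycomb, thermalise, run the
#' protocol, compute the metric report, and append one row to the landscape
#' table. Finished rows are written to `landscape.csv` in `out_dir` as they
#' complete and the generated networks saved as JSON, so an interrupted
#' sweep resumes where it stopped (existing completed rows are skipped,
#' never mutated). A failed run records a row with `error = TRUE` and does
#' not abort the sweep.
#'
#' @param config a [sweep_config()].
#' @param out_dir output directory (created if needed).
#' @return The landscape table (data frame), invisibly also written to
#'   `file.path(out_dir, "landscape.csv")`.
#' @export
run_sweep <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "landscape.csv")
  grid <- sweep_grid(config)
  existing <- if (file.exists(csv))
    utils::read.csv(csv, stringsAsFactors = FALSE) else NULL
  key <- function(df) paste(df$k_r, df$K_theta, df$k_max, df$T_min,
                            df$T_fixed, df$seed)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (!is.null(existing) && key(g) %in% key(existing)) next
    row <- tryCatch({
      gn <- generate_network(
        nx = config$nx, ny = config$ny,
        params = potential_params(k_r = g$k_r, K_theta = g$K_theta),
        constraints = mc_constraints(k_max = g$k_max),
        schedule = {
          s <- config$schedule
          if (!is.na(g$T_min)) s$T_min <- g$T_min
          s
        },
        protocol = config$protocol,
        fixed = if (config$protocol == "fixed_T")
          fixed_t_schedule(g$T_fixed, config$fixed_steps) else NULL,
        seed = g$seed)
      tag <- sprintf("net_kr%g_Kth%g_kmax%d_%s_seed%d",
                     g$k_r, g$K_theta, g$k_max,
                     if (config$protocol == "anneal")
                       sprintf("Tmin%g", g$T_min) else sprintf("Tfix%g", g$T_fixed),
                     g$seed)
      write_network(gn$network, file.path(out_dir, paste0(tag, ".json")))
      cbind(g, as.data.frame(gn$report), error = FALSE)
    }, error = function(e) {
      cbind(g, data.frame(mean_k = NA, mu2_k = NA, mean_n = NA, mu2_n = NA,
                          N_rings = NA, r_assort = NA, V = NA, E = NA,
                          valid = NA), error = TRUE)
    })
    rows[[length(rows) + 1]] <- row
    tab <- rbind(existing, do.call(rbind, rows))
    utils::write.csv(tab, csv, row.names = FALSE)
  }
  tab <- if (length(rows)) rbind(existing, do.call(rbind, rows)) else existing
  if (is.null(tab)) tab <- data.frame()
  if (nrow(tab))
    tab <- tab[order(tab$k_r, tab$K_theta, tab$k_max, tab$T_min,
                     tab$T_fixed, tab$seed), , drop = FALSE]
  utils::write.csv(tab, csv, row.names = FALSE)
  invisible(tab)
}

#' Plot the network landscape
#'
#' Scatter of assortativity r against the node-distribution width mu2(k),
#' one marker per completed sweep row, coloured by a chosen parameter. Rows
#' with undefined assortativity are skipped (their count is reported via a
#' message). Low-temperature networks populate the bottom-left of this
#' landscape (uncorrelated defects in a near-regular lattice, negative r);
#' entropy-dominated high-temperature networks sit to the top right.
#'
#' @param table landscape data frame from [run_sweep()].
#' @param out_path output PNG path.
#' @param color_by column name used for the colour scale (default: the
#'   first varied parameter).
#' @return `out_path`, invisibly.
#' @export
plot_landscape <- function(table, out_path, color_by = NULL) {
  if (is.null(table) || !nrow(table)) stop("empty landscape table")
  tab <- table[!is.na(table$mu2_k), , drop = FALSE]
  skipped <- sum(is.na(tab$r_assort))
  if (skipped) message(skipped, " row(s) with undefined assortativity skipped")
  tab <- tab[!is.na(tab$r_assort), , drop = FALSE]
  if (is.null(color_by)) {
    varied <- c("k_r", "K_theta", "k_max", "T_min", "T_fixed", "seed")
    nv <- vapply(varied, function(v)
      length(unique(stats::na.omit(tab[[v]]))), integer(1))
    color_by <- if (any(nv > 1)) varied[which(nv > 1)[1]] else "k_r"
  }
  vals <- tab[[color_by]]
  pal <- grDevices::hcl.colors(max(2, length(unique(vals))), "viridis")
  cols <- pal[as.integer(factor(vals))]
  grDevices::png(out_path, width = 720, height = 560)
  on.exit(grDevices::dev.off())
  graphics::plot(tab$mu2_k, tab$r_assort, col = cols, pch = 16,
                 xlab = expression(mu[2](k)), ylab = "assortativity r",
                 ylim = range(c(-1, 1, tab$r_assort)))
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = unique(vals),
                   col = pal[as.integer(factor(unique(vals)))],
                   pch = 16, title = color_by, cex = 0.8)
  invisible(out_path)
}
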