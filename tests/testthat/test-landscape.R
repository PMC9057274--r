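tiny_sched <- anneal_schedule(T_start = 100, therm_steps = 100,
                              moves_per_T = 40, factor = 0.1, T_min = 0.1)

test_that("a small sweep produces one bounded row per grid point and seed", {
  cfg <- sweep_config(k_r = c(0.1, 10), K_theta = c(0.1, 10), seeds = 1L,
                      nx = 4, ny = 4, schedule = tiny_sched)
  out <- tempfile()
  tab <- run_sweep(cfg, out)
  expect_equal(nrow(tab), 4)
  expect_true(all(is.finite(tab$mu2_k)))
  expect_true(all(is.na(tab$r_assort) | (tab$r_assort >= -1 & tab$r_assort <= 1)))
  expect_true(all(!tab$error))
  expect_true(file.exists(file.path(out, "landscape.csv")))
  expect_equal(length(list.files(out, pattern = "^net_.*json$")), 4)
  unlink(out, recursive = TRUE)
})

test_that("sweeps are deterministic and resumable", {
  cfg <- sweep_config(k_r = 1, K_theta = c(0.1, 1), seeds = c(1L, 2L),
                      nx = 4, ny = 4, schedule = tiny_sched)
  o1 <- tempfile(); o2 <- tempfile()
  t1 <- run_sweep(cfg, o1)
  t2 <- run_sweep(cfg, o2)
  expect_equal(t1, t2)
  # re-running on the same directory skips completed rows and changes nothing
  before <- readLines(file.path(o1, "landscape.csv"))
  t3 <- run_sweep(cfg, o1)
  expect_identical(readLines(file.path(o1, "landscape.csv")), before)
  # a superset grid appends without mutating existing rows
  cfg2 <- sweep_config(k_r = c(1, 10), K_theta = c(0.1, 1), seeds = c(1L, 2L),
                       nx = 4, ny = 4, schedule = tiny_sched)
  t4 <- run_sweep(cfg2, o1)
  expect_equal(nrow(t4), 8)
  old <- t4[t4$k_r == 1, c("k_r", "K_theta", "seed", "mu2_k", "r_assort")]
  new <- t1[, c("k_r", "K_theta", "seed", "mu2_k", "r_assort")]
  expect_equal(old[order(old$K_theta, old$seed), ],
               new[order(new$K_theta, new$seed), ], ignore_attr = TRUE)
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("every landscape row regenerates exactly from its stored parameters", {
  cfg <- sweep_config(k_r = 0.5, K_theta = 2, seeds = 7L, nx = 4, ny = 4,
                      schedule = tiny_sched)
  out <- tempfile()
  tab <- run_sweep(cfg, out)
  sch <- tiny_sched
  sch$T_min <- tab$T_min[1]
  gn <- generate_network(nx = 4, ny = 4,
                         params = potential_params(k_r = 0.5, K_theta = 2),
                         constraints = mc_constraints(k_max = tab$k_max[1]),
                         schedule = sch, seed = 7L)
  expect_equal(gn$report$mu2_k, tab$mu2_k[1])
  expect_equal(gn$report$r_assort, tab$r_assort[1])
  unlink(out, recursive = TRUE)
})

test_that("landscape plotting writes a figure and rejects empty tables", {
  cfg <- sweep_config(k_r = c(0.1, 10), K_theta = 1, seeds = 1L,
                      nx = 4, ny = 4, schedule = tiny_sched)
  out <- tempfile()
  tab <- run_sweep(cfg, out)
  fig <- file.path(out, "landscape.png")
  plot_landscape(tab, fig)
  expect_true(file.exists(fig))
  expect_gt(file.info(fig)$size, 0)
  expect_error(plot_landscape(tab[0, ], tempfile()), "empty")
  unlink(out, recursive = TRUE)
})

test_that("sweep configuration reads from YAML", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("k_r: [0.1, 1]", "K_theta: [1]", "seeds: [1, 2]",
               "nx: 4", "ny: 4",
               "schedule:", "  therm_steps: 100", "  moves_per_T: 50"), p)
  cfg <- read_sweep_config(p)
  expect_equal(cfg$k_r, c(0.1, 1))
  expect_equal(cfg$seeds, c(1L, 2L))
  expect_equal(cfg$schedule$moves_per_T, 50L)
  unlink(p)
})

test_that("a fixed-T sweep separates the low- and high-temperature regimes", {
  # bottom-left (near-pristine, disassortative defects) versus top-right
  # (entropy-dominated melt): mu2 must rise with T_fixed and the low-T
  # assortativity must be negative
  lows <- t(vapply(1:3, function(s) {
    gn <- generate_network(nx = 6, ny = 6, protocol = "fixed_T",
                           schedule = anneal_schedule(therm_steps = 0),
                           fixed = fixed_t_schedule(0.05, 3000), seed = 300 + s)
    c(gn$report$mu2_k, gn$report$r_assort)
  }, numeric(2)))
  highs <- t(vapply(1:3, function(s) {
    gn <- generate_network(nx = 6, ny = 6, protocol = "fixed_T",
                           schedule = anneal_schedule(therm_steps = 0),
                           fixed = fixed_t_schedule(0.5, 3000), seed = 400 + s)
    c(gn$report$mu2_k, gn$report$r_assort)
  }, numeric(2)))
  expect_lt(mean(lows[, 1]), mean(highs[, 1]))
  expect_lt(mean(lows[, 2], na.rm = TRUE), 0)
  expect_gt(mean(highs[, 2], na.rm = TRUE), mean(lows[, 2], na.rm = TRUE))
})
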