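# 1D dorso-ventral line model: discretisation, integration, classification,
# ensembles.

test_that("default discretisation and clock match the model definition", {
  dom <- domain_1d()
  expect_identical(dom$n_nodes, 201L)
  expect_equal(dom$positions[1], 0)
  expect_equal(dom$positions[201], 70)
  expect_lt(diff(range(diff(dom$positions))), 1e-12)
  clk <- sim_clock()
  expect_identical(clk$n_steps, 500L)           # (13 h * 3600) / 93.6 s
  expect_error(sim_clock(dt_s = 97), "multiple")
})

test_that("single-node saturating-Bmp trajectory follows the linear closed form", {
  g <- grn_params()
  S <- (g$b[["V"]] + g$v[["V"]]) / g$d[["V"]]
  closed <- function(t) S * (1 - exp(-g$d[["V"]] * t))
  run_v <- function(dt_s) {
    clk <- sim_clock(dt_s = dt_s, save_every_min = Inf)
    dom <- domain_1d(n_nodes = 2L)
    # saturate Bmp so that hill(A1, p1) == 1 to machine precision
    traj <- integrate_deterministic(dom, clk, g,
                                    morphogen_params(amp1 = 1e9))
    final_state(traj)[1, "V"]
  }
  v_dt <- run_v(93.6)
  err_dt <- abs(v_dt - closed(13))
  expect_lt(err_dt, 0.02)                       # Euler truncation at dt
  err_half <- abs(run_v(46.8) - closed(13))
  expect_lt(err_half / err_dt, 0.6)             # observed order ~1
})

test_that("zero production gives the identically zero trajectory", {
  # with all production switched off nothing can grow ...
  g <- grn_params(basal_ratio = 0)
  g$v[] <- 0
  m <- morphogen_params(scale1 = 0, scale2 = 0)
  traj <- integrate_deterministic(domain_1d(n_nodes = 11L), sim_clock(), g, m)
  expect_equal(max(abs(traj$states)), 0)
  # ... while with regulated production on but zero gradients, the activated
  # groups (V, I) stay silent and only the fully de-repressed D group rises
  g2 <- grn_params(basal_ratio = 0)
  traj2 <- integrate_deterministic(domain_1d(n_nodes = 11L), sim_clock(), g2, m)
  expect_equal(max(abs(traj2$states[, , c("V", "I")])), 0)
  expect_gt(max(traj2$states[, , "D"]), 0.9)
})

test_that("classification applies threshold, winner and strict-tie rules", {
  ref <- c(V = 1, I = 1, D = 1)
  expect_equal(as.character(classify(c(0.5, 0.1, 0.1), ref)), "V")
  expect_equal(as.character(classify(c(0.15, 0.18, 0.19), ref)), "unpatterned")
  expect_equal(as.character(classify(c(0.5, 0.5, 0.1), ref)), "unpatterned")
  expect_error(classify(c(1, 1, 1), c(0, 1, 1)), "positive")
  # normalisation by reference maxima
  expect_equal(as.character(classify(c(0.3, 0.4, 0), c(V = 0.5, I = 1, D = 1))),
               "V")
})

test_that("wild-type 1D run ends in ordered V / I / D bands with narrow V", {
  traj <- wt_1d()
  lab <- classify(final_state(traj), trajectory_reference_max(traj))
  runs <- rle(as.character(lab))
  expect_identical(runs$values, c("V", "I", "D"))
  expect_lt(runs$lengths[1], runs$lengths[2])   # ventral band stays narrow
  expect_lt(runs$lengths[1], runs$lengths[3])
})

test_that("noise-free stochastic integration equals the deterministic path", {
  dom <- domain_1d(n_nodes = 21L)
  g <- grn_params(nu = 0)
  m <- morphogen_params(eta1 = 0, eta2 = 0)
  det <- integrate_deterministic(dom, sim_clock(), g, m)
  sto <- integrate_stochastic(dom, sim_clock(), g, m, seed = 5)
  expect_identical(det$states, sto$states)
  # identical seeds reproduce bitwise; different seeds do not
  g2 <- grn_params(nu = 0.05)
  s1 <- integrate_stochastic(dom, sim_clock(), g2, m, seed = 11)
  s2 <- integrate_stochastic(dom, sim_clock(), g2, m, seed = 11)
  s3 <- integrate_stochastic(dom, sim_clock(), g2, m, seed = 12)
  expect_identical(s1$states, s2$states)
  expect_false(identical(s1$states, s3$states))
})

test_that("ensemble aggregation uses the population-sigma convention", {
  dom <- domain_1d(n_nodes = 11L)
  g <- grn_params(nu = 0.05)
  m <- morphogen_params()
  ens <- ensemble(dom, sim_clock(), g, m, n_runs = 2L, base_seed = 21L)
  r1 <- integrate_stochastic(dom, sim_clock(), g, m, seed = 21L)
  r2 <- integrate_stochastic(dom, sim_clock(), g, m, seed = 22L)
  expect_equal(ens$mean, (r1$states + r2$states) / 2)
  expect_equal(ens$sd, abs(r1$states - r2$states) / 2)  # population: sigma = a
  # all-deterministic members: zero spread
  ens0 <- ensemble(dom, sim_clock(), grn_params(nu = 0), m, n_runs = 3L)
  expect_equal(max(ens0$sd), 0, tolerance = 1e-6)
  expect_error(ensemble(dom, n_runs = 1L), ">= 2")
})

test_that("ensemble mean approaches the deterministic path as noise vanishes", {
  dom <- domain_1d(n_nodes = 21L)
  m <- morphogen_params()
  det <- final_state(integrate_deterministic(dom, sim_clock(), grn_params(), m))
  dev <- vapply(c(0.05, 0.01, 0), function(nu) {
    if (nu == 0) {
      ens <- ensemble(dom, sim_clock(), grn_params(nu = 0), m, n_runs = 5L,
                      base_seed = 31L)
    } else {
      ens <- ensemble(dom, sim_clock(), grn_params(nu = nu), m, n_runs = 20L,
                      base_seed = 31L)
    }
    nf <- dim(ens$mean)[1]
    max(abs(ens$mean[nf, , ] - det))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_equal(dev[[3]], 0)
})
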