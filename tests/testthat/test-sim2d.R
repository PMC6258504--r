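# 2D cell-centre tissue: mechanics, growth events, and the full growing-arch
# simulation.

test_that("equilibrium distance matches a numeric stationary point of the pair potential", {
  # worked example: U0=1, V0=2, xi1=2, xi2=1 -> r0 = 2 ln 4
  m_ex <- list(U0 = 1, V0 = 2, xi1 = 2, xi2 = 1)
  expect_equal(equilibrium_distance(m_ex), 2 * log(4))
  # default parameters: force at r0 vanishes; numeric root agrees
  m <- mechanics_params()
  expect_lt(abs(archpattern:::morse_force(m$r0, m)), 1e-10)
  pair_pot <- function(r) m$U0 * exp(-r / m$xi1) - m$V0 * exp(-r / m$xi2)
  root <- optimize(pair_pot, c(0.5, 10))$minimum
  expect_equal(m$r0, root, tolerance = 1e-4)
  # degenerate: U0 xi2 == V0 xi1 puts the stationary point at 0
  expect_error(equilibrium_distance(list(U0 = 1, V0 = 2, xi1 = 1, xi2 = 2)),
               "positive stationary point")
})

test_that("total force has the expected stationary points and monotonicity", {
  m <- mechanics_params()
  nobody <- matrix(numeric(0), 0, 2)
  # single cell at the chemoattractant target, nothing else: zero force
  f0 <- total_force(c(3, 7), nobody, nobody, m, attractor = c(3, 7))
  expect_equal(unname(f0), c(0, 0))
  # two cells at separation r0: zero net pair force
  m0 <- mechanics_params(W1 = 0, W2 = 0)
  f_pair <- total_force(c(0, 0), matrix(c(m0$r0, 0), 1), nobody, m0)
  expect_equal(max(abs(f_pair)), 0, tolerance = 1e-10)
  # repulsion from a boundary node grows monotonically as it gets closer
  node <- matrix(c(0, 0), 1)
  push <- vapply(c(4, 3, 2, 1, 0.5), function(d)
    total_force(c(d, 0), nobody, node, m0)[1], numeric(1))
  expect_true(all(diff(push) > 0))
  expect_true(all(push > 0))   # always away from the node
})

test_that("position stepping relaxes towards equilibrium", {
  m <- mechanics_params(W1 = 0, W2 = 0)
  nobody <- matrix(numeric(0), 0, 2)
  # zero-force configuration is a fixed point
  pos <- rbind(c(0, 0), c(m$r0, 0))
  expect_equal(step_positions(pos, nobody, m), pos, tolerance = 1e-12)
  # overlapping cells separate
  pos2 <- rbind(c(0, 0), c(m$r0 / 3, 0))
  sep <- function(p) abs(diff(p[, 1]))
  expect_gt(sep(step_positions(pos2, nobody, m)), sep(pos2))
  # random 75-cell placement relaxes apart after one step
  set.seed(4)
  outline <- interpolate_outline(wt_series(), 22)
  pos75 <- archpattern:::place_cells_uniform(75L, outline)
  rings <- build_boundary_rings(outline)
  min_d <- function(p) min(dist(p))
  relaxed <- step_positions(pos75, rings$nodes, m,
                            archpattern:::ventral_tip(outline))
  expect_gt(min_d(relaxed), min_d(pos75))
})

test_that("growth schedule splits division and migration events exactly", {
  gs <- make_growth_schedule()
  expect_length(gs$division_times, 68L)
  expect_length(gs$migration_times, 7L)
  expect_equal(length(gs$division_times) + length(gs$migration_times), 75L)
  expect_true(all(gs$division_times > 22 & gs$division_times <= 35))
  expect_lt(diff(range(diff(gs$division_times))), 1e-9)  # constant intervals
  all_div <- make_growth_schedule(division_fraction = 1)
  expect_length(all_div$migration_times, 0L)
  expect_length(all_div$division_times, 75L)
  expect_error(make_growth_schedule(n0 = 100, n_end = 50), "exceed")
})

test_that("division places an inheriting daughter at r0/20", {
  m <- mechanics_params()
  tissue <- list(positions = matrix(c(5, 5), 1),
                 states = matrix(c(0.3, 0.6, 0.1), 1,
                                 dimnames = list(NULL, c("V", "I", "D"))),
                 origin = "initial", parent = NA_integer_, ids = 1L)
  set.seed(1)
  t2 <- apply_division(tissue, m)
  expect_identical(nrow(t2$positions), 2L)
  expect_equal(sqrt(sum(diff(t2$positions)^2)), m$r0 / 20)
  expect_equal(t2$states[2, ], t2$states[1, ])
  expect_identical(t2$origin[2], "division")
  expect_identical(t2$parent[2], 1L)
})

test_that("migrants enter dorsally with 40% dorsal expression", {
  m <- mechanics_params()
  g <- grn_params()
  outline <- interpolate_outline(wt_series(), 30)
  tissue <- list(positions = matrix(c(0, 30), 1),
                 states = matrix(0, 1, 3,
                                 dimnames = list(NULL, c("V", "I", "D"))),
                 origin = "initial", parent = NA_integer_, ids = 1L)
  set.seed(2)
  for (k in 1:10) {
    t2 <- apply_migration(tissue, outline, m, g)
    expect_identical(nrow(t2$positions), 2L)
    st <- t2$states[2, ]
    expect_equal(unname(st[c("V", "I")]), c(0, 0))
    expect_equal(st[["D"]],
                 0.4 * (g$b[["D"]] + g$v[["D"]]) / g$d[["D"]])
    # inside the dorsal quarter of the outline's D-V extent
    ymax <- max(outline[, 2]); H <- diff(range(outline[, 2]))
    expect_gte(t2$positions[2, 2], ymax - 0.27 * H)
  }
})

test_that("the default wild-type 2D run grows, stays confined and patterns", {
  run <- wt_2d()
  expect_identical(nrow(run$frames[[1]]$positions), 75L)
  ft <- final_tissue(run)
  expect_identical(nrow(ft$positions), 150L)
  # confinement: every cell within tolerance of the final outline
  ring <- rbind(ft$outline, ft$outline[1, ])
  inside <- archpattern:::point_in_polygon(ft$positions[, 1],
                                           ft$positions[, 2], ft$outline)
  esc <- archpattern:::dist_to_polyline(
    ft$positions[!inside, , drop = FALSE], ring)
  expect_true(all(esc < 2))
  # no frame has two centres closer than r0/25
  for (fr in run$frames) {
    if (nrow(fr$positions) < 2) next
    expect_gt(min(dist(fr$positions)), run$mech$r0 / 25)
  }
  # final labels form V, I, D bands ordered along the D-V axis
  lab <- classify(ft$states, tissue_reference_max(run))
  expect_true(all(c("V", "I", "D") %in% lab))
  ymin <- min(ft$outline[, 2])
  mean_y <- tapply(ft$positions[, 2] - ymin, lab, mean)
  expect_true(mean_y[["V"]] < mean_y[["I"]] &&
                mean_y[["I"]] < mean_y[["D"]])
  expect_lt(sum(lab == "unpatterned") / length(lab), 0.2)
})

test_that("2D runs are bit-reproducible for a fixed seed", {
  a <- run_2d(seed = 3, clock = sim_clock(t_end_hpf = 24, dt_s = 180),
              schedule = make_growth_schedule(t_end = 24))
  b <- run_2d(seed = 3, clock = sim_clock(t_end_hpf = 24, dt_s = 180),
              schedule = make_growth_schedule(t_end = 24))
  expect_identical(final_tissue(a)$positions, final_tissue(b)$positions)
  expect_identical(final_tissue(a)$states, final_tissue(b)$states)
})
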