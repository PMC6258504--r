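# Forward sensitivity analysis: analytic partials, the augmented solver, and
# the box-plot summaries.

test_that("augmented rhs matches finite differences of the plain rhs", {
  g <- grn_params()
  st <- c(V = 0.4, I = 0.3, D = 0.2)
  A1 <- 0.6; A2 <- 0.8
  pr <- archpattern:::grn_partials(st, A1, A2, g)
  h <- 1e-6
  # Jacobian columns
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    fd <- (grn_rhs(st + e, A1, A2, g) - grn_rhs(st - e, A1, A2, g)) / (2 * h)
    expect_equal(unname(pr$J[, j]), unname(fd), tolerance = 1e-6)
  }
  # parameter partials
  for (i in 1:7) {
    gp <- g; gp$p[i] <- g$p[i] + h
    gm <- g; gm$p[i] <- g$p[i] - h
    fd <- (grn_rhs(st, A1, A2, gp) - grn_rhs(st, A1, A2, gm)) / (2 * h)
    expect_equal(unname(pr$dfdp[, i]), unname(fd), tolerance = 1e-6)
  }
  # structural zeros: s = 0 and A1 = 0 leave p1's sensitivity inert
  d0 <- augmented_rhs(c(0, 0, 0), matrix(0, 3, 7), 0, 1, g)
  expect_equal(max(abs(d0$ds[, "p1"])), 0)
  expect_equal(d0$ds[2, "p1"], 0)   # p1 appears only in the V equation
})

test_that("zero-signal context yields identically zero morphogen-parameter sensitivities", {
  tr <- run_sensitivity(list(A1 = 0, A2 = 0))
  expect_equal(max(abs(tr$s[, , c("p1", "p2", "p5", "p7")])), 0)
  expect_equal(max(abs(tr$s[1, , ])), 0)   # s(0) = 0
})

test_that("sensitivity trajectories match central finite differences (one context)", {
  ctx <- sensitivity_context("I")
  times <- seq(22, 35, length.out = 11)
  tr <- run_sensitivity(ctx, times = times)
  fd <- sensitivity_fd(ctx, times = times)
  for (i in 1:7) {
    scale_i <- max(abs(fd[, , i]), 1e-12)
    rel <- max(abs(tr$s[, , i] - fd[, , i]) /
                 pmax(abs(fd[, , i]), 1e-3 * scale_i))
    expect_lt(rel, 1e-3)
  }
})

test_that("sensitivity signs and magnitudes follow the network topology", {
  ctx <- sensitivity_context("V")
  tr <- run_sensitivity(ctx)
  nt <- length(tr$times)
  # raising p1 weakens Bmp activation of V: s_V(p1) < 0 once V is up
  expect_lt(tr$s[nt, "V", "p1"], 0)
  # ... which de-represses I: s_I(p1) > 0
  expect_gt(tr$s[nt, "I", "p1"], 0)
  # D couples to the Bmp parameters only indirectly, so its sensitivity is
  # the smallest of the three genes
  m <- apply(abs(tr$s[, , c("p1", "p5")]), 2, max)
  expect_lt(m[["D"]], m[["V"]])
  expect_lt(m[["D"]], m[["I"]])
  # low-morphogen (D-typical) context: I is controlled directly by the two
  # morphogen parameters p2 and p5
  trD <- run_sensitivity(sensitivity_context("D"))
  mi <- apply(abs(trD$s[, "I", ]), 2, max)
  expect_true(all(sort(mi, decreasing = TRUE)[1:2] %in% mi[c("p2", "p5")]))
})

test_that("single-morphogen variant confines V to p1 and moves I/D mass onto p2", {
  ctx <- sensitivity_context("V")
  g1 <- grn_params(); g1$single_morphogen <- TRUE
  tr2 <- run_sensitivity(ctx)                 # two morphogens
  tr1 <- run_sensitivity(ctx, g1)             # merged gradient
  # p5 is gone from the merged model
  expect_equal(max(abs(tr1$s[, , "p5"])), 0)
  # V sensitivity is confined to p1 in both variants
  v_other <- max(abs(tr1$s[, "V", c("p2", "p3", "p4", "p6", "p7")]))
  expect_lt(v_other, 1e-12)
  expect_gt(max(abs(tr1$s[, "V", "p1"])), 0)
  # the collapsed p2 accumulates at least the I-gene mass p2 + p5 carried
  m1 <- max(abs(tr1$s[, "I", "p2"]))
  m2 <- max(abs(tr2$s[, "I", "p2"]))
  expect_gt(m1, m2)
})

test_that("summaries honour sampling count and normalisation rules", {
  ctx <- sensitivity_context("V")
  tr <- run_sensitivity(ctx)
  sm <- summarize_sensitivity(tr, n_points = 10)
  # self-normalisation: the largest |statistic| over p1/p5 is exactly 1
  p15 <- sm[sm$parameter %in% c("p1", "p5"), ]
  expect_equal(max(abs(c(p15$lo, p15$hi))), 1)
  # constant trajectory: median = c, zero interquartile range
  fake <- structure(list(times = 1:10,
                         s = array(2, dim = c(10, 3, 7),
                                   dimnames = list(NULL, c("V", "I", "D"),
                                                   paste0("p", 1:7)))),
                    class = "sensitivity_trajectory")
  smf <- summarize_sensitivity(fake)
  expect_true(all(smf$median == 1))   # 2 / max == 1 after normalisation
  expect_true(all(smf$q75 - smf$q25 == 0))
  expect_error(summarize_sensitivity(tr, n_points = 1), ">= 2")
})
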