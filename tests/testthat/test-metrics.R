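# Boundary-error metric, precision/accuracy statistics and perturbation
# outcome classification.

fake_tissue <- function(positions, labels, H = 10) {
  # states chosen so classification against unit reference returns `labels`
  st <- matrix(0.01, nrow(positions), 3,
               dimnames = list(NULL, c("V", "I", "D")))
  for (i in seq_along(labels))
    if (labels[i] != "unpatterned") st[i, labels[i]] <- 0.9
  list(positions = positions, states = st,
       outline = cbind(x = c(-5, 5, 5, -5), y = c(0, 0, H, H)),
       origin = rep("initial", nrow(positions)),
       parent = rep(NA_integer_, nrow(positions)),
       ids = seq_len(nrow(positions)))
}
unit_ref <- c(V = 1, I = 1, D = 1)

test_that("boundary error sums point-to-polyline distances", {
  curve <- cbind(x = c(-5, 5), y = c(2, 2))
  # cells on the curve: zero error
  on_curve <- rbind(c(-1, 2), c(0, 2), c(3, 2))
  expect_equal(boundary_error(on_curve, curve)$E, 0)
  # one cell at distance 2
  expect_equal(boundary_error(matrix(c(0, 4), 1), curve)$E, 2)
  # duplicated cell doubles its contribution
  expect_equal(boundary_error(rbind(c(0, 4), c(0, 4)), curve)$E, 4)
  # rigid motion applied to cells and reference leaves E unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- rbind(c(0.3, 3.1), c(-2, 1.2), c(4, 2.5))
  e0 <- boundary_error(pts, curve)$E
  shift <- c(11, -3)
  e1 <- boundary_error(sweep(pts %*% t(R), 2, shift, "+"),
                       sweep(curve %*% t(R), 2, shift, "+"))$E
  expect_equal(e0, e1)
})

test_that("boundary cells are the ventral-side cells touching the dorsal side", {
  r0 <- 3.3
  two <- fake_tissue(rbind(c(0, 1), c(0, 2)), c("V", "I"))
  expect_identical(find_boundary_cells(two, "V-I", unit_ref, r0 = r0), 1L)
  # distant pair: no contact
  far <- fake_tissue(rbind(c(0, 1), c(0, 9)), c("V", "I"))
  expect_length(find_boundary_cells(far, "V-I", unit_ref, r0 = r0), 0L)
  # tissue entirely dorsal: empty with a warning for both interfaces
  alld <- fake_tissue(rbind(c(0, 1), c(0, 2)), c("D", "D"))
  expect_warning(out <- find_boundary_cells(alld, "V-I", unit_ref, r0 = r0),
                 "no labelled")
  expect_length(out, 0L)
  expect_warning(find_boundary_cells(alld, "I-D", unit_ref, r0 = r0))
})

test_that("wild-type 2D boundary cells form a thin band near the reference", {
  run <- wt_2d()
  refs <- generate_reference_boundaries(wt_series())
  ref_max <- tissue_reference_max(run)
  ft <- final_tissue(run)
  idx <- find_boundary_cells(ft, "V-I", ref_max, r0 = run$mech$r0)
  expect_gt(length(idx), 3L)
  expect_lt(length(idx), 30L)          # 1-2 cells thick, not a blob
  be <- boundary_error(ft$positions[idx, , drop = FALSE], refs$vi_curve)
  expect_lt(mean(be$per_cell), run$mech$r0 / 2)  # near-zero wild-type error
})

test_that("accuracy normalises by the worst condition; precision is the max sigma", {
  acc <- accuracy(list(a = c(2, 2, 2), b = c(4, 4, 4)))
  expect_equal(acc$mean[acc$condition == "b"], 1)
  expect_equal(acc$mean[acc$condition == "a"], 0.5)
  expect_equal(acc$sd, c(0, 0))
  expect_error(accuracy(list(a = c(0, 0))), "zero")
  # noise-free ensemble has precision 0
  dom <- domain_1d(n_nodes = 11L)
  ens0 <- ensemble(dom, grn = grn_params(nu = 0), n_runs = 2L)
  expect_equal(precision(ens0), 0, tolerance = 1e-6)
  expect_gt(precision(ensemble(dom, grn = grn_params(nu = 0.05), n_runs = 5L)),
            0)
})

test_that("perturbation outcomes report presence and dorsal expansion", {
  pos <- cbind(0, seq(0.5, 9.5, length.out = 20))
  wt_lab <- c(rep("V", 4), rep("I", 8), rep("D", 8))
  out <- classify_perturbation_outcome(fake_tissue(pos, wt_lab), unit_ref)
  expect_true(out$V_present && out$I_present && out$D_present)
  expect_false(out$D_expanded_ventrally)
  alld <- classify_perturbation_outcome(fake_tissue(pos, rep("D", 20)),
                                        unit_ref)
  expect_false(alld$V_present || alld$I_present)
  expect_true(alld$D_present && alld$D_expanded_ventrally)
})

test_that("Edn1 noise acts unidirectionally: mean I is depressed, never raised", {
  dom <- domain_1d()
  det <- wt_1d()
  ref <- trajectory_reference_max(det)
  lab <- classify(final_state(det), ref)
  ens <- ensemble(dom, morph = morphogen_params(eta2 = 1), n_runs = 20L,
                  base_seed = 101L)
  nf <- dim(ens$mean)[1]
  i_nodes <- which(lab == "I")
  diffs <- ens$mean[nf, i_nodes, "I"] - final_state(det)[i_nodes, "I"]
  se <- ens$sd[nf, i_nodes, "I"] / sqrt(ens$n_runs)
  expect_true(all(diffs <= 2 * se))
})
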