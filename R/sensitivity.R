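# Forward sensitivity analysis of the GRN with respect to the dissociation
# constants p1..p7, at fixed morphogen levels typical of the V, I and D
# domains. The augmented system (states + one 3-vector of sensitivities per
# parameter) is integrated with an adaptive, error-controlled solver.

# analytic Hill partials
d_hact_ds <- function(s, p) 2 * s * p^2 / (p^2 + s^2)^2
d_hact_dp <- function(s, p) -2 * p * s^2 / (p^2 + s^2)^2
d_hrep_ds <- function(s, p) -2 * s * p^2 / (p^2 + s^2)^2
d_hrep_dp <- function(s, p) 2 * p * s^2 / (p^2 + s^2)^2

# Jacobian of the rhs w.r.t. (V, I, D) and partials w.r.t. p1..p7 at one state
grn_partials <- function(y, A1, A2, grn) {
  p <- grn$p
  single <- isTRUE(grn$single_morphogen)
  a2 <- if (single) A1 else A2
  V <- y[1L]; I <- y[2L]; D <- y[3L]
  Ha1 <- hill(A1, p[["p1"]])
  Ha2 <- hill(a2, p[["p2"]])
  RV <- hill(V, p[["p3"]], mode = "repressing")
  RD <- hill(D, p[["p4"]], mode = "repressing")
  Ha5 <- if (single) 1 else hill(A1, p[["p5"]])
  RI <- hill(I, p[["p6"]], mode = "repressing")
  RA2 <- hill(a2, p[["p7"]], mode = "repressing")
  vI <- grn$v[["I"]] * grn$prod_scale[["I"]]
  vV <- grn$v[["V"]] * grn$prod_scale[["V"]]
  vD <- grn$v[["D"]] * grn$prod_scale[["D"]]
  J <- matrix(0, 3L, 3L)
  J[1L, 1L] <- -grn$d[["V"]]
  J[2L, 2L] <- -grn$d[["I"]]
  J[3L, 3L] <- -grn$d[["D"]]
  J[2L, 1L] <- vI * Ha2 * RD * Ha5 * d_hrep_ds(V, p[["p3"]])
  J[2L, 3L] <- vI * Ha2 * RV * Ha5 * d_hrep_ds(D, p[["p4"]])
  J[3L, 2L] <- vD * RA2 * d_hrep_ds(I, p[["p6"]])
  dfdp <- matrix(0, 3L, 7L, dimnames = list(GENES, names(p)))
  dfdp[1L, "p1"] <- vV * d_hact_dp(A1, p[["p1"]])
  dfdp[2L, "p2"] <- vI * RV * RD * Ha5 * d_hact_dp(a2, p[["p2"]])
  dfdp[2L, "p3"] <- vI * Ha2 * RD * Ha5 * d_hrep_dp(V, p[["p3"]])
  dfdp[2L, "p4"] <- vI * Ha2 * RV * Ha5 * d_hrep_dp(D, p[["p4"]])
  if (!single)
    dfdp[2L, "p5"] <- vI * Ha2 * RV * RD * d_hact_dp(A1, p[["p5"]])
  dfdp[3L, "p6"] <- vD * RA2 * d_hrep_dp(I, p[["p6"]])
  dfdp[3L, "p7"] <- vD * RI * d_hrep_dp(a2, p[["p7"]])
  list(J = J, dfdp = dfdp)
}

#' Right-hand side of the augmented (state + sensitivity) system
#'
#' For each parameter \eqn{p_i} the sensitivity \eqn{s_i = \partial y /
#' \partial p_i} obeys \eqn{ds_i/dt = (\partial f/\partial y) s_i +
#' \partial f/\partial p_i}, with both partials computed analytically from the
#' GRN equations.
#'
#' @param state length-3 gene state (V, I, D).
#' @param s 3 x 7 sensitivity block (genes x parameters).
#' @param A1,A2 fixed morphogen concentrations.
#' @param grn `grn_params`.
#' @return list with `dstate` (length 3) and `ds` (3 x 7).
#' @export
augmented_rhs <- function(state, s, A1, A2, grn) {
  if (any(state < 0)) stop("augmented_rhs(): state must be non-negative")
  pr <- grn_partials(state, A1, A2, grn)
  list(dstate = as.numeric(grn_rhs(state, A1, A2, grn)),
       ds = pr$J %*% s + pr$dfdp)
}

#' Morphogen context typical of one domain
#'
#' "V-typical" samples the gradients at the ventral source (x = 0),
#' "I-typical" at 0.45 of the domain length, "D-typical" at 0.9.
#'
#' @param domain_label one of `"V"`, `"I"`, `"D"`.
#' @param morph `morphogen_params`.
#' @param domain_length 1D domain length (um).
#' @return list with `A1`, `A2`.
#' @export
sensitivity_context <- function(domain_label = c("V", "I", "D"),
                                morph = morphogen_params(),
                                domain_length = 70) {
  domain_label <- match.arg(domain_label)
  x <- c(V = 0, I = 0.45, D = 0.9)[[domain_label]] * domain_length
  prof <- profile_1d(x, morph, domain_length)
  list(A1 = prof$A1, A2 = prof$A2, x = x, label = domain_label)
}

#' Integrate the augmented sensitivity system
#'
#' Solves states and sensitivities from 22 to 35 hpf with `deSolve::ode`
#' (lsoda; relative tolerance 1e-8, absolute 1e-10) at fixed morphogen input.
#'
#' @param signal_context list with `A1`, `A2` (see [sensitivity_context()]).
#' @param grn `grn_params`.
#' @param times output times (hpf), default 131 points over 22-35.
#' @param rtol,atol solver tolerances.
#' @return object of class `sensitivity_trajectory`: `times`, `y` (times x 3),
#'   `s` (times x 3 genes x 7 parameters), `signal_context`.
#' @export
run_sensitivity <- function(signal_context, grn = grn_params(),
                            times = seq(22, 35, length.out = 131L),
                            rtol = 1e-8, atol = 1e-10) {
  A1 <- signal_context$A1; A2 <- signal_context$A2
  y0 <- c(rep(0, 3L), rep(0, 21L))   # state + sensitivities (zero initial data)
  f <- function(t, y, parms) {
    st <- pmax(y[1:3], 0)
    sm <- matrix(y[4:24], 3L, 7L)
    d <- augmented_rhs(st, sm, A1, A2, grn)
    list(c(d$dstate, as.numeric(d$ds)))
  }
  sol <- deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("run_sensitivity(): integration failed (istate ",
         attr(sol, "istate")[1L], ")")
  nt <- nrow(sol)
  y <- sol[, 2:4, drop = FALSE]
  colnames(y) <- GENES
  s <- array(sol[, 5:25], dim = c(nt, 3L, 7L),
             dimnames = list(NULL, GENES, paste0("p", 1:7)))
  structure(list(times = sol[, 1L], y = y, s = s,
                 signal_context = signal_context, grn = grn),
            class = "sensitivity_trajectory")
}

#' Central-finite-difference sensitivities (independent check)
#'
#' Re-solves the plain GRN at `p_i` perturbed by a relative `delta` and
#' differences the solutions; used to validate [run_sensitivity()].
#'
#' @param signal_context list with `A1`, `A2`.
#' @param grn `grn_params`.
#' @param times output times.
#' @param delta relative parameter perturbation.
#' @param rtol,atol solver tolerances (tight: the difference is small).
#' @return array times x 3 genes x 7 parameters.
#' @export
sensitivity_fd <- function(signal_context, grn = grn_params(),
                           times = seq(22, 35, length.out = 11L),
                           delta = 1e-5, rtol = 1e-11, atol = 1e-13) {
  A1 <- signal_context$A1; A2 <- signal_context$A2
  solve_y <- function(g) {
    f <- function(t, y, parms) list(as.numeric(grn_rhs(pmax(y, 0), A1, A2, g)))
    deSolve::ode(y = rep(0, 3L), times = times, func = f, parms = NULL,
                 rtol = rtol, atol = atol)[, 2:4, drop = FALSE]
  }
  out <- array(NA_real_, dim = c(length(times), 3L, 7L),
               dimnames = list(NULL, GENES, paste0("p", 1:7)))
  for (i in 1:7) {
    dp <- delta * grn$p[i]
    gp <- grn; gp$p[i] <- grn$p[i] + dp
    gm <- grn; gm$p[i] <- grn$p[i] - dp
    out[, , i] <- (solve_y(gp) - solve_y(gm)) / (2 * dp)
  }
  out
}

#' Box-plot summary of a sensitivity trajectory
#'
#' Samples the sensitivities at `n_points` equidistant times, then reports
#' median, quartiles and extremes per gene and parameter. Normalisation:
#' `"p1p5"` divides all values by the largest |s| over parameters p1 and p5 at
#' all sampled times (the headline-figure rule); `"per_gene"` divides each
#' gene's values by that gene's largest |s| over all parameters and times.
#'
#' @param traj `sensitivity_trajectory`.
#' @param n_points number of equidistant sample times (default 10).
#' @param normalization `"p1p5"` or `"per_gene"`.
#' @return data.frame (gene, parameter, median, q25, q75, lo, hi).
#' @export
summarize_sensitivity <- function(traj, n_points = 10L,
                                  normalization = c("p1p5", "per_gene")) {
  normalization <- match.arg(normalization)
  if (n_points < 2L) stop("summarize_sensitivity(): n_points must be >= 2")
  tt <- seq(min(traj$times), max(traj$times), length.out = n_points)
  idx <- vapply(tt, function(t) which.min(abs(traj$times - t)), integer(1L))
  s <- traj$s[idx, , , drop = FALSE]
  if (normalization == "p1p5") {
    nrm <- max(abs(s[, , c("p1", "p5")]))
    if (nrm == 0) stop("summarize_sensitivity(): zero normaliser (p1/p5)")
    s <- s / nrm
  } else {
    for (g in 1:3) {
      nrm <- max(abs(s[, g, ]))
      if (nrm == 0) stop("summarize_sensitivity(): zero normaliser for gene ", GENES[g])
      s[, g, ] <- s[, g, ] / nrm
    }
  }
  out <- expand.grid(gene = GENES, parameter = paste0("p", 1:7),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats <- t(apply(out, 1L, function(row) {
    v <- s[, row[["gene"]], row[["parameter"]]]
    c(median = median(v), q25 = unname(quantile(v, 0.25)),
      q75 = unname(quantile(v, 0.75)), lo = min(v), hi = max(v))
  }))
  cbind(out, as.data.frame(stats))
}
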