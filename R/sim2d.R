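# Growing 2D arch: off-lattice cell centres with Morse-potential mechanics,
# deforming outline enforced by repulsive boundary rings, a global ventral
# chemoattractant, a quasi-static morphogen grid, cell division and dorsal
# immigration, and one GRN copy per cell.

#' Mechanical parameters of the 2D tissue
#'
#' Pairwise cell interactions follow a generalised Morse potential
#' \eqn{U(r) = U_0 e^{-r/\xi_1} - V_0 e^{-r/\xi_2}} (short-range volume
#' exclusion, longer-range adhesion). Motion is overdamped: each centre moves
#' with velocity equal to the sum of the pair forces, an anisotropic
#' exponential chemoattractant pulling towards the ventral-anterior tip, and
#' a repulsive force from the boundary-ring nodes,
#' \eqn{S e^{-d/\xi_5}} per node. Forces are in um/h; `dt` is 180 s.
#'
#' @param U0,V0 Morse amplitudes; `xi1,xi2` their ranges (um).
#' @param W1,W2 chemoattractant weights; `xi3,xi4` its ranges (1/um).
#' @param S boundary-repulsion amplitude; `xi5` its range (um).
#' @param dt_s mechanics/GRN time step (seconds).
#' @param pair_cutoff pair interactions beyond this distance (um) are dropped.
#' @return object of class `mechanics_params` (with the equilibrium distance
#'   `r0` precomputed).
#' @export
mechanics_params <- function(U0 = 40, V0 = 20, xi1 = 1.2, xi2 = 4.5,
                             W1 = 300, W2 = 300, xi3 = 0.005, xi4 = 0.005,
                             S = 2, xi5 = 1.5, dt_s = 180, pair_cutoff = NULL) {
  if (any(c(xi1, xi2, xi3, xi4, xi5) <= 0) || any(c(U0, V0, W1, W2, S) < 0))
    stop("mechanics_params(): ranges must be positive, amplitudes non-negative")
  m <- structure(list(U0 = U0, V0 = V0, xi1 = xi1, xi2 = xi2,
                      W1 = W1, W2 = W2, xi3 = xi3, xi4 = xi4,
                      S = S, xi5 = xi5, dt_s = dt_s, dt_h = dt_s / 3600,
                      pair_cutoff = pair_cutoff),
                 class = "mechanics_params")
  m$r0 <- equilibrium_distance(m)
  # adhesion is contact-mediated: restrict pair interactions to the first
  # neighbour shell (with the tail included, summed attraction over outer
  # shells compresses the lattice far below r0 / collapses the swarm)
  if (is.null(pair_cutoff)) m$pair_cutoff <- 1.4 * m$r0
  m
}

#' Equilibrium separation of the Morse pair potential
#'
#' The distance at which the pair force vanishes:
#' \eqn{r_0 = \ln(U_0 \xi_2 / (V_0 \xi_1)) \cdot \xi_1 \xi_2 / (\xi_2 - \xi_1)}.
#'
#' @param m `mechanics_params` (or a bare list with U0, V0, xi1, xi2).
#' @return equilibrium distance (um), > 0.
#' @export
equilibrium_distance <- function(m) {
  if (m$xi1 == m$xi2)
    stop("equilibrium_distance(): xi1 == xi2 admits no stationary point")
  r0 <- log(m$U0 * m$xi2 / (m$V0 * m$xi1)) * m$xi1 * m$xi2 / (m$xi2 - m$xi1)
  if (!is.finite(r0) || r0 <= 0)
    stop("equilibrium_distance(): parameters admit no positive stationary point")
  r0
}

# scalar pair force (positive = repulsive) at separation r
morse_force <- function(r, m) {
  m$U0 / m$xi1 * exp(-r / m$xi1) - m$V0 / m$xi2 * exp(-r / m$xi2)
}

# forces on all cells: pair + chemoattractant + boundary rings (um/h)
tissue_forces <- function(positions, boundary_nodes, m, attractor) {
  n <- nrow(positions)
  fx <- numeric(n); fy <- numeric(n)
  eps <- m$r0 / 100   # coincident-centre guard
  if (n > 1L) {
    dx <- outer(positions[, 1L], positions[, 1L], "-")
    dy <- outer(positions[, 2L], positions[, 2L], "-")
    r <- sqrt(dx^2 + dy^2)
    act <- r < m$pair_cutoff
    diag(act) <- FALSE
    rr <- pmax(r, eps)
    f <- matrix(0, n, n)
    f[act] <- morse_force(rr[act], m) / rr[act]
    fx <- fx + rowSums(f * dx)
    fy <- fy + rowSums(f * dy)
  }
  # chemoattractant: separable exponential pull towards the attractor point
  d1 <- positions[, 1L] - attractor[1L]
  d2 <- positions[, 2L] - attractor[2L]
  fx <- fx - m$W1 * m$xi3 * exp(-m$xi3 * abs(d1)) * sign(d1)
  fy <- fy - m$W2 * m$xi4 * exp(-m$xi4 * abs(d2)) * sign(d2)
  # boundary rings: short-range repulsion, evaluated only within 8 xi5
  cut2 <- (8 * m$xi5)^2
  bx <- boundary_nodes[, 1L]; by <- boundary_nodes[, 2L]
  for (i in seq_len(n)) {
    ddx <- positions[i, 1L] - bx
    ddy <- positions[i, 2L] - by
    d2b <- ddx^2 + ddy^2
    sel <- d2b < cut2
    if (any(sel)) {
      d <- sqrt(pmax(d2b[sel], eps^2))
      w <- m$S / m$xi5 * exp(-d / m$xi5) / d
      fx[i] <- fx[i] + sum(w * ddx[sel])
      fy[i] <- fy[i] + sum(w * ddy[sel])
    }
  }
  cbind(fx, fy, deparse.level = 0)
}

#' Total force on one cell
#'
#' Sum of the Morse pair force from all other cells, the chemoattractant pull
#' towards the attractor point, and the boundary-ring repulsion.
#'
#' @param cell position of the focal cell (length-2).
#' @param others positions of the other cells (matrix, possibly 0 rows).
#' @param boundary_nodes boundary-ring node positions (matrix).
#' @param m `mechanics_params`.
#' @param attractor chemoattractant target `(s1, s2)` (um).
#' @return force vector (um/h).
#' @export
total_force <- function(cell, others, boundary_nodes, m,
                        attractor = c(0, 0)) {
  pos <- rbind(matrix(cell, ncol = 2L), others)
  tissue_forces(pos, boundary_nodes, m, attractor)[1L, ]
}

#' Advance all cell positions by one overdamped Euler step
#'
#' @param positions n x 2 matrix (um).
#' @param boundary_nodes boundary-ring nodes.
#' @param m `mechanics_params`.
#' @param attractor chemoattractant target.
#' @return updated positions.
#' @export
step_positions <- function(positions, boundary_nodes, m, attractor = c(0, 0)) {
  f <- tissue_forces(positions, boundary_nodes, m, attractor)
  disp <- m$dt_h * f
  if (max(abs(disp)) > m$r0)
    stop("step_positions(): displacement exceeds r0 in one step; reduce dt")
  positions + disp
}

#' Division / migration event schedule
#'
#' Splits the growth from `n0` to `n_end` cells into division and dorsal
#' immigration events at constant intervals spanning `(t0, t_end]`. With the
#' defaults (75 -> 150 cells, 90% divisions) this yields 68 division and 7
#' migration events.
#'
#' @param n0 initial cell count.
#' @param n_end final cell count at `t_end`.
#' @param division_fraction fraction of the increase due to division.
#' @param t0,t_end window (hpf).
#' @return object of class `growth_schedule` with sorted `division_times` and
#'   `migration_times`.
#' @export
make_growth_schedule <- function(n0 = 75L, n_end = 150L, division_fraction = 0.9,
                                 t0 = 22, t_end = 35) {
  if (n_end <= n0) stop("make_growth_schedule(): n_end must exceed n0")
  if (division_fraction < 0 || division_fraction > 1)
    stop("make_growth_schedule(): division_fraction must be in [0, 1]")
  n_new <- n_end - n0
  n_div <- round(division_fraction * n_new)
  n_mig <- n_new - n_div
  ev <- function(k) if (k == 0L) numeric(0) else t0 + seq_len(k) * (t_end - t0) / k
  structure(list(division_times = ev(n_div), migration_times = ev(n_mig),
                 n0 = n0, n_end = n_end, t0 = t0, t_end = t_end),
            class = "growth_schedule")
}

#' Divide one randomly chosen cell
#'
#' The daughter is placed at distance `r0/20` from the mother in a uniformly
#' random direction and inherits the mother's gene expression.
#'
#' @param tissue a `tissue_state` (list with `positions`, `states`, `origin`,
#'   `parent`, `ids`).
#' @param m `mechanics_params`.
#' @return updated tissue with one extra cell.
#' @export
apply_division <- function(tissue, m) {
  n <- nrow(tissue$positions)
  mother <- sample.int(n, 1L)
  ang <- runif(1L, 0, 2 * pi)
  newpos <- tissue$positions[mother, ] + (m$r0 / 20) * c(cos(ang), sin(ang))
  tissue$positions <- rbind(tissue$positions, newpos)
  tissue$states <- rbind(tissue$states, tissue$states[mother, , drop = FALSE])
  tissue$origin <- c(tissue$origin, "division")
  tissue$parent <- c(tissue$parent, tissue$ids[mother])
  tissue$ids <- c(tissue$ids, max(tissue$ids) + 1L)
  tissue
}

#' Add one immigrating cell at the dorsal boundary
#'
#' A uniformly random point (by arc length) on the dorsal segment of the
#' outline — the part within the dorsal-most `dorsal_band` fraction of the
#' current D-V extent — inset towards the centroid by `r0/2`. Migrants enter
#' already expressing dorsal genes at `dorsal_fraction` of the maximal dorsal
#' level (`(b_do + v_do)/d_do`).
#'
#' @param tissue `tissue_state`.
#' @param outline current outline polygon.
#' @param m `mechanics_params`.
#' @param grn `grn_params` (for the dorsal maximum).
#' @param dorsal_fraction entry dorsal expression fraction, default 0.4.
#' @param dorsal_band dorsal fraction of the D-V extent that counts as entry
#'   zone, default 0.25.
#' @return updated tissue with one extra cell.
#' @export
apply_migration <- function(tissue, outline, m, grn, dorsal_fraction = 0.4,
                            dorsal_band = 0.25) {
  dense <- resample_closed(outline, 400L)
  ymax <- max(outline[, 2L]); H <- diff(range(outline[, 2L]))
  sel <- dense[, 2L] >= ymax - dorsal_band * H
  if (!any(sel)) stop("apply_migration(): dorsal segment undefined")
  pt <- dense[sample(which(sel), 1L), ]
  cen <- polygon_centroid(outline)
  dir <- cen - pt
  pt <- pt + (m$r0 / 2) * dir / sqrt(sum(dir^2))
  d_max <- (grn$b[["D"]] + grn$v[["D"]]) / grn$d[["D"]]
  tissue$positions <- rbind(tissue$positions, pt)
  tissue$states <- rbind(tissue$states,
                         matrix(c(0, 0, dorsal_fraction * d_max), 1L,
                                dimnames = list(NULL, GENES)))
  tissue$origin <- c(tissue$origin, "migration")
  tissue$parent <- c(tissue$parent, NA_integer_)
  tissue$ids <- c(tissue$ids, max(tissue$ids) + 1L)
  tissue
}

# uniform placement inside the outline, inset from the wall and with a small
# minimum separation so the single equilibration step stays stable
place_cells_uniform <- function(n, outline, inset = 0, min_sep = 0) {
  xr <- range(outline[, 1L]); yr <- range(outline[, 2L])
  ring <- rbind(outline, outline[1L, ])
  out <- matrix(NA_real_, 0L, 2L)
  tries <- 0L
  while (nrow(out) < n && tries < 200L) {
    tries <- tries + 1L
    k <- 4L * (n - nrow(out)) + 10L
    cand <- cbind(runif(k, xr[1L], xr[2L]), runif(k, yr[1L], yr[2L]))
    ok <- point_in_polygon(cand[, 1L], cand[, 2L], outline)
    if (inset > 0) ok <- ok & dist_to_polyline(cand, ring) >= inset
    cand <- cand[ok, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      if (nrow(out) >= n) break
      if (min_sep > 0 && nrow(out) > 0L &&
          min((out[, 1L] - cand[i, 1L])^2 + (out[, 2L] - cand[i, 2L])^2) <
            min_sep^2) next
      out <- rbind(out, cand[i, , drop = FALSE])
    }
  }
  if (nrow(out) < n)
    stop("place_cells_uniform(): could not place ", n, " cells in the outline")
  out
}

ventral_tip <- function(outline) {
  outline[which.min(outline[, 2L]), ]
}

#' Run the growing 2D arch simulation
#'
#' Per 180 s step: (1) the outline is advanced by key-frame interpolation and
#' the boundary rings and ventral production zone rebuilt; (2) the
#' quasi-steady-state morphogen fields are re-solved on the fixed 50x50 grid;
#' (3) every cell samples its nearest grid point (with multiplicative noise
#' when stochastic) and advances its GRN copy by Euler / Euler-Maruyama;
#' (4) cell centres move by the overdamped force law; (5) due division and
#' migration events fire. Initialisation places `schedule$n0` cells uniformly
#' at random inside the first outline and relaxes them with a single position
#' step.
#'
#' @param series `outline_series` (must span the clock window).
#' @param clock `sim_clock`; default 22-35 hpf at 180 s (260 steps).
#' @param grn `grn_params`.
#' @param morph `morphogen_params`.
#' @param mech `mechanics_params`.
#' @param schedule `growth_schedule`.
#' @param seed RNG seed (placement, division, migration; and noise when
#'   stochastic). Fixed seed implies a bit-reproducible run.
#' @param stochastic apply morphogen (`eta1`, `eta2`) and GRN (`nu`) noise.
#' @param n_rings total boundary-ring node count (default 2118).
#' @param grid_shape morphogen grid, default `c(50, 50)`.
#' @param grid_margin margin (um) added around the final outline's bounding box.
#' @param clip clip gene states at zero after each step.
#' @return object of class `tissue_trajectory`: list with `times`, `frames`
#'   (each a `tissue_state`: `positions`, `states`, `origin`, `parent`, `ids`,
#'   `outline`, `t`), and the inputs.
#' @export
run_2d <- function(series = generate_outline_series(),
                   clock = sim_clock(dt_s = 180),
                   grn = grn_params(),
                   morph = morphogen_params(),
                   mech = mechanics_params(),
                   schedule = make_growth_schedule(t0 = clock$t0_hpf,
                                                   t_end = clock$t_end_hpf),
                   seed = 1L,
                   stochastic = FALSE,
                   n_rings = 2118L,
                   grid_shape = c(50L, 50L),
                   grid_margin = 3,
                   clip = TRUE) {
  set.seed(seed)
  final_poly <- interpolate_outline(series, clock$t_end_hpf)
  grid <- morphogen_grid(range(final_poly[, 1L]) + c(-grid_margin, grid_margin),
                         range(final_poly[, 2L]) + c(-grid_margin, grid_margin),
                         grid_shape)
  ops <- field_operators(grid, morph)
  outline <- interpolate_outline(series, clock$t0_hpf)
  tissue <- list(
    positions = place_cells_uniform(schedule$n0, outline,
                                    inset = mech$r0 / 2, min_sep = mech$r0 / 4),
    states = matrix(0, schedule$n0, 3L, dimnames = list(NULL, GENES)),
    origin = rep("initial", schedule$n0),
    parent = rep(NA_integer_, schedule$n0),
    ids = seq_len(schedule$n0))
  rings <- build_boundary_rings(outline, n_rings)
  tissue$positions <- step_positions(tissue$positions, rings$nodes, mech,
                                     ventral_tip(outline))   # equilibrate once
  dt <- clock$dt_h
  sqdt <- sqrt(dt)
  stride <- save_stride(clock)
  noisy_morph <- stochastic && (morph$eta1 > 0 || morph$eta2 > 0)
  noisy_grn <- stochastic && grn$nu > 0
  frames <- list()
  times <- numeric(0)
  snap <- function(tis, t, out) {
    c(tis, list(outline = out, t = t))
  }
  frames[[1L]] <- snap(tissue, clock$t0_hpf, outline)
  times[1L] <- clock$t0_hpf
  for (k in seq_len(clock$n_steps)) {
    t_prev <- clock$t0_hpf + (k - 1L) * dt
    t_now <- clock$t0_hpf + k * dt
    outline <- interpolate_outline(series, min(t_now, clock$t_end_hpf))
    rings <- build_boundary_rings(outline, n_rings, validate = FALSE)
    field <- solve_field_2d(outline, morph, grid = grid, operators = ops)
    samp <- sample_nearest(field, tissue$positions)
    a1 <- samp$A1; a2 <- samp$A2
    if (noisy_morph) {
      if (morph$eta1 > 0) a1 <- apply_noise(a1, morph$eta1)
      if (morph$eta2 > 0) a2 <- apply_noise(a2, morph$eta2)
    }
    st <- tissue$states + dt * grn_rhs(tissue$states, a1, a2, grn, t = t_prev)
    if (noisy_grn)
      st <- st + grn$nu * sqdt * matrix(rnorm(length(st)), nrow(st), 3L)
    if (clip) st[st < 0] <- 0
    if (any(!is.finite(st)))
      stop(sprintf("run_2d(): numerical instability in the GRN at step %d", k))
    tissue$states <- st
    tissue$positions <- step_positions(tissue$positions, rings$nodes, mech,
                                       ventral_tip(outline))
    n_div <- sum(schedule$division_times > t_prev + 1e-9 &
                   schedule$division_times <= t_now + 1e-9)
    n_mig <- sum(schedule$migration_times > t_prev + 1e-9 &
                   schedule$migration_times <= t_now + 1e-9)
    for (i in seq_len(n_div)) tissue <- apply_division(tissue, mech)
    for (i in seq_len(n_mig))
      tissue <- apply_migration(tissue, outline, mech, grn)
    if (k %% stride == 0L || k == clock$n_steps) {
      frames[[length(frames) + 1L]] <- snap(tissue, t_now, outline)
      times <- c(times, t_now)
    }
  }
  structure(list(times = times, frames = frames, series = series, clock = clock,
                 grn = grn, morph = morph, mech = mech, schedule = schedule,
                 seed = seed, stochastic = stochastic),
            class = "tissue_trajectory")
}

#' Final tissue frame of a 2D run
#' @param run `tissue_trajectory`.
#' @return the last frame (a `tissue_state`).
#' @export
final_tissue <- function(run) run$frames[[length(run$frames)]]

#' Per-gene maximum over cells and time of a 2D run
#' @param run `tissue_trajectory`.
#' @return named vector (V, I, D), the 2D classification reference.
#' @export
tissue_reference_max <- function(run) {
  mx <- c(V = 0, I = 0, D = 0)
  for (fr in run$frames) mx <- pmax(mx, apply(fr$states, 2L, max))
  mx
}

#' Frame export of a 2D run
#' @param run `tissue_trajectory`.
#' @param reference_max classification reference (default: the run's own).
#' @return data.frame (time_hpf, id, x, y, V, I, D, label, origin).
#' @export
tissue_as_data_frame <- function(run, reference_max = tissue_reference_max(run)) {
  do.call(rbind, lapply(run$frames, function(fr) {
    data.frame(time_hpf = fr$t, id = fr$ids,
               x = fr$positions[, 1L], y = fr$positions[, 2L],
               V = fr$states[, 1L], I = fr$states[, 2L], D = fr$states[, 3L],
               label = as.character(classify(fr$states, reference_max)),
               origin = fr$origin)
  }))
}
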