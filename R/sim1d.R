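# 1D dorso-ventral line model: fixed exponential gradients, one GRN per node,
# Euler forward / Euler-Maruyama integration, patterning classification,
# and stochastic ensembles.

#' 1D dorso-ventral domain
#'
#' @param length D-V extent (um), default 70.
#' @param n_nodes node count, default 201 (603 equations with 3 genes).
#' @return object of class `domain_1d` with equidistant `positions` including
#'   both endpoints.
#' @export
domain_1d <- function(length = 70, n_nodes = 201L) {
  stopifnot(length > 0, n_nodes >= 2L)
  structure(list(length = length, n_nodes = as.integer(n_nodes),
                 positions = seq(0, length, length.out = n_nodes)),
            class = "domain_1d")
}

#' Simulation clock
#'
#' Simulation time 0 corresponds to 22 hpf; runs stop at 35 hpf (transients,
#' not steady state). Default step 93.6 s gives exactly 500 Euler steps over
#' the 13 h window.
#'
#' @param t0_hpf start (hpf).
#' @param t_end_hpf end (hpf).
#' @param dt_s step size in seconds (93.6 in 1D, 180 in 2D).
#' @param save_every_min saved-frame cadence in simulated minutes (`Inf` =
#'   final frame only, 0 = every step).
#' @return object of class `sim_clock`.
#' @export
sim_clock <- function(t0_hpf = 22, t_end_hpf = 35, dt_s = 93.6,
                      save_every_min = 30) {
  span_s <- (t_end_hpf - t0_hpf) * 3600
  n_steps <- round(span_s / dt_s)
  if (abs(n_steps * dt_s - span_s) > 1e-6 * span_s)
    stop("sim_clock(): (t_end - t0) must be an exact multiple of dt")
  structure(list(t0_hpf = t0_hpf, t_end_hpf = t_end_hpf, dt_s = dt_s,
                 dt_h = dt_s / 3600, n_steps = as.integer(n_steps),
                 save_every_min = save_every_min),
            class = "sim_clock")
}

save_stride <- function(clock) {
  if (is.infinite(clock$save_every_min)) return(clock$n_steps)
  if (clock$save_every_min <= 0) return(1L)
  max(1L, round(clock$save_every_min * 60 / clock$dt_s))
}

#' Integrate the 1D model deterministically
#'
#' Each node carries one copy of the GRN with its own fixed morphogen input
#' from [profile_1d()]; all nodes advance by Euler forward.
#'
#' @param domain `domain_1d`.
#' @param clock `sim_clock`.
#' @param grn `grn_params`.
#' @param morph `morphogen_params`.
#' @param init initial state: n_nodes x 3 matrix, or `NULL` for all zeros.
#' @return object of class `trajectory_1d`: `times` (hpf), `states`
#'   (array saved-frames x nodes x 3), `positions`, plus the inputs.
#' @export
integrate_deterministic <- function(domain, clock = sim_clock(), grn = grn_params(),
                                    morph = morphogen_params(), init = NULL) {
  integrate_1d(domain, clock, grn, morph, init, stochastic = FALSE, seed = NULL)
}

#' Integrate the 1D model with noise (Euler-Maruyama)
#'
#' Per step and node the morphogen inputs receive fresh multiplicative noise
#' ([apply_noise()], strengths `morph$eta1`, `morph$eta2`; one draw per
#' morphogen per node, shared across equations) and each gene equation receives
#' an additive increment `nu * sqrt(dt) * N(0,1)`. States are clipped at zero
#' after each step (optional, on by default). With all noise strengths zero
#' the trajectory equals the deterministic one exactly.
#'
#' @inheritParams integrate_deterministic
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param clip clip states at 0 after each step.
#' @return `trajectory_1d`.
#' @export
integrate_stochastic <- function(domain, clock = sim_clock(), grn = grn_params(),
                                 morph = morphogen_params(), init = NULL,
                                 seed = 1L, clip = TRUE) {
  integrate_1d(domain, clock, grn, morph, init, stochastic = TRUE, seed = seed,
               clip = clip)
}

integrate_1d <- function(domain, clock, grn, morph, init, stochastic, seed,
                         clip = TRUE) {
  n <- domain$n_nodes
  prof <- profile_1d(domain$positions, morph, domain$length)
  A1 <- prof$A1; A2 <- prof$A2
  state <- if (is.null(init)) matrix(0, n, 3L, dimnames = list(NULL, GENES)) else {
    if (any(init < 0)) stop("integrate_1d(): init must be non-negative")
    matrix(init, n, 3L, dimnames = list(NULL, GENES))
  }
  if (stochastic && !is.null(seed)) set.seed(seed)
  dt <- clock$dt_h
  sqdt <- sqrt(dt)
  stride <- save_stride(clock)
  keep <- unique(c(seq(0L, clock$n_steps, by = stride), clock$n_steps))
  frames <- array(NA_real_, dim = c(length(keep), n, 3L),
                  dimnames = list(NULL, NULL, GENES))
  times <- clock$t0_hpf + keep * dt
  fi <- 1L
  frames[fi, , ] <- state
  noisy_morph <- stochastic && (morph$eta1 > 0 || morph$eta2 > 0)
  noisy_grn <- stochastic && grn$nu > 0
  for (k in seq_len(clock$n_steps)) {
    t_now <- clock$t0_hpf + (k - 1L) * dt
    a1 <- if (noisy_morph && morph$eta1 > 0) apply_noise(A1, morph$eta1) else A1
    a2 <- if (noisy_morph && morph$eta2 > 0) apply_noise(A2, morph$eta2) else A2
    state <- state + dt * grn_rhs(state, a1, a2, grn, t = t_now)
    if (noisy_grn)
      state <- state + grn$nu * sqdt * matrix(rnorm(3L * n), n, 3L)
    if (clip) state[state < 0] <- 0
    if (any(!is.finite(state)))
      stop(sprintf("integrate_1d(): numerical instability at step %d (t = %.2f hpf)",
                   k, t_now + dt))
    if (k %% stride == 0L || k == clock$n_steps) {
      fi <- fi + 1L
      frames[fi, , ] <- state
    }
  }
  structure(list(times = times, states = frames, positions = domain$positions,
                 domain = domain, clock = clock, grn = grn, morph = morph,
                 seed = seed, stochastic = stochastic),
            class = "trajectory_1d")
}

#' Final-frame states of a trajectory
#' @param traj `trajectory_1d`.
#' @return n_nodes x 3 matrix.
#' @export
final_state <- function(traj) {
  nf <- dim(traj$states)[1L]
  traj$states[nf, , , drop = TRUE]
}

#' Per-gene maximum over nodes and time
#'
#' The classification reference: "maximum achieved in time" in the
#' deterministic wild-type run.
#'
#' @param traj `trajectory_1d`.
#' @return named vector (V, I, D).
#' @export
trajectory_reference_max <- function(traj) {
  setNames(apply(traj$states, 3L, max), GENES)
}

#' Classify states into patterning labels
#'
#' A location is labelled by gene group g iff its normalised expression
#' `state_g / reference_max_g` exceeds `threshold` *and* strictly exceeds the
#' other two normalised levels; otherwise it is `unpatterned` (exact ties are
#' unpatterned).
#'
#' @param state n x 3 matrix (or length-3 vector) of expression levels.
#' @param reference_max per-gene maxima (> 0) of the reference run.
#' @param threshold expression fraction, default 0.2.
#' @return factor with levels V, I, D, unpatterned.
#' @export
classify <- function(state, reference_max, threshold = 0.2) {
  if (any(reference_max <= 0)) stop("classify(): reference maxima must be positive")
  if (threshold <= 0 || threshold >= 1) stop("classify(): threshold must be in (0,1)")
  if (is.null(dim(state))) state <- matrix(state, nrow = 1L)
  norm <- sweep(state, 2L, reference_max[GENES], "/")
  lab <- rep("unpatterned", nrow(norm))
  top <- max.col(norm, ties.method = "first")
  topval <- norm[cbind(seq_len(nrow(norm)), top)]
  # strictly greater than both others (ties fail), and above threshold
  second <- apply(norm, 1L, function(r) sort(r, decreasing = TRUE)[2L])
  ok <- topval > threshold & topval > second
  lab[ok] <- GENES[top[ok]]
  factor(lab, levels = c(GENES, "unpatterned"))
}

#' Stochastic ensemble of 1D runs
#'
#' Runs `n_runs` stochastic trajectories seeded `base_seed .. base_seed +
#' n_runs - 1` and aggregates, per node, saved time and gene, the sample mean
#' and the population standard deviation (divide by n; the bands are
#' descriptive).
#'
#' @param domain,clock,grn,morph as in [integrate_stochastic()].
#' @param n_runs ensemble size (>= 2), default 100.
#' @param base_seed first seed.
#' @param clip clip states at zero after each step.
#' @return object of class `ensemble_1d` with `times`, `mean`, `sd` (arrays
#'   frames x nodes x 3) and `n_runs`.
#' @export
ensemble <- function(domain, clock = sim_clock(), grn = grn_params(),
                     morph = morphogen_params(), n_runs = 100L, base_seed = 1L,
                     clip = TRUE) {
  if (n_runs < 2L) stop("ensemble(): n_runs must be >= 2")
  seeds <- base_seed + seq_len(n_runs) - 1L
  sum1 <- NULL; sum2 <- NULL; times <- NULL
  failed <- integer(0)
  for (s in seeds) {
    traj <- tryCatch(
      integrate_stochastic(domain, clock, grn, morph, seed = s, clip = clip),
      error = function(e) NULL)
    if (is.null(traj)) { failed <- c(failed, s); next }
    if (is.null(sum1)) {
      sum1 <- traj$states * 0; sum2 <- sum1; times <- traj$times
    }
    sum1 <- sum1 + traj$states
    sum2 <- sum2 + traj$states^2
  }
  if (length(failed))
    stop("ensemble(): member runs failed for seeds ",
         paste(failed, collapse = ", "))
  m <- sum1 / n_runs
  v <- sum2 / n_runs - m^2   # population convention
  v[v < 0] <- 0
  structure(list(times = times, mean = m, sd = sqrt(v), n_runs = n_runs,
                 positions = domain$positions, grn = grn, morph = morph,
                 base_seed = base_seed),
            class = "ensemble_1d")
}

#' Long-format export of a 1D trajectory
#' @param traj `trajectory_1d`.
#' @param reference_max classification reference; default the trajectory's own
#'   per-gene maxima.
#' @return data.frame (time_hpf, x_um, gene, value, label).
#' @export
trajectory_as_data_frame <- function(traj,
                                     reference_max = trajectory_reference_max(traj)) {
  nf <- length(traj$times); n <- length(traj$positions)
  labels <- character(nf * n)
  for (i in seq_len(nf))
    labels[(i - 1L) * n + seq_len(n)] <-
      as.character(classify(traj$states[i, , ], reference_max))
  out <- expand.grid(x_um = traj$positions, time_hpf = traj$times,
                     KEEP.OUT.ATTRS = FALSE)
  data.frame(time_hpf = rep(out$time_hpf, times = 3L),
             x_um = rep(out$x_um, times = 3L),
             gene = rep(GENES, each = nf * n),
             value = c(aperm(traj$states, c(2L, 1L, 3L))),
             label = rep(labels, times = 3L))
}
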