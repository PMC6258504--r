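#' @importFrom stats rnorm sd setNames quantile median cor approx
NULL

GENES <- c("V", "I", "D")

#' Gene-regulatory-network parameters
#'
#' Builds the parameter set of the three-gene-group arch network (ventral V,
#' intermediate I, dorsal D). Dissociation constants `p1..p7` gate the Hill
#' terms: p1 = Bmp activation of V, p2 = Edn1 activation of I, p3 = repression
#' of I by V, p4 = repression of I by D, p5 = Bmp activation of I,
#' p6 = repression of D by I, p7 = Edn1 repression of D.
#'
#' Temporal order of expression onset is encoded *intrinsically* by assigning
#' fast/medium/slow production and degradation magnitudes to the three groups
#' (earliest gene gets the largest rates) while keeping every group's
#' production/degradation ratio fixed, so all orders share identical steady
#' states. Alternatively (`timing_mode = "extrinsic"`) all groups share one
#' rate and the regulated production term of each group is switched on at a
#' fixed onset time (`gate_times`, hpf).
#'
#' Concentrations are dimensionless (steady-state-normalised); time is in
#' hours. Defaults: rate levels (3, 1.5, 0.75)/h, v/d = 1 per group,
#' b/d = 0.05, Hill coefficient 2, GRN noise strength `nu` = 0.05.
#'
#' @param order temporal order, one of `"VID","VDI","IVD","IDV","DIV","DVI"`
#'   (default `"IVD"`, the observed order).
#' @param p named or unnamed numeric vector of the seven dissociation constants.
#' @param rate_levels fast/medium/slow degradation rates (1/h) handed to the
#'   earliest/middle/latest gene group.
#' @param vd_ratio common production/degradation ratio (steady-state scale).
#' @param basal_ratio basal production as a fraction of degradation, b = ratio * d.
#' @param hill_n Hill coefficient.
#' @param nu additive gene-regulation noise strength (conc/sqrt(h)).
#' @param timing_mode `"intrinsic"` (rate magnitudes) or `"extrinsic"` (time gates).
#' @param gate_times named onset times (hpf) per gene group, used only when
#'   `timing_mode = "extrinsic"`.
#' @param extrinsic_rate single degradation rate (1/h) shared by all groups in
#'   extrinsic mode.
#' @return object of class `grn_params`.
#' @export
grn_params <- function(order = "IVD",
                       p = c(p1 = 0.6, p2 = 0.2, p3 = 0.45, p4 = 0.45,
                             p5 = 0.1, p6 = 0.5, p7 = 0.25),
                       rate_levels = c(3, 1.5, 0.75),
                       vd_ratio = 1,
                       basal_ratio = 0.05,
                       hill_n = 2L,
                       nu = 0.05,
                       timing_mode = c("intrinsic", "extrinsic"),
                       gate_times = c(V = 24, I = 22, D = 26),
                       extrinsic_rate = 1.5) {
  timing_mode <- match.arg(timing_mode)
  p <- unname(unlist(p))
  if (length(p) != 7L || any(!is.finite(p)) || any(p <= 0))
    stop("grn_params(): 'p' must be 7 positive dissociation constants")
  if (any(rate_levels <= 0) || vd_ratio <= 0 || basal_ratio < 0)
    stop("grn_params(): rates and ratios must be positive")
  names(p) <- paste0("p", 1:7)
  base <- structure(list(
    p = p, hill_n = as.integer(hill_n), nu = nu,
    vd_ratio = vd_ratio, basal_ratio = basal_ratio,
    rate_levels = sort(rate_levels, decreasing = TRUE),
    timing_mode = timing_mode,
    gate_times = gate_times[GENES],
    order = NULL, d = NULL, v = NULL, b = NULL,
    prod_scale = c(V = 1, I = 1, D = 1),  # per-group multiplier on v (perturbations)
    single_morphogen = FALSE   # merge the two gradients (p5 term dropped)
  ), class = "grn_params")
  if (timing_mode == "extrinsic") {
    d <- setNames(rep(extrinsic_rate, 3L), GENES)
    base$order <- order_permutation(order)  # order kept for bookkeeping
    base$d <- d
    base$v <- vd_ratio * d
    base$b <- basal_ratio * d
    base
  } else {
    apply_temporal_order(base, order)
  }
}

order_permutation <- function(order) {
  orders <- c("VID", "VDI", "IVD", "IDV", "DIV", "DVI")
  if (is.character(order) && length(order) == 1L) {
    order <- toupper(order)
    if (!order %in% orders)
      stop("temporal order must be one of: ", paste(orders, collapse = ", "))
    strsplit(order, "")[[1]]
  } else {
    order <- toupper(as.character(order))
    if (length(order) != 3L || !setequal(order, GENES))
      stop("temporal order must be a permutation of V, I, D")
    order
  }
}

#' All six temporal orders
#' @return character vector of the six orders.
#' @export
temporal_orders <- function() c("VID", "VDI", "IVD", "IDV", "DIV", "DVI")

#' Assign rate magnitudes realising a temporal order
#'
#' Hands the fast/medium/slow (production, degradation) magnitude pair to the
#' earliest/middle/latest gene group of `order`, preserving each group's v/d
#' and b/d ratios, so the steady states of the returned system are identical
#' to those of `base` for any fixed morphogen input.
#'
#' @param base a `grn_params` object (intrinsic timing).
#' @param order temporal order string or 3-vector, earliest first.
#' @return `grn_params` with `d`, `v`, `b` set per group.
#' @export
apply_temporal_order <- function(base, order) {
  stopifnot(inherits(base, "grn_params"))
  perm <- order_permutation(order)
  d <- setNames(numeric(3L), GENES)
  d[perm] <- base$rate_levels  # earliest <- fastest
  base$order <- perm
  base$d <- d
  base$v <- base$vd_ratio * d
  base$b <- base$basal_ratio * d
  base
}

gate_factor <- function(params, t) {
  if (params$timing_mode != "extrinsic" || is.null(t)) return(c(V = 1, I = 1, D = 1))
  as.numeric(t >= params$gate_times[GENES]) |> setNames(GENES)
}

#' Right-hand side of the arch GRN
#'
#' Time derivatives of the three gene groups at one or many locations/cells:
#' \deqn{dV/dt = -d_{ve} V + b_{ve} + v_{ve}\, h^+(A_1, p_1)}
#' \deqn{dI/dt = -d_{in} I + b_{in} + v_{in}\, h^+(A_2, p_2)\, h^-(V, p_3)\,
#'   h^-(D, p_4)\, h^+(A_1, p_5)}
#' \deqn{dD/dt = -d_{do} D + b_{do} + v_{do}\, h^-(I, p_6)\, h^-(A_2, p_7)}
#' with \eqn{h^+}/\eqn{h^-} the activating/repressing Hill terms. In extrinsic
#' timing mode each regulated production term is multiplied by the indicator
#' \eqn{[t \ge} onset time\eqn{]}; basal production is always on.
#'
#' @param state numeric matrix (rows = locations, columns V, I, D) or length-3
#'   vector; must be non-negative.
#' @param A1,A2 Bmp and Edn1 concentrations (scalar or one per row).
#' @param params a `grn_params` object.
#' @param t simulation time (hpf); only consulted in extrinsic mode.
#' @return derivative with the same shape as `state`.
#' @export
grn_rhs <- function(state, A1, A2, params, t = NULL) {
  vec <- is.null(dim(state))
  if (vec) state <- matrix(state, nrow = 1L, dimnames = list(NULL, GENES))
  if (any(state < 0) || any(A1 < 0) || any(A2 < 0))
    stop("grn_rhs(): state and morphogen inputs must be non-negative")
  n <- params$hill_n
  p <- params$p
  g <- gate_factor(params, t) * params$prod_scale
  if (isTRUE(params$single_morphogen)) A2 <- A1   # merged-gradient variant
  V <- state[, 1L]; I <- state[, 2L]; D <- state[, 3L]
  dV <- -params$d[["V"]] * V + params$b[["V"]] +
    params$v[["V"]] * g[["V"]] * hill(A1, p[["p1"]], n)
  h5 <- if (isTRUE(params$single_morphogen)) 1 else hill(A1, p[["p5"]], n)
  dI <- -params$d[["I"]] * I + params$b[["I"]] +
    params$v[["I"]] * g[["I"]] * hill(A2, p[["p2"]], n) *
    hill(V, p[["p3"]], n, "repressing") * hill(D, p[["p4"]], n, "repressing") *
    h5
  dD <- -params$d[["D"]] * D + params$b[["D"]] +
    params$v[["D"]] * g[["D"]] * hill(I, p[["p6"]], n, "repressing") *
    hill(A2, p[["p7"]], n, "repressing")
  out <- cbind(V = dV, I = dI, D = dD)
  if (vec) out[1L, ] else out
}

#' Fixed point of the GRN at constant morphogen input
#'
#' Damped fixed-point iteration on the production/degradation balance
#' y <- (1 - w) y + w (b + v H(y))/d. A verification aid: the simulations
#' themselves run transients only.
#'
#' @param A1,A2 morphogen concentrations (scalars, >= 0).
#' @param params `grn_params`.
#' @param tol residual tolerance on `grn_rhs` (per component).
#' @param max_iter iteration cap.
#' @param damping step fraction in (0, 1].
#' @return named state vector (V, I, D) with `grn_rhs` residual < `tol`.
#' @export
fixed_point <- function(A1, A2, params, tol = 1e-12, max_iter = 10000L,
                        damping = 0.5) {
  if (A1 < 0 || A2 < 0) stop("fixed_point(): morphogen inputs must be non-negative")
  # extrinsic gates fully open at the fixed point (t beyond all onsets)
  t_open <- if (params$timing_mode == "extrinsic") max(params$gate_times) else NULL
  y <- setNames(rep(0, 3L), GENES)
  for (k in seq_len(max_iter)) {
    rhs <- grn_rhs(y, A1, A2, params, t = t_open)
    target <- y + rhs / params$d[GENES]      # = (b + v H(y))/d
    y_new <- (1 - damping) * y + damping * target
    if (max(abs(grn_rhs(y_new, A1, A2, params, t = t_open))) < tol) return(y_new)
    y <- y_new
  }
  stop(sprintf(
    "fixed_point(): no convergence after %d iterations (residual %.3g)",
    max_iter, max(abs(grn_rhs(y, A1, A2, params, t = t_open)))))
}

#' @export
print.grn_params <- function(x, ...) {
  cat("Arch GRN parameters\n")
  cat("  temporal order:", paste(x$order, collapse = ""),
      sprintf("(%s timing)\n", x$timing_mode))
  cat("  d (1/h):", paste(sprintf("%s=%.3g", GENES, x$d[GENES]), collapse = " "), "\n")
  cat("  v/d =", x$vd_ratio, "  b/d =", x$basal_ratio,
      "  Hill n =", x$hill_n, "  nu =", x$nu, "\n")
  cat("  p1..p7:", paste(sprintf("%.3g", x$p), collapse = " "), "\n")
  invisible(x)
}
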