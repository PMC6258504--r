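#' Morphogen gradient parameters
#'
#' Bmp (A1) and Edn1 (A2) are secreted at the ventral end of the arch and form
#' ventral-to-dorsal declining gradients. In 1D they are time-independent
#' exponentials \eqn{A_k(x) = scale_k\, amp_k\, e^{-x/\lambda_k}}; in 2D the
#' quasi-steady state of diffusion + uniform degradation with a moving ventral
#' production zone is solved on a grid. Edn1 diffuses much faster than Bmp
#' (measured diffusion coefficients ~104-140 vs ~2-4.4 um^2/s), so its decay
#' length is larger: default `lambda2` (45 um) > `lambda1` (15 um).
#'
#' @param amp1,amp2 source amplitudes (concentration, dimensionless units).
#' @param lambda1,lambda2 decay lengths (um); `lambda2 > lambda1` required.
#' @param eta1,eta2 multiplicative noise strengths (dimensionless).
#' @param scale1,scale2 perturbation multipliers (1 = wild type).
#' @param uniform2 optional spatially-uniform Edn1 override, as a fraction of
#'   the wild-type gradient maximum (`NULL` = gradient as usual).
#' @param band_width width (um) of the ventral production band used by the 2D
#'   field solver.
#' @return object of class `morphogen_params`.
#' @export
morphogen_params <- function(amp1 = 1, amp2 = 1,
                             lambda1 = 15, lambda2 = 45,
                             eta1 = 0, eta2 = 0,
                             scale1 = 1, scale2 = 1,
                             uniform2 = NULL,
                             band_width = 2) {
  if (lambda2 <= lambda1)
    stop("morphogen_params(): lambda2 must exceed lambda1 (Edn1 reaches farther)")
  if (amp1 <= 0 || amp2 <= 0 || lambda1 <= 0)
    stop("morphogen_params(): amplitudes and decay lengths must be positive")
  if (scale1 < 0 || scale2 < 0 || eta1 < 0 || eta2 < 0)
    stop("morphogen_params(): scales and noise strengths must be non-negative")
  structure(list(amp1 = amp1, amp2 = amp2, lambda1 = lambda1, lambda2 = lambda2,
                 eta1 = eta1, eta2 = eta2, scale1 = scale1, scale2 = scale2,
                 uniform2 = uniform2, band_width = band_width),
            class = "morphogen_params")
}

#' 1D morphogen profiles
#'
#' @param x positions along the D-V axis (um, ventral at 0); must lie in
#'   \[0, `domain_length`\].
#' @param params `morphogen_params`.
#' @param domain_length extent of the 1D domain (um).
#' @return list with components `A1`, `A2` (same length as `x`).
#' @export
profile_1d <- function(x, params, domain_length = 70) {
  if (any(x < 0) || any(x > domain_length))
    stop("profile_1d(): position outside the [0, ", domain_length, "] um domain")
  A1 <- params$scale1 * params$amp1 * exp(-x / params$lambda1)
  A2 <- if (!is.null(params$uniform2))
    rep(params$uniform2 * params$amp2, length(x))
  else
    params$scale2 * params$amp2 * exp(-x / params$lambda2)
  list(A1 = A1, A2 = A2)
}

#' Multiplicative morphogen noise
#'
#' Gaussian noise scaled with the local concentration and clipped at zero:
#' `max(0, A + eta * draw * A)`. Draws are resampled independently at every
#' evaluation (white noise).
#'
#' @param A concentration(s), >= 0.
#' @param eta noise strength, >= 0.
#' @param draw standard-normal deviate(s); defaults to fresh `rnorm` draws.
#' @return noisy concentration(s), clipped at 0. Exact identity when `eta = 0`.
#' @export
apply_noise <- function(A, eta, draw = rnorm(length(A))) {
  if (any(A < 0) || eta < 0) stop("apply_noise(): A and eta must be non-negative")
  if (eta == 0) return(A)
  pmax(0, A + eta * draw * A)
}

# -- 2D quasi-steady-state field -----------------------------------------------

#' Regular morphogen grid covering a bounding box
#'
#' @param xlim,ylim bounding box (um).
#' @param grid_shape `(rows, cols)`, default `c(50, 50)`.
#' @return list with `x`, `y` (vectors of length rows*cols, row-major by row
#'   index), `rows`, `cols`, `xs`, `ys` coordinate axes.
#' @keywords internal
morphogen_grid <- function(xlim, ylim, grid_shape = c(50L, 50L)) {
  rows <- grid_shape[1L]; cols <- grid_shape[2L]
  xs <- seq(xlim[1L], xlim[2L], length.out = cols)
  ys <- seq(ylim[1L], ylim[2L], length.out = rows)
  idx <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  list(x = xs[idx$col], y = ys[idx$row], row = idx$row, col = idx$col,
       rows = rows, cols = cols, xs = xs, ys = ys,
       hx = diff(xlim) / (cols - 1L), hy = diff(ylim) / (rows - 1L))
}

# Factorised steady-state operator (k I - D L) with zero-flux Laplacian for a
# given decay length; k = 1, D = lambda^2 so the far-field decay length is lambda.
field_operator <- function(grid, lambda) {
  rows <- grid$rows; cols <- grid$cols
  n <- rows * cols
  id <- function(r, c) (c - 1L) * rows + r
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  rc <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  r <- rc$r; c <- rc$c
  here <- id(r, c)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, rep_len(v, length(i)))
  }
  hx2 <- grid$hx^2; hy2 <- grid$hy^2
  # neighbours with zero-flux (mirror) boundary handling
  for (dd in list(c(0L, -1L, hx2), c(0L, 1L, hx2), c(-1L, 0L, hy2), c(1L, 0L, hy2))) {
    rn <- r + dd[1L]; cn <- c + dd[2L]
    inside <- rn >= 1L & rn <= rows & cn >= 1L & cn <= cols
    add(here[inside], id(rn[inside], cn[inside]), -lambda^2 / dd[3L])
    # mirrored neighbour folds back onto the centre point
    add(here[!inside], here[!inside], -lambda^2 / dd[3L])
  }
  add(here, here, 1 + 2 * lambda^2 / hx2 + 2 * lambda^2 / hy2)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"))
}

#' Solve the 2D quasi-steady-state morphogen fields
#'
#' Steady state of diffusion with uniform degradation and a constant source on
#' the production zone, solved on a regular grid with zero-flux boundaries,
#' then normalised so the field maximum equals `scale_k * amp_k` (wild-type
#' amplitude at the source). The production zone is the set of grid points
#' inside the outline within `band_width` of its ventral-most extent.
#'
#' @param outline closed simple polygon, 2-column matrix (um), used to place
#'   the production zone.
#' @param params `morphogen_params`.
#' @param grid precomputed grid from `morphogen_grid`, or `NULL` to build a
#'   50x50 grid over the outline's bounding box.
#' @param operators optional list of cached factorisations (`op1`, `op2`) from
#'   `field_operators`, reused across time steps.
#' @param production_zone optional logical vector over grid points overriding
#'   the ventral-band construction.
#' @return object of class `morphogen_field` with `grid`, `values1`, `values2`,
#'   `production_zone`.
#' @export
solve_field_2d <- function(outline, params, grid = NULL, operators = NULL,
                           production_zone = NULL) {
  if (is.null(grid)) {
    grid <- morphogen_grid(range(outline[, 1L]), range(outline[, 2L]))
  }
  if (is.null(production_zone)) {
    ymin <- min(outline[, 2L])
    cand <- which(grid$y <= ymin + params$band_width)   # ventral band only
    production_zone <- logical(length(grid$x))
    if (length(cand))
      production_zone[cand] <- pracma::inpolygon(
        grid$x[cand], grid$y[cand], outline[, 1L], outline[, 2L],
        boundary = TRUE)
  }
  if (!any(production_zone))
    stop("solve_field_2d(): empty production zone (outline does not reach the grid)")
  if (is.null(operators))
    operators <- field_operators(grid, params)
  src <- as.numeric(production_zone)
  raw1 <- as.numeric(Matrix::solve(operators$op1, src))
  raw2 <- as.numeric(Matrix::solve(operators$op2, src))
  v1 <- params$scale1 * params$amp1 * raw1 / max(raw1)
  v2 <- if (!is.null(params$uniform2))
    rep(params$uniform2 * params$amp2, length(raw2))
  else
    params$scale2 * params$amp2 * raw2 / max(raw2)
  structure(list(grid = grid, values1 = pmax(0, v1), values2 = pmax(0, v2),
                 production_zone = production_zone),
            class = "morphogen_field")
}

#' Cache the two field factorisations for repeated solves
#' @param grid grid from `morphogen_grid`.
#' @param params `morphogen_params`.
#' @return list with `op1`, `op2`.
#' @export
field_operators <- function(grid, params) {
  list(op1 = field_operator(grid, params$lambda1),
       op2 = field_operator(grid, params$lambda2))
}

#' Nearest-grid-point sampling of a 2D field
#'
#' Each cell experiences the morphogen concentrations of the grid point closest
#' to its centre. Ties are broken towards the lowest (row, col) index.
#'
#' @param field `morphogen_field`.
#' @param position n x 2 matrix of positions (um) inside the grid bounding box.
#' @return list with vectors `A1`, `A2` (one value per row of `position`).
#' @export
sample_nearest <- function(field, position) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 2L)
  g <- field$grid
  eps <- 1e-9
  if (any(position[, 1L] < min(g$xs) - eps) || any(position[, 1L] > max(g$xs) + eps) ||
      any(position[, 2L] < min(g$ys) - eps) || any(position[, 2L] > max(g$ys) + eps))
    stop("sample_nearest(): position outside the grid bounding box")
  # nearest index per axis; exact midpoints resolve to the lower index
  near_idx <- function(v, axis) {
    i <- round((v - axis[1L]) / (axis[2L] - axis[1L])) + 1L
    frac <- (v - axis[1L]) / (axis[2L] - axis[1L])
    mid <- abs(frac - floor(frac) - 0.5) < 1e-12
    i[mid] <- floor(frac[mid]) + 1L       # lower index on ties
    pmin(pmax(i, 1L), length(axis))
  }
  ci <- near_idx(position[, 1L], g$xs)
  ri <- near_idx(position[, 2L], g$ys)
  k <- (ci - 1L) * g$rows + ri
  list(A1 = field$values1[k], A2 = field$values2[k])
}

#' Export a field snapshot as a data frame
#' @param field `morphogen_field`.
#' @return data.frame with row, col, x, y, A1, A2.
#' @export
field_as_data_frame <- function(field) {
  g <- field$grid
  data.frame(row = g$row, col = g$col, x = g$x, y = g$y,
             A1 = field$values1, A2 = field$values2,
             production = field$production_zone)
}
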