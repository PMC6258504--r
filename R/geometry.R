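# Synthetic arch geometry: outline key frames, interpolation, boundary rings,
# and reference expression-boundary curves. This stage stands in for traced,
# averaged arch outlines; every object it emits is synthetic by construction.

#' D-V extent growth law of the synthetic arch
#'
#' Linear growth of the dorso-ventral extent from 30 um at 14 hpf to 60 um at
#' 36 hpf, matching the observed rough doubling of arch D-V length over the
#' patterning window.
#'
#' @param t_hpf time(s) in hours post-fertilisation.
#' @return D-V extent (um).
#' @export
dv_extent_at <- function(t_hpf) 30 + 30 * (t_hpf - 14) / 22

#' Generate a series of synthetic arch outlines
#'
#' Emits one closed simple polygon per key time. The shape is a smooth,
#' slightly bean-shaped oval whose D-V extent follows [dv_extent_at()]; the
#' dorsal end stays fixed while the ventral tip extends ventrally and the
#' whole ventral half shifts anteriorly (negative x), emulating the observed
#' anterior-ventral elongation. All key frames share the same angular
#' parameterisation, so vertices correspond one-to-one across frames and
#' linear interpolation between frames is well defined.
#'
#' @param key_times key frame times (hpf), default `c(22, 24, 28, 32, 35)`.
#' @param n_vertices vertices per polygon.
#' @param width_ratio A-P width as a fraction of the D-V extent.
#' @param anterior_shift anterior drift of the ventral tip (um/h).
#' @param jitter radial shape jitter amplitude (fraction); 0 = deterministic.
#' @param seed RNG seed used only when `jitter > 0`.
#' @return object of class `outline_series`: list with `key_times`, `polygons`
#'   (list of closed 2-column matrices, first vertex not repeated), `dv_axis`.
#' @export
generate_outline_series <- function(key_times = c(22, 24, 28, 32, 35),
                                    n_vertices = 200L,
                                    width_ratio = 0.6,
                                    anterior_shift = 0.5,
                                    jitter = 0,
                                    seed = 1L) {
  stopifnot(n_vertices >= 8L, width_ratio > 0)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  wig <- rep(0, n_vertices)
  if (jitter > 0) {
    set.seed(seed)
    # smooth periodic perturbation (low-order Fourier modes)
    for (m in 2:4) {
      wig <- wig + rnorm(1, 0, jitter / 3) * cos(m * theta) +
        rnorm(1, 0, jitter / 3) * sin(m * theta)
    }
  }
  y_top <- dv_extent_at(36)   # dorsal edge pinned at the final extent
  polys <- lapply(key_times, function(t) {
    H <- dv_extent_at(t)
    W <- width_ratio * H
    # s in [0,1]: 0 at dorsal (sin=1), 1 at ventral (sin=-1)
    s <- (1 - sin(theta)) / 2
    cx <- -anterior_shift * (t - key_times[1L]) * s   # ventral half drifts anterior
    x <- cx + (W / 2) * cos(theta) * (1 + wig)
    y <- y_top - H * s
    poly <- cbind(x = x, y = y)
    if (!is_simple_polygon(poly))
      stop("generate_outline_series(): parameters produce a self-intersecting outline")
    poly
  })
  structure(list(key_times = key_times, polygons = polys,
                 dv_axis = c(0, 1), y_top = y_top),
            class = "outline_series")
}

#' Interpolate the outline at an arbitrary time
#'
#' Vertex-wise linear interpolation between the bracketing key frames; exact at
#' key times.
#'
#' @param series `outline_series`.
#' @param t time (hpf) within `range(series$key_times)`.
#' @return closed polygon (2-column matrix).
#' @export
interpolate_outline <- function(series, t) {
  kt <- series$key_times
  if (t < kt[1L] || t > kt[length(kt)])
    stop("interpolate_outline(): t outside the key-frame range")
  i <- findInterval(t, kt, rightmost.closed = TRUE)
  if (t == kt[i]) return(series$polygons[[i]])
  w <- (t - kt[i]) / (kt[i + 1L] - kt[i])
  (1 - w) * series$polygons[[i]] + w * series$polygons[[i + 1L]]
}

#' Build the two repulsive boundary rings
#'
#' One ring of nodes lies on the outline, a second is offset outward by
#' `offset`; nodes are equally spaced by arc length within each ring and the
#' two rings total exactly `n_total` nodes, split proportionally to perimeter.
#'
#' @param polygon closed simple polygon (2-column matrix).
#' @param n_total total node count across both rings (default 2118).
#' @param offset outward offset of the second ring (um).
#' @param validate check the offset ring for self-intersection (skippable in
#'   tight loops over smoothly deforming outlines).
#' @return list with `nodes` ((n_total) x 2 matrix), `inner`, `outer` index
#'   vectors.
#' @export
build_boundary_rings <- function(polygon, n_total = 2118L, offset = 2,
                                 validate = TRUE) {
  if (n_total %% 2L != 0L) stop("build_boundary_rings(): n_total must be even")
  outer_poly <- offset_polygon(polygon, offset)
  if (validate && !is_simple_polygon(outer_poly))
    stop("build_boundary_rings(): offset ring self-intersects")
  per_in <- polygon_perimeter(polygon)
  per_out <- polygon_perimeter(outer_poly)
  n_in <- round(n_total * per_in / (per_in + per_out))
  n_out <- n_total - n_in
  inner <- resample_closed(polygon, n_in)
  outer <- resample_closed(outer_poly, n_out)
  list(nodes = rbind(inner, outer),
       inner = seq_len(n_in), outer = n_in + seq_len(n_out))
}

#' Reference wild-type expression boundary curves
#'
#' Level sets of the D-V coordinate at fractions `f_vi` and `f_id` of the
#' arch's D-V extent at `t`, measured from the ventral end and clipped to the
#' outline: synthetic stand-ins for averaged ventral-intermediate (hand2-like)
#' and intermediate-dorsal (dlx5a-like) expression boundaries.
#'
#' @param series `outline_series`.
#' @param fractions `(f_vi, f_id)` with `0 < f_vi < f_id < 1`.
#' @param t time (hpf) at which the reference is drawn (default 35).
#' @return object of class `reference_boundaries`: list with `vi_curve`,
#'   `id_curve` (2-column polylines) and the fractions used.
#' @export
generate_reference_boundaries <- function(series, fractions = c(0.11, 0.5),
                                          t = 35) {
  f_vi <- fractions[1L]; f_id <- fractions[2L]
  if (!(f_vi >= 0 && f_vi < f_id && f_id < 1))
    stop("generate_reference_boundaries(): need 0 <= f_vi < f_id < 1")
  poly <- interpolate_outline(series, t)
  ymin <- min(poly[, 2L]); H <- diff(range(poly[, 2L]))
  level_curve <- function(f) {
    y0 <- ymin + f * H
    xr <- polygon_chord(poly, y0)
    eps <- 1e-6 * diff(xr)   # keep endpoints strictly interior
    cbind(x = seq(xr[1L] + eps, xr[2L] - eps, length.out = 25L), y = y0)
  }
  structure(list(vi_curve = level_curve(f_vi), id_curve = level_curve(f_id),
                 fractions = c(f_vi = f_vi, f_id = f_id), t = t),
            class = "reference_boundaries")
}

# -- polygon utilities ----------------------------------------------------------

polygon_perimeter <- function(poly) {
  p2 <- rbind(poly, poly[1L, ])
  sum(sqrt(rowSums(diff(p2)^2)))
}

polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_centroid <- function(poly) colMeans(poly)

#' D-V extent of a polygon along the dorso-ventral axis
#' @param poly 2-column matrix.
#' @param dv_axis unit vector, default `(0, 1)`.
#' @return extent (um).
#' @export
dv_extent <- function(poly, dv_axis = c(0, 1)) {
  proj <- poly %*% dv_axis
  diff(range(proj))
}

# segment-intersection based simplicity check (O(n^2) on the small outlines used)
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  a <- poly
  b <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE])
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]   # skip edges sharing a vertex
    if (!length(js)) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

segments_intersect <- function(p1, p2, q1, q2) {
  # vectorised over rows of q1/q2
  d <- p2 - p1
  e <- q2 - q1
  denom <- d[1L] * e[, 2L] - d[2L] * e[, 1L]
  rx <- q1[, 1L] - p1[1L]; ry <- q1[, 2L] - p1[2L]
  t <- (rx * e[, 2L] - ry * e[, 1L]) / denom
  u <- (rx * d[2L] - ry * d[1L]) / denom
  ok <- abs(denom) > 1e-12
  ok & t > 0 & t < 1 & u > 0 & u < 1
}

# outward offset along averaged vertex normals (adequate for the smooth,
# near-convex synthetic outlines)
offset_polygon <- function(poly, offset) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  e1 <- poly[nxt, ] - poly           # edge leaving each vertex
  e0 <- poly - poly[prv, ]           # edge arriving
  normal_of <- function(e) {
    len <- sqrt(rowSums(e^2))
    cbind(e[, 2L], -e[, 1L]) / len
  }
  nv <- normal_of(e0) + normal_of(e1)
  nv <- nv / sqrt(rowSums(nv^2))
  # ensure outward orientation: flip if pointing towards the centroid
  cen <- polygon_centroid(poly)
  dotc <- rowSums(nv * sweep(poly, 2L, cen))
  if (mean(sign(dotc)) < 0) nv <- -nv
  poly + offset * nv
}

# resample a closed polygon to n equally spaced (arc length) nodes
resample_closed <- function(poly, n) {
  p2 <- rbind(poly, poly[1L, ])
  seg <- sqrt(rowSums(diff(p2)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  x <- approx(cum, p2[, 1L], xout = s)$y
  y <- approx(cum, p2[, 2L], xout = s)$y
  cbind(x = x, y = y)
}

# x-range of the widest chord of the polygon at height y0
polygon_chord <- function(poly, y0) {
  p2 <- rbind(poly, poly[1L, ])
  xs <- numeric(0)
  for (i in seq_len(nrow(poly))) {
    y1 <- p2[i, 2L]; y2 <- p2[i + 1L, 2L]
    if ((y1 - y0) * (y2 - y0) <= 0 && y1 != y2) {
      w <- (y0 - y1) / (y2 - y1)
      xs <- c(xs, p2[i, 1L] + w * (p2[i + 1L, 1L] - p2[i, 1L]))
    }
  }
  if (length(xs) < 2L) stop("polygon_chord(): level does not cross the outline")
  range(xs)
}

# minimal distance from points to a polyline (vectorised over points)
dist_to_polyline <- function(points, polyline) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  m <- nrow(polyline)
  best <- rep(Inf, nrow(points))
  for (i in seq_len(m - 1L)) {
    a <- polyline[i, ]; b <- polyline[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(points)) else
      pmin(1, pmax(0, ((points[, 1L] - a[1L]) * ab[1L] +
                       (points[, 2L] - a[2L]) * ab[2L]) / len2))
    dx <- points[, 1L] - (a[1L] + t * ab[1L])
    dy <- points[, 2L] - (a[2L] + t * ab[2L])
    best <- pmin(best, sqrt(dx^2 + dy^2))
  }
  best
}

point_in_polygon <- function(x, y, poly) {
  pracma::inpolygon(x, y, poly[, 1L], poly[, 2L], boundary = TRUE)
}
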