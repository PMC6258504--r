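# Quantitative readouts: boundary error E, precision (ensemble variability),
# accuracy (distance to reference boundaries), perturbation-outcome
# classification, and the precision-accuracy trade-off across temporal orders.

#' Cells sitting on a domain interface
#'
#' Returns the cells carrying the interface's ventral-side label (`V` for the
#' V-I interface, `I` for I-D) that have at least one contact-graph neighbour
#' carrying the dorsal-side label. The contact graph connects cell centres
#' closer than `contact_factor * r0`, a standard proxy for the Voronoi
#' neighbourhood at near-uniform packing.
#'
#' @param tissue a `tissue_state` (frame of [run_2d()]).
#' @param interface `"V-I"` or `"I-D"`.
#' @param reference_max classification reference (per-gene maxima of the
#'   deterministic wild-type run).
#' @param r0 equilibrium cell spacing (um).
#' @param contact_factor adjacency radius in units of `r0`.
#' @param threshold classification threshold.
#' @return integer indices of boundary cells (possibly empty, with a warning
#'   when either side has no labelled cells).
#' @export
find_boundary_cells <- function(tissue, interface = c("V-I", "I-D"),
                                reference_max, r0 = mechanics_params()$r0,
                                contact_factor = 1.5, threshold = 0.2) {
  interface <- match.arg(interface)
  lab <- classify(tissue$states, reference_max, threshold)
  side <- if (interface == "V-I") c("V", "I") else c("I", "D")
  iv <- which(lab == side[1L]); id <- which(lab == side[2L])
  if (!length(iv) || !length(id)) {
    warning("find_boundary_cells(): no labelled cells on one side of ", interface)
    return(integer(0))
  }
  pos <- tissue$positions
  cut2 <- (contact_factor * r0)^2
  keep <- vapply(iv, function(i) {
    any((pos[id, 1L] - pos[i, 1L])^2 + (pos[id, 2L] - pos[i, 2L])^2 < cut2)
  }, logical(1L))
  iv[keep]
}

#' Boundary-positioning error E
#'
#' For each boundary cell, the minimal Euclidean distance d_i from its centre
#' to the reference polyline; the error is their sum \eqn{E = \sum_i d_i},
#' sensitive both to displaced and to long, ragged boundaries.
#'
#' @param positions boundary-cell centres (n x 2 matrix; may have 0 rows).
#' @param reference reference polyline (2-column matrix).
#' @param boundary interface name carried through to the result.
#' @return object of class `boundary_error`: list with `per_cell`, `E`,
#'   `boundary`.
#' @export
boundary_error <- function(positions, reference, boundary = "V-I") {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2L)
  if (!nrow(reference)) stop("boundary_error(): empty reference polyline")
  d <- if (nrow(positions)) dist_to_polyline(positions, reference) else numeric(0)
  structure(list(per_cell = d, E = sum(d), boundary = boundary),
            class = "boundary_error")
}

# E for one finished 2D run and one interface
run_boundary_error <- function(run, interface, reference_max, refs) {
  ft <- final_tissue(run)
  idx <- suppressWarnings(
    find_boundary_cells(ft, interface, reference_max, r0 = run$mech$r0))
  curve <- if (interface == "V-I") refs$vi_curve else refs$id_curve
  boundary_error(ft$positions[idx, , drop = FALSE], curve, interface)$E
}

#' Normalised accuracy statistics across conditions
#'
#' Takes the per-run boundary errors of each condition, divides by the largest
#' condition mean, and returns mean and population standard deviation of the
#' normalised error per condition.
#'
#' @param e_by_condition named list of numeric vectors (per-run E values).
#' @return data.frame (condition, mean, sd, mean_raw).
#' @export
accuracy <- function(e_by_condition) {
  if (!length(e_by_condition)) stop("accuracy(): no conditions")
  if (any(vapply(e_by_condition, length, 1L) < 1L))
    stop("accuracy(): empty condition")
  means <- vapply(e_by_condition, mean, numeric(1L))
  mx <- max(means)
  if (mx == 0) stop("accuracy(): all condition means are zero")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  data.frame(condition = names(e_by_condition),
             mean = means / mx,
             sd = vapply(e_by_condition, pop_sd, numeric(1L)) / mx,
             mean_raw = means,
             row.names = NULL)
}

#' Precision of a stochastic ensemble
#'
#' The maximal ensemble standard deviation of expression — the maximal width
#' of the mean +/- sigma bands. Lower is better.
#'
#' @param ens `ensemble_1d`.
#' @param scope `"final"` (default: final saved time) or `"all"` (all saved
#'   times).
#' @return scalar, max over genes and nodes (and times for `"all"`).
#' @export
precision <- function(ens, scope = c("final", "all")) {
  scope <- match.arg(scope)
  if (scope == "final") max(ens$sd[dim(ens$sd)[1L], , ]) else max(ens$sd)
}

#' Qualitative outcome of a perturbation run
#'
#' Presence of each domain (at least `presence_frac` of cells carry the
#' label) and whether the dorsal domain has expanded ventrally (D labels span
#' more than `expanded_frac` of the tissue's D-V extent).
#'
#' @param tissue final `tissue_state`.
#' @param reference_max wild-type classification reference.
#' @param presence_frac presence threshold (fraction of cells).
#' @param expanded_frac D-V-span threshold for "expanded".
#' @return list with `V_present`, `I_present`, `D_present`,
#'   `D_expanded_ventrally` and the label table.
#' @export
classify_perturbation_outcome <- function(tissue, reference_max,
                                          presence_frac = 0.05,
                                          expanded_frac = 0.6) {
  lab <- classify(tissue$states, reference_max)
  n <- length(lab)
  present <- function(g) sum(lab == g) / n >= presence_frac
  H <- diff(range(tissue$outline[, 2L]))
  d_span <- if (any(lab == "D")) diff(range(tissue$positions[lab == "D", 2L])) / H else 0
  list(V_present = present("V"), I_present = present("I"),
       D_present = present("D"),
       D_expanded_ventrally = d_span > expanded_frac,
       labels = table(lab))
}

noise_settings <- function(source = c("bmp", "edn1", "grn", "all"),
                           eta = 1, nu = 0.05) {
  source <- match.arg(source)
  list(eta1 = if (source %in% c("bmp", "all")) eta else 0,
       eta2 = if (source %in% c("edn1", "all")) eta else 0,
       nu = if (source %in% c("grn", "all")) nu else 0)
}

#' Precision-accuracy trade-off across temporal orders
#'
#' For each temporal order and noise source: precision from a 1D stochastic
#' ensemble (maximal sigma), accuracy from repeated stochastic 2D runs
#' (mean boundary error E against the synthetic reference curves, normalised
#' by the largest order mean within the noise source). All stochastic runs are
#' classified against the deterministic wild-type (IVD) reference. A Spearman
#' rank correlation between precision and accuracy across the orders is
#' attached per noise source and boundary.
#'
#' @param orders temporal orders to compare (default all six).
#' @param noise_sources subset of `"bmp"`, `"edn1"`, `"grn"`, `"all"`.
#' @param n_runs_1d 1D ensemble size (full analysis scale: 100).
#' @param n_runs_2d 2D repeat count (full analysis scale: 10).
#' @param base_seed seed root; every run derives a distinct seed from it.
#' @param series outline series (synthetic geometry).
#' @param fractions reference-boundary fractions.
#' @param eta,nu noise strengths for the morphogen and GRN sources.
#' @return list with `records` (data.frame: order, noise_source, boundary,
#'   precision, accuracy, accuracy_sd, E_mean_raw) and `correlations`
#'   (data.frame: noise_source, boundary, spearman).
#' @export
tradeoff_table <- function(orders = temporal_orders(),
                           noise_sources = "all",
                           n_runs_1d = 100L, n_runs_2d = 10L,
                           base_seed = 1L,
                           series = generate_outline_series(),
                           fractions = c(0.11, 0.5),
                           eta = 1, nu = 0.05) {
  dom <- domain_1d()
  refs <- generate_reference_boundaries(series, fractions)
  wt2d <- run_2d(series = series, seed = base_seed)
  ref_max <- tissue_reference_max(wt2d)
  wt1d <- integrate_deterministic(dom)
  records <- NULL
  for (src in noise_sources) {
    ns <- noise_settings(src, eta, nu)
    prec <- setNames(numeric(length(orders)), orders)
    e_vi <- list(); e_id <- list()
    for (io in seq_along(orders)) {
      o <- orders[io]
      g <- grn_params(order = o, nu = ns$nu)
      mo <- morphogen_params(eta1 = ns$eta1, eta2 = ns$eta2)
      ens <- ensemble(dom, grn = g, morph = mo, n_runs = n_runs_1d,
                      base_seed = base_seed + 1000L * io)
      prec[o] <- precision(ens)
      evi <- numeric(n_runs_2d); eid <- numeric(n_runs_2d)
      for (r in seq_len(n_runs_2d)) {
        run <- run_2d(series = series, grn = g, morph = mo,
                      seed = base_seed + 1000L * io + 100L + r,
                      stochastic = TRUE)
        evi[r] <- run_boundary_error(run, "V-I", ref_max, refs)
        eid[r] <- run_boundary_error(run, "I-D", ref_max, refs)
      }
      e_vi[[o]] <- evi; e_id[[o]] <- eid
    }
    for (bnd in c("V-I", "I-D")) {
      acc <- accuracy(if (bnd == "V-I") e_vi else e_id)
      records <- rbind(records, data.frame(
        order = orders, noise_source = src, boundary = bnd,
        precision = unname(prec[orders]),
        accuracy = acc$mean, accuracy_sd = acc$sd, E_mean_raw = acc$mean_raw))
    }
  }
  cors <- do.call(rbind, lapply(split(records,
                                      list(records$noise_source,
                                           records$boundary)), function(d) {
    data.frame(noise_source = d$noise_source[1L], boundary = d$boundary[1L],
               spearman = suppressWarnings(
                 cor(d$precision, d$accuracy, method = "spearman")))
  }))
  rownames(cors) <- NULL
  list(records = records, correlations = cors)
}
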