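# Reproducible scenario runner: named perturbation scenarios, configuration
# serialisation, result bundles with manifests, and canned experiments
# mirroring the package's standard figures.

#' Named perturbation scenarios
#'
#' The canonical genetic/pharmacological perturbations: Bmp or Edn1 source
#' scaled to 1%; Edn1 to 500% or uniform at 50% of the wild-type maximum;
#' dorsal-gene (jag-like) production scaled to 1% or 500%.
#'
#' @return named list of factor settings (`scale1`, `scale2`, `uniform2`,
#'   `jag`).
#' @export
perturbation_scenarios <- function() {
  list(
    bmp_low   = list(scale1 = 0.01),
    jag_low   = list(jag = 0.01),
    jag_high  = list(jag = 5),
    edn1_low  = list(scale2 = 0.01),
    edn1_uniform50 = list(uniform2 = 0.5),
    edn1_high = list(scale2 = 5)
  )
}

#' Scenario configuration
#'
#' @param model `"1d"` or `"2d"`.
#' @param order temporal order.
#' @param timing_mode `"intrinsic"` or `"extrinsic"`.
#' @param eta1,eta2,nu noise strengths (0 = deterministic).
#' @param perturbation `NULL`, a name from [perturbation_scenarios()], or an
#'   explicit list of factor settings.
#' @param runs number of stochastic runs (1 = single run).
#' @param base_seed first seed.
#' @param output_dir directory for CSV export, or `NULL` to keep results in
#'   memory.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(model = c("1d", "2d"), order = "IVD",
                            timing_mode = "intrinsic",
                            eta1 = 0, eta2 = 0, nu = 0,
                            perturbation = NULL, runs = 1L, base_seed = 1L,
                            output_dir = NULL) {
  model <- match.arg(model)
  if (is.character(perturbation)) {
    known <- perturbation_scenarios()
    if (!perturbation %in% names(known))
      stop("scenario_config(): unknown perturbation '", perturbation,
           "'; choices: ", paste(names(known), collapse = ", "))
    perturbation <- known[[perturbation]]
  }
  structure(list(model = model, order = order_permutation(order),
                 timing_mode = timing_mode,
                 eta1 = eta1, eta2 = eta2, nu = nu,
                 perturbation = perturbation, runs = as.integer(runs),
                 base_seed = as.integer(base_seed), output_dir = output_dir),
            class = "scenario_config")
}

config_params <- function(config) {
  grn <- grn_params(order = paste(config$order, collapse = ""),
                    nu = config$nu, timing_mode = config$timing_mode)
  pert <- config$perturbation
  morph <- morphogen_params(
    eta1 = config$eta1, eta2 = config$eta2,
    scale1 = if (!is.null(pert$scale1)) pert$scale1 else 1,
    scale2 = if (!is.null(pert$scale2)) pert$scale2 else 1,
    uniform2 = pert$uniform2)
  if (!is.null(pert$jag)) grn$prod_scale[["D"]] <- pert$jag
  list(grn = grn, morph = morph)
}

#' Flat key-value serialisation of a scenario configuration
#' @param config `scenario_config`.
#' @param path YAML file path.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(config, path) {
  x <- unclass(config)
  x$order <- paste(x$order, collapse = "")
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#' @param path YAML file path.
#' @return `scenario_config`.
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(scenario_config, c(
    x[c("model", "order", "timing_mode", "eta1", "eta2", "nu",
        "runs", "base_seed")],
    list(perturbation = x$perturbation, output_dir = x$output_dir)))
}

#' Run one scenario
#'
#' Executes the configured model (`runs` trajectories, seeds `base_seed ..
#' base_seed + runs - 1`), classifies against the deterministic wild-type
#' reference of the same model, and returns (or writes) trajectories plus a
#' manifest. Identical config and seed give identical results.
#'
#' @param config `scenario_config`.
#' @param series outline series for the 2D model.
#' @return list with `config`, `runs` (trajectories), `reference_max`,
#'   `manifest`; when `output_dir` is set, CSV files are written there.
#' @export
run_scenario <- function(config, series = generate_outline_series()) {
  pp <- config_params(config)
  stoch <- config$eta1 > 0 || config$eta2 > 0 || config$nu > 0
  seeds <- config$base_seed + seq_len(config$runs) - 1L
  if (config$model == "1d") {
    dom <- domain_1d()
    wt <- integrate_deterministic(dom)
    ref <- trajectory_reference_max(wt)
    out <- lapply(seeds, function(s) {
      if (stoch) integrate_stochastic(dom, grn = pp$grn, morph = pp$morph,
                                      seed = s)
      else integrate_deterministic(dom, grn = pp$grn, morph = pp$morph)
    })
  } else {
    wt <- run_2d(series = series, seed = config$base_seed)
    ref <- tissue_reference_max(wt)
    out <- lapply(seeds, function(s)
      run_2d(series = series, grn = pp$grn, morph = pp$morph, seed = s,
             stochastic = stoch))
  }
  manifest <- list(
    model = config$model, order = paste(config$order, collapse = ""),
    noise = c(eta1 = config$eta1, eta2 = config$eta2, nu = config$nu),
    perturbation = config$perturbation, seeds = seeds,
    reference_max = ref,
    package_version = as.character(utils::packageVersion("archpattern")),
    timestamp = format(Sys.time(), tz = "UTC"))
  bundle <- list(config = config, runs = out, reference_max = ref,
                 manifest = manifest)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(out)) {
      df <- if (config$model == "1d")
        trajectory_as_data_frame(out[[i]], ref)
      else tissue_as_data_frame(out[[i]], ref)
      utils::write.csv(df, file.path(config$output_dir,
                                     sprintf("run_%03d.csv", i)),
                       row.names = FALSE)
    }
    yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  }
  bundle
}

#' Run canned figure experiments
#'
#' Available names: `fig3` (deterministic wild type, 1D and 2D), `fig4` (six
#' perturbation outcomes, 2D), `fig5` (sensitivity box summaries per order),
#' `fig6` (1D noise ensembles per source), `fig7` (Bmp-noise ensembles per
#' order), `fig8` (boundary accuracy per order and source), `fig9`
#' (precision-accuracy trade-off), `s3` (order invariance of the final
#' pattern), `s8` (single-morphogen sensitivity), `s9`/`s10`/`s11`
#' (GRN / Edn1 / combined-noise ensembles per order), `s13`/`s14`/`s15`
#' (extrinsic temporal control counterparts).
#'
#' @param names character vector of experiment names (empty = empty index).
#' @param n_runs_1d,n_runs_2d run counts (defaults are reduced working sizes;
#'   the full-scale analyses use 100 and 10).
#' @param base_seed seed root.
#' @param noise_sources noise sources for `fig9`.
#' @return named list of experiment results (empty list for empty input).
#' @export
run_figure_suite <- function(names, n_runs_1d = 20L, n_runs_2d = 5L,
                             base_seed = 1L, noise_sources = "all") {
  choices <- c("fig3", "fig4", "fig5", "fig6", "fig7", "fig8", "fig9",
               "s3", "s8", "s9", "s10", "s11", "s13", "s14", "s15")
  if (!all(names %in% choices))
    stop("run_figure_suite(): unknown experiment(s) ",
         paste(setdiff(names, choices), collapse = ", "),
         "; choices: ", paste(choices, collapse = ", "))
  out <- list()
  dom <- domain_1d()
  for (nm in names) out[[nm]] <- switch(nm,
    fig3 = {
      wt1 <- integrate_deterministic(dom)
      wt2 <- run_2d(seed = base_seed)
      list(traj_1d = wt1, run_2d = wt2,
           labels_1d = classify(final_state(wt1),
                                trajectory_reference_max(wt1)),
           labels_2d = classify(final_tissue(wt2)$states,
                                tissue_reference_max(wt2)))
    },
    fig4 = {
      wt <- run_2d(seed = base_seed)
      ref <- tissue_reference_max(wt)
      lapply(perturbation_scenarios(), function(pert) {
        cfg <- scenario_config("2d", perturbation = pert,
                               base_seed = base_seed)
        b <- run_scenario(cfg)
        classify_perturbation_outcome(final_tissue(b$runs[[1L]]), ref)
      })
    },
    fig5 = {
      ctx <- sensitivity_context("V")
      do.call(rbind, lapply(temporal_orders(), function(o) {
        tr <- run_sensitivity(ctx, grn_params(order = o))
        cbind(order = o, summarize_sensitivity(tr))
      }))
    },
    fig6 = {
      lapply(c(none = "none", grn = "grn", bmp = "bmp", edn1 = "edn1",
               all = "all"),
             function(src) {
               if (src == "none") return(integrate_deterministic(dom))
               ns <- noise_settings(src)
               ensemble(dom, grn = grn_params(nu = ns$nu),
                        morph = morphogen_params(eta1 = ns$eta1,
                                                 eta2 = ns$eta2),
                        n_runs = n_runs_1d, base_seed = base_seed)
             })
    },
    fig7 = ,
    s9 = ,
    s10 = ,
    s11 = {
      src <- c(fig7 = "bmp", s9 = "grn", s10 = "edn1", s11 = "all")[[nm]]
      ns <- noise_settings(src)
      lapply(setNames(nm = temporal_orders()), function(o)
        ensemble(dom, grn = grn_params(order = o, nu = ns$nu),
                 morph = morphogen_params(eta1 = ns$eta1, eta2 = ns$eta2),
                 n_runs = n_runs_1d, base_seed = base_seed))
    },
    fig8 = ,
    fig9 = tradeoff_table(noise_sources = noise_sources,
                          n_runs_1d = n_runs_1d, n_runs_2d = n_runs_2d,
                          base_seed = base_seed),
    s3 = {
      wt <- integrate_deterministic(dom)
      ref <- trajectory_reference_max(wt)
      lapply(setNames(nm = temporal_orders()), function(o)
        classify(final_state(
          integrate_deterministic(dom, grn = grn_params(order = o))), ref))
    },
    s8 = {
      g1 <- grn_params(); g1$single_morphogen <- TRUE
      ctx <- sensitivity_context("V")
      list(two_morphogen = summarize_sensitivity(run_sensitivity(ctx)),
           single_morphogen = summarize_sensitivity(
             run_sensitivity(ctx, g1), normalization = "per_gene"))
    },
    s13 = ,
    s14 = ,
    s15 = {
      src <- c(s13 = "all", s14 = "bmp", s15 = "all")[[nm]]
      ns <- noise_settings(src)
      lapply(setNames(nm = c("intrinsic", "extrinsic")), function(tm)
        ensemble(dom,
                 grn = grn_params(nu = ns$nu, timing_mode = tm),
                 morph = morphogen_params(eta1 = ns$eta1, eta2 = ns$eta2),
                 n_runs = n_runs_1d, base_seed = base_seed))
    })
  out
}
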