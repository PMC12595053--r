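# End-to-end pipeline over the synthetic scenario: simulate -> phases ->
# preprocess -> correlate -> exposure -> sensitivity -> lags, with text
# outputs and a JSON manifest.

#' Pipeline run configuration
#'
#' Validated bundle of the knobs a full run needs. Defaults reproduce the
#' packaged synthetic study conditions: a 348-month (29-year) record, ONI
#' threshold 0.5 degC, per-pixel significance at alpha 0.05 with at least 8
#' phase months, lags -3..+3, deforestation filter rule `"any"` applied to
#' the GPP layers only.
#'
#' @param out_dir output directory, or NULL for an in-memory run.
#' @param seed root seed for all synthetic components.
#' @param grid_shape integer `(rows, cols)` of the analysis grid.
#' @param n_months record length in months.
#' @param oni_threshold phase threshold (degC).
#' @param alpha per-pixel significance level.
#' @param min_n minimum phase months per pixel.
#' @param lags integer lag window.
#' @param phases subset of `c("elnino", "lanina")`.
#' @param deforestation_rule `"any"` or `"fraction"`.
#' @param deforestation_tau loss-fraction threshold for the fraction rule.
#' @param suitable_fraction,loss_fraction,fine_factor mask generator
#'   settings, see [simulate_masks()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir = NULL, seed = 1L, grid_shape = c(20L, 20L),
                       n_months = 348L, oni_threshold = 0.5, alpha = 0.05,
                       min_n = 8L, lags = -3:3,
                       phases = c("elnino", "lanina"),
                       deforestation_rule = "any", deforestation_tau = 0.25,
                       suitable_fraction = 0.9, loss_fraction = 0.03,
                       fine_factor = 4L) {
  phases <- match.arg(phases, c("elnino", "lanina"), several.ok = TRUE)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 4),
            n_months >= 24, oni_threshold > 0,
            alpha > 0, alpha < 1, min_n >= 3,
            all(lags == round(lags)), all(diff(sort(lags)) == 1))
  deforestation_rule <- match.arg(deforestation_rule, c("any", "fraction"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 grid_shape = as.integer(grid_shape),
                 n_months = as.integer(n_months),
                 oni_threshold = oni_threshold, alpha = alpha,
                 min_n = as.integer(min_n), lags = as.integer(sort(lags)),
                 phases = phases,
                 deforestation_rule = deforestation_rule,
                 deforestation_tau = deforestation_tau,
                 suitable_fraction = suitable_fraction,
                 loss_fraction = loss_fraction,
                 fine_factor = as.integer(fine_factor)),
            class = "run_config")
}

# spatial signal patterns: each climate variable teleconnects over a
# different share of the grid so the EWM entropies genuinely differ
scenario_beta <- function(grid_shape, base, coverage) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  b <- matrix(0, nr, nc)
  b[seq_len(max(1L, round(nr * coverage))), ] <- base
  b
}

#' Synthetic study scenario
#'
#' The packaged stand-in for the continental inputs: six climate variables
#' whose teleconnection signs mimic the El Nino drought pattern (warming
#' temperatures and vapour-pressure deficit, drying precipitation, soil
#' moisture and drought index) with variable-specific spatial coverage, and
#' a sun/shade GPP pair whose quadrant block structure constructs all four
#' sensitivity categories, the shade layer leading the index by one month.
#'
#' @param config a [run_config()].
#' @return List of [sim_config()]s: one per climate variable plus
#'   `gpp_sun` and `gpp_shade`.
#' @export
synthetic_scenario <- function(config) {
  stopifnot(inherits(config, "run_config"))
  gs <- config$grid_shape; n <- config$n_months; seed <- config$seed
  base <- function(beta_field, lag_field = 0L)
    sim_config(n_months = n, grid_shape = gs, beta_field = beta_field,
               lag_field = lag_field, seed = seed)
  specs <- list(
    tmax = scenario_beta(gs, +0.8, 1.00),   # warms nearly everywhere
    tmin = scenario_beta(gs, +0.6, 0.90),
    vpd  = scenario_beta(gs, +0.9, 0.35),   # strong but patchy -> top weight
    pr   = scenario_beta(gs, -0.7, 0.75),
    soil = scenario_beta(gs, -0.6, 0.70),
    pdsi = scenario_beta(gs, -0.8, 0.60)
  )
  out <- lapply(specs, base)

  # sun/shade quadrants: (top-left) both decrease, (top-right) both increase,
  # (bottom-left) sun-only decrease, (bottom-right) shade-only decrease
  nr <- gs[1]; nc <- gs[2]
  top <- seq_len(nr %/% 2); left <- seq_len(nc %/% 2)
  bsun <- matrix(0, nr, nc); bshade <- matrix(0, nr, nc)
  bsun[top, left] <- -0.8;  bshade[top, left] <- -0.8
  bsun[top, -left] <- +0.8; bshade[top, -left] <- +0.8
  bsun[-top, left] <- -0.8  # shade stays 0
  bshade[-top, -left] <- -0.8
  out$gpp_sun <- base(bsun)
  out$gpp_shade <- base(bshade, lag_field = -1L)  # shade leads by one month
  out
}

#' Run the full teleconnection pipeline on the synthetic scenario
#'
#' Simulates the scenario from `config$seed`, classifies phases, preprocesses
#' all cubes (anomalies, detrend, 3-month smoothing), computes
#' phase-conditional correlation maps, the EWM exposure index per phase, the
#' sun/shade sensitivity typology with area percentages, and the lag
#' profiles/transition maps. With `config$out_dir` set, writes all tables,
#' grids and a deterministic JSON manifest.
#'
#' @param config a [run_config()].
#' @return A list of class `pipeline_result` with elements `index`,
#'   `labels`, `episodes`, `masks`, `climate` (per-phase maps and EWM),
#'   `gpp` (per-phase sensitivity), `lags` (per-phase, per-layer profiles
#'   and transitions), `config`, and `files` when written.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  scen <- synthetic_scenario(config)
  climate_vars <- setdiff(names(scen), c("gpp_sun", "gpp_shade"))

  idx_raw <- simulate_index(scen[[1]])
  idx <- running_mean3(idx_raw)
  labels <- classify_phases(idx, threshold = config$oni_threshold)
  episodes <- extract_episodes(labels)

  masks <- simulate_masks(config$grid_shape,
                          suitable_fraction = config$suitable_fraction,
                          loss_fraction = config$loss_fraction,
                          fine_factor = config$fine_factor,
                          seed = config$seed)
  retained <- deforestation_filter(masks$loss, config$grid_shape,
                                   rule = config$deforestation_rule,
                                   tau = config$deforestation_tau)
  climate_mask <- masks$suitability                     # filter is GPP-only
  gpp_mask <- combine_masks(masks$suitability, retained)

  sims <- lapply(names(scen), function(v) simulate_cube(scen[[v]], idx_raw, v))
  names(sims) <- names(scen)
  cubes <- lapply(sims, function(s) preprocess_cube(s$cube))

  climate <- list()
  for (ph in config$phases) {
    maps <- lapply(climate_vars, function(v)
      correlation_map(cubes[[v]], idx, labels, ph, lag = 0L,
                      mask = climate_mask, alpha = config$alpha,
                      min_n = config$min_n))
    names(maps) <- climate_vars
    climate[[ph]] <- list(maps = maps,
                          ewm = ewm_pipeline(maps, climate_mask))
  }

  gpp <- list()
  lags_out <- list()
  for (ph in config$phases) {
    sun0 <- correlation_map(cubes$gpp_sun, idx, labels, ph, lag = 0L,
                            mask = gpp_mask, alpha = config$alpha,
                            min_n = config$min_n)
    shade0 <- correlation_map(cubes$gpp_shade, idx, labels, ph, lag = 0L,
                              mask = gpp_mask, alpha = config$alpha,
                              min_n = config$min_n)
    smap <- sensitivity_typology(productivity_direction(sun0, ph),
                                 productivity_direction(shade0, ph),
                                 phase = ph)
    gpp[[ph]] <- list(sun = sun0, shade = shade0, typology = smap,
                      areas = area_percentages(smap, gpp_mask))

    lags_out[[ph]] <- lapply(c(sun = "gpp_sun", shade = "gpp_shade"),
      function(v) {
        maps <- lag_correlation_maps(cubes[[v]], idx, labels, ph,
                                     mask = gpp_mask, lags = config$lags,
                                     alpha = config$alpha,
                                     min_n = config$min_n)
        prof <- lag_profiles(maps, mask = gpp_mask)
        pair <- detect_transition(prof)
        tmap <- transition_map(maps[[sprintf("lag%+d", pair[1])]],
                               maps[[sprintf("lag%+d", pair[2])]],
                               alpha = config$alpha, mask = gpp_mask)
        list(maps = maps, profile = prof, pair = pair, transition = tmap)
      })
  }

  res <- structure(list(index = idx, labels = labels, episodes = episodes,
                        masks = list(suitability = masks$suitability,
                                     retained = retained,
                                     climate = climate_mask, gpp = gpp_mask),
                        truths = lapply(sims, `[[`, "truth"),
                        climate = climate, gpp = gpp, lags = lags_out,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) res$files <- write_pipeline(res, config$out_dir)
  res
}

# serialize a pipeline_result into out_dir; returns the file list
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, paste0(...))
  files <- character(0)
  add <- function(f) files <<- c(files, f)
  add_cmap <- function(cmap, prefix) {
    write_correlation_map(cmap, prefix)
    add(paste0(prefix, c("_r.csv", "_p.csv", "_n.csv", "_summary.csv")))
  }

  add(write_index_csv(res$index, fp("index_smoothed.csv")))
  add(write_labels_csv(res$labels, fp("phase_labels.csv")))
  data.table::fwrite(res$episodes, fp("episodes.csv")); add(fp("episodes.csv"))
  add(write_grid(res$masks$suitability, fp("mask_suitability.csv")))
  add(write_grid(res$masks$gpp, fp("mask_gpp.csv")))

  wtab <- do.call(rbind, lapply(names(res$climate), function(ph) {
    e <- res$climate[[ph]]$ewm
    if (e$status != "ok") return(NULL)
    data.frame(phase = ph, variable = names(e$w),
               entropy = unname(e$E), weight = unname(e$w))
  }))
  if (!is.null(wtab)) { data.table::fwrite(wtab, fp("ewm_weights.csv")); add(fp("ewm_weights.csv")) }

  for (ph in names(res$climate)) {
    for (v in names(res$climate[[ph]]$maps))
      add_cmap(res$climate[[ph]]$maps[[v]], fp("cmap_", v, "_", ph))
    add(write_grid(res$climate[[ph]]$ewm$exposure, fp("exposure_", ph, ".csv")))
  }
  for (ph in names(res$gpp)) {
    g <- res$gpp[[ph]]
    add_cmap(g$sun, fp("cmap_gpp_sun_", ph))
    add_cmap(g$shade, fp("cmap_gpp_shade_", ph))
    code <- matrix(match(g$typology$category, g$typology$levels),
                   nrow(g$typology$category))
    add(write_grid(code, fp("sensitivity_", ph, ".csv")))
    data.table::fwrite(g$areas, fp("sensitivity_areas_", ph, ".csv"))
    add(fp("sensitivity_areas_", ph, ".csv"))
  }
  for (ph in names(res$lags)) {
    for (ly in names(res$lags[[ph]])) {
      l <- res$lags[[ph]][[ly]]
      data.table::fwrite(l$profile$summary, fp("lag_profile_", ly, "_", ph, ".csv"))
      add(fp("lag_profile_", ly, "_", ph, ".csv"))
      code <- matrix(match(l$transition$class, c("increase", "decrease", "none")),
                     nrow(l$transition$class))
      add(write_grid(code, fp("transition_", ly, "_", ph, ".csv")))
    }
  }
  cfg <- unclass(res$config)
  cfg$out_dir <- NULL
  write_manifest(cfg, files, file.path(out_dir, "manifest.json"))
  c(files, file.path(out_dir, "manifest.json"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %dx%d grid, %d months, phases: %s\n",
              x$config$grid_shape[1], x$config$grid_shape[2],
              x$config$n_months, paste(x$config$phases, collapse = ", ")))
  print(x$labels)
  for (ph in names(x$climate))
    cat(sprintf("  %s: EWM %s over %d pixels\n", ph,
                x$climate[[ph]]$ewm$status, x$climate[[ph]]$ewm$n_pixels))
  invisible(x)
}
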