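#' Assemble the forward/inverse pipeline configuration
#'
#' Bundles the shared state of the two use modes: the head mesh, the DMN
#' template and element mapping, the surrogate parameters, the scenario
#' library (built on demand) and a per-threshold ensemble cache (one model
#' per damage threshold).
#'
#' @param mesh a `head_mesh` (default: resolution-3 toy head).
#' @param template a `network_template`.
#' @param params a `surrogate_params`.
#' @param grid scenario grid for library construction.
#' @param library optional pre-built scenario library.
#' @param seed base seed.
#' @return object of class `impact_config` (an environment).
#' @export
impact_config <- function(mesh = build_toy_head_mesh(3, seed = 0L),
                          template = default_dmn_template(),
                          params = surrogate_params(),
                          grid = scenario_grid(),
                          library = NULL, seed = 0L) {
  cfg <- new.env(parent = emptyenv())
  cfg$mesh <- mesh
  cfg$template <- template
  cfg$params <- params
  cfg$grid <- grid
  cfg$seed <- as.integer(seed)
  cfg$library <- library
  cfg$dmn_ids <- if (!is.null(library)) attr(library, "dmn_ids")
  cfg$ensembles <- list()
  class(cfg) <- "impact_config"
  cfg
}

config_library <- function(cfg) {
  if (is.null(cfg$library)) {
    cfg$library <- build_scenario_library(cfg$grid, cfg$mesh, cfg$params,
                                          template = cfg$template)
    cfg$dmn_ids <- attr(cfg$library, "dmn_ids")
  }
  if (is.null(cfg$dmn_ids)) {
    mask <- binarize_dmn_template(cfg$template)
    cfg$dmn_ids <- map_dmn_elements(cfg$mesh, mask)
  }
  cfg$library
}

config_ensemble <- function(cfg, damage_threshold) {
  key <- format(damage_threshold)
  if (!is.null(cfg$ensembles[[key]])) return(cfg$ensembles[[key]])
  lib <- config_library(cfg)
  lib <- dplyr::filter(lib, !.data$fractured)
  labels <- label_library(lib, damage_threshold)
  if (length(unique(labels)) < 2L) {
    abort(sprintf(
      "library has a single class at threshold %g%%: cannot train.",
      damage_threshold))
  }
  feats <- extract_features(lib, cfg$mesh, cfg$dmn_ids)
  sel <- forward_feature_selection(feats, labels, seed = cfg$seed)
  ens <- train_bagging_ensemble(feats, labels, sel,
                                damage_threshold = damage_threshold,
                                seed = cfg$seed)
  cfg$ensembles[[key]] <- ens
  ens
}

#' Forward prediction: scenario to damage probability
#'
#' Trains (or reuses) the ensemble at the requested damage threshold and
#' reports the probability that at least that proportion of the DMN is
#' damaged in the given impact scenario.
#'
#' @param cfg an `impact_config`.
#' @param scenario one-row scenario tibble.
#' @param damage_threshold DMN damage threshold (%).
#' @return list: `scenario`, `features`, `probability`, `threshold`.
#' @export
run_forward <- function(cfg, scenario, damage_threshold = 50) {
  stopifnot(inherits(cfg, "impact_config"))
  if (scenario$velocity <= 0 || scenario$velocity > 16) {
    abort("scenario velocity must be in (0, 16] m/s.")
  }
  ens <- config_ensemble(cfg, damage_threshold)
  config_library(cfg)
  feats <- extract_features(scenario, cfg$mesh, cfg$dmn_ids)
  list(scenario = as.list(scenario),
       features = as.list(feats),
       probability = unname(predict(ens, feats)),
       threshold = damage_threshold)
}

#' Inverse prediction: observed damage to impact velocity
#'
#' Trains (or reuses) an ensemble at a damage threshold equal to the
#' observed functional damage percentage, sweeps the impact velocity with
#' the rest of the scenario fixed, and reports the plateau probability
#' `P_f` and the velocity at which 95% of the plateau is first reached —
#' the estimated velocity at which exactly the observed damage proportion
#' is produced.
#'
#' @param cfg an `impact_config`.
#' @param scenario one-row scenario tibble (its velocity is ignored).
#' @param observed_damage_percent observed DMN damage load, in (0, 100].
#' @param v_min,v_max,step sweep grid (m/s).
#' @param smooth isotonic smoothing before plateau detection.
#' @return list: `P_f`, `v_at_95`, `reached`, `threshold`, `curve`
#'   (a `velocity_curve`).
#' @export
run_inverse <- function(cfg, scenario, observed_damage_percent,
                        v_min = 1, v_max = 15, step = 0.1, smooth = TRUE) {
  stopifnot(inherits(cfg, "impact_config"))
  if (observed_damage_percent <= 0 || observed_damage_percent > 100) {
    abort("`observed_damage_percent` must be in (0, 100].")
  }
  ens <- config_ensemble(cfg, observed_damage_percent)
  curve <- probability_velocity_curve(ens, scenario, cfg$mesh, cfg$dmn_ids,
                                      v_min = v_min, v_max = v_max,
                                      step = step)
  pl <- plateau_and_velocity(curve, smooth = smooth)
  c(pl, list(threshold = observed_damage_percent, curve = curve))
}

#' Serialize / restore a trained ensemble
#'
#' Writes the ensemble to a directory holding a JSON manifest (threshold,
#' selected features, training size, seed) next to the fitted members.
#'
#' @param ensemble a `dmn_ensemble`.
#' @param dir output directory (created if needed).
#' @param path directory written by `write_ensemble`.
#' @return the directory (write) or a `dmn_ensemble` (read).
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "dmn_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(
    class = "dmn_ensemble",
    damage_threshold = ensemble$damage_threshold,
    selected_features = ensemble$selected,
    members = names(ensemble$members),
    n_train = ensemble$n_train,
    dataset_balance = ensemble$balance,
    seed = ensemble$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(ensemble, file.path(dir, "ensemble.rds"))
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  ens <- readRDS(file.path(path, "ensemble.rds"))
  stopifnot(inherits(ens, "dmn_ensemble"))
  ens
}
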