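#' Parameters of the parametric impact-response surrogate
#'
#' The surrogate replaces an explicit-dynamics finite-element library with a
#' closed-form model of the per-element peak fields. For a gray-matter
#' element at distance `d` from the impact point, the peak shear energy
#' rate is
#' `e = A (v/v_ref)^alpha exp(-d/lambda) (1 + beta cos(theta))
#' (R_ref/R)^gamma_R (1 + eta)`, and for a skull element the peak von Mises
#' stress is `B v (R_ref/R)^gamma_R exp(-d/lambda) (1 + eta)`, with
#' `eta ~ N(0, noise_cv)` truncated below at -0.9 so fields stay positive.
#'
#' @param A amplitude (MJ/m^3/s).
#' @param v_ref reference velocity (m/s).
#' @param alpha velocity exponent.
#' @param lambda decay length (m).
#' @param beta angle gain (response is largest for perpendicular impacts).
#' @param gamma_R impactor sharpness exponent.
#' @param R_ref reference radius of curvature (m).
#' @param B skull gain (MPa s/m).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed base seed; each scenario derives its own stream from it.
#' @return object of class `surrogate_params`.
#' @export
surrogate_params <- function(A = 1.5, v_ref = 8, alpha = 2.5, lambda = 0.055,
                             beta = 0.5, gamma_R = 0.25, R_ref = 0.036,
                             B = 8.5, noise_cv = 0.05, seed = 0L) {
  for (nm in c("A", "v_ref", "lambda", "R_ref")) {
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  }
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  structure(
    list(A = A, v_ref = v_ref, alpha = alpha, lambda = lambda, beta = beta,
         gamma_R = gamma_R, R_ref = R_ref, B = B, noise_cv = noise_cv,
         seed = as.integer(seed)),
    class = "surrogate_params"
  )
}

#' Define an impact scenario
#'
#' @param velocity impact velocity (m/s), in (0, 16].
#' @param location one of the five labels of [impact_locations()].
#' @param angle impact angle from perpendicular (degrees, within \[-45, 45\]).
#' @param impactor one of the labels of [impactor_shapes()].
#' @return one-row tibble with columns `velocity`, `location`, `angle`,
#'   `impactor`, `radius` (m).
#' @export
impact_scenario <- function(velocity, location, angle = 0,
                            impactor = "round") {
  if (!is.numeric(velocity) || velocity <= 0 || velocity > 16) {
    abort("`velocity` must be in (0, 16] m/s.")
  }
  if (abs(angle) > 45) abort("`angle` must be within [-45, 45] degrees.")
  shapes <- impactor_shapes()
  if (!impactor %in% shapes$impactor) {
    abort(sprintf("unknown impactor '%s'.", impactor))
  }
  if (!location %in% impact_locations()$location) {
    abort(sprintf("unknown impact location '%s'.", location))
  }
  tibble::tibble(
    velocity = velocity, location = location, angle = angle,
    impactor = impactor,
    radius = shapes$radius_m[match(impactor, shapes$impactor)]
  )
}

#' Full-factorial grid of impact scenarios
#'
#' Defaults give 5 locations x 4 impactors x 7 velocities x 3 angles = 420
#' scenarios, the same order of size as a realistic pre-computed impact
#' library; density is configurable.
#'
#' @param velocities velocity levels (m/s).
#' @param locations impact-location labels.
#' @param angles impact angles (degrees).
#' @param impactors impactor labels.
#' @return tibble of scenarios (one row each).
#' @export
scenario_grid <- function(velocities = seq(2, 14, by = 2),
                          locations = impact_locations()$location,
                          angles = c(-45, 0, 45),
                          impactors = impactor_shapes()$impactor) {
  if (!length(velocities) || !length(locations) || !length(angles) ||
      !length(impactors)) {
    abort("every grid dimension must be non-empty.")
  }
  grid <- tidyr::expand_grid(location = locations, impactor = impactors,
                             velocity = velocities, angle = angles)
  purrr::pmap_dfr(grid, function(location, impactor, velocity, angle) {
    impact_scenario(velocity, location, angle, impactor)
  })
}

# deterministic per-scenario RNG stream derived from the base seed
scenario_seed <- function(params, scenario) {
  loc_i <- match(scenario$location, impact_locations()$location)
  imp_i <- match(scenario$impactor, impactor_shapes()$impactor)
  key <- (as.double(params$seed) * 7919 +
          round(scenario$velocity * 1000) * 104729 +
          loc_i * 15485863 + imp_i * 32452843 +
          round(scenario$angle * 100) * 49979687)
  as.integer(key %% 2147483647)
}

#' Surrogate per-element peak fields for one scenario
#'
#' Evaluates the parametric surrogate on a toy head mesh: peak shear energy
#' rate (MJ/m^3/s) for every gray-matter element and peak von Mises stress
#' (MPa) for every skull element. Deterministic given
#' `(params$seed, scenario)`; with `noise_cv = 0` the gray field is strictly
#' increasing in velocity and strictly decreasing in distance from the
#' impact point.
#'
#' @param scenario one-row tibble from [impact_scenario()].
#' @param mesh a `head_mesh`.
#' @param params a `surrogate_params`.
#' @return object of class `peak_fields`: list with `gray_ids`, `gray_ser`,
#'   `skull_ids`, `skull_vm`, and the scenario row.
#' @export
surrogate_peak_fields <- function(scenario, mesh, params = surrogate_params()) {
  stopifnot(inherits(mesh, "head_mesh"), inherits(params, "surrogate_params"))
  if (nrow(scenario) != 1L) abort("`scenario` must be a single scenario row.")
  v <- scenario$velocity
  if (v <= 0 || v > 16) abort("velocity must be in (0, 16] m/s.")

  geom <- impact_geometry(scenario$location, mesh$radius)
  gray_ids <- which(mesh$region == "gray")
  skull_ids <- which(mesh$region == "skull")
  d_gray <- sqrt(rowSums((mesh$centroids[gray_ids, , drop = FALSE] -
                          matrix(geom$point, length(gray_ids), 3,
                                 byrow = TRUE))^2))
  d_skull <- sqrt(rowSums((mesh$centroids[skull_ids, , drop = FALSE] -
                           matrix(geom$point, length(skull_ids), 3,
                                  byrow = TRUE))^2))
  sharp <- (params$R_ref / scenario$radius)^params$gamma_R
  ang <- 1 + params$beta * cos(scenario$angle * pi / 180)

  ser <- params$A * (v / params$v_ref)^params$alpha * exp(-d_gray / params$lambda) *
    ang * sharp
  vm <- params$B * v * sharp * exp(-d_skull / params$lambda)

  if (params$noise_cv > 0) {
    eta <- local_seed(scenario_seed(params, scenario), {
      pmax(rnorm(length(ser) + length(vm), 0, params$noise_cv), -0.9)
    })
    ser <- ser * (1 + eta[seq_along(ser)])
    vm <- vm * (1 + eta[length(ser) + seq_along(vm)])
  }

  structure(
    list(gray_ids = gray_ids, gray_ser = ser,
         skull_ids = skull_ids, skull_vm = vm,
         scenario = scenario),
    class = "peak_fields"
  )
}

#' Build a surrogate scenario library
#'
#' Runs the surrogate over a full scenario grid and applies the damage
#' rules: skull-fracture flag from the von Mises field and DMN damage
#' percentage from the shear-energy-rate field over the mapped DMN element
#' set. One record per grid combination.
#'
#' @param grid scenario tibble from [scenario_grid()].
#' @param mesh a `head_mesh`.
#' @param params a `surrogate_params`.
#' @param dmn_ids DMN element ids (from [map_dmn_elements()]); computed
#'   from `template` when missing.
#' @param template `network_template` used when `dmn_ids` is missing.
#' @param ser_threshold element damage criterion (MJ/m^3/s).
#' @param bone_strength ultimate strength of bone (MPa).
#' @param fracture_fraction fraction of skull elements above strength that
#'   declares a fracture.
#' @param z_threshold template binarization threshold.
#' @return tibble: scenario columns plus `fractured` and `damage_percent`,
#'   with the DMN element ids as attribute `"dmn_ids"`.
#' @export
build_scenario_library <- function(grid, mesh, params = surrogate_params(),
                                   dmn_ids = NULL,
                                   template = default_dmn_template(),
                                   ser_threshold = 1.0,
                                   bone_strength = 92.72,
                                   fracture_fraction = 0.04,
                                   z_threshold = 3.1) {
  if (nrow(grid) == 0L) abort("scenario grid is empty.")
  if (is.null(dmn_ids)) {
    mask <- binarize_dmn_template(template, z_threshold)
    dmn_ids <- map_dmn_elements(mesh, mask)
  }
  recs <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sc <- grid[i, ]
    pf <- surrogate_peak_fields(sc, mesh, params)
    fractured <- skull_fractured(pf$skull_vm, strength = bone_strength,
                                 fraction = fracture_fraction)
    dmg <- dmn_damage_percent(pf, dmn_ids, threshold = ser_threshold)
    dplyr::mutate(sc, fractured = fractured,
                  damage_percent = dmg$damage_percent)
  })
  attr(recs, "dmn_ids") <- dmn_ids
  recs
}

#' Read / write a scenario library as CSV
#'
#' @param library scenario-library tibble.
#' @param path CSV path.
#' @return the path (write) or the library tibble (read).
#' @export
write_library_csv <- function(library, path) {
  readr::write_csv(library, path)
  invisible(path)
}

#' @rdname write_library_csv
#' @export
read_library_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    location = readr::col_character(),
                    impactor = readr::col_character(),
                    fractured = readr::col_logical()
                  ))
}
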