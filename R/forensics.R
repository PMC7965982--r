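#' Compose a fall height from signed components
#'
#' Forensic fall heights are built from additive components (building height
#' to the gutter, gutter height, standing height, minus the offset from the
#' crown to the likely contact point). The algebraic sum is rounded to one
#' decimal, the resolution at which such reconstructions are quoted.
#'
#' @param components numeric vector of signed lengths (m).
#' @return composed height (m), rounded to 1 decimal.
#' @export
#' @examples
#' compose_fall_height(c(8.3, 0.1, 1.76, -0.1)) # 10.1
compose_fall_height <- function(components) {
  if (length(components) == 0L || !is.numeric(components) ||
      any(!is.finite(components))) {
    abort("`components` must be a non-empty finite numeric vector.")
  }
  h <- round(sum(components), 1)
  if (h <= 0) abort("composed fall height must be > 0.")
  h
}

round_profile <- function(x, profile) {
  switch(profile,
    integer = round(x),
    `1dp` = round(x, 1),
    `2dp` = round(x, 2),
    none = x,
    abort("unknown rounding profile; use 'integer', '1dp', '2dp' or 'none'.")
  )
}

#' Free-fall impact velocity
#'
#' `v = sqrt(2 g h)` for a simple fall with no initial velocity and no arc
#' of rotation.
#'
#' @param h fall height (m), > 0.
#' @param g gravitational acceleration (m/s^2).
#' @param rounding rounding profile: "integer", "1dp", "2dp" or "none".
#' @return impact velocity (m/s).
#' @export
#' @examples
#' freefall_velocity(7.3, rounding = "integer") # 12
#' freefall_velocity(10.1, rounding = "1dp")    # 14.1
freefall_velocity <- function(h, g = 9.81, rounding = "none") {
  stopifnot_scalar_number(h, "h", positive = TRUE)
  round_profile(sqrt(2 * g * h), rounding)
}

#' Impact force from head mass and acceleration in g
#'
#' `F = m * a_g * g`, reported in kN to two decimals (the convention of
#' fracture-tolerance tables).
#'
#' @param mass head mass (kg), > 0.
#' @param accel_g acceleration in multiples of g.
#' @param g gravitational acceleration (m/s^2).
#' @return force (kN), 2-decimal rounding.
#' @export
#' @examples
#' impact_force(6.82, 80) # 5.35
impact_force <- function(mass, accel_g, g = 9.81) {
  stopifnot_scalar_number(mass, "mass", positive = TRUE)
  stopifnot_scalar_number(accel_g, "accel_g")
  round(mass * accel_g * g / 1000, 2)
}

MPH_TO_MS <- 0.44704  # exact by definition of the international mile

#' Convert miles per hour to metres per second (and back)
#'
#' @param v_mph velocity in mph.
#' @param v_ms velocity in m/s.
#' @param rounding rounding profile: "integer", "1dp", "2dp" or "none".
#' @return converted velocity.
#' @export
#' @examples
#' mph_to_ms(30, rounding = "1dp") # 13.4
#' mph_to_ms(40, rounding = "2dp") # 17.88
mph_to_ms <- function(v_mph, rounding = "none") {
  if (!is.numeric(v_mph) || any(!is.finite(v_mph))) abort("`v_mph` must be finite.")
  round_profile(v_mph * MPH_TO_MS, rounding)
}

#' @rdname mph_to_ms
#' @export
ms_to_mph <- function(v_ms, rounding = "none") {
  if (!is.numeric(v_ms) || any(!is.finite(v_ms))) abort("`v_ms` must be finite.")
  round_profile(v_ms / MPH_TO_MS, rounding)
}

#' Reconstruct a forensic head-impact case from a case file
#'
#' Case files are small YAML documents describing an accident narrative in
#' computable terms: fall-height components and/or literature velocity
#' ranges, optional head mass / acceleration for force estimates. Nine
#' worked cases are bundled under `inst/extdata/cases/`.
#'
#' @param case path to a YAML case file, or a bare case id like `"case1"`
#'   resolving to the bundled set.
#' @return a tibble with one row per derived quantity (`quantity`, `value`,
#'   `unit`, `note`).
#' @export
reconstruct_case <- function(case) {
  path <- case
  if (!file.exists(path)) {
    path <- system.file("extdata", "cases", paste0(case, ".yaml"),
                        package = "dmnimpact")
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("case file not found: %s", case))
  }
  spec <- yaml::read_yaml(path)
  rows <- list()
  add <- function(quantity, value, unit, note = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      quantity = quantity, value = value, unit = unit, note = note)
  }
  if (!is.null(spec$height_components_m)) {
    add("composed_fall_height", compose_fall_height(unlist(spec$height_components_m)),
        "m", "algebraic sum of components, 1-decimal rounding")
  }
  h <- spec$stated_fall_height_m %||%
    (if (!is.null(spec$height_components_m))
       compose_fall_height(unlist(spec$height_components_m)))
  if (!is.null(h)) {
    prof <- spec$velocity_rounding %||% "1dp"
    add("freefall_velocity", freefall_velocity(h, rounding = prof), "m/s",
        sprintf("sqrt(2 g h), h = %g m", h))
  }
  if (!is.null(spec$head_mass_kg) && !is.null(spec$accel_g)) {
    add("impact_force", impact_force(spec$head_mass_kg, spec$accel_g), "kN",
        sprintf("m = %g kg at %g g", spec$head_mass_kg, spec$accel_g))
  }
  if (!is.null(spec$velocity_range_ms)) {
    vr <- unlist(spec$velocity_range_ms)
    add("velocity_range_low", vr[1], "m/s", "literature/estimated range")
    add("velocity_range_high", vr[2], "m/s", "literature/estimated range")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "case_id") <- spec$id %||% basename(path)
  attr(out, "narrative") <- spec$narrative %||% ""
  out
}
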