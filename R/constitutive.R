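#' Brain tissue material parameters
#'
#' Construct the parameter set of the hyperelastic brain-tissue model: a
#' Gent (limiting chain extensibility) isochoric matrix, an optional
#' exponential fiber-reinforcement term along the axonal direction (white
#' matter only), and an Ogden-type volumetric response driven by the density
#' ratio. All stress-like inputs are in Pa.
#'
#' @param mu_m matrix shear modulus (Pa).
#' @param j_m Gent limiting parameter (dimensionless); the isochoric
#'   response diverges as `I1* - 3` approaches `j_m`.
#' @param K_o bulk modulus (Pa).
#' @param Lambda_o volumetric exponent (dimensionless).
#' @param rho_o reference density (kg/m^3).
#' @param k1 fiber stiffness (Pa), or `NULL` for an isotropic tissue
#'   (gray matter). Anisotropy is present iff `k1` is given.
#' @param k2 fiber exponent coefficient (dimensionless in the exponential);
#'   ignored when `k1` is `NULL`.
#' @return an object of class `brain_material`.
#' @seealso [white_matter_params()], [gray_matter_params()]
#' @export
brain_material_params <- function(mu_m, j_m, K_o, Lambda_o, rho_o,
                                  k1 = NULL, k2 = 0) {
  stopifnot_scalar_number(mu_m, "mu_m", positive = TRUE)
  stopifnot_scalar_number(j_m, "j_m", positive = TRUE)
  stopifnot_scalar_number(K_o, "K_o", positive = TRUE)
  stopifnot_scalar_number(Lambda_o, "Lambda_o")
  stopifnot_scalar_number(rho_o, "rho_o", positive = TRUE)
  if (!is.null(k1)) {
    stopifnot_scalar_number(k1, "k1")
    stopifnot_scalar_number(k2, "k2")
  }
  structure(
    list(mu_m = mu_m, j_m = j_m, K_o = K_o, Lambda_o = Lambda_o,
         rho_o = rho_o, k1 = k1, k2 = if (is.null(k1)) NULL else k2),
    class = "brain_material"
  )
}

#' @export
print.brain_material <- function(x, ...) {
  kind <- if (is.null(x$k1)) "isotropic" else "fiber-reinforced"
  cat(sprintf("<brain_material> %s\n", kind))
  cat(sprintf("  mu_m = %g Pa, j_m = %g, K_o = %g Pa, Lambda_o = %g, rho_o = %g kg/m^3\n",
              x$mu_m, x$j_m, x$K_o, x$Lambda_o, x$rho_o))
  if (!is.null(x$k1)) cat(sprintf("  k1 = %g Pa, k2 = %g\n", x$k1, x$k2))
  invisible(x)
}

load_material_config <- function() {
  path <- system.file("extdata", "materials.yaml", package = "dmnimpact")
  yaml::read_yaml(path)
}

material_from_config <- function(entry) {
  brain_material_params(
    mu_m = entry$mu_m_kPa * 1e3,
    j_m = entry$j_m,
    K_o = entry$K_o_GPa * 1e9,
    Lambda_o = entry$Lambda_o,
    rho_o = entry$rho_o,
    k1 = if (!is.null(entry$k1_kPa)) entry$k1_kPa * 1e3,
    k2 = entry$k2 %||% 0
  )
}

#' Calibrated white-matter parameters
#'
#' White matter carries the fiber-reinforcement term (axonal anisotropy);
#' values are read from the versioned material table shipped with the
#' package (`inst/extdata/materials.yaml`).
#'
#' @return a `brain_material` object.
#' @export
white_matter_params <- function() {
  material_from_config(load_material_config()$white_matter)
}

#' Calibrated gray-matter parameters
#'
#' Gray matter is isotropic (no fiber term).
#'
#' @return a `brain_material` object.
#' @export
gray_matter_params <- function() {
  material_from_config(load_material_config()$gray_matter)
}

dev3 <- function(m) m - diag(mean(diag(m)), 3)

#' Multiplicative volumetric/isochoric split of a deformation gradient
#'
#' Splits `F = J^(1/3) F*` into the Jacobian `J = det(F)` and the
#' distortional (unimodular) part `F*`, and evaluates the isochoric
#' invariants used by the constitutive model: `I1* = tr(F*^T F*)` and,
#' when a fiber direction is supplied, `I4* = tr(A_o F*^T F*)` with
#' `A_o = a (x) a` the structural tensor of the axonal direction.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param fiber optional unit 3-vector of the reference axonal direction.
#' @return an object of class `deformation_state` with elements
#'   `F`, `J`, `Fstar`, `Bstar` (`= F* F*^T`), `I1s`, and (if `fiber`
#'   given) `I4s` and `A_o`.
#' @export
decompose_deformation <- function(F, fiber = NULL) {
  F <- as.matrix(F)
  if (!identical(dim(F), c(3L, 3L)) || any(!is.finite(F))) {
    abort("`F` must be a finite 3x3 matrix.")
  }
  J <- det(F)
  if (J <= 0) {
    abort("det(F) must be > 0: deformation is non-physical.",
          class = "dmnimpact_invalid_deformation")
  }
  Fstar <- J^(-1 / 3) * F
  Cstar <- crossprod(Fstar)           # F*^T F*
  state <- list(
    F = F, J = J, Fstar = Fstar,
    Bstar = tcrossprod(Fstar),        # F* F*^T
    I1s = sum(diag(Cstar))
  )
  if (!is.null(fiber)) {
    fiber <- as.numeric(fiber)
    if (length(fiber) != 3L || abs(sqrt(sum(fiber^2)) - 1) > 1e-6) {
      abort("`fiber` must be a unit 3-vector.")
    }
    A_o <- tcrossprod(fiber)
    state$A_o <- A_o
    state$I4s <- sum(diag(A_o %*% Cstar))
  }
  structure(state, class = "deformation_state")
}

#' Cauchy stress of the brain-tissue constitutive model
#'
#' Total Cauchy stress as the sum of a volumetric and an isochoric part.
#' The isochoric part is a Gent matrix term
#' `(mu_m / J) * 1/(1 - (I1* - 3)/j_m) * dev(B*)` plus, for
#' fiber-reinforced tissue, `(2 k1 / J) (I4* - 1) exp(k2 (I4* - 1)^2)
#' dev(F* A_o F*^T)`. The volumetric part is
#' `-(K_o / (Lambda_o + 1)) ((rho/rho_o)^(Lambda_o + 1) - 1) I`, with the
#' density ratio obtained from mass conservation, `rho/rho_o = 1/J`.
#'
#' @param state a `deformation_state`, or a raw 3x3 deformation gradient.
#' @param params a `brain_material` object.
#' @param fiber unit 3-vector axonal direction; required iff `params`
#'   carries a fiber term and `state` does not already hold one.
#' @return an object of class `cauchy_stress`: list with `sigma`,
#'   `sigma_vol`, `sigma_iso` (Pa, 3x3 symmetric matrices).
#' @export
cauchy_stress <- function(state, params, fiber = NULL) {
  if (!inherits(state, "deformation_state")) {
    state <- decompose_deformation(state, fiber = fiber)
  } else if (!is.null(fiber) && is.null(state$A_o)) {
    state <- decompose_deformation(state$F, fiber = fiber)
  }
  if (!inherits(params, "brain_material")) {
    abort("`params` must be a `brain_material` object.")
  }
  anis <- !is.null(params$k1)
  if (anis && is.null(state$A_o)) {
    abort("fiber-reinforced material needs a fiber direction.",
          class = "dmnimpact_fiber_mismatch")
  }
  if (!anis && !is.null(state$A_o)) {
    abort("isotropic material given a fiber direction.",
          class = "dmnimpact_fiber_mismatch")
  }
  gent_arg <- (state$I1s - 3) / params$j_m
  if (gent_arg >= 1) {
    abort(sprintf(
      "Gent limit reached: I1* - 3 = %.6g >= j_m = %.6g (stress unbounded).",
      state$I1s - 3, params$j_m), class = "dmnimpact_gent_limit")
  }
  J <- state$J
  sigma_iso <- (params$mu_m / J) / (1 - gent_arg) * dev3(state$Bstar)
  if (anis) {
    i4 <- state$I4s - 1
    fib_tensor <- state$Fstar %*% state$A_o %*% t(state$Fstar)
    sigma_iso <- sigma_iso +
      (2 * params$k1 / J) * i4 * exp(params$k2 * i4^2) * dev3(fib_tensor)
  }
  dens_ratio <- 1 / J                      # rho / rho_o by mass conservation
  p <- -(params$K_o / (params$Lambda_o + 1)) *
    (dens_ratio^(params$Lambda_o + 1) - 1)
  sigma_vol <- diag(p, 3)
  structure(
    list(sigma = sigma_vol + sigma_iso,
         sigma_vol = sigma_vol,
         sigma_iso = sigma_iso),
    class = "cauchy_stress"
  )
}

as_stress_matrix <- function(sigma) {
  if (inherits(sigma, "cauchy_stress")) sigma <- sigma$sigma
  sigma <- as.matrix(sigma)
  if (!identical(dim(sigma), c(3L, 3L))) abort("stress must be 3x3.")
  if (max(abs(sigma - t(sigma))) > 1e-6 * max(abs(sigma), 1e-300)) {
    abort("stress tensor must be symmetric.")
  }
  sigma
}

#' von Mises equivalent stress
#'
#' `sqrt(3/2 * dev(sigma) : dev(sigma))`; used as the skull-fracture
#' indicator against the ultimate strength of bone.
#'
#' @param sigma 3x3 symmetric Cauchy stress (Pa) or a `cauchy_stress`.
#' @return scalar von Mises stress (Pa), >= 0.
#' @export
von_mises <- function(sigma) {
  s <- dev3(as_stress_matrix(sigma))
  sqrt(3 / 2 * sum(s * s))
}

#' Shear (deviatoric) energy rate density
#'
#' Deviatoric stress power per unit volume, `dev(sigma) : dev(D)`, the
#' tissue damage criterion for gray matter. The rate-of-deformation tensor
#' `D` must be symmetric; its deviator is taken internally so a traceful
#' `D` (volumetric stretching) contributes nothing.
#'
#' @param sigma 3x3 symmetric Cauchy stress (Pa) or a `cauchy_stress`.
#' @param D 3x3 symmetric rate-of-deformation tensor (1/s).
#' @return scalar shear energy rate in MJ/m^3/s.
#' @export
shear_energy_rate <- function(sigma, D) {
  s <- dev3(as_stress_matrix(sigma))
  D <- as.matrix(D)
  if (!identical(dim(D), c(3L, 3L))) abort("`D` must be 3x3.")
  if (max(abs(D - t(D))) > 1e-6 * max(abs(D), 1e-300)) {
    abort("`D` must be symmetric.")
  }
  sum(s * dev3(D)) * 1e-6   # W/m^3 -> MJ/m^3/s
}
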