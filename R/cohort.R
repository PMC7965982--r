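#' Specification of a synthetic resting-state cohort
#'
#' Describes a cohort of control subjects plus one patient on a voxel
#' grid: each subject's 4D series is a sum of network spatial maps driven
#' by AR(1) time courses plus white Gaussian noise; the patient carries a
#' contiguous connectivity deficit inside the DMN mask.
#'
#' @param grid_shape voxel grid dimensions.
#' @param n_timepoints number of volumes per subject (must exceed
#'   `n_networks + 1` so the temporal regression is determined).
#' @param n_controls number of control subjects (>= 2).
#' @param n_networks number of network templates driving the signal.
#' @param ar1_coefficient lag-1 autocorrelation of the network time
#'   courses (marginal variance 1).
#' @param noise_sd standard deviation of the additive voxel noise,
#'   relative to a unit peak network loading.
#' @param deficit_fraction fraction of DMN-mask voxels inside the
#'   patient's deficit region, in \[0, 1\].
#' @param deficit_effect multiplicative connectivity loss in the deficit
#'   region, in \[0, 1\] (1 = complete disconnection).
#' @param seed base seed; every subject derives its own stream.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(grid_shape = c(16L, 16L, 16L), n_timepoints = 150L,
                        n_controls = 18L, n_networks = 3L,
                        ar1_coefficient = 0.4, noise_sd = 0.5,
                        deficit_fraction = 0.3, deficit_effect = 0.7,
                        seed = 0L) {
  if (n_controls < 2) abort("`n_controls` must be >= 2.")
  if (deficit_fraction < 0 || deficit_fraction > 1) {
    abort("`deficit_fraction` must be in [0, 1].")
  }
  if (deficit_effect < 0 || deficit_effect > 1) {
    abort("`deficit_effect` must be in [0, 1].")
  }
  if (n_timepoints < n_networks + 2) {
    abort("`n_timepoints` must be >= n_networks + 2 (regression would be underdetermined).")
  }
  if (abs(ar1_coefficient) >= 1) abort("`ar1_coefficient` must be in (-1, 1).")
  structure(
    list(grid_shape = as.integer(grid_shape),
         n_timepoints = as.integer(n_timepoints),
         n_controls = as.integer(n_controls),
         n_networks = as.integer(n_networks),
         ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
         deficit_fraction = deficit_fraction,
         deficit_effect = deficit_effect, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

ar1_series <- function(n, phi) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov_sd <- sqrt(1 - phi^2)
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov_sd * rnorm(1)
  x
}

# quasi-contiguous deficit region: the `n_deficit` mask voxels nearest (in
# voxel space) to the mask's peak-z voxel
deficit_region <- function(template, z_threshold, fraction) {
  mask <- binarize_dmn_template(template, z_threshold)
  vox <- which(mask)
  n_def <- round(fraction * length(vox))
  if (n_def == 0L) return(integer(0))
  dims <- dim(mask)
  coord <- arrayInd(vox, dims)
  peak <- arrayInd(which.max(template$z_map * mask), dims)
  d2 <- rowSums((coord - matrix(peak, nrow(coord), 3, byrow = TRUE))^2)
  vox[order(d2, vox)][seq_len(n_def)]
}

#' Generate a synthetic resting-state cohort
#'
#' Each subject's series is `sum_k s_k(t) M_k(voxel) + noise`, with
#' `s_k` AR(1) time courses (marginal variance 1) and `M_k` the template
#' z-maps rescaled to unit peak. The single patient has its DMN loading
#' multiplied by `1 - deficit_effect` inside a contiguous region covering
#' `deficit_fraction` of the binarized DMN mask (the mask voxels nearest
#' the template peak). Subjects draw independent, seed-derived streams, so
#' the cohort is reproducible and the patient with `deficit_effect = 0` is
#' distributed exactly as a control sharing its stream.
#'
#' @param spec a `cohort_spec`.
#' @param templates list of `network_template`s, one per network; the one
#'   named `"DMN"` (or the first) receives the deficit.
#' @param z_threshold binarization threshold defining the DMN mask.
#' @return list of class `synthetic_cohort`: `patient` (T x-last 4D
#'   array), `controls` (list of 4D arrays), `templates`, `dmn_mask`,
#'   `deficit_voxels` (linear indices), `spec`.
#' @export
synth_rsfmri_cohort <- function(spec, templates, z_threshold = 3.1) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(templates) != spec$n_networks) {
    abort("`templates` must have length `n_networks`.")
  }
  dims <- spec$grid_shape
  V <- prod(dims)
  Tn <- spec$n_timepoints
  K <- spec$n_networks

  M <- vapply(templates, function(tp) {
    if (!all(dim(tp$z_map) == dims)) {
      abort("template grid does not match the cohort grid.")
    }
    as.numeric(tp$z_map) / max(abs(tp$z_map))
  }, numeric(V))                          # V x K unit-peak loadings

  nm <- vapply(templates, function(tp) tp$name, character(1))
  dmn_k <- if (any(nm == "DMN")) which(nm == "DMN")[1] else 1L
  defect <- deficit_region(templates[[dmn_k]], z_threshold,
                           spec$deficit_fraction)

  subject_series <- function(stream_seed, is_patient) {
    local_seed(stream_seed, {
      S <- vapply(seq_len(K), function(k) ar1_series(Tn, spec$ar1_coefficient),
                  numeric(Tn))              # T x K
      Msub <- M
      if (is_patient && length(defect)) {
        Msub[defect, dmn_k] <- Msub[defect, dmn_k] * (1 - spec$deficit_effect)
      }
      Y <- S %*% t(Msub)                    # T x V
      if (spec$noise_sd > 0) {
        Y <- Y + matrix(rnorm(Tn * V, 0, spec$noise_sd), Tn, V)
      }
      array(t(Y), dim = c(dims, Tn))        # x, y, z, t
    })
  }

  streams <- spec$seed + 1000003L * seq_len(spec$n_controls + 1L)
  controls <- lapply(streams[seq_len(spec$n_controls)], subject_series,
                     is_patient = FALSE)
  patient <- subject_series(streams[spec$n_controls + 1L], is_patient = TRUE)

  mask <- binarize_dmn_template(templates[[dmn_k]], z_threshold)
  structure(
    list(patient = patient, controls = controls, templates = templates,
         dmn_mask = mask, deficit_voxels = defect, spec = spec),
    class = "synthetic_cohort"
  )
}
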