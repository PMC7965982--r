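#' Label connected components of a binary 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 6) {
  dims <- dim(mask)
  if (length(dims) != 3L) abort("`mask` must be a 3D array.")
  labels <- .label_components_cpp(as.logical(mask), as.integer(dims),
                                  as.integer(connectivity))
  array(labels, dim = dims)
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' For every voxel, `TFCE(v) = sum over h = dh, 2dh, ... <= stat(v) of
#' e(h, v)^E * h^H * dh`, where `e(h, v)` is the voxel count of the
#' connected component containing `v` in the supra-threshold set at height
#' `h`. Voxels with non-positive statistic get 0; the enhancement is
#' therefore one-sided.
#'
#' @param stat_map finite numeric 3D array.
#' @param E extent exponent (published default 0.5).
#' @param H height exponent (published default 2).
#' @param dh threshold step; `"auto"` uses a tenth of the map maximum,
#'   a numeric value is used as an absolute step.
#' @param connectivity 6 or 26.
#' @return numeric 3D array of enhanced values.
#' @export
tfce_enhance <- function(stat_map, E = 0.5, H = 2, dh = "auto",
                         connectivity = 6) {
  dims <- dim(stat_map)
  if (length(dims) != 3L) abort("`stat_map` must be a 3D array.")
  if (any(!is.finite(stat_map))) abort("`stat_map` must be finite.")
  mx <- max(stat_map)
  if (identical(dh, "auto")) {
    if (mx <= 0) return(array(0, dim = dims))
    dh <- mx / 10
  }
  if (!is.numeric(dh) || dh <= 0) abort("`dh` must be > 0 (or \"auto\").")
  if (mx / dh > 1e6) {
    abort("`dh` implies more than 1e6 integration steps; use a larger step.")
  }
  out <- .tfce_cpp(as.numeric(stat_map), as.integer(dims), E, H, dh,
                   as.integer(connectivity))
  array(out, dim = dims)
}

crawford_howell_t <- function(control_mat, patient_vec) {
  # control_mat: N x V; single-case t for contrast controls > patient
  N <- nrow(control_mat)
  mu <- colMeans(control_mat)
  sdv <- sqrt(colSums(sweep(control_mat, 2, mu)^2) / (N - 1))
  t <- (mu - patient_vec) / (sdv * sqrt(1 + 1 / N))
  zero_var <- sdv == 0
  t[zero_var] <- 0
  list(t = t, zero_var = zero_var)
}

#' Single-case permutation inference with sign flipping
#'
#' Compares one patient map against `N` control maps voxelwise with the
#' Crawford-Howell single-case t statistic for the contrast
#' controls > patient, `t = (mean_c - patient) / (sd_c sqrt(1 + 1/N))`.
#' The null distribution is generated by randomly sign-flipping the
#' mean-centred maps (all subjects centred by the pooled voxelwise mean; a
#' valid null under symmetric errors) and recomputing the statistic. By
#' default the observed and permuted maps are TFCE-enhanced before
#' comparison (each map with the conventional adaptive step, its maximum
#' over 10); `use_tfce = FALSE` compares raw t maps instead.
#' Voxelwise p-values are `(1 + #permuted >= observed) / (n_perm + 1)`.
#'
#' @param patient_map 3D array (or `subject_network_map`, using its z map).
#' @param control_maps list of 3D arrays (or `subject_network_map`s).
#' @param n_perm number of permutations.
#' @param seed RNG seed (sign flips).
#' @param use_tfce enhance maps with TFCE before comparison.
#' @param E,H,connectivity TFCE parameters.
#' @return object of class `case_control_result`: `t_map`, `tfce_map`,
#'   `p_map`, `n_perm`, `seed`, `zero_variance` (logical array).
#' @export
single_case_permutation <- function(patient_map, control_maps,
                                    n_perm = 5000, seed = 0L,
                                    use_tfce = TRUE, E = 0.5, H = 2,
                                    connectivity = 6) {
  as_map <- function(m) {
    if (inherits(m, "subject_network_map")) m$z else m
  }
  patient <- as_map(patient_map)
  controls <- lapply(control_maps, as_map)
  N <- length(controls)
  if (N < 2L) abort("need at least 2 control maps.")
  dims <- dim(patient)
  V <- prod(dims)
  C <- t(vapply(controls, function(m) {
    if (!all(dim(m) == dims)) abort("control map grid mismatch.")
    as.numeric(m)
  }, numeric(V)))                          # N x V
  p_vec <- as.numeric(patient)

  obs <- crawford_howell_t(C, p_vec)
  t_map <- array(obs$t, dim = dims)

  # dh adapts to each map (max/10), the conventional TFCE discretization;
  # a fixed absolute step would blow up on permuted maps whose flipped
  # control variance is near zero and whose t values are huge
  enhance <- if (use_tfce) {
    function(tv) {
      mx <- max(tv)
      if (mx <= 0) return(numeric(length(tv)))
      .tfce_cpp(tv, as.integer(dims), E, H, mx / 10,
                as.integer(connectivity))
    }
  } else {
    identity
  }
  obs_enh <- enhance(obs$t)

  all_maps <- rbind(C, p_vec)              # (N+1) x V
  centred <- sweep(all_maps, 2, colMeans(all_maps))
  count_ge <- numeric(V)
  local_seed(seed, {
    for (b in seq_len(n_perm)) {
      s <- sample(c(-1, 1), N + 1L, replace = TRUE)
      flipped <- centred * s
      perm <- crawford_howell_t(flipped[seq_len(N), , drop = FALSE],
                                flipped[N + 1L, ])
      count_ge <- count_ge + (enhance(perm$t) >= obs_enh)
    }
  })
  p_map <- array((1 + count_ge) / (n_perm + 1), dim = dims)

  structure(
    list(t_map = t_map,
         tfce_map = array(obs_enh, dim = dims),
         p_map = p_map, n_perm = as.integer(n_perm),
         seed = as.integer(seed),
         zero_variance = array(obs$zero_var, dim = dims),
         use_tfce = use_tfce),
    class = "case_control_result"
  )
}

#' @export
print.case_control_result <- function(x, ...) {
  cat(sprintf(
    "<case_control_result> %s, %d permutations, min p = %.4g\n",
    if (x$use_tfce) "TFCE-enhanced" else "raw t", x$n_perm, min(x$p_map)))
  invisible(x)
}

#' DMN damage load from a voxelwise p-map
#'
#' Counts the statistically "disconnected" voxels (`p < alpha`) inside the
#' binary DMN mask (optionally intersected with a gray-matter mask) and
#' expresses them as a percentage of the full DMN mask volume.
#'
#' @param p_map 3D array of p-values, or a `case_control_result`.
#' @param dmn_binary_mask logical 3D array (non-empty).
#' @param alpha significance level.
#' @param gray_mask optional logical 3D array restricting the count.
#' @return one-row tibble of class `damage_load`: `n_disconnected`,
#'   `dmn_mask_volume`, `damage_load_percent`.
#' @export
damage_load <- function(p_map, dmn_binary_mask, alpha = 0.05,
                        gray_mask = NULL) {
  if (inherits(p_map, "case_control_result")) p_map <- p_map$p_map
  if (!all(dim(p_map) == dim(dmn_binary_mask))) {
    abort("`p_map` and `dmn_binary_mask` must share a grid.")
  }
  vol <- sum(dmn_binary_mask)
  if (vol == 0L) abort("DMN mask is empty.")
  sig <- (p_map < alpha) & dmn_binary_mask
  if (!is.null(gray_mask)) {
    if (!all(dim(gray_mask) == dim(p_map))) {
      abort("`gray_mask` must share the grid.")
    }
    sig <- sig & gray_mask
  }
  out <- tibble::tibble(
    n_disconnected = sum(sig),
    dmn_mask_volume = vol,
    damage_load_percent = 100 * sum(sig) / vol
  )
  class(out) <- c("damage_load", class(out))
  out
}
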