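#' Probability-velocity curve for a fixed impact configuration
#'
#' Sweeps the impact velocity over a grid with all other scenario inputs
#' held constant, re-extracting features at each velocity (the
#' DMN-geometry features depend on the location only and stay constant)
#' and evaluating the ensemble probability that the damage threshold is
#' exceeded.
#'
#' @param ensemble a `dmn_ensemble` trained at the target damage threshold.
#' @param base one-row scenario tibble; its `velocity` entry is ignored.
#' @param mesh a `head_mesh`.
#' @param dmn_ids DMN element ids.
#' @param v_min,v_max sweep range (m/s), `v_min < v_max`.
#' @param step grid step (m/s), > 0.
#' @return object of class `velocity_curve`: tibble with `velocity` and
#'   `probability`.
#' @export
probability_velocity_curve <- function(ensemble, base, mesh, dmn_ids,
                                       v_min = 1, v_max = 15, step = 0.1) {
  if (v_min >= v_max) abort("`v_min` must be < `v_max`.")
  if (step <= 0) abort("`step` must be > 0.")
  velocities <- seq(v_min, v_max, by = step)
  scen <- base[rep(1L, length(velocities)), ]
  scen$velocity <- velocities
  feats <- extract_features(scen, mesh, dmn_ids)
  p <- predict(ensemble, feats)
  structure(
    tibble::tibble(velocity = velocities, probability = as.numeric(p)),
    class = c("velocity_curve", class(tibble::tibble())))
}

isotonic_probs <- function(p) {
  # monotone non-decreasing fit; isoreg expects increasing x order
  as.numeric(stats::isoreg(seq_along(p), p)$yf)
}

#' Plateau probability and the velocity at 95% of the plateau
#'
#' The plateau probability `P_f` is the mean probability over the top 10%
#' of the velocity grid (optionally after isotonic, i.e. monotone
#' non-decreasing, smoothing — recommended for noisy ensembles whose
#' sigmoid oscillates in the upper plateau). The reported velocity is the
#' smallest grid velocity whose probability reaches `level * P_f`
#' (default 95%), interpreted as the velocity at which the target damage
#' proportion is first reached.
#'
#' @param curve a `velocity_curve` (or tibble with `velocity`,
#'   `probability`).
#' @param level fraction of the plateau to reach (default 0.95).
#' @param plateau_window fraction of the grid (from the top) averaged for
#'   `P_f`.
#' @param smooth apply isotonic smoothing before plateau detection.
#' @return list with `P_f`, `v_at_95` (`NA` when not reached) and
#'   `reached`.
#' @export
plateau_and_velocity <- function(curve, level = 0.95, plateau_window = 0.1,
                                 smooth = FALSE) {
  v <- curve$velocity
  p <- curve$probability
  if (length(v) < 10L) abort("need at least 10 curve samples.")
  if (smooth) p <- isotonic_probs(p)
  n_top <- max(1L, ceiling(plateau_window * length(v)))
  P_f <- mean(tail(p, n_top))
  if (P_f <= 0) {
    return(list(P_f = 0, v_at_95 = NA_real_, reached = FALSE))
  }
  hit <- which(p >= level * P_f)
  if (length(hit) == 0L) {
    return(list(P_f = P_f, v_at_95 = NA_real_, reached = FALSE))
  }
  list(P_f = P_f, v_at_95 = v[hit[1L]], reached = TRUE)
}
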