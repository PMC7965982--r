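#' Candidate feature names, in declaration order
#'
#' Declaration order is the tie-break order of the greedy forward
#' selection.
#'
#' @return character vector.
#' @export
feature_names <- function() {
  c("velocity",
    paste0("loc_", impact_locations()$location),
    "perpendicular", "radius_of_curvature",
    "dist_to_dmn", "angle_to_dmn")
}

#' Extract classifier features for impact scenarios
#'
#' Builds the feature vector for each scenario row: velocity, five
#' impact-location indicators, a perpendicular-impact flag (`angle == 0`),
#' the impactor radius of curvature, and two DMN-geometry features —
#' `dist_to_dmn`, the Euclidean distance from the impact point to the
#' nearest DMN element centroid, and `angle_to_dmn`, the angle (degrees)
#' between the impact direction and the direction from the impact point to
#' that nearest centroid (0 by convention when the distance is 0).
#'
#' @param scenarios tibble of scenario rows ([impact_scenario()] /
#'   [scenario_grid()] / a scenario library).
#' @param mesh a `head_mesh`.
#' @param dmn_ids non-empty DMN element ids.
#' @return tibble of features, one row per scenario, columns in
#'   [feature_names()] order.
#' @export
extract_features <- function(scenarios, mesh, dmn_ids) {
  if (length(dmn_ids) == 0L) abort("`dmn_ids` must be non-empty.")
  stopifnot(inherits(mesh, "head_mesh"))
  cent <- mesh$centroids[dmn_ids, , drop = FALSE]

  # DMN geometry depends on the impact location only
  locs <- impact_locations()$location
  geo <- purrr::map_dfr(locs, function(loc) {
    g <- impact_geometry(loc, mesh$radius)
    if (sqrt(sum(g$direction^2)) < 1e-12) {
      abort("impact direction has zero length.")
    }
    d <- sqrt(rowSums((cent - matrix(g$point, nrow(cent), 3,
                                     byrow = TRUE))^2))
    i <- which.min(d)
    dist <- d[i]
    if (dist < 1e-12) {
      ang <- 0
    } else {
      u <- (cent[i, ] - g$point) / dist
      cosang <- sum(u * g$direction / sqrt(sum(g$direction^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    }
    tibble::tibble(location = loc, dist_to_dmn = dist, angle_to_dmn = ang)
  })

  out <- dplyr::left_join(scenarios, geo, by = "location")
  for (loc in locs) {
    out[[paste0("loc_", loc)]] <- as.integer(out$location == loc)
  }
  out$perpendicular <- as.integer(out$angle == 0)
  out$radius_of_curvature <- out$radius
  dplyr::select(out, dplyr::all_of(feature_names()))
}

#' Label a scenario library at a damage threshold
#'
#' Binary outcome: 1 iff `damage_percent` strictly exceeds the threshold.
#' Fractured records must have been removed by the caller — a simulated
#' skull fracture invalidates the record, mirroring the exclusion applied
#' when assembling the training library.
#'
#' @param records scenario-library tibble with `fractured` and
#'   `damage_percent` columns.
#' @param damage_threshold DMN damage threshold (% of DMN elements).
#' @return integer vector of 0/1 labels.
#' @export
label_library <- function(records, damage_threshold) {
  if (!all(c("fractured", "damage_percent") %in% names(records))) {
    abort("`records` must have `fractured` and `damage_percent` columns.")
  }
  if (any(records$fractured)) {
    abort("fractured records present: filter them out before labelling.",
          class = "dmnimpact_contract_violation")
  }
  if (damage_threshold < 0 || damage_threshold > 100) {
    abort("`damage_threshold` must be in [0, 100].")
  }
  as.integer(records$damage_percent > damage_threshold)
}
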