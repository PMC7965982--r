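# Shared fixtures, built once per test run. The resolution-3 head, its DMN
# element set and the default (noisy, seed-0) scenario library back the
# ML-layer and acceptance tests; everything else builds its own small inputs.

fx <- new.env()

fixture_mesh <- function() {
  if (is.null(fx$mesh)) fx$mesh <- build_toy_head_mesh(3, seed = 0)
  fx$mesh
}

fixture_dmn_ids <- function() {
  if (is.null(fx$ids)) {
    fx$template <- default_dmn_template()
    fx$ids <- map_dmn_elements(fixture_mesh(),
                               binarize_dmn_template(fx$template))
  }
  fx$ids
}

fixture_template <- function() {
  fixture_dmn_ids()
  fx$template
}

fixture_library <- function() {
  if (is.null(fx$lib)) {
    fx$lib <- build_scenario_library(scenario_grid(), fixture_mesh(),
                                     surrogate_params(seed = 0),
                                     dmn_ids = fixture_dmn_ids())
  }
  fx$lib
}

fixture_features <- function() {
  if (is.null(fx$feats)) {
    lib <- dplyr::filter(fixture_library(), !fractured)
    fx$lib_ok <- lib
    fx$feats <- extract_features(lib, fixture_mesh(), fixture_dmn_ids())
  }
  fx$feats
}

fixture_unfractured <- function() {
  fixture_features()
  fx$lib_ok
}

# minimal hand-built mesh: `centroids`/`tets`/`region` chosen per test
toy_mesh <- function(nodes, tets, region, radius = 0.09) {
  tets <- matrix(as.integer(tets), ncol = 4L)
  centroids <- (nodes[tets[, 1], , drop = FALSE] +
                nodes[tets[, 2], , drop = FALSE] +
                nodes[tets[, 3], , drop = FALSE] +
                nodes[tets[, 4], , drop = FALSE]) / 4
  structure(
    list(nodes = nodes, tets = tets,
         region = factor(region, levels = c("gray", "white", "skull", "csf")),
         fiber = matrix(NA_real_, nrow(tets), 3),
         centroids = centroids, volumes = rep(1, nrow(tets)),
         radius = radius, resolution = NA_integer_, seed = NA_integer_),
    class = "head_mesh")
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_posdet_F <- function(spread = 0.2) {
  repeat {
    F <- diag(3) + matrix(rnorm(9, 0, spread), 3, 3)
    if (det(F) > 0.2) return(F)
  }
}
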