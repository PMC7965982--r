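test_that("noise-free peak fields match the closed-form surrogate", {
  m <- build_toy_head_mesh(2, seed = 0)
  p <- surrogate_params(noise_cv = 0)
  sc <- impact_scenario(6, "vertex", angle = 30, impactor = "sharp_corner")
  pf <- surrogate_peak_fields(sc, m, p)
  # independent evaluation of the stated formula
  point <- m$radius * c(0, 0, 1)
  d <- sqrt(rowSums((m$centroids[pf$gray_ids, , drop = FALSE] -
                     matrix(point, length(pf$gray_ids), 3, byrow = TRUE))^2))
  expected <- p$A * (6 / p$v_ref)^p$alpha * exp(-d / p$lambda) *
    (1 + p$beta * cos(30 * pi / 180)) * (p$R_ref / sc$radius)^p$gamma_R
  expect_equal(pf$gray_ser, expected, tolerance = 1e-12)
  ds <- sqrt(rowSums((m$centroids[pf$skull_ids, , drop = FALSE] -
                      matrix(point, length(pf$skull_ids), 3, byrow = TRUE))^2))
  expect_equal(pf$skull_vm,
               p$B * 6 * (p$R_ref / sc$radius)^p$gamma_R * exp(-ds / p$lambda),
               tolerance = 1e-12)
  # at the reference configuration the d = 0 limit is A (1 + beta)
  sc_ref <- impact_scenario(p$v_ref, "vertex", 0, "round")
  pf_ref <- surrogate_peak_fields(sc_ref, m, p)
  d_ref <- sqrt(rowSums((m$centroids[pf_ref$gray_ids, , drop = FALSE] -
                         matrix(point, length(pf_ref$gray_ids), 3,
                                byrow = TRUE))^2))
  expect_equal(pf_ref$gray_ser, p$A * (1 + p$beta) * exp(-d_ref / p$lambda),
               tolerance = 1e-12)
})

test_that("noise-free fields are strictly increasing in velocity", {
  m <- build_toy_head_mesh(2, seed = 0)
  p <- surrogate_params(noise_cv = 0)
  f1 <- surrogate_peak_fields(impact_scenario(4, "occipital"), m, p)
  f2 <- surrogate_peak_fields(impact_scenario(9, "occipital"), m, p)
  expect_true(all(f2$gray_ser > f1$gray_ser))
  expect_true(all(f2$skull_vm > f1$skull_vm))
})

test_that("fields are reproducible and reject invalid velocities", {
  m <- build_toy_head_mesh(2, seed = 0)
  p <- surrogate_params(noise_cv = 0.1, seed = 5)
  sc <- impact_scenario(7, "temporal", -20, "blunt_corner")
  a <- surrogate_peak_fields(sc, m, p)
  b <- surrogate_peak_fields(sc, m, p)
  expect_identical(a$gray_ser, b$gray_ser)
  expect_identical(a$skull_vm, b$skull_vm)
  expect_error(impact_scenario(0, "vertex"))
  expect_error(impact_scenario(16.5, "vertex"))
})

test_that("library size equals the grid product and respects fracture limits", {
  m <- build_toy_head_mesh(2, seed = 0)
  ids <- map_dmn_elements(m, binarize_dmn_template(default_dmn_template()))
  g <- scenario_grid(velocities = c(2, 5, 8, 11, 14), angles = 0)
  expect_equal(nrow(g), 5 * 4 * 5 * 1)
  lib <- build_scenario_library(g, m, surrogate_params(noise_cv = 0),
                                dmn_ids = ids)
  expect_equal(nrow(lib), 100)
  expect_true(all(lib$damage_percent >= 0 & lib$damage_percent <= 100))
  # a huge skull gain fractures every record
  lib_b <- build_scenario_library(g[1:10, ], m,
                                  surrogate_params(noise_cv = 0, B = 1e6),
                                  dmn_ids = ids)
  expect_true(all(lib_b$fractured))
  expect_equal(nrow(dplyr::filter(lib_b, !fractured)), 0)
  expect_error(scenario_grid(velocities = numeric(0)))
})

test_that("noise-free damage is non-decreasing in velocity within every slice", {
  m <- build_toy_head_mesh(2, seed = 0)
  ids <- map_dmn_elements(m, binarize_dmn_template(default_dmn_template()))
  lib <- build_scenario_library(scenario_grid(), m,
                                surrogate_params(noise_cv = 0),
                                dmn_ids = ids)
  bad <- lib |>
    dplyr::arrange(location, impactor, angle, velocity) |>
    dplyr::group_by(location, impactor, angle) |>
    dplyr::summarise(mono = all(diff(damage_percent) >= 0),
                     .groups = "drop")
  expect_true(all(bad$mono))
})

test_that("library CSV round-trips", {
  lib <- fixture_library()[1:20, ]
  path <- tempfile(fileext = ".csv")
  write_library_csv(lib, path)
  back <- read_library_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(lib), tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(path)
})
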