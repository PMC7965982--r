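test_that("deformation split yields unimodular distortional part", {
  st <- decompose_deformation(diag(3))
  expect_equal(st$J, 1)
  expect_equal(st$I1s, 3)

  st2 <- decompose_deformation(2 * diag(3))
  expect_equal(st2$J, 8)
  expect_equal(st2$Fstar, diag(3))
  expect_equal(st2$I1s, 3)

  set.seed(42)
  for (i in 1:25) {
    F <- random_posdet_F()
    st <- decompose_deformation(F)
    expect_lt(abs(det(st$Fstar) - 1), 1e-9)
  }

  expect_error(decompose_deformation(-diag(3)),
               class = "dmnimpact_invalid_deformation")
})

test_that("fiber invariant needs a unit direction and stays positive", {
  expect_error(decompose_deformation(diag(3), fiber = c(1, 1, 0)))
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    st <- decompose_deformation(random_posdet_F(), fiber = a)
    expect_gt(st$I4s, 0)
  }
})

test_that("reference state is stress-free for both tissues", {
  for (p in list(gray_matter_params(), white_matter_params())) {
    fib <- if (is.null(p$k1)) NULL else c(0, 0, 1)
    s <- cauchy_stress(diag(3), p, fiber = fib)
    expect_lt(max(abs(s$sigma)), 1e-9)
  }
})

test_that("pure dilatation matches the closed-form volumetric branch", {
  gp <- gray_matter_params()
  a <- 0.99
  s <- cauchy_stress(diag(a, 3), gp)
  p_expected <- -gp$K_o / (gp$Lambda_o + 1) * ((a^-3)^(gp$Lambda_o + 1) - 1)
  expect_equal(diag(s$sigma), rep(p_expected, 3), tolerance = 1e-12)
  expect_lt(max(abs(s$sigma_iso)), 1e-6 * abs(p_expected))
})

test_that("small simple shear recovers the matrix shear modulus", {
  gp <- gray_matter_params()
  g <- 1e-4
  F <- diag(3); F[1, 2] <- g
  s <- cauchy_stress(F, gp)
  expect_equal(s$sigma[1, 2], gp$mu_m * g, tolerance = 1e-3)
})

test_that("stress is objective under superposed rotations", {
  set.seed(7)
  wp <- white_matter_params()
  gp <- gray_matter_params()
  for (i in 1:100) {
    R <- random_rotation()
    F <- random_posdet_F(0.1)
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    s1 <- cauchy_stress(F, wp, fiber = a)$sigma
    s2 <- cauchy_stress(R %*% F, wp, fiber = a)$sigma
    expect_lt(max(abs(s2 - R %*% s1 %*% t(R))), 1e-8 * max(abs(s1), 1))
    g1 <- cauchy_stress(F, gp)$sigma
    g2 <- cauchy_stress(R %*% F, gp)$sigma
    expect_lt(max(abs(g2 - R %*% g1 %*% t(R))), 1e-8 * max(abs(g1), 1))
  }
})

test_that("isochoric stress is deviatoric and gray equals fiber-free white", {
  set.seed(3)
  wp <- white_matter_params()
  wp_nofiber <- brain_material_params(wp$mu_m, wp$j_m, wp$K_o, wp$Lambda_o,
                                      wp$rho_o)
  gp_matched <- wp_nofiber
  for (i in 1:20) {
    F <- random_posdet_F(0.1)
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    sw <- cauchy_stress(F, wp, fiber = a)
    expect_lt(abs(sum(diag(sw$sigma_iso))), 1e-6 * max(abs(sw$sigma_iso)))
    # zero fiber stiffness must reproduce the isotropic response exactly
    wp0 <- brain_material_params(wp$mu_m, wp$j_m, wp$K_o, wp$Lambda_o,
                                 wp$rho_o, k1 = 0, k2 = 0)
    s_k0 <- cauchy_stress(F, wp0, fiber = a)$sigma
    s_iso <- cauchy_stress(F, gp_matched)$sigma
    expect_equal(s_k0, s_iso, tolerance = 1e-12)
  }
})

test_that("stress blows up monotonically approaching the Gent limit", {
  gp <- gray_matter_params()
  # simple shear: I1* - 3 = gamma^2, limit at gamma = sqrt(j_m)
  gams <- sqrt(gp$j_m) * c(0.9, 0.99, 0.999, 0.9999)
  norms <- vapply(gams, function(g) {
    F <- diag(3); F[1, 2] <- g
    max(abs(cauchy_stress(F, gp)$sigma))
  }, numeric(1))
  expect_true(all(diff(norms) > 0))
  expect_gt(norms[4] / norms[1], 100)
  Fbad <- diag(3); Fbad[1, 2] <- sqrt(gp$j_m) * 1.01
  expect_error(cauchy_stress(Fbad, gp), class = "dmnimpact_gent_limit")
})

test_that("fiber/material mismatches are rejected", {
  expect_error(cauchy_stress(diag(3), white_matter_params()),
               class = "dmnimpact_fiber_mismatch")
  expect_error(cauchy_stress(decompose_deformation(diag(3), c(0, 0, 1)),
                             gray_matter_params()),
               class = "dmnimpact_fiber_mismatch")
})

test_that("von Mises stress matches the eigenvalue oracle", {
  expect_equal(von_mises(diag(3) * 5e4), 0)
  expect_equal(von_mises(diag(c(7, 0, 0))), 7)
  set.seed(11)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3, 3)
    S <- (A + t(A)) / 2
    ev <- eigen(S, symmetric = TRUE)$values
    oracle <- sqrt(((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                    (ev[3] - ev[1])^2) / 2)
    expect_equal(von_mises(S), oracle, tolerance = 1e-12)
  }
})

test_that("shear energy rate is the deviatoric stress power", {
  sig <- matrix(0, 3, 3)
  expect_equal(shear_energy_rate(sig, diag(3) * 100), 0)
  # hydrostatic stress transmits no shear power
  D <- matrix(rnorm(9), 3, 3); D <- (D + t(D)) / 2
  expect_equal(shear_energy_rate(diag(3) * 1e6, D), 0, tolerance = 1e-9)
  # pure-shear contraction oracle: dev(s):dev(D) = 2 s12 D12
  sig[1, 2] <- sig[2, 1] <- 1e3
  D12 <- matrix(0, 3, 3); D12[1, 2] <- D12[2, 1] <- 500
  oracle <- 2 * 1e3 * 500 * 1e-6        # W/m^3 -> MJ/m^3/s
  expect_equal(shear_energy_rate(sig, D12), oracle, tolerance = 1e-12)
  # full random double contraction oracle
  set.seed(5)
  for (i in 1:10) {
    S <- matrix(rnorm(9, sd = 1e3), 3, 3); S <- (S + t(S)) / 2
    D <- matrix(rnorm(9, sd = 10), 3, 3); D <- (D + t(D)) / 2
    devS <- S - diag(mean(diag(S)), 3)
    devD <- D - diag(mean(diag(D)), 3)
    expect_equal(shear_energy_rate(S, D), sum(devS * devD) * 1e-6,
                 tolerance = 1e-12)
  }
})

test_that("shipped material tables carry the calibrated values", {
  wp <- white_matter_params()
  expect_equal(wp$mu_m, 550e3)
  expect_equal(wp$j_m, 1.1)
  expect_equal(wp$k1, 2.14e3)
  expect_equal(wp$k2, 0)
  gp <- gray_matter_params()
  expect_equal(gp$mu_m, 450e3)
  expect_equal(gp$j_m, 1.4)
  expect_null(gp$k1)
  for (p in list(wp, gp)) {
    expect_equal(p$rho_o, 1140)
    expect_equal(p$K_o, 2.19e9)
    expect_equal(p$Lambda_o, 6.15)
  }
})
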