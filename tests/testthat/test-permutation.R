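test_that("TFCE matches the hand-summed discrete formula", {
  stat <- array(0, c(7, 7, 7))
  expect_true(all(tfce_enhance(stat, dh = 0.1) == 0))
  # single isolated voxel of height 1.0: e = 1 at every threshold
  stat[4, 4, 4] <- 1.0
  oracle <- sum(1^0.5 * (0.1 * (1:10))^2 * 0.1)
  expect_equal(tfce_enhance(stat, dh = 0.1)[4, 4, 4], oracle,
               tolerance = 1e-12)
  expect_true(all(tfce_enhance(stat, dh = 0.1)[-(4 + 7 * 3 + 49 * 3)] == 0))
})

test_that("a constant-height cube cluster enhances uniformly", {
  stat <- array(0, c(9, 9, 9))
  stat[3:5, 3:5, 3:5] <- 2.0
  enh <- tfce_enhance(stat, dh = 0.2)
  vals <- enh[3:5, 3:5, 3:5]
  expect_equal(max(vals) - min(vals), 0)
  # oracle: component size 27 at every threshold 0.2, 0.4, ..., 2.0
  oracle <- sum(27^0.5 * (0.2 * (1:10))^2 * 0.2)
  expect_equal(vals[1], oracle, tolerance = 1e-12)
  expect_true(all(enh[stat == 0] == 0))
})

test_that("TFCE never decreases under pointwise upscaling", {
  set.seed(41)
  for (i in 1:5) {
    stat <- array(pmax(rnorm(6^3), 0), c(6, 6, 6))
    e1 <- tfce_enhance(stat, dh = 0.05)
    e2 <- tfce_enhance(1.7 * stat, dh = 0.05)
    expect_true(all(e2 - e1 >= -1e-12))
  }
  expect_error(tfce_enhance(array(NaN, c(4, 4, 4))))
})

test_that("negative statistic values contribute nothing", {
  stat <- array(-1, c(5, 5, 5))
  stat[2, 2, 2] <- 0.5
  enh <- tfce_enhance(stat, dh = 0.1)
  expect_true(all(enh[stat < 0] == 0))
  expect_gt(enh[2, 2, 2], 0)
})

test_that("single-case t handles zero-variance voxels and the p floor", {
  set.seed(42)
  dims <- c(5, 5, 5)
  controls <- lapply(1:6, function(i) array(rnorm(prod(dims)), dims))
  for (ct in seq_along(controls)) controls[[ct]][1, 1, 1] <- 3  # no variance
  patient <- array(rnorm(prod(dims)), dims)
  res <- single_case_permutation(patient, controls, n_perm = 19, seed = 1)
  expect_true(res$zero_variance[1, 1, 1])
  expect_equal(res$t_map[1, 1, 1], 0)
  # permutation p floor at 19 permutations is 1/20
  expect_gte(min(res$p_map), 1 / 20)
  expect_true(all(res$p_map <= 1))
})

test_that("a patient equal to the control mean is never declared damaged", {
  set.seed(43)
  dims <- c(8, 8, 8)
  controls <- lapply(1:10, function(i) array(rnorm(prod(dims)), dims))
  mu <- Reduce(`+`, controls) / 10
  res <- single_case_permutation(mu, controls, n_perm = 500, seed = 2)
  expect_lte(mean(res$p_map < 0.05), 0.08)
})

test_that("a planted strong deficit is detected across the block", {
  set.seed(44)
  dims <- c(12, 12, 12)
  controls <- lapply(1:18, function(i) array(rnorm(prod(dims)), dims))
  C <- sapply(controls, as.numeric)
  mu <- rowMeans(C); sdv <- apply(C, 1, sd)
  patient <- array(mu, dims)
  block <- as.matrix(expand.grid(4:8, 4:8, 4:8))
  bi <- block[, 1] + dims[1] * (block[, 2] - 1) +
    dims[1] * dims[2] * (block[, 3] - 1)
  patient[bi] <- mu[bi] - 5 * sdv[bi]
  res <- single_case_permutation(patient, controls, n_perm = 500, seed = 3)
  expect_gte(mean(res$p_map[bi] < 0.05), 0.9)
})

test_that("permutation results are bit-reproducible", {
  set.seed(45)
  dims <- c(6, 6, 6)
  controls <- lapply(1:5, function(i) array(rnorm(prod(dims)), dims))
  patient <- array(rnorm(prod(dims)), dims)
  a <- single_case_permutation(patient, controls, n_perm = 100, seed = 9)
  b <- single_case_permutation(patient, controls, n_perm = 100, seed = 9)
  expect_identical(a$p_map, b$p_map)
  expect_identical(a$tfce_map, b$tfce_map)
})

test_that("damage load counts significant voxels inside the mask", {
  dims <- c(10, 10, 2)
  p1 <- array(1, dims)
  mask <- array(FALSE, dims); mask[1:10, 1:10, 1] <- TRUE  # 100 voxels
  expect_equal(damage_load(p1, mask)$damage_load_percent, 0)
  p0 <- array(0.001, dims)
  expect_equal(damage_load(p0, mask)$damage_load_percent, 100)
  # 31 of 200 mask voxels significant
  mask2 <- array(TRUE, dims)                                # 200 voxels
  p <- array(1, dims); p[seq_len(31)] <- 0.01
  dl <- damage_load(p, mask2)
  expect_equal(dl$n_disconnected, 31L)
  expect_equal(dl$damage_load_percent, 15.5)
  # gray-mask intersection shrinks the numerator, not the denominator
  gray <- array(FALSE, dims); gray[seq_len(10)] <- TRUE
  dlg <- damage_load(p, mask2, gray_mask = gray)
  expect_equal(dlg$n_disconnected, 10L)
  expect_equal(dlg$dmn_mask_volume, 200L)
  expect_error(damage_load(p, array(FALSE, dims)))
})

test_that("binarized template volume matches the damage-load denominator", {
  tpl <- default_dmn_template()
  mask <- binarize_dmn_template(tpl)
  p <- array(1, dim(mask))
  expect_equal(damage_load(p, mask)$dmn_mask_volume, sum(mask))
})
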