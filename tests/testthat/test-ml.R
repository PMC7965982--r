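test_that("DMN geometry features follow the stated conventions", {
  # single gray tet whose centroid sits on the z axis at 0.05
  nodes <- rbind(c(-0.01, -0.01, 0.04), c(0.01, -0.01, 0.04),
                 c(0, 0.02, 0.04), c(0, 0, 0.08))
  m <- toy_mesh(nodes, rbind(c(1, 2, 3, 4)), "gray")
  f <- extract_features(impact_scenario(5, "vertex"), m, dmn_ids = 1L)
  # impact at (0,0,0.09) aiming -z; centroid at (0,0,0.05): aligned
  expect_equal(f$dist_to_dmn, 0.04, tolerance = 1e-12)
  expect_equal(f$angle_to_dmn, 0, tolerance = 1e-9)
  expect_equal(f$loc_vertex, 1L)
  expect_equal(sum(dplyr::select(f, dplyr::starts_with("loc_"))), 1)
  expect_equal(f$perpendicular, 1L)
  # occipital impact at (0,-0.09,0) aiming +y; centroid direction has an
  # arccos-dot-product angle against the impact direction
  f2 <- extract_features(impact_scenario(5, "occipital", angle = 30), m, 1L)
  u <- c(0, 0, 0.05) - c(0, -0.09, 0)
  oracle <- acos(sum(u / sqrt(sum(u^2)) * c(0, 1, 0))) * 180 / pi
  expect_equal(f2$angle_to_dmn, oracle, tolerance = 1e-9)
  expect_equal(f2$perpendicular, 0L)
})

test_that("a centroid opposite the impact direction gives 180 degrees", {
  nodes <- rbind(c(-0.01, -0.01, 0.16), c(0.01, -0.01, 0.16),
                 c(0, 0.02, 0.16), c(0, 0, 0.20))
  m <- toy_mesh(nodes, rbind(c(1, 2, 3, 4)), "gray")
  # vertex impact point (0, 0, 0.09) aims (0, 0, -1); centroid at z = 0.17
  f <- extract_features(impact_scenario(5, "vertex"), m, 1L)
  expect_equal(f$angle_to_dmn, 180, tolerance = 1e-9)
})

test_that("library labelling is strict and rejects fractured records", {
  rec <- tibble::tibble(fractured = FALSE,
                        damage_percent = c(50, 50.0001, 0.2, 0, 100))
  expect_equal(label_library(rec, 50), c(0L, 1L, 0L, 0L, 1L))
  expect_equal(label_library(rec, 0), c(1L, 1L, 1L, 0L, 1L))
  expect_equal(label_library(rec, 100), rep(0L, 5))
  rec$fractured[2] <- TRUE
  expect_error(label_library(rec, 50),
               class = "dmnimpact_contract_violation")
})

test_that("forward selection finds the informative feature first", {
  set.seed(21)
  n <- 200
  x1 <- rnorm(n)
  y <- as.integer(x1 > 0)
  feats <- tibble::tibble(x1 = x1,
                          n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                          n4 = rnorm(n), n5 = rnorm(n))
  sel <- forward_feature_selection(feats, y, seed = 1)
  expect_equal(sel[1], "x1")

  # constant feature is never selected
  feats$const <- 1
  sel2 <- forward_feature_selection(feats, y, seed = 1)
  expect_false("const" %in% sel2)

  # duplicated informative feature: the earlier-declared copy wins
  feats3 <- tibble::tibble(a_copy = x1, b_copy = x1, noise = rnorm(n))
  sel3 <- forward_feature_selection(feats3, y, seed = 1)
  expect_true("a_copy" %in% sel3)
  expect_false("b_copy" %in% sel3)

  expect_error(forward_feature_selection(feats, rep(1L, n)))
})

test_that("ensemble probability is the mean of five member probabilities", {
  set.seed(22)
  n <- 120
  X <- tibble::tibble(x = rnorm(n), z = rnorm(n))
  y <- as.integer(X$x + 0.5 * X$z + rnorm(n, 0, 0.3) > 0)
  ens <- train_bagging_ensemble(X, y, c("x", "z"), seed = 0)
  P <- predict(ens, X, type = "members")
  expect_equal(ncol(P), 5)
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(predict(ens, X), rowMeans(P), tolerance = 1e-12)
})

test_that("ensemble separates a linearly separable set and is deterministic", {
  set.seed(23)
  n <- 200
  # wide class gap so separation survives the nuisance dimension
  X <- tibble::tibble(x = c(rnorm(n / 2, -5), rnorm(n / 2, 5)),
                      z = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  ens <- train_bagging_ensemble(X, y, c("x", "z"), seed = 0)
  expect_equal(auc_rank(predict(ens, X), y), 1.0)
  ens2 <- train_bagging_ensemble(X, y, c("x", "z"), seed = 0)
  expect_identical(predict(ens, X), predict(ens2, X))
  expect_error(train_bagging_ensemble(dplyr::mutate(X, x = 1), y, c("x", "z")),
               class = "dmnimpact_degenerate_feature")
  expect_error(train_bagging_ensemble(X, y, character(0)))
})

test_that("rank AUC matches pROC and is monotone-transform invariant", {
  set.seed(24)
  p <- runif(150)
  y <- rbinom(150, 1, p)
  expect_equal(auc_rank(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
               tolerance = 1e-12)
  expect_equal(auc_rank(qlogis(p), y), auc_rank(p, y), tolerance = 1e-12)
  expect_equal(auc_rank(p^3, y), auc_rank(p, y), tolerance = 1e-12)
})

test_that("leave-one-out evaluation reaches the perfect-information limit", {
  set.seed(25)
  n <- 80
  x <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  feats <- tibble::tibble(x = x, z = rnorm(n))
  y <- as.integer(x > 0)
  ev <- evaluate_loo(feats, y, method = "bagging", seed = 0)
  expect_equal(ev$metrics$auc, 1.0)
  expect_gt(ev$metrics$accuracy, 0.97)
})

test_that("leave-one-out AUC is near chance for permuted labels", {
  set.seed(26)
  n <- 200
  feats <- tibble::tibble(x = rnorm(n), z = rnorm(n))
  y <- sample(rep(c(0L, 1L), each = n / 2))
  ev <- evaluate_loo(feats, y, method = "logistic", selected = c("x", "z"),
                     seed = 0)
  expect_gt(ev$metrics$auc, 0.4)
  expect_lt(ev$metrics$auc, 0.6)
  expect_equal(ev$metrics$dataset_balance, 0.5)
})

test_that("dataset balance reports the positive fraction", {
  set.seed(27)
  n <- 200
  feats <- tibble::tibble(x = rnorm(n), z = rnorm(n))
  y <- c(rep(1L, 30), rep(0L, 170))
  feats$x <- feats$x + 3 * y
  ev <- evaluate_loo(feats, y, method = "logistic", selected = "x", seed = 0)
  expect_equal(ev$metrics$dataset_balance, 0.15)
})

test_that("tidy and glance summarise fitted objects", {
  set.seed(28)
  X <- tibble::tibble(x = rnorm(60), z = rnorm(60))
  y <- as.integer(X$x > 0)
  ens <- train_bagging_ensemble(X, y, c("x", "z"), damage_threshold = 50,
                                seed = 0)
  td <- tidy(ens)
  expect_equal(td$feature, c("x", "z"))
  expect_equal(glance(ens)$damage_threshold, 50)
  ev <- evaluate_loo(X, y, method = "logistic", selected = "x", seed = 0)
  expect_setequal(tidy(ev)$metric,
                  c("auc", "brier", "sensitivity", "specificity", "accuracy",
                    "dataset_balance"))
  expect_equal(glance(ev)$method, "logistic")
})
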