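test_that("nrmse follows RMSE/mean with the stated edge behavior", {
  expect_equal(nrmse(c(2, 2), c(2, 2)), 0)
  expect_equal(nrmse(c(1, 3), c(2, 2)), 0.5)  # RMSE 1 over mean 2
  expect_error(nrmse(c(0, 0), c(1, 1)), "not positive")
  expect_error(nrmse(c(-2, -2), c(1, 1)), "not positive")
  expect_warning(v <- nrmse(c(-2, -2), c(-2, -2),
                            allow_nonpositive_mean = TRUE), "nonpositive")
  expect_equal(v, 0)
  expect_error(nrmse(1:3, 1:2), "equal")
})

test_that("maape follows the arctan formula with zero-observation conventions", {
  expect_equal(maape(c(3, 5), c(3, 5)), 0)
  expect_equal(maape(1, 2), pi / 4)
  expect_equal(maape(0, 5), pi / 2)
  expect_equal(maape(0, 0), 0)
  set.seed(1)
  y <- rnorm(50, 10)
  expect_gte(maape(y, rnorm(50, 10)), 0)
  expect_lte(maape(y, rnorm(50, 1e6)), pi / 2)
})

test_that("metrics match naive per-element loop oracles on random vectors", {
  loop_nrmse <- function(y, p) {
    s <- 0
    for (i in seq_along(y)) s <- s + (y[i] - p[i])^2
    sqrt(s / length(y)) / (sum(y) / length(y))
  }
  loop_maape <- function(y, p) {
    s <- 0
    for (i in seq_along(y)) s <- s + atan(abs((y[i] - p[i]) / y[i]))
    s / length(y)
  }
  set.seed(42)
  for (rep in 1:20) {
    y <- runif(30, 1, 100)
    p <- y + rnorm(30, 0, 10)
    expect_equal(nrmse(y, p), loop_nrmse(y, p), tolerance = 1e-12)
    expect_equal(maape(y, p), loop_maape(y, p), tolerance = 1e-12)
    # joint permutation invariance
    perm <- sample(30)
    expect_equal(nrmse(y[perm], p[perm]), nrmse(y, p), tolerance = 1e-12)
    expect_equal(maape(y[perm], p[perm]), maape(y, p), tolerance = 1e-12)
  }
})

test_that("top_quantile_subset uses the inclusive 80th-percentile rule", {
  t <- trait_vector(1:10, paste0("L", sprintf("%02d", 1:10)))
  ids <- top_quantile_subset(t, 0.2)
  expect_true(all(c("L09", "L10") %in% ids))
  expect_true(all(as.numeric(t[ids]) >= 8))
  tie <- trait_vector(rep(4, 6), paste0("L", 1:6))
  expect_setequal(top_quantile_subset(tie, 0.2), names(tie))
  one <- trait_vector(3, "L1")
  expect_identical(top_quantile_subset(one, 0.2), "L1")
})

test_that("make_folds produces seeded 80/20 line partitions", {
  ids <- paste0("L", 1:100)
  folds <- make_folds(ids, 10, 0.2, seed = 5)
  expect_length(folds, 10)
  for (f in folds) {
    expect_length(f$test_ids, 20)
    expect_length(f$train_ids, 80)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_setequal(c(f$train_ids, f$test_ids), ids)
  }
  expect_identical(folds, make_folds(ids, 10, 0.2, seed = 5))
  expect_false(identical(folds[[1]]$test_ids, folds[[2]]$test_ids))
  expect_length(make_folds(paste0("L", 1:5), 3, 0.2, 1)[[1]]$test_ids, 1)
  expect_error(make_folds(paste0("L", 1:3), 2, 0.01, 1), "empty")
})

test_that("relative_gain is the signed percent difference", {
  expect_equal(relative_gain(2.084, 1.0), 108.4)
  expect_equal(relative_gain(1, 1), 0)
  expect_equal(relative_gain(0.5, 1), -50)
  expect_error(relative_gain(1, 0), "positive")
})

test_that("run_experiment emits 2 records per fold and is reproducible", {
  fx <- fixture_dataset(seed = 43)
  folds <- make_folds(rownames(fx$markers), 3, 0.2, seed = 7)
  rec <- run_experiment(fx$markers, fx$trait, mixup_config(), folds)
  expect_equal(nrow(rec), 6)
  expect_setequal(rec$method, c("C", "A"))
  expect_true(all(rec$nrmse >= 0))
  expect_true(all(rec$maape >= 0 & rec$maape <= pi / 2))
  expect_true(all(rec$maape_80 <= pi / 2))
  rec2 <- run_experiment(fx$markers, fx$trait, mixup_config(), folds)
  expect_identical(rec, rec2)
})

test_that("degenerate mixup configs still yield finite metrics", {
  fx <- fixture_dataset(seed = 47)
  folds <- make_folds(rownames(fx$markers), 2, 0.2, seed = 3)
  cfg <- mixup_config(lam = 1, top_fraction = 1)
  rec <- run_experiment(fx$markers, fx$trait, cfg, folds)
  expect_true(all(is.finite(rec$nrmse)))
  expect_true(all(is.finite(rec$maape_80)))
})

test_that("summarize_metrics averages folds, adds AT rows and gains", {
  rec <- data.frame(method = "C", trait = "GY", fold = 1:2,
                    nrmse = c(0.2, 0.4), maape = c(0.1, 0.3),
                    nrmse_80 = c(0.2, 0.2), maape_80 = c(0.1, 0.1))
  s <- summarize_metrics(rec)
  expect_equal(s$C_nrmse[s$trait == "GY"], 0.3)
  expect_false(any(grepl("gain", names(s))))  # one method: no gain columns

  rec2 <- rbind(
    data.frame(method = "C", trait = "GY", fold = 1, nrmse = 0.3,
               maape = 0.2, nrmse_80 = 0.4, maape_80 = 0.3),
    data.frame(method = "C", trait = "PH", fold = 1, nrmse = 0.5,
               maape = 0.4, nrmse_80 = 0.6, maape_80 = 0.5),
    data.frame(method = "A", trait = "GY", fold = 1, nrmse = 0.6,
               maape = 0.4, nrmse_80 = 0.2, maape_80 = 0.15),
    data.frame(method = "A", trait = "PH", fold = 1, nrmse = 1.0,
               maape = 0.8, nrmse_80 = 0.3, maape_80 = 0.25))
  s2 <- summarize_metrics(rec2)
  at <- s2[s2$trait == "AT", ]
  expect_equal(at$C_nrmse, 0.4)  # mean of 0.3 and 0.5
  expect_equal(at$A_nrmse, 0.8)
  expect_equal(at$gain_nrmse, 100)  # worse A exceeds better C by 100%
  expect_identical(at$better_nrmse, "C")
  expect_equal(s2$gain_nrmse_80[s2$trait == "GY"], 100)
  expect_identical(s2$better_nrmse_80[s2$trait == "GY"], "A")
})
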