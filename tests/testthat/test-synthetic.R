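test_that("default benchmark has the canonical shape", {
  bench <- generate_benchmark(benchmark_config(), seed = 1)
  expect_identical(dim(bench$train$values), c(300L, 4000L))
  expect_identical(dim(bench$test$values), c(1000L, 4000L))
  expect_identical(as.integer(table(bench$train$labels)), c(150L, 150L))
  expect_identical(as.integer(table(bench$test$labels)), c(500L, 500L))
  expect_length(bench$truth$informative, 20L)
  expect_true(all(bench$truth$informative %in% seq_len(4000L)))
})

test_that("same seed gives a bit-identical benchmark, different seed does not", {
  cfg <- benchmark_config(n_features = 200, n_train_per_class = 30,
                          n_test_per_class = 30)
  b1 <- generate_benchmark(cfg, seed = 42)
  b2 <- generate_benchmark(cfg, seed = 42)
  expect_identical(b1$train$values, b2$train$values)
  expect_identical(b1$test$values, b2$test$values)
  expect_identical(b1$truth$informative, b2$truth$informative)
  b3 <- generate_benchmark(cfg, seed = 43)
  expect_false(identical(b1$train$values, b3$train$values))
})

test_that("non-informative features are class-null; informative ones discriminate", {
  cfg <- benchmark_config(n_features = 1000, n_train_per_class = 150,
                          n_test_per_class = 10)
  bench <- generate_benchmark(cfg, seed = 3)
  y <- bench$train$labels
  null_idx <- setdiff(seq_len(1000), bench$truth$informative)
  pvals <- vapply(null_idx, function(j) {
    t.test(bench$train$values[y == 0, j], bench$train$values[y == 1, j])$p.value
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / length(null_idx)))

  aucs <- vapply(bench$truth$informative, function(j) {
    auc(bench$train$values[, j], y)
  }, numeric(1))
  expect_true(all(aucs > 0.6))  # effect size 1 sd => theoretical AUC ~ 0.76
})

test_that("zero confounder shift leaves the side study and test set unshifted", {
  cfg <- benchmark_config(n_features = 100, n_train_per_class = 20,
                          n_test_per_class = 20, shift_mu_sd = 0,
                          shift_sigma_range = c(0, 0))
  bench <- generate_benchmark(cfg, seed = 5)
  expect_equal(unname(bench$truth$true_shift$mu), rep(0, 100))
  expect_equal(unname(bench$truth$true_shift$sigma2), rep(0, 100))
  side <- generate_side_study(bench$truth, cfg, n_subjects = 10, seed = 6)
  expect_equal(side$a$values, side$b$values)
})

test_that("side study is drawn from the class-0 distribution and recovers the truth", {
  cfg <- benchmark_config(n_features = 20, n_informative = 5,
                          n_train_per_class = 10, n_test_per_class = 10)
  bench <- generate_benchmark(cfg, seed = 8)
  side <- generate_side_study(bench$truth, cfg, n_subjects = 1e5, seed = 9)
  # base measurement centres on the class-0 means, informative features included
  expect_equal(unname(colMeans(side$a$values)),
               unname(bench$truth$feature_mean), tolerance = 0.03)
  nm <- estimate_noise_paired(side)
  expect_equal(unname(nm$mu), unname(bench$truth$true_shift$mu), tolerance = 0.02)
  expect_equal(unname(sqrt(nm$sigma2)), unname(sqrt(bench$truth$true_shift$sigma2)),
               tolerance = 0.02)

  small <- generate_side_study(bench$truth, cfg, n_subjects = 30, seed = 10)
  nm30 <- estimate_noise_paired(small)
  expect_true(all(nm30$sigma2[bench$truth$true_shift$sigma2 > 0] > 0))
  expect_error(generate_side_study(bench$truth, cfg, n_subjects = 1), ">= 2")
})

test_that("skew-normal family with zero shape equals the normal family", {
  cfg_n <- benchmark_config(n_features = 150, n_train_per_class = 20,
                            n_test_per_class = 20, noise_family = "normal")
  cfg_s <- benchmark_config(n_features = 150, n_train_per_class = 20,
                            n_test_per_class = 20, noise_family = "skew_normal",
                            skew_alpha = 0)
  expect_identical(generate_benchmark(cfg_n, seed = 2)$test$values,
                   generate_benchmark(cfg_s, seed = 2)$test$values)
})

test_that("skewed shifts keep the requested mean/sd but gain asymmetry", {
  cfg <- benchmark_config(n_features = 20000, n_train_per_class = 2,
                          n_test_per_class = 2, noise_family = "skew_normal",
                          skew_alpha = 8, shift_mu_sd = 1.5)
  delta <- generate_benchmark(cfg, seed = 4)$truth$true_shift$mu
  expect_equal(mean(delta), 0, tolerance = 0.04)
  expect_equal(sd(delta), 1.5, tolerance = 0.04)
  skew <- mean((delta - mean(delta))^3) / sd(delta)^3
  expect_gt(skew, 0.5)  # alpha = 8 gives skewness ~ 0.9
})

test_that("benchmark_config validates its fields", {
  expect_error(benchmark_config(n_informative = 50, n_features = 20), "<=")
  expect_error(benchmark_config(feature_sd_range = c(0, 1)), "positive")
  expect_error(benchmark_config(shift_mu_sd = -1), "non-negative")
  expect_error(benchmark_config(effect_size = 0), "positive")
  expect_error(benchmark_config(feature_mean_range = c(2, 1)), "increasing")
})
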