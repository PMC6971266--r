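test_that("auc matches enumeration on toy cases and pROC on random data", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.6, 0.4, 0.7, 0.2), c(1, 0, 0, 1)), 0.25)
  expect_equal(auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")

  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:3) {
    s <- round(rnorm(40), 1)  # rounding forces ties
    y <- rbinom(40, 1, 0.5)
    expect_equal(auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("bootstrap CI brackets the mean and degenerates on constants", {
  expect_equal(unname(bootstrap_ci(rep(3, 10), seed = 1)), c(3, 3))
  set.seed(2)
  for (i in 1:5) {
    v <- rnorm(30)
    ci <- bootstrap_ci(v, n_boot = 500, seed = i)
    expect_lte(ci["lo"], mean(v))
    expect_gte(ci["hi"], mean(v))
  }
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("bootstrap CI of a Normal(0,1) mean covers zero at roughly 95%", {
  set.seed(8)
  covered <- vapply(1:300, function(i) {
    v <- rnorm(50)
    ci <- bootstrap_ci(v, n_boot = 400, seed = i)
    ci["lo"] <= 0 && 0 <= ci["hi"]
  }, logical(1))
  expect_gt(mean(covered), 0.88)  # percentile bootstrap undercovers slightly
  expect_lte(mean(covered), 1)
})

fake_result <- function(ranking) {
  structure(list(failed = FALSE,
                 importance = stats::setNames(seq(1, 0, length.out = length(ranking)),
                                              ranking)),
            class = "strategy_result")
}

test_that("importance_overlap counts informative features in the ranking head", {
  cfg <- benchmark_config(n_features = 50, n_informative = 20,
                          n_train_per_class = 5, n_test_per_class = 5)
  truth <- generate_benchmark(cfg, seed = 1)$truth
  inf_names <- names(truth$feature_mean)[truth$informative]
  other <- setdiff(names(truth$feature_mean), inf_names)

  res <- importance_overlap(fake_result(c(inf_names, other)), truth, top_k = 20)
  expect_identical(res$n_meaningful_in_top_k, 20L)
  expect_identical(res$prefix_meaningful, 20L)

  res0 <- importance_overlap(fake_result(c(other, inf_names)), truth, top_k = 20)
  expect_identical(res0$n_meaningful_in_top_k, 0L)
  expect_identical(res0$prefix_meaningful, 0L)

  mixed <- c(inf_names[1:2], other[1], inf_names[3:20], other[-1])
  resm <- importance_overlap(fake_result(mixed), truth, top_k = 20)
  expect_identical(resm$n_meaningful_in_top_k, 19L)
  expect_identical(resm$prefix_meaningful, 2L)

  expect_error(importance_overlap(fake_result(mixed), truth, top_k = 100),
               "top_k")
})

test_that("run_strategy is deterministic given a seed, for every learner", {
  bb <- tiny_bundle(seed = 2)
  lasso <- classifier_spec("lasso_logistic")
  for (clf in list(tiny_rf(), tiny_gbm(), lasso)) {
    r1 <- run_strategy(bb$bundle, strategy_spec("proposed"), clf, seed = 5)
    r2 <- run_strategy(bb$bundle, strategy_spec("proposed"), clf, seed = 5)
    expect_false(r1$failed)
    expect_equal(r1$cv_auc, r2$cv_auc)
    expect_equal(r1$test_aucs, r2$test_aucs)
    expect_equal(r1$importance, r2$importance)
    expect_true(r1$cv_auc >= 0 && r1$cv_auc <= 1)
    expect_true(all(r1$test_aucs >= 0 & r1$test_aucs <= 1))
    expect_equal(r1$aee, abs(r1$cv_auc - min(r1$test_aucs)))
  }
})

test_that("filtering decisions come from the side study alone", {
  bb <- tiny_bundle(seed = 3)
  r1 <- run_strategy(bb$bundle, strategy_spec("filtering"), tiny_rf(), seed = 7)
  # perturbing the test groups must not change the kept set or the CV estimate
  tweaked <- bb$bundle
  tweaked$test_groups[[1]]$values <- tweaked$test_groups[[1]]$values + 100
  r2 <- run_strategy(tweaked, strategy_spec("filtering"), tiny_rf(), seed = 7)
  expect_identical(r1$kept_features, r2$kept_features)
  expect_equal(r1$cv_auc, r2$cv_auc)
  expect_lt(length(r1$kept_features), ncol(bb$bundle$main$values))
})

test_that("oracle strategy uses the confounder-bearing pool and needs it", {
  bb <- tiny_bundle(seed = 4)
  r <- run_strategy(bb$bundle, strategy_spec("oracle"), tiny_rf(), seed = 1)
  expect_false(r$failed)
  no_oracle <- bb$bundle
  no_oracle$oracle_extra <- NULL
  r2 <- run_strategy(no_oracle, strategy_spec("oracle"), tiny_rf(), seed = 1)
  expect_true(r2$failed)
  expect_match(r2$message, "oracle_extra")
})

test_that("a filter that removes every feature yields a failed row, not an abort", {
  bb <- tiny_bundle(seed = 5)
  # side study with huge constant offsets: every CCC ~ 0
  side <- bb$bundle$side
  side$b$values <- side$b$values + 1000
  broken <- study_bundle(side, bb$bundle$main, bb$bundle$test_groups,
                         oracle_extra = bb$bundle$oracle_extra)
  r <- run_strategy(broken, strategy_spec("filtering"), tiny_rf(), seed = 1)
  expect_true(r$failed)
  expect_match(r$message, "all features removed")

  exp <- run_experiment(broken,
                        list(strategy_spec("filtering"), strategy_spec("simple")),
                        list(tiny_rf()), n_repeats = 1, base_seed = 1)
  expect_identical(nrow(exp$results), 2L)
  expect_identical(exp$results$failed, c(TRUE, FALSE))
})

test_that("combined strategy filters first, then augments the survivors", {
  bb <- tiny_bundle(seed = 6)
  r <- run_strategy(bb$bundle, strategy_spec("combined"), tiny_rf(), seed = 2)
  expect_false(r$failed)
  rf_filter <- run_strategy(bb$bundle, strategy_spec("filtering"), tiny_rf(), seed = 2)
  expect_identical(r$n_features_used, rf_filter$n_features_used)
  expect_identical(r$kept_features, rf_filter$kept_features)
})

test_that("run_experiment shape, determinism and summary", {
  cfg <- benchmark_config(n_features = 80, n_informative = 8,
                          n_train_per_class = 25, n_test_per_class = 25)
  strategies <- list(strategy_spec("simple"), strategy_spec("proposed"))
  e1 <- run_experiment(cfg, strategies, list(tiny_rf()), n_repeats = 3,
                       base_seed = 19)
  expect_identical(nrow(e1$results), 6L)
  expect_identical(sort(unique(e1$results$strategy)), c("proposed", "simple"))
  e2 <- run_experiment(cfg, strategies, list(tiny_rf()), n_repeats = 3,
                       base_seed = 19)
  expect_identical(e1$results, e2$results)
  expect_identical(nrow(e1$summary), 2L)
  expect_true(all(e1$summary$aee_ci_lo <= e1$summary$mean_aee &
                    e1$summary$mean_aee <= e1$summary$aee_ci_hi))
})

test_that("smote-flagged strategies match the augmented training size", {
  bb <- tiny_bundle(seed = 7)
  r <- run_strategy(bb$bundle, strategy_spec("filtering", smote = TRUE),
                    tiny_rf(), seed = 3)
  expect_false(r$failed)
  expect_equal(r$strategy, "filtering+smote")
})
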