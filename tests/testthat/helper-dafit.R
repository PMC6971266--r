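# Fixture builders shared across test files. Everything is generated in code;
# no data files.

random_table <- function(m = 10, n = 4, seed = 1, labels = FALSE,
                         confounder = FALSE) {
  set.seed(seed)
  feature_table(matrix(rnorm(m * n), m, n),
                feature_names = paste0("feat_", seq_len(n)),
                labels = if (labels) rep_len(c(0L, 1L), m),
                confounder = if (confounder) rep_len(c("x", "y"), m))
}

# A labelled two-class table with `n_inf` shifted informative features.
classed_table <- function(m_per_class = 40, n = 150, n_inf = 10,
                          effect = 1.5, seed = 1) {
  set.seed(seed)
  v0 <- matrix(rnorm(m_per_class * n), m_per_class, n)
  v1 <- matrix(rnorm(m_per_class * n), m_per_class, n)
  v1[, seq_len(n_inf)] <- v1[, seq_len(n_inf)] + effect
  feature_table(rbind(v0, v1), feature_names = sprintf("f%03d", seq_len(n)),
                labels = rep(c(0L, 1L), each = m_per_class))
}

# Small single-combination classifier specs so unit tests skip inner tuning.
tiny_rf <- function(trees = 100L) {
  classifier_spec("random_forest",
                  tuning_grid = data.frame(num.trees = trees, mtry_rule = "sqrt",
                                           min.node.size = 5L,
                                           stringsAsFactors = FALSE))
}

tiny_gbm <- function(rounds = 50L) {
  classifier_spec("gradient_boosting",
                  tuning_grid = data.frame(nrounds = rounds, eta = 0.1,
                                           max_depth = 2L,
                                           stringsAsFactors = FALSE))
}

# A small synthetic study bundle for harness tests.
tiny_bundle <- function(seed = 1, n_features = 150, m = 40, n_test = 60,
                        shift_mu_sd = 1, ...) {
  cfg <- benchmark_config(n_features = n_features, n_informative = 10,
                          n_train_per_class = m, n_test_per_class = n_test,
                          shift_mu_sd = shift_mu_sd, ...)
  make_benchmark_bundle(cfg, seed = seed, n_side_subjects = 25)
}
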