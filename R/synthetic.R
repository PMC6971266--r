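#' Configuration of the synthetic benchmark generator
#'
#' Describes a two-class benchmark mimicking a typical radiomics study: a
#' modest training cohort, a large independent test cohort measured under a
#' different confounder value, thousands of Gaussian features of which only a
#' handful are class-informative.
#'
#' Per feature j, a base mean is drawn uniformly from `feature_mean_range`
#' and a base standard deviation from `feature_sd_range`. Class 0 values are
#' `Normal(m_j, s_j^2)`; for the `n_informative` randomly chosen informative
#' features the class-1 mean is `m_j + effect_size * s_j` (so the effect size
#' is expressed in units of the feature's own spread), otherwise the classes
#' are identically distributed.
#'
#' The confounder shift applied to the test set has a systematic per-feature
#' component `delta_j` (drawn once per feature with standard deviation
#' `shift_mu_sd`) plus per-observation noise with a per-feature standard
#' deviation drawn uniformly from `shift_sigma_range`. With
#' `noise_family = "skew_normal"` both components are drawn from a centred
#' skew-normal with shape `skew_alpha` (zero mean, same standard deviation),
#' which stress-tests the Gaussian assumption of the augmentation transform;
#' `skew_alpha = 0` recovers the normal family.
#'
#' @param n_features Number of features (default 4000).
#' @param n_informative Number of class-informative features (default 20).
#' @param n_train_per_class Training observations per class (default 150).
#' @param n_test_per_class Test observations per class (default 500).
#' @param feature_mean_range,feature_sd_range Ranges of the per-feature base
#'   mean and standard deviation.
#' @param effect_size Class-1 mean shift of informative features, in units of
#'   the feature sd (default 1).
#' @param shift_mu_sd Standard deviation of the systematic per-feature
#'   confounder shift (default 1).
#' @param shift_sigma_range Range for the per-feature sd of the
#'   per-observation shift noise (default \[0, 1\]).
#' @param noise_family `"normal"` or `"skew_normal"`.
#' @param skew_alpha Shape parameter of the skew-normal family (default 0).
#' @param seed Optional default seed used by [generate_benchmark()] when none
#'   is passed there.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_features = 4000L, n_informative = 20L,
                             n_train_per_class = 150L, n_test_per_class = 500L,
                             feature_mean_range = c(-1, 1),
                             feature_sd_range = c(0.5, 2),
                             effect_size = 1,
                             shift_mu_sd = 1,
                             shift_sigma_range = c(0, 1),
                             noise_family = c("normal", "skew_normal"),
                             skew_alpha = 0,
                             seed = NULL) {
  noise_family <- match.arg(noise_family)
  cfg <- list(n_features = as.integer(n_features),
              n_informative = as.integer(n_informative),
              n_train_per_class = as.integer(n_train_per_class),
              n_test_per_class = as.integer(n_test_per_class),
              feature_mean_range = as.numeric(feature_mean_range),
              feature_sd_range = as.numeric(feature_sd_range),
              effect_size = as.numeric(effect_size),
              shift_mu_sd = as.numeric(shift_mu_sd),
              shift_sigma_range = as.numeric(shift_sigma_range),
              noise_family = noise_family,
              skew_alpha = as.numeric(skew_alpha),
              seed = seed)
  if (cfg$n_informative > cfg$n_features) stop("n_informative must be <= n_features")
  if (cfg$n_features < 1L || cfg$n_train_per_class < 1L || cfg$n_test_per_class < 1L) {
    stop("feature and observation counts must be positive")
  }
  bad_range <- function(r) length(r) != 2L || r[1L] > r[2L]
  if (bad_range(cfg$feature_mean_range) || bad_range(cfg$feature_sd_range) ||
      bad_range(cfg$shift_sigma_range)) {
    stop("ranges must be length-2 increasing intervals")
  }
  if (cfg$feature_sd_range[1L] <= 0) stop("feature_sd_range must be positive")
  if (cfg$shift_mu_sd < 0 || any(cfg$shift_sigma_range < 0)) {
    stop("shift scales must be non-negative")
  }
  if (cfg$effect_size <= 0) stop("effect_size must be positive")
  structure(cfg, class = "benchmark_config")
}

# Centred skew-normal draws: zero mean, standard deviation `sd`, shape
# `alpha`. Uses the half-normal representation
#   X = delta |Z0| + sqrt(1 - delta^2) Z1,  delta = alpha / sqrt(1 + alpha^2),
# rescaled so that E[X] = 0 and Var[X] = sd^2. alpha = 0 is exactly N(0, sd^2)
# in distribution.
rnorm_family <- function(n, sd, family, alpha) {
  if (family == "normal" || alpha == 0) return(stats::rnorm(n, 0, sd))
  delta <- alpha / sqrt(1 + alpha^2)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  raw <- delta * z0 + sqrt(1 - delta^2) * z1
  omega <- sd / sqrt(1 - 2 * delta^2 / pi)     # scale giving Var = sd^2
  omega * (raw - delta * sqrt(2 / pi))          # centre to zero mean
}

# Draw an (m x n) matrix with per-feature means mu (length n) and sds s.
draw_class_matrix <- function(m, mu, s) {
  n <- length(mu)
  matrix(stats::rnorm(m * n, mean = rep(mu, each = m), sd = rep(s, each = m)),
         nrow = m, ncol = n)
}

# Apply the confounder shift of `truth` to a value matrix: systematic delta_j
# plus per-observation noise of sd sigma_j, drawn from the configured family.
apply_confounder_shift <- function(values, truth, family, alpha) {
  m <- nrow(values); n <- ncol(values)
  delta <- truth$true_shift$mu
  sig <- sqrt(truth$true_shift$sigma2)
  eps <- matrix(rnorm_family(m * n, sd = rep(sig, each = m),
                             family = family, alpha = alpha),
                nrow = m, ncol = n)
  values + rep(delta, each = m) + eps
}

#' Generate the synthetic benchmark
#'
#' Draws a training table (both classes, no confounder shift), a test table
#' (both classes, every feature shifted by the confounder effect), and the
#' ground truth: the indices of the informative features and the true
#' per-feature shift parameters as a `"known"` [noise_model()]. Fully
#' deterministic given the seed.
#'
#' @param cfg A [benchmark_config()].
#' @param seed Integer seed (falls back to `cfg$seed`).
#' @return List with elements `train`, `test` (labelled [feature_table()]s)
#'   and `truth` (class `benchmark_truth`: `informative`, `true_shift`, and
#'   the base `feature_mean` / `feature_sd` used to draw observations).
#' @export
generate_benchmark <- function(cfg = benchmark_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "benchmark_config"))
  if (is.null(seed)) stop("generate_benchmark needs a seed (argument or cfg$seed)")
  with_seed(seed, {
    n <- cfg$n_features
    fnames <- sprintf("f%04d", seq_len(n))
    base_mean <- stats::runif(n, cfg$feature_mean_range[1L], cfg$feature_mean_range[2L])
    base_sd <- stats::runif(n, cfg$feature_sd_range[1L], cfg$feature_sd_range[2L])
    informative <- sort(sample.int(n, cfg$n_informative))
    mean1 <- base_mean
    mean1[informative] <- mean1[informative] + cfg$effect_size * base_sd[informative]

    delta <- rnorm_family(n, cfg$shift_mu_sd, cfg$noise_family, cfg$skew_alpha)
    shift_sigma <- stats::runif(n, cfg$shift_sigma_range[1L], cfg$shift_sigma_range[2L])
    truth <- structure(list(
      informative = informative,
      true_shift = noise_model(delta, shift_sigma^2, "known", feature_names = fnames),
      feature_mean = stats::setNames(base_mean, fnames),
      feature_sd = stats::setNames(base_sd, fnames)),
      class = "benchmark_truth")

    mtr <- cfg$n_train_per_class
    train_values <- rbind(draw_class_matrix(mtr, base_mean, base_sd),
                          draw_class_matrix(mtr, mean1, base_sd))
    train <- feature_table(train_values, feature_names = fnames,
                           labels = rep(c(0L, 1L), each = mtr))

    mte <- cfg$n_test_per_class
    test_values <- rbind(draw_class_matrix(mte, base_mean, base_sd),
                         draw_class_matrix(mte, mean1, base_sd))
    test_values <- apply_confounder_shift(test_values, truth,
                                          cfg$noise_family, cfg$skew_alpha)
    test <- feature_table(test_values, feature_names = fnames,
                          labels = rep(c(0L, 1L), each = mte))
    list(train = train, test = test, truth = truth)
  })
}

#' Generate a paired side study matching a benchmark's ground truth
#'
#' Simulates a scan-rescan side experiment: `n_subjects` base observations
#' are drawn from the class-0 training distribution (a side study carries no
#' target information); measurement `a` is the base value and measurement `b`
#' adds the true per-feature confounder shift (systematic component plus
#' per-observation noise). Estimating a noise model on this study therefore
#' recovers `truth$true_shift` up to sampling error.
#'
#' @param truth The `truth` element of [generate_benchmark()].
#' @param cfg The matching [benchmark_config()] (supplies the noise family).
#' @param n_subjects Number of paired subjects, >= 2 (side studies are
#'   typically small; 30 is a common scale).
#' @param seed Integer seed.
#' @return A paired [side_study()] without labels.
#' @export
generate_side_study <- function(truth, cfg, n_subjects = 30L, seed = NULL) {
  stopifnot(inherits(truth, "benchmark_truth"), inherits(cfg, "benchmark_config"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  with_seed(seed, {
    base <- draw_class_matrix(n_subjects, truth$feature_mean, truth$feature_sd)
    shifted <- apply_confounder_shift(base, truth, cfg$noise_family, cfg$skew_alpha)
    fnames <- names(truth$feature_mean)
    side_study(feature_table(base, feature_names = fnames),
               feature_table(shifted, feature_names = fnames),
               mode = "paired")
  })
}

#' Assemble a full study bundle from the synthetic benchmark
#'
#' Convenience wrapper reproducing the split design of a confounder-aware
#' study on synthetic data: split A is a paired side study, group B1 the
#' unshifted training table, the single test group C1 the confounder-shifted
#' test table, and (optionally) an oracle extension of split B — a second
#' training draw with the confounder shift applied, so that the oracle
#' strategy's training pool itself contains the confounder variation.
#'
#' @param cfg A [benchmark_config()].
#' @param seed Integer seed driving every draw.
#' @param n_side_subjects Paired subjects in the side study (default 30).
#' @param include_oracle Also generate the shifted `oracle_extra` table
#'   (default `TRUE`).
#' @return List with `bundle` (a [study_bundle()]) and `truth`.
#' @export
make_benchmark_bundle <- function(cfg = benchmark_config(), seed = cfg$seed,
                                  n_side_subjects = 30L, include_oracle = TRUE) {
  if (is.null(seed)) stop("make_benchmark_bundle needs a seed")
  with_seed(seed, {
    bench <- generate_benchmark(cfg, seed = draw_seed())
    side <- generate_side_study(bench$truth, cfg, n_subjects = n_side_subjects,
                                seed = draw_seed())
    oracle_extra <- NULL
    if (include_oracle) {
      oracle_seed <- draw_seed()
      oracle_extra <- with_seed(oracle_seed, {
        mtr <- cfg$n_train_per_class
        fnames <- names(bench$truth$feature_mean)
        mean1 <- bench$truth$feature_mean
        mean1[bench$truth$informative] <- mean1[bench$truth$informative] +
          cfg$effect_size * bench$truth$feature_sd[bench$truth$informative]
        vals <- rbind(draw_class_matrix(mtr, bench$truth$feature_mean, bench$truth$feature_sd),
                      draw_class_matrix(mtr, mean1, bench$truth$feature_sd))
        vals <- apply_confounder_shift(vals, bench$truth, cfg$noise_family, cfg$skew_alpha)
        feature_table(vals, feature_names = fnames,
                      labels = rep(c(0L, 1L), each = mtr))
      })
    }
    list(bundle = study_bundle(side, bench$train, list(bench$test),
                               oracle_extra = oracle_extra),
         truth = bench$truth)
  })
}
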