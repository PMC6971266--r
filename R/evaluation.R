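#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' observation receives a higher score than a randomly chosen negative one,
#' counting ties as one half.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param labels Binary 0/1 labels of the same length, both classes present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels must have equal length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values Numeric vector, length >= 2.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, n_boot = 2000L, level = 0.95, seed = NULL) {
  if (length(values) < 2L) stop("bootstrap_ci needs at least 2 values")
  stopifnot(level > 0, level < 1)
  means <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(sample(values, length(values), replace = TRUE)),
           numeric(1))
  })
  q <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(lo = q[1L], hi = q[2L])
}

#' Strategy specification
#'
#' The five ways of handling side-study information compared by the harness:
#' * `simple` — ignore the side study entirely; train on the main study.
#' * `oracle` — pool the main study with extra labelled data that itself
#'   contains the confounder variation (upper-bound reference, not an
#'   applicable method).
#' * `filtering` — remove unstable features (CCC filter for paired side
#'   studies, t-test filter for unpaired) before training.
#' * `proposed` — DAFIT: estimate the noise model from the side study and
#'   train on noise-augmented copies of the training rows.
#' * `combined` — filter first, then augment on the surviving features.
#'
#' Any strategy can additionally set `smote = TRUE`, which oversamples the
#' processed training rows with SMOTE so the row count matches what the DAFIT
#' augmentation would have produced (`augment$copies` times the originals) —
#' the sample-size control separating "more rows" from "more information".
#'
#' @param name Strategy name, see above.
#' @param filter_method `"ccc"` or `"ttest"`; required meaningfully only for
#'   `filtering`/`combined`, inferred from the side-study mode when `NULL`.
#' @param augment List of augmentation settings for `proposed`/`combined`:
#'   `copies` (default 2), `include_originals` (default `FALSE`),
#'   `symmetrize` (default `FALSE`, zeroes the transferred mean shift).
#' @param smote Add SMOTE oversampling (default `FALSE`).
#' @param tau_ccc,tau_test Filter thresholds, see [ccc_filter()] /
#'   [ttest_filter()].
#' @param noise Optional [noise_model()] overriding side-study estimation
#'   (e.g. a known generating model on synthetic data).
#' @return A `strategy_spec`.
#' @export
strategy_spec <- function(name = c("simple", "oracle", "filtering", "proposed", "combined"),
                          filter_method = NULL,
                          augment = list(copies = 2L, include_originals = FALSE,
                                         symmetrize = FALSE),
                          smote = FALSE, tau_ccc = 0.8, tau_test = 0.05,
                          noise = NULL) {
  name <- match.arg(name)
  if (!is.null(filter_method)) {
    filter_method <- match.arg(filter_method, c("ccc", "ttest"))
  }
  defaults <- list(copies = 2L, include_originals = FALSE, symmetrize = FALSE)
  augment <- utils::modifyList(defaults, as.list(augment))
  if (augment$copies < 1L) stop("augment$copies must be >= 1")
  if (!is.null(noise) && !inherits(noise, "noise_model")) {
    stop("noise must be a noise_model")
  }
  structure(list(name = name, filter_method = filter_method, augment = augment,
                 smote = isTRUE(smote), tau_ccc = tau_ccc, tau_test = tau_test,
                 noise = noise),
            class = "strategy_spec")
}

strategy_label <- function(strategy) {
  paste0(strategy$name, if (strategy$smote) "+smote")
}

# Resolve the stable feature set (or NULL) and noise model (or NULL) a
# strategy needs, from the bundle's side study only.
resolve_strategy_inputs <- function(bundle, strategy) {
  kept <- NULL
  noise <- NULL
  wants_filter <- strategy$name %in% c("filtering", "combined")
  wants_noise <- strategy$name %in% c("proposed", "combined")
  if (wants_filter) {
    method <- strategy$filter_method
    if (is.null(method)) method <- if (bundle$side$mode == "paired") "ccc" else "ttest"
    ss <- if (method == "ccc") ccc_filter(bundle$side, tau_ccc = strategy$tau_ccc)
          else ttest_filter(bundle$side, tau_test = strategy$tau_test)
    if (length(ss$kept) == 0L) stop("all features removed by the stability filter")
    kept <- ss$kept
  }
  if (wants_noise) {
    noise <- strategy$noise
    if (is.null(noise)) {
      noise <- if (bundle$side$mode == "paired") estimate_noise_paired(bundle$side)
               else estimate_noise_unpaired(bundle$side)
    }
    if (isTRUE(strategy$augment$symmetrize)) noise <- symmetrize_noise(noise)
    if (!is.null(kept)) {
      noise <- noise_model(noise$mu[kept], noise$sigma2[kept], noise$source_mode,
                           feature_names = names(noise$mu)[kept])
    }
  }
  list(kept = kept, noise = noise)
}

# Apply a strategy's training-data processing to a labelled feature table
# (already restricted to the kept features). Augmentation and SMOTE draw from
# the current RNG stream via sub-seeds.
process_training <- function(train_tab, strategy, noise) {
  out <- train_tab
  if (strategy$name %in% c("proposed", "combined")) {
    out <- dafit_augment(out, noise, copies = strategy$augment$copies,
                         include_originals = strategy$augment$include_originals,
                         seed = draw_seed())
  }
  if (strategy$smote) {
    counts <- table(train_tab$labels)
    extra <- (strategy$augment$copies - 1L) * as.integer(counts)
    out <- smote_oversample(out, stats::setNames(extra, names(counts)),
                            seed = draw_seed())
  }
  out
}

#' Run one strategy with one classifier on a study bundle
#'
#' The core benchmarking protocol. The training pool is the main study (plus
#' `oracle_extra` for the oracle strategy). An outer stratified K-fold
#' cross-validation estimates model performance: inside each fold the
#' strategy is applied to the fold-training rows only (filtering restricts
#' features using the side study; augmentation perturbs fold-training rows;
#' held-out rows are never augmented), hyperparameters are tuned by inner
#' stratified CV, and the fold model scores the untouched held-out rows. The
#' CV estimate is the mean fold AUC. The model is then refit on the whole
#' processed pool and evaluated on every confounder-shifted test group; the
#' absolute estimation error (AEE) is
#' `|cv_auc - min(test group AUCs)|` — how far the CV estimate is from the
#' worst performance actually realised under a confounder shift.
#'
#' A strategy that fails (e.g. the filter removes every feature) is returned
#' as a failed result (`failed = TRUE` with the error message) rather than an
#' exception, so that experiment sweeps keep running.
#'
#' @param bundle A [study_bundle()].
#' @param strategy A [strategy_spec()].
#' @param classifier A [classifier_spec()].
#' @param outer_folds Outer CV folds (default 5).
#' @param seed Integer seed; results are deterministic given it.
#' @return A `strategy_result`: `cv_auc`, `test_aucs`, `min_test_auc`, `aee`,
#'   `n_features_used`, `importance` (named, sorted decreasing), `params`
#'   (tuned hyperparameters of the final model), `failed`, `seed`.
#' @export
run_strategy <- function(bundle, strategy, classifier, outer_folds = 5L, seed = 1L) {
  stopifnot(inherits(bundle, "study_bundle"),
            inherits(strategy, "strategy_spec"),
            inherits(classifier, "classifier_spec"))
  res <- try(run_strategy_impl(bundle, strategy, classifier, outer_folds, seed),
             silent = TRUE)
  if (inherits(res, "try-error")) {
    return(structure(list(strategy = strategy_label(strategy),
                          classifier = classifier$kind,
                          failed = TRUE,
                          message = trimws(attr(res, "condition")$message %||%
                                             as.character(res)),
                          cv_auc = NA_real_, test_aucs = NA_real_,
                          min_test_auc = NA_real_, aee = NA_real_,
                          n_features_used = NA_integer_,
                          importance = NULL, params = NULL, seed = seed),
                     class = "strategy_result"))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_strategy_impl <- function(bundle, strategy, classifier, outer_folds, seed) {
  if (strategy$name == "oracle" && is.null(bundle$oracle_extra)) {
    stop("oracle strategy requires bundle$oracle_extra")
  }
  inputs <- resolve_strategy_inputs(bundle, strategy)
  kept <- inputs$kept

  pool <- bundle$main
  if (strategy$name == "oracle") {
    pool <- feature_table(rbind(pool$values, bundle$oracle_extra$values),
                          feature_names = colnames(pool$values),
                          labels = c(pool$labels, bundle$oracle_extra$labels))
  }
  if (!is.null(kept)) pool <- subset_table(pool, features = kept)

  with_seed(seed, {
    folds <- stratified_folds(pool$labels, outer_folds)
    fold_aucs <- vapply(seq_len(outer_folds), function(f) {
      tr_idx <- which(folds != f)
      te_idx <- which(folds == f)
      if (length(unique(pool$labels[te_idx])) < 2L) {
        stop("outer fold with a single class; too few observations per class")
      }
      tr <- process_training(subset_table(pool, rows = tr_idx), strategy, inputs$noise)
      fit <- tune_and_fit(tr$values, tr$labels, classifier, seed = draw_seed())
      auc(fit$model$predict_scores(pool$values[te_idx, , drop = FALSE]),
          pool$labels[te_idx])
    }, numeric(1))
    cv_auc <- mean(fold_aucs)

    full_tr <- process_training(pool, strategy, inputs$noise)
    final <- tune_and_fit(full_tr$values, full_tr$labels, classifier,
                          seed = draw_seed())
    test_aucs <- vapply(bundle$test_groups, function(gr) {
      vals <- gr$values
      if (!is.null(kept)) vals <- vals[, kept, drop = FALSE]
      auc(final$model$predict_scores(vals), gr$labels)
    }, numeric(1))

    imp <- sort(final$model$importance(), decreasing = TRUE)
    structure(list(strategy = strategy_label(strategy),
                   classifier = classifier$kind,
                   failed = FALSE, message = NULL,
                   cv_auc = cv_auc, fold_aucs = fold_aucs,
                   test_aucs = test_aucs,
                   min_test_auc = min(test_aucs),
                   aee = abs(cv_auc - min(test_aucs)),
                   n_features_used = ncol(pool$values),
                   kept_features = if (!is.null(kept))
                     colnames(bundle$main$values)[kept],
                   importance = imp, params = final$params, seed = seed),
              class = "strategy_result")
  })
}

#' @export
print.strategy_result <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat(sprintf("<strategy_result> %s / %s FAILED: %s\n",
                x$strategy, x$classifier, x$message))
    return(invisible(x))
  }
  cat(sprintf("<strategy_result> %s / %s: cv_auc %.3f, min test auc %.3f, aee %.3f (%d features)\n",
              x$strategy, x$classifier, x$cv_auc, x$min_test_auc, x$aee,
              x$n_features_used))
  invisible(x)
}

#' Run a full strategy-by-classifier experiment
#'
#' The Cartesian product of strategies, classifiers and repeats. Given a
#' [benchmark_config()], each repeat draws a fresh synthetic benchmark and
#' side study (via [make_benchmark_bundle()]); given a fixed
#' [study_bundle()], repeats vary only the cross-validation and augmentation
#' randomness. Per-repeat seeds are derived deterministically from
#' `base_seed`, so the whole experiment is reproducible.
#'
#' @param x A [study_bundle()] or [benchmark_config()].
#' @param strategies List of [strategy_spec()]s.
#' @param classifiers List of [classifier_spec()]s.
#' @param n_repeats Number of repeats (default 10).
#' @param base_seed Integer seed for the whole experiment.
#' @param outer_folds Outer CV folds (default 5).
#' @param n_side_subjects Side-study size when generating benchmarks
#'   (default 30).
#' @param include_oracle Generate `oracle_extra` when simulating (default:
#'   `TRUE` iff an oracle strategy is requested).
#' @return A list of class `experiment_result` with `results` (one data-frame
#'   row per run: strategy, classifier, repeat, seed, cv_auc, min_test_auc,
#'   aee, n_features_used, failed), `details` (the full `strategy_result`
#'   objects), `truths` (per-repeat [generate_benchmark()] truths, when
#'   simulating) and `summary` (per strategy x classifier: mean AUC/AEE with
#'   percentile-bootstrap 95% confidence intervals).
#' @export
run_experiment <- function(x, strategies, classifiers, n_repeats = 10L,
                           base_seed = 1L, outer_folds = 5L,
                           n_side_subjects = 30L, include_oracle = NULL) {
  if (inherits(x, "strategy_spec")) strategies <- list(strategies)
  if (inherits(strategies, "strategy_spec")) strategies <- list(strategies)
  if (inherits(classifiers, "classifier_spec")) classifiers <- list(classifiers)
  simulate <- inherits(x, "benchmark_config")
  if (!simulate) stopifnot(inherits(x, "study_bundle"))
  if (is.null(include_oracle)) {
    include_oracle <- any(vapply(strategies, function(s) s$name == "oracle", logical(1)))
  }
  repeat_seeds <- with_seed(base_seed, replicate(n_repeats, draw_seed()))

  details <- list()
  truths <- list()
  rows <- list()
  for (r in seq_len(n_repeats)) {
    if (simulate) {
      bb <- make_benchmark_bundle(x, seed = repeat_seeds[r],
                                  n_side_subjects = n_side_subjects,
                                  include_oracle = include_oracle)
      bundle <- bb$bundle
      truths[[r]] <- bb$truth
    } else {
      bundle <- x
    }
    run_seeds <- with_seed(repeat_seeds[r] + 1L,
                           replicate(length(strategies) * length(classifiers),
                                     draw_seed()))
    k <- 0L
    for (si in seq_along(strategies)) {
      for (ci in seq_along(classifiers)) {
        k <- k + 1L
        res <- run_strategy(bundle, strategies[[si]], classifiers[[ci]],
                            outer_folds = outer_folds, seed = run_seeds[k])
        res$repeat_index <- r
        details[[length(details) + 1L]] <- res
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = res$strategy, classifier = res$classifier,
          repeat_index = r, seed = res$seed,
          cv_auc = res$cv_auc, min_test_auc = res$min_test_auc,
          aee = res$aee, n_features_used = res$n_features_used,
          failed = isTRUE(res$failed), stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 details = details,
                 truths = if (simulate) truths,
                 summary = summarize_experiment(results, base_seed)),
            class = "experiment_result")
}

summarize_experiment <- function(results, base_seed) {
  ok <- results[!results$failed, , drop = FALSE]
  if (!nrow(ok)) return(NULL)
  groups <- unique(ok[, c("strategy", "classifier")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- ok$strategy == groups$strategy[i] & ok$classifier == groups$classifier[i]
    aee <- ok$aee[sel]; aucv <- ok$min_test_auc[sel]; cv <- ok$cv_auc[sel]
    ci_of <- function(v, s) {
      if (length(v) < 2L) return(c(lo = NA_real_, hi = NA_real_))
      bootstrap_ci(v, seed = base_seed + s)
    }
    aee_ci <- ci_of(aee, 1L); auc_ci <- ci_of(aucv, 2L)
    data.frame(strategy = groups$strategy[i], classifier = groups$classifier[i],
               n_runs = sum(sel),
               mean_cv_auc = mean(cv),
               mean_min_test_auc = mean(aucv),
               auc_ci_lo = auc_ci["lo"], auc_ci_hi = auc_ci["hi"],
               mean_aee = mean(aee),
               aee_ci_lo = aee_ci["lo"], aee_ci_hi = aee_ci["hi"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d runs (%d failed)\n",
              nrow(x$results), sum(x$results$failed)))
  if (!is.null(x$summary)) {
    print(x$summary, digits = 3)
  }
  invisible(x)
}

#' Overlap between a model's important features and the ground truth
#'
#' For benchmarks with known informative features: how many of the truly
#' informative features appear among the model's `top_k` most important ones,
#' and how long the leading run of the importance ranking consisting only of
#' informative features is.
#'
#' @param result A non-failed [run_strategy()] result with importances.
#' @param truth A `benchmark_truth` (from [generate_benchmark()]).
#' @param top_k Size of the head of the ranking to inspect (default 20).
#' @return List with `n_meaningful_in_top_k` and `prefix_meaningful`.
#' @export
importance_overlap <- function(result, truth, top_k = 20L) {
  stopifnot(inherits(result, "strategy_result"), inherits(truth, "benchmark_truth"))
  if (isTRUE(result$failed) || is.null(result$importance)) {
    stop("result carries no importances")
  }
  informative_names <- names(truth$feature_mean)[truth$informative]
  ranking <- names(result$importance)
  if (top_k > length(ranking)) stop("top_k exceeds the number of ranked features")
  is_inf <- ranking %in% informative_names
  prefix <- match(FALSE, is_inf, nomatch = length(is_inf) + 1L) - 1L
  list(n_meaningful_in_top_k = sum(is_inf[seq_len(top_k)]),
       prefix_meaningful = prefix)
}
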