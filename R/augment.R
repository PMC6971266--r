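#' Augment a feature table with confounder noise (DAFIT)
#'
#' The information-transfer transform: every augmented observation is
#' \deqn{\Theta(x \mid \mu, \sigma^2) = x + N(\mu, \sigma^2)}
#' with the noise drawn independently per feature and per copy from the
#' per-feature normal model estimated on a side study. Instead of deleting
#' unstable features, the main-study data are perturbed by the instability
#' those features showed in the side study, so that a downstream learner can
#' weigh noisy-but-informative features on its own.
#'
#' Noise is applied to raw feature values; any standardization is the
#' classifier's concern. By default the augmented copies replace the
#' originals; set `include_originals = TRUE` to keep them too.
#'
#' @param main A labelled [feature_table()] (the main study).
#' @param noise A [noise_model()] whose length matches the feature count.
#' @param copies Number of augmented copies per original observation
#'   (default 2).
#' @param include_originals Keep the unperturbed originals in the output
#'   (default `FALSE`).
#' @param seed Optional integer seed; the result is deterministic given it.
#' @return A [feature_table()] with `m * copies` rows (plus the `m` originals
#'   first when `include_originals`), labels copied from the source rows.
#' @export
dafit_augment <- function(main, noise, copies = 2L, include_originals = FALSE,
                          seed = NULL) {
  stopifnot(inherits(main, "feature_table"), inherits(noise, "noise_model"))
  copies <- as.integer(copies)
  if (copies < 1L) stop("copies must be >= 1")
  m <- nrow(main$values)
  n <- ncol(main$values)
  if (length(noise$mu) != n) {
    stop(sprintf("noise model has %d features but table has %d",
                 length(noise$mu), n))
  }
  if (is.null(main$labels)) stop("main table must carry class labels")
  sd_vec <- sqrt(noise$sigma2)
  blocks <- with_seed(seed, {
    lapply(seq_len(copies), function(k) {
      eps <- matrix(stats::rnorm(m * n,
                                 mean = rep(noise$mu, each = m),
                                 sd = rep(sd_vec, each = m)),
                    nrow = m, ncol = n)
      main$values + eps
    })
  })
  if (include_originals) blocks <- c(list(main$values), blocks)
  reps <- length(blocks)
  feature_table(do.call(rbind, blocks),
                feature_names = colnames(main$values),
                labels = rep(main$labels, times = reps),
                confounder = if (!is.null(main$confounder))
                  rep(main$confounder, times = reps))
}

#' SMOTE oversampling
#'
#' Classic synthetic minority oversampling: each synthetic observation is a
#' random point on the segment between a randomly chosen class member `x` and
#' one of its `k_neighbors` nearest same-class neighbours `z` (Euclidean
#' distance on raw features), i.e. `x + u * (z - x)` with `u ~ Uniform(0,1)`.
#' Used here as a sample-size control: it grows the training set without
#' adding any confounder information, which separates "more rows" from
#' "more information" when benchmarking the augmentation strategy.
#'
#' @param table A labelled [feature_table()].
#' @param n_synthetic_per_class Named integer vector mapping class (`"0"`,
#'   `"1"`) to the number of synthetic rows to generate, or a single number
#'   applied to every class.
#' @param k_neighbors Number of nearest neighbours to interpolate towards
#'   (default 5, the value of the original SMOTE formulation). Each class
#'   must have more than `k_neighbors` members.
#' @param seed Optional integer seed.
#' @return A [feature_table()] containing the originals followed by the
#'   synthetic rows; the attribute `smote_parents` records, per synthetic row,
#'   the row indices of the parent and the interpolated neighbour.
#' @export
smote_oversample <- function(table, n_synthetic_per_class, k_neighbors = 5L,
                             seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("table must carry class labels")
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  classes <- sort(unique(table$labels))
  if (is.null(names(n_synthetic_per_class))) {
    if (length(n_synthetic_per_class) == 1L) {
      n_synthetic_per_class <- stats::setNames(
        rep(as.integer(n_synthetic_per_class), length(classes)), classes)
    } else stop("n_synthetic_per_class must be named by class or a single number")
  }
  synth <- with_seed(seed, {
    out <- list()
    for (cl in classes) {
      want <- n_synthetic_per_class[[as.character(cl)]]
      if (is.null(want) || is.na(want) || want <= 0) next
      idx <- which(table$labels == cl)
      if (length(idx) <= k_neighbors) {
        stop(sprintf("class %s has %d members; needs more than k_neighbors = %d",
                     cl, length(idx), k_neighbors))
      }
      xs <- table$values[idx, , drop = FALSE]
      dd <- as.matrix(stats::dist(xs))
      diag(dd) <- Inf
      # k nearest same-class neighbours of each member, ties broken by index
      nn <- apply(dd, 1L, function(d) order(d)[seq_len(k_neighbors)])
      parents <- sample.int(length(idx), want, replace = TRUE)
      pick <- sample.int(k_neighbors, want, replace = TRUE)
      u <- stats::runif(want)
      nb <- nn[cbind(pick, parents)]
      z <- xs[nb, , drop = FALSE]
      x <- xs[parents, , drop = FALSE]
      out[[as.character(cl)]] <- list(values = x + u * (z - x),
                                      labels = rep(as.integer(cl), want),
                                      parent = idx[parents], neighbor = idx[nb])
    }
    out
  })
  if (!length(synth)) return(table)
  new_values <- do.call(rbind, c(list(table$values), lapply(synth, `[[`, "values")))
  new_labels <- c(table$labels, unlist(lapply(synth, `[[`, "labels"), use.names = FALSE))
  res <- feature_table(new_values, feature_names = colnames(table$values),
                       labels = new_labels)
  # provenance of the synthetic rows (row indices into `table`), in output order
  attr(res, "smote_parents") <- data.frame(
    parent = unlist(lapply(synth, `[[`, "parent"), use.names = FALSE),
    neighbor = unlist(lapply(synth, `[[`, "neighbor"), use.names = FALSE))
  res
}
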