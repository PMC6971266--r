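#' Construct a per-feature confounder noise model
#'
#' The object a side study transfers to the main study: for every feature a
#' mean shift `mu` (in feature units) and a variance `sigma2` (squared feature
#' units) describing the additive effect of changing the confounder value.
#'
#' @param mu Numeric vector of per-feature mean shifts.
#' @param sigma2 Numeric vector of per-feature variances, elementwise >= 0.
#' @param source_mode How the model was obtained: `"paired"`, `"unpaired"` or
#'   `"known"` (e.g. the generating truth of a synthetic benchmark).
#' @param feature_names Optional feature names; taken from `names(mu)` if
#'   absent.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(mu, sigma2, source_mode = c("paired", "unpaired", "known"),
                        feature_names = names(mu)) {
  source_mode <- match.arg(source_mode)
  mu <- as.numeric(mu); sigma2 <- as.numeric(sigma2)
  if (length(mu) != length(sigma2)) stop("mu and sigma2 must have equal length")
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative")
  if (!is.null(feature_names)) {
    if (length(feature_names) != length(mu)) stop("feature_names length mismatch")
    names(mu) <- names(sigma2) <- feature_names
  }
  structure(list(mu = mu, sigma2 = sigma2, source_mode = source_mode),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> %d features, source=%s\n", length(x$mu), x$source_mode))
  cat(sprintf("  mu: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$mu), min(x$mu), max(x$mu)))
  cat(sprintf("  sigma2: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$sigma2), min(x$sigma2), max(x$sigma2)))
  invisible(x)
}

#' Estimate the noise model from a paired side study
#'
#' Assumes the within-pair difference is due to the confounder alone: per
#' feature, `mu` is the mean and `sigma2` the sample variance (1/(m-1)) of
#' the differences `b - a` across pairs. The sample-variance divisor keeps the
#' estimator unbiased at the small subject counts typical of side studies.
#'
#' The direction convention is `b - a`: `mu` describes the shift from
#' measurement condition a to condition b. Use [symmetrize_noise()] when the
#' sign of the shift should not be transferred.
#'
#' @param side A paired [side_study()] with >= 2 pairs.
#' @return A [noise_model()] with `source_mode = "paired"`.
#' @export
estimate_noise_paired <- function(side) {
  stopifnot(inherits(side, "side_study"))
  if (side$mode != "paired") stop("estimate_noise_paired requires a paired side study")
  if (nrow(side$a$values) < 2L) stop("need at least 2 pairs")
  d <- side$b$values - side$a$values
  noise_model(colMeans(d), col_vars(d), "paired",
              feature_names = colnames(side$a$values))
}

#' Estimate the noise model from an unpaired side study
#'
#' Per feature, `mu` is the difference of group means (b minus a) and
#' `sigma2` the sum of the two group sample variances — the Bienaymé formula
#' for the variance of a difference of independent observations. Note this
#' estimator necessarily includes the biological within-group variance on top
#' of the confounder effect, so it is inflated relative to the paired
#' estimator; that is an inherent property of the unpaired design, not a bug.
#'
#' @param side An unpaired [side_study()] with >= 2 rows per group.
#' @return A [noise_model()] with `source_mode = "unpaired"`.
#' @export
estimate_noise_unpaired <- function(side) {
  stopifnot(inherits(side, "side_study"))
  if (side$mode != "unpaired") stop("estimate_noise_unpaired requires an unpaired side study")
  if (nrow(side$a$values) < 2L || nrow(side$b$values) < 2L) {
    stop("each side-study group needs at least 2 rows")
  }
  mu <- colMeans(side$b$values) - colMeans(side$a$values)
  sigma2 <- col_vars(side$a$values) + col_vars(side$b$values)
  noise_model(mu, sigma2, "unpaired", feature_names = colnames(side$a$values))
}

#' Drop the directional component of a noise model
#'
#' Returns the model with `mu` set to zero, keeping `sigma2`. Useful when the
#' sign convention of the side study (which measurement condition corresponds
#' to the main study) is unknown, so only the magnitude of the instability
#' should be transferred.
#'
#' @param noise A [noise_model()].
#' @return A [noise_model()] with zero means.
#' @export
symmetrize_noise <- function(noise) {
  stopifnot(inherits(noise, "noise_model"))
  noise_model(rep(0, length(noise$mu)), noise$sigma2, noise$source_mode,
              feature_names = names(noise$mu))
}

#' Write / read a noise model as CSV
#'
#' Plain three-column CSV (`feature,mu,sigma2`) for interchange with the
#' command-line interface.
#'
#' @param noise A [noise_model()].
#' @param path File path.
#' @return `write_noise_model` returns `path` invisibly; `read_noise_model`
#'   returns a [noise_model()] with `source_mode = "known"`.
#' @export
write_noise_model <- function(noise, path) {
  stopifnot(inherits(noise, "noise_model"))
  nm <- names(noise$mu)
  if (is.null(nm)) nm <- paste0("feature_", seq_along(noise$mu))
  utils::write.table(data.frame(feature = nm, mu = noise$mu, sigma2 = noise$sigma2),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_noise_model
#' @export
read_noise_model <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  if (!all(c("feature", "mu", "sigma2") %in% names(df))) {
    stop("noise-model file must have columns feature, mu, sigma2")
  }
  noise_model(df$mu, df$sigma2, "known", feature_names = df$feature)
}
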