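#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two paired measurement vectors, combining their
#' correlation with their deviation from the identity line:
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with population (1/n) moments, the standard Lin (1989) estimator. Perfect
#' agreement gives 1, perfect anti-agreement -1.
#'
#' Two identical constant vectors agree perfectly and return 1 by convention;
#' constant vectors with different means return 0 (the numerator vanishes
#' while the mean-shift term does not).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A scalar in \[-1, 1\].
#' @examples
#' ccc(c(1, 2, 3), c(1, 2, 3))  # 1
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  m <- length(x)
  if (m < 2L) stop("ccc needs at least 2 observations")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) return(1)   # identical constant vectors
  2 * sxy / denom
}

#' Stability filter for paired side studies (CCC)
#'
#' Computes Lin's concordance correlation coefficient between the two paired
#' measurements of every feature and keeps the features whose CCC reaches the
#' threshold; features below it are considered unstable under the confounder
#' and are removed. 0.8 is the threshold commonly used in radiomics stability
#' analyses and is the default.
#'
#' @param side A paired [side_study()].
#' @param tau_ccc Threshold in (0, 1\]; features with CCC >= `tau_ccc` are
#'   kept.
#' @return A `stable_set`: list with `kept` (indices of stable features, in
#'   original order), `scores` (per-feature CCC), `method` and `threshold`.
#' @export
ccc_filter <- function(side, tau_ccc = 0.8) {
  stopifnot(inherits(side, "side_study"))
  if (side$mode != "paired") stop("ccc_filter requires a paired side study")
  stopifnot(is.numeric(tau_ccc), tau_ccc > 0, tau_ccc <= 1)
  n <- ncol(side$a$values)
  scores <- vapply(seq_len(n),
                   function(j) ccc(side$a$values[, j], side$b$values[, j]),
                   numeric(1))
  names(scores) <- colnames(side$a$values)
  stable_set(which(scores >= tau_ccc), scores, "ccc", tau_ccc)
}

#' Stability filter for unpaired side studies (uncorrected t-test)
#'
#' Per feature, a two-sided two-sample t-test between the two confounder
#' groups; features whose p-value falls below the threshold differ
#' significantly between confounder values and are removed. No
#' multiple-testing correction is applied: the p-value acts as a probability
#' threshold, not a significance test, so under a true null about `tau_test`
#' of the features are removed by construction.
#'
#' Degenerate zero-variance features are handled deterministically: constant
#' and equal in both groups -> p = 1 (kept); constant but unequal -> p = 0
#' (removed).
#'
#' @param side An unpaired [side_study()] with >= 2 rows per group.
#' @param tau_test Removal threshold on the p-value, default 0.05.
#' @param var_equal If `TRUE` use the pooled-variance t-test; default `FALSE`
#'   (Welch), since groups measured under different confounder values carry no
#'   equal-variance guarantee.
#' @return A `stable_set` with per-feature p-values as `scores`.
#' @export
ttest_filter <- function(side, tau_test = 0.05, var_equal = FALSE) {
  stopifnot(inherits(side, "side_study"))
  if (side$mode != "unpaired") stop("ttest_filter requires an unpaired side study")
  stopifnot(is.numeric(tau_test), tau_test > 0, tau_test < 1)
  if (nrow(side$a$values) < 2L || nrow(side$b$values) < 2L) {
    stop("each side-study group needs at least 2 rows")
  }
  n <- ncol(side$a$values)
  pvals <- vapply(seq_len(n), function(j) {
    xa <- side$a$values[, j]
    xb <- side$b$values[, j]
    va <- stats::var(xa); vb <- stats::var(xb)
    if (va == 0 && vb == 0) {
      return(if (mean(xa) == mean(xb)) 1 else 0)
    }
    stats::t.test(xa, xb, var.equal = var_equal)$p.value
  }, numeric(1))
  names(pvals) <- colnames(side$a$values)
  stable_set(which(pvals >= tau_test), pvals, "ttest", tau_test)
}

stable_set <- function(kept, scores, method, threshold) {
  structure(list(kept = as.integer(kept), scores = scores,
                 method = method, threshold = threshold),
            class = "stable_set")
}

#' @export
print.stable_set <- function(x, ...) {
  cat(sprintf("<stable_set> %s filter (threshold %g): kept %d of %d features\n",
              x$method, x$threshold, length(x$kept), length(x$scores)))
  invisible(x)
}

#' Normality diagnostic for paired side-study differences
#'
#' The augmentation transform models the confounder effect as additive
#' Gaussian noise. This diagnostic checks how well that assumption holds:
#' a Shapiro-Wilk test per feature on the paired differences, with a
#' Bonferroni-adjusted threshold `alpha / n_features`, reporting per feature
#' whether normality is *not* rejected, plus the count and fraction of such
#' features.
#'
#' @param differences Numeric matrix of paired differences (pairs x features),
#'   >= 3 rows. Shapiro-Wilk accepts at most 5000 rows; larger inputs are an
#'   error.
#' @param alpha Family-wise level in (0, 1), default 0.05.
#' @return List with `p` (per-feature p-values), `normal_not_rejected`
#'   (logical vector), `threshold` (the per-test Bonferroni level),
#'   `n_not_rejected` and `fraction_not_rejected`.
#' @export
normality_diagnostic <- function(differences, alpha = 0.05) {
  differences <- as.matrix(differences)
  if (nrow(differences) < 3L) stop("normality diagnostic needs at least 3 rows")
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  n <- ncol(differences)
  p <- vapply(seq_len(n), function(j) {
    x <- differences[, j]
    if (stats::var(x) == 0) return(0)  # a point mass is maximally non-normal
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  names(p) <- colnames(differences)
  thr <- alpha / n
  ok <- p >= thr
  list(p = p, normal_not_rejected = ok, threshold = thr,
       n_not_rejected = sum(ok), fraction_not_rejected = mean(ok))
}
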