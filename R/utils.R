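# Internal helpers shared across modules.

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
# stream; a NULL seed leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Draw a sub-seed from the current stream; keeps all derived seeds in the
# 32-bit integer range.
draw_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

# Per-column sample variances (1/(m-1)) of a matrix.
col_vars <- function(m) {
  mu <- colMeans(m)
  colSums((m - rep(mu, each = nrow(m)))^2) / (nrow(m) - 1L)
}

# Stratified fold assignment: returns an integer vector of fold ids with each
# class spread as evenly as possible across folds. Uses the current RNG stream.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}
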