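#' Construct a feature table
#'
#' A feature table is the basic data container of the package: a dense numeric
#' matrix of observations (rows) by features (columns), optionally carrying
#' binary class labels and/or a categorical confounder value per observation.
#' Missing values are a hard error: silently imputing them would contaminate
#' downstream noise estimation.
#'
#' @param values Numeric matrix, m observations x n features.
#' @param feature_names Character vector of n unique feature names. Defaults to
#'   the column names of `values`.
#' @param labels Optional vector of m binary class labels coded 0/1.
#' @param confounder Optional vector of m categorical confounder values.
#' @return An object of class `feature_table` with elements `values`
#'   (matrix with feature names as column names), `labels` and `confounder`.
#' @examples
#' ft <- feature_table(matrix(rnorm(12), 4, 3), paste0("f", 1:3),
#'                     labels = c(0, 0, 1, 1))
#' dim(ft$values)
#' @export
feature_table <- function(values, feature_names = colnames(values),
                          labels = NULL, confounder = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature values must be numeric")
  m <- nrow(values)
  n <- ncol(values)
  if (m < 1L || n < 1L) stop("a feature table needs at least 1 observation and 1 feature")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column %d", idx[1L], idx[2L]))
  }
  if (is.null(feature_names)) feature_names <- paste0("feature_", seq_len(n))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != n) stop("feature_names length must equal number of columns")
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  }
  colnames(values) <- feature_names
  rownames(values) <- NULL
  if (!is.null(labels)) {
    if (length(labels) != m) stop("labels length must equal number of observations")
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  }
  if (!is.null(confounder)) {
    if (length(confounder) != m) stop("confounder length must equal number of observations")
    confounder <- as.character(confounder)
  }
  structure(list(values = values, labels = labels, confounder = confounder),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d observations x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  if (!is.null(x$confounder)) {
    cat("  confounder values:", paste(unique(x$confounder), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

n_features <- function(x) ncol(x$values)
n_obs <- function(x) nrow(x$values)

#' Subset a feature table
#'
#' @param x A [feature_table()].
#' @param rows,features Optional row / feature (column) index vectors.
#' @return A `feature_table` with the selected rows and features.
#' @export
subset_table <- function(x, rows = NULL, features = NULL) {
  stopifnot(inherits(x, "feature_table"))
  if (is.null(rows)) rows <- seq_len(nrow(x$values))
  if (is.null(features)) features <- seq_len(ncol(x$values))
  feature_table(x$values[rows, features, drop = FALSE],
                labels = if (!is.null(x$labels)) x$labels[rows],
                confounder = if (!is.null(x$confounder)) x$confounder[rows])
}

#' Read a feature table from a delimited text file
#'
#' Reads a CSV/TSV file with a header row into a [feature_table()]. Columns
#' named by `label_column` / `confounder_column` are removed from the feature
#' matrix and stored as metadata. Label values are mapped to 0/1 by the
#' lexicographic order of the two original values; the mapping is reported in
#' a message.
#'
#' @param path Path to the file.
#' @param label_column Optional name of the class-label column (exactly two
#'   distinct values required).
#' @param confounder_column Optional name of the confounder column.
#' @param id_column Optional name of a subject-identifier column to drop from
#'   the feature matrix (used by [read_side_study()]).
#' @param delimiter Field delimiter, default `","`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_column = NULL, confounder_column = NULL,
                               id_column = NULL, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "", quote = "\"")
  if (anyDuplicated(names(df))) {
    stop("duplicate feature names in header: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  meta_cols <- c(label_column, confounder_column, id_column)
  missing_cols <- setdiff(meta_cols, names(df))
  if (length(missing_cols)) stop("column not found: ", paste(missing_cols, collapse = ", "))

  labels <- NULL
  if (!is.null(label_column)) {
    raw <- df[[label_column]]
    lev <- sort(unique(as.character(raw)))
    if (length(lev) != 2L) {
      stop(sprintf("label column '%s' must have exactly 2 distinct values, found %d",
                   label_column, length(lev)))
    }
    message(sprintf("label mapping: '%s' -> 0, '%s' -> 1", lev[1L], lev[2L]))
    labels <- as.integer(match(as.character(raw), lev) - 1L)
  }
  confounder <- if (!is.null(confounder_column)) as.character(df[[confounder_column]])

  feat_df <- df[, setdiff(names(df), meta_cols), drop = FALSE]
  if (ncol(feat_df) < 1L) stop("no feature columns left after removing metadata columns")
  for (j in seq_along(feat_df)) {
    col <- feat_df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      if (length(bad)) {
        stop(sprintf("non-numeric feature cell at row %d, column '%s'",
                     bad[1L], names(feat_df)[j]))
      }
      feat_df[[j]] <- as.numeric(col)
    }
  }
  values <- as.matrix(feat_df)
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column '%s'",
                 idx[1L], colnames(values)[idx[2L]]))
  }
  feature_table(values, feature_names = colnames(values),
                labels = labels, confounder = confounder)
}

#' Write a feature table to a delimited text file
#'
#' Writes the feature matrix with a header row; labels and confounder values,
#' when present, are appended as trailing columns named `label` and
#' `confounder`. Values are written at full double precision so that a
#' read/write round trip is the identity to at least 12 significant digits.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param delimiter Field delimiter, default `","`.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$values, check.names = FALSE)
  if (!is.null(table$labels)) df[["label"]] <- table$labels
  if (!is.null(table$confounder)) df[["confounder"]] <- table$confounder
  ok <- tryCatch({
    utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write to path: ", path, " (", conditionMessage(e), ")"))
  invisible(path)
}

#' Construct a side study
#'
#' A side study holds two sets of measurements of the same features under two
#' different values of a confounding variable. In `paired` mode the two tables
#' are aligned row by row (row i of `a` and row i of `b` are the same subject
#' measured twice); in `unpaired` mode they are independent groups.
#'
#' Side studies quantify feature stability only; class labels on them are never
#' used (a stability experiment typically carries no information on the
#' prediction target).
#'
#' @param a,b [feature_table()]s with identical feature names in identical
#'   order.
#' @param mode `"paired"` or `"unpaired"`.
#' @return An object of class `side_study`.
#' @export
side_study <- function(a, b, mode = c("paired", "unpaired")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  if (!identical(colnames(a$values), colnames(b$values))) {
    stop("side-study groups must have identical feature names in identical order")
  }
  if (mode == "paired" && nrow(a$values) != nrow(b$values)) {
    stop("paired side study requires equal row counts in both measurements")
  }
  structure(list(mode = mode, a = a, b = b), class = "side_study")
}

#' @export
print.side_study <- function(x, ...) {
  cat(sprintf("<side_study> mode=%s, %d + %d observations, %d features\n",
              x$mode, nrow(x$a$values), nrow(x$b$values), ncol(x$a$values)))
  invisible(x)
}

#' Read a side study from a single delimited file
#'
#' The file must contain a confounder column taking exactly two distinct
#' values; rows are split into groups `a` and `b` by the lexicographically
#' first and second value. For a paired study a subject-identifier column is
#' required and rows are matched by subject id; a subject present in only one
#' group is an error (explicit pairing beats positional convention).
#'
#' @param path Path to the file.
#' @param mode `"paired"` or `"unpaired"`.
#' @param confounder_column Name of the confounder column.
#' @param subject_column Name of the subject-id column (required for paired
#'   mode).
#' @param delimiter Field delimiter, default `","`.
#' @return A [side_study()].
#' @export
read_side_study <- function(path, mode = c("paired", "unpaired"),
                            confounder_column = "confounder",
                            subject_column = NULL, delimiter = ",") {
  mode <- match.arg(mode)
  if (mode == "paired" && is.null(subject_column)) {
    stop("paired mode requires a subject_column for row matching")
  }
  ft <- read_feature_table(path, confounder_column = confounder_column,
                           id_column = subject_column, delimiter = delimiter)
  lev <- sort(unique(ft$confounder))
  if (length(lev) != 2L) {
    stop(sprintf("confounder column must have exactly 2 distinct values, found %d",
                 length(lev)))
  }
  ia <- which(ft$confounder == lev[1L])
  ib <- which(ft$confounder == lev[2L])
  if (mode == "paired") {
    df <- utils::read.table(path, header = TRUE, sep = delimiter,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[subject_column]])
    unmatched <- c(setdiff(ids[ia], ids[ib]), setdiff(ids[ib], ids[ia]))
    if (length(unmatched)) {
      stop("unmatched subjects in paired side study: ",
           paste(unique(unmatched), collapse = ", "))
    }
    ib <- ib[match(ids[ia], ids[ib])]
  }
  side_study(subset_table(ft, rows = ia), subset_table(ft, rows = ib), mode = mode)
}

#' Bundle the study splits used by the evaluation harness
#'
#' Mirrors the split design of a confounder-aware benchmarking study: a side
#' study quantifying the confounder effect (split A), a main study with labels
#' but a single confounder value (group B1), an optional extra labelled table
#' containing confounder variation (rest of split B, used only by the oracle
#' strategy), and one or more labelled test groups with different confounder
#' values (groups C1..Cn).
#'
#' @param side A [side_study()].
#' @param main A labelled [feature_table()] (the main study, group B1).
#' @param test_groups List of labelled [feature_table()]s (groups C1..Cn).
#' @param oracle_extra Optional labelled [feature_table()] with confounder
#'   variation, pooled with `main` by the oracle strategy.
#' @return An object of class `study_bundle`.
#' @export
study_bundle <- function(side, main, test_groups, oracle_extra = NULL) {
  stopifnot(inherits(side, "side_study"), inherits(main, "feature_table"))
  if (inherits(test_groups, "feature_table")) test_groups <- list(test_groups)
  ref <- colnames(side$a$values)
  all_tabs <- c(list(main), test_groups, if (!is.null(oracle_extra)) list(oracle_extra))
  for (tab in all_tabs) {
    if (!identical(colnames(tab$values), ref)) {
      stop("all bundle tables must share identical feature names in identical order")
    }
  }
  check_two_classes <- function(tab, what) {
    if (is.null(tab$labels)) stop(what, " must carry class labels")
    if (length(unique(tab$labels)) != 2L) stop(what, " must contain both classes")
  }
  check_two_classes(main, "main study")
  for (i in seq_along(test_groups)) {
    check_two_classes(test_groups[[i]], sprintf("test group %d", i))
  }
  if (!is.null(oracle_extra)) check_two_classes(oracle_extra, "oracle_extra")
  structure(list(side = side, main = main, oracle_extra = oracle_extra,
                 test_groups = test_groups),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> main %dx%d, %d test group(s), side mode=%s%s\n",
              nrow(x$main$values), ncol(x$main$values), length(x$test_groups),
              x$side$mode,
              if (is.null(x$oracle_extra)) "" else
                sprintf(", oracle_extra %d rows", nrow(x$oracle_extra$values))))
  invisible(x)
}
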