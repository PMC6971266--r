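test_that("feature_table enforces its invariants", {
  expect_error(feature_table(matrix(c(1, NA, 3, 4), 2, 2)),
               "missing value at row 2, column 1")
  expect_error(feature_table(matrix(1:4, 2, 2), c("a", "a")), "duplicate feature")
  expect_error(feature_table(matrix(1:4, 2, 2), c("a", "b"), labels = c(0, 1, 1)),
               "labels length")
  expect_error(feature_table(matrix(1:4, 2, 2), c("a", "b"), labels = c(1, 2)),
               "binary")
  expect_error(feature_table(matrix(numeric(0), 0, 2)), "at least 1")
  ft <- feature_table(matrix(1:6, 3, 2), c("a", "b"), labels = c(0, 1, 1))
  expect_identical(dim(ft), c(3L, 2L))
  expect_identical(colnames(ft$values), c("a", "b"))
})

test_that("read_feature_table parses a labelled CSV and maps labels lexicographically", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("f1,f2,f3,y",
               "1.5,2,3,B",
               "4,5,6,A",
               "7,8,9,B",
               "1,2,3,A"), path)
  expect_message(ft <- read_feature_table(path, label_column = "y"),
                 "'A' -> 0, 'B' -> 1")
  expect_identical(dim(ft), c(4L, 3L))
  expect_identical(ft$labels, c(1L, 0L, 1L, 0L))
  expect_equal(ft$values[1, ], c(f1 = 1.5, f2 = 2, f3 = 3))
})

test_that("read_feature_table rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("f1,f2", "1,", "3,4"), path)
  expect_error(read_feature_table(path), "missing value at row 1, column 'f2'")

  writeLines(c("f1,f2", "1,x", "3,4"), path)
  expect_error(read_feature_table(path), "non-numeric feature cell")

  writeLines(c("f1,y", "1,A", "2,B", "3,C"), path)
  expect_error(read_feature_table(path, label_column = "y"),
               "exactly 2 distinct values")

  expect_error(read_feature_table(file.path(tempdir(), "no-such-file.csv")),
               "file not found")
})

test_that("write/read round trip is the identity", {
  for (seed in 1:4) {
    ft <- random_table(m = 7, n = 5, seed = seed,
                       labels = seed %% 2 == 0, confounder = seed > 2)
    path <- withr::local_tempfile(fileext = ".csv")
    write_feature_table(ft, path)
    back <- suppressMessages(read_feature_table(
      path,
      label_column = if (!is.null(ft$labels)) "label",
      confounder_column = if (!is.null(ft$confounder)) "confounder"))
    expect_equal(back$values, ft$values, tolerance = 1e-12)
    expect_identical(colnames(back$values), colnames(ft$values))
    expect_identical(back$labels, ft$labels)
    expect_identical(back$confounder, ft$confounder)
  }
})

test_that("write_feature_table emits header plus one line per observation", {
  ft <- random_table(m = 2, n = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  expect_length(readLines(path), 3L)
})

test_that("side_study validates alignment and pairing", {
  a <- random_table(m = 5, n = 3, seed = 1)
  b <- random_table(m = 5, n = 3, seed = 2)
  expect_s3_class(side_study(a, b, "paired"), "side_study")
  b_short <- subset_table(b, rows = 1:4)
  expect_error(side_study(a, b_short, "paired"), "equal row counts")
  expect_s3_class(side_study(a, b_short, "unpaired"), "side_study")
  b_renamed <- feature_table(b$values, feature_names = c("q1", "q2", "q3"))
  expect_error(side_study(a, b_renamed, "paired"), "identical feature names")
})

test_that("read_side_study pairs rows by subject id, not file order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("f1,f2,id,cond",
               "1,10,s1,scan1",
               "2,20,s2,scan1",
               "22,220,s2,scan2",
               "11,110,s1,scan2"), path)
  ss <- read_side_study(path, mode = "paired", confounder_column = "cond",
                        subject_column = "id")
  expect_equal(ss$a$values[, "f1"], c(1, 2))
  expect_equal(ss$b$values[, "f1"], c(11, 22))  # matched s1->s1, s2->s2

  writeLines(c("f1,id,cond", "1,s1,scan1", "2,s2,scan2"), path)
  expect_error(read_side_study(path, mode = "paired", confounder_column = "cond",
                               subject_column = "id"),
               "unmatched subjects")
})

test_that("study_bundle rejects mismatched tables and single-class groups", {
  a <- random_table(m = 6, n = 4, seed = 1)
  side <- side_study(a, random_table(m = 6, n = 4, seed = 2), "paired")
  main <- random_table(m = 8, n = 4, seed = 3, labels = TRUE)
  test_g <- random_table(m = 6, n = 4, seed = 4, labels = TRUE)
  expect_s3_class(study_bundle(side, main, list(test_g)), "study_bundle")

  other <- feature_table(main$values, paste0("z", 1:4), labels = main$labels)
  expect_error(study_bundle(side, other, list(test_g)), "identical feature names")

  one_class <- feature_table(test_g$values, colnames(test_g$values),
                             labels = rep(0L, 6))
  expect_error(study_bundle(side, main, list(one_class)), "both classes")
  expect_error(study_bundle(side, subset_table(main, rows = 1:6), list(test_g),
                            oracle_extra = one_class),
               "both classes")
})
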