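# Manifest I/O and split protocols.

make_manifest_df <- function(n, datasets = "d1", with_patients = TRUE,
                             balance = 0.5) {
  labels <- rep(rep(0:1, each = 2), length.out = n)
  data.frame(image_path = sprintf("img%04d.png", seq_len(n)),
             label = labels,
             patient_id = if (with_patients) sprintf("P%03d", (seq_len(n) + 1L) %/% 2L)
                          else "",
             dataset_id = rep(datasets, length.out = n),
             stringsAsFactors = FALSE)
}

write_manifest <- function(df) {
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  p
}

test_that("well-formed manifests load; duplicates and missing columns are rejected", {
  df <- make_manifest_df(4)
  rec <- load_manifest(write_manifest(df))
  expect_equal(nrow(rec), 4L)
  expect_type(rec$label, "integer")
  dup <- df
  dup$image_path[2] <- dup$image_path[1]
  expect_error(load_manifest(write_manifest(dup)), "img0001.png")
  expect_error(load_manifest(write_manifest(df[, -2])), "label")
})

test_that("numeric and text labels map to the same records", {
  df1 <- make_manifest_df(4)
  df2 <- df1
  df2$label <- c("normal", "normal", "glaucoma", "glaucoma")
  expect_identical(load_manifest(write_manifest(df1)),
                   load_manifest(write_manifest(df2)))
  bad <- df1
  bad$label[1] <- "maybe"
  expect_error(load_manifest(write_manifest(bad)), "maybe")
})

test_that("patient-level split keeps eyes together and realizes 70/30 + 20% val", {
  rec <- make_manifest_df(200)  # 100 patients x 2 eyes
  plan <- patient_level_split(rec, seed = 5)
  pt <- function(d) unique(d$patient_id)
  expect_equal(length(pt(plan$test)), 30L)
  expect_equal(length(pt(plan$val)), 14L)
  expect_equal(length(pt(plan$train)), 56L)
  expect_equal(sort(c(plan$train$image_path, plan$val$image_path,
                      plan$test$image_path)), sort(rec$image_path))
  # no patient straddles partitions
  expect_length(intersect(pt(plan$train), pt(plan$test)), 0L)
  expect_length(intersect(pt(plan$train), pt(plan$val)), 0L)
  expect_length(intersect(pt(plan$val), pt(plan$test)), 0L)
  expect_error(patient_level_split(make_manifest_df(4, with_patients = FALSE)),
               "patient_id")
})

test_that("splits are pure functions of records and seed", {
  rec <- make_manifest_df(60)
  expect_identical(patient_level_split(rec, seed = 9),
                   patient_level_split(rec, seed = 9))
  a <- patient_level_split(rec, seed = 1)
  b <- patient_level_split(rec, seed = 2)
  expect_false(identical(a$test$image_path, b$test$image_path))
  expect_equal(nrow(a$test), nrow(b$test))  # same marginal counts
  expect_identical(make_cv_folds(rec, 5, seed = 3), make_cv_folds(rec, 5, seed = 3))
})

test_that("five-fold assignment is balanced per dataset and class", {
  rec <- make_manifest_df(300, datasets = rep(c("A", "B", "C"), each = 100))
  folds <- make_cv_folds(rec, k = 5, seed = 7)
  expect_true(all(folds %in% 1:5))
  # every fold receives 100 / 5 = 20 records per dataset
  tab <- table(rec$dataset_id, folds)
  expect_true(all(tab == 20))
  # per (dataset, class) cell sizes differ by at most 1
  for (ds in c("A", "B", "C")) for (lb in 0:1) {
    cell <- folds[rec$dataset_id == ds & rec$label == lb]
    expect_lte(diff(range(table(factor(cell, levels = 1:5)))), 1)
  }
  # patient grouping: both eyes in the same fold
  expect_true(all(tapply(folds, rec$patient_id, function(f) length(unique(f))) == 1))
})

test_that("a cell smaller than k warns and still assigns valid folds", {
  rec <- make_manifest_df(6, with_patients = FALSE)
  w <- testthat::capture_warnings(folds <- make_cv_folds(rec, k = 5, seed = 1))
  expect_true(any(grepl("fewer than k", w)))
  expect_true(all(folds %in% 1:5))
})

test_that("cross-validation iterations partition the manifest with balanced 80/20", {
  rec <- make_manifest_df(300, datasets = rep(c("A", "B", "C"), each = 100),
                          with_patients = FALSE)
  folds <- make_cv_folds(rec, k = 5, seed = 11)
  tested <- character()
  for (i in 1:5) {
    plan <- cv_iteration(rec, folds, i, seed = 13)
    expect_equal(nrow(plan$test), 60L)
    expect_equal(nrow(plan$train), 192L)
    expect_equal(nrow(plan$val), 48L)
    all_paths <- c(plan$train$image_path, plan$val$image_path, plan$test$image_path)
    expect_length(unique(all_paths), 300L)  # no image in two partitions
    # class proportions preserved within one count per (dataset, class) cell
    for (ds in c("A", "B", "C")) {
      n_val_cell <- sum(plan$val$dataset_id == ds & plan$val$label == 1)
      n_rest_cell <- sum(plan$train$dataset_id == ds & plan$train$label == 1) +
        n_val_cell
      expect_lte(abs(n_val_cell - 0.2 * n_rest_cell), 1)
    }
    tested <- c(tested, plan$test$image_path)
  }
  # across the k iterations every record is tested exactly once
  expect_equal(sort(tested), sort(rec$image_path))
  expect_error(cv_iteration(rec, folds, 6), "held_out_index")
})
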