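# Manifest I/O and split protocols.
#
# A manifest is a CSV with columns image_path, label, patient_id, dataset_id
# (labels 0/1 or normal/glaucoma). Three protocols are provided:
# predefined splits are just manifests; patient-level 70/30 splitting with a
# further 20% of the training pool as validation; and k-fold multi-dataset
# cross-validation balanced per (dataset, class) cell, patient-grouped
# whenever patient identifiers are available.

#' Load and validate a sample manifest
#'
#' @param path CSV file with header columns `image_path`, `label`,
#'   `patient_id`, `dataset_id`. Labels may be `0`/`1` or
#'   `normal`/`glaucoma`. Extra columns are kept.
#' @return a data frame of validated records (label coerced to integer 0/1,
#'   empty patient ids to `NA`).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("image_path", "label", "patient_id", "dataset_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stopf("manifest is missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(!nzchar(df$image_path))) stopf("manifest contains empty image paths")
  dup <- df$image_path[duplicated(df$image_path)]
  if (length(dup)) {
    stopf("duplicated image_path in manifest: %s", dup[1])
  }
  df$label <- as_label01(df$label)
  df$patient_id[!nzchar(df$patient_id)] <- NA_character_
  df$dataset_id[!nzchar(df$dataset_id)] <- "default"
  df
}

normalize_patient_id <- function(x) {
  x <- as.character(x)
  x[!nzchar(x)] <- NA_character_
  x
}

split_plan <- function(train, val, test) {
  structure(list(train = train, val = val, test = test), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d / val %d / test %d records\n",
              nrow(x$train), nrow(x$val), nrow(x$test)))
  invisible(x)
}

#' Patient-level train/validation/test split
#'
#' Partitions records at patient granularity: `train_frac` of the patients
#' form the training pool and the rest the test set; `val_frac_of_train` of
#' the training-pool patients are then held out for validation. Every record
#' of a patient lands in the same partition.
#'
#' @param records manifest data frame (all rows must carry `patient_id`).
#' @param train_frac fraction of patients allocated to the training pool.
#' @param val_frac_of_train fraction of the training pool moved to validation.
#' @param seed integer seed; the split is a pure function of
#'   `(records, fractions, seed)`.
#' @return a `split_plan` with `train`, `val`, `test` data frames.
#' @export
patient_level_split <- function(records, train_frac = 0.70,
                                val_frac_of_train = 0.20, seed = 1L) {
  records$patient_id <- normalize_patient_id(records$patient_id)
  if (anyNA(records$patient_id)) {
    stopf("patient_level_split requires patient_id on every record")
  }
  patients <- unique(records$patient_id)
  with_seed(seed, {
    patients <- sample(patients)
    n_pool <- round(train_frac * length(patients))
    pool <- patients[seq_len(n_pool)]
    test_p <- patients[setdiff(seq_along(patients), seq_len(n_pool))]
    n_val <- round(val_frac_of_train * length(pool))
    val_p <- if (n_val > 0) pool[seq_len(n_val)] else character()
    train_p <- setdiff(pool, val_p)
    split_plan(train = records[records$patient_id %in% train_p, , drop = FALSE],
               val = records[records$patient_id %in% val_p, , drop = FALSE],
               test = records[records$patient_id %in% test_p, , drop = FALSE])
  })
}

#' Assign cross-validation folds
#'
#' Assigns every record to one of `k` folds, independently inside each
#' (dataset, class) cell so each fold sees the same composition; records
#' sharing a `patient_id` are kept in the same fold. Cell fold sizes differ
#' by at most one record (up to patient-group granularity).
#'
#' @param records manifest data frame.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold indices in `1..k`, one per record.
#' @export
make_cv_folds <- function(records, k = 5L, seed = 1L) {
  if (k < 2L) stopf("k must be at least 2")
  n <- nrow(records)
  records$patient_id <- normalize_patient_id(records$patient_id)
  folds <- integer(n)
  with_seed(seed, {
    cells <- split(seq_len(n),
                   list(records$dataset_id, records$label), drop = TRUE)
    for (cell in cells) {
      pid <- records$patient_id[cell]
      units <- if (anyNA(pid)) as.list(cell) else split(cell, pid)
      if (length(cell) < k) {
        warning(sprintf(
          "a (dataset, class) cell has %d records, fewer than k = %d folds",
          length(cell), k), call. = FALSE)
      }
      units <- units[sample(length(units))]
      # largest-first greedy keeps per-cell fold sizes within one unit
      units <- units[order(-lengths(units))]
      sizes <- integer(k)
      for (u in units) {
        f <- which.min(sizes)
        folds[u] <- f
        sizes[f] <- sizes[f] + length(u)
      }
    }
  })
  folds
}

#' One cross-validation iteration
#'
#' The held-out fold (across all datasets) is the test set; the remaining
#' records are split `1 - val_frac` / `val_frac` into training and
#' validation, stratified per (dataset, class) cell so class proportions are
#' preserved within one record.
#'
#' @param records manifest data frame.
#' @param folds fold assignment from [make_cv_folds()].
#' @param held_out_index fold used as the test set (in `1..k`).
#' @param val_frac fraction of the non-test records used for validation.
#' @param seed integer seed for the train/validation shuffle.
#' @return a `split_plan`.
#' @export
cv_iteration <- function(records, folds, held_out_index, val_frac = 0.20,
                         seed = 1L) {
  k <- max(folds)
  if (held_out_index < 1L || held_out_index > k) {
    stopf("held_out_index must be in 1..%d", k)
  }
  test_idx <- which(folds == held_out_index)
  rest <- which(folds != held_out_index)
  val_idx <- integer()
  with_seed(seed, {
    cells <- split(rest, list(records$dataset_id[rest], records$label[rest]),
                   drop = TRUE)
    for (cell in cells) {
      cell <- cell[sample(length(cell))]
      n_val <- round(val_frac * length(cell))
      val_idx <- c(val_idx, cell[seq_len(n_val)])
    }
  })
  train_idx <- setdiff(rest, val_idx)
  split_plan(train = records[train_idx, , drop = FALSE],
             val = records[val_idx, , drop = FALSE],
             test = records[test_idx, , drop = FALSE])
}
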