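#' Read a single omics layer from CSV
#'
#' Reads a samples-by-features CSV into an `omics_matrix`. The layout is
#' the per-omics convention used by multi-omics classifiers of the
#' MOGONET family: the first column (named `sample_id`) holds sample
#' identifiers, the header row holds feature identifiers, every other
#' cell is a finite real number.
#'
#' @param path Path to the CSV file.
#' @param omics_name Short name for the layer (e.g. `"mrna"`, `"meth"`).
#' @return An `omics_matrix`: numeric matrix with sample IDs as rownames
#'   and feature IDs as colnames, plus an `omics_name` attribute.
#' @export
read_omics_csv <- function(path, omics_name) {
  if (!file.exists(path)) {
    stop("omics file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) {
    stop("omics file needs a sample_id column plus at least one feature: ",
         path, call. = FALSE)
  }
  sample_ids <- df[[1L]]
  feature_ids <- colnames(df)[-1L]
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)), USE.NAMES = FALSE)
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(sample_ids, feature_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric or non-finite value in %s at sample '%s', feature '%s'",
      path, sample_ids[bad[1L, 1L]], feature_ids[bad[1L, 2L]]),
      call. = FALSE)
  }
  omics_matrix(vals, omics_name)
}

#' Construct an omics_matrix from a numeric matrix
#'
#' @param values Numeric matrix, samples in rows (rownames = sample IDs,
#'   colnames = feature IDs).
#' @param omics_name Short layer name.
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, omics_name) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("omics matrix needs sample rownames and feature colnames",
         call. = FALSE)
  }
  if (nrow(values) < 2L) {
    stop("omics layer '", omics_name, "' needs at least 2 samples",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample IDs in omics layer '", omics_name, "'",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature IDs in omics layer '", omics_name, "'",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("non-finite values in omics layer '", omics_name, "'",
         call. = FALSE)
  }
  structure(values, omics_name = omics_name,
            class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix '%s'> %d samples x %d features\n",
              attr(x, "omics_name"), nrow(x), ncol(x)))
  invisible(x)
}

#' Write an omics layer to CSV
#'
#' Inverse of [read_omics_csv()]; round-trips values at full precision.
#'
#' @param x An `omics_matrix`.
#' @param path Output CSV path.
#' @export
write_omics_csv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample labels from CSV
#'
#' Expects two columns: sample ID and class label. Class names are
#' mapped to integer indices `0..Q-1` in lexicographic order so the
#' mapping is independent of file row order.
#'
#' @param path Path to the label CSV.
#' @return A `label_vector`: list with `sample_ids`, integer `y`
#'   (0-based) and `class_names`.
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("label file needs two columns (sample_id, label): ", path,
         call. = FALSE)
  }
  label_vector(sample_ids = as.character(df[[1L]]),
               labels = as.character(df[[2L]]))
}

#' Construct a label_vector
#'
#' @param sample_ids Character vector of sample IDs.
#' @param labels Character (or coercible) class label per sample.
#' @return A `label_vector` with 0-based `y` and lexicographically
#'   ordered `class_names`.
#' @export
label_vector <- function(sample_ids, labels) {
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  if (length(sample_ids) != length(labels)) {
    stop("sample_ids and labels differ in length", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample IDs in labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  class_names <- sort(unique(labels))
  if (length(class_names) < 2L) {
    stop("need at least 2 classes, found ", length(class_names),
         call. = FALSE)
  }
  y <- match(labels, class_names) - 1L
  structure(list(sample_ids = sample_ids, y = y, class_names = class_names),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("<label_vector> %d samples, %d classes (%s)\n",
              length(x$y), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Write labels to CSV
#' @param labels A `label_vector`.
#' @param path Output CSV path.
#' @export
write_labels_csv <- function(labels, path) {
  df <- data.frame(sample_id = labels$sample_ids,
                   label = labels$class_names[labels$y + 1L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble aligned multi-omics dataset
#'
#' Reorders every omics layer to the label sample order and validates
#' alignment. The result is the universal input of the pipeline.
#'
#' @param matrices List of `omics_matrix` objects (one per layer).
#' @param labels A `label_vector` covering exactly the same samples.
#' @return A `multiomics_dataset`: list with `omics` (named list of
#'   matrices, rows in label order) and `labels`.
#' @export
assemble_dataset <- function(matrices, labels) {
  stopifnot(inherits(labels, "label_vector"), length(matrices) >= 1L)
  ids <- labels$sample_ids
  omics <- lapply(matrices, function(m) {
    nm <- attr(m, "omics_name")
    missing <- setdiff(ids, rownames(m))
    if (length(missing) > 0L) {
      stop("omics layer '", nm, "' is missing labeled samples: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(rownames(m), ids)
    if (length(extra) > 0L) {
      stop("omics layer '", nm, "' has unlabeled samples: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    omics_matrix(unclass(m)[ids, , drop = FALSE], nm)
  })
  names(omics) <- vapply(omics, attr, "", "omics_name")
  if (anyDuplicated(names(omics))) {
    stop("duplicate omics_name among layers", call. = FALSE)
  }
  structure(list(omics = omics, labels = labels),
            class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("<multiomics_dataset> %d samples, %d classes, %d omics\n",
              length(x$labels$y), length(x$labels$class_names),
              length(x$omics)))
  for (m in x$omics) {
    cat(sprintf("  %-8s %d features\n", attr(m, "omics_name"), ncol(m)))
  }
  invisible(x)
}

#' Read a dataset directory
#'
#' Directory layout: one `<omics>.csv` per layer plus `labels.csv`.
#'
#' @param dir Dataset directory.
#' @param omics_names Optional layer names to read; default: every
#'   `*.csv` except `labels.csv`.
#' @return A `multiomics_dataset`.
#' @export
read_dataset_dir <- function(dir, omics_names = NULL) {
  if (is.null(omics_names)) {
    files <- list.files(dir, pattern = "\\.csv$")
    omics_names <- sort(setdiff(sub("\\.csv$", "", files), "labels"))
  }
  labels <- read_labels_csv(file.path(dir, "labels.csv"))
  mats <- lapply(omics_names, function(nm) {
    read_omics_csv(file.path(dir, paste0(nm, ".csv")), nm)
  })
  assemble_dataset(mats, labels)
}

#' Write a dataset directory
#' @param dataset A `multiomics_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_dataset_dir <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in dataset$omics) {
    write_omics_csv(m, file.path(dir, paste0(attr(m, "omics_name"), ".csv")))
  }
  write_labels_csv(dataset$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' Restrict a dataset to a subset of omics layers and/or samples
#'
#' @param dataset A `multiomics_dataset`.
#' @param omics Character vector of layer names to keep (default all).
#' @param sample_idx Integer indices of samples to keep (default all).
#' @return A `multiomics_dataset`.
#' @export
subset_dataset <- function(dataset, omics = NULL, sample_idx = NULL) {
  om <- dataset$omics
  if (!is.null(omics)) {
    missing <- setdiff(omics, names(om))
    if (length(missing) > 0L) {
      stop("unknown omics layer(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    om <- om[omics]
  }
  lab <- dataset$labels
  if (!is.null(sample_idx)) {
    keep <- lab$sample_ids[sample_idx]
    # keep the global class index mapping even if a class drops out
    lab <- structure(list(sample_ids = keep, y = lab$y[sample_idx],
                          class_names = lab$class_names),
                     class = "label_vector")
    om <- lapply(om, function(m) {
      omics_matrix(unclass(m)[keep, , drop = FALSE], attr(m, "omics_name"))
    })
    names(om) <- vapply(om, attr, "", "omics_name")
  }
  structure(list(omics = om, labels = lab), class = "multiomics_dataset")
}
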