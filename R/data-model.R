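#' Construct a multi-location protein dataset
#'
#' Bundles a numeric feature table and a binary location-indicator table into
#' a single dataset object, the input type consumed by every other function
#' in the package. Each protein carries a feature vector
#' \eqn{f^P = (f_1^P, \dots, f_d^P)} and, when labeled, a location-indicator
#' vector \eqn{l^P = (l_1^P, \dots, l_q^P)} with \eqn{l_i^P = 1} iff the
#' protein localizes to compartment \eqn{s_i}.
#'
#' @param features A data frame with an `id` column followed by `d` numeric
#'   feature columns (one row per protein).
#' @param labels Optional. Either a data frame with an `id` column plus `q`
#'   0/1 indicator columns (column names define the location vocabulary), or
#'   a data frame with columns `id` and `locations` where `locations` holds
#'   comma-separated location names. `NULL` for unlabeled query proteins.
#' @param locations Optional character vector fixing the location vocabulary
#'   (its order defines indicator positions). Required information when
#'   `labels` uses the name-list form and the full vocabulary should exceed
#'   the names observed; otherwise inferred.
#'
#' @return An object of class `multiloc_dataset`: a list with elements `ids`,
#'   `x` (n x d numeric feature matrix), `y` (n x q 0/1 integer matrix, or
#'   `NULL` when unlabeled), `feature_names`, `locations`, and `discrete`
#'   (whether `x` holds integer codes from [mdlp_apply()]).
#'
#' @examples
#' feats <- tibble::tibble(id = c("p1", "p2"), f1 = c(0.2, 1.4), f2 = c(3, 5))
#' labs <- tibble::tibble(id = c("p1", "p2"), cyt = c(1, 0), nuc = c(1, 1))
#' multiloc_dataset(feats, labs)
#' @export
multiloc_dataset <- function(features, labels = NULL, locations = NULL) {
  features <- as.data.frame(features)
  if (!"id" %in% names(features)) {
    abort("`features` must contain an `id` column.")
  }
  ids <- as.character(features$id)
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicated protein ids in `features`: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  fcols <- setdiff(names(features), "id")
  if (length(fcols) < 1) abort("`features` must contain at least one feature column.")
  x <- as.matrix(features[fcols])
  if (!is.numeric(x)) {
    bad <- which(!vapply(features[fcols], is.numeric, logical(1)))
    abort(paste0(
      "Non-numeric feature column(s): ", paste(fcols[bad], collapse = ", ")
    ))
  }
  if (anyNA(x)) abort("Feature values must not be missing.")
  dimnames(x) <- list(NULL, fcols)

  y <- NULL
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (!"id" %in% names(labels)) abort("`labels` must contain an `id` column.")
    lab_ids <- as.character(labels$id)
    missing_in_labels <- setdiff(ids, lab_ids)
    missing_in_features <- setdiff(lab_ids, ids)
    if (length(missing_in_labels) || length(missing_in_features)) {
      abort(paste0(
        "Protein ids do not match between features and labels.",
        if (length(missing_in_labels)) {
          paste0(
            "\n  In features but not labels: ",
            paste(missing_in_labels, collapse = ", ")
          )
        } else "",
        if (length(missing_in_features)) {
          paste0(
            "\n  In labels but not features: ",
            paste(missing_in_features, collapse = ", ")
          )
        } else ""
      ))
    }
    labels <- labels[match(ids, lab_ids), , drop = FALSE]
    y <- parse_label_frame(labels, locations)
    empty <- which(rowSums(y) == 0)
    if (length(empty)) {
      abort(paste0(
        "Labeled proteins must have at least one positive location; ",
        "offending id(s): ", paste(ids[empty], collapse = ", ")
      ))
    }
  }
  q <- if (is.null(y)) length(locations) else ncol(y)
  if (!is.null(y) && q < 2) abort("At least two locations are required.")

  structure(
    list(
      ids = ids,
      x = x,
      y = y,
      feature_names = fcols,
      locations = if (is.null(y)) locations else colnames(y),
      discrete = FALSE
    ),
    class = "multiloc_dataset"
  )
}

# Turn the label frame (indicator columns or a comma-separated name column)
# into an n x q 0/1 integer matrix with location names as colnames.
parse_label_frame <- function(labels, locations) {
  other <- setdiff(names(labels), "id")
  if (identical(other, "locations")) {
    sets <- strsplit(trimws(as.character(labels$locations)), "\\s*,\\s*")
    sets <- lapply(sets, function(s) s[nzchar(s)])
    seen <- unique(unlist(sets))
    if (is.null(locations)) {
      locations <- sort(seen)
    } else {
      unknown <- setdiff(seen, locations)
      if (length(unknown)) {
        abort(paste0(
          "Unknown location name(s) not in the supplied vocabulary: ",
          paste(unknown, collapse = ", ")
        ))
      }
    }
    y <- matrix(0L, nrow(labels), length(locations),
      dimnames = list(NULL, locations)
    )
    for (i in seq_along(sets)) y[i, match(sets[[i]], locations)] <- 1L
    return(y)
  }
  if (!is.null(locations)) {
    unknown <- setdiff(other, locations)
    if (length(unknown)) {
      abort(paste0(
        "Unknown location column(s) not in the supplied vocabulary: ",
        paste(unknown, collapse = ", ")
      ))
    }
    other <- intersect(locations, other)
    if (!setequal(other, locations)) {
      abort("Label columns must cover the supplied vocabulary.")
    }
  }
  y <- as.matrix(labels[other])
  if (!is_binary01(y)) abort("Label columns must contain only 0/1 values.")
  storage.mode(y) <- "integer"
  dimnames(y) <- list(NULL, other)
  y
}

#' @export
print.multiloc_dataset <- function(x, ...) {
  cat(sprintf(
    "<multiloc_dataset> %d proteins, %d features (%s), %s\n",
    length(x$ids), length(x$feature_names),
    if (x$discrete) "discrete codes" else "numeric",
    if (is.null(x$y)) {
      "unlabeled"
    } else {
      sprintf("%d locations [%s]", ncol(x$y), paste(colnames(x$y), collapse = ", "))
    }
  ))
  invisible(x)
}

#' @export
#' @importFrom tibble as_tibble
as_tibble.multiloc_dataset <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$x))
  out <- tibble::add_column(out, id = x$ids, .before = 1)
  if (!is.null(x$y)) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(x$y)))
  }
  out
}

n_records <- function(dataset) length(dataset$ids)
n_features <- function(dataset) length(dataset$feature_names)
n_locations <- function(dataset) length(dataset$locations)

# Subset a dataset by row indices, preserving order and metadata.
dataset_slice <- function(dataset, idx) {
  out <- dataset
  out$ids <- dataset$ids[idx]
  out$x <- dataset$x[idx, , drop = FALSE]
  if (!is.null(dataset$y)) out$y <- dataset$y[idx, , drop = FALSE]
  out
}

require_labels <- function(dataset, what = "this operation") {
  if (is.null(dataset$y)) {
    abort(paste0("A labeled dataset is required for ", what, "."))
  }
  invisible(dataset)
}

#' Read a multi-location dataset from delimited text files
#'
#' Reads a feature table and a label table (TSV or CSV, autodetected from the
#' header line), joins them on the `id` column, and returns a
#' [multiloc_dataset()]. Record order follows the features file.
#'
#' @param features_path Path to the feature table: header `id,<f1>,...,<fd>`,
#'   numeric cells, `.` decimal separator.
#' @param labels_path Path to the label table: header `id,<loc1>,...,<locq>`
#'   with 0/1 cells, or `id,locations` with comma-separated location names.
#'   `NULL` to load unlabeled query proteins.
#' @param locations Optional fixed location vocabulary (see
#'   [multiloc_dataset()]).
#' @return A `multiloc_dataset`.
#' @export
read_multiloc <- function(features_path, labels_path = NULL, locations = NULL) {
  features <- read_delim_auto(features_path)
  fcols <- setdiff(names(features), "id")
  for (cl in fcols) {
    v <- features[[cl]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric feature value '%s' at row %d, column '%s' of %s",
        v[bad[1]], bad[1], cl, features_path
      ))
    }
    features[[cl]] <- num
  }
  labels <- if (!is.null(labels_path)) read_delim_auto(labels_path) else NULL
  multiloc_dataset(features, labels, locations = locations)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path,
    header = TRUE, sep = sep, colClasses = "character",
    check.names = FALSE, stringsAsFactors = FALSE, quote = "\"",
    comment.char = "", fileEncoding = "UTF-8"
  )
}

#' Write a multi-location dataset to delimited text files
#'
#' Inverse of [read_multiloc()]: feature values are written in full precision
#' so that a read/write round trip is exact.
#'
#' @param dataset A `multiloc_dataset`.
#' @param features_path,labels_path Output paths (TSV). `labels_path` is
#'   ignored for unlabeled datasets.
#' @return `dataset`, invisibly.
#' @export
write_multiloc <- function(dataset, features_path, labels_path = NULL) {
  stopifnot(inherits(dataset, "multiloc_dataset"))
  fdf <- data.frame(id = dataset$ids, stringsAsFactors = FALSE)
  for (j in seq_along(dataset$feature_names)) {
    v <- dataset$x[, j]
    fdf[[dataset$feature_names[j]]] <-
      if (dataset$discrete) format(as.integer(v)) else num_to_chr(v)
  }
  utils::write.table(fdf, features_path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  if (!is.null(dataset$y) && !is.null(labels_path)) {
    ldf <- data.frame(id = dataset$ids, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(dataset$y))) {
      ldf[[colnames(dataset$y)[j]]] <- dataset$y[, j]
    }
    utils::write.table(ldf, labels_path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, fileEncoding = "UTF-8"
    )
  }
  invisible(dataset)
}

#' Stratified fold assignment for multi-labeled data
#'
#' Splits a labeled dataset into `k` disjoint folds. Stratification groups
#' proteins by their exact label combination (e.g. all `cyt+nuc` proteins form
#' one stratum) and spreads each stratum as evenly as possible across folds,
#' so per-combination fold counts differ by at most one, as do total fold
#' sizes. The assignment is fully determined by `(dataset order, k, seed)`.
#'
#' @param dataset A labeled `multiloc_dataset`.
#' @param k Number of folds (`2 <= k <=` number of records).
#' @param seed Integer seed controlling the within-stratum shuffle.
#' @return A list of `k` integer vectors of record indices (sorted within
#'   fold), jointly partitioning `1:n`.
#' @export
split_stratified <- function(dataset, k, seed) {
  require_labels(dataset, "stratified splitting")
  n <- n_records(dataset)
  k <- as.integer(k)
  if (k < 2) abort("`k` must be at least 2.")
  if (k > n) abort(sprintf("`k` (%d) exceeds the number of records (%d).", k, n))

  key <- apply(dataset$y, 1, paste, collapse = "")
  strata <- split(seq_len(n), key)
  # Largest strata first; deterministic tie-break by key.
  ord <- order(-lengths(strata), names(strata))
  strata <- strata[ord]

  fold_of <- integer(n)
  totals <- integer(k)
  with_seed(seed, {
    for (members in strata) {
      members <- members[sample.int(length(members))]
      scount <- integer(k)
      tie <- sample.int(k) # per-stratum deterministic tie-break among folds
      for (m in members) {
        cand <- which(scount == min(scount))
        cand <- cand[totals[cand] == min(totals[cand])]
        f <- cand[which.min(tie[cand])]
        fold_of[m] <- f
        scount[f] <- scount[f] + 1L
        totals[f] <- totals[f] + 1L
      }
    }
  })
  lapply(seq_len(k), function(f) sort(which(fold_of == f)))
}
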