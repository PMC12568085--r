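#' Build a dataset bundle from samples
#'
#' A bundle is the unit of leave-one-subject-out bookkeeping: a tibble with a
#' `trajectory` list-column plus `label`, `subject_id`, `trial_index` and
#' `provenance` columns, carrying the declared (ordered) class set and a
#' dataset name as attributes. Class order is the lexicographic sort of the
#' labels, which fixes the logit ordering with no hidden state.
#'
#' @param samples A tibble/data frame with columns `trajectory` (list of
#'   `eyw_traj`), `label`, `subject_id`, `trial_index`, and optionally
#'   `provenance` (defaults to `"raw"`).
#' @param class_set Optional ordered character vector of class labels;
#'   defaults to the sorted unique labels.
#' @param name Dataset name.
#' @return A tibble of class `eyw_bundle`.
#' @export
bundle <- function(samples, class_set = NULL, name = "dataset") {
  samples <- as_tibble(samples)
  req <- c("trajectory", "label", "subject_id", "trial_index")
  missing <- setdiff(req, names(samples))
  if (length(missing) > 0) {
    abort(paste0("samples are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"provenance" %in% names(samples)) samples$provenance <- "raw"
  samples$label <- as.character(samples$label)
  samples$subject_id <- as.character(samples$subject_id)
  samples$trial_index <- as.integer(samples$trial_index)
  if (is.null(class_set)) class_set <- sort(unique(samples$label))
  class_set <- as.character(class_set)
  if (!all(samples$label %in% class_set)) {
    abort("every sample label must belong to the class set.")
  }
  if (length(class_set) < 2) abort("a bundle needs at least 2 classes.")
  if (length(unique(samples$subject_id)) < 2) {
    abort("a bundle needs at least 2 distinct subjects (LOSO requires >= 2).")
  }
  structure(samples, class_set = class_set, dataset_name = name,
            class = c("eyw_bundle", class(tibble())))
}

#' Declared class set of a bundle
#' @param x An `eyw_bundle` (or sample tibble; falls back to sorted labels).
#' @return Ordered character vector of class labels.
#' @export
class_set <- function(x) {
  attr(x, "class_set") %||% sort(unique(as.character(x$label)))
}

#' Load a dataset bundle from a manifest CSV
#'
#' The manifest has one row per sample, with columns `file` (trajectory CSV,
#' relative to the manifest's directory unless absolute), `label`,
#' `subject_id`, `trial_index`. All loaded samples carry `provenance = "raw"`.
#'
#' @param path Path to the manifest CSV.
#' @param name Dataset name; defaults to the manifest file name.
#' @return An `eyw_bundle`.
#' @export
load_manifest <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  mf <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("file", "label", "subject_id", "trial_index")
  missing <- setdiff(req, names(mf))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ", paste(missing, collapse = ", ")))
  }
  key <- paste(mf$subject_id, mf$label, mf$trial_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- mf[duplicated(key), , drop = FALSE][1, ]
    abort(sprintf("duplicate (subject, label, trial) key in manifest: (%s, %s, %s)",
                  d$subject_id, d$label, d$trial_index))
  }
  base <- dirname(path)
  files <- ifelse(grepl("^(/|[A-Za-z]:)", mf$file), mf$file, file.path(base, mf$file))
  gone <- files[!file.exists(files)]
  if (length(gone) > 0) {
    abort(paste0("manifest references missing trajectory file(s): ",
                 paste(head(gone, 3), collapse = ", ")))
  }
  samples <- tibble(
    trajectory = lapply(files, read_trajectory_csv),
    label = as.character(mf$label),
    subject_id = as.character(mf$subject_id),
    trial_index = as.integer(mf$trial_index),
    provenance = "raw")
  bundle(samples, name = name %||% basename(path))
}

#' Write a bundle as trajectory CSVs plus a manifest
#'
#' @param x An `eyw_bundle`.
#' @param dir Output directory (created if needed).
#' @param manifest Manifest file name within `dir`.
#' @return The manifest path, invisibly.
#' @export
write_bundle <- function(x, dir, manifest = "manifest.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("s%s_%s_t%02d.csv", x$subject_id, x$label, x$trial_index)
  for (i in seq_len(nrow(x))) {
    write_trajectory_csv(x$trajectory[[i]], file.path(dir, files[i]))
  }
  mf <- data.frame(file = files, label = x$label, subject_id = x$subject_id,
                   trial_index = x$trial_index)
  path <- file.path(dir, manifest)
  lines <- c("file,label,subject_id,trial_index",
             sprintf("%s,%s,%s,%d", mf$file, mf$label, mf$subject_id, mf$trial_index))
  writeLines(lines, path)
  invisible(path)
}

#' Leave-one-subject-out splits
#'
#' Builds one train/test split per distinct subject: the held-out subject's
#' samples form the test set and every other subject's samples form the
#' training set. Splits are ordered by subject id, so the result is a pure
#' function of the bundle.
#'
#' @param x An `eyw_bundle` (raw samples; augmented samples are rejected to
#'   keep augmentation leakage structurally impossible).
#' @return A tibble with columns `test_subject`, `train` and `test`
#'   (list-columns of sample tibbles).
#' @export
loso_splits <- function(x) {
  if (any(x$provenance != "raw")) {
    abort("loso_splits() expects raw samples only; augment within training folds.")
  }
  subjects <- sort(unique(x$subject_id))
  if (length(subjects) < 2) abort("LOSO needs at least 2 subjects.")
  tibble(
    test_subject = subjects,
    train = lapply(subjects, function(s) x[x$subject_id != s, , drop = FALSE]),
    test = lapply(subjects, function(s) x[x$subject_id == s, , drop = FALSE]))
}

#' Validate a bundle's structural invariants
#'
#' @param x An `eyw_bundle`.
#' @return Invisibly, a list with `n_samples`, `n_subjects`, `n_classes`;
#'   errors describe the first violated invariant.
#' @export
validate_bundle <- function(x) {
  cs <- class_set(x)
  if (!all(x$label %in% cs)) abort("label outside the declared class set.")
  if (length(cs) < 2) abort("fewer than 2 classes.")
  if (length(unique(x$subject_id)) < 2) abort("fewer than 2 subjects.")
  ok <- vapply(x$trajectory, function(tr) {
    nrow(tr) >= 1 && all(is.finite(tr$x)) && all(is.finite(tr$y))
  }, logical(1))
  if (!all(ok)) abort(sprintf("invalid trajectory at sample %d.", which(!ok)[1]))
  invisible(list(n_samples = nrow(x), n_subjects = length(unique(x$subject_id)),
                 n_classes = length(cs)))
}
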