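#' Construct a dataset manifest
#'
#' The manifest is the single source of subject/class truth: one row per
#' recording with subject, class, category and (optionally) a file path.
#' File names are never parsed for metadata.
#'
#' @param entries `data.frame` with columns `recording_id`, `subject_id`,
#'   `class_label`, `category`, and optionally `file_path`.
#' @param class_universe Ordered class labels; defaults to the sorted unique
#'   labels present.
#' @param subject_universe Ordered subject ids; defaults likewise.
#' @return An object of class `eeg_manifest` (a validated data.frame).
#' @export
eeg_manifest <- function(entries, class_universe = NULL,
                         subject_universe = NULL) {
  req <- c("recording_id", "subject_id", "class_label", "category")
  if (!is.data.frame(entries) || nrow(entries) == 0L) {
    stop("manifest must be a non-empty data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  entries[req] <- lapply(entries[req], as.character)
  if (anyDuplicated(entries$recording_id)) {
    dup <- entries$recording_id[duplicated(entries$recording_id)][1]
    stop("duplicate recording_id in manifest: ", dup, call. = FALSE)
  }
  bad_cat <- setdiff(unique(entries$category),
                     c("characters", "digits", "objects"))
  if (length(bad_cat) > 0L) {
    stop("unknown category token in manifest: ", bad_cat[1], call. = FALSE)
  }
  if (is.null(class_universe)) class_universe <- sort(unique(entries$class_label))
  if (is.null(subject_universe)) subject_universe <- sort(unique(entries$subject_id))
  if (!all(entries$class_label %in% class_universe)) {
    stop("manifest contains class labels outside the class universe",
         call. = FALSE)
  }
  structure(entries, class = c("eeg_manifest", "data.frame"),
            class_universe = class_universe,
            subject_universe = subject_universe)
}

#' @export
print.eeg_manifest <- function(x, ...) {
  cat(sprintf("<eeg_manifest> %d recordings, %d subjects, %d classes\n",
              nrow(x), length(unique(x$subject_id)),
              length(attr(x, "class_universe"))))
  invisible(x)
}

#' Load a manifest from TSV or JSON
#'
#' @param path Path to a TSV (with header) or JSON array of records.
#' @return An `eeg_manifest`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    entries <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    entries <- utils::read.table(path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
  }
  if (nrow(entries) == 0L) stop("manifest at ", path, " is empty", call. = FALSE)
  eeg_manifest(entries)
}

#' Write a manifest to TSV
#' @param manifest An `eeg_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter a manifest to one classification setting
#'
#' The five settings of increasing vocabulary size: each single category
#' (10 classes), characters + digits (20), or all three categories (30).
#' Optionally drops subjects lacking complete class coverage for the
#' requested setting, mirroring the exclusion of incompletely recorded
#' subjects from the benchmark.
#'
#' @param manifest An `eeg_manifest`.
#' @param setting One of `"characters"`, `"digits"`, `"objects"`,
#'   `"chardig"`, `"chardigobj"`.
#' @param complete_subjects_only Drop subjects without all classes of the
#'   setting (default `TRUE`).
#' @return A filtered `eeg_manifest`.
#' @export
filter_setting <- function(manifest,
                           setting = c("characters", "digits", "objects",
                                       "chardig", "chardigobj"),
                           complete_subjects_only = TRUE) {
  setting <- match.arg(setting)
  cats <- switch(setting,
                 characters = "characters", digits = "digits",
                 objects = "objects",
                 chardig = c("characters", "digits"),
                 chardigobj = c("characters", "digits", "objects"))
  df <- as.data.frame(manifest)
  df <- df[df$category %in% cats, , drop = FALSE]
  if (nrow(df) == 0L) stop("no recordings match setting ", setting, call. = FALSE)
  classes <- sort(unique(df$class_label))
  if (complete_subjects_only) {
    keep <- vapply(split(df$class_label, df$subject_id),
                   function(cl) all(classes %in% cl), logical(1))
    df <- df[df$subject_id %in% names(keep)[keep], , drop = FALSE]
    if (nrow(df) == 0L) {
      stop("no subject has complete class coverage for setting ", setting,
           call. = FALSE)
    }
  }
  eeg_manifest(df, class_universe = classes,
               subject_universe = sort(unique(df$subject_id)))
}
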