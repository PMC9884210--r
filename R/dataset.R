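#' Read and code a subject table
#'
#' Reads a comma-separated subject table (one row per subject, header
#' required) and codes every column against the schema: cells may hold
#' category labels directly, or raw numeric measurements for variables that
#' carry a [coding_rule()].
#'
#' @param path CSV file path.
#' @param schema Named list of [variable_spec()]s; every CSV column must
#'   appear in it.
#' @param quiet Suppress the row-count message.
#' @return A tibble whose columns are factors with the schema's state
#'   labels as levels, in schema state order.
#' @export
load_dataset <- function(path, schema, quiet = FALSE) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown) > 0L) {
    abort(paste0("columns not in schema: ", paste(unknown, collapse = ", ")))
  }
  out <- purrr::imap(raw, function(col, nm) code_column(col, schema[[nm]]))
  out <- tibble::as_tibble(out)
  if (!quiet) inform(sprintf("loaded %d subjects, %d variables from %s",
                             nrow(out), ncol(out), path))
  out
}

# Map one character column (labels or raw numerics) onto schema states.
code_column <- function(col, spec) {
  res <- factor(rep(NA_character_, length(col)), levels = spec$states)
  missing <- is.na(col) | col == ""
  is_label <- col %in% spec$states
  res[is_label] <- col[is_label]
  todo <- !missing & !is_label
  if (any(todo)) {
    if (is.null(spec$coding)) {
      bad <- which(todo)[1L]
      abort(sprintf("cannot code value '%s' (row %d, column %s): not a state label and no coding rule",
                    col[bad], bad, spec$name))
    }
    num <- suppressWarnings(as.numeric(col[todo]))
    if (any(is.na(num))) {
      bad <- which(todo)[which(is.na(num))[1L]]
      abort(sprintf("cannot code value '%s' (row %d, column %s)",
                    col[bad], bad, spec$name))
    }
    res[todo] <- code_value(num, spec$coding)
  }
  res
}

#' Write a coded dataset as labelled CSV
#'
#' Inverse of [load_dataset()] up to coding: category labels are written as
#' text so that reloading reproduces the cells exactly.
#'
#' @param dataset A coded tibble of factors.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  out <- dplyr::mutate(dataset, dplyr::across(dplyr::everything(),
                                              as.character))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Complete-case and age exclusions
#'
#' Removes subjects with any missing cell (complete-case rule) and, when an
#' `Age` column in years is supplied separately or the coded `Age` factor is
#' missing, subjects below the minimum age. Mirrors the study design of
#' enrolling residents over 40 with complete records.
#'
#' @param dataset Tibble of factors, possibly containing `NA` cells.
#' @param min_age Minimum age in years; rows of `age_years` below it are
#'   dropped. Ignored when `age_years` is `NULL`.
#' @param age_years Optional numeric vector of raw ages, one per row.
#' @param quiet Suppress the exclusion-count message.
#' @return The filtered tibble; errors if no rows survive.
#' @export
apply_exclusions <- function(dataset, min_age = 40, age_years = NULL,
                             quiet = FALSE) {
  keep <- stats::complete.cases(dataset)
  if (!is.null(age_years)) {
    stopifnot(length(age_years) == nrow(dataset))
    keep <- keep & !is.na(age_years) & age_years >= min_age
  }
  dropped <- sum(!keep)
  out <- dataset[keep, , drop = FALSE]
  if (nrow(out) == 0L) abort("no subjects remain after exclusions")
  if (!quiet) inform(sprintf("excluded %d of %d subjects", dropped,
                             length(keep)))
  out
}
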