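# Trial-level data handling: the user-facing format is a tidy tibble with one
# row per trial (columns subject, trial, choice, outcome, and task-specific
# stimulus / state2 / choice2); internally each subject becomes a plain list
# consumed by the compiled likelihoods.

# Coerce trial data to a named list of internal subject lists.
split_subjects <- function(data) {
  if (is.data.frame(data)) {
    stopifnot(!is.null(data$subject), !is.null(data$choice),
              !is.null(data$outcome))
    ids <- unique(data$subject)
    out <- lapply(ids, function(id) as_subject(data[data$subject == id, ]))
    names(out) <- as.character(ids)
    return(out)
  }
  stopifnot(is.list(data), length(data) >= 1)
  out <- lapply(data, as_subject)
  if (is.null(names(out)) || any(names(out) == "")) {
    names(out) <- paste0("s", seq_along(out))
  }
  out
}

#' Read and write trial-level subject data
#'
#' CSV files hold one row per trial with columns `subject`, `trial`,
#' `choice`, `outcome` and, where the task requires them, `stimulus`,
#' `state2`, `choice2`. JSON files hold a list of subjects with the same
#' keys as vectors.
#'
#' @param path File path (`.csv` or `.json`).
#' @return A trials tibble.
#' @export
read_subject_data <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    subs <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- purrr::imap(subs, function(s, id) {
      tibble::tibble(subject = id, trial = seq_along(s$choice),
                     choice = as.integer(s$choice),
                     outcome = as.double(s$outcome),
                     stimulus = if (!is.null(s$stimulus)) as.integer(s$stimulus) else NULL,
                     state2 = if (!is.null(s$state2)) as.integer(s$state2) else NULL,
                     choice2 = if (!is.null(s$choice2)) as.integer(s$choice2) else NULL)
    })
    return(dplyr::bind_rows(out))
  }
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_subject_data
#' @param data Trials tibble.
#' @export
write_subject_data <- function(data, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    subs <- split_subjects(data)
    jsonlite::write_json(subs, path, auto_unbox = FALSE, digits = NA)
  } else {
    readr::write_csv(data, path)
  }
  invisible(path)
}
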