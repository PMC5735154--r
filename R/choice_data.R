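#' Construct a choice dataset
#'
#' A `choice_dataset` holds a long table of two-alternative forced-choice
#' trials together with the number of items in the choice set. Each trial
#' records which of two items a subject chose; the exhaustive design presents
#' every unordered pair of the `n_items` items exactly once per subject and
#' task, i.e. `n_items * (n_items - 1) / 2` trials.
#'
#' @param trials data frame with columns `subject_id` (character), `group`
#'   (one of CON, ETL, MTL), `task` (one of "preference", "number"),
#'   `trial_index` (integer >= 1, position within the subject's session),
#'   `item_a`, `item_b` (integer item codes), `choice` (the chosen item code,
#'   `NA` for a missing response) and `rt` (response time in seconds, may be
#'   `NA`).
#' @param n_items number of items in the choice set (>= 3 for triplet
#'   scoring; >= 2 accepted for raw storage).
#' @param item_labels optional named character vector mapping item codes
#'   (as names) to display labels.
#' @return An object of class `choice_dataset`: a list with elements
#'   `trials` (tibble), `n_items` and `item_labels`.
#' @export
choice_dataset <- function(trials, n_items, item_labels = NULL) {
  required <- c("subject_id", "group", "task", "trial_index",
                "item_a", "item_b", "choice", "rt")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop("trials is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials <- tibble::as_tibble(trials)[required]
  trials$subject_id <- as.character(trials$subject_id)
  trials$group <- as.character(trials$group)
  trials$task <- as.character(trials$task)
  for (col in c("trial_index", "item_a", "item_b", "choice")) {
    trials[[col]] <- as.integer(trials[[col]])
  }
  trials$rt <- as.numeric(trials$rt)

  n_items <- as.integer(n_items)
  if (is.na(n_items) || n_items < 2) {
    stop("n_items must be an integer >= 2", call. = FALSE)
  }
  bad_same <- which(trials$item_a == trials$item_b)
  if (length(bad_same) > 0) {
    stop("item_a equals item_b in row(s): ",
         paste(utils::head(bad_same, 10), collapse = ", "), call. = FALSE)
  }
  bad_choice <- which(!is.na(trials$choice) &
                        trials$choice != trials$item_a &
                        trials$choice != trials$item_b)
  if (length(bad_choice) > 0) {
    stop("choice is not a member of its pair in row(s): ",
         paste(utils::head(bad_choice, 10), collapse = ", "), call. = FALSE)
  }
  out_of_range <- which(trials$item_a < 1L | trials$item_a > n_items |
                          trials$item_b < 1L | trials$item_b > n_items)
  if (length(out_of_range) > 0) {
    stop("item codes outside 1..n_items in row(s): ",
         paste(utils::head(out_of_range, 10), collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(trials$rt) & trials$rt < 0)) {
    stop("negative response times are not allowed", call. = FALSE)
  }
  structure(
    list(trials = trials, n_items = n_items, item_labels = item_labels),
    class = "choice_dataset"
  )
}

#' @export
print.choice_dataset <- function(x, ...) {
  nsub <- length(unique(x$trials$subject_id))
  cat(sprintf(
    "<choice_dataset> %d trials, %d subject(s), %d item(s), tasks: %s\n",
    nrow(x$trials), nsub, x$n_items,
    paste(sort(unique(x$trials$task)), collapse = ", ")
  ))
  invisible(x)
}

#' Reader dialect for delimited choice tables
#'
#' @param sep field separator (default comma).
#' @param columns named character vector mapping the canonical column names
#'   (`subject_id`, `group`, `task`, `trial_index`, `item_a`, `item_b`,
#'   `choice`, `rt`) to the names used in the file. Unmapped names are
#'   assumed identical.
#' @param rt_unit `"s"` (default) or `"ms"`; millisecond inputs are divided
#'   by 1000 on read so the in-memory unit is always seconds.
#' @param na_strings strings treated as missing values.
#' @return A list of class `choice_dialect`.
#' @export
choice_dialect <- function(sep = ",", columns = character(), rt_unit = c("s", "ms"),
                           na_strings = c("NA", "")) {
  rt_unit <- match.arg(rt_unit)
  structure(list(sep = sep, columns = columns, rt_unit = rt_unit,
                 na_strings = na_strings),
            class = "choice_dialect")
}

.canonical_cols <- c("subject_id", "group", "task", "trial_index",
                     "item_a", "item_b", "choice", "rt")

#' Read a delimited table of forced-choice trials
#'
#' Reads a long-format delimited text file (one row per trial) into a
#' [choice_dataset()]. Item codes are normalised to `1..n_items` by rank of
#' their sorted unique values; the original codes are kept as `item_labels`
#' when they differ. Malformed rows (non-numeric item codes or trial
#' indices, a choice that is neither member of its pair) are reported by
#' line number rather than silently dropped.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect a [choice_dialect()].
#' @param n_items optional; inferred from the data when `NULL`.
#' @return A [choice_dataset()].
#' @export
read_choice_table <- function(path, dialect = choice_dialect(), n_items = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           na.strings = dialect$na_strings,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  colmap <- dialect$columns
  for (canon in .canonical_cols) {
    file_name <- if (canon %in% names(colmap)) colmap[[canon]] else canon
    if (!file_name %in% names(raw)) {
      stop(sprintf("missing required column '%s' (looked for '%s') in %s",
                   canon, file_name, path), call. = FALSE)
    }
    names(raw)[names(raw) == file_name] <- canon
  }
  raw <- raw[.canonical_cols]

  to_num <- function(x) suppressWarnings(as.numeric(x))
  num_cols <- c("trial_index", "item_a", "item_b", "choice", "rt")
  parsed <- lapply(raw[num_cols], to_num)
  # choice and rt may legitimately be NA; others may not
  bad <- (is.na(parsed$trial_index) & !is.na(raw$trial_index)) |
    is.na(parsed$item_a) | is.na(parsed$item_b) |
    (is.na(parsed$choice) & !is.na(raw$choice)) |
    (is.na(parsed$rt) & !is.na(raw$rt)) |
    is.na(raw$trial_index) | is.na(raw$item_a) | is.na(raw$item_b)
  if (any(bad)) {
    stop("unparseable row(s) at line(s): ",
         paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  df <- tibble::tibble(
    subject_id = raw$subject_id, group = raw$group, task = raw$task,
    trial_index = as.integer(parsed$trial_index),
    item_a = as.integer(parsed$item_a),
    item_b = as.integer(parsed$item_b),
    choice = as.integer(parsed$choice),
    rt = parsed$rt
  )
  if (dialect$rt_unit == "ms") df$rt <- df$rt / 1000

  codes <- sort(unique(c(df$item_a, df$item_b)))
  item_labels <- NULL
  if (!identical(codes, seq_along(codes))) {
    remap <- stats::setNames(seq_along(codes), codes)
    item_labels <- stats::setNames(as.character(codes), seq_along(codes))
    df$item_a <- unname(remap[as.character(df$item_a)])
    df$item_b <- unname(remap[as.character(df$item_b)])
    df$choice <- unname(remap[as.character(df$choice)])
  }
  if (is.null(n_items)) n_items <- max(length(codes), 2L)
  choice_dataset(df, n_items = n_items, item_labels = item_labels)
}

#' Write a choice dataset to delimited text
#'
#' Rows are ordered by (subject_id, task, trial_index) and columns are in
#' the canonical order, so the output is deterministic and
#' [read_choice_table()] inverts it exactly.
#'
#' @param ds a [choice_dataset()].
#' @param path output file path.
#' @param sep field separator.
#' @return Invisibly, `path`.
#' @export
write_choice_table <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "choice_dataset"))
  tr <- ds$trials
  tr <- tr[order(tr$subject_id, tr$task, tr$trial_index), ]
  utils::write.table(tr, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Validate the complete-pairwise design of a choice dataset
#'
#' Checks, per subject and task, that every unordered pair of items appears
#' exactly once, that trial indices form a permutation of `1..n_trials`, and
#' that no responses are missing. Defects are returned as data, not raised
#' as errors.
#'
#' @param ds a [choice_dataset()].
#' @return An object of class `validation_report`: a list with `is_complete`
#'   (TRUE iff all defect tables are empty), `missing_pairs`,
#'   `duplicate_pairs` and `irregular_trials` tibbles.
#' @export
validate_design <- function(ds) {
  stopifnot(inherits(ds, "choice_dataset"))
  if (nrow(ds$trials) == 0) stop("dataset has no trials", call. = FALSE)
  n <- ds$n_items
  all_pairs <- enumerate_pairs(n)
  all_keys <- paste(all_pairs[, 1], all_pairs[, 2], sep = "-")

  tr <- ds$trials
  lo <- pmin(tr$item_a, tr$item_b)
  hi <- pmax(tr$item_a, tr$item_b)
  key <- paste(lo, hi, sep = "-")
  grp <- paste(tr$subject_id, tr$task, sep = "\r")

  missing_pairs <- list(); duplicate_pairs <- list(); irregular <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sid <- tr$subject_id[idx[1]]; task <- tr$task[idx[1]]
    tab <- table(key[idx])
    miss <- setdiff(all_keys, names(tab))
    dup <- names(tab)[tab > 1]
    if (length(miss) > 0) {
      missing_pairs[[g]] <- tibble::tibble(subject_id = sid, task = task,
                                           pair = miss)
    }
    if (length(dup) > 0) {
      duplicate_pairs[[g]] <- tibble::tibble(
        subject_id = sid, task = task, pair = dup,
        n_occurrences = as.integer(tab[dup]))
    }
    ti <- sort(tr$trial_index[idx])
    bad_index <- !identical(ti, seq_along(idx))
    na_choice <- idx[is.na(tr$choice[idx])]
    if (bad_index || length(na_choice) > 0) {
      irregular[[g]] <- tibble::tibble(
        subject_id = sid, task = task,
        issue = c(if (bad_index) "trial_index not a permutation of 1..n",
                  if (length(na_choice) > 0)
                    sprintf("missing choice on %d trial(s)", length(na_choice)))
      )
    }
  }
  empty_pairs <- tibble::tibble(subject_id = character(), task = character(),
                                pair = character())
  res <- list(
    missing_pairs = if (length(missing_pairs)) dplyr::bind_rows(missing_pairs) else empty_pairs,
    duplicate_pairs = if (length(duplicate_pairs)) dplyr::bind_rows(duplicate_pairs) else
      tibble::tibble(subject_id = character(), task = character(),
                     pair = character(), n_occurrences = integer()),
    irregular_trials = if (length(irregular)) dplyr::bind_rows(irregular) else
      tibble::tibble(subject_id = character(), task = character(), issue = character())
  )
  res$is_complete <- nrow(res$missing_pairs) == 0 &&
    nrow(res$duplicate_pairs) == 0 && nrow(res$irregular_trials) == 0
  structure(res, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>",
      if (x$is_complete) "complete pairwise design\n" else "defects found\n")
  cat(sprintf("  missing pairs: %d | duplicate pairs: %d | irregular: %d\n",
              nrow(x$missing_pairs), nrow(x$duplicate_pairs),
              nrow(x$irregular_trials)))
  invisible(x)
}
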