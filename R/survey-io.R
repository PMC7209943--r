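# Rating scale -----------------------------------------------------------

# Informative answers are coded 1..4 on the ordered scale
# never < rarely < occasionally < often.  Non-informative cells carry
# sentinel codes <= 0 so that informative/uninformative splits are a single
# comparison and codes survive CSV round-trips.

#' Ordinal rating scale
#'
#' The questionnaire answers are ordinal with four informative categories,
#' `never < rarely < occasionally < often`, coded 1 to 4.  Three sentinel
#' codes mark non-informative cells:
#'
#' * `blank` (0): the respondent skipped the question (empty cell);
#' * `na_answer` (-1): an explicit "n.a." answer;
#' * `multi` (-2): more than one category was selected;
#' * `deleted` (-3): a multi-answer cell removed by [clean_survey()].
#'
#' @return `rating_labels()` returns the four informative labels in scale
#'   order; `rating_codes()` returns a named list of the sentinel codes;
#'   `is_informative()` returns a logical vector.
#' @seealso [parse_rating()], [format_rating()]
#' @export
rating_labels <- function() c("never", "rarely", "occasionally", "often")

#' @rdname rating_labels
#' @export
rating_codes <- function() {
  list(blank = 0L, na_answer = -1L, multi = -2L, deleted = -3L)
}

#' @rdname rating_labels
#' @param x integer vector of rating codes.
#' @export
is_informative <- function(x) !is.na(x) & x >= 1L & x <= 4L

#' Parse and format rating answers
#'
#' `parse_rating()` maps free-text questionnaire answers onto rating codes.
#' Category labels (or the digits 1-4) map to codes 1..4; empty cells map to
#' the blank sentinel; "n.a." variants map to the n.a. sentinel; cells
#' containing more than one category (e.g. `"often, rarely"`) map to the
#' multi-answer sentinel.  Anything unparseable maps to blank with a
#' warning.  `format_rating()` is the inverse used when writing CSV.
#'
#' @param x character vector of raw answers.
#' @param quiet suppress the unparseable-cell warning.
#' @return integer vector of rating codes.
#' @export
parse_rating <- function(x, quiet = FALSE) {
  codes <- rating_codes()
  x <- tolower(trimws(as.character(x)))
  out <- rep(codes$blank, length(x))
  out[is.na(x) | x == ""] <- codes$blank
  na_tokens <- c("n.a.", "na", "n/a", "n.a")
  out[x %in% na_tokens] <- codes$na_answer
  out[x == "[deleted]"] <- codes$deleted

  labs <- rating_labels()
  idx <- match(x, labs)
  hit <- !is.na(idx)
  out[hit] <- idx[hit]
  digit <- x %in% c("1", "2", "3", "4")
  out[digit] <- as.integer(x[digit])

  # multiple selections: >= 2 informative labels in one cell
  maybe_multi <- grepl("[,;/]", x)
  if (any(maybe_multi)) {
    n_lab <- vapply(strsplit(x[maybe_multi], "[,;/]"), function(parts) {
      sum(trimws(parts) %in% labs)
    }, integer(1))
    out[which(maybe_multi)[n_lab >= 2]] <- codes$multi
  }

  known <- hit | digit | is.na(x) | x == "" | x %in% na_tokens |
    x == "[deleted]" | out == codes$multi
  if (any(!known) && !quiet) {
    warning(sprintf("%d unparseable answer cell(s) mapped to blank", sum(!known)),
            call. = FALSE)
  }
  out
}

#' @rdname parse_rating
#' @export
format_rating <- function(x) {
  codes <- rating_codes()
  out <- character(length(x))
  out[is_informative(x)] <- rating_labels()[x[is_informative(x)]]
  out[x == codes$blank] <- ""
  out[x == codes$na_answer] <- "n.a."
  out[x == codes$multi] <- "rarely, often"
  out[x == codes$deleted] <- "[deleted]"
  out
}

# Survey table ------------------------------------------------------------

#' Construct a survey table
#'
#' A `survey_table` is a data.frame with one row per respondent carrying
#' demographics (`id`, `age`, `sex` in `{M, W, unreported}`, `country`,
#' optionally `parent`, `child_phase_noticed`, `child_phase_age`) and one
#' integer rating-code column per question.  The question columns are
#' recorded in the `questions` attribute.
#'
#' @param df data.frame with the columns above.
#' @param questions character vector naming the question columns; defaults
#'   to all columns matching `^q[0-9]+$`.
#' @return a `survey_table`.
#' @export
survey_table <- function(df, questions = NULL) {
  stopifnot(is.data.frame(df))
  if (is.null(questions)) {
    questions <- grep("^q[0-9]+$", names(df), value = TRUE)
  }
  missing_cols <- setdiff(c("id", "age", "sex", "country", questions), names(df))
  if (length(missing_cols)) {
    stop_data(sprintf("survey table is missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  bad_sex <- !df$sex %in% c("M", "W", "unreported")
  if (any(bad_sex)) {
    stop_data("sex must be one of 'M', 'W', 'unreported'")
  }
  for (q in questions) {
    v <- df[[q]]
    if (!is.numeric(v) || any(!v %in% c(1:4, unlist(rating_codes())))) {
      stop_data(sprintf("column %s holds values outside the rating code set", q))
    }
    df[[q]] <- as.integer(v)
  }
  structure(df, questions = questions,
            class = c("survey_table", "data.frame"))
}

#' @rdname survey_table
#' @param x a `survey_table`.
#' @export
survey_questions <- function(x) attr(x, "questions")

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("Survey table: %d respondents, %d questions (%s)\n",
              nrow(x), length(survey_questions(x)),
              paste(utils::head(survey_questions(x), 3), collapse = ", ")))
  cat(sprintf("  sex: %s\n",
              paste(sprintf("%s=%d", names(table(x$sex)), table(x$sex)),
                    collapse = ", ")))
  invisible(x)
}

# Keep the questions attribute through subsetting.
#' @export
`[.survey_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    qs <- intersect(attr(x, "questions"), names(out))
    attr(out, "questions") <- qs
    class(out) <- c("survey_table", "data.frame")
  }
  out
}

#' Read a questionnaire CSV
#'
#' Reads a delimited respondent table, normalizes the demographics and
#' parses every answer cell into rating codes.  Unparseable answer cells
#' are mapped to the blank sentinel with a warning; a missing mandatory
#' column is an error naming the column.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator.
#' @param questions question column names; defaults to all `^q[0-9]+$`
#'   columns found in the header.
#' @return a [survey_table()].
#' @export
read_survey <- function(path, sep = ",", questions = NULL) {
  if (!file.exists(path)) stop_data(sprintf("no such file: %s", path))
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = TRUE,
                           na.strings = NULL, quote = "\"",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop_data(sprintf("empty survey file: %s", path))
  if (is.null(questions)) {
    questions <- grep("^q[0-9]+$", names(raw), value = TRUE)
  }
  mandatory <- c("id", "age", "sex", "country")
  missing_cols <- setdiff(c(mandatory, questions), names(raw))
  if (length(missing_cols)) {
    stop_data(sprintf("survey file %s is missing column(s): %s", path,
                      paste(missing_cols, collapse = ", ")))
  }

  df <- data.frame(id = raw$id, stringsAsFactors = FALSE)
  df$age <- suppressWarnings(as.numeric(raw$age))
  df$sex <- normalize_sex(raw$sex)
  df$country <- trimws(raw$country)
  if ("parent" %in% names(raw)) {
    df$parent <- tolower(trimws(raw$parent)) %in% c("true", "yes", "1", "t")
  }
  if ("child_phase_noticed" %in% names(raw)) {
    v <- tolower(trimws(raw$child_phase_noticed))
    df$child_phase_noticed <- ifelse(v %in% c("true", "yes", "1", "t"), TRUE,
                                     ifelse(v %in% c("false", "no", "0", "f"),
                                            FALSE, NA))
  }
  if ("child_phase_age" %in% names(raw)) {
    df$child_phase_age <- suppressWarnings(as.integer(raw$child_phase_age))
  }
  for (q in questions) df[[q]] <- parse_rating(raw[[q]])
  survey_table(df, questions)
}

normalize_sex <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("unreported", length(x))
  out[x %in% c("m", "man", "male", "men")] <- "M"
  out[x %in% c("w", "f", "woman", "female", "women")] <- "W"
  out
}

#' Write a survey table as CSV
#'
#' Inverse of [read_survey()]: rating codes are written back as category
#' labels and sentinel tokens so the file round-trips.
#'
#' @param table a [survey_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_survey <- function(table, path) {
  out <- as.data.frame(table)
  for (q in survey_questions(table)) out[[q]] <- format_rating(out[[q]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

# Cleaning ----------------------------------------------------------------

#' Clean a survey table
#'
#' Applies the questionnaire exclusion rules, in this order:
#'
#' 1. every multi-answer cell is set to the deleted sentinel (an
#'    answer-level deletion, not a respondent-level exclusion);
#' 2. respondents failing the screens are removed: respondents younger than
#'    `min_age`, and respondents with at least `max_uninformative`
#'    uninformative answers (blank, "n.a.", or deleted).
#'
#' The order of the two respondent screens is configurable because a
#' respondent can qualify for both; `underage_first = TRUE` (default)
#' tallies such a respondent as underage.  Respondents with unreported sex
#' are retained (they are only dropped later, inside sex contrasts).
#'
#' @param table a [survey_table()].
#' @param min_age minimum age in years to retain (default 18).
#' @param max_uninformative a respondent with at least this many
#'   uninformative answers is excluded (default 5).
#' @param underage_first apply the age screen before the uninformative
#'   screen.
#' @return a list with elements `table` (the cleaned [survey_table()]) and
#'   `report` (a `cleaning_report` with fields `n_raw`,
#'   `n_excluded_underage`, `n_excluded_uninformative`,
#'   `n_multi_answer_deletions`, `n_retained`).
#' @export
clean_survey <- function(table, min_age = 18, max_uninformative = 5,
                         underage_first = TRUE) {
  stopifnot(inherits(table, "survey_table"))
  codes <- rating_codes()
  qs <- survey_questions(table)
  n_raw <- nrow(table)

  # answer-level multi-answer deletion first
  n_del <- 0L
  for (q in qs) {
    hit <- table[[q]] == codes$multi
    n_del <- n_del + sum(hit)
    table[[q]][hit] <- codes$deleted
  }

  ans <- as.matrix(as.data.frame(table)[, qs, drop = FALSE])
  n_uninf <- rowSums(!is_informative(ans))
  underage <- !is.na(table$age) & table$age < min_age
  too_uninf <- n_uninf >= max_uninformative

  if (underage_first) {
    n_under <- sum(underage)
    n_bad <- sum(too_uninf & !underage)
  } else {
    n_bad <- sum(too_uninf)
    n_under <- sum(underage & !too_uninf)
  }
  keep <- !underage & !too_uninf
  cleaned <- table[keep, , drop = FALSE]
  rownames(cleaned) <- NULL

  report <- structure(list(
    n_raw = n_raw,
    n_excluded_underage = n_under,
    n_excluded_uninformative = n_bad,
    n_multi_answer_deletions = n_del,
    n_retained = nrow(cleaned)
  ), class = "cleaning_report")
  stopifnot(report$n_retained ==
              report$n_raw - report$n_excluded_underage -
              report$n_excluded_uninformative)
  list(table = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Survey cleaning: %d raw respondents\n",
    "  excluded underage:              %d\n",
    "  excluded >=max uninformative:   %d\n",
    "  multi-answer cell deletions:    %d\n",
    "  retained:                       %d\n"),
    x$n_raw, x$n_excluded_underage, x$n_excluded_uninformative,
    x$n_multi_answer_deletions, x$n_retained))
  invisible(x)
}
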