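#' @importFrom rlang .data
NULL

empty_events <- function() {
  tibble::tibble(t_ms = numeric(), gesture = character(), outcome = character())
}

#' Validate level sessions against a schema
#'
#' Checks every session row: known `game_id`, level within the game's range,
#' events sorted by time and inside the level timer, legal gesture/outcome
#' codes, and `attempted = FALSE` implying an empty event list.
#'
#' @param sessions A session tibble (`child_id`, `game_id`, `level`,
#'   `attempted`, `completed`, `events` list-column of event tibbles with
#'   `t_ms`, `gesture`, `outcome`).
#' @param schema A `deep_schema`, by default the built-in battery.
#' @return `sessions`, invisibly, if valid; otherwise an error naming the
#'   first offending row.
#' @export
validate_sessions <- function(sessions, schema = deep_schema()) {
  required <- c("child_id", "game_id", "level", "attempted", "completed", "events")
  missing_cols <- setdiff(required, names(sessions))
  if (length(missing_cols) > 0) {
    stop("sessions missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  n_levels <- stats::setNames(schema$n_levels, schema$game_id)
  timer_ms <- stats::setNames(schema$level_timer_s * 1000, schema$game_id)
  for (i in seq_len(nrow(sessions))) {
    row <- sessions[i, ]
    where <- sprintf(
      "session %d (child %s, game %s, level %s)",
      i, row$child_id, row$game_id, row$level
    )
    if (!row$game_id %in% names(n_levels)) {
      stop(where, ": unknown game_id", call. = FALSE)
    }
    if (row$level < 1 || row$level > n_levels[[row$game_id]]) {
      stop(where, ": level out of range 1..", n_levels[[row$game_id]],
        call. = FALSE
      )
    }
    ev <- row$events[[1]]
    if (!row$attempted && nrow(ev) > 0) {
      stop(where, ": attempted = FALSE but events present", call. = FALSE)
    }
    if (nrow(ev) > 0) {
      if (is.unsorted(ev$t_ms)) {
        stop(where, ": event timestamps not sorted", call. = FALSE)
      }
      if (any(ev$t_ms < 0) || any(ev$t_ms > timer_ms[[row$game_id]])) {
        stop(where, ": event timestamp outside [0, level timer]", call. = FALSE)
      }
      if (!all(ev$gesture %in% c("tap", "drag"))) {
        stop(where, ": gesture must be tap or drag", call. = FALSE)
      }
      if (!all(ev$outcome %in% c("correct", "incorrect", "background"))) {
        stop(where, ": outcome must be correct, incorrect or background",
          call. = FALSE
        )
      }
    }
  }
  invisible(sessions)
}

#' Read gameplay event logs
#'
#' Reads a JSON-lines file with one level session per line, of the form
#' `{"child_id": ..., "game_id": ..., "level": ..., "attempted": ...,
#' "completed": ..., "events": [{"t_ms": ..., "gesture": ..., "outcome":
#' ...}, ...]}`, validates every record against the schema, and returns a
#' tidy session tibble with an `events` list-column.
#'
#' @param path Path to a JSON-lines event log.
#' @param schema Game schema used for validation.
#' @return A session tibble (see [validate_sessions()] for its shape),
#'   empty if the file has no lines.
#' @export
read_event_logs <- function(path, schema = deep_schema()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(
      child_id = character(), game_id = character(), level = integer(),
      attempted = logical(), completed = logical(), events = list()
    ))
  }
  parse_line <- function(line, lineno) {
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyDataFrame = TRUE),
      error = function(e) {
        stop("line ", lineno, ": malformed JSON: ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
    for (field in c("child_id", "game_id", "level", "attempted", "completed")) {
      if (is.null(rec[[field]])) {
        stop("line ", lineno, ": missing field '", field, "'", call. = FALSE)
      }
    }
    ev <- rec$events
    ev <- if (is.null(ev) || length(ev) == 0) {
      empty_events()
    } else {
      tibble::tibble(
        t_ms = as.numeric(ev$t_ms),
        gesture = as.character(ev$gesture),
        outcome = as.character(ev$outcome)
      )
    }
    row <- tibble::tibble(
      child_id = as.character(rec$child_id),
      game_id = as.character(rec$game_id),
      level = as.integer(rec$level),
      attempted = as.logical(rec$attempted),
      completed = as.logical(rec$completed),
      events = list(ev)
    )
    tryCatch(
      validate_sessions(row, schema),
      error = function(e) {
        stop("line ", lineno, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    row
  }
  purrr::list_rbind(purrr::imap(lines, parse_line))
}

#' Write gameplay event logs
#'
#' Serializes a session tibble to JSON-lines, one level session per line,
#' in row order. Writing then reading with [read_event_logs()] reproduces
#' the input exactly, and the output is byte-stable for a given input.
#'
#' @param sessions A valid session tibble.
#' @param path Output path.
#' @param schema Schema used to validate before writing.
#' @return `path`, invisibly.
#' @export
write_event_logs <- function(sessions, path, schema = deep_schema()) {
  validate_sessions(sessions, schema)
  lines <- purrr::map_chr(seq_len(nrow(sessions)), function(i) {
    row <- sessions[i, ]
    ev <- row$events[[1]]
    rec <- list(
      child_id = row$child_id, game_id = row$game_id, level = row$level,
      attempted = row$attempted, completed = row$completed,
      events = if (nrow(ev) == 0) list() else ev
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a child table
#'
#' The child table is a CSV with one row per child: identifier, age in
#' months, sex, smartphone exposure flag, preschool enrolment, the raw
#' benchmark cognitive score, the fine-motor score, and (for synthetic
#' cohorts) the latent ability that generated the data.
#'
#' @param path CSV path.
#' @return For `read_child_table()`, a tibble with typed columns.
#' @export
read_child_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    child_id = readr::col_character(),
    age_months = readr::col_double(),
    sex = readr::col_character(),
    smartphone_exposure = readr::col_logical(),
    preschool = readr::col_character(),
    bsid_cognitive_raw = readr::col_integer(),
    bsid_fine_motor = readr::col_double(),
    .default = readr::col_double()
  ))
}

#' @rdname read_child_table
#' @param children Child tibble to write.
#' @export
write_child_table <- function(children, path) {
  readr::write_csv(children, path)
  invisible(path)
}
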