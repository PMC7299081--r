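#' The default nine-game battery
#'
#' Returns the built-in game schema: nine games, each with 2--6 difficulty
#' levels summing to 40 levels in total. Each game row records its gesture
#' type, the per-level timer in seconds, and the number of correct responses
#' a child needs in a level to unlock the next one.
#'
#' The per-game level counts are configurable (see [load_schema()]); the
#' defaults place three levels on matching shapes and five on jigsaw so that
#' the feature namespace includes the deeper levels of both drag games.
#'
#' @return A `deep_schema` tibble with columns `game_id`, `name`, `n_levels`,
#'   `gesture` (one of `"tap"`, `"drag"`, `"mixed"`), `level_timer_s`, and
#'   `advance_threshold`.
#' @examples
#' deep_schema()
#' sum(deep_schema()$n_levels) # 40
#' @export
deep_schema <- function() {
  schema <- tibble::tibble(
    game_id = c("st", "at", "pb", "gg", "ho", "oo", "ms", "jig", "lr"),
    name = c(
      "single tap", "alternate tap", "popping balloons", "grow your garden",
      "hidden objects", "odd one out", "matching shapes", "jigsaw puzzles",
      "location recall"
    ),
    n_levels = c(2L, 2L, 4L, 6L, 6L, 6L, 3L, 5L, 6L),
    gesture = c("tap", "tap", "tap", "mixed", "tap", "tap", "drag", "drag", "tap"),
    level_timer_s = 60,
    advance_threshold = 5L
  )
  new_deep_schema(schema)
}

new_deep_schema <- function(x) {
  structure(x, class = c("deep_schema", class(tibble::tibble())))
}

#' Load a game schema, optionally overriding the defaults
#'
#' Reads a YAML override whose top level is a list of games mirroring the
#' columns of [deep_schema()]; fields omitted from a game fall back to the
#' default for that game. With no `config` the built-in schema is returned.
#' The result is always validated: exactly nine games, unique ids, 2--6
#' levels per game, positive timers and thresholds.
#'
#' @param config Optional path to a YAML file. Each entry must carry a
#'   `game_id`; any of `name`, `n_levels`, `gesture`, `level_timer_s`,
#'   `advance_threshold` may be overridden.
#' @return A validated `deep_schema` tibble.
#' @export
load_schema <- function(config = NULL) {
  schema <- deep_schema()
  if (!is.null(config)) {
    spec <- yaml::read_yaml(config)
    if (!is.list(spec) || length(spec) == 0) {
      stop("schema override must be a non-empty list of games", call. = FALSE)
    }
    overridden <- purrr::map(spec, function(g) {
      if (is.null(g$game_id)) {
        stop("schema override entry missing field 'game_id'", call. = FALSE)
      }
      g
    })
    ids <- purrr::map_chr(overridden, "game_id")
    unknown <- setdiff(ids, schema$game_id)
    if (length(unknown) > 0) {
      stop("schema override names unknown game_id: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    for (g in overridden) {
      i <- match(g$game_id, schema$game_id)
      for (field in intersect(
        names(g),
        c("name", "n_levels", "gesture", "level_timer_s", "advance_threshold")
      )) {
        bad <- switch(field,
          n_levels = ,
          advance_threshold = !rlang::is_scalar_integerish(g[[field]]),
          level_timer_s = !rlang::is_scalar_double(g[[field]]) &&
            !rlang::is_scalar_integerish(g[[field]]),
          !rlang::is_scalar_character(g[[field]])
        )
        if (bad) {
          stop("schema override field '", field, "' for game '", g$game_id,
            "' has the wrong type",
            call. = FALSE
          )
        }
        schema[i, field] <- g[[field]]
      }
    }
    schema$n_levels <- as.integer(schema$n_levels)
    schema$advance_threshold <- as.integer(schema$advance_threshold)
  }
  validate_schema(schema)
}

#' Validate a game schema
#'
#' Asserts the structural invariants of the battery: exactly nine games with
#' unique ids, each with 2--6 levels, positive timers and an advance
#' threshold of at least one correct response.
#'
#' @param schema A `deep_schema` tibble (or coercible data frame).
#' @return The validated schema, invisibly classed as `deep_schema`.
#' @export
validate_schema <- function(schema) {
  required <- c(
    "game_id", "name", "n_levels", "gesture", "level_timer_s",
    "advance_threshold"
  )
  missing_cols <- setdiff(required, names(schema))
  if (length(missing_cols) > 0) {
    stop("schema missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(schema) != 9) {
    stop("schema must define exactly 9 games, got ", nrow(schema),
      call. = FALSE
    )
  }
  if (anyDuplicated(schema$game_id)) {
    stop("schema game_id values must be unique", call. = FALSE)
  }
  if (any(schema$n_levels < 2 | schema$n_levels > 6)) {
    stop("every game must have between 2 and 6 levels", call. = FALSE)
  }
  if (any(schema$level_timer_s <= 0)) {
    stop("level_timer_s must be positive", call. = FALSE)
  }
  if (any(schema$advance_threshold < 1)) {
    stop("advance_threshold must be at least 1", call. = FALSE)
  }
  if (!all(schema$gesture %in% c("tap", "drag", "mixed"))) {
    stop("gesture must be one of tap, drag, mixed", call. = FALSE)
  }
  new_deep_schema(tibble::as_tibble(schema))
}

# total level count of a schema; the default battery has 40
schema_total_levels <- function(schema) sum(schema$n_levels)

# long (game_id, level) grid in battery order
schema_level_grid <- function(schema) {
  tidyr::unnest(
    dplyr::mutate(
      schema[, c("game_id", "n_levels", "gesture", "level_timer_s",
                 "advance_threshold")],
      level = purrr::map(.data$n_levels, seq_len)
    ),
    "level"
  )
}
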