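#' Read an event log into an episode corpus
#'
#' Two dialects are accepted, auto-detected from the first non-blank line:
#'
#' * **CSV** with mandatory header `timestamp,entity,state` and optional
#'   `episode_id` and `behavior` columns. The action label is
#'   `"<entity>, <state>"`. When there is no `episode_id` column, episodes
#'   are delimited by blank lines.
#' * **JSON lines**, one object per record:
#'   `{"t": ..., "action": "<entity>, <state>", "episode_id": ...,
#'   "behavior": ...}` (`episode_id`/`behavior` optional; without
#'   `episode_id`, blank lines delimit episodes).
#'
#' Timestamps may be ISO-8601 or numeric epoch (auto-detected). Actions are
#' ordered by timestamp within each episode; rows already in order are left
#' untouched, out-of-order rows are sorted with a warning.
#'
#' @param path Path to the log file.
#' @return A tibble with columns `episode_id`, `timestamp` (character, as
#'   read), `action`, and `behavior` (`NA` if absent) — the long-format
#'   corpus consumed by [learn_behavior()] and [cross_validate()].
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[trimws(lines) != ""]
  if (length(nonblank) == 0) stop("empty event log: ", path, call. = FALSE)
  json <- startsWith(trimws(nonblank[1]), "{")
  rows <- if (json) parse_jsonl_log(lines, path) else parse_csv_log(lines, path)
  # order by timestamp within episode, warning when re-ordering was needed
  ts <- parse_timestamps(rows$timestamp)
  if (!all(is.na(ts))) {
    reordered <- FALSE
    rows <- dplyr::bind_rows(lapply(
      split(rows, factor(rows$episode_id, levels = unique(rows$episode_id))),
      function(g) {
        o <- order(ts[match(g$.row, rows$.row)])
        if (is.unsorted(o)) reordered <<- TRUE
        g[o, , drop = FALSE]
      }))
    if (reordered) {
      warning("out-of-order timestamps within an episode; rows sorted",
              call. = FALSE)
    }
  }
  rows$.row <- NULL
  tibble::as_tibble(rows)
}

parse_csv_log <- function(lines, path) {
  blank <- trimws(lines) == ""
  header <- strsplit(lines[which(!blank)[1]], ",")[[1]]
  header <- trimws(header)
  need <- c("timestamp", "entity", "state")
  if (!all(need %in% header)) {
    stop("CSV event log must have header columns timestamp,entity,state ",
         "(got: ", paste(header, collapse = ","), ")", call. = FALSE)
  }
  body_idx <- setdiff(seq_along(lines), which(!blank)[1])
  # episode breaks at blank lines when no episode_id column is present
  episode_break <- cumsum(blank)
  out <- list()
  for (i in body_idx) {
    if (blank[i]) next
    f <- strsplit(lines[i], ",")[[1]]
    if (length(f) < length(header)) {
      stop("malformed row at line ", i, " of ", path,
           ": expected ", length(header), " fields, got ", length(f),
           call. = FALSE)
    }
    rec <- stats::setNames(as.list(trimws(f[seq_along(header)])), header)
    out[[length(out) + 1L]] <- tibble::tibble(
      episode_id = if ("episode_id" %in% header) rec$episode_id else
        paste0("ep", episode_break[i] + 1L),
      timestamp = rec$timestamp,
      action = normalize_action(paste0(rec$entity, ", ", rec$state)),
      behavior = if ("behavior" %in% header) rec$behavior else NA_character_
    )
  }
  if (length(out) == 0) stop("empty event log: ", path, call. = FALSE)
  res <- dplyr::bind_rows(out)
  res$.row <- seq_len(nrow(res))
  res
}

parse_jsonl_log <- function(lines, path) {
  out <- list()
  episode_break <- cumsum(trimws(lines) == "")
  for (i in seq_along(lines)) {
    if (trimws(lines[i]) == "") next
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$action)) {
      stop("malformed JSON record at line ", i, " of ", path, call. = FALSE)
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      episode_id = as.character(rec$episode_id %||%
                                  paste0("ep", episode_break[i] + 1L)),
      timestamp = as.character(rec$t %||% NA_character_),
      action = normalize_action(rec$action),
      behavior = as.character(rec$behavior %||% NA_character_)
    )
  }
  if (length(out) == 0) stop("empty event log: ", path, call. = FALSE)
  res <- dplyr::bind_rows(out)
  res$.row <- seq_len(nrow(res))
  res
}

parse_timestamps <- function(x) {
  if (all(is.na(x))) return(rep(NA_real_, length(x)))
  num <- suppressWarnings(as.numeric(x))
  if (!any(is.na(num[!is.na(x)]))) return(num)
  t <- suppressWarnings(as.POSIXct(x, tz = "UTC",
                                   tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                  "%Y-%m-%d %H:%M:%OS",
                                                  "%Y-%m-%d")))
  as.numeric(t)
}

#' Write an episode corpus as a CSV event log
#'
#' Inverse of [read_event_log()]: writes `episode_id,timestamp,entity,state`
#' (plus `behavior` when present), splitting each action label on its first
#' comma into entity and state.
#'
#' @param corpus Tibble with columns `episode_id`, `action`, optionally
#'   `timestamp` and `behavior`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(corpus, path) {
  stopifnot(is.data.frame(corpus),
            all(c("episode_id", "action") %in% names(corpus)))
  act <- normalize_action(as.character(corpus$action))
  entity <- sub(",.*$", "", act)
  state <- trimws(sub("^[^,]*,", "", act))
  df <- tibble::tibble(
    episode_id = as.character(corpus$episode_id),
    timestamp = if ("timestamp" %in% names(corpus)) {
      as.character(corpus$timestamp)
    } else {
      as.character(seq_len(nrow(corpus)))
    },
    entity = entity, state = state
  )
  if ("behavior" %in% names(corpus)) df$behavior <- corpus$behavior
  readr::write_csv(df, path)
  invisible(path)
}

#' Read and write frequent-behavior models as JSON
#'
#' The on-disk format mirrors the in-memory model: keys `id`, `states`,
#' `initial_probs` (map state -> probability), `transitions` (array of
#' `{from, to, p}`), `end_probs` (map; omitted entries are 0), and
#' `terminal_states`. `write_model()` followed by `read_model()` is the
#' identity.
#'
#' @param behavior A `behavior_model`.
#' @param path File path.
#' @return `read_model()` returns a validated `behavior_model`;
#'   `write_model()` returns `path` invisibly.
#' @export
write_model <- function(behavior, path) {
  assert_valid_behavior(behavior)
  obj <- list(
    id = behavior$id,
    states = behavior$states,
    initial_probs = as.list(behavior$initial_probs[behavior$initial_probs > 0]),
    transitions = behavior$transitions,
    end_probs = as.list(behavior$end_probs[behavior$end_probs > 0]),
    terminal_states = behavior$terminal_states
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (k in c("id", "states", "initial_probs", "transitions")) {
    if (is.null(obj[[k]])) {
      stop("model file ", path, " lacks required key `", k, "`",
           call. = FALSE)
    }
  }
  behavior_model(
    id = obj$id,
    states = obj$states,
    initial_probs = unlist(obj$initial_probs),
    transitions = as.data.frame(obj$transitions),
    end_probs = if (!is.null(obj$end_probs)) unlist(obj$end_probs)
  )
}

#' Read and write criticality maps as JSON
#'
#' Format: `{"default_value": v, "rules": [{"op": ..., "action": ...,
#'   "action2": ..., "value": ...}, ...]}`; `action`/`action2` may be
#' omitted as wildcards. Validated on load.
#'
#' @param cmap A [criticality_map()].
#' @param path File path.
#' @return `read_criticality_map()` returns a `criticality_map`;
#'   `write_criticality_map()` returns `path` invisibly.
#' @export
write_criticality_map <- function(cmap, path) {
  stopifnot(inherits(cmap, "criticality_map"))
  jsonlite::write_json(
    list(default_value = cmap$default_value, rules = cmap$rules),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_criticality_map
#' @export
read_criticality_map <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rules <- if (!is.null(obj$rules) && length(obj$rules)) {
    as.data.frame(obj$rules)
  }
  criticality_map(rules, default_value = obj$default_value %||% 1)
}

#' Write a shift report to disk
#'
#' `format = "json"` mirrors the report object (episode, per-behavior
#' likelihoods, modification sets, criticality, risk factor, anomaly flag)
#' plus a header with the package version and the run configuration;
#' `format = "text"` writes the human-readable rendering of
#' [print.shift_report()] under the same header.
#'
#' @param report A `shift_report` (or list of them).
#' @param path Output path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (inherits(report, "shift_report")) report <- list(report)
  stopifnot(all(vapply(report, inherits, logical(1), "shift_report")))
  cfg <- report[[1]]$config
  header <- list(
    package = "adlshift",
    version = as.character(utils::packageVersion("adlshift")),
    config = cfg[!vapply(cfg, is.null, logical(1))]
  )
  if (format == "json") {
    body <- lapply(report, function(r) {
      list(
        episode_id = r$episode_id,
        episode = r$episode,
        matched = r$matched,
        behaviors = r$results,
        warnings = r$warnings
      )
    })
    jsonlite::write_json(list(header = header, reports = body), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    txt <- c(
      sprintf("# adlshift %s", header$version),
      sprintf("# config: %s",
              paste(names(header$config),
                    vapply(header$config, function(v) paste(format(v), collapse = ","),
                           character(1)),
                    sep = "=", collapse = " ")),
      "",
      unlist(lapply(report, function(r) c(format(r), "")))
    )
    writeLines(txt, path)
  }
  invisible(path)
}
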