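#' Run configuration for shift detection
#'
#' Collects the tunable constants of the pipeline in one validated object.
#' Unknown names are rejected so a typo in a config file cannot silently
#' fall back on a default.
#'
#' @param path_threshold Minimum path likelihood retained during path
#'   enumeration, in `(0, 1]` (default 0.01).
#' @param max_path_length Hard cap on enumerated path length (default 100);
#'   together with `path_threshold` it bounds enumeration on cyclic chains.
#' @param criticality_aggregation How per-modification criticalities combine
#'   into `Cr(M)`: `"min"` (default; most critical member dominates),
#'   `"product"`, or `"mean"`.
#' @param anomaly_threshold Risk-factor level above which an episode is
#'   flagged anomalous (default 1: strictly more than one fully critical
#'   modification's worth of risk).
#' @param include_initial_prob Multiply the start state's initial
#'   probability into episode likelihoods (default `FALSE`; it always acts
#'   as a positivity gate).
#' @param seed Integer seed recorded in reports and used by CLI runs for
#'   any randomness (default `NULL`).
#' @param verbose Emit progress messages (default `FALSE`).
#' @return An object of class `shift_config` (a validated named list).
#' @examples
#' shift_config(path_threshold = 0.001)
#' @export
shift_config <- function(path_threshold = 0.01, max_path_length = 100,
                         criticality_aggregation = c("min", "product", "mean"),
                         anomaly_threshold = 1, include_initial_prob = FALSE,
                         seed = NULL, verbose = FALSE) {
  criticality_aggregation <- match.arg(criticality_aggregation)
  stopifnot(path_threshold > 0, path_threshold <= 1,
            max_path_length >= 1, anomaly_threshold >= 0,
            is.logical(include_initial_prob), is.logical(verbose))
  structure(
    list(path_threshold = path_threshold,
         max_path_length = as.integer(max_path_length),
         criticality_aggregation = criticality_aggregation,
         anomaly_threshold = anomaly_threshold,
         include_initial_prob = include_initial_prob,
         seed = if (!is.null(seed)) as.integer(seed),
         verbose = verbose),
    class = "shift_config"
  )
}

as_shift_config <- function(x) {
  if (inherits(x, "shift_config")) return(x)
  if (is.null(x)) return(shift_config())
  if (!is.list(x)) stop("config must be a shift_config or a named list",
                        call. = FALSE)
  unknown <- setdiff(names(x), names(formals(shift_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(shift_config, x)
}

#' @export
print.shift_config <- function(x, ...) {
  cat("<shift_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-24s %s\n", k,
                if (is.null(x[[k]])) "NULL" else format(x[[k]])))
  }
  invisible(x)
}

as_behavior_list <- function(behaviors) {
  if (inherits(behaviors, "behavior_model")) behaviors <- list(behaviors)
  if (!is.list(behaviors) ||
      !all(vapply(behaviors, inherits, logical(1), "behavior_model"))) {
    stop("`behaviors` must be a behavior_model or a list of them",
         call. = FALSE)
  }
  names(behaviors) <- vapply(behaviors, `[[`, character(1), "id")
  behaviors
}

#' Detect a shift of an observed episode from the frequent behaviors
#'
#' The main driver. Computes the likelihood of the observed episode under
#' every frequent behavior; if any likelihood is positive, the episode *is*
#' a frequent behavior and the report carries that likelihood with an empty
#' modification set. Otherwise the episode has shifted: for each behavior,
#' all sufficiently likely paths are enumerated, the episode is compared to
#' each by edit distance, the path needing the fewest modifications is
#' selected (ties broken by higher path likelihood, then lower criticality),
#' and the behavior's criticality `Cr`, risk factor `phi`, and anomaly flag
#' are filled in. A behavior with no enumerable path is skipped with a
#' warning recorded in the report.
#'
#' @param behaviors A `behavior_model` or list of them (the user's frequent
#'   behaviors `F`).
#' @param episode The observed episode: character vector of action labels or
#'   data frame with an `action` column.
#' @param cmap A [criticality_map()]; `NULL` means every modification is
#'   non-critical (criticality 1).
#' @param config A [shift_config()] or named list of its arguments.
#' @param episode_id Identifier stored in the report (default `"episode"`).
#' @return An object of class `shift_report`; see [tidy.shift_report()] for
#'   the per-behavior table and [glance.shift_report()] for the one-row
#'   summary.
#' @examples
#' f1 <- load_fixture("michael_f1")
#' cmap <- load_fixture("criticality_map_michael")
#' calculate_shifts(f1, load_fixture("C2"), cmap)
#' @export
calculate_shifts <- function(behaviors, episode, cmap = NULL,
                             config = shift_config(),
                             episode_id = "episode") {
  behaviors <- as_behavior_list(behaviors)
  if (length(behaviors) == 0) stop("`behaviors` is empty", call. = FALSE)
  C <- as_episode(episode)
  cfg <- as_shift_config(config)
  if (is.null(cmap)) cmap <- criticality_map()
  stopifnot(inherits(cmap, "criticality_map"))

  ll <- vapply(behaviors, function(f) {
    episode_likelihood(C, f, include_initial_prob = cfg$include_initial_prob)
  }, numeric(1))

  empty_mods <- tibble::tibble(op = character(), action = character(),
                               action2 = character(), position = integer())
  warnings <- character()

  if (any(ll > 0)) {
    # the episode is itself a frequent behavior: report and stop searching
    hit <- names(ll)[ll > 0]
    res <- tibble::tibble(
      behavior_id = hit,
      likelihood = unname(ll[hit]),
      path_id = NA_character_,
      modification_count = 0L,
      modifications = rep(list(empty_mods), length(hit)),
      criticality = 1,
      risk_factor = 0,
      anomalous = FALSE
    )
    matched <- TRUE
  } else {
    rows <- list()
    for (f in behaviors) {
      paths <- withCallingHandlers(
        enumerate_paths(f, threshold = cfg$path_threshold,
                        max_length = cfg$max_path_length),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      if (nrow(paths) == 0) next
      per_path <- purrr::map(seq_len(nrow(paths)), function(j) {
        D <- build_distance_matrix(C, paths$actions[[j]])
        mods <- backtrace_modifications(D)
        list(path_id = paths$path_id[j],
             path_likelihood = paths$likelihood[j],
             count = D$count, mods = mods,
             cr = criticality(mods, cmap,
                              aggregation = cfg$criticality_aggregation))
      })
      counts <- vapply(per_path, `[[`, numeric(1), "count")
      lks <- vapply(per_path, `[[`, numeric(1), "path_likelihood")
      crs <- vapply(per_path, `[[`, numeric(1), "cr")
      best <- order(counts, -lks, crs)[1]
      b <- per_path[[best]]
      phi <- risk_factor(b$count, b$cr)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        behavior_id = f$id,
        likelihood = 0,
        path_id = b$path_id,
        modification_count = as.integer(b$count),
        modifications = list(b$mods),
        criticality = b$cr,
        risk_factor = phi,
        anomalous = phi > cfg$anomaly_threshold
      )
    }
    if (length(rows) == 0) {
      res <- tibble::tibble(
        behavior_id = character(), likelihood = numeric(),
        path_id = character(), modification_count = integer(),
        modifications = list(), criticality = numeric(),
        risk_factor = numeric(), anomalous = logical()
      )
    } else {
      res <- dplyr::bind_rows(rows)
    }
    matched <- FALSE
  }

  structure(
    list(episode_id = episode_id, episode = C, matched = matched,
         results = res, config = cfg, warnings = warnings),
    class = "shift_report"
  )
}

#' Tidy a shift report into its per-behavior table
#'
#' @param x A `shift_report` from [calculate_shifts()].
#' @param ... Unused.
#' @return A tibble with one row per frequent behavior: `behavior_id`,
#'   `likelihood`, `path_id` (best path, `NA` for a matched episode),
#'   `modification_count`, `modifications` (list column of modification
#'   tibbles), `criticality`, `risk_factor`, `anomalous`.
#' @method tidy shift_report
#' @export
tidy.shift_report <- function(x, ...) {
  dplyr::mutate(x$results, episode_id = x$episode_id, .before = 1)
}

#' One-row summary of a shift report
#'
#' Summarizes by the best behavior: the matched behavior with the highest
#' likelihood, or — for a shifted episode — the behavior with the lowest
#' modification count (ties by higher path likelihood, then lower
#' criticality).
#'
#' @inheritParams tidy.shift_report
#' @return A one-row tibble: `episode_id`, `episode_length`, `matched`,
#'   `behavior_id`, `likelihood`, `modification_count`, `criticality`,
#'   `risk_factor`, `anomalous`.
#' @method glance shift_report
#' @export
glance.shift_report <- function(x, ...) {
  r <- x$results
  if (nrow(r) == 0) {
    return(tibble::tibble(
      episode_id = x$episode_id, episode_length = length(x$episode),
      matched = FALSE, behavior_id = NA_character_, likelihood = NA_real_,
      modification_count = NA_integer_, criticality = NA_real_,
      risk_factor = NA_real_, anomalous = NA
    ))
  }
  best <- if (x$matched) {
    r[order(-r$likelihood), ][1, ]
  } else {
    r[order(r$modification_count, r$criticality), ][1, ]
  }
  tibble::tibble(
    episode_id = x$episode_id, episode_length = length(x$episode),
    matched = x$matched, behavior_id = best$behavior_id,
    likelihood = best$likelihood,
    modification_count = best$modification_count,
    criticality = best$criticality, risk_factor = best$risk_factor,
    anomalous = best$anomalous
  )
}

#' @export
print.shift_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.shift_report <- function(x, ...) {
  out <- c(sprintf("Shift report for %s (%d actions)",
                   x$episode_id, length(x$episode)))
  if (x$matched) {
    for (i in seq_len(nrow(x$results))) {
      out <- c(out, sprintf(
        "  matches frequent behavior '%s' with likelihood %g; no modification needed",
        x$results$behavior_id[i], x$results$likelihood[i]))
    }
  } else if (nrow(x$results) == 0) {
    out <- c(out, "  no frequent behavior had an enumerable path")
  } else {
    out <- c(out, "  does not match any frequent behavior (likelihood 0)")
    for (i in seq_len(nrow(x$results))) {
      r <- x$results[i, ]
      out <- c(out, sprintf(
        "  vs '%s': %d modification(s) to path %s; criticality %g, risk factor %g%s",
        r$behavior_id, r$modification_count, r$path_id, r$criticality,
        r$risk_factor, if (r$anomalous) " [ANOMALOUS]" else ""))
      m <- r$modifications[[1]]
      for (j in seq_len(nrow(m))) {
        operand <- if (is.na(m$action2[j])) {
          sprintf("('%s')", m$action[j])
        } else {
          sprintf("('%s', '%s')", m$action[j], m$action2[j])
        }
        out <- c(out, sprintf("    - %s %s at position %d",
                              m$op[j], operand, m$position[j]))
      }
    }
  }
  for (w in x$warnings) out <- c(out, paste0("  warning: ", w))
  out
}
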