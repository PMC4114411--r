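#' Normalize action labels
#'
#' Actions are atomic labelled events of the form `"<entity>, <state>"`
#' (e.g. `"Pill, on"`). Labels are compared by exact, case-sensitive string
#' equality after whitespace normalization: leading/trailing whitespace is
#' trimmed and internal runs of whitespace collapse to a single space, so
#' `"Pill,  on "` and `"Pill, on"` denote the same action.
#'
#' @param x Character vector of action labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_action(c("  Pill,   on", "Kitchen, off "))
#' @export
normalize_action <- function(x) {
  if (!is.character(x)) {
    stop("action labels must be character", call. = FALSE)
  }
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  if (any(!nzchar(x))) {
    stop("action labels must be non-empty", call. = FALSE)
  }
  x
}

# Coerce an episode to an ordered character vector of normalized action
# labels. Accepts a character vector or a data frame with an `action` column
# (row order = order of occurrence).
as_episode <- function(x, arg = "episode") {
  if (is.data.frame(x)) {
    if (!"action" %in% names(x)) {
      stop(sprintf("`%s` data frame must have an `action` column", arg),
           call. = FALSE)
    }
    x <- x$action
  }
  if (length(x) == 0) {
    stop(sprintf("`%s` must contain at least one action", arg), call. = FALSE)
  }
  normalize_action(as.character(x))
}

# Split a long-format corpus (episode_id, action, optional behavior) into a
# named list of episodes (character vectors), preserving row order within
# each episode.
corpus_episodes <- function(corpus) {
  if (is.list(corpus) && !is.data.frame(corpus)) {
    eps <- lapply(corpus, as_episode)
    if (is.null(names(eps))) names(eps) <- paste0("ep", seq_along(eps))
    return(eps)
  }
  if (!is.data.frame(corpus) || !all(c("episode_id", "action") %in% names(corpus))) {
    stop("corpus must be a data frame with `episode_id` and `action` columns, ",
         "or a list of character vectors", call. = FALSE)
  }
  if (nrow(corpus) == 0) stop("corpus is empty", call. = FALSE)
  ids <- as.character(corpus$episode_id)
  split(normalize_action(as.character(corpus$action)),
        factor(ids, levels = unique(ids)))
}

# Per-episode grouping labels (behavior column), aligned with corpus_episodes().
corpus_groups <- function(corpus) {
  if (!is.data.frame(corpus) || !"behavior" %in% names(corpus)) return(NULL)
  ids <- as.character(corpus$episode_id)
  first <- !duplicated(ids)
  stats::setNames(as.character(corpus$behavior)[first], ids[first])
}

# Occurrence tagging: the model learner can distinguish repeated occurrences
# of the same action within an episode (the k-th occurrence of label L
# becomes the internal state "L<U+2016>k" for k >= 2). Tags never appear in
# user-facing episodes or paths.
occ_sep <- "\u2016"

tag_occurrences <- function(x) {
  k <- stats::ave(seq_along(x), x, FUN = seq_along)
  ifelse(k == 1L, x, paste0(x, occ_sep, k))
}

strip_occurrences <- function(x) {
  sub(paste0(occ_sep, "[0-9]+$"), "", x)
}

model_is_tagged <- function(behavior) {
  any(grepl(occ_sep, behavior$states, fixed = TRUE))
}
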