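#' Construct a frequent-behavior Markov chain
#'
#' A frequent behavior is a Markov chain over discrete actions: a set of
#' states (action labels), an initial distribution, a transition matrix, and
#' a per-state probability of the episode ending there. For every state the
#' outgoing transition probabilities plus the end probability sum to 1;
#' *terminal* states are those with end probability 1 (equivalently, no
#' outgoing transitions). Complete realizations of the behavior (paths) run
#' from an initial state to a state where the episode may end. Routines
#' whose action sequence never revisits an action need no explicit end
#' probabilities — the last action is simply terminal — but routines that
#' revisit an action (say, opening the same cabinet twice) end at a state
#' that can also continue, which the end probability expresses.
#'
#' @param id Character identifier for the behavior.
#' @param states Character vector of action labels (the chain's state set).
#' @param initial_probs Named numeric vector, state -> initial probability.
#'   States omitted get probability 0. Must sum to 1.
#' @param transitions Data frame with columns `from`, `to`, `p`: the nonzero
#'   entries of the transition matrix.
#' @param end_probs Optional named numeric vector, state -> probability that
#'   an episode ends at that state. Defaults to 1 for states with no
#'   outgoing transitions and 0 elsewhere.
#' @param terminal_states Deprecated alias accepted for convenience: states
#'   listed here get end probability 1 when `end_probs` is `NULL`.
#' @param validate Check invariants and error on violation (default `TRUE`).
#' @return An object of class `behavior_model`.
#' @examples
#' m <- behavior_model(
#'   id = "tea",
#'   states = c("Kettle, on", "Kettle, off"),
#'   initial_probs = c("Kettle, on" = 1),
#'   transitions = data.frame(from = "Kettle, on", to = "Kettle, off", p = 1)
#' )
#' episode_likelihood(c("Kettle, on", "Kettle, off"), m)
#' @seealso [validate_behavior()], [episode_likelihood()], [enumerate_paths()]
#' @export
behavior_model <- function(id, states, initial_probs, transitions,
                           end_probs = NULL, terminal_states = NULL,
                           validate = TRUE) {
  states <- normalize_action(as.character(states))
  transitions <- tibble::tibble(
    from = normalize_action(as.character(transitions$from)),
    to   = normalize_action(as.character(transitions$to)),
    p    = as.numeric(transitions$p)
  )
  p0 <- stats::setNames(rep(0, length(states)), states)
  ip <- stats::setNames(as.numeric(initial_probs),
                        normalize_action(names(initial_probs)))
  known <- intersect(names(ip), states)
  p0[known] <- ip[known]
  extra_init <- setdiff(names(ip), states)

  pe <- stats::setNames(rep(0, length(states)), states)
  if (is.null(end_probs)) {
    no_out <- setdiff(states, unique(transitions$from))
    pe[no_out] <- 1
    if (!is.null(terminal_states)) {
      pe[intersect(normalize_action(terminal_states), states)] <- 1
    }
  } else {
    ep <- stats::setNames(as.numeric(end_probs),
                          normalize_action(names(end_probs)))
    pe[intersect(names(ep), states)] <- ep[intersect(names(ep), states)]
    # states with no outgoing transitions always end the episode
    pe[setdiff(states, unique(transitions$from))] <- 1
  }

  model <- structure(
    list(id = as.character(id), states = states, initial_probs = p0,
         transitions = transitions, end_probs = pe,
         terminal_states = states[pe >= 1 - 1e-9],
         extra_initial_states = extra_init),
    class = "behavior_model"
  )
  if (validate) assert_valid_behavior(model)
  model
}

#' Validate a frequent-behavior model
#'
#' Checks the Markov-chain invariants: probabilities in `[0, 1]`, initial
#' distribution summing to 1, every state's outgoing probabilities plus end
#' probability summing to 1 (tolerance 1e-9), and all transition endpoints
#' declared in the state set. Reports violations; never raises.
#'
#' @param behavior A `behavior_model`.
#' @return A tibble with columns `where` (offending state or field) and
#'   `violation` (description); zero rows iff the model is valid.
#' @examples
#' m <- load_fixture("michael_f1")
#' validate_behavior(m)   # zero rows
#' @export
validate_behavior <- function(behavior) {
  tol <- 1e-9
  out <- list()
  add <- function(where, what) {
    out[[length(out) + 1L]] <<- tibble::tibble(where = where, violation = what)
  }
  tr <- behavior$transitions
  for (s in behavior$extra_initial_states %||% character()) {
    add(s, "initial probability assigned to a state not in `states`")
  }
  for (s in setdiff(unique(c(tr$from, tr$to)), behavior$states)) {
    add(s, "transition references an undeclared state")
  }
  for (i in which(tr$p < -tol | tr$p > 1 + tol)) {
    add(tr$from[i], sprintf("transition probability %g outside [0, 1]", tr$p[i]))
  }
  if (any(behavior$initial_probs < -tol | behavior$initial_probs > 1 + tol)) {
    add("initial_probs", "initial probability outside [0, 1]")
  }
  if (any(behavior$end_probs < -tol | behavior$end_probs > 1 + tol)) {
    add("end_probs", "end probability outside [0, 1]")
  }
  s0 <- sum(behavior$initial_probs)
  if (abs(s0 - 1) > tol) {
    add("initial_probs", sprintf("initial probabilities sum to %g, not 1", s0))
  }
  rows <- vapply(behavior$states, function(s) {
    sum(tr$p[tr$from == s]) + behavior$end_probs[[s]]
  }, numeric(1))
  for (s in behavior$states) {
    if (abs(rows[[s]] - 1) > tol) {
      add(s, sprintf(
        "outgoing plus end probability sums to %g, not 1", rows[[s]]))
    }
  }
  if (length(out) == 0) {
    tibble::tibble(where = character(), violation = character())
  } else {
    dplyr::bind_rows(out)
  }
}

assert_valid_behavior <- function(behavior) {
  v <- validate_behavior(behavior)
  if (nrow(v) > 0) {
    stop("invalid behavior model `", behavior$id, "`:\n",
         paste0("  - ", v$where, ": ", v$violation, collapse = "\n"),
         call. = FALSE)
  }
  invisible(behavior)
}

# Vectorized transition-probability lookup; 0 for absent transitions.
transition_prob <- function(behavior, from, to) {
  tr <- behavior$transitions
  key <- paste0(tr$from, "\r", tr$to)
  idx <- match(paste0(from, "\r", to), key)
  ifelse(is.na(idx), 0, tr$p[idx])
}

#' @export
print.behavior_model <- function(x, ...) {
  cat(sprintf("<behavior_model> %s: %d states, %d transitions, %d terminal\n",
              x$id, length(x$states), nrow(x$transitions),
              length(x$terminal_states)))
  invisible(x)
}

#' @export
format.behavior_model <- function(x, ...) {
  sprintf("<behavior_model: %s>", x$id)
}

#' Likelihood of an observed episode under a frequent behavior
#'
#' The likelihood of an observed episode `C = c_1, ..., c_n` under a chain is
#' the product of the transition probabilities `Pr(c_k -> c_(k+1))` over
#' consecutive pairs. The episode is compared over its full length as one
#' complete realization of the behavior: the likelihood is 0 when any action
#' is not a state of the chain, when the first action has initial probability
#' 0, when any consecutive transition is absent, or when the episode does not
#' end at a state where the behavior can end. A zero likelihood therefore
#' means "this is not a complete frequent behavior as-is" and triggers the
#' edit-script comparison in [calculate_shifts()].
#'
#' @param episode Character vector of action labels (or data frame with an
#'   `action` column), in order of occurrence.
#' @param behavior A `behavior_model`.
#' @param include_initial_prob Multiply the first action's initial
#'   probability into the product (default `FALSE`: the initial probability
#'   acts only as a positivity gate, which reproduces the worked values for
#'   chains with a single certain start).
#' @return A probability in `[0, 1]`.
#' @examples
#' f1 <- load_fixture("michael_f1")
#' episode_likelihood(load_fixture("C1"), f1)  # 0.6
#' episode_likelihood(load_fixture("C2"), f1)  # 0
#' @export
episode_likelihood <- function(episode, behavior, include_initial_prob = FALSE) {
  episode <- as_episode(episode)
  assert_valid_behavior(behavior)
  if (model_is_tagged(behavior)) episode <- tag_occurrences(episode)
  if (!all(episode %in% behavior$states)) return(0)
  p0 <- behavior$initial_probs[[episode[1]]]
  if (p0 <= 0) return(0)
  if (behavior$end_probs[[episode[length(episode)]]] <= 0) return(0)
  ll <- if (length(episode) > 1) {
    prod(transition_prob(behavior, episode[-length(episode)], episode[-1]))
  } else {
    1
  }
  if (include_initial_prob) ll <- ll * p0
  ll
}

#' Likelihood of a path through a frequent behavior
#'
#' A path is one complete start-to-end traversal of the chain; its
#' likelihood is the product of the transition probabilities along it.
#' Unlike [episode_likelihood()] this errors (rather than returning 0) when
#' the sequence is not a traversal, since paths come from the chain itself.
#'
#' @inheritParams episode_likelihood
#' @param path Character vector of action labels forming a traversal of the
#'   chain (every consecutive pair a transition with positive probability).
#' @return A probability in `(0, 1]`.
#' @examples
#' f1 <- load_fixture("michael_f1")
#' path_likelihood(load_fixture("rho11"), f1)  # 0.4
#' @export
path_likelihood <- function(path, behavior) {
  path <- as_episode(path, "path")
  assert_valid_behavior(behavior)
  if (model_is_tagged(behavior)) path <- tag_occurrences(path)
  if (!all(path %in% behavior$states)) {
    stop("path contains actions that are not states of `", behavior$id, "`",
         call. = FALSE)
  }
  if (length(path) == 1) return(1)
  p <- transition_prob(behavior, path[-length(path)], path[-1])
  if (any(p <= 0)) {
    i <- which(p <= 0)[1]
    stop(sprintf("not a traversal: no transition '%s' -> '%s' in `%s`",
                 path[i], path[i + 1], behavior$id), call. = FALSE)
  }
  prod(p)
}

#' Enumerate all sufficiently likely paths of a frequent behavior
#'
#' Depth-first enumeration of every complete path — from a start state to a
#' state where the behavior can end — whose likelihood is at least
#' `threshold` and whose length is at most `max_length`. Branches are pruned
#' as soon as the running product drops below `threshold`; this is sound
#' because transition probabilities are at most 1, so the product never
#' recovers, and together with `max_length` it guarantees termination on
#' chains with loops.
#'
#' @inheritParams episode_likelihood
#' @param threshold Minimum path likelihood retained, in `(0, 1]`
#'   (default 0.01).
#' @param max_length Maximum path length in actions (default 100).
#' @return A tibble with columns `path_id`, `actions` (list column of
#'   character vectors), `length`, and `likelihood`, sorted by decreasing
#'   likelihood; attributes `threshold` and `max_length` record the pruning
#'   parameters. Zero rows (with a warning) if no complete path exists
#'   within the caps.
#' @examples
#' paths <- enumerate_paths(load_fixture("michael_f1"))
#' paths$likelihood  # 0.6, 0.4
#' @export
enumerate_paths <- function(behavior, threshold = 0.01, max_length = 100) {
  assert_valid_behavior(behavior)
  stopifnot(threshold > 0, threshold <= 1, max_length >= 1)
  succ <- split(behavior$transitions[c("to", "p")], behavior$transitions$from)
  acc <- list()
  dfs <- function(prefix, prob) {
    state <- prefix[length(prefix)]
    if (behavior$end_probs[[state]] > 0) {
      acc[[length(acc) + 1L]] <<- list(actions = prefix, likelihood = prob)
    }
    if (length(prefix) >= max_length) return(invisible())
    nxt <- succ[[state]]
    if (is.null(nxt)) return(invisible())
    for (i in seq_len(nrow(nxt))) {
      p2 <- prob * nxt$p[i]
      if (p2 >= threshold) dfs(c(prefix, nxt$to[i]), p2)
    }
  }
  starts <- names(behavior$initial_probs)[behavior$initial_probs > 0]
  for (s in starts) {
    if (1 >= threshold) dfs(s, 1)
  }
  if (length(acc) == 0) {
    warning("no complete path of `", behavior$id, "` reaches an ending state ",
            "within threshold ", threshold, " and max_length ", max_length,
            call. = FALSE)
    out <- tibble::tibble(path_id = character(), actions = list(),
                          length = integer(), likelihood = numeric())
  } else {
    out <- tibble::tibble(
      actions = lapply(acc, `[[`, "actions"),
      likelihood = vapply(acc, `[[`, numeric(1), "likelihood")
    )
    out <- dplyr::arrange(out, dplyr::desc(.data$likelihood))
    out <- tibble::tibble(
      path_id = sprintf("%s_p%d", behavior$id, seq_len(nrow(out))),
      actions = lapply(out$actions, strip_occurrences),
      length = lengths(out$actions),
      likelihood = out$likelihood
    )
  }
  attr(out, "threshold") <- threshold
  attr(out, "max_length") <- max_length
  out
}

#' @method tidy behavior_model
#' @export
tidy.behavior_model <- function(x, ...) {
  x$transitions
}

#' @method glance behavior_model
#' @export
glance.behavior_model <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    n_states = length(x$states),
    n_transitions = nrow(x$transitions),
    n_terminal = length(x$terminal_states),
    n_start = sum(x$initial_probs > 0)
  )
}
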