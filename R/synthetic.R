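#' Sample one episode from a frequent behavior
#'
#' Draws the start state from the initial distribution, then repeatedly
#' either ends the episode (with the current state's end probability) or
#' follows an outgoing transition drawn from the transition matrix. The same
#' seed always yields the same episode.
#'
#' @param behavior A `behavior_model`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param max_length Truncate non-terminating walks at this many actions
#'   (default 100); a truncated episode carries attribute
#'   `truncated = TRUE` and a warning is raised.
#' @return Character vector of action labels.
#' @examples
#' sample_episode(load_fixture("michael_f1"), seed = 42)
#' @export
sample_episode <- function(behavior, seed = NULL, max_length = 100) {
  assert_valid_behavior(behavior)
  with_seed_(seed, {
    succ <- split(behavior$transitions[c("to", "p")], behavior$transitions$from)
    state <- sample(names(behavior$initial_probs), 1,
                    prob = behavior$initial_probs)
    out <- state
    truncated <- FALSE
    repeat {
      pe <- behavior$end_probs[[state]]
      if (pe >= 1 || (pe > 0 && stats::runif(1) < pe)) break
      if (length(out) >= max_length) {
        truncated <- TRUE
        break
      }
      nxt <- succ[[state]]
      state <- sample(nxt$to, 1, prob = nxt$p)
      out <- c(out, state)
    }
    out <- strip_occurrences(out)
    if (truncated) {
      warning("episode truncated at max_length = ", max_length, call. = FALSE)
      attr(out, "truncated") <- TRUE
    }
    out
  })
}

#' Sample a corpus of episodes from one behavior
#'
#' @inheritParams sample_episode
#' @param n Number of episodes.
#' @return A tibble with columns `episode_id`, `step`, `action` (long
#'   format, one row per action occurrence).
#' @examples
#' sample_episodes(load_fixture("michael_f1"), n = 5, seed = 1)
#' @export
sample_episodes <- function(behavior, n, seed = NULL, max_length = 100) {
  rng <- rng_stream(seed %||% sample.int(.Machine$integer.max, 1))
  eps <- lapply(seq_len(n), function(i) {
    sample_episode(behavior, seed = rng$next_seed(), max_length = max_length)
  })
  tibble::tibble(
    episode_id = rep(sprintf("%s_e%03d", behavior$id, seq_len(n)),
                     lengths(eps)),
    step = unlist(lapply(lengths(eps), seq_len)),
    action = unlist(eps)
  )
}

#' Synthetic smart-apartment ADL corpus
#'
#' Builds the corpus the validation harness runs on: `n` episodes realizing
#' the five activities of daily living recorded in the WSU smart apartment
#' (make a phone call, wash hands, cook, eat, clean). Each ADL is a fixed
#' action sequence, so episodes replicate the sequences — balanced across
#' the five activities and shuffled into a seeded order; the randomness of
#' the validation enters through fold assignment and perturbation draws.
#'
#' @param n Number of episodes (default 200).
#' @param seed Integer seed for the episode order.
#' @return A tibble with columns `episode_id`, `behavior` (ADL name),
#'   `step`, `action`.
#' @examples
#' corpus <- sample_adl_corpus(n = 10, seed = 1)
#' dplyr::count(corpus, behavior)
#' @export
sample_adl_corpus <- function(n = 200, seed = NULL) {
  stopifnot(n >= 1)
  nm <- names(adl_sequences)
  labels <- rep_len(nm, n)
  labels <- with_seed_(seed, sample(labels, n))
  tibble::tibble(
    episode_id = rep(sprintf("ep%04d", seq_len(n)),
                     lengths(adl_sequences[labels])),
    behavior = rep(labels, lengths(adl_sequences[labels])),
    step = unlist(lapply(lengths(adl_sequences[labels]), seq_len)),
    action = unlist(adl_sequences[labels], use.names = FALSE)
  )
}

#' Inject controlled corruptions into an episode
#'
#' Perturbs an episode the way a drifting routine would: `delete` removes an
#' action (the user forgot it), `insert` adds a spurious action from `pool`
#' (the user did something extra), `substitute` replaces an action with a
#' different one from `pool`, and `swap` transposes two adjacent distinct
#' actions. Returns the corrupted episode together with the ground-truth
#' *repairs* — the modification set, from the detector's perspective, that
#' turns the corrupted episode back into the original — so detector output
#' is directly comparable. Multiple corruptions are placed at pairwise
#' non-adjacent positions so their repairs cannot interact or cancel.
#'
#' @param episode Character vector of action labels (or data frame with an
#'   `action` column).
#' @param ops Corruption types to draw from (default all four).
#' @param n_ops Number of corruptions to inject (default 1).
#' @param pool Action pool for insertions and substitutions; defaults to the
#'   episode's own distinct actions.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list with `episode` (the corrupted character vector) and
#'   `truth` (tibble of repairing modifications with columns `op`, `action`,
#'   `action2`, `position`; positions index the corrupted episode).
#' @examples
#' p <- perturb_episode(load_fixture("rho12"), ops = "delete", seed = 7)
#' p$truth
#' @export
perturb_episode <- function(episode,
                            ops = c("insert", "delete", "substitute", "swap"),
                            n_ops = 1, pool = NULL, seed = NULL) {
  orig <- as_episode(episode)
  ops <- match.arg(ops, several.ok = TRUE)
  stopifnot(n_ops >= 0)
  if (is.null(pool)) pool <- unique(orig)
  pool <- normalize_action(pool)
  if (n_ops == 0) {
    return(list(episode = orig,
                truth = tibble::tibble(op = character(), action = character(),
                                       action2 = character(),
                                       position = integer())))
  }
  with_seed_(seed, {
    len <- length(orig)
    if (n_ops == 1) {
      op1 <- sample(rep(ops, 2), 1)
      if (op1 == "swap") {
        valid <- which(orig[-len] != orig[-1])  # adjacent distinct pairs
        if (len < 2 || length(valid) == 0) {
          stop("swap infeasible: no adjacent pair of distinct actions",
               call. = FALSE)
        }
        sites <- valid[sample.int(length(valid), 1)]
      } else if (op1 == "delete" && len == 1) {
        stop("cannot delete the only action of an episode", call. = FALSE)
      } else {
        sites <- sample.int(len, 1)
      }
      chosen <- op1
    } else {
      # multiple corruptions: pairwise non-adjacent sites in 1..(len-1) so a
      # swap's second action and neighbouring repairs never touch
      if (len - 1L < 2 * n_ops - 1L) {
        stop("episode too short for ", n_ops, " non-adjacent corruption(s)",
             call. = FALSE)
      }
      sites <- sort(with_pos_gap(len - 1L, n_ops))
      chosen <- sample(rep(ops, n_ops), n_ops)
      for (i in seq_len(n_ops)) {
        if (chosen[i] == "swap" && orig[sites[i]] == orig[sites[i] + 1]) {
          alt <- setdiff(ops, "swap")
          if (length(alt) == 0) {
            stop("swap requested but adjacent actions are identical",
                 call. = FALSE)
          }
          chosen[i] <- sample(rep(alt, 2), 1)
        }
      }
    }
    if (any(chosen == "substitute") && length(pool) < 2) {
      stop("action pool too small for substitution", call. = FALSE)
    }

    corrupted <- orig
    truth <- vector("list", n_ops)
    shift <- 0L  # net length change from corruptions left of the current one
    for (i in seq_len(n_ops)) {
      s <- sites[i]
      pos <- s + shift  # position in the corrupted episode
      if (chosen[i] == "delete") {
        removed <- corrupted[pos]
        corrupted <- corrupted[-pos]
        truth[[i]] <- tibble::tibble(op = "insert", action = removed,
                                     action2 = NA_character_,
                                     position = pos - 1L)
        shift <- shift - 1L
      } else if (chosen[i] == "insert") {
        extra <- sample(pool, 1)
        corrupted <- append(corrupted, extra, after = pos - 1L)
        truth[[i]] <- tibble::tibble(op = "delete", action = extra,
                                     action2 = NA_character_, position = pos)
        shift <- shift + 1L
      } else if (chosen[i] == "substitute") {
        old <- corrupted[pos]
        new <- sample(setdiff(pool, old), 1)
        corrupted[pos] <- new
        truth[[i]] <- tibble::tibble(op = "substitute", action = new,
                                     action2 = old, position = pos)
      } else {  # swap
        corrupted[c(pos, pos + 1)] <- corrupted[c(pos + 1, pos)]
        truth[[i]] <- tibble::tibble(op = "swap", action = corrupted[pos],
                                     action2 = corrupted[pos + 1],
                                     position = pos)
      }
    }
    list(episode = corrupted, truth = dplyr::bind_rows(truth))
  })
}

# Draw k positions from 1..n with pairwise gaps of at least 2 (non-adjacent),
# uniformly over the feasible sets.
with_pos_gap <- function(n, k) {
  if (k == 1) return(sample.int(n, 1))
  if (n - (k - 1) < k) {
    stop("episode too short for ", k, " non-adjacent corruption(s)",
         call. = FALSE)
  }
  base <- sort(sample.int(n - (k - 1), k))
  base + (seq_len(k) - 1L)
}
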