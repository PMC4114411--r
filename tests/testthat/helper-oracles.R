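# Independent oracles used to cross-check the dynamic-programming distance
# matrix and the pruned path enumeration.

# Minimum number of unit-cost aligned edit operations (insert, delete,
# substitute, adjacent swap) transforming `a` into `b`, found by recursive
# enumeration of edit scripts applied left-to-right at the first mismatch,
# with branch-and-bound pruning. Each position is edited at most once (a
# swap consumes both its positions), matching the modification model in
# which every observed action is repaired once.
oracle_edit_distance <- function(a, b) {
  la <- length(a)
  lb <- length(b)
  best <- la + lb  # upper bound: delete everything, insert everything
  rec <- function(i, j, cost) {
    while (i <= la && j <= lb && a[i] == b[j]) {
      i <- i + 1L
      j <- j + 1L
    }
    lower <- cost + abs((la - i) - (lb - j))
    if (lower >= best) return(invisible())
    if (i > la && j > lb) {
      best <<- min(best, cost)
      return(invisible())
    }
    if (i > la) {
      best <<- min(best, cost + (lb - j + 1L))
      return(invisible())
    }
    if (j > lb) {
      best <<- min(best, cost + (la - i + 1L))
      return(invisible())
    }
    if (i < la && j < lb && a[i] == b[j + 1L] && a[i + 1L] == b[j]) {
      rec(i + 2L, j + 2L, cost + 1L)  # swap
    }
    rec(i + 1L, j + 1L, cost + 1L)    # substitute
    rec(i + 1L, j, cost + 1L)         # delete a[i]
    rec(i, j + 1L, cost + 1L)         # insert b[j]
    invisible()
  }
  rec(1L, 1L, 0L)
  best
}

# All complete start-to-end paths of a chain up to max_length, found by
# plain exhaustive recursion with no likelihood pruning; likelihoods are
# multiplied along the way. Filtering afterwards mimics "enumerate
# everything, then discard".
oracle_enumerate_paths <- function(behavior, max_length) {
  succ <- split(behavior$transitions[c("to", "p")], behavior$transitions$from)
  acc <- list()
  walk <- function(prefix, prob) {
    s <- prefix[length(prefix)]
    if (behavior$end_probs[[s]] > 0) {
      acc[[length(acc) + 1L]] <<- list(actions = prefix, likelihood = prob)
    }
    if (length(prefix) >= max_length) return(invisible())
    nxt <- succ[[s]]
    if (is.null(nxt)) return(invisible())
    for (k in seq_len(nrow(nxt))) walk(c(prefix, nxt$to[k]), prob * nxt$p[k])
  }
  for (s in names(behavior$initial_probs)[behavior$initial_probs > 0]) {
    walk(s, 1)
  }
  acc
}

# Random acyclic chain over `n_states` states: state i can only reach
# states j > i, so termination is guaranteed and total path probability
# is 1. Useful for property tests.
random_acyclic_chain <- function(n_states, seed, id = "rand") {
  withr::with_seed(seed, {
    states <- paste0("S", seq_len(n_states))
    rows <- list()
    for (i in seq_len(n_states - 1)) {
      succ <- (i + 1):n_states
      k <- sample(seq_along(succ), 1)
      to <- sample(states[succ], k)
      w <- stats::runif(k) + 0.05
      rows[[i]] <- tibble::tibble(from = states[i], to = to, p = w / sum(w))
    }
    behavior_model(
      id = id, states = states,
      initial_probs = stats::setNames(1, states[1]),
      transitions = dplyr::bind_rows(rows)
    )
  })
}

# Random episode over a small alphabet.
random_episode <- function(len, alphabet = c("a", "b", "c", "d")) {
  sample(alphabet, len, replace = TRUE)
}
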