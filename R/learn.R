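#' Learn a frequent behavior from a corpus of episodes
#'
#' A lightweight frequency-count estimator of the Markov chain behind a set
#' of observed episodes of one routine. Actions appearing in at least
#' `min_support` of the episodes become states (infrequent actions are
#' dropped from the episodes before counting, keeping the chain connected);
#' transition probabilities are the row-normalized empirical frequencies of
#' consecutive pairs; the initial distribution is the empirical distribution
#' of first retained actions; and each state's end probability is the
#' fraction of its occurrences that closed an episode. Counting only — the
#' result is deterministic given the corpus.
#'
#' @param corpus A data frame with columns `episode_id` and `action` (row
#'   order = order of occurrence), or a list of character vectors.
#' @param min_support Minimum fraction of episodes an action must appear in
#'   to become a state, in `(0, 1]` (default 0.5).
#' @param id Identifier for the learned behavior (default `"learned"`).
#' @param distinguish_occurrences Treat repeated occurrences of an action
#'   within an episode as distinct chain states (default `FALSE`). Routines
#'   observed as fixed sequences that revisit an action (opening the same
#'   cabinet at the start and the end, say) are not expressible as a
#'   first-order chain over action labels: the label-level chain invents
#'   never-observed orderings of the repeated actions. Occurrence
#'   distinction restores the observed ordering; the tagging is internal,
#'   and episodes, enumerated paths and sampled episodes always carry plain
#'   action labels. Leave `FALSE` to estimate a genuinely stochastic chain
#'   (e.g. recovering transition probabilities of a looping process).
#' @return A validated `behavior_model`.
#' @examples
#' corpus <- list(
#'   c("Water On", "Water Off"),
#'   c("Water On", "Soap On", "Water Off"),
#'   c("Water On", "Water Off")
#' )
#' learn_behavior(corpus, min_support = 0.5, id = "wash")
#' @export
learn_behavior <- function(corpus, min_support = 0.5, id = "learned",
                           distinguish_occurrences = FALSE) {
  stopifnot(min_support > 0, min_support <= 1)
  eps <- corpus_episodes(corpus)
  n <- length(eps)
  support <- table(unlist(lapply(eps, unique))) / n
  keep <- names(support)[support >= min_support - 1e-12]
  if (length(keep) == 0) {
    stop("no action reaches min_support = ", min_support,
         " in the corpus; cannot learn a model", call. = FALSE)
  }
  eps <- lapply(eps, function(e) e[e %in% keep])
  eps <- eps[lengths(eps) > 0]
  if (length(eps) == 0) {
    stop("no episode retains any supported action", call. = FALSE)
  }
  if (distinguish_occurrences) {
    eps <- lapply(eps, tag_occurrences)
    keep <- unique(unlist(eps))
  }

  firsts <- vapply(eps, `[[`, character(1), 1)
  lasts <- vapply(eps, function(e) e[length(e)], character(1))
  pair_from <- unlist(lapply(eps, function(e) e[-length(e)]))
  pair_to <- unlist(lapply(eps, function(e) e[-1]))

  # each occurrence of a state either has a successor (one outgoing pair) or
  # closes an episode, so occurrences = outgoing counts + end counts and the
  # normalized rows satisfy sum(outgoing) + end = 1 exactly
  occ <- table(factor(unlist(eps), levels = keep))
  endn <- table(factor(lasts, levels = keep))

  tr <- if (length(pair_from)) {
    agg <- stats::aggregate(
      list(n = rep(1L, length(pair_from))),
      by = list(from = pair_from, to = pair_to), FUN = sum)
    tibble::tibble(from = agg$from, to = agg$to,
                   p = agg$n / as.numeric(occ[agg$from]))
  } else {
    tibble::tibble(from = character(), to = character(), p = numeric())
  }
  init <- table(factor(firsts, levels = keep)) / length(eps)
  endp <- as.numeric(endn) / as.numeric(occ)
  endp[is.nan(endp)] <- 0

  behavior_model(
    id = id,
    states = keep,
    initial_probs = stats::setNames(as.numeric(init), keep),
    transitions = tr,
    end_probs = stats::setNames(endp, keep)
  )
}

#' Learn one behavior per group of a labelled corpus
#'
#' Splits a corpus on its `behavior` column (e.g. ADL name) and runs
#' [learn_behavior()] on each group.
#'
#' @inheritParams learn_behavior
#' @param corpus Data frame with columns `episode_id`, `action`, and
#'   `behavior`.
#' @return A named list of `behavior_model`s, one per behavior label.
#' @export
learn_behaviors <- function(corpus, min_support = 0.5,
                            distinguish_occurrences = FALSE) {
  stopifnot(is.data.frame(corpus), "behavior" %in% names(corpus))
  labs <- unique(as.character(corpus$behavior))
  stats::setNames(lapply(labs, function(l) {
    learn_behavior(corpus[corpus$behavior == l, , drop = FALSE],
                   min_support = min_support, id = l,
                   distinguish_occurrences = distinguish_occurrences)
  }), labs)
}

# Multiset equality of two modification tables by (op, action, action2),
# ignoring positions: with repeated actions, equally minimal scripts can
# place the same repair at several equivalent positions.
same_modification_set <- function(a, b) {
  key <- function(m) {
    sort(paste(m$op, m$action,
               ifelse(is.na(m$action2), "", m$action2), sep = "\r"))
  }
  nrow(a) == nrow(b) && identical(key(a), key(b))
}

#' Adapted cross-validation of shift detection
#'
#' Validates the whole pipeline the way a field deployment would be
#' validated: the corpus is split into folds; on each fold the behaviors
#' are learned from the training episodes and [calculate_shifts()] is run
#' on the held-out episodes, twice per episode —
#'
#' 1. *unperturbed*: the episode is correct, so the detector should report
#'    a positive likelihood with zero modifications (a path match);
#' 2. *perturbed* (optional): one seeded corruption (delete, substitute, or
#'    swap) is injected, and the detector should recover exactly the
#'    repairing modification set. A drawn corruption whose result still has
#'    positive likelihood under some learned model is not a shift at all (a
#'    first-order chain cannot distinguish it from frequent behavior) and
#'    is redrawn.
#'
#' @param corpus Data frame with columns `episode_id`, `action`, and
#'   `behavior` (the routine each episode realizes).
#' @param folds Number of folds (default 10); must not exceed the number of
#'   episodes.
#' @param perturb Also run the perturbed-recovery arm (default `TRUE`).
#' @param min_support Passed to [learn_behavior()].
#' @param config A [shift_config()] for the detector.
#' @param seed Integer seed for fold shuffling and perturbation draws
#'   (default 17).
#' @param shuffle Shuffle episodes before round-robin fold assignment
#'   (default `TRUE`).
#' @param distinguish_occurrences Passed to [learn_behavior()]; default
#'   `TRUE` here because routine corpora are fixed-order sequences.
#' @return An object of class `cv_result`: per-episode results (see
#'   [tidy.cv_result()]) and summary rates in percent (see
#'   [glance.cv_result()]).
#' @examples
#' corpus <- sample_adl_corpus(n = 30, seed = 1)
#' cv <- cross_validate(corpus, folds = 3, seed = 1)
#' glance(cv)
#' @export
cross_validate <- function(corpus, folds = 10, perturb = TRUE,
                           min_support = 0.5, config = shift_config(),
                           seed = 17, shuffle = TRUE,
                           distinguish_occurrences = TRUE) {
  stopifnot(is.data.frame(corpus),
            all(c("episode_id", "action", "behavior") %in% names(corpus)))
  cfg <- as_shift_config(config)
  eps <- corpus_episodes(corpus)
  groups <- corpus_groups(corpus)
  n <- length(eps)
  if (folds < 2) stop("`folds` must be at least 2", call. = FALSE)
  if (folds > n) {
    stop("`folds` (", folds, ") exceeds the number of episodes (", n, ")",
         call. = FALSE)
  }
  rng <- rng_stream(seed)
  ord <- if (shuffle) rng$sample_int(n, n) else seq_len(n)
  fold_of <- stats::setNames(integer(n), names(eps))
  fold_of[ord] <- rep_len(seq_len(folds), n)

  alphabet <- sort(unique(unlist(eps)))
  rows <- vector("list", n)
  k <- 0L
  for (f in seq_len(folds)) {
    test_ids <- names(eps)[fold_of == f]
    train <- corpus[!(as.character(corpus$episode_id) %in% test_ids), ,
                    drop = FALSE]
    models <- learn_behaviors(train, min_support = min_support,
                              distinguish_occurrences = distinguish_occurrences)
    for (eid in test_ids) {
      ep <- eps[[eid]]
      rep0 <- calculate_shifts(models, ep, config = cfg, episode_id = eid)
      g0 <- glance(rep0)
      matched <- isTRUE(g0$matched) && g0$modification_count == 0 &&
        g0$likelihood > 0
      recovered <- NA
      n_inject <- NA_integer_
      if (perturb) {
        drawn <- NULL
        for (try in 1:50) {
          cand <- perturb_episode(
            ep, ops = c("delete", "substitute", "swap"), n_ops = 1,
            pool = alphabet, seed = rng$next_seed())
          still_frequent <- any(vapply(models, function(m) {
            episode_likelihood(cand$episode, m,
                               include_initial_prob = cfg$include_initial_prob)
          }, numeric(1)) > 0)
          if (!still_frequent) { drawn <- cand; break }
        }
        if (is.null(drawn)) {
          recovered <- NA  # no genuine shift could be injected
        } else {
          repP <- calculate_shifts(models, drawn$episode, config = cfg,
                                   episode_id = paste0(eid, "_perturbed"))
          gP <- glance(repP)
          best_mods <- if (isTRUE(gP$matched) || nrow(repP$results) == 0) {
            tibble::tibble(op = character(), action = character(),
                           action2 = character(), position = integer())
          } else {
            r <- repP$results
            r[order(r$modification_count, r$criticality), ]$modifications[[1]]
          }
          recovered <- same_modification_set(best_mods, drawn$truth)
          n_inject <- nrow(drawn$truth)
        }
      }
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        fold = f, episode_id = eid,
        behavior = if (is.null(groups)) NA_character_ else groups[[eid]],
        matched = matched, likelihood = g0$likelihood,
        recovered = recovered, n_injected = n_inject
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  structure(
    list(results = results, folds = folds, seed = seed, config = cfg,
         perturb = perturb),
    class = "cv_result"
  )
}

#' Per-episode cross-validation results
#'
#' @param x A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @return Tibble with one row per held-out episode: `fold`, `episode_id`,
#'   `behavior`, `matched` (unperturbed episode identified as a path match),
#'   `likelihood`, `recovered` (injected modification set recovered
#'   exactly), `n_injected`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  x$results
}

#' Cross-validation summary rates
#'
#' @inheritParams tidy.cv_result
#' @return One-row tibble: `n_episodes`, `folds`, `match_rate_pct`
#'   (unperturbed episodes identified as path matches), `recovery_rate_pct`
#'   (perturbed episodes whose injected modification set was recovered
#'   exactly; `NA` if the perturbed arm was off).
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  r <- x$results
  rec <- if (x$perturb) 100 * mean(r$recovered, na.rm = TRUE) else NA_real_
  tibble::tibble(
    n_episodes = nrow(r),
    folds = x$folds,
    match_rate_pct = 100 * mean(r$matched),
    recovery_rate_pct = rec
  )
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<cv_result> %d episodes, %d folds: %.1f%% path matches%s\n",
    g$n_episodes, g$folds, g$match_rate_pct,
    if (!is.na(g$recovery_rate_pct)) {
      sprintf(", %.1f%% modification sets recovered", g$recovery_rate_pct)
    } else ""))
  invisible(x)
}
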