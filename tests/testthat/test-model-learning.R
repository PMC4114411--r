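test_that("a corpus of identical linear episodes learns a certain chain", {
  corpus <- rep(list(c("a", "b", "c", "d")), 6)
  m <- learn_behavior(corpus, min_support = 0.5)
  expect_equal(nrow(validate_behavior(m)), 0)
  expect_true(all(m$transitions$p == 1))
  expect_equal(m$terminal_states, "d")
  expect_equal(episode_likelihood(c("a", "b", "c", "d"), m), 1)
})

test_that("branch probabilities are exact empirical frequencies", {
  shower <- c("alarm", "bath", "shower", "kitchen")
  skip <- c("alarm", "bath", "kitchen")
  corpus <- c(rep(list(shower), 6), rep(list(skip), 4))
  m <- learn_behavior(corpus, min_support = 0.3)
  tr <- m$transitions
  expect_equal(tr$p[tr$from == "bath" & tr$to == "shower"], 0.6)
  expect_equal(tr$p[tr$from == "bath" & tr$to == "kitchen"], 0.4)
  expect_equal(episode_likelihood(shower, m), 0.6)
  expect_equal(episode_likelihood(skip, m), 0.4)
})

test_that("low-support actions are dropped before pair counting", {
  base <- c("a", "b", "c")
  rare <- c("a", "b", "x", "c")
  corpus <- c(rep(list(base), 8), rep(list(rare), 2))
  m <- learn_behavior(corpus, min_support = 0.5)
  expect_false("x" %in% m$states)
  # the pair (b, c) bridges the dropped action
  tr <- m$transitions
  expect_equal(tr$p[tr$from == "b" & tr$to == "c"], 1)
  disjoint <- list(c("p", "q"), c("r", "s"), c("t", "u"), c("v", "w"))
  expect_error(learn_behavior(disjoint, min_support = 0.9), "min_support")
})

test_that("transition matrix is recovered from seeded samples of a known chain", {
  truth <- behavior_model(
    id = "truth5",
    states = c("A", "B", "C", "D", "E"),
    initial_probs = c(A = 1),
    transitions = data.frame(
      from = c("A", "A", "B", "B", "C", "C", "D"),
      to   = c("B", "C", "C", "D", "D", "E", "E"),
      p    = c(0.3, 0.7, 0.5, 0.5, 0.2, 0.8, 1)
    )
  )
  corpus <- sample_episodes(truth, n = 1000, seed = 2024)
  corpus$behavior <- "truth5"
  m <- learn_behavior(corpus, min_support = 0.05, id = "est")
  expect_equal(nrow(validate_behavior(m)), 0)
  est <- m$transitions
  for (i in seq_len(nrow(truth$transitions))) {
    hit <- est$p[est$from == truth$transitions$from[i] &
                   est$to == truth$transitions$to[i]]
    expect_equal(length(hit), 1)
    expect_lt(abs(hit - truth$transitions$p[i]), 0.05)
  }
  # estimates tighten as the corpus grows
  m100 <- learn_behavior(sample_episodes(truth, n = 100, seed = 7),
                         min_support = 0.05)
  err <- function(est) {
    max(vapply(seq_len(nrow(truth$transitions)), function(i) {
      hit <- est$transitions$p[
        est$transitions$from == truth$transitions$from[i] &
          est$transitions$to == truth$transitions$to[i]]
      abs((if (length(hit)) hit else 0) - truth$transitions$p[i])
    }, numeric(1)))
  }
  expect_lt(err(m), 0.05)
  expect_lt(err(m100), 0.15)
})

test_that("learning is deterministic and invariant to re-running", {
  corpus <- sample_adl_corpus(n = 25, seed = 5)
  m1 <- learn_behaviors(corpus, distinguish_occurrences = TRUE)
  m2 <- learn_behaviors(corpus, distinguish_occurrences = TRUE)
  expect_identical(m1, m2)
  for (m in m1) expect_equal(nrow(validate_behavior(m)), 0)
})

test_that("occurrence distinction keeps revisited actions in observed order", {
  seqs <- list(c("open", "take", "close", "open", "put", "close"))
  plain <- learn_behavior(seqs, min_support = 1)
  tagged <- learn_behavior(seqs, min_support = 1,
                           distinguish_occurrences = TRUE)
  # the label-level chain admits an order never observed...
  expect_equal(
    episode_likelihood(c("open", "put", "close"), plain) > 0, TRUE)
  # ...the occurrence-distinguishing chain does not
  expect_equal(episode_likelihood(c("open", "put", "close"), tagged), 0)
  expect_equal(episode_likelihood(seqs[[1]], tagged), 1)
  p <- enumerate_paths(tagged)
  expect_equal(nrow(p), 1)
  expect_equal(p$actions[[1]], seqs[[1]])  # paths expose plain labels
})

test_that("cross-validation is exact on the ADL corpus and handles boundaries", {
  corpus <- sample_adl_corpus(n = 40, seed = 11)
  cv <- cross_validate(corpus, folds = 4, seed = 11)
  g <- glance(cv)
  expect_equal(g$match_rate_pct, 100)
  expect_equal(g$recovery_rate_pct, 100)
  expect_equal(nrow(tidy(cv)), 40)

  # degenerate two-episode, two-fold split is defined
  tiny <- corpus[corpus$episode_id %in% unique(corpus$episode_id)[1:2], ]
  cv2 <- cross_validate(tiny, folds = 2, perturb = FALSE, min_support = 0.1,
                        seed = 1)
  expect_equal(nrow(tidy(cv2)), 2)

  expect_error(cross_validate(tiny, folds = 3), "exceeds")
})

test_that("cross-validation is reproducible under a fixed seed", {
  corpus <- sample_adl_corpus(n = 20, seed = 2)
  cv1 <- cross_validate(corpus, folds = 4, seed = 99)
  cv2 <- cross_validate(corpus, folds = 4, seed = 99)
  expect_identical(tidy(cv1), tidy(cv2))
})
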