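test_that("worked-example likelihoods reproduce the printed values", {
  f1 <- load_fixture("michael_f1")
  expect_equal(episode_likelihood(load_fixture("C1"), f1), 0.6)
  expect_equal(episode_likelihood(load_fixture("C2"), f1), 0)
  expect_equal(episode_likelihood(load_fixture("C3"), f1), 0)
  expect_equal(path_likelihood(load_fixture("rho11"), f1), 0.4)
  expect_equal(path_likelihood(load_fixture("rho12"), f1), 0.6)
})

test_that("likelihood is zero off the chain and one on an all-certain chain", {
  f1 <- load_fixture("michael_f1")
  # unknown action
  expect_equal(episode_likelihood(c("Alarm, on", "Dog, out"), f1), 0)
  # valid prefix that stops before an ending state
  expect_equal(
    episode_likelihood(c("Alarm, on", "Bathroom, on", "Shower, on"), f1), 0)
  # does not start at a start state
  expect_equal(episode_likelihood(c("Kitchen, on", "Breakfast, on"), f1), 0)
  lin <- linear_behavior("lin", c("a", "b", "c"))
  expect_equal(episode_likelihood(c("a", "b", "c"), lin), 1)
  expect_equal(path_likelihood(c("a", "b", "c"), lin), 1)
})

test_that("episode likelihood equals a brute-force product of matrix entries", {
  for (seed in 1:5) {
    ch <- random_acyclic_chain(5, seed = seed)
    ep <- sample_episode(ch, seed = seed + 100)
    byhand <- prod(vapply(seq_len(length(ep) - 1), function(k) {
      tr <- ch$transitions
      hit <- tr$p[tr$from == ep[k] & tr$to == ep[k + 1]]
      if (length(hit)) hit else 0
    }, numeric(1)))
    expect_equal(episode_likelihood(ep, ch), byhand)
  }
})

test_that("initial probability can optionally multiply into the likelihood", {
  ch <- behavior_model(
    id = "twostart", states = c("a", "b", "z"),
    initial_probs = c(a = 0.25, b = 0.75),
    transitions = data.frame(from = c("a", "b"), to = c("z", "z"), p = 1)
  )
  expect_equal(episode_likelihood(c("a", "z"), ch), 1)
  expect_equal(episode_likelihood(c("a", "z"), ch, include_initial_prob = TRUE),
               0.25)
})

test_that("path enumeration finds exactly the two Michael paths", {
  p <- enumerate_paths(load_fixture("michael_f1"), threshold = 0.01,
                       max_length = 50)
  expect_equal(nrow(p), 2)
  expect_equal(p$likelihood, c(0.6, 0.4))
  expect_equal(p$actions[[1]], load_fixture("rho12"))
  expect_equal(p$actions[[2]], load_fixture("rho11"))
})

test_that("threshold prunes self-loop paths exactly as exhaustive filtering", {
  looped <- behavior_model(
    id = "loop", states = c("s", "t"),
    initial_probs = c(s = 1),
    transitions = data.frame(from = c("s", "s"), to = c("s", "t"),
                             p = c(0.5, 0.5))
  )
  p <- enumerate_paths(looped, threshold = 0.1, max_length = 20)
  expect_equal(sort(p$likelihood), c(0.125, 0.25, 0.5))
  oracle <- oracle_enumerate_paths(looped, max_length = 20)
  kept <- Filter(function(x) x$likelihood >= 0.1, oracle)
  expect_setequal(vapply(kept, function(x) paste(x$actions, collapse = "|"),
                         character(1)),
                  vapply(p$actions, paste, character(1), collapse = "|"))
})

test_that("pruned DFS equals exhaustive enumeration plus filter on random chains", {
  for (seed in 1:8) {
    ch <- random_acyclic_chain(sample(3:6, 1), seed = seed)
    thr <- c(0.001, 0.05, 0.3)[seed %% 3 + 1]
    p <- suppressWarnings(enumerate_paths(ch, threshold = thr,
                                          max_length = 30))
    oracle <- oracle_enumerate_paths(ch, max_length = 30)
    kept <- Filter(function(x) x$likelihood >= thr, oracle)
    expect_equal(nrow(p), length(kept))
    if (length(kept) == 0) next
    key <- function(actions) paste(actions, collapse = "|")
    om <- vapply(kept, function(x) x$likelihood, numeric(1))
    names(om) <- vapply(kept, function(x) key(x$actions), character(1))
    pm <- stats::setNames(p$likelihood, vapply(p$actions, key, character(1)))
    expect_mapequal(as.list(pm), as.list(om))
  }
})

test_that("path likelihoods of an acyclic chain sum to one and match both equations", {
  for (seed in 1:5) {
    ch <- random_acyclic_chain(6, seed = seed + 50)
    p <- enumerate_paths(ch, threshold = 1e-12, max_length = 50)
    expect_equal(sum(p$likelihood), 1, tolerance = 1e-9)
    for (j in seq_len(nrow(p))) {
      expect_equal(episode_likelihood(p$actions[[j]], ch), p$likelihood[j])
      expect_equal(path_likelihood(p$actions[[j]], ch), p$likelihood[j])
    }
  }
})

test_that("a frequent episode is found among paths at its own likelihood", {
  f1 <- load_fixture("michael_f1")
  C1 <- load_fixture("C1")
  ll <- episode_likelihood(C1, f1)
  p <- enumerate_paths(f1, threshold = ll, max_length = length(C1))
  expect_true(any(vapply(p$actions, identical, logical(1), C1)))
})

test_that("model validation reports violations without raising", {
  f1 <- load_fixture("michael_f1")
  expect_equal(nrow(validate_behavior(f1)), 0)

  bad <- f1
  bad$transitions$p[bad$transitions$from == "Bathroom, on" &
                      bad$transitions$to == "Shower, on"] <- 0.7
  v <- validate_behavior(bad)
  expect_equal(nrow(v), 1)
  expect_equal(v$where, "Bathroom, on")
  expect_match(v$violation, "1.1")

  bad2 <- f1
  bad2$transitions <- rbind(bad2$transitions,
                            data.frame(from = "Kitchen, off", to = "Ghost, on",
                                       p = 1))
  v2 <- validate_behavior(bad2)
  expect_true(any(v2$where == "Ghost, on" &
                    grepl("undeclared", v2$violation)))

  expect_error(episode_likelihood(load_fixture("C1"), bad), "invalid")
})

test_that("empty or malformed episodes are rejected", {
  f1 <- load_fixture("michael_f1")
  expect_error(episode_likelihood(character(), f1), "at least one action")
  expect_error(path_likelihood(c("Alarm, on", "Pill, on"), f1),
               "not a traversal")
})

test_that("action labels are whitespace-normalized, case kept", {
  expect_equal(normalize_action("  Pill,   on "), "Pill, on")
  f1 <- load_fixture("michael_f1")
  C1_messy <- gsub(", ", ",   ", load_fixture("C1"))
  expect_equal(episode_likelihood(C1_messy, f1), 0.6)
  expect_equal(episode_likelihood(toupper(load_fixture("C1")), f1), 0)
})

test_that("chains with no reachable ending state warn and return no paths", {
  ch <- behavior_model(
    id = "nowhere", states = c("a", "b"),
    initial_probs = c(a = 1),
    transitions = data.frame(from = c("a", "b"), to = c("b", "a"),
                             p = c(1, 1)),
    end_probs = c(a = 0, b = 0),
    validate = FALSE
  )
  expect_warning(p <- enumerate_paths(ch, threshold = 0.5, max_length = 10),
                 "no complete path")
  expect_equal(nrow(p), 0)
})
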