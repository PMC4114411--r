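test_that("distance matrix reproduces the worked modification counts", {
  C2 <- load_fixture("C2")
  C3 <- load_fixture("C3")
  rho11 <- load_fixture("rho11")
  rho12 <- load_fixture("rho12")
  expect_equal(build_distance_matrix(C2, rho11)$count, 3)
  expect_equal(build_distance_matrix(C2, rho12)$count, 1)
  expect_equal(build_distance_matrix(C3, rho11)$count, 3)
  expect_equal(build_distance_matrix(C3, rho12)$count, 1)
  expect_equal(build_distance_matrix(C2, C2)$count, 0)
})

test_that("backtraced modification sets match the worked examples and replay", {
  C2 <- load_fixture("C2")
  C3 <- load_fixture("C3")
  rho11 <- load_fixture("rho11")
  rho12 <- load_fixture("rho12")

  m1 <- backtrace_modifications(build_distance_matrix(C2, rho11))
  expect_setequal(paste(m1$op, m1$action),
                  c("delete Shower, on", "delete Shower, off",
                    "insert Pill, on"))
  expect_equal(apply_modifications(C2, m1), rho11)

  m2 <- backtrace_modifications(build_distance_matrix(C2, rho12))
  expect_equal(m2$op, "insert")
  expect_equal(m2$action, "Pill, on")
  expect_equal(apply_modifications(C2, m2), rho12)

  m3 <- backtrace_modifications(build_distance_matrix(C3, rho12))
  expect_equal(m3$op, "swap")
  expect_equal(m3$action, "Pill, on")
  expect_equal(m3$action2, "Breakfast, on")
  expect_equal(apply_modifications(C3, m3), rho12)

  expect_equal(nrow(backtrace_modifications(build_distance_matrix(C3, C3))), 0)
})

test_that("distance matrix structure follows the recurrence invariants", {
  D <- build_distance_matrix(load_fixture("C2"), load_fixture("rho11"))
  expect_equal(D$d[1, ], 0:length(D$path))
  expect_equal(D$d[, 1], 0:length(D$episode))
  for (m in 2:nrow(D$d)) {
    for (n in 2:ncol(D$d)) {
      expect_lte(D$d[m, n],
                 1 + min(D$d[m - 1, n], D$d[m, n - 1], D$d[m - 1, n - 1]))
    }
  }
})

test_that("matrix counts equal the exhaustive edit-script oracle", {
  # exhaustive over all pairs of very short episodes
  ab <- c("a", "b")
  shorts <- unlist(lapply(1:2, function(l) {
    apply(expand.grid(rep(list(ab), l)), 1, paste, collapse = "")
  }))
  for (x in shorts) {
    for (y in shorts) {
      a <- strsplit(x, "")[[1]]
      b <- strsplit(y, "")[[1]]
      expect_equal(build_distance_matrix(a, b)$count,
                   oracle_edit_distance(a, b),
                   info = paste(x, "vs", y))
    }
  }
  # randomized pairs up to length 6 over a 4-letter alphabet
  withr::with_seed(424, {
    for (k in 1:60) {
      a <- random_episode(sample(1:6, 1))
      b <- random_episode(sample(1:6, 1))
      D <- build_distance_matrix(a, b)
      expect_equal(D$count, oracle_edit_distance(a, b),
                   info = paste(paste(a, collapse = ""), "vs",
                                paste(b, collapse = "")))
      mods <- backtrace_modifications(D)
      expect_equal(nrow(mods), D$count)
      expect_equal(apply_modifications(a, mods), b)
    }
  })
})

test_that("distance respects the length bounds", {
  withr::with_seed(99, {
    for (k in 1:25) {
      a <- random_episode(sample(1:6, 1))
      b <- random_episode(sample(1:6, 1))
      d <- build_distance_matrix(a, b)$count
      expect_gte(d, abs(length(a) - length(b)))
      expect_lte(d, max(length(a), length(b)))
    }
  })
})

test_that("criticality aggregates per the configured rule", {
  cmap <- criticality_map(
    data.frame(op = c("insert", "swap"),
               action = c("Pill, on", "Pill, on"),
               action2 = c(NA, "Breakfast, on"),
               value = c(0.2, 0.4))
  )
  ins <- data.frame(op = "insert", action = "Pill, on",
                    action2 = NA_character_)
  expect_equal(criticality(ins, cmap), 0.2)
  expect_equal(criticality(ins[0, ], cmap), 1)
  two <- data.frame(op = c("insert", "swap"),
                    action = c("Pill, on", "Pill, on"),
                    action2 = c(NA, "Breakfast, on"))
  expect_equal(criticality(two, cmap), 0.2)
  expect_equal(criticality(two, cmap, aggregation = "product"),
               0.2 * 0.4)
  expect_equal(criticality(two, cmap, aggregation = "mean"), 0.3)
  # unmapped modification falls back on the default
  del <- data.frame(op = "delete", action = "Shower, on",
                    action2 = NA_character_)
  expect_equal(criticality(del, cmap), 1)
})

test_that("criticality rules resolve by specificity, wildcards last", {
  cmap <- criticality_map(
    data.frame(op = c("insert", "insert"),
               action = c(NA, "Pill, on"),
               value = c(0.9, 0.2))
  )
  expect_equal(
    criticality(data.frame(op = "insert", action = "Pill, on"), cmap), 0.2)
  expect_equal(
    criticality(data.frame(op = "insert", action = "Shower, on"), cmap), 0.9)
  expect_error(criticality_map(data.frame(op = "insert", value = 1.5)),
               "\\[0, 1\\]")
  expect_error(criticality_map(data.frame(op = "teleport", value = 0.5)),
               "unknown modification op")
})

test_that("risk factor is zero without modifications and grows with both inputs", {
  expect_equal(risk_factor(0, 0.2), 0)
  expect_equal(risk_factor(1, 0.2), 0.8)
  expect_equal(risk_factor(3, 0.2), 2.4)
  expect_equal(risk_factor(5, 1), 0)
  counts <- 0:6
  phis <- risk_factor(counts, 0.3)
  expect_true(all(diff(phis) > 0))
  crits <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(risk_factor(2, crits)) < 0))
})

test_that("calculate_shifts reproduces the worked end-to-end decisions", {
  f1 <- load_fixture("michael_f1")
  cmap <- load_fixture("criticality_map_michael")

  r1 <- calculate_shifts(f1, load_fixture("C1"), cmap)
  g1 <- glance(r1)
  expect_true(g1$matched)
  expect_equal(g1$likelihood, 0.6)
  expect_equal(g1$modification_count, 0)
  expect_equal(g1$risk_factor, 0)

  r2 <- calculate_shifts(f1, load_fixture("C2"), cmap)
  g2 <- glance(r2)
  expect_false(g2$matched)
  expect_equal(g2$modification_count, 1)
  expect_equal(g2$criticality, 0.2)
  expect_equal(g2$risk_factor, 0.8)
  m2 <- tidy(r2)$modifications[[1]]
  expect_equal(m2$op, "insert")
  expect_equal(m2$action, "Pill, on")
  # the one-edit path is the shower-taking one, not the 3-edit alternative
  p <- enumerate_paths(f1)
  best_path <- p$actions[[match(tidy(r2)$path_id, p$path_id)]]
  expect_equal(best_path, load_fixture("rho12"))

  r3 <- calculate_shifts(f1, load_fixture("C3"), cmap)
  g3 <- glance(r3)
  expect_equal(g3$modification_count, 1)
  expect_equal(g3$criticality, 0.4)
  m3 <- tidy(r3)$modifications[[1]]
  expect_equal(m3$op, "swap")
})

test_that("an episode sharing no actions with the chain needs max-length edits", {
  f1 <- load_fixture("michael_f1")
  alien <- c("TV, on", "Sofa, sat", "TV, off")
  r <- calculate_shifts(f1, alien)
  res <- tidy(r)
  # oracle on the disjoint alphabet: substitutions + inserts
  p <- enumerate_paths(f1)
  expected <- min(vapply(p$actions, function(path) {
    oracle_edit_distance(alien, path)
  }, numeric(1)))
  expect_equal(res$modification_count, expected)
  expect_equal(expected, min(lengths(p$actions)))  # max(|C|, |rho|) here
})

test_that("calculate_shifts on an enumerated path returns its likelihood, no edits", {
  for (seed in c(2, 7)) {
    ch <- random_acyclic_chain(5, seed = seed)
    p <- enumerate_paths(ch, threshold = 1e-9, max_length = 30)
    for (j in seq_len(min(nrow(p), 4))) {
      r <- glance(calculate_shifts(ch, p$actions[[j]]))
      expect_true(r$matched)
      expect_equal(r$likelihood, p$likelihood[j])
      expect_equal(r$modification_count, 0)
    }
  }
})

test_that("injecting k separated corruptions yields a count of at most k", {
  ch <- load_fixture("adl_cook")
  path <- enumerate_paths(ch)$actions[[1]]
  withr::with_seed(5, {
    for (k in 1:3) {
      pert <- perturb_episode(path, n_ops = k, pool = c(path, "Radio On"))
      r <- glance(calculate_shifts(ch, pert$episode))
      expect_lte(r$modification_count, k)
    }
  })
})

test_that("anomaly flag follows the configured risk threshold", {
  f1 <- load_fixture("michael_f1")
  cmap <- load_fixture("criticality_map_michael")
  C2 <- load_fixture("C2")
  r_default <- glance(calculate_shifts(f1, C2, cmap))          # phi = 0.8
  expect_false(r_default$anomalous)
  r_strict <- glance(calculate_shifts(f1, C2, cmap,
                                      config = list(anomaly_threshold = 0.5)))
  expect_true(r_strict$anomalous)
  expect_error(calculate_shifts(f1, C2, cmap, config = list(bogus = 1)),
               "unknown config key")
})
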