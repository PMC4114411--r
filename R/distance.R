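#' Edit-distance matrix between an observed episode and a path
#'
#' Builds the dynamic-programming distance matrix `D` whose cell `d[m, n]` is
#' the minimum number of unit-cost modifications turning the first `m`
#' observed actions into the first `n` path actions. Four modification types
#' are allowed, reflecting how a routine can drift:
#'
#' * **insert(a)** — add a forgotten action `a` to the observed episode;
#' * **delete(a)** — remove an extra action the user performed;
#' * **substitute(a, b)** — the user did `a` instead of the required `b`;
#' * **swap(a, b)** — the user did two adjacent actions in reverse order.
#'
#' The recurrence is the Damerau–Levenshtein one: a matching action carries
#' the diagonal value; otherwise `1 + min(deletion, insertion, substitution)`
#' and, when the two trailing actions are crossed
#' (`C[m] == path[n-1] && C[m-1] == path[n]`), the adjacent-transposition
#' case `d[m-2, n-2] + 1`. Boundary cells are `d[m, 0] = m` (delete
#' everything) and `d[0, n] = n` (insert everything). The bottom-right cell
#' is the minimum modification count; per-cell provenance (which operation
#' achieved the minimum, under the deterministic preference
#' match > swap > substitute > delete > insert) drives
#' [backtrace_modifications()].
#'
#' @param episode Observed episode: character vector of action labels or
#'   data frame with an `action` column.
#' @param path Target path (same forms).
#' @return An object of class `distance_matrix`: list with `d` (the
#'   `(|C|+1) x (|path|+1)` integer matrix), `op` (provenance matrix),
#'   `episode`, `path`, and `count` (the bottom-right cell).
#' @examples
#' D <- build_distance_matrix(load_fixture("C2"), load_fixture("rho12"))
#' D$count  # 1
#' @export
build_distance_matrix <- function(episode, path) {
  C <- as_episode(episode)
  P <- as_episode(path, "path")
  nC <- length(C)
  nP <- length(P)
  d <- matrix(0L, nC + 1, nP + 1)
  op <- matrix("", nC + 1, nP + 1)
  d[, 1] <- 0:nC
  d[1, ] <- 0:nP
  op[-1, 1] <- "delete"
  op[1, -1] <- "insert"
  for (m in seq_len(nC)) {
    for (n in seq_len(nP)) {
      if (C[m] == P[n]) {
        # diagonal carry is always minimal at unit costs
        d[m + 1, n + 1] <- d[m, n]
        op[m + 1, n + 1] <- "match"
        next
      }
      cand <- c(substitute = d[m, n] + 1L,
                delete     = d[m, n + 1] + 1L,
                insert     = d[m + 1, n] + 1L)
      if (m >= 2 && n >= 2 && C[m] == P[n - 1] && C[m - 1] == P[n]) {
        cand <- c(swap = d[m - 1, n - 1] + 1L, cand)
      }
      best <- min(cand)
      pref <- c("swap", "substitute", "delete", "insert")
      pick <- pref[pref %in% names(cand)[cand == best]][1]
      d[m + 1, n + 1] <- best
      op[m + 1, n + 1] <- pick
    }
  }
  structure(
    list(d = d, op = op, episode = C, path = P, count = d[nC + 1, nP + 1]),
    class = "distance_matrix"
  )
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> |C| = %d, |path| = %d, modifications = %d\n",
              length(x$episode), length(x$path), x$count))
  invisible(x)
}

#' Extract the modification set from a distance matrix
#'
#' Walks the provenance of the distance matrix from the bottom-right cell
#' back to the origin and emits the modification set `M` that transforms the
#' observed episode into the path. `|M|` always equals the bottom-right cell
#' of the matrix, and replaying `M` on the episode (see
#' [apply_modifications()]) reproduces the path exactly. Among equally
#' minimal scripts the deterministic preference match > swap > substitute >
#' delete > insert recorded at matrix-construction time picks one.
#'
#' @param D A `distance_matrix` from [build_distance_matrix()].
#' @return A tibble of modifications, in left-to-right episode order, with
#'   columns `op` (`insert`/`delete`/`substitute`/`swap`), `action`,
#'   `action2` (`NA` except for substitute — the required replacement — and
#'   swap — the second transposed action), and `position` (1-based index in
#'   the observed episode; an insert at position `p` adds the action after
#'   the episode's `p`-th action, `p = 0` meaning at the front).
#' @examples
#' D <- build_distance_matrix(load_fixture("C3"), load_fixture("rho12"))
#' backtrace_modifications(D)  # one swap('Pill, on', 'Breakfast, on')
#' @export
backtrace_modifications <- function(D) {
  stopifnot(inherits(D, "distance_matrix"))
  C <- D$episode
  P <- D$path
  m <- length(C)
  n <- length(P)
  mods <- list()
  emit <- function(op, action, action2, position) {
    mods[[length(mods) + 1L]] <<- tibble::tibble(
      op = op, action = action, action2 = action2, position = position
    )
  }
  while (m > 0 || n > 0) {
    step <- D$op[m + 1, n + 1]
    if (step == "match") {
      m <- m - 1; n <- n - 1
    } else if (step == "substitute") {
      emit("substitute", C[m], P[n], m)
      m <- m - 1; n <- n - 1
    } else if (step == "delete") {
      emit("delete", C[m], NA_character_, m)
      m <- m - 1
    } else if (step == "insert") {
      emit("insert", P[n], NA_character_, m)
      n <- n - 1
    } else if (step == "swap") {
      emit("swap", C[m - 1], C[m], m - 1)
      m <- m - 2; n <- n - 2
    } else {
      stop("inconsistent distance matrix: no provenance at cell (",
           m, ", ", n, ")", call. = FALSE)
    }
  }
  if (length(mods) == 0) {
    return(tibble::tibble(op = character(), action = character(),
                          action2 = character(), position = integer()))
  }
  # backtrace emits right-to-left; present left-to-right
  dplyr::bind_rows(rev(mods))
}

#' Replay a modification set on an episode
#'
#' Applies a modification tibble (as produced by
#' [backtrace_modifications()]) to an observed episode. Positions refer to
#' the *original* episode, so modifications are applied right-to-left; the
#' result of replaying a backtraced set is exactly the path the set was
#' computed against.
#'
#' @param episode Character vector of action labels.
#' @param modifications Tibble with columns `op`, `action`, `action2`,
#'   `position`.
#' @return The modified episode as a character vector.
#' @export
apply_modifications <- function(episode, modifications) {
  out <- as_episode(episode)
  if (nrow(modifications) == 0) return(out)
  for (i in rev(seq_len(nrow(modifications)))) {
    op <- modifications$op[i]
    pos <- modifications$position[i]
    if (op == "insert") {
      out <- append(out, modifications$action[i], after = pos)
    } else if (op == "delete") {
      out <- out[-pos]
    } else if (op == "substitute") {
      out[pos] <- modifications$action2[i]
    } else if (op == "swap") {
      out[c(pos, pos + 1)] <- out[c(pos + 1, pos)]
    } else {
      stop("unknown modification op: ", op, call. = FALSE)
    }
  }
  out
}
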