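# Built-in worked-example fixtures: Michael's morning-ritual chain with its
# two paths and three observed behaviors, the five WSU smart-apartment ADL
# action sequences, and the matching criticality map. All are constructed in
# code so the examples and tests need no external files.

michael_states <- c(
  "Alarm, on", "Bathroom, on", "Shower, on", "Shower, off", "Bathroom, off",
  "Kitchen, on", "Breakfast, on", "Pill, on", "Kitchen, off"
)

# Branch probabilities reconstructed from the worked-example path likelihoods:
# the shower branch is taken with probability 0.6 and skipped with 0.4;
# every other transition is certain, and the chain starts at 'Alarm, on'.
michael_f1 <- function() {
  behavior_model(
    id = "michael_f1",
    states = michael_states,
    initial_probs = c("Alarm, on" = 1),
    transitions = tibble::tribble(
      ~from,           ~to,             ~p,
      "Alarm, on",     "Bathroom, on",  1,
      "Bathroom, on",  "Shower, on",    0.6,
      "Bathroom, on",  "Bathroom, off", 0.4,
      "Shower, on",    "Shower, off",   1,
      "Shower, off",   "Bathroom, off", 1,
      "Bathroom, off", "Kitchen, on",   1,
      "Kitchen, on",   "Breakfast, on", 1,
      "Breakfast, on", "Pill, on",      1,
      "Pill, on",      "Kitchen, off",  1
    )
  )
}

michael_episodes <- list(
  # the complete shower-taking realization
  C1 = c("Alarm, on", "Bathroom, on", "Shower, on", "Shower, off",
         "Bathroom, off", "Kitchen, on", "Breakfast, on", "Pill, on",
         "Kitchen, off"),
  # the pill is forgotten
  C2 = c("Alarm, on", "Bathroom, on", "Shower, on", "Shower, off",
         "Bathroom, off", "Kitchen, on", "Breakfast, on", "Kitchen, off"),
  # the pill is taken before breakfast
  C3 = c("Alarm, on", "Bathroom, on", "Shower, on", "Shower, off",
         "Bathroom, off", "Kitchen, on", "Pill, on", "Breakfast, on",
         "Kitchen, off"),
  # shower-skipping path
  rho11 = c("Alarm, on", "Bathroom, on", "Bathroom, off", "Kitchen, on",
            "Breakfast, on", "Pill, on", "Kitchen, off"),
  # shower-taking path
  rho12 = c("Alarm, on", "Bathroom, on", "Shower, on", "Shower, off",
            "Bathroom, off", "Kitchen, on", "Breakfast, on", "Pill, on",
            "Kitchen, off")
)

# The five ADL action sequences recorded in the WSU smart-apartment
# environment. Each activity is a fixed sequence, so transitions are
# deterministic.
adl_sequences <- list(
  adl_phone = c("PhoneBook On", "Phone On", "Phone Off"),
  adl_wash  = c("Water On", "Water Off"),
  adl_cook  = c("Cabinet On", "Raisins On", "Oatmeal On", "MeasuringSpoon On",
                "Bowl On", "Sugar On", "Cabinet Off", "Water On", "Water Off",
                "Pot On", "Burner On", "Burner Off"),
  adl_eat   = c("Cabinet On", "Medicine On", "Cabinet Off", "Water On",
                "Water Off", "Cabinet On", "Medicine Off", "Cabinet Off"),
  adl_clean = c("Water On", "Water Off")
)

#' Build a deterministic linear chain from an action sequence
#'
#' Each consecutive pair becomes a transition with probability 1; the first
#' action is the certain start and the last the terminal state. Useful for
#' routines observed as fixed sequences. The sequence may revisit an action
#' (the chain then has a merged state), but only if every revisit is
#' followed by the same successor — otherwise the sequence is not expressible
#' as a first-order chain and an error is raised.
#'
#' @param id Behavior identifier.
#' @param actions Character vector of action labels in order.
#' @return A `behavior_model`.
#' @examples
#' linear_behavior("wash", c("Water On", "Water Off"))
#' @export
linear_behavior <- function(id, actions) {
  actions <- as_episode(actions, "actions")
  if (length(actions) < 2) {
    stop("a linear behavior needs at least 2 actions", call. = FALSE)
  }
  tr <- tibble::tibble(from = actions[-length(actions)], to = actions[-1], p = 1)
  tr <- unique(tr)
  if (anyDuplicated(tr$from)) {
    stop("sequence revisits '",
         tr$from[duplicated(tr$from)][1],
         "' with different successors; not a deterministic chain",
         call. = FALSE)
  }
  if (actions[length(actions)] %in% tr$from) {
    stop("last action '", actions[length(actions)],
         "' reoccurs mid-sequence; no terminal state", call. = FALSE)
  }
  behavior_model(id = id, states = unique(actions),
                 initial_probs = setNames(1, actions[1]), transitions = tr)
}

#' Load a built-in worked-example fixture
#'
#' Returns the objects of the package's running example — Michael's
#' morning-ritual chain, its two paths and three observed behaviors, the
#' expert criticality map — and the five smart-apartment ADL chains used by
#' the validation harness.
#'
#' @param name One of `"michael_f1"` (the `behavior_model`), `"C1"`, `"C2"`,
#'   `"C3"` (observed episodes, character vectors), `"rho11"`, `"rho12"`
#'   (the chain's two paths), `"adl_phone"`, `"adl_wash"`, `"adl_cook"`,
#'   `"adl_eat"`, `"adl_clean"` (linear `behavior_model`s), or
#'   `"criticality_map_michael"`. The criticality map is reconstructed from
#'   the worked outputs: `g(insert('Pill, on')) = 0.2`,
#'   `g(swap('Pill, on', 'Breakfast, on')) = 0.4`, everything else 1.
#' @return A `behavior_model`, character vector, or `criticality_map`.
#' @examples
#' load_fixture("adl_wash")
#' load_fixture("C2")
#' @export
load_fixture <- function(name) {
  if (name == "michael_f1") return(michael_f1())
  if (name %in% names(michael_episodes)) return(michael_episodes[[name]])
  if (name %in% names(adl_sequences)) {
    # frequency-count chain of the fixed sequence: identical to
    # linear_behavior() when no action repeats; occurrence distinction keeps
    # sequences that revisit an action (Eat) deterministic
    return(learn_behavior(list(adl_sequences[[name]]), min_support = 1,
                          id = name, distinguish_occurrences = TRUE))
  }
  if (name == "criticality_map_michael") {
    return(criticality_map(
      tibble::tribble(
        ~op,      ~action,    ~action2,        ~value,
        "insert", "Pill, on", NA_character_,   0.2,
        "swap",   "Pill, on", "Breakfast, on", 0.4
      ),
      default_value = 1
    ))
  }
  stop("unknown fixture: '", name, "'. Available: michael_f1, C1, C2, C3, ",
       "rho11, rho12, adl_phone, adl_wash, adl_cook, adl_eat, adl_clean, ",
       "criticality_map_michael", call. = FALSE)
}

#' All five ADL chains as a named list
#'
#' Convenience wrapper around [load_fixture()] for the validation harness.
#'
#' @return Named list of five linear `behavior_model`s.
#' @export
adl_behaviors <- function() {
  nm <- names(adl_sequences)
  setNames(lapply(nm, load_fixture), nm)
}
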