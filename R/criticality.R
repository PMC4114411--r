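#' Build a criticality mapping
#'
#' Domain experts assign each possible modification a criticality value in
#' `[0, 1]`, **lower meaning more critical**: forgetting a daily pill
#' (`insert('Pill, on')` as the repairing modification) might map to 0.2,
#' while skipping the shower is harmless and stays near 1. Rules may name
#' the full operand(s) or leave them `NA` as an op-level wildcard; the most
#' specific matching rule wins, and unmapped modifications fall back on
#' `default_value`.
#'
#' @param rules Data frame with columns `op` (one of `insert`, `delete`,
#'   `substitute`, `swap`), `action`, `action2` (optional, `NA` = wildcard)
#'   and `value` (criticality in `[0, 1]`). May have zero rows.
#' @param default_value Criticality for modifications matched by no rule
#'   (default 1: non-critical).
#' @return An object of class `criticality_map`.
#' @examples
#' cmap <- criticality_map(
#'   data.frame(op = "insert", action = "Pill, on", value = 0.2)
#' )
#' criticality(data.frame(op = "insert", action = "Pill, on"), cmap)
#' @export
criticality_map <- function(rules = NULL, default_value = 1) {
  if (is.null(rules) || nrow(as.data.frame(rules)) == 0) {
    rules <- tibble::tibble(op = character(), action = character(),
                            action2 = character(), value = numeric())
  } else {
    rules <- tibble::as_tibble(rules)
    if (!"action" %in% names(rules)) rules$action <- NA_character_
    if (!"action2" %in% names(rules)) rules$action2 <- NA_character_
    rules <- rules[c("op", "action", "action2", "value")]
    rules$action <- vapply(rules$action, function(a)
      if (is.na(a)) NA_character_ else normalize_action(a), character(1),
      USE.NAMES = FALSE)
    rules$action2 <- vapply(rules$action2, function(a)
      if (is.na(a)) NA_character_ else normalize_action(a), character(1),
      USE.NAMES = FALSE)
  }
  bad_op <- setdiff(unique(rules$op), c("insert", "delete", "substitute", "swap"))
  if (length(bad_op)) {
    stop("unknown modification op in criticality map: ",
         paste(bad_op, collapse = ", "), call. = FALSE)
  }
  if (any(rules$value < 0 | rules$value > 1) ||
      default_value < 0 || default_value > 1) {
    stop("criticality values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(rules = rules, default_value = as.numeric(default_value)),
            class = "criticality_map")
}

#' @export
print.criticality_map <- function(x, ...) {
  cat(sprintf("<criticality_map> %d rule(s), default %g\n",
              nrow(x$rules), x$default_value))
  invisible(x)
}

# Criticality value g(h) of each modification row; most specific rule wins
# (exact operands beat op-level wildcards), ties broken by lower value.
modification_criticality <- function(modifications, cmap) {
  stopifnot(inherits(cmap, "criticality_map"))
  if (nrow(modifications) == 0) return(numeric(0))
  r <- cmap$rules
  vapply(seq_len(nrow(modifications)), function(i) {
    m <- modifications[i, ]
    ok <- r$op == m$op &
      (is.na(r$action) | r$action == m$action) &
      (is.na(r$action2) | (!is.na(m$action2) & r$action2 == m$action2))
    if (!any(ok)) return(cmap$default_value)
    hit <- r[ok, ]
    spec <- (!is.na(hit$action)) + (!is.na(hit$action2))
    hit <- hit[order(-spec, hit$value), ]
    hit$value[1]
  }, numeric(1))
}

#' Criticality of a modification set
#'
#' Aggregates the per-modification criticality values `g(h)` of a
#' modification set into a single value `Cr(M)`. The default aggregation is
#' the minimum — the most critical member dominates, so a missed pill is not
#' diluted by harmless edits; `product` and `mean` are available
#' alternatives. The empty set has criticality 1 (nothing critical
#' happened).
#'
#' @param modifications Tibble of modifications (columns `op`, `action`,
#'   optionally `action2`) as from [backtrace_modifications()].
#' @param cmap A [criticality_map()].
#' @param aggregation One of `"min"`, `"product"`, `"mean"`.
#' @return A criticality value in `[0, 1]`; lower = more critical.
#' @export
criticality <- function(modifications, cmap,
                        aggregation = c("min", "product", "mean")) {
  aggregation <- match.arg(aggregation)
  modifications <- tibble::as_tibble(modifications)
  if (!"action2" %in% names(modifications)) {
    modifications$action2 <- NA_character_
  }
  if (nrow(modifications) == 0) return(1)
  v <- modification_criticality(modifications, cmap)
  switch(aggregation, min = min(v), product = prod(v), mean = mean(v))
}

#' Behavior risk factor
#'
#' Combines the size of a modification set with its criticality into the
#' scalar risk factor `phi = count * (1 - Cr)`. It is 0 when no
#' modifications are needed (the episode is a frequent behavior) or when all
#' modifications are fully non-critical (`Cr = 1`), and grows both with the
#' number of modifications and with their severity (decreasing `Cr`). An
#' episode is flagged anomalous when `phi` exceeds the configured threshold.
#'
#' @param modification_count Non-negative integer.
#' @param criticality_value Criticality `Cr` in `[0, 1]`.
#' @return The risk factor, a non-negative number.
#' @examples
#' risk_factor(1, 0.2)  # 0.8
#' risk_factor(3, 0.2)  # 2.4
#' @export
risk_factor <- function(modification_count, criticality_value) {
  stopifnot(modification_count >= 0,
            criticality_value >= 0, criticality_value <= 1)
  modification_count * (1 - criticality_value)
}
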