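#' Fractional occupancy of each state
#'
#' Proportion of timepoints a subject spends in each state; unvisited
#' states get 0. Occupancies sum to 1 by construction.
#'
#' @param labels Integer state sequence (values in `1..n_states`).
#' @param n_states Number of states K.
#' @return Numeric vector of length K.
#' @export
occupancy <- function(labels, n_states) {
  labels <- assert_labels(labels, n_states)
  tabulate(labels, n_states) / length(labels)
}

#' Average lifetime (dwell time) of each state
#'
#' Mean duration of maximal uninterrupted runs of each state. The default
#' convention scores a run of L volumes as `L * TR` seconds; the
#' `"runlength_minus_one_times_TR"` convention scores it as `(L - 1) * TR`
#' (time between first and last volume of the visit), and `"volumes"`
#' returns the mean run length itself. Unvisited states are `NA`.
#'
#' @param labels Integer state sequence.
#' @param n_states Number of states K.
#' @param tr Repetition time in seconds.
#' @param convention Lifetime convention (see Details).
#' @return Numeric vector of length K (seconds, or volumes).
#' @export
lifetimes <- function(labels, n_states, tr = 2,
                      convention = c("runlength_times_TR",
                                     "runlength_minus_one_times_TR",
                                     "volumes")) {
  convention <- match.arg(convention)
  labels <- assert_labels(labels, n_states)
  r <- rle(labels)
  out <- rep(NA_real_, n_states)
  for (k in seq_len(n_states)) {
    runs <- r$lengths[r$values == k]
    if (length(runs) == 0) next
    out[k] <- switch(
      convention,
      runlength_times_TR = mean(runs) * tr,
      runlength_minus_one_times_TR = mean(runs - 1) * tr,
      volumes = mean(runs)
    )
  }
  out
}

#' Switch-conditional transition probabilities
#'
#' `Q[i, j]` is the probability that the next state is j given the current
#' state is i and a switch occurs: self-transitions are excluded, so the
#' diagonal is structurally zero and each defined row sums to 1. Rows of
#' states with no observed exits are `NA`. Set
#' `normalization = "per_volume"` for the self-inclusive variant in which
#' rows are normalized by all volume-to-volume steps out of the state.
#'
#' @param labels Integer state sequence.
#' @param n_states Number of states K.
#' @param normalization `"switch"` (default) or `"per_volume"`.
#' @return K x K numeric matrix.
#' @export
transition_matrix <- function(labels, n_states,
                              normalization = c("switch", "per_volume")) {
  normalization <- match.arg(normalization)
  labels <- assert_labels(labels, n_states)
  counts <- matrix(0, n_states, n_states)
  if (length(labels) > 1) {
    from <- labels[-length(labels)]
    to <- labels[-1]
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  q <- matrix(NA_real_, n_states, n_states)
  for (i in seq_len(n_states)) {
    exits <- sum(counts[i, -i])
    denom <- if (normalization == "switch") exits else sum(counts[i, ])
    if ((normalization == "switch" && exits > 0) ||
        (normalization == "per_volume" && denom > 0)) {
      q[i, ] <- counts[i, ] / denom
      if (normalization == "switch") q[i, i] <- 0
    }
  }
  dimnames(q) <- list(paste0("state_", seq_len(n_states)),
                      paste0("state_", seq_len(n_states)))
  q
}

#' Per-subject dynamic state metrics for a cohort
#'
#' Computes the three dynamic metrics per subject -- fractional occupancy,
#' average lifetime, and switch-conditional transition probabilities -- and
#' returns them as one long table, the input contract for the group
#' statistics. Undefined entries (unvisited states, rows without exits) are
#' `NA` and are excluded pairwise downstream.
#'
#' @param label_tbl Tibble with `subject_id`, a `labels` list-column, and
#'   optionally covariate columns such as `group` (carried through).
#' @param n_states Number of states K.
#' @param tr Repetition time in seconds.
#' @param lifetime_convention Passed to [lifetimes()].
#' @param transition_normalization Passed to [transition_matrix()].
#' @return Long tibble: `subject_id`, carried covariates, `metric`
#'   (`"occupancy"`, `"lifetime"`, `"transition"`), `state`, `to_state`
#'   (`NA` except for transitions), `value`.
#' @export
cohort_metrics <- function(label_tbl, n_states, tr = 2,
                           lifetime_convention = "runlength_times_TR",
                           transition_normalization = "switch") {
  stopifnot(is.data.frame(label_tbl),
            all(c("subject_id", "labels") %in% names(label_tbl)))
  carried <- setdiff(names(label_tbl), c("labels", "ts", "eig", "truth_labels"))
  rows <- purrr::map(seq_len(nrow(label_tbl)), function(i) {
    lab <- label_tbl$labels[[i]]
    occ <- occupancy(lab, n_states)
    lt <- lifetimes(lab, n_states, tr = tr, convention = lifetime_convention)
    q <- transition_matrix(lab, n_states,
                           normalization = transition_normalization)
    off <- which(row(q) != col(q), arr.ind = TRUE)
    base <- label_tbl[i, carried, drop = FALSE]
    bind_rows(
      tibble(base, metric = "occupancy", state = seq_len(n_states),
             to_state = NA_integer_, value = occ),
      tibble(base, metric = "lifetime", state = seq_len(n_states),
             to_state = NA_integer_, value = lt),
      tibble(base, metric = "transition", state = off[, 1],
             to_state = off[, 2], value = q[off])
    )
  })
  bind_rows(rows)
}

#' Group means and standard deviations of the dynamic metrics
#'
#' Summarizes a long metrics table by group, excluding undefined (`NA`)
#' entries pairwise.
#'
#' @param metrics_tbl Long table from [cohort_metrics()] including a
#'   `group` column.
#' @return Tibble: `metric`, `state`, `to_state`, `group`, `n`, `mean`, `sd`.
#' @export
summarise_metrics <- function(metrics_tbl) {
  stopifnot("group" %in% names(metrics_tbl))
  metrics_tbl |>
    group_by(.data$metric, .data$state, .data$to_state, .data$group) |>
    summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
}
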