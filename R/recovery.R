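#' Planted-occupancy recovery experiment
#'
#' Generates a single-group cohort whose state sequences are fixed-dwell
#' blocks drawn from a target occupancy vector, runs the full pipeline
#' (signal synthesis, band-pass, Hilbert phase, leading eigenvectors,
#' k-means at the planted k), matches recovered clusters to the planted
#' patterns, and reports per-subject and mean recovered occupancies in
#' planted-state order. This is the package's end-to-end check that the
#' analysis recovers the dynamics it was pointed at.
#'
#' @param pi Target occupancy vector (renormalized if it does not sum
#'   exactly to 1).
#' @param n_subjects Number of subjects.
#' @param dwell Dwell-block length in volumes.
#' @param n_regions,n_volumes,tr Acquisition geometry.
#' @param seed Master seed.
#' @param n_restarts k-means restarts.
#' @return List: `occupancy` (subjects x states matrix, planted-state
#'   order), `mean_occupancy` (length-K vector), `accuracy` (fraction of
#'   pooled frames assigned to the matched planted state), `matching`
#'   (tibble from [match_states()]).
#' @export
recover_occupancy <- function(pi, n_subjects = 20, dwell = 4,
                              n_regions = 105, n_volumes = 240, tr = 2,
                              seed = 1, n_restarts = 10) {
  pi <- pi / sum(pi)
  cfg <- cohort_config(
    n_per_group = n_subjects,
    dynamics = list(cohort = occupancy_dynamics(pi, dwell = dwell)),
    n_regions = n_regions, n_volumes = n_volumes, tr = tr, seed = seed
  )
  run_recovery(simulate_cohort(cfg), seed = seed, n_restarts = n_restarts)
}

#' Planted-transition recovery experiment
#'
#' Same design as [recover_occupancy()] but with Markov dynamics: geometric
#' dwell with the given stay probability and switch-conditional transitions
#' from `Q`. The recovered switch-conditional matrix is estimated from
#' switch counts pooled across subjects (after matching clusters to
#' planted states), which is the aggregate estimator whose sampling error
#' shrinks with cohort size.
#'
#' @param Q Planted switch-conditional matrix (rows renormalized to 1).
#' @param stay Per-volume stay probability.
#' @inheritParams recover_occupancy
#' @return List: `Q_hat` (pooled switch-conditional estimate, planted-state
#'   order), `max_abs_error` against the planted `Q`, `accuracy`,
#'   `matching`.
#' @export
recover_transitions <- function(Q, stay = 0.75, n_subjects = 20,
                                n_regions = 105, n_volumes = 240, tr = 2,
                                seed = 1, n_restarts = 10) {
  Q <- as.matrix(Q)
  diag(Q) <- 0
  Q <- Q / rowSums(Q)
  cfg <- cohort_config(
    n_per_group = n_subjects,
    dynamics = list(cohort = markov_dynamics(Q, stay = stay)),
    n_regions = n_regions, n_volumes = n_volumes, tr = tr, seed = seed
  )
  out <- run_recovery(simulate_cohort(cfg), seed = seed,
                      n_restarts = n_restarts)
  k <- nrow(Q)
  counts <- matrix(0, k, k)
  for (lab in out$labels_matched) {
    from <- lab[-length(lab)]
    to <- lab[-1]
    sw <- from != to
    for (i in which(sw)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  q_hat <- counts / rowSums(counts)
  diag(q_hat) <- 0
  out$Q_hat <- q_hat
  out$max_abs_error <- max(abs(q_hat - Q))
  out
}

# Shared engine: pipeline at the planted k, cluster-to-pattern matching,
# matched per-subject label streams and occupancies, frame accuracy.
run_recovery <- function(cohort, seed, n_restarts) {
  k <- cohort$config$n_states
  eigs <- cohort_eigenvectors(cohort$subjects, tr = cohort$config$tr)
  pooled <- pool_eigenvectors(eigs)
  sol <- cluster_states(pooled, k = k, seed = seed, n_restarts = n_restarts)
  matching <- match_states(sol, cohort$states)
  to_state <- integer(k)
  to_state[matching$cluster] <- matching$state
  lab_tbl <- subject_labels(sol)
  lab_tbl <- lab_tbl[match(cohort$subjects$subject_id, lab_tbl$subject_id), ]
  labels_matched <- purrr::map(lab_tbl$labels, function(l) to_state[l])
  truth <- purrr::map2(cohort$subjects$truth_labels, eigs$eig,
                       function(tl, e) tl[e$kept])
  accuracy <- mean(unlist(labels_matched) == unlist(truth))
  occ <- t(vapply(labels_matched, occupancy, numeric(k), n_states = k))
  list(
    occupancy = occ,
    mean_occupancy = colMeans(occ),
    accuracy = accuracy,
    matching = matching,
    labels_matched = labels_matched,
    solution = sol
  )
}
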