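# Small fixtures built in code, shared across test files.

# A fast low-dimensional cohort for structural tests.
tiny_cohort <- function(n_per_group = 2, n_regions = 16, n_volumes = 60,
                        n_states = 3, seed = 42, ...) {
  pi1 <- rep(1 / n_states, n_states)
  cfg <- cohort_config(
    n_per_group = n_per_group,
    dynamics = list(
      patient = occupancy_dynamics(pi1, dwell = 4),
      control = occupancy_dynamics(pi1, dwell = 4)
    ),
    n_regions = n_regions, n_volumes = n_volumes,
    sex_p = 0.5, handedness_p = 0.6, seed = seed, ...
  )
  simulate_cohort(cfg)
}

# Subjects that each sit in a single planted state for the whole scan:
# pooled eigenvectors then form k well-separated clusters with no
# switch-boundary frames bridging them.
constant_state_subjects <- function(states, n_per_state = 2, n_volumes = 240,
                                    seed = 1, ...) {
  k <- nrow(states)
  n <- k * n_per_state
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n)),
    ts = lapply(seq_len(n), function(i) {
      synthesize_subject(rep((i - 1) %% k + 1, n_volumes), states,
                         seed = seed * 100 + i, ...)
    })
  )
}

# Per-subject metric + covariate table with a given group effect.
simulated_metric_tbl <- function(n_per_group = 20, mean1 = 0, mean2 = 0,
                                 sd1 = 1, sd2 = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = rep(c("a", "b"), each = n_per_group),
    age = rnorm(n, 40, 10),
    sex = rbinom(n, 1, 0.5),
    handedness = sample(c(0L, 1L, rbinom(n - 2, 1, 0.9))),
    education = rnorm(n, 18, 3),
    value = c(rnorm(n_per_group, mean1, sd1), rnorm(n_per_group, mean2, sd2))
  )
}

# Independent power-iteration oracle for the leading eigenvector: shifts
# the matrix to make all eigenvalues positive so magnitude dominance
# coincides with the algebraically largest eigenvalue.
power_iteration_eigenvector <- function(m, iters = 2000) {
  shift <- sum(abs(m))
  ms <- m + diag(shift, nrow(m))
  v <- rep(1, nrow(m)) + seq_len(nrow(m)) / nrow(m)
  for (i in seq_len(iters)) {
    v <- ms %*% v
    v <- v / sqrt(sum(v^2))
  }
  as.numeric(v)
}

# Brute-force Dunn index over all point pairs.
dunn_brute_force <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  same <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  max_within <- if (any(same & ut)) max(d[same & ut]) else 0
  min_between <- min(d[!same & ut])
  if (max_within == 0) Inf else min_between / max_within
}

abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Renormalized group-level occupancy and switch-conditional transition
# profiles, as printed for a two-group resting-state comparison.
reference_control_occupancy <- function() {
  p <- c(0.185, 0.175, 0.205, 0.228, 0.207)
  p / sum(p)
}

reference_patient_occupancy <- function() {
  p <- c(0.136, 0.157, 0.198, 0.233, 0.277)
  p / sum(p)
}

reference_patient_switch_matrix <- function() {
  q <- matrix(0, 5, 5)
  q[1, 2:5] <- c(0.193, 0.301, 0.268, 0.277)
  q[2, c(1, 3:5)] <- c(0.207, 0.253, 0.257, 0.355)
  q[3, c(1, 2, 4, 5)] <- c(0.205, 0.218, 0.235, 0.342)
  q[4, c(1:3, 5)] <- c(0.177, 0.225, 0.252, 0.356)
  q[5, 1:4] <- c(0.190, 0.248, 0.239, 0.345)
  q / rowSums(q)
}
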