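#' Construct planted two-community phase-locking patterns
#'
#' Each planted state is a signed membership vector over regions: regions in
#' community A (+1) oscillate in phase with each other and in anti-phase with
#' community B (-1). When a subject's signal follows such a pattern without
#' noise, the phase-locking matrix is exactly rank one and its leading
#' eigenvector is proportional to the pattern, which is what makes these
#' patterns recoverable ground truth for the whole pipeline.
#'
#' Community-A sizes are spread over 10--42% of the regions. Sizes are kept
#' strictly distinct so the states are mutually distinguishable, and are kept
#' below half of the regions so every pattern has a strictly negative mean
#' under the eigenvector sign convention -- patterns with a near-zero mean
#' flip sign unstably under noise and split into antipodal clouds.
#'
#' @param n_regions Number of regions N (at least `2 * n_states`).
#' @param n_states Number of planted states K (at least 2).
#' @param seed Integer seed; the construction is deterministic given it.
#' @return A K x N matrix with entries in `{-1, +1}`, one row per state.
#'   Row names are `state_1..state_K`, column names `roi_001...`.
#' @export
make_planted_states <- function(n_regions, n_states, seed = 1) {
  if (n_states < 2) invalid_config("need at least 2 planted states")
  if (n_regions < 2 * n_states) {
    invalid_config(sprintf(
      "cannot construct %d distinct patterns over %d regions (need n_regions >= 2 * n_states)",
      n_states, n_regions
    ))
  }
  sizes <- round(seq(0.10, 0.42, length.out = n_states) * n_regions)
  sizes <- pmin(pmax(sizes, 1L), n_regions - 1L)
  for (i in seq_along(sizes)[-1]) {
    sizes[i] <- max(sizes[i], sizes[i - 1] + 1L)
  }
  if (max(sizes) > n_regions - 1L) {
    invalid_config("too many states for the requested number of regions")
  }
  set.seed(seed)
  for (attempt in 1:100) {
    pat <- matrix(-1, n_states, n_regions)
    for (k in seq_len(n_states)) {
      pat[k, sample.int(n_regions, sizes[k])] <- 1
    }
    cs <- tcrossprod(pat) / n_regions
    if (max(abs(cs[upper.tri(cs)])) < 0.95) {
      dimnames(pat) <- list(
        paste0("state_", seq_len(n_states)),
        sprintf("roi_%03d", seq_len(n_regions))
      )
      return(pat)
    }
  }
  invalid_config("failed to construct mutually distinguishable patterns")
}

#' Dynamics specifications for the state-sequence generator
#'
#' `occupancy_dynamics()` describes fixed-dwell block dynamics: the sequence
#' is cut into blocks of exactly `dwell` volumes and each block's state is
#' drawn independently from the target occupancy vector `pi`, so the planted
#' occupancy is exactly the categorical probability. `markov_dynamics()`
#' describes switch-conditional dynamics: dwell is geometric with the given
#' `stay` probability (or fixed when `dwell` is supplied) and the next state
#' on a switch is drawn from the corresponding row of `Q`.
#'
#' @param pi Target occupancy vector (sums to 1).
#' @param dwell Dwell length in volumes (fixed-length blocks).
#' @param Q K x K switch-conditional transition matrix: zero diagonal, rows
#'   sum to 1.
#' @param stay Probability of remaining in the current state at each volume
#'   (geometric dwell with mean `1 / (1 - stay)` volumes).
#' @return A dynamics specification list, accepted by
#'   [sample_state_sequence()] and [cohort_config()].
#' @export
occupancy_dynamics <- function(pi, dwell = 4) {
  if (abs(sum(pi) - 1) > 1e-9) {
    invalid_config("occupancy vector pi must sum to 1")
  }
  if (any(pi < 0)) invalid_config("occupancy vector pi must be non-negative")
  if (dwell < 1) invalid_config("dwell must be at least 1 volume")
  structure(
    list(mode = "occupancy", pi = as.numeric(pi), dwell = as.integer(dwell)),
    class = "leida_dynamics"
  )
}

#' @rdname occupancy_dynamics
#' @export
markov_dynamics <- function(Q, stay = 0.75, dwell = NULL) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) invalid_config("Q must be square")
  if (any(abs(diag(Q)) > 1e-12)) {
    invalid_config("Q must have a zero diagonal (switch-conditional)")
  }
  if (any(abs(rowSums(Q) - 1) > 1e-9)) {
    invalid_config("every row of Q must sum to 1")
  }
  if (any(Q < 0)) invalid_config("Q entries must be non-negative")
  if (is.null(dwell) && (stay < 0 || stay >= 1)) {
    invalid_config("stay must lie in [0, 1)")
  }
  structure(
    list(
      mode = "markov", Q = unname(Q), stay = stay,
      dwell = if (is.null(dwell)) NULL else as.integer(dwell)
    ),
    class = "leida_dynamics"
  )
}

n_dynamics_states <- function(dynamics) {
  if (dynamics$mode == "occupancy") length(dynamics$pi) else nrow(dynamics$Q)
}

#' Sample a planted state-label sequence
#'
#' Generates the ground-truth sequence of state visits for one scan under a
#' dynamics specification (see [occupancy_dynamics()] and
#' [markov_dynamics()]). In Markov mode without an explicit `start`, the
#' initial state is drawn from the stationary distribution of the full
#' per-volume transition matrix `stay * I + (1 - stay) * Q`.
#'
#' @param dynamics A dynamics specification.
#' @param n_volumes Sequence length T (volumes).
#' @param seed Integer seed.
#' @param start Optional fixed initial state (Markov mode).
#' @return Integer vector of length `n_volumes` with values in `1..K`.
#' @export
sample_state_sequence <- function(dynamics, n_volumes, seed = 1, start = NULL) {
  if (!inherits(dynamics, "leida_dynamics")) {
    invalid_config("dynamics must be built with occupancy_dynamics() or markov_dynamics()")
  }
  if (n_volumes < 1) invalid_config("n_volumes must be positive")
  k <- n_dynamics_states(dynamics)
  set.seed(seed)
  if (dynamics$mode == "occupancy") {
    nb <- ceiling(n_volumes / dynamics$dwell)
    blocks <- sample.int(k, nb, replace = TRUE, prob = dynamics$pi)
    return(rep(blocks, each = dynamics$dwell)[seq_len(n_volumes)])
  }
  Q <- dynamics$Q
  if (!is.null(dynamics$dwell)) {
    # fixed-dwell semi-Markov: block transitions follow Q
    nb <- ceiling(n_volumes / dynamics$dwell)
    blocks <- integer(nb)
    blocks[1] <- start %||% sample.int(k, 1)
    for (b in seq_len(nb)[-1]) {
      blocks[b] <- sample.int(k, 1, prob = Q[blocks[b - 1], ])
    }
    return(rep(blocks, each = dynamics$dwell)[seq_len(n_volumes)])
  }
  stay <- dynamics$stay
  P <- stay * diag(k) + (1 - stay) * Q
  if (is.null(start)) {
    e <- eigen(t(P))
    i <- which.min(abs(e$values - 1))
    pi0 <- abs(Re(e$vectors[, i]))
    pi0 <- pi0 / sum(pi0)
    start <- sample.int(k, 1, prob = pi0)
  }
  labels <- integer(n_volumes)
  labels[1] <- start
  stays <- runif(n_volumes) < stay
  for (t in seq_len(n_volumes)[-1]) {
    labels[t] <- if (stays[t]) {
      labels[t - 1]
    } else {
      sample.int(k, 1, prob = Q[labels[t - 1], ])
    }
  }
  labels
}

#' Synthesize one subject's BOLD-like region time series
#'
#' Every region oscillates on a common carrier (default 0.05 Hz, inside the
#' 0.01--0.1 Hz analysis band). At volume t the region's phase offset is 0 if
#' the region belongs to community A of the active planted state and pi if it
#' belongs to community B, plus independent von Mises phase noise; Gaussian
#' amplitude noise is added to the cosine signal. In the noiseless limit the
#' per-timepoint phase-locking matrix is exactly the rank-1 outer product of
#' the planted pattern.
#'
#' @param labels Ground-truth state sequence (length T).
#' @param states Planted pattern matrix from [make_planted_states()].
#' @param tr Repetition time in seconds.
#' @param carrier_freq Carrier frequency in Hz.
#' @param phase_noise_kappa von Mises concentration of the phase noise;
#'   `Inf` disables it.
#' @param amplitude_noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed.
#' @return A T x N numeric matrix (timepoints x regions) with the repetition
#'   time attached as attribute `"tr"` and region names as column names.
#' @export
synthesize_subject <- function(labels, states, tr = 2, carrier_freq = 0.05,
                               phase_noise_kappa = 4, amplitude_noise_sd = 0.2,
                               seed = 1) {
  labels <- assert_labels(labels, nrow(states))
  n_volumes <- length(labels)
  n_regions <- ncol(states)
  set.seed(seed)
  carrier <- 2 * pi * carrier_freq * (seq_len(n_volumes) - 1) * tr
  offsets <- (states[labels, , drop = FALSE] < 0) * pi
  theta <- carrier + offsets
  if (is.finite(phase_noise_kappa)) {
    theta <- theta + matrix(
      rvonmises(n_volumes * n_regions, phase_noise_kappa),
      n_volumes, n_regions
    )
  }
  x <- cos(theta)
  if (amplitude_noise_sd > 0) {
    x <- x + matrix(rnorm(n_volumes * n_regions, 0, amplitude_noise_sd),
                    n_volumes, n_regions)
  }
  colnames(x) <- colnames(states)
  attr(x, "tr") <- tr
  x
}

#' Generate a synthetic 7-network atlas
#'
#' Partitions the regions into disjoint networks of near-equal size and
#' names them after the canonical Yeo networks (visual, somatomotor, dorsal
#' attention, ventral attention, limbic, frontoparietal, default mode). The
#' result is a stand-in for a real region-to-network lookup table and has
#' the same shape, so a real table can be dropped in unchanged.
#'
#' @param n_regions Number of regions (at least `n_networks`).
#' @param n_networks Number of networks (default 7).
#' @param seed Integer seed for the random assignment of regions.
#' @return A tibble with columns `region` and `network` (factor in the
#'   canonical network order).
#' @export
make_atlas <- function(n_regions, n_networks = 7, seed = 1) {
  if (n_regions < n_networks) {
    invalid_config("need at least one region per network")
  }
  nm <- yeo_network_names(n_networks)
  set.seed(seed)
  assign <- sample(rep(seq_len(n_networks), length.out = n_regions))
  tibble(
    region = sprintf("roi_%03d", seq_len(n_regions)),
    network = factor(nm[assign], levels = nm)
  )
}

yeo_network_names <- function(n_networks) {
  base <- c("Visual", "SMN", "DA", "VA", "Limbic", "FPN", "DMN")
  if (n_networks <= length(base)) {
    base[seq_len(n_networks)]
  } else {
    c(base, paste0("Network", seq(length(base) + 1, n_networks)))
  }
}

#' Configure a synthetic cohort
#'
#' Bundles the acquisition facts (regions, volumes, TR), the planted-state
#' model, per-group dynamics, noise levels, and covariate distributions into
#' a validated configuration. Defaults mirror a typical single-site
#' resting-state protocol: 105 regions, 240 volumes at TR = 2 s, carrier at
#' 0.05 Hz, von Mises phase noise kappa = 4, amplitude noise sd = 0.2.
#'
#' @param n_per_group Subjects per group.
#' @param dynamics Named list mapping group names to dynamics specifications
#'   (see [occupancy_dynamics()], [markov_dynamics()]); all groups must share
#'   the same number of states.
#' @param n_regions,n_volumes,tr Acquisition geometry.
#' @param carrier_freq,phase_noise_kappa,amplitude_noise_sd Signal model.
#' @param age_mean,age_sd,sex_p,handedness_p,education_mean,education_sd
#'   Covariate distributions: age and education Gaussian, sex and handedness
#'   Bernoulli indicator proportions. Covariates are independent of the
#'   dynamics, so covariate-adjusted tests are calibrated under the null.
#' @param seed Master seed; all randomness derives from it.
#' @return A `leida_cohort_config` list.
#' @export
cohort_config <- function(n_per_group, dynamics,
                          n_regions = 105, n_volumes = 240, tr = 2,
                          carrier_freq = 0.05, phase_noise_kappa = 4,
                          amplitude_noise_sd = 0.2,
                          age_mean = 40, age_sd = 10, sex_p = 0.5,
                          handedness_p = 0.9, education_mean = 18,
                          education_sd = 3, seed = 1) {
  if (n_per_group < 1) invalid_config("n_per_group must be positive")
  if (n_volumes < 10) invalid_config("need at least 10 volumes")
  if (tr <= 0) invalid_config("tr must be positive")
  if (!is.list(dynamics) || length(dynamics) < 1 || is.null(names(dynamics))) {
    invalid_config("dynamics must be a named list of dynamics specifications")
  }
  ks <- vapply(dynamics, function(d) {
    if (!inherits(d, "leida_dynamics")) {
      invalid_config("each dynamics entry must be a leida_dynamics specification")
    }
    n_dynamics_states(d)
  }, integer(1))
  if (length(unique(ks)) != 1) {
    invalid_config("all groups must share the same number of states")
  }
  n_states <- ks[[1]]
  if (n_states < 2) invalid_config("need at least 2 states")
  if (n_regions < n_states) invalid_config("need n_regions >= n_states")
  structure(
    list(
      n_per_group = as.integer(n_per_group), dynamics = dynamics,
      n_regions = as.integer(n_regions), n_volumes = as.integer(n_volumes),
      tr = tr, n_states = n_states, carrier_freq = carrier_freq,
      phase_noise_kappa = phase_noise_kappa,
      amplitude_noise_sd = amplitude_noise_sd,
      age_mean = age_mean, age_sd = age_sd, sex_p = sex_p,
      handedness_p = handedness_p, education_mean = education_mean,
      education_sd = education_sd, seed = as.integer(seed)
    ),
    class = "leida_cohort_config"
  )
}

#' Simulate a cohort with planted states, dynamics, and covariates
#'
#' Draws planted patterns and a synthetic atlas, then per subject a
#' ground-truth state sequence under the subject's group dynamics, the
#' corresponding noisy signal matrix, and covariates. The same configuration
#' and seed always reproduce the identical cohort.
#'
#' @param config A configuration from [cohort_config()].
#' @return A `leida_cohort` list: `subjects` (tibble with one row per
#'   subject: ids, group, covariates, a `ts` list-column of timepoints x
#'   regions matrices, and a `truth_labels` list-column), `states` (planted
#'   pattern matrix), `atlas` (tibble), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "leida_cohort_config"))
  states <- make_planted_states(config$n_regions, config$n_states,
                                seed = config$seed)
  atlas <- make_atlas(config$n_regions, seed = config$seed)
  groups <- names(config$dynamics)
  n_total <- config$n_per_group * length(groups)
  set.seed(config$seed)
  covars <- tibble(
    subject_id = sprintf("sub-%03d", seq_len(n_total)),
    group = rep(groups, each = config$n_per_group),
    age = round(rnorm(n_total, config$age_mean, config$age_sd), 1),
    sex = rbinom(n_total, 1, config$sex_p),
    handedness = rbinom(n_total, 1, config$handedness_p),
    education = round(rnorm(n_total, config$education_mean, config$education_sd), 1)
  )
  subjects <- covars |>
    mutate(
      truth_labels = purrr::imap(.data$group, function(g, i) {
        sample_state_sequence(config$dynamics[[g]], config$n_volumes,
                              seed = derive_seed(config$seed, i))
      }),
      ts = purrr::imap(.data$truth_labels, function(lab, i) {
        synthesize_subject(
          lab, states,
          tr = config$tr, carrier_freq = config$carrier_freq,
          phase_noise_kappa = config$phase_noise_kappa,
          amplitude_noise_sd = config$amplitude_noise_sd,
          seed = derive_seed(config$seed, i) + 500000L
        )
      })
    )
  structure(
    list(subjects = subjects, states = states, atlas = atlas, config = config),
    class = "leida_cohort"
  )
}

#' @export
print.leida_cohort <- function(x, ...) {
  cat(sprintf(
    "<leida_cohort> %d subjects (%s), %d regions x %d volumes, TR = %gs, %d planted states\n",
    nrow(x$subjects),
    paste(sprintf("%d %s", table(x$subjects$group), names(table(x$subjects$group))),
          collapse = ", "),
    x$config$n_regions, x$config$n_volumes, x$config$tr, x$config$n_states
  ))
  invisible(x)
}
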