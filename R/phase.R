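#' Zero-phase band-pass filter for region time series
#'
#' Removes each column's mean and applies a 2nd-order Butterworth filter
#' forward and backward (`signal::filtfilt`), so the filter contributes no
#' phase shift -- a prerequisite for meaningful instantaneous-phase
#' estimates downstream. With `low_hz = 0` the filter reduces to a low-pass.
#'
#' @param x Timepoints x regions matrix (attribute `"tr"` used when `tr` is
#'   missing).
#' @param tr Repetition time in seconds.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 <= low_hz < high_hz < 1 / (2 * tr)`.
#' @return Filtered matrix of the same shape, `"tr"` attribute preserved.
#' @export
bandpass <- function(x, tr = attr(x, "tr"), low_hz = 0.01, high_hz = 0.1) {
  if (is.null(tr) || tr <= 0) invalid_config("tr must be a positive number")
  nyquist <- 1 / (2 * tr)
  if (low_hz < 0 || low_hz >= high_hz || high_hz >= nyquist) {
    abort(
      sprintf("band [%g, %g] Hz must satisfy 0 <= low < high < Nyquist (%g Hz)",
              low_hz, high_hz, nyquist),
      class = "leidar_invalid_band"
    )
  }
  flt <- if (low_hz == 0) {
    signal::butter(2, high_hz / nyquist, type = "low")
  } else {
    signal::butter(2, c(low_hz, high_hz) / nyquist, type = "pass")
  }
  out <- apply(x, 2, function(col) signal::filtfilt(flt, col - mean(col)))
  dimnames(out) <- dimnames(x)
  attr(out, "tr") <- tr
  out
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the analytic signal of each (demeaned) column in the frequency
#' domain and returns its argument: `theta[t, n]` is the instantaneous phase
#' of region n at volume t, in `(-pi, pi]`. Input should be band-limited for
#' the phase to be interpretable (not enforced).
#'
#' @param x Timepoints x regions matrix.
#' @return Matrix of phases with the same shape and dimnames.
#' @export
instantaneous_phase <- function(x) {
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    abort(
      sprintf("zero-variance signal in region(s): %s",
              paste(bad, collapse = ", ")),
      class = "leidar_degenerate_signal"
    )
  }
  n <- nrow(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  theta <- apply(x, 2, function(col) {
    col <- col - mean(col)
    Arg(fft(fft(col) * h, inverse = TRUE) / n)
  })
  dimnames(theta) <- dimnames(x)
  theta
}

#' Phase-locking matrix at one timepoint
#'
#' `dPL[n, p] = cos(theta_n - theta_p)`: +1 for perfectly in-phase region
#' pairs, -1 for anti-phase. The matrix is symmetric with a unit diagonal
#' and, being `cos(a - b) = cos(a)cos(b) + sin(a)sin(b)`, has rank at most 2.
#'
#' @param theta Phase vector of length N (radians).
#' @return Symmetric N x N matrix with entries in `[-1, 1]`.
#' @export
phase_locking_matrix <- function(theta) {
  if (anyNA(theta) || any(!is.finite(theta))) {
    invalid_config("phases must be finite")
  }
  c1 <- cos(theta)
  s1 <- sin(theta)
  m <- tcrossprod(c1) + tcrossprod(s1)
  if (!is.null(names(theta))) dimnames(m) <- list(names(theta), names(theta))
  m
}

#' Leading eigenvector of a symmetric matrix
#'
#' Returns the unit-norm eigenvector of the algebraically largest
#' eigenvalue, sign-normalized so that its mean is non-positive (and, when
#' the mean is exactly zero, its first nonzero entry negative). The sign
#' convention is essential: eigenvectors are defined up to sign, and
#' clustering without a fixed convention produces duplicate antipodal
#' states.
#'
#' @param m Symmetric matrix.
#' @return Unit-norm numeric vector.
#' @export
leading_eigenvector <- function(m) {
  v <- eigen(m, symmetric = TRUE)$vectors[, 1]
  out <- fix_sign(unit_norm(v))
  names(out) <- rownames(m)
  out
}

# Leading eigenvectors of all per-timepoint phase-locking matrices at once,
# using the exact rank-2 factorization dPL(t) = c c' + s s' with
# c = cos(theta_t), s = sin(theta_t): the nonzero eigenpairs of dPL(t) are
# those of the 2x2 Gram matrix of [c s], so no N x N eigendecomposition is
# needed. Returns a T x N matrix of sign-normalized unit eigenvectors.
leading_eigenvectors_rank2 <- function(theta) {
  C <- cos(theta)
  S <- sin(theta)
  t(vapply(seq_len(nrow(theta)), function(t) {
    ct <- C[t, ]; st <- S[t, ]
    g11 <- sum(ct * ct); g12 <- sum(ct * st); g22 <- sum(st * st)
    # top eigenvector of [[g11, g12], [g12, g22]]
    tr2 <- (g11 + g22) / 2
    disc <- sqrt(max(((g11 - g22) / 2)^2 + g12^2, 0))
    lam <- tr2 + disc
    y <- if (abs(g12) > 1e-300) c(lam - g22, g12) else if (g11 >= g22) c(1, 0) else c(0, 1)
    fix_sign(unit_norm(ct * y[1] + st * y[2]))
  }, numeric(ncol(theta))))
}

#' Per-timepoint leading eigenvectors of the phase-locking dynamics
#'
#' Composes the per-subject pipeline: band-pass filter, Hilbert phase,
#' per-timepoint phase-locking matrix, leading eigenvector. The first and
#' last `trim_edges` volumes are dropped because the Hilbert transform is
#' unreliable at the series boundaries.
#'
#' @param x Timepoints x regions signal matrix (attribute `"tr"` used when
#'   `tr` is missing).
#' @param tr Repetition time in seconds.
#' @param low_hz,high_hz Band edges passed to [bandpass()]; set
#'   `filter = FALSE` to skip filtering for signals already band-limited.
#' @param trim_edges Volumes to drop at each end (default 1).
#' @param filter Apply the band-pass filter first (default `TRUE`).
#' @return A `leida_eigenseries` list: `v1` (T_eff x N matrix of unit-norm
#'   sign-normalized eigenvectors), `kept` (indices of retained volumes in
#'   the original series), and `tr`.
#' @export
eigenvector_series <- function(x, tr = attr(x, "tr"), low_hz = 0.01,
                               high_hz = 0.1, trim_edges = 1, filter = TRUE) {
  n_volumes <- nrow(x)
  if (n_volumes - 2 * trim_edges < 2) {
    invalid_config("too few volumes left after edge trimming")
  }
  if (filter) x <- bandpass(x, tr = tr, low_hz = low_hz, high_hz = high_hz)
  theta <- instantaneous_phase(x)
  kept <- seq.int(1 + trim_edges, n_volumes - trim_edges)
  v1 <- leading_eigenvectors_rank2(theta[kept, , drop = FALSE])
  colnames(v1) <- colnames(x)
  structure(
    list(v1 = v1, kept = kept, tr = tr),
    class = "leida_eigenseries"
  )
}

#' Eigenvector series for every subject of a cohort
#'
#' @param cohort A `leida_cohort` from [simulate_cohort()], or a tibble with
#'   columns `subject_id` and a `ts` list-column of timepoints x regions
#'   matrices.
#' @param ... Passed to [eigenvector_series()].
#' @return The subjects tibble with an added `eig` list-column of
#'   `leida_eigenseries` objects.
#' @export
cohort_eigenvectors <- function(cohort, ...) {
  subjects <- if (inherits(cohort, "leida_cohort")) cohort$subjects else cohort
  stopifnot(is.data.frame(subjects), "ts" %in% names(subjects))
  subjects |>
    mutate(eig = purrr::map(.data$ts, eigenvector_series, ...))
}
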