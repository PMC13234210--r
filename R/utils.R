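# Internal helpers shared across the pipeline.

# Draw n angles from a von Mises distribution centred at 0 with
# concentration kappa, by the Best & Fisher (1979) wrapped-Cauchy
# rejection sampler. kappa = 0 falls back to uniform on (-pi, pi].
rvonmises <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- max(2L * (n - filled), 32L)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    acc <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    take <- min(length(acc), n - filled)
    if (take > 0) {
      out[(filled + 1L):(filled + take)] <- acc[seq_len(take)]
      filled <- filled + take
    }
  }
  out
}

# Sign convention for eigenvectors and centroids: mean(v) <= 0; when the
# mean is exactly zero the first nonzero entry must be negative. Without a
# fixed convention, k-means sees +v and -v as two different patterns.
fix_sign <- function(v) {
  m <- mean(v)
  if (m > 0) return(-v)
  if (m == 0) {
    nz <- which(v != 0)
    if (length(nz) > 0 && v[nz[1]] > 0) return(-v)
  }
  v
}

unit_norm <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(v)
  v / nv
}

# Deterministic per-subject seed derived from a master seed; kept well
# below .Machine$integer.max.
derive_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + 7L * as.integer(i) %% 1000003L
}

assert_labels <- function(labels, n_states) {
  if (length(labels) == 0) {
    abort("empty state sequence", class = "leidar_empty_input")
  }
  if (anyNA(labels) || any(labels < 1L) || any(labels > n_states)) {
    abort(
      sprintf("state labels must lie in 1..%d", n_states),
      class = "leidar_invalid_config"
    )
  }
  invisible(as.integer(labels))
}

invalid_config <- function(msg) abort(msg, class = "leidar_invalid_config")

`%||%` <- rlang::`%||%`
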