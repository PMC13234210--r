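make_eig_tbl <- function(mats, kept = NULL) {
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_along(mats)),
    eig = lapply(mats, function(m) {
      structure(list(v1 = m, kept = kept %||% seq_len(nrow(m)) + 1, tr = 2),
                class = "leida_eigenseries")
    })
  )
}

unit_rows <- function(m) m / sqrt(rowSums(m^2))

test_that("pooling stacks eigenvectors with full provenance", {
  set.seed(1)
  mats <- replicate(3, unit_rows(matrix(rnorm(40), 10, 4)), simplify = FALSE)
  pooled <- pool_eigenvectors(make_eig_tbl(mats))
  expect_equal(nrow(pooled$v), 30)
  expect_equal(nrow(pooled$index), 30)
  expect_equal(pooled$index$row, 1:30)
  expect_identical(pooled$v[11:20, ], mats[[2]])

  single <- pool_eigenvectors(make_eig_tbl(mats[1]))
  expect_identical(single$v, mats[[1]])

  bad <- make_eig_tbl(list(mats[[1]], unit_rows(matrix(rnorm(30), 10, 3))))
  expect_error(pool_eigenvectors(bad), class = "leidar_shape_mismatch")
})

test_that("k-means separates repeated orthogonal patterns exactly", {
  p1 <- c(1, 0, 0, 0)
  p2 <- c(0, 1, 0, 0)
  x <- rbind(matrix(p1, 30, 4, byrow = TRUE), matrix(p2, 30, 4, byrow = TRUE))
  sol <- suppressWarnings(cluster_states(x, k = 2, seed = 1, n_restarts = 5))
  expect_s3_class(sol, "leida_states")
  sims <- abs(sol$centroids %*% cbind(p1, p2))
  expect_true(all(apply(sims, 2, max) >= 0.999))
  expect_equal(sol$inertia, 0, tolerance = 1e-9)

  # stability: different seeds give the same partition up to renumbering
  sol2 <- suppressWarnings(cluster_states(x, k = 2, seed = 2, n_restarts = 5))
  expect_equal(length(unique(paste(sol$labels, sol2$labels))), 2)

  expect_error(cluster_states(x[1:3, ], k = 5), class = "leidar_invalid_k")
})

test_that("noiseless planted cohort is recovered one-to-one at k = K", {
  states <- make_planted_states(30, 5, seed = 2)
  subs <- constant_state_subjects(states, n_per_state = 1, n_volumes = 60,
                                  phase_noise_kappa = Inf,
                                  amplitude_noise_sd = 0)
  pooled <- pool_eigenvectors(cohort_eigenvectors(subs, tr = 2))
  sol <- cluster_states(pooled, k = 5, seed = 1, n_restarts = 10)
  m <- match_states(sol, states)
  expect_equal(sort(m$state), 1:5)          # one-to-one
  expect_true(all(m$similarity >= 0.99))
})

test_that("dunn index matches hand and brute-force computation", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  expect_equal(dunn_index(x, c(1, 1, 2, 2)), 10)

  # coincident clusters: zero separation
  x2 <- rbind(c(0, 0), c(0, 1), c(0, 0), c(0, 1))
  expect_equal(dunn_index(x2, c(1, 1, 2, 2)), 0)

  # all-singleton clusters: infinite sentinel with a warning
  x3 <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_warning(d <- dunn_index(x3, c(1, 2, 3)), "infinite")
  expect_identical(d, Inf)

  set.seed(3)
  for (rep in 1:5) {
    xr <- matrix(rnorm(200 * 3), 200, 3)
    lr <- sample(1:4, 200, replace = TRUE)
    expect_equal(dunn_index(xr, lr), dunn_brute_force(xr, lr),
                 tolerance = 1e-12)
  }
  # blockwise accumulation is independent of block size
  expect_equal(dunn_index(xr, lr, block_size = 7), dunn_brute_force(xr, lr),
               tolerance = 1e-12)
})

test_that("select_k sweeps the range and honours the tie-break", {
  set.seed(4)
  x <- rbind(matrix(rnorm(60, 0, 0.05), 20, 3),
             matrix(rnorm(60, 5, 0.05), 20, 3))
  x <- unit_rows(x)
  pooled <- structure(
    list(v = x, index = tibble::tibble(subject_id = "s", volume = 1:40,
                                       row = 1:40)),
    class = "leida_pooled"
  )
  only5 <- select_k(pooled, k_min = 5, k_max = 5, seed = 1, n_restarts = 3)
  expect_equal(only5$k, 5L)
  expect_equal(nrow(only5$sweep), 1)

  sw <- select_k(pooled, k_min = 2, k_max = 4, seed = 1, n_restarts = 5)
  expect_equal(nrow(sw$sweep), 3)
  expect_equal(sw$k, sw$sweep$k[which.max(sw$sweep$dunn)])
  # which.max takes the first maximum, i.e. the smaller k on ties
  expect_equal(which.max(c(1, 2, 2)), 2L)
})

test_that("order_states renumbers by descending occupancy, stably", {
  sol <- structure(
    list(
      k = 3L,
      centroids = diag(3) * -1,
      labels = c(rep(1L, 1), rep(2L, 6), rep(3L, 3)),
      inertia = 0, dunn = 1,
      index = tibble::tibble(subject_id = "s", volume = 1:10, row = 1:10),
      seed = 1L, metric = "cosine"
    ),
    class = "leida_states"
  )
  ordered <- order_states(sol)
  # occupancies (0.1, 0.6, 0.3) -> old states (2, 3, 1) become (1, 2, 3)
  expect_equal(tabulate(ordered$labels, 3), c(6, 3, 1))
  expect_equal(ordered$centroids[1, ], sol$centroids[2, ],
               ignore_attr = TRUE)

  already <- sol
  already$labels <- c(rep(1L, 6), rep(2L, 3), rep(3L, 1))
  expect_equal(order_states(already)$labels, already$labels)

  # equal occupancies (states 1 and 2) keep original relative order
  tied <- sol
  tied$labels <- c(rep(1L, 3), rep(2L, 3), rep(3L, 4))
  expect_equal(order_states(tied)$centroids[2, ], tied$centroids[1, ],
               ignore_attr = TRUE)
})

test_that("metrics are invariant under consistent state renumbering", {
  coh <- tiny_cohort(seed = 12)
  pooled <- pool_eigenvectors(cohort_eigenvectors(coh$subjects, tr = 2))
  sol <- cluster_states(pooled, k = 3, seed = 1, n_restarts = 5)
  ordered <- order_states(sol)
  perm <- vapply(seq_len(sol$k), function(s) {
    unique(ordered$labels[sol$labels == s])
  }, integer(1))

  m_raw <- cohort_metrics(subject_labels(sol), 3, tr = 2)
  m_ord <- cohort_metrics(subject_labels(ordered), 3, tr = 2)
  for (s in 1:3) {
    expect_equal(
      m_raw$value[m_raw$metric == "occupancy" & m_raw$state == s],
      m_ord$value[m_ord$metric == "occupancy" & m_ord$state == perm[s]]
    )
  }
})

test_that("tidiers expose centroids and model summary", {
  x <- unit_rows(matrix(rnorm(80), 20, 4))
  sol <- cluster_states(x, k = 2, seed = 1, n_restarts = 3)
  td <- tidy(sol)
  expect_equal(nrow(td), 8)
  expect_named(td, c("state", "region", "loading"))
  gl <- glance(sol)
  expect_equal(gl$k, 2L)
  expect_equal(gl$n_pooled, 20L)
})
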