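#' Pool leading eigenvectors across subjects
#'
#' Stacks every subject's eigenvector series into one matrix for clustering
#' and keeps a provenance index mapping each pooled row back to its subject
#' and volume.
#'
#' @param eig_tbl Tibble with columns `subject_id` and `eig` (list-column of
#'   `leida_eigenseries`), as returned by [cohort_eigenvectors()].
#' @return A `leida_pooled` list: `v` (M x N matrix of unit-norm rows) and
#'   `index` (tibble: `subject_id`, `volume`, `row`).
#' @export
pool_eigenvectors <- function(eig_tbl) {
  stopifnot(is.data.frame(eig_tbl), all(c("subject_id", "eig") %in% names(eig_tbl)))
  if (nrow(eig_tbl) == 0) invalid_config("need at least one subject")
  ns <- vapply(eig_tbl$eig, function(e) ncol(e$v1), integer(1))
  if (length(unique(ns)) != 1) {
    abort(
      sprintf("subjects have inconsistent region counts: %s",
              paste(unique(ns), collapse = ", ")),
      class = "leidar_shape_mismatch"
    )
  }
  v <- do.call(rbind, lapply(eig_tbl$eig, function(e) e$v1))
  index <- purrr::map2(eig_tbl$subject_id, eig_tbl$eig, function(id, e) {
    tibble(subject_id = id, volume = e$kept)
  }) |>
    bind_rows() |>
    mutate(row = row_number())
  structure(list(v = v, index = index), class = "leida_pooled")
}

# k-means++ seeding under cosine distance on unit-norm rows.
init_kmeanspp <- function(x, k) {
  m <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(m, 1)
  d2 <- pmax(1 - x %*% x[centers[1], ], 0)
  for (j in seq_len(k)[-1]) {
    probs <- as.numeric(d2)
    if (sum(probs) <= 0) probs <- rep(1, m)
    centers[j] <- sample.int(m, 1, prob = probs)
    d2 <- pmin(d2, pmax(1 - x %*% x[centers[j], ], 0))
  }
  x[centers, , drop = FALSE]
}

# One spherical k-means run: assign by maximal dot product (= minimal
# cosine distance on unit vectors), update centroids as renormalized means.
# Empty clusters are reseeded at the point farthest from its centroid.
skmeans_once <- function(x, k, max_iter, tol) {
  cen <- init_kmeanspp(x, k)
  obj_prev <- Inf
  labels <- rep(1L, nrow(x))
  for (it in seq_len(max_iter)) {
    sims <- x %*% t(cen)
    labels <- max.col(sims, ties.method = "first")
    for (j in which(tabulate(labels, k) == 0L)) {
      far <- which.min(sims[cbind(seq_len(nrow(x)), labels)])
      labels[far] <- j
      sims[far, ] <- -Inf
    }
    obj <- sum(1 - sims[cbind(seq_len(nrow(x)), labels)])
    cen_new <- rowsum(x, labels)
    cen_new <- cen_new / sqrt(rowSums(cen_new^2))
    if (obj > obj_prev + 1e-8) {
      warn("k-means objective increased; numerical degeneracy in this restart")
    }
    converged <- is.finite(obj_prev) &&
      (obj_prev - obj) <= tol * max(obj_prev, .Machine$double.eps)
    cen <- cen_new
    obj_prev <- obj
    if (converged) break
  }
  sims <- x %*% t(cen)
  labels <- max.col(sims, ties.method = "first")
  obj <- sum(1 - sims[cbind(seq_len(nrow(x)), labels)])
  list(labels = labels, centroids = cen, objective = obj, iterations = it)
}

#' Cluster pooled eigenvectors into k recurrent states
#'
#' Best-of-restarts k-means. The default metric is cosine distance
#' (spherical k-means with k-means++ seeding): leading eigenvectors are
#' directions, and the convention in the phase-locking state literature is
#' to cluster them on the unit sphere. `metric = "euclidean"` delegates to
#' [stats::kmeans()] instead. Returned centroids are unit-norm and
#' sign-normalized.
#'
#' @param pooled A `leida_pooled` object (or plain matrix of unit-norm rows).
#' @param k Number of clusters (2 <= k <= number of rows).
#' @param seed Integer seed controlling all restarts.
#' @param n_restarts Independent restarts; the lowest-inertia run wins.
#' @param max_iter,tol Iteration cap and relative convergence tolerance.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return A `leida_states` object: `k`, `centroids` (k x N), `labels`
#'   (length M), `inertia`, `dunn` (filled by [select_k()] /
#'   [dunn_index()]), `index` provenance tibble, `seed`, `metric`.
#' @export
cluster_states <- function(pooled, k, seed = 1, n_restarts = 20,
                           max_iter = 500, tol = 1e-6,
                           metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  x <- if (inherits(pooled, "leida_pooled")) pooled$v else as.matrix(pooled)
  index <- if (inherits(pooled, "leida_pooled")) pooled$index else NULL
  m <- nrow(x)
  if (k < 2 || k > m) {
    abort(sprintf("k = %d must lie in 2..%d", k, m), class = "leidar_invalid_k")
  }
  set.seed(seed)
  if (metric == "euclidean") {
    km <- stats::kmeans(x, centers = k, nstart = n_restarts,
                        iter.max = max_iter)
    centroids <- km$centers
    labels <- km$cluster
    inertia <- km$tot.withinss
  } else {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      run <- skmeans_once(x, k, max_iter, tol)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
    centroids <- best$centroids
    labels <- best$labels
    inertia <- best$objective
  }
  centroids <- t(apply(centroids, 1, function(v) fix_sign(unit_norm(v))))
  colnames(centroids) <- colnames(x)
  structure(
    list(
      k = as.integer(k), centroids = centroids, labels = as.integer(labels),
      inertia = inertia, dunn = dunn_index(x, labels), index = index,
      seed = as.integer(seed), metric = metric
    ),
    class = "leida_states"
  )
}

#' Dunn cluster-validity index
#'
#' Ratio of the minimum between-cluster distance (single linkage) to the
#' maximum within-cluster diameter, on Euclidean distances. Larger is
#' better. Distances are accumulated blockwise so the full M x M distance
#' matrix is never materialized.
#'
#' @param x Data matrix (rows are observations).
#' @param labels Integer cluster assignment.
#' @param block_size Rows per block in the pairwise-distance sweep.
#' @return Scalar Dunn index; `Inf` (with a warning) when every
#'   within-cluster diameter is zero.
#' @export
dunn_index <- function(x, labels, block_size = 1024) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  counts <- tabulate(labels)
  if (sum(counts > 0) < 2) invalid_config("need at least 2 non-empty clusters")
  m <- nrow(x)
  sq <- rowSums(x^2)
  min_between <- Inf
  max_within <- 0
  starts <- seq(1, m, by = block_size)
  for (bi in starts) {
    ri <- bi:min(bi + block_size - 1, m)
    for (bj in starts[starts >= bi]) {
      rj <- bj:min(bj + block_size - 1, m)
      d2 <- pmax(outer(sq[ri], sq[rj], "+") - 2 * tcrossprod(x[ri, , drop = FALSE],
                                                             x[rj, , drop = FALSE]), 0)
      same <- outer(labels[ri], labels[rj], "==")
      if (bi == bj) {
        keep <- upper.tri(d2)
        within <- d2[same & keep]
        between <- d2[!same & keep]
      } else {
        within <- d2[same]
        between <- d2[!same]
      }
      if (length(within)) max_within <- max(max_within, max(within))
      if (length(between)) min_between <- min(min_between, min(between))
    }
  }
  if (max_within == 0) {
    warn("all within-cluster diameters are zero; Dunn index is infinite")
    return(Inf)
  }
  sqrt(min_between) / sqrt(max_within)
}

#' Select the number of states by the Dunn index
#'
#' Runs [cluster_states()] for each k in `k_min..k_max` and returns the
#' solution with the largest Dunn index (ties broken toward smaller k). The
#' full sweep is attached as a tibble so the model-selection curve can be
#' inspected.
#'
#' @param pooled A `leida_pooled` object.
#' @param k_min,k_max Sweep range (defaults 5 and 10).
#' @param ... Passed to [cluster_states()] (seed, restarts, metric, ...).
#' @return The winning `leida_states`, with a `sweep` tibble
#'   (`k`, `dunn`, `inertia`) attached as element `$sweep`.
#' @export
select_k <- function(pooled, k_min = 5, k_max = 10, ...) {
  if (k_min < 2 || k_max < k_min) invalid_config("need 2 <= k_min <= k_max")
  sols <- lapply(seq(k_min, k_max), function(k) cluster_states(pooled, k, ...))
  sweep <- tibble(
    k = vapply(sols, `[[`, integer(1), "k"),
    dunn = vapply(sols, `[[`, numeric(1), "dunn"),
    inertia = vapply(sols, `[[`, numeric(1), "inertia")
  )
  best <- sols[[which.max(sweep$dunn)]]
  best$sweep <- sweep
  best
}

#' Renumber states by descending pooled occupancy
#'
#' States are conventionally numbered so that state 1 is the most frequent
#' across the pooled cohort. Labels and centroids are permuted consistently;
#' ties keep their original relative order (stable sort).
#'
#' @param solution A `leida_states` object.
#' @return The same object with states renumbered.
#' @export
order_states <- function(solution) {
  stopifnot(inherits(solution, "leida_states"))
  occ <- tabulate(solution$labels, solution$k)
  perm <- order(-occ)              # perm[new] = old, stable for ties
  inv <- integer(solution$k)
  inv[perm] <- seq_len(solution$k) # inv[old] = new
  solution$labels <- inv[solution$labels]
  solution$centroids <- solution$centroids[perm, , drop = FALSE]
  rownames(solution$centroids) <- paste0("state_", seq_len(solution$k))
  solution
}

#' Match recovered states to planted patterns
#'
#' Finds the one-to-one assignment between cluster centroids and planted
#' patterns that maximizes total absolute cosine similarity (exhaustive over
#' permutations for k <= 8, greedy beyond). Used by recovery experiments to
#' compare pipeline output against ground truth.
#'
#' @param solution A `leida_states` object.
#' @param patterns Planted pattern matrix from [make_planted_states()]
#'   (rows are states).
#' @return Tibble with one row per cluster: `cluster`, `state` (matched
#'   planted state), `similarity` (absolute cosine).
#' @export
match_states <- function(solution, patterns) {
  cen <- solution$centroids
  pat <- t(apply(patterns, 1, function(p) fix_sign(unit_norm(p))))
  if (ncol(cen) != ncol(pat)) {
    abort("centroids and patterns have different region counts",
          class = "leidar_shape_mismatch")
  }
  sim <- abs(tcrossprod(cen, pat)) # k x K
  k <- nrow(sim)
  if (k <= 8 && ncol(sim) == k) {
    perms <- all_permutations(k)
    tot <- vapply(perms, function(p) sum(sim[cbind(seq_len(k), p)]), numeric(1))
    best <- perms[[which.max(tot)]]
  } else {
    best <- integer(k)
    taken <- rep(FALSE, ncol(sim))
    for (i in order(-apply(sim, 1, max))) {
      j <- order(-sim[i, ])
      j <- j[!taken[j]][1]
      best[i] <- j
      taken[j] <- TRUE
    }
  }
  tibble(
    cluster = seq_len(k),
    state = best,
    similarity = sim[cbind(seq_len(k), best)]
  )
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

#' Per-subject state-label streams from a clustering solution
#'
#' @param solution A `leida_states` with provenance index.
#' @return Tibble with `subject_id` and a `labels` list-column of integer
#'   state sequences (in volume order).
#' @export
subject_labels <- function(solution) {
  stopifnot(inherits(solution, "leida_states"))
  if (is.null(solution$index)) {
    abort("solution has no provenance index; cluster a leida_pooled object",
          class = "leidar_invalid_config")
  }
  solution$index |>
    mutate(state = solution$labels[.data$row]) |>
    arrange(.data$subject_id, .data$volume) |>
    group_by(.data$subject_id) |>
    summarise(labels = list(.data$state), .groups = "drop")
}

#' @export
print.leida_states <- function(x, ...) {
  cat(sprintf(
    "<leida_states> k = %d (%s distance), %d pooled eigenvectors, Dunn = %.4g, inertia = %.4g\n",
    x$k, x$metric, length(x$labels), x$dunn, x$inertia
  ))
  invisible(x)
}

#' Tidy centroid table for a clustering solution
#'
#' One row per state x region with the centroid loading.
#'
#' @param x A `leida_states` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.leida_states <- function(x, ...) {
  cen <- x$centroids
  tibble(
    state = rep(seq_len(nrow(cen)), each = ncol(cen)),
    region = rep(colnames(cen) %||% sprintf("roi_%03d", seq_len(ncol(cen))),
                 nrow(cen)),
    loading = as.numeric(t(cen))
  )
}

#' One-row model summary for a clustering solution
#'
#' @param x A `leida_states` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.leida_states <- function(x, ...) {
  tibble(
    k = x$k, dunn = x$dunn, inertia = x$inertia,
    n_pooled = length(x$labels), metric = x$metric, seed = x$seed
  )
}
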