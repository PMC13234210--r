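#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error level.
#' @param m Number of comparisons (at least 1).
#' @return `alpha / m`. Display rounding (3 decimals) is left to callers.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 7) {
  if (m < 1) invalid_config("number of comparisons must be at least 1")
  if (alpha <= 0 || alpha > 1) invalid_config("alpha must lie in (0, 1]")
  alpha / m
}

# Spearman rho with tie-corrected ranks and a two-sided p-value from the
# t-approximation; exact p by complete permutation enumeration for n <= 7.
spearman_test <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (method == "permutation" && n <= 7) {
    perms <- all_permutations(n)
    rhos <- vapply(perms, function(p) cor(rx, ry[p]), numeric(1))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

#' Network profile of one state centroid
#'
#' Spearman-correlates a state centroid's spatial topography with each
#' binary network membership vector of the atlas, over regions. Networks
#' with `p` below the Bonferroni threshold `alpha / n_networks` are flagged
#' significant.
#'
#' @param centroid Numeric vector over regions (a row of
#'   `leida_states$centroids`).
#' @param atlas Atlas tibble (`region`, `network`), e.g. from
#'   [make_atlas()] or [read_atlas()].
#' @param alpha Family-wise error level before Bonferroni division.
#' @param method P-value method: `"t"` approximation (default) or
#'   `"permutation"` (exact enumeration, only for 7 or fewer regions).
#' @return Tibble: `network`, `rho`, `p`, `significant`.
#' @export
state_network_profile <- function(centroid, atlas, alpha = 0.05,
                                  method = c("t", "permutation")) {
  networks <- levels(factor(atlas$network))
  if (length(centroid) != nrow(atlas)) {
    abort("centroid length does not match the atlas region count",
          class = "leidar_shape_mismatch")
  }
  thr <- bonferroni_threshold(alpha, length(networks))
  rows <- purrr::map(networks, function(nw) {
    member <- as.numeric(atlas$network == nw)
    st <- spearman_test(centroid, member, method = method)
    tibble(network = nw, rho = st$rho, p = st$p, significant = st$p < thr)
  })
  bind_rows(rows) |>
    mutate(network = factor(.data$network, levels = networks))
}

#' Label a state from its network profile
#'
#' Concatenates the names of networks with a significant positive
#' correlation, ordered by descending rho and joined with "/"
#' (e.g. `"Visual/DA"`); `"Unclassified"` when no network qualifies.
#'
#' @param profile Tibble from [state_network_profile()].
#' @return Character label.
#' @export
label_state <- function(profile) {
  hits <- profile |>
    filter(.data$significant, .data$rho > 0) |>
    arrange(dplyr::desc(.data$rho))
  if (nrow(hits) == 0) return("Unclassified")
  paste(as.character(hits$network), collapse = "/")
}

#' Network profiles and labels for every state of a solution
#'
#' @param solution A `leida_states` object.
#' @param atlas Atlas tibble (`region`, `network`).
#' @param ... Passed to [state_network_profile()].
#' @return Tibble with one row per state x network (`state`, `label`,
#'   `network`, `rho`, `p`, `significant`).
#' @export
map_states <- function(solution, atlas, ...) {
  stopifnot(inherits(solution, "leida_states"))
  purrr::map(seq_len(solution$k), function(s) {
    prof <- state_network_profile(solution$centroids[s, ], atlas, ...)
    mutate(prof, state = s, label = label_state(prof), .before = 1)
  }) |>
    bind_rows()
}
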