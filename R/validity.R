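#' Cluster validity indices for a fuzzy partition
#'
#' Five indices covering compactness, separation and fuzziness of a fuzzy
#' c-means solution:
#' \describe{
#'   \item{partition_coefficient}{`mean(U^2)` summed over clusters; higher is
#'     better (crisper partition).}
#'   \item{partition_entropy}{`-mean(U log U)` summed over clusters; lower is
#'     better.}
#'   \item{xie_beni}{fuzzy objective divided by `n` times the smallest
#'     squared centroid separation; lower is better.}
#'   \item{fukuyama_sugeno}{fuzzy within-cluster scatter minus the weighted
#'     centroid spread around the grand mean; lower is better.}
#'   \item{fuzzy_silhouette}{crisp silhouette widths weighted by the margin
#'     between the two largest memberships; higher is better.}
#' }
#'
#' @param clustering A `fuzzy_clustering`.
#' @param X The data matrix the fit was computed on.
#' @param dist2 Optional pre-computed matrix of squared pairwise distances
#'   between rows of `X` (reused across candidate `c` by [validity_vote()]).
#' @return Named numeric vector of the five index values.
#' @export
validity_indices <- function(clustering, X, dist2 = NULL) {
  U <- clustering$membership
  V <- clustering$centroids
  X <- unclass(X); attr(X, "row_info") <- NULL
  n <- nrow(U); cc <- ncol(U)
  m <- clustering$m

  pc <- sum(U^2) / n
  pe <- -sum(ifelse(U > 0, U * log(U), 0)) / n

  d2 <- pairwise_sq_dist(X, V)
  J <- sum(U^m * d2)
  if (cc > 1) {
    vsep <- pairwise_sq_dist(V, V)
    diag(vsep) <- Inf
    xb <- J / (n * min(vsep))
  } else xb <- Inf
  xbar <- colMeans(X)
  fs <- J - sum(U^m * matrix(rep(rowSums(sweep(V, 2, xbar)^2), each = n), n, cc))

  sil <- fuzzy_silhouette(U, X, dist2)
  c(partition_coefficient = pc, partition_entropy = pe, xie_beni = xb,
    fukuyama_sugeno = fs, fuzzy_silhouette = sil)
}

pairwise_sq_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  pmax(d2, 0)
}

fuzzy_silhouette <- function(U, X, dist2 = NULL, alpha = 1) {
  n <- nrow(U); cc <- ncol(U)
  if (cc < 2) return(NA_real_)
  hard <- max.col(U, ties.method = "first")
  if (length(unique(hard)) < 2) return(-1)
  if (is.null(dist2)) dist2 <- pairwise_sq_dist(X, X)
  d <- sqrt(dist2)
  s <- numeric(n)
  mean_to <- matrix(0, n, cc)
  for (k in seq_len(cc)) {
    idx <- hard == k
    if (!any(idx)) { mean_to[, k] <- Inf; next }
    mean_to[, k] <- rowSums(d[, idx, drop = FALSE]) / sum(idx)
  }
  for (i in seq_len(n)) {
    k <- hard[i]
    nk <- sum(hard == k)
    a <- if (nk > 1) mean_to[i, k] * nk / (nk - 1) else 0
    b <- min(mean_to[i, -k])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  srt <- t(apply(U, 1, sort, decreasing = TRUE))
  w <- (srt[, 1] - srt[, 2])^alpha
  if (sum(w) == 0) mean(s) else sum(w * s) / sum(w)
}

#' Choose the number of clusters by a validity-index vote
#'
#' For each candidate `c` the best of `n_restarts` fuzzy c-means fits (by
#' final objective) is scored with the five [validity_indices()]; each index
#' votes for the `c` at which it is optimal, and the winner is the modal
#' vote, ties broken toward the smaller `c`.
#'
#' @param X Data matrix or `profile_matrix`.
#' @param c_range Candidate numbers of clusters, all within
#'   `[2, nrow(X) - 1]`.
#' @param m Fuzziness exponent. Default 2.
#' @param n_restarts Restarts per candidate `c`. Default 10.
#' @param seed Integer seed controlling all restarts.
#' @return A list of class `validity_vote`: `c_star` (chosen cluster
#'   number), `votes` (tibble index -> voted c), `index_table` (tibble of all
#'   index values per c) and `fits` (best `fuzzy_clustering` per c, named by
#'   c).
#' @export
validity_vote <- function(X, c_range = 2:12, m = 2, n_restarts = 10,
                          seed = 1L) {
  n <- nrow(X)
  c_range <- sort(unique(as.integer(c_range)))
  if (length(c_range) == 0 || min(c_range) < 2 || max(c_range) > n - 1)
    abort("`c_range` must lie within [2, nrow(X) - 1].")
  Xm <- unclass(X); attr(Xm, "row_info") <- NULL
  dist2 <- if (n <= 4000) pairwise_sq_dist(Xm, Xm) else NULL

  fits <- list(); index_rows <- list()
  for (cc in c_range) {
    best <- fuzzy_cmeans(X, cc, m = m, seed = seed + 1000L * cc,
                         n_restarts = n_restarts)
    fits[[as.character(cc)]] <- best
    idx <- validity_indices(best, Xm, dist2)
    index_rows[[as.character(cc)]] <- tibble(c = cc, index = names(idx),
                                             value = unname(idx))
  }
  index_table <- bind_rows(index_rows)

  direction <- c(partition_coefficient = "max", partition_entropy = "min",
                 xie_beni = "min", fukuyama_sugeno = "min",
                 fuzzy_silhouette = "max")
  votes <- index_table |>
    group_by(.data$index) |>
    summarise(voted_c = {
      v <- .data$value
      cs <- .data$c
      ok <- is.finite(v)
      v <- v[ok]; cs <- cs[ok]
      if (direction[[unique(.data$index)]] == "max") cs[which.max(v)]
      else cs[which.min(v)]
    }, .groups = "drop")
  tallied <- sort(table(votes$voted_c), decreasing = TRUE)
  top <- as.integer(names(tallied)[tallied == max(tallied)])
  c_star <- min(top)

  structure(list(c_star = c_star, votes = votes, index_table = index_table,
                 fits = fits),
            class = "validity_vote")
}

#' @export
print.validity_vote <- function(x, ...) {
  cat(sprintf("validity_vote: c* = %d\n", x$c_star))
  print(x$votes)
  invisible(x)
}
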