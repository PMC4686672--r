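#' Rescale chronological ages to a common unit interval
#'
#' Species differ in lifespan, so chronological ages are mapped linearly to
#' `[0, 1]` per species: `t' = (age - min) / (max - min)`.
#'
#' @param ages Either a numeric vector of ages (one species) or a data frame
#'   with columns `species`, `age_group`, `age`.
#' @return For a vector, a numeric vector of rescaled times; for a data
#'   frame, the input tibble with an added `t` column.
#' @export
#' @examples
#' rescale_timepoints(c(1, 10, 20))
rescale_timepoints <- function(ages) {
  if (is.data.frame(ages)) {
    ages |>
      as_tibble() |>
      group_by(.data$species) |>
      mutate(t = rescale_timepoints(.data$age)) |>
      ungroup()
  } else {
    rng <- range(ages)
    if (diff(rng) <= 0) abort("Need at least two distinct ages per species.")
    (ages - rng[1]) / diff(rng)
  }
}

#' Build the combined cross-species profile matrix
#'
#' Restricts each species' differentially expressed genes to ortholog groups
#' represented in every species, summarizes expression per age group as the
#' mean of `log(normalized count + 1)`, z-scores each row, and stacks all
#' species on the common rank-aligned time grid. Constant rows cannot be
#' standardized and are dropped (count reported).
#'
#' Expression is depth-normalized by median-of-ratios size factors rather
#' than by total mapped reads: under per-row standardization the gene length
#' cancels, so RPKM and normalized counts yield identical profiles up to the
#' depth estimator, and the median-of-ratios depth is robust to the
#' compositional shifts that age-regulated genes induce in total counts.
#'
#' @param datasets Named list of [count_dataset()] objects, one per species.
#' @param deg_calls Named list (same names) of [call_degs()] tibbles.
#' @param orthology An [orthology_map()].
#' @return A `profile_matrix`: numeric matrix (rows = species/gene pairs,
#'   columns = rescaled time grid) with attribute `row_info`, a tibble of
#'   `species` and `gene` per row.
#' @export
build_profiles <- function(datasets, deg_calls, orthology) {
  species <- names(datasets)
  if (is.null(species) || !identical(sort(species), sort(names(deg_calls))))
    abort("`datasets` and `deg_calls` must be named lists over the same species.")
  spanning <- orthology |>
    group_by(.data$group) |>
    summarise(n_sp = dplyr::n_distinct(.data$species), .groups = "drop") |>
    filter(.data$n_sp == length(species)) |>
    pull(.data$group)
  eligible <- filter(orthology, .data$group %in% spanning)

  blocks <- list(); infos <- list(); dropped <- 0L
  for (sp in species) {
    cd <- datasets[[sp]]
    degs <- deg_calls[[sp]] |> filter(.data$is_deg) |> pull(.data$gene)
    keep <- intersect(degs, eligible$gene[eligible$species == sp])
    keep <- intersect(keep, rownames(cd$counts))
    if (!length(keep)) next
    expr <- sweep(cd$counts, 2, compute_size_factors(cd$counts), "/")
    lexpr <- log(expr[keep, , drop = FALSE] + 1)
    groups <- factor(cd$design$age_group, levels = unique(cd$design$age_group))
    prof <- vapply(levels(groups),
                   function(g) rowMeans(lexpr[, groups == g, drop = FALSE]),
                   numeric(length(keep)))
    if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1,
                                           dimnames = list(keep, levels(groups)))
    sds <- apply(prof, 1, sd)
    const <- sds == 0 | !is.finite(sds)
    dropped <- dropped + sum(const)
    prof <- prof[!const, , drop = FALSE]
    if (!nrow(prof)) next
    prof <- t(scale(t(prof)))
    colnames(prof) <- format(seq(0, 1, length.out = ncol(prof)), digits = 3)
    blocks[[sp]] <- prof
    infos[[sp]] <- tibble(species = sp, gene = rownames(prof))
  }
  if (!length(blocks)) abort("No qualifying DEG rows across species.")
  if (dropped > 0) inform(sprintf("Dropped %d constant profile rows.", dropped))
  X <- do.call(rbind, blocks)
  row_info <- bind_rows(infos)
  rownames(X) <- paste(row_info$species, row_info$gene, sep = ":")
  structure(X, row_info = row_info, class = c("profile_matrix", "matrix", "array"))
}

#' Fuzzy c-means clustering
#'
#' Soft clustering by alternating optimization of the fuzzy objective
#' `J = sum_ij u_ij^m d(x_i, v_j)^2` with Euclidean distance: memberships
#' `u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))`, centroids as the
#' membership-weighted means. A point coincident with one or more centroids
#' receives membership 1 split equally across the coincident centroids.
#' Iteration stops when the largest centroid coordinate shift falls below
#' `tol` or after `max_iter` sweeps.
#'
#' @param X Numeric matrix (rows = items) or `profile_matrix`.
#' @param c Number of clusters (`1 <= c <= nrow(X)`).
#' @param m Fuzziness exponent, `> 1`. Default 2.
#' @param tol Convergence threshold on centroid movement. Default 1e-6.
#' @param max_iter Iteration cap. Default 300.
#' @param seed Optional integer seed for the centroid initialization
#'   (sampling `c` distinct rows).
#' @param n_restarts Number of random initializations; the fit with the
#'   lowest final objective is returned. Default 1.
#' @return An object of class `fuzzy_clustering`: list with `c`, `m`,
#'   `membership` (rows sum to 1), `centroids`, `objective_trace`,
#'   `course_label` per cluster (via [classify_course()]) and `row_info`
#'   when clustering a `profile_matrix`.
#' @export
fuzzy_cmeans <- function(X, c, m = 2, tol = 1e-6, max_iter = 300, seed = NULL,
                         n_restarts = 1) {
  if (n_restarts > 1) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- fuzzy_cmeans(X, c, m = m, tol = tol, max_iter = max_iter,
                          seed = if (is.null(seed)) NULL else seed + 1009L * (r - 1L))
      if (is.null(best) ||
          tail(fit$objective_trace, 1) < tail(best$objective_trace, 1))
        best <- fit
    }
    return(best)
  }
  row_info <- attr(X, "row_info")
  X <- unclass(X); attr(X, "row_info") <- NULL
  n <- nrow(X)
  if (c < 1 || c > n) abort("`c` must lie between 1 and the number of rows.")
  if (m <= 1) abort("`m` must exceed 1.")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  # initialize from c distinct data rows so coincident duplicates cannot
  # seed identical centroids
  uniq <- unique(X)
  if (nrow(uniq) < c)
    abort("`c` exceeds the number of distinct rows.")
  V <- uniq[sample.int(nrow(uniq), c), , drop = FALSE]

  sq_dist <- function(X, V) {
    # n x c matrix of squared Euclidean distances
    outer(rowSums(X^2), rep(1, nrow(V))) +
      outer(rep(1, nrow(X)), rowSums(V^2)) - 2 * X %*% t(V)
  }
  memberships <- function(d2) {
    d2 <- pmax(d2, 0)
    U <- matrix(0, nrow(d2), ncol(d2))
    zero <- d2 < 1e-300
    hit <- rowSums(zero) > 0
    if (any(hit)) U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    if (any(!hit)) {
      # stabilized in log space: at small m the exponent 1/(m-1) underflows
      # d2^(-1/(m-1)) for all clusters at once
      ld <- log(d2[!hit, , drop = FALSE]) / (m - 1)
      w <- exp(-(ld - apply(ld, 1, min)))
      U[!hit, ] <- w / rowSums(w)
    }
    U
  }

  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist(X, V)
    U <- memberships(d2)
    trace <- c(trace, sum(U^m * pmax(d2, 0)))
    Um <- U^m
    V_new <- (t(Um) %*% X) / colSums(Um)
    shift <- max(abs(V_new - V))
    V <- V_new
    if (shift < tol) break
  }
  d2 <- sq_dist(X, V)
  U <- memberships(d2)
  trace <- c(trace, sum(U^m * pmax(d2, 0)))
  rownames(V) <- paste0("cluster_", seq_len(c))
  colnames(V) <- colnames(X)
  dimnames(U) <- list(rownames(X), rownames(V))
  structure(list(c = c, m = m, membership = U, centroids = V,
                 objective_trace = trace,
                 course_label = apply(V, 1, classify_course),
                 row_info = row_info),
            class = "fuzzy_clustering")
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf("fuzzy_clustering: %d rows, c = %d, m = %g, J = %.4g (%d sweeps)\n",
              nrow(x$membership), x$c, x$m, tail(x$objective_trace, 1),
              length(x$objective_trace)))
  cat("  course labels:", paste(x$course_label, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a centroid time course
#'
#' `"up"` if strictly increasing over all consecutive rescaled time points,
#' `"down"` if strictly decreasing, `"other"` otherwise.
#'
#' @param centroid Numeric vector of at least two time points.
#' @return One of `"up"`, `"down"`, `"other"`.
#' @export
#' @examples
#' classify_course(c(-1, 0, 1))
classify_course <- function(centroid) {
  d <- diff(centroid)
  if (all(d > 0)) "up" else if (all(d < 0)) "down" else "other"
}

#' Hard cluster assignment by maximum membership
#'
#' @param clustering A `fuzzy_clustering`.
#' @return Tibble of `row`, `cluster`, `max_membership`, `course` plus the
#'   `species`/`gene` columns when the fit carries row information. Ties on
#'   the maximum go to the lowest cluster index (reported).
#' @export
hard_assignment <- function(clustering) {
  U <- clustering$membership
  idx <- max.col(U, ties.method = "first")
  n_tied <- sum(vapply(seq_len(nrow(U)),
                       function(i) sum(U[i, ] == max(U[i, ])) > 1, logical(1)))
  if (n_tied > 0)
    inform(sprintf("%d membership ties assigned to the lowest cluster index.",
                   n_tied))
  out <- tibble(row = rownames(U) %||% as.character(seq_len(nrow(U))),
                cluster = idx,
                max_membership = U[cbind(seq_len(nrow(U)), idx)],
                course = unname(clustering$course_label[idx]))
  if (!is.null(clustering$row_info))
    out <- dplyr::bind_cols(clustering$row_info, select(out, -"row"))
  out
}

#' Intersect cluster-based direction calls across species
#'
#' Rows are hard-assigned to their maximum-membership cluster; a species'
#' up (down) set contains the genes sitting in clusters whose centroid course
#' is `"up"` (`"down"`). An ortholog group is conserved-up when at least one
#' member gene of every species lies in that species' up set; conserved-down
#' analogously. Groups qualifying in both directions are flagged conflicting
#' and excluded from both sets.
#'
#' @param clustering A `fuzzy_clustering` fitted on a `profile_matrix`.
#' @param orthology An [orthology_map()].
#' @param row_info Optional tibble of `species`, `gene` per row; defaults to
#'   the fit's own row information.
#' @return A list of class `venn_result`: `per_species` (tibble of species,
#'   gene, direction), `conserved_up`, `conserved_down`, `conflicting`
#'   (character vectors of ortholog groups) and `pairwise_counts` (tibble of
#'   species pairs with shared-group counts per direction).
#' @export
conserved_sets <- function(clustering, orthology, row_info = NULL) {
  row_info <- row_info %||% clustering$row_info
  if (is.null(row_info)) abort("Row species/gene information is required.")
  assign_tab <- hard_assignment(clustering)
  per_species <- dplyr::bind_cols(row_info["species"], row_info["gene"],
                                  direction = assign_tab$course) |>
    filter(.data$direction %in% c("up", "down"))

  species <- unique(row_info$species)
  evidence <- per_species |>
    inner_join(orthology, by = c("species", "gene")) |>
    distinct(.data$group, .data$species, .data$direction)
  conserved_in <- function(dir) {
    evidence |>
      filter(.data$direction == dir) |>
      group_by(.data$group) |>
      summarise(n_sp = dplyr::n_distinct(.data$species), .groups = "drop") |>
      filter(.data$n_sp == length(species)) |>
      pull(.data$group)
  }
  up <- conserved_in("up")
  down <- conserved_in("down")
  conflicting <- intersect(up, down)
  if (length(conflicting))
    inform(sprintf("%d ortholog groups conserved in both directions excluded.",
                   length(conflicting)))

  pairs <- utils::combn(sort(species), 2, simplify = FALSE)
  pairwise_counts <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(c("up", "down"), function(dir) {
      shared <- evidence |>
        filter(.data$direction == dir, .data$species %in% pr) |>
        count(.data$group) |>
        filter(.data$n == 2)
      tibble(species_a = pr[1], species_b = pr[2], direction = dir,
             n_shared_groups = nrow(shared))
    })
  })

  structure(list(per_species = per_species,
                 conserved_up = setdiff(up, conflicting),
                 conserved_down = setdiff(down, conflicting),
                 conflicting = conflicting,
                 pairwise_counts = pairwise_counts),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("venn_result: %d conserved-up, %d conserved-down, %d conflicting groups\n",
              length(x$conserved_up), length(x$conserved_down),
              length(x$conflicting)))
  invisible(x)
}
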