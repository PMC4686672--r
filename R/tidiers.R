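#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fuzzy clustering fit
#'
#' @param x A `fuzzy_clustering`.
#' @param ... Unused.
#' @return One row per item: hard assignment, maximum membership and the
#'   assigned cluster's course label (plus species/gene when available).
#' @export
#' @exportS3Method generics::tidy
tidy.fuzzy_clustering <- function(x, ...) {
  hard_assignment(x)
}

#' @rdname tidy.fuzzy_clustering
#' @return For `glance`, a one-row tibble with `c`, `m`, `n`, `objective`,
#'   `n_iter`, `n_up`, `n_down`, `n_other`.
#' @export
#' @exportS3Method generics::glance
glance.fuzzy_clustering <- function(x, ...) {
  tibble(c = x$c, m = x$m, n = nrow(x$membership),
         objective = tail(x$objective_trace, 1),
         n_iter = length(x$objective_trace),
         n_up = sum(x$course_label == "up"),
         n_down = sum(x$course_label == "down"),
         n_other = sum(x$course_label == "other"))
}

#' Tidy a Monte Carlo overlap test
#'
#' @param x An `overlap_test`.
#' @param ... Unused.
#' @return One-row tibble of the test's summary fields.
#' @export
#' @exportS3Method generics::tidy
tidy.overlap_test <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null_draws),
         q_threshold = x$q_threshold, significant = x$significant,
         p_emp = x$p_emp, n_a = x$n_a, n_b = x$n_b, n_universe = x$n_universe)
}

#' Tidy a conserved-sets Venn result
#'
#' @param x A `venn_result`.
#' @param ... Unused.
#' @return Tibble with one row per conserved ortholog group and its
#'   direction.
#' @export
#' @exportS3Method generics::tidy
tidy.venn_result <- function(x, ...) {
  bind_rows(tibble(group = x$conserved_up, direction = "up"),
            tibble(group = x$conserved_down, direction = "down"))
}

#' Plot cluster centroid courses
#'
#' @param object A `fuzzy_clustering`.
#' @param ... Unused.
#' @return A ggplot of centroid trajectories over rescaled time, faceted by
#'   course label.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fuzzy_clustering <- function(object, ...) {
  V <- object$centroids
  df <- as_tibble(V, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "time", values_to = "value") |>
    mutate(time = suppressWarnings(as.numeric(gsub("[^0-9.]", "", .data$time))),
           course = object$course_label[.data$cluster])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   group = .data$cluster,
                                   colour = .data$course)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rescaled age", y = "standardized expression",
                  colour = "course") +
    ggplot2::theme_minimal()
}

#' Plot the Monte Carlo null distribution of an overlap test
#'
#' @param object An `overlap_test`.
#' @param ... Unused.
#' @return A ggplot histogram of null intersection sizes with the observed
#'   value and quantile threshold marked.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.overlap_test <- function(object, ...) {
  df <- tibble(draw = object$null_draws)
  ggplot2::ggplot(df, ggplot2::aes(.data$draw)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$q_threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "null intersection size", y = "iterations") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves for one or more groups
#'
#' @param records Survival record tibble; a `group` column, when present,
#'   yields one curve per group.
#' @return A ggplot of step survival curves.
#' @export
plot_survival <- function(records) {
  groups <- if ("group" %in% names(records)) unique(records$group) else "all"
  df <- purrr::map_dfr(groups, function(g) {
    rec <- if ("group" %in% names(records))
      filter(records, .data$group == g) else records
    km <- kaplan_meier(rec)
    bind_rows(tibble(time = 0, survival = 1),
              select(km, "time", "survival")) |>
      mutate(group = g)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "day", y = "S(t)") +
    ggplot2::theme_minimal()
}
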