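#' Read a lifespan-assay table
#'
#' @param path CSV with columns `individual`, `group`, `day`, `status`
#'   (`"death"` or `"censored"`) and optionally `replicate`.
#' @return Tibble of per-individual records.
#' @export
read_survival_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_survival_records(tab)
  tab
}

validate_survival_records <- function(records) {
  if (!all(c("day", "status") %in% names(records)))
    abort("Survival records need columns `day` and `status`.")
  if (any(records$day <= 0)) abort("Lifespan days must be positive.")
  if (!all(records$status %in% c("death", "censored")))
    abort("`status` must be 'death' or 'censored'.")
  invisible(records)
}

as_surv <- function(records) {
  survival::Surv(records$day, records$status == "death")
}

#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimate of the survival function; censored individuals
#' leave the risk set at their censoring day.
#'
#' @param records Tibble with columns `day`, `status`.
#' @return Tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
#' @examples
#' rec <- tibble::tibble(day = c(2, 3, 4, 5),
#'                       status = c("death", "censored", "death", "death"))
#' kaplan_meier(rec)
kaplan_meier <- function(records) {
  validate_survival_records(records)
  if (!any(records$status == "death"))
    warn("No death events; survival curve is identically 1.")
  fit <- survival::survfit(as_surv(records) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, survival = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic over the pooled event times, referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param records_a,records_b Survival record tibbles for the two groups.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(records_a, records_b) {
  validate_survival_records(records_a)
  validate_survival_records(records_b)
  if (!any(records_a$status == "death") || !any(records_b$status == "death"))
    warn("A group has no death events; log-rank statistic may be degenerate.")
  pooled <- bind_rows(mutate(records_a, .grp = "a"),
                      mutate(records_b, .grp = "b"))
  sd <- tryCatch(
    survival::survdiff(as_surv(pooled) ~ .grp, data = pooled),
    error = function(e) NULL
  )
  if (is.null(sd)) return(tibble(statistic = 0, df = 1L, p_value = 1))
  tibble(statistic = unname(sd$chisq), df = 1L,
         p_value = pchisq(unname(sd$chisq), 1, lower.tail = FALSE))
}

#' Lifespan summary statistics
#'
#' Mean lifespan is the restricted mean from the Kaplan-Meier curve (area
#' under the survival function up to the last observed time; equal to the
#' arithmetic mean of death days when nothing is censored). Median is the
#' first time at which survival drops to 0.5 or below. Maximum lifespan is
#' the mean lifespan of the longest-lived fraction (default decile) of
#' deaths.
#'
#' @param records Survival record tibble.
#' @param max_fraction Fraction of longest-lived deaths defining "maximum
#'   lifespan". Default 0.1.
#' @return Tibble with `mean`, `median`, `maximum`, `n`, `n_deaths`,
#'   `n_censored`.
#' @export
lifespan_summary <- function(records, max_fraction = 0.1) {
  km <- kaplan_meier(records)
  times <- c(0, km$time)
  surv <- c(1, km$survival)
  rmean <- sum(diff(times) * head(surv, -1))
  med_idx <- which(km$survival <= 0.5)
  med <- if (length(med_idx)) km$time[min(med_idx)] else NA_real_
  deaths <- sort(records$day[records$status == "death"], decreasing = TRUE)
  k <- max(1L, ceiling(max_fraction * length(deaths)))
  tibble(mean = rmean, median = med, maximum = mean(deaths[seq_len(k)]),
         n = nrow(records), n_deaths = length(deaths),
         n_censored = sum(records$status == "censored"))
}

#' Categorize a lifespan effect
#'
#' Applies the screen's effect scheme: `Unchanged` when the log-rank test is
#' not significant at `alpha`; otherwise `Shortened` when the mean-lifespan
#' change is negative, `Extended>=5%` when it is at least +5%, and
#' `Extended<5%` in between.
#'
#' @param control,treated Survival record tibbles.
#' @param alpha Log-rank significance level. Default 0.05.
#' @param label Treatment label carried into the result.
#' @return One-row tibble: `treatment`, `mean_control`, `mean_treated`,
#'   `pct_change_mean`, `pct_change_max`, `logrank_p`, `category`.
#' @export
categorize_effect <- function(control, treated, alpha = 0.05,
                              label = "treatment") {
  sc <- lifespan_summary(control)
  st <- lifespan_summary(treated)
  lr <- logrank_test(control, treated)
  pct_mean <- 100 * (st$mean - sc$mean) / sc$mean
  pct_max <- 100 * (st$maximum - sc$maximum) / sc$maximum
  category <- if (lr$p_value >= alpha) "Unchanged"
  else if (pct_mean < 0) "Shortened"
  else if (pct_mean >= 5) "Extended>=5%"
  else "Extended<5%"
  tibble(treatment = label, mean_control = sc$mean, mean_treated = st$mean,
         pct_change_mean = pct_mean, pct_change_max = pct_max,
         logrank_p = lr$p_value, category = category)
}

#' Screen summary cross-tabulation
#'
#' Tabulates genes by lifespan-effect category and ageing-regulation
#' direction, in the shape of the published screen table.
#'
#' @param effects Tibble with columns `gene`, `regulation`
#'   (`"upregulated"`/`"downregulated"`) and `category` (one of
#'   `"Shortened"`, `"Unchanged"`, `"Extended<5%"`, `"Extended>=5%"`); e.g.
#'   [load_screen_table()] output or categorized assay results.
#' @return A list of class `screen_summary`: `table` (tibble of category x
#'   regulation with `n` and comma-joined `genes`), `category_counts`,
#'   `n_genes`, `n_with_effect` (genes outside `Unchanged`),
#'   `n_upregulated`, `n_downregulated`.
#' @export
#' @examples
#' screen_summary(load_screen_table())
screen_summary <- function(effects) {
  if (nrow(effects) == 0) {
    return(structure(list(table = tibble(category = character(),
                                         regulation = character(),
                                         n = integer(), genes = character()),
                          category_counts = setNames(integer(4), .screen_categories),
                          n_genes = 0L, n_with_effect = 0L,
                          n_upregulated = 0L, n_downregulated = 0L),
                     class = "screen_summary"))
  }
  stopifnot(all(effects$category %in% .screen_categories))
  tab <- effects |>
    mutate(category = factor(.data$category, levels = .screen_categories)) |>
    group_by(.data$category, .data$regulation) |>
    summarise(n = n(), genes = paste(sort(.data$gene), collapse = ", "),
              .groups = "drop") |>
    tidyr::complete(category = factor(.screen_categories, .screen_categories),
                    regulation = unique(effects$regulation),
                    fill = list(n = 0L, genes = "")) |>
    arrange(.data$category, dplyr::desc(.data$regulation))
  cat_counts <- vapply(.screen_categories,
                       function(k) sum(effects$category == k), integer(1))
  structure(list(table = tab,
                 category_counts = cat_counts,
                 n_genes = nrow(effects),
                 n_with_effect = sum(effects$category != "Unchanged"),
                 n_upregulated = sum(effects$regulation == "upregulated"),
                 n_downregulated = sum(effects$regulation == "downregulated")),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("screen_summary: %d genes, %d with a lifespan effect\n",
              x$n_genes, x$n_with_effect))
  print(select(x$table, "category", "regulation", "n"))
  invisible(x)
}
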