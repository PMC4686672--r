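#' Monte Carlo test of gene-set overlap
#'
#' Draws, in each iteration, two uniform random subsets of the universe with
#' the same sizes as the observed sets and records their intersection size.
#' The observed intersection is called significant when it exceeds the
#' `mc_quantile` nearest-rank quantile of the null draws (strict inequality).
#' The empirical p-value uses the plus-one convention
#' `(1 + #draws >= observed) / (iterations + 1)`, so it is never zero.
#'
#' @param set_a,set_b Character vectors of genes, subsets of `universe`.
#' @param universe Character vector of all genes measured in both datasets.
#' @param mc_iterations Number of Monte Carlo iterations. Default 1000.
#' @param mc_quantile Significance quantile. Default 0.95.
#' @param seed Optional integer seed.
#' @return A list of class `overlap_test`: `observed`, `null_draws`,
#'   `q_threshold`, `significant`, `p_emp`, `n_a`, `n_b`, `n_universe`.
#' @export
#' @examples
#' u <- paste0("g", 1:100)
#' montecarlo_intersection(u[1:30], u[21:50], u, mc_iterations = 200, seed = 1)
montecarlo_intersection <- function(set_a, set_b, universe,
                                    mc_iterations = 1000, mc_quantile = 0.95,
                                    seed = NULL) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    abort("Both sets must be subsets of the universe.")
  nu <- length(universe); na <- length(set_a); nb <- length(set_b)
  if (na > nu || nb > nu) abort("Set larger than universe.")
  if (!is.null(seed)) set.seed(seed)

  observed <- length(intersect(set_a, set_b))
  null_draws <- integer(mc_iterations)
  member <- logical(nu)
  for (i in seq_len(mc_iterations)) {
    a <- sample.int(nu, na)
    b <- sample.int(nu, nb)
    member[a] <- TRUE
    null_draws[i] <- sum(member[b])
    member[a] <- FALSE
  }
  q_threshold <- sort(null_draws)[max(1L, ceiling(mc_quantile * mc_iterations))]
  structure(list(observed = observed, null_draws = null_draws,
                 q_threshold = q_threshold,
                 significant = observed > q_threshold,
                 p_emp = (1 + sum(null_draws >= observed)) / (mc_iterations + 1),
                 n_a = na, n_b = nb, n_universe = nu),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(paste0("overlap_test: observed %d (|A|=%d, |B|=%d, universe %d)\n",
                     "  null quantile threshold %d; %ssignificant; empirical p = %.4g\n"),
              x$observed, x$n_a, x$n_b, x$n_universe, x$q_threshold,
              if (x$significant) "" else "not ", x$p_emp))
  invisible(x)
}

#' Directional concordance between two differential-expression call sets
#'
#' Cross-tabulates regulation directions over the genes called in both
#' analyses and reports, for each call set, the fraction of its genes that
#' are also called in the other.
#'
#' @param calls_a,calls_b Tibbles with columns `gene` and `direction`
#'   (values `"up"`/`"down"`; other directions are ignored).
#' @return A list of class `concordance`: `table` (tibble with
#'   `direction_a`, `direction_b`, `n`), `n_same`, `n_opposing`,
#'   `overlap_fraction_a`, `overlap_fraction_b`.
#' @export
concordance_table <- function(calls_a, calls_b) {
  a <- calls_a |> filter(.data$direction %in% c("up", "down")) |>
    distinct(.data$gene, .data$direction)
  b <- calls_b |> filter(.data$direction %in% c("up", "down")) |>
    distinct(.data$gene, .data$direction)
  both <- inner_join(a, b, by = "gene", suffix = c("_a", "_b"))
  grid <- tidyr::expand_grid(direction_a = c("up", "down"),
                             direction_b = c("up", "down"))
  tab <- both |>
    count(.data$direction_a, .data$direction_b) |>
    dplyr::right_join(grid, by = c("direction_a", "direction_b")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    arrange(.data$direction_a, .data$direction_b)
  structure(list(
    table = tab,
    n_same = sum(tab$n[tab$direction_a == tab$direction_b]),
    n_opposing = sum(tab$n[tab$direction_a != tab$direction_b]),
    overlap_fraction_a = if (nrow(a)) nrow(both) / nrow(a) else NA_real_,
    overlap_fraction_b = if (nrow(b)) nrow(both) / nrow(b) else NA_real_
  ), class = "deg_concordance")
}

#' @export
print.deg_concordance <- function(x, ...) {
  cat(sprintf("concordance: %d same-direction, %d opposing genes\n",
              x$n_same, x$n_opposing))
  print(x$table)
  invisible(x)
}

#' Construct a reaction network
#'
#' @param reaction_genes Tibble with columns `reaction`, `gene` (catalysing
#'   enzymes; a reaction may have several genes).
#' @param pathway_reactions Tibble with columns `pathway`, `reaction`.
#' @return A list of class `reaction_network` with the two (deduplicated)
#'   tibbles.
#' @export
reaction_network <- function(reaction_genes, pathway_reactions) {
  rg <- distinct(as_tibble(reaction_genes)[, c("reaction", "gene")])
  pr <- distinct(as_tibble(pathway_reactions)[, c("pathway", "reaction")])
  orphan <- setdiff(pr$reaction, rg$reaction)
  if (length(orphan))
    abort(paste0("Pathway references unknown reactions: ",
                 paste(head(orphan, 5), collapse = ", ")))
  structure(list(reaction_genes = rg, pathway_reactions = pr),
            class = "reaction_network")
}

#' Read a reaction network from two TSV files
#'
#' @param reaction_gene_path TSV with columns `reaction`, `gene`.
#' @param pathway_reaction_path TSV with columns `pathway`, `reaction`.
#' @return A [reaction_network()].
#' @export
read_reaction_network <- function(reaction_gene_path, pathway_reaction_path) {
  reaction_network(
    readr::read_tsv(reaction_gene_path, show_col_types = FALSE, progress = FALSE),
    readr::read_tsv(pathway_reaction_path, show_col_types = FALSE, progress = FALSE)
  )
}

#' Reaction-level pathway enrichment of differentially expressed genes
#'
#' A reaction counts as differentially regulated if at least one enzyme
#' catalysing it is differentially expressed. Each pathway is then tested by
#' the hypergeometric upper tail `P(X >= k)` with the loaded network's
#' reactions as the population, the dysregulated reactions as successes and
#' the pathway's reactions as draws, followed by BH adjustment across
#' pathways.
#'
#' @param deg_genes Character vector of differentially expressed genes.
#' @param network A [reaction_network()].
#' @param alpha_fdr FDR threshold for the `significant` flag. Default 0.05.
#' @return Tibble with columns `pathway`, `n_reactions`, `n_dysregulated`,
#'   `p_value`, `q_value`, `significant`, ordered by `p_value`.
#' @export
reaction_pathway_enrichment <- function(deg_genes, network, alpha_fdr = 0.05) {
  stopifnot(inherits(network, "reaction_network"))
  dysreg <- network$reaction_genes |>
    group_by(.data$reaction) |>
    summarise(dys = any(.data$gene %in% deg_genes), .groups = "drop")
  n_total <- nrow(dysreg)
  n_dys <- sum(dysreg$dys)

  res <- network$pathway_reactions |>
    inner_join(dysreg, by = "reaction") |>
    group_by(.data$pathway) |>
    summarise(n_reactions = n(), n_dysregulated = sum(.data$dys),
              .groups = "drop") |>
    mutate(
      p_value = phyper(.data$n_dysregulated - 1, n_dys, n_total - n_dys,
                       .data$n_reactions, lower.tail = FALSE),
      q_value = bh_adjust(.data$p_value),
      significant = .data$q_value < alpha_fdr
    ) |>
    arrange(.data$p_value, .data$pathway)
  res
}

#' Compare two Pearson correlations by Fisher z transformation
#'
#' `z_i = atanh(r_i)`; the statistic
#' `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` is referred to the standard
#' normal, two-sided.
#'
#' @param r1,r2 Pearson correlation coefficients, `|r| < 1`.
#' @param n1,n2 Sample sizes, both `> 3`.
#' @return Tibble with columns `z1`, `z2`, `statistic`, `p_value`.
#' @export
#' @examples
#' compare_correlations_fisher_z(0.9, 50, 0.0, 50)
compare_correlations_fisher_z <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) abort("Sample sizes must exceed 3.")
  if (abs(r1) >= 1 || abs(r2) >= 1) abort("Correlations must satisfy |r| < 1.")
  z1 <- atanh(r1); z2 <- atanh(r2)
  stat <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z1 = z1, z2 = z2, statistic = stat, p_value = 2 * pnorm(-abs(stat)))
}
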