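#' Median-of-ratios size factors
#'
#' Normalizes library sizes by the median ratio of each sample's counts to a
#' geometric-mean pseudo-reference, computed over genes with all-positive
#' counts, then rescales the factors to geometric mean 1. When no gene is
#' positive in every sample the function falls back to total-count ratios
#' with a warning.
#'
#' @param counts Gene-by-sample count matrix (or a [count_dataset()]).
#' @return Named numeric vector of positive size factors, one per sample,
#'   geometric mean 1.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' compute_size_factors(m)
compute_size_factors <- function(counts) {
  if (inherits(counts, "count_dataset")) counts <- counts$counts
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos)) {
    warn("No gene with all-positive counts; falling back to total-count ratios.")
    sf <- colSums(counts)
    if (any(sf == 0)) abort("A sample has zero total counts.")
  } else {
    lref <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2,
                function(col) median(exp(log(col) - lref)))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `rpkm = 1e9 * count / (length_bp * total_mapped_reads_of_sample)`. Genes
#' without a known length are dropped with a warning.
#'
#' @param counts Gene-by-sample count matrix or [count_dataset()].
#' @param lengths Named numeric vector of transcript lengths in bp; taken
#'   from the dataset when a `count_dataset` carries them.
#' @return Numeric matrix of RPKM values (possibly fewer rows than `counts`).
#' @export
compute_rpkm <- function(counts, lengths = NULL) {
  if (inherits(counts, "count_dataset")) {
    lengths <- lengths %||% counts$lengths
    counts <- counts$counts
  }
  if (is.null(lengths)) abort("Transcript lengths are required for RPKM.")
  keep <- rownames(counts) %in% names(lengths)
  if (!all(keep))
    warn(sprintf("Dropping %d genes without transcript length.", sum(!keep)))
  counts <- counts[keep, , drop = FALSE]
  len <- lengths[rownames(counts)]
  depth <- colSums(counts)
  sweep(counts / len, 2, depth, "/") * 1e9
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments estimation on size-factor-normalized counts, pooled
#' across age groups (within-group variability only), followed by shrinkage
#' halfway toward a fitted mean-dispersion trend. Raw estimates below zero
#' and shrunken values are floored at `1e-8`. Genes with zero counts
#' throughout are returned with `NA` dispersion and are excluded from
#' testing.
#'
#' @param counts Gene-by-sample count matrix or [count_dataset()].
#' @param groups Factor/character vector of age groups per sample (taken from
#'   the design for a `count_dataset`).
#' @param size_factors Optional; computed by [compute_size_factors()] when
#'   missing.
#' @return Tibble with columns `gene`, `base_mean`, `phi_raw`, `phi_trend`,
#'   `phi`.
#' @export
estimate_dispersion <- function(counts, groups = NULL, size_factors = NULL) {
  if (inherits(counts, "count_dataset")) {
    groups <- groups %||% counts$design$age_group
    counts <- counts$counts
  }
  if (is.null(groups)) abort("Age groups are required.")
  groups <- as.factor(groups)
  if (max(table(groups)) < 2)
    abort("Dispersion estimation needs at least one group with >= 2 replicates.")
  size_factors <- size_factors %||% compute_size_factors(counts)

  y <- sweep(counts, 2, size_factors, "/")
  mu <- rowMeans(y)
  # pooled within-group residual variance
  G <- nlevels(groups)
  resid2 <- y * 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    m_g <- rowMeans(y[, idx, drop = FALSE])
    resid2[, idx] <- (y[, idx, drop = FALSE] - m_g)^2
  }
  s2 <- rowSums(resid2) / (ncol(y) - G)
  # shot-noise term of normalized counts: E Var(y_j) = mu / s_j at phi = 0
  shot <- mu * mean(1 / size_factors)
  phi_raw <- ifelse(mu > 0, pmax((s2 - shot) / mu^2, 1e-8), NA_real_)

  ok <- is.finite(phi_raw) & mu > 0
  phi_trend <- rep(NA_real_, length(mu))
  if (sum(ok) >= 50) {
    lo <- lowess(log(mu[ok]), phi_raw[ok], f = 0.5)
    phi_trend[ok] <- pmax(approx(lo$x, lo$y, xout = log(mu[ok]), rule = 2,
                                 ties = mean)$y, 1e-8)
  } else if (any(ok)) {
    phi_trend[ok] <- median(phi_raw[ok])
  }
  phi <- pmax(0.5 * phi_raw + 0.5 * phi_trend, 1e-8)
  tibble(gene = rownames(counts), base_mean = mu,
         phi_raw = phi_raw, phi_trend = phi_trend, phi = phi)
}

# conditional two-sided p-value of the split (tA, tB) of normalized group
# totals under a common NB mean; the conditional law given tA + tB does not
# depend on the mean because both group sums share the NB probability
# parameter 1 / (1 + phi * mu)
nb_exact_split_p <- function(tA, tB, nA, nB, phi) {
  N <- tA + tB
  if (N == 0) return(1)
  t <- 0:N
  if (phi < 1e-12) {
    lw <- dbinom(t, N, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi
    rB <- nB / phi
    lw <- lgamma(t + rA) - lgamma(t + 1) + lgamma(N - t + rB) - lgamma(N - t + 1)
  }
  lw <- lw - max(lw)
  w <- exp(lw)
  p_obs <- w[tA + 1]
  sum(w[w <= p_obs * (1 + 1e-8)]) / sum(w)
}

#' Exact conditional negative-binomial test for two age groups
#'
#' First of the two pairwise tests entering the consensus rule. Group totals
#' of size-factor-normalized counts are compared by conditioning on their sum:
#' under equal means the conditional distribution of the split is free of the
#' mean, and the two-sided p-value sums the probabilities of all splits at
#' most as probable as the observed one. At `phi = 0` this reduces to the
#' exact binomial split test.
#'
#' @param counts_a,counts_b Integer count vectors of the gene's replicates in
#'   the two groups.
#' @param phi Gene dispersion (from [estimate_dispersion()]).
#' @param sf_a,sf_b Size factors of the corresponding samples (default 1).
#' @return One-row tibble: `test_id`, `lfc`, `phi`, `p_value`.
#' @export
#' @examples
#' pairwise_test_A(c(10, 12), c(50, 55), phi = 0.05)
pairwise_test_A <- function(counts_a, counts_b, phi,
                            sf_a = rep(1, length(counts_a)),
                            sf_b = rep(1, length(counts_b))) {
  tA <- round(sum(counts_a / sf_a))
  tB <- round(sum(counts_b / sf_b))
  p <- nb_exact_split_p(tA, tB, length(counts_a), length(counts_b), phi)
  tibble(test_id = "pairwise_A",
         lfc = log2((tB / length(counts_b) + 0.5) / (tA / length(counts_a) + 0.5)),
         phi = phi, p_value = min(p, 1))
}

#' Wald test on the negative-binomial log2 fold change
#'
#' Second pairwise test of the consensus rule. The log2 fold change is
#' estimated from normalized group means with pseudocount 0.5; its standard
#' error follows from the NB variance function `mu + phi * mu^2` by the delta
#' method; the p-value is two-sided standard normal.
#'
#' @inheritParams pairwise_test_A
#' @return One-row tibble: `test_id`, `lfc`, `se`, `stat`, `phi`, `p_value`.
#' @export
pairwise_test_B <- function(counts_a, counts_b, phi,
                            sf_a = rep(1, length(counts_a)),
                            sf_b = rep(1, length(counts_b))) {
  ya <- counts_a / sf_a
  yb <- counts_b / sf_b
  ma <- mean(ya) + 0.5
  mb <- mean(yb) + 0.5
  lfc <- log2(mb / ma)
  # Var(group mean) on the normalized scale
  va <- (ma * mean(1 / sf_a) + phi * ma^2) / length(ya)
  vb <- (mb * mean(1 / sf_b) + phi * mb^2) / length(yb)
  se <- sqrt(va / (ma * log(2))^2 + vb / (mb * log(2))^2)
  stat <- ifelse(se > 0, lfc / se, 0)
  tibble(test_id = "pairwise_B", lfc = lfc, se = se, stat = stat, phi = phi,
         p_value = 2 * pnorm(-abs(stat)))
}

#' Omnibus likelihood-ratio test across three age groups
#'
#' Tests group-specific NB means against a common mean at fixed dispersion;
#' the statistic is referred to a chi-square distribution with
#' `n_groups - 1` degrees of freedom.
#'
#' @param counts Integer count vector of the gene over all samples.
#' @param groups Age-group factor per sample.
#' @param phi Gene dispersion.
#' @param size_factors Size factors per sample (default 1).
#' @return One-row tibble: `test_id`, `stat`, `df`, `phi`, `p_value`.
#' @export
omnibus_test <- function(counts, groups, phi,
                         size_factors = rep(1, length(counts))) {
  groups <- as.factor(groups)
  size <- if (phi < 1e-12) NULL else 1 / phi
  ll <- function(mu_per_sample) {
    if (is.null(size)) sum(stats::dpois(counts, pmax(mu_per_sample, 1e-12),
                                        log = TRUE))
    else sum(dnbinom(counts, size = size, mu = pmax(mu_per_sample, 1e-12),
                     log = TRUE))
  }
  mu_null <- sum(counts) / sum(size_factors)
  mu_alt <- vapply(levels(groups), function(g) {
    idx <- groups == g
    sum(counts[idx]) / sum(size_factors[idx])
  }, numeric(1))
  stat <- 2 * (ll(mu_alt[as.integer(groups)] * size_factors) -
                 ll(mu_null * size_factors))
  stat <- max(stat, 0)
  df <- nlevels(groups) - 1
  tibble(test_id = "omnibus", stat = stat, df = df, phi = phi,
         p_value = if (sum(counts) == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as a
#' named step so every FDR adjustment in the pipeline goes through one
#' function.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Run all differential-expression tests for one species
#'
#' Computes size factors and dispersions, then applies both pairwise NB tests
#' to every ordered age-group pair and the omnibus test across all groups.
#' q-values are BH-adjusted within each (test, contrast) family.
#'
#' @param dataset A [count_dataset()].
#' @param config A [pipeline_config()].
#' @return Tibble with columns `gene`, `contrast`, `test_id`, `lfc`, `phi`,
#'   `p_value`, `q_value`. All-zero genes are excluded.
#' @export
run_deg_tests <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "count_dataset"))
  counts <- dataset$counts
  groups <- factor(dataset$design$age_group,
                   levels = unique(dataset$design$age_group))
  if (nlevels(groups) != 3)
    abort("The consensus rule expects exactly three age groups.")
  sf <- compute_size_factors(counts)
  disp <- estimate_dispersion(counts, groups, sf)
  phi <- setNames(disp$phi, disp$gene)
  keep <- rownames(counts)[rowSums(counts) > 0 & !is.na(phi[rownames(counts)])]
  if (length(keep) < nrow(counts))
    inform(sprintf("Excluding %d all-zero genes from testing.",
                   nrow(counts) - length(keep)))

  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- list()
  for (pr in pairs) {
    ia <- which(groups == pr[1]); ib <- which(groups == pr[2])
    contrast <- paste(pr, collapse = "|")
    a_rows <- vector("list", length(keep)); b_rows <- a_rows
    for (k in seq_along(keep)) {
      g <- keep[k]
      a_rows[[k]] <- pairwise_test_A(counts[g, ia], counts[g, ib], phi[[g]],
                                     sf[ia], sf[ib])
      b_rows[[k]] <- pairwise_test_B(counts[g, ia], counts[g, ib], phi[[g]],
                                     sf[ia], sf[ib])
    }
    res[[length(res) + 1]] <- bind_rows(a_rows) |>
      mutate(gene = keep, contrast = contrast)
    res[[length(res) + 1]] <- bind_rows(b_rows) |>
      mutate(gene = keep, contrast = contrast) |>
      select(-"se", -"stat")
  }
  o_rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    g <- keep[k]
    o_rows[[k]] <- omnibus_test(counts[g, ], groups, phi[[g]], sf)
  }
  res[[length(res) + 1]] <- bind_rows(o_rows) |>
    mutate(gene = keep, contrast = "omnibus") |>
    select(-"stat", -"df")

  bind_rows(res) |>
    group_by(.data$test_id, .data$contrast) |>
    mutate(q_value = bh_adjust(.data$p_value)) |>
    ungroup() |>
    select("gene", "contrast", "test_id", dplyr::any_of("lfc"), "phi",
           "p_value", "q_value")
}

#' Call differentially expressed genes by the consensus rule
#'
#' A gene is a DEG if both pairwise tests agree at FDR `alpha` on at least
#' one age-group contrast, or if the omnibus test over all three ages is
#' significant at FDR `alpha`. The regulation direction during ageing is
#' taken from the log2 fold change of the first-vs-last age contrast when
#' both pairwise tests call that contrast; genes whose first-to-last change
#' is not consensus-significant are labelled `"mixed"`.
#'
#' @param results Tibble from [run_deg_tests()].
#' @param alpha_fdr FDR threshold (default 0.05).
#' @return Tibble with columns `gene`, `is_deg`, `direction` (`"up"`,
#'   `"down"`, `"mixed"`, `NA` when not a DEG) and `supporting_rule`
#'   (`"pairwise_consensus"`, `"omnibus"` or `"both"`).
#' @export
call_degs <- function(results, alpha_fdr = 0.05) {
  pw <- results |>
    filter(.data$test_id %in% c("pairwise_A", "pairwise_B")) |>
    tidyr::pivot_wider(id_cols = c("gene", "contrast"),
                       names_from = "test_id",
                       values_from = c("q_value", "lfc"))
  per_contrast <- pw |>
    mutate(consensus = .data$q_value_pairwise_A <= alpha_fdr &
             .data$q_value_pairwise_B <= alpha_fdr)
  pairwise_call <- per_contrast |>
    group_by(.data$gene) |>
    summarise(pairwise_hit = any(.data$consensus), .groups = "drop")

  contrasts <- unique(per_contrast$contrast)
  # contrasts are ordered pairs "A|B" of the ordered age levels; the
  # first-vs-last contrast joins the left end of the first pair to the right
  # end of the last pair
  first_age <- strsplit(contrasts[1], "|", fixed = TRUE)[[1]][1]
  last_age <- strsplit(contrasts[length(contrasts)], "|", fixed = TRUE)[[1]][2]
  first_last <- paste(first_age, last_age, sep = "|")
  fl <- per_contrast |>
    filter(.data$contrast == first_last) |>
    select("gene", fl_consensus = "consensus", fl_lfc = "lfc_pairwise_B")

  omni <- results |>
    filter(.data$test_id == "omnibus") |>
    mutate(omnibus_hit = .data$q_value <= alpha_fdr) |>
    select("gene", "omnibus_hit")

  pairwise_call |>
    left_join(omni, by = "gene") |>
    left_join(fl, by = "gene") |>
    mutate(
      is_deg = .data$pairwise_hit | .data$omnibus_hit,
      supporting_rule = dplyr::case_when(
        .data$pairwise_hit & .data$omnibus_hit ~ "both",
        .data$pairwise_hit ~ "pairwise_consensus",
        .data$omnibus_hit ~ "omnibus",
        TRUE ~ NA_character_
      ),
      direction = dplyr::case_when(
        !.data$is_deg ~ NA_character_,
        .data$fl_consensus & .data$fl_lfc > 0 ~ "up",
        .data$fl_consensus & .data$fl_lfc < 0 ~ "down",
        TRUE ~ "mixed"
      )
    ) |>
    select("gene", "is_deg", "direction", "supporting_rule")
}
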