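# shared fixture builders; everything is generated in code

toy_count_dataset <- function() {
  m <- matrix(c(10, 20, 30,
                12, 22, 28,
                40, 50, 60,
                38, 52, 62,
                90, 15, 33,
                88, 17, 35), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"),
                              paste0("s", 1:6)))
  design <- tibble::tibble(sample = paste0("s", 1:6),
                           species = "worm",
                           age_group = rep(c("young", "middle", "old"), each = 2),
                           replicate = rep(1:2, 3))
  count_dataset(m, design)
}

# a high-information width-10 matrix: near-deterministic consensus ACGTACGTAC
strong_pssm <- function(count = 50) {
  consensus <- c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C")
  counts <- matrix(0, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- count
  pssm(counts, "strongTF")
}

# brute-force conditional NB split distribution (independent oracle for the
# exact pairwise test): joint probability of (t, N - t) for any common mean,
# normalized over all splits
enumerate_split_p <- function(tA, tB, nA, nB, phi, mu = 10) {
  N <- tA + tB
  t <- 0:N
  pr <- if (phi < 1e-12) {
    stats::dpois(t, nA * mu) * stats::dpois(N - t, nB * mu)
  } else {
    stats::dnbinom(t, size = nA / phi, mu = nA * mu) *
      stats::dnbinom(N - t, size = nB / phi, mu = nB * mu)
  }
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[tA + 1] * (1 + 1e-8)])
}

# permutation log-rank p-value oracle
permutation_logrank_p <- function(records_a, records_b, n_perm = 20000,
                                  seed = 1) {
  set.seed(seed)
  pooled <- dplyr::bind_rows(dplyr::mutate(records_a, grp = "a"),
                             dplyr::mutate(records_b, grp = "b"))
  obs <- logrank_test(records_a, records_b)$statistic
  n <- nrow(pooled)
  na <- nrow(records_a)
  stat <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    stat[i] <- logrank_test(pooled[idx, ], pooled[-idx, ])$statistic
  }
  mean(stat >= obs - 1e-12)
}
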