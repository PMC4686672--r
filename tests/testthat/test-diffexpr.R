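test_that("size factors respect symmetry, scaling and the median-of-ratios rule", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(compute_size_factors(m)), c(1, 1))

  m2 <- matrix(c(10, 20, 30, 20, 40, 60), 3,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  sf <- compute_size_factors(m2)
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  # brute-force oracle on a 3x3 matrix
  m3 <- matrix(c(4, 10, 40, 8, 30, 40, 6, 20, 80), 3,
               dimnames = list(paste0("g", 1:3), c("a", "b", "c")))
  ref <- exp(rowMeans(log(m3)))
  raw <- apply(m3, 2, function(col) median(col / ref))
  expect_equal(unname(compute_size_factors(m3)),
               unname(raw / exp(mean(log(raw)))))

  m4 <- matrix(c(0L, 5L, 3L, 0L), 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_warning(compute_size_factors(m4), "total-count")
})

test_that("RPKM follows its defining formula", {
  counts <- matrix(c(100L, 0L), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  # make sample depth exactly 1e6
  counts <- rbind(counts, filler = 1e6L - 100L)
  rpkm <- compute_rpkm(counts, c(g1 = 1000, g2 = 500, filler = 1e6 - 100))
  expect_equal(rpkm["g1", 1], 100)
  expect_equal(rpkm["g2", 1], 0)
  # doubling depth at fixed counts halves RPKM
  counts2 <- counts
  counts2["filler", 1] <- 2e6L - 100L
  rpkm2 <- compute_rpkm(counts2, c(g1 = 1000, g2 = 500, filler = 1e6))
  expect_equal(rpkm2["g1", 1], 50)
  expect_warning(compute_rpkm(counts, c(g1 = 1000, filler = 1)), "length")
})

test_that("dispersion estimation floors, recovers NB truth and shrinks Poisson", {
  set.seed(5)
  # Poisson data: raw estimates must shrink to near zero
  mu <- exp(rnorm(400, log(100), 1))
  cp <- matrix(rpois(400 * 200, rep(mu, 200)), 400, 200,
               dimnames = list(paste0("g", 1:400), paste0("s", 1:200)))
  dp <- estimate_dispersion(cp, rep("a", 200), rep(1, 200))
  expect_lt(unname(quantile(dp$phi, 0.95)), 0.02)

  cn <- matrix(rnbinom(400 * 200, size = 5, mu = rep(mu, 200)), 400, 200,
               dimnames = dimnames(cp))
  dn <- estimate_dispersion(cn, rep("a", 200), rep(1, 200))
  expect_true(all(dn$phi >= 0.1 & dn$phi <= 0.3))

  # variance below mean floors the raw estimate
  m <- matrix(rep(c(9L, 10L, 11L, 10L), 5), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  d <- estimate_dispersion(m, rep("a", 4), rep(1, 4))
  expect_true(all(d$phi_raw == 1e-8))
})

test_that("exact conditional NB test matches enumeration oracles", {
  # most probable split under symmetric design is included: p = 1
  expect_equal(pairwise_test_A(c(5, 5), c(5, 5), 0.1)$p_value, 1)
  # zero totals give p = 1 by convention
  expect_equal(pairwise_test_A(c(0, 0), c(0, 0), 0.1)$p_value, 1)

  # phi = 0: reduces to the exact binomial split on totals
  for (case in list(c(3, 7), c(0, 12), c(10, 20))) {
    tA <- case[1]; tB <- case[2]
    got <- pairwise_test_A(c(tA, 0), c(tB, 0), phi = 0)$p_value
    pr <- dbinom(0:(tA + tB), tA + tB, 0.5)
    expect_equal(got, sum(pr[pr <= pr[tA + 1] * (1 + 1e-8)]),
                 tolerance = 1e-10)
  }

  # NB enumeration oracle for totals <= 50 at several dispersions
  grid <- expand.grid(tA = c(0, 3, 12, 25), tB = c(1, 8, 25),
                      phi = c(0.05, 0.2, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- pairwise_test_A(c(g$tA, 0), c(g$tB, 0), g$phi)$p_value
    want <- enumerate_split_p(g$tA, g$tB, 2, 2, g$phi)
    expect_equal(got, want, tolerance = 1e-8,
                 label = sprintf("tA=%d tB=%d phi=%g", g$tA, g$tB, g$phi))
  }
  # oracle is mean-invariant, as the conditional law requires
  expect_equal(enumerate_split_p(4, 20, 2, 2, 0.2, mu = 3),
               enumerate_split_p(4, 20, 2, 2, 0.2, mu = 70), tolerance = 1e-9)
})

test_that("Wald test statistic follows its hand formula and nulls at equality", {
  eq <- pairwise_test_B(c(10, 10), c(10, 10), 0.1)
  expect_equal(eq$stat, 0)
  expect_equal(eq$p_value, 1)

  # hand computation on a toy gene, unit size factors
  a <- c(10, 14); b <- c(40, 44); phi <- 0.1
  ma <- mean(a) + 0.5; mb <- mean(b) + 0.5
  lfc <- log2(mb / ma)
  va <- (ma + phi * ma^2) / 2
  vb <- (mb + phi * mb^2) / 2
  se <- sqrt(va / (ma * log(2))^2 + vb / (mb * log(2))^2)
  got <- pairwise_test_B(a, b, phi)
  expect_equal(got$lfc, lfc)
  expect_equal(got$stat, lfc / se)
  expect_equal(got$p_value, 2 * pnorm(-abs(lfc / se)))
})

test_that("omnibus LRT nulls on identical groups and separates strong effects", {
  groups <- rep(c("y", "m", "o"), each = 2)
  res <- omnibus_test(rep(10L, 6), groups, 0.1)
  expect_equal(res$stat, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1)
  sep <- omnibus_test(c(10L, 10L, 10L, 10L, 1000L, 1000L), groups, 0.01)
  expect_lt(sep$p_value, 1e-6)
  expect_equal(omnibus_test(rep(0L, 6), groups, 0.1)$p_value, 1)
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the consensus DEG rule combines pairwise agreement and the omnibus", {
  mk <- function(gene, contrast, test_id, q, lfc = 1) {
    tibble::tibble(gene = gene, contrast = contrast, test_id = test_id,
                   lfc = ifelse(test_id == "omnibus", NA_real_, lfc),
                   phi = 0.1, p_value = q, q_value = q)
  }
  contrasts <- c("young|middle", "young|old", "middle|old")
  rows <- list()
  for (ct in contrasts) {
    # g1: both pairwise tests significant on (young, old) only, upward
    rows[[length(rows) + 1]] <- mk("g1", ct, "pairwise_A",
                                   ifelse(ct == "young|old", 0.01, 0.5))
    rows[[length(rows) + 1]] <- mk("g1", ct, "pairwise_B",
                                   ifelse(ct == "young|old", 0.01, 0.5), lfc = 2)
    # g2: only test A fires, everywhere
    rows[[length(rows) + 1]] <- mk("g2", ct, "pairwise_A", 0.01)
    rows[[length(rows) + 1]] <- mk("g2", ct, "pairwise_B", 0.5)
    # g3: neither pairwise test fires
    rows[[length(rows) + 1]] <- mk("g3", ct, "pairwise_A", 0.5)
    rows[[length(rows) + 1]] <- mk("g3", ct, "pairwise_B", 0.5)
  }
  rows[[length(rows) + 1]] <- mk("g1", "omnibus", "omnibus", 0.2)
  rows[[length(rows) + 1]] <- mk("g2", "omnibus", "omnibus", 0.5)
  rows[[length(rows) + 1]] <- mk("g3", "omnibus", "omnibus", 0.01)
  res <- dplyr::bind_rows(rows)

  calls <- call_degs(res, alpha_fdr = 0.05)
  g1 <- calls[calls$gene == "g1", ]
  expect_true(g1$is_deg)
  expect_equal(g1$supporting_rule, "pairwise_consensus")
  expect_equal(g1$direction, "up")
  g2 <- calls[calls$gene == "g2", ]
  expect_false(g2$is_deg)
  g3 <- calls[calls$gene == "g3", ]
  expect_true(g3$is_deg)
  expect_equal(g3$supporting_rule, "omnibus")
  expect_equal(g3$direction, "mixed")
})

test_that("rejection rate grows with simulated fold change", {
  set.seed(21)
  rate_at <- function(fc) {
    n <- 200
    a <- matrix(rnbinom(n * 4, size = 10, mu = 100), n, 4)
    b <- matrix(rnbinom(n * 4, size = 10, mu = 100 * fc), n, 4)
    mean(vapply(seq_len(n), function(i)
      pairwise_test_B(a[i, ], b[i, ], 0.1)$p_value, numeric(1)) < 0.05)
  }
  rates <- vapply(c(1, 1.5, 3), rate_at, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})
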