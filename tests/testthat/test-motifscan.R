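test_that("PSSM construction normalizes columns and handles formats identically", {
  m <- matrix(c(8, 0, 0, 0,
                0, 8, 0, 0,
                0, 0, 8, 0,
                2, 2, 2, 2), 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pm <- pssm(m, "toy")
  expect_equal(unname(colSums(pm$freq)), rep(1, 4))
  expect_equal(pm$width, 4)

  uni <- pssm(matrix(2, 4, 3), "uniform")
  expect_equal(unname(uni$weights), matrix(0, 4, 3), tolerance = 1e-12)

  jaspar <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">toy test factor",
               "A [ 8 0 0 2 ]",
               "C [ 0 8 0 2 ]",
               "G [ 0 0 8 2 ]",
               "T [ 0 0 0 2 ]"), jaspar)
  transfac <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("ID toy", "P0 A C G T",
               "01 8 0 0 0", "02 0 8 0 0", "03 0 0 8 0", "04 2 2 2 2",
               "//"), transfac)
  pj <- load_pssm(jaspar, "JASPAR")[[1]]
  pt <- load_pssm(transfac, "TRANSFAC")[[1]]
  expect_equal(unname(pj$counts), matrix(c(8, 0, 0, 2,
                                           0, 8, 0, 2,
                                           0, 0, 8, 2,
                                           0, 0, 0, 2), 4, byrow = TRUE))
  expect_equal(unname(pj$counts), unname(pt$counts))
  expect_equal(pj$freq, pt$freq, ignore_attr = TRUE)
  bad <- withr::local_tempfile(fileext = ".x")
  writeLines("no headers here", bad)
  expect_error(load_pssm(bad, "JASPAR"), "format error")
})

test_that("score distribution equals exhaustive word enumeration", {
  set.seed(4)
  counts <- matrix(rpois(16, 5) + 1, 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  bg <- c(A = 0.4, C = 0.1, G = 0.2, T = 0.3)
  pm <- pssm(counts, "w4", background = bg)
  sdist <- score_distribution(pm, bg, bin_width = 0.01)
  W <- sdist$binned_weights

  # enumerate all 4^4 words with their background probabilities
  words <- expand.grid(1:4, 1:4, 1:4, 1:4)
  word_scores <- as.matrix(words)
  scores <- W[cbind(word_scores[, 1], 1)] + W[cbind(word_scores[, 2], 2)] +
    W[cbind(word_scores[, 3], 3)] + W[cbind(word_scores[, 4], 4)]
  probs <- bg[word_scores[, 1]] * bg[word_scores[, 2]] *
    bg[word_scores[, 3]] * bg[word_scores[, 4]]
  for (s in unique(scores)) {
    want <- sum(probs[scores >= s])
    got <- agecourse:::score_p_value(sdist, s)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # tail is non-increasing in the score
  expect_true(all(diff(sdist$tail_p) <= 1e-15))
})

test_that("uniform matrix under uniform background has a single score mass", {
  uni <- pssm(matrix(3, 4, 5), "uniform")
  sdist <- score_distribution(uni)
  expect_equal(length(sdist$bins[sdist$prob > 0]), 1)
  expect_equal(agecourse:::score_p_value(sdist, sdist$bins[1]), 1)
})

test_that("promoter scanning recovers planted sites and skips N windows", {
  pm <- strong_pssm()
  gp <- generate_promoters(pm, 1, 1000, sites_per_promoter = 3, seed = 2)
  rep <- scan_promoter(gp$sequences[[1]], pm,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       p_threshold = 1e-4)
  expect_gte(nrow(rep$hits), 3)
  overlapping <- vapply(gp$sites$position, function(p)
    any(abs(rep$hits$position - p) < pm$width), logical(1))
  expect_true(all(overlapping))
  expect_true(all(rep$hits$p_site < 1e-4))
  expect_true(all(rep$hits$position >= 0 &
                    rep$hits$position <= 1000 - pm$width))

  allN <- scan_promoter(strrep("N", 200), pm)
  expect_equal(nrow(allN$hits), 0)
  short <- scan_promoter("ACG", pm)
  expect_equal(nrow(short$hits), 0)
})

test_that("false-hit count on background sequence is Poisson-consistent", {
  set.seed(6)
  seq10k <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  counts <- matrix(rpois(32, 3) + 1, 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pm <- pssm(counts, "w8")
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  rep <- scan_promoter(seq10k, pm, background = bg, p_threshold = 1e-2)
  n_win <- rep$summary$n_windows
  # the discrete score distribution makes the achievable per-window level
  # the largest tail mass strictly below the threshold; hit counts must sit
  # inside the 99% interval of the corresponding Poisson law
  sdist <- score_distribution(pm, bg)
  alpha_eff <- max(sdist$tail_p[sdist$tail_p < 1e-2])
  lambda <- n_win * alpha_eff
  expect_gte(rep$summary$n_sites, qpois(0.005, lambda))
  expect_lte(rep$summary$n_sites, qpois(0.995, lambda))
  expect_equal(rep$summary$p_aggregate,
               pbinom(rep$summary$n_sites - 1, n_win, 1e-2,
                      lower.tail = FALSE))
})

test_that("hit counts are invariant under reverse complementing", {
  pm <- strong_pssm()
  gp <- generate_promoters(pm, 1, 600, sites_per_promoter = 2, seed = 9)
  fwd <- scan_promoter(gp$sequences[[1]], pm, p_threshold = 1e-4)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(gp$sequences[[1]],
                                                  NULL)[[1]]), collapse = ""))
  bwd <- scan_promoter(rc, pm, p_threshold = 1e-4)
  expect_equal(fwd$summary$n_sites, bwd$summary$n_sites)
  expect_equal(fwd$summary$n_windows, bwd$summary$n_windows)
})

test_that("halving the bin width moves p-values by at most the coarser bin mass", {
  set.seed(10)
  counts <- matrix(rpois(24, 4) + 1, 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pm <- pssm(counts, "w6")
  coarse <- score_distribution(pm, bin_width = 0.02)
  fine <- score_distribution(pm, bin_width = 0.01)
  max_mass <- max(coarse$prob)
  for (s in seq(-2, 4, by = 0.5)) {
    pc <- agecourse:::score_p_value(coarse, round(s / 0.02))
    pf <- agecourse:::score_p_value(fine, round(s / 0.01))
    expect_lte(abs(pc - pf), max_mass + 1e-12)
  }
})

test_that("TF ranking orders by site count then aggregate p", {
  summ <- tibble::tibble(promoter = "p", tf = c("a", "b", "c", "d"),
                         n_sites = c(3L, 1L, 0L, 1L),
                         n_windows = 1900,
                         p_aggregate = c(1e-6, 1e-3, 1, 1e-5))
  r <- rank_tfs(summ)
  expect_equal(r$tf, c("a", "d", "b"))
  expect_equal(r$rank, 1:3)
  none <- rank_tfs(dplyr::mutate(summ, n_sites = 0L))
  expect_equal(nrow(none), 0)
})

test_that("FASTA promoters round-trip through Biostrings", {
  skip_if_not_installed("Biostrings")
  pm <- strong_pssm()
  gp <- generate_promoters(pm, 2, 80, seed = 3)
  path <- withr::local_tempfile(fileext = ".fa")
  write_promoters(gp$sequences, path)
  back <- read_promoters(path)
  expect_equal(back, gp$sequences)
})
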