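test_that("age rescaling maps lifespans onto the unit interval", {
  expect_equal(rescale_timepoints(c(1, 10, 20)), c(0, 9 / 19, 1))
  expect_equal(round(rescale_timepoints(c(1, 10, 20))[2], 4), 0.4737)
  expect_equal(round(rescale_timepoints(c(2, 15, 30))[2], 4), 0.4643)
  expect_equal(rescale_timepoints(c(3, 12)), c(0, 1))
  expect_error(rescale_timepoints(c(5, 5)), "distinct ages")
  df <- tibble::tibble(species = rep(c("worm", "mouse"), each = 2),
                       age_group = rep(c("young", "old"), 2),
                       age = c(1, 20, 2, 30))
  out <- rescale_timepoints(df)
  expect_equal(out$t, c(0, 1, 0, 1))
})

test_that("profile construction filters to spanning orthologs and z-scores rows", {
  sim <- generate_species_counts(n_genes = 60, seed = 17)
  calls <- lapply(sim$datasets,
                  function(d) call_degs(run_deg_tests(d), 0.05))
  # remove one species' membership of the first group: its genes must drop out
  ortho <- dplyr::filter(sim$orthology,
                         !(group == "og00001" & species == "worm"))
  pm <- suppressMessages(build_profiles(sim$datasets, calls,
                                        orthology_map(ortho)))
  info <- attr(pm, "row_info")
  dropped_genes <- paste0(names(sim$datasets), "_g1")
  expect_false(any(info$gene %in% dropped_genes))
  expect_equal(unname(rowMeans(pm)), rep(0, nrow(pm)), tolerance = 1e-12)
  expect_equal(unname(apply(pm, 1, sd)), rep(1, nrow(pm)), tolerance = 1e-12)
})

test_that("fuzzy c-means honours its degenerate and separated-cloud limits", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3)
  one <- fuzzy_cmeans(X, 1, seed = 1)
  expect_equal(unname(one$membership[, 1]), rep(1, 20))
  expect_equal(unname(one$centroids[1, ]), unname(colMeans(X)))

  # two well-separated clouds: near-crisp membership, closed-form check
  A <- matrix(rnorm(45, 0, 0.1), 15, 3)
  B <- matrix(rnorm(45, 10, 0.1), 15, 3)
  fit <- fuzzy_cmeans(rbind(A, B), 2, seed = 3)
  expect_true(all(apply(fit$membership, 1, max) > 0.95))
  # membership formula: u = 1 / (1 + (d1/d2)^2) at m = 2
  d2 <- cbind(rowSums((rbind(A, B) - matrix(fit$centroids[1, ], 30, 3,
                                            byrow = TRUE))^2),
              rowSums((rbind(A, B) - matrix(fit$centroids[2, ], 30, 3,
                                            byrow = TRUE))^2))
  u1 <- (1 / d2[, 1]) / (1 / d2[, 1] + 1 / d2[, 2])
  expect_equal(unname(fit$membership[, 1]), u1, tolerance = 1e-6)

  expect_error(fuzzy_cmeans(X, 21), "between 1 and")
})

test_that("fuzzy objective is non-increasing and memberships are a partition", {
  set.seed(9)
  X <- matrix(rnorm(300), 100, 3)
  fit <- fuzzy_cmeans(X, 5, seed = 4)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  expect_equal(unname(rowSums(fit$membership)), rep(1, 100), tolerance = 1e-9)
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
  # centroids lie within the per-coordinate convex hull of the data
  expect_true(all(t(fit$centroids) >= apply(X, 2, min) - 1e-9))
  expect_true(all(t(fit$centroids) <= apply(X, 2, max) + 1e-9))
})

test_that("near-crisp fuzziness approaches k-means and e1071 agrees at m = 2", {
  skip_if_not_installed("e1071")
  set.seed(31)
  X <- rbind(matrix(rnorm(60, 0, 0.3), 20, 3),
             matrix(rnorm(60, 5, 0.3), 20, 3),
             matrix(rnorm(60, -5, 0.3), 20, 3))
  fit <- fuzzy_cmeans(X, 3, m = 1.05, seed = 6, n_restarts = 5)
  km <- stats::kmeans(X, centers = fit$centroids)
  hard <- max.col(fit$membership)
  # identical partitions up to label permutation
  expect_equal(length(unique(paste(hard, km$cluster))), 3)

  fit2 <- fuzzy_cmeans(X, 3, m = 2, seed = 6, tol = 1e-10)
  ref <- e1071::cmeans(X, centers = fit2$centroids, m = 2,
                       iter.max = 200)
  expect_equal(unname(sort(rowSums(ref$centers))),
               unname(sort(rowSums(fit2$centroids))), tolerance = 1e-3)
  expect_lt(max(abs(sort(fit2$membership[1, ]) -
                      sort(ref$membership[1, ]))), 1e-3)
})

test_that("course classification is strict monotonicity", {
  expect_equal(classify_course(c(-1, 0, 1)), "up")
  expect_equal(classify_course(c(1, 0, -1)), "down")
  expect_equal(classify_course(c(-1, 1, 0)), "other")
  expect_equal(classify_course(c(0, 0, 1)), "other")
})

test_that("conserved sets require unanimous direction across species", {
  # 3 species x 2 groups; group og1 up in all, og2 up in two species only
  info <- tibble::tibble(
    species = rep(c("s1", "s2", "s3"), each = 2),
    gene = c("a1", "a2", "b1", "b2", "c1", "c2"))
  X <- rbind(c(-1, 0, 1), c(-1, 0, 1),
             c(-1, 0, 1), c(-1, 0, 1),
             c(-1, 0, 1), c(1, 0, -1))
  rownames(X) <- paste(info$species, info$gene, sep = ":")
  pmx <- structure(X, row_info = info,
                   class = c("profile_matrix", "matrix", "array"))
  fit <- fuzzy_cmeans(pmx, 2, seed = 2)
  ortho <- orthology_map(tibble::tibble(
    species = info$species, gene = info$gene,
    group = rep(c("og1", "og2"), 3)))
  vn <- conserved_sets(fit, ortho)
  expect_equal(vn$conserved_up, "og1")
  expect_equal(vn$conserved_down, character(0))

  empty <- orthology_map(tibble::tibble(species = character(),
                                        gene = character(),
                                        group = character()))
  vn0 <- conserved_sets(fit, empty)
  expect_length(vn0$conserved_up, 0)
  expect_length(vn0$conserved_down, 0)
})

test_that("row order does not change conserved sets", {
  sim <- generate_species_counts(n_genes = 80, amplitude = 3, seed = 23)
  calls <- lapply(sim$datasets, function(d) call_degs(run_deg_tests(d), 0.05))
  pm <- build_profiles(sim$datasets, calls, sim$orthology)
  fit <- fuzzy_cmeans(pm, 6, seed = 11)
  vn <- conserved_sets(fit, sim$orthology)

  perm <- sample(nrow(pm))
  pm2 <- structure(unclass(pm)[perm, ],
                   row_info = attr(pm, "row_info")[perm, ],
                   class = class(pm))
  fit2 <- fuzzy_cmeans(pm2, 6, seed = 11)
  vn2 <- conserved_sets(fit2, sim$orthology)
  expect_setequal(vn$conserved_up, vn2$conserved_up)
  expect_setequal(vn$conserved_down, vn2$conserved_down)
})

test_that("tidiers expose assignments and fit summaries", {
  X <- simulate_course_profiles(30, 2, 0.1, seed = 2)
  fit <- fuzzy_cmeans(X, 6, seed = 2)
  td <- tidy(fit)
  expect_true(all(c("species", "gene", "cluster", "max_membership",
                    "course") %in% names(td)))
  expect_equal(nrow(td), 60)
  gl <- glance(fit)
  expect_equal(gl$c, 6)
  expect_equal(gl$n_up + gl$n_down + gl$n_other, 6)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
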