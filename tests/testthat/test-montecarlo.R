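make_posterior <- function(counts, trials, initial) {
  post <- structure(list(counts = counts, trials = trials,
                         received = rowSums(counts), initial = initial,
                         pep_mode = "normalized", seed = 0L),
                    class = "ffc_posterior")
  post$never_reached <- post$received == 0
  post$pep <- pep(post)
  post$entropy <- label_entropy(post)
  post
}

test_that("PEP modes reproduce their printed arithmetic", {
  # one point: counts {initial: 6, other: 4}, 10 receiving trials of T = 20
  post <- make_posterior(matrix(c(6L, 4L), 1, 2), trials = 20L, initial = 1L)
  expect_equal(pep(post, "normalized"), 0.4)
  expect_equal(pep(post, "raw"), 1 - 4 / 20)
  expect_equal(pep(post, "coverage"), 1 - 6 / 20)
  expect_error(pep(post, mode = 1), "normalized, raw, coverage")

  # a point receiving only its initial label has PEP 0 in every mode with
  # received > 0 semantics
  pure <- make_posterior(matrix(c(10L, 0L), 1, 2), trials = 10L, initial = 1L)
  expect_equal(pep(pure, "normalized"), 0)
  expect_equal(pep(pure, "coverage"), 0)

  # never-reached points: normalized mode flags full uncertainty
  none <- make_posterior(matrix(c(0L, 0L), 1, 2), trials = 10L, initial = 1L)
  expect_equal(pep(none, "normalized"), 1)
  expect_true(none$never_reached)
})

test_that("label entropy matches hand values and its bound", {
  even <- make_posterior(matrix(c(5L, 5L), 1, 2), 10L, 1L)
  expect_equal(even$entropy, log(2), tolerance = 1e-12)

  skew <- make_posterior(matrix(c(8L, 1L, 1L), 1, 3), 10L, 1L)
  expect_equal(skew$entropy, -(0.8 * log(0.8) + 2 * 0.1 * log(0.1)),
               tolerance = 1e-12)

  one <- make_posterior(matrix(c(7L, 0L), 1, 2), 10L, 1L)
  expect_equal(one$entropy, 0)

  none <- make_posterior(matrix(0L, 1, 2), 10L, 1L)
  expect_equal(none$entropy, 0)
})

test_that("high-confidence mask uses a strict threshold", {
  post <- make_posterior(rbind(c(10L, 0L), c(9L, 1L), c(5L, 5L)), 10L,
                         c(1L, 1L, 1L))
  post$pep <- c(0, 0.1, 0.5)   # exact boundary value
  expect_equal(high_confidence(post, 0.1), c(TRUE, FALSE, FALSE))
  expect_equal(high_confidence(post, 1.0), c(TRUE, TRUE, TRUE))
})

test_that("a validation trial equals a standalone propagation from the same seed", {
  blobs <- two_blobs()
  fit <- forest_fire(blobs$X, temperature = 10, K = 10, seed = 1)
  for (r in c(3L, 57L, 90L)) {
    tr <- mc_trial(fit$graph, fit$labels, r, fit$temperature)
    pr <- propagate(fit$graph, integer(100), r, fit$labels[r], fit$temperature)
    expect_identical(tr$accepted, which(pr$labels == fit$labels[r]))
    expect_true(r %in% tr$accepted)  # the seed always records its own label
  }
})

test_that("trials respect disconnected components and conservation holds", {
  blobs <- two_blobs()   # zero cross-blob affinity at K = 10
  fit <- forest_fire(blobs$X, temperature = 10, K = 10, seed = 1)
  post <- mc_validate(fit, trials = 200, seed = 2)
  expect_true(all(rowSums(post$counts) == post$received))
  expect_true(all(post$received <= post$trials))
  # a seed in one blob never labels the other: counts stay block-diagonal
  cl1 <- blobs$truth == 1
  lab1 <- fit$labels[which(cl1)[1]]
  expect_true(all(post$counts[!cl1, lab1] == 0))
  # entropy bounded by ln(k observed at the point)
  kobs <- rowSums(post$counts > 0)
  expect_true(all(post$entropy <= log(pmax(kobs, 1)) + 1e-12))
  # normalized PEP complements the initial-label posterior mass
  own <- post$counts[cbind(1:100, post$initial)]
  got <- own / pmax(post$received, 1)
  expect_equal(post$pep[post$received > 0] + got[post$received > 0],
               rep(1, sum(post$received > 0)), tolerance = 1e-12)
})

test_that("a hot fire on one connected blob reaches every point in every trial", {
  sim <- sim_circle_gaussians(n = 80, n_clusters = 1, sigma = 0.3, seed = 12)
  fit <- forest_fire(sim$X, temperature = 100, K = 15, seed = 1)
  expect_equal(fit$k, 1L)
  post <- suppressWarnings(mc_validate(fit, trials = 40, seed = 3))
  expect_true(all(post$received == post$trials))
})

test_that("worker count never changes the tallies", {
  blobs <- two_blobs()
  fit <- forest_fire(blobs$X, temperature = 10, K = 10, seed = 1)
  p1 <- mc_validate(fit, trials = 60, workers = 1, seed = 5)
  p4 <- mc_validate(fit, trials = 60, workers = 4, seed = 5)
  expect_identical(p1$counts, p4$counts)
  expect_identical(p1$pep, p4$pep)
  # and identical master seeds reproduce byte-identically
  p1b <- mc_validate(fit, trials = 60, workers = 2, seed = 5)
  expect_identical(p1$counts, p1b$counts)
})

test_that("a single-cluster fit warns and yields all-zero PEP", {
  sim <- sim_circle_gaussians(n = 100, n_clusters = 1, sigma = 0.3, seed = 8)
  fit <- forest_fire(sim$X, temperature = 50, K = 20, seed = 1)
  expect_equal(fit$k, 1L)
  expect_warning(post <- mc_validate(fit, trials = 50, seed = 1),
                 "one cluster")
  expect_true(all(post$pep == 0))
})

test_that("T = 1 tallies exactly one trial's acceptance set", {
  blobs <- two_blobs()
  fit <- forest_fire(blobs$X, temperature = 10, K = 10, seed = 1)
  post <- mc_validate(fit, trials = 1, seed = 9)
  expect_equal(sum(post$counts), sum(post$received))
  expect_true(all(post$received %in% c(0L, 1L)))
  r <- withr::with_seed(9, sample.int(100, 1, replace = TRUE))
  tr <- mc_trial(fit$graph, fit$labels, r, fit$temperature)
  expect_equal(which(post$counts[, tr$label] == 1L), tr$accepted)
})
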