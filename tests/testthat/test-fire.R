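test_that("average influence follows the full-cluster-size arithmetic", {
  # labeled members with affinities {0.5, 0.3} to vertex 4, temperature 2:
  # (2*0.5 + 2*0.3) / 2 = 0.8
  A <- matrix(0, 4, 4)
  A[1, 4] <- A[4, 1] <- 0.5
  A[2, 4] <- A[4, 2] <- 0.3
  A[1, 2] <- A[2, 1] <- 0.9
  g <- manual_graph(A)
  acc <- forestfire:::new_heat(4)
  acc <- forestfire:::heat_add(acc, g, c(1L, 2L), temperature = 2)
  expect_equal(forestfire:::average_influence(acc, 4L), 0.8)

  # single labeled neighbour, c = 1, A = 0.5
  acc1 <- forestfire:::new_heat(4)
  acc1 <- forestfire:::heat_add(acc1, g, 1L, temperature = 1)
  expect_equal(forestfire:::average_influence(acc1, 4L), 0.5)

  # zero-affinity members dilute: {0.9, 0, 0} at c = 1 -> 0.3
  B <- matrix(0, 4, 4)
  B[1, 4] <- B[4, 1] <- 0.9
  B[1, 2] <- B[2, 1] <- B[2, 3] <- B[3, 2] <- 0.5
  gb <- manual_graph(B)
  accb <- forestfire:::new_heat(4)
  accb <- forestfire:::heat_add(accb, gb, c(1L, 2L, 3L), temperature = 1)
  expect_equal(forestfire:::average_influence(accb, 4L), 0.3)

  expect_error(forestfire:::average_influence(forestfire:::new_heat(4), 1L),
               "empty cluster")
})

test_that("propagation reproduces hand fixed points on tiny graphs", {
  # two vertices, affinity a: seeding accepts the other iff c*a >= 1/a
  a <- 0.5
  A <- matrix(c(0, a, a, 0), 2, 2)
  g <- manual_graph(A)
  res <- propagate(g, integer(2), 1L, 1L, temperature = 1 / a^2)
  expect_equal(res$labels, c(1L, 1L))  # acceptance at exact equality
  res2 <- propagate(g, integer(2), 1L, 1L, temperature = 1 / a^2 - 1e-9)
  expect_equal(res2$labels, c(1L, 0L))

  # zero affinity between components: the label never crosses
  Z <- matrix(0, 4, 4)
  Z[1, 2] <- Z[2, 1] <- 0.8
  Z[3, 4] <- Z[4, 3] <- 0.8
  gz <- manual_graph(Z)
  rz <- propagate(gz, integer(4), 1L, 1L, temperature = 1e6)
  expect_equal(rz$labels, c(1L, 1L, 0L, 0L))

  expect_error(propagate(gz, c(2L, 0L, 0L, 0L), 1L, 1L, 5), "already labeled")
})

test_that("chain propagation matches the brute-force sweep oracle", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 0.9
  A[2, 3] <- A[3, 2] <- 0.9
  A[3, 4] <- A[4, 3] <- 0.1
  g <- manual_graph(A)
  for (cc in c(0.5, 1.5, 3, 10, 40)) {
    got <- propagate(g, integer(4), 1L, 1L, cc)$labels
    want <- oracle_propagate(A, 1 / rowSums(A), integer(4), 1L, 1L, cc)
    expect_equal(got, as.integer(want), info = paste("c =", cc))
  }
  # a temperature that reaches {1,2,3} but stops before 4:
  # vertex 4 threshold = 10; heat from {1,2,3} = c*0.1/3 < 10 for c = 40,
  # while 40*0.9 >= 1/1.8 lets the chain ignite
  r <- propagate(g, integer(4), 1L, 1L, 40)
  expect_equal(r$labels, c(1L, 1L, 1L, 0L))
})

test_that("next seed is the coldest unlabeled vertex with lowest-index ties", {
  acc <- list(heat = c(0.4, 0.1, 0.2, 0, 0), size = 1L)
  labels <- c(0L, 0L, 0L, 9L, 9L)    # candidate heats {0.4, 0.1, 0.2}
  expect_equal(forestfire:::select_next_seed(labels, acc), 2L)
  labels2 <- c(9L, 9L, 9L, 0L, 0L)   # both remaining at zero heat -> lower index
  expect_equal(forestfire:::select_next_seed(labels2, acc), 4L)
  labels3 <- c(9L, 9L, 9L, 9L, 0L)   # singleton argmin
  expect_equal(forestfire:::select_next_seed(labels3, acc), 5L)
  expect_error(forestfire:::select_next_seed(rep(1L, 5), acc), "no unlabeled")
})

test_that("fitting two separated blobs recovers the blobs exactly", {
  blobs <- two_blobs()
  fit <- forest_fire(blobs$X, temperature = 10, K = 10, seed = 1)
  expect_equal(fit$k, 2L)
  expect_equal(purity(fit$labels, blobs$truth), 1)
  expect_equal(sort(unique(fit$labels)), 1:2)
  expect_equal(fit$labels[fit$seeds], 1:2)
  expect_equal(nrow(fit$trace), 100L)
  cert <- fire_certificate(fit)
  expect_true(cert$ok)
})

test_that("vanishing temperature yields all-singleton clusters", {
  blobs <- two_blobs(n_per = 20)
  fit <- forest_fire(blobs$X, temperature = 1e-12, K = 5, seed = 1)
  expect_equal(fit$k, 40L)
  expect_equal(sort(tabulate(fit$labels)), rep(1L, 40))
})

test_that("fits are deterministic given the first seed and equivariant to row permutation", {
  blobs <- two_blobs()
  f1 <- forest_fire(blobs$X, temperature = 10, K = 10, first_seed = 7)
  f2 <- forest_fire(blobs$X, temperature = 10, K = 10, first_seed = 7)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$trace, f2$trace)

  perm <- withr::with_seed(11, sample(100))
  fp <- forest_fire(blobs$X[perm, ], temperature = 10, K = 10,
                    first_seed = match(7, perm))
  expect_identical(fp$labels, f1$labels[perm])
})

test_that("asynchronous acceptance agrees with synchronous sweeps on separated data", {
  blobs <- two_blobs()
  fs <- forest_fire(blobs$X, temperature = 10, K = 10, first_seed = 3)
  fa <- forest_fire(blobs$X, temperature = 10, K = 10, first_seed = 3,
                    async = TRUE)
  expect_identical(fs$labels, fa$labels)
})

test_that("heat trace has one entry per vertex in contiguous cluster segments", {
  blobs <- two_blobs()
  fit <- forest_fire(blobs$X, temperature = 10, K = 10, seed = 1)
  tr <- heat_trace(fit)
  expect_equal(nrow(tr), 100L)
  expect_equal(sort(tr$vertex), 1:100)
  segments <- rle(tr$cluster)$values
  expect_equal(segments, seq_len(fit$k))       # clusters are sequential
  expect_equal(sum(tr$is_seed), fit$k)
  expect_true(all(tr$avg_heat[tr$is_seed] == 0))
})

test_that("a single Gaussian labeled in one fire recovers its moments", {
  sim <- sim_circle_gaussians(n = 2000, n_clusters = 1, sigma = 0.5, seed = 9)
  fit <- forest_fire(sim$X, temperature = 100, K = 50, seed = 2)
  expect_equal(fit$k, 1L)
  mu <- colMeans(sim$X)
  se_mean <- 0.5 / sqrt(2000)
  expect_lt(max(abs(mu - c(1, 0))), 3 * se_mean)
  v <- apply(sim$X, 2, var)
  se_var <- 0.25 * sqrt(2 / 1999)
  expect_lt(max(abs(v - 0.25)), 3 * se_var)
})

test_that("temperature rejects non-positive values", {
  blobs <- two_blobs(n_per = 10)
  expect_error(forest_fire(blobs$X, temperature = 0, K = 3), "c > 0")
})
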