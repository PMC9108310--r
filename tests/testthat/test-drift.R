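test_that("expected copy number follows the exponential closed form", {
  expect_equal(expected_copies(drift_params(3, 0), c(0, 10, 1e6)),
               c(3, 3, 3))
  p <- drift_params(1, 1.1e-6)
  expect_equal(expected_copies(p, 2.4e6), exp(1.1e-6 * 2.4e6),
               tolerance = 1e-12)
  # log-derivative equals U_dup
  g <- 1e6
  num <- (log(expected_copies(p, g + 1)) - log(expected_copies(p, g)))
  expect_equal(num, p$U_dup, tolerance = 1e-9)
  expect_error(expected_copies(p, -1), "non-negative")
})

test_that("the simulator is conservative, deterministic, and flat at U_dup = 0", {
  p0 <- drift_params(2, 0)
  sim <- simulate_drift(p0, 100, replicates = 5, seed = 11)
  expect_true(all(sim$counts == 2L))
  p <- drift_params(1, 5e-3)
  s1 <- simulate_drift(p, 500, replicates = 20, seed = 3)
  s2 <- simulate_drift(p, 500, replicates = 20, seed = 3)
  expect_identical(s1$counts, s2$counts)
  # pure birth: counts never decrease along any trajectory
  expect_true(all(apply(s1$counts, 1, function(x) all(diff(x) >= 0))))
  expect_error(simulate_drift(p, 10, seed = 1, replicates = 0), ">= 1")
  expect_error(simulate_drift(drift_params(1, 0.5), 10, replicates = 1),
               "seed")
})

test_that("bernoulli and poisson generation modes agree in the mean", {
  p <- drift_params(1, 1e-3)
  mb <- mean(simulate_drift(p, 1000, 3000, seed = 5,
                            method = "bernoulli")$counts[, 51])
  mp <- mean(simulate_drift(p, 1000, 3000, seed = 6,
                            method = "poisson")$counts[, 51])
  se <- exp(1) * sqrt(exp(1) - 1) / sqrt(3000)   # Yule sd at U*t = 1
  expect_lt(abs(mb - mp), 6 * se)
})

test_that("log-slope fitting recovers exact and two-point slopes", {
  tt <- seq(0, 100, by = 10)
  traj <- data.frame(time = tt, copies = exp(0.03 * tt))
  fit <- fit_log_slope(traj)
  expect_equal(fit$slope, 0.03, tolerance = 1e-12)
  two <- fit_log_slope(copy_trajectory(c(0, 6e7), c(1, 19)))
  expect_equal(two$slope, log(19) / 6e7, tolerance = 1e-12)
  flat <- fit_log_slope(copy_trajectory(c(0, 10, 20), c(4, 4, 4)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(fit_log_slope(data.frame(time = 1, copies = 2)), "2 distinct")
})

test_that("the duplication-rate estimator converts slopes per generation", {
  expect_equal(estimate_Udup(4.6e-8, 25), 1.15e-6, tolerance = 1e-12)
  expect_equal(estimate_Udup(3.3e-7, 1), 3.3e-7)
  expect_error(estimate_Udup(-1, 25), "positive")
})

test_that("genealogies have the requested tips and pure-birth waiting times", {
  p <- drift_params(1, 1e-6)
  g1 <- simulate_genealogy(p, 1, seed = 2)
  expect_null(g1$tree)
  expect_equal(g1$birth_times, 0)
  g <- simulate_genealogy(p, 12, seed = 2)
  expect_s3_class(g$tree, "phylo")
  expect_equal(length(g$tree$tip.label), 12)
  expect_true(ape::is.ultrametric(g$tree))
  # serializable to newick and back
  nwk <- ape::write.tree(g$tree)
  expect_equal(sort(ape::read.tree(text = nwk)$tip.label),
               sort(paste0("RTG", 1:12)))
  # identical seed, identical genealogy
  g2 <- simulate_genealogy(p, 12, seed = 2)
  expect_identical(ape::write.tree(g2$tree), nwk)
  expect_error(simulate_genealogy(drift_params(1, 0), 5, seed = 1),
               "unreachable")
  # mean time to the last birth matches the sum of expected exponential waits
  n <- 8
  last <- vapply(1:60, function(i)
    utils::tail(simulate_genealogy(p, n, seed = 100 + i)$birth_times, 1),
    numeric(1))
  expected <- sum(1 / ((1:(n - 1)) * p$U_dup))
  sd_theory <- sqrt(sum(1 / ((1:(n - 1)) * p$U_dup)^2))
  expect_lt(abs(mean(last) - expected), 3 * sd_theory / sqrt(60))
})

test_that("trajectory TSV round-trips with its time unit", {
  tr <- copy_trajectory(c(0, 1e6, 2e6), c(1, 3, 9), unit = "generations")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$time, tr$time)
  expect_equal(back$copies, tr$copies)
  expect_identical(attr(back, "unit"), "generations")
  expect_error(copy_trajectory(c(0, 0), c(1, 2)), "strictly increasing")
})
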