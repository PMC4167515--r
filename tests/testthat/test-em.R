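# Mixture likelihood, E-step, M-step, and the EM driver

test_that("mixture log-likelihood has the closed value for a degenerate fixture", {
  d <- paired_counts(c("a", "b", "c"), c(3, 5, 0), c(3, 5, 0))  # all z = 0
  m <- skmix_model(1, 1, 1)
  expect_equal(skmix_loglik(d, m), 3 * log(0.30850832), tolerance = 1e-6)
})

test_that("duplicating every gene doubles the log-likelihood", {
  d <- tiny_counts(25)
  m <- skmix_model(c(0.4, 0.6), c(10, 3), c(5, 9))
  d2 <- paired_counts(c(d$gene_id, paste0(d$gene_id, "_dup")),
                      c(d$x, d$x), c(d$y, d$y))
  expect_equal(skmix_loglik(d2, m), 2 * skmix_loglik(d, m))
})

test_that("log-likelihood is invariant under component relabelling", {
  d <- tiny_counts(30)
  m1 <- skmix_model(c(0.3, 0.7), c(10, 2), c(4, 9))
  m2 <- skmix_model(c(0.7, 0.3), c(2, 10), c(9, 4))
  expect_equal(skmix_loglik(d, m1), skmix_loglik(d, m2))
})

test_that("posterior equals the prior when components are identical", {
  d <- tiny_counts(15)
  m <- skmix_model(c(0.3, 0.7), c(6, 6), c(4, 4))
  es <- skmix_estep(d, m)
  expect_equal(unname(es$posterior),
               matrix(c(0.3, 0.7), 15, 2, byrow = TRUE))
})

test_that("posterior is 1 for a single component and rows always sum to 1", {
  d <- tiny_counts(12)
  expect_equal(unname(skmix_estep(d, skmix_model(1, 5, 5))$posterior),
               matrix(1, 12, 1))
  m <- skmix_model(c(0.2, 0.5, 0.3), c(30, 15, 60), c(25, 45, 8))
  es <- skmix_estep(d, m)
  expect_lt(max(abs(rowSums(es$posterior) - 1)), 1e-10)
  expect_true(all(es$posterior >= 0 & es$posterior <= 1))
})

test_that("log-space posterior equals the direct density ratio", {
  d <- tiny_counts(50, theta1 = 20, theta2 = 10)
  m <- skmix_model(c(0.25, 0.75), c(25, 8), c(10, 14))
  es <- skmix_estep(d, m)
  f1 <- dskellam(d$z, 25, 10); f2 <- dskellam(d$z, 8, 14)
  direct <- cbind(0.25 * f1, 0.75 * f2) / (0.25 * f1 + 0.75 * f2)
  expect_lt(max(abs(es$posterior - direct)), 1e-12)
})

test_that("far-outlying genes keep a valid posterior row (log-space rescue)", {
  d <- paired_counts(c("g1", "g2"), c(500, 2), c(0, 3))
  m <- skmix_model(c(0.5, 0.5), c(3, 2), c(3, 4))
  es <- skmix_estep(d, m)
  expect_lt(max(abs(rowSums(es$posterior) - 1)), 1e-10)
  expect_true(all(is.finite(es$posterior)))
})

test_that("one-step M-step reproduces the latent conditional mean at z = 0", {
  d <- paired_counts(c("a", "b"), c(4, 1), c(4, 1))  # both z = 0
  m <- skmix_model(1, 1, 1)
  es <- skmix_estep(d, m)
  up <- skmix_mstep(d, es$posterior, es$ex, es$ey)
  expect_equal(up$theta1, 0.6977747, tolerance = 1e-6)
  expect_equal(up$theta2, 0.6977747, tolerance = 1e-6)
})

test_that("M-step difference equals the responsibility-weighted mean of z", {
  d <- tiny_counts(40, theta1 = 25, theta2 = 10)
  m <- skmix_model(c(0.5, 0.5), c(20, 5), c(8, 12))
  es <- skmix_estep(d, m)
  up <- skmix_mstep(d, es$posterior, es$ex, es$ey)
  for (j in 1:2) {
    wz <- sum(es$posterior[, j] * d$z) / sum(es$posterior[, j])
    expect_equal(up$theta1[j] - up$theta2[j], wz, tolerance = 1e-8)
  }
})

test_that("uniform responsibilities give identical component updates", {
  d <- tiny_counts(30)
  post <- matrix(0.5, 30, 2)
  m <- skmix_model(c(0.5, 0.5), c(9, 9), c(5, 5))
  es <- skmix_estep(d, m)   # identical components: latents equal across j
  up <- skmix_mstep(d, post, es$ex, es$ey)
  expect_equal(up$theta1[1], up$theta1[2])
  expect_equal(up$theta2[1], up$theta2[2])
})

test_that("EM log-likelihood trace is non-decreasing on varied fixtures", {
  for (seed in 1:4) {
    sim <- skmix_simulate(skmix_sim_spec(pi = c(0.6, 0.4),
                                         theta1 = c(20, 4), theta2 = c(6, 18),
                                         n_genes = 300, seed = seed))
    fit <- skmix_fit(sim$counts, 2, n_restarts = 4, seed = seed)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
    expect_gte(fit$loglik, fit$loglik_trace[1])
  }
})

test_that("EM attains the exhaustive-grid likelihood on tiny fixtures", {
  d1 <- tiny_counts(20, theta1 = 8, theta2 = 3)
  fit1 <- skmix_fit(d1, 1)
  g1 <- grid_best_loglik(d1$z, 1, seq(0.5, 20, by = 0.25))
  expect_gte(fit1$loglik, g1 - 1e-4)

  withr::with_seed(11, {
    z2 <- c(rpois(15, 12) - rpois(15, 2), rpois(15, 2) - rpois(15, 12))
    d2 <- paired_counts(sprintf("g%02d", 1:30), pmax(z2, 0), pmax(-z2, 0))
  })
  fit2 <- skmix_fit(d2, 2, seed = 3)
  g2 <- grid_best_loglik(d2$z, 2, c(0.5, 1, 2, 4, 8, 12, 16))
  expect_gte(fit2$loglik, g2 - 1e-4)
})

test_that("fits are deterministic given the seed", {
  sim <- skmix_simulate(bench_spec(n_genes = 400, seed = 8))
  f1 <- skmix_fit(sim$counts, 3, seed = 21)
  f2 <- skmix_fit(sim$counts, 3, seed = 21)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("components are reported in canonical order with matching assignments", {
  sim <- skmix_simulate(bench_spec(n_genes = 600, seed = 2))
  fit <- skmix_fit(sim$counts, 3, seed = 2)
  dd <- fit$model$theta1 - fit$model$theta2
  expect_true(all(diff(dd) <= 1e-12))
  expect_identical(fit$assignments,
                   max.col(fit$posterior, ties.method = "first"))
})

test_that("single-Skellam fit recovers the truth within sampling error", {
  sim <- skmix_simulate(skmix_sim_spec(pi = 1, theta1 = 30, theta2 = 25,
                                       n_genes = 2000, seed = 77))
  fit <- skmix_fit(sim$counts, 1)
  # SEs from the observed information of the Skellam at (30, 25), n = 2000:
  # the difference is pinned to mean(z) (SE ~ sqrt(55/2000) ~ 0.17), the sum
  # is much weaker; 3 SEs with a generous sum SE of 3.5
  expect_lt(abs((fit$model$theta1 - fit$model$theta2) - 5), 3 * 0.166)
  expect_lt(abs((fit$model$theta1 + fit$model$theta2) - 55), 3 * 3.5)
})

test_that("initialisation applies the moment equations", {
  # z with mean 5, variance 55 -> theta ~ (30, 25)
  withr::with_seed(5, {
    x <- rpois(4000, 30); y <- rpois(4000, 25)
  })
  d <- paired_counts(sprintf("g%04d", 1:4000), x, y)
  m0 <- skmix_init(d, 1)
  mz <- mean(d$z); vz <- var(d$z)
  expect_equal(m0$theta1, (vz + mz) / 2, tolerance = 1e-6)
  expect_equal(m0$theta2, (vz - mz) / 2, tolerance = 1e-6)
  expect_equal(m0$theta1 - m0$theta2, mz, tolerance = 1e-6)
})

test_that("initialisation separates well-separated z clusters and is seed-stable", {
  withr::with_seed(9, {
    z <- c(rnorm(50, -30, 3), rnorm(50, 52, 3))
    z <- round(z)
  })
  d <- paired_counts(sprintf("g%03d", 1:100), pmax(z, 0), pmax(-z, 0))
  m0 <- skmix_init(d, 2, seed = 4)
  expect_identical(m0, skmix_init(d, 2, seed = 4))
  dd <- m0$theta1 - m0$theta2
  expect_equal(sort(round(dd, -1)), c(-30, 50), tolerance = 0.4)
})

test_that("n < J is rejected", {
  d <- tiny_counts(3)
  expect_error(skmix_fit(d, 5), "1 <= J")
})
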