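# Constrained refits and the three nested likelihood-ratio tests

test_that("constrained log-likelihood never exceeds the unconstrained one", {
  sim <- skmix_simulate(bench_spec(n_genes = 500, seed = 41))
  fit <- skmix_fit(sim$counts, 3, seed = 41)
  for (con in list(list(kind = "theta_eq", j = 1),
                   list(kind = "diff_fixed", j = 2, c = -10),
                   list(kind = "diff_eq", j = 1, l = 3))) {
    h0 <- skmix_fit_constrained(sim$counts, fit, con)
    expect_lte(h0$loglik, fit$loglik + 1e-6)
  }
})

test_that("constraint at the H1 optimum gives LR ~ 0", {
  sim <- skmix_simulate(skmix_sim_spec(pi = 1, theta1 = 30, theta2 = 25,
                                       n_genes = 600, seed = 17))
  fit <- skmix_fit(sim$counts, 1)
  c_hat <- fit$model$theta1 - fit$model$theta2
  tst <- skmix_test_consistency(sim$counts, fit, 1, c_hat)
  expect_lt(tst$lr, 1e-6)
  expect_gte(tst$lr, 0)
})

test_that("plasticity constraint is inactive when the group mean of z is zero", {
  # symmetric fixture: z values mirror-imaged so mean(z) = 0 exactly
  z <- c(-5, -3, -1, 0, 0, 1, 3, 5)
  d <- paired_counts(sprintf("g%d", 1:8), pmax(z, 0), pmax(-z, 0))
  fit <- skmix_fit(d, 1)
  tst <- skmix_test_plasticity(d, fit, 1)
  expect_lt(tst$lr, 1e-6)
})

test_that("symmetric-Skellam constrained fit matches a 1-D grid search", {
  d <- tiny_counts(20, theta1 = 9, theta2 = 9, seed = 5)
  fit <- skmix_fit(d, 1)
  h0 <- skmix_fit_constrained(d, fit, list(kind = "theta_eq", j = 1))
  grid <- seq(0.05, 100, by = 0.05)
  ll_grid <- vapply(grid, function(t) sum(dskellam(d$z, t, t, log = TRUE)),
                    numeric(1))
  expect_equal(h0$loglik, max(ll_grid), tolerance = 1e-3)
  expect_equal(h0$model$theta1, h0$model$theta2)
})

test_that("plasticity LR is invariant to swapping the treatment columns", {
  sim <- skmix_simulate(skmix_sim_spec(pi = 1, theta1 = 14, theta2 = 9,
                                       n_genes = 400, seed = 23))
  d <- sim$counts
  d_swap <- paired_counts(d$gene_id, d$y, d$x)
  f1 <- skmix_fit(d, 1); f2 <- skmix_fit(d_swap, 1)
  t1 <- skmix_test_plasticity(d, f1, 1)
  t2 <- skmix_test_plasticity(d_swap, f2, 1)
  expect_equal(t1$lr, t2$lr, tolerance = 1e-6)
})

test_that("interaction test is symmetric in its group pair", {
  sim <- skmix_simulate(bench_spec(n_genes = 600, seed = 29))
  fit <- skmix_fit(sim$counts, 3, seed = 29)
  t_jl <- skmix_test_interaction(sim$counts, fit, 1, 3)
  t_lj <- skmix_test_interaction(sim$counts, fit, 3, 1)
  expect_identical(t_jl$lr, t_lj$lr)
  expect_identical(t_jl$p_value, t_lj$p_value)
})

test_that("a strongly plastic group is detected with overwhelming evidence", {
  sim <- skmix_simulate(skmix_sim_spec(pi = 1, theta1 = 60, theta2 = 8,
                                       n_genes = 2000, seed = 57))
  fit <- skmix_fit(sim$counts, 1)
  tst <- skmix_test_plasticity(sim$counts, fit, 1)
  expect_lt(tst$p_value, 1e-6)
})

test_that("interaction between clearly different groups is detected", {
  sim <- skmix_simulate(skmix_sim_spec(pi = c(0.4, 0.6),
                                       theta1 = c(30, 15), theta2 = c(25, 45),
                                       n_genes = 2000, seed = 61))
  fit <- skmix_fit(sim$counts, 2, seed = 61)
  tst <- skmix_test_interaction(sim$counts, fit, 1, 2)
  expect_lt(tst$p_value, 1e-6)
})

test_that("consistency test at c = 0 is identical to the plasticity test", {
  sim <- skmix_simulate(skmix_sim_spec(pi = 1, theta1 = 10, theta2 = 8,
                                       n_genes = 300, seed = 3))
  fit <- skmix_fit(sim$counts, 1)
  tp <- skmix_test_plasticity(sim$counts, fit, 1)
  tc <- skmix_test_consistency(sim$counts, fit, 1, 0)
  expect_identical(tc$lr, tp$lr)
  expect_identical(tc$p_value, tp$p_value)
})

test_that("consistency test rejects a far-off environmental difference", {
  sim <- skmix_simulate(skmix_sim_spec(pi = 1, theta1 = 30, theta2 = 25,
                                       n_genes = 2000, seed = 19))
  fit <- skmix_fit(sim$counts, 1)
  tst <- skmix_test_consistency(sim$counts, fit, 1, c = 10)  # truth is 5
  expect_lt(tst$p_value, 1e-4)
})

test_that("LR is invariant to gene order", {
  sim <- skmix_simulate(skmix_sim_spec(pi = 1, theta1 = 12, theta2 = 9,
                                       n_genes = 300, seed = 37))
  d <- sim$counts
  perm <- withr::with_seed(1, sample.int(nrow(d)))
  d_perm <- paired_counts(d$gene_id[perm], d$x[perm], d$y[perm])
  f1 <- skmix_fit(d, 1); f2 <- skmix_fit(d_perm, 1)
  expect_equal(skmix_test_plasticity(d, f1, 1)$lr,
               skmix_test_plasticity(d_perm, f2, 1)$lr, tolerance = 1e-8)
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_identical(adjust_fdr(numeric(0)), numeric(0))
  withr::with_seed(8, {
    for (i in 1:100) {
      p <- runif(sample(1:40, 1))
      adj <- adjust_fdr(p)
      expect_equal(adj, bh_stepup(p))
      expect_true(all(adj >= p))
      expect_identical(order(adj[order(p)]), seq_along(p))  # monotone in p
    }
  })
})

test_that("the full test battery returns a well-formed FDR-adjusted table", {
  sim <- skmix_simulate(bench_spec(n_genes = 500, seed = 73))
  fit <- skmix_fit(sim$counts, 3, seed = 73)
  tab <- skmix_test_all(sim$counts, fit, c = 5)
  expect_identical(nrow(tab), 3L + 2L + 3L)
  expect_true(all(tab$lr >= 0))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$fdr >= tab$p_value - 1e-12))
})
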