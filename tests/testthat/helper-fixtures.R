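# Shared fixtures, all built in code.

# the three-group benchmark generator used across tests
bench_spec <- function(n_genes = 2000L, seed = 1L) {
  skmix_sim_spec(pi = c(0.2, 0.5, 0.3), theta1 = c(30, 15, 60),
                 theta2 = c(25, 45, 8), n_genes = n_genes, seed = seed)
}

# small deterministic paired-count fixture with a known z spread
tiny_counts <- function(n = 20, theta1 = 12, theta2 = 7, seed = 99) {
  withr::with_seed(seed, {
    paired_counts(sprintf("g%02d", 1:n), rpois(n, theta1), rpois(n, theta2))
  })
}

# direct-summation conditional mean E[X | Z = z]: independent of the
# Bessel-ratio implementation
cond_mean_direct <- function(z, theta1, theta2, kmax = 400) {
  x <- max(0, z):(max(theta1, theta1 + z) + kmax)
  px <- dpois(x, theta1) * dpois(x - z, theta2)
  sum(x * px) / sum(px)
}

# naive Benjamini-Hochberg step-up, written independently of p.adjust
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# exhaustive-grid maximum log-likelihood for tiny Skellam mixtures
grid_best_loglik <- function(z, J, theta_grid, pi_grid = NULL) {
  best <- -Inf
  if (J == 1) {
    for (t1 in theta_grid) for (t2 in theta_grid) {
      ll <- sum(dskellam(z, t1, t2, log = TRUE))
      if (ll > best) best <- ll
    }
  } else if (J == 2) {
    if (is.null(pi_grid)) pi_grid <- seq(0.1, 0.9, by = 0.1)
    cmb <- expand.grid(a1 = theta_grid, a2 = theta_grid,
                       b1 = theta_grid, b2 = theta_grid)
    for (i in seq_len(nrow(cmb))) {
      la <- dskellam(z, cmb$a1[i], cmb$a2[i], log = TRUE)
      lb <- dskellam(z, cmb$b1[i], cmb$b2[i], log = TRUE)
      for (p in pi_grid) {
        ll <- sum(log(p * exp(la) + (1 - p) * exp(lb)))
        if (ll > best) best <- ll
      }
    }
  }
  best
}
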