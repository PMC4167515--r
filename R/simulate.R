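#' Specification of a synthetic paired-count dataset
#'
#' Describes a J-component mixture generator: gene i draws its group from
#' Categorical(pi), then its counts in the two treatments independently
#' from Poisson(theta1[j]) and Poisson(theta2[j]).  The default is the
#' three-group benchmark scenario used throughout the package's
#' recovery studies: n = 2000 genes, pi = (0.2, 0.5, 0.3), means
#' (30, 25), (15, 45), (60, 8).
#'
#' @param pi mixing proportions (sum to 1).
#' @param theta1,theta2 per-group Poisson means for the two treatments.
#' @param n_genes number of genes to simulate.
#' @param seed integer seed.
#' @return object of class `skmix_sim_spec`.
#' @export
skmix_sim_spec <- function(pi = c(0.2, 0.5, 0.3),
                           theta1 = c(30, 15, 60),
                           theta2 = c(25, 45, 8),
                           n_genes = 2000L, seed = 1L) {
  J <- length(pi)
  stopifnot(length(theta1) == J, length(theta2) == J,
            abs(sum(pi) - 1) < 1e-8, all(pi > 0),
            all(theta1 > 0), all(theta2 > 0), n_genes >= 1)
  structure(list(J = J, pi = pi, theta1 = theta1, theta2 = theta2,
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "skmix_sim_spec")
}

#' Simulate a paired count dataset from a mixture specification
#'
#' @param spec a [skmix_sim_spec()].
#' @return list with `counts` (a [paired_counts()] object) and `labels`
#'   (true group index per gene).  Deterministic given `spec$seed`.
#' @export
skmix_simulate <- function(spec) {
  stopifnot(inherits(spec, "skmix_sim_spec"))
  withr::with_seed(spec$seed, {
    lab <- sample.int(spec$J, spec$n_genes, replace = TRUE, prob = spec$pi)
    x <- stats::rpois(spec$n_genes, spec$theta1[lab])
    y <- stats::rpois(spec$n_genes, spec$theta2[lab])
  })
  list(counts = paired_counts(sprintf("gene%05d", seq_len(spec$n_genes)), x, y),
       labels = lab)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between hard cluster assignments and a
#' reference labelling, computed from the contingency table; 1 if and only
#' if the partitions coincide up to relabelling, near 0 for independent
#' partitions, possibly negative for worse-than-chance agreement.
#'
#' @param a,b integer label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  tab <- table(a, b)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.numeric(tab))
  sum_a <- ch2(as.numeric(rowSums(tab)))
  sum_b <- ch2(as.numeric(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxidx - expected)
}

# greedy one-to-one matching of fitted components to true components by
# nearest difference theta1 - theta2 (label switching across replicates)
.align_components <- function(fit_model, true_d) {
  J <- length(true_d)
  fit_d <- fit_model$theta1 - fit_model$theta2
  perm <- integer(J)           # perm[true j] = fitted component
  cost <- abs(outer(true_d, fit_d, "-"))
  for (k in seq_len(J)) {
    idx <- which(cost == min(cost), arr.ind = TRUE)[1, ]
    perm[idx[1]] <- idx[2]
    cost[idx[1], ] <- Inf
    cost[, idx[2]] <- Inf
  }
  perm
}

#' Parameter-recovery study over simulation replicates
#'
#' Repeatedly simulates from `spec`, fits the mixture at the true J, aligns
#' fitted components to the truth by nearest theta1 - theta2 (greedy
#' one-to-one), and summarises the sampling distribution of the MLEs:
#' per-parameter mean, per-replicate mean squared error against the truth,
#' standard error of the replicate mean, and the mean adjusted Rand index
#' of the hard assignments against the true labels.
#'
#' @param spec a [skmix_sim_spec()].
#' @param n_replicates number of simulation replicates (>= 2).
#' @param seed integer master seed; replicate r is simulated with seed
#'   `seed + r`.
#' @param ... EM settings forwarded to [skmix_fit()].
#' @return list of class `skmix_recovery`: `estimates` (replicates x
#'   parameters matrix), `summary` (data frame: parameter, truth, mean,
#'   mse, se_mean), `ari` (per replicate), `mean_ari`, `n_dropped`.
#' @export
skmix_recovery <- function(spec, n_replicates = 100L, seed = 1L, ...) {
  stopifnot(inherits(spec, "skmix_sim_spec"), n_replicates >= 2)
  J <- spec$J
  true_d <- spec$theta1 - spec$theta2
  par_names <- c(sprintf("pi%d", 1:J), sprintf("theta%d1", 1:J),
                 sprintf("theta%d2", 1:J))
  truth <- c(spec$pi, spec$theta1, spec$theta2)
  est <- matrix(NA_real_, n_replicates, 3 * J,
                dimnames = list(NULL, par_names))
  ari <- rep(NA_real_, n_replicates)
  dropped <- 0L
  for (r in seq_len(n_replicates)) {
    rspec <- spec
    rspec$seed <- as.integer(seed) + r
    sim <- skmix_simulate(rspec)
    fit <- try(skmix_fit(sim$counts, J, seed = as.integer(seed) + r, ...),
               silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged || fit$degenerate) {
      dropped <- dropped + 1L
      next
    }
    perm <- .align_components(fit$model, true_d)
    est[r, ] <- c(fit$model$pi[perm], fit$model$theta1[perm],
                  fit$model$theta2[perm])
    ari[r] <- adjusted_rand_index(match(fit$assignments, perm), sim$labels)
  }
  keep <- !is.na(est[, 1])
  est_k <- est[keep, , drop = FALSE]
  summ <- data.frame(
    parameter = par_names,
    truth = truth,
    mean = colMeans(est_k),
    mse = colMeans((est_k - matrix(truth, nrow(est_k), 3 * J,
                                   byrow = TRUE))^2),
    se_mean = apply(est_k, 2, stats::sd) / sqrt(nrow(est_k))
  )
  structure(list(estimates = est_k, summary = summ,
                 ari = ari[keep], mean_ari = mean(ari[keep]),
                 n_replicates = nrow(est_k), n_dropped = dropped),
            class = "skmix_recovery")
}

#' @export
print.skmix_recovery <- function(x, ...) {
  cat(sprintf("Recovery study: %d replicates (%d dropped), mean ARI %.3f\n",
              x$n_replicates, x$n_dropped, x$mean_ari))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
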