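#' Bootstrap standard errors for mixture parameters
#'
#' Nonparametric bootstrap over genes: each replicate resamples genes with
#' replacement, refits the mixture starting from the point estimate, and
#' aligns its components to the original fit by nearest theta1 - theta2
#' (greedy one-to-one, resolving label switching).  Standard errors are
#' the standard deviations of the aligned replicate estimates.
#'
#' @param data a [paired_counts()] object.
#' @param fit the point-estimate [skmix_fit()].
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param ... EM settings forwarded to the replicate refits.
#' @return list with `se` (data frame: group, se_pi, se_theta1,
#'   se_theta2), `replicates` (B x 3J matrix, NA rows dropped) and
#'   `n_dropped` non-convergent replicates.
#' @export
skmix_boot_se <- function(data, fit, B = 200L, seed = 1L, ...) {
  stopifnot(inherits(data, "paired_counts"), inherits(fit, "skmix_fit"),
            B >= 2)
  J <- fit$J
  ref_d <- fit$model$theta1 - fit$model$theta2
  est <- matrix(NA_real_, B, 3 * J)
  n <- nrow(data)
  idx_mat <- withr::with_seed(as.integer(seed), {
    matrix(sample.int(n, n * B, replace = TRUE), n, B)
  })
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- idx_mat[, b]
    boot <- paired_counts(sprintf("b%06d", seq_len(n)),
                          data$x[idx], data$y[idx])
    bf <- try(skmix_fit(boot, J, init = fit$model, ...), silent = TRUE)
    if (inherits(bf, "try-error") || !bf$converged) {
      dropped <- dropped + 1L
      next
    }
    perm <- .align_components(bf$model, ref_d)
    est[b, ] <- c(bf$model$pi[perm], bf$model$theta1[perm],
                  bf$model$theta2[perm])
  }
  keep <- !is.na(est[, 1])
  se_all <- apply(est[keep, , drop = FALSE], 2, stats::sd)
  list(se = data.frame(group = seq_len(J),
                       se_pi = se_all[1:J],
                       se_theta1 = se_all[J + 1:J],
                       se_theta2 = se_all[2 * J + 1:J]),
       replicates = est[keep, , drop = FALSE],
       n_dropped = dropped)
}
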