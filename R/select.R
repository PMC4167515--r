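#' Bayesian information criterion for a fitted mixture
#'
#' BIC = -2 log L + J log(n) (natural logs).  The default penalty counts
#' one parameter per group; the alternative `penalty = "full"` counts all
#' 3J - 1 free parameters (J - 1 proportions plus two Poisson means per
#' group) and is provided for sensitivity analysis, never as the default.
#'
#' @param loglik maximised log-likelihood.
#' @param J number of components.
#' @param n number of genes.
#' @param penalty `"groups"` (default, J log n) or `"full"` ((3J - 1) log n).
#' @return scalar BIC; lower is better.
#' @export
skmix_bic <- function(loglik, J, n, penalty = c("groups", "full")) {
  penalty <- match.arg(penalty)
  stopifnot(n >= 1, J >= 1)
  k <- if (penalty == "groups") J else 3 * J - 1
  -2 * loglik + k * log(n)
}

#' Choose the number of groups by BIC
#'
#' Fits the mixture for each J in `J_range` with [skmix_fit()] and returns
#' the J minimising BIC among converged, non-degenerate fits (ties go to
#' the smaller J).
#'
#' @param data a [paired_counts()] object.
#' @param J_range integer vector of candidate numbers of groups.
#' @param penalty BIC penalty variant, see [skmix_bic()].
#' @param seed integer seed (each J uses a seed derived from it).
#' @param ... EM settings forwarded to [skmix_fit()] (`tol`, `max_iter`,
#'   `n_restarts`).
#' @return list with `best_J`, `table` (data frame: J, loglik, bic,
#'   converged, degenerate) and `fits` (one `skmix_fit` per J).
#' @export
skmix_select <- function(data, J_range, penalty = c("groups", "full"),
                         seed = 1L, ...) {
  penalty <- match.arg(penalty)
  J_range <- sort(unique(as.integer(J_range)))
  if (any(J_range < 1) || any(J_range > nrow(data))) {
    stop("J_range must lie within [1, number of genes]", call. = FALSE)
  }
  fits <- vector("list", length(J_range))
  tab <- data.frame(J = J_range, loglik = NA_real_, bic = NA_real_,
                    converged = FALSE, degenerate = FALSE)
  for (k in seq_along(J_range)) {
    f <- skmix_fit(data, J_range[k], seed = seed, ...)
    f$bic <- skmix_bic(f$loglik, J_range[k], f$n, penalty = penalty)
    fits[[k]] <- f
    tab$loglik[k] <- f$loglik
    tab$bic[k] <- f$bic
    tab$converged[k] <- f$converged
    tab$degenerate[k] <- f$degenerate
  }
  ok <- tab$converged & !tab$degenerate
  if (!any(ok)) {
    stop_obj <- simpleError("no converged non-degenerate fit in J_range")
    stop_obj$table <- tab
    stop(stop_obj)
  }
  cand <- which(ok)
  best <- cand[which.min(tab$bic[cand])]   # which.min takes the first: smaller J on ties
  list(best_J = J_range[best], table = tab, fits = fits,
       best_fit = fits[[best]])
}
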