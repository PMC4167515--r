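#' Refit the mixture under an equality constraint (null hypothesis)
#'
#' Maximises the mixture likelihood subject to one of the nested
#' constraints used by the group-level tests, with all other parameters
#' (including responsibilities) free:
#' \describe{
#'   \item{`theta_eq`}{theta_j1 = theta_j2 (no plastic response in group j)}
#'   \item{`diff_eq`}{theta_j1 - theta_j2 = theta_l1 - theta_l2 (groups j
#'     and l respond equally)}
#'   \item{`diff_fixed`}{theta_j1 - theta_j2 = c (response equals a stated
#'     environmental difference c, on the count-difference scale)}
#' }
#' The constrained M-step solves the weighted complete-data score under
#' the linear constraint in closed form (a quadratic in the free mean; for
#' `diff_eq` a one-dimensional concave profile search over the common
#' difference), so EM monotonicity is preserved.
#'
#' @param data a [paired_counts()] object.
#' @param fit the unconstrained [skmix_fit()] (the alternative H1), used as
#'   the starting point.
#' @param constraint list with `kind` one of `"theta_eq"`, `"diff_eq"`,
#'   `"diff_fixed"`, component index `j`, and `l` or `c` as required.
#' @param ... EM settings forwarded to [skmix_fit()].
#' @return a `skmix_fit` whose log-likelihood is at most `fit$loglik`.
#' @export
skmix_fit_constrained <- function(data, fit, constraint, ...) {
  stopifnot(inherits(fit, "skmix_fit"))
  kind <- constraint$kind
  J <- fit$J
  j <- constraint$j
  if (is.null(j) || j < 1 || j > J) stop("invalid group index j", call. = FALSE)
  if (kind == "diff_eq") {
    l <- constraint$l
    if (is.null(l) || l < 1 || l > J || l == j) {
      stop("invalid group index l", call. = FALSE)
    }
    # symmetric constraint: canonicalise the pair so test(j,l) == test(l,j)
    constraint$j <- min(j, l); constraint$l <- max(j, l)
  }
  if (kind == "diff_fixed") {
    if (!is.finite(constraint$c)) stop("c must be finite", call. = FALSE)
  }
  skmix_fit(data, J, init = fit$model, constraint = constraint, ...)
}

.lr_test <- function(data, fit, constraint, test_kind, target, c = NA_real_,
                     ...) {
  h0 <- skmix_fit_constrained(data, fit, constraint, ...)
  ll1 <- fit$loglik
  lr <- 2 * (ll1 - h0$loglik)
  if (lr < 0) {
    # EM local maximum under H1: restart H1 from the H0 solution, which is
    # feasible for H1, and keep the better likelihood
    refit <- skmix_fit(data, fit$J, init = h0$model, ...)
    ll1 <- max(ll1, refit$loglik)
    lr <- max(2 * (ll1 - h0$loglik), 0)
  }
  structure(list(
    test_kind = test_kind, target = target, c = c,
    lr = lr, df = 1L,
    p_value = stats::pchisq(lr, df = 1L, lower.tail = FALSE),
    loglik_h1 = ll1, loglik_h0 = h0$loglik, fit_h0 = h0
  ), class = "skmix_test")
}

#' @export
print.skmix_test <- function(x, ...) {
  cat(sprintf("%s test, group(s) %s%s: LR = %.4f (df = %d), p = %.4g\n",
              x$test_kind, paste(x$target, collapse = " vs "),
              if (is.finite(x$c)) sprintf(", c = %g", x$c) else "",
              x$lr, x$df, x$p_value))
  invisible(x)
}

#' Test whether a group's genes respond to the environment
#'
#' Likelihood-ratio test of H0: theta_j1 = theta_j2 against the
#' unconstrained alternative; 2 (logL1 - logL0) is referred to
#' chi-square(1).  Rejection means group j is differentially expressed
#' between treatments and can serve as a predictor of environment-induced
#' change.
#'
#' @param data a [paired_counts()] object.
#' @param fit unconstrained [skmix_fit()].
#' @param j group index.
#' @param ... EM settings forwarded to the constrained refit.
#' @return a `skmix_test` object (`lr`, `df`, `p_value`).
#' @export
skmix_test_plasticity <- function(data, fit, j, ...) {
  .lr_test(data, fit, list(kind = "theta_eq", j = j),
           "plasticity", j, ...)
}

#' Test whether two groups interact with the environment differently
#'
#' Likelihood-ratio test of H0: theta_j1 - theta_j2 = theta_l1 - theta_l2.
#' Rejection means groups j and l show significant interaction effects on
#' expression change between treatments.
#'
#' @inheritParams skmix_test_plasticity
#' @param l second group index, `l != j`.
#' @return a `skmix_test` object.
#' @export
skmix_test_interaction <- function(data, fit, j, l, ...) {
  .lr_test(data, fit, list(kind = "diff_eq", j = j, l = l),
           "interaction", sort(c(j, l)), ...)
}

#' Test whether a group's response matches a stated environmental difference
#'
#' Likelihood-ratio test of H0: theta_j1 - theta_j2 = c, where c is the
#' difference between the environmental signals on the count-difference
#' scale.  Non-rejection is read as the group's expression change being
#' consistent with the stated environmental change.  With c = 0 the test
#' reduces exactly to [skmix_test_plasticity()].
#'
#' @inheritParams skmix_test_plasticity
#' @param c hypothesised count-difference, finite real.
#' @return a `skmix_test` object.
#' @export
skmix_test_consistency <- function(data, fit, j, c, ...) {
  if (identical(c, 0) || identical(c, 0L)) {
    out <- skmix_test_plasticity(data, fit, j, ...)
    out$test_kind <- "consistency"
    out$c <- 0
    return(out)
  }
  .lr_test(data, fit, list(kind = "diff_fixed", j = j, c = c),
           "consistency", j, c = c, ...)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values for a family of group-level tests; a thin
#' wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Run the standard battery of group-level tests on a fitted mixture
#'
#' Plasticity for every group, interaction for consecutive group pairs
#' (mirroring the usual reporting layout), and optionally consistency at a
#' stated environmental difference c for every group; FDR-adjusted within
#' each family.
#'
#' @param data a [paired_counts()] object.
#' @param fit unconstrained [skmix_fit()].
#' @param c optional environmental difference for the consistency tests.
#' @param ... EM settings forwarded to the constrained refits.
#' @return data frame with columns test, group, group2, c, lr, df,
#'   p_value, fdr.
#' @export
skmix_test_all <- function(data, fit, c = NULL, ...) {
  J <- fit$J
  rows <- list()
  add <- function(tst, group, group2 = NA_integer_) {
    data.frame(test = tst$test_kind, group = group, group2 = group2,
               c = tst$c, lr = tst$lr, df = tst$df, p_value = tst$p_value,
               fdr = NA_real_)
  }
  for (j in seq_len(J)) {
    rows[[length(rows) + 1L]] <- add(skmix_test_plasticity(data, fit, j, ...), j)
  }
  if (J > 1) {
    for (j in seq_len(J - 1)) {
      rows[[length(rows) + 1L]] <-
        add(skmix_test_interaction(data, fit, j, j + 1, ...), j, j + 1L)
    }
  }
  if (!is.null(c)) {
    for (j in seq_len(J)) {
      rows[[length(rows) + 1L]] <-
        add(skmix_test_consistency(data, fit, j, c, ...), j)
    }
  }
  out <- do.call(rbind, rows)
  for (kind in unique(out$test)) {
    sel <- out$test == kind
    out$fdr[sel] <- adjust_fdr(out$p_value[sel])
  }
  out
}
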