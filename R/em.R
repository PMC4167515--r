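#' Skellam mixture model object
#'
#' A J-component mixture in which the count difference of a gene in group j
#' follows a Skellam distribution with treatment means `theta1[j]` and
#' `theta2[j]`, and `pi[j]` is the prior probability of group j.
#'
#' @param pi mixing proportions, positive, summing to 1.
#' @param theta1,theta2 per-component positive Poisson means.
#' @return object of class `skmix_model`.
#' @export
skmix_model <- function(pi, theta1, theta2) {
  J <- length(pi)
  if (length(theta1) != J || length(theta2) != J) {
    stop("pi, theta1, theta2 must have equal length", call. = FALSE)
  }
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be positive and sum to 1", call. = FALSE)
  }
  theta1 <- pmax(theta1, .THETA_FLOOR)
  theta2 <- pmax(theta2, .THETA_FLOOR)
  structure(list(J = J, pi = pi / sum(pi), theta1 = theta1, theta2 = theta2),
            class = "skmix_model")
}

#' @export
print.skmix_model <- function(x, ...) {
  cat(sprintf("Skellam mixture model, J = %d components\n", x$J))
  print(data.frame(group = seq_len(x$J), pi = x$pi,
                   theta1 = x$theta1, theta2 = x$theta2), row.names = FALSE)
  invisible(x)
}

# unchecked log Skellam pmf on a prepared grid (z and nu = |z| precomputed);
# all Bessel orders come from one backward-recurrence pass in C++
.lskellam <- function(z, nu, th1, th2) {
  -(th1 + th2) + (z / 2) * (log(th1) - log(th2)) +
    .cpp_log_besseli(2 * sqrt(th1 * th2), nu)
}

# component log densities at unique differences: n_u x J matrix
.comp_logdens <- function(zu, model, shift = 0L) {
  J <- model$J
  z <- zu + shift
  nu <- abs(z)
  m <- matrix(0, length(zu), J)
  for (j in seq_len(J)) {
    m[, j] <- .lskellam(z, nu, model$theta1[j], model$theta2[j])
  }
  m
}

.row_logsumexp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

#' Observed-data log-likelihood of a Skellam mixture
#'
#' Computes sum_i log sum_j pi_j f(z_i; theta_j1, theta_j2) with the inner
#' sum taken by log-sum-exp.
#'
#' @param data a [paired_counts()] object.
#' @param model a [skmix_model()].
#' @return scalar log-likelihood (natural log).
#' @export
skmix_loglik <- function(data, model) {
  zt <- .z_table(data)
  lf <- .comp_logdens(zt$zu, model)
  lw <- sweep(lf, 2, log(model$pi), "+")
  sum(zt$w * .row_logsumexp(lw))
}

#' E-step: responsibilities and latent-count expectations
#'
#' The two-stage E-step of the hierarchical EM: the outer expectation over
#' group membership yields posterior responsibilities P_j(i) (log-space, so
#' no gene can receive an all-zero row); the inner expectation over the
#' latent Poisson pair (X_i, Y_i) given z_i and component j yields
#' E[X_i | z_i, j] and E[Y_i | z_i, j] via the Bessel-ratio identity.
#'
#' @param data a [paired_counts()] object.
#' @param model a [skmix_model()].
#' @return list with `posterior` (n x J, rows sum to 1), `ex` and `ey`
#'   (n x J latent expectations), and `loglik` of `model` on `data`.
#' @export
skmix_estep <- function(data, model) {
  zt <- .z_table(data)
  es <- .estep_core(zt, model)
  idx <- match(data$z, zt$zu)
  list(posterior = es$post[idx, , drop = FALSE],
       ex = es$ex[idx, , drop = FALSE],
       ey = es$ey[idx, , drop = FALSE],
       loglik = es$loglik)
}

.estep_core <- function(zt, model, latents = TRUE) {
  lf <- .comp_logdens(zt$zu, model)
  lw <- sweep(lf, 2, log(model$pi), "+")
  lrow <- .row_logsumexp(lw)
  post <- exp(lw - lrow)
  out <- list(post = post, loglik = sum(zt$w * lrow), lf = lf)
  if (latents) {
    lfm1 <- .comp_logdens(zt$zu, model, shift = -1L)
    out$ex <- sweep(exp(lfm1 - lf), 2, model$theta1, "*")
    out$ey <- out$ex - zt$zu
  }
  out
}

# Exact weighted Skellam MLE for one component.  Every stationary point of
# the weighted score satisfies theta1 - theta2 = weighted mean of z (a
# consequence of the Bessel-ratio identity), leaving a one-dimensional
# search over the sum s = theta1 + theta2.  Rows carrying a negligible
# share of the component's responsibility mass are dropped before the
# search.
.weighted_skellam_mle <- function(zu, wj, d = NULL) {
  keep <- wj > 1e-15 * sum(wj)
  zu <- zu[keep]; wj <- wj[keep]
  nu <- as.integer(abs(zu))
  N <- sum(wj)
  zbar <- sum(wj * zu) / N
  if (is.null(d)) d <- zbar
  v <- sum(wj * (zu - zbar)^2) / N   # weighted variance: moment guess for s
  lo <- abs(d) + 2 * .THETA_FLOOR
  hi <- max(5 * max(v, abs(d)), lo + 10, 20)
  opt <- .cpp_skellam_wmle(zu, nu, wj, d, lo, hi, 1e-8)
  # widen once if the optimum sits on the upper bracket edge
  if (opt[1] > hi - 1e-3 * (hi - lo)) {
    opt <- .cpp_skellam_wmle(zu, nu, wj, d, lo, 20 * hi, 1e-8)
  }
  s <- opt[1]
  c(theta1 = (s + d) / 2, theta2 = (s - d) / 2, q = opt[2])
}

# Exact M-step: given responsibilities, each component's (theta1, theta2)
# is the weighted Skellam MLE (difference pinned to the weighted mean of
# z, one-dimensional search over the sum), optionally under one equality
# constraint.  A per-component guard keeps the previous parameters if the
# weighted log-likelihood would not improve (bracketing edge cases), so
# the observed-data log-likelihood never decreases.
.mstep_core <- function(zt, es, model, constraint = NULL) {
  W <- zt$w * es$post                      # n_u x J weights
  N <- colSums(W)
  J <- length(N)
  pi <- N / zt$n
  theta1 <- model$theta1; theta2 <- model$theta2
  q_old <- colSums(W * es$lf)
  free <- rep(TRUE, J)

  set_comp <- function(m, th, force = FALSE) {
    if (force || th["q"] >= q_old[m]) {
      theta1[m] <<- max(th["theta1"], .THETA_FLOOR)
      theta2[m] <<- max(th["theta2"], .THETA_FLOOR)
    }
  }

  if (!is.null(constraint)) {
    kind <- constraint$kind
    if (kind == "theta_eq") {
      j <- constraint$j
      # force the move whenever the current parameters violate the constraint
      set_comp(j, .weighted_skellam_mle(zt$zu, W[, j], d = 0),
               force = abs(model$theta1[j] - model$theta2[j]) > 1e-9)
      free[j] <- FALSE
    } else if (kind == "diff_fixed") {
      j <- constraint$j
      set_comp(j, .weighted_skellam_mle(zt$zu, W[, j], d = constraint$c),
               force = abs(model$theta1[j] - model$theta2[j] -
                             constraint$c) > 1e-9)
      free[j] <- FALSE
    } else if (kind == "diff_eq") {
      j <- constraint$j; l <- constraint$l
      dj <- sum(W[, j] * zt$zu) / N[j]
      dl <- sum(W[, l] * zt$zu) / N[l]
      qfun <- function(d) {
        .weighted_skellam_mle(zt$zu, W[, j], d = d)["q"] +
          .weighted_skellam_mle(zt$zu, W[, l], d = d)["q"]
      }
      d_star <- if (abs(dj - dl) < 1e-10) dj else
        stats::optimize(qfun, lower = min(dj, dl), upper = max(dj, dl),
                        maximum = TRUE, tol = 1e-7)$maximum
      q_pair_old <- q_old[j] + q_old[l]
      th_j <- .weighted_skellam_mle(zt$zu, W[, j], d = d_star)
      th_l <- .weighted_skellam_mle(zt$zu, W[, l], d = d_star)
      if (th_j["q"] + th_l["q"] >= q_pair_old ||
          abs(model$theta1[j] - model$theta2[j] -
              (model$theta1[l] - model$theta2[l])) > 1e-9) {
        theta1[j] <- th_j["theta1"]; theta2[j] <- th_j["theta2"]
        theta1[l] <- th_l["theta1"]; theta2[l] <- th_l["theta2"]
      }
      free[c(j, l)] <- FALSE
    } else stop("unknown constraint kind: ", kind, call. = FALSE)
  }

  for (m in which(free)) {
    set_comp(m, .weighted_skellam_mle(zt$zu, W[, m]))
  }

  degenerate <- any(pi < 1 / (10 * zt$n)) || any(N < 1)
  list(model = skmix_model(pmax(pi, 1e-300) / sum(pmax(pi, 1e-300)),
                           theta1, theta2),
       degenerate = degenerate)
}

#' M-step: parameter updates from responsibilities and latent expectations
#'
#' Closed-form complete-data maximisation: pi_j is the mean responsibility,
#' and each theta is the responsibility-weighted mean of the corresponding
#' latent expectation.  As a consequence theta_j1 - theta_j2 equals the
#' responsibility-weighted mean of z exactly.
#'
#' @param data a [paired_counts()] object.
#' @param posterior n x J row-stochastic responsibility matrix.
#' @param ex,ey n x J latent-count expectation matrices as returned by
#'   [skmix_estep()].
#' @return updated [skmix_model()].
#' @export
skmix_mstep <- function(data, posterior, ex, ey) {
  n <- nrow(data)
  N <- colSums(posterior)
  if (any(N < 10 * .Machine$double.eps)) {
    stop("component with vanishing responsibility mass: degenerate",
         call. = FALSE)
  }
  pi <- N / n
  theta1 <- pmax(colSums(posterior * ex) / N, .THETA_FLOOR)
  theta2 <- pmax(colSums(posterior * ey) / N, .THETA_FLOOR)
  skmix_model(pi, theta1, theta2)
}

#' Moment-based initialisation over quantile bins of z
#'
#' Partitions genes by quantiles of the count difference into J bins whose
#' edges are randomly jittered across restarts, then applies the Skellam
#' moment equations within each bin: with bin mean m and variance v,
#' theta1 = (v + m)/2 and theta2 = (v - m)/2 (floored).  Deterministic
#' given `seed` and `restart`.
#'
#' @param data a [paired_counts()] object.
#' @param J number of components.
#' @param seed integer seed.
#' @param restart restart index; restart 1 uses unjittered quantile edges.
#' @return a [skmix_model()].
#' @export
skmix_init <- function(data, J, seed = 1L, restart = 1L) {
  if (nrow(data) < J) stop("need at least J genes", call. = FALSE)
  withr::with_seed(as.integer(seed) + 977L * (as.integer(restart) - 1L), {
    z <- data$z
    if (J == 1L) {
      groups <- rep(1L, length(z))
    } else {
      probs <- seq_len(J - 1) / J
      if (restart > 1L) {
        probs <- probs + stats::runif(J - 1, -0.4, 0.4) / J
        probs <- pmin(pmax(sort(probs), 0.02), 0.98)
      }
      edges <- unique(stats::quantile(z, probs, type = 1))
      groups <- findInterval(z, edges, left.open = TRUE) + 1L
    }
    init_floor <- 0.01
    tab <- table(factor(groups, levels = seq_len(max(groups))))
    pi <- as.numeric(tab) / length(z)
    th1 <- numeric(length(tab)); th2 <- numeric(length(tab))
    for (g in seq_along(tab)) {
      zg <- z[groups == g]
      m <- if (length(zg)) mean(zg) else mean(z)
      v <- if (length(zg) > 1) stats::var(zg) else abs(m) + 1
      th1[g] <- max((v + m) / 2, init_floor)
      th2[g] <- max((v - m) / 2, init_floor)
    }
    # constant z (or collapsed quantiles) can leave fewer bins than J:
    # pad with perturbed copies of the first bin
    while (length(pi) < J) {
      k <- length(pi) + 1L
      pi <- c(pi * (1 - 1 / J), 1 / J)
      th1 <- c(th1, th1[1] * stats::runif(1, 0.5, 2) + init_floor)
      th2 <- c(th2, th2[1] * stats::runif(1, 0.5, 2) + init_floor)
    }
    pi[pi <= 0] <- 1e-3
    skmix_model(pi / sum(pi), th1, th2)
  })
}

# canonical component order: descending theta1 - theta2, ties by ascending
# theta1; keeps reports and bootstrap alignment reproducible.
.canonical_order <- function(model) {
  order(-(model$theta1 - model$theta2), model$theta1)
}

.reorder_model <- function(model, ord) {
  skmix_model(model$pi[ord], model$theta1[ord], model$theta2[ord])
}

# EM driver on the compressed z table; single initialisation.
.em_run <- function(zt, model, tol, max_iter, constraint = NULL) {
  trace <- numeric(0)
  degenerate <- FALSE
  converged <- FALSE
  # an initial model violating the constraint is projected by one
  # constrained M-step before the trace starts
  if (!is.null(constraint)) {
    es <- .estep_core(zt, model, latents = FALSE)
    ms <- .mstep_core(zt, es, model, constraint)
    model <- ms$model
  }
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    es <- .estep_core(zt, model, latents = FALSE)
    trace <- c(trace, es$loglik)
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ms <- .mstep_core(zt, es, model, constraint)
    degenerate <- degenerate || ms$degenerate
    model <- ms$model
    ll_old <- es$loglik
  }
  list(model = model, loglik = trace[length(trace)], trace = trace,
       n_iter = iter, converged = converged, degenerate = degenerate)
}

#' Fit a Skellam mixture by the two-stage hierarchical EM algorithm
#'
#' Alternates the double E-step of [skmix_estep()] (latent Poisson pair
#' within component; component membership across components) with the
#' closed-form M-step until the relative change in log-likelihood falls
#' below `tol`.  Because the likelihood surface has local maxima and is
#' sensitive to starting values, `n_restarts` initialisations from
#' [skmix_init()] are run and the fit with the highest final
#' log-likelihood is returned.  Components are reported in canonical order
#' (descending theta1 - theta2, ties by ascending theta1).
#'
#' @param data a [paired_counts()] object.
#' @param J number of components, `1 <= J <= nrow(data)`.
#' @param init optional [skmix_model()] used as the single starting point
#'   (restarts are then skipped).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param n_restarts number of jittered initialisations.
#' @param seed integer seed controlling the initialisations.
#' @param constraint internal use; equality constraint forwarded to the
#'   M-step (see [skmix_fit_constrained()]).
#' @return object of class `skmix_fit`: `model`, `loglik`, `bic`,
#'   `posterior` (n x J), `assignments` (argmax responsibility, ties to the
#'   lowest index), `loglik_trace`, `n_iter`, `converged`, `degenerate`.
#' @examples
#' sim <- skmix_simulate(skmix_sim_spec(
#'   pi = c(0.5, 0.5), theta1 = c(40, 10), theta2 = c(10, 40),
#'   n_genes = 300, seed = 7))
#' fit <- skmix_fit(sim$counts, J = 2, n_restarts = 3, seed = 7)
#' @export
skmix_fit <- function(data, J, init = NULL, tol = 1e-8, max_iter = 500L,
                      n_restarts = 10L, seed = 1L, constraint = NULL) {
  stopifnot(inherits(data, "paired_counts"))
  J <- as.integer(J)
  if (J < 1L || nrow(data) < J) {
    stop("J must satisfy 1 <= J <= number of genes", call. = FALSE)
  }
  zt <- .z_table(data)
  runs <- list()
  if (!is.null(init)) {
    runs[[1]] <- .em_run(zt, init, tol, max_iter, constraint)
  } else {
    n_restarts <- max(1L, as.integer(n_restarts))
    if (J == 1L) n_restarts <- 1L  # initialisation is identical for J = 1
    if (n_restarts <= 3L) {
      for (r in seq_len(n_restarts)) {
        m0 <- skmix_init(data, J, seed = seed, restart = r)
        runs[[r]] <- .em_run(zt, m0, tol, max_iter, constraint)
      }
    } else {
      # short-run/polish scheme: run every initialisation for a burst of
      # iterations, then polish the most promising third to convergence
      short <- lapply(seq_len(n_restarts), function(r) {
        m0 <- skmix_init(data, J, seed = seed, restart = r)
        .em_run(zt, m0, tol, min(30L, max_iter), constraint)
      })
      ll_short <- vapply(short, `[[`, numeric(1), "loglik")
      top <- order(ll_short, decreasing = TRUE)[seq_len(max(3L, ceiling(n_restarts / 3)))]
      runs <- lapply(top, function(r) {
        .em_run(zt, short[[r]]$model, tol, max_iter, constraint)
      })
    }
  }
  ll <- vapply(runs, `[[`, numeric(1), "loglik")
  ok <- !vapply(runs, `[[`, logical(1), "degenerate")
  pick <- if (any(ok)) which(ok)[which.max(ll[ok])] else which.max(ll)
  best <- runs[[pick]]
  if (!any(ok) && is.null(constraint)) {
    warning("all EM runs flagged degenerate components for J = ", J,
            call. = FALSE)
  }

  ord <- .canonical_order(best$model)
  model <- .reorder_model(best$model, ord)
  es <- .estep_core(zt, model, latents = FALSE)
  idx <- match(data$z, zt$zu)
  posterior <- es$post[idx, , drop = FALSE]
  rownames(posterior) <- data$gene_id
  assignments <- max.col(posterior, ties.method = "first")

  structure(list(
    model = model, loglik = es$loglik,
    bic = skmix_bic(es$loglik, J, zt$n),
    posterior = posterior, assignments = assignments,
    loglik_trace = best$trace, n_iter = best$n_iter,
    converged = best$converged, degenerate = best$degenerate,
    n = zt$n, J = J,
    settings = list(tol = tol, max_iter = max_iter,
                    n_restarts = if (is.null(init)) n_restarts else 0L,
                    seed = seed),
    constraint = constraint
  ), class = "skmix_fit")
}

#' @export
print.skmix_fit <- function(x, ...) {
  cat(sprintf("Skellam mixture fit: J = %d, n = %d genes\n", x$J, x$n))
  cat(sprintf("log-likelihood %.4f, BIC %.4f, %d iterations (%s)\n",
              x$loglik, x$bic, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  print(x$model)
  invisible(x)
}
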