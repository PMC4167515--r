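#' Read a paired count table from delimited text
#'
#' Expects a header row and three columns: gene identifier and the read
#' counts under the two treatments.  Comma or tab delimiters are detected
#' from the header line.  Malformed rows (missing, negative or
#' non-integer counts, duplicate identifiers) are rejected with messages
#' naming the offending row.
#'
#' @param path file path (UTF-8 text).
#' @return a [paired_counts()] object.
#' @export
read_paired_counts <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(header) == 0) stop("empty input file: ", path, call. = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", comment.char = "",
                          quote = "\"", fileEncoding = "UTF-8",
                          check.names = FALSE)
  if (ncol(df) < 3) {
    stop("expected 3 columns (gene_id, count_1, count_2), found ", ncol(df),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  parse_counts <- function(v, colname) {
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad)) {
      stop(sprintf("%s: row %d, column %s: invalid count '%s' (need a non-negative integer)",
                   path, bad[1], colname, v[bad[1]]), call. = FALSE)
    }
    num
  }
  paired_counts(df[[1]],
                parse_counts(df[[2]], names(df)[2]),
                parse_counts(df[[3]], names(df)[3]))
}

#' Write fit, test and bootstrap results to an output directory
#'
#' Emits `model.json` (proportions, means, log-likelihood, BIC, settings,
#' seed), `assignments.tsv` (gene, assigned group, max posterior, full
#' posterior row), `groups.tsv` (group summary with bootstrap SEs when
#' available) and `tests.tsv`.  Outputs are deterministic apart from the
#' timestamp field in the JSON.
#'
#' @param fit a [skmix_fit()].
#' @param tests optional data frame from [skmix_test_all()].
#' @param se optional bootstrap output from [skmix_boot_se()].
#' @param outdir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_skmix_results <- function(fit, tests = NULL, se = NULL, outdir) {
  stopifnot(inherits(fit, "skmix_fit"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  mj <- file.path(outdir, "model.json")
  jsonlite::write_json(list(
    J = fit$J, pi = fit$model$pi, theta1 = fit$model$theta1,
    theta2 = fit$model$theta2, loglik = fit$loglik, bic = fit$bic,
    n = fit$n, converged = fit$converged, n_iter = fit$n_iter,
    settings = fit$settings, timestamp = format(Sys.time(), tz = "UTC")
  ), mj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, mj)

  at <- file.path(outdir, "assignments.tsv")
  post <- fit$posterior
  adf <- data.frame(gene_id = rownames(post), group = fit$assignments,
                    max_posterior = apply(post, 1, max))
  colnames(post) <- sprintf("P%d", seq_len(fit$J))
  utils::write.table(cbind(adf, as.data.frame(post)), at, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, at)

  gt <- file.path(outdir, "groups.tsv")
  gdf <- data.frame(group = seq_len(fit$J), proportion = fit$model$pi,
                    theta1 = fit$model$theta1, theta2 = fit$model$theta2)
  if (!is.null(se)) gdf <- cbind(gdf, se$se[, -1, drop = FALSE])
  utils::write.table(gdf, gt, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, gt)

  if (!is.null(tests)) {
    tt <- file.path(outdir, "tests.tsv")
    utils::write.table(tests, tt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, tt)
  }
  invisible(paths)
}

#' Load a mixture model from a `model.json` written by [write_skmix_results()]
#'
#' @param path path to the JSON file.
#' @return a [skmix_model()].
#' @export
read_skmix_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  skmix_model(m$pi, m$theta1, m$theta2)
}

#' Read a simulation specification from a YAML config file
#'
#' Recognised keys: `pi` (list of proportions), `theta1`, `theta2`
#' (lists of means), `n_genes`, `seed`.  Missing keys fall back to the
#' [skmix_sim_spec()] defaults.
#'
#' @param path YAML file path.
#' @return a [skmix_sim_spec()].
#' @export
read_sim_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- formals(skmix_sim_spec)
  args <- list(
    pi = if (!is.null(cfg$pi)) unlist(cfg$pi) else eval(defaults$pi),
    theta1 = if (!is.null(cfg$theta1)) unlist(cfg$theta1) else eval(defaults$theta1),
    theta2 = if (!is.null(cfg$theta2)) unlist(cfg$theta2) else eval(defaults$theta2),
    n_genes = if (!is.null(cfg$n_genes)) cfg$n_genes else eval(defaults$n_genes),
    seed = if (!is.null(cfg$seed)) cfg$seed else eval(defaults$seed)
  )
  do.call(skmix_sim_spec, args)
}
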