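#' Paired count matrix constructor
#'
#' Validates and assembles per-gene read counts under two treatments into
#' the container used by all fitting functions.  Counts are used as given;
#' no library-size normalisation is applied (the model treats raw reads as
#' Poisson), so the two libraries are assumed to have comparable depth.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param x,y non-negative integer read counts for treatments 1 and 2.
#' @return a `paired_counts` data frame with columns `gene_id`, `x`, `y`
#'   and the derived difference `z = x - y`.
#' @examples
#' pc <- paired_counts(paste0("g", 1:3), c(10, 0, 25), c(8, 2, 30))
#' @export
paired_counts <- function(gene_id, x, y) {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  if (n < 1) stop("at least one gene is required", call. = FALSE)
  if (length(x) != n || length(y) != n) {
    stop("gene_id, x and y must have equal length", call. = FALSE)
  }
  if (anyDuplicated(gene_id)) {
    dup <- gene_id[duplicated(gene_id)][1]
    stop("duplicate gene_id: ", dup, call. = FALSE)
  }
  for (nm in c("x", "y")) {
    v <- get(nm)
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf("column %s: row %d has invalid count %s (need a non-negative integer)",
                   nm, bad[1], format(v[bad[1]])), call. = FALSE)
    }
  }
  out <- data.frame(gene_id = gene_id, x = as.integer(round(x)),
                    y = as.integer(round(y)), stringsAsFactors = FALSE)
  out$z <- out$x - out$y
  class(out) <- c("paired_counts", "data.frame")
  out
}

#' @export
print.paired_counts <- function(x, ...) {
  cat(sprintf("Paired counts: %d genes, z range [%d, %d]\n",
              nrow(x), min(x$z), max(x$z)))
  NextMethod()
}

# Aggregate the differences to unique values with multiplicities; the
# likelihood depends on genes only through z, so all EM passes run on this
# compressed form.
.z_table <- function(data) {
  zu <- sort(unique(data$z))
  w <- as.numeric(table(factor(data$z, levels = zu)))
  list(zu = zu, w = w, n = nrow(data))
}
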