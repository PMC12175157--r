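# Fingerprint-based chemical-space diagnostics: Tanimoto similarity,
# per-compound max/mean similarity to a training set, and eCDF coordinates.

#' Tanimoto similarity of two bit vectors
#'
#' Intersection over union of the on-bits; defined as 0 when both vectors
#' are empty.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' tanimoto(c(0, 1, 1, 1, 0), c(0, 0, 1, 1, 1)) # 2/4
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("bit vectors must have equal length", call. = FALSE)
  }
  a <- a != 0
  b <- b != 0
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

#' Empirical cumulative distribution coordinates
#'
#' Sorted unique values with their cumulative fractions: the coordinates of
#' the right-continuous eCDF step function. The terminal cumulative fraction
#' is exactly 1.
#'
#' @param values non-empty numeric vector.
#' @return `data.frame` with `value` and `cumfrac`.
#' @export
#' @examples
#' ecdf_coords(c(1, 2, 3, 4))
ecdf_coords <- function(values) {
  if (!length(values)) stop("empty vector", call. = FALSE)
  v <- sort(unique(values))
  data.frame(value = v,
             cumfrac = cumsum(tabulate(match(sort(values), v))) /
               length(values))
}

#' Similarity of query compounds to a training set
#'
#' For every query fingerprint, the maximum and mean Tanimoto similarity
#' over all training fingerprints, together with eCDF coordinates for both
#' statistics -- the standard chemical-space coverage diagnostic for a
#' held-out set.
#'
#' @param query,train 0/1 matrices (compounds by bits) of equal width;
#'   `train` must be non-empty.
#' @return an object of class `"similarity_summary"`: list with
#'   `per_compound` (`max_tanimoto`, `mean_tanimoto` per query row),
#'   `ecdf_max`, and `ecdf_mean`.
#' @export
similarity_summary <- function(query, train) {
  query <- as.matrix(query)
  train <- as.matrix(train)
  if (!nrow(train)) stop("empty training set", call. = FALSE)
  if (ncol(query) != ncol(train)) {
    stop("query and train must share the same bit width", call. = FALSE)
  }
  q <- (query != 0) * 1
  t_ <- (train != 0) * 1
  inter <- q %*% t(t_)
  un <- outer(rowSums(q), rowSums(t_), "+") - inter
  sim <- ifelse(un == 0, 0, inter / un)
  per <- data.frame(
    compound = rownames(query) %||% seq_len(nrow(query)),
    max_tanimoto = apply(sim, 1, max),
    mean_tanimoto = rowMeans(sim),
    stringsAsFactors = FALSE)
  structure(list(per_compound = per,
                 ecdf_max = ecdf_coords(per$max_tanimoto),
                 ecdf_mean = ecdf_coords(per$mean_tanimoto)),
            class = "similarity_summary")
}

#' @export
print.similarity_summary <- function(x, ...) {
  p <- x$per_compound
  cat(sprintf(
    "Similarity summary: %d query compounds; median max-Tanimoto %.3f, median mean-Tanimoto %.3f\n",
    nrow(p), stats::median(p$max_tanimoto), stats::median(p$mean_tanimoto)))
  invisible(x)
}

#' eCDF plot of query-to-training similarities
#'
#' @param x a `"similarity_summary"`.
#' @param which `"max"` or `"mean"` statistic.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.similarity_summary <- function(x, which = c("max", "mean"), ...) {
  which <- match.arg(which)
  e <- if (which == "max") x$ecdf_max else x$ecdf_mean
  graphics::plot(e$value, e$cumfrac, type = "s",
                 xlab = sprintf("%s Tanimoto similarity to training set",
                                which),
                 ylab = "cumulative fraction", ylim = c(0, 1), ...)
  invisible(x)
}
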