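# Active/inactive classification and functional-group enrichment-factor
# analysis.

#' Classify compounds as active
#'
#' Active means the experimental activity strictly exceeds the threshold
#' (default 20% of the positive-control displacement).
#'
#' @param y_exp activity vector (%).
#' @param threshold activity cutoff; strictly-greater comparison.
#' @return logical vector.
#' @export
#' @examples
#' classify_active(c(20, 20.1, -5)) # FALSE TRUE FALSE
classify_active <- function(y_exp, threshold = 20) {
  if (any(!is.finite(y_exp))) stop("activities must be finite", call. = FALSE)
  y_exp > threshold
}

check_counts <- function(n_active_with, n_active_total, n_inactive_with,
                         n_inactive_total) {
  check_number(n_active_with, "n_active_with", lower = 0, integer = TRUE)
  check_number(n_inactive_with, "n_inactive_with", lower = 0, integer = TRUE)
  check_number(n_active_total, "n_active_total", lower = 1, integer = TRUE)
  check_number(n_inactive_total, "n_inactive_total", lower = 1,
               integer = TRUE)
  if (n_active_with > n_active_total || n_inactive_with > n_inactive_total) {
    stop("group counts cannot exceed subset totals", call. = FALSE)
  }
}

#' Enrichment factor of a functional group
#'
#' Ratio of the group's prevalence among active compounds to its prevalence
#' among inactive compounds:
#' `(n_active_with / n_active_total) / (n_inactive_with / n_inactive_total)`.
#' `Inf` marks a group absent from the inactives but present in the actives;
#' `NA` a group absent from both.
#'
#' @param n_active_with,n_inactive_with compounds carrying the group in the
#'   active / inactive subset.
#' @param n_active_total,n_inactive_total subset sizes.
#' @return non-negative ratio (possibly `Inf` or `NA`).
#' @export
#' @examples
#' enrichment_factor(185, 888, 50, 624) # 2.6
enrichment_factor <- function(n_active_with, n_active_total,
                              n_inactive_with, n_inactive_total) {
  check_counts(n_active_with, n_active_total, n_inactive_with,
               n_inactive_total)
  if (n_inactive_with == 0) {
    return(if (n_active_with > 0) Inf else NA_real_)
  }
  (n_active_with / n_active_total) / (n_inactive_with / n_inactive_total)
}

#' Exact over-representation p-value
#'
#' One-sided hypergeometric tail probability of observing at least
#' `n_active_with` group members among the actives, given the group's total
#' prevalence -- the standard exact test for over-representation in the
#' active subset.
#'
#' @inheritParams enrichment_factor
#' @return p-value in (0, 1].
#' @export
enrichment_significance <- function(n_active_with, n_active_total,
                                    n_inactive_with, n_inactive_total) {
  check_counts(n_active_with, n_active_total, n_inactive_with,
               n_inactive_total)
  n_with <- n_active_with + n_inactive_with
  n_total <- n_active_total + n_inactive_total
  stats::phyper(n_active_with - 1, n_with, n_total - n_with, n_active_total,
                lower.tail = FALSE)
}

#' Functional-group enrichment table
#'
#' For each group-membership mask, tabulates the 2x2 counts against the
#' active/inactive classification and reports the enrichment factor, the
#' exact over-representation p-value, and whether the group passes both
#' default criteria (EF strictly above `ef_threshold` and p strictly below
#' `p_threshold`). Rows are sorted by descending EF.
#'
#' @param active logical vector from [classify_active()].
#' @param groups named list of logical membership masks, or a 0/1
#'   compounds-by-groups matrix with column names; masks must align with
#'   `active`.
#' @param ef_threshold minimum enrichment factor (strict).
#' @param p_threshold maximum p-value (strict).
#' @return a `data.frame` of class `"enrichment_table"` with columns `group`,
#'   `n_active_with`, `n_inactive_with`, `n_active_total`,
#'   `n_inactive_total`, `ef`, `p`, `passes`.
#' @export
enrichment_table <- function(active, groups, ef_threshold = 2.5,
                             p_threshold = 0.01) {
  if (is.matrix(groups)) {
    groups <- stats::setNames(
      lapply(seq_len(ncol(groups)), function(j) groups[, j] == 1),
      colnames(groups))
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be named", call. = FALSE)
  }
  n_act <- sum(active)
  n_inact <- sum(!active)
  rows <- lapply(names(groups), function(g) {
    mask <- groups[[g]]
    if (length(mask) != length(active)) {
      stop("group mask '", g, "' does not align with the activity vector",
           call. = FALSE)
    }
    aw <- sum(mask & active)
    iw <- sum(mask & !active)
    ef <- enrichment_factor(aw, n_act, iw, n_inact)
    p <- enrichment_significance(aw, n_act, iw, n_inact)
    data.frame(group = g, n_active_with = aw, n_inactive_with = iw,
               n_active_total = n_act, n_inactive_total = n_inact,
               ef = ef, p = p,
               passes = is.finite(ef) && ef > ef_threshold &&
                 p < p_threshold || is.infinite(ef) && p < p_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ef, out$group, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"),
            ef_threshold = ef_threshold, p_threshold = p_threshold)
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf(
    "Functional-group enrichment (%d active / %d inactive): %d of %d pass EF > %g, p < %g\n",
    x$n_active_total[1] %||% 0, x$n_inactive_total[1] %||% 0,
    sum(x$passes), nrow(x), attr(x, "ef_threshold"), attr(x, "p_threshold")))
  shown <- as.data.frame(x)
  shown$ef <- round_half_up(shown$ef, 1)
  shown$p <- signif(shown$p, 2)
  print.data.frame(shown)
  invisible(x)
}
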