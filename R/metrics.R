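# Regression metrics on the percent-activity scale, their bootstrap
# uncertainty, the activity-conditional error curve, and the Grubbs statistic
# used for refined consensus averaging.

#' Root-mean-square error
#'
#' `RMSE = sqrt(mean((y_exp - y_pred)^2))`, in the units of the activity
#' (percent displacement here).
#'
#' @param y_exp experimental activities.
#' @param y_pred predicted activities.
#' @return non-negative scalar.
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(12.5)
rmse <- function(y_exp, y_pred) {
  if (length(y_exp) != length(y_pred)) {
    stop("y_exp and y_pred must have equal length", call. = FALSE)
  }
  if (!length(y_exp)) stop("empty input", call. = FALSE)
  if (any(!is.finite(y_exp)) || any(!is.finite(y_pred))) {
    stop("inputs must be finite", call. = FALSE)
  }
  sqrt(mean((y_exp - y_pred)^2))
}

#' Coefficient of determination (Q-squared / R-squared)
#'
#' `1 - RSS/TSS` with the total sum of squares about the mean of `y_exp`.
#' The same formula serves as Q-squared when `y_pred` are cross-validated
#' training predictions and as R-squared on held-out test predictions; only
#' the `label` differs.
#'
#' @inheritParams rmse
#' @param label which role the predictions play: `"test"` (R-squared) or
#'   `"train_cv"` (Q-squared).
#' @return for `rsq()`, a scalar `<= 1`; for `metric_report()`, a
#'   `"metric_report"` list with `rmse`, `r2_or_q2`, `n`, `label` and an
#'   optional bootstrap confidence interval for the RMSE.
#' @export
#' @examples
#' rsq(c(0, 1, 2), c(0, 0, 2)) # 0.5
rsq <- function(y_exp, y_pred) {
  if (length(y_exp) != length(y_pred)) {
    stop("y_exp and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_exp) < 2) stop("need at least 2 observations", call. = FALSE)
  tss <- sum((y_exp - mean(y_exp))^2)
  if (tss == 0) {
    stop("y_exp is constant: coefficient of determination undefined",
         call. = FALSE)
  }
  1 - sum((y_exp - y_pred)^2) / tss
}

#' @rdname rsq
#' @param ci_level if non-`NULL`, percentile bootstrap level for an RMSE
#'   confidence interval.
#' @param n_boot,seed bootstrap resamples and seed, passed to
#'   [bootstrap_rmse_ci()].
#' @export
metric_report <- function(y_exp, y_pred, label = c("test", "train_cv"),
                          ci_level = NULL, n_boot = 1000, seed = NULL) {
  label <- match.arg(label)
  out <- list(rmse = rmse(y_exp, y_pred), r2_or_q2 = rsq(y_exp, y_pred),
              n = length(y_exp), label = label)
  if (!is.null(ci_level)) {
    ci <- bootstrap_rmse_ci(y_exp, y_pred, n_boot = n_boot,
                            level = ci_level, seed = seed)
    out$ci_low <- ci[1]
    out$ci_high <- ci[2]
  }
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  stat <- if (x$label == "train_cv") "Q2" else "R2"
  cat(sprintf("n = %d: RMSE = %.2f%%, %s = %.3f", x$n, x$rmse, stat,
              x$r2_or_q2))
  if (!is.null(x$ci_low)) {
    cat(sprintf(" (RMSE CI [%.1f, %.1f])", x$ci_low, x$ci_high))
  }
  cat("\n")
  invisible(x)
}

#' Percentile bootstrap confidence interval for the RMSE
#'
#' Compound-level resampling with replacement; the interval is the
#' percentile interval of the resampled RMSE values.
#'
#' @inheritParams rmse
#' @param n_boot number of bootstrap resamples.
#' @param level interval level in (0, 1), e.g. `0.95`.
#' @param seed optional seed for reproducible resampling.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_rmse_ci <- function(y_exp, y_pred, n_boot = 1000, level = 0.95,
                              seed = NULL) {
  if (level <= 0 || level >= 1) {
    stop("level must be inside (0, 1)", call. = FALSE)
  }
  check_number(n_boot, "n_boot", lower = 1, integer = TRUE)
  se <- (y_exp - y_pred)^2
  if (length(se) != length(y_exp) || !length(se)) {
    stop("invalid inputs", call. = FALSE)
  }
  n <- length(se)
  if (n == 1) return(rep(sqrt(se), 2))
  with_local_seed(seed, {
    draws <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    boots <- sqrt(rowMeans(matrix(se[draws], nrow = n_boot)))
    alpha <- (1 - level) / 2
    unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 1))
  })
}

#' RMSE as a function of experimental activity
#'
#' Bins the activity axis into fixed-width intervals and reports the RMSE and
#' compound count per bin, tracing how prediction accuracy varies across the
#' activity range (models are usually most reliable where training data are
#' dense). Empty bins carry count 0 and an `NA` RMSE.
#'
#' @inheritParams rmse
#' @param bin_width bin width in activity % units.
#' @param limits axis limits; bins cover `seq(limits[1], limits[2],
#'   bin_width)`. Observations outside are clamped into the terminal bins.
#' @return a `data.frame` of class `"activity_error_curve"` with `bin_low`,
#'   `bin_high`, `n`, `rmse`.
#' @export
activity_error_curve <- function(y_exp, y_pred, bin_width = 10,
                                 limits = c(-50, 110)) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (length(y_exp) != length(y_pred)) {
    stop("y_exp and y_pred must have equal length", call. = FALSE)
  }
  edges <- seq(limits[1], limits[2], by = bin_width)
  if (edges[length(edges)] < limits[2]) edges <- c(edges, limits[2])
  nb <- length(edges) - 1
  idx <- findInterval(y_exp, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  se <- (y_exp - y_pred)^2
  n <- tabulate(idx, nbins = nb)
  r <- rep(NA_real_, nb)
  for (b in which(n > 0)) r[b] <- sqrt(mean(se[idx == b]))
  structure(data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
                       n = n, rmse = r),
            class = c("activity_error_curve", "data.frame"))
}

#' @export
plot.activity_error_curve <- function(x, ...) {
  mid <- (x$bin_low + x$bin_high) / 2
  graphics::plot(mid, x$rmse, type = "b", pch = 16,
                 xlab = "experimental activity (%)", ylab = "RMSE (%)", ...)
  invisible(x)
}

# Core single-outlier two-sided Grubbs test, no logging; critical value from
# the standard t-based closed form.
grubbs_index <- function(values, alpha) {
  n <- length(values)
  if (n < 3) return(integer(0))
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(integer(0))
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  t2 <- stats::qt(1 - alpha / (2 * n), n - 2)^2
  g_crit <- ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
  if (g > g_crit) which.max(dev) else integer(0)
}

#' Grubbs test for a single extreme value
#'
#' Two-sided single-outlier Grubbs test: flags the most extreme value if
#' `G = max|v - mean| / sd` exceeds the t-based critical value at `alpha`.
#' Undefined for fewer than 3 values or zero variance (returns no index,
#' with a message).
#'
#' @param values numeric vector.
#' @param alpha two-sided significance level.
#' @return integer index of the flagged value, or `integer(0)` if none.
#' @export
#' @examples
#' grubbs_flag(c(rep(10, 8), 50), alpha = 0.1)
grubbs_flag <- function(values, alpha = 0.1) {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (length(values) < 3) {
    message("Grubbs test undefined for fewer than 3 values; none flagged")
    return(integer(0))
  }
  grubbs_index(values, alpha)
}
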