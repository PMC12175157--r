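# Bin-based averaging (BBA) over the distance-to-model axis: ordered bins of
# minimum size with non-decreasing error, per-bin outlier thresholds,
# Williams-plot data, the AD coverage cutoff, and cross-model outlier
# intersection.

#' Fit distance-to-model bins (bin-based averaging)
#'
#' Sorts compounds by ascending distance to model (DM; here the
#' Consensus-STD) and partitions them into non-overlapping bins. A bin is
#' closed once it holds at least `min_bin_size` compounds and -- unless it is
#' the first bin -- its RMSE exceeds the preceding bin's RMSE, reflecting
#' the expectation that accuracy degrades (or at least does not improve) as
#' DM grows. The trailing remainder smaller than `min_bin_size` is merged
#' into the last bin and that bin's RMSE recomputed. Compounds with equal DM
#' are never split across a bin boundary.
#'
#' @param dm non-negative distance-to-model values (e.g. `std_<m>`).
#' @param abs_error absolute prediction errors, same length.
#' @param min_bin_size minimum compounds per bin.
#' @return a `data.frame` of class `"bba_bins"` with `bin`, `dm_min`,
#'   `dm_max`, `n`, `rmse`; attributes keep the fitting scale.
#' @seealso [flag_outliers()], [ad_threshold()]
#' @export
fit_bins <- function(dm, abs_error, min_bin_size = 50) {
  if (length(dm) != length(abs_error)) {
    stop("dm and abs_error must have equal length", call. = FALSE)
  }
  if (any(!is.finite(dm)) || any(dm < 0)) {
    stop("dm must be finite and non-negative", call. = FALSE)
  }
  check_number(min_bin_size, "min_bin_size", lower = 1, integer = TRUE)
  n <- length(dm)
  ord <- order(dm)
  d <- dm[ord]
  e2 <- abs_error[ord]^2
  if (n < min_bin_size) {
    message("fewer compounds than min_bin_size: single bin covering all")
  }

  # tie groups: runs of identical DM are assigned atomically
  runs <- rle(d)$lengths
  ends <- cumsum(runs)

  bins <- list()
  start <- 1L
  prev_rmse <- -Inf
  cnt <- 0L
  ssq <- 0
  for (g in seq_along(ends)) {
    take <- seq.int(ends[g] - runs[g] + 1L, ends[g])
    cnt <- cnt + length(take)
    ssq <- ssq + sum(e2[take])
    cur_rmse <- sqrt(ssq / cnt)
    if (cnt >= min_bin_size &&
        (length(bins) == 0L || cur_rmse > prev_rmse)) {
      bins[[length(bins) + 1L]] <- list(from = start, to = ends[g],
                                        n = cnt, rmse = cur_rmse)
      prev_rmse <- cur_rmse
      start <- ends[g] + 1L
      cnt <- 0L
      ssq <- 0
    }
  }
  if (cnt > 0L) {
    if (cnt >= min_bin_size || length(bins) == 0L) {
      bins[[length(bins) + 1L]] <- list(from = start, to = n, n = cnt,
                                        rmse = sqrt(ssq / cnt))
    } else {
      # merge trailing remainder into the last closed bin, recompute RMSE
      last <- bins[[length(bins)]]
      idx <- seq.int(last$from, n)
      bins[[length(bins)]] <- list(from = last$from, to = n,
                                   n = length(idx),
                                   rmse = sqrt(mean(e2[idx])))
    }
  }
  # A terminal bin closed by running out of data (or by merging) never met
  # the "RMSE exceeds the preceding bin" criterion; absorb it backwards
  # until the bin sequence is non-decreasing, keeping the error/uncertainty
  # relationship monotone by construction.
  while (length(bins) > 1L &&
         bins[[length(bins)]]$rmse < bins[[length(bins) - 1L]]$rmse) {
    prev <- bins[[length(bins) - 1L]]
    idx <- seq.int(prev$from, n)
    bins[[length(bins) - 1L]] <- list(from = prev$from, to = n,
                                      n = length(idx),
                                      rmse = sqrt(mean(e2[idx])))
    bins[[length(bins)]] <- NULL
  }

  out <- do.call(rbind, lapply(seq_along(bins), function(k) {
    b <- bins[[k]]
    data.frame(bin = k, dm_min = d[b$from], dm_max = d[b$to], n = b$n,
               rmse = b$rmse)
  }))
  structure(out, class = c("bba_bins", "data.frame"),
            min_bin_size = as.integer(min_bin_size), n_fit = n,
            dm_range = range(d))
}

#' @export
print.bba_bins <- function(x, ...) {
  cat(sprintf("BBA bins: %d bins over %d compounds (min size %d)\n",
              nrow(x), attr(x, "n_fit"), attr(x, "min_bin_size")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

# Map DM values onto fitted bins by the bins' upper edges; values outside the
# fitted range fall into the nearest terminal bin.
assign_bins <- function(dm, bins) {
  if (nrow(bins) == 1L) return(rep(1L, length(dm)))
  findInterval(dm, bins$dm_max[-nrow(bins)], left.open = TRUE) + 1L
}

#' Flag uncertainty-calibrated outliers
#'
#' Applies the bin-wise error thresholds from [fit_bins()]: each compound's
#' threshold is `z` times the RMSE of its DM bin, and the compound is flagged
#' when its absolute error strictly exceeds that threshold. Compounds with DM
#' outside the fitted range are assigned to the nearest terminal bin (with a
#' message). The summary reports RMSE of the full, flagged, and clean sets,
#' and the clean-set coefficient of determination when `y_exp`/`y_pred` are
#' supplied.
#'
#' @inheritParams fit_bins
#' @param bins a `"bba_bins"` object fitted on the same DM scale.
#' @param z threshold multiplier: flag errors beyond `z` times the bin RMSE.
#' @param y_exp,y_pred optional activity vectors for clean-set Q2/R2.
#' @param ids optional compound identifiers.
#' @return an object of class `"outlier_report"`: list with `compounds`
#'   (per-compound DM, error, bin, threshold, flag -- the Williams-plot
#'   coordinates), `bins` (with a `threshold` column), `summary`, and `z`.
#' @export
flag_outliers <- function(dm, abs_error, bins, z = 3, y_exp = NULL,
                          y_pred = NULL, ids = NULL) {
  stopifnot(inherits(bins, "bba_bins"))
  if (length(dm) != length(abs_error)) {
    stop("dm and abs_error must have equal length", call. = FALSE)
  }
  check_number(z, "z", lower = 0)
  rng <- attr(bins, "dm_range")
  outside <- sum(dm < rng[1] | dm > rng[2])
  if (outside > 0) {
    message(outside, " compound(s) with DM outside the fitted range ",
            "assigned to the nearest terminal bin")
  }
  bin_idx <- assign_bins(dm, bins)
  threshold <- z * bins$rmse[bin_idx]
  flagged <- abs_error > threshold

  compounds <- data.frame(
    compound_id = ids %||% seq_along(dm),
    dm = dm, abs_error = abs_error, bin = bin_idx,
    threshold = threshold, flagged = flagged,
    stringsAsFactors = FALSE)

  bins_out <- as.data.frame(bins)
  bins_out$threshold <- z * bins_out$rmse

  summary <- list(
    n = length(dm),
    n_flagged = sum(flagged),
    rmse_full = sqrt(mean(abs_error^2)),
    rmse_outlier = if (any(flagged)) sqrt(mean(abs_error[flagged]^2))
                   else NA_real_,
    rmse_clean = if (any(!flagged)) sqrt(mean(abs_error[!flagged]^2))
                 else NA_real_)
  if (!is.null(y_exp) && !is.null(y_pred) && sum(!flagged) >= 2) {
    summary$q2_clean <- rsq(y_exp[!flagged], y_pred[!flagged])
  }

  structure(list(compounds = compounds, bins = bins_out, summary = summary,
                 z = z),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Outlier report (z = %g): %d of %d compounds flagged\n", x$z,
    s$n_flagged, s$n))
  cat(sprintf("  RMSE full %.2f%% | clean %.2f%% | outliers %.2f%%\n",
              s$rmse_full, s$rmse_clean, s$rmse_outlier))
  if (!is.null(s$q2_clean)) {
    cat(sprintf("  clean-set coefficient of determination: %.3f\n",
                s$q2_clean))
  }
  invisible(x)
}

#' Williams plot of an outlier report
#'
#' Absolute prediction error against the distance-to-model metric, with the
#' bin-averaged threshold drawn as a step line, flagged compounds in dark
#' red, and (optionally) the AD cutoff as a vertical line.
#'
#' @param x an `"outlier_report"`.
#' @param ad_cutoff optional DM cutoff from [ad_threshold()].
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.outlier_report <- function(x, ad_cutoff = NULL, ...) {
  cmp <- x$compounds
  graphics::plot(cmp$dm, cmp$abs_error,
                 col = ifelse(cmp$flagged, "darkred", "steelblue"),
                 pch = ifelse(cmp$flagged, 16, 3),
                 xlab = "distance to model (Consensus-STD, %)",
                 ylab = "absolute prediction error (%)", ...)
  b <- x$bins
  graphics::segments(b$dm_min, b$threshold, b$dm_max, b$threshold,
                     col = "red", lwd = 2)
  if (!is.null(ad_cutoff)) {
    graphics::abline(v = ad_cutoff, lty = 2)
  }
  invisible(x)
}

#' Applicability-domain cutoff from training DM values
#'
#' The DM value below which the requested fraction of the training set lies:
#' the `ceiling(coverage * n)`-th smallest training DM (empirical
#' order-statistic quantile). Compounds with DM at or below the cutoff are
#' considered inside the AD.
#'
#' @param training_dm DM values of the training compounds.
#' @param coverage fraction in (0, 1]; e.g. 0.9 for an AD covering 90% of
#'   the training set.
#' @return scalar DM cutoff.
#' @export
#' @examples
#' ad_threshold(1:100, 0.9) # 90
ad_threshold <- function(training_dm, coverage = 0.9) {
  if (!length(training_dm)) stop("empty DM vector", call. = FALSE)
  if (coverage <= 0 || coverage > 1) {
    stop("coverage must be in (0, 1]", call. = FALSE)
  }
  quantile_type1(training_dm, coverage)
}

#' Outliers shared across models
#'
#' Intersects per-model outlier flag sets: identifiers flagged by at least
#' `min_models` of the supplied sets. Compounds consistently flagged by
#' several independently built models are more likely true data problems
#' (measurement artifacts, activity cliffs) than model noise.
#'
#' @param flag_sets list of per-model vectors of flagged compound ids.
#' @param min_models minimum number of sets an id must appear in.
#' @return vector of ids flagged by at least `min_models` models.
#' @export
cross_model_outliers <- function(flag_sets, min_models = 3) {
  check_number(min_models, "min_models", lower = 1, integer = TRUE)
  ids <- unlist(lapply(flag_sets, unique), use.names = FALSE)
  if (!length(ids)) return(ids)
  counts <- table(ids)
  out <- names(counts)[counts >= min_models]
  if (is.numeric(flag_sets[[1]])) out <- as.numeric(out)
  out
}

#' Per-model BBA outlier scan with cross-model intersection
#'
#' Convenience pipeline over a full prediction table: for every model with a
#' `std_<m>` column, fits DM bins on that model's Consensus-STD and absolute
#' errors, flags outliers at multiplier `z`, and finally intersects the
#' per-model flag sets.
#'
#' @inheritParams build_consensus
#' @inheritParams fit_bins
#' @inheritParams flag_outliers
#' @param min_models minimum number of models that must flag a compound.
#' @param split optional split label(s) to restrict to (bins are typically
#'   fitted on training cross-validation predictions).
#' @return list with `per_model` (named list of `"outlier_report"`s) and
#'   `consensus_ids` (ids flagged by at least `min_models` models).
#' @export
ensemble_outlier_scan <- function(table, models = NULL, min_bin_size = 50,
                                  z = 3, min_models = 3, split = NULL) {
  models <- models %||% pt_models(table)
  if (!is.null(split)) table <- table[table$split %in% split, , drop = FALSE]
  std_cols <- paste0("std_", models)
  have_std <- std_cols %in% names(table)
  if (!any(have_std)) {
    stop("no std_* columns available for the BBA scan", call. = FALSE)
  }
  models <- models[have_std]
  reports <- list()
  for (m in models) {
    dm <- table[[paste0("std_", m)]]
    err <- abs(table$y_exp - table[[paste0("pred_", m)]])
    ok <- !is.na(dm) & !is.na(err)
    bins <- fit_bins(dm[ok], err[ok], min_bin_size = min_bin_size)
    reports[[m]] <- flag_outliers(dm[ok], err[ok], bins, z = z,
                                  ids = table$compound_id[ok])
  }
  flag_sets <- lapply(reports, function(r) {
    r$compounds$compound_id[r$compounds$flagged]
  })
  list(per_model = reports,
       consensus_ids = cross_model_outliers(flag_sets,
                                            min_models = min_models))
}
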