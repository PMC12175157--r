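# Substructure-conditional prediction-error significance: support filtering,
# a rescaled-error bootstrap null, directional p-values, and FDR control.

#' Drop substructure bits with low support
#'
#' Retains only bits present in at least `min_support` compounds of the
#' evaluation set; rarer substructures give too unstable an RMSE to test.
#'
#' @param matrix 0/1 compounds-by-bits matrix with column labels.
#' @param min_support minimum column sum.
#' @return the filtered matrix (possibly with zero columns).
#' @export
filter_support <- function(matrix, min_support = 32) {
  check_number(min_support, "min_support", lower = 1, integer = TRUE)
  matrix[, colSums(matrix) >= min_support, drop = FALSE]
}

# Bootstrap RMSE draws from a pool of squared errors, chunked to bound
# memory.
boot_rmse_draws <- function(pool, n_sub, n_boot) {
  out <- numeric(n_boot)
  done <- 0L
  chunk <- max(1L, as.integer(5e6 %/% n_sub))
  while (done < n_boot) {
    k <- min(chunk, n_boot - done)
    m <- matrix(sample(pool, k * n_sub, replace = TRUE), nrow = k)
    out[done + seq_len(k)] <- sqrt(rowMeans(m))
    done <- done + k
  }
  out
}

#' Bootstrap p-values for a substructure's prediction error
#'
#' Tests whether the compounds carrying a substructure are predicted better
#' or worse than the evaluation set as a whole. The subset RMSE
#' (`rmse_sub`) is computed from the unadjusted subset; the null hypothesis
#' "the substructure does not affect prediction quality" is simulated by
#' rescaling each subset squared error by `(rmse_overall / rmse_sub)^2` so
#' the adjusted subset RMSE equals the overall RMSE, then drawing `n_boot`
#' bootstrap resamples of the subset size and recording their RMSEs
#' (`RMSE_bs`). The improvement p-value is the fraction of `RMSE_bs` strictly
#' below `rmse_sub`; the degradation p-value the fraction strictly above.
#'
#' @param squared_errors squared prediction errors of the full evaluation
#'   set.
#' @param subset_mask logical vector marking the compounds carrying the
#'   substructure; must select at least one compound.
#' @param n_boot number of bootstrap resamples.
#' @param seed optional seed.
#' @param source `"subset"` (default) resamples from the adjusted subset
#'   errors; `"full"` resamples the subset size from the full error pool
#'   (whose RMSE is the overall RMSE by definition, so no adjustment is
#'   applied).
#' @return list with `p_improvement`, `p_degradation`, `rmse_sub`,
#'   `rmse_overall`, `n_sub`.
#' @export
substructure_pvalues <- function(squared_errors, subset_mask, n_boot = 1e5,
                                 seed = NULL,
                                 source = c("subset", "full")) {
  source <- match.arg(source)
  check_number(n_boot, "n_boot", lower = 1, integer = TRUE)
  if (length(subset_mask) != length(squared_errors)) {
    stop("subset_mask must match squared_errors", call. = FALSE)
  }
  if (!any(subset_mask)) stop("empty substructure subset", call. = FALSE)
  if (any(squared_errors < 0)) {
    stop("squared errors must be non-negative", call. = FALSE)
  }
  n_sub <- sum(subset_mask)
  rmse_overall <- sqrt(mean(squared_errors))
  rmse_sub <- sqrt(mean(squared_errors[subset_mask]))

  if (rmse_sub == 0 && rmse_overall > 0) {
    warning("subset RMSE is zero: degenerate null, p_improvement = 0",
            call. = FALSE)
    return(list(p_improvement = 0, p_degradation = 1, rmse_sub = rmse_sub,
                rmse_overall = rmse_overall, n_sub = n_sub))
  }

  pool <- if (source == "subset") {
    scale <- if (rmse_sub > 0) (rmse_overall / rmse_sub)^2 else 1
    squared_errors[subset_mask] * scale
  } else {
    squared_errors
  }
  bs <- with_local_seed(seed, boot_rmse_draws(pool, n_sub, n_boot))
  list(p_improvement = mean(bs < rmse_sub),
       p_degradation = mean(bs > rmse_sub),
       rmse_sub = rmse_sub, rmse_overall = rmse_overall, n_sub = n_sub)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate (a
#' validated front end to [stats::p.adjust()]), capped at 1 and monotone
#' after sorting.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04, 0.8))
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Substructure-conditional error scan
#'
#' Full pipeline over a bit matrix aligned with an evaluated prediction
#' column: support filtering, per-bit bootstrap p-values (improvement and
#' degradation tails), direction assignment by the smaller one-sided
#' p-value, one Benjamini-Hochberg pass over the per-bit `p_min`, and a
#' significance call at the requested FDR. Per-bit bootstrap seeds are
#' derived from the master seed and the bit label, so results are invariant
#' to the column order of the matrix.
#'
#' @param table prediction table (or `"consensus_result"`) containing
#'   `y_exp` and the evaluated prediction column, aligned row-by-row with
#'   `bits`.
#' @param bits 0/1 compounds-by-bits matrix with column labels.
#' @param column name of the prediction column to evaluate (e.g.
#'   `"consensus"` or `"pred_m1"`).
#' @param min_support support filter threshold.
#' @param n_boot bootstrap resamples per bit.
#' @param fdr false-discovery-rate level for the significance call.
#' @param seed master seed for the per-bit bootstraps.
#' @param source resampling source, see [substructure_pvalues()].
#' @return a `data.frame` of class `"substructure_scan"`: one row per
#'   retained bit with `bit`, `support`, `rmse_sub`, `rmse_overall`,
#'   `p_improvement`, `p_degradation`, `direction`, `p_min`, `p_bh`,
#'   `significant`, sorted by `p_bh`.
#' @export
run_substructure_scan <- function(table, bits, column = "consensus",
                                  min_support = 32, n_boot = 1e5,
                                  fdr = 0.05, seed = 1L,
                                  source = c("subset", "full")) {
  source <- match.arg(source)
  if (!column %in% names(table)) {
    stop("prediction column not found: ", column, call. = FALSE)
  }
  if (nrow(bits) != nrow(table)) {
    stop("bit matrix rows do not align with the evaluation table",
         call. = FALSE)
  }
  check_number(fdr, "fdr", lower = 0, upper = 1)
  keep <- !is.na(table[[column]]) & !is.na(table$y_exp)
  se <- (table$y_exp[keep] - table[[column]][keep])^2
  bits <- bits[keep, , drop = FALSE]
  kept <- filter_support(bits, min_support)

  rows <- lapply(colnames(kept), function(label) {
    mask <- kept[, label] == 1
    pv <- substructure_pvalues(se, mask, n_boot = n_boot,
                               seed = derive_seed(seed, label),
                               source = source)
    data.frame(bit = label, support = sum(mask), rmse_sub = pv$rmse_sub,
               rmse_overall = pv$rmse_overall,
               p_improvement = pv$p_improvement,
               p_degradation = pv$p_degradation,
               direction = if (pv$p_improvement <= pv$p_degradation)
                 "improvement" else "degradation",
               p_min = min(pv$p_improvement, pv$p_degradation),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bit = character(0), support = integer(0),
               rmse_sub = numeric(0), rmse_overall = numeric(0),
               p_improvement = numeric(0), p_degradation = numeric(0),
               direction = character(0), p_min = numeric(0),
               stringsAsFactors = FALSE)
  out$p_bh <- if (nrow(out)) bh_adjust(out$p_min) else numeric(0)
  out$significant <- out$p_bh < fdr
  out <- out[order(out$p_bh, out$p_min, out$bit), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("substructure_scan", "data.frame"),
            min_support = min_support, n_boot = n_boot, fdr = fdr,
            seed = seed, column = column, source = source)
}

#' @export
print.substructure_scan <- function(x, ...) {
  cat(sprintf(
    "Substructure scan of '%s': %d bits tested (support >= %d), %d significant at FDR %.2g\n",
    attr(x, "column"), nrow(x), attr(x, "min_support"), sum(x$significant),
    attr(x, "fdr")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
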