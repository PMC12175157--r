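# Consensus averaging across model ensembles, with and without
# applicability-domain constraints, plus the AD stringency sweep and
# Grubbs-refined averaging.

#' Build a consensus prediction
#'
#' Unweighted averaging of per-model predictions. Mode `"I"` averages all
#' non-missing predictions for each compound. Mode `"II"` averages only the
#' predictions of models whose applicability domain (AD) contains the
#' compound, and defines the consensus only where at least `min_models`
#' models cover it (default 1: inside the consensus AD as soon as one
#' contributing model claims the compound). The cross-model standard
#' deviation of the averaged predictions is reported alongside.
#'
#' A model with a missing prediction for a compound is treated as not
#' covering it in either mode. Compounds with no usable prediction are
#' dropped with a message in mode I and carry `NA` in mode II.
#'
#' @param table prediction table (see [read_prediction_table()] or
#'   [generate_dataset()]).
#' @param mode `"I"` (ignore ADs) or `"II"` (AD-restricted).
#' @param min_models minimum number of covering models for a mode-II
#'   consensus to be defined.
#' @param models optional character subset of model names to average.
#' @return a `data.frame` of class `"consensus_result"` with columns
#'   `compound_id`, `y_exp`, `split`, `n_models_used`, `consensus`,
#'   `consensus_std`; attributes record the mode and settings.
#'   Methods: [print()], [summary()], [predict()], [residuals()].
#' @export
#' @examples
#' tab <- data.frame(compound_id = "a", y_exp = 25, split = "test",
#'                   pred_m1 = 10, pred_m2 = 20, pred_m3 = 30)
#' build_consensus(tab)$consensus # 20
build_consensus <- function(table, mode = c("I", "II"), min_models = 1,
                            models = NULL) {
  mode <- match.arg(mode)
  check_number(min_models, "min_models", lower = 1, integer = TRUE)
  models <- models %||% pt_models(table)
  if (!length(models)) stop("no prediction columns found", call. = FALSE)
  pred <- pt_pred_matrix(table, models)

  use <- !is.na(pred)
  if (mode == "II") {
    use <- use & pt_ad_matrix(table, models)
  }
  n_used <- rowSums(use)
  psum <- rowSums(pred * use, na.rm = TRUE)
  consensus <- ifelse(n_used > 0, psum / n_used, NA_real_)
  # sample SD of the predictions entering each average
  ssq <- rowSums((pred - consensus)^2 * use, na.rm = TRUE)
  cons_std <- ifelse(n_used > 1, sqrt(ssq / (n_used - 1)), NA_real_)

  defined_min <- if (mode == "II") min_models else 1L
  consensus[n_used < defined_min] <- NA_real_
  cons_std[n_used < defined_min] <- NA_real_

  out <- data.frame(compound_id = table$compound_id,
                    y_exp = table$y_exp,
                    split = table$split,
                    n_models_used = n_used,
                    consensus = consensus,
                    consensus_std = cons_std,
                    stringsAsFactors = FALSE)
  if (mode == "I") {
    drop <- which(n_used == 0)
    if (length(drop)) {
      message(length(drop), " compound(s) without any model prediction ",
              "excluded from the consensus")
      out <- out[-drop, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  structure(out,
            class = c("consensus_result", "data.frame"),
            mode = mode, min_models = as.integer(min_models),
            models = models)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus %s over %d models (min_models = %d)\n",
              attr(x, "mode"), length(attr(x, "models")),
              attr(x, "min_models")))
  def <- sum(!is.na(x$consensus))
  cat(sprintf("  %d/%d compounds with a defined consensus (%.1f%% coverage)\n",
              def, nrow(x), 100 * def / nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
summary.consensus_result <- function(object, ...) {
  out <- list()
  for (sp in intersect(SPLIT_LEVELS, unique(object$split))) {
    rows <- object$split == sp & !is.na(object$consensus)
    if (sum(rows) >= 2) {
      out[[sp]] <- metric_report(object$y_exp[rows], object$consensus[rows],
                                 label = if (sp == "train") "train_cv"
                                         else "test")
    }
  }
  structure(out, class = "summary.consensus_result")
}

#' @export
print.summary.consensus_result <- function(x, ...) {
  for (sp in names(x)) {
    cat(sprintf("%-12s", sp))
    print(x[[sp]])
  }
  invisible(x)
}

#' @export
#' @rdname build_consensus
#' @param object a `"consensus_result"`.
#' @param newdata a prediction table with the same model columns.
#' @param ... unused.
predict.consensus_result <- function(object, newdata, ...) {
  res <- build_consensus(newdata, mode = attr(object, "mode"),
                         min_models = attr(object, "min_models"),
                         models = attr(object, "models"))
  res$consensus[match(newdata$compound_id, res$compound_id)]
}

#' @export
residuals.consensus_result <- function(object, ...) {
  object$y_exp - object$consensus
}

#' Applicability-domain stringency sweep
#'
#' Re-evaluates the mode-II consensus while progressively raising the minimum
#' number of models whose AD must contain a compound, tracing the trade-off
#' between reliability (RMSE, R-squared on the covered subset) and coverage
#' (percent of compounds with a defined consensus). Coverage is
#' non-increasing in `min_models` by construction.
#'
#' @inheritParams build_consensus
#' @param min_models integer vector of stringency levels; defaults to
#'   `2:n_models`.
#' @param split optional split label to evaluate on (e.g. `"test"`); default
#'   uses all compounds.
#' @return a `data.frame` of class `"stringency_sweep"` with `min_models`,
#'   `n_covered`, `coverage` (%), `r2`, `rmse`. Levels with an empty covered
#'   set carry coverage 0 and `NA` metrics.
#' @export
stringency_sweep <- function(table, min_models = NULL, split = NULL,
                             models = NULL) {
  models <- models %||% pt_models(table)
  pt_ad_matrix(table, models) # validates AD availability for every model
  if (is.null(min_models)) {
    min_models <- if (length(models) >= 2) seq(2L, length(models)) else 1L
  }
  if (!is.null(split)) table <- table[table$split %in% split, , drop = FALSE]
  n_total <- nrow(table)
  rows <- lapply(min_models, function(k) {
    cons <- build_consensus(table, mode = "II", min_models = k,
                            models = models)
    ok <- !is.na(cons$consensus)
    if (sum(ok) >= 2 && stats::var(cons$y_exp[ok]) > 0) {
      data.frame(min_models = k, n_covered = sum(ok),
                 coverage = 100 * sum(ok) / n_total,
                 r2 = rsq(cons$y_exp[ok], cons$consensus[ok]),
                 rmse = rmse(cons$y_exp[ok], cons$consensus[ok]))
    } else {
      data.frame(min_models = k, n_covered = sum(ok),
                 coverage = 100 * sum(ok) / n_total,
                 r2 = NA_real_, rmse = NA_real_)
    }
  })
  structure(do.call(rbind, rows),
            class = c("stringency_sweep", "data.frame"), models = models)
}

#' Grubbs-refined consensus
#'
#' Per compound, applies the single-outlier two-sided Grubbs test to the
#' model predictions; if one prediction is flagged as deviating it is
#' excluded and the remainder averaged, otherwise the plain mode-I mean is
#' used. With fewer than 3 models the test is undefined and the function
#' falls back to mode I with a warning.
#'
#' @inheritParams build_consensus
#' @param alpha significance level of the Grubbs test.
#' @return a `"consensus_result"`; its `mode` attribute is `"I+grubbs"`.
#' @export
grubbs_refined_consensus <- function(table, alpha = 0.1, models = NULL) {
  models <- models %||% pt_models(table)
  if (length(models) < 3) {
    warning("fewer than 3 models: Grubbs refinement undefined, ",
            "falling back to consensus mode I", call. = FALSE)
    return(build_consensus(table, mode = "I", models = models))
  }
  pred <- pt_pred_matrix(table, models)
  n <- nrow(pred)
  consensus <- rep(NA_real_, n)
  cons_std <- rep(NA_real_, n)
  n_used <- integer(n)
  for (i in seq_len(n)) {
    p <- pred[i, ]
    p <- p[!is.na(p)]
    if (!length(p)) next
    if (length(p) >= 3) {
      flagged <- grubbs_index(p, alpha)
      if (length(flagged)) p <- p[-flagged]
    }
    n_used[i] <- length(p)
    consensus[i] <- mean(p)
    cons_std[i] <- if (length(p) > 1) stats::sd(p) else NA_real_
  }
  out <- data.frame(compound_id = table$compound_id, y_exp = table$y_exp,
                    split = table$split, n_models_used = n_used,
                    consensus = consensus, consensus_std = cons_std,
                    stringsAsFactors = FALSE)
  drop <- which(n_used == 0)
  if (length(drop)) {
    message(length(drop), " compound(s) without any model prediction ",
            "excluded from the consensus")
    out <- out[-drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("consensus_result", "data.frame"),
            mode = "I+grubbs", min_models = 1L, models = models,
            alpha = alpha)
}
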