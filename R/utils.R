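# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x))) {
    stop_field(field, sprintf("must be %d finite numeric value(s)", len))
  }
  if (any(x < lower) || any(x > upper)) {
    stop_field(field, sprintf("must lie in [%s, %s]", lower, upper))
  }
  if (integer && any(x != round(x))) stop_field(field, "must be integral")
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps all package randomness flowing from explicit seeds without clobbering
# the global stream. A NULL seed uses (and advances) the current stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic stream seed from a master seed and a string label, so that
# per-item analyses (e.g. per-substructure bootstraps) are invariant to item
# order. Result is kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer((h + as.numeric(seed)) %% 2147483629)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (`2.65 -> 2.7`), the
#' convention used for displayed enrichment factors. Base R's [round()]
#' rounds half to even, which differs on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, half away from zero.
#' @export
#' @examples
#' round_half_up(c(2.55, 2.65), 1)
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Empirical order-statistic quantile (type 1): the ceiling(p * n)-th smallest
# value. Reproducible without interpolation ambiguity.
quantile_type1 <- function(x, p) {
  n <- length(x)
  sort(x)[max(1L, ceiling(p * n))]
}

# Model names inferred from pred_* columns of a prediction table.
pt_models <- function(table) {
  sub("^pred_", "", grep("^pred_", names(table), value = TRUE))
}

pt_pred_matrix <- function(table, models) {
  as.matrix(table[paste0("pred_", models)])
}

pt_ad_matrix <- function(table, models) {
  cols <- paste0("in_ad_", models)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("applicability-domain flags missing for model(s): ",
         paste(sub("^in_ad_", "", missing_cols), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(table[cols])
  mode(m) <- "logical"
  m
}
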