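#' Configuration for the synthetic prediction-ensemble generator
#'
#' Builds and validates the parameter set for [generate_dataset()]. The
#' defaults emulate the statistical structure of a multi-team consensus
#' evaluation on a percent-displacement binding assay: 1512 compounds whose
#' activities concentrate in the 0--30% region of the -41.6..110.9% range,
#' nine models with correlated heteroscedastic errors, per-model sub-ensembles
#' whose spread yields a Consensus-STD (the distance-to-model metric), AD
#' masks, planted low-STD/high-error outliers, and binary substructure /
#' fingerprint matrices.
#'
#' @param n_compounds number of compounds.
#' @param n_models number of prediction models (columns `pred_m1` ...).
#' @param n_submodels_per_model sub-ensemble size per model; the per-compound
#'   sample SD of the sub-model predictions is reported as `std_<m>`.
#' @param activity_mixture list with `weights`, `means`, `sds` of a truncated
#'   normal mixture on the activity axis (% units). Weights must sum to 1.
#' @param activity_range closed interval (% units) the activities are
#'   truncated to.
#' @param error_sd_base baseline per-model prediction error SD (% units) for
#'   an in-domain compound of unit difficulty.
#' @param error_correlation pairwise correlation of the models' error vectors
#'   (through a shared latent error term), in `[0, 1]`.
#' @param submodel_spread baseline SD (% units) of the sub-model predictions
#'   around their model's centre; scales with compound difficulty, making the
#'   Consensus-STD informative about the local error level.
#' @param difficulty_sdlog log-SD of the lognormal within-component spread of
#'   the per-compound difficulty factor.
#' @param ood_fraction fraction of compounds drawn from the "out-of-domain"
#'   difficulty component (elevated error and Consensus-STD).
#' @param ood_difficulty multiplicative difficulty of the out-of-domain
#'   component relative to in-domain compounds.
#' @param outlier_fraction expected fraction of planted outliers (per-compound
#'   Bernoulli, so the realised count is binomial).
#' @param outlier_error_shift magnitude (% units) added to the experimental
#'   activity of planted outliers. Their predictions are untouched, so every
#'   model's error grows by the shift while the Consensus-STD stays at
#'   baseline: the low-STD / high-error signature of suspect measurements.
#' @param n_substructure_bits number of binary substructure bits.
#' @param planted_effect_bits list of `list(bit =, multiplier =, support =)`
#'   entries; compounds carrying a planted bit have their error SD multiplied
#'   by `multiplier`. `support` (optional) fixes the exact number of carriers.
#' @param ad_coverage_per_model fraction(s) in (0, 1] of compounds inside each
#'   model's AD; scalar or length-`n_models` vector. Membership is the
#'   low-STD quantile of that model's Consensus-STD.
#' @param fingerprint_bits width of the hashed fingerprint matrix.
#' @param fingerprint_density_range range of per-bit Bernoulli densities for
#'   the fingerprint matrix.
#' @param seed master seed; all generator randomness flows from it.
#' @return a validated list of class `"synthetic_config"`.
#' @seealso [generate_dataset()], [split_dataset()]
#' @export
synthetic_config <- function(n_compounds = 1512,
                             n_models = 9,
                             n_submodels_per_model = 10,
                             activity_mixture = list(weights = c(0.8, 0.2),
                                                     means = c(15, 60),
                                                     sds = c(10, 25)),
                             activity_range = c(-41.6, 110.9),
                             error_sd_base = 15,
                             error_correlation = 0.5,
                             submodel_spread = 12,
                             difficulty_sdlog = 0.25,
                             ood_fraction = 0.2,
                             ood_difficulty = 2,
                             outlier_fraction = 0.04,
                             outlier_error_shift = 45,
                             n_substructure_bits = 200,
                             planted_effect_bits = list(),
                             ad_coverage_per_model = 0.9,
                             fingerprint_bits = 1024,
                             fingerprint_density_range = c(0.01, 0.1),
                             seed = 1L) {
  check_number(n_compounds, "n_compounds", lower = 1, integer = TRUE)
  check_number(n_models, "n_models", lower = 1, integer = TRUE)
  check_number(n_submodels_per_model, "n_submodels_per_model",
               lower = 2, integer = TRUE)
  if (!is.list(activity_mixture) ||
      !all(c("weights", "means", "sds") %in% names(activity_mixture))) {
    stop_field("activity_mixture", "must list weights, means and sds")
  }
  k <- length(activity_mixture$weights)
  check_number(activity_mixture$weights, "activity_mixture$weights",
               lower = 0, len = k)
  check_number(activity_mixture$means, "activity_mixture$means", len = k)
  check_number(activity_mixture$sds, "activity_mixture$sds",
               lower = 1e-12, len = k)
  if (abs(sum(activity_mixture$weights) - 1) > 1e-8) {
    stop_field("activity_mixture$weights", "must sum to 1")
  }
  check_number(activity_range, "activity_range", len = 2)
  if (diff(activity_range) <= 0) {
    stop_field("activity_range", "must be an increasing interval")
  }
  check_number(error_sd_base, "error_sd_base", lower = 0)
  check_number(error_correlation, "error_correlation", lower = 0, upper = 1)
  check_number(submodel_spread, "submodel_spread", lower = 0)
  check_number(difficulty_sdlog, "difficulty_sdlog", lower = 0)
  check_number(ood_fraction, "ood_fraction", lower = 0, upper = 1)
  check_number(ood_difficulty, "ood_difficulty", lower = 1)
  check_number(outlier_fraction, "outlier_fraction", lower = 0, upper = 1)
  check_number(outlier_error_shift, "outlier_error_shift", lower = 0)
  if (outlier_error_shift >= diff(activity_range)) {
    stop_field("outlier_error_shift",
               "must be smaller than the activity range width")
  }
  check_number(n_substructure_bits, "n_substructure_bits",
               lower = 0, integer = TRUE)
  if (!is.list(planted_effect_bits)) {
    stop_field("planted_effect_bits", "must be a list")
  }
  for (pb in planted_effect_bits) {
    if (!is.list(pb) || is.null(pb$bit) || is.null(pb$multiplier)) {
      stop_field("planted_effect_bits",
                 "entries need 'bit' and 'multiplier' fields")
    }
    check_number(pb$bit, "planted_effect_bits$bit", lower = 1,
                 upper = n_substructure_bits, integer = TRUE)
    check_number(pb$multiplier, "planted_effect_bits$multiplier", lower = 0)
    if (!is.null(pb$support)) {
      check_number(pb$support, "planted_effect_bits$support", lower = 1,
                   upper = n_compounds, integer = TRUE)
    }
  }
  nc <- length(ad_coverage_per_model)
  if (!nc %in% c(1L, n_models)) {
    stop_field("ad_coverage_per_model", "must have length 1 or n_models")
  }
  check_number(ad_coverage_per_model, "ad_coverage_per_model",
               lower = 1e-12, upper = 1, len = nc)
  check_number(fingerprint_bits, "fingerprint_bits", lower = 1,
               integer = TRUE)
  check_number(fingerprint_density_range, "fingerprint_density_range",
               lower = 0, upper = 1, len = 2)
  check_number(seed, "seed", integer = TRUE)

  structure(list(
    n_compounds = as.integer(n_compounds),
    n_models = as.integer(n_models),
    n_submodels_per_model = as.integer(n_submodels_per_model),
    activity_mixture = activity_mixture,
    activity_range = activity_range,
    error_sd_base = error_sd_base,
    error_correlation = error_correlation,
    submodel_spread = submodel_spread,
    difficulty_sdlog = difficulty_sdlog,
    ood_fraction = ood_fraction,
    ood_difficulty = ood_difficulty,
    outlier_fraction = outlier_fraction,
    outlier_error_shift = outlier_error_shift,
    n_substructure_bits = as.integer(n_substructure_bits),
    planted_effect_bits = planted_effect_bits,
    ad_coverage_per_model = rep_len(ad_coverage_per_model, n_models),
    fingerprint_bits = as.integer(fingerprint_bits),
    fingerprint_density_range = fingerprint_density_range,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Truncated-mixture activity draws by rejection; the mixture mode sits in the
# low-activity region so most compounds fall in 0-30%.
sample_activity <- function(n, mix, range) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 64L)
    comp <- sample.int(length(mix$weights), m, replace = TRUE,
                       prob = mix$weights)
    y <- stats::rnorm(m, mix$means[comp], mix$sds[comp])
    out <- c(out, y[y >= range[1] & y <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic prediction ensemble
#'
#' Draws a complete synthetic data set with the statistical structure the
#' downstream consensus / outlier / substructure analyses assume: per-model
#' predictions formed as the mean of a sub-ensemble, Consensus-STD columns as
#' the sub-ensemble sample SD, AD flags, planted low-STD/high-error outliers
#' (the experimental activity is perturbed, not the predictions), and planted
#' substructure effects that multiply the local error SD.
#'
#' @param config a [synthetic_config()] object (or a list of arguments to it).
#' @return an object of class `"synthetic_qsar_data"`: a list with
#'   \describe{
#'     \item{table}{the prediction table (`compound_id`, `y_exp`, `split`,
#'       `pred_<m>`, `std_<m>`, `in_ad_<m>`).}
#'     \item{substructure}{0/1 compounds-by-bits matrix, columns `bit_1` ...}
#'     \item{fingerprints}{0/1 compounds-by-bits hashed fingerprint matrix.}
#'     \item{truth}{ground truth: `is_outlier`, `y_clean`, `difficulty`,
#'       `error_scale`, `submodel_preds` (compounds x models x sub-models
#'       array), and the planted bit effects.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_compounds = 100, n_models = 3,
#'                                         seed = 7))
#' dim(ds$table)
generate_dataset <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  cfg <- config
  n <- cfg$n_compounds
  M <- cfg$n_models
  K <- cfg$n_submodels_per_model

  with_local_seed(cfg$seed, {
    y_clean <- sample_activity(n, cfg$activity_mixture, cfg$activity_range)

    is_outlier <- stats::runif(n) < cfg$outlier_fraction
    # Planted outliers stay in-domain: their measurement is suspect, not
    # their chemistry, so the ensemble remains confidently (and wrongly)
    # in agreement.
    is_ood <- stats::runif(n) < cfg$ood_fraction & !is_outlier
    difficulty <- exp(stats::rnorm(n, 0, cfg$difficulty_sdlog)) *
      ifelse(is_ood, cfg$ood_difficulty, 1)

    # Substructure bits; planted-effect bits may have a fixed support.
    nb <- cfg$n_substructure_bits
    bits <- NULL
    if (nb > 0) {
      prevalence <- stats::runif(nb, 0.02, 0.2)
      bits <- matrix(0L, n, nb,
                     dimnames = list(NULL, paste0("bit_", seq_len(nb))))
      for (b in seq_len(nb)) {
        bits[stats::runif(n) < prevalence[b], b] <- 1L
      }
      for (pb in cfg$planted_effect_bits) {
        if (!is.null(pb$support)) {
          col <- integer(n)
          col[sample.int(n, pb$support)] <- 1L
          bits[, pb$bit] <- col
        }
      }
    }
    error_scale <- rep(1, n)
    for (pb in cfg$planted_effect_bits) {
      error_scale <- error_scale * pb$multiplier^bits[, pb$bit]
    }

    sd_i <- cfg$error_sd_base * difficulty * error_scale
    tau_i <- cfg$submodel_spread * difficulty * error_scale

    # The reported prediction (sub-ensemble mean) carries extra noise of
    # variance tau^2/K on top of the model-centre error, which attenuates
    # the between-model error correlation; inflate the shared-variance
    # fraction so the realized correlation of the final prediction errors
    # equals error_correlation.
    lambda <- if (cfg$error_sd_base > 0) {
      cfg$submodel_spread^2 /
        (cfg$n_submodels_per_model * cfg$error_sd_base^2)
    } else 0
    a <- min(1, cfg$error_correlation * (1 + lambda))

    shared <- stats::rnorm(n, 0, sd_i * sqrt(a))
    specific <- matrix(stats::rnorm(n * M), n, M) * (sd_i * sqrt(1 - a))
    centre <- y_clean + shared + specific

    sub <- array(stats::rnorm(n * M * K), dim = c(n, M, K)) * tau_i +
      as.vector(centre)
    pred <- rowMeans(sub, dims = 2)
    dev <- sub - as.vector(pred)
    std <- sqrt(rowSums(dev * dev, dims = 2) / (K - 1))

    # Perturb the experimental activity of planted outliers, choosing the
    # shift direction that stays inside the printed activity range.
    y_exp <- y_clean
    if (any(is_outlier)) {
      idx <- which(is_outlier)
      sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
      hi_ok <- y_clean[idx] + cfg$outlier_error_shift <= cfg$activity_range[2]
      lo_ok <- y_clean[idx] - cfg$outlier_error_shift >= cfg$activity_range[1]
      sgn[sgn > 0 & !hi_ok] <- -1
      sgn[sgn < 0 & !lo_ok] <- 1
      y_exp[idx] <- y_clean[idx] + sgn * cfg$outlier_error_shift
    }

    in_ad <- matrix(FALSE, n, M)
    for (m in seq_len(M)) {
      in_ad[, m] <- std[, m] <= quantile_type1(std[, m],
                                               cfg$ad_coverage_per_model[m])
    }

    fp <- matrix(0L, n, cfg$fingerprint_bits)
    fp_density <- stats::runif(cfg$fingerprint_bits,
                               cfg$fingerprint_density_range[1],
                               cfg$fingerprint_density_range[2])
    for (b in seq_len(cfg$fingerprint_bits)) {
      fp[stats::runif(n) < fp_density[b], b] <- 1L
    }
    colnames(fp) <- paste0("fp_", seq_len(cfg$fingerprint_bits))

    models <- paste0("m", seq_len(M))
    table <- data.frame(
      compound_id = sprintf("cmpd_%05d", seq_len(n)),
      y_exp = y_exp,
      split = "train",
      stringsAsFactors = FALSE
    )
    for (m in seq_len(M)) table[[paste0("pred_", models[m])]] <- pred[, m]
    for (m in seq_len(M)) table[[paste0("std_", models[m])]] <- std[, m]
    for (m in seq_len(M)) {
      table[[paste0("in_ad_", models[m])]] <- as.integer(in_ad[, m])
    }

    structure(list(
      table = table,
      substructure = bits,
      fingerprints = fp,
      truth = list(
        is_outlier = is_outlier,
        y_clean = y_clean,
        difficulty = difficulty,
        error_scale = error_scale,
        is_ood = is_ood,
        submodel_preds = sub,
        planted_effect_bits = cfg$planted_effect_bits
      ),
      config = cfg
    ), class = "synthetic_qsar_data")
  })
}

#' @export
print.synthetic_qsar_data <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic QSAR ensemble: %d compounds, %d models (x%d sub-models)\n",
    cfg$n_compounds, cfg$n_models, cfg$n_submodels_per_model))
  cat(sprintf("  planted outliers: %d; substructure bits: %d; seed: %d\n",
              sum(x$truth$is_outlier), cfg$n_substructure_bits, cfg$seed))
  cat(sprintf("  splits: %s\n",
              paste(names(table(x$table$split)), table(x$table$split),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Assign train / leaderboard / test labels
#'
#' Splits a data set into the three evaluation roles with sizes obtained
#' from the requested proportions by largest-remainder rounding, so
#' proportions `c(1012, 200, 300) / 1512` on 1512 compounds reproduce a
#' 1012/200/300 split exactly. Assignment is a seeded random permutation.
#'
#' @param ds a `"synthetic_qsar_data"` object or a prediction-table
#'   `data.frame`.
#' @param fractions positive weights for train / leaderboard / test; must sum
#'   to 1 (within 1e-8).
#' @param seed seed for the assignment permutation.
#' @return the input with its `split` column overwritten.
#' @export
split_dataset <- function(ds, fractions = c(train = 1012, leaderboard = 200,
                                            test = 300) / 1512,
                          seed = 1L) {
  check_number(fractions, "fractions", lower = 0, len = 3L)
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop_field("fractions", "must sum to 1")
  }
  table <- if (inherits(ds, "synthetic_qsar_data")) ds$table else ds
  n <- nrow(table)

  # Largest-remainder apportionment of n compounds to the three roles.
  raw <- fractions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }

  labels <- rep(c("train", "leaderboard", "test"), times = sizes)
  split <- with_local_seed(seed, labels[sample.int(n)])
  if (inherits(ds, "synthetic_qsar_data")) {
    ds$table$split <- split
    ds
  } else {
    ds$split <- split
    ds
  }
}
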