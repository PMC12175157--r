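# Reading and writing the delimited interchange formats: prediction tables,
# 0/1 bit matrices, run configurations, and result-table sets. Comma
# delimited, decimal point, UTF-8. Numeric payloads are written with 17
# significant digits so read/write round-trips are value-exact.

SPLIT_LEVELS <- c("train", "leaderboard", "test")

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
  sub("^\\s+", "", out)
}

format_table_for_write <- function(table) {
  out <- table
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- fmt_num(out[[nm]])
    } else if (is.logical(out[[nm]])) {
      out[[nm]] <- as.integer(out[[nm]])
    }
  }
  out
}

#' Read a prediction table
#'
#' Reads the delimited prediction-table format: required columns
#' `compound_id` (unique), `y_exp` (% activity) and `split` (one of `train`,
#' `leaderboard`, `test`), an optional `smiles` column, plus one `pred_<m>`
#' column per model with optional `std_<m>` (sub-ensemble SD, the
#' distance-to-model metric) and `in_ad_<m>` (0/1 applicability-domain flag)
#' companions. Model names are inferred from the `pred_*` columns; absent
#' `std`/`in_ad` columns are recorded as absent, never defaulted.
#'
#' @param path file path.
#' @return a `data.frame`; model names are recoverable from the `pred_*`
#'   columns.
#' @export
read_prediction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  required <- c("compound_id", "y_exp", "split")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("prediction table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- raw$compound_id[duplicated(raw$compound_id)]
  if (length(dup)) {
    stop("duplicate compound_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_split <- setdiff(unique(raw$split), SPLIT_LEVELS)
  if (length(bad_split)) {
    stop("unknown split label(s): ", paste(bad_split, collapse = ", "),
         call. = FALSE)
  }

  parse_num <- function(col, what) {
    x <- suppressWarnings(as.numeric(ifelse(raw[[col]] == "", NA, raw[[col]])))
    bad <- which(is.na(x) & raw[[col]] != "")
    if (length(bad)) {
      stop(sprintf("non-numeric %s in column '%s' at row(s) %s", what, col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    x
  }

  out <- data.frame(compound_id = raw$compound_id, stringsAsFactors = FALSE)
  if ("smiles" %in% names(raw)) out$smiles <- raw$smiles
  out$y_exp <- parse_num("y_exp", "activity")
  if (anyNA(out$y_exp)) {
    stop("non-numeric activity: empty y_exp at row(s) ",
         paste(which(is.na(out$y_exp)), collapse = ", "), call. = FALSE)
  }
  out$split <- raw$split
  for (col in grep("^(pred|std)_", names(raw), value = TRUE)) {
    out[[col]] <- parse_num(col, "value")
    if (grepl("^std_", col) && any(out[[col]] < 0, na.rm = TRUE)) {
      stop("negative ensemble STD in column '", col, "'", call. = FALSE)
    }
  }
  for (col in grep("^in_ad_", names(raw), value = TRUE)) {
    x <- parse_num(col, "flag")
    if (!all(x %in% c(0, 1) | is.na(x))) {
      stop("AD flag column '", col, "' must be 0/1", call. = FALSE)
    }
    out[[col]] <- as.integer(x)
  }
  models <- pt_models(out)
  if (!length(models)) {
    stop("prediction table has no pred_* columns", call. = FALSE)
  }
  out
}

#' Write a prediction table
#'
#' Inverse of [read_prediction_table()]; numeric values are written with 17
#' significant digits so the round-trip is value-exact.
#'
#' @param table a prediction-table `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(table, path) {
  utils::write.csv(format_table_for_write(table), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a 0/1 bit matrix
#'
#' Delimited text with a `compound_id` first column and one column per bit;
#' the header row carries the bit labels.
#'
#' @param mat integer 0/1 matrix with column names; row identity is carried
#'   by `ids`.
#' @param ids compound identifiers, one per row.
#' @param path file path.
#' @return `write_bit_matrix()` returns `path` invisibly;
#'   `read_bit_matrix()` returns a 0/1 integer matrix with `compound_id`
#'   row names.
#' @export
write_bit_matrix <- function(mat, ids, path) {
  if (length(ids) != nrow(mat)) {
    stop("ids must match the matrix rows", call. = FALSE)
  }
  df <- data.frame(compound_id = ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_bit_matrix
#' @export
read_bit_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (names(df)[1] != "compound_id") {
    stop("bit matrix must start with a compound_id column", call. = FALSE)
  }
  m <- as.matrix(df[-1])
  if (!all(m %in% c(0L, 1L))) stop("bit matrix entries must be 0/1",
                                   call. = FALSE)
  mode(m) <- "integer"
  rownames(m) <- df$compound_id
  m
}

#' Read / write a run configuration
#'
#' YAML key/value files mirroring [synthetic_config()] plus optional
#' per-stage parameter blocks. The `synthetic` block (or a flat file) is
#' validated through [synthetic_config()].
#'
#' @param path YAML file path.
#' @param config list to serialise.
#' @return `read_run_config()` returns a list; if a `synthetic` block is
#'   present it is replaced by a validated `"synthetic_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$synthetic)) {
    cfg$synthetic <- do.call(synthetic_config, cfg$synthetic)
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' Write a set of result tables
#'
#' One delimited file per result table (consensus, stringency sweep, bins,
#' outliers, substructures, enrichment, similarity, ...), each with a header
#' and the table's column order. Re-running with identical inputs yields
#' byte-identical files.
#'
#' @param tables named list of `data.frame`s (classed results are accepted;
#'   they are written as their underlying tables).
#' @param out_dir output directory, created if needed.
#' @return character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  if (!length(tables)) return(invisible(character(0)))
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("'tables' must be a fully named list", call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (inherits(tab, "outlier_report")) tab <- tab$compounds
    if (inherits(tab, "similarity_summary")) tab <- tab$per_compound
    tab <- as.data.frame(tab)
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(format_table_for_write(tab), path, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Approximate functional-group pattern table
#'
#' Loads the bundled table of named substructure patterns (SMARTS strings)
#' for the functional-group enrichment analysis. The patterns are
#' approximate, generic definitions supplied for convenience; matching them
#' against structures requires external chemistry tooling, and the enrichment
#' functions themselves operate on precomputed membership masks.
#'
#' @param path pattern file; defaults to the bundled table.
#' @return `data.frame` with `group`, `smarts`, `note` columns.
#' @export
read_group_patterns <- function(path = system.file("extdata",
                                                   "functional_groups_approx.csv",
                                                   package = "qsarcons")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
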