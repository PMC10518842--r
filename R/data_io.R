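#' Canonical indicator names
#'
#' The twelve plot-level forest-health indicators, in canonical order:
#' disturbance level (IL), slope direction and slope (SDS), mean diameter at
#' breast height (DBH), tree height (TH), east-west and north-south crown
#' widths (CWEW, CWNS), soil impact index (SNI), fire risk index (FRI), the
#' Menhinick richness, Pielou evenness and Gleason diversity indices, and
#' plot elevation.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' fh_indicators()
fh_indicators <- function() {
  c("IL", "SDS", "DBH", "TH", "CWEW", "CWNS",
    "SNI", "FRI", "Menhinick", "Pielou", "Gleason", "Elevation")
}

#' Health class labels
#'
#' Ordered labels for the four forest health classes: unhealthy (UHF, code
#' 0), sub-healthy (SHF, 1), healthy (HF, 2) and very healthy (VHF, 3).
#'
#' @return Character vector of length 4, worst to best.
#' @export
fh_classes <- function() c("UHF", "SHF", "HF", "VHF")

# case-insensitive column lookup; returns index vector named by `wanted`
.match_cols <- function(have, wanted, context = "input") {
  idx <- match(tolower(wanted), tolower(have))
  if (anyNA(idx)) {
    stop(sprintf("%s is missing required column(s): %s", context,
                 paste(wanted[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  names(idx) <- wanted
  idx
}

#' Read stem-level tree survey records
#'
#' Reads a CSV of individual surveyed stems (one row per tree or shrub) and
#' applies the survey's minimum-diameter rule: stems with diameter at breast
#' height below \code{min_dbh} are excluded, mirroring the field protocol of
#' tagging every woody stem with DBH >= 1.0 cm in a 400 m2 plot.
#'
#' Required columns (matched case-insensitively): \code{plot_id},
#' \code{stratum} (\code{"primary"} or \code{"secondary"}), \code{species},
#' \code{dbh} (cm), \code{height} (m), \code{crown_ew}, \code{crown_ns} (m).
#'
#' @param path Path to a CSV file.
#' @param min_dbh Minimum diameter at breast height to retain, in cm.
#'   Default 1.0; use 0 to keep every parseable row.
#' @return A data frame of tree records in input order, one row per retained
#'   stem. The number of excluded stems is reported with a message.
#' @export
read_tree_records <- function(path, min_dbh = 1.0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  wanted <- c("plot_id", "stratum", "species", "dbh", "height",
              "crown_ew", "crown_ns")
  idx <- .match_cols(names(raw), wanted, context = basename(path))
  df <- raw[, idx, drop = FALSE]
  names(df) <- wanted

  if (nrow(df) == 0L) {
    warning("no data rows in ", basename(path), call. = FALSE)
    return(df)
  }

  for (col in c("dbh", "height", "crown_ew", "crown_ns")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad)) {
      stop(sprintf("non-numeric %s at data row %d: '%s'",
                   col, bad[1], df[[col]][bad[1]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  bad_stratum <- setdiff(unique(df$stratum), c("primary", "secondary"))
  if (length(bad_stratum)) {
    stop("unknown stratum value(s): ", paste(bad_stratum, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(df$species) & df$species == "")) {
    stop("empty species name in ", basename(path), call. = FALSE)
  }

  keep <- !is.na(df$dbh) & df$dbh >= min_dbh
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("read_tree_records: excluded %d record(s) with dbh < %g cm",
                    n_drop, min_dbh))
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a plot-by-indicator table
#'
#' Reads a CSV with one row per plot and the twelve forest-health indicator
#' columns (see \code{\link{fh_indicators}}), plus \code{plot_id} and
#' \code{stratum}. Column matching is case-insensitive and order-free; the
#' returned table always carries the indicators in canonical order.
#'
#' @param path Path to a CSV file.
#' @param na_action What to do with rows containing missing indicator
#'   values: \code{"drop"} (default; dropped rows are counted in a message)
#'   or \code{"error"}.
#' @return An \code{indicator_table}: a data frame with columns
#'   \code{plot_id}, \code{stratum} and the 12 indicators.
#' @export
read_indicator_table <- function(path, na_action = c("drop", "error")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  idx <- .match_cols(names(raw), c("plot_id", "stratum", fh_indicators()),
                     context = basename(path))
  df <- raw[, idx, drop = FALSE]
  names(df) <- c("plot_id", "stratum", fh_indicators())
  as_indicator_table(df, na_action = na_action)
}

#' Build an indicator table from a data frame
#'
#' Validates plot ids (unique), stratum labels and indicator completeness,
#' and orders the indicator columns canonically.
#'
#' @param df Data frame with \code{plot_id}, \code{stratum} and the 12
#'   indicator columns.
#' @param na_action \code{"drop"} incomplete rows (logged) or \code{"error"}.
#' @return An \code{indicator_table} data frame.
#' @export
as_indicator_table <- function(df, na_action = c("drop", "error")) {
  na_action <- match.arg(na_action)
  idx <- .match_cols(names(df), c("plot_id", "stratum", fh_indicators()),
                     context = "indicator table")
  df <- df[, idx, drop = FALSE]
  names(df) <- c("plot_id", "stratum", fh_indicators())
  df$plot_id <- as.character(df$plot_id)

  dup <- df$plot_id[duplicated(df$plot_id)]
  if (length(dup)) {
    stop("duplicate plot_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$stratum), c("primary", "secondary"))
  if (length(bad)) {
    stop("unknown stratum value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (col in fh_indicators()) df[[col]] <- as.numeric(df[[col]])

  complete <- complete.cases(df[, fh_indicators()])
  if (!all(complete)) {
    if (na_action == "error") {
      stop(sum(!complete), " row(s) with missing indicator values",
           call. = FALSE)
    }
    message(sprintf("as_indicator_table: dropped %d incomplete row(s)",
                    sum(!complete)))
    df <- df[complete, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("indicator_table", "data.frame")
  df
}

#' Extract the numeric indicator matrix from an indicator table
#'
#' @param table An \code{indicator_table}.
#' @return Numeric matrix (plots x 12) with plot ids as row names.
#' @export
indicator_matrix <- function(table) {
  m <- as.matrix(table[, fh_indicators()])
  rownames(m) <- table$plot_id
  m
}

#' Write a pipeline product to disk
#'
#' Tabular products (data frames, CRITIC results) are written as CSV;
#' nested products (fitted trees, evaluation reports) as JSON. The matching
#' reader (\code{read.csv}, \code{\link{read_tree_model}},
#' \code{\link{read_eval_report}}) round-trips the structure.
#'
#' @param x Object to write.
#' @param path Output file path; the parent directory must exist.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(x, path) UseMethod("write_results")

#' @export
write_results.data.frame <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.critic_result <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.fh_tree <- function(x, path) {
  jsonlite::write_json(tree_to_list(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
write_results.eval_report <- function(x, path) {
  out <- list(
    confusion = unclass(x$confusion),
    per_class = x$per_class,
    macro = as.list(x$macro),
    auc_per_class = as.list(x$auc_per_class),
    auc_average = x$auc_average,
    n_test = x$n_test,
    split_seed = x$split_seed,
    train_fraction = x$train_fraction
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a serialized evaluation report
#'
#' @param path Path to a JSON file written by \code{\link{write_results}}.
#' @return An \code{eval_report} object.
#' @export
read_eval_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  conf <- as.matrix(raw$confusion)
  storage.mode(conf) <- "double"
  rep <- list(
    confusion = conf,
    per_class = as.data.frame(raw$per_class),
    macro = unlist(raw$macro),
    auc_per_class = unlist(raw$auc_per_class),
    auc_average = raw$auc_average,
    n_test = raw$n_test,
    split_seed = raw$split_seed,
    train_fraction = raw$train_fraction
  )
  class(rep) <- "eval_report"
  rep
}

#' Read a pipeline configuration file
#'
#' Configuration is YAML (or JSON) with optional top-level keys:
#' \code{input} (path to an indicator CSV, or \code{"simulate"}),
#' \code{tree_records} (path to a stem-level CSV), \code{plot_area},
#' \code{min_dbh}, \code{polarity} (named map indicator -> benefit/cost),
#' \code{scheme} (\code{quartile}/\code{fixed}), \code{thresholds},
#' \code{corr_kind}, \code{use_abs}, \code{criterion}, \code{max_depth},
#' \code{min_samples_split}, \code{train_fraction}, \code{stratify},
#' \code{per_stratum}, \code{seed}, and a \code{simulate} block forwarded
#' to \code{\link{simulation_config}}.
#'
#' @param path Path to a YAML or JSON config file.
#' @return Named list of settings.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
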