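# numeric feature matrix for CRITIC/CART: the canonical 12 when present,
# otherwise every numeric column except bookkeeping ones
.feature_matrix <- function(table) {
  if (inherits(table, "indicator_table")) return(indicator_matrix(table))
  drop <- c("plot_id", "stratum", "S", "n", "Shannon")
  keep <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], drop)
  m <- as.matrix(table[, keep, drop = FALSE])
  rownames(m) <- table$plot_id
  m
}

#' Run the full forest-health assessment pipeline
#'
#' Executes the assessment end to end: obtain the plot-by-indicator table
#' (from a CSV, from stem-level survey records via the diversity module,
#' or from the synthetic generator), derive CRITIC weights and the
#' composite FH score, assign the four health classes, fit an
#' interpretable classification tree (pooled, or one per stratum), and
#' evaluate it on a held-out split. All artifacts are written to
#' \code{output_dir} together with a JSON run manifest (config snapshot,
#' seed, package version, per-file MD5 digests, timestamps).
#'
#' @param input An \code{indicator_table}, a path to an indicator CSV, a
#'   data frame of tree records, or \code{"simulate"} (default) for the
#'   synthetic generator.
#' @param output_dir Directory for artifacts (created if needed);
#'   \code{NULL} skips writing.
#' @param seed Integer seed driving simulation and the train/test split.
#' @param per_stratum Fit one tree per stratum (primary/secondary) rather
#'   than a pooled model.
#' @param polarity,scheme,thresholds CRITIC settings; see
#'   \code{\link{critic_assess}}.
#' @param corr_kind,use_abs See \code{\link{critic_conflict}}.
#' @param labels Optional externally supplied class labels overriding the
#'   CRITIC-derived ones.
#' @param criterion,max_depth,min_samples_split Tree hyperparameters; see
#'   \code{\link{tree_params}}.
#' @param train_fraction,stratify Split settings; see
#'   \code{\link{train_test_split}}.
#' @param sim_config Optional \code{\link{simulation_config}} used when
#'   \code{input = "simulate"} (its seed is overridden by \code{seed}).
#' @param plot_area,min_dbh Used when \code{input} is a tree-record CSV
#'   path or data frame.
#' @param verbose Print stage progress to standard error.
#' @return List with \code{table}, \code{critic}, \code{labels},
#'   \code{models}, \code{reports}, \code{correlation} and
#'   \code{manifest}, invisibly when \code{output_dir} is set.
#' @export
run_pipeline <- function(input = "simulate", output_dir = NULL, seed = 1L,
                         per_stratum = FALSE,
                         polarity = NULL, scheme = "quartile",
                         thresholds = NULL, corr_kind = "pearson",
                         use_abs = FALSE, labels = NULL,
                         criterion = "gini", max_depth = Inf,
                         min_samples_split = 2L,
                         train_fraction = 0.8, stratify = FALSE,
                         sim_config = NULL, plot_area = 400, min_dbh = 1.0,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[pipeline] ", sprintf(...))
  t0 <- Sys.time()

  # --- stage 1: indicator table -------------------------------------------
  table <- tryCatch({
    if (inherits(input, "indicator_table")) {
      input
    } else if (is.character(input) && identical(input, "simulate")) {
      say("simulating indicator table (seed %d)", seed)
      cfg <- sim_config %||% simulation_config(seed = seed)
      cfg$seed <- as.integer(seed)
      simulate_indicator_table(cfg)
    } else if (is.character(input)) {
      header <- names(read.csv(input, nrows = 1))
      if (any(tolower(header) == "species")) {
        # stem-level survey: assessment proceeds on the four diversity
        # indicators computable from it
        say("computing diversity indices from tree records: %s", input)
        recs <- read_tree_records(input, min_dbh = min_dbh)
        idx <- plot_indices(recs, plot_area = plot_area)
        ok <- complete.cases(idx[, c("Gleason", "Menhinick", "Shannon",
                                     "Pielou")])
        if (!all(ok)) {
          message(sprintf("dropping %d plot(s) with undefined evenness",
                          sum(!ok)))
          idx <- idx[ok, , drop = FALSE]
        }
        idx
      } else {
        say("reading indicator table: %s", input)
        read_indicator_table(input)
      }
    } else if (inherits(input, "data.frame") &&
               "species" %in% names(input)) {
      idx <- plot_indices(input, plot_area = plot_area)
      idx[complete.cases(idx), , drop = FALSE]
    } else {
      as_indicator_table(as.data.frame(input))
    }
  }, error = function(e) {
    stop("pipeline stage 'indicators' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  # --- stage 2: CRITIC weighting, FH score, classes -----------------------
  X <- .feature_matrix(table)
  critic <- tryCatch(
    critic_assess(X, polarity = polarity, scheme = scheme,
                  thresholds = thresholds, corr_kind = corr_kind,
                  use_abs = use_abs),
    error = function(e) stop("pipeline stage 'critic' failed: ",
                             conditionMessage(e), call. = FALSE))
  say("CRITIC: top weight %s = %.3f", names(which.max(critic$weights)),
      max(critic$weights))
  corr_report <- correlation_analysis(X)

  y <- labels %||% critic$health_class
  if (!is.factor(y)) y <- factor(fh_classes()[as.integer(y) + 1L],
                                 levels = fh_classes(), ordered = TRUE)

  # --- stage 3: per-stratum or pooled tree + evaluation -------------------
  params <- tree_params(criterion = criterion, max_depth = max_depth,
                        min_samples_split = min_samples_split)
  groups <- if (per_stratum) split(seq_len(nrow(X)), table$stratum) else
    list(pooled = seq_len(nrow(X)))

  models <- list(); reports <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    say("fitting %s tree on %d plots", g, length(idx))
    sp <- train_test_split(length(idx), train_fraction, seed = seed,
                           stratify_by = if (stratify) y[idx] else NULL)
    tr <- idx[sp$train]; te <- idx[sp$test]
    fit <- grow_tree(X[tr, , drop = FALSE], y[tr], params)
    models[[g]] <- fit
    reports[[g]] <- evaluation_report(fit, X[te, , drop = FALSE], y[te],
                                      split_seed = seed,
                                      train_fraction = train_fraction)
    say("%s: macro F1 %.3f, average AUC %.3f", g,
        reports[[g]]$macro["f1"], reports[[g]]$auc_average)
  }

  result <- list(table = table, critic = critic, labels = y,
                 models = models, reports = reports,
                 correlation = corr_report)

  # --- stage 4: artifacts + manifest --------------------------------------
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c()
    emit <- function(obj, name) {
      p <- file.path(output_dir, name)
      write_results(obj, p)
      paths <<- c(paths, p)
      p
    }
    emit(critic, "critic_weights.csv")
    emit(data.frame(plot_id = table$plot_id, stratum = table$stratum,
                    fh = critic$fh,
                    health_class = as.character(critic$health_class),
                    class_code = as.integer(critic$health_class) - 1L),
         "fh_classes.csv")
    emit(as.data.frame(corr_report$r), "correlation.csv")
    for (g in names(models)) {
      emit(models[[g]], sprintf("model_%s.json", g))
      writeLines(export_tree(models[[g]], "text", display_depth = 3),
                 file.path(output_dir, sprintf("model_%s.txt", g)))
      writeLines(export_tree(models[[g]], "dot", display_depth = 3),
                 file.path(output_dir, sprintf("model_%s.dot", g)))
      paths <- c(paths, file.path(output_dir, sprintf("model_%s.txt", g)),
                 file.path(output_dir, sprintf("model_%s.dot", g)))
      emit(reports[[g]], sprintf("report_%s.json", g))
    }
    manifest <- list(
      seed = seed,
      version = as.character(packageVersion("foresthealth")),
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      settings = list(per_stratum = per_stratum, scheme = scheme,
                      thresholds = thresholds, corr_kind = corr_kind,
                      use_abs = use_abs, criterion = criterion,
                      max_depth = if (is.finite(max_depth)) max_depth else
                        "unlimited",
                      min_samples_split = min_samples_split,
                      train_fraction = train_fraction, stratify = stratify,
                      polarity = as.list(critic$polarity)),
      outputs = lapply(setNames(nm = basename(paths)), function(b) {
        list(md5 = unname(tools::md5sum(file.path(output_dir, b))))
      })
    )
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    result$manifest <- manifest
    say("artifacts written to %s", output_dir)
    return(invisible(result))
  }
  result
}
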