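#' Configure a full analysis run
#'
#' @param scenario a [simulation_scenario()] to generate the data, or
#'   `NULL` when `dataset` is supplied.
#' @param dataset a [study_dataset()] (ignored when `scenario` given).
#' @param layout the [stimulus_layout()] shared by the stimuli (defaults to
#'   the scenario's).
#' @param answer_key an [answer_key()] for accuracy scoring (defaults to
#'   the scenario's); `NULL` skips accuracy outputs.
#' @param schemes AOI schemes to run, subset of `c("lead", "grid")`.
#' @param comparisons group comparisons to run, subset of
#'   `c("order", "accuracy")`: `"order"` contrasts the history-first
#'   group's history-condition scanpaths with the history-last group's
#'   no-history scanpaths (each group's first exposure); `"accuracy"`
#'   contrasts, per stimulus, participants correct in both conditions with
#'   participants incorrect in both (mixed participants excluded).
#' @param n_permutations shuffles per permutation test.
#' @param alpha family-wise significance level (reported, Bonferroni
#'   threshold included in the bundle).
#' @param min_pts DBSCAN core threshold for grid derivation.
#' @param diameter rule filling the optimal diameter, see
#'   [dbscan_cluster()].
#' @param seed master seed; every test's seed is derived from it and the
#'   cell identity, so results do not depend on execution order.
#' @param outdir optional directory: result tables are written as CSV.
#' @return object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, dataset = NULL, layout = NULL,
                       answer_key = NULL, schemes = c("lead", "grid"),
                       comparisons = c("order", "accuracy"),
                       n_permutations = 10000L, alpha = 0.05,
                       min_pts = 5L, diameter = "eps", seed = 1L,
                       outdir = NULL) {
  schemes <- match.arg(schemes, c("lead", "grid"), several.ok = TRUE)
  comparisons <- match.arg(comparisons, c("order", "accuracy"),
                           several.ok = TRUE)
  stopifnot(n_permutations >= 1)
  if (is.null(scenario) && is.null(dataset)) {
    stop("either a scenario or a dataset is required")
  }
  if (is.null(layout) && !is.null(scenario)) layout <- scenario$layout
  if (is.null(answer_key) && !is.null(scenario)) {
    answer_key <- scenario$answer_key
  }
  structure(list(scenario = scenario, dataset = dataset, layout = layout,
                 answer_key = answer_key, schemes = schemes,
                 comparisons = comparisons,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 min_pts = as.integer(min_pts), diameter = diameter,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

# Post hoc accuracy split for one stimulus: correct in both conditions
# versus incorrect in both; participants mixed across conditions excluded.
accuracy_groups <- function(scored, stimulus) {
  s <- scored[scored$stimulus == stimulus, ]
  agg <- stats::aggregate(correct ~ participant, s, function(v) {
    if (all(v)) 1L else if (!any(v)) 2L else 0L
  })
  g1 <- agg$participant[agg$correct == 1L]
  g2 <- agg$participant[agg$correct == 2L]
  if (!length(g1) || !length(g2)) {
    stop("accuracy split degenerate for stimulus '", stimulus, "'")
  }
  group_assignment(g1, g2)
}

#' Run the full scanpath analysis pipeline
#'
#' Segmentation, transition permutation tests, and conventional clinical
#' statistics from one config: per stimulus the lead AOIs come from the
#' layout and the grid AOIs from DBSCAN on the stimulus's pooled fixation
#' points (all participants, both conditions — both comparison groups share
#' one grid); each (stimulus, scheme, comparison) cell runs one
#' participant-shuffling Hellinger permutation test; accuracy and fixation
#' metrics are tabulated per stimulus. A failing cell is logged and skipped,
#' remaining cells still run.
#'
#' @param config a [run_config()].
#' @return list of class `run_result`: `results` (one row per cell:
#'   `stimulus`, `scheme`, `comparison`, `n1`, `n2`, `M`, `SD`, `d`, `Hd`,
#'   `p`, `n_perm`, `seed`), `accuracy`, `fixation_metrics`,
#'   `bonferroni_alpha`, `aoi_sets`, `log`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  if (!is.null(config$scenario)) {
    sc <- config$scenario
    sc$seed <- derive_seed(config$seed, "simulate")
    sim <- simulate_study(sc)
    dataset <- sim$dataset
    note("simulated dataset from scenario (seed ", sc$seed, ")")
  } else {
    dataset <- config$dataset
  }
  fx <- dataset$fixations
  stimuli <- sort(unique(fx$stimulus))
  layout <- config$layout
  if (is.null(layout)) stop("a stimulus layout is required")

  scored <- NULL
  accuracy <- NULL
  if (!is.null(config$answer_key) && !is.null(dataset$responses)) {
    scored <- score_responses(dataset, config$answer_key)
    accuracy <- accuracy_table(dataset, config$answer_key)
  } else if ("accuracy" %in% config$comparisons) {
    stop("accuracy comparison requested but no answer key / responses")
  }
  fixation_metrics <- fixation_metric_table(dataset)

  og <- dataset$participants
  order_groups <- group_assignment(
    og$participant[og$order_group == "history_first"],
    og$participant[og$order_group == "history_last"],
    conditions = c("history", "no_history"))

  aoi_sets <- list()
  results <- list()
  for (st in stimuli) {
    lay <- layout
    lay$stimulus_id <- st
    sets <- list()
    if ("lead" %in% config$schemes) sets$lead <- lead_aois(lay)
    if ("grid" %in% config$schemes) {
      pts <- as.matrix(fx[fx$stimulus == st, c("x", "y")])
      sets$grid <- tryCatch({
        eps <- select_epsilon(pts, config$min_pts)
        cl <- dbscan_cluster(pts, eps, config$min_pts,
                             diameter = config$diameter)
        derive_grid(lay, cl)
      }, error = function(e) {
        note("grid derivation failed for ", st, ": ", conditionMessage(e))
        NULL
      })
    }
    aoi_sets[[st]] <- sets
    for (cmp in config$comparisons) {
      groups <- tryCatch(
        if (cmp == "order") order_groups else accuracy_groups(scored, st),
        error = function(e) {
          note("comparison '", cmp, "' unavailable for ", st, ": ",
               conditionMessage(e))
          NULL
        })
      if (is.null(groups)) next
      for (schm in names(sets)) {
        if (is.null(sets[[schm]])) next
        cell_seed <- derive_seed(config$seed, st, schm, cmp)
        res <- tryCatch(
          permutation_test(dataset, groups, sets[[schm]], st,
                           n_perm = config$n_permutations,
                           seed = cell_seed),
          error = function(e) {
            note("cell (", st, ", ", schm, ", ", cmp, ") failed: ",
                 conditionMessage(e))
            NULL
          })
        if (is.null(res)) next
        row <- as.data.frame(res)
        row$comparison <- cmp
        results[[length(results) + 1L]] <- row
      }
    }
  }
  results <- if (length(results)) do.call(rbind, results) else
    data.frame()
  if (nrow(results)) {
    results <- results[, c("stimulus", "scheme", "comparison", "n1", "n2",
                           "M", "SD", "d", "Hd", "p", "n_perm", "seed")]
    rownames(results) <- NULL
  }
  out <- structure(list(results = results, accuracy = accuracy,
                        fixation_metrics = fixation_metrics,
                        bonferroni_alpha = bonferroni_alpha(
                          config$alpha, max(1L, length(stimuli))),
                        aoi_sets = aoi_sets, log = log),
                   class = "run_result")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_table(results, file.path(config$outdir, "permutation_results.csv"))
    if (!is.null(accuracy)) {
      write_table(accuracy, file.path(config$outdir, "accuracy.csv"))
    }
    write_table(fixation_metrics,
                file.path(config$outdir, "fixation_metrics.csv"))
    writeLines(log, file.path(config$outdir, "run.log"))
  }
  out
}

#' @export
print.run_result <- function(x, ...) {
  cat("run_result:", nrow(x$results), "permutation-test rows;",
      "Bonferroni threshold", format(x$bonferroni_alpha, digits = 3), "\n")
  if (length(x$log)) cat("log:", length(x$log), "message(s)\n")
  invisible(x)
}
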