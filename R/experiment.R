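#' Run one Monte-Carlo scenario
#'
#' Generates `scenario$reps` replicate datasets, applies the requested
#' discretization methods to each, and aggregates the cut-point
#' distributions (median, mean, simulation SE = SD across replicates).
#' Optionally computes cross-validated performance measures per replicate.
#' Replicate failures are recorded and skipped; more than `max_fail_frac`
#' failures for any method is an error. Fully deterministic given the
#' scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @param methods Subset of `c("median", "q1q3", "minp", "oehr")`.
#' @param cv_metrics If `TRUE`, compute cross-validated measures per
#'   replicate ([cv_performance()]).
#' @param cv_folds,cv_measures Cross-validation controls (default two-fold).
#' @param min_group_frac Passed to the OEHR search.
#' @param max_fail_frac Maximum tolerated fraction of failed replicates.
#' @param verbose Print progress every 10 replicates.
#' @return An object of class `scenario_summary` with elements `cuts`
#'   (long data frame of per-replicate cut-points), `cuts_summary`,
#'   `metrics` (long per-replicate measure means, if requested),
#'   `metrics_summary`, `failures` and the `scenario`.
#' @export
run_scenario <- function(scenario,
                         methods = c("median", "q1q3", "minp", "oehr"),
                         cv_metrics = FALSE, cv_folds = 2,
                         cv_measures = c("cindex", "cpe", "ibs", "r2_pm", "r2_d"),
                         min_group_frac = 0.05, max_fail_frac = 0.2,
                         verbose = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  methods <- match.arg(methods, several.ok = TRUE)
  cut_rows <- list()
  metric_rows <- list()
  failures <- stats::setNames(integer(length(methods)), methods)

  for (rep in seq_len(scenario$reps)) {
    if (verbose && rep %% 10 == 0) message("replicate ", rep, "/", scenario$reps)
    data <- generate_dataset(scenario, rep)
    fit <- if ("oehr" %in% methods)
      tryCatch(fit_spline_cox(data), error = function(e) NULL) else NULL
    for (m in methods) {
      res <- tryCatch(switch(
        m,
        median = median_cutpoint(data),
        q1q3 = quartile_cutpoints(data),
        minp = minp_cutpoint(data),
        oehr = {
          if (is.null(fit)) stop("spline fit failed")
          oehr_cutpoints(data, fit, min_group_frac = min_group_frac,
                         check_u_shape = FALSE)
        }), error = function(e) NULL)
      if (is.null(res)) { failures[m] <- failures[m] + 1L; next }
      cut_rows[[length(cut_rows) + 1]] <- data.frame(
        rep = rep, method = m, cut = seq_along(res$cuts),
        value = unname(res$cuts))
      if (cv_metrics) {
        perf <- tryCatch(
          cv_performance(data, m, n_folds = cv_folds, n_repeats = 1,
                         seed = as.integer((scenario$seed * 10007 + 500000 + rep)
                                           %% 2147483647),
                         measures = cv_measures,
                         min_group_frac = min_group_frac),
          error = function(e) NULL)
        if (!is.null(perf))
          metric_rows[[length(metric_rows) + 1]] <- data.frame(
            rep = rep, method = m, measure = names(perf$mean),
            value = unname(perf$mean))
      }
    }
  }
  if (any(failures > max_fail_frac * scenario$reps))
    stop("method(s) failed on more than ", round(100 * max_fail_frac),
         "% of replicates: ",
         paste(names(failures)[failures > max_fail_frac * scenario$reps],
               collapse = ", "))

  cuts <- do.call(rbind, cut_rows)
  cuts_summary <- do.call(rbind, lapply(
    split(cuts, list(cuts$method, cuts$cut), drop = TRUE),
    function(d) data.frame(method = d$method[1], cut = d$cut[1],
                           median = stats::median(d$value),
                           mean = mean(d$value),
                           sim_se = if (nrow(d) > 1) stats::sd(d$value) else NA_real_,
                           n_reps = nrow(d))))
  cuts_summary <- cuts_summary[order(cuts_summary$method, cuts_summary$cut), ]
  rownames(cuts_summary) <- NULL

  metrics <- if (length(metric_rows)) do.call(rbind, metric_rows) else NULL
  metrics_summary <- if (!is.null(metrics)) {
    ms <- do.call(rbind, lapply(
      split(metrics, list(metrics$method, metrics$measure), drop = TRUE),
      function(d) data.frame(method = d$method[1], measure = d$measure[1],
                             mean = mean(d$value), median = stats::median(d$value),
                             sim_se = stats::sd(d$value), n_reps = nrow(d))))
    rownames(ms) <- NULL
    ms
  } else NULL

  structure(list(scenario = scenario, label = scenario_label(scenario),
                 cuts = cuts, cuts_summary = cuts_summary,
                 metrics = metrics, metrics_summary = metrics_summary,
                 failures = failures), class = "scenario_summary")
}

scenario_label <- function(sc) {
  sprintf("k1=%g,k2=%g,a=%g,v=%g,Pc=%g", sc$k1, sc$k2, sc$a, sc$v, sc$Pc)
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("Scenario summary:", x$label, "\n")
  cat(sprintf("  %d replicates of n = %d\n", x$scenario$reps, x$scenario$n))
  print(transform(x$cuts_summary,
                  median = round(median, 3), mean = round(mean, 3),
                  sim_se = round(sim_se, 3)))
  if (!is.null(x$metrics_summary)) {
    cat("  cross-validated performance (per-replicate means):\n")
    print(transform(x$metrics_summary, mean = round(mean, 4),
                    median = round(median, 4), sim_se = round(sim_se, 4)))
  }
  if (any(x$failures > 0))
    cat("  failures:", paste(sprintf("%s=%d", names(x$failures), x$failures),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Combine scenario summaries into flat tables
#'
#' Stacks the cut-point summaries (one row per scenario, method and
#' cut slot: median / mean / simulation SE) and the long per-replicate
#' measure table used for boxplots.
#'
#' @param summaries A list of [run_scenario()] results.
#' @return A list with data frames `cutpoints` and `metrics` (the latter
#'   `NULL` when no summary carried measures).
#' @export
summarize_tables <- function(summaries) {
  if (inherits(summaries, "scenario_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1)
  cutpoints <- do.call(rbind, lapply(summaries, function(s) {
    cbind(scenario = s$label, Pc = s$scenario$Pc, s$cuts_summary)
  }))
  have <- Filter(function(s) !is.null(s$metrics), summaries)
  metrics <- if (length(have)) do.call(rbind, lapply(have, function(s) {
    cbind(scenario = s$label, Pc = s$scenario$Pc, s$metrics)
  })) else NULL
  rownames(cutpoints) <- NULL
  if (!is.null(metrics)) rownames(metrics) <- NULL
  list(cutpoints = cutpoints, metrics = metrics)
}
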