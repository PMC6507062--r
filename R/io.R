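#' Read a survival dataset from a delimited file
#'
#' Reads a CSV (or other delimited) file, renames the time / status /
#' predictor columns to the package's canonical `time`, `status`, `x`,
#' recodes the status column through an explicit mapping, drops rows with
#' missing required fields (with a message stating the count), and
#' validates the result.
#'
#' @param path Path to a delimited text file with a header row.
#' @param time_col,status_col,x_col Column names in the file.
#' @param covariate_cols Optional adjustment covariate columns to keep.
#' @param status_map Named vector mapping raw status codes to 0/1,
#'   e.g. `c(alive = 0, dead = 1)`; by default the column must already be
#'   coded 0/1.
#' @param sep Field separator (default `","`).
#' @return A validated data frame with columns `time`, `status`, `x` and
#'   any covariates.
#' @export
read_survival_data <- function(path, time_col = "time", status_col = "status",
                               x_col = "x", covariate_cols = character(),
                               status_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c(time_col, status_col, x_col, covariate_cols)
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("columns not found in file: ", paste(miss, collapse = ", "))
  d <- raw[need]
  names(d) <- c("time", "status", "x", covariate_cols)
  if (!is.null(status_map)) {
    idx <- match(as.character(d$status), names(status_map))
    if (anyNA(idx) && any(!is.na(d$status) & is.na(idx))) {
      bad <- which(!is.na(d$status) & is.na(idx))
      stop("unknown status codes in rows: ", paste(utils::head(bad, 10), collapse = ", "))
    }
    d$status <- unname(status_map[idx])
  }
  keep <- stats::complete.cases(d[c("time", "status", "x")])
  if (any(!keep))
    message("dropped ", sum(!keep), " row(s) with missing time/status/x")
  d <- d[keep, , drop = FALSE]
  if (!all(d$status %in% c(0, 1))) {
    bad <- which(!d$status %in% c(0, 1))
    stop("status values outside {0, 1} in rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         " (supply 'status_map')")
  }
  if (any(d$time < 0)) {
    bad <- which(d$time < 0)
    stop("negative times in rows: ", paste(utils::head(bad, 10), collapse = ", "))
  }
  rownames(d) <- NULL
  validate_survival_data(d)
}

#' Write a survival dataset to CSV
#'
#' @param data A survival data frame (`time`, `status`, `x`, covariates).
#' @param path Output file path.
#' @export
write_survival_data <- function(data, path) {
  utils::write.csv(validate_survival_data(data), path, row.names = FALSE)
}

cutpoint_result_row <- function(res) {
  co <- res$coefficients
  data.frame(method = res$method,
             cut1 = unname(res$cuts[1]),
             cut2 = if (length(res$cuts) > 1) unname(res$cuts[2]) else NA_real_,
             aic = res$aic, bic = res$bic,
             hr1 = unname(res$hrs[1]),
             hr2 = if (length(res$hrs) > 1) unname(res$hrs[2]) else NA_real_,
             p1 = unname(res$p_values[1]),
             p2 = if (length(res$p_values) > 1) unname(res$p_values[2]) else NA_real_)
}

#' Run the full applied workflow: diagnose, cut, refit, cross-validate
#'
#' The workflow used on real data: fit the P-spline Cox diagnostic and test
#' for a U shape; apply the requested discretization methods; refit
#' categorical Cox models and report cut-points, hazard ratios and AIC/BIC;
#' cross-validate the predictive performance of each method. Optionally
#' writes the diagnostic curve (CSV), the result tables (CSV) and a
#' machine-readable JSON bundle to `out_dir`.
#'
#' @param data A survival data frame (see [read_survival_data()]).
#' @param methods Discretization methods to apply.
#' @param criterion `"aic"` or `"bic"` for the OEHR selection.
#' @param cv_folds,cv_repeats Cross-validation scheme (default two-fold,
#'   one repeat).
#' @param seed Seed controlling all randomness (fold draws).
#' @param min_group_frac Minimum group-size fraction for the OEHR search.
#' @param allow_non_u Proceed with OEHR even when the U-shape diagnostic
#'   flag is false.
#' @param out_dir Optional output directory.
#' @return An `analysis_bundle`: `diagnosis`, `curve`, `cutpoints` (table),
#'   `results` (full `cutpoint_result` objects), `performance` (table),
#'   `config`.
#' @export
run_full_analysis <- function(data, methods = c("median", "q1q3", "minp", "oehr"),
                              criterion = c("aic", "bic"), cv_folds = 2,
                              cv_repeats = 1, seed = 1, min_group_frac = 0.05,
                              allow_non_u = FALSE, out_dir = NULL) {
  criterion <- match.arg(criterion)
  data <- validate_survival_data(data)
  methods <- match.arg(methods, c("median", "q1q3", "minp", "oehr"),
                       several.ok = TRUE)
  fit <- fit_spline_cox(data)
  diag <- diagnose_u_shape(fit)
  if ("oehr" %in% methods && !diag$is_u_shaped && !allow_non_u)
    stop("the diagnostic curve is not U-shaped; review the diagnostic plot ",
         "(diagnose_u_shape) or set allow_non_u = TRUE")

  results <- lapply(stats::setNames(methods, methods), function(m) switch(
    m,
    median = median_cutpoint(data),
    q1q3 = quartile_cutpoints(data),
    minp = minp_cutpoint(data),
    oehr = oehr_cutpoints(data, fit, criterion = criterion,
                          min_group_frac = min_group_frac,
                          check_u_shape = FALSE)))
  cut_table <- do.call(rbind, lapply(results, cutpoint_result_row))
  rownames(cut_table) <- NULL

  perf <- lapply(stats::setNames(methods, methods), function(m)
    cv_performance(data, m, n_folds = cv_folds, n_repeats = cv_repeats,
                   seed = seed, min_group_frac = min_group_frac))
  perf_table <- do.call(rbind, lapply(methods, function(m)
    data.frame(method = m, measure = names(perf[[m]]$mean),
               mean = unname(perf[[m]]$mean), se = unname(perf[[m]]$se))))

  bundle <- structure(list(
    diagnosis = diag, curve = diag$curve, spline_fit = fit,
    cutpoints = cut_table, results = results, performance = perf_table,
    config = list(methods = methods, criterion = criterion,
                  cv_folds = cv_folds, cv_repeats = cv_repeats, seed = seed,
                  min_group_frac = min_group_frac)),
    class = "analysis_bundle")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(diag$curve, file.path(out_dir, "diagnostic_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(cut_table, file.path(out_dir, "cutpoints.csv"),
                     row.names = FALSE)
    utils::write.csv(perf_table, file.path(out_dir, "performance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(u_shape = list(is_u_shaped = diag$is_u_shaped,
                          minimum = diag$minimum,
                          p_nonlinear = diag$p_nonlinear),
           cutpoints = cut_table, performance = perf_table,
           config = bundle$config),
      file.path(out_dir, "analysis.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("Survival cut-point analysis\n")
  print(x$diagnosis)
  cat("\nCut-points and categorical Cox refits:\n")
  print(transform(x$cutpoints, aic = round(aic, 2), bic = round(bic, 2),
                  hr1 = round(hr1, 3), hr2 = round(hr2, 3),
                  p1 = signif(p1, 3), p2 = signif(p2, 3),
                  cut1 = round(cut1, 3), cut2 = round(cut2, 3)))
  cat(sprintf("\nCross-validated performance (%d-fold x %d):\n",
              x$config$cv_folds, x$config$cv_repeats))
  print(transform(x$performance, mean = round(mean, 4), se = round(se, 4)))
  invisible(x)
}
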