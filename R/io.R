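#' Read a multi-hive dance table from delimited text
#'
#' Expects a header and (at least) a hive identifier column and a duration
#' column; an optional site-class column labels the landscape type of each
#' hive's location. Rows with missing, non-numeric or nonpositive durations
#' are dropped with a single warning reporting the count. Column names can be
#' remapped via `col_map` to accommodate other dialects.
#'
#' @param path Path to a delimited text file.
#' @param col_map Named character vector mapping the roles `hive_id`,
#'   `duration` and (optionally) `site_class` to column names in the file.
#' @param sep Field separator (default comma).
#' @return A list of [waggle_dataset()] objects, one per hive, each with
#'   `m` set to the hive's minimum duration.
#' @export
read_dance_table <- function(path,
                             col_map = c(hive_id = "hive_id",
                                         duration = "duration_s",
                                         site_class = "site_class"),
                             sep = ",") {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_input(sprintf("empty input file: %s", path))
  for (role in c("hive_id", "duration")) {
    if (!col_map[[role]] %in% names(df))
      stop_input(sprintf("missing required column '%s' (role: %s)",
                         col_map[[role]], role))
  }
  has_site <- !is.na(col_map["site_class"]) &&
    col_map[["site_class"]] %in% names(df)
  dur <- suppressWarnings(as.numeric(df[[col_map[["duration"]]]]))
  bad <- !is.finite(dur) | dur <= 0
  if (any(bad)) {
    warning(sprintf("dropped %d row(s) with missing or nonpositive durations",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
    dur <- dur[!bad]
  }
  if (nrow(df) == 0) stop_input("no valid rows after filtering durations")
  hive <- as.character(df[[col_map[["hive_id"]]]])
  lapply(split(seq_along(dur), hive), function(idx) {
    sc <- if (has_site) as.character(df[[col_map[["site_class"]]]][idx[1]]) else NULL
    if (!is.null(sc) && (is.na(sc) || !nzchar(sc))) sc <- NULL
    waggle_dataset(hive[idx[1]], dur[idx], site_class = sc)
  })
}

#' Write a list of waggle datasets as a dance table
#'
#' Writes the CSV dialect that [read_dance_table()] reads, so synthetic
#' studies are drop-in replacements for field data.
#'
#' @param datasets A list of [waggle_dataset()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dance_table <- function(datasets, path) {
  if (inherits(datasets, "waggle_dataset")) datasets <- list(datasets)
  rows <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(hive_id = d$hive_id, duration_s = d$durations,
               site_class = if (is.null(d$site_class)) NA_character_
                            else d$site_class,
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full per-hive analysis pipeline
#'
#' For each hive: fit the individual and collective models, compare them by
#' AIC, test both fits for goodness of fit with the bootstrapped two-sample
#' KS test, and classify the hive as `"collective"`- or
#' `"individual"`-selected, or `"no-acceptable-fit"` if both fits fail the
#' GOF test (p below `gof_alpha`). Hives whose fits error out are reported in
#' the result rather than aborting the batch. If the datasets carry site
#' classes, pooled fits per class are run as well. The whole run is
#' deterministic given `seed` (per-hive seeds are derived from it).
#'
#' @param datasets A list of [waggle_dataset()] objects.
#' @param settings A [fit_settings()] object.
#' @param n_boot Bootstrap resamples for the KS tests.
#' @param gof_alpha Significance threshold for an acceptable fit (default
#'   0.05).
#' @param pool_by_site Also fit pooled models per site class when site
#'   classes are present.
#' @param seed Integer master seed for the run.
#' @return A list of class `analysis_report`: `comparisons` (per-hive
#'   `model_comparison` objects, with `gof_pvalues` filled in),
#'   `classification` (named character vector), `summary` (data frame, one
#'   row per hive), `pooled` (per site class, or `NULL`), `failures`, and a
#'   `manifest` sufficient to reproduce the run.
#' @export
run_full_analysis <- function(datasets, settings = fit_settings(),
                              n_boot = 1000, gof_alpha = 0.05,
                              pool_by_site = TRUE, seed = 1) {
  if (inherits(datasets, "waggle_dataset")) datasets <- list(datasets)
  if (length(datasets) < 1) stop_input("need at least one dataset")
  comparisons <- list(); failures <- list()
  classification <- character(0)
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    res <- tryCatch({
      st <- settings; st$seed <- seed + i
      ind <- fit_individual(d, st)
      col <- fit_collective(d, st)
      cmp <- compare_models(ind, col)
      gof <- c(
        individual = bootstrap_ks_gof(d, ind, n_boot = n_boot,
                                      seed = seed + 1000L + i)$pvalue,
        collective = bootstrap_ks_gof(d, col, n_boot = n_boot,
                                      seed = seed + 2000L + i)$pvalue)
      cmp$gof_pvalues <- gof
      cmp
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[d$hive_id]] <- conditionMessage(res)
    } else {
      comparisons[[d$hive_id]] <- res
      classification[d$hive_id] <-
        if (all(res$gof_pvalues < gof_alpha)) "no-acceptable-fit"
        else res$selected
    }
  }

  pooled <- NULL
  sites <- vapply(datasets, function(d)
    if (is.null(d$site_class)) NA_character_ else d$site_class, "")
  if (pool_by_site && any(!is.na(sites))) {
    pooled <- lapply(split(datasets[!is.na(sites)], sites[!is.na(sites)]),
                     function(ds) {
                       if (length(ds) < 2) return(NULL)
                       st <- settings; st$seed <- seed
                       tryCatch(pooled_summary(ds, st),
                                error = function(e) conditionMessage(e))
                     })
  }

  summary_df <- do.call(rbind, lapply(names(comparisons), function(h) {
    cmp <- comparisons[[h]]
    data.frame(hive_id = h,
               n = length(datasets[[match(h, vapply(datasets, `[[`,
                                                    "", "hive_id"))]]$durations),
               aic_individual = cmp$fits$individual$aic,
               aic_collective = cmp$fits$collective$aic,
               delta_aic = cmp$delta_aic,
               selected = cmp$selected,
               waggle_dance_use = cmp$waggle_dance_use,
               gof_p_individual = cmp$gof_pvalues["individual"],
               gof_p_collective = cmp$gof_pvalues["collective"],
               classification = classification[h],
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  structure(list(comparisons = comparisons,
                 classification = classification,
                 summary = summary_df,
                 pooled = pooled,
                 failures = failures,
                 manifest = list(seed = seed, n_boot = n_boot,
                                 gof_alpha = gof_alpha,
                                 settings = unclass(settings),
                                 n_hives = length(datasets),
                                 package_version =
                                   as.character(packageVersion("wagglefit")),
                                 timestamp = format(Sys.time(), tz = "UTC"))),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  counts <- table(factor(x$classification,
                         levels = c("collective", "individual",
                                    "no-acceptable-fit")))
  cat(sprintf("Analysis of %d hive(s): %d collective-selected, %d individual-selected, %d with no acceptable fit\n",
              length(x$classification), counts["collective"],
              counts["individual"], counts["no-acceptable-fit"]))
  if (length(x$failures))
    cat(sprintf("  %d hive(s) failed: %s\n", length(x$failures),
                paste(names(x$failures), collapse = ", ")))
  if (!is.null(x$summary)) {
    cat("\n")
    print(x$summary, digits = 4)
  }
  invisible(x)
}

#' Write an analysis report (or any result object) as JSON
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  flat <- list(
    hives = lapply(report$comparisons, function(cmp) list(
      hive_id = cmp$hive_id,
      aic_individual = cmp$fits$individual$aic,
      aic_collective = cmp$fits$collective$aic,
      loglik_individual = cmp$fits$individual$loglik,
      loglik_collective = cmp$fits$collective$loglik,
      delta_aic = cmp$delta_aic,
      akaike_weights = as.list(cmp$akaike_weights),
      selected = cmp$selected,
      waggle_dance_use = cmp$waggle_dance_use,
      p_scout = cmp$fits$collective$params$p,
      gof_pvalues = as.list(cmp$gof_pvalues),
      classification = report$classification[[cmp$hive_id]],
      params_collective = list(
        a_s = cmp$fits$collective$params$scout$a_s,
        b_s = cmp$fits$collective$params$scout$b_s,
        a_r = cmp$fits$collective$params$recruit$a_r,
        b_r = cmp$fits$collective$params$recruit$b_r,
        m = cmp$fits$collective$params$m))),
    pooled = if (is.null(report$pooled)) NULL else
      lapply(report$pooled, function(ps) {
        if (is.null(ps) || is.character(ps)) return(ps)
        list(sum_best_aic = ps$sum_best_aic,
             pooled_best_aic = ps$pooled_best_aic,
             delta_aic = ps$delta_aic,
             akaike_weights = as.list(ps$akaike_weights))
      }),
    failures = report$failures,
    manifest = report$manifest)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Complementary cumulative frequency plot of durations and fitted models
#'
#' The standard diagnostic view of a dancefloor: `1 - ECDF` of the observed
#' waggle-run durations, overlaid with the complementary CDFs of fitted
#' models. Recruitment shows up as a shoulder ("hump") at short durations.
#'
#' @param data A [waggle_dataset()] or numeric vector.
#' @param fits Optional named list of `waggle_fit` or [mixture_params()]
#'   objects to overlay.
#' @param ... Passed to [plot()].
#' @return Invisibly, `NULL`. Called for its side effect.
#' @export
plot_ccdf <- function(data, fits = NULL, ...) {
  x <- sort(as_durations(data))
  n <- length(x)
  ccdf <- 1 - seq_len(n) / n
  plot(x, ccdf, pch = 16, cex = 0.5, xlab = "waggle-run duration (s)",
       ylab = "complementary cumulative frequency", ...)
  if (!is.null(fits)) {
    cols <- seq_along(fits) + 1
    grid_x <- seq(min(x), max(x), length.out = 300)
    for (i in seq_along(fits)) {
      f <- fits[[i]]
      params <- if (inherits(f, "waggle_fit")) f$params else f
      lines(grid_x, 1 - pmixture(grid_x, params), col = cols[i], lwd = 2)
    }
    legend("topright", legend = names(fits), col = cols, lwd = 2, bty = "n")
  }
  invisible(NULL)
}
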