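#' Settings for maximum-likelihood fitting
#'
#' The likelihood surface has ridges along the support boundaries
#' `a * max(x) -> 1`, so fits use Nelder-Mead from multiple Latin-hypercube
#' starting points on transformed parameters (log for the positive scale and
#' intensity parameters, logit for the scout fraction `p`).
#'
#' @param n_starts Number of Latin-hypercube multistarts.
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @param min_obs Minimum number of observations required to attempt a fit.
#' @param seed Optional seed controlling the multistart design.
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(n_starts = 32, maxit = 1000, reltol = 1e-8,
                         min_obs = 10, seed = NULL) {
  stopifnot(n_starts >= 1, maxit >= 1, reltol > 0, min_obs >= 1)
  structure(list(n_starts = as.integer(n_starts), maxit = as.integer(maxit),
                 reltol = reltol, min_obs = as.integer(min_obs), seed = seed),
            class = "fit_settings")
}

# Latin-hypercube starting points mapped into [lo, hi] per column.
lhs_starts <- function(n, lo, hi, seed = NULL) {
  u <- with_seed(seed, lhs::randomLHS(n, length(lo)))
  sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
}

# Two-stage multistart: a coarse Nelder-Mead pass from every start, then a
# full-tolerance polish of the most promising candidates.
best_optim <- function(starts, nll, maxit, reltol, n_polish = 4L) {
  stage1 <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      optim(starts[i, ], nll, method = "Nelder-Mead",
            control = list(maxit = max(150L, maxit %/% 5L), reltol = 1e-6)),
      error = function(e) NULL)
  })
  stage1 <- Filter(Negate(is.null), stage1)
  if (length(stage1) == 0) stop_input("all optimizer restarts failed")
  vals <- vapply(stage1, `[[`, 0, "value")
  top <- order(vals)[seq_len(min(n_polish, length(vals)))]
  best <- NULL
  n_conv <- 0L
  for (i in top) {
    fit <- tryCatch(
      optim(stage1[[i]]$par, nll, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop_input("all optimizer restarts failed")
  list(best = best, n_conv = n_conv)
}

new_fit_result <- function(model_kind, params, loglik, k, converged, n_restarts,
                           hive_id) {
  structure(list(model_kind = model_kind, params = params, loglik = loglik,
                 n_free_params = k, aic = 2 * k - 2 * loglik,
                 converged = converged, n_restarts_used = n_restarts,
                 hive_id = hive_id),
            class = "waggle_fit")
}

#' @export
print.waggle_fit <- function(x, ...) {
  cat(sprintf("%s model fit (hive '%s'): logLik = %.3f, AIC = %.3f, k = %d%s\n",
              x$model_kind, x$hive_id, x$loglik, x$aic, x$n_free_params,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (x$model_kind == "collective")
    cat(sprintf("  p = %.4f (waggle dance use = %.4f)\n",
                x$params$p, 1 - x$params$p))
  cat(sprintf("  scout a_s = %.5f, b_s = %.4f", x$params$scout$a_s, x$params$scout$b_s))
  if (x$model_kind == "collective")
    cat(sprintf("; recruit a_r = %.5f, b_r = %.4f",
                x$params$recruit$a_r, x$params$recruit$b_r))
  cat(sprintf("; m = %.4f\n", x$params$m))
  invisible(x)
}

#' Fit the individual-search and collective-foraging models to one hive
#'
#' `fit_individual()` fits the scout-only model (`p = 1`): all forage sites
#' are found through scouting, and the dancefloor durations follow the scout
#' component alone. Two parameters, `(a_s, b_s)`, are free; the truncation
#' point `m` is fixed at the dataset minimum. `fit_collective()` frees the
#' scout fraction `p` on `[0, 1]` together with both components' parameters,
#' five free parameters in all. Both maximize the likelihood by multistart
#' Nelder-Mead; since the individual model is nested in the collective model
#' (at `p = 1`), the collective fit is seeded with the individual solution in
#' addition to the Latin-hypercube starts, so its log-likelihood is never
#' materially below the individual one.
#'
#' @param data A [waggle_dataset()] (or numeric vector of durations, in which
#'   case `m = min(data)`).
#' @param settings A [fit_settings()] object.
#' @return A `waggle_fit` with elements `model_kind`, `params`
#'   ([mixture_params()]), `loglik`, `n_free_params`, `aic`, `converged` and
#'   `n_restarts_used`.
#' @examples
#' mp <- mixture_params(0.3, scout_params(0.25, 2, 0.5), recruit_params(0.3, 3, 0.5))
#' d <- waggle_dataset("demo", rmixture(300, mp, seed = 7))
#' fit_collective(d, fit_settings(n_starts = 8, seed = 1))
#' @export
fit_individual <- function(data, settings = fit_settings()) {
  if (is.numeric(data)) data <- waggle_dataset("unnamed", data)
  x <- data$durations
  if (length(x) < settings$min_obs)
    stop_input(sprintf("need at least %d observations, got %d",
                       settings$min_obs, length(x)))
  m <- data$m; xmax <- max(x)
  nll <- function(th) {
    a <- exp(th[1]); b <- exp(th[2])
    if (!is.finite(a) || !is.finite(b) || a * m >= 1) return(1e10)
    d <- dscout(x, structure(list(a_s = a, b_s = b, m = m), class = "scout_params"))
    if (any(d <= 0)) return(1e10)
    -sum(log(d))
  }
  lo <- c(log(0.05 / xmax), log(0.02))
  hi <- c(log(0.95 / xmax), log(50))
  starts <- lhs_starts(settings$n_starts, lo, hi, settings$seed)
  res <- best_optim(starts, nll, settings$maxit, settings$reltol)
  a_s <- exp(res$best$par[1]); b_s <- exp(res$best$par[2])
  sp <- scout_params(a_s, b_s, m)
  params <- mixture_params(1, sp, recruit_params(a_s, b_s, m))
  new_fit_result("individual", params, -res$best$value, 2L,
                 res$n_conv > 0, settings$n_starts, data$hive_id)
}

#' @rdname fit_individual
#' @export
fit_collective <- function(data, settings = fit_settings()) {
  if (is.numeric(data)) data <- waggle_dataset("unnamed", data)
  x <- data$durations
  if (length(x) < settings$min_obs)
    stop_input(sprintf("need at least %d observations, got %d",
                       settings$min_obs, length(x)))
  m <- data$m; xmax <- max(x)
  make_par <- function(th) {
    list(p = plogis(th[1]), a_s = exp(th[2]), b_s = exp(th[3]),
         a_r = exp(th[4]), b_r = exp(th[5]))
  }
  nll <- function(th) {
    pr <- make_par(th)
    if (any(!vapply(pr, is.finite, logical(1)))) return(1e10)
    # Both components must be able to produce the longest observed run;
    # without this the mixture likelihood is unbounded (a component can
    # collapse its support onto the observation at m). See the vignette.
    if (pr$a_s * xmax >= 1 || pr$a_r * xmax >= 1) return(1e10)
    sp <- structure(list(a_s = pr$a_s, b_s = pr$b_s, m = m), class = "scout_params")
    rp <- structure(list(a_r = pr$a_r, b_r = pr$b_r, m = m), class = "recruit_params")
    d <- pr$p * dscout(x, sp) + (1 - pr$p) * drecruit(x, rp)
    if (any(d <= 0)) return(1e10)
    -sum(log(d))
  }
  lo <- c(qlogis(0.05), log(0.05 / xmax), log(0.02), log(0.05 / xmax), log(0.02))
  hi <- c(qlogis(0.95), log(0.95 / xmax), log(50), log(0.95 / xmax), log(50))
  starts <- lhs_starts(settings$n_starts, lo, hi, settings$seed)
  # seed with the individual optimum at p ~ 1 so the nested model is dominated
  ind <- fit_individual(data, settings)
  ind_start <- c(qlogis(1 - 1e-10), log(ind$params$scout$a_s),
                 log(ind$params$scout$b_s), log(0.5 / xmax), log(3))
  starts <- rbind(starts, ind_start)
  res <- best_optim(starts, nll, settings$maxit, settings$reltol)
  pr <- make_par(res$best$par)
  params <- mixture_params(pr$p, scout_params(pr$a_s, pr$b_s, m),
                           recruit_params(pr$a_r, pr$b_r, m))
  new_fit_result("collective", params, -res$best$value, 5L,
                 res$n_conv > 0, settings$n_starts + 1L, data$hive_id)
}

#' Compare the individual and collective fits for one hive
#'
#' Computes `AIC = 2k - 2 logL` for both fits, the AIC difference
#' `delta_aic = AIC_individual - AIC_collective`, Akaike weights
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)`, and selects the
#' lower-AIC model (ties go to the simpler, individual model). The estimated
#' waggle dance use -- the fraction of trips driven by recruitment -- is
#' `1 - p` from the collective fit.
#'
#' @param ind A `waggle_fit` from [fit_individual()].
#' @param col A `waggle_fit` from [fit_collective()].
#' @return A list of class `model_comparison` with elements `hive_id`,
#'   `fits`, `delta_aic`, `akaike_weights` (named pair summing to 1),
#'   `selected`, and `waggle_dance_use`.
#' @export
compare_models <- function(ind, col) {
  stopifnot(inherits(ind, "waggle_fit"), inherits(col, "waggle_fit"))
  if (ind$model_kind != "individual" || col$model_kind != "collective")
    stop_input("compare_models() expects an individual fit and a collective fit")
  if (!identical(ind$hive_id, col$hive_id))
    stop_input("fits come from different hives")
  aics <- c(individual = ind$aic, collective = col$aic)
  delta <- aics - min(aics)
  w <- exp(-delta / 2); w <- w / sum(w)
  delta_aic <- ind$aic - col$aic
  selected <- if (delta_aic > 1e-9) "collective" else "individual"
  structure(list(hive_id = ind$hive_id,
                 fits = list(individual = ind, collective = col),
                 delta_aic = delta_aic, akaike_weights = w,
                 selected = selected,
                 waggle_dance_use = 1 - col$params$p,
                 gof_pvalues = NULL),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Hive '%s': AIC individual = %.2f, collective = %.2f (delta = %.2f)\n",
              x$hive_id, x$fits$individual$aic, x$fits$collective$aic, x$delta_aic))
  cat(sprintf("  Akaike weights: individual %.3f, collective %.3f -> %s selected\n",
              x$akaike_weights["individual"], x$akaike_weights["collective"],
              x$selected))
  cat(sprintf("  waggle dance use (1 - p, collective fit) = %.3f\n",
              x$waggle_dance_use))
  if (!is.null(x$gof_pvalues))
    cat(sprintf("  bootstrap KS GOF p-values: individual %.3f, collective %.3f\n",
                x$gof_pvalues["individual"], x$gof_pvalues["collective"]))
  invisible(x)
}

#' Fit both models to data pooled across hives
#'
#' Concatenates the durations of several hives into one dataset (truncation
#' point = the global minimum), fits the individual and collective models,
#' and returns the comparison. Used to ask whether hives within a landscape
#' class behave like one homogeneous colony: if they do not, the sum of the
#' per-hive best AICs will beat the pooled AIC by a wide margin.
#'
#' @param datasets A list of [waggle_dataset()] objects (at least 2 for
#'   `pooled_summary()`; `fit_pooled()` accepts 1).
#' @param settings A [fit_settings()] object.
#' @param pooled_id Label for the pooled pseudo-hive.
#' @return `fit_pooled()`: a `model_comparison` for the pooled data.
#'   `pooled_summary()`: a list with the per-hive comparisons, the pooled
#'   comparison, `sum_best_aic` (sum of per-hive winning AICs),
#'   `pooled_best_aic`, `delta_aic` (pooled minus summed) and Akaike weights
#'   between the per-hive ensemble and the pooled description.
#' @export
fit_pooled <- function(datasets, settings = fit_settings(), pooled_id = "pooled") {
  if (inherits(datasets, "waggle_dataset")) datasets <- list(datasets)
  if (length(datasets) < 1) stop_input("datasets must contain at least one hive")
  all_x <- unlist(lapply(datasets, function(d) d$durations))
  pooled <- waggle_dataset(pooled_id, all_x)
  compare_models(fit_individual(pooled, settings), fit_collective(pooled, settings))
}

#' @rdname fit_pooled
#' @export
pooled_summary <- function(datasets, settings = fit_settings(), pooled_id = "pooled") {
  if (length(datasets) < 2) stop_input("pooled_summary() needs at least 2 hives")
  per_hive <- lapply(datasets, function(d)
    compare_models(fit_individual(d, settings), fit_collective(d, settings)))
  pooled <- fit_pooled(datasets, settings, pooled_id)
  sum_best <- sum(vapply(per_hive, function(cmp) cmp$fits[[cmp$selected]]$aic, 0))
  pooled_best <- pooled$fits[[pooled$selected]]$aic
  aics <- c(per_hive = sum_best, pooled = pooled_best)
  delta <- aics - min(aics)
  w <- exp(-delta / 2); w <- w / sum(w)
  list(per_hive = per_hive, pooled = pooled,
       sum_best_aic = sum_best, pooled_best_aic = pooled_best,
       delta_aic = pooled_best - sum_best, akaike_weights = w)
}
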