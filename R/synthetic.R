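#' Configuration for a synthetic multi-hive dance study
#'
#' Describes a study of `n_hives` observation hives, each contributing
#' `per_hive_n` decoded waggle-run durations drawn from the scout/recruit
#' mixture with hive-specific scout fraction `p` and minimum duration `m`.
#' The defaults emulate the scale of a field study of 20 hives with ~141
#' decoded dances each (2820 in total). Component parameters default to
#' values giving waggle runs of roughly 0.3-5 s: the scout component decays
#' gently up to the maximum duration `1/a_s = 5` s, while the recruit
#' component (Rayleigh intensity `a_r^2 * b_r = 0.6`) is concentrated below
#' ~1.5 s, the short-distance hump characteristic of recruitment. See the
#' methods vignette for how these defaults were chosen.
#'
#' @param n_hives Number of hives (default 20).
#' @param per_hive_n Durations per hive, a single count or one per hive
#'   (default 141; fixed, not Poisson, for determinism).
#' @param p_by_hive Scout fractions, one per hive; `NULL` draws them
#'   uniformly on `[0.05, 0.95]` under the study seed.
#' @param a_s,b_s,a_r,b_r Component parameters, scalars (shared) or one per
#'   hive.
#' @param m_by_hive Minimum durations, one per hive; `NULL` draws them
#'   uniformly on `[0.3, 0.7]` s.
#' @param site_class Optional site labels recycled across hives.
#' @param calibration Named pair `c(slope, intercept)` for the linear
#'   duration-to-distance calibration attached to the study (no defaults are
#'   claimed as field-calibrated; supply your own).
#' @param seed Integer seed for the whole study.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_hives = 20, per_hive_n = 141, p_by_hive = NULL,
                         a_s = 0.2, b_s = 1, a_r = 0.2, b_r = 15,
                         m_by_hive = NULL, site_class = NULL,
                         calibration = c(slope = 1, intercept = 0),
                         seed = NULL) {
  stopifnot(n_hives >= 1, all(per_hive_n >= 1))
  structure(list(n_hives = as.integer(n_hives),
                 per_hive_n = rep_len(as.integer(per_hive_n), n_hives),
                 p_by_hive = p_by_hive,
                 a_s = rep_len(a_s, n_hives), b_s = rep_len(b_s, n_hives),
                 a_r = rep_len(a_r, n_hives), b_r = rep_len(b_r, n_hives),
                 m_by_hive = m_by_hive, site_class = site_class,
                 calibration = calibration, seed = seed),
            class = "study_config")
}

#' Generate a synthetic multi-hive study with known ground truth
#'
#' Draws each hive's durations from the mixture model with that hive's
#' parameters via [rmixture()]. The generating parameters are attached as a
#' `ground_truth` attribute (a data frame, one row per hive) so that
#' parameter-recovery and model-selection behaviour can be scored against
#' the truth.
#'
#' @param config A [study_config()] object.
#' @return A list of [waggle_dataset()] objects with attribute
#'   `ground_truth`.
#' @examples
#' study <- generate_study(study_config(n_hives = 3, per_hive_n = 50, seed = 1))
#' attr(study, "ground_truth")
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  with_seed(config$seed, {
    n <- config$n_hives
    p <- if (is.null(config$p_by_hive)) runif(n, 0.05, 0.95)
         else rep_len(config$p_by_hive, n)
    m <- if (is.null(config$m_by_hive)) runif(n, 0.3, 0.7)
         else rep_len(config$m_by_hive, n)
    site <- if (is.null(config$site_class)) rep(NA_character_, n)
            else rep_len(config$site_class, n)
    datasets <- vector("list", n)
    for (i in seq_len(n)) {
      params <- tryCatch(
        mixture_params(p[i],
                       scout_params(config$a_s[i], config$b_s[i], m[i]),
                       recruit_params(config$a_r[i], config$b_r[i], m[i])),
        error = function(e)
          stop_param(sprintf("hive %d: invalid parameters (%s)",
                             i, conditionMessage(e))))
      x <- rmixture(config$per_hive_n[i], params)
      datasets[[i]] <- waggle_dataset(sprintf("hive_%02d", i), x,
                                      site_class = if (is.na(site[i])) NULL
                                                   else site[i])
    }
    attr(datasets, "ground_truth") <- data.frame(
      hive_id = sprintf("hive_%02d", seq_len(n)), p = p,
      a_s = config$a_s, b_s = config$b_s, a_r = config$a_r, b_r = config$b_r,
      m = m, n = config$per_hive_n, site_class = site,
      stringsAsFactors = FALSE)
    datasets
  })
}

#' Convert waggle-run durations to foraging distances (and back)
#'
#' Waggle-run duration and foraging distance are linearly related; the slope
#' and intercept are a per-study calibration that must be supplied by the
#' user (they vary between landscapes and studies and none are built in).
#'
#' @param duration Durations (s), nonnegative.
#' @param calibration Named pair `c(slope, intercept)`: distance =
#'   `slope * duration + intercept` (slope in m/s, intercept in m).
#' @param distance Distances (m) for the inverse transformation.
#' @return Distances in metres (`duration_to_distance`) or durations in
#'   seconds (`distance_to_duration`). Negative results are clipped to zero
#'   with a warning.
#' @examples
#' duration_to_distance(2, c(slope = 750, intercept = 0))  # 1500
#' @export
duration_to_distance <- function(duration, calibration) {
  if (any(duration < 0)) stop_input("durations must be nonnegative")
  out <- calibration[["slope"]] * duration + calibration[["intercept"]]
  if (any(out < 0)) {
    warning("negative distances clipped to zero")
    out <- pmax(out, 0)
  }
  unname(out)
}

#' @rdname duration_to_distance
#' @export
distance_to_duration <- function(distance, calibration) {
  out <- (distance - calibration[["intercept"]]) / calibration[["slope"]]
  if (any(out < 0)) {
    warning("negative durations clipped to zero")
    out <- pmax(out, 0)
  }
  unname(out)
}
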