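#' Parameter sets for the scout, recruit and mixture duration distributions
#'
#' Constructors with validation for the parameters of the dancefloor duration
#' model. Durations are in seconds throughout.
#'
#' The scout component is a truncated, linearly tapered exponential on
#' `[m, 1/a_s]`: `a_s` is the reciprocal of the maximum waggle-run duration a
#' scout can report, `b_s` a dimensionless intensity factor (`a_s * b_s` is the
#' intensity of resources found by scouts). The recruit component is a
#' truncated, tapered Rayleigh on `[m, 1/a_r]`: `a_r^2 * b_r` is the intensity
#' of high-quality resources reported by recruits. `m` is the minimum recorded
#' waggle-run duration; both components share it and place zero density
#' below it.
#'
#' @param a_s,a_r Inverse-duration scale parameters (1/s), strictly positive,
#'   with `a * m < 1` so the support is nonempty.
#' @param b_s,b_r Dimensionless intensity factors, strictly positive.
#' @param m Minimum recorded waggle-run duration (s), nonnegative.
#' @param p Fraction of scout trips, in `[0, 1]`; `1 - p` is the fraction of
#'   recruit trips ("waggle dance use").
#' @param scout A `scout_params` object.
#' @param recruit A `recruit_params` object. Must share `m` with `scout`.
#'
#' @return A classed list of validated parameters.
#' @examples
#' sp <- scout_params(a_s = 0.2, b_s = 2, m = 0.5)
#' rp <- recruit_params(a_r = 0.15, b_r = 3, m = 0.5)
#' mixture_params(p = 0.4, scout = sp, recruit = rp)
#' @export
scout_params <- function(a_s, b_s, m) {
  if (!is.finite(a_s) || a_s <= 0) stop_param("a_s must be a positive finite number")
  if (!is.finite(b_s) || b_s <= 0) stop_param("b_s must be a positive finite number")
  if (!is.finite(m) || m < 0) stop_param("m must be a nonnegative finite number")
  if (a_s * m >= 1) stop_param("a_s * m must be < 1 (support [m, 1/a_s] is empty)")
  structure(list(a_s = a_s, b_s = b_s, m = m), class = "scout_params")
}

#' @rdname scout_params
#' @export
recruit_params <- function(a_r, b_r, m) {
  if (!is.finite(a_r) || a_r <= 0) stop_param("a_r must be a positive finite number")
  if (!is.finite(b_r) || b_r <= 0) stop_param("b_r must be a positive finite number")
  if (!is.finite(m) || m < 0) stop_param("m must be a nonnegative finite number")
  if (a_r * m >= 1) stop_param("a_r * m must be < 1 (support [m, 1/a_r] is empty)")
  structure(list(a_r = a_r, b_r = b_r, m = m), class = "recruit_params")
}

#' @rdname scout_params
#' @export
mixture_params <- function(p, scout, recruit) {
  if (!inherits(scout, "scout_params")) scout <- do.call(scout_params, unclass(scout))
  if (!inherits(recruit, "recruit_params")) recruit <- do.call(recruit_params, unclass(recruit))
  if (!is.finite(p) || p < 0 || p > 1) stop_param("p must lie in [0, 1]")
  if (!isTRUE(all.equal(scout$m, recruit$m)))
    stop_param("scout and recruit components must share the same minimum duration m")
  structure(list(p = p, scout = scout, recruit = recruit, m = scout$m),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf(
    "Mixture parameters (durations in s):\n  p (scout fraction) = %.4f  [waggle dance use = %.4f]\n",
    x$p, 1 - x$p))
  cat(sprintf("  scout:   a_s = %.5f  b_s = %.4f\n", x$scout$a_s, x$scout$b_s))
  cat(sprintf("  recruit: a_r = %.5f  b_r = %.4f\n", x$recruit$a_r, x$recruit$b_r))
  cat(sprintf("  m = %.4f\n", x$m))
  invisible(x)
}

#' A single hive's decoded waggle-run durations
#'
#' Bundles the durations decoded from one observation hive's dancefloor with
#' the minimum duration `m` used as the truncation point of the duration
#' model, and optionally a landscape class for the hive's site.
#'
#' @param hive_id Label identifying the hive.
#' @param durations Numeric vector of waggle-run durations (s), all positive.
#' @param m Minimum duration considered; defaults to `min(durations)`.
#' @param site_class Optional site label (e.g. `"urban"`, `"agri-rural"`).
#' @return An object of class `waggle_dataset`.
#' @examples
#' waggle_dataset("H1", c(0.8, 1.2, 2.0))
#' @export
waggle_dataset <- function(hive_id, durations, m = min(durations), site_class = NULL) {
  durations <- as.numeric(durations)
  if (length(durations) < 1) stop_input("durations must contain at least one value")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop_input("all durations must be positive finite numbers")
  if (!is.finite(m) || m < 0 || m > min(durations))
    stop_input("m must be nonnegative and no larger than min(durations)")
  structure(list(hive_id = as.character(hive_id), durations = durations,
                 m = m, site_class = site_class),
            class = "waggle_dataset")
}

#' @export
print.waggle_dataset <- function(x, ...) {
  cat(sprintf("Waggle dataset '%s': %d durations, m = %.3f s%s\n",
              x$hive_id, length(x$durations), x$m,
              if (is.null(x$site_class)) "" else paste0(" (", x$site_class, ")")))
  invisible(x)
}

# Coerce a numeric vector or waggle_dataset to a bare duration vector.
as_durations <- function(data) {
  if (inherits(data, "waggle_dataset")) data$durations
  else if (is.numeric(data)) as.numeric(data)
  else stop_input("data must be a waggle_dataset or a numeric vector of durations")
}
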