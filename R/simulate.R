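#' Configuration for the central-place foraging simulation
#'
#' Sets up a circular environment of radius `radius` (lengths in km) centred
#' on the hive, with resource patches scattered uniformly in area at density
#' `resource_density` per unit area. The default density of 200 per squared
#' unit corresponds to one patch per 5000 m^2 and gives an expected
#' `density * pi * radius^2 ~ 3927` patches at the default radius.
#'
#' Scouts search along random piecewise-linear paths from the hive; each
#' straight segment sweeps a corridor of width `corridor_width`. Of the
#' resources inside the swept corridors the one closest to the hive is
#' selected, and reported to the shared dance pool if its quality exceeds
#' `quality_threshold`. Recruits sample a dance from the pool with probability
#' proportional to the advertised resource's profitability and visit it,
#' adding their resource to the pool at the next iteration.
#'
#' `profitability_mode = "literal"` (default) scores a resource as
#' `quality * distance`. Because the pool's scout-found distances decay
#' roughly exponentially, this distance-proportional sampling tilts recruit
#' visits into the rising-then-falling (Rayleigh-like) shape, and is the mode
#' that reproduces the scout-exponential / recruit-Rayleigh dichotomy.
#' `"inverse_distance"` scores a resource as
#' `quality / max(distance, 0.05 * radius)`, implementing the premise that
#' recruitment favours close profitable sites; under it recruits converge
#' onto the few nearest patches (shorter mean trips, near-degenerate distance
#' atoms). The methods vignette discusses the tension between the two
#' readings.
#'
#' @param radius Environment radius (default 2.5).
#' @param resource_density Mean resources per unit area (default 200).
#' @param n_bees Number of foraging bees (default 100).
#' @param n_iterations Number of time steps (default 100).
#' @param record_every Trips are stamped with the end of the
#'   `record_every`-step window they fall in (default 5).
#' @param corridor_width Width of a scout's search corridor (default 0.01).
#' @param quality_range Range of uniform resource quality (default `c(0, 10)`).
#' @param quality_threshold Minimum quality a scout will report (default 5,
#'   the midpoint of the quality range).
#' @param replacement_rate Expected number of resource replacements over the
#'   whole run (default 1.5, i.e. "once or twice per simulation").
#' @param profitability_mode `"literal"` or `"inverse_distance"`.
#' @param scout_fraction Fraction of bees behaving as scouts (default 0.5).
#' @param max_segments Scout paths have `U{1, ..., max_segments}` segments.
#' @param max_segment_length Segment lengths are `U(0, max_segment_length)`
#'   (default `radius / 2`).
#' @param seed Integer seed; runs are bitwise reproducible given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(radius = 2.5, resource_density = 200, n_bees = 100,
                       n_iterations = 100, record_every = 5,
                       corridor_width = 0.01, quality_range = c(0, 10),
                       quality_threshold = 5, replacement_rate = 1.5,
                       profitability_mode = c("literal", "inverse_distance"),
                       scout_fraction = 0.5, max_segments = 10,
                       max_segment_length = radius / 2, seed = NULL) {
  profitability_mode <- match.arg(profitability_mode)
  stopifnot(radius > 0, resource_density > 0, n_bees >= 1, n_iterations >= 1,
            record_every >= 1, corridor_width > 0, corridor_width < radius,
            length(quality_range) == 2, quality_range[1] < quality_range[2],
            replacement_rate >= 0, scout_fraction >= 0, scout_fraction <= 1,
            max_segments >= 1, max_segment_length > 0)
  structure(list(radius = radius, resource_density = resource_density,
                 n_bees = as.integer(n_bees),
                 n_iterations = as.integer(n_iterations),
                 record_every = as.integer(record_every),
                 corridor_width = corridor_width,
                 quality_range = quality_range,
                 quality_threshold = quality_threshold,
                 replacement_rate = replacement_rate,
                 profitability_mode = profitability_mode,
                 scout_fraction = scout_fraction,
                 max_segments = as.integer(max_segments),
                 max_segment_length = max_segment_length,
                 seed = seed),
            class = "sim_config")
}

resource_profitability <- function(quality, distance, mode, radius) {
  switch(mode,
         inverse_distance = quality / pmax(distance, 0.05 * radius),
         literal = quality * distance)
}

# Indices of resources (given coords) inside the corridor swept by one scout
# path: per segment, a point is inside if its projection onto the segment axis
# lies within [0, L] and its perpendicular distance is at most half the width.
scout_path_hits <- function(rx, ry, alive, cfg) {
  n_seg <- sample.int(cfg$max_segments, 1)
  lens <- runif(n_seg, 0, cfg$max_segment_length)
  angs <- runif(n_seg, 0, 2 * pi)
  vx <- cumsum(c(0, lens * cos(angs)))
  vy <- cumsum(c(0, lens * sin(angs)))
  half_w <- cfg$corridor_width / 2
  hits <- logical(length(rx))
  for (s in seq_len(n_seg)) {
    L <- lens[s]
    if (L <= 0) next
    dx <- (vx[s + 1] - vx[s]) / L; dy <- (vy[s + 1] - vy[s]) / L
    px <- rx - vx[s]; py <- ry - vy[s]
    t <- px * dx + py * dy
    perp <- abs(py * dx - px * dy)
    hits <- hits | (t >= 0 & t <= L & perp <= half_w)
  }
  which(hits & alive)
}

#' Run the agent-based scout/recruit foraging simulation
#'
#' Simulates `n_iterations` foraging steps in the environment described by a
#' [sim_config()]. Scouts search for resources along random paths and report
#' the nearest sufficiently good find to a shared dance pool; recruits sample
#' dances from the pool in proportion to profitability, visit the advertised
#' resource, and re-advertise it at the next step. Resources are occasionally
#' replaced by fresh ones at random positions. Every completed trip is
#' recorded with its type and the distance of the visited resource from the
#' hive.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_result` with `trips` (data frame:
#'   `time_step`, `trip_type` = `"scout"`/`"recruit"`, `distance`),
#'   `pool_history` (dance-pool size per step), `n_resources_initial`, and
#'   `config` (the configuration echo).
#' @examples
#' res <- run_simulation(sim_config(n_iterations = 20, n_bees = 20, seed = 1))
#' table(res$trips$trip_type)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    area <- pi * config$radius^2
    n0 <- rpois(1, config$resource_density * area)
    theta <- runif(n0, 0, 2 * pi)
    rho <- config$radius * sqrt(runif(n0))
    qual <- runif(n0, config$quality_range[1], config$quality_range[2])
    rx <- rho * cos(theta); ry <- rho * sin(theta)
    alive <- rep(TRUE, n0)
    prof <- resource_profitability(qual, rho, config$profitability_mode,
                                   config$radius)

    n_scouts <- round(config$n_bees * config$scout_fraction)
    n_recruits <- config$n_bees - n_scouts
    pool <- integer(0)           # resource indices advertised on the dancefloor
    pending <- integer(0)        # recruit re-advertisements for the next step
    p_replace <- min(1, config$replacement_rate / config$n_iterations)

    step_v <- integer(0); type_v <- character(0); dist_v <- numeric(0)
    pool_history <- integer(config$n_iterations)

    for (step in seq_len(config$n_iterations)) {
      stamp <- ceiling(step / config$record_every) * config$record_every
      pool <- c(pool[alive[pool]], pending[alive[pending]])
      pending <- integer(0)
      pool_history[step] <- length(pool)

      new_dances <- integer(0)
      for (s in seq_len(n_scouts)) {
        found <- scout_path_hits(rx, ry, alive, config)
        if (length(found) == 0) next
        nearest <- found[which.min(rho[found])]
        if (qual[nearest] > config$quality_threshold) {
          new_dances <- c(new_dances, nearest)
          step_v <- c(step_v, stamp); type_v <- c(type_v, "scout")
          dist_v <- c(dist_v, rho[nearest])
        }
      }

      if (n_recruits > 0 && length(pool) > 0) {
        w <- prof[pool]
        picks <- if (length(pool) == 1) rep(pool, n_recruits)
                 else sample(pool, n_recruits, replace = TRUE, prob = w)
        step_v <- c(step_v, rep(stamp, n_recruits))
        type_v <- c(type_v, rep("recruit", n_recruits))
        dist_v <- c(dist_v, rho[picks])
        pending <- picks
      }
      pool <- c(pool, new_dances)

      if (runif(1) < p_replace && any(alive)) {
        gone <- sample(which(alive), 1)
        alive[gone] <- FALSE
        th_new <- runif(1, 0, 2 * pi)
        rho_new <- config$radius * sqrt(runif(1))
        q_new <- runif(1, config$quality_range[1], config$quality_range[2])
        rx <- c(rx, rho_new * cos(th_new)); ry <- c(ry, rho_new * sin(th_new))
        rho <- c(rho, rho_new); qual <- c(qual, q_new)
        prof <- c(prof, resource_profitability(q_new, rho_new,
                                               config$profitability_mode,
                                               config$radius))
        alive <- c(alive, TRUE)
      }
    }

    structure(list(trips = data.frame(time_step = step_v, trip_type = type_v,
                                      distance = dist_v,
                                      stringsAsFactors = FALSE),
                   pool_history = pool_history,
                   n_resources_initial = n0,
                   config = config),
              class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  tab <- table(x$trips$trip_type)
  cat(sprintf("Foraging simulation: %d resources, %d steps, %d trips (%s)\n",
              x$n_resources_initial, x$config$n_iterations, nrow(x$trips),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Analytic maximum-likelihood fits for trip-distance distributions
#'
#' `fit_exponential()` fits the exponential density `lambda * exp(-lambda x)`
#' and returns the closed-form MLE `lambda_hat = 1 / mean(x)`.
#' `fit_rayleigh()` fits the Rayleigh-type density
#' `2 * pi * lambda * x * exp(-pi * lambda * x^2)` and returns
#' `lambda_hat = 1 / (pi * mean(x^2))`. Because both densities start at zero,
#' distances are first shifted by their minimum (`x - min(x)`) when
#' `shift = TRUE` (the default).
#'
#' @param distances Numeric vector of trip distances (>= 2 values).
#' @param shift Subtract `min(distances)` before fitting.
#' @return The estimated rate/intensity `lambda_hat`.
#' @examples
#' fit_exponential(c(1, 2, 3))        # shifted to (0, 1, 2); 1/mean = 1
#' fit_rayleigh(c(1, 1, 1), shift = FALSE)  # 1/pi
#' @export
fit_exponential <- function(distances, shift = TRUE) {
  if (length(distances) < 2) stop_input("need at least 2 distances")
  z <- if (shift) distances - min(distances) else distances
  mz <- mean(z)
  if (mz <= 0) stop_input("degenerate sample: all distances equal (infinite rate)")
  1 / mz
}

#' @rdname fit_exponential
#' @export
fit_rayleigh <- function(distances, shift = TRUE) {
  if (length(distances) < 2) stop_input("need at least 2 distances")
  z <- if (shift) distances - min(distances) else distances
  ms <- mean(z^2)
  if (ms <= 0) stop_input("degenerate sample: all distances equal (infinite intensity)")
  1 / (pi * ms)
}

# Log-likelihoods of the shifted sample under the two analytic fits; the
# shifted minimum (exactly zero) is dropped because the Rayleigh density
# vanishes there, which would veto the comparison on a single boundary point.
trip_loglik <- function(distances) {
  z <- distances - min(distances)
  z <- z[z > 0]
  lam_e <- 1 / mean(z)
  lam_r <- 1 / (pi * mean(z^2))
  list(lambda_exp = lam_e, lambda_ray = lam_r,
       loglik_exp = sum(log(lam_e) - lam_e * z),
       loglik_ray = sum(log(2 * pi * lam_r * z) - pi * lam_r * z^2))
}

#' Which distribution best describes each trip type?
#'
#' Fits the exponential and Rayleigh forms (analytic MLEs, after min-shift)
#' to the scout-trip and recruit-trip distances of a simulation run and
#' reports per-type log-likelihoods and the winning form. Under the default
#' configuration scout trips are expected to be better described by the
#' exponential and recruit trips by the Rayleigh.
#'
#' @param result A `sim_result`, or a data frame with columns `trip_type` and
#'   `distance` (e.g. trips pooled over several runs).
#' @param min_trips Minimum number of trips per type required.
#' @return A data frame with one row per trip type: `n`, the two
#'   `lambda` estimates, both log-likelihoods, and `best` (`"exponential"` or
#'   `"rayleigh"`).
#' @export
classify_trip_distributions <- function(result, min_trips = 100) {
  trips <- if (inherits(result, "sim_result")) result$trips else result
  if (!all(c("trip_type", "distance") %in% names(trips)))
    stop_input("result must contain trip_type and distance columns")
  out <- lapply(c("scout", "recruit"), function(tt) {
    d <- trips$distance[trips$trip_type == tt]
    if (length(d) < min_trips)
      stop_input(sprintf("insufficient %s trips: %d < %d", tt, length(d), min_trips))
    ll <- trip_loglik(d)
    data.frame(trip_type = tt, n = length(d),
               lambda_exp = ll$lambda_exp, lambda_ray = ll$lambda_ray,
               loglik_exp = ll$loglik_exp, loglik_ray = ll$loglik_ray,
               best = if (ll$loglik_exp >= ll$loglik_ray) "exponential" else "rayleigh",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
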