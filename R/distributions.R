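#' Scout, recruit and mixture distributions of waggle-run durations
#'
#' Density, distribution function and random generation for the dancefloor
#' duration model. The scout component is an exponential decay in duration,
#' tapered by the hinge factor `(1 - a_s x)+` so that no scout reports a
#' duration beyond `1/a_s`; the recruit component is a Rayleigh-type density
#' tapered by `(1 - a_r x)+`. Both are truncated below at the minimum recorded
#' duration `m`. The full dancefloor density is the convex combination
#' `p * f_s(x) + (1 - p) * f_r(x)`.
#'
#' The scout density on `[m, 1/a_s]` is
#' \deqn{f_s(x) = a_s M_s^{-1} b_s e^{-b_s a_s (x - m)} (1 - a_s x)_+}
#' with normalizer
#' \deqn{M_s = (1 - a_s m) - b_s^{-1} (1 - e^{-b_s (1 - a_s m)}).}
#' The recruit density on `[m, 1/a_r]` is
#' \deqn{f_r(x) = M_r^{-1} 2 \pi a_r^2 b_r x e^{-\pi b_r (a_r x)^2} (1 - a_r x)_+}
#' with normalizer
#' \deqn{M_r = (1 - a_r m) e^{-\pi b_r (a_r m)^2} +
#'   \frac{\mathrm{erf}(a_r m \sqrt{\pi b_r}) - \mathrm{erf}(\sqrt{\pi b_r})}
#'        {2 \sqrt{b_r}}.}
#' As `m -> 0` and for `a_r x << 1` the recruit component reduces to the
#' plain Rayleigh density `2 \pi \lambda x e^{-\pi \lambda x^2}` with
#' intensity `\lambda = a_r^2 b_r`.
#'
#' Densities are exactly zero below `m` and at or above the component's
#' upper support limit `1/a`.
#'
#' @param x Vector of durations (s).
#' @param params For the component functions, a [scout_params()] or
#'   [recruit_params()] object; for the mixture functions, a
#'   [mixture_params()] object.
#' @param n Number of draws.
#' @param seed Optional integer seed; when supplied the caller's RNG state is
#'   left untouched and the draw is reproducible.
#' @return `dscout`, `drecruit`, `dmixture`: densities (1/s). `pscout`,
#'   `precruit`, `pmixture`: cumulative probabilities. `rmixture`: a numeric
#'   vector of durations.
#' @examples
#' sp <- scout_params(0.2, 2, 0.5)
#' rp <- recruit_params(0.15, 3, 0.5)
#' mp <- mixture_params(0.4, sp, rp)
#' integrate(dmixture, 0.5, 1 / 0.15, params = mp)$value  # ~1
#' pmixture(2, mp)
#' summary(rmixture(500, mp, seed = 1))
#' @name waggle-distributions
NULL

#' Normalizing constants of the scout and recruit components
#'
#' `scout_norm()` returns \eqn{M_s}, `recruit_norm()` returns \eqn{M_r}; see
#' [waggle-distributions] for the closed forms. These are the factors that make
#' the unnormalized integrands integrate to one over `[m, 1/a]`.
#'
#' @param params A [scout_params()] or [recruit_params()] object.
#' @return A positive scalar.
#' @export
scout_norm <- function(params) {
  stopifnot(inherits(params, "scout_params"))
  cc <- 1 - params$a_s * params$m
  u <- params$b_s * cc
  # M_s = (1 - a_s m) - (1 - e^{-u})/b_s = c * (e^{-u} - 1 + u)/u, with the
  # last factor evaluated stably for small u (it is O(u) and the naive form
  # cancels catastrophically there).
  f <- if (u < 1e-3) u^2 / 2 * (1 - u / 3 + u^2 / 12) else u + expm1(-u)
  cc * f / u
}

# Tail-accurate complementary error function.
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# Stable \int_lo^hi t (1 - t) e^{-c t^2} dt, 0 <= lo <= hi <= 1. The recruit
# normalizer and CDF are both proportional to this integral. The textbook
# antiderivative cancels catastrophically both as c -> 0 (the integral is
# O(c) smaller than its terms) and for c lo^2 >> 1 (the erf difference is a
# difference of values rounding to 1), so the integral is assembled from
# nonnegative pieces: a power series in c when c hi^2 is small, otherwise a
# factored form with the Gaussian tail expressed through erfc.
ray_integral <- function(lo, hi, c) {
  if (c * hi^2 < 1) {
    k <- 0:25
    terms <- (-c)^k / factorial(k) *
      ((hi^(2 * k + 2) - lo^(2 * k + 2)) / (2 * k + 2) -
       (hi^(2 * k + 3) - lo^(2 * k + 3)) / (2 * k + 3))
    sum(terms)
  } else {
    sig <- c * (hi^2 - lo^2)
    # int t e^{-ct^2} - int t^2 e^{-ct^2}, each factored by e^{-c lo^2}:
    # bracket = (1-lo)(1 - e^{-sig}) + (hi-lo) e^{-sig}, all nonnegative.
    bracket <- (1 - lo) * (-expm1(-sig)) + (hi - lo) * exp(-sig)
    exp(-c * lo^2) * bracket / (2 * c) -
      sqrt(pi) * (erfc(sqrt(c) * lo) - erfc(sqrt(c) * hi)) / (4 * c^1.5)
  }
}

#' @rdname scout_norm
#' @export
recruit_norm <- function(params) {
  stopifnot(inherits(params, "recruit_params"))
  a <- params$a_r; b <- params$b_r; m <- params$m
  # Equals (1 - a m) e^{-pi b (a m)^2} +
  #        (erf(a m sqrt(pi b)) - erf(sqrt(pi b))) / (2 sqrt(b)),
  # but computed without cancellation (the two terms are O(1) while their
  # sum is O(b) as b -> 0).
  2 * pi * b * ray_integral(a * m, 1, pi * b)
}

# The recruit normalizer with the erf argument a_r*sqrt(pi*b_r*m) instead of
# a_r*m*sqrt(pi*b_r). Kept only so tests can document that this variant does
# NOT normalize the recruit density (the exported recruit_norm() is the form
# obtained by direct integration, which does).
recruit_norm_alt <- function(params) {
  a <- params$a_r; b <- params$b_r; m <- params$m
  (1 - a * m) * exp(-pi * b * (a * m)^2) +
    (erf(a * sqrt(pi * b * m)) - erf(sqrt(pi * b))) / (2 * sqrt(b))
}

#' @rdname waggle-distributions
#' @export
dscout <- function(x, params) {
  stopifnot(inherits(params, "scout_params"))
  a <- params$a_s; b <- params$b_s; m <- params$m
  d <- numeric(length(x))
  inside <- is.finite(x) & x >= m & x < 1 / a
  xi <- x[inside]
  d[inside] <- a * b / scout_norm(params) *
    exp(-b * a * (xi - m)) * (1 - a * xi)
  d
}

#' @rdname waggle-distributions
#' @export
pscout <- function(x, params) {
  stopifnot(inherits(params, "scout_params"))
  a <- params$a_s; b <- params$b_s; m <- params$m
  cc <- 1 - a * m
  p <- numeric(length(x))
  p[x >= 1 / a] <- 1
  inside <- is.finite(x) & x >= m & x < 1 / a
  v <- a * (x[inside] - m)
  # G(v) = int_0^v b e^{-bu} (cc - u) du = cc (1 - e^{-bv}) - v h(bv), with
  # h(w) = (1 - (1 + w) e^{-w})/w = w/2 - w^2/3 + ... evaluated stably.
  w <- b * v
  h <- ifelse(w < 1e-3, w / 2 - w^2 / 3 + w^3 / 8,
              (1 - (1 + w) * exp(-w)) / w)
  G <- cc * (-expm1(-w)) - v * h
  p[inside] <- G / scout_norm(params)
  pmin(pmax(p, 0), 1)
}

#' @rdname waggle-distributions
#' @export
drecruit <- function(x, params) {
  stopifnot(inherits(params, "recruit_params"))
  a <- params$a_r; b <- params$b_r; m <- params$m
  d <- numeric(length(x))
  inside <- is.finite(x) & x >= m & x < 1 / a
  xi <- x[inside]
  d[inside] <- 2 * pi * a^2 * b * xi * exp(-pi * b * (a * xi)^2) *
    (1 - a * xi) / recruit_norm(params)
  d
}

#' @rdname waggle-distributions
#' @export
precruit <- function(x, params) {
  stopifnot(inherits(params, "recruit_params"))
  a <- params$a_r; b <- params$b_r; m <- params$m
  p <- numeric(length(x))
  p[x >= 1 / a] <- 1
  inside <- is.finite(x) & x >= m & x < 1 / a
  xi <- x[inside]
  # F(x) = I(a m, a x) / I(a m, 1) with I the stable taper-weighted Rayleigh
  # integral; the 2 pi b prefactors cancel.
  denom <- ray_integral(a * m, 1, pi * b)
  p[inside] <- vapply(xi, function(z) ray_integral(a * m, a * z, pi * b), 0) /
    denom
  pmin(pmax(p, 0), 1)
}

#' @rdname waggle-distributions
#' @export
dmixture <- function(x, params) {
  stopifnot(inherits(params, "mixture_params"))
  params$p * dscout(x, params$scout) + (1 - params$p) * drecruit(x, params$recruit)
}

#' @rdname waggle-distributions
#' @export
pmixture <- function(x, params) {
  stopifnot(inherits(params, "mixture_params"))
  params$p * pscout(x, params$scout) + (1 - params$p) * precruit(x, params$recruit)
}

# Rejection sampler for the scout component: truncated-exponential proposal on
# [m, 1/a_s], acceptance probability proportional to the hinge taper.
rscout <- function(n, params) {
  a <- params$a_s; b <- params$b_s; m <- params$m
  cc <- 1 - a * m
  E <- expm1(-b * cc)
  out <- numeric(0)
  while (length(out) < n) {
    k <- max(n - length(out), 16L)
    u <- runif(k)
    # inverse CDF of the truncated exponential proposal, in expm1/log1p form
    # so it stays exact in the b -> 0 (uniform proposal) limit
    x <- m - log1p(u * E) / (b * a)
    keep <- runif(k) < (1 - a * x) / cc
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

# Rejection sampler for the recruit component: truncated-Rayleigh proposal.
rrecruit <- function(n, params) {
  a <- params$a_r; b <- params$b_r; m <- params$m
  lam <- pi * b * a^2
  E1 <- expm1(-lam * m^2); E2 <- expm1(-pi * b)
  out <- numeric(0)
  while (length(out) < n) {
    k <- max(n - length(out), 16L)
    u <- runif(k)
    # inverse CDF of the truncated Rayleigh proposal; exact as b -> 0
    x <- sqrt(-log1p(E1 - u * (E1 - E2)) / lam)
    keep <- runif(k) < (1 - a * x) / (1 - a * m)
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

#' @rdname waggle-distributions
#' @export
rmixture <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "mixture_params"))
  if (n < 1) stop_input("n must be at least 1")
  with_seed(seed, {
    n_scout <- rbinom(1, n, params$p)
    x <- c(if (n_scout > 0) rscout(n_scout, params$scout),
           if (n - n_scout > 0) rrecruit(n - n_scout, params$recruit))
    sample(x)  # shuffle so component identity is not positional
  })
}

#' Log-likelihood of mixture parameters given observed durations
#'
#' Sums the log mixture density over the observations. If any observation has
#' zero density under `params` (below `m` or at/beyond both upper support
#' limits) the log-likelihood is `-Inf`; optimizers treat such parameter
#' points as inadmissible, which implicitly enforces
#' `a <= 1/max(durations)` during fitting.
#'
#' @param data A [waggle_dataset()] or numeric vector of durations.
#' @param params A [mixture_params()] object.
#' @return The log-likelihood in nats (scalar; possibly `-Inf`).
#' @examples
#' mp <- mixture_params(0.4, scout_params(0.2, 2, 0.5), recruit_params(0.15, 3, 0.5))
#' log_likelihood(c(0.8, 1.1, 2.4), mp)
#' @export
log_likelihood <- function(data, params) {
  x <- as_durations(data)
  if (length(x) == 0) stop_input("data must contain at least one duration")
  d <- dmixture(x, params)
  if (any(d <= 0)) return(-Inf)
  sum(log(d))
}
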