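# Shared fixtures: parameter sets spanning the regimes the tests exercise,
# and the study-default mixture used for recovery-style checks.

ref_scout <- function(m = 0.5) scout_params(a_s = 0.2, b_s = 2, m = m)
ref_recruit <- function(m = 0.5) recruit_params(a_r = 0.15, b_r = 3, m = m)
ref_mixture <- function(p = 0.4, m = 0.5) {
  mixture_params(p, scout_params(0.2, 2, m), recruit_params(0.15, 3, m))
}

# The synthetic-study default components.
study_mixture <- function(p, m = 0.5) {
  mixture_params(p, scout_params(0.2, 1, m), recruit_params(0.2, 15, m))
}

# Draw a random valid (scout, recruit) parameter pair; regimes include small
# and large intensities and truncation points close to the support limit.
random_params <- function() {
  m <- runif(1, 0.05, 1)
  list(
    scout = scout_params(runif(1, 0.05, 0.95) / m, exp(runif(1, log(0.01), log(50))), m),
    recruit = recruit_params(runif(1, 0.05, 0.95) / m, exp(runif(1, log(0.01), log(50))), m),
    p = runif(1))
}

# Quadrature of a density over [lo, hi] with a substitution that spreads
# sharply concentrated integrands (used as the independent normalization
# oracle): s in [0,1] maps to x = sqrt(lo^2 + s*(hi^2 - lo^2)).
quad_density <- function(dens, lo, hi, ...) {
  f <- function(s) {
    x <- sqrt(lo^2 + s * (hi^2 - lo^2))
    dens(x, ...) * (hi^2 - lo^2) / (2 * x)
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-11, subdivisions = 1000L)$value
}
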