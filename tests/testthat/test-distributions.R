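# Scout/recruit/mixture densities: normalization, support, closed-form
# normalizers and CDFs against quadrature, limiting behaviour, sampling.

test_that("parameter constructors reject invalid values", {
  expect_error(scout_params(-0.1, 2, 0.5), class = "wagglefit_param_error")
  expect_error(scout_params(0.2, 0, 0.5), class = "wagglefit_param_error")
  expect_error(scout_params(2.1, 2, 0.5), class = "wagglefit_param_error")  # a*m >= 1
  expect_error(recruit_params(0.15, 3, -1), class = "wagglefit_param_error")
  expect_error(mixture_params(1.2, ref_scout(), ref_recruit()),
               class = "wagglefit_param_error")
  expect_error(mixture_params(0.5, ref_scout(0.4), ref_recruit(0.5)),
               class = "wagglefit_param_error")  # mismatched m
})

test_that("densities vanish outside their support and at the hinge point", {
  sp <- ref_scout(); rp <- ref_recruit()
  expect_identical(dscout(1 / sp$a_s, sp), 0)
  expect_identical(dscout(sp$m - 0.01, sp), 0)
  expect_identical(drecruit(1 / rp$a_r, rp), 0)
  expect_identical(drecruit(rp$m - 0.01, rp), 0)
  x <- seq(sp$m, 1 / sp$a_s - 1e-9, length.out = 50)
  expect_true(all(dscout(x, sp) >= 0))
  expect_true(all(drecruit(seq(rp$m, 1 / rp$a_r - 1e-9, length.out = 50), rp) >= 0))
})

test_that("fixed-parameter densities integrate to one (quadrature oracle)", {
  sp <- ref_scout(); rp <- ref_recruit()
  expect_equal(stats::integrate(dscout, 0.5, 5, params = sp,
                                rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  expect_equal(stats::integrate(drecruit, 0.5, 1 / 0.15, params = rp,
                                rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
})

test_that("closed-form normalizers match quadrature of the unnormalized integrands", {
  set.seed(421)
  for (i in 1:50) {
    pr <- random_params()
    sp <- pr$scout; rp <- pr$recruit
    s_un <- function(x) sp$a_s * sp$b_s * exp(-sp$b_s * sp$a_s * (x - sp$m)) *
      pmax(1 - sp$a_s * x, 0)
    r_un <- function(x) 2 * pi * rp$a_r^2 * rp$b_r * x *
      exp(-pi * rp$b_r * (rp$a_r * x)^2) * pmax(1 - rp$a_r * x, 0)
    expect_equal(scout_norm(sp),
                 quad_density(function(x, ...) s_un(x), sp$m, 1 / sp$a_s),
                 tolerance = 1e-9)
    expect_equal(recruit_norm(rp),
                 quad_density(function(x, ...) r_un(x), rp$m, 1 / rp$a_r),
                 tolerance = 1e-9)
  }
})

test_that("all three densities normalize over 50 random parameter sets", {
  set.seed(77)
  worst <- 0
  for (i in 1:50) {
    pr <- random_params()
    mp <- mixture_params(pr$p, pr$scout, pr$recruit)
    hi_s <- 1 / pr$scout$a_s; hi_r <- 1 / pr$recruit$a_r
    worst <- max(worst,
                 abs(quad_density(dscout, pr$scout$m, hi_s, params = pr$scout) - 1),
                 abs(quad_density(drecruit, pr$recruit$m, hi_r, params = pr$recruit) - 1),
                 abs(quad_density(dmixture, mp$m, max(hi_s, hi_r), params = mp) - 1))
  }
  expect_lt(worst, 1e-7)
})

test_that("the erf-argument variant of the recruit normalizer fails to normalize", {
  # The variant writes erf(a*sqrt(pi*b*m)) where direct integration gives
  # erf(a*m*sqrt(pi*b)); quadrature adjudicates between the two forms.
  rp <- ref_recruit()
  quad <- quad_density(function(x, ...)
    2 * pi * rp$a_r^2 * rp$b_r * x * exp(-pi * rp$b_r * (rp$a_r * x)^2) *
      pmax(1 - rp$a_r * x, 0), rp$m, 1 / rp$a_r)
  expect_equal(recruit_norm(rp), quad, tolerance = 1e-9)
  expect_gt(abs(wagglefit:::recruit_norm_alt(rp) - quad), 1e-3)
})

test_that("mixture density is the convex combination of its components", {
  sp <- ref_scout(); rp <- ref_recruit()
  x <- seq(0.5, 6.5, length.out = 101)
  expect_equal(dmixture(x, mixture_params(1, sp, rp)), dscout(x, sp))
  expect_equal(dmixture(x, mixture_params(0, sp, rp)), drecruit(x, rp))
  expect_equal(dmixture(x, mixture_params(0.5, sp, rp)),
               (dscout(x, sp) + drecruit(x, rp)) / 2)
})

test_that("mixture CDF is 0 at m, 1 at the support end, and matches quadrature", {
  mp <- ref_mixture()
  hi <- max(1 / mp$scout$a_s, 1 / mp$recruit$a_r)
  expect_identical(pmixture(mp$m, mp), 0)
  expect_identical(pmixture(hi, mp), 1)
  expect_equal(pmixture(2, mp),
               stats::integrate(dmixture, 0.5, 2, params = mp,
                                rel.tol = 1e-11)$value,
               tolerance = 1e-8)
  grid <- seq(mp$m, hi, length.out = 400)
  expect_true(all(diff(pmixture(grid, mp)) >= -1e-12))
})

test_that("mixture CDF derivative matches the density on a grid", {
  set.seed(99)
  for (i in 1:5) {
    pr <- random_params()
    mp <- mixture_params(pr$p, pr$scout, pr$recruit)
    hi <- max(1 / pr$scout$a_s, 1 / pr$recruit$a_r)
    x <- seq(mp$m + 0.02 * (hi - mp$m), hi - 0.02 * (hi - mp$m), length.out = 40)
    h <- (hi - mp$m) * 1e-6
    deriv <- (pmixture(x + h, mp) - pmixture(x - h, mp)) / (2 * h)
    expect_equal(deriv, dmixture(x, mp), tolerance = 1e-5)
  }
})

test_that("recruit density approaches the plain Rayleigh once the taper is negligible", {
  # With m = 0 and the recruit mass concentrated well inside the support
  # (large b_r), both the hinge factor and the normalizer tend to 1 and the
  # density reduces to 2*pi*lambda*x*exp(-pi*lambda*x^2), lambda = a_r^2*b_r.
  a <- 0.05; b <- 5000
  rp <- recruit_params(a, b, 0)
  lam <- a^2 * b
  x <- seq(1e-3, 0.005 / a, length.out = 50)
  rayleigh <- 2 * pi * lam * x * exp(-pi * lam * x^2)
  expect_equal(drecruit(x, rp), rayleigh, tolerance = 0.01)
})

test_that("sampling is seed-reproducible and stays inside the support", {
  mp <- ref_mixture()
  expect_identical(rmixture(500, mp, seed = 11), rmixture(500, mp, seed = 11))
  x <- rmixture(5000, mp, seed = 3)
  expect_true(all(x >= mp$m))
  expect_true(all(x < max(1 / mp$scout$a_s, 1 / mp$recruit$a_r)))
  xs <- rmixture(2000, mixture_params(1, ref_scout(), ref_recruit()), seed = 4)
  expect_true(all(xs < 1 / 0.2))
})

test_that("the empirical CDF of a large sample converges to the model CDF", {
  mp <- ref_mixture(p = 0.4)
  x <- sort(rmixture(1e5, mp, seed = 202))
  sup <- max(abs(seq_along(x) / length(x) - pmixture(x, mp)))
  expect_lt(sup, 0.01)
})

test_that("log-likelihood sums elementwise log densities and signals zero density", {
  mp <- ref_mixture()
  x0 <- 1.3
  expect_equal(log_likelihood(x0, mp), log(dmixture(x0, mp)))
  x <- rmixture(100, mp, seed = 8)
  expect_equal(log_likelihood(x, mp), sum(log(dmixture(x, mp))))
  expect_identical(log_likelihood(c(x, 100), mp), -Inf)
  expect_error(log_likelihood(numeric(0), mp), class = "wagglefit_input_error")
})
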