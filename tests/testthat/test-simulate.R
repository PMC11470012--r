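# Agent-based foraging simulation and the analytic trip-distance fits.

small_sim <- function(seed, ...) {
  sim_config(n_bees = 30, n_iterations = 30, seed = seed, ...)
}

test_that("identical seeds give identical simulation results", {
  r1 <- run_simulation(small_sim(21))
  r2 <- run_simulation(small_sim(21))
  expect_identical(r1$trips, r2$trips)
  expect_identical(r1$pool_history, r2$pool_history)
})

test_that("trips are stamped at record_every multiples and stay in the arena", {
  res <- run_simulation(small_sim(3))
  expect_true(all(res$trips$time_step %% res$config$record_every == 0))
  expect_true(all(res$trips$distance >= 0 & res$trips$distance <= res$config$radius))
  expect_true(all(res$trips$trip_type %in% c("scout", "recruit")))
})

test_that("an unreachable quality threshold yields no trips", {
  res <- run_simulation(small_sim(4, quality_threshold = 11))
  expect_identical(nrow(res$trips), 0L)
})

test_that("resource placement is uniform in area (equal-area annuli)", {
  cfg <- sim_config(radius = 2.5, seed = 10)
  set.seed(10)
  rho <- cfg$radius * sqrt(runif(10000))
  edges <- cfg$radius * sqrt(seq(0, 1, length.out = 11))
  counts <- table(cut(rho, edges, include.lowest = TRUE))
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("inverse-distance profitability biases recruits towards closer sites", {
  means <- sapply(1:5, function(s) {
    tr <- run_simulation(sim_config(n_bees = 50, n_iterations = 40, seed = 30 + s,
                                    profitability_mode = "inverse_distance"))$trips
    c(scout = mean(tr$distance[tr$trip_type == "scout"]),
      recruit = mean(tr$distance[tr$trip_type == "recruit"]))
  })
  expect_lt(median(means["recruit", ]), median(means["scout", ]))
})

test_that("analytic exponential MLE: shift, closed form, consistency", {
  expect_equal(fit_exponential(c(1, 2, 3)), 1)      # shifted to 0,1,2
  expect_equal(fit_exponential(c(2, 4)), 1)
  expect_error(fit_exponential(c(2, 2, 2)), class = "wagglefit_input_error")
  set.seed(90)
  expect_equal(fit_exponential(rexp(1e5, 3), shift = FALSE), 3, tolerance = 0.05 / 3)
})

test_that("analytic Rayleigh MLE: closed form, scale property, consistency", {
  expect_equal(fit_rayleigh(c(1, 1, 1), shift = FALSE), 1 / pi)
  z <- c(0.3, 0.8, 1.4, 2.2)
  expect_equal(fit_rayleigh(2 * z, shift = FALSE), fit_rayleigh(z, shift = FALSE) / 4)
  set.seed(91)
  draws <- sqrt(-log(runif(1e5)) / (pi * 2))  # Rayleigh with intensity 2
  expect_equal(fit_rayleigh(draws, shift = FALSE), 2, tolerance = 0.05 / 2)
})

test_that("classification is self-consistent on labelled exponential data", {
  set.seed(92)
  trips <- data.frame(trip_type = "scout", distance = rexp(2000, 1))
  trips <- rbind(trips, data.frame(trip_type = "recruit",
                                   distance = sqrt(-log(runif(2000)) / pi)))
  out <- classify_trip_distributions(trips)
  expect_identical(out$best[out$trip_type == "scout"], "exponential")
  expect_identical(out$best[out$trip_type == "recruit"], "rayleigh")
  expect_error(classify_trip_distributions(
    data.frame(trip_type = "scout", distance = rexp(10))),
    class = "wagglefit_input_error")
})

test_that("default-config runs reproduce the exponential/Rayleigh dichotomy", {
  trips <- do.call(rbind, lapply(1:3, function(s)
    run_simulation(sim_config(seed = 100 + s))$trips))
  out <- classify_trip_distributions(trips)
  expect_identical(out$best[out$trip_type == "scout"], "exponential")
  expect_identical(out$best[out$trip_type == "recruit"], "rayleigh")
})
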