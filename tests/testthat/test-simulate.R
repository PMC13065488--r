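make_proc <- function(n, beta, seed = 1, n_cov = 1) {
  L <- generate_landscape(n_cov, seed = seed)
  pts <- cbind(runif(n, 0, 10000), runif(n, 0, 10000))
  simulate_occupancy(L, beta, pts, seed = seed + 1)
}

test_that("single-visit detections are conditional on presence", {
  proc <- make_proc(2000, c(-30, 0))  # psi ~ 0: z = 0 everywhere
  expect_true(all(proc$z == 0))
  rec <- simulate_single_visit(proc, c(2, 1, 1), days = rep(150:169, 100), seed = 3)
  expect_true(all(rec$outcome == 0))
})

test_that("single-visit detection frequency matches the quadratic day model", {
  proc <- make_proc(30000, c(30, 0), seed = 2)  # z = 1 everywhere
  expect_true(all(proc$z == 1))
  # neutral coefficients: frequency ~ 0.5
  days <- sample(145:186, 30000, replace = TRUE)
  rec0 <- simulate_single_visit(proc, c(0, 0, 0), days, seed = 4)
  expect_lt(abs(mean(rec0$outcome) - 0.5), 3 * sqrt(0.25 / 30000))
  # curved day effect: empirical detection-vs-day matches the closed form
  # at three standardized day values
  alpha <- c(0, 1, -0.5)
  rec <- simulate_single_visit(proc, alpha, days, seed = 5)
  ds <- (days - mean(days)) / sd(days)
  for (target in c(-1, 0, 1)) {
    sel <- abs(ds - target) < 0.15
    d0 <- mean(ds[sel])
    expected <- plogis(alpha[1] + alpha[2] * d0 + alpha[3] * d0^2)
    mc_se <- sqrt(expected * (1 - expected) / sum(sel))
    expect_lt(abs(mean(rec$outcome[sel]) - expected), 4 * mc_se + 0.01)
  }
})

test_that("five-interval outcomes are Binomial(5, z * p)", {
  proc0 <- make_proc(500, c(-30, 0), seed = 3)
  rec0 <- simulate_five_interval(proc0, c(3, 0, 0, 0, 0),
                                 days = rep(150, 500), times = rep(8, 500),
                                 seed = 1)
  expect_true(all(rec0$outcome == 0))

  proc1 <- make_proc(20000, c(30, 0), seed = 4)
  days <- sample(145:186, 20000, replace = TRUE)
  times <- runif(20000, 5, 11)
  # neutral gamma: mean W ~ 5 * 0.5
  recm <- simulate_five_interval(proc1, rep(0, 5), days, times, seed = 2)
  expect_lt(abs(mean(recm$outcome) - 2.5), 0.05)
  # constant p = 0.3: full distribution matches the binomial pmf
  rec <- simulate_five_interval(proc1, c(qlogis(0.3), 0, 0, 0, 0),
                                days, times, seed = 3)
  obs <- tabulate(rec$outcome + 1L, nbins = 6)
  expected <- dbinom(0:5, 5, 0.3) * 20000
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 5))
})

test_that("checklist outcomes follow the effort and false-positive models", {
  # absent species, no false positives: nothing detected
  proc0 <- make_proc(100, c(-30, 0), seed = 5)
  rec0 <- simulate_checklists(proc0, delta = c(1, 0.5), n = 2000, seed = 1)
  expect_true(all(rec0$outcome == 0))

  # absent species, f = 0.25 at unit effort: detection frequency ~ 0.25
  eff1 <- effort_spec(duration_sdlog = 1e-9, p_stationary = 1)  # duration ~ 0.75 h
  rec1 <- simulate_checklists(proc0, delta = c(1 / 0.75, 0), n = 20000,
                              effort = eff1, f_true = 0.25, seed = 2)
  tr <- attr(rec1, "truth")
  expect_true(all(abs(tr$E - 1) < 1e-6))
  expect_lt(abs(mean(rec1$outcome) - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))

  # present species, E = 1: detection probability is the standardizing 0.5
  proc1 <- make_proc(100, c(30, 0), seed = 6)
  eff2 <- effort_spec(duration_meanlog = log(1), duration_sdlog = 1e-9,
                      p_stationary = 1)
  rec2 <- simulate_checklists(proc1, delta = c(1, 0), p_star = 0.5, n = 20000,
                              effort = eff2, f_true = 0, seed = 3)
  expect_lt(abs(mean(rec2$outcome) - 0.5), 3 * sqrt(0.25 / 20000))
})

test_that("checklist effort fields have the documented structure", {
  proc <- make_proc(100, c(0, 0), seed = 7)
  rec <- simulate_checklists(proc, delta = c(1, 0.5), n = 5000, seed = 9)
  # stationary mass at distance zero, plus tails past every filter threshold
  expect_gt(mean(rec$distance_km == 0), 0.3)
  expect_gt(sum(rec$duration_hours >= 5), 0)
  expect_gt(sum(rec$distance_km >= 10), 0)
  expect_gt(sum(rec$n_observers >= 10), 0)
  expect_gt(sum(!rec$complete), 0)
  expect_true(all(rec$outcome %in% c(0, 1)))
})

test_that("checklist locations are spatially clustered", {
  proc <- make_proc(100, c(0, 0), seed = 8)
  rec <- simulate_checklists(proc, delta = c(1, 0.5), n = 500, seed = 4,
                             clustering = cluster_spec(0.1, 60, 150))
  # clustered pattern occupies far fewer 1-km cells than a uniform one
  occupied <- length(unique(hex_cell_of(rec, hex_grid(1000))))
  unif <- cbind(runif(500, 0, 10000), runif(500, 0, 10000))
  occupied_unif <- length(unique(hex_cell_of(unif, hex_grid(1000))))
  expect_lt(occupied, 0.7 * occupied_unif)
})

test_that("generators are bit-reproducible given the seed", {
  b1 <- tiny_bundle(seed = 21)
  b2 <- tiny_bundle(seed = 21)
  for (key in c("single_visit", "five_interval", "checklist"))
    expect_identical(b1[[key]], b2[[key]])
  b3 <- tiny_bundle(seed = 22)
  expect_false(identical(b1$checklist$outcome, b3$checklist$outcome))
})

test_that("marginal detection frequency converges to the analytic value", {
  # E_site[psi * p + (1 - psi) * f*] with constant effort, by MC integration
  # over the clustered site distribution
  L <- generate_landscape(2, seed = 31)
  pts <- cbind(runif(3000, 0, 10000), runif(3000, 0, 10000))
  proc <- simulate_occupancy(L, c(-0.4, 1.2, -0.8), pts, seed = 32)
  eff <- effort_spec(duration_meanlog = log(1), duration_sdlog = 1e-9,
                     p_stationary = 1)
  n <- 40000
  rec <- simulate_checklists(proc, delta = c(2, 0), n = n, effort = eff,
                             f_true = 0.1, seed = 33)
  tr <- attr(rec, "truth")
  p_const <- 1 - 0.5^2           # E = 2 exactly
  f_const <- 1 - 0.9^2
  analytic <- mean(tr$psi * p_const + (1 - tr$psi) * f_const)
  expect_lt(abs(mean(rec$outcome) - analytic), 4 * sqrt(0.25 / n))
})

test_that("historic shift perturbs the occupancy surface as specified", {
  proc <- make_proc(200, c(-0.5, 1), seed = 41)
  probe <- cbind(runif(300, 0, 10000), runif(300, 0, 10000))

  # zero shift: identical surface
  h0 <- simulate_historic_shift(proc, historic_shift(0, NA, 0), seed = 1)
  expect_equal(h0$process$psi_fn(probe), proc$psi_fn(probe), tolerance = 1e-12)

  # catastrophic intercept drop: historic range collapses
  proc30 <- make_proc(5000, c(qlogis(0.3), 0), seed = 42)
  h1 <- simulate_historic_shift(proc30, historic_shift(-10, NA, 0), seed = 2,
                                n_single_visit = 200)
  expect_lt(mean(h1$process$z), 0.01)
  expect_true(all(h1$records$era == "historic"))

  # coefficient perturbation decorrelates the surfaces without collapse
  h2 <- simulate_historic_shift(proc, historic_shift(0, 1, -2), seed = 3)
  r <- cor(h2$process$psi_fn(probe), proc$psi_fn(probe))
  expect_lt(r, 0.999)
})

test_that("historic generator reuses the observation machinery for all protocols", {
  proc <- make_proc(200, c(0.5, 1), seed = 51)
  h <- simulate_historic_shift(proc, historic_shift(-1, 1, -1), seed = 4,
                               n_single_visit = 30, n_five_interval = 20,
                               n_checklists = 40, delta = c(1, 0.5))
  expect_setequal(unique(h$records$protocol),
                  c("single_visit", "five_interval", "checklist"))
  expect_true(all(h$records$era == "historic"))
  fi <- h$records[h$records$protocol == "five_interval", ]
  expect_true(all(fi$outcome %in% 0:5))
})
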