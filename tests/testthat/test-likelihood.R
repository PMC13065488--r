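test_that("closed-form probabilities of the model components", {
  # occupancy with and without integration covariates
  st <- list(beta = c(0, 0), beta_count = 1, beta_lists = -1)
  expect_equal(occupancy_prob(st, c(1, 0)), 0.5)
  expect_equal(occupancy_prob(st, c(1, 0), integration = c(2, 0)),
               plogis(2), tolerance = 1e-12)
  expect_equal(occupancy_prob(st, c(1, 0), integration = c(0, 3)),
               plogis(-3), tolerance = 1e-12)
  expect_equal(plogis(2), 0.880797, tolerance = 1e-6)
  expect_equal(plogis(-3), 0.0474259, tolerance = 1e-6)

  # single-visit day curve
  expect_equal(detect_single_visit(c(0, 0, 0), 0.7), 0.5)
  expect_equal(detect_single_visit(c(0, 0, -1), 1), plogis(-1), tolerance = 1e-12)
  expect_equal(detect_single_visit(c(0.3, 0, -0.4), 1.2),
               detect_single_visit(c(0.3, 0, -0.4), -1.2))  # even in day

  # five-interval curve
  expect_equal(detect_five_interval(rep(0, 5), 0.2, -0.3), 0.5)
  expect_equal(detect_five_interval(c(1, 0, 0, 0, 0), 2, -2), plogis(1),
               tolerance = 1e-12)
  expect_equal(detect_five_interval(c(0.1, 0, -0.5, 0, 0), 1.5, 0),
               detect_five_interval(c(0.1, 0, -0.5, 0, 0), -1.5, 0))

  # effort combination
  expect_equal(effort_value(c(1, 1), 0, 0), 0)
  expect_equal(effort_value(c(2, 0.5), 1, 2), 3)
  expect_error(effort_value(c(-1, 0), 1, 1), ">= 0")

  # saturating detection and false-positive forms
  expect_identical(effort_detection(1, 0.5), 0.5)
  expect_identical(effort_detection(0, 0.5), 0)
  expect_equal(effort_detection(2, 0.5), 0.75)
  expect_error(effort_detection(1, 1.2), "p_star")
  expect_equal(false_positive_prob(0, c(0, 1, 7)), c(0, 0, 0))
  expect_equal(false_positive_prob(0.25, 1), 0.25)
  expect_equal(false_positive_prob(0.1, 2), 0.19)
  expect_error(false_positive_prob(0.3, 1), "0.25")
})

test_that("effort-scaled probabilities are strictly increasing in effort", {
  E <- seq(0, 10, by = 0.25)
  expect_true(all(diff(effort_detection(E, 0.5)) > 0))
  expect_true(all(diff(false_positive_prob(0.1, E)) > 0))
  expect_true(all(diff(effort_value(c(1, 0.5), E, 0)) > 0))
})

test_that("record likelihoods marginalize the latent state correctly", {
  expect_equal(record_loglik("single_visit", 1, 1, 0.3), log(0.3))
  expect_equal(record_loglik("single_visit", 0, 0.4, 0.5), log(0.8))
  expect_equal(record_loglik("five_interval", 0, 0.4, 0.3),
               log(0.4 * 0.7^5 + 0.6))
  expect_equal(record_loglik("checklist", 1, 0.4, 0.5, fstar = 0.2),
               log(0.4 * 0.5 + 0.6 * 0.2))
  expect_error(record_loglik("single_visit", 1, 1.4, 0.5), "0, 1")
})

test_that("outcome probabilities sum to one over each outcome space", {
  set.seed(101)
  for (rep in 1:20) {
    psi <- runif(1); p <- runif(1); fs <- runif(1, 0, 0.3)
    tot_bin <- exp(record_loglik("checklist", 0, psi, p, fs)) +
      exp(record_loglik("checklist", 1, psi, p, fs))
    expect_equal(tot_bin, 1, tolerance = 1e-12)
    tot5 <- sum(exp(vapply(0:5, function(w)
      record_loglik("five_interval", w, psi, p), numeric(1))))
    expect_equal(tot5, 1, tolerance = 1e-12)
  }
})

test_that("buffer summarization counts records in a closed 1000-m ball", {
  src <- manual_checklists(4, x = c(500, 300, 100, 5000), y = 0,
                           outcome = c(1, 1, 0, 1))
  tp <- rbind(c(0, 0))
  sm <- summarize_as_covariate(tp, src, radius_m = 1000)
  expect_identical(unname(sm[1, ]), c(2L, 3L))       # counting micro-example
  # no record in range
  expect_identical(unname(summarize_as_covariate(rbind(c(50000, 0)), src)[1, ]),
                   c(0L, 0L))
  # boundary: exactly 1000 m is included (closed ball), oracle by distance
  src2 <- manual_checklists(1, x = 1000, y = 0, outcome = 1)
  expect_identical(unname(summarize_as_covariate(tp, src2, 1000)[1, ]),
                   c(1L, 1L))
  expect_identical(unname(summarize_as_covariate(tp, src2, 999.999)[1, ]),
                   c(0L, 0L))
})

test_that("joint likelihood equals the enumeration oracle across model variants", {
  variants <- list(
    list(id = "R1", f_true = 0),          # effort model on
    list(id = "F5", f_true = 0),          # intercept-only checklist detection
    list(id = "E1", f_true = 0.15),       # false-positive path
    list(id = "E2", f_true = 0)           # covariate integration
  )
  for (v in variants) {
    b <- tiny_bundle(seed = 111, n_sv = 4, n_fi = 3, n_cl = 3,
                     f_true = v$f_true)
    tr <- prepare_scenario_data(b, v$id, seed = 2)
    md <- prepare_model_data(tr)
    set.seed(112)
    st <- make_state(md,
                     beta = rnorm(4, 0, 0.8), alpha = rnorm(3, 0, 0.5),
                     gamma = rnorm(5, 0, 0.5), delta = c(1.3, 0.4),
                     p_det0 = 0.2, f = 0.12, beta_count = 0.3,
                     beta_lists = -0.2)
    expect_equal(joint_loglik(st, md), oracle_joint_loglik(st, md),
                 tolerance = 1e-10, label = paste("scenario", v$id))
  }
})

test_that("joint likelihood is additive and zero on an empty bundle", {
  b <- tiny_bundle(seed = 113, n_sv = 1, n_fi = 1, n_cl = 1)
  tr <- prepare_scenario_data(b, "R1", seed = 1)
  md <- prepare_model_data(tr)
  st <- make_state(md, beta = c(0.2, 0.5, -0.3, 0.1))
  parts <- vapply(names(md$sets), function(k) {
    md1 <- md; md1$sets <- md$sets[k]
    joint_loglik(st, md1)
  }, numeric(1))
  expect_equal(joint_loglik(st, md), sum(parts), tolerance = 1e-12)

  empty <- structure(list(sets = list()), class = "occufuse_model_data")
  expect_identical(joint_loglik(st, empty), 0)
})

test_that("the false-positive path at f = 0 equals the plain model exactly", {
  b <- tiny_bundle(seed = 114, n_sv = 5, n_fi = 4, n_cl = 10, f_true = 0)
  md_fp <- prepare_model_data(prepare_scenario_data(b, "E1", seed = 3))
  md_plain <- prepare_model_data(prepare_scenario_data(b, "R1", seed = 3))
  st_fp <- make_state(md_fp, beta = c(0.1, 0.4, -0.2, 0.3), f = 0)
  st_plain <- make_state(md_plain, beta = c(0.1, 0.4, -0.2, 0.3))
  expect_identical(joint_loglik(st_fp, md_fp), joint_loglik(st_plain, md_plain))
})

test_that("without the effort model the likelihood ignores effort fields", {
  b <- tiny_bundle(seed = 115, n_cl = 40)
  tr <- prepare_scenario_data(b, "F5", seed = 1)
  md <- prepare_model_data(tr)
  st <- make_state(md, beta = c(0, 0.5, -0.5, 0.2), p_det0 = 0.3)
  ll0 <- joint_loglik(st, md)
  perm <- sample(md$sets$checklist$n)
  md$sets$checklist$duration <- md$sets$checklist$duration[perm]
  md$sets$checklist$distance <- md$sets$checklist$distance[perm]
  expect_identical(joint_loglik(st, md), ll0)
})

test_that("integration covariates respect their sign constraints on psi", {
  st <- list(beta = c(0, 0.3), beta_count = 0.8, beta_lists = -0.6)
  row <- c(1, 0.5)
  counts <- 0:5
  psi_by_count <- vapply(counts, function(ct)
    occupancy_prob(st, row, integration = c(ct, 5)), numeric(1))
  expect_true(all(diff(psi_by_count) >= 0))
  psi_by_lists <- vapply(counts, function(ls)
    occupancy_prob(st, row, integration = c(2, ls)), numeric(1))
  expect_true(all(diff(psi_by_lists) <= 0))
})

test_that("constraint violations yield -Inf likelihood", {
  b <- tiny_bundle(seed = 116, n_sv = 3, n_fi = 0, n_cl = 3, f_true = 0.1)
  md <- prepare_model_data(prepare_scenario_data(b, "E1", seed = 1))
  st <- make_state(md)
  for (bad in list(list(f = 0.3), list(f = -0.01), list(delta = c(-0.1, 1)))) {
    stb <- st
    stb[names(bad)] <- bad
    expect_identical(joint_loglik(stb, md), -Inf)
  }
})
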