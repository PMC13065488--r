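#' @title Synthetic survey-record generators
#' @description Generators for the three survey protocols the integrated
#'   model consumes: single-visit detection/non-detection surveys (BBS-like
#'   roadside point counts), five-interval repeated point counts (atlas-like
#'   surveys where the outcome is the number of 75-s intervals with a
#'   detection), and semi-structured checklists (eBird-like records with
#'   self-reported duration, distance and group size, spatially clustered and
#'   optionally contaminated with false positives).
#' @name simulators
NULL

RECORD_COLS <- c("record_id", "protocol", "x", "y", "day", "time",
                 "duration_hours", "distance_km", "n_observers", "complete",
                 "era", "outcome")

## Assemble a records data frame: schema columns first, then raw covariate
## columns cov1..covK pulled from the process.
build_records <- function(process, prefix, protocol, day = NA, time = NA,
                          duration = NA, distance = NA, observers = NA,
                          complete = NA, era = "current", outcome) {
  n <- length(outcome)
  df <- data.frame(
    record_id = sprintf("%s%06d", prefix, seq_len(n)),
    protocol = rep(protocol, n),
    x = process$sites[, 1], y = process$sites[, 2],
    day = rep_len(day, n), time = rep_len(time, n),
    duration_hours = rep_len(duration, n), distance_km = rep_len(distance, n),
    n_observers = rep_len(observers, n), complete = rep_len(complete, n),
    era = rep_len(era, n), outcome = as.integer(outcome),
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(process$X_raw))
}

std_vec <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Single-visit detection probability (day-of-year effect)
#'
#' Quadratic logit-scale model for the detection probability of a
#' single-visit survey: `logit(p) = alpha0 + alpha1*day + alpha2*day^2`,
#' with day standardized.
#'
#' @param alpha numeric length 3 `(alpha0, alpha1, alpha2)`.
#' @param day_std standardized day-of-year.
#' @return detection probability vector.
#' @export
detect_single_visit <- function(alpha, day_std) {
  alpha <- as.numeric(alpha)
  stopifnot(length(alpha) == 3)
  plogis(alpha[1] + alpha[2] * day_std + alpha[3] * day_std^2)
}

#' Five-interval detection probability (time and day effects)
#'
#' `logit(p) = gamma0 + gamma1*time + gamma2*time^2 + gamma3*day +
#' gamma4*day^2`, with time-of-day and day-of-year standardized.
#'
#' @param gamma numeric length 5.
#' @param time_std,day_std standardized time-of-day / day-of-year.
#' @return per-interval detection probability vector.
#' @export
detect_five_interval <- function(gamma, time_std, day_std) {
  gamma <- as.numeric(gamma)
  stopifnot(length(gamma) == 5)
  plogis(gamma[1] + gamma[2] * time_std + gamma[3] * time_std^2 +
           gamma[4] * day_std + gamma[5] * day_std^2)
}

#' Survey effort from checklist duration and distance
#'
#' `E = delta1 * duration + delta2 * distance`, with both coefficients
#' constrained non-negative so more time or distance never means less effort.
#'
#' @param delta numeric length 2, elementwise `>= 0`.
#' @param duration_hours,distance_km non-negative effort fields.
#' @return non-negative effort values.
#' @export
effort_value <- function(delta, duration_hours, distance_km) {
  delta <- as.numeric(delta)
  stopifnot(length(delta) == 2)
  if (any(delta < 0)) stop_param("effort coefficients `delta` must be >= 0")
  delta[1] * duration_hours + delta[2] * distance_km
}

#' Effort-dependent detection probability
#'
#' Saturating detection function `p = 1 - (1 - p_star)^E`: detection
#' approaches 1 as effort grows and 0 as effort vanishes, with a constant
#' detection rate per unit effort. Effort is standardized so that one unit of
#' effort corresponds to a detection probability of `p_star` (default 0.5).
#'
#' @param E non-negative effort (see [effort_value()]).
#' @param p_star per-unit-effort detection probability, in (0, 1).
#' @return detection probability vector.
#' @export
effort_detection <- function(E, p_star = 0.5) {
  if (!is_number(p_star) || p_star <= 0 || p_star >= 1)
    stop_param("`p_star` must be in (0, 1)")
  if (any(E < 0)) stop_param("effort must be non-negative")
  1 - (1 - p_star)^E
}

#' Effort-scaled false-positive probability
#'
#' `f_star = 1 - (1 - f)^E`: the probability of recording the species at an
#' unoccupied site, growing with survey effort at constant per-unit rate `f`.
#' `f` is box-constrained to `[0, 0.25]` for identifiability.
#'
#' @param f per-unit-effort false-positive rate in `[0, 0.25]`.
#' @param E non-negative effort.
#' @return false-positive probability vector.
#' @export
false_positive_prob <- function(f, E) {
  if (!is_number(f) || f < 0 || f > 0.25)
    stop_param("false-positive rate `f` must lie in [0, 0.25]")
  if (any(E < 0)) stop_param("effort must be non-negative")
  1 - (1 - f)^E
}

#' Simulate single-visit detection/non-detection records
#'
#' One visit per site: `Y ~ Bernoulli(z * p)` with `p` from
#' [detect_single_visit()] evaluated at the standardized day-of-year.
#'
#' @param process an `occufuse_process`.
#' @param alpha detection coefficients, length 3.
#' @param days integer day-of-year per site.
#' @param seed integer seed.
#' @param era `"current"` or `"historic"`.
#' @return records data frame (one row per site) with a `truth` attribute
#'   holding psi, z, p, and the day-standardization statistics.
#' @export
simulate_single_visit <- function(process, alpha, days, seed, era = "current") {
  stopifnot(inherits(process, "occufuse_process"))
  n <- nrow(process$sites)
  if (length(days) != n) stop_param("`days` must supply one day per site")
  day_std <- std_vec(days)
  p <- detect_single_visit(alpha, day_std)
  y <- with_seed(seed, rbinom(n, 1L, process$z * p))
  rec <- build_records(process, "sv", "single_visit", day = days,
                       era = era, outcome = y)
  attr(rec, "truth") <- list(psi = process$psi, z = process$z, p = p,
                             day_center = mean(days), day_scale = sd(days))
  rec
}

#' Simulate five-interval point-count records
#'
#' The outcome is the number of intervals (out of 5) with a detection:
#' `W ~ Binomial(5, z * p)` with `p` from [detect_five_interval()].
#'
#' @param process an `occufuse_process`.
#' @param gamma detection coefficients, length 5.
#' @param days,times day-of-year and time-of-day (hours since midnight) per
#'   site.
#' @param seed integer seed.
#' @param era `"current"` or `"historic"`.
#' @return records data frame with outcomes in `0..5` and a `truth` attribute.
#' @export
simulate_five_interval <- function(process, gamma, days, times, seed,
                                   era = "current") {
  stopifnot(inherits(process, "occufuse_process"))
  n <- nrow(process$sites)
  if (length(days) != n || length(times) != n)
    stop_param("`days` and `times` must supply one value per site")
  p <- detect_five_interval(gamma, std_vec(times), std_vec(days))
  w <- with_seed(seed, rbinom(n, 5L, process$z * p))
  rec <- build_records(process, "fi", "five_interval", day = days, time = times,
                       era = era, outcome = w)
  attr(rec, "truth") <- list(psi = process$psi, z = process$z, p = p)
  rec
}

#' Checklist clustering specification (Thomas process)
#'
#' Checklist locations are drawn from a Thomas cluster process: Poisson
#' parent centers uniform over the region, each with a Poisson number of
#' offspring displaced by isotropic Gaussian noise. This reproduces the
#' extreme spatial clustering of participatory-science sampling so that
#' hexagonal balancing has real work to do.
#'
#' @param parents_per_km2 expected parent intensity.
#' @param offspring_per_parent expected checklists per parent.
#' @param offspring_sd_m Gaussian dispersal of offspring around parents.
#' @export
cluster_spec <- function(parents_per_km2 = 0.3, offspring_per_parent = 8,
                         offspring_sd_m = 300) {
  stopifnot(parents_per_km2 > 0, offspring_per_parent > 0, offspring_sd_m > 0)
  list(parents_per_km2 = parents_per_km2,
       offspring_per_parent = offspring_per_parent,
       offspring_sd_m = offspring_sd_m)
}

#' Checklist effort distribution specification
#'
#' Self-reported effort fields: duration lognormal with median 0.75 h and a
#' heavy tail past 5 h; distance zero (stationary list) with probability
#' `p_stationary`, else lognormal with median 2 km and a tail past 10 km;
#' observers `1 + Poisson(0.7)` plus a rare large-group component giving a
#' tail past 10. Defaults are chosen so each standard quality filter removes
#' a nontrivial fraction of lists.
#'
#' @param duration_meanlog,duration_sdlog lognormal parameters for duration.
#' @param p_stationary probability a list is stationary (distance = 0).
#' @param distance_meanlog,distance_sdlog lognormal parameters for traveled
#'   distance.
#' @param observers_lambda Poisson rate for extra observers.
#' @param group_prob,group_lambda probability and Poisson rate of a rare
#'   large-group event.
#' @param p_incomplete probability a list is flagged incomplete.
#' @export
effort_spec <- function(duration_meanlog = log(0.75), duration_sdlog = 0.9,
                        p_stationary = 0.4,
                        distance_meanlog = log(2), distance_sdlog = 0.8,
                        observers_lambda = 0.7, group_prob = 0.03,
                        group_lambda = 15, p_incomplete = 0.1) {
  list(duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
       p_stationary = p_stationary, distance_meanlog = distance_meanlog,
       distance_sdlog = distance_sdlog, observers_lambda = observers_lambda,
       group_prob = group_prob, group_lambda = group_lambda,
       p_incomplete = p_incomplete)
}

## Thomas cluster point pattern clipped to bounds; at least `n_min` points.
rthomas_points <- function(bounds, clustering, n_min) {
  area_km2 <- (bounds[2] - bounds[1]) * (bounds[4] - bounds[3]) / 1e6
  pts <- matrix(numeric(0), ncol = 2)
  scale <- 1
  while (nrow(pts) < n_min) {
    n_par <- rpois(1, clustering$parents_per_km2 * area_km2 * scale) + 1L
    px <- runif(n_par, bounds[1], bounds[2])
    py <- runif(n_par, bounds[3], bounds[4])
    n_off <- rpois(n_par, clustering$offspring_per_parent)
    cx <- rep(px, n_off) + rnorm(sum(n_off), 0, clustering$offspring_sd_m)
    cy <- rep(py, n_off) + rnorm(sum(n_off), 0, clustering$offspring_sd_m)
    keep <- cx >= bounds[1] & cx <= bounds[2] & cy >= bounds[3] & cy <= bounds[4]
    pts <- rbind(pts, cbind(cx[keep], cy[keep]))
    scale <- scale * 2  # escalate if clipping left too few
  }
  pts
}

#' Simulate semi-structured checklist records
#'
#' Draws checklist locations from a clustered (Thomas) point process over the
#' process landscape, self-reported effort from [effort_spec()], the latent
#' state `z ~ Bernoulli(psi)` at each location, and the binary outcome
#' `V ~ Bernoulli(z * p + (1 - z) * f_star)` where `p = 1 - (1 - p_star)^E`,
#' `E = delta1*duration + delta2*distance`, and
#' `f_star = 1 - (1 - f_true)^E` injects false positives at unoccupied sites.
#'
#' @param process an `occufuse_process` (its `psi_fn` is evaluated at the new
#'   clustered locations).
#' @param delta effort coefficients (length 2, `>= 0`).
#' @param p_star per-unit-effort detection probability, in (0, 1).
#' @param n number of checklists to generate.
#' @param clustering a [cluster_spec()].
#' @param effort an [effort_spec()].
#' @param f_true per-unit-effort false-positive rate in `[0, 0.25]`.
#' @param seed integer seed.
#' @param era `"current"` or `"historic"`.
#' @param days optional day-of-year per checklist (default: uniform over the
#'   peak breeding window, days 145-186).
#' @return records data frame with a `truth` attribute (psi, z, E, p, f_star).
#' @export
simulate_checklists <- function(process, delta, p_star = 0.5, n = 500,
                                clustering = cluster_spec(),
                                effort = effort_spec(), f_true = 0, seed = 1,
                                era = "current", days = NULL) {
  stopifnot(inherits(process, "occufuse_process"))
  if (!is_number(p_star) || p_star <= 0 || p_star >= 1)
    stop_param("`p_star` must be in (0, 1)")
  if (!is_number(f_true) || f_true < 0 || f_true > 0.25)
    stop_param("`f_true` must lie in [0, 0.25]")
  delta <- as.numeric(delta)
  if (length(delta) != 2 || any(delta < 0))
    stop_param("`delta` must be length 2 and elementwise >= 0")
  bounds <- process$landscape$bounds

  out <- with_seed(seed, {
    pts <- rthomas_points(bounds, clustering, n)[seq_len(n), , drop = FALSE]
    duration <- rlnorm(n, effort$duration_meanlog, effort$duration_sdlog)
    stationary <- runif(n) < effort$p_stationary
    distance <- ifelse(stationary, 0,
                       rlnorm(n, effort$distance_meanlog, effort$distance_sdlog))
    observers <- 1L + rpois(n, effort$observers_lambda) +
      ifelse(runif(n) < effort$group_prob, rpois(n, effort$group_lambda), 0L)
    complete <- runif(n) >= effort$p_incomplete
    time <- runif(n, 5, 20)
    day <- if (is.null(days)) sample(145:186, n, replace = TRUE) else rep_len(days, n)
    psi <- process$psi_fn(pts)
    z <- rbinom(n, 1L, psi)
    E <- effort_value(delta, duration, distance)
    p <- effort_detection(E, p_star)
    fstar <- false_positive_prob(f_true, E)
    y <- rbinom(n, 1L, z * p + (1 - z) * fstar)
    list(pts = pts, duration = duration, distance = distance,
         observers = observers, complete = complete, time = time, day = day,
         psi = psi, z = z, E = E, p = p, fstar = fstar, y = y)
  })

  ## a lightweight process view at the checklist locations for build_records
  proc_cl <- process
  proc_cl$sites <- out$pts
  proc_cl$X_raw <- landscape_covariates(process$landscape, out$pts)
  rec <- build_records(proc_cl, "cl", "checklist", day = out$day,
                       time = out$time, duration = out$duration,
                       distance = out$distance, observers = out$observers,
                       complete = out$complete, era = era, outcome = out$y)
  attr(rec, "truth") <- list(psi = out$psi, z = out$z, E = out$E, p = out$p,
                             fstar = out$fstar)
  rec
}

#' Historic range-shift specification
#'
#' Perturbation of the true occupancy coefficients used to generate historic
#' records: an additive intercept shift (overall prevalence change) plus an
#' additive change to one covariate coefficient (habitat-association change).
#'
#' @param intercept_shift added to the logit-scale intercept.
#' @param coef_index which covariate coefficient to perturb (1 = first
#'   covariate); `NA` for none.
#' @param coef_shift added to that coefficient.
#' @export
historic_shift <- function(intercept_shift = -1, coef_index = 1,
                           coef_shift = 0) {
  list(intercept_shift = intercept_shift, coef_index = coef_index,
       coef_shift = coef_shift)
}

#' Simulate historic records from a shifted occupancy surface
#'
#' Applies a [historic_shift()] to the true coefficients, rebuilds the
#' occupancy process under the *same* covariate standardization, and
#' generates records tagged `era = "historic"` with the same observation
#' machinery as the current-era generators. Any combination of the three
#' protocols can be requested (atlas-style five-interval data are typically
#' entirely historic in the reliability experiments).
#'
#' @param process the current-era `occufuse_process`.
#' @param shift a [historic_shift()].
#' @param seed integer seed.
#' @param n_single_visit,n_five_interval,n_checklists record counts per
#'   protocol (0 skips a protocol).
#' @param alpha,gamma,delta,p_star,clustering,effort,f_true observation
#'   parameters passed to the per-protocol generators.
#' @return list with `process` (the shifted `occufuse_process`, sites at the
#'   union of generated locations is not stored; `psi_fn` is) and `records`
#'   (row-bound data frame, `era = "historic"`).
#' @export
simulate_historic_shift <- function(process, shift = historic_shift(), seed = 1,
                                    n_single_visit = 0, n_five_interval = 0,
                                    n_checklists = 0,
                                    alpha = c(0, 0, 0), gamma = rep(0, 5),
                                    delta = c(1, 0.5), p_star = 0.5,
                                    clustering = cluster_spec(),
                                    effort = effort_spec(), f_true = 0) {
  stopifnot(inherits(process, "occufuse_process"))
  beta_h <- process$beta_true
  beta_h[1] <- beta_h[1] + shift$intercept_shift
  if (!is.na(shift$coef_index) && shift$coef_shift != 0) {
    j <- shift$coef_index + 1L
    if (j > length(beta_h)) stop_param("`coef_index` exceeds the number of covariates")
    beta_h[j] <- beta_h[j] + shift$coef_shift
  }
  bounds <- process$landscape$bounds
  recs <- list()
  if (n_single_visit > 0) {
    sites <- with_seed(seed + 11L, cbind(runif(n_single_visit, bounds[1], bounds[2]),
                                         runif(n_single_visit, bounds[3], bounds[4])))
    proc <- process_at(process$landscape, beta_h, sites, process$center,
                       process$scale, seed + 12L)
    days <- with_seed(seed + 13L, sample(145:186, n_single_visit, replace = TRUE))
    recs$sv <- simulate_single_visit(proc, alpha, days, seed + 14L, era = "historic")
  }
  if (n_five_interval > 0) {
    sites <- with_seed(seed + 21L, cbind(runif(n_five_interval, bounds[1], bounds[2]),
                                         runif(n_five_interval, bounds[3], bounds[4])))
    proc <- process_at(process$landscape, beta_h, sites, process$center,
                       process$scale, seed + 22L)
    dt <- with_seed(seed + 23L, list(days = sample(145:186, n_five_interval, TRUE),
                                     times = runif(n_five_interval, 5, 11)))
    recs$fi <- simulate_five_interval(proc, gamma, dt$days, dt$times, seed + 24L,
                                      era = "historic")
  }
  hist_proc <- process_at(process$landscape, beta_h, process$sites,
                          process$center, process$scale, seed + 1L)
  if (n_checklists > 0) {
    recs$cl <- simulate_checklists(hist_proc, delta, p_star, n = n_checklists,
                                   clustering = clustering, effort = effort,
                                   f_true = f_true, seed = seed + 31L,
                                   era = "historic")
  }
  records <- if (length(recs)) do.call(rbind, unname(lapply(recs, function(r) {
    attr(r, "truth") <- NULL; r
  }))) else NULL
  if (!is.null(records)) rownames(records) <- NULL
  list(process = hist_proc, records = records)
}

#' Simulate a full multi-protocol dataset bundle
#'
#' Generates a landscape, a shared occupancy truth (standardized over a
#' dense reference grid so every protocol shares one parameterization), and
#' the three protocol datasets; optionally a historic-era dataset from a
#' shifted surface. This is the study-condition generator used throughout
#' the analysis scripts and tests.
#'
#' @param seed master integer seed; every internal draw derives from it.
#' @param n_covariates number of environmental covariates.
#' @param beta_true occupancy coefficients (intercept first).
#' @param alpha,gamma,delta,p_star observation-model parameters.
#' @param n_single_visit,n_five_interval,n_checklists dataset sizes.
#' @param f_true false-positive contamination rate of the checklist stream.
#' @param clustering,effort checklist location / effort specifications.
#' @param bounds region rectangle (meters).
#' @param historic `NULL`, or a list with elements `shift`
#'   ([historic_shift()]) and counts `n_single_visit`, `n_five_interval`,
#'   `n_checklists` for the historic-era records.
#' @return a bundle: list with `single_visit`, `five_interval`, `checklist`,
#'   `historic` (or `NULL`), `landscape`, `process` (current-era truth with
#'   `psi_fn`), and `truth` (all generating parameter values and the seed).
#' @export
simulate_bundle <- function(seed = 1, n_covariates = 3,
                            beta_true = c(-0.5, 1, -0.7, 0.5),
                            alpha = c(0.5, 0.2, -0.2),
                            gamma = c(0.3, 0.1, -0.1, 0.1, -0.1),
                            delta = c(1, 0.5), p_star = 0.5,
                            n_single_visit = 300, n_five_interval = 200,
                            n_checklists = 800, f_true = 0,
                            clustering = cluster_spec(), effort = effort_spec(),
                            bounds = c(0, 20000, 0, 20000), historic = NULL) {
  landscape <- generate_landscape(n_covariates, seed, bounds)
  ## reference standardization over a dense grid, shared by all site sets
  ref <- with_seed(seed + 101L, cbind(runif(2000, bounds[1], bounds[2]),
                                      runif(2000, bounds[3], bounds[4])))
  Xr <- standardize_cols(landscape_covariates(landscape, ref))
  center <- attr(Xr, "center"); scale <- attr(Xr, "scale")

  sv_sites <- with_seed(seed + 102L, cbind(runif(n_single_visit, bounds[1], bounds[2]),
                                           runif(n_single_visit, bounds[3], bounds[4])))
  fi_sites <- with_seed(seed + 103L, cbind(runif(n_five_interval, bounds[1], bounds[2]),
                                           runif(n_five_interval, bounds[3], bounds[4])))
  proc_sv <- process_at(landscape, beta_true, sv_sites, center, scale, seed + 104L)
  proc_fi <- process_at(landscape, beta_true, fi_sites, center, scale, seed + 105L)
  sv_days <- with_seed(seed + 106L, sample(145:186, n_single_visit, TRUE))
  fi_dt <- with_seed(seed + 107L, list(days = sample(145:186, n_five_interval, TRUE),
                                       times = runif(n_five_interval, 5, 11)))

  single_visit <- simulate_single_visit(proc_sv, alpha, sv_days, seed + 108L)
  five_interval <- simulate_five_interval(proc_fi, gamma, fi_dt$days,
                                          fi_dt$times, seed + 109L)
  proc_ref <- process_at(landscape, beta_true, ref, center, scale, seed + 110L)
  checklist <- simulate_checklists(proc_ref, delta, p_star, n = n_checklists,
                                   clustering = clustering, effort = effort,
                                   f_true = f_true, seed = seed + 111L)

  hist <- NULL
  if (!is.null(historic)) {
    hs <- simulate_historic_shift(
      proc_ref, shift = historic$shift %||% historic_shift(), seed = seed + 200L,
      n_single_visit = historic$n_single_visit %||% 0,
      n_five_interval = historic$n_five_interval %||% 0,
      n_checklists = historic$n_checklists %||% 0,
      alpha = alpha, gamma = gamma, delta = delta, p_star = p_star,
      clustering = clustering, effort = effort,
      f_true = historic$f_true %||% 0)
    hist <- hs$records
  }

  list(single_visit = single_visit, five_interval = five_interval,
       checklist = checklist, historic = hist,
       landscape = landscape, process = proc_ref,
       truth = list(beta_true = beta_true, alpha = alpha, gamma = gamma,
                    delta = delta, p_star = p_star, f_true = f_true,
                    center = center, scale = scale, seed = seed,
                    historic = historic))
}
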