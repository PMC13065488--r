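#' Prior specification
#'
#' Priors of the hierarchical model: each penalized smooth coefficient block
#' gets a partially improper Gaussian prior `beta_j ~ N(0, (lambda_j S_j)^-)`
#' with `lambda_j ~ Gamma(shape, rate)` (the jagam-style smoothing prior);
#' unpenalized/linear and detection coefficients get `N(0, sd_fixed)` on the
#' logit scale; the false-positive rate `f` is uniform on `[0, f_max]`; the
#' effort coefficients and the integration coefficients get half/truncated
#' `N(0, sd_fixed)` priors on their sign boxes.
#'
#' @param sd_fixed prior sd of unconstrained coefficients (logit scale).
#' @param lambda_shape,lambda_rate Gamma prior on smoothing parameters.
#' @param f_max upper bound of the false-positive-rate box.
#' @export
prior_spec <- function(sd_fixed = 10, lambda_shape = 0.05,
                       lambda_rate = 0.005, f_max = 0.25) {
  structure(list(sd_fixed = sd_fixed, lambda_shape = lambda_shape,
                 lambda_rate = lambda_rate, f_max = f_max),
            class = "prior_spec")
}

#' Log prior density of a parameter state
#'
#' @param state an [make_state()] state.
#' @param md model data (supplies penalty matrices and ranks).
#' @param priors a [prior_spec()].
#' @return scalar log prior (`-Inf` outside the constraint boxes).
#' @export
log_prior <- function(state, md, priors = prior_spec()) {
  if (!state_ok(state)) return(-Inf)
  if (!is.null(state$f) && state$f > priors$f_max) return(-Inf)
  lp <- 0
  des <- md$design
  if (!is.null(des) && length(des$S)) {
    for (nm in names(des$S)) {
      bj <- state$beta[des$blocks[[nm]]]
      lam <- state$lambda[[nm]]
      quad <- as.numeric(bj %*% des$S[[nm]] %*% bj)
      lp <- lp + 0.5 * des$ranks[[nm]] * log(lam) - 0.5 * lam * quad
      lp <- lp + dgamma(lam, priors$lambda_shape, rate = priors$lambda_rate, log = TRUE)
    }
    free <- setdiff(seq_along(state$beta), unlist(des$blocks))
    lp <- lp + sum(dnorm(state$beta[free], 0, priors$sd_fixed, log = TRUE))
  } else {
    lp <- lp + sum(dnorm(state$beta, 0, priors$sd_fixed, log = TRUE))
  }
  for (nm in c("alpha", "gamma", "p_det0"))
    if (!is.null(state[[nm]]))
      lp <- lp + sum(dnorm(state[[nm]], 0, priors$sd_fixed, log = TRUE))
  ## truncated-normal priors on sign-constrained coefficients (truncation
  ## constants are fixed and drop out of MCMC ratios)
  for (nm in c("delta", "beta_count", "beta_lists"))
    if (!is.null(state[[nm]]))
      lp <- lp + sum(dnorm(state[[nm]], 0, priors$sd_fixed, log = TRUE))
  if (!is.null(state$f))
    lp <- lp + dunif(state$f, 0, priors$f_max, log = TRUE)
  lp
}

#' Log posterior density
#'
#' `joint_loglik + log_prior`; `-Inf` outside the constraint boxes.
#'
#' @inheritParams log_prior
#' @export
log_posterior <- function(state, md, priors = prior_spec()) {
  lp <- log_prior(state, md, priors)
  if (!is.finite(lp)) return(-Inf)
  lp + joint_loglik(state, md)
}

#' MCMC schedule
#'
#' @param iterations post-initialization iterations per chain.
#' @param burn_in discarded (and adaptation) iterations.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param chains number of chains.
#' @export
mcmc_schedule <- function(iterations = 2500, burn_in = 500, thin = 2,
                          chains = 3) {
  if (!is_count(iterations) || !is_count(burn_in) || burn_in >= iterations)
    stop_param("`burn_in` must be a non-negative integer < `iterations`")
  if (!is_count(thin) || thin < 1) stop_param("`thin` must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 chains = as.integer(chains),
                 retained = as.integer((iterations - burn_in) %/% thin)),
            class = "mcmc_schedule")
}

## ---- sampler internals ---------------------------------------------------

## Update blocks: name, state element, index within element, affected
## likelihood parts ("all" resolved to every set key).
build_blocks <- function(state, md) {
  keys <- names(md$sets)
  of_protocol <- function(pr) keys[vapply(md$sets, function(s) s$protocol == pr,
                                          logical(1))]
  fp_keys <- keys[vapply(md$sets, function(s) isTRUE(s$fp), logical(1))]
  cl_keys <- of_protocol("checklist")
  blocks <- list()
  des <- md$design
  if (length(des$S)) {
    free <- setdiff(seq_along(state$beta), unlist(des$blocks))
    if (length(free))
      blocks[[length(blocks) + 1L]] <- list(name = "beta_free", elem = "beta",
                                            idx = free, parts = keys)
    for (nm in names(des$blocks))
      blocks[[length(blocks) + 1L]] <- list(name = paste0("beta_", nm),
                                            elem = "beta",
                                            idx = des$blocks[[nm]], parts = keys)
  } else {
    blocks[[length(blocks) + 1L]] <- list(name = "beta", elem = "beta",
                                          idx = seq_along(state$beta), parts = keys)
  }
  if (!is.null(state$alpha))
    blocks[[length(blocks) + 1L]] <- list(name = "alpha", elem = "alpha",
                                          idx = 1:3, parts = of_protocol("single_visit"))
  if (!is.null(state$gamma))
    blocks[[length(blocks) + 1L]] <- list(name = "gamma", elem = "gamma",
                                          idx = 1:5, parts = of_protocol("five_interval"))
  if (!is.null(state$delta))
    blocks[[length(blocks) + 1L]] <- list(name = "delta", elem = "delta",
                                          idx = 1:2, parts = unique(c(cl_keys, fp_keys)))
  if (!is.null(state$p_det0))
    blocks[[length(blocks) + 1L]] <- list(name = "p_det0", elem = "p_det0",
                                          idx = 1L, parts = cl_keys)
  if (!is.null(state$f))
    blocks[[length(blocks) + 1L]] <- list(name = "f", elem = "f", idx = 1L,
                                          parts = fp_keys)
  if (!is.null(state$beta_count)) {
    int_keys <- keys[vapply(md$sets, function(s) !is.null(s$int), logical(1))]
    blocks[[length(blocks) + 1L]] <- list(name = "integration",
                                          elem = c("beta_count", "beta_lists"),
                                          idx = 1L, parts = int_keys)
  }
  blocks
}

flatten_state <- function(state) {
  out <- c()
  for (nm in names(state)) {
    v <- state[[nm]]
    names(v) <- if (length(v) > 1) paste0(nm, "[", seq_along(v), "]") else nm
    out <- c(out, v)
  }
  out
}

#' Sample the marginalized posterior by adaptive blockwise Metropolis
#'
#' Adaptive random-walk Metropolis within Gibbs: parameters are updated in
#' blocks (per-smooth process coefficients, each detection set, effort
#' coefficients, false-positive rate, integration coefficients) with
#' Gaussian proposals whose scales adapt by Robbins-Monro during burn-in
#' only; smoothing parameters `lambda` are updated by their conjugate Gamma
#' full conditional. Per-dataset log-likelihood parts are cached so a block
#' update recomputes only the datasets it touches. Box-constraint violations
#' are rejected (posterior density `-Inf`), which keeps the priors uniform
#' over their boxes near the bounds.
#'
#' @param md model data from [prepare_model_data()].
#' @param priors a [prior_spec()].
#' @param schedule an [mcmc_schedule()].
#' @param seed integer seed; chain `c` uses stream `seed + 7919 * c`.
#' @param init optional initial state ([make_state()] default, jittered
#'   across chains).
#' @param verbose print per-chain acceptance summaries.
#' @return `occufuse_draws`: list of per-chain draw matrices (one column per
#'   scalar), acceptance rates, split-Rhat and effective sample size per
#'   scalar, the schedule, and the model data (kept for prediction).
#' @export
sample_posterior <- function(md, priors = prior_spec(),
                             schedule = mcmc_schedule(), seed = 1,
                             init = NULL, verbose = FALSE) {
  stopifnot(inherits(md, "occufuse_model_data"))
  base_init <- init %||% make_state(md)
  lp0 <- log_posterior(base_init, md, priors)
  if (!is.finite(lp0)) stop_param("non-finite posterior at the initial state")

  des <- md$design
  has_lambda <- !is.null(base_init$lambda)
  chains <- vector("list", schedule$chains)
  accept <- vector("list", schedule$chains)

  for (ch in seq_len(schedule$chains)) {
    set.seed(as.integer(seed + 7919 * ch))
    state <- base_init
    if (ch > 1) { # jitter chains apart (kept inside all boxes)
      state$beta <- state$beta + rnorm(length(state$beta), 0, 0.1)
      if (!is.null(state$f))
        state$f <- min(priors$f_max * 0.99, max(1e-4, state$f * runif(1, 0.5, 1.5)))
      if (!is.null(state$delta)) state$delta <- state$delta * runif(2, 0.7, 1.3)
    }
    blocks <- build_blocks(state, md)
    touches_psi <- vapply(blocks, function(b)
      grepl("^beta", b$name) || b$name == "integration", logical(1))
    scales <- rep(0.1, length(blocks))
    acc_n <- acc_k <- numeric(length(blocks))
    psi_cache <- psi_all(state, md)
    parts <- loglik_parts(state, md, psi_cache = psi_cache)
    lprior <- log_prior(state, md, priors)
    keep <- matrix(NA_real_, schedule$retained,
                   length(flatten_state(state)),
                   dimnames = list(NULL, names(flatten_state(state))))
    ki <- 0L

    for (it in seq_len(schedule$iterations)) {
      for (b in seq_along(blocks)) {
        bl <- blocks[[b]]
        prop <- state
        if (length(bl$elem) > 1) {        # integration pair
          prop$beta_count <- state$beta_count + rnorm(1, 0, scales[b])
          prop$beta_lists <- state$beta_lists + rnorm(1, 0, scales[b])
        } else {
          v <- prop[[bl$elem]]
          v[bl$idx] <- v[bl$idx] + rnorm(length(bl$idx), 0, scales[b])
          prop[[bl$elem]] <- v
        }
        lprior_p <- log_prior(prop, md, priors)
        if (is.finite(lprior_p)) {
          parts_p <- parts
          psi_p <- if (touches_psi[b]) psi_all(prop, md) else psi_cache
          parts_p[bl$parts] <- loglik_parts(prop, md, bl$parts,
                                            psi_cache = psi_p)
          lr <- (lprior_p + sum(parts_p)) - (lprior + sum(parts))
          acc <- is.finite(lr) && log(runif(1)) < lr
        } else acc <- FALSE
        if (acc) {
          state <- prop; parts <- parts_p; lprior <- lprior_p
          if (touches_psi[b]) psi_cache <- psi_p
        }
        if (it <= schedule$burn_in) {     # Robbins-Monro adaptation
          target <- if (length(bl$idx) == 1 && length(bl$elem) == 1) 0.44 else 0.234
          scales[b] <- scales[b] * exp((as.numeric(acc) - target) / sqrt(it))
        }
        acc_n[b] <- acc_n[b] + 1; acc_k[b] <- acc_k[b] + as.numeric(acc)
      }
      if (has_lambda) {                   # conjugate Gamma update
        for (nm in names(des$S)) {
          bj <- state$beta[des$blocks[[nm]]]
          quad <- as.numeric(bj %*% des$S[[nm]] %*% bj)
          state$lambda[[nm]] <- rgamma(1, priors$lambda_shape + des$ranks[[nm]] / 2,
                                       rate = priors$lambda_rate + quad / 2)
        }
        lprior <- log_prior(state, md, priors)
      }
      if (it > schedule$burn_in &&
          (it - schedule$burn_in) %% schedule$thin == 0) {
        ki <- ki + 1L
        keep[ki, ] <- flatten_state(state)
      }
    }
    chains[[ch]] <- keep[seq_len(ki), , drop = FALSE]
    accept[[ch]] <- setNames(acc_k / acc_n,
                             vapply(blocks, `[[`, character(1), "name"))
    if (verbose)
      message(sprintf("chain %d: acceptance %s", ch,
                      paste(sprintf("%s=%.2f", names(accept[[ch]]),
                                    accept[[ch]]), collapse = " ")))
  }

  pn <- colnames(chains[[1]])
  rhat <- vapply(pn, function(p) split_rhat(lapply(chains, function(m) m[, p])),
                 numeric(1))
  ess <- vapply(pn, function(p) ess_basic(lapply(chains, function(m) m[, p])),
                numeric(1))
  structure(list(chains = chains, param_names = pn, schedule = schedule,
                 accept = accept, rhat = rhat, ess = ess, md = md,
                 priors = priors, seed = seed),
            class = "occufuse_draws")
}

#' @export
print.occufuse_draws <- function(x, ...) {
  cat(sprintf("<occufuse_draws> %d chain(s) x %d retained draws; %d scalars; max split-Rhat = %.3f\n",
              length(x$chains), nrow(x$chains[[1]]), length(x$param_names),
              max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

## split-Rhat (each chain halved) for one scalar across chains
split_rhat <- function(chain_vectors) {
  halves <- unlist(lapply(chain_vectors, function(v) {
    n <- length(v) %/% 2
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## basic multi-chain effective sample size (Geyer initial positive sequence)
ess_basic <- function(chain_vectors) {
  m <- length(chain_vectors); n <- length(chain_vectors[[1]])
  if (n < 4) return(NA_real_)
  v_all <- var(unlist(chain_vectors))
  if (v_all < .Machine$double.eps) return(m * n)
  rho_sum <- 0
  for (v in chain_vectors) {
    vc <- v - mean(v)
    ac <- stats::acf(vc, lag.max = min(n - 2, 100), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[k] + ac[k + 1]
      if (is.na(pair) || pair <= 0) break
      s <- s + pair
    }
    rho_sum <- rho_sum + s
  }
  m * n / (1 + 2 * rho_sum / m)
}

#' Extract pooled draws of one scalar parameter
#' @param draws an `occufuse_draws`.
#' @param parameter scalar parameter name (see `draws$param_names`).
#' @export
draws_of <- function(draws, parameter) {
  if (!parameter %in% draws$param_names)
    stop_param("unknown parameter: ", parameter)
  unlist(lapply(draws$chains, function(m) m[, parameter]))
}

#' Posterior credible interval of one scalar parameter
#' @inheritParams draws_of
#' @param level central interval mass.
#' @export
credible_interval <- function(draws, parameter, level = 0.95) {
  v <- draws_of(draws, parameter)
  a <- (1 - level) / 2
  unname(quantile(v, c(a, 1 - a)))
}

#' Posterior occupancy surface at new points
#'
#' Evaluates the occupancy probability at each retained posterior draw and
#' summarizes per point as posterior mean and central credible interval.
#' Covariates must be raw values; they are standardized with the training
#' statistics stored in the model data (no leakage of prediction-time
#' statistics).
#'
#' @param draws an `occufuse_draws`.
#' @param newdata data frame with raw covariate columns (`cov1`, ...) and,
#'   for spatial smooths, `x`,`y` coordinates.
#' @param level credible-interval mass.
#' @return data frame with `mean`, `lower`, `upper` per point.
#' @export
predict_occupancy <- function(draws, newdata, level = 0.95) {
  md <- draws$md
  cc <- md$design$covariate_names
  Xn <- standardize_cols(as.matrix(newdata[, cc, drop = FALSE]),
                         md$center, md$scale)
  if (inherits(md$design, "spline_basis_set")) {
    if (!is.null(md$cov_range) &&
        (any(sweep(Xn, 2, md$cov_range[1, ], "<")) ||
         any(sweep(Xn, 2, md$cov_range[2, ], ">"))))
      warning("some prediction covariates fall outside the basis support (extrapolation)")
    Xd <- evaluate_bases(md$design, Xn,
                         coords = if (md$design$has_space) cbind(newdata$x, newdata$y) else NULL)
  } else {
    Xd <- cbind(1, Xn[, md$design$covariate_names, drop = FALSE])
  }
  bcols <- grep("^beta\\[", draws$param_names)
  if (length(bcols) == 0) bcols <- which(draws$param_names == "beta")
  B <- do.call(rbind, lapply(draws$chains, function(m) m[, bcols, drop = FALSE]))
  psi <- plogis(Xd %*% t(B))  # n points x n draws
  a <- (1 - level) / 2
  qs <- t(apply(psi, 1, quantile, probs = c(a, 1 - a)))
  data.frame(mean = rowMeans(psi), lower = qs[, 1], upper = qs[, 2])
}

#' Check posterior mass near a parameter's box bounds
#'
#' Reports the fraction of pooled draws within `tol` of each bound of a
#' box-constrained parameter and flags the parameter when either fraction
#' exceeds `flag_above` (the posterior piling up at a bound signals an
#' identifiability problem or a truth outside the box).
#'
#' @param draws an `occufuse_draws`.
#' @param parameter scalar parameter name.
#' @param bounds numeric `c(lower, upper)`.
#' @param tol closeness tolerance.
#' @param flag_above flag threshold on either fraction.
#' @return list with `fraction_lower`, `fraction_upper`, `flagged`.
#' @export
check_boundaries <- function(draws, parameter, bounds, tol = 1e-3,
                             flag_above = 0.01) {
  v <- draws_of(draws, parameter)
  fl <- mean(v <= bounds[1] + tol)
  fu <- mean(v >= bounds[2] - tol)
  list(parameter = parameter, fraction_lower = fl, fraction_upper = fu,
       flagged = fl > flag_above || fu > flag_above)
}
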