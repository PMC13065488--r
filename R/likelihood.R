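#' Occupancy probability from a design row and parameter state
#'
#' Inverse-logit of the process linear predictor; when buffer-summarized
#' integration covariates are supplied, the predictor additionally includes
#' `beta_count * count + beta_lists * lists` (sign-constrained so detections
#' of the summarized dataset raise occupancy and sheer list volume discounts
#' it).
#'
#' @param state parameter state (see [make_state()]).
#' @param basis_row numeric design vector (or matrix of rows).
#' @param integration optional `c(count, lists)` vector or two-column matrix.
#' @return occupancy probability/probabilities.
#' @export
occupancy_prob <- function(state, basis_row, integration = NULL) {
  X <- if (is.matrix(basis_row)) basis_row else matrix(basis_row, nrow = 1)
  eta <- as.numeric(X %*% state$beta)
  if (!is.null(integration)) {
    intm <- if (is.matrix(integration)) integration else matrix(integration, nrow = 1)
    eta <- eta + state$beta_count * intm[, 1] + state$beta_lists * intm[, 2]
  }
  plogis(eta)
}

#' Marginal log-likelihood of one survey record
#'
#' The latent presence state is marginalized analytically. For binary
#' protocols (single-visit, checklist): `P(y = 1) = psi * p + (1 - psi) *
#' f_star`. For the five-interval protocol: `P(W = w) = psi * Binom(w; 5, p)
#' + (1 - psi) * 1[w = 0]` (no false-positive path). Vectorized over
#' records; numerically guarded near probability 0/1.
#'
#' @param protocol `"single_visit"`, `"checklist"`, or `"five_interval"`.
#' @param outcome 0/1 for binary protocols, 0..5 for five-interval.
#' @param psi,p occupancy and conditional detection probabilities.
#' @param fstar false-positive probability (0 when the false-positive model
#'   is off; ignored for five-interval records).
#' @return log-probability per record.
#' @export
record_loglik <- function(protocol, outcome, psi, p, fstar = 0) {
  if (any(psi < 0 | psi > 1 | p < 0 | p > 1 | fstar < 0 | fstar > 1))
    stop_param("probabilities must lie in [0, 1]")
  if (protocol == "five_interval") {
    if (any(outcome < 0 | outcome > 5)) stop_param("five-interval outcomes must be in 0..5")
    pr <- psi * dbinom(outcome, 5, p) + (1 - psi) * (outcome == 0)
  } else {
    if (any(!outcome %in% c(0, 1))) stop_param("binary outcomes must be 0/1")
    p1 <- psi * p + (1 - psi) * fstar
    pr <- rep_len(p1, length(outcome))
    zero <- outcome == 0
    pr[zero] <- 1 - p1[if (length(p1) == 1) 1 else zero]
  }
  log_safe(pr)
}

#' Summarize point records into buffer covariates
#'
#' For each target point, counts source records within a closed Euclidean
#' ball of `radius_m` (`lists`) and how many of those had a positive
#' detection (`count`). This is the covariate-integration summary: the less
#' reliable dataset enters the occupancy model through these two numbers
#' instead of its own likelihood.
#'
#' @param target_points two-column coordinate matrix.
#' @param source_records records data frame (`x`, `y`, `outcome`).
#' @param radius_m buffer radius in meters (boundary inclusive).
#' @return matrix with columns `count` and `lists`, one row per target.
#' @export
summarize_as_covariate <- function(target_points, source_records,
                                   radius_m = 1000) {
  tp <- as.matrix(target_points)[, 1:2, drop = FALSE]
  n <- nrow(tp)
  out <- matrix(0L, n, 2, dimnames = list(NULL, c("count", "lists")))
  if (is.null(source_records) || nrow(source_records) == 0) return(out)
  sx <- source_records$x; sy <- source_records$y
  pos <- source_records$outcome >= 1
  r2 <- radius_m^2
  chunk <- max(1L, floor(5e6 / max(1L, length(sx))))
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    d2 <- outer(tp[idx, 1], sx, "-")^2 + outer(tp[idx, 2], sy, "-")^2
    inside <- d2 <= r2
    out[idx, "lists"] <- as.integer(rowSums(inside))
    out[idx, "count"] <- as.integer(inside %*% pos)
  }
  out
}

## ---- model data ----------------------------------------------------------

cov_cols <- function(df) grep("^cov[0-9]+$", names(df), value = TRUE)

#' Assemble likelihood-ready model data from a prepared bundle
#'
#' Standardizes covariates over the union of all training records (or with
#' supplied statistics), builds the process-model design (linear or
#' penalized-spline), standardizes day-of-year and time-of-day per protocol,
#' and packages per-dataset outcome/effort vectors together with the
#' scenario's model-structure switches. Everything [joint_loglik()],
#' [sample_posterior()] and [predict_occupancy()] need is in this object.
#'
#' @param bundle a bundle treated by [prepare_scenario_data()] (its
#'   `scenario` attribute is used unless `scenario` is given).
#' @param scenario optional `model_scenario` override.
#' @param design `"linear"` or `"spline"`.
#' @param k_cov,k_space spline basis dimensions (see [build_bases()]).
#' @param spatial_smooth include the spatial tensor smooth (spline design
#'   only).
#' @param p_star effort-standardization constant of the checklist detection
#'   function.
#' @param center,scale optional externally supplied covariate
#'   standardization statistics.
#' @return an `occufuse_model_data` object.
#' @export
prepare_model_data <- function(bundle, scenario = NULL,
                               design = c("linear", "spline"),
                               k_cov = 10, k_space = 100,
                               spatial_smooth = FALSE, p_star = 0.5,
                               center = NULL, scale = NULL) {
  design <- match.arg(design)
  scenario <- scenario %||% attr(bundle, "scenario")
  if (is.null(scenario))
    stop_param("no scenario: pass one or use prepare_scenario_data() first")

  sets_raw <- list()
  for (key in c("single_visit", "five_interval", "checklist")) {
    df <- bundle[[key]]
    if (!is.null(df) && nrow(df) > 0) sets_raw[[key]] <- df
  }
  if (!is.null(bundle$historic) && nrow(bundle$historic) > 0) {
    for (pr in unique(bundle$historic$protocol)) {
      sets_raw[[paste0("historic_", pr)]] <-
        bundle$historic[bundle$historic$protocol == pr, , drop = FALSE]
    }
  }
  if (length(sets_raw) == 0) {
    return(structure(list(sets = list(), design = NULL, scenario = scenario,
                          p_star = p_star, has_fp = FALSE, has_int = FALSE,
                          effort_model = scenario$effort_model,
                          protocols = character(0)),
                     class = "occufuse_model_data"))
  }

  cc <- cov_cols(sets_raw[[1]])
  allX <- do.call(rbind, lapply(sets_raw, function(df) as.matrix(df[, cc, drop = FALSE])))
  allXs <- standardize_cols(allX, center, scale)
  center <- attr(allXs, "center"); scale <- attr(allXs, "scale")
  all_coords <- do.call(rbind, lapply(sets_raw, function(df) cbind(df$x, df$y)))

  des <- if (design == "spline")
    build_bases(allXs, coords = if (spatial_smooth) all_coords else NULL,
                k_cov = k_cov, k_space = k_space)
  else build_linear_design(allXs)

  ## per-protocol day/time standardization statistics over training data
  stat_of <- function(keys, col) {
    v <- unlist(lapply(sets_raw[keys], function(df) df[[col]]))
    v <- v[!is.na(v)]
    if (length(v) == 0) c(mean = 0, sd = 1)
    else if (length(v) < 2 || sd(v) < .Machine$double.eps) c(mean = mean(v), sd = 1)
    else c(mean = mean(v), sd = sd(v))
  }
  keys_of_protocol <- function(pr) names(sets_raw)[vapply(sets_raw, function(df)
    df$protocol[1] == pr, logical(1))]
  dt_stats <- list()
  for (pr in c("single_visit", "five_interval")) {
    ks <- keys_of_protocol(pr)
    if (length(ks)) {
      dt_stats[[pr]] <- list(day = stat_of(ks, "day"),
                             time = if (pr == "five_interval") stat_of(ks, "time") else NULL)
    }
  }

  offset <- 0L
  sets <- list()
  has_fp <- FALSE; has_int <- FALSE
  for (key in names(sets_raw)) {
    df <- sets_raw[[key]]
    idx <- offset + seq_len(nrow(df)); offset <- offset + nrow(df)
    pr <- df$protocol[1]
    fp_target <- scenario$false_positive_on
    fp <- !is.null(fp_target) && pr != "five_interval" && (
      (fp_target == "checklist" && key == "checklist") ||
        (fp_target == "historic" && startsWith(key, "historic_")))
    has_fp <- has_fp || fp
    intm <- NULL
    if (all(c("int_count", "int_lists") %in% names(df))) {
      intm <- cbind(count = df$int_count, lists = df$int_lists)
      has_int <- TRUE
    }
    st <- dt_stats[[pr]]
    sets[[key]] <- list(
      key = key, protocol = pr, n = nrow(df),
      X = des$X[idx, , drop = FALSE],
      coords = cbind(df$x, df$y),
      y = df$outcome,
      day_std = if (!is.null(st)) (df$day - st$day["mean"]) / st$day["sd"] else NULL,
      time_std = if (!is.null(st$time)) (df$time - st$time["mean"]) / st$time["sd"] else NULL,
      duration = df$duration_hours, distance = df$distance_km,
      fp = fp, int = intm)
  }

  structure(list(sets = sets, design = des, scenario = scenario,
                 p_star = p_star, center = center, scale = scale,
                 cov_range = apply(allXs, 2, range),
                 dt_stats = dt_stats, has_fp = has_fp, has_int = has_int,
                 effort_model = scenario$effort_model,
                 protocols = unique(vapply(sets, `[[`, character(1), "protocol"))),
            class = "occufuse_model_data")
}

## ---- parameter state -----------------------------------------------------

#' Construct a full parameter state for a model-data object
#'
#' @param md an `occufuse_model_data`.
#' @param beta,alpha,gamma,delta,p_det0,f,beta_count,beta_lists,lambda
#'   parameter values; defaults give a valid interior state (coefficients 0,
#'   `delta = c(1, 1)`, `f = 0.05`, `lambda = 1`).
#' @return named list (`occufuse_state`) with exactly the parameters the
#'   model structure uses.
#' @export
make_state <- function(md, beta = NULL, alpha = NULL, gamma = NULL,
                       delta = NULL, p_det0 = NULL, f = NULL,
                       beta_count = NULL, beta_lists = NULL, lambda = NULL) {
  if (length(md$sets) == 0)
    return(structure(list(beta = beta %||% numeric(0)), class = "occufuse_state"))
  st <- list(beta = beta %||% numeric(ncol(md$design$X)))
  if ("single_visit" %in% md$protocols) st$alpha <- alpha %||% c(0, 0, 0)
  if ("five_interval" %in% md$protocols) st$gamma <- gamma %||% rep(0, 5)
  if ("checklist" %in% md$protocols) {
    if (md$effort_model) st$delta <- delta %||% c(1, 1)
    else st$p_det0 <- p_det0 %||% 0
  }
  if (md$has_fp) st$f <- f %||% 0.05
  if (md$has_int) {
    st$beta_count <- beta_count %||% 0.1
    st$beta_lists <- beta_lists %||% -0.1
  }
  if (length(md$design$S))
    st$lambda <- lambda %||% setNames(rep(1, length(md$design$S)), names(md$design$S))
  structure(st, class = "occufuse_state")
}

state_ok <- function(state) {
  if (!is.null(state$delta) && any(state$delta < 0)) return(FALSE)
  if (!is.null(state$f) && (state$f < 0 || state$f > 0.25)) return(FALSE)
  if (!is.null(state$beta_count) && state$beta_count < 0) return(FALSE)
  if (!is.null(state$beta_lists) && state$beta_lists > 0) return(FALSE)
  if (!is.null(state$lambda) && any(state$lambda <= 0)) return(FALSE)
  TRUE
}

## ---- joint likelihood ----------------------------------------------------

set_loglik <- function(state, set, md, psi = NULL) {
  if (is.null(psi)) psi <- occupancy_prob(state, set$X, set$int)
  if (set$protocol == "single_visit") {
    p <- detect_single_visit(state$alpha, set$day_std)
    fstar <- if (set$fp) false_positive_prob(state$f, 1) else 0
    sum(record_loglik("single_visit", set$y, psi, p, fstar))
  } else if (set$protocol == "five_interval") {
    p <- detect_five_interval(state$gamma, set$time_std, set$day_std)
    sum(record_loglik("five_interval", set$y, psi, p))
  } else {
    if (md$effort_model) {
      E <- effort_value(state$delta, set$duration, set$distance)
      p <- effort_detection(E, md$p_star)
    } else {
      E <- 1
      p <- rep(plogis(state$p_det0), set$n)
    }
    fstar <- if (set$fp) false_positive_prob(state$f, E) else 0
    sum(record_loglik("checklist", set$y, psi, p, fstar))
  }
}

loglik_parts <- function(state, md, parts = names(md$sets), psi_cache = NULL) {
  if (!state_ok(state))
    return(setNames(rep(-Inf, length(parts)), parts))
  vapply(parts, function(key) set_loglik(state, md$sets[[key]], md,
                                         psi = psi_cache[[key]]),
         numeric(1))
}

psi_all <- function(state, md) {
  lapply(md$sets, function(s) occupancy_prob(state, s$X, s$int))
}

#' Joint marginalized log-likelihood over all datasets
#'
#' Sum of the marginal record log-likelihoods over every dataset in the
#' joint likelihood, with the scenario's model structure applied: the
#' checklist effort model (or an intercept-only detection when off), the
#' false-positive path for the dataset the scenario names, and the
#' buffer-covariate terms when integration is on. States violating a box
#' constraint (`delta >= 0`, `f` in `[0, 0.25]`, `beta_count >= 0`,
#' `beta_lists <= 0`, `lambda > 0`) return `-Inf`.
#'
#' @param state an [make_state()] parameter state.
#' @param md an [prepare_model_data()] object.
#' @return scalar log-likelihood (0 for an empty bundle).
#' @export
joint_loglik <- function(state, md) {
  stopifnot(inherits(md, "occufuse_model_data"))
  if (length(md$sets) == 0) return(0)
  sum(loglik_parts(state, md))
}
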