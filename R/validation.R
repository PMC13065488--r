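#' Train/test split specification
#'
#' @param holdout_fraction fraction of the eligible pool moved to the test
#'   set (per dataset, i.e. stratified).
#' @param pool `"structured_only"` (single-visit and five-interval records)
#'   or `"current_only"` (current-era single-visit and checklist records).
#'   Historic records are never held out.
#' @param seed integer seed.
#' @export
split_spec <- function(holdout_fraction = 0.2,
                       pool = c("structured_only", "current_only"), seed = 1) {
  if (!is_number(holdout_fraction) || holdout_fraction <= 0 ||
      holdout_fraction >= 1)
    stop_param("`holdout_fraction` must be in (0, 1)")
  structure(list(holdout_fraction = holdout_fraction, pool = match.arg(pool),
                 seed = as.integer(seed)), class = "split_spec")
}

#' Split a bundle into training data and holdout records
#'
#' Draws `round(fraction * n)` records per pool dataset uniformly at random
#' (stratified by dataset) into the test set; everything else — including
#' all historic records — stays in training.
#'
#' @param bundle a dataset bundle.
#' @param spec a [split_spec()].
#' @return list with `train` (bundle) and `test` (one data frame of holdout
#'   records across pool datasets).
#' @export
split_data <- function(bundle, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  pool_keys <- if (spec$pool == "structured_only")
    c("single_visit", "five_interval") else c("single_visit", "checklist")
  pool_keys <- pool_keys[vapply(pool_keys, function(k)
    !is.null(bundle[[k]]) && nrow(bundle[[k]]) > 0, logical(1))]
  if (length(pool_keys) == 0) stop_param("holdout pool is empty")

  train <- bundle
  test_list <- list()
  for (i in seq_along(pool_keys)) {
    key <- pool_keys[i]
    df <- bundle[[key]]
    eligible <- which(df$era == "current")
    n_test <- round(spec$holdout_fraction * length(eligible))
    if (n_test == 0) next
    take <- with_seed(spec$seed + i, sort(sample(eligible, n_test)))
    test_list[[key]] <- df[take, , drop = FALSE]
    train[[key]] <- df[-take, , drop = FALSE]
  }
  test <- do.call(rbind, unname(test_list))
  rownames(test) <- NULL
  list(train = train, test = test)
}

#' Brier score of probabilistic predictions
#'
#' Mean squared error between predicted probabilities and binary outcomes.
#'
#' @param predictions probabilities in `[0, 1]`.
#' @param outcomes binary outcomes (0/1).
#' @export
brier_score <- function(predictions, outcomes) {
  if (length(predictions) != length(outcomes))
    stop_param("`predictions` and `outcomes` must have equal length")
  if (length(predictions) == 0) stop_param("empty inputs")
  if (any(!outcomes %in% c(0, 1))) stop_param("outcomes must be binary 0/1")
  mean((predictions - outcomes)^2)
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive receives a higher prediction
#' than a randomly chosen negative; computed by the rank (Mann-Whitney)
#' formula, equivalent to exhaustive pair enumeration. Ties score 0.5 by
#' default; `ties = "strict"` counts only strict inequalities (scoring ties
#' as 0).
#'
#' @param predictions numeric predictions.
#' @param outcomes binary outcomes with at least one 0 and one 1.
#' @param ties `"half"` (Mann-Whitney, default) or `"strict"`.
#' @export
auc <- function(predictions, outcomes, ties = c("half", "strict")) {
  ties <- match.arg(ties)
  if (length(predictions) != length(outcomes))
    stop_param("`predictions` and `outcomes` must have equal length")
  if (any(!outcomes %in% c(0, 1))) stop_param("outcomes must be binary 0/1")
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0)
    stop_param("AUC undefined: outcomes contain a single class")
  r <- rank(predictions, ties.method = "average")
  a <- (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (ties == "strict") {
    ## remove the half-credit that average ranks give tied pairs
    pos <- predictions[outcomes == 1]
    tied_pairs <- sum(vapply(pos, function(p) sum(predictions[outcomes == 0] == p),
                             numeric(1)))
    a <- a - 0.5 * tied_pairs / (n1 * n0)
  }
  a
}

#' Percent-change comparison of two validation reports
#'
#' Percent change of each metric relative to the reference model, signed so
#' that positive values always indicate improvement: AUC uses
#' `(alt - ref) / ref`, Brier uses `-(alt - ref) / ref` (lower Brier is
#' better, hence the sign flip).
#'
#' @param alt,ref validation reports from [score_holdout()] (must be scored
#'   on the same test set).
#' @return list with `pct_change_auc` and `pct_change_brier`, in percent.
#' @export
compare_models <- function(alt, ref) {
  if (!isTRUE(all.equal(alt$n_test, ref$n_test)))
    stop_param("reports must be scored on the same test set")
  if (ref$auc == 0 || ref$brier == 0)
    stop_param("reference metric is zero; percent change undefined")
  list(pct_change_auc = 100 * (alt$auc - ref$auc) / ref$auc,
       pct_change_brier = -100 * (alt$brier - ref$brier) / ref$brier)
}

## per-draw parameter matrix helpers
pooled_draws <- function(draws) do.call(rbind, draws$chains)

param_cols <- function(draws, stem, k = NULL) {
  if (!is.null(k)) {
    nm <- paste0(stem, "[", seq_len(k), "]")
    if (all(nm %in% draws$param_names)) return(nm)
  }
  if (stem %in% draws$param_names) return(stem)
  grep(paste0("^", stem, "\\["), draws$param_names, value = TRUE)
}

#' Posterior-mean detection-scale predictions for holdout records
#'
#' For each holdout record, computes the probability of an observed
#' detection under each retained posterior draw — `psi * p` for binary
#' protocols (plus the false-positive path `(1 - psi) * f_star` when the
#' scenario models it for that protocol), and `psi * (1 - (1 - p)^5)` for
#' the five-interval binary event "detected in at least one interval" — and
#' averages over draws. All standardizations (covariates, day, time) use
#' training statistics stored in the model data.
#'
#' @param draws an `occufuse_draws` from [sample_posterior()].
#' @param records holdout records data frame.
#' @return numeric prediction per record.
#' @export
predict_detection <- function(draws, records) {
  md <- draws$md
  D <- pooled_draws(draws)
  nd <- nrow(D)
  cc <- md$design$covariate_names
  preds <- numeric(nrow(records))

  B <- D[, param_cols(draws, "beta", ncol(md$design$X)), drop = FALSE]
  for (pr in unique(records$protocol)) {
    ii <- which(records$protocol == pr)
    df <- records[ii, , drop = FALSE]
    Xs <- standardize_cols(as.matrix(df[, cc, drop = FALSE]), md$center, md$scale)
    Xd <- design_matrix_at(md$design, Xs,
                           coords = if (isTRUE(md$design$has_space)) cbind(df$x, df$y) else NULL)
    eta <- Xd %*% t(B)                       # n x draws
    if (!is.null(md$scenario$covariate_integration) &&
        all(c("int_count", "int_lists") %in% names(df))) {
      eta <- eta + outer(df$int_count, D[, "beta_count"]) +
        outer(df$int_lists, D[, "beta_lists"])
    }
    psi <- plogis(eta)
    st <- md$dt_stats[[pr]]
    if (pr == "single_visit") {
      A <- D[, param_cols(draws, "alpha", 3), drop = FALSE]
      ds <- (df$day - st$day["mean"]) / st$day["sd"]
      p <- plogis(outer(ds, A[, 2]) + outer(ds^2, A[, 3]) +
                    matrix(A[, 1], length(ii), nd, byrow = TRUE))
      pd <- psi * p
    } else if (pr == "five_interval") {
      G <- D[, param_cols(draws, "gamma", 5), drop = FALSE]
      ds <- (df$day - st$day["mean"]) / st$day["sd"]
      ts <- (df$time - st$time["mean"]) / st$time["sd"]
      p <- plogis(matrix(G[, 1], length(ii), nd, byrow = TRUE) +
                    outer(ts, G[, 2]) + outer(ts^2, G[, 3]) +
                    outer(ds, G[, 4]) + outer(ds^2, G[, 5]))
      pd <- psi * (1 - (1 - p)^5)
    } else {
      if (md$effort_model) {
        dl <- D[, param_cols(draws, "delta", 2), drop = FALSE]
        E <- outer(df$duration_hours, dl[, 1]) + outer(df$distance_km, dl[, 2])
        p <- 1 - (1 - md$p_star)^E
      } else {
        E <- matrix(1, length(ii), nd)
        p <- plogis(matrix(D[, "p_det0"], length(ii), nd, byrow = TRUE))
      }
      pd <- psi * p
      if (identical(md$scenario$false_positive_on, "checklist") &&
          all(df$era == "current")) {
        fs <- 1 - (1 - matrix(D[, "f"], length(ii), nd, byrow = TRUE))^E
        pd <- pd + (1 - psi) * fs
      }
    }
    preds[ii] <- rowMeans(pd)
  }
  preds
}

#' Score a fitted model on holdout records
#'
#' @param draws an `occufuse_draws`.
#' @param test holdout records (from [split_data()]).
#' @param scenario_id label recorded in the report.
#' @return a `validation_report`: Brier score, AUC, test size.
#' @export
score_holdout <- function(draws, test, scenario_id = NA_character_) {
  preds <- predict_detection(draws, test)
  outcomes <- ifelse(test$protocol == "five_interval",
                     as.integer(test$outcome > 0), test$outcome)
  structure(list(scenario_id = scenario_id,
                 brier = brier_score(preds, outcomes),
                 auc = auc(preds, outcomes), n_test = length(outcomes)),
            class = "validation_report")
}

#' Run the scenario-comparison experiment
#'
#' For each requested scenario: apply its data treatment, fit by MCMC,
#' predict the holdout records, score Brier and AUC, and express each
#' scenario as percent change against its family's reference model (R1 for
#' the effort and checklist-reliability scenarios, R2 for the historic-data
#' scenarios). Within a family every scenario is scored on the identical
#' test set, drawn from the family's holdout pool before any
#' scenario-specific treatment. For the current-era pool the common
#' checklist treatment (standard filters plus balancing) is applied before
#' splitting, since every historic-family scenario shares it.
#'
#' @param scenario_ids character vector; each family's reference must be
#'   included.
#' @param bundle a raw dataset bundle (e.g. from [simulate_bundle()]).
#' @param schedule an [mcmc_schedule()].
#' @param seed master seed for splitting, balancing and the samplers.
#' @param design `"linear"` or `"spline"` process design.
#' @param spatial_smooth include the spatial tensor smooth (spline only).
#' @param holdout_fraction holdout fraction.
#' @param priors a [prior_spec()].
#' @param grid hex grid for balancing (default 1 km, landscape origin).
#' @param verbose print progress lines.
#' @return data frame: one row per scenario with `brier`, `auc`, `n_test`,
#'   `pct_change_brier`, `pct_change_auc`, `reference`.
#' @export
run_experiment <- function(scenario_ids, bundle, schedule = mcmc_schedule(),
                           seed = 1, design = "linear",
                           spatial_smooth = FALSE, holdout_fraction = 0.2,
                           priors = prior_spec(), grid = NULL,
                           verbose = FALSE) {
  registry <- scenario_registry()
  scens <- lapply(scenario_ids, get_scenario, registry = registry)
  names(scens) <- scenario_ids
  refs <- unique(vapply(scens, `[[`, character(1), "reference"))
  missing_refs <- setdiff(refs, scenario_ids)
  if (length(missing_refs))
    stop_param("family reference(s) not in `scenario_ids`: ",
               paste(missing_refs, collapse = ", "))
  if (is.null(grid)) {
    origin <- if (!is.null(bundle$landscape)) bundle$landscape$bounds[c(1, 3)] else c(0, 0)
    grid <- hex_grid(1000, origin = origin)
  }

  reports <- list()
  for (ref_id in refs) {
    fam_ids <- scenario_ids[vapply(scens, function(s) s$reference == ref_id,
                                   logical(1))]
    pool <- scens[[ref_id]]$holdout_pool
    work <- bundle
    if (pool == "current_only" && !is.null(work$checklist)) {
      cl <- apply_effort_filters(work$checklist, effort_filter_spec())
      work$checklist <- spatially_balance(cl, grid, seed)
    }
    sp <- split_data(work, split_spec(holdout_fraction, pool, seed))

    for (k in seq_along(fam_ids)) {
      id <- fam_ids[k]
      if (verbose) message("fitting scenario ", id)
      train <- prepare_scenario_data(sp$train, scens[[id]], seed, grid)
      md <- prepare_model_data(train, design = design,
                               spatial_smooth = spatial_smooth)
      draws <- sample_posterior(md, priors, schedule,
                                seed = seed + 17L * match(id, scenario_ids))
      test <- sp$test
      if (!is.null(scens[[id]]$covariate_integration)) {
        src <- attr(train, "int_source")
        sm <- summarize_as_covariate(cbind(test$x, test$y), src)
        test$int_count <- sm[, "count"]; test$int_lists <- sm[, "lists"]
      }
      reports[[id]] <- score_holdout(draws, test, id)
    }
  }

  out <- do.call(rbind, lapply(scenario_ids, function(id) {
    r <- reports[[id]]
    cmp <- compare_models(r, reports[[scens[[id]]$reference]])
    data.frame(scenario = id, reference = scens[[id]]$reference,
               brier = r$brier, auc = r$auc, n_test = r$n_test,
               pct_change_brier = cmp$pct_change_brier,
               pct_change_auc = cmp$pct_change_auc,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
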