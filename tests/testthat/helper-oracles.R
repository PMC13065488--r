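# Independent oracles and small fixtures used across the suite.
# Oracles deliberately re-derive quantities by brute force (enumeration,
# pairwise loops, nearest-center search) and share no code with the package
# implementation beyond reading its data structures.

## Joint log-likelihood by per-record enumeration of the latent state.
oracle_joint_loglik <- function(state, md) {
  total <- 0
  for (set in md$sets) {
    for (i in seq_len(set$n)) {
      eta <- sum(set$X[i, ] * state$beta)
      if (!is.null(set$int))
        eta <- eta + state$beta_count * set$int[i, 1] +
          state$beta_lists * set$int[i, 2]
      psi <- 1 / (1 + exp(-eta))
      y <- set$y[i]
      if (set$protocol == "five_interval") {
        p <- 1 / (1 + exp(-sum(state$gamma * c(1, set$time_std[i],
                                               set$time_std[i]^2,
                                               set$day_std[i],
                                               set$day_std[i]^2))))
        pr <- psi * choose(5, y) * p^y * (1 - p)^(5 - y) +
          (1 - psi) * as.numeric(y == 0)
      } else {
        if (set$protocol == "single_visit") {
          p <- 1 / (1 + exp(-(state$alpha[1] + state$alpha[2] * set$day_std[i] +
                                state$alpha[3] * set$day_std[i]^2)))
          E <- 1
        } else if (md$effort_model) {
          E <- state$delta[1] * set$duration[i] + state$delta[2] * set$distance[i]
          p <- 1 - (1 - md$p_star)^E
        } else {
          E <- 1
          p <- 1 / (1 + exp(-state$p_det0))
        }
        fstar <- if (set$fp) 1 - (1 - state$f)^E else 0
        ## enumerate z in {0, 1}
        pr <- psi * (if (y == 1) p else 1 - p) +
          (1 - psi) * (if (y == 1) fstar else 1 - fstar)
      }
      total <- total + as.numeric(log(pr))
    }
  }
  total
}

## AUC by exhaustive enumeration of positive x negative pairs.
oracle_auc <- function(pred, out, tie_credit = 0.5) {
  pos <- pred[out == 1]; neg <- pred[out == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) tie_credit else 0
  s / (length(pos) * length(neg))
}

## Nearest hexagon center by brute-force search over a window of axial
## indices around each point.
oracle_hex_nearest <- function(points, grid) {
  points <- as.matrix(points)
  span <- ceiling(max(abs(points)) / grid$size) + 3
  qs <- -span:span
  centers <- as.matrix(expand.grid(q = qs, r = qs))
  xy <- hex_cell_center(centers, grid)
  vapply(seq_len(nrow(points)), function(i) {
    d2 <- (xy[, 1] - points[i, 1])^2 + (xy[, 2] - points[i, 2])^2
    j <- which.min(d2)
    paste0(centers[j, 1], ":", centers[j, 2])
  }, character(1))
}

## Small fixture bundle used where the exact generating values do not matter.
tiny_bundle <- function(seed = 7, n_sv = 40, n_fi = 30, n_cl = 80,
                        f_true = 0, historic = NULL) {
  simulate_bundle(seed = seed, n_single_visit = n_sv, n_five_interval = n_fi,
                  n_checklists = n_cl, f_true = f_true, historic = historic)
}

## Hand-built checklist records at chosen coordinates/effort for filter tests.
manual_checklists <- function(n, x = NULL, y = NULL, duration = 1,
                              distance = 1, observers = 2, complete = TRUE,
                              outcome = 0) {
  data.frame(
    record_id = sprintf("m%04d", seq_len(n)), protocol = "checklist",
    x = rep_len(x %||% runif(n, 0, 5000), n),
    y = rep_len(y %||% runif(n, 0, 5000), n),
    day = 160L, time = 8, duration_hours = rep_len(duration, n),
    distance_km = rep_len(distance, n), n_observers = rep_len(observers, n),
    complete = rep_len(complete, n), era = "current",
    outcome = rep_len(outcome, n), cov1 = rnorm(n), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
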