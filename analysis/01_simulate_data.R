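#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study data.
#
# Builds two dataset bundles over a 20 x 20 km landscape with three
# environmental covariates:
#   * "effort" bundle: current-era single-visit (BBS-like), five-interval
#     (atlas-like) and checklist (eBird-like) data, with mild false-positive
#     contamination of the checklist stream;
#   * "reliability" bundle: the same protocols plus a historic-era dataset
#     generated from a shifted occupancy surface (range change since the
#     historic records were collected).
# Writes one CSV per dataset plus a truth.json sidecar under results/data/.

suppressPackageStartupMessages(library(occufuse))

seed <- 20260924L
out_dir <- file.path("results", "data")

message("simulating effort bundle ...")
effort_bundle <- simulate_bundle(
  seed = seed, n_covariates = 3,
  beta_true = c(-0.5, 1, -0.7, 0.5),
  n_single_visit = 400, n_five_interval = 250, n_checklists = 1500,
  f_true = 0.05)
write_bundle(effort_bundle, file.path(out_dir, "effort"))

message("simulating reliability bundle (historic range shift) ...")
rel_bundle <- simulate_bundle(
  seed = seed + 1L, n_covariates = 3,
  beta_true = c(-0.3, 1, -0.7, 0.5),
  n_single_visit = 300, n_five_interval = 0, n_checklists = 800,
  historic = list(shift = historic_shift(-1.5, 1, -2),
                  n_single_visit = 250, n_five_interval = 150,
                  n_checklists = 300))
write_bundle(rel_bundle, file.path(out_dir, "reliability"))

summarize <- function(bundle, name) {
  for (key in c("single_visit", "five_interval", "checklist", "historic")) {
    df <- bundle[[key]]
    if (is.null(df) || nrow(df) == 0) next
    det <- mean(df$outcome > 0)
    message(sprintf("  %-12s %-13s n = %5d  detection frequency = %.3f",
                    name, key, nrow(df), det))
  }
}
summarize(effort_bundle, "effort")
summarize(rel_bundle, "reliability")
message("wrote ", out_dir)
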