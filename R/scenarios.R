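#' Model-scenario registry
#'
#' Loads the declarative scenario grid (one entry per model variant of the
#' comparison experiment) from the YAML registry shipped with the package:
#' the effort-handling family (reference R1; F1-F6 varying checklist filters,
#' spatial balancing, and the effort model) and the data-reliability family
#' (E1-E3 treating checklists as less reliable, compared to R1; R2 and O1-O3
#' treating historic records as less reliable).
#'
#' @param path optional path to an alternative YAML registry.
#' @return named list of `model_scenario` objects.
#' @export
scenario_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "scenarios.yaml", package = "occufuse")
  raw <- yaml::read_yaml(path)$scenarios
  out <- lapply(raw, function(s) {
    if (!is.null(s$false_positive_on) && !is.null(s$covariate_integration))
      stop_param("scenario ", s$id,
                 ": false_positive_on and covariate_integration cannot both be set")
    filt <- if (identical(s$filters, "standard"))
      effort_filter_spec(exclude_traveling = isTRUE(s$exclude_traveling))
    else NULL
    structure(list(
      id = s$id, family = s$family, reference = s$reference,
      filter = filt, balancing = isTRUE(s$balancing),
      effort_model = isTRUE(s$effort_model),
      false_positive_on = s$false_positive_on,
      covariate_integration = s$covariate_integration,
      drop_checklist = isTRUE(s$drop_checklist),
      uses_historic = isTRUE(s$uses_historic),
      holdout_pool = s$holdout_pool
    ), class = "model_scenario")
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Look up a single scenario by id
#' @param id scenario identifier (e.g. `"R1"`, `"F4"`, `"E2"`, `"O3"`).
#' @param registry a [scenario_registry()] (reloaded if omitted).
#' @export
get_scenario <- function(id, registry = scenario_registry()) {
  if (!id %in% names(registry)) stop_param("unknown scenario id: ", id)
  registry[[id]]
}

#' @export
print.model_scenario <- function(x, ...) {
  cat(sprintf("<model_scenario %s> family=%s ref=%s filters=%s balancing=%s effort_model=%s fp=%s covint=%s\n",
              x$id, x$family, x$reference,
              if (is.null(x$filter)) "none" else "standard",
              x$balancing, x$effort_model,
              x$false_positive_on %||% "-", x$covariate_integration %||% "-"))
  invisible(x)
}

#' Apply a scenario's data treatment to a dataset bundle
#'
#' Implements the per-scenario data handling of the experiment grid: effort
#' filtering and hexagonal balancing of checklists, dropping datasets that
#' the scenario excludes, and summarizing a less reliable dataset into
#' buffer covariates (`int_count`, `int_lists`) attached to the remaining
#' datasets' records. Model-structure switches (effort model on/off,
#' false-positive path) live in the scenario itself and are consumed at
#' likelihood-building time, not here.
#'
#' @param bundle a dataset bundle (list with `single_visit`,
#'   `five_interval`, `checklist`, optionally `historic`).
#' @param scenario a `model_scenario` or scenario id string.
#' @param seed integer seed (used by the balancing selection).
#' @param grid hexagonal grid for balancing (defaults to 1-km spacing with
#'   origin at the landscape's lower-left corner when a landscape is
#'   bundled, else at (0, 0)).
#' @param buffer_radius_m radius of the covariate-summarization buffer.
#' @return the treated bundle, with the scenario attached as attribute
#'   `scenario`.
#' @export
prepare_scenario_data <- function(bundle, scenario, seed = 1, grid = NULL,
                                  buffer_radius_m = 1000) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  stopifnot(inherits(scenario, "model_scenario"))
  out <- bundle
  if (is.null(grid)) {
    origin <- if (!is.null(bundle$landscape))
      bundle$landscape$bounds[c(1, 3)] else c(0, 0)
    grid <- hex_grid(1000, origin = origin)
  }

  if (!scenario$uses_historic) out$historic <- NULL

  if (scenario$drop_checklist) {
    out$checklist <- NULL
  } else if (!is.null(out$checklist)) {
    cl <- out$checklist
    if (!is.null(scenario$filter)) cl <- apply_effort_filters(cl, scenario$filter)
    if (identical(scenario$covariate_integration, "checklist")) {
      ## summarize the (effort-filtered, unbalanced) checklist stream into
      ## buffer covariates on the structured datasets, then remove it from
      ## the joint likelihood
      for (key in c("single_visit", "five_interval")) {
        if (is.null(out[[key]])) next
        sm <- summarize_as_covariate(cbind(out[[key]]$x, out[[key]]$y), cl,
                                     radius_m = buffer_radius_m)
        out[[key]]$int_count <- sm[, "count"]
        out[[key]]$int_lists <- sm[, "lists"]
      }
      attr(out, "int_source") <- cl
      out$checklist <- NULL
    } else {
      if (scenario$balancing) cl <- spatially_balance(cl, grid, seed)
      out$checklist <- cl
    }
  }

  if (identical(scenario$covariate_integration, "historic")) {
    if (is.null(bundle$historic))
      stop_param("scenario ", scenario$id, " summarizes historic data but the bundle has none")
    for (key in c("single_visit", "checklist")) {
      if (is.null(out[[key]])) next
      sm <- summarize_as_covariate(cbind(out[[key]]$x, out[[key]]$y),
                                   bundle$historic, radius_m = buffer_radius_m)
      out[[key]]$int_count <- sm[, "count"]
      out[[key]]$int_lists <- sm[, "lists"]
    }
    attr(out, "int_source") <- bundle$historic
    out$historic <- NULL
  }

  attr(out, "scenario") <- scenario
  out
}
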