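#' Checklist effort-filter specification
#'
#' Quality thresholds for semi-structured checklists, following the standard
#' recommendations for participatory bird data: keep only checklists strictly
#' under 5 h duration, strictly under 10 km traveled, and with strictly fewer
#' than 10 observers; optionally restrict to complete lists and/or exclude
#' traveling lists (distance > 0) entirely.
#'
#' @param max_duration_hours,max_distance_km,max_observers strict upper
#'   thresholds (a record is kept only if its value is `<` the threshold).
#' @param exclude_traveling if `TRUE`, remove every record with
#'   `distance_km > 0`.
#' @param complete_lists_only if `TRUE`, remove records flagged incomplete.
#' @export
effort_filter_spec <- function(max_duration_hours = 5, max_distance_km = 10,
                               max_observers = 10, exclude_traveling = FALSE,
                               complete_lists_only = TRUE) {
  if (max_duration_hours <= 0 || max_distance_km <= 0 || max_observers <= 0)
    stop_param("all filter thresholds must be strictly positive")
  structure(list(max_duration_hours = max_duration_hours,
                 max_distance_km = max_distance_km,
                 max_observers = max_observers,
                 exclude_traveling = isTRUE(exclude_traveling),
                 complete_lists_only = isTRUE(complete_lists_only)),
            class = "effort_filter_spec")
}

#' Apply checklist effort filters
#'
#' Removes checklist records failing any enabled criterion of an
#' [effort_filter_spec()]; comparisons are strict (`<`), record order is
#' preserved, and per-criterion removal counts are attached as the
#' `removed_counts` attribute (one log line per criterion is emitted at
#' `message` level).
#'
#' @param records checklist records data frame (all `protocol == "checklist"`).
#' @param spec an [effort_filter_spec()].
#' @param quiet suppress per-criterion log messages.
#' @return the retained records (original order), with attribute
#'   `removed_counts`.
#' @export
apply_effort_filters <- function(records, spec = effort_filter_spec(),
                                 quiet = TRUE) {
  stopifnot(inherits(spec, "effort_filter_spec"))
  if (nrow(records) == 0) return(records)
  if (any(records$protocol != "checklist"))
    stop_param("effort filters apply to checklist records only")
  crit <- list(
    duration  = records$duration_hours < spec$max_duration_hours,
    distance  = records$distance_km < spec$max_distance_km,
    observers = records$n_observers < spec$max_observers
  )
  if (spec$exclude_traveling) crit$traveling <- records$distance_km == 0
  if (spec$complete_lists_only && "complete" %in% names(records) &&
      !all(is.na(records$complete)))
    crit$incomplete <- records$complete %in% TRUE
  keep <- Reduce(`&`, lapply(crit, function(k) !is.na(k) & k))
  removed <- vapply(crit, function(k) sum(!(!is.na(k) & k)), integer(1))
  if (!quiet)
    for (nm in names(removed))
      message(sprintf("filter %-10s removed %d / %d records (marginal)",
                      nm, removed[[nm]], nrow(records)))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_counts") <- removed
  out
}

#' Hexagonal grid specification
#'
#' A planar hexagonal partition used for spatial balancing. `cell_spacing_m`
#' is the center-to-center distance of adjacent cells (1 km by default, the
#' standard balancing resolution); the origin is a cell center.
#'
#' @param cell_spacing_m center-to-center spacing of adjacent cells, meters.
#' @param origin planar coordinates of one cell center.
#' @param orientation `"flat_top"` or `"pointy_top"` hexagons.
#' @export
hex_grid <- function(cell_spacing_m = 1000, origin = c(0, 0),
                     orientation = c("flat_top", "pointy_top")) {
  if (!is_number(cell_spacing_m) || cell_spacing_m <= 0)
    stop_param("`cell_spacing_m` must be positive")
  structure(list(cell_spacing_m = cell_spacing_m,
                 origin = as.numeric(origin),
                 orientation = match.arg(orientation),
                 # circumradius R such that adjacent centers are spacing apart
                 size = cell_spacing_m / sqrt(3)),
            class = "hex_grid")
}

## axial coordinates (possibly fractional) of points
hex_axial_frac <- function(xy, grid) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  x <- xy[, 1] - grid$origin[1]
  y <- xy[, 2] - grid$origin[2]
  R <- grid$size
  if (grid$orientation == "flat_top") {
    q <- (2 / 3) * x / R
    r <- (-1 / 3 * x + sqrt(3) / 3 * y) / R
  } else {
    q <- (sqrt(3) / 3 * x - 1 / 3 * y) / R
    r <- (2 / 3) * y / R
  }
  cbind(q = q, r = r)
}

## standard cube rounding of fractional axial coordinates
hex_round <- function(qr) {
  q <- qr[, 1]; r <- qr[, 2]; s <- -q - r
  rq <- round(q); rr <- round(r); rs <- round(s)
  dq <- abs(rq - q); dr <- abs(rr - r); ds <- abs(rs - s)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  rq[fix_q] <- -rr[fix_q] - rs[fix_q]
  rr[fix_r] <- -rq[fix_r] - rs[fix_r]
  cbind(q = as.integer(rq), r = as.integer(rr))
}

#' Hexagonal cell index of planar points
#'
#' Maps each point to the index of the unique hexagonal cell containing it
#' (partition property: ties on edges resolve deterministically through cube
#' rounding).
#'
#' @param points two-column matrix/data frame of planar coordinates, or a
#'   records data frame with `x`,`y` columns.
#' @param grid a [hex_grid()].
#' @return character vector of cell keys `"q:r"` (axial coordinates), with
#'   the integer axial coordinates attached as attribute `axial`.
#' @export
hex_cell_of <- function(points, grid = hex_grid()) {
  stopifnot(inherits(grid, "hex_grid"))
  if (is.data.frame(points) && all(c("x", "y") %in% names(points)))
    points <- cbind(points$x, points$y)
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  if (any(!is.finite(points))) stop_param("coordinates must be finite")
  ax <- hex_round(hex_axial_frac(points, grid))
  keys <- paste0(ax[, 1], ":", ax[, 2])
  attr(keys, "axial") <- ax
  keys
}

#' Center coordinates of hexagonal cells
#'
#' @param axial integer matrix of axial coordinates `(q, r)`.
#' @param grid a [hex_grid()].
#' @return two-column matrix of cell-center coordinates.
#' @export
hex_cell_center <- function(axial, grid = hex_grid()) {
  axial <- matrix(as.numeric(axial), ncol = 2)
  R <- grid$size
  if (grid$orientation == "flat_top") {
    x <- R * 1.5 * axial[, 1]
    y <- R * sqrt(3) * (axial[, 2] + axial[, 1] / 2)
  } else {
    x <- R * sqrt(3) * (axial[, 1] + axial[, 2] / 2)
    y <- R * 1.5 * axial[, 2]
  }
  cbind(x + grid$origin[1], y + grid$origin[2])
}

#' Spatially balance records on a hexagonal grid
#'
#' Retains exactly one record per occupied hexagonal cell, selected
#' uniformly at random under `seed`. The selection depends only on the set
#' of record ids in each cell (candidates are ordered by id and cells
#' processed in sorted key order), so the result is invariant to the input
#' row order.
#'
#' @param records records data frame with `x`, `y`, `record_id`.
#' @param grid a [hex_grid()].
#' @param seed integer seed for the within-cell selection.
#' @return the retained records, in original row order.
#' @export
spatially_balance <- function(records, grid = hex_grid(), seed = 1) {
  if (nrow(records) == 0) return(records)
  keys <- hex_cell_of(records, grid)
  ids_by_cell <- split(records$record_id, keys)
  cells <- sort(names(ids_by_cell))
  chosen <- with_seed(seed, vapply(cells, function(cell) {
    ids <- sort(ids_by_cell[[cell]])
    ids[[max(1L, ceiling(runif(1) * length(ids)))]]
  }, character(1)))
  out <- records[records$record_id %in% chosen, , drop = FALSE]
  rownames(out) <- NULL
  out
}
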