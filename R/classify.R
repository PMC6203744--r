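#' Strategy features
#'
#' Quantitative descriptors of a swim path used by the rule cascade in
#' \code{\link{classify_strategy}}. Occupancy features (wall, annulus, inner
#' zone, platform proximity, previous-platform proximity, target quadrant)
#' are time-weighted sample fractions; the efficiency ratio and corridor
#' fraction are path-based; coverage is the fraction of pool-interior cells
#' of a 10 x 10 grid overlay that the path visits (a diagnostic, unused by
#' the default rules).
#'
#' Zone definitions: "wall" means within 8 cm of the pool wall; "annulus"
#' means a radial distance within 10 cm of the platform's orbit radius
#' (diameter/4); "inner" means inside the central disk of half the pool
#' radius; "proximity" means within 30 cm of the (previous) platform centre.
#'
#' @param traj a swim \code{trajectory}.
#' @param start,platform,previous_platform geometry overrides (cm); by
#'   default taken from the trial metadata.
#' @param wall_zone_cm,annulus_halfwidth_cm,prox_radius_cm zone parameters
#'   (defaults 8, 10, 30).
#' @return a \code{strategy_features} list.
#' @export
extract_features <- function(traj, start = NULL, platform = NULL,
                             previous_platform = NULL,
                             wall_zone_cm = 8, annulus_halfwidth_cm = 10,
                             prox_radius_cm = 30) {
  arena <- trajectory_arena(traj)
  if (is.null(start)) start <- trajectory_start_point(traj)
  if (is.null(platform)) platform <- trajectory_platform(traj)
  if (is.null(platform)) stop("no platform defined for this trial", call. = FALSE)
  if (is.null(previous_platform))
    previous_platform <- trajectory_platform(traj, previous = TRUE)
  R <- arena_radius(arena)
  n <- nrow(traj)
  # trapezoidal dwell weights: each sample owns half its adjacent intervals
  dts <- diff(traj$t)
  w <- c(dts / 2, 0) + c(0, dts / 2)
  r <- sqrt(traj$x^2 + traj$y^2)
  tw <- function(flag) sum(w[flag]) / sum(w)
  d_plat <- sqrt((traj$x - platform[1])^2 + (traj$y - platform[2])^2)
  feats <- list(
    efficiency_ratio = path_efficiency_ratio(traj, start, platform),
    corridor_fraction = corridor_percent_path(traj, start, platform) / 100,
    wall_fraction = tw(R - r < wall_zone_cm),
    annulus_fraction = tw(abs(r - arena$platform_orbit_cm) <= annulus_halfwidth_cm),
    inner_fraction = tw(r < R / 2),
    target_prox_fraction = tw(d_plat <= prox_radius_cm),
    prev_prox_fraction = if (is.null(previous_platform)) NA_real_ else {
      d_prev <- sqrt((traj$x - previous_platform[1])^2 +
                     (traj$y - previous_platform[2])^2)
      tw(d_prev <= prox_radius_cm)
    },
    target_quadrant_fraction = {
      qs <- quadrant_of(cbind(traj$x, traj$y), arena, tolerance_cm = Inf)
      qp <- quadrant_of(platform, arena)
      tw(qs == qp)
    },
    coverage = {
      edges <- seq(-R, R, length.out = 11L)
      cx <- (edges[-11] + edges[-1]) / 2
      ctr <- expand.grid(x = cx, y = cx)
      interior <- sqrt(ctr$x^2 + ctr$y^2) <= R
      ix <- pmin(10L, pmax(1L, findInterval(traj$x, edges, rightmost.closed = TRUE)))
      iy <- pmin(10L, pmax(1L, findInterval(traj$y, edges, rightmost.closed = TRUE)))
      visited <- unique((iy - 1L) * 10L + ix)
      cell_int <- which(interior)
      length(intersect(visited, cell_int)) / length(cell_int)
    })
  structure(feats, class = "strategy_features")
}

#' Classification thresholds for the strategy rule cascade
#'
#' The ordered cascade tests spatial rules first, so near-goal behaviour
#' dominates ambiguous paths, and perseverance before the non-spatial rules
#' so focal search at the old goal is not absorbed by scanning.
#'
#' @param dsw_efficiency_max,dsw_corridor_min direct swim: efficiency ratio
#'   at most 1.3 and corridor fraction at least 0.8.
#' @param dse_corridor_min directed search: corridor fraction at least 0.7.
#' @param fs_prox_min focal search: at least half the trial within 30 cm of
#'   the platform.
#' @param p_prev_prox_min perseverance: at least half the trial within
#'   30 cm of the previous platform position.
#' @param t_wall_min thigmotaxis: wall fraction at least 0.65.
#' @param c_annulus_min chaining: annulus fraction at least 0.7.
#' @param s_inner_min scanning: inner fraction at least 0.6.
#' @return named list of thresholds.
#' @export
strategy_thresholds <- function(dsw_efficiency_max = 1.3,
                                dsw_corridor_min = 0.8,
                                dse_corridor_min = 0.7,
                                fs_prox_min = 0.5,
                                p_prev_prox_min = 0.5,
                                t_wall_min = 0.65,
                                c_annulus_min = 0.7,
                                s_inner_min = 0.6) {
  list(dsw_efficiency_max = dsw_efficiency_max,
       dsw_corridor_min = dsw_corridor_min,
       dse_corridor_min = dse_corridor_min,
       fs_prox_min = fs_prox_min,
       p_prev_prox_min = p_prev_prox_min,
       t_wall_min = t_wall_min,
       c_annulus_min = c_annulus_min,
       s_inner_min = s_inner_min)
}

#' Classify a swim path into one of eight search strategies
#'
#' Deterministic first-match rule cascade over
#' \code{\link{extract_features}} output: (1) direct swim (DSw), (2)
#' directed search (DSe), (3) focal search (FS), (4) perseverance (P), (5)
#' thigmotaxis (T), (6) chaining (C), (7) scanning (S), (8) random swim
#' (RS, the catch-all). Every feature vector receives exactly one label.
#' If no previous platform position is known, the perseverance rule is
#' skipped.
#'
#' @param features a \code{strategy_features}, or a swim \code{trajectory}
#'   (features are then extracted first).
#' @param thresholds see \code{\link{strategy_thresholds}}.
#' @return a one-row tibble with \code{label} and \code{category}.
#' @export
classify_strategy <- function(features, thresholds = strategy_thresholds()) {
  if (inherits(features, "trajectory")) features <- extract_features(features)
  stopifnot(inherits(features, "strategy_features"))
  th <- thresholds
  f <- features
  label <-
    if (f$efficiency_ratio <= th$dsw_efficiency_max &&
        f$corridor_fraction >= th$dsw_corridor_min) "DSw"
    else if (f$corridor_fraction >= th$dse_corridor_min) "DSe"
    else if (f$target_prox_fraction >= th$fs_prox_min) "FS"
    else if (!is.na(f$prev_prox_fraction) &&
             f$prev_prox_fraction >= th$p_prev_prox_min) "P"
    else if (f$wall_fraction >= th$t_wall_min) "T"
    else if (f$annulus_fraction >= th$c_annulus_min) "C"
    else if (f$inner_fraction >= th$s_inner_min) "S"
    else "RS"
  tibble::tibble(label = label, category = strategy_category(label))
}

#' Classify every trial of a cohort
#'
#' @param cohort tibble with a \code{trajectory} list-column.
#' @param thresholds see \code{\link{strategy_thresholds}}.
#' @return the cohort tibble with \code{label} and \code{category} columns
#'   (trajectories retained).
#' @export
classify_cohort <- function(cohort, thresholds = strategy_thresholds()) {
  labs <- dplyr::bind_rows(lapply(cohort$trajectory, classify_strategy,
                                  thresholds = thresholds))
  dplyr::bind_cols(cohort, labs)
}

#' Spatial-strategy percentage and improvement rate
#'
#' \code{spatial_percent} is the percentage of trials classified into any
#' spatial strategy (DSe, FS, DSw, P). The improvement rate is the
#' percentage-point difference between the last and first training days'
#' spatial-strategy use; it is negative when spatial use declines.
#'
#' @param labels character vector of strategy labels.
#' @return \code{spatial_percent}: percentage in [0, 100].
#' @examples
#' spatial_percent(c("DSw", "T", "FS", "RS"))  # 50
#' improvement_rate(44, 87)                    # 43
#' @export
spatial_percent <- function(labels) {
  if (!length(labels)) stop("no labels", call. = FALSE)
  100 * mean(is_spatial_strategy(labels))
}

#' @rdname spatial_percent
#' @param day_first_percent,day_last_percent spatial-strategy percentages
#'   on the first and last training days.
#' @export
improvement_rate <- function(day_first_percent, day_last_percent) {
  day_last_percent - day_first_percent
}

#' Per-day strategy summary
#'
#' Counts of each label per day plus the per-day spatial percentage and the
#' first-to-last-day improvement rate.
#'
#' @param labels character vector of labels.
#' @param day integer vector of training days (same length).
#' @return a \code{strategy_summary}: list with \code{counts} (day x label
#'   table), \code{spatial_percent_by_day}, and
#'   \code{improvement_rate_percent}.
#' @export
strategy_summary <- function(labels, day) {
  stopifnot(length(labels) == length(day))
  days <- sort(unique(day))
  counts <- table(factor(day, levels = days),
                  factor(labels, levels = strategy_levels()))
  sp <- vapply(days, function(d) spatial_percent(labels[day == d]), numeric(1))
  names(sp) <- days
  structure(list(counts = counts,
                 spatial_percent_by_day = sp,
                 improvement_rate_percent =
                   improvement_rate(sp[[1]], sp[[length(sp)]])),
            class = "strategy_summary")
}

#' @export
print.strategy_summary <- function(x, ...) {
  cat("<strategy_summary>\n")
  print(x$counts)
  cat("spatial % by day:",
      paste(sprintf("%s: %.1f", names(x$spatial_percent_by_day),
                    x$spatial_percent_by_day), collapse = ", "), "\n")
  cat(sprintf("improvement rate: %.1f percentage points\n",
              x$improvement_rate_percent))
  invisible(x)
}
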