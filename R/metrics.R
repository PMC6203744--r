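#' Swim and locomotion metrics
#'
#' Per-trial measures computed from a \code{\link{trajectory}}: total path
#' length, mean and time-binned speed, escape latency, the corridor-based
#' swim error index, the path efficiency ratio, probe-trial quadrant
#' occupancy, central-zone path length and stop counts. All are exact
#' polyline computations (segments are split analytically at zone and
#' corridor boundaries), which makes them robust to the tracker's sampling
#' rate.
#'
#' @param traj a \code{trajectory}.
#' @return \code{path_length}: metres. \code{mean_speed}: m/s.
#' @name trajectory_metrics
NULL

seg_lengths <- function(traj) sqrt(diff(traj$x)^2 + diff(traj$y)^2)

#' @rdname trajectory_metrics
#' @export
path_length <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sum(seg_lengths(traj)) / 100
}

#' @rdname trajectory_metrics
#' @export
mean_speed <- function(traj) {
  path_length(traj) / (traj$t[nrow(traj)] - traj$t[1])
}

#' Time-binned speed
#'
#' Splits the session into consecutive bins of \code{bin_s} seconds and
#' returns the mean speed in each. The session duration must divide into
#' whole bins (the 20-min open-field protocol gives four exact 5-min bins);
#' a partial final bin is an error.
#'
#' @param traj a \code{trajectory}.
#' @param bin_s bin width in seconds, default 300.
#' @return numeric vector of per-bin speeds (m/s).
#' @export
binned_speed <- function(traj, bin_s = 300) {
  dur <- traj$t[nrow(traj)] - traj$t[1]
  nb <- dur / bin_s
  if (abs(nb - round(nb)) > 1e-6)
    stop(sprintf("duration %.1f s is not a whole number of %g-s bins", dur, bin_s),
         call. = FALSE)
  nb <- round(nb)
  cum <- c(0, cumsum(seg_lengths(traj)))
  bounds <- traj$t[1] + bin_s * (0:nb)
  # arc length is piecewise linear in time (constant speed per segment)
  cl <- stats::approx(traj$t, cum, xout = bounds)$y
  diff(cl) / 100 / bin_s
}

#' Escape latency
#'
#' Time from release until the first platform contact (centre-to-centre
#' distance at most the platform radius), with the crossing time solved
#' exactly within the straddling segment. Trials that never contact the
#' platform return the trial cap with attribute \code{censored = TRUE}.
#'
#' @param traj a swim \code{trajectory}.
#' @param platform platform centre (cm); defaults from the trial metadata.
#' @param platform_radius_cm contact radius; defaults from the arena.
#' @param cap_s censoring value for no-contact trials, default 60.
#' @return latency in seconds with a logical \code{censored} attribute.
#' @export
latency <- function(traj, platform = NULL, platform_radius_cm = NULL,
                    cap_s = 60) {
  if (is.null(platform)) platform <- trajectory_platform(traj)
  if (is.null(platform)) stop("no platform defined for this trial", call. = FALSE)
  if (is.null(platform_radius_cm))
    platform_radius_cm <- trajectory_arena(traj)$platform_radius_cm
  dx <- traj$x - platform[1]; dy <- traj$y - platform[2]
  d2 <- dx^2 + dy^2
  # tolerate rounding for paths truncated exactly at the platform edge
  r2 <- platform_radius_cm^2 * (1 + 1e-12) + 1e-9
  n <- nrow(traj)
  if (d2[1] <= r2) {
    out <- 0; attr(out, "censored") <- FALSE
    return(out)
  }
  for (i in seq_len(n - 1)) {
    if (d2[i + 1] <= r2) {
      # solve |p_i + s (p_{i+1} - p_i) - c|^2 = r^2 for s in [0, 1]
      ax <- dx[i]; ay <- dy[i]
      bx <- dx[i + 1] - dx[i]; by <- dy[i + 1] - dy[i]
      A <- bx^2 + by^2; B <- 2 * (ax * bx + ay * by); C <- ax^2 + ay^2 - r2
      s <- if (A == 0) 0 else (-B - sqrt(max(0, B^2 - 4 * A * C))) / (2 * A)
      s <- min(1, max(0, s))
      out <- traj$t[i] + s * (traj$t[i + 1] - traj$t[i]) - traj$t[1]
      attr(out, "censored") <- FALSE
      return(out)
    }
  }
  out <- cap_s
  attr(out, "censored") <- TRUE
  out
}

# Clip the segment p0 -> p1 to the axis-aligned box [0, L] x [-h, h] in the
# corridor frame; returns the in-box parameter interval via Liang-Barsky.
clip_fraction_box <- function(u0, v0, u1, v1, L, h) {
  du <- u1 - u0; dv <- v1 - v0
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    p <- c(-du, du, -dv, dv)[k]
    q <- c(u0 - 0, L - u0, v0 + h, h - v0)[k]
    if (p == 0) {
      if (q < 0) return(0)
    } else {
      r <- q / p
      if (p < 0) { if (r > t1) return(0); if (r > t0) t0 <- r }
      else       { if (r < t0) return(0); if (r < t1) t1 <- r }
    }
  }
  max(0, t1 - t0)
}

#' Corridor percent path (swim error index)
#'
#' Percentage of the swim path lying inside the 20-cm-wide straight corridor
#' from the release point to the platform centre. Segments are clipped
#' analytically at the corridor boundary, so the result is exact for the
#' recorded polyline. Path outside the corridor is the swim "error"; the
#' in-corridor and off-corridor percentages sum to 100 exactly. A
#' time-weighted variant is available via \code{weight = "time"}.
#'
#' @param traj a swim \code{trajectory}.
#' @param start,platform corridor endpoints (cm); default from metadata.
#' @param width_cm full corridor width, default 20.
#' @param weight \code{"path"} (length-weighted, default) or \code{"time"}.
#' @return percentage in [0, 100].
#' @export
corridor_percent_path <- function(traj, start = NULL, platform = NULL,
                                  width_cm = 20, weight = c("path", "time")) {
  weight <- match.arg(weight)
  if (is.null(start)) start <- trajectory_start_point(traj)
  if (is.null(platform)) platform <- trajectory_platform(traj)
  if (is.null(platform)) stop("no platform defined for this trial", call. = FALSE)
  d <- platform - start
  L <- sqrt(sum(d^2))
  if (L == 0) stop("degenerate corridor: start equals platform centre", call. = FALSE)
  u_ax <- d / L
  ucoord <- (traj$x - start[1]) * u_ax[1] + (traj$y - start[2]) * u_ax[2]
  vcoord <- -(traj$x - start[1]) * u_ax[2] + (traj$y - start[2]) * u_ax[1]
  n <- nrow(traj)
  fr <- vapply(seq_len(n - 1), function(i)
    clip_fraction_box(ucoord[i], vcoord[i], ucoord[i + 1], vcoord[i + 1],
                      L, width_cm / 2), numeric(1))
  w <- if (weight == "path") seg_lengths(traj) else diff(traj$t)
  tot <- sum(w)
  if (tot == 0) stop("zero-length path", call. = FALSE)
  100 * sum(fr * w) / tot
}

#' Path efficiency ratio
#'
#' Actual swim path length divided by the direct distance from the release
#' point to the platform (the straight-line distance to the platform edge,
#' i.e. the shortest swim that achieves contact). A perfectly direct swim
#' scores 1; larger values mean less efficient search.
#'
#' @inheritParams corridor_percent_path
#' @param platform_radius_cm platform radius subtracted from the
#'   centre-to-centre distance; defaults from the arena. Use 0 to measure
#'   against the platform centre.
#' @return dimensionless ratio \eqn{\ge 1} for platform-terminated paths.
#' @export
path_efficiency_ratio <- function(traj, start = NULL, platform = NULL,
                                  platform_radius_cm = NULL) {
  if (is.null(start)) start <- trajectory_start_point(traj)
  if (is.null(platform)) platform <- trajectory_platform(traj)
  if (is.null(platform)) stop("no platform defined for this trial", call. = FALSE)
  if (is.null(platform_radius_cm))
    platform_radius_cm <- trajectory_arena(traj)$platform_radius_cm
  direct <- sqrt(sum((platform - start)^2)) - platform_radius_cm
  if (direct <= 0) stop("start point lies on the platform", call. = FALSE)
  sum(seg_lengths(traj)) / direct
}

#' Probe-trial quadrant occupancy
#'
#' Time-weighted percentage of the trial spent in each pool quadrant,
#' computed exactly: every polyline segment is split at its crossings of the
#' two quadrant axes and each piece's dwell time is assigned by the
#' half-open angular convention of \code{\link{quadrant_of}}. The four
#' percentages sum to 100.
#'
#' @param traj a \code{trajectory} in a circular arena.
#' @return numeric vector of four percentages (quadrants 1..4).
#' @export
quadrant_occupancy <- function(traj) {
  arena <- trajectory_arena(traj)
  occ <- numeric(4)
  n <- nrow(traj)
  for (i in seq_len(n - 1)) {
    p0 <- c(traj$x[i], traj$y[i]); p1 <- c(traj$x[i + 1], traj$y[i + 1])
    dt <- traj$t[i + 1] - traj$t[i]
    ss <- c(0, 1)
    dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
    if (dx != 0) { s <- -p0[1] / dx; if (s > 0 && s < 1) ss <- c(ss, s) }
    if (dy != 0) { s <- -p0[2] / dy; if (s > 0 && s < 1) ss <- c(ss, s) }
    ss <- sort(ss)
    for (k in seq_len(length(ss) - 1)) {
      mid <- (ss[k] + ss[k + 1]) / 2
      q <- quadrant_of(p0 + mid * c(dx, dy), arena, tolerance_cm = Inf)
      occ[q] <- occ[q] + dt * (ss[k + 1] - ss[k])
    }
  }
  tot <- sum(occ)
  if (tot == 0) stop("zero-duration trajectory", call. = FALSE)
  100 * occ / tot
}

# length (cm) of the polyline restricted to the disk |p - c| <= r
polyline_length_in_disk <- function(traj, center, r) {
  dx0 <- traj$x - center[1]; dy0 <- traj$y - center[2]
  n <- nrow(traj)
  total <- 0
  for (i in seq_len(n - 1)) {
    ax <- dx0[i]; ay <- dy0[i]
    bx <- dx0[i + 1] - dx0[i]; by <- dy0[i + 1] - dy0[i]
    A <- bx^2 + by^2
    if (A == 0) next
    B <- 2 * (ax * bx + ay * by); C <- ax^2 + ay^2 - r^2
    disc <- B^2 - 4 * A * C
    if (disc <= 0) next  # misses the disk (or tangent: zero length inside)
    s_lo <- (-B - sqrt(disc)) / (2 * A); s_hi <- (-B + sqrt(disc)) / (2 * A)
    ov <- min(1, s_hi) - max(0, s_lo)
    if (ov > 0) total <- total + ov * sqrt(A)
  }
  total
}

#' Central-zone path length
#'
#' Path length (m) restricted to the concentric central zone of the open
#' field (diameter 52 cm by default). Segments are clipped exactly at the
#' zone boundary.
#'
#' @param traj an open-field \code{trajectory}.
#' @param zone_diameter_cm zone diameter; defaults from the arena.
#' @return metres.
#' @export
central_zone_path <- function(traj, zone_diameter_cm = NULL) {
  arena <- trajectory_arena(traj)
  if (is.null(zone_diameter_cm))
    zone_diameter_cm <- arena$central_zone_diameter_cm
  if (is.null(zone_diameter_cm))
    stop("no central zone defined for this arena", call. = FALSE)
  polyline_length_in_disk(traj, arena$center, zone_diameter_cm / 2) / 100
}

#' Count stops
#'
#' Number of maximal intervals during which the smoothed instantaneous
#' speed stays below \code{speed_thresh_cmps} for at least
#' \code{min_dwell_s}. Speeds are per-sample displacements smoothed with a
#' centred moving average of width \code{smooth_window_s}.
#'
#' @param traj a \code{trajectory}.
#' @param speed_thresh_cmps stop threshold in cm/s, default 2.
#' @param min_dwell_s minimum stop duration in seconds, default 1.
#' @param smooth_window_s moving-average window, default 0.5.
#' @return integer stop count.
#' @export
count_stops <- function(traj, speed_thresh_cmps = 2, min_dwell_s = 1,
                        smooth_window_s = 0.5) {
  dts <- diff(traj$t)
  sp <- seg_lengths(traj) / dts
  k <- max(1L, round(smooth_window_s / stats::median(dts)))
  if (k > 1) {
    kern <- rep(1 / k, k)
    sp <- stats::filter(sp, kern, sides = 2)
    sp[is.na(sp)] <- seg_lengths(traj)[is.na(sp)] / dts[is.na(sp)]
    sp <- as.numeric(sp)
  }
  low <- sp < speed_thresh_cmps
  n_stops <- 0L
  i <- 1L
  while (i <= length(low)) {
    if (low[i]) {
      j <- i
      while (j < length(low) && low[j + 1]) j <- j + 1
      if (sum(dts[i:j]) >= min_dwell_s) n_stops <- n_stops + 1L
      i <- j + 1L
    } else i <- i + 1L
  }
  n_stops
}

#' Extract strides from a tracked hindlimb series
#'
#' Detects stance phases as near-zero-velocity plateaus in the tracked
#' hindlimb position along the beam, then measures each stride as the
#' distance between the takeoff position of one stance and the landing
#' position of the next. Latency is the duration of the series.
#'
#' @param series data.frame with columns \code{t} (s) and \code{x} (cm along
#'   the beam), e.g. from \code{\link{simulate_stride_series}}.
#' @param stance_speed_thresh_cmps plateau speed threshold, default 5.
#' @param min_stance_s minimum plateau duration, default 0.12.
#' @param smooth_window_s speed smoothing window, default 0.05.
#' @param n_slips externally scored hind-foot slips, passed through.
#' @return a \code{beam_trial_result}: list with \code{stride_lengths_cm},
#'   \code{mean_stride_cm}, \code{latency_s}, \code{n_strides},
#'   \code{n_slips}.
#' @export
extract_strides <- function(series, stance_speed_thresh_cmps = 5,
                            min_stance_s = 0.12, smooth_window_s = 0.05,
                            n_slips = NA_integer_) {
  stopifnot(is.data.frame(series), all(c("t", "x") %in% names(series)))
  if (nrow(series) < 3) stop("series too short", call. = FALSE)
  dts <- diff(series$t)
  sp <- abs(diff(series$x)) / dts
  k <- max(1L, round(smooth_window_s / stats::median(dts)))
  if (k > 1) {
    raw <- sp
    sp <- as.numeric(stats::filter(sp, rep(1 / k, k), sides = 2))
    sp[is.na(sp)] <- raw[is.na(sp)]
  }
  low <- sp < stance_speed_thresh_cmps
  stance_pos <- numeric(0)
  i <- 1L
  while (i <= length(low)) {
    if (low[i]) {
      j <- i
      while (j < length(low) && low[j + 1]) j <- j + 1
      if (sum(dts[i:j]) >= min_stance_s)
        stance_pos <- c(stance_pos, mean(series$x[i:(j + 1)]))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(stance_pos) < 2)
    stop("fewer than 2 stance phases detected (no plateaus in the series)",
         call. = FALSE)
  strides <- diff(stance_pos)
  if (any(strides <= 0))
    stop("non-monotone progression along the beam", call. = FALSE)
  structure(list(stride_lengths_cm = strides,
                 mean_stride_cm = mean(strides),
                 latency_s = series$t[nrow(series)] - series$t[1],
                 n_strides = length(strides),
                 n_slips = n_slips),
            class = "beam_trial_result")
}

#' @export
print.beam_trial_result <- function(x, ...) {
  cat(sprintf("<beam trial: %d strides, mean %.2f cm, latency %.2f s>\n",
              x$n_strides, x$mean_stride_cm, x$latency_s))
  invisible(x)
}

#' Per-trial metric table for a swim cohort
#'
#' Computes the standard swim measures (latency with censoring, path
#' length, mean speed, corridor percent path, path efficiency ratio) for
#' every trial of a simulated or assembled cohort table.
#'
#' @param cohort tibble with a \code{trajectory} list-column, e.g. from
#'   \code{\link{simulate_cohort}}.
#' @return the cohort tibble (without trajectories) with metric columns
#'   appended.
#' @export
cohort_metrics <- function(cohort) {
  stopifnot("trajectory" %in% names(cohort))
  met <- lapply(cohort$trajectory, function(tr) {
    lat <- latency(tr)
    tibble::tibble(latency_s = as.numeric(lat),
                   censored = attr(lat, "censored"),
                   path_length_m = path_length(tr),
                   mean_speed_mps = mean_speed(tr),
                   corridor_percent = corridor_percent_path(tr),
                   efficiency_ratio = path_efficiency_ratio(tr))
  })
  dplyr::bind_cols(dplyr::select(cohort, -"trajectory"),
                   dplyr::bind_rows(met))
}
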