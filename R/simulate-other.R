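#' Open-field exploration speed presets (m/s)
#'
#' Mean locomotion speeds for the two generator presets, derived from the
#' reported 20-min open-field path lengths of the two strains
#' (143.69 m and 280.5 m over 1200 s): control-like 0.12 m/s and
#' hyperactive (BTBR-like) 0.23 m/s.
#' @return named numeric vector.
#' @export
open_field_speed_presets <- function() c(control = 0.12, hyperactive = 0.23)

#' Simulate open-field exploration
#'
#' Bounded correlated random walk in the circular open field with an
#' explicit Markov pause process: while moving, a pause begins with hazard
#' \code{pause_rate_hz}; each pause lasts \code{pause_dwell_min_s} plus an
#' exponential excess, during which the animal is stationary. The number of
#' emitted pauses is returned as ground truth, so stop-counting can be
#' validated exactly. A short refractory period after each pause keeps
#' consecutive pauses from fusing into one stationary bout.
#'
#' @param duration_s session length in seconds, default 1200 (20 min).
#' @param speed_mps locomotion speed while moving (m/s).
#' @param pause_rate_hz pause onset hazard while moving (1/s), default 0.03.
#' @param pause_dwell_min_s minimum pause duration, default 2.
#' @param pause_dwell_mean_extra_s mean of the exponential excess dwell,
#'   default 1.
#' @param heading_noise_sd per-step heading noise (radians), default 0.4.
#' @param dt_s sampling interval, default 0.1.
#' @param arena an open-field \code{arena_geometry}.
#' @param seed integer seed or NULL.
#' @param subject,group metadata.
#' @return a \code{trajectory} with attribute \code{n_true_stops}.
#' @export
simulate_open_field <- function(duration_s = 1200,
                                speed_mps = open_field_speed_presets()[["control"]],
                                pause_rate_hz = 0.03,
                                pause_dwell_min_s = 2,
                                pause_dwell_mean_extra_s = 1,
                                heading_noise_sd = 0.4, dt_s = 0.1,
                                arena = open_field_arena(), seed = NULL,
                                subject = NA_character_, group = NA_character_) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (speed_mps <= 0) stop("speed_mps must be > 0", call. = FALSE)
  run <- function() {
    R <- arena_radius(arena)
    n <- ceiling(duration_s / dt_s) + 1L
    xs <- numeric(n); ys <- numeric(n)
    # release in the central zone, slightly off-centre
    p <- c(stats::runif(1, -5, 5), stats::runif(1, -5, 5))
    th <- stats::runif(1, -pi, pi)
    xs[1] <- p[1]; ys[1] <- p[2]
    kappa <- if (heading_noise_sd > 0) 1 / heading_noise_sd^2 else Inf
    step_cm <- speed_mps * 100 * dt_s
    pause_left <- 0
    refractory_left <- 0
    n_stops <- 0L
    for (i in 2:n) {
      if (pause_left > 0) {
        pause_left <- pause_left - dt_s
      } else {
        if (refractory_left > 0) refractory_left <- refractory_left - dt_s
        if (refractory_left <= 0 && stats::runif(1) < pause_rate_hz * dt_s) {
          n_stops <- n_stops + 1L
          pause_left <- pause_dwell_min_s +
            stats::rexp(1, 1 / pause_dwell_mean_extra_s) - dt_s
          refractory_left <- 2
        } else {
          th <- if (is.finite(kappa)) rvonmises1(th, kappa) else th
          v <- c(cos(th), sin(th))
          q <- p + step_cm * v
          rq <- sqrt(sum(q^2))
          if (rq > R - 1.5) {
            nrm <- q / rq
            v <- v - 2 * sum(v * nrm) * nrm
            th <- atan2(v[2], v[1])
            q <- p + step_cm * v
            rq <- sqrt(sum(q^2))
            if (rq > R - 1.5) q <- q * (R - 1.5) / rq
          }
          p <- q
        }
      }
      xs[i] <- p[1]; ys[i] <- p[2]
    }
    tr <- trajectory(seq(0, by = dt_s, length.out = n), xs, ys, arena = arena,
                     subject = subject, group = group,
                     max_duration_s = duration_s + dt_s)
    attr(tr, "n_true_stops") <- n_stops
    tr
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

#' Simulate a tracked hindlimb series on the balance beam
#'
#' One-dimensional progression of the tracked left-hindlimb point along the
#' beam: stationary stance plateaus separated by smooth swing phases. Stride
#' lengths are drawn from a normal distribution (truncated at 1 cm) and the
#' series stops early if the next landing would leave the beam, so the
#' cumulative stride sum never exceeds the beam length. The drawn strides
#' are returned as ground truth.
#'
#' @param n_strides number of strides requested (> 0).
#' @param stride_mean_cm,stride_sd_cm stride-length distribution (cm).
#' @param stance_s,swing_s stance and swing durations (s), defaults 0.25/0.2.
#' @param dt_s frame interval, default 1/60 (60 fps video).
#' @param noise_cm tracking jitter SD added to positions, default 0.02.
#' @param beam a beam \code{arena_geometry}.
#' @param seed integer seed or NULL.
#' @return a data.frame with columns \code{t, x} (s, cm along the beam) and
#'   attributes \code{true_strides_cm} and \code{landing_positions_cm}.
#' @export
simulate_stride_series <- function(n_strides, stride_mean_cm = 8,
                                   stride_sd_cm = 0.5,
                                   stance_s = 0.25, swing_s = 0.2,
                                   dt_s = 1 / 60, noise_cm = 0.02,
                                   beam = beam_arena(), seed = NULL) {
  if (n_strides < 1) stop("n_strides must be >= 1", call. = FALSE)
  run <- function() {
    start_x <- 2
    max_x <- beam$beam_length_cm - 2
    strides <- numeric(0)
    pos <- start_x
    for (k in seq_len(n_strides)) {
      s <- stats::rnorm(1, stride_mean_cm, stride_sd_cm)
      while (s < 1) s <- stats::rnorm(1, stride_mean_cm, stride_sd_cm)
      if (pos[length(pos)] + s > max_x) break
      strides <- c(strides, s)
      pos <- c(pos, pos[length(pos)] + s)
    }
    if (!length(strides))
      stop("beam too short for a single stride of the requested length",
           call. = FALSE)
    t <- numeric(0); x <- numeric(0)
    now <- 0
    for (k in seq_along(pos)) {
      # stance plateau
      ts <- seq(now, now + stance_s, by = dt_s)
      t <- c(t, ts); x <- c(x, rep(pos[k], length(ts)))
      now <- ts[length(ts)] + dt_s
      if (k < length(pos)) {
        # swing: cosine-eased displacement to the next landing
        ts <- seq(now, now + swing_s, by = dt_s)
        frac <- (1 - cos(pi * (ts - now) / swing_s)) / 2
        t <- c(t, ts); x <- c(x, pos[k] + frac * (pos[k + 1] - pos[k]))
        now <- ts[length(ts)] + dt_s
      }
    }
    x <- x + stats::rnorm(length(x), 0, noise_cm)
    out <- data.frame(t = t, x = x)
    attr(out, "true_strides_cm") <- strides
    attr(out, "landing_positions_cm") <- pos
    attr(out, "beam") <- beam
    out
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

#' Simulate a Nissl-like section image with known cell count
#'
#' Dark disks ("cells") on a light background. Disk grey levels fall inside
#' the detection band used by the particle counter (90-180 on the 8-bit
#' scale) and the background lies above it. Optionally, touching pairs of
#' disks are placed (centres closer than the sum of radii) so that watershed
#' separation can be exercised: without it each pair fuses into one
#' connected component.
#'
#' @param n_cells number of isolated cells.
#' @param n_touching_pairs number of touching pairs (each adds 2 cells).
#' @param radius_px range of disk radii in pixels, default c(4, 7).
#' @param intensity_range grey-level range for disks, default c(100, 170).
#' @param background background grey level, default 230.
#' @param size image size (rows, cols), default c(256, 256).
#' @param seed integer seed or NULL.
#' @return a list with \code{image} (numeric matrix, 0-255 grey levels),
#'   \code{count} (ground-truth cell count), \code{centers}, \code{radii},
#'   and \code{pair_id} (NA for singletons).
#' @export
simulate_section_image <- function(n_cells, n_touching_pairs = 0,
                                   radius_px = c(4, 7),
                                   intensity_range = c(100, 170),
                                   background = 230, size = c(256, 256),
                                   seed = NULL) {
  stopifnot(n_cells >= 0, n_touching_pairs >= 0)
  run <- function() {
    img <- matrix(background, size[1], size[2])
    centers <- matrix(numeric(0), ncol = 2)
    radii <- numeric(0)
    pair_id <- integer(0)
    rmax <- radius_px[2]
    place <- function(r, near = NULL, gap = 4) {
      # rejection-sample a centre keeping `gap` px clearance from all placed
      # disks (or touching `near` when given)
      for (attempt in 1:2000) {
        if (is.null(near)) {
          c_new <- c(stats::runif(1, rmax + 3, size[1] - rmax - 3),
                     stats::runif(1, rmax + 3, size[2] - rmax - 3))
        } else {
          a <- stats::runif(1, 0, 2 * pi)
          d <- near$r + r - 2  # slight overlap: guaranteed merged mask
          c_new <- near$c + d * c(cos(a), sin(a))
          if (any(c_new < rmax + 3) || c_new[1] > size[1] - rmax - 3 ||
              c_new[2] > size[2] - rmax - 3) next
        }
        ok <- TRUE
        if (nrow(centers)) {
          dd <- sqrt((centers[, 1] - c_new[1])^2 + (centers[, 2] - c_new[2])^2)
          sep <- radii + r + gap
          if (!is.null(near)) {
            # the partner is allowed to touch; everyone else must keep clear
            keep <- dd < sep
            keep[nrow(centers)] <- dd[nrow(centers)] < near$r + r - 3
            ok <- !any(keep)
          } else ok <- all(dd >= sep)
        }
        if (ok) return(c_new)
      }
      stop("could not place all cells; reduce n_cells or enlarge the image",
           call. = FALSE)
    }
    add_disk <- function(ctr, r) {
      val <- stats::runif(1, intensity_range[1], intensity_range[2])
      i0 <- max(1, floor(ctr[1] - r)); i1 <- min(size[1], ceiling(ctr[1] + r))
      j0 <- max(1, floor(ctr[2] - r)); j1 <- min(size[2], ceiling(ctr[2] + r))
      for (i in i0:i1) for (j in j0:j1)
        if ((i - ctr[1])^2 + (j - ctr[2])^2 <= r^2) img[i, j] <<- val
    }
    for (k in seq_len(n_cells)) {
      r <- stats::runif(1, radius_px[1], radius_px[2])
      ctr <- place(r)
      centers <- rbind(centers, ctr); radii <- c(radii, r)
      pair_id <- c(pair_id, NA_integer_)
      add_disk(ctr, r)
    }
    for (k in seq_len(n_touching_pairs)) {
      r1 <- stats::runif(1, radius_px[1], radius_px[2])
      c1 <- place(r1)
      centers <- rbind(centers, c1); radii <- c(radii, r1)
      pair_id <- c(pair_id, k)
      r2 <- stats::runif(1, radius_px[1], radius_px[2])
      c2 <- place(r2, near = list(c = c1, r = r1))
      centers <- rbind(centers, c2); radii <- c(radii, r2)
      pair_id <- c(pair_id, k)
      add_disk(c1, r1); add_disk(c2, r2)
    }
    list(image = img, count = as.integer(n_cells + 2L * n_touching_pairs),
         centers = centers, radii = radii, pair_id = pair_id)
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}
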