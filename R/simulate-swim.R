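#' Swim-trial simulation configuration
#'
#' Configuration for the strategy-conditioned swim-path generator. Paths are
#' correlated-heading walks: at each time step the animal's heading is the
#' strategy's steering direction perturbed by von Mises noise, and the
#' animal advances at constant speed. Strategy-specific steering rules
#' produce the eight archetypes: wall-following (T), ballistic wandering
#' (RS), inner-zone scanning (S), orbiting at the platform's radial distance
#' (C), weaving along the start-platform corridor (DSe), direct approach
#' followed by localized search near the platform (FS), straight goal
#' approach (DSw), and focal search at the previously learned platform
#' location (P).
#'
#' Speed presets follow the two strain means reported for swim speed:
#' 0.217 m/s (control-like) and 0.314 m/s (BTBR-like); see
#' \code{\link{swim_speed_presets}}.
#'
#' @param strategy one of \code{strategy_levels()}.
#' @param arena a pool \code{arena_geometry}.
#' @param speed_mps swim speed in m/s (> 0).
#' @param heading_noise_sd per-step heading noise in radians (von Mises with
#'   concentration \code{1/sd^2}; 0 = deterministic archetype).
#' @param dt_s sampling interval in seconds, default 0.1.
#' @param max_duration_s trial cap, default (and maximum) 60 s.
#' @return a \code{swim_sim_config} list.
#' @export
swim_sim_config <- function(strategy, arena = pool_arena(),
                            speed_mps = 0.22, heading_noise_sd = 0.3,
                            dt_s = 0.1, max_duration_s = 60) {
  strategy <- match.arg(strategy, strategy_levels())
  if (speed_mps <= 0) stop("speed_mps must be > 0", call. = FALSE)
  if (dt_s <= 0) stop("dt_s must be > 0", call. = FALSE)
  if (max_duration_s <= 0 || max_duration_s > 60)
    stop("max_duration_s must be in (0, 60] for swim trials", call. = FALSE)
  if (heading_noise_sd < 0) stop("heading_noise_sd must be >= 0", call. = FALSE)
  structure(list(strategy = strategy, arena = arena, speed_mps = speed_mps,
                 heading_noise_sd = heading_noise_sd, dt_s = dt_s,
                 max_duration_s = max_duration_s),
            class = "swim_sim_config")
}

#' Strain-like swim speed presets (m/s)
#'
#' Group-mean swim speeds used by the cohort generator: the control strain
#' preset is 0.217 m/s and the BTBR-like preset 0.314 m/s.
#' @return named numeric vector.
#' @export
swim_speed_presets <- function() c(b6 = 0.217, btbr = 0.314)

# Best-Fisher (1979) von Mises sampler; one draw, mean mu, concentration kappa.
rvonmises1 <- function(mu, kappa) {
  if (kappa > 500) return(mu + stats::rnorm(1, 0, sqrt(1 / kappa)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      return(mu + sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f))))
    }
  }
}

unit2 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0) else v / n
}

# steering direction (radians) toward a blend of tangential orbit motion
# around `center` at radius r_target, with proportional radial correction
orbit_heading <- function(p, center, r_target, sense, gain = 1.5) {
  rel <- p - center
  r <- sqrt(sum(rel^2))
  ur <- if (r == 0) c(1, 0) else rel / r
  ut <- sense * c(-ur[2], ur[1])
  corr <- pmin(2, pmax(-2, gain * (r_target - r) / 10))
  v <- ut + corr * ur
  atan2(v[2], v[1])
}

#' Simulate one swim trial
#'
#' Generates a strategy-conditioned swim path from a cardinal release point
#' to (or around) the platform. The walk terminates when the animal contacts
#' the platform (centre-to-centre distance at most the platform radius) or
#' at the trial cap. Identical configurations and seeds give byte-identical
#' trajectories.
#'
#' @param cfg a \code{\link{swim_sim_config}}.
#' @param start release point, one of "N","W","S","E".
#' @param platform_quadrant quadrant (1..4) holding the platform.
#' @param previous_platform_quadrant quadrant of the previously learned
#'   platform position; required for the perseverance (P) strategy.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param day,trial,subject,group metadata passed through to the trajectory.
#' @return a \code{trajectory} with attributes \code{true_strategy} (the
#'   generating label) and \code{escaped} (TRUE if the platform was
#'   contacted).
#' @examples
#' cfg <- swim_sim_config("DSw", heading_noise_sd = 0)
#' tr <- simulate_swim(cfg, start = "N", platform_quadrant = 4)
#' path_efficiency_ratio(tr)  # 1 for the noise-free direct swim
#' @export
simulate_swim <- function(cfg, start, platform_quadrant,
                          previous_platform_quadrant = NULL, seed = NULL,
                          day = NA_integer_, trial = NA_integer_,
                          subject = NA_character_, group = NA_character_) {
  stopifnot(inherits(cfg, "swim_sim_config"))
  if (cfg$strategy == "P" && is.null(previous_platform_quadrant))
    stop("perseverance (P) requires a previous platform quadrant", call. = FALSE)
  run <- function() {
    simulate_swim_impl(cfg, start, platform_quadrant, previous_platform_quadrant,
                       day = day, trial = trial, subject = subject, group = group)
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

simulate_swim_impl <- function(cfg, start, platform_quadrant,
                               previous_platform_quadrant,
                               day, trial, subject, group) {
  arena <- cfg$arena
  R <- arena_radius(arena)
  plat <- platform_center(arena, platform_quadrant)
  prev_plat <- if (!is.null(previous_platform_quadrant))
    platform_center(arena, previous_platform_quadrant) else NULL
  p0 <- start_position(arena, start)
  step_cm <- cfg$speed_mps * 100 * cfg$dt_s
  n_max <- ceiling(cfg$max_duration_s / cfg$dt_s) + 1L
  kappa <- if (cfg$heading_noise_sd > 0) 1 / cfg$heading_noise_sd^2 else Inf
  strat <- cfg$strategy

  # strategy state -----------------------------------------------------
  corridor_u <- unit2(plat - p0)
  corridor_n <- c(-corridor_u[2], corridor_u[1])
  corridor_len <- sqrt(sum((plat - p0)^2))
  weave_amp <- 8; weave_lambda <- 26; lookahead <- 4
  orbit_sense <- if (cfg$heading_noise_sd > 0) sample(c(-1, 1), 1) else 1
  # chaining: orbit the long way round so the annulus is actually traversed
  if (strat == "C") {
    a_start <- atan2(p0[2], p0[1])
    a_plat <- atan2(plat[2], plat[1])
    d_ccw <- (a_plat - a_start) %% (2 * pi)
    orbit_sense <- if (d_ccw < pi) -1 else 1
  }
  fs_anchor <- if (strat == "P") prev_plat else plat
  fs_side <- if (cfg$heading_noise_sd > 0) sample(c(-1, 1), 1) else 1
  fs_aim <- if (strat %in% c("FS", "P")) fs_anchor + 20 * fs_side * corridor_n else NULL
  fs_search_until <- if (strat == "FS")
    stats::runif(1, 10, 18) else Inf  # P searches the old site to the end
  fs_mode <- "approach"
  fs_search_start <- Inf
  s_mode <- "inbound"  # scanning rosette: inbound toward centre, then hold
  s_deflect <- 0.45

  t <- numeric(n_max); xs <- numeric(n_max); ys <- numeric(n_max)
  p <- p0; xs[1] <- p[1]; ys[1] <- p[2]
  th <- atan2(-p[2], -p[1])  # face the pool interior
  if (strat == "T") th <- orbit_heading(p, c(0, 0), R - 4, orbit_sense)
  escaped <- FALSE
  i <- 1L
  while (i < n_max) {
    now <- (i - 1) * cfg$dt_s
    mu <- switch(strat,
      DSw = { v <- plat - p; atan2(v[2], v[1]) },
      DSe = {
        s_prog <- sum((p - p0) * corridor_u)
        s_t <- min(s_prog + lookahead, corridor_len)
        tgt <- p0 + corridor_u * s_t +
          corridor_n * weave_amp * sin(2 * pi * s_t / weave_lambda)
        v <- tgt - p; atan2(v[2], v[1])
      },
      T = orbit_heading(p, c(0, 0), R - 4, orbit_sense),
      C = orbit_heading(p, c(0, 0), arena$platform_orbit_cm, orbit_sense),
      RS = th,
      S = {
        r <- sqrt(sum(p^2))
        if (s_mode == "inbound") {
          if (r < 6) { s_mode <- "hold"; th } else atan2(-p[2], -p[1]) + s_deflect
        } else {
          if (r >= 22) { s_mode <- "inbound"; atan2(-p[2], -p[1]) + s_deflect } else th
        }
      },
      FS = ,
      P = {
        d_anchor <- sqrt(sum((p - fs_anchor)^2))
        if (fs_mode == "approach" && d_anchor <= 26) {
          fs_mode <- "search"; fs_search_start <- now
        }
        if (fs_mode == "search" && strat == "FS" &&
            now - fs_search_start > fs_search_until)
          fs_mode <- "home"
        switch(fs_mode,
          approach = { v <- fs_aim - p; atan2(v[2], v[1]) },
          search = orbit_heading(p, fs_anchor, 18, orbit_sense),
          home = { v <- plat - p; atan2(v[2], v[1]) })
      })
    th <- if (is.finite(kappa)) rvonmises1(mu, kappa) else mu
    v <- c(cos(th), sin(th))
    q <- p + step_cm * v
    # reflect off the wall
    rq <- sqrt(sum(q^2))
    if (rq > R - 1.5) {
      nrm <- q / rq
      v <- v - 2 * sum(v * nrm) * nrm
      th <- atan2(v[2], v[1])
      q <- p + step_cm * v
      rq <- sqrt(sum(q^2))
      if (rq > R - 1.5) q <- q * (R - 1.5) / rq
    }
    i <- i + 1L
    prev <- c(xs[i - 1], ys[i - 1])
    if (sqrt(sum((q - plat)^2)) <= arena$platform_radius_cm) {
      # trial ends at platform contact: cut the final step at the exact
      # crossing of the platform edge
      a <- prev - plat; b <- q - prev
      A <- sum(b^2); B <- 2 * sum(a * b)
      C <- sum(a^2) - arena$platform_radius_cm^2
      s <- if (A == 0) 0 else (-B - sqrt(max(0, B^2 - 4 * A * C))) / (2 * A)
      s <- min(1, max(1e-6, s))  # keep time stamps strictly increasing
      p <- prev + s * b
      t[i] <- now + cfg$dt_s * s; xs[i] <- p[1]; ys[i] <- p[2]
      escaped <- TRUE
      break
    }
    p <- q
    t[i] <- now + cfg$dt_s; xs[i] <- p[1]; ys[i] <- p[2]
  }
  tr <- trajectory(t[1:i], xs[1:i], ys[1:i], arena = arena,
                   start_position = start,
                   platform_quadrant = platform_quadrant,
                   previous_platform_quadrant =
                     if (is.null(previous_platform_quadrant)) NA_integer_
                     else previous_platform_quadrant,
                   day = day, trial = trial, subject = subject, group = group,
                   max_duration_s = cfg$max_duration_s + cfg$dt_s)
  attr(tr, "true_strategy") <- strat
  attr(tr, "escaped") <- escaped
  tr
}
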