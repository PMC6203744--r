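#' Cohort simulation configuration
#'
#' Defines a two-group simulated study of the 5-day hidden-platform
#' reversal protocol: group sizes, days, trials per day, swim speeds, and
#' per-group per-day strategy-mixture weights. The bundled presets emulate
#' the two strains' published behaviour: the control-like ("b6") group uses
#' spatial strategies on 44% of day-1 trials rising to 87% by day 5 (a 43
#' percentage-point improvement), while the BTBR-like group stays nearly
#' flat (31% to 36%, a 5-point improvement) and swims faster
#' (0.314 vs 0.217 m/s). Within-category label weights give the BTBR-like
#' group more chaining and scanning among its non-spatial trials.
#'
#' @param n_per_group named integer vector of subjects per group; the
#'   default \code{c(b6 = 13, btbr = 9)} matches the published group sizes.
#' @param days number of training days, default 5.
#' @param trials_per_day trials per subject per day, default 4.
#' @param mixtures named list (one element per group) of day-by-label weight
#'   matrices (days x 8 labels, rows summing to 1); NULL uses the presets.
#' @param speeds_mps named numeric vector of group swim speeds; NULL uses
#'   \code{\link{swim_speed_presets}}.
#' @param heading_noise_sd per-step heading noise, default 0.3.
#' @param dt_s sampling interval, default 0.1.
#' @param platform_quadrant,previous_platform_quadrant the reversal
#'   protocol's new (4) and previously learned (3) platform quadrants.
#' @return a \code{cohort_sim_config} list.
#' @export
cohort_sim_config <- function(n_per_group = c(b6 = 13, btbr = 9),
                              days = 5, trials_per_day = 4,
                              mixtures = NULL, speeds_mps = NULL,
                              heading_noise_sd = 0.3, dt_s = 0.1,
                              platform_quadrant = 4,
                              previous_platform_quadrant = 3) {
  stopifnot(length(n_per_group) >= 1, all(n_per_group >= 1),
            days >= 1, trials_per_day >= 1)
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("n_per_group must be a named vector of group sizes", call. = FALSE)
  groups <- names(n_per_group)
  if (is.null(mixtures))
    mixtures <- lapply(stats::setNames(groups, groups), preset_mixture,
                       days = days)
  if (is.null(speeds_mps)) {
    pre <- swim_speed_presets()
    speeds_mps <- vapply(groups, function(g)
      if (g %in% names(pre)) pre[[g]] else pre[["b6"]], numeric(1))
  }
  for (g in groups) {
    m <- mixtures[[g]]
    if (is.null(m) || nrow(m) != days || ncol(m) != 8)
      stop(sprintf("mixture for group '%s' must be a %d x 8 matrix", g, days),
           call. = FALSE)
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8))
      stop(sprintf("mixture rows for group '%s' must be nonnegative and sum to 1", g),
           call. = FALSE)
  }
  structure(list(n_per_group = n_per_group, days = days,
                 trials_per_day = trials_per_day, mixtures = mixtures,
                 speeds_mps = speeds_mps,
                 heading_noise_sd = heading_noise_sd, dt_s = dt_s,
                 platform_quadrant = platform_quadrant,
                 previous_platform_quadrant = previous_platform_quadrant),
            class = "cohort_sim_config")
}

# Strategy-mixture preset for a group. Spatial share interpolates linearly
# between the day-1 and day-final anchors; within-category weights are fixed.
preset_mixture <- function(group, days) {
  labs <- strategy_levels()
  spatial <- c("DSe", "FS", "DSw", "P")
  if (group == "btbr") {
    anchors <- c(0.31, 0.36)
    w_sp <- c(DSe = 0.60, FS = 0.20, DSw = 0.10, P = 0.10)
    w_ns <- c(T = 0.15, RS = 0.30, S = 0.30, C = 0.25)
  } else {
    anchors <- c(0.44, 0.87)
    w_sp <- c(DSe = 0.45, FS = 0.25, DSw = 0.20, P = 0.10)
    w_ns <- c(T = 0.20, RS = 0.35, S = 0.25, C = 0.20)
  }
  s <- if (days == 1) anchors[2] else
    anchors[1] + (anchors[2] - anchors[1]) * (seq_len(days) - 1) / (days - 1)
  m <- matrix(0, days, 8, dimnames = list(NULL, labs))
  for (d in seq_len(days)) {
    m[d, spatial] <- s[d] * w_sp[spatial]
    m[d, setdiff(labs, spatial)] <- (1 - s[d]) * w_ns[setdiff(labs, spatial)]
  }
  m
}

#' Simulate a full training cohort
#'
#' Draws each trial's search strategy from the group's day-specific mixture
#' and generates the corresponding swim path. Start positions follow a
#' pseudo-random rotation of the four cardinal release points within each
#' day. Reproducible: identical configs and seeds give identical cohorts.
#'
#' @param cfg a \code{\link{cohort_sim_config}}.
#' @param seed integer seed or NULL.
#' @return a tibble with one row per trial: subject, group, day, trial,
#'   start, true_strategy, escaped, and a \code{trajectory} list-column.
#' @export
simulate_cohort <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  run <- function() {
    rows <- list()
    starts <- c("N", "W", "S", "E")
    for (g in names(cfg$n_per_group)) {
      mix <- cfg$mixtures[[g]]
      scfgs <- lapply(strategy_levels(), function(s)
        swim_sim_config(s, speed_mps = cfg$speeds_mps[[g]],
                        heading_noise_sd = cfg$heading_noise_sd,
                        dt_s = cfg$dt_s))
      names(scfgs) <- strategy_levels()
      for (sj in seq_len(cfg$n_per_group[[g]])) {
        subject <- sprintf("%s_%02d", g, sj)
        for (d in seq_len(cfg$days)) {
          day_starts <- sample(starts)
          for (tr in seq_len(cfg$trials_per_day)) {
            strat <- sample(strategy_levels(), 1, prob = mix[d, ])
            st <- day_starts[((tr - 1) %% 4) + 1]
            traj <- simulate_swim(scfgs[[strat]], start = st,
                                  platform_quadrant = cfg$platform_quadrant,
                                  previous_platform_quadrant =
                                    cfg$previous_platform_quadrant,
                                  day = d, trial = tr,
                                  subject = subject, group = g)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              subject = subject, group = g, day = d, trial = tr,
              start = st, true_strategy = strat,
              escaped = attr(traj, "escaped"),
              trajectory = list(traj))
          }
        }
      }
    }
    dplyr::bind_rows(rows)
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

#' Write a simulated cohort to disk
#'
#' Writes one trajectory CSV per trial, a trials manifest CSV (subject,
#' group, day, trial, start, true label, file), and a ground-truth JSON.
#' Output is byte-stable for identical cohorts.
#'
#' @param cohort output of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    f <- sprintf("%s_d%d_t%d.csv", cohort$subject[i], cohort$day[i],
                 cohort$trial[i])
    write_trajectory_csv(cohort$trajectory[[i]], file.path(dir, f))
    files[i] <- f
  }
  manifest <- data.frame(subject = cohort$subject, group = cohort$group,
                         day = cohort$day, trial = cohort$trial,
                         start = cohort$start,
                         true_strategy = cohort$true_strategy,
                         escaped = cohort$escaped, file = files)
  utils::write.table(manifest, file.path(dir, "manifest.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  jsonlite::write_json(
    list(n_trials = nrow(manifest),
         labels = stats::setNames(as.list(manifest$true_strategy),
                                  paste(manifest$subject, manifest$day,
                                        manifest$trial, sep = "_"))),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.csv"))
}
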