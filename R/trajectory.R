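#' Tracked trajectory
#'
#' A trajectory is a time-stamped 2-D point series in the arena frame
#' (origin at arena centre, cm, seconds), with its arena geometry and trial
#' metadata attached. The constructor validates the invariants every
#' downstream metric relies on: at least two samples, strictly increasing
#' time stamps, all points inside the arena boundary up to a 1-cm tracking
#' jitter tolerance, and total duration within the trial cap (60 s for swim
#' trials, 30 s for the probe, 1200 s for the open field).
#'
#' @param t numeric vector of time stamps in seconds, strictly increasing.
#' @param x,y numeric vectors of positions in cm.
#' @param arena an \code{arena_geometry}.
#' @param start_position one of "N","W","S","E", or NA.
#' @param platform_quadrant integer 1..4 or NA.
#' @param previous_platform_quadrant integer 1..4 or NA (reversal protocol).
#' @param day,trial,subject,group trial metadata (scalar, optional).
#' @param max_duration_s trial cap in seconds; defaults by arena kind
#'   (60 for pool, 1200 for open field, none for beam).
#' @param tolerance_cm allowed excursion beyond the wall, default 1.
#' @return a \code{trajectory}: a data.frame with columns \code{t, x, y} and
#'   attributes \code{arena} and \code{meta}.
#' @examples
#' pool <- pool_arena()
#' tr <- trajectory(t = c(0, 1, 2), x = c(0, 10, 20), y = c(0, 0, 0),
#'                  arena = pool)
#' path_length(tr)  # 0.2 m
#' @export
trajectory <- function(t, x, y, arena,
                       start_position = NA_character_,
                       platform_quadrant = NA_integer_,
                       previous_platform_quadrant = NA_integer_,
                       day = NA_integer_, trial = NA_integer_,
                       subject = NA_character_, group = NA_character_,
                       max_duration_s = NULL, tolerance_cm = 1) {
  stopifnot(is.numeric(t), is.numeric(x), is.numeric(y))
  n <- length(t)
  if (n < 2) stop("trajectory needs at least 2 samples", call. = FALSE)
  if (length(x) != n || length(y) != n)
    stop("t, x, y must have equal length", call. = FALSE)
  if (anyNA(t) || anyNA(x) || anyNA(y))
    stop("trajectory contains missing values", call. = FALSE)
  if (any(diff(t) <= 0))
    stop(sprintf("time stamps must be strictly increasing (first violation at row %d)",
                 which(diff(t) <= 0)[1] + 1L), call. = FALSE)
  if (is.null(max_duration_s)) {
    max_duration_s <- switch(arena$kind, pool = 60, open_field = 1200, beam = Inf)
  }
  dur <- t[n] - t[1]
  if (dur > max_duration_s + 1e-9)
    stop(sprintf("duration %.2f s exceeds trial cap %.0f s", dur, max_duration_s),
         call. = FALSE)
  if (is_circular_arena(arena)) {
    r <- sqrt(x^2 + y^2)
    bad <- which(r > arena_radius(arena) + tolerance_cm)
    if (length(bad))
      stop(sprintf("%d point(s) outside arena wall beyond %g cm tolerance (rows %s)",
                   length(bad), tolerance_cm,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (!is.na(start_position))
    start_position <- match.arg(start_position, c("N", "W", "S", "E"))
  out <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y))
  attr(out, "arena") <- arena
  attr(out, "meta") <- list(start_position = start_position,
                            platform_quadrant = platform_quadrant,
                            previous_platform_quadrant = previous_platform_quadrant,
                            day = day, trial = trial,
                            subject = subject, group = group,
                            max_duration_s = max_duration_s)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  m <- trajectory_meta(x)
  cat(sprintf("<trajectory: %d samples, %.1f s, arena = %s>\n",
              nrow(x), x$t[nrow(x)] - x$t[1], trajectory_arena(x)$kind))
  if (!is.na(m$subject))
    cat(sprintf("  subject %s (%s), day %s trial %s\n",
                m$subject, m$group, m$day, m$trial))
  invisible(x)
}

#' Accessors for trajectory attributes
#' @param traj a \code{trajectory}.
#' @return the attached \code{arena_geometry} or metadata list.
#' @export
trajectory_arena <- function(traj) attr(traj, "arena")

#' @rdname trajectory_arena
#' @export
trajectory_meta <- function(traj) attr(traj, "meta")

#' Platform geometry for a trajectory's trial
#'
#' Resolves the platform centre (and, for reversal trials, the previous
#' platform centre) from the metadata attached to a swim trajectory.
#'
#' @param traj a pool \code{trajectory}.
#' @param previous if TRUE return the previous platform centre.
#' @return length-2 numeric, or NULL if the quadrant is not recorded.
#' @export
trajectory_platform <- function(traj, previous = FALSE) {
  m <- trajectory_meta(traj)
  q <- if (previous) m$previous_platform_quadrant else m$platform_quadrant
  if (is.null(q) || is.na(q)) return(NULL)
  platform_center(trajectory_arena(traj), q)
}

trajectory_start_point <- function(traj) {
  m <- trajectory_meta(traj)
  if (!is.na(m$start_position))
    start_position(trajectory_arena(traj), m$start_position)
  else c(traj$x[1], traj$y[1])
}

#' Read and write trajectory CSV files
#'
#' The on-disk format is a plain CSV with header \code{t,x,y} (seconds, cm,
#' cm). \code{read_trajectory_csv} validates every row and reports row-level
#' problems (non-numeric fields, non-increasing time, out-of-arena points)
#' with their line numbers.
#'
#' @param traj a \code{trajectory}.
#' @param path file path.
#' @param arena arena geometry to attach on read.
#' @param ... metadata fields passed to \code{\link{trajectory}}.
#' @return \code{read_trajectory_csv} returns a \code{trajectory};
#'   \code{write_trajectory_csv} returns \code{path} invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  # fixed significant-digit formatting keeps output byte-stable across runs
  df <- data.frame(t = sprintf("%.6f", traj$t),
                   x = sprintf("%.6f", traj$x),
                   y = sprintf("%.6f", traj$y))
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, arena, ...) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("t", "x", "y")))
    stop(sprintf("%s: expected header t,x,y, got %s",
                 path, paste(names(df), collapse = ",")), call. = FALSE)
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop(sprintf("%s: non-numeric or missing values at data row(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  trajectory(df$t, df$x, df$y, arena = arena, ...)
}

#' Read and write arena configuration JSON
#'
#' @param arena an \code{arena_geometry}.
#' @param path file path.
#' @return \code{read_arena_json} returns an \code{arena_geometry}.
#' @export
write_arena_json <- function(arena, path) {
  stopifnot(inherits(arena, "arena_geometry"))
  jsonlite::write_json(unclass(arena), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_arena_json
#' @export
read_arena_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$kind)) stop("arena config missing 'kind'", call. = FALSE)
  switch(cfg$kind,
         pool = pool_arena(diameter_cm = cfg$diameter_cm,
                           platform_radius_cm = cfg$platform_radius_cm),
         open_field = open_field_arena(diameter_cm = cfg$diameter_cm,
                                       central_zone_diameter_cm = cfg$central_zone_diameter_cm),
         beam = beam_arena(length_cm = cfg$beam_length_cm,
                           width_cm = cfg$beam_width_cm),
         stop(sprintf("unknown arena kind '%s'", cfg$kind), call. = FALSE))
}

#' Strategy labels and their spatial/non-spatial grouping
#'
#' The eight swim search strategies: thigmotaxis (T), random swim (RS),
#' scanning (S) and chaining (C) are non-spatial; directed search (DSe),
#' focal search (FS), direct swim (DSw) and perseverance (P) are spatial.
#'
#' @param label character vector of labels among
#'   \code{c("T","RS","S","C","DSe","FS","DSw","P")}.
#' @return \code{strategy_levels()} returns the eight labels in canonical
#'   order; \code{strategy_category} returns a factor with levels
#'   \code{non_spatial, spatial}; \code{is_spatial_strategy} a logical.
#' @export
strategy_levels <- function() c("T", "RS", "S", "C", "DSe", "FS", "DSw", "P")

#' @rdname strategy_levels
#' @export
is_spatial_strategy <- function(label) {
  if (!all(label %in% strategy_levels()))
    stop("unknown strategy label(s): ",
         paste(setdiff(label, strategy_levels()), collapse = ", "), call. = FALSE)
  label %in% c("DSe", "FS", "DSw", "P")
}

#' @rdname strategy_levels
#' @export
strategy_category <- function(label) {
  factor(ifelse(is_spatial_strategy(label), "spatial", "non_spatial"),
         levels = c("non_spatial", "spatial"))
}
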