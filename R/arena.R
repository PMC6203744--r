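#' Arena geometry
#'
#' Constructors for the three apparatus geometries used throughout the
#' package: the circular swim pool, the circular open field, and the narrow
#' balance beam. All coordinates are in centimetres in an arena-centred
#' frame: the origin is the arena centre, the positive y axis points toward
#' the "North" start position, and angles are measured counter-clockwise
#' from the positive x axis ("East").
#'
#' Quadrants are numbered 1..4 counter-clockwise with quadrant 1 spanning
#' angles \eqn{[0, 90)} degrees, so the quadrant-q bisector lies at
#' \eqn{(2q - 1) \times 45} degrees. The escape platform sits on the
#' bisector of its quadrant, half-way between the pool centre and the wall
#' (radial distance \code{diameter/4}).
#'
#' @param diameter_cm arena diameter; 154 cm for both pool and open field.
#' @param platform_radius_cm escape platform radius (pool only), 12 cm.
#' @param central_zone_diameter_cm diameter of the concentric central zone
#'   scored in the open field, 52 cm.
#' @param length_cm,width_cm beam dimensions (92 cm x 1 cm).
#'
#' @return An object of class \code{arena_geometry}: a list with fields
#'   \code{kind} (one of \code{"pool"}, \code{"open_field"}, \code{"beam"}),
#'   \code{center}, and the kind-specific dimensions.
#' @examples
#' pool <- pool_arena()
#' arena_radius(pool)           # 77
#' platform_center(pool, 4)     # on the quadrant-4 bisector at r = 38.5
#' @name arena_geometry
NULL

#' @rdname arena_geometry
#' @export
pool_arena <- function(diameter_cm = 154, platform_radius_cm = 12) {
  stopifnot(diameter_cm > 0, platform_radius_cm > 0)
  # platform at diameter/4 from centre must fit inside the wall
  if (diameter_cm / 4 + platform_radius_cm >= diameter_cm / 2)
    stop("platform does not fit inside the pool", call. = FALSE)
  structure(list(kind = "pool", diameter_cm = diameter_cm,
                 center = c(0, 0),
                 platform_radius_cm = platform_radius_cm,
                 platform_orbit_cm = diameter_cm / 4),
            class = "arena_geometry")
}

#' @rdname arena_geometry
#' @export
open_field_arena <- function(diameter_cm = 154, central_zone_diameter_cm = 52) {
  stopifnot(diameter_cm > 0,
            central_zone_diameter_cm > 0,
            central_zone_diameter_cm < diameter_cm)
  structure(list(kind = "open_field", diameter_cm = diameter_cm,
                 center = c(0, 0),
                 central_zone_diameter_cm = central_zone_diameter_cm),
            class = "arena_geometry")
}

#' @rdname arena_geometry
#' @export
beam_arena <- function(length_cm = 92, width_cm = 1) {
  stopifnot(length_cm > 0, width_cm > 0)
  structure(list(kind = "beam", beam_length_cm = length_cm,
                 beam_width_cm = width_cm, center = c(0, 0)),
            class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  if (x$kind == "beam") {
    cat(sprintf("<arena_geometry: beam %g cm x %g cm>\n",
                x$beam_length_cm, x$beam_width_cm))
  } else {
    cat(sprintf("<arena_geometry: %s, diameter %g cm>\n", x$kind, x$diameter_cm))
  }
  invisible(x)
}

is_circular_arena <- function(arena) {
  inherits(arena, "arena_geometry") && arena$kind %in% c("pool", "open_field")
}

#' Arena radius in cm
#' @param arena an \code{arena_geometry} (pool or open field).
#' @return radius in cm.
#' @export
arena_radius <- function(arena) {
  if (!is_circular_arena(arena)) stop("circular arena required", call. = FALSE)
  arena$diameter_cm / 2
}

# Cardinal start positions sit on the wall: N/W/S/E at 90/180/270/0 degrees.
start_angles_deg <- c(N = 90, W = 180, S = 270, E = 0)

#' Start position coordinates for a cardinal release point
#'
#' Animals are released at the pool wall at one of the four cardinal compass
#' positions. The returned point sits just inside the wall (2 cm in) so that
#' the release point itself satisfies the in-arena invariant.
#'
#' @param arena a pool \code{arena_geometry}.
#' @param start one of \code{"N"}, \code{"W"}, \code{"S"}, \code{"E"}.
#' @param inset_cm radial inset from the wall, default 2.
#' @return length-2 numeric (x, y) in cm.
#' @export
start_position <- function(arena, start, inset_cm = 2) {
  start <- match.arg(start, c("N", "W", "S", "E"))
  r <- arena_radius(arena) - inset_cm
  a <- start_angles_deg[[start]] * pi / 180
  c(r * cos(a), r * sin(a))
}

#' Platform centre for a quadrant
#'
#' The platform is placed on the bisector of its quadrant at radial distance
#' \code{diameter/4} from the pool centre (half-way between centre and wall).
#'
#' @param arena a pool \code{arena_geometry}.
#' @param quadrant integer 1..4.
#' @return length-2 numeric (x, y) in cm.
#' @export
platform_center <- function(arena, quadrant) {
  stopifnot(arena$kind == "pool", quadrant %in% 1:4)
  a <- (2 * quadrant - 1) * 45 * pi / 180
  arena$platform_orbit_cm * c(cos(a), sin(a))
}

as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    points
  } else {
    stopifnot(is.numeric(points), length(points) == 2)
    matrix(points, ncol = 2)
  }
}

#' Quadrant assignment
#'
#' Assigns points to quadrants 1..4 by angle, using the half-open convention
#' that quadrant q covers angles \eqn{[(q-1) \times 90, q \times 90)} degrees.
#' The arena centre (angle undefined) maps to quadrant 1 by this convention.
#'
#' @param points a length-2 numeric or an n x 2 matrix of (x, y) in cm.
#' @param arena a circular \code{arena_geometry}.
#' @param tolerance_cm how far outside the wall a point may lie before it is
#'   rejected (tracking jitter allowance), default 1.
#' @return integer vector of quadrant indices.
#' @export
quadrant_of <- function(points, arena, tolerance_cm = 1) {
  p <- as_point_matrix(points)
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  bad <- r > arena_radius(arena) + tolerance_cm
  if (any(bad))
    stop(sprintf("%d point(s) outside arena beyond %g cm tolerance (first at row %d, r = %.2f cm)",
                 sum(bad), tolerance_cm, which(bad)[1], r[which(bad)[1]]),
         call. = FALSE)
  ang <- atan2(p[, 2], p[, 1]) # (-pi, pi]
  deg <- (ang * 180 / pi) %% 360
  as.integer(deg %/% 90) + 1L
}

#' Distance to the arena wall
#'
#' Radial clearance \code{radius - |point - center|} in cm. Points beyond
#' the wall get distance 0 and are flagged in the \code{"out_of_bounds"}
#' attribute.
#'
#' @inheritParams quadrant_of
#' @return numeric vector of clearances with a logical
#'   \code{"out_of_bounds"} attribute.
#' @export
distance_to_wall <- function(points, arena) {
  p <- as_point_matrix(points)
  d <- arena_radius(arena) - sqrt(p[, 1]^2 + p[, 2]^2)
  oob <- d < 0
  d[oob] <- 0
  attr(d, "out_of_bounds") <- oob
  d
}

#' Corridor membership
#'
#' Tests whether points lie inside the straight corridor band from the
#' release point to the platform centre: perpendicular distance to the
#' start-to-platform segment at most \code{width_cm/2} (boundary inclusive)
#' and projection falling between start and platform centre (the band is
#' capped at both ends).
#'
#' @param points length-2 numeric or n x 2 matrix (cm).
#' @param start,platform_center length-2 numerics (cm).
#' @param width_cm full corridor width, default 20.
#' @return logical vector.
#' @export
in_corridor <- function(points, start, platform_center, width_cm = 20) {
  p <- as_point_matrix(points)
  d <- platform_center - start
  L2 <- sum(d^2)
  if (L2 == 0) stop("degenerate corridor: start equals platform centre", call. = FALSE)
  rel <- cbind(p[, 1] - start[1], p[, 2] - start[2])
  t <- (rel[, 1] * d[1] + rel[, 2] * d[2]) / L2
  perp <- abs(rel[, 1] * d[2] - rel[, 2] * d[1]) / sqrt(L2)
  t >= 0 & t <= 1 & perp <= width_cm / 2
}
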