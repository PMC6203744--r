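#' Ordered section-area set for volumetry
#'
#' Holds the ordered per-section cross-sectional areas (mm^2, measured on
#' the shrunken tissue) for one brain structure, with the sectioning
#' constants used by the volume estimator: 40-um slice thickness and a
#' sampling interval of 5 (every fifth section measured). The standard
#' protocol uses 8 sections for cortex and 4 for dorsal hippocampus; other
#' counts are accepted with a warning. Missing (damaged) sections are
#' encoded as \code{NA}.
#'
#' @param areas_mm2 numeric vector of per-section areas, ordered
#'   rostro-caudally; \code{NA} marks a missing section.
#' @param structure \code{"cortex"}, \code{"dHPC"}, or another label.
#' @param slice_thickness_um section thickness in micrometres, default 40.
#' @param sampling_interval every k-th section measured, default 5.
#' @return a \code{section_set}.
#' @export
section_set <- function(areas_mm2, structure = c("cortex", "dHPC", "other"),
                        slice_thickness_um = 40, sampling_interval = 5) {
  structure_lbl <- match.arg(structure)
  if (!length(areas_mm2)) stop("empty section set", call. = FALSE)
  if (any(areas_mm2 < 0, na.rm = TRUE))
    stop("section areas must be >= 0", call. = FALSE)
  expected <- c(cortex = 8L, dHPC = 4L)[structure_lbl]
  if (!is.na(expected) && length(areas_mm2) != expected)
    warning(sprintf("%s volumetry normally uses %d sections; got %d",
                    structure_lbl, expected, length(areas_mm2)), call. = FALSE)
  structure(list(areas_mm2 = as.numeric(areas_mm2),
                 structure = structure_lbl,
                 slice_thickness_um = slice_thickness_um,
                 sampling_interval = sampling_interval),
            class = "section_set")
}

# Flanking-mean imputation for missing sections. Only isolated interior
# gaps can be imputed (the flanking mean is undefined for runs or edges),
# and at most `max_missing` sections may be missing in total.
impute_sections <- function(areas, max_missing = 2) {
  miss <- which(is.na(areas))
  if (!length(miss)) return(areas)
  if (length(miss) > max_missing)
    stop(sprintf("%d missing sections exceeds the tolerance of %d",
                 length(miss), max_missing), call. = FALSE)
  n <- length(areas)
  for (i in miss) {
    if (i == 1 || i == n)
      stop("cannot impute a missing first or last section (no flanking pair)",
           call. = FALSE)
    if (is.na(areas[i - 1]) || is.na(areas[i + 1]))
      stop("cannot impute consecutive missing sections", call. = FALSE)
    areas[i] <- (areas[i - 1] + areas[i + 1]) / 2
  }
  areas
}

#' Sectional (Cavalieri) volume estimate
#'
#' Volume in mm^3 from serial sections: the summed section areas multiplied
#' by the slice thickness (40 um = 0.040 mm) and the sampling interval (5).
#' Isolated missing interior sections (at most two per set) are imputed as
#' the mean of the flanking sections before summation.
#'
#' @param sections a \code{\link{section_set}}.
#' @return volume in mm^3.
#' @examples
#' estimate_volume(section_set(rep(1, 8), "cortex"))          # 1.6
#' estimate_volume(section_set(c(1, 2, NA, 4), "dHPC"))       # 2.0
#' @export
estimate_volume <- function(sections) {
  stopifnot(inherits(sections, "section_set"))
  areas <- impute_sections(sections$areas_mm2)
  sum(areas) * (sections$slice_thickness_um / 1000) * sections$sampling_interval
}

#' Mean section area
#'
#' Sum of the (imputation-completed) section areas divided by the number of
#' sections, in mm^2.
#'
#' @param sections a \code{\link{section_set}}.
#' @return mm^2.
#' @export
mean_section_area <- function(sections) {
  stopifnot(inherits(sections, "section_set"))
  areas <- impute_sections(sections$areas_mm2)
  mean(areas)
}

#' Aggregate cortical thickness measurements
#'
#' Cortical thickness is measured at three points (dorsal, lateral,
#' ventral) per hemisphere on each of seven consecutive sections, up to six
#' measurements per section. This aggregates a long-format measurement
#' table to arithmetic means overall, per measurement point, or per
#' hemisphere; missing cells are excluded and counted.
#'
#' @param records data.frame with columns \code{slice}, \code{hemisphere}
#'   (\code{"left"/"right"}), \code{point}
#'   (\code{"dorsal"/"lateral"/"ventral"}), \code{thickness_mm}.
#' @param by \code{"overall"}, \code{"point"}, or \code{"hemisphere"}.
#' @return a tibble with the grouping column(s), \code{mean_mm}, \code{n},
#'   and \code{n_missing}.
#' @export
aggregate_thickness <- function(records, by = c("overall", "point", "hemisphere")) {
  by <- match.arg(by)
  stopifnot(all(c("slice", "hemisphere", "point", "thickness_mm") %in% names(records)))
  if (!all(records$point %in% c("dorsal", "lateral", "ventral")))
    stop("point must be dorsal, lateral or ventral", call. = FALSE)
  if (any(records$thickness_mm <= 0, na.rm = TRUE))
    stop("thickness must be > 0", call. = FALSE)
  per_slice <- table(records$slice[!is.na(records$thickness_mm)])
  if (any(per_slice > 6))
    stop("more than six measurements on one section", call. = FALSE)
  grp <- switch(by, overall = character(0), point = "point",
                hemisphere = "hemisphere")
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(mean_mm = mean(.data$thickness_mm, na.rm = TRUE),
                     n = sum(!is.na(.data$thickness_mm)),
                     n_missing = sum(is.na(.data$thickness_mm)),
                     .groups = "drop")
}

#' Count stained particles (cells) in a section image
#'
#' Reproduces the standard particle-analysis procedure for Nissl-stained
#' sections: the greyscale image is thresholded to the inclusive band
#' \code{[low, high]} on the 8-bit scale (pixels inside the band are
#' foreground), merged particles are optionally split by watershed (1-pixel
#' divide lines on the distance map), and connected components
#' (8-connectivity) are filtered by pixel area and circularity
#' \eqn{4\pi A / P^2} before counting. RGB arrays are converted to
#' greyscale first. Circularity estimates from discrete perimeters can
#' slightly exceed 1 for small round objects; values are capped at 1 so
#' the default filter [0, 1] keeps every particle.
#'
#' @param image numeric matrix of grey levels on the 0-255 scale (values in
#'   [0, 1] are rescaled by 255), or an RGB array (rows x cols x 3).
#' @param low,high inclusive detection band, defaults 90 and 180.
#' @param size_px size filter (pixel-area range), default c(0, Inf).
#' @param circularity circularity filter, default c(0, 1).
#' @param watershed split merged particles, default TRUE.
#' @param ws_tolerance watershed minimum object-height tolerance on the
#'   distance map, default 0.3 (splits touching cell-sized disks without
#'   fragmenting round single cells).
#' @param roi_area_mm2 ROI area for density (dorsal ROI ~0.352 mm^2,
#'   lateral ~0.30 mm^2), optional.
#' @return a \code{particle_count_result}: list with \code{count},
#'   \code{roi_area_mm2}, \code{density_per_mm2}, and \code{settings}.
#' @export
count_particles <- function(image, low = 90, high = 180,
                            size_px = c(0, Inf), circularity = c(0, 1),
                            watershed = TRUE, ws_tolerance = 0.3,
                            roi_area_mm2 = NULL) {
  if (low > high) stop("low must be <= high", call. = FALSE)
  if (length(dim(image)) == 3) {
    if (dim(image)[3] != 3) stop("expected an RGB array with 3 channels", call. = FALSE)
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  if (!is.matrix(image)) stop("image must be a matrix or RGB array", call. = FALSE)
  if (max(image) <= 1) image <- image * 255
  mask <- (image >= low & image <= high) * 1
  if (!any(mask == 1)) {
    count <- 0L
  } else {
    labels <- if (watershed) {
      EBImage::watershed(EBImage::distmap(mask), tolerance = ws_tolerance,
                         ext = 1)
    } else {
      EBImage::bwlabel(mask)
    }
    shp <- EBImage::computeFeatures.shape(labels)
    area <- shp[, "s.area"]
    per <- shp[, "s.perimeter"]
    circ <- pmin(1, 4 * pi * area / pmax(per, 1)^2)
    keep <- area >= size_px[1] & area <= size_px[2] &
      circ >= circularity[1] & circ <= circularity[2]
    count <- sum(keep)
  }
  density <- if (is.null(roi_area_mm2)) NA_real_ else count / roi_area_mm2
  structure(list(count = as.integer(count),
                 roi_area_mm2 = if (is.null(roi_area_mm2)) NA_real_ else roi_area_mm2,
                 density_per_mm2 = density,
                 settings = list(low = low, high = high, size_px = size_px,
                                 circularity = circularity,
                                 watershed = watershed)),
            class = "particle_count_result")
}

#' @export
print.particle_count_result <- function(x, ...) {
  cat(sprintf("<particle count: %d%s>\n", x$count,
              if (is.na(x$density_per_mm2)) ""
              else sprintf(", %.1f / mm^2 in %.3f mm^2", x$density_per_mm2,
                           x$roi_area_mm2)))
  invisible(x)
}

#' Cell density from a particle count
#'
#' Count divided by the ROI area, in cells per mm^2.
#'
#' @param result a \code{particle_count_result}.
#' @param roi_area_mm2 ROI area override (required if the count was made
#'   without one).
#' @return cells per mm^2.
#' @export
cell_density <- function(result, roi_area_mm2 = NULL) {
  stopifnot(inherits(result, "particle_count_result"))
  a <- if (!is.null(roi_area_mm2)) roi_area_mm2 else result$roi_area_mm2
  if (is.na(a)) stop("no ROI area available", call. = FALSE)
  result$count / a
}
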