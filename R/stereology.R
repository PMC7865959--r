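#' Synapse density estimation
#'
#' Two estimators: the size-frequency method on 2D micrographs, which
#' converts the areal density of synaptic profiles not touching the
#' counting-frame exclusion boundary into a numerical density via the mean
#' PSD length, and the direct 3D count inside a subvolume with three
#' excluding planes.
#'
#' @name stereology
#' @keywords internal
NULL

#' Counting frames covering each micrograph field
#'
#' @param planes A [section_planes()] table.
#' @return A `data.frame` with `micrograph_id`, `x0`, `y0`, `x1`, `y1`.
#' @export
frames_from_sections <- function(planes) {
  data.frame(micrograph_id = planes$micrograph_id,
             x0 = planes$field_x, y0 = planes$field_y,
             x1 = planes$field_x + planes$field_w,
             y1 = planes$field_y + planes$field_h)
}

# Distance from point (cx, cy) to the forbidden line of an unbiased frame:
# the bottom edge segment {y = y0, x0 <= x <= x1} plus the left edge
# extended upward as the ray {x = x0, y >= y0}.
.forbidden_dist <- function(cx, cy, x0, y0, x1) {
  # vertical ray at x0 from y0 upward
  d_ray <- ifelse(cy >= y0, abs(cx - x0),
                  sqrt((cx - x0)^2 + (cy - y0)^2))
  # horizontal segment at y0 from x0 to x1
  d_seg <- ifelse(cx < x0, sqrt((cx - x0)^2 + (cy - y0)^2),
                  ifelse(cx > x1, sqrt((cx - x1)^2 + (cy - y0)^2),
                         abs(cy - y0)))
  pmin(d_ray, d_seg)
}

# Does the circle overlap the frame rectangle at all?
.circle_overlaps_rect <- function(cx, cy, rp, x0, y0, x1, y1) {
  dx <- pmax(x0 - cx, 0, cx - x1)
  dy <- pmax(y0 - cy, 0, cy - y1)
  dx^2 + dy^2 < rp^2
}

#' Classify profiles against counting frames
#'
#' Implements the unbiased two-edge counting frame: a circular profile is
#' countable when it overlaps the frame and does not touch the forbidden
#' line (the bottom edge plus the left edge extended upward beyond the
#' frame). Under a tiling of the plane by such frames every profile is
#' counted exactly once, which is what makes the frame unbiased. The
#' `"all_edges"` mode instead counts only profiles lying entirely inside the
#' frame -- the convention of discarding every edge-touching profile,
#' which undercounts large profiles.
#'
#' @param profiles Profile table with `micrograph_id`, `center_x_um`,
#'   `center_y_um`, `radius_um`.
#' @param frames Frame table from [frames_from_sections()] (one frame per
#'   micrograph).
#' @param mode `"unbiased"` (default) or `"all_edges"`.
#' @return A `data.frame` with logical columns `countable` and
#'   `touches_exclusion`, one row per profile.
#' @export
classify_profiles <- function(profiles, frames,
                              mode = c("unbiased", "all_edges")) {
  mode <- match.arg(mode)
  if (nrow(profiles) == 0) {
    return(data.frame(countable = logical(), touches_exclusion = logical()))
  }
  i <- match(profiles$micrograph_id, frames$micrograph_id)
  if (anyNA(i)) stop("profile references a micrograph with no frame",
                     call. = FALSE)
  x0 <- frames$x0[i]; y0 <- frames$y0[i]
  x1 <- frames$x1[i]; y1 <- frames$y1[i]
  cx <- profiles$center_x_um; cy <- profiles$center_y_um
  rp <- profiles$radius_um

  if (mode == "unbiased") {
    touches <- .forbidden_dist(cx, cy, x0, y0, x1) < rp
    countable <- .circle_overlaps_rect(cx, cy, rp, x0, y0, x1, y1) & !touches
  } else {
    inside <- cx - rp > x0 & cx + rp < x1 & cy - rp > y0 & cy + rp < y1
    touches <- !inside
    countable <- inside
  }
  data.frame(countable = countable, touches_exclusion = touches)
}

#' Density estimate record
#'
#' @param na Estimated density, synapses per um^3.
#' @param method One of `"size_frequency_2d"`, `"count_3d_spines"`,
#'   `"count_3d_all"`.
#' @param n_counted Number of profiles or spines counted.
#' @param examined Area (um^2) or volume (um^3) examined.
#' @param mean_psd_length Mean PSD length of counted profiles, um
#'   (size-frequency only).
#' @return An object of class `"density_estimate"`.
#' @export
density_estimate <- function(na, method, n_counted, examined,
                             mean_psd_length = NA_real_) {
  stopifnot(na >= 0)
  out <- list(na = na, method = method, n_counted = n_counted,
              examined = examined, mean_psd_length = mean_psd_length)
  class(out) <- "density_estimate"
  out
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Density estimate (%s): %.3f synapses/um^3\n", x$method, x$na))
  cat(sprintf("  counted %d over %.1f %s", x$n_counted, x$examined,
              if (x$method == "size_frequency_2d") "um^2" else "um^3"))
  if (!is.na(x$mean_psd_length)) {
    cat(sprintf("; mean PSD length %.3f um", x$mean_psd_length))
  }
  cat("\n")
  invisible(x)
}

#' Size-frequency estimate of synapse density from 2D profiles
#'
#' Computes `Na = (Nd / A) / d`, where `Nd` is the number of synaptic
#' profiles not touching the exclusion boundary of their counting frame,
#' `A` the total examined area (um^2) and `d` the mean PSD length (um) of
#' the counted profiles (a single global mean over the analysed set).
#'
#' @param profiles Profile table (e.g. from [section_volume()] or
#'   [read_profile_table()]).
#' @param frames Optional frame table; when supplied, countability is
#'   computed geometrically via [classify_profiles()]. When `NULL`, the
#'   logical `excluded` column of `profiles` is used instead.
#' @param total_area Total examined area, um^2. Defaults to the summed
#'   frame areas when `frames` is given; required otherwise.
#' @param mode Counting-frame convention, see [classify_profiles()].
#' @return A [density_estimate()] with method `"size_frequency_2d"`.
#' @examples
#' pr <- data.frame(psd_length_um = c(0.2, 0.2, 0.2, 0.3),
#'                  excluded = c(FALSE, FALSE, FALSE, TRUE))
#' size_frequency_density(pr, total_area = 2)
#' @export
size_frequency_density <- function(profiles, frames = NULL,
                                   total_area = NULL,
                                   mode = c("unbiased", "all_edges")) {
  mode <- match.arg(mode)
  if (inherits(profiles, "micrograph_set")) {
    if (is.null(frames)) frames <- frames_from_sections(profiles$planes)
    profiles <- profiles$profiles
  }
  if (!is.null(frames)) {
    countable <- classify_profiles(profiles, frames, mode)$countable
    if (is.null(total_area)) {
      total_area <- sum((frames$x1 - frames$x0) * (frames$y1 - frames$y0))
    }
  } else {
    if (is.null(profiles$excluded)) {
      stop("need either frames or an 'excluded' column", call. = FALSE)
    }
    countable <- !profiles$excluded
    if (is.null(total_area)) {
      stop("total_area is required when frames are not given", call. = FALSE)
    }
  }
  if (total_area <= 0) stop("total_area must be positive", call. = FALSE)
  nd <- sum(countable)
  if (nd == 0) {
    stop("no countable profiles: mean PSD length is undefined",
         call. = FALSE)
  }
  d <- mean(profiles$psd_length_um[countable])
  density_estimate(na = (nd / total_area) / d,
                   method = "size_frequency_2d",
                   n_counted = nd, examined = total_area,
                   mean_psd_length = d)
}

#' Direct 3D synapse count with three excluding planes
#'
#' Counts synapses inside an axis-aligned subvolume using the unbiased
#' brick rule: a spine head is counted when its sphere intersects the
#' subvolume and does not cross any of the three excluding planes (the
#' low-x, low-y and low-z faces, extended to full planes). Heads crossing
#' the three opposite (inclusion) faces are counted, so that under a tiling
#' of space by such bricks every synapse is counted exactly once. Shaft
#' synapses are points and are counted by centroid inclusion when
#' `include_shaft` is `TRUE`.
#'
#' @param x A `"neuropil"` object or a spine table with filled coordinates.
#' @param subvolume Numeric length-6 `(x0, y0, z0, x1, y1, z1)`, um; defaults
#'   to the full extent when `x` is a neuropil.
#' @param include_shaft Count shaft synapses as well as spine-head synapses?
#' @return A [density_estimate()] with method `"count_3d_spines"` or
#'   `"count_3d_all"`.
#' @export
count_density_3d <- function(x, subvolume = NULL, include_shaft = FALSE) {
  if (inherits(x, "neuropil")) {
    spines <- x$spines
    if (is.null(subvolume)) subvolume <- c(0, 0, 0, x$extent)
  } else {
    spines <- x
    if (is.null(subvolume)) {
      stop("subvolume is required when x is a bare spine table",
           call. = FALSE)
    }
  }
  stopifnot(length(subvolume) == 6)
  lo <- subvolume[1:3]; hi <- subvolume[4:6]
  if (any(hi <= lo)) stop("degenerate subvolume", call. = FALSE)
  if (inherits(x, "neuropil") &&
      (any(lo < -1e-9) || any(hi > x$extent + 1e-9))) {
    stop("subvolume extends outside the parent volume", call. = FALSE)
  }
  if (anyNA(spines$x)) {
    stop("spine table has no coordinates; place the population first",
         call. = FALSE)
  }

  heads <- spines[!spines$on_shaft, , drop = FALSE]
  r <- heads$head_radius_um
  # sphere-box intersection
  dx <- pmax(lo[1] - heads$x, 0, heads$x - hi[1])
  dy <- pmax(lo[2] - heads$y, 0, heads$y - hi[2])
  dz <- pmax(lo[3] - heads$z, 0, heads$z - hi[3])
  intersects <- dx^2 + dy^2 + dz^2 < r^2
  # crossing any of the three excluding planes (extended)
  crosses <- abs(heads$x - lo[1]) < r |
    abs(heads$y - lo[2]) < r |
    abs(heads$z - lo[3]) < r
  n <- sum(intersects & !crosses)

  method <- "count_3d_spines"
  if (include_shaft) {
    sh <- spines[spines$on_shaft, , drop = FALSE]
    n <- n + sum(sh$x > lo[1] & sh$x <= hi[1] &
                   sh$y > lo[2] & sh$y <= hi[2] &
                   sh$z > lo[3] & sh$z <= hi[3])
    method <- "count_3d_all"
  }
  vol <- prod(hi - lo)
  density_estimate(na = n / vol, method = method, n_counted = n,
                   examined = vol)
}
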