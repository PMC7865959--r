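#' Virtual TEM sectioning of a synthetic neuropil
#'
#' Cuts thin slabs (default 65 nm, matching 60--70 nm ultramicrotome
#' sections) through a placed spine population and emits the measurement
#' table a microscopist would produce from the resulting micrographs: spine
#' head profile area, synaptic apposition length (SAL) and PSD length per
#' sectioned synapse. A TEM image is a projection through the slab, so the
#' observed head profile is the largest circle of the sphere--slab
#' intersection, and the apposition cap is observed through the chord of its
#' rim circle. Slabs are half-open intervals `[z0, z0 + thickness)` with z
#' increasing into the block.
#'
#' @name virtual_sectioning
#' @keywords internal
NULL

#' Sample random section planes through a volume
#'
#' Draws `n` micrograph fields: square (or rectangular) x--y windows placed
#' uniformly inside the volume footprint, each with an independent uniform
#' slab depth.
#'
#' @param n Number of micrographs.
#' @param extent Volume extent `(Lx, Ly, Lz)`, um.
#' @param field_size Field edge length(s), um: scalar or `(w, h)`.
#' @param thickness Slab thickness, um (default 0.065).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `micrograph_id`, `field_x`,
#'   `field_y`, `field_w`, `field_h`, `z0`, `thickness`.
#' @export
section_planes <- function(n, extent, field_size, thickness = 0.065,
                           seed = NULL) {
  stopifnot(n >= 1, length(extent) == 3, thickness > 0)
  fs <- rep(as.numeric(field_size), length.out = 2)
  if (any(fs <= 0) || fs[1] > extent[1] || fs[2] > extent[2]) {
    stop("field does not fit inside the volume's x-y extent", call. = FALSE)
  }
  if (thickness > extent[3]) {
    stop("slab thicker than the volume", call. = FALSE)
  }
  .with_seed(seed, {
    data.frame(
      micrograph_id = seq_len(n),
      field_x = stats::runif(n, 0, extent[1] - fs[1]),
      field_y = stats::runif(n, 0, extent[2] - fs[2]),
      field_w = fs[1], field_h = fs[2],
      z0 = stats::runif(n, 0, extent[3] - thickness),
      thickness = thickness
    )
  })
}

# Squared radius of the projected profile of a sphere cut by a slab
# [z0, z1); NA when the sphere misses the slab. The projection through the
# slab shows the largest circle of the intersection: the equatorial circle
# when the slab contains the sphere centre's plane, otherwise the circle cut
# at the nearer slab face.
.profile_radius2 <- function(cz, r, z0, z1) {
  d <- ifelse(cz < z0, z0 - cz, ifelse(cz >= z1, cz - z1, 0))
  ifelse(d >= r, NA_real_, r^2 - d^2)
}

#' Projected profile area of a sphere sectioned by a slab
#'
#' @param center Sphere centre `(x, y, z)`, um.
#' @param radius Sphere radius, um (> 0).
#' @param plane One row of a [section_planes()] table (or any list with
#'   `z0` and `thickness`).
#' @return Profile area in um^2, or `NA` if the sphere misses the slab.
#' @examples
#' pl <- list(z0 = 0, thickness = 0.065)
#' slab_sphere_profile(c(0, 0, 0.03), 0.3, pl) # equatorial: pi * 0.09
#' @export
slab_sphere_profile <- function(center, radius, plane) {
  stopifnot(length(center) == 3, radius > 0)
  rho2 <- .profile_radius2(center[3], radius, plane$z0,
                           plane$z0 + plane$thickness)
  if (is.na(rho2)) NA_real_ else pi * rho2
}

# Rim-circle geometry of the apposition cap: a cap of area `sas` on a
# sphere of radius `r` has height h = sas / (2 pi r); its rim circle sits at
# signed distance m = r - h from the centre along the cap axis with radius
# a = sqrt(r^2 - m^2).
.cap_rim <- function(r, sas) {
  h <- sas / (2 * pi * r)
  m <- r - h
  list(m = m, a = sqrt(pmax(r^2 - m^2, 0)))
}

# Chord of a tilted circle (centre z `pz`, radius `a`, axis z-component
# `uz`) cut by the slab [z0, z1), as seen in projection: the full diameter
# when the slab contains the circle's centre plane, otherwise the chord at
# the nearer slab face. The circle's half-extent along z is a * wz with
# wz = sqrt(1 - uz^2). NA when the circle misses the slab.
.rim_chord <- function(pz, a, uz, z0, z1) {
  a <- rep_len(a, length(pz))
  wz <- rep_len(sqrt(pmax(1 - uz^2, 0)), length(pz))
  d <- ifelse(pz < z0, z0 - pz, ifelse(pz >= z1, pz - z1, 0))
  hz <- a * wz
  out <- rep(NA_real_, length(d))
  inside <- d == 0
  out[inside] <- 2 * a[inside]
  partial <- !inside & d < hz
  out[partial] <- 2 * a[partial] *
    sqrt(1 - (d[partial] / hz[partial])^2)
  out
}

#' Inclusion and measurement criteria for virtual sectioning
#'
#' @param min_psd_length Visibility threshold, um: a profile is emitted only
#'   if its PSD chord reaches this length (default 0.05 um, below the
#'   shortest PSD observed in tissue, ~0.09 um). Stands in for the
#'   requirement that the PSD and cleft be clearly identifiable.
#' @param psd_sal_ratio_mean Mean of the per-synapse PSD/SAL rim-diameter
#'   ratio (default 0.75, the ratio of the measured mean lengths
#'   0.217/0.291).
#' @param psd_sal_ratio_conc Beta concentration (a + b) of the ratio
#'   distribution; the default 20 gives a ratio SD of about 0.095.
#' @param min_edge_on Orientation visibility criterion: a synapse is
#'   measurable only when its apposition plane is steep enough relative to
#'   the section, `sqrt(1 - uz^2) >= min_edge_on` where `uz` is the z
#'   component of the apposition axis. The default 0.5 (plane within 60
#'   degrees of vertical) models the requirement that the synaptic cleft be
#'   clearly distinguishable: a PSD cut en face shows no cleft line and
#'   cannot be measured.
#' @param frame_mode Counting-frame convention used when flagging emitted
#'   profiles: `"unbiased"` (two exclusion edges) or `"all_edges"`.
#' @return A list of class `"section_criteria"`.
#' @export
section_criteria <- function(min_psd_length = 0.05,
                             psd_sal_ratio_mean = 0.75,
                             psd_sal_ratio_conc = 20,
                             min_edge_on = 0.5,
                             frame_mode = c("unbiased", "all_edges")) {
  stopifnot(min_psd_length >= 0,
            psd_sal_ratio_mean > 0, psd_sal_ratio_mean <= 1,
            psd_sal_ratio_conc > 0,
            min_edge_on >= 0, min_edge_on < 1)
  out <- list(min_psd_length = min_psd_length,
              psd_sal_ratio_mean = psd_sal_ratio_mean,
              psd_sal_ratio_conc = psd_sal_ratio_conc,
              min_edge_on = min_edge_on,
              frame_mode = match.arg(frame_mode))
  class(out) <- "section_criteria"
  out
}

#' Section a neuropil volume into 2D profile tables
#'
#' For every spine head intersecting a slab, the head profile area is the
#' projected sphere--slab circle. The apposition cap (whose area is the SAS)
#' is sectioned through the chord of its rim circle, giving the SAL; the PSD
#' is modelled as a concentric sub-cap whose rim diameter is a
#' Beta-distributed fraction (drawn once per synapse) of the SAL rim
#' diameter, reflecting that the electron-dense PSD occupies part of the
#' apposition zone, and its own rim chord gives the PSD length. A synapse is
#' emitted only when its PSD chord reaches the visibility threshold -- the
#' measurable object is the PSD, exactly as in tissue, which is what makes
#' the size-frequency estimator consistent -- and when its head profile
#' overlaps the micrograph field. Shaft synapses have no head sphere and are
#' not sectioned.
#'
#' @param volume A `"neuropil"` object from [place_in_volume()].
#' @param planes A [section_planes()] table.
#' @param criteria A [section_criteria()] configuration.
#' @param seed Integer seed (PSD/SAL ratio draws); the run is deterministic
#'   given the seed.
#' @return An object of class `"micrograph_set"`: list with `planes`,
#'   `profiles` (a `data.frame` with columns `micrograph_id`, `spine_id`,
#'   `center_x_um`, `center_y_um`, `radius_um`, `head_area_um2`,
#'   `sal_length_um`, `psd_length_um`, `excluded`), and `total_area_um2`.
#'   `excluded` flags profiles touching the exclusion boundary of their
#'   field's counting frame under `criteria$frame_mode`.
#' @export
section_volume <- function(volume, planes, criteria = section_criteria(),
                           seed = NULL) {
  stopifnot(inherits(volume, "neuropil"), inherits(criteria, "section_criteria"))
  if (!is.data.frame(planes) || nrow(planes) == 0) {
    stop("empty section-plane list", call. = FALSE)
  }
  sp <- volume$spines
  heads <- sp[!sp$on_shaft, , drop = FALSE]

  .with_seed(seed, {
    # PSD/SAL rim-diameter ratio: one draw per synapse, a fixed anatomical
    # property of that synapse across every slab that cuts it
    fr <- stats::rbeta(nrow(heads),
                       criteria$psd_sal_ratio_mean * criteria$psd_sal_ratio_conc,
                       (1 - criteria$psd_sal_ratio_mean) * criteria$psd_sal_ratio_conc)
    sal_rim <- .cap_rim(heads$head_radius_um, heads$sas_um2)
    psd_a <- fr * sal_rim$a
    psd_m <- sqrt(pmax(heads$head_radius_um^2 - psd_a^2, 0))

    rows <- vector("list", nrow(planes))
    for (k in seq_len(nrow(planes))) {
      pl <- planes[k, ]
      z0 <- pl$z0; z1 <- pl$z0 + pl$thickness

      rho2 <- .profile_radius2(heads$z, heads$head_radius_um, z0, z1)
      hit <- which(!is.na(rho2))
      if (length(hit) == 0) { rows[[k]] <- NULL; next }

      h <- heads[hit, , drop = FALSE]
      sal <- .rim_chord(h$z + sal_rim$m[hit] * h$axis_z, sal_rim$a[hit],
                        h$axis_z, z0, z1)
      psd <- .rim_chord(h$z + psd_m[hit] * h$axis_z, psd_a[hit],
                        h$axis_z, z0, z1)
      # the apposition zone contains the PSD, so the measured SAL can never
      # fall short of the PSD chord; the rim-chord approximation may, rarely
      sal <- pmax(sal, psd, na.rm = TRUE)
      sal[is.na(psd)] <- NA_real_

      rp <- sqrt(rho2[hit])
      in_field <- h$x + rp > pl$field_x & h$x - rp < pl$field_x + pl$field_w &
        h$y + rp > pl$field_y & h$y - rp < pl$field_y + pl$field_h
      edge_on <- sqrt(pmax(1 - h$axis_z^2, 0)) >= criteria$min_edge_on
      keep <- !is.na(psd) & psd >= criteria$min_psd_length & in_field &
        edge_on
      if (!any(keep)) { rows[[k]] <- NULL; next }

      rows[[k]] <- data.frame(
        micrograph_id = pl$micrograph_id,
        spine_id = h$spine_id[keep],
        center_x_um = h$x[keep],
        center_y_um = h$y[keep],
        radius_um = rp[keep],
        head_area_um2 = pi * rho2[hit][keep],
        sal_length_um = sal[keep],
        psd_length_um = psd[keep]
      )
    }
    profiles <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(profiles)) {
      profiles <- data.frame(
        micrograph_id = integer(), spine_id = integer(),
        center_x_um = numeric(), center_y_um = numeric(),
        radius_um = numeric(), head_area_um2 = numeric(),
        sal_length_um = numeric(), psd_length_um = numeric()
      )
    }
    frames <- frames_from_sections(planes)
    cl <- classify_profiles(profiles, frames, mode = criteria$frame_mode)
    profiles$excluded <- !cl$countable

    out <- list(planes = planes,
                profiles = profiles,
                total_area_um2 = sum(planes$field_w * planes$field_h),
                criteria = criteria)
    class(out) <- "micrograph_set"
    out
  })
}

#' @export
print.micrograph_set <- function(x, ...) {
  cat(sprintf(
    "Virtual micrographs: %d fields, %.0f um^2 examined, %d synaptic profiles (%d countable)\n",
    nrow(x$planes), x$total_area_um2, nrow(x$profiles),
    sum(!x$profiles$excluded)))
  invisible(x)
}
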