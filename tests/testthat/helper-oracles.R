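# Independent oracles used across the suite. These deliberately take the
# slowest, most literal route to each quantity so that they share no code
# path with the implementation they check.

# Spearman coefficient by the classical rank-difference formula (ties-free
# inputs only): 1 - 6 * sum(d^2) / (n (n^2 - 1)).
oracle_spearman_noties <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Area of the projection of (sphere intersect slab) onto the xy plane by
# brute force: uniform points in the xy bounding square, each classified by
# scanning a fine z grid through the slab for sphere membership.
oracle_projection_area_mc <- function(center, radius, z0, z1,
                                      n_pts = 50000, n_z = 400) {
  half <- radius * 1.05
  px <- runif(n_pts, center[1] - half, center[1] + half)
  py <- runif(n_pts, center[2] - half, center[2] + half)
  zg <- seq(z0, z1, length.out = n_z)
  inside <- rep(FALSE, n_pts)
  for (z in zg) {
    inside <- inside |
      ((px - center[1])^2 + (py - center[2])^2 + (z - center[3])^2 <=
         radius^2)
  }
  mean(inside) * (2 * half)^2
}

# Counting-frame classification by exhaustive geometry: dense samples along
# the circle boundary and along the forbidden line, no reuse of the
# package's distance formulas.
oracle_frame_classify <- function(cx, cy, rp, x0, y0, x1, y1,
                                  mode = "unbiased", n_samp = 4000) {
  th <- seq(0, 2 * pi, length.out = n_samp)
  bx <- cx + rp * cos(th)
  by <- cy + rp * sin(th)
  in_rect <- function(px, py) px > x0 & px < x1 & py > y0 & py < y1
  overlaps <- any(in_rect(bx, by)) || in_rect(cx, cy)
  if (mode == "all_edges") {
    return(all(in_rect(bx, by)))
  }
  # forbidden line: bottom segment plus left edge extended far upward
  lx <- c(seq(x0, x1, length.out = n_samp), rep(x0, n_samp))
  ly <- c(rep(y0, n_samp), seq(y0, y1 + 10 * rp + 10, length.out = n_samp))
  touches <- any((lx - cx)^2 + (ly - cy)^2 < rp^2)
  overlaps && !touches
}

# Mean of the truncated head-volume distribution by direct numerical
# integration of the density (independent of the sampler).
oracle_truncated_mean <- function(params) {
  if (params$v_family == "lognormal") {
    Z <- plnorm(params$v_max, params$v_meanlog, params$v_sdlog) -
      plnorm(params$v_min, params$v_meanlog, params$v_sdlog)
    integrate(function(x) {
      x * dlnorm(x, params$v_meanlog, params$v_sdlog) / Z
    }, params$v_min, params$v_max, rel.tol = 1e-10)$value
  } else {
    Z <- pgamma(params$v_max, params$v_shape, params$v_rate) -
      pgamma(params$v_min, params$v_shape, params$v_rate)
    integrate(function(x) {
      x * dgamma(x, params$v_shape, params$v_rate) / Z
    }, params$v_min, params$v_max, rel.tol = 1e-10)$value
  }
}

# Tiny deterministic profile/spine tables for io round trips.
make_profile_fixture <- function() {
  data.frame(spine_id = 1:3, micrograph_id = c(1L, 1L, 2L),
             head_area_um2 = c(0.12, 0.08, 0.2),
             psd_length_um = c(0.2, 0.15, 0.3),
             sal_length_um = c(0.25, 0.2, 0.31),
             excluded = c(FALSE, TRUE, FALSE))
}

make_spine_fixture <- function() {
  data.frame(spine_id = 1:5,
             volume_um3 = c(0.01, 0.05, 0.1, 0.2, 0.3),
             sas_um2 = c(0.02, 0.06, 0.1, 0.15, 0.2),
             on_shaft = FALSE,
             x = c(1, 2, 3, 4, 5), y = 1, z = 0.5)
}

# Hand-built one-spine neuropil for targeted sectioning/counting cases.
make_single_spine_neuropil <- function(volume, sas, axis, center,
                                       extent = c(4, 4, 2)) {
  r <- (3 * volume / (4 * pi))^(1 / 3)
  sp <- data.frame(spine_id = 1L, x = center[1], y = center[2],
                   z = center[3],
                   head_volume_um3 = volume, head_radius_um = r,
                   sas_um2 = sas,
                   axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
                   on_shaft = FALSE, shape_class = "mushroom")
  structure(list(spines = sp, extent = extent,
                 true_density = 1 / prod(extent), seed = NULL,
                 tolerance = 0),
            class = "neuropil")
}
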