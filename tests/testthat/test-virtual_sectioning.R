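test_that("slab-sphere profile areas match closed cases and a brute-force projection", {
  pl <- list(z0 = 0, thickness = 0.065)
  # slab contains the equatorial plane -> equatorial circle
  expect_equal(slab_sphere_profile(c(0, 0, 0.03), 0.3, pl), pi * 0.09)
  # centre 0.25 above the slab's top face
  expect_equal(slab_sphere_profile(c(0, 0, 0.065 + 0.25), 0.3, pl),
               pi * (0.09 - 0.0625))
  # no intersection
  expect_true(is.na(slab_sphere_profile(c(0, 0, 0.065 + 0.5), 0.3, pl)))

  set.seed(61)
  for (cz in c(0.02, 0.2, 0.33)) {
    a_mc <- oracle_projection_area_mc(c(0, 0, cz), 0.3, 0, 0.065)
    expect_equal(slab_sphere_profile(c(0, 0, cz), 0.3, pl), a_mc,
                 tolerance = 0.02)
  }
})

test_that("mean profile area over random slabs matches 1D quadrature", {
  r <- 0.25; t <- 0.065
  # all slab positions that intersect the sphere: z0 in (cz - r - t, cz + r)
  cz <- 1
  set.seed(62)
  z0 <- runif(1e5, cz - r - t, cz + r)
  areas <- pi * spinestereo:::.profile_radius2(cz, r, z0, z0 + t)
  # quadrature of the projected-circle area over uniform slab offsets,
  # derived independently: the profile radius^2 is r^2 minus the squared
  # gap between the centre and the nearer slab face
  integrand <- function(z0) {
    gap <- pmax(z0 - cz, cz - (z0 + t), 0)
    pi * (r^2 - gap^2)
  }
  expected <- integrate(integrand, cz - r - t, cz + r)$value / (2 * r + t)
  expect_equal(mean(areas), expected, tolerance = 0.02)
  # internal vectorised kernel agrees with the exported scalar interface
  expect_equal(areas[1],
               slab_sphere_profile(c(0, 0, cz), r,
                                   list(z0 = z0[1], thickness = t)))
})

test_that("a bisected spine with in-plane apposition axis shows the full rim diameters", {
  V <- 0.1; sas <- 0.12
  r <- (3 * V / (4 * pi))^(1 / 3)
  h <- sas / (2 * pi * r)
  a <- sqrt(r^2 - (r - h)^2)       # apposition-cap rim radius
  np <- make_single_spine_neuropil(V, sas, axis = c(1, 0, 0),
                                   center = c(2, 2, 1))
  planes <- data.frame(micrograph_id = 1L, field_x = 0, field_y = 0,
                       field_w = 4, field_h = 4,
                       z0 = 1 - 0.065 / 2, thickness = 0.065)
  sect <- section_volume(np, planes, section_criteria(), seed = 9)
  pr <- sect$profiles
  expect_equal(nrow(pr), 1)
  expect_equal(pr$head_area_um2, pi * r^2)       # equatorial profile
  expect_equal(pr$sal_length_um, 2 * a)          # full SAL rim diameter
  # PSD rim diameter: the per-synapse ratio times the SAL rim diameter
  expect_lte(pr$psd_length_um, pr$sal_length_um)
  expect_gt(pr$psd_length_um, 0)
})

test_that("sectioning respects its invariants on default simulations", {
  pop <- generate_population(380, spine_params(), seed = 21)
  np <- place_in_volume(pop, c(10, 10, 1.9), seed = 21)
  planes <- section_planes(75, np$extent, sqrt(1900 / 75), seed = 22)
  s1 <- section_volume(np, planes, section_criteria(), seed = 23)
  s2 <- section_volume(np, planes, section_criteria(), seed = 23)
  expect_identical(s1$profiles, s2$profiles)

  pr <- s1$profiles
  expect_gt(nrow(pr), 0)
  expect_true(all(pr$head_area_um2 > 0))
  expect_true(all(pr$psd_length_um <= pr$sal_length_um + 1e-12))
  expect_true(all(pr$psd_length_um >= section_criteria()$min_psd_length))

  # no profile from a spine whose sphere misses the slab (brute force)
  sp <- np$spines
  for (k in seq_len(nrow(pr))) {
    row <- pr[k, ]
    spine <- sp[sp$spine_id == row$spine_id, ]
    plane <- planes[planes$micrograph_id == row$micrograph_id, ]
    gap <- max(plane$z0 - spine$z, spine$z - (plane$z0 + plane$thickness), 0)
    expect_lt(gap, spine$head_radius_um)
  }

  # projection through the slab means 2D areas understate 3D sizes
  heads <- sp[!sp$on_shaft, ]
  expect_lt(mean(pr$head_area_um2),
            volume_to_equivalent_area(mean(heads$head_volume_um3)))

  # a volume with no spines yields empty micrographs
  empty_np <- place_in_volume(pop[0, ], c(10, 10, 1.9), seed = 1)
  s0 <- section_volume(empty_np, planes, section_criteria(), seed = 1)
  expect_equal(nrow(s0$profiles), 0)

  expect_error(section_volume(np, planes[0, ], section_criteria()),
               "empty")
})
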