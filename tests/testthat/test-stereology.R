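test_that("the size-frequency formula evaluates Na = (Nd/A)/d with edge exclusion", {
  pr <- data.frame(psd_length_um = c(0.5, 0.5),
                   excluded = c(FALSE, FALSE))
  est <- size_frequency_density(pr, total_area = 1)
  expect_equal(est$na, 4.0)
  expect_equal(est$n_counted, 2L)

  pr2 <- data.frame(psd_length_um = c(0.2, 0.2, 0.2, 0.9),
                    excluded = c(FALSE, FALSE, FALSE, TRUE))
  est2 <- size_frequency_density(pr2, total_area = 2)
  expect_equal(est2$na, (3 / 2) / 0.2)   # 7.5
  expect_equal(est2$mean_psd_length, 0.2)

  all_excluded <- data.frame(psd_length_um = 0.2, excluded = TRUE)
  expect_error(size_frequency_density(all_excluded, total_area = 1),
               "no countable")
  expect_error(size_frequency_density(pr), "total_area")
})

test_that("counting-frame classification matches exhaustive geometry in both modes", {
  set.seed(31)
  frame <- data.frame(micrograph_id = 1L, x0 = 1, y0 = 1, x1 = 5, y1 = 5)
  n <- 300
  profiles <- data.frame(
    micrograph_id = 1L,
    center_x_um = runif(n, 0, 6), center_y_um = runif(n, 0, 6),
    radius_um = runif(n, 0.02, 0.6),
    psd_length_um = runif(n, 0.05, 0.4)
  )
  for (mode in c("unbiased", "all_edges")) {
    got <- classify_profiles(profiles, frame, mode = mode)$countable
    want <- mapply(oracle_frame_classify,
                   profiles$center_x_um, profiles$center_y_um,
                   profiles$radius_um,
                   MoreArgs = list(x0 = 1, y0 = 1, x1 = 5, y1 = 5,
                                   mode = mode))
    expect_identical(got, unname(want))
  }
  # all-edges is never more permissive than the unbiased frame
  u <- classify_profiles(profiles, frame, "unbiased")$countable
  a <- classify_profiles(profiles, frame, "all_edges")$countable
  expect_true(all(!a | u))
})

test_that("under a tiling of frames every profile is counted exactly once", {
  set.seed(32)
  n <- 200
  # profiles on a torus-like central region, frames tile a 3x3 block of 2x2
  profiles <- data.frame(
    micrograph_id = 1L,
    center_x_um = runif(n, 2, 4), center_y_um = runif(n, 2, 4),
    radius_um = runif(n, 0.05, 0.45),
    psd_length_um = 0.2
  )
  counted <- rep(0, n)
  for (ix in 0:2) for (iy in 0:2) {
    fr <- data.frame(micrograph_id = 1L, x0 = 2 * ix, y0 = 2 * iy,
                     x1 = 2 * ix + 2, y1 = 2 * iy + 2)
    counted <- counted + classify_profiles(profiles, fr, "unbiased")$countable
  }
  expect_true(all(counted == 1))
})

test_that("3D counting obeys the excluding-plane rule and shaft toggling", {
  pop <- generate_population(380, spine_params(), seed = 41)
  np <- place_in_volume(pop, c(10, 10, 1.9), seed = 41)
  est_sp <- count_density_3d(np)
  est_all <- count_density_3d(np, include_shaft = TRUE)
  # whole heads are inside the block, so the full-volume count is exact
  expect_equal(est_all$na, 2.0)
  expect_equal(est_sp$na, sum(!np$spines$on_shaft) / 190)
  expect_gte(est_all$na, est_sp$na)

  # a head overlapping the low-x face of a subvolume is not counted
  one <- make_single_spine_neuropil(0.1, 0.1, c(0, 0, 1), c(2.05, 2, 1))
  r <- one$spines$head_radius_um
  sub <- c(2, 0, 0, 4, 4, 2)      # low-x plane at x = 2, centre 0.05 away
  expect_lt(2.05 - 2, r)
  expect_equal(count_density_3d(one$spines, sub)$n_counted, 0L)
  # moved clear of the plane it is counted
  one$spines$x <- 2 + r + 0.01
  expect_equal(count_density_3d(one$spines, sub)$n_counted, 1L)

  expect_error(count_density_3d(np, c(0, 0, 0, 0, 4, 2)), "degenerate")
  expect_error(count_density_3d(np, c(0, 0, 0, 11, 4, 1)), "outside")
})

test_that("the brick-counting rule is unbiased for interior subvolumes", {
  p <- spine_params()
  sub <- c(1, 1, 1, 5, 5, 5)
  nas <- vapply(1:40, function(s) {
    pop <- generate_population(432, p, seed = 5000 + s)
    np <- place_in_volume(pop, c(6, 6, 6), seed = 5000 + s,
                          contain = FALSE)
    count_density_3d(np, sub, include_shaft = TRUE)$na
  }, numeric(1))
  se <- sd(nas) / sqrt(length(nas))
  expect_lt(abs(mean(nas) - 2.0), 3 * se)
})
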