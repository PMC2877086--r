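test_that("digitized balls read sphericity within 3% of 1", {
  for (r in c(8, 12, 16)) {
    b <- make_fixture("ball", r = r, L = 2 * r + 8)
    s <- sphericity(b)
    expect_gt(s, 0.97)
    expect_lt(s, 1.03)
  }
  # the calibration anchor: r = 12
  s12 <- sphericity(make_fixture("ball", r = 12, L = 32))
  expect_true(s12 >= 0.97 && s12 <= 1.01)
  expect_error(sphericity(array(FALSE, dim = c(4, 4, 4))), "empty")
})

test_that("cube sphericity converges toward the continuum value with refinement", {
  cont <- (pi / 6)^(1 / 3)
  err <- vapply(c(10, 16, 32), function(a) {
    abs(sphericity(make_fixture("cube", a = a, L = a + 6)) / cont - 1)
  }, numeric(1))
  # smoothing chamfers the sharp edges; the relative bias shrinks ~ 1/a
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
  expect_gt(sphericity(make_fixture("cube", a = 32, L = 38)), cont)  # bias is upward
})

test_that("digitized disks read circularity within 3% of 1; squares converge to pi/4", {
  for (r in c(8, 12, 16, 20)) {
    L <- 2 * r + 8
    d <- make_fixture("ball", r = r, L = L)[, , L %/% 2 + 1]
    cc <- circularity(d)
    expect_gt(cc, 0.97)
    expect_lt(cc, 1.02)
  }
  sq_err <- vapply(c(10, 32), function(a) {
    m <- matrix(0, a + 8, a + 8); m[5:(a + 4), 5:(a + 4)] <- 1
    abs(circularity(m) / (pi / 4) - 1)
  }, numeric(1))
  expect_lt(sq_err[2], sq_err[1])
  expect_lt(sq_err[2], 0.05)
  expect_error(circularity(matrix(0, 5, 5)), "empty")
})

test_that("splitting mass into two distant pieces rescales s and c predictably", {
  # 3D: equal distant balls double A and V: s drops by 2^(-1/3)
  one <- make_fixture("ball", r = 10, L = 64)
  two <- make_fixture("two_balls", r = 10, separation = 36, L = 64)
  expect_equal(sphericity(two) / sphericity(one), 2^(-1 / 3), tolerance = 0.02)
  # 2D: two identical disjoint disks halve the circularity
  d1 <- make_fixture("ball", r = 10, L = 28)[, , 15]
  d2 <- matrix(0, 64, 28)
  d2[4:31, ] <- d1; d2[34:61, ] <- d1
  expect_equal(circularity(d2) / circularity(d1), 0.5, tolerance = 0.02)
})

test_that("mid-plane circularities average correctly and flag empty planes", {
  # centered ball: all three planes identical, cbar equals the disk value
  b <- make_fixture("ball", r = 10, L = 32)
  mp <- mean_midplane_circularity(b)
  expect_equal(unname(mp$circ["xy"]), unname(mp$circ["xz"]))
  expect_equal(unname(mp$circ["xy"]), unname(mp$circ["yz"]))
  expect_equal(mp$mean_circularity, circularity(b[, , 17]))
  expect_equal(unname(mp$n_components), c(1L, 1L, 1L))
  expect_length(mp$empty_planes, 0)

  # randomly rotated ellipsoid: cbar matches recomputation from the same masks
  rot <- random_rotation(seed = 42)
  e <- make_fixture("ellipsoid", a = 12, b = 8, c = 5, rot = rot, L = 40)
  mp_e <- mean_midplane_circularity(e)
  mid <- 21L
  manual <- mean(c(circularity(e[, , mid]), circularity(e[, mid, ]),
                   circularity(e[mid, , ])))
  expect_equal(mp_e$mean_circularity, manual)

  # a small ball displaced along z misses the XY midplane: excluded and flagged
  off <- array(FALSE, dim = c(40, 40, 40))
  ctr <- c(20, 20, 32)
  for (z in 27:37) for (y in 15:25) for (x in 15:25)
    off[x, y, z] <- sum((c(x, y, z) - ctr)^2) <= 25
  mp_off <- mean_midplane_circularity(off)
  expect_true("xy" %in% mp_off$empty_planes)
  expect_true(is.na(mp_off$circ["xy"]))
  expect_false(is.na(mp_off$mean_circularity))
})

test_that("connected components respect the 26/8 and 6/4 conventions", {
  b <- make_fixture("ball", r = 6, L = 20)
  expect_equal(connected_components(b)$n, 1L)
  expect_equal(connected_components(b[, , 11])$n, 1L)

  # two cubes sharing only a corner vertex: one 26-component, two 6-components
  v <- array(FALSE, dim = c(10, 10, 10))
  v[2:4, 2:4, 2:4] <- TRUE
  v[5:7, 5:7, 5:7] <- TRUE
  expect_equal(connected_components(v, connectivity = 26)$n, 1L)
  expect_equal(connected_components(v, connectivity = 6)$n, 2L)
  # 2D diagonal touch: 8-connected joins, 4-connected separates
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE; m[4:5, 4:5] <- TRUE
  expect_equal(connected_components(m, connectivity = 8)$n, 1L)
  expect_equal(connected_components(m, connectivity = 4)$n, 2L)

  # the U-tube: connected in 3D, disconnected in its mid-height section
  u <- make_fixture("u_tube", r = 5, L = 48)
  expect_equal(connected_components(u, connectivity = 26)$n, 1L)
  mid_section <- u[, , 25]
  expect_equal(connected_components(mid_section, connectivity = 8)$n, 2L)
  # labels cover exactly the foreground
  lab <- connected_components(u)$labels
  expect_equal(lab != 0L, u)
})

test_that("boundary-reach time is the first touching snapshot, else censored", {
  rec <- data.frame(day = c(0, 1, 2, 3), touches_boundary = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(boundary_reach_time(rec), list(day = 2, censored = FALSE))
  rec2 <- data.frame(day = 0:3, touches_boundary = rep(FALSE, 4))
  out <- boundary_reach_time(rec2)
  expect_true(out$censored)
  expect_true(is.na(out$day))
  # a seed already touching a face reports day 0
  L <- 10
  sigma <- array(1L, dim = c(L, L, L)); sigma[1, 5, 5] <- 2L
  sim <- sim_from_sigma(sigma, c(0L, 1L), quiet_config(L = L))
  expect_true(sim_touches_boundary(sim))
  expect_equal(boundary_reach_time(morphometrics_record(sim)),
               list(day = 0, censored = FALSE))
})

test_that("the characteristic-time fit recovers, flags, and rescales correctly", {
  # parameter recovery from noisy quasi-Gaussian data
  set.seed(99)
  day <- seq(0, 40, by = 2)
  s <- 0.9 * exp(-(day / 20)^2) + rnorm(length(day), sd = 0.01)
  fit <- fit_characteristic_time(day, s)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau - 20) / 20, 0.05)
  expect_lt(abs(fit$amplitude - 0.9) / 0.9, 0.05)

  # constant s: tau unidentified, flagged rather than silently returned
  flat <- fit_characteristic_time(0:10, rep(0.8, 11))
  expect_false(flat$converged)
  expect_match(flat$message, "flat|unidentified|singular|converge", ignore.case = TRUE)

  # time rescaling t -> 2t doubles tau (noise-free)
  s0 <- 0.85 * exp(-(day / 15)^2)
  f1 <- fit_characteristic_time(day, s0)
  f2 <- fit_characteristic_time(2 * day, s0)
  expect_equal(f2$tau / f1$tau, 2, tolerance = 1e-6)
  expect_error(fit_characteristic_time(1:3, c(1, 2, 3)), "at least 5")
})

test_that("fixture volumes match their analytic values", {
  b <- make_fixture("ball", r = 12, L = 64)
  expect_lt(abs(sum(b) - 4 / 3 * pi * 12^3) / (4 / 3 * pi * 12^3), 0.01)
  expect_equal(sum(make_fixture("cube", a = 10, L = 32)), 1000L)
  e <- make_fixture("ellipsoid", a = 10, b = 7, c = 4, L = 32)
  expect_lt(abs(sum(e) - 4 / 3 * pi * 280) / (4 / 3 * pi * 280), 0.02)
  expect_error(make_fixture("two_balls", r = 10, separation = 5, L = 40), "disjoint")
  expect_error(make_fixture("ball", r = 20, L = 30), "fit")
})

test_that("snapshot records agree with direct recomputation from the mask", {
  cfg <- sim_config(L = 20, seed = 2, G = 50, g = 0.3, snapshot_interval = 20)
  sim <- cpm_sim(cfg)
  run_mcs(sim, 40)
  rec <- morphometrics_record(sim)
  mask <- tumor_mask(sim)
  expect_identical(rec$tumor_volume, sum(mask))
  expect_identical(rec$sphericity, sphericity(mask))
  expect_identical(rec$mean_circularity, mean_midplane_circularity(mask)$mean_circularity)
  expect_identical(rec$n_components_3d, connected_components(mask)$n)
  expect_identical(rec$day, rec$mcs / cfg$mcs_per_day)
})
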