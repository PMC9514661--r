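test_that("activation generation is deterministic and structurally valid", {
  p <- default_parameter_set()
  a <- gen_activation_profiles(p)
  b <- gen_activation_profiles(p)
  expect_identical(a, b)
  expect_length(a, 9L)
  sg <- (0:9) / 9
  for (nm in names(a)) {
    cp <- a[[nm]]$control_points
    expect_length(cp, 10L)
    expect_true(all(cp >= 0 & cp <= 1))
    expect_lte(cp[1], 0.2)
    expect_lte(cp[10], 0.2)
    amax <- sg[which.max(cp)]
    if (nm %in% c("tib_ant", "edl", "ehl")) {
      expect_lte(amax, 0.4)
    } else if (max(cp) > 0) {
      expect_gte(amax, 0.6)
    }
  }
})

test_that("weight jitter is seed-stable and seed-sensitive", {
  p <- default_parameter_set()
  p$activation$jitter <- 0.05
  p$sim$seed <- 42L
  a1 <- gen_activation_profiles(p)
  a2 <- gen_activation_profiles(p)
  expect_identical(a1, a2)
  p$sim$seed <- 43L
  a3 <- gen_activation_profiles(p)
  expect_false(identical(a1, a3))
})

test_that("all-zero weights produce all-zero profiles", {
  p <- default_parameter_set()
  for (nm in names(p$activation$shapes))
    p$activation$shapes[[nm]]$weight <- 0
  p$activation$coactivation <- list()
  prof <- gen_activation_profiles(p)
  for (nm in names(prof))
    expect_identical(prof[[nm]]$control_points, rep(0, 10))
})

test_that("the generated trajectory spans the stance and is smooth", {
  b <- ag_bundle()
  traj <- b$trajectory
  expect_equal(traj$duration, 4.09)
  ## twice-differentiable coordinates: spline second derivative is finite
  ## and the first derivative is continuous across samples
  for (t in seq(0.2, 3.9, by = 0.5)) {
    h <- 1e-4
    v1 <- plane_pose(traj, t - h)$v
    v2 <- plane_pose(traj, t + h)$v
    expect_lt(max(abs(v2 - v1)), 0.05)  # no velocity jumps
  }
})

test_that("only the heel can contact at heel strike, only toes at toe off", {
  b <- ag_bundle()
  m <- build_foot_model("ARCHED", b$params)
  traj <- b$trajectory
  qs <- attr(traj, "qs")

  depths <- function(t, q) {
    pl <- plane_pose(traj, t)
    cw <- archgait:::sphere_centers_world(m, q)
    vapply(seq_len(5), function(i)
      m$sphere_radius[i] - sum(pl$n * (cw[, i] - pl$p)), 0)
  }
  d0 <- depths(0, qs$q[1, ])
  expect_true(all(d0[m$sphere_names != "heel"] < 1e-4))
  dT <- depths(4.09, qs$q[nrow(qs$q), ])
  expect_true(all(dT[!m$sphere_names %in% c("hallux", "toe5")] < 1e-4))
})

test_that("the plane surface rolls without slip under the load centroid", {
  b <- ag_bundle()
  traj <- b$trajectory
  qs <- attr(traj, "qs")
  tp <- b$params$trajectory
  copf <- archgait:::knot_spline(tp$cop_knots$s, tp$cop_knots$x)
  hfun <- stats::splinefun(qs$s, qs$h_refined, method = "natural")
  for (s in seq(0.1, 0.9, by = 0.2)) {
    t <- s * traj$duration
    pl <- plane_pose(traj, t)
    cw <- c(copf(s), hfun(s), tp$z_amp_m * sin(pi * s))
    vmat <- pl$v + archgait:::cross3(pl$w, cw - pl$p)
    vtan <- vmat - sum(pl$n * vmat) * pl$n
    expect_lt(sqrt(sum(vtan^2)), 1e-3)  # < 1 mm/s tangential
  }
})

test_that("zero roll and yaw amplitudes still generate a usable trajectory", {
  p <- default_parameter_set()
  p$trajectory$roll_amp_deg <- 0
  p$trajectory$yaw_amp_deg <- 0
  p$trajectory$z_amp_m <- 0
  p$trajectory$n_refine <- 0
  traj <- suppressWarnings(gen_ground_trajectory(p))
  expect_s3_class(traj, "ground_trajectory")
  expect_true(all(traj$samples$roll == 0))
  expect_true(all(traj$samples$yaw == 0))
})

test_that("the default bundle is cached, valid and at the 82 kg scale", {
  b1 <- ag_bundle()
  b2 <- default_input_bundle()
  expect_identical(b1, b2)  # cached
  expect_silent(validate_params(b1$params))
  expect_equal(b1$params$subject$mass_kg, 82)
  expect_equal(b1$params$trajectory$stance_duration, 4.09)
})
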