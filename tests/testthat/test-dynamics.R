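test_that("accelerations vanish for an unforced model", {
  m <- build_foot_model("ARCHED")
  set.seed(5)
  for (i in 1:3) {
    q <- runif(5, -0.3, 0.3)
    qdd <- equations_of_motion(m, q, numeric(5), tensions = NULL,
                               plane = NULL, gravity = FALSE,
                               passive = FALSE)
    expect_equal(qdd, numeric(5), tolerance = 1e-10)
  }
  expect_error(equations_of_motion(m, rep(NaN, 5), numeric(5)), "finite")
})

test_that("the mass matrix is symmetric positive definite", {
  m <- build_foot_model("FLATFOOT")
  set.seed(8)
  for (i in 1:5) {
    q <- runif(5, -0.4, 0.4)
    M <- mass_matrix(m, q)
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_true(all(eigen(M, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("locking all joints but the ankle reduces to the analytic pendulum", {
  ## oracle: composite rigid-body inertia and gravity moment about the
  ## ankle axis from plain Steiner sums over the segment parameters, at the
  ## reference pose (all rotations identity)
  p <- default_parameter_set()
  m <- build_foot_model("ARCHED", p)
  a <- m$axis[, 1]
  o <- m$jo[, 1]
  I_axis <- 0
  tau_g <- 0
  g <- p$subject$gravity
  for (k in seq_len(5)) {
    com <- m$com[, k]
    r <- com - o
    r_par <- sum(r * a) * a
    r_perp <- r - r_par
    I_axis <- I_axis + as.numeric(t(a) %*% m$inertia[, , k] %*% a) +
      m$mass[k] * sum(r_perp^2)
    ## moment of gravity (0, -m g, 0) at the com about the axis
    f <- c(0, -m$mass[k] * g, 0)
    tau_g <- tau_g + sum((c(r[2] * f[3] - r[3] * f[2],
                            r[3] * f[1] - r[1] * f[3],
                            r[1] * f[2] - r[2] * f[1])) * a)
  }

  q0 <- numeric(5)
  M <- mass_matrix(m, q0)
  expect_equal(M[1, 1], unname(I_axis), tolerance = 1e-10)

  ## with the other joints constrained (zero acceleration), the ankle
  ## angular acceleration is the pendulum form (gravity + spring) / inertia
  pose <- fk_pose(m, q0)
  waxes <- archgait:::world_axes(m, pose)
  tau <- archgait:::gravity_torques(m, pose, waxes) +
    archgait:::passive_torques(m, q0, numeric(5))
  spring1 <- unname(-m$stiffness[1] * (0 - m$neutral[1]))
  expect_equal(tau[1], unname(tau_g) + spring1, tolerance = 1e-10)
  expect_equal(tau[1] / M[1, 1], unname((tau_g + spring1) / I_axis),
               tolerance = 1e-10)
})

test_that("compiled and reference dynamics agree", {
  b <- ag_bundle()
  m <- build_foot_model("ARCHED")
  rhs_r <- archgait:::make_rhs(m, b$trajectory, b$profiles)
  rhs_c <- archgait:::make_rhs_compiled(m, b$trajectory, b$profiles,
                                        grid_n = 8193L)
  set.seed(21)
  for (i in 1:10) {
    y <- c(runif(5, -0.15, 0.15), runif(5, -1, 1))
    t <- runif(1, 0, 4.09)
    a <- rhs_r(t, y, NULL)[[1]]
    c_ <- rhs_c(t, y, NULL)[[1]]
    ## the compiled path interpolates the plane pose and tensions from a
    ## dense grid, so agreement is to the interpolation error
    expect_lt(max(abs(a - c_) / pmax(abs(a), 1)), 2e-5)
  }
})

test_that("stance simulation is deterministic", {
  b <- ag_bundle()
  m <- build_foot_model("ARCHED")
  opts <- list(rtol = 1e-5, atol = 1e-7, n_out = 1025L)
  t1 <- simulate_stance(m, b$trajectory, b$profiles, opts)
  t2 <- simulate_stance(m, b$trajectory, b$profiles, opts)
  expect_identical(t1$q, t2$q)
  expect_identical(t1$sphere_f, t2$sphere_f)
})

test_that("the simulated trace spans the stance on a dense grid", {
  tr <- ag_trace("ARCHED")
  expect_gte(length(tr$time), 1000L)
  expect_equal(tr$time[1], 0)
  expect_equal(tr$time[length(tr$time)], 4.09)
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(is.finite(tr$q)))
})

test_that("with the plane withdrawn and muscles silent there is no contact force", {
  b <- ag_bundle()
  m <- build_foot_model("ARCHED")
  far <- ground_trajectory(data.frame(t = seq(0, 4.09, length.out = 9),
                                      x = 0, y = -5, z = 0,
                                      roll = 0, pitch = 0, yaw = 0))
  zero <- lapply(b$profiles, function(pr)
    activation_profile(pr$muscle, rep(0, 10)))
  tr <- simulate_stance(m, far, zero,
                        options = list(rtol = 1e-6, atol = 1e-8,
                                       n_out = 1001L))
  expect_true(all(tr$sphere_f == 0))
  expect_true(all(tr$sphere_depth < 0))
})

test_that("body-weight calibration converges within its budget", {
  cal <- ag_calibration()
  expect_true(cal$converged)
  expect_lte(cal$iterations, 30)
  expect_lt(abs(cal$achieved_peak - cal$target_peak_bw), 0.02 + 1e-9)
})

test_that("deeper initial penetration never lowers the calibration peak", {
  ## the map the calibration bisects: offset -> mean of the two vGRF peak
  ## magnitudes (the global maximum alone can sit on the muscle-dominated
  ## push-off peak, which is insensitive to plane height)
  b <- ag_bundle()
  m <- build_foot_model("ARCHED")
  opts <- list(rtol = 1e-5, atol = 1e-7, n_out = 1001L)
  peaks <- vapply(c(-0.004, -0.002, 0, 0.002, 0.004), function(off) {
    tr <- simulate_stance(m, shift_trajectory(b$trajectory, off),
                          b$profiles, opts)
    pk <- find_double_peak(total_vgrf(tr))
    unname(pk$peak1["bw"] + pk$peak2["bw"]) / 2
  }, 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("heel loading keeps a common shape across the four scenarios", {
  ## the heel sphere sits on the lateral hindfoot and the treatment
  ## differences act mostly after heel-off, so the heel traces stay close;
  ## the arch drop does feed back into mid-stance loading through the
  ## shared calibration, which bounds how similar they can be
  traces <- ag_traces()
  ref <- traces$ARCHED$sphere_f[2, 1, ]
  pk <- max(ref)
  for (k in names(traces)) {
    h <- traces[[k]]$sphere_f[2, 1, ]
    expect_lt(max(abs(h - ref)), 0.3 * pk)
    expect_gt(stats::cor(h, ref), 0.95)
  }
})
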