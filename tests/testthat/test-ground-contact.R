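test_that("trajectory construction validates its sample table", {
  s <- data.frame(t = c(0, 1, 2, 3), x = 0, y = 0, z = 0,
                  roll = 0, pitch = 0, yaw = 0)
  expect_s3_class(ground_trajectory(s), "ground_trajectory")
  expect_error(ground_trajectory(s[, -2]), "columns")
  s2 <- s; s2$t <- c(0, 2, 1, 3)
  expect_error(ground_trajectory(s2), "increasing")
  s3 <- s; s3$t <- s3$t + 1
  expect_error(ground_trajectory(s3), "t = 0")
})

test_that("plane_pose reproduces the stored samples and rejects bad times", {
  b <- ag_bundle()
  traj <- b$trajectory
  smp <- traj$samples
  for (i in c(1, 25, 100, nrow(smp))) {
    pl <- plane_pose(traj, smp$t[i])
    expect_equal(pl$p[1], smp$x[i], tolerance = 1e-9)
    expect_equal(pl$p[2], smp$y[i] + traj$y_offset, tolerance = 1e-9)
    expect_equal(pl$p[3], smp$z[i], tolerance = 1e-9)
  }
  expect_error(plane_pose(traj, -0.5), "outside")
  expect_error(plane_pose(traj, traj$duration + 1), "outside")
})

test_that("plane velocities match central differences of the pose", {
  b <- ag_bundle()
  traj <- b$trajectory
  h <- 1e-5
  for (t in c(0.5, 1.7, 2.9, 3.6)) {
    p1 <- plane_pose(traj, t - h); p2 <- plane_pose(traj, t + h)
    pl <- plane_pose(traj, t)
    ## linear velocity
    expect_equal(pl$v, (p2$p - p1$p) / (2 * h), tolerance = 1e-4)
    ## angular velocity from the rotation finite difference
    W <- (p2$R - p1$R) %*% t(pl$R) / (2 * h)
    w_fd <- c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1], W[2, 1] - W[1, 2]) / 2
    expect_equal(pl$w, w_fd, tolerance = 1e-4)
  }
})

test_that("sphere penetration matches the closest-point computation", {
  ## trivial cases against a horizontal plane at y = 0
  pl <- list(R = diag(3), p = c(0, 0, 0), n = c(0, 1, 0),
             v = rep(0, 3), w = rep(0, 3))
  expect_equal(sphere_penetration(c(0, 0.03, 0), 0.03, pl)$depth, 0)
  expect_equal(sphere_penetration(c(0, 0, 0), 0.03, pl)$depth, 0.03)

  ## randomized poses against a brute-force closest point on the plane
  set.seed(3)
  for (i in 1:20) {
    ang <- runif(3, -0.5, 0.5)
    R <- archgait:::rot_y(ang[1]) %*% archgait:::rot_z(ang[2]) %*%
      archgait:::rot_x(ang[3])
    pl <- list(R = R, p = runif(3, -0.1, 0.1), n = as.numeric(R[, 2]))
    cw <- runif(3, -0.2, 0.2); r <- runif(1, 0.01, 0.05)
    ## oracle: minimise |cw - (p + R [u, 0, w])| over a dense plane grid,
    ## refined by projection
    d_center <- sum(pl$n * (cw - pl$p))
    oracle_depth <- r - d_center
    got <- sphere_penetration(cw, r, pl)
    expect_equal(got$depth, oracle_depth, tolerance = 1e-12)
    ## contact point lies on the sphere surface towards the plane
    expect_equal(sqrt(sum((got$point - cw)^2)), r, tolerance = 1e-12)
  }
})

test_that("the normal force law is compliant, floored, and continuous", {
  ct <- default_parameter_set()$contact
  expect_equal(normal_force(0, 0, ct), 0)
  expect_equal(normal_force(-0.01, 5, ct), 0)

  ## static-weight oracle: the depth solving k d^p = W carries exactly W
  W <- 804.1
  d <- (W / ct$stiffness)^(1 / ct$exponent)
  expect_equal(normal_force(d, 0, ct), W, tolerance = 1e-9)

  ## strong separation velocity clamps to zero (no adhesion)
  expect_equal(normal_force(0.01, -10 / ct$dissipation, ct), 0)

  ## continuity at the contact boundary for p >= 1
  eps <- 1e-8
  expect_lt(normal_force(eps, 0, ct), 1e-3)
})

test_that("viscous friction opposes slip in proportion to load and velocity", {
  expect_equal(friction_force(100, 1, c(0.02, 0)), c(-2, 0))
  expect_equal(friction_force(100, 1, c(0, 0)), c(0, 0))
  f1 <- friction_force(250, 0.7, c(0.01, -0.03))
  f2 <- friction_force(250, 0.7, c(0.02, -0.06))
  expect_equal(f2, 2 * f1)
  expect_error(friction_force(-1, 1, c(0, 0)), ">= 0")
})

test_that("contact forces vanish without penetration and push along the normal", {
  m <- build_foot_model("ARCHED")
  ## plane far below: no contact anywhere
  pl <- list(R = diag(3), p = c(0, -10, 0), n = c(0, 1, 0),
             v = rep(0, 3), w = rep(0, 3))
  cf <- archgait:::contact_forces(m, numeric(5), numeric(5), pl)
  expect_identical(cf$tau, numeric(5))
  expect_true(all(cf$force == 0))

  ## plane at the sphere bottoms: vertical forces are non-negative
  pl2 <- list(R = diag(3), p = c(0, -0.083, 0), n = c(0, 1, 0),
              v = rep(0, 3), w = rep(0, 3))
  cf2 <- archgait:::contact_forces(m, numeric(5), numeric(5), pl2)
  expect_true(all(cf2$force[2, ] >= 0))
  expect_gt(sum(cf2$force[2, ]), 0)
})
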