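test_that("activation profiles interpolate linearly and clamp at the ends", {
  cp <- c(0, 0.1, 0.2, 0.4, 0.6, 0.5, 0.3, 0.8, 0.9, 0.1)
  p <- activation_profile("soleus", cp)

  ## exact values at the control abscissae
  for (i in 0:9) expect_identical(activation_at(p, i / 9), cp[i + 1])
  ## linear midpoint
  expect_equal(activation_at(p, 0.5 / 9), 0.05)
  expect_equal(activation_at(p, 2.5 / 9), 0.3)
  ## clamping outside [0, 1]
  expect_identical(activation_at(p, -0.3), cp[1])
  expect_identical(activation_at(p, 1.7), cp[10])

  ## dense-table oracle: approx() on a fine grid
  s <- seq(0, 1, length.out = 757)
  oracle <- stats::approx((0:9) / 9, cp, xout = s)$y
  expect_equal(activation_at(p, s), oracle, tolerance = 1e-12)
})

test_that("profile construction validates its control points", {
  expect_error(activation_profile("x", rep(0.5, 9)), "10 control points")
  expect_error(activation_profile("x", c(rep(0.5, 9), 1.2)), "\\[0, 1\\]")
  expect_error(activation_profile("x", c(rep(0.5, 9), -0.1)), "\\[0, 1\\]")
})

test_that("muscle tension is the activation times the maximum isometric force", {
  p <- activation_profile("fdl", c(0, 0, 0, 0, 0, 0, 0, 0.37, 1, 0))
  expect_equal(muscle_tension(p, 0, 500), 0)
  expect_equal(muscle_tension(p, 8 / 9, 500), 500)
  expect_equal(muscle_tension(p, 7 / 9, 1000), 370)
  expect_error(muscle_tension(p, 0.5, -5), "fmax")
})

test_that("path geometry sums straight-line segment lengths", {
  m <- build_foot_model("ARCHED")
  ## synthetic 2-point path, 0.1 m apart on the fixed tibia
  path2 <- list(name = "p2", body = c(0L, 0L),
                points = cbind(c(0, 0, 0), c(0.1, 0, 0)), fmax = 1)
  g2 <- path_geometry(m, path2, numeric(5))
  expect_equal(g2$length, 0.1)
  expect_equal(as.numeric(g2$dirs), c(1, 0, 0))

  ## right-angle 3-point path with legs 0.3 and 0.4 m
  path3 <- list(name = "p3", body = c(0L, 0L, 0L),
                points = cbind(c(0, 0, 0), c(0.3, 0, 0), c(0.3, 0.4, 0)),
                fmax = 1)
  expect_equal(path_geometry(m, path3, numeric(5))$length, 0.7)

  ## coincident consecutive points are rejected
  bad <- list(name = "bad", body = c(0L, 0L),
              points = cbind(c(0, 0, 0), c(0, 0, 0)), fmax = 1)
  expect_error(path_geometry(m, bad, numeric(5)), "coincident")
})

test_that("muscle torques satisfy the moment-arm identity", {
  m <- build_foot_model("ARCHED")
  set.seed(42)
  for (trial in 1:3) {
    q <- runif(5, -0.15, 0.15)
    for (mu in c("soleus", "tib_ant", "tib_post", "fhl")) {
      tau <- apply_muscle_forces(m, q, stats::setNames(100, mu))
      for (j in 1:5) {
        arm <- fd_moment_arm(m, mu, j, q)
        expect_equal(tau[j], 100 * arm, tolerance = 5e-3,
                     label = sprintf("%s torque about joint %d", mu, j))
      }
    }
  }
})

test_that("muscle torques are zero without tension and linear in tension", {
  m <- build_foot_model("ARCHED")
  q <- c(0.05, -0.03, 0.1, 0.02, -0.04)
  zero <- apply_muscle_forces(m, q, c(soleus = 0, fdl = 0))
  expect_identical(zero, numeric(5))
  t1 <- apply_muscle_forces(m, q, c(soleus = 123))
  t2 <- apply_muscle_forces(m, q, c(soleus = 246))
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
  expect_error(apply_muscle_forces(m, q, c(soleus = -1)), ">= 0")
})

test_that("the ideal pulley amplifies tension and divides excursion", {
  imp <- list(amplification = 2)
  expect_equal(pulley_output_tension(100, imp), 200)
  expect_equal(pulley_output_tension(0, imp), 0)
  expect_equal(pulley_output_tension(250, list(amplification = 1)), 250)
  expect_error(pulley_output_tension(10, list(amplification = 0.5)), ">= 1")

  ex <- pulley_excursion(0.020, imp)
  expect_equal(ex$output_excursion, 0.010)
  expect_equal(ex$implant_translation, 0.010)
  expect_equal(pulley_excursion(0, imp)$output_excursion, 0)

  ## power balance across the ideal pulley, several amplifications
  for (n in c(1, 1.5, 2, 3)) {
    impn <- list(amplification = n)
    t_in <- 137; x_in <- 0.0123
    work_in <- t_in * x_in
    work_out <- pulley_output_tension(t_in, impn) *
      pulley_excursion(x_in, impn)$output_excursion
    expect_equal(work_in, work_out, tolerance = 1e-12)
  }
})

test_that("scenario muscle maps disable and reroute as prescribed", {
  arched <- configure_scenario_muscles("ARCHED")
  expect_true(all(vapply(arched, `[[`, TRUE, "enabled")))
  expect_true(all(vapply(arched, function(x) x$source == x$muscle, TRUE)))

  flat <- configure_scenario_muscles("FLATFOOT")
  expect_false(flat$tib_post$enabled)
  expect_true(flat$fdl$enabled)

  tt <- configure_scenario_muscles("FLATFOOT_TT")
  expect_false(tt$fdl$enabled)
  expect_identical(tt$tib_post$source, "fdl")
  expect_identical(tt$tib_post$fmax_source, "fdl")
  expect_identical(tt$tib_post$route, "native")

  imp <- configure_scenario_muscles("FLATFOOT_TT_IMPLANT")
  expect_identical(imp$tib_post$route, "implant")
  expect_equal(imp$tib_post$amp, 2)
})

test_that("a unit pulley degenerates to the direct tendon transfer", {
  b <- ag_bundle()
  m1 <- build_foot_model(foot_scenario("FLATFOOT_TT_IMPLANT",
                                       pulley_amplification = 1))
  m2 <- build_foot_model("FLATFOOT_TT")
  set.seed(7)
  for (trial in 1:5) {
    q <- runif(5, -0.25, 0.25)
    tens <- archgait:::scenario_tensions(m1, b$profiles, runif(1))
    expect_identical(apply_muscle_forces(m1, q, tens),
                     apply_muscle_forces(m2, q, tens))
  }
})

test_that("disabling a muscle equals driving it with a zero profile", {
  b <- ag_bundle()
  flat <- build_foot_model("FLATFOOT")       # tib_post disabled
  arched <- build_foot_model("ARCHED")
  set.seed(11)
  for (trial in 1:5) {
    q <- runif(5, -0.2, 0.2)
    s <- runif(1)
    t_flat <- archgait:::scenario_tensions(flat, b$profiles, s)
    t_arched <- archgait:::scenario_tensions(arched, b$profiles, s)
    t_arched["tib_post"] <- 0                # zero profile equivalent
    expect_equal(apply_muscle_forces(flat, q, t_flat),
                 apply_muscle_forces(arched, q, t_arched),
                 tolerance = 1e-12)
  }
})
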