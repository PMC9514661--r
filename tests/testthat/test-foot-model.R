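test_that("the built model satisfies its structural invariants", {
  for (kind in c("ARCHED", "FLATFOOT", "FLATFOOT_TT", "FLATFOOT_TT_IMPLANT")) {
    m <- build_foot_model(kind)
    expect_identical(m$joint_names,
                     c("ankle", "subtalar", "arch", "mtp_medial",
                       "mtp_lateral"))
    expect_equal(m$nq, 5L)
    ## tree rooted at the fixed tibia: every body reaches index 0
    for (b in seq_len(m$nq)) {
      k <- b
      while (k != 0L) k <- unname(m$parent[k])
      expect_identical(k, 0L)
    }
    ## medial chain connects through the arch joint only
    expect_identical(m$body_names[m$parent[match("medial_foot",
                                                 m$body_names)]],
                     "hindfoot_lateral")
    expect_identical(m$body_names[m$parent[match("hallux", m$body_names)]],
                     "medial_foot")
    ## every distal segment carries a contact sphere
    expect_setequal(unique(m$body_names[m$sphere_body]),
                    c("hindfoot_lateral", "medial_foot", "hallux",
                      "lateral_toes"))
    ## unit axes
    expect_equal(colSums(m$axis^2), rep(1, 5), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("invalid configurations are rejected with informative errors", {
  p <- default_parameter_set()
  p$spheres <- list()
  expect_error(build_foot_model("ARCHED", p), "5 contact spheres")
  expect_error(foot_scenario("WOBBLY"), "arg")
  p2 <- default_parameter_set()
  p2$segments$talus$mass <- -1
  expect_error(build_foot_model("ARCHED", p2), "mass")
  p3 <- default_parameter_set()
  p3$muscles$soleus$via <- p3$muscles$soleus$via[1]
  expect_error(build_foot_model("ARCHED", p3), "via points")
})

test_that("forward kinematics is deterministic, bit for bit", {
  m <- build_foot_model("ARCHED")
  q <- c(0.11, -0.07, 0.23, 0.05, -0.12)
  a <- fk_pose(m, q)
  b <- fk_pose(m, q)
  expect_identical(a, b)
  expect_identical(landmark_position(m, q), landmark_position(m, q))
})

test_that("flatten_arch drops the landmark by the requested amount", {
  p <- default_parameter_set()
  arch <- p$joints$arch
  lm <- p$landmarks$first_mtc$point

  ## identity at zero drop
  expect_identical(flatten_arch(arch, lm, 0), arch)

  ## 8 mm drop reproduced in the neutral pose of the built model
  m0 <- build_foot_model("ARCHED", p)
  mf <- build_foot_model("FLATFOOT", p)
  y0 <- landmark_position(m0)[2]
  yf <- landmark_position(mf)[2]
  expect_equal((y0 - yf) * 1000, 8, tolerance = 0.1 / 8)

  ## unreachable drop errors
  expect_error(flatten_arch(arch, lm, 500), "unreachable|range")
})

test_that("flatten_arch agrees with a bisection oracle on the landmark height", {
  p <- default_parameter_set()
  arch <- p$joints$arch
  lm <- p$landmarks$first_mtc$point
  m <- build_foot_model("ARCHED", p)

  ## oracle: plain bisection on the forward-kinematics landmark height as a
  ## function of the arch angle (independent of the closed-form solution)
  arch_idx <- 3L
  height_at <- function(delta_deg) {
    q <- m$neutral
    q[arch_idx] <- q[arch_idx] + delta_deg * pi / 180
    landmark_position(m, q)[2]
  }
  drop_mm <- 4
  target <- height_at(0) - drop_mm / 1000
  lo <- 0; hi <- 30
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (height_at(mid) > target) lo <- mid else hi <- mid
  }
  oracle_delta <- (lo + hi) / 2

  flat <- flatten_arch(arch, lm, drop_mm)
  expect_equal(flat$neutral_angle - arch$neutral_angle, oracle_delta,
               tolerance = 1e-6)
})

test_that("flatten_arch is monotone in the requested drop", {
  p <- default_parameter_set()
  arch <- p$joints$arch
  lm <- p$landmarks$first_mtc$point
  drops <- c(0, 1, 2, 4, 6, 8, 10)
  deltas <- vapply(drops, function(d)
    flatten_arch(arch, lm, d)$neutral_angle, 0)
  expect_true(all(diff(deltas) > 0))
})

test_that("the arch restoring torque is a linear spring about the neutral", {
  arch <- default_parameter_set()$joints$arch
  n <- arch$neutral_angle
  expect_equal(arch_restoring_torque(n, arch), 0)
  expect_equal(arch_restoring_torque(n + 1, arch), -1)  # 1 Nm per degree
  expect_equal(arch_restoring_torque(n + 5, arch), -5)
  expect_equal(arch_restoring_torque(n - 3, arch), 3)
  ## viscous term adds on top of the spring
  expect_equal(arch_restoring_torque(n, arch, velocity = 2),
               -2 * arch$damping)
})
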