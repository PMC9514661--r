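## build a minimal synthetic trace for the pure-analysis operations
fake_trace <- function(fy, body_weight = 804.145,
                       names = c("heel", "met1", "met5", "hallux", "toe5")) {
  n <- ncol(fy)
  sphere_f <- array(0, c(3, nrow(fy), n))
  sphere_f[2, , ] <- fy
  structure(list(time = seq(0, 4.09, length.out = n),
                 pct = seq(0, 100, length.out = n),
                 sphere_f = sphere_f, sphere_names = names,
                 body_weight = body_weight, scenario = "SYNTH"),
            class = "sim_trace")
}

test_that("total vGRF sums sphere verticals and decomposes exactly", {
  n <- 201
  set.seed(2)
  fy <- matrix(runif(5 * n, 0, 300), 5, n)
  tr <- fake_trace(fy)
  v <- total_vgrf(tr)
  expect_equal(v$bw, colSums(fy) / tr$body_weight, tolerance = 1e-12)

  ## zero forces give a zero series
  expect_true(all(total_vgrf(fake_trace(matrix(0, 5, n)))$bw == 0))

  ## a single sphere carrying exactly one body weight reads 1 BW
  fy1 <- matrix(0, 5, n); fy1[1, 100] <- tr$body_weight
  expect_equal(total_vgrf(fake_trace(fy1))$bw[100], 1)

  ## medial + lateral + heel partials reproduce the total pointwise
  med <- archgait:::sphere_vgrf(tr, c("met1", "hallux"))
  lat <- archgait:::sphere_vgrf(tr, c("met5", "toe5"))
  heel <- archgait:::sphere_vgrf(tr, "heel")
  expect_equal(med$bw + lat$bw + heel$bw, v$bw, tolerance = 1e-12)
})

test_that("find_double_peak locates constructed two-bump waveforms", {
  pct <- seq(0, 100, length.out = 501)
  ## symmetric double bump with a valley at 50%
  bw <- 1 - cos(2 * pi * pct / 50) / 2 - 0.5
  bw <- pmax(bw, 0)
  pk <- find_double_peak(data.frame(pct = pct, bw = bw))
  expect_false(pk$degenerate)
  expect_equal(unname(pk$valley["pct"]), 50, tolerance = 0.5)
  expect_equal(unname(pk$peak1["bw"]), unname(pk$peak2["bw"]),
               tolerance = 1e-9)

  ## brute-force scan oracle on an asymmetric curve
  bw2 <- 1.1 * exp(-((pct - 30) / 12)^2) + 1.05 * exp(-((pct - 72) / 10)^2)
  s2 <- data.frame(pct = pct, bw = bw2)
  pk2 <- find_double_peak(s2)
  w1 <- which(pct > 5 & pct <= 50)
  w2 <- which(pct > 50 & pct < 95)
  i1 <- w1[which.max(bw2[w1])]; i2 <- w2[which.max(bw2[w2])]
  iv <- (i1:i2)[which.min(bw2[i1:i2])]
  expect_equal(unname(pk2$peak1["pct"]), pct[i1])
  expect_equal(unname(pk2$peak2["pct"]), pct[i2])
  expect_equal(unname(pk2$valley["pct"]), pct[iv])

  ## monotone ramp flags degenerate instead of erroring
  mono <- find_double_peak(data.frame(pct = pct, bw = pct / 100))
  expect_true(mono$degenerate)
  expect_error(find_double_peak(data.frame(pct = 1:50, bw = 1:50)),
               "100 samples")
})

test_that("the medial/lateral split follows the peak forces", {
  n <- 301
  bw <- 804.145
  fy <- matrix(0, 5, n)
  fy[2, ] <- 0.397 * bw * sin(seq(0, pi, length.out = n))  # met1
  fy[4, ] <- 0                                             # hallux
  fy[3, ] <- 0.603 * bw * sin(seq(0, pi, length.out = n))  # met5
  tr <- fake_trace(fy, bw)
  sp <- medial_lateral_peak_split(tr)
  expect_equal(sp$medial_peak, 0.397, tolerance = 1e-9)
  expect_equal(sp$lateral_peak, 0.603, tolerance = 1e-9)
  expect_equal(sp$medial_pct, 39.7, tolerance = 1e-9)
  expect_equal(sp$medial_pct + sp$lateral_pct, 100, tolerance = 1e-9)

  ## all force on the medial side
  fy2 <- matrix(0, 5, n); fy2[2, ] <- 100
  expect_equal(medial_lateral_peak_split(fake_trace(fy2, bw))$medial_pct, 100)

  ## equal mirrored series split 50/50
  fy3 <- matrix(0, 5, n); fy3[2, ] <- fy3[3, ] <- 50
  expect_equal(medial_lateral_peak_split(fake_trace(fy3, bw))$medial_pct, 50)

  ## undefined split is flagged
  expect_error(medial_lateral_peak_split(fake_trace(matrix(0, 5, n), bw)),
               "undefined")
})

test_that("lateral shift is the drop in medial percentage", {
  expect_equal(lateral_shift(48.3, 44.4), 3.9)
  expect_equal(lateral_shift(48.3, 40.2), 8.1)
  expect_equal(lateral_shift(37, 37), 0)
  expect_error(lateral_shift(101, 50), "\\[0, 100\\]")
})

test_that("restoration percentage normalises the shift by the arched-flat gap", {
  expect_equal(restoration_pct(39.7, 48.3, 48.3), 0)
  expect_equal(restoration_pct(39.7, 48.3, 39.7), 100)
  expect_equal(round(restoration_pct(39.7, 48.3, 40.2), 1), 94.2)
  expect_equal(round(restoration_pct(39.7, 48.3, 44.4), 1), 45.3)
  expect_error(restoration_pct(50, 45, 47), "medial shift")

  ## affine invariance: shifting all three percentages leaves it unchanged
  set.seed(9)
  for (i in 1:10) {
    a <- runif(1, 30, 45); u <- a + runif(1, 2, 15); t <- runif(1, a, u)
    d <- runif(1, -10, 10)
    expect_equal(restoration_pct(a, u, t),
                 restoration_pct(a + d, u + d, t + d), tolerance = 1e-9)
  }
})

test_that("compare_scenarios assembles a self-consistent report", {
  n <- 201; bw <- 804.145
  mk <- function(med_pct) {
    fy <- matrix(0, 5, n)
    fy[2, ] <- med_pct * sin(seq(0, pi, length.out = n))
    fy[3, ] <- (100 - med_pct) * sin(seq(0, pi, length.out = n))
    fy[1, ] <- 50
    fake_trace(fy, bw)
  }
  traces <- list(ARCHED = mk(39.7), FLATFOOT = mk(48.3),
                 FLATFOOT_TT = mk(44.4), FLATFOOT_TT_IMPLANT = mk(40.2))
  rep <- compare_scenarios(traces)
  expect_equal(unname(rep$shifts), c(3.9, 8.1), tolerance = 1e-9)
  expect_equal(unname(rep$restorations), c(45.3, 94.2))
  expect_equal(rep$improvement_ratio, 2.1)

  ## internal consistency: restorations recomputed from the report's own
  ## splits match to 1e-9
  m <- rep$medial_pct
  for (k in c("FLATFOOT_TT", "FLATFOOT_TT_IMPLANT"))
    expect_equal(unname(rep$restorations_raw[k]),
                 restoration_pct(m["ARCHED"], m["FLATFOOT"], m[k]),
                 tolerance = 1e-9, ignore_attr = TRUE)

  ## identical treatment traces give a unit ratio
  traces2 <- traces; traces2$FLATFOOT_TT_IMPLANT <- traces$FLATFOOT_TT
  expect_equal(compare_scenarios(traces2)$improvement_ratio, 1)

  ## a missing scenario is an error
  expect_error(compare_scenarios(traces[-2]), "FLATFOOT")
})
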