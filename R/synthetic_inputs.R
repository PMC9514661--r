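## Synthetic study inputs: the nine muscle activation profiles and the
## 6-DOF ground-plane stance trajectory.  Neither is printed numerically in
## the source experimental literature; the generators below produce inputs
## with the structural properties the analysis assumes (dorsiflexors early,
## plantarflexors late, heel-only contact at heel strike, toe-only contact
## at toe off, physiological double-peak loading), deterministically for a
## given parameter bundle.

dorsiflexor_names <- function() c("tib_ant", "edl", "ehl")

## tiny integer LCG in [-1, 1]: platform-stable jitter source (control
## points are derived through integer state before float conversion)
lcg_unit <- function(seed, k) {
  s <- as.integer(seed)
  for (i in seq_len(k + 1L)) s <- as.integer((1103515245 * (s %% 65536L) + 12345L) %% 2147483647L)
  (s %% 20001L - 10000L) / 10000
}

## signed ankle moment arm of a muscle at the neutral pose (m; positive =
## dorsiflexion), from a central difference of the path length
ankle_moment_arm <- function(model, muscle, h = 1e-6) {
  qp <- numeric(model$nq); qm <- numeric(model$nq)
  qp[1] <- h; qm[1] <- -h
  -(path_geometry(model, muscle, qp)$length -
      path_geometry(model, muscle, qm)$length) / (2 * h)
}

#' Generate the nine muscle activation profiles
#'
#' Builds stance-phase activation profiles for the nine extrinsic muscles
#' by distributing the ankle-torque demand of gait across the dorsiflexor
#' and plantarflexor groups.  The demand at stance fraction `s` is the
#' torque needed to balance the target vertical loading profile applied at
#' the advancing centre of pressure: contact behind the ankle in early
#' stance demands dorsiflexor torque (eccentric control of foot lowering),
#' contact ahead of the ankle in late stance demands plantarflexor torque
#' (push-off).  Each group member receives a share proportional to its
#' `weight` times a Gaussian timing envelope `exp(-((s - t0)/w)^2)`, and
#' the share is converted to activation through the muscle's maximum
#' isometric force and its ankle moment arm in the arched model.  The
#' result mirrors electromyography-derived muscle forces of healthy gait.
#'
#' Activations are evaluated at the ten control abscissae `0, 1/9, ..., 1`,
#' clipped to `[0, 1]` and rounded to 1e-6 after an integer-based jitter
#' draw, so generation is deterministic and bit-stable across platforms.
#' Structural constraints are enforced and violations reported together:
#' control points in `[0, 1]`, first and last control point at most 0.2,
#' dorsiflexor peaks in the first 40% of stance, plantarflexor peaks at or
#' after 60% of stance.
#'
#' @param params a parameter bundle (see `default_parameter_set()`);
#'   `params$activation$shapes` carries per-muscle `weight`, `t0`, `w`,
#'   `params$activation$jitter` a relative jitter amplitude (default 0) and
#'   `params$sim$seed` the seed it draws from.
#' @param model optionally the arched [build_foot_model()] (built from
#'   `params` when `NULL`) supplying moment arms and force capacities.
#' @return named list of nine [activation_profile()]s.
#' @export
#' @examples
#' profs <- gen_activation_profiles(default_parameter_set())
#' profs$soleus
gen_activation_profiles <- function(params = default_parameter_set(),
                                    model = NULL, tau_adjust = rep(1, 10)) {
  if (is.null(model)) model <- build_foot_model("ARCHED", params)
  shapes <- params$activation$shapes
  jit <- params$activation$jitter
  seed <- if (is.null(params$sim$seed)) 1L else params$sim$seed
  sg <- (0:9) / 9
  tp <- params$trajectory
  vgrff <- knot_spline(tp$vgrf_knots$s, tp$vgrf_knots$bw)
  copf <- knot_spline(tp$cop_knots$s, tp$cop_knots$x)
  bw <- params$subject$mass_kg * params$subject$gravity
  az <- model$axis[3, 1]  # ankle axis alignment with the lateral axis
  pitchf <- knot_spline(tp$pitch_knots$s, tp$pitch_knots$deg)
  y_c <- if (is.null(tp$contact_height_m)) -0.095 else tp$contact_height_m

  ## ankle-torque demand the muscles must supply at each control abscissa:
  ## the negative of the moment of the target contact load about the ankle.
  ## The force acts along the plane normal at the advancing centre of
  ## pressure, so its lever about the ankle is x_c cos(pitch) + y_c
  ## sin(pitch) (the contact points lie ~9.5 cm below the ankle centre)
  pr <- deg2rad(pitchf(sg))
  lever <- copf(sg) * cos(pr) + y_c * sin(pr)
  tau_need <- -az * pmax(vgrff(sg), 0) * bw * lever
  tau_need <- tau_need * tau_adjust

  weights <- vapply(shapes, `[[`, 0, "weight")
  if (jit > 0) {
    for (i in seq_along(weights))
      weights[i] <- max(weights[i] * (1 + jit * lcg_unit(seed, i)), 0)
  }
  arms <- vapply(names(shapes), function(nm) ankle_moment_arm(model, nm), 0)
  fmax <- vapply(names(shapes), function(nm) model$muscles[[nm]]$fmax, 0)
  is_dorsi <- names(shapes) %in% dorsiflexor_names()

  cp_mat <- matrix(0, length(shapes), 10,
                   dimnames = list(names(shapes), NULL))
  for (i in seq_along(sg)) {
    need <- tau_need[i]
    grp <- if (need > 0) is_dorsi else !is_dorsi
    env <- vapply(shapes, function(sh)
      exp(-((sg[i] - sh$t0) / sh$w)^2), 0)
    share <- weights * env * grp
    tot <- sum(share)
    if (tot <= 0 || abs(need) < 1e-9) next
    share <- share / tot
    cp_mat[, i] <- pmin(pmax(abs(need) * share / (fmax * abs(arms)), 0), 1)
  }

  co <- params$activation$coactivation
  for (nm in names(co)) {
    bump <- co[[nm]]$amp * exp(-((sg - co[[nm]]$t0) / co[[nm]]$w)^2)
    cp_mat[nm, ] <- pmin(cp_mat[nm, ] + bump, 1)
  }

  out <- list()
  violations <- character()
  for (nm in names(shapes)) {
    cp <- round(cp_mat[nm, ] * 1e6) / 1e6
    if (cp[1] > 0.2 || cp[10] > 0.2)
      violations <- c(violations,
                      paste0(nm, ": activation must start and end low (<= 0.2)"))
    amax <- sg[which.max(cp)]
    if (nm %in% dorsiflexor_names()) {
      if (max(cp) > 0 && amax > 0.4)
        violations <- c(violations,
                        paste0(nm, ": dorsiflexor must peak in early stance"))
    } else {
      if (max(cp) > 0 && amax < 0.6)
        violations <- c(violations,
                        paste0(nm, ": plantarflexor must peak at >= 60% stance"))
    }
    out[[nm]] <- activation_profile(nm, cp)
  }
  if (length(violations) > 0L)
    stop("activation profile constraints violated:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  out
}

## rotation matrix of the plane for roll/pitch/yaw in degrees (pitch
## positive = anterior edge down; must match plane_pose())
rpy_matrix <- function(roll_deg, pitch_deg, yaw_deg) {
  rot_y(deg2rad(yaw_deg)) %*% rot_z(-deg2rad(pitch_deg)) %*%
    rot_x(deg2rad(roll_deg))
}

## tangency height: the plane reference y such that the plane with normal n
## through (px, y, pz) just touches the sphere with world centre cw and
## radius r: n . (cw - p) = r
tangency_height <- function(cw, r, n, px, pz) {
  (sum(n * cw) - r - n[1] * px - n[3] * pz) / n[2]
}

## world sphere centres at pose q
sphere_centers_world <- function(model, q) {
  pose <- fk_pose(model, q)
  ns <- length(model$sphere_radius)
  cw <- matrix(0, 3, ns)
  for (i in seq_len(ns))
    cw[, i] <- body_point(model, pose, model$sphere_body[i],
                          model$sphere_center[, i])
  cw
}

#' Generate the 6-DOF ground-plane stance trajectory
#'
#' Constructs the moving ground plane's trajectory over the stance phase by
#' quasi-static inversion against the arched foot model: for a grid of
#' stance fractions, the plane attitude (pitch sweeping from heel-down to
#' toe-down, plus small roll/yaw) and an anteriorly progressing reference
#' point are prescribed, and the plane height together with the foot's
#' equilibrium posture are solved so that the total vertical contact force
#' matches the target double-peak loading profile of healthy gait at the
#' subject's body weight.  At heel strike the plane is tangent to the heel
#' sphere (only the heel can contact) and at toe off it is tangent to the
#' toe-region spheres.
#'
#' The plane's rigid motion is then completed by integrating a rolling
#' (no-slip) origin path: the plane's material origin moves so that the
#' surface point under the current contact reference has zero tangential
#' velocity, as a plank rolling under a stationary foot.  Without this the
#' prescribed translation would drag the foot through the viscous friction.
#'
#' @param params parameter bundle; `params$trajectory` carries the stance
#'   duration (4.09 s), the pitch/centre-of-pressure/vGRF knot tables and
#'   the roll/yaw/z amplitudes.
#' @param model optionally, the arched [build_foot_model()] to invert
#'   against (built from `params` when `NULL`).
#' @param profiles optionally, activation profiles (generated from
#'   `params` when `NULL`).
#' @return a [ground_trajectory()]; attribute `"qs"` carries the
#'   quasi-static solution table (stance fraction, joint angles, plane
#'   height, achieved vertical force) for diagnostics.
#' @export
gen_ground_trajectory <- function(params = default_parameter_set(),
                                  model = NULL, profiles = NULL) {
  tp <- params$trajectory
  dur <- tp$stance_duration
  if (dur <= 0) stop("stance_duration must be > 0", call. = FALSE)
  if (is.null(model)) model <- build_foot_model("ARCHED", params)
  if (is.null(profiles)) profiles <- gen_activation_profiles(params)
  bw <- params$subject$mass_kg * params$subject$gravity

  pitchf <- knot_spline(tp$pitch_knots$s, tp$pitch_knots$deg)
  copf <- knot_spline(tp$cop_knots$s, tp$cop_knots$x)
  vgrff <- knot_spline(tp$vgrf_knots$s, tp$vgrf_knots$bw)
  ## plane roll builds in late stance: the rig's counterpart of body-weight
  ## roll-over towards the first ray during propulsion
  rollf <- function(s) tp$roll_amp_deg * exp(-((s - 0.80) / 0.22)^2)
  yawf <- function(s) tp$yaw_amp_deg * (2 * s - 1)
  zf <- function(s) tp$z_amp_m * sin(pi * s)

  ng <- tp$grid_n
  sg <- seq(0, 1, length.out = ng)
  nq <- model$nq

  plane_at <- function(s, h) {
    R <- rpy_matrix(rollf(s), pitchf(s), yawf(s))
    p <- c(copf(s), h, zf(s))
    list(R = R, p = p, n = as.numeric(R[, 2]),
         v = c(0, 0, 0), w = c(0, 0, 0))
  }

  ## quasi-static inversion pass: march over the stance grid solving foot
  ## equilibrium and plane height for the target total vertical force
  qs_pass <- function(profiles) {
    qs_q <- matrix(0, ng, nq)
    qs_h <- numeric(ng); qs_f <- numeric(ng)
    qs_slope <- rep(NA_real_, ng)
    q_prev <- model$neutral
    h_prev <- NA_real_
    for (k in seq_len(ng)) {
      s <- sg[k]
      target <- max(vgrff(s), 0) * bw
      tens <- scenario_tensions(model, profiles, s)
      if (k == 1L || k == ng || target < 0.5) {
        ## free equilibrium, plane tangent to the nearest sphere
        q <- solve_static(model, tens, pl = NULL, q0 = q_prev)
        cw <- sphere_centers_world(model, q)
        n <- as.numeric(rpy_matrix(rollf(s), pitchf(s), yawf(s))[, 2])
        hs <- vapply(seq_len(ncol(cw)), function(i)
          tangency_height(cw[, i], model$sphere_radius[i], n, copf(s), zf(s)),
          0)
        h <- min(hs)
        limiting <- model$sphere_names[which.min(hs)]
        if (k == 1L && limiting != "heel")
          stop("trajectory boundary condition violated: at heel strike the ",
               "limiting contact sphere is '", limiting, "', not the heel",
               call. = FALSE)
        if (k == ng && !limiting %in% c("hallux", "toe5"))
          stop("trajectory boundary condition violated: at toe off the ",
               "limiting contact sphere is '", limiting,
               "', not a toe sphere", call. = FALSE)
        qs_q[k, ] <- q; qs_h[k] <- h; qs_f[k] <- 0
        q_prev <- q; h_prev <- h
      } else {
        ## outer secant on the plane height against the total vertical
        ## contact force target; inner equilibria by dynamic relaxation
        q_eq <- q_prev
        fy_at <- function(h) {
          pl <- plane_at(s, h)
          q_eq <<- solve_static(model, tens, pl, q0 = q_eq)
          cf <- contact_forces(model, q_eq, numeric(nq), pl)
          sum(cf$force[2, ])
        }
        h0 <- if (is.na(h_prev)) -0.085 else h_prev
        f0 <- fy_at(h0)
        h1 <- h0 + if (f0 < target) 0.002 else -0.002
        f1 <- fy_at(h1)
        best_h <- if (abs(f1 - target) < abs(f0 - target)) h1 else h0
        best_f <- min(abs(f1 - target), abs(f0 - target))
        best_q <- q_eq
        for (it in seq_len(10L)) {
          if (best_f < 1 || abs(f1 - f0) < 1e-6) break
          hn <- h1 + (target - f1) * (h1 - h0) / (f1 - f0)
          hn <- min(max(hn, h1 - 0.006), h1 + 0.006)  # clamp the step
          h0 <- h1; f0 <- f1
          h1 <- hn; f1 <- fy_at(hn)
          if (abs(f1 - target) < best_f) {
            best_f <- abs(f1 - target); best_h <- h1; best_q <- q_eq
          }
        }
        qs_q[k, ] <- best_q; qs_h[k] <- best_h
        qs_slope[k] <- if (abs(h1 - h0) > 1e-9) abs((f1 - f0) / (h1 - h0)) else NA
        pl <- plane_at(s, best_h)
        cf <- contact_forces(model, best_q, numeric(nq), pl)
        qs_f[k] <- sum(cf$force[2, ])
        q_prev <- best_q; h_prev <- best_h
      }
    }
    list(q = qs_q, h = qs_h, f = qs_f, slope = qs_slope)
  }

  ## rolling-origin integration: the plane's material origin r(t) moves so
  ## that the surface has no tangential velocity at the contact reference
  ## c(t) = (cop(s), h(s), z(s)), while the plane keeps containing c(t).
  Rfun <- function(t) {
    s <- t / dur
    rpy_matrix(rollf(s), pitchf(s), yawf(s))
  }
  omega_fd <- function(t) {
    h <- min(1e-4 * dur, 1e-3)
    t1 <- max(t - h, 0); t2 <- min(t + h, dur)
    W <- (Rfun(t2) - Rfun(t1)) %*% t(Rfun(t)) / (t2 - t1)
    c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1], W[2, 1] - W[1, 2]) / 2
  }
  nfun <- function(t) as.numeric(Rfun(t)[, 2])

  build_traj <- function(h_vec) {
    hf <- stats::splinefun(sg, h_vec, method = "natural")
    cfun <- function(t) {
      s <- t / dur
      c(copf(s), hf(s), zf(s))
    }
    cdot <- function(t) {
      s <- t / dur
      c(copf(s, deriv = 1), hf(s, deriv = 1),
        tp$z_amp_m * pi * cos(pi * s)) / dur
    }
    nfine <- 801L
    tf <- seq(0, dur, length.out = nfine)
    r <- matrix(0, 3, nfine)
    r[, 1] <- cfun(0)
    rdot <- function(t, rv) {
      n <- nfun(t)
      sum(n * cdot(t)) * n - cross3(omega_fd(t), cfun(t) - rv)
    }
    for (i in seq_len(nfine - 1L)) {
      h <- tf[i + 1] - tf[i]
      k1 <- rdot(tf[i], r[, i])
      k2 <- rdot(tf[i] + h / 2, r[, i] + h / 2 * k1)
      k3 <- rdot(tf[i] + h / 2, r[, i] + h / 2 * k2)
      k4 <- rdot(tf[i + 1], r[, i] + h * k3)
      rn <- r[, i] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      ## project back onto the constraint plane n . (c - r) = 0
      n <- nfun(tf[i + 1])
      rn <- rn + sum(n * (cfun(tf[i + 1]) - rn)) * n
      r[, i + 1] <- rn
    }
    keep <- seq(1, nfine, by = 4L)  # 201 output samples
    sk <- tf[keep] / dur
    ground_trajectory(data.frame(
      t = tf[keep],
      x = r[1, keep], y = r[2, keep], z = r[3, keep],
      roll = rollf(sk), pitch = pitchf(sk), yaw = yawf(sk)
    ))
  }

  sim_fast <- function(traj, profiles)
    simulate_stance(model, traj, profiles,
                    options = list(rtol = 1e-5, atol = 1e-7, n_out = 401L))

  ## stage 1: initial inversion and a dynamic probe
  qs1 <- qs_pass(profiles)
  traj <- build_traj(qs1$h)
  tr <- sim_fast(traj, profiles)
  ftr <- apply(tr$sphere_f[2, , , drop = FALSE], 3, sum)

  ## stage 2: one-shot correction of the late activation control points.
  ## In push-off the load is set by plantarflexor torque, not plane height,
  ## and the analytic lever model is only approximate; the probe measures
  ## the realised torque-to-force map at each control abscissa.  The
  ## control point nearest the push-off peak is targeted at the peak
  ## magnitude of the loading profile so the second vGRF peak lands there.
  sg10 <- (0:9) / 9
  target10 <- pmax(vgrff(sg10), 0) * bw
  sfine <- seq(0.55, 0.9, by = 0.005)
  i_push <- which(sg10 > 0.5)[which.max(target10[sg10 > 0.5])]
  target10[i_push] <- max(vgrff(sfine)) * bw
  f10 <- stats::approx(tr$pct / 100, ftr, xout = sg10, rule = 2)$y
  tau_adjust <- rep(1, 10)
  late <- which(sg10 >= 0.5 & target10 > 1)
  tau_adjust[late] <- pmin(pmax(target10[late] / pmax(f10[late], 1), 0.6), 1.6)
  profiles <- gen_activation_profiles(params, model, tau_adjust)

  ## stage 3: keep the stage-1 height profile (re-inverting with the
  ## corrected activations would chase the late-stance force target by
  ## wedging the plane into the forefoot, undoing the correction), then
  ## refine the heights where the foot is wedged between heel and forefoot
  ## contact (early/mid stance, where height has authority)
  qs2 <- qs1
  h_cur <- qs2$h
  ## effective vertical stiffness of the loaded foot (N/m); measured from
  ## offset probes of full runs, fairly uniform across the stance
  slope <- rep(1.1e5, ng)
  target_f <- pmax(vgrff(sg), 0) * bw
  n_refine <- if (is.null(tp$n_refine)) 2L else tp$n_refine
  traj <- build_traj(h_cur)
  for (it in seq_len(n_refine)) {
    tr <- sim_fast(traj, profiles)
    ftr <- apply(tr$sphere_f[2, , , drop = FALSE], 3, sum)
    fdyn <- stats::approx(tr$pct / 100, ftr, xout = sg, rule = 2)$y
    corr <- 0.8 * (target_f - fdyn) / slope
    corr <- pmin(pmax(corr, -0.003), 0.003)
    corr[sg > 0.95] <- 0   # leave the toe-off approach untouched
    corr[c(1L, ng)] <- 0   # keep the tangency endpoints
    ## smoothing to avoid spline ringing and exciting foot transients
    corr <- stats::filter(corr, c(0.25, 0.5, 0.25), sides = 2)
    corr[is.na(corr)] <- 0
    h_cur <- h_cur + as.numeric(corr)
    traj <- build_traj(h_cur)
  }
  qs_q <- qs2$q; qs_h <- qs2$h; qs_f <- qs2$f
  attr(traj, "profiles") <- profiles

  ## boundary contact check on the realised trajectory: no sphere other
  ## than the heel (toe region) may penetrate at heel strike (toe off)
  chk <- function(t, q, allowed) {
    pl <- plane_pose(traj, t)
    cw <- sphere_centers_world(model, q)
    d <- vapply(seq_len(ncol(cw)), function(i)
      model$sphere_radius[i] - sum(pl$n * (cw[, i] - pl$p)), 0)
    bad <- which(d > 1e-4 & !model$sphere_names %in% allowed)
    if (length(bad) > 0L)
      stop("trajectory boundary condition violated at t = ", t, ": sphere ",
           paste(model$sphere_names[bad], collapse = ", "),
           " penetrates the plane", call. = FALSE)
  }
  chk(0, qs_q[1, ], "heel")
  chk(dur, qs_q[ng, ], c("hallux", "toe5"))

  attr(traj, "qs") <- list(s = sg, q = qs_q, h = qs_h, h_refined = h_cur,
                           fy = qs_f, target = target_f)
  traj
}

## per-session cache of the default bundle (the generators are
## deterministic, so caching only skips recomputation)
.bundle_cache <- new.env(parent = emptyenv())

#' Default synthetic input bundle
#'
#' Builds (and caches for the session) the complete default study inputs:
#' the parameter bundle, the arched-foot model, the nine activation
#' profiles and the ground-plane trajectory.
#'
#' @param params parameter bundle; only the shipped defaults are cached.
#' @return list with `params`, `profiles`, `trajectory`.
#' @export
default_input_bundle <- function(params = default_parameter_set()) {
  is_default <- identical(params, default_parameter_set())
  if (is_default && !is.null(.bundle_cache$default))
    return(.bundle_cache$default)
  validate_params(params)
  profiles <- gen_activation_profiles(params)
  traj <- gen_ground_trajectory(params, profiles = profiles)
  if (!is.null(attr(traj, "profiles"))) profiles <- attr(traj, "profiles")
  out <- list(params = params, profiles = profiles, trajectory = traj)
  if (is_default) .bundle_cache$default <- out
  out
}
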