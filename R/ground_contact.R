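#' Construct a ground-plane trajectory
#'
#' A ground-plane trajectory is the time-parameterised 6-DOF pose of the
#' moving ground plane over the stance phase, represented as a sample table
#' of the six coordinates interpolated with natural cubic splines (twice
#' differentiable; velocities come from the analytic spline derivative).
#'
#' Coordinate conventions (laboratory frame, tibia fixed): `x` anterior,
#' `y` up, `z` lateral (right).  The plane is the `y = 0` surface of its
#' local frame, with outward normal along local `+y`.  Orientation is
#' composed as yaw about world `y`, then pitch about the rotated `z`
#' (heel-down positive at heel strike), then roll about the twice-rotated
#' `x`; angles are degrees in the sample table.
#'
#' @param samples data frame with columns `t, x, y, z, roll, pitch, yaw`
#'   (seconds, metres, degrees), `t` strictly increasing from 0.
#' @param y_offset vertical offset (m) added to the `y` coordinate at
#'   evaluation time; used by the body-weight calibration.
#' @return An object of class `ground_trajectory`.
#' @export
ground_trajectory <- function(samples, y_offset = 0) {
  need <- c("t", "x", "y", "z", "roll", "pitch", "yaw")
  if (!all(need %in% names(samples)))
    stop("trajectory samples need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(samples) < 4L) stop("need at least 4 trajectory samples",
                               call. = FALSE)
  if (any(diff(samples$t) <= 0))
    stop("trajectory sample times must be strictly increasing",
         call. = FALSE)
  if (abs(samples$t[1]) > 1e-12)
    stop("trajectory must start at t = 0", call. = FALSE)
  fns <- lapply(need[-1], function(cn)
    stats::splinefun(samples$t, samples[[cn]], method = "natural"))
  names(fns) <- need[-1]
  structure(list(duration = samples$t[nrow(samples)],
                 samples = samples, fns = fns, y_offset = y_offset),
            class = "ground_trajectory")
}

#' @export
print.ground_trajectory <- function(x, ...) {
  cat("<ground_trajectory> duration", format(x$duration), "s,",
      nrow(x$samples), "samples")
  if (x$y_offset != 0) cat(", y offset", format(x$y_offset), "m")
  cat("\n")
  invisible(x)
}

#' Shift a trajectory vertically
#'
#' Returns the same trajectory with an additional vertical offset (m),
#' positive moving the plane up into the foot.  Used by
#' [calibrate_heel_offset()] to scale the simulated body-weight loading.
#'
#' @param traj a [ground_trajectory()].
#' @param dy vertical shift (m) added to the current offset.
#' @export
shift_trajectory <- function(traj, dy) {
  traj$y_offset <- traj$y_offset + dy
  traj
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Pose and velocity of the ground plane
#'
#' Evaluates the plane's rigid pose at time `t`, together with its linear
#' and angular velocity obtained by analytic differentiation of the spline
#' representation.
#'
#' @param traj a [ground_trajectory()].
#' @param t time (s) in `[0, duration]`.
#' @return list with `R` (3 x 3 rotation), `p` (origin, m), `n` (unit
#'   outward normal), `v` (origin velocity, m/s) and `w` (angular velocity,
#'   rad/s).
#' @export
plane_pose <- function(traj, t) {
  if (t < -1e-9 || t > traj$duration + 1e-9)
    stop("t = ", t, " outside trajectory span [0, ", traj$duration, "]",
         call. = FALSE)
  t <- min(max(t, 0), traj$duration)
  f <- traj$fns
  p <- c(f$x(t), f$y(t) + traj$y_offset, f$z(t))
  v <- c(f$x(t, deriv = 1), f$y(t, deriv = 1), f$z(t, deriv = 1))
  roll <- deg2rad(f$roll(t)); pitch <- deg2rad(f$pitch(t))
  yaw <- deg2rad(f$yaw(t))
  droll <- deg2rad(f$roll(t, deriv = 1)); dpitch <- deg2rad(f$pitch(t, deriv = 1))
  dyaw <- deg2rad(f$yaw(t, deriv = 1))
  ## positive pitch tilts the anterior (toe) end of the plane down: the
  ## heel-strike attitude.  Composition: yaw about world y, pitch about the
  ## rotated z (sign-flipped), roll about the twice-rotated x.
  Ry <- rot_y(yaw); Rz <- rot_z(-pitch); Rx <- rot_x(roll)
  R <- Ry %*% Rz %*% Rx
  w <- dyaw * c(0, 1, 0) + Ry %*% (-dpitch * c(0, 0, 1) + Rz %*% (droll * c(1, 0, 0)))
  list(R = R, p = p, n = as.numeric(R[, 2]), v = v, w = as.numeric(w))
}

#' Sphere-plane penetration
#'
#' Analytic sphere versus half-space test: the penetration depth is the
#' sphere radius minus the signed distance of the centre from the plane
#' along the plane normal.  Depth <= 0 means no contact.
#'
#' @param center_w sphere centre, world frame (m).
#' @param radius sphere radius (m).
#' @param plane a pose from [plane_pose()].
#' @return list with `depth` (m), `point` (the contact point on the sphere
#'   surface towards the plane) and `normal`.
#' @export
sphere_penetration <- function(center_w, radius, plane) {
  sd <- sum(plane$n * (center_w - plane$p))
  list(depth = radius - sd,
       point = center_w - radius * plane$n,
       normal = plane$n)
}

#' Compliant normal contact force
#'
#' `k * depth^p * (1 + dissipation * depth_rate)` for positive depth,
#' floored at zero (the plane cannot pull on the foot), zero otherwise.
#' With `p = 3/2` this is a Hertz-type law with linear Hunt-Crossley
#' dissipation.
#'
#' @param depth penetration depth (m).
#' @param depth_rate penetration rate (m/s, positive = penetrating).
#' @param contact contact-law constants: `stiffness`, `exponent`,
#'   `dissipation` (see `default_parameter_set()$contact`).
#' @return normal force magnitude (N, >= 0).
#' @export
#' @examples
#' normal_force(0.01, 0, default_parameter_set()$contact)
normal_force <- function(depth, depth_rate, contact) {
  if (depth <= 0) return(0)
  f <- contact$stiffness * depth^contact$exponent *
    (1 + contact$dissipation * depth_rate)
  max(f, 0)
}

#' Viscous friction force
#'
#' `F_F = -F_N * f_v * v_s`: a tangential force proportional to the normal
#' force and the slip velocity, opposing slip.  The default coefficient is
#' small: with five rigid contact spheres the no-slip behaviour of the gait
#' rig is provided kinematically by the rolling plane trajectory, and large
#' viscous coefficients turn transient slip into destabilising tangential
#' forces.
#'
#' @param f_n normal force (N, >= 0).
#' @param f_v coefficient of viscous friction (s/m).
#' @param v_s slip velocity (m/s; 2- or 3-vector in the plane's tangent
#'   space).
#' @return tangential force vector, same length as `v_s` (N).
#' @export
#' @examples
#' friction_force(100, 1, c(0.02, 0))  # c(-2, 0)
friction_force <- function(f_n, f_v, v_s) {
  if (f_n < 0) stop("normal force must be >= 0", call. = FALSE)
  -f_n * f_v * v_s
}

## Full contact evaluation for all five spheres at state (q, qdot) against
## the plane pose `pl`.  Returns generalized torques plus per-sphere world
## force vectors, application points and penetration depths.
contact_forces <- function(model, q, qdot, pl, pose = NULL, waxes = NULL) {
  if (is.null(pose)) pose <- fk_pose(model, q)
  if (is.null(waxes)) waxes <- world_axes(model, pose)
  ns <- length(model$sphere_radius)
  tau <- numeric(model$nq)
  F <- matrix(0, 3, ns); P <- matrix(0, 3, ns); depth <- numeric(ns)
  ct <- model$contact
  n <- pl$n
  for (i in seq_len(ns)) {
    b <- model$sphere_body[i]
    cw <- as.numeric(body_point(model, pose, b, model$sphere_center[, i]))
    d <- model$sphere_radius[i] - sum(n * (cw - pl$p))
    depth[i] <- d
    if (d <= 0) next
    cp <- cw - model$sphere_radius[i] * n
    ## velocity of the foot material point at the contact point
    vf <- c(0, 0, 0)
    j <- b
    while (j != 0L) {
      a <- waxes[, j]; r <- cp - pose$O[, j]
      vf <- vf + qdot[j] * c(a[2] * r[3] - a[3] * r[2],
                             a[3] * r[1] - a[1] * r[3],
                             a[1] * r[2] - a[2] * r[1])
      j <- model$parent[j]
    }
    ## velocity of the plane surface point currently at cp
    rp <- cp - pl$p
    vp <- pl$v + c(pl$w[2] * rp[3] - pl$w[3] * rp[2],
                   pl$w[3] * rp[1] - pl$w[1] * rp[3],
                   pl$w[1] * rp[2] - pl$w[2] * rp[1])
    vrel <- vf - vp
    ## penetration rate: -d/dt [ n . (c - p) ]
    wn <- c(pl$w[2] * n[3] - pl$w[3] * n[2],
            pl$w[3] * n[1] - pl$w[1] * n[3],
            pl$w[1] * n[2] - pl$w[2] * n[1])
    ddot <- -(sum(wn * (cw - pl$p)) + sum(n * (vf - pl$v)))
    fn <- model$sphere_k[i] * d^ct$exponent * (1 + ct$dissipation * ddot)
    if (fn < 0) fn <- 0
    vs <- vrel - sum(n * vrel) * n
    fvec <- fn * n - fn * ct$f_v * vs
    F[, i] <- fvec; P[, i] <- cp
    if (fn > 0) tau <- accum_point_force(model, pose, waxes, b, cp, fvec, tau)
  }
  list(tau = tau, force = F, point = P, depth = depth)
}
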