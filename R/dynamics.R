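## ---- rigid-body machinery -------------------------------------------------

## world-frame inertia of body k at pose
world_inertia <- function(model, pose, k) {
  R <- pose$R[, , k]
  R %*% model$inertia[, , k] %*% t(R)
}

## world centre-of-mass positions, 3 x nb
world_coms <- function(model, pose) {
  nb <- model$nq
  cm <- matrix(0, 3, nb)
  for (k in seq_len(nb))
    cm[, k] <- body_point(model, pose, k, model$com[, k])
  cm
}

#' Joint-space mass matrix
#'
#' Assembles the 5 x 5 generalized mass matrix
#' `M(q) = sum_b m_b J_v^T J_v + J_w^T I_b(q) J_w` over the movable
#' segments, where `J_v` and `J_w` are the centre-of-mass point and
#' angular Jacobians of each body.  `M` is symmetric positive definite for
#' any valid parameter set.
#'
#' @param model a [build_foot_model()] object.
#' @param q joint angles (rad).
#' @return 5 x 5 numeric matrix (kg m^2).
#' @export
mass_matrix <- function(model, q) {
  pose <- fk_pose(model, q)
  waxes <- world_axes(model, pose)
  nb <- model$nq
  M <- matrix(0, nb, nb)
  cm <- world_coms(model, pose)
  for (k in seq_len(nb)) {
    Jv <- matrix(0, 3, nb); Jw <- matrix(0, 3, nb)
    j <- k
    while (j != 0L) {
      Jv[, j] <- cross3(waxes[, j], cm[, k] - pose$O[, j])
      Jw[, j] <- waxes[, j]
      j <- model$parent[j]
    }
    Iw <- world_inertia(model, pose, k)
    M <- M + model$mass[k] * crossprod(Jv) + t(Jw) %*% Iw %*% Jw
  }
  (M + t(M)) / 2
}

## velocity-product (Coriolis/centrifugal) generalized forces C(q, qdot),
## computed by a recursive Newton-Euler sweep with qddot = 0 and gravity
## excluded.  Returns the bias vector such that M qddot + bias = tau.
bias_forces <- function(model, q, qdot, pose = NULL, waxes = NULL) {
  nb <- model$nq
  if (is.null(pose)) pose <- fk_pose(model, q)
  if (is.null(waxes)) waxes <- world_axes(model, pose)
  omega <- matrix(0, 3, nb); alpha <- matrix(0, 3, nb)
  aO <- matrix(0, 3, nb); vO <- matrix(0, 3, nb)
  acom <- matrix(0, 3, nb)
  cm <- world_coms(model, pose)
  for (k in seq_len(nb)) {
    p <- model$parent[k]
    if (p == 0L) {
      wp <- c(0, 0, 0); ap <- c(0, 0, 0); vOp <- c(0, 0, 0); aOp <- c(0, 0, 0)
      Op <- model$jo[, k]  # joint origin on the fixed tibia: zero velocity
      dO <- c(0, 0, 0)
    } else {
      wp <- omega[, p]; ap <- alpha[, p]; vOp <- vO[, p]; aOp <- aO[, p]
      dO <- pose$O[, k] - pose$O[, p]
    }
    a <- waxes[, k]
    omega[, k] <- wp + a * qdot[k]
    alpha[, k] <- ap + cross3(wp, a) * qdot[k]
    vO[, k] <- vOp + cross3(wp, dO)
    aO[, k] <- aOp + cross3(ap, dO) + cross3(wp, cross3(wp, dO))
    rc <- cm[, k] - pose$O[, k]
    acom[, k] <- aO[, k] + cross3(alpha[, k], rc) +
      cross3(omega[, k], cross3(omega[, k], rc))
  }
  Fb <- matrix(0, 3, nb); Nb <- matrix(0, 3, nb)
  tau <- numeric(nb)
  for (k in rev(seq_len(nb))) {
    fk <- model$mass[k] * acom[, k]
    Iw <- world_inertia(model, pose, k)
    nk <- Iw %*% alpha[, k] + cross3(omega[, k], Iw %*% omega[, k]) +
      cross3(cm[, k] - pose$O[, k], fk)
    Fb[, k] <- Fb[, k] + fk
    Nb[, k] <- Nb[, k] + nk
    tau[k] <- sum(waxes[, k] * Nb[, k])
    p <- model$parent[k]
    if (p != 0L) {
      Fb[, p] <- Fb[, p] + Fb[, k]
      Nb[, p] <- Nb[, p] + Nb[, k] +
        cross3(pose$O[, k] - pose$O[, p], Fb[, k])
    }
  }
  tau
}

## gravity generalized torques (J_com^T m g per body)
gravity_torques <- function(model, pose, waxes) {
  nb <- model$nq
  g <- c(0, -model$subject$gravity, 0)
  tau <- numeric(nb)
  cm <- world_coms(model, pose)
  for (k in seq_len(nb))
    tau <- accum_point_force(model, pose, waxes, k, cm[, k],
                             model$mass[k] * g, tau)
  tau
}

## passive joint torques: linear spring to the neutral angle, viscous
## damping, and stiff soft-stops beyond the joint range
STOP_STIFFNESS <- 250  # N m / rad beyond the range limits

passive_torques <- function(model, q, qdot, damping = TRUE) {
  tau <- -model$stiffness * (q - model$neutral)
  if (damping) tau <- tau - model$damping * qdot
  lo <- model$range[1, ]; hi <- model$range[2, ]
  over <- q > hi; under <- q < lo
  if (any(over)) tau[over] <- tau[over] - STOP_STIFFNESS * (q[over] - hi[over])
  if (any(under)) tau[under] <- tau[under] - STOP_STIFFNESS * (q[under] - lo[under])
  tau
}

## total generalized applied torque at a state (excluding inertial bias):
## muscles + contact + gravity + passive.  `pl` may be NULL (no contact).
applied_torques <- function(model, q, qdot, tensions = NULL, pl = NULL,
                            gravity = TRUE, passive = TRUE, damping = TRUE,
                            return_contact = FALSE) {
  pose <- fk_pose(model, q)
  waxes <- world_axes(model, pose)
  tau <- numeric(model$nq)
  cf <- NULL
  if (!is.null(tensions)) tau <- tau + muscle_torques(model, pose, waxes, tensions)
  if (!is.null(pl)) {
    cf <- contact_forces(model, q, qdot, pl, pose, waxes)
    tau <- tau + cf$tau
  }
  if (gravity) tau <- tau + gravity_torques(model, pose, waxes)
  if (passive) tau <- tau + passive_torques(model, q, qdot, damping)
  if (return_contact) list(tau = tau, contact = cf) else tau
}

#' Equations of motion of the articulated foot
#'
#' Computes joint accelerations from `M(q) qddot = tau_applied - C(q,
#' qdot)`, where the applied torque gathers muscle, contact, gravity and
#' passive (spring/damper/soft-stop) contributions and `C` is the
#' velocity-product bias from a recursive Newton-Euler sweep.
#'
#' @param model a [build_foot_model()] object.
#' @param q,qdot joint angles (rad) and velocities (rad/s).
#' @param tensions named tensions (N) for the active scenario paths, or
#'   `NULL` for no muscle forces.
#' @param plane a [plane_pose()] result, or `NULL` for no ground contact.
#' @param gravity,passive include gravity / passive joint torques.
#' @return numeric vector of 5 joint accelerations (rad/s^2).
#' @export
equations_of_motion <- function(model, q, qdot, tensions = NULL,
                                plane = NULL, gravity = TRUE,
                                passive = TRUE) {
  if (any(!is.finite(q)) || any(!is.finite(qdot)))
    stop("non-finite state", call. = FALSE)
  M <- mass_matrix(model, q)
  cn <- tryCatch(solve(M, diag(model$nq)), error = function(e) NULL)
  if (is.null(cn))
    stop("singular mass matrix: check segment inertial parameters",
         call. = FALSE)
  tau <- applied_torques(model, q, qdot, tensions, plane,
                         gravity = gravity, passive = passive)
  b <- bias_forces(model, q, qdot)
  as.numeric(cn %*% (tau - b))
}

## fast RHS used by the integrator (avoids repeated FK where possible)
make_rhs <- function(model, traj, profiles, gravity = TRUE) {
  dur <- traj$duration
  function(t, y, parms) {
    q <- y[1:5]; qdot <- y[6:10]
    s <- min(max(t / dur, 0), 1)
    tensions <- scenario_tensions(model, profiles, s)
    pl <- plane_pose(traj, s * dur)
    pose <- fk_pose(model, q)
    waxes <- world_axes(model, pose)
    tau <- muscle_torques(model, pose, waxes, tensions) +
      gravity_torques(model, pose, waxes) +
      passive_torques(model, q, qdot)
    cf <- contact_forces(model, q, qdot, pl, pose, waxes)
    tau <- tau + cf$tau
    M <- mass_matrix(model, q)
    b <- bias_forces(model, q, qdot, pose, waxes)
    qddot <- solve(M, tau - b)
    list(c(qdot, as.numeric(qddot)))
  }
}

## Build the compiled-RHS context: flattened model arrays plus dense time
## grids of the plane pose and path tensions (linear interpolation inside
## the compiled code; grid fine enough that the error is negligible).
model_ctx_list <- function(model, damping_scale = 1) {
  paths <- active_paths(model)
  list(
    nq = as.integer(model$nq),
    parent = as.integer(model$parent),
    jo = model$jo, axis = model$axis, com = model$com,
    stiffness = model$stiffness, damping = model$damping * damping_scale,
    neutral = model$neutral, range = model$range,
    mass = model$mass,
    inertia = as.numeric(model$inertia),
    stop_k = STOP_STIFFNESS,
    sphere_body = as.integer(model$sphere_body),
    sphere_center = model$sphere_center,
    sphere_radius = model$sphere_radius,
    sphere_k = model$sphere_k,
    contact = model$contact,
    gravity = model$subject$gravity,
    paths = lapply(paths, function(p)
      list(body = as.integer(p$body), points = p$points, amp = p$amp))
  )
}

make_rhs_context <- function(model, traj, profiles, grid_n = 2049L) {
  paths <- active_paths(model)
  ml <- model_ctx_list(model)
  tg <- seq(0, traj$duration, length.out = grid_n)
  Rg <- matrix(0, 9, grid_n); pg <- matrix(0, 3, grid_n)
  vg <- matrix(0, 3, grid_n); wg <- matrix(0, 3, grid_n)
  tn <- matrix(0, length(paths), grid_n)
  for (i in seq_len(grid_n)) {
    pl <- plane_pose(traj, tg[i])
    Rg[, i] <- as.numeric(pl$R); pg[, i] <- pl$p
    vg[, i] <- pl$v; wg[, i] <- pl$w
    tn[, i] <- scenario_tensions(model, profiles, tg[i] / traj$duration)
  }
  .rhs_context(ml, list(t = tg, R = Rg, p = pg, v = vg, w = wg,
                        tension = tn))
}

make_rhs_compiled <- function(model, traj, profiles, grid_n = 2049L) {
  ctx <- make_rhs_context(model, traj, profiles, grid_n)
  function(t, y, parms) list(.rhs_eval(ctx, t, y))
}

## ---- static equilibrium ---------------------------------------------------

## Dynamic-relaxation equilibrium: integrate the damped dynamics under a
## frozen plane pose and frozen tensions until motion dies out, then polish
## with a few damped-Newton steps.  Far more robust than Newton alone when
## contact activates/deactivates or a joint rests on a range stop.
relax_static <- function(model, tensions = NULL, pl = NULL,
                         q0 = model$neutral, t_relax = 1.5,
                         damping_scale = 15) {
  ml <- model_ctx_list(model, damping_scale)
  if (is.null(pl))
    pl <- list(R = diag(3), p = c(0, -100, 0), n = c(0, 1, 0),
               v = c(0, 0, 0), w = c(0, 0, 0))
  np <- length(active_paths(model))
  tn <- if (is.null(tensions)) numeric(np) else as.numeric(tensions)
  grids <- list(t = c(0, t_relax),
                R = matrix(as.numeric(pl$R), 9, 2),
                p = matrix(pl$p, 3, 2), v = matrix(0, 3, 2),
                w = matrix(0, 3, 2), tension = matrix(tn, np, 2))
  ctx <- .rhs_context(ml, grids)
  rhs <- function(t, y, parms) list(.rhs_eval(ctx, t, y))
  y <- c(q0, numeric(model$nq))
  for (chunk in 1:3) {
    sol <- deSolve::ode(y, c(0, t_relax / 2, t_relax), rhs, NULL,
                        method = "lsoda", rtol = 1e-6, atol = 1e-8,
                        maxsteps = 100000)
    y <- sol[nrow(sol), -1]
    if (max(abs(y[(model$nq + 1):(2 * model$nq)])) < 1e-3) break
    y[(model$nq + 1):(2 * model$nq)] <- 0  # kill residual momentum
  }
  y[1:model$nq]
}

## Solve joint angles q such that the applied torques vanish at rest,
## optionally against a plane pose.  Used for initial conditions and by the
## trajectory generator.
solve_static <- function(model, tensions = NULL, pl = NULL,
                         q0 = model$neutral, tol = 1e-7, relax = TRUE) {
  fn <- function(q) applied_torques(model, q, numeric(model$nq), tensions,
                                    pl, damping = FALSE)
  if (relax) q0 <- relax_static(model, tensions, pl, q0)
  res <- newton_solve(fn, q0, tol = tol, max_iter = 12, step_max = 0.1)
  if (relax && res$residual > 0.5) {
    ## polish failed: re-relax from the polished point and try again
    q1 <- relax_static(model, tensions, pl, res$x, t_relax = 5)
    res2 <- newton_solve(fn, q1, tol = tol, max_iter = 12, step_max = 0.1)
    if (res2$residual < res$residual) res <- res2
  }
  if (!res$converged && res$residual > 1e-3)
    warning("static equilibrium solve residual ",
            format(res$residual, digits = 3), " N m")
  res$x
}

## ---- stance simulation ----------------------------------------------------

#' Simulate the stance phase of gait
#'
#' Integrates the fixed-tibia foot model forward over the full stance
#' (default 4.09 s) under muscle tensions from the activation profiles,
#' passive joint torques, gravity and moving-plane contact, using a stiff
#' variable-step integrator (`deSolve::lsoda`).  The initial pose is the
#' static equilibrium against the plane at heel strike with zero joint
#' velocity, and the output is resampled onto a uniform stance grid.
#'
#' @param model a [build_foot_model()] object.
#' @param traj a [ground_trajectory()] (already carrying any calibration
#'   offset).
#' @param profiles named list of [activation_profile()]s covering every
#'   profile the scenario's muscle map draws from.
#' @param options list of integrator options: `rtol`, `atol`, `n_out`
#'   (output samples, >= 1000 for full runs); defaults from
#'   `default_parameter_set()$sim`.
#' @return An object of class `sim_trace`: list with `time` (s), `pct`
#'   (percent stance), `q`, `qdot` (n x 5), `sphere_f` (3 x 5 x n world
#'   contact forces), `sphere_depth` (n x 5), `tensions` (n x paths),
#'   `sphere_names`, `body_weight` (N), `scenario`.
#' @export
simulate_stance <- function(model, traj, profiles,
                            options = default_parameter_set()$sim) {
  dur <- traj$duration
  n_out <- if (is.null(options$n_out)) 1025L else options$n_out
  rtol <- if (is.null(options$rtol)) 1e-6 else options$rtol
  atol <- if (is.null(options$atol)) 1e-8 else options$atol

  pl0 <- plane_pose(traj, 0)
  tens0 <- scenario_tensions(model, profiles, 0)
  q0 <- solve_static(model, tens0, pl0)
  y0 <- c(q0, numeric(model$nq))

  times <- seq(0, dur, length.out = n_out)
  use_compiled <- if (is.null(options$use_compiled)) TRUE else options$use_compiled
  rhs <- if (use_compiled) make_rhs_compiled(model, traj, profiles)
         else make_rhs(model, traj, profiles)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (any(!is.finite(sol)) || nrow(sol) < n_out) {
    bad <- if (nrow(sol) >= 1) sol[nrow(sol), 1] else NA
    stop("stance integration failed near t = ", format(bad),
         " s; last state: ",
         paste(format(sol[nrow(sol), -1], digits = 3), collapse = " "),
         call. = FALSE)
  }

  q <- sol[, 2:6, drop = FALSE]
  qdot <- sol[, 7:11, drop = FALSE]
  ns <- length(model$sphere_radius)
  np <- length(active_paths(model))
  sphere_f <- array(0, c(3, ns, n_out))
  sphere_depth <- matrix(0, n_out, ns)
  tension_mat <- matrix(0, n_out, np)
  colnames(tension_mat) <- names(active_paths(model))
  for (i in seq_len(n_out)) {
    t <- times[i]
    s <- min(max(t / dur, 0), 1)
    pl <- plane_pose(traj, t)
    tens <- scenario_tensions(model, profiles, s)
    cf <- contact_forces(model, q[i, ], qdot[i, ], pl)
    sphere_f[, , i] <- cf$force
    sphere_depth[i, ] <- cf$depth
    tension_mat[i, ] <- tens
  }
  structure(list(
    time = times, pct = 100 * times / dur,
    q = q, qdot = qdot,
    sphere_f = sphere_f, sphere_depth = sphere_depth,
    tensions = tension_mat,
    sphere_names = model$sphere_names,
    body_weight = model$subject$mass_kg * model$subject$gravity,
    scenario = model$scenario$kind,
    duration = dur
  ), class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  v <- total_vgrf(x)
  cat("<sim_trace>", x$scenario, "-", length(x$time), "samples over",
      format(x$duration), "s\n")
  cat("  peak total vGRF:", format(max(v$bw), digits = 4), "BW\n")
  invisible(x)
}

#' Calibrate the initial foot-plane distance to a body-weight target
#'
#' Adjusts the vertical offset of the ground-plane trajectory (the initial
#' penetration of the heel sphere at heel strike) until the mean of the two
#' vertical ground reaction force peak magnitudes matches the double-peak
#' scale of the target subject's gait (default 1.105 body weights for an
#' 82 kg individual).  The offset-to-peak map is monotone, so the root is
#' found by secant iteration safeguarded by bisection on a bracketing
#' interval.
#'
#' @param model the model to calibrate against (the arched scenario; the
#'   resulting offset is shared by all scenarios).
#' @param traj the uncalibrated [ground_trajectory()].
#' @param profiles activation profiles.
#' @param target_mass_kg subject mass (kg) defining one body weight.
#' @param tol tolerance on the mean peak magnitude (body weights).
#' @param target_peak_bw target mean-of-peaks (body weights).
#' @param options integrator options for the calibration runs (defaults use
#'   a reduced output grid for speed; the returned offset is independent of
#'   the grid to within the stated tolerance).
#' @param max_iter iteration cap.
#' @return list of class `calibration_result`: `heel_offset` (m),
#'   `achieved_peak` (BW), `iterations`, `target_peak_bw`, `converged`.
#' @export
calibrate_heel_offset <- function(model, traj, profiles,
                                  target_mass_kg = 82, tol = 0.02,
                                  target_peak_bw = 1.105,
                                  options = NULL, max_iter = 30) {
  if (target_mass_kg <= 0) stop("target_mass_kg must be > 0", call. = FALSE)
  if (is.null(options))
    options <- list(rtol = 1e-5, atol = 1e-7, n_out = 401L)
  bw <- target_mass_kg * model$subject$gravity

  peak_of <- function(offset) {
    tr <- simulate_stance(model, shift_trajectory(traj, offset), profiles,
                          options)
    v <- total_vgrf(tr, body_weight = bw)
    pk <- find_double_peak(v)
    if (pk$degenerate) max(v$bw) else (pk$peak1["bw"] + pk$peak2["bw"]) / 2
  }

  iter <- 0L
  x0 <- 0; f0 <- peak_of(x0) - target_peak_bw; iter <- iter + 1L
  if (abs(f0) <= tol)
    return(structure(list(heel_offset = x0, achieved_peak = f0 + target_peak_bw,
                          iterations = iter, target_peak_bw = target_peak_bw,
                          converged = TRUE), class = "calibration_result"))
  ## bracket the root by stepping in the descent direction
  step <- if (f0 > 0) -0.002 else 0.002
  x1 <- x0; f1 <- f0
  repeat {
    x1 <- x1 + step; iter <- iter + 1L
    if (iter > max_iter || abs(x1) > 0.05)
      stop("calibration failed to bracket the body-weight target ",
           "(offset search reached ", format(x1), " m)", call. = FALSE)
    f1 <- peak_of(x1) - target_peak_bw
    if (sign(f1) != sign(f0)) break
    x0 <- x1; f0 <- f1
  }
  lo <- min(x0, x1); hi <- max(x0, x1)
  flo <- if (lo == x0) f0 else f1
  fhi <- if (hi == x1) f1 else f0
  while (iter < max_iter) {
    xm <- (lo * fhi - hi * flo) / (fhi - flo)  # secant / regula falsi
    if (!is.finite(xm) || xm <= lo || xm >= hi) xm <- (lo + hi) / 2
    fm <- peak_of(xm) - target_peak_bw; iter <- iter + 1L
    if (abs(fm) <= tol)
      return(structure(list(heel_offset = xm,
                            achieved_peak = fm + target_peak_bw,
                            iterations = iter,
                            target_peak_bw = target_peak_bw,
                            converged = TRUE), class = "calibration_result"))
    if (sign(fm) == sign(flo)) { lo <- xm; flo <- fm } else { hi <- xm; fhi <- fm }
  }
  structure(list(heel_offset = (lo + hi) / 2,
                 achieved_peak = NA_real_, iterations = iter,
                 target_peak_bw = target_peak_bw, converged = FALSE),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> offset", format(x$heel_offset, digits = 4),
      "m, mean peak", format(x$achieved_peak, digits = 4), "BW (target",
      format(x$target_peak_bw, digits = 4), "BW),", x$iterations,
      "simulations\n")
  invisible(x)
}

## total mechanical energy (kinetic + gravity + joint springs incl. soft
## stops); used by conservation tests
total_energy <- function(model, q, qdot) {
  M <- mass_matrix(model, q)
  ke <- 0.5 * sum(qdot * (M %*% qdot))
  pose <- fk_pose(model, q)
  cm <- world_coms(model, pose)
  pe_g <- model$subject$gravity * sum(model$mass * cm[2, ])
  dq <- q - model$neutral
  pe_s <- 0.5 * sum(model$stiffness * dq^2)
  lo <- model$range[1, ]; hi <- model$range[2, ]
  pe_s <- pe_s + 0.5 * STOP_STIFFNESS * sum(pmax(q - hi, 0)^2 +
                                              pmax(lo - q, 0)^2)
  ke + pe_g + pe_s
}
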