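#' Construct an activation profile
#'
#' An activation profile is a muscle's excitation over the stance phase,
#' defined by exactly ten control values in `[0, 1]` at the evenly spaced
#' stance fractions `0, 1/9, ..., 1` and interpolated linearly in between.
#'
#' @param muscle muscle label.
#' @param control_points numeric vector of 10 values in `[0, 1]`.
#' @return An object of class `activation_profile`.
#' @export
activation_profile <- function(muscle, control_points) {
  control_points <- as.numeric(control_points)
  if (length(control_points) != 10L)
    stop("an activation profile needs exactly 10 control points",
         call. = FALSE)
  if (any(!is.finite(control_points)) ||
      any(control_points < 0) || any(control_points > 1))
    stop("activation control points must lie in [0, 1] (muscle '",
         muscle, "')", call. = FALSE)
  structure(list(muscle = muscle, control_points = control_points),
            class = "activation_profile")
}

#' @export
print.activation_profile <- function(x, ...) {
  cat("<activation_profile>", x$muscle, "\n ",
      paste(format(x$control_points, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Evaluate an activation profile
#'
#' Piecewise-linear interpolation between the ten control points; values of
#' `s` outside `[0, 1]` clamp to the nearest endpoint, and the control
#' values are returned exactly at the control abscissae.
#'
#' @param profile an [activation_profile()].
#' @param s stance fraction(s) in `[0, 1]` (vectorised).
#' @return activation value(s) in `[0, 1]`.
#' @export
#' @examples
#' p <- activation_profile("soleus", c(0, 0, .1, .2, .3, .5, .8, .9, .4, .1))
#' activation_at(p, 3 / 9)   # == control_points[4]
activation_at <- function(profile, s) {
  cp <- profile$control_points
  s <- pmin(pmax(s, 0), 1)
  u <- s * 9
  i <- pmin(floor(u), 8)
  w <- u - i
  (1 - w) * cp[i + 1] + w * cp[i + 2]
}

#' Muscle tension from activation
#'
#' The tension delivered by a muscle is the product of its activation and
#' its maximum isometric force; no force-length or force-velocity scaling
#' is applied.
#'
#' @param profile an [activation_profile()].
#' @param s stance fraction in `[0, 1]`.
#' @param fmax maximum isometric force (N, > 0).
#' @return tension (N).
#' @export
muscle_tension <- function(profile, s, fmax) {
  if (fmax <= 0) stop("fmax must be > 0", call. = FALSE)
  activation_at(profile, s) * fmax
}

#' Geometry of a muscle path at a pose
#'
#' Routes a via-point muscle path through the model at joint configuration
#' `q` and returns the world positions of the via points, the unit
#' direction of each straight-line segment and the total path length.
#'
#' @param model a [build_foot_model()] object.
#' @param path a muscle path (an element of `model$muscles`, or a muscle
#'   name).
#' @param q joint angles (rad).
#' @return list with `points` (3 x k world positions), `dirs`
#'   (3 x (k-1) unit directions) and `length` (m).
#' @export
path_geometry <- function(model, path, q) {
  if (is.character(path)) {
    path <- model$muscles[[path]]
    if (is.null(path)) stop("unknown muscle path", call. = FALSE)
  }
  pose <- fk_pose(model, q)
  k <- ncol(path$points)
  pts <- matrix(0, 3, k)
  for (i in seq_len(k))
    pts[, i] <- body_point(model, pose, path$body[i], path$points[, i])
  dirs <- matrix(0, 3, k - 1)
  len <- 0
  for (i in seq_len(k - 1)) {
    d <- pts[, i + 1] - pts[, i]
    L <- sqrt(sum(d^2))
    if (L < 1e-9)
      stop("coincident consecutive via points in path '", path$name, "'",
           call. = FALSE)
    dirs[, i] <- d / L
    len <- len + L
  }
  list(points = pts, dirs = dirs, length = len)
}

## world joint axes for a pose: column k = axis of joint k in world frame
world_axes <- function(model, pose) {
  nb <- model$nq
  w <- matrix(0, 3, nb)
  for (k in seq_len(nb)) {
    p <- model$parent[k]
    w[, k] <- if (p == 0L) model$axis[, k] else pose$R[, , p] %*% model$axis[, k]
  }
  w
}

## accumulate generalized torque of a world force F applied at world point P
## on body b: tau_j += (a_j x (P - O_j)) . F for every ancestor joint j
accum_point_force <- function(model, pose, waxes, b, P, F, tau) {
  if (b == 0L) return(tau)
  j <- b
  while (j != 0L) {
    r <- P - pose$O[, j]
    a <- waxes[, j]
    tau[j] <- tau[j] +
      (a[2] * r[3] - a[3] * r[2]) * F[1] +
      (a[3] * r[1] - a[1] * r[3]) * F[2] +
      (a[1] * r[2] - a[2] * r[1]) * F[3]
    j <- model$parent[j]
  }
  tau
}

#' Generalized joint torques from muscle tensions
#'
#' Applies each straight path segment as an equal and opposite force pair
#' of magnitude equal to the path tension along the segment direction at
#' its endpoints, and accumulates the resulting generalized torque about
#' each joint.  By the moment-arm identity the torque about joint `j`
#' equals `-tension * dL/dq_j`.
#'
#' @param model a [build_foot_model()] object.
#' @param q joint angles (rad).
#' @param tensions named numeric vector of non-negative path tensions (N),
#'   named by path; paths absent from the vector carry zero tension.
#'   Tensions are interpreted on the model's *active* scenario paths (see
#'   [configure_scenario_muscles()]), so in the implant scenario the
#'   `tib_post` entry is the input tension of the transferred tendon and
#'   the artificial tendon applies `amplification` times that value.
#' @return numeric vector of 5 generalized torques (N m).
#' @export
apply_muscle_forces <- function(model, q, tensions) {
  if (any(tensions < 0)) stop("tensions must be >= 0", call. = FALSE)
  pose <- fk_pose(model, q)
  waxes <- world_axes(model, pose)
  muscle_torques(model, pose, waxes, tensions)
}

## fast path used by the dynamics right-hand side: pose/axes precomputed
muscle_torques <- function(model, pose, waxes, tensions) {
  tau <- numeric(model$nq)
  paths <- active_paths(model)
  for (ap in paths) {
    Tin <- tensions[ap$tension_name]
    if (is.na(Tin) || Tin == 0) next
    Tapp <- Tin * ap$amp
    k <- ncol(ap$points)
    pts <- matrix(0, 3, k)
    for (i in seq_len(k))
      pts[, i] <- body_point(model, pose, ap$body[i], ap$points[, i])
    for (i in seq_len(k - 1L)) {
      b1 <- ap$body[i]; b2 <- ap$body[i + 1L]
      if (b1 == 0L && b2 == 0L) next
      d <- pts[, i + 1L] - pts[, i]
      L <- sqrt(sum(d^2))
      u <- d / L
      ## force +T u on the proximal point's body, -T u on the distal one
      if (b1 != 0L) tau <- accum_point_force(model, pose, waxes, b1,
                                             pts[, i], Tapp * u, tau)
      if (b2 != 0L) tau <- accum_point_force(model, pose, waxes, b2,
                                             pts[, i + 1L], -Tapp * u, tau)
    }
  }
  tau
}

#' Output tension of the ideal pulley implant
#'
#' The pulley implant replaces the direct tendon-to-bone attachment of the
#' tendon transfer: the transferred donor tendon wraps the implant and is
#' anchored back on the tibia, so the artificial tendon between the implant
#' and the navicular insertion carries `amplification` times the donor
#' tension.  The implant is ideal and frictionless: no energy is lost, and
#' the price of the mechanical advantage is a proportional loss of
#' excursion (see [pulley_excursion()]).
#'
#' @param input_tension donor (transferred FDL) tension (N, >= 0).
#' @param implant implant definition with `amplification` >= 1 (see
#'   `default_parameter_set()$implant`).
#' @return artificial-tendon tension (N).
#' @export
#' @examples
#' pulley_output_tension(100, list(amplification = 2))  # 200
pulley_output_tension <- function(input_tension, implant) {
  if (implant$amplification < 1)
    stop("pulley amplification must be >= 1", call. = FALSE)
  if (any(input_tension < 0))
    stop("input_tension must be >= 0", call. = FALSE)
  implant$amplification * input_tension
}

#' Excursion across the ideal pulley implant
#'
#' The artificial tendon moves `1/amplification` times the excursion of the
#' donor tendon, and the implant itself translates by the same reduced
#' amount along its sagittal-plane routing direction, so that mechanical
#' work is conserved: `input_tension * input_excursion = output_tension *
#' output_excursion`.
#'
#' @param input_excursion donor tendon excursion (m).
#' @param implant implant definition with `amplification` >= 1.
#' @return list with `output_excursion` and `implant_translation` (m).
#' @export
#' @examples
#' pulley_excursion(0.020, list(amplification = 2))$output_excursion  # 0.010
pulley_excursion <- function(input_excursion, implant) {
  if (implant$amplification < 1)
    stop("pulley amplification must be >= 1", call. = FALSE)
  out <- input_excursion / implant$amplification
  list(output_excursion = out, implant_translation = out)
}

#' Scenario muscle map
#'
#' Returns, for each of the nine muscle paths, whether it is enabled in the
#' given scenario, which activation profile drives it, which muscle's
#' maximum isometric force scales that profile, and whether the path is
#' rerouted through the pulley implant:
#'
#' * `ARCHED`: all nine muscles enabled with native profiles.
#' * `FLATFOOT`: the posterior tibialis is disabled (tendon dysfunction).
#' * `FLATFOOT_TT`: the native FDL path is disabled and the FDL profile and
#'   force capacity drive the original PT path (the transferred tendon).
#' * `FLATFOOT_TT_IMPLANT`: as `FLATFOOT_TT`, with the transferred tendon
#'   rerouted through the implant; the artificial tendon delivers
#'   `pulley_amplification` times the donor tension at the navicular.
#'
#' @param scenario a [foot_scenario()] object or kind string.
#' @return named list (one entry per muscle) with fields `enabled`,
#'   `source`, `fmax_source`, `route` and `amp`; class `scenario_muscle_map`.
#' @export
configure_scenario_muscles <- function(scenario) {
  if (is.character(scenario)) scenario <- foot_scenario(scenario)
  muscles <- c("tib_post", "fdl", "tib_ant", "edl", "ehl", "fhl",
               "per_long", "per_brev", "soleus")
  map <- lapply(muscles, function(m)
    list(muscle = m, enabled = TRUE, source = m, fmax_source = m,
         route = "native", amp = 1))
  names(map) <- muscles
  if (scenario$kind == "FLATFOOT") {
    map$tib_post$enabled <- FALSE
  } else if (scenario$kind %in% c("FLATFOOT_TT", "FLATFOOT_TT_IMPLANT")) {
    map$fdl$enabled <- FALSE
    map$tib_post$source <- "fdl"
    map$tib_post$fmax_source <- "fdl"
    if (scenario$kind == "FLATFOOT_TT_IMPLANT") {
      map$tib_post$route <- "implant"
      map$tib_post$amp <- scenario$pulley_amplification
    }
  }
  structure(map, class = "scenario_muscle_map")
}

## Resolve the scenario muscle map into concrete force-application paths.
## For the implant route the applied path is the artificial tendon from the
## implant point (tibia frame, on the original distal PT course) to the
## navicular insertion, carrying `amp` times the input tension; the donor
## strands run tibia-to-tibia and exert no force on the foot.
active_paths <- function(model) {
  if (!is.null(model$.active_paths)) return(model$.active_paths)
  out <- list()
  for (m in model$muscle_map) {
    if (!m$enabled) next
    path <- model$muscles[[m$muscle]]
    if (m$route == "implant") {
      k <- ncol(path$points)
      path <- list(name = paste0(m$muscle, "_implant"),
                   body = c(0L, path$body[k]),
                   points = cbind(model$implant$implant_point,
                                  path$points[, k]),
                   fmax = path$fmax)
    }
    out[[m$muscle]] <- c(path, list(tension_name = m$muscle, amp = m$amp,
                                    source = m$source,
                                    fmax_source = m$fmax_source))
  }
  out
}

## tensions (N) applied to each active path at stance fraction s:
## activation of the source profile times the source muscle's fmax
scenario_tensions <- function(model, profiles, s) {
  paths <- active_paths(model)
  out <- numeric(length(paths))
  names(out) <- names(paths)
  for (nm in names(paths)) {
    ap <- paths[[nm]]
    pr <- profiles[[ap$source]]
    if (is.null(pr))
      stop("no activation profile for muscle '", ap$source, "'",
           call. = FALSE)
    fmax <- model$muscles[[ap$fmax_source]]$fmax
    out[nm] <- activation_at(pr, s) * fmax
  }
  out
}
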