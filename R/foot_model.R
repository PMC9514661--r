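#' Foot model scenarios
#'
#' Constructs a scenario descriptor for one of the four foot
#' configurations studied by the package:
#'
#' * `ARCHED` - healthy arched foot, all nine muscles active, native routing.
#' * `FLATFOOT` - stage II adult acquired flatfoot deformity: the arch is
#'   flattened so the first metatarsocuneiform landmark sits 8 mm lower in
#'   the neutral pose, and the posterior tibialis is disabled.
#' * `FLATFOOT_TT` - flatfoot treated with a flexor digitorum longus to
#'   posterior tibialis tendon transfer: the native FDL path is disabled and
#'   the FDL activation/force drives the original PT path.
#' * `FLATFOOT_TT_IMPLANT` - flatfoot treated with the implant-modified
#'   tendon transfer: as `FLATFOOT_TT` but the transferred tendon is routed
#'   through an ideal pulley implant that doubles the tension delivered to
#'   the navicular insertion (at the cost of doubled donor excursion).
#'
#' @param kind one of `"ARCHED"`, `"FLATFOOT"`, `"FLATFOOT_TT"`,
#'   `"FLATFOOT_TT_IMPLANT"`.
#' @param arch_drop_mm vertical drop (mm) of the first metatarsocuneiform
#'   landmark defining the flatfoot; default 0 for `ARCHED`, 8 otherwise.
#' @param pulley_amplification force amplification of the pulley implant;
#'   default 2 for `FLATFOOT_TT_IMPLANT`, 1 otherwise.
#' @return An object of class `foot_scenario`.
#' @export
#' @examples
#' foot_scenario("FLATFOOT")
foot_scenario <- function(kind = c("ARCHED", "FLATFOOT", "FLATFOOT_TT",
                                   "FLATFOOT_TT_IMPLANT"),
                          arch_drop_mm = NULL, pulley_amplification = NULL) {
  kind <- match.arg(kind)
  if (is.null(arch_drop_mm))
    arch_drop_mm <- if (kind == "ARCHED") 0 else 8
  if (is.null(pulley_amplification))
    pulley_amplification <- if (kind == "FLATFOOT_TT_IMPLANT") 2 else 1
  if (arch_drop_mm < 0) stop("arch_drop_mm must be >= 0", call. = FALSE)
  if (pulley_amplification < 1)
    stop("pulley_amplification must be >= 1", call. = FALSE)
  structure(list(kind = kind, arch_drop_mm = arch_drop_mm,
                 pulley_amplification = pulley_amplification),
            class = "foot_scenario")
}

#' @export
print.foot_scenario <- function(x, ...) {
  cat("<foot_scenario> ", x$kind,
      "  arch drop: ", x$arch_drop_mm, " mm",
      "  pulley amplification: ", x$pulley_amplification, "x\n", sep = "")
  invisible(x)
}

scenario_kinds <- function() c("ARCHED", "FLATFOOT", "FLATFOOT_TT",
                               "FLATFOOT_TT_IMPLANT")

#' Build an articulated foot model
#'
#' Assembles the five-segment articulated foot (talus, lateral hindfoot
#' with calcaneus and rays 2-5, medial midfoot with the first ray, hallux,
#' lateral toes) rooted at a fixed tibia, with five revolute joints (ankle,
#' subtalar, arch, medial and lateral metatarsophalangeal), five plantar
#' contact spheres and the nine extrinsic muscle paths, configured for the
#' requested scenario.
#'
#' For flatfoot scenarios the arch joint's spring neutral angle is raised by
#' [flatten_arch()] so the first metatarsocuneiform landmark drops by
#' `scenario$arch_drop_mm` in the neutral pose; the skeleton itself is
#' shared across all scenarios.  The scenario muscle map (which paths are
#' enabled, which activation profile drives each, and whether the pulley
#' implant reroutes the transferred tendon) is attached via
#' [configure_scenario_muscles()].
#'
#' Internally all angles are radians; joint coordinates `q` are measured
#' from the reference pose (the arched neutral pose, in which the sphere
#' bottoms are coplanar).
#'
#' @param scenario a [foot_scenario()] object or a scenario kind string.
#' @param params a parameter bundle from [default_parameter_set()].
#' @return An object of class `foot_model`.
#' @export
#' @examples
#' m <- build_foot_model("ARCHED")
#' m$joint_names
build_foot_model <- function(scenario = "ARCHED",
                             params = default_parameter_set()) {
  if (is.character(scenario)) scenario <- foot_scenario(scenario)
  if (!inherits(scenario, "foot_scenario"))
    stop("scenario must be a foot_scenario or scenario kind string",
         call. = FALSE)
  validate_params(params)

  segdefs <- params$segments
  segnames <- vapply(segdefs, `[[`, "", "name")
  body_names <- setdiff(segnames, "tibia")
  nb <- length(body_names)

  jdefs <- params$joints
  joint_names <- c("ankle", "subtalar", "arch", "mtp_medial", "mtp_lateral")

  ## scenario: flatten the arch spring neutral before unit conversion
  arch <- jdefs$arch
  if (scenario$arch_drop_mm > 0) {
    lm <- params$landmarks$first_mtc
    if (lm$segment != "medial_foot")
      stop("first metatarsocuneiform landmark must lie on the medial chain",
           call. = FALSE)
    jdefs$arch <- flatten_arch(arch, lm$point, scenario$arch_drop_mm)
  }

  ## body bookkeeping: order must be topological (parent before child)
  body_of <- function(seg) if (seg == "tibia") 0L else match(seg, body_names)
  parent <- integer(nb); jo <- matrix(0, 3, nb); axis <- matrix(0, 3, nb)
  stiff <- dampc <- neutral <- numeric(nb)
  jrange <- matrix(0, 2, nb)
  for (k in seq_len(nb)) {
    segname <- body_names[k]
    jname <- segdefs[[segname]]$parent_joint
    jd <- jdefs[[jname]]
    if (jd$child != segname)
      stop("joint '", jname, "' child mismatch for segment '", segname, "'",
         call. = FALSE)
    pidx <- body_of(jd$parent)
    if (pidx >= k && pidx != 0L)
      stop("segments are not in topological order", call. = FALSE)
    parent[k] <- pidx
    jo[, k] <- jd$origin
    a <- jd$axis; axis[, k] <- a / sqrt(sum(a^2))
    stiff[k] <- jd$stiffness * 180 / pi      # N m / rad
    dampc[k] <- jd$damping * 180 / pi        # N m s / rad
    neutral[k] <- deg2rad(jd$neutral_angle)
    jrange[, k] <- deg2rad(jd$range)
  }
  names(parent) <- body_names

  mass <- vapply(body_names, function(s) segdefs[[s]]$mass, 0)
  com <- vapply(body_names, function(s) segdefs[[s]]$com, numeric(3))
  inertia <- array(0, c(3, 3, nb))
  for (k in seq_len(nb)) inertia[, , k] <- segdefs[[body_names[k]]]$inertia

  ## ancestor mask: anc[j, b] is TRUE if joint j lies on the path from the
  ## tibia to body b (joint k moves body k, so this is the ancestor chain)
  anc <- matrix(FALSE, nb, nb)
  for (b in seq_len(nb)) {
    k <- b
    while (k != 0L) { anc[k, b] <- TRUE; k <- parent[k] }
  }

  ## contact spheres
  spdefs <- params$spheres
  sp_body <- vapply(spdefs, function(s) body_of(s$segment), 0L)
  sp_center <- vapply(spdefs, function(s) as.numeric(s$center), numeric(3))
  sp_radius <- vapply(spdefs, function(s) s$diameter / 2, 0)
  sp_kscale <- vapply(spdefs, function(s)
    if (is.null(s$stiffness_scale)) 1 else s$stiffness_scale, 0)
  sp_names <- vapply(spdefs, `[[`, "", "name")
  if (any(sp_body == 0L))
    stop("contact spheres must be attached to movable segments", call. = FALSE)

  ## every distal foot segment must carry at least one contact sphere
  distal <- c("hindfoot_lateral", "medial_foot", "hallux", "lateral_toes")
  carried <- body_names[unique(sp_body)]
  if (!all(distal %in% carried))
    stop("each distal foot segment must carry at least one contact sphere; ",
         "missing: ", paste(setdiff(distal, carried), collapse = ", "),
         call. = FALSE)

  ## the medial chain (medial_foot + hallux) must connect to the rest of the
  ## foot only through the arch joint
  med_idx <- match(c("medial_foot", "hallux"), body_names)
  if (parent[med_idx[1]] != match("hindfoot_lateral", body_names) ||
      body_names[match("medial_foot", body_names)] != "medial_foot" ||
      parent[med_idx[2]] != med_idx[1])
    stop("medial chain must attach through the arch joint only", call. = FALSE)

  muscle_paths <- lapply(params$muscles, function(m) {
    pts <- vapply(m$via, function(v) as.numeric(v[[2]]), numeric(3))
    bds <- vapply(m$via, function(v) body_of(v[[1]]), 0L)
    for (i in seq_len(ncol(pts) - 1L))
      if (sqrt(sum((pts[, i + 1] - pts[, i])^2)) < 1e-9)
        stop("muscle '", m$name, "': coincident consecutive via points",
             call. = FALSE)
    list(name = m$name, body = bds, points = pts, fmax = m$fmax)
  })

  model <- structure(list(
    scenario = scenario,
    body_names = body_names,
    joint_names = joint_names,
    nq = nb,
    parent = parent, jo = jo, axis = axis,
    stiffness = stiff, damping = dampc, neutral = neutral, range = jrange,
    mass = mass, com = com, inertia = inertia,
    anc = anc,
    sphere_names = sp_names, sphere_body = sp_body,
    sphere_center = sp_center, sphere_radius = sp_radius,
    sphere_k = sp_kscale * params$contact$stiffness,
    contact = params$contact,
    muscles = muscle_paths,
    implant = params$implant,
    landmarks = params$landmarks,
    subject = params$subject,
    params = params
  ), class = "foot_model")
  model$muscle_map <- configure_scenario_muscles(scenario)
  model$.active_paths <- active_paths(model)
  model
}

#' @export
print.foot_model <- function(x, ...) {
  cat("<foot_model> scenario:", x$scenario$kind, "\n")
  cat("  segments:", paste(x$body_names, collapse = ", "), "\n")
  cat("  joints:  ", paste(x$joint_names, collapse = ", "), "\n")
  cat("  spheres: ", paste(x$sphere_names, collapse = ", "), "\n")
  cat("  arch spring neutral:",
      format(rad2deg(x$neutral[match("medial_foot", x$body_names)]),
             digits = 4), "deg\n")
  invisible(x)
}

## Rodrigues rotation matrix about unit axis a by angle th
rot_axis <- function(a, th) {
  c1 <- cos(th); s1 <- sin(th); v <- 1 - c1
  ax <- a[1]; ay <- a[2]; az <- a[3]
  matrix(c(
    c1 + ax * ax * v, ax * ay * v + az * s1, ax * az * v - ay * s1,
    ax * ay * v - az * s1, c1 + ay * ay * v, ay * az * v + ax * s1,
    ax * az * v + ay * s1, ay * az * v - ax * s1, c1 + az * az * v
  ), 3, 3)
}

#' Forward kinematics of the foot model
#'
#' Computes the world pose of every movable segment for joint coordinates
#' `q` (radians, measured from the reference pose).  The tibia is the fixed
#' world frame.
#'
#' @param model a [build_foot_model()] object.
#' @param q numeric vector of 5 joint angles (rad).
#' @return list with `R` (3 x 3 x 5 array of body rotations) and `O`
#'   (3 x 5 matrix of body frame origins, i.e. world positions of the joint
#'   centres).
#' @export
fk_pose <- function(model, q) {
  nb <- model$nq
  stopifnot(length(q) == nb)
  R <- array(0, c(3, 3, nb)); O <- matrix(0, 3, nb)
  for (k in seq_len(nb)) {
    p <- model$parent[k]
    Rj <- rot_axis(model$axis[, k], q[k])
    if (p == 0L) {
      R[, , k] <- Rj
      O[, k] <- model$jo[, k]
    } else {
      Rp <- R[, , p]
      R[, , k] <- Rp %*% Rj
      O[, k] <- O[, p] + Rp %*% (model$jo[, k] - model$jo[, p])
    }
  }
  list(R = R, O = O)
}

## world position of a reference-coordinate point attached to body b
## (b = 0 means the fixed tibia)
body_point <- function(model, pose, b, pt) {
  if (b == 0L) return(pt)
  pose$O[, b] + pose$R[, , b] %*% (pt - model$jo[, b])
}

#' World position of a named landmark
#'
#' @param model a [build_foot_model()] object.
#' @param q joint angles (rad); defaults to the model's neutral pose (the
#'   spring rest angles).
#' @param name landmark name, e.g. `"first_mtc"`.
#' @return numeric 3-vector (m, world frame).
#' @export
landmark_position <- function(model, q = model$neutral, name = "first_mtc") {
  lm <- model$landmarks[[name]]
  if (is.null(lm)) stop("unknown landmark '", name, "'", call. = FALSE)
  b <- match(lm$segment, model$body_names)
  pose <- fk_pose(model, q)
  as.numeric(body_point(model, pose, b, lm$point))
}

#' Flatten the medial longitudinal arch
#'
#' Raises the arch joint's spring neutral angle so that a landmark on the
#' medial chain (the first metatarsocuneiform point) drops vertically by
#' `drop_mm` in the neutral pose, holding stiffness and all other joint
#' properties fixed.  Increasing the arch angle relaxes the medial
#' longitudinal arch and flattens the foot.
#'
#' The neutral-angle change is solved in closed form from the rotation of
#' the landmark about the arch axis: writing the landmark position relative
#' to the joint origin as an axial part plus a perpendicular part `p`, the
#' landmark height after rotating by `delta` is
#' `A cos(delta) + B sin(delta) + const` with `A = p_y` and
#' `B = (axis x p)_y`, and the drop equation is solved for the smallest
#' non-negative `delta`.
#'
#' @param arch_joint an arch joint definition (a list with `origin`, `axis`,
#'   `neutral_angle` in degrees, `stiffness`, `range`), as stored in
#'   `default_parameter_set()$joints$arch`.
#' @param landmark 3-vector: the landmark position in the parent reference
#'   frame at the current neutral angle.
#' @param drop_mm requested vertical drop of the landmark (mm, >= 0).
#' @return The modified joint definition (neutral angle in degrees).
#' @export
#' @examples
#' arch <- default_parameter_set()$joints$arch
#' lm <- default_parameter_set()$landmarks$first_mtc$point
#' flatten_arch(arch, lm, 8)$neutral_angle
flatten_arch <- function(arch_joint, landmark, drop_mm) {
  if (drop_mm < 0) stop("drop_mm must be >= 0", call. = FALSE)
  if (drop_mm == 0) return(arch_joint)
  a <- arch_joint$axis / sqrt(sum(arch_joint$axis^2))
  p <- as.numeric(landmark) - as.numeric(arch_joint$origin)
  ## the landmark is given in reference coordinates (joint angle 0); move
  ## it to the current neutral pose before solving for the extra rotation
  p <- as.numeric(rot_axis(a, deg2rad(arch_joint$neutral_angle)) %*% p)
  p_par <- sum(p * a) * a
  p_perp <- p - p_par
  A <- p_perp[2]
  B <- (a[3] * p_perp[1] - a[1] * p_perp[3])  # (a x p_perp)_y
  C <- p_perp[2] - drop_mm / 1000
  Rm <- sqrt(A^2 + B^2)
  if (Rm < 1e-12 || abs(C) > Rm)
    stop("requested arch drop of ", drop_mm,
         " mm is geometrically unreachable", call. = FALSE)
  phi <- atan2(B, A)
  cand <- c(phi + acos(C / Rm), phi - acos(C / Rm))
  cand <- c(cand, cand + 2 * pi, cand - 2 * pi)
  cand <- sort(cand[cand >= -1e-12])
  if (length(cand) == 0L)
    stop("no non-negative arch rotation achieves the requested drop",
         call. = FALSE)
  delta <- cand[1]
  new_neutral <- arch_joint$neutral_angle + rad2deg(delta)
  if (new_neutral > arch_joint$range[2] + 1e-9)
    stop("arch drop of ", drop_mm, " mm exceeds the arch joint range",
         call. = FALSE)
  arch_joint$neutral_angle <- new_neutral
  arch_joint
}

#' Passive restoring torque of the arch joint
#'
#' Linear torsional spring (plus optional viscous term) representing the
#' passive elasticity of the medial longitudinal arch:
#' `-stiffness * (angle - neutral) - damping * velocity`.
#'
#' @param angle current arch angle (deg).
#' @param joint a joint definition with `stiffness` (N m/deg), `damping`
#'   (N m s/deg) and `neutral_angle` (deg).
#' @param velocity angular velocity (deg/s); 0 gives the pure spring torque.
#' @return torque (N m).
#' @export
#' @examples
#' arch <- default_parameter_set()$joints$arch
#' arch_restoring_torque(arch$neutral_angle + 1, arch)  # -1 N m
arch_restoring_torque <- function(angle, joint, velocity = 0) {
  if (joint$stiffness < 0) stop("stiffness must be >= 0", call. = FALSE)
  -joint$stiffness * (angle - joint$neutral_angle) - joint$damping * velocity
}
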