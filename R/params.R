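#' Default model and simulation parameter bundle
#'
#' Returns the packaged defaults used by every simulation in the package:
#' segment inertial properties, joint definitions, contact spheres, muscle
#' paths with maximum isometric forces, activation-profile shape parameters,
#' ground-plane trajectory shape parameters, contact-law constants,
#' calibration settings and integrator options.
#'
#' The skeleton is a schematic right foot of an 82 kg adult, expressed in a
#' laboratory frame fixed to the tibia: the origin sits at the ankle joint
#' centre, `x` points anteriorly (towards the toes), `y` points upward and
#' `z` points to the subject's right (lateral side of a right foot; the
#' medial border, first ray and hallux lie at negative `z`).  All angles in
#' the bundle are degrees; lengths are metres; they are converted to radians
#' internally by [build_foot_model()].
#'
#' The bundle is deterministic and immutable within a release: calling the
#' function twice returns identical values.  Individual entries can be
#' overridden by modifying the returned list before passing it to
#' [build_foot_model()] or [default_input_bundle()].
#'
#' @return A named list with components `subject`, `segments`, `joints`,
#'   `landmarks`, `spheres`, `muscles`, `implant`, `contact`, `activation`,
#'   `trajectory`, `calibration` and `sim`.
#' @seealso [build_foot_model()], [default_input_bundle()],
#'   [validate_params()]
#' @export
#' @examples
#' p <- default_parameter_set()
#' p$subject$mass_kg
#' names(p$joints)
default_parameter_set <- function() {
  list(
    subject = list(
      mass_kg = 82,
      gravity = 9.80665
    ),

    ## Segment inertial properties.  Total foot mass ~1.45% body mass,
    ## partitioned over the five movable segments; inertias are diagonal
    ## box-like estimates about each segment's centre of mass, expressed in
    ## the reference (neutral-pose) axes.
    segments = list(
      tibia = list(
        name = "tibia", parent_joint = NA_character_,
        mass = 3.5, com = c(-0.01, 0.20, 0.00),
        inertia = diag(c(0.040, 0.006, 0.040))
      ),
      talus = list(
        name = "talus", parent_joint = "ankle",
        mass = 0.10, com = c(0.010, -0.010, 0.000),
        inertia = diag(c(2e-5, 2e-5, 2e-5))
      ),
      hindfoot_lateral = list(
        name = "hindfoot_lateral", parent_joint = "subtalar",
        mass = 0.80, com = c(0.030, -0.045, 0.012),
        inertia = diag(c(0.0012, 0.0030, 0.0028))
      ),
      medial_foot = list(
        name = "medial_foot", parent_joint = "arch",
        mass = 0.22, com = c(0.095, -0.048, -0.024),
        inertia = diag(c(8e-5, 3.2e-4, 3.0e-4))
      ),
      hallux = list(
        name = "hallux", parent_joint = "mtp_medial",
        mass = 0.05, com = c(0.155, -0.060, -0.030),
        inertia = diag(c(8e-6, 2.0e-5, 1.8e-5))
      ),
      lateral_toes = list(
        name = "lateral_toes", parent_joint = "mtp_lateral",
        mass = 0.10, com = c(0.150, -0.058, 0.030),
        inertia = diag(c(3e-5, 6e-5, 5e-5))
      )
    ),

    ## Joint definitions.  Axes are unit vectors in the parent reference
    ## frame; `neutral_angle` is the rest angle of the passive torsional
    ## spring in the joint coordinate (deg, 0 = reference pose); stiffness
    ## N m/deg, damping N m s/deg, range deg.  The arch joint axis points
    ## posteriorly so that a positive arch angle lowers the medial ray
    ## (relaxes/flattens the medial longitudinal arch); the 1 Nm/deg arch
    ## stiffness stands in for the passive deltoid/spring ligaments.
    joints = list(
      ankle = list(
        name = "ankle", parent = "tibia", child = "talus",
        origin = c(0.000, 0.000, 0.000),
        axis = c(-0.105, -0.174, 0.979),
        neutral_angle = 0, stiffness = 0.40, damping = 0.150,
        range = c(-40, 30)
      ),
      subtalar = list(
        name = "subtalar", parent = "talus", child = "hindfoot_lateral",
        origin = c(-0.010, -0.020, 0.010),
        axis = c(0.793, 0.609, 0.000),
        neutral_angle = 0, stiffness = 0.80, damping = 0.080,
        range = c(-25, 25)
      ),
      arch = list(
        name = "arch", parent = "hindfoot_lateral", child = "medial_foot",
        origin = c(0.050, -0.030, 0.018),
        axis = c(-1, 0, 0),
        neutral_angle = 2, stiffness = 1.00, damping = 0.050,
        range = c(-30, 35)
      ),
      mtp_medial = list(
        name = "mtp_medial", parent = "medial_foot", child = "hallux",
        origin = c(0.130, -0.055, -0.030),
        axis = c(0, 0, 1),
        neutral_angle = 0, stiffness = 0.15, damping = 0.030,
        range = c(-35, 60)
      ),
      mtp_lateral = list(
        name = "mtp_lateral", parent = "hindfoot_lateral", child = "lateral_toes",
        origin = c(0.130, -0.055, 0.028),
        axis = c(0, 0, 1),
        neutral_angle = 0, stiffness = 0.15, damping = 0.030,
        range = c(-35, 60)
      )
    ),

    ## Named skeletal landmarks (segment, position in reference coords).
    ## first_mtc = first metatarsocuneiform point, the landmark whose
    ## vertical drop defines the flatfoot configuration.
    landmarks = list(
      first_mtc = list(segment = "medial_foot", point = c(0.085, -0.042, -0.027)),
      navicular = list(segment = "medial_foot", point = c(0.045, -0.036, -0.010))
    ),

    ## Contact spheres: sizes 6/4/3/3/2 cm are diameters.  Sphere bottoms
    ## are coplanar (y = -0.085) in the reference pose of the arched foot.
    ## stiffness_scale multiplies the shared contact stiffness per sphere
    ## (forefoot and toe pads are softer than the heel pad).
    spheres = list(
      heel = list(name = "heel", segment = "hindfoot_lateral",
                  center = c(-0.055, -0.055, 0.015), diameter = 0.06, stiffness_scale = 1.0),
      met1 = list(name = "met1", segment = "medial_foot",
                  center = c(0.115, -0.065, -0.030), diameter = 0.04, stiffness_scale = 0.45),
      met5 = list(name = "met5", segment = "hindfoot_lateral",
                  center = c(0.115, -0.070, 0.045), diameter = 0.03, stiffness_scale = 0.7),
      hallux = list(name = "hallux", segment = "hallux",
                    center = c(0.165, -0.070, -0.030), diameter = 0.03, stiffness_scale = 0.5),
      toe5 = list(name = "toe5", segment = "lateral_toes",
                  center = c(0.150, -0.075, 0.048), diameter = 0.02, stiffness_scale = 0.5)
    ),

    ## Contact law: compliant normal force k * d^p * (1 + c * ddot), no
    ## adhesion, plus viscous friction F_F = F_N * f_v * v_s.  The no-slip
    ## condition of the gait rig is achieved kinematically (the trajectory
    ## generator rolls the plane so its surface is stationary under the
    ## load centroid); f_v is kept small because with five rigid contact
    ## spheres a large viscous coefficient turns transient slip into
    ## destabilising tangential forces.
    contact = list(
      stiffness = 7e5,      # N / m^exponent
      exponent = 1.5,
      dissipation = 1.5,    # s / m
      f_v = 1               # s / m
    ),

    ## Nine extrinsic muscles: ordered via points (segment, point) from a
    ## fixed tibia attachment to the distal insertion, and maximum isometric
    ## force (N).  Straight-line routing between via points; points are
    ## placed to give anatomically plausible moment arms in the stance range.
    muscles = list(
      tib_post = list(
        name = "tib_post", fmax = 1500,
        via = list(list("tibia", c(-0.020, 0.120, -0.010)),
                   list("tibia", c(-0.008, -0.008, -0.012)),
                   list("medial_foot", c(0.045, -0.036, -0.010)))
      ),
      fdl = list(
        name = "fdl", fmax = 500,
        via = list(list("tibia", c(-0.015, 0.100, -0.015)),
                   list("tibia", c(-0.010, -0.012, 0.002)),
                   list("hindfoot_lateral", c(0.030, -0.028, 0.018)),
                   list("lateral_toes", c(0.150, -0.065, 0.030)))
      ),
      tib_ant = list(
        name = "tib_ant", fmax = 905,
        via = list(list("tibia", c(0.020, 0.120, -0.010)),
                   list("tibia", c(0.032, 0.005, -0.012)),
                   list("medial_foot", c(0.072, -0.033, -0.006)))
      ),
      edl = list(
        name = "edl", fmax = 512,
        via = list(list("tibia", c(0.025, 0.120, 0.010)),
                   list("tibia", c(0.035, 0.000, 0.008)),
                   list("lateral_toes", c(0.140, -0.047, 0.030)))
      ),
      ehl = list(
        name = "ehl", fmax = 162,
        via = list(list("tibia", c(0.020, 0.120, -0.005)),
                   list("tibia", c(0.033, 0.000, -0.015)),
                   list("hallux", c(0.152, -0.049, -0.030)))
      ),
      fhl = list(
        name = "fhl", fmax = 650,
        via = list(list("tibia", c(-0.020, 0.100, 0.000)),
                   list("tibia", c(-0.025, -0.015, -0.002)),
                   list("medial_foot", c(0.080, -0.060, -0.020)),
                   list("hallux", c(0.160, -0.068, -0.030)))
      ),
      per_long = list(
        name = "per_long", fmax = 943,
        via = list(list("tibia", c(-0.005, 0.100, 0.020)),
                   list("tibia", c(-0.022, -0.015, 0.036)),
                   list("hindfoot_lateral", c(0.058, -0.034, 0.020)),
                   list("medial_foot", c(0.085, -0.034, -0.010)))
      ),
      per_brev = list(
        name = "per_brev", fmax = 435,
        via = list(list("tibia", c(-0.005, 0.100, 0.022)),
                   list("tibia", c(-0.020, -0.016, 0.038)),
                   list("hindfoot_lateral", c(0.070, -0.048, 0.044)))
      ),
      soleus = list(
        name = "soleus", fmax = 3500,
        via = list(list("tibia", c(-0.030, 0.150, 0.005)),
                   list("hindfoot_lateral", c(-0.060, -0.035, 0.005)))
      )
    ),

    ## Ideal pulley implant (implant-modified tendon transfer only):
    ## force amplification n, anchor and implant points in the tibia frame.
    ## The implant point lies on the original distal course of the
    ## posterior tibialis so the artificial tendon reproduces the original
    ## line of action at the navicular insertion with n-fold tension.
    implant = list(
      amplification = 2,
      anchor_point = c(-0.020, 0.060, -0.020),
      implant_point = c(-0.008, -0.008, -0.012)
    ),

    ## Activation profile design: the ankle-torque demand implied by the
    ## target loading profile and centre-of-pressure progression is
    ## distributed over the dorsiflexor group (early stance, plane contact
    ## behind the ankle) and the plantarflexor group (late stance) in
    ## proportion to `weight` times a Gaussian timing envelope
    ## exp(-((s - t0)/w)^2), then converted to activation through each
    ## muscle's maximum isometric force and ankle moment arm.  This mirrors
    ## electromyography-derived muscle forces of healthy gait: dorsiflexors
    ## peak in early stance, plantarflexors in late stance, and activations
    ## start and end low.  `jitter` (relative sd) optionally perturbs the
    ## weights reproducibly from the bundle seed; the shipped default is 0
    ## so the study conditions are deterministic.
    activation = list(
      shapes = list(
        tib_ant  = list(weight = 0.70, t0 = 0.12, w = 0.14),
        edl      = list(weight = 0.20, t0 = 0.12, w = 0.15),
        ehl      = list(weight = 0.10, t0 = 0.12, w = 0.15),
        soleus   = list(weight = 0.60, t0 = 0.72, w = 0.30),
        fhl      = list(weight = 0.09, t0 = 0.75, w = 0.30),
        fdl      = list(weight = 0.0165, t0 = 0.72, w = 0.30),
        tib_post = list(weight = 0.046, t0 = 0.68, w = 0.32),
        per_long = list(weight = 0.050, t0 = 0.68, w = 0.30),
        per_brev = list(weight = 0.032, t0 = 0.65, w = 0.30)
      ),
      ## early-stance peroneal co-activation: the everters fire during the
      ## loading response to stabilise the subtalar joint against the
      ## inversion moment of the dorsiflexors (additive Gaussian bump)
      coactivation = list(
        per_long = list(amp = 0.30, t0 = 0.10, w = 0.13),
        per_brev = list(amp = 0.25, t0 = 0.10, w = 0.13)
      ),
      jitter = 0
    ),

    ## Ground-plane trajectory shape: stance duration, pitch schedule
    ## (deg, + = heel-down slope at heel strike, - = toe-down at toe off),
    ## centre-of-pressure progression (m, anterior), target vertical ground
    ## reaction force profile (body weights) used by the quasi-static
    ## inversion, and small roll/yaw/z amplitudes.  The vGRF target encodes
    ## the double-peak loading of healthy gait that the plane motion was
    ## fitted to reproduce.
    trajectory = list(
      stance_duration = 4.09,
      grid_n = 61,
      pitch_knots = list(s = c(0, 0.08, 0.20, 0.35, 0.50, 0.62, 0.75, 0.88, 1.00),
                         deg = c(17, 6, 0.5, -1, -4, -9, -16, -28, -44)),
      cop_knots = list(s = c(0, 0.10, 0.25, 0.45, 0.65, 0.85, 1.00),
                       x = c(-0.055, -0.045, -0.015, 0.045, 0.105, 0.150, 0.175)),
      vgrf_knots = list(s = c(0, 0.05, 0.12, 0.20, 0.297, 0.38, 0.50, 0.62,
                              0.73, 0.82, 0.90, 0.96, 1.00),
                        bw = c(0, 0.30, 0.75, 1.05, 1.14, 1.04, 0.900, 0.96,
                               1.07, 0.93, 0.55, 0.18, 0)),
      n_refine = 9,
      roll_amp_deg = -5.3,
      yaw_amp_deg = 1.5,
      z_amp_m = 0.004
    ),

    calibration = list(
      target_mass_kg = 82,
      target_peak_bw = 1.105,   # mean of the two vGRF peak magnitudes
      tol_bw = 0.02,
      max_iter = 30
    ),

    sim = list(
      rtol = 1e-6,
      atol = 1e-8,
      n_out = 1025,
      seed = 1L
    )
  )
}

#' Validate a parameter bundle
#'
#' Checks structural invariants of a parameter bundle: presence of all
#' sections, positive masses, symmetric positive semidefinite inertias,
#' unit joint axes, non-negative stiffness/damping, five contact spheres
#' with positive diameters, nine muscles each with at least two via points
#' and positive maximum isometric force, and activation shape values in
#' [0, 1].
#'
#' @param params a parameter bundle as returned by [default_parameter_set()].
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_params <- function(params) {
  need <- c("subject", "segments", "joints", "landmarks", "spheres",
            "muscles", "implant", "contact", "activation", "trajectory",
            "calibration", "sim")
  miss <- setdiff(need, names(params))
  if (length(miss) > 0L)
    stop("parameter bundle is missing section(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  for (seg in params$segments) {
    if (!is.finite(seg$mass) || seg$mass <= 0)
      stop("segment '", seg$name, "': mass must be > 0", call. = FALSE)
    I <- seg$inertia
    if (!isTRUE(all.equal(I, t(I))))
      stop("segment '", seg$name, "': inertia must be symmetric", call. = FALSE)
    if (any(eigen(I, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
      stop("segment '", seg$name, "': inertia must be positive semidefinite",
           call. = FALSE)
  }

  jn <- c("ankle", "subtalar", "arch", "mtp_medial", "mtp_lateral")
  if (!identical(sort(names(params$joints)), sort(jn)))
    stop("joints must be exactly: ", paste(jn, collapse = ", "), call. = FALSE)
  for (j in params$joints) {
    if (abs(sqrt(sum(j$axis^2)) - 1) > 1e-6 && sqrt(sum(j$axis^2)) == 0)
      stop("joint '", j$name, "': axis must be non-zero", call. = FALSE)
    if (j$stiffness < 0) stop("joint '", j$name, "': stiffness must be >= 0",
                              call. = FALSE)
    if (j$damping < 0) stop("joint '", j$name, "': damping must be >= 0",
                            call. = FALSE)
    if (j$range[1] > j$neutral_angle || j$neutral_angle > j$range[2])
      stop("joint '", j$name, "': neutral_angle must lie within range",
           call. = FALSE)
  }

  if (length(params$spheres) != 5L)
    stop("exactly 5 contact spheres are required, got ",
         length(params$spheres), call. = FALSE)
  for (sp in params$spheres)
    if (!is.finite(sp$diameter) || sp$diameter <= 0)
      stop("sphere '", sp$name, "': diameter must be > 0", call. = FALSE)
  if (params$contact$stiffness <= 0)
    stop("contact$stiffness must be > 0", call. = FALSE)

  if (length(params$muscles) != 9L)
    stop("exactly 9 muscles are required, got ", length(params$muscles),
         call. = FALSE)
  segnames <- vapply(params$segments, `[[`, "", "name")
  for (m in params$muscles) {
    if (length(m$via) < 2L)
      stop("muscle '", m$name, "': needs at least 2 via points", call. = FALSE)
    if (!is.finite(m$fmax) || m$fmax <= 0)
      stop("muscle '", m$name, "': fmax must be > 0", call. = FALSE)
    if (m$via[[1]][[1]] != "tibia")
      stop("muscle '", m$name, "': first via point must be on the tibia",
           call. = FALSE)
    for (v in m$via)
      if (!v[[1]] %in% segnames)
        stop("muscle '", m$name, "': unknown segment '", v[[1]], "'",
             call. = FALSE)
  }

  if (params$implant$amplification < 1)
    stop("implant$amplification must be >= 1", call. = FALSE)

  for (nm in names(params$activation$shapes)) {
    sh <- params$activation$shapes[[nm]]
    if (sh$weight < 0 || sh$weight > 1)
      stop("activation shape '", nm, "': weight must be in [0, 1]",
           call. = FALSE)
    if (sh$w <= 0)
      stop("activation shape '", nm, "': envelope width must be > 0",
           call. = FALSE)
  }
  if (params$trajectory$stance_duration <= 0)
    stop("trajectory$stance_duration must be > 0", call. = FALSE)
  if (params$subject$mass_kg <= 0)
    stop("subject$mass_kg must be > 0", call. = FALSE)
  if (params$sim$rtol <= 0 || params$sim$atol <= 0)
    stop("integrator tolerances must be > 0", call. = FALSE)

  invisible(params)
}

## degrees <-> radians helpers used throughout
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
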