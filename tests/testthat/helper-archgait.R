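## Session-wide cache of the expensive objects (input bundle, calibration,
## full scenario traces) shared across test files.
ag <- new.env(parent = emptyenv())

ag_bundle <- function() {
  if (is.null(ag$bundle))
    ag$bundle <- suppressWarnings(default_input_bundle())
  ag$bundle
}

ag_calibration <- function() {
  if (is.null(ag$cal)) {
    b <- ag_bundle()
    ag$cal <- calibrate_heel_offset(build_foot_model("ARCHED"),
                                    b$trajectory, b$profiles)
  }
  ag$cal
}

## calibrated full-resolution trace for one scenario
ag_trace <- function(kind) {
  key <- paste0("trace_", kind)
  if (is.null(ag[[key]])) {
    b <- ag_bundle()
    traj <- shift_trajectory(b$trajectory, ag_calibration()$heel_offset)
    ag[[key]] <- simulate_stance(build_foot_model(kind, b$params), traj,
                                 b$profiles)
  }
  ag[[key]]
}

ag_traces <- function() {
  sapply(c("ARCHED", "FLATFOOT", "FLATFOOT_TT", "FLATFOOT_TT_IMPLANT"),
         ag_trace, simplify = FALSE)
}

## moment arm of a muscle about one joint by central difference of the
## path length (independent of the force-application code)
fd_moment_arm <- function(model, muscle, joint, q = numeric(5), h = 1e-6) {
  qp <- q; qp[joint] <- q[joint] + h
  qm <- q; qm[joint] <- q[joint] - h
  -(path_geometry(model, muscle, qp)$length -
      path_geometry(model, muscle, qm)$length) / (2 * h)
}
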