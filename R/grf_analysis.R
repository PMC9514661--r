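#' Total vertical ground reaction force
#'
#' Sums the vertical (world `y`) components of the five contact sphere
#' forces and normalises by body weight.
#'
#' @param trace a [simulate_stance()] trace.
#' @param body_weight body weight (N); defaults to the trace's subject.
#' @return data frame with `pct` (percent stance) and `bw` (vGRF in body
#'   weights).
#' @export
total_vgrf <- function(trace, body_weight = trace$body_weight) {
  if (body_weight <= 0) stop("body_weight must be > 0", call. = FALSE)
  fy <- apply(trace$sphere_f[2, , , drop = FALSE], 3, sum)
  data.frame(pct = trace$pct, bw = fy / body_weight)
}

## vertical force series (BW) of a named subset of spheres
sphere_vgrf <- function(trace, names, body_weight = trace$body_weight) {
  idx <- match(names, trace$sphere_names)
  if (any(is.na(idx))) stop("unknown sphere name", call. = FALSE)
  fy <- apply(trace$sphere_f[2, idx, , drop = FALSE], 3, sum)
  data.frame(pct = trace$pct, bw = fy / body_weight)
}

#' Locate the double-peak profile of a vGRF series
#'
#' Finds the loading-response peak (global maximum over (5%, 50%] stance),
#' the push-off peak (global maximum over (50%, 95%)) and the mid-stance
#' valley (global minimum between the two peaks), at the resolution of the
#' series' sample grid.  A series without two interior maxima (e.g. a
#' monotone ramp) is flagged `degenerate` rather than raising an error.
#'
#' @param series data frame with `pct` (0-100) and `bw` columns, at least
#'   100 samples.
#' @return list with `peak1`, `valley`, `peak2` (each `c(bw, pct)`) and
#'   `degenerate`.
#' @export
find_double_peak <- function(series) {
  if (nrow(series) < 100L)
    stop("need at least 100 samples over the stance phase", call. = FALSE)
  pct <- series$pct; bw <- series$bw
  w1 <- which(pct > 5 & pct <= 50)
  w2 <- which(pct > 50 & pct < 95)
  i1 <- w1[which.max(bw[w1])]
  i2 <- w2[which.max(bw[w2])]
  wv <- seq(i1, i2)
  iv <- wv[which.min(bw[wv])]
  degenerate <- FALSE
  ## interior-peak check: a peak at the window edge with the series still
  ## rising/falling through it indicates a monotone series
  if (i1 == max(w1) && i2 == max(w2)) degenerate <- TRUE
  if (i1 == min(w1) && i2 == min(w2)) degenerate <- TRUE
  if (bw[iv] >= bw[i1] || bw[iv] >= bw[i2]) degenerate <- TRUE
  list(peak1 = c(bw = bw[i1], pct = pct[i1]),
       valley = c(bw = bw[iv], pct = pct[iv]),
       peak2 = c(bw = bw[i2], pct = pct[i2]),
       degenerate = degenerate)
}

#' Medial/lateral split of peak forefoot vertical forces
#'
#' The medial series is the summed vertical force of the first-metatarsal
#' and hallux spheres; the lateral series that of the fifth-metatarsal and
#' fifth-toe spheres (the heel is excluded).  The split is computed from
#' the peak of each series over the whole stance:
#' `medial_pct = 100 * medial_peak / (medial_peak + lateral_peak)`.
#'
#' @param trace a [simulate_stance()] trace.
#' @param body_weight body weight (N).
#' @return list with `medial_peak`, `lateral_peak` (BW), `medial_pct`,
#'   `lateral_pct`, and the two series (`medial`, `lateral`).
#' @export
medial_lateral_peak_split <- function(trace,
                                      body_weight = trace$body_weight) {
  med <- sphere_vgrf(trace, c("met1", "hallux"), body_weight)
  lat <- sphere_vgrf(trace, c("met5", "toe5"), body_weight)
  mp <- max(med$bw); lp <- max(lat$bw)
  if (mp + lp <= 0)
    stop("undefined medial/lateral split: both forefoot peak forces are zero",
         call. = FALSE)
  list(medial_peak = mp, lateral_peak = lp,
       medial_pct = 100 * mp / (mp + lp),
       lateral_pct = 100 * lp / (mp + lp),
       medial = med, lateral = lat)
}

#' Lateral shift of the medial/lateral split
#'
#' A treatment's lateral shift is the decrease in the peak medial
#' percentage relative to the untreated condition (positive values mean
#' forces moved laterally).
#'
#' @param untreated_medial_pct,treated_medial_pct peak medial percentages
#'   (0-100).
#' @return shift in percentage points.
#' @export
#' @examples
#' lateral_shift(48.3, 44.4)  # 3.9
lateral_shift <- function(untreated_medial_pct, treated_medial_pct) {
  if (any(c(untreated_medial_pct, treated_medial_pct) < 0) ||
      any(c(untreated_medial_pct, treated_medial_pct) > 100))
    stop("medial percentages must be in [0, 100]", call. = FALSE)
  untreated_medial_pct - treated_medial_pct
}

#' Restoration percentage of a treatment
#'
#' The lateral shift achieved by a treatment divided by the total medial
#' shift between the arched reference and the untreated flatfoot:
#' `100 * (untreated - treated) / (untreated - arched)`.  A treatment that
#' does nothing scores 0; one that restores the arched distribution
#' exactly scores 100.
#'
#' Note that the worked-example inputs in the literature quote the
#' untreated flatfoot split both as 49.3% and as 48.3% in different
#' passages; the shift/restoration arithmetic (3.9 and 8.1 point shifts
#' over an 8.6-point gap giving 45.3% and 94.2%) follows from the 48.3%
#' value, which is therefore the reference used in the package's worked
#' examples.  The discrepancy is reproduced as printed, not reconciled.
#'
#' @param arched_medial_pct,untreated_medial_pct,treated_medial_pct peak
#'   medial percentages (0-100).
#' @return restoration percentage.
#' @export
#' @examples
#' restoration_pct(39.7, 48.3, 40.2)  # ~94.2
restoration_pct <- function(arched_medial_pct, untreated_medial_pct,
                            treated_medial_pct) {
  if (untreated_medial_pct <= arched_medial_pct)
    stop("no medial shift to restore: untreated medial percentage must ",
         "exceed the arched reference", call. = FALSE)
  100 * (untreated_medial_pct - treated_medial_pct) /
    (untreated_medial_pct - arched_medial_pct)
}

#' Summarise a stance trace
#'
#' Combines the double-peak features of the total vGRF with the
#' medial/lateral peak split into a single summary.
#'
#' @param trace a [simulate_stance()] trace.
#' @param body_weight body weight (N).
#' @return object of class `grf_summary`.
#' @export
grf_summary <- function(trace, body_weight = trace$body_weight) {
  v <- total_vgrf(trace, body_weight)
  pk <- find_double_peak(v)
  sp <- medial_lateral_peak_split(trace, body_weight)
  structure(list(scenario = trace$scenario,
                 peak1 = pk$peak1, valley = pk$valley, peak2 = pk$peak2,
                 degenerate = pk$degenerate,
                 medial_peak = sp$medial_peak, lateral_peak = sp$lateral_peak,
                 medial_pct = sp$medial_pct, lateral_pct = sp$lateral_pct),
            class = "grf_summary")
}

#' @export
print.grf_summary <- function(x, ...) {
  cat("<grf_summary>", x$scenario, "\n")
  cat(sprintf("  peak1 %.3f BW @ %.1f%%  valley %.3f BW @ %.1f%%  peak2 %.3f BW @ %.1f%%\n",
              x$peak1["bw"], x$peak1["pct"], x$valley["bw"], x$valley["pct"],
              x$peak2["bw"], x$peak2["pct"]))
  cat(sprintf("  medial/lateral peak split: %.1f%% / %.1f%% (%.3f / %.3f BW)\n",
              x$medial_pct, x$lateral_pct, x$medial_peak, x$lateral_peak))
  invisible(x)
}

#' Compare the four treatment scenarios
#'
#' Builds the treatment-comparison report from four stance traces sharing
#' one calibration: per-scenario vGRF summaries, the lateral shifts of the
#' two treatments relative to the untreated flatfoot, their restoration
#' percentages relative to the arched reference, and the improvement ratio
#' of the implant-modified over the traditional tendon transfer.
#'
#' @param traces named list of [simulate_stance()] traces with entries
#'   `ARCHED`, `FLATFOOT`, `FLATFOOT_TT`, `FLATFOOT_TT_IMPLANT`.
#' @param body_weight body weight (N).
#' @return object of class `comparison_report`: list with `summaries`,
#'   `shifts`, `restorations` (percent, one decimal as reported),
#'   `improvement_ratio` (2 significant figures) and the unrounded values.
#' @export
compare_scenarios <- function(traces, body_weight = NULL) {
  need <- scenario_kinds()
  miss <- setdiff(need, names(traces))
  if (length(miss) > 0L)
    stop("missing scenario trace(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(body_weight)) body_weight <- traces$ARCHED$body_weight
  summaries <- lapply(traces[need], grf_summary, body_weight = body_weight)
  m <- vapply(summaries, `[[`, 0, "medial_pct")
  shifts <- c(
    FLATFOOT_TT = lateral_shift(m["FLATFOOT"], m["FLATFOOT_TT"]),
    FLATFOOT_TT_IMPLANT = lateral_shift(m["FLATFOOT"], m["FLATFOOT_TT_IMPLANT"])
  )
  names(shifts) <- c("FLATFOOT_TT", "FLATFOOT_TT_IMPLANT")
  rest <- c(
    FLATFOOT_TT = restoration_pct(m["ARCHED"], m["FLATFOOT"], m["FLATFOOT_TT"]),
    FLATFOOT_TT_IMPLANT = restoration_pct(m["ARCHED"], m["FLATFOOT"],
                                          m["FLATFOOT_TT_IMPLANT"])
  )
  names(rest) <- c("FLATFOOT_TT", "FLATFOOT_TT_IMPLANT")
  ratio <- unname(shifts["FLATFOOT_TT_IMPLANT"] / shifts["FLATFOOT_TT"])
  structure(list(
    summaries = summaries,
    medial_pct = m,
    shifts = shifts,
    restorations = round(rest, 1),
    restorations_raw = rest,
    improvement_ratio = signif(ratio, 2),
    improvement_ratio_raw = ratio
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat("  peak medial split (%):",
      paste(sprintf("%s %.1f", names(x$medial_pct), x$medial_pct),
            collapse = ", "), "\n")
  cat(sprintf("  lateral shift: tendon transfer %.1f pp, implant %.1f pp\n",
              x$shifts["FLATFOOT_TT"], x$shifts["FLATFOOT_TT_IMPLANT"]))
  cat(sprintf("  restoration:   tendon transfer %.1f%%, implant %.1f%%\n",
              x$restorations["FLATFOOT_TT"],
              x$restorations["FLATFOOT_TT_IMPLANT"]))
  cat(sprintf("  improvement ratio: %.2gX\n", x$improvement_ratio))
  invisible(x)
}
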