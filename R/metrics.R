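#' Extract the ventricular pressure-volume loop from a converged beat
#'
#' @param solution a `beat_solution`.
#' @param chamber name of the chamber to extract (default the systemic
#'   ventricle).
#' @return An object of class `pv_loop`: sampled `volume` and `pressure`
#'   over one beat, `edv`, `esv` (mL), the end-systolic point (`es_volume`,
#'   `es_pressure`, the loop point maximizing P/(V - V0)), and the
#'   chamber's unstressed volume `v0`.
#' @export
extract_pv_loop <- function(solution, chamber = "ventricle") {
  if (!chamber %in% colnames(solution$states))
    stop("no chamber '", chamber, "' in solution", call. = FALSE)
  V <- solution$states[, chamber]
  P <- solution$pressures[, chamber]
  v0 <- solution$topology$chambers[[chamber]]$v0
  edv <- max(V)
  esv <- min(V)
  if (edv - esv < 1e-3 * max(edv, 1))
    stop("degenerate pressure-volume loop: chamber volume excursion ",
         signif(edv - esv, 3), " mL (non-beating solution?)", call. = FALSE)
  ratio <- P / pmax(V - v0, 1e-6)
  ies <- which.max(ratio)
  structure(list(volume = V, pressure = P, time = solution$time,
                 edv = edv, esv = esv,
                 es_volume = V[ies], es_pressure = P[ies], v0 = v0),
            class = "pv_loop")
}

#' Cardiac function indices from a pressure-volume loop
#'
#' Computes ejection fraction `EF = (EDV - ESV)/EDV`, arterial elastance
#' `Ea = Pes/SV`, end-systolic elastance `Ees` (the chamber's configured
#' peak elastance), ventriculoarterial coupling `Ees/Ea`, stroke work
#' `SW` (signed loop area by the shoelace formula), pressure-volume area
#' `PVA = SW + PE` with the potential energy `PE` taken as the triangle
#' between the linear end-systolic pressure-volume relation through
#' (V0, 0), the end-systolic point and the volume axis, and the
#' mechanical efficiency `SW/PVA`.
#'
#' @param loop a [extract_pv_loop()] result.
#' @param chamber the [chamber_parameters()] of the chamber the loop
#'   belongs to (supplies `Ees`).
#' @return An object of class `cardiac_function_indices` with fields
#'   `ef` (percent), `ea`, `ees` (mmHg/mL), `ees_over_ea`, `sw`, `pe`,
#'   `pva` (mmHg·mL), `sw_over_pva`, `edv`, `esv`, `sv` (mL),
#'   `es_pressure` (mmHg).
#' @examples
#' # rectangular loop, V: 50..120 mL, P: 8..90 mmHg
#' lp <- structure(list(volume = c(120, 50, 50, 120, 120),
#'                      pressure = c(8, 8, 90, 90, 8),
#'                      edv = 120, esv = 50, es_volume = 50,
#'                      es_pressure = 90, v0 = 10), class = "pv_loop")
#' ch <- chamber_parameters(e_max = 2.25, e_min = 0.1, v0 = 10)
#' compute_indices(lp, ch)$ef  # 58.33
#' @export
compute_indices <- function(loop, chamber) {
  sv <- loop$edv - loop$esv
  if (sv <= 0)
    stop("degenerate pressure-volume loop: zero stroke volume",
         call. = FALSE)
  ef <- 100 * sv / loop$edv
  ea <- loop$es_pressure / sv
  ees <- chamber$e_max

  v <- loop$volume
  p <- loop$pressure
  if (v[1] != v[length(v)] || p[1] != p[length(p)]) {
    v <- c(v, v[1])
    p <- c(p, p[1])
  }
  n <- length(v)
  sw <- abs(sum(v[-n] * p[-1] - v[-1] * p[-n])) / 2

  pe <- max(0, loop$es_pressure * (loop$es_volume - loop$v0) / 2)
  pva <- sw + pe
  structure(list(ef = ef, ea = ea, ees = ees, ees_over_ea = ees / ea,
                 sw = sw, pe = pe, pva = pva, sw_over_pva = sw / pva,
                 edv = loop$edv, esv = loop$esv, sv = sv,
                 es_pressure = loop$es_pressure),
            class = "cardiac_function_indices")
}

#' @export
print.cardiac_function_indices <- function(x, ...) {
  cat(sprintf(
    "<cardiac_function_indices> EF %.1f%%, Ees/Ea %.3g, SW/PVA %.3g\n",
    x$ef, x$ees_over_ea, x$sw_over_pva))
  cat(sprintf("  EDV %.1f, ESV %.1f mL; Ea %.3g, Ees %.3g mmHg/mL; SW %.3g mmHg.mL\n",
              x$edv, x$esv, x$ea, x$ees, x$sw))
  invisible(x)
}

#' Estimate end-systolic elastance from two afterload runs
#'
#' Runs a circulation at two systemic-resistance scalings, extracts the
#' end-systolic points of the two loops and returns the slope of the
#' line through them.  For an ideal elastance chamber with a linear
#' end-systolic pressure-volume relation through V0 this recovers the
#' chamber's configured `e_max`; it exists as an independent check of
#' the loop analysis, not as the reported `Ees`.
#'
#' @param topology a `fontan_topology`.
#' @param patient a [patient_parameters()] object.
#' @param svr_ratios two systemic-resistance scalings.
#' @param control integrator control, see [limit_cycle_control()].
#' @return Estimated end-systolic elastance (mmHg/mL).
#' @export
estimate_ees_two_load <- function(topology, patient = patient_parameters(),
                                  svr_ratios = c(0.85, 1.15),
                                  control = limit_cycle_control()) {
  pts <- lapply(svr_ratios, function(r) {
    topo <- topology
    sys <- topo$edges$class == "systemic"
    topo$edges$R[sys] <- topo$edges$R[sys] * r
    sol <- run_to_limit_cycle(topo, patient, control = control)
    lp <- extract_pv_loop(sol)
    c(v = lp$es_volume, p = lp$es_pressure)
  })
  (pts[[2]]["p"] - pts[[1]]["p"]) / (pts[[2]]["v"] - pts[[1]]["v"])
}

#' Export a pressure-volume loop as CSV
#'
#' @param loop a `pv_loop`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
export_pv_loop_csv <- function(loop, path) {
  write.csv(data.frame(time = loop$time, volume = loop$volume,
                       pressure = loop$pressure),
            path, row.names = FALSE)
  invisible(path)
}
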