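#' Dobutamine dose-response table
#'
#' Returns the dose grid and multiplier table applied by
#' [apply_dobutamine()]: multiplicative factors for end-systolic
#' ventricular elastance, systemic vascular resistance, heart rate and
#' oxygen consumption index, anchored at 0, 5 and 10 ug/kg/min with
#' linear interpolation between anchors.  All multipliers are 1 at dose
#' 0; the elastance multiplier is non-decreasing and the resistance
#' multiplier non-increasing in dose.
#'
#' @param registry a `fontan_registry`.
#' @return A data frame with columns `dose`, `e_max`, `svr`,
#'   `heart_rate`, `vo2i`.
#' @export
dobutamine_response <- function(registry = default_registry()) {
  tab <- registry$dobutamine
  stopifnot(all(c("dose", "e_max", "svr", "heart_rate", "vo2i") %in%
                  names(tab)))
  tab
}

dobutamine_multipliers <- function(registry, dose) {
  tab <- dobutamine_response(registry)
  if (dose < 0)
    stop("apply_dobutamine: dose must be >= 0", call. = FALSE)
  if (dose > max(tab$dose))
    stop(sprintf(
      "apply_dobutamine: dose %g exceeds the dose grid maximum (%g ug/kg/min)",
      dose, max(tab$dose)), call. = FALSE)
  vapply(c("e_max", "svr", "heart_rate", "vo2i"), function(col)
    approx(tab$dose, tab[[col]], xout = dose)$y, numeric(1))
}

#' Apply the dobutamine dose-response to a parameter set
#'
#' Scales the ventricular end-systolic elastance, every systemic-bed
#' resistance, the heart rate and the resting oxygen consumption index
#' by the interpolated multipliers of the shipped dose-response table.
#' All other parameters are unchanged, and the input is not modified.
#'
#' @param params a parameter set: a list with elements `patient`
#'   ([patient_parameters()]) and `registry` ([default_registry()]).
#' @param dose dobutamine infusion rate (ug/kg/min), within the dose
#'   grid.
#' @return The modified parameter set.
#' @examples
#' p <- list(patient = patient_parameters(), registry = default_registry())
#' p10 <- apply_dobutamine(p, 10)
#' p10$registry$chambers$ventricle$e_max / p$registry$chambers$ventricle$e_max
#' @export
apply_dobutamine <- function(params, dose) {
  m <- dobutamine_multipliers(params$registry, dose)
  reg <- params$registry
  sys <- reg$edges$class == "systemic"
  reg$edges$R[sys] <- reg$edges$R[sys] * m[["svr"]]
  vent <- reg$chambers$ventricle
  vent$e_max <- vent$e_max * m[["e_max"]]
  reg$chambers$ventricle <- do.call(
    chamber_parameters,
    vent[setdiff(names(unclass(vent)), "act_norm")])
  pat <- params$patient
  pat$heart_rate <- pat$heart_rate * m[["heart_rate"]]
  pat$vo2i_rest <- pat$vo2i_rest * m[["vo2i"]]
  validate_patient_parameters(pat)
  params$registry <- reg
  params$patient <- pat
  params$dobutamine_multipliers <- m
  params
}

#' Scale systemic and pulmonary resistances
#'
#' Multiplies every systemic-bed resistance by `svr_ratio` and every
#' pulmonary (lung) resistance by `pvr_ratio`; compliances, inertances
#' and all other parameters are untouched.  Because both this operation
#' and [apply_dobutamine()] act multiplicatively on the resistances,
#' they commute.
#'
#' @param params a parameter set (list with `patient` and `registry`).
#' @param svr_ratio,pvr_ratio positive magnification ratios.
#' @return The modified parameter set.
#' @examples
#' p <- list(patient = patient_parameters(), registry = default_registry())
#' pulmonary_resistance(scale_resistances(p, 1, 1.6)$registry)  # 0.08
#' @export
scale_resistances <- function(params, svr_ratio, pvr_ratio) {
  if (!is.numeric(svr_ratio) || svr_ratio <= 0 ||
      !is.numeric(pvr_ratio) || pvr_ratio <= 0)
    stop("scale_resistances: ratios must be > 0", call. = FALSE)
  reg <- params$registry
  sys <- reg$edges$class == "systemic"
  pul <- reg$edges$class == "pulmonary"
  reg$edges$R[sys] <- reg$edges$R[sys] * svr_ratio
  reg$edges$R[pul] <- reg$edges$R[pul] * pvr_ratio
  params$registry <- reg
  params
}
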