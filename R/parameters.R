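#' Patient-level parameters
#'
#' Constructs the set of patient-level constants used throughout a
#' simulation.  Defaults describe the idealized single-ventricle Fontan
#' patient used for all shipped scenarios: body surface area 1.63 m2,
#' hemoglobin 15 g/dL, and a typical resting oxygen consumption index of
#' 125 mL/min/m2 at a heart rate of 80 beats/min.
#'
#' @param bsa body surface area (m2); must be positive.
#' @param hb hemoglobin concentration (g/dL); must be positive.
#' @param heart_rate heart rate (beats/min); must lie in \[30, 220\].
#' @param vo2i_rest resting oxygen consumption index (mL/min/m2).
#' @return An object of class `patient_parameters` (a named list).
#' @examples
#' patient_parameters()
#' patient_parameters(bsa = 1.2, heart_rate = 100)
#' @export
patient_parameters <- function(bsa = 1.63, hb = 15, heart_rate = 80,
                               vo2i_rest = 125) {
  p <- list(bsa = bsa, hb = hb, heart_rate = heart_rate,
            vo2i_rest = vo2i_rest)
  validate_patient_parameters(p)
  structure(p, class = "patient_parameters")
}

validate_patient_parameters <- function(p) {
  if (!is.numeric(p$bsa) || length(p$bsa) != 1L || !is.finite(p$bsa) || p$bsa <= 0)
    stop("invalid patient parameter 'bsa': must be a positive number", call. = FALSE)
  if (!is.numeric(p$hb) || length(p$hb) != 1L || !is.finite(p$hb) || p$hb <= 0)
    stop("invalid patient parameter 'hb': must be a positive number", call. = FALSE)
  if (!is.numeric(p$heart_rate) || length(p$heart_rate) != 1L ||
      !is.finite(p$heart_rate) || p$heart_rate < 30 || p$heart_rate > 220)
    stop("invalid patient parameter 'heart_rate': must lie in [30, 220] beats/min",
         call. = FALSE)
  if (!is.numeric(p$vo2i_rest) || length(p$vo2i_rest) != 1L ||
      !is.finite(p$vo2i_rest) || p$vo2i_rest <= 0)
    stop("invalid patient parameter 'vo2i_rest': must be a positive number",
         call. = FALSE)
  invisible(p)
}

#' Scenario configuration
#'
#' A scenario selects which collateral shunts are present, the dobutamine
#' infusion rate, and multiplicative scalings ("magnification ratios") of
#' the systemic and pulmonary vascular resistances around their reference
#' values of 0.9 and 0.05 mmHg·s/mL.  Ratios are restricted to the studied
#' range \[0.6, 1.6\] unless `allow_extended_ratios = TRUE`.
#'
#' @param svr_ratio,pvr_ratio dimensionless scalings of the systemic and
#'   pulmonary vascular resistance.
#' @param dobutamine_dose dobutamine infusion rate (ug/kg/min), >= 0.
#' @param vvc_enabled,apc_enabled,fenestration_enabled logical flags
#'   switching the venovenous collateral, aortopulmonary collateral and
#'   conduit fenestration on or off.  The fenestration is open by default
#'   in every scenario.
#' @param initial_sao2,initial_svo2 starting values (percent) for the
#'   oxygen-saturation fixed-point iteration.
#' @param svr_baseline,pvr_baseline reference resistances (mmHg·s/mL) that
#'   the ratios multiply.
#' @param allow_extended_ratios permit ratios outside \[0.6, 1.6\].
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config(vvc_enabled = TRUE, apc_enabled = TRUE)
#' scenario_config(pvr_ratio = 1.4, dobutamine_dose = 10)
#' @export
scenario_config <- function(svr_ratio = 1, pvr_ratio = 1,
                            dobutamine_dose = 0,
                            vvc_enabled = FALSE, apc_enabled = FALSE,
                            fenestration_enabled = TRUE,
                            initial_sao2 = 97, initial_svo2 = 60,
                            svr_baseline = 0.9, pvr_baseline = 0.05,
                            allow_extended_ratios = FALSE) {
  cfg <- list(svr_baseline = svr_baseline, pvr_baseline = pvr_baseline,
              svr_ratio = svr_ratio, pvr_ratio = pvr_ratio,
              dobutamine_dose = dobutamine_dose,
              vvc_enabled = isTRUE(vvc_enabled),
              apc_enabled = isTRUE(apc_enabled),
              fenestration_enabled = isTRUE(fenestration_enabled),
              initial_sao2 = initial_sao2, initial_svo2 = initial_svo2,
              allow_extended_ratios = isTRUE(allow_extended_ratios))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$svr_baseline) || cfg$svr_baseline <= 0)
    stop("invalid scenario key 'svr_baseline': must be > 0", call. = FALSE)
  if (!num1(cfg$pvr_baseline) || cfg$pvr_baseline <= 0)
    stop("invalid scenario key 'pvr_baseline': must be > 0", call. = FALSE)
  if (cfg$svr_baseline <= cfg$pvr_baseline)
    stop("invalid scenario keys: 'svr_baseline' must exceed 'pvr_baseline'",
         call. = FALSE)
  for (key in c("svr_ratio", "pvr_ratio")) {
    v <- cfg[[key]]
    if (!num1(v) || v <= 0)
      stop(sprintf("invalid scenario key '%s': must be > 0", key), call. = FALSE)
    if (!cfg$allow_extended_ratios && (v < 0.6 || v > 1.6))
      stop(sprintf(
        "invalid scenario key '%s': %g outside the studied range [0.6, 1.6] (set allow_extended_ratios = TRUE to override)",
        key, v), call. = FALSE)
  }
  if (!num1(cfg$dobutamine_dose) || cfg$dobutamine_dose < 0)
    stop("invalid scenario key 'dobutamine_dose': must be >= 0", call. = FALSE)
  for (key in c("initial_sao2", "initial_svo2")) {
    v <- cfg[[key]]
    if (!num1(v) || v <= 0 || v > 100)
      stop(sprintf("invalid scenario key '%s': must lie in (0, 100]", key),
           call. = FALSE)
  }
  invisible(cfg)
}

#' Default calibrated parameter registry
#'
#' Returns the complete, versioned parameter set for the shipped Fontan
#' model: vascular compartments (compliance, unstressed volume), network
#' edges (resistance, inertance), chamber elastance parameters, valves,
#' shunt conductances, the oxygen-layer constants, and the dobutamine
#' dose-response table.
#'
#' The registry is calibrated so that the reference operating points of
#' the model (arterial/venous saturations with and without collaterals,
#' with and without dobutamine) match their target values; the
#' calibration machinery itself is exposed through
#' [calibrate_registry()].  Aggregate systemic and pulmonary resistances
#' of the shipped registry equal the reference values 0.9 and
#' 0.05 mmHg·s/mL exactly (see [systemic_resistance()] and
#' [pulmonary_resistance()]).
#'
#' @return An object of class `fontan_registry`: a named list with
#'   elements `compartments`, `edges`, `chambers`, `shunts`, `oxygen`,
#'   `dobutamine`, `reference` and `version`.
#' @examples
#' reg <- default_registry()
#' systemic_resistance(reg)   # 0.9 mmHg.s/mL
#' pulmonary_resistance(reg)  # 0.05 mmHg.s/mL
#' @export
default_registry <- function() {
  compartments <- data.frame(
    name = c("aorta", "ub_veins", "org_veins", "leg_veins",
             "svc", "conduit", "rpa", "lpa", "pv"),
    C    = c(1.1, 6.0, 10.0, 7.0, 1.2, 1.3, 0.35, 0.35, 2.5),
    V0   = c(30, 100, 150, 120, 20, 30, 10, 10, 40),
    init_pressure = c(55, 14.0, 14.0, 14.0, 11.4, 11.4, 10.4, 10.4, 7.7),
    stringsAsFactors = FALSE)

  # Systemic bed resistances are derived from the reference aggregate
  # (0.9 mmHg.s/mL) and the design flow shares (upper body 30%,
  # abdominal organs 45%, lower extremities 20%, coronary ~3.75% via a
  # fixed coronary resistance), so the parallel aggregate equals the
  # reference exactly.  Each bed splits 85% arterial / 15% venous.
  # Coronary venous return is lumped into the SVC, so without shunts
  # all systemic return is caval and the arterial saturation equals the
  # pulmonary end-capillary saturation.  The two lung resistances
  # aggregate to exactly 0.05.
  svr_ref <- 0.9
  cor_R <- 24
  w <- c(ub = 0.30, org = 0.45, leg = 0.20) / 0.95
  bed_R <- 1 / ((1 / svr_ref - 1 / cor_R) * w)

  edges <- data.frame(
    name  = c("mitral", "aortic",
              "ub_art", "org_art", "leg_art", "coronary",
              "ub_ven", "org_ven", "leg_ven",
              "svc_rpa", "svc_lpa", "graft",
              "rlung", "llung", "pulm_ven"),
    from  = c("atrium", "ventricle",
              "aorta", "aorta", "aorta", "aorta",
              "ub_veins", "org_veins", "leg_veins",
              "svc", "svc", "conduit",
              "rpa", "lpa", "pv"),
    to    = c("ventricle", "aorta",
              "ub_veins", "org_veins", "leg_veins", "svc",
              "svc", "conduit", "conduit",
              "rpa", "lpa", "rpa",
              "pv", "pv", "atrium"),
    type  = c("valve", "valve",
              "resistor", "resistor", "resistor", "resistor",
              "resistor", "resistor", "resistor",
              "inertial", "inertial", "inertial",
              "resistor", "resistor", "resistor"),
    R     = c(0.004, 0.008,
              0.85 * bed_R[["ub"]], 0.85 * bed_R[["org"]],
              0.85 * bed_R[["leg"]], cor_R,
              0.15 * bed_R[["ub"]], 0.15 * bed_R[["org"]],
              0.15 * bed_R[["leg"]],
              0.012, 0.012, 0.008,
              0.09, 0.1125, 0.015),
    L     = c(0, 0,
              0, 0, 0, 0,
              0, 0, 0,
              0.0015, 0.0015, 0.001,
              0, 0, 0),
    class = c("valve", "valve",
              "systemic", "systemic", "systemic", "systemic",
              "systemic", "systemic", "systemic",
              "fontan", "fontan", "fontan",
              "pulmonary", "pulmonary", "fontan"),
    bed   = c(FALSE, FALSE,
              TRUE, TRUE, TRUE, TRUE,
              FALSE, FALSE, FALSE,
              FALSE, FALSE, FALSE,
              FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)

  chambers <- list(
    ventricle = chamber_parameters(
      e_max = 2.9, e_min = 0.11, v0 = 8,
      viscoelastic_coefficient = 0.012,
      activation_onset = 0, tau1_frac = 0.269, tau2_frac = 0.452,
      m1 = 1.32, m2 = 27.4),
    atrium = chamber_parameters(
      e_max = 0.35, e_min = 0.17, v0 = 4,
      viscoelastic_coefficient = 0.003,
      activation_onset = 0.80, tau1_frac = 0.110, tau2_frac = 0.180,
      m1 = 1.9, m2 = 13.0))

  valves <- list(
    mitral = valve_parameters(forward_resistance = 0.004),
    aortic = valve_parameters(forward_resistance = 0.008))

  # Collateral/fenestration conductances and the distensibility
  # exponent of the venous-side shunts are calibrated jointly with the
  # pulmonary end-capillary saturation and the dobutamine table so the
  # model reproduces its reference operating points (see the vignette).
  shunts <- list(
    fenestration = shunt_parameters(kind = "fenestration",
                                    source_node = "conduit",
                                    target_node = "atrium",
                                    conductance = 0.042, exponent = 3.5),
    vvc = shunt_parameters(kind = "VVC", source_node = "conduit",
                           target_node = "pv",
                           conductance = 0.19, exponent = 3.5),
    apc = shunt_parameters(kind = "APC", source_node = "aorta",
                           target_node = "lpa",
                           conductance = 0.32, exponent = 1))

  oxygen <- list(pao2 = 100, pvo2 = 40, s_pulm_cap = 98.8)

  dobutamine <- data.frame(
    dose = c(0, 5, 10),
    e_max = c(1, 1.60, 2.20),
    svr = c(1, 0.81, 0.62),
    heart_rate = c(1, 1.19, 1.38),
    vo2i = c(1, 1.14, 1.28))  # dose-response anchors at 0/5/10 ug/kg/min

  structure(list(
    version = "1.0.0",
    compartments = compartments,
    edges = edges,
    chambers = chambers,
    valves = valves,
    shunts = shunts,
    oxygen = oxygen,
    dobutamine = dobutamine,
    reference = list(svr = 0.9, pvr = 0.05)),
    class = "fontan_registry")
}

#' Aggregate systemic and pulmonary vascular resistance of a registry
#'
#' `systemic_resistance()` combines the systemic bed resistances (each
#' bed's arterial and venous elements in series, beds in parallel);
#' `pulmonary_resistance()` combines the two lung resistances in
#' parallel.  On the shipped registry these equal the reference values
#' 0.9 and 0.05 mmHg·s/mL.
#'
#' @param registry a `fontan_registry`.
#' @return Aggregate resistance (mmHg·s/mL).
#' @export
systemic_resistance <- function(registry) {
  e <- registry$edges
  art <- e[e$bed, ]
  series <- vapply(seq_len(nrow(art)), function(i) {
    ven <- e[e$from == art$to[i] & e$class == "systemic" & !e$bed, ]
    art$R[i] + sum(ven$R)
  }, numeric(1))
  1 / sum(1 / series)
}

#' @rdname systemic_resistance
#' @export
pulmonary_resistance <- function(registry) {
  R <- registry$edges$R[registry$edges$class == "pulmonary"]
  1 / sum(1 / R)
}

#' Load a scenario configuration from a YAML document
#'
#' Reads a structured-text (YAML) configuration with optional sections
#' `patient`, `scenario`, `compartments`, `edges`, `chambers`, `shunts`
#' and `oxygen`.  Unspecified keys are filled from [patient_parameters()]
#' defaults, [scenario_config()] defaults and [default_registry()].  The
#' fully resolved configuration is echoed via `message()` unless
#' `quiet = TRUE`.
#'
#' @param source path to a YAML file, or a YAML string.
#' @param registry base registry to apply overrides to.
#' @param quiet suppress the resolved-configuration echo.
#' @return A list with elements `patient` (class `patient_parameters`),
#'   `scenario` (class `scenario_config`) and `registry` (class
#'   `fontan_registry`).
#' @examples
#' cfg <- load_config("scenario: {pvr_ratio: 1.2, vvc_enabled: yes}",
#'                    quiet = TRUE)
#' cfg$scenario$pvr_ratio
#' @export
load_config <- function(source, registry = default_registry(), quiet = FALSE) {
  doc <- if (length(source) == 1L && file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  if (is.null(doc)) doc <- list()
  if (!is.list(doc))
    stop("configuration document must be a YAML mapping", call. = FALSE)
  known <- c("patient", "scenario", "compartments", "edges", "chambers",
             "shunts", "oxygen")
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  patient <- do.call(patient_parameters,
                     resolve_section(doc$patient, formals(patient_parameters),
                                     "patient"))
  scenario <- do.call(scenario_config,
                      resolve_section(doc$scenario, formals(scenario_config),
                                      "scenario"))
  registry <- apply_registry_overrides(registry, doc)

  if (!quiet) {
    message("resolved configuration:")
    message(yaml::as.yaml(list(
      patient = unclass(patient),
      scenario = unclass(scenario),
      registry_version = registry$version)))
  }
  list(patient = patient, scenario = scenario, registry = registry)
}

resolve_section <- function(section, defaults, label) {
  if (is.null(section)) return(list())
  if (!is.list(section))
    stop(sprintf("configuration section '%s' must be a mapping", label),
         call. = FALSE)
  unknown <- setdiff(names(section), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown key(s) in section '%s': %s", label,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  section
}

apply_registry_overrides <- function(registry, doc) {
  for (nm in names(doc$compartments)) {
    i <- match(nm, registry$compartments$name)
    if (is.na(i))
      stop("configuration names unknown compartment: ", nm, call. = FALSE)
    for (f in names(doc$compartments[[nm]])) {
      if (!f %in% c("C", "V0", "init_pressure"))
        stop(sprintf("unknown compartment field '%s' for '%s'", f, nm),
             call. = FALSE)
      registry$compartments[i, f] <- doc$compartments[[nm]][[f]]
    }
  }
  for (nm in names(doc$edges)) {
    i <- match(nm, registry$edges$name)
    if (is.na(i))
      stop("configuration names unknown edge: ", nm, call. = FALSE)
    for (f in names(doc$edges[[nm]])) {
      if (!f %in% c("R", "L"))
        stop(sprintf("unknown edge field '%s' for '%s'", f, nm), call. = FALSE)
      registry$edges[i, f] <- doc$edges[[nm]][[f]]
    }
  }
  for (nm in names(doc$chambers)) {
    if (!nm %in% names(registry$chambers))
      stop("configuration names unknown chamber: ", nm, call. = FALSE)
    ch <- modifyList(unclass(registry$chambers[[nm]]), doc$chambers[[nm]])
    registry$chambers[[nm]] <-
      do.call(chamber_parameters, ch[setdiff(names(ch), "act_norm")])
  }
  for (nm in names(doc$shunts)) {
    if (!nm %in% names(registry$shunts))
      stop("configuration names unknown shunt: ", nm, call. = FALSE)
    sh <- modifyList(unclass(registry$shunts[[nm]]), doc$shunts[[nm]])
    registry$shunts[[nm]] <- do.call(shunt_parameters, sh)
  }
  if (!is.null(doc$oxygen)) {
    unknown <- setdiff(names(doc$oxygen), names(registry$oxygen))
    if (length(unknown))
      stop("unknown oxygen key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    registry$oxygen <- modifyList(registry$oxygen, doc$oxygen)
  }
  registry
}

#' Serialize a resolved configuration to YAML
#'
#' Inverse of [load_config()] for the patient and scenario sections:
#' `load_config(serialize_config(cfg), quiet = TRUE)` resolves to an
#' identical configuration.
#'
#' @param config a list with `patient` and `scenario` entries as returned
#'   by [load_config()].
#' @return A YAML string.
#' @export
serialize_config <- function(config) {
  yaml::as.yaml(list(patient = unclass(config$patient),
                     scenario = unclass(config$scenario)))
}

#' @export
print.fontan_registry <- function(x, ...) {
  cat("<fontan_registry> version", x$version, "\n")
  cat(sprintf("  %d compartments, %d edges, %d chambers, %d shunts\n",
              nrow(x$compartments), nrow(x$edges), length(x$chambers),
              length(x$shunts)))
  cat(sprintf("  aggregate SVR %.4g, PVR %.4g mmHg.s/mL\n",
              systemic_resistance(x), pulmonary_resistance(x)))
  invisible(x)
}
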