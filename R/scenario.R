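#' Run one complete Fontan scenario
#'
#' End-to-end pipeline: resolve the parameter set (resistance scaling,
#' dobutamine dose-response), build the topology with the enabled
#' shunts, integrate to the periodic steady state, average the beat,
#' solve the oxygen mixing balance, and compute the cardiac function
#' indices.  The pipeline contains no randomness: identical inputs give
#' identical outputs.
#'
#' @param config a [scenario_config()].
#' @param patient a [patient_parameters()] object.
#' @param registry a [default_registry()]-shaped registry.
#' @param control integrator control, see [limit_cycle_control()].
#' @param init optional initial state to warm-start the limit-cycle
#'   search.
#' @param keep_solution keep the full `beat_solution` in the result
#'   (otherwise only the pressure-volume loop and diagnostics are kept).
#' @return An object of class `scenario_result` with elements `config`,
#'   `patient`, `hemodynamics` (`mean_hemodynamics`), `oxygen`
#'   (`oxygen_state`), `indices` (`cardiac_function_indices`), `loop`
#'   (`pv_loop`), `convergence` (beats, residuals, volume drift),
#'   `config_hash`, and optionally `solution`.
#' @examples
#' \donttest{
#' res <- run_scenario(scenario_config())
#' res$oxygen$sao2
#' }
#' @export
run_scenario <- function(config = scenario_config(),
                         patient = patient_parameters(),
                         registry = default_registry(),
                         control = limit_cycle_control(),
                         init = NULL, keep_solution = FALSE) {
  validate_scenario_config(config)
  params <- list(patient = patient, registry = registry)
  params <- scale_resistances(
    params,
    config$svr_ratio * config$svr_baseline / registry$reference$svr,
    config$pvr_ratio * config$pvr_baseline / registry$reference$pvr)
  params <- apply_dobutamine(params, config$dobutamine_dose)
  topo <- build_fontan_topology(config, params$registry)

  sol <- tryCatch(
    run_to_limit_cycle(topo, params$patient, init = init,
                       control = control),
    error = function(e) stop("scenario [", scenario_label(config), "]: ",
                             conditionMessage(e), call. = FALSE))
  mh <- beat_averages(sol)
  fick <- fick_parameters(hb = params$patient$hb,
                          vo2i = params$patient$vo2i_rest,
                          pao2 = registry$oxygen$pao2,
                          pvo2 = registry$oxygen$pvo2,
                          s_pulm_cap = registry$oxygen$s_pulm_cap)
  ox <- tryCatch(
    solve_saturations(mh, topo, fick, params$patient,
                      init_sao2 = config$initial_sao2,
                      init_svo2 = config$initial_svo2),
    error = function(e) stop("scenario [", scenario_label(config), "]: ",
                             conditionMessage(e), call. = FALSE))
  loop <- extract_pv_loop(sol)
  indices <- compute_indices(loop, params$registry$chambers$ventricle)

  res <- structure(list(
    config = config, patient = params$patient,
    hemodynamics = mh, oxygen = ox, indices = indices, loop = loop,
    convergence = list(beats = sol$beats,
                       residual = utils::tail(sol$residuals, 1),
                       total_volume_drift = sol$total_volume_drift),
    final_state = sol$final_state,
    config_hash = config_hash(list(config, unclass(patient),
                                   registry$version))),
    class = "scenario_result")
  if (keep_solution) res$solution <- sol
  res
}

scenario_label <- function(config) {
  sprintf("vvc=%s apc=%s fen=%s pvr=%.2g svr=%.2g dob=%g",
          config$vvc_enabled, config$apc_enabled,
          config$fenestration_enabled, config$pvr_ratio,
          config$svr_ratio, config$dobutamine_dose)
}

# Deterministic 31-bit hash of a serialized R object (djb2 over the
# serialization bytes); recorded with every result for reproducibility.
config_hash <- function(obj) {
  b <- as.integer(serialize(obj, NULL, version = 2))
  h <- Reduce(function(h, x) (h * 33 + x) %% 2147483647, b, 5381)
  sprintf("%08x", h)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", scenario_label(x$config), "\n")
  cat(sprintf("  SaO2 %.1f%%  SvO2 %.1f%%\n", x$oxygen$sao2, x$oxygen$svo2))
  cat(sprintf("  CO %.2f L/min  net CO %.2f L/min\n",
              x$hemodynamics$co, x$hemodynamics$net_co))
  cat(sprintf("  EF %.1f%%  Ees/Ea %.2f  SW/PVA %.2f\n",
              x$indices$ef, x$indices$ees_over_ea,
              x$indices$sw_over_pva))
  cat(sprintf("  converged in %d beats (hash %s)\n",
              x$convergence$beats, x$config_hash))
  invisible(x)
}

#' Named collateral configurations
#'
#' The enumerated collateral settings used in sweeps: `none`, `vvc`
#' (VVC only), `vvc_apc` (both), and `apc` (APC only, included for
#' completeness as an extrapolation beyond the reference
#' configurations).  The fenestration stays open in all of them.
#'
#' @return Named list of flag pairs.
#' @export
collateral_configs <- function() {
  list(none = c(vvc = FALSE, apc = FALSE),
       vvc = c(vvc = TRUE, apc = FALSE),
       vvc_apc = c(vvc = TRUE, apc = TRUE),
       apc = c(vvc = FALSE, apc = TRUE))
}

#' Sweep pulmonary resistance, dobutamine dose and collateral settings
#'
#' Runs [run_scenario()] on the full grid
#' `collaterals x pvr_ratios x doses` and collects the scalar outputs in
#' a table, one row per grid point.  Within each collateral
#' configuration the limit-cycle search is warm-started from the
#' neighboring grid point.  A failed cell is recorded with its error
#' message; the remaining cells are still computed.
#'
#' @param config base [scenario_config()]; its `pvr_ratio`,
#'   `dobutamine_dose` and collateral flags are overridden by the grid.
#' @param pvr_ratios,doses grid vectors (non-empty).
#' @param collaterals character subset of `names(collateral_configs())`.
#' @param patient,registry,control passed to [run_scenario()].
#' @return A data frame of class `sweep_table`.
#' @export
run_sweep <- function(config = scenario_config(),
                      pvr_ratios = c(0.6, 0.8, 1.0, 1.2, 1.4, 1.6),
                      doses = c(0, 10),
                      collaterals = c("none", "vvc", "vvc_apc"),
                      patient = patient_parameters(),
                      registry = default_registry(),
                      control = limit_cycle_control()) {
  if (!length(pvr_ratios) || !length(doses) || !length(collaterals))
    stop("run_sweep: empty grid", call. = FALSE)
  cc <- collateral_configs()
  bad <- setdiff(collaterals, names(cc))
  if (length(bad))
    stop("unknown collateral configuration(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  rows <- list()
  for (col in collaterals) {
    warm <- NULL
    for (pvr in sort(pvr_ratios)) {
      for (dose in doses) {
        cfg <- config
        cfg$vvc_enabled <- unname(cc[[col]]["vvc"])
        cfg$apc_enabled <- unname(cc[[col]]["apc"])
        cfg$pvr_ratio <- pvr
        cfg$dobutamine_dose <- dose
        row <- tryCatch({
          res <- run_scenario(cfg, patient, registry, control, init = warm)
          warm <- res$final_state
          data.frame(collateral = col, pvr_ratio = pvr, dose = dose,
                     sao2 = res$oxygen$sao2, svo2 = res$oxygen$svo2,
                     co = res$hemodynamics$co,
                     net_co = res$hemodynamics$net_co,
                     ef = res$indices$ef,
                     ees_over_ea = res$indices$ees_over_ea,
                     sw_over_pva = res$indices$sw_over_pva,
                     map = unname(res$hemodynamics$node_pressures["aorta"]),
                     beats = res$convergence$beats,
                     error = NA_character_)
        }, error = function(e) {
          data.frame(collateral = col, pvr_ratio = pvr, dose = dose,
                     sao2 = NA, svo2 = NA, co = NA, net_co = NA, ef = NA,
                     ees_over_ea = NA, sw_over_pva = NA, map = NA,
                     beats = NA, error = conditionMessage(e))
        })
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Calibrate free registry parameters against scalar targets
#'
#' Bounded derivative-free minimization of the sum of squared relative
#' residuals between predicted and target scalars.  With a single free
#' parameter and target, monotone bisection on the bounds is used; with
#' several, Nelder-Mead on logit-transformed (hence bounded)
#' coordinates.
#'
#' Targets name a quantity of a [run_scenario()] result (`"sao2"`,
#' `"svo2"`, `"co"`, `"net_co"`, `"ef"`, `"ees_over_ea"`,
#' `"sw_over_pva"`), the target value, and the scenario configuration
#' under which it is evaluated.  Free parameters are registry paths:
#' `"shunts.<name>.<field>"`, `"oxygen.<field>"`,
#' `"chambers.<name>.<field>"`, `"edges.<name>.<field>"`, or
#' `"dobutamine.<column>.<dose>"`.
#'
#' @param targets list of `list(quantity =, value =, config =)` entries.
#' @param free named list: parameter path -> `c(lower, upper)` bounds.
#' @param registry starting registry.
#' @param patient patient parameters for all target scenarios.
#' @param control integrator control (targets are re-simulated at every
#'   evaluation).
#' @param residual_tol absolute residual (in the target's units) above
#'   which the calibration is reported as failed.
#' @param maxit optimizer iteration budget.
#' @return A list: `registry` (updated), `residuals` (named, predicted
#'   minus target), `values` (fitted parameter values), `success`,
#'   `evaluations`.  A failure is additionally signalled with a warning;
#'   it is never silently accepted.
#' @export
calibrate_registry <- function(targets, free, registry = default_registry(),
                               patient = patient_parameters(),
                               control = limit_cycle_control(),
                               residual_tol = 0.5, maxit = 200) {
  if (length(free) > length(targets))
    stop("calibrate_registry: more free parameters than targets",
         call. = FALSE)
  bounds <- do.call(rbind, free)
  if (any(!is.finite(bounds)))
    stop("calibrate_registry: bounds must be finite", call. = FALSE)

  n_eval <- 0L
  warm <- new.env(parent = emptyenv())
  predict_targets <- function(reg) {
    n_eval <<- n_eval + 1L
    vapply(targets, function(tg) {
      key <- scenario_label(tg$config)
      res <- run_scenario(tg$config, patient, reg, control,
                         init = mget(key, warm, ifnotfound = list(NULL))[[1]])
      assign(key, res$final_state, warm)
      extract_quantity(res, tg$quantity)
    }, numeric(1))
  }

  target_vals <- vapply(targets, `[[`, numeric(1), "value")
  resid <- function(reg) predict_targets(reg) - target_vals

  r0 <- resid(registry)
  if (max(abs(r0)) <= residual_tol) {
    return(list(registry = registry, residuals = setNames(r0, target_names(targets)),
                values = setNames(vapply(names(free), get_registry_value,
                                         numeric(1), registry = registry),
                                  names(free)),
                success = TRUE, evaluations = n_eval))
  }

  if (length(free) == 1L && length(targets) == 1L) {
    path <- names(free)[1]
    lo <- bounds[1, 1]; hi <- bounds[1, 2]
    f <- function(x) resid(set_registry_value(registry, path, x))[1]
    flo <- f(lo); fhi <- f(hi)
    if (sign(flo) == sign(fhi)) {
      # target unreachable within the bounds: report the best endpoint
      fitted <- if (abs(flo) <= abs(fhi)) lo else hi
    } else {
      mid <- (lo + hi) / 2
      for (i in seq_len(maxit)) {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (abs(fm) < residual_tol / 5 || (hi - lo) < 1e-6 * (1 + abs(mid)))
          break
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      fitted <- mid
    }
    reg <- set_registry_value(registry, path, fitted)
    final <- resid(reg)
  } else {
    to_unit <- function(x, b) stats::qlogis((x - b[1]) / (b[2] - b[1]))
    from_unit <- function(z, b) b[1] + (b[2] - b[1]) * stats::plogis(z)
    x0 <- vapply(seq_along(free), function(i)
      to_unit(get_registry_value(registry, names(free)[i]),
              bounds[i, ]), numeric(1))
    obj <- function(z) {
      reg <- registry
      for (i in seq_along(free))
        reg <- set_registry_value(reg, names(free)[i],
                                  from_unit(z[i], bounds[i, ]))
      sum((resid(reg) / pmax(abs(target_vals), 1))^2)
    }
    opt <- optim(x0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8))
    fitted <- vapply(seq_along(free), function(i)
      from_unit(opt$par[i], bounds[i, ]), numeric(1))
    reg <- registry
    for (i in seq_along(free))
      reg <- set_registry_value(reg, names(free)[i], fitted[i])
    final <- resid(reg)
  }

  success <- max(abs(final)) <= residual_tol
  if (!success)
    warning("calibration failure: residuals ",
            paste(sprintf("%s %+0.3g", target_names(targets), final),
                  collapse = ", "),
            " exceed tolerance ", residual_tol, call. = FALSE)
  list(registry = reg,
       residuals = setNames(final, target_names(targets)),
       values = setNames(fitted, names(free)),
       success = success, evaluations = n_eval)
}

target_names <- function(targets) {
  vapply(targets, function(tg)
    paste0(tg$quantity, "@", scenario_label(tg$config)), character(1))
}

extract_quantity <- function(res, quantity) {
  switch(quantity,
         sao2 = res$oxygen$sao2,
         svo2 = res$oxygen$svo2,
         co = res$hemodynamics$co,
         net_co = res$hemodynamics$net_co,
         ef = res$indices$ef,
         ees_over_ea = res$indices$ees_over_ea,
         sw_over_pva = res$indices$sw_over_pva,
         stop("unknown target quantity: ", quantity, call. = FALSE))
}

#' Get or set a registry value by path
#'
#' Paths take the forms `"shunts.<name>.<field>"`, `"oxygen.<field>"`,
#' `"chambers.<name>.<field>"`, `"edges.<name>.<field>"` and
#' `"dobutamine.<column>.<dose>"`.
#'
#' @param registry a `fontan_registry`.
#' @param path parameter path.
#' @param value replacement value (for `set_registry_value`).
#' @return The value, or the updated registry.
#' @export
get_registry_value <- function(registry, path) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  switch(p[1],
    shunts = registry$shunts[[p[2]]][[p[3]]],
    oxygen = registry$oxygen[[p[2]]],
    chambers = registry$chambers[[p[2]]][[p[3]]],
    edges = registry$edges[registry$edges$name == p[2], p[3]],
    dobutamine = registry$dobutamine[
      registry$dobutamine$dose == as.numeric(p[3]), p[2]],
    stop("unknown registry path: ", path, call. = FALSE))
}

#' @rdname get_registry_value
#' @export
set_registry_value <- function(registry, path, value) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (p[1] == "shunts") {
    sh <- unclass(registry$shunts[[p[2]]])
    sh[[p[3]]] <- value
    registry$shunts[[p[2]]] <- do.call(shunt_parameters, sh)
  } else if (p[1] == "oxygen") {
    registry$oxygen[[p[2]]] <- value
  } else if (p[1] == "chambers") {
    ch <- unclass(registry$chambers[[p[2]]])
    ch[[p[3]]] <- value
    registry$chambers[[p[2]]] <-
      do.call(chamber_parameters, ch[setdiff(names(ch), "act_norm")])
  } else if (p[1] == "edges") {
    registry$edges[registry$edges$name == p[2], p[3]] <- value
  } else if (p[1] == "dobutamine") {
    registry$dobutamine[registry$dobutamine$dose == as.numeric(p[3]),
                        p[2]] <- value
  } else {
    stop("unknown registry path: ", path, call. = FALSE)
  }
  registry
}

#' Two-node shunt-mixing instance
#'
#' The smallest oxygen-mixing problem with venous admixture: one
#' arterial and one venous node, a systemic bed edge extracting the
#' whole oxygen consumption, a lung edge carrying fraction
#' `1 - shunt_fraction` of the flow at the end-capillary saturation, and
#' a shunt edge carrying fraction `shunt_fraction` of desaturated venous
#' blood to the arterial side.  Its exact solution is the closed-form
#' pair of linear equations used as the mixing oracle in the test suite.
#'
#' @param shunt_fraction fraction of arterial inflow that is venous
#'   admixture.
#' @param q_total systemic flow (mL/s).
#' @return list with `topology` and a `mean_hemodynamics`-shaped `mean`.
#' @export
two_node_mixing_instance <- function(shunt_fraction = 0.1, q_total = 50) {
  comp <- data.frame(name = c("art", "ven"), C = c(1, 1), V0 = c(0, 0),
                     init_pressure = c(50, 10), kind = "vascular")
  edges <- data.frame(
    name = c("bed", "lung", "shunt"),
    from = c("art", "ven", "ven"), to = c("ven", "art", "art"),
    type = c("resistor", "resistor", "shunt"),
    R = c(1, 1, NA), L = 0,
    class = c("systemic", "pulmonary", "shunt"),
    bed = c(TRUE, FALSE, FALSE), g = c(0, 0, 1), n = 1, w = NA_real_)
  topo <- structure(list(compartments = comp, chambers = list(),
                         edges = edges,
                         node_class = c(art = "systemic_arterial",
                                        ven = "systemic_venous"),
                         shunts = list()),
                    class = "fontan_topology")
  mean <- structure(list(
    edge_flows = c(bed = q_total, lung = q_total * (1 - shunt_fraction),
                   shunt = q_total * shunt_fraction),
    node_pressures = c(art = NA, ven = NA),
    co = q_total * 0.06, net_co = q_total * 0.06, balance = 0),
    class = "mean_hemodynamics")
  list(topology = topo, mean = mean)
}

#' Write deterministic test fixtures
#'
#' Writes small plain-text fixture inputs together with their
#' analytically computed expected outputs:
#' `rc_loop` (two-compartment RC circuit and its closed-form decay),
#' `two_node_mixing` (shunt-mixing instance and its algebraic solution),
#' `rectangle_pv` (a rectangular pressure-volume loop and its indices),
#' `reference_scenarios` (the collateral configurations at baseline
#' resistance as YAML).
#'
#' @param kind fixture family.
#' @param dir output directory (created if needed).
#' @return Character vector of the files written.
#' @export
generate_fixtures <- function(kind = c("rc_loop", "two_node_mixing",
                                       "rectangle_pv",
                                       "reference_scenarios"),
                              dir = ".") {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) file.path(dir, name)

  if (kind == "rc_loop") {
    R <- 1; C1 <- 2; C2 <- 3
    tau <- R * C1 * C2 / (C1 + C2)
    t <- seq(0, 5, by = 0.5)
    dp0 <- 10
    df <- data.frame(time = t, delta_p = dp0 * exp(-t / tau))
    writeLines(yaml::as.yaml(list(R = R, C1 = C1, C2 = C2, tau = tau,
                                  delta_p0 = dp0)),
               out("rc_loop.yaml"))
    write.csv(df, out("rc_loop_expected.csv"), row.names = FALSE)
    files <- c(out("rc_loop.yaml"), out("rc_loop_expected.csv"))
  } else if (kind == "two_node_mixing") {
    f <- 0.1; spc <- 98; hb <- 15; vo2i <- 125; bsa <- 1.63
    q <- 50; pao2 <- 100; pvo2 <- 40
    # closed form: Sa = (1-f) spc + f Sv;  Cv = Ca - VO2/(10 Q)
    k <- 100 / (hb * 1.36)
    drop_s <- (vo2i * bsa / (10 * (q * 0.06)) -
                 (pao2 - pvo2) * 0.0031) * k
    sv <- ((1 - f) * spc - drop_s) / (1 - f)
    sa <- (1 - f) * spc + f * sv
    writeLines(yaml::as.yaml(list(shunt_fraction = f, s_pulm_cap = spc,
                                  hb = hb, vo2i = vo2i, bsa = bsa,
                                  q_total = q)),
               out("two_node_mixing.yaml"))
    write.csv(data.frame(sao2 = sa, svo2 = sv),
              out("two_node_mixing_expected.csv"), row.names = FALSE)
    files <- c(out("two_node_mixing.yaml"),
               out("two_node_mixing_expected.csv"))
  } else if (kind == "rectangle_pv") {
    df <- data.frame(volume = c(120, 50, 50, 120, 120),
                     pressure = c(8, 8, 90, 90, 8))
    write.csv(df, out("rectangle_pv.csv"), row.names = FALSE)
    write.csv(data.frame(edv = 120, esv = 50, ef = 100 * 70 / 120,
                         ea = 90 / 70, sw = 70 * 82),
              out("rectangle_pv_expected.csv"), row.names = FALSE)
    files <- c(out("rectangle_pv.csv"), out("rectangle_pv_expected.csv"))
  } else {
    cc <- collateral_configs()
    scen <- lapply(names(cc), function(nm)
      list(name = nm, vvc_enabled = unname(cc[[nm]]["vvc"]),
           apc_enabled = unname(cc[[nm]]["apc"]),
           fenestration_enabled = TRUE, svr_ratio = 1, pvr_ratio = 1,
           dobutamine_dose = 0))
    writeLines(yaml::as.yaml(scen), out("reference_scenarios.yaml"))
    files <- out("reference_scenarios.yaml")
  }
  invisible(files)
}
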