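# Shared lazily computed simulation results.  Everything is
# deterministic, so caching converged runs across test files is safe
# and keeps the suite fast.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache))
    assign(name, force(expr), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

baseline_result <- function()
  cached("baseline", run_scenario(scenario_config()))

vvc_apc_result <- function()
  cached("vvc_apc",
         run_scenario(scenario_config(vvc_enabled = TRUE,
                                      apc_enabled = TRUE)))

dobutamine_result <- function()
  cached("dob10",
         run_scenario(scenario_config(vvc_enabled = TRUE,
                                      apc_enabled = TRUE,
                                      dobutamine_dose = 10)))

no_shunt_result <- function()
  cached("no_shunt",
         run_scenario(scenario_config(fenestration_enabled = FALSE)))

toy_solution <- function()
  cached("toy", run_to_limit_cycle(toy_loop_topology(),
                                   patient_parameters()))

acceptance_sweep <- function()
  cached("sweep",
         run_sweep(pvr_ratios = c(0.6, 0.8, 1.0, 1.2, 1.4, 1.6),
                   doses = c(0, 10),
                   collaterals = c("none", "vvc", "vvc_apc")))
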