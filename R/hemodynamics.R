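# Network ODE assembly and periodic steady-state integration.
#
# State vector: volumes of all compartments (mL), then flows of the
# inertial edges (mL/s).  Resistor, valve and shunt edges are algebraic.
#
# The chamber viscoelastic term P = E(t)(V-V0) + visc * dV/dt couples
# the chamber pressure to the flows through the adjacent (low
# resistance) valves, so an explicit evaluation is unstable whenever
# visc exceeds a valve resistance.  The right-hand side therefore
# solves that coupling semi-implicitly: every algebraic edge is frozen
# at its secant conductance ceff (with Q = ceff * dp exactly, for the
# valve sigmoid and the shunt power law evaluated at the current dp),
# which makes the chamber-pressure conditions a small linear system
# that is solved exactly; one refresh pass re-evaluates the secants at
# the solved pressures.  All quantities are smooth functions of the
# state.  The R and compiled right-hand sides implement exactly the
# same scheme and agree to rounding error.

EDGE_RESISTOR <- 1L
EDGE_VALVE <- 2L
EDGE_SHUNT <- 3L
EDGE_INERTIAL <- 4L

# Flatten a topology into the index/parameter arrays consumed by the
# right-hand side (R and C++ versions share this structure).
compile_topology <- function(topology, period) {
  comp <- topology$compartments
  edges <- topology$edges
  nv <- nrow(comp)
  node_idx <- setNames(seq_len(nv), comp$name)

  is_chamber <- comp$kind == "chamber"
  ch_node <- which(is_chamber)
  ch <- topology$chambers[comp$name[ch_node]]
  ch_par <- if (length(ch)) t(vapply(ch, function(x) c(
    x$e_max, x$e_min, x$v0, x$viscoelastic_coefficient,
    x$activation_onset, x$tau1_frac, x$tau2_frac, x$m1, x$m2,
    x$act_norm), numeric(10))) else matrix(0, 0, 10)

  type <- c(resistor = EDGE_RESISTOR, valve = EDGE_VALVE,
            shunt = EDGE_SHUNT, inertial = EDGE_INERTIAL)[edges$type]
  alg <- which(type != EDGE_INERTIAL)
  inr <- which(type == EDGE_INERTIAL)

  C <- comp$C
  C[is_chamber] <- 0
  list(nv = nv, ni = length(inr),
       C = C, V0 = comp$V0,
       ch_node = ch_node, ch_par = ch_par,
       a_from = node_idx[edges$from[alg]], a_to = node_idx[edges$to[alg]],
       a_type = unname(type[alg]),
       a_R = edges$R[alg], a_g = edges$g[alg], a_n = edges$n[alg],
       a_w = ifelse(is.na(edges$w[alg]), 1, edges$w[alg]),
       i_from = node_idx[edges$from[inr]], i_to = node_idx[edges$to[inr]],
       i_R = edges$R[inr], i_L = edges$L[inr],
       alg_edge = alg, inr_edge = inr,
       edge_names = edges$name, node_names = comp$name,
       period = period)
}

compiled_elastance <- function(p, t) {
  tn <- ((t / p$period) - p$ch_par[, 5]) %% 1
  h1 <- (tn / p$ch_par[, 6])^p$ch_par[, 8]
  phi <- (h1 / (1 + h1)) / (1 + (tn / p$ch_par[, 7])^p$ch_par[, 9]) /
    p$ch_par[, 10]
  p$ch_par[, 2] + (p$ch_par[, 1] - p$ch_par[, 2]) * phi
}

# Secant conductance of every algebraic edge at pressure drop dp, such
# that the edge flow is exactly ceff * dp.
compiled_alg_ceff <- function(p, dp) {
  ceff <- 1 / p$a_R
  vi <- p$a_type == EDGE_VALVE
  if (any(vi)) {
    dpv <- dp[vi]; w <- p$a_w[vi]; R <- p$a_R[vi]
    ceff[vi] <- ifelse(dpv >= 2 * w, (dpv - w) / (dpv * R),
                       ifelse(dpv > 0, dpv / (4 * w * R), p$a_g[vi]))
  }
  si <- p$a_type == EDGE_SHUNT
  if (any(si))
    ceff[si] <- p$a_g[si] * abs(dp[si])^(p$a_n[si] - 1)
  ceff
}

rhs_r <- function(t, y, p) {
  if (any(!is.finite(y))) {
    bad <- c(p$node_names, p$edge_names[p$inr_edge])[which(!is.finite(y))[1]]
    stop("non-finite state encountered in variable '", bad, "'",
         call. = FALSE)
  }
  V <- y[seq_len(p$nv)]
  Qi <- if (p$ni) y[p$nv + seq_len(p$ni)] else numeric(0)
  nch <- length(p$ch_node)

  P <- ifelse(p$C > 0, (V - p$V0) / ifelse(p$C > 0, p$C, 1), 0)
  E <- if (nch) compiled_elastance(p, t) else numeric(0)
  Pe <- E * (V[p$ch_node] - p$ch_par[, 3])
  P[p$ch_node] <- Pe
  ch_of <- match(seq_len(p$nv), p$ch_node)  # node -> chamber index or NA
  visc <- p$ch_par[, 4]

  for (pass in 1:2) {
    ceff <- compiled_alg_ceff(p, P[p$a_from] - P[p$a_to])
    if (nch && any(visc > 0)) {
      A <- diag(nch)
      b <- Pe
      for (k in seq_along(ceff)) {
        f <- p$a_from[k]; to <- p$a_to[k]
        for (end in c(f, to)) {
          c <- ch_of[end]
          if (is.na(c)) next
          o <- if (end == f) to else f
          A[c, c] <- A[c, c] + visc[c] * ceff[k]
          d <- ch_of[o]
          if (is.na(d)) b[c] <- b[c] + visc[c] * ceff[k] * P[o]
          else A[c, d] <- A[c, d] - visc[c] * ceff[k]
        }
      }
      for (k in seq_along(Qi)) {
        c <- ch_of[p$i_to[k]]
        if (!is.na(c)) b[c] <- b[c] + visc[c] * Qi[k]
        c <- ch_of[p$i_from[k]]
        if (!is.na(c)) b[c] <- b[c] - visc[c] * Qi[k]
      }
      P[p$ch_node] <- solve(A, b)
    }
  }

  Qa <- ceff * (P[p$a_from] - P[p$a_to])
  dV <- numeric(p$nv)
  for (k in seq_along(Qa)) {
    dV[p$a_from[k]] <- dV[p$a_from[k]] - Qa[k]
    dV[p$a_to[k]] <- dV[p$a_to[k]] + Qa[k]
  }
  for (k in seq_along(Qi)) {
    dV[p$i_from[k]] <- dV[p$i_from[k]] - Qi[k]
    dV[p$i_to[k]] <- dV[p$i_to[k]] + Qi[k]
  }

  dQi <- if (p$ni) (P[p$i_from] - P[p$i_to] - p$i_R * Qi) / p$i_L
         else numeric(0)

  Qall <- numeric(length(p$edge_names))
  Qall[p$alg_edge] <- Qa
  Qall[p$inr_edge] <- Qi
  list(c(dV, dQi), c(P, Qall))
}

#' Time derivative of the circulation state
#'
#' Evaluates the network right-hand side at one instant: dV/dt for every
#' compartment (mass conservation at each node, so the derivatives sum
#' to zero exactly), dQ/dt for every inertial edge, plus the node
#' pressures and edge flows implied by the state.
#'
#' @param topology a `fontan_topology`.
#' @param state named state vector: compartment volumes (mL) followed by
#'   inertial-edge flows (mL/s), as produced by [initial_state()].
#' @param t time within the beat (s).
#' @param period beat period (s).
#' @return A list with elements `dstate` (named derivative vector),
#'   `pressures` (mmHg, per node) and `flows` (mL/s, per edge).
#' @examples
#' topo <- rc_loop_topology(R = 1, C1 = 2, C2 = 3)
#' d <- state_derivative(topo, initial_state(topo), 0, 1)
#' sum(d$dstate)  # 0: conservation
#' @export
state_derivative <- function(topology, state, t, period) {
  p <- compile_topology(topology, period)
  nstate <- p$nv + p$ni
  if (length(state) != nstate)
    stop(sprintf("state has length %d; topology requires %d",
                 length(state), nstate), call. = FALSE)
  out <- rhs_r(t, unname(state), p)
  ds <- setNames(out[[1]],
                 c(p$node_names, p$edge_names[p$inr_edge]))
  list(dstate = ds,
       pressures = setNames(out[[2]][seq_len(p$nv)], p$node_names),
       flows = setNames(out[[2]][p$nv + seq_along(p$edge_names)],
                        p$edge_names))
}

#' Default initial circulation state
#'
#' Distributes volume so each vascular compartment sits at its registry
#' initial-pressure guess (V = V0 + C·P) and each chamber at the given
#' filling pressure through its diastolic elastance.  This is a
#' numerical starting point for the limit-cycle search, not a
#' physiological assertion.
#'
#' @param topology a `fontan_topology`.
#' @param chamber_pressure chamber filling-pressure guess (mmHg).
#' @return Named state vector (volumes, then inertial-edge flows).
#' @export
initial_state <- function(topology, chamber_pressure = 7) {
  comp <- topology$compartments
  V <- numeric(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    if (comp$kind[i] == "chamber") {
      ch <- topology$chambers[[comp$name[i]]]
      V[i] <- ch$v0 + chamber_pressure / ch$e_min
    } else {
      V[i] <- comp$V0[i] + comp$C[i] * comp$init_pressure[i]
    }
  }
  ni <- sum(topology$edges$type == "inertial")
  setNames(c(V, rep(0, ni)),
           c(comp$name,
             topology$edges$name[topology$edges$type == "inertial"]))
}

#' Control settings for the limit-cycle integrator
#'
#' @param rtol,atol relative / absolute integration tolerances passed to
#'   [deSolve::lsoda()] (absolute tolerance in mL for volumes).
#' @param cycle_tol limit-cycle criterion: max-norm relative change of
#'   the state across one beat.
#' @param max_beats maximum number of beats before giving up.
#' @param sample_dt output sampling interval for the final beat (s).
#' @param use_compiled use the compiled right-hand side (the R version
#'   gives identical derivatives and exists for testing and inspection).
#' @return A list of control settings.
#' @export
limit_cycle_control <- function(rtol = 1e-6, atol = 1e-8,
                                cycle_tol = 2e-5, max_beats = 200,
                                sample_dt = 1e-3, use_compiled = TRUE) {
  list(rtol = rtol, atol = atol, cycle_tol = cycle_tol,
       max_beats = max_beats, sample_dt = sample_dt,
       use_compiled = use_compiled)
}

#' Integrate a circulation to its periodic steady state
#'
#' Integrates the network beat by beat until the beat-to-beat change of
#' the state (max-norm, relative) falls below `control$cycle_tol`, then
#' returns one densely sampled converged beat with node pressures and
#' edge flows.
#'
#' @param topology a `fontan_topology`.
#' @param patient a [patient_parameters()] object (sets the beat period).
#' @param init optional initial state (defaults to [initial_state()]);
#'   pass the `final_state` of a previous solution to warm-start.
#' @param control see [limit_cycle_control()].
#' @return An object of class `beat_solution`: list with `time`,
#'   `states` (matrix), `pressures`, `flows`, `period`, `beats`,
#'   `residuals`, `final_state`, `total_volume_drift`.
#' @examples
#' \donttest{
#' sol <- run_to_limit_cycle(toy_loop_topology(), patient_parameters())
#' sol$beats
#' }
#' @export
run_to_limit_cycle <- function(topology, patient = patient_parameters(),
                               init = NULL,
                               control = limit_cycle_control()) {
  period <- 60 / patient$heart_rate
  p <- compile_topology(topology, period)
  y0 <- if (is.null(init)) unname(initial_state(topology)) else unname(init)
  if (length(y0) != p$nv + p$ni)
    stop("initial state has wrong length", call. = FALSE)

  func <- if (isTRUE(control$use_compiled)) fontan_rhs else rhs_r
  total0 <- sum(y0[seq_len(p$nv)])

  residuals <- numeric(0)
  converged <- FALSE
  for (beat in seq_len(control$max_beats)) {
    out <- deSolve::lsoda(y0, c(0, period), func, parms = p,
                          rtol = control$rtol, atol = control$atol)
    y1 <- unname(out[2, 1 + seq_len(p$nv + p$ni)])
    rel <- max(abs(y1 - y0) / pmax(abs(y0), 1))
    residuals <- c(residuals, rel)
    y0 <- y1
    if (rel < control$cycle_tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf(
      "limit cycle not reached in %d beats; last residuals: %s",
      control$max_beats,
      paste(signif(utils::tail(residuals, 5), 3), collapse = " ")),
      call. = FALSE)

  times <- seq(0, period, by = control$sample_dt)
  if (times[length(times)] < period) times <- c(times, period)
  out <- deSolve::lsoda(y0, times, func, parms = p,
                        rtol = control$rtol, atol = control$atol)
  ns <- p$nv + p$ni
  states <- out[, 1 + seq_len(ns), drop = FALSE]
  aux <- out[, 1 + ns + seq_len(p$nv + length(p$edge_names)),
             drop = FALSE]
  colnames(states) <- c(p$node_names, p$edge_names[p$inr_edge])
  pressures <- aux[, seq_len(p$nv), drop = FALSE]
  colnames(pressures) <- p$node_names
  flows <- aux[, p$nv + seq_along(p$edge_names), drop = FALSE]
  colnames(flows) <- p$edge_names

  totals <- rowSums(states[, seq_len(p$nv), drop = FALSE])
  structure(list(time = out[, 1], states = states, pressures = pressures,
                 flows = flows, period = period, beats = beat,
                 residuals = residuals,
                 final_state = unname(out[nrow(out), 1 + seq_len(ns)]),
                 total_volume_drift = max(abs(totals - total0)) / total0,
                 topology = topology, patient = patient),
            class = "beat_solution")
}

#' @export
print.beat_solution <- function(x, ...) {
  cat(sprintf(
    "<beat_solution> period %.3f s, converged in %d beats (residual %.2g)\n",
    x$period, x$beats, utils::tail(x$residuals, 1)))
  cat(sprintf("  total volume drift over final beat: %.2g (relative)\n",
              x$total_volume_drift))
  invisible(x)
}

#' Beat-averaged hemodynamics
#'
#' Averages node pressures and edge flows over the converged beat and
#' derives cardiac output (mean flow through the ventricular outflow
#' valve) and net cardiac output (mean caval return: SVC plus
#' IVC/conduit flow into the pulmonary arteries).  Without
#' recirculation paths the two coincide.
#'
#' @param solution a `beat_solution`.
#' @return An object of class `mean_hemodynamics`: list with
#'   `node_pressures` (mmHg), `edge_flows` (mL/s), `co` and `net_co`
#'   (L/min), and `balance` (worst junction flow imbalance relative to
#'   cardiac output).
#' @export
beat_averages <- function(solution) {
  # trapezoidal time average over the beat (the sampling grid may not
  # divide the period exactly)
  tt <- solution$time
  n <- length(tt)
  wt <- c(diff(tt), 0) / 2 + c(0, diff(tt)) / 2
  wt <- wt / sum(wt)
  mean_P <- colSums(solution$pressures * wt)
  mean_Q <- colSums(solution$flows * wt)

  topo <- solution$topology
  edges <- topo$edges
  cls <- topo$node_class

  out_valve <- which(edges$type == "valve" & edges$from == "ventricle")
  co <- if (length(out_valve) == 1L) unname(mean_Q[out_valve]) * 0.06
        else NA_real_  # pump-less test circuit

  caval <- which(cls[edges$from] == "systemic_venous" &
                   cls[edges$to] == "pulmonary_arterial" &
                   edges$type != "shunt")
  net_co <- if (length(caval)) sum(mean_Q[caval]) * 0.06 else co

  # mean inflow - outflow at every node (zero on a periodic solution)
  resid <- numeric(nrow(topo$compartments))
  names(resid) <- topo$compartments$name
  for (k in seq_len(nrow(edges))) {
    resid[edges$from[k]] <- resid[edges$from[k]] - mean_Q[k]
    resid[edges$to[k]] <- resid[edges$to[k]] + mean_Q[k]
  }
  denom <- if (is.finite(co) && co > 0) co / 0.06
           else max(abs(mean_Q), 1e-9)
  balance <- max(abs(resid)) / max(denom, 1e-9)

  structure(list(node_pressures = mean_P, edge_flows = mean_Q,
                 co = co, net_co = net_co, balance = balance,
                 node_balance = resid),
            class = "mean_hemodynamics")
}

#' @export
print.mean_hemodynamics <- function(x, ...) {
  cat(sprintf("<mean_hemodynamics> CO %.2f L/min, net CO %.2f L/min\n",
              x$co, x$net_co))
  cat(sprintf("  worst junction imbalance: %.2g of CO\n", x$balance))
  invisible(x)
}

#' Export a converged beat as CSV
#'
#' Writes one row per sample with columns `time`, `P_<node>` for every
#' node pressure and `Q_<edge>` for every edge flow.
#'
#' @param solution a `beat_solution`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
export_beat_csv <- function(solution, path) {
  df <- data.frame(time = solution$time,
                   setNames(as.data.frame(solution$pressures),
                            paste0("P_", colnames(solution$pressures))),
                   setNames(as.data.frame(solution$flows),
                            paste0("Q_", colnames(solution$flows))),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
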