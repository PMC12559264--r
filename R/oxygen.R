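#' Oxygen content of blood
#'
#' Evaluates the standard content formula
#' `content = Hb * 1.36 * saturation/100 + PO2 * 0.0031`
#' (bound plus dissolved oxygen).
#'
#' @param saturation hemoglobin saturation (percent), in \[0, 100\].
#' @param hb hemoglobin (g/dL), >= 0.
#' @param po2 dissolved-oxygen partial pressure (mmHg), >= 0.
#' @return Oxygen content (mL O2/dL); vectorized.
#' @examples
#' o2_content(97, 15, 100)  # 20.098
#' o2_content(60, 15, 40)   # 12.364
#' @export
o2_content <- function(saturation, hb, po2) {
  if (any(saturation < 0 | saturation > 100))
    stop("o2_content: saturation must lie in [0, 100]", call. = FALSE)
  if (any(hb < 0) || any(po2 < 0))
    stop("o2_content: hb and po2 must be >= 0", call. = FALSE)
  hb * 1.36 * saturation / 100 + po2 * 0.0031
}

#' Saturation from oxygen content
#'
#' Inverse of [o2_content()] at a given dissolved partial pressure.
#' @param content oxygen content (mL O2/dL).
#' @inheritParams o2_content
#' @return Saturation (percent); may fall outside \[0, 100\] for
#'   infeasible contents (callers check).
#' @export
o2_saturation_from_content <- function(content, hb, po2) {
  (content - po2 * 0.0031) * 100 / (hb * 1.36)
}

#' Fick-principle oxygen consumption
#'
#' `VO2I = COI * (CaO2 - CvO2) * 10`, with the cardiac output index in
#' L/min/m2, contents in mL O2/dL and the result in mL/min/m2.
#'
#' @param coi cardiac output index (L/min/m2), >= 0.
#' @param cao2,cvo2 arterial and mixed-venous oxygen content (mL O2/dL).
#' @return Oxygen consumption index (mL/min/m2).
#' @examples
#' fick_vo2(3.0, 20.098, 12.364)  # 232.02
#' @export
fick_vo2 <- function(coi, cao2, cvo2) {
  if (any(coi < 0))
    stop("fick_vo2: coi must be >= 0", call. = FALSE)
  coi * (cao2 - cvo2) * 10
}

#' Fick-layer parameters
#'
#' @param hb hemoglobin (g/dL), > 0.
#' @param vo2i oxygen consumption index (mL/min/m2), > 0.
#' @param pao2,pvo2 dissolved-oxygen partial pressures on the arterial
#'   and venous side (mmHg); fixed operating-point values, the dissolved
#'   term being ~1.5% of total content.
#' @param s_pulm_cap pulmonary end-capillary saturation (percent): the
#'   saturation of blood leaving the lungs.
#' @return An object of class `fick_parameters`.
#' @export
fick_parameters <- function(hb = 15, vo2i = 125, pao2 = 100, pvo2 = 40,
                            s_pulm_cap = 98) {
  if (hb <= 0) stop("fick_parameters: hb must be > 0", call. = FALSE)
  if (vo2i <= 0) stop("fick_parameters: vo2i must be > 0", call. = FALSE)
  if (s_pulm_cap <= 0 || s_pulm_cap > 100)
    stop("fick_parameters: s_pulm_cap must lie in (0, 100]", call. = FALSE)
  structure(list(hb = hb, vo2i = vo2i, pao2 = pao2, pvo2 = pvo2,
                 s_pulm_cap = s_pulm_cap), class = "fick_parameters")
}

# Per-edge affine saturation transfer s_delivered = a * S[source] + b,
# given beat-averaged flows.  Lung edges deliver the end-capillary
# saturation; systemic bed edges extract the total oxygen consumption in
# proportion to their flow (so every bed delivers the same content drop
# per dL); all other edges pass their source saturation through.
edge_transfer <- function(topology, mean_Q, fick, patient) {
  edges <- topology$edges
  ne <- nrow(edges)
  a <- rep(1, ne)
  b <- rep(0, ne)

  bed <- which(edges$bed)
  q_tis <- sum(mean_Q[bed]) * 0.06  # L/min
  if (length(bed) && q_tis <= 0)
    stop("solve_saturations: no forward systemic bed flow", call. = FALSE)
  vo2 <- fick$vo2i * patient$bsa     # mL/min
  if (length(bed)) {
    drop <- vo2 / (10 * q_tis)       # content drop, mL O2/dL
    shift <- ((fick$pao2 - fick$pvo2) * 0.0031 - drop) * 100 /
      (fick$hb * 1.36)
    b[bed] <- shift
  }

  lung <- which(edges$class == "pulmonary")
  a[lung] <- 0
  b[lung] <- fick$s_pulm_cap

  list(a = a, b = b, q_tis = q_tis, vo2 = vo2)
}

#' Solve the oxygen saturation mixing balance
#'
#' Given beat-averaged flows on a topology, finds the fixed point of the
#' node mixing system: at every node the saturation equals the
#' flow-weighted mean of the incoming saturations, blood leaving the
#' lungs carries the pulmonary end-capillary saturation, and the
#' systemic beds jointly extract `vo2i * bsa`, distributed in proportion
#' to bed flow.  The default method is damped successive substitution
#' started from (`init_sao2`, `init_svo2`); `method = "linear"` solves
#' the same affine system directly and is the independent cross-check
#' used in the test suite.
#'
#' @param mean a [beat_averages()] result (`mean_hemodynamics`).
#' @param topology the `fontan_topology` the flows belong to.
#' @param fick a [fick_parameters()] object.
#' @param patient a [patient_parameters()] object (supplies BSA).
#' @param init_sao2,init_svo2 iteration starting values (percent).
#' @param method `"fixedpoint"` or `"linear"`.
#' @param tol convergence tolerance on the max-norm saturation change.
#' @param max_iter iteration cap.
#' @param relax damping factor of the substitution step.
#' @return An object of class `oxygen_state`: node saturations,
#'   `sao2`, `svo2`, `cao2`, `cvo2` (mL O2/dL), `coi` (L/min/m2), and
#'   the Fick-closure residual `fick_residual`.
#' @export
solve_saturations <- function(mean, topology, fick = fick_parameters(),
                              patient = patient_parameters(),
                              init_sao2 = 97, init_svo2 = 60,
                              method = c("fixedpoint", "linear"),
                              tol = 1e-12, max_iter = 10000,
                              relax = 0.9) {
  method <- match.arg(method)
  edges <- topology$edges
  nodes <- topology$compartments$name
  nn <- length(nodes)
  cls <- topology$node_class[nodes]
  mean_Q <- mean$edge_flows

  tr <- edge_transfer(topology, mean_Q, fick, patient)

  # incoming edge lists per node, honoring mean-flow direction
  src <- ifelse(mean_Q >= 0, edges$from, edges$to)
  dst <- ifelse(mean_Q >= 0, edges$to, edges$from)
  qab <- abs(mean_Q)
  live <- qab > 1e-12
  src_i <- match(src, nodes)
  dst_i <- match(dst, nodes)

  venous <- cls %in% c("systemic_venous", "pulmonary_arterial")
  s0 <- ifelse(venous, init_svo2, init_sao2)

  solve_linear <- function() {
    A <- matrix(0, nn, nn)
    rhs <- numeric(nn)
    W <- numeric(nn)
    for (k in which(live)) {
      j <- dst_i[k]
      W[j] <- W[j] + qab[k]
      A[j, src_i[k]] <- A[j, src_i[k]] - qab[k] * tr$a[k]
      rhs[j] <- rhs[j] + qab[k] * tr$b[k]
    }
    for (j in seq_len(nn)) {
      if (W[j] > 0) A[j, j] <- A[j, j] + W[j]
      else { A[j, j] <- 1; rhs[j] <- s0[j] }
    }
    solve(A, rhs)
  }

  if (method == "linear") {
    s <- solve_linear()
    iters <- NA_integer_
  } else {
    s <- s0
    iters <- 0L
    repeat {
      num <- numeric(nn)
      den <- numeric(nn)
      for (k in which(live)) {
        j <- dst_i[k]
        num[j] <- num[j] + qab[k] * (tr$a[k] * s[src_i[k]] + tr$b[k])
        den[j] <- den[j] + qab[k]
      }
      s_new <- ifelse(den > 0, num / pmax(den, 1e-300), s0)
      s_next <- (1 - relax) * s + relax * s_new
      delta <- max(abs(s_next - s))
      s <- s_next
      iters <- iters + 1L
      if (delta < tol) break
      if (iters >= max_iter)
        stop("solve_saturations: fixed point not reached in ", max_iter,
             " iterations (last change ", signif(delta, 3), ")",
             call. = FALSE)
    }
  }
  names(s) <- nodes

  if (any(s < -1e-9)) {
    # affine in vo2i: find the largest supportable consumption
    fick0 <- fick; fick0$vo2i <- fick$vo2i * 1e-6
    s_ref <- solve_saturations(mean, topology, fick0, patient,
                               init_sao2, init_svo2, method = "linear")
    slope <- (s - s_ref$saturations) / (fick$vo2i - fick0$vo2i)
    cand <- -s_ref$saturations / slope + fick0$vo2i
    vmax <- min(cand[slope < 0 & is.finite(cand)])
    stop(sprintf(
      "solve_saturations: vo2i = %.4g mL/min/m2 infeasible at these flows (saturation would fall below 0); maximum supportable vo2i ~ %.4g",
      fick$vo2i, vmax), call. = FALSE)
  }
  s <- pmin(pmax(s, 0), 100)

  arterial_node <- nodes[cls == "systemic_arterial"][1]
  sao2 <- unname(s[arterial_node])

  caval <- which(cls[edges$from] == "systemic_venous" &
                   cls[edges$to] == "pulmonary_arterial" &
                   edges$type != "shunt")
  svo2 <- if (length(caval)) {
    sum(qab[caval] * s[match(edges$from[caval], nodes)]) /
      sum(qab[caval])
  } else {
    vnodes <- which(cls == "systemic_venous")
    unname(s[vnodes][which.max(topology$compartments$C[vnodes])])
  }

  cao2 <- o2_content(sao2, fick$hb, fick$pao2)
  cvo2 <- o2_content(svo2, fick$hb, fick$pvo2)
  coi <- tr$q_tis / patient$bsa
  structure(list(saturations = s, sao2 = sao2, svo2 = unname(svo2),
                 cao2 = cao2, cvo2 = cvo2, coi = coi,
                 fick_residual = abs(fick$vo2i - fick_vo2(coi, cao2, cvo2)),
                 q_tis = tr$q_tis, vo2 = tr$vo2, iterations = iters,
                 fick = fick),
            class = "oxygen_state")
}

#' @export
print.oxygen_state <- function(x, ...) {
  cat(sprintf("<oxygen_state> SaO2 %.1f%%, SvO2 %.1f%%\n", x$sao2, x$svo2))
  cat(sprintf("  CaO2 %.3f, CvO2 %.3f mL O2/dL; COI %.2f L/min/m2\n",
              x$cao2, x$cvo2, x$coi))
  cat(sprintf("  Fick closure residual %.2g mL/min/m2\n", x$fick_residual))
  invisible(x)
}

#' Export node saturations as a one-row CSV
#'
#' @param state an `oxygen_state`.
#' @param path output file path.
#' @param meta optional named list of scenario metadata columns.
#' @return The path, invisibly.
#' @export
export_oxygen_csv <- function(state, path, meta = list()) {
  row <- c(meta, as.list(state$saturations),
           list(sao2 = state$sao2, svo2 = state$svo2, coi = state$coi))
  write.csv(as.data.frame(row), path, row.names = FALSE)
  invisible(path)
}
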