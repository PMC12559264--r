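#' Shunt (collateral / fenestration) parameters
#'
#' A shunt is an algebraic flow path Q = g · dP · |dP|^(n-1) between two
#' network nodes.  `exponent = 1` gives the linear conductance law used
#' for aortopulmonary collaterals; the venovenous collateral and the
#' fenestration default to a supralinear exponent, representing
#' thin-walled, distensible vessels whose effective conductance grows
#' with distending pressure (see the package vignette).  The conductance
#' `g` is the flow at a 1 mmHg pressure difference.
#'
#' Kind-consistent endpoints are enforced when the shunt is attached to a
#' topology: a VVC runs from a systemic-venous node to the
#' pulmonary-venous side (or atrium), an APC from a systemic-arterial to
#' a pulmonary-arterial node, and a fenestration from the conduit to the
#' atrium.
#'
#' @param kind one of `"VVC"`, `"APC"`, `"fenestration"`.
#' @param source_node,target_node node identifiers.
#' @param conductance flow at 1 mmHg (mL/s), >= 0.
#' @param exponent flow-law exponent, > 0.
#' @return An object of class `shunt_parameters`.
#' @export
shunt_parameters <- function(kind, source_node, target_node, conductance,
                             exponent = 1) {
  kind <- match.arg(kind, c("VVC", "APC", "fenestration"))
  if (conductance < 0)
    stop("shunt_parameters: conductance must be >= 0", call. = FALSE)
  if (exponent <= 0)
    stop("shunt_parameters: exponent must be > 0", call. = FALSE)
  structure(list(kind = kind, source_node = source_node,
                 target_node = target_node, conductance = conductance,
                 exponent = exponent),
            class = "shunt_parameters")
}

#' Signed shunt flow law
#'
#' @param delta_p pressure difference source - target (mmHg).
#' @param shunt a [shunt_parameters()] object.
#' @return Flow (mL/s), positive from source to target.
#' @export
shunt_flow <- function(delta_p, shunt) {
  shunt$conductance * delta_p * abs(delta_p)^(shunt$exponent - 1)
}

# Node side classification used by the shunt kind-consistency rules and
# by the oxygen layer.
fontan_node_class <- function() {
  c(aorta = "systemic_arterial",
    ub_veins = "systemic_venous", org_veins = "systemic_venous",
    leg_veins = "systemic_venous", svc = "systemic_venous",
    conduit = "systemic_venous",
    rpa = "pulmonary_arterial", lpa = "pulmonary_arterial",
    pv = "pulmonary_venous",
    ventricle = "chamber", atrium = "atrium")
}

#' Build the closed-loop TCPC Fontan topology
#'
#' Assembles the circulation graph from a registry: single ventricle and
#' atrium, aorta, four parallel systemic beds (upper body, abdominal
#' organs, lower extremities, coronary), superior vena cava, the
#' IVC/conduit compartment with its artificial graft to the right
#' pulmonary artery, two parallel pulmonary branches, and the pulmonary
#' veins.  Per the total cavopulmonary connection, both cavae drain to
#' the pulmonary arteries (SVC to both branches, conduit to the right
#' branch), never to the atrium.  Shunts enabled in the scenario
#' configuration are attached with [attach_shunt()].
#'
#' @param config a [scenario_config()] (controls which shunts are
#'   attached).
#' @param registry a [default_registry()]-shaped parameter registry.
#' @return An object of class `fontan_topology`.
#' @examples
#' topo <- build_fontan_topology(scenario_config(vvc_enabled = TRUE),
#'                               default_registry())
#' nrow(validate_topology(topo))  # 0: valid
#' @export
build_fontan_topology <- function(config = scenario_config(),
                                  registry = default_registry()) {
  comp <- registry$compartments
  needed <- unique(c(registry$edges$from, registry$edges$to))
  chamber_names <- names(registry$chambers)
  missing <- setdiff(needed, c(comp$name, chamber_names))
  if (length(missing))
    stop("registry gap: no parameters for bed/compartment '",
         paste(missing, collapse = "', '"), "'", call. = FALSE)

  comp$kind <- "vascular"
  for (nm in chamber_names) {
    ch <- registry$chambers[[nm]]
    comp <- rbind(comp, data.frame(name = nm, C = NA_real_, V0 = ch$v0,
                                   init_pressure = NA_real_,
                                   kind = "chamber"))
  }

  edges <- registry$edges
  edges$g <- 0
  edges$n <- 1
  edges$w <- NA_real_
  for (i in which(edges$type == "valve")) {
    vp <- registry$valves[[edges$name[i]]]
    if (is.null(vp))
      stop("registry gap: no valve parameters for edge '", edges$name[i],
           "'", call. = FALSE)
    edges$R[i] <- vp$forward_resistance
    edges$g[i] <- vp$leak_conductance
    edges$w[i] <- vp$smoothing_width
  }

  topo <- structure(list(compartments = comp,
                         chambers = registry$chambers,
                         edges = edges,
                         node_class = fontan_node_class(),
                         shunts = list()),
                    class = "fontan_topology")

  if (config$fenestration_enabled)
    topo <- attach_shunt(topo, registry$shunts$fenestration)
  if (config$vvc_enabled)
    topo <- attach_shunt(topo, registry$shunts$vvc)
  if (config$apc_enabled)
    topo <- attach_shunt(topo, registry$shunts$apc)
  topo
}

#' Attach a shunt to a topology
#'
#' Returns a new topology containing the shunt edge; the input topology
#' is unchanged.  Endpoints must exist and satisfy the kind-consistency
#' rules (see [shunt_parameters()]).  Attachment is order-independent up
#' to edge ordering: attaching a set of shunts in any order yields the
#' same circulation.
#'
#' @param topology a `fontan_topology`.
#' @param shunt a [shunt_parameters()] object.
#' @return The augmented `fontan_topology`.
#' @export
attach_shunt <- function(topology, shunt) {
  stopifnot(inherits(shunt, "shunt_parameters"))
  nodes <- topology$compartments$name
  for (ep in c(shunt$source_node, shunt$target_node))
    if (!ep %in% nodes)
      stop("shunt endpoint '", ep, "' is not a node of the topology",
           call. = FALSE)
  cls <- topology$node_class
  src <- cls[[shunt$source_node]]
  tgt <- cls[[shunt$target_node]]
  ok <- switch(shunt$kind,
    VVC = identical(src, "systemic_venous") &&
      tgt %in% c("pulmonary_venous", "atrium"),
    APC = identical(src, "systemic_arterial") &&
      identical(tgt, "pulmonary_arterial"),
    fenestration = identical(shunt$source_node, "conduit") &&
      identical(tgt, "atrium"))
  if (!isTRUE(ok))
    stop(sprintf(
      "kind-inconsistent %s shunt: %s (%s) -> %s (%s)", shunt$kind,
      shunt$source_node, src, shunt$target_node, tgt), call. = FALSE)

  nm <- tolower(shunt$kind)
  if (nm %in% topology$edges$name)
    nm <- make.unique(c(topology$edges$name, nm))[nrow(topology$edges) + 1L]
  topology$edges <- rbind(topology$edges, data.frame(
    name = nm, from = shunt$source_node, to = shunt$target_node,
    type = "shunt", R = NA_real_, L = 0, class = "shunt", bed = FALSE,
    g = shunt$conductance, n = shunt$exponent, w = NA_real_))
  topology$shunts[[nm]] <- shunt
  topology
}

#' Validate a topology and report violations
#'
#' Checks graph closure (every compartment on a directed cycle through
#' the rest of the circulation), the TCPC constraint (no structural
#' caval-to-atrium edge; both cavae reach a pulmonary-arterial node), and
#' parameter positivity (C > 0, R >= 0, L >= 0, shunt conductance >= 0).
#'
#' @param topology a `fontan_topology`.
#' @return A data frame with columns `check` and `detail`; zero rows iff
#'   the topology is valid.
#' @export
validate_topology <- function(topology) {
  report <- list()
  add <- function(check, detail)
    report[[length(report) + 1L]] <<- data.frame(check = check,
                                                 detail = detail)

  comp <- topology$compartments
  edges <- topology$edges

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     vertices = comp$name)
  if (!igraph::is_connected(g, mode = "strong"))
    add("connectivity",
        "graph is not a single closed loop (not strongly connected)")

  cls <- topology$node_class
  caval <- names(cls)[cls == "systemic_venous"]
  caval <- intersect(caval, c("svc", "conduit"))
  bad <- edges$from %in% caval & edges$to == "atrium" & edges$type != "shunt"
  if (any(bad))
    add("tcpc", paste("structural caval-to-atrium edge:",
                      paste(edges$name[bad], collapse = ", ")))
  pa <- names(cls)[cls == "pulmonary_arterial"]
  for (cv in caval) {
    if (!cv %in% comp$name) next
    if (!any(edges$from == cv & edges$to %in% pa & edges$type != "shunt"))
      add("tcpc", paste0("caval compartment '", cv,
                         "' has no connection to a pulmonary artery"))
  }

  vasc <- comp$kind == "vascular"
  if (any(vasc & (!is.finite(comp$C) | comp$C <= 0)))
    add("parameters", paste("non-positive compliance:",
                            paste(comp$name[vasc & (!is.finite(comp$C) | comp$C <= 0)],
                                  collapse = ", ")))
  if (any(edges$R < 0, na.rm = TRUE))
    add("parameters", paste("negative resistance:",
                            paste(edges$name[which(edges$R < 0)], collapse = ", ")))
  if (any(edges$L < 0))
    add("parameters", paste("negative inertance:",
                            paste(edges$name[edges$L < 0], collapse = ", ")))
  if (any(edges$g < 0, na.rm = TRUE))
    add("parameters", paste("negative conductance:",
                            paste(edges$name[which(edges$g < 0)], collapse = ", ")))

  if (length(report)) do.call(rbind, report)
  else data.frame(check = character(), detail = character())
}

#' Serialize a topology to a YAML document
#'
#' @param topology a `fontan_topology`.
#' @return A YAML string listing compartments, chambers and edges.
#' @export
serialize_topology <- function(topology) {
  yaml::as.yaml(list(
    compartments = topology$compartments,
    chambers = lapply(topology$chambers, unclass),
    edges = topology$edges))
}

#' @export
print.fontan_topology <- function(x, ...) {
  ns <- sum(x$edges$type == "shunt")
  cat("<fontan_topology>", nrow(x$compartments), "compartments,",
      nrow(x$edges), "edges,", ns, "shunt(s)\n")
  if (ns)
    cat("  shunts:", paste(x$edges$name[x$edges$type == "shunt"],
                           collapse = ", "), "\n")
  invisible(x)
}

#' Minimal test circuits
#'
#' `rc_loop_topology()` builds a two-compartment RC circuit whose
#' pressure difference decays with the closed-form time constant
#' `tau = R * C1 * C2 / (C1 + C2)`; it is the analytic oracle for the
#' network integrator.  `toy_loop_topology()` builds the smallest beating
#' closed loop (ventricle, atrium, one arterial and one venous
#' Windkessel) used for fast chamber/afterload experiments.
#'
#' @param R,R_sys,R_ven resistances (mmHg·s/mL).
#' @param C1,C2,C_art,C_ven compliances (mL/mmHg).
#' @param e_max,e_min,v0,visc ventricular elastance parameters.
#' @return A `fontan_topology` (without the Fontan-specific node classes).
#' @export
rc_loop_topology <- function(R = 1, C1 = 2, C2 = 3) {
  comp <- data.frame(name = c("a", "b"), C = c(C1, C2), V0 = c(0, 0),
                     init_pressure = c(10, 0), kind = "vascular")
  edges <- data.frame(name = "rab", from = "a", to = "b",
                      type = "resistor", R = R, L = 0, class = "other",
                      bed = FALSE, g = 0, n = 1, w = NA_real_)
  structure(list(compartments = comp, chambers = list(), edges = edges,
                 node_class = c(a = "other", b = "other"),
                 shunts = list()),
            class = "fontan_topology")
}

#' @rdname rc_loop_topology
#' @export
toy_loop_topology <- function(e_max = 2.5, e_min = 0.08, v0 = 10,
                              visc = 0, R_sys = 1.0, R_ven = 0.05,
                              C_art = 1.2, C_ven = 15) {
  comp <- data.frame(
    name = c("artery", "vein"), C = c(C_art, C_ven), V0 = c(20, 100),
    init_pressure = c(70, 8), kind = "vascular")
  chambers <- list(
    ventricle = chamber_parameters(e_max = e_max, e_min = e_min, v0 = v0,
                                   viscoelastic_coefficient = visc),
    atrium = chamber_parameters(e_max = 0.3, e_min = 0.15, v0 = 4,
                                activation_onset = 0.8,
                                tau1_frac = 0.11, tau2_frac = 0.18,
                                m1 = 1.9, m2 = 13))
  for (nm in names(chambers))
    comp <- rbind(comp, data.frame(name = nm, C = NA_real_,
                                   V0 = chambers[[nm]]$v0,
                                   init_pressure = NA_real_,
                                   kind = "chamber"))
  edges <- data.frame(
    name = c("mitral", "aortic", "sys", "ven"),
    from = c("atrium", "ventricle", "artery", "vein"),
    to = c("ventricle", "artery", "vein", "atrium"),
    type = c("valve", "valve", "resistor", "resistor"),
    R = c(0.004, 0.008, R_sys, R_ven), L = 0,
    class = c("valve", "valve", "systemic", "other"),
    bed = c(FALSE, FALSE, TRUE, FALSE),
    g = 0, n = 1, w = c(0.05, 0.05, NA, NA))
  structure(list(compartments = comp, chambers = chambers, edges = edges,
                 node_class = c(artery = "systemic_arterial",
                                vein = "systemic_venous",
                                ventricle = "chamber", atrium = "atrium"),
                 shunts = list()),
            class = "fontan_topology")
}
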