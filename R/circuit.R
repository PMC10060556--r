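#' Lumped-parameter hydraulic circuits
#'
#' A `circuit` is the electrical-analog substrate shared by every model in
#' this package: nodes carry pressures (Pa), elements carry volumetric flows
#' (m^3/s).  Supported elements are resistors, inductors (blood inertia),
#' capacitors (wall or tissue compliance, constant or pressure-dependent),
#' smoothed diodes (one-way CSF valves), pressure sources, flow sources and
#' tracking sources (a node pinned to the instantaneous pressure of another
#' node, used for one-way boundary coupling).
#'
#' Conventions: element flow is positive from the `pos` to the `neg` endpoint;
#' a flow source injects its value into `pos`; exactly one node is ground
#' (reference pressure 0 Pa).  Capacitors may name an `external_pressure_ref`
#' node whose pressure offsets the transmural pressure without receiving the
#' displaced volume; a capacitor whose `neg` endpoint is a non-ground node is
#' a true two-terminal element and does return its flow to `neg`.
#'
#' @param label human-readable node description.
#' @param ground logical, is this the reference node?
#' @return `circuit()` returns an empty circuit object; `add_*()` helpers
#'   return the modified circuit.
#' @name circuit
#' @examples
#' ck <- circuit()
#' ck <- add_node(ck, "ground", ground = TRUE)
#' ck <- add_node(ck, "n1")
#' ck <- add_resistor(ck, "R1", "n1", "ground", 1)
#' ck <- add_capacitor(ck, "C1", "n1", value = 1)
NULL

#' @rdname circuit
#' @export
circuit <- function() {
  structure(list(nodes = data.frame(id = character(), label = character(),
                                    is_ground = logical(),
                                    stringsAsFactors = FALSE),
                 elements = list(), probes = list()),
            class = "circuit")
}

#' @rdname circuit
#' @param ckt a circuit object.
#' @param id unique node / element identifier.
#' @export
add_node <- function(ckt, id, label = id, ground = FALSE) {
  stopifnot(inherits(ckt, "circuit"), is.character(id), length(id) == 1L)
  if (id %in% ckt$nodes$id) stop("duplicate node id: ", id, call. = FALSE)
  ckt$nodes <- rbind(ckt$nodes,
                     data.frame(id = id, label = label, is_ground = ground,
                                stringsAsFactors = FALSE))
  ckt
}

add_element <- function(ckt, el) {
  ids <- vapply(ckt$elements, `[[`, "", "id")
  if (el$id %in% ids) stop("duplicate element id: ", el$id, call. = FALSE)
  ckt$elements[[length(ckt$elements) + 1L]] <- el
  ckt
}

#' @rdname circuit
#' @param pos,neg endpoint node ids (positive to negative).
#' @param value element value in SI units (Pa*s/m^3, Pa*s^2/m^3, m^3/Pa, Pa
#'   or m^3/s according to kind).
#' @export
add_resistor <- function(ckt, id, pos, neg, value) {
  stopifnot(is.numeric(value), value > 0)
  add_element(ckt, list(kind = "resistor", id = id, pos = pos, neg = neg,
                        value = value))
}

#' @rdname circuit
#' @param series_r resistance in series with the inductor (same branch),
#'   Pa*s/m^3; 0 for a pure inductor.
#' @export
add_inductor <- function(ckt, id, pos, neg, value, series_r = 0) {
  stopifnot(is.numeric(value), value > 0, series_r >= 0)
  add_element(ckt, list(kind = "inductor", id = id, pos = pos, neg = neg,
                        value = value, series_r = series_r))
}

#' @rdname circuit
#' @param law for capacitors: instead of a constant `value`, a capacitance
#'   law created by [cap_law_aorta()], [cap_law_cca()], [cap_law_icp()] or
#'   [cap_law_fun()]; evaluated at the transmural pressure each step.
#' @param external_pressure_ref node id whose pressure offsets the transmural
#'   pressure of a capacitor without receiving its displaced volume.
#' @export
add_capacitor <- function(ckt, id, pos, neg = NULL, value = NULL, law = NULL,
                          external_pressure_ref = NULL) {
  if (is.null(neg)) {
    gi <- ckt$nodes$id[ckt$nodes$is_ground]
    if (length(gi) != 1L) stop("no unique ground node to default 'neg' to",
                               call. = FALSE)
    neg <- gi
  }
  if (is.null(value) == is.null(law)) {
    stop("capacitor needs exactly one of 'value' or 'law'", call. = FALSE)
  }
  if (!is.null(value)) {
    stopifnot(is.numeric(value), value > 0)
    law <- cap_law_const(value)
  }
  if (!is.null(external_pressure_ref)) {
    gi <- ckt$nodes$id[ckt$nodes$is_ground]
    if (!identical(neg, gi)) {
      stop("a capacitor with an external pressure reference must have its ",
           "'neg' endpoint at ground", call. = FALSE)
    }
  }
  add_element(ckt, list(kind = "capacitor", id = id, pos = pos, neg = neg,
                        law = law, ext_ref = external_pressure_ref))
}

#' @rdname circuit
#' @param g_on,g_off forward / reverse conductance, 1/(Pa*s/m^3); `NULL`
#'   defers to the solver configuration defaults.
#' @param smoothing_width pressure width (Pa) of the smooth transition from
#'   blocking to conducting; `NULL` defers to the solver configuration.
#' @export
add_diode <- function(ckt, id, pos, neg, series_r = 0, g_on = NULL,
                      g_off = NULL, smoothing_width = NULL) {
  stopifnot(series_r >= 0)
  add_element(ckt, list(kind = "diode", id = id, pos = pos, neg = neg,
                        series_r = series_r, g_on = g_on, g_off = g_off,
                        width = smoothing_width))
}

#' @rdname circuit
#' @export
add_pressure_source <- function(ckt, id, pos, value) {
  stopifnot(is.numeric(value), length(value) == 1L)
  gi <- ckt$nodes$id[ckt$nodes$is_ground]
  add_element(ckt, list(kind = "pressure_source", id = id, pos = pos,
                        neg = gi, value = value))
}

#' @rdname circuit
#' @export
add_flow_source <- function(ckt, id, pos, neg = NULL, value) {
  if (is.null(neg)) neg <- ckt$nodes$id[ckt$nodes$is_ground]
  stopifnot(is.function(value) || (is.numeric(value) && length(value) == 1L))
  add_element(ckt, list(kind = "flow_source", id = id, pos = pos, neg = neg,
                        value = value))
}

#' @rdname circuit
#' @param track node id whose instantaneous pressure the `pos` node is pinned
#'   to (one-way coupling: flow into `pos` is absorbed by the source).
#' @export
add_tracking_source <- function(ckt, id, pos, track) {
  add_element(ckt, list(kind = "tracking_source", id = id, pos = pos,
                        neg = pos, track = track))
}

#' @rdname circuit
#' @param name probe name.
#' @param type one of `"pressure"` (node pressure), `"flow"` (element flow),
#'   `"transmural"` (capacitor transmural pressure).
#' @param target node id (for pressure) or element id (for flow/transmural).
#' @export
add_probe <- function(ckt, name, type = c("pressure", "flow", "transmural"),
                      target) {
  type <- match.arg(type)
  ckt$probes[[name]] <- list(type = type, target = target)
  ckt
}

# --- capacitance laws ------------------------------------------------------

cap_law_const <- function(value) {
  structure(list(type = "const", value = value), class = "cap_law")
}

#' Capacitance laws for pressure-dependent capacitors
#'
#' Constructors for the nonlinear capacitance laws used by the vascular and
#' intracranial models; pass the result as the `law` argument of
#' [add_capacitor()].  `cap_law_aorta()` and `cap_law_cca()` wrap
#' [aorta_capacitance()] and [cca_capacitance()] (their pressure argument is
#' the element's transmural pressure, converted internally from Pa to mmHg);
#' `cap_law_icp()` wraps [intracranial_capacitance()] (argument in Pa);
#' `cap_law_fun()` wraps an arbitrary `function(P_trans_Pa)` returning m^3/Pa.
#'
#' @param age age in years.
#' @param L_aorta aortic length (m) attributed to this capacitor.
#' @param Amax maximal aortic cross-sectional area, m^2.
#' @param scale multiplicative factor (used to split one anatomical
#'   capacitance across several circuit nodes).
#' @param ratio_cd intracranial capacitance-reduction ratio in (0, 1].
#' @param fun function of transmural pressure in Pa returning m^3/Pa.
#' @return A `cap_law` object.
#' @name cap_law
#' @export
cap_law_aorta <- function(age, L_aorta, Amax = 5.8e-4, scale = 1) {
  check_age(age)
  structure(list(type = "aorta", age = age, L = L_aorta, Amax = Amax,
                 scale = scale), class = "cap_law")
}

#' @rdname cap_law
#' @export
cap_law_cca <- function(age, scale = 1) {
  check_age(age)
  structure(list(type = "cca", age = age, scale = scale), class = "cap_law")
}

#' @rdname cap_law
#' @export
cap_law_icp <- function(ratio_cd = 1) {
  structure(list(type = "icp", ratio_cd = ratio_cd), class = "cap_law")
}

#' @rdname cap_law
#' @export
cap_law_fun <- function(fun) {
  stopifnot(is.function(fun))
  structure(list(type = "fun", fun = fun), class = "cap_law")
}

eval_cap_law <- function(law, p_trans) {
  switch(law$type,
    const = rep_len(law$value, length(p_trans)),
    aorta = law$scale * aorta_capacitance(Pa_to_mmHg(p_trans), law$age, law$L,
                                          law$Amax),
    cca   = law$scale * cca_capacitance(Pa_to_mmHg(p_trans), law$age),
    icp   = intracranial_capacitance(p_trans, law$ratio_cd),
    fun   = law$fun(p_trans),
    stop("unknown capacitance law type: ", law$type)
  )
}

# --- validation ------------------------------------------------------------

#' Validate circuit topology
#'
#' Checks the structural invariants required before assembly: unique ids,
#' exactly one ground node, all element endpoints defined, a connected graph,
#' no loop made exclusively of two-terminal capacitors, and (when the circuit
#' is driven at all) every non-ground node reachable from a source.
#'
#' @param ckt a circuit.
#' @return Invisibly `TRUE`; otherwise an error naming the offending nodes.
#' @export
validate_circuit <- function(ckt) {
  stopifnot(inherits(ckt, "circuit"))
  nd <- ckt$nodes
  if (anyDuplicated(nd$id)) {
    stop("duplicate node ids: ",
         paste(unique(nd$id[duplicated(nd$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (sum(nd$is_ground) != 1L) {
    stop("circuit must have exactly one ground node (found ",
         sum(nd$is_ground), ")", call. = FALSE)
  }
  ends <- unlist(lapply(ckt$elements, function(e) {
    c(e$pos, e$neg, e$ext_ref, e$track)
  }))
  missing <- setdiff(ends, nd$id)
  if (length(missing)) {
    stop("element endpoints reference undefined nodes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # connectivity over all elements
  adj <- lapply(stats::setNames(nm = nd$id), function(i) character())
  link <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b); adj[[b]] <<- c(adj[[b]], a)
  }
  for (e in ckt$elements) {
    link(e$pos, e$neg)
    if (!is.null(e$track)) link(e$pos, e$track)
  }
  if (nrow(nd) > 1L) {
    seen <- bfs_reach(adj, nd$id[1L])
    stray <- setdiff(nd$id, seen)
    if (length(stray)) {
      stop("floating (disconnected) nodes: ", paste(stray, collapse = ", "),
           call. = FALSE)
    }
  }
  # capacitor-only loops (two-terminal capacitors must form a forest)
  cap2 <- Filter(function(e) {
    e$kind == "capacitor" && !nd$is_ground[match(e$neg, nd$id)]
  }, ckt$elements)
  if (length(cap2)) {
    comp <- stats::setNames(seq_len(nrow(nd)), nd$id)
    for (e in cap2) {
      a <- comp[[e$pos]]; b <- comp[[e$neg]]
      if (a == b) {
        stop("capacitor-only loop through nodes ", e$pos, " and ", e$neg,
             call. = FALSE)
      }
      comp[comp == b] <- a
    }
  }
  # source reachability (only meaningful for driven circuits)
  src <- Filter(function(e) e$kind %in%
                  c("pressure_source", "flow_source", "tracking_source"),
                ckt$elements)
  if (length(src)) {
    roots <- unique(c(unlist(lapply(src, `[[`, "pos")),
                      nd$id[nd$is_ground]))
    seen <- bfs_reach(adj, roots)
    stray <- setdiff(nd$id, seen)
    if (length(stray)) {
      stop("nodes not reachable from any source: ",
           paste(stray, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

bfs_reach <- function(adj, roots) {
  seen <- stats::setNames(logical(length(adj)), names(adj))
  queue <- roots
  seen[queue] <- TRUE
  while (length(queue)) {
    nxt <- unique(unlist(adj[queue], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- nxt
  }
  names(seen)[seen]
}

#' @export
print.circuit <- function(x, ...) {
  kinds <- vapply(x$elements, `[[`, "", "kind")
  cat("<circuit> ", nrow(x$nodes), " nodes, ", length(x$elements),
      " elements, ", length(x$probes), " probes\n", sep = "")
  if (length(kinds)) print(table(kinds))
  invisible(x)
}
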