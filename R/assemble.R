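#' Solver configuration
#'
#' Numerical settings for [integrate_circuit()].  Defaults: the `lsoda`
#' stiff/non-stiff switching integrator with relative tolerance 1e-6 and
#' absolute tolerance 1e-8 (SI state units), output sampled at 1 kHz, a
#' smoothed two-conductance diode (fully on above 1 Pa forward bias,
#' conductances 1e-6 / 1e-14 SI) and a 1e-11 m^3/Pa parasitic capacitance
#' that regularises junction nodes carrying no physical compliance.
#'
#' @param method deSolve integrator name.
#' @param rel_tol,abs_tol integration tolerances.
#' @param max_step maximal internal step, s.
#' @param output_rate output sampling rate, Hz.
#' @param diode_on_conductance,diode_off_conductance forward/reverse diode
#'   conductance, 1/(Pa*s/m^3).
#' @param diode_smoothing_width width (Pa) of the smooth on/off transition.
#' @param parasitic_capacitance floor (m^3/Pa) for the total capacitance at
#'   any free node.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(method = "lsoda", rel_tol = 1e-6, abs_tol = 1e-8,
                          max_step = Inf, output_rate = 1000,
                          diode_on_conductance = 1e-6,
                          diode_off_conductance = 1e-14,
                          diode_smoothing_width = 1,
                          parasitic_capacitance = 1e-11) {
  stopifnot(rel_tol > 0, abs_tol > 0, output_rate > 0,
            diode_on_conductance > diode_off_conductance,
            diode_off_conductance > 0, diode_smoothing_width > 0,
            parasitic_capacitance >= 0)
  structure(list(method = method, rel_tol = rel_tol, abs_tol = abs_tol,
                 max_step = max_step, output_rate = output_rate,
                 g_on = diode_on_conductance, g_off = diode_off_conductance,
                 width = diode_smoothing_width,
                 c_floor = parasitic_capacitance),
            class = "solver_config")
}

#' Assemble a circuit into an ODE system
#'
#' Compiles a validated circuit into a state-derivative contract for the
#' stiff integrator.  The state vector holds the pressures of all free nodes
#' (nodes that are neither ground nor pinned by a pressure or tracking
#' source) followed by the flows of all inductors.  At each evaluation the
#' nodal volume balance `M(p) dp/dt = f(p, q, t)` is solved exactly, where
#' `M` collects the (possibly pressure-dependent) capacitances and `f` the
#' resistive, diode, inductive and source flows, so the net flow into every
#' free node balances by construction.
#'
#' @param ckt a circuit (validated with [validate_circuit()]).
#' @param solver a [solver_config()].
#' @return An object of class `ode_system` with the derivative function and
#'   index maps used by [integrate_circuit()].
#' @export
assemble <- function(ckt, solver = solver_config()) {
  validate_circuit(ckt)
  nd <- ckt$nodes
  nn <- nrow(nd)
  idx <- stats::setNames(seq_len(nn), nd$id)

  kinds <- vapply(ckt$elements, `[[`, "", "kind")
  pinned <- integer(0); pin_val <- numeric(0)
  for (e in ckt$elements[kinds == "pressure_source"]) {
    pinned <- c(pinned, idx[[e$pos]]); pin_val <- c(pin_val, e$value)
  }
  trk_pos <- integer(0); trk_tgt <- integer(0)
  for (e in ckt$elements[kinds == "tracking_source"]) {
    trk_pos <- c(trk_pos, idx[[e$pos]]); trk_tgt <- c(trk_tgt, idx[[e$track]])
  }
  if (any(trk_tgt %in% trk_pos)) {
    stop("chained tracking sources are not supported", call. = FALSE)
  }
  ground <- which(nd$is_ground)
  fixed <- c(ground, pinned, trk_pos)
  if (anyDuplicated(fixed)) {
    stop("a node is pinned by more than one source", call. = FALSE)
  }
  free <- setdiff(seq_len(nn), fixed)
  nf <- length(free)
  free_of <- rep(NA_integer_, nn); free_of[free] <- seq_len(nf)

  # flow-carrying elements in fixed order: resistors, diodes, inductors, fsrc
  res <- ckt$elements[kinds == "resistor"]
  dio <- ckt$elements[kinds == "diode"]
  ind <- ckt$elements[kinds == "inductor"]
  fsr <- ckt$elements[kinds == "flow_source"]
  caps <- ckt$elements[kinds == "capacitor"]

  gi <- function(els, fld) {
    vapply(els, function(e) idx[[e[[fld]]]], NA_integer_, USE.NAMES = FALSE)
  }
  gn <- function(els, fld) vapply(els, `[[`, NA_real_, fld)

  r_pos <- gi(res, "pos"); r_neg <- gi(res, "neg")
  r_G <- 1 / gn(res, "value")
  d_pos <- gi(dio, "pos"); d_neg <- gi(dio, "neg")
  d_gon <- vapply(dio, function(e) {
    g <- if (is.null(e$g_on)) solver$g_on else e$g_on
    1 / (1 / g + e$series_r)
  }, 0)
  d_goff <- vapply(dio, function(e) {
    if (is.null(e$g_off)) solver$g_off else e$g_off
  }, 0)
  d_w <- vapply(dio, function(e) {
    if (is.null(e$width)) solver$width else e$width
  }, 0)
  l_pos <- gi(ind, "pos"); l_neg <- gi(ind, "neg")
  l_L <- gn(ind, "value"); l_Rs <- gn(ind, "series_r")
  f_pos <- gi(fsr, "pos"); f_neg <- gi(fsr, "neg")
  f_fun <- lapply(fsr, function(e) {
    if (is.function(e$value)) e$value else local({v <- e$value; function(t) v})
  })
  f_const <- vapply(fsr, function(e) !is.function(e$value), TRUE)

  nl <- length(ind)
  nflow <- length(res) + length(dio) + nl + length(fsr)
  # incidence of flows into free nodes (+ into neg, - out of pos)
  B <- matrix(0, nf, nflow)
  all_pos <- c(r_pos, d_pos, l_pos, f_pos)
  all_neg <- c(r_neg, d_neg, l_neg, f_neg)
  for (j in seq_len(nflow)) {
    ip <- free_of[all_pos[j]]; iq <- free_of[all_neg[j]]
    if (!is.na(ip)) B[ip, j] <- B[ip, j] - 1
    if (!is.na(iq)) B[iq, j] <- B[iq, j] + 1
  }
  # flow sources inject INTO pos: flip their columns
  if (length(fsr)) {
    jj <- nflow - length(fsr) + seq_along(fsr)
    B[, jj] <- -B[, jj, drop = FALSE]
  }

  # capacitors
  c_pos <- gi(caps, "pos")
  c_neg <- gi(caps, "neg")
  c_two <- !nd$is_ground[c_neg]                 # true two-terminal capacitor
  c_ref <- vapply(caps, function(e) {
    if (!is.null(e$ext_ref)) idx[[e$ext_ref]] else NA_integer_
  }, 0L)
  c_law <- lapply(caps, `[[`, "law")
  c_const <- vapply(c_law, function(l) l$type == "const", TRUE)
  c_val0 <- vapply(seq_along(caps), function(j) {
    if (c_const[j]) c_law[[j]]$value else NA_real_
  }, 0)
  # reference node whose derivative enters the row (two-terminal neg or ext ref)
  c_refnode <- ifelse(c_two, c_neg, ifelse(is.na(c_ref), NA_integer_, c_ref))
  # a capacitor endpoint on a tracking node moves with the tracked node
  dyn_of <- seq_len(nn)
  if (length(trk_pos)) dyn_of[trk_pos] <- trk_tgt
  c_pos_dyn <- dyn_of[c_pos]
  c_ref_dyn <- ifelse(is.na(c_refnode), NA_integer_, dyn_of[c_refnode])

  # constant part of the mass matrix
  M0 <- diag(rep(solver$c_floor, nf), nf, nf)
  add_M <- function(M, j, C) {
    ip <- free_of[c_pos_dyn[j]]
    ir <- if (!is.na(c_ref_dyn[j])) free_of[c_ref_dyn[j]] else NA_integer_
    if (!is.na(ip)) {
      M[ip, ip] <- M[ip, ip] + C
      if (!is.na(ir)) M[ip, ir] <- M[ip, ir] - C
    }
    if (c_two[j] && !is.na(ir)) {
      M[ir, ir] <- M[ir, ir] + C
      if (!is.na(ip)) M[ir, ip] <- M[ir, ip] - C
    }
    M
  }
  for (j in which(c_const)) M0 <- add_M(M0, j, c_val0[j])
  j_var <- which(!c_const)

  pressures <- function(p_free, t) {
    P <- numeric(nn)
    if (length(pinned)) P[pinned] <- pin_val
    P[free] <- p_free
    if (length(trk_pos)) P[trk_pos] <- P[trk_tgt]
    P
  }

  diode_g <- function(dp) {
    x <- pmin(pmax(dp / d_w, 0), 1)
    s <- x * x * (3 - 2 * x)
    d_goff + (d_gon - d_goff) * s
  }

  flows <- function(P, q, t) {
    c(r_G * (P[r_pos] - P[r_neg]),
      if (length(dio)) {
        dp <- P[d_pos] - P[d_neg]
        diode_g(dp) * dp
      },
      q,
      vapply(seq_along(fsr), function(k) f_fun[[k]](t), 0))
  }

  rhs <- function(t, y, parms) {
    p_free <- y[seq_len(nf)]
    q <- y[nf + seq_len(nl)]
    P <- pressures(p_free, t)
    Fv <- flows(P, q, t)
    f <- as.vector(B %*% Fv)
    M <- M0
    for (j in j_var) {
      ptr <- P[c_pos[j]] -
        (if (!is.na(c_refnode[j])) P[c_refnode[j]] else 0)
      M <- add_M(M, j, eval_cap_law(c_law[[j]], ptr))
    }
    dp <- solve(M, f)
    dq <- if (nl) (P[l_pos] - P[l_neg] - l_Rs * q) / l_L else numeric(0)
    list(c(dp, dq))
  }

  # compiled evaluator spec (NULL when the circuit needs the R fallback:
  # arbitrary function capacitance laws or non-half-sine function sources)
  cpp_spec <- NULL
  law_ok <- all(vapply(c_law[j_var], function(l) {
    l$type %in% c("aorta", "cca", "icp")
  }, TRUE))
  src_ok <- all(vapply(fsr, function(e) {
    !is.function(e$value) || !is.null(attr(e$value, "halfsine"))
  }, TRUE))
  if (law_ok && src_ok) {
    enc <- lapply(c_law[j_var], function(l) {
      switch(l$type,
        aorta = {
          P0 <- 76 - 0.98 * l$age; P1 <- 57 - 0.44 * l$age
          c(1, l$scale * l$Amax * l$L / (pi * P1 * 133.322), P0, P1)
        },
        cca = c(2, l$scale * (1.3 - 0.012 * (l$age - 20)) * 3.14 * 1e-6 /
                  133.322, 0.018, 0),
        icp = c(3, l$ratio_cd, 0, 0))
    })
    enc <- do.call(rbind, c(enc, list(matrix(0, 0, 4))))
    fpar <- t(vapply(fsr, function(e) {
      if (is.function(e$value)) unname(attr(e$value, "halfsine"))
      else c(e$value, 0, 0)
    }, numeric(3)))
    if (length(fsr) == 0L) fpar <- matrix(0, 0, 3)
    as0 <- function(x) as.integer(x) - 1L   # 1-based -> 0-based
    fo0 <- function(x) {                    # free index or -1
      ifelse(is.na(x) | is.na(free_of[x]), -1L, free_of[x] - 1L)
    }
    cpp_spec <- list(
      nn = nn, nf = nf, nl = nl,
      pinned = as0(pinned), pin_val = pin_val,
      trk_pos = as0(trk_pos), trk_tgt = as0(trk_tgt),
      free_idx = as0(free),
      rpos = as0(r_pos), rneg = as0(r_neg), rG = r_G,
      dpos = as0(d_pos), dneg = as0(d_neg),
      dgon = d_gon, dgoff = d_goff, dw = d_w,
      lpos = as0(l_pos), lneg = as0(l_neg), lL = l_L, lRs = l_Rs,
      ftype = vapply(fsr, function(e) {
        if (is.function(e$value)) 1L else 0L
      }, 0L),
      fpar = fpar, B = B, M0 = M0,
      cpos = as0(c_pos[j_var]),
      cref = ifelse(is.na(c_refnode[j_var]), -1L,
                    as.integer(c_refnode[j_var]) - 1L),
      claw = as.integer(enc[, 1]),
      cfree_pos = fo0(c_pos_dyn[j_var]),
      cfree_ref = fo0(c_ref_dyn[j_var]),
      ctwo = as.integer(c_two[j_var]),
      cpar = enc[, -1, drop = FALSE])
  }

  structure(list(ckt = ckt, solver = solver, rhs = rhs, cpp_spec = cpp_spec,
                 pressures = pressures, flows = flows,
                 n_free = nf, n_ind = nl, n_nodes = nn,
                 free = free, pinned = pinned, pin_val = pin_val,
                 trk_pos = trk_pos, trk_tgt = trk_tgt,
                 node_ids = nd$id,
                 free_ids = nd$id[free],
                 ind_ids = vapply(ind, `[[`, "", "id"),
                 flow_ids = c(vapply(res, `[[`, "", "id"),
                              vapply(dio, `[[`, "", "id"),
                              vapply(ind, `[[`, "", "id"),
                              vapply(fsr, `[[`, "", "id")),
                 cap_ids = vapply(caps, `[[`, "", "id"),
                 cap_pos = c_pos, cap_refnode = c_refnode, cap_law = c_law,
                 ind_pos = l_pos, ind_neg = l_neg, ind_L = l_L),
            class = "ode_system")
}

#' Integrate a circuit in time
#'
#' Runs the stiff integrator over `t_span` and returns every probe declared
#' on the circuit as a uniformly sampled time series.  Integration is fully
#' deterministic: identical inputs give bit-identical output.
#'
#' @param ckt a circuit with probes (see [add_probe()]).
#' @param solver a [solver_config()].
#' @param t_span length-2 numeric, start and end time (s).
#' @param init named numeric vector of initial node pressures in Pa (matched
#'   by node id; unlisted free nodes start at 0); inductor flows start at 0.
#' @return A list of class `circuit_run`: `probes` (named list of
#'   [timeseries()] objects), `diagnostics` (integrator stats), and the
#'   assembled system.
#' @export
integrate_circuit <- function(ckt, solver = solver_config(),
                              t_span = c(0, 1), init = NULL) {
  sys <- if (inherits(ckt, "ode_system")) ckt else assemble(ckt, solver)
  solver <- sys$solver
  stopifnot(length(t_span) == 2L, all(is.finite(t_span)),
            t_span[2] > t_span[1])
  y0 <- numeric(sys$n_free + sys$n_ind)
  if (!is.null(init)) {
    hit <- match(names(init), sys$free_ids)
    y0[hit[!is.na(hit)]] <- init[!is.na(hit)]
  }
  times <- seq(t_span[1], t_span[2], by = 1 / solver$output_rate)
  if (length(y0) == 0L) {
    # purely algebraic circuit (no capacitors or inductors): nothing to integrate
    states <- matrix(0, length(times), 0)
    probes <- eval_probes(sys, times, states)
    return(structure(list(probes = probes, times = times, states = states,
                          system = sys, diagnostics = NULL),
                     class = "circuit_run"))
  }
  func <- sys$rhs
  if (!is.null(sys$cpp_spec)) {
    ptr <- circuit_model_new(sys$cpp_spec)
    func <- function(t, y, parms) list(circuit_model_rhs(ptr, t, y))
  }
  out <- try(deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                          method = solver$method, rtol = solver$rel_tol,
                          atol = solver$abs_tol, hmax = solver$max_step),
             silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    last_t <- if (inherits(out, "try-error")) NA_real_ else out[nrow(out), 1]
    stop("integrator failure (step-size collapse); last accepted time: ",
         format(last_t), call. = FALSE)
  }
  diag <- attributes(out)[c("istate", "rstate")]
  states <- unclass(out)[, -1, drop = FALSE]
  probes <- eval_probes(sys, times, states)
  structure(list(probes = probes, times = times, states = states,
                 system = sys, diagnostics = diag),
            class = "circuit_run")
}

# full node-pressure matrix (nt x nn) from the state matrix
pressure_matrix <- function(sys, states) {
  nt <- nrow(states)
  P <- matrix(0, nt, sys$n_nodes)
  if (length(sys$pinned)) {
    P[, sys$pinned] <- matrix(sys$pin_val, nt, length(sys$pinned),
                              byrow = TRUE)
  }
  P[, sys$free] <- states[, seq_len(sys$n_free), drop = FALSE]
  if (length(sys$trk_pos)) P[, sys$trk_pos] <- P[, sys$trk_tgt, drop = FALSE]
  P
}

eval_probes <- function(sys, times, states) {
  P <- pressure_matrix(sys, states)
  q <- states[, sys$n_free + seq_len(sys$n_ind), drop = FALSE]
  out <- list()
  for (nm in names(sys$ckt$probes)) {
    pr <- sys$ckt$probes[[nm]]
    v <- switch(pr$type,
      pressure = {
        j <- match(pr$target, sys$node_ids)
        if (is.na(j)) stop("probe '", nm, "': unknown node ", pr$target,
                           call. = FALSE)
        P[, j]
      },
      flow = probe_flow(sys, pr$target, P, q, times),
      transmural = {
        j <- match(pr$target, sys$cap_ids)
        if (is.na(j)) stop("probe '", nm, "': unknown capacitor ", pr$target,
                           call. = FALSE)
        ref <- sys$cap_refnode[j]
        P[, sys$cap_pos[j]] - (if (!is.na(ref)) P[, ref] else 0)
      })
    unit <- if (pr$type == "flow") "m3_per_s" else "Pa"
    out[[nm]] <- timeseries(times, v, unit)
  }
  out
}

probe_flow <- function(sys, target, P, q, times) {
  els <- sys$ckt$elements
  ids <- vapply(els, `[[`, "", "id")
  e <- els[[match(target, ids)]]
  if (is.null(e)) stop("probe target not found: ", target, call. = FALSE)
  idx <- stats::setNames(seq_len(sys$n_nodes), sys$node_ids)
  dp <- P[, idx[[e$pos]]] - P[, idx[[e$neg]]]
  solver <- sys$solver
  switch(e$kind,
    resistor = dp / e$value,
    diode = {
      g_on <- if (is.null(e$g_on)) solver$g_on else e$g_on
      g_on <- 1 / (1 / g_on + e$series_r)
      g_off <- if (is.null(e$g_off)) solver$g_off else e$g_off
      w <- if (is.null(e$width)) solver$width else e$width
      x <- pmin(pmax(dp / w, 0), 1)
      (g_off + (g_on - g_off) * x * x * (3 - 2 * x)) * dp
    },
    inductor = q[, match(target, sys$ind_ids)],
    flow_source = {
      if (is.function(e$value)) vapply(times, e$value, 0)
      else rep_len(e$value, length(times))
    },
    stop("flow probe unsupported for element kind ", e$kind, call. = FALSE))
}

#' Check passivity of an undriven trajectory
#'
#' For a circuit whose sources are all zero, the total stored energy
#' \eqn{\sum \frac{1}{2} C P_{trans}^2 + \sum \frac{1}{2} L q^2} must be
#' non-increasing between output samples (dissipation only).  Driven circuits
#' are refused.
#'
#' @param run a `circuit_run` from [integrate_circuit()].
#' @param tol relative tolerance on energy increase between samples.
#' @return A list with the energy trace, a logical vector of violations and
#'   `passive` (TRUE if no violation).
#' @export
check_passivity <- function(run, tol = 1e-6) {
  sys <- run$system
  active <- Filter(function(e) {
    (e$kind == "pressure_source" && e$value != 0) ||
      (e$kind == "flow_source" &&
         (is.function(e$value) || e$value != 0)) ||
      e$kind == "tracking_source"
  }, sys$ckt$elements)
  if (length(active)) {
    stop("check_passivity requires all sources to be zero", call. = FALSE)
  }
  P <- pressure_matrix(sys, run$states)
  q <- run$states[, sys$n_free + seq_len(sys$n_ind), drop = FALSE]
  E <- numeric(nrow(P))
  for (j in seq_along(sys$cap_law)) {
    ref <- sys$cap_refnode[j]
    ptr <- P[, sys$cap_pos[j]] - (if (!is.na(ref)) P[, ref] else 0)
    E <- E + 0.5 * eval_cap_law(sys$cap_law[[j]], ptr) * ptr^2
  }
  for (j in seq_along(sys$ind_L)) E <- E + 0.5 * sys$ind_L[j] * q[, j]^2
  dE <- diff(E)
  viol <- dE > tol * pmax(E[-length(E)], .Machine$double.eps)
  list(energy = E, violations = viol, passive = !any(viol))
}

#' Uniformly sampled time series
#'
#' @param t strictly increasing, uniformly spaced sample times (s).
#' @param v sample values.
#' @param unit unit string (`"Pa"`, `"m3_per_s"`, `"mmHg"`, ...).
#' @return An object of class `icp_ts`.
#' @export
timeseries <- function(t, v, unit = "Pa") {
  stopifnot(length(t) == length(v), length(t) >= 2L)
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9) {
    stop("time base must be strictly increasing and uniform to 1e-9 s",
         call. = FALSE)
  }
  structure(list(t = as.numeric(t), v = as.numeric(v), unit = unit),
            class = "icp_ts")
}

#' @export
print.icp_ts <- function(x, ...) {
  cat("<timeseries> ", length(x$t), " samples @ ",
      format(1 / (x$t[2] - x$t[1])), " Hz, unit ", x$unit,
      ", range [", format(min(x$v)), ", ", format(max(x$v)), "]\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.icp_ts <- function(x, ...) data.frame(t = x$t, v = x$v)

#' Export a time series to CSV
#'
#' Writes two columns with the header `t_s,<name>_<unit>`, 9 significant
#' digits, locale-independent.
#'
#' @param ts a [timeseries()].
#' @param name probe name used in the header.
#' @param file output path.
#' @export
write_timeseries <- function(ts, name, file) {
  header <- paste0("t_s,", name, "_", ts$unit)
  lines <- paste(formatC(ts$t, digits = 9, format = "g"),
                 formatC(ts$v, digits = 9, format = "g"), sep = ",")
  writeLines(c(header, lines), file)
  invisible(file)
}

# convert a pressure timeseries to mmHg for display/export
ts_to_mmHg <- function(ts) {
  stopifnot(ts$unit == "Pa")
  timeseries(ts$t, Pa_to_mmHg(ts$v), "mmHg")
}
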