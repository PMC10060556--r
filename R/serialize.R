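#' Serialise circuits to a structured text format
#'
#' Writes a circuit as plain text, one record per line with stable field
#' names (`node`, `element`, `probe`), e.g.
#' `element kind=resistor id=R1 pos=n1 neg=ground value=1`.  Capacitance
#' laws are stored by type and parameters; function-valued flow sources are
#' stored by their half-sine parameters when available and are otherwise an
#' error (arbitrary closures have no text form).  `read_circuit()` restores
#' an equivalent circuit.
#'
#' @param ckt a circuit.
#' @param file path to write to / read from.
#' @return `write_circuit()` the path, invisibly; `read_circuit()` a
#'   circuit.
#' @export
write_circuit <- function(ckt, file) {
  stopifnot(inherits(ckt, "circuit"))
  kv <- function(...) {
    x <- c(...)
    paste(names(x), unname(x), sep = "=", collapse = " ")
  }
  lines <- character(0)
  for (i in seq_len(nrow(ckt$nodes))) {
    nd <- ckt$nodes[i, ]
    lines <- c(lines, paste("node", kv(id = nd$id, ground = nd$is_ground,
                                       label = gsub(" ", "_", nd$label))))
  }
  fmt <- function(x) sprintf("%.17g", x)
  for (e in ckt$elements) {
    fields <- c(kind = e$kind, id = e$id, pos = e$pos, neg = e$neg)
    fields <- c(fields, switch(e$kind,
      resistor = c(value = fmt(e$value)),
      inductor = c(value = fmt(e$value), series_r = fmt(e$series_r)),
      capacitor = {
        l <- e$law
        law_fields <- switch(l$type,
          const = c(law = "const", value = fmt(l$value)),
          aorta = c(law = "aorta", age = fmt(l$age), L = fmt(l$L),
                    Amax = fmt(l$Amax), scale = fmt(l$scale)),
          cca = c(law = "cca", age = fmt(l$age), scale = fmt(l$scale)),
          icp = c(law = "icp", ratio_cd = fmt(l$ratio_cd)),
          stop("cannot serialise a function-valued capacitance law",
               call. = FALSE))
        if (!is.null(e$ext_ref)) {
          law_fields <- c(law_fields, external_pressure_ref = e$ext_ref)
        }
        law_fields
      },
      diode = c(series_r = fmt(e$series_r),
                if (!is.null(e$g_on)) c(g_on = fmt(e$g_on)),
                if (!is.null(e$g_off)) c(g_off = fmt(e$g_off)),
                if (!is.null(e$width)) c(width = fmt(e$width))),
      pressure_source = c(value = fmt(e$value)),
      flow_source = {
        if (is.function(e$value)) {
          hs <- attr(e$value, "halfsine")
          if (is.null(hs)) {
            stop("cannot serialise an arbitrary function-valued flow source",
                 call. = FALSE)
          }
          c(shape = "halfsine", T = fmt(hs[["T"]]), sv = fmt(hs[["sv"]]),
            sf = fmt(hs[["sf"]]))
        } else c(value = fmt(e$value))
      },
      tracking_source = c(track = e$track),
      stop("unknown element kind: ", e$kind)))
    lines <- c(lines, paste("element", kv(fields)))
  }
  for (nm in names(ckt$probes)) {
    pr <- ckt$probes[[nm]]
    lines <- c(lines, paste("probe", kv(name = nm, type = pr$type,
                                        target = pr$target)))
  }
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  ck <- circuit()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    rec <- parts[1]
    f <- strsplit(parts[-1], "=", fixed = TRUE)
    v <- stats::setNames(vapply(f, `[`, "", 2), vapply(f, `[`, "", 1))
    num <- function(k) as.numeric(v[[k]])
    if (rec == "node") {
      ck <- add_node(ck, v[["id"]], gsub("_", " ", v[["label"]]),
                     ground = as.logical(v[["ground"]]))
    } else if (rec == "element") {
      ck <- switch(v[["kind"]],
        resistor = add_resistor(ck, v[["id"]], v[["pos"]], v[["neg"]],
                                num("value")),
        inductor = add_inductor(ck, v[["id"]], v[["pos"]], v[["neg"]],
                                num("value"), series_r = num("series_r")),
        capacitor = {
          law <- switch(v[["law"]],
            const = cap_law_const(num("value")),
            aorta = cap_law_aorta(num("age"), num("L"), num("Amax"),
                                  num("scale")),
            cca = cap_law_cca(num("age"), num("scale")),
            icp = cap_law_icp(num("ratio_cd")))
          add_capacitor(ck, v[["id"]], v[["pos"]], neg = v[["neg"]],
                        law = law,
                        external_pressure_ref =
                          if ("external_pressure_ref" %in% names(v)) {
                            v[["external_pressure_ref"]]
                          })
        },
        diode = add_diode(ck, v[["id"]], v[["pos"]], v[["neg"]],
                          series_r = num("series_r"),
                          g_on = if ("g_on" %in% names(v)) num("g_on"),
                          g_off = if ("g_off" %in% names(v)) num("g_off"),
                          smoothing_width =
                            if ("width" %in% names(v)) num("width")),
        pressure_source = add_pressure_source(ck, v[["id"]], v[["pos"]],
                                              num("value")),
        flow_source = {
          if (identical(unname(v["shape"]), "halfsine")) {
            add_flow_source(ck, v[["id"]], v[["pos"]], v[["neg"]],
                            inflow_closure(num("T"), num("sv"), num("sf")))
          } else {
            add_flow_source(ck, v[["id"]], v[["pos"]], v[["neg"]],
                            num("value"))
          }
        },
        tracking_source = add_tracking_source(ck, v[["id"]], v[["pos"]],
                                              v[["track"]]),
        stop("unknown element kind in file: ", v[["kind"]]))
    } else if (rec == "probe") {
      ck <- add_probe(ck, v[["name"]], v[["type"]], v[["target"]])
    } else stop("unknown record type: ", rec)
  }
  ck
}
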