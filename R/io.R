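# Configuration (YAML) and snapshot (JSON / SVG) input-output.

#' Load a simulation configuration from YAML
#'
#' The document may contain a `params` mapping (fields of [leaf_params()]),
#' a `rules` sequence (fields of [morphogen_rule()]), and either a `preset`
#' name or a `primordium` mapping (`length`, `half_width`, `n`, `morphogens`:
#' morphogen name -> list of `[lo, hi]` fractional arc ranges). Unknown
#' fields and morphogen names without rules are rejected with the offending
#' field named.
#'
#' @param path Path to a YAML file.
#' @return A list with `params` and `primordium`.
#' @export
load_leaf_config <- function(path) {
  doc <- yaml::read_yaml(path)
  bad_fields <- function(got, allowed, where) {
    extra <- setdiff(names(got), allowed)
    if (length(extra)) {
      stop("unknown field(s) in ", where, ": ", paste(extra, collapse = ", "))
    }
  }
  rules <- list()
  if (!is.null(doc$rules)) {
    rule_args <- names(formals(morphogen_rule))
    rules <- lapply(seq_along(doc$rules), function(k) {
      r <- doc$rules[[k]]
      bad_fields(r, rule_args, sprintf("rules[%d]", k))
      if (!is.null(r$max_age) && identical(r$max_age, "Inf")) r$max_age <- Inf
      do.call(morphogen_rule, r)
    })
  }
  pargs <- list()
  if (!is.null(doc$params)) {
    par_fields <- setdiff(names(formals(leaf_params)), "rules")
    bad_fields(doc$params, par_fields, "params")
    pargs <- doc$params
    if (!is.null(pargs$rerg)) {
      rp <- pargs$rerg
      pargs$rerg <- if (is.character(rp) && rp == "uniform") {
        rerg_profile(0, 1)
      } else {
        rerg_profile(vapply(rp, `[[`, 0, 1), vapply(rp, `[[`, 0, 2))
      }
    }
    for (f in c("max_base_distance", "max_age")) {
      if (!is.null(pargs$competence[[f]]) && identical(pargs$competence[[f]], "Inf")) {
        pargs$competence[[f]] <- Inf
      }
    }
  }
  params <- do.call(leaf_params, c(pargs, list(rules = rules)))
  if (!is.null(doc$preset)) {
    primordium <- leaf_preset(doc$preset)$primordium
  } else if (!is.null(doc$primordium)) {
    pd <- doc$primordium
    bad_fields(pd, c("length", "half_width", "n", "morphogens"), "primordium")
    mor <- lapply(pd$morphogens, function(rgs) lapply(rgs, as.numeric))
    unknown <- setdiff(names(mor), names(params$rules))
    if (length(unknown)) {
      stop("primordium.morphogens: no rule declared for: ",
           paste(unknown, collapse = ", "))
    }
    primordium <- primordium_outline(
      length = pd$length %||% 1, half_width = pd$half_width %||% 0.25,
      n = pd$n %||% 21, morphogens = mor
    )
  } else {
    primordium <- primordium_outline()
  }
  list(params = params, primordium = primordium)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration to YAML
#'
#' Round trip: writing a configuration and loading it back reproduces the
#' parameter set exactly.
#'
#' @param params A [leaf_params()].
#' @param primordium A primordium description (only outlines produced by
#'   [primordium_outline()] carry enough structure to serialize; custom
#'   outlines should be saved by the caller).
#' @param path Output path.
#' @export
write_leaf_config <- function(params, primordium = NULL, path) {
  ser_inf <- function(x) if (is.infinite(x)) "Inf" else x
  p <- params
  doc <- list(params = list(
    dt = p$dt, lambda = p$lambda, delta = p$delta, tip_growth = p$tip_growth,
    rerg = mapply(function(s, r) c(s, r), p$rerg$breakpoints, p$rerg$rates,
                  SIMPLIFY = FALSE),
    iso_rate = p$iso_rate, margin_rate = p$margin_rate,
    b = p$b, v = p$v, sigma_max = p$sigma_max,
    webbing = p$webbing,
    competence = list(max_base_distance = ser_inf(p$competence$max_base_distance),
                      max_age = ser_inf(p$competence$max_age)),
    h_max = p$h_max, h_min = p$h_min, n_steps = p$n_steps,
    mesh_every = p$mesh_every
  ))
  if (length(p$rules)) {
    doc$rules <- lapply(unname(p$rules), function(r) {
      r <- unclass(r)
      r$max_age <- ser_inf(r$max_age)
      r
    })
  }
  if (!is.null(primordium)) {
    out <- primordium$outline
    doc$primordium <- list(
      length = max(out[, 2]), half_width = max(abs(out[, 1])), n = nrow(out),
      morphogens = lapply(primordium$morphogens, function(rgs) lapply(rgs, as.numeric))
    )
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Write a leaf state snapshot
#'
#' JSON snapshots carry the complete state (margin attributes, vein
#' segments, optional mesh) and are bit-reproducible for identical runs. SVG
#' snapshots contain one path for the margin, one line per vein segment and
#' an optional mesh layer.
#'
#' @param state A `leaf_state`.
#' @param path Output path.
#' @param format `"json"`, `"svg"`, or `"off"` (the blade mesh as a plain
#'   Object File Format text file; requires a meshed state).
#' @param mesh Include the mesh layer (if the state carries one).
#' @export
write_snapshot <- function(state, path, format = c("json", "svg", "off"), mesh = FALSE) {
  format <- match.arg(format)
  if (format == "off") {
    if (is.null(state$mesh)) stop("state carries no mesh; run triangulate_blade() first")
    v <- state$mesh$vertices
    tr <- state$mesh$triangles
    writeLines(c(
      "OFF",
      sprintf("%d %d 0", nrow(v), nrow(tr)),
      sprintf("%.10g %.10g 0", v[, 1], v[, 2]),
      sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L)
    ), path)
    return(invisible(path))
  }
  if (format == "json") {
    doc <- list(
      step = state$step, age = state$age,
      margin = list(
        pos = unname(state$margin$pos),
        is_cp = state$margin$is_cp,
        vein_id = state$margin$vein_id,
        birth_step = state$margin$birth_step,
        barrier = state$margin$barrier,
        morphogens = as.list(as.data.frame(state$margin$morph))
      ),
      veins = list(base = state$veins$base, segments = state$veins$segs)
    )
    if (mesh && !is.null(state$mesh)) {
      doc$mesh <- list(vertices = unname(state$mesh$vertices),
                       triangles = unname(state$mesh$triangles),
                       role = state$mesh$role)
    }
    jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, pretty = FALSE)
  } else {
    write_svg_snapshot(state, path, mesh = mesh)
  }
  invisible(path)
}

write_svg_snapshot <- function(state, path, mesh = FALSE) {
  p <- state$margin$pos
  rng <- apply(p, 2, range)
  pad <- 0.05 * max(rng[2, ] - rng[1, ], 1e-9)
  vb <- sprintf("%g %g %g %g", rng[1, 1] - pad, -(rng[2, 2] + pad),
                diff(rng[, 1]) + 2 * pad, diff(rng[, 2]) + 2 * pad)
  fmt <- function(x, y) sprintf("%.6g,%.6g", x, -y)
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="%s">', vb),
    sprintf('<g stroke-width="%.6g" fill="none">', 0.004 * max(rng[2, ] - rng[1, ]))
  )
  if (mesh && !is.null(state$mesh)) {
    v <- state$mesh$vertices
    tr <- state$mesh$triangles
    tri_paths <- vapply(seq_len(nrow(tr)), function(k) {
      q <- v[tr[k, ], , drop = FALSE]
      sprintf("M %s L %s L %s Z", fmt(q[1, 1], q[1, 2]), fmt(q[2, 1], q[2, 2]),
              fmt(q[3, 1], q[3, 2]))
    }, "")
    lines <- c(lines, sprintf('<path class="mesh" stroke="#9ed89e" d="%s"/>',
                              paste(tri_paths, collapse = " ")))
  }
  margin_d <- paste0("M ", paste(fmt(p[, 1], p[, 2]), collapse = " L "), " Z")
  lines <- c(lines, sprintf('<path class="margin" stroke="#000" d="%s"/>', margin_d))
  segs <- state$veins$segs
  lines <- c(lines, vapply(seq_len(nrow(segs)), function(k) {
    sprintf('<line class="vein" stroke="#4682b4" x1="%.6g" y1="%.6g" x2="%.6g" y2="%.6g"/>',
            segs$x0[k], -segs$y0[k], segs$x1[k], -segs$y1[k])
  }, ""))
  lines <- c(lines, "</g>", "</svg>")
  writeLines(lines, path)
  invisible(path)
}
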