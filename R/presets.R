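# Packaged preset configurations reproducing the qualitative leaf-form
# repertoire: a simple cordate leaf, compound marginal teeth, palmately lobed
# leaves (with and without higher-order lobes), and a pinnately compound
# leaf. Parameter values are the package's own calibration; they were chosen
# to reproduce the published morphologies qualitatively.

#' Packaged simulation presets
#'
#' @param name One of `"simple-cordate"`, `"compound-teeth"`,
#'   `"palmate-lobed"`, `"palmate-simple-lobes"`, `"pinnate-compound"`; or
#'   missing to list the available names.
#' @return A list with `params` ([leaf_params()]) and `primordium` (see
#'   [make_primordium()]).
#' @export
leaf_preset <- function(name) {
  presets <- list(
    "simple-cordate" = preset_simple_cordate,
    "compound-teeth" = preset_compound_teeth,
    "palmate-lobed" = preset_palmate_lobed,
    "palmate-simple-lobes" = preset_palmate_simple_lobes,
    "pinnate-compound" = preset_pinnate_compound
  )
  if (missing(name)) return(names(presets))
  f <- presets[[name]]
  if (is.null(f)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  f()
}

petiole_rule <- function() {
  morphogen_rule("petiole", blocks_cp = TRUE, growth_factor = 0)
}

preset_simple_cordate <- function() {
  params <- leaf_params(
    dt = 0.015, lambda = 1.5, delta = 0.3,
    tip_growth = 0.012, rerg = rerg_profile(0, 0.75), iso_rate = 0,
    margin_rate = 0.45, b = 2, v = 1, sigma_max = 75,
    webbing = list(stretch = 1, bend = 2, iterations = 12, relax = 0.1),
    rules = list(petiole_rule()),
    n_steps = 200
  )
  prim <- primordium_outline(length = 1, half_width = 0.25, n = 25,
                             morphogens = list(petiole = list(c(0, 0.06), c(0.94, 1))))
  list(params = params, primordium = prim)
}

preset_compound_teeth <- function() {
  params <- leaf_params(
    dt = 0.02, lambda = 1.5, delta = 0.25,
    tip_growth = 0.012, rerg = rerg_profile(0, 0.3), iso_rate = 0.3,
    margin_rate = 0.35, b = 2, v = 1, sigma_max = 75,
    webbing = list(stretch = 1, bend = 1, iterations = 6, relax = 0.05),
    rules = list(petiole_rule()),
    n_steps = 150
  )
  prim <- primordium_outline(length = 1, half_width = 0.25, n = 25,
                             morphogens = list(petiole = list(c(0, 0.06), c(0.94, 1))))
  list(params = params, primordium = prim)
}

preset_palmate_lobed <- function() {
  sinus <- morphogen_rule("sinus", blocks_cp = TRUE, webbing_factor = 0.5,
                          growth_factor = 0,
                          rho_r = 0.45, rho_bmin = 0.55, rho_bmax = 0.95)
  params <- leaf_params(
    dt = 0.02, lambda = 1.5, delta = 0.3,
    tip_growth = 0.018, rerg = rerg_profile(0, 0.5), iso_rate = 0.1,
    margin_rate = 0.45, b = 2, v = 1, sigma_max = 75,
    webbing = list(stretch = 1, bend = 1, iterations = 10, relax = 0.08),
    rules = list(petiole_rule(), sinus),
    n_steps = 130
  )
  prim <- primordium_outline(length = 1, half_width = 0.25, n = 25,
                             morphogens = list(petiole = list(c(0, 0.06), c(0.94, 1)),
                                               sinus = list(c(0.07, 0.2), c(0.8, 0.93))))
  list(params = params, primordium = prim)
}

preset_palmate_simple_lobes <- function() {
  sinus <- morphogen_rule("sinus", blocks_cp = TRUE, webbing_factor = 0.5,
                          growth_factor = 0,
                          metric_factor = 0.6,
                          rho_r = 0.45, rho_bmin = 0.55, rho_bmax = 0.95,
                          max_age = 1.2)
  params <- leaf_params(
    dt = 0.02, lambda = 1.5, delta = 0.3,
    tip_growth = 0.018, rerg = rerg_profile(0, 0.5), iso_rate = 0.1,
    margin_rate = 0.45, b = 2, v = 1, sigma_max = 75,
    webbing = list(stretch = 1, bend = 1, iterations = 10, relax = 0.08),
    rules = list(petiole_rule(), sinus),
    n_steps = 130
  )
  prim <- primordium_outline(length = 1, half_width = 0.25, n = 25,
                             morphogens = list(petiole = list(c(0, 0.06), c(0.94, 1)),
                                               sinus = list(c(0.07, 0.2), c(0.8, 0.93))))
  list(params = params, primordium = prim)
}

preset_pinnate_compound <- function() {
  rachis <- morphogen_rule("rachis", blocks_cp = TRUE, is_barrier = TRUE,
                           webbing_factor = 0.05, growth_factor = 0)
  params <- leaf_params(
    dt = 0.02, lambda = 1.2, delta = 0.25,
    tip_growth = 0.012, rerg = rerg_profile(0, 0.4), iso_rate = 0,
    margin_rate = 0.3, b = 2, v = 1, sigma_max = 75,
    webbing = list(stretch = 1, bend = 2, iterations = 10, relax = 0.1),
    rules = list(petiole_rule(), rachis),
    h_max = 0.12, h_min = 0.03,
    n_steps = 130
  )
  prim <- primordium_outline(length = 3, half_width = 0.5, n = 61,
                             morphogens = list(
                               petiole = list(c(0, 0.04), c(0.96, 1)),
                               rachis = list(c(0.16, 0.22), c(0.36, 0.42),
                                             c(0.58, 0.64), c(0.78, 0.84))))
  list(params = params, primordium = prim)
}
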