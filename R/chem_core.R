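#' Metal ions handled by the calculators
#'
#' The six exchangeable cytosolic metals for which sensors and availability
#' presets exist, in Irving-Williams presentation order. Copper is modelled
#' exclusively as Cu+, the predominant cytosolic oxidation state.
#'
#' @return Character vector of metal symbols:
#'   `"Mn2+", "Fe2+", "Co2+", "Ni2+", "Zn2+", "Cu1+"`.
#' @examples
#' metal_ions()
#' @export
metal_ions <- function() {
  c("Mn2+", "Fe2+", "Co2+", "Ni2+", "Zn2+", "Cu1+")
}

#' Display labels for metal symbols
#'
#' @param metal character vector of metal symbols as in [metal_ions()].
#' @return Character vector of human-readable labels (unicode superscripts).
#' @export
metal_label <- function(metal) {
  labs <- c(
    "Mn2+" = "Mn²⁺", "Fe2+" = "Fe²⁺",
    "Co2+" = "Co²⁺", "Ni2+" = "Ni²⁺",
    "Zn2+" = "Zn²⁺", "Cu1+" = "Cu⁺"
  )
  assert_metal(metal)
  unname(labs[metal])
}

assert_metal <- function(metal) {
  bad <- setdiff(metal, metal_ions())
  if (length(bad)) {
    stop("unknown metal symbol(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(metal_ions(), collapse = ", "),
         call. = FALSE)
  }
  invisible(metal)
}

#' Thermodynamic constants
#'
#' Gas constant and temperature used in every free-energy conversion.
#' Defaults are R = 8.314e-3 kJ K^-1 mol^-1 and T = 298.15 K; both can be
#' overridden explicitly, e.g. for sensitivity analysis at growth temperature.
#'
#' @param R gas constant in kJ K^-1 mol^-1.
#' @param T absolute temperature in K.
#' @return An object of class `"thermo_constants"`: a list with elements
#'   `R`, `T` and their product `RT` (kJ mol^-1).
#' @examples
#' thermo_constants()$RT
#' @export
thermo_constants <- function(R = 8.314e-3, T = 298.15) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R), R > 0,
            is.numeric(T), length(T) == 1L, is.finite(T), T > 0)
  structure(list(R = R, T = T, RT = R * T), class = "thermo_constants")
}

#' Free energy of a buffered metal concentration (or dissociation constant)
#'
#' Converts a molar concentration to the free energy of forming a metal
#' complex that is half-saturated at that concentration:
#' `delta G = RT ln c` (kJ mol^-1). Applied to a buffered available metal
#' concentration it gives the availability free energy; applied to a
#' dissociation constant K_D it gives the free energy of forming the
#' half-saturated protein complex (identical to -RT ln K_A since
#' K_A = 1/K_D).
#'
#' @param concentration molar concentration(s), strictly positive and finite.
#' @param constants a [thermo_constants()] object.
#' @return Free energy in kJ mol^-1 (negative for concentrations below 1 M).
#' @examples
#' delta_g(4.5e-20)   # aerobic Cu+ availability, about -110.4 kJ/mol
#' @export
delta_g <- function(concentration, constants = thermo_constants()) {
  stopifnot(inherits(constants, "thermo_constants"))
  if (!is.numeric(concentration) || any(!is.finite(concentration)) ||
      any(concentration <= 0)) {
    stop("concentration must be finite and strictly positive (molar)",
         call. = FALSE)
  }
  constants$RT * log(concentration)
}

#' Concentration corresponding to a free energy
#'
#' Inverse of [delta_g()]: `c = exp(g / RT)`. Round-trips with [delta_g()]
#' to floating-point tolerance.
#'
#' @param g free energy in kJ mol^-1, finite.
#' @param constants a [thermo_constants()] object.
#' @return Molar concentration(s).
#' @export
delta_g_to_concentration <- function(g, constants = thermo_constants()) {
  stopifnot(inherits(constants, "thermo_constants"))
  if (!is.numeric(g) || any(!is.finite(g))) {
    stop("free energy must be finite (kJ mol^-1)", call. = FALSE)
  }
  out <- exp(g / constants$RT)
  if (any(!is.finite(out))) {
    stop("free energy ", max(g), " kJ mol^-1 overflows to a non-finite ",
         "concentration", call. = FALSE)
  }
  out
}
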