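#' Metal descriptor
#'
#' Bundles one element's identity with the toxicological reference values the
#' risk pipeline needs: the oral reference dose (RfD) used in the target
#' hazard quotient, the maximum permissible concentration in food used in
#' limit screening, and the maximum tolerable daily intake used in the
#' probabilistic exposure module. Any of the three may be absent (`NA`) when
#' no authority value is carried for that element.
#'
#' @param symbol Short element code, e.g. `"Cd"`. Must be non-empty.
#' @param name Element name, free text.
#' @param rfd Oral reference dose, mg per kg body weight per day, or `NA`.
#' @param food_limit Maximum permissible concentration in food, mg/kg, or `NA`.
#' @param intake_limit Maximum daily intake, ug per kg body weight per day,
#'   or `NA`.
#'
#' @return A list of class `"metal_descriptor"`.
#' @export
#' @examples
#' metal_descriptor("Cd", "Cadmium", rfd = 1e-3, food_limit = 0.1, intake_limit = 1)
metal_descriptor <- function(symbol, name = symbol, rfd = NA_real_,
                             food_limit = NA_real_, intake_limit = NA_real_) {
  if (!is.character(symbol) || length(symbol) != 1L || !nzchar(symbol)) {
    stop_named("vegrisk_registry_error", "`symbol` must be a non-empty string")
  }
  for (v in list(rfd = rfd, food_limit = food_limit, intake_limit = intake_limit)) NULL
  chk <- function(x, nm) {
    if (!is.na(x) && (!is.numeric(x) || x <= 0)) {
      stop_named("vegrisk_registry_error", "`", nm, "` for ", symbol,
                 " must be positive when present")
    }
    as.numeric(x)
  }
  structure(list(symbol = symbol, name = name,
                 rfd = chk(rfd, "rfd"),
                 food_limit = chk(food_limit, "food_limit"),
                 intake_limit = chk(intake_limit, "intake_limit")),
            class = "metal_descriptor")
}

#' Build a metal registry
#'
#' A registry is a named list of [metal_descriptor()] objects keyed by
#' symbol; symbols must be unique.
#'
#' @param ... `metal_descriptor` objects.
#' @return A named list of class `"metal_registry"`.
#' @export
metal_registry <- function(...) {
  descs <- list(...)
  if (!all(vapply(descs, inherits, logical(1), "metal_descriptor"))) {
    stop_named("vegrisk_registry_error", "all entries must be metal_descriptor objects")
  }
  syms <- vapply(descs, `[[`, character(1), "symbol")
  if (anyDuplicated(syms)) {
    stop_named("vegrisk_registry_error", "duplicate metal symbols: ",
               paste(unique(syms[duplicated(syms)]), collapse = ", "))
  }
  structure(setNames(descs, syms), class = "metal_registry")
}

#' Built-in registry for the 19 surveyed trace elements
#'
#' Reference values used throughout the package:
#' \itemize{
#'   \item Oral reference doses (USEPA, mg/kg bw/day) for the seven elements
#'     carried into the hazard index: As 3.0e-4, Cd 1.0e-3, Cu 4.0e-2,
#'     Fe 7.0e-1, Mn 1.4e-1, Pb 4.0e-3, Zn 3.0e-1.
#'   \item FAO/WHO maximum permissible concentrations in leafy vegetables
#'     (mg/kg dry weight): Cr 1.3, Cu 40, Cd 0.1, Pb 0.3, Hg 0.001. These are
#'     fixed by back-calculation from the survey's reported fold-exceedance
#'     ratios (site maximum / limit), because the printed limit row in the
#'     source table is typographically unreliable.
#'   \item Maximum tolerable daily intakes (ug/kg bw/day) for the seven RfD
#'     elements: Mn 700, Fe 1000, Cu 40, Zn 1000, As 2.14, Cd 1, Pb 3.6.
#' }
#'
#' @return A `"metal_registry"` covering Ti, V, Cr, Mn, Fe, Co, Ni, Cu, Zn,
#'   As, Se, Mo, Ag, Cd, Sn, Sb, Ba, Pb, Hg.
#' @export
#' @examples
#' reg <- builtin_registry()
#' reg[["Cd"]]$rfd        # 0.001
#' reg[["Hg"]]$food_limit # 0.001
builtin_registry <- function() {
  metal_registry(
    metal_descriptor("Ti", "Titanium"),
    metal_descriptor("V",  "Vanadium"),
    metal_descriptor("Cr", "Chromium",   food_limit = 1.3),
    metal_descriptor("Mn", "Manganese",  rfd = 1.4e-1, intake_limit = 700),
    metal_descriptor("Fe", "Iron",       rfd = 7.0e-1, intake_limit = 1000),
    metal_descriptor("Co", "Cobalt"),
    metal_descriptor("Ni", "Nickel"),
    metal_descriptor("Cu", "Copper",     rfd = 4.0e-2, food_limit = 40,
                     intake_limit = 40),
    metal_descriptor("Zn", "Zinc",       rfd = 3.0e-1, intake_limit = 1000),
    metal_descriptor("As", "Arsenic",    rfd = 3.0e-4, intake_limit = 2.14),
    metal_descriptor("Se", "Selenium"),
    metal_descriptor("Mo", "Molybdenum"),
    metal_descriptor("Ag", "Silver"),
    metal_descriptor("Cd", "Cadmium",    rfd = 1.0e-3, food_limit = 0.1,
                     intake_limit = 1),
    metal_descriptor("Sn", "Tin"),
    metal_descriptor("Sb", "Antimony"),
    metal_descriptor("Ba", "Barium"),
    metal_descriptor("Pb", "Lead",       rfd = 4.0e-3, food_limit = 0.3,
                     intake_limit = 3.6),
    metal_descriptor("Hg", "Mercury",    food_limit = 0.001)
  )
}

# Named numeric vector of one reference field over a registry, NA dropped.
registry_field <- function(registry, field) {
  v <- vapply(registry, function(d) d[[field]], numeric(1))
  v[!is.na(v)]
}
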