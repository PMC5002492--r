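#' Chemical composition of guava processing waste
#'
#' Packaged means and standard deviations of dry (dried-and-ground) and fresh
#' guava waste over the 2006-2011 batches: macro elements in g kg^-1 dry mass,
#' micro elements (B, Cu, Fe, Mn, Zn) in mg kg^-1 dry mass.
#'
#' @return data.frame with columns \code{element}, \code{unit}
#'   (\code{"g_kg"} or \code{"mg_kg"}), \code{dry_mean}, \code{dry_sd},
#'   \code{fresh_mean}, \code{fresh_sd}.
#' @export
waste_composition <- function() {
  path <- system.file("extdata", "guava_waste_composition.csv",
                      package = "nutribal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Amendment batch
#'
#' @param contents named numeric vector of element contents on a dry-mass
#'   basis; units per \code{units}.
#' @param units named character vector (or single string) giving
#'   \code{"g_kg"} or \code{"mg_kg"} per element.
#' @param source label, e.g. \code{"dry_waste"}.
#' @param year optional batch year.
#' @return Object of class \code{"amendment"}.
#' @export
amendment <- function(contents, units = "g_kg", source = "waste", year = NA) {
  if (any(contents < 0)) stop("amendment contents must be >= 0")
  if (length(units) == 1) units <- stats::setNames(rep(units, length(contents)), names(contents))
  if (!all(units %in% c("g_kg", "mg_kg"))) stop("units must be 'g_kg' or 'mg_kg'")
  structure(list(contents = contents, units = units[names(contents)],
                 source = source, year = year),
            class = "amendment")
}

#' Amendment built from the packaged waste analyses
#'
#' @param source \code{"dry"} or \code{"fresh"}.
#' @return \code{"amendment"} with the mean composition of that waste type.
#' @export
waste_amendment <- function(source = c("dry", "fresh")) {
  source <- match.arg(source)
  tab <- waste_composition()
  amendment(stats::setNames(tab[[paste0(source, "_mean")]], tab$element),
            units = stats::setNames(tab$unit, tab$element),
            source = paste0(source, "_waste"))
}

#' Nutrient input from an organic amendment
#'
#' Input (kg ha^-1) = dose (Mg dry matter ha^-1) x content (g kg^-1 dry mass,
#' i.e. kg Mg^-1). Contents in mg kg^-1 contribute dose x content / 1000.
#'
#' @param dose applied dose in Mg dry matter ha^-1, >= 0.
#' @param batch an \code{"amendment"}.
#' @return Named vector of element inputs in kg ha^-1.
#' @examples
#' waste_input(9, waste_amendment("dry"))["N"]  # 109.8 kg N ha^-1
#' @export
waste_input <- function(dose, batch) {
  if (dose < 0) stop("'dose' must be >= 0")
  if (!inherits(batch, "amendment")) stop("'batch' must be an amendment")
  scale <- ifelse(batch$units == "mg_kg", 1e-3, 1)
  dose * batch$contents * scale
}

#' Mineral fertilizer input
#'
#' The packaged standard recipe is the locally recommended mineral
#' fertilization of the orchard (urea, ordinary superphosphate, KCl):
#' 229 kg N, 12.5 kg P, 71.4 kg K, 31.5 kg Ca and 19 kg S ha^-1 yr^-1.
#' Elements absent from the recipe are reported as 0.
#'
#' @param recipe named numeric vector of per-element amounts in kg ha^-1;
#'   default is the standard recommendation.
#' @param elements elements to report (defaults to the budget element set).
#' @return Named vector of inputs in kg ha^-1 over \code{elements}.
#' @export
mineral_input <- function(recipe = c(N = 229, P = 12.5, K = 71.4, Ca = 31.5, S = 19),
                          elements = budget_elements()) {
  if (any(recipe < 0)) stop("recipe amounts must be >= 0")
  out <- stats::setNames(numeric(length(elements)), elements)
  known <- intersect(names(recipe), elements)
  out[known] <- recipe[known]
  extra <- setdiff(names(recipe), elements)
  if (length(extra)) out <- c(out, recipe[extra])
  out
}

#' @rdname mineral_input
#' @export
budget_elements <- function() c("N", "P", "K", "Ca", "Mg", "S", "B", "Cu", "Fe", "Mn", "Zn")

#' Nutrient removal through harvested fruit
#'
#' Removal (kg ha^-1) = fresh fruit yield (Mg ha^-1) x dry-matter fraction x
#' fruit nutrient concentration (g kg^-1 dry mass). Fruit dry matter at
#' harvest defaults to 11\%. When several fruit analyses exist, pass their
#' compositional mean (see \code{\link{comp_mean}}).
#'
#' @param yield fresh fruit yield, Mg ha^-1.
#' @param fruit_conc named vector of fruit concentrations, g kg^-1 dry mass.
#' @param dm_fraction fruit dry-matter fraction, in (0, 1).
#' @return Named vector of removals in kg ha^-1.
#' @export
fruit_removal <- function(yield, fruit_conc, dm_fraction = 0.11) {
  if (yield < 0) stop("'yield' must be >= 0")
  if (dm_fraction <= 0 || dm_fraction >= 1) stop("'dm_fraction' must be in (0, 1)")
  yield * dm_fraction * fruit_conc
}

#' Cumulated nutrient balance sheet
#'
#' Sums inputs and removals element-wise over cropping cycles; the budget is
#' input minus removal (negative = deficit, the pattern observed for K under
#' all waste treatments).
#'
#' @param cycles list of cycles, each a list with named numeric vectors
#'   \code{inputs} and \code{removals} (kg ha^-1) over a common element set.
#' @param treatment optional treatment label.
#' @return Object of class \code{"balance_sheet"}: data.frame with columns
#'   \code{element}, \code{input}, \code{removal}, \code{budget}.
#' @export
cumulate_budget <- function(cycles, treatment = NA) {
  if (length(cycles) < 1) stop("need at least one cycle")
  elems <- sort(names(cycles[[1]]$inputs))
  for (cy in cycles) {
    if (!setequal(names(cy$inputs), elems) || !setequal(names(cy$removals), elems))
      stop("mismatched element sets across cycles")
    if (any(cy$removals < 0)) stop("removals must be >= 0")
  }
  inp <- Reduce(`+`, lapply(cycles, function(cy) cy$inputs[elems]))
  rem <- Reduce(`+`, lapply(cycles, function(cy) cy$removals[elems]))
  out <- data.frame(element = elems, input = unname(inp), removal = unname(rem),
                    budget = unname(inp - rem))
  attr(out, "treatment") <- treatment
  class(out) <- c("balance_sheet", "data.frame")
  out
}

#' @export
print.balance_sheet <- function(x, ...) {
  tr <- attr(x, "treatment")
  cat("Nutrient balance sheet (kg ha^-1)",
      if (!is.na(tr)) paste0(" - treatment ", tr), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Convert a surface nutrient mass to a soil charge concentration
#'
#' Converts kg ha^-1 of a cation into mmol of charge per dm^3 of soil, given
#' the molar mass and ionic charge, assuming the mass is mixed through
#' \code{soil_volume} dm^3 of soil per hectare (default 10^6 dm^3, i.e. a
#' 0.1 m mixing depth).
#'
#' @param mass kg ha^-1, >= 0.
#' @param molar_mass g mol^-1, > 0.
#' @param charge ionic charge, integer >= 1.
#' @param soil_volume dm^3 ha^-1, > 0.
#' @return mmol_c dm^-3.
#' @examples
#' kg_ha_to_mmolc(152, 39.098)  # 3.89 mmol_c K dm^-3
#' @export
kg_ha_to_mmolc <- function(mass, molar_mass, charge = 1, soil_volume = 1e6) {
  if (any(mass < 0)) stop("'mass' must be >= 0")
  if (molar_mass <= 0) stop("'molar_mass' must be > 0")
  if (charge < 1) stop("'charge' must be >= 1")
  if (soil_volume <= 0) stop("'soil_volume' must be > 0")
  (mass * 1e3 / molar_mass) * charge * 1e3 / soil_volume
}

#' @rdname kg_ha_to_mmolc
#' @param conc mmol_c dm^-3 (for the inverse conversion).
#' @export
mmolc_to_kg_ha <- function(conc, molar_mass, charge = 1, soil_volume = 1e6) {
  if (molar_mass <= 0) stop("'molar_mass' must be > 0")
  conc * soil_volume / 1e3 / charge * molar_mass / 1e3
}

#' Soil base saturation
#'
#' Base saturation (\%) = 100 (K + Ca + Mg) / CEC with the cation exchange
#' capacity CEC = K + Ca + Mg + (H+Al), all in mmol_c dm^-3.
#'
#' @param k,ca,mg,h_al exchangeable cation charges, mmol_c dm^-3, >= 0.
#' @return Percent base saturation, with the CEC attached as attribute
#'   \code{"cec"}.
#' @examples
#' base_saturation(2.3, 15.3, 6.4, 19.8)
#' @export
base_saturation <- function(k, ca, mg, h_al) {
  if (any(c(k, ca, mg, h_al) < 0)) stop("cation concentrations must be >= 0")
  cec <- k + ca + mg + h_al
  if (any(cec == 0)) stop("CEC is zero")
  structure(100 * (k + ca + mg) / cec, cec = cec)
}
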