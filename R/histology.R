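#' Histomorphometry measurements of a myocardial cross-section
#'
#' Bundles the raw measurements taken from stained myocardial sections:
#' the vessel-lumen area fraction (smooth-muscle-actin staining), the
#' hematocrit used to convert vessel area to plasma area, the cell count
#' and assumed cell diameter (HE nucleus counting), and the fat and
#' collagen volume fractions excluded from the interstitial estimate.
#'
#' The cell area ratio can be supplied either directly
#' (`cell_area_ratio_pct`, the usual case when only the summary
#' morphometry is available) or via the raw triple
#' `cell_count`/`cell_diameter_um`/`section_area_um2`.
#'
#' @param vessel_area_ratio_pct Percent of the cross-section occupied by
#'   vessel lumina, in `[0, 100]`.
#' @param hematocrit Red-cell volume fraction of blood, in `[0, 1]`.
#'   The plasma area is `(1 - hematocrit)` of the vessel area.
#' @param cell_area_ratio_pct Percent of the cross-section occupied by
#'   cells, in `[0, 100]`; alternative to the raw count triple.
#' @param cell_count Nonnegative integer number of cells counted.
#' @param cell_diameter_um Assumed cell diameter in micrometres (a cell
#'   is modelled as a sphere; its cross-section contributes the
#'   great-circle area).
#' @param section_area_um2 Area of the analysed cross-section in square
#'   micrometres.
#' @param fat_fraction_pct Fat volume fraction, percent, treated as an
#'   area fraction under an isotropy assumption.
#' @param collagen_fraction_pct Collagen volume fraction, percent,
#'   treated likewise.
#'
#' @return An object of class `histology_measurements` (a validated
#'   list of the fields above).
#' @seealso [area_ratios()], [volume_ratios()]
#' @examples
#' canine_histology()
#' histology_measurements(12.3, 0.45, cell_area_ratio_pct = 61.7)
#' @export
histology_measurements <- function(vessel_area_ratio_pct,
                                   hematocrit,
                                   cell_area_ratio_pct = NULL,
                                   cell_count = NULL,
                                   cell_diameter_um = NULL,
                                   section_area_um2 = NULL,
                                   fat_fraction_pct = 11.7,
                                   collagen_fraction_pct = 3.9) {
  check_number(vessel_area_ratio_pct, "vessel_area_ratio_pct", 0, 100)
  check_number(hematocrit, "hematocrit", 0, 1)
  check_number(fat_fraction_pct, "fat_fraction_pct", 0, 100)
  check_number(collagen_fraction_pct, "collagen_fraction_pct", 0, 100)
  if (is.null(cell_area_ratio_pct)) {
    if (is.null(cell_count) || is.null(cell_diameter_um) ||
        is.null(section_area_um2))
      stop("supply either `cell_area_ratio_pct` or all of `cell_count`, ",
           "`cell_diameter_um`, `section_area_um2`", call. = FALSE)
    check_number(cell_count, "cell_count", 0)
    check_number(cell_diameter_um, "cell_diameter_um", 0, strict_lower = TRUE)
    check_number(section_area_um2, "section_area_um2", 0, strict_lower = TRUE)
  } else {
    check_number(cell_area_ratio_pct, "cell_area_ratio_pct", 0, 100)
  }
  structure(list(vessel_area_ratio_pct = vessel_area_ratio_pct,
                 hematocrit = hematocrit,
                 cell_area_ratio_pct = cell_area_ratio_pct,
                 cell_count = cell_count,
                 cell_diameter_um = cell_diameter_um,
                 section_area_um2 = section_area_um2,
                 fat_fraction_pct = fat_fraction_pct,
                 collagen_fraction_pct = collagen_fraction_pct),
            class = "histology_measurements")
}

#' Canine histology reference values
#'
#' The published canine myocardial morphometry: vessel area 12.3%,
#' hematocrit 0.45, cell area 61.7%, fat 11.7%, collagen 3.9%.  The raw
#' section area behind the cell ratio is not published, so the cell area
#' ratio is carried as a direct input.
#'
#' @return A `histology_measurements` object.
#' @export
canine_histology <- function() {
  histology_measurements(vessel_area_ratio_pct = 12.3,
                         hematocrit = 0.45,
                         cell_area_ratio_pct = 61.7,
                         fat_fraction_pct = 11.7,
                         collagen_fraction_pct = 3.9)
}

#' Plasma area ratio from vessel area and hematocrit
#'
#' The plasma fraction of blood is `1 - hematocrit`, so the plasma area
#' ratio is that fraction of the vessel-lumen area ratio.
#'
#' @param vessel_area_ratio_pct Vessel-lumen area percent, `[0, 100]`.
#' @param hematocrit Red-cell volume fraction, `[0, 1]`.
#' @return Plasma area ratio, percent.
#' @examples
#' plasma_area_ratio(12.3, 0.45) # 6.765, reported as 6.77
#' @export
plasma_area_ratio <- function(vessel_area_ratio_pct, hematocrit) {
  check_number(vessel_area_ratio_pct, "vessel_area_ratio_pct", 0, 100)
  check_number(hematocrit, "hematocrit", 0, 1)
  vessel_area_ratio_pct * (1 - hematocrit)
}

#' Cell area ratio from a nucleus count
#'
#' Each counted cell contributes the great-circle area of a sphere of
#' the given diameter (the dimensionally consistent reading of a
#' spherical cell in a 2-D cross-section).
#'
#' @param cell_count Number of cells counted, nonnegative.
#' @param cell_diameter_um Cell diameter, micrometres, > 0.
#' @param section_area_um2 Cross-section area, square micrometres, > 0.
#' @return Cell area ratio, percent.
#' @examples
#' cell_area_ratio(1000, 18.5, 435662) # about 61.7
#' @export
cell_area_ratio <- function(cell_count, cell_diameter_um, section_area_um2) {
  check_number(cell_count, "cell_count", 0)
  check_number(cell_diameter_um, "cell_diameter_um", 0, strict_lower = TRUE)
  check_number(section_area_um2, "section_area_um2", 0, strict_lower = TRUE)
  100 * cell_count * pi * (cell_diameter_um / 2)^2 / section_area_um2
}

#' Interstitial area ratio as the remainder of the cross-section
#'
#' What is not plasma, cell, fat or collagen is interstitium.  A
#' negative remainder means the morphometry inputs are inconsistent and
#' raises an error.
#'
#' @param plasma_pct,cell_pct,fat_pct,collagen_pct Area percents.
#' @return Interstitial area ratio, percent.
#' @examples
#' interstitial_area_ratio(6.77, 61.7, 11.7, 3.9) # 15.93, reported 15.9
#' @export
interstitial_area_ratio <- function(plasma_pct, cell_pct, fat_pct,
                                    collagen_pct) {
  for (nm in c("plasma_pct", "cell_pct", "fat_pct", "collagen_pct"))
    check_number(get(nm), nm, 0, 100)
  out <- 100 - plasma_pct - cell_pct - fat_pct - collagen_pct
  if (out < 0)
    stop("inconsistent morphometry: component areas exceed 100% ",
         sprintf("(remainder %.3f%%)", out), call. = FALSE)
  out
}

#' Derive the three area ratios from histology measurements
#'
#' @param hist A [histology_measurements()] object.
#' @return An object of class `area_ratios`: named numeric vector with
#'   elements `plasma_pct`, `interstitial_pct`, `cell_pct`.
#' @examples
#' area_ratios(canine_histology())
#' @export
area_ratios <- function(hist) {
  stopifnot(inherits(hist, "histology_measurements"))
  plasma <- plasma_area_ratio(hist$vessel_area_ratio_pct, hist$hematocrit)
  cell <- if (!is.null(hist$cell_area_ratio_pct)) hist$cell_area_ratio_pct
          else cell_area_ratio(hist$cell_count, hist$cell_diameter_um,
                               hist$section_area_um2)
  inter <- interstitial_area_ratio(plasma, cell, hist$fat_fraction_pct,
                                   hist$collagen_fraction_pct)
  structure(c(plasma_pct = plasma, interstitial_pct = inter,
              cell_pct = cell),
            class = "area_ratios")
}

#' Fluorescence volume ratios R1, R2, R3
#'
#' Normalizes the plasma, interstitial and cell area ratios to weights
#' summing exactly to 1.  These are the mixture weights with which each
#' compartment's concentration contributes to the measured myocardial
#' fluorescence: `Cmyo = R1*C1 + R2*C2 + R3*C3`.
#'
#' Zero components are allowed (degenerate configurations), but the
#' total must be positive.
#'
#' @param plasma_pct,interstitial_pct,cell_pct Area percents, >= 0, not
#'   all zero.  Alternatively pass a single `area_ratios` object as the
#'   first argument.
#' @return Object of class `volume_ratios`: named numeric `c(R1, R2, R3)`
#'   summing to 1.
#' @examples
#' volume_ratios(6.77, 15.93, 61.7) # (0.080, 0.189, 0.731)
#' volume_ratios(area_ratios(canine_histology()))
#' @export
volume_ratios <- function(plasma_pct, interstitial_pct = NULL,
                          cell_pct = NULL) {
  if (inherits(plasma_pct, "area_ratios")) {
    ar <- plasma_pct
    plasma_pct <- ar[["plasma_pct"]]
    interstitial_pct <- ar[["interstitial_pct"]]
    cell_pct <- ar[["cell_pct"]]
  }
  for (nm in c("plasma_pct", "interstitial_pct", "cell_pct"))
    check_number(get(nm), nm, 0)
  total <- plasma_pct + interstitial_pct + cell_pct
  if (total <= 0)
    stop("area ratios sum to zero; cannot normalize", call. = FALSE)
  r <- c(R1 = plasma_pct, R2 = interstitial_pct, R3 = cell_pct) / total
  r <- r / sum(r)  # exact renormalization
  structure(r, class = "volume_ratios")
}

#' @export
print.volume_ratios <- function(x, digits = 3, ...) {
  cat("Fluorescence volume ratios (plasma, interstitial, cell):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
print.area_ratios <- function(x, digits = 3, ...) {
  cat("Cross-section area ratios (%):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
print.histology_measurements <- function(x, ...) {
  cat("Histology measurements:\n")
  cat(sprintf("  vessel area: %.3g%%, hematocrit: %.3g\n",
              x$vessel_area_ratio_pct, x$hematocrit))
  if (!is.null(x$cell_area_ratio_pct))
    cat(sprintf("  cell area ratio: %.3g%% (direct)\n", x$cell_area_ratio_pct))
  else
    cat(sprintf("  cells: %d of diameter %.3g um in %.4g um^2\n",
                x$cell_count, x$cell_diameter_um, x$section_area_um2))
  cat(sprintf("  fat: %.3g%%, collagen: %.3g%%\n",
              x$fat_fraction_pct, x$collagen_fraction_pct))
  invisible(x)
}
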