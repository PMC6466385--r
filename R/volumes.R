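#' Subject physiology profile
#'
#' Holds the physiological inputs from which the compartment volumes and
#' the post-bolus initial plasma concentration are derived: body weight,
#' dose per kilogram, the blood fraction of body weight, the plasma
#' fraction of blood (1 - hematocrit), and the reference tissue
#' distribution volume (interstitium + cells combined) borrowed from a
#' water-soluble tracer of similar molecular weight (glucose).
#'
#' @param body_weight_kg Body weight, kg, > 0.
#' @param dose_mg_per_kg Bolus dose, mg per kg body weight, >= 0.
#' @param blood_fraction Blood mass as a fraction of body weight, (0,1).
#'   Canine default 0.077.
#' @param plasma_fraction Plasma volume fraction of blood, (0,1).
#'   Default 0.55 (hematocrit 0.45).
#' @param reference_tissue_volume_ml Combined interstitial + cell
#'   distribution volume, mL, > 0.  Canine default 1221 mL.
#' @return Object of class `subject_profile`.
#' @examples
#' canine_subject()
#' @export
subject_profile <- function(body_weight_kg,
                            dose_mg_per_kg,
                            blood_fraction = 0.077,
                            plasma_fraction = 0.55,
                            reference_tissue_volume_ml = 1221) {
  check_number(body_weight_kg, "body_weight_kg", 0, strict_lower = TRUE)
  check_number(dose_mg_per_kg, "dose_mg_per_kg", 0)
  check_number(blood_fraction, "blood_fraction", 0, 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(plasma_fraction, "plasma_fraction", 0, 1,
               strict_lower = TRUE)
  check_number(reference_tissue_volume_ml, "reference_tissue_volume_ml",
               0, strict_lower = TRUE)
  structure(list(body_weight_kg = body_weight_kg,
                 dose_mg_per_kg = dose_mg_per_kg,
                 blood_fraction = blood_fraction,
                 plasma_fraction = plasma_fraction,
                 reference_tissue_volume_ml = reference_tissue_volume_ml),
            class = "subject_profile")
}

#' Canine subject reference values
#'
#' The published canine study subject: 9.3 kg body weight, 2.5 mg/kg
#' bolus, blood 7.7% of body weight, plasma 55% of blood, and a
#' 1221 mL glucose-derived tissue distribution volume.
#'
#' @return A `subject_profile` object.
#' @export
canine_subject <- function() {
  subject_profile(body_weight_kg = 9.3, dose_mg_per_kg = 2.5)
}

#' Plasma compartment volume from physiology
#'
#' Blood mass is converted to volume at density 1 g/mL, so
#' `V1 = weight * 1000 * blood_fraction * plasma_fraction` millilitres.
#'
#' @param body_weight_kg Body weight, kg.
#' @param blood_fraction Blood fraction of body weight.
#' @param plasma_fraction Plasma fraction of blood.
#' @return Plasma volume V1, mL.
#' @examples
#' plasma_volume(9.3, 0.077, 0.55) # 393.86, reported as 394
#' @export
plasma_volume <- function(body_weight_kg, blood_fraction, plasma_fraction) {
  check_number(body_weight_kg, "body_weight_kg", 0, strict_lower = TRUE)
  check_number(blood_fraction, "blood_fraction", 0, 1, strict_lower = TRUE)
  check_number(plasma_fraction, "plasma_fraction", 0, 1, strict_lower = TRUE)
  body_weight_kg * 1000 * blood_fraction * plasma_fraction
}

#' Split the reference tissue volume into interstitial and cell volumes
#'
#' The combined tissue distribution volume is divided in proportion to
#' the measured interstitial and cell area ratios; the split conserves
#' the total exactly (V3 is the remainder).
#'
#' @param reference_tissue_volume_ml Combined volume, mL, > 0.
#' @param interstitial_pct,cell_pct Area percents, > 0.
#' @return Named numeric `c(V2_ml, V3_ml)`.
#' @examples
#' split_tissue_volume(1221, 15.93, 61.7) # (250.6, 970.4) ~ (251, 970)
#' @export
split_tissue_volume <- function(reference_tissue_volume_ml,
                                interstitial_pct, cell_pct) {
  check_number(reference_tissue_volume_ml, "reference_tissue_volume_ml",
               0, strict_lower = TRUE)
  check_number(interstitial_pct, "interstitial_pct", 0, strict_lower = TRUE)
  check_number(cell_pct, "cell_pct", 0, strict_lower = TRUE)
  v2 <- reference_tissue_volume_ml *
    interstitial_pct / (interstitial_pct + cell_pct)
  c(V2_ml = v2, V3_ml = reference_tissue_volume_ml - v2)
}

#' Initial plasma concentration after an intravenous bolus
#'
#' The whole dose is assumed instantaneously mixed in the plasma
#' compartment: `C1(0) = dose / V1` with the dose in micrograms.
#'
#' @param dose_mg_per_kg Dose, mg/kg.
#' @param body_weight_kg Body weight, kg.
#' @param V1_ml Plasma volume, mL.
#' @return C1(0), ug/mL.
#' @examples
#' initial_plasma_concentration(2.5, 9.3, 394) # 59.01
#' @export
initial_plasma_concentration <- function(dose_mg_per_kg, body_weight_kg,
                                         V1_ml) {
  check_number(dose_mg_per_kg, "dose_mg_per_kg", 0)
  check_number(body_weight_kg, "body_weight_kg", 0, strict_lower = TRUE)
  check_number(V1_ml, "V1_ml", 0, strict_lower = TRUE)
  dose_mg_per_kg * body_weight_kg * 1000 / V1_ml
}

#' Compartment volumes container
#'
#' @param V1_ml,V2_ml,V3_ml Plasma, interstitial and cell compartment
#'   volumes, mL, all > 0.
#' @return Object of class `compartment_volumes` (named numeric).
#' @export
compartment_volumes <- function(V1_ml, V2_ml, V3_ml) {
  for (nm in c("V1_ml", "V2_ml", "V3_ml"))
    check_number(get(nm), nm, 0, strict_lower = TRUE)
  structure(c(V1_ml = V1_ml, V2_ml = V2_ml, V3_ml = V3_ml),
            class = "compartment_volumes")
}

#' Derive compartment volumes and C1(0) for a subject
#'
#' Convenience wrapper running [plasma_volume()],
#' [split_tissue_volume()] and [initial_plasma_concentration()] off a
#' subject profile and the histological area ratios (full precision:
#' the unrounded interstitial ratio is used, which is what reproduces
#' the published 251/970 mL split).
#'
#' @param subject A [subject_profile()].
#' @param areas An `area_ratios` object (or named vector with
#'   `interstitial_pct`, `cell_pct`).
#' @return List with `volumes` (a `compartment_volumes`) and `C1_0`
#'   (ug/mL).
#' @examples
#' derive_volumes(canine_subject(), area_ratios(canine_histology()))
#' @export
derive_volumes <- function(subject, areas) {
  stopifnot(inherits(subject, "subject_profile"))
  v1 <- plasma_volume(subject$body_weight_kg, subject$blood_fraction,
                      subject$plasma_fraction)
  v23 <- split_tissue_volume(subject$reference_tissue_volume_ml,
                             areas[["interstitial_pct"]],
                             areas[["cell_pct"]])
  vols <- compartment_volumes(v1, v23[["V2_ml"]], v23[["V3_ml"]])
  list(volumes = vols,
       C1_0 = initial_plasma_concentration(subject$dose_mg_per_kg,
                                           subject$body_weight_kg, v1))
}

#' @export
print.compartment_volumes <- function(x, digits = 4, ...) {
  cat("Compartment volumes (mL): plasma, interstitial, cell\n")
  print(signif(unclass(x), digits))
  invisible(x)
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "Subject: %.3g kg, dose %.3g mg/kg, blood %.3g%% of weight,\n",
    x$body_weight_kg, x$dose_mg_per_kg, 100 * x$blood_fraction))
  cat(sprintf("  plasma %.3g%% of blood, reference tissue volume %.4g mL\n",
              100 * x$plasma_fraction, x$reference_tissue_volume_ml))
  invisible(x)
}
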