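#' Physicochemical acid-base constants for calf plasma
#'
#' Returns the set of constants used by the acid-base derivations. The
#' defaults are the experimentally determined values for bovine neonatal
#' plasma: `pk1` and `s_co2` for the Henderson-Hasselbalch bicarbonate
#' calculation, the van Slyke buffering coefficients, the `atot_coeff`
#' linking total protein to the nonvolatile weak acid pool, and the weak
#' acid dissociation constant `pka`. All are overridable for other species
#' or analyzers.
#'
#' @param pk1 Negative log dissociation constant of carbonic acid.
#' @param s_co2 CO2 solubility, mmol/L per mm Hg.
#' @param atot_coeff Atot per unit total protein, mmol/L per g/L.
#' @param pka Negative log dissociation constant of nonvolatile weak acids.
#' @param be_hb_coeff,be_buffer_slope,be_buffer_intercept Van Slyke
#'   hemoglobin-buffering coefficients (hemoglobin in g/dL).
#' @param hco3_ref,ph_ref Reference bicarbonate (mmol/L) and pH of the van
#'   Slyke equation.
#' @param temp_ph_slope,temp_pco2_slope,temp_po2_slope Per-degree
#'   temperature-correction slopes for pH (additive) and for pCO2/pO2
#'   (log10-linear).
#' @return A named list of constants.
#' @export
#' @examples
#' acid_base_constants()
#' acid_base_constants(pka = 7.10)
acid_base_constants <- function(pk1 = 6.105,
                                s_co2 = 0.0307,
                                atot_coeff = 0.343,
                                pka = 7.08,
                                be_hb_coeff = 0.014,
                                be_buffer_slope = 1.43,
                                be_buffer_intercept = 7.7,
                                hco3_ref = 24.8,
                                ph_ref = 7.4,
                                temp_ph_slope = -0.0146,
                                temp_pco2_slope = 0.019,
                                temp_po2_slope = 0.0052) {
  list(
    pk1 = pk1, s_co2 = s_co2, atot_coeff = atot_coeff, pka = pka,
    be_hb_coeff = be_hb_coeff, be_buffer_slope = be_buffer_slope,
    be_buffer_intercept = be_buffer_intercept,
    hco3_ref = hco3_ref, ph_ref = ph_ref,
    temp_ph_slope = temp_ph_slope, temp_pco2_slope = temp_pco2_slope,
    temp_po2_slope = temp_po2_slope
  )
}

validate_blood_gas <- function(ph, pco2, po2 = NULL, rectal_temp = NULL) {
  check_range <- function(x, lo, hi, name) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) {
      abort(sprintf(
        "`%s` outside validation bounds [%s, %s]: %s",
        name, lo, hi, paste(format(x[bad]), collapse = ", ")
      ), class = "calfsid_validation_error")
    }
  }
  check_range(ph, 6.0, 8.0, "ph")
  check_range(pco2, 5, 200, "pco2")
  if (!is.null(po2)) {
    bad <- !is.na(po2) & (po2 <= 0 | po2 > 300)
    if (any(bad)) {
      abort("`po2` outside validation bounds (0, 300]",
            class = "calfsid_validation_error")
    }
  }
  if (!is.null(rectal_temp)) check_range(rectal_temp, 25, 43, "rectal_temp")
  invisible(TRUE)
}

#' Correct blood-gas values for body temperature
#'
#' Blood pH, pCO2 and pO2 are measured at 37 degrees C; this converts them
#' to the patient's rectal temperature using the standard linear-in-log
#' corrections: `pH_T = pH + slope_pH * (T - 37)` and
#' `p_T = p * 10^(slope * (T - 37))` for the gas tensions. At 37 degrees C
#' the correction is the identity.
#'
#' @param ph,pco2 Measured pH (dimensionless) and pCO2 (mm Hg) at 37 C.
#' @param rectal_temp Rectal temperature, degrees C (25-43).
#' @param po2 Optional pO2 (mm Hg) at 37 C.
#' @param constants See [acid_base_constants()].
#' @return A tibble with columns `ph`, `pco2` (and `po2` when supplied) at
#'   the patient's temperature.
#' @export
#' @examples
#' correct_for_temperature(7.40, 40, rectal_temp = 38.5)
correct_for_temperature <- function(ph, pco2, rectal_temp, po2 = NULL,
                                    constants = acid_base_constants()) {
  validate_blood_gas(ph, pco2, po2, rectal_temp)
  dt <- rectal_temp - 37
  out <- tibble::tibble(
    ph = ph + constants$temp_ph_slope * dt,
    pco2 = pco2 * 10^(constants$temp_pco2_slope * dt)
  )
  if (!is.null(po2)) out$po2 <- po2 * 10^(constants$temp_po2_slope * dt)
  out
}

#' Actual bicarbonate from pH and pCO2 (Henderson-Hasselbalch)
#'
#' `HCO3 = S * pCO2 * 10^(pH - pK1)` with the plasma CO2 solubility `S` and
#' carbonic acid `pK1` for calf plasma. Inputs are the values measured at
#' 37 degrees C.
#'
#' @inheritParams correct_for_temperature
#' @return Bicarbonate concentration, mmol/L.
#' @export
#' @examples
#' bicarbonate(7.40, 40) # ~24.2 mmol/L
bicarbonate <- function(ph, pco2, constants = acid_base_constants()) {
  validate_blood_gas(ph, pco2)
  constants$s_co2 * pco2 * 10^(ph - constants$pk1)
}

#' In vitro base excess (van Slyke equation)
#'
#' `BE = (1 - 0.014*Hb) * ((HCO3 - 24.8) + (1.43*Hb + 7.7) * (pH - 7.4))`
#' with hemoglobin in g/dL. Zero at the reference point (pH 7.4,
#' HCO3 24.8 mmol/L) for any hemoglobin concentration.
#'
#' @param ph Blood pH at 37 C.
#' @param hco3 Actual bicarbonate, mmol/L.
#' @param hb Hemoglobin concentration, g/dL.
#' @inheritParams correct_for_temperature
#' @return Base excess, mmol/L.
#' @export
#' @examples
#' base_excess(7.0, 10, 12) # ~ -20.6
base_excess <- function(ph, hco3, hb, constants = acid_base_constants()) {
  if (any(!is.na(hb) & hb < 0)) {
    abort("`hb` must be >= 0", class = "calfsid_validation_error")
  }
  (1 - constants$be_hb_coeff * hb) *
    ((hco3 - constants$hco3_ref) +
       (constants$be_buffer_slope * hb + constants$be_buffer_intercept) *
       (ph - constants$ph_ref))
}

#' Anion gap
#'
#' `AG = Na + K - Cl - HCO3` (all mmol/L; result mEq/L), the traditional
#' estimate of unmeasured anions.
#'
#' @param na,k,cl Plasma sodium, potassium, chloride, mmol/L.
#' @param hco3 Actual bicarbonate, mmol/L.
#' @return Anion gap, mEq/L.
#' @export
anion_gap <- function(na, k, cl, hco3) {
  na + k - cl - hco3
}

#' Nonvolatile weak acid concentration (Atot)
#'
#' `Atot = 0.343 * total protein` with protein in g/L; the coefficient is
#' the experimentally determined value for calf plasma.
#'
#' @param total_protein Serum total protein, g/L.
#' @inheritParams correct_for_temperature
#' @return Atot, mmol/L.
#' @export
atot <- function(total_protein, constants = acid_base_constants()) {
  if (any(!is.na(total_protein) & total_protein < 0)) {
    abort("`total_protein` must be >= 0", class = "calfsid_validation_error")
  }
  constants$atot_coeff * total_protein
}

#' Net negative charge of nonvolatile weak acids (A-)
#'
#' `A- = Atot / (1 + 10^(pKa - pH))` with the calf plasma `pKa`. Equals
#' `Atot / 2` exactly when pH equals pKa.
#'
#' @param atot Nonvolatile weak acid concentration, mmol/L.
#' @param ph Blood pH.
#' @inheritParams correct_for_temperature
#' @return A-, mEq/L.
#' @export
a_minus <- function(atot, ph, constants = acid_base_constants()) {
  atot / (1 + 10^(constants$pka - ph))
}

#' Measured strong ion difference
#'
#' `SIDm = Na + K - Cl - D-lactate - L-lactate`, mEq/L.
#'
#' @param na,k,cl Plasma electrolytes, mmol/L.
#' @param d_lactate,l_lactate Plasma lactate stereoisomers, mmol/L.
#' @return SIDm, mEq/L.
#' @export
sid_measured <- function(na, k, cl, d_lactate, l_lactate) {
  na + k - cl - d_lactate - l_lactate
}

#' Strong ion gap
#'
#' `SIG = A- - AG`: the difference between unmeasured strong cations and
#' anions. Negative values indicate an excess of unmeasured strong anions.
#'
#' @param atot Nonvolatile weak acid concentration, mmol/L.
#' @param ph Blood pH.
#' @param ag Anion gap, mEq/L.
#' @inheritParams correct_for_temperature
#' @return SIG, mEq/L.
#' @export
strong_ion_gap <- function(atot, ph, ag, constants = acid_base_constants()) {
  a_minus(atot, ph, constants) - ag
}

#' Unidentified strong ions (unmeasured strong ion difference)
#'
#' `USI = SIG + D-lactate + L-lactate`: the strong ion gap corrected for the
#' measured lactate stereoisomers, estimating still-unidentified strong
#' ions.
#'
#' @param sig Strong ion gap, mEq/L.
#' @param d_lactate,l_lactate Plasma lactates, mmol/L.
#' @return USI, mEq/L.
#' @export
unidentified_strong_ions <- function(sig, d_lactate, l_lactate) {
  sig + d_lactate + l_lactate
}

#' Derive all acid-base quantities for a cohort
#'
#' Appends the eight derived acid-base columns to a one-row-per-calf cohort
#' table: `hco3`, `base_excess`, `anion_gap`, `atot`, `a_minus`, `sid_m`,
#' `sig` and `usi`, computed from the measured blood gas (`ph`, `pco2`) and
#' chemistry (`na`, `k`, `cl`, `d_lactate`, `l_lactate`, `total_protein`,
#' `hb`) columns. Bicarbonate and base excess use the pH/pCO2 values
#' measured at 37 degrees C, matching analyzer convention. When
#' `temp_correct = TRUE` and a `rectal_temp` column is present,
#' temperature-corrected gas columns `ph_temp`, `pco2_temp` (and `po2_temp`
#' if `po2` exists) are appended as well; they do not enter the
#' derivations.
#'
#' Two algebraic identities hold for every row by construction:
#' `usi = sig + d_lactate + l_lactate` and
#' `usi + sid_m = a_minus + hco3`.
#'
#' @param data Cohort data frame, one row per calf.
#' @param temp_correct Append temperature-corrected gas columns?
#' @param constants See [acid_base_constants()].
#' @return The input as a tibble with derived columns appended.
#' @export
#' @examples
#' calf <- tibble::tibble(
#'   ph = 7.181, pco2 = 47.4, na = 134.7, k = 4.8, cl = 101,
#'   d_lactate = 3.9, l_lactate = 1.6, total_protein = 57.7, hb = 12.8
#' )
#' derive_acid_base(calf)
derive_acid_base <- function(data, temp_correct = FALSE,
                             constants = acid_base_constants()) {
  required <- c("ph", "pco2", "na", "k", "cl", "d_lactate", "l_lactate",
                "total_protein", "hb")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("cohort is missing required analyte column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "calfsid_missing_columns"
    )
  }
  data <- tibble::as_tibble(data)
  validate_blood_gas(data$ph, data$pco2)
  plaus <- !is.na(data$na) & !is.na(data$cl) & data$na <= data$cl
  if (any(plaus)) {
    warn(sprintf("%d row(s) with na <= cl: physiologically implausible",
                 sum(plaus)))
  }
  out <- dplyr::mutate(
    data,
    hco3 = bicarbonate(.data$ph, .data$pco2, constants),
    base_excess = base_excess(.data$ph, .data$hco3, .data$hb, constants),
    anion_gap = anion_gap(.data$na, .data$k, .data$cl, .data$hco3),
    atot = atot(.data$total_protein, constants),
    a_minus = a_minus(.data$atot, .data$ph, constants),
    sid_m = sid_measured(.data$na, .data$k, .data$cl,
                         .data$d_lactate, .data$l_lactate),
    sig = strong_ion_gap(.data$atot, .data$ph, .data$anion_gap, constants),
    usi = unidentified_strong_ions(.data$sig, .data$d_lactate,
                                   .data$l_lactate)
  )
  if (temp_correct) {
    if (!"rectal_temp" %in% names(out)) {
      abort("`temp_correct = TRUE` requires a `rectal_temp` column",
            class = "calfsid_missing_columns")
    }
    tc <- correct_for_temperature(
      out$ph, out$pco2, out$rectal_temp,
      po2 = if ("po2" %in% names(out)) out$po2 else NULL,
      constants = constants
    )
    out$ph_temp <- tc$ph
    out$pco2_temp <- tc$pco2
    if ("po2" %in% names(tc)) out$po2_temp <- tc$po2
  }
  out
}
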