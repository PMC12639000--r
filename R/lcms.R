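#' Fit an external calibration curve
#'
#' Ordinary least-squares fit of instrument response against standard amount
#' for one analyte. The slope is the relative response factor (rRF) used to
#' convert signal to absolute amount; the intercept is fitted by default and
#' reported as a QC diagnostic, but quantification divides by the slope only.
#'
#' @param standards Data frame with columns `level` (amount; pmol for UV,
#'   fmol for MS) and `response` (signal, arbitrary units); optional
#'   `analyte` and `channel` columns (single value each) are carried through.
#' @param force_origin Constrain the line through the origin (default
#'   `FALSE`).
#' @return An object of class `oab_calibration` with elements `rrf`
#'   (slope), `intercept`, `r_squared`, `n`, `range` (level range), `fit`
#'   (the underlying `lm`), `analyte`, `channel`. Has [tidy()] and
#'   [glance()] methods.
#' @export
fit_calibration <- function(standards, force_origin = FALSE) {
  stopifnot(is.data.frame(standards),
            all(c("level", "response") %in% names(standards)))
  lv <- standards$level
  rs <- standards$response
  if (length(lv) < 2L || length(unique(lv)) < 2L) {
    stop("calibration needs at least 2 distinct standard levels", call. = FALSE)
  }
  fit <- if (force_origin) lm(rs ~ 0 + lv) else lm(rs ~ lv)
  slope <- unname(coef(fit)[["lv"]])
  intercept <- if (force_origin) 0 else unname(coef(fit)[["(Intercept)"]])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope (rRF) is not positive; check the standards", call. = FALSE)
  }
  ss_tot <- sum((rs - mean(rs))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(rrf = slope, intercept = intercept, r_squared = r2,
                 n = length(lv), range = range(lv), fit = fit,
                 analyte = if ("analyte" %in% names(standards))
                   standards$analyte[1] else NA_character_,
                 channel = if ("channel" %in% names(standards))
                   standards$channel[1] else NA_character_,
                 force_origin = force_origin),
            class = "oab_calibration")
}

#' @export
tidy.oab_calibration <- function(x, ...) {
  tibble(term = c("intercept", "rrf"),
         estimate = c(x$intercept, x$rrf))
}

#' @export
glance.oab_calibration <- function(x, ...) {
  tibble(analyte = x$analyte, channel = x$channel, rrf = x$rrf,
         intercept = x$intercept, r_squared = x$r_squared, n = x$n,
         level_min = x$range[1], level_max = x$range[2])
}

#' @export
print.oab_calibration <- function(x, ...) {
  cat(sprintf("Calibration%s: rRF = %.4g, intercept = %.4g, R^2 = %.4f (n = %d)\n",
              if (is.na(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$rrf, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Quantify signals against a calibration curve
#'
#' Absolute amount = signal / rRF (the slope of the external calibration
#' curve); any fitted intercept is deliberately ignored here and available
#' from the curve object as a diagnostic. Signals outside the calibration
#' range raise a warning, not an error.
#'
#' @param samples Data frame with a `signal` column (or a bare numeric
#'   vector).
#' @param curve An `oab_calibration`.
#' @return The input tibble with an `amount` column (same units as the
#'   standard levels), or a numeric vector if `samples` was one.
#' @export
quantify <- function(samples, curve) {
  stopifnot(inherits(curve, "oab_calibration"))
  vec_in <- is.numeric(samples)
  sig <- if (vec_in) samples else samples$signal
  if (any(sig < 0, na.rm = TRUE)) stop("negative signal", call. = FALSE)
  amount <- sig / curve$rrf
  expected_hi <- curve$rrf * curve$range[2] + curve$intercept
  if (any(sig > expected_hi, na.rm = TRUE)) {
    warning("signal(s) above the top calibration standard; ",
            "amounts are extrapolated", call. = FALSE)
  }
  if (vec_in) return(amount)
  mutate(as_tibble(samples), amount = amount)
}

#' Normalization schemes for absolute amounts
#'
#' `normalize_to_control_total()` divides each absolute amount by the total
#' nucleoside amount of the untreated control sample (used at nucleoside
#' level, where no single nucleoside is unaffected enough to serve as an
#' internal reference). `normalize_per_g()` divides by the injected amount
#' and the number of guanosines in the sequence (used for abasic-site
#' ribose-phosphate and oxo8G monophosphate quantification). Both are
#' homogeneous of degree 1 in the raw amount and tag their scheme.
#'
#' @param amounts Data frame with an `amount` column, or numeric vector.
#' @param control_total Total nucleoside amount in the untreated control
#'   (> 0).
#' @return Input with `normalized` and `scheme` columns (or a numeric
#'   vector).
#' @export
normalize_to_control_total <- function(amounts, control_total) {
  stopifnot(is.numeric(control_total), length(control_total) == 1L,
            control_total > 0)
  if (is.numeric(amounts)) return(amounts / control_total)
  mutate(as_tibble(amounts), normalized = .data$amount / control_total,
         scheme = "control_total")
}

#' @rdname normalize_to_control_total
#' @param injected_amount Amount of RNA injected (> 0).
#' @param g_count Number of guanosines in the sequence (> 0).
#' @export
normalize_per_g <- function(amounts, injected_amount, g_count) {
  stopifnot(injected_amount > 0, g_count > 0)
  if (is.numeric(amounts)) return(amounts / (injected_amount * g_count))
  mutate(as_tibble(amounts),
         normalized = .data$amount / (injected_amount * g_count),
         scheme = "per_injected_per_G")
}

#' Cellular RNA composition model
#'
#' Composition model used to normalize in vivo lesion quantification to the
#' guanosine content of total RNA: by default 80% rRNA (5475 nt combined),
#' 15% tRNA (76 nt), 5% mRNA (mean 1700 nt), each with 25% guanosine.
#'
#' @param fractions Named numeric vector of species fractions (must sum
#'   to 1).
#' @param lengths Representative species lengths in nt (same names).
#' @param g_fraction Per-species guanosine fraction; recycled if scalar.
#' @return A list of class `oab_rna_composition`.
#' @export
rna_composition <- function(fractions = c(rRNA = 0.80, tRNA = 0.15, mRNA = 0.05),
                            lengths = c(rRNA = 5475, tRNA = 76, mRNA = 1700),
                            g_fraction = 0.25) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(lengths > 0),
            all(g_fraction > 0), all(g_fraction < 1))
  if (length(g_fraction) == 1L) {
    g_fraction <- setNames(rep(g_fraction, length(fractions)), names(fractions))
  }
  stopifnot(identical(names(fractions), names(lengths)),
            identical(names(fractions), names(g_fraction)))
  structure(list(fractions = fractions, lengths = lengths,
                 g_fraction = g_fraction),
            class = "oab_rna_composition")
}

#' Guanosine content of total RNA under a composition model
#'
#' Composition-weighted guanosine fraction of total RNA nucleotides. Under
#' `"molar"` weighting the species fractions are read as molar fractions of
#' molecules and converted to nucleotide fractions via the species lengths;
#' under `"mass"` weighting the fractions are taken as mass (~nucleotide)
#' fractions directly. With a uniform per-species G fraction the two
#' coincide. Multiplied by `mass_per_od` (nucleotides per OD unit, when
#' supplied) this yields guanosines per OD of input RNA.
#'
#' @param model An `oab_rna_composition`.
#' @param weighting `"molar"` (default) or `"mass"`.
#' @param mass_per_od Optional conversion factor (nucleotide amount per OD).
#' @return Guanosine fraction of nucleotides (scalar), or guanosines per OD
#'   when `mass_per_od` is given.
#' @export
g_per_mass <- function(model, weighting = c("molar", "mass"),
                       mass_per_od = NULL) {
  stopifnot(inherits(model, "oab_rna_composition"))
  weighting <- match.arg(weighting)
  w <- if (weighting == "molar") {
    nt <- model$fractions * model$lengths
    nt / sum(nt)
  } else {
    model$fractions
  }
  gfrac <- sum(w * model$g_fraction)
  if (is.null(mass_per_od)) gfrac else gfrac * mass_per_od
}

#' Free chlorine equivalents from potassium iodate
#'
#' The DPD free-chlorine assay (ISO 7393-2) is calibrated with KIO3
#' standards; one mole of KIO3 (molar mass 214.00 g/mol) is equivalent to
#' three moles of Cl2. Hence 10.06 ug KIO3 corresponds to 0.141 umol Cl2.
#'
#' @param mass_ug KIO3 mass in micrograms (vectorized, must be >= 0).
#' @return Micromoles of Cl2 equivalents.
#' @examples
#' free_chlorine_from_kio3(10.06)  # 0.141 umol
#' @export
free_chlorine_from_kio3 <- function(mass_ug) {
  if (any(mass_ug < 0, na.rm = TRUE)) stop("negative KIO3 mass", call. = FALSE)
  (mass_ug / 214.00) * 3
}

#' Chlorine assay description
#'
#' Bundles the DPD calibration standards and a sample measurement for
#' [dpd_sample_concentration()].
#'
#' @param standard_mass_ug KIO3 standard masses (ug) in the assay volume.
#' @param standard_abs Their absorbances at 515 nm.
#' @param sample_abs Sample absorbance at 515 nm.
#' @param dilution Dilution factor of the stock into the assay (>= 1).
#' @param volume_ml Assay volume in mL (default 1).
#' @return A list of class `oab_chlorine_assay`.
#' @export
chlorine_assay <- function(standard_mass_ug, standard_abs, sample_abs,
                           dilution = 1, volume_ml = 1) {
  stopifnot(length(standard_mass_ug) == length(standard_abs),
            length(standard_mass_ug) >= 2L,
            all(standard_mass_ug >= 0), all(standard_abs >= 0),
            all(sample_abs >= 0), dilution >= 1, volume_ml > 0)
  structure(list(standard_mass_ug = standard_mass_ug,
                 standard_abs = standard_abs, sample_abs = sample_abs,
                 dilution = dilution, volume_ml = volume_ml),
            class = "oab_chlorine_assay")
}

#' Free chlorine concentration of a stock solution by DPD assay
#'
#' Fits the KIO3-mass calibration line (absorbance vs mass), inverts it at
#' the sample absorbance to a KIO3-mass equivalent, converts to umol Cl2 via
#' [free_chlorine_from_kio3()], and scales by the dilution factor and assay
#' volume. Absorbances above the top standard are flagged, not rejected.
#'
#' @param assay An `oab_chlorine_assay`.
#' @return A tibble: per sample absorbance, `kio3_equiv_ug` (in the assay),
#'   `cl2_umol` (in the assay), `cl2_umol_stock` (per assay volume of
#'   stock), `stock_mM` (umol/mL of stock), and `above_range`.
#' @export
dpd_sample_concentration <- function(assay) {
  stopifnot(inherits(assay, "oab_chlorine_assay"))
  cal <- fit_calibration(tibble(level = assay$standard_mass_ug,
                                response = assay$standard_abs))
  above <- assay$sample_abs > max(assay$standard_abs)
  if (any(above)) {
    warning("sample absorbance above the top standard; dilute further",
            call. = FALSE)
  }
  kio3 <- (assay$sample_abs - cal$intercept) / cal$rrf
  kio3 <- pmax(kio3, 0)
  cl2 <- free_chlorine_from_kio3(kio3)
  tibble(sample_abs = assay$sample_abs,
         kio3_equiv_ug = kio3,
         cl2_umol = cl2,
         cl2_umol_stock = cl2 * assay$dilution,
         stock_mM = cl2 * assay$dilution / assay$volume_ml,
         above_range = above)
}
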