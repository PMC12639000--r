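test_that("calibration fitting recovers exact and noisy slopes", {
  # responses exactly 2x levels: rRF 2, intercept 0, perfect fit
  std <- tibble::tibble(level = c(1, 5, 10, 50, 100), response = 2 * level)
  cal <- fit_calibration(std)
  expect_equal(cal$rrf, 2)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$r_squared, 1)
  # noisy standards match the closed-form normal-equation solution
  set.seed(401)
  lv <- c(1, 2, 5, 10, 20, 50, 100, 200)
  rs <- 3.5 * lv + rnorm(8, 0, 2)
  caln <- fit_calibration(tibble::tibble(level = lv, response = rs))
  slope_oracle <- sum((lv - mean(lv)) * (rs - mean(rs))) / sum((lv - mean(lv))^2)
  expect_equal(caln$rrf, slope_oracle)
  expect_equal(caln$intercept, mean(rs) - slope_oracle * mean(lv))
  # origin-forced fit uses the through-origin estimator
  cal0 <- fit_calibration(tibble::tibble(level = lv, response = rs),
                          force_origin = TRUE)
  expect_equal(cal0$rrf, sum(lv * rs) / sum(lv^2))
  expect_equal(cal0$intercept, 0)
  # degenerate standards are rejected
  expect_error(fit_calibration(tibble::tibble(level = 5, response = 10)),
               "at least 2")
  expect_error(fit_calibration(tibble::tibble(level = c(5, 5),
                                              response = c(9, 11))),
               "at least 2")
  expect_equal(tidy(cal)$estimate, c(0, 2))
  expect_equal(glance(caln)$rrf, slope_oracle)
})

test_that("quantification divides by the response factor only", {
  cal <- fit_calibration(tibble::tibble(level = c(1, 10, 100),
                                        response = c(2, 20, 200)))
  expect_equal(quantify(0, cal), 0)
  expect_equal(quantify(10, cal), 5)
  smp <- quantify(tibble::tibble(signal = c(4, 40)), cal)
  expect_equal(smp$amount, c(2, 20))
  expect_error(quantify(-1, cal), "negative")
  expect_warning(quantify(1e5, cal), "extrapolated")
})

test_that("noiseless round trip is exact and held-out standards recover", {
  lv <- c(1, 5, 10, 50, 100, 500)
  rs <- 7.3 * lv
  cal <- fit_calibration(tibble::tibble(level = lv, response = rs))
  expect_equal(quantify(7.3 * 42, cal), 42)
  # leave-one-out on noisy standards: recovery within the fit's own error
  set.seed(402)
  rs_n <- 7.3 * lv * exp(rnorm(6, 0, 0.02))
  for (k in seq_along(lv)) {
    cal_k <- fit_calibration(tibble::tibble(level = lv[-k],
                                            response = rs_n[-k]))
    # holding out the top standard makes its signal an extrapolation
    expect_equal(suppressWarnings(quantify(rs_n[k], cal_k)), lv[k],
                 tolerance = 0.1)
  }
})

test_that("normalization schemes behave and are homogeneous of degree 1", {
  amounts <- tibble::tibble(analyte = c("oxo8G", "5RP"), amount = c(4, 0))
  nc <- normalize_to_control_total(amounts, control_total = 4)
  expect_equal(nc$normalized, c(1, 0))
  expect_equal(unique(nc$scheme), "control_total")
  ng <- normalize_per_g(amounts, injected_amount = 2, g_count = 10)
  expect_equal(ng$normalized, c(0.2, 0))
  expect_equal(unique(ng$scheme), "per_injected_per_G")
  # doubling the G count halves the value
  expect_equal(normalize_per_g(10, 2, 20), normalize_per_g(10, 2, 10) / 2)
  # a 38mer with 9 guanosines, hand computed: 18 / (2 * 9) = 1
  expect_equal(normalize_per_g(18, 2, 9), 1)
  # homogeneity: scaling the raw amount scales every scheme linearly
  for (s in c(0.5, 3)) {
    expect_equal(normalize_to_control_total(s * 7, 11),
                 s * normalize_to_control_total(7, 11))
    expect_equal(normalize_per_g(s * 7, 3, 5), s * normalize_per_g(7, 3, 5))
  }
  expect_error(normalize_to_control_total(amounts, 0))
})

test_that("composition model yields the weighted guanosine fraction", {
  m <- rna_composition()
  # uniform 25% G across species: overall exactly 0.25 either weighting
  expect_equal(g_per_mass(m), 0.25)
  expect_equal(g_per_mass(m, weighting = "mass"), 0.25)
  # single species: that species' G fraction
  m1 <- rna_composition(fractions = c(rRNA = 1), lengths = c(rRNA = 5475),
                        g_fraction = c(rRNA = 0.31))
  expect_equal(g_per_mass(m1), 0.31)
  # three species with distinct G fractions match the hand-weighted mean
  g <- c(rRNA = 0.30, tRNA = 0.26, mRNA = 0.22)
  md <- rna_composition(g_fraction = g)
  fr <- c(rRNA = 0.80, tRNA = 0.15, mRNA = 0.05)
  ln <- c(rRNA = 5475, tRNA = 76, mRNA = 1700)
  w_molar <- fr * ln / sum(fr * ln)
  expect_equal(g_per_mass(md), sum(w_molar * g))
  expect_equal(g_per_mass(md, weighting = "mass"), sum(fr * g))
  # per-OD scaling
  expect_equal(g_per_mass(m, mass_per_od = 100), 25)
  expect_error(rna_composition(fractions = c(rRNA = 0.5, tRNA = 0.1,
                                             mRNA = 0.05)))
})

test_that("KIO3 to free chlorine conversion matches the ISO stoichiometry", {
  # 10.06 ug KIO3 corresponds to 0.141 umol Cl2
  expect_equal(free_chlorine_from_kio3(10.06), 0.141, tolerance = 5e-3)
  expect_equal(free_chlorine_from_kio3(0), 0)
  expect_equal(free_chlorine_from_kio3(21.4), 0.300)
  # linearity
  expect_equal(free_chlorine_from_kio3(3.1 + 4.7),
               free_chlorine_from_kio3(3.1) + free_chlorine_from_kio3(4.7))
  expect_error(free_chlorine_from_kio3(-1), "negative")
})

test_that("DPD assay inverts the calibration and scales by dilution", {
  # exact linear assay: absorbance 0.08 per ug KIO3, zero intercept
  mass <- c(0.5, 1, 2, 3, 5)
  assay <- chlorine_assay(standard_mass_ug = mass, standard_abs = 0.08 * mass,
                          sample_abs = 0.08 * 2, dilution = 100)
  res <- dpd_sample_concentration(assay)
  # fixed point: a sample matching a standard returns that standard's
  # chlorine equivalent times the dilution
  expect_equal(res$kio3_equiv_ug, 2)
  expect_equal(res$cl2_umol, free_chlorine_from_kio3(2))
  expect_equal(res$cl2_umol_stock, free_chlorine_from_kio3(2) * 100)
  expect_false(res$above_range)
  # zero absorbance on a zero-intercept curve, dilution 1
  a0 <- chlorine_assay(mass, 0.08 * mass, sample_abs = 0, dilution = 1)
  expect_equal(dpd_sample_concentration(a0)$cl2_umol_stock, 0)
  # above-range samples warn and are flagged
  ahigh <- chlorine_assay(mass, 0.08 * mass, sample_abs = 1.0, dilution = 10)
  expect_warning(rh <- dpd_sample_concentration(ahigh), "dilute")
  expect_true(rh$above_range)
})

test_that("a synthetic chlorine assay round-trips the stock concentration", {
  # forward-simulate: stock of known free chlorine, diluted into the assay
  set.seed(403)
  stock_umol_per_ml <- 0.5             # 0.5 mM free Cl2
  dilution <- 50
  # absorbance responds linearly to Cl2 equivalents with slight noise
  mass <- c(0.5, 1, 2, 3, 4, 5)
  k_abs <- 0.075                        # absorbance per ug KIO3 equivalent
  std_abs <- k_abs * mass * exp(rnorm(6, 0, 0.01))
  cl2_in_assay <- stock_umol_per_ml / dilution          # umol in 1 mL assay
  kio3_equiv <- cl2_in_assay / 3 * 214.00               # invert stoichiometry
  smp_abs <- k_abs * kio3_equiv
  assay <- chlorine_assay(mass, std_abs, smp_abs, dilution = dilution,
                          volume_ml = 1)
  res <- dpd_sample_concentration(assay)
  expect_equal(res$stock_mM, stock_umol_per_ml, tolerance = 0.05)
})
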