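test_that("extinction risk ratio follows the allometric power law", {
  default <- extinction_scaling()
  expect_equal(extinction_risk_ratio(default, 10), 10^2.5, tolerance = 1e-12)
  expect_equal(round(extinction_risk_ratio(default, 10)), 316)
  expect_equal(extinction_risk_ratio(default, 1), 1)
  # component exponents are used when no override is given: 10^(1+0.25+1)
  comps <- extinction_scaling(b = 1, c = 0.25, d = 1, composite_override = NULL)
  expect_equal(effective_exponent(comps), 2.25)
  expect_equal(extinction_risk_ratio(comps, 10), 177.828, tolerance = 1e-4)
  expect_error(extinction_risk_ratio(default, 0), "mass_ratio")
  expect_error(extinction_risk_ratio(default, -3), "mass_ratio")
  expect_error(extinction_scaling(b = -1), ">= 0")
})

test_that("extinction risk composes multiplicatively across mass ratios", {
  scal <- extinction_scaling(composite_override = NULL)
  set.seed(11)
  for (i in 1:20) {
    x <- runif(1, 0.1, 50); y <- runif(1, 0.1, 50)
    expect_equal(extinction_risk_ratio(scal, x) * extinction_risk_ratio(scal, y),
                 extinction_risk_ratio(scal, x * y), tolerance = 1e-12)
  }
})

test_that("plant total biomass: closed form, quadrature, and the 5/3 law", {
  s <- plant_size_spectrum(c_n = 1, c_m = 1, r_min = 1e-8, r_max = 1)
  # closed form (3/5) c_n c_m r_max^(5/3); quadrature of r^(8/3-2) agrees
  expect_equal(plant_total_biomass(s), 0.6, tolerance = 1e-12)
  expect_equal(plant_total_biomass(s, "quadrature"), 0.6, tolerance = 1e-6)
  s10 <- plant_size_spectrum(c_n = 1, c_m = 1, r_min = 1e-8, r_max = 10)
  expect_equal(plant_total_biomass(s10) / plant_total_biomass(s), 10^(5 / 3),
               tolerance = 1e-12)
  # vanishing integration range
  tiny <- plant_size_spectrum(r_min = 1, r_max = 1 + 1e-9)
  expect_lt(plant_total_biomass(tiny, "quadrature"), 1e-8)
  expect_error(plant_size_spectrum(r_min = 2, r_max = 1), "r_min < r_max")
  # closed form rejects non-default exponents
  expect_error(plant_total_biomass(
    plant_size_spectrum(eta = 1.8, r_min = 0.01, r_max = 1)), "quadrature")
})

test_that("quadrature matches closed forms at lower limit 1e-6 of the upper", {
  prm <- flux_params()
  s <- plant_size_spectrum(c_n = 2, c_m = 3, r_min = 1e-6, r_max = 1)
  expect_equal(plant_total_biomass(s, "quadrature"), plant_total_biomass(s),
               tolerance = 1e-4)
  expect_equal(plant_total_flux(s, prm, "quadrature"), plant_total_flux(s, prm),
               tolerance = 1e-4)
  a <- animal_size_spectrum(c_a = 2, m_min = 1e-6, m_max = 1)
  expect_equal(animal_total_biomass(a, "quadrature"), animal_total_biomass(a),
               tolerance = 1e-4)
  expect_equal(animal_total_flux(a, prm, "quadrature"),
               animal_total_flux(a, prm), tolerance = 1e-4)
})

test_that("biomass-vs-largest-tree exponent is 5/8 for the default spectrum", {
  s <- plant_size_spectrum(r_min = 1e-6)
  expect_equal(plant_mmax_exponent(s, method = "closed",
                                   r_max_values = 10^seq(0, 3, 0.5)),
               0.625, tolerance = 1e-9)
  expect_equal(plant_mmax_exponent(s), 0.625, tolerance = 1e-4)
  # scale-free: one decade and three decades give the same slope
  expect_equal(plant_mmax_exponent(s, r_max_values = 10^seq(0, 1, 0.25),
                                   method = "closed"),
               plant_mmax_exponent(s, r_max_values = 10^seq(0, 3, 0.5),
                                   method = "closed"), tolerance = 1e-9)
  # general exponents: oracle slope = (mass_exponent - eta + 1)/mass_exponent
  toy <- plant_size_spectrum(eta = 2, mass_exponent = 2, r_min = 1e-7)
  expect_equal(plant_mmax_exponent(toy, r_max_values = 10^seq(0, 3, 0.5)),
               0.5, tolerance = 1e-4)
  expect_error(plant_mmax_exponent(s, r_max_values = c(1, 2)), "decade")
})

test_that("animal total biomass follows the 4/5 m_max^(5/4) closed form", {
  a <- animal_size_spectrum(c_a = 1, m_min = 1e-8, m_max = 1)
  expect_equal(animal_total_biomass(a), 0.8, tolerance = 1e-12)
  expect_equal(animal_total_biomass(a, "quadrature"), 0.8, tolerance = 1e-6)
  mm <- 10^seq(0, 3, 0.5)
  b <- vapply(mm, function(m)
    animal_total_biomass(animal_size_spectrum(m_min = 1e-8, m_max = m)),
    numeric(1))
  expect_equal(unname(coef(lm(log(b) ~ log(mm)))[2]), 1.25, tolerance = 1e-9)
  expect_error(animal_size_spectrum(m_min = 1, m_max = 0.5), "m_min < m_max")
})

test_that("flux ratios reproduce the 10x and ~18x rules", {
  prm <- flux_params()
  p1 <- plant_size_spectrum(r_min = 1e-6, r_max = 1)
  p10 <- plant_size_spectrum(r_min = 1e-6, r_max = 10)
  expect_equal(plant_total_flux(p10, prm) / plant_total_flux(p1, prm), 10,
               tolerance = 1e-12)
  a1 <- animal_size_spectrum(m_min = 1e-6, m_max = 1)
  a10 <- animal_size_spectrum(m_min = 1e-6, m_max = 10)
  expect_equal(animal_total_flux(a10, prm) / animal_total_flux(a1, prm),
               10^1.25, tolerance = 1e-12)
  # empty assemblages flux nothing
  expect_equal(plant_total_flux(plant_size_spectrum(c_n = 0, r_min = 0.1,
                                                    r_max = 1), prm), 0)
  expect_equal(animal_total_flux(animal_size_spectrum(c_a = 0, m_min = 0.1,
                                                      m_max = 1), prm), 0)
})

test_that("totals are monotone in upper limits and homogeneous in normalizations", {
  prm <- flux_params()
  for (f in c(1, 2.5, 7)) {
    s1 <- plant_size_spectrum(c_n = 1, r_min = 1e-4, r_max = 2)
    sf <- plant_size_spectrum(c_n = f, r_min = 1e-4, r_max = 2)
    expect_equal(plant_total_biomass(sf), f * plant_total_biomass(s1))
    expect_equal(plant_total_flux(sf, prm), f * plant_total_flux(s1, prm))
    a1 <- animal_size_spectrum(c_a = 1, m_min = 1e-4, m_max = 2)
    af <- animal_size_spectrum(c_a = f, m_min = 1e-4, m_max = 2)
    expect_equal(animal_total_biomass(af), f * animal_total_biomass(a1))
  }
  upper <- c(1, 2, 5, 20)
  pb <- vapply(upper, function(u)
    plant_total_biomass(plant_size_spectrum(r_min = 1e-4, r_max = u)), numeric(1))
  ab <- vapply(upper, function(u)
    animal_total_biomass(animal_size_spectrum(m_min = 1e-4, m_max = u)), numeric(1))
  expect_true(all(diff(pb) > 0))
  expect_true(all(diff(ab) > 0))
})

test_that("NPP scales as the 3/5 power of biomass and linearly in r_max", {
  s <- plant_size_spectrum(c_n = 2, c_m = 5, r_min = 1e-6)
  prm <- flux_params(b_0 = 3)
  expect_equal(npp_from_biomass(0, s, prm), 0)
  m <- 10^seq(0, 3, 0.5)
  slope <- unname(coef(lm(log(npp_from_biomass(m, s, prm)) ~ log(m)))[2])
  expect_equal(slope, 0.6, tolerance = 1e-12)
  # composing with the biomass integral recovers exact linearity in r_max:
  # npp(M_tot(r_max)) = b_0 c_n r_max
  for (rm in c(0.5, 1, 4)) {
    sr <- s; sr$r_max <- rm
    expect_equal(npp_from_biomass(plant_total_biomass(sr), sr, prm),
                 prm$b_0 * sr$c_n * rm, tolerance = 1e-12)
  }
  expect_error(npp_from_biomass(-1, s, prm), "m_tot")
})

test_that("conservation gain multiplies area and maximum-size effects", {
  expect_equal(conservation_gain(2, 1, "plant"), 2)
  expect_equal(conservation_gain(2, 1, "animal"), 2)
  expect_equal(conservation_gain(1, 1, "plant"), 1)
  expect_equal(conservation_gain(2, 2, "animal"), 2 * 2^1.25, tolerance = 1e-12)
  expect_equal(conservation_gain(1, 4, "plant"), 4^0.625, tolerance = 1e-12)
  expect_error(conservation_gain(0, 1, "plant"), "> 0")
})

test_that("metabolic rate: mass power law, endothermy, activity", {
  prm <- metabolic_params(normalization_field = 2, normalization_basal = 1)
  expect_equal(metabolic_rate(2, 293, params = prm) /
                 metabolic_rate(1, 293, params = prm), 2^0.75,
               tolerance = 1e-12)
  # endotherms regulate to 310 K regardless of ambient
  expect_equal(metabolic_rate(50, 280, is_endotherm = TRUE, params = prm),
               metabolic_rate(50, 310, is_endotherm = TRUE, params = prm))
  # ectotherms respond to ambient temperature
  expect_lt(metabolic_rate(50, 280, is_endotherm = FALSE, params = prm),
            metabolic_rate(50, 310, is_endotherm = FALSE, params = prm))
  # equal normalizations make activity state irrelevant
  eq <- metabolic_params(normalization_field = 1, normalization_basal = 1)
  expect_equal(metabolic_rate(10, 300, is_active = TRUE, params = eq),
               metabolic_rate(10, 300, is_active = FALSE, params = eq))
  expect_error(metabolic_rate(-1, 300, params = prm), "mass")
  expect_error(metabolic_rate(1, 150, params = prm), "temperature")
  expect_error(metabolic_params(normalization_field = 1,
                                normalization_basal = 2), "normalization")
})
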