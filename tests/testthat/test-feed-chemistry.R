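test_that("compound compositions derive their molar weight from the indices", {
  carb <- compound_composition(n_H = 2, n_O = 1, n_N = 0, mu = 525e3, d = 1.55)
  expect_equal(carb$w, 30)                      # glucose monomer CH2O
  lib <- compound_library()
  for (cmp in lib) {
    expect_equal(cmp$w, 12 + cmp$n_H + 16 * cmp$n_O + 14 * cmp$n_N,
                 tolerance = 1e-12)
  }
  expect_equal(lib$lipid$n_N, 0)                # lipids carry no nitrogen
  expect_error(compound_composition(-0.1, 1, 0, 1e5, 1), "invalid composition")
  expect_error(compound_composition(2, 1, 0, -5, 1), "invalid composition")
})

test_that("compound library overrides apply and round-trip through YAML", {
  lib <- compound_library(overrides = list(protein = list(n_N = 0.2)))
  expect_equal(lib$protein$n_N, 0.2)
  expect_equal(lib$protein$n_H, compound_library()$protein$n_H)
  expect_error(compound_library(overrides = list(gluten = list(n_N = 1))),
               "unknown compound")
  # serialise, re-read, rebuild: identical values
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(lib, function(x) x[c("n_H", "n_O", "n_N", "mu", "d")]),
                   tmp)
  lib2 <- compound_library(overrides = yaml::read_yaml(tmp))
  expect_equal(lib2, lib)
})

test_that("diet_spec computes a_P, substrate mixtures and w_X on a C-mol basis", {
  d <- test_diet     # 45/22/19/14
  lib <- test_params$compounds
  cm <- c(0.45 / lib$protein$w, 0.22 / lib$lipid$w, 0.19 / lib$carbohydrate$w)
  expect_equal(d$a_P, cm[1] / sum(cm), tolerance = 1e-12)
  expect_equal(d$w_X, 0.86 / sum(cm), tolerance = 1e-12)
  # pure protein diet: single-substrate limit
  expect_equal(diet_spec(1, 0, 0, 0)$a_P, 1)
  expect_equal(diet_spec(0, 0.5, 0.5, 0)$a_P, 0)
  # 50/50 lipid:carb by C-mol: indices are the arithmetic mean
  w_l <- lib$lipid$w; w_c <- lib$carbohydrate$w  # masses giving equal C-mol
  d2 <- diet_spec(0.2, 0.8 * w_l / (w_l + w_c), 0.8 * w_c / (w_l + w_c), 0)
  expect_equal(d2$comp_XnP$n_H, (lib$lipid$n_H + lib$carbohydrate$n_H) / 2,
               tolerance = 1e-12)
  expect_equal(d2$comp_XnP$n_O, (lib$lipid$n_O + lib$carbohydrate$n_O) / 2,
               tolerance = 1e-12)
  expect_error(diet_spec(0.5, 0.2, 0.2, 0.2), "sum to 1")
  expect_error(diet_spec(0, 0, 0, 1), "degenerate")
})

test_that("gross energy is the mass-weighted combustion energy, monotone in fat", {
  coefs <- c(protein = 23.6, fat = 39.5, carb = 17.2)
  expect_equal(gross_energy_density(test_diet, coefs),
               0.45 * 23.6 + 0.22 * 39.5 + 0.19 * 17.2, tolerance = 1e-12)
  # fat <-> carb swap raises energy at fixed protein and ash
  lo <- diet_spec(0.45, 0.19, 0.22, 0.14)
  expect_gt(gross_energy_density(test_diet), gross_energy_density(lo))
  # linearity in mass fractions
  a <- diet_spec(0.3, 0.3, 0.4, 0); b <- diet_spec(0.5, 0.1, 0.4, 0)
  mid <- diet_spec(0.4, 0.2, 0.4, 0)
  expect_equal(gross_energy_density(mid),
               (gross_energy_density(a) + gross_energy_density(b)) / 2,
               tolerance = 1e-12)
})

test_that("coupling yields conserve carbon and respond to digestibility", {
  y <- test_yields
  expect_gte(y$q_P + y$q_nP, 1)
  expect_equal(y$q_P + y$q_nP - 1, y$kappa_CA, tolerance = 1e-12)
  expect_true(y$q_P > 0 && y$q_nP > 0)
  # all ADCs = 1: nothing indigestible
  d1 <- diet_spec(0.45, 0.22, 0.19, 0.14, adc = c(protein = 1, fat = 1, carb = 1))
  y1 <- coupling_yields(d1, test_params$compounds$reserve)
  expect_equal(y1$y_PE, 0)
  # faeces increases when carbohydrate (lowest ADC) replaces fat at fixed protein
  hi_carb <- diet_spec(0.45, 0.10, 0.31, 0.14)
  y_hc <- coupling_yields(hi_carb, test_params$compounds$reserve)
  expect_gt(y_hc$y_PE, y$y_PE)
  # halving all ADCs at least doubles faecal matter per mol reserve:
  # brute-force bookkeeping phi = q (1 - adc) / adc per substrate
  half <- diet_spec(0.45, 0.22, 0.19, 0.14,
                    adc = c(protein = 0.45, fat = 0.45, carb = 0.35))
  y_h <- coupling_yields(half, test_params$compounds$reserve)
  expect_gte(y_h$y_PE, 2 * y$y_PE)
  # single-substrate flag, not an error
  expect_true(coupling_yields(diet_spec(1, 0, 0, 0))$single_substrate)
  expect_true(coupling_yields(diet_spec(0, 0.6, 0.4, 0))$single_substrate)
})

test_that("carbon surplus of the yields equals the assimilation CO2 coefficient", {
  # C entering per C-mol reserve (absorbed + faecal drain) must equal
  # C leaving (reserve + faeces + assimilation CO2), element by element
  for (d in list(test_diet, diet_spec(0.3, 0.38, 0.19, 0.13),
                 diet_spec(0.6, 0.2, 0.1, 0.1))) {
    y <- coupling_yields(d, test_params$compounds$reserve)
    c_in <- y$q_P + y$phi_P + y$q_nP + y$phi_nP
    c_out <- 1 + y$y_PE + y$kappa_CA
    expect_equal(c_in, c_out, tolerance = 1e-9)
  }
})

test_that("nitrogen closure puts the assimilation N surplus into faeces", {
  y <- test_yields
  n_in <- y$q_P * test_diet$comp_XP$n_N + y$q_nP * test_diet$comp_XnP$n_N +
    y$phi_P * test_diet$comp_XP$n_N + y$phi_nP * test_diet$comp_XnP$n_N
  n_out <- test_params$compounds$reserve$n_N + y$y_PE * y$comp_P$n_N
  expect_equal(n_in, n_out, tolerance = 1e-12)
  expect_equal(y$n_NH3_A, 0)
  # switchable: surplus excreted as ammonia instead
  y2 <- coupling_yields(test_diet, test_params$compounds$reserve,
                        ammonia_assim = TRUE)
  expect_gt(y2$n_NH3_A, 0)
  expect_lt(y2$comp_P$n_N, y$comp_P$n_N)
})

test_that("diet files read from YAML and JSON", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(protein = 0.45, fat = 0.22, carb = 0.19, ash = 0.14,
                        moisture = 0.08,
                        adc = list(protein = 0.9, fat = 0.9, carb = 0.7),
                        densities = list(dry = 0.65)), tmp)
  d <- read_diet(tmp)
  expect_equal(d$a_P, test_diet$a_P)
  expect_equal(d$w_X, test_diet$w_X)
  tmp2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(protein = 0.3, fat = 0.38, carb = 0.19, ash = 0.13),
                       tmp2, auto_unbox = TRUE)
  expect_s3_class(read_diet(tmp2), "diet_spec")
  expect_error(read_diet("nope.txt"), "not found")
})
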