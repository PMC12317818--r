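test_that("stomach capacity follows the moisture-corrected closed form", {
  p <- test_params; d <- test_diet
  Mgm <- max_stomach_capacity(d, p)
  # forward check: dry content at capacity plus its water fills the stomach
  V <- 60
  M <- Mgm * V
  vol <- p$y_HXd * d$w_X * M / 1 + d$w_X * M / d$d_Xd
  expect_equal(vol, p$delta_g * V, tolerance = 1e-9)
  # no water displacement: capacity reduces to delta_g d_Xd / w_X
  p0 <- deb_params(y_HXd = 0)
  expect_equal(max_stomach_capacity(d, p0), p0$delta_g * d$d_Xd / d$w_X,
               tolerance = 1e-12)
  # inverse proportionality to the C-molar weight of the food
  d_half <- d; d_half$w_X <- 2 * d$w_X
  expect_equal(max_stomach_capacity(d_half, p), Mgm / 2, tolerance = 1e-12)
})

test_that("half-saturation constant follows the parallel-complementary SU form", {
  p <- test_params
  # symmetric oracle: q_P = q_nP = q and a_P = 1/2 give M_KX = 3 q ratio
  q <- 0.8
  sym_diet <- list(a_P = 0.5)
  sym_yields <- list(q_P = q, q_nP = q)
  expect_equal(half_saturation(sym_diet, sym_yields, p),
               3 * q * p$J_EAm_d / p$J_Xg_m, tolerance = 1e-12)
  # nullification at the composition boundaries
  expect_identical(half_saturation(list(a_P = 0), sym_yields, p), Inf)
  expect_identical(half_saturation(list(a_P = 1), sym_yields, p), Inf)
  # unique interior minimum over a_P at fixed yields
  y <- test_yields
  f <- function(a) half_saturation(list(a_P = a), y, p)
  grid <- seq(0.01, 0.99, length.out = 400)
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(diff(vals)); sgn <- sgn[sgn != 0]
  expect_equal(sum(diff(sgn) != 0), 1)
  opt <- stats::optimize(f, c(0.01, 0.99))
  expect_equal(grid[which.min(vals)], opt$minimum, tolerance = 5e-3)
})

test_that("functional response saturates and is nullified at infinite M_KX", {
  expect_equal(functional_response(0, 0.04), 0)
  expect_equal(functional_response(0.04, 0.04), 0.5)
  expect_equal(functional_response(5, Inf), 0)
  expect_error(functional_response(-1, 0.04), "negative")
  M <- runif(50, 0, 1)
  f <- functional_response(M, 0.04)
  expect_true(all(f >= 0 & f < 1))
})

test_that("assimilation scales with surface area and vanishes when fasting", {
  p <- test_params
  a1 <- assimilation_flux(0.6, 2, p)
  a2 <- assimilation_flux(0.6, 4, p)
  expect_equal(a2$J_EA, 4 * a1$J_EA, tolerance = 1e-12)
  expect_equal(assimilation_flux(0, 3, p)$J_EA, 0)
  expect_equal(assimilation_flux(1, 3, p)$J_EA, p$J_EAm_d * 9, tolerance = 1e-12)
  expect_equal(a1$p_A, p$mu_E * a1$J_EA, tolerance = 1e-12)
  # temperature and acceleration multiply the rate
  a3 <- assimilation_flux(0.6, 2, p, temp_factor = 0.5, s_M = 3)
  expect_equal(a3$J_EA, 1.5 * a1$J_EA, tolerance = 1e-12)
})

test_that("substrate and faeces fluxes are proportional to reserve formation", {
  y <- test_yields
  fl <- substrate_faeces_fluxes(0.02, y)
  expect_equal(fl$J_XP, y$q_P * 0.02)
  expect_equal(fl$J_XnP, y$q_nP * 0.02)
  expect_equal(fl$J_P, y$y_PE * 0.02)
  z <- substrate_faeces_fluxes(0, y)
  expect_equal(unlist(z), c(J_XP = 0, J_XnP = 0, J_P = 0))
  # the summed stomach drain matches the between-meal ODE coefficient
  L <- 3; MKX <- half_saturation(test_diet, y, test_params)
  MX <- 0.05
  fX <- functional_response(MX, MKX)
  JEA <- assimilation_flux(fX, L, test_params)$J_EA
  fl2 <- substrate_faeces_fluxes(JEA, y)
  drain <- fl2$J_XP + fl2$J_XnP + fl2$J_P
  expect_equal(stomach_ode(MX, L, y, MKX, test_params), -drain,
               tolerance = 1e-12)
})

test_that("meal intake takes the smaller of offer and stomach deficit", {
  p <- test_params; d <- test_diet
  V <- 60; W <- 150
  cap <- max_stomach_capacity(d, p) * V
  # stomach at capacity: nothing eaten
  m <- meal_intake(cap, V, W, 0.012, d, p)
  expect_equal(m$delta_M_X, 0)
  expect_equal(m$uneaten, m$offered)
  # tiny ration on empty stomach: the full offer is eaten
  m2 <- meal_intake(0, V, W, 1e-4, d, p)
  expect_equal(m2$delta_M_X, m2$offered, tolerance = 1e-15)
  # direct arithmetic: 150 g fish, 1.2 % BW meal, empty stomach
  m3 <- meal_intake(0, V, 150, 0.012, d, p)
  expect_equal(m3$delta_M_X, 0.012 * 150 * (d$d_Xd / d$d_Xw) / d$w_X,
               tolerance = 1e-12)
  # numerical overshoot clipped to zero
  m4 <- meal_intake(cap * 1.001, V, W, 0.012, d, p)
  expect_equal(m4$delta_M_X, 0)
})

test_that("between-meal trajectory matches the separable-ODE implicit solution", {
  p <- test_params; d <- test_diet; y <- test_yields
  MKX <- half_saturation(d, y, p)
  st <- initial_state_from_weight(30, 0.8, p)
  L <- st$V^(1/3)
  sM <- acceleration_factor(st$E_H, L, p)
  for (temp in c(10, 15)) {
    cT <- temperature_factor(temp + 273.15, p)
    k <- (y$q_P + y$q_nP + y$y_PE) * p$J_EAm_d * sM * cT * L^2
    ev <- evacuation_curve(30, temp, times = seq(0, 2, length.out = 21),
                           params = p, diet = d)
    M0 <- max_stomach_capacity(d, p) * st$V
    Mt <- ev$pct / 100 * M0
    lhs <- Mt - M0 + MKX * log(Mt / M0)
    expect_lt(max(abs(lhs[-1] + k * ev$time[-1]) / (k * ev$time[-1])), 1e-6)
  }
  # analytic bisection solver agrees with the integrator too
  k15 <- (y$q_P + y$q_nP + y$y_PE) * p$J_EAm_d * sM *
    temperature_factor(288.15, p) * L^2
  M0 <- max_stomach_capacity(d, p) * st$V
  ev15 <- evacuation_curve(30, 15, times = c(0, 0.5, 1), params = p, diet = d)
  Man <- nutriDEB:::stomach_drain_analytic(M0, MKX, k15, c(0.5, 1))
  expect_equal(ev15$pct[-1], 100 * Man / M0, tolerance = 1e-6)
})

test_that("stomach content is non-increasing and emptying speeds up with warmth and size", {
  p <- test_params; d <- test_diet
  e5 <- evacuation_curve(30, 5, params = p, diet = d)
  e10 <- evacuation_curve(30, 10, params = p, diet = d)
  e15 <- evacuation_curve(30, 15, params = p, diet = d)
  expect_true(all(diff(e10$pct) <= 0))
  expect_equal(e10$pct[1], 100)
  i <- e10$time > 0
  expect_true(all(e15$pct[i] < e10$pct[i]))
  expect_true(all(e10$pct[i] < e5$pct[i]))
  # time to reach 10 % of the load shortens at higher temperature
  t10 <- function(ev) ev$time[which(ev$pct <= 10)[1]]
  expect_lt(t10(e15), t10(e10))
  # larger fish empty a proportionally scaled load faster (in % terms)
  big <- evacuation_curve(70, 10, params = p, diet = d)
  expect_true(all(big$pct[i] <= e10$pct[i] + 1e-9))
  expect_lt(big$pct[sum(i)], e10$pct[sum(i)])
})
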