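test_that("feeding schedules place meals on a strict grid", {
  s <- feeding_schedule(3, 3, 0.012)
  expect_equal(nrow(s), 9)
  expect_true(all(diff(s$time) > 0))
  expect_equal(unique(s$ration), 0.012 / 3)
  expect_error(scenario(10, 150, schedule = data.frame(
    time = c(1, 1), ration = 0.01, diet_id = "diet")), "strictly increasing")
  expect_error(scenario(10, 150, schedule = data.frame(
    time = 1, ration = 0.01, diet_id = "mystery")), "unknown diet id")
})

test_that("simulation is deterministic and weight is continuous across meals", {
  p <- test_params
  scn <- fig6_scenario(duration = 5, n_fish = 1)
  s1 <- simulate_fish(scn, p)
  s2 <- simulate_fish(scn, p)
  expect_identical(s1$W_g, s2$W_g)
  expect_identical(s1$TAN_gN_per_d, s2$TAN_gN_per_d)
  # weight has no jumps at meal times (stomach excluded from body mass)
  expect_lt(max(abs(diff(s1$W_g))), 0.05 * max(s1$W_g) / 24)
  # stomach content jumps only at meals: large positive increments happen
  # exactly at scheduled times
  jumps <- which(diff(s1$M_X_mol) > 1e-4)
  jump_times <- s1$time[jumps + 1]
  expect_true(all(vapply(jump_times, function(t) {
    any(abs(scn$schedule$time - (t - 1 / 24)) < 1e-9 |
          abs(scn$schedule$time - t) < 1e-9)
  }, logical(1))))
  # maturity never decreases; stomach content never negative
  expect_true(all(diff(s1$E_H) >= 0))
  expect_true(all(s1$M_X_mol >= 0))
})

test_that("energy balance holds at every output step of a 30-day group run", {
  sim <- simulate_fish(fig6_scenario(duration = 30), test_params)
  res <- abs(sim$p_C - (sim$p_S + sim$p_J + sim$p_G + sim$p_R)) /
    pmax(sim$p_C, 1e-12)
  expect_lt(max(res), 1e-9)
})

test_that("population scaling multiplies all flux outputs exactly", {
  p <- test_params
  s1 <- simulate_fish(fig6_scenario(duration = 3, n_fish = 1), p)
  s100 <- simulate_fish(fig6_scenario(duration = 3, n_fish = 100), p)
  expect_equal(s100$TAN_gN_per_d, 100 * s1$TAN_gN_per_d, tolerance = 1e-12)
  expect_equal(s100$JO_gO2_per_d, 100 * s1$JO_gO2_per_d, tolerance = 1e-12)
  expect_equal(s100$cum_feed_eaten_g, 100 * s1$cum_feed_eaten_g,
               tolerance = 1e-12)
  expect_equal(s100$W_g, s1$W_g, tolerance = 1e-12)   # per-fish weight
})

test_that("daily output equals the aggregate of the hourly output", {
  p <- test_params
  hourly <- simulate_fish(fig6_scenario(duration = 4, n_fish = 1), p)
  daily <- aggregate_daily(hourly)
  expect_equal(nrow(daily), 4)
  day2 <- hourly$time > 1 & hourly$time <= 2
  expect_equal(daily$TAN_gN_per_d[2], mean(hourly$TAN_gN_per_d[day2]),
               tolerance = 1e-12)
  expect_equal(daily$W_g[2], hourly$W_g[max(which(day2))], tolerance = 1e-12)
  scn_daily <- fig6_scenario(duration = 4, n_fish = 1)
  scn_daily$output <- "daily"
  expect_equal(simulate_fish(scn_daily, p)$W_g, daily$W_g, tolerance = 1e-12)
})

test_that("higher feeding level gives faster growth; fasting only empties the stomach", {
  p <- test_params
  hi <- simulate_fish(fig6_scenario(duration = 15, ration = 0.012, n_fish = 1), p)
  lo <- simulate_fish(fig6_scenario(duration = 15, ration = 0.008, n_fish = 1), p)
  expect_gt(tail(hi$W_g, 1), tail(lo$W_g, 1))
  # zero-ration schedule: pure fasting
  fast_scn <- scenario(duration = 5, initial_weight = 150, temperature = 15,
                       schedule = feeding_schedule(5, 1, 0),
                       diets = list(diet = test_diet), n_fish = 1)
  fasted <- simulate_fish(fast_scn, p)
  expect_true(all(fasted$M_X_mol == 0))
  expect_true(all(fasted$f_X == 0))
  expect_true(all(fasted$p_A == 0))
  expect_lt(tail(fasted$W_g, 1), fasted$W_g[1])   # reserve burns down
  expect_gt(min(fasted$JO_gO2_per_d), 0)          # basal metabolism persists
})

test_that("meal clipping reports uneaten feed when the ration exceeds capacity", {
  p <- test_params
  glut <- simulate_fish(fig6_scenario(duration = 3, ration = 0.08, n_fish = 1), p)
  meals <- attr(glut, "meals")
  expect_gt(sum(meals$uneaten_g), 0)
  expect_true(all(meals$uneaten_g >= 0))
  expect_equal(meals$offered_g, meals$eaten_g + meals$uneaten_g,
               tolerance = 1e-12)
  # stomach never exceeds capacity after any meal
  cap <- max_stomach_capacity(test_diet, p)
  expect_true(all(meals$M_X_after <= cap * max(glut$V) + 1e-12))
})

test_that("mixed-diet meals re-pool the stomach content", {
  p <- test_params
  d2 <- diet_spec(0.3, 0.38, 0.19, 0.13, library = p$compounds)
  sched <- data.frame(time = c(0, 0.5, 1, 1.5),
                      ration = 0.006,
                      diet_id = c("a", "a", "b", "b"))
  scn <- scenario(duration = 2, initial_weight = 150, temperature = 15,
                  schedule = sched, diets = list(a = test_diet, b = d2),
                  n_fish = 1)
  sim <- simulate_fish(scn, p)
  expect_s3_class(sim, "fish_sim")
  expect_true(all(sim$M_X_mol >= 0))
  expect_gt(tail(sim$W_g, 1), sim$W_g[1])
  # single-diet run is unaffected by the re-pooling machinery
  sched_a <- sched; sched_a$diet_id <- "a"
  scn_a <- scenario(duration = 2, initial_weight = 150, temperature = 15,
                    schedule = sched_a, diets = list(a = test_diet), n_fish = 1)
  ref <- simulate_fish(scn_a, p)
  expect_false(identical(ref$TAN_gN_per_d, sim$TAN_gN_per_d))
})

test_that("reserve exhaustion truncates the run with a diagnostic", {
  p <- test_params
  scn <- scenario(duration = 400, initial_weight = 2, temperature = 15,
                  schedule = feeding_schedule(400, 1, 0),
                  diets = list(diet = test_diet), n_fish = 1, f_initial = 0.3)
  expect_warning(sim <- simulate_fish(scn, p), "reserve exhausted")
  expect_true(attr(sim, "truncated"))
  expect_lt(max(sim$time), 400)
})

test_that("assimilation response surface is nullified at the protein extremes", {
  p <- test_params
  surf <- diet_response_surface(c(0, 0.01, 0.5, 0.99, 1), 0.5, 150, 14, p)
  expect_equal(surf$assim_g_d[surf$protein == 0], 0)
  expect_equal(surf$assim_g_d[surf$protein == 1], 0)
  expect_gt(surf$assim_g_d[surf$protein == 0.5],
            3 * surf$assim_g_d[surf$protein == 0.01])
  expect_gt(surf$assim_g_d[surf$protein == 0.5],
            3 * surf$assim_g_d[surf$protein == 0.99])
  expect_true(all(surf$assim_g_d <= surf$intake_g_d + 1e-12))
  # the fat share of the non-protein component moves the curve
  s3 <- diet_response_surface(0.5, 0.3, 150, 14, p)
  s7 <- diet_response_surface(0.5, 0.7, 150, 14, p)
  expect_false(isTRUE(all.equal(s3$assim_g_d, s7$assim_g_d)))
})

test_that("energy-matched diets can still differ in intake", {
  p <- test_params
  # two ash-free diets with equal gross energy but different composition
  ge <- function(pr, fs) gross_energy_density(
    diet_spec(pr, fs * (1 - pr), (1 - fs) * (1 - pr), 0))
  target <- ge(0.45, 0.5)
  f2 <- uniroot(function(fs) ge(0.3, fs) - target, c(0.01, 0.99))$root
  i1 <- diet_response_surface(0.45, 0.5, 150, 14, p)$intake_g_d
  i2 <- diet_response_surface(0.3, f2, 150, 14, p)$intake_g_d
  expect_gt(abs(i1 - i2) / i1, 0.01)   # intake is not a function of energy alone
})
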