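# satiation feeding at fixed fish state: refill the stomach to capacity at
# each of m meals per day and measure the periodic daily intake/assimilation.
# The between-meal trajectory uses the analytic implicit solution of the
# separable stomach ODE (solved by bisection), which is smooth to machine
# precision -- important when differencing the surface on fine grids.
satiation_day <- function(diet, fish_weight, temp_C, params,
                          meals_per_day = 2, f_assumed = 0.8) {
  st <- initial_state_from_weight(fish_weight, f_assumed, params)
  L <- st$V^(1/3)
  cT <- temperature_factor(temp_C + 273.15, params)
  sM <- acceleration_factor(st$E_H, L, params)
  yields <- coupling_yields(diet, reserve = params$compounds$reserve,
                            sigma_A = params$sigma_A)
  M_KX <- half_saturation(diet, yields, params)
  cap <- max_stomach_capacity(diet, params) * st$V
  if (is.infinite(M_KX)) {
    return(list(intake_mol = 0, intake_g = 0, assim_mol = 0, assim_g = 0,
                reserve_mol = 0))
  }
  k <- drain_per_reserve(yields) * params$J_EAm_d * sM * cT * L^2
  M_end <- stomach_drain_analytic(cap, M_KX, k, 1 / meals_per_day)
  drained <- meals_per_day * (cap - M_end)      # C-mol food per day
  reserve <- drained / drain_per_reserve(yields)
  absorbed_g <- reserve * (yields$q_P * diet$comp_XP$w +
                             yields$q_nP * (if (!is.null(diet$comp_XnP))
                               diet$comp_XnP$w else 0))
  list(intake_mol = drained, intake_g = drained * diet$w_X,
       assim_mol = reserve * (yields$q_P + yields$q_nP),
       assim_g = absorbed_g, reserve_mol = reserve)
}

#' Diet-composition response surface for intake and assimilation
#'
#' For each combination of protein fraction and fat share of the non-protein
#' component, builds an ash-free diet, and computes the steady daily food
#' intake and assimilation of a fish of fixed size fed to stomach capacity
#' at each meal ("satiation"). Both are reported as ash-free dry mass
#' (g/d): intake as food leaving the stomach, assimilation as the food mass
#' actually absorbed (intake minus faecal losses), which is therefore always
#' below intake. Boundary compositions (protein fraction 0 or 1) return zero
#' assimilation, not errors: a single-substrate diet nullifies the
#' synthesising unit.
#'
#' @param protein_grid protein mass fractions of the (ash-free) dry diet
#' @param fat_share_grid fat mass share of the non-protein component
#' @param fish_weight fish wet weight, g
#' @param temp_C water temperature, deg C
#' @param params model parameters
#' @param adc apparent digestibility coefficients (protein, fat, carb)
#' @param meals_per_day meals per day used to operationalise satiation
#' @return data.frame with `protein`, `fat_share`, `a_P`, `gross_energy`,
#'   `intake_g_d`, `assim_g_d`
#' @export
diet_response_surface <- function(protein_grid, fat_share_grid,
                                  fish_weight = 150, temp_C = 14,
                                  params = deb_params(),
                                  adc = c(protein = 0.9, fat = 0.9, carb = 0.7),
                                  meals_per_day = 2) {
  stopifnot(all(protein_grid >= 0), all(protein_grid <= 1),
            all(fat_share_grid >= 0), all(fat_share_grid <= 1))
  grid <- expand.grid(protein = protein_grid, fat_share = fat_share_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$protein[i]; fs <- grid$fat_share[i]
    if (p <= 0 || p >= 1) {
      # single-substrate limit: build the diet at the boundary if possible,
      # assimilation is zero by the SU nullification
      ge <- if (p >= 1) {
        gross_energy_density(diet_spec(1, 0, 0, 0))
      } else {
        gross_energy_density(diet_spec(0, fs, 1 - fs, 0))
      }
      return(data.frame(a_P = as.numeric(p >= 1), gross_energy = ge,
                        intake_g_d = 0, assim_g_d = 0))
    }
    d <- diet_spec(p, fs * (1 - p), (1 - fs) * (1 - p), 0, adc = adc,
                   library = params$compounds)
    s <- satiation_day(d, fish_weight, temp_C, params, meals_per_day)
    data.frame(a_P = d$a_P, gross_energy = d$gross_energy,
               intake_g_d = s$intake_g, assim_g_d = s$assim_g)
  })
  cbind(grid, do.call(rbind, res))
}

#' Satiation intake versus dietary gross energy
#'
#' Sweeps the fat share of the non-protein component at one or more fixed
#' protein levels and reports the satiation intake against the gross energy
#' density of each diet. Diets low in energy require higher intake to fill
#' the same stomach volume and digest faster per unit energy, so intake
#' decreases as gross energy rises within each protein level.
#'
#' @param fat_shares fat shares of the non-protein component to sweep
#' @param protein_levels protein mass fractions (one curve each)
#' @inheritParams diet_response_surface
#' @return data.frame with `protein`, `fat_share`, `gross_energy`,
#'   `intake_g_d`, `assim_g_d`
#' @export
intake_vs_energy <- function(fat_shares = seq(0.2, 0.8, by = 0.05),
                             protein_levels = c(0.3, 0.6),
                             fish_weight = 150, temp_C = 14,
                             params = deb_params(),
                             adc = c(protein = 0.9, fat = 0.9, carb = 0.7),
                             meals_per_day = 2) {
  out <- diet_response_surface(protein_levels, fat_shares, fish_weight,
                               temp_C, params, adc, meals_per_day)
  out[order(out$protein, out$fat_share),
      c("protein", "fat_share", "gross_energy", "intake_g_d", "assim_g_d")]
}

#' Gastric evacuation curve
#'
#' Stomach content as a percentage of the initial load versus time since
#' feeding stopped, for a fish of fixed size at constant temperature (no
#' meals, growth over the window neglected). Integrated with
#' [deSolve::lsoda] at tight tolerance.
#'
#' @param fish_weight fish wet weight, g
#' @param temp_C temperature, deg C
#' @param times output times, d
#' @param initial_load initial stomach fill as a fraction of capacity
#' @param params model parameters
#' @param diet a [diet_spec()]
#' @param f_assumed assumed functional response for sizing the fish
#' @return data.frame with `time` (d) and `pct` (% of initial content),
#'   monotone decreasing from 100
#' @export
evacuation_curve <- function(fish_weight, temp_C, times = seq(0, 5, by = 0.05),
                             initial_load = 1, params = deb_params(),
                             diet = diet_spec(0.45, 0.22, 0.19, 0.14,
                                              library = params$compounds),
                             f_assumed = 0.8) {
  stopifnot(initial_load > 0, initial_load <= 1, all(times >= 0))
  st <- initial_state_from_weight(fish_weight, f_assumed, params)
  L <- st$V^(1/3)
  cT <- temperature_factor(temp_C + 273.15, params)
  sM <- acceleration_factor(st$E_H, L, params)
  yields <- coupling_yields(diet, reserve = params$compounds$reserve,
                            sigma_A = params$sigma_A)
  M_KX <- half_saturation(diet, yields, params)
  M0 <- initial_load * max_stomach_capacity(diet, params) * st$V
  times <- sort(unique(c(0, times)))
  rate <- function(t, y, p) {
    list(stomach_ode(max(y, 0), L, yields, M_KX, params,
                     temp_factor = cT, s_M = sM))
  }
  sol <- deSolve::lsoda(c(M_X = M0), times, rate, parms = NULL,
                        rtol = 1e-10, atol = 1e-14 * M0)
  data.frame(time = sol[, "time"], pct = 100 * pmax(sol[, "M_X"], 0) / M0)
}
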