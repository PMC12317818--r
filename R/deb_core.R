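#' Arrhenius temperature correction factor
#'
#' One-parameter Arrhenius correction applied to every rate parameter:
#' `exp(T_A / T_ref - T_A / T)`. Equals 1 at the reference temperature.
#'
#' @param T_K body temperature, K
#' @param params model parameters (uses `T_A`, `T_ref`)
#' @return dimensionless multiplier
#' @export
temperature_factor <- function(T_K, params) {
  stopifnot(all(T_K > 0))
  exp(params$T_A / params$T_ref - params$T_A / T_K)
}

#' abj metabolic acceleration factor
#'
#' Surface-specific assimilation and conductance accelerate with length
#' between birth and metamorphosis: `s_M = 1` before birth, `L / L_b` while
#' `E_Hb <= E_H < E_Hj`, and frozen at `L_j / L_b` afterwards.
#'
#' @param E_H cumulative maturity, J
#' @param L structural length, cm
#' @param params model parameters (uses `E_Hb`, `E_Hj`, `L_b`, `L_j`)
#' @return `s_M`, dimensionless
#' @export
acceleration_factor <- function(E_H, L, params) {
  if (E_H < params$E_Hb) return(1)
  if (E_H < params$E_Hj) return(max(1, min(L, params$L_j) / params$L_b))
  params$L_j / params$L_b
}

#' Construct a fish state
#'
#' @param V structural volume, cm^3
#' @param E reserve energy, J
#' @param E_H cumulative maturity, J
#' @param E_R reproduction buffer, J
#' @param M_X stomach content, mol ash-free dry food
#' @return object of class `fish_state`
#' @export
fish_state <- function(V, E, E_H, E_R = 0, M_X = 0) {
  stopifnot(V > 0, E >= 0, E_H >= 0, E_R >= 0, M_X >= 0)
  structure(list(V = V, E = E, E_H = E_H, E_R = E_R, M_X = M_X),
            class = "fish_state")
}

#' @export
print.fish_state <- function(x, ...) {
  cat(sprintf("Fish state: V = %.3g cm3 (L = %.3g cm), E = %.4g J, E_H = %.4g J, E_R = %.4g J, M_X = %.3g mol\n",
              x$V, x$V^(1/3), x$E, x$E_H, x$E_R, x$M_X))
  invisible(x)
}

#' DEB energy fluxes (powers)
#'
#' Standard DEB kappa-rule energetics with abj acceleration. Reserve is
#' mobilised at
#' `p_C = E/V * (E_G * s_M * v * c_T / L + p_M * c_T) * V / (E_G + kappa * E/V)`;
#' a fraction `kappa` covers somatic maintenance `p_S` and growth `p_G`, the
#' remainder covers maturity maintenance `p_J` and maturation/reproduction
#' `p_R`. If mobilisation cannot cover a maintenance cost, maintenance is
#' paid in full, the corresponding growth/maturation flux is zero and the
#' shortfall is drawn from reserve (flagged `starved`; no shrinking rules).
#' Dissipation is `p_S + p_J + p_R` before puberty and
#' `p_S + p_J + (1 - kappa_R) p_R` for adults.
#'
#' @param state a [fish_state()]
#' @param f_X scaled functional response from the digestion module
#' @param T_K temperature, K
#' @param params model parameters
#' @return named numeric with `p_A`, `p_C`, `p_S`, `p_J`, `p_G`, `p_R`,
#'   `p_D` (J/d) and attribute `starved`
#' @export
deb_fluxes <- function(state, f_X, T_K, params) {
  cT <- temperature_factor(T_K, params)
  L <- state$V^(1/3)
  sM <- acceleration_factor(state$E_H, L, params)
  p_A <- assimilation_flux(f_X, L, params, temp_factor = cT, s_M = sM)$p_A
  fl <- deb_powers(state$V, state$E, state$E_H, p_A, cT, sM, params)
  fl
}

# core power computation given p_A already known (internal fast path)
deb_powers <- function(V, E, E_H, p_A, cT, sM, params) {
  V <- unname(V); E <- unname(E); E_H <- unname(E_H); p_A <- unname(p_A)
  L <- V^(1/3)
  Ev <- E / V                                     # reserve density, J/cm^3
  p_C <- Ev * (params$E_G * sM * params$v * cT / L + params$p_M * cT) * V /
    (params$E_G + params$kappa * Ev)
  p_S <- params$p_M * cT * V
  p_J <- params$k_J * cT * E_H
  p_G <- params$kappa * p_C - p_S
  p_R <- (1 - params$kappa) * p_C - p_J
  starved <- p_G < 0 || p_R < 0
  if (p_G < 0) p_G <- 0
  if (p_R < 0) p_R <- 0
  adult <- E_H >= params$E_Hp
  p_D <- if (adult) p_S + p_J + (1 - params$kappa_R) * p_R else p_S + p_J + p_R
  # mobilisation consistent with the clamps so the energy balance
  # p_C = p_S + p_J + p_G + p_R holds identically
  p_C <- p_S + p_J + p_G + p_R
  out <- c(p_A = p_A, p_C = p_C, p_S = p_S, p_J = p_J, p_G = p_G,
           p_R = p_R, p_D = p_D)
  attr(out, "starved") <- starved
  out
}

#' State derivatives of the DEB core
#'
#' `dE = p_A - p_C`; `dV = p_G / E_G`; maturation accumulates until puberty
#' after which `kappa_R p_R` fills the reproduction buffer.
#'
#' @param state a [fish_state()]
#' @param fluxes powers from [deb_fluxes()]
#' @param params model parameters
#' @return named numeric `dV`, `dE`, `dE_H`, `dE_R` (per day)
#' @export
state_derivatives <- function(state, fluxes, params) {
  adult <- state$E_H >= params$E_Hp
  c(dV = unname(fluxes["p_G"]) / params$E_G,
    dE = unname(fluxes["p_A"] - fluxes["p_C"]),
    dE_H = if (adult) 0 else unname(fluxes["p_R"]),
    dE_R = if (adult) params$kappa_R * unname(fluxes["p_R"]) else 0)
}

#' Wet weight of a fish
#'
#' `W = d_Vw V + (E + E_R) w_Ed / (d_Ed mu_E)`: structure at its wet density
#' plus the wet volume occupied by reserve (dry reserve mass over its
#' dry-per-wet-volume density, times the 1 g/cm^3 density of water). Stomach
#' content is part of the environment and excluded.
#'
#' @param state a [fish_state()]
#' @param params model parameters
#' @return wet weight, g
#' @export
wet_weight <- function(state, params) {
  params$d_Vw * state$V +
    (state$E + state$E_R) * params$w_Ed / (params$d_Ed * params$mu_E)
}

#' Integrate the DEB core at a fixed functional response
#'
#' Bypasses the stomach and drives assimilation with a constant `f`, the
#' classical DEB configuration. At constant temperature and past
#' metamorphosis the length trajectory follows the von Bertalanffy closed
#' form `L(t) = L_inf - (L_inf - L_0) exp(-r_B t)` with
#' `L_inf = kappa f s_M p_Am / p_M` and
#' `r_B = p_M c_T / (3 (E_G + kappa f [E_m]))`, which serves as an analytic
#' reference for the integrator.
#'
#' @param state0 initial [fish_state()]
#' @param f constant functional response in `[0, 1]`
#' @param T_C temperature, deg C
#' @param duration length of the run, d
#' @param params model parameters
#' @param dt output step, d
#' @return data.frame with `time`, `V`, `E`, `E_H`, `E_R`, `L_cm`, `W_g`
#' @export
simulate_constant_f <- function(state0, f, T_C, duration, params,
                                dt = 0.25) {
  TK <- T_C + 273.15
  deriv <- function(t, y, parms) {
    L <- y[1]^(1/3)
    cT <- temperature_factor(TK, params)
    sM <- acceleration_factor(y[3], L, params)
    p_A <- params$mu_E * params$J_EAm_d * sM * cT * f * L^2
    fl <- deb_powers(y[1], y[2], y[3], p_A, cT, sM, params)
    adult <- y[3] >= params$E_Hp
    list(c(fl["p_G"] / params$E_G, fl["p_A"] - fl["p_C"],
           if (adult) 0 else fl["p_R"],
           if (adult) params$kappa_R * fl["p_R"] else 0))
  }
  y0 <- c(V = state0$V, E = state0$E, E_H = state0$E_H, E_R = state0$E_R)
  sol <- as.data.frame(deSolve::lsoda(y0, seq(0, duration, by = dt), deriv,
                                      parms = NULL, rtol = 1e-10,
                                      atol = 1e-8))
  sol$L_cm <- sol$V^(1/3)
  sol$W_g <- params$d_Vw * sol$V +
    (sol$E + sol$E_R) * params$w_Ed / (params$d_Ed * params$mu_E)
  sol
}

#' Initialise a fish state from its wet weight
#'
#' Sets the reserve density to the equilibrium for an assumed functional
#' response (`E = f [E_m] V` with `[E_m] = p_Am / v`), solves the wet-weight
#' relation for `V`, and assigns a maturity level consistent with the size
#' (scaled cubically between the stage thresholds, capped at puberty). The
#' stomach starts empty.
#'
#' @param W0 initial wet weight, g
#' @param f_assumed assumed functional response in `(0, 1]`
#' @param params model parameters
#' @return a [fish_state()]
#' @export
initial_state_from_weight <- function(W0, f_assumed = 0.8, params = deb_params()) {
  stopifnot(W0 > 0, f_assumed > 0, f_assumed <= 1)
  Em <- params$p_Am / params$v                  # maximum reserve density, J/cm^3
  coef <- f_assumed * Em * params$w_Ed / (params$d_Ed * params$mu_E)
  V <- W0 / (params$d_Vw + coef)
  L <- V^(1/3)
  W_b <- (params$d_Vw + coef) * params$L_b^3
  if (W0 < W_b) {
    stop(sprintf("initial weight %.3g g is below the weight at birth (~%.3g g)",
                 W0, W_b), call. = FALSE)
  }
  E_H <- if (L >= params$L_j) {
    min(params$E_Hp, params$E_Hj * (L / params$L_j)^3)
  } else {
    max(params$E_Hb, params$E_Hj * (L / params$L_j)^3)
  }
  fish_state(V = V, E = f_assumed * Em * V, E_H = E_H, E_R = 0, M_X = 0)
}
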