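#' Volume-specific maximum stomach capacity
#'
#' The stomach holds dry food plus the water needed to moisturise it
#' (`y_HXd` g water per g dry food). At capacity the combined volume of the
#' dry matter and its water equals the stomach volume `delta_g * V`, which
#' gives the closed form
#' `[M_gm] = (y_HXd d_Xd / d_H + 1)^-1 * d_Xd / w_X * delta_g`
#' with `d_H = 1` g/cm^3 the density of water. The capacity therefore depends
#' on the food's density and C-molar weight, not only on stomach geometry.
#'
#' @param diet a [diet_spec()]
#' @param params model parameters (uses `delta_g`, `y_HXd`)
#' @return `[M_gm]`, mol of ash-free dry food per cm^3 of structure
#' @export
max_stomach_capacity <- function(diet, params) {
  stopifnot(inherits(diet, "diet_spec"))
  d_H <- 1
  (params$y_HXd * diet$d_Xd / d_H + 1)^-1 * diet$d_Xd / diet$w_X * params$delta_g
}

#' Half-saturation stomach content of the digestion SU
#'
#' Parallel-complementary synthesising-unit kinetics for the two food
#' substrates give a hyperbolic functional response in stomach content with
#' half-saturation constant
#' `M_KX = (J_EAm_d / J_Xg_m) * (A + B - (A^-1 + B^-1)^-1)`,
#' where `A = q_P / a_P` and `B = q_nP / (1 - a_P)`.
#'
#' Note on the closed form: the bracket grouping above is the standard
#' parallel-complementary SU expression and is the reading adopted here; it
#' is the unique grouping that nullifies assimilation (`M_KX -> Inf`) for
#' diets containing only one of the two substrates (`a_P` of 0 or 1), which
#' is the documented limiting behaviour of the model.
#'
#' @param diet a [diet_spec()]
#' @param yields a [coupling_yields()]
#' @param params model parameters (uses `J_EAm_d`, `J_Xg_m`)
#' @return half-saturation constant, mol (Inf for single-substrate diets)
#' @export
half_saturation <- function(diet, yields, params) {
  a_P <- diet$a_P
  if (a_P <= 0 || a_P >= 1) return(Inf)
  A <- yields$q_P / a_P
  B <- yields$q_nP / (1 - a_P)
  (params$J_EAm_d / params$J_Xg_m) * (A + B - 1 / (1 / A + 1 / B))
}

#' Scaled functional response for digestion
#'
#' @param M_X stomach content, mol (>= 0)
#' @param M_KX half-saturation constant, mol (may be Inf)
#' @return `f_X = M_X / (M_X + M_KX)` in `[0, 1)`
#' @export
functional_response <- function(M_X, M_KX) {
  if (any(M_X < 0)) stop("stomach content cannot be negative", call. = FALSE)
  ifelse(is.infinite(M_KX), 0, M_X / (M_X + M_KX))
}

#' Assimilation flux
#'
#' Reserve formation scales with the digestion functional response and the
#' squared structural length: `J_EA = J_EAm_d * s_M * c_T * f_X * L^2`,
#' with the abj acceleration factor `s_M` and Arrhenius correction `c_T`
#' multiplying the surface-specific maximum rate. The energy flux is
#' `p_A = mu_E * J_EA`.
#'
#' @param f_X functional response in `[0, 1]`
#' @param L structural length, cm
#' @param params model parameters (uses `J_EAm_d`, `mu_E`)
#' @param temp_factor Arrhenius temperature factor
#' @param s_M metabolic acceleration factor
#' @return list with `J_EA` (mol reserve/d) and `p_A` (J/d)
#' @export
assimilation_flux <- function(f_X, L, params, temp_factor = 1, s_M = 1) {
  stopifnot(f_X >= 0, f_X <= 1, L > 0)
  J_EA <- params$J_EAm_d * s_M * temp_factor * f_X * L^2
  list(J_EA = J_EA, p_A = params$mu_E * J_EA)
}

#' Substrate-use and faeces-production fluxes
#'
#' All three fluxes are proportional to the reserve-formation rate:
#' absorbed protein `q_P * J_EA`, absorbed non-protein `q_nP * J_EA`, and
#' faeces `y_PE * J_EA`.
#'
#' @param J_EA reserve formation rate, mol/d
#' @param yields a [coupling_yields()]
#' @return list with `J_XP` and `J_XnP` (mol substrate/d) and `J_P`
#'   (C-mol faeces/d)
#' @export
substrate_faeces_fluxes <- function(J_EA, yields) {
  stopifnot(J_EA >= 0)
  list(J_XP = yields$q_P * J_EA,
       J_XnP = yields$q_nP * J_EA,
       J_P = yields$y_PE * J_EA)
}

#' Meal intake
#'
#' A meal offers `k_X * W` grams of as-fed feed, converted to ash-free dry
#' moles by the dry:wet density ratio and `w_X`. The amount actually eaten is
#' the smaller of the offer and the remaining stomach deficit; the stomach
#' content jumps instantaneously by that amount and the difference is logged
#' as uneaten feed.
#'
#' @param M_X current stomach content, mol
#' @param V structural volume, cm^3
#' @param W wet body weight, g
#' @param k_X meal ration as fraction of body weight
#' @param diet a [diet_spec()]
#' @param params model parameters
#' @return list with `delta_M_X` (mol eaten), `offered` and `uneaten` (mol),
#'   and `offered_g` (g as-fed)
#' @export
meal_intake <- function(M_X, V, W, k_X, diet, params) {
  stopifnot(k_X >= 0, V > 0, W > 0)
  cap <- max_stomach_capacity(diet, params) * V
  deficit <- cap - M_X
  if (deficit < 0) deficit <- 0   # numerical overshoot: clip
  offered_g <- k_X * W
  offered <- offered_g * (diet$d_Xd / diet$d_Xw) / diet$w_X
  eaten <- min(deficit, offered)
  list(delta_M_X = eaten, offered = offered, uneaten = offered - eaten,
       offered_g = offered_g)
}

#' Between-meal stomach dynamics
#'
#' Between meals the stomach only empties, at the combined rate of substrate
#' absorption and faeces production:
#' `dM_X/dt = -(q_P + q_nP + y_PE) * J_EAm_d * s_M * c_T * f_X * L^2`.
#'
#' @param M_X stomach content, mol
#' @param L structural length, cm
#' @param yields a [coupling_yields()]
#' @param M_KX half-saturation constant (from [half_saturation()])
#' @param params model parameters
#' @param temp_factor Arrhenius temperature factor
#' @param s_M metabolic acceleration factor
#' @return dM_X/dt, mol/d (<= 0)
#' @export
stomach_ode <- function(M_X, L, yields, M_KX, params, temp_factor = 1, s_M = 1) {
  if (M_X <= 0) return(0)
  f_X <- functional_response(M_X, M_KX)
  -drain_per_reserve(yields) * params$J_EAm_d * s_M * temp_factor * f_X * L^2
}

# Analytic between-meal trajectory for constant L: the separable ODE has the
# implicit solution M - M0 + M_KX log(M / M0) = -k t with
# k = (q_P + q_nP + y_PE) J_EAm_d s_M c_T L^2. Solved by bisection to high
# precision; used by the response-surface code where smoothness matters.
stomach_drain_analytic <- function(M0, M_KX, k, t) {
  if (M0 <= 0 || k <= 0) return(rep(M0, length(t)))
  if (is.infinite(M_KX)) return(rep(M0, length(t)))
  vapply(t, function(ti) {
    if (ti <= 0) return(M0)
    g <- function(M) M - M0 + M_KX * log(M / M0) + k * ti
    lo <- M0 * 1e-15
    if (g(lo) > 0) return(lo)
    stats::uniroot(g, c(lo, M0), tol = M0 * 1e-14)$root
  }, numeric(1))
}
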