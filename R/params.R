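#' Construct a full model parameter set
#'
#' Bundles the core DEB abj parameters with the digestion parameters and the
#' compound library. Units are fixed throughout the package: J, mol, cm, g, d
#' and K; conversions happen only at the I/O boundary. Rate parameters are
#' stated at the reference temperature `T_ref`.
#'
#' `J_EAm_d` defaults to `p_Am / mu_E`, keeping the energy and molar
#' descriptions of maximum assimilation consistent; supply it explicitly to
#' decouple them.
#'
#' @param p_Am surface-specific maximum assimilation rate, J/d/cm^2
#'   (before acceleration)
#' @param v energy conductance, cm/d
#' @param kappa fraction of mobilised reserve allocated to soma
#' @param p_M volume-specific somatic maintenance, J/d/cm^3
#' @param E_G volume-specific cost of structure, J/cm^3
#' @param k_J maturity maintenance rate coefficient, 1/d
#' @param kappa_R reproduction efficiency
#' @param E_Hb,E_Hj,E_Hp maturity thresholds at birth, metamorphosis and
#'   puberty, J
#' @param L_b,L_j structural lengths at birth and metamorphosis, cm (fixture
#'   values consistent with the maturity thresholds; they anchor the abj
#'   acceleration factor)
#' @param T_A Arrhenius temperature, K
#' @param T_ref reference temperature, K
#' @param mu_E chemical potential of reserve, J/mol
#' @param w_Ed C-molar weight of dry reserve, g/mol (derived from the reserve
#'   composition when `NULL`)
#' @param d_Vw specific density of wet structure, g/cm^3
#' @param d_Ed specific density of dry reserve (dry mass per wet reserve
#'   volume), g/cm^3
#' @param d_Vd specific density of dry structure, g/cm^3
#' @param J_EAm_d surface-specific maximum assimilation rate, mol/d/cm^2
#' @param J_Xg_m surface-specific maximum digestion rate coefficient,
#'   1/d/cm^2
#' @param delta_g stomach shape coefficient (stomach volume / structural
#'   volume)
#' @param y_HXd g water added in the stomach per g ingested dry food
#' @param sigma_A assimilation overhead: C-mol substrate respired as CO2 per
#'   C-mol reserve formed
#' @param compounds compound library from [compound_library()]
#' @return object of class `deb_params`
#' @export
deb_params <- function(p_Am = 1200, v = 0.15, kappa = 0.75, p_M = 106,
                       E_G = 5220, k_J = 0.002, kappa_R = 0.95,
                       E_Hb = 60, E_Hj = 700, E_Hp = 3e5,
                       L_b = 0.4, L_j = 1.2,
                       T_A = 8000, T_ref = 288.15,
                       mu_E = 550000, w_Ed = NULL,
                       d_Vw = 1.0, d_Ed = 0.2, d_Vd = 0.2,
                       J_EAm_d = NULL, J_Xg_m = 0.098,
                       delta_g = 0.12, y_HXd = 0.8425, sigma_A = 0.2,
                       compounds = compound_library()) {
  if (is.null(w_Ed)) w_Ed <- compounds$reserve$w
  if (is.null(J_EAm_d)) J_EAm_d <- p_Am / mu_E
  p <- structure(
    list(p_Am = p_Am, v = v, kappa = kappa, p_M = p_M, E_G = E_G, k_J = k_J,
         kappa_R = kappa_R, E_Hb = E_Hb, E_Hj = E_Hj, E_Hp = E_Hp,
         L_b = L_b, L_j = L_j, T_A = T_A, T_ref = T_ref,
         mu_E = mu_E, w_Ed = w_Ed, d_Vw = d_Vw, d_Ed = d_Ed, d_Vd = d_Vd,
         J_EAm_d = J_EAm_d, J_Xg_m = J_Xg_m, delta_g = delta_g,
         y_HXd = y_HXd, sigma_A = sigma_A, compounds = compounds),
    class = "deb_params"
  )
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of all rates and densities, the ordering of maturity
#' thresholds, `0 < kappa < 1`, and that the growth reaction is chemically
#' feasible (structure formed per J of growth must not contain more carbon
#' than the reserve spent on it).
#'
#' @param params a `deb_params` object
#' @return the parameter set, invisibly; errors on violation
#' @export
validate_params <- function(params) {
  with(params, {
    pos <- c(p_Am = p_Am, v = v, p_M = p_M, E_G = E_G, k_J = k_J,
             T_A = T_A, T_ref = T_ref, mu_E = mu_E, w_Ed = w_Ed,
             d_Vw = d_Vw, d_Ed = d_Ed, d_Vd = d_Vd,
             J_EAm_d = J_EAm_d, J_Xg_m = J_Xg_m, delta_g = delta_g,
             L_b = L_b, L_j = L_j)
    if (any(pos <= 0)) {
      stop("non-positive parameter(s): ",
           paste(names(pos)[pos <= 0], collapse = ", "), call. = FALSE)
    }
    if (y_HXd < 0) stop("y_HXd must be non-negative", call. = FALSE)
    if (kappa <= 0 || kappa >= 1) stop("kappa must lie in (0, 1)", call. = FALSE)
    if (kappa_R < 0 || kappa_R > 1) stop("kappa_R must lie in [0, 1]", call. = FALSE)
    if (!(E_Hb < E_Hj && E_Hj < E_Hp)) {
      stop("maturity thresholds must satisfy E_Hb < E_Hj < E_Hp", call. = FALSE)
    }
    if (L_b >= L_j) stop("L_b must be smaller than L_j", call. = FALSE)
    M_V <- d_Vd / compounds$structure$w      # mol structure per cm^3
    if (M_V / E_G >= 1 / mu_E) {
      stop("infeasible growth stoichiometry: structure carbon per J of growth ",
           "exceeds reserve carbon spent (check d_Vd, E_G, mu_E)", call. = FALSE)
    }
  })
  invisible(params)
}

#' @export
print.deb_params <- function(x, ...) {
  cat("DEB abj + digestion parameter set (rates at T_ref =",
      sprintf("%.2f K)\n", x$T_ref))
  cat(sprintf("  core:      p_Am = %.4g J/d/cm2, v = %.3g cm/d, kappa = %.3g, p_M = %.4g J/d/cm3\n",
              x$p_Am, x$v, x$kappa, x$p_M))
  cat(sprintf("             E_G = %.4g J/cm3, k_J = %.3g 1/d, E_Hb/E_Hj/E_Hp = %.3g/%.3g/%.3g J\n",
              x$E_G, x$k_J, x$E_Hb, x$E_Hj, x$E_Hp))
  cat(sprintf("  digestion: J_EAm_d = %.4g mol/d/cm2, J_Xg_m = %.4g 1/d/cm2, delta_g = %.3g, y_HXd = %.4g\n",
              x$J_EAm_d, x$J_Xg_m, x$delta_g, x$y_HXd))
  invisible(x)
}

#' Read a parameter file
#'
#' Reads a YAML or JSON parameter file (by extension) whose keys mirror the
#' arguments of [deb_params()]; an optional `compounds` block overrides
#' library entries as in [compound_library()]. Missing keys fall back to the
#' bundled defaults.
#'
#' @param path file path (.yaml/.yml or .json)
#' @return a `deb_params` object
#' @export
read_params <- function(path) {
  vals <- read_config(path)
  comp <- NULL
  if (!is.null(vals$compounds)) {
    comp <- compound_library(overrides = vals$compounds)
    vals$compounds <- NULL
  }
  args <- vals[names(vals) %in% names(formals(deb_params))]
  if (!is.null(comp)) args$compounds <- comp
  do.call(deb_params, args)
}

#' Read a diet file
#'
#' Reads a YAML or JSON diet description with keys `protein`, `fat`, `carb`,
#' `ash`, `moisture`, an `adc` block (`protein`, `fat`, `carb`) and an
#' optional `densities` block (`dry`, `wet`).
#'
#' @param path file path (.yaml/.yml or .json)
#' @param library compound library
#' @return a `diet_spec` object
#' @export
read_diet <- function(path, library = compound_library()) {
  v <- read_config(path)
  adc <- c(protein = 0.9, fat = 0.9, carb = 0.7)
  if (!is.null(v$adc)) adc[names(v$adc)] <- unlist(v$adc)
  args <- list(protein = v$protein, fat = v$fat, carb = v$carb,
               ash = if (is.null(v$ash)) 0 else v$ash,
               adc = adc, library = library)
  if (!is.null(v$moisture)) args$moisture <- v$moisture
  if (!is.null(v$densities$dry)) args$d_Xd <- v$densities$dry
  if (!is.null(v$densities$wet)) args$d_Xw <- v$densities$wet
  do.call(diet_spec, args)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use YAML or JSON)", call. = FALSE)
  }
}
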