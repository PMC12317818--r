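#' Generalised-compound composition
#'
#' Describes a generalised organic compound (protein, lipid, carbohydrate,
#' reserve, structure, faeces) by its chemical indices relative to carbon:
#' the molecule is written CH_nH O_nO N_nN, one C-mol at a time. The C-molar
#' weight `w` is always derived from the indices (12 + n_H + 16 n_O + 14 n_N),
#' never supplied.
#'
#' @param n_H mol H per mol C (>= 0)
#' @param n_O mol O per mol C (>= 0)
#' @param n_N mol N per mol C (>= 0)
#' @param mu chemical potential, J per C-mol (> 0)
#' @param d specific density, g/cm^3 (> 0)
#' @return object of class `compound_composition`: list with fields
#'   `n_H`, `n_O`, `n_N`, `mu`, `d` and the derived C-molar weight `w` (g/mol)
#' @examples
#' glucose_monomer <- compound_composition(n_H = 2, n_O = 1, n_N = 0,
#'                                         mu = 525e3, d = 1.55)
#' glucose_monomer$w  # 30 g per C-mol
#' @export
compound_composition <- function(n_H, n_O, n_N, mu, d) {
  if (any(c(n_H, n_O, n_N) < 0)) {
    stop("invalid composition: chemical indices must be non-negative", call. = FALSE)
  }
  if (!is.finite(mu) || mu <= 0) {
    stop("invalid composition: chemical potential must be positive", call. = FALSE)
  }
  if (!is.finite(d) || d <= 0) {
    stop("invalid composition: specific density must be positive", call. = FALSE)
  }
  structure(
    list(n_H = n_H, n_O = n_O, n_N = n_N, mu = mu, d = d,
         w = 12 + n_H * 1 + n_O * 16 + n_N * 14),
    class = "compound_composition"
  )
}

#' @export
print.compound_composition <- function(x, ...) {
  cat(sprintf("CH_%.3g O_%.3g N_%.3g  (w = %.4g g/C-mol, mu = %.4g kJ/C-mol, d = %.3g g/cm3)\n",
              x$n_H, x$n_O, x$n_N, x$w, x$mu / 1000, x$d))
  invisible(x)
}

#' Default library of generalised compounds
#'
#' Returns the compositions used for the two food substrates (generalised
#' protein and the lipid/carbohydrate pool), plus reserve and structure.
#' The shipped values are conventional indices for generalised macronutrients
#' and biomass; they are configuration, not measurements, and any entry may be
#' overridden.
#'
#' @param overrides optional named list; each element a list with any of
#'   `n_H`, `n_O`, `n_N`, `mu`, `d` replacing the default for that compound
#'   (names among `protein`, `lipid`, `carbohydrate`, `reserve`, `structure`)
#' @return named list of [compound_composition()] objects
#' @export
compound_library <- function(overrides = NULL) {
  defaults <- list(
    protein      = list(n_H = 1.6,  n_O = 0.32, n_N = 0.26, mu = 527700, d = 1.30),
    lipid        = list(n_H = 1.92, n_O = 0.12, n_N = 0,    mu = 625700, d = 0.93),
    carbohydrate = list(n_H = 2,    n_O = 1,    n_N = 0,    mu = 525000, d = 1.55),
    reserve      = list(n_H = 1.8,  n_O = 0.5,  n_N = 0.15, mu = 550000, d = 0.20),
    structure    = list(n_H = 1.8,  n_O = 0.5,  n_N = 0.15, mu = 500000, d = 0.20)
  )
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop("unknown compound(s) in overrides: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(overrides)) {
      defaults[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    }
  }
  lapply(defaults, function(x) {
    compound_composition(x$n_H, x$n_O, x$n_N, x$mu, x$d)
  })
}

# C-mol-weighted mixture of compound compositions. Chemical indices, potential
# and density are averaged with the given C-mol weights; w is re-derived.
mix_compounds <- function(comps, weights) {
  weights <- weights / sum(weights)
  f <- function(field) sum(vapply(comps, `[[`, numeric(1), field) * weights)
  compound_composition(f("n_H"), f("n_O"), f("n_N"), f("mu"), f("d"))
}

#' Diet specification from proximate composition
#'
#' Converts a proximate feed analysis (mass fractions of protein, fat,
#' carbohydrate and ash on a dry-matter basis, plus moisture of the as-fed
#' feed) and apparent digestibility coefficients into the chemical description
#' the model runs on: the C-mol protein fraction `a_P` of ash-free dry matter,
#' the compositions of the protein and non-protein substrates, the C-molar
#' weight `w_X` of ash-free dry food, and the gross energy density.
#'
#' Ash is inert: it is excluded from `a_P`, `w_X` and all reserve dynamics,
#' and only traced to the faecal output.
#'
#' @param protein,fat,carb,ash mass fractions of dry feed; must sum to 1
#' @param moisture mass fraction of the as-fed feed that is water
#' @param adc named numeric with apparent digestibility coefficients
#'   `protein`, `fat`, `carb`, each in `[0, 1]`
#' @param library compound library from [compound_library()]
#' @param d_Xd specific density of dry food, g/cm^3
#' @param d_Xw specific density of wet (as-fed) food, g/cm^3; default derived
#'   so that `d_Xd / d_Xw` equals the dry-matter fraction `1 - moisture`
#' @param ge_coefficients combustion energies per macronutrient, kJ/g
#' @return object of class `diet_spec`
#' @export
diet_spec <- function(protein, fat, carb, ash = 0, moisture = 0.08,
                      adc = c(protein = 0.9, fat = 0.9, carb = 0.7),
                      library = compound_library(),
                      d_Xd = 0.65, d_Xw = NULL,
                      ge_coefficients = c(protein = 23.6, fat = 39.5, carb = 17.2)) {
  frac <- c(protein = protein, fat = fat, carb = carb, ash = ash)
  if (any(frac < 0)) stop("diet fractions must be non-negative", call. = FALSE)
  if (abs(sum(frac) - 1) > 1e-9) {
    stop("dry-matter fractions must sum to 1 (got ", signif(sum(frac), 8), ")",
         call. = FALSE)
  }
  if (protein + fat + carb <= 0) {
    stop("degenerate diet: no organic matter (all ash)", call. = FALSE)
  }
  adc <- adc[c("protein", "fat", "carb")]
  if (anyNA(adc) || any(adc < 0) || any(adc > 1)) {
    stop("digestibilities must be named protein/fat/carb and lie in [0, 1]",
         call. = FALSE)
  }
  if (moisture < 0 || moisture >= 1) stop("moisture must be in [0, 1)", call. = FALSE)
  if (is.null(d_Xw)) d_Xw <- d_Xd / (1 - moisture)

  # C-mol per g of dry feed contributed by each macronutrient
  cmol <- c(protein = protein / library$protein$w,
            fat     = fat / library$lipid$w,
            carb    = carb / library$carbohydrate$w)
  cmol_tot <- sum(cmol)
  a_P <- unname(cmol["protein"] / cmol_tot)
  af_dry <- protein + fat + carb           # ash-free dry mass per g dry feed
  w_X <- af_dry / cmol_tot                 # g ash-free dry food per C-mol

  comp_XP <- library$protein
  comp_XnP <- if (cmol["fat"] + cmol["carb"] > 0) {
    mix_compounds(list(library$lipid, library$carbohydrate),
                  c(cmol["fat"], cmol["carb"]))
  } else {
    NULL   # pure-protein diet: no non-protein substrate
  }
  # C-mol share of fat within the non-protein substrate
  fat_cmol_share <- if (cmol["fat"] + cmol["carb"] > 0) {
    unname(cmol["fat"] / (cmol["fat"] + cmol["carb"]))
  } else NA_real_

  structure(
    list(frac_protein = protein, frac_fat = fat, frac_carb = carb,
         frac_ash = ash, moisture = moisture,
         adc_protein = unname(adc["protein"]), adc_fat = unname(adc["fat"]),
         adc_carb = unname(adc["carb"]),
         a_P = a_P, comp_XP = comp_XP, comp_XnP = comp_XnP,
         fat_cmol_share = fat_cmol_share,
         w_X = w_X, d_Xd = d_Xd, d_Xw = d_Xw,
         gross_energy = sum(frac[c("protein", "fat", "carb")] *
                              ge_coefficients[c("protein", "fat", "carb")]),
         library = library),
    class = "diet_spec"
  )
}

#' @export
print.diet_spec <- function(x, ...) {
  cat("Diet (dry-matter basis):\n")
  cat(sprintf("  protein %.1f%%  fat %.1f%%  carbohydrate %.1f%%  ash %.1f%%  (moisture %.1f%% as fed)\n",
              100 * x$frac_protein, 100 * x$frac_fat, 100 * x$frac_carb,
              100 * x$frac_ash, 100 * x$moisture))
  cat(sprintf("  ADC: protein %.2f, fat %.2f, carbohydrate %.2f\n",
              x$adc_protein, x$adc_fat, x$adc_carb))
  cat(sprintf("  a_P = %.3f (C-mol protein share of ash-free dry matter)\n", x$a_P))
  cat(sprintf("  w_X = %.2f g/C-mol, gross energy = %.2f kJ/g dry feed\n",
              x$w_X, x$gross_energy))
  invisible(x)
}

#' Gross energy density of a diet
#'
#' Mass-weighted combustion energy of the dry feed; ash contributes nothing.
#'
#' @param diet a [diet_spec()]
#' @param coefficients combustion energies, kJ/g, named `protein`, `fat`, `carb`
#' @return kJ per g dry feed
#' @export
gross_energy_density <- function(diet,
                                 coefficients = c(protein = 23.6, fat = 39.5,
                                                  carb = 17.2)) {
  stopifnot(inherits(diet, "diet_spec"))
  if (any(coefficients[c("protein", "fat", "carb")] <= 0)) {
    stop("combustion coefficients must be positive", call. = FALSE)
  }
  unname(diet$frac_protein * coefficients["protein"] +
           diet$frac_fat * coefficients["fat"] +
           diet$frac_carb * coefficients["carb"])
}

#' Coupling yields of reserve synthesis
#'
#' Determines how much protein and non-protein substrate is absorbed per
#' C-mol of reserve built, and how much faeces that drags along. The scheme
#' is a documented reconstruction (the generalised-compound bookkeeping that
#' turns proximate composition into stoichiometric coefficients admits more
#' than one closure):
#'
#' * Reserve synthesis consumes `1 + sigma_A` C-mol of absorbed substrate per
#'   C-mol of reserve; the surplus `sigma_A` is respired as assimilation CO2.
#' * The protein share of the absorbed substrate is fixed by nitrogen
#'   stoichiometry: all reserve N comes from the protein substrate, so
#'   `theta_P = n_NE / n_N(protein)` of the absorbed pool is protein.
#' * The indigestible companions of the absorbed substrate
#'   (`(1 - ADC) / ADC` per unit absorbed, per macronutrient) leave as
#'   faeces; their flux-weighted elemental mixture sets the faeces
#'   composition.
#' * By default the small N surplus of assimilation (`sigma_A * n_NE` per
#'   C-mol reserve) is also routed to faeces, so that the ammonia flux
#'   carries no assimilation term; set `ammonia_assim = TRUE` to excrete it
#'   as ammonia instead (sensitivity switch).
#'
#' @param diet a [diet_spec()]
#' @param reserve reserve composition; defaults to the diet's library entry
#' @param sigma_A assimilation overhead: C-mol of absorbed substrate respired
#'   as CO2 per C-mol reserve formed
#' @param ammonia_assim logical; excrete the assimilation N surplus as ammonia
#'   (`TRUE`) or absorb it into the faeces composition (`FALSE`, default)
#' @return object of class `coupling_yields`: `q_P`, `q_nP` (C-mol absorbed
#'   substrate per C-mol reserve), `y_PE` (C-mol faeces per C-mol reserve),
#'   `kappa_CA` (C-mol assimilation CO2 per C-mol reserve), the faeces
#'   composition `comp_P`, `n_NH3_A` (mol ammonia-N per C-mol reserve under
#'   the chosen closure) and the flag `single_substrate`
#' @export
coupling_yields <- function(diet, reserve = diet$library$reserve,
                            sigma_A = 0.2, ammonia_assim = FALSE) {
  stopifnot(inherits(diet, "diet_spec"))
  if (sigma_A < 0) stop("sigma_A must be non-negative", call. = FALSE)
  n_NP_sub <- diet$comp_XP$n_N
  if (reserve$n_N > 0 && n_NP_sub <= 0) {
    stop("cannot close nitrogen balance: reserve contains N but the protein substrate does not",
         call. = FALSE)
  }
  theta_P <- if (reserve$n_N > 0) reserve$n_N / n_NP_sub else 0
  if (theta_P > 1) {
    stop("reserve is richer in N than the protein substrate; N balance infeasible",
         call. = FALSE)
  }
  q_P <- (1 + sigma_A) * theta_P
  q_nP <- (1 + sigma_A) * (1 - theta_P)

  adc_P <- diet$adc_protein
  # C-mol-weighted digestibility of the lipid/carbohydrate pool
  adc_nP <- if (!is.null(diet$comp_XnP)) {
    diet$fat_cmol_share * diet$adc_fat + (1 - diet$fat_cmol_share) * diet$adc_carb
  } else NA_real_

  single <- diet$a_P <= 0 || diet$a_P >= 1
  if (adc_P <= 0 || (!is.na(adc_nP) && adc_nP <= 0)) {
    stop("apparent digestibility of an absorbed substrate cannot be zero",
         call. = FALSE)
  }

  # indigestible companions, C-mol per C-mol reserve
  phi_P <- q_P * (1 - adc_P) / adc_P
  phi_nP <- if (!is.na(adc_nP)) q_nP * (1 - adc_nP) / adc_nP else 0
  y_PE <- phi_P + phi_nP

  # faeces composition: indigestible mixture, with the fat/carb split taken
  # at their indigestible (not average) proportions
  comp_P <- NULL
  n_NH3_A <- 0
  n_surplus <- q_P * diet$comp_XP$n_N +
    q_nP * (if (!is.null(diet$comp_XnP)) diet$comp_XnP$n_N else 0) -
    reserve$n_N
  if (y_PE > 0) {
    comps <- list(diet$comp_XP)
    wts <- phi_P
    if (phi_nP > 0) {
      fshare <- diet$fat_cmol_share
      ind_fat <- fshare * (1 - diet$adc_fat)
      ind_carb <- (1 - fshare) * (1 - diet$adc_carb)
      comps <- c(comps, list(diet$library$lipid, diet$library$carbohydrate))
      wts <- c(wts, phi_nP * ind_fat / (ind_fat + ind_carb),
               phi_nP * ind_carb / (ind_fat + ind_carb))
    }
    comp_P <- mix_compounds(comps, wts)
    if (!ammonia_assim) {
      # route the assimilation N surplus into faeces: eta_NA becomes 0
      comp_P <- compound_composition(
        comp_P$n_H, comp_P$n_O,
        comp_P$n_N + n_surplus / y_PE,
        comp_P$mu, comp_P$d
      )
    } else {
      n_NH3_A <- n_surplus
    }
  } else {
    # fully digestible diet: no faeces; surplus N must leave as ammonia
    n_NH3_A <- n_surplus
  }

  structure(
    list(q_P = q_P, q_nP = q_nP, y_PE = y_PE,
         kappa_CA = q_P + q_nP - 1,
         adc_P = adc_P, adc_nP = adc_nP,
         phi_P = phi_P, phi_nP = phi_nP,
         comp_P = comp_P, n_NH3_A = n_NH3_A,
         sigma_A = sigma_A, ammonia_assim = ammonia_assim,
         single_substrate = single),
    class = "coupling_yields"
  )
}

#' @export
print.coupling_yields <- function(x, ...) {
  cat(sprintf("Coupling yields: q_P = %.4f, q_nP = %.4f (C-mol absorbed / C-mol reserve)\n",
              x$q_P, x$q_nP))
  cat(sprintf("  y_PE = %.4f C-mol faeces / C-mol reserve, assimilation CO2 = %.4f\n",
              x$y_PE, x$kappa_CA))
  if (x$single_substrate) cat("  [single-substrate diet: assimilation is nullified]\n")
  invisible(x)
}

# total stomach drain, C-mol per C-mol reserve formed (Eq-6 coefficient)
drain_per_reserve <- function(yields) {
  yields$q_P + yields$q_nP + yields$y_PE
}
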