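#' Build a regular feeding schedule
#'
#' Meals evenly spaced within each day, with the daily ration split equally
#' among them. Rations are fractions of the *current* model body weight,
#' re-evaluated at each meal.
#'
#' @param duration simulation length, d
#' @param meals_per_day number of meals each day
#' @param daily_ration daily ration as fraction of body weight (e.g. 0.012
#'   for 1.2 \% BW/d)
#' @param diet_id diet identifier (name in the scenario's diet list)
#' @param first_meal time of the first meal within the day, d
#' @return data.frame with columns `time`, `ration`, `diet_id`
#' @export
feeding_schedule <- function(duration, meals_per_day = 1, daily_ration = 0.012,
                             diet_id = "diet", first_meal = 0) {
  stopifnot(duration > 0, meals_per_day >= 1, daily_ration >= 0)
  days <- seq_len(ceiling(duration)) - 1
  within_day <- first_meal + (seq_len(meals_per_day) - 1) / meals_per_day
  times <- as.vector(outer(within_day, days, `+`))
  times <- sort(times[times < duration])
  data.frame(time = times, ration = daily_ration / meals_per_day,
             diet_id = diet_id, stringsAsFactors = FALSE)
}

#' Define a simulation scenario
#'
#' @param duration simulation length, d
#' @param initial_weight initial wet weight, g
#' @param temperature water temperature: a single value in deg C, or a
#'   data.frame with columns `time` (d) and `temp_C` interpreted as
#'   piecewise-constant between the supplied points
#' @param schedule feeding schedule data.frame (`time`, `ration`, `diet_id`),
#'   e.g. from [feeding_schedule()]; an empty schedule means fasting
#' @param diets named list of [diet_spec()] objects
#' @param n_fish number of identical fish in the group (flux outputs are
#'   population totals)
#' @param output `"hourly"` or `"daily"`
#' @param f_initial assumed functional response for the initial state
#' @return object of class `scenario`
#' @export
scenario <- function(duration, initial_weight, temperature = 15,
                     schedule = feeding_schedule(duration),
                     diets = list(diet = diet_spec(0.45, 0.22, 0.19, 0.14)),
                     n_fish = 1, output = c("hourly", "daily"),
                     f_initial = 0.8) {
  output <- match.arg(output)
  stopifnot(duration > 0, initial_weight > 0, n_fish >= 1)
  if (nrow(schedule)) {
    if (is.unsorted(schedule$time, strictly = TRUE)) {
      stop("meal times must be strictly increasing", call. = FALSE)
    }
    if (any(schedule$ration < 0)) stop("rations must be non-negative", call. = FALSE)
    missing_diet <- setdiff(unique(schedule$diet_id), names(diets))
    if (length(missing_diet)) {
      stop("schedule refers to unknown diet id(s): ",
           paste(missing_diet, collapse = ", "), call. = FALSE)
    }
  }
  if (is.numeric(temperature) && length(temperature) == 1) {
    temperature <- data.frame(time = 0, temp_C = temperature)
  }
  stopifnot(all(c("time", "temp_C") %in% names(temperature)))
  structure(list(duration = duration, initial_weight = initial_weight,
                 temperature = temperature, schedule = schedule,
                 diets = diets, n_fish = n_fish, output = output,
                 f_initial = f_initial),
            class = "scenario")
}

# piecewise-constant temperature lookup, K
temp_fun <- function(temperature) {
  tt <- temperature$time
  TK <- temperature$temp_C + 273.15
  function(t) TK[findInterval(t, tt, rightmost.closed = FALSE, left.open = FALSE)]
}

# per-diet context reused across integration intervals
diet_context <- function(diet, params) {
  yields <- coupling_yields(diet, reserve = params$compounds$reserve,
                            sigma_A = params$sigma_A)
  eta <- eta_matrix(diet, yields, params)
  list(diet = diet, yields = yields, eta = eta,
       M_KX = half_saturation(diet, yields, params),
       drain = drain_per_reserve(yields),
       M_gm = max_stomach_capacity(diet, params),
       w_P = if (!is.null(yields$comp_P)) yields$comp_P$w else 0,
       ash_per_af = diet$frac_ash / (diet$frac_protein + diet$frac_fat +
                                       diet$frac_carb))
}

#' Simulate a feeding scenario
#'
#' Event-driven integration of the coupled stomach + DEB state. Between
#' meals the five states (V, E, E_H, E_R, M_X) follow the stiff-safe adaptive
#' integrator ([deSolve::lsoda], relative tolerance 1e-8); at each meal the
#' integration stops, the stomach content jumps by the eaten amount, and
#' integration resumes. Output is produced on an hourly grid and aggregated
#' to daily means/sums when requested. If the diet of a meal differs from
#' the resident stomach content, the content is re-pooled to the
#' mass-weighted mixture of the two proximate compositions.
#'
#' All flux columns are population totals (`n_fish` identical individuals);
#' `W_g` is the weight of one fish. Rates: `JO_gO2_per_d`, `JC_gCO2_per_d`,
#' `TAN_gN_per_d`, `faecalN_gN_per_d`, `faeces_dry_g_per_d` (organic + ash),
#' plus cumulative feed offered/eaten/uneaten in g as-fed. If the reserve is
#' exhausted the run stops early with a diagnostic attribute.
#'
#' @param scn a [scenario()]
#' @param params model parameters
#' @return data.frame of class `fish_sim` with one row per output time;
#'   attributes `meals` (meal log), `params`, `scenario`, `truncated`
#' @export
simulate_fish <- function(scn, params = deb_params()) {
  stopifnot(inherits(scn, "scenario"))
  validate_params(params)
  state0 <- initial_state_from_weight(scn$initial_weight, scn$f_initial, params)
  Tfun <- temp_fun(scn$temperature)

  contexts <- lapply(scn$diets, diet_context, params = params)
  sched <- scn$schedule

  # integration breakpoints: meals and temperature switches
  brk <- sort(unique(c(0, sched$time, scn$temperature$time, scn$duration)))
  brk <- brk[brk >= 0 & brk <= scn$duration]
  out_times <- seq(0, scn$duration, by = 1 / 24)

  y <- c(V = state0$V, E = state0$E, E_H = state0$E_H, E_R = state0$E_R,
         M_X = 0, cO2 = 0, cCO2 = 0, cN = 0, cPN = 0, cFa = 0, cEA = 0)
  cur_ctx_id <- if (nrow(sched)) sched$diet_id[1] else names(contexts)[1]
  ctx <- contexts[[cur_ctx_id]]
  meal_log <- NULL
  rows <- list()
  truncated <- FALSE
  cum_off_g <- 0; cum_eat_g <- 0

  deriv <- function(t, y, parms) {
    V <- y[1]; E <- y[2]; E_H <- y[3]; E_R <- y[4]; M_X <- max(y[5], 0)
    L <- V^(1/3)
    cT <- temperature_factor(parms$TK, params)
    sM <- acceleration_factor(E_H, L, params)
    f_X <- functional_response(M_X, ctx$M_KX)
    J_EA <- params$J_EAm_d * sM * cT * f_X * L^2
    p_A <- params$mu_E * J_EA
    fl <- deb_powers(V, E, E_H, p_A, cT, sM, params)
    adult <- E_H >= params$E_Hp
    mins <- mineral_fluxes(fl["p_A"], fl["p_D"], fl["p_G"], ctx$eta)
    J_P <- ctx$yields$y_PE * J_EA
    J_drain <- ctx$drain * J_EA
    faeces_g <- J_P * ctx$w_P + J_drain * ctx$diet$w_X * ctx$ash_per_af
    list(c(
      fl["p_G"] / params$E_G,
      fl["p_A"] - fl["p_C"],
      if (adult) 0 else fl["p_R"],
      if (adult) params$kappa_R * fl["p_R"] else 0,
      -J_drain,
      mins$J_O, mins$J_C, mins$J_N,
      faecal_nitrogen(unname(fl["p_A"]), ctx$yields, params),
      faeces_g,
      J_EA
    ))
  }

  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]; t1 <- brk[i + 1]
    # meal event at t0?
    mi <- which(nrow(sched) > 0 & sched$time == t0)
    if (length(mi) == 1 && sched$ration[mi] > 0) {
      new_id <- sched$diet_id[mi]
      new_ctx <- contexts[[new_id]]
      st <- fish_state(y["V"], max(y["E"], 0), y["E_H"], y["E_R"], y["M_X"])
      W <- wet_weight(st, params)
      meal <- meal_intake(y["M_X"], y["V"], W, sched$ration[mi],
                          new_ctx$diet, params)
      resident <- unname(y["M_X"])
      y["M_X"] <- y["M_X"] + meal$delta_M_X
      if (new_id != cur_ctx_id && resident > 1e-12 && meal$delta_M_X > 0) {
        # resident content re-pooled to the C-mol-weighted mixture of the
        # two diets; single-diet runs never take this branch
        ctx <- diet_context(
          repool_diet(ctx$diet, new_ctx$diet, resident, meal$delta_M_X),
          params)
        cur_ctx_id <- new_id
        contexts[[new_id]] <- ctx   # subsequent same-diet meals reuse blend
      } else {
        ctx <- new_ctx
        cur_ctx_id <- new_id
      }
      eaten_g <- meal$delta_M_X * ctx$diet$w_X / (ctx$diet$d_Xd / ctx$diet$d_Xw)
      cum_off_g <- cum_off_g + meal$offered_g
      cum_eat_g <- cum_eat_g + eaten_g
      meal_log <- rbind(meal_log, data.frame(
        time = t0, diet_id = cur_ctx_id, offered_g = meal$offered_g,
        eaten_g = eaten_g, uneaten_g = meal$offered_g - eaten_g,
        W_g = W, M_X_after = unname(y["M_X"])))
    }
    tt <- unique(c(t0, out_times[out_times > t0 & out_times < t1], t1))
    TK <- Tfun(t0)
    sol <- deSolve::lsoda(y, tt, deriv, parms = list(TK = TK),
                          rtol = 1e-8, atol = 1e-10)
    sol <- as.data.frame(sol)
    if (any(sol$E < 0)) {
      first_bad <- which(sol$E < 0)[1]
      sol <- sol[seq_len(max(first_bad - 1, 1)), , drop = FALSE]
      truncated <- TRUE
    }
    sol$TK <- TK
    sol$cum_off_g <- cum_off_g
    sol$cum_eat_g <- cum_eat_g
    sol$diet_id <- cur_ctx_id
    # drop the duplicated interval start except for the very first interval
    rows[[i]] <- if (i == 1) sol else sol[-1, , drop = FALSE]
    y <- unlist(sol[nrow(sol), names(y)])
    names(y) <- names(y)
    if (truncated) break
  }

  res <- do.call(rbind, rows)
  res <- res[res$time %in% out_times | res$time == res$time[nrow(res)], ,
             drop = FALSE]
  out <- finalize_output(res, contexts, params, scn)
  attr(out, "meals") <- meal_log
  attr(out, "params") <- params
  attr(out, "scenario") <- scn
  attr(out, "truncated") <- truncated
  if (truncated) {
    warning("reserve exhausted: run truncated at t = ",
            signif(max(out$time), 6), " d", call. = FALSE)
  }
  class(out) <- c("fish_sim", "data.frame")
  if (scn$output == "daily") aggregate_daily(out) else out
}

# blended stomach content: mass-weighted mixture of resident and incoming
# proximate compositions, weighted by the dry masses actually present
repool_diet <- function(old_diet, new_diet, resident_cmol, eaten_cmol) {
  m_old <- resident_cmol * old_diet$w_X
  m_new <- eaten_cmol * new_diet$w_X
  w_old <- m_old / (m_old + m_new)
  blend <- function(field) {
    w_old * old_diet[[field]] + (1 - w_old) * new_diet[[field]]
  }
  fr <- c(blend("frac_protein"), blend("frac_fat"), blend("frac_carb"),
          blend("frac_ash"))
  fr <- fr / sum(fr)
  diet_spec(fr[1], fr[2], fr[3], fr[4], moisture = new_diet$moisture,
            adc = c(protein = blend("adc_protein"), fat = blend("adc_fat"),
                    carb = blend("adc_carb")),
            library = new_diet$library, d_Xd = new_diet$d_Xd)
}

finalize_output <- function(res, contexts, params, scn) {
  n <- nrow(res)
  L <- res$V^(1/3)
  cT <- temperature_factor(res$TK, params)
  sM <- vapply(seq_len(n), function(i) {
    acceleration_factor(res$E_H[i], L[i], params)
  }, numeric(1))
  M_KX <- vapply(res$diet_id, function(id) contexts[[id]]$M_KX, numeric(1))
  f_X <- ifelse(is.infinite(M_KX), 0, res$M_X / (res$M_X + M_KX))
  J_EA <- params$J_EAm_d * sM * cT * f_X * L^2
  p_A <- params$mu_E * J_EA
  pw <- t(vapply(seq_len(n), function(i) {
    deb_powers(res$V[i], res$E[i], res$E_H[i], p_A[i], cT[i], sM[i], params)
  }, numeric(7)))
  colnames(pw) <- c("p_A", "p_C", "p_S", "p_J", "p_G", "p_R", "p_D")
  mins <- lapply(seq_len(n), function(i) {
    ctx <- contexts[[res$diet_id[i]]]
    mineral_fluxes(pw[i, "p_A"], pw[i, "p_D"], pw[i, "p_G"], ctx$eta)
  })
  J_O <- vapply(mins, `[[`, numeric(1), "J_O")
  J_C <- vapply(mins, `[[`, numeric(1), "J_C")
  J_N <- vapply(mins, `[[`, numeric(1), "J_N")
  J_PN <- vapply(seq_len(n), function(i) {
    faecal_nitrogen(pw[i, "p_A"], contexts[[res$diet_id[i]]]$yields, params)
  }, numeric(1))
  faeces_g <- vapply(seq_len(n), function(i) {
    ctx <- contexts[[res$diet_id[i]]]
    J_P <- ctx$yields$y_PE * J_EA[i]
    J_P * ctx$w_P + ctx$drain * J_EA[i] * ctx$diet$w_X * ctx$ash_per_af
  }, numeric(1))
  W <- params$d_Vw * res$V + (res$E + res$E_R) * params$w_Ed /
    (params$d_Ed * params$mu_E)
  nf <- scn$n_fish
  out <- data.frame(
    time = res$time, W_g = W, L_cm = L, f_X = f_X, M_X_mol = res$M_X,
    JO_gO2_per_d = 32 * J_O * nf, JC_gCO2_per_d = 44 * J_C * nf,
    TAN_gN_per_d = 14 * J_N * nf, faecalN_gN_per_d = J_PN * nf,
    faeces_dry_g_per_d = faeces_g * nf,
    p_A = pw[, "p_A"], p_C = pw[, "p_C"], p_S = pw[, "p_S"],
    p_J = pw[, "p_J"], p_G = pw[, "p_G"], p_R = pw[, "p_R"],
    p_D = pw[, "p_D"],
    E_H = res$E_H, E_R = res$E_R, V = res$V, E = res$E,
    diet_id = res$diet_id,
    cum_O2_g = 32 * res$cO2 * nf, cum_CO2_g = 44 * res$cCO2 * nf,
    cum_TAN_gN = 14 * res$cN * nf, cum_faecalN_gN = res$cPN * nf,
    cum_faeces_g = res$cFa * nf,
    cum_feed_offered_g = res$cum_off_g * nf,
    cum_feed_eaten_g = res$cum_eat_g * nf,
    cum_feed_uneaten_g = (res$cum_off_g - res$cum_eat_g) * nf,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Aggregate hourly simulation output to daily resolution
#'
#' Rates become day means, cumulative columns keep their value at the end of
#' each day, and state columns are sampled at the end of each day.
#'
#' @param sim hourly output from [simulate_fish()]
#' @return daily data.frame
#' @export
aggregate_daily <- function(sim) {
  day <- ceiling(sim$time - 1e-9)   # day d covers the window (d-1, d]
  day[day < 1] <- 1
  rate_cols <- c("JO_gO2_per_d", "JC_gCO2_per_d", "TAN_gN_per_d",
                 "faecalN_gN_per_d", "faeces_dry_g_per_d", "f_X",
                 "p_A", "p_C", "p_S", "p_J", "p_G", "p_R", "p_D")
  state_cols <- setdiff(names(sim), c(rate_cols, "time", "diet_id"))
  agg <- lapply(split(seq_len(nrow(sim)), day), function(ix) {
    last <- ix[length(ix)]
    row <- sim[last, c("time", state_cols), drop = FALSE]
    means <- colMeans(sim[ix, rate_cols, drop = FALSE])
    cbind(row, as.data.frame(as.list(means)), diet_id = sim$diet_id[last])
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  for (a in c("meals", "params", "scenario", "truncated")) {
    attr(out, a) <- attr(sim, a)
  }
  class(out) <- c("fish_sim", "data.frame")
  out
}

#' Diurnal peak-to-trough range of an output rate
#'
#' Amplitude of the daily cycle of a rate column on a given day, after
#' removing the slow growth trend. The trend is estimated from the two
#' endpoints of the 24 h window, which sit at the same diurnal phase one day
#' apart, so the periodic (meal-driven) component cannot leak into the trend
#' estimate.
#'
#' @param sim hourly output from [simulate_fish()]
#' @param col column name, e.g. `"TAN_gN_per_d"` or `"JO_gO2_per_d"`
#' @param day day number (window `[day - 1, day]`)
#' @return peak-to-trough range in the column's units
#' @export
diurnal_range <- function(sim, col, day) {
  x <- sim[sim$time >= day - 1 & sim$time <= day, ]
  if (nrow(x) < 3) stop("no hourly output in day ", day, call. = FALSE)
  slope <- (x[[col]][nrow(x)] - x[[col]][1]) /
    (x$time[nrow(x)] - x$time[1])
  r <- x[[col]] - slope * (x$time - x$time[1])
  max(r) - min(r)
}

#' @export
print.fish_sim <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Fish simulation: %d output steps over %.3g d\n", n, max(x$time)))
  cat(sprintf("  weight %.4g -> %.4g g per fish; cumulative feed eaten %.4g g\n",
              x$W_g[1], x$W_g[n], x$cum_feed_eaten_g[n]))
  cat(sprintf("  cumulative O2 %.4g g, TAN %.4g g N, faeces %.4g g (population)\n",
              x$cum_O2_g[n], x$cum_TAN_gN[n], x$cum_faeces_g[n]))
  invisible(x)
}
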