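#' Mean relative error
#'
#' `MRE = (1/n) sum(|predicted - observed| / observed)`.
#'
#' @param observed observed values (all non-zero)
#' @param predicted model predictions, same length
#' @return dimensionless; 0 iff predictions equal observations
#' @export
mre <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (any(observed == 0)) {
    stop("MRE is undefined for zero observations", call. = FALSE)
  }
  mean(abs(predicted - observed) / abs(observed))
}

#' Symmetric mean squared error
#'
#' `SMSE = (1/n) sum((predicted - observed)^2 / (observed^2 + predicted^2))`,
#' bounded in `[0, 1]` and symmetric in its arguments.
#'
#' @inheritParams mre
#' @return dimensionless in `[0, 1]`
#' @export
smse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (any(observed == 0 & predicted == 0)) {
    stop("SMSE is undefined where observation and prediction are both zero",
         call. = FALSE)
  }
  mean((predicted - observed)^2 / (observed^2 + predicted^2))
}

#' Least-squares calibration of the digestion parameters
#'
#' Fits a subset of the digestion parameters to observation sets by
#' Levenberg-Marquardt least squares ([minpack.lm::nls.lm]) on
#' log-transformed parameters (all are positive). Supported observation
#' kinds:
#'
#' * `evacuation` — records of stomach content (% of initial) versus time,
#'   with metadata `T_C` and `weight_g`; fitted through [evacuation_curve()].
#' * `stomach_water` — paired (dry mass, water mass) records; the
#'   moisturising coefficient `y_HXd` is the slope of the through-origin
#'   regression, estimated by [stats::lm] and reported alongside.
#'
#' The objective is the sum over datasets of squared residuals, each dataset
#' normalised by the mean of its observed values (configurable weights).
#' A finite-difference sensitivity check warns when a requested parameter
#' leaves the residuals essentially unchanged (unidentifiable).
#'
#' @param datasets list of observation sets as produced by
#'   [synth_evacuation()] / [synth_stomach_water()] (data.frames with columns
#'   `dataset_id`, `kind`, `covariate`, `value`, `units`, `T_C`, `weight_g`,
#'   `feeding_state`)
#' @param free character vector of parameters to fit, from
#'   `c("J_Xg_m", "J_EAm_d", "delta_g")`; `y_HXd` is fitted automatically
#'   when a `stomach_water` dataset is present
#' @param params starting parameter set (also supplies all fixed values)
#' @param diet diet used for the evacuation predictions
#' @param weights optional numeric vector, one per dataset
#' @param initial_load initial stomach fill assumed for evacuation data
#' @return list with `estimates` (named vector), `params` (updated set),
#'   `report` (per-dataset MRE/SMSE), `converged`, and the `nls.lm` fit
#'   object (`fit`)
#' @export
fit_digestion_params <- function(datasets,
                                 free = c("J_Xg_m", "J_EAm_d"),
                                 params = deb_params(),
                                 diet = diet_spec(0.45, 0.22, 0.19, 0.14,
                                                  library = params$compounds),
                                 weights = NULL, initial_load = 1) {
  if (!length(datasets)) stop("at least one dataset is required", call. = FALSE)
  kinds <- vapply(datasets, function(d) d$kind[1], character(1))
  allowed <- c("J_Xg_m", "J_EAm_d", "delta_g")
  free <- match.arg(free, allowed, several.ok = TRUE)
  if (is.null(weights)) weights <- rep(1, length(datasets))

  estimates <- numeric(0)

  # water-content line: closed-form slope, independent of the ODE fit
  iw <- which(kinds == "stomach_water")
  if (length(iw)) {
    wd <- do.call(rbind, datasets[iw])
    sl <- stats::lm(value ~ covariate - 1, data = wd)
    estimates["y_HXd"] <- unname(stats::coef(sl)[1])
    params$y_HXd <- estimates[["y_HXd"]]
  }

  ie <- which(kinds == "evacuation")
  fit <- NULL
  converged <- TRUE
  if (length(ie) && length(free)) {
    ev_sets <- datasets[ie]
    ev_w <- weights[ie]
    resid_fn <- function(logp) {
      p2 <- params
      p2[free] <- as.list(exp(logp))
      unlist(lapply(seq_along(ev_sets), function(k) {
        d <- ev_sets[[k]]
        pred <- evacuation_curve(d$weight_g[1], d$T_C[1],
                                 times = d$covariate, params = p2,
                                 diet = diet, initial_load = initial_load)
        m <- match(round(d$covariate, 10), round(pred$time, 10))
        sqrt(ev_w[k]) * (pred$pct[m] - d$value) / mean(d$value)
      }))
    }
    start <- log(unlist(params[free]))
    base <- resid_fn(start)
    # identifiability: does each free parameter move the residuals at all?
    for (j in seq_along(free)) {
      pert <- start
      pert[j] <- pert[j] + 0.05
      if (sqrt(mean((resid_fn(pert) - base)^2)) < 1e-10) {
        warning("parameter ", free[j],
                " appears unidentifiable from the supplied datasets",
                call. = FALSE)
      }
    }
    fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 100, ftol = 1e-12, ptol = 1e-10))
    converged <- fit$info %in% 1:4
    if (!converged) {
      warning("optimiser did not converge (info = ", fit$info,
              "); best-so-far estimates returned", call. = FALSE)
    }
    est <- exp(fit$par)
    names(est) <- free
    estimates <- c(estimates, est)
    params[free] <- as.list(est)
  }

  report <- do.call(rbind, lapply(seq_along(datasets), function(k) {
    d <- datasets[[k]]
    pred <- switch(
      d$kind[1],
      evacuation = {
        pc <- evacuation_curve(d$weight_g[1], d$T_C[1], times = d$covariate,
                               params = params, diet = diet,
                               initial_load = initial_load)
        pc$pct[match(round(d$covariate, 10), round(pc$time, 10))]
      },
      stomach_water = params$y_HXd * d$covariate,
      stop("unsupported observation kind: ", d$kind[1], call. = FALSE)
    )
    ok <- d$value != 0
    data.frame(dataset_id = d$dataset_id[1], kind = d$kind[1],
               n = nrow(d),
               mre = mre(d$value[ok], pred[ok]),
               smse = smse(d$value[ok], pred[ok]))
  }))

  list(estimates = estimates, params = params, report = report,
       converged = converged, fit = fit)
}
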