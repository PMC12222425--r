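# Translational analyses: external-beam comparison, dose-survival curves,
# one-at-a-time stability analysis, tumor growth-curve inversion, and the
# linear concentration-effect extrapolation to clinical dosing scenarios.

#' Compare instantaneous (EBRT) and protracted (RPT) dose delivery
#'
#' For each dose on the grid, simulates endpoint ensemble survival for an
#' instantaneous delivery at t = 0 (external-beam-like impulse) and for a
#' constant-rate delivery spread over the radiopharmaceutical exposure
#' window, both with the same total nucleus dose and identical
#' radiobiology. The crossover is the smallest dose at which the impulse
#' becomes the more effective modality (EBRT survival drops below RPT
#' survival), refined linearly between grid points.
#'
#' @param doses dose grid, Gy.
#' @param model an [rpt_model()] object.
#' @param proto a [protocol()] template (its `rpt_exposure` sets the
#'   protracted delivery window; activity-based dosimetry is bypassed).
#' @return List with `curve` (data frame: `dose_Gy`, `surv_ebrt`,
#'   `surv_rpt`) and `crossover_Gy` (`NA` if the curves do not cross on the
#'   grid).
#' @export
compare_ebrt_rpt <- function(doses, model, proto) {
  p0 <- proto; p0$A0 <- 0
  surv_e <- numeric(length(doses))
  surv_r <- numeric(length(doses))
  for (i in seq_along(doses)) {
    pe <- p0; pe$ebrt_dose <- doses[i]
    surv_e[i] <- ensemble_simulate(pe, model)$endpoint_rel_survival
    surv_r[i] <- if (doses[i] == 0) {
      ensemble_simulate(p0, model)$endpoint_rel_survival
    } else {
      ensemble_simulate(p0, model,
        forced_doserate = doses[i] / proto$rpt_exposure
      )$endpoint_rel_survival
    }
  }
  diff <- surv_e - surv_r
  cross <- NA_real_
  idx <- which(diff[-1] < 0 & diff[-length(diff)] >= 0)
  if (length(idx)) {
    i <- idx[1]
    # linear interpolation of the sign change between grid points
    cross <- doses[i] + (doses[i + 1] - doses[i]) *
      diff[i] / (diff[i] - diff[i + 1])
  }
  list(curve = data.frame(dose_Gy = doses, surv_ebrt = surv_e,
                          surv_rpt = surv_r),
       crossover_Gy = cross)
}

#' Dose-survival curve with optional uncertainty band
#'
#' Endpoint ensemble survival against the endpoint nucleus absorbed dose
#' over a grid of initial activities. An uncertainty band is generated by
#' perturbing selected parameters with seeded normal draws of configured
#' relative standard deviations.
#'
#' @param activities initial activities, Bq.
#' @param model an [rpt_model()] object.
#' @param proto a [protocol()] template.
#' @param param_sds optional named numeric vector of relative standard
#'   deviations for perturbed parameters; names use `block.field` paths,
#'   e.g. `c("repair.k_dsb" = 0.1)`.
#' @param n_draws perturbation draws per activity when `param_sds` given.
#' @param seed RNG seed for the perturbations.
#' @return Data frame with `activity_Bq`, `dose_Gy`, `survival`, and when
#'   perturbed also `surv_lo`, `surv_hi` (2.5 and 97.5 percent quantiles).
#' @export
dose_survival_curve <- function(activities, model, proto,
                                param_sds = NULL, n_draws = 20, seed = 1L) {
  base <- lapply(activities, function(A) {
    p <- proto; p$A0 <- A
    e <- ensemble_simulate(p, model)
    c(dose = e$endpoint_dose, surv = e$endpoint_rel_survival)
  })
  out <- data.frame(activity_Bq = activities,
                    dose_Gy = vapply(base, `[[`, numeric(1), "dose"),
                    survival = vapply(base, `[[`, numeric(1), "surv"))
  if (!is.null(param_sds)) {
    set.seed(seed)
    draws <- matrix(stats::rnorm(n_draws * length(param_sds)),
                    nrow = n_draws)
    lo <- hi <- numeric(length(activities))
    for (i in seq_along(activities)) {
      p <- proto; p$A0 <- activities[i]
      s <- vapply(seq_len(n_draws), function(d) {
        m <- model
        for (j in seq_along(param_sds)) {
          path <- strsplit(names(param_sds)[j], ".", fixed = TRUE)[[1]]
          val <- m[[path[1]]][[path[2]]]
          m[[path[1]]][[path[2]]] <-
            val * max(1 + param_sds[j] * draws[d, j], 0.01)
        }
        ensemble_simulate(p, m)$endpoint_rel_survival
      }, numeric(1))
      lo[i] <- stats::quantile(s, 0.025)
      hi[i] <- stats::quantile(s, 0.975)
    }
    out$surv_lo <- lo; out$surv_hi <- hi
  }
  out
}

# parameter registry for the stability analysis: name -> (block, field)
.PARAM_REGISTRY <- list(
  k_on = c("kinetics", "k_on"), k_off = c("kinetics", "k_off"),
  k_int = c("kinetics", "k_int"), k_rel = c("kinetics", "k_rel"),
  mu_dec = c("kinetics", "mu_dec"),
  R_cell = c("receptors", "R_cell"),
  S_m = c("svalues", "S_m"), S_cs = c("svalues", "S_cs"),
  S_cy = c("svalues", "S_cy"),
  k_ssb = c("repair", "k_ssb"), lambda_ssb = c("repair", "lambda_ssb"),
  k_dsb = c("repair", "k_dsb"),
  lambda_f = c("repair", "lambda_f"), lambda_s = c("repair", "lambda_s"),
  lambda_m = c("repair", "lambda_m"),
  p_c = c("repair", "p_c"), p_HR = c("repair", "p_HR"),
  psi = c("survival", "psi"), phi = c("survival", "phi"))

#' One-at-a-time parameter stability analysis
#'
#' Scales a single parameter by each multiplier on the grid, re-simulates
#' the baseline scenario, and reports the endpoint relative survival. A
#' flat response identifies parameters whose effects are insignificant
#' under the scenario conditions.
#'
#' @param param parameter name from the registry (see Details).
#' @param multipliers multiplier grid (must contain 1 for the baseline).
#' @param model baseline [rpt_model()].
#' @param proto baseline [protocol()].
#' @return Data frame with `multiplier`, `value`, `survival`.
#' @details Registered parameters:
#'   `r paste(names(.PARAM_REGISTRY), collapse = ", ")`.
#' @export
stability_analysis <- function(param, multipliers, model, proto) {
  if (!param %in% names(.PARAM_REGISTRY))
    stop("stability_analysis: unknown parameter '", param, "'",
         call. = FALSE)
  path <- .PARAM_REGISTRY[[param]]
  base_val <- model[[path[1]]][[path[2]]]
  surv <- vapply(multipliers, function(mult) {
    m <- model
    v <- base_val * mult
    if (param %in% c("p_c", "p_HR")) v <- min(v, 1)
    m[[path[1]]][[path[2]]] <- v
    ensemble_simulate(proto, m)$endpoint_rel_survival
  }, numeric(1))
  data.frame(multiplier = multipliers, value = base_val * multipliers,
             survival = surv)
}

#' Invert a tumor growth curve into a survival curve
#'
#' Assuming exponential growth of the surviving fraction at rate `mu_gr`
#' (taken from a control arm), the survival probability obeys
#' `d/dt S = -(mu_gr - d/dt ln N) S`, so
#' `S(t) = N(t) / (N(0) exp(mu_gr t))`. A single-rate exponential
#' `S = exp(-mu_dea t)` is then fitted to report the net death rate.
#'
#' @param series tumor series: data frame with columns `t_days` (strictly
#'   increasing) and `size` (> 0; relative volume or cell number).
#' @param mu_gr growth rate from the control arm, per day.
#' @return List with `survival` (data frame `t_days`, `S`) and `mu_dea`
#'   (per day, from a log-linear fit through the origin).
#' @export
invivo_integrate <- function(series, mu_gr) {
  if (nrow(series) < 3L)
    stop("invivo_integrate: need at least 3 time points", call. = FALSE)
  if (any(series$size <= 0))
    stop("invivo_integrate: sizes must be > 0", call. = FALSE)
  if (any(diff(series$t_days) <= 0))
    stop("invivo_integrate: times must be strictly increasing",
         call. = FALSE)
  t <- series$t_days - series$t_days[1]
  # integrating d lnS = (d lnN - mu_gr) dt from the log-size differences
  lnS <- log(series$size / series$size[1]) - mu_gr * t
  S <- exp(lnS)
  fit <- stats::lm(lnS ~ t + 0)
  list(survival = data.frame(t_days = series$t_days, S = S),
       mu_dea = -unname(stats::coef(fit)[1]))
}

#' PARP-inhibitor monotherapy rate from a growth curve
#'
#' Under drug monotherapy the living-cell count grows as
#' `N(t) = N(0) exp((mu_gr + mu_parpi - 1) t)`, so the constant survival
#' term follows from the fitted net exponent as
#' `mu_parpi = 1 + net - mu_gr`.
#'
#' @param series tumor series as in [invivo_integrate()].
#' @param mu_gr control-arm growth rate, per day.
#' @return List with `mu_parpi`, `net_exponent` (per day) and the log-linear
#'   fit.
#' @export
parpi_monotherapy_rate <- function(series, mu_gr) {
  if (any(series$size <= 0))
    stop("parpi_monotherapy_rate: sizes must be > 0", call. = FALSE)
  t <- series$t_days - series$t_days[1]
  fit <- stats::lm(log(series$size / series$size[1]) ~ t + 0)
  net <- unname(stats::coef(fit)[1])
  list(mu_parpi = 1 + net - mu_gr, net_exponent = net, fit = fit)
}

#' Linear concentration-effect model
#'
#' @param slope radiosensitizer effect per unit tumor concentration (for
#'   the reference drug).
#' @param tumor_to_body_ratio concentration ratio between the tumor
#'   microenvironment and the whole body (default 7.2e-3).
#' @param ic50_map named list/vector of IC50 concentrations per drug; drug
#'   potency scales the slope inversely with IC50 relative to
#'   `reference_drug`.
#' @param reference_drug drug whose IC50 anchors `slope`.
#' @param window therapeutic concentration window (body concentration) in
#'   which linearity is assumed.
#' @return An object of class `conc_effect_model`.
#' @export
conc_effect_model <- function(slope, tumor_to_body_ratio = 7.2e-3,
                              ic50_map = NULL, reference_drug = NULL,
                              window = c(0, Inf)) {
  if (slope < 0) stop("conc_effect_model: 'slope' must be >= 0",
                      call. = FALSE)
  if (tumor_to_body_ratio <= 0 || tumor_to_body_ratio >= 1)
    stop("conc_effect_model: 'tumor_to_body_ratio' must lie in (0, 1)",
         call. = FALSE)
  structure(list(slope = slope, tumor_to_body_ratio = tumor_to_body_ratio,
                 ic50_map = ic50_map, reference_drug = reference_drug,
                 window = window),
            class = "conc_effect_model")
}

#' Radiosensitizer effect from a body concentration
#'
#' The tumor concentration is the body concentration scaled by the
#' tumor-to-body ratio; the effect (cell death-rate ratio relative to no
#' radiosensitizer) grows linearly with tumor concentration. For a drug
#' other than the reference, the slope scales inversely with its IC50.
#'
#' @param model a [conc_effect_model()].
#' @param body_concentration whole-body drug concentration (same unit as
#'   the window and IC50s).
#' @param drug optional drug name present in the model's `ic50_map`.
#' @return Effect as a death-rate ratio (>= 1); with a warning and an
#'   `extrapolated` attribute when outside the therapeutic window.
#' @export
concentration_to_effect <- function(model, body_concentration,
                                    drug = NULL) {
  extrap <- body_concentration < model$window[1] |
    body_concentration > model$window[2]
  if (any(extrap))
    warning("concentration_to_effect: concentration outside the ",
            "therapeutic window; linear extrapolation", call. = FALSE)
  slope <- model$slope
  if (!is.null(drug)) {
    if (is.null(model$ic50_map) || !drug %in% names(model$ic50_map))
      stop("concentration_to_effect: no IC50 for drug '", drug, "'",
           call. = FALSE)
    ref <- if (!is.null(model$reference_drug))
      model$ic50_map[[model$reference_drug]] else model$ic50_map[[drug]]
    slope <- slope * ref / model$ic50_map[[drug]]
  }
  eff <- 1 + slope * body_concentration * model$tumor_to_body_ratio
  attr(eff, "extrapolated") <- extrap
  eff
}

#' Predict combination outcome for a clinical dosing scenario
#'
#' Maps a drug amount and body weight to a whole-body concentration
#' (one-compartment distribution proportional to body mass), converts it to
#' a radiosensitizer effect through the linear concentration-effect model,
#' scales the radiopharmaceutical-monotherapy death rate by that effect
#' over the treatment duration, and reports the tumor size relative to
#' monotherapy with a 95 percent normal confidence interval from the
#' configured effect variance. Homologous-recombination deficiency enters
#' as a configured death-rate multiplier per HR-capability level.
#'
#' @param scenario list/data frame with `body_weight_kg`, `amount_mg`,
#'   `days`, and optionally `hr_capability` (default 1).
#' @param effect_model a [conc_effect_model()].
#' @param mu_dea_mono radiopharmaceutical-monotherapy death rate, per day.
#' @param vd_L_per_kg distribution volume per body mass (L/kg); the body
#'   concentration is `amount_mg / (body_weight_kg * vd_L_per_kg)`.
#' @param weight_exponent exponent of the body-weight scaling (default 1).
#' @param hrd_multipliers named vector of death-rate multipliers by HR
#'   capability (names are capability values, e.g. `"1"`, `"0.5"`).
#' @param effect_rel_sd relative standard deviation of the radiosensitizer
#'   effect used for the normal confidence interval.
#' @param drug optional drug name for IC50 scaling.
#' @return Data frame with one row per scenario: concentrations, effect,
#'   `rel_size` (tumor size relative to RPT monotherapy) and `ci_lo`,
#'   `ci_hi`.
#' @export
predict_combination <- function(scenario, effect_model, mu_dea_mono,
                                vd_L_per_kg = 1, weight_exponent = 1,
                                hrd_multipliers = c("1" = 1),
                                effect_rel_sd = 0, drug = NULL) {
  sc <- as.data.frame(scenario)
  if (is.null(sc$hr_capability)) sc$hr_capability <- 1
  body_conc <- sc$amount_mg /
    (sc$body_weight_kg^weight_exponent * vd_L_per_kg)
  eff <- as.numeric(concentration_to_effect(effect_model, body_conc,
                                            drug = drug))
  key <- as.character(sc$hr_capability)
  if (!all(key %in% names(hrd_multipliers)))
    stop("predict_combination: missing hrd_multipliers entry for ",
         paste(setdiff(key, names(hrd_multipliers)), collapse = ", "),
         call. = FALSE)
  mult <- unname(hrd_multipliers[key])
  # relative size vs monotherapy: exp(-(effect - 1) * mu_dea * t), with the
  # HRD multiplier acting on the monotherapy death rate
  expo <- (eff - 1) * mu_dea_mono * mult * sc$days
  rel <- exp(-expo)
  if (effect_rel_sd > 0) {
    z <- stats::qnorm(0.975)
    d_eff <- z * effect_rel_sd * eff
    lo <- exp(-(eff + d_eff - 1) * mu_dea_mono * mult * sc$days)
    hi <- exp(-(pmax(eff - d_eff, 1) - 1) * mu_dea_mono * mult * sc$days)
  } else {
    lo <- hi <- rel
  }
  data.frame(body_weight_kg = sc$body_weight_kg, amount_mg = sc$amount_mg,
             hr_capability = sc$hr_capability, days = sc$days,
             body_conc = body_conc, effect = eff,
             rel_size = rel, ci_lo = lo, ci_hi = hi)
}
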