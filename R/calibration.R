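# Calibration against survival-vs-activity data: bounded Levenberg-
# Marquardt least squares on log relative survival, plus the synthetic-data
# generator used for parameter-recovery studies.

# model-predicted endpoint relative survival for each initial activity
.predict_rel_survival <- function(activities, model, proto) {
  vapply(activities, function(A) {
    p <- proto; p$A0 <- A
    ensemble_simulate(p, model)$endpoint_rel_survival
  }, numeric(1))
}

# weights for log-survival residuals: sd(log obs) ~ sem / obs
.log_weights <- function(data) {
  if (!"sem" %in% names(data) || all(is.na(data$sem)) ||
      all(data$sem <= 0, na.rm = TRUE)) return(rep(1, nrow(data)))
  w <- data$survival / data$sem
  w[!is.finite(w) | w <= 0] <- stats::median(w[is.finite(w) & w > 0])
  w / mean(w)
}

# shared bounded multi-start Levenberg-Marquardt driver on log survival.
# `apply_par` maps a named parameter vector into a modified model.
.fit_survival_model <- function(data, model, proto, start, lower, upper,
                                apply_par, n_opt_starts = 5, seed = 1L,
                                maxiter = 50, log_params = names(start)) {
  if (!nrow(data)) stop("fit: empty dataset", call. = FALSE)
  if (any(data$survival <= 0))
    stop("fit: relative survival must be > 0", call. = FALSE)
  obs <- log(data$survival)
  w <- .log_weights(data)
  acts <- data$activity_Bq
  nm <- names(start)
  is_log <- nm %in% log_params
  # strictly positive scale parameters are fitted on log10 scale: the
  # landscape is far better conditioned across orders of magnitude
  to_theta <- function(p) { p[is_log] <- log10(p[is_log]); p }
  to_par <- function(th) { th[is_log] <- 10^th[is_log]; th }
  resid_fn <- function(theta) {
    m <- apply_par(to_par(theta))
    pred <- .predict_rel_survival(acts, m, proto)
    w * (log(pmax(pred, 1e-300)) - obs)
  }
  set.seed(seed)
  starts <- list(to_theta(start))
  if (n_opt_starts > 1) {
    # probe a Latin hypercube around the user start (one decade on log
    # parameters, +/- 10 % on linear ones) with cheap single objective
    # evaluations, then descend from the best probes; far more robust on
    # this multimodal landscape than blind restarts
    n_probe <- max(20L, 8L * length(start))
    cube <- lhs::randomLHS(n_probe, length(start))
    probes <- lapply(seq_len(n_probe), function(i) {
      cand <- start
      cand[is_log] <- cand[is_log] * 10^(2 * (cube[i, is_log] - 0.5))
      cand[!is_log] <- cand[!is_log] * (1 + 0.2 * (cube[i, !is_log] - 0.5))
      to_theta(pmin(pmax(cand, lower), upper))
    })
    ssr <- vapply(probes, function(th)
      sum(resid_fn(th)^2), numeric(1))
    starts <- c(starts, probes[order(ssr)[seq_len(n_opt_starts - 1L)]])
  }
  lower <- to_theta(lower); upper <- to_theta(upper)
  best <- NULL
  diags <- list()
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-10, ftol = 1e-12,
                           # finite-difference step must clear the ODE
                           # solver noise floor
                           epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(fit)) next
    diags[[length(diags) + 1L]] <-
      data.frame(start = i, ssr = fit$deviance, niter = fit$niter,
                 info = fit$info)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("fit: no optimizer start converged", call. = FALSE)
  par <- stats::setNames(as.numeric(to_par(unlist(best$par))), nm)
  fitted_model <- apply_par(par)
  pred <- .predict_rel_survival(acts, fitted_model, proto)
  dev_pct <- 100 * abs(pred - data$survival) / data$survival
  structure(list(
    par = par, lower = lower, upper = upper,
    residuals = best$fvec,
    predicted = pred, observed = data$survival,
    deviation_pct = c(mean = mean(dev_pct), sd = stats::sd(dev_pct)),
    model = fitted_model,
    convergence = list(info = best$info, message = best$message,
                       niter = best$niter, deviance = best$deviance,
                       starts = do.call(rbind, diags))),
    class = "rpt_fit")
}

#' @export
print.rpt_fit <- function(x, ...) {
  cat("<rpt_fit>\n  parameters:\n")
  for (nm in names(x$par))
    cat(sprintf("    %-22s %.6g\n", nm, x$par[[nm]]))
  cat(sprintf("  mean deviation: %.2f %% (SD %.2f %%), SSR %.4g, %d iter\n",
              x$deviation_pct[["mean"]], x$deviation_pct[["sd"]],
              x$convergence$deviance, x$convergence$niter))
  invisible(x)
}

#' Fit radionuclide kinetic parameters to monotherapy survival data
#'
#' Bounded Levenberg-Marquardt least squares on log relative survival with
#' exactly four free parameters (`k_on`, `k_off`, `k_int`, `k_rel`); all
#' radiobiological parameters stay fixed at the values in `model`.
#' Residuals are weighted by `survival / sem` (the delta-method standard
#' deviation of log survival) when SEMs are available. Multiple seeded
#' starting points guard against local minima.
#'
#' @param data survival dataset: data frame with columns `activity_Bq`,
#'   `survival` (relative to untreated), optional `sem`, optional
#'   `condition` (rows other than monotherapy are ignored when a
#'   `condition` column is present).
#' @param model an [rpt_model()] whose kinetics provide the fixed decay
#'   rate; its `cellcycle$n_starts` and solver settings control the cost of
#'   each objective evaluation.
#' @param proto a [protocol()] template; `A0` is overridden per data row.
#' @param start named start values for the four rates (defaults to 0.1
#'   each, per hour resp. per nmol/L per hour).
#' @param lower,upper box bounds on the rates.
#' @param n_opt_starts number of optimizer starting points (first is
#'   `start`, the rest seeded log-uniform perturbations).
#' @param seed seed for the multi-start draws.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return An object of class `rpt_fit`; `$par` holds the estimates,
#'   `$model` the refitted model, `$deviation_pct` the mean and SD of the
#'   percent deviations `100 |pred - obs| / obs`.
#' @export
fit_kinetics <- function(data, model, proto,
                         start = c(k_on = 0.1, k_off = 0.1,
                                   k_int = 0.1, k_rel = 0.1),
                         lower = start / 300, upper = start * 300,
                         n_opt_starts = 5, seed = 1L, maxiter = 50) {
  if ("condition" %in% names(data))
    data <- data[data$condition == "mono", , drop = FALSE]
  if (length(unique(data$activity_Bq)) < 4L)
    stop("fit_kinetics: need at least 4 activity levels", call. = FALSE)
  mu_dec <- model$kinetics$mu_dec
  apply_par <- function(par) {
    m <- model
    m$kinetics <- kinetic_params(par[["k_on"]], par[["k_off"]],
                                 par[["k_int"]], par[["k_rel"]], mu_dec)
    m$parpi <- parpi_model("none")
    m
  }
  .fit_survival_model(data, model, proto, start, lower, upper, apply_par,
                      n_opt_starts = n_opt_starts, seed = seed,
                      maxiter = maxiter)
}

#' Fit PARP-inhibitor parameters with kinetics held fixed
#'
#' One-parameter fit of the constant survival term `mu_parpi` for an
#' Olaparib-style drug (`"constant_only"`), or a two-parameter fit of
#' `mu_parpi` together with either a replacement SSB repair rate
#' (`"reduced_ssb_repair"`) or the abundance-coupled reduction rate
#' (`"decaying_ssb_repair"`, Rucaparib-style) — PARP trapping enters through
#' slowed SSB clearance and subsequent replication-driven conversion to
#' DSBs.
#'
#' @param data survival dataset for the drug-combination arm (columns as in
#'   [fit_kinetics()]).
#' @param model an [rpt_model()] with calibrated kinetics.
#' @param proto a [protocol()] template.
#' @param mode the PARPi mechanism to fit.
#' @param start named start values (`mu_parpi` plus `lambda_ssb_override`
#'   or `lambda_red` for the two-parameter modes).
#' @param lower,upper box bounds.
#' @param n_opt_starts,seed,maxiter as in [fit_kinetics()].
#' @return An `rpt_fit` object.
#' @export
fit_parpi <- function(data, model, proto,
                      mode = c("constant_only", "reduced_ssb_repair",
                               "decaying_ssb_repair"),
                      start = NULL, lower = NULL, upper = NULL,
                      n_opt_starts = 5, seed = 1L, maxiter = 50) {
  mode <- match.arg(mode)
  if (is.null(start))
    start <- switch(mode,
                    constant_only = c(mu_parpi = 0.95),
                    reduced_ssb_repair = c(mu_parpi = 0.95,
                                           lambda_ssb_override = 0.5),
                    decaying_ssb_repair = c(mu_parpi = 0.95,
                                            lambda_red = 0.005))
  if (is.null(lower)) {
    lower <- start; lower["mu_parpi"] <- 0.5
    if (length(start) > 1L) lower[2L] <- start[[2L]] / 1000
  }
  if (is.null(upper)) {
    upper <- start; upper["mu_parpi"] <- 1
    if (length(start) > 1L) upper[2L] <- start[[2L]] * 1000
  }
  apply_par <- function(par) {
    m <- model
    m$parpi <- switch(mode,
      constant_only = parpi_model("constant_only",
                                  mu_parpi = par[["mu_parpi"]]),
      reduced_ssb_repair = parpi_model("reduced_ssb_repair",
        mu_parpi = par[["mu_parpi"]],
        lambda_ssb_override = par[["lambda_ssb_override"]]),
      decaying_ssb_repair = parpi_model("decaying_ssb_repair",
        mu_parpi = par[["mu_parpi"]],
        lambda_red = par[["lambda_red"]]))
    m
  }
  .fit_survival_model(data, model, proto, start, lower, upper, apply_par,
                      n_opt_starts = n_opt_starts, seed = seed,
                      maxiter = maxiter,
                      log_params = setdiff(names(start), "mu_parpi"))
}

#' Generate a synthetic survival-vs-activity dataset
#'
#' Runs the ensemble simulation at each initial activity and emulates the
#' replicate structure of a survival assay: multiplicative lognormal noise
#' with the stated coefficient of variation per technical replicate
#' (`n_bio` biological repeats times `n_tech` technical replicates),
#' aggregated to mean and standard error. Reproducible for a given seed.
#'
#' @param model an [rpt_model()] (its PARPi slot defines the condition).
#' @param proto a [protocol()] template; `A0` is overridden per activity.
#' @param activities initial activities, Bq.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   replicate noise (0 returns the model predictions exactly).
#' @param n_bio,n_tech biological repeats and technical replicates per
#'   repeat (defaults 3 and 4, within the 3-6 range typical of the assay).
#' @param condition label stored in the `condition` column.
#' @param seed RNG seed.
#' @return Data frame with columns `activity_Bq`, `condition`, `survival`,
#'   `sem`, `n_rep`, plus attribute `truth` (the noise-free predictions).
#' @export
generate_synthetic_survival <- function(model, proto, activities,
                                        noise_cv = 0.1, n_bio = 3,
                                        n_tech = 4, condition = "mono",
                                        seed = 1L) {
  set.seed(seed)
  truth <- .predict_rel_survival(activities, model, proto)
  n_rep <- n_bio * n_tech
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    reps <- lapply(truth, function(mu)
      mu * stats::rlnorm(n_rep, meanlog = -sdlog^2 / 2, sdlog = sdlog))
    mean_s <- vapply(reps, mean, numeric(1))
    sem_s <- vapply(reps, function(r) stats::sd(r) / sqrt(length(r)),
                    numeric(1))
  } else {
    mean_s <- truth
    sem_s <- rep(0, length(truth))
  }
  structure(data.frame(activity_Bq = activities, condition = condition,
                       survival = mean_s, sem = sem_s, n_rep = n_rep),
            truth = truth)
}

#' Per-condition validation report
#'
#' Percent deviation `100 |pred - obs| / obs` per data point, summarized as
#' mean and standard deviation per condition.
#'
#' @param data survival dataset (columns `activity_Bq`, `condition`,
#'   `survival`).
#' @param predicted model predictions aligned with the rows of `data`.
#' @return Data frame with one row per condition: `condition`, `n`,
#'   `mean_dev_pct`, `sd_dev_pct`.
#' @export
validation_report <- function(data, predicted) {
  if (length(predicted) != nrow(data))
    stop("validation_report: 'predicted' must match the rows of 'data'",
         call. = FALSE)
  dev <- 100 * abs(predicted - data$survival) / data$survival
  cond <- if ("condition" %in% names(data)) data$condition
          else rep("all", nrow(data))
  out <- do.call(rbind, lapply(split(dev, cond), function(d)
    data.frame(n = length(d), mean_dev_pct = mean(d),
               sd_dev_pct = if (length(d) > 1) stats::sd(d) else 0)))
  data.frame(condition = rownames(out), out, row.names = NULL)
}
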