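# Trajectory engine: integrates the coupled kinetics-dose-damage-survival-
# population system piecewise over cell-cycle phase segments and protocol
# events (washout, PARPi stop, EBRT impulse) for one cell-cycle starting
# point, and averages an ensemble of starting points.
#
# Unified state vector (17 slots). Outside S phase the "_rl" damage slots
# hold the whole pools and the "_url" slots are inert at zero; at the G1->S
# transition pools move into "_url", at S->G2 residuals merge back.
.STATE_NAMES <- c("c_m", "c_acs", "c_dcs", "c_acy", "c_dcy", "D",
                  "ssb_url", "ssb_rl", "dsb_f_url", "dsb_f_rl",
                  "dsb_s_url", "dsb_s_rl", "dsb_m", "s_prog",
                  "S", "N_alive", "N_dead")

#' Cell-cycle phase schedule for one starting point
#'
#' Phases G1, S, G2, M repeat with durations proportional to the configured
#' ratios scaled to the cycle length; the first segment is the remainder of
#' the phase containing the start offset. Start offsets are evenly spaced:
#' start `k` (0-based) sits at `k / n_starts` of the cycle, measured from
#' the beginning of G1.
#'
#' @param config a [cellcycle_config()] object.
#' @param start_index 0-based starting-point index in `0:(n_starts - 1)`.
#' @param horizon schedule horizon, h (> 0).
#' @return Data frame with columns `phase`, `t_start`, `t_end`.
#' @export
build_phase_schedule <- function(config, start_index, horizon) {
  if (horizon <= 0) stop("build_phase_schedule: 'horizon' must be > 0",
                         call. = FALSE)
  if (start_index < 0 || start_index >= config$n_starts)
    stop("build_phase_schedule: 'start_index' must lie in 0:(n_starts - 1)",
         call. = FALSE)
  offset <- (start_index / config$n_starts) * config$cycle_length
  dur <- config$durations
  ends <- cumsum(dur)
  ph_idx <- which(offset < ends - 1e-9)[1]
  if (is.na(ph_idx)) { ph_idx <- 1L; offset <- 0 }  # offset at cycle end
  pos <- offset  # position within cycle from G1 start
  phases <- character(0); t0 <- numeric(0); t1 <- numeric(0)
  t <- 0
  idx <- ph_idx
  # remainder of the current phase
  remain <- ends[idx] - pos
  repeat {
    phases <- c(phases, names(dur)[idx])
    t0 <- c(t0, t)
    seg_end <- min(t + remain, horizon)
    t1 <- c(t1, seg_end)
    t <- t + remain
    if (t >= horizon - 1e-12) break
    idx <- if (idx == 4L) 1L else idx + 1L
    remain <- dur[[idx]]
  }
  data.frame(phase = phases, t_start = t0, t_end = t1,
             stringsAsFactors = FALSE)
}

# fraction of the S phase already elapsed at t = 0 for this start point
# (0 unless the start offset falls inside S)
.initial_sprog <- function(config, start_index) {
  offset <- (start_index / config$n_starts) * config$cycle_length
  dur <- config$durations
  s_start <- dur[["G1"]]
  s_end <- s_start + dur[["S"]]
  if (offset >= s_start - 1e-9 && offset < s_end - 1e-9)
    (offset - s_start) / dur[["S"]]
  else 0
}

# instantaneous EBRT lesion jump at the current phase / s_prog
.apply_ebrt_impulse <- function(y, dose, model, phase) {
  rp <- model$repair
  opt <- model$options
  if (phase == "S") {
    s <- min(y[["s_prog"]], 1 - opt$eps_sprog)
    pr <- repair_probabilities(rp$p_c, rp$p_HR, "S")
    if (opt$s_induction_literal) {
      wfu <- wsu <- wfr <- wsr <- wmr <- 1
    } else {
      wfu <- 1 - rp$p_c; wsu <- rp$p_c
      wfr <- pr[["p_f"]]; wsr <- pr[["p_s"]]; wmr <- pr[["p_m"]]
    }
    y["ssb_url"] <- y[["ssb_url"]] + rp$k_ssb * (1 - s) * dose
    y["ssb_rl"] <- y[["ssb_rl"]] + rp$k_ssb * s * dose
    y["dsb_f_url"] <- y[["dsb_f_url"]] + wfu * rp$k_dsb * (1 - s) * dose
    y["dsb_s_url"] <- y[["dsb_s_url"]] + wsu * rp$k_dsb * (1 - s) * dose
    y["dsb_f_rl"] <- y[["dsb_f_rl"]] + wfr * 2 * rp$k_dsb * s * dose
    y["dsb_s_rl"] <- y[["dsb_s_rl"]] + wsr * 2 * rp$k_dsb * s * dose
    y["dsb_m"] <- y[["dsb_m"]] + wmr * 2 * rp$k_dsb * s * dose
  } else {
    n_gen <- if (phase == "G1") 1 else 2
    pr <- repair_probabilities(rp$p_c, rp$p_HR, phase)
    y["ssb_rl"] <- y[["ssb_rl"]] + n_gen * rp$k_ssb * dose
    y["dsb_f_rl"] <- y[["dsb_f_rl"]] + pr[["p_f"]] * n_gen * rp$k_dsb * dose
    y["dsb_s_rl"] <- y[["dsb_s_rl"]] + pr[["p_s"]] * n_gen * rp$k_dsb * dose
    y["dsb_m"] <- y[["dsb_m"]] + pr[["p_m"]] * n_gen * rp$k_dsb * dose
  }
  y["D"] <- y[["D"]] + dose
  y
}

# parameter vector for the compiled right-hand side (order must match
# src/rpt_rhs.c)
.rhs_parms <- function(model, phase, A0cur, t_ref, parpi_active,
                       forced_doserate = NULL) {
  kin <- model$kinetics; sv <- model$svalues; rp <- model$repair
  spar <- model$survival; cc <- model$cellcycle; opt <- model$options
  parpi <- if (parpi_active) model$parpi else parpi_model("none")
  in_s <- phase == "S"
  ssb_mode <- switch(parpi$mode, none = 0, constant_only = 0,
                     reduced_ssb_repair = 1,
                     decaying_ssb_repair =
                       if (parpi$decay_form == "exponential") 2 else 3)
  c(kin$k_on, kin$k_off, kin$k_int, kin$k_rel, kin$mu_dec,
    model$receptors$R_cell,
    sv$S_m, sv$S_cs, sv$S_cy,
    rp$k_ssb, rp$lambda_ssb, rp$k_dsb,
    rp$lambda_f, rp$lambda_s, rp$lambda_m,
    rp$p_c, rp$p_HR,
    if (in_s) 0 else spar$a[[phase]], if (in_s) 0 else spar$b[[phase]],
    spar$a0, spar$b0, spar$a1, spar$b1,
    spar$psi, spar$phi, spar$dsb_checkpoint_cap,
    cc$mu_gr, cc$mu_inter,
    match(phase, c("G1", "S", "G2", "M")),
    if (phase == "G1") 1 else 2,
    as.numeric(phase %in% spar$apop_phases),
    as.numeric(phase %in% spar$mitot_phases),
    parpi$mu_parpi,
    ssb_mode,
    if (ssb_mode == 1) parpi$lambda_ssb_override else 0,
    if (ssb_mode >= 2) parpi$lambda_red else 0,
    opt$eps_sprog,
    as.numeric(opt$s_induction_literal),
    as.numeric(opt$receptor_literal),
    A0cur, t_ref,
    as.numeric(!is.null(forced_doserate)),
    if (is.null(forced_doserate)) 0 else forced_doserate)
}

#' Simulate one cell-cycle starting point
#'
#' Integrates the coupled compartment-dose-damage-survival-population system
#' from t = 0 (radiopharmaceutical addition, 24 h after seeding by default)
#' to the protocol endpoint, piecewise over cell-cycle phase segments and
#' protocol events. At the G1 to S transition lesion pools move to the
#' unreplicated slots and replication progress restarts; the S segment ends
#' when replication progress reaches `1 - eps`, at which point residual
#' unreplicated lesions merge into the corresponding G2 pools; at mitosis
#' lesion counts halve (partitioning between daughters) and the genome
#' count drops back to 1. The washout event empties the medium and
#' dead-cell compartments, removes dead cells, and rebases the activity to
#' the ligand retained on and in living cells.
#'
#' @param start_index 0-based cell-cycle starting-point index.
#' @param protocol a [protocol()] object.
#' @param model an [rpt_model()] object.
#' @param forced_doserate optional constant absorbed dose rate (Gy/h)
#'   applied while t < `rpt_exposure`, bypassing the compartment dosimetry
#'   (used for idealized constant-rate irradiation).
#' @return An object of class `rpt_trajectory`: a data frame with the time
#'   grid, all state variables, activity, dose rate and death rate, plus
#'   attributes `start_offset` (h into the cycle at t = 0) and `schedule`.
#' @export
simulate_trajectory <- function(start_index, protocol, model,
                                forced_doserate = NULL) {
  cc <- model$cellcycle
  opt <- model$options
  sol <- model$solver
  horizon <- protocol$endpoint
  sched <- build_phase_schedule(cc, start_index, horizon)

  # shift S->G2 boundaries so the S segment ends at s_prog = 1 - eps
  shift <- opt$eps_sprog / cc$mu_inter
  for (i in seq_len(nrow(sched) - 1L)) {
    if (sched$phase[i] == "S" && sched$t_end[i] - sched$t_start[i] > shift) {
      sched$t_end[i] <- sched$t_end[i] - shift
      sched$t_start[i + 1L] <- sched$t_end[i]
    }
  }

  events <- sort(unique(c(protocol$rpt_exposure, protocol$parpi_exposure)))
  events <- events[events > 0 & events < horizon]
  breaks <- sort(unique(c(0, sched$t_end, events, horizon)))
  breaks <- breaks[breaks <= horizon + 1e-12]

  phase_at <- function(t) {
    i <- findInterval(t + 1e-9, c(0, sched$t_end)) # segment containing t
    sched$phase[min(i, nrow(sched))]
  }

  # initial state
  N0 <- protocol$n_seeded * exp(cc$mu_gr * protocol$seeding_offset)
  cm0 <- protocol$A0 / (protocol$molar_activity * protocol$volume) * 1e9
  y <- stats::setNames(numeric(17), .STATE_NAMES)
  y["c_m"] <- cm0; y["S"] <- 1; y["N_alive"] <- N0
  ph0 <- phase_at(0)
  if (ph0 == "S") y["s_prog"] <- .initial_sprog(cc, start_index)
  if (ph0 != "S") {
    # outside S the whole pools live in the "_rl" slots (nothing to do:
    # all lesions start at zero)
  }
  ds <- dose_state(protocol$A0, model$kinetics$mu_dec)
  if (protocol$ebrt_dose > 0)
    y <- .apply_ebrt_impulse(y, protocol$ebrt_dose, model, ph0)

  grid <- unique(sort(c(seq(0, horizon, by = sol$dt_out), breaks)))
  out <- list()
  prev_phase <- ph0
  parpi_on <- protocol$parpi_exposure > 0 && model$parpi$mode != "none"

  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    phase <- phase_at(t0)

    # phase-transition state maps at the segment opening
    if (phase != prev_phase) {
      if (prev_phase == "G1" && phase == "S") {
        y["ssb_url"] <- y[["ssb_rl"]]; y["ssb_rl"] <- 0
        y["dsb_f_url"] <- y[["dsb_f_rl"]]; y["dsb_f_rl"] <- 0
        y["dsb_s_url"] <- y[["dsb_s_rl"]]; y["dsb_s_rl"] <- 0
        y["s_prog"] <- 0
      } else if (prev_phase == "S" && phase == "G2") {
        # residual unreplicated lesions merge into the G2 pools
        y["ssb_rl"] <- y[["ssb_rl"]] + y[["ssb_url"]]
        y["dsb_f_rl"] <- y[["dsb_f_rl"]] + y[["dsb_f_url"]]
        y["dsb_s_rl"] <- y[["dsb_s_rl"]] + y[["dsb_s_url"]]
        y["ssb_url"] <- 0; y["dsb_f_url"] <- 0; y["dsb_s_url"] <- 0
        y["s_prog"] <- 0
      } else if (prev_phase == "M" && phase == "G1") {
        if (opt$mitosis_halves_lesions) {
          les <- c("ssb_rl", "dsb_f_rl", "dsb_s_rl", "dsb_m")
          y[les] <- y[les] / 2
        }
      }
      prev_phase <- phase
    }

    # protocol events firing at the segment opening
    if (abs(t0 - protocol$rpt_exposure) < 1e-9) {
      w <- apply_washout(compartment_state(y[["c_m"]], y[["c_acs"]],
                                           y[["c_dcs"]], y[["c_acy"]],
                                           y[["c_dcy"]]),
                         y[["N_dead"]], ds, t0)
      y[1:5] <- as.numeric(w$state)
      y["N_dead"] <- 0
      ds <- w$dose_state
    }
    if (abs(t0 - protocol$parpi_exposure) < 1e-9) parpi_on <- FALSE

    seg_times <- unique(sort(c(t0, grid[grid > t0 & grid < t1], t1)))
    fdr <- if (is.null(forced_doserate)) NULL
      else if (t0 < protocol$rpt_exposure - 1e-9) forced_doserate else 0
    pv <- .rhs_parms(model, phase, ds$A0, ds$t_ref, parpi_on, fdr)
    sol_out <- deSolve::ode(y = y, times = seg_times, func = "rpt_derivs",
                            parms = pv, dllname = "rptparpi",
                            initfunc = "rpt_initmod", nout = 3,
                            outnames = c("A_Bq", "doserate", "mu_dea"),
                            method = sol$method,
                            rtol = sol$rtol, atol = sol$atol)
    if (attr(sol_out, "istate")[1L] < 0)
      stop(sprintf(paste0("simulate_trajectory: solver failure in segment ",
                          "[%.3f, %.3f] (phase %s, start %d)"),
                   t0, t1, phase, start_index), call. = FALSE)
    m <- unclass(sol_out)
    # at internal boundaries keep the opening (post-event/post-transition)
    # row of the next segment, not the closing row of this one
    keep <- if (k == length(breaks) - 1L) seq_len(nrow(m))
            else seq_len(nrow(m) - 1L)
    out[[k]] <- cbind(m[keep, , drop = FALSE],
                      phase_id = match(phase, c("G1", "S", "G2", "M")))
    y <- m[nrow(m), 1L + seq_len(17L)]
    names(y) <- .STATE_NAMES
    if (any(y < -1e-6 * max(1, max(abs(y)))))
      stop("simulate_trajectory: negative state beyond tolerance at t = ",
           signif(breaks[k + 1L], 6), call. = FALSE)
    y[y < 0] <- 0
  }

  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("t_h", .STATE_NAMES, "A_Bq", "doserate_Gy_per_h",
                 "mu_dea", "phase_id")
  df$phase <- c("G1", "S", "G2", "M")[df$phase_id]
  df$phase_id <- NULL
  df$N_dsb <- df$dsb_f_url + df$dsb_f_rl + df$dsb_s_url + df$dsb_s_rl +
    df$dsb_m
  structure(df, class = c("rpt_trajectory", "data.frame"),
            start_index = start_index,
            start_offset = (start_index / cc$n_starts) * cc$cycle_length,
            schedule = sched)
}

#' Ensemble simulation over cell-cycle starting points
#'
#' Runs one trajectory per starting point, linearly interpolates each onto
#' a common time grid, and averages. The endpoint relative survival is the
#' mean living-cell count at the endpoint relative to an untreated control
#' simulation of the same protocol (zero activity, no drug, same washout
#' handling).
#'
#' @param protocol a [protocol()] object.
#' @param model an [rpt_model()] object.
#' @param keep_trajectories retain the per-start trajectories in the result.
#' @param forced_doserate passed through to [simulate_trajectory()].
#' @return An object of class `rpt_ensemble`: list with `grid` (data frame
#'   of per-variable means over start points, plus `rel_survival`),
#'   `endpoint_rel_survival`, `control` (control trajectory), and
#'   optionally `trajectories`.
#' @export
ensemble_simulate <- function(protocol, model, keep_trajectories = FALSE,
                              forced_doserate = NULL) {
  cc <- model$cellcycle
  n <- cc$n_starts
  trajs <- lapply(seq_len(n) - 1L, simulate_trajectory, protocol = protocol,
                  model = model, forced_doserate = forced_doserate)

  ctrl_proto <- protocol
  ctrl_proto$A0 <- 0
  ctrl_proto$ebrt_dose <- 0
  ctrl_model <- model
  ctrl_model$parpi <- parpi_model("none")
  ctrl <- simulate_trajectory(0L, ctrl_proto, ctrl_model)

  grid_t <- seq(0, protocol$endpoint, by = model$solver$dt_out)
  vars <- setdiff(names(trajs[[1L]]), c("t_h", "phase"))
  interp <- function(tr, v) stats::approx(tr$t_h, tr[[v]], xout = grid_t,
                                          rule = 2)$y
  means <- sapply(vars, function(v) {
    rowMeans(sapply(trajs, interp, v = v))
  })
  grid <- data.frame(t_h = grid_t, means, check.names = FALSE)
  ctrl_n <- interp(ctrl, "N_alive")
  grid$rel_survival <- grid$N_alive / ctrl_n
  res <- list(grid = grid,
              endpoint_rel_survival = grid$rel_survival[nrow(grid)],
              endpoint_dose = grid$D[nrow(grid)],
              control = ctrl)
  if (keep_trajectories) res$trajectories <- trajs
  structure(res, class = "rpt_ensemble")
}

#' @export
print.rpt_ensemble <- function(x, ...) {
  cat("<rpt_ensemble>\n")
  cat(sprintf("  endpoint: %.1f h, mean nucleus dose %.3g Gy\n",
              max(x$grid$t_h), x$endpoint_dose))
  cat(sprintf("  endpoint relative survival: %.4g\n",
              x$endpoint_rel_survival))
  invisible(x)
}

#' Per-phase survival-probability reductions
#'
#' Aggregates the drop in log survival probability over each completed
#' cell-cycle phase occurrence, per starting point, and averages by phase.
#' Because `-ln S` is additive over time, the per-occurrence reductions of
#' one trajectory sum to `-ln S(endpoint)` up to interpolation error.
#'
#' @param trajectories list of [simulate_trajectory()] results (e.g.
#'   `ensemble_simulate(..., keep_trajectories = TRUE)$trajectories`).
#' @return List with `by_phase` (named mean reduction per phase) and
#'   `occurrences` (data frame of every completed phase occurrence with its
#'   reduction).
#' @export
phase_death_rates <- function(trajectories) {
  if (inherits(trajectories, "rpt_trajectory"))
    trajectories <- list(trajectories)
  rows <- do.call(rbind, lapply(trajectories, function(tr) {
    sched <- attr(tr, "schedule")
    horizon <- max(tr$t_h)
    lnS <- function(t) stats::approx(tr$t_h, log(tr$S), xout = t,
                                     rule = 2)$y
    done <- sched[sched$t_end <= horizon + 1e-9, , drop = FALSE]
    if (!nrow(done)) return(NULL)
    data.frame(start_index = attr(tr, "start_index"),
               phase = done$phase, t_start = done$t_start,
               t_end = done$t_end,
               reduction = lnS(done$t_start) - lnS(done$t_end))
  }))
  by_phase <- tapply(rows$reduction, factor(rows$phase,
                                            c("G1", "S", "G2", "M")),
                     mean)
  list(by_phase = by_phase, occurrences = rows)
}
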