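# Shared fixtures: the synthetic baseline parameter set (built in code, not
# read from disk) and two independent oracles -- a fixed-step explicit Euler
# integrator composed from the exported per-module rate functions, and a
# discrete per-lesion replication simulator.

baseline_repair <- function(p_HR = 1)
  repair_params(k_ssb = 1000, lambda_ssb = 2, k_dsb = 35,
                lambda_f = 2, lambda_s = 0.25, lambda_m = 0.04,
                p_c = 0.4, p_HR = p_HR)

baseline_model <- function(n_starts = 6, p_HR = 1,
                           parpi = parpi_model("none"),
                           rtol = 1e-7, atol = 1e-9, dt_out = 2,
                           options = list()) {
  rpt_model(
    kinetics = kinetic_params(k_on = 0.3, k_off = 0.1, k_int = 0.3,
                              k_rel = 0.05),
    receptors = receptor_model(1.6e-5),
    svalues = svalue_set(S_m = 5e-9, S_cs = 2.5e-5, S_cy = 1.2e-4),
    repair = baseline_repair(p_HR),
    survival = survival_params(a = -1e-5, b = -1e-3, psi = 0.002,
                               phi = 0.03),
    cellcycle = cellcycle_config(mu_gr = log(2) / 24, n_starts = n_starts),
    parpi = parpi,
    solver = list(rtol = rtol, atol = atol, dt_out = dt_out),
    options = options)
}

baseline_protocol <- function(A0 = 1e5, ...)
  protocol(A0 = A0, molar_activity = 1e17, volume = 1e-4, ...)

random_compartment_state <- function() {
  # receptors sized so that bound ligand can stay below capacity
  n_alive <- runif(1, 1e3, 1e5)
  n_dead <- runif(1, 0, 1e4)
  R_cell <- 10^runif(1, -6, -4)
  list(state = compartment_state(
         c_m = runif(1, 0, 10),
         c_acs = runif(1, 0, R_cell * n_alive),
         c_dcs = runif(1, 0, R_cell * n_dead),
         c_acy = runif(1, 0, 5),
         c_dcy = runif(1, 0, 5)),
       receptors = receptor_model(R_cell),
       n_alive = n_alive, n_dead = n_dead)
}

random_kinetic_params <- function()
  kinetic_params(k_on = runif(1, 0, 2), k_off = runif(1, 0, 2),
                 k_int = runif(1, 0, 2), k_rel = runif(1, 0, 2),
                 mu_dec = runif(1, 0, 0.1))

# ---------------------------------------------------------------------------
# Fixed-step explicit Euler integrator built from the exported module-level
# rate functions. Deliberately independent of the compiled trajectory
# engine: phases, events and state maps are re-derived here from the same
# protocol contracts.
euler_trajectory <- function(start_index, proto, model, dt = 1e-3) {
  cc <- model$cellcycle
  eps <- model$options$eps_sprog
  sched <- build_phase_schedule(cc, start_index, proto$endpoint)
  shift <- eps / cc$mu_inter
  for (i in seq_len(max(nrow(sched) - 1L, 0))) {
    if (sched$phase[i] == "S" &&
        sched$t_end[i] - sched$t_start[i] > shift) {
      sched$t_end[i] <- sched$t_end[i] - shift
      sched$t_start[i + 1L] <- sched$t_end[i]
    }
  }
  events <- c(proto$rpt_exposure, proto$parpi_exposure)
  breaks <- sort(unique(c(0, sched$t_end, events[events < proto$endpoint],
                          proto$endpoint)))
  breaks <- breaks[breaks >= 0 & breaks <= proto$endpoint]
  phase_of <- function(t) sched$phase[findInterval(t + 1e-9,
                                                   c(0, sched$t_end))]

  comp <- compartment_state(
    c_m = proto$A0 / (proto$molar_activity * proto$volume) * 1e9)
  ds <- dose_state(proto$A0, model$kinetics$mu_dec)
  N_alive <- proto$n_seeded * exp(cc$mu_gr * proto$seeding_offset)
  N_dead <- 0; S <- 1; D <- 0
  dmg_i <- c(N_ssb = 0, N_dsb_f = 0, N_dsb_s = 0, N_dsb_m = 0)
  dmg_s <- NULL
  prev_phase <- phase_of(0)
  if (prev_phase == "S") {
    dmg_s <- c(N_ssb_url = 0, N_ssb_rl = 0, N_dsb_f_url = 0,
               N_dsb_f_rl = 0, N_dsb_s_url = 0, N_dsb_s_rl = 0,
               N_dsb_m = 0,
               s_prog = rptparpi:::.initial_sprog(cc, start_index))
  }
  parpi_on <- model$parpi$mode != "none"

  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    phase <- phase_of(t0)
    if (phase != prev_phase) {
      if (prev_phase == "G1" && phase == "S") {
        dmg_s <- c(N_ssb_url = dmg_i[["N_ssb"]], N_ssb_rl = 0,
                   N_dsb_f_url = dmg_i[["N_dsb_f"]], N_dsb_f_rl = 0,
                   N_dsb_s_url = dmg_i[["N_dsb_s"]], N_dsb_s_rl = 0,
                   N_dsb_m = dmg_i[["N_dsb_m"]], s_prog = 0)
      } else if (prev_phase == "S" && phase == "G2") {
        dmg_i <- c(N_ssb = dmg_s[["N_ssb_url"]] + dmg_s[["N_ssb_rl"]],
                   N_dsb_f = dmg_s[["N_dsb_f_url"]] + dmg_s[["N_dsb_f_rl"]],
                   N_dsb_s = dmg_s[["N_dsb_s_url"]] + dmg_s[["N_dsb_s_rl"]],
                   N_dsb_m = dmg_s[["N_dsb_m"]])
        dmg_s <- NULL
      } else if (prev_phase == "M" && phase == "G1") {
        if (model$options$mitosis_halves_lesions) dmg_i <- dmg_i / 2
      }
      prev_phase <- phase
    }
    if (abs(t0 - proto$rpt_exposure) < 1e-9) {
      w <- apply_washout(comp, N_dead, ds, t0)
      comp <- w$state; N_dead <- 0; ds <- w$dose_state
    }
    if (abs(t0 - proto$parpi_exposure) < 1e-9) parpi_on <- FALSE
    parpi_eff <- if (parpi_on) model$parpi else parpi_model("none")

    n_steps <- max(1L, ceiling((t1 - t0) / dt))
    h <- (t1 - t0) / n_steps
    t <- t0
    for (i in seq_len(n_steps)) {
      A <- activity_at(t, ds)
      dr <- dose_rate(comp, A, model$svalues, N_alive)
      if (phase == "S") {
        mu_dea <- survival_rate(dmg_s, dr, model$repair, model$survival,
                                parpi_eff, "S")
        dd <- s_phase_damage_rates(dmg_s, dr, model$repair, cc$mu_inter,
                                   parpi_eff, eps = eps,
                                   s_induction_literal =
                                     model$options$s_induction_literal)
        dmg_s <- dmg_s + h * dd
        dmg_s[dmg_s < 0] <- 0
        dmg_s[["s_prog"]] <- min(dmg_s[["s_prog"]], 1 - eps)
      } else {
        mu_dea <- survival_rate(dmg_i, dr, model$repair, model$survival,
                                parpi_eff, phase)
        dd <- interphase_damage_rates(dmg_i, dr, model$repair, phase,
                                      parpi = parpi_eff)
        dmg_i <- dmg_i + h * dd
        dmg_i[dmg_i < 0] <- 0
      }
      dc <- compartment_rates(comp, model$kinetics, model$receptors,
                              N_alive, N_dead, mu_dea)
      comp <- comp + h * dc
      comp[comp < 0] <- 0
      D <- D + h * dr
      S <- S + h * (-mu_dea * S)
      N_dead <- N_dead + h * mu_dea * N_alive
      N_alive <- N_alive + h * (cc$mu_gr - mu_dea) * N_alive
      t <- t + h
    }
  }
  list(S = S, N_alive = N_alive, N_dead = N_dead, D = D)
}

# ---------------------------------------------------------------------------
# Discrete per-lesion replication oracle: with all repair rates and the
# dose rate at zero, pushes individual lesions through one complete S phase.
# Unreplicated SSBs convert to one DSB on replicated DNA, unreplicated DSBs
# are duplicated; converted/transferred slow-pathway material routes to the
# slow pool with probability p_HR and to MMEJ otherwise.
discrete_replication <- function(n_ssb_u, n_f_u, n_s_u, p_HR) {
  f_rl <- 2L * n_f_u
  n_routed <- 2L * n_s_u + n_ssb_u
  to_slow <- rbinom(1L, n_routed, p_HR)
  c(N_dsb_f_rl = f_rl, N_dsb_s_rl = to_slow, N_dsb_m = n_routed - to_slow)
}

# companion continuous-model result: integrate the S-phase lesion equations
# (zero dose, zero repair) over a full S traversal, then merge residuals
ode_replication <- function(n_ssb_u, n_f_u, n_s_u, p_HR,
                            mu_inter = 0.125, eps = 1e-6) {
  rp <- repair_params(k_ssb = 1000, lambda_ssb = 0, k_dsb = 35,
                      lambda_f = 0, lambda_s = 0, lambda_m = 0,
                      p_c = 0.4, p_HR = p_HR)
  y0 <- c(N_ssb_url = n_ssb_u, N_ssb_rl = 0, N_dsb_f_url = n_f_u,
          N_dsb_f_rl = 0, N_dsb_s_url = n_s_u, N_dsb_s_rl = 0,
          N_dsb_m = 0, s_prog = 0)
  rhs <- function(t, y, p) {
    # solver trial steps may overshoot the S end or dip below zero; clamp
    # before evaluating the contract-checked rate function
    y[y < 0] <- 0
    y["s_prog"] <- min(y[["s_prog"]], 1 - eps)
    list(s_phase_damage_rates(y, 0, rp, mu_inter, eps = eps))
  }
  t_end <- (1 - eps) / mu_inter
  out <- deSolve::ode(y0, c(0, t_end), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  y <- out[nrow(out), -1]
  c(N_dsb_f_rl = unname(y["N_dsb_f_rl"] + y["N_dsb_f_url"]),
    N_dsb_s_rl = unname(y["N_dsb_s_rl"] + y["N_dsb_s_url"]),
    N_dsb_m = unname(y["N_dsb_m"]))
}
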