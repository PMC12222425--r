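# Trajectory engine: schedules, closed-form limits, event handling,
# invariants, ensemble averaging.

test_that("phase schedule repeats 11:8:4:1 with evenly spaced starts", {
  cc <- cellcycle_config(log(2) / 24)
  expect_equal(cc$cycle_length, 24)
  expect_equal(unname(cc$durations), c(11, 8, 4, 1))
  expect_equal(cc$mu_inter, 1 / 8)
  expect_equal(cc$one_genome_fraction, 0.625)

  s <- build_phase_schedule(cc, 0, 72)
  expect_equal(s$phase[1:4], c("G1", "S", "G2", "M"))
  expect_equal(s$t_end[1:4] - s$t_start[1:4], c(11, 8, 4, 1))

  # a start inside S: first segment is the remainder of S
  s13 <- build_phase_schedule(cc, 13, 72)  # offset 13 h, 2 h into S
  expect_equal(s13$phase[1], "S")
  expect_equal(s13$t_end[1], 6)
  expect_equal(rptparpi:::.initial_sprog(cc, 13), 2 / 8)

  offsets <- sapply(0:23, function(k)
    attr(simulate_trajectory(k, baseline_protocol(0),
                             baseline_model(n_starts = 24)),
         "start_offset"))
  expect_equal(offsets, (0:23) / 24 * 24)
  expect_error(build_phase_schedule(cc, 0, -1), "horizon")
  expect_error(build_phase_schedule(cc, 24, 72), "start_index")
})

test_that("unperturbed and drug-only trajectories match their closed
           forms", {
  mod <- baseline_model()
  pr <- baseline_protocol(A0 = 0)
  tr <- simulate_trajectory(0L, pr, mod)
  mu_gr <- mod$cellcycle$mu_gr
  expect_equal(max(abs(tr$S - 1)), 0, tolerance = 1e-8)
  expect_lt(max(abs(tr$N_alive /
                      (tr$N_alive[1] * exp(mu_gr * tr$t_h)) - 1)), 1e-6)

  # constant-term drug alone: N(t) = N(0) exp((mu_gr + mu_parpi - 1) t)
  modp <- baseline_model(parpi = parpi_model("constant_only",
                                             mu_parpi = 0.9))
  trp <- simulate_trajectory(0L, pr, modp)
  lam <- mu_gr + 0.9 - 1
  expect_lt(max(abs(trp$N_alive /
                      (trp$N_alive[1] * exp(lam * trp$t_h)) - 1)), 1e-6)
  expect_lt(max(abs(trp$S / exp(-(1 - 0.9) * trp$t_h) - 1)), 1e-5)
})

test_that("dose is monotone, activity decays exactly, washout rebases it,
           and the occupancy bound holds along trajectories", {
  mod <- baseline_model()
  pr <- baseline_protocol(1e5)
  tr <- simulate_trajectory(3L, pr, mod)
  expect_true(all(diff(tr$D) >= -1e-12))

  pre <- tr$t_h < 24
  mu_dec <- mod$kinetics$mu_dec
  expect_equal(tr$A_Bq[pre], 1e5 * exp(-mu_dec * tr$t_h[pre]),
               tolerance = 1e-10)

  # the stored t = 24 row is post-washout: medium and dead compartments
  # empty, activity rebased to the retained (surface + cytoplasm) ligand
  i_pre <- max(which(tr$t_h < 24))
  row <- tr[tr$t_h == 24, ][1, ]
  expect_equal(row$c_m, 0)
  expect_equal(row$c_dcs, 0)
  expect_equal(row$c_dcy, 0)
  expect_equal(row$N_dead, 0)
  expect_lt(row$A_Bq, 1e5 * exp(-mu_dec * 24))
  # the retained fraction view: post-washout activity / pre-washout
  # activity equals the pre-washout cell-bound ligand share
  pre <- tr[i_pre, ]
  frac_pre <- (pre$c_acs + pre$c_acy) /
    (pre$c_m + pre$c_acs + pre$c_dcs + pre$c_acy + pre$c_dcy)
  expect_equal(row$A_Bq / (1e5 * exp(-mu_dec * 24)), frac_pre,
               tolerance = 0.05) # the share still drifts between the rows

  occ <- tr$c_acs - mod$receptors$R_cell * tr$N_alive
  expect_lt(max(occ), 1e-9 * max(tr$c_acs))

  # lesion non-negativity along the trajectory
  les <- c("ssb_url", "ssb_rl", "dsb_f_url", "dsb_f_rl", "dsb_s_url",
           "dsb_s_rl", "dsb_m")
  expect_true(all(as.matrix(tr[les]) >= 0))
})

test_that("with binding disabled no activity survives washout and dose
           stops accruing", {
  mod <- baseline_model()
  mod$kinetics <- kinetic_params(0, 0, 0, 0, mod$kinetics$mu_dec)
  tr <- simulate_trajectory(0L, baseline_protocol(1e5), mod)
  post <- tr$t_h > 24
  expect_lt(max(tr$A_Bq[post]), 1e-12 * 1e5)
  expect_equal(max(tr$D[post]) - min(tr$D[post]), 0, tolerance = 1e-12)
})

test_that("population bookkeeping: total births equal the growth integral", {
  mod <- baseline_model(dt_out = 0.25)
  tr <- simulate_trajectory(5L, baseline_protocol(1e5), mod)
  # d(N_alive + N_dead)/dt = mu_gr * N_alive between events; N_dead is
  # reset at washout, so check on the post-washout window
  post <- tr[tr$t_h >= 24, ]
  tot <- post$N_alive + post$N_dead
  growth <- cumsum(c(0, diff(post$t_h) *
                       (head(post$N_alive, -1) + tail(post$N_alive, -1)) / 2))
  expect_lt(max(abs(tot - tot[1] - mod$cellcycle$mu_gr * growth)) / tot[1],
            1e-3)
})

test_that("ensemble averaging: single start equals the trajectory,
           untreated control self-normalizes", {
  mod1 <- baseline_model(n_starts = 1)
  pr <- baseline_protocol(3e4)
  ens <- ensemble_simulate(pr, mod1, keep_trajectories = TRUE)
  tr <- ens$trajectories[[1]]
  expect_equal(ens$grid$S, approx(tr$t_h, tr$S, ens$grid$t_h)$y,
               tolerance = 1e-10)

  ens0 <- ensemble_simulate(baseline_protocol(0), mod1)
  expect_equal(ens0$grid$rel_survival, rep(1, nrow(ens0$grid)),
               tolerance = 1e-6)
})

test_that("solver tolerance halving and start-point refinement leave the
           endpoint survival essentially unchanged", {
  pr <- baseline_protocol(1e5)
  m1 <- baseline_model(n_starts = 6, rtol = 1e-8, atol = 1e-10)
  m2 <- baseline_model(n_starts = 6, rtol = 5e-9, atol = 5e-11)
  s1 <- ensemble_simulate(pr, m1)$endpoint_rel_survival
  s2 <- ensemble_simulate(pr, m2)$endpoint_rel_survival
  expect_lt(abs(s1 - s2) / s1, 1e-3)

  m24 <- baseline_model(n_starts = 24)
  m48 <- baseline_model(n_starts = 48)
  s24 <- ensemble_simulate(pr, m24)$endpoint_rel_survival
  s48 <- ensemble_simulate(pr, m48)$endpoint_rel_survival
  expect_lt(abs(s24 - s48) / s24, 0.01)
})

test_that("per-phase survival reductions are additive and vanish without
           dose", {
  mod <- baseline_model(n_starts = 4)
  ens <- ensemble_simulate(baseline_protocol(1e5), mod,
                           keep_trajectories = TRUE)
  pd <- phase_death_rates(ens$trajectories)
  expect_true(all(pd$by_phase >= 0))
  for (tr in ens$trajectories) {
    occ <- phase_death_rates(tr)$occurrences
    # completed phases cover [0, 72] exactly for this cycle length, so the
    # reductions must reassemble the endpoint log survival
    expect_equal(sum(occ$reduction), -log(tr$S[nrow(tr)]),
                 tolerance = 1e-6)
  }
  pd0 <- phase_death_rates(
    simulate_trajectory(0L, baseline_protocol(0), mod))
  expect_equal(max(abs(pd0$by_phase)), 0, tolerance = 1e-9)
})

test_that("an EBRT impulse deposits its dose and lesions at t = 0", {
  mod <- baseline_model()
  pr <- baseline_protocol(0)
  pr$ebrt_dose <- 2
  tr <- simulate_trajectory(0L, pr, mod)  # starts in G1, one genome
  expect_equal(tr$D[1], 2)
  rp <- mod$repair
  expect_equal(tr$ssb_rl[1], rp$k_ssb * 2)
  expect_equal(tr$dsb_f_rl[1], (1 - rp$p_c) * rp$k_dsb * 2)
  expect_equal(tr$dsb_s_rl[1], rp$p_c * rp$k_dsb * 2)
  expect_lt(tr$S[nrow(tr)], 1)
})
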