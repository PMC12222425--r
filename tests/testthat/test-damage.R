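# Lesion induction/repair kinetics and the composite survival rate.

test_that("repair-pathway probabilities close to one and follow the
           HR-dependent routing", {
  expect_equal(unname(repair_probabilities(0.3, 1, "G1")), c(0.7, 0.3, 0))
  expect_equal(unname(repair_probabilities(0.3, 1, "G2")), c(0.7, 0.3, 0))
  expect_equal(unname(repair_probabilities(0.3, 0, "G2")), c(0.7, 0, 0.3))
  expect_equal(unname(repair_probabilities(0.4, 0.5, "G2")),
               c(0.6, 0.2, 0.2))
  # complete HRD changes nothing in G1 (no sister chromatid to lose)
  expect_equal(unname(repair_probabilities(0.3, 0, "G1")), c(0.7, 0.3, 0))
  for (pc in c(0, 0.25, 0.7, 1)) for (ph in c(0, 0.4, 1))
    for (phase in c("G1", "S", "G2", "M"))
      expect_equal(sum(repair_probabilities(pc, ph, phase)), 1)
})

test_that("effective SSB repair implements the drug modes", {
  expect_equal(effective_ssb_repair(1.2, parpi_model("none")), 1.2)
  expect_equal(effective_ssb_repair(1.2, parpi_model("constant_only",
                                                     mu_parpi = 0.9)), 1.2)
  pr <- parpi_model("reduced_ssb_repair", mu_parpi = 0.9,
                    lambda_ssb_override = 0.3)
  expect_equal(effective_ssb_repair(1.2, pr, 500), 0.3)
  pd <- parpi_model("decaying_ssb_repair", mu_parpi = 0.9,
                    lambda_red = 0.01)
  expect_equal(effective_ssb_repair(1.0, pd, 0), 1.0)
  expect_equal(effective_ssb_repair(1.0, pd, 100), exp(-1))
  pq <- parpi_model("decaying_ssb_repair", mu_parpi = 0.9,
                    lambda_red = 0.01, decay_form = "rational")
  expect_equal(effective_ssb_repair(1.0, pq, 100), 1 / 2)
  expect_error(parpi_model("decaying_ssb_repair", mu_parpi = 0.9),
               "lambda_red")
})

test_that("interphase lesion rates: fixed point, pure repair, and the
           constant-rate fast-DSB steady state", {
  rp <- baseline_repair()
  z <- c(N_ssb = 0, N_dsb_f = 0, N_dsb_s = 0, N_dsb_m = 0)
  expect_equal(unname(interphase_damage_rates(z, 0, rp, "G1")), rep(0, 4))

  d <- interphase_damage_rates(c(N_ssb = 0, N_dsb_f = 10, N_dsb_s = 0,
                                 N_dsb_m = 0), 0, rp, "G1")
  expect_equal(d[["N_dsb_f"]], -20)

  # constant dose rate: integrate to steady state and compare with the
  # closed form p_f * N_gen * k_dsb * drate / lambda_f
  drate <- 0.5
  rhs <- function(t, y, p)
    list(interphase_damage_rates(y, drate, rp, "G2"))
  out <- deSolve::ode(z, c(0, 40), rhs, NULL, rtol = 1e-10, atol = 1e-10)
  nf <- out[nrow(out), "N_dsb_f"]
  nf_star <- 0.6 * 2 * rp$k_dsb * drate / rp$lambda_f
  expect_lt(abs(nf - nf_star) / nf_star, 1e-3)
  # slow and MMEJ pools likewise approach induction / repair-rate
  ns_star <- (0.4 * 1) * 2 * rp$k_dsb * drate / rp$lambda_s  # p_HR = 1
  expect_lt(abs(out[nrow(out), "N_dsb_s"] - ns_star) / ns_star, 2e-2)
})

test_that("S-phase rates: progression-only fixed point and full-HR routing", {
  rp <- baseline_repair()
  z <- c(N_ssb_url = 0, N_ssb_rl = 0, N_dsb_f_url = 0, N_dsb_f_rl = 0,
         N_dsb_s_url = 0, N_dsb_s_rl = 0, N_dsb_m = 0, s_prog = 0.25)
  d <- s_phase_damage_rates(z, 0, rp, mu_inter = 0.125)
  expect_equal(unname(d), c(rep(0, 7), 0.125))

  # with full HR the MMEJ transfer weight is zero: everything converted
  # lands in the slow replicated pool
  y <- z; y["N_ssb_url"] <- 100; y["N_dsb_s_url"] <- 20
  d <- s_phase_damage_rates(y, 0, rp, mu_inter = 0.125)
  expect_equal(d[["N_dsb_m"]], 0)
  trans <- 0.125 / 0.75
  expect_equal(d[["N_dsb_s_rl"]], trans * (2 * 20 + 100))
  # with complete HRD the same flux lands in MMEJ
  rp0 <- baseline_repair(p_HR = 0)
  d0 <- s_phase_damage_rates(y, 0, rp0, mu_inter = 0.125)
  expect_equal(d0[["N_dsb_m"]], trans * (2 * 20 + 100))
  expect_equal(d0[["N_dsb_s_rl"]], 0)

  y_bad <- z; y_bad["s_prog"] <- 1
  expect_error(s_phase_damage_rates(y_bad, 0, rp, 0.125), "s_prog")
})

test_that("completing S phase duplicates double-strand lesion content and
           matches the discrete per-lesion oracle", {
  set.seed(101)
  for (i in 1:10) {
    U <- rpois(1, 4e4); F <- rpois(1, 3e4); V <- rpois(1, 3e4)
    p_HR <- runif(1)
    ode <- ode_replication(U, F, V, p_HR)
    disc <- discrete_replication(U, F, V, p_HR)
    tot_ode <- sum(ode); tot_disc <- sum(disc)
    # exact duplication of total double-strand content: 2(F + V) + U
    expect_equal(tot_ode, 2 * (F + V) + U, tolerance = 1e-5)
    for (nm in names(disc)) {
      scale <- max(tot_disc, 1)
      expect_lt(abs(ode[[nm]] - disc[[nm]]) / scale, 0.01)
    }
  }
})

test_that("genomic-loss factor evaluates the quadratic and clamps", {
  sp <- survival_params(a = -1e-3, b = -1e-2, psi = 0, phi = 0)
  expect_equal(genomic_loss_factor(0, sp, "G1"), 1)
  expect_equal(genomic_loss_factor(10, sp, "G1"),
               (-1e-3 * 10 - 1e-2) * 10 + 1) # = 0.8
  expect_equal(genomic_loss_factor(1e4, sp, "G1"), 0) # clamped
  expect_equal(genomic_loss_factor(sparams = sp, phase = "S",
                                   n_url = 0, n_rl = 0), 1)
  # per-phase coefficients are honored
  spp <- survival_params(a = c(G1 = 0, G2 = -1e-3, M = 0),
                         b = c(G1 = 0, G2 = -1e-2, M = 0),
                         psi = 0, phi = 0)
  expect_equal(genomic_loss_factor(10, spp, "G1"), 1)
  expect_equal(genomic_loss_factor(10, spp, "G2"), 0.8)
})

test_that("composite death rate combines the survival factors and applies
           the G2/M checkpoint cap", {
  rp <- baseline_repair()
  sp <- survival_params(a = -1e-5, b = -1e-3, psi = 0.002, phi = 0.05)
  z <- c(N_ssb = 0, N_dsb_f = 0, N_dsb_s = 0, N_dsb_m = 0)
  expect_equal(survival_rate(z, 0, rp, sp, parpi_model("none"), "G1"), 0)
  expect_equal(survival_rate(z, 0, rp, sp,
                             parpi_model("constant_only", mu_parpi = 0.9),
                             "G1"), 0.1)

  # checkpoint clamp: 100 present DSBs enter the mitotic term as 20
  y <- c(N_ssb = 0, N_dsb_f = 100, N_dsb_s = 0, N_dsb_m = 0)
  got <- survival_rate(y, 0, rp, sp, parpi_model("none"), "G2")
  mu_loss <- max((-1e-5 * 100 - 1e-3) * 100 + 1, 0)
  mu_mitot <- exp(-0.05 * 20)
  expect_equal(got, 1 - mu_loss * mu_mitot, tolerance = 1e-12)
  expect_equal(mu_mitot, exp(-1))

  # apoptosis acts through the induction rate, not the standing burden
  drate <- 0.3
  got_g1 <- survival_rate(z, drate, rp, sp, parpi_model("none"), "G1")
  expect_equal(got_g1, 1 - exp(-0.002 * rp$k_dsb * drate))
  # and not in G2 with default phase assignment
  got_g2 <- survival_rate(z, drate, rp, sp, parpi_model("none"), "G2")
  expect_equal(got_g2, 0)
})
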