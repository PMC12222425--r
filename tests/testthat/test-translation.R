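# Translational analyses: growth-curve inversion, concentration-effect
# extrapolation, EBRT comparison, stability analysis.

test_that("growth-curve inversion is exact on exponential series", {
  mu_gr <- 0.182
  t <- seq(0, 20, by = 2)
  ctrl <- data.frame(t_days = t, size = exp(mu_gr * t))
  res <- invivo_integrate(ctrl, mu_gr)
  expect_equal(res$survival$S, rep(1, length(t)), tolerance = 1e-12)
  expect_equal(res$mu_dea, 0, tolerance = 1e-12)

  d <- 0.041
  arm <- data.frame(t_days = t, size = 3 * exp((mu_gr - d) * t))
  res2 <- invivo_integrate(arm, mu_gr)
  expect_equal(res2$mu_dea, d, tolerance = 1e-9)
  expect_equal(res2$survival$S, exp(-d * t), tolerance = 1e-9)

  expect_error(invivo_integrate(ctrl[1:2, ], mu_gr), "3 time points")
  bad <- ctrl; bad$size[3] <- -1
  expect_error(invivo_integrate(bad, mu_gr), "> 0")
})

test_that("drug monotherapy rate inverts the net growth exponent", {
  t <- seq(0, 15, by = 3)
  # net exponent equal to the growth rate: no drug effect
  s0 <- data.frame(t_days = t, size = exp(0.182 * t))
  expect_equal(parpi_monotherapy_rate(s0, 0.182)$mu_parpi, 1,
               tolerance = 1e-9)
  # xenograft-like rates: net 0.141/d under growth 0.182/d
  s1 <- data.frame(t_days = t, size = exp(0.141 * t))
  expect_equal(parpi_monotherapy_rate(s1, 0.182)$mu_parpi, 0.959,
               tolerance = 1e-9)
  # flat series
  s2 <- data.frame(t_days = t, size = rep(2, length(t)))
  expect_equal(parpi_monotherapy_rate(s2, 0.148)$mu_parpi, 0.852,
               tolerance = 1e-9)
})

test_that("round trip: simulated drug-only growth curve returns the
           configured survival term", {
  mod <- baseline_model(n_starts = 1,
                        parpi = parpi_model("constant_only",
                                            mu_parpi = 0.93))
  pr <- baseline_protocol(A0 = 0)
  tr <- simulate_trajectory(0L, pr, mod)
  idx <- seq(1, nrow(tr), length.out = 8)
  series <- data.frame(t_days = tr$t_h[idx] / 24,
                       size = tr$N_alive[idx])
  # rates per day: mu_gr and (1 - mu_parpi) scale by 24
  mu_gr_d <- mod$cellcycle$mu_gr * 24
  est <- parpi_monotherapy_rate(series, mu_gr_d)
  mu_parpi_d <- 1 + (est$net_exponent - mu_gr_d) / 24
  expect_equal(mu_parpi_d, 0.93, tolerance = 1e-6)
  rt <- invivo_integrate(series, mu_gr_d)
  expect_equal(rt$survival$S,
               exp(-(1 - 0.93) * 24 * series$t_days), tolerance = 1e-6)
})

test_that("concentration-effect model is linear and orders drugs by
           inverse IC50", {
  em <- conc_effect_model(slope = 2, tumor_to_body_ratio = 7.2e-3,
                          ic50_map = c(talazoparib = 4.8e-3,
                                       rucaparib = 1.4,
                                       olaparib = 1.2),
                          reference_drug = "rucaparib",
                          window = c(0, 100))
  expect_equal(as.numeric(concentration_to_effect(em, 0)), 1)
  e1 <- as.numeric(concentration_to_effect(em, 10))
  e2 <- as.numeric(concentration_to_effect(em, 20))
  expect_equal(e2 - 1, 2 * (e1 - 1), tolerance = 1e-12)

  et <- as.numeric(concentration_to_effect(em, 10, drug = "talazoparib"))
  er <- as.numeric(concentration_to_effect(em, 10, drug = "rucaparib"))
  eo <- as.numeric(concentration_to_effect(em, 10, drug = "olaparib"))
  expect_gt(et, eo)
  expect_gt(eo, er)   # IC50 1.2 uM < 1.4 uM
  expect_warning(concentration_to_effect(em, 200), "window")
  expect_error(concentration_to_effect(em, 1, drug = "unknown"), "IC50")
})

test_that("combination predictions respond monotonically to dose, weight
           and HR deficiency", {
  em <- conc_effect_model(slope = 0.5, tumor_to_body_ratio = 7.2e-3)
  hrd <- c("1" = 1, "0.5" = 3)
  grid <- expand.grid(body_weight_kg = c(60, 75, 90),
                      amount_mg = c(0, 100, 250), days = 14,
                      hr_capability = c(1, 0.5))
  res <- predict_combination(grid, em, mu_dea_mono = 0.1,
                             vd_L_per_kg = 1, hrd_multipliers = hrd,
                             effect_rel_sd = 0.05)
  expect_equal(res$rel_size[res$amount_mg == 0], rep(1, 6))
  for (w in c(60, 75, 90)) for (h in c(1, 0.5)) {
    sub <- res[res$body_weight_kg == w & res$hr_capability == h, ]
    expect_true(all(diff(sub$rel_size[order(sub$amount_mg)]) <= 0))
  }
  for (a in c(100, 250)) for (h in c(1, 0.5)) {
    sub <- res[res$amount_mg == a & res$hr_capability == h, ]
    expect_true(all(diff(sub$rel_size[order(sub$body_weight_kg)]) >= 0))
  }
  hi <- res[res$amount_mg == 250 & res$body_weight_kg == 60, ]
  expect_lt(hi$rel_size[hi$hr_capability == 0.5],
            hi$rel_size[hi$hr_capability == 1])
  expect_true(all(res$ci_lo <= res$rel_size & res$rel_size <= res$ci_hi))
})

test_that("stability analysis scales one parameter at a time with the
           expected directions", {
  mod <- baseline_model(n_starts = 2, rtol = 1e-6, atol = 1e-8,
                        dt_out = 12)
  pr <- baseline_protocol(1e5)
  base <- ensemble_simulate(pr, mod)$endpoint_rel_survival
  st <- stability_analysis("mu_dec", c(1, 10), mod, pr)
  expect_equal(st$survival[1], base, tolerance = 1e-9)
  expect_gt(st$survival[2], st$survival[1])  # faster decay, less dose

  # medium S-value is insignificant next to the cytoplasm S-value
  s_m <- stability_analysis("S_m", c(0.5, 1, 1.5), mod, pr)
  s_cy <- stability_analysis("S_cy", c(0.5, 1, 1.5), mod, pr)
  spread <- function(x) abs(log(max(x$survival) / min(x$survival)))
  expect_lt(spread(s_m), spread(s_cy))
  expect_error(stability_analysis("nope", 1, mod, pr), "unknown parameter")
})

test_that("EBRT and RPT delivery agree at zero dose and the impulse is
           never less damaging when death acts through genomic loss
           alone", {
  mod <- baseline_model(n_starts = 4, rtol = 1e-6, atol = 1e-8,
                        dt_out = 12)
  # isolate the genomic-loss mechanism: no apoptosis, no checkpoint, and
  # no SSB-to-DSB replication conversion (protracted delivery otherwise
  # gains lethality from overlapping S phases)
  mod$survival <- survival_params(a = -1e-5, b = -1e-3, psi = 0, phi = 0)
  mod$repair$k_ssb <- 0
  pr <- baseline_protocol(0)
  res <- compare_ebrt_rpt(c(0, 2, 6), mod, pr)
  expect_equal(res$curve$surv_ebrt[1], 1, tolerance = 1e-6)
  expect_equal(res$curve$surv_rpt[1], 1, tolerance = 1e-6)
  expect_true(all(res$curve$surv_ebrt <= res$curve$surv_rpt + 1e-9))
})
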