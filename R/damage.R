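#' Double-strand-break repair-pathway probabilities
#'
#' A radiation-induced DSB is simple with probability `1 - p_c` (fast
#' non-homologous end joining) and complex with probability `p_c`. Complex
#' breaks are repaired with slow kinetics via homologous recombination when
#' a sister chromatid is available and HR succeeds; with HR deficiency in
#' G2/M (and on replicated DNA during S), failing HR events are routed to
#' the very slow MMEJ backup pathway. In G1 (single genome, no sister
#' chromatid) all complex breaks take the slow route regardless of HR
#' status, so `p_s = p_c` there.
#'
#' @param p_c probability that an induced DSB is complex.
#' @param p_HR probability that an HR event succeeds.
#' @param phase cell-cycle phase, one of `"G1"`, `"S"`, `"G2"`, `"M"`.
#'   `"S"` returns the replicated-DNA routing (HR-dependent); unreplicated
#'   DNA during S uses the `"G1"` routing.
#' @return Named numeric vector `(p_f, p_s, p_m)` summing to 1.
#' @export
repair_probabilities <- function(p_c, p_HR, phase = c("G1", "S", "G2", "M")) {
  phase <- match.arg(phase)
  stopifnot(p_c >= 0, p_c <= 1, p_HR >= 0, p_HR <= 1)
  if (phase == "G1") {
    p_s <- p_c; p_m <- 0
  } else {
    p_s <- p_c * p_HR; p_m <- p_c * (1 - p_HR)
  }
  c(p_f = 1 - p_c, p_s = p_s, p_m = p_m)
}

#' Effective SSB repair rate under PARP inhibition
#'
#' PARP trapping slows single-strand-break clearance. Mode
#' `"reduced_ssb_repair"` replaces the physiological rate with a fitted
#' constant; `"decaying_ssb_repair"` lets the rate decay with the current
#' SSB abundance (trap accumulation saturating the repair machinery).
#'
#' @param lambda_ssb physiological SSB repair rate, per hour.
#' @param parpi a [parpi_model()] object.
#' @param n_ssb current SSB count (>= 0).
#' @return Effective repair rate, per hour.
#' @export
effective_ssb_repair <- function(lambda_ssb, parpi, n_ssb = 0) {
  if (n_ssb < 0) stop("effective_ssb_repair: 'n_ssb' must be >= 0",
                      call. = FALSE)
  switch(parpi$mode,
         none = ,
         constant_only = lambda_ssb,
         reduced_ssb_repair = parpi$lambda_ssb_override,
         decaying_ssb_repair =
           if (parpi$decay_form == "exponential")
             lambda_ssb * exp(-parpi$lambda_red * n_ssb)
           else
             lambda_ssb / (1 + parpi$lambda_red * n_ssb))
}

#' Lesion derivatives outside S phase
#'
#' SSBs are induced in proportion to the dose rate (per genome) and
#' repaired at the effective SSB rate. DSBs are induced per genome,
#' partitioned over fast / slow / MMEJ pathways by
#' [repair_probabilities()], and each pool decays at its own repair rate.
#' MMEJ induction only occurs in G2/M (in G1 the routing probability is
#' zero); residual MMEJ lesions carried into other phases keep repairing.
#'
#' @param damage named vector with elements `N_ssb`, `N_dsb_f`, `N_dsb_s`,
#'   `N_dsb_m`.
#' @param doserate absorbed dose rate, Gy/h.
#' @param params a [repair_params()] object.
#' @param phase `"G1"`, `"G2"` or `"M"` (use [s_phase_damage_rates()] in S).
#' @param n_gen number of present genomes (1 in G1, 2 in G2/M).
#' @param parpi a [parpi_model()] object.
#' @return Named vector of derivatives, per hour.
#' @export
interphase_damage_rates <- function(damage, doserate, params,
                                    phase = c("G1", "G2", "M"),
                                    n_gen = if (phase == "G1") 1 else 2,
                                    parpi = parpi_model("none")) {
  phase <- match.arg(phase)
  pr <- repair_probabilities(params$p_c, params$p_HR, phase)
  lam_eff <- effective_ssb_repair(params$lambda_ssb, parpi,
                                  damage[["N_ssb"]])
  ind <- n_gen * params$k_dsb * doserate
  c(N_ssb = n_gen * params$k_ssb * doserate -
      lam_eff * damage[["N_ssb"]],
    N_dsb_f = pr[["p_f"]] * ind - params$lambda_f * damage[["N_dsb_f"]],
    N_dsb_s = pr[["p_s"]] * ind - params$lambda_s * damage[["N_dsb_s"]],
    N_dsb_m = pr[["p_m"]] * ind - params$lambda_m * damage[["N_dsb_m"]])
}

#' Lesion derivatives during S phase
#'
#' Lesions are tracked separately on unreplicated (`_url`) and replicated
#' (`_rl`) DNA. The replication fork advances at rate `mu_inter` (progress
#' variable `s_prog` in \[0, 1)); unreplicated material is depleted at rate
#' `mu_inter / (1 - s_prog)`. SSBs reached by the fork are converted to
#' DSBs on replicated DNA (PARP trapping makes this the radiosensitizing
#' route), existing unreplicated DSBs are duplicated into the replicated
#' pool, and converted/transferred slow-pathway material is split between
#' the replicated slow pool and the MMEJ pool with weights
#' `p_s / (p_s + p_m)` and `p_m / (p_s + p_m)` (i.e. `p_HR` and
#' `1 - p_HR`). Induction on unreplicated DNA uses the single-genome
#' routing, induction on replicated DNA is doubled and uses the
#' HR-dependent routing; with `s_induction_literal` the pathway weights on
#' induction are dropped so each pool receives the full induction term.
#'
#' @param damage named vector with elements `N_ssb_url`, `N_ssb_rl`,
#'   `N_dsb_f_url`, `N_dsb_f_rl`, `N_dsb_s_url`, `N_dsb_s_rl`, `N_dsb_m`,
#'   `s_prog`.
#' @param doserate absorbed dose rate, Gy/h.
#' @param params a [repair_params()] object.
#' @param mu_inter S-phase progression per hour.
#' @param parpi a [parpi_model()] object.
#' @param eps clamp on `1 - s_prog` guarding the replication-transfer
#'   singularity (default 1e-6).
#' @param s_induction_literal drop pathway weights on S-phase induction.
#' @return Named vector of derivatives (including `s_prog`), per hour.
#' @export
s_phase_damage_rates <- function(damage, doserate, params, mu_inter,
                                 parpi = parpi_model("none"), eps = 1e-6,
                                 s_induction_literal = FALSE) {
  sp <- damage[["s_prog"]]
  if (sp < 0 || sp >= 1)
    stop("s_phase_damage_rates: 's_prog' must lie in [0, 1)", call. = FALSE)
  s <- min(sp, 1 - eps)
  oms <- max(1 - s, eps)
  trans <- mu_inter / oms
  pr_rl <- repair_probabilities(params$p_c, params$p_HR, "S")
  w_den <- pr_rl[["p_s"]] + pr_rl[["p_m"]]
  w_s <- if (w_den > 0) pr_rl[["p_s"]] / w_den else 1
  w_m <- 1 - w_s
  if (s_induction_literal) {
    i_f_u <- i_s_u <- 1
    i_f_r <- i_s_r <- i_m_r <- 1
  } else {
    i_f_u <- 1 - params$p_c; i_s_u <- params$p_c
    i_f_r <- pr_rl[["p_f"]]; i_s_r <- pr_rl[["p_s"]]; i_m_r <- pr_rl[["p_m"]]
  }
  lam_eff <- effective_ssb_repair(params$lambda_ssb, parpi,
                                  damage[["N_ssb_url"]] + damage[["N_ssb_rl"]])
  ind_u <- params$k_dsb * (1 - s) * doserate
  ind_r <- 2 * params$k_dsb * s * doserate
  conv <- trans * (2 * damage[["N_dsb_s_url"]] + damage[["N_ssb_url"]])
  c(N_ssb_url = params$k_ssb * (1 - s) * doserate -
      (lam_eff + trans) * damage[["N_ssb_url"]],
    N_ssb_rl = params$k_ssb * s * doserate -
      lam_eff * damage[["N_ssb_rl"]],
    N_dsb_f_url = i_f_u * ind_u -
      (params$lambda_f + trans) * damage[["N_dsb_f_url"]],
    N_dsb_f_rl = i_f_r * ind_r + 2 * trans * damage[["N_dsb_f_url"]] -
      params$lambda_f * damage[["N_dsb_f_rl"]],
    N_dsb_s_url = i_s_u * ind_u -
      (params$lambda_s + trans) * damage[["N_dsb_s_url"]],
    N_dsb_s_rl = i_s_r * ind_r + w_s * conv -
      params$lambda_s * damage[["N_dsb_s_rl"]],
    N_dsb_m = i_m_r * ind_r + w_m * conv -
      params$lambda_m * damage[["N_dsb_m"]],
    s_prog = mu_inter)
}

#' Genomic-loss survival factor
#'
#' Quadratic survival factor in the present DSB burden,
#' `(a N + b) N + 1` with `a, b <= 0`, clamped to \[0, 1\]. During S phase
#' the factor is the product of an unreplicated-DNA and a replicated-DNA
#' quadratic with their own coefficients.
#'
#' @param n_dsb present DSB count (outside S phase).
#' @param sparams a [survival_params()] object.
#' @param phase cell-cycle phase.
#' @param n_url,n_rl present DSB counts on unreplicated / replicated DNA
#'   (S phase only).
#' @return Dimensionless survival factor in \[0, 1\].
#' @export
genomic_loss_factor <- function(n_dsb = NULL, sparams,
                                phase = c("G1", "S", "G2", "M"),
                                n_url = NULL, n_rl = NULL) {
  phase <- match.arg(phase)
  quad <- function(a, b, n) (a * n + b) * n + 1
  f <- if (phase == "S") {
    quad(sparams$a0, sparams$b0, n_url) * quad(sparams$a1, sparams$b1, n_rl)
  } else {
    quad(sparams$a[[phase]], sparams$b[[phase]], n_dsb)
  }
  min(max(f, 0), 1)
}

#' Composite cell death rate
#'
#' The per-hour death rate is one minus the product of the survival-factor
#' rates: genomic loss (quadratic in the present DSB burden), apoptosis
#' (driven by the instantaneous DSB induction rate, active in interphase),
#' mitotic catastrophe (driven by the present DSB burden capped at the
#' G2/M checkpoint threshold, active in G2/M), and the constant
#' PARP-inhibitor term. Inactive factors are 1, so an undamaged, untreated
#' cell has death rate 0.
#'
#' @param damage named lesion vector; outside S phase with elements
#'   `N_ssb`, `N_dsb_f`, `N_dsb_s`, `N_dsb_m`; during S the S-phase layout
#'   of [s_phase_damage_rates()].
#' @param doserate absorbed dose rate, Gy/h.
#' @param params a [repair_params()] object.
#' @param sparams a [survival_params()] object.
#' @param parpi a [parpi_model()] object (its `mu_parpi` enters while the
#'   drug is present).
#' @param phase cell-cycle phase.
#' @return `mu_dea`, per hour (>= 0).
#' @export
survival_rate <- function(damage, doserate, params, sparams,
                          parpi = parpi_model("none"),
                          phase = c("G1", "S", "G2", "M")) {
  phase <- match.arg(phase)
  if (phase == "S") {
    n_url <- damage[["N_dsb_f_url"]] + damage[["N_dsb_s_url"]]
    n_rl <- damage[["N_dsb_f_rl"]] + damage[["N_dsb_s_rl"]] +
      damage[["N_dsb_m"]]
    mu_loss <- genomic_loss_factor(sparams = sparams, phase = "S",
                                   n_url = n_url, n_rl = n_rl)
    n_dsb <- n_url + n_rl
  } else {
    n_dsb <- damage[["N_dsb_f"]] + damage[["N_dsb_s"]] + damage[["N_dsb_m"]]
    mu_loss <- genomic_loss_factor(n_dsb, sparams, phase)
  }
  mu_apop <- if (phase %in% sparams$apop_phases)
    exp(-sparams$psi * params$k_dsb * doserate) else 1
  mu_mitot <- if (phase %in% sparams$mitot_phases)
    exp(-sparams$phi * min(n_dsb, sparams$dsb_checkpoint_cap)) else 1
  1 - mu_loss * mu_apop * mu_mitot * parpi$mu_parpi
}
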