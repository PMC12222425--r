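#' Radionuclide kinetic parameters
#'
#' Rates governing ligand exchange between the medium, cell-surface and
#' cytoplasm compartments, plus the physical decay constant of the
#' radionuclide label.
#'
#' @param k_on association rate, per (nmol/L) per hour.
#' @param k_off dissociation rate, per hour.
#' @param k_int internalization rate (surface to cytoplasm), per hour.
#' @param k_rel release rate (cytoplasm to surface), per hour.
#' @param mu_dec radionuclide decay rate, per hour. The default is the
#'   Lu-177 value, ln(2) / 159.53 h (half-life 6.647 d).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_on, k_off, k_int, k_rel,
                           mu_dec = log(2) / 159.53) {
  p <- list(k_on = k_on, k_off = k_off, k_int = k_int, k_rel = k_rel,
            mu_dec = mu_dec)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("kinetic_params: '", nm, "' must be a single finite value >= 0",
           call. = FALSE)
  }
  structure(p, class = "kinetic_params")
}

#' Receptor model
#'
#' @param R_cell receptor concentration contributed by a single cell, in the
#'   same concentration unit as the ligand compartments (nmol/L per cell).
#'   Population-level receptor concentrations are derived as
#'   `R_alive(t) = R_cell * N_alive(t)` and `R_dead(t) = R_cell * N_dead(t)`.
#' @return An object of class `receptor_model`.
#' @export
receptor_model <- function(R_cell) {
  if (!is.numeric(R_cell) || length(R_cell) != 1L || !is.finite(R_cell) ||
      R_cell <= 0)
    stop("receptor_model: 'R_cell' must be a single finite value > 0",
         call. = FALSE)
  structure(list(R_cell = R_cell), class = "receptor_model")
}

#' Cellular S-values
#'
#' Mean absorbed dose to the cell nucleus per decay occurring in each source
#' region (MIRD formalism). Values are configuration inputs, typically from
#' Monte-Carlo particle transport for the cell geometry at hand.
#'
#' @param S_m,S_cs,S_cy Gy per decay in the medium, on the cell surface, and
#'   in the cytoplasm.
#' @param warn warn when the beta-emitter spherical-geometry ordering
#'   `S_cy >= S_cs >= S_m` is violated (sanity check, not an error).
#' @return An object of class `svalue_set`.
#' @export
svalue_set <- function(S_m, S_cs, S_cy, warn = TRUE) {
  p <- list(S_m = S_m, S_cs = S_cs, S_cy = S_cy)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("svalue_set: '", nm, "' must be a single finite value >= 0",
           call. = FALSE)
  }
  if (warn && !(S_cy >= S_cs && S_cs >= S_m))
    warning("svalue_set: expected S_cy >= S_cs >= S_m for a beta emitter ",
            "with spherical geometry", call. = FALSE)
  structure(p, class = "svalue_set")
}

#' DNA damage induction and repair parameters
#'
#' @param k_ssb induced single-strand breaks per Gy per genome.
#' @param lambda_ssb SSB repair rate, per hour.
#' @param k_dsb induced double-strand breaks per Gy per genome.
#' @param lambda_f,lambda_s,lambda_m repair rates (per hour) for the fast,
#'   slow and MMEJ (very slow) double-strand-break repair kinetics.
#' @param p_c probability that a radiation-induced DSB is complex, routing it
#'   to slow kinetics.
#' @param p_HR probability that a homologous-recombination event succeeds;
#'   1 is full HR capability, 0 is complete HR deficiency.
#' @return An object of class `repair_params`.
#' @export
repair_params <- function(k_ssb, lambda_ssb, k_dsb,
                          lambda_f, lambda_s, lambda_m,
                          p_c, p_HR = 1) {
  p <- list(k_ssb = k_ssb, lambda_ssb = lambda_ssb, k_dsb = k_dsb,
            lambda_f = lambda_f, lambda_s = lambda_s, lambda_m = lambda_m,
            p_c = p_c, p_HR = p_HR)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("repair_params: '", nm, "' must be a single finite value >= 0",
           call. = FALSE)
  }
  if (p_c > 1) stop("repair_params: 'p_c' must lie in [0, 1]", call. = FALSE)
  if (p_HR > 1) stop("repair_params: 'p_HR' must lie in [0, 1]", call. = FALSE)
  structure(p, class = "repair_params")
}

#' PARP-inhibitor model
#'
#' The drug acts through (a) a constant multiplicative survival term
#' `mu_parpi` (monotherapy effect) and, optionally, (b) impaired SSB repair
#' representing PARP trapping. Trapped SSBs are converted to DSBs during DNA
#' replication by the S-phase equations; slowing SSB clearance is what makes
#' the drug a radiosensitizer in this model.
#'
#' @param mode one of `"none"`, `"constant_only"` (survival term only, the
#'   Olaparib-style model), `"reduced_ssb_repair"` (survival term plus a
#'   fixed replacement SSB repair rate), or `"decaying_ssb_repair"` (survival
#'   term plus an SSB repair rate that decays with SSB abundance, the
#'   Rucaparib-style model).
#' @param mu_parpi constant survival term in (0, 1]; 1 means no monotherapy
#'   effect.
#' @param lambda_ssb_override replacement SSB repair rate (per hour), used by
#'   `"reduced_ssb_repair"`.
#' @param lambda_red reduction rate coupling repair to SSB abundance (per
#'   SSB), used by `"decaying_ssb_repair"`.
#' @param decay_form functional form of the abundance-dependent reduction:
#'   `"exponential"` gives `lambda_ssb * exp(-lambda_red * N_ssb)`,
#'   `"rational"` gives `lambda_ssb / (1 + lambda_red * N_ssb)`.
#' @return An object of class `parpi_model`.
#' @export
parpi_model <- function(mode = c("none", "constant_only",
                                 "reduced_ssb_repair", "decaying_ssb_repair"),
                        mu_parpi = 1,
                        lambda_ssb_override = NULL,
                        lambda_red = NULL,
                        decay_form = c("exponential", "rational")) {
  mode <- match.arg(mode)
  decay_form <- match.arg(decay_form)
  if (!is.numeric(mu_parpi) || length(mu_parpi) != 1L ||
      !is.finite(mu_parpi) || mu_parpi <= 0 || mu_parpi > 1)
    stop("parpi_model: 'mu_parpi' must lie in (0, 1]", call. = FALSE)
  if (mode == "reduced_ssb_repair") {
    if (is.null(lambda_ssb_override) || !is.finite(lambda_ssb_override) ||
        lambda_ssb_override < 0)
      stop("parpi_model: mode 'reduced_ssb_repair' requires ",
           "'lambda_ssb_override' >= 0", call. = FALSE)
  }
  if (mode == "decaying_ssb_repair") {
    if (is.null(lambda_red) || !is.finite(lambda_red) || lambda_red < 0)
      stop("parpi_model: mode 'decaying_ssb_repair' requires ",
           "'lambda_red' >= 0", call. = FALSE)
  }
  structure(list(mode = mode, mu_parpi = mu_parpi,
                 lambda_ssb_override = lambda_ssb_override,
                 lambda_red = lambda_red, decay_form = decay_form),
            class = "parpi_model")
}

#' Cell-survival parameters
#'
#' Coefficients of the composite per-hour survival rate: a quadratic
#' genomic-loss factor in the number of present DSBs, an apoptosis factor
#' driven by the DSB induction rate, a mitotic-catastrophe factor driven by
#' the present DSB burden (capped at the G2/M checkpoint threshold), and the
#' constant PARP-inhibitor term.
#'
#' @param a,b genomic-loss quadratic coefficients outside S phase (both
#'   must be <= 0); may be single values or named vectors with entries per
#'   phase (`G1`, `G2`, `M`).
#' @param a0,b0 coefficients for unreplicated DNA during S phase (<= 0).
#' @param a1,b1 coefficients for replicated DNA during S phase (<= 0).
#' @param psi apoptosis rate coefficient per induced DSB (>= 0).
#' @param phi mitotic-catastrophe rate coefficient per present DSB (>= 0).
#' @param dsb_checkpoint_cap maximum DSB count entering the mitotic term,
#'   representing the G2/M checkpoint (default 20).
#' @param apop_phases phases in which the apoptosis factor is active.
#' @param mitot_phases phases in which the mitotic-catastrophe factor is
#'   active.
#' @return An object of class `survival_params`.
#' @export
survival_params <- function(a, b, a0 = a[[1]], b0 = b[[1]],
                            a1 = a[[1]], b1 = b[[1]],
                            psi, phi, dsb_checkpoint_cap = 20,
                            apop_phases = c("G1", "S"),
                            mitot_phases = c("G2", "M")) {
  phase_coef <- function(x, nm) {
    if (is.null(names(x))) {
      x <- rep(x[[1]], 3L); names(x) <- c("G1", "G2", "M")
    } else if (!all(c("G1", "G2", "M") %in% names(x))) {
      stop("survival_params: named '", nm,
           "' must have entries G1, G2 and M", call. = FALSE)
    }
    if (any(x > 0))
      stop("survival_params: '", nm, "' must be <= 0", call. = FALSE)
    x[c("G1", "G2", "M")]
  }
  a <- phase_coef(a, "a"); b <- phase_coef(b, "b")
  for (nm in c("a0", "b0", "a1", "b1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v > 0)
      stop("survival_params: '", nm, "' must be a single value <= 0",
           call. = FALSE)
  }
  if (psi < 0 || phi < 0)
    stop("survival_params: 'psi' and 'phi' must be >= 0", call. = FALSE)
  if (dsb_checkpoint_cap <= 0)
    stop("survival_params: 'dsb_checkpoint_cap' must be > 0", call. = FALSE)
  bad <- setdiff(c(apop_phases, mitot_phases), c("G1", "S", "G2", "M"))
  if (length(bad))
    stop("survival_params: unknown phase(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(a = a, b = b, a0 = a0, b0 = b0, a1 = a1, b1 = b1,
                 psi = psi, phi = phi,
                 dsb_checkpoint_cap = dsb_checkpoint_cap,
                 apop_phases = apop_phases, mitot_phases = mitot_phases),
            class = "survival_params")
}

#' Cell-cycle configuration
#'
#' @param mu_gr Malthusian cell growth rate, per hour; the cycle length is
#'   derived as `ln(2) / mu_gr`.
#' @param proportions phase duration ratios G1:S:G2:M (default 11:8:4:1).
#' @param n_starts number of evenly spaced cell-cycle starting points over
#'   which ensemble results are averaged (default 24).
#' @return An object of class `cellcycle_config` with derived fields
#'   `cycle_length` (h), per-phase durations, `mu_inter` (S-phase progression
#'   per hour) and the one-genome predominance fraction `(G1 + S/2) / total`.
#' @export
cellcycle_config <- function(mu_gr, proportions = c(11, 8, 4, 1),
                             n_starts = 24) {
  if (!is.numeric(mu_gr) || length(mu_gr) != 1L || mu_gr <= 0)
    stop("cellcycle_config: 'mu_gr' must be > 0", call. = FALSE)
  if (length(proportions) != 4L || any(proportions <= 0))
    stop("cellcycle_config: 'proportions' must be 4 positive values (G1:S:G2:M)",
         call. = FALSE)
  if (n_starts < 1) stop("cellcycle_config: 'n_starts' must be >= 1",
                         call. = FALSE)
  cycle_length <- log(2) / mu_gr
  durations <- cycle_length * proportions / sum(proportions)
  names(durations) <- c("G1", "S", "G2", "M")
  structure(list(
    mu_gr = mu_gr, proportions = proportions, n_starts = as.integer(n_starts),
    cycle_length = cycle_length, durations = durations,
    mu_inter = 1 / durations[["S"]],
    one_genome_fraction =
      (proportions[1] + proportions[2] / 2) / sum(proportions)),
    class = "cellcycle_config")
}

#' Experimental protocol
#'
#' @param A0 initial activity, Bq.
#' @param molar_activity Bq per mol of ligand.
#' @param volume system volume, L.
#' @param n_seeded number of seeded cells.
#' @param seeding_offset hours of Malthusian pre-growth between seeding and
#'   the experiment start at t = 0 (default 24).
#' @param rpt_exposure radiopharmaceutical exposure window, h (default 24);
#'   the washout event fires at its end.
#' @param parpi_exposure PARP-inhibitor exposure window, h (default 72).
#' @param endpoint simulation endpoint, h after experiment start (default 72).
#' @param ebrt_dose optional instantaneous external-beam dose (Gy) delivered
#'   at t = 0.
#' @return An object of class `protocol`.
#' @export
protocol <- function(A0, molar_activity, volume, n_seeded = 5000,
                     seeding_offset = 24, rpt_exposure = 24,
                     parpi_exposure = 72, endpoint = 72, ebrt_dose = 0) {
  p <- list(A0 = A0, molar_activity = molar_activity, volume = volume,
            n_seeded = n_seeded, seeding_offset = seeding_offset,
            rpt_exposure = rpt_exposure, parpi_exposure = parpi_exposure,
            endpoint = endpoint, ebrt_dose = ebrt_dose)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("protocol: '", nm, "' must be a single finite value >= 0",
           call. = FALSE)
  }
  if (molar_activity <= 0 || volume <= 0 || n_seeded <= 0)
    stop("protocol: 'molar_activity', 'volume' and 'n_seeded' must be > 0",
         call. = FALSE)
  if (endpoint < rpt_exposure)
    stop("protocol: 'endpoint' must be >= 'rpt_exposure'", call. = FALSE)
  structure(p, class = "protocol")
}

#' Assemble a full model parameter set
#'
#' Bundles the component parameter objects plus solver and model switches
#' into the single object consumed by [simulate_trajectory()] and
#' [ensemble_simulate()].
#'
#' @param kinetics a [kinetic_params()] object.
#' @param receptors a [receptor_model()] object.
#' @param svalues an [svalue_set()] object.
#' @param repair a [repair_params()] object.
#' @param survival a [survival_params()] object.
#' @param cellcycle a [cellcycle_config()] object.
#' @param parpi a [parpi_model()] object.
#' @param solver list of solver settings: `method` (deSolve method name,
#'   default `"lsoda"`), `rtol` (default 1e-8), `atol` (default 1e-10),
#'   `dt_out` output grid spacing in hours (default 0.5).
#' @param options list of model switches: `receptor_literal` uses the
#'   printed per-cell receptor term in the surface-binding gain (breaking
#'   ligand conservation), `s_induction_literal` drops the pathway weights
#'   on S-phase induction, `mitosis_halves_lesions` partitions lesions
#'   between daughters at mitosis (default TRUE), `eps_sprog` the clamp on
#'   `1 - s_prog` (default 1e-6).
#' @return An object of class `rpt_model`.
#' @export
rpt_model <- function(kinetics, receptors, svalues, repair, survival,
                      cellcycle, parpi = parpi_model("none"),
                      solver = list(), options = list()) {
  stopifnot(inherits(kinetics, "kinetic_params"),
            inherits(receptors, "receptor_model"),
            inherits(svalues, "svalue_set"),
            inherits(repair, "repair_params"),
            inherits(survival, "survival_params"),
            inherits(cellcycle, "cellcycle_config"),
            inherits(parpi, "parpi_model"))
  sdef <- list(method = "lsoda", rtol = 1e-8, atol = 1e-10, dt_out = 0.5)
  odef <- list(receptor_literal = FALSE, s_induction_literal = FALSE,
               mitosis_halves_lesions = TRUE, eps_sprog = 1e-6)
  bad <- setdiff(names(solver), names(sdef))
  if (length(bad)) stop("rpt_model: unknown solver setting(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(names(options), names(odef))
  if (length(bad)) stop("rpt_model: unknown option(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  sdef[names(solver)] <- solver
  odef[names(options)] <- options
  structure(list(kinetics = kinetics, receptors = receptors,
                 svalues = svalues, repair = repair, survival = survival,
                 cellcycle = cellcycle, parpi = parpi,
                 solver = sdef, options = odef),
            class = "rpt_model")
}

#' @export
print.rpt_model <- function(x, ...) {
  cc <- x$cellcycle
  cat("<rpt_model>\n")
  cat(sprintf("  cell cycle: %.1f h (G1:S:G2:M = %s), %d start points\n",
              cc$cycle_length, paste(cc$proportions, collapse = ":"),
              cc$n_starts))
  cat(sprintf("  kinetics: k_on=%.3g k_off=%.3g k_int=%.3g k_rel=%.3g mu_dec=%.3g /h\n",
              x$kinetics$k_on, x$kinetics$k_off, x$kinetics$k_int,
              x$kinetics$k_rel, x$kinetics$mu_dec))
  cat(sprintf("  repair: p_c=%.2f p_HR=%.2f\n", x$repair$p_c, x$repair$p_HR))
  cat(sprintf("  PARPi: mode=%s mu_parpi=%.3f\n", x$parpi$mode,
              x$parpi$mu_parpi))
  invisible(x)
}
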