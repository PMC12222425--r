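#' Compartment-state constructor
#'
#' Ligand concentrations (nmol/L) in the five radionuclide compartments:
#' medium, living-cell surface, dead-cell surface, living-cell cytoplasm,
#' dead-cell cytoplasm.
#'
#' @param c_m,c_acs,c_dcs,c_acy,c_dcy compartment concentrations, nmol/L.
#' @return Named numeric vector of class `compartment_state`.
#' @export
compartment_state <- function(c_m = 0, c_acs = 0, c_dcs = 0,
                              c_acy = 0, c_dcy = 0) {
  x <- c(c_m = c_m, c_acs = c_acs, c_dcs = c_dcs, c_acy = c_acy,
         c_dcy = c_dcy)
  if (any(!is.finite(x)) || any(x < 0))
    stop("compartment_state: concentrations must be finite and >= 0",
         call. = FALSE)
  structure(x, class = "compartment_state")
}

#' Compartment transition rates
#'
#' Time derivatives of the five ligand compartments. Ligand in the medium
#' binds free receptors on living and dead cells, surface-bound ligand
#' dissociates, living cells internalize and release ligand, and cell death
#' moves surface- and cytoplasm-bound ligand from the living-cell to the
#' dead-cell compartments. With the receptor-consistent formulation
#' (default) the five derivatives sum to zero: ligand molecules are
#' chemically stable and only change compartment (radioactive decay acts on
#' the activity, not the ligand bookkeeping).
#'
#' @param state a [compartment_state()] (or named vector with the same
#'   elements).
#' @param params a [kinetic_params()] object.
#' @param receptors a [receptor_model()] object.
#' @param n_alive,n_dead living / dead cell counts.
#' @param mu_dea instantaneous cell death rate, per hour.
#' @param receptor_literal if `TRUE`, use the per-cell receptor
#'   concentration in the living-surface binding gain and the dead-receptor
#'   pool in the dead-surface gain exactly as a literal reading of the
#'   model would have it; this breaks total-ligand conservation and exists
#'   for comparison only.
#' @return Named numeric vector of the five derivatives, nmol/L per hour.
#' @export
compartment_rates <- function(state, params, receptors, n_alive, n_dead,
                              mu_dea, receptor_literal = FALSE) {
  s <- as.numeric(state)
  if (length(s) != 5L || any(!is.finite(s)) || any(s < 0))
    stop("compartment_rates: state must be 5 finite non-negative values",
         call. = FALSE)
  if (mu_dea < 0) stop("compartment_rates: 'mu_dea' must be >= 0",
                       call. = FALSE)
  R_alive <- receptors$R_cell * n_alive
  R_dead <- receptors$R_cell * n_dead
  if (s[2] > R_alive * (1 + 1e-9) + 1e-12 ||
      s[3] > R_dead * (1 + 1e-9) + 1e-12)
    stop("compartment_rates: bound ligand exceeds receptor capacity",
         call. = FALSE)
  R_gain_alive <- if (receptor_literal) receptors$R_cell else R_alive
  d <- .compartment_rates_raw(s, params$k_on, params$k_off, params$k_int,
                              params$k_rel, R_gain_alive, R_alive, R_dead,
                              mu_dea)
  names(d) <- c("c_m", "c_acs", "c_dcs", "c_acy", "c_dcy")
  d
}

# Internal: unchecked right-hand side shared with the trajectory engine.
# R_gain_alive is the receptor term in the living-surface binding gain
# (equal to R_alive unless the literal variant is requested).
.compartment_rates_raw <- function(s, k_on, k_off, k_int, k_rel,
                                   R_gain_alive, R_alive, R_dead, mu_dea) {
  c_m <- s[1]; c_acs <- s[2]; c_dcs <- s[3]; c_acy <- s[4]; c_dcy <- s[5]
  bind_a <- k_on * c_m * (R_gain_alive - c_acs)
  bind_d <- k_on * c_m * (R_dead - c_dcs)
  c(k_off * (c_acs + c_dcs) -
      k_on * c_m * (R_alive + R_dead - c_acs - c_dcs),
    bind_a + k_rel * c_acy - (k_off + k_int + mu_dea) * c_acs,
    bind_d + mu_dea * c_acs - k_off * c_dcs,
    k_int * c_acs - (k_rel + mu_dea) * c_acy,
    mu_dea * c_acy)
}

#' Absorbed dose rate to living-cell nuclei
#'
#' Mean absorbed dose rate to the nuclei of living cells from the current
#' activity, partitioned over the compartments by their ligand share and
#' weighted by the cellular S-values. The medium term carries the crossfire
#' contribution. Activity is apportioned to compartments proportionally to
#' ligand concentration; with no ligand anywhere the rate is zero (the
#' expression is otherwise 0/0). For dosimetry the living-cell count is
#' floored at 1.
#'
#' @param state a [compartment_state()] (or named vector).
#' @param activity current activity, Bq.
#' @param svals an [svalue_set()] object (Gy per decay).
#' @param n_alive living-cell count (floored at 1 for the dose computation).
#' @return Dose rate in Gy per hour.
#' @export
dose_rate <- function(state, activity, svals, n_alive) {
  if (activity < 0) stop("dose_rate: 'activity' must be >= 0", call. = FALSE)
  s <- as.numeric(state)
  sum_c <- sum(s)
  if (sum_c <= 0) return(0)
  n <- max(n_alive, 1)
  3600 * activity *
    (svals$S_m * sum_c + svals$S_cs * s[2] + svals$S_cy * s[4]) /
    (sum_c * n)
}

#' Dose / activity bookkeeping state
#'
#' Tracks the exponential-decay reference for the activity and the
#' cumulative absorbed dose. After a washout event the reference is rebased
#' to the activity retained on and in living cells.
#'
#' @param A0 initial activity, Bq.
#' @param mu_dec radionuclide decay rate, per hour.
#' @param t_ref reference time for `A0`, h.
#' @param D cumulative absorbed dose so far, Gy.
#' @return An object of class `dose_state`.
#' @export
dose_state <- function(A0, mu_dec, t_ref = 0, D = 0) {
  if (A0 < 0 || mu_dec < 0 || D < 0)
    stop("dose_state: 'A0', 'mu_dec' and 'D' must be >= 0", call. = FALSE)
  structure(list(A0 = A0, mu_dec = mu_dec, t_ref = t_ref, D = D),
            class = "dose_state")
}

#' Activity at a given time
#'
#' Exact exponential decay from the current reference:
#' `A(t) = A0 * exp(-mu_dec * (t - t_ref))`.
#'
#' @param t time, h (must be >= the state's reference time).
#' @param dose_state a [dose_state()] object.
#' @return Activity in Bq.
#' @export
activity_at <- function(t, dose_state) {
  if (any(t < 0)) stop("activity_at: 't' must be >= 0", call. = FALSE)
  if (any(t < dose_state$t_ref - 1e-12))
    stop("activity_at: 't' precedes the activity reference time",
         call. = FALSE)
  dose_state$A0 * exp(-dose_state$mu_dec * (t - dose_state$t_ref))
}

#' Apply the end-of-exposure washout
#'
#' At the configured end of radiopharmaceutical exposure the medium is
#' replaced and dead cells are removed with it: the medium and both
#' dead-cell compartments are emptied and the dead-cell count is reset.
#' Ligand on and in living cells endures, and the activity is rebased
#' proportionally to the retained ligand fraction.
#'
#' @param state a [compartment_state()].
#' @param n_dead dead-cell count before washout.
#' @param dose_state a [dose_state()].
#' @param t_washout washout time, h.
#' @return List with elements `state` (post-washout compartments), `n_dead`
#'   (0), and `dose_state` (rebased).
#' @export
apply_washout <- function(state, n_dead, dose_state, t_washout) {
  if (t_washout < dose_state$t_ref)
    stop("apply_washout: washout precedes the exposure start",
         call. = FALSE)
  s <- as.numeric(state)
  sum_c <- sum(s)
  A_pre <- activity_at(t_washout, dose_state)
  frac <- if (sum_c > 0) (s[2] + s[4]) / sum_c else 0
  new_state <- compartment_state(c_m = 0, c_acs = s[2], c_dcs = 0,
                                 c_acy = s[4], c_dcy = 0)
  list(state = new_state, n_dead = 0,
       dose_state = dose_state(A_pre * frac, dose_state$mu_dec,
                               t_ref = t_washout, D = dose_state$D))
}
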