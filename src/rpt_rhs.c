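/* Compiled right-hand side of the coupled kinetics-dose-damage-survival-
 * population system, in the standard deSolve compiled-model form.
 *
 * State vector (17):
 *  0 c_m   1 c_acs  2 c_dcs  3 c_acy  4 c_dcy  5 D
 *  6 ssb_url  7 ssb_rl  8 dsb_f_url  9 dsb_f_rl
 * 10 dsb_s_url 11 dsb_s_rl 12 dsb_m 13 s_prog
 * 14 S  15 N_alive  16 N_dead
 *
 * Output slots (3): A_Bq, doserate (Gy/h), mu_dea (per h).
 *
 * Parameter vector: see .rhs_parms() in R/engine.R (order must match).
 */
#include <R.h>
#include <math.h>

#define NPARMS 43

static double p[NPARMS];

void rpt_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

void rpt_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    if (ip[0] < 3) error("rpt_derivs: nout must be >= 3");

    const double k_on = p[0], k_off = p[1], k_int = p[2], k_rel = p[3];
    const double mu_dec = p[4], R_cell = p[5];
    const double S_m = p[6], S_cs = p[7], S_cy = p[8];
    const double k_ssb = p[9], lambda_ssb = p[10], k_dsb = p[11];
    const double lambda_f = p[12], lambda_s = p[13], lambda_m = p[14];
    const double p_c = p[15], p_HR = p[16];
    const double a_ph = p[17], b_ph = p[18];
    const double a0 = p[19], b0 = p[20], a1 = p[21], b1 = p[22];
    const double psi = p[23], phi = p[24], cap = p[25];
    const double mu_gr = p[26], mu_inter = p[27];
    const int phase = (int) p[28];       /* 1 G1, 2 S, 3 G2, 4 M */
    const double n_gen = p[29];
    const int apop = (int) p[30], mitot = (int) p[31];
    const double mu_parpi = p[32];
    const int ssb_mode = (int) p[33];
    const double lam_override = p[34], lambda_red = p[35];
    const double eps = p[36];
    const int lit = (int) p[37], rec_lit = (int) p[38];
    const double A0cur = p[39], t_ref = p[40];
    const int forced = (int) p[41];
    const double forced_dr = p[42];

    const double N_alive = y[15], N_dead = y[16];
    const double A = A0cur * exp(-mu_dec * (*t - t_ref));
    const double sum_c = y[0] + y[1] + y[2] + y[3] + y[4];

    double drate;
    if (forced)
        drate = forced_dr;
    else if (sum_c > 0.0) {
        double n_dose = N_alive > 1.0 ? N_alive : 1.0;
        drate = 3600.0 * A *
            (S_m * sum_c + S_cs * y[1] + S_cy * y[3]) / (sum_c * n_dose);
    } else
        drate = 0.0;

    /* pathway routing: simple -> fast; complex -> slow (HR) or MMEJ.
     * G1 and unreplicated DNA: no sister chromatid, all complex -> slow.
     * G2/M and replicated DNA: HR succeeds with p_HR, else MMEJ. */
    const double p_f = 1.0 - p_c;
    double p_s, p_m;
    if (phase == 1) { p_s = p_c; p_m = 0.0; }
    else { p_s = p_c * p_HR; p_m = p_c * (1.0 - p_HR); }

    double n_dsb, mu_loss;
    double d_ssb_u = 0.0, d_ssb_r, d_f_u = 0.0, d_f_r, d_s_u = 0.0,
        d_s_r, d_m, d_sprog = 0.0;
    double n_ssb, lam_eff;

    if (phase == 2) {                    /* S phase */
        double s = y[13] < 1.0 - eps ? y[13] : 1.0 - eps;
        double oms = 1.0 - s;
        double trans = mu_inter / oms;
        n_ssb = y[6] + y[7];
        if (n_ssb < 0.0) n_ssb = 0.0;
        switch (ssb_mode) {
        case 1: lam_eff = lam_override; break;
        case 2: lam_eff = lambda_ssb * exp(-lambda_red * n_ssb); break;
        case 3: lam_eff = lambda_ssb / (1.0 + lambda_red * n_ssb); break;
        default: lam_eff = lambda_ssb;
        }
        double wfu, wsu, wfr, wsr, wmr;
        if (lit) { wfu = wsu = wfr = wsr = wmr = 1.0; }
        else { wfu = p_f; wsu = p_c; wfr = p_f; wsr = p_s; wmr = p_m; }
        double w_den = p_s + p_m;
        double w_s = w_den > 0.0 ? p_s / w_den : 1.0;
        double w_m = 1.0 - w_s;
        double ind_u = k_dsb * oms * drate;
        double ind_r = 2.0 * k_dsb * s * drate;
        double conv = trans * (2.0 * y[10] + y[6]);
        d_ssb_u = k_ssb * oms * drate - (lam_eff + trans) * y[6];
        d_ssb_r = k_ssb * s * drate - lam_eff * y[7];
        d_f_u = wfu * ind_u - (lambda_f + trans) * y[8];
        d_f_r = wfr * ind_r + 2.0 * trans * y[8] - lambda_f * y[9];
        d_s_u = wsu * ind_u - (lambda_s + trans) * y[10];
        d_s_r = wsr * ind_r + w_s * conv - lambda_s * y[11];
        d_m = wmr * ind_r + w_m * conv - lambda_m * y[12];
        d_sprog = mu_inter;
        double n_url = y[8] + y[10];
        double n_rl = y[9] + y[11] + y[12];
        mu_loss = ((a0 * n_url + b0) * n_url + 1.0) *
            ((a1 * n_rl + b1) * n_rl + 1.0);
        n_dsb = n_url + n_rl;
    } else {                             /* G1, G2, M */
        n_ssb = y[7] > 0.0 ? y[7] : 0.0;
        switch (ssb_mode) {
        case 1: lam_eff = lam_override; break;
        case 2: lam_eff = lambda_ssb * exp(-lambda_red * n_ssb); break;
        case 3: lam_eff = lambda_ssb / (1.0 + lambda_red * n_ssb); break;
        default: lam_eff = lambda_ssb;
        }
        double ind = n_gen * k_dsb * drate;
        d_ssb_r = n_gen * k_ssb * drate - lam_eff * y[7];
        d_f_r = p_f * ind - lambda_f * y[9];
        d_s_r = p_s * ind - lambda_s * y[11];
        d_m = p_m * ind - lambda_m * y[12];
        n_dsb = y[9] + y[11] + y[12];
        mu_loss = (a_ph * n_dsb + b_ph) * n_dsb + 1.0;
    }

    if (mu_loss < 0.0) mu_loss = 0.0;
    if (mu_loss > 1.0) mu_loss = 1.0;
    double fac = mu_loss * mu_parpi;
    if (apop) fac *= exp(-psi * k_dsb * drate);
    if (mitot) fac *= exp(-phi * (n_dsb < cap ? n_dsb : cap));
    const double mu_dea = 1.0 - fac;

    const double R_alive = R_cell * N_alive;
    const double R_dead = R_cell * N_dead;
    const double R_gain = rec_lit ? R_cell : R_alive;
    const double c_m = y[0], c_acs = y[1], c_dcs = y[2], c_acy = y[3];

    ydot[0] = k_off * (c_acs + c_dcs) -
        k_on * c_m * (R_alive + R_dead - c_acs - c_dcs);
    ydot[1] = k_on * c_m * (R_gain - c_acs) + k_rel * c_acy -
        (k_off + k_int + mu_dea) * c_acs;
    ydot[2] = k_on * c_m * (R_dead - c_dcs) + mu_dea * c_acs -
        k_off * c_dcs;
    ydot[3] = k_int * c_acs - (k_rel + mu_dea) * c_acy;
    ydot[4] = mu_dea * c_acy;
    ydot[5] = drate;
    ydot[6] = d_ssb_u;
    ydot[7] = d_ssb_r;
    ydot[8] = d_f_u;
    ydot[9] = d_f_r;
    ydot[10] = d_s_u;
    ydot[11] = d_s_r;
    ydot[12] = d_m;
    ydot[13] = d_sprog;
    ydot[14] = -mu_dea * y[14];
    ydot[15] = (mu_gr - mu_dea) * N_alive;
    ydot[16] = mu_dea * N_alive;

    yout[0] = A;
    yout[1] = drate;
    yout[2] = mu_dea;
}
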