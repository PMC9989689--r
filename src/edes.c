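/* Compiled right-hand side of the glucose-insulin model for deSolve.
 *
 * The amino-acid forcing function is passed in as piecewise cubic
 * Hermite data (knot times, values, and slopes taken from the same
 * shape-preserving interpolant the R side uses), so compiled and
 * interpreted simulations evaluate the identical polynomial. Constant
 * extension with zero derivative outside the sampled window.
 *
 * Parameter vector layout (see pack_parms() on the R side):
 *   0..12   k1..k13
 *   13..16  g_b_liv, G_b, I_b, AA_b
 *   17..26  sigma, K_M, G_th, c1, V_G, beta, tau_i, tau_d, f, M_b
 *   27..29  D_glucose, t_meal, clamp_nonneg
 *   30      n_knots
 *   31..            knot times   (n)
 *   31 + n ..       knot values  (n)
 *   31 + 2n ..      knot slopes  (n)
 */
#include <R.h>
#include <math.h>

#define EDES_NMAX 256
#define EDES_PVLEN (31 + 3 * EDES_NMAX)

static double pv[EDES_PVLEN];

void edes_init(void (*odeparms)(int *, double *))
{
    int n = EDES_PVLEN;
    odeparms(&n, pv);
}

/* cubic Hermite evaluation with cached interval lookup */
static void aa_eval(double t, double *val, double *der)
{
    int n = (int) pv[30];
    const double *kt = pv + 31;
    const double *ky = pv + 31 + n;
    const double *km = pv + 31 + 2 * n;

    if (t <= kt[0]) { *val = ky[0]; *der = 0.0; return; }
    if (t >= kt[n - 1]) { *val = ky[n - 1]; *der = 0.0; return; }

    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (kt[mid] <= t) lo = mid; else hi = mid;
    }
    double h = kt[lo + 1] - kt[lo];
    double s = (t - kt[lo]) / h;
    double s2 = s * s, s3 = s2 * s;
    double h00 = 2 * s3 - 3 * s2 + 1;
    double h10 = s3 - 2 * s2 + s;
    double h01 = -2 * s3 + 3 * s2;
    double h11 = s3 - s2;
    *val = h00 * ky[lo] + h10 * h * km[lo] + h01 * ky[lo + 1] +
        h11 * h * km[lo + 1];
    double d00 = (6 * s2 - 6 * s) / h;
    double d10 = 3 * s2 - 4 * s + 1;
    double d01 = (-6 * s2 + 6 * s) / h;
    double d11 = 3 * s2 - 2 * s;
    *der = d00 * ky[lo] + d10 * km[lo] + d01 * ky[lo + 1] +
        d11 * km[lo + 1];
}

void edes_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double k1 = pv[0], k2 = pv[1], k3 = pv[2], k4 = pv[3], k5 = pv[4];
    double k6 = pv[5], k7 = pv[6], k8 = pv[7], k9 = pv[8], k10 = pv[9];
    double k11 = pv[10], k12 = pv[11], k13 = pv[12];
    double g_b_liv = pv[13], G_b = pv[14], I_b = pv[15], AA_b = pv[16];
    double sigma = pv[17], K_M = pv[18], G_th = pv[19], c1 = pv[20];
    double V_G = pv[21], beta = pv[22], tau_i = pv[23], tau_d = pv[24];
    double f = pv[25], M_b = pv[26];
    double D = pv[27], t_meal = pv[28];
    int clamp = pv[29] != 0.0;

    double M_gut = y[0], G = y[1], I = y[2], I_if = y[3], Z = y[4];
    double AA, dAA;
    aa_eval(*t, &AA, &dAA);

    /* (i) gut glucose balance */
    double tau = *t - t_meal;
    double m_meal = 0.0;
    if (D > 0.0 && tau > 0.0)
        m_meal = sigma * pow(k1, sigma) * pow(tau, sigma - 1.0) *
            exp(-pow(k1 * tau, sigma)) * D;
    ydot[0] = m_meal - k2 * M_gut;

    /* (ii) plasma glucose balance */
    double vgm = V_G * M_b;
    double g_gut = f * k2 * M_gut / vgm;
    double g_liv = g_b_liv - k3 * (G - G_b) - k4 * beta * I_if +
        k11 * (AA - AA_b);
    if (clamp && g_liv < 0.0) g_liv = 0.0;
    double g_nonit = g_b_liv * (K_M + G_b) / G_b * G / (K_M + G);
    double g_it = k5 * beta * I_if * G / (K_M + G);
    double g_ren = (G > G_th) ? c1 / vgm * (G - G_th) : 0.0;
    double dG = g_gut + g_liv - g_nonit - g_it - g_ren;
    ydot[1] = dG;

    /* (iii) plasma insulin balance; dG/dt substituted algebraically */
    double i_pnc = (k6 * (G - G_b) + (k7 / tau_i) * Z +
                    (k7 / tau_i) * G_b + (k8 / tau_d) * dG +
                    k12 * dAA + k13 * (AA - AA_b)) / beta;
    if (clamp && i_pnc < 0.0) i_pnc = 0.0;
    double i_liv = k7 * G_b / (beta * tau_i) * I / I_b;
    double i_trans = k9 * (I - I_b);
    ydot[2] = i_pnc - i_liv - i_trans;

    /* (iv) interstitial insulin balance */
    ydot[3] = i_trans - k10 * I_if;

    /* running glucose-excursion integral */
    ydot[4] = G - G_b;
}
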