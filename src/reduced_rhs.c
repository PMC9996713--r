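/* Compiled right-hand side of the reduced nine-ODE switch model for deSolve.
 *
 * Parameter order (14): alpha_a, alpha_b, alpha_d, beta_p, beta_d, K_a, K_b,
 *                       k1, k2, k3, k4, k_r, delta, vbar
 * State order (9): F, OHT, Fa, Fb, D_S1, D_tS1, D_tS2, D_SX, D_S2
 */
#include <R.h>

static double p[14];

void init_reduced(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, p);
}

void derivs_reduced(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double alpha_a = p[0], alpha_b = p[1], alpha_d = p[2];
    double beta_p = p[3], beta_d = p[4], K_a = p[5], K_b = p[6];
    double k1 = p[7], k2 = p[8], k3 = p[9], k4 = p[10];
    double k_r = p[11], delta = p[12], vbar = p[13];

    double F = y[0], OHT = y[1], Fa = y[2], Fb = y[3];
    double DS1 = y[4], DtS1 = y[5], DtS2 = y[6], DSX = y[7], DS2 = y[8];

    ydot[0] = K_a * vbar * OHT * Fa + K_b * vbar * Fb - beta_p * F
        - k1 * F * DS1 - k_r * F * DtS1 - k2 * F * DS1 - k_r * F * DtS2
        - k3 * F * DtS1 - k4 * F * DtS2;
    ydot[1] = alpha_d - beta_d * OHT - K_a * OHT * Fa;
    ydot[2] = alpha_a - beta_p * Fa - K_a * OHT * Fa;
    ydot[3] = alpha_b - beta_p * Fb - K_b * Fb;
    ydot[4] = k_r * F * DtS1 - k1 * F * DS1 + k_r * F * DtS2 - k2 * F * DS1;
    ydot[5] = k1 * F * DS1 - k_r * F * DtS1 - k3 * F * DtS1 + k_r * DSX * DS2;
    ydot[6] = k2 * F * DS1 - k_r * F * DtS2 - k4 * F * DtS2 + k_r * DSX * DS2;
    ydot[7] = k3 * F * DtS1 - k_r * DSX * DS2 + k4 * F * DtS2
        - k_r * DSX * DS2 - delta * DSX;
    ydot[8] = k3 * F * DtS1 - k_r * DSX * DS2 + k4 * F * DtS2
        - k_r * DSX * DS2;
}
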