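/* Compiled right-hand sides for the blastocyst compartment models,
 * in the deSolve compiled-function convention (initfunc + derivs).
 *
 * State order (base):    B, T, C, P, E
 * State order (chimera): B, T, C, P, E, D_plus, D_minus
 *
 * Parameter vectors are passed from R by solve_embryo(); the R-level
 * base_rhs()/chimera_rhs() are the documented reference forms and the
 * test suite pins the two implementations together.
 */
#include <R.h>
#include <math.h>

/* ---- base model: parms = alpha, beta, rho, zeta, l, eta, m ---- */

static double base_p[7];

void base_initmod(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, base_p);
}

void base_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double alpha = base_p[0], beta = base_p[1], rho = base_p[2];
    double zeta = base_p[3], l = base_p[4], eta = base_p[5], m = base_p[6];
    double B = fmax(y[0], 0.0), T = fmax(y[1], 0.0), C = fmax(y[2], 0.0);
    double P = fmax(y[3], 0.0), E = fmax(y[4], 0.0);
    double pre = eta * pow(C + E, m); /* FGF4 feedback on PrE spec. */
    double epi = zeta * pow(P, l);    /* PrE feedback on EPI spec.  */

    ydot[0] = alpha * B - beta * B;
    ydot[1] = alpha * T + (1.0 - rho) * beta * B;
    ydot[2] = alpha * C + rho * beta * B - (pre + epi) * C;
    ydot[3] = alpha * P + pre * C;
    ydot[4] = alpha * E + epi * C;
}

/* ---- chimera model:
 * parms = alpha, beta, rho0, zeta, l, eta, m, alpha_D, a, n ---- */

static double chi_p[10];

void chimera_initmod(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, chi_p);
}

void chimera_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double alpha = chi_p[0], beta = chi_p[1], rho0 = chi_p[2];
    double zeta = chi_p[3], l = chi_p[4], eta = chi_p[5], m = chi_p[6];
    double alpha_D = chi_p[7], a = chi_p[8], n = chi_p[9];
    double B = fmax(y[0], 0.0), T = fmax(y[1], 0.0), C = fmax(y[2], 0.0);
    double P = fmax(y[3], 0.0), E = fmax(y[4], 0.0);
    double Dp = fmax(y[5], 0.0), Dm = fmax(y[6], 0.0);
    double rho_eff = rho0 / (1.0 + a * pow(Dp + Dm, n));
    double pre = eta * pow(C + E + Dp, m); /* Fgf4+/+ donors induce PrE */
    double epi = zeta * pow(P, l);

    ydot[0] = alpha * B - beta * B;
    ydot[1] = alpha * T + (1.0 - rho_eff) * beta * B;
    ydot[2] = alpha * C + rho_eff * beta * B - (pre + epi) * C;
    ydot[3] = alpha * P + pre * C;
    ydot[4] = alpha * E + epi * C;
    ydot[5] = alpha_D * Dp;
    ydot[6] = alpha_D * Dm;
}
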