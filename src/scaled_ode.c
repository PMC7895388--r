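/* Right-hand side of the nondimensionalized two-cell model with finite Hill
 * nonlinearities, in deSolve's compiled-model interface.
 *
 * State:  y = (M1, M2, P1, P2)
 * Parms:  theta1, theta2, mu, gamma, eta, kappa, pi, eps, n, nu
 *
 * Protein coordinates are clipped at 0 before evaluating the Hill terms:
 * fractional-exponent powers are undefined for the tiny negative excursions
 * adaptive solvers can produce.
 */
#include <R.h>
#include <math.h>

static double parms[10];
#define THETA1 parms[0]
#define THETA2 parms[1]
#define MU     parms[2]
#define GAMMA  parms[3]
#define ETA    parms[4]
#define KAPPA  parms[5]
#define PI_    parms[6]
#define EPS    parms[7]
#define NEXP   parms[8]
#define NUEXP  parms[9]

void sm_init(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, parms);
}

static double hill(double x, double theta, double n)
{
    double xn;
    if (x <= 0.0) return 0.0;
    xn = pow(x / theta, n);
    return xn / (1.0 + xn);
}

void sm_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double M1 = y[0], M2 = y[1];
    double P1 = y[2] > 0.0 ? y[2] : 0.0;
    double P2 = y[3] > 0.0 ? y[3] : 0.0;

    double h1a = hill(P1, THETA1, NEXP);   /* binding/transport switch  */
    double h1b = hill(P2, THETA1, NEXP);
    double h2a = hill(P1, THETA2, NUEXP);  /* translation switch        */
    double h2b = hill(P2, THETA2, NUEXP);

    double T1 = 1.0 / (1.0 + KAPPA * h1a);
    double T2 = 1.0 / (1.0 + KAPPA * h1b);
    double B1 = (1.0 + GAMMA * h2a) * (1.0 + ETA * h1a) / (1.0 + KAPPA * h1a);
    double B2 = (1.0 + GAMMA * h2b) * (1.0 + ETA * h1b) / (1.0 + KAPPA * h1b);

    ydot[0] = 1.0 - MU * M1 - T1 * M1 + T2 * M2;
    ydot[1] = 1.0 - MU * M2 + T1 * M1 - T2 * M2;
    ydot[2] = B1 * M1 - PI_ * P1 + EPS * (P2 - P1);
    ydot[3] = B2 * M2 + EPS * (P1 - P2) - PI_ * P2;
}
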