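/* Compiled right-hand side for the 1-D germarium reaction-diffusion model.
 *
 * State layout (n = total compartments, CC first):
 *   y[0..n-1]       extracellular Dpp
 *   y[n..2n-1]      Dpp-receptor complex
 *   y[(2+j)n ...]   intracellular species j (j = 0..nsp-1)
 *
 * Parameters arrive as one packed double vector (see pack_parms() on the
 * R side):
 *   p[0]=n  p[1]=nsp  p[2]=hill_n  p[3]=dx^2  p[4]=D_coef  p[5]=delta_D
 *   p[6]=k_on  p[7]=k_off  p[8]=k_int  p[9]=k_sig  p[10]=oe_Dpp
 *   p[11]=secretion(CC)  p[12]=imad(1-based, 0 if absent)  p[13]=Rtot
 *   p[14]=n_edges
 *   then per species: phi, delta, oe  (3 doubles each)
 *   then per edge: to(1-based), from(1-based), sign(1=repress), K
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

/* The R side pads the packed vector to exactly OSFIT_NPARMS doubles. */
#define OSFIT_NPARMS 1024

static double parms[OSFIT_NPARMS];

void osfit_init(void (*odeparms)(int *, double *))
{
    int N = OSFIT_NPARMS;
    odeparms(&N, parms);
}

void osfit_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double *p = parms;
    int n = (int) p[0];
    int nsp = (int) p[1];
    double hn = p[2], dx2 = p[3], Dco = p[4], deltaD = p[5];
    double kon = p[6], koff = p[7], kint = p[8], ksig = p[9];
    double oe_dpp = p[10], sec = p[11];
    int imad = (int) p[12];
    double Rtot = p[13];
    int nedge = (int) p[14];
    const double *spp = p + 15;           /* phi, delta, oe per species */
    const double *epp = p + 15 + 3 * nsp; /* to, from, sign, K per edge */

    double *D = y;
    double *C = y + n;
    double *dD = ydot;
    double *dC = ydot + n;
    double ksig_h = pow(ksig, hn);

    for (int i = 0; i < n; i++) {
        double Dl = (i == 0) ? D[0] : D[i - 1];
        double Dr = (i == n - 1) ? D[n - 1] : D[i + 1];
        double lap = (Dl - 2.0 * D[i] + Dr) / dx2;
        double Rt = (i == 0) ? 0.0 : Rtot; /* no receptors in the CC */
        double Rfree = Rt - C[i];
        if (Rfree < 0.0) Rfree = 0.0;
        double bind = kon * D[i] * Rfree;
        double s = (i == 0) ? sec : 0.0;   /* secretion in the CC only */
        dD[i] = Dco * lap + s + oe_dpp - bind + koff * C[i] - deltaD * D[i];
        dC[i] = bind - koff * C[i] - kint * C[i];
    }

    for (int j = 0; j < nsp; j++) {
        double phi = spp[3 * j], del = spp[3 * j + 1], oe = spp[3 * j + 2];
        double *X = y + (2 + j) * n;
        double *dX = ydot + (2 + j) * n;
        for (int i = 0; i < n; i++) {
            double prod = phi;
            if (j + 1 == imad) {
                double ch = pow(C[i], hn);
                prod *= ch / (ksig_h + ch);
            }
            for (int e = 0; e < nedge; e++) {
                if ((int) epp[4 * e] != j + 1) continue;
                int from = (int) epp[4 * e + 1] - 1;
                double K = epp[4 * e + 3];
                double Kh = pow(K, hn);
                double Rh = pow(y[(2 + from) * n + i], hn);
                prod *= (epp[4 * e + 2] > 0.5) ? Kh / (Kh + Rh)
                                               : Rh / (Kh + Rh);
            }
            double g = (i == 0) ? 0.0 : 1.0; /* no production in the CC */
            dX[i] = (prod + oe) * g - del * X[i];
        }
    }
}
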