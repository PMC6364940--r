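/* Right-hand side of the extended beta-cell dual oscillator model,
 * in the form expected by deSolve's compiled-code interface.
 *
 * State: v (mV), n, ca_c (uM), ca_er (uM), f6p (uM), fbp (uM),
 *        atp (uM), ip3 (uM).  Time in seconds.
 *
 * The parameter vector (see params_vector() on the R side) ends with a
 * drive flag: the IP3 drive amplitude is drive * ip3_amp, held constant
 * within each integration segment (segments are split at pulse
 * boundaries by the caller).
 */
#include <R.h>
#include <math.h>

static double p[32];

#define GCA    p[0]
#define GK     p[1]
#define GKCA   p[2]
#define GKATP  p[3]
#define CM     p[4]
#define TAUN   p[5]
#define KDKCA  p[6]
#define ALPHA  p[7]
#define KPMCA  p[8]
#define FCA    p[9]
#define PLEAK  p[10]
#define KSERCA p[11]
#define SIGMAV p[12]
#define PIP3R  p[13]
#define KIP3   p[14]
#define VPFK   p[15]
#define KPFK   p[16]
#define JGK    p[17]
#define VPDH   p[18]
#define KPDH   p[19]
#define NUPDH  p[20]
#define KPROD  p[21]
#define CAATP  p[22]
#define TAUA   p[23]
#define ATOT   p[24]
#define K1AMP  p[25]
#define K2FBP  p[26]
#define K3F6P  p[27]
#define K4ATP  p[28]
#define IP3AMP p[29]
#define TAUIP3 p[30]
#define DRIVE  p[31]

void iom_initmod(void (* odeparms)(int *, double *))
{
    int n = 32;
    odeparms(&n, p);
}

void iom_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double v = y[0], n = y[1], ca = y[2], caer = y[3];
    double f6p = y[4], fbp = y[5], atp = y[6], ip3 = y[7];

    /* electrical oscillator */
    double minf = 1.0 / (1.0 + exp((-20.0 - v) / 12.0));
    double ninf = 1.0 / (1.0 + exp((-16.0 - v) / 5.0));
    double ica  = GCA * minf * (v - 25.0);
    double ik   = GK * n * (v + 75.0);
    double ikca = GKCA * (ca * ca / (ca * ca + KDKCA * KDKCA)) * (v + 75.0);

    /* Magnus-Keizer K(ATP) open fraction from the nucleotide pool */
    double adp = ATOT - atp;
    if (adp < 1e-9) adp = 1e-9;
    double mgadp = 0.165 * adp, adp3 = 0.135 * adp, atp4 = 0.05 * atp;
    double okatp = (0.08 * (1.0 + 2.0 * mgadp / 17.0) +
                    0.89 * (mgadp / 17.0) * (mgadp / 17.0)) /
        ((1.0 + mgadp / 17.0) * (1.0 + mgadp / 17.0) *
         (1.0 + adp3 / 26.0 + atp4 / 1.0));
    double ikatp = GKATP * okatp * (v + 75.0);

    /* calcium fluxes (uM/s); IP3 gates ER -> cytosol release */
    double jmem = -(ALPHA * ica + KPMCA * ca);
    double oip3 = PIP3R * ip3 * ip3 / (ip3 * ip3 + KIP3 * KIP3);
    double jer  = (PLEAK + oip3) * (caer - ca) - KSERCA * ca;

    /* glycolytic oscillator: PFK with AMP/FBP activation and ATP
     * inhibition (16 binding states), AMP from adenylate-kinase
     * equilibrium */
    double amp = adp * adp / atp;
    double a1 = amp / K1AMP, a2 = fbp / K2FBP;
    double a3 = f6p * f6p / K3F6P, a4 = atp * atp / K4ATP;
    const double f13 = 0.02, f23 = 0.2, f41 = 20.0, f42 = 20.0, f43 = 20.0;
    double top = 0.0, bot = 0.0, w1110 = 0.0;
    int i, j, k, l;
    for (i = 0; i <= 1; i++) for (j = 0; j <= 1; j++)
    for (k = 0; k <= 1; k++) for (l = 0; l <= 1; l++) {
        double w = 1.0;
        if (i) w *= a1;
        if (j) w *= a2;
        if (k) w *= a3;
        if (l) w *= a4;
        if (i && k) w /= f13;
        if (j && k) w /= f23;
        if (i && l) w /= f41;
        if (j && l) w /= f42;
        if (k && l) w /= f43;
        bot += w;
        if (k) {
            top += w;
            if (i && j && !l) w1110 = w;
        }
    }
    double jpfk = VPFK * (w1110 + KPFK * (top - w1110)) / bot;

    /* Ca2+-activated PDH consumes FBP and drives ATP production */
    double jpdh = VPDH * (ca / (ca + KPDH)) * sqrt(fbp > 0.0 ? fbp : 0.0);

    ydot[0] = -(ica + ik + ikca + ikatp) / CM * 1000.0;
    ydot[1] = (ninf - n) / TAUN;
    ydot[2] = FCA * (jmem + jer);
    ydot[3] = -FCA * SIGMAV * jer;
    ydot[4] = 0.3 * (JGK - jpfk);
    ydot[5] = jpfk - 0.5 * jpdh;
    ydot[6] = (adp * exp((1.0 + NUPDH * jpdh / (jpdh + KPROD)) *
                         (1.0 - CAATP * ca)) - atp) / TAUA;
    ydot[7] = (DRIVE * IP3AMP - ip3) / TAUIP3;
}
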