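/* Compiled right-hand side of the beta-cell integrated oscillator model,
 * mirroring the reference implementation in R/iom.R (iom_rhs). Used through
 * deSolve's compiled-model interface for speed; parameter order must match
 * iom_param_vector() on the R side. */

#include <R.h>
#include <math.h>

static double parms[45];

#define gca     parms[0]
#define gk      parms[1]
#define gkca    parms[2]
#define gkatpbar parms[3]
#define vca     parms[4]
#define vk      parms[5]
#define cm      parms[6]
#define vm      parms[7]
#define sm      parms[8]
#define vn      parms[9]
#define sn      parms[10]
#define taun    parms[11]
#define kd      parms[12]
#define fca     parms[13]
#define alpha   parms[14]
#define kpmca   parms[15]
#define kserca  parms[16]
#define pleak   parms[17]
#define sigmav  parms[18]
#define Jgk     parms[19]
#define vpfk    parms[20]
#define kpfk    parms[21]
#define k1      parms[22]
#define k2      parms[23]
#define k3      parms[24]
#define k4      parms[25]
#define famp    parms[26]
#define fatp    parms[27]
#define ffbp    parms[28]
#define fbt     parms[29]
#define fmt     parms[30]
#define vpdh    parms[31]
#define kcapdh  parms[32]
#define atot    parms[33]
#define taua    parms[34]
#define r_exch  parms[35]
#define r1      parms[36]
#define vg      parms[37]
#define kg      parms[38]
#define fmgadp  parms[39]
#define fadp3   parms[40]
#define fatp4   parms[41]
#define kdd     parms[42]
#define ktd     parms[43]
#define ktt     parms[44]

void iom_initpar(void (*odeparms)(int *, double *))
{
    int n = 45;
    odeparms(&n, parms);
}

void iom_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double v = y[0], n = y[1], c = y[2], cer = y[3];
    double f6p = y[4], fbp = y[5], adp = y[6];
    if (fbp < 0) fbp = 0;

    double atp = atot - adp;
    if (atp < 1e-6) atp = 1e-6;
    double amp = adp * adp / atp;

    double minf = 1.0 / (1.0 + exp((vm - v) / sm));
    double ninf = 1.0 / (1.0 + exp((vn - v) / sn));
    double ica = gca * minf * (v - vca);
    double ik = gk * n * (v - vk);
    double ikca = gkca * (c * c / (c * c + kd * kd)) * (v - vk);

    double mgadp = fmgadp * adp / kdd;
    double adp3 = fadp3 * adp / ktd;
    double atp4 = fatp4 * atp / ktt;
    double o = (0.08 * (1.0 + 2.0 * mgadp) + 0.89 * mgadp * mgadp) /
               ((1.0 + mgadp) * (1.0 + mgadp) * (1.0 + adp3 + atp4));
    double ikatp = gkatpbar * o * (v - vk);

    double jmem = -(alpha * ica + kpmca * c);
    double jer = pleak * (cer - c) - kserca * c;

    /* Smolen PFK: 16 binding states of (AMP, FBP, F6P, ATP) */
    double wamp = amp / k1, wfbp = fbp / k2;
    double wf6p = f6p * f6p / k3, watp = atp * atp / k4;
    double w1000 = wamp, w0100 = wfbp, w0010 = wf6p, w0001 = watp;
    double w1100 = wamp * wfbp;
    double w1010 = wamp * wf6p / famp;
    double w1001 = wamp * watp / fmt;
    double w0110 = wfbp * wf6p / ffbp;
    double w0101 = wfbp * watp / fbt;
    double w0011 = wf6p * watp / fatp;
    double w1110 = wamp * wfbp * wf6p / (famp * ffbp);
    double w1101 = wamp * wfbp * watp / (fmt * fbt);
    double w1011 = wamp * wf6p * watp / (famp * fmt * fatp);
    double w0111 = wfbp * wf6p * watp / (ffbp * fbt * fatp);
    double w1111 = wamp * wfbp * wf6p * watp / (famp * ffbp * fmt * fbt * fatp);
    double total = 1.0 + w1000 + w0100 + w0010 + w0001 + w1100 + w1010 +
                   w1001 + w0110 + w0101 + w0011 + w1110 + w1101 + w1011 +
                   w0111 + w1111;
    double activated = w1010 + w0110 + w1110 + w1011 + w0111 + w1111;
    double plain = w0010 + w0011;
    double jpfk = vpfk * (activated + kpfk * plain) / total;

    double jpdh = vpdh * sqrt(fbp) * c / (c + kcapdh);
    double gam = vg * jpdh / (kg + jpdh);

    ydot[0] = -(ica + ik + ikca + ikatp) / cm;
    ydot[1] = (ninf - n) / taun;
    ydot[2] = fca * (jmem + jer);
    ydot[3] = -fca * sigmav * jer;
    ydot[4] = 0.3 * (Jgk - jpfk);
    ydot[5] = jpfk - 0.5 * jpdh;
    ydot[6] = (atp - adp * exp((r_exch + gam) * (1.0 - c / r1))) / taua;
}
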