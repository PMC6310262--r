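/* Compiled right-hand side of the three-compartment dialysis session
 * ODE system, in the standard deSolve compiled-model form. Mirrors the
 * R reference implementation hd_rhs() exactly; internal units are L,
 * mmHg, mmol, g, min (all flow coefficients pre-scaled to L/min by the
 * R-side packer).
 *
 * Parameter vector layout (see pack_parms() in R/engine.R):
 *   0 Lp            1-3 alpha[LP,SP,UP]   4-6 sigma      7-9 PS
 *  10 P_c          11 P_IS0   12 V_IS0   13 compliance  14 LS
 *  15 Jv_L0        16 k_f     17 osm     18 MW_protein  19 Jp_max
 *  20 Ch_Na        21 Ch_K    22 H_Na    23 H_K         24 n_solutes
 *  25 Q_b          26 J_UF    27 ramp    28 ramp_rate   29 ramp_horizon
 *  30 gamma_A      31-34 w[Na,K,U,A]     35-38 offset   39-42 D
 *  43-46 C_d       47 M_eq_IS 48 M_eq_IC
 *
 * State layout: V_P, V_IS, V_IC, M_TP_P, M_TP_IS,
 *   then per solute (MEC, MIC) pairs, then per-solute cumulative
 *   removed mass, then cumulative ultrafiltrate volume.
 */

#include <R.h>
#include <math.h>

#define NPARMS 49
static double p[NPARMS];

void hd_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

/* Patlak flow-weighting of the intramembrane mean concentration */
static double pe_weight(double Pe)
{
    if (fabs(Pe) < 1e-6) return 0.5 + Pe / 12.0;
    if (Pe > 500.0) return 1.0;
    if (Pe < -500.0) return 0.0;
    return 1.0 / (1.0 - exp(-Pe)) - 1.0 / Pe;
}

static double oncotic(double c_gdl)
{
    return 2.1 * c_gdl + 0.16 * c_gdl * c_gdl + 0.009 * c_gdl * c_gdl * c_gdl;
}

void hd_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int ns = (int) p[24];
    double V_P = y[0], V_IS = y[1], V_IC = y[2];
    double cTP_P = y[3] / V_P, cTP_IS = y[4] / V_IS;  /* g/L */

    double Pi_P = oncotic(cTP_P / 10.0);
    double Pi_IS = oncotic(cTP_IS / 10.0);
    double P_IS = p[11] + (V_IS - p[12]) / p[13];
    double dP = p[10] - P_IS, dPi = Pi_P - Pi_IS;

    /* per-pore fluid flux (L/min) and protein flux (g/min) */
    double Jv_ISP = 0.0, J_TP_ISP = 0.0;
    double Jv_r[3];
    for (int r = 0; r < 3; r++) {
        Jv_r[r] = p[1 + r] * p[0] * (dP - p[4 + r] * dPi);
        Jv_ISP += Jv_r[r];
    }
    for (int r = 0; r < 2; r++) {   /* LP, SP only */
        double S = 1.0 - p[4 + r], PS = p[7 + r];
        double Cm;
        if (PS > 0.0) {
            double Pe = S * Jv_r[r] / PS;
            double f = pe_weight(Pe);
            Cm = f * cTP_P + (1.0 - f) * cTP_IS;
            J_TP_ISP += PS * (cTP_P - cTP_IS) + S * Jv_r[r] * Cm;
        } else {
            Cm = (Jv_r[r] >= 0.0) ? cTP_P : cTP_IS;
            J_TP_ISP += S * Jv_r[r] * Cm;
        }
    }

    double Jv_L = p[15] * (1.0 + p[14] * (P_IS - p[11]));
    if (Jv_L < 0.0) Jv_L = 0.0;
    double J_TP_L = cTP_IS * Jv_L;

    /* solute concentrations */
    double c_P[4], c_IS[4], c_IC[4];
    for (int s = 0; s < ns; s++) {
        double off = p[35 + s];
        c_P[s] = y[5 + 2 * s] / (V_P + off * V_IS);
        c_IS[s] = off * c_P[s];
        c_IC[s] = y[6 + 2 * s] / V_IC;
    }

    /* osmolarities; protein counts only extracellularly */
    double sum_IS = c_IS[0] + c_IS[1] + c_IS[2] + cTP_IS / p[18];
    double sum_IC = c_IC[0] + c_IC[1] + c_IC[2];
    if (ns == 4) { sum_IS += c_IS[3]; sum_IC += c_IC[3]; }
    double th_IS = p[17] * (sum_IS + p[47] / V_IS);
    double th_IC = p[17] * (sum_IC + p[48] / V_IC);
    double Jv_ISIC = p[16] * (th_IC - th_IS);   /* L/min, + into cell */

    /* pump + diffusion (Na = 0, K = 1, urea = 2, A = 3) */
    double B = (c_IS[1] / (c_IS[1] + p[21])) * (c_IC[0] / (c_IC[0] + p[20]));
    double Js[4];
    Js[0] = p[31] * (c_IS[0] - c_IC[0]) + p[22] * B * p[19];
    Js[1] = p[32] * (c_IS[1] - c_IC[1]) + p[23] * B * p[19];
    Js[2] = p[33] * (c_IS[2] - c_IC[2]);
    if (ns == 4) Js[3] = p[34] * (c_IS[3] - p[30] * c_IC[3]);

    /* dialyzer with optional exponential onset */
    double rf = 1.0;
    if (p[27] > 0.5 && *t < p[29])
        rf = expm1(p[28] * *t) / expm1(p[28] * p[29]);
    double Juf = p[26] * rf;
    double Jd[4];
    for (int s = 0; s < ns; s++) {
        double D = p[39 + s] * rf;
        Jd[s] = Juf * c_P[s] + D * (1.0 - Juf / p[25]) * (c_P[s] - p[43 + s]);
    }

    ydot[0] = -Jv_ISP + Jv_L - Juf;
    ydot[1] = Jv_ISP - Jv_L - Jv_ISIC;
    ydot[2] = Jv_ISIC;
    ydot[3] = -J_TP_ISP + J_TP_L;
    ydot[4] = J_TP_ISP - J_TP_L;
    for (int s = 0; s < ns; s++) {
        ydot[5 + 2 * s] = -Js[s] - Jd[s];
        ydot[6 + 2 * s] = Js[s];
        ydot[5 + 2 * ns + s] = Jd[s];
    }
    ydot[5 + 3 * ns] = Juf;
}
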