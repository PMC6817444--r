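/* Right-hand side of the two-compartment antibody disposition model with
 * parallel linear (CL) and saturable Michaelis-Menten (Vm, Km) elimination
 * from the central compartment, for n co-circulating analytes.
 *
 * Called by deSolve through the string interface (dllname = "adcpk").
 *
 * Parameter vector (length 8):
 *   p[0] n analytes, p[1] coupling (0 = shared saturable pathway driven by
 *   total central concentration, 1 = independent), p[2..7] V1 V2 CL Cld Vm Km.
 *
 * State layout, per analyte i (3 slots each):
 *   y[3i]   A1  central amount (ug/kg)
 *   y[3i+1] A2  peripheral amount (ug/kg)
 *   y[3i+2] E   cumulative eliminated amount (ug/kg), for mass balance
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[8];

void tmdd_init(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

void tmdd_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int n = (int) parms[0];
    int indep = (int) parms[1];
    double V1 = parms[2], V2 = parms[3], CL = parms[4],
           Cld = parms[5], Vm = parms[6], Km = parms[7];
    double ctot = 0.0;
    int i;

    for (i = 0; i < n; i++) {
        double c = y[3 * i] / V1;
        if (c > 0.0) ctot += c;
    }
    for (i = 0; i < n; i++) {
        double A1 = y[3 * i], A2 = y[3 * i + 1];
        double c1 = A1 / V1;
        double cdrv = indep ? (c1 > 0.0 ? c1 : 0.0) : ctot;
        double mm = Vm * c1 / (Km + cdrv);
        double lin = CL / V1 * A1;
        double d12 = Cld / V1 * A1;
        double d21 = Cld / V2 * A2;
        ydot[3 * i]     = -lin - d12 + d21 - mm;
        ydot[3 * i + 1] =  d12 - d21;
        ydot[3 * i + 2] =  lin + mm;
    }
}

void R_init_adcpk(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
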