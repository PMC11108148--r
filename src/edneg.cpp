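// Six-compartment electrodiffusive neuron-extracellular-glia (edNEG) model.
//
// State (34): ion amounts N (attomol), gating variables x in [0,1],
// compartment volumes V (micrometre^3).  Concentrations are derived as N/V
// (1 amol/um^3 == 1 mM), so per-species totals are conserved exactly under
// volume change.
//
// Internal unit system: mV, ms, um, amol, mM.  Charge is carried in
// "charge-amol" (amount times valence); dividing a current density by the
// valence gives a particle flux density in amol um^-2 ms^-1.
//
// Compartment order: sn, se, sg, dn, de, dg
// State order:
//   0..5   Na  (sn se sg dn de dg)
//   6..11  K
//   12..17 Cl
//   18..21 Ca  (sn se dn de; Ca does not enter glia)
//   22..27 gates n h s c q z
//   28..33 V   (sn se sg dn de dg)
//
// Derived potentials (10): phi_sn, phi_se, phi_sg, phi_dn, phi_de, phi_dg
// (absolute, gauge phi_de = 0) and the four membrane potentials
// phi_msn, phi_mdn, phi_msg, phi_mdg (intracellular minus extracellular).
//
// Sign conventions: transmembrane flux positive outward; axial flux positive
// from the soma layer to the dendrite layer.

#include <Rcpp.h>
#include <R_ext/Rdynload.h>
#include <cstring>
#include <string>
#include <vector>
#include "dual.h"

// ---- parameter vector layout (see R/parameters.R, edneg_pack_parms) -------
enum {
  P_GNAL_N = 0, P_GKL_N, P_GCLL_N, P_RHO_N, P_UKCC2, P_UNKCC1, P_UCADEC,
  P_GNAL_G, P_GKIR, P_GCLL_G, P_RHO_G,
  P_GNA, P_GDR, P_GCA, P_GAHP, P_GC,
  P_PSI,
  P_AMSN, P_AMDN, P_AMSG, P_AMDG,
  P_CSPEC_N, P_CSPEC_G,
  P_AXN, P_AXE, P_AXG,
  P_DX,
  P_DNA, P_DK, P_DCL, P_DCA,
  P_LAM2_N, P_LAM2_E, P_LAM2_G,
  P_WN, P_WG,
  P_X0,  /* 6 slots: X_sn..X_dg (osmotic amount of impermeant species) */
  P_B0 = P_X0 + 6, /* 6 slots: background charge per compartment */
  P_CAB_SN = P_B0 + 6, P_CAB_DN,
  P_KE_BASE, P_FCA_FREE, P_CA_SCALE, P_EKG_REST,
  P_PUMPG_KMNA, P_PUMPG_KMK,
  P_ZMID, P_ZSLOPE, P_TAUZ, P_BETAQ, P_QCAP, P_CA_ACT_THR, P_PUMPN_NAHALF,
  P_S_SHIFT,
  P_STIM_AMP, P_STIM_ON, P_STIM_OFF,
  NPARMS
};

#define N_STATE 34
#define N_PHI 10

static double parms_store[NPARMS];

// state indices
enum { C_SN = 0, C_SE, C_SG, C_DN, C_DE, C_DG };
static const int iNa = 0, iK = 6, iCl = 12, iCa = 18;
static const int iGate = 22, iVol = 28;
// Ca compartment slots: sn, se, dn, de
static const int caSlot[6] = { 0, 1, -1, 2, 3, -1 };

// optional per-channel flux record (filled only for T = double)
struct FluxRecord {
  std::vector<std::string> name;
  std::vector<double> value;
  void add(const std::string &n, double v) { name.push_back(n); value.push_back(v); }
};

// x / (exp(x) - 1), stable near 0
template <class T>
inline T vtrap(const T &x) {
  if (std::fabs(val(x)) < 1e-9) return 1.0 - x / 2.0;
  return x / expm1(x);
}

// ---- Hodgkin-Huxley rate functions (ms^-1, phi in mV) ----------------------
// Pinsky-Rinzel CA3 kinetics shifted by -60 mV so that phi is an absolute
// membrane potential.
template <class T> inline T alpha_m(const T &phi) { T u = (-46.9 - phi) / 4.0; return 1.28 * vtrap(u); }
template <class T> inline T beta_m(const T &phi)  { T u = (phi + 19.9) / 5.0;  return 1.4 * vtrap(u); }
template <class T> inline T alpha_h(const T &phi) { return 0.128 * exp((-43.0 - phi) / 18.0); }
template <class T> inline T beta_h(const T &phi)  { return 4.0 / (1.0 + exp((-20.0 - phi) / 5.0)); }
template <class T> inline T alpha_n(const T &phi) { T u = (-24.9 - phi) / 5.0; return 0.08 * vtrap(u); }
template <class T> inline T beta_n(const T &phi)  { return 0.25 * exp(-(phi + 40.0) / 40.0); }
template <class T> inline T alpha_s(const T &phi) { return 1.6 / (1.0 + exp(-0.072 * (phi - 5.0))); }
template <class T> inline T beta_s(const T &phi)  { T u = (phi + 8.9) / 5.0; return 0.1 * vtrap(u); }
template <class T>
inline void rates_c(const T &phi, T &ac, T &bc) {
  if (val(phi) <= -10.0) {
    ac = exp((phi + 50.0) / 11.0 - (phi + 53.5) / 27.0) / 18.975;
    bc = 2.0 * exp(-(phi + 53.5) / 27.0) - ac;
  } else {
    ac = 2.0 * exp(-(phi + 53.5) / 27.0);
    bc = 0.0;
  }
}
// q gate (Ca-dependent afterhyperpolarization) and the Ca saturation chi use
// a dimensionless Ca activity: ca_scale * (free [Ca] excess over baseline).
template <class T> inline T alpha_q(const T &ca_act, double cap) { return dmin(2e-5 * ca_act, cap); }
// slow inactivation of the dendritic Ca channel
template <class T>
inline T z_inf(const T &phi, const double *p) {
  return 1.0 / (1.0 + exp((phi - p[P_ZMID]) / p[P_ZSLOPE]));
}

template <class T>
inline T nernst(double psi, double z, const T &cin, const T &cout) {
  return (psi / z) * log(cout / cin);
}

// neuronal Na/K pump activity (dimensionless in [0,1])
template <class T>
inline T pump_n(const T &na_in, const T &k_out, double na_half) {
  return 1.0 / ((1.0 + exp((na_half - na_in) / 3.0)) * (1.0 + exp(3.5 - k_out)));
}
// glial Na/K pump activity (saturating Michaelis-Menten-type form)
template <class T>
inline T pump_g(const T &na_in, const T &k_out, double kmna, double kmk) {
  T na32 = na_in * sqrt(na_in);
  double km32 = kmna * std::sqrt(kmna);
  return (na32 / (na32 + km32)) * (k_out / (k_out + kmk));
}
// glial inward-rectifying K conductance factor
template <class T>
inline T f_kir(const T &k_out, double ke_base, const T &dphi, const T &phi, double ekg_rest) {
  T a = sqrt(k_out / ke_base);
  T f1 = (1.0 + std::exp(18.4 / 42.4)) / (1.0 + exp((dphi + 18.5) / 42.5));
  T f2 = (1.0 + std::exp(-(118.6 + ekg_rest) / 44.1)) / (1.0 + exp(-(118.6 + phi) / 44.1));
  return a * f1 * f2;
}

// ---- the model core --------------------------------------------------------
// Computes dy (34), phi (10).  rec, if non-null (double instantiation only),
// receives a per-channel flux breakdown for the membrane `rec_mem`
// (0 = neuron soma, 1 = neuron dendrite, 2 = glia soma, 3 = glia dendrite).
template <class T>
void edneg_core(double t, const T *y, const double *p, T *dy, T *phi,
                FluxRecord *rec = 0, int rec_mem = -1) {
  const double psi = p[P_PSI];

  // concentrations
  T cNa[6], cK[6], cCl[6], cCa[4], V[6];
  for (int i = 0; i < 6; ++i) {
    V[i] = y[iVol + i];
    cNa[i] = y[iNa + i] / V[i];
    cK[i] = y[iK + i] / V[i];
    cCl[i] = y[iCl + i] / V[i];
  }
  for (int i = 0; i < 4; ++i) {
    int comp = (i < 2) ? i : i + 1; // sn, se, dn, de
    cCa[i] = y[iCa + i] / V[comp];
  }

  // ---- algebraic potentials (Kirchhoff-Nernst-Planck solve) ----------------
  // net charge per compartment (charge-amol)
  T Q[6];
  for (int i = 0; i < 6; ++i) {
    Q[i] = y[iNa + i] + y[iK + i] - y[iCl + i] + p[P_B0 + i];
    if (caSlot[i] >= 0) Q[i] = Q[i] + 2.0 * y[iCa + caSlot[i]];
  }
  // membrane potentials from the capacitor relation
  T a_sn = Q[C_SN] / (p[P_CSPEC_N] * p[P_AMSN]);
  T a_dn = Q[C_DN] / (p[P_CSPEC_N] * p[P_AMDN]);
  T a_sg = Q[C_SG] / (p[P_CSPEC_G] * p[P_AMSG]);
  T a_dg = Q[C_DG] / (p[P_CSPEC_G] * p[P_AMDG]);

  // axial conductance-like and diffusive charge-flux terms per domain
  const double Dk[4] = { p[P_DNA], p[P_DK], p[P_DCL], p[P_DCA] };
  const double zk[4] = { 1.0, 1.0, -1.0, 2.0 };
  // domain 0 = neuron (sn-dn), 1 = ECS (se-de), 2 = glia (sg-dg)
  const int sComp[3] = { C_SN, C_SE, C_SG };
  const int dComp[3] = { C_DN, C_DE, C_DG };
  const double Ax[3] = { p[P_AXN], p[P_AXE], p[P_AXG] };
  const double lam2[3] = { p[P_LAM2_N], p[P_LAM2_E], p[P_LAM2_G] };
  const double dx = p[P_DX];

  T beta[3], gam[3];
  for (int d = 0; d < 3; ++d) {
    beta[d] = 0.0; gam[d] = 0.0;
    for (int k = 0; k < 4; ++k) {
      if (k == 3 && d == 2) continue; // no Ca in glia
      T cs, cd;
      if (k == 0) { cs = cNa[sComp[d]]; cd = cNa[dComp[d]]; }
      else if (k == 1) { cs = cK[sComp[d]]; cd = cK[dComp[d]]; }
      else if (k == 2) { cs = cCl[sComp[d]]; cd = cCl[dComp[d]]; }
      else { cs = cCa[caSlot[sComp[d]]]; cd = cCa[caSlot[dComp[d]]]; }
      double Dt = Dk[k] / lam2[d];
      T cbar = 0.5 * (cs + cd);
      beta[d] = beta[d] + (Ax[d] / dx) * zk[k] * zk[k] * Dt * cbar / psi;
      gam[d] = gam[d] + (Ax[d] / dx) * zk[k] * Dt * (cd - cs);
    }
  }
  // Kirchhoff condition across the soma/dendrite boundary fixes phi_se
  // (gauge: phi_de = 0)
  T phi_se = (gam[0] + gam[1] + gam[2]
              + beta[0] * (a_dn - a_sn) + beta[2] * (a_dg - a_sg))
             / (beta[0] + beta[1] + beta[2]);
  T phiA[6];
  phiA[C_SN] = phi_se + a_sn; phiA[C_SE] = phi_se; phiA[C_SG] = phi_se + a_sg;
  phiA[C_DN] = a_dn; phiA[C_DE] = 0.0; phiA[C_DG] = a_dg;
  phi[0] = phiA[C_SN]; phi[1] = phiA[C_SE]; phi[2] = phiA[C_SG];
  phi[3] = phiA[C_DN]; phi[4] = phiA[C_DE]; phi[5] = phiA[C_DG];
  phi[6] = a_sn; phi[7] = a_dn; phi[8] = a_sg; phi[9] = a_dg;

  for (int i = 0; i < N_STATE; ++i) dy[i] = 0.0;

  // ---- transmembrane fluxes (positive outward), amol um^-2 ms^-1 -----------
  // mem: 0 neuron soma (sn|se), 1 neuron dendrite (dn|de),
  //      2 glia soma (sg|se), 3 glia dendrite (dg|de)
  const int inComp[4] = { C_SN, C_DN, C_SG, C_DG };
  const int exComp[4] = { C_SE, C_DE, C_SE, C_DE };
  const T phim[4] = { a_sn, a_dn, a_sg, a_dg };
  const double Am[4] = { p[P_AMSN], p[P_AMDN], p[P_AMSG], p[P_AMDG] };

  for (int m = 0; m < 4; ++m) {
    int ci = inComp[m], ce = exComp[m];
    bool neuron = (m < 2);
    bool record = (rec && m == rec_mem);
    T jNa = 0.0, jK = 0.0, jCl = 0.0, jCa = 0.0;
    T ENa = nernst(psi, 1.0, cNa[ci], cNa[ce]);
    T EK  = nernst(psi, 1.0, cK[ci], cK[ce]);
    T ECl = nernst(psi, -1.0, cCl[ci], cCl[ce]);
    const T &vm = phim[m];

    if (neuron) {
      T jl_na = p[P_GNAL_N] * (vm - ENa);
      T jl_k  = p[P_GKL_N] * (vm - EK);
      T jl_cl = -p[P_GCLL_N] * (vm - ECl);
      T fp = pump_n(cNa[ci], cK[ce], p[P_PUMPN_NAHALF]);
      T jp = p[P_RHO_N] * fp;
      T jkcc2 = p[P_UKCC2] * log(cK[ci] * cCl[ci] / (cK[ce] * cCl[ce]));
      T fn = 1.0 / (1.0 + exp(16.0 - cK[ce]));
      T jnkcc1 = p[P_UNKCC1] * fn *
        (log(cK[ci] * cCl[ci] / (cK[ce] * cCl[ce])) +
         log(cNa[ci] * cCl[ci] / (cNa[ce] * cCl[ce])));
      // Ca/2Na exchanger: exports the Ca excess over baseline, imports 2 Na
      double cab = (m == 0) ? p[P_CAB_SN] : p[P_CAB_DN];
      T jcadec = p[P_UCADEC] * (cCa[caSlot[ci]] - cab) * V[ci] / Am[m];

      jNa = jNa + jl_na + 3.0 * jp + jnkcc1 - 2.0 * jcadec;
      jK  = jK + jl_k - 2.0 * jp + jkcc2 + jnkcc1;
      jCl = jCl + jl_cl + jkcc2 + 2.0 * jnkcc1;
      jCa = jCa + jcadec;

      T jact_na = 0.0, jact_k = 0.0, jca_chan = 0.0;
      if (m == 0) { // soma: Na and delayed-rectifier K
        T minf = alpha_m(vm) / (alpha_m(vm) + beta_m(vm));
        jact_na = p[P_GNA] * minf * minf * y[iGate + 1] * (vm - ENa);
        jact_k = p[P_GDR] * y[iGate + 0] * (vm - EK);
      } else { // dendrite: Ca, K-AHP, K-C
        T ECa = nernst(psi, 2.0, p[P_FCA_FREE] * cCa[caSlot[ci]], cCa[caSlot[ce]]);
        T s = y[iGate + 2], zg = y[iGate + 5];
        jca_chan = p[P_GCA] * s * s * zg * (vm - ECa) / 2.0;
        T ca_act = dmax(p[P_CA_SCALE] * p[P_FCA_FREE] *
                        (cCa[caSlot[ci]] - p[P_CA_ACT_THR]), 0.0);
        T chi = dmin(ca_act / 250.0, 1.0);
        jact_k = p[P_GAHP] * y[iGate + 4] * (vm - EK) +
                 p[P_GC] * y[iGate + 3] * chi * (vm - EK);
      }
      jNa = jNa + jact_na;
      jK = jK + jact_k;
      jCa = jCa + jca_chan;

      if (record) {
        if constexpr (std::is_same<T, double>::value) {
          rec->add("Na_leak", jl_na); rec->add("K_leak", jl_k); rec->add("Cl_leak", jl_cl);
          rec->add("Na_pump", 3.0 * jp); rec->add("K_pump", -2.0 * jp);
          rec->add("K_kcc2", jkcc2); rec->add("Cl_kcc2", jkcc2);
          rec->add("Na_nkcc1", jnkcc1); rec->add("K_nkcc1", jnkcc1); rec->add("Cl_nkcc1", 2.0 * jnkcc1);
          rec->add("Ca_cadec", jcadec); rec->add("Na_cadec", -2.0 * jcadec);
          if (m == 0) { rec->add("Na_active", jact_na); rec->add("K_DR", jact_k); }
          else { rec->add("Ca_channel", jca_chan); rec->add("K_AHP_C", jact_k); }
        }
      }
    } else { // glia
      T jl_na = p[P_GNAL_G] * (vm - ENa);
      T jl_cl = -p[P_GCLL_G] * (vm - ECl);
      T fk = f_kir(cK[ce], p[P_KE_BASE], vm - EK, vm, p[P_EKG_REST]);
      T jkir = p[P_GKIR] * fk * (vm - EK);
      T fp = pump_g(cNa[ci], cK[ce], p[P_PUMPG_KMNA], p[P_PUMPG_KMK]);
      T jp = p[P_RHO_G] * fp;
      jNa = jNa + jl_na + 3.0 * jp;
      jK = jK + jkir - 2.0 * jp;
      jCl = jCl + jl_cl;
      if (record) {
        if constexpr (std::is_same<T, double>::value) {
          rec->add("Na_leak", jl_na); rec->add("Cl_leak", jl_cl);
          rec->add("K_kir", jkir);
          rec->add("Na_pump", 3.0 * jp); rec->add("K_pump", -2.0 * jp);
        }
      }
    }

    dy[iNa + ci] = dy[iNa + ci] - Am[m] * jNa;
    dy[iNa + ce] = dy[iNa + ce] + Am[m] * jNa;
    dy[iK + ci] = dy[iK + ci] - Am[m] * jK;
    dy[iK + ce] = dy[iK + ce] + Am[m] * jK;
    dy[iCl + ci] = dy[iCl + ci] - Am[m] * jCl;
    dy[iCl + ce] = dy[iCl + ce] + Am[m] * jCl;
    if (neuron) {
      dy[iCa + caSlot[ci]] = dy[iCa + caSlot[ci]] - Am[m] * jCa;
      dy[iCa + caSlot[ce]] = dy[iCa + caSlot[ce]] + Am[m] * jCa;
    }
  }

  // ---- axial (intradomain) fluxes, positive soma -> dendrite ---------------
  for (int d = 0; d < 3; ++d) {
    int cs = sComp[d], cd = dComp[d];
    T dphi = phiA[cd] - phiA[cs];
    for (int k = 0; k < 4; ++k) {
      if (k == 3 && d == 2) continue;
      T cs_c, cd_c; int is, id;
      if (k == 0) { cs_c = cNa[cs]; cd_c = cNa[cd]; is = iNa + cs; id = iNa + cd; }
      else if (k == 1) { cs_c = cK[cs]; cd_c = cK[cd]; is = iK + cs; id = iK + cd; }
      else if (k == 2) { cs_c = cCl[cs]; cd_c = cCl[cd]; is = iCl + cs; id = iCl + cd; }
      else { cs_c = cCa[caSlot[cs]]; cd_c = cCa[caSlot[cd]]; is = iCa + caSlot[cs]; id = iCa + caSlot[cd]; }
      double Dt = Dk[k] / lam2[d];
      T cbar = 0.5 * (cs_c + cd_c);
      T j = -Dt * (cd_c - cs_c) / dx - Dt * zk[k] * cbar * dphi / (psi * dx);
      dy[is] = dy[is] - Ax[d] * j;
      dy[id] = dy[id] + Ax[d] * j;
    }
  }

  // ---- stimulus: K+ into soma-neuron, matched removal from soma-ECS --------
  if (t >= p[P_STIM_ON] && t < p[P_STIM_OFF]) {
    dy[iK + C_SN] = dy[iK + C_SN] + p[P_STIM_AMP];
    dy[iK + C_SE] = dy[iK + C_SE] - p[P_STIM_AMP];
  }

  // ---- gating dynamics -----------------------------------------------------
  {
    const T &vs = a_sn, &vd = a_dn;
    T n = y[iGate + 0], h = y[iGate + 1], s = y[iGate + 2];
    T c = y[iGate + 3], q = y[iGate + 4], zg = y[iGate + 5];
    dy[iGate + 0] = alpha_n(vs) * (1.0 - n) - beta_n(vs) * n;
    dy[iGate + 1] = alpha_h(vs) * (1.0 - h) - beta_h(vs) * h;
    T vds = vd - p[P_S_SHIFT];
    dy[iGate + 2] = alpha_s(vds) * (1.0 - s) - beta_s(vds) * s;
    T ac, bc; rates_c(vd, ac, bc);
    dy[iGate + 3] = ac * (1.0 - c) - bc * c;
    T ca_act = dmax(p[P_CA_SCALE] * p[P_FCA_FREE] * (cCa[caSlot[C_DN]] - p[P_CA_ACT_THR]), 0.0);
    dy[iGate + 4] = alpha_q(ca_act, p[P_QCAP]) * (1.0 - q) - p[P_BETAQ] * q;
    dy[iGate + 5] = (z_inf(vd, p) - zg) / p[P_TAUZ];
  }

  // ---- osmotic water flow (volume dynamics) --------------------------------
  // osmolarity per compartment, including the impermeant species X
  T osm[6];
  for (int i = 0; i < 6; ++i) {
    osm[i] = cNa[i] + cK[i] + cCl[i] + p[P_X0 + i] / V[i];
    if (caSlot[i] >= 0) osm[i] = osm[i] + cCa[caSlot[i]];
  }
  const double Wm[4] = { p[P_WN], p[P_WN], p[P_WG], p[P_WG] };
  for (int m = 0; m < 4; ++m) {
    int ci = inComp[m], ce = exComp[m];
    T w = Wm[m] * (osm[ci] - osm[ce]); // um^3/ms into the intracellular side
    dy[iVol + ci] = dy[iVol + ci] + w;
    dy[iVol + ce] = dy[iVol + ce] - w;
  }
}

// ---- deSolve compiled interface --------------------------------------------
extern "C" {

void edneg_initmod(void (*odeparms)(int *, double *)) {
  int n = NPARMS;
  odeparms(&n, parms_store);
}

void edneg_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip) {
  double phi[N_PHI];
  edneg_core<double>(*t, y, parms_store, ydot, phi);
  if (ip[0] >= N_PHI) for (int i = 0; i < N_PHI; ++i) yout[i] = phi[i];
}

void edneg_jac(int *neq, double *t, double *y, int *ml, int *mu,
               double *pd, int *nrowpd, double *yout, int *ip) {
  Dual yd[N_STATE], dy[N_STATE], phi[N_PHI];
  for (int j = 0; j < N_STATE; ++j) {
    for (int i = 0; i < N_STATE; ++i) { yd[i].v = y[i]; yd[i].d = (i == j) ? 1.0 : 0.0; }
    edneg_core<Dual>(*t, yd, parms_store, dy, phi);
    for (int i = 0; i < N_STATE; ++i) pd[i + j * (*nrowpd)] = dy[i].d;
  }
}

} // extern "C"

// ---- Rcpp interfaces (tests and module-level operations) -------------------

extern "C" SEXP c_edneg_rhs(SEXP tS, SEXP yS, SEXP parmsS) {
BEGIN_RCPP
  double t = Rcpp::as<double>(tS);
  Rcpp::NumericVector y(yS), parms(parmsS);
  if (y.size() != N_STATE) Rcpp::stop("state must have length 34");
  if (parms.size() != NPARMS) Rcpp::stop("parameter vector has wrong length");
  double dy[N_STATE], phi[N_PHI];
  edneg_core<double>(t, y.begin(), parms.begin(), dy, phi);
  return Rcpp::List::create(
    Rcpp::Named("dy") = Rcpp::NumericVector(dy, dy + N_STATE),
    Rcpp::Named("phi") = Rcpp::NumericVector(phi, phi + N_PHI));
END_RCPP
}

extern "C" SEXP c_edneg_jacobian(SEXP tS, SEXP yS, SEXP parmsS) {
BEGIN_RCPP
  double t = Rcpp::as<double>(tS);
  Rcpp::NumericVector y(yS), parms(parmsS);
  if (y.size() != N_STATE) Rcpp::stop("state must have length 34");
  Rcpp::NumericMatrix J(N_STATE, N_STATE);
  Dual yd[N_STATE], dy[N_STATE], phi[N_PHI];
  for (int j = 0; j < N_STATE; ++j) {
    for (int i = 0; i < N_STATE; ++i) { yd[i].v = y[i]; yd[i].d = (i == j) ? 1.0 : 0.0; }
    edneg_core<Dual>(t, yd, parms.begin(), dy, phi);
    for (int i = 0; i < N_STATE; ++i) J(i, j) = dy[i].d;
  }
  return Rcpp::wrap(J);
END_RCPP
}

extern "C" SEXP c_edneg_gates(SEXP phi_sS, SEXP phi_dS, SEXP ca_dnS,
                              SEXP xS, SEXP parmsS) {
BEGIN_RCPP
  double phi_s = Rcpp::as<double>(phi_sS), phi_d = Rcpp::as<double>(phi_dS);
  double ca_dn = Rcpp::as<double>(ca_dnS);
  Rcpp::NumericVector x(xS), parms(parmsS);
  const double *p = parms.begin();
  double ca_act = dmax(p[P_CA_SCALE] * p[P_FCA_FREE] * (ca_dn - p[P_CA_ACT_THR]), 0.0);
  double al[6], be[6];
  al[0] = alpha_n(phi_s); be[0] = beta_n(phi_s);
  al[1] = alpha_h(phi_s); be[1] = beta_h(phi_s);
  al[2] = alpha_s(phi_d - p[P_S_SHIFT]); be[2] = beta_s(phi_d - p[P_S_SHIFT]);
  rates_c(phi_d, al[3], be[3]);
  al[4] = alpha_q(ca_act, p[P_QCAP]); be[4] = p[P_BETAQ];
  al[5] = z_inf(phi_d, p) / p[P_TAUZ];
  be[5] = (1.0 - z_inf(phi_d, p)) / p[P_TAUZ];
  Rcpp::NumericVector dx_(6), xinf(6), tau(6);
  for (int i = 0; i < 6; ++i) {
    xinf[i] = al[i] / (al[i] + be[i]);
    tau[i] = 1.0 / (al[i] + be[i]);
    dx_[i] = (x.size() == 6) ? al[i] * (1.0 - x[i]) - be[i] * x[i] : NA_REAL;
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx_,
                            Rcpp::Named("x_inf") = xinf,
                            Rcpp::Named("tau") = tau);
END_RCPP
}

extern "C" SEXP c_edneg_fluxes(SEXP yS, SEXP parmsS, SEXP membraneS) {
BEGIN_RCPP
  Rcpp::NumericVector y(yS), parms(parmsS);
  int membrane = Rcpp::as<int>(membraneS);
  if (membrane < 0 || membrane > 3) Rcpp::stop("unknown membrane index");
  double dy[N_STATE], phi[N_PHI];
  FluxRecord rec;
  edneg_core<double>(0.0, y.begin(), parms.begin(), dy, phi, &rec, membrane);
  Rcpp::NumericVector out(rec.value.begin(), rec.value.end());
  out.attr("names") = Rcpp::wrap(rec.name);
  return Rcpp::wrap(out);
END_RCPP
}
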