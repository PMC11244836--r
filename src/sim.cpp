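// Fixed-step RK4 integrator for the micturition network.
//
// Node kinds: 0 = Hodgkin-Huxley single compartment (state v, m, h, n, gTMS),
//             1 = first-order relay (state r, an instantaneous-rate estimate in
//                 spikes/ms; impulse response (1/tau) exp(-t/tau)),
//             2 = threshold gate (PAG): relay state r plus a binary activation
//                 act = permit && (1000 * r >= threshold_Hz).
// Edge types: 0 = spike synapse (per-edge gate s; jumps by `weight` on a
//                 presynaptic spike, decays with tau; postsynaptic current
//                 s * (v - vsyn)). When the postsynaptic node is a relay or
//                 gate, a presynaptic spike instead increments r by
//                 weight / tau_relay (unit-area impulse for weight = 1).
//             1 = drive synapse (continuous conductance from a relay or gate;
//                 g = weight * r * 25 for relays -- i.e. `weight` is the
//                 conductance delivered at a presynaptic rate of 40 Hz --
//                 and g = weight * act for gates).
//             2 = axial coupling (bidirectional ohmic current between cable
//                 compartments, weight = axial conductance in mS/cm^2).
//
// External (bladder afferent) input uses edges with pre == 0; their jumps are
// driven by the sorted spike-time vector `aff_times`.
//
// Units: mV, ms, mS/cm^2, uF/cm^2, uA/cm^2.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// x / (1 - exp(-x/k)), removable singularity at x = 0
static inline double expdiv(double x, double k) {
  double e = x / k;
  if (std::fabs(e) < 1e-7) return k * (1.0 + 0.5 * e);
  return x / (1.0 - std::exp(-e));
}

struct NetDef {
  int n, ne;
  std::vector<int> kind, clamped, tmscol, pagpermit;
  std::vector<double> cm, gNa, gK, gL, vNa, vK, vL, rtau, ttau, iinj, v0, pagthr;
  std::vector<double> vsm, vsh, vsn; // gating voltage shifts (mV)
  std::vector<int> epre, epost, etype, egate; // egate: state slot of the gate, -1 none
  std::vector<double> ew, evs, etau;
  bool rectified;
  const NumericMatrix *ku; // half-grid TMS drive, one column per target
};

// derivative of the full state; Icur is scratch of length n
static void deriv(const NetDef &d, const std::vector<double> &x,
                  std::vector<double> &dx, int urow, std::vector<double> &Icur) {
  const int n = d.n;
  std::fill(Icur.begin(), Icur.end(), 0.0);
  std::fill(dx.begin(), dx.end(), 0.0);

  for (int e = 0; e < d.ne; ++e) {
    int post = d.epost[e] - 1;
    if (d.etype[e] == 0) {
      int gs = d.egate[e];
      if (gs >= 0) {
        double s = x[gs];
        dx[gs] = -s / d.etau[e];
        Icur[post] += s * (x[5 * post] - d.evs[e]);
      }
    } else if (d.etype[e] == 1) {
      int pre = d.epre[e] - 1;
      double act;
      if (d.kind[pre] == 2) {
        act = (d.pagpermit[pre] && 1000.0 * x[5 * pre] >= d.pagthr[pre]) ? 1.0 : 0.0;
      } else {
        act = x[5 * pre] * 25.0; // conductance = weight at 40 Hz presynaptic rate
      }
      Icur[post] += d.ew[e] * act * (x[5 * post] - d.evs[e]);
    } else { // axial
      int pre = d.epre[e] - 1;
      double dif = x[5 * post] - x[5 * pre];
      Icur[post] += d.ew[e] * dif;
      Icur[pre] -= d.ew[e] * dif;
    }
  }

  for (int i = 0; i < n; ++i) {
    int b = 5 * i;
    if (d.kind[i] == 0) {
      if (d.clamped[i]) continue; // all derivatives stay 0
      double v = x[b], m = x[b + 1], h = x[b + 2], nn = x[b + 3], g = x[b + 4];
      double vm = v - d.vsm[i], vh = v - d.vsh[i], vn = v - d.vsn[i];
      double am = 0.1 * expdiv(vm + 40.0, 10.0);
      double bm = 4.0 * std::exp(-(vm + 65.0) / 18.0);
      double ah = 0.07 * std::exp(-(vh + 65.0) / 20.0);
      double bh = 1.0 / (1.0 + std::exp(-(vh + 35.0) / 10.0));
      double an = 0.01 * expdiv(vn + 55.0, 10.0);
      double bn = 0.125 * std::exp(-(vn + 65.0) / 80.0);
      double m3h = m * m * m * h;
      double n4 = nn * nn * nn * nn;
      double ion = (d.gNa[i] * m3h + g) * (v - d.vNa[i]) +
                   d.gK[i] * n4 * (v - d.vK[i]) + d.gL[i] * (v - d.vL[i]);
      dx[b] = (-(ion)-Icur[i] + d.iinj[i]) / d.cm[i];
      dx[b + 1] = am * (1.0 - m) - bm * m;
      dx[b + 2] = ah * (1.0 - h) - bh * h;
      dx[b + 3] = an * (1.0 - nn) - bn * nn;
      double drv = 0.0;
      if (d.tmscol[i] > 0) {
        double u = (*d.ku)(urow, d.tmscol[i] - 1);
        drv = d.rectified ? (u > 0.0 ? u : 0.0) : u;
      }
      dx[b + 4] = (drv - g) / d.ttau[i];
    } else { // relay / gate: r decays
      dx[b] = -x[b] / d.rtau[i];
    }
  }
}

// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(List nodes, List edges, NumericVector aff_times,
                     NumericMatrix ku, double dt, int nsteps,
                     double spike_thresh, double refractory,
                     int record_every, bool tms_rectified) {
  NetDef d;
  {
    IntegerVector kind = nodes["kind"], clamped = nodes["clamped"],
                  tmscol = nodes["tms_col"], pagpermit = nodes["pag_permit"];
    NumericVector cm = nodes["c"], gNa = nodes["gNa"], gK = nodes["gK"],
                  gL = nodes["gL"], vNa = nodes["vNa"], vK = nodes["vK"],
                  vL = nodes["vL"], rtau = nodes["relay_tau"],
                  ttau = nodes["tms_tau"], iinj = nodes["i_inj"],
                  v0 = nodes["v0"], pagthr = nodes["pag_threshold"],
                  vsm = nodes["vshift_m"], vsh = nodes["vshift_h"],
                  vsn = nodes["vshift_n"];
    d.n = kind.size();
    d.kind.assign(kind.begin(), kind.end());
    d.clamped.assign(clamped.begin(), clamped.end());
    d.tmscol.assign(tmscol.begin(), tmscol.end());
    d.pagpermit.assign(pagpermit.begin(), pagpermit.end());
    d.cm.assign(cm.begin(), cm.end());
    d.gNa.assign(gNa.begin(), gNa.end());
    d.gK.assign(gK.begin(), gK.end());
    d.gL.assign(gL.begin(), gL.end());
    d.vNa.assign(vNa.begin(), vNa.end());
    d.vK.assign(vK.begin(), vK.end());
    d.vL.assign(vL.begin(), vL.end());
    d.rtau.assign(rtau.begin(), rtau.end());
    d.ttau.assign(ttau.begin(), ttau.end());
    d.iinj.assign(iinj.begin(), iinj.end());
    d.v0.assign(v0.begin(), v0.end());
    d.pagthr.assign(pagthr.begin(), pagthr.end());
    d.vsm.assign(vsm.begin(), vsm.end());
    d.vsh.assign(vsh.begin(), vsh.end());
    d.vsn.assign(vsn.begin(), vsn.end());
  }
  {
    IntegerVector epre = edges["pre"], epost = edges["post"], etype = edges["type"];
    NumericVector ew = edges["weight"], evs = edges["vsyn"], etau = edges["tau"];
    d.ne = epre.size();
    d.epre.assign(epre.begin(), epre.end());
    d.epost.assign(epost.begin(), epost.end());
    d.etype.assign(etype.begin(), etype.end());
    d.ew.assign(ew.begin(), ew.end());
    d.evs.assign(evs.begin(), evs.end());
    d.etau.assign(etau.begin(), etau.end());
  }
  d.rectified = tms_rectified;
  d.ku = &ku;

  // gate slots: one per spike edge whose postsynaptic node is HH
  int L = 5 * d.n;
  d.egate.assign(d.ne, -1);
  for (int e = 0; e < d.ne; ++e)
    if (d.etype[e] == 0 && d.kind[d.epost[e] - 1] == 0) d.egate[e] = L++;

  // outgoing spike-edge lists per node (0 = external source)
  std::vector<std::vector<int> > out(d.n + 1);
  for (int e = 0; e < d.ne; ++e)
    if (d.etype[e] == 0) out[d.epre[e]].push_back(e);

  // initial state: v0 with gating at steady state, gTMS 0, gates 0, relays 0
  std::vector<double> x(L, 0.0), dx(L), k1(L), k2(L), k3(L), k4(L), xt(L),
      Icur(d.n);
  for (int i = 0; i < d.n; ++i) {
    int b = 5 * i;
    if (d.kind[i] == 0) {
      double v = d.v0[i];
      x[b] = v;
      double vm = v - d.vsm[i], vh = v - d.vsh[i], vn = v - d.vsn[i];
      double am = 0.1 * expdiv(vm + 40.0, 10.0), bm = 4.0 * std::exp(-(vm + 65.0) / 18.0);
      double ah = 0.07 * std::exp(-(vh + 65.0) / 20.0),
             bh = 1.0 / (1.0 + std::exp(-(vh + 35.0) / 10.0));
      double an = 0.01 * expdiv(vn + 55.0, 10.0), bn = 0.125 * std::exp(-(vn + 65.0) / 80.0);
      x[b + 1] = am / (am + bm);
      x[b + 2] = ah / (ah + bh);
      x[b + 3] = an / (an + bn);
    }
  }

  int nrec = 1 + nsteps / record_every;
  NumericMatrix V(nrec, d.n);
  NumericVector tout(nrec);
  for (int i = 0; i < d.n; ++i) V(0, i) = x[5 * i];
  tout[0] = 0.0;
  int rec = 1;

  std::vector<std::vector<double> > spikes(d.n);
  std::vector<double> last_spike(d.n, -1e18);
  std::vector<double> vprev(d.n);
  int naff = aff_times.size(), affp = 0;

  auto fire = [&](int src) {
    for (size_t j = 0; j < out[src].size(); ++j) {
      int e = out[src][j];
      int post = d.epost[e] - 1;
      if (d.egate[e] >= 0)
        x[d.egate[e]] += d.ew[e];
      else if (d.kind[post] != 0)
        x[5 * post] += d.ew[e] / d.rtau[post];
    }
  };

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    // external afferent spikes falling in [t, t + dt)
    while (affp < naff && aff_times[affp] < t + dt) {
      if (aff_times[affp] >= t) fire(0);
      ++affp;
    }
    for (int i = 0; i < d.n; ++i) vprev[i] = x[5 * i];

    int r0 = 2 * step, r1 = 2 * step + 1, r2 = 2 * step + 2;
    deriv(d, x, k1, r0, Icur);
    for (int j = 0; j < L; ++j) xt[j] = x[j] + 0.5 * dt * k1[j];
    deriv(d, xt, k2, r1, Icur);
    for (int j = 0; j < L; ++j) xt[j] = x[j] + 0.5 * dt * k2[j];
    deriv(d, xt, k3, r1, Icur);
    for (int j = 0; j < L; ++j) xt[j] = x[j] + dt * k3[j];
    deriv(d, xt, k4, r2, Icur);
    for (int j = 0; j < L; ++j)
      x[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    double tnew = t + dt;
    for (int i = 0; i < d.n; ++i) {
      if (d.kind[i] != 0) continue;
      int b = 5 * i;
      // numerical guards: gating in [0,1], gTMS >= 0
      for (int q = 1; q <= 3; ++q) {
        if (x[b + q] < 0.0) x[b + q] = 0.0;
        else if (x[b + q] > 1.0) x[b + q] = 1.0;
      }
      if (x[b + 4] < 0.0) x[b + 4] = 0.0;
      double v = x[b];
      if (!R_finite(v) || std::fabs(v) > 200.0)
        stop("numerical blow-up at node %d, t = %.4f ms (v = %g mV)", i + 1, tnew, v);
      if (!d.clamped[i] && vprev[i] < spike_thresh && v >= spike_thresh &&
          tnew - last_spike[i] >= refractory) {
        double frac = (spike_thresh - vprev[i]) / (v - vprev[i]);
        double tspk = t + frac * dt;
        spikes[i].push_back(tspk);
        last_spike[i] = tspk;
        fire(i + 1);
      }
    }

    if ((step + 1) % record_every == 0 && rec < nrec) {
      for (int i = 0; i < d.n; ++i) V(rec, i) = x[5 * i];
      tout[rec] = tnew;
      ++rec;
    }
  }

  List spk(d.n);
  for (int i = 0; i < d.n; ++i) spk[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  return List::create(_["time"] = tout, _["v"] = V, _["spikes"] = spk);
}
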