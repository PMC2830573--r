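// Core time-stepping engine for the two-layer oscillatory semantic network.
//
// Layout conventions (all 0-based internally):
//   feature units:  global index g = area*M*M + r*M + c   (row-major in area)
//   lexical units:  only declared word units carry trainable synapses; the
//                   remaining sheet units share one "background" trajectory
//                   because they receive identical input (gating inhibition
//                   only), so a single scalar tracks them exactly.
//
// Weight matrices (post-synaptic index first):
//   WA : N_f x N_f   inter-area feature synapses (within-area block absent)
//   WF : n_w x N_f   feature -> word
//   WL : N_f x n_w   word -> feature
//   WI : n_w x n_w   interneuron -> word (diagonal structurally zero)

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Oscillator activation: logistic rescaled so H(0) = 0 and sup H = 1, then
// clamped at zero. Gives an exact silent rest state and [0,1] activities.
inline double sig_rest0(double u, double th, double p, double s0) {
  if (u <= 0.0) return 0.0;
  double v = 1.0 / (1.0 + std::exp(-p * (u - th)));
  v = (v - s0) / (1.0 - s0);
  return v > 0.0 ? v : 0.0;
}

// Plain logistic used by lexical units and interneurons.
inline double sig_plain(double u, double th, double p) {
  return 1.0 / (1.0 + std::exp(-p * (u - th)));
}

// 4-connected flood fill; returns number of components above threshold.
int count_bubbles(const std::vector<double>& grid, int M, double th,
                  std::vector<int>& scratch) {
  std::fill(scratch.begin(), scratch.end(), 0);
  int ncomp = 0;
  std::vector<int> stack;
  for (int s = 0; s < M * M; ++s) {
    if (grid[s] < th || scratch[s]) continue;
    ++ncomp;
    stack.clear();
    stack.push_back(s);
    scratch[s] = ncomp;
    while (!stack.empty()) {
      int q = stack.back();
      stack.pop_back();
      int r = q / M, c = q % M;
      const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= M || cc < 0 || cc >= M) continue;
        int qq = rr * M + cc;
        if (grid[qq] >= th && !scratch[qq]) {
          scratch[qq] = ncomp;
          stack.push_back(qq);
        }
      }
    }
  }
  return ncomp;
}

}  // namespace

// [[Rcpp::export(name = ".engine_simulate")]]
List engine_simulate(List geom, List osc, List lex, List dec, List lrn,
                     NumericMatrix lat, NumericMatrix WA, NumericMatrix WF,
                     NumericMatrix WL, NumericMatrix WI,
                     NumericVector ext_feature, NumericVector word_input,
                     NumericVector word_bias,
                     NumericVector x0, NumericVector y0,
                     NumericVector xl0, NumericVector xi0,
                     double xlbg0, double xibg0,
                     double dt, double duration_ms, double record_ms,
                     bool record_features) {
  const int F = as<int>(geom["n_areas"]);
  const int M = as<int>(geom["side"]);
  const int Nf = F * M * M;
  const int nw = as<int>(geom["n_words"]);

  const double taux = as<double>(osc["tau_ex"]);
  const double tauy = as<double>(osc["tau_inh"]);
  const double c1 = as<double>(osc["g_ee"]);
  const double c2 = as<double>(osc["g_ie"]);
  const double c3 = as<double>(osc["g_ei"]);
  const double c4 = as<double>(osc["g_ii"]);
  const double thx = as<double>(osc["theta_ex"]);
  const double px = as<double>(osc["slope_ex"]);
  const double thy = as<double>(osc["theta_inh"]);
  const double py = as<double>(osc["slope_inh"]);
  const double rest_in = as<double>(osc["rest_input"]);
  const double s0x = 1.0 / (1.0 + std::exp(px * thx));
  const double s0y = 1.0 / (1.0 + std::exp(py * thy));

  const double tauL = as<double>(lex["tau"]);
  const double thL = as<double>(lex["theta"]);
  const double pL = as<double>(lex["slope"]);
  const double GL = as<double>(lex["gate_strength"]);
  const double tauI = as<double>(lex["tau_int"]);
  const double thI = as<double>(lex["theta_int"]);
  const double pI = as<double>(lex["slope_int"]);

  // which oscillator signal the lexical layer reads: 0 = excitatory
  // sub-unit (default assumption), 1 = mean of both sub-units
  const int feat_out = lex.containsElementNamed("feature_output_mode")
                           ? as<int>(lex["feature_output_mode"])
                           : 0;

  const double bub_th = as<double>(dec["bubble_threshold"]);
  const double window_ms = as<double>(dec["window_ms"]);
  const double persist_ms = as<double>(dec["persistence_ms"]);
  const double eval_ms = as<double>(dec["eval_ms"]);

  const bool learnA = as<bool>(lrn["learn_inter_area"]);
  const bool learnF = as<bool>(lrn["learn_feature_to_word"]);
  const bool learnL = as<bool>(lrn["learn_word_to_feature"]);
  const bool learnI = as<bool>(lrn["learn_competition"]);
  const double betaA = as<double>(lrn["beta_inter_area"]);
  const double betaF = as<double>(lrn["beta_feature_to_word"]);
  const double betaL = as<double>(lrn["beta_word_to_feature"]);
  const double betaI = as<double>(lrn["beta_competition"]);
  const double wmaxA = as<double>(lrn["wmax_inter_area"]);
  const double wmaxF = as<double>(lrn["wmax_feature_to_word"]);
  const double wmaxL = as<double>(lrn["wmax_word_to_feature"]);
  const double wmaxI = as<double>(lrn["wmax_competition"]);
  const double ts_ms = as<double>(lrn["sample_ms"]);
  // activities below the floor do not drive learning: keeps never-co-active
  // unit/word pairs at exactly zero weight despite the lexical sigmoid's
  // nonzero baseline
  const double hebb_floor = as<double>(lrn["activity_floor"]);
  const bool any_learn = learnA || learnF || learnL || learnI;

  const double act_eps = 1e-4;

  const int nsteps = (int)std::lround(duration_ms / dt);
  const int rec_every = std::max(1, (int)std::lround(record_ms / dt));
  const int eval_every = std::max(1, (int)std::lround(eval_ms / dt));
  const int ts_every = std::max(1, (int)std::lround(ts_ms / dt));
  const int nrec = nsteps / rec_every;

  // working copies of state
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> xl(xl0.begin(), xl0.end());
  std::vector<double> xi(xi0.begin(), xi0.end());
  double xlbg = xlbg0, xibg = xibg0;

  // clone weights so the caller's matrices are untouched
  NumericMatrix WAo = clone(WA), WFo = clone(WF), WLo = clone(WL),
                WIo = clone(WI);

  // decision machinery: ring buffer of feature snapshots, one slot per eval
  const int nwin = std::max(1, (int)std::lround(window_ms / eval_ms));
  std::vector<double> ring((size_t)nwin * Nf, 0.0);
  std::vector<double> winmax(Nf, 0.0);
  std::vector<double> areagrid(M * M, 0.0);
  std::vector<int> ffscratch(M * M, 0);
  std::vector<int> counts(F, 0);
  int ring_pos = 0, ring_filled = 0;
  double valid_ms = 0.0;
  int z = 0;
  double gate_open_t = -1.0;

  // recording buffers
  NumericMatrix Xrec(record_features ? nrec : 0, record_features ? Nf : 0);
  NumericMatrix XLrec(nrec, nw), XIrec(nrec, nw);
  NumericVector XLbgrec(nrec), Zrec(nrec), Trec(nrec);
  IntegerMatrix Crec(nrec, F);
  int irec = 0;

  std::vector<int> active;
  active.reserve(Nf);
  std::vector<double> P(Nf), VF(nw), CL(nw), xnew(Nf), ynew(Nf);
  const int MM = M * M;

  for (int step = 0; step < nsteps; ++step) {
    // ---- gather active feature units
    active.clear();
    for (int i = 0; i < Nf; ++i)
      if (x[i] > act_eps) active.push_back(i);

    // ---- synaptic drives onto feature units
    std::fill(P.begin(), P.end(), 0.0);
    for (int idx : active) {
      const double xj = x[idx];
      const int a = idx / MM, loc = idx % MM;
      // lateral, within area only
      const double* latcol = &lat(0, loc);
      double* Pa = &P[(size_t)a * MM];
      for (int i = 0; i < MM; ++i) Pa[i] += latcol[i] * xj;
      // learned inter-area synapses
      const double* wacol = &WAo(0, idx);
      for (int i = 0; i < Nf; ++i) P[i] += wacol[i] * xj;
    }
    // word -> feature feedback
    for (int w = 0; w < nw; ++w) {
      const double xw = xl[w];
      if (xw <= act_eps) continue;
      const double* wlcol = &WLo(0, w);
      for (int i = 0; i < Nf; ++i) P[i] += wlcol[i] * xw;
    }

    // ---- drives onto word units
    for (int w = 0; w < nw; ++w) {
      double s = 0.0;
      for (int idx : active) {
        const double xe =
            feat_out == 0 ? x[idx] : 0.5 * (x[idx] + y[idx]);
        s += WFo(w, idx) * xe;
      }
      VF[w] = s;
      double ci = 0.0;
      for (int v = 0; v < nw; ++v)
        if (v != w) ci += WIo(w, v) * xi[v];
      CL[w] = ci;
    }

    // ---- Euler updates (all inputs computed from the pre-step state)
    const double gate_inh = GL * (1.0 - (double)z);
    for (int i = 0; i < Nf; ++i) {
      const double ux = c1 * x[i] - c2 * y[i] + P[i] + ext_feature[i] + rest_in;
      const double uy = c3 * x[i] - c4 * y[i];
      xnew[i] = x[i] + dt / taux * (-x[i] + sig_rest0(ux, thx, px, s0x));
      ynew[i] = y[i] + dt / tauy * (-y[i] + sig_rest0(uy, thy, py, s0y));
    }
    std::vector<double> xl_old(xl);
    for (int w = 0; w < nw; ++w) {
      const double u = word_input[w] + VF[w] - gate_inh - CL[w] - word_bias[w];
      xl[w] += dt / tauL * (-xl[w] + sig_plain(u, thL, pL));
      xi[w] += dt / tauI * (-xi[w] + sig_plain(xl_old[w], thI, pI));
    }
    // background (non-word) lexical unit: gating inhibition only
    const double xlbg_old = xlbg;
    xlbg += dt / tauL * (-xlbg + sig_plain(-gate_inh, thL, pL));
    xibg += dt / tauI * (-xibg + sig_plain(xlbg_old, thI, pI));
    x.swap(xnew);
    y.swap(ynew);

    // ---- decision network, evaluated every eval_ms
    if ((step + 1) % eval_every == 0) {
      double* slot = &ring[(size_t)ring_pos * Nf];
      for (int i = 0; i < Nf; ++i) slot[i] = x[i];
      ring_pos = (ring_pos + 1) % nwin;
      if (ring_filled < nwin) ++ring_filled;
      for (int i = 0; i < Nf; ++i) {
        double m = 0.0;
        for (int s = 0; s < ring_filled; ++s) {
          const double v = ring[(size_t)s * Nf + i];
          if (v > m) m = v;
        }
        winmax[i] = m;
      }
      bool ok = true;
      for (int a = 0; a < F; ++a) {
        std::copy(winmax.begin() + (size_t)a * MM,
                  winmax.begin() + (size_t)(a + 1) * MM, areagrid.begin());
        counts[a] = count_bubbles(areagrid, M, bub_th, ffscratch);
        if (counts[a] != 1) ok = false;
      }
      if (ok) {
        valid_ms += eval_ms;
        if (valid_ms >= persist_ms && z == 0) {
          z = 1;
          gate_open_t = (step + 1) * dt;
        }
      } else {
        valid_ms = 0.0;
        z = 0;
      }
    }

    // ---- Hebbian updates every sample_ms of co-activity
    if (any_learn && (step + 1) % ts_every == 0) {
      if (learnA) {
        for (int ip : active) {
          const int ap = ip / MM;
          const double xp = x[ip];
          if (xp < hebb_floor) continue;
          for (int jq : active) {
            if (jq / MM == ap) continue;  // within-area entries absent
            if (x[jq] < hebb_floor) continue;
            double w = WAo(ip, jq);
            w += betaA * (1.0 - w / wmaxA) * xp * x[jq];
            WAo(ip, jq) = w < 0.0 ? 0.0 : (w > wmaxA ? wmaxA : w);
          }
        }
      }
      if (learnF || learnL) {
        for (int w = 0; w < nw; ++w) {
          const double xw = xl[w];
          if (xw < hebb_floor) continue;
          for (int jq : active) {
            if (x[jq] < hebb_floor) continue;
            if (learnF) {
              double v = WFo(w, jq);
              v += betaF * (1.0 - v / wmaxF) * xw * x[jq];
              WFo(w, jq) = v < 0.0 ? 0.0 : (v > wmaxF ? wmaxF : v);
            }
            if (learnL) {
              double v = WLo(jq, w);
              v += betaL * (1.0 - v / wmaxL) * x[jq] * xw;
              WLo(jq, w) = v < 0.0 ? 0.0 : (v > wmaxL ? wmaxL : v);
            }
          }
        }
      }
      if (learnI) {
        for (int w = 0; w < nw; ++w) {
          if (xl[w] < hebb_floor) continue;
          for (int v = 0; v < nw; ++v) {
            if (v == w) continue;  // a word is never inhibited by its own pair
            if (xi[v] < hebb_floor) continue;
            double u = WIo(w, v);
            u += betaI * (1.0 - u / wmaxI) * xl[w] * xi[v];
            WIo(w, v) = u < 0.0 ? 0.0 : (u > wmaxI ? wmaxI : u);
          }
        }
      }
    }

    // ---- recording
    if ((step + 1) % rec_every == 0 && irec < nrec) {
      if (record_features)
        for (int i = 0; i < Nf; ++i) Xrec(irec, i) = x[i];
      for (int w = 0; w < nw; ++w) {
        XLrec(irec, w) = xl[w];
        XIrec(irec, w) = xi[w];
      }
      XLbgrec[irec] = xlbg;
      Zrec[irec] = z;
      Trec[irec] = (step + 1) * dt;
      for (int a = 0; a < F; ++a) Crec(irec, a) = counts[a];
      ++irec;
    }
  }

  return List::create(
      _["time_ms"] = Trec, _["feature_ex"] = Xrec, _["word_act"] = XLrec,
      _["word_int"] = XIrec, _["lex_background"] = XLbgrec, _["gate"] = Zrec,
      _["bubble_counts"] = Crec, _["gate_open_ms"] = gate_open_t,
      _["WA"] = WAo, _["WF"] = WFo, _["WL"] = WLo, _["WI"] = WIo,
      _["x_final"] = NumericVector(x.begin(), x.end()),
      _["y_final"] = NumericVector(y.begin(), y.end()),
      _["xl_final"] = NumericVector(xl.begin(), xl.end()),
      _["xi_final"] = NumericVector(xi.begin(), xi.end()),
      _["xl_background_final"] = xlbg, _["xi_background_final"] = xibg);
}

// Single free-running oscillator under constant drive; used by the
// construction-time regime check and by unit tests.
// [[Rcpp::export(name = ".engine_single_oscillator")]]
NumericMatrix engine_single_oscillator(List osc, double drive,
                                       double duration_ms, double dt) {
  const double taux = as<double>(osc["tau_ex"]);
  const double tauy = as<double>(osc["tau_inh"]);
  const double c1 = as<double>(osc["g_ee"]);
  const double c2 = as<double>(osc["g_ie"]);
  const double c3 = as<double>(osc["g_ei"]);
  const double c4 = as<double>(osc["g_ii"]);
  const double thx = as<double>(osc["theta_ex"]);
  const double px = as<double>(osc["slope_ex"]);
  const double thy = as<double>(osc["theta_inh"]);
  const double py = as<double>(osc["slope_inh"]);
  const double rest_in = as<double>(osc["rest_input"]);
  const double s0x = 1.0 / (1.0 + std::exp(px * thx));
  const double s0y = 1.0 / (1.0 + std::exp(py * thy));
  const int n = (int)std::lround(duration_ms / dt);
  NumericMatrix out(n, 3);
  double x = 0.0, yv = 0.0;
  for (int i = 0; i < n; ++i) {
    const double ux = c1 * x - c2 * yv + drive + rest_in;
    const double uy = c3 * x - c4 * yv;
    const double xn = x + dt / taux * (-x + sig_rest0(ux, thx, px, s0x));
    const double yn = yv + dt / tauy * (-yv + sig_rest0(uy, thy, py, s0y));
    x = xn;
    yv = yn;
    out(i, 0) = (i + 1) * dt;
    out(i, 1) = x;
    out(i, 2) = yv;
  }
  colnames(out) = CharacterVector::create("time_ms", "x", "y");
  return out;
}
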