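#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step RK4 integrator for a gap-junction-coupled network of pituitary
// lactotroph model cells. Per-cell state is (V, n, c, b); the BK activation b
// is integrated for every cell and is inert when g_BK = 0, so the state shape
// is uniform across the network.
//
// Parameter matrix column order (must match pitnet:::PAR_COLS on the R side):
//  0 C_m   1 g_Kdr 2 g_Ca  3 g_L   4 g_SK  5 g_BK  6 V_Ca  7 V_K   8 V_L
//  9 tau_n 10 tau_b 11 nu_n 12 nu_m 13 nu_b 14 l_n 15 l_m 16 l_b
// 17 alpha 18 f_c  19 k_c  20 k_SK

static inline double sigm(double v, double nu, double l) {
  return 1.0 / (1.0 + std::exp((nu - v) / l));
}

struct Work {
  std::vector<double> dV, dn, dc, db;
  explicit Work(int m) : dV(m), dn(m), dc(m), db(m) {}
};

// per-cell parameters, contiguous for cache-friendly access in the inner loop
struct CellPar {
  double Cm, gKdr, gCa, gL, gSK, gBK, VCa, VK, VL, taun, taub,
         nun, num, nub, ln, lm, lb, alpha, fc, kc, kSK;
};

// derivative of the full network state at time t
static void net_rhs(const std::vector<double>& V, const std::vector<double>& n,
                    const std::vector<double>& c, const std::vector<double>& b,
                    const std::vector<CellPar>& par,
                    const std::vector<int>& adj_ptr, const std::vector<int>& adj_idx,
                    double gc, double t,
                    int input_cell, double input_gc, double input_vfix,
                    const std::vector<std::pair<double, double> >& windows,
                    Work& out) {
  const int m = (int)V.size();
  for (int i = 0; i < m; ++i) {
    const CellPar& q = par[i];
    const double Cm = q.Cm, gKdr = q.gKdr, gCa = q.gCa, gL = q.gL,
                 gSK = q.gSK, gBK = q.gBK, VCa = q.VCa, VK = q.VK,
                 VL = q.VL, taun = q.taun, taub = q.taub, nun = q.nun,
                 num = q.num, nub = q.nub, ln = q.ln, lm = q.lm,
                 lb = q.lb, alpha = q.alpha, fc = q.fc, kc = q.kc,
                 kSK = q.kSK;
    const double Vi = V[i];
    const double minf = sigm(Vi, num, lm);
    const double ICa  = gCa * minf * (Vi - VCa);
    const double IKdr = gKdr * n[i] * (Vi - VK);
    const double IBK  = gBK * b[i] * (Vi - VK);
    const double c2   = c[i] * c[i];
    const double ISK  = gSK * (c2 / (c2 + kSK * kSK)) * (Vi - VK);
    const double IL   = gL * (Vi - VL);

    // gap-junction current: sum_j gc (V_i - V_j) over structural neighbors
    double Ic = 0.0;
    for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k)
      Ic += gc * (Vi - V[adj_idx[k]]);

    // optional clamped-partner input, active only inside the given windows
    if (i == input_cell) {
      for (size_t w = 0; w < windows.size(); ++w) {
        if (t >= windows[w].first && t < windows[w].second) {
          Ic += input_gc * (Vi - input_vfix);
          break;
        }
      }
    }

    out.dV[i] = -(IKdr + ICa + IBK + ISK + IL + Ic) / Cm;
    out.dn[i] = (sigm(Vi, nun, ln) - n[i]) / taun;
    out.dc[i] = -fc * (alpha * ICa + kc * c[i]);
    out.db[i] = (sigm(Vi, nub, lb) - b[i]) / taub;
  }
}

// [[Rcpp::export]]
List rk4_network_cpp(NumericMatrix par, IntegerMatrix edges, NumericMatrix init,
                     double dt, int n_steps, double gc, int stride,
                     int input_cell, double input_gc, double input_vfix,
                     NumericMatrix windows) {
  const int m = par.nrow();
  if (init.nrow() != m || init.ncol() != 4)
    stop("init must be an n_cells x 4 matrix (V, n, c, b)");
  if (dt <= 0.0) stop("dt must be positive");
  if (stride < 1) stop("stride must be >= 1");

  // adjacency in CSR form from the 0-based undirected edge list
  std::vector<int> deg(m, 0);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b2 = edges(e, 1);
    if (a < 0 || a >= m || b2 < 0 || b2 >= m || a == b2)
      stop("edge list contains invalid node ids");
    ++deg[a]; ++deg[b2];
  }
  std::vector<int> adj_ptr(m + 1, 0);
  for (int i = 0; i < m; ++i) adj_ptr[i + 1] = adj_ptr[i] + deg[i];
  std::vector<int> adj_idx(adj_ptr[m]);
  std::vector<int> fill(m, 0);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b2 = edges(e, 1);
    adj_idx[adj_ptr[a] + fill[a]++] = b2;
    adj_idx[adj_ptr[b2] + fill[b2]++] = a;
  }

  std::vector<CellPar> cpar(m);
  for (int i = 0; i < m; ++i) {
    CellPar& q = cpar[i];
    q.Cm = par(i, 0); q.gKdr = par(i, 1); q.gCa = par(i, 2); q.gL = par(i, 3);
    q.gSK = par(i, 4); q.gBK = par(i, 5); q.VCa = par(i, 6); q.VK = par(i, 7);
    q.VL = par(i, 8); q.taun = par(i, 9); q.taub = par(i, 10); q.nun = par(i, 11);
    q.num = par(i, 12); q.nub = par(i, 13); q.ln = par(i, 14); q.lm = par(i, 15);
    q.lb = par(i, 16); q.alpha = par(i, 17); q.fc = par(i, 18); q.kc = par(i, 19);
    q.kSK = par(i, 20);
  }
  std::vector<std::pair<double, double> > win(windows.nrow());
  for (int w = 0; w < windows.nrow(); ++w)
    win[w] = std::make_pair(windows(w, 0), windows(w, 1));

  std::vector<double> V(m), n(m), c(m), b(m);
  for (int i = 0; i < m; ++i) {
    V[i] = init(i, 0); n[i] = init(i, 1); c[i] = init(i, 2); b[i] = init(i, 3);
  }

  const int n_rec = n_steps / stride + 1;
  NumericMatrix Vout(n_rec, m), nout(n_rec, m), cout_(n_rec, m), bout(n_rec, m);
  NumericVector times(n_rec);
  int rec = 0;
  for (int i = 0; i < m; ++i) {
    Vout(0, i) = V[i]; nout(0, i) = n[i]; cout_(0, i) = c[i]; bout(0, i) = b[i];
  }
  times[0] = 0.0;
  ++rec;

  Work k1(m), k2(m), k3(m), k4(m);
  std::vector<double> Vt(m), nt(m), ct(m), bt(m);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    net_rhs(V, n, c, b, cpar, adj_ptr, adj_idx, gc, t,
            input_cell, input_gc, input_vfix, win, k1);
    for (int i = 0; i < m; ++i) {
      Vt[i] = V[i] + 0.5 * dt * k1.dV[i]; nt[i] = n[i] + 0.5 * dt * k1.dn[i];
      ct[i] = c[i] + 0.5 * dt * k1.dc[i]; bt[i] = b[i] + 0.5 * dt * k1.db[i];
    }
    net_rhs(Vt, nt, ct, bt, cpar, adj_ptr, adj_idx, gc, t + 0.5 * dt,
            input_cell, input_gc, input_vfix, win, k2);
    for (int i = 0; i < m; ++i) {
      Vt[i] = V[i] + 0.5 * dt * k2.dV[i]; nt[i] = n[i] + 0.5 * dt * k2.dn[i];
      ct[i] = c[i] + 0.5 * dt * k2.dc[i]; bt[i] = b[i] + 0.5 * dt * k2.db[i];
    }
    net_rhs(Vt, nt, ct, bt, cpar, adj_ptr, adj_idx, gc, t + 0.5 * dt,
            input_cell, input_gc, input_vfix, win, k3);
    for (int i = 0; i < m; ++i) {
      Vt[i] = V[i] + dt * k3.dV[i]; nt[i] = n[i] + dt * k3.dn[i];
      ct[i] = c[i] + dt * k3.dc[i]; bt[i] = b[i] + dt * k3.db[i];
    }
    net_rhs(Vt, nt, ct, bt, cpar, adj_ptr, adj_idx, gc, t + dt,
            input_cell, input_gc, input_vfix, win, k4);

    for (int i = 0; i < m; ++i) {
      V[i] += dt / 6.0 * (k1.dV[i] + 2.0 * k2.dV[i] + 2.0 * k3.dV[i] + k4.dV[i]);
      n[i] += dt / 6.0 * (k1.dn[i] + 2.0 * k2.dn[i] + 2.0 * k3.dn[i] + k4.dn[i]);
      c[i] += dt / 6.0 * (k1.dc[i] + 2.0 * k2.dc[i] + 2.0 * k3.dc[i] + k4.dc[i]);
      b[i] += dt / 6.0 * (k1.db[i] + 2.0 * k2.db[i] + 2.0 * k3.db[i] + k4.db[i]);
      if (!std::isfinite(V[i]))
        stop("non-finite state encountered at step %d (cell %d)", step + 1, i);
    }

    if ((step + 1) % stride == 0) {
      for (int i = 0; i < m; ++i) {
        Vout(rec, i) = V[i]; nout(rec, i) = n[i];
        cout_(rec, i) = c[i]; bout(rec, i) = b[i];
      }
      times[rec] = (step + 1) * dt;
      ++rec;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["times"] = times, _["V"] = Vout, _["n"] = nout,
                      _["c"] = cout_, _["b"] = bout);
}
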