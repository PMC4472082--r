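// Constant-pressure Metropolis Monte Carlo of a periodic stack of M
// discretized membranes with Helfrich bending elasticity and nearest
// neighbour bare interactions.
//
// Units: lengths in angstrom, energies in zJ, pressures in Pa.
// Pressure enters only via P * volume with 1 Pa*A^3 = 1e-9 zJ.
//
// Degrees of freedom: the Fourier coefficients u_m(q) of the M displacement
// fields (updated one independent mode at a time, Hermitian symmetry
// preserved) and the mean inter-membrane spacing abar (one uniform-step
// proposal per sweep, with the enthalpy term P*M*L^2*abar).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF_E = std::numeric_limits<double>::infinity();
static const double PA_A3_TO_ZJ = 1e-9;
static const double KB_ZJ = 1.380649e-2;

// xoshiro256+ with splitmix64 seeding; self-contained so runs are
// reproducible independent of R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  bool have_norm;
  double cached;
  explicit Xoshiro(uint64_t seed) : have_norm(false), cached(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double norm() {
    if (have_norm) { have_norm = false; return cached; }
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    cached = r * std::sin(th);
    have_norm = true;
    return r * std::cos(th);
  }
  inline int randint(int n) { return (int)(next() % (uint64_t)n); }
};

struct Pot {
  int type;          // 0 = hydration/vdW/steric, 1 = harmonic test hook
  bool steric, hard_wall;
  double A_zJ, lam, H, Ast_zJ, lamst, acut;  // dlvo
  double B_zJ, a0;                            // harmonic: (B/2)(a-a0)^2
  inline double phi(double a) const {
    if (hard_wall && a < 0.0) return INF_E;
    if (type == 1) { double d = a - a0; return 0.5 * B_zJ * d * d; }
    double v = A_zJ * lam * std::exp(-a / lam);
    // steric term is sub-angstrom ranged; beyond 50 decay lengths it is
    // below double precision relative to the hydration term
    if (steric && a < 50.0 * lamst) v += Ast_zJ * lamst * std::exp(-a / lamst);
    double ac = a < acut ? acut : a;
    return v - H / (12.0 * M_PI * ac * ac);
  }
};

static Pot parse_pot(const List& pot) {
  Pot p;
  std::string ty = as<std::string>(pot["type"]);
  p.type = (ty == "harmonic") ? 1 : 0;
  p.hard_wall = as<bool>(pot["hard_wall"]);
  p.A_zJ = as<double>(pot["A"]) * PA_A3_TO_ZJ;
  p.lam = as<double>(pot["lam"]);
  p.H = as<double>(pot["H"]);
  p.steric = as<bool>(pot["steric"]);
  p.Ast_zJ = as<double>(pot["A_st"]) * PA_A3_TO_ZJ;
  p.lamst = as<double>(pot["lam_st"]);
  p.acut = as<double>(pot["a_cut"]);
  p.B_zJ = as<double>(pot["B"]) * PA_A3_TO_ZJ;  // Pa/A -> zJ/A^4
  p.a0 = as<double>(pot["a0"]);
  return p;
}

// [[Rcpp::export]]
List cpp_run_stack(List cfg, List pot_in) {
  const int N = as<int>(cfg["N"]);
  const int M = as<int>(cfg["M"]);
  const double L = as<double>(cfg["L"]);
  const double Kc = as<double>(cfg["K_c"]);
  const double P = as<double>(cfg["P"]);
  const double T = as<double>(cfg["T"]);
  const int n_equil = as<int>(cfg["n_equil"]);
  const int n_collect = as<int>(cfg["n_collect"]);
  const int record_every = as<int>(cfg["record_every"]);
  const int adapt_every = as<int>(cfg["adapt_every"]);
  const double target_acc = as<double>(cfg["target_acc"]);
  const bool domc = as<std::string>(cfg["step_adapt"]) == "DOMC";
  const double abar0 = as<double>(cfg["abar0"]);
  const bool freeze_u = as<bool>(cfg["freeze_u"]);
  const bool fix_abar = as<bool>(cfg["fix_abar"]);
  const double hist_bin = as<double>(cfg["hist_bin"]);
  const double hist_max = as<double>(cfg["hist_max"]);
  const int bookkeep_every = as<int>(cfg["bookkeep_every"]);
  const uint64_t seed = (uint64_t)as<double>(cfg["seed"]);

  const Pot pot = parse_pot(pot_in);
  const int N2 = N * N;
  const double h = L / N, h2 = h * h, L2 = L * L;
  const double kT = KB_ZJ * T;
  const double P_zJ = P * PA_A3_TO_ZJ;

  Xoshiro rng(seed);

  // --- independent-mode enumeration ------------------------------------
  // Canonical representative (j,k) with linear index <= that of its
  // conjugate ((N-j)%N,(N-k)%N); self-conjugate modes carry one real dof.
  std::vector<int> jv, kv, cidv, idv;
  std::vector<char> pairv;
  std::vector<double> q4v;
  for (int j = 0; j < N; j++) {
    for (int k = 0; k < N; k++) {
      int id = j * N + k;
      int cj = (N - j) % N, ck = (N - k) % N;
      int cid = cj * N + ck;
      if (id > cid) continue;
      double q2 = (4.0 / h2) * (std::pow(std::sin(M_PI * j / N), 2) +
                                std::pow(std::sin(M_PI * k / N), 2));
      jv.push_back(j); kv.push_back(k); idv.push_back(id); cidv.push_back(cid);
      pairv.push_back(id < cid); q4v.push_back(q2 * q2);
    }
  }
  const int nmodes = (int)jv.size();

  // shells: modes grouped by q^4 value (step sizes adapted per shell)
  std::vector<double> uq;  // unique q4, ascending
  for (double q : q4v) {
    bool found = false;
    for (double v : uq) if (std::abs(v - q) <= 1e-9 * (1.0 + v)) { found = true; break; }
    if (!found) uq.push_back(q);
  }
  std::sort(uq.begin(), uq.end());
  const int nshell = (int)uq.size();
  std::vector<int> shellv(nmodes);
  for (int i = 0; i < nmodes; i++)
    for (int s = 0; s < nshell; s++)
      if (std::abs(uq[s] - q4v[i]) <= 1e-9 * (1.0 + uq[s])) { shellv[i] = s; break; }

  // 1-D phase tables: c1[j*N+x] = cos(2*pi*j*x/N)
  std::vector<double> c1(N * N), s1(N * N);
  for (int j = 0; j < N; j++)
    for (int x = 0; x < N; x++) {
      c1[j * N + x] = std::cos(2.0 * M_PI * j * x / N);
      s1[j * N + x] = std::sin(2.0 * M_PI * j * x / N);
    }

  // --- state ------------------------------------------------------------
  std::vector<std::vector<double> > u(M, std::vector<double>(N2, 0.0));
  std::vector<std::vector<double> > re(M, std::vector<double>(N2, 0.0));
  std::vector<std::vector<double> > im(M, std::vector<double>(N2, 0.0));
  std::vector<std::vector<double> > phi_cur(M, std::vector<double>(N2));
  double abar = abar0;

  auto gap = [&](int m, int s) { return u[(m + 1) % M][s] - u[m][s] + abar; };
  auto refresh_phi = [&]() {
    for (int m = 0; m < M; m++)
      for (int s = 0; s < N2; s++) phi_cur[m][s] = pot.phi(gap(m, s));
  };
  auto e_int_scratch = [&]() {
    double e = 0.0;
    for (int m = 0; m < M; m++)
      for (int s = 0; s < N2; s++) e += pot.phi(gap(m, s));
    return h2 * e;
  };
  auto S_scratch = [&]() {
    double S = 0.0;
    for (int m = 0; m < M; m++) {
      const double* rm = re[m].data();
      const double* imm = im[m].data();
      for (int i = 0; i < nmodes; i++) {
        int id = idv[i];
        double a2 = rm[id] * rm[id] + imm[id] * imm[id];
        S += (pairv[i] ? 2.0 : 1.0) * q4v[i] * a2;
      }
    }
    return 0.5 * L2 * S;
  };

  refresh_phi();
  double E_int = e_int_scratch();
  double S_bend = S_scratch();  // bending energy = Kc * S_bend

  // --- initial step sizes from a harmonic estimate ----------------------
  // curvature of the repulsive part of the potential at the start spacing
  double Beff;
  if (pot.type == 1) {
    Beff = pot.B_zJ;
  } else {
    Beff = pot.A_zJ / pot.lam * std::exp(-abar0 / pot.lam);
    if (pot.steric) Beff += pot.Ast_zJ / pot.lamst * std::exp(-abar0 / pot.lamst);
  }
  if (!(Beff > 1e-10)) Beff = 1e-10;
  std::vector<double> sig(nshell);
  for (int s = 0; s < nshell; s++)
    sig[s] = std::sqrt(kT / (L2 * (Kc * uq[s] + Beff)));
  double sig_abar = 0.05 * abar0 + 0.01;

  // --- proposal machinery ------------------------------------------------
  std::vector<double> dub(N2), pdb(N2), pub(N2);
  std::vector<double> phib;  // buffer for abar moves
  phib.resize(M * N2);

  std::vector<long> prop_shell(nshell, 0), acc_shell(nshell, 0);
  long prop_abar = 0, acc_abar_n = 0;
  long prop_mode_tot = 0, acc_mode_tot = 0;

  auto mode_proposal = [&]() {
    int mi = rng.randint(nmodes);
    int m = rng.randint(M);
    int sh = shellv[mi];
    bool pr = pairv[mi];
    double sg = sig[sh];
    double dr = sg * rng.norm();
    double di = pr ? sg * rng.norm() : 0.0;
    int id = idv[mi], cid = cidv[mi];
    int j = jv[mi], k = kv[mi];
    double re0 = re[m][id], im0 = im[m][id];
    double re1 = re0 + dr, im1 = im0 + di;
    double q4 = q4v[mi];
    double dS = pr ? L2 * q4 * ((re1 * re1 + im1 * im1) - (re0 * re0 + im0 * im0))
                   : 0.5 * L2 * q4 * (re1 * re1 - re0 * re0);
    int mm = (m + M - 1) % M, mp = (m + 1) % M;
    const double* um = u[m].data();
    const double* umm = u[mm].data();
    const double* ump = u[mp].data();
    const double* c1j = &c1[j * N];
    const double* s1j = &s1[j * N];
    const double* c1k = &c1[k * N];
    const double* s1k = &s1[k * N];
    double dphi = 0.0;
    bool bad = false;
    for (int x = 0; x < N && !bad; x++) {
      double cx = c1j[x], sx = s1j[x];
      for (int y = 0; y < N; y++) {
        double C = cx * c1k[y] - sx * s1k[y];
        double Sq = sx * c1k[y] + cx * s1k[y];
        double du = pr ? 2.0 * (dr * C - di * Sq) : dr * C;
        int s = x * N + y;
        dub[s] = du;
        double adn = um[s] - umm[s] + abar + du;   // gap below (index mm)
        double aun = ump[s] - um[s] + abar - du;   // gap above (index m)
        double pd = pot.phi(adn), pu = pot.phi(aun);
        if (pd == INF_E || pu == INF_E) { bad = true; break; }
        pdb[s] = pd; pub[s] = pu;
        dphi += pd - phi_cur[mm][s] + pu - phi_cur[m][s];
      }
    }
    prop_shell[sh]++; prop_mode_tot++;
    if (bad) return;
    double dE = Kc * dS + h2 * dphi;
    if (dE <= 0.0 || rng.unif() < std::exp(-dE / kT)) {
      for (int s = 0; s < N2; s++) {
        u[m][s] += dub[s];
        phi_cur[mm][s] = pdb[s];
        phi_cur[m][s] = pub[s];
      }
      re[m][id] = re1; im[m][id] = im1;
      if (pr) { re[m][cid] = re1; im[m][cid] = -im1; }
      E_int += h2 * dphi;
      S_bend += dS;
      acc_shell[sh]++; acc_mode_tot++;
    }
  };

  auto abar_proposal = [&]() {
    double da = (2.0 * rng.unif() - 1.0) * sig_abar;
    double dphi = 0.0;
    bool bad = false;
    for (int m = 0; m < M && !bad; m++) {
      for (int s = 0; s < N2; s++) {
        double an = gap(m, s) + da;
        double pn = pot.phi(an);
        if (pn == INF_E) { bad = true; break; }
        phib[m * N2 + s] = pn;
        dphi += pn - phi_cur[m][s];
      }
    }
    prop_abar++;
    if (bad) return;
    double dE = h2 * dphi + P_zJ * M * L2 * da;
    if (dE <= 0.0 || rng.unif() < std::exp(-dE / kT)) {
      abar += da;
      for (int m = 0; m < M; m++)
        for (int s = 0; s < N2; s++) phi_cur[m][s] = phib[m * N2 + s];
      E_int += h2 * dphi;
      acc_abar_n++;
    }
  };

  auto recenter = [&]() {
    double c = 0.0;
    for (int m = 0; m < M; m++) c += re[m][0];
    c /= M;
    if (c == 0.0) return;
    for (int m = 0; m < M; m++) {
      re[m][0] -= c;
      for (int s = 0; s < N2; s++) u[m][s] -= c;
    }
  };

  const int n_mode_prop = freeze_u ? 0 : N2 * M;
  double book_dev_eint = 0.0, book_dev_bend = 0.0;

  auto bookkeep = [&]() {
    double e2 = e_int_scratch();
    double S2 = S_scratch();
    double d1 = std::abs(E_int - e2) / std::max(std::abs(e2), 1e-9);
    double d2 = std::abs(S_bend - S2) / std::max(std::abs(S2), 1e-12);
    if (d1 > book_dev_eint) book_dev_eint = d1;
    if (d2 > book_dev_bend) book_dev_bend = d2;
    E_int = e2; S_bend = S2;
    refresh_phi();
  };

  // DOMC: step size per shell tied to the running RMS mode amplitude in
  // the shell, with a global prefactor steered by the acceptance rate.
  double domc_c = 1.0;
  std::vector<double> shell_ms(nshell, 0.0);
  std::vector<long> shell_cnt(nshell, 0);

  auto adapt = [&]() {
    if (domc) {
      // accumulate |u(q)|^2 per shell from the instantaneous state
      for (int m = 0; m < M; m++)
        for (int i = 0; i < nmodes; i++) {
          int s = shellv[i], id = idv[i];
          shell_ms[s] += re[m][id] * re[m][id] + im[m][id] * im[m][id];
          shell_cnt[s]++;
        }
      long pt = 0, at = 0;
      for (int s = 0; s < nshell; s++) { pt += prop_shell[s]; at += acc_shell[s]; }
      if (pt > 0) {
        double f = (double)at / pt / target_acc;
        f = std::min(2.0, std::max(0.5, f));
        domc_c *= f;
      }
      for (int s = 0; s < nshell; s++) {
        if (shell_cnt[s] > 0) {
          double rms = std::sqrt(shell_ms[s] / shell_cnt[s]);
          if (rms > 1e-8) sig[s] = domc_c * rms;
        }
      }
    } else {
      // ARM: multiply each shell step by (acceptance / target), clipped
      for (int s = 0; s < nshell; s++) {
        if (prop_shell[s] == 0) continue;
        double f = (double)acc_shell[s] / prop_shell[s] / target_acc;
        f = std::min(2.0, std::max(0.5, f));
        sig[s] *= f;
      }
    }
    for (int s = 0; s < nshell; s++) {
      sig[s] = std::min(sig[s], L);
      sig[s] = std::max(sig[s], 1e-7);
      prop_shell[s] = 0; acc_shell[s] = 0;
    }
    if (!fix_abar && prop_abar > 0) {
      double f = (double)acc_abar_n / prop_abar / target_acc;
      f = std::min(2.0, std::max(0.5, f));
      sig_abar = std::min(std::max(sig_abar * f, 1e-7), 0.5 * abar0 + 1.0);
      prop_abar = 0; acc_abar_n = 0;
    }
  };

  // --- equilibration -----------------------------------------------------
  for (int t = 0; t < n_equil; t++) {
    for (int i = 0; i < n_mode_prop; i++) mode_proposal();
    if (!fix_abar) abar_proposal();
    recenter();
    if ((t + 1) % adapt_every == 0) adapt();
    if ((t + 1) % bookkeep_every == 0) bookkeep();
  }

  // --- collection (steps frozen so detailed balance holds) ---------------
  for (int s = 0; s < nshell; s++) { prop_shell[s] = 0; acc_shell[s] = 0; }
  prop_abar = 0; acc_abar_n = 0; prop_mode_tot = 0; acc_mode_tot = 0;

  const int nsamp = n_collect / record_every;
  const int nbins = (int)std::ceil(hist_max / hist_bin);
  NumericVector abar_s(nsamp), s2_s(nsamp), sbend_s(nsamp), etot_s(nsamp);
  IntegerMatrix hist(nbins, nsamp);
  int isamp = 0;

  for (int t = 0; t < n_collect; t++) {
    for (int i = 0; i < n_mode_prop; i++) mode_proposal();
    if (!fix_abar) abar_proposal();
    recenter();
    if ((t + 1) % bookkeep_every == 0) bookkeep();
    if ((t + 1) % record_every == 0 && isamp < nsamp) {
      double s2 = 0.0;
      int* hc = &hist(0, isamp);
      for (int m = 0; m < M; m++)
        for (int s = 0; s < N2; s++) {
          double a = gap(m, s);
          s2 += a * a;
          int b = (int)(a / hist_bin);
          if (b >= nbins) b = nbins - 1;
          if (b < 0) b = 0;
          hc[b]++;
        }
      s2 /= (double)(M * N2);
      abar_s[isamp] = abar;
      s2_s[isamp] = s2;
      sbend_s[isamp] = S_bend;
      etot_s[isamp] = Kc * S_bend + E_int + P_zJ * M * L2 * abar;
      isamp++;
    }
  }

  double acc_mode = prop_mode_tot > 0 ? (double)acc_mode_tot / prop_mode_tot : NA_REAL;
  double acc_ab = prop_abar > 0 ? (double)acc_abar_n / prop_abar : NA_REAL;

  NumericMatrix u_out(M, N2);
  for (int m = 0; m < M; m++)
    for (int s = 0; s < N2; s++) u_out(m, s) = u[m][s];

  return List::create(
    _["abar"] = abar_s, _["s2"] = s2_s, _["sbend"] = sbend_s,
    _["etot"] = etot_s, _["hist"] = hist,
    _["acc_mode"] = acc_mode, _["acc_abar"] = acc_ab,
    _["book_dev_eint"] = book_dev_eint, _["book_dev_bend"] = book_dev_bend,
    _["final_u"] = u_out, _["final_abar"] = abar,
    _["sig_shells"] = NumericVector(sig.begin(), sig.end()),
    _["sig_abar"] = sig_abar, _["n_modes"] = nmodes);
}

// Total energy of an explicit configuration, with the bending term
// evaluated in real space through the 5-point discrete Laplacian (whose
// eigenvalues are exactly the q-hat^2 used in the spectral updates).
// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix u, double abar, double L, double Kc,
                        double P, List pot_in) {
  const Pot pot = parse_pot(pot_in);
  const int M = u.nrow();
  const int N2 = u.ncol();
  const int N = (int)std::lround(std::sqrt((double)N2));
  if (N * N != N2) stop("u must have N^2 columns");
  const double h = L / N, h2 = h * h;

  double e_bend = 0.0;
  for (int m = 0; m < M; m++) {
    for (int x = 0; x < N; x++) {
      int xp = (x + 1) % N, xm = (x + N - 1) % N;
      for (int y = 0; y < N; y++) {
        int yp = (y + 1) % N, ym = (y + N - 1) % N;
        double lap = (u(m, xp * N + y) + u(m, xm * N + y) +
                      u(m, x * N + yp) + u(m, x * N + ym) -
                      4.0 * u(m, x * N + y)) / h2;
        e_bend += lap * lap;
      }
    }
  }
  e_bend *= 0.5 * Kc * h2;

  double e_int = 0.0;
  for (int m = 0; m < M; m++) {
    int mp = (m + 1) % M;
    for (int s = 0; s < N2; s++) {
      double a = u(mp, s) - u(m, s) + abar;
      double ph = pot.phi(a);
      if (ph == INF_E) return R_PosInf;
      e_int += ph;
    }
  }
  e_int *= h2;

  return e_bend + e_int + P * PA_A3_TO_ZJ * M * L * L * abar;
}
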