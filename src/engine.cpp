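// Coarse-grained Go-model engine: potential energy, analytic forces,
// BAOAB Langevin integration and temperature replica exchange.
//
// Units: length A, energy kcal/mol, mass Da, temperature K.
// Internal time unit tau = sqrt(Da * A^2 / (kcal/mol)) = 48.8882 fs;
// dt is passed in fs and friction in ps^-1 and converted at the interface.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double KB = 0.0019872041;     // kcal/mol/K
static const double TIME_UNIT_FS = 48.8882;

// ---------------------------------------------------------------------------
// deterministic RNG: xoshiro-free, plain 64-bit splitmix + Box-Muller normals
// (self-contained so trajectories are bit-reproducible for a given seed)
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; i++) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
    have_spare = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() { // xoshiro256**
    uint64_t r = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare; double spare;
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a); have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
struct System {
  int n = 0;                       // mobile beads
  std::vector<double> mass, radius;
  // bonds
  std::vector<int> bi, bj; std::vector<double> bk, br0;
  // angles (i-j-k, j vertex)
  std::vector<int> ai, aj, ak; std::vector<double> akf, ath0;
  // dihedrals
  std::vector<int> di, dj, dk, dl; std::vector<double> dk1, dk2, dphi0;
  // native contacts
  std::vector<int> ci, cj; std::vector<double> ceps, csig;
  double lambda = 1.0;
  // pair classification: 0 repulsive, 1 excluded, 2.. = 2+contact index
  std::vector<int> pcls;
  // scaffold
  std::vector<double> sx, sy, sz, srad;
  // scaffold cell grid
  double cell = 8.0; int ngx = 0, ngy = 0, ngz = 0;
  double ox = 0, oy = 0, oz = 0;
  std::vector<std::vector<int>> grid;
  // params
  double eps_rep = 1.0, k_teth = 10.0;
  double rep_cut_factor = 2.5;     // repulsion cutoff = factor * sigma_pair
  double contact_cut = 12.0;       // native-contact cutoff (A)
  bool tether_on = false;
  double axx = 0, axy = 0, axz = 0; // anchor
  bool use_grid = true;

  inline int pair_id(int i, int j) const { return i * n + j; }

  void build_grid() {
    grid.clear();
    int ns = (int)sx.size();
    if (ns == 0) { use_grid = false; return; }
    double maxrad = 0;
    for (int k = 0; k < ns; k++) maxrad = std::max(maxrad, srad[k]);
    // worst-case pair cutoff: factor * (max chain radius + max scaffold radius)
    double maxcr = 0;
    for (int i = 0; i < n; i++) maxcr = std::max(maxcr, radius[i]);
    cell = rep_cut_factor * (maxcr + maxrad);
    double lx = 1e30, ly = 1e30, lz = 1e30, hx = -1e30, hy = -1e30, hz = -1e30;
    for (int k = 0; k < ns; k++) {
      lx = std::min(lx, sx[k]); hx = std::max(hx, sx[k]);
      ly = std::min(ly, sy[k]); hy = std::max(hy, sy[k]);
      lz = std::min(lz, sz[k]); hz = std::max(hz, sz[k]);
    }
    ox = lx; oy = ly; oz = lz;
    ngx = (int)((hx - lx) / cell) + 1;
    ngy = (int)((hy - ly) / cell) + 1;
    ngz = (int)((hz - lz) / cell) + 1;
    grid.assign((size_t)ngx * ngy * ngz, {});
    for (int k = 0; k < ns; k++) {
      int gx = (int)((sx[k] - ox) / cell);
      int gy = (int)((sy[k] - oy) / cell);
      int gz = (int)((sz[k] - oz) / cell);
      grid[(size_t)(gx * ngy + gy) * ngz + gz].push_back(k);
    }
    use_grid = true;
  }
};

enum Term { BOND = 0, ANGLE, DIHEDRAL, CONTACT, REP, SCAFFOLD, TETHER, NTERM };

// full energy + (optionally) forces; returns per-term energies in `terms`
static void compute(const System& S, const std::vector<double>& x,
                    std::vector<double>* f, double terms[NTERM]) {
  const int n = S.n;
  for (int t = 0; t < NTERM; t++) terms[t] = 0.0;
  if (f) std::fill(f->begin(), f->end(), 0.0);

  auto addf = [&](int i, double fx, double fy, double fz) {
    (*f)[3 * i] += fx; (*f)[3 * i + 1] += fy; (*f)[3 * i + 2] += fz;
  };

  // bonds
  for (size_t b = 0; b < S.bi.size(); b++) {
    int i = S.bi[b], j = S.bj[b];
    double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < 1e-6) stop("singular geometry: bonded beads overlap");
    double dr = r - S.br0[b];
    terms[BOND] += 0.5 * S.bk[b] * dr * dr;
    if (f) {
      double c = -S.bk[b] * dr / r;
      addf(i,  c*dx,  c*dy,  c*dz);
      addf(j, -c*dx, -c*dy, -c*dz);
    }
  }

  // angles: harmonic in theta up to THETA_C, then continued smoothly as a
  // linear function of cos(theta) (value- and slope-matched), so the
  // force stays bounded and exactly conservative at collinear geometry
  // (the plain harmonic force carries a divergent 1/sin(theta) factor).
  static const double THETA_C = 2.8; // ~160 degrees
  for (size_t a = 0; a < S.ai.size(); a++) {
    int i = S.ai[a], j = S.aj[a], k = S.ak[a];
    double ux = x[3*i]-x[3*j], uy = x[3*i+1]-x[3*j+1], uz = x[3*i+2]-x[3*j+2];
    double vx = x[3*k]-x[3*j], vy = x[3*k+1]-x[3*j+1], vz = x[3*k+2]-x[3*j+2];
    double ru = std::sqrt(ux*ux + uy*uy + uz*uz);
    double rv = std::sqrt(vx*vx + vy*vy + vz*vz);
    double c = (ux*vx + uy*vy + uz*vz) / (ru * rv);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double kf = S.akf[a], th0 = S.ath0[a];
    static const double THETA_L = 0.5; // ~29 degrees, same guard at theta=0
    double dVdth_over_s;  // (dV/dtheta) / sin(theta), always finite
    if (th < THETA_L) {
      double sl = std::sin(THETA_L), cl = std::cos(THETA_L);
      double b1 = kf * (THETA_L - th0) / sl;
      double a1 = 0.5 * kf * (THETA_L - th0) * (THETA_L - th0) -
                  b1 * (1.0 - cl);
      terms[ANGLE] += a1 + b1 * (1.0 - c);
      dVdth_over_s = b1;    // dU3/dtheta = b1*sin(theta)
    } else if (th <= THETA_C) {
      double dth = th - th0;
      terms[ANGLE] += 0.5 * kf * dth * dth;
      double s = std::max(1e-8, std::sqrt(std::max(0.0, 1.0 - c * c)));
      dVdth_over_s = kf * dth / s;
    } else {
      // U2 = a0 + b0*(1 + cos th); match value and slope at THETA_C
      double sc = std::sin(THETA_C), cc = std::cos(THETA_C);
      double b0 = -kf * (THETA_C - th0) / sc;
      double a0 = 0.5 * kf * (THETA_C - th0) * (THETA_C - th0) -
                  b0 * (1.0 + cc);
      terms[ANGLE] += a0 + b0 * (1.0 + c);
      dVdth_over_s = -b0;   // dU2/dtheta = -b0*sin(theta)
    }
    if (f) {
      double uxh = ux/ru, uyh = uy/ru, uzh = uz/ru;
      double vxh = vx/rv, vyh = vy/rv, vzh = vz/rv;
      double fix = dVdth_over_s * (vxh - c*uxh) / ru;
      double fiy = dVdth_over_s * (vyh - c*uyh) / ru;
      double fiz = dVdth_over_s * (vzh - c*uzh) / ru;
      double fkx = dVdth_over_s * (uxh - c*vxh) / rv;
      double fky = dVdth_over_s * (uyh - c*vyh) / rv;
      double fkz = dVdth_over_s * (uzh - c*vzh) / rv;
      addf(i, fix, fiy, fiz);
      addf(k, fkx, fky, fkz);
      addf(j, -fix - fkx, -fiy - fky, -fiz - fkz);
    }
  }

  // dihedrals: V = k1[1-cos(phi-phi0)] + k2[1-cos 3(phi-phi0)]
  for (size_t d = 0; d < S.di.size(); d++) {
    int i = S.di[d], j = S.dj[d], k = S.dk[d], l = S.dl[d];
    double b1x = x[3*j]-x[3*i], b1y = x[3*j+1]-x[3*i+1], b1z = x[3*j+2]-x[3*i+2];
    double b2x = x[3*k]-x[3*j], b2y = x[3*k+1]-x[3*j+1], b2z = x[3*k+2]-x[3*j+2];
    double b3x = x[3*l]-x[3*k], b3y = x[3*l+1]-x[3*k+1], b3z = x[3*l+2]-x[3*k+2];
    double mx = b1y*b2z - b1z*b2y, my = b1z*b2x - b1x*b2z, mz = b1x*b2y - b1y*b2x;
    double nx = b2y*b3z - b2z*b3y, ny = b2z*b3x - b2x*b3z, nz = b2x*b3y - b2y*b3x;
    double m2 = mx*mx + my*my + mz*mz;
    double n2 = nx*nx + ny*ny + nz*nz;
    double rb2 = std::sqrt(b2x*b2x + b2y*b2y + b2z*b2z);
    double b12sq = b1x*b1x + b1y*b1y + b1z*b1z;
    double b22sq = rb2 * rb2;
    double b32sq = b3x*b3x + b3y*b3y + b3z*b3z;
    // near-collinear bond angles make the torsion ill-conditioned; skip it
    if (m2 < 1e-4 * b12sq * b22sq || n2 < 1e-4 * b22sq * b32sq) continue;
    double cphi = (mx*nx + my*ny + mz*nz) / std::sqrt(m2 * n2);
    cphi = std::max(-1.0, std::min(1.0, cphi));
    double sphi = (mx*b3x + my*b3y + mz*b3z) * rb2 / std::sqrt(m2 * n2);
    double phi = std::atan2(sphi, cphi);
    double dphi = phi - S.dphi0[d];
    terms[DIHEDRAL] += S.dk1[d] * (1.0 - std::cos(dphi)) +
                       S.dk2[d] * (1.0 - std::cos(3.0 * dphi));
    if (f) {
      double dV = S.dk1[d] * std::sin(dphi) + 3.0 * S.dk2[d] * std::sin(3.0 * dphi);
      // standard torsion force decomposition
      // dphi/dp1 = -(|b2|/|m|^2) m ; dphi/dp4 = +(|b2|/|n|^2) n
      double f1s =  dV * rb2 / m2;
      double f4s = -dV * rb2 / n2;
      double F1x = f1s*mx, F1y = f1s*my, F1z = f1s*mz;
      double F4x = f4s*nx, F4y = f4s*ny, F4z = f4s*nz;
      double b12 = (b1x*b2x + b1y*b2y + b1z*b2z) / (rb2 * rb2);
      double b32 = (b3x*b2x + b3y*b2y + b3z*b2z) / (rb2 * rb2);
      double F2x = -(1.0 + b12)*F1x + b32*F4x;
      double F2y = -(1.0 + b12)*F1y + b32*F4y;
      double F2z = -(1.0 + b12)*F1z + b32*F4z;
      double F3x = b12*F1x - (1.0 + b32)*F4x;
      double F3y = b12*F1y - (1.0 + b32)*F4y;
      double F3z = b12*F1z - (1.0 + b32)*F4z;
      addf(i, F1x, F1y, F1z);
      addf(j, F2x, F2y, F2z);
      addf(k, F3x, F3y, F3z);
      addf(l, F4x, F4y, F4z);
    }
  }

  // chain-chain nonbonded: native 12-10 contacts and generic repulsion
  double cc2 = S.contact_cut * S.contact_cut;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      int cls = S.pcls[S.pair_id(i, j)];
      if (cls == 1) continue; // excluded (bonded/angle neighbours)
      double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (cls >= 2) {
        if (r2 > cc2) continue;
        if (r2 < 1e-12) stop("singular geometry: contact beads overlap");
        int c = cls - 2;
        double sig2 = S.csig[c] * S.csig[c];
        double s2 = sig2 / r2;
        double s10 = s2 * s2 * s2 * s2 * s2;
        double s12 = s10 * s2;
        double de = S.lambda * S.ceps[c];
        terms[CONTACT] += de * (5.0 * s12 - 6.0 * s10);
        if (f) {
          // dV/dr = de * (-60 s12 + 60 s10)/r ; F = -dV/dr * rhat
          double g = de * 60.0 * (s12 - s10) / r2; // = -dV/dr / r
          addf(i,  g*dx,  g*dy,  g*dz);
          addf(j, -g*dx, -g*dy, -g*dz);
        }
      } else {
        double sig = S.radius[i] + S.radius[j];
        double cut = S.rep_cut_factor * sig;
        if (r2 > cut * cut) continue;
        if (r2 < 1e-12) stop("singular geometry: beads overlap");
        double s2 = sig * sig / r2;
        double s12 = s2 * s2 * s2; s12 = s12 * s12;
        terms[REP] += S.eps_rep * s12;
        if (f) {
          double g = S.eps_rep * 12.0 * s12 / r2;
          addf(i,  g*dx,  g*dy,  g*dz);
          addf(j, -g*dx, -g*dy, -g*dz);
        }
      }
    }
  }

  // chain-scaffold repulsion (scaffold static; no force on scaffold beads)
  int ns = (int)S.sx.size();
  if (ns > 0) {
    for (int i = 0; i < n; i++) {
      double xi = x[3*i], yi = x[3*i+1], zi = x[3*i+2];
      auto pair_term = [&](int k) {
        double dx = xi - S.sx[k], dy = yi - S.sy[k], dz = zi - S.sz[k];
        double sig = S.radius[i] + S.srad[k];
        double cut = S.rep_cut_factor * sig;
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 > cut * cut) return;
        if (r2 < 1e-12) stop("singular geometry: bead inside scaffold bead");
        double s2 = sig * sig / r2;
        double s12 = s2 * s2 * s2; s12 = s12 * s12;
        terms[SCAFFOLD] += S.eps_rep * s12;
        if (f) {
          double g = S.eps_rep * 12.0 * s12 / r2;
          addf(i, g*dx, g*dy, g*dz);
        }
      };
      if (S.use_grid) {
        int gx = (int)std::floor((xi - S.ox) / S.cell);
        int gy = (int)std::floor((yi - S.oy) / S.cell);
        int gz = (int)std::floor((zi - S.oz) / S.cell);
        for (int ax = gx - 1; ax <= gx + 1; ax++) {
          if (ax < 0 || ax >= S.ngx) continue;
          for (int ay = gy - 1; ay <= gy + 1; ay++) {
            if (ay < 0 || ay >= S.ngy) continue;
            for (int az = gz - 1; az <= gz + 1; az++) {
              if (az < 0 || az >= S.ngz) continue;
              const std::vector<int>& cellv =
                S.grid[(size_t)(ax * S.ngy + ay) * S.ngz + az];
              for (int k : cellv) pair_term(k);
            }
          }
        }
      } else {
        for (int k = 0; k < ns; k++) pair_term(k);
      }
    }
  }

  // tether: harmonic restraint of the last bead to the anchor
  if (S.tether_on) {
    int i = n - 1;
    double dx = x[3*i] - S.axx, dy = x[3*i+1] - S.axy, dz = x[3*i+2] - S.axz;
    terms[TETHER] += 0.5 * S.k_teth * (dx*dx + dy*dy + dz*dz);
    if (f) addf(i, -S.k_teth * dx, -S.k_teth * dy, -S.k_teth * dz);
  }
}

// ---------------------------------------------------------------------------
static System build_system(List topo, List scaffold, List params, int n,
                           NumericVector mass, NumericVector radius) {
  System S;
  S.n = n;
  S.mass.assign(mass.begin(), mass.end());
  S.radius.assign(radius.begin(), radius.end());

  NumericMatrix B = topo["bonds"];
  for (int b = 0; b < B.nrow(); b++) {
    S.bi.push_back((int)B(b,0) - 1); S.bj.push_back((int)B(b,1) - 1);
    S.bk.push_back(B(b,2)); S.br0.push_back(B(b,3));
  }
  NumericMatrix A = topo["angles"];
  for (int a = 0; a < A.nrow(); a++) {
    S.ai.push_back((int)A(a,0) - 1); S.aj.push_back((int)A(a,1) - 1);
    S.ak.push_back((int)A(a,2) - 1);
    S.akf.push_back(A(a,3)); S.ath0.push_back(A(a,4));
  }
  NumericMatrix D = topo["dihedrals"];
  for (int d = 0; d < D.nrow(); d++) {
    S.di.push_back((int)D(d,0) - 1); S.dj.push_back((int)D(d,1) - 1);
    S.dk.push_back((int)D(d,2) - 1); S.dl.push_back((int)D(d,3) - 1);
    S.dk1.push_back(D(d,4)); S.dk2.push_back(D(d,5)); S.dphi0.push_back(D(d,6));
  }
  NumericMatrix C = topo["contacts"];
  for (int c = 0; c < C.nrow(); c++) {
    S.ci.push_back((int)C(c,0) - 1); S.cj.push_back((int)C(c,1) - 1);
    S.ceps.push_back(C(c,2)); S.csig.push_back(C(c,3));
  }
  S.lambda = as<double>(topo["lambda"]);

  // pair classification
  S.pcls.assign((size_t)n * n, 0);
  for (size_t b = 0; b < S.bi.size(); b++) {
    S.pcls[S.pair_id(std::min(S.bi[b], S.bj[b]), std::max(S.bi[b], S.bj[b]))] = 1;
  }
  for (size_t a = 0; a < S.ai.size(); a++) {
    S.pcls[S.pair_id(std::min(S.ai[a], S.ak[a]), std::max(S.ai[a], S.ak[a]))] = 1;
  }
  for (size_t c = 0; c < S.ci.size(); c++) {
    int i = std::min(S.ci[c], S.cj[c]), j = std::max(S.ci[c], S.cj[c]);
    S.pcls[S.pair_id(i, j)] = 2 + (int)c;
  }

  if (scaffold.size() > 0 && scaffold.containsElementNamed("xyz")) {
    NumericMatrix SX = scaffold["xyz"];
    NumericVector SR = scaffold["radius"];
    for (int k = 0; k < SX.nrow(); k++) {
      S.sx.push_back(SX(k,0)); S.sy.push_back(SX(k,1)); S.sz.push_back(SX(k,2));
      S.srad.push_back(SR[k]);
    }
  }

  S.eps_rep = as<double>(params["eps_rep"]);
  S.k_teth = as<double>(params["k_tether"]);
  S.rep_cut_factor = as<double>(params["rep_cut_factor"]);
  S.contact_cut = as<double>(params["contact_cutoff"]);
  S.tether_on = as<bool>(params["tether_on"]);
  if (S.tether_on) {
    NumericVector anc = params["anchor"];
    S.axx = anc[0]; S.axy = anc[1]; S.axz = anc[2];
  }
  S.build_grid();
  return S;
}

static const char* TERM_NAMES[NTERM] = {
  "bond", "angle", "dihedral", "contact", "repulsion", "scaffold", "tether"
};

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix xyz, List topo, List scaffold,
                         List params, NumericVector mass, NumericVector radius) {
  int n = xyz.nrow();
  System S = build_system(topo, scaffold, params, n, mass, radius);
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; i++) {
    x[3*i] = xyz(i,0); x[3*i+1] = xyz(i,1); x[3*i+2] = xyz(i,2);
  }
  double terms[NTERM];
  compute(S, x, nullptr, terms);
  NumericVector out(NTERM + 1);
  CharacterVector nm(NTERM + 1);
  double tot = 0;
  for (int t = 0; t < NTERM; t++) { out[t] = terms[t]; nm[t] = TERM_NAMES[t]; tot += terms[t]; }
  out[NTERM] = tot; nm[NTERM] = "total";
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix xyz, List topo, List scaffold,
                         List params, NumericVector mass, NumericVector radius) {
  int n = xyz.nrow();
  System S = build_system(topo, scaffold, params, n, mass, radius);
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; i++) {
    x[3*i] = xyz(i,0); x[3*i+1] = xyz(i,1); x[3*i+2] = xyz(i,2);
  }
  double terms[NTERM];
  compute(S, x, &f, terms);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) {
    out(i,0) = f[3*i]; out(i,1) = f[3*i+1]; out(i,2) = f[3*i+2];
  }
  return out;
}

// ---------------------------------------------------------------------------
struct Replica {
  std::vector<double> x, v, f;
  double T = 300, epot = 0;
};

static void baoab_steps(const System& S, Replica& R, int nsteps, double dt,
                        double gamma, Rng& rng, double terms[NTERM]) {
  int n = S.n;
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  double kT = KB * R.T;
  for (int s = 0; s < nsteps; s++) {
    for (int i = 0; i < n; i++) {
      double im = 0.5 * dt / S.mass[i];
      R.v[3*i]   += im * R.f[3*i];
      R.v[3*i+1] += im * R.f[3*i+1];
      R.v[3*i+2] += im * R.f[3*i+2];
      R.x[3*i]   += 0.5 * dt * R.v[3*i];
      R.x[3*i+1] += 0.5 * dt * R.v[3*i+1];
      R.x[3*i+2] += 0.5 * dt * R.v[3*i+2];
    }
    if (gamma > 0 && R.T > 0) {
      for (int i = 0; i < n; i++) {
        double sd = c2 * std::sqrt(kT / S.mass[i]);
        R.v[3*i]   = c1 * R.v[3*i]   + sd * rng.norm();
        R.v[3*i+1] = c1 * R.v[3*i+1] + sd * rng.norm();
        R.v[3*i+2] = c1 * R.v[3*i+2] + sd * rng.norm();
      }
    } else if (gamma > 0) { // T = 0: pure damping
      for (int i = 0; i < 3 * n; i++) R.v[i] *= c1;
    }
    for (int i = 0; i < 3 * n; i++) R.x[i] += 0.5 * dt * R.v[i];
    compute(S, R.x, &R.f, terms);
    for (int i = 0; i < n; i++) {
      double im = 0.5 * dt / S.mass[i];
      R.v[3*i]   += im * R.f[3*i];
      R.v[3*i+1] += im * R.f[3*i+1];
      R.v[3*i+2] += im * R.f[3*i+2];
    }
  }
  double tot = 0;
  for (int t = 0; t < NTERM; t++) tot += terms[t];
  R.epot = tot;
  if (!std::isfinite(tot) || tot > 1e8)
    stop("dynamics blow-up: potential energy %.3g kcal/mol (reduce dt)", tot);
}

static void init_velocities(const System& S, Replica& R, Rng& rng) {
  for (int i = 0; i < S.n; i++) {
    double sd = (R.T > 0) ? std::sqrt(KB * R.T / S.mass[i]) : 0.0;
    R.v[3*i] = sd * rng.norm();
    R.v[3*i+1] = sd * rng.norm();
    R.v[3*i+2] = sd * rng.norm();
  }
}

// Langevin dynamics at a single temperature.
// Returns frames (n x 3 x nframe), per-frame energies, final state.
// [[Rcpp::export]]
List cpp_langevin(NumericMatrix xyz, List topo, List scaffold, List params,
                  NumericVector mass, NumericVector radius,
                  double temperature, int steps, double dt_fs,
                  double friction_ps, int seed, int n_save) {
  int n = xyz.nrow();
  System S = build_system(topo, scaffold, params, n, mass, radius);
  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  Replica R;
  R.T = temperature;
  R.x.resize(3 * n); R.v.assign(3 * n, 0.0); R.f.assign(3 * n, 0.0);
  for (int i = 0; i < n; i++) {
    R.x[3*i] = xyz(i,0); R.x[3*i+1] = xyz(i,1); R.x[3*i+2] = xyz(i,2);
  }
  double dt = dt_fs / TIME_UNIT_FS;
  double gamma = friction_ps * (TIME_UNIT_FS / 1000.0);
  double terms[NTERM];
  compute(S, R.x, &R.f, terms);
  double e0 = 0; for (int t = 0; t < NTERM; t++) e0 += terms[t];
  R.epot = e0;
  init_velocities(S, R, rng);

  int nframe = steps / n_save + 1; // frame 0 = initial
  NumericVector frames(Dimension(n, 3, nframe));
  NumericVector energies(nframe);
  int fi = 0;
  auto save_frame = [&]() {
    for (int i = 0; i < n; i++) {
      frames[i + (size_t)n * 0 + (size_t)3 * n * fi] = R.x[3*i];
      frames[i + (size_t)n * 1 + (size_t)3 * n * fi] = R.x[3*i+1];
      frames[i + (size_t)n * 2 + (size_t)3 * n * fi] = R.x[3*i+2];
    }
    energies[fi] = R.epot;
    fi++;
  };
  save_frame();
  int done = 0;
  while (done < steps) {
    int chunk = std::min(n_save, steps - done);
    baoab_steps(S, R, chunk, dt, gamma, rng, terms);
    done += chunk;
    if (done % n_save == 0) save_frame();
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; i++) {
    xf(i,0) = R.x[3*i]; xf(i,1) = R.x[3*i+1]; xf(i,2) = R.x[3*i+2];
    vf(i,0) = R.v[3*i]; vf(i,1) = R.v[3*i+1]; vf(i,2) = R.v[3*i+2];
  }
  return List::create(_["frames"] = frames, _["energies"] = energies,
                      _["final_xyz"] = xf, _["final_vel"] = vf);
}

// Temperature replica exchange with neighbour swaps.
// save_rung: 1-based rung indices whose frames are stored (others discarded).
// [[Rcpp::export]]
List cpp_replica_exchange(NumericMatrix xyz, List topo, List scaffold,
                          List params, NumericVector mass, NumericVector radius,
                          NumericVector ladder, int steps, int swap_interval,
                          double dt_fs, double friction_ps, int seed,
                          int n_save, IntegerVector save_rung,
                          NumericMatrix xyz_alt, IntegerVector alt_rung) {
  int n = xyz.nrow();
  int nrep = ladder.size();
  System S = build_system(topo, scaffold, params, n, mass, radius);
  Rng rng((uint64_t)seed * 2654435761ULL + 17ULL);
  double dt = dt_fs / TIME_UNIT_FS;
  double gamma = friction_ps * (TIME_UNIT_FS / 1000.0);

  std::vector<bool> alt(nrep, false);
  for (int k = 0; k < alt_rung.size(); k++) alt[alt_rung[k] - 1] = true;

  std::vector<Replica> reps(nrep);
  double terms[NTERM];
  for (int r = 0; r < nrep; r++) {
    Replica& R = reps[r];
    R.T = ladder[r];
    R.x.resize(3 * n); R.v.assign(3 * n, 0.0); R.f.assign(3 * n, 0.0);
    const NumericMatrix& X0 = (alt[r] && xyz_alt.nrow() == n) ? xyz_alt : xyz;
    for (int i = 0; i < n; i++) {
      R.x[3*i] = X0(i,0); R.x[3*i+1] = X0(i,1); R.x[3*i+2] = X0(i,2);
    }
    compute(S, R.x, &R.f, terms);
    double e = 0; for (int t = 0; t < NTERM; t++) e += terms[t];
    R.epot = e;
    init_velocities(S, R, rng);
  }

  std::vector<bool> keep(nrep, false);
  for (int k = 0; k < save_rung.size(); k++) keep[save_rung[k] - 1] = true;

  // frames are saved every n_save steps, aligned to swap cycles
  int nframe_max = steps / n_save + 1;
  std::vector<NumericVector> frames;
  std::vector<NumericVector> energies;
  for (int r = 0; r < nrep; r++) {
    frames.push_back(keep[r] ? NumericVector(Dimension(n, 3, nframe_max))
                             : NumericVector(0));
    energies.push_back(NumericVector(nframe_max));
  }
  int fi = 0;
  auto save_frames = [&]() {
    for (int r = 0; r < nrep; r++) {
      energies[r][fi] = reps[r].epot;
      if (!keep[r]) continue;
      for (int i = 0; i < n; i++) {
        frames[r][i + (size_t)n * 0 + (size_t)3 * n * fi] = reps[r].x[3*i];
        frames[r][i + (size_t)n * 1 + (size_t)3 * n * fi] = reps[r].x[3*i+1];
        frames[r][i + (size_t)n * 2 + (size_t)3 * n * fi] = reps[r].x[3*i+2];
      }
    }
    fi++;
  };
  save_frames();

  std::vector<int> sw_step, sw_i, sw_acc; std::vector<double> sw_delta;
  int done = 0, cycle = 0, next_save = n_save, next_swap = swap_interval;
  while (done < steps) {
    int target = std::min(steps, std::min(next_save, next_swap));
    int chunk = target - done;
    if (chunk > 0) {
      for (int r = 0; r < nrep; r++) {
        baoab_steps(S, reps[r], chunk, dt, gamma, rng, terms);
      }
      Rcpp::checkUserInterrupt();
    }
    done = target;
    if (done == next_save) {
      if (fi < nframe_max) save_frames();
      next_save += n_save;
    }
    if (done == next_swap && done < steps) {
      cycle++;
      int start = (cycle % 2 == 1) ? 0 : 1; // alternate even/odd pairs
      for (int r = start; r + 1 < nrep; r += 2) {
        double bi = 1.0 / (KB * ladder[r]);
        double bj = 1.0 / (KB * ladder[r + 1]);
        double delta = (bi - bj) * (reps[r].epot - reps[r + 1].epot);
        int acc = 0;
        if (delta >= 0.0 || rng.unif() < std::exp(delta)) acc = 1;
        sw_step.push_back(done); sw_i.push_back(r + 1);
        sw_delta.push_back(delta); sw_acc.push_back(acc);
        if (acc) {
          std::swap(reps[r].x, reps[r + 1].x);
          std::swap(reps[r].v, reps[r + 1].v);
          std::swap(reps[r].f, reps[r + 1].f);
          std::swap(reps[r].epot, reps[r + 1].epot);
          double up = std::sqrt(ladder[r + 1] / ladder[r]);
          for (int i = 0; i < 3 * n; i++) {
            reps[r].v[i] /= up;       // config moved to the colder rung
            reps[r + 1].v[i] *= up;   // config moved to the hotter rung
          }
        }
      }
      next_swap += swap_interval;
    }
  }

  List frames_out(nrep), energies_out(nrep);
  for (int r = 0; r < nrep; r++) {
    frames_out[r] = frames[r];
    energies_out[r] = energies[r];
  }
  return List::create(
    _["frames"] = frames_out, _["energies"] = energies_out,
    _["swap_log"] = DataFrame::create(
      _["step"] = sw_step, _["pair_lo"] = sw_i,
      _["delta"] = sw_delta, _["accepted"] = sw_acc),
    _["n_frames"] = fi);
}
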