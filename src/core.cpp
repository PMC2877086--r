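// Cellular Potts (GGH) engine: lattice state, effective energy, Metropolis
// copy dynamics, reaction-diffusion fields, growth/mitosis/phenotype rules.
// All stochastic state lives in the Sim object (own mt19937_64 stream) so
// trajectories are bit-reproducible for a given seed, independent of R's RNG.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <random>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: mt19937_64 with explicit derivations (std::*_distribution is not
// bit-portable across standard libraries; these are).
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double u01() { return (gen() >> 11) * 0x1.0p-53; }  // [0,1)
  // uniform integer in [0, n), multiply-shift (n << 2^64 so bias negligible
  // and, more importantly, deterministic)
  int64_t bounded(uint64_t n) {
    return (int64_t)((unsigned __int128)gen() * n >> 64);
  }
  double normal() {
    // Box-Muller (single value; simplicity over speed, used only in mitosis)
    double u1 = u01(), u2 = u01();
    if (u1 <= 0) u1 = 0x1.0p-53;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

enum CellType { TM_TYPE = 0, TUMOR_TYPE = 1 };
enum CellState { PROLIF = 0, QUIESCENT = 1, NECROTIC = 2 };

struct Cell {
  int type = TUMOR_TYPE;
  int state = PROLIF;
  long V = 0;       // current volume (voxel count)
  double Vt = 0;    // target volume
  long S = 0;       // surface: in-lattice face-adjacent heterolabel pairs
  double St = 0;    // target surface
  double sx = 0, sy = 0, sz = 0;  // coordinate sums (COM = s / V)
  int x0 = 0, x1 = -1, y0 = 0, y1 = -1, z0 = 0, z1 = -1;  // grow-only bbox
  bool alive = false;
};

struct Params {
  int L = 100;
  double J_tt = 4, J_ttm = 8;   // contact energies (per unit boundary area)
  double Tm = 60;               // motility ("temperature")
  double lambda_V = 20, lambda_S = 0.4;
  double V_doubling = 54;
  double shape_A = 6.0;         // S_t = A * V_t^(2/3); A = 54 / 27^(2/3)
  double D_c = 10, D_m = 0.01, delta = 0.5, mu = 1.0, S_prod = 0.1;
  double k = 0.05, g = 0.3;
  bool quiescence = false, necrosis = false;
  double c_threshold = 0.05, g_necrotic = -0.15;
  bool divide_on_target = false;  // division trigger: actual V (default)
};

static const int FACE_OFF[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};

// neighbor offsets with 1 <= dx^2+dy^2+dz^2 <= maxr2 (order = maxr2)
static std::vector<std::array<int,3>> neighbor_offsets_vec(int order) {
  std::vector<std::array<int,3>> off;
  int m = (int)std::ceil(std::sqrt((double)order));
  for (int dz = -m; dz <= m; ++dz)
    for (int dy = -m; dy <= m; ++dy)
      for (int dx = -m; dx <= m; ++dx) {
        int r2 = dx*dx + dy*dy + dz*dz;
        if (r2 >= 1 && r2 <= order)
          off.push_back({dx, dy, dz});
      }
  return off;
}

struct Sim {
  Params p;
  int L;
  long L3;
  std::vector<int> sigma;                 // label lattice, x fastest
  std::vector<Cell> cells;                // index = cell id; 0 unused, 1 = TM
  std::vector<float> f, m, c, buf;        // fields (single precision: bandwidth-bound loop, values in [0,1])
  std::vector<std::array<int,3>> nbr;     // interaction neighborhood (order 4)
  Rng rng;
  long mcs = 0;
  int n_sub_c = 1, n_sub_m = 1;

  Sim(const Params& pp, uint64_t seed) : p(pp), L(pp.L), L3((long)pp.L*pp.L*pp.L),
      rng(seed) {
    sigma.assign(L3, 1);
    f.assign(L3, 1.0); m.assign(L3, 0.0); c.assign(L3, 1.0); buf.assign(L3, 0.0);
    nbr = neighbor_offsets_vec(4);
    n_sub_c = stability_substeps(p.D_c);
    n_sub_m = stability_substeps(p.D_m);
  }

  static int stability_substeps(double D) {
    if (D <= 0) return 1;
    // smallest n with D/n <= safety/6, safety = 0.8 (3D explicit Euler, dx=1)
    int n = (int)std::ceil(D * 6.0 / 0.8);
    if (n < 1) n = 1;
    return n;
  }

  inline long idx(int x, int y, int z) const { return ((long)z * L + y) * L + x; }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < L && y >= 0 && y < L && z >= 0 && z < L;
  }
  inline double J(int ta, int tb) const {
    if (ta == TUMOR_TYPE && tb == TUMOR_TYPE) return p.J_tt;
    if (ta == TM_TYPE && tb == TM_TYPE) return 0.0;  // single TM cell; unused
    return p.J_ttm;
  }

  // ------------------------------------------------------------------ setup
  void seed_tumor() {
    // 8 tumor cells, each a 3x3x3 cube, forming a 6x6x6 block at the center
    if (L < 8) stop("lattice too small for the 6x6x6 tumor seed block");
    int start = (L - 6) / 2;
    cells.assign(2, Cell());
    Cell tm; tm.type = TM_TYPE; tm.alive = true;
    tm.x0 = 0; tm.x1 = L - 1; tm.y0 = 0; tm.y1 = L - 1; tm.z0 = 0; tm.z1 = L - 1;
    cells[1] = tm;
    for (int cz = 0; cz < 2; ++cz)
      for (int cy = 0; cy < 2; ++cy)
        for (int cx = 0; cx < 2; ++cx) {
          Cell cell; cell.type = TUMOR_TYPE; cell.alive = true;
          cell.Vt = 27.0; cell.St = p.shape_A * std::pow(27.0, 2.0/3.0);
          int id = (int)cells.size();
          for (int dz = 0; dz < 3; ++dz)
            for (int dy = 0; dy < 3; ++dy)
              for (int dx = 0; dx < 3; ++dx) {
                int x = start + 3*cx + dx, y = start + 3*cy + dy, z = start + 3*cz + dz;
                sigma[idx(x,y,z)] = id;
              }
          cell.x0 = start + 3*cx; cell.x1 = cell.x0 + 2;
          cell.y0 = start + 3*cy; cell.y1 = cell.y0 + 2;
          cell.z0 = start + 3*cz; cell.z1 = cell.z0 + 2;
          cells.push_back(cell);
        }
    recompute_registry();
  }

  // rebuild V, S, coordinate sums for all ids from sigma (authoritative scan)
  void recompute_registry() {
    for (auto& cl : cells) { cl.V = 0; cl.S = 0; cl.sx = cl.sy = cl.sz = 0; }
    for (int z = 0; z < L; ++z)
      for (int y = 0; y < L; ++y)
        for (int x = 0; x < L; ++x) {
          int id = sigma[idx(x,y,z)];
          Cell& cl = cells[id];
          cl.V++; cl.sx += x; cl.sy += y; cl.sz += z;
          for (const auto& o : FACE_OFF) {
            int nx = x + o[0], ny = y + o[1], nz = z + o[2];
            if (inside(nx,ny,nz) && sigma[idx(nx,ny,nz)] != id) cl.S++;
          }
        }
    for (auto& cl : cells) if (cl.V > 0) cl.alive = true;
  }

  bool audit(std::string* msg = nullptr) const {
    std::vector<long> V(cells.size(), 0), S(cells.size(), 0);
    long tot = 0;
    for (int z = 0; z < L; ++z)
      for (int y = 0; y < L; ++y)
        for (int x = 0; x < L; ++x) {
          int id = sigma[idx(x,y,z)];
          if (id <= 0 || id >= (int)cells.size()) {
            if (msg) *msg = "sigma contains an unregistered id";
            return false;
          }
          V[id]++; tot++;
          for (const auto& o : FACE_OFF) {
            int nx = x + o[0], ny = y + o[1], nz = z + o[2];
            if (inside(nx,ny,nz) && sigma[idx(nx,ny,nz)] != id) S[id]++;
          }
        }
    for (size_t i = 0; i < cells.size(); ++i) {
      if (V[i] != cells[i].V) { if (msg) *msg = "volume ledger mismatch"; return false; }
      if (S[i] != cells[i].S) { if (msg) *msg = "surface ledger mismatch"; return false; }
    }
    if (tot != L3) { if (msg) *msg = "total volume != L^3"; return false; }
    return true;
  }

  // ----------------------------------------------------------------- energy
  double contact_energy() const {
    // each unordered in-range voxel pair counted once: enumerate half-space
    double E = 0;
    for (int z = 0; z < L; ++z)
      for (int y = 0; y < L; ++y)
        for (int x = 0; x < L; ++x) {
          int ida = sigma[idx(x,y,z)];
          for (const auto& o : nbr) {
            // count pair once: lexicographic positive direction
            if (o[2] < 0 || (o[2] == 0 && (o[1] < 0 || (o[1] == 0 && o[0] < 0))))
              continue;
            int nx = x + o[0], ny = y + o[1], nz = z + o[2];
            if (!inside(nx,ny,nz)) continue;
            int idb = sigma[idx(nx,ny,nz)];
            if (idb != ida) E += J(cells[ida].type, cells[idb].type);
          }
        }
    return E;
  }

  double effective_energy() const {
    double E = contact_energy();
    for (size_t i = 1; i < cells.size(); ++i) {
      const Cell& cl = cells[i];
      if (cl.type == TM_TYPE) continue;  // TM is unconstrained
      if (cl.V == 0 && cl.Vt == 0) continue;
      double dV = cl.V - cl.Vt, dS = cl.S - cl.St;
      E += p.lambda_V * dV * dV + p.lambda_S * dS * dS;
    }
    return E;
  }

  // Local energy difference for overwriting sigma(x) with id_new
  double delta_h(int x, int y, int z, int id_new) const {
    long i = idx(x,y,z);
    int id_old = sigma[i];
    int t_old = cells[id_old].type, t_new = cells[id_new].type;
    double dE = 0;
    for (const auto& o : nbr) {
      int nx = x + o[0], ny = y + o[1], nz = z + o[2];
      if (!inside(nx,ny,nz)) continue;
      int idn = sigma[idx(nx,ny,nz)];
      int tn = cells[idn].type;
      if (idn != id_old) dE -= J(t_old, tn);
      if (idn != id_new) dE += J(t_new, tn);
    }
    // volume terms (TM excluded)
    if (cells[id_old].type != TM_TYPE) {
      double d0 = cells[id_old].V - cells[id_old].Vt;
      dE += p.lambda_V * ((d0 - 1) * (d0 - 1) - d0 * d0);
    }
    if (cells[id_new].type != TM_TYPE) {
      double d1 = cells[id_new].V - cells[id_new].Vt;
      dE += p.lambda_V * ((d1 + 1) * (d1 + 1) - d1 * d1);
    }
    // surface terms: only first-neighbor pairs at x change status
    int same_old = 0, same_new = 0, n_in = 0;
    for (const auto& o : FACE_OFF) {
      int nx = x + o[0], ny = y + o[1], nz = z + o[2];
      if (!inside(nx,ny,nz)) continue;
      n_in++;
      int idn = sigma[idx(nx,ny,nz)];
      if (idn == id_old) same_old++;
      if (idn == id_new) same_new++;
    }
    long dS_old = 2 * same_old - n_in;        // +same - (n_in - same)
    long dS_new = n_in - 2 * same_new;        // +(n_in - same) - same
    if (cells[id_old].type != TM_TYPE) {
      double s0 = cells[id_old].S - cells[id_old].St;
      dE += p.lambda_S * ((s0 + dS_old) * (s0 + dS_old) - s0 * s0);
    }
    if (cells[id_new].type != TM_TYPE) {
      double s1 = cells[id_new].S - cells[id_new].St;
      dE += p.lambda_S * ((s1 + dS_new) * (s1 + dS_new) - s1 * s1);
    }
    return dE;
  }

  void apply_copy(int x, int y, int z, int id_new) {
    long i = idx(x,y,z);
    int id_old = sigma[i];
    int same_old = 0, same_new = 0, n_in = 0;
    for (const auto& o : FACE_OFF) {
      int nx = x + o[0], ny = y + o[1], nz = z + o[2];
      if (!inside(nx,ny,nz)) continue;
      n_in++;
      int idn = sigma[idx(nx,ny,nz)];
      if (idn == id_old) same_old++;
      if (idn == id_new) same_new++;
    }
    Cell& co = cells[id_old];
    Cell& cn = cells[id_new];
    co.V--; co.sx -= x; co.sy -= y; co.sz -= z; co.S += 2 * same_old - n_in;
    cn.V++; cn.sx += x; cn.sy += y; cn.sz += z; cn.S += n_in - 2 * same_new;
    cn.alive = true;
    sigma[i] = id_new;
    if (x < cn.x0) cn.x0 = x; if (x > cn.x1) cn.x1 = x;
    if (y < cn.y0) cn.y0 = y; if (y > cn.y1) cn.y1 = y;
    if (z < cn.z0) cn.z0 = z; if (z > cn.z1) cn.z1 = z;
    if (co.V == 0) co.alive = false;
  }

  inline bool accept_rule(double dH) {
    if (dH <= 0) return true;
    return rng.u01() < std::exp(-dH / p.Tm);
  }

  // one copy attempt; returns 1 if a copy was accepted, 0 otherwise
  int attempt() {
    long site = rng.bounded((uint64_t)L3);
    int x = (int)(site % L);
    int y = (int)((site / L) % L);
    int z = (int)(site / ((long)L * L));
    const auto& o = nbr[rng.bounded(nbr.size())];
    int nx = x + o[0], ny = y + o[1], nz = z + o[2];
    if (!inside(nx,ny,nz)) return 0;         // counts toward the MCS budget
    int id_src = sigma[idx(nx,ny,nz)];
    int id_tgt = sigma[idx(x,y,z)];
    if (id_src == id_tgt) return 0;          // same-cell no-op
    double dH = delta_h(x, y, z, id_src);
    if (!accept_rule(dH)) return 0;
    apply_copy(x, y, z, id_src);
    return 1;
  }

  void sweep() { for (long a = 0; a < L3; ++a) attempt(); }

  // ----------------------------------------------------------------- fields
  // 7-point no-flux Laplacian contribution at (x,y,z) for vector v
  inline double lap_at(const std::vector<float>& v, int x, int y, int z) const {
    long i = idx(x,y,z);
    double acc = 0; int cnt = 0;
    if (x > 0)     { acc += v[i-1]; cnt++; }
    if (x < L - 1) { acc += v[i+1]; cnt++; }
    if (y > 0)     { acc += v[i-L]; cnt++; }
    if (y < L - 1) { acc += v[i+L]; cnt++; }
    if (z > 0)     { acc += v[i-(long)L*L]; cnt++; }
    if (z < L - 1) { acc += v[i+(long)L*L]; cnt++; }
    return acc - cnt * v[i];
  }

  inline long com_voxel(const Cell& cl) const {
    // nearest integer, ties toward -inf; clamp into the domain
    auto rnd = [this](double s, long V) {
      int v = (int)std::ceil(s / V - 0.5);
      if (v < 0) v = 0; if (v >= L) v = L - 1;
      return v;
    };
    return idx(rnd(cl.sx, cl.V), rnd(cl.sy, cl.V), rnd(cl.sz, cl.V));
  }

  void update_fields() {
    // substrate: fused row-wise forward-Euler substeps of diffusion plus
    // saturating production S_prod * f * (1 - c) (f held at its MCS-start
    // value across the substeps; f itself changes by < delta*mu per MCS)
    double dt = 1.0 / n_sub_c;
    const long stz = (long)L * L;
    for (int s = 0; s < n_sub_c; ++s) {
      for (int z = 0; z < L; ++z)
        for (int y = 0; y < L; ++y) {
          long base = ((long)z * L + y) * L;
          const float* __restrict__ cc = &c[base];
          const float* __restrict__ cym = &c[y > 0     ? base - L   : base];
          const float* __restrict__ cyp = &c[y < L - 1 ? base + L   : base];
          const float* __restrict__ czm = &c[z > 0     ? base - stz : base];
          const float* __restrict__ czp = &c[z < L - 1 ? base + stz : base];
          const float* __restrict__ ff = &f[base];
          float* __restrict__ bb = &buf[base];
          const float dtD = (float)(dt * p.D_c), dtS = (float)(dt * p.S_prod);
          // x boundary columns peeled (mirror: missing neighbor = center);
          // interior is a branchless loop the compiler can vectorize
          // values below 1e-12 flush to zero (well under any physical
          // concentration; avoids subnormal-float penalties in starved zones)
          auto pointstep = [&](int x, float xm, float xp) {
            float ctr = cc[x];
            float lap = xm + xp + cym[x] + cyp[x] + czm[x] + czp[x] - 6.0f * ctr;
            float v = ctr + dtD * lap + dtS * ff[x] * (1.0f - ctr);
            bb[x] = v < 1e-12f ? 0.0f : std::min(1.0f, v);
          };
          pointstep(0, cc[0], cc[1]);
          for (int x = 1; x < L - 1; ++x) {
            float ctr = cc[x];
            float lap = cc[x-1] + cc[x+1] + cym[x] + cyp[x] + czm[x] + czp[x]
                        - 6.0f * ctr;
            float v = ctr + dtD * lap + dtS * ff[x] * (1.0f - ctr);
            bb[x] = v < 1e-12f ? 0.0f : std::min(1.0f, v);
          }
          pointstep(L - 1, cc[L-2], cc[L-1]);
        }
      c.swap(buf);
    }
    // TM degradation: per-substep factor (1 - delta*m*dt), applied n_sub_c
    // times with m fixed within the MCS -- computed in closed form. Voxels
    // whose per-MCS factor differs from 1 by less than single-precision
    // resolution are skipped (diffusion leaves sub-epsilon MDE tails
    // everywhere); saturated-MDE voxels use a precomputed factor.
    if (p.delta > 0) {
      const float sat = (float)std::pow(1.0 - p.delta * dt, n_sub_c);
      for (long i = 0; i < L3; ++i) {
        float mi = m[i];
        if (mi <= 0 || f[i] <= 0) continue;
        if ((double)p.delta * mi < 1e-6) continue;
        if (mi >= 1.0f) { f[i] *= sat; continue; }
        double r = 1.0 - p.delta * mi * dt;
        f[i] = r <= 0 ? 0.0f : (float)(f[i] * std::pow(r, n_sub_c));
      }
    }
    // MDE diffusion
    if (p.D_m > 0) {
      double dtm = 1.0 / n_sub_m;
      for (int s = 0; s < n_sub_m; ++s) {
        for (int z = 0; z < L; ++z)
          for (int y = 0; y < L; ++y)
            for (int x = 0; x < L; ++x) {
              long i = idx(x,y,z);
              double v = m[i] + dtm * p.D_m * lap_at(m, x, y, z);
              // flush far-field tails to zero: keeps the slow-diffusion halo
              // physical and avoids subnormal-float arithmetic penalties
              if (v < 1e-12) v = 0; else if (v > 1) v = 1;
              buf[i] = (float)v;
            }
        m.swap(buf);
      }
    }
    // per-MCS source/sink at every voxel occupied by a proliferating tumor
    // cell (the indicator-function coupling of the field equations): MDE
    // deposition mu capped at 1, substrate uptake k floored at 0
    for (long i = 0; i < L3; ++i) {
      const Cell& cl = cells[sigma[i]];
      if (cl.type != TUMOR_TYPE || cl.state != PROLIF) continue;
      m[i] = (float)std::min(1.0, (double)m[i] + p.mu);
      c[i] = (float)std::max(0.0, (double)c[i] - p.k);
    }
  }

  // ---------------------------------------------------------------- biology
  void set_target_surface(Cell& cl) {
    cl.St = cl.Vt > 0 ? p.shape_A * std::pow(cl.Vt, 2.0/3.0) : 0.0;
  }

  void grow_cells() {
    for (size_t id = 2; id < cells.size(); ++id) {
      Cell& cl = cells[id];
      if (!cl.alive || cl.V == 0) continue;
      if (cl.state == PROLIF) {
        cl.Vt += p.g * c[com_voxel(cl)];
      } else if (cl.state == NECROTIC) {
        cl.Vt = std::max(0.0, cl.Vt + p.g_necrotic);
      }
      set_target_surface(cl);
    }
  }

  // split cell `id` by the plane through its COM with normal `n`;
  // returns new id, or 0 if the split is degenerate
  int split_by_plane(int id, double nx_, double ny_, double nz_) {
    Cell& parent = cells[id];
    std::vector<std::array<int,3>> vox;
    vox.reserve(parent.V);
    for (int z = std::max(0, parent.z0); z <= std::min(L-1, parent.z1); ++z)
      for (int y = std::max(0, parent.y0); y <= std::min(L-1, parent.y1); ++y)
        for (int x = std::max(0, parent.x0); x <= std::min(L-1, parent.x1); ++x)
          if (sigma[idx(x,y,z)] == id) vox.push_back({x,y,z});
    double cx = parent.sx / parent.V, cy = parent.sy / parent.V, cz = parent.sz / parent.V;
    long n_pos = 0;
    for (const auto& v : vox)
      if ((v[0]-cx)*nx_ + (v[1]-cy)*ny_ + (v[2]-cz)*nz_ >= 0) n_pos++;
    if (n_pos == 0 || n_pos == (long)vox.size()) return 0;
    Cell d; d.type = TUMOR_TYPE; d.state = parent.state; d.alive = true;
    int id_new = (int)cells.size();
    cells.push_back(d);
    Cell& daughter = cells[id_new];
    Cell& par = cells[id];  // re-reference after push_back
    for (const auto& v : vox)
      if ((v[0]-cx)*nx_ + (v[1]-cy)*ny_ + (v[2]-cz)*nz_ >= 0)
        sigma[idx(v[0],v[1],v[2])] = id_new;
    // recompute both daughters from their voxels
    auto recompute = [this](int cid, const std::vector<std::array<int,3>>& vv) {
      Cell& cl = cells[cid];
      cl.V = 0; cl.S = 0; cl.sx = cl.sy = cl.sz = 0;
      cl.x0 = L; cl.x1 = -1; cl.y0 = L; cl.y1 = -1; cl.z0 = L; cl.z1 = -1;
      for (const auto& v : vv) {
        if (sigma[idx(v[0],v[1],v[2])] != cid) continue;
        cl.V++; cl.sx += v[0]; cl.sy += v[1]; cl.sz += v[2];
        if (v[0] < cl.x0) cl.x0 = v[0]; if (v[0] > cl.x1) cl.x1 = v[0];
        if (v[1] < cl.y0) cl.y0 = v[1]; if (v[1] > cl.y1) cl.y1 = v[1];
        if (v[2] < cl.z0) cl.z0 = v[2]; if (v[2] > cl.z1) cl.z1 = v[2];
        for (const auto& o : FACE_OFF) {
          int ax = v[0]+o[0], ay = v[1]+o[1], az = v[2]+o[2];
          if (inside(ax,ay,az) && sigma[idx(ax,ay,az)] != cid) cl.S++;
        }
      }
    };
    recompute(id, vox);
    recompute(id_new, vox);
    double vt_half = par.Vt / 2.0;
    par.Vt = vt_half; daughter.Vt = vt_half;
    set_target_surface(par); set_target_surface(daughter);
    return id_new;
  }

  int mitose(int id, const double* forced_axis) {
    Cell& cl = cells[id];
    if (cl.V < 2) return 0;
    if (forced_axis) {
      return split_by_plane(id, forced_axis[0], forced_axis[1], forced_axis[2]);
    }
    for (int tries = 0; tries < 10; ++tries) {
      double ax = rng.normal(), ay = rng.normal(), az = rng.normal();
      double nrm = std::sqrt(ax*ax + ay*ay + az*az);
      if (nrm < 1e-12) continue;
      int nid = split_by_plane(id, ax/nrm, ay/nrm, az/nrm);
      if (nid) return nid;
    }
    // fall back: coordinate axis of largest extent
    int ex = cl.x1 - cl.x0, ey = cl.y1 - cl.y0, ez = cl.z1 - cl.z0;
    double ax = 0, ay = 0, az = 0;
    if (ex >= ey && ex >= ez) ax = 1; else if (ey >= ez) ay = 1; else az = 1;
    return split_by_plane(id, ax, ay, az);
  }

  void mitosis_pass() {
    size_t n0 = cells.size();  // daughters created this MCS do not re-divide
    for (size_t id = 2; id < n0; ++id) {
      Cell& cl = cells[id];
      if (!cl.alive || cl.V == 0 || cl.state == NECROTIC) continue;
      double trigger = p.divide_on_target ? cl.Vt : (double)cl.V;
      if (trigger >= p.V_doubling) mitose((int)id, nullptr);
    }
  }

  void phenotype_pass() {
    if (!p.quiescence && !p.necrosis) return;
    for (size_t id = 2; id < cells.size(); ++id) {
      Cell& cl = cells[id];
      if (!cl.alive || cl.V == 0) continue;
      double cc = c[com_voxel(cl)];
      if (p.necrosis) {
        if (cl.state != NECROTIC && cc < p.c_threshold) cl.state = NECROTIC;
      } else if (p.quiescence) {
        if (cl.state == PROLIF && cc < p.c_threshold) cl.state = QUIESCENT;
        else if (cl.state == QUIESCENT && cc >= p.c_threshold) cl.state = PROLIF;
      }
    }
  }

  void step_mcs() {
    sweep();
    update_fields();
    grow_cells();
    mitosis_pass();
    phenotype_pass();
    mcs++;
  }

  bool touches_boundary() const {
    auto tumor_at = [this](long i) {
      int id = sigma[i];
      return cells[id].type == TUMOR_TYPE;
    };
    for (int a = 0; a < L; ++a)
      for (int b = 0; b < L; ++b) {
        if (tumor_at(idx(0,a,b)) || tumor_at(idx(L-1,a,b))) return true;
        if (tumor_at(idx(a,0,b)) || tumor_at(idx(a,L-1,b))) return true;
        if (tumor_at(idx(a,b,0)) || tumor_at(idx(a,b,L-1))) return true;
      }
    return false;
  }
};

// ===========================================================================
// Rcpp interface

static Sim* get_sim(SEXP ptr) {
  Rcpp::XPtr<Sim> xp(ptr);
  return xp.get();
}

static Params params_from_list(const List& pl) {
  Params p;
  p.L = as<int>(pl["L"]);
  p.J_tt = as<double>(pl["J_tt"]);
  p.J_ttm = as<double>(pl["J_ttm"]);
  p.Tm = as<double>(pl["T_m"]);
  p.lambda_V = as<double>(pl["lambda_V"]);
  p.lambda_S = as<double>(pl["lambda_S"]);
  p.V_doubling = as<double>(pl["V_doubling"]);
  p.shape_A = as<double>(pl["shape_constant"]);
  p.D_c = as<double>(pl["D_c"]);
  p.D_m = as<double>(pl["D_m"]);
  p.delta = as<double>(pl["delta"]);
  p.mu = as<double>(pl["mu"]);
  p.S_prod = as<double>(pl["S_prod"]);
  p.k = as<double>(pl["k"]);
  p.g = as<double>(pl["g"]);
  p.quiescence = as<bool>(pl["quiescence_enabled"]);
  p.necrosis = as<bool>(pl["necrosis_enabled"]);
  p.c_threshold = as<double>(pl["c_threshold"]);
  p.g_necrotic = as<double>(pl["g_necrotic"]);
  p.divide_on_target = as<bool>(pl["divide_on_target"]);
  return p;
}

// [[Rcpp::export]]
SEXP cpp_sim_new(List params, int seed) {
  Params p = params_from_list(params);
  Sim* s = new Sim(p, (uint64_t)(uint32_t)seed);
  s->seed_tumor();
  return Rcpp::XPtr<Sim>(s, true);
}

// [[Rcpp::export]]
SEXP cpp_sim_from_sigma(IntegerVector sigma, IntegerVector types, List params, int seed) {
  Params p = params_from_list(params);
  IntegerVector dims = sigma.attr("dim");
  if (dims.size() != 3 || dims[0] != p.L || dims[1] != p.L || dims[2] != p.L)
    stop("sigma must be an L x L x L array matching config L");
  Sim* s = new Sim(p, (uint64_t)(uint32_t)seed);
  int maxid = 0;
  for (long i = 0; i < s->L3; ++i) {
    if (sigma[i] < 1) stop("labels must be >= 1 (id 1 is the tissue-matrix cell)");
    s->sigma[i] = sigma[i];
    if (sigma[i] > maxid) maxid = sigma[i];
  }
  if (types.size() < maxid) stop("types must cover every id present in sigma");
  s->cells.assign(maxid + 1, Cell());
  for (int id = 1; id <= maxid; ++id) {
    s->cells[id].type = types[id - 1] == 0 ? TM_TYPE : TUMOR_TYPE;
    s->cells[id].x0 = 0; s->cells[id].x1 = p.L - 1;
    s->cells[id].y0 = 0; s->cells[id].y1 = p.L - 1;
    s->cells[id].z0 = 0; s->cells[id].z1 = p.L - 1;
  }
  s->recompute_registry();
  // default targets equal to current values (zero constraint energy)
  for (int id = 1; id <= maxid; ++id) {
    s->cells[id].Vt = (double)s->cells[id].V;
    s->cells[id].St = (double)s->cells[id].S;
  }
  return Rcpp::XPtr<Sim>(s, true);
}

// [[Rcpp::export]]
void cpp_sim_run(SEXP ptr, int n_mcs) {
  Sim* s = get_sim(ptr);
  for (int i = 0; i < n_mcs; ++i) {
    s->step_mcs();
    if ((i & 15) == 0) Rcpp::checkUserInterrupt();
  }
}

// [[Rcpp::export]]
int cpp_sim_attempt(SEXP ptr) { return get_sim(ptr)->attempt(); }

// [[Rcpp::export]]
int cpp_sim_sweep(SEXP ptr) {
  Sim* s = get_sim(ptr);
  int acc = 0;
  for (long a = 0; a < s->L3; ++a) acc += s->attempt();
  return acc;
}

// [[Rcpp::export]]
double cpp_sim_delta_h(SEXP ptr, IntegerVector x, int id_new) {
  Sim* s = get_sim(ptr);
  return s->delta_h(x[0], x[1], x[2], id_new);
}

// [[Rcpp::export]]
void cpp_sim_apply_copy(SEXP ptr, IntegerVector x, int id_new) {
  get_sim(ptr)->apply_copy(x[0], x[1], x[2], id_new);
}

// [[Rcpp::export]]
double cpp_sim_contact_energy(SEXP ptr) { return get_sim(ptr)->contact_energy(); }

// [[Rcpp::export]]
double cpp_sim_effective_energy(SEXP ptr) { return get_sim(ptr)->effective_energy(); }

// [[Rcpp::export]]
IntegerVector cpp_sim_sigma(SEXP ptr) {
  Sim* s = get_sim(ptr);
  IntegerVector out(s->L3);
  for (long i = 0; i < s->L3; ++i) out[i] = s->sigma[i];
  out.attr("dim") = IntegerVector::create(s->L, s->L, s->L);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sim_field(SEXP ptr, std::string which) {
  Sim* s = get_sim(ptr);
  const std::vector<float>* v =
    which == "f" ? &s->f : which == "m" ? &s->m : &s->c;
  NumericVector out(s->L3);
  for (long i = 0; i < s->L3; ++i) out[i] = (*v)[i];
  out.attr("dim") = IntegerVector::create(s->L, s->L, s->L);
  return out;
}

// [[Rcpp::export]]
void cpp_sim_set_field(SEXP ptr, std::string which, NumericVector val) {
  Sim* s = get_sim(ptr);
  std::vector<float>* v = which == "f" ? &s->f : which == "m" ? &s->m : &s->c;
  if ((long)val.size() != s->L3) stop("field size mismatch");
  for (long i = 0; i < s->L3; ++i) (*v)[i] = (float)val[i];
}

// [[Rcpp::export]]
DataFrame cpp_sim_cells(SEXP ptr) {
  Sim* s = get_sim(ptr);
  int n = (int)s->cells.size() - 1;
  IntegerVector id(n), type(n), state(n), V(n), S(n);
  NumericVector Vt(n), St(n), comx(n), comy(n), comz(n);
  LogicalVector alive(n);
  for (int i = 1; i <= n; ++i) {
    const Cell& cl = s->cells[i];
    id[i-1] = i; type[i-1] = cl.type; state[i-1] = cl.state;
    V[i-1] = (int)cl.V; S[i-1] = (int)cl.S; Vt[i-1] = cl.Vt; St[i-1] = cl.St;
    if (cl.V > 0) {
      comx[i-1] = cl.sx / cl.V; comy[i-1] = cl.sy / cl.V; comz[i-1] = cl.sz / cl.V;
    } else { comx[i-1] = NA_REAL; comy[i-1] = NA_REAL; comz[i-1] = NA_REAL; }
    alive[i-1] = cl.alive;
  }
  return DataFrame::create(_["id"] = id, _["type"] = type, _["state"] = state,
    _["V"] = V, _["V_t"] = Vt, _["S"] = S, _["S_t"] = St,
    _["com_x"] = comx, _["com_y"] = comy, _["com_z"] = comz, _["alive"] = alive);
}

// [[Rcpp::export]]
void cpp_sim_set_cell(SEXP ptr, int id, Nullable<double> Vt, Nullable<double> St,
                      Nullable<int> state) {
  Sim* s = get_sim(ptr);
  if (id < 1 || id >= (int)s->cells.size()) stop("no such cell id");
  Cell& cl = s->cells[id];
  if (Vt.isNotNull()) cl.Vt = as<double>(Vt.get());
  if (St.isNotNull()) cl.St = as<double>(St.get());
  if (state.isNotNull()) cl.state = as<int>(state.get());
}

// [[Rcpp::export]]
bool cpp_sim_audit(SEXP ptr) {
  std::string msg;
  if (!get_sim(ptr)->audit(&msg)) stop("state audit failed: " + msg);
  return true;
}

// [[Rcpp::export]]
int cpp_sim_mitose(SEXP ptr, int id, Nullable<NumericVector> axis) {
  Sim* s = get_sim(ptr);
  if (id < 2 || id >= (int)s->cells.size()) stop("no such tumor cell id");
  if (axis.isNotNull()) {
    NumericVector a(axis.get());
    double ax[3] = {a[0], a[1], a[2]};
    return s->mitose(id, ax);
  }
  return s->mitose(id, nullptr);
}

// [[Rcpp::export]]
void cpp_sim_biology_step(SEXP ptr, bool grow, bool divide, bool phenotype) {
  Sim* s = get_sim(ptr);
  if (grow) s->grow_cells();
  if (divide) s->mitosis_pass();
  if (phenotype) s->phenotype_pass();
}

// [[Rcpp::export]]
void cpp_sim_update_fields(SEXP ptr) { get_sim(ptr)->update_fields(); }

// [[Rcpp::export]]
bool cpp_sim_touches_boundary(SEXP ptr) { return get_sim(ptr)->touches_boundary(); }

// [[Rcpp::export]]
long cpp_sim_mcs(SEXP ptr) { return get_sim(ptr)->mcs; }

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_offsets(int order) {
  auto off = neighbor_offsets_vec(order);
  IntegerMatrix out((int)off.size(), 3);
  for (size_t i = 0; i < off.size(); ++i) {
    out(i,0) = off[i][0]; out(i,1) = off[i][1]; out(i,2) = off[i][2];
  }
  return out;
}

// Acceptance decisions at a forced energy difference, using the engine's
// decision rule and RNG derivation (for testing the Metropolis law).
// [[Rcpp::export]]
int cpp_accept_count(double dH, double Tm, int n, int seed) {
  Rng rng((uint64_t)(uint32_t)seed);
  int acc = 0;
  for (int i = 0; i < n; ++i) {
    if (dH <= 0) { acc++; continue; }
    if (rng.u01() < std::exp(-dH / Tm)) acc++;
  }
  return acc;
}

// [[Rcpp::export]]
int cpp_stability_substeps(double D) { return Sim::stability_substeps(D); }

// ---------------------------------------------------------------------------
// Standalone field operators on plain arrays (same stencil as the engine)

static void get_dims3(const NumericVector& v, int d[3]) {
  IntegerVector dims = v.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  d[0] = dims[0]; d[1] = dims[1]; d[2] = dims[2];
}

// [[Rcpp::export]]
NumericVector cpp_laplacian_noflux(NumericVector v) {
  int d[3]; get_dims3(v, d);
  NumericVector out(v.size());
  auto id3 = [&](int x, int y, int z) { return ((long)z * d[1] + y) * d[0] + x; };
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        long i = id3(x,y,z);
        double acc = 0; int cnt = 0;
        if (x > 0)        { acc += v[id3(x-1,y,z)]; cnt++; }
        if (x < d[0]-1)   { acc += v[id3(x+1,y,z)]; cnt++; }
        if (y > 0)        { acc += v[id3(x,y-1,z)]; cnt++; }
        if (y < d[1]-1)   { acc += v[id3(x,y+1,z)]; cnt++; }
        if (z > 0)        { acc += v[id3(x,y,z-1)]; cnt++; }
        if (z < d[2]-1)   { acc += v[id3(x,y,z+1)]; cnt++; }
        out[i] = acc - cnt * v[i];
      }
  out.attr("dim") = v.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_diffuse(NumericVector v, double D, double dt, int nsteps,
                          bool clamp01) {
  int d[3]; get_dims3(v, d);
  NumericVector cur = clone(v), nxt(v.size());
  auto id3 = [&](int x, int y, int z) { return ((long)z * d[1] + y) * d[0] + x; };
  for (int s = 0; s < nsteps; ++s) {
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          long i = id3(x,y,z);
          double acc = 0; int cnt = 0;
          if (x > 0)        { acc += cur[id3(x-1,y,z)]; cnt++; }
          if (x < d[0]-1)   { acc += cur[id3(x+1,y,z)]; cnt++; }
          if (y > 0)        { acc += cur[id3(x,y-1,z)]; cnt++; }
          if (y < d[1]-1)   { acc += cur[id3(x,y+1,z)]; cnt++; }
          if (z > 0)        { acc += cur[id3(x,y,z-1)]; cnt++; }
          if (z < d[2]-1)   { acc += cur[id3(x,y,z+1)]; cnt++; }
          double val = cur[i] + dt * D * (acc - cnt * cur[i]);
          if (clamp01) { if (val < 0) val = 0; else if (val > 1) val = 1; }
          nxt[i] = val;
        }
    std::swap(cur, nxt);
  }
  cur.attr("dim") = v.attr("dim");
  return cur;
}

// [[Rcpp::export]]
NumericVector cpp_degrade_tm(NumericVector f, NumericVector m, double delta,
                             double dt, int nsteps) {
  NumericVector out = clone(f);
  for (int s = 0; s < nsteps; ++s)
    for (long i = 0; i < (long)out.size(); ++i) {
      double v = out[i] * (1.0 - delta * m[i] * dt);
      out[i] = v > 0 ? v : 0;
    }
  out.attr("dim") = f.attr("dim");
  return out;
}

// Random-plane split fractions through the COM of a voxel set (Monte-Carlo
// property of the mitosis plane chooser; shares the side rule with mitose).
// [[Rcpp::export]]
NumericVector cpp_random_split_fractions(IntegerVector mask, int n, int seed) {
  int d[3];
  {
    IntegerVector dims = mask.attr("dim");
    if (dims.size() != 3) stop("expected a 3D array");
    d[0] = dims[0]; d[1] = dims[1]; d[2] = dims[2];
  }
  std::vector<std::array<int,3>> vox;
  long i = 0;
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x, ++i)
        if (mask[i]) vox.push_back({x,y,z});
  if (vox.empty()) stop("empty mask");
  double cx = 0, cy = 0, cz = 0;
  for (const auto& v : vox) { cx += v[0]; cy += v[1]; cz += v[2]; }
  cx /= vox.size(); cy /= vox.size(); cz /= vox.size();
  Rng rng((uint64_t)(uint32_t)seed);
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    double ax = rng.normal(), ay = rng.normal(), az = rng.normal();
    double nrm = std::sqrt(ax*ax + ay*ay + az*az);
    if (nrm < 1e-12) { out[t] = NA_REAL; continue; }
    long pos = 0;
    for (const auto& v : vox)
      if ((v[0]-cx)*ax + (v[1]-cy)*ay + (v[2]-cz)*az >= 0) pos++;
    out[t] = (double)pos / vox.size();
  }
  return out;
}
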